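---
title: "Supersaturation scoring and its resampling tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supersaturation scoring and its resampling tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supersat)
```

## The model

A protein is *supersaturated* when its cellular concentration exceeds
its solubility. `supersat` scores this as

$$\sigma = C + Z,$$

with $C$ the log10 relative concentration and $Z$ an
aggregation-propensity z-score standing in for (negative log)
solubility. $Z$ scores — Zyggregator unfolded-state ($Z_{agg}$),
structurally corrected folded-state ($Z_{agg}^{SC}$), or TANGO — are
inputs supplied per protein; the package deliberately does not
recompute them from sequence. Five variants pair concentration sources
with Z columns (`SIGMA_VARIANTS`): cross-tissue or skeletal-muscle mRNA
with $Z_{agg}$ (the unfolded scores), and tissue protein abundance with
$Z_{agg}^{SC}$, $Z_{agg}$ or TANGO (the folded scores and its
sensitivity variants).

Scores are assembled per *database* — one table per tissue context
(healthy control HC, disease control DC, affected fiber AF, rimmed
vacuole RV) and variant — and recentered so the database median is 0.
Recentering is always per table, never per subset, so the median fold
change of a protein set over the proteome is simply
$\Delta = 10^{\mathrm{median}(\sigma)}$ over the set members present in
the table. A consequence used throughout: $\Delta$ is invariant to
adding any constant to all $C$ values, so unit conventions of the
concentration source do not matter.

### Concentration terms

Spectral counts are converted to relative abundance NSAF-style: divide
each count by the sample total, then by protein length (longer proteins
yield proportionally more peptides), then renormalize each sample to
sum 1. Replicates of a context are averaged on the *linear* scale and
then log10-transformed; proteins averaging zero are *absent*, never
imputed as $-\infty$ or with a pseudo-count, because downstream
analyses explicitly distinguish proteins expressed in some contexts but
not others. Microarray expression is processed in the opposite order —
log10 per value, then averaged per accession — because the two
measurement models differ (multiplicative array noise vs additive count
noise); RNA-seq FPKM values are averaged linearly across transcripts
and then logged. These orderings are contracts of the respective
functions and are tested.

Replicate averaging pools all samples of a context by default;
`per_patient = TRUE` produces per-patient tables for the paired tests.
Both pooling levels are exposed because published per-context tables
reflect pooled averaging while patient-matched testing needs the
per-patient form.

### RNA-seq q-values

Differential-expression q-values arrive two-tailed. Per accession the
*largest* transcript q is kept (the conservative choice) and converted
to one-tailed: $q/2$ when that transcript's fold-change direction
matches the tested tail, $1 - q/2$ otherwise. The direction is taken
from the same transcript that contributed the maximum q; when several
transcripts map to one accession this is a genuine free choice, made
for consistency between the magnitude and direction of the retained
evidence.

## Hypothesis tests and multiple testing

Subset-vs-proteome location shifts use the one-tailed
Wilcoxon/Mann-Whitney test: exact for tie-free samples of combined size
at most 40, otherwise the normal approximation with tie and continuity
correction (continuity correction is on by default and toggleable; the
approximation formula is computed directly for speed and unit-tested
against `wilcox.test`). Family-wise correction is Holm-Bonferroni,
step-down, applied within declarative *families* given in the panel
configuration — e.g. all unfolded-score analyses as one family, each
folded-score subset across the four contexts as its own family — so
that the correction structure is auditable data, not code.
Inclusion-enrichment and regulation calls use one-tailed paired t-tests
(or Welch tests when the two contexts come from different patients)
with Benjamini-Hochberg FDR at 5% per direction. Zero-variance
difference vectors, which leave the t-statistic undefined, resolve by
the sign of the common difference with a warning. Overlap questions use
the one-tailed Fisher exact test with the 2x2 table built from disjoint
rows (subset vs background excluding the subset); the
whole-background construction is available as an option, and with a
two-test Holm family the disjoint construction reproduces the adjusted
overlap p-values reported for such analyses.

## The Monte-Carlo ordering null

The escalation test asks whether a protein set's median $\Delta$ is
positive in every context and strictly increasing HC → DC → AF → RV.
Each of $K$ trials draws $N$ proteins (the set's *nominal* size, which
may exceed the members present in any one table) uniformly without
replacement from the universe — the union of proteins appearing in any
context table, matching the inclusion of proteins expressed in only
some contexts. Per context the trial median is computed over the
sampled proteins present there; a context with no sampled member makes
the trial score 0 (and the test aborts with a diagnostic if that
happens in more than 1% of trials). The *strict* criterion requires all
four medians positive and strictly ordered; the *relaxed* criterion
only the ordering.

Two quantities are reported. `p_null` $= \sum_k E_k / K$ is the chance
probability that a random set achieves the pattern. The p-value `p`
equals `p_null` when the observed set itself achieves the pattern and 1
otherwise: a set that does not escalate cannot reject the null,
whatever random sets do. Zero-exceedance runs report `p_null` at its
floor $1/K$ with an `at_floor` flag, since a Monte-Carlo p-value cannot
be 0. Under exchangeable contexts the relaxed `p_null` converges to
$1/4! = 1/24$, which the test suite uses as an analytic calibration
point. Note what `p_null` is *not*: it does not measure the strength of
the observed escalation, only the rarity of the qualitative pattern, so
even a perfectly escalating planted set cannot drive it below the
data-determined chance rate (about 1–2% for correlated context tables
of the kind the generator produces, with a floor of $1/384$ for fully
independent symmetric contexts). The comparative median-$\Delta$ test
is the magnitude-sensitive companion: it resamples the *difference* in
median $\Delta$ between two contexts and counts trials exceeding the
observed difference, one-tailed.

The trial loop is compiled (Rcpp) with an in-place partial Fisher-Yates
sampler driven by R's RNG, so runs are bit-reproducible from `set.seed`
and $K = 10^6$ on a 20000-protein universe takes seconds. Seeds are
mandatory arguments for every stochastic entry point, and the command
wrappers record seed, $K$, criterion and universe size in a JSON
sidecar.

## Gaussian-noise robustness

Robustness curves perturb every score with one mean-zero Gaussian draw
per protein at 100 noise levels (standard deviations linearly spaced
from $\log_{10} 1.1$ to $\log_{10} 10.1$; the spacing is a package
choice, the endpoints and count are fixed), 100 trials per level. Per
trial the subset-vs-proteome Mann-Whitney p (scaled by the size of the
original correction family) and the fold change
$d = 10^{\mathrm{median}(E) - \mathrm{median}(C)}$ are recomputed. A
level is "colored" when a one-sided one-sample t-test rejects the
hypothesis that the mean trial p is not below 0.05 (respectively that
the mean fold change is not above 1). The x-axis value is the median
over trials of the per-trial median linear noise magnitude
$m = 10^{|n|}$, with the standard error of the mean (sample sd over
$\sqrt{n}$) as error bar. The $m = 10^{|n|}$ reading implements the
intended "linear magnitude of noise"; alternative readings can be
plugged in at the trial level.

Two numerical facts shape what these curves can show. First, the sample
median is median-unbiased under symmetric noise, so for a subset that
is a pure location shift of the proteome the median fold change does
*not* decay with noise — it stays at the planted $\Delta$
indefinitely. Decay occurs when the subset distribution is skewed:
under heavy noise the median drifts toward the *mean*, so $d$ decays
toward $10^{\text{mean difference}}$. Left-skewed subsets — a shifted
majority plus a low-abundance minority, the shape real
inclusion-enriched sets have because some members are scarcely
expressed outside the inclusion — therefore show the characteristic
decay toward 1. Second, at large noise the Mann-Whitney statistic is
driven by the mean difference, so a subset with mean difference
exactly 0 loses significance quickly; persistence of the colored flag
up to noise magnitudes comparable with the signal requires a positive
mean difference. The validation fixture (480 values at
$N(0.525, 0.15)$ plus 120 at $N(-1.8, 0.2)$ against a 6000-protein
standard-normal proteome) balances the two: median shift
$\log_{10} 3$, small positive mean difference, fold change decaying
from 3 to about 1.6 across the grid while the significance flag stays
colored well past noise magnitude 3.

## The synthetic cohort generator

`generate_cohort` emulates the study design end to end: lognormal
protein lengths (median ≈ 450 residues), Gaussian log10 relative
abundances (sd 1), independent standard-normal propensity scores (an
optional correlation knob couples them to abundance), four contexts
with five patients each — disease contexts share patients so paired
designs work; healthy controls are separate patients — two replicates
per patient, and multinomial spectral counts per sample (total $10^4$
by default) with probabilities proportional to abundance × length.
Multinomial rather than independent Poisson counts make per-sample
normalization exact by construction, matching the relative-quantification
premise of spectral counting. The planted *metastable subproteome* (50
proteins from the upper abundance half) gains +0.2/+0.4/+0.6 log10 in
DC/AF/RV; a planted *downregulated set* (the top 5% most supersaturated
remaining proteins) loses 0.5 log10 in AF and RV. Per-patient
biological noise is 0.15 log10. These defaults were chosen once as
realistic study conditions and are the conditions under which the test
suite runs.

Because abundances are relative, planted increments are compressed by
closure: raising the subproteome's share depresses everyone else's, and
the distortion grows with the subproteome's share of total signal. The
generator does not model peptide-level detectability bias, protein
inference ambiguity, or missingness mechanisms other than sampling
zeros — passing tests demonstrate the statistical machinery, not
robustness to those real-data complications.

`generate_expression` emits matched microarray-like values (normal,
skeletal-muscle, cell-line and malignant arrays, so both processing
modes have work to do) and RNA-seq-like FPKM with 1–2 transcripts per
accession and two-tailed q-values from a simulated
5-vs-5-replicate t-test, exercising the q-conversion path against the
planted downregulated truth.

## Problem sizes and numerical choices

The shipped tests run scaled-down designs chosen for statistical
clarity: cohorts of 250–800 proteins for structural checks, the full
2000-protein default for the end-to-end acceptance checks, $K$ between
$10^3$ (smoke) and $2 \times 10^5$ (null calibration, where 3
Monte-Carlo standard errors around 1/24 is the asserted band), and the
exchangeability fixture uses a 20000-protein universe because on small
universes the conditional pattern probability given one realized
permutation set fluctuates beyond pure Monte-Carlo error (shared-value
coupling of order $N^2/n$). Medians of even-sized sets are the mean of
the two central values everywhere. Ties in `top_supersaturated` break
lexicographically by accession for determinism. Recentering asserts
median 0 to 1e-12 (floating-point exactness up to the even-median
average); per-sample normalization asserts column sums of 1 to 1e-9.

## Known limitations

- The escalation p-value is pattern-based, not magnitude-based (see
  above); use the comparative-$\Delta$ test for magnitude questions.
- Fold-change decay under noise reaches $10^{\text{mean difference}}$,
  not 1, within the grid's top noise level for any subset that also
  retains Mann-Whitney significance at moderate noise; the two
  robustness claims trade off against each other.
- Isoforms sharing an accession are treated as one row; identifier
  mapping is static-table only (ambiguous or unreviewed ids are
  excluded, never resolved online).
- Paired enrichment requires at least three matched patients and two
  complete pairs per protein; proteins failing that are silently
  untested (reported via `n_tested`).
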