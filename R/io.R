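# Table readers/writers. All files are tab-separated UTF-8 with a header
# row; missing values are empty cells (zero is a meaningful count and is
# never used to encode absence).

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE, na.strings = c("NA", "")),
    error = function(e) stop("cannot parse ", path, " (line 1): ",
                             conditionMessage(e)))
  if (!ncol(df)) stop("malformed header in ", path, " (line 1)")
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a spectral-count table with its sample metadata
#'
#' The count file has columns `id`, `length`, then one column per sample;
#' the metadata file has columns `sample_id`, `patient_id`, `context`,
#' `replicate`. Every metadata row must reference a count column and every
#' count column (beyond `id`/`length`) must be referenced.
#'
#' @param path count TSV path.
#' @param meta_path sample-metadata TSV path.
#' @return A [sample_table()].
#' @seealso [write_sample_table()]
#' @export
read_sample_table <- function(path, meta_path) {
  df <- read_tsv_checked(path)
  meta <- read_tsv_checked(meta_path)
  if (!all(c("id", "length") %in% names(df)))
    stop("count table must start with columns 'id' and 'length'")
  need <- c("sample_id", "patient_id", "context", "replicate")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  sample_cols <- setdiff(names(df), c("id", "length"))
  missing <- setdiff(meta$sample_id, sample_cols)
  if (length(missing))
    stop("metadata references absent sample column(s): ",
         paste(missing, collapse = ", "))
  unref <- setdiff(sample_cols, meta$sample_id)
  if (length(unref))
    stop("count column(s) not referenced by metadata: ",
         paste(unref, collapse = ", "))
  counts <- as.matrix(df[meta$sample_id])
  if (any(is.na(counts))) stop("missing values in count matrix")
  sample_table(counts,
               proteins = df[c("id", "length")],
               samples = meta[need])
}

#' Write a sample table and its metadata
#' @param x a [sample_table()].
#' @param path,meta_path output TSV paths for counts and metadata.
#' @export
write_sample_table <- function(x, path, meta_path) {
  stopifnot(inherits(x, "sample_table"))
  df <- cbind(x$proteins, as.data.frame(x$counts, check.names = FALSE))
  write_tsv(df, path)
  write_tsv(x$samples, meta_path)
  invisible(c(path, meta_path))
}

#' Read a protein set
#'
#' One accession per line, or a two-column `name<TAB>accession` format (the
#' last column is taken as the accession). A leading comment line of the
#' form `# name=<label> N=<int>` sets the set label and nominal size; the
#' nominal size defaults to the number of distinct accessions listed.
#'
#' @param path file path.
#' @param name fallback set label (defaults to the file name).
#' @return A [protein_set()].
#' @export
read_protein_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  nominal <- NULL
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("N=([0-9]+)", hdr[1]))[[1]]
    if (length(m) == 2) nominal <- as.integer(m[2])
    m <- regmatches(hdr[1], regexec("name=([^ \t]+)", hdr[1]))[[1]]
    if (length(m) == 2 && is.null(name)) name <- m[2]
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty protein set file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  acc <- vapply(parts, function(p) p[length(p)], character(1))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  protein_set(name, acc, nominal_size = nominal)
}

#' Write a protein set
#' @param x a [protein_set()].
#' @param path output path.
#' @export
write_protein_set <- function(x, path) {
  stopifnot(inherits(x, "protein_set"))
  writeLines(c(sprintf("# name=%s N=%d", x$name, x$nominal_size),
               x$members), path)
  invisible(path)
}

#' Read an aggregation-propensity table
#' @param path TSV with columns `id` and any of `z_agg`, `z_agg_sc`, `z_tango`.
#' @return A [propensity_table()].
#' @export
read_propensity_table <- function(path) propensity_table(read_tsv_checked(path))

#' Write an aggregation-propensity table
#' @param x a [propensity_table()].
#' @param path output path.
#' @export
write_propensity_table <- function(x, path) write_tsv(x, path)

#' Map raw identifiers to reviewed accessions
#'
#' Identifiers that resolve to exactly one reviewed accession are mapped;
#' those resolving to zero or to several are excluded from analysis
#' (exclusion is a result, not an error).
#'
#' @param raw_ids character vector of identifiers to map.
#' @param mapping data.frame with columns `raw` and `accession`, optionally
#'   a logical `reviewed` column (unreviewed rows are dropped first).
#' @return data.frame with columns `raw`, `accession` (NA when excluded)
#'   and `status` (`"mapped"`, `"ambiguous"` or `"unmapped"`).
#' @export
map_identifiers <- function(raw_ids, mapping) {
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  stopifnot(all(c("raw", "accession") %in% names(mapping)))
  if (!is.null(mapping$reviewed)) mapping <- mapping[as.logical(mapping$reviewed), ]
  hits <- split(mapping$accession, mapping$raw)
  res <- lapply(as.character(raw_ids), function(id) {
    h <- unique(hits[[id]])
    if (is.null(h) || !length(h)) list(NA_character_, "unmapped")
    else if (length(h) > 1) list(NA_character_, "ambiguous")
    else list(h, "mapped")
  })
  data.frame(raw = as.character(raw_ids),
             accession = vapply(res, `[[`, character(1), 1),
             status = vapply(res, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}
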