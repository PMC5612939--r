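#' Construct an OTU count table
#'
#' The central data container: a non-negative integer matrix with OTUs in
#' rows and samples in columns, plus optional per-sample metadata (time in
#' days, replicate label, group/habitat label). The orientation is fixed as
#' OTUs-in-rows; transposed input is never guessed.
#'
#' @param counts numeric matrix of non-negative integer counts with unique
#'   OTU ids as row names and unique sample ids as column names.
#' @param sample_meta optional `data.frame` with one row per sample and
#'   columns among `sample_id`, `time_days`, `replicate`, `group`. Rows are
#'   matched to `colnames(counts)` by `sample_id` and must cover exactly the
#'   samples of the table.
#'
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `sample_meta` (data.frame keyed by sample id).
#' @export
#' @examples
#' m <- matrix(c(5L, 1L, 0L, 0L, 2L, 3L), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' tab <- otu_table(m)
#' colSums(tab$counts)
otu_table <- function(counts, sample_meta = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("'counts' must be a numeric matrix (OTUs x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("'counts' must have OTU ids as row names and sample ids as column names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate OTU id: '%s'", rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample id: '%s'", colnames(counts)[duplicated(colnames(counts))][1L])
  bad <- which(!(is_wholenumber(counts) & counts >= 0))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stopf("counts must be non-negative integers; offending cell at OTU '%s', sample '%s' (value %s)",
          rownames(counts)[i[1L]], colnames(counts)[i[2L]], format(counts[bad[1L]]))
  }
  storage.mode(counts) <- "integer"

  meta <- empty_sample_meta(colnames(counts))
  if (!is.null(sample_meta)) {
    if (!is.data.frame(sample_meta) || !("sample_id" %in% names(sample_meta)))
      stopf("'sample_meta' must be a data.frame with a 'sample_id' column")
    sample_meta$sample_id <- as.character(sample_meta$sample_id)
    if (anyDuplicated(sample_meta$sample_id))
      stopf("duplicate sample id in metadata: '%s'",
            sample_meta$sample_id[duplicated(sample_meta$sample_id)][1L])
    idx <- match(colnames(counts), sample_meta$sample_id)
    if (anyNA(idx))
      stopf("metadata missing sample id(s): %s",
            paste(colnames(counts)[is.na(idx)], collapse = ", "))
    for (col in c("time_days", "replicate", "group"))
      if (col %in% names(sample_meta)) meta[[col]] <- sample_meta[[col]][idx]
    if (!is.null(meta$time_days)) {
      meta$time_days <- as.numeric(meta$time_days)
      if (any(meta$time_days < 0, na.rm = TRUE))
        stopf("'time_days' must be non-negative")
    }
  }
  structure(list(counts = counts, sample_meta = meta), class = "otu_table")
}

empty_sample_meta <- function(sample_ids) {
  data.frame(sample_id = as.character(sample_ids),
             time_days = NA_real_, replicate = NA_character_,
             group = NA_character_, stringsAsFactors = FALSE)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples, total reads %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  has <- vapply(c("time_days", "replicate", "group"),
                function(f) any(!is.na(x$sample_meta[[f]])), logical(1))
  if (any(has)) cat("metadata:", paste(names(has)[has], collapse = ", "), "\n")
  invisible(x)
}

#' Read an OTU count table from TSV
#'
#' Expects a UTF-8 tab-delimited file with a header row of sample ids and a
#' first column named `otu_id` holding OTU identifiers. An optional sidecar
#' metadata TSV maps `sample_id` to `time_days`, `replicate` and `group`.
#'
#' @param path path to the count table TSV.
#' @param meta_path optional path to a sample-metadata TSV.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stopf("cannot parse '%s': %s", path, conditionMessage(e)))
  if (nrow(df) == 0L) stopf("no data rows in '%s'", path)
  if (ncol(df) < 2L) stopf("'%s' has no sample columns", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("duplicate OTU id in '%s': '%s'", path, ids[duplicated(ids)][1L])
  if (anyDuplicated(names(df)[-1L]))
    stopf("duplicate sample id in '%s': '%s'", path,
          names(df)[-1L][duplicated(names(df)[-1L])][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric count cells in '%s'", path)
  rownames(m) <- ids
  meta <- if (!is.null(meta_path)) read_sample_metadata(meta_path) else NULL
  otu_table(m, sample_meta = meta)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, and optionally `time_days`,
#'   `replicate`, `group`.
#' @return A data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!("sample_id" %in% names(df)))
    stopf("metadata '%s' lacks a 'sample_id' column", path)
  df
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table()]: emits a header row of sample ids and a
#' first column `otu_id`.
#'
#' @param x an [otu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU-to-genus taxonomy map from TSV
#'
#' Genus strings are trimmed; empty or missing genera become the sentinel
#' `"unassigned"`. Matching against the copy-number lookup is done
#' case-insensitively downstream.
#'
#' @param path TSV with columns `otu_id` and `genus`.
#' @return Named character vector mapping OTU id to genus.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("otu_id", "genus") %in% names(df)))
    stopf("taxonomy '%s' must have columns 'otu_id' and 'genus'", path)
  ids <- as.character(df$otu_id)
  if (anyDuplicated(ids))
    stopf("duplicate OTU id in taxonomy '%s': '%s'", path,
          ids[duplicated(ids)][1L])
  gen <- trimws(as.character(df$genus))
  gen[is.na(gen) | gen == ""] <- "unassigned"
  stats::setNames(gen, ids)
}
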