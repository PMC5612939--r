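#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw, via [vegan::rrarefy()]) down to `depth`. Samples
#' whose total is below `depth` are dropped with a warning, never padded.
#' Deterministic given `seed`.
#'
#' @param x an [otu_table()].
#' @param depth target reads per sample, a positive integer.
#' @param seed integer seed controlling the subsampling.
#' @return An [otu_table()] whose retained columns each sum to `depth`.
#' @export
#' @examples
#' m <- matrix(c(10L, 0L, 4L, 6L), nrow = 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' rarefy(otu_table(m), depth = 10, seed = 1)
rarefy <- function(x, depth, seed) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.numeric(depth) || length(depth) != 1L || !is_wholenumber(depth) ||
      depth <= 0)
    stopf("'depth' must be a positive integer")
  depth <- as.integer(depth)
  totals <- colSums(x$counts)
  keep <- totals >= depth
  if (!any(keep)) {
    warnf("all %d samples have fewer than %d reads; returning empty table",
          ncol(x$counts), depth)
    out <- x
    out$counts <- x$counts[, 0, drop = FALSE]
    out$sample_meta <- x$sample_meta[0, , drop = FALSE]
    return(out)
  }
  if (any(!keep))
    warnf("dropping %d sample(s) below depth %d: %s", sum(!keep), depth,
          paste(colnames(x$counts)[!keep], collapse = ", "))
  counts <- x$counts[, keep, drop = FALSE]
  sub <- withr::with_seed(as.integer(seed), {
    # muffle vegan's heuristic "should be used for observed counts" note,
    # which fires on legitimate count tables
    withCallingHandlers(
      t(vegan::rrarefy(t(counts), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  })
  storage.mode(sub) <- "integer"
  dimnames(sub) <- dimnames(counts)
  out <- x
  out$counts <- sub
  out$sample_meta <- x$sample_meta[keep, , drop = FALSE]
  rownames(out$sample_meta) <- NULL
  out
}

#' Relative abundances per sample
#'
#' Converts counts to proportions. With a `subset` of OTU ids and
#' `renormalize = TRUE`, proportions are computed over the subset's counts
#' only (each retained column sums to 1); with `renormalize = FALSE` the
#' whole-sample totals stay in the denominator. All-zero samples are
#' flagged, not an error.
#'
#' @param x an [otu_table()].
#' @param subset optional character vector of OTU ids to restrict to.
#' @param renormalize logical; recompute denominators over `subset` only.
#' @return An object of class `rel_abundance`: list with `props` (numeric
#'   matrix), `sample_meta`, `zero_samples` (ids whose denominator was 0)
#'   and `renormalized`.
#' @export
relative_abundance <- function(x, subset = NULL, renormalize = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  if (!is.null(subset)) {
    subset <- intersect(as.character(subset), rownames(counts))
    if (length(subset) == 0L) stopf("empty subset intersection")
    sub_counts <- counts[subset, , drop = FALSE]
  } else {
    sub_counts <- counts
  }
  denom <- if (renormalize) colSums(sub_counts) else colSums(counts)
  zero <- colnames(counts)[denom == 0]
  denom[denom == 0] <- 1  # keeps all-zero columns at 0 without dividing by 0
  props <- sweep(sub_counts, 2L, denom, "/")
  structure(list(props = props, sample_meta = x$sample_meta,
                 zero_samples = zero, renormalized = isTRUE(renormalize)),
            class = "rel_abundance")
}

#' @export
print.rel_abundance <- function(x, ...) {
  cat(sprintf("Relative abundances: %d OTUs x %d samples%s\n",
              nrow(x$props), ncol(x$props),
              if (x$renormalized) " (renormalized over subset)" else ""))
  if (length(x$zero_samples))
    cat("all-zero samples:", paste(x$zero_samples, collapse = ", "), "\n")
  invisible(x)
}
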