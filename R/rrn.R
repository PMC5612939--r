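#' Round a mean rrn copy number to its integer trait value
#'
#' Genus-level copy-number databases report averages over sequenced genomes;
#' the trait analysis needs integers in the biological range 1-15. The
#' default rounds half-up to the nearest integer ("half-up"); "ceiling"
#' always rounds up. Results are clamped into \[1, 15\].
#'
#' @param mean_copies positive numeric vector of mean copy numbers.
#' @param method `"half-up"` (default) or `"ceiling"`.
#' @return Integer vector in \[1, 15\].
#' @export
#' @examples
#' round_copy_number(c(2.4, 3.5, 16.2))  # 2 4 15
round_copy_number <- function(mean_copies, method = c("half-up", "ceiling")) {
  method <- match.arg(method)
  if (!is.numeric(mean_copies) || any(!is.finite(mean_copies)) ||
      any(mean_copies <= 0))
    stopf("'mean_copies' must be positive finite numbers")
  r <- switch(method,
              "half-up" = floor(mean_copies + 0.5),
              "ceiling" = ceiling(mean_copies))
  as.integer(pmin(pmax(r, 1), 15))
}

#' Construct a genus-level rrn copy-number lookup
#'
#' @param genus character vector of genus names (unique after trimming,
#'   case-insensitively).
#' @param mean_copies positive numeric vector of mean copy numbers.
#' @param rounding rounding convention, see [round_copy_number()].
#' @return An object of class `rrn_lookup`: data.frame with columns
#'   `genus`, `mean_copies`, `copies_int`, plus the normalized key used for
#'   matching.
#' @export
rrn_lookup <- function(genus, mean_copies, rounding = c("half-up", "ceiling")) {
  rounding <- match.arg(rounding)
  genus <- trimws(as.character(genus))
  if (length(genus) != length(mean_copies))
    stopf("'genus' and 'mean_copies' lengths differ")
  if (any(genus == "")) stopf("empty genus name in lookup")
  key <- normalize_genus(genus)
  if (anyDuplicated(key))
    stopf("duplicate genus in lookup: '%s'", genus[duplicated(key)][1L])
  mean_copies <- as.numeric(mean_copies)
  bad <- which(!is.finite(mean_copies) | mean_copies <= 0)
  if (length(bad))
    stopf("non-positive mean_copies for genus '%s'", genus[bad[1L]])
  out <- data.frame(genus = genus, mean_copies = mean_copies,
                    copies_int = round_copy_number(mean_copies, rounding),
                    stringsAsFactors = FALSE)
  attr(out, "key") <- key
  attr(out, "rounding") <- rounding
  class(out) <- c("rrn_lookup", "data.frame")
  out
}

#' Load a genus -> mean copy number lookup from TSV
#'
#' Accepts the tab-separated export format `genus<TAB>mean_copies` (header
#' required), e.g. a genus-level extract of a copy-number database. A small
#' synthetic fixture spanning rrn 1-15 ships with the package:
#' `system.file("extdata", "rrn_lookup_synthetic.tsv", package = "rrntraits")`.
#'
#' @param path path to the TSV.
#' @param rounding rounding convention, see [round_copy_number()].
#' @return An [rrn_lookup()].
#' @export
load_rrn_lookup <- function(path, rounding = c("half-up", "ceiling")) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("genus", "mean_copies") %in% names(df)))
    stopf("lookup '%s' must have columns 'genus' and 'mean_copies'", path)
  rrn_lookup(df$genus, df$mean_copies, rounding = match.arg(rounding))
}

#' Assign integer rrn copy numbers to OTUs at genus level
#'
#' Every OTU whose genus has a lookup entry receives that genus's integer
#' copy number; OTUs with genus `"unassigned"`, missing from the taxonomy,
#' or absent from the lookup are reported in `unassigned`, never silently
#' dropped. Genus matching is case-insensitive after trimming.
#'
#' @param x an [otu_table()].
#' @param taxonomy named character vector OTU id -> genus
#'   (see [read_taxonomy()]).
#' @param lookup an [rrn_lookup()].
#' @return An object of class `rrn_assignment`: list with `copies` (named
#'   integer vector over assigned OTUs), `genus` (named character vector of
#'   their genera) and `unassigned` (character vector of OTU ids).
#' @export
assign_rrn <- function(x, taxonomy, lookup) {
  stopifnot(inherits(x, "otu_table"), inherits(lookup, "rrn_lookup"))
  otus <- rownames(x$counts)
  gen <- taxonomy[otus]
  gen[is.na(gen)] <- "unassigned"
  gen <- trimws(gen)
  gen[gen == ""] <- "unassigned"
  key <- normalize_genus(gen)
  idx <- match(key, attr(lookup, "key"))
  idx[key == "unassigned"] <- NA_integer_
  hit <- !is.na(idx)
  structure(list(
    copies = stats::setNames(lookup$copies_int[idx[hit]], otus[hit]),
    genus = stats::setNames(lookup$genus[idx[hit]], otus[hit]),
    unassigned = otus[!hit]
  ), class = "rrn_assignment")
}

#' @export
print.rrn_assignment <- function(x, ...) {
  cat(sprintf("rrn assignment: %d OTUs assigned (%d genera), %d unassigned\n",
              length(x$copies), length(unique(x$genus)), length(x$unassigned)))
  if (length(x$copies))
    print(table(rrn = x$copies))
  invisible(x)
}
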