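#' Core genera shared across datasets
#'
#' Identifies the genera detected in every dataset under comparison ("core"
#' biofilm formers). A genus counts as present in a dataset when at least
#' one of its OTUs reaches `min_count` reads in at least `min_prevalence`
#' samples of that dataset. The sentinel genus `"unassigned"` never enters
#' the core.
#'
#' @param tables list of [otu_table()] objects, one per dataset.
#' @param taxonomies list (same length) of named OTU -> genus vectors, or a
#'   single vector recycled for all tables.
#' @param min_count minimum reads for an OTU to count as detected.
#' @param min_prevalence minimum number of samples in which the genus must
#'   be detected.
#' @return List with `genera` (sorted character vector, possibly empty with
#'   a warning) and `coverage` (per-table fraction of OTUs belonging to
#'   core genera).
#' @export
core_genera <- function(tables, taxonomies, min_count = 1, min_prevalence = 1) {
  if (inherits(tables, "otu_table")) tables <- list(tables)
  if (is.character(taxonomies)) taxonomies <- rep(list(taxonomies), length(tables))
  if (length(tables) < 1L) stopf("need at least one table")
  if (length(taxonomies) != length(tables))
    stopf("'taxonomies' must match 'tables' in length")

  per_table_genera <- vector("list", length(tables))
  otu_genus <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    stopifnot(inherits(tab, "otu_table"))
    gen <- taxonomies[[i]][rownames(tab$counts)]
    gen[is.na(gen) | trimws(gen) == ""] <- "unassigned"
    gen <- trimws(gen)
    otu_genus[[i]] <- gen
    detected <- rowSums(tab$counts >= min_count) >= min_prevalence
    g <- unique(normalize_genus(gen[detected]))
    per_table_genera[[i]] <- setdiff(g, "unassigned")
  }
  core <- Reduce(intersect, per_table_genera)
  if (length(core) == 0L)
    warnf("no genus is shared across all %d tables", length(tables))
  # report core in the capitalization of the first table that carries it
  pretty <- character(0)
  all_gen <- unlist(otu_genus, use.names = FALSE)
  for (g in sort(core))
    pretty <- c(pretty, all_gen[match(g, normalize_genus(all_gen))])
  coverage <- vapply(seq_along(tables), function(i)
    mean(normalize_genus(otu_genus[[i]]) %in% core), numeric(1))
  names(coverage) <- names(tables) %||% paste0("table", seq_along(tables))
  list(genera = pretty, coverage = coverage)
}

#' Bin assigned OTUs into LCN and HCN trait classes
#'
#' Low copy number (LCN) taxa carry 1-3 rrn copies; high copy number (HCN)
#' taxa carry 4-15. The two classes partition the full 1-15 range.
#'
#' @param assignment an [assign_rrn()] result.
#' @return Named factor (`"LCN"`/`"HCN"`) over the assigned OTU ids.
#' @export
bin_rrn <- function(assignment) {
  stopifnot(inherits(assignment, "rrn_assignment"))
  factor(ifelse(assignment$copies >= 4L, "HCN", "LCN"),
         levels = c("LCN", "HCN"))
}

#' Community-aggregated rrn trait profile of one sample
#'
#' Computes, over the assigned OTUs of one sample: the summed relative
#' abundance of LCN (rrn 1-3) and HCN (rrn 4-15) taxa, their ratio
#' HCN:LCN, the abundance-weighted community mean copy number, the
#' unweighted mean over taxa present, and the number of distinct genera
#' with non-zero abundance in each class. The ratio is `NA` (undefined)
#' when LCN abundance is zero, never infinite; a sample with zero assigned
#' abundance yields an all-`NA` profile flagged `undefined`.
#'
#' @param rel a [relative_abundance()] result. For LCN + HCN to sum to 1 it
#'   should be computed over the assigned (core) OTUs with
#'   `renormalize = TRUE`.
#' @param assignment an [assign_rrn()] result.
#' @param sample_id which sample column to profile.
#' @param presence_by `"otu"` (default) averages presence-based rrn over
#'   OTUs; `"genus"` collapses to one value per genus first.
#' @return One-row data.frame with columns `sample_id`, `lcn_abund`,
#'   `hcn_abund`, `ratio_hcn_lcn`, `cwm_rrn_abundance`,
#'   `mean_rrn_presence`, `n_genera_lcn`, `n_genera_hcn`, `undefined`.
#' @export
trait_profile <- function(rel, assignment, sample_id,
                          presence_by = c("otu", "genus")) {
  stopifnot(inherits(rel, "rel_abundance"),
            inherits(assignment, "rrn_assignment"))
  presence_by <- match.arg(presence_by)
  if (!sample_id %in% colnames(rel$props))
    stopf("unknown sample id '%s'", sample_id)
  otus <- intersect(rownames(rel$props), names(assignment$copies))
  p <- rel$props[otus, sample_id]
  rrn <- assignment$copies[otus]
  gen <- assignment$genus[otus]
  tot <- sum(p)
  if (length(otus) == 0L || tot <= 0) {
    return(data.frame(sample_id = sample_id, lcn_abund = NA_real_,
                      hcn_abund = NA_real_, ratio_hcn_lcn = NA_real_,
                      cwm_rrn_abundance = NA_real_,
                      mean_rrn_presence = NA_real_,
                      n_genera_lcn = 0L, n_genera_hcn = 0L,
                      undefined = TRUE, stringsAsFactors = FALSE))
  }
  hcn <- rrn >= 4L
  lcn_abund <- sum(p[!hcn])
  hcn_abund <- sum(p[hcn])
  ratio <- if (lcn_abund > 0) hcn_abund / lcn_abund else NA_real_
  # weighted mean normalized by total assigned abundance so the value stays
  # in [1,15] also when proportions were not renormalized over the subset
  cwm <- sum(p * rrn) / tot
  present <- p > 0
  mrp <- if (presence_by == "otu") {
    mean(rrn[present])
  } else {
    mean(tapply(rrn[present], gen[present], function(v) v[1L]))
  }
  data.frame(sample_id = sample_id,
             lcn_abund = lcn_abund, hcn_abund = hcn_abund,
             ratio_hcn_lcn = ratio, cwm_rrn_abundance = cwm,
             mean_rrn_presence = mrp,
             n_genera_lcn = length(unique(gen[present & !hcn])),
             n_genera_hcn = length(unique(gen[present & hcn])),
             undefined = FALSE, stringsAsFactors = FALSE)
}

#' Trait profiles for every sample of a table
#'
#' Convenience pipeline: assigns rrn copy numbers, optionally restricts to
#' a set of core genera, computes relative abundances over the assigned
#' OTUs (renormalized by default so LCN + HCN = 1), and profiles each
#' sample. Sample metadata columns are carried along.
#'
#' @param x an [otu_table()].
#' @param taxonomy named OTU -> genus vector.
#' @param lookup an [rrn_lookup()].
#' @param core optional character vector of genera to restrict to (e.g.
#'   from [core_genera()]).
#' @param renormalize logical; renormalize proportions over the assigned
#'   (core) OTUs (default `TRUE`).
#' @param presence_by see [trait_profile()].
#' @return data.frame with one row per sample: all [trait_profile()] fields
#'   plus `time_days`, `replicate`, `group` from the table metadata.
#' @export
trait_profiles <- function(x, taxonomy, lookup, core = NULL,
                           renormalize = TRUE,
                           presence_by = c("otu", "genus")) {
  stopifnot(inherits(x, "otu_table"))
  presence_by <- match.arg(presence_by)
  asg <- assign_rrn(x, taxonomy, lookup)
  if (!is.null(core)) {
    keep <- names(asg$genus)[normalize_genus(asg$genus) %in%
                               normalize_genus(core)]
    asg$copies <- asg$copies[keep]
    asg$genus <- asg$genus[keep]
  }
  if (length(asg$copies) == 0L)
    stopf("no assigned OTUs left to profile")
  rel <- relative_abundance(x, subset = names(asg$copies),
                            renormalize = renormalize)
  rows <- lapply(colnames(x$counts), function(s)
    trait_profile(rel, asg, s, presence_by = presence_by))
  out <- do.call(rbind, rows)
  cbind(out, x$sample_meta[match(out$sample_id, x$sample_meta$sample_id),
                           c("time_days", "replicate", "group")],
        row.names = NULL)
}

#' Ratio of genera counts between the HCN and LCN classes
#'
#' Counts may be replicate means, hence real-valued.
#'
#' @param n_hcn number (or mean number) of genera in the HCN class.
#' @param n_lcn number (or mean number) of genera in the LCN class.
#' @return `n_hcn / n_lcn`; `NA` with a warning when `n_lcn` is 0.
#' @export
#' @examples
#' genera_ratio(34.3, 97.4)  # 0.352...
genera_ratio <- function(n_hcn, n_lcn) {
  assert_scalar_number(n_hcn, "n_hcn")
  assert_scalar_number(n_lcn, "n_lcn")
  if (n_hcn < 0 || n_lcn < 0) stopf("genera counts must be non-negative")
  if (n_lcn == 0) {
    warnf("LCN genera count is 0; ratio undefined")
    return(NA_real_)
  }
  n_hcn / n_lcn
}

#' Replicate-averaged succession trajectory of a trait field
#'
#' Aggregates a trait field across replicates at each time point and labels
#' time points as the `"initial"` succession phase (time <= `phase_cut`,
#' inclusive) or `"late"`. Undefined (`NA`) values are skipped with a
#' warning and a reduced replicate count.
#'
#' @param profiles data.frame from [trait_profiles()] (needs `time_days`
#'   and `replicate` metadata).
#' @param field name of the trait column to aggregate.
#' @param phase_cut phase boundary in days (default 25, inclusive).
#' @return data.frame with `time_days` (strictly increasing), `mean`, `sd`
#'   (0 for a single replicate), `n`, `phase`.
#' @export
trajectory <- function(profiles, field = "ratio_hcn_lcn", phase_cut = 25) {
  if (!all(c("time_days", "replicate", field) %in% names(profiles)))
    stopf("profiles need 'time_days', 'replicate' and '%s' columns", field)
  if (any(is.na(profiles$time_days)) || any(is.na(profiles$replicate)))
    stopf("every sample needs time_days and replicate metadata")
  v <- profiles[[field]]
  if (anyNA(v)) {
    warnf("%d undefined value(s) in '%s' skipped; reduced n at affected time points",
          sum(is.na(v)), field)
  }
  keep <- !is.na(v)
  tp <- sort(unique(profiles$time_days))
  agg <- lapply(tp, function(t) {
    vals <- v[keep & profiles$time_days == t]
    data.frame(time_days = t,
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) > 1L) stats::sd(vals) else 0,
               n = length(vals))
  })
  out <- do.call(rbind, agg)
  out$phase <- ifelse(out$time_days <= phase_cut, "initial", "late")
  out
}

#' Per-sample summed abundance by integer rrn value
#'
#' The table behind rrn-class composition bar charts: for each integer copy
#' number present in the assignment, the summed relative abundance per
#' sample.
#'
#' @param rel a [relative_abundance()] result.
#' @param assignment an [assign_rrn()] result.
#' @return Numeric matrix, rrn values x samples.
#' @export
rrn_value_abundance <- function(rel, assignment) {
  stopifnot(inherits(rel, "rel_abundance"),
            inherits(assignment, "rrn_assignment"))
  otus <- intersect(rownames(rel$props), names(assignment$copies))
  rrn <- assignment$copies[otus]
  vals <- sort(unique(rrn))
  out <- vapply(colnames(rel$props), function(s)
    vapply(vals, function(v) sum(rel$props[otus[rrn == v], s]), numeric(1)),
    numeric(length(vals)))
  out <- matrix(out, nrow = length(vals),
                dimnames = list(vals, colnames(rel$props)))
  out
}
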