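# Synthetic genus-structured communities with known rrn trait composition.
# Counts are Dirichlet-multinomial (rarefied amplicon tables are
# overdispersed multinomials); genus base abundances follow a geometric
# rank-abundance series, a simple long-tailed model of biofilm communities.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) return(rep(1 / length(alpha), length(alpha)))
  g / s
}

default_rrn_spectrum <- function() {
  # LCN-dominated community with a mode at rrn 2 and a small rrn-9 tail,
  # the composition typical of stream biofilm core genera
  c(`1` = 8L, `2` = 18L, `3` = 14L, `4` = 6L, `5` = 8L, `6` = 2L, `9` = 4L)
}

#' Configuration of a synthetic biofilm succession experiment
#'
#' Defaults emulate a 45-day two-regime flume experiment: 60 core genera
#' with an LCN-dominated copy-number spectrum, 3 OTUs per genus, 8 sampling
#' days, 3 replicates, sequencing depth 10^4 and moderate
#' Dirichlet-multinomial overdispersion. The "eutrophic" regime starts with
#' HCN taxa boosted by a factor `1 + hcn_boost_initial` that decays
#' exponentially at `decay_rate` per day, so the two regimes converge after
#' the initial phase (`phase_cut`, default day 25). `hcn_boost_initial = 0`
#' in both regimes is the null scenario (no time-by-class interaction).
#'
#' @param n_genera number of genera.
#' @param rrn_spectrum named integer vector, copy number -> number of
#'   genera; must sum to `n_genera`.
#' @param otus_per_genus OTUs per genus.
#' @param time_points sampling days.
#' @param n_replicates replicate flumes per regime and day (default 3).
#' @param regimes named list; each element a list with `hcn_boost_initial`
#'   (>= 0).
#' @param phase_cut initial-phase boundary in days (inclusive).
#' @param decay_rate exponential decay of the HCN boost, per day.
#' @param depth reads per sample.
#' @param overdispersion Dirichlet concentration (larger = closer to
#'   multinomial).
#' @param rank_k geometric rank-abundance parameter in (0, 1).
#' @return A validated list of class `succession_config`.
#' @export
succession_config <- function(n_genera = 60L,
                              rrn_spectrum = default_rrn_spectrum(),
                              otus_per_genus = 3L,
                              time_points = c(4, 8, 12, 18, 25, 32, 39, 45),
                              n_replicates = 3L,
                              regimes = list(
                                oligotrophic = list(hcn_boost_initial = 0),
                                eutrophic = list(hcn_boost_initial = 1)),
                              phase_cut = 25, decay_rate = 0.1,
                              depth = 10000L, overdispersion = 200,
                              rank_k = 0.05) {
  if (sum(rrn_spectrum) != n_genera)
    stopf("rrn_spectrum must sum to n_genera (%d != %d)",
          sum(rrn_spectrum), n_genera)
  rrn_vals <- as.integer(names(rrn_spectrum))
  if (any(is.na(rrn_vals)) || any(rrn_vals < 1L) || any(rrn_vals > 15L))
    stopf("rrn_spectrum names must be integers in [1, 15]")
  if (is.null(names(regimes)) || any(!nzchar(names(regimes))))
    stopf("'regimes' must be a named list")
  for (r in regimes)
    if (is.null(r$hcn_boost_initial) || r$hcn_boost_initial < 0)
      stopf("each regime needs hcn_boost_initial >= 0")
  if (depth < n_genera)
    warnf("depth %d below n_genera %d: tables will be sparse", depth, n_genera)
  stopifnot(otus_per_genus >= 1, n_replicates >= 1, decay_rate >= 0,
            overdispersion > 0, rank_k > 0, rank_k < 1,
            all(diff(time_points) > 0), all(time_points >= 0))
  structure(list(n_genera = as.integer(n_genera),
                 rrn_spectrum = rrn_spectrum,
                 otus_per_genus = as.integer(otus_per_genus),
                 time_points = time_points,
                 n_replicates = as.integer(n_replicates),
                 regimes = regimes, phase_cut = phase_cut,
                 decay_rate = decay_rate, depth = as.integer(depth),
                 overdispersion = overdispersion, rank_k = rank_k),
            class = "succession_config")
}

# shared machinery: genus identities, rrn values, base OTU composition
build_community <- function(n_genera, rrn_spectrum, otus_per_genus, rank_k) {
  genera <- sprintf("Genus%03d", seq_len(n_genera))
  rrn_per_genus <- sample(rep(as.integer(names(rrn_spectrum)), rrn_spectrum))
  genus_props <- rank_k * (1 - rank_k)^(seq_len(n_genera) - 1)
  genus_props <- genus_props / sum(genus_props)
  otu_ids <- as.vector(t(outer(genera, seq_len(otus_per_genus),
                               function(g, k) sprintf("%s_OTU%d", g, k))))
  otu_genus <- rep(genera, each = otus_per_genus)
  otu_rrn <- rep(rrn_per_genus, each = otus_per_genus)
  # how each genus's abundance is split across its OTUs, drawn once
  w <- unlist(lapply(seq_len(n_genera), function(i)
    rdirichlet1(rep(5, otus_per_genus))))
  base_props <- rep(genus_props, each = otus_per_genus) * w
  list(otu_ids = otu_ids,
       taxonomy = stats::setNames(otu_genus, otu_ids),
       otu_rrn = stats::setNames(otu_rrn, otu_ids),
       lookup = rrn_lookup(genera, as.numeric(rrn_per_genus)),
       base_props = stats::setNames(base_props, otu_ids))
}

sample_counts <- function(expected_props, depth, overdispersion) {
  p <- rdirichlet1(overdispersion * expected_props)
  as.integer(stats::rmultinom(1L, size = depth, prob = p))
}

#' Generate a synthetic two-regime biofilm succession experiment
#'
#' Produces one OTU table per regime together with the taxonomy, the
#' genus-level copy-number lookup and a ground-truth record (true per-OTU
#' rrn, exact expected LCN/HCN proportions and HCN:LCN ratio per sample).
#' Bit-reproducible given `seed`.
#'
#' @param config a [succession_config()].
#' @param seed integer seed.
#' @return List with `tables` (named list of [otu_table()], one per
#'   regime), `taxonomy`, `lookup`, `truth` (list with `otu_rrn` and a
#'   per-sample `expected` data.frame), `config`, `seed`.
#' @export
generate_succession <- function(config = succession_config(), seed) {
  stopifnot(inherits(config, "succession_config"))
  withr::with_seed(as.integer(seed), {
    com <- build_community(config$n_genera, config$rrn_spectrum,
                           config$otus_per_genus, config$rank_k)
    hcn <- com$otu_rrn >= 4L
    tables <- list()
    expected <- list()
    for (rg in names(config$regimes)) {
      boost <- config$regimes[[rg]]$hcn_boost_initial
      cols <- list(); meta <- list()
      for (t in config$time_points) {
        f <- 1 + boost * exp(-config$decay_rate * t)
        ep <- com$base_props * ifelse(hcn, f, 1)
        ep <- ep / sum(ep)
        for (rep_i in seq_len(config$n_replicates)) {
          sid <- sprintf("%s_t%02d_r%d", rg, as.integer(round(t)), rep_i)
          cols[[sid]] <- sample_counts(ep, config$depth,
                                       config$overdispersion)
          meta[[sid]] <- data.frame(sample_id = sid, time_days = t,
                                    replicate = paste0("R", rep_i),
                                    group = rg, stringsAsFactors = FALSE)
          expected[[sid]] <- data.frame(
            sample_id = sid, group = rg, time_days = t,
            replicate = paste0("R", rep_i),
            exp_lcn = sum(ep[!hcn]), exp_hcn = sum(ep[hcn]),
            exp_ratio = sum(ep[hcn]) / sum(ep[!hcn]),
            stringsAsFactors = FALSE)
        }
      }
      counts <- do.call(cbind, cols)
      rownames(counts) <- com$otu_ids
      tables[[rg]] <- otu_table(counts, do.call(rbind, meta))
    }
    list(tables = tables, taxonomy = com$taxonomy, lookup = com$lookup,
         truth = list(otu_rrn = com$otu_rrn,
                      expected = do.call(rbind, c(expected,
                                                  make.row.names = FALSE))),
         config = config, seed = as.integer(seed))
  })
}

#' Configuration of a synthetic two-stream-type comparison
#'
#' Two habitat groups sharing one community, where the HCN taxa of each
#' group are scaled by `exp(mean_rrn_shift)`; `mean_rrn_shift = 0` in both
#' groups is the null. Compositional machinery (rank-abundance, OTU split,
#' Dirichlet-multinomial counts) matches [succession_config()].
#'
#' @param groups named list of two lists, each with `mean_rrn_shift`.
#' @param n_samples samples per group.
#' @inheritParams succession_config
#' @return A validated list of class `stream_config`.
#' @export
stream_config <- function(groups = list(
                            glacier_fed = list(mean_rrn_shift = 0.5),
                            subalpine = list(mean_rrn_shift = 0)),
                          n_samples = 20L, n_genera = 60L,
                          rrn_spectrum = default_rrn_spectrum(),
                          otus_per_genus = 3L, depth = 10000L,
                          overdispersion = 200, rank_k = 0.05) {
  if (length(groups) != 2L || is.null(names(groups)))
    stopf("'groups' must be a named list of two group specs")
  for (g in groups)
    if (is.null(g$mean_rrn_shift) || !is.finite(g$mean_rrn_shift))
      stopf("each group needs a finite mean_rrn_shift")
  if (sum(rrn_spectrum) != n_genera)
    stopf("rrn_spectrum must sum to n_genera")
  structure(list(groups = groups, n_samples = as.integer(n_samples),
                 n_genera = as.integer(n_genera),
                 rrn_spectrum = rrn_spectrum,
                 otus_per_genus = as.integer(otus_per_genus),
                 depth = as.integer(depth), overdispersion = overdispersion,
                 rank_k = rank_k),
            class = "stream_config")
}

#' Generate synthetic stream-type communities
#'
#' @param config a [stream_config()].
#' @param seed integer seed.
#' @return List with `tables` (one [otu_table()] per group), `taxonomy`,
#'   `lookup`, `truth` (per-OTU rrn and per-group expected
#'   abundance-weighted mean rrn), `config`, `seed`.
#' @export
generate_streams <- function(config = stream_config(), seed) {
  stopifnot(inherits(config, "stream_config"))
  withr::with_seed(as.integer(seed), {
    com <- build_community(config$n_genera, config$rrn_spectrum,
                           config$otus_per_genus, config$rank_k)
    hcn <- com$otu_rrn >= 4L
    tables <- list(); exp_cwm <- numeric(0)
    for (gname in names(config$groups)) {
      f <- exp(config$groups[[gname]]$mean_rrn_shift)
      ep <- com$base_props * ifelse(hcn, f, 1)
      ep <- ep / sum(ep)
      exp_cwm[gname] <- sum(ep * com$otu_rrn)
      cols <- lapply(seq_len(config$n_samples), function(i)
        sample_counts(ep, config$depth, config$overdispersion))
      counts <- do.call(cbind, cols)
      dimnames(counts) <- list(com$otu_ids,
                               sprintf("%s_s%02d", gname,
                                       seq_len(config$n_samples)))
      meta <- data.frame(sample_id = colnames(counts), group = gname,
                         stringsAsFactors = FALSE)
      tables[[gname]] <- otu_table(counts, meta)
    }
    list(tables = tables, taxonomy = com$taxonomy, lookup = com$lookup,
         truth = list(otu_rrn = com$otu_rrn, expected_cwm_rrn = exp_cwm),
         config = config, seed = as.integer(seed))
  })
}

#' Generate noisy logistic growth curves with known parameters
#'
#' Values follow the Zwietering logistic at the given times plus i.i.d.
#' Gaussian noise, truncated at 0.
#'
#' @param A,mu_max,lag true curve parameters (`A`, `mu_max` > 0,
#'   `lag` >= 0).
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @param times observation times (days).
#' @param n_replicates number of replicate curves.
#' @param seed integer seed.
#' @return List with `curves` (data.frame `label`, `time_days`, `value`)
#'   and `truth` (the parameters).
#' @export
generate_growth_curves <- function(A = 100, mu_max = 5, lag = 2,
                                   noise_sd = 5,
                                   times = seq(0, 20, length.out = 20),
                                   n_replicates = 3L, seed) {
  stopifnot(A > 0, mu_max > 0, lag >= 0, noise_sd >= 0,
            all(diff(times) > 0))
  curves <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_len(n_replicates), function(i) {
      y <- logistic_zwietering(times, A, mu_max, lag) +
        stats::rnorm(length(times), 0, noise_sd)
      data.frame(label = sprintf("rep%d", i), time_days = times,
                 value = pmax(y, 0), stringsAsFactors = FALSE)
    }))
  })
  list(curves = curves,
       truth = list(A = A, mu_max = mu_max, lag = lag,
                    noise_sd = noise_sd))
}
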