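test_that("generators are bit-reproducible given the seed", {
  cfg <- succession_config(n_genera = 12L,
                           rrn_spectrum = c(`2` = 6L, `5` = 6L),
                           time_points = c(5, 30), depth = 500L)
  a <- generate_succession(cfg, seed = 7)
  b <- generate_succession(cfg, seed = 7)
  expect_identical(a$tables$eutrophic$counts, b$tables$eutrophic$counts)
  expect_identical(a$truth$expected, b$truth$expected)
  c <- generate_succession(cfg, seed = 8)
  expect_false(identical(a$tables$eutrophic$counts,
                         c$tables$eutrophic$counts))

  g1 <- generate_growth_curves(seed = 3)$curves
  g2 <- generate_growth_curves(seed = 3)$curves
  expect_identical(g1, g2)

  s1 <- generate_streams(seed = 5)
  s2 <- generate_streams(seed = 5)
  expect_identical(s1$tables[[1]]$counts, s2$tables[[1]]$counts)
})

test_that("succession ground truth obeys the trait identities", {
  sim <- generate_succession(seed = 13)
  tr <- sim$truth$expected
  expect_equal(tr$exp_lcn + tr$exp_hcn, rep(1, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$exp_ratio, tr$exp_hcn / tr$exp_lcn, tolerance = 1e-12)
  # every OTU's true rrn is in range and genus-consistent
  expect_true(all(sim$truth$otu_rrn >= 1 & sim$truth$otu_rrn <= 15))
  per_genus <- tapply(sim$truth$otu_rrn, sim$taxonomy[names(sim$truth$otu_rrn)],
                      function(v) length(unique(v)))
  expect_true(all(per_genus == 1))
  # lookup agrees with truth after assignment
  tab <- sim$tables$oligotrophic
  asg <- assign_rrn(tab, sim$taxonomy, sim$lookup)
  expect_length(asg$unassigned, 0L)
  expect_equal(asg$copies[names(sim$truth$otu_rrn)],
               sim$truth$otu_rrn)
})

test_that("a zero boost is a null with time-constant expected ratio", {
  cfg <- succession_config(regimes = list(
    a = list(hcn_boost_initial = 0), b = list(hcn_boost_initial = 0)))
  sim <- generate_succession(cfg, seed = 2)
  tr <- sim$truth$expected
  expect_equal(length(unique(round(tr$exp_ratio, 12))), 1L)
})

test_that("a fast-decaying boost touches only the earliest samples", {
  cfg <- succession_config(time_points = c(0, 10, 20),
                           decay_rate = 1000,
                           regimes = list(
                             ctrl = list(hcn_boost_initial = 0),
                             boosted = list(hcn_boost_initial = 1)))
  sim <- generate_succession(cfg, seed = 4)
  tr <- sim$truth$expected
  r0 <- unique(round(tr$exp_ratio[tr$group == "ctrl"], 10))
  boosted_late <- tr$exp_ratio[tr$group == "boosted" & tr$time_days > 0]
  boosted_t0 <- tr$exp_ratio[tr$group == "boosted" & tr$time_days == 0]
  expect_equal(unique(round(boosted_late, 10)), r0)
  expect_true(all(boosted_t0 > boosted_late[1]))
})

test_that("estimated trait proportions converge to the ground truth", {
  cfg <- succession_config(time_points = c(5, 30), n_replicates = 1L,
                           depth = 1000000L, overdispersion = 1e7)
  sim <- generate_succession(cfg, seed = 6)
  prof <- trait_profiles(sim$tables$eutrophic, sim$taxonomy, sim$lookup)
  tr <- sim$truth$expected
  for (i in seq_len(nrow(prof))) {
    want <- tr$exp_lcn[tr$sample_id == prof$sample_id[i]]
    expect_lt(abs(prof$lcn_abund[i] - want), 0.01)
  }
})

test_that("noiseless growth curves sit exactly on the model", {
  g <- generate_growth_curves(A = 50, mu_max = 2, lag = 3, noise_sd = 0,
                              times = 0:10, n_replicates = 2, seed = 1)
  expect_equal(g$curves$value,
               rep(logistic_zwietering(0:10, 50, 2, 3), 2))
  # lag = 0: the curve starts at A / (1 + e^2)
  z <- generate_growth_curves(A = 50, mu_max = 2, lag = 0, noise_sd = 0,
                              times = 0:10, n_replicates = 1, seed = 1)
  expect_equal(z$curves$value[1], 50 / (1 + exp(2)))
  # the asymptote is reached at large t
  far <- generate_growth_curves(A = 50, mu_max = 2, lag = 0, noise_sd = 0,
                                times = c(0, 500, 1000), n_replicates = 1,
                                seed = 1)
  expect_equal(far$curves$value[3], 50, tolerance = 1e-6)
})

test_that("noisy growth values are truncated at zero", {
  g <- generate_growth_curves(A = 5, mu_max = 1, lag = 10, noise_sd = 50,
                              times = 0:19, n_replicates = 3, seed = 2)
  expect_true(all(g$curves$value >= 0))
})

test_that("stream groups differ in mean rrn exactly as configured", {
  null_cfg <- stream_config(groups = list(a = list(mean_rrn_shift = 0),
                                          b = list(mean_rrn_shift = 0)))
  ns <- generate_streams(null_cfg, seed = 9)
  expect_equal(unname(diff(ns$truth$expected_cwm_rrn)), 0, tolerance = 1e-12)

  shifted <- generate_streams(stream_config(), seed = 9)
  expect_gt(shifted$truth$expected_cwm_rrn["glacier_fed"],
            shifted$truth$expected_cwm_rrn["subalpine"])

  # the generated tables carry the shift: group-level weighted mean rrn is
  # higher in the shifted group across independent seeds
  hits <- 0L
  for (s in 1:20) {
    sim <- generate_streams(stream_config(n_samples = 5L, depth = 2000L),
                            seed = s)
    cwms <- vapply(sim$tables, function(tab) {
      prof <- trait_profiles(tab, sim$taxonomy, sim$lookup)
      mean(prof$cwm_rrn_abundance)
    }, numeric(1))
    hits <- hits + (cwms["glacier_fed"] > cwms["subalpine"])
  }
  expect_gte(hits, 19L)
})

test_that("the boosted regime's ratio declines from initial to late phase", {
  hits <- 0L
  for (s in 1:10) {
    sim <- generate_succession(seed = 300 + s)
    prof <- trait_profiles(sim$tables$eutrophic, sim$taxonomy, sim$lookup)
    initial <- prof$ratio_hcn_lcn[prof$time_days <= sim$config$phase_cut]
    late <- prof$ratio_hcn_lcn[prof$time_days > sim$config$phase_cut]
    hits <- hits + (mean(initial) > mean(late))
  }
  expect_gte(hits, 9L)
})

test_that("config invariants are enforced", {
  expect_error(succession_config(n_genera = 10L,
                                 rrn_spectrum = c(`2` = 5L)),
               "must sum to n_genera")
  expect_error(succession_config(regimes = list(a = list())),
               "hcn_boost_initial")
  expect_error(stream_config(groups = list(a = list(mean_rrn_shift = 0))),
               "two group specs")
  expect_warning(succession_config(depth = 10L), "sparse")
})
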