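profile_of <- function(counts, rrn, genus = NULL, renormalize = TRUE) {
  genus <- genus %||% paste0("G", seq_along(counts))
  tab <- make_table(matrix(as.integer(counts), ncol = 1))
  tax <- setNames(genus, rownames(tab$counts))
  lk <- rrn_lookup(unique(genus),
                   as.numeric(rrn[!duplicated(genus)]))
  asg <- assign_rrn(tab, tax, lk)
  rel <- relative_abundance(tab, subset = names(asg$copies),
                            renormalize = renormalize)
  trait_profile(rel, asg, "s1")
}

test_that("core genera are the intersection of per-table genus sets", {
  tabs <- list(make_table(matrix(1L, 3, 1), otus = paste0("x", 1:3)),
               make_table(matrix(1L, 3, 1), otus = paste0("y", 1:3)),
               make_table(matrix(1L, 2, 1), otus = paste0("z", 1:2)))
  taxs <- list(setNames(c("A", "B", "C"), paste0("x", 1:3)),
               setNames(c("B", "C", "D"), paste0("y", 1:3)),
               setNames(c("B", "C"), paste0("z", 1:2)))
  cg <- core_genera(tabs, taxs)
  expect_setequal(cg$genera, c("B", "C"))
  expect_equal(unname(cg$coverage), c(2/3, 2/3, 1))

  single <- core_genera(tabs[1], taxs[1])
  expect_setequal(single$genera, c("A", "B", "C"))

  expect_warning(
    none <- core_genera(tabs[c(1, 2)],
                        list(setNames("A", "x1")[c(1, 1, 1)],
                             setNames(c("E", "E", "E"), paste0("y", 1:3)))),
    "no genus is shared")
  expect_length(none$genera, 0L)
})

test_that("core selection requires counts, not mere row presence", {
  tab1 <- make_table(matrix(c(1L, 0L), ncol = 1), otus = c("a", "b"))
  tab2 <- make_table(matrix(c(1L, 1L), ncol = 1), otus = c("a", "b"))
  taxs <- list(setNames(c("A", "B"), c("a", "b")),
               setNames(c("A", "B"), c("a", "b")))
  cg <- core_genera(list(tab1, tab2), taxs)
  expect_equal(cg$genera, "A")  # B has zero counts in table 1
})

test_that("LCN/HCN binning partitions the 1-15 range at the 3/4 boundary", {
  tab <- make_table(matrix(1L, 15, 1), otus = paste0("o", 1:15))
  tax <- setNames(paste0("G", 1:15), paste0("o", 1:15))
  lk <- rrn_lookup(paste0("G", 1:15), as.numeric(1:15))
  bins <- bin_rrn(assign_rrn(tab, tax, lk))
  expect_equal(unname(bins[paste0("o", 1:3)]),
               factor(rep("LCN", 3), levels = c("LCN", "HCN")))
  expect_equal(unname(bins[paste0("o", 4:15)]),
               factor(rep("HCN", 12), levels = c("LCN", "HCN")))
  expect_false(anyNA(bins))  # exhaustive: every assigned OTU falls in a bin
})

test_that("trait profile arithmetic matches the worked examples", {
  p <- profile_of(c(5, 2, 3), rrn = c(2, 3, 5))
  expect_equal(p$lcn_abund, 0.7)
  expect_equal(p$hcn_abund, 0.3)
  expect_equal(p$ratio_hcn_lcn, 3 / 7)
  expect_equal(p$cwm_rrn_abundance, 3.1)

  solo <- profile_of(c(4, 6), rrn = c(2, 2))
  expect_equal(solo$ratio_hcn_lcn, 0)
  expect_equal(solo$cwm_rrn_abundance, 2)
  expect_equal(solo$mean_rrn_presence, 2)

  sym <- profile_of(c(3, 3, 3), rrn = c(1, 2, 3))
  expect_equal(sym$mean_rrn_presence, 2)
})

test_that("zero assigned abundance yields an undefined-flagged profile", {
  tab <- make_table(matrix(c(0L, 5L), ncol = 1), otus = c("a", "b"))
  tax <- setNames(c("A", "B"), c("a", "b"))
  lk <- rrn_lookup("A", 2)  # only the zero-count OTU is assignable
  asg <- assign_rrn(tab, tax, lk)
  rel <- relative_abundance(tab, subset = names(asg$copies),
                            renormalize = TRUE)
  p <- trait_profile(rel, asg, "s1")
  expect_true(p$undefined)
  expect_true(is.na(p$ratio_hcn_lcn))
})

test_that("profiles match brute-force enumeration on all small tables", {
  # grid over table size, count patterns and rrn assignments
  count_sets <- list(c(1), c(2, 3), c(5, 0, 2), c(1, 1, 1, 1),
                     c(7, 0, 0, 2, 4), c(3, 1, 4, 1, 5, 9))
  rrn_choices <- list(c(2), c(3, 4), c(1, 5, 9), c(2, 3, 4, 15),
                      c(1, 2, 3, 4, 5), c(2, 2, 5, 5, 9, 1))
  for (i in seq_along(count_sets)) {
    counts <- count_sets[[i]]
    for (shift in 0:2) {
      rrn <- rrn_choices[[i]]
      rrn <- pmin(pmax(((rrn + shift - 1) %% 15) + 1, 1), 15)
      genus <- paste0("G", rrn)  # same rrn -> same genus, as at genus level
      got <- profile_of(counts, rrn, genus)
      p <- counts / sum(counts)
      want <- brute_trait(p, rrn, genus)
      expect_equal(got$lcn_abund, want$lcn, tolerance = 1e-12)
      expect_equal(got$hcn_abund, want$hcn, tolerance = 1e-12)
      expect_equal(got$ratio_hcn_lcn, want$ratio, tolerance = 1e-12)
      expect_equal(got$cwm_rrn_abundance, want$cwm, tolerance = 1e-12)
      expect_equal(got$mean_rrn_presence, want$presence, tolerance = 1e-12)
      expect_equal(got$n_genera_lcn, want$n_gen_lcn)
      expect_equal(got$n_genera_hcn, want$n_gen_hcn)
      expect_equal(got$lcn_abund + got$hcn_abund, 1, tolerance = 1e-9)
    }
  }
})

test_that("class abundances sum to one over renormalized assigned OTUs", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    counts <- rpois(n, 20) + 1L
    rrn <- sample(1:15, n, replace = TRUE)
    p <- profile_of(counts, rrn, genus = paste0("G", rrn))
    expect_equal(p$lcn_abund + p$hcn_abund, 1, tolerance = 1e-9)
    expect_true(p$cwm_rrn_abundance >= 1 && p$cwm_rrn_abundance <= 15)
    expect_true(p$mean_rrn_presence >= 1 && p$mean_rrn_presence <= 15)
  }
})

test_that("the weighted mean is invariant to splitting an OTU within a genus", {
  whole <- profile_of(c(6, 4), rrn = c(2, 5), genus = c("A", "B"))
  split <- profile_of(c(3, 3, 4), rrn = c(2, 2, 5), genus = c("A", "A", "B"))
  expect_equal(split$cwm_rrn_abundance, whole$cwm_rrn_abundance)
  expect_equal(split$ratio_hcn_lcn, whole$ratio_hcn_lcn)
  expect_equal(split$n_genera_lcn, whole$n_genera_lcn)
})

test_that("moving abundance from LCN to HCN strictly increases the ratio", {
  base <- c(6, 4)
  prev <- profile_of(base, rrn = c(2, 5))$ratio_hcn_lcn
  for (moved in 1:5) {
    cur <- profile_of(base + c(-moved, moved), rrn = c(2, 5))$ratio_hcn_lcn
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("genera ratio matches its contract", {
  expect_equal(round(genera_ratio(34.3, 97.4), 2), 0.35)
  expect_equal(genera_ratio(1, 1), 1)
  expect_equal(genera_ratio(0, 10), 0)
  expect_warning(r <- genera_ratio(3, 0), "undefined")
  expect_true(is.na(r))
  expect_error(genera_ratio(c(1, 2), 1), "single")
})

test_that("trajectories average replicates and label phases inclusively", {
  prof <- data.frame(
    ratio_hcn_lcn = c(0.2, 0.3, 0.4, 0.6, 0.5, 0.7, 0.9),
    time_days = c(10, 10, 10, 25, 25, 25, 30),
    replicate = c("R1", "R2", "R3", "R1", "R2", "R3", "R1"))
  tr <- trajectory(prof, "ratio_hcn_lcn", phase_cut = 25)
  expect_equal(tr$time_days, c(10, 25, 30))
  expect_equal(tr$mean[1], 0.3)
  expect_equal(tr$sd[1], 0.1)
  expect_equal(tr$phase, c("initial", "initial", "late"))  # day 25 inclusive
  expect_equal(tr$sd[3], 0)  # single replicate
  expect_equal(tr$n, c(3, 3, 1))
})

test_that("undefined trait values reduce n with a warning", {
  prof <- data.frame(ratio_hcn_lcn = c(0.2, NA, 0.4),
                     time_days = c(10, 10, 10),
                     replicate = c("R1", "R2", "R3"))
  expect_warning(tr <- trajectory(prof, "ratio_hcn_lcn"), "undefined")
  expect_equal(tr$n, 2L)
  expect_equal(tr$mean, 0.3)
})

test_that("per-rrn-value abundance table partitions the assigned abundance", {
  com <- tiny_community()
  tab <- make_table(matrix(c(4L, 3L, 2L, 1L), ncol = 1), otus = com$otus)
  asg <- assign_rrn(tab, com$tax, com$lookup)
  rel <- relative_abundance(tab, subset = names(asg$copies),
                            renormalize = TRUE)
  va <- rrn_value_abundance(rel, asg)
  expect_equal(rownames(va), c("2", "3", "5", "9"))
  expect_equal(unname(va[, 1]), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(sum(va), 1)
})
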