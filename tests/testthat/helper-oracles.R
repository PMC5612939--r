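# Test fixtures and independent oracles (deliberately naive: explicit
# loops, no shared code with the implementation under test).

make_table <- function(counts, otus = NULL, samples = NULL, meta = NULL) {
  m <- as.matrix(counts)
  storage.mode(m) <- "integer"
  rownames(m) <- otus %||% paste0("OTU", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  rrntraits::otu_table(m, sample_meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force trait statistics: explicit element-by-element enumeration
brute_trait <- function(p, rrn, genus) {
  lcn <- 0; hcn <- 0; cwm_num <- 0; tot <- 0
  pres_rrn <- c(); lcn_gen <- c(); hcn_gen <- c()
  for (i in seq_along(p)) {
    if (rrn[i] <= 3) lcn <- lcn + p[i] else hcn <- hcn + p[i]
    cwm_num <- cwm_num + p[i] * rrn[i]
    tot <- tot + p[i]
    if (p[i] > 0) {
      pres_rrn <- c(pres_rrn, rrn[i])
      if (rrn[i] <= 3) lcn_gen <- c(lcn_gen, genus[i])
      else hcn_gen <- c(hcn_gen, genus[i])
    }
  }
  list(lcn = lcn, hcn = hcn,
       ratio = if (lcn > 0) hcn / lcn else NA_real_,
       cwm = if (tot > 0) cwm_num / tot else NA_real_,
       presence = if (length(pres_rrn)) mean(pres_rrn) else NA_real_,
       n_gen_lcn = length(unique(lcn_gen)),
       n_gen_hcn = length(unique(hcn_gen)))
}

# brute-force one-way ANOVA F from explicit sum-of-squares decomposition
brute_anova_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ss_b <- 0; ss_w <- 0
  for (g in groups) {
    ss_b <- ss_b + length(g) * (mean(g) - gm)^2
    for (v in g) ss_w <- ss_w + (v - mean(g))^2
  }
  k <- length(groups); n <- length(all_v)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

# brute-force simple OLS from the normal equations
brute_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot)
}

# a tiny ready-made community used across tests
tiny_community <- function() {
  otus <- c("o1", "o2", "o3", "o4")
  tax <- setNames(c("Sphingomonas", "Acidovorax", "Flavobacterium",
                    "Azospirillum"), otus)
  lk <- rrntraits::rrn_lookup(
    c("Sphingomonas", "Acidovorax", "Flavobacterium", "Azospirillum"),
    c(2, 3, 5, 9))
  list(otus = otus, tax = tax, lookup = lk)
}
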