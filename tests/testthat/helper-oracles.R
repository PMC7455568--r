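# Independent oracles used to cross-check the package's statistics.
# Deliberately written by a different route than the implementation
# (choose()-sum enumeration instead of phyper; manual step-up instead of
# p.adjust; manual order-statistic interpolation instead of quantile).

# Upper-tail hypergeometric P(X >= k) by direct enumeration of the overlap
# support: population N, K successes, n draws.  Exact in doubles for the
# small N used in tests.
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- seq(max(k, 0L), hi)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Lower quartile under the linear-interpolation (type 7) convention,
# h = (n - 1) p + 1 between order statistics.
oracle_q25 <- function(x) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * 0.25 + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Per-gene brute-force evaluation of the selection rule for one week:
# L_KO < 0, L_WT > 0, DIF < lower quartile of DIF over the universe.
oracle_select_week <- function(contrasts, week) {
  cw <- contrasts[contrasts$week == week, ]
  dif <- cw$L_KO - cw$L_WT
  thr <- oracle_q25(dif)
  hits <- character(0)
  for (i in seq_len(nrow(cw))) {
    if (cw$L_KO[i] < 0 && cw$L_WT[i] > 0 && dif[i] < thr)
      hits <- c(hits, cw$gene[i])
  }
  hits
}

# Benjamini-Hochberg step-up, written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- running
  }
  q
}

# Build a contrast table directly from per-gene L values (both weeks share
# the supplied values unless week-specific ones are given).
make_contrasts <- function(l_wt, l_ko, genes = NULL,
                           l_wt4 = l_wt, l_ko4 = l_ko) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_along(l_wt))
  rbind(
    data.frame(gene = genes, week = 2L, L_WT = l_wt, L_KO = l_ko,
               stringsAsFactors = FALSE),
    data.frame(gene = genes, week = 4L, L_WT = l_wt4, L_KO = l_ko4,
               stringsAsFactors = FALSE))
}

# Write a small expression matrix + sample sheet fixture and return paths.
# `tpm` is a genes x 8 matrix (or data frame) with gene names as rownames;
# the column order fixes the sample ids.
write_expression_fixture <- function(tpm, dir = NULL,
                                     genotype = rep(c("WT", "KO"), each = 4),
                                     condition = rep(c("sham", "DMM"), 4),
                                     week = rep(rep(c(2, 4), each = 2), 2),
                                     sample_ids = NULL,
                                     gene_col = rownames(tpm)) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  if (is.null(sample_ids))
    sample_ids <- paste0(genotype, "_", condition, "_wk", week)
  colnames(tpm) <- sample_ids
  mat_path <- file.path(dir, "matrix.tsv")
  sheet_path <- file.path(dir, "samples.tsv")
  df <- data.frame(gene = gene_col, tpm, check.names = FALSE)
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = sample_ids, genotype = genotype,
                         condition = condition, week = week),
              sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mat_path, samples = sheet_path, sample_ids = sample_ids)
}

# A small deterministic 8-sample TPM matrix for I/O tests.
toy_tpm <- function(n_genes = 3, seed = 42) {
  withr::with_seed(seed,
    matrix(round(runif(n_genes * 8, 0, 100), 3), nrow = n_genes,
           dimnames = list(sprintf("Gene%02d", seq_len(n_genes)), NULL)))
}

expect_difatten_error <- function(expr, class) {
  expect_error(expr, class = class)
}
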