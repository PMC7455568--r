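make_se <- function(tpm) {
  fx <- write_expression_fixture(tpm)
  read_expression_matrix(fx$matrix, fx$samples)
}

test_that("expression filter applies a strict TPM floor over all samples", {
  tpm <- rbind(low = c(0.5, 0.9, 0.3, 0.7, 0.2, 0.6, 0.8, 0.2),
               one = rep(1.0, 8),
               hit = c(0, 0, 0, 0, 0, 0, 0, 1.5))
  se <- make_se(tpm)
  filt <- filter_expressed(se)
  expect_equal(rownames(filt), "hit")

  expect_difatten_error(filter_expressed(se, tpm_min = 10),
                        "difatten_value_error")
  # floor is configurable
  expect_equal(sort(rownames(filter_expressed(se, tpm_min = 0.1))),
               c("hit", "low", "one"))
})

test_that("log2 contrasts follow the pseudocount formula and flag zeros", {
  # WT: sham 2, DMM 8; KO: sham 8, DMM 2 (both weeks)
  tpm <- matrix(c(2, 8, 2, 8, 8, 2, 8, 2), nrow = 1,
                dimnames = list("GeneA", NULL))
  se <- make_se(tpm)
  ct0 <- log2_contrast(se, pseudocount = 0)
  expect_equal(ct0$L_WT, c(2, 2))
  expect_equal(ct0$L_KO, c(-2, -2))
  ct1 <- log2_contrast(se, pseudocount = 1)
  expect_equal(ct1$L_WT, rep(log2(9 / 3), 2))

  flat <- matrix(rep(5, 8), nrow = 1, dimnames = list("GeneB", NULL))
  ctf <- log2_contrast(make_se(flat), pseudocount = runif(1, 0, 2))
  expect_equal(ctf$L_WT, c(0, 0))
  expect_equal(ctf$L_KO, c(0, 0))

  zero <- matrix(c(0, 8, 2, 8, 8, 2, 8, 2), nrow = 1,
                 dimnames = list("GeneZ", NULL))
  err <- tryCatch(log2_contrast(make_se(zero), pseudocount = 0),
                  error = function(e) e)
  expect_s3_class(err, "difatten_domain_error")
  expect_match(conditionMessage(err), "GeneZ")
  expect_difatten_error(log2_contrast(se, pseudocount = -1),
                        "difatten_argument_error")
})

test_that("DIF scores and lower-quartile thresholds match the definitions", {
  ct <- make_contrasts(l_wt = c(2, 1, 0, -1), l_ko = c(-2, -1, 0, 1))
  difs <- dif_scores(ct)
  # DIF = L_KO - L_WT: {-4, -2, 0, 2}; type-7 lower quartile = -2.5
  expect_equal(sort(difs$table$dif[difs$table$week == 2]), c(-4, -2, 0, 2))
  expect_equal(unname(difs$q25[["2"]]), -2.5)
  expect_true(all(difs$q25 >= min(difs$table$dif) &
                    difs$q25 <= max(difs$table$dif)))

  # pooled scope gives one threshold across weeks
  ct2 <- make_contrasts(l_wt = c(2, 1, 0, -1), l_ko = c(-2, -1, 0, 1),
                        l_wt4 = c(0, 0, 0, 0), l_ko4 = c(1, 1, 1, 1))
  pooled <- dif_scores(ct2, quartile_scope = "pooled")
  expect_equal(unname(pooled$q25[["2"]]), unname(pooled$q25[["4"]]))
  expect_equal(unname(pooled$q25[["2"]]),
               unname(quantile(c(-4, -2, 0, 2, 1, 1, 1, 1), 0.25,
                               names = FALSE)))
})

test_that("per-week selection applies the three strict requirements", {
  # gene A passes all three; B fails L_WT > 0 at the boundary;
  # C fails the quartile threshold; D fails L_KO < 0
  ct <- make_contrasts(l_wt = c(1.2, 0, 1.0, 2.0, 1, 1, 1, 1),
                       l_ko = c(-0.8, -3.0, -0.1, 0.5, 1, 1, 1, 1),
                       genes = LETTERS[1:8])
  difs <- dif_scores(ct)
  sel <- select_week(ct, difs, 2)
  expect_true("A" %in% sel)
  expect_false(any(c("B", "D") %in% sel))
  expect_setequal(sel, oracle_select_week(ct, 2))

  expect_difatten_error(select_week(ct, difs, 3),
                        "difatten_argument_error")
})

test_that("selection equals brute-force rule evaluation on random universes", {
  withr::local_seed(101)
  for (rep in 1:50) {
    n <- sample(10:50, 1)
    ct <- make_contrasts(l_wt = round(rnorm(n), 3),
                         l_ko = round(rnorm(n), 3),
                         l_wt4 = round(rnorm(n), 3),
                         l_ko4 = round(rnorm(n), 3))
    difs <- dif_scores(ct)
    for (w in c(2, 4))
      expect_setequal(select_week(ct, difs, w), oracle_select_week(ct, w))
  }
})

test_that("DIF is exactly antisymmetric under genotype-label swap", {
  withr::local_seed(7)
  ct <- make_contrasts(l_wt = rnorm(100), l_ko = rnorm(100),
                       l_wt4 = rnorm(100), l_ko4 = rnorm(100))
  swapped <- ct
  swapped$L_WT <- ct$L_KO
  swapped$L_KO <- ct$L_WT
  expect_identical(dif_scores(swapped)$table$dif, -dif_scores(ct)$table$dif)
})

test_that("strict quartile threshold bounds the selected fraction", {
  withr::local_seed(31)
  for (rep in 1:25) {
    n <- sample(8:200, 1)
    dif <- rnorm(n)
    # draw with ties sometimes
    if (rep %% 3 == 0) dif <- round(dif, 1)
    ct <- make_contrasts(l_wt = rep(0, n), l_ko = dif)
    difs <- dif_scores(ct)
    n_below <- sum(dif < difs$q25[["2"]])
    expect_lte(n_below, ceiling(0.25 * n))
  }
})

test_that("set intersection and overlap p-value behave as defined", {
  expect_setequal(common_genes(c("A", "B", "C"), c("B", "C", "D")),
                  c("B", "C"))
  expect_length(common_genes(c("A"), c("B")), 0L)
  expect_setequal(common_genes(c("A", "B"), c("A", "B", "C")), c("A", "B"))

  expect_equal(overlap_pvalue(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(overlap_pvalue(0, 5, 4, 10), 1)
  expect_equal(overlap_pvalue(6, 6, 6, 6), 1)
  expect_difatten_error(overlap_pvalue(5, 4, 4, 10),
                        "difatten_argument_error")

  # monotone non-increasing in k
  ps <- vapply(0:4, overlap_pvalue, numeric(1), n1 = 5, n2 = 4, N = 12)
  expect_true(all(diff(ps) <= 0))

  # stable -log10 form agrees where the plain p is representable
  expect_equal(overlap_pvalue(4, 5, 4, 10, log10p = TRUE),
               -log10(5 / 210), tolerance = 1e-10)
})

test_that("gene-wise scaling gives zero-mean unit-sd rows and flags constants", {
  tpm <- rbind(a = c(1, 2, 3, 4, 5, 6, 7, 8),
               b = rep(3, 8),
               c = runif(8, 1, 50))
  se <- make_se(tpm)
  expect_warning(sc <- genewise_scale(se, c("a", "b", "c")), "constant")
  expect_equal(unname(rowMeans(sc)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(sc["b", ]), rep(0, 8))
  expect_equal(unname(apply(sc[c("a", "c"), ], 1, sd)), c(1, 1),
               tolerance = 1e-12)

  # explicit three-point example under the sample-sd convention
  x <- c(1, 2, 3)
  expect_equal((x - mean(x)) / sd(x), c(-1, 0, 1))

  expect_difatten_error(genewise_scale(se, "nope"), "difatten_key_error")
})

test_that("DIF node-attribute export honors the week policy", {
  ct <- make_contrasts(l_wt = c(1, 2), l_ko = c(-1, -2),
                       l_wt4 = c(2, 3), l_ko4 = c(-2, -3),
                       genes = c("gA", "gB"))
  difs <- dif_scores(ct)
  per <- export_dif_attributes(difs, c("gA", "gB"), "per_week")
  expect_equal(colnames(per), c("gene", "DIF_wk2", "DIF_wk4"))
  expect_equal(per$DIF_wk2, c(-2, -4))
  expect_equal(per$DIF_wk4, c(-4, -6))

  mn <- export_dif_attributes(difs, "gA", "mean")
  expect_equal(mn$DIF, mean(c(-2, -4)))

  empty <- export_dif_attributes(difs, character(0), "per_week")
  expect_equal(nrow(empty), 0L)
  expect_true("gene" %in% colnames(empty))
})
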