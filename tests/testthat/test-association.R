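test_that("log normalization matches hand-computed CPM/log2 values", {
  cnt <- matrix(c(10, 0, 90,
                  20, 0, 180,
                  5, 5, 90), nrow = 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  norm <- normalize_log(expression_matrix(cnt, "counts"))
  lib <- colSums(cnt)
  expected <- log2(sweep(cnt, 2, lib / 1e6, "/") + 1)
  expect_equal(unclass(norm), expected, ignore_attr = TRUE)
  # all-zero gene stays all-zero
  expect_equal(unname(unclass(norm)["g2", c(1, 2)]), c(0, 0))
  # doubling depth leaves log rows unchanged
  norm2 <- normalize_log(expression_matrix(cbind(cnt[, 1], 2 * cnt[, 1]), "counts"))
  expect_equal(unclass(norm2)[, 1], unclass(norm2)[, 2], ignore_attr = TRUE)
  # idempotent on a log layer; error on negatives
  expect_equal(unclass(normalize_log(norm)), unclass(norm))
  expect_error(normalize_log(expression_matrix(matrix(-1), "normalized")), "nonnegative")
})

test_that("single-gene OLS matches lm() and nails a noiseless line", {
  q <- seq(0.05, 0.95, length.out = 10)
  fit <- fit_gene_ancestry(2 * q + 1, q)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)
  # n = 5 worked example against the standard linear-model fit
  y <- c(3.1, 4.0, 2.7, 5.5, 4.9); qq <- c(0.1, 0.3, 0.2, 0.9, 0.7)
  fit2 <- fit_gene_ancestry(y, qq)
  lmfit <- summary(stats::lm(y ~ qq))$coefficients
  expect_equal(fit2$slope, lmfit["qq", "Estimate"], tolerance = 1e-10)
  expect_equal(fit2$se, lmfit["qq", "Std. Error"], tolerance = 1e-10)
  expect_equal(fit2$t_stat, lmfit["qq", "t value"], tolerance = 1e-10)
  expect_equal(fit2$p_value, lmfit["qq", "Pr(>|t|)"], tolerance = 1e-10)
  expect_error(fit_gene_ancestry(y, rep(0.5, 5)), "variance")
  expect_error(fit_gene_ancestry(y[1:2], qq[1:2]), "3 samples")
})

test_that("null p-values are uniform", {
  set.seed(61)
  n <- 40
  q <- runif(n)
  y <- matrix(rnorm(2000 * n), 2000, n, dimnames = list(paste0("g", 1:2000), NULL))
  p <- vapply(seq_len(nrow(y)), function(i) fit_gene_ancestry(y[i, ], q)$p_value, double(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  set.seed(71)
  p <- runif(100)
  expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  # q-values non-decreasing in sorted p order
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_warning(out <- bh_adjust(c(0.1, NA, 0.5)), "NA")
  expect_true(is.na(out[2]))
})

test_that("the ancestry screen recovers planted genes with controlled FDR", {
  recalls <- c(); fdrs <- c()
  for (s in 1:3) {
    co <- simulate_cohort(sim_config(J = 30, seed = s))
    scr <- screen_ancestry_genes(co$expression, co$truth$q_true, "AFR")
    tp <- sum(scr$significant_set %in% co$truth$effect_genes$gene)
    recalls <- c(recalls, tp / nrow(co$truth$effect_genes))
    fdrs <- c(fdrs, if (length(scr$significant_set)) 1 - tp / length(scr$significant_set) else 0)
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(mean(fdrs), 0.10)
})

test_that("AFR and EUR screens mirror each other exactly when K = 2", {
  co <- simulate_cohort(sim_config(K = 2, J = 20, n = 30, G = 800,
                                   n_effect_genes = 40, seed = 81))
  a <- screen_ancestry_genes(co$expression, co$truth$q_true, "AFR")
  e <- screen_ancestry_genes(co$expression, co$truth$q_true, "EUR")
  ra <- dplyr::arrange(tidy(a), gene_id)
  re <- dplyr::arrange(tidy(e), gene_id)
  expect_lt(max(abs(ra$slope + re$slope)), 1e-9)
  expect_equal(ra$p_value, re$p_value, tolerance = 1e-9)
  expect_setequal(a$significant_set, e$significant_set)
})

test_that("screen results are invariant to gene and sample permutations", {
  co <- tiny_cohort(seed = 91)
  scr <- screen_ancestry_genes(co$expression, co$truth$q_true, "AFR")
  x <- unclass(co$expression)
  set.seed(92)
  gp <- sample(nrow(x)); sp <- sample(ncol(x))
  perm <- expression_matrix(x[gp, sp], "counts")
  scr2 <- screen_ancestry_genes(perm, co$truth$q_true[sp, ], "AFR")
  r1 <- dplyr::arrange(tidy(scr), gene_id)
  r2 <- dplyr::arrange(tidy(scr2), gene_id)
  expect_equal(r1$slope, r2$slope, tolerance = 1e-9)
  expect_setequal(scr$significant_set, scr2$significant_set)
})

test_that("misaligned samples raise an informative error", {
  co <- tiny_cohort(seed = 95)
  anc <- tibble::tibble(sample_id = paste0("zz", 1:5), q_AFR = runif(5))
  expect_error(screen_ancestry_genes(co$expression, anc, "AFR"), "missing")
  expect_error(screen_ancestry_genes(co$expression, co$truth$q_true, "ZZZ"), "ZZZ")
})

test_that("the SRR two-group contrast matches Welch t-tests and planted folds", {
  # toy 4-sample, 3-gene matrix against stats::t.test
  y <- expression_matrix(matrix(
    c(5.2, 1.0, 3.3,
      5.8, 1.4, 3.1,
      7.1, 1.2, 3.4,
      7.4, 0.9, 3.2), nrow = 3,
    dimnames = list(paste0("g", 1:3), paste0("s", 1:4))), "log")
  res <- srr_differential(y, c("AA", "AA", "EA", "EA"))
  r <- dplyr::arrange(tidy(res), gene_id)
  for (i in 1:3) {
    tt <- stats::t.test(unclass(y)[i, 1:2], unclass(y)[i, 3:4])
    expect_equal(r$p_value[i], tt$p.value, tolerance = 1e-10)
    expect_equal(r$log2fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
  # label permutation of identical groups: zero fold change, no discoveries
  same <- expression_matrix(cbind(unclass(y), unclass(y)), "log")
  res0 <- srr_differential(same, rep(c("AA", "EA"), each = 4))
  expect_true(all(abs(tidy(res0)$log2fc) < 1e-12))
  expect_length(res0$significant_set, 0)
  expect_error(srr_differential(y, c("a", "b", "c", "c")), "two group")
})

test_that("planted two-fold group differences are recovered at |log2FC| near 1", {
  set.seed(101)
  n <- 30; G <- 500
  grp <- rep(c("AA", "EA"), each = n / 2)
  base <- matrix(2^rnorm(G * n, 7, 0.4), G, n, dimnames = list(sprintf("g%03d", 1:G), paste0("s", 1:n)))
  planted <- sprintf("g%03d", 1:40)
  base[planted, grp == "AA"] <- base[planted, grp == "AA"] * 2
  res <- srr_differential(expression_matrix(round(base), "counts"), grp)
  hits <- intersect(res$significant_set, planted)
  expect_gt(length(hits), 30)
  r <- tidy(res)
  expect_equal(mean(abs(r$log2fc[r$gene_id %in% hits])), 1, tolerance = 0.15)
})

test_that("overlap summaries count shared and specific genes correctly", {
  ov <- overlap_summary(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(unlist(ov$counts), c(shared = 2, a_only = 1, b_only = 1))
  ident <- overlap_summary(c("x", "y"), c("y", "x"))
  expect_equal(ident$counts$a_only + ident$counts$b_only, 0)
  # planted intersection recovered by brute-force recount
  co <- simulate_cohort(sim_config(K = 2, J = 20, n = 40, G = 800,
                                   n_effect_genes = 40, seed = 111))
  scr <- screen_ancestry_genes(co$expression, co$truth$q_true, "AFR")
  grp <- ifelse(co$truth$q_true[, "AFR"] >= 0.5, "AA", "EA")
  srr <- srr_differential(co$expression, grp)
  ov2 <- overlap_summary(scr$significant_set, srr$significant_set)
  brute <- length(intersect(scr$significant_set, srr$significant_set))
  expect_identical(ov2$counts$shared, brute)
  # fold-change summary: ancestry hits show larger magnitude than group-only hits
  fc <- setNames(tidy(srr)$log2fc, tidy(srr)$gene_id)
  ov3 <- overlap_summary(scr$significant_set, setdiff(srr$significant_set, scr$significant_set), fc)
  expect_gt(ov3$avg_abs_fold_change$mean_abs_fc[1], ov3$avg_abs_fold_change$mean_abs_fc[2])
})
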