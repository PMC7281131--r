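toy_sigs <- function() {
  list(
    BL1 = subtype_signature("BL1", c("g1", "g2"), c("g3", "g4")),
    BL2 = subtype_signature("BL2", c("g5", "g6"), c("g7", "g8")),
    LAR = subtype_signature("LAR", c("g9", "g10"), c("g11", "g12")),
    M   = subtype_signature("M", c("g13", "g14"), c("g15", "g16")),
    IM  = subtype_signature("IM", c("g17", "g18"), c("g19", "g20")),
    MSL = subtype_signature("MSL", c("g21", "g22"), c("g23", "g24"))
  )
}

test_that("minimum-rank ranking matches definitions and a brute-force oracle", {
  m <- matrix(c(5, 5, 7), 1, dimnames = list("g", c("a", "b", "c")))
  expect_equal(unname(rank_genes(m)[1, ]), c(1, 1, 3))
  m2 <- matrix(1:4, 1)
  expect_equal(unname(rank_genes(m2)[1, ]), 1:4)
  expect_error(rank_genes(matrix(1:5, 5, 1)), "2 samples")
  set.seed(121)
  for (rep in 1:20) {
    x <- matrix(sample(1:6, 160, replace = TRUE), 20, 8,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
    across <- rank_genes(x, "across_samples")
    within <- rank_genes(x, "within_sample")
    for (i in seq_len(nrow(x))) {
      expect_identical(unname(across[i, ]), rank_min_brute(x[i, ]))
    }
    for (j in seq_len(ncol(x))) {
      expect_identical(unname(within[, j]), rank_min_brute(x[, j]))
    }
  }
})

test_that("summarized-rank scores match hand computation on a worked toy", {
  # 6 genes x 3 samples; ranks are taken per gene across samples (max rank 3)
  x <- matrix(c(5, 5, 7,
                1, 2, 3,
                9, 8, 7,
                2, 2, 2,
                4, 6, 5,
                10, 1, 6), nrow = 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:6), c("A", "B", "C")))
  r <- rank_genes(x)
  up_only <- subtype_signature("S", c("g1", "g3"))
  # ranks: g1 = (1,1,3), g3 = (3,2,1); medians per sample 2, 1.5, 2 over max 3
  expect_equal(unname(tnhf_score(r, up_only, "median")), c(2, 1.5, 2) / 3)
  expect_equal(unname(tnhf_score(r, up_only, "mean")), c(2, 1.5, 2) / 3)
  directional <- subtype_signature("S", c("g1", "g3"), "g2")
  # g2 ranks (1,2,3); down part = 1 - rank/3; average of up and down parts
  expect_equal(unname(tnhf_score(r, directional, "median")),
               (c(2, 1.5, 2) / 3 + (1 - c(1, 2, 3) / 3)) / 2)
  # maximal case: every up-gene at top rank -> score 1
  top <- matrix(c(1, 9, 2, 8, 3, 7), 3, 2, byrow = TRUE,
                dimnames = list(paste0("h", 1:3), c("lo", "hi")))
  expect_equal(unname(tnhf_score(rank_genes(top), subtype_signature("T", paste0("h", 1:3)))[2]), 1)
  # absent genes warn; fully absent signature errors
  expect_warning(tnhf_score(r, subtype_signature("S", c("g1", "zz"))), "absent")
  expect_error(tnhf_score(r, subtype_signature("S", "zz")), "zz|present|S")
})

test_that("subtype assignment is argmax with the fixed BL1 > BL2 > LAR > M tie order", {
  expect_identical(assign_tnhf_subtype(c(BL1 = 0.8, BL2 = 0.4, LAR = 0.2, M = 0.1)), "BL1")
  expect_identical(assign_tnhf_subtype(c(BL1 = 0.6, BL2 = 0.6, LAR = 0.2, M = 0.1)), "BL1")
  expect_identical(assign_tnhf_subtype(c(BL1 = 0.1, M = 0.7, LAR = 0.7, BL2 = 0.2)), "LAR")
  expect_error(assign_tnhf_subtype(c(BL1 = 1, BL2 = 1, LAR = 1)), "required")
})

test_that("planted subtypes are recovered by max rank score", {
  co <- tiny_cohort(seed = 131)
  ranks <- rank_genes(unclass(normalize_log(co$expression)))
  scores <- sapply(c("BL1", "BL2", "LAR", "M"),
                   function(s) tnhf_score(ranks, co$signatures[[s]], "median"))
  called <- apply(scores, 1, function(v) assign_tnhf_subtype(v))
  expect_gte(mean(called == co$truth$subtype_true), 0.9)
})

test_that("signature correlation hits the concordance extremes and the null", {
  sig <- subtype_signature("S", paste0("u", 1:5), paste0("d", 1:5))
  template <- c(rep(1, 5), rep(-1, 5))
  # two samples mirroring the template exactly (log layer, already centered-ish)
  x <- cbind(5 + template, 5 - template)
  rownames(x) <- c(paste0("u", 1:5), paste0("d", 1:5))
  colnames(x) <- c("pos", "neg")
  cs <- signature_correlation(expression_matrix(x, "log"), sig)
  expect_equal(unname(cs["pos"]), 1)
  expect_equal(unname(cs["neg"]), -1)
  # random expression: mean correlation near zero
  set.seed(141)
  xr <- matrix(rnorm(10 * 1000, 5), 10, 1000,
               dimnames = list(rownames(x), paste0("s", 1:1000)))
  cs_null <- signature_correlation(expression_matrix(xr, "log"), sig)
  expect_lt(abs(mean(cs_null)), 0.05)
  # constant expression over signature genes: flagged zero
  xc <- matrix(5, 10, 3, dimnames = list(rownames(x), paste0("s", 1:3)))
  cs0 <- signature_correlation(expression_matrix(xc, "log"), sig)
  expect_true(all(cs0 == 0))
  expect_length(attr(cs0, "degenerate"), 3)
  expect_error(signature_correlation(expression_matrix(xr[1:2, ], "log"), sig), "fewer than 3")
})

test_that("IM/MSL primaries are reassigned to the best valid subtype", {
  cs <- rbind(
    c(BL1 = 0.3, BL2 = 0.7, LAR = 0.1, M = 0.0, IM = 0.9, MSL = 0.5),
    c(BL1 = 0.8, BL2 = 0.2, LAR = 0.1, M = 0.0, IM = 0.3, MSL = 0.1),
    c(BL1 = -0.2, BL2 = -0.4, LAR = -0.1, M = -0.3, IM = -0.05, MSL = -0.5)
  )
  calls <- tnhf:::reassign_calls(cs)
  expect_identical(calls$primary, c("IM", "BL1", "IM"))
  expect_identical(calls$reassigned, c("BL2", "BL1", "LAR"))
  expect_identical(calls$secondary[1], "BL2")
  expect_true(calls$uns[3])
  # enumerated orderings: reassignment never emits a retired label and always
  # picks the top-ranked valid subtype
  vals <- c(0.9, 0.75, 0.6, 0.45, 0.3, 0.15)
  idx <- seq_len(6)
  set.seed(151)
  for (rep in 1:120) {
    ord <- sample(idx)
    cs1 <- matrix(vals[ord], 1, dimnames = list(NULL, c("BL1", "BL2", "LAR", "M", "IM", "MSL")))
    call1 <- tnhf:::reassign_calls(cs1)
    expect_false(call1$reassigned %in% c("IM", "MSL"))
    valid <- cs1[1, c("BL1", "BL2", "LAR", "M")]
    if (call1$primary %in% c("IM", "MSL")) {
      expect_identical(call1$reassigned, names(which.max(valid)))
    } else {
      expect_identical(call1$reassigned, call1$primary)
    }
  }
})

test_that("cohort calls never retain IM or MSL after reassignment", {
  co <- tiny_cohort(seed = 161)
  calls <- call_with_reassignment(co$expression, co$signatures)
  expect_true(all(calls$reassigned %in% c("BL1", "BL2", "LAR", "M")))
  expect_true(any(calls$primary %in% c("BL1", "BL2", "LAR", "M", "IM", "MSL")))
  expect_error(call_with_reassignment(co$expression, co$signatures[1:4]), "MSL|IM|missing")
})

test_that("the correlation-score matrix has 16 columns, bounded values and deterministic rows", {
  co <- tiny_cohort(seed = 171)
  norm <- normalize_log(co$expression)
  cs <- build_cs_matrix(co$expression, norm, co$signatures)
  expect_identical(ncol(cs), 16L)
  expect_true(all(cs >= -1 - 1e-9 & cs <= 1 + 1e-9))
  expect_false(anyNA(unclass(cs)))
  # duplicated sample gives identical rows
  x <- unclass(co$expression)[, c(1, 1, 2:8)]
  colnames(x) <- paste0("r", seq_len(ncol(x)))
  e2 <- expression_matrix(x, "counts")
  cs2 <- build_cs_matrix(e2, normalize_log(e2), co$signatures)
  expect_equal(unclass(cs2)[1, ], unclass(cs2)[2, ], tolerance = 1e-12)
  # planted subtype dominates its own columns in >= 3 of 4 methods
  bl2 <- which(co$truth$subtype_true == "BL2")[1]
  row <- unclass(cs)[bl2, ]
  wins <- 0
  for (meth in c("corr_counts", "corr_log", "tnhf_median", "tnhf_mean")) {
    own <- row[paste(meth, "BL2", sep = ".")]
    if (all(own >= row[paste(meth, c("BL1", "LAR", "M"), sep = ".")])) wins <- wins + 1
  }
  expect_gte(wins, 3)
  # degenerate all-equal expression: correlation columns all flagged zero
  flat <- expression_matrix(matrix(3, 300, 5,
    dimnames = list(co$truth$genes[1:300], paste0("f", 1:5))), "log")
  cs_flat <- suppressWarnings(build_cs_matrix(flat, flat, co$signatures))  # coverage warnings expected
  expect_true(all(unclass(cs_flat)[, grep("^corr", colnames(cs_flat))] == 0))
  expect_error(build_cs_matrix(co$expression, flat, co$signatures), "samples")
})

test_that("Ward clustering splits separable archetypes and respects degenerate cuts", {
  arch <- gen_cs_archetypes(n_per = 6, seed = 181)
  # two well-separated planted blocks
  two <- arch$cs[arch$archetype %in% c("M+", "M-"), ]
  cl2 <- cluster_heterogenic(tnhf:::new_cs_matrix(two), k = 2)
  expect_equal(ari(cl2$clusters, rep(c(1, 2), each = 6)), 1)
  # six archetypes, k = 6
  cl6 <- cluster_heterogenic(arch$cs, k = 6)
  expect_gte(ari(cl6$clusters, arch$archetype), 0.9)
  # k = n gives singletons; n < k errors
  few <- tnhf:::new_cs_matrix(unclass(arch$cs)[1:5, ])
  expect_identical(sort(unique(cluster_heterogenic(few, k = 5)$clusters)), 1:5)
  expect_error(cluster_heterogenic(few, k = 6), "cannot cut")
})

test_that("status labels threshold cluster means into canonical node names", {
  # two synthetic clusters with prescribed standardized means
  methods <- c("a", "b", "c", "d")
  cols <- as.vector(outer(c("BL1", "BL2", "LAR", "M"), methods,
                          function(s, m) paste(m, s, sep = ".")))
  mk_row <- function(bl1, bl2, lar, m) {
    setNames(rep(c(bl1, bl2, lar, m), times = length(methods)), cols)
  }
  m <- rbind(mk_row(-0.9, 0.8, 0.05, 0.1), mk_row(-0.9, 0.8, 0.05, 0.1),
             mk_row(0.05, -0.1, 0.02, 0.0), mk_row(0.05, -0.1, 0.02, 0.0),
             mk_row(0.0, 0.05, -0.02, 0.7), mk_row(0.0, 0.05, -0.02, 0.7))
  rownames(m) <- paste0("s", 1:6)
  cs <- structure(m, standardized = m, class = c("cs_matrix", "matrix", "array"))
  labs <- status_labels(cs, setNames(c(1, 1, 2, 2, 3, 3), rownames(m)), tau = 0.2)
  expect_identical(labs$label[1], "BL2+/BL1-")
  expect_identical(labs$label[2], "IND")
  expect_identical(labs$label[3], "M+")
  expect_identical(labs$status_BL1[1], "-")
  expect_error(status_labels(cs, setNames(c(1, 1, 2, 2, 3, 3), rownames(m)), tau = 0), "tau")
})

test_that("planted archetype nodes are recovered with correct canonical labels", {
  for (s in 1:3) {
    arch <- gen_cs_archetypes(n_per = 8, seed = 200 + s)
    cl <- cluster_heterogenic(arch$cs, k = 6)
    expect_gte(ari(cl$clusters, arch$archetype), 0.9)
    labs <- status_labels(arch$cs, cl$clusters, tau = 0.2)
    expect_setequal(labs$label, arch$expected_labels)
  }
})

test_that("tnhf scores are monotone in up-gene expression", {
  set.seed(191)
  x <- matrix(rnorm(30 * 6, 5), 30, 6,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  sig <- subtype_signature("S", paste0("g", 1:5))
  base <- tnhf_score(rank_genes(x), sig, "mean")
  x2 <- x
  x2[1:5, 3] <- x2[1:5, 3] + 10     # push sample 3's up-genes higher
  bumped <- tnhf_score(rank_genes(x2), sig, "mean")
  expect_gte(bumped[3], base[3])
  expect_true(all(base >= 0 & base <= 1))
})
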