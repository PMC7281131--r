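snp_key <- function(snps) paste(snps$chrom, snps$pos, snps$ref, snps$alt, sep = ":")

is_snv <- function(ref, alt) {
  nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

#' Filter and align genotypes against a reference panel
#'
#' Applies the variant filters used before supervised ancestry estimation:
#' only biallelic SNVs are kept (INDELs and multiallelic records are assumed
#' already excluded at VCF parse; residual non-SNV alleles are dropped here),
#' records are matched to the panel on chromosome + position + ref + alt
#' (strand flips and ref/alt swaps are dropped, not repaired), and variants
#' whose pooled panel minor-allele frequency falls below `maf_min` are
#' excluded. The pooled frequency is the unweighted mean of the panel's
#' per-population alternate-allele frequencies, i.e. a panel-wide "across all
#' populations" criterion; the conventional threshold is 5%.
#'
#' @param genotypes a [genotype_matrix()] whose `snp_meta` attribute (set by
#'   [read_vcf_genotypes()]) or colnames identify variants. If no metadata is
#'   attached, colnames are matched directly against panel snp_ids.
#' @param panel a [reference_panel()].
#' @param maf_min minimum pooled panel minor-allele frequency in \[0, 0.5\].
#' @return list with `genotypes` and `panel`, aligned and equally ordered,
#'   plus a `dropped` tibble counting each exclusion category.
#' @export
filter_variants <- function(genotypes, panel, maf_min = 0.05) {
  if (maf_min < 0 || maf_min > 0.5) abort("maf_min must lie in [0, 0.5]")
  meta <- attr(genotypes, "snp_meta")
  dropped <- c(non_snv = 0L, unmatched = 0L, low_maf = 0L)

  if (!is.null(meta)) {
    keep_snv <- is_snv(meta$ref, meta$alt)
    dropped["non_snv"] <- sum(!keep_snv)
    idx <- match(snp_key(meta), snp_key(panel$snps))
    matched <- keep_snv & !is.na(idx)
    dropped["unmatched"] <- sum(keep_snv & is.na(idx))
    g_idx <- which(matched)
    p_idx <- idx[matched]
  } else {
    idx <- match(colnames(genotypes), panel$snps$snp_id)
    matched <- !is.na(idx)
    dropped["unmatched"] <- sum(!matched)
    g_idx <- which(matched)
    p_idx <- idx[matched]
  }

  pooled <- colMeans(panel$freq)[p_idx]
  maf <- pmin(pooled, 1 - pooled)
  pass <- maf >= maf_min
  dropped["low_maf"] <- sum(!pass)
  g_idx <- g_idx[pass]
  p_idx <- p_idx[pass]
  if (!length(g_idx)) {
    abort("no variants survive panel intersection and MAF filtering")
  }

  g <- genotype_matrix(unclass(genotypes)[, g_idx, drop = FALSE],
                       sample_ids = rownames(genotypes),
                       snp_ids = panel$snps$snp_id[p_idx])
  p <- reference_panel(panel$freq[, p_idx, drop = FALSE],
                       panel$snps[p_idx, ], rownames(panel$freq))
  list(
    genotypes = g, panel = p,
    dropped = tibble::tibble(reason = names(dropped), n = as.integer(dropped))
  )
}

#' Log-likelihood of an admixture proportion vector
#'
#' The supervised admixture model treats the 2J allele copies of one
#' individual as independent Bernoulli draws with site-specific success
#' probability `p_j = sum_k q_k f_kj`, giving
#' `sum_j [ g_j log p_j + (2 - g_j) log(1 - p_j) ]` over non-missing sites.
#' Panel clamping keeps every term finite.
#'
#' @param q length-K proportions on the unit simplex.
#' @param dosages length-J dosage vector in \{0,1,2\}; `NA` sites are skipped.
#' @param panel_freqs K x J matrix of alternate-allele frequencies.
#' @param tol simplex tolerance on `q`.
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(q, dosages, panel_freqs, tol = 1e-6) {
  q <- as.numeric(q)
  panel_freqs <- as.matrix(panel_freqs)
  if (length(q) != nrow(panel_freqs)) abort("q length must equal panel population count")
  if (abs(sum(q) - 1) > tol || any(q < -tol)) abort("q must lie on the unit simplex")
  obs <- !is.na(dosages)
  g <- dosages[obs]
  p <- as.numeric(crossprod(q, panel_freqs[, obs, drop = FALSE]))
  sum(g * log(p) + (2 - g) * log1p(-p))
}

#' Estimate one individual's ancestry proportions by EM
#'
#' Maximizes the supervised admixture log-likelihood over the simplex by the
#' standard EM update: each allele copy at site j is fractionally attributed
#' to population k with posterior weight `q_k f_kj / p_j` (alternate allele)
#' or `q_k (1 - f_kj) / (1 - p_j)` (reference allele), and `q` is re-estimated
#' as the average attribution over all 2J' observed allele copies. Starts from
#' the uniform vector and stops when the log-likelihood improves by less than
#' `tol`. EM guarantees a non-decreasing log-likelihood at every step.
#'
#' @param dosages length-J dosage vector in \{0,1,2\} with `NA` for missing.
#' @param panel a [reference_panel()] or bare K x J frequency matrix.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap; non-convergence sets `converged = FALSE`
#'   rather than erroring.
#' @param keep_trace if `TRUE`, attach the per-iteration log-likelihood trace.
#' @return one-row tibble: `q_<pop>` columns, `loglik`, `n_iter`, `converged`.
#' @export
estimate_ancestry <- function(dosages, panel, tol = 1e-6, max_iter = 2000, keep_trace = FALSE) {
  f <- if (inherits(panel, "reference_panel")) panel$freq else as.matrix(panel)
  K <- nrow(f)
  if (is.null(rownames(f))) rownames(f) <- paste0("P", seq_len(K))
  obs <- !is.na(dosages)
  if (!any(obs)) abort("all genotypes missing for this individual")
  g <- as.numeric(dosages[obs])
  f <- f[, obs, drop = FALSE]
  J <- length(g)

  q <- rep(1 / K, K)
  ll <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    qf <- q * f                                   # K x J: q_k f_kj
    qf1 <- q * (1 - f)                            # K x J: q_k (1 - f_kj)
    p <- colSums(qf)                              # p_j = sum_k q_k f_kj
    q <- (qf %*% (g / p) + qf1 %*% ((2 - g) / (1 - p))) / (2 * J)
    q <- as.numeric(q)
    q <- q / sum(q)                               # guard FP drift off the simplex
    ll_new <- sum(g * log(colSums(q * f))) + sum((2 - g) * log1p(-colSums(q * f)))
    if (keep_trace) trace <- c(trace, ll_new)
    if (is.finite(ll) && abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
    if (iter >= max_iter) break
  }
  out <- tibble::tibble(!!!setNames(as.list(q), paste0("q_", rownames(f))),
                        loglik = ll, n_iter = iter, converged = converged)
  if (keep_trace) attr(out, "loglik_trace") <- trace
  out
}

#' Estimate ancestry proportions for a whole cohort
#'
#' Runs [estimate_ancestry()] independently for every row of the genotype
#' matrix, preserving sample order. Estimation is deterministic (uniform
#' start, fixed-point iteration), so repeated runs on identical input give
#' identical estimates.
#'
#' @param genotypes a [genotype_matrix()] aligned to `panel` (see
#'   [filter_variants()]).
#' @param panel a [reference_panel()].
#' @inheritParams estimate_ancestry
#' @return tibble with one row per sample: `sample_id`, `q_<pop>` columns,
#'   `loglik`, `n_iter`, `converged`; classed `ancestry_estimates`.
#' @export
cohort_ancestry <- function(genotypes, panel, tol = 1e-6, max_iter = 2000) {
  ids <- rownames(genotypes)
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    res <- tryCatch(
      estimate_ancestry(unclass(genotypes)[i, ], panel, tol = tol, max_iter = max_iter),
      error = function(e) abort(sprintf("sample %s: %s", ids[i], conditionMessage(e)))
    )
    dplyr::bind_cols(tibble::tibble(sample_id = ids[i]), res)
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(sample_id = character(), loglik = double(),
                   n_iter = integer(), converged = logical())
  }
  class(out) <- c("ancestry_estimates", class(out))
  out
}

#' @method glance ancestry_estimates
#' @export
glance.ancestry_estimates <- function(x, ...) {
  qcols <- grep("^q_", names(x), value = TRUE)
  tibble::tibble(
    n_samples = nrow(x),
    n_populations = length(qcols),
    mean_loglik = mean(x$loglik),
    prop_converged = mean(x$converged)
  )
}

#' Stacked ancestry-composition plot
#'
#' Draws the classic admixture bar plot: one bar per individual, filled by
#' estimated ancestry proportions, ordered by the first population's
#' proportion.
#'
#' @param object an `ancestry_estimates` tibble from [cohort_ancestry()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ancestry_estimates
#' @export
autoplot.ancestry_estimates <- function(object, ...) {
  qcols <- grep("^q_", names(object), value = TRUE)
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[, c("sample_id", qcols)],
    dplyr::all_of(qcols), names_to = "population", values_to = "proportion",
    names_prefix = "q_"
  )
  ord <- object$sample_id[order(object[[qcols[1]]], decreasing = TRUE)]
  long$sample_id <- factor(long$sample_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                                     fill = .data$population)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "Ancestry proportion", fill = "Population") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Grid-search maximizer of the two-population admixture likelihood
#'
#' Exhaustive search over `q_1` in \{0, step, 2*step, ..., 1\} for K = 2.
#' Intended as an independent check of the EM estimator on small inputs.
#'
#' @param dosages length-J dosage vector.
#' @param panel a [reference_panel()] or 2 x J frequency matrix.
#' @param step grid resolution.
#' @return list with `q` (length 2) and `loglik`.
#' @export
grid_ancestry_k2 <- function(dosages, panel, step = 0.001) {
  f <- if (inherits(panel, "reference_panel")) panel$freq else as.matrix(panel)
  if (nrow(f) != 2) abort("grid search supports exactly 2 populations")
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(q1) admixture_loglik(c(q1, 1 - q1), dosages, f), double(1))
  best <- which.max(ll)
  list(q = c(grid[best], 1 - grid[best]), loglik = ll[best])
}
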