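#' Log-normalize an expression matrix
#'
#' Counts are scaled to counts-per-million by each sample's library size and
#' then transformed with log2(x + 1); already-normalized abundances skip the
#' library scaling; a log layer is returned unchanged (the transform is
#' idempotent). The pseudocount keeps all-zero genes at exactly zero and the
#' per-million scaling makes equal-composition samples identical regardless of
#' sequencing depth.
#'
#' @param expression an [expression_matrix()] with nonnegative values.
#' @return an [expression_matrix()] with `layer = "log"`.
#' @export
normalize_log <- function(expression) {
  x <- as.matrix(expression)
  layer <- expr_layer(expression)
  if (layer == "log") return(expression_matrix(x, layer = "log"))
  if (any(x < 0, na.rm = TRUE)) abort("expression values must be nonnegative")
  if (layer == "counts") {
    libsize <- colSums(x, na.rm = TRUE)
    libsize[libsize == 0] <- 1
    x <- sweep(x, 2, libsize / 1e6, "/")
  }
  expression_matrix(log2(x + 1), layer = "log")
}

#' Per-gene ordinary least squares against a continuous ancestry proportion
#'
#' Fits `y = a + b * q` by OLS for one gene and tests the slope with a
#' two-sided t test on n - 2 degrees of freedom. The slope is the change in
#' log2 expression per unit ancestry proportion (0 to 1), so `2^slope` is the
#' fold change contrasting a fully African against a fully European genome.
#'
#' @param y_log numeric vector of log2 expression values for one gene.
#' @param q_component numeric vector of ancestry proportions in \[0, 1\].
#' @param gene_id optional identifier carried into the result.
#' @return one-row tibble: gene_id, slope, se, t_stat, p_value, n_used.
#' @export
fit_gene_ancestry <- function(y_log, q_component, gene_id = NA_character_) {
  ok <- !is.na(y_log) & !is.na(q_component)
  y <- y_log[ok]; q <- q_component[ok]
  n <- length(y)
  if (n < 3) abort("need at least 3 samples with non-missing values")
  if (var(q) == 0) abort("ancestry component has zero variance; slope not identifiable")
  qc <- q - mean(q)
  sxx <- sum(qc^2)
  slope <- sum(qc * y) / sxx
  resid <- y - mean(y) - slope * qc
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  t_stat <- slope / se
  tibble::tibble(
    gene_id = gene_id, slope = slope, se = se, t_stat = t_stat,
    p_value = 2 * pt(-abs(t_stat), df = n - 2), n_used = n
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin, NA-propagating wrapper around
#' [stats::p.adjust()]. Missing p-values yield missing q-values with a
#' warning and do not count toward the number of tests.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values))) warn("NA p-values propagated as NA q-values")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

# Vectorized per-gene OLS of a log-expression matrix on one covariate.
# Complete matrices take the closed-form matrix path; genes with missing
# values fall back to fit_gene_ancestry row by row.
ols_screen <- function(ylog, x) {
  n <- ncol(ylog)
  if (!anyNA(ylog) && !anyNA(x)) {
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    slope <- as.numeric(ylog %*% xc) / sxx
    fitted_dev <- outer(slope, xc)
    resid <- ylog - rowMeans(ylog) - fitted_dev
    s2 <- rowSums(resid^2) / (n - 2)
    se <- sqrt(s2 / sxx)
    t_stat <- slope / se
    tibble::tibble(
      gene_id = rownames(ylog), slope = slope, se = se, t_stat = t_stat,
      p_value = 2 * pt(-abs(t_stat), df = n - 2), n_used = n
    )
  } else {
    dplyr::bind_rows(lapply(seq_len(nrow(ylog)), function(g) {
      fit_gene_ancestry(ylog[g, ], x, gene_id = rownames(ylog)[g])
    }))
  }
}

# Genes expressed (nonzero) in too few samples produce degenerate fits;
# exclude them before testing.
expressed_genes <- function(expression, min_prop_nonzero = 0.1) {
  x <- as.matrix(expression)
  rownames(x)[rowMeans(x != 0, na.rm = TRUE) >= min_prop_nonzero]
}

#' Screen all genes for association with a continuous ancestry component
#'
#' Log-normalizes expression (if needed), fits gene-by-gene OLS of log2
#' expression on the chosen ancestry proportion, adjusts p-values across all
#' tested genes by Benjamini-Hochberg, and reports the genes significant at
#' `q_value < alpha`. Genes with nonzero expression in fewer than 10% of
#' samples are excluded before testing.
#'
#' @param expression an [expression_matrix()] (any layer).
#' @param ancestry_table tibble with `sample_id` and `q_<component>` columns,
#'   e.g. from [cohort_ancestry()], or a matrix of proportions with sample
#'   rownames and population colnames.
#' @param component population label to screen on (e.g. `"AFR"`, `"EUR"`).
#' @param alpha FDR threshold for the significant set.
#' @return an `ancestry_screen` object: list with `records` (per-gene tibble
#'   with q_value), `significant_set`, `ancestry_label`, `alpha`.
#' @export
screen_ancestry_genes <- function(expression, ancestry_table, component = "AFR",
                                  alpha = 0.05) {
  ylog <- normalize_log(expression)
  samples <- colnames(ylog)
  q <- extract_component(ancestry_table, component, samples)
  keep <- expressed_genes(expression)
  ylog <- unclass(ylog)[keep, , drop = FALSE]
  records <- ols_screen(ylog, q)
  records$q_value <- bh_adjust(records$p_value)
  records <- dplyr::arrange(records, .data$p_value)
  structure(list(
    ancestry_label = component,
    records = records,
    significant_set = records$gene_id[records$q_value < alpha],
    alpha = alpha
  ), class = "ancestry_screen")
}

extract_component <- function(ancestry_table, component, samples) {
  if (is.matrix(ancestry_table)) {
    if (!component %in% colnames(ancestry_table)) {
      abort(sprintf("component %s not found in ancestry matrix", component))
    }
    miss <- setdiff(samples, rownames(ancestry_table))
    if (length(miss)) {
      abort(paste("samples missing from ancestry table:", paste(miss, collapse = ", ")))
    }
    return(ancestry_table[samples, component])
  }
  col <- paste0("q_", component)
  if (!col %in% names(ancestry_table)) {
    abort(sprintf("column %s not found in ancestry table", col))
  }
  idx <- match(samples, ancestry_table$sample_id)
  if (anyNA(idx)) {
    abort(paste("samples missing from ancestry table:",
                paste(samples[is.na(idx)], collapse = ", ")))
  }
  ancestry_table[[col]][idx]
}

#' @export
print.ancestry_screen <- function(x, ...) {
  cat(sprintf(
    "<ancestry_screen> %s: %d genes tested, %d significant at q < %g\n",
    x$ancestry_label, nrow(x$records), length(x$significant_set), x$alpha
  ))
  invisible(x)
}

#' @method tidy ancestry_screen
#' @export
tidy.ancestry_screen <- function(x, ...) x$records

#' @method glance ancestry_screen
#' @export
glance.ancestry_screen <- function(x, ...) {
  tibble::tibble(
    ancestry_label = x$ancestry_label,
    n_genes = nrow(x$records),
    n_significant = length(x$significant_set),
    alpha = x$alpha
  )
}

#' Volcano plot of an ancestry (or group) expression screen
#'
#' @param object an `ancestry_screen` from [screen_ancestry_genes()] or
#'   [srr_differential()].
#' @param ... unused.
#' @return a ggplot object: per-gene slope (or log2 fold change) against
#'   -log10 q-value, significant genes highlighted.
#' @method autoplot ancestry_screen
#' @export
autoplot.ancestry_screen <- function(object, ...) {
  d <- object$records
  d$effect <- if ("log2fc" %in% names(d)) d$log2fc else d$slope
  d$significant <- d$q_value < object$alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect, y = -log10(.data$q_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = if ("log2fc" %in% names(d)) "log2 fold change" else "log2 expression per unit ancestry",
      y = expression(-log[10] ~ "q-value"),
      colour = sprintf("q < %g", object$alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Two-group expression contrast between self-reported-race groups
#'
#' Per-gene Welch contrast on the log2 layer: group means are compared with
#' unequal-variance standard errors and Welch-Satterthwaite degrees of
#' freedom, then Benjamini-Hochberg adjusted. The reported `log2fc` is
#' mean(group a) - mean(group b) on the log2 scale, with group a the first
#' level (alphabetical unless `group_labels` is a factor), e.g. AA vs EA.
#'
#' @param expression an [expression_matrix()] (any layer).
#' @param group_labels per-sample labels with exactly two levels, each with
#'   at least 2 samples; order must match `colnames(expression)`.
#' @param alpha FDR threshold for the significant set.
#' @return an `ancestry_screen`-classed result whose records carry `log2fc`
#'   instead of an ancestry slope.
#' @export
srr_differential <- function(expression, group_labels, alpha = 0.05) {
  ylog <- normalize_log(expression)
  f <- if (is.factor(group_labels)) droplevels(group_labels) else factor(group_labels)
  if (nlevels(f) != 2) abort("exactly two group labels required")
  if (any(table(f) < 2)) abort("each group needs at least 2 samples")
  if (length(f) != ncol(ylog)) abort("group_labels length must match sample count")
  keep <- expressed_genes(expression)
  y <- unclass(ylog)[keep, , drop = FALSE]

  a <- y[, f == levels(f)[1], drop = FALSE]
  b <- y[, f == levels(f)[2], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se <- sqrt(va / na + vb / nb)
  t_stat <- (ma - mb) / se
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t_stat), df = df)
  p[se == 0 & ma == mb] <- 1               # identical constant rows: no evidence
  records <- tibble::tibble(
    gene_id = rownames(y), log2fc = unname(ma - mb), se = unname(se),
    t_stat = unname(t_stat), df = unname(df), p_value = unname(p),
    n_used = na + nb
  )
  records$q_value <- bh_adjust(records$p_value)
  records <- dplyr::arrange(records, .data$p_value)
  structure(list(
    ancestry_label = paste0("SRR:", levels(f)[1], "-vs-", levels(f)[2]),
    records = records,
    significant_set = records$gene_id[records$q_value < alpha],
    alpha = alpha
  ), class = "ancestry_screen")
}

#' Overlap summary of two significant gene sets
#'
#' Counts shared and set-specific genes between two screens (e.g. the
#' African-ancestry screen against the European-ancestry screen, or a
#' quantitative-ancestry screen against a self-reported-race contrast) and
#' reports the mean absolute fold change of each set's genes, the summary
#' used to compare effect-size magnitudes between screening strategies.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param fold_changes optional named numeric vector of per-gene log2 fold
#'   changes over the shared gene universe; each set is then summarized by
#'   `mean(2^|log2fc|)`, the average absolute fold change on the linear scale.
#' @return list with counts, memberships and (if fold changes supplied) a
#'   per-set mean absolute fold change tibble; classed `overlap_report`.
#' @export
overlap_summary <- function(set_a, set_b, fold_changes = NULL) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  shared <- intersect(set_a, set_b)
  a_only <- setdiff(set_a, set_b)
  b_only <- setdiff(set_b, set_a)
  out <- list(
    counts = tibble::tibble(
      shared = length(shared), a_only = length(a_only), b_only = length(b_only)
    ),
    shared = shared, a_only = a_only, b_only = b_only
  )
  if (!is.null(fold_changes)) {
    avg_fc <- function(set) {
      v <- fold_changes[intersect(set, names(fold_changes))]
      if (!length(v)) NA_real_ else mean(2^abs(v))
    }
    out$avg_abs_fold_change <- tibble::tibble(
      set = c("set_a", "set_b", "shared"),
      mean_abs_fc = c(avg_fc(set_a), avg_fc(set_b), avg_fc(shared))
    )
  }
  structure(out, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> shared %d | a_only %d | b_only %d\n",
              x$counts$shared, x$counts$a_only, x$counts$b_only))
  if (!is.null(x$avg_abs_fold_change)) print(x$avg_abs_fold_change)
  invisible(x)
}

#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  tibble::tibble(
    gene_id = c(x$shared, x$a_only, x$b_only),
    membership = rep(c("shared", "a_only", "b_only"),
                     c(length(x$shared), length(x$a_only), length(x$b_only)))
  )
}
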