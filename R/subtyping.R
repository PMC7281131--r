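#' Rank expression values with minimum-rank tie handling
#'
#' Ranks low-to-high with [rank()] and `ties.method = "min"`. In the default
#' `across_samples` orientation each gene's values are ranked over the n
#' samples (rank 1 = lowest-expressing sample for that gene); the alternative
#' `within_sample` orientation ranks each sample's G genes. The maximum
#' attainable rank (n or G) is attached so signature scores can be
#' normalized.
#'
#' @param expression numeric genes x samples matrix (any layer; ranks are
#'   invariant to monotone transforms within the ranked axis).
#' @param orientation `"across_samples"` (default) or `"within_sample"`.
#' @return a `rank_matrix`: genes x samples matrix of ranks with attributes
#'   `orientation` and `rank_max`.
#' @export
rank_genes <- function(expression, orientation = c("across_samples", "within_sample")) {
  orientation <- match.arg(orientation)
  x <- as.matrix(expression)
  if (orientation == "across_samples") {
    if (ncol(x) < 2) abort("across_samples ranking needs at least 2 samples")
    r <- t(apply(x, 1, rank, ties.method = "min"))
    rank_max <- ncol(x)
  } else {
    r <- apply(x, 2, rank, ties.method = "min")
    rank_max <- nrow(x)
  }
  dimnames(r) <- dimnames(x)
  structure(r, orientation = orientation, rank_max = rank_max,
            class = c("rank_matrix", "matrix", "array"))
}

#' Summarized-rank signature score per sample
#'
#' For each sample, the ranks of the signature's up-genes are summarized with
#' the chosen statistic (median or mean) and normalized by the maximum
#' attainable rank to \[0, 1\]; a sample whose up-genes all carry the top
#' rank scores 1. Down-genes contribute as one minus their normalized
#' summarized rank, and when both directions are present the two parts are
#' averaged. Signature genes absent from the matrix are dropped with a
#' warning; a signature with no matched genes is an error.
#'
#' @param rank_matrix a `rank_matrix` from [rank_genes()].
#' @param signature a [subtype_signature()].
#' @param stat `"median"` or `"mean"`.
#' @return named numeric vector of per-sample scores in \[0, 1\].
#' @export
tnhf_score <- function(rank_matrix, signature, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  fun <- if (stat == "median") median else mean
  rank_max <- attr(rank_matrix, "rank_max") %||% max(rank_matrix)
  genes <- rownames(rank_matrix)
  up <- intersect(signature$up_genes, genes)
  dn <- intersect(signature$down_genes, genes)
  n_absent <- length(signature$up_genes) + length(signature$down_genes) -
    length(up) - length(dn)
  if (!length(up) && !length(dn)) {
    abort(sprintf("no genes of signature %s present in the matrix", signature$name))
  }
  if (n_absent > 0) {
    warn(sprintf("signature %s: %d gene(s) absent from the matrix dropped",
                 signature$name, n_absent))
  }
  part <- function(set) apply(rank_matrix[set, , drop = FALSE], 2, fun) / rank_max
  if (length(up) && length(dn)) {
    (part(up) + (1 - part(dn))) / 2
  } else if (length(up)) {
    part(up)
  } else {
    1 - part(dn)
  }
}

#' Assign the TNHF subtype as the maximal signature score
#'
#' Argmax over the four valid subtype scores; exact ties resolve by the fixed
#' priority BL1 > BL2 > LAR > M.
#'
#' @param scores named numeric vector (or single-row matrix/data frame) with
#'   entries for BL1, BL2, LAR and M.
#' @return the winning subtype label.
#' @export
assign_tnhf_subtype <- function(scores) {
  scores <- unlist(scores)[VALID_SUBTYPES]
  if (anyNA(scores)) abort("scores for all of BL1, BL2, LAR, M are required")
  VALID_SUBTYPES[which.max(scores)]   # which.max keeps the first of tied maxima
}

#' Correlation score of one signature across a cohort
#'
#' Computes, for every sample, the Spearman correlation between the sample's
#' median-centered log expression over the signature genes and the signature
#' template (+1 for up-genes, -1 for down-genes). Centering is per gene
#' across the cohort, so the score measures whether the signature genes sit
#' above or below their cohort-typical level in that sample. Samples with
#' constant expression over the signature genes score 0 and are flagged in
#' the `degenerate` attribute.
#'
#' @param expression an [expression_matrix()] (log layer applied internally).
#' @param signature a [subtype_signature()] with at least 3 genes present.
#' @return named numeric vector of per-sample scores in \[-1, 1\].
#' @export
signature_correlation <- function(expression, signature) {
  ylog <- unclass(normalize_log(expression))
  genes <- rownames(ylog)
  up <- intersect(signature$up_genes, genes)
  dn <- intersect(signature$down_genes, genes)
  sig <- c(up, dn)
  if (length(sig) < 3) {
    abort(sprintf("signature %s: fewer than 3 genes present", signature$name))
  }
  template <- c(rep(1, length(up)), rep(-1, length(dn)))
  centered <- ylog[sig, , drop = FALSE] -
    apply(ylog[sig, , drop = FALSE], 1, median)
  degenerate <- apply(centered, 2, function(v) length(unique(v)) == 1)
  scores <- rep(0, ncol(ylog))
  if (any(!degenerate)) {
    scores[!degenerate] <- suppressWarnings(
      cor(centered[, !degenerate, drop = FALSE], template, method = "spearman")[, 1]
    )
  }
  scores[is.na(scores)] <- 0
  names(scores) <- colnames(ylog)
  attr(scores, "degenerate") <- names(scores)[degenerate]
  scores
}

#' Call subtypes for a cohort with IM/MSL reassignment
#'
#' Correlation scores are computed for all six Lehmann-style signatures; each
#' sample's primary call is the argmax. Because the IM and MSL categories are
#' retired (they reflect infiltrating immune and stromal cell content rather
#' than tumor-intrinsic biology), samples whose primary call is IM or MSL are
#' reassigned to their most-correlated valid subtype — equivalently their
#' second-most-correlated subtype once the retired categories are set aside.
#' Samples with no positive correlation anywhere are still assigned by argmax
#' but flagged `uns = TRUE` (unclassifiable).
#'
#' @param expression an [expression_matrix()].
#' @param signatures named list of [subtype_signature()] covering all of
#'   BL1, BL2, LAR, M, IM, MSL.
#' @return tibble: sample_id, one correlation column per signature (`cs_*`),
#'   primary, secondary, reassigned, uns; classed `subtype_calls`.
#' @export
call_with_reassignment <- function(expression, signatures) {
  signatures <- check_signature_list(signatures, required = ALL_SUBTYPES)
  cs <- vapply(ALL_SUBTYPES, function(s) {
    as.numeric(signature_correlation(expression, signatures[[s]]))
  }, numeric(ncol(expression)))
  if (ncol(expression) == 1) cs <- matrix(cs, nrow = 1, dimnames = list(NULL, ALL_SUBTYPES))
  rownames(cs) <- colnames(expression)
  calls <- reassign_calls(cs)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(expression)),
    tibble::as_tibble(cs, .name_repair = ~ paste0("cs_", .x)),
    calls
  )
  class(out) <- c("subtype_calls", class(out))
  out
}

# Primary/secondary/reassigned logic on a samples x 6 correlation matrix.
# Ties resolve by the fixed column order BL1, BL2, LAR, M, IM, MSL.
reassign_calls <- function(cs) {
  cs <- cs[, ALL_SUBTYPES, drop = FALSE]
  prim_i <- apply(cs, 1, which.max)
  primary <- ALL_SUBTYPES[prim_i]
  secondary <- vapply(seq_len(nrow(cs)), function(i) {
    v <- cs[i, ]
    v[prim_i[i]] <- -Inf
    ALL_SUBTYPES[which.max(v)]
  }, character(1))
  valid <- cs[, VALID_SUBTYPES, drop = FALSE]
  best_valid <- VALID_SUBTYPES[apply(valid, 1, which.max)]
  reassigned <- ifelse(primary %in% RETIRED_SUBTYPES, best_valid, primary)
  tibble::tibble(
    primary = primary, secondary = secondary, reassigned = reassigned,
    uns = apply(cs, 1, function(v) all(v <= 0))
  )
}

new_cs_matrix <- function(m) {
  sds <- apply(m, 2, sd)
  sds[sds == 0] <- 1
  std <- sweep(m, 2, sds, "/")
  structure(m, standardized = std, class = c("cs_matrix", "matrix", "array"))
}

#' @export
print.cs_matrix <- function(x, ...) {
  cat(sprintf("<cs_matrix> %d samples x %d method-by-subtype scores\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Build the correlation-score matrix over methods and subtypes
#'
#' Assembles, per sample, 16 scores: the signature correlation computed on
#' each of two supplied expression scalings (e.g. TPM-like and FPKM-like, or
#' counts and normalized layers) and the TNHF median- and mean-rank scores,
#' each over the four valid subtypes. TNHF scores, natively in \[0, 1\], are
#' recentred to \[-1, 1\] via `2 * score - 1` so all columns share a scale
#' with a meaningful zero. A column-standardized copy (divided by the column
#' standard deviation; the natural zero is preserved) is attached for
#' clustering and status calling.
#'
#' @param expression_a,expression_b two [expression_matrix()] objects over the
#'   same samples in any two declared layers.
#' @param signatures named list of [subtype_signature()] covering BL1, BL2,
#'   LAR, M (retired signatures are ignored here).
#' @param rank_orientation passed to [rank_genes()] for the TNHF scores.
#' @return a `cs_matrix`: samples x 16 matrix, columns
#'   `<method>.<subtype>`, with a `standardized` attribute.
#' @export
build_cs_matrix <- function(expression_a, expression_b, signatures,
                            rank_orientation = "across_samples") {
  signatures <- check_signature_list(signatures, required = VALID_SUBTYPES)
  if (!identical(colnames(expression_a), colnames(expression_b))) {
    abort("the two expression scalings carry different samples")
  }
  layer_a <- paste0("corr_", expr_layer(expression_a))
  layer_b <- paste0("corr_", expr_layer(expression_b))
  if (layer_a == layer_b) layer_b <- paste0(layer_b, "2")

  ranks <- rank_genes(normalize_log(expression_b), orientation = rank_orientation)
  blocks <- list()
  for (s in VALID_SUBTYPES) {
    sig <- signatures[[s]]
    blocks[[paste(layer_a, s, sep = ".")]] <- as.numeric(signature_correlation(expression_a, sig))
    blocks[[paste(layer_b, s, sep = ".")]] <- as.numeric(signature_correlation(expression_b, sig))
    blocks[[paste("tnhf_median", s, sep = ".")]] <- 2 * tnhf_score(ranks, sig, "median") - 1
    blocks[[paste("tnhf_mean", s, sep = ".")]] <- 2 * tnhf_score(ranks, sig, "mean") - 1
  }
  m <- do.call(cbind, blocks)
  rownames(m) <- colnames(expression_a)
  new_cs_matrix(m)
}

#' Heterogenic clustering of the correlation-score matrix
#'
#' Agglomerative hierarchical clustering (Ward's minimum-variance linkage on
#' Euclidean distances) of the column-standardized correlation-score matrix,
#' cut into k clusters. Deterministic for a given sample order; `hclust`
#' resolves merge ties by agglomeration order.
#'
#' @param cs_matrix a `cs_matrix` from [build_cs_matrix()] (or any samples x
#'   scores matrix).
#' @param k number of clusters (default 6, the number of heterogenic nodes
#'   recovered in TNBC cohorts).
#' @return list with `clusters` (named integer vector), `hclust` (the tree)
#'   and the matrix used; classed `heterogenic_clustering`.
#' @export
cluster_heterogenic <- function(cs_matrix, k = 6) {
  std <- attr(cs_matrix, "standardized") %||% as.matrix(cs_matrix)
  if (k < 2) abort("k must be >= 2")
  if (nrow(std) < k) abort(sprintf("cannot cut %d samples into %d clusters", nrow(std), k))
  tree <- hclust(dist(std, method = "euclidean"), method = "ward.D2")
  structure(list(
    clusters = cutree(tree, k = k), hclust = tree, k = k, cs = cs_matrix
  ), class = "heterogenic_clustering")
}

#' @export
print.heterogenic_clustering <- function(x, ...) {
  cat(sprintf("<heterogenic_clustering> %d samples in %d clusters (Ward/Euclidean)\n",
              length(x$clusters), x$k))
  print(table(x$clusters))
  invisible(x)
}

#' @method tidy heterogenic_clustering
#' @export
tidy.heterogenic_clustering <- function(x, ...) {
  tibble::tibble(sample_id = names(x$clusters), cluster = unname(x$clusters))
}

#' Dendrogram-free cluster map of the correlation-score matrix
#'
#' @param object a `heterogenic_clustering` from [cluster_heterogenic()].
#' @param ... unused.
#' @return a ggplot heatmap of standardized scores, samples ordered by the
#'   dendrogram and annotated by cluster.
#' @method autoplot heterogenic_clustering
#' @export
autoplot.heterogenic_clustering <- function(object, ...) {
  std <- attr(object$cs, "standardized") %||% as.matrix(object$cs)
  ord <- object$hclust$order
  d <- tibble::as_tibble(std, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "score", values_to = "value")
  d$sample_id <- factor(d$sample_id, levels = rownames(std)[ord])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$score,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "standardized CS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Heterogenic +/-/IND status labels per cluster
#'
#' For each cluster and each valid subtype, the mean standardized correlation
#' score (averaged over that subtype's method columns and the cluster's
#' samples) is thresholded at `tau`: above +tau the subtype is present (+),
#' below -tau absent (-), otherwise indistinct (0). The canonical label
#' concatenates the non-zero statuses with "/", positive statuses first and
#' each group ordered by decreasing magnitude — yielding node names of the
#' forms seen in heterogenic TNBC cohorts such as `LAR+/BL1-`, `M-`, `M+`,
#' `BL2+/BL1-`, `BL1+/BL2-`. A cluster with no status at all is `IND`.
#'
#' @param cs_matrix a `cs_matrix` (its `standardized` attribute is used).
#' @param clusters named integer vector of cluster ids per sample (e.g.
#'   `cluster_heterogenic(...)$clusters`).
#' @param tau positive threshold on the cluster-mean standardized score.
#' @return tibble: cluster, label, and one status column per subtype
#'   (values "+", "-", "0"), plus the mean score per subtype.
#' @export
status_labels <- function(cs_matrix, clusters, tau = 0.2) {
  if (tau <= 0) abort("tau must be positive")
  std <- attr(cs_matrix, "standardized") %||% as.matrix(cs_matrix)
  if (is.null(names(clusters))) names(clusters) <- rownames(std)
  subtype_of <- sub(".*\\.", "", colnames(std))
  rows <- lapply(sort(unique(clusters)), function(cl) {
    members <- names(clusters)[clusters == cl]
    if (!length(members)) abort(sprintf("cluster %s is empty", cl))
    block <- std[members, , drop = FALSE]
    means <- vapply(VALID_SUBTYPES, function(s) {
      mean(block[, subtype_of == s, drop = FALSE])
    }, double(1))
    status <- ifelse(means > tau, "+", ifelse(means < -tau, "-", "0"))
    lab <- canonical_label(means, status)
    dplyr::bind_cols(
      tibble::tibble(cluster = cl, label = lab),
      tibble::as_tibble(as.list(setNames(status, paste0("status_", VALID_SUBTYPES)))),
      tibble::as_tibble(as.list(setNames(means, paste0("mean_", VALID_SUBTYPES))))
    )
  })
  dplyr::bind_rows(rows)
}

canonical_label <- function(means, status) {
  plus <- names(means)[status == "+"]
  minus <- names(means)[status == "-"]
  plus <- plus[order(abs(means[plus]), decreasing = TRUE)]
  minus <- minus[order(abs(means[minus]), decreasing = TRUE)]
  parts <- c(if (length(plus)) paste0(plus, "+"),
             if (length(minus)) paste0(minus, "-"))
  if (!length(parts)) "IND" else paste(parts, collapse = "/")
}
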