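#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm rbeta runif rbinom rgamma rnbinom median cor sd
#'   pt p.adjust ks.test hclust cutree dist var setNames complete.cases
#' @importFrom utils head
NULL

# Superpopulation labels used by default, in 1000G ordering convention.
SUPERPOP <- c("AFR", "EUR", "EAS", "SAS", "AMR")

VALID_SUBTYPES <- c("BL1", "BL2", "LAR", "M")
RETIRED_SUBTYPES <- c("IM", "MSL")
ALL_SUBTYPES <- c("BL1", "BL2", "LAR", "M", "IM", "MSL")

pop_labels <- function(K) {
  if (K <= length(SUPERPOP)) SUPERPOP[seq_len(K)] else c(SUPERPOP, paste0("POP", seq_len(K - length(SUPERPOP))))
}

#' Construct a reference allele-frequency panel
#'
#' A reference panel holds alternate-allele frequencies for K ancestral
#' populations over a shared set of biallelic SNVs. Frequencies are clamped to
#' \[0.01, 0.99\] so that every genotype configuration has finite
#' log-likelihood, mirroring the exclusion of rare variants from ancestry
#' panels.
#'
#' @param freq numeric K x J matrix of alternate-allele frequencies; rows are
#'   populations, columns are SNVs.
#' @param snps tibble with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`
#'   describing the J variants, in column order of `freq`.
#' @param populations character vector of K population labels; defaults to the
#'   rownames of `freq`.
#' @return an object of class `reference_panel`: a list with elements `freq`
#'   (clamped matrix with dimnames) and `snps`.
#' @export
reference_panel <- function(freq, snps, populations = rownames(freq)) {
  freq <- as.matrix(freq)
  if (is.null(populations)) populations <- pop_labels(nrow(freq))
  stopifnot(nrow(freq) >= 2, length(populations) == nrow(freq))
  snps <- tibble::as_tibble(snps)
  req <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(snps))) {
    abort(paste("panel `snps` must have columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(snps$snp_id)) abort("panel snp_ids must be unique")
  if (ncol(freq) != nrow(snps)) abort("freq columns and snps rows disagree")
  freq <- clamp_freq(freq)
  dimnames(freq) <- list(populations, snps$snp_id)
  structure(list(freq = freq, snps = snps), class = "reference_panel")
}

clamp_freq <- function(f, lo = 0.01, hi = 0.99) pmin(pmax(f, lo), hi)

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf(
    "<reference_panel> %d populations (%s) x %d SNVs\n",
    nrow(x$freq), paste(rownames(x$freq), collapse = ", "), ncol(x$freq)
  ))
  invisible(x)
}

#' Construct a genotype dosage matrix
#'
#' @param dosage integer n x J matrix of alternate-allele dosages in
#'   \{0, 1, 2\}; `NA` marks missing genotypes. Rows are samples, columns SNVs.
#' @param sample_ids,snp_ids optional dimnames; taken from `dosage` if absent.
#' @return a `genotype_matrix`: the dosage matrix with dimnames and class set.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage), snp_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  bad <- !is.na(dosage) & !dosage %in% c(0, 1, 2)
  if (any(bad)) abort("dosages must be 0, 1, 2 or NA")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosage)))
  dimnames(dosage) <- list(sample_ids, snp_ids)
  structure(dosage, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d SNVs (%.1f%% missing)\n",
    nrow(x), ncol(x), 100 * mean(is.na(x))
  ))
  invisible(x)
}

#' Construct an expression matrix with a declared layer
#'
#' Expression values are stored genes x samples, the orientation used
#' throughout transcriptomics toolchains. The `layer` attribute declares what
#' the values are — raw counts, normalized abundances (TPM/FPKM-like), or
#' log2-transformed values — so downstream steps can transform appropriately.
#'
#' @param x numeric genes x samples matrix.
#' @param layer one of `"counts"`, `"normalized"`, `"log"`.
#' @return an `expression_matrix` (matrix with a `layer` attribute).
#' @export
expression_matrix <- function(x, layer = c("counts", "normalized", "log")) {
  layer <- match.arg(layer)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  structure(x, layer = layer, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples, layer = %s\n",
    nrow(x), ncol(x), expr_layer(x)
  ))
  invisible(x)
}

expr_layer <- function(x) attr(x, "layer") %||% "counts"

#' Construct a directional subtype gene signature
#'
#' @param name signature name, one of BL1, BL2, IM, LAR, M, MSL.
#' @param up_genes,down_genes character vectors of gene identifiers expected
#'   to be up- / down-regulated in tumors of this subtype. Must be disjoint
#'   and jointly nonempty.
#' @return a `subtype_signature` list.
#' @export
subtype_signature <- function(name, up_genes, down_genes = character()) {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (length(intersect(up_genes, down_genes))) {
    abort(sprintf("signature %s: up and down gene sets overlap", name))
  }
  if (!length(up_genes) && !length(down_genes)) {
    abort(sprintf("signature %s is empty", name))
  }
  structure(list(name = name, up_genes = up_genes, down_genes = down_genes),
            class = "subtype_signature")
}

#' @export
print.subtype_signature <- function(x, ...) {
  cat(sprintf("<subtype_signature> %s: %d up, %d down\n",
              x$name, length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

check_signature_list <- function(signatures, required = VALID_SUBTYPES) {
  nm <- vapply(signatures, function(s) s$name, character(1))
  names(signatures) <- nm
  missing <- setdiff(required, nm)
  if (length(missing)) {
    abort(paste("missing subtype signatures:", paste(missing, collapse = ", ")))
  }
  signatures
}

# Derive a stream of sub-seeds from one master seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 100000L) * 13L + seq_len(n) * 7919L
}
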