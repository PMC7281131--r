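#' Read genotype dosages from a VCF file
#'
#' Parses a VCFv4.2 file (via \pkg{vcfR}) and converts GT fields to
#' alternate-allele dosages. Only biallelic SNVs are retained: records with
#' more than one ALT allele, or with REF/ALT longer than one base (INDELs),
#' are excluded and counted. Missing genotypes (`./.` or `.`) become `NA`.
#' Variant metadata (chrom, pos, ref, alt) is attached as the `snp_meta`
#' attribute for downstream panel harmonization.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @return a [genotype_matrix()] (samples x variants) with attributes
#'   `snp_meta` (tibble) and `dropped` (tibble of exclusion counts).
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  multiallelic <- grepl(",", fix$ALT %||% "")
  indel <- !multiallelic & (nchar(fix$REF) != 1 | nchar(fix$ALT) != 1)
  keep <- !multiallelic & !indel
  if (!any(keep)) abort("no biallelic SNV records in VCF")

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = sum(keep))
  alt_count <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }
  dosage <- t(apply(gt, 2, function(col) vapply(col, alt_count, integer(1))))
  if (ncol(v@gt) - 1 == 1) dosage <- matrix(dosage, nrow = 1)

  meta <- tibble::tibble(
    snp_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                    paste(fix$CHROM[keep], fix$POS[keep], sep = ":"), fix$ID[keep]),
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep]
  )
  g <- genotype_matrix(dosage,
                       sample_ids = colnames(v@gt)[-1],
                       snp_ids = meta$snp_id)
  attr(g, "snp_meta") <- meta
  attr(g, "dropped") <- tibble::tibble(
    reason = c("multiallelic", "indel"),
    n = c(sum(multiallelic), sum(indel))
  )
  g
}

#' Write a genotype matrix as a minimal VCFv4.2 file
#'
#' Emits biallelic SNV records with GT-only genotype columns (unphased,
#' `0/0`, `0/1`, `1/1`, or `./.` for missing), 1-based positions. The subset
#' of VCF written here round-trips through [read_vcf_genotypes()].
#'
#' @param genotypes a [genotype_matrix()].
#' @param snps tibble with snp_id, chrom, pos, ref, alt (one row per column
#'   of `genotypes`); defaults to the attached `snp_meta` attribute.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(genotypes, path, snps = attr(genotypes, "snp_meta")) {
  if (is.null(snps)) abort("no snp metadata supplied or attached")
  stopifnot(nrow(snps) == ncol(genotypes))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(snps)), function(j) {
    d <- unclass(genotypes)[, j]
    gts <- ifelse(is.na(d), "./.", gt_str[d + 1])
    paste(c(snps$chrom[j], snps$pos[j], snps$snp_id[j], snps$ref[j],
            snps$alt[j], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read directional subtype signatures from a GMT file
#'
#' Parses the tab-separated GMT gene-set format (via
#' [fgsea::gmtPathways()]) and merges `<NAME>_UP` / `<NAME>_DN` line pairs
#' into one directional [subtype_signature()]; a line without the suffix (or
#' an unpaired `_UP`) becomes an up-only signature.
#'
#' @param path path to a GMT file.
#' @return named list of [subtype_signature()] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT not found: %s", path))
  if (length(readLines(path, warn = FALSE)) == 0) return(list())
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) abort("duplicate signature names in GMT")
  base <- sub("_(UP|DN)$", "", names(sets))
  out <- list()
  for (b in unique(base)) {
    up <- sets[[paste0(b, "_UP")]] %||% (if (b %in% names(sets)) sets[[b]] else character())
    dn <- sets[[paste0(b, "_DN")]] %||% character()
    out[[b]] <- subtype_signature(b, up_genes = up, down_genes = dn)
  }
  out
}

#' Write directional subtype signatures to a GMT file
#'
#' @param signatures named list of [subtype_signature()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  lines <- character()
  for (s in signatures) {
    if (length(s$up_genes)) {
      nm <- if (length(s$down_genes)) paste0(s$name, "_UP") else s$name
      lines <- c(lines, paste(c(nm, s$name, s$up_genes), collapse = "\t"))
    }
    if (length(s$down_genes)) {
      lines <- c(lines, paste(c(paste0(s$name, "_DN"), s$name, s$down_genes), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a reference panel as TSV
#'
#' The panel TSV has columns snp_id, chrom, pos, ref, alt followed by one
#' alternate-allele-frequency column per population.
#'
#' @param path file path.
#' @return [read_panel_tsv()] returns a [reference_panel()];
#'   [write_panel_tsv()] returns `path` invisibly.
#' @export
read_panel_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  pops <- setdiff(names(d), meta_cols)
  if (length(pops) < 2) abort("panel TSV needs at least 2 population columns")
  freq <- t(as.matrix(d[, pops]))
  reference_panel(freq, d[, meta_cols], pops)
}

#' @rdname read_panel_tsv
#' @param panel a [reference_panel()].
#' @export
write_panel_tsv <- function(panel, path) {
  d <- dplyr::bind_cols(panel$snps,
                        tibble::as_tibble(t(panel$freq)))
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' Read/write an expression matrix as TSV
#'
#' Genes x samples with a leading `gene_id` column; the layer is recorded in
#' a `# layer: <layer>` comment on the first line and restored on read.
#'
#' @param path file path.
#' @return [read_expression_tsv()] returns an [expression_matrix()];
#'   [write_expression_tsv()] returns `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1)
  layer <- if (grepl("^# layer:", first)) trimws(sub("^# layer:", "", first)) else "counts"
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  expression_matrix(m, layer = layer)
}

#' @rdname read_expression_tsv
#' @param expression an [expression_matrix()].
#' @export
write_expression_tsv <- function(expression, path) {
  d <- tibble::as_tibble(as.matrix(expression), rownames = "gene_id")
  body <- sub("\n$", "", readr::format_tsv(d))
  writeLines(c(sprintf("# layer: %s", expr_layer(expression)), body), path)
  invisible(path)
}
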