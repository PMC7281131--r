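# Writes a simulated cohort to disk in the pipeline's input formats.
write_cohort_inputs <- function(co, dir) {
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    panel = file.path(dir, "panel.tsv"),
    expression = file.path(dir, "expression.tsv"),
    signatures = file.path(dir, "signatures.gmt"),
    metadata = file.path(dir, "metadata.tsv")
  )
  g <- co$genotypes
  attr(g, "snp_meta") <- co$panel$snps
  write_vcf_genotypes(g, paths$vcf)
  write_panel_tsv(co$panel, paths$panel)
  write_expression_tsv(co$expression, paths$expression)
  write_gmt(co$signatures, paths$signatures)
  readr::write_tsv(co$metadata, paths$metadata, progress = FALSE)
  paths
}

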