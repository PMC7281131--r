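#' Configuration for a full pipeline run
#'
#' Collects the input paths and stage parameters of one reproducible run:
#' variant filtering, cohort ancestry estimation, the continuous-ancestry
#' gene screen (optionally also the self-reported-group contrast), and TNHF
#' subtyping with heterogenic clustering. Paths are validated up front so a
#' misconfigured run fails before any stage executes.
#'
#' @param vcf path to the genotype VCF.
#' @param panel path to the reference-panel TSV.
#' @param expression path to the expression TSV (counts or normalized).
#' @param signatures path to the signature GMT (all six subtype signatures).
#' @param metadata optional path to a sample-metadata TSV with `sample_id`
#'   and a group column; enables the SRR contrast and subsetting.
#' @param out_dir output directory (created if absent).
#' @param maf_min,tol,max_iter ancestry-stage parameters.
#' @param component,alpha association-stage parameters.
#' @param group_col metadata column holding the two-level group label.
#' @param subset_col,subset_value optional metadata filter applied before the
#'   association stage (e.g. restrict to treatment-naive samples).
#' @param k,tau,stat,rank_orientation subtyping-stage parameters.
#' @param seed integer seed recorded in the manifest (estimation itself is
#'   deterministic; the seed governs any simulated inputs upstream).
#' @return a validated `run_config` list.
#' @export
run_config <- function(vcf, panel, expression, signatures, out_dir,
                       metadata = NULL, maf_min = 0.05, tol = 1e-6,
                       max_iter = 2000, component = "AFR", alpha = 0.05,
                       group_col = "srr_group", subset_col = NULL,
                       subset_value = NULL, k = 6, tau = 0.2,
                       stat = "median", rank_orientation = "across_samples",
                       seed = 1L) {
  cfg <- list(
    vcf = vcf, panel = panel, expression = expression, signatures = signatures,
    metadata = metadata, out_dir = out_dir, maf_min = maf_min, tol = tol,
    max_iter = max_iter, component = component, alpha = alpha,
    group_col = group_col, subset_col = subset_col,
    subset_value = subset_value, k = k, tau = tau, stat = stat,
    rank_orientation = rank_orientation, seed = as.integer(seed)
  )
  required <- c("vcf", "panel", "expression", "signatures")
  for (f in required) {
    if (is.null(cfg[[f]])) abort(sprintf("config field `%s` is required", f))
    if (!file.exists(cfg[[f]])) abort(sprintf("config: %s path does not exist: %s", f, cfg[[f]]))
  }
  if (!is.null(metadata) && !file.exists(metadata)) {
    abort(sprintf("config: metadata path does not exist: %s", metadata))
  }
  structure(cfg, class = "run_config")
}

#' Run the full ancestry/association/subtyping pipeline
#'
#' Executes the stages in order — read and filter variants against the panel,
#' estimate per-individual ancestry, screen genes for association with the
#' configured ancestry component (plus the two-group contrast when metadata
#' is present), call TNHF subtypes with IM/MSL reassignment, build the
#' correlation-score matrix and derive heterogenic category nodes — writing
#' each stage's table into `out_dir` together with a manifest of input/output
#' checksums. All stages are deterministic, so re-running an identical
#' configuration reproduces identical output checksums.
#'
#' @param config a [run_config()].
#' @return a `run_manifest`: list with `config`, `files` (tibble of path,
#'   md5), `warnings`, `timestamp`, plus the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warns <- character()
  note <- function(stage, msg) sprintf("[%s] %s", stage, msg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }

  genotypes <- stage("read_vcf", read_vcf_genotypes(config$vcf))
  drop0 <- attr(genotypes, "dropped")
  warns <- c(warns, note("read_vcf", paste(drop0$reason, drop0$n, sep = "=", collapse = " ")))
  panel <- stage("read_panel", read_panel_tsv(config$panel))
  expression <- stage("read_expression", read_expression_tsv(config$expression))
  signatures <- stage("read_gmt", read_gmt(config$signatures))
  metadata <- if (!is.null(config$metadata)) {
    readr::read_tsv(config$metadata, show_col_types = FALSE, progress = FALSE)
  }

  flt <- stage("filter_variants", filter_variants(genotypes, panel, config$maf_min))
  warns <- c(warns, note("filter_variants",
                         paste(flt$dropped$reason, flt$dropped$n, sep = "=", collapse = " ")))
  ancestry <- stage("ancestry", cohort_ancestry(flt$genotypes, flt$panel,
                                                tol = config$tol,
                                                max_iter = config$max_iter))

  assoc_samples <- colnames(expression)
  if (!is.null(config$subset_col)) {
    if (is.null(metadata)) abort("subset requested but no metadata supplied")
    keep_ids <- metadata$sample_id[metadata[[config$subset_col]] == config$subset_value]
    assoc_samples <- intersect(assoc_samples, keep_ids)
  }
  expr_assoc <- expression_matrix(
    as.matrix(expression)[, assoc_samples, drop = FALSE], expr_layer(expression))
  screen <- stage("associate",
                  screen_ancestry_genes(expr_assoc, ancestry,
                                        component = config$component,
                                        alpha = config$alpha))
  srr <- NULL
  if (!is.null(metadata) && config$group_col %in% names(metadata)) {
    groups <- metadata[[config$group_col]][match(assoc_samples, metadata$sample_id)]
    if (length(unique(groups)) == 2 && all(table(groups) >= 2)) {
      srr <- stage("srr_differential", srr_differential(expr_assoc, groups, config$alpha))
    } else {
      warns <- c(warns, note("srr_differential",
                             "skipped: need two groups with >= 2 samples each"))
    }
  }

  norm <- normalize_log(expression)
  calls <- stage("subtype", call_with_reassignment(expression, signatures))
  cs <- stage("cs_matrix", build_cs_matrix(expression, norm, signatures,
                                           rank_orientation = config$rank_orientation))
  het <- stage("cluster", cluster_heterogenic(cs, k = min(config$k, nrow(cs))))
  labels <- stage("status_labels", status_labels(cs, het$clusters, tau = config$tau))

  p <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(dplyr::as_tibble(ancestry), p("ancestry.tsv"), progress = FALSE)
  readr::write_tsv(screen$records, p("ancestry_screen.tsv"), progress = FALSE)
  writeLines(screen$significant_set, p("ancestry_significant_genes.txt"))
  if (!is.null(srr)) readr::write_tsv(srr$records, p("srr_screen.tsv"), progress = FALSE)
  calls_out <- dplyr::mutate(dplyr::as_tibble(calls),
                             cluster = unname(het$clusters[.data$sample_id]))
  calls_out <- dplyr::left_join(calls_out,
                                labels[, c("cluster", "label")], by = "cluster")
  readr::write_tsv(calls_out, p("subtype_calls.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(as.matrix(cs), rownames = "sample_id"),
                   p("cs_matrix.tsv"), progress = FALSE)
  readr::write_tsv(labels, p("heterogenic_nodes.tsv"), progress = FALSE)

  cfg_serial <- unclass(config)
  cfg_serial[vapply(cfg_serial, is.null, logical(1))] <- NULL
  jsonlite::write_json(cfg_serial, p("run_config.json"), auto_unbox = TRUE, pretty = TRUE)

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, p("manifest.json"))
  inputs <- c(config$vcf, config$panel, config$expression, config$signatures,
              config$metadata)
  files <- tibble::tibble(
    role = c(rep("input", length(inputs)), rep("output", length(outputs))),
    path = c(inputs, outputs),
    md5 = unname(tools::md5sum(c(inputs, outputs)))
  )
  manifest <- structure(list(
    version = as.character(utils::packageVersion("tnhf")),
    config = cfg_serial,
    config_md5 = unname(tools::md5sum(p("run_config.json"))),
    files = files,
    warnings = warns,
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "run_manifest")
  jsonlite::write_json(
    list(version = manifest$version, config_md5 = manifest$config_md5,
         files = files, warnings = warns, timestamp = manifest$timestamp),
    p("manifest.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  manifest$results <- list(ancestry = ancestry, screen = screen, srr = srr,
                           calls = calls_out, cs = cs, clustering = het,
                           labels = labels)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> tnhf %s, %d files tracked, %d warnings\n",
              x$version, nrow(x$files), length(x$warnings)))
  invisible(x)
}
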