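#' Simulation configuration for a synthetic TNBC cohort
#'
#' Bundles the knobs of the synthetic-data generator. Defaults describe the
#' desk-scale study conditions used throughout the package's validation: three
#' ancestral populations diverged at Fst 0.15 (on the order of continental
#' human divergence), 5000 biallelic SNVs, 60 tumors, 2000 genes of which 100
#' carry a planted log2 slope of 1.25 per unit African proportion — a
#' realized fold change of 2^1.25 ~ 2.4 when contrasting fully African
#' against fully European genomes — and a log2 shift of 2 on each sample's
#' own subtype signature genes.
#'
#' @param K number of ancestral populations (>= 2).
#' @param J number of biallelic SNVs.
#' @param n number of samples (individuals/tumors).
#' @param fst divergence of population allele frequencies from the shared
#'   ancestral frequency, in (0, 1).
#' @param dirichlet_alpha Dirichlet concentration for true admixture
#'   proportions; scalar or length-K.
#' @param G total number of genes.
#' @param n_effect_genes number of genes with a planted ancestry slope.
#' @param beta_effect log2 expression change per unit African ancestry
#'   proportion at the planted genes.
#' @param signature_effect log2 shift applied to a sample's own subtype
#'   up-genes (+) and down-genes (-).
#' @param noise_dispersion negative-binomial dispersion of count noise
#'   (variance = mu + dispersion * mu^2).
#' @param seed integer seed fixing all randomness; identical config + seed
#'   reproduce identical cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(K = 3, J = 5000, n = 60, fst = 0.15, dirichlet_alpha = 1,
                       G = 2000, n_effect_genes = 100, beta_effect = 1.25,
                       signature_effect = 2, noise_dispersion = 0.05, seed = 1L) {
  if (K < 2) abort("K must be >= 2")
  if (J < 1 || n < 1 || G < 1) abort("J, n and G must be positive")
  if (fst <= 0 || fst >= 1) abort("fst must lie in (0, 1)")
  if (n_effect_genes > G) abort("n_effect_genes cannot exceed G")
  if (noise_dispersion < 0) abort("noise_dispersion must be >= 0")
  structure(list(
    K = as.integer(K), J = as.integer(J), n = as.integer(n), fst = fst,
    dirichlet_alpha = dirichlet_alpha, G = as.integer(G),
    n_effect_genes = as.integer(n_effect_genes), beta_effect = beta_effect,
    signature_effect = signature_effect, noise_dispersion = noise_dispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a diverged reference allele-frequency panel
#'
#' Draws, for each SNV, a shared ancestral frequency and then one frequency
#' per population from the Balding-Nichols Beta model
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is the ancestral frequency `p`
#' and whose spread grows with the divergence parameter `F`. All frequencies
#' are clamped to \[0.01, 0.99\].
#'
#' @param K number of populations (>= 2).
#' @param J number of SNVs (>= 1).
#' @param fst divergence parameter in (0, 1).
#' @param seed integer seed.
#' @param populations optional population labels (default 1000G-style).
#' @return a [reference_panel()].
#' @export
gen_reference_panel <- function(K, J, fst, seed = 1L, populations = pop_labels(K)) {
  if (K < 2) abort("K must be >= 2")
  if (J < 1) abort("J must be >= 1")
  if (fst <= 0 || fst >= 1) abort("fst must lie in (0, 1)")
  set.seed(as.integer(seed))
  p_anc <- runif(J, 0.1, 0.9)
  shape_scale <- (1 - fst) / fst
  freq <- matrix(NA_real_, K, J)
  for (k in seq_len(K)) {
    freq[k, ] <- rbeta(J, p_anc * shape_scale, (1 - p_anc) * shape_scale)
  }
  snps <- tibble::tibble(
    snp_id = sprintf("snp%05d", seq_len(J)),
    chrom = "1",
    pos = seq_len(J) * 100L,
    ref = "A",
    alt = "G"
  )
  reference_panel(freq, snps, populations)
}

#' Draw true admixture proportions from a Dirichlet distribution
#'
#' @param n number of individuals.
#' @param K number of populations.
#' @param alpha Dirichlet concentration, scalar or length-K.
#' @param seed integer seed.
#' @param populations population labels.
#' @return an n x K matrix of proportions; each row sums to 1.
#' @export
gen_ancestry_truth <- function(n, K, alpha = 1, seed = 1L, populations = pop_labels(K)) {
  set.seed(as.integer(seed))
  alpha <- rep_len(alpha, K)
  g <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  q <- g / rowSums(g)
  dimnames(q) <- list(paste0("S", seq_len(n)), populations)
  q
}

#' Generate admixed genotypes from a panel and true ancestry proportions
#'
#' Each dosage is drawn `Binomial(2, p_ij)` with
#' `p_ij = sum_k q_ik * f_kj`: the two allele copies of individual i at site j
#' are independent draws from that individual's ancestry-weighted allele
#' frequency.
#'
#' @param panel a [reference_panel()].
#' @param q_true n x K matrix of ancestry proportions on the simplex, with
#'   columns matching the panel's populations.
#' @param seed integer seed.
#' @return a [genotype_matrix()] (n x J, values in \{0,1,2\}).
#' @export
gen_admixed_genotypes <- function(panel, q_true, seed = 1L) {
  q_true <- as.matrix(q_true)
  if (ncol(q_true) != nrow(panel$freq)) {
    abort("q_true columns must match the panel's population count")
  }
  if (any(abs(rowSums(q_true) - 1) > 1e-6) || any(q_true < 0)) {
    abort("q_true rows must be proportions on the simplex")
  }
  set.seed(as.integer(seed))
  p <- q_true %*% panel$freq                       # n x J success probabilities
  g <- matrix(rbinom(length(p), size = 2L, prob = p), nrow(p), ncol(p))
  genotype_matrix(g,
    sample_ids = rownames(q_true) %||% paste0("S", seq_len(nrow(p))),
    snp_ids = colnames(panel$freq)
  )
}

#' Generate directional subtype signatures over a synthetic gene universe
#'
#' Draws disjoint up/down gene sets for the six Lehmann-style subtype labels
#' (BL1, BL2, LAR, M plus the retired IM and MSL) from the supplied gene pool,
#' so that planted subtype identities are recoverable by signature scoring.
#'
#' @param genes character vector: the gene universe to draw from.
#' @param genes_per_set genes in each up and each down set.
#' @param seed integer seed.
#' @param subtypes signature names to generate.
#' @return named list of [subtype_signature()] objects.
#' @export
gen_signatures <- function(genes, genes_per_set = 25, seed = 1L, subtypes = ALL_SUBTYPES) {
  need <- 2 * genes_per_set * length(subtypes)
  if (length(genes) < need) {
    abort(sprintf("gene pool too small: need %d, have %d", need, length(genes)))
  }
  set.seed(as.integer(seed))
  picked <- sample(genes, need)
  sigs <- vector("list", length(subtypes))
  for (i in seq_along(subtypes)) {
    block <- picked[((i - 1) * 2 * genes_per_set + 1):(i * 2 * genes_per_set)]
    sigs[[i]] <- subtype_signature(
      subtypes[i],
      up_genes = block[seq_len(genes_per_set)],
      down_genes = block[genes_per_set + seq_len(genes_per_set)]
    )
  }
  names(sigs) <- subtypes
  sigs
}

#' Generate a synthetic expression count matrix with planted structure
#'
#' The log2 mean of gene g in sample i is
#' `baseline_g + beta_effect * q_AFR_i * [g is an effect gene]
#'  + signature_effect * dir(g, subtype_i)`,
#' where `dir` is +1 for the sample's own subtype up-genes, -1 for its
#' down-genes and 0 otherwise. Counts are drawn from a negative-binomial with
#' that mean (on the count scale) and the configured dispersion, emulating
#' overdispersed RNA-seq counts.
#'
#' @param config a [sim_config()].
#' @param truth list with `q_true` (n x K matrix containing an AFR column or
#'   first column used as the African proportion), `effect_genes` (tibble
#'   gene/slope), `subtype_true` (length-n labels among BL1/BL2/LAR/M).
#' @param signatures named list of [subtype_signature()] covering the four
#'   valid subtypes.
#' @param seed integer seed (defaults to `config$seed`).
#' @return an [expression_matrix()] of counts (G x n).
#' @export
gen_expression <- function(config, truth, signatures, seed = config$seed) {
  signatures <- check_signature_list(signatures, required = VALID_SUBTYPES)
  if (!all(truth$subtype_true %in% VALID_SUBTYPES)) {
    bad <- setdiff(unique(truth$subtype_true), VALID_SUBTYPES)
    abort(paste("unknown subtype label(s):", paste(bad, collapse = ", ")))
  }
  n <- length(truth$subtype_true)
  genes <- truth$genes %||% sprintf("gene%04d", seq_len(config$G))
  G <- length(genes)
  q_afr <- if ("AFR" %in% colnames(truth$q_true)) truth$q_true[, "AFR"] else truth$q_true[, 1]

  # Baseline log2 means emulate quantified, expressed genes (the universe a
  # cohort screen actually tests after low-expression filtering); planting
  # effects in near-zero genes would make them undetectable at any slope.
  set.seed(as.integer(seed))
  baseline <- rnorm(G, mean = 7, sd = 1)
  logmu <- matrix(baseline, G, n)
  if (nrow(truth$effect_genes)) {
    idx <- match(truth$effect_genes$gene, genes)
    logmu[idx, ] <- logmu[idx, ] + outer(truth$effect_genes$slope, q_afr)
  }
  for (i in seq_len(n)) {
    sig <- signatures[[truth$subtype_true[i]]]
    up <- match(intersect(sig$up_genes, genes), genes)
    dn <- match(intersect(sig$down_genes, genes), genes)
    logmu[up, i] <- logmu[up, i] + config$signature_effect
    logmu[dn, i] <- logmu[dn, i] - config$signature_effect
  }
  mu <- 2^logmu
  counts <- if (config$noise_dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$noise_dispersion), G, n)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), G, n)
  }
  dimnames(counts) <- list(genes, rownames(truth$q_true) %||% paste0("S", seq_len(n)))
  expression_matrix(counts, layer = "counts")
}

#' Simulate a complete synthetic cohort with known ground truth
#'
#' Runs the whole generator: reference panel, Dirichlet admixture truth,
#' binomial genotypes, directional subtype signatures, planted ancestry-effect
#' genes and negative-binomial expression counts. Ancestry-effect genes are
#' drawn outside the signature gene sets so each planted structure is
#' independently recoverable. Self-reported-race labels are derived from the
#' African proportion (AA if q_AFR >= 0.5, else EA), emulating the observed
#' concordance between self-report and majority genetic ancestry.
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `genotypes`, `expression` (counts), `signatures`
#'   and a `truth` list carrying `q_true`, `effect_genes` (tibble gene, slope),
#'   `subtype_true`, plus a `metadata` tibble (sample_id, srr_group).
#' @export
simulate_cohort <- function(config = sim_config()) {
  s <- derive_seeds(config$seed, 6)
  panel <- gen_reference_panel(config$K, config$J, config$fst, seed = s[1])
  q_true <- gen_ancestry_truth(config$n, config$K, config$dirichlet_alpha, seed = s[2])
  genotypes <- gen_admixed_genotypes(panel, q_true, seed = s[3])

  genes <- sprintf("gene%04d", seq_len(config$G))
  signatures <- gen_signatures(genes, genes_per_set = 25, seed = s[4])
  sig_genes <- unique(unlist(lapply(signatures, function(x) c(x$up_genes, x$down_genes))))

  set.seed(s[5])
  pool <- setdiff(genes, sig_genes)
  effect <- tibble::tibble(
    gene = sample(pool, config$n_effect_genes),
    slope = config$beta_effect
  )
  subtype_true <- sample(VALID_SUBTYPES, config$n, replace = TRUE)

  truth <- list(
    q_true = q_true, effect_genes = effect, subtype_true = subtype_true,
    genes = genes
  )
  expression <- gen_expression(config, truth, signatures, seed = s[6])
  metadata <- tibble::tibble(
    sample_id = rownames(q_true),
    srr_group = ifelse(q_true[, "AFR"] >= 0.5, "AA", "EA"),
    subtype_true = subtype_true
  )
  list(
    config = config, panel = panel, genotypes = genotypes,
    expression = expression, signatures = signatures, truth = truth,
    metadata = metadata
  )
}

#' Generate planted correlation-score archetypes for heterogenic clustering
#'
#' Emits a correlation-score matrix whose samples follow six archetypal
#' patterns over the four valid subtypes — LAR+/BL1-, M-, M+, BL2+/BL1-,
#' BL1+/BL2- and an indistinct pattern with no signal — replicated over the
#' four scoring methods with Gaussian noise. Used to validate that Ward
#' clustering plus status labelling recovers known heterogenic category nodes.
#'
#' @param n_per samples per archetype.
#' @param effect absolute mean correlation score of a +/- subtype (default 0.8).
#' @param noise_sd Gaussian noise added per cell.
#' @param seed integer seed.
#' @return list with `cs` (a `cs_matrix`), `archetype` (character labels per
#'   sample) and `expected_labels` (canonical node label per archetype).
#' @export
gen_cs_archetypes <- function(n_per = 8, effect = 0.8, noise_sd = 0.15, seed = 1L) {
  arch <- list(
    "LAR+/BL1-" = c(BL1 = -1, BL2 = 0, LAR = 1, M = 0),
    "M-"        = c(BL1 = 0, BL2 = 0, LAR = 0, M = -1),
    "M+"        = c(BL1 = 0, BL2 = 0, LAR = 0, M = 1),
    "BL2+/BL1-" = c(BL1 = -1, BL2 = 1, LAR = 0, M = 0),
    "BL1+/BL2-" = c(BL1 = 1, BL2 = -1, LAR = 0, M = 0),
    "IND"       = c(BL1 = 0, BL2 = 0, LAR = 0, M = 0)
  )
  set.seed(as.integer(seed))
  methods <- c("corr_a", "corr_b", "tnhf_median", "tnhf_mean")
  labels <- rep(names(arch), each = n_per)
  n <- length(labels)
  cols <- as.vector(outer(VALID_SUBTYPES, methods, function(s, m) paste(m, s, sep = ".")))
  m <- matrix(0, n, length(cols), dimnames = list(sprintf("S%02d", seq_len(n)), cols))
  for (i in seq_len(n)) {
    base <- arch[[labels[i]]] * effect
    for (meth in methods) {
      m[i, paste(meth, VALID_SUBTYPES, sep = ".")] <-
        pmin(pmax(base + rnorm(4, 0, noise_sd), -1), 1)
    }
  }
  list(cs = new_cs_matrix(m), archetype = labels, expected_labels = names(arch))
}
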