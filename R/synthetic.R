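## Synthetic data with the statistical structure the imputation method
## assumes: lineage-clustered latent factors drive expression through a
## bounded nonlinearity, and each drug's response decomposes exactly
## into an expression-regulated component (a linear function of the
## true factors), an independent non-expression component, and
## measurement noise. Causal mutations are enriched in responders via a
## logistic link. Everything is seeded and byte-reproducible.

#' Configuration for the synthetic-data generator
#'
#' The variance of each drug's response is partitioned on a unit-total
#' scale: the expression-regulated component carries `erex_fraction`,
#' measurement noise carries `noise_sd^2`, and the independent
#' non-expression component carries the remainder (an error is raised
#' if the partition is infeasible).
#'
#' @param n_samples,n_genes,n_drugs Problem dimensions.
#' @param n_latent_factors True factor dimension driving expression.
#' @param n_lineages Number of lineage clusters.
#' @param lineage_shift_scale SD of lineage centroid offsets in factor
#'   space (factors have unit within-lineage SD; >= 3 gives linearly
#'   separable clusters).
#' @param erex_fraction Share of response variance carried by the
#'   expression-regulated component, in [0, 1].
#' @param noise_sd SD of response measurement noise (unit-total scale).
#' @param expr_noise_sd SD of gene-level expression noise before the
#'   squashing nonlinearity.
#' @param mutation_rate Baseline per-sample probability of a
#'   deleterious mutation in each mutated gene.
#' @param causal_mutation_effect Log-odds increase in mutation
#'   probability per SD of response for causal drug-gene pairs.
#' @param n_mut_genes,n_causal_genes Mutated-gene counts (causal genes
#'   are coupled to drug 1's response).
#' @param seed Integer seed.
#' @return A `vaen_sim_config` list.
#' @export
sim_config <- function(n_samples = 500L, n_genes = 300L, n_latent_factors = 8L,
                       n_lineages = 4L, lineage_shift_scale = 3,
                       erex_fraction = 0.5, noise_sd = 0.5,
                       expr_noise_sd = 0.3, n_drugs = 3L,
                       mutation_rate = 0.15, causal_mutation_effect = 1.5,
                       n_mut_genes = 6L, n_causal_genes = 2L, seed = 1L) {
  stopifnot(n_samples >= 1L, n_genes >= 1L, n_latent_factors >= 1L,
            n_lineages >= 1L, n_drugs >= 1L, erex_fraction >= 0,
            erex_fraction <= 1, noise_sd >= 0, mutation_rate > 0,
            mutation_rate < 1, n_causal_genes <= n_mut_genes)
  other_var <- 1 - erex_fraction - noise_sd^2
  if (other_var < -1e-12)
    stopf("infeasible variance partition: erex_fraction + noise_sd^2 = %.3f > 1",
          erex_fraction + noise_sd^2)
  structure(as.list(environment())[c(
    "n_samples", "n_genes", "n_latent_factors", "n_lineages",
    "lineage_shift_scale", "erex_fraction", "noise_sd", "expr_noise_sd",
    "n_drugs", "mutation_rate", "causal_mutation_effect", "n_mut_genes",
    "n_causal_genes", "seed")], class = "vaen_sim_config")
}

## Scaled logistic squash keeping expression in (0, scale); a bounded
## monotone nonlinearity, which is all rank normalization needs. The
## slope controls how saturating the measurement response is; cohorts
## measured on different platforms get different slope/scale, i.e. a
## strictly monotone distortion that rank normalization removes but
## raw-scale feature spaces do not.
squash <- function(a, scale = 10, slope = 2) scale / (1 + exp(-a / slope))

## Draw factors and expression for n samples given fixed truth
## (loadings, lineage centroids). Used for the primary cohort and for
## additional cohorts from the same generative model.
draw_cohort <- function(truth, n, sample_prefix, expr_noise_sd,
                        platform_shift = NULL, squash_scale = 10,
                        squash_slope = 2) {
  k <- ncol(truth$loadings)
  lineage <- sample(truth$lineages, n, replace = TRUE)
  factors <- truth$centroids[lineage, , drop = FALSE] +
    matrix(stats::rnorm(n * k), n, k)
  raw <- truth$loadings %*% t(factors) +
    matrix(stats::rnorm(nrow(truth$loadings) * n, sd = expr_noise_sd),
           nrow(truth$loadings), n)
  if (!is.null(platform_shift)) raw <- raw + platform_shift
  expr <- squash(raw, scale = squash_scale, slope = squash_slope)
  rownames(expr) <- rownames(truth$loadings)
  colnames(expr) <- sprintf("%s%04d", sample_prefix, seq_len(n))
  rownames(factors) <- colnames(expr)
  attr(expr, "normalization") <- "raw"
  list(expr = expr, factors = factors, lineage = lineage)
}

response_components <- function(truth, factors, config) {
  n <- nrow(factors)
  erex <- matrix(0, n, config$n_drugs)
  for (d in seq_len(config$n_drugs)) {
    raw <- as.numeric(factors %*% truth$drug_weights[, d])
    s <- stats::sd(raw)
    erex[, d] <- if (s == 0) raw else raw / s * sqrt(config$erex_fraction)
  }
  other_var <- max(0, 1 - config$erex_fraction - config$noise_sd^2)
  other <- matrix(stats::rnorm(n * config$n_drugs, sd = sqrt(other_var)),
                  n, config$n_drugs)
  noise <- matrix(stats::rnorm(n * config$n_drugs, sd = config$noise_sd),
                  n, config$n_drugs)
  dimnames(erex) <- dimnames(other) <- dimnames(noise) <-
    list(rownames(factors), sprintf("drug%02d", seq_len(config$n_drugs)))
  list(erex = erex, other = other, noise = noise)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Factors are per-lineage shifted Gaussians; expression is a scaled
#' logistic squash of `loadings %*% factors` plus gene-level noise;
#' each drug's observed response is exactly
#' `erex + other + noise` where `erex` (the expression-regulated
#' component) is a linear function of the true factors scaled to carry
#' `erex_fraction` of unit variance. Deleterious mutations in causal
#' genes are sampled with probability increasing in drug 1's observed
#' response (logistic link on the standardized response); the remaining
#' mutated genes are response-independent. Causal genes carry clustered
#' protein positions.
#'
#' @param config A [sim_config()].
#' @return List: `expr` (genes x samples, raw scale), `response`
#'   (samples x drugs), `meta` (sample metadata), `mutations`
#'   (mutation table), `truth` (factors, loadings, per-drug components,
#'   causal gene assignments, lineage labels).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "vaen_sim_config"))
  with_seed(config$seed, {
    k <- config$n_latent_factors
    centroids <- matrix(stats::rnorm(config$n_lineages * k,
                                     sd = config$lineage_shift_scale),
                        config$n_lineages, k,
                        dimnames = list(sprintf("lineage%02d",
                                                seq_len(config$n_lineages)), NULL))
    loadings <- matrix(stats::rnorm(config$n_genes * k, sd = 1 / sqrt(k)),
                       config$n_genes, k,
                       dimnames = list(sprintf("gene%04d", seq_len(config$n_genes)),
                                       NULL))
    drug_weights <- matrix(stats::rnorm(k * config$n_drugs), k, config$n_drugs)
    truth <- list(centroids = centroids, loadings = loadings,
                  drug_weights = drug_weights,
                  lineages = rownames(centroids))
    cohort <- draw_cohort(truth, config$n_samples, "S", config$expr_noise_sd)
    comp <- response_components(truth, cohort$factors, config)
    response <- comp$erex + comp$other + comp$noise

    ## mutations: causal genes coupled to drug 1, others at base rate
    mut_genes <- sprintf("MUT%02d", seq_len(config$n_mut_genes))
    causal <- mut_genes[seq_len(config$n_causal_genes)]
    y1 <- response[, 1L]
    y1s <- if (stats::sd(y1) > 0) (y1 - mean(y1)) / stats::sd(y1) else y1 * 0
    base_logit <- stats::qlogis(config$mutation_rate)
    recs <- list()
    for (g in mut_genes) {
      p <- if (g %in% causal)
        stats::plogis(base_logit + config$causal_mutation_effect * y1s)
      else rep(config$mutation_rate, config$n_samples)
      hit <- stats::runif(config$n_samples) < p
      if (!any(hit)) next
      ## causal genes mutate inside a tight hotspot, others scattered
      gi <- match(g, mut_genes)
      pos <- if (g %in% causal)
        sample(100:104, sum(hit), replace = TRUE)
      else sample(seq_len(400), sum(hit), replace = TRUE)
      recs[[g]] <- data.frame(
        sample_id = colnames(cohort$expr)[hit], gene = g,
        protein_position = as.integer(pos),
        consequence = "deleterious_missense",
        gene_length_bases = 20000 + gi * 10000,
        stringsAsFactors = FALSE)
    }
    mutations <- if (length(recs)) do.call(rbind, recs) else
      data.frame(sample_id = character(), gene = character(),
                 protein_position = integer(), consequence = character(),
                 gene_length_bases = numeric())
    rownames(mutations) <- NULL

    meta <- data.frame(sample_id = colnames(cohort$expr),
                       lineage = cohort$lineage,
                       cancer_type = cohort$lineage,
                       subtype = NA_character_, stringsAsFactors = FALSE)
    truth$factors <- cohort$factors
    truth$erex <- comp$erex
    truth$other <- comp$other
    truth$noise <- comp$noise
    truth$causal_genes <- causal
    truth$causal_drug <- colnames(response)[1L]
    truth$lineage <- cohort$lineage
    truth$config <- config
    list(expr = cohort$expr, response = response, meta = meta,
         mutations = mutations, truth = truth)
  })
}

#' Draw a second cohort from the same generative model
#'
#' New samples from the truth object of an existing simulation,
#' optionally with per-gene platform offsets added to the pre-squash
#' expression (emulating a cohort measured on a different platform).
#' Rank normalization is unaffected by monotone per-sample distortions
#' but per-gene shifts do perturb it mildly and perturb raw-scale
#' feature spaces strongly.
#'
#' @param truth `truth` element of [simulate_cohort()] output.
#' @param n Number of new samples.
#' @param platform_shift_sd SD of per-gene additive offsets (0 = same
#'   platform).
#' @param squash_scale,squash_slope Saturation curve of the new
#'   cohort's measurement response (defaults 10 and 2 reproduce the
#'   training platform; other values emulate a cross-platform monotone
#'   distortion).
#' @param sample_gain_sd Log-scale SD of per-sample multiplicative
#'   intensity gains (library size / scanner intensity variation).
#'   A per-sample positive gain is a strictly monotone within-sample
#'   transform, so rank normalization removes it exactly while
#'   raw-scale feature spaces do not.
#' @param expr_noise_sd Gene-level noise SD (defaults to the original).
#' @param seed Integer seed.
#' @return List: `expr`, `response`, `meta`, `truth` (with the new
#'   cohort's factors/components).
#' @export
simulate_new_cohort <- function(truth, n, platform_shift_sd = 0,
                                squash_scale = 10, squash_slope = 2,
                                sample_gain_sd = 0,
                                expr_noise_sd = NULL, seed = 1L) {
  config <- truth$config
  if (is.null(expr_noise_sd)) expr_noise_sd <- config$expr_noise_sd
  with_seed(seed, {
    shift <- if (platform_shift_sd > 0)
      matrix(stats::rnorm(nrow(truth$loadings), sd = platform_shift_sd),
             nrow(truth$loadings), n)
    else NULL
    cohort <- draw_cohort(truth, n, "T", expr_noise_sd, platform_shift = shift,
                          squash_scale = squash_scale,
                          squash_slope = squash_slope)
    if (sample_gain_sd > 0) {
      gains <- exp(stats::rnorm(ncol(cohort$expr), sd = sample_gain_sd))
      cohort$expr <- sweep(cohort$expr, 2L, gains, "*")
      attr(cohort$expr, "normalization") <- "raw"
    }
    comp <- response_components(truth, cohort$factors, config)
    response <- comp$erex + comp$other + comp$noise
    new_truth <- truth
    new_truth$factors <- cohort$factors
    new_truth$erex <- comp$erex
    new_truth$other <- comp$other
    new_truth$noise <- comp$noise
    new_truth$lineage <- cohort$lineage
    list(expr = cohort$expr, response = response,
         meta = data.frame(sample_id = colnames(cohort$expr),
                           lineage = cohort$lineage,
                           cancer_type = cohort$lineage,
                           subtype = NA_character_, stringsAsFactors = FALSE),
         truth = new_truth)
  })
}

#' Paired response panels sharing the expression-regulated component
#'
#' Two observed-response tables for the same samples and drugs: both
#' equal the shared expression-regulated component plus independent
#' measurement noise of panel-specific SD. This is the substrate for
#' cross-panel consistency tests -- predictions that recover the
#' shared component can agree across panels more strongly than the
#' noisy observations do.
#'
#' @param config A [sim_config()].
#' @param response_noise_a,response_noise_b Measurement-noise SD of
#'   each panel, in units of the component's SD.
#' @return List: `sim` (the underlying [simulate_cohort()] output),
#'   `response_a`, `response_b` (samples x drugs observed responses),
#'   `erex` (the shared component).
#' @export
make_paired_panels <- function(config = sim_config(),
                               response_noise_a = 1,
                               response_noise_b = 1) {
  sim <- simulate_cohort(config)
  erex <- sim$truth$erex
  with_seed(child_seed(config$seed, 77L), {
    es <- apply(erex, 2L, stats::sd)
    noise_a <- sweep(matrix(stats::rnorm(length(erex)), nrow(erex), ncol(erex)),
                     2L, es * response_noise_a, "*")
    noise_b <- sweep(matrix(stats::rnorm(length(erex)), nrow(erex), ncol(erex)),
                     2L, es * response_noise_b, "*")
    ra <- erex + noise_a
    rb <- erex + noise_b
    dimnames(ra) <- dimnames(rb) <- dimnames(erex)
    list(sim = sim, response_a = ra, response_b = rb, erex = erex)
  })
}

#' Write all artifacts of a simulated cohort to a directory
#'
#' Emits `expression.tsv`, `response.tsv`, `metadata.tsv`,
#' `mutations.tsv` and `truth.json` in the formats the package
#' readers consume.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  utils::write.table(data.frame(sample_id = rownames(sim$response),
                                sim$response, check.names = FALSE),
                     file.path(dir, "response.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mut <- sim$mutations
  maf <- data.frame(Hugo_Symbol = mut$gene,
                    Tumor_Sample_Barcode = mut$sample_id,
                    Protein_position = mut$protein_position,
                    SIFT = ifelse(mut$consequence == "deleterious_missense",
                                  "deleterious(0)", "tolerated(0.6)"),
                    PolyPhen = ifelse(mut$consequence == "deleterious_missense",
                                      "probably_damaging(0.99)", "benign(0.1)"),
                    Variant_Classification = ifelse(mut$consequence == "nonsense",
                                                    "Nonsense_Mutation",
                                                    "Missense_Mutation"),
                    gene_length_bases = mut$gene_length_bases)
  utils::write.table(maf, file.path(dir, "mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(config = unclass(sim$truth$config),
                            causal_genes = sim$truth$causal_genes,
                            causal_drug = sim$truth$causal_drug),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
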