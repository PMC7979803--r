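## Downstream statistics on imputed drug response: extreme-group
## enrichment, mutation and mutation-cluster tests, tumor mutational
## burden comparisons, expression trend tests combined by Stouffer's
## method, drug-class enrichment, and mutation-by-pathway interaction
## models. Tests that cannot run (too few mutants, degenerate groups)
## are skipped with a machine-readable reason code rather than
## silently dropped.

assoc_row <- function(feature_id, drug_id = NA_character_, stratum = NA_character_,
                      direction = NA_character_, statistic = NA_real_,
                      effect = NA_real_, p_raw = NA_real_,
                      p_adjusted = NA_real_, n_case = NA_integer_,
                      n_control = NA_integer_, status = "ok",
                      reason = NA_character_) {
  data.frame(feature_id = feature_id, drug_id = drug_id, stratum = stratum,
             direction = direction, statistic = statistic, effect = effect,
             p_raw = p_raw, p_adjusted = p_adjusted,
             n_case = as.integer(n_case), n_control = as.integer(n_control),
             status = status, reason = reason, stringsAsFactors = FALSE)
}

#' Read a minimal MAF-like mutation table
#'
#' Accepts a TSV with columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Protein_position`, `SIFT`, `PolyPhen` (and optionally
#' `Variant_Classification`, `gene_length_bases`). A record counts as
#' deleterious missense when SIFT annotates it deleterious and PolyPhen
#' damaging; nonsense records are taken from `Variant_Classification ==
#' "Nonsense_Mutation"`. Only deleterious missense and nonsense records
#' participate in association tests; indels and benign variants are
#' excluded upstream.
#'
#' @param path File path.
#' @return data.frame with columns `sample_id`, `gene`,
#'   `protein_position`, `consequence`, `gene_length_bases`.
#' @export
read_mutations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Protein_position")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("mutation table missing column(s): %s",
                          paste(miss, collapse = ", "))
  cons <- rep("other", nrow(df))
  if (all(c("SIFT", "PolyPhen") %in% colnames(df))) {
    cons[grepl("deleterious", df$SIFT, ignore.case = TRUE) &
         grepl("damaging", df$PolyPhen, ignore.case = TRUE)] <- "deleterious_missense"
  }
  if ("Variant_Classification" %in% colnames(df)) {
    cons[df$Variant_Classification == "Nonsense_Mutation"] <- "nonsense"
  }
  data.frame(sample_id = df$Tumor_Sample_Barcode, gene = df$Hugo_Symbol,
             protein_position = as.integer(df$Protein_position),
             consequence = cons,
             gene_length_bases = if ("gene_length_bases" %in% colnames(df))
               as.numeric(df$gene_length_bases) else NA_real_,
             stringsAsFactors = FALSE)
}

deleterious_records <- function(mut) {
  mut[mut$consequence %in% c("deleterious_missense", "nonsense"), , drop = FALSE]
}

#' Top and bottom extreme-response groups
#'
#' The sensitive group is the `ceiling(frac * n)` samples with the
#' highest imputed response, the insensitive group the same number with
#' the lowest. Ties at either boundary are broken deterministically by
#' sample id.
#'
#' @param imputed Named numeric vector of imputed response.
#' @param frac Fraction per tail, in (0, 0.5) (default 0.05).
#' @return List with character vectors `sensitive` and `insensitive`.
#' @export
define_extreme_groups <- function(imputed, frac = 0.05) {
  stopifnot(frac > 0, frac < 0.5)
  n <- length(imputed)
  m <- ceiling(frac * n)
  if (m < 1L) stopf("frac * n < 1: no samples in the extreme groups")
  ids <- names(imputed)
  sens <- ids[order(-imputed, ids)][seq_len(m)]
  insens <- ids[order(imputed, ids)][seq_len(m)]
  list(sensitive = sens, insensitive = insens)
}

#' Fisher enrichment of a sample group within a stratum
#'
#' Two-sided Fisher exact test on the 2x2 table {in stratum} x
#' {in group} over the sample universe (e.g. is a cancer type enriched
#' among the most drug-sensitive samples).
#'
#' @param group_ids Samples in the group (e.g. the sensitive tail).
#' @param stratum_ids Samples in the stratum (e.g. one cancer type).
#' @param universe_ids All samples.
#' @return One-row association data.frame (statistic = odds ratio).
#' @export
enrichment_fisher <- function(group_ids, stratum_ids, universe_ids) {
  if (!all(group_ids %in% universe_ids) || !all(stratum_ids %in% universe_ids))
    stopf("group and stratum must be subsets of the universe")
  in_g <- universe_ids %in% group_ids
  in_s <- universe_ids %in% stratum_ids
  tab <- table(factor(in_s, c(TRUE, FALSE)), factor(in_g, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(assoc_row(feature_id = "stratum", statistic = NA_real_, p_raw = 1,
                     n_case = sum(in_g), n_control = sum(!in_g),
                     status = "degenerate", reason = "empty_margin"))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  assoc_row(feature_id = "stratum", statistic = unname(ft$estimate),
            effect = unname(ft$estimate), p_raw = ft$p.value,
            n_case = sum(in_g), n_control = sum(!in_g))
}

#' Mutation vs imputed drug response (Wilcoxon rank-sum)
#'
#' Compares imputed response between samples carrying a deleterious
#' SNV (deleterious missense or nonsense) in `gene` and wild-type
#' samples, within a stratum. The mutant group must have at least
#' `min_mut` samples or the test is skipped. The reported effect is the
#' difference of mean imputed response (mutant - wild-type), and the
#' direction is `"sensitive"` when mutants respond more.
#'
#' @param imputed Named imputed-response vector.
#' @param mut Mutation table (see [read_mutations()]).
#' @param gene Gene symbol to test.
#' @param stratum_ids Samples forming the stratum; defaults to all of
#'   `names(imputed)`.
#' @param min_mut Minimum mutant-group size (default 10).
#' @return One-row association data.frame (statistic = Wilcoxon W).
#' @export
mutation_drug_test <- function(imputed, mut, gene, stratum_ids = names(imputed),
                               min_mut = 10L) {
  del <- deleterious_records(mut)
  carriers <- unique(del$sample_id[del$gene == gene])
  ids <- intersect(stratum_ids, names(imputed))
  mt <- intersect(ids, carriers)
  wt <- setdiff(ids, carriers)
  if (length(mt) < min_mut)
    return(assoc_row(gene, n_case = length(mt), n_control = length(wt),
                     status = "skipped", reason = "too_few_mutants"))
  if (length(wt) == 0L)
    return(assoc_row(gene, n_case = length(mt), n_control = 0L,
                     status = "skipped", reason = "no_wildtype"))
  wt_test <- stats::wilcox.test(imputed[mt], imputed[wt], alternative = "two.sided")
  diff <- mean(imputed[mt]) - mean(imputed[wt])
  assoc_row(gene, direction = if (diff > 0) "sensitive" else "insensitive",
            statistic = unname(wt_test$statistic), effect = diff,
            p_raw = wt_test$p.value, n_case = length(mt), n_control = length(wt))
}

#' Chain mutation positions into clusters
#'
#' Deleterious mutation positions within one gene are merged by
#' single-linkage chaining: two positions belong to the same cluster if
#' a chain of positions connects them with consecutive gaps of at most
#' `window` amino acids. Cluster ids are `gene:minpos-maxpos`.
#'
#' @param mut Mutation table.
#' @param gene Gene symbol.
#' @param window Maximum chained gap in amino acids (default 5).
#' @return List of clusters: `id`, `gene`, `positions`, `sample_ids`.
#' @export
build_mutation_clusters <- function(mut, gene, window = 5L) {
  del <- deleterious_records(mut)
  del <- del[del$gene == gene, , drop = FALSE]
  if (!nrow(del)) return(list())
  pos <- sort(unique(del$protein_position))
  breaks <- which(diff(pos) > window)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(pos))
  lapply(seq_along(starts), function(i) {
    p <- pos[starts[i]:ends[i]]
    list(id = sprintf("%s:%d-%d", gene, min(p), max(p)), gene = gene,
         positions = p,
         sample_ids = unique(del$sample_id[del$protein_position %in% p]))
  })
}

#' Mutation-cluster vs imputed drug response
#'
#' For each cluster of one or more genes, imputed response in samples
#' mutated inside the cluster is compared (two-sided Wilcoxon) against
#' samples with no deleterious mutation anywhere in the same gene;
#' samples mutated only outside the cluster are excluded from the
#' comparison. Raw P values are BH-adjusted across all clusters in the
#' family (one drug x stratum). Clusters in long genes (default
#' > 200 kb) are flagged `reported = FALSE` but retained in the output.
#'
#' @param imputed Named imputed-response vector.
#' @param clusters List of clusters from [build_mutation_clusters()]
#'   (possibly concatenated over genes).
#' @param mut Mutation table (for gene-wide carrier sets and lengths).
#' @param stratum_ids Stratum samples (default all).
#' @param min_mut Minimum cluster-mutant count (default 10).
#' @param long_gene_bases Genes longer than this are excluded from the
#'   reported set (default 2e5).
#' @param report_p_bh BH threshold for the reported set (default 0.2).
#' @return Association data.frame, one row per cluster, with columns
#'   `p_adjusted` (BH within the family) and `reported`.
#' @export
cluster_drug_test <- function(imputed, clusters, mut, stratum_ids = names(imputed),
                              min_mut = 10L, long_gene_bases = 2e5,
                              report_p_bh = 0.2) {
  del <- deleterious_records(mut)
  ids <- intersect(stratum_ids, names(imputed))
  rows <- lapply(clusters, function(cl) {
    carriers_gene <- unique(del$sample_id[del$gene == cl$gene])
    mt <- intersect(ids, cl$sample_ids)
    wt <- setdiff(ids, carriers_gene)
    if (length(mt) < min_mut)
      return(assoc_row(cl$id, n_case = length(mt), n_control = length(wt),
                       status = "skipped", reason = "too_few_mutants"))
    if (!length(wt))
      return(assoc_row(cl$id, n_case = length(mt), n_control = 0L,
                       status = "skipped", reason = "no_wildtype"))
    w <- stats::wilcox.test(imputed[mt], imputed[wt], alternative = "two.sided")
    diff <- mean(imputed[mt]) - mean(imputed[wt])
    assoc_row(cl$id, direction = if (diff > 0) "sensitive" else "insensitive",
              statistic = unname(w$statistic), effect = diff, p_raw = w$p.value,
              n_case = length(mt), n_control = length(wt))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  ok <- res$status == "ok"
  res$p_adjusted[ok] <- bh_adjust(res$p_raw[ok])
  glen <- vapply(clusters, function(cl) {
    gl <- mut$gene_length_bases[mut$gene == cl$gene]
    if (all(is.na(gl))) NA_real_ else max(gl, na.rm = TRUE)
  }, numeric(1))
  res$long_gene <- !is.na(glen) & glen > long_gene_bases
  res$reported <- ok & !res$long_gene & !is.na(res$p_adjusted) &
    res$p_adjusted < report_p_bh
  res
}

#' Tumor mutational burden in responders vs the rest
#'
#' Responders are the top `top_frac` (default 25%) of the stratum by
#' imputed response (nearest-rank cut). TMB is the log-transformed
#' per-sample mutation count with a pseudo-count of 1. Both a two-sided
#' Wilcoxon rank-sum test and a two-sided t test on log10(TMB) are
#' computed; the t test supplies the headline P and the direction. The
#' effect columns carry the difference of mean log10 TMB and the log2
#' fold change of mean (count + 1).
#'
#' @param imputed Named imputed-response vector (stratum subset taken).
#' @param tmb Named per-sample mutation counts.
#' @param stratum_ids Stratum samples (default all shared ids).
#' @param top_frac Responder fraction (default 0.25).
#' @param min_n Minimum stratum size to test (default 8).
#' @return One-row data.frame with `p_t`, `p_wilcoxon`, `diff_log10`,
#'   `log2_fc`, `direction`, plus the shared association columns
#'   (`p_raw` = `p_t`).
#' @export
tmb_responder_test <- function(imputed, tmb, stratum_ids = NULL,
                               top_frac = 0.25, min_n = 8L) {
  ids <- intersect(names(imputed), names(tmb))
  if (!is.null(stratum_ids)) ids <- intersect(ids, stratum_ids)
  if (any(tmb[ids] < 0)) stopf("negative TMB counts")
  if (length(ids) < min_n)
    return(cbind(assoc_row("TMB", status = "skipped", reason = "stratum_too_small"),
                 p_t = NA_real_, p_wilcoxon = NA_real_,
                 diff_log10 = NA_real_, log2_fc = NA_real_))
  n <- length(ids)
  k <- ceiling(top_frac * n)
  resp <- ids[order(-imputed[ids], ids)][seq_len(k)]
  rest <- setdiff(ids, resp)
  lt <- log10(tmb[ids] + 1)
  lr <- lt[resp]; lo <- lt[rest]
  diff_log10 <- mean(lr) - mean(lo)
  log2_fc <- log2(mean(tmb[resp] + 1) / mean(tmb[rest] + 1))
  if (stats::sd(c(lr, lo)) == 0) {
    p_t <- 1; p_w <- 1; stat <- 0
  } else {
    ## both groups internally constant but different: degenerate t test,
    ## treated as an exact separation
    tt <- tryCatch(stats::t.test(lr, lo), error = function(e) NULL)
    p_t <- if (is.null(tt)) as.numeric(diff_log10 == 0) else tt$p.value
    stat <- if (is.null(tt)) sign(diff_log10) * Inf else unname(tt$statistic)
    p_w <- suppressWarnings(stats::wilcox.test(tmb[resp], tmb[rest])$p.value)
  }
  cbind(assoc_row("TMB", direction = if (diff_log10 > 0) "sensitive" else "insensitive",
                  statistic = stat, effect = diff_log10, p_raw = p_t,
                  n_case = length(resp), n_control = length(rest)),
        p_t = p_t, p_wilcoxon = p_w, diff_log10 = diff_log10, log2_fc = log2_fc)
}

#' Drug-class over-representation among TMB-associated drugs
#'
#' Given per-drug TMB association results, the positive set is the
#' drugs with nominal P below `p_thresh` and effect above `diff_thresh`
#' (the negative set mirrors with effect below `-diff_thresh`); each
#' drug class is tested for over-representation in the set by a
#' two-sided Fisher exact test over all tested drugs.
#'
#' @param results data.frame with columns `drug_id`, `p_raw` and the
#'   effect column named by `effect_col` (default `"log2_fc"`).
#' @param classes Named character vector: drug id -> class (missing
#'   drugs are `"unclassified"`).
#' @param p_thresh Nominal P cutoff (default 0.01).
#' @param diff_thresh Effect cutoff (default 0.2).
#' @param effect_col Which effect column defines the sets.
#' @return Association data.frame, one row per class x direction.
#' @export
drug_class_enrichment <- function(results, classes, p_thresh = 0.01,
                                  diff_thresh = 0.2, effect_col = "log2_fc") {
  drugs <- unique(results$drug_id)
  cls <- classes[drugs]
  cls[is.na(cls)] <- "unclassified"
  names(cls) <- drugs
  eff <- results[[effect_col]]
  pos <- unique(results$drug_id[results$p_raw < p_thresh & eff > diff_thresh])
  neg <- unique(results$drug_id[results$p_raw < p_thresh & eff < -diff_thresh])
  out <- list()
  for (set_name in c("increased", "decreased")) {
    set <- if (set_name == "increased") pos else neg
    if (!length(set)) next
    for (cl in unique(cls)) {
      in_cl <- names(cls)[cls == cl]
      tab <- matrix(c(length(intersect(set, in_cl)),
                      length(setdiff(set, in_cl)),
                      length(setdiff(in_cl, set)),
                      length(setdiff(drugs, union(set, in_cl)))), 2L, 2L)
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      out[[length(out) + 1L]] <-
        assoc_row(cl, direction = set_name, statistic = unname(ft$estimate),
                  effect = unname(ft$estimate), p_raw = ft$p.value,
                  n_case = tab[1, 1], n_control = length(set) - tab[1, 1])
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Trend t-value of imputed response across expression tertiles
#'
#' Samples in a stratum are split by a gene's expression into the
#' lowest quarter (coded 0), middle half (1) and top quarter (2) using
#' nearest-rank quartiles with boundary samples assigned to the lower
#' bin; imputed response is regressed on the 0/1/2 code as a
#' quantitative variable (a trend test rather than an ANOVA) and the
#' slope's t-value is returned.
#'
#' @param imputed Named imputed-response vector.
#' @param gene_expr Named expression vector for one gene.
#' @param stratum_ids Stratum samples (default all shared).
#' @param min_n Minimum stratum size (default 12).
#' @return Slope t-value (`Inf`/`-Inf` for a perfect monotone fit; 0
#'   with attribute `degenerate = TRUE` if expression is constant).
#' @export
expression_trend_t <- function(imputed, gene_expr, stratum_ids = NULL,
                               min_n = 12L) {
  ids <- intersect(names(imputed), names(gene_expr))
  if (!is.null(stratum_ids)) ids <- intersect(ids, stratum_ids)
  if (length(ids) < min_n) stopf("stratum has %d samples (< %d)", length(ids), min_n)
  x <- gene_expr[ids]
  if (stats::sd(x) == 0) return(structure(0, degenerate = TRUE))
  xs <- sort(x)
  n <- length(x)
  q25 <- xs[ceiling(0.25 * n)]
  q75 <- xs[ceiling(0.75 * n)]
  code <- ifelse(x <= q25, 0, ifelse(x <= q75, 1, 2))
  if (length(unique(code)) < 2L) return(structure(0, degenerate = TRUE))
  y <- imputed[ids]
  fit <- stats::lm(y ~ code)
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  if (sfit$sigma < sqrt(.Machine$double.eps) * stats::sd(y))
    return(sign(sm["code", "Estimate"]) * Inf)  # perfect monotone fit
  unname(sm["code", "t value"])
}

#' Combine per-stratum t-values by Stouffer's method
#'
#' `t = sum(t_i) / sqrt(K)` over the K strata (cancer types); under the
#' null of independent standard-normal inputs the combination is again
#' standard normal.
#'
#' @param t_values Nonempty numeric vector.
#' @return Combined statistic.
#' @export
stouffer_combine <- function(t_values) {
  if (!length(t_values)) stopf("empty t-value list")
  sum(t_values) / sqrt(length(t_values))
}

#' Benjamini-Hochberg adjusted P values
#'
#' Step-up FDR adjustment, monotone and capped at 1; intended to be
#' applied within one family (all features tested for one drug in one
#' stratum).
#'
#' @param p_values Numeric vector in [0, 1].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stopf("p values outside [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Bonferroni significance threshold
#' @param alpha Family-wise error rate.
#' @param m Number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Mutation-by-covariate interaction model
#'
#' Fits `response ~ mut + covariate + mut:covariate` with the 3-level
#' covariate (e.g. expression or pathway-activity tertile, coded
#' 0/1/2) treated as categorical. Returns the OLS coefficient table,
#' a joint F-test P value for the interaction dummies, and per-level
#' stratified two-sided t tests of mutant vs wild-type.
#'
#' @param imputed Named imputed-response vector.
#' @param mut_status Named 0/1 vector (1 = mutant).
#' @param covariate_levels Named vector with up to 3 levels (0/1/2 or a
#'   factor).
#' @return List: `coefficients`, `interaction_p`, `stratified` (one
#'   t-test row per covariate level).
#' @export
interaction_model <- function(imputed, mut_status, covariate_levels) {
  ids <- Reduce(intersect, list(names(imputed), names(mut_status),
                                names(covariate_levels)))
  y <- imputed[ids]
  m <- mut_status[ids]
  cv <- factor(covariate_levels[ids])
  if (length(unique(m)) < 2L) stopf("both mutation groups must be nonempty")
  strat <- do.call(rbind, lapply(levels(cv), function(l) {
    sel <- cv == l
    if (length(unique(m[sel])) < 2L || sum(sel) < 4L)
      return(data.frame(level = l, diff = NA_real_, p = NA_real_,
                        n = sum(sel), stringsAsFactors = FALSE))
    tt <- stats::t.test(y[sel][m[sel] == 1], y[sel][m[sel] == 0])
    data.frame(level = l,
               diff = mean(y[sel][m[sel] == 1]) - mean(y[sel][m[sel] == 0]),
               p = tt$p.value, n = sum(sel), stringsAsFactors = FALSE)
  }))
  if (nlevels(cv) < 2L) {
    tt <- stats::t.test(y[m == 1], y[m == 0])
    return(list(coefficients = NULL, interaction_p = NA_real_,
                stratified = strat, two_sample_p = tt$p.value))
  }
  full <- stats::lm(y ~ m * cv)
  reduced <- stats::lm(y ~ m + cv)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stopf("rank-deficient interaction design; collinear term(s): %s",
          paste(bad, collapse = ", "))
  }
  an <- stats::anova(reduced, full)
  list(coefficients = summary(full)$coefficients,
       interaction_p = an[["Pr(>F)"]][2L],
       stratified = strat)
}

#' Write association results as tidy TSV
#' @param results Association data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
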