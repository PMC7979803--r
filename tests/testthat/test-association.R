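mut_df <- function(samples, gene = "TP53", pos = 100L,
                   consequence = "deleterious_missense", len = 50000) {
  if (!length(samples))
    return(data.frame(sample_id = character(), gene = character(),
                      protein_position = integer(), consequence = character(),
                      gene_length_bases = numeric()))
  data.frame(sample_id = samples, gene = gene,
             protein_position = as.integer(pos), consequence = consequence,
             gene_length_bases = len, stringsAsFactors = FALSE)
}

test_that("extreme groups take the expected tails with deterministic ties", {
  y <- setNames(1:100, sprintf("s%03d", 1:100))
  g <- define_extreme_groups(y, 0.05)
  expect_length(g$sensitive, 5)
  expect_setequal(g$sensitive, sprintf("s%03d", 96:100))
  expect_setequal(g$insensitive, sprintf("s%03d", 1:5))

  # boundary ties resolved by sample id, stable across repeated calls
  yt <- setNames(c(rep(1, 10), rep(0, 10)), sprintf("x%02d", 1:20))
  g1 <- define_extreme_groups(yt, 0.1)
  ids <- names(sort(yt))  # oracle: order by value then id
  expect_identical(g1$insensitive, names(yt)[order(yt, names(yt))][1:2])
  expect_identical(g1, define_extreme_groups(yt, 0.1))
  expect_error(define_extreme_groups(y, 0.6), "frac")
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # the spec's worked table
  univ <- sprintf("u%04d", 1:1000)
  stratum <- univ[1:100]
  group <- c(univ[1:10], univ[101:141])  # 10 in-stratum, 41 outside
  r <- enrichment_fisher(group, stratum, univ)
  tab <- table(factor(univ %in% stratum, c(TRUE, FALSE)),
               factor(univ %in% group, c(TRUE, FALSE)))
  expect_equal(r$p_raw, oracle_fisher_p(tab), tolerance = 1e-9)

  set.seed(13)
  for (i in 1:30) {
    n <- sample(40:200, 1)
    univ <- sprintf("v%04d", 1:n)
    stratum <- sample(univ, sample(5:(n / 2), 1))
    group <- sample(univ, sample(5:(n / 2), 1))
    r <- enrichment_fisher(group, stratum, univ)
    tab <- table(factor(univ %in% stratum, c(TRUE, FALSE)),
                 factor(univ %in% group, c(TRUE, FALSE)))
    expect_equal(r$p_raw, oracle_fisher_p(tab), tolerance = 1e-9)
  }

  # group entirely inside a small stratum: extreme enrichment
  univ <- sprintf("w%04d", 1:1000)
  r2 <- enrichment_fisher(univ[1:10], univ[1:20], univ)
  expect_lt(r2$p_raw, 1e-4)
  # empty margin degenerates to P = 1 with a flag
  r3 <- enrichment_fisher(character(0), univ[1:20], univ)
  expect_identical(r3$status, "degenerate")
  expect_equal(r3$p_raw, 1)
})

test_that("mutation test matches exact rank-sum enumeration and thresholds", {
  set.seed(17)
  ids <- sprintf("s%02d", 1:20)
  y <- setNames(rnorm(20), ids)
  mut <- mut_df(ids[1:10])
  r <- mutation_drug_test(y, mut, "TP53", min_mut = 10)
  expect_equal(r$p_raw, oracle_wilcoxon_p(y[ids[1:10]], y[ids[11:20]]),
               tolerance = 1e-12)
  expect_identical(r$direction,
                   if (mean(y[ids[1:10]]) > mean(y[ids[11:20]])) "sensitive"
                   else "insensitive")
  expect_equal(r$effect, mean(y[ids[1:10]]) - mean(y[ids[11:20]]))

  # all mutants strictly higher: smallest attainable two-sided P
  y2 <- setNames(c(11:20, 1:10) + runif(20, 0, 0.01), ids)
  r2 <- mutation_drug_test(y2, mut, "TP53", min_mut = 10)
  expect_equal(r2$p_raw, 2 / choose(20, 10), tolerance = 1e-9)

  # nine mutants with min_mut = 10 is skipped, and benign records do
  # not count as mutant
  r3 <- mutation_drug_test(y, mut_df(ids[1:9]), "TP53", min_mut = 10)
  expect_identical(r3$status, "skipped")
  r4 <- mutation_drug_test(y, mut_df(ids[1:10], consequence = "other"),
                           "TP53", min_mut = 10)
  expect_identical(r4$status, "skipped")
})

test_that("mutation and TMB tests are calibrated under the null", {
  set.seed(19)
  ids <- sprintf("s%03d", 1:60)
  p_mut <- replicate(400, {
    y <- setNames(rnorm(60), ids)
    mutation_drug_test(y, mut_df(sample(ids, 15)), "TP53", min_mut = 10)$p_raw
  })
  rate <- mean(p_mut < 0.05)
  ci <- qbinom(c(0.025, 0.975), 400, 0.05) / 400
  expect_gte(rate, ci[1] - 1e-9)
  expect_lte(rate, ci[2] + 1e-9)
  # and roughly uniform overall (rank-sum P values are discrete, so the
  # KS statistic is only approximate; ties warning is expected)
  expect_gt(suppressWarnings(ks.test(p_mut, "punif"))$p.value, 1e-3)
})

test_that("mutation clusters chain positions within the window", {
  m <- rbind(mut_df("a", pos = 12), mut_df("b", pos = 15), mut_df("c", pos = 30),
             mut_df("d", pos = 33), mut_df("e", pos = 34))
  cl <- build_mutation_clusters(m, "TP53", window = 5)
  expect_length(cl, 2)
  expect_identical(cl[[1]]$id, "TP53:12-15")
  expect_identical(cl[[2]]$id, "TP53:30-34")
  expect_setequal(cl[[2]]$sample_ids, c("c", "d", "e"))

  # transitive chaining joins 1-6-11 into one cluster
  m2 <- rbind(mut_df("a", pos = 1), mut_df("b", pos = 6), mut_df("c", pos = 11))
  cl2 <- build_mutation_clusters(m2, "TP53", window = 5)
  expect_length(cl2, 1)
  expect_identical(cl2[[1]]$id, "TP53:1-11")

  # union-find oracle over random position sets
  set.seed(23)
  for (i in 1:20) {
    pos <- sort(sample(1:80, sample(3:12, 1)))
    m3 <- do.call(rbind, lapply(seq_along(pos), function(j)
      mut_df(paste0("s", j), pos = pos[j])))
    cl3 <- build_mutation_clusters(m3, "TP53", window = 5)
    # oracle: number of chains = 1 + number of gaps > window
    expect_length(cl3, 1 + sum(diff(unique(pos)) > 5))
  }

  expect_length(build_mutation_clusters(mut_df("a", pos = 7), "TP53"), 1)
  expect_length(build_mutation_clusters(m, "NOSUCH"), 0)
})

test_that("cluster tests exclude same-gene carriers and flag long genes", {
  set.seed(29)
  ids <- sprintf("s%03d", 1:80)
  y <- setNames(rnorm(80), ids)
  # one causal cluster (samples with high response) and one neutral
  causal_samp <- names(sort(y, decreasing = TRUE))[1:12]
  neutral_samp <- setdiff(sample(ids, 30), causal_samp)[1:12]
  m <- rbind(mut_df(causal_samp, gene = "KRAS", pos = 12),
             mut_df(neutral_samp, gene = "KRAS", pos = 61),
             mut_df(causal_samp[1:10], gene = "LONGG", pos = 5, len = 2.5e5))
  cl <- c(build_mutation_clusters(m, "KRAS"), build_mutation_clusters(m, "LONGG"))
  res <- cluster_drug_test(y, cl, m, min_mut = 10)
  expect_identical(res$feature_id, c("KRAS:12-12", "KRAS:61-61", "LONGG:5-5"))
  causal_row <- res[res$feature_id == "KRAS:12-12", ]
  neutral_row <- res[res$feature_id == "KRAS:61-61", ]
  expect_lt(causal_row$p_adjusted, 0.2)
  expect_gt(neutral_row$p_raw, causal_row$p_raw)
  # long gene stays in the table but is never reported
  expect_true(res$long_gene[res$feature_id == "LONGG:5-5"])
  expect_false(res$reported[res$feature_id == "LONGG:5-5"])
  # wild-type pool excludes carriers of the other cluster:
  # n_control = 80 - carriers of any KRAS mutation
  expect_identical(causal_row$n_control,
                   length(setdiff(ids, c(causal_samp, neutral_samp))))

  # a cluster spanning all of a gene's mutations reduces to the plain test
  solo <- mut_df(causal_samp, gene = "BRAF", pos = 600)
  cl_b <- build_mutation_clusters(solo, "BRAF")
  res_b <- cluster_drug_test(y, cl_b, solo, min_mut = 10)
  plain <- mutation_drug_test(y, solo, "BRAF", min_mut = 10)
  expect_equal(res_b$p_raw, plain$p_raw)
  expect_equal(res_b$effect, plain$effect)
})

test_that("TMB responder test computes both tests and the fold change", {
  ids <- sprintf("s%03d", 1:40)
  y <- setNames(seq_along(ids), ids)
  # responders (top 10 by response) have exactly 10x the TMB of the rest
  tmb <- setNames(rep(9, 40), ids)        # counts + 1 = 10
  tmb[names(sort(y, decreasing = TRUE))[1:10]] <- 99  # counts + 1 = 100
  r <- tmb_responder_test(y, tmb, top_frac = 0.25)
  expect_equal(r$log2_fc, log2(10))
  expect_equal(r$diff_log10, 1)
  expect_identical(r$direction, "sensitive")
  expect_lt(r$p_t, 1e-10)

  # identical TMB in both groups: flat result
  r2 <- tmb_responder_test(y, setNames(rep(5, 40), ids))
  expect_equal(r2$p_t, 1)
  expect_equal(r2$diff_log10, 0)

  # null calibration of the headline t test
  set.seed(31)
  p_null <- replicate(400, {
    yy <- setNames(rnorm(40), ids)
    tt <- setNames(rpois(40, 20), ids)
    tmb_responder_test(yy, tt)$p_t
  })
  rate <- mean(p_null < 0.05)
  ci <- qbinom(c(0.025, 0.975), 400, 0.05) / 400
  expect_gte(rate, ci[1] - 1e-9)
  expect_lte(rate, ci[2] + 1e-9)
})

test_that("drug-class enrichment matches the hypergeometric oracle", {
  # 6 of 20 drugs positive, all from class A of size 6
  drugs <- sprintf("d%02d", 1:20)
  classes <- setNames(rep(c("A", "B"), c(6, 14)), drugs)
  res <- data.frame(drug_id = drugs, p_raw = c(rep(1e-4, 6), rep(0.5, 14)),
                    log2_fc = c(rep(1, 6), rep(0, 14)))
  out <- drug_class_enrichment(res, classes)
  rowA <- out[out$feature_id == "A" & out$direction == "increased", ]
  tab <- matrix(c(6, 0, 0, 14), 2, 2)
  expect_equal(rowA$p_raw, oracle_fisher_p(tab), tolerance = 1e-9)
  expect_lt(rowA$p_raw, 1e-4)

  # thresholds that exclude everything produce no tests
  res2 <- transform(res, p_raw = 0.5)
  expect_null(drug_class_enrichment(res2, classes))

  # shuffled class labels are null-calibrated
  set.seed(37)
  p_perm <- replicate(300, {
    cls <- setNames(sample(classes), drugs)
    out <- drug_class_enrichment(res, cls)
    out$p_raw[out$feature_id == "A" & out$direction == "increased"]
  })
  expect_gt(mean(p_perm > 0.05), 0.8)
})

test_that("expression trend t behaves like a trend test", {
  ids <- sprintf("s%03d", 1:40)
  ex <- setNames(seq(1, 40), ids)
  # response stepping +1 per expression tertile, no noise: perfect trend
  code <- ifelse(ex <= 10, 0, ifelse(ex <= 30, 1, 2))
  y <- setNames(code * 1.0, ids)
  expect_identical(expression_trend_t(y, ex), Inf)
  # reversing the coding flips the sign
  expect_identical(expression_trend_t(-y, ex), -Inf)

  # degenerate expression flags t = 0
  t0 <- expression_trend_t(y, setNames(rep(2, 40), ids))
  expect_equal(as.numeric(t0), 0)
  expect_true(attr(t0, "degenerate"))

  # null distribution is Student-t-like: calibrated rejections
  set.seed(41)
  tn <- replicate(500, expression_trend_t(setNames(rnorm(40), ids), ex))
  rate <- mean(abs(tn) > qt(0.975, 38))
  ci <- qbinom(c(0.025, 0.975), 500, 0.05) / 500
  expect_gte(rate, ci[1] - 1e-9)
  expect_lte(rate, ci[2] + 1e-9)
  expect_error(expression_trend_t(y[1:5], ex[1:5]), "samples")
})

test_that("Stouffer combination and its null distribution", {
  expect_equal(stouffer_combine(c(2, 2, 2, 2)), 4)
  expect_equal(stouffer_combine(3), 3)
  expect_equal(stouffer_combine(c(1, -1)), 0)
  set.seed(43)
  z <- replicate(2000, stouffer_combine(rnorm(8)))
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.1)
  expect_gt(ks.test(z, "pnorm")$p.value, 1e-3)
})

test_that("BH adjustment matches the step-up formula and is stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))

  set.seed(47)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    # order invariance; adjusted values dominate the raw ones
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
    expect_true(all(adj >= p - 1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("Bonferroni threshold reproduces the worked division", {
  expect_equal(bonferroni_threshold(0.05, 462), 0.05 / 462)
  expect_equal(signif(bonferroni_threshold(0.05, 462), 3), 1.08e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
})

test_that("interaction model recovers effects and is null-calibrated", {
  set.seed(53)
  ids <- sprintf("s%03d", 1:150)
  mut <- setNames(rbinom(150, 1, 0.4), ids)
  cov3 <- setNames(sample(0:2, 150, replace = TRUE), ids)

  # pure additive shift: mutation main effect recovered, no interaction
  y_add <- setNames(2 * mut + 0.5 * cov3 + rnorm(150, sd = 0.5), ids)
  fit <- interaction_model(y_add, mut, cov3)
  expect_equal(unname(fit$coefficients["m", "Estimate"]), 2, tolerance = 0.5)
  expect_gt(fit$interaction_p, 0.001)

  # real interaction shows up jointly and in the stratified contrasts
  y_int <- setNames(mut * (cov3 == 2) * 3 + rnorm(150, sd = 0.5), ids)
  fit2 <- interaction_model(y_int, mut, cov3)
  expect_lt(fit2$interaction_p, 1e-6)
  expect_gt(fit2$stratified$diff[fit2$stratified$level == "2"], 2)

  # null calibration of the joint interaction F test
  p_null <- replicate(400, {
    yy <- setNames(mut * 1 + cov3 * 0.5 + rnorm(150), ids)
    interaction_model(yy, mut, cov3)$interaction_p
  })
  rate <- mean(p_null < 0.05)
  ci <- qbinom(c(0.025, 0.975), 400, 0.05) / 400
  expect_gte(rate, ci[1] - 1e-9)
  expect_lte(rate, ci[2] + 1e-9)

  # single-level covariate degrades to a two-sample comparison
  fit3 <- interaction_model(y_add, mut, setNames(rep(1, 150), ids))
  expect_false(is.null(fit3$two_sample_p))
  expect_lt(fit3$two_sample_p, 1e-10)
})

test_that("MAF-like reader classifies consequences from SIFT/PolyPhen", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    c("Hugo_Symbol\tTumor_Sample_Barcode\tProtein_position\tSIFT\tPolyPhen\tVariant_Classification",
      "KRAS\ts1\t12\tdeleterious(0.01)\tprobably_damaging(0.98)\tMissense_Mutation",
      "KRAS\ts2\t13\ttolerated(0.8)\tbenign(0.1)\tMissense_Mutation",
      "TP53\ts3\t200\ttolerated(0.9)\tbenign(0)\tNonsense_Mutation"),
    collapse = "\n"), path)
  mut <- read_mutations(path)
  expect_identical(mut$consequence, c("deleterious_missense", "other", "nonsense"))
  # only deleterious missense + nonsense participate
  del <- vaen:::deleterious_records(mut)
  expect_setequal(del$sample_id, c("s1", "s3"))
})
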