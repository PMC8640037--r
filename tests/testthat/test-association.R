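test_that("Bonferroni thresholds derive from the realized test counts", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(100, alpha = 0.01), 1e-4)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("fixed-effects meta matches the hand-solved two-study case", {
  # w = (100, 25): beta = (100*0.5 + 25*0.3)/125 = 0.46; se = 1/sqrt(125)
  m <- meta_fixed(c(0.5, 0.3), c(0.1, 0.2))
  expect_equal(m$beta_meta, 0.46, tolerance = 1e-12)
  expect_equal(m$se_meta, sqrt(1 / 125), tolerance = 1e-12)
  expect_equal(m$p_meta, 2 * pnorm(-0.46 / sqrt(1 / 125)), tolerance = 1e-12)
  expect_equal(m$k_datasets, 2L)
})

test_that("meta agrees with metafor's fixed-effects fit", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    beta <- rnorm(k); se <- runif(k, 0.05, 0.5)
    m <- meta_fixed(beta, se)
    r <- metafor::rma(yi = beta, sei = se, method = "FE")
    expect_equal(m$beta_meta, as.numeric(r$beta), tolerance = 1e-10)
    expect_equal(m$se_meta, r$se, tolerance = 1e-10)
    expect_equal(m$p_meta, r$pval, tolerance = 1e-10)
  }
})

test_that("meta se never exceeds any single-study se, single studies pass through", {
  m <- meta_fixed(c(0.2, 0.1, 0.4), c(0.1, 0.3, 0.2))
  expect_lte(m$se_meta, 0.1)
  res <- meta_analyze(list(a = data.frame(site_id = c("s1", "s2"),
                                          beta = c(0.5, 0.2),
                                          se = c(0.1, 0.1)),
                           b = data.frame(site_id = "s1",
                                          beta = 0.3, se = 0.2)))
  s2 <- res[res$site_id == "s2", ]
  expect_equal(s2$flag, "single_study")
  expect_equal(s2$beta_meta, 0.2)
  expect_equal(res[res$site_id == "s1", "beta_meta"], 0.46, tolerance = 1e-12)
})

test_that("lambda is calibrated on uniform p-values", {
  set.seed(7)
  p <- runif(20000)
  expect_lt(abs(inflation_lambda(p) - 1), 0.05)
})

test_that("matrix and single-site diagnosis GLM paths agree exactly", {
  sim <- simulate_level_matrix(15, 120, ad_beta = 0.05, seed = 31)
  rm_ <- diagnosis_glm(sim$levels, sim$pheno)
  for (i in c(1, 7, 15)) {
    r1 <- diagnosis_glm(sim$levels[i, ], sim$pheno)
    expect_equal(rm_$beta[i], r1$beta, tolerance = 1e-10)
    expect_equal(rm_$se[i], r1$se, tolerance = 1e-10)
    expect_equal(rm_$p[i], r1$p, tolerance = 1e-10)
  }
  # logit link returns different units, tagged
  rl <- diagnosis_glm(sim$levels, sim$pheno, link = "logit")
  expect_false(isTRUE(all.equal(rl$beta, rm_$beta)))
})

test_that("diagnosis GLM recovers a planted effect and handles 0/2 coding", {
  sim <- simulate_level_matrix(60, 600, ad_beta = 0.05, seed = 12)
  r <- diagnosis_glm(sim$levels, sim$pheno)
  expect_lt(abs(mean(r$beta) - 0.05), 0.01)
  # MAYO-like: only codes 0 and 2
  sim2 <- simulate_level_matrix(20, 200, ad_beta = 0.05,
                                diagnosis_codes = c(0, 2), seed = 13)
  r2 <- diagnosis_glm(sim2$levels, sim2$pheno)
  expect_lt(abs(mean(r2$beta) - 0.05), 0.015)
  expect_error(diagnosis_glm(sim$levels, sim$pheno,
                             covariates = c("age", "nope")),
               "missing covariate")
})

test_that("listwise deletion reports the analyzed n", {
  sim <- simulate_level_matrix(5, 100, seed = 14)
  ph <- sim$pheno; ph$pmi[1:10] <- NA
  r <- diagnosis_glm(sim$levels, ph)
  expect_true(all(r$n == 90))
})

test_that("permuted diagnosis gives a null beta distribution", {
  sim <- simulate_level_matrix(200, 150, ad_beta = 0.05, seed = 15)
  ph <- sim$pheno
  set.seed(16); ph$diagnosis <- sample(ph$diagnosis)
  r <- diagnosis_glm(sim$levels, ph)
  expect_lt(abs(median(r$beta)), 0.01)
})

test_that("regional contrast is exactly zero for identical regions", {
  set.seed(17)
  n <- 30
  base <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     level = runif(n, 0.2, 0.6),
                     age = rnorm(n, 85), sex = rbinom(n, 1, 0.5),
                     pmi = rgamma(n, 4), rin = rnorm(n, 7))
  long <- rbind(cbind(base, region = "R1"), cbind(base, region = "R2"))
  long$site_id <- "siteX"
  r <- regional_contrast(long)
  expect_lt(abs(r$beta), 1e-8)
  # constant level is flagged and excluded from the multiplicity count
  long2 <- long; long2$level <- 0.5; long2$site_id <- "siteY"
  r2 <- regional_contrast(long2)
  expect_equal(r2$flag, "constant_level")
  expect_equal(attr(r2, "n_tested"), 0L)
})

test_that("regional contrast recovers a planted paired difference", {
  set.seed(18)
  n <- 80
  subj_eff <- rnorm(n, 0, 0.05)
  base <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     age = rnorm(n, 85), sex = rbinom(n, 1, 0.5),
                     pmi = rgamma(n, 4), rin = rnorm(n, 7))
  l1 <- 0.3 + subj_eff + rnorm(n, 0, 0.02)
  l2 <- 0.3 + 0.2 + subj_eff + rnorm(n, 0, 0.02)
  long <- rbind(cbind(base, region = "R1", level = l1),
                cbind(base, region = "R2", level = l2))
  long$site_id <- "siteX"
  r <- regional_contrast(long)
  expect_lt(abs(r$beta - 0.2), 0.01)
  expect_lt(r$p, 1e-10)
})

test_that("the two-stage workflow filters on the suggestive threshold", {
  stage1 <- data.frame(site_id = c("s1", "s2", "s3"),
                       beta = c(0.5, 0.1, 0.4), se = c(0.1, 0.1, 0.1),
                       p = c(1e-4, 0.5, 9e-4))
  ds2 <- data.frame(site_id = c("s1", "s2", "s3"),
                    beta = c(0.4, 0.2, 0.3), se = c(0.15, 0.15, 0.15))
  ts <- two_stage(stage1, list(a = stage1, b = ds2), suggestive_p = 1e-3)
  expect_equal(ts$n_selected, 2L)
  expect_setequal(ts$meta$site_id, c("s1", "s3"))
  expect_true(all(ts$meta$k_datasets == 2))
  # no suggestive site: empty result
  ts0 <- two_stage(transform(stage1, p = 0.5), list(a = stage1))
  expect_equal(ts0$n_selected, 0L)
})

test_that("trait GLM direction and degenerate inputs", {
  set.seed(19)
  n <- 300
  level <- runif(n, 0.1, 0.6)
  ph <- data.frame(age = rnorm(n, 85), sex = rbinom(n, 1, 0.5),
                   pmi = rgamma(n, 4), rin = rnorm(n, 7))
  trait <- 2.5 * level + 0.01 * ph$age + rnorm(n, 0, 0.2)
  r <- trait_glm(trait, level, ph)
  expect_lt(abs(r$beta - 2.5), 0.15)
  expect_error(trait_glm(rep(1, n), level, ph), "zero variance")
})

test_that("cis effects are classified by sign and significance tier", {
  set.seed(20)
  n <- 200
  ph <- data.frame(age = rnorm(n, 85), sex = rbinom(n, 1, 0.5),
                   pmi = rgamma(n, 4), rin = rnorm(n, 7))
  status <- rbind(siteA = rbinom(n, 1, 0.5), siteB = rbinom(n, 1, 0.5),
                  siteC = rep(1, n))  # constant: skipped
  expr <- rbind(geneA = 5 + 2.0 * status["siteA", ] + rnorm(n, 0, 0.3),
                geneB = 5 + rnorm(n, 0, 0.3),
                geneC = 5 + rnorm(n, 0, 0.3))
  colnames(status) <- colnames(expr) <- sprintf("s%03d", 1:n)
  s2g <- data.frame(site_id = c("siteA", "siteB", "siteC"),
                    gene_id = c("geneA", "geneB", "geneC"),
                    region_annotation = c("exonic", "3'UTR", "intronic"))
  res <- cis_effect(status, expr, s2g, ph, threshold = 1e-6)
  expect_equal(res$n_skipped_constant, 1L)
  ra <- res$results[res$results$site_id == "siteA", ]
  expect_equal(ra$effect_class, "positive_genome_wide")
  rb <- res$results[res$results$site_id == "siteB", ]
  expect_match(rb$effect_class, "_non$|_nominal$")
  # six-cell partition sums to the number of tested pairs
  expect_equal(sum(res$summary), nrow(res$results))
})

test_that("principal components are standardized, signed, and complete", {
  set.seed(23)
  n <- 100
  a <- rnorm(n)
  x <- cbind(e1 = a + rnorm(n, 0, 0.01), e2 = -a + rnorm(n, 0, 0.01),
             e3 = rnorm(n))
  pc <- top_event_pcs(x)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-12)
  expect_gt(pc$var_explained[1], 0.6)  # correlated pair absorbed by PC1
  # sign convention: the largest-|loading| entry of each PC is positive
  for (j in 1:3)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  expect_error(top_event_pcs(x, k = 4), "exceeds")
  x[1, 1] <- NA
  expect_error(top_event_pcs(x), "complete-case")
})
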