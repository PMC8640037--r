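# Statistical stages: Bonferroni thresholds, mixed-model regional
# contrasts, per-dataset diagnosis GLMs (fast many-site path via limma
# ordinary statistics), two-stage inverse-variance fixed-effects
# meta-analysis with inflation lambda, pathology/cognition GLMs, cis-effect
# classification, and principal components of top events.

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Family-wise error rate, default 0.05.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a single count >= 1", call. = FALSE)
  alpha / n_tests
}

#' Inverse-variance fixed-effects meta-analysis of one site
#'
#' Weights are 1/SE^2: `beta_meta = sum(w b) / sum(w)`,
#' `se_meta = sqrt(1 / sum(w))`, with a two-sided normal p-value.
#' Cochran's Q heterogeneity statistic is reported but never used for
#' filtering.
#'
#' @param beta,se Per-study effect estimates and standard errors.
#' @return One-row data frame: `beta_meta`, `se_meta`, `z`, `p_meta`,
#'   `k_datasets`, `Q`, `p_Q`.
#' @export
meta_fixed <- function(beta, se) {
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sem <- sqrt(1 / sum(w))
  z <- bm / sem
  k <- length(beta)
  Q <- sum(w * (beta - bm)^2)
  data.frame(beta_meta = bm, se_meta = sem, z = z,
             p_meta = 2 * pnorm(-abs(z)), k_datasets = k, Q = Q,
             p_Q = if (k > 1) pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_)
}

#' Genomic inflation factor lambda
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the null median (~0.4549).
#'
#' @param p Vector of p-values.
#' @return lambda.
#' @export
inflation_lambda <- function(p) {
  p <- p[!is.na(p)]
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

# ordinary (unmoderated) per-site statistics for one coefficient from a
# limma fit; used as the fast many-site path
.ordinary_stats <- function(fit, coef_name) {
  b <- fit$coefficients[, coef_name]
  se <- fit$stdev.unscaled[, coef_name] * fit$sigma
  t <- b / se
  p <- 2 * pt(-abs(t), df = fit$df.residual)
  data.frame(beta = b, se = se, p = p, n = fit$df.residual + ncol(fit$design))
}

.clamp_logit <- function(x, eps = 1e-4) qlogis(pmin(pmax(x, eps), 1 - eps))

# covariates that still vary within the analyzed (complete-case) subset;
# a factor collapsing to one level after listwise deletion is dropped
.varying_covars <- function(d, covariates) {
  covariates[vapply(covariates, function(v)
    length(unique(d[[v]][!is.na(d[[v]])])) > 1, logical(1))]
}

#' Per-dataset association of editing levels with diagnosis
#'
#' General linear model with the editing level (% alternative reads, as a
#' proportion) as the response and the diagnosis code (0 = control,
#' 1 = MCI, 2 = AD; ordinal numeric) as predictor, adjusted for the
#' dataset-specific covariates. Identity-link Gaussian by default; `link =
#' "logit"` models the logit-transformed level instead. A single site
#' (numeric vector) is fitted with [stats::glm()]; a sites x samples matrix
#' uses [limma::lmFit()] with ordinary (unmoderated) t-statistics — the
#' two paths agree exactly.
#'
#' @param levels Numeric vector (one site) or sites x samples matrix of
#'   editing levels, columns aligned with `pheno` rows.
#' @param pheno Data frame with the diagnosis column and covariates; rows
#'   with missing values are dropped listwise (count reported via the `n`
#'   column).
#' @param covariates Character vector of covariate column names.
#' @param diagnosis_col Name of the diagnosis column, default `"diagnosis"`.
#' @param link `"identity"` (default) or `"logit"`.
#' @param model_tag Label stored with the results.
#' @return Data frame with `site_id`, `beta`, `se`, `p`, `n`, `model_tag`
#'   (beta in level units per diagnosis step).
#' @export
diagnosis_glm <- function(levels, pheno, covariates = c("age", "sex", "pmi", "rin"),
                          diagnosis_col = "diagnosis",
                          link = c("identity", "logit"),
                          model_tag = "diagnosis_glm") {
  link <- match.arg(link)
  vars <- c(diagnosis_col, covariates)
  missing_cov <- setdiff(vars, names(pheno))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  cc <- complete.cases(pheno[, vars, drop = FALSE])
  ph <- pheno[cc, , drop = FALSE]
  form <- reformulate(c(diagnosis_col, covariates))
  if (is.matrix(levels)) {
    y <- levels[, cc, drop = FALSE]
    if (link == "logit") y <- .clamp_logit(y)
    design <- model.matrix(form, data = ph)
    fit <- limma::lmFit(y, design)
    out <- .ordinary_stats(fit, diagnosis_col)
    out <- data.frame(site_id = rownames(levels), out,
                      model_tag = model_tag, row.names = NULL)
  } else {
    y <- as.numeric(levels)[cc]
    if (link == "logit") y <- .clamp_logit(y)
    d <- cbind(.level = y, ph)
    fit <- glm(update(form, .level ~ .), data = d, family = gaussian())
    co <- summary(fit)$coefficients[diagnosis_col, ]
    out <- data.frame(site_id = "site1", beta = co[1], se = co[2],
                      p = co[4], n = length(fit$residuals),
                      model_tag = model_tag, row.names = NULL)
  }
  out
}

#' Trait association: pathology or cognition as outcome, editing as exposure
#'
#' General linear model with the trait (tangle density, amyloid burden,
#' neuritic plaques, or cognitive slope) as the outcome and the editing
#' level as the exposure, adjusted for covariates. Beta is in trait units
#' per unit editing level (a positive beta means higher editing accompanies
#' a higher trait value).
#'
#' @param trait Numeric outcome vector aligned with `pheno` rows.
#' @param levels Numeric vector or sites x samples matrix of editing levels.
#' @param pheno Covariate data frame.
#' @param covariates Covariate column names.
#' @param model_tag Label stored with the results.
#' @return Data frame as in [diagnosis_glm()].
#' @export
trait_glm <- function(trait, levels, pheno,
                      covariates = c("age", "sex", "pmi", "rin"),
                      model_tag = "trait_glm") {
  if (length(unique(trait[!is.na(trait)])) < 2)
    stop("trait has zero variance", call. = FALSE)
  if (!is.matrix(levels)) levels <- matrix(levels, nrow = 1,
                                           dimnames = list("site1", NULL))
  out <- lapply(rownames(levels), function(s) {
    d <- data.frame(.trait = trait, .level = levels[s, ],
                    pheno[, covariates, drop = FALSE])
    d <- d[complete.cases(d), , drop = FALSE]
    cv <- .varying_covars(d, covariates)
    if (nrow(d) < length(cv) + 3 || length(unique(d$.level)) < 2)
      return(data.frame(site_id = s, beta = NA_real_, se = NA_real_,
                        p = NA_real_, n = nrow(d), model_tag = model_tag))
    fit <- glm(reformulate(c(".level", cv), response = ".trait"),
               data = d, family = gaussian())
    co <- summary(fit)$coefficients
    if (!".level" %in% rownames(co))
      return(data.frame(site_id = s, beta = NA_real_, se = NA_real_,
                        p = NA_real_, n = nrow(d), model_tag = model_tag))
    data.frame(site_id = s, beta = co[".level", 1], se = co[".level", 2],
               p = co[".level", 4], n = nrow(d), model_tag = model_tag)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mixed-model regional contrast of editing levels
#'
#' For each site, a linear mixed model of the editing level on the region
#' (two levels) with a subject random intercept and fixed covariates;
#' two-sided p-values use Satterthwaite degrees of freedom. Sites whose
#' level is constant (singular fit) are flagged and excluded from the
#' multiplicity count.
#'
#' @param data Long data frame with `site_id`, `subject_id`, `region`,
#'   `level` and the covariate columns; exactly two regions, every subject
#'   present in both.
#' @param covariates Covariate column names, default
#'   `c("age", "sex", "pmi", "rin")`.
#' @return Data frame with `site_id`, `beta` (second region vs first),
#'   `se`, `p`, `n`, `model_tag`, `flag`; attribute `n_tested` counts
#'   cleanly fitted sites.
#' @export
regional_contrast <- function(data, covariates = c("age", "sex", "pmi", "rin")) {
  regions <- sort(unique(data$region))
  if (length(regions) != 2)
    stop("regional_contrast expects exactly 2 regions", call. = FALSE)
  data$region <- factor(data$region, levels = regions)
  form <- as.formula(paste("level ~ region +",
                           paste(covariates, collapse = " + "),
                           "+ (1 | subject_id)"))
  coef_name <- paste0("region", regions[2])
  out <- lapply(split(data, data$site_id), function(d) {
    sid <- d$site_id[1]
    if (length(unique(d$level)) == 1)
      return(data.frame(site_id = sid, beta = 0, se = NA_real_, p = NA_real_,
                        n = nrow(d), model_tag = "regional_lmm",
                        flag = "constant_level"))
    # exactly identical region profiles: the contrast is 0 with no residual
    # variance left for the mixed model — report the exact zero
    d1 <- d[d$region == regions[1], ]; d2 <- d[d$region == regions[2], ]
    if (nrow(d1) == nrow(d2) &&
        isTRUE(all.equal(d1$level[order(d1$subject_id)],
                         d2$level[order(d2$subject_id)], tolerance = 0)))
      return(data.frame(site_id = sid, beta = 0, se = NA_real_, p = NA_real_,
                        n = nrow(d), model_tag = "regional_lmm",
                        flag = "zero_region_difference"))
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(form, data = d,
                                      control = lme4::lmerControl(
                                        check.conv.singular = "ignore"))),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(site_id = sid, beta = NA_real_, se = NA_real_,
                        p = NA_real_, n = nrow(d), model_tag = "regional_lmm",
                        flag = "fit_failed"))
    co <- coef(summary(fit))
    data.frame(site_id = sid, beta = co[coef_name, "Estimate"],
               se = co[coef_name, "Std. Error"],
               p = co[coef_name, "Pr(>|t|)"], n = nrow(d),
               model_tag = "regional_lmm", flag = "ok")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "n_tested") <- sum(out$flag == "ok")
  out
}

#' Fixed-effects meta-analysis across per-dataset association results
#'
#' @param results_list Named list of per-dataset association data frames
#'   (`site_id`, `beta`, `se`, `p`).
#' @param min_datasets Sites present in fewer datasets are carried forward
#'   unmeta-analyzed and flagged (default 2).
#' @return Data frame with one row per site: meta estimates, `k_datasets`,
#'   heterogeneity `Q`/`p_Q`, `flag`.
#' @export
meta_analyze <- function(results_list, min_datasets = 2L) {
  stopifnot(length(results_list) >= 1)
  long <- do.call(rbind, lapply(names(results_list), function(nm) {
    d <- results_list[[nm]]
    data.frame(dataset = nm, site_id = d$site_id, beta = d$beta, se = d$se,
               stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$beta) & !is.na(long$se) & long$se > 0, ]
  out <- lapply(split(long, long$site_id), function(g) {
    if (nrow(g) < min_datasets) {
      data.frame(site_id = g$site_id[1], beta_meta = g$beta[1],
                 se_meta = g$se[1], z = g$beta[1] / g$se[1],
                 p_meta = 2 * pnorm(-abs(g$beta[1] / g$se[1])),
                 k_datasets = nrow(g), Q = NA_real_, p_Q = NA_real_,
                 flag = "single_study")
    } else {
      m <- meta_fixed(g$beta, g$se)
      cbind(data.frame(site_id = g$site_id[1]), m,
            data.frame(flag = "meta"))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-stage association: suggestive Stage I filter, Stage II meta-analysis
#'
#' Stage II meta-analyzes (inverse-variance fixed effects) only the sites
#' whose Stage I p-value meets the suggestive threshold, across all
#' supplied datasets (Stage I included, as in the source design). The
#' inflation factor lambda is computed from the Stage II meta p-values.
#'
#' @param stage1 Stage I association data frame (`site_id`, `beta`, `se`,
#'   `p`).
#' @param stage2_results Named list of per-dataset association data frames
#'   to meta-analyze (should include the Stage I dataset).
#' @param suggestive_p Stage I inclusion threshold, default 1e-3.
#' @return List of class `two_stage_result`: `meta` (Stage II results),
#'   `lambda`, `n_selected`, `suggestive_p`.
#' @export
two_stage <- function(stage1, stage2_results, suggestive_p = 1e-3) {
  sel <- stage1$site_id[!is.na(stage1$p) & stage1$p <= suggestive_p]
  if (!length(sel)) {
    return(structure(list(meta = data.frame(), lambda = NA_real_,
                          n_selected = 0L, suggestive_p = suggestive_p),
                     class = "two_stage_result"))
  }
  sub <- lapply(stage2_results, function(d) d[d$site_id %in% sel, , drop = FALSE])
  meta <- meta_analyze(sub)
  structure(list(meta = meta, lambda = inflation_lambda(meta$p_meta),
                 n_selected = length(sel), suggestive_p = suggestive_p),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat(sprintf("<two_stage_result> %d suggestive site(s) (p <= %g), lambda = %.3f\n",
              x$n_selected, x$suggestive_p,
              if (is.na(x$lambda)) NA else x$lambda))
  invisible(x)
}

#' Cis-effect of binary editing status on expression, with classification
#'
#' For each (site, gene) pair, a general linear model of the (log-scale)
#' expression on the binary editing status (1 = event detected in the
#' subject, 0 = not), adjusted for covariates. Effects are classified by
#' sign and significance tier: `non` (p > 0.05), `nominal`
#' (threshold < p <= 0.05), `genome_wide` (p <= threshold). A per-region
#' six-cell summary (sign x tier) is returned; the partition sums to the
#' number of tested pairs.
#'
#' @param status Sites x subjects binary (0/1) matrix.
#' @param expression Genes x subjects matrix (log scale), columns aligned.
#' @param site2gene Data frame with `site_id`, `gene_id` and optionally
#'   `region_annotation`.
#' @param pheno Covariate data frame aligned with subjects.
#' @param covariates Covariate column names.
#' @param threshold Genome-wide significance threshold (from
#'   [bonferroni_threshold()] on the realized number of tested events).
#' @return List: `results` (per pair: beta, se, p, `effect_class`),
#'   `summary` (region x class counts), `n_skipped_constant`.
#' @export
cis_effect <- function(status, expression, site2gene, pheno,
                       covariates = c("age", "sex", "pmi", "rin"),
                       threshold) {
  keep <- site2gene$site_id %in% rownames(status) &
    site2gene$gene_id %in% rownames(expression)
  site2gene <- site2gene[keep, , drop = FALSE]
  skipped <- 0L
  res <- list()
  for (j in seq_len(nrow(site2gene))) {
    s <- site2gene$site_id[j]; gene <- site2gene$gene_id[j]
    st <- status[s, ]
    if (length(unique(st[!is.na(st)])) < 2) { skipped <- skipped + 1L; next }
    d <- data.frame(.expr = expression[gene, ], .status = st,
                    pheno[, covariates, drop = FALSE])
    d <- d[complete.cases(d), , drop = FALSE]
    if (length(unique(d$.status)) < 2) { skipped <- skipped + 1L; next }
    cv <- .varying_covars(d, covariates)
    fit <- glm(reformulate(c(".status", cv), response = ".expr"),
               data = d, family = gaussian())
    co <- summary(fit)$coefficients
    if (!".status" %in% rownames(co)) { skipped <- skipped + 1L; next }
    res[[length(res) + 1L]] <- data.frame(
      site_id = s, gene_id = gene,
      region_annotation = if ("region_annotation" %in% names(site2gene))
        site2gene$region_annotation[j] else NA_character_,
      beta = co[".status", 1], se = co[".status", 2], p = co[".status", 4],
      n = nrow(d), stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(list(results = data.frame(), summary = NULL,
                n_skipped_constant = skipped))
  res <- do.call(rbind, res)
  tier <- ifelse(res$p <= threshold, "genome_wide",
                 ifelse(res$p <= 0.05, "nominal", "non"))
  sign_lbl <- ifelse(res$beta >= 0, "positive", "negative")
  res$effect_class <- paste(sign_lbl, tier, sep = "_")
  classes <- as.vector(outer(c("positive", "negative"),
                             c("non", "nominal", "genome_wide"), paste, sep = "_"))
  smry <- table(factor(res$region_annotation),
                factor(res$effect_class, levels = classes))
  list(results = res, summary = smry, n_skipped_constant = skipped)
}

#' Principal components of the top disease-associated events
#'
#' Editing levels are standardized per event (mean 0, SD 1) before the
#' decomposition; `k` components are returned with their
#' explained-variance fractions (which sum to 1 when `k` equals the number
#' of events). Component signs are fixed so that each component's
#' largest-magnitude loading is positive, making scores reproducible.
#'
#' @param levels Subjects x events matrix, complete cases only.
#' @param k Number of components, default all events.
#' @return List: `scores` (subjects x k), `loadings`, `var_explained`.
#' @export
top_event_pcs <- function(levels, k = ncol(levels)) {
  levels <- as.matrix(levels)
  if (k > ncol(levels))
    stop("k exceeds the number of events", call. = FALSE)
  if (any(is.na(levels)))
    stop("levels must be complete-case across subjects", call. = FALSE)
  z <- scale(levels)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores[, seq_len(k), drop = FALSE],
       loadings = rot[, seq_len(k), drop = FALSE],
       var_explained = ve[seq_len(k)])
}
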