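# End-to-end orchestration of the synthetic atlas analysis: one
# config-driven run writing every stage table plus a reproducibility
# manifest. The numbered scripts under analysis/ are thin drivers over
# these stages.

#' Pipeline configuration
#'
#' @param design A [simulation_design()].
#' @param qc QC thresholds (`min_total`, `min_alt`, `min_frequency`,
#'   `frequency_mode`).
#' @param digest Digestion parameters (`max_missed`, `min_length`,
#'   `max_sites`).
#' @param tampor TAMPOR settings (`tol`, `max_iter`, `gis_mode`).
#' @param covariates Named list of covariate sets per dataset; datasets not
#'   listed fall back to `default`.
#' @param suggestive_p Stage I suggestive threshold.
#' @param n_top_events Events entering the principal-component stage.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = simulation_design(),
                            qc = list(min_total = 20, min_alt = 5,
                                      min_frequency = 0.10,
                                      frequency_mode = "prevalence"),
                            digest = list(max_missed = 2L, min_length = 6L,
                                          max_sites = 16L),
                            tampor = list(tol = 1e-8, max_iter = 250L,
                                          gis_mode = TRUE),
                            covariates = list(
                              default = c("age", "sex", "pmi", "rin"),
                              ROSMAP = c("age", "sex", "pmi", "rin", "batch", "study"),
                              MSBB = c("age", "sex", "pmi", "rin", "batch", "race"),
                              MAYO = c("age", "sex", "pmi", "rin", "tissue_source")),
                            suggestive_p = 1e-3,
                            n_top_events = 7L) {
  stopifnot(inherits(design, "simulation_design"))
  for (th in c(qc$min_total, qc$min_alt, qc$min_frequency,
               digest$max_missed + 1, digest$min_length, tampor$tol,
               tampor$max_iter, suggestive_p))
    if (!is.numeric(th) || th <= 0) stop("thresholds must be positive",
                                         call. = FALSE)
  structure(list(design = design, qc = qc, digest = digest, tampor = tampor,
                 covariates = covariates, suggestive_p = suggestive_p,
                 n_top_events = as.integer(n_top_events)),
            class = "pipeline_config")
}

.covars_for <- function(config, dataset, pheno) {
  cv <- config$covariates[[dataset]]
  if (is.null(cv)) cv <- config$covariates$default
  # drop covariates that are entirely missing or constant in this dataset
  ok <- vapply(cv, function(v)
    v %in% names(pheno) && length(unique(pheno[[v]][!is.na(pheno[[v]])])) > 1,
    logical(1))
  cv[ok]
}

# sites x samples level matrix for one dataset+region from passing calls
.level_matrix <- function(qc, region = NULL) {
  calls <- qc$calls
  ok <- calls$pass & calls$site_id %in% qc$sites$site_id
  if (!is.null(region)) ok <- ok & calls$region == region
  calls <- calls[ok, , drop = FALSE]
  subjects <- sort(unique(calls$subject_id))
  sites <- qc$sites$site_id
  m <- matrix(NA_real_, length(sites), length(subjects),
              dimnames = list(sites, subjects))
  m[cbind(match(calls$site_id, sites), match(calls$subject_id, subjects))] <-
    calls$level
  m
}

#' Run the full synthetic-atlas pipeline
#'
#' Stages: simulate (reference, cohort, peptide matrix) -> QC per dataset ->
#' annotate -> recode (coding effects, proteoforms, digestion, edited
#' peptide database) -> TAMPOR (cull, normalize, connectivity outliers) ->
#' Stage I diagnosis GLM -> Stage II meta-analysis with inflation lambda ->
#' regional contrasts -> trait GLMs -> cis effects -> principal components
#' of top events. Every stage table is written to `out_dir` and a manifest
#' records the seed, package version, per-stage row counts and output
#' checksums; a rerun with the same config is byte-identical for
#' deterministic stages.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- config$design
  counts <- list()

  # -- simulate ---------------------------------------------------------
  reference <- generate_reference(design)
  cohort <- generate_calls(design, reference)
  write_reference(reference, file.path(out_dir, "reference"))
  write_tsv_commented(cohort$calls, file.path(out_dir, "calls.tsv"),
                      "per-sample editing calls")
  write_tsv_commented(cohort$phenotypes, file.path(out_dir, "phenotypes.tsv"),
                      "subject phenotypes")
  counts$calls <- nrow(cohort$calls)

  # -- qc ---------------------------------------------------------------
  qc <- qc_filter_all(cohort$calls, known_variants = reference$known_variants,
                      min_total = config$qc$min_total,
                      min_alt = config$qc$min_alt,
                      min_frequency = config$qc$min_frequency,
                      frequency_mode = config$qc$frequency_mode)
  audit <- do.call(rbind, lapply(names(qc), function(ds)
    data.frame(dataset = ds, t(qc[[ds]]$audit))))
  write_tsv_commented(audit, file.path(out_dir, "qc_audit.tsv"),
                      "QC removal counts per filter, in order")
  summaries <- do.call(rbind, lapply(names(qc), function(ds) {
    s <- suppressWarnings(subject_summaries(qc[[ds]]))
    if (nrow(s)) cbind(dataset = ds, s) else NULL
  }))
  write_tsv_commented(summaries, file.path(out_dir, "subject_summaries.tsv"),
                      "per-sample overall editing level and event count")
  counts$passing_sites <- sum(vapply(qc, function(x) nrow(x$sites), integer(1)))

  # -- annotate ---------------------------------------------------------
  ds1 <- design$datasets[1]
  annotated <- annotate_sites(qc[[ds1]]$sites, reference$models,
                              reference$reported_sites)
  write_tsv_commented(annotated, file.path(out_dir, "sites_annotated.tsv"),
                      "annotated passing sites (Stage I dataset)")
  counts$annotated_sites <- nrow(annotated)

  # -- recode -----------------------------------------------------------
  truth_sites <- reference$sites
  anno_key <- paste(annotated$chrom, annotated$pos)
  truth_pass <- truth_sites[paste(truth_sites$chrom, truth_sites$pos) %in%
                              anno_key, , drop = FALSE]
  effects <- coding_effects(truth_pass, reference$models, reference$genome)
  rec <- effects[effects$coding_effect == "recoding", , drop = FALSE]
  prot <- reference_proteome(reference$models, reference$genome)
  pf_all <- list()
  for (tx in unique(rec$transcript_id)) {
    stx <- rec[rec$transcript_id == tx, , drop = FALSE]
    if (nrow(stx) > config$digest$max_sites) next
    pf_all[[tx]] <- suppressWarnings(
      enumerate_proteoforms(reference$models[[tx]], reference$genome, stx,
                            max_sites = config$digest$max_sites))
  }
  proteoforms <- do.call(rbind, pf_all)
  db <- if (!is.null(proteoforms) && nrow(proteoforms)) {
    build_edited_peptide_db(proteoforms, prot,
                            max_missed = config$digest$max_missed,
                            min_length = config$digest$min_length)
  } else data.frame()
  if (nrow(db)) {
    write_peptide_fasta(db, file.path(out_dir, "edited_peptides.fasta"))
    write_tsv_commented(db, file.path(out_dir, "edited_peptide_db.tsv"),
                        "edited-peptide search database")
  }
  counts$recoding_sites <- nrow(rec)
  counts$proteoforms <- if (is.null(proteoforms)) 0L else nrow(proteoforms)
  counts$edited_peptides <- nrow(db)

  # -- tampor -----------------------------------------------------------
  ref_pep <- unique(unlist(lapply(prot$sequence, function(s)
    tryptic_digest(s, config$digest$max_missed,
                   config$digest$min_length)$sequence)))
  set.seed(design$seed + 3L)
  n_bg <- min(200L, length(ref_pep))
  peptides <- rbind(
    data.frame(sequence = sample(ref_pep, n_bg), is_edited = FALSE),
    if (nrow(db)) data.frame(sequence = db$sequence, is_edited = TRUE))
  pepmat <- generate_peptide_matrix(design, peptides)
  culled <- cull_missing(pepmat)
  tam <- tampor_normalize(culled, tol = config$tampor$tol,
                          max_iter = config$tampor$max_iter,
                          gis_mode = config$tampor$gis_mode)
  write_abundance_tsv(tam$corrected, file.path(out_dir, "peptides_corrected.tsv"))
  conn <- connectivity_outliers(
    tam$corrected$values[, !tam$corrected$is_gis, drop = FALSE])
  write_tsv_commented(conn, file.path(out_dir, "connectivity.tsv"),
                      "sample connectivity and outlier flags")
  counts$tampor_iterations <- tam$iterations
  counts$outlier_samples <- length(outlier_samples(conn))

  # -- association: Stage I + Stage II ----------------------------------
  ph <- cohort$phenotypes
  stage_results <- list()
  for (ds in design$datasets) {
    lv <- .level_matrix(qc[[ds]], region = "R1")
    ph_ds <- ph[match(colnames(lv), ph$subject_id), , drop = FALSE]
    stage_results[[ds]] <- diagnosis_glm(lv, ph_ds,
                                         covariates = .covars_for(config, ds, ph_ds))
  }
  stage1 <- stage_results[[ds1]]
  write_tsv_commented(stage1, file.path(out_dir, "stage1_association.tsv"),
                      "Stage I diagnosis associations")
  ts <- two_stage(stage1, stage_results, suggestive_p = config$suggestive_p)
  if (nrow(ts$meta))
    write_tsv_commented(ts$meta, file.path(out_dir, "stage2_meta.tsv"),
                        sprintf("Stage II meta-analysis; lambda = %.4f", ts$lambda))
  counts$stage1_tested <- nrow(stage1)
  counts$stage2_selected <- ts$n_selected

  # -- regional contrasts (Stage I dataset) -----------------------------
  calls1 <- qc[[ds1]]$calls
  ok <- calls1$pass & calls1$site_id %in% qc[[ds1]]$sites$site_id
  long <- calls1[ok, c("site_id", "subject_id", "region", "level")]
  long <- merge(long, ph[ph$dataset == ds1,
                         c("subject_id", "age", "sex", "pmi", "rin")],
                by = "subject_id")
  regional <- regional_contrast(long)
  write_tsv_commented(regional, file.path(out_dir, "regional_contrasts.tsv"),
                      "mixed-model regional contrasts")
  counts$regional_tested <- attr(regional, "n_tested")

  # -- traits -----------------------------------------------------------
  lv1 <- .level_matrix(qc[[ds1]], region = "R1")
  ph1 <- ph[match(colnames(lv1), ph$subject_id), , drop = FALSE]
  thr <- bonferroni_threshold(nrow(lv1))
  traits <- do.call(rbind, lapply(
    c("tangles", "amyloid", "plaques", "cog_slope"),
    function(tr) cbind(trait = tr,
                       trait_glm(ph1[[tr]], lv1, ph1,
                                 covariates = .covars_for(config, ds1, ph1),
                                 model_tag = paste0("trait_", tr)))))
  write_tsv_commented(traits, file.path(out_dir, "trait_associations.tsv"),
                      sprintf("trait GLMs; genome-wide threshold %.3g", thr))
  counts$trait_tests <- nrow(traits)

  # -- cis effects ------------------------------------------------------
  if (!is.null(cohort$expression)) {
    status <- (!is.na(lv1)) * 1
    s2g <- annotated[annotated$site_id %in% rownames(status),
                     c("site_id", "closest_gene", "region_annotation")]
    names(s2g)[2] <- "gene_id"
    expr <- cohort$expression[, colnames(status)[colnames(status) %in%
                                                   colnames(cohort$expression)],
                              drop = FALSE]
    status <- status[, colnames(expr), drop = FALSE]
    ph_e <- ph[match(colnames(expr), ph$subject_id), , drop = FALSE]
    cis <- cis_effect(status, expr, s2g, ph_e,
                      covariates = .covars_for(config, ds1, ph_e),
                      threshold = thr)
    if (nrow(cis$results))
      write_tsv_commented(cis$results, file.path(out_dir, "cis_effects.tsv"),
                          "cis-effect GLMs of binary editing status on expression")
    counts$cis_tested <- nrow(cis$results)
  }

  # -- principal components of top events -------------------------------
  rank_src <- if (nrow(ts$meta)) {
    ts$meta[order(ts$meta$p_meta), "site_id"]
  } else stage1[order(stage1$p), "site_id"]
  top <- head(rank_src, config$n_top_events)
  lv_top <- t(lv1[top, , drop = FALSE])
  lv_top <- lv_top[complete.cases(lv_top), , drop = FALSE]
  if (nrow(lv_top) > length(top) && length(top) >= 2) {
    pcs <- top_event_pcs(lv_top, k = length(top))
    write_tsv_commented(
      data.frame(subject_id = rownames(pcs$scores), pcs$scores),
      file.path(out_dir, "top_event_pcs.tsv"),
      sprintf("PC scores of top %d events; variance fractions: %s",
              length(top), paste(round(pcs$var_explained, 3), collapse = ", ")))
    counts$pc_events <- length(top)
  }

  # -- manifest ---------------------------------------------------------
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("editatlas")),
    r_version = as.character(getRversion()),
    seed = design$seed,
    stage_counts = counts,
    checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
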