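#!/usr/bin/env Rscript
# Stage 2 — quality control and annotation.
#
# Applies the four posterior filters (total reads >= 20, alternative reads
# >= 5, subject frequency >= 10%, no known-variant overlap) per dataset,
# writes the per-filter audit, per-sample overall-editing summaries, the
# cross-region overlap partition, and the annotated site table (genomic
# region by precedence, closest gene, reported status).

library(editatlas)

inp <- "results/01_inputs"
out <- "results/02_qc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

calls <- read_tsv_commented(file.path(inp, "calls.tsv"))
known_variants <- read_tsv_commented(file.path(inp, "reference",
                                               "known_variants.tsv"))
reported <- read_tsv_commented(file.path(inp, "reference",
                                         "reported_sites.tsv"))
models <- read_models_tsv(file.path(inp, "reference", "models.tsv"))

qc <- qc_filter_all(calls, known_variants = known_variants)

audit <- do.call(rbind, lapply(names(qc), function(ds)
  data.frame(dataset = ds, t(qc[[ds]]$audit))))
write_tsv_commented(audit, file.path(out, "qc_audit.tsv"),
                    "QC removals per filter, applied in order")
cat("QC audit (sites):\n"); print(audit)

for (ds in names(qc)) {
  write_tsv_commented(qc[[ds]]$sites,
                      file.path(out, sprintf("sites_%s.tsv", ds)),
                      sprintf("passing sites, dataset %s", ds))
}

summaries <- do.call(rbind, lapply(names(qc), function(ds) {
  s <- suppressWarnings(subject_summaries(qc[[ds]]))
  if (nrow(s)) cbind(dataset = ds, s) else NULL
}))
write_tsv_commented(summaries, file.path(out, "subject_summaries.tsv"),
                    "per-sample overall editing level and event count")
cat(sprintf("mean overall editing level per sample: %.3f\n",
            mean(summaries$overall_level)))

# cross-region overlap of frequent events in the Stage I dataset
ds1 <- "ROSMAP"
calls1 <- qc[[ds1]]$calls
per_region <- split(calls1$site_id[calls1$pass], calls1$region[calls1$pass])
per_region <- lapply(per_region, intersect, qc[[ds1]]$sites$site_id)
venn <- region_overlap_counts(per_region)
write_tsv_commented(venn, file.path(out, "region_overlap.tsv"),
                    sprintf("frequent-event region partition, dataset %s", ds1))
cat(sprintf("%d of %d frequent events present in both regions (%s)\n",
            venn$count[venn$n_regions == 2], sum(venn$count), ds1))

ann <- annotate_sites(qc[[ds1]]$sites, models, reported)
write_tsv_commented(ann, file.path(out, "sites_annotated.tsv"),
                    "annotated passing sites (Stage I dataset)")
cat("region annotation of passing sites:\n")
print(table(ann$region_annotation))
cat(sprintf("not reported before: %d of %d (%.0f%%)\n",
            sum(ann$reported_status == "not_reported"), nrow(ann),
            100 * mean(ann$reported_status == "not_reported")))
cat(sprintf("canonical A-to-I: %.0f%%\n", 100 * mean(ann$is_canonical_AtoI)))
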