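#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds the toy reference (genome, gene models, known-variant and
# reported-editing sets), the multi-dataset editing-call tables with
# planted regional (0.30) and diagnosis (0.05/step) effects, phenotypes
# with pathology traits, and expression for the cis analyses. Everything
# downstream reads these files; ground truth is written alongside so every
# estimator can be scored.

library(editatlas)

out <- "results/01_inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- simulation_design()
reference <- generate_reference(design)
cohort <- generate_calls(design, reference)

write_reference(reference, file.path(out, "reference"))
write_tsv_commented(cohort$calls, file.path(out, "calls.tsv"),
                    "per-sample editing calls: chrom,pos,ref,alt,depths")
write_tsv_commented(cohort$phenotypes, file.path(out, "phenotypes.tsv"),
                    "subject phenotypes, diagnosis 0=control/1=MCI/2=AD")
write_tsv_commented(
  data.frame(gene_id = rownames(cohort$expression), cohort$expression,
             check.names = FALSE),
  file.path(out, "expression.tsv"), "log2 expression, Stage I dataset")
write_tsv_commented(cohort$truth$site_params,
                    file.path(out, "site_truth.tsv"),
                    "planted per-site ground truth")

cat(sprintf("simulated %d sites, %d calls across %d datasets x %d regions\n",
            design$n_sites, nrow(cohort$calls), length(design$datasets),
            design$n_regions))
cat(sprintf("planted: %d regional-effect sites (delta %.2f), %d disease sites (beta %.2f/step)\n",
            sum(cohort$truth$site_params$is_region_site),
            design$planted_region_delta,
            sum(cohort$truth$site_params$is_ad_site),
            design$planted_ad_beta))
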