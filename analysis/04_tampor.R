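#!/usr/bin/env Rscript
# Stage 4 — peptide-level batch correction.
#
# Builds the TMT-style abundance matrix (edited peptides from stage 3 plus
# background peptides from the unedited proteome digest; multiplicative
# batch factors; 2 GIS channels per batch), culls >= 50%-missing
# non-edited rows, removes batch variance with TAMPOR, flags connectivity
# outliers, and writes edited/non-edited ratios.

library(editatlas)

inp <- "results/01_inputs"
out <- "results/04_tampor"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- simulation_design()
genome <- Biostrings::readDNAStringSet(file.path(inp, "reference",
                                                 "genome.fasta"))
models <- read_models_tsv(file.path(inp, "reference", "models.tsv"))
db <- read_tsv_commented("results/03_recoding/edited_peptide_db.tsv")
prot <- reference_proteome(models, genome)

set.seed(design$seed + 3L)
ref_pep <- unique(unlist(lapply(prot$sequence, function(s)
  tryptic_digest(s)$sequence)))
peptides <- rbind(
  data.frame(sequence = sample(ref_pep, min(200L, length(ref_pep))),
             is_edited = FALSE),
  data.frame(sequence = db$sequence, is_edited = TRUE))

raw <- generate_peptide_matrix(design, peptides)
write_abundance_tsv(raw, file.path(out, "peptides_raw.tsv"))
culled <- cull_missing(raw)
cull <- attr(culled, "cull")
cat(sprintf("cull: %d rows in, %d dropped (>= 50%% missing), %d kept (%d edited retained regardless)\n",
            cull["input"], cull["dropped"], cull["kept"],
            cull["edited_retained_over_threshold"]))

tam <- tampor_normalize(culled)
write_abundance_tsv(tam$corrected, file.path(out, "peptides_corrected.tsv"))
write_tsv_commented(tam$trace, file.path(out, "tampor_trace.tsv"),
                    "per-iteration max relative change")
est <- estimate_batch_factors(culled, tam$corrected)
cat(sprintf("TAMPOR converged in %d iterations; batch factors %s (planted %s)\n",
            tam$iterations, paste(round(est, 3), collapse = "/"),
            paste(design$batch_factors, collapse = "/")))

conn <- connectivity_outliers(
  tam$corrected$values[, !tam$corrected$is_gis, drop = FALSE])
write_tsv_commented(conn, file.path(out, "connectivity.tsv"),
                    "sample connectivity z-scores, 3-SD outlier flags")
cat(sprintf("connectivity outliers: %d of %d case samples\n",
            length(outlier_samples(conn)), sum(!tam$corrected$is_gis)))

# edited/non-edited ratios: each edited peptide against one background row
if (nrow(db)) {
  bg <- rownames(tam$corrected$values)[!tam$corrected$is_edited]
  pairs <- data.frame(
    edited = rownames(tam$corrected$values)[tam$corrected$is_edited],
    unedited = bg[seq_len(sum(tam$corrected$is_edited)) %% length(bg) + 1L])
  ratios <- edited_ratio(tam$corrected, pairs)
  write_tsv_commented(
    data.frame(pair = rownames(ratios), ratios, check.names = FALSE),
    file.path(out, "edited_ratios.tsv"),
    c("edited/non-edited relative abundance ratios",
      attr(ratios, "comparability")))
  cat(sprintf("wrote %d edited/non-edited ratio rows\n", nrow(ratios)))
}
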