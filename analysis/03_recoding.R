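#!/usr/bin/env Rscript
# Stage 3 — re-coding consequences and the edited-peptide database.
#
# Maps passing exonic sites onto transcript models, classifies amino-acid
# consequences, enumerates all within-proteoform edit combinations
# (2^k - 1 per transcript), digests proteoforms fully tryptically (Keil
# rule, <= 2 missed cleavages, length >= 6) and keeps the peptides that
# cover an edited residue and are absent from the unedited proteome's
# digest. A simulated observed-peptide list demonstrates RNA <-> peptide
# concordance.

library(editatlas)

inp <- "results/01_inputs"
out <- "results/03_recoding"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- Biostrings::readDNAStringSet(file.path(inp, "reference",
                                                 "genome.fasta"))
models <- read_models_tsv(file.path(inp, "reference", "models.tsv"))
sites <- read_tsv_commented(file.path(inp, "reference", "sites_truth.tsv"))
passing <- read_tsv_commented("results/02_qc/sites_ROSMAP.tsv")
sites <- sites[paste(sites$chrom, sites$pos) %in%
                 paste(passing$chrom, passing$pos), ]

effects <- coding_effects(sites, models, genome)
write_tsv_commented(
  effects[, c("site_id", "chrom", "pos", "ref", "alt", "transcript_id",
              "coding_effect", "aa_ref", "aa_alt", "aa_pos")],
  file.path(out, "coding_effects.tsv"), "amino-acid consequences")
cat("coding effects of passing sites:\n")
print(table(effects$coding_effect))

rec <- effects[effects$coding_effect == "recoding", ]
prot <- reference_proteome(models, genome)
proteoforms <- do.call(rbind, lapply(unique(rec$transcript_id), function(tx)
  suppressWarnings(enumerate_proteoforms(models[[tx]], genome,
                                         rec[rec$transcript_id == tx, ]))))
cat(sprintf("%d re-coding sites on %d transcripts -> %d proteoforms\n",
            nrow(rec), length(unique(rec$transcript_id)),
            nrow(proteoforms)))

db <- build_edited_peptide_db(proteoforms, prot)
write_tsv_commented(db, file.path(out, "edited_peptide_db.tsv"),
                    "edited-peptide search database")
write_peptide_fasta(db, file.path(out, "edited_peptides.fasta"))
cat(sprintf("edited-peptide database: %d unique tryptic peptides\n",
            nrow(db)))

# simulate a shotgun-proteomics observation: a subset of edited peptides
# plus unrelated decoys; concordance = sites with peptide-level support
set.seed(7)
observed <- c(sample(db$sequence, min(5L, nrow(db))),
              "ELVISLIVESK", "AAAAAAAAGGR")
conc <- match_observed_peptides(observed, db)
write_tsv_commented(conc$concordance, file.path(out, "concordance.tsv"),
                    "per-site RNA <-> peptide concordance")
cat(sprintf("observed list of %d peptides matched %d database entries; %d/%d sites with peptide support\n",
            length(observed), nrow(conc$matched),
            sum(conc$concordance$status == "RNA+peptide"),
            nrow(conc$concordance)))
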