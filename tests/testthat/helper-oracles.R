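# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately re-derive results from first
# principles (exhaustive enumeration, per-call re-checks) and never call
# the implementation paths they validate.

small_design <- function(...) {
  defaults <- list(n_subjects_per_dataset = 25L, n_sites = 60L, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_design, args)
}

# exhaustive tryptic-digest oracle: enumerate every substring and keep the
# ones whose boundaries are valid fully tryptic termini with at most
# `max_missed` internal missed cleavages
brute_digest <- function(protein, max_missed = 2L, min_length = 6L) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  is_cut <- function(i) {  # cleavage after residue i?
    i >= 1 && i < n && res[i] %in% c("K", "R") && res[i + 1] != "P"
  }
  out <- character(0)
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (b - a + 1L < min_length) next
      left_ok <- (a == 1L) || is_cut(a - 1L)
      right_ok <- (b == n) || is_cut(b)
      if (!left_ok || !right_ok) next
      internal <- if (b > a) sum(vapply(a:(b - 1L), is_cut, logical(1))) else 0L
      if (internal <= max_missed) out <- c(out, paste(res[a:b], collapse = ""))
    }
  }
  sort(unique(out))
}

# random CDS for fixture genes: ATG + sense codons + TAA
.rand_cds_test <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# per-call / per-site re-check of the QC contract, written independently of
# qc_filter's vectorised implementation
brute_qc <- function(calls, known_variants, min_total = 20, min_alt = 5,
                     min_frequency = 0.10) {
  if (!"subject_id" %in% names(calls)) calls$subject_id <- calls$sample_id
  calls$site_id <- sprintf("%s:%d:%s>%s", calls$chrom, as.integer(calls$pos),
                           calls$ref, calls$alt)
  n_subjects <- length(unique(calls$subject_id))
  kv <- paste(known_variants$chrom, known_variants$pos)
  audit <- c(removed_low_total = 0L, removed_low_alt = 0L,
             removed_low_frequency = 0L, removed_known_variant = 0L)
  passing <- character(0)
  for (s in unique(calls$site_id)) {
    g <- calls[calls$site_id == s, ]
    p1 <- g$ref_depth + g$alt_depth >= min_total
    p2 <- p1 & g$alt_depth >= min_alt
    if (!any(p1)) { audit["removed_low_total"] <- audit["removed_low_total"] + 1L; next }
    if (!any(p2)) { audit["removed_low_alt"] <- audit["removed_low_alt"] + 1L; next }
    freq <- length(unique(g$subject_id[p2])) / n_subjects
    if (freq < min_frequency) {
      audit["removed_low_frequency"] <- audit["removed_low_frequency"] + 1L; next
    }
    if (paste(g$chrom[1], g$pos[1]) %in% kv) {
      audit["removed_known_variant"] <- audit["removed_known_variant"] + 1L; next
    }
    passing <- c(passing, s)
  }
  list(passing = sort(passing), audit = audit)
}

# hand-built coding gene on a small genome, for recoding tests:
# CDS is a single exon on the given strand; utr5/utr3 flank it
toy_gene <- function(cds_seq, strand = "+", utr5 = 12L, utr3 = 12L,
                     pad = 30L, gene_id = "geneT", tx_id = "txT") {
  premrna <- paste0(paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
                          collapse = ""),
                    cds_seq,
                    paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE),
                          collapse = ""))
  gseg <- if (strand == "+") premrna else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(premrna)))
  genome_seq <- paste0(strrep("C", pad), gseg, strrep("C", pad))
  genome <- Biostrings::DNAStringSet(setNames(genome_seq, "chrT"))
  o <- pad + 1L
  L <- nchar(premrna)
  span <- c(o, o + L - 1L)
  if (strand == "+") {
    cds <- data.frame(start = o + utr5, end = o + utr5 + nchar(cds_seq) - 1L)
  } else {
    cds <- data.frame(start = o + utr3, end = o + utr3 + nchar(cds_seq) - 1L)
  }
  model <- transcript_model(gene_id, tx_id, "chrT", strand,
                            exons = data.frame(start = span[1], end = span[2]),
                            cds = cds)
  # genomic position of a 1-based CDS (coding-strand) index
  cds_pos <- function(i) if (strand == "+") cds$start + i - 1L else cds$end - i + 1L
  list(genome = genome, model = model, cds_pos = cds_pos)
}
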