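# Synthetic cohort generator: toy genome with gene models, editing-call
# tables with planted regional/diagnosis effects, phenotypes, expression,
# and a batch-structured TMT-style peptide matrix with GIS channels.

#' Simulation design for the synthetic editing cohort
#'
#' Bundles every tunable of the synthetic-data generator. The defaults are
#' the package's reference study conditions: four datasets of 150 subjects
#' each (600 in total), two brain regions per dataset, sequencing depth
#' around 500 reads per site, a planted regional editing-level difference of
#' 0.30 at a designated subset of sites, and a planted disease effect of
#' 0.05 editing-level units per diagnosis step (0 = control, 1 = MCI,
#' 2 = AD; the MAYO-like dataset codes 0/2 only).
#'
#' @param n_subjects_per_dataset Subjects per dataset.
#' @param n_regions Brain regions per dataset; every subject is sampled in
#'   all regions (paired design). The last region carries the planted
#'   regional shift.
#' @param n_sites Number of editing sites planted in the toy genome.
#' @param fraction_recoding Fraction of sites placed at CDS adenosines whose
#'   A>G edit changes the encoded amino acid.
#' @param planted_region_delta Editing-level difference (proportion units)
#'   added in the designated region at regional-effect sites.
#' @param planted_ad_beta Editing-level change per diagnosis step at
#'   disease-effect sites.
#' @param batch_factors Multiplicative batch scalars for the peptide matrix;
#'   one TMT-style batch per element.
#' @param depth_mean Mean read depth; depths are negative binomial around
#'   this value so low-depth QC failures occur naturally.
#' @param seed Integer seed; a fixed seed makes all generator outputs
#'   byte-identical across runs.
#' @param datasets Dataset names.
#' @param binary_dx_datasets Datasets whose diagnosis omits MCI (coded 0/2).
#' @param fraction_region_sites,fraction_ad_sites Fractions of sites that
#'   carry the planted regional / disease effect (disjoint subsets).
#' @param fraction_reported Fraction of sites listed in the
#'   reported-editing reference (RADAR/GTEx-style).
#' @param fraction_variant_overlap Fraction of sites whose position is also
#'   a known genomic variant (QC-filter contamination).
#' @param fraction_rare_sites Fraction of sites planted at low subject
#'   prevalence so the frequency filter removes them naturally.
#' @param level_noise_sd SD of the subject-level biological variation in
#'   true editing levels.
#' @param peptide_noise_sd Log-normal entry-wise noise SD of the peptide
#'   matrix.
#' @param peptide_loading_sd Log-normal per-case-sample loading SD of the
#'   peptide matrix (GIS channels carry no loading).
#' @param peptide_missing_fraction Fraction of case-sample entries of
#'   non-edited peptide rows set missing.
#' @param samples_per_batch Case samples per TMT batch (plus 2 GIS channels).
#' @param n_transcripts Optional override of the number of gene models;
#'   `NULL` sizes the toy genome from `n_sites`.
#' @return A validated list of class `simulation_design`.
#' @export
simulation_design <- function(n_subjects_per_dataset = 150,
                              n_regions = 2,
                              n_sites = 240,
                              fraction_recoding = 0.10,
                              planted_region_delta = 0.30,
                              planted_ad_beta = 0.05,
                              batch_factors = c(1, 1.6, 0.7, 1.2),
                              depth_mean = 500,
                              seed = 1L,
                              datasets = c("ROSMAP", "MSBB", "MAYO", "ROSMAP_MR"),
                              binary_dx_datasets = "MAYO",
                              fraction_region_sites = 0.20,
                              fraction_ad_sites = 0.10,
                              fraction_reported = 0.50,
                              fraction_variant_overlap = 0.05,
                              fraction_rare_sites = 0.05,
                              level_noise_sd = 0.05,
                              peptide_noise_sd = 0.05,
                              peptide_loading_sd = 0.10,
                              peptide_missing_fraction = 0.10,
                              samples_per_batch = 8,
                              n_transcripts = NULL) {
  design <- list(
    n_subjects_per_dataset = as.integer(n_subjects_per_dataset),
    n_regions = as.integer(n_regions),
    n_sites = as.integer(n_sites),
    fraction_recoding = fraction_recoding,
    planted_region_delta = planted_region_delta,
    planted_ad_beta = planted_ad_beta,
    batch_factors = as.numeric(batch_factors),
    depth_mean = depth_mean,
    seed = as.integer(seed),
    datasets = datasets,
    binary_dx_datasets = binary_dx_datasets,
    fraction_region_sites = fraction_region_sites,
    fraction_ad_sites = fraction_ad_sites,
    fraction_reported = fraction_reported,
    fraction_variant_overlap = fraction_variant_overlap,
    fraction_rare_sites = fraction_rare_sites,
    level_noise_sd = level_noise_sd,
    peptide_noise_sd = peptide_noise_sd,
    peptide_loading_sd = peptide_loading_sd,
    peptide_missing_fraction = peptide_missing_fraction,
    samples_per_batch = as.integer(samples_per_batch),
    n_transcripts = if (is.null(n_transcripts)) NULL else as.integer(n_transcripts)
  )
  props <- c("fraction_recoding", "fraction_region_sites", "fraction_ad_sites",
             "fraction_reported", "fraction_variant_overlap",
             "fraction_rare_sites", "peptide_missing_fraction")
  for (p in props) {
    if (design[[p]] < 0 || design[[p]] > 1)
      stop("'", p, "' must be a proportion in [0, 1]", call. = FALSE)
  }
  if (design$planted_region_delta < 0 || design$planted_region_delta > 1 ||
      design$planted_ad_beta < 0 || design$planted_ad_beta > 1)
    stop("planted effects are editing-level proportions in [0, 1]", call. = FALSE)
  if (design$depth_mean <= 0) stop("depth_mean must be > 0", call. = FALSE)
  if (design$n_subjects_per_dataset < 2 || design$n_regions < 1 ||
      design$n_sites < 1)
    stop("counts must be positive", call. = FALSE)
  if (!all(design$batch_factors > 0))
    stop("batch_factors must be positive multiplicative scalars", call. = FALSE)
  if (!all(design$binary_dx_datasets %in% design$datasets))
    stop("binary_dx_datasets must be a subset of datasets", call. = FALSE)
  class(design) <- "simulation_design"
  design
}

# geometry of a toy coding gene (pre-mRNA coordinates, 0-based)
.TX_GEOM <- list(utr5 = 60L, cds1 = 90L, intron = 120L, cds2 = 60L, utr3 = 60L)
.GAP <- 2500L  # intergenic gap between genes (> 2 x 1 kb flank)

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# random CDS: ATG + non-stop codons + TAA
.rand_cds <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Transcript model
#'
#' Strand-aware gene model: sorted, non-overlapping exon and CDS intervals
#' (1-based, fully closed) on a chromosome. Models without CDS are treated
#' as non-coding RNA genes.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with `start`, `end` (1-based closed), sorted.
#' @param cds Optional data frame with `start`, `end`; must lie within exons.
#' @return An object of class `transcript_model` with derived `tss` (the
#'   transcription start, strand-aware) and `span`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons,
                             cds = NULL) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end < exons$start)) stop("malformed exon interval")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exon intervals overlap")
  if (!is.null(cds)) {
    cds <- cds[order(cds$start), , drop = FALSE]
    if (any(cds$end < cds$start)) stop("malformed CDS interval")
  }
  span <- c(min(exons$start), max(exons$end))
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand,
                 exons = exons[, c("start", "end")],
                 cds = if (is.null(cds)) NULL else cds[, c("start", "end")],
                 tss = if (strand == "+") span[1] else span[2],
                 span = span),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s/%s %s:%d-%d (%s), %d exon(s), %s\n",
              x$gene_id, x$transcript_id, x$chrom, x$span[1], x$span[2],
              x$strand, nrow(x$exons),
              if (is.null(x$cds)) "non-coding" else "coding"))
  invisible(x)
}

# map each CDS genomic position to its coding-sequence index (1-based)
.cds_map <- function(model) {
  if (is.null(model$cds)) return(NULL)
  pos <- unlist(lapply(seq_len(nrow(model$cds)), function(i)
    seq(model$cds$start[i], model$cds$end[i])))
  if (model$strand == "-") pos <- rev(pos)
  data.frame(genome_pos = pos, cds_index = seq_along(pos))
}

#' Extract the coding sequence of a transcript model from a genome
#'
#' @param model A `transcript_model` with CDS intervals.
#' @param genome A named [Biostrings::DNAStringSet] keyed by chromosome.
#' @return The coding-strand CDS as a character string.
#' @export
coding_sequence <- function(model, genome) {
  if (is.null(model$cds)) stop("model has no CDS")
  chrom_seq <- genome[[model$chrom]]
  parts <- vapply(seq_len(nrow(model$cds)), function(i)
    as.character(Biostrings::subseq(chrom_seq, model$cds$start[i],
                                    model$cds$end[i])), character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- .revcomp(s)
  s
}

# enumerate CDS adenosines (coding strand) whose A>G edit is non-synonymous
# and not stop-gain; returns genomic positions with amino-acid consequences
.recoding_candidates <- function(model, cds_seq) {
  map <- .cds_map(model)
  bases <- strsplit(cds_seq, "")[[1]]
  a_idx <- which(bases == "A")
  a_idx <- a_idx[a_idx > 3]  # keep the initiator codon intact
  if (!length(a_idx)) return(NULL)
  gc <- Biostrings::GENETIC_CODE
  out <- lapply(a_idx, function(i) {
    ci <- (i - 1L) %/% 3L
    codon <- substr(cds_seq, ci * 3L + 1L, ci * 3L + 3L)
    alt_codon <- codon
    substr(alt_codon, (i - 1L) %% 3L + 1L, (i - 1L) %% 3L + 1L) <- "G"
    aa_ref <- gc[[codon]]; aa_alt <- gc[[alt_codon]]
    if (aa_ref == aa_alt || aa_alt == "*" || aa_ref == "*") return(NULL)
    gpos <- map$genome_pos[map$cds_index == i]
    data.frame(pos = gpos, cds_index = i, aa_pos = ci + 1L,
               aa_ref = aa_ref, aa_alt = aa_alt)
  })
  out <- do.call(rbind, out)
  out
}

#' Generate the toy reference: genome, gene models, variant and reported sets
#'
#' Builds a single-chromosome genome of coding genes (5'UTR, two CDS exons
#' separated by an intron, 3'UTR) on alternating strands, plus occasional
#' non-coding RNA genes, and plants `n_sites` A-to-I editing sites:
#' a `fraction_recoding` share at CDS adenosines whose A>G edit is
#' non-synonymous, the rest across UTRs, introns, ncRNA exons, 1 kb flanks
#' and intergenic space. A subset of site positions is marked as known
#' genomic variants (QC contamination) and, disjointly from those, a
#' `fraction_reported` share is listed in the reported-editing reference.
#'
#' @param design A [simulation_design()].
#' @return A list of class `editing_reference`: `genome` (DNAStringSet),
#'   `models` (list of [transcript_model()]), `known_variants` and
#'   `reported_sites` (data frames of 1-based positions), and `sites`
#'   (ground-truth site table with true region and coding consequence).
#' @export
generate_reference <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  g <- .TX_GEOM
  n_rec <- round(design$n_sites * design$fraction_recoding)
  n_nonc <- design$n_sites - n_rec
  n_tx <- design$n_transcripts
  if (is.null(n_tx))
    n_tx <- max(2L, ceiling(n_rec / 10), ceiling(n_nonc / 40))

  chrom <- "chr1"
  segs <- character(0)
  models <- list()
  rec_pool <- list()    # recoding candidates across transcripts
  nonc_pool <- list()   # non-CDS editable positions with truth labels
  offset <- 0L

  add_seg <- function(s) { segs[[length(segs) + 1L]] <<- s; offset <<- offset + nchar(s) }
  add_seg(.rand_dna(.GAP))

  for (i in seq_len(n_tx)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("gene%03d", i)
    tx_id <- sprintf("tx%03d", i)
    is_nc <- (i %% 8L == 0L) && n_tx > 2L
    o <- offset + 1L  # 1-based genomic start of the gene segment
    if (is_nc) {
      exon_len <- 200L
      seq_tx <- .rand_dna(exon_len)
      add_seg(if (strand == "+") seq_tx else .revcomp(seq_tx))
      model <- transcript_model(gene_id, tx_id, chrom, strand,
                                exons = data.frame(start = o, end = o + exon_len - 1L))
      # editable positions inside the ncRNA exon
      want <- if (strand == "+") "A" else "T"
      gseq <- strsplit(if (strand == "+") seq_tx else .revcomp(seq_tx), "")[[1]]
      hit <- which(gseq == want)
      if (length(hit))
        nonc_pool[[length(nonc_pool) + 1L]] <- data.frame(
          pos = o + hit - 1L, strand = strand, region = "ncRNA",
          gene_id = gene_id, transcript_id = tx_id)
    } else {
      cds_seq <- .rand_cds((g$cds1 + g$cds2) / 3L)
      utr5 <- .rand_dna(g$utr5); utr3 <- .rand_dna(g$utr3)
      intron <- .rand_dna(g$intron)
      premrna <- paste0(utr5, substr(cds_seq, 1, g$cds1), intron,
                        substr(cds_seq, g$cds1 + 1L, g$cds1 + g$cds2), utr3)
      add_seg(if (strand == "+") premrna else .revcomp(premrna))
      L <- nchar(premrna)
      # pre-mRNA (tx) intervals, 0-based: utr5 [0,59], cds1 [60,149],
      # intron [150,269], cds2 [270,329], utr3 [330,389]
      tx2g <- function(a, b) {
        if (strand == "+") c(o + a, o + b) else c(o + (L - 1L) - b, o + (L - 1L) - a)
      }
      iv <- list(utr5 = tx2g(0L, g$utr5 - 1L),
                 cds1 = tx2g(g$utr5, g$utr5 + g$cds1 - 1L),
                 intron = tx2g(g$utr5 + g$cds1, g$utr5 + g$cds1 + g$intron - 1L),
                 cds2 = tx2g(g$utr5 + g$cds1 + g$intron,
                             g$utr5 + g$cds1 + g$intron + g$cds2 - 1L),
                 utr3 = tx2g(L - g$utr3, L - 1L))
      exons <- data.frame(
        start = c(min(iv$utr5[1], iv$cds1[1]), min(iv$cds2[1], iv$utr3[1])),
        end = c(max(iv$utr5[2], iv$cds1[2]), max(iv$cds2[2], iv$utr3[2])))
      cds <- data.frame(start = c(iv$cds1[1], iv$cds2[1]),
                        end = c(iv$cds1[2], iv$cds2[2]))
      model <- transcript_model(gene_id, tx_id, chrom, strand, exons, cds)
      cand <- .recoding_candidates(model, cds_seq)
      if (!is.null(cand) && nrow(cand)) {
        cand$gene_id <- gene_id; cand$transcript_id <- tx_id
        cand$strand <- strand
        rec_pool[[length(rec_pool) + 1L]] <- cand
      }
      # non-CDS editable positions (UTRs, intron) with truth labels
      for (part in c("utr5", "intron", "utr3")) {
        a <- iv[[part]][1]; b <- iv[[part]][2]
        part_seq <- switch(part, utr5 = utr5, intron = intron, utr3 = utr3)
        # positions of coding-strand A within the part, mapped to genome
        tx_off <- switch(part, utr5 = 0L, intron = g$utr5 + g$cds1,
                         utr3 = L - g$utr3)
        a_in <- which(strsplit(part_seq, "")[[1]] == "A")
        if (!length(a_in)) next
        tpos <- tx_off + a_in - 1L
        gpos <- if (strand == "+") o + tpos else o + (L - 1L) - tpos
        lbl <- c(utr5 = "5'UTR", intron = "intronic", utr3 = "3'UTR")[[part]]
        nonc_pool[[length(nonc_pool) + 1L]] <- data.frame(
          pos = gpos, strand = strand, region = lbl,
          gene_id = gene_id, transcript_id = tx_id)
      }
    }
    models[[tx_id]] <- model
    # flank + intergenic editable positions in the trailing gap
    gap_seq <- .rand_dna(.GAP)
    gap_start <- offset + 1L
    add_seg(gap_seq)
    a_gap <- which(strsplit(gap_seq, "")[[1]] == "A")
    if (length(a_gap)) {
      gpos <- gap_start + a_gap - 1L
      dist_left <- gpos - (gap_start - 1L)          # distance past gene i end
      dist_right <- (gap_start + .GAP) - gpos       # distance to gene i+1 start
      has_next <- i < n_tx
      next_strand <- if ((i + 1L) %% 2L == 1L) "+" else "-"
      lbl <- ifelse(dist_left <= 1000L,
                    if (strand == "+") "downstream" else "upstream",
                    ifelse(has_next & dist_right <= 1000L,
                           if (next_strand == "+") "upstream" else "downstream",
                           "intergenic"))
      near_gene <- ifelse(dist_left <= 1000L | !has_next, gene_id,
                          ifelse(dist_right <= 1000L | dist_right < dist_left,
                                 sprintf("gene%03d", i + 1L), gene_id))
      nonc_pool[[length(nonc_pool) + 1L]] <- data.frame(
        pos = gpos, strand = "+", region = lbl,
        gene_id = near_gene, transcript_id = tx_id)
    }
  }

  genome <- Biostrings::DNAStringSet(setNames(paste(unlist(segs), collapse = ""),
                                              chrom))
  rec_pool <- if (length(rec_pool)) do.call(rbind, rec_pool) else NULL
  nonc_pool <- do.call(rbind, nonc_pool)
  if (is.null(rec_pool) || nrow(rec_pool) < n_rec || nrow(nonc_pool) < n_nonc)
    stop("n_sites exceeds the available editable adenosines in the toy genome",
         call. = FALSE)

  rec_sel <- rec_pool[sample.int(nrow(rec_pool), n_rec), , drop = FALSE]
  nonc_sel <- nonc_pool[sample.int(nrow(nonc_pool), n_nonc), , drop = FALSE]

  mk_site <- function(pos, strand) {
    ref <- ifelse(strand == "+", "A", "T")
    alt <- ifelse(strand == "+", "G", "C")
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, strand = strand)
  }
  s_rec <- mk_site(rec_sel$pos, rec_sel$strand)
  s_rec$gene_id <- rec_sel$gene_id; s_rec$transcript_id <- rec_sel$transcript_id
  s_rec$region_truth <- "exonic"; s_rec$coding_effect_truth <- "recoding"
  s_rec$aa_ref <- rec_sel$aa_ref; s_rec$aa_alt <- rec_sel$aa_alt
  s_rec$aa_pos <- rec_sel$aa_pos
  s_nonc <- mk_site(nonc_sel$pos, nonc_sel$strand)
  s_nonc$gene_id <- nonc_sel$gene_id; s_nonc$transcript_id <- nonc_sel$transcript_id
  s_nonc$region_truth <- nonc_sel$region
  s_nonc$coding_effect_truth <- "noncoding"
  s_nonc$aa_ref <- NA_character_; s_nonc$aa_alt <- NA_character_
  s_nonc$aa_pos <- NA_integer_
  sites <- rbind(s_rec, s_nonc)
  sites <- sites[order(sites$pos), ]
  rownames(sites) <- NULL
  sites$site_id <- sprintf("%s:%d:%s>%s", sites$chrom, sites$pos,
                           sites$ref, sites$alt)

  n_var <- round(design$n_sites * design$fraction_variant_overlap)
  var_idx <- if (n_var > 0) sample.int(nrow(sites), n_var) else integer(0)
  sites$in_known_variant <- FALSE
  sites$in_known_variant[var_idx] <- TRUE
  rep_cand <- setdiff(seq_len(nrow(sites)), var_idx)
  n_rep <- min(round(design$fraction_reported * design$n_sites), length(rep_cand))
  rep_idx <- if (n_rep > 0) sample(rep_cand, n_rep) else integer(0)
  sites$is_reported <- FALSE
  sites$is_reported[rep_idx] <- TRUE

  extra_var <- nonc_pool$pos[!(nonc_pool$pos %in% sites$pos)]
  extra_var <- sample(extra_var, min(20L, length(extra_var)))
  known_variants <- data.frame(chrom = chrom,
                               pos = sort(c(sites$pos[var_idx], extra_var)))
  reported_sites <- data.frame(chrom = chrom, pos = sort(sites$pos[rep_idx]))

  structure(list(genome = genome, models = models,
                 known_variants = known_variants,
                 reported_sites = reported_sites, sites = sites,
                 design = design),
            class = "editing_reference")
}

#' Generate per-sample editing-call tables, phenotypes and expression
#'
#' Draws, for every subject x region x site, a true editing level
#' (site base level + planted regional shift + planted diagnosis effect +
#' subject-level biological variation), then a negative-binomial read depth
#' and a binomial edited-read count. Non-carrier subjects (per-site
#' prevalence) have true level 0 and hence zero alternative reads. Pathology
#' traits and cognitive slope are generated from the latent level at a
#' designated trait site; log-scale expression of recoding-site genes
#' carries planted cis effects of the binary carrier status.
#'
#' @param design A [simulation_design()].
#' @param reference The matching [generate_reference()] output.
#' @return A list of class `editing_cohort`: `calls` (long table with
#'   chrom, pos, ref, alt, ref_depth, alt_depth, sample_id, subject_id,
#'   region, dataset), `phenotypes`, `expression` (genes x subjects, log2
#'   scale, first dataset only), and `truth` (site parameters plus planted
#'   trait and cis effects — sufficient to score every downstream
#'   estimator).
#' @export
generate_calls <- function(design, reference) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(reference, "editing_reference"))
  set.seed(design$seed + 1L)
  sites <- reference$sites
  ns <- nrow(sites)
  regions <- paste0("R", seq_len(design$n_regions))
  delta_region <- regions[length(regions)]

  base_level <- runif(ns, 0.05, 0.55)
  idx <- sample.int(ns)
  n_reg <- round(ns * design$fraction_region_sites)
  n_ad <- round(ns * design$fraction_ad_sites)
  n_rare <- round(ns * design$fraction_rare_sites)
  is_region_site <- seq_len(ns) %in% idx[seq_len(n_reg)]
  is_ad_site <- seq_len(ns) %in% idx[n_reg + seq_len(n_ad)]
  is_rare <- seq_len(ns) %in% idx[n_reg + n_ad + seq_len(n_rare)]
  prevalence <- runif(ns, 0.15, 1)
  prevalence[is_rare] <- runif(sum(is_rare), 0.01, 0.08)
  prevalence[is_region_site | is_ad_site] <- 1  # planted sites always carried

  cis_beta <- rep(0, ns)
  rec <- which(sites$coding_effect_truth == "recoding")
  cis_beta[rec] <- sample(c(-0.8, 0, 0.8), length(rec), replace = TRUE)
  trait_site <- if (any(is_ad_site)) which(is_ad_site)[1] else 1L
  trait_betas <- c(tangles = 8, amyloid = 6, plaques = 4, cog_slope = -6)

  all_calls <- vector("list", length(design$datasets))
  all_pheno <- vector("list", length(design$datasets))
  expression <- NULL

  for (d in seq_along(design$datasets)) {
    ds <- design$datasets[d]
    nsub <- design$n_subjects_per_dataset
    sid <- sprintf("%s_s%03d", ds, seq_len(nsub))
    dx_codes <- if (ds %in% design$binary_dx_datasets) c(0L, 2L) else c(0L, 1L, 2L)
    diagnosis <- sample(dx_codes, nsub, replace = TRUE)
    pheno <- data.frame(
      dataset = ds, subject_id = sid, diagnosis = diagnosis,
      age = round(pmin(pmax(rnorm(nsub, 85, 6), 66), 100), 1),
      sex = sample(c(0L, 1L), nsub, replace = TRUE),
      pmi = round(rgamma(nsub, shape = 4, scale = 1.5), 1),
      rin = round(pmin(pmax(rnorm(nsub, 7, 0.8), 4), 10), 1),
      batch = sample(sprintf("b%d", 1:3), nsub, replace = TRUE),
      study = if (ds == "ROSMAP") sample(c("ROS", "MAP"), nsub, replace = TRUE) else NA,
      race = if (ds == "MSBB") sample(c("W", "B", "H"), nsub, replace = TRUE) else NA,
      tissue_source = if (ds == "MAYO")
        sample(c("Banner", "MayoBrainBank"), nsub, replace = TRUE) else NA,
      stringsAsFactors = FALSE)

    carrier <- matrix(runif(ns * nsub) < prevalence, ns, nsub)  # site x subj
    u <- matrix(rnorm(ns * nsub, 0, design$level_noise_sd), ns, nsub)
    p_base <- base_level + outer(rep(1, ns), rep(0, nsub))
    p_subj <- p_base + u +
      outer(is_ad_site * design$planted_ad_beta, diagnosis)  # shared across regions

    ds_calls <- vector("list", design$n_regions)
    for (r in seq_len(design$n_regions)) {
      reg <- regions[r]
      e <- matrix(rnorm(ns * nsub, 0, 0.03), ns, nsub)
      p <- p_subj + e +
        (reg == delta_region) * is_region_site * design$planted_region_delta
      p <- pmin(pmax(p, 0.001), 0.999)
      p[!carrier] <- 0
      depth <- matrix(rnbinom(ns * nsub, mu = design$depth_mean, size = 4),
                      ns, nsub)
      alt <- matrix(rbinom(ns * nsub, as.vector(depth), as.vector(p)), ns, nsub)
      keep <- depth > 0  # zero-coverage positions yield no call row
      ii <- which(keep, arr.ind = TRUE)
      ds_calls[[r]] <- data.frame(
        chrom = sites$chrom[ii[, 1]], pos = sites$pos[ii[, 1]],
        ref = sites$ref[ii[, 1]], alt = sites$alt[ii[, 1]],
        ref_depth = depth[keep] - alt[keep], alt_depth = alt[keep],
        sample_id = paste0(sid[ii[, 2]], "_", reg),
        subject_id = sid[ii[, 2]], region = reg, dataset = ds,
        stringsAsFactors = FALSE)
      if (r == 1) p_r1 <- p  # latent level in the reference region
    }
    all_calls[[d]] <- do.call(rbind, ds_calls)

    latent <- p_r1[trait_site, ]
    pheno$tangles <- round(trait_betas["tangles"] * latent + rnorm(nsub, 0, 0.4), 4)
    pheno$amyloid <- round(trait_betas["amyloid"] * latent + rnorm(nsub, 0, 0.5), 4)
    pheno$plaques <- round(trait_betas["plaques"] * latent + rnorm(nsub, 0, 0.5), 4)
    pheno$cog_slope <- round(trait_betas["cog_slope"] * latent + rnorm(nsub, 0, 0.4), 4)
    all_pheno[[d]] <- pheno

    if (d == 1L) {
      genes <- unique(sites$gene_id[rec])
      if (length(genes)) {
        expression <- matrix(5 + rnorm(length(genes) * nsub, 0, 0.3),
                             length(genes), nsub,
                             dimnames = list(genes, sid))
        for (s in rec) {
          if (cis_beta[s] != 0)
            expression[sites$gene_id[s], ] <-
              expression[sites$gene_id[s], ] + cis_beta[s] * carrier[s, ]
        }
      }
      carrier_d1 <- carrier
    }
  }

  truth <- list(
    site_params = data.frame(
      site_id = sites$site_id, base_level = base_level,
      prevalence = prevalence, is_region_site = is_region_site,
      is_ad_site = is_ad_site, is_rare = is_rare,
      region_delta = is_region_site * design$planted_region_delta,
      ad_beta = is_ad_site * design$planted_ad_beta,
      cis_beta = cis_beta, gene_id = sites$gene_id,
      in_known_variant = sites$in_known_variant,
      stringsAsFactors = FALSE),
    trait_site = sites$site_id[trait_site],
    trait_betas = trait_betas,
    delta_region = delta_region,
    carrier_dataset1 = carrier_d1)

  structure(list(calls = do.call(rbind, all_calls),
                 phenotypes = do.call(rbind, all_pheno),
                 expression = expression, truth = truth,
                 regions = regions, design = design),
            class = "editing_cohort")
}

#' Simulate an editing-level matrix at calibration scale
#'
#' A genome-free counterpart of [generate_calls()] for large statistical
#' calibration studies (null type-I error, inflation lambda): sites are
#' abstract, levels are drawn through the same sampling model (uniform base
#' level, subject-level Gaussian variation, binomial read sampling at
#' negative-binomial depth), and an optional diagnosis effect can be
#' planted at all sites.
#'
#' @param n_sites,n_subjects Problem size.
#' @param depth_mean Mean sequencing depth.
#' @param ad_beta Editing-level change per diagnosis step (0 = null).
#' @param diagnosis_codes Diagnosis levels sampled uniformly.
#' @param level_noise_sd Subject-level biological SD.
#' @param seed Integer seed.
#' @return List with `levels` (site x subject matrix of observed levels),
#'   `pheno` (diagnosis + standard covariates), `true_beta`.
#' @export
simulate_level_matrix <- function(n_sites, n_subjects, depth_mean = 500,
                                  ad_beta = 0, diagnosis_codes = c(0, 1, 2),
                                  level_noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  diagnosis <- sample(diagnosis_codes, n_subjects, replace = TRUE)
  pheno <- data.frame(
    subject_id = sprintf("s%04d", seq_len(n_subjects)),
    diagnosis = diagnosis,
    age = round(pmin(pmax(rnorm(n_subjects, 85, 6), 66), 100), 1),
    sex = sample(c(0L, 1L), n_subjects, replace = TRUE),
    pmi = round(rgamma(n_subjects, shape = 4, scale = 1.5), 1),
    rin = round(pmin(pmax(rnorm(n_subjects, 7, 0.8), 4), 10), 1))
  base <- runif(n_sites, 0.05, 0.55)
  p <- base + matrix(rnorm(n_sites * n_subjects, 0, level_noise_sd),
                     n_sites, n_subjects) +
    ad_beta * outer(rep(1, n_sites), diagnosis)
  p <- pmin(pmax(p, 0.001), 0.999)
  depth <- matrix(pmax(rnbinom(n_sites * n_subjects, mu = depth_mean, size = 4), 1L),
                  n_sites, n_subjects)
  alt <- matrix(rbinom(n_sites * n_subjects, as.vector(depth), as.vector(p)),
                n_sites, n_subjects)
  levels <- alt / depth
  dimnames(levels) <- list(sprintf("site%05d", seq_len(n_sites)),
                           pheno$subject_id)
  list(levels = levels, pheno = pheno, true_beta = ad_beta)
}

#' Generate a batch-structured peptide abundance matrix with GIS channels
#'
#' Emulates a TMT experiment: each batch contributes `samples_per_batch`
#' case channels plus exactly 2 pooled global internal standard (GIS)
#' channels. Abundance = row baseline x batch factor x case-sample loading x
#' log-normal noise; a fraction of case entries of non-edited rows is set
#' missing. GIS channels, being pooled standards, stay complete and carry no
#' sample loading.
#'
#' @param design A [simulation_design()]; `batch_factors` (>= 2 of them),
#'   `peptide_noise_sd` and `peptide_missing_fraction` are used.
#' @param peptides Data frame with columns `sequence` and `is_edited`.
#' @return An [abundance_matrix()] with attribute `true_batch_factors`.
#' @export
generate_peptide_matrix <- function(design, peptides) {
  stopifnot(inherits(design, "simulation_design"),
            is.data.frame(peptides), all(c("sequence", "is_edited") %in% names(peptides)))
  if (length(design$batch_factors) < 2)
    stop("at least 2 batches are required", call. = FALSE)
  set.seed(design$seed + 2L)
  nb <- length(design$batch_factors)
  npep <- nrow(peptides)
  per <- design$samples_per_batch + 2L
  batch <- rep(sprintf("batch%d", seq_len(nb)), each = per)
  is_gis <- rep(c(rep(FALSE, design$samples_per_batch), TRUE, TRUE), nb)
  sample_id <- ifelse(is_gis,
                      paste0(batch, "_GIS", ave(seq_along(batch), batch, is_gis,
                                                FUN = seq_along)),
                      paste0(batch, "_case", ave(seq_along(batch), batch, is_gis,
                                                 FUN = seq_along)))
  baseline <- 2^runif(npep, 10, 20)
  loading <- ifelse(is_gis, 1, exp(rnorm(length(batch), 0,
                                         design$peptide_loading_sd)))
  bf <- design$batch_factors[as.integer(factor(batch, levels = unique(batch)))]
  noise <- matrix(exp(rnorm(npep * length(batch), 0, design$peptide_noise_sd)),
                  npep, length(batch))
  values <- outer(baseline, bf * loading) * noise
  if (design$peptide_missing_fraction > 0) {
    miss <- matrix(runif(npep * length(batch)) < design$peptide_missing_fraction,
                   npep, length(batch))
    miss[peptides$is_edited, ] <- FALSE
    miss[, is_gis] <- FALSE
    values[miss] <- NA_real_
  }
  dimnames(values) <- list(peptides$sequence, sample_id)
  am <- abundance_matrix(values, batch = batch, is_gis = is_gis,
                         is_edited = peptides$is_edited)
  attr(am, "true_batch_factors") <- design$batch_factors
  am
}
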