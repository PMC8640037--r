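# Re-coding consequences of exonic edits, proteoform enumeration,
# in-silico tryptic digestion, and the edited-peptide search database.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Amino-acid consequence of an editing site on a transcript
#'
#' Maps the genomic position into the coding sequence (strand-aware: a
#' genome-reported T>C on a minus-strand transcript is A>G on the coding
#' strand), substitutes the edited base, translates the affected codon and
#' compares amino acids. Positions outside the CDS are non-coding. An edit
#' creating a stop codon is classified as re-coding with `aa_alt = "*"`.
#'
#' @param pos Genomic position (1-based).
#' @param ref,alt Genome-reported bases.
#' @param model A [transcript_model()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @return List with `effect` (`"recoding"`, `"synonymous"` or
#'   `"noncoding"`), `aa_ref`, `aa_alt`, `aa_pos`, `cds_index`.
#' @export
coding_effect <- function(pos, ref, alt, model, genome) {
  stopifnot(inherits(model, "transcript_model"))
  if (is.null(model$cds))
    return(list(effect = "noncoding", aa_ref = NA_character_,
                aa_alt = NA_character_, aa_pos = NA_integer_,
                cds_index = NA_integer_))
  map <- .cds_map(model)
  i <- map$cds_index[match(pos, map$genome_pos)]
  if (is.na(i))
    return(list(effect = "noncoding", aa_ref = NA_character_,
                aa_alt = NA_character_, aa_pos = NA_integer_,
                cds_index = NA_integer_))
  cds <- coding_sequence(model, genome)
  if (nchar(cds) %% 3 != 0)
    stop("model integrity error: CDS length not divisible by 3", call. = FALSE)
  ci <- (i - 1L) %/% 3L
  if (ci * 3L + 3L > nchar(cds))
    stop("model integrity error: incomplete codon at CDS position ", i,
         call. = FALSE)
  genome_base <- as.character(Biostrings::subseq(genome[[model$chrom]], pos, pos))
  if (genome_base != ref)
    warning("genome base ", genome_base, " at ", pos,
            " differs from reported ref ", ref)
  coding_alt <- if (model$strand == "+") alt else .comp_base[[alt]]
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  alt_codon <- codon
  substr(alt_codon, (i - 1L) %% 3L + 1L, (i - 1L) %% 3L + 1L) <- coding_alt
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- gc[[codon]]; aa_alt <- gc[[alt_codon]]
  if (aa_alt == "*" && aa_ref != "*")
    warning("edit at ", pos, " creates a premature stop codon")
  effect <- if (aa_ref == aa_alt) "synonymous" else "recoding"
  list(effect = effect, aa_ref = aa_ref, aa_alt = aa_alt,
       aa_pos = ci + 1L, cds_index = i)
}

#' Coding effects for a site table across transcript models
#'
#' @param sites Data frame with `pos`, `ref`, `alt` and `transcript_id`.
#' @param models Named list of [transcript_model()] (names = transcript id).
#' @param genome Named [Biostrings::DNAStringSet].
#' @return `sites` with `coding_effect`, `aa_ref`, `aa_alt`, `aa_pos` added.
#' @export
coding_effects <- function(sites, models, genome) {
  res <- lapply(seq_len(nrow(sites)), function(j) {
    m <- models[[sites$transcript_id[j]]]
    if (is.null(m))
      return(list(effect = "noncoding", aa_ref = NA, aa_alt = NA,
                  aa_pos = NA, cds_index = NA))
    coding_effect(sites$pos[j], sites$ref[j], sites$alt[j], m, genome)
  })
  sites$coding_effect <- vapply(res, `[[`, character(1), "effect")
  sites$aa_ref <- vapply(res, function(x) as.character(x$aa_ref), character(1))
  sites$aa_alt <- vapply(res, function(x) as.character(x$aa_alt), character(1))
  sites$aa_pos <- vapply(res, function(x) as.integer(x$aa_pos), integer(1))
  sites
}

# translate a coding-strand CDS string, truncating at the first stop
.translate_cds <- function(cds, warn_premature = TRUE) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    if (warn_premature && stop_at < nchar(aa))
      warning("premature stop codon truncates the proteoform")
    aa <- substr(aa, 1L, stop_at - 1L)
  }
  aa
}

#' Enumerate edited proteoforms of a transcript
#'
#' All 2^k - 1 non-empty combinations of k re-coding sites applied to the
#' coding sequence; the unedited form is excluded from the augmentation
#' set. A premature stop introduced by an edit truncates the proteoform
#' (with a warning).
#'
#' @param model A coding [transcript_model()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param sites Data frame with `pos`, `ref`, `alt`; all positions must map
#'   into the model's CDS.
#' @param max_sites Combinatorial guard: more than this many sites is
#'   refused (default 16, i.e. at most 65,535 proteoforms).
#' @return Data frame with `proteoform_id`, `transcript_id`, `edit_set`
#'   (comma-joined site ids), `n_edits`, `sequence` (amino acids) and
#'   `changed_positions` (comma-joined residue indices differing from the
#'   reference translation).
#' @export
enumerate_proteoforms <- function(model, genome, sites, max_sites = 16L) {
  stopifnot(inherits(model, "transcript_model"), !is.null(model$cds))
  k <- nrow(sites)
  if (k > max_sites)
    stop("refusing to enumerate 2^", k, " - 1 proteoforms (max_sites = ",
         max_sites, ")", call. = FALSE)
  empty <- data.frame(proteoform_id = character(0), transcript_id = character(0),
                      edit_set = character(0), n_edits = integer(0),
                      sequence = character(0), changed_positions = character(0),
                      stringsAsFactors = FALSE)
  if (k == 0) return(empty)
  map <- .cds_map(model)
  cds_idx <- map$cds_index[match(sites$pos, map$genome_pos)]
  if (any(is.na(cds_idx)))
    stop("all sites must map into the model's CDS", call. = FALSE)
  cds_ref <- coding_sequence(model, genome)
  ref_aa <- .translate_cds(cds_ref, warn_premature = FALSE)
  site_ids <- if ("site_id" %in% names(sites)) sites$site_id else
    sprintf("%s:%d:%s>%s", model$chrom, sites$pos, sites$ref, sites$alt)
  coding_alt <- if (model$strand == "+") sites$alt else
    unname(.comp_base[sites$alt])

  out <- vector("list", 2^k - 1)
  for (mask in seq_len(2^k - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    cds <- cds_ref
    for (s in sel)
      substr(cds, cds_idx[s], cds_idx[s]) <- coding_alt[s]
    aa <- .translate_cds(cds)
    n <- min(nchar(aa), nchar(ref_aa))
    diffs <- which(strsplit(substr(aa, 1, n), "")[[1]] !=
                     strsplit(substr(ref_aa, 1, n), "")[[1]])
    if (nchar(aa) != nchar(ref_aa) && nchar(aa) > 0)
      diffs <- sort(unique(c(diffs, nchar(aa))))  # new C-terminus
    out[[mask]] <- data.frame(
      proteoform_id = sprintf("%s_pf%d", model$transcript_id, mask),
      transcript_id = model$transcript_id,
      edit_set = paste(site_ids[sel], collapse = ","),
      n_edits = length(sel), sequence = aa,
      changed_positions = paste(diffs, collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fully tryptic in-silico digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P (Keil
#' rule) and emits all fully tryptic peptides with 0 to `max_missed`
#' internal missed cleavages and length >= `min_length`, ordered N- to
#' C-terminal, then by missed-cleavage count.
#'
#' @param protein Amino-acid string over the 20-letter alphabet.
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param min_length Minimum peptide length (default 6).
#' @return Data frame with `sequence`, `start`, `end`, `missed_cleavages`.
#' @export
tryptic_digest <- function(protein, max_missed = 2L, min_length = 6L) {
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  res <- strsplit(protein, "")[[1]]
  if (!all(res %in% .AA20))
    stop("invalid residue(s): ",
         paste(unique(res[!res %in% .AA20]), collapse = ", "), call. = FALSE)
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut_after, n))  # segment boundaries
  m <- length(bounds) - 1L
  out <- list()
  for (t in seq_len(m)) {
    for (u in t:min(m, t + max_missed)) {
      a <- bounds[t] + 1L; b <- bounds[u + 1L]
      if (b - a + 1L >= min_length)
        out[[length(out) + 1L]] <- data.frame(
          sequence = paste(res[a:b], collapse = ""), start = a, end = b,
          missed_cleavages = u - t, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0)))
  out <- do.call(rbind, out)
  out[order(out$start, out$missed_cleavages), , drop = FALSE]
}

#' Build the edited-peptide search database
#'
#' Digests every edited proteoform and retains the tryptic peptides that
#' (a) cover at least one edited residue and (b) are absent from the digest
#' of the unedited proteome. Uniqueness is by peptide sequence; a peptide
#' generated by several proteoforms keeps one record listing all sources.
#'
#' @param proteoforms Data frame from [enumerate_proteoforms()] (possibly
#'   row-bound across transcripts).
#' @param unedited_proteome Data frame with `transcript_id`, `sequence` of
#'   the reference (unedited) proteome.
#' @param max_missed,min_length Digestion parameters (defaults: fully
#'   tryptic, at most two missed cleavages, minimum length 6).
#' @return Data frame of unique edited peptides: `sequence`, `n_sources`,
#'   `sources` (semicolon-joined `transcript|edit_set`), `edit_sets`,
#'   `min_missed_cleavages`, `is_edited_unique` (always `TRUE` here by
#'   construction).
#' @export
build_edited_peptide_db <- function(proteoforms, unedited_proteome,
                                    max_missed = 2L, min_length = 6L) {
  ref_peps <- unique(unlist(lapply(unedited_proteome$sequence, function(s)
    tryptic_digest(s, max_missed, min_length)$sequence)))
  recs <- list()
  for (j in seq_len(nrow(proteoforms))) {
    pf <- proteoforms[j, ]
    if (!nzchar(pf$edit_set) || !nzchar(pf$sequence)) next
    changed <- as.integer(strsplit(pf$changed_positions, ",")[[1]])
    if (!length(changed)) next  # silent at the protein level
    dig <- tryptic_digest(pf$sequence, max_missed, min_length)
    if (!nrow(dig)) next
    covers <- vapply(seq_len(nrow(dig)), function(i)
      any(changed >= dig$start[i] & changed <= dig$end[i]), logical(1))
    dig <- dig[covers & !(dig$sequence %in% ref_peps), , drop = FALSE]
    if (!nrow(dig)) next
    dig$source <- paste0(pf$transcript_id, "|", pf$edit_set)
    dig$edit_set <- pf$edit_set
    recs[[length(recs) + 1L]] <- dig
  }
  if (!length(recs))
    return(data.frame(sequence = character(0), n_sources = integer(0),
                      sources = character(0), edit_sets = character(0),
                      min_missed_cleavages = integer(0),
                      is_edited_unique = logical(0)))
  recs <- do.call(rbind, recs)
  split_recs <- split(recs, recs$sequence)
  out <- do.call(rbind, lapply(split_recs, function(g) data.frame(
    sequence = g$sequence[1],
    n_sources = length(unique(g$source)),
    sources = paste(sort(unique(g$source)), collapse = ";"),
    edit_sets = paste(sort(unique(g$edit_set)), collapse = ";"),
    min_missed_cleavages = min(g$missed_cleavages),
    is_edited_unique = TRUE, stringsAsFactors = FALSE)))
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an edited-peptide (or proteoform) FASTA
#'
#' @param db Data frame with `sequence` plus `sources` (peptide db) or
#'   `proteoform_id`/`edit_set` (proteoforms).
#' @param path Output file.
#' @export
write_peptide_fasta <- function(db, path) {
  ids <- if ("sources" %in% names(db)) {
    sprintf("editpep%04d %s", seq_len(nrow(db)), db$sources)
  } else {
    sprintf("%s %s", db$proteoform_id, db$edit_set)
  }
  aa <- Biostrings::AAStringSet(setNames(db$sequence, ids))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Match observed peptide sequences against the edited-peptide database
#'
#' Exact string matching only. The concordance table reports, per re-coding
#' site, whether at least one edited peptide carrying that site was
#' observed (`"RNA+peptide"`) or not (`"RNA-only"`).
#'
#' @param observed Character vector of observed peptide sequences.
#' @param db Database from [build_edited_peptide_db()].
#' @param site_ids Optional character vector of re-coding site ids to report
#'   on; defaults to all sites appearing in the database's edit sets.
#' @return List with `matched` (db rows observed) and `concordance`
#'   (`site_id`, `n_matched_peptides`, `status`).
#' @export
match_observed_peptides <- function(observed, db, site_ids = NULL) {
  if (!length(observed)) stop("observed peptide list is empty", call. = FALSE)
  matched <- db[db$sequence %in% observed, , drop = FALSE]
  db_sites <- unique(unlist(strsplit(unlist(strsplit(db$edit_sets, ";")), ",")))
  if (is.null(site_ids)) site_ids <- sort(db_sites)
  n_hit <- vapply(site_ids, function(s)
    sum(vapply(strsplit(matched$edit_sets, "[;,]"), function(x) s %in% x,
               logical(1))), integer(1))
  concordance <- data.frame(
    site_id = site_ids, n_matched_peptides = n_hit,
    status = ifelse(n_hit > 0, "RNA+peptide", "RNA-only"),
    stringsAsFactors = FALSE)
  rownames(concordance) <- NULL
  list(matched = matched, concordance = concordance)
}

#' Reference (unedited) proteome of the toy gene models
#'
#' @param models Named list of [transcript_model()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @return Data frame with `transcript_id`, `gene_id`, `sequence`.
#' @export
reference_proteome <- function(models, genome) {
  coding <- Filter(function(m) !is.null(m$cds), models)
  do.call(rbind, lapply(coding, function(m) data.frame(
    transcript_id = m$transcript_id, gene_id = m$gene_id,
    sequence = .translate_cds(coding_sequence(m, genome),
                              warn_premature = FALSE),
    stringsAsFactors = FALSE)))
}
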