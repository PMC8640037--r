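# Editing-call QC, substitution classification, per-subject summaries,
# genomic annotation, and cross-region overlap partitions.

#' Editing level of a call
#'
#' The ratio of edited-allele reads to total reads, alt / (ref + alt).
#'
#' @param ref_depth,alt_depth Non-negative read counts (vectorised).
#' @return Numeric vector of levels in \[0, 1\].
#' @export
editing_level <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0 | alt_depth < 0)) stop("read depths must be >= 0")
  total <- ref_depth + alt_depth
  if (any(total == 0))
    stop("editing level is undefined at zero total depth", call. = FALSE)
  alt_depth / total
}

#' Classify a substitution and flag canonical A-to-I
#'
#' The substitution class is the genome-reported base pair (one of 12
#' ordered pairs, e.g. `"A>G"`). Canonical A-to-I editing appears as A>G on
#' the plus strand and as T>C when the edited transcript is on the minus
#' strand, so the canonical flag is decided from the genome-reported pair
#' alone, independent of any transcript annotation.
#'
#' @param ref,alt Reference and alternative bases (vectorised).
#' @return Data frame with `substitution_class` and `is_canonical_AtoI`.
#' @export
classify_substitution <- function(ref, alt) {
  if (!length(ref))
    return(data.frame(substitution_class = character(0),
                      is_canonical_AtoI = logical(0)))
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("ref and alt must be single bases in {A,C,G,T}", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  cls <- paste0(ref, ">", alt)
  data.frame(substitution_class = cls,
             is_canonical_AtoI = cls %in% c("A>G", "T>C"))
}

#' Quality-control filter for editing calls within one dataset
#'
#' Applies the four posterior filters in order: (1) calls with total reads
#' < `min_total` fail; (2) calls with alternative reads < `min_alt` fail;
#' (3) sites detected (a passing call in >= 1 sample) in fewer than
#' `min_frequency` of the dataset's subjects are removed; (4) sites at known
#' genomic-variant positions are removed. Filter (3) is interpreted as
#' subject prevalence by default; `frequency_mode = "level"` instead
#' thresholds the per-call allele fraction at `min_frequency`.
#'
#' @param calls Data frame with `chrom`, `pos`, `ref`, `alt`, `ref_depth`,
#'   `alt_depth`, `sample_id` and optionally `subject_id` (defaults to
#'   `sample_id`). Must come from a single dataset.
#' @param known_variants Optional data frame of known genomic variants
#'   (`chrom`, `pos`).
#' @param min_total,min_alt,min_frequency Filter thresholds.
#' @param frequency_mode `"prevalence"` (default) or `"level"`.
#' @return List of class `qc_result`: `sites` (passing sites with
#'   subject frequency and mean level), `calls` (input plus `level`,
#'   `pass_total`, `pass_alt`, `pass` flags), `audit` (named removal counts
#'   per filter, in order; input sites = passing + sum(removed)), `params`.
#' @export
qc_filter <- function(calls, known_variants = NULL, min_total = 20,
                      min_alt = 5, min_frequency = 0.10,
                      frequency_mode = c("prevalence", "level")) {
  frequency_mode <- match.arg(frequency_mode)
  need <- c("chrom", "pos", "ref", "alt", "ref_depth", "alt_depth", "sample_id")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if ("dataset" %in% names(calls) && length(unique(calls$dataset)) > 1)
    stop("qc_filter expects calls from a single dataset; split first",
         call. = FALSE)
  empty_audit <- c(input_sites = 0L, removed_low_total = 0L,
                   removed_low_alt = 0L, removed_low_frequency = 0L,
                   removed_known_variant = 0L, passing_sites = 0L)
  params <- list(min_total = min_total, min_alt = min_alt,
                 min_frequency = min_frequency, frequency_mode = frequency_mode)
  if (nrow(calls) == 0) {
    return(structure(list(sites = data.frame(), calls = calls,
                          audit = empty_audit, params = params),
                     class = "qc_result"))
  }
  calls <- as.data.frame(calls)
  if (!"subject_id" %in% names(calls)) calls$subject_id <- calls$sample_id
  calls$site_id <- sprintf("%s:%d:%s>%s", calls$chrom, as.integer(calls$pos),
                           calls$ref, calls$alt)
  total <- calls$ref_depth + calls$alt_depth
  calls$level <- ifelse(total > 0, calls$alt_depth / total, NA_real_)
  calls$pass_total <- total >= min_total
  calls$pass_alt <- calls$pass_total & calls$alt_depth >= min_alt
  calls$pass <- calls$pass_alt
  if (frequency_mode == "level")
    calls$pass <- calls$pass & calls$level >= min_frequency

  n_subjects <- length(unique(calls$subject_id))
  site_ids <- unique(calls$site_id)
  # per-site aggregates over passing calls
  agg <- function(flag) {
    tapply(flag, calls$site_id, any)[site_ids]
  }
  any_pass1 <- agg(calls$pass_total)
  any_pass2 <- agg(calls$pass_alt)
  any_pass <- agg(calls$pass)
  pass_subj <- tapply(ifelse(calls$pass, calls$subject_id, NA_character_),
                      calls$site_id,
                      function(s) length(unique(s[!is.na(s)])))[site_ids]
  frequency <- pass_subj / n_subjects
  mean_level <- tapply(ifelse(calls$pass, calls$level, NA_real_),
                       calls$site_id, mean, na.rm = TRUE)[site_ids]
  first <- match(site_ids, calls$site_id)
  is_kv <- if (is.null(known_variants) || nrow(known_variants) == 0) {
    rep(FALSE, length(site_ids))
  } else {
    paste(calls$chrom[first], calls$pos[first]) %in%
      paste(known_variants$chrom, known_variants$pos)
  }

  freq_ok <- if (frequency_mode == "prevalence") frequency >= min_frequency
             else any_pass
  rm1 <- !any_pass1
  rm2 <- any_pass1 & !any_pass2
  rm3 <- any_pass2 & (!any_pass | !freq_ok)
  rm4 <- any_pass2 & any_pass & freq_ok & is_kv
  keep <- !(rm1 | rm2 | rm3 | rm4)

  cls <- classify_substitution(calls$ref[first][keep], calls$alt[first][keep])
  sites <- data.frame(
    site_id = site_ids[keep],
    chrom = calls$chrom[first][keep], pos = calls$pos[first][keep],
    ref = calls$ref[first][keep], alt = calls$alt[first][keep],
    substitution_class = cls$substitution_class,
    is_canonical_AtoI = cls$is_canonical_AtoI,
    frequency = as.numeric(frequency[keep]),
    mean_level = as.numeric(mean_level[keep]),
    n_subjects_passing = as.integer(pass_subj[keep]),
    stringsAsFactors = FALSE)
  sites <- sites[order(sites$pos, sites$site_id), ]
  rownames(sites) <- NULL
  audit <- c(input_sites = length(site_ids),
             removed_low_total = sum(rm1), removed_low_alt = sum(rm2),
             removed_low_frequency = sum(rm3), removed_known_variant = sum(rm4),
             passing_sites = sum(keep))
  structure(list(sites = sites, calls = calls, audit = audit, params = params),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$audit)
  invisible(x)
}

#' Apply the QC filter per dataset
#'
#' @param calls Call table with a `dataset` column.
#' @param ... Passed to [qc_filter()].
#' @return Named list of `qc_result`, one per dataset.
#' @export
qc_filter_all <- function(calls, ...) {
  lapply(split(calls, calls$dataset), qc_filter, ...)
}

#' Per-sample overall editing summaries
#'
#' For each sample, the overall editing level is the sum of per-event
#' levels divided by the number of events called in that sample (i.e. the
#' mean level across its passing events), together with the event count.
#'
#' @param qc A `qc_result` from [qc_filter()].
#' @return Data frame with `sample_id`, `subject_id`, `overall_level`,
#'   `n_events` (samples with zero passing events are excluded with a
#'   warning).
#' @export
subject_summaries <- function(qc) {
  stopifnot(inherits(qc, "qc_result"))
  calls <- qc$calls
  ok <- calls$pass & calls$site_id %in% qc$sites$site_id
  all_samples <- unique(calls$sample_id)
  calls <- calls[ok, , drop = FALSE]
  if (nrow(calls) == 0) {
    warning("no passing calls; empty summary")
    return(data.frame(sample_id = character(0), subject_id = character(0),
                      overall_level = numeric(0), n_events = integer(0)))
  }
  lev <- tapply(calls$level, calls$sample_id, mean)
  n <- tapply(calls$level, calls$sample_id, length)
  subj <- calls$subject_id[match(names(lev), calls$sample_id)]
  dropped <- setdiff(all_samples, names(lev))
  if (length(dropped))
    warning(length(dropped), " sample(s) with zero passing events excluded")
  out <- data.frame(sample_id = names(lev), subject_id = subj,
                    overall_level = as.numeric(lev), n_events = as.integer(n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.REGION_PRECEDENCE <- c(exonic = 1, `5'UTR` = 2, `3'UTR` = 3, intronic = 4,
                        ncRNA = 5, upstream = 6, downstream = 7, intergenic = 8)

# flatten transcript models into a feature GRanges with precedence ranks
.feature_granges <- function(models, flank = 1000L) {
  feats <- lapply(models, function(m) {
    rows <- list()
    add <- function(start, end, type) {
      if (length(start) && any(end >= start))
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = m$chrom, start = start, end = end, type = type,
          gene_id = m$gene_id, strand = m$strand)
    }
    if (!is.null(m$cds)) {
      add(m$cds$start, m$cds$end, "exonic")
      # UTRs: exonic sequence outside the CDS span, split by strand polarity
      cds_lo <- min(m$cds$start); cds_hi <- max(m$cds$end)
      for (i in seq_len(nrow(m$exons))) {
        a <- m$exons$start[i]; b <- m$exons$end[i]
        if (a < cds_lo)
          add(a, min(b, cds_lo - 1L),
              if (m$strand == "+") "5'UTR" else "3'UTR")
        if (b > cds_hi)
          add(max(a, cds_hi + 1L), b,
              if (m$strand == "+") "3'UTR" else "5'UTR")
      }
    } else {
      add(m$exons$start, m$exons$end, "ncRNA")
    }
    # introns: gaps between exons
    if (nrow(m$exons) > 1)
      add(m$exons$end[-nrow(m$exons)] + 1L, m$exons$start[-1] - 1L, "intronic")
    if (m$strand == "+") {
      add(max(1L, m$span[1] - flank), m$span[1] - 1L, "upstream")
      add(m$span[2] + 1L, m$span[2] + flank, "downstream")
    } else {
      add(m$span[2] + 1L, m$span[2] + flank, "upstream")
      add(max(1L, m$span[1] - flank), m$span[1] - 1L, "downstream")
    }
    do.call(rbind, rows)
  })
  feats <- do.call(rbind, feats)
  GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(feats$start, feats$end),
    type = feats$type, gene_id = feats$gene_id,
    precedence = .REGION_PRECEDENCE[feats$type])
}

#' Annotate editing sites with genomic region, closest gene, reported status
#'
#' Each site gets exactly one region category (5'UTR, exonic, 3'UTR,
#' intronic, ncRNA, upstream/downstream within 1 kb of the transcript
#' boundaries, or intergenic) assigned by precedence — the most
#' transcript-internal consequence wins when features overlap:
#' exonic > 5'UTR > 3'UTR > intronic > ncRNA > upstream > downstream >
#' intergenic. The closest gene is the nearest model by distance to the
#' gene span (ties broken by lexicographic gene id), and reported status is
#' membership in the reported-editing reference.
#'
#' @param sites Data frame with `chrom`, `pos`, `ref`, `alt` (e.g. the
#'   `sites` element of a [qc_filter()] result).
#' @param models List of [transcript_model()] objects.
#' @param reported_sites Data frame of reported positions (`chrom`, `pos`).
#' @param flank Flank width for upstream/downstream, default 1000 bp.
#' @return `sites` with added `region_annotation`, `closest_gene`,
#'   `gene_distance`, `reported_status`, `substitution_class`,
#'   `is_canonical_AtoI`.
#' @export
annotate_sites <- function(sites, models, reported_sites = NULL,
                           flank = 1000L) {
  stopifnot(is.data.frame(sites), length(models) >= 1)
  sites <- as.data.frame(sites)
  feats <- .feature_granges(models, flank = flank)
  known_chroms <- as.character(unique(GenomicRanges::seqnames(feats)))
  unknown <- !(sites$chrom %in% known_chroms)
  if (any(unknown))
    warning(sum(unknown), " site(s) on chromosomes without gene models; ",
            "annotated as intergenic")

  region <- rep("intergenic", nrow(sites))
  closest <- rep(NA_character_, nrow(sites))
  gdist <- rep(NA_real_, nrow(sites))

  if (any(!unknown)) {
    q <- GenomicRanges::GRanges(sites$chrom[!unknown],
                                IRanges::IRanges(sites$pos[!unknown],
                                                 sites$pos[!unknown]))
    hits <- GenomicRanges::findOverlaps(q, feats)
    if (length(hits)) {
      hdf <- data.frame(q = S4Vectors::queryHits(hits),
                        prec = feats$precedence[S4Vectors::subjectHits(hits)],
                        type = feats$type[S4Vectors::subjectHits(hits)])
      best <- tapply(seq_len(nrow(hdf)), hdf$q, function(i)
        i[which.min(hdf$prec[i])])
      idx_un <- which(!unknown)
      region[idx_un[as.integer(names(best))]] <- hdf$type[unlist(best)]
    }
    # closest gene by distance to gene span, ties to lexicographic gene id
    spans <- do.call(rbind, lapply(models, function(m)
      data.frame(chrom = m$chrom, start = m$span[1], end = m$span[2],
                 gene_id = m$gene_id)))
    spans <- spans[order(spans$gene_id), ]
    gr_spans <- GenomicRanges::GRanges(spans$chrom,
                                       IRanges::IRanges(spans$start, spans$end))
    for (j in which(!unknown)) {
      qg <- GenomicRanges::GRanges(sites$chrom[j],
                                   IRanges::IRanges(sites$pos[j], sites$pos[j]))
      d <- GenomicRanges::distance(qg, gr_spans)
      d[is.na(d)] <- Inf  # different chromosome
      k <- which(d == min(d))[1]  # spans sorted by gene id => lexicographic tie-break
      closest[j] <- spans$gene_id[k]
      gdist[j] <- d[k]
    }
  }

  reported <- if (is.null(reported_sites) || nrow(reported_sites) == 0) {
    rep(FALSE, nrow(sites))
  } else {
    paste(sites$chrom, sites$pos) %in%
      paste(reported_sites$chrom, reported_sites$pos)
  }
  if (!"substitution_class" %in% names(sites)) {
    cls <- classify_substitution(sites$ref, sites$alt)
    sites$substitution_class <- cls$substitution_class
    sites$is_canonical_AtoI <- cls$is_canonical_AtoI
  }
  sites$region_annotation <- region
  sites$closest_gene <- closest
  sites$gene_distance <- gdist
  sites$reported_status <- ifelse(reported, "reported", "not_reported")
  sites
}

#' Partition frequent sites by region membership
#'
#' Venn-style exact partition: every site is counted in exactly one region
#' combination, so the per-region totals reconstruct the input sets.
#'
#' @param site_sets Named list of character vectors of site ids, one per
#'   region (>= 2 regions).
#' @return Data frame with `combination` (region names joined by `&`),
#'   `n_regions`, `count`.
#' @export
region_overlap_counts <- function(site_sets) {
  if (length(site_sets) < 2) stop("need >= 2 regions")
  if (is.null(names(site_sets)) || any(names(site_sets) == ""))
    stop("site_sets must be named by region")
  all_sites <- unique(unlist(site_sets))
  memb <- vapply(site_sets, function(s) all_sites %in% s,
                 logical(length(all_sites)))
  if (length(all_sites) == 1) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(site_sets)))
  pattern <- apply(memb, 1, function(r)
    paste(names(site_sets)[r], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(combination = names(tab),
                    n_regions = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$n_regions, out$combination), , drop = FALSE]
}
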