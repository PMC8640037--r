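test_that("editing level is the edited-allele fraction of total reads", {
  expect_equal(editing_level(10, 10), 0.5)
  expect_equal(editing_level(0, 25), 1.0)
  expect_equal(editing_level(90, 10), 0.10)
  expect_equal(editing_level(c(10, 0), c(10, 25)), c(0.5, 1))
  expect_error(editing_level(0, 0), "zero total depth")
  expect_error(editing_level(-1, 5), ">= 0")
})

test_that("substitution classes and the canonical A-to-I flag", {
  r <- classify_substitution(c("A", "T", "C", "G"), c("G", "C", "T", "A"))
  expect_equal(r$substitution_class, c("A>G", "T>C", "C>T", "G>A"))
  expect_equal(r$is_canonical_AtoI, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "A,C,G,T")
})

# 20 subjects; sX appears at subject s01..; helper to build one-call rows
mk_call <- function(pos, subject, ref_depth, alt_depth, ref = "A", alt = "G") {
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
             ref_depth = ref_depth, alt_depth = alt_depth,
             sample_id = paste0(subject, "_R1"), subject_id = subject)
}

test_that("the four QC filters act in order with the documented thresholds", {
  subjects <- sprintf("s%02d", 1:20)
  calls <- rbind(
    # site 100: total 19 at every subject -> filter 1
    do.call(rbind, lapply(subjects, function(s) mk_call(100, s, 14, 5))),
    # site 200: total 100 but alt 4 -> filter 2
    do.call(rbind, lapply(subjects, function(s) mk_call(200, s, 96, 4))),
    # site 300: passing in 1 of 20 subjects (5%) -> filter 3
    mk_call(300, "s01", 50, 25),
    # site 400: passes everywhere but sits on a known variant -> filter 4
    do.call(rbind, lapply(subjects, function(s) mk_call(400, s, 50, 50))),
    # site 500: clean pass in all subjects
    do.call(rbind, lapply(subjects, function(s) mk_call(500, s, 60, 20))))
  kv <- data.frame(chrom = "chr1", pos = 400)
  qc <- qc_filter(calls, kv)
  expect_equal(unname(qc$audit["removed_low_total"]), 1L)
  expect_equal(unname(qc$audit["removed_low_alt"]), 1L)
  expect_equal(unname(qc$audit["removed_low_frequency"]), 1L)
  expect_equal(unname(qc$audit["removed_known_variant"]), 1L)
  expect_equal(qc$sites$site_id, "chr1:500:A>G")
  expect_equal(qc$sites$frequency, 1)
  expect_equal(qc$sites$mean_level, 0.25)
  # audit conservation
  expect_equal(unname(qc$audit["input_sites"]),
               unname(qc$audit["passing_sites"] + sum(qc$audit[2:5])))
})

test_that("QC matches a brute-force per-call re-check on a random fixture", {
  set.seed(77)
  n <- 1000
  subjects <- sprintf("s%02d", 1:25)
  calls <- data.frame(
    chrom = "chr1", pos = sample(seq(100, 2000, by = 20), n, replace = TRUE),
    ref = "A", alt = "G",
    ref_depth = rnbinom(n, mu = 30, size = 2),
    alt_depth = rnbinom(n, mu = 6, size = 2),
    sample_id = NA, subject_id = sample(subjects, n, replace = TRUE))
  calls$sample_id <- paste0(calls$subject_id, "_R1")
  calls <- calls[calls$ref_depth + calls$alt_depth > 0, ]
  kv <- data.frame(chrom = "chr1", pos = sample(unique(calls$pos), 10))
  qc <- qc_filter(calls, kv)
  bf <- brute_qc(calls, kv)
  expect_identical(sort(qc$sites$site_id), bf$passing)
  expect_identical(qc$audit[2:5], bf$audit)
  expect_equal(unname(qc$audit["input_sites"]),
               unname(qc$audit["passing_sites"] + sum(qc$audit[2:5])))
})

test_that("the level-mode frequency switch thresholds the allele fraction", {
  subjects <- sprintf("s%02d", 1:10)
  # passing depth but 5% allele fraction at every subject
  calls <- do.call(rbind, lapply(subjects, function(s) mk_call(100, s, 95, 5)))
  qc_prev <- qc_filter(calls, min_frequency = 0.10, frequency_mode = "prevalence")
  qc_lev <- qc_filter(calls, min_frequency = 0.10, frequency_mode = "level")
  expect_equal(nrow(qc_prev$sites), 1)  # prevalence 100%
  expect_equal(nrow(qc_lev$sites), 0)   # allele fraction 5% < 10%
})

test_that("per-sample summaries average event levels and count events", {
  subjects <- c("s01", "s02")
  calls <- rbind(
    mk_call(100, "s01", 80, 20), mk_call(200, "s01", 60, 40),
    mk_call(300, "s01", 40, 60),
    mk_call(100, "s02", 80, 20), mk_call(200, "s02", 60, 40),
    mk_call(300, "s02", 40, 60))
  qc <- qc_filter(calls)
  s <- subject_summaries(qc)
  expect_equal(s$overall_level, c(0.4, 0.4))
  expect_equal(s$n_events, c(3L, 3L))
  # identical calls -> identical summaries
  expect_equal(s$overall_level[1], s$overall_level[2])
  # single event
  qc1 <- qc_filter(mk_call(100, "s01", 63, 37))
  s1 <- subject_summaries(qc1)
  expect_equal(s1$overall_level, 0.37)
  expect_equal(s1$n_events, 1L)
})

test_that("annotation precedence, flanks, and reported status", {
  set.seed(4)
  tg <- toy_gene(.rand_cds_test(30), strand = "+", utr5 = 20, utr3 = 20,
                 pad = 1500)
  m <- tg$model
  sites <- data.frame(
    chrom = "chrT",
    pos = c(tg$cds_pos(5),            # inside CDS
            m$span[1] - 500,          # 500 bp 5' of a '+' TSS
            m$span[1] + 3,            # 5'UTR
            m$span[2] - 3,            # 3'UTR
            m$span[2] + 500,          # downstream
            m$span[1] - 1400),        # > 1 kb away: intergenic
    ref = "A", alt = "G")
  rep_sites <- data.frame(chrom = "chrT", pos = sites$pos[1])
  ann <- annotate_sites(sites, list(txT = m), rep_sites)
  expect_equal(ann$region_annotation,
               c("exonic", "upstream", "5'UTR", "3'UTR", "downstream",
                 "intergenic"))
  expect_equal(ann$reported_status,
               c("reported", rep("not_reported", 5)))
  expect_true(all(ann$closest_gene == "geneT"))
})

test_that("every position receives exactly one region category", {
  set.seed(11)
  d <- small_design(n_sites = 40L, n_transcripts = 4L)
  ref <- generate_reference(d)
  span <- range(unlist(lapply(ref$models, `[[`, "span")))
  pos <- seq(max(1, span[1] - 1200), span[2] + 1200, by = 97)
  sites <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G")
  ann <- annotate_sites(sites, ref$models)
  expect_equal(nrow(ann), length(pos))
  expect_true(all(ann$region_annotation %in%
                    c("exonic", "5'UTR", "3'UTR", "intronic", "ncRNA",
                      "upstream", "downstream", "intergenic")))
  # unknown chromosome falls back to intergenic with a warning
  expect_warning(
    ann2 <- annotate_sites(data.frame(chrom = "chrZ", pos = 50,
                                      ref = "A", alt = "G"), ref$models),
    "without gene models")
  expect_equal(ann2$region_annotation, "intergenic")
})

test_that("annotation agrees with the generator's ground truth", {
  d <- small_design(n_sites = 80L)
  ref <- generate_reference(d)
  ann <- annotate_sites(ref$sites[, c("chrom", "pos", "ref", "alt")],
                        ref$models, ref$reported_sites)
  truth <- ref$sites$region_truth
  truth[truth == "exonic"] <- "exonic"
  expect_equal(ann$region_annotation, truth)
  expect_equal(ann$reported_status == "reported", ref$sites$is_reported)
})

test_that("region overlap counts form an exact partition", {
  r <- region_overlap_counts(list(A = c("s1", "s2"), B = c("s2", "s3")))
  expect_equal(r$count[r$combination == "A&B"], 1L)
  expect_equal(r$count[r$combination == "A"], 1L)
  expect_equal(r$count[r$combination == "B"], 1L)
  expect_equal(sum(r$count), 3L)  # every site in exactly one cell
  # identical sets: all in the full intersection
  r2 <- region_overlap_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(r2$combination, "A&B")
  expect_equal(r2$count, 2L)
  # disjoint sets: no intersection cell
  r3 <- region_overlap_counts(list(A = "x", B = "y"))
  expect_false("A&B" %in% r3$combination)
  expect_error(region_overlap_counts(list(A = "x")), ">= 2")
})
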