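# shared fixture: nb batches x (nc cases + 2 GIS), optional factors/noise
pep_matrix <- function(npep = 40, nb = 2, nc = 6, factors = rep(1, nb),
                       noise_sd = 0, seed = 1, edited_rows = integer(0)) {
  set.seed(seed)
  per <- nc + 2
  batch <- rep(sprintf("b%d", seq_len(nb)), each = per)
  is_gis <- rep(c(rep(FALSE, nc), TRUE, TRUE), nb)
  base <- 2^runif(npep, 12, 18)
  v <- outer(base, factors[match(batch, unique(batch))]) *
    matrix(exp(rnorm(npep * length(batch), 0, noise_sd)), npep)
  rownames(v) <- sprintf("PEPTIDE%03d", seq_len(npep))
  colnames(v) <- paste0(batch, "_", seq_along(batch))
  is_edited <- seq_len(npep) %in% edited_rows
  abundance_matrix(v, batch, is_gis, is_edited)
}

test_that("the abundance-matrix container enforces its invariants", {
  expect_error(pep_matrix(factors = c(1, -1)), "positive")
  v <- matrix(1:8, 2, 4)
  expect_error(abundance_matrix(v, batch = c("a", "a", "b", "b"),
                                is_gis = c(TRUE, FALSE, FALSE, FALSE),
                                is_edited = c(FALSE, FALSE)),
               "batch without GIS")
})

test_that("the missingness cull spares edited peptides", {
  am <- pep_matrix(npep = 3, nc = 8, edited_rows = 2)
  # 20 samples; make row 1 60% missing, row 2 (edited) 90%, row 3 45%
  am$values[1, 1:12] <- NA
  am$values[2, 1:18] <- NA
  am$values[3, 1:9] <- NA
  culled <- cull_missing(am)
  expect_equal(rownames(culled$values), c("PEPTIDE002", "PEPTIDE003"))
  cull <- attr(culled, "cull")
  expect_equal(unname(cull["dropped"]), 1)
  expect_equal(unname(cull["edited_retained_over_threshold"]), 1)
  # exactly at 50%: dropped; just below: kept
  am2 <- pep_matrix(npep = 2, nc = 8)
  am2$values[1, 1:10] <- NA   # 50% -> dropped
  am2$values[2, 1:9] <- NA    # 45% -> kept
  expect_equal(rownames(cull_missing(am2)$values), "PEPTIDE002")
})

test_that("a single batch with no batch effect is a fixed point", {
  am <- pep_matrix(nb = 1, noise_sd = 0)
  res <- tampor_normalize(am)
  expect_true(res$converged)
  expect_equal(res$corrected$values, am$values, tolerance = 1e-10)
})

test_that("a planted 2x batch factor is removed exactly when noise-free", {
  am <- pep_matrix(nb = 2, factors = c(1, 2), noise_sd = 0)
  res <- tampor_normalize(am)
  expect_true(res$converged)
  expect_lt(res$iterations, 50)
  v <- res$corrected$values
  med <- vapply(unique(am$batch), function(b)
    apply(v[, am$batch == b, drop = FALSE], 1, median), numeric(nrow(v)))
  expect_lt(max(abs(med[, 1] - med[, 2]) / med[, 1]), 1e-6)
  # restoration contract: row geometric means preserved
  expect_equal(exp(rowMeans(log(v))), exp(rowMeans(log(am$values))),
               tolerance = 1e-8)
})

test_that("planted batch factors are recovered under noise", {
  am <- pep_matrix(npep = 60, nb = 2, nc = 8, factors = c(1, 2),
                   noise_sd = 0.05, seed = 5)
  res <- tampor_normalize(am)
  expect_true(res$converged)
  est <- estimate_batch_factors(am, res$corrected)
  expect_lt(abs(est[2] - 2) / 2, 0.05)
})

test_that("the all-samples denominator mode also removes the batch factor", {
  am <- pep_matrix(nb = 2, factors = c(1, 2), noise_sd = 0)
  res <- tampor_normalize(am, gis_mode = FALSE)
  v <- res$corrected$values
  med <- vapply(unique(am$batch), function(b)
    apply(v[, am$batch == b, drop = FALSE], 1, median), numeric(nrow(v)))
  expect_lt(max(abs(med[, 1] - med[, 2]) / med[, 1]), 1e-6)
})

test_that("correction is invariant to sample permutation within batches", {
  am <- pep_matrix(npep = 30, nb = 2, nc = 6, factors = c(1, 1.5),
                   noise_sd = 0.05, seed = 8)
  perm <- c(sample(1:8), 8 + sample(1:8))  # permute within each batch
  am_p <- abundance_matrix(am$values[, perm], am$batch[perm],
                           am$is_gis[perm], am$is_edited)
  r1 <- tampor_normalize(am)
  r2 <- tampor_normalize(am_p)
  expect_equal(r2$corrected$values, r1$corrected$values[, perm],
               tolerance = 1e-8)
})

test_that("missing GIS denominators propagate missingness, and non-convergence warns", {
  am <- pep_matrix(npep = 10, nb = 2, nc = 4, noise_sd = 0.05, seed = 2)
  am$values[1, am$batch == "b2" & am$is_gis] <- NA
  res <- suppressWarnings(tampor_normalize(am))
  expect_true(all(is.na(res$corrected$values[1, am$batch == "b2"])))
  expect_warning(tampor_normalize(pep_matrix(noise_sd = 0.1, seed = 3),
                                  max_iter = 1),
                 "did not converge")
})

test_that("connectivity flags a noise sample among correlated ones", {
  set.seed(13)
  shared <- rnorm(200, 15, 2)
  v <- 2^(matrix(shared, 200, 20) + matrix(rnorm(200 * 20, 0, 0.05), 200))
  v <- cbind(v, 2^rnorm(200, 15, 2))  # one pure-noise sample
  colnames(v) <- c(sprintf("good%02d", 1:20), "noisy")
  conn <- connectivity_outliers(v)
  expect_true("noisy" %in% outlier_samples(conn))
  expect_false(any(sprintf("good%02d", 1:20) %in% outlier_samples(conn)))
  # brute-force z-score check, round 1
  cc <- cor(log2(v)); k <- colSums(cc) - 1
  z <- (k - mean(k)) / sd(k)
  r1 <- conn[conn$round == 1, ]
  expect_equal(r1$z, unname(z), tolerance = 1e-12)
})

test_that("degenerate connectivity cases are safe", {
  v <- matrix(rep(2^seq(10, 14, length.out = 50), 6), 50, 6)
  expect_equal(nrow(connectivity_outliers(v)[connectivity_outliers(v)$flagged, ]),
               0)  # zero connectivity variance: no flags
  set.seed(14)
  v2 <- 2^matrix(rnorm(50 * 6, 15, 1), 50, 6)
  conn <- connectivity_outliers(v2, z_cut = Inf)
  expect_false(any(conn$flagged))
  expect_error(connectivity_outliers(v2[, 1:3]), ">= 4")
})

test_that("edited/non-edited ratios are within-sample and scale-invariant", {
  am <- pep_matrix(npep = 4, nb = 2, nc = 4, noise_sd = 0.1, seed = 6,
                   edited_rows = 1:2)
  pairs <- data.frame(edited = c("PEPTIDE001", "PEPTIDE002"),
                      unedited = c("PEPTIDE003", "PEPTIDE004"))
  r <- edited_ratio(am, pairs)
  expect_equal(dim(r), c(2, ncol(am$values)))
  # equal abundances give ratio 1
  am$values["PEPTIDE001", ] <- am$values["PEPTIDE003", ]
  expect_true(all(edited_ratio(am, pairs)[1, ] == 1))
  # doubling both members leaves the ratio unchanged
  am2 <- am; am2$values <- am$values * 2
  expect_equal(edited_ratio(am2, pairs), edited_ratio(am, pairs))
  # a missing member yields a missing ratio
  am$values["PEPTIDE004", 3] <- NA
  expect_true(is.na(edited_ratio(am, pairs)[2, 3]))
  expect_match(attr(r, "comparability"), "across samples")
  expect_error(edited_ratio(am, data.frame(edited = "X", unedited = "Y")),
               "not in matrix")
})
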