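test_that("MI equals the marginal entropy when y duplicates x", {
  x <- rep(c(0, 1), 50)
  expect_equal(mutual_information(x, x, 2, 2), log(2), tolerance = 1e-12)
  expect_equal(relative_mi(x, x, 2, 2), 1.0, tolerance = 1e-12)
})

test_that("a constant variable gives zero MI and zero rMI by convention", {
  y <- withr::with_seed(1, rnorm(50))
  x <- rep(3, 50)
  expect_equal(mutual_information(x, y), 0)
  expect_equal(relative_mi(x, y), 0)
})

test_that("plug-in MI matches direct cell-by-cell summation", {
  # data realising joint counts [[2,1],[1,2]] under 2x2 equal-width binning
  x <- c(0, 0, 0, 1, 1, 1, 0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1)
  joint <- matrix(c(4, 2, 2, 4), 2, 2)
  expect_equal(mutual_information(x, y, 2, 2), mi_oracle(joint),
               tolerance = 1e-12)
  # closed form for that table: (2/3)ln(4/3) + (1/3)ln(2/3)
  expect_equal(mi_oracle(joint), (2 / 3) * log(4 / 3) + (1 / 3) * log(2 / 3),
               tolerance = 1e-12)
})

test_that("MI is symmetric in its arguments (bins swapped accordingly)", {
  withr::with_seed(5, {
    x <- rnorm(200)
    y <- x + rnorm(200)
  })
  expect_equal(mutual_information(x, y, 7, 4), mutual_information(y, x, 4, 7),
               tolerance = 1e-12)
})

test_that("2-bin MI equals MI of the explicitly coarsened discrete data", {
  withr::with_seed(6, {
    x <- runif(300)
    y <- x^2 + runif(300) * 0.3
  })
  coarse_x <- as.numeric(x > (min(x) + max(x)) / 2)
  coarse_y <- as.numeric(y > (min(y) + max(y)) / 2)
  expect_equal(mutual_information(x, y, 2, 2),
               mutual_information(coarse_x, coarse_y, 2, 2),
               tolerance = 1e-12)
})

test_that("rMI of independent uniforms is near zero at n = 10000", {
  withr::with_seed(7, {
    x <- runif(10000)
    y <- runif(10000)
  })
  expect_lt(relative_mi(x, y), 0.02)
})

test_that("input validation: length mismatch, short vectors, bad bins", {
  expect_error(mutual_information(1:20, 1:19), "same length")
  expect_error(mutual_information(1:5, 1:5), "at least 10")
  expect_error(mutual_information(1:20, 1:20, bins_x = 1), "bins")
})

test_that("resampling produces a reproducible CI containing the estimate", {
  withr::with_seed(8, {
    x <- rnorm(150)
    y <- x + rnorm(150)
  })
  r1 <- resample_mi(x, y, n_boot = 200, n_perm = 200, seed = 99)
  r2 <- resample_mi(x, y, n_boot = 200, n_perm = 200, seed = 99)
  expect_equal(glance(r1), glance(r2))
  expect_lte(r1$ci_low, r1$ci_high)
  expect_gte(r1$mi_nats, r1$ci_low)
  expect_lte(r1$mi_nats, r1$ci_high)
  expect_s3_class(ggplot2::autoplot(r1), "ggplot")
  expect_warning(resample_mi(x, y, n_boot = 50, n_perm = 200, seed = 1),
                 "coarse")
})

test_that("identity data is highly significant under permutation", {
  x <- rep(seq_len(10), 20) # n = 200
  res <- resample_mi(x, x, n_boot = 100, n_perm = 500, seed = 3)
  expect_lte(res$p_perm, 0.01)
})

test_that("permutation p-values on independent data are near-uniform at 5%", {
  # null calibration at reduced scale; the acceptance suite runs the full one
  rejections <- vapply(1:50, function(i) {
    withr::with_seed(1000 + i, {
      x <- runif(80)
      y <- runif(80)
    })
    suppressWarnings(
      resample_mi(x, y, n_boot = 100, n_perm = 99, seed = 2000 + i)$p_perm
    ) <= 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.80)
})

test_that("pearson reproduces hand-computed and exact-line correlations", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1)$r, 1.0, tolerance = 1e-12)
  expect_equal(pearson(x, -x)$r, -1.0, tolerance = 1e-12)

  y <- c(1, 3, 2, 4)
  # direct product-moment computation as the oracle
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_hand, 0.8, tolerance = 1e-12)
  expect_equal(pearson(x, y)$r, r_hand, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("pearson r is invariant under positive affine transforms", {
  withr::with_seed(12, {
    x <- rnorm(60)
    y <- 0.5 * x + rnorm(60)
  })
  r0 <- pearson(x, y)$r
  expect_equal(pearson(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(x, 0.1 * y - 2)$r, r0, tolerance = 1e-12)
})

test_that("correlation table is symmetric with a unit diagonal", {
  tab <- plant_utr_table(300, 0.7, 0.3, seed = 5)
  ct <- correlation_table(tab)
  m <- correlation_matrix(ct)
  expect_equal(diag(m), setNames(rep(1, 5), colnames(m)))
  expect_equal(m, t(m))
  expect_s3_class(ggplot2::autoplot(ct), "ggplot")
})

test_that("an exactly proportional column correlates perfectly", {
  tab <- plant_utr_table(100, 0.5, 0.2, seed = 6)
  tab$n_pred_A <- tab$utr3_length / 100
  ct <- correlation_table(tab)
  expect_equal(ct$r[ct$var1 == "utr3_length" & ct$var2 == "n_pred_A"], 1.0,
               tolerance = 1e-12)
})

test_that("pairs with too few complete rows are flagged not-computable", {
  tab <- plant_utr_table(10, 0.5, 0.2, seed = 7)
  tab$n_pred_A[3:10] <- NA
  ct <- correlation_table(tab)
  bad <- ct[ct$var1 == "utr3_length" & ct$var2 == "n_pred_A", ]
  expect_false(bad$computable)
  expect_true(is.na(bad$r))
  expect_error(correlation_table(tab[, 1:3]), "missing column")
})

test_that("chance k-mer spacing is 4^k with its companion expected count", {
  expect_identical(kmer_chance_spacing(6), 4096)
  expect_identical(kmer_chance_spacing(1), 4)
  expect_identical(kmer_chance_spacing(7), 16384)
  expect_error(kmer_chance_spacing(0), "1..15")
  expect_error(kmer_chance_spacing(16), "1..15")
  expect_equal(expected_kmer_count(4101, 6), 1.0)
  expect_error(expected_kmer_count(3, 6), ">= k")
})
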