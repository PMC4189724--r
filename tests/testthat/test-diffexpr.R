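test_that("reads-per-million normalization and zero revision", {
  expect_equal(normalize_rpm(50, 2e6), 25)
  expect_equal(normalize_rpm(0, 12345), 0.01)
  expect_equal(normalize_rpm(2e6, 2e6), 1e6)
  expect_error(normalize_rpm(-1, 100), "negative")
  expect_error(normalize_rpm(1, 0), "positive")
})

test_that("low-expression filter drops only all-library-low miRNAs", {
  m <- rbind(c(0.5, 0.8, 0.9),
             c(0.5, 1.0, 0.2),
             c(0.01, 0.01, 2.0))
  expect_identical(low_expression_filter(m), c(FALSE, TRUE, TRUE))
})

test_that("log2 fold change follows the printed rule and is antisymmetric", {
  expect_equal(log2_fold_change(40, 10), 2)
  expect_equal(log2_fold_change(7.3, 7.3), 0)
  # zero revised to 0.01 before the ratio
  expect_equal(log2_fold_change(normalize_rpm(10, 1e6),
                                normalize_rpm(0, 1e6)),
               log2(1000))
  withr::with_seed(3, {
    a <- runif(20, 0.01, 100); b <- runif(20, 0.01, 100)
    expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  })
  expect_error(log2_fold_change(0, 1), "positive")
})

test_that("Audic-Claverie point probability matches exact rational values", {
  expect_identical(audic_claverie_p(0, 0, 1e6, 1e6), 0.5)
  expect_identical(audic_claverie_p(5, 5, 1e6, 1e6), 252 / 2048)
  expect_equal(audic_claverie_p(10, 0, 1e6, 2e6), 1 / 3^11,
               tolerance = 1e-12)
  expect_error(audic_claverie_p(1.5, 2, 1e6, 1e6), "integer")
  expect_error(audic_claverie_p(-1, 2, 1e6, 1e6), "integer|nonneg")
})

test_that("equal-total limit equals the binomial form exactly (x+y <= 20)", {
  # independent oracle: Pascal's triangle, all-integer arithmetic
  pascal <- matrix(0, 21, 21)
  pascal[, 1] <- 1
  for (n in 2:21) {
    for (k in 2:n) pascal[n, k] <- pascal[n - 1, k - 1] + pascal[n - 1, k]
  }
  for (x in 0:20) for (y in 0:(20 - x)) {
    expected <- pascal[x + y + 1, y + 1] / 2^(x + y + 1)
    expect_identical(audic_claverie_p(x, y, 5e5, 5e5), expected)
  }
})

test_that("the kernel is normalized over y and tails obey the overlap identity", {
  for (r in c(0.5, 1, 2)) {
    for (x in c(0, 3, 25)) {
      ymax <- ceiling(r * (x + 30) + 200)
      total <- sum(audic_claverie_p(x, 0:ymax, 1e6, r * 1e6))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
  # brute-force both tails independently and check C + D = 1 + p(y|x)
  for (x in c(2, 5, 40)) for (y in c(0, 3, 17)) {
    tails <- cumulative_tails(x, y, 1e6, 1e6)
    C_bf <- sum(audic_claverie_p(x, 0:y, 1e6, 1e6))
    D_bf <- sum(audic_claverie_p(x, y:(y + 600), 1e6, 1e6))
    expect_equal(unname(tails["C"]), C_bf, tolerance = 1e-9)
    expect_equal(unname(tails["D"]), D_bf, tolerance = 1e-9)
    expect_equal(sum(tails), 1 + audic_claverie_p(x, y, 1e6, 1e6),
                 tolerance = 1e-9)
  }
})

test_that("lower tail matches the negative-binomial closed form", {
  for (r in c(0.5, 1, 2)) {
    n1 <- 1e6; n2 <- r * 1e6
    for (x in c(0, 7, 60)) for (y in c(0, 5, 90)) {
      tails <- cumulative_tails(x, y, n1, n2)
      expect_equal(unname(tails["C"]),
                   stats::pnbinom(y, size = x + 1, prob = n1 / (n1 + n2)),
                   tolerance = 1e-9)
    }
  }
})

test_that("tails stay accurate for extreme upper deviations", {
  tails <- cumulative_tails(2000, 3000, 97930, 97930)
  expect_gt(tails[["D"]], 0)
  expect_lt(tails[["D"]], 1e-30)
  expect_equal(tails[["C"]], 1, tolerance = 1e-9)
  # tail so deep it underflows entirely: must terminate, not hang
  tails <- cumulative_tails(2000, 8600, 97930, 97930)
  expect_identical(tails[["D"]], 0)
  expect_equal(tails[["C"]], 1, tolerance = 1e-9)
  # at the support edge the upper tail is the whole mass
  expect_equal(unname(cumulative_tails(5, 0, 1e6, 1e6)["D"]), 1,
               tolerance = 1e-12)
})

test_that("significance calls respect thresholds and direction", {
  expect_identical(significance_call(0, 1e-10), "unchanged")
  expect_identical(significance_call(1.5, 0.001), "up")
  expect_identical(significance_call(-1.5, 0.001), "down")
  expect_identical(significance_call(1.5, 0.5), "unchanged")
  # degenerate thresholds: everything with |fc| >= 0 and p <= 1 is called
  expect_identical(significance_call(0.2, 0.9, p_threshold = 1,
                                     fc_threshold = 0), "up")
})

test_that("diff_expression assembles per-comparison results", {
  counts <- data.frame(mirna = c("a", "b", "c"),
                       SD8 = c(100L, 10L, 0L),
                       C5 = c(400L, 10L, 0L),
                       LD3 = c(100L, 0L, 0L))
  totals <- c(SD8 = 1e5, C5 = 1e5, LD3 = 1e5)
  de <- diff_expression(counts, totals, control = "SD8")
  expect_equal(nrow(de), 6)
  a_c5 <- de[de$mirna == "a" & de$treatment == "C5", ]
  expect_equal(a_c5$fold_change, 2)
  expect_identical(a_c5$call, "up")
  # all-zero miRNA is filtered, not called
  expect_true(all(de$call[de$mirna == "c"] == "filtered"))
  expect_error(diff_expression(counts, totals, control = "XX"),
               "control")
})

test_that("delta-delta-Ct relative quantities", {
  expect_equal(ddct_relative_expression(20, 15, 22, 17), 1)
  expect_equal(ddct_relative_expression(22, 15, 20, 15), 0.25)
  expect_equal(ddct_relative_expression(17, 15, 20, 15), 8)
})
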