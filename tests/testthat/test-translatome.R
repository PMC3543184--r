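# Proportions, occupancy, bootstrap peak assignment, density.

test_that("mRNA proportions normalize to 1 and handle degenerate inputs", {
  p <- mrna_proportions(rep(1, 7))
  expect_equal(as.numeric(p), rep(1 / 7, 7))
  p2 <- mrna_proportions(c(0, 0, 5, 0, 0, 0, 0))
  expect_equal(unname(p2[["D"]]), 1)
  expect_equal(ribosome_occupancy(p2)$mean, 1)
  # negative values are clipped and counted; all-zero replicates are NA
  m <- rbind(c(-1, 1, 1, 1, 1, 1, 1), rep(0, 7))
  pm <- mrna_proportions(m)
  expect_equal(attr(pm, "n_clipped"), 1)
  expect_true(attr(pm, "undefined")[2])
  expect_true(all(is.na(pm[2, ])))
  expect_equal(sum(pm[1, ]), 1)
})

test_that("proportion vectors sum to 1 for arbitrary positive input", {
  set.seed(3)
  vals <- matrix(rlnorm(1e4 * 7), ncol = 7)
  pr <- mrna_proportions(vals)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  occ <- ribosome_occupancy(pr)$per_replicate
  expect_true(all(occ >= 0 & occ <= 1))
})

test_that("occupancy is the D-H sum averaged over replicates", {
  expect_equal(ribosome_occupancy(c(0.1, 0.2, 0.1, 0.1, 0.1, 0.2, 0.2))$mean,
               0.7)
  m <- rbind(c(0.2, 0.2, 0.6, 0, 0, 0, 0),
             c(0.15, 0.15, 0.7, 0, 0, 0, 0),
             c(0.1, 0.1, 0.8, 0, 0, 0, 0))
  o <- ribosome_occupancy(m)
  expect_equal(o$per_replicate, c(0.6, 0.7, 0.8))
  expect_equal(o$mean, 0.7)
})

test_that("degenerate bootstrap (zero residuals) returns the strict maximum", {
  m <- rbind(c(.1, .1, .1, .1, .1, .2, .3),
             c(.1, .1, .1, .1, .1, .2, .3))
  bp <- bootstrap_peak_fraction(m, n_boot = 100, seed = 1)
  expect_identical(bp$label, "H")
  expect_equal(bp$support, 1.0)
  expect_false(bp$widened)
  # exact tie with zero residuals: broken toward the lighter fraction, flagged
  m2 <- rbind(c(.1, .1, .2, .2, .1, .1, .2),
              c(.1, .1, .2, .2, .1, .1, .2))
  bp2 <- bootstrap_peak_fraction(m2, n_boot = 100, seed = 1)
  expect_identical(bp2$label, "D")
  expect_true(bp2$tied)
})

test_that("bootstrap assignment is deterministic under a fixed seed", {
  set.seed(42)
  m <- matrix(rlnorm(21), 3, 7)
  m <- m / rowSums(m)
  b1 <- bootstrap_peak_fraction(m, n_boot = 2000, seed = 7)
  b2 <- bootstrap_peak_fraction(m, n_boot = 2000, seed = 7)
  expect_identical(b1, b2)
})

test_that("clear peaks are assigned with high support across seeds", {
  # true peak D with residual SD far below the D-vs-E gap
  base <- c(0.17, 0.17, 0.30, 0.14, 0.09, 0.07, 0.06)
  ok <- vapply(1:50, function(s) {
    set.seed(s)
    m <- rbind(base + rnorm(7, 0, 0.004),
               base + rnorm(7, 0, 0.004),
               base + rnorm(7, 0, 0.004))
    bp <- bootstrap_peak_fraction(m, n_boot = 2000, seed = s)
    identical(bp$label, "D") && bp$support >= 0.95
  }, logical(1))
  expect_true(all(ok))
})

test_that("near-ties trigger widening to adjacent fractions", {
  # G and H nearly tied, large residuals: no single fraction reaches 95%
  m <- rbind(c(0.10, 0.10, 0.05, 0.05, 0.10, 0.280, 0.320),
             c(0.10, 0.10, 0.05, 0.05, 0.10, 0.320, 0.280),
             c(0.10, 0.10, 0.05, 0.05, 0.10, 0.295, 0.305))
  bp <- bootstrap_peak_fraction(m, n_boot = 4000, seed = 3)
  expect_true(bp$widened)
  expect_identical(bp$label, "G+H")
  expect_gte(bp$support, 0.95)
})

test_that("bootstrap modal frequencies match exhaustive enumeration", {
  # 2-replicate fixtures with binary-fraction values so the enumeration is
  # exact in floating point; pools have <= 6 distinct residual values
  fixtures <- list(
    rbind(c(4, 4, 6, 5, 8, 10, 12), c(4, 4, 8, 7, 8, 12, 10)) / 64,
    rbind(c(8, 8, 10, 9, 9, 11, 12), c(8, 8, 9, 10, 10, 12, 11)) / 64
  )
  for (m in fixtures) {
    exact <- enum_argmax_freq(m)
    n_boot <- 10000
    set.seed(11)
    bp_freq <- translatomics:::boot_argmax_freq(m, 3:7, n_boot)
    se <- sqrt(pmax(exact * (1 - exact), 1e-6) / n_boot)
    expect_true(all(abs(bp_freq - exact) <= 2 * se + 1e-8))
    expect_equal(sum(exact), 1, tolerance = 1e-12)
  }
})

test_that("density uses the peak fraction's representative ribosome number", {
  ribs <- c(D = 1, E = 2.1, F = 4.2, G = 7.5, H = 10)
  expect_equal(ribosome_density("H", ribs, 1000), 1.0)
  expect_equal(ribosome_density("H", c(H = 14), 1000), 1.4)
  d <- ribosome_density("D", ribs, 30)
  expect_equal(d, 100 / 30, tolerance = 1e-12)
  expect_true(is.na(ribosome_density("G+H", ribs, 1000)))
})

test_that("the 3.33 filter excludes strictly greater densities only", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    density = c(3.5, 100 / 30, 1.2, NA),
                    peak_widened = c(FALSE, FALSE, FALSE, TRUE))
  out <- filter_max_density(rec)
  expect_identical(out$density_exceeds_max, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(attr(out, "modeling_genes"), c("b", "c"))
  # generator bookkeeping: constructed above-threshold genes are exactly flagged
  set.seed(2)
  n <- 50
  lens <- ifelse(seq_len(n) <= 5, 20, 2000)   # 10% constructed above 3.33
  rec2 <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                     density = 1 * 100 / lens,
                     peak_widened = FALSE)
  out2 <- filter_max_density(rec2)
  expect_identical(which(out2$density_exceeds_max), 1:5)
})

test_that("theoretical maximal density derives from the footprint", {
  expect_equal(theoretical_max_density(), 100 / 30)
  expect_equal(theoretical_max_density(25), 4)
})
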