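# Cutoff filtering and the three normalization stages.

make_series <- function(intens, empty_mean = 100, empty_sd = 20,
                        rna = NULL) {
  n <- dim(intens)[1]
  K <- dim(intens)[3]
  dimnames(intens) <- list(sprintf("g%02d", seq_len(n)), LETTERS[1:8],
                           paste0("R", seq_len(K)))
  if (is.null(rna)) {
    rna <- matrix(100, 8, K, dimnames = list(LETTERS[1:8], NULL))
  }
  array_series(intens,
               data.frame(array = LETTERS[1:8], mean = empty_mean,
                          sd = empty_sd),
               rna, dimnames(intens)[[1]])
}

test_that("cutoff keeps genes above empty mean + 1 SD on at least one array", {
  # gene 1: 110 everywhere (below 120) -> excluded;
  # gene 2: 121 on array C only -> kept
  intens <- array(110, dim = c(2, 8, 3))
  intens[2, , ] <- 50
  intens[2, 3, ] <- 121
  ser <- make_series(intens, empty_mean = 100, empty_sd = 20)
  kept <- apply_cutoff(ser)
  expect_identical(as.character(kept), "g02")
  expect_equal(unname(attr(kept, "cutoffs")["C"]), 120)
})

test_that("reference normalization divides by the replicate's array-A mean", {
  intens <- array(1, dim = c(3, 8, 2))
  intens[, 1, 1] <- c(1, 2, 3)          # array A mean 2 in replicate 1
  intens[, 2, 1] <- 4                    # array B
  intens[, 1, 2] <- c(2, 4, 6)          # array A mean 4 in replicate 2
  intens[, 2, 2] <- 4
  ser <- make_series(intens, empty_mean = 0, empty_sd = 0)
  nv <- normalize_to_reference(ser, ser$gene_ids)
  expect_equal(unname(nv[, "B", 1]), rep(2, 3))
  expect_equal(unname(nv[, "B", 2]), rep(1, 3))
})

test_that("reference normalization is invariant to per-replicate rescaling", {
  set.seed(4)
  intens <- array(rlnorm(5 * 8 * 3, 3, 0.4), dim = c(5, 8, 3))
  ser <- make_series(intens, empty_mean = 0, empty_sd = 0)
  nv1 <- normalize_to_reference(ser, ser$gene_ids)
  intens2 <- intens
  intens2[, , 2] <- intens2[, , 2] * 17.3   # uniform rescale of replicate 2
  ser2 <- make_series(intens2, empty_mean = 0, empty_sd = 0)
  nv2 <- normalize_to_reference(ser2, ser2$gene_ids)
  expect_equal(nv1, nv2, tolerance = 1e-12)
  # array B identical to A: normalized B has mean 1 over kept genes
  intens3 <- intens
  intens3[, 2, ] <- intens3[, 1, ]
  ser3 <- make_series(intens3, empty_mean = 0, empty_sd = 0)
  nv3 <- normalize_to_reference(ser3, ser3$gene_ids)
  expect_equal(unname(colMeans(nv3[, "B", ])), rep(1, 3), tolerance = 1e-12)
})

test_that("RNA-quantity correction rescales to concentration units", {
  nv <- array(2, dim = c(2, 7, 1),
              dimnames = list(c("g1", "g2"), LETTERS[2:8], "R1"))
  rna <- matrix(c(20, 10, rep(20, 6)), 8, 1,
                dimnames = list(LETTERS[1:8], NULL))
  out <- correct_rna_quantity(nv, rna)
  expect_equal(unname(out[1, "B", 1]), 1.0)    # 2 * (10/20)
  expect_equal(unname(out[1, "C", 1]), 2.0)    # RNA_C = RNA_A -> identity
  rna_bad <- rna; rna_bad["A", 1] <- 0
  expect_error(correct_rna_quantity(nv, rna_bad), "positive")
})

test_that("inter-series regression inverts an exact affine distortion", {
  set.seed(9)
  base <- rlnorm(40, 0, 0.5)
  # choose replicate 2 so that rep2 = 2 * replicate_mean + 1 exactly
  r1 <- base; r3 <- base * 1.0
  r2 <- 2 * (r1 + r3) + 3
  nv <- array(0, dim = c(40, 7, 3),
              dimnames = list(sprintf("g%02d", 1:40), LETTERS[2:8],
                              paste0("R", 1:3)))
  for (j in 1:7) { nv[, j, 1] <- r1; nv[, j, 2] <- r2; nv[, j, 3] <- r3 }
  cr <- center_reduce_interseries(nv)
  p2 <- cr$fit_params[cr$fit_params$replicate == 2, ]
  expect_equal(p2$r_hat, rep(2, 7), tolerance = 1e-9)
  expect_equal(p2$b_hat, rep(1, 7), tolerance = 1e-9)
  rep_mean <- (r1 + r2 + r3) / 3
  expect_equal(unname(cr$ncr[, 1, 2]), rep_mean, tolerance = 1e-9)

  # identical replicates: identity correction
  nv2 <- nv
  for (k in 1:3) nv2[, , k] <- nv[, , 1]
  cr2 <- center_reduce_interseries(nv2)
  expect_equal(cr2$fit_params$r_hat, rep(1, 21), tolerance = 1e-9)
  expect_equal(cr2$fit_params$b_hat, rep(0, 21), tolerance = 1e-9)
  expect_equal(cr2$ncr, nv2, tolerance = 1e-9)
})

test_that("random affine distortions are removed exactly at zero noise", {
  set.seed(12)
  n_true <- matrix(rlnorm(30 * 7, 0, 0.6), 30, 7)
  nv <- array(0, dim = c(30, 7, 3),
              dimnames = list(sprintf("g%02d", 1:30), LETTERS[2:8],
                              paste0("R", 1:3)))
  for (j in 1:7) for (k in 1:3) {
    r <- runif(1, 0.5, 2); b <- runif(1, -0.2, 0.5)
    nv[, j, k] <- r * n_true[, j] + b
  }
  cr <- center_reduce_interseries(nv)
  # corrected replicates agree with each other (affine family collapses to
  # the common profile r_bar * n_true + b_bar per fraction)
  for (j in 1:7) {
    expect_lt(max(abs(cr$ncr[, j, 1] - cr$ncr[, j, 2])), 1e-9)
    expect_lt(max(abs(cr$ncr[, j, 1] - cr$ncr[, j, 3])), 1e-9)
  }
  # post-correction invariant: slope 1, intercept 0 against replicate mean
  for (j in 1:7) for (k in 1:3) {
    nbar <- rowMeans(cr$ncr[, j, ])
    cf <- coef(lm(cr$ncr[, j, k] ~ nbar))
    expect_equal(unname(cf), c(0, 1), tolerance = 1e-8)
  }
  expect_error(center_reduce_interseries(nv[, , 1, drop = FALSE]),
               ">= 2 replicates")
})

test_that("RNA-quantity correction is required for proportion recovery", {
  cfg <- synthetic_config(n_genes = 40, seed = 6, noise_cv = 0,
                          loss_mean = 1, loss_sd = 0,
                          distortion_r_range = c(1, 1),
                          distortion_b_range = c(0, 0))
  truth <- generate_gene_truth(cfg)
  series <- synthesize_arrays(truth, cfg)
  kept <- apply_cutoff(series)
  n_ref <- normalize_to_reference(series, kept)
  with_rna <- correct_rna_quantity(n_ref, series$rna_quantity)
  props_with <- t(apply(with_rna[, , 1], 1, function(v) v / sum(v)))
  props_without <- t(apply(n_ref[, , 1], 1, function(v) v / sum(v)))
  true_props <- attr(truth, "true_proportions")[as.character(kept), ]
  expect_equal(unname(props_with), unname(true_props), tolerance = 1e-9)
  expect_gt(max(abs(props_without - true_props)), 0.01)
})
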