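#' Construct an array series container
#'
#' Bundles the gene x array x replicate intensity tensor with the empty-spot
#' background statistics and the per-fraction total RNA quantities that the
#' normalization stages need. Spot duplicates are assumed already averaged;
#' intensities are post-background and nonnegative.
#'
#' @param intensities Numeric array `genes x 8 x replicates` with array
#'   dimnames `A`..`H` (A = unfractionated reference).
#' @param empty_stats Data frame with columns `array`, `mean`, `sd`: empty-spot
#'   statistics per array A..H.
#' @param rna_quantity Numeric matrix `8 x replicates` (rownames A..H) of
#'   total RNA quantities in micrograms.
#' @param gene_ids Character vector of gene identifiers.
#' @return An `array_series` object.
#' @export
array_series <- function(intensities, empty_stats, rna_quantity, gene_ids) {
  stopifnot(length(dim(intensities)) == 3)
  if (!identical(dimnames(intensities)[[2]], ARRAYS_ALL)) {
    stop("intensities must have arrays A..H in the second dimension",
         call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be nonnegative (post-background)", call. = FALSE)
  }
  if (!all(c("array", "mean", "sd") %in% names(empty_stats)) ||
      !setequal(empty_stats$array, ARRAYS_ALL)) {
    stop("empty_stats must give mean and sd for each array A..H",
         call. = FALSE)
  }
  if (!identical(rownames(rna_quantity), ARRAYS_ALL) ||
      any(rna_quantity <= 0)) {
    stop("rna_quantity must be a positive matrix with rows A..H",
         call. = FALSE)
  }
  stopifnot(length(gene_ids) == dim(intensities)[1],
            ncol(rna_quantity) == dim(intensities)[3])
  structure(list(intensities = intensities,
                 empty_stats = empty_stats[match(ARRAYS_ALL, empty_stats$array), ],
                 rna_quantity = rna_quantity,
                 gene_ids = gene_ids),
            class = "array_series")
}

#' @export
print.array_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("array_series: %d genes x %d arrays (A..H) x %d replicates\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate replicate microarray series from ground truth
#'
#' Forward model for the fraction-resolved intensities. For replicate `k`,
#' fraction array `j` in B..H, and gene `i` with unfractionated abundance
#' `m_i` and true fraction proportion `p_ij`:
#'
#' \deqn{I_{ijk} = s_k \frac{p_{ij} m_i L_{jk}}{RNA_{jk}} (r_{jk} x + b_{jk})
#'   \epsilon_{ijk}}
#'
#' where `L_jk` is the mRNA recovery after fractionation (drawn once per
#' fraction and replicate, constant across genes), `RNA_jk` the total RNA
#' quantity of the fraction (equal RNA amounts are hybridized, so spot signal
#' reflects the gene's share per microgram), `s_k` a detector scale,
#' `(r, b)` the per-array affine distortion, and `eps` multiplicative
#' log-normal noise with the configured CV. The reference array A measures
#' `m_i` relative to the unfractionated RNA quantity. Genes constructed as
#' unexpressed are rescaled below the empty-spot cutoff on every array;
#' expressed genes are guaranteed above it on at least one array.
#'
#' @param truth A [generate_gene_truth()] result.
#' @param config The matching [synthetic_config()].
#' @return An [array_series()] with extra attributes recording the simulation
#'   internals (`loss`, `distortion`, `recovered_ratio` = per-gene recovered /
#'   unfractionated mRNA).
#' @export
synthesize_arrays <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "synthetic_config"))
  if (nrow(truth) != config$n_genes) {
    stop("truth and config disagree on n_genes", call. = FALSE)
  }
  with_seed(config$seed + 1L, synthesize_arrays_impl(truth, config))
}

synthesize_arrays_impl <- function(truth, config) {
  n <- config$n_genes
  K <- config$n_replicates
  props <- attr(truth, "true_proportions")         # n x 7, B..H

  empty_stats <- data.frame(
    array = ARRAYS_ALL,
    mean = config$empty_mean * stats::runif(8, 0.9, 1.1),
    sd = config$empty_sd * stats::runif(8, 0.9, 1.1),
    stringsAsFactors = FALSE
  )
  cutoffs <- empty_stats$mean + empty_stats$sd

  abundance <- stats::rlnorm(n, config$abundance_meanlog,
                             config$abundance_sdlog)

  # Per-(fraction, replicate) mRNA recovery, constant across genes.
  loss <- matrix(rtruncnorm(7 * K, config$loss_mean, config$loss_sd,
                            lo = 1e-3, hi = 1),
                 nrow = 7, ncol = K, dimnames = list(ARRAYS_FRAC, NULL))

  # Total RNA per fraction (all species, dominated by rRNA) and for the
  # unfractionated aliquot.
  rna <- matrix(stats::runif(8 * K, config$fraction_rna_range[1],
                             config$fraction_rna_range[2]),
                nrow = 8, ncol = K, dimnames = list(ARRAYS_ALL, NULL))
  rna["A", ] <- stats::runif(K, 80, 120)

  # Affine per-(array, replicate) distortions; the reference array gets one
  # too (the pipeline never needs to undo it).
  r_dist <- matrix(stats::runif(8 * K, config$distortion_r_range[1],
                                config$distortion_r_range[2]),
                   8, K, dimnames = list(ARRAYS_ALL, NULL))
  b_dist <- matrix(stats::runif(8 * K, config$distortion_b_range[1],
                                config$distortion_b_range[2]),
                   8, K, dimnames = list(ARRAYS_ALL, NULL))

  detector <- stats::runif(K, 800, 1200)           # per-replicate scale

  # Expression floor: expressed genes are guaranteed detectable on the
  # reference array by raising abundance (not by rescaling observed
  # intensities, which would break the affine structure the inter-series
  # normalization inverts).
  floor_a <- max(3 * cutoffs[1] * rna["A", ] /
                   (detector * r_dist["A", ]))
  abundance[truth$expressed] <- pmax(abundance[truth$expressed], floor_a)

  sdlog <- sqrt(log1p(config$noise_cv^2))          # log-normal with given CV
  noise <- function(n) {
    if (sdlog == 0) rep(1, n) else stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }

  intens <- array(0, dim = c(n, 8, K),
                  dimnames = list(truth$gene_id, ARRAYS_ALL,
                                  paste0("R", seq_len(K))))
  for (k in seq_len(K)) {
    base_a <- abundance / rna["A", k] * detector[k]
    intens[, "A", k] <- (r_dist["A", k] * base_a + b_dist["A", k]) * noise(n)
    for (j in ARRAYS_FRAC) {
      base <- props[, j] * abundance * loss[j, k] / rna[j, k] * detector[k]
      intens[, j, k] <- (r_dist[j, k] * base + b_dist[j, k]) * noise(n)
    }
  }

  # Unexpressed genes are rescaled below every cutoff. They are excluded by
  # the cutoff filter, so distorting their affine structure is harmless.
  rep_mean <- apply(intens, c(1, 2), mean)         # n x 8
  for (i in which(!truth$expressed)) {
    f <- 0.5 * min(cutoffs / rep_mean[i, ])
    intens[i, , ] <- intens[i, , ] * f
  }

  # Bookkeeping: realized recovered/unfractionated mRNA ratio per gene,
  # averaged over replicates (loss is gene-independent so this is the
  # proportion-weighted mean recovery).
  recovered <- sapply(seq_len(K), function(k) as.numeric(props %*% loss[, k]))
  recovered_ratio <- rowMeans(recovered)

  out <- array_series(intens, empty_stats, rna, truth$gene_id)
  attr(out, "loss") <- loss
  attr(out, "distortion") <- list(r = r_dist, b = b_dist)
  attr(out, "recovered_ratio") <- recovered_ratio
  attr(out, "config") <- config
  out
}
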