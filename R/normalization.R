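#' Empty-spot cutoff filter
#'
#' For each array A..H the cutoff is the mean empty-spot intensity plus one
#' standard deviation. A gene is kept when its across-replicate mean
#' intensity exceeds the cutoff on at least one of the eight arrays.
#'
#' @param series An [array_series()].
#' @return Character vector of kept gene ids, with attribute `cutoffs`
#'   (named per-array cutoff values).
#' @export
apply_cutoff <- function(series) {
  stopifnot(inherits(series, "array_series"))
  es <- series$empty_stats
  if (anyNA(es$mean) || anyNA(es$sd)) {
    stop("empty-spot statistics missing for some arrays", call. = FALSE)
  }
  cutoffs <- stats::setNames(es$mean + es$sd, es$array)
  rep_mean <- apply(series$intensities, c(1, 2), mean)
  keep <- rowSums(rep_mean > rep(cutoffs[ARRAYS_ALL],
                                 each = nrow(rep_mean))) > 0
  structure(series$gene_ids[keep], cutoffs = cutoffs)
}

#' Standardize fraction arrays by the unfractionated reference
#'
#' Each intensity on arrays B..H is divided by the mean intensity of the
#' reference array A over the kept genes of the same replicate (equivalently,
#' multiplied by the kept-gene count and divided by the summed A
#' intensities). This removes per-replicate detector scale so replicate
#' series become comparable.
#'
#' @param series An [array_series()].
#' @param kept_genes Gene ids retained by [apply_cutoff()].
#' @return Numeric array `kept genes x 7 (B..H) x replicates`.
#' @export
normalize_to_reference <- function(series, kept_genes) {
  stopifnot(inherits(series, "array_series"))
  idx <- match(kept_genes, series$gene_ids)
  if (anyNA(idx)) stop("kept_genes not all present in series", call. = FALSE)
  K <- dim(series$intensities)[3]
  out <- series$intensities[idx, ARRAYS_FRAC, , drop = FALSE]
  for (k in seq_len(K)) {
    ref <- mean(series$intensities[idx, "A", k])
    if (ref <= 0) stop("reference array A has nonpositive mean intensity",
                       call. = FALSE)
    out[, , k] <- out[, , k] / ref
  }
  out
}

#' Convert to fraction-level concentration scale
#'
#' Equal RNA amounts are hybridized per array, so spot signal measures a
#' gene's share per microgram of fraction RNA. Multiplying by the ratio of
#' the fraction's total RNA quantity to that of the unfractionated reference
#' restores abundance proportionality across fractions.
#'
#' @param n_values Output of [normalize_to_reference()].
#' @param rna_quantity Matrix `8 x replicates`, rownames A..H, micrograms.
#' @return Array of the same shape as `n_values`.
#' @export
correct_rna_quantity <- function(n_values, rna_quantity) {
  stopifnot(identical(rownames(rna_quantity), ARRAYS_ALL))
  K <- dim(n_values)[3]
  if (any(rna_quantity["A", ] <= 0)) {
    stop("unfractionated RNA quantity must be positive", call. = FALSE)
  }
  for (k in seq_len(K)) {
    ratio <- rna_quantity[ARRAYS_FRAC, k] / rna_quantity["A", k]
    n_values[, , k] <- sweep(n_values[, , k], 2, ratio, `*`)
  }
  n_values
}

#' Inter-series centering and reduction
#'
#' For each fraction array and replicate, the replicate's values are
#' regressed on the across-replicate mean profile by ordinary least squares;
#' the fitted intercept and slope `(b_hat, r_hat)` are then used to correct
#' the replicate as `(N - b_hat) / r_hat`. By construction, regressing the
#' corrected values back on the replicate mean gives slope 1 and intercept 0.
#'
#' @param n_values Array `genes x 7 x replicates` (needs >= 2 replicates).
#' @return List with `ncr` (corrected array, same shape) and `fit_params`
#'   (data frame: array, replicate, r_hat, b_hat).
#' @export
center_reduce_interseries <- function(n_values) {
  K <- dim(n_values)[3]
  if (K < 2) stop("inter-series normalization needs >= 2 replicates",
                  call. = FALSE)
  ncr <- n_values
  params <- expand.grid(array = ARRAYS_FRAC, replicate = seq_len(K),
                        stringsAsFactors = FALSE)
  params$r_hat <- NA_real_
  params$b_hat <- NA_real_
  for (j in ARRAYS_FRAC) {
    nbar <- rowMeans(n_values[, j, , drop = FALSE], dims = 1)
    for (k in seq_len(K)) {
      fit <- stats::lm.fit(cbind(1, nbar), n_values[, j, k])
      b_hat <- fit$coefficients[1]
      r_hat <- fit$coefficients[2]
      if (!is.finite(r_hat) || abs(r_hat) < 1e-12) {
        stop(sprintf("degenerate inter-series regression for array %s, replicate %d",
                     j, k), call. = FALSE)
      }
      ncr[, j, k] <- (n_values[, j, k] - b_hat) / r_hat
      row <- params$array == j & params$replicate == k
      params$r_hat[row] <- r_hat
      params$b_hat[row] <- b_hat
    }
  }
  list(ncr = ncr, fit_params = params)
}

#' Run the full normalization stack
#'
#' Applies the empty-spot cutoff, reference-array standardization, total-RNA
#' correction and inter-series centering/reduction in order.
#'
#' @param series An [array_series()].
#' @return A `normalized_series` list: `n_values` (post reference and RNA
#'   correction), `ncr_values`, `fit_params`, `kept_genes`, `cutoffs`.
#' @export
normalize_series <- function(series) {
  kept <- apply_cutoff(series)
  n_ref <- normalize_to_reference(series, kept)
  n_vals <- correct_rna_quantity(n_ref, series$rna_quantity)
  cr <- center_reduce_interseries(n_vals)
  structure(list(n_values = n_vals,
                 ncr_values = cr$ncr,
                 fit_params = cr$fit_params,
                 kept_genes = as.character(kept),
                 cutoffs = attr(kept, "cutoffs")),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("normalized_series: %d kept genes x 7 arrays (B..H) x %d replicates\n",
              length(x$kept_genes), dim(x$ncr_values)[3]))
  invisible(x)
}
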