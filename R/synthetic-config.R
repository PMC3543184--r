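#' Configuration for the synthetic translatome generator
#'
#' Collects every knob of the forward model that turns latent per-gene truth
#' (occupancy, peak fraction, sequence features) into the raw inputs the
#' pipeline consumes: three replicate series of eight arrays (A =
#' unfractionated reference, B--H = pooled sucrose-gradient fractions),
#' per-fraction total RNA quantities, empty-spot background statistics, and a
#' polysome absorbance profile.
#'
#' Defaults encode the study conditions the generator emulates: mRNA recovery
#' after fractionation of 60 +/- 16 percent (constant across genes within a
#' fraction/replicate), per-fraction total RNA between roughly 30 and 440
#' micrograms, ribosome occupancy distributed around 0.66 with SD 0.06, and a
#' two-class peak-fraction mixture (monosome fraction D vs the heaviest
#' polysome fraction H, weights 0.17/0.83).
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_replicates Number of replicate series (default 3).
#' @param seed Integer seed; together with the other fields it fully
#'   determines every generated object.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise applied to every spot.
#' @param loss_mean,loss_sd Mean and SD of the per-(fraction, replicate) mRNA
#'   recovery after polysome separation, truncated to (0, 1].
#' @param fraction_rna_range Interval (micrograms) from which per-fraction
#'   total RNA quantities are drawn.
#' @param distortion_r_range,distortion_b_range Intervals for the
#'   per-(array, replicate) affine intensity distortion `r * x + b` that the
#'   inter-series normalization is expected to remove.
#' @param occupancy_mean,occupancy_sd Location and spread of true ribosome
#'   occupancy (fraction of a gene's mRNA in ribosome-bearing fractions D--H).
#' @param peak_weights Named weights over fractions D--H for the true peak
#'   fraction; the default two-class mixture puts 17 percent of genes in the
#'   monosome class D and 83 percent in the heaviest class H.
#' @param kernel_decay Geometric decay (per fraction of distance from the
#'   peak) of the within-gene mRNA distribution over D--H; the engaged mass
#'   `occupancy` is spread as `kernel_decay^distance`, and the non-engaged
#'   mass `1 - occupancy` is split equally between fractions B and C.
#' @param cds_meanlog,cds_sdlog Log-normal parameters of coding-sequence
#'   length in nucleotides.
#' @param fraction_ribosomes Named vector D--H of representative ribosome
#'   numbers per fraction used for true density; defaults are the rounded
#'   midpoints of the calibrated per-fraction ribosome ranges (D is exactly 1).
#' @param engaged_fraction Target share of the absorbance area in elution
#'   fractions 4--11 relative to 2--11 for synthetic profiles (default 0.61).
#' @param prop_below_cutoff Share of genes constructed to fall below the
#'   empty-spot cutoff on every array (not expressed at detectable level).
#' @param empty_mean,empty_sd Mean and SD of empty-spot intensities.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of
#'   unfractionated per-gene mRNA abundance (arbitrary intensity units).
#' @param ancova_coefficients Named list of true standardized effects of the
#'   quantitative gene/mRNA/protein features on log ribosome occupancy; names
#'   must be a subset of the generated feature columns.
#' @param category_levels,category_probs Functional-category vocabulary and
#'   sampling weights.
#' @param category_effects Named standardized deviations of log occupancy for
#'   specific category levels (others 0).
#' @param ancova_noise_sd Residual SD of the standardized log-occupancy
#'   linear model. `NULL` (default) chooses the value that makes the total
#'   variance of the standardized response 1, so fitted standardized
#'   coefficients estimate the configured effects directly.
#' @param missing_halflife_prop Share of genes with missing mRNA half-life,
#'   emulating incomplete feature tables.
#' @param protein_detect_prop Share of expressed genes with a measured
#'   protein level.
#' @param protein_coefficients Named standardized effects for the latent
#'   protein-level model (may reference `occupancy`).
#' @param protein_noise_sd Residual SD of the standardized log protein level;
#'   `NULL` totals the variance to 1 as for `ancova_noise_sd`.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_gene_truth()], [synthesize_arrays()],
#'   [synthesize_profile()]
#' @export
#' @examples
#' cfg <- synthetic_config(n_genes = 50, seed = 1)
#' cfg$loss_mean
synthetic_config <- function(n_genes,
                             n_replicates = 3,
                             seed = 1,
                             noise_cv = 0.05,
                             loss_mean = 0.60,
                             loss_sd = 0.16,
                             fraction_rna_range = c(29.7, 436.3),
                             distortion_r_range = c(0.8, 1.25),
                             distortion_b_range = c(0, 30),
                             occupancy_mean = 0.66,
                             occupancy_sd = 0.06,
                             peak_weights = c(D = 0.17, H = 0.83),
                             kernel_decay = 0.55,
                             cds_meanlog = log(900),
                             cds_sdlog = 0.6,
                             fraction_ribosomes = c(D = 1, E = 2.1, F = 4.2,
                                                    G = 7.5, H = 13.8),
                             engaged_fraction = 0.61,
                             prop_below_cutoff = 0,
                             empty_mean = 30,
                             empty_sd = 10,
                             abundance_meanlog = log(2000),
                             abundance_sdlog = 0.8,
                             ancova_coefficients = list(
                               mrna_conc = 0.12, half_life = -0.38,
                               cds_length = 0.24, cai = 0.16,
                               dg_up = 0.15, dg_down = 0.12),
                             category_levels = c("AMI", "COF", "INT", "MET",
                                                 "REG", "TRS"),
                             category_probs = c(0.12, 0.06, 0.03, 0.60,
                                                0.07, 0.12),
                             category_effects = c(INT = 0.68, REG = 0.62,
                                                  TRS = -0.23),
                             ancova_noise_sd = NULL,
                             missing_halflife_prop = 0,
                             protein_detect_prop = 0.18,
                             protein_coefficients = list(
                               mrna_conc = 0.25, cai = 0.54,
                               occupancy = 0.23),
                             protein_noise_sd = NULL) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 10) {
    stop_field("n_genes", "must be a single number >= 10")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop_field("n_replicates", "must be a positive count")
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_field("seed", "must be a single finite integer")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop_field("noise_cv", "must be >= 0")
  }
  if (!is.numeric(loss_mean) || loss_mean <= 0 || loss_mean > 1) {
    stop_field("loss_mean", "must lie in (0, 1]")
  }
  if (!is.numeric(loss_sd) || loss_sd < 0) {
    stop_field("loss_sd", "must be >= 0")
  }
  if (length(fraction_rna_range) != 2 || any(fraction_rna_range <= 0) ||
      diff(fraction_rna_range) < 0) {
    stop_field("fraction_rna_range", "must be a positive increasing interval")
  }
  if (length(distortion_r_range) != 2 || any(distortion_r_range <= 0)) {
    stop_field("distortion_r_range", "must be a positive interval")
  }
  if (occupancy_mean <= 0 || occupancy_mean > 1) {
    stop_field("occupancy_mean", "must lie in (0, 1]")
  }
  if (is.null(names(peak_weights)) ||
      !all(names(peak_weights) %in% FRACTIONS_ENGAGED)) {
    stop_field("peak_weights", "must be named with fractions among D..H")
  }
  if (any(peak_weights < 0) || sum(peak_weights) <= 0) {
    stop_field("peak_weights", "must be nonnegative with positive sum")
  }
  if (kernel_decay <= 0 || kernel_decay >= 1) {
    stop_field("kernel_decay", "must lie in (0, 1)")
  }
  if (!identical(sort(names(fraction_ribosomes)), sort(FRACTIONS_ENGAGED)) ||
      any(fraction_ribosomes <= 0)) {
    stop_field("fraction_ribosomes", "must be positive and named D..H")
  }
  if (engaged_fraction <= 0 || engaged_fraction >= 1) {
    stop_field("engaged_fraction", "must lie in (0, 1)")
  }
  if (prop_below_cutoff < 0 || prop_below_cutoff >= 1) {
    stop_field("prop_below_cutoff", "must lie in [0, 1)")
  }
  if (length(category_levels) != length(category_probs) ||
      any(category_probs < 0)) {
    stop_field("category_probs", "must match category_levels and be >= 0")
  }
  if (!all(names(category_effects) %in% category_levels)) {
    stop_field("category_effects", "names must be category levels")
  }

  cfg <- list(
    n_genes = as.integer(n_genes),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    noise_cv = noise_cv,
    loss_mean = loss_mean,
    loss_sd = loss_sd,
    fraction_rna_range = fraction_rna_range,
    distortion_r_range = distortion_r_range,
    distortion_b_range = distortion_b_range,
    occupancy_mean = occupancy_mean,
    occupancy_sd = occupancy_sd,
    peak_weights = peak_weights / sum(peak_weights),
    kernel_decay = kernel_decay,
    cds_meanlog = cds_meanlog,
    cds_sdlog = cds_sdlog,
    fraction_ribosomes = fraction_ribosomes[FRACTIONS_ENGAGED],
    engaged_fraction = engaged_fraction,
    prop_below_cutoff = prop_below_cutoff,
    empty_mean = empty_mean,
    empty_sd = empty_sd,
    abundance_meanlog = abundance_meanlog,
    abundance_sdlog = abundance_sdlog,
    ancova_coefficients = ancova_coefficients,
    category_levels = category_levels,
    category_probs = category_probs / sum(category_probs),
    category_effects = category_effects,
    ancova_noise_sd = ancova_noise_sd,
    missing_halflife_prop = missing_halflife_prop,
    protein_detect_prop = protein_detect_prop,
    protein_coefficients = protein_coefficients,
    protein_noise_sd = protein_noise_sd
  )

  # Residual SDs default so the standardized linear predictor has unit total
  # variance; effects are then directly comparable to fitted standardized
  # coefficients.
  if (is.null(cfg$ancova_noise_sd)) {
    cfg$ancova_noise_sd <- residual_sd_for_unit_variance(
      unlist(ancova_coefficients), category_effects, cfg$category_probs,
      category_levels)
  }
  if (is.null(cfg$protein_noise_sd)) {
    cfg$protein_noise_sd <- residual_sd_for_unit_variance(
      unlist(protein_coefficients), numeric(0), cfg$category_probs,
      category_levels)
  }
  structure(cfg, class = "synthetic_config")
}

# Residual SD that tops the variance of (sum of standardized effects +
# category deviations + noise) up to 1; 0 if the systematic part already
# exceeds 1.
residual_sd_for_unit_variance <- function(beta, cat_effects, cat_probs,
                                          cat_levels) {
  v <- sum(beta^2)
  if (length(cat_effects)) {
    lambda <- stats::setNames(rep(0, length(cat_levels)), cat_levels)
    lambda[names(cat_effects)] <- cat_effects
    mu <- sum(cat_probs * lambda)
    v <- v + sum(cat_probs * (lambda - mu)^2)
  }
  sqrt(max(0, 1 - v))
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic_config: %d genes x %d replicates (seed %d)\n",
    x$n_genes, x$n_replicates, x$seed))
  cat(sprintf("  noise_cv %.3g, recovery %.2f +/- %.2f, occupancy %.2f +/- %.2f\n",
              x$noise_cv, x$loss_mean, x$loss_sd,
              x$occupancy_mean, x$occupancy_sd))
  cat(sprintf("  peak classes: %s\n",
              paste(sprintf("%s=%.2f", names(x$peak_weights), x$peak_weights),
                    collapse = " ")))
  invisible(x)
}
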