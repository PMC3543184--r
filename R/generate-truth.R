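#' Generate latent per-gene ground truth
#'
#' Draws, for every gene, its true ribosome occupancy, peak fraction, mRNA
#' distribution over the pooled fractions B--H, coding-sequence length,
#' ribosome density, and the gene/mRNA/protein feature table used by the
#' covariance models. All downstream synthetic inputs are deterministic
#' functions of this object and the configuration.
#'
#' Occupancy is drawn so that its marginal distribution is approximately
#' Gaussian with the configured mean and SD (truncated to (0, 1]), while its
#' log is linearly driven by the standardized features with the configured
#' standardized effects, so the covariance-model stage can recover them.
#' Peak fractions come from the configured mixture over D--H. The within-gene
#' mRNA distribution places `1 - occupancy` equally in the non-engaged
#' fractions B and C and spreads `occupancy` over D--H with a geometric
#' kernel centred on the peak fraction.
#'
#' @param config A [synthetic_config()].
#' @return A `ground_truth` data frame with one row per gene (gene_id,
#'   true_occupancy, true_peak_fraction, true_density, cds_length_nt,
#'   expressed flag, feature columns) and a `true_proportions` attribute
#'   (genes x fractions B--H matrix, rows summing to 1).
#' @export
#' @examples
#' truth <- generate_gene_truth(synthetic_config(n_genes = 20, seed = 1))
#' head(truth$true_occupancy)
#' rowSums(attr(truth, "true_proportions"))[1:3]
generate_gene_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_gene_truth_impl(config))
}

generate_gene_truth_impl <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))

  # --- feature table ------------------------------------------------------
  features <- data.frame(
    gene_id = gene_id,
    chrom_position = stats::runif(n, 1, 2.37e6),
    mrna_conc = stats::rlnorm(n, log(10), 0.9),
    half_life = stats::rlnorm(n, log(5), 0.5),
    cds_length = pmax(90, round(stats::rlnorm(n, config$cds_meanlog,
                                              config$cds_sdlog))),
    aromaticity = stats::rlnorm(n, log(0.08), 0.3),
    gravy = stats::rnorm(n, -0.1, 0.35),
    cai = pmin(0.99, stats::rlnorm(n, log(0.45), 0.25)),
    dg_up = stats::rnorm(n, -8, 4),
    dg_down = stats::rnorm(n, -7, 4),
    category = factor(sample(config$category_levels, n, replace = TRUE,
                             prob = config$category_probs),
                      levels = config$category_levels),
    stringsAsFactors = FALSE
  )

  # Standardized covariates on the modelling scale: log for positive
  # features, raw for sign-changing ones (positions, GRAVY, folding energies).
  z <- function(v, transform) as.numeric(scale(if (transform == "log") log(v) else v))
  transforms <- feature_transforms()
  beta <- config$ancova_coefficients
  eta <- rep(0, n)
  for (nm in names(beta)) {
    eta <- eta + beta[[nm]] * z(features[[nm]], transforms[[nm]])
  }
  lambda <- stats::setNames(rep(0, length(config$category_levels)),
                            config$category_levels)
  lambda[names(config$category_effects)] <- config$category_effects
  lambda <- lambda - sum(config$category_probs * lambda)  # deviation coding
  eta <- eta + lambda[as.character(features$category)]
  eta <- eta + stats::rnorm(n, 0, config$ancova_noise_sd)

  # Map the standardized log-scale predictor onto an occupancy with the
  # configured location/spread; the log-scale SD occ_sd/occ_mean is the
  # delta-method match to a Gaussian(occ_mean, occ_sd) marginal.
  sdlog <- config$occupancy_sd / config$occupancy_mean
  ln_occ <- log(config$occupancy_mean) - sdlog^2 / 2 + sdlog * eta
  true_occupancy <- pmin(1, pmax(1e-6, exp(ln_occ)))

  # --- peak fraction and within-gene mRNA distribution --------------------
  classes <- names(config$peak_weights)
  true_peak_fraction <- factor(
    sample(classes, n, replace = TRUE, prob = config$peak_weights),
    levels = FRACTIONS_ENGAGED)

  true_proportions <- proportions_from_truth(
    true_occupancy, true_peak_fraction, config$kernel_decay)
  rownames(true_proportions) <- gene_id

  # --- density ------------------------------------------------------------
  ribs <- config$fraction_ribosomes[as.character(true_peak_fraction)]
  true_density <- unname(ribs) * 100 / features$cds_length

  # --- protein level (latent, observed for a subset) ----------------------
  pbeta <- config$protein_coefficients
  peta <- rep(0, n)
  for (nm in names(pbeta)) {
    val <- if (nm == "occupancy") true_occupancy else features[[nm]]
    tr <- if (nm == "occupancy") "log" else transforms[[nm]]
    peta <- peta + pbeta[[nm]] * z(val, tr)
  }
  peta <- peta + stats::rnorm(n, 0, config$protein_noise_sd)
  protein_level <- exp(log(50) + 0.8 * peta)
  detected <- stats::runif(n) < config$protein_detect_prop
  protein_level[!detected] <- NA_real_

  if (config$missing_halflife_prop > 0) {
    drop <- stats::runif(n) < config$missing_halflife_prop
    features$half_life[drop] <- NA_real_
  }

  expressed <- rep(TRUE, n)
  if (config$prop_below_cutoff > 0) {
    n_low <- round(config$prop_below_cutoff * n)
    expressed[sample.int(n, n_low)] <- FALSE
  }

  out <- data.frame(
    gene_id = gene_id,
    true_occupancy = true_occupancy,
    true_peak_fraction = true_peak_fraction,
    true_density = true_density,
    cds_length_nt = features$cds_length,
    expressed = expressed,
    protein_level = protein_level,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, features[setdiff(names(features), "gene_id")])
  structure(out,
            true_proportions = true_proportions,
            config = config,
            class = c("ground_truth", "data.frame"))
}

# Within-gene mRNA distribution over B..H: (1 - occupancy) split 50/50
# between B and C, occupancy spread over D..H with a geometric kernel
# centred on the peak fraction.
proportions_from_truth <- function(occupancy, peak, decay) {
  pos <- match(as.character(peak), FRACTIONS_ENGAGED)
  kern <- outer(pos, seq_along(FRACTIONS_ENGAGED),
                function(p, j) decay^abs(j - p))
  kern <- kern / rowSums(kern)
  props <- cbind((1 - occupancy) / 2, (1 - occupancy) / 2, kern * occupancy)
  colnames(props) <- ARRAYS_FRAC
  props
}

#' Map feature names to their covariance-model transform
#'
#' Positive-valued features are log-transformed before standardization;
#' features that can take negative values (chromosome position is kept raw
#' for scale reasons, GRAVY, folding energies) enter untransformed.
#'
#' @return Named list of `"log"` / `"raw"` tags.
#' @export
feature_transforms <- function() {
  list(chrom_position = "raw",
       mrna_conc = "log",
       half_life = "log",
       cds_length = "log",
       aromaticity = "log",
       gravy = "raw",
       cai = "log",
       dg_up = "raw",
       dg_down = "raw")
}
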