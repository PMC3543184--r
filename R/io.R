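# Tabular input/output. All outputs are TSV with a commented header block
# recording the stage, seed and configuration hash, so reruns are diffable
# and attributable.

write_tsv_stamped <- function(df, path, stage, seed = NA, hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s", stage), con)
  writeLines(sprintf("# seed: %s", seed), con)
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_stamped <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write and read pipeline tables
#'
#' Long-format TSV contracts for the pipeline inputs and outputs:
#' intensities as `(gene_id, array, replicate, intensity)` rows, the
#' absorbance profile as `(time, absorbance)`, per-gene features and
#' translatome records as wide tables. Every file starts with a commented
#' header carrying the stage name, seed and configuration hash.
#'
#' @param series An [array_series()].
#' @param path Output file path.
#' @param seed,hash Provenance stamps for the header block.
#' @return The path, invisibly (writers); a data frame or object (readers).
#' @name translatome_io
NULL

#' @rdname translatome_io
#' @export
write_intensities_tsv <- function(series, path, seed = NA, hash = NA) {
  stopifnot(inherits(series, "array_series"))
  d <- dim(series$intensities)
  long <- data.frame(
    gene_id = rep(series$gene_ids, times = d[2] * d[3]),
    array = rep(rep(ARRAYS_ALL, each = d[1]), times = d[3]),
    replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
    intensity = as.numeric(series$intensities),
    stringsAsFactors = FALSE
  )
  write_tsv_stamped(long, path, "intensities", seed, hash)
}

#' @rdname translatome_io
#' @param empty_stats_path,rna_path Side-table paths written alongside the
#'   intensities (empty-spot statistics, RNA quantities).
#' @export
write_series_metadata_tsv <- function(series, empty_stats_path, rna_path,
                                      seed = NA, hash = NA) {
  stopifnot(inherits(series, "array_series"))
  write_tsv_stamped(series$empty_stats, empty_stats_path, "empty_spot_stats",
                    seed, hash)
  rna <- data.frame(array = rownames(series$rna_quantity),
                    series$rna_quantity, check.names = FALSE)
  names(rna)[-1] <- paste0("R", seq_len(ncol(series$rna_quantity)))
  write_tsv_stamped(rna, rna_path, "rna_quantity", seed, hash)
}

#' @rdname translatome_io
#' @export
read_intensities_tsv <- function(path, empty_stats_path, rna_path) {
  long <- read_tsv_stamped(path)
  genes <- unique(long$gene_id)
  reps <- sort(unique(long$replicate))
  arr <- array(NA_real_,
               dim = c(length(genes), 8, length(reps)),
               dimnames = list(genes, ARRAYS_ALL, paste0("R", reps)))
  idx <- cbind(match(long$gene_id, genes),
               match(long$array, ARRAYS_ALL),
               match(long$replicate, reps))
  arr[idx] <- long$intensity
  empty <- read_tsv_stamped(empty_stats_path)
  rna_df <- read_tsv_stamped(rna_path)
  rna <- as.matrix(rna_df[-1])
  rownames(rna) <- rna_df$array
  colnames(rna) <- NULL
  array_series(arr, empty, rna[ARRAYS_ALL, , drop = FALSE], genes)
}

#' @rdname translatome_io
#' @param profile A [polysome_profile()].
#' @export
write_profile_tsv <- function(profile, path, seed = NA, hash = NA) {
  stopifnot(inherits(profile, "polysome_profile"))
  write_tsv_stamped(data.frame(time = profile$time,
                               absorbance = profile$absorbance),
                    path, "polysome_profile", seed, hash)
}

#' @rdname translatome_io
#' @param boundaries,roles Fraction layout to attach to a profile read back
#'   from its two-column TSV (stored separately, e.g. in the YAML config).
#' @export
read_profile_tsv <- function(path, boundaries, roles = default_fraction_roles()) {
  df <- read_tsv_stamped(path)
  polysome_profile(df$time, df$absorbance, boundaries, roles)
}

#' @rdname translatome_io
#' @param truth A [generate_gene_truth()] result.
#' @export
write_truth_tsv <- function(truth, path, seed = NA, hash = NA) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- cbind(as.data.frame(truth),
              as.data.frame(attr(truth, "true_proportions")))
  names(df)[(ncol(df) - 6):ncol(df)] <- paste0("true_prop_", ARRAYS_FRAC)
  write_tsv_stamped(df, path, "ground_truth", seed, hash)
}

#' @rdname translatome_io
#' @param records A [compute_translatome()] result.
#' @export
write_translatome_tsv <- function(records, path, seed = NA, hash = NA) {
  write_tsv_stamped(as.data.frame(records), path, "translatome_records",
                    seed, hash)
}

#' @rdname translatome_io
#' @param config A [synthetic_config()].
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  # named vectors must go out as maps, not bare sequences
  for (nm in c("ancova_coefficients", "protein_coefficients",
               "peak_weights", "fraction_ribosomes", "category_effects")) {
    x[[nm]] <- as.list(x[[nm]])
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname translatome_io
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$peak_weights <- unlist(x$peak_weights)
  x$fraction_ribosomes <- unlist(x$fraction_ribosomes)
  x$category_effects <- unlist(x$category_effects)
  do.call(synthetic_config, x)
}
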