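#' Theoretical maximal ribosome density
#'
#' One bound bacterial ribosome protects about 30 nucleotides of mRNA, so at
#' most `100 / footprint_nt` ribosomes fit per 100 nucleotides of coding
#' sequence. Genes whose measured density exceeds this bound (a symptom of,
#' e.g., unannotated 5'UTR length in short genes) are excluded from
#' downstream modelling.
#'
#' @param footprint_nt Nucleotides protected per ribosome (default 30).
#' @return Maximal density in ribosomes per 100 nt (3.33 for the default).
#' @export
#' @examples
#' theoretical_max_density()  # 3.333...
theoretical_max_density <- function(footprint_nt = 30) {
  stopifnot(footprint_nt > 0)
  100 / footprint_nt
}

#' Per-gene mRNA proportions across fractions B--H
#'
#' Divides each replicate's corrected intensities by their sum over B--H so
#' every replicate vector sums to 1. Negative corrected intensities (possible
#' after centering low-signal genes) are clipped to zero before
#' normalization and counted; all-zero replicates yield an undefined (NA)
#' proportion vector and are flagged.
#'
#' @param values Numeric matrix `replicates x 7` (columns B..H), or a single
#'   7-vector.
#' @return Proportions of the same shape, with attributes `n_clipped`
#'   (count of negative values zeroed) and `undefined` (logical per
#'   replicate).
#' @export
#' @examples
#' mrna_proportions(c(1, 1, 1, 1, 1, 1, 1))
mrna_proportions <- function(values) {
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  if (ncol(m) != 7) stop("expected 7 fraction values (B..H)", call. = FALSE)
  n_clipped <- sum(m < 0)
  m[m < 0] <- 0
  tot <- rowSums(m)
  undefined <- tot <= 0
  out <- m / ifelse(tot > 0, tot, NA_real_)
  colnames(out) <- ARRAYS_FRAC
  if (vec) out <- out[1, ]
  structure(out, n_clipped = n_clipped, undefined = undefined)
}

#' Ribosome occupancy of a gene
#'
#' The fraction of a gene's mRNA population engaged in translation: per
#' replicate, the summed proportions over the ribosome-bearing fractions
#' D--H; replicate values are then averaged. Fractions B and C hold free
#' mRNA or mRNA bound to an incomplete ribosome and do not count.
#'
#' @param proportions Matrix `replicates x 7` (columns B..H) of proportion
#'   vectors, or a single 7-vector. NA replicates are excluded from the mean.
#' @return List with `mean` (scalar occupancy in `[0, 1]`, NA if no valid
#'   replicate) and `per_replicate`.
#' @export
#' @examples
#' ribosome_occupancy(c(0.1, 0.2, 0.1, 0.1, 0.1, 0.2, 0.2))$mean  # 0.7
ribosome_occupancy <- function(proportions) {
  m <- if (is.null(dim(proportions))) matrix(proportions, nrow = 1)
       else as.matrix(proportions)
  if (ncol(m) != 7) stop("expected 7 fraction proportions (B..H)",
                         call. = FALSE)
  per_rep <- rowSums(m[, 3:7, drop = FALSE])
  valid <- !is.na(per_rep)
  list(mean = if (any(valid)) mean(per_rep[valid]) else NA_real_,
       per_replicate = per_rep)
}

# Bootstrap frequency of each engaged category being the argmax.
# m: replicates x categories matrix; eng_idx: engaged category columns.
# Residuals are pooled over ALL categories and replicates of the gene; each
# bootstrap value is the per-category mean plus the mean of `nrow(m)`
# residuals drawn with replacement. Argmax ties break toward the lower
# (lighter) category, deterministically.
boot_argmax_freq <- function(m, eng_idx, n_boot) {
  pbar <- colMeans(m)
  pool <- as.numeric(sweep(m, 2, pbar))
  K <- nrow(m)
  ne <- length(eng_idx)
  if (all(pool == 0)) {
    w <- which.max(pbar[eng_idx])
    freq <- numeric(ne)
    freq[w] <- 1
    return(freq)
  }
  idx <- sample.int(length(pool), n_boot * K * ne, replace = TRUE)
  em <- rowMeans(matrix(pool[idx], nrow = n_boot * ne, ncol = K))
  vals <- matrix(em, nrow = n_boot, ncol = ne) +
    rep(pbar[eng_idx], each = n_boot)
  tabulate(max.col(vals, ties.method = "first"), ne) / n_boot
}

#' Bootstrap peak-fraction assignment with adjacent-fraction widening
#'
#' Assigns the peak fraction -- the fraction among D--H holding the highest
#' mean mRNA proportion -- by a bootstrap on residuals. Residuals of each
#' replicate value from the per-fraction mean, taken over all seven
#' fractions, are pooled within the gene; each of `n_boot` bootstrap data
#' sets adds resampled residuals back onto the per-fraction means and records
#' the argmax fraction over D--H. If one fraction is modal in at least `conf`
#' of the bootstrap sets it is the peak. Otherwise the search widens: every
#' window of 2 (then 3, ...) adjacent fractions within D--H is merged by
#' summing proportions and the full bootstrap is re-run on the merged
#' categories. Among windows reaching `conf` in their merged bootstrap, the
#' one covering the largest share of the single-fraction argmax mass is
#' assigned, so a widened peak always covers the fractions the bootstrap
#' actually hesitates between.
#'
#' @param proportions Matrix `replicates x 7` (columns B..H); needs >= 2
#'   valid replicates.
#' @param n_boot Bootstrap data sets (default 10000).
#' @param conf Required modal relative frequency (default 0.95).
#' @param seed Optional integer seed making the assignment reproducible.
#' @return List: `peak` (character vector of member fractions), `label`
#'   (e.g. `"H"` or `"G+H"`), `support` (modal relative frequency),
#'   `widened`, `tied` (exact tie in the mean proportions, broken toward the
#'   lighter fraction).
#' @export
#' @examples
#' p <- rbind(c(.1, .1, .1, .1, .1, .2, .3),
#'            c(.1, .1, .1, .1, .1, .19, .31))
#' bootstrap_peak_fraction(p, n_boot = 500, seed = 1)$label
bootstrap_peak_fraction <- function(proportions, n_boot = 10000,
                                    conf = 0.95, seed = NULL) {
  m <- as.matrix(proportions)
  if (ncol(m) != 7) stop("expected 7 fraction proportions (B..H)",
                         call. = FALSE)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) {
    stop("bootstrap peak assignment needs >= 2 valid replicates",
         call. = FALSE)
  }
  colnames(m) <- ARRAYS_FRAC
  with_seed(seed, bootstrap_peak_impl(m, n_boot, conf))
}

bootstrap_peak_impl <- function(m, n_boot, conf) {
  eng <- 3:7
  pbar <- colMeans(m)
  tied <- sum(pbar[eng] == max(pbar[eng])) > 1

  freq <- boot_argmax_freq(m, eng, n_boot)
  if (max(freq) >= conf) {
    w <- which.max(freq)
    return(list(peak = FRACTIONS_ENGAGED[w], label = FRACTIONS_ENGAGED[w],
                support = max(freq), widened = FALSE, tied = tied))
  }

  for (width in 2:5) {
    n_windows <- 5 - width + 1
    best_support <- -Inf
    best_start <- NA_integer_
    best_mass <- -Inf
    for (s in seq_len(n_windows)) {
      # a widened peak must actually cover the bootstrap argmax mass, not
      # merely outgrow the other categories by summing; rank windows by the
      # single-fraction modal mass they contain
      mass_s <- sum(freq[s:(s + width - 1)])
      cols_in <- eng[s:(s + width - 1)]
      merged <- cbind(m[, 1:2, drop = FALSE],
                      if (s > 1) m[, eng[seq_len(s - 1)], drop = FALSE],
                      rowSums(m[, cols_in, drop = FALSE]),
                      if (s + width - 1 < 5)
                        m[, eng[(s + width):5], drop = FALSE])
      eng_merged <- 3:(2 + n_windows)   # engaged categories after merging
      fr <- boot_argmax_freq(merged, eng_merged, n_boot)
      support_s <- fr[s]                # merged window sits at position s
      if (support_s >= conf && mass_s > best_mass) {
        best_mass <- mass_s
        best_support <- support_s
        best_start <- s
      }
    }
    if (!is.na(best_start)) {
      members <- FRACTIONS_ENGAGED[best_start:(best_start + width - 1)]
      return(list(peak = members, label = paste(members, collapse = "+"),
                  support = best_support, widened = TRUE, tied = tied))
    }
  }
  # width 5 always reaches support 1; not reachable
  stop("peak widening failed unexpectedly")
}

#' Ribosome density of a gene
#'
#' Number of ribosomes loaded per 100 nucleotides of coding sequence, taking
#' the representative ribosome number of the gene's (single) peak fraction.
#' Genes with a widened or unassigned peak have no defined density.
#'
#' @param peak_fraction Single fraction letter among D..H (anything else,
#'   including widened labels, yields NA).
#' @param fraction_ribosomes Named vector D..H of representative ribosome
#'   numbers, e.g. the `representative` column of
#'   [fraction_ribosome_table()].
#' @param cds_length_nt Positive coding-sequence length in nucleotides.
#' @return Density in ribosomes per 100 nt, or NA.
#' @export
#' @examples
#' ribosome_density("H", c(D = 1, E = 2.1, F = 4.2, G = 7.5, H = 14), 1000)
ribosome_density <- function(peak_fraction, fraction_ribosomes,
                             cds_length_nt) {
  stopifnot(all(cds_length_nt > 0))
  ribs <- fraction_ribosomes[as.character(peak_fraction)]
  unname(ribs) * 100 / cds_length_nt
}

#' Compute per-gene translatome records
#'
#' Runs proportions, occupancy, bootstrap peak assignment and density for
#' every gene of a normalized series.
#'
#' @param norm A [normalize_series()] result (or a `genes x 7 x replicates`
#'   array of corrected intensities).
#' @param cds_length_nt Named vector of coding-sequence lengths covering the
#'   kept genes.
#' @param fraction_ribosomes Named vector D..H of representative ribosome
#'   numbers.
#' @param n_boot,conf,seed Bootstrap parameters; per-gene seeds are derived
#'   from `seed` so assignments are reproducible and order-independent.
#' @return A `translatome_records` data frame: gene_id, occupancy,
#'   per-replicate occupancies, peak_fraction label, peak_support,
#'   peak_widened, ribosome_number, cds_length_nt, density and QC flags
#'   (`proportions_clipped`, `peak_tied`, `density_exceeds_max`). The
#'   replicate x fraction proportion arrays are kept in the `proportions`
#'   attribute.
#' @export
compute_translatome <- function(norm, cds_length_nt, fraction_ribosomes,
                                n_boot = 10000, conf = 0.95, seed = NULL) {
  if (inherits(norm, "normalized_series")) {
    ncr <- norm$ncr_values
    genes <- norm$kept_genes
  } else {
    ncr <- norm
    genes <- dimnames(ncr)[[1]] %||% sprintf("g%04d", seq_len(dim(ncr)[1]))
  }
  if (!all(genes %in% names(cds_length_nt))) {
    stop("cds_length_nt must be named and cover all kept genes",
         call. = FALSE)
  }
  n <- length(genes)
  K <- dim(ncr)[3]

  occ <- rep(NA_real_, n)
  occ_rep <- matrix(NA_real_, n, K,
                    dimnames = list(genes, paste0("R", seq_len(K))))
  peak_label <- rep(NA_character_, n)
  support <- rep(NA_real_, n)
  widened <- rep(FALSE, n)
  tied <- rep(FALSE, n)
  clipped <- rep(FALSE, n)
  props_all <- array(NA_real_, dim = c(n, K, 7),
                     dimnames = list(genes, paste0("R", seq_len(K)),
                                     ARRAYS_FRAC))

  for (i in seq_len(n)) {
    vals <- t(ncr[i, , ])                      # replicates x fractions
    pr <- mrna_proportions(vals)
    clipped[i] <- attr(pr, "n_clipped") > 0
    props_all[i, , ] <- pr
    o <- ribosome_occupancy(pr)
    occ[i] <- o$mean
    occ_rep[i, ] <- o$per_replicate
    valid <- sum(stats::complete.cases(pr))
    if (valid >= 2) {
      gene_seed <- if (is.null(seed)) NULL else (seed + i) %% 2147483647L
      bp <- bootstrap_peak_fraction(pr, n_boot = n_boot, conf = conf,
                                    seed = gene_seed)
      peak_label[i] <- bp$label
      support[i] <- bp$support
      widened[i] <- bp$widened
      tied[i] <- bp$tied
    }
  }

  single <- !is.na(peak_label) & !widened
  ribnum <- ifelse(single, fraction_ribosomes[peak_label], NA_real_)
  lens <- unname(cds_length_nt[genes])
  density <- ifelse(single, ribnum * 100 / lens, NA_real_)

  rec <- data.frame(
    gene_id = genes,
    occupancy = occ,
    peak_fraction = peak_label,
    peak_support = support,
    peak_widened = widened,
    ribosome_number = unname(ribnum),
    cds_length_nt = lens,
    density = density,
    proportions_clipped = clipped,
    peak_tied = tied,
    density_exceeds_max = !is.na(density) & density > theoretical_max_density(),
    stringsAsFactors = FALSE
  )
  rec <- cbind(rec, as.data.frame(occ_rep))
  structure(rec, proportions = props_all,
            class = c("translatome_records", "data.frame"))
}

#' Flag genes exceeding the theoretical maximal density
#'
#' Genes whose density is strictly greater than `100 / 30` ribosomes per 100
#' nt are flagged and excluded from the modelling gene set; they remain in
#' the records. A density of exactly `100 / 30` is retained.
#'
#' @param records A [compute_translatome()] result.
#' @return The records with the `density_exceeds_max` flag set and a
#'   `modeling_genes` attribute listing gene ids with a single-fraction peak
#'   and admissible density.
#' @export
filter_max_density <- function(records) {
  maxd <- theoretical_max_density()
  records$density_exceeds_max <- !is.na(records$density) &
    records$density > maxd
  keep <- !is.na(records$density) & !records$density_exceeds_max
  attr(records, "modeling_genes") <- records$gene_id[keep]
  records
}
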