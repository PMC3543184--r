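#' Hypergeometric enrichment test
#'
#' Tests whether a gene subset of size `n1`, sampled without replacement from
#' a universe of `n2` genes of which `m` carry a trait of interest, is
#' enriched for that trait. Under the null the trait-positive count follows
#' the hypergeometric distribution `H(m, n2 - m, n1)`, and the p-value is the
#' strictly-greater tail `P(N > n_obs)`. (Note the strict inequality: the
#' observed count itself is not included in the tail, unlike the more common
#' `P(N >= n_obs)` convention.)
#'
#' @param n1 Subset size.
#' @param n2 Universe size.
#' @param m Trait-positive genes in the universe.
#' @param n_obs Trait-positive genes observed in the subset.
#' @return List with the counts and `p_value`.
#' @export
#' @examples
#' hypergeometric_enrichment(n1 = 5, n2 = 10, m = 4, n_obs = 3)$p_value
hypergeometric_enrichment <- function(n1, n2, m, n_obs) {
  vals <- c(n1 = n1, n2 = n2, m = m, n_obs = n_obs)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (n1 > n2 || m > n2) {
    stop("subset and trait counts cannot exceed the universe size",
         call. = FALSE)
  }
  if (n_obs > min(n1, m)) {
    stop("n_obs cannot exceed min(n1, m)", call. = FALSE)
  }
  p <- stats::phyper(n_obs, m, n2 - m, n1, lower.tail = FALSE)
  list(n1 = n1, n2 = n2, m = m, n_obs = n_obs, p_value = p)
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation between two variables with the usual two-sided
#' t-test p-value.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite, each with
#'   positive variance.
#' @return List with `r`, `p_value` and `n`.
#' @export
#' @examples
#' pearson_correlation(1:10, 2 * (1:10) + 1)$r  # 1
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for zero-variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# Build the standardized design matrix for the covariance models: log or raw
# transform per covariate, centred and reduced; the functional category
# enters as deviation-coded indicator columns (one per level except the
# last), each selectable on its own.
build_model_frame <- function(data, response, covariates, category) {
  cols <- c(response, names(covariates), category)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[cols]
  complete <- stats::complete.cases(df)
  df <- df[complete, , drop = FALSE]
  n_dropped <- sum(!complete)
  if (nrow(df) < 20) {
    stop("need >= 20 complete cases to fit a covariance model",
         call. = FALSE)
  }
  y_raw <- df[[response]]
  if (any(y_raw <= 0)) {
    stop("response must be strictly positive (it is log-transformed)",
         call. = FALSE)
  }
  y <- as.numeric(scale(log(y_raw)))

  X <- list()
  for (nm in names(covariates)) {
    v <- df[[nm]]
    tr <- covariates[[nm]]
    if (!tr %in% c("log", "raw")) {
      stop(sprintf("unknown transform '%s' for covariate %s", tr, nm),
           call. = FALSE)
    }
    if (tr == "log") {
      if (any(v <= 0)) {
        stop(sprintf("covariate %s has nonpositive values; use transform 'raw'",
                     nm), call. = FALSE)
      }
      v <- log(v)
    }
    if (stats::sd(v) == 0) {
      stop(sprintf("covariate %s is constant", nm), call. = FALSE)
    }
    X[[nm]] <- as.numeric(scale(v))
  }
  if (!is.null(category)) {
    f <- factor(df[[category]])
    f <- droplevels(f)
    lev <- levels(f)
    if (length(lev) >= 2) {
      ref <- lev[length(lev)]
      for (l in lev[-length(lev)]) {
        X[[paste0("cat_", l)]] <- (f == l) - (f == ref)
      }
    }
  }
  mf <- data.frame(.y = y, X, check.names = FALSE)

  # collinearity diagnostic on the standardized design
  Xm <- as.matrix(mf[-1])
  if (ncol(Xm) >= 2) {
    cc <- suppressWarnings(stats::cor(Xm))
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    if (max(abs(cc)) > 0.999) {
      stop(sprintf("covariates %s and %s are collinear",
                   colnames(Xm)[worst[1]], colnames(Xm)[worst[2]]),
           call. = FALSE)
    }
  }
  list(frame = mf, n_dropped = n_dropped)
}

#' Fit a centred/reduced log-linear covariance model with AIC selection
#'
#' Models the log of a positive response (ribosome occupancy, ribosome
#' density or protein level) as a linear combination of standardized gene,
#' mRNA and protein-sequence features plus functional-category deviations.
#' Quantitative covariates are log-transformed where tagged, then centred
#' and reduced so coefficients are standardized effects; the response is
#' log-transformed and standardized the same way. Covariates are selected by
#' stepwise search (both directions, from the full model) under the Akaike
#' Information Criterion, or by exhaustive subset search for small designs.
#'
#' @param data Data frame holding the response and covariate columns.
#' @param response Name of the positive response column.
#' @param covariates Named list/vector mapping covariate column names to
#'   transform tags `"log"` or `"raw"` (see [feature_transforms()]).
#' @param category Optional name of a factor column entering as
#'   deviation-coded per-level terms, each selectable individually.
#' @param selection `"stepwise"` (default) or `"exhaustive"` (all subsets;
#'   at most 12 candidate terms).
#' @return A `model_fit`: `coefficients` (term, estimate, p_value for the
#'   selected covariates), `selected`, `adjusted_r2`, `aic`, `aic_trace`,
#'   `n_used`, `n_dropped`, and the underlying `lm` fit.
#' @export
fit_covariance_model <- function(data, response,
                                 covariates = feature_transforms(),
                                 category = NULL,
                                 selection = c("stepwise", "exhaustive")) {
  selection <- match.arg(selection)
  built <- build_model_frame(data, response, covariates, category)
  mf <- built$frame

  if (selection == "stepwise") {
    full <- stats::lm(.y ~ ., data = mf)
    null <- stats::lm(.y ~ 1, data = mf)
    sel <- stats::step(full, direction = "both",
                       scope = list(lower = stats::formula(null),
                                    upper = stats::formula(full)),
                       trace = 0)
    trace <- sel$anova
  } else {
    terms_all <- setdiff(names(mf), ".y")
    if (length(terms_all) > 12) {
      stop("exhaustive selection supports at most 12 candidate terms",
           call. = FALSE)
    }
    best <- NULL
    best_aic <- Inf
    trace <- NULL
    for (mask in 0:(2^length(terms_all) - 1)) {
      inc <- terms_all[bitwAnd(mask, 2^(seq_along(terms_all) - 1)) > 0]
      fml <- if (length(inc)) {
        stats::reformulate(sprintf("`%s`", inc), response = ".y")
      } else {
        .y ~ 1
      }
      fit <- stats::lm(fml, data = mf)
      aic <- stats::AIC(fit)
      if (aic < best_aic) {
        best_aic <- aic
        best <- fit
      }
    }
    sel <- best
  }

  sm <- summary(sel)
  coefs <- stats::coef(sm)
  keep <- setdiff(rownames(coefs), "(Intercept)")
  coef_df <- data.frame(
    term = gsub("`", "", keep),
    estimate = coefs[keep, "Estimate"],
    p_value = coefs[keep, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = coef_df,
                 selected = coef_df$term,
                 adjusted_r2 = sm$adj.r.squared,
                 aic = stats::AIC(sel),
                 aic_trace = trace,
                 n_used = nrow(mf),
                 n_dropped = built$n_dropped,
                 fit = sel),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: %d covariates selected, adjusted R^2 = %.3f (n = %d, %d dropped)\n",
              length(x$selected), x$adjusted_r2, x$n_used, x$n_dropped))
  if (nrow(x$coefficients)) {
    print(transform(x$coefficients,
                    estimate = round(estimate, 3),
                    p_value = signif(p_value, 2)), row.names = FALSE)
  }
  invisible(x)
}

#' Protein-level covariance models with and without translatome variables
#'
#' Fits the protein-level model twice: model I from the sequence/mRNA
#' features alone, model II additionally offering ribosome occupancy and
#' ribosome density as candidate covariates. Comparing the two adjusted R^2
#' values quantifies what the translatome variables add to explaining
#' protein concentrations.
#'
#' @param data Data frame with the protein level, feature columns, and
#'   `occupancy` / `density` columns (both strictly positive where present).
#' @param response Name of the protein-level column.
#' @param covariates Base covariate transform map (as in
#'   [fit_covariance_model()]).
#' @param category Optional functional-category column.
#' @param selection Passed through to [fit_covariance_model()].
#' @return List with elements `without` (model I) and `with` (model II),
#'   both `model_fit` objects.
#' @export
protein_level_model <- function(data, response = "protein_level",
                                covariates = feature_transforms(),
                                category = NULL,
                                selection = "stepwise") {
  fit1 <- fit_covariance_model(data, response, covariates, category,
                               selection)
  cov2 <- c(covariates, list(occupancy = "log", density = "log"))
  fit2 <- fit_covariance_model(data, response, cov2, category, selection)
  list(without = fit1, with = fit2)
}
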