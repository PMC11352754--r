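# Dose-response analysis for GES drug screens: the four-parameter logistic
# (4PL) model
#     v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)
# fitted by least squares on log10 concentration, plus the IC50 fold-change
# comparison between culture models.

#' Four-parameter logistic parameter set
#'
#' @param bottom,top Lower/upper viability asymptotes (% of untreated
#'   control); `top > bottom`.
#' @param ic50 Half-maximal inhibitory concentration (uM), positive.
#' @param hill Hill slope (dimensionless); positive for viability falling
#'   with concentration.
#' @return Object of class `fourpl`.
#' @export
fourpl <- function(bottom, top, ic50, hill) {
  check_number(bottom, "bottom")
  check_number(top, "top")
  check_number(ic50, "ic50", positive = TRUE)
  check_number(hill, "hill")
  if (top <= bottom) stopf("top (%g) must exceed bottom (%g)", top, bottom)
  structure(list(bottom = bottom, top = top, ic50 = ic50, hill = hill),
            class = "fourpl")
}

#' Predicted viability under a 4PL model
#'
#' At `concentration == ic50` the prediction is exactly the midpoint
#' `(top + bottom) / 2`; for positive Hill slopes viability decreases
#' monotonically from `top` (c -> 0) to `bottom` (c -> Inf).
#'
#' @param object A [fourpl()] (or `fourpl_fit`).
#' @param concentration Concentration(s) in uM, positive.
#' @param ... Unused.
#' @return Predicted viability (%).
#' @export
predict.fourpl <- function(object, concentration, ...) {
  if (any(concentration <= 0)) stopf("concentration must be positive")
  with(object, bottom + (top - bottom) / (1 + (concentration / ic50)^hill))
}

#' @export
print.fourpl <- function(x, ...) {
  cat(sprintf("4PL: bottom %.3g, top %.3g, IC50 %.4g uM, hill %.3g\n",
              x$bottom, x$top, x$ic50, x$hill))
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Unweighted least squares on log10 concentration via Levenberg-Marquardt
#' (`minpack.lm::nlsLM`). Replicates are fitted pointwise as individual
#' observations, preserving their variance structure. Initialisation: `top`
#' and `bottom` from the extremes of the dose-averaged viability, `ic50`
#' from the concentration whose mean response is closest to the midpoint,
#' `hill = 1`. Data with no dose effect (flat dose-averaged response) raise
#' an error; an optimizer failure returns a result flagged
#' `converged = FALSE` rather than failing silently.
#'
#' @param data Data frame with `concentration_uM` and `viability_pct`
#'   (optionally `replicate`); at least 4 distinct concentrations.
#' @param init Optional [fourpl()] starting values.
#' @return Object of class `c("fourpl_fit", "fourpl")`: the parameters plus
#'   `rss`, `converged` and `n_obs`.
#' @export
fit_fourpl <- function(data, init = NULL) {
  stopifnot(all(c("concentration_uM", "viability_pct") %in% names(data)))
  data <- data[complete.cases(data[, c("concentration_uM", "viability_pct")]), ]
  if (any(data$concentration_uM <= 0)) {
    stopf("concentrations must be strictly positive")
  }
  if (!all(is.finite(data$viability_pct))) stopf("viabilities must be finite")
  doses <- sort(unique(data$concentration_uM))
  if (length(doses) < 4L) {
    stopf("need >= 4 distinct concentrations, got %d", length(doses))
  }
  mean_by_dose <- vapply(doses, function(d) {
    mean(data$viability_pct[data$concentration_uM == d])
  }, numeric(1))
  span <- diff(range(mean_by_dose))
  if (span <= 1e-3 * (max(abs(mean_by_dose)) + 1)) {
    stopf("no dose effect: viability is flat across all concentrations")
  }
  if (is.null(init)) {
    mid <- (max(mean_by_dose) + min(mean_by_dose)) / 2
    init <- fourpl(bottom = min(mean_by_dose), top = max(mean_by_dose),
                   ic50 = doses[which.min(abs(mean_by_dose - mid))],
                   hill = 1)
  }
  df <- data.frame(lc = log10(data$concentration_uM),
                   v = data$viability_pct)
  start <- list(bottom = init$bottom, top = init$top,
                lic50 = log10(init$ic50), hill = init$hill)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- init
    out$rss <- NA_real_
    out$converged <- FALSE
    out$n_obs <- nrow(df)
    out$message <- conditionMessage(fit)
    class(out) <- c("fourpl_fit", "fourpl")
    return(out)
  }
  cf <- coef(fit)
  out <- list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
              ic50 = 10^unname(cf["lic50"]), hill = unname(cf["hill"]),
              rss = sum(residuals(fit)^2),
              converged = fit$convInfo$isConv, n_obs = nrow(df))
  class(out) <- c("fourpl_fit", "fourpl")
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit (%s, n = %d): bottom %.3g, top %.3g, IC50 %.4g uM, hill %.3g, RSS %.4g\n",
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_obs, x$bottom, x$top, x$ic50, x$hill, x$rss))
  invisible(x)
}

#' IC50 fold change between two models
#'
#' @param ic50_a,ic50_b IC50s (uM), positive; the ratio reported is `a / b`.
#' @return List with `ratio` and `fold` (ratio rounded to the nearest
#'   integer fold).
#' @export
fold_change <- function(ic50_a, ic50_b) {
  check_number(ic50_a, "ic50_a", positive = TRUE)
  check_number(ic50_b, "ic50_b", positive = TRUE)
  ratio <- ic50_a / ic50_b
  list(ratio = ratio, fold = round(ratio))
}

#' Simulate replicate dose-response data from a known 4PL truth
#'
#' Emulates a 10-fold serial dilution screen: viabilities are the 4PL
#' prediction plus additive Gaussian noise expressed as a fraction of the
#' top asymptote.
#'
#' @param params True [fourpl()] parameters.
#' @param concentrations Dose series (uM); default a 10-fold dilution from
#'   1 mM down to 0.1 nM.
#' @param n_replicates Replicates per dose.
#' @param noise_frac Noise sd as a fraction of `top`.
#' @param seed Integer seed.
#' @return Data frame `concentration_uM, replicate, viability_pct`.
#' @export
simulate_dose_response <- function(params,
                                   concentrations = 10^seq(3, -4),
                                   n_replicates = 3, noise_frac = 0.05,
                                   seed = 1L) {
  stopifnot(inherits(params, "fourpl"))
  grid <- expand.grid(concentration_uM = concentrations,
                      replicate = seq_len(n_replicates))
  grid <- grid[order(grid$concentration_uM, grid$replicate), ]
  truth <- predict.fourpl(params, grid$concentration_uM)
  noise <- with_seed(seed, rnorm(nrow(grid), 0, noise_frac * params$top))
  grid$viability_pct <- truth + noise
  rownames(grid) <- NULL
  grid
}
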