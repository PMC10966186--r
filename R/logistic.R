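#' Logistic calibration linking canal diameter to endothermy
#'
#' A fixed logistic model mapping the harmonic mean of primary vascular canal
#' diameters (HMC, in micrometres) to a probability of endothermy. The
#' defaults are the published calibration obtained by phylogenetic logistic
#' regression on extant tetrapods: slope \eqn{c = -0.45} per micrometre,
#' intercept \eqn{i = 6.04}, and classification cut-off 0.59. Smaller canals
#' imply smaller erythrocytes and hence higher aerobic capacity, so the slope
#' is negative.
#'
#' @param coefficient Slope on HMC, per micrometre. Default -0.45.
#' @param intercept Dimensionless intercept. Default 6.04.
#' @param threshold Probability cut-off: a specimen with
#'   `p_end >= threshold` is classified endothermic. Must lie strictly in
#'   (0, 1). Default 0.59.
#' @return An object of class `logistic_model`.
#' @examples
#' m <- logistic_model()
#' predict_pend(29.171, m)   # a large-canal ectotherm, p_end ~ 8.4e-4
#' predict_pend(10.246, m)   # a small-canal endotherm, p_end ~ 0.81
#' @export
logistic_model <- function(coefficient = -0.45, intercept = 6.04,
                           threshold = 0.59) {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L, is.finite(coefficient),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
            is.numeric(threshold), length(threshold) == 1L)
  if (!(threshold > 0 && threshold < 1)) {
    stop("`threshold` must lie strictly between 0 and 1, got ", threshold)
  }
  structure(
    list(coefficient = coefficient, intercept = intercept, threshold = threshold),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic endothermy model: p_end = plogis(", x$coefficient,
      " * HMC + ", x$intercept, "), cut-off ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Probability of endothermy from harmonic mean canal diameter
#'
#' Evaluates `p_end = exp(c*HMC + i) / (1 + exp(c*HMC + i))` through
#' [stats::plogis()], which is numerically stable for arbitrarily large
#' magnitudes of the linear predictor (no overflow up to and beyond
#' |c*HMC + i| = 700).
#'
#' @param hmc Harmonic mean canal diameter(s), micrometres; strictly positive.
#' @param model A [logistic_model()].
#' @return Probabilities in \[0, 1\], one per element of `hmc`.
#' @export
predict_pend <- function(hmc, model = logistic_model()) {
  stopifnot(inherits(model, "logistic_model"))
  if (length(hmc) == 0L) stop("`hmc` is empty")
  if (!is.numeric(hmc) || anyNA(hmc) || any(hmc <= 0)) {
    bad <- which(!is.finite(hmc) | hmc <= 0)[1L]
    stop("`hmc` must be positive and finite; entry ", bad, " is ",
         hmc[bad])
  }
  stats::plogis(model$coefficient * hmc + model$intercept)
}

#' Classify a probability of endothermy against the cut-off
#'
#' A probability greater than or equal to the model threshold is classified
#' `"endothermy"` (the boundary is inclusive), otherwise `"ectothermy"`.
#'
#' @param p_end Probabilities in \[0, 1\].
#' @param model A [logistic_model()] supplying the threshold.
#' @return Character vector of `"endothermy"` / `"ectothermy"`.
#' @export
classify <- function(p_end, model = logistic_model()) {
  stopifnot(inherits(model, "logistic_model"))
  if (length(p_end) == 0L) stop("`p_end` is empty")
  if (!is.numeric(p_end) || anyNA(p_end) || any(p_end < 0 | p_end > 1)) {
    bad <- which(!is.finite(p_end) | p_end < 0 | p_end > 1)[1L]
    stop("`p_end` must lie in [0, 1]; entry ", bad, " is ", p_end[bad])
  }
  ifelse(p_end >= model$threshold, "endothermy", "ectothermy")
}
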