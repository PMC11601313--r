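#' Likelihood-ratio test for episodic diversifying selection
#'
#' Compares the alternative fit (selection-class omega free, >= 1) to the
#' matched null (selection-class omega = 1).  The statistic `2 (logL_alt -
#' logL_null)` is referred to a conservative chi-squared distribution with 2
#' degrees of freedom, whose tail is `exp(-LRT / 2)`.  At `LRT = 0` the
#' reported p-value is capped at 0.5, the maximum for the one-sided test;
#' the raw chi-squared tail is also returned.
#'
#' @param alt,null Matched `busted_fit` objects (same model family, same
#'   data, `variant` alternative / null).
#' @return A `selection_test`: list with `lrt`, `p_value` (capped),
#'   `p_raw` (uncapped chi-squared tail), `df`, and `test`.
#' @export
eds_test <- function(alt, null) {
  check_matched(alt, null)
  stopifnot(alt$hyper$variant == "alternative", null$hyper$variant == "null",
            alt$hyper$error_sink == null$hyper$error_sink)
  if (alt$loglik < null$loglik - 1e-4)
    warning("alternative log-likelihood below null by ",
            format(null$loglik - alt$loglik), "; optimization artifact")
  lrt <- max(0, 2 * (alt$loglik - null$loglik))
  p_raw <- exp(-lrt / 2)
  structure(list(lrt = lrt, p_value = min(p_raw, 0.5), p_raw = p_raw,
                 df = 2L,
                 test = paste0("EDS (",
                               if (alt$hyper$error_sink) "BUSTED-E" else "BUSTED-S",
                               ")")),
            class = "selection_test")
}

#' Likelihood-ratio test of the error model against the plain model
#'
#' Tests whether adding the error-sink class (BUSTED-E) significantly
#' improves on the plain model (BUSTED-S); both must be alternative-variant
#' fits of the same data.  BUSTED-S is nested in BUSTED-E (error weight 0),
#' so the BUSTED-E log-likelihood can never be lower.  The conservative
#' chi-squared with 2 degrees of freedom is used; both the capped and raw
#' conventions are reported.
#'
#' @param busted_s,busted_e Alternative-variant `busted_fit` objects without
#'   and with the error sink.
#' @return A `selection_test`.
#' @export
error_model_test <- function(busted_s, busted_e) {
  check_matched(busted_s, busted_e)
  stopifnot(!busted_s$hyper$error_sink, busted_e$hyper$error_sink,
            busted_s$hyper$variant == "alternative",
            busted_e$hyper$variant == "alternative")
  if (busted_e$loglik < busted_s$loglik - 1e-4)
    warning("BUSTED-E log-likelihood below BUSTED-S (nesting violated by ",
            format(busted_s$loglik - busted_e$loglik), ")")
  lrt <- max(0, 2 * (busted_e$loglik - busted_s$loglik))
  p_raw <- exp(-lrt / 2)
  structure(list(lrt = lrt, p_value = min(p_raw, 0.5), p_raw = p_raw,
                 df = 2L, test = "BUSTED-E vs BUSTED-S"),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(x$test, ": LRT = ", format(x$lrt, digits = 6), ", p = ",
      format(x$p_value, digits = 4), " (chi2_", x$df, " tail ",
      format(x$p_raw, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' AICc model averaging of EDS p-values
#'
#' Akaike weights are `w_i = exp(0.5 (min AICc - AICc_i))`, normalized to
#' sum to 1; the model-averaged p-value is the weight-weighted sum of the
#' per-model EDS p-values, which always lies between the smallest and
#' largest of them.
#'
#' @param fits List of alternative-variant `busted_fit` objects on the same
#'   data (at least two).
#' @param ps Matched numeric vector of per-model EDS p-values.
#' @return A `model_average`: list with `aicc`, `weights`, `ps`, and `p_ma`.
#' @export
model_average <- function(fits, ps) {
  stopifnot(length(fits) >= 2, length(ps) == length(fits))
  for (i in seq_along(fits)[-1]) check_matched(fits[[1]], fits[[i]])
  ai <- vapply(fits, function(f) f$aicc, numeric(1))
  if (any(!is.finite(ai))) stop("non-finite AICc in model average")
  w <- akaike_weights(ai)
  nm <- vapply(fits, function(f)
    if (f$hyper$error_sink) "BUSTED-E" else "BUSTED-S", character(1))
  structure(list(aicc = stats::setNames(ai, nm),
                 weights = stats::setNames(w, nm),
                 ps = stats::setNames(ps, nm),
                 p_ma = sum(w * ps)),
            class = "model_average")
}

#' Akaike weights from AICc scores
#'
#' @param aicc Numeric vector of AICc scores.
#' @return Weights proportional to `exp(0.5 (min(aicc) - aicc))`, summing
#'   to 1.
#' @export
akaike_weights <- function(aicc) {
  w <- exp(0.5 * (min(aicc) - aicc))
  w / sum(w)
}

#' @export
print.model_average <- function(x, ...) {
  for (i in seq_along(x$weights))
    cat(sprintf("%-9s AICc = %.4f  w = %.4f  p = %.4g\n",
                names(x$weights)[i], x$aicc[i], x$weights[i], x$ps[i]))
  cat("model-averaged p =", format(x$p_ma, digits = 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg q-values for a batch of alignments
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted q-values via [stats::p.adjust()] with `method = "BH"`.
#' @export
bh_qvalues <- function(p) stats::p.adjust(p, method = "BH")

check_matched <- function(a, b) {
  if (!identical(a$fingerprint, b$fingerprint))
    stop("fits were computed on different data (fingerprint mismatch)")
  invisible(TRUE)
}
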