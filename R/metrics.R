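## Global-function parameters (EF, SV, LV mass) and the evaluation
## statistics used throughout the validation experiments: percent error,
## Bland-Altman agreement and paired significance testing.

#' Global LV function from paired volumes
#'
#' Stroke volume SV = EDV - ESV, ejection fraction EF = 100 SV / EDV, and
#' (when an epicardial end-diastolic volume is supplied) myocardial mass
#' LVM = density * (epicardial EDV - endocardial EDV).  The default
#' density 1.05 g/ml is the standard literature value for myocardium.
#'
#' @param edv,esv endocardial end-diastolic and end-systolic volumes (ml).
#' @param epi_edv epicardial end-diastolic volume (ml), or \code{NA} to
#'   skip the mass computation.
#' @param density myocardial density in g/ml.
#' @param method,n_slices labels carried into the report.
#' @return object of class \code{function_report} with fields EDV, ESV,
#'   SV (ml), EF (percent), LVM (g or NA).
#' @export
global_function <- function(edv, esv, epi_edv = NA, density = 1.05,
                            method = "unspecified", n_slices = NA) {
  stopifnot(edv > 0, esv >= 0)
  if (esv > edv)
    warning("ESV exceeds EDV; EF reported negative (pathological input passed through)")
  if (!is.na(epi_edv) && epi_edv < edv)
    stop("global_function: epicardial EDV must be >= endocardial EDV")
  sv <- edv - esv
  ef <- 100 * sv / edv
  lvm <- if (is.na(epi_edv)) NA_real_ else density * (epi_edv - edv)
  structure(
    list(EDV = edv, ESV = esv, SV = sv, EF = ef, LVM = lvm,
         method = method, n_slices = n_slices),
    class = "function_report"
  )
}

#' @export
print.function_report <- function(x, ...) {
  cat(sprintf("function_report [%s]: EDV %.1f ml, ESV %.1f ml, SV %.1f ml, EF %.1f%%",
              x$method, x$EDV, x$ESV, x$SV, x$EF))
  if (!is.na(x$LVM)) cat(sprintf(", LVM %.1f g", x$LVM))
  cat("\n")
  invisible(x)
}

#' Mean and SD of per-case percent error
#'
#' Per-case error is 100 (estimate - truth) / truth; the SD uses the
#' sample (n - 1) denominator.
#'
#' @param estimates,truths equal-length numeric vectors (ml); truths must
#'   be positive.
#' @return list with \code{mean} and \code{sd} (percent), plus the
#'   per-case errors in \code{errors}.
#' @export
percent_error_stats <- function(estimates, truths) {
  if (length(estimates) != length(truths) || length(estimates) == 0)
    stop("percent_error_stats: estimates and truths must have equal nonzero length")
  if (any(truths <= 0)) stop("percent_error_stats: truths must be positive")
  e <- 100 * (estimates - truths) / truths
  list(mean = mean(e), sd = if (length(e) > 1) stats::sd(e) else NA_real_,
       errors = e)
}

#' Bland-Altman agreement between two paired measurement sets
#'
#' Differences are taken a - b; the limits of agreement are
#' bias +/- 1.96 SD.
#'
#' @param method_a,method_b paired numeric vectors (ml), n >= 2.
#' @return list with \code{bias}, \code{sd}, \code{loa} (lower, upper) and
#'   a \code{points} data.frame of per-pair (mean, difference) for
#'   plotting.
#' @export
bland_altman <- function(method_a, method_b) {
  if (length(method_a) != length(method_b))
    stop("bland_altman: paired vectors must have equal length")
  if (length(method_a) < 2) stop("bland_altman: need n >= 2 pairs")
  d <- method_a - method_b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       points = data.frame(mean = (method_a + method_b) / 2, difference = d))
}

#' Paired significance test between two error sets
#'
#' Two-sided paired comparison of error magnitudes (absolute values by
#' default) between two methods evaluated on the same cases: paired
#' t-test, or Wilcoxon signed-rank as the distribution-free alternative.
#'
#' @param errors_a,errors_b paired numeric vectors, n >= 3.
#' @param alpha significance level for the returned flag.
#' @param method \code{"t"} (default) or \code{"wilcoxon"}.
#' @param absolute compare absolute errors (default \code{TRUE}); pass
#'   \code{FALSE} to compare signed values.
#' @return list with \code{statistic}, \code{p}, \code{significant}.
#' @export
paired_significance <- function(errors_a, errors_b, alpha = 0.05,
                                method = c("t", "wilcoxon"), absolute = TRUE) {
  method <- match.arg(method)
  if (length(errors_a) != length(errors_b))
    stop("paired_significance: paired vectors must have equal length")
  if (length(errors_a) < 3) stop("paired_significance: need n >= 3 pairs")
  a <- if (absolute) abs(errors_a) else errors_a
  b <- if (absolute) abs(errors_b) else errors_b
  d <- a - b
  if (all(abs(d) < .Machine$double.eps^0.5)) {
    warning("degenerate-test: all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p = 1, significant = FALSE))
  }
  ht <- if (method == "t") stats::t.test(a, b, paired = TRUE)
        else stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha)
}
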