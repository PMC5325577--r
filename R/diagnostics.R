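## Convergence checks applied to stored (thinned, post-burn-in) samples:
## the lag-1 autocorrelation rule, a Geweke-style trend comparison, and a
## moment-based normality screen.

#' Lag-1 autocorrelation of a stored sample series
#'
#' Sample autocorrelation at lag 1, mean-centred with the biased (1/n)
#' normalisation. The usual chain-validity rule requires this to be below
#' 0.1 for every monitored parameter.
#'
#' @param x numeric series of stored samples (at least 10).
#' @return A value in `[-1, 1]`; a constant series returns 0 with a warning.
#' @export
lag1_autocorrelation <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("need at least 10 stored samples")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    warning("constant series; autocorrelation defined as 0")
    return(0)
  }
  sum(xc[-n] * xc[-1L]) / denom
}

## Spectral density at frequency zero from an AR fit (used to scale the
## Geweke comparison for autocorrelated series).
spectrum0 <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x)) == 1L) return(0)
  fit <- try(stats::ar(x, aic = TRUE,
                       order.max = min(20L, floor(length(x) / 5))),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(stats::var(x))
  if (length(fit$ar) == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Trend check for a stored sample series
#'
#' Geweke-style comparison of the mean of the first 10% of the series with
#' the mean of the last 50%, scaled by spectral-density standard errors.
#' `|z| >= 2` flags a trend (a reproducible stand-in for the visual
#' "no obvious trends" inspection of trace plots).
#'
#' @param x numeric series (at least 50 stored samples).
#' @return List with `z` and logical `flagged`.
#' @export
trend_check <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 50L) stop("need at least 50 stored samples")
  n1 <- max(2L, floor(0.1 * n))
  x1 <- x[seq_len(n1)]
  x2 <- x[seq.int(floor(0.5 * n) + 1L, n)]
  if (stats::var(x) == 0) return(list(z = 0, flagged = FALSE))
  se2 <- spectrum0(x1) / length(x1) + spectrum0(x2) / length(x2)
  z <- if (se2 > 0) (mean(x1) - mean(x2)) / sqrt(se2) else 0
  list(z = z, flagged = abs(z) >= 2)
}

#' Normality screen for a posterior sample
#'
#' Flags clearly non-normal posterior densities via sample skewness
#' (`|skewness| > 1`) and excess kurtosis (`|kurtosis| > 2`).
#'
#' @param x numeric series (at least 100 stored samples).
#' @return List with `skewness`, `kurtosis` (excess) and logical `flagged`.
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 100L) stop("need at least 100 stored samples")
  s <- stats::sd(x)
  if (s == 0) return(list(skewness = 0, kurtosis = 0, flagged = FALSE))
  xc <- (x - mean(x)) / s
  sk <- mean(xc^3)
  ku <- mean(xc^4) - 3
  list(skewness = sk, kurtosis = ku, flagged = abs(sk) > 1 || abs(ku) > 2)
}

#' Convergence report for a fitted chain
#'
#' Applies the chain-validity criteria to every monitored parameter series
#' (variance components, residual correlation and fixed effects): lag-1
#' autocorrelation below `ac_threshold`, no Geweke trend flag, and the
#' normality screen (reported but not gating). The overall `pass` flag is
#' true iff all monitored autocorrelations are below the threshold and no
#' trend is flagged.
#'
#' @param fit a [thram] fit (or a numeric matrix of stored samples with
#'   named columns).
#' @param ac_threshold lag-1 autocorrelation bound (default 0.1).
#' @return An object of class `"convergence_report"`: data frame `checks`
#'   plus attributes; serialisable with [write_convergence_report()].
#' @export
convergence_report <- function(fit, ac_threshold = 0.1) {
  mat <- if (inherits(fit, "thram")) monitored_samples(fit) else as.matrix(fit)
  checks <- do.call(rbind, lapply(colnames(mat), function(nm) {
    x <- mat[, nm]
    ac <- lag1_autocorrelation(x)
    tc <- trend_check(x)
    nc <- if (length(x) >= 100L) normality_check(x)
          else list(skewness = NA_real_, kurtosis = NA_real_, flagged = FALSE)
    data.frame(parameter = nm, lag1_autocorr = ac, geweke_z = tc$z,
               trend_flagged = tc$flagged, skewness = nc$skewness,
               excess_kurtosis = nc$kurtosis, nonnormal_flagged = nc$flagged,
               stringsAsFactors = FALSE)
  }))
  pass <- all(abs(checks$lag1_autocorr) < ac_threshold) &&
    !any(checks$trend_flagged)
  structure(list(checks = checks, pass = pass,
                 ac_threshold = ac_threshold,
                 n_samples = nrow(mat)),
            class = "convergence_report")
}

## variance components + residual correlation + fixed effects, as monitored
monitored_samples <- function(fit) {
  stopifnot(inherits(fit, "thram"))
  out <- fit$samples$G0
  if (!is.null(fit$samples$r_he) && stats::var(fit$samples$r_he) > 0)
    out <- cbind(out, r_he = fit$samples$r_he)
  cbind(out, fit$samples$beta)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence report over", x$n_samples, "stored samples\n")
  worst <- x$checks[which.max(abs(x$checks$lag1_autocorr)), ]
  cat(sprintf("  max |lag-1 autocorrelation|: %.3f (%s; threshold %g)\n",
              abs(worst$lag1_autocorr), worst$parameter, x$ac_threshold))
  cat("  trend flags:", sum(x$checks$trend_flagged),
      " non-normality flags:", sum(x$checks$nonnormal_flagged), "\n")
  cat(if (x$pass) "  PASS\n" else "  FAIL\n")
  invisible(x)
}

#' Serialise a convergence report to JSON
#'
#' @param report a [convergence_report] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_convergence_report <- function(report, path) {
  jsonlite::write_json(
    list(pass = report$pass, ac_threshold = report$ac_threshold,
         n_samples = report$n_samples, checks = report$checks),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
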