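#' Summarise posterior samples
#'
#' Per-parameter posterior mean, SD, standard error of the mean (SEM over
#' the stored draws), lag-1 autocorrelation and pMCMC. pMCMC is twice the
#' smaller of the fractions of samples above and below zero -- the quantity
#' used to call an effect significant at 0.05.
#'
#' @param x a [thram] fit (all monitored parameters), or a numeric vector /
#'   matrix of stored samples.
#' @return Data frame with one row per parameter.
#' @export
posterior_summary <- function(x) {
  mat <- if (inherits(x, "thram")) monitored_samples(x)
         else if (is.null(dim(x))) matrix(x, dimnames = list(NULL, "x"))
         else as.matrix(x)
  out <- do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    data.frame(parameter = colnames(mat)[j] %||% paste0("par", j),
               mean = mean(v), sd = stats::sd(v),
               sem = stats::sd(v) / sqrt(length(v)),
               lag1_autocorr = if (length(v) >= 10)
                 suppressWarnings(lag1_autocorrelation(v)) else NA_real_,
               pMCMC = pmcmc(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

pmcmc <- function(v) {
  above <- mean(v > 0)
  below <- mean(v < 0)
  p <- 2 * min(above, below)
  if (stats::sd(v) == 0) {
    # degenerate constant chain: 0 when off zero, else 1
    return(if (all(v == 0)) 1 else 0)
  }
  p
}

#' Extract estimated breeding values
#'
#' One EBV per pedigree animal per trait (including unphenotyped
#' ancestors), the posterior mean of the animal effect on the liability
#' (probit) scale, with its posterior SD. Breeding values are relative
#' quantities: they rank animals by transmitted disease liability but have
#' no direct interpretation as a disease severity.
#'
#' @param fit a [thram] fit.
#' @return Data frame with columns `animal`, `trait`, `ebv`, `ebv_sd`.
#' @export
extract_ebv <- function(fit) {
  stopifnot(inherits(fit, "thram"))
  out <- do.call(rbind, lapply(seq_along(fit$traits), function(m) {
    data.frame(animal = rownames(fit$ebv_mean),
               trait = fit$traits[m],
               ebv = fit$ebv_mean[, m],
               ebv_sd = fit$ebv_sd[, m],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Liability-scale heritability
#'
#' `h2 = g / (g + 1)` with `g` the additive genetic variance and the
#' residual variance fixed at 1. Applied sample-wise: pass the vector of
#' stored `g` draws to obtain the posterior of `h2` (the reported estimate
#' is the posterior mean of `h2`, not `h2` of the posterior-mean `g`).
#'
#' @param g additive genetic variance (scalar or vector of samples; must be
#'   positive).
#' @return `g / (g + 1)`, same shape as `g`.
#' @examples
#' heritability(1)  # 0.5
#' heritability(3)  # 0.75
#' @export
heritability <- function(g) {
  bad <- !is.na(g) & g <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive genetic variance sample(s) dropped")
    g[bad] <- NA_real_
  }
  g / (g + 1)
}

#' Genetic correlation between two traits
#'
#' `r_g = g_he / sqrt(g_h * g_e)`, applied sample-wise over stored draws of
#' the genetic covariance matrix and summarised as mean and SD.
#'
#' @param g_h,g_e genetic variances (vectors of samples).
#' @param g_he genetic covariance (vector of samples).
#' @return Vector of sample-wise correlations.
#' @examples
#' genetic_correlation(2, 0.5, -0.5)  # -0.5
#' @export
genetic_correlation <- function(g_h, g_e, g_he) {
  bad <- !is.na(g_h) & (g_h <= 0 | g_e <= 0)
  if (any(bad)) {
    warning(sum(bad), " non-positive-definite sample(s) dropped")
    g_h[bad] <- NA_real_
  }
  g_he / sqrt(g_h * g_e)
}

#' Sex and age effect report
#'
#' Posterior summaries of the male-minus-female contrast and the age
#' regression slope for each trait, with pMCMC and a significance flag at
#' 0.05. By the sign convention, a negative sex contrast means males have
#' more favourable (lower-liability) evaluations.
#'
#' @param fit a [thram] fit.
#' @param alpha significance level for the flag (default 0.05).
#' @return Data frame with columns `trait`, `effect`, `estimate`, `sd`,
#'   `pMCMC`, `significant`.
#' @export
sex_age_report <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "thram"))
  beta <- fit$samples$beta
  rows <- list()
  for (m in seq_along(fit$traits)) {
    tr <- fit$traits[m]
    for (eff in c("sex", "age")) {
      patt <- if (eff == "sex") paste0("^", tr, ":sexM$")
              else paste0("^", tr, ":age_c$")
      j <- grep(patt, colnames(beta))
      if (!length(j)) next
      v <- beta[, j]
      degenerate <- stats::sd(v) == 0
      if (degenerate)
        warning("constant chain for ", tr, " ", eff,
                " effect; pMCMC degenerate")
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr,
        effect = if (eff == "sex") "sex (M - F)" else "age (per month)",
        estimate = mean(v), sd = stats::sd(v), pMCMC = pmcmc(v),
        significant = !degenerate && pmcmc(v) < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
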