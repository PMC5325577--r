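## S3 methods for fitted threshold animal models.

#' @export
print.thram <- function(x, ...) {
  cat("Threshold (probit liability) animal model\n")
  cat("  traits:", paste(x$traits, collapse = " + "),
      sprintf("(%s categories)", paste(x$ncat, collapse = "/")), "\n")
  cat("  records:", x$n_records, " animals in pedigree:", x$pedigree$n, "\n")
  cat("  chain:", x$chain$iterations, "iterations, burn-in",
      x$chain$burn_in, ", thin", x$chain$thin,
      sprintf("(%d stored)", x$n_stored), "\n")
  g <- x$samples$G0
  for (m in seq_along(x$traits)) {
    gm <- g[, paste0("g_", x$traits[m])]
    h2 <- heritability(gm)
    cat(sprintf("  h2(%s) = %.3f (posterior SD %.3f)\n", x$traits[m],
                mean(h2), stats::sd(h2)))
  }
  if (length(x$traits) == 2L) {
    rg <- genetic_correlation(g[, 1L], g[, 3L], g[, 2L])
    cat(sprintf("  r_g = %.3f (posterior SD %.3f)\n", mean(rg),
                stats::sd(rg)))
  }
  invisible(x)
}

#' Summarise a fitted threshold animal model
#'
#' Posterior means and dispersions of heritabilities, the genetic
#' correlation, variance components, fixed effects (with pMCMC) and
#' cutpoints, plus sampler acceptance rates and convergence checks.
#'
#' @param object a [thram] fit.
#' @param ... unused.
#' @return An object of class `"summary.thram"`.
#' @export
summary.thram <- function(object, ...) {
  g <- object$samples$G0
  h2 <- lapply(seq_along(object$traits), function(m)
    heritability(g[, paste0("g_", object$traits[m])]))
  names(h2) <- object$traits
  rg <- if (length(object$traits) == 2L)
    genetic_correlation(g[, 1L], g[, 3L], g[, 2L]) else NULL
  structure(list(
    traits = object$traits,
    n_records = object$n_records, n_animals = object$pedigree$n,
    chain = object$chain, n_stored = object$n_stored,
    h2 = h2, r_g = rg,
    variance_components = posterior_summary(local({
      m <- object$samples$G0
      if (!is.null(object$samples$r_he))
        m <- cbind(m, r_he = object$samples$r_he)
      m
    })),
    fixed_effects = posterior_summary(object$samples$beta),
    cutpoints = posterior_summary(object$samples$cutpoints),
    sex_age = sex_age_report(object),
    acceptance = object$acceptance,
    convergence = convergence_report(object)
  ), class = "summary.thram")
}

#' @export
print.summary.thram <- function(x, ...) {
  cat("Bivariate threshold animal model" , "\n")
  cat("Records:", x$n_records, " Pedigree animals:", x$n_animals,
      " Stored samples:", x$n_stored, "\n\n")
  cat("Heritabilities (liability scale, h2 = g/(g+1)):\n")
  for (tr in x$traits)
    cat(sprintf("  %-6s %.3f +/- %.3f (posterior mean +/- SD)\n",
                tr, mean(x$h2[[tr]]), stats::sd(x$h2[[tr]])))
  if (!is.null(x$r_g))
    cat(sprintf("Genetic correlation: %.3f +/- %.3f\n",
                mean(x$r_g), stats::sd(x$r_g)))
  cat("\nVariance components:\n")
  print(x$variance_components, digits = 3, row.names = FALSE)
  cat("\nSex and age effects:\n")
  print(x$sex_age, digits = 3, row.names = FALSE)
  cat("\nConvergence:", if (x$convergence$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Posterior-mean fixed effects
#'
#' @param object a [thram] fit.
#' @param ... unused.
#' @return Named numeric vector of posterior-mean fixed-effect coefficients
#'   (per trait, on the liability scale).
#' @export
coef.thram <- function(object, ...) {
  colMeans(object$samples$beta)
}

#' Trace and density plots for a fitted chain
#'
#' @param x a [thram] fit.
#' @param parameters which monitored columns to show (default: variance
#'   components and, if present, the residual correlation).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.thram <- function(x, parameters = NULL, ...) {
  mat <- x$samples$G0
  if (!is.null(x$samples$r_he)) mat <- cbind(mat, r_he = x$samples$r_he)
  if (!is.null(parameters)) mat <- mat[, parameters, drop = FALSE]
  k <- ncol(mat)
  old <- graphics::par(mfrow = c(k, 2), mar = c(3, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (j in seq_len(k)) {
    v <- mat[, j]
    graphics::plot(v, type = "l", xlab = "stored iteration",
                   ylab = colnames(mat)[j], ...)
    if (stats::sd(v) > 0) {
      graphics::plot(stats::density(v), main = "",
                     xlab = colnames(mat)[j])
    } else {
      graphics::plot.new()
    }
  }
  invisible(x)
}

#' Posterior-mean breeding values as random-effect estimates
#'
#' @param object a [thram] fit.
#' @param ... unused.
#' @return Matrix (animals x traits) of posterior-mean animal effects.
#' @export
ranef.thram <- function(object, ...) object$ebv_mean

#' @rdname ranef.thram
#' @param object a [thram] fit.
#' @export
ranef <- function(object, ...) UseMethod("ranef")
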