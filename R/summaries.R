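## Population-level summaries: prevalence, phenotypic and genetic trends by
## birth year, the four-path selection-response decomposition, and the
## breed-inclusion filter.

#' Prevalence of dysplastic scores
#'
#' Percentage of scored dogs with a dysplastic grade: hip scores 5-7
#' (mild/moderate/severe) or elbow scores 2-4 (DJD grades I-III). Hip
#' scores 1-3 are non-dysplastic; borderline hips (score 4) count in the
#' denominator but in neither class.
#'
#' @param records score-record data frame.
#' @param trait `"hip"` or `"elbow"`.
#' @return Percentage in `[0, 100]`.
#' @export
prevalence <- function(records, trait = c("hip", "elbow")) {
  trait <- match.arg(trait)
  v <- records[[paste0(trait, "_score")]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no scored records for trait ", trait)
  dys <- if (trait == "hip") v >= 5L else v >= 2L
  100 * mean(dys)
}

#' Phenotypic trend by birth year
#'
#' Proportion of dogs scored in the most favourable category (hip
#' "excellent" or elbow "normal", score 1) among scored dogs, per birth
#' year. Birth years are taken from the pedigree.
#'
#' @param records score-record data frame.
#' @param pedigree a [pedigree] carrying birth years.
#' @param trait `"hip"` or `"elbow"`.
#' @param category score counted as favourable (default 1).
#' @return Data frame of class `"trend_series"`: `year`, `n`, `proportion`.
#' @export
phenotypic_trend <- function(records, pedigree, trait = c("hip", "elbow"),
                             category = 1L) {
  trait <- match.arg(trait)
  v <- records[[paste0(trait, "_score")]]
  by <- pedigree$entries$birth_year[match(records$animal,
                                          pedigree$entries$animal)]
  keep <- !is.na(v) & !is.na(by)
  v <- v[keep]; by <- by[keep]
  if (!length(v)) stop("no scored records with known birth year")
  years <- sort(unique(by))
  out <- data.frame(
    year = years,
    n = as.integer(table(factor(by, levels = years))),
    proportion = as.numeric(tapply(v == category, factor(by, levels = years),
                                   mean)))
  class(out) <- c("trend_series", "data.frame")
  out
}

#' Genetic trend: mean EBV by year of birth
#'
#' The arithmetic mean of the EBVs of all pedigree animals (phenotyped or
#' not) born in each calendar year, with a loess smooth. On this coding a
#' population improving its genetic merit shows a negative slope across
#' birth years.
#'
#' @param fit a [thram] fit (or a data frame from [extract_ebv()]).
#' @param pedigree pedigree carrying birth years; defaults to the fit's.
#' @param trait trait to summarise (default the fit's first trait).
#' @param span loess span (default 0.75, degree 2).
#' @return Data frame of class `"trend_series"`: `year`, `n`, `mean_ebv`,
#'   `smooth` (`NA` when fewer than 4 years). Animals with unknown birth
#'   year are excluded, with the count in attribute `n_unknown_year`.
#' @export
genetic_trend <- function(fit, pedigree = NULL, trait = NULL, span = 0.75) {
  ebv <- if (inherits(fit, "thram")) extract_ebv(fit) else fit
  if (is.null(pedigree)) {
    stopifnot(inherits(fit, "thram"))
    pedigree <- fit$pedigree
  }
  if (is.null(trait)) trait <- ebv$trait[1L]
  ebv <- ebv[ebv$trait == trait, , drop = FALSE]
  by <- pedigree$entries$birth_year[match(ebv$animal,
                                          pedigree$entries$animal)]
  n_unknown <- sum(is.na(by))
  if (n_unknown > 0)
    message(n_unknown, " animal(s) with unknown birth year excluded")
  keep <- !is.na(by)
  ebv <- ebv[keep, , drop = FALSE]; by <- by[keep]
  years <- sort(unique(by))
  f <- factor(by, levels = years)
  out <- data.frame(year = years,
                    n = as.integer(table(f)),
                    mean_ebv = as.numeric(tapply(ebv$ebv, f, mean)))
  ## loess (span 0.75, degree 2) needs a reasonable number of year points;
  ## short simulated series keep the raw yearly means only
  out$smooth <- if (nrow(out) >= 8L) {
    fitl <- stats::loess(mean_ebv ~ year, data = out, span = span, degree = 2)
    as.numeric(stats::predict(fitl, out$year))
  } else rep(NA_real_, nrow(out))
  attr(out, "n_unknown_year") <- n_unknown
  attr(out, "trait") <- trait
  class(out) <- c("trend_series", "data.frame")
  out
}

#' Four-path selection-response decomposition
#'
#' Splits the genetic trend across the four grand-parental selection
#' pathways -- sires of sires (SS), sires of dams (SD), dams of sires (DS)
#' and dams of dams (DD). For each category the unweighted mean EBV of
#' member animals is computed per birth year, and a quadratic polynomial in
#' birth year (ordinary least squares, years centred at their mean) is
#' fitted when at least three distinct years are present.
#'
#' @param fit a [thram] fit (or an [extract_ebv()] data frame).
#' @param pedigree pedigree carrying birth years; defaults to the fit's.
#' @param trait trait to summarise (default the fit's first trait).
#' @return List of class `"four_path"`: `series` (data frame `category`,
#'   `year`, `n`, `mean_ebv`, `fitted`), `fits` (per-category quadratic
#'   coefficients: intercept, linear, quadratic, with `year_center`),
#'   `paths` (the membership sets).
#' @export
four_path <- function(fit, pedigree = NULL, trait = NULL) {
  ebv <- if (inherits(fit, "thram")) extract_ebv(fit) else fit
  if (is.null(pedigree)) {
    stopifnot(inherits(fit, "thram"))
    pedigree <- fit$pedigree
  }
  if (is.null(trait)) trait <- ebv$trait[1L]
  ebv <- ebv[ebv$trait == trait, , drop = FALSE]
  paths <- grandparent_paths(pedigree)
  by_all <- pedigree$entries$birth_year
  names(by_all) <- pedigree$entries$animal
  series <- list(); fits <- list()
  for (catg in names(paths)) {
    ids <- paths[[catg]]
    if (!length(ids)) {
      warning("four-path category ", catg, " is empty; omitted")
      next
    }
    e <- ebv[match(ids, ebv$animal), , drop = FALSE]
    by <- by_all[ids]
    keep <- !is.na(by) & !is.na(e$ebv)
    e <- e[keep, , drop = FALSE]; by <- by[keep]
    if (!nrow(e)) next
    years <- sort(unique(by))
    f <- factor(by, levels = years)
    d <- data.frame(category = catg, year = years,
                    n = as.integer(table(f)),
                    mean_ebv = as.numeric(tapply(e$ebv, f, mean)),
                    stringsAsFactors = FALSE)
    if (length(years) >= 3L) {
      yc <- d$year - mean(d$year)
      qf <- stats::lm(mean_ebv ~ yc + I(yc^2), data = d)
      d$fitted <- stats::fitted(qf)
      fits[[catg]] <- c(coef(qf), year_center = mean(d$year))
    } else {
      d$fitted <- NA_real_
      fits[catg] <- list(NULL)
    }
    series[[catg]] <- d
  }
  structure(list(series = do.call(rbind, series), fits = fits,
                 paths = paths, trait = trait),
            class = "four_path")
}

#' Compare the sire and dam selection pathways
#'
#' Permutation test of the difference in mean EBV between the sire-derived
#' (SS and SD) and dam-derived (DS and DD) grand-parental groups. This is
#' one interpretation of a sire-versus-dam contribution contrast; animals
#' in both groups are excluded.
#'
#' @param fit a [thram] fit.
#' @param trait trait to test (default the fit's first).
#' @param n_perm permutation count (default 2000).
#' @param birth_year_min restrict to animals born in or after this year
#'   (e.g. the last simulated generation); `NULL` for all.
#' @return List with `diff` (sire-group mean minus dam-group mean), `p`
#'   (two-sided permutation p-value), group sizes.
#' @export
sire_dam_test <- function(fit, trait = NULL, n_perm = 2000,
                          birth_year_min = NULL) {
  stopifnot(inherits(fit, "thram"))
  ebv <- extract_ebv(fit)
  if (is.null(trait)) trait <- fit$traits[1L]
  ebv <- ebv[ebv$trait == trait, , drop = FALSE]
  paths <- grandparent_paths(fit$pedigree)
  sire_g <- union(paths$SS, paths$SD)
  dam_g <- union(paths$DS, paths$DD)
  overlap <- intersect(sire_g, dam_g)
  sire_g <- setdiff(sire_g, overlap)
  dam_g <- setdiff(dam_g, overlap)
  if (!is.null(birth_year_min)) {
    e <- fit$pedigree$entries
    young <- e$animal[!is.na(e$birth_year) & e$birth_year >= birth_year_min]
    sire_g <- intersect(sire_g, young)
    dam_g <- intersect(dam_g, young)
  }
  xs <- ebv$ebv[match(sire_g, ebv$animal)]
  xd <- ebv$ebv[match(dam_g, ebv$animal)]
  if (!length(xs) || !length(xd))
    stop("empty pathway group; cannot compare")
  obs <- mean(xs) - mean(xd)
  pool <- c(xs, xd)
  ns <- length(xs)
  perm <- replicate(n_perm, {
    idx <- sample.int(length(pool), ns)
    mean(pool[idx]) - mean(pool[-idx])
  })
  list(diff = obs, p = mean(abs(perm) >= abs(obs)),
       n_sire_group = length(xs), n_dam_group = length(xd))
}

#' Breed-inclusion filter
#'
#' Includes breeds with more than `min_hip` hip records and more than
#' `min_elbow` elbow records (strict inequalities).
#'
#' @param counts data frame with columns `breed`, `hip`, `elbow`.
#' @param min_hip,min_elbow thresholds (defaults 1000 and 500).
#' @return Character vector of included breeds.
#' @examples
#' breed_filter(data.frame(breed = c("a", "b"),
#'                         hip = c(1000, 1001), elbow = c(600, 501)))
#' @export
breed_filter <- function(counts, min_hip = 1000L, min_elbow = 500L) {
  stopifnot(all(c("breed", "hip", "elbow") %in% names(counts)))
  counts$breed[counts$hip > min_hip & counts$elbow > min_elbow]
}

#' @export
print.trend_series <- function(x, ...) {
  cat("Trend series over", nrow(x), "birth years (",
      min(x$year), "-", max(x$year), ")\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' @export
plot.trend_series <- function(x, ...) {
  ycol <- if ("mean_ebv" %in% names(x)) "mean_ebv" else "proportion"
  graphics::plot(x$year, x[[ycol]], type = "b", pch = 16,
                 xlab = "Year of birth",
                 ylab = if (ycol == "mean_ebv") "Mean EBV" else
                   "Proportion in best category", ...)
  if (!is.null(x$smooth) && any(!is.na(x$smooth)))
    graphics::lines(x$year, x$smooth, col = "red3", lwd = 2)
  invisible(x)
}

#' @export
print.four_path <- function(x, ...) {
  cat("Four-path decomposition (", x$trait, ")\n")
  for (catg in unique(x$series$category)) {
    d <- x$series[x$series$category == catg, ]
    cat(sprintf("  %s: %d animals across %d years, mean EBV %.3f\n",
                catg, sum(d$n), nrow(d), stats::weighted.mean(d$mean_ebv, d$n)))
  }
  invisible(x)
}

#' @export
plot.four_path <- function(x, ...) {
  d <- x$series
  cols <- c(SS = "purple3", SD = "blue3", DS = "olivedrab4", DD = "orange3")
  graphics::plot(range(d$year), range(c(d$mean_ebv, d$fitted), na.rm = TRUE),
                 type = "n", xlab = "Year of birth", ylab = "Mean EBV", ...)
  for (catg in unique(d$category)) {
    dd <- d[d$category == catg, ]
    graphics::points(dd$year, dd$mean_ebv, col = cols[[catg]], pch = 16)
    if (any(!is.na(dd$fitted)))
      graphics::lines(dd$year, dd$fitted, col = cols[[catg]], lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), col = cols,
                   lwd = 2, bty = "n")
  invisible(x)
}
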