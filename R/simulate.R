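#' Define the true parameters of a simulated population
#'
#' Collects every quantity of the generative liability model into a single
#' truth object: genetic (co)variances implied by the requested liability
#' heritabilities, residual correlation, fixed effects, cutpoints, the
#' demography of a multi-generation pedigree, per-trait observation
#' probabilities, and an optional truncation-selection regime.
#'
#' @param traits character, `"hip"` (7 ordered categories), `"elbow"`
#'   (4 categories), or both.
#' @param h2 named numeric, true liability-scale heritability per trait;
#'   additive variance is recovered as `g = h2 / (1 - h2)` since the
#'   residual variance is fixed at 1.
#' @param r_g true genetic correlation between the two traits (bivariate
#'   only).
#' @param r_he true residual correlation for dogs observed on both traits.
#' @param cum_probs named list of cumulative category probabilities per
#'   trait (length K-1, increasing); together with the total liability
#'   variance these fix the intercept and cutpoints so that the first
#'   cutpoint is 0. Defaults mimic screening-registry score distributions:
#'   hips `(0.12, 0.55, 0.88, 0.92, 0.96, 0.99)`, elbows
#'   `(0.80, 0.90, 0.96)`.
#' @param sex_effect named numeric, male-minus-female liability shift per
#'   trait (default 0).
#' @param beta_age named numeric, liability change per month of age at
#'   evaluation (default 0).
#' @param year_effects optional named numeric vector of evaluation-year
#'   effects (default none, i.e. all zero).
#' @param p_obs named numeric, probability a dog is scored on each trait.
#' @param n_founders,n_generations,n_per_gen demography: founder count,
#'   total number of cohorts including the founders, and offspring per
#'   later cohort.
#' @param n_sires,n_dams number of sires/dams drawn as parents of each
#'   cohort (from the previous cohort).
#' @param selection list describing parent selection: `list(type = "none")`
#'   or `list(type = "truncation", proportion =, on = "phenotype"|"true_bv",
#'   sexes = "both"|"sires"|"dams", trait = "hip")`. Truncation keeps the
#'   best (lowest-scoring) fraction of candidates as eligible parents.
#' @param base_year birth year of the founder cohort.
#' @param years_per_gen birth-year spacing between cohorts.
#' @param age_range evaluation ages are drawn uniformly (integer months)
#'   from this range; the default starts at the 24-month eligibility floor.
#' @param seed integer master seed; all generator randomness derives from it.
#'
#' @return An object of class `"sim_truth"` (a named list, with derived
#'   elements `G0` (true genetic covariance matrix), `mu` and `cutpoints`).
#' @export
sim_truth <- function(traits = c("hip", "elbow"),
                      h2 = c(hip = 0.57, elbow = 0.29),
                      r_g = 0.5, r_he = 0.2,
                      cum_probs = NULL,
                      sex_effect = NULL, beta_age = NULL,
                      year_effects = NULL,
                      p_obs = c(hip = 1, elbow = 0.7),
                      n_founders = 300L, n_generations = 4L,
                      n_per_gen = 400L, n_sires = 60L, n_dams = 150L,
                      selection = list(type = "none"),
                      base_year = 2000L, years_per_gen = 2L,
                      age_range = c(24L, 120L),
                      seed = 1L) {
  traits <- match.arg(traits, c("hip", "elbow"), several.ok = TRUE)
  ntr <- length(traits)
  ncat <- c(hip = 7L, elbow = 4L)[traits]
  h2 <- resolve_per_trait(h2, traits, "h2")
  if (any(h2 <= 0) || any(h2 >= 1)) stop("true h2 must lie in (0, 1)")
  g <- h2 / (1 - h2)
  G0 <- diag(g, ntr)
  if (ntr == 2L) {
    G0[1, 2] <- G0[2, 1] <- r_g * sqrt(prod(g))
    if (abs(r_g) > 1) stop("r_g must lie in [-1, 1]")
    if (abs(r_he) >= 1) stop("r_he must lie in (-1, 1)")
  }
  dimnames(G0) <- list(traits, traits)
  default_cp <- list(hip = c(0.12, 0.55, 0.88, 0.92, 0.96, 0.99),
                     elbow = c(0.80, 0.90, 0.96))
  if (is.null(cum_probs)) cum_probs <- default_cp[traits]
  cum_probs <- cum_probs[traits]
  mu <- numeric(ntr); names(mu) <- traits
  cutpoints <- vector("list", ntr); names(cutpoints) <- traits
  for (m in seq_len(ntr)) {
    cp <- cum_probs[[m]]
    if (length(cp) != ncat[m] - 1L || is.unsorted(cp, strictly = TRUE) ||
        any(cp <= 0) || any(cp >= 1))
      stop("cum_probs for ", traits[m], " must be ", ncat[m] - 1L,
           " strictly increasing values in (0,1)")
    sd_tot <- sqrt(g[m] + 1)
    q <- stats::qnorm(cp) * sd_tot
    mu[m] <- -q[1L]              # places the first cutpoint at 0
    cutpoints[[m]] <- q - q[1L]
  }
  if (is.null(sex_effect)) sex_effect <- stats::setNames(numeric(ntr), traits)
  else sex_effect <- resolve_per_trait(sex_effect, traits, "sex_effect")
  if (is.null(beta_age)) beta_age <- stats::setNames(numeric(ntr), traits)
  else beta_age <- resolve_per_trait(beta_age, traits, "beta_age")
  p_obs <- resolve_per_trait(p_obs, traits, "p_obs")
  sel_types <- c("none", "truncation")
  if (!is.list(selection) || !selection$type %in% sel_types)
    stop("selection$type must be one of: ", paste(sel_types, collapse = ", "))
  if (selection$type == "truncation") {
    selection$proportion <- selection$proportion %||% 0.2
    selection$on <- selection$on %||% "phenotype"
    selection$sexes <- selection$sexes %||% "both"
    selection$trait <- selection$trait %||% traits[1L]
    if (selection$proportion <= 0 || selection$proportion > 1)
      stop("truncation proportion must lie in (0, 1]")
  }
  structure(list(
    traits = traits, ncat = ncat, h2 = h2, g = g, G0 = G0,
    r_g = if (ntr == 2L) r_g else NA_real_,
    r_he = if (ntr == 2L) r_he else NA_real_,
    mu = mu, cutpoints = cutpoints, cum_probs = cum_probs,
    sex_effect = sex_effect, beta_age = beta_age,
    year_effects = year_effects, p_obs = p_obs,
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_per_gen = as.integer(n_per_gen),
    n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
    selection = selection, base_year = as.integer(base_year),
    years_per_gen = as.integer(years_per_gen),
    age_range = as.integer(age_range), seed = as.integer(seed)
  ), class = "sim_truth")
}

resolve_per_trait <- function(x, traits, what) {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(traits))
    if (length(x) != length(traits))
      stop(what, " must be named by trait or of length ", length(traits))
    names(x) <- traits
    return(x)
  }
  if (!all(traits %in% names(x)))
    stop(what, " missing entries for: ",
         paste(setdiff(traits, names(x)), collapse = ", "))
  x[traits]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a multi-generation pedigree with true breeding values
#'
#' Forward simulation with non-overlapping cohorts. Founder breeding values
#' are drawn from `N(0, G0)`; an offspring's breeding value is the parental
#' mean plus a Mendelian deviation with covariance
#' `G0/2 * (1 - (F_s + F_d)/2)`. When the truth specifies truncation
#' selection, parents of each cohort are the surviving fraction after
#' selection on the simulated phenotype (or on the true breeding value);
#' the returned records are the same realisations selection acted on.
#'
#' @param truth a [sim_truth] object.
#' @return A list of class `"sim_dataset"` with elements `pedigree` (a
#'   [pedigree]), `bv` (n x traits matrix of true breeding values),
#'   `records` (a score-record data frame; see [simulate_scores()]),
#'   `liabilities` (matrix of realised liabilities, `NA` where unscored)
#'   and `truth`.
#' @export
simulate_dataset <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed)
  ntr <- length(truth$traits)
  Lg <- t(chol(truth$G0))
  nf <- truth$n_founders

  animal <- paste0("F", seq_len(nf))
  sire <- rep(NA_character_, nf); dam <- rep(NA_character_, nf)
  sex <- rep(c("M", "F"), length.out = nf)
  byear <- rep(truth$base_year, nf)
  bv <- t(Lg %*% matrix(stats::rnorm(ntr * nf), ntr, nf))
  Fcoef <- rep(0, nf)

  rec_list <- list(); liab_list <- list()
  cohort <- seq_len(nf)
  sr <- simulate_scores(animal[cohort], sex[cohort], byear[cohort],
                        bv[cohort, , drop = FALSE], truth)
  rec_list[[1L]] <- sr$records; liab_list[[1L]] <- sr$liabilities

  if (truth$n_generations > 1L) {
    for (gen in 2L:truth$n_generations) {
      cand <- cohort
      sires_pool <- select_parents(cand, animal, sex, sr, bv, truth, "M")
      dams_pool <- select_parents(cand, animal, sex, sr, bv, truth, "F")
      if (!length(sires_pool) || !length(dams_pool))
        stop("selection left no eligible ",
             if (!length(sires_pool)) "sires" else "dams",
             " for generation ", gen)
      use_s <- resample(sires_pool, min(truth$n_sires, length(sires_pool)))
      use_d <- resample(dams_pool, min(truth$n_dams, length(dams_pool)))
      n_new <- truth$n_per_gen
      s_idx <- resample(use_s, n_new, replace = TRUE)
      d_idx <- resample(use_d, n_new, replace = TRUE)
      new_ids <- paste0("G", gen, "_", seq_len(n_new))
      new_sex <- sample(c("M", "F"), n_new, replace = TRUE)
      ## Mendelian deviations scaled by parental inbreeding
      scale <- sqrt(0.5 * (1 - 0.5 * (Fcoef[s_idx] + Fcoef[d_idx])))
      dev <- t(Lg %*% matrix(stats::rnorm(ntr * n_new), ntr, n_new)) * scale
      new_bv <- 0.5 * (bv[s_idx, , drop = FALSE] + bv[d_idx, , drop = FALSE]) + dev

      animal <- c(animal, new_ids)
      sire <- c(sire, animal[s_idx]); dam <- c(dam, animal[d_idx])
      sex <- c(sex, new_sex)
      byear <- c(byear, rep(truth$base_year +
                              (gen - 1L) * truth$years_per_gen, n_new))
      bv <- rbind(bv, new_bv)
      cohort <- seq.int(length(animal) - n_new + 1L, length(animal))
      ## inbreeding of the new cohort (parents' F already known)
      ped_now <- pedigree(animal, sire, dam, sex = sex, birth_year = byear)
      Ford <- inbreeding(ped_now)[animal]   # back to build order
      Fcoef <- as.numeric(Ford)
      sr <- simulate_scores(animal[cohort], sex[cohort], byear[cohort],
                            bv[cohort, , drop = FALSE], truth)
      rec_list[[gen]] <- sr$records; liab_list[[gen]] <- sr$liabilities
    }
  }

  ped <- pedigree(animal, sire, dam, sex = sex, birth_year = byear)
  ## pedigree() topologically re-orders; cohort construction order already is
  ## topological, but align bv to the pedigree's order by id to be safe
  ord <- match(ped$entries$animal, animal)
  bv <- bv[ord, , drop = FALSE]
  rownames(bv) <- ped$entries$animal
  colnames(bv) <- truth$traits
  records <- do.call(rbind, rec_list)
  liab <- do.call(rbind, liab_list)
  rownames(records) <- NULL
  structure(list(pedigree = ped, bv = bv, records = records,
                 liabilities = liab, truth = truth),
            class = "sim_dataset")
}

#' @rdname simulate_dataset
#' @export
simulate_pedigree <- function(truth) {
  ds <- simulate_dataset(truth)
  list(pedigree = ds$pedigree, bv = ds$bv)
}

resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

## Candidate parents of one sex after (optional) truncation selection.
select_parents <- function(cand, animal, sex, sr, bv, truth, want_sex) {
  cand <- cand[sex[cand] == want_sex]
  sel <- truth$selection
  if (sel$type == "none") return(cand)
  apply_sex <- switch(sel$sexes, both = c("M", "F"), sires = "M", dams = "F")
  if (!want_sex %in% apply_sex || sel$proportion >= 1) return(cand)
  if (sel$on == "true_bv") {
    crit <- bv[cand, match(sel$trait, truth$traits)]
  } else {
    sc <- sr$records[[paste0(sel$trait, "_score")]]
    crit <- sc[match(animal[cand], sr$records$animal)]
    crit[is.na(crit)] <- max(truth$ncat[sel$trait]) + 1L  # unscored worst
  }
  keep <- ceiling(sel$proportion * length(cand))
  ## lowest scores are most favourable; ties broken by an independent draw
  cand[order(crit, stats::runif(length(cand)))[seq_len(keep)]]
}

#' Simulate ordinal score records for a set of animals
#'
#' Runs the liability model generatively: for each animal the liability of
#' trait m is `mu_m + sex_effect_m + beta_m * age + year_effect + bv_m + e`,
#' with unit residual variances and residual correlation `r_he` between the
#' two traits; the ordinal score is one plus the number of cutpoints below
#' the liability. Ages at evaluation are uniform integers over the truth's
#' `age_range`; birth months are uniform so evaluation years follow from
#' the birth date and age. Per-trait missingness is applied afterwards;
#' records missing both traits are dropped.
#'
#' @param animal,sex,birth_year vectors describing the animals.
#' @param bv matrix of true breeding values (animals x traits).
#' @param truth a [sim_truth] object.
#' @return list with `records` (data frame: `animal`, `sex`, `birth_date`
#'   (`"YYYY-MM"`), `age_months`, `eval_year`, `hip_score`/`elbow_score` as
#'   present, `NA` when unscored) and `liabilities` (matrix, `NA` where the
#'   trait was not observed).
#' @export
simulate_scores <- function(animal, sex, birth_year, bv, truth) {
  n <- length(animal)
  ntr <- length(truth$traits)
  age <- sample(seq(truth$age_range[1L], truth$age_range[2L]), n, replace = TRUE)
  bmonth <- sample.int(12L, n, replace = TRUE)
  eval_year <- birth_year + (bmonth - 1L + age) %/% 12L

  R <- diag(ntr)
  if (ntr == 2L) R[1, 2] <- R[2, 1] <- truth$r_he
  e <- matrix(stats::rnorm(n * ntr), n, ntr) %*% chol(R)

  liab <- matrix(NA_real_, n, ntr, dimnames = list(animal, truth$traits))
  scores <- matrix(NA_integer_, n, ntr)
  for (m in seq_len(ntr)) {
    tr <- truth$traits[m]
    yr_eff <- 0
    if (!is.null(truth$year_effects)) {
      ye <- truth$year_effects[as.character(eval_year)]
      yr_eff <- ifelse(is.na(ye), 0, ye)
    }
    l <- truth$mu[m] + ifelse(sex == "M", truth$sex_effect[m], 0) +
      truth$beta_age[m] * age + yr_eff + bv[, m] + e[, m]
    liab[, m] <- l
    scores[, m] <- 1L + rowSums(outer(l, truth$cutpoints[[m]], ">"))
  }
  ## per-trait voluntary-participation missingness
  for (m in seq_len(ntr)) {
    miss <- stats::runif(n) > truth$p_obs[m]
    scores[miss, m] <- NA_integer_
    liab[miss, m] <- NA_real_
  }
  rec <- data.frame(animal = animal, sex = sex,
                    birth_date = sprintf("%d-%02d", birth_year, bmonth),
                    age_months = age, eval_year = eval_year,
                    stringsAsFactors = FALSE)
  for (m in seq_len(ntr))
    rec[[paste0(truth$traits[m], "_score")]] <- scores[, m]
  keep <- rowSums(!is.na(scores)) > 0L
  list(records = rec[keep, , drop = FALSE],
       liabilities = liab[keep, , drop = FALSE])
}

#' Truncation selection of parents on observed scores
#'
#' Keeps the most favourable (lowest-scoring) fraction of candidates,
#' breaking ties by an independent uniform draw. Exposed as the selection
#' primitive the forward simulator applies between generations.
#'
#' @param ids candidate animal identifiers.
#' @param score the ordinal score used as the selection criterion (`NA`
#'   treated as worst).
#' @param proportion fraction retained, in (0, 1].
#' @return Character vector of selected ids.
#' @export
apply_truncation_selection <- function(ids, score, proportion) {
  stopifnot(proportion > 0, proportion <= 1)
  score[is.na(score)] <- Inf
  keep <- ceiling(proportion * length(ids))
  ids[order(score, stats::runif(length(ids)))[seq_len(keep)]]
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth:", paste(x$traits, collapse = " + "),
      sprintf("(h2 = %s)", paste(signif(x$h2, 3), collapse = ", ")), "\n")
  if (length(x$traits) == 2L)
    cat("  r_g =", x$r_g, " r_he =", x$r_he, "\n")
  cat("  demography:", x$n_founders, "founders,", x$n_generations,
      "cohorts x", x$n_per_gen, "\n")
  cat("  selection:", x$selection$type, "\n")
  invisible(x)
}
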