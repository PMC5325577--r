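#' Prior specification for the threshold animal model
#'
#' Fixed effects receive independent diffuse normal priors with mean zero
#' and variance `exp(10)`. The genetic (co)variance matrix G0 receives an
#' inverse-Wishart prior with scale `V * nu` and degree-of-belief `nu`
#' (mode `V * nu / (nu + 2)`); the default `nu = 0.002` makes it effectively
#' flat over the variances. Residual variances are fixed at 1 per trait
#' (the identification constraint of the probit threshold model); the
#' residual correlation of doubly-observed dogs carries the same
#' inverse-Wishart form constrained to keep R0 positive definite.
#'
#' @param fixed_effect_variance prior variance of each fixed effect.
#' @param V inverse-Wishart scale parameter for G0 (matrix of trait
#'   dimension, default identity).
#' @param nu inverse-Wishart degree-of-belief parameter (> 0).
#' @return A list of class `"thram_priors"`.
#' @export
thram_priors <- function(fixed_effect_variance = exp(10), V = NULL,
                         nu = 0.002) {
  if (nu <= 0) stop("nu must be positive")
  if (fixed_effect_variance <= 0) stop("fixed_effect_variance must be positive")
  structure(list(fixed_effect_variance = fixed_effect_variance, V = V,
                 nu = nu), class = "thram_priors")
}

#' Mode of the inverse-Wishart prior
#'
#' @param V scale parameter (scalar or matrix).
#' @param nu degree-of-belief parameter (> 0).
#' @return `V * nu / (nu + 2)`.
#' @examples
#' iw_mode(1, 2)      # 0.5
#' iw_mode(1, 0.002)  # ~9.99e-4
#' @export
iw_mode <- function(V, nu) {
  if (nu <= 0) stop("nu must be positive")
  V * nu / (nu + 2)
}

#' MCMC schedule for the Gibbs sampler
#'
#' @param iterations total Gibbs rounds (default 100000).
#' @param burn_in discarded initial rounds (default 20000).
#' @param thin storage interval (default 20); the default schedule stores
#'   4000 samples.
#' @param seed integer seed for the chain.
#' @return A list of class `"thram_chain"`.
#' @export
thram_chain <- function(iterations = 100000L, burn_in = 20000L, thin = 20L,
                        seed = 1L) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= iterations) stop("burn_in must be below iterations")
  if (burn_in < 0L) stop("burn_in must be non-negative")
  if (thin < 1L) stop("thin must be at least 1")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)), class = "thram_chain")
}

#' Number of stored posterior samples under a schedule
#'
#' @param iterations,burn_in,thin the chain schedule.
#' @return `floor((iterations - burn_in) / thin)`; the default schedule
#'   yields 4000.
#' @examples
#' stored_samples(100000, 20000, 20)  # 4000
#' @export
stored_samples <- function(iterations, burn_in, thin) {
  if (burn_in >= iterations) stop("burn_in must be below iterations")
  if (thin < 1) stop("thin must be at least 1")
  as.integer((iterations - burn_in) %/% thin)
}

#' Fit a threshold (probit liability) animal model by Gibbs sampling
#'
#' Fits the ordered-categorical liability model
#' \deqn{y = \mu + sex + \beta\,age + year + animal + e}
#' per trait, with animal effects distributed `N(0, G0 (x) A)` for the
#' pedigree numerator relationship matrix A and unit residual variances
#' (residual correlation `r_he` between traits for dogs scored on both).
#' The sampler augments latent liabilities from truncated normals, draws
#' all fixed and animal effects jointly from the sparse mixed-model
#' equations, draws G0 from its conjugate inverse-Wishart conditional, and
#' updates cutpoints (first fixed at 0 per trait) and `r_he` by adaptive
#' random-walk Metropolis-Hastings.
#'
#' @param records score-record data frame (see [read_records()]): columns
#'   `animal`, `sex`, `age_months`, `eval_year` (or `birth_date` from which
#'   it is derived) and `<trait>_score` columns.
#' @param pedigree a [pedigree] object containing every recorded animal.
#' @param traits `"hip"`, `"elbow"` or both; hip scores have 7 ordered
#'   categories, elbow scores 4.
#' @param priors a [thram_priors] object.
#' @param chain a [thram_chain] schedule.
#' @param min_age_months age filter applied before fitting (default 24).
#' @param store_animals keep all thinned animal-effect samples (memory
#'   heavy); running means and SDs are always kept.
#' @param verbose print progress.
#' @return An object of class `"thram"` with components `samples` (thinned
#'   posterior draws of G0, `r_he`, fixed effects and cutpoints),
#'   `ebv` (per-animal, per-trait posterior mean and SD of breeding
#'   values), `acceptance`, `design`, `chain`, `priors` and `pedigree`.
#' @seealso [summary.thram()], [extract_ebv()], [convergence_report()]
#' @export
thram <- function(records, pedigree, traits = c("hip", "elbow"),
                  priors = thram_priors(), chain = thram_chain(),
                  min_age_months = 24, store_animals = FALSE,
                  verbose = FALSE) {
  cl <- match.call()
  stopifnot(inherits(pedigree, "pedigree"))
  traits <- match.arg(traits, c("hip", "elbow"), several.ok = TRUE)
  ntr <- length(traits)
  ncat <- trait_categories[traits]

  records <- filter_records(records, min_age_months)
  n_dropped <- attr(records, "n_dropped")
  if (is.null(records$eval_year))
    records$eval_year <- derive_eval_year(records$birth_date,
                                          records$age_months)
  no_year <- is.na(records$eval_year)
  if (any(no_year)) {
    message(sum(no_year), " record(s) without resolvable evaluation year excluded")
    records <- records[!no_year, , drop = FALSE]
  }

  score_cols <- paste0(traits, "_score")
  missing_cols <- setdiff(score_cols, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  scores <- as.matrix(records[score_cols])
  keep <- rowSums(!is.na(scores)) > 0L
  records <- records[keep, , drop = FALSE]
  scores <- scores[keep, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records with any observed score")

  unknown <- setdiff(records$animal, pedigree$entries$animal)
  if (length(unknown))
    stop("record animal(s) absent from pedigree: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  for (m in seq_len(ntr)) {
    v <- scores[, m]
    if (any(!is.na(v) & (v < 1L | v > ncat[m])))
      stop(traits[m], " scores outside 1..", ncat[m])
    if (length(unique(v[!is.na(v)])) < 2L && any(!is.na(v)))
      stop("trait ", traits[m], " has a single observed category; ",
           "the threshold model is degenerate")
  }

  ## ---- fixed-effect design (shared across traits, coefficients per trait)
  age_center <- mean(records$age_months)
  dat <- data.frame(age_c = records$age_months - age_center)
  terms <- "1"
  sex_levels <- sort(unique(records$sex[!is.na(records$sex)]))
  if (length(sex_levels) == 2L) {
    dat$sex <- factor(records$sex, levels = c("F", "M"))  # male minus female
    terms <- c(terms, "sex")
  }
  terms <- c(terms, "age_c")
  year_levels <- sort(unique(records$eval_year))
  if (length(year_levels) > 1L) {
    dat$year <- factor(records$eval_year, levels = year_levels)
    terms <- c(terms, "year")
  }
  X <- stats::model.matrix(stats::reformulate(terms), dat)
  p <- ncol(X)

  rec_anim <- match(records$animal, pedigree$entries$animal)
  catm <- scores
  catm[is.na(catm)] <- 0L
  storage.mode(catm) <- "integer"

  V <- priors$V
  if (is.null(V)) V <- diag(ntr)
  V <- as.matrix(V)
  if (!isTRUE(all.equal(dim(V), c(ntr, ntr))))
    stop("prior V must be a ", ntr, "x", ntr, " matrix")

  obs <- scores
  obs[] <- !is.na(scores)
  mme <- build_mme(pedigree, X, rec_anim, matrix(as.logical(obs), ncol = ntr),
                   1 / priors$fixed_effect_variance)

  ## ---- initial values: cutpoints from marginal frequencies, rescaled to
  ## the anchored parameterisation (first cutpoint 0, second 1)
  init_cut <- vector("list", ntr)
  init_beta <- matrix(0, p, ntr)
  for (m in seq_len(ntr)) {
    cnt <- tabulate(scores[, m], nbins = ncat[m]) + 0.5
    cum <- cumsum(cnt) / sum(cnt)
    q <- stats::qnorm(cum[-ncat[m]])
    cr <- q - q[1L]
    if (ncat[m] > 2L) {
      anchor <- cr[2L]
      if (!is.finite(anchor) || anchor <= 0) anchor <- 1
      cr <- cr / anchor
      init_beta[1L, m] <- -q[1L] / anchor
    } else {
      init_beta[1L, m] <- -q[1L]
    }
    init_cut[[m]] <- cr
  }
  init <- list(cutpoints = init_cut, beta = as.numeric(init_beta),
               G0 = diag(ntr), r_he = 0, res_var = rep(1, ntr))

  set.seed(chain$seed)
  t0 <- proc.time()[["elapsed"]]
  res <- .gibbs_chain_cpp(
    n_anim = pedigree$n, ntraits = ntr, p = p,
    rec_anim = rec_anim - 1L, X = X, cat = catm,
    ncat = as.integer(ncat),
    Qp = mme$Qp, Qi = mme$Qi, basis = mme$basis,
    diag_idx = mme$diag_idx,
    Ati = mme$Ati, Atj = mme$Atj, Atx = mme$Atx,
    Vprior = V, nu = priors$nu,
    niter = chain$iterations, burnin = chain$burn_in, thin = chain$thin,
    init = init, store_animals = store_animals, verbose = verbose)
  elapsed <- proc.time()[["elapsed"]] - t0

  ## ---- label the sample matrices
  gnames <- if (ntr == 2L)
    c(paste0("g_", traits[1L]), paste0("g_", traits[1L], "_", traits[2L]),
      paste0("g_", traits[2L]))
  else paste0("g_", traits)
  colnames(res$G0) <- gnames
  colnames(res$beta) <- paste(rep(traits, each = p), colnames(X), sep = ":")
  cutnames <- unlist(lapply(seq_len(ntr), function(m)
    paste0(traits[m], ":cut", seq_len(ncat[m] - 1L))))
  colnames(res$cutpoints) <- cutnames
  colnames(res$res_var) <- paste0("v_", traits)
  dimnames(res$ebv_mean) <- list(pedigree$entries$animal, traits)
  dimnames(res$ebv_sd) <- list(pedigree$entries$animal, traits)

  structure(list(
    call = cl, traits = traits, ncat = ncat,
    samples = list(G0 = res$G0,
                   r_he = if (ntr == 2L) as.numeric(res$r_he) else NULL,
                   beta = res$beta, cutpoints = res$cutpoints,
                   res_var = res$res_var),
    animals = if (store_animals) res$animals else NULL,
    ebv_mean = res$ebv_mean, ebv_sd = res$ebv_sd,
    pedigree = pedigree,
    n_records = nrow(records), n_dropped_age = n_dropped,
    design = list(age_center = age_center, sex_levels = sex_levels,
                  year_levels = year_levels, colnames = colnames(X)),
    acceptance = list(cutpoints = stats::setNames(
                        as.numeric(res$accept_cutpoints), traits),
                      r_he = res$accept_r_he,
                      step_cutpoints = as.numeric(res$step_cutpoints),
                      step_r_he = res$step_r_he),
    jitter_count = res$jitter_count,
    n_stored = res$n_stored,
    chain = chain, priors = priors, elapsed = elapsed
  ), class = "thram")
}

#' Sample the genetic (co)variance prior through the Gibbs machinery
#'
#' Runs the sampler with no records attached: the chain then alternates
#' between drawing animal effects from `N(0, G0 (x) A)` and G0 from its
#' conditional inverse-Wishart, whose stationary marginal for G0 is the
#' inverse-Wishart prior itself. Used to verify the variance-component
#' machinery against the prior (choose a proper `nu` for a well-defined
#' comparison). Draws are returned on the internal (unrescaled) scale.
#'
#' @param ped a [pedigree].
#' @param traits trait set (determines the dimension of G0).
#' @param priors a [thram_priors] object.
#' @param chain a [thram_chain] schedule.
#' @return Matrix of stored G0 draws.
#' @keywords internal
#' @export
prior_chain <- function(ped, traits = "hip", priors = thram_priors(),
                        chain = thram_chain(4000, 0, 1)) {
  traits <- match.arg(traits, c("hip", "elbow"), several.ok = TRUE)
  ntr <- length(traits)
  ncat <- trait_categories[traits]
  X <- matrix(numeric(0), nrow = 0L, ncol = 1L,
              dimnames = list(NULL, "(Intercept)"))
  mme <- build_mme(ped, X, integer(0), matrix(logical(0), 0L, ntr),
                   1 / priors$fixed_effect_variance)
  V <- priors$V
  if (is.null(V)) V <- diag(ntr)
  init <- list(cutpoints = lapply(ncat, function(K)
                 c(0, seq_len(K - 2L))),
               beta = numeric(ntr), G0 = diag(ntr), r_he = 0,
               res_var = rep(1, ntr))
  set.seed(chain$seed)
  res <- .gibbs_chain_cpp(
    n_anim = ped$n, ntraits = ntr, p = 1L,
    rec_anim = integer(0), X = X,
    cat = matrix(integer(0), 0L, ntr), ncat = as.integer(ncat),
    Qp = mme$Qp, Qi = mme$Qi, basis = mme$basis, diag_idx = mme$diag_idx,
    Ati = mme$Ati, Atj = mme$Atj, Atx = mme$Atx,
    Vprior = as.matrix(V), nu = priors$nu,
    niter = chain$iterations, burnin = chain$burn_in, thin = chain$thin,
    init = init, store_animals = FALSE, verbose = FALSE)
  ## undo the reporting rescale: internal G0 = stored G0 * res_var scaling
  lam2 <- res$res_var
  if (ntr == 1L) {
    res$G0[, 1L] * lam2[, 1L]
  } else {
    cbind(res$G0[, 1L] * lam2[, 1L],
          res$G0[, 2L] * sqrt(lam2[, 1L] * lam2[, 2L]),
          res$G0[, 3L] * lam2[, 2L])
  }
}

## ---- sparse mixed-model-equation structures -------------------------------
## Assembles the coefficient matrix of the joint location system as a fixed
## sparsity pattern with per-iteration scalar weights:
##   Q = B_prior + sum_s alpha_s B_s
## where the bases are (univariate) prior/data/A-inverse or (bivariate)
## prior, singly- and doubly-observed crossproducts, and the three A-inverse
## placements for G0^{-1} (x) A^{-1}. The symbolic Cholesky (fill-reducing
## permutation, factor pattern, row lists) is computed once here; the C++
## sampler refactorises numerically every iteration.
build_mme <- function(ped, X, rec_anim, obs, fixed_prec) {
  n <- ped$n
  p <- ncol(X)
  ntr <- ncol(obs)
  blk <- p + n
  ntot <- ntr * blk
  nrec <- nrow(X)

  Ainv <- inverse_relationship(ped)
  At <- methods::as(methods::as(Ainv, "generalMatrix"), "TsparseMatrix")

  Z <- Matrix::sparseMatrix(i = seq_len(nrec), j = rec_anim,
                            dims = c(nrec, n))
  W <- methods::cbind2(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                   "CsparseMatrix"), Z)

  tripl <- function(M, oi, oj) {
    Tm <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    list(i = Tm@i + oi, j = Tm@j + oj, x = Tm@x)
  }
  assemble <- function(trs) {
    Matrix::sparseMatrix(i = unlist(lapply(trs, `[[`, "i")),
                         j = unlist(lapply(trs, `[[`, "j")),
                         x = unlist(lapply(trs, `[[`, "x")),
                         dims = c(ntot, ntot), index1 = FALSE)
  }
  cross_basis <- function(rows, bi, bj) {
    Wi <- W[rows, , drop = FALSE]
    if (bi == bj) return(assemble(list(
      tripl(Matrix::crossprod(Wi), (bi - 1L) * blk, (bi - 1L) * blk))))
    Cij <- Matrix::crossprod(Wi, Wi)  # same rows both traits (doubly observed)
    assemble(list(tripl(Cij, (bi - 1L) * blk, (bj - 1L) * blk),
                  tripl(Matrix::t(Cij), (bj - 1L) * blk, (bi - 1L) * blk)))
  }
  ainv_basis <- function(bi, bj) {
    if (bi == bj) return(assemble(list(
      tripl(Ainv, (bi - 1L) * blk + p, (bi - 1L) * blk + p))))
    assemble(list(tripl(Ainv, (bi - 1L) * blk + p, (bj - 1L) * blk + p),
                  tripl(Ainv, (bj - 1L) * blk + p, (bi - 1L) * blk + p)))
  }
  prior_idx <- unlist(lapply(seq_len(ntr), function(m)
    (m - 1L) * blk + seq_len(p)))
  B_prior <- Matrix::sparseMatrix(i = prior_idx, j = prior_idx,
                                  x = rep(fixed_prec, length(prior_idx)),
                                  dims = c(ntot, ntot))

  if (ntr == 1L) {
    bases <- list(B_prior,
                  cross_basis(which(obs[, 1L]), 1L, 1L),
                  ainv_basis(1L, 1L))
  } else {
    singly1 <- which(obs[, 1L] & !obs[, 2L])
    singly2 <- which(obs[, 2L] & !obs[, 1L])
    doubly <- which(obs[, 1L] & obs[, 2L])
    zero_b <- Matrix::sparseMatrix(i = 1L, j = 1L, x = 0,
                                   dims = c(ntot, ntot))
    cb <- function(rows, bi, bj) if (length(rows)) cross_basis(rows, bi, bj)
                                 else zero_b
    bases <- list(B_prior,
                  cb(singly1, 1L, 1L), cb(singly2, 2L, 2L),
                  cb(doubly, 1L, 1L), cb(doubly, 2L, 2L),
                  cb(doubly, 1L, 2L),
                  ainv_basis(1L, 1L), ainv_basis(2L, 2L), ainv_basis(1L, 2L))
  }

  ## union sparsity pattern (lower triangle, with a guaranteed full diagonal);
  ## the sampler fills values per iteration as basis %*% alpha and CHOLMOD
  ## reuses one symbolic analysis for every numeric refactorisation
  Uabs <- Reduce(`+`, c(lapply(bases, abs), Matrix::Diagonal(ntot, 1)))
  Qlow <- methods::as(Matrix::tril(methods::as(Uabs, "generalMatrix")),
                      "CsparseMatrix")
  Qp <- Qlow@p
  Qi <- Qlow@i
  qcol <- rep(0:(ntot - 1L), diff(Qp))
  qkey <- Qi + as.numeric(ntot) * qcol

  basis_mat <- matrix(0, length(Qi), length(bases))
  for (s in seq_along(bases)) {
    Bt <- methods::as(Matrix::tril(methods::as(bases[[s]], "generalMatrix")),
                      "TsparseMatrix")
    pos <- match(Bt@i + as.numeric(ntot) * Bt@j, qkey)
    if (anyNA(pos)) stop("internal error: basis entry outside union pattern")
    basis_mat[pos, s] <- Bt@x
  }
  diag_idx <- match(0:(ntot - 1L) + as.numeric(ntot) * 0:(ntot - 1L), qkey)
  if (anyNA(diag_idx)) stop("internal error: missing diagonal entry")

  ## full symmetric A-inverse triplets for the quadratic forms a' A^{-1} a
  list(Qp = Qp, Qi = Qi, basis = basis_mat,
       diag_idx = as.integer(diag_idx - 1L),
       Ati = At@i, Atj = At@j, Atx = At@x)
}
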