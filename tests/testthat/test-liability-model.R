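test_that("stored-sample arithmetic matches the chain schedule", {
  expect_equal(stored_samples(100000, 20000, 20), 4000L)
  expect_equal(stored_samples(100, 0, 1), 100L)
  expect_equal(stored_samples(1000, 200, 10), 80L)
  expect_error(stored_samples(100, 100, 1), "burn_in")
  expect_error(thram_chain(100, 200, 1), "burn_in")
  expect_error(thram_chain(100, 10, 0), "thin")
})

test_that("inverse-Wishart mode follows V nu / (nu + 2)", {
  expect_equal(iw_mode(1, 2), 0.5)
  expect_equal(iw_mode(1, 0.002), 0.002 / 2.002)
  expect_equal(iw_mode(3, 1e8), 3, tolerance = 1e-7)  # approaches V
  expect_error(iw_mode(1, 0), "positive")
  expect_error(thram_priors(nu = -1), "positive")
})

test_that("degenerate score data are rejected", {
  tr <- small_truth(seed = 11)
  ds <- simulate_dataset(tr)
  rec <- ds$records
  rec$hip_score <- 1L      # single observed category
  expect_error(
    suppressMessages(thram(rec, ds$pedigree, traits = "hip",
                           chain = thram_chain(100, 10, 1))),
    "single observed category")
  rec2 <- ds$records
  rec2$animal[1] <- "not-in-pedigree"
  expect_error(
    suppressMessages(thram(rec2, ds$pedigree, traits = "hip",
                           chain = thram_chain(100, 10, 1))),
    "not-in-pedigree")
})

test_that("a fitted chain satisfies its structural invariants", {
  cb <- cached_bivariate_fit()
  fit <- cb$fit
  expect_equal(fit$n_stored,
               stored_samples(fit$chain$iterations, fit$chain$burn_in,
                              fit$chain$thin))
  expect_equal(nrow(fit$samples$G0), fit$n_stored)

  # every stored G0 positive definite; implied |r_g| <= 1
  G <- fit$samples$G0
  dets <- G[, 1] * G[, 3] - G[, 2]^2
  expect_true(all(G[, 1] > 0 & G[, 3] > 0 & dets > 0))
  rg <- genetic_correlation(G[, 1], G[, 3], G[, 2])
  expect_true(all(abs(rg) <= 1))
  expect_true(all(abs(fit$samples$r_he) < 1))

  # stored cutpoints strictly increasing within trait, first fixed at 0
  cuts <- fit$samples$cutpoints
  for (tr in fit$traits) {
    cm <- cuts[, grep(paste0("^", tr, ":"), colnames(cuts)), drop = FALSE]
    expect_true(all(cm[, 1] == 0))
    if (ncol(cm) > 1)
      expect_true(all(apply(cm, 1, function(r) all(diff(r) > 0))))
  }

  # cutpoint Metropolis acceptance lands in a sensible band after adaptation
  expect_true(all(fit$acceptance$cutpoints > 0.1 &
                    fit$acceptance$cutpoints < 0.7))
})

test_that("EBVs: shrinkage, exchangeability and ordering", {
  cb <- cached_bivariate_fit()
  fit <- cb$fit
  ebv <- extract_ebv(fit)
  expect_setequal(unique(ebv$trait), c("hip", "elbow"))
  expect_equal(nrow(ebv), 2L * fit$pedigree$n)

  # correlation with simulated true breeding values
  hip <- ebv[ebv$trait == "hip", ]
  truebv <- cb$ds$bv[match(hip$animal, rownames(cb$ds$bv)), "hip"]
  expect_gt(cor(hip$ebv, truebv), 0.4)
})

test_that("an isolated founder's EBV is shrunk toward zero", {
  tr <- small_truth(seed = 13)
  ds <- simulate_dataset(tr)
  ## append an unphenotyped founder with no descendants
  e <- ds$pedigree$entries
  ped2 <- pedigree(c(e$animal, "LONER"), c(e$sire, NA), c(e$dam, NA),
                   sex = c(e$sex, NA), birth_year = c(e$birth_year, NA))
  fit <- suppressMessages(thram(ds$records, ped2, traits = "hip",
                                chain = thram_chain(2000, 500, 5, seed = 3)))
  ebv <- extract_ebv(fit)
  loner <- ebv$ebv[ebv$animal == "LONER"]
  others <- ebv$ebv[ebv$animal != "LONER"]
  expect_lt(abs(loner), 3 * stats::sd(others))
  expect_lt(abs(loner), 0.5 * max(abs(others)))
})

test_that("identical full sibs with identical records get equal EBVs", {
  # symmetric pedigree: two offspring of the same founder pair, same scores
  ped <- pedigree(animal = c("T1", "T2"), sire = c("P1", "P1"),
                  dam = c("P2", "P2"))
  set.seed(4)
  n_extra <- 60
  extra <- pedigree(animal = paste0("E", 1:n_extra),
                    sire = rep(NA, n_extra), dam = rep(NA, n_extra))
  ped_all <- pedigree(
    animal = c(ped$entries$animal, extra$entries$animal),
    sire = c(ped$entries$sire, extra$entries$sire),
    dam = c(ped$entries$dam, extra$entries$dam))
  scores <- sample(1:7, n_extra, replace = TRUE)
  rec <- data.frame(
    animal = c("T1", "T2", paste0("E", 1:n_extra)),
    sex = "F", birth_date = "2000-01",
    age_months = 36L, eval_year = 2003L,
    hip_score = c(5L, 5L, scores), elbow_score = NA_integer_)
  fit <- suppressMessages(thram(rec, ped_all, traits = "hip",
                                chain = thram_chain(6000, 1000, 5, seed = 9)))
  ebv <- fit$ebv_mean[, "hip"]
  mc_tol <- 4 * max(fit$ebv_sd[c("T1", "T2"), "hip"]) / sqrt(fit$n_stored / 10)
  expect_lt(abs(ebv[["T1"]] - ebv[["T2"]]), mc_tol + 0.05)
})

test_that("posterior summaries behave on degenerate and simulated chains", {
  s <- posterior_summary(rep(2, 100))
  expect_equal(s$sd, 0)
  expect_equal(s$pMCMC, 0)          # constant positive chain

  alt <- rep(c(1, -1), 2000)
  s2 <- posterior_summary(alt)
  expect_equal(s2$mean, 0)
  expect_equal(s2$pMCMC, 1)

  set.seed(1)
  s3 <- posterior_summary(rnorm(4000))
  expect_lt(abs(s3$mean), 0.05)     # Monte-Carlo error ~ 1/sqrt(4000)
})

test_that("with no data the Gibbs chain reproduces the inverse-Wishart
           prior for the genetic variance", {
  ped <- random_pedigree(60, seed = 8)
  nu <- 5
  draws <- prior_chain(ped, traits = "hip",
                       priors = thram_priors(V = matrix(1), nu = nu),
                       chain = thram_chain(4000, 500, 1, seed = 2))
  # IW(V nu, nu) with p=1 means g = nu / chisq_nu
  set.seed(3)
  ref <- nu / rchisq(4000, df = nu)
  qs <- seq(0.05, 0.95, by = 0.05)
  qq <- cbind(quantile(draws, qs), quantile(ref, qs))
  expect_gt(cor(qq[, 1], qq[, 2]), 0.98)
  expect_lt(max(abs(log(qq[, 1] / qq[, 2]))), 0.35)
})

test_that("the sparse mixed-model solver matches a dense solve", {
  tr <- small_truth(seed = 21)
  ds <- simulate_dataset(tr)
  ped <- ds$pedigree
  rec <- ds$records
  set.seed(2)
  X <- cbind(1, rnorm(nrow(rec)))
  rec_anim <- match(rec$animal, ped$entries$animal)
  mme <- thram:::build_mme(ped, X, rec_anim,
                           matrix(TRUE, nrow(rec), 1), 1e-4)
  gval <- 0.8
  Qx <- as.numeric(mme$basis %*% c(1, 1, 1 / gval))
  ntot <- length(mme$diag_idx)
  W <- cbind(X, as.matrix(Matrix::sparseMatrix(
    i = seq_len(nrow(rec)), j = rec_anim, dims = c(nrow(rec), ped$n))))
  Qd <- crossprod(W)
  Qd[1:2, 1:2] <- Qd[1:2, 1:2] + diag(1e-4, 2)
  idx <- 3:ntot
  Qd[idx, idx] <- Qd[idx, idx] +
    as.matrix(inverse_relationship(ped)) / gval
  b <- rnorm(ntot)
  x_cpp <- thram:::.chol_solve_cpp(mme$Qp, mme$Qi, Qx, b)
  expect_lt(max(abs(x_cpp - solve(Qd, b))), 1e-9)
})

test_that("the location-draw noise has the inverse of the system matrix
           as its covariance", {
  ped <- random_pedigree(60, seed = 51)
  Ai <- inverse_relationship(ped)
  n <- ped$n
  Q <- Matrix::forceSymmetric(Ai + Matrix::Diagonal(n, 0.5))
  Ql <- methods::as(Matrix::tril(methods::as(Q, "generalMatrix")),
                    "CsparseMatrix")
  set.seed(3)
  draws <- thram:::.noise_draws_cpp(Ql@p, Ql@i, Ql@x, 20000L)
  emp <- stats::cov(draws)
  ref <- solve(as.matrix(Q))
  expect_lt(max(abs(emp - ref)), 0.05 * max(abs(ref)) + 0.01)
})

test_that("posterior-mean heritability is recovered across a grid of
           simulated truths", {
  # univariate 7-category trait, n ~ 1500, three seeds per truth
  for (h2_true in c(0.1, 0.5, 0.8)) {
    est <- vapply(1:3, function(s) {
      tr <- sim_truth(traits = "hip", h2 = c(hip = h2_true),
                      seed = 400 + round(100 * h2_true) + s)
      ds <- simulate_dataset(tr)
      fit <- suppressMessages(thram(ds$records, ds$pedigree, traits = "hip",
                                    chain = thram_chain(5000, 1500, 5,
                                                        seed = s)))
      g <- fit$samples$G0[, 1]
      mean(heritability(g))
    }, numeric(1))
    expect_lt(abs(mean(est) - h2_true), 0.07)
  }
})
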