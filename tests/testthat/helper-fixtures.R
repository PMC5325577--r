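# Shared fixtures: small pedigrees built in code, quick simulated datasets,
# and a lazy cache so expensive fits are shared across test files within a
# single test run.

# full-sib mating: P1 x P2 -> S1, S2; S1 x S2 -> X (F_X = 0.25)
ped_fullsib <- function() {
  pedigree(animal = c("S1", "S2", "X"),
           sire = c("P1", "P1", "S1"),
           dam = c("P2", "P2", "S2"))
}

# half-sib mating: P x D1 -> H1; P x D2 -> H2; H1 x H2 -> X2 (F = 0.125)
ped_halfsib <- function() {
  pedigree(animal = c("H1", "H2", "X2"),
           sire = c("P", "P", "H1"),
           dam = c("D1", "D2", "H2"))
}

# random valid pedigree with n animals over a few non-overlapping cohorts
random_pedigree <- function(n, seed) {
  set.seed(seed)
  nf <- max(6L, round(n / 4))
  animal <- paste0("A", seq_len(nf))
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  sex <- rep(c("M", "F"), length.out = nf)
  while (length(animal) < n) {
    males <- animal[sex == "M"]
    fems <- animal[sex == "F"]
    id <- paste0("A", length(animal) + 1L)
    animal <- c(animal, id)
    sire <- c(sire, sample(males, 1L))
    dam <- c(dam, sample(fems, 1L))
    sex <- c(sex, sample(c("M", "F"), 1L))
  }
  pedigree(animal, sire, dam, sex = sex)
}

# small simulated dataset for fast fits
small_truth <- function(h2 = c(hip = 0.5), traits = "hip", seed = 1, ...) {
  sim_truth(traits = traits, h2 = h2, seed = seed,
            n_founders = 80L, n_generations = 3L, n_per_gen = 120L,
            n_sires = 16L, n_dams = 40L, ...)
}

quick_fit <- function(ds, traits, iterations = 3000, burn_in = 800,
                      thin = 5, seed = 1, ...) {
  suppressMessages(thram(ds$records, ds$pedigree, traits = traits,
                         chain = thram_chain(iterations, burn_in, thin, seed),
                         ...))
}

# one shared moderate fit reused by several test files
.fit_cache <- new.env(parent = emptyenv())
cached_bivariate_fit <- function() {
  if (is.null(.fit_cache$biv)) {
    tr <- sim_truth(h2 = c(hip = 0.5, elbow = 0.3), r_g = 0.4, seed = 7,
                    n_founders = 100L, n_generations = 3L, n_per_gen = 150L,
                    n_sires = 20L, n_dams = 50L)
    ds <- simulate_dataset(tr)
    .fit_cache$biv <- list(ds = ds,
                           fit = quick_fit(ds, c("hip", "elbow"),
                                           iterations = 4000, burn_in = 1000,
                                           seed = 2))
  }
  .fit_cache$biv
}
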