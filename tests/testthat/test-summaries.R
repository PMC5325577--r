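test_that("heritability transform is applied sample-wise", {
  expect_equal(heritability(1), 0.5)
  expect_equal(heritability(3), 0.75)
  expect_equal(heritability(1e-9), 1e-9, tolerance = 1e-6)  # g -> 0+
  expect_equal(heritability(c(1, 3)), c(0.5, 0.75))
  expect_warning(h <- heritability(c(1, -2)), "non-positive")
  expect_true(is.na(h[2]))
})

test_that("genetic correlation from (co)variance samples", {
  expect_equal(genetic_correlation(1, 1, 1), 1)
  expect_equal(genetic_correlation(2, 3, 0), 0)
  expect_equal(genetic_correlation(2, 0.5, -0.5), -0.5)
})

test_that("prevalence counts dysplastic categories over scored dogs", {
  rec <- data.frame(hip_score = c(1L, 2L, 3L, 5L, 6L),
                    elbow_score = NA_integer_)
  expect_equal(prevalence(rec, "hip"), 40)
  rec2 <- data.frame(hip_score = NA_integer_,
                     elbow_score = rep(1L, 5))
  expect_equal(prevalence(rec2, "elbow"), 0)
  rec3 <- data.frame(hip_score = NA_integer_,
                     elbow_score = c(1L, 1L, 2L, 4L))
  expect_equal(prevalence(rec3, "elbow"), 50)
  expect_error(prevalence(data.frame(hip_score = NA_integer_), "hip"),
               "no scored records")
})

test_that("hip classes partition: dysplastic + non-dysplastic + borderline",
{
  set.seed(6)
  rec <- data.frame(hip_score = sample(1:7, 200, replace = TRUE))
  p_dys <- prevalence(rec, "hip")
  p_non <- 100 * mean(rec$hip_score <= 3)
  p_bord <- 100 * mean(rec$hip_score == 4)
  expect_equal(p_dys + p_non + p_bord, 100)
})

test_that("phenotypic trend tracks the best-category proportion by year", {
  ped <- pedigree(animal = paste0("a", 1:5), sire = rep(NA, 5),
                  dam = rep(NA, 5),
                  birth_year = c(2000, 2000, 2000, 2001, 2001))
  rec <- data.frame(animal = paste0("a", 1:5),
                    hip_score = c(1L, 1L, 2L, 1L, 7L),
                    elbow_score = NA_integer_)
  tr <- phenotypic_trend(rec, ped, "hip")
  expect_equal(tr$year, c(2000, 2001))
  expect_equal(tr$proportion, c(2 / 3, 1 / 2))
  expect_equal(tr$n, c(3L, 2L))

  rec$hip_score <- 1L
  expect_equal(phenotypic_trend(rec, ped, "hip")$proportion, c(1, 1))
})

test_that("genetic trend under truncation selection slopes downward,
           and is flat without selection", {
  tr_sel <- sim_truth(h2 = c(hip = 0.6, elbow = 0.3), seed = 5,
                      n_founders = 120L, n_generations = 4L,
                      n_per_gen = 150L, n_sires = 20L, n_dams = 60L,
                      selection = list(type = "truncation", proportion = 0.2,
                                       on = "phenotype", sexes = "both",
                                       trait = "hip"))
  ds_sel <- simulate_dataset(tr_sel)
  fit_sel <- quick_fit(ds_sel, "hip", iterations = 3000, burn_in = 800,
                       seed = 4)
  gt <- genetic_trend(fit_sel, trait = "hip")
  slope <- coef(lm(mean_ebv ~ year, data = gt))[["year"]]
  expect_lt(slope, -0.02)

  # true breeding values show the same direction (simulation oracle)
  bv_by_year <- tapply(ds_sel$bv[, "hip"],
                       ds_sel$pedigree$entries$birth_year, mean)
  expect_true(all(diff(bv_by_year) < 0))

  tr_no <- sim_truth(h2 = c(hip = 0.6, elbow = 0.3), seed = 5,
                     n_founders = 120L, n_generations = 4L,
                     n_per_gen = 150L, n_sires = 20L, n_dams = 60L)
  ds_no <- simulate_dataset(tr_no)
  fit_no <- quick_fit(ds_no, "hip", iterations = 3000, burn_in = 800,
                      seed = 4)
  gt0 <- genetic_trend(fit_no, trait = "hip")
  slope0 <- coef(lm(mean_ebv ~ year, data = gt0))[["year"]]
  expect_lt(abs(slope0), abs(slope) / 2)
})

test_that("four-path series: degenerate cases and the accounting identity", {
  # every category flat when all EBVs are equal
  ped <- random_pedigree(150, seed = 33)
  e <- ped$entries
  yrs <- rep(2000:2004, length.out = ped$n)
  ped2 <- pedigree(e$animal, e$sire, e$dam, sex = e$sex, birth_year = yrs)
  ebv <- data.frame(animal = e$animal, trait = "hip", ebv = 0.7,
                    ebv_sd = 0.1)
  fp <- four_path(ebv, ped2, trait = "hip")
  expect_true(all(abs(fp$series$mean_ebv - 0.7) < 1e-12))
  for (f in fp$fits) {
    if (is.null(f)) next
    expect_equal(unname(f[1]), 0.7, tolerance = 1e-8)
    expect_equal(unname(f[2]), 0, tolerance = 1e-8)
    expect_equal(unname(f[3]), 0, tolerance = 1e-8)
  }

  # single-member category gives a single point
  chain <- pedigree(animal = c("sg", "sp", "off"), sire = c(NA, "sg", "sp"),
                    dam = c(NA, NA, NA), birth_year = c(2000, 2001, 2002))
  ebv1 <- data.frame(animal = c("sg", "sp", "off"), trait = "hip",
                     ebv = c(-0.3, 0.1, 0.2), ebv_sd = 0.1)
  fp1 <- suppressWarnings(four_path(ebv1, chain, trait = "hip"))
  ss <- fp1$series[fp1$series$category == "SS", ]
  expect_equal(nrow(ss), 1L)
  expect_equal(ss$mean_ebv, -0.3)
})

test_that("sires-only selection shows through the sire pathways", {
  tr <- sim_truth(h2 = c(hip = 0.6, elbow = 0.3), seed = 9,
                  n_founders = 150L, n_generations = 4L, n_per_gen = 200L,
                  n_sires = 15L, n_dams = 90L,
                  selection = list(type = "truncation", proportion = 0.15,
                                   on = "phenotype", sexes = "sires",
                                   trait = "hip"))
  ds <- simulate_dataset(tr)
  fit <- quick_fit(ds, "hip", iterations = 3000, burn_in = 800, seed = 6)
  paths <- grandparent_paths(ds$pedigree)
  ebv <- fit$ebv_mean[, "hip"]
  sire_group <- union(paths$SS, paths$SD)
  dam_group <- union(paths$DS, paths$DD)
  expect_lt(mean(ebv[sire_group]), mean(ebv[dam_group]))

  sd_test <- sire_dam_test(fit, "hip", n_perm = 500)
  expect_lt(sd_test$diff, 0)

  # four-path series carry the same signal in the final generation
  fp <- four_path(fit, trait = "hip")
  last <- max(fp$series$year)
  d <- fp$series[fp$series$year == last, ]
  sire_mean <- stats::weighted.mean(d$mean_ebv[d$category %in% c("SS", "SD")],
                                    d$n[d$category %in% c("SS", "SD")])
  dam_mean <- stats::weighted.mean(d$mean_ebv[d$category %in% c("DS", "DD")],
                                   d$n[d$category %in% c("DS", "DD")])
  expect_lt(sire_mean, dam_mean)
})

test_that("breed filter uses strict inequalities", {
  counts <- data.frame(breed = c("b1", "b2", "b3", "b4", "b5"),
                       hip = c(1000, 1001, 5000, 999, 2000),
                       elbow = c(600, 501, 500, 5000, 700))
  expect_setequal(breed_filter(counts), c("b2", "b5"))
})

test_that("sex and age effects are reported with correct sign convention", {
  # males shifted toward lower liability -> negative contrast, significant
  tr <- sim_truth(traits = "hip", h2 = c(hip = 0.4),
                  sex_effect = c(hip = -0.4), seed = 14,
                  n_founders = 100L, n_generations = 3L, n_per_gen = 200L,
                  n_sires = 20L, n_dams = 60L)
  ds <- simulate_dataset(tr)
  fit <- quick_fit(ds, "hip", iterations = 3000, burn_in = 800, seed = 2)
  rep_ <- sex_age_report(fit)
  sex_row <- rep_[rep_$effect == "sex (M - F)", ]
  expect_lt(sex_row$estimate, 0)
  expect_true(sex_row$significant)
})
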