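test_that("pedigree construction orders parents before offspring and
           materialises implicit founders", {
  ped <- pedigree(animal = "C", sire = "A", dam = "B")
  expect_equal(ped$n, 3L)
  pos <- match(c("A", "B", "C"), ped$entries$animal)
  expect_true(pos[1] < pos[3] && pos[2] < pos[3])
  founders <- ped$entries$animal[ped$sire_idx == 0 & ped$dam_idx == 0]
  expect_setequal(founders, c("A", "B"))

  # a record listing an undefined sire appends it as a founder
  ped2 <- pedigree(animal = c("C", "E"), sire = c("A", "D"),
                   dam = c("B", NA))
  expect_equal(ped2$n, 5L)
  expect_true("D" %in% ped2$entries$animal)
})

test_that("pedigree validation rejects cycles and sire/dam role conflicts", {
  expect_error(pedigree(animal = c("X", "Y"), sire = c("Y", "X"),
                        dam = c(NA, NA)),
               "cycle")
  expect_error(pedigree(animal = c("A", "B", "C"), sire = c(NA, NA, "A"),
                        dam = c(NA, NA, NA), sex = c("F", NA, NA)),
               "sex inconsistent")
  expect_error(pedigree(animal = c("C", "D"), sire = c("A", "B"),
                        dam = c("B", NA)),
               "both as sire and as dam")
  expect_error(pedigree(animal = c("A", "A"), sire = c(NA, NA),
                        dam = c(NA, NA)),
               "duplicate")
})

test_that("sex is inferred from the parental role", {
  ped <- pedigree(animal = "C", sire = "A", dam = "B")
  e <- ped$entries
  expect_equal(e$sex[e$animal == "A"], "M")
  expect_equal(e$sex[e$animal == "B"], "F")
})

test_that("inbreeding matches hand-computed tabular values", {
  ped0 <- pedigree(animal = c("A", "B", "C"), sire = c(NA, NA, NA),
                   dam = c(NA, NA, NA))
  expect_equal(unname(inbreeding(ped0)), c(0, 0, 0))

  F1 <- inbreeding(ped_fullsib())
  expect_equal(unname(F1[names(F1) == "X"]), 0.25)

  F2 <- inbreeding(ped_halfsib())
  expect_equal(unname(F2[names(F2) == "X2"]), 0.125)
})

test_that("relationship matrix follows the tabular method", {
  ped <- ped_fullsib()
  A <- relationship_matrix(ped)
  expect_equal(A["S1", "S2"], 0.5)         # full sibs of founder parents
  expect_equal(A["X", "X"], 1.25)          # 1 + F of full-sib offspring
  expect_equal(unname(diag(A)), unname(1 + inbreeding(ped)))

  trio <- pedigree("C", "A", "B")
  At <- relationship_matrix(trio)
  expect_equal(At["A", "A"], 1)            # founder diagonal
  expect_equal(At["A", "C"], 0.5)          # parent-offspring
  expect_error(relationship_matrix(trio, dense_limit = 2L), "dense limit")
})

test_that("Henderson-Quaas sparse inverse matches the dense inverse", {
  # founders only -> identity
  ped0 <- pedigree(animal = c("A", "B"), sire = c(NA, NA), dam = c(NA, NA))
  expect_equal(as.matrix(inverse_relationship(ped0)), diag(2),
               ignore_attr = TRUE)

  # non-inbred trio: offspring diagonal entry is 2
  trio <- pedigree("C", "A", "B")
  Ai <- as.matrix(inverse_relationship(trio))
  expect_equal(Ai[trio$entries$animal == "C", trio$entries$animal == "C"], 2)

  # oracle equivalence on random pedigrees up to 200 animals
  for (seed in 1:5) {
    n <- sample(30:200, 1)
    ped <- random_pedigree(n, seed = seed)
    A <- relationship_matrix(ped)
    Ai <- as.matrix(inverse_relationship(ped))
    expect_lt(max(abs(A %*% Ai - diag(ped$n))), 1e-8)
  }
})

test_that("inbreeding is non-negative and zero for unrelated parents", {
  for (seed in 1:3) {
    ped <- random_pedigree(120, seed = 10 + seed)
    F <- inbreeding(ped)
    expect_true(all(F >= 0))
    A <- relationship_matrix(ped)
    s <- ped$sire_idx; d <- ped$dam_idx
    both <- which(s > 0 & d > 0)
    unrelated <- both[vapply(both, function(i) A[s[i], d[i]] == 0,
                             logical(1))]
    expect_true(all(F[unrelated] == 0))
  }
})

test_that("grand-parental path classification", {
  # three-generation male chain: only SS occupied
  chain <- pedigree(animal = c("sireP", "off"), sire = c("sireG", "sireP"),
                    dam = c(NA, NA))
  gp <- grandparent_paths(chain)
  expect_equal(gp$SS, "sireG")
  expect_equal(lengths(gp[c("SD", "DS", "DD")]), c(SD = 0L, DS = 0L, DD = 0L))

  # no third generation -> all empty
  trio <- pedigree("C", "A", "B")
  expect_true(all(lengths(grandparent_paths(trio)) == 0))

  # a male who sires both a sire and a dam appears in SS and SD
  ped12 <- pedigree(
    animal = c("s1", "d1", "o1", "o2"),
    sire = c("gs", "gs", "s1", "s1"),
    dam = c("gd1", "gd2", "d1", "d1"))
  gp2 <- grandparent_paths(ped12)
  expect_true("gs" %in% gp2$SS && "gs" %in% gp2$SD)
  expect_true("gd1" %in% gp2$DS && "gd2" %in% gp2$DD)
})

test_that("path categories partition the grand-parent set", {
  for (seed in 1:3) {
    ped <- random_pedigree(150, seed = 20 + seed)
    gp <- grandparent_paths(ped)
    e <- ped$entries
    s <- ped$sire_idx; d <- ped$dam_idx
    parents <- unique(c(s[s > 0], d[d > 0]))
    has_grand <- unique(unlist(lapply(parents, function(i) {
      c(s[i], d[i])
    })))
    has_grand <- e$animal[has_grand[has_grand > 0]]
    expect_setequal(unique(unlist(gp)), has_grand)
  }
})

test_that("pedigree files round-trip losslessly", {
  ped <- random_pedigree(60, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  ped2 <- read_pedigree(path)
  expect_equal(ped2$entries, ped$entries)

  # unknown-parent encodings "", "0", "NA" all accepted
  tsv <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("animal\tsire\tdam", "C\tA\tB", "A\t0\tNA", "B\t\t"), tsv)
  ped3 <- read_pedigree(tsv)
  expect_equal(ped3$n, 3L)
  expect_true(all(ped3$sire_idx[ped3$entries$animal %in% c("A", "B")] == 0))
})
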