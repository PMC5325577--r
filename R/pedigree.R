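#' Construct and validate a pedigree
#'
#' Builds a topologically ordered pedigree from parallel vectors of animal,
#' sire and dam identifiers. Identifiers are opaque strings; unknown parents
#' may be encoded as `NA`, `""` or `"0"`. Animals that appear only as parents
#' are materialised as founder entries. Sex is inferred from the parental
#' role where it is not supplied (sires are male, dams female).
#'
#' @param animal character vector of animal identifiers (unique).
#' @param sire,dam character vectors of parent identifiers, same length as
#'   `animal`; unknown parents as `NA`, `""` or `"0"`.
#' @param sex optional character vector, `"M"`, `"F"` or `NA`.
#' @param birth_year optional integer vector of calendar birth years, `NA`
#'   when unknown.
#'
#' @return An object of class `"pedigree"`: a list with a data frame
#'   `entries` (columns `animal`, `sire`, `dam`, `sex`, `birth_year`, in
#'   topological order so every parent precedes its offspring), integer
#'   parent indices `sire_idx`/`dam_idx` (0 for unknown) and `n`, the number
#'   of animals.
#'
#' @details Validation rejects pedigree cycles (an animal that is its own
#'   ancestor), identifiers used both as a sire and as a dam, and explicit
#'   sexes that contradict an animal's parental role.
#'
#' @examples
#' ped <- pedigree(animal = c("C"), sire = c("A"), dam = c("B"))
#' ped$entries$animal   # founders A, B precede C
#' @export
pedigree <- function(animal, sire, dam, sex = NULL, birth_year = NULL) {
  animal <- as.character(animal)
  sire <- normalize_parent(sire, length(animal))
  dam <- normalize_parent(dam, length(animal))
  if (anyNA(animal) || any(animal == ""))
    stop("animal identifiers must be non-missing")
  if (anyDuplicated(animal))
    stop("duplicate animal identifiers: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (is.null(sex)) sex <- rep(NA_character_, length(animal))
  sex <- toupper(as.character(sex))
  sex[!sex %in% c("M", "F")] <- NA_character_
  if (is.null(birth_year)) birth_year <- rep(NA_integer_, length(animal))
  birth_year <- as.integer(birth_year)

  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal))
    stop("pedigree cycle: animal listed as its own parent")

  ## materialise animals appearing only as parents as founders
  only_parents <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), animal)
  if (length(only_parents)) {
    animal <- c(animal, only_parents)
    sire <- c(sire, rep(NA_character_, length(only_parents)))
    dam <- c(dam, rep(NA_character_, length(only_parents)))
    sex <- c(sex, rep(NA_character_, length(only_parents)))
    birth_year <- c(birth_year, rep(NA_integer_, length(only_parents)))
  }

  sires_used <- unique(sire[!is.na(sire)])
  dams_used <- unique(dam[!is.na(dam)])
  both <- intersect(sires_used, dams_used)
  if (length(both))
    stop("identifier(s) used both as sire and as dam: ",
         paste(both, collapse = ", "))

  ## sex consistency / inference from parental role
  idx <- seq_along(animal)
  names(idx) <- animal
  conflict_m <- intersect(sires_used, animal[!is.na(sex) & sex == "F"])
  conflict_f <- intersect(dams_used, animal[!is.na(sex) & sex == "M"])
  if (length(conflict_m) || length(conflict_f))
    stop("sex inconsistent with parental role for: ",
         paste(c(conflict_m, conflict_f), collapse = ", "))
  sex[idx[sires_used]] <- "M"
  sex[idx[dams_used]] <- "F"

  ord <- topo_order(animal, sire, dam)
  animal <- animal[ord]; sire <- sire[ord]; dam <- dam[ord]
  sex <- sex[ord]; birth_year <- birth_year[ord]
  sire_idx <- match(sire, animal); sire_idx[is.na(sire_idx)] <- 0L
  dam_idx <- match(dam, animal); dam_idx[is.na(dam_idx)] <- 0L

  structure(list(
    entries = data.frame(animal = animal, sire = sire, dam = dam,
                         sex = sex, birth_year = birth_year,
                         stringsAsFactors = FALSE),
    sire_idx = as.integer(sire_idx),
    dam_idx = as.integer(dam_idx),
    n = length(animal)
  ), class = "pedigree")
}

normalize_parent <- function(x, n) {
  if (is.null(x)) return(rep(NA_character_, n))
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0" | toupper(x) == "NA"] <- NA_character_
  x
}

## Kahn's algorithm; on failure names one animal on a cycle.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  si <- match(sire, animal); di <- match(dam, animal)
  children <- vector("list", n)
  indeg <- integer(n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        children[[p]] <- c(children[[p]], i)
        indeg[i] <- indeg[i] + 1L
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    on_cycle <- setdiff(seq_len(n), ord)[1L]
    stop("pedigree cycle detected involving animal '", animal[on_cycle], "'")
  }
  ord
}

#' Read a pedigree file
#'
#' Reads a delimited pedigree (comma or tab, autodetected from the header
#' line) with required columns `animal`, `sire`, `dam` and optional `sex`
#' and `birth_year`. Unknown parents may be encoded `""`, `"0"` or `"NA"`.
#'
#' @param path file path.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  tab <- read_delimited(path)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(tab)))
    stop("pedigree file must have columns animal, sire, dam")
  pedigree(tab$animal, tab$sire, tab$dam,
           sex = if ("sex" %in% names(tab)) tab$sex else NULL,
           birth_year = if ("birth_year" %in% names(tab)) tab$birth_year else NULL)
}

#' Write a pedigree file
#'
#' Comma-separated with header; unknown parents written as empty fields.
#'
#' @param ped a [pedigree] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  e <- ped$entries
  out <- data.frame(animal = e$animal,
                    sire = ifelse(is.na(e$sire), "", e$sire),
                    dam = ifelse(is.na(e$dam), "", e$dam),
                    sex = ifelse(is.na(e$sex), "", e$sex),
                    birth_year = ifelse(is.na(e$birth_year), "", e$birth_year))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = character(0),
                    strip.white = TRUE)
}

#' @export
print.pedigree <- function(x, ...) {
  e <- x$entries
  founders <- sum(x$sire_idx == 0L & x$dam_idx == 0L)
  cat("Pedigree:", x$n, "animals (", founders, "founders )\n")
  if (!all(is.na(e$birth_year)))
    cat("Birth years:", min(e$birth_year, na.rm = TRUE), "-",
        max(e$birth_year, na.rm = TRUE), "\n")
  cat("Inbred animals:", sum(inbreeding(x) > 0), "\n")
  invisible(x)
}

## Per-animal Mendelian-sampling variance scale given parental inbreeding:
## both parents known: 0.5 - 0.25 (F_s + F_d); one: 0.75 - 0.25 F_p; none: 1.
mendelian_variance <- function(ped, F = inbreeding(ped)) {
  s <- ped$sire_idx; d <- ped$dam_idx
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], NA_real_)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], NA_real_)
  ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
         ifelse(s > 0L, 0.75 - 0.25 * Fs,
                ifelse(d > 0L, 0.75 - 0.25 * Fd, 1)))
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficient F computed by the Meuwissen-Luo
#' ancestor-tracing algorithm (equivalent to the diagonal of the numerator
#' relationship matrix minus one, but without forming A). Founders and
#' animals with any unknown parent get F = 0 under the base-population
#' convention.
#'
#' @param ped a [pedigree] object.
#' @return Numeric vector of F, one per animal in pedigree order, named by
#'   animal identifier.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  s <- ped$sire_idx; d <- ped$dam_idx
  F <- numeric(n)
  D <- numeric(n)   # Mendelian variance of j, filled as we go
  coef <- numeric(n)
  for (i in seq_len(n)) {
    Fs <- if (s[i] > 0L) F[s[i]] else NA_real_
    Fd <- if (d[i] > 0L) F[d[i]] else NA_real_
    D[i] <- if (s[i] > 0L && d[i] > 0L) 0.5 - 0.25 * (Fs + Fd)
            else if (s[i] > 0L) 0.75 - 0.25 * Fs
            else if (d[i] > 0L) 0.75 - 0.25 * Fd
            else 1
    if (s[i] == 0L || d[i] == 0L) { F[i] <- 0; next }
    ## trace L-row of i downwards: a_ii = sum_j L_ij^2 D_j
    touched <- integer(0)
    coef[i] <- 1; touched <- i
    aii <- 0
    for (j in seq(i, 1L)) {
      cj <- coef[j]
      if (cj == 0) next
      aii <- aii + cj * cj * D[j]
      if (s[j] > 0L) {
        if (coef[s[j]] == 0) touched <- c(touched, s[j])
        coef[s[j]] <- coef[s[j]] + cj / 2
      }
      if (d[j] > 0L) {
        if (coef[d[j]] == 0) touched <- c(touched, d[j])
        coef[d[j]] <- coef[d[j]] + cj / 2
      }
      coef[j] <- 0
    }
    coef[touched] <- 0
    F[i] <- aii - 1
  }
  names(F) <- ped$entries$animal
  F
}

#' Dense numerator relationship matrix
#'
#' Computes A by the tabular method: `a_ii = 1 + F_i` and, for `j < i`,
#' `a_ij = (a_{j,sire(i)} + a_{j,dam(i)}) / 2` with unknown parents
#' contributing zero.
#'
#' @param ped a [pedigree] object.
#' @param dense_limit refuse to form A for pedigrees larger than this
#'   (default 5000); use [inverse_relationship()] instead at scale.
#' @return Dense symmetric matrix with animal identifiers as dimnames.
#' @export
relationship_matrix <- function(ped, dense_limit = 5000L) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  if (n > dense_limit)
    stop("pedigree has ", n, " animals, above the dense limit of ",
         dense_limit, "; use inverse_relationship() for the sparse inverse")
  s <- ped$sire_idx; d <- ped$dam_idx
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s[i] > 0L) row <- row + 0.5 * A[j, s[i]]
      if (d[i] > 0L) row <- row + 0.5 * A[j, d[i]]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + (if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0)
  }
  dimnames(A) <- list(ped$entries$animal, ped$entries$animal)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules with the Quaas inbreeding
#' adjustment: each animal i contributes `1/delta_i` times the pattern
#' `(1, -1/2, -1/2) x (1, -1/2, -1/2)` to the `{i, sire, dam}` block, where
#' `delta_i` is the Mendelian-sampling variance given parental inbreeding.
#'
#' @param ped a [pedigree] object.
#' @param F optional precomputed inbreeding coefficients.
#' @return A [Matrix::sparseMatrix()] (symmetric `dsCMatrix`) with animal
#'   identifiers as dimnames.
#' @export
inverse_relationship <- function(ped, F = inbreeding(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  s <- ped$sire_idx; d <- ped$dam_idx
  delta <- mendelian_variance(ped, F)
  w <- 1 / delta
  i0 <- seq_len(n)
  hs <- s > 0L; hd <- d > 0L; hb <- hs & hd
  ii <- c(i0,
          i0[hs], s[hs], s[hs],
          i0[hd], d[hd], d[hd],
          s[hb], d[hb])
  jj <- c(i0,
          s[hs], i0[hs], s[hs],
          d[hd], i0[hd], d[hd],
          d[hb], s[hb])
  xx <- c(w,
          -0.5 * w[hs], -0.5 * w[hs], 0.25 * w[hs],
          -0.5 * w[hd], -0.5 * w[hd], 0.25 * w[hd],
          0.25 * w[hb], 0.25 * w[hb])
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$entries$animal,
                                            ped$entries$animal))
  Matrix::forceSymmetric(M)
}

#' Grand-parental path membership
#'
#' Classifies animals with grand-progeny into the four selection pathways:
#' sires of sires (SS), sires of dams (SD), dams of sires (DS) and dams of
#' dams (DD). Membership is per category and unweighted by the number of
#' grand-offspring; one animal may fall in several categories.
#'
#' @param ped a [pedigree] object.
#' @return Named list of character vectors `SS`, `SD`, `DS`, `DD`.
#' @export
grandparent_paths <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  e <- ped$entries
  s <- ped$sire_idx; d <- ped$dam_idx
  is_sire <- seq_len(ped$n) %in% s
  is_dam <- seq_len(ped$n) %in% d
  ids <- e$animal
  list(
    SS = sort(unique(ids[s[is_sire][s[is_sire] > 0L]])),
    SD = sort(unique(ids[s[is_dam][s[is_dam] > 0L]])),
    DS = sort(unique(ids[d[is_sire][d[is_sire] > 0L]])),
    DD = sort(unique(ids[d[is_dam][d[is_dam] > 0L]]))
  )
}
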