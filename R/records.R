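## Score-record handling: reading, validation, age filtering, evaluation-year
## derivation. Records carry one evaluation per dog: ordinal hip score (1-7),
## ordinal elbow score (1-4), either possibly missing.

trait_categories <- c(hip = 7L, elbow = 4L)

#' Read a score-record file
#'
#' Delimited text (comma or tab autodetected) with header
#' `animal,sex,birth_date,age_months,hip_score,elbow_score`; scores blank
#' when missing; `birth_date` ISO `YYYY-MM` or `YYYY-MM-DD`. An
#' `eval_year` column is accepted and otherwise derived from birth date
#' and age.
#'
#' @param path file path.
#' @return Data frame of score records.
#' @export
read_records <- function(path) {
  tab <- read_delimited(path)
  need <- c("animal", "age_months")
  if (!all(need %in% names(tab)))
    stop("records file must have columns animal and age_months")
  rec <- data.frame(animal = tab$animal, stringsAsFactors = FALSE)
  rec$sex <- if ("sex" %in% names(tab)) toupper(tab$sex) else NA_character_
  rec$birth_date <- if ("birth_date" %in% names(tab)) tab$birth_date else NA_character_
  rec$age_months <- as.integer(tab$age_months)
  for (tr in names(trait_categories)) {
    col <- paste0(tr, "_score")
    rec[[col]] <- if (col %in% names(tab)) {
      v <- tab[[col]]
      v[v == "" | toupper(v) == "NA"] <- NA
      as.integer(v)
    } else NA_integer_
  }
  rec$eval_year <- if ("eval_year" %in% names(tab)) as.integer(tab$eval_year)
                   else derive_eval_year(rec$birth_date, rec$age_months)
  rec
}

#' Write score records
#'
#' Comma-separated with header; missing scores as empty fields.
#' @param records data frame of score records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  for (col in names(out))
    if (is.numeric(out[[col]]) || is.integer(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluation year from birth date and age
#'
#' The calendar year in which a dog aged `age_months` months was evaluated,
#' given its birth date (`YYYY-MM` or `YYYY-MM-DD`).
#'
#' @param birth_date character vector of ISO birth dates.
#' @param age_months integer vector of ages at evaluation, in months.
#' @return Integer vector of evaluation years (`NA` where the birth date is
#'   missing or unparseable; such records are meant to be excluded, with a
#'   count reported by the caller).
#' @examples
#' derive_eval_year("1990-01", 24)  # 1992
#' derive_eval_year("1990-11", 26)  # 1993
#' @export
derive_eval_year <- function(birth_date, age_months) {
  m <- regmatches(birth_date,
                  regexec("^(\\d{4})-(\\d{2})(-\\d{2})?$", birth_date))
  year <- vapply(m, function(g) if (length(g)) as.integer(g[2]) else NA_integer_,
                 integer(1))
  month <- vapply(m, function(g) if (length(g)) as.integer(g[3]) else NA_integer_,
                  integer(1))
  as.integer(year + (month - 1L + as.integer(age_months)) %/% 12L)
}

#' Age filter for evaluation records
#'
#' Retains records of dogs evaluated at or above a minimum age; the default
#' 24 months restricts to dogs two years of age and older, the eligibility
#' floor for definitive joint grading.
#'
#' @param records data frame with an `age_months` column.
#' @param min_age_months inclusive lower age bound (months).
#' @return Filtered data frame with attribute `n_dropped`, the number of
#'   removed records (also reported via `message()`).
#' @export
filter_records <- function(records, min_age_months = 24) {
  keep <- !is.na(records$age_months) & records$age_months >= min_age_months
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " record(s) below ", min_age_months,
            " months of age removed")
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no records remain after the age filter")
  attr(out, "n_dropped") <- dropped
  out
}

#' Validate a pedigree/records pair
#'
#' Cross-checks identifier sets, score ranges and age fields, returning a
#' machine-readable issue list rather than failing on first error.
#'
#' @param ped a [pedigree] object (or path to a pedigree file).
#' @param records score-record data frame (or path to a records file).
#' @return Data frame with columns `severity`, `field`, `animal`, `message`
#'   (zero rows when clean).
#' @export
validate_inputs <- function(ped, records) {
  if (is.character(ped)) ped <- read_pedigree(ped)
  if (is.character(records)) records <- read_records(records)
  issues <- list()
  add <- function(severity, field, animal, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, field = field, animal = animal, message = msg,
      stringsAsFactors = FALSE)
  unknown <- setdiff(records$animal, ped$entries$animal)
  for (id in unknown)
    add("error", "animal", id, "record references an animal absent from the pedigree")
  for (tr in names(trait_categories)) {
    col <- paste0(tr, "_score")
    if (!col %in% names(records)) next
    v <- records[[col]]
    bad <- which(!is.na(v) & (v < 1L | v > trait_categories[[tr]]))
    for (i in bad)
      add("error", col, records$animal[i],
          sprintf("%s %d outside 1..%d", col, v[i], trait_categories[[tr]]))
  }
  bad_age <- which(is.na(records$age_months) | records$age_months < 0)
  for (i in bad_age)
    add("error", "age_months", records$animal[i], "missing or negative age")
  no_score <- which(rowSums(!is.na(
    records[paste0(names(trait_categories), "_score")])) == 0L)
  for (i in no_score)
    add("warning", "scores", records$animal[i], "no score on any trait")
  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(), field = character(),
                  animal = character(), message = character(),
                  stringsAsFactors = FALSE)
}
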