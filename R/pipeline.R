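## Reproducible end-to-end pipeline: simulate or load data, validate, fit,
## diagnose, summarise, trend, four-path; every artifact carries the config
## hash and seed in a JSON sidecar.

#' Run the full analysis pipeline
#'
#' Executes filter -> fit -> diagnose -> summarise -> trend -> four-path on
#' a pedigree/records pair and writes all artifacts (CSV tables and JSON
#' sidecars) into an output directory. If the convergence diagnostics fail,
#' summaries are withheld unless `force = TRUE`, in which case outputs are
#' emitted with a warning banner in their metadata.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `pedigree`, `records` (paths; or `simulate: true` plus [sim_truth]
#'   fields), `outdir`, `traits` (comma-separated or vector), `iterations`,
#'   `burn_in`, `thin`, `seed`, `min_age_months`, `force`, `loess_span`.
#' @param force emit summaries even when diagnostics fail.
#' @return Invisibly, a list with the fit, the convergence report and the
#'   paths of all written artifacts.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  outdir <- cfg$outdir %||% "thram-run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  traits <- cfg$traits %||% c("hip", "elbow")
  if (length(traits) == 1L) traits <- strsplit(traits, ",")[[1]]
  seed <- as.integer(cfg$seed %||% 1L)
  force <- isTRUE(cfg$force) || force

  if (isTRUE(cfg$simulate)) {
    truth_args <- cfg[names(cfg) %in% names(formals(sim_truth))]
    truth_args$traits <- traits
    truth_args$seed <- seed
    truth <- do.call(sim_truth, truth_args)
    ds <- simulate_dataset(truth)
    ped <- ds$pedigree
    records <- ds$records
    write_pedigree(ped, file.path(outdir, "pedigree.csv"))
    write_records(records, file.path(outdir, "records.csv"))
    truth_sidecar <- file.path(outdir, "truth.json")
    jsonlite::write_json(
      list(h2 = as.list(truth$h2), r_g = truth$r_g, r_he = truth$r_he,
           cutpoints = truth$cutpoints, mu = as.list(truth$mu),
           selection = truth$selection, seed = truth$seed,
           true_bv = as.data.frame(cbind(animal = rownames(ds$bv),
                                         as.data.frame(ds$bv)))),
      truth_sidecar, auto_unbox = TRUE, digits = NA)
  } else {
    ped <- read_pedigree(cfg$pedigree)
    records <- read_records(cfg$records)
  }

  issues <- validate_inputs(ped, records)
  if (any(issues$severity == "error"))
    stop("input validation failed: ", issues$message[issues$severity == "error"][1L],
         " (animal ", issues$animal[issues$severity == "error"][1L], ")")

  chain <- thram_chain(iterations = as.integer(cfg$iterations %||% 100000L),
                       burn_in = as.integer(cfg$burn_in %||% 20000L),
                       thin = as.integer(cfg$thin %||% 20L),
                       seed = seed)
  fit <- thram(records, ped, traits = traits,
               chain = chain,
               min_age_months = as.numeric(cfg$min_age_months %||% 24))

  report <- convergence_report(fit)
  write_convergence_report(report, file.path(outdir, "convergence.json"))

  meta <- list(config = cfg[setdiff(names(cfg), "outdir")],
               config_hash = config_hash(cfg[setdiff(names(cfg), "outdir")]),
               seed = seed,
               package_version = as.character(utils::packageVersion("thram")),
               diagnostics_pass = report$pass,
               acceptance_rates = fit$acceptance,
               warning = if (!report$pass && force)
                 "diagnostics FAILED; outputs forced" else NULL)
  jsonlite::write_json(meta, file.path(outdir, "run-metadata.json"),
                       auto_unbox = TRUE, digits = NA)

  artifacts <- c(convergence = file.path(outdir, "convergence.json"),
                 metadata = file.path(outdir, "run-metadata.json"))
  write_samples(fit, file.path(outdir, "samples.csv"))
  artifacts["samples"] <- file.path(outdir, "samples.csv")

  if (!report$pass && !force) {
    warning("convergence diagnostics failed; summaries withheld (use force)")
    return(invisible(list(fit = fit, convergence = report,
                          artifacts = artifacts)))
  }

  ## summaries
  g <- fit$samples$G0
  h2 <- lapply(fit$traits, function(tr) heritability(g[, paste0("g_", tr)]))
  names(h2) <- fit$traits
  summ <- list(
    h2 = lapply(h2, function(v) list(mean = mean(v), sd = stats::sd(v))),
    r_g = if (length(fit$traits) == 2L) {
      rg <- genetic_correlation(g[, 1L], g[, 3L], g[, 2L])
      list(mean = mean(rg), sd = stats::sd(rg))
    } else NULL,
    prevalence = lapply(stats::setNames(fit$traits, fit$traits), function(tr)
      prevalence(records, tr)),
    effects = sex_age_report(fit),
    metadata = meta)
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  artifacts["summary"] <- file.path(outdir, "summary.json")

  span <- as.numeric(cfg$loess_span %||% 0.75)
  for (tr in fit$traits) {
    gt <- genetic_trend(fit, trait = tr, span = span)
    utils::write.csv(as.data.frame(gt),
                     file.path(outdir, paste0("trend_", tr, ".csv")),
                     row.names = FALSE)
    artifacts[paste0("trend_", tr)] <-
      file.path(outdir, paste0("trend_", tr, ".csv"))
    fp <- four_path(fit, trait = tr)
    if (!is.null(fp$series)) {
      utils::write.csv(fp$series,
                       file.path(outdir, paste0("fourpath_", tr, ".csv")),
                       row.names = FALSE)
      artifacts[paste0("fourpath_", tr)] <-
        file.path(outdir, paste0("fourpath_", tr, ".csv"))
    }
  }
  utils::write.csv(extract_ebv(fit), file.path(outdir, "ebv.csv"),
                   row.names = FALSE)
  artifacts["ebv"] <- file.path(outdir, "ebv.csv")

  invisible(list(fit = fit, convergence = report, summary = summ,
                 artifacts = artifacts))
}

#' Write thinned posterior samples as a tidy table
#'
#' One row per (iteration, parameter) pair, covering variance components,
#' residual correlation, fixed effects and cutpoints.
#'
#' @param fit a [thram] fit.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(fit, path) {
  mat <- fit$samples$G0
  if (!is.null(fit$samples$r_he)) mat <- cbind(mat, r_he = fit$samples$r_he)
  mat <- cbind(mat, fit$samples$beta, fit$samples$cutpoints)
  long <- data.frame(
    iteration = rep(seq_len(nrow(mat)), ncol(mat)),
    parameter = rep(colnames(mat), each = nrow(mat)),
    value = as.numeric(mat))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy samples table back into a matrix
#'
#' @param path CSV written by [write_samples()].
#' @return Numeric matrix (iterations x parameters).
#' @export
read_samples <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  params <- unique(long$parameter)
  mat <- vapply(params, function(p) long$value[long$parameter == p],
                numeric(sum(long$parameter == params[1L])))
  colnames(mat) <- params
  mat
}

#' Read a flat YAML-style run configuration
#'
#' Accepts the flat `key: value` subset of YAML (strings, numbers,
#' booleans; comma-separated lists).
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) < 3L) next
    key <- m[2]; val <- m[3]
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (val %in% c("true", "TRUE", "yes")) return(TRUE)
  if (val %in% c("false", "FALSE", "no")) return(FALSE)
  if (grepl(",", val)) {
    parts <- trimws(strsplit(val, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    return(if (anyNA(nums)) parts else nums)
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) num else val
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small stable FNV-1a style hash; avoids a digest dependency
  h <- 2166136261 %% 2147483648
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), ch)
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", h)
}
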