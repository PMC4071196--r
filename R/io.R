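#' Read a long-format time-series table
#'
#' Reads a delimited text file with header columns `output`, `time`, `value`
#' (comma or tab separated; extra columns are ignored) and validates it:
#' every row must have finite numeric `time` and `value`, duplicate
#' `(output, time)` pairs are rejected unless `replicates = TRUE`, and each
#' output must have at least `min_points` observations. Errors name the
#' offending file line (header is line 1).
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default; sniffs the header line), `"csv"` or
#'   `"tsv"`.
#' @param replicates Allow repeated `(output, time)` pairs.
#' @param min_points Minimum observations per output (default 3, the minimum
#'   for which fitting a smooth trend is meaningful).
#' @return A tibble with columns `output`, `time`, `value`.
#' @export
read_timeseries <- function(path, dialect = c("auto", "csv", "tsv"),
                            replicates = FALSE, min_points = 3L) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  assert_that(length(lines) >= 1L, paste0("empty file: ", path))
  sep <- switch(dialect,
                csv = ",", tsv = "\t",
                auto = if (grepl("\t", lines[1L])) "\t" else ",")
  raw <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           colClasses = "character", check.names = TRUE,
                           quote = "\"", comment.char = "")
  missing <- setdiff(c("output", "time", "value"), names(raw))
  assert_that(length(missing) == 0L,
              paste0(path, ": missing required column(s): ",
                     paste(missing, collapse = ", ")))
  assert_that(nrow(raw) >= 1L, paste0(path, ": no data rows"))

  line_no <- seq_len(nrow(raw)) + 1L   # header is line 1
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(x))
    assert_that(length(bad) == 0L,
                paste0(path, ": non-numeric or non-finite `", col,
                       "` at line(s) ",
                       paste(line_no[bad], collapse = ", ")))
    x
  }
  out <- tibble::tibble(output = as.character(raw$output),
                        time = num("time"), value = num("value"))
  if (!replicates) {
    dup <- which(duplicated(paste(out$output, out$time, sep = "\r")))
    assert_that(length(dup) == 0L,
                paste0(path, ": duplicate (output, time) pair at line(s) ",
                       paste(line_no[dup], collapse = ", "),
                       "; set replicates = TRUE to allow"))
  }
  if (min_points > 0L) {
    n_i <- table(out$output)
    low <- names(n_i)[n_i < min_points]
    assert_that(length(low) == 0L,
                paste0(path, ": fewer than ", min_points,
                       " observations for output(s): ",
                       paste(low, collapse = ", ")))
  }
  out
}

#' Write a long-format time-series table as CSV
#'
#' @param data Tibble with columns `output`, `time`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path) {
  data <- as_timeseries(data, replicates = TRUE)
  readr::write_csv(data[, c("output", "time", "value")], path)
  invisible(path)
}

# --- pipeline configuration --------------------------------------------------

builtin_spec <- function(name) {
  switch(name,
         two_output = two_output_spec(),
         nitrogen = nitrogen_pathway_spec(),
         NULL)
}

builtin_generator <- function(name) {
  switch(name,
         oscillators = simulate_oscillators,
         linear_pathway = simulate_linear_pathway,
         branched_pathway = simulate_branched_pathway,
         nitrogen_pathway = simulate_nitrogen_pathway,
         NULL)
}

# Validate a pipeline config, collecting *all* problems before failing.
validate_config <- function(cfg) {
  problems <- character()
  need <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)

  need(is.list(cfg), "config must be a list (or a YAML file containing one)")
  if (!is.list(cfg)) {
    abort(paste0("invalid pipeline config:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  has_data <- !is.null(cfg$data)
  has_sim <- !is.null(cfg$simulate)
  need(xor(has_data, has_sim),
       "exactly one of `data` (a file path) or `simulate` must be given")
  if (has_data) need(is.character(cfg$data) && file.exists(cfg$data),
                     paste0("data file not found: ", cfg$data))
  if (has_sim) {
    need(is.list(cfg$simulate) && !is.null(cfg$simulate$generator),
         "`simulate` must be a list with a `generator` field")
    if (!is.null(cfg$simulate$generator)) {
      need(!is.null(builtin_generator(cfg$simulate$generator)),
           paste0("unknown generator: ", cfg$simulate$generator,
                  " (available: oscillators, linear_pathway, ",
                  "branched_pathway, nitrogen_pathway)"))
    }
  }
  need(!is.null(cfg$model), "`model` is required")
  if (!is.null(cfg$model)) {
    if (is.character(cfg$model)) {
      need(!is.null(builtin_spec(cfg$model)),
           paste0("unknown builtin model: ", cfg$model,
                  " (available: two_output, nitrogen)"))
    } else {
      need(is.list(cfg$model) && !is.null(cfg$model$outputs) &&
             !is.null(cfg$model$edges),
           "`model` must be a builtin name or a list with `outputs` and `edges`")
    }
  }
  if (!is.null(cfg$stoichiometry)) {
    st <- cfg$stoichiometry
    need(is.list(st) && !is.null(st$S) && !is.null(st$fluxes),
         "`stoichiometry` needs `S` (list of rows) and `fluxes`")
  }
  if (length(problems)) {
    abort(paste0("invalid pipeline config:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  invisible(cfg)
}

config_spec <- function(cfg) {
  if (is.character(cfg$model)) return(builtin_spec(cfg$model))
  edges <- cfg$model$edges
  if (!is.data.frame(edges)) {
    edges <- data.frame(source = vapply(edges, `[[`, "", 1),
                        output = vapply(edges, `[[`, "", 2))
  }
  mgp_spec(unlist(cfg$model$outputs), edges)
}

config_stoichiometry <- function(cfg, sim = NULL) {
  st <- cfg$stoichiometry
  if (is.null(st)) {
    if (!is.null(sim) && !is.null(sim$stoichiometry)) return(sim$stoichiometry)
    return(NULL)
  }
  S <- do.call(rbind, lapply(st$S, unlist))
  known <- list()
  for (v in names(st$known %||% list())) {
    k <- st$known[[v]]
    known[[v]] <- if (is.character(k)) {
      tab <- utils::read.csv(k)
      tab[, c("time", "value")]
    } else {
      data.frame(time = unlist(k$time), value = unlist(k$value))
    }
  }
  stoichiometry(S, metabolites = unlist(st$metabolites) %||% rownames(S),
                fluxes = unlist(st$fluxes), known = known)
}

#' Run the full estimation pipeline from a configuration
#'
#' Binds the stages together: obtain data (read a file or run a bundled
#' generator), fit the dependent GP model by multistart MAP, predict
#' functions and derivatives on a test grid, and (if a stoichiometry is
#' configured or supplied by the generator) estimate fluxes. All artifacts
#' are written as delimited text plus a JSON run log.
#'
#' Config fields (YAML file or list): `data` (CSV path) *or* `simulate`
#' (`generator` plus generator arguments); `model` (builtin name
#' `"two_output"` / `"nitrogen"`, or `outputs` + `edges`); optional `priors`
#' (`location`, `scale`), `fit` (`n_starts`, `center`, `fixed`), `predict`
#' (`from`, `to`, `length`, `include_noise`), `stoichiometry` (`S` as a list
#' of rows, `fluxes`, `metabolites`, `known`), `seed`.
#'
#' All randomness flows from the single top-level `seed`, split
#' deterministically across the simulate / fit stages.
#'
#' @param config Path to a YAML file or a config list.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir` or a temporary directory.
#' @return Invisibly, a named list of artifact paths (`observations`,
#'   `hyperparameters`, `predictions`, `fluxes` (if any), `log`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("fluxgp_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seed <- cfg$seed %||% 1L
  seeds <- split_seed(seed, 2L)   # simulate, fit
  log <- list(seed = seed,
              package_version = as.character(utils::packageVersion("fluxgp")),
              r_version = as.character(getRversion()),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  note <- function(msg) {
    message("[fluxgp] ", msg)
    log$notes <<- c(log$notes, msg)
  }

  sim <- NULL
  if (!is.null(cfg$simulate)) {
    gen <- builtin_generator(cfg$simulate$generator)
    args <- cfg$simulate
    args$generator <- NULL
    args$seed <- args$seed %||% seeds[1L]
    sim <- do.call(gen, args)
    data <- sim$observations
    note(paste0("simulated data with generator `", cfg$simulate$generator,
                "` (seed ", args$seed, ")"))
  } else {
    data <- read_timeseries(cfg$data)
    note(paste0("read ", nrow(data), " observations from ", cfg$data))
  }
  obs_path <- file.path(out_dir, "observations.csv")
  write_timeseries(data, obs_path)

  spec <- config_spec(cfg)
  priors <- do.call(mgp_priors, c(list(spec), cfg$priors %||% list()))
  fit_args <- cfg$fit %||% list()
  fixed <- NULL
  if (!is.null(fit_args$fixed)) fixed <- unlist(fit_args$fixed)
  fit <- mgp_fit(data, spec, priors = priors,
                 n_starts = fit_args$n_starts %||% 10,
                 seed = seeds[2L],
                 fixed = fixed,
                 center = isTRUE(fit_args$center),
                 control = fit_args$control %||% list())
  note(paste0("MAP fit: log posterior ", format(fit$log_posterior, digits = 8),
              " from ", fit$n_starts_used, " usable starts"))
  par_path <- file.path(out_dir, "hyperparameters.csv")
  readr::write_csv(tidy(fit), par_path)

  pr <- cfg$predict %||% list()
  times <- if (!is.null(pr$times)) {
    unlist(pr$times)
  } else {
    r <- range(data$time)
    seq(pr$from %||% r[1], pr$to %||% r[2], length.out = pr$length %||% 101)
  }
  pred <- predict(fit, times = times,
                  include_noise = isTRUE(pr$include_noise))
  pred_path <- file.path(out_dir, "predictions.csv")
  readr::write_csv(tidy(pred), pred_path)

  paths <- list(observations = obs_path, hyperparameters = par_path,
                predictions = pred_path)
  st <- config_stoichiometry(cfg, sim)
  if (is.null(st)) {
    note("no stoichiometry configured; flux estimation stage skipped")
  } else {
    fl <- estimate_fluxes(pred, st, interpolate_known = TRUE)
    flux_path <- file.path(out_dir, "fluxes.csv")
    readr::write_csv(tidy(fl), flux_path)
    paths$fluxes <- flux_path
    cls <- attr(fl, "classification")
    note(paste0("flux system ", attr(fl, "system"), "; ",
                paste0(cls$flux, "=", cls$status, collapse = ", ")))
  }

  log$log_posterior <- fit$log_posterior
  log$log_lik <- fit$log_lik
  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE)
  paths$log <- log_path
  invisible(paths)
}
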