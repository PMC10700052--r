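#' Trajectory TSV round-trip
#'
#' Writes a simulated trajectory as a tab-separated table with columns
#' `generation, q_before, fitness, delta_s, delta_d, q_after`, preceded by
#' comment lines recording the population size and initial copy number and
#' followed by a trailing comment `# outcome=<fixed|lost|censored>`.
#' Frequencies live on the `1/ne` lattice, so they are restored exactly by
#' the reader (copy counts are recovered with `round(q * ne)`); all numeric
#' columns are written with full precision.
#'
#' @param traj a `wf_traj` object.
#' @param path output file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `wf_traj` object.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "wf_traj"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ne=%d", traj$ne), con)
  writeLines(sprintf("# init_copies=%d", as.integer(round(traj$q0 * traj$ne))), con)
  g <- traj$generations
  writeLines(paste(c("generation", "q_before", "fitness", "delta_s",
                     "delta_d", "q_after"), collapse = "\t"), con)
  if (nrow(g) > 0) {
    lines <- sprintf("%d\t%.17g\t%.17g\t%.17g\t%.17g\t%.17g",
                     g$generation, g$q_before, g$fitness, g$delta_s,
                     g$delta_d, g$q_after)
    writeLines(lines, con)
  }
  writeLines(sprintf("# outcome=%s", traj$outcome), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trajectory file: ", path, call. = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m) != 1) stop("missing '# ", key, "=' line in ", path, call. = FALSE)
    sub(paste0("^# ", key, "="), "", m)
  }
  ne <- as.integer(get_meta("ne"))
  init_copies <- as.integer(get_meta("init_copies"))
  outcome <- get_meta("outcome")
  body <- lines[!grepl("^#", lines)]
  g <- utils::read.delim(text = body, sep = "\t")
  # snap frequencies back onto the exact 1/ne lattice
  g$q_before <- round(g$q_before * ne) / ne
  g$q_after <- round(g$q_after * ne) / ne
  g$delta_d <- (g$q_after - g$q_before) - g$delta_s
  structure(list(ne = ne, q0 = init_copies / ne, generations = g,
                 outcome = outcome, n_generations = nrow(g),
                 regime = NULL, seed = NULL, linear = NA),
            class = "wf_traj")
}

#' Write a metrics summary or experiment result
#'
#' `write_metrics()` serialises a `wf_metrics` object to JSON (an undefined
#' `C` becomes `null`). `write_experiment()` writes each table of a
#' `wf_experiment` to TSV files under a directory, plus a JSON manifest
#' (config, seed, file checksums) via [write_manifest()].
#'
#' @param metrics a `wf_metrics` object.
#' @param experiment a `wf_experiment` object.
#' @param path,dir output locations.
#' @return The output path(s), invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "wf_metrics"))
  out <- unclass(metrics)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "wf_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in c("table", "records", "contradictions")) {
    obj <- experiment[[nm]]
    if (is.null(obj)) next
    f <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(obj, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  write_manifest(file.path(dir, "manifest.json"),
                 command = paste0("experiment/", experiment$name),
                 params = experiment$config, files = files)
  invisible(files)
}

#' Run manifest
#'
#' Writes a JSON manifest sufficient to re-execute a run: the command, the
#' full parameter set (including seeds), the package version, and an md5
#' checksum per output file. `verify_manifest()` recomputes the checksums
#' and reports which files still match.
#'
#' @param path manifest path.
#' @param command a label for the command executed.
#' @param params named list of parameters (seeds included).
#' @param files character vector of output files to checksum.
#' @return `write_manifest()` returns `path` invisibly; `verify_manifest()`
#'   returns a named logical vector, one element per file.
#' @export
write_manifest <- function(path, command, params, files = character(0)) {
  manifest <- list(
    command = command,
    params = params,
    package_version = as.character(utils::packageVersion("effsel")),
    files = if (length(files) > 0)
      as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
    else NULL,
    file_paths = as.list(files)
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  file.rename(tmp, path)  # atomic publish after success
  invisible(path)
}

#' @rdname write_manifest
#' @export
verify_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  files <- unlist(m$file_paths)
  expected <- unlist(m$files)
  if (length(files) == 0) return(logical(0))
  actual <- unname(tools::md5sum(files))
  stats::setNames(actual == unname(expected), basename(files))
}

#' Load and validate a simulation configuration
#'
#' Builds a validated simulation configuration from a JSON config file
#' and/or a named list of overrides (command-line flags override file
#' values). Recognised keys: `ne`, `init_freq` or `init_copies` (exactly
#' one), `regime` (a regime kind name), regime parameters (`f`, `f1`, `f2`,
#' `n_switch`, `f_odd`, `f_even`, `switch_prob`, `mean_block`, `f_low`,
#' `f_high`, `threshold`, `delta_schedule`), `max_generations`, `seed`,
#' `stop_on_absorption`. Unknown keys are rejected. The preset `"canonical"`
#' fills the canonical fluctuating-selection setup (`ne = 1000`, Markov
#' switching between 11/10 and 10/11 at probability 0.05).
#'
#' @param file optional JSON file path.
#' @param overrides named list of values overriding the file.
#' @param preset optional preset name (currently `"canonical"`).
#' @return A list of class `wf_config` with elements `ne`, `init_copies`,
#'   `regime` (a built [regimes] object), `max_generations`, `seed`,
#'   `stop_on_absorption`.
#' @export
load_config <- function(file = NULL, overrides = list(), preset = NULL) {
  cfg <- list()
  if (!is.null(preset)) {
    if (!identical(preset, "canonical"))
      stop("unknown preset: ", preset, call. = FALSE)
    cfg <- list(ne = 1000, regime = "markov_switch", f1 = 11 / 10,
                f2 = 10 / 11, switch_prob = 0.05)
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
    fromfile <- jsonlite::read_json(file, simplifyVector = TRUE)
    cfg[names(fromfile)] <- fromfile
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides

  allowed <- c("ne", "init_freq", "init_copies", "regime", "f", "f1", "f2",
               "n_switch", "f_odd", "f_even", "switch_prob", "mean_block",
               "f_low", "f_high", "threshold", "delta_schedule",
               "max_generations", "seed", "stop_on_absorption")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$ne)) stop("config requires 'ne'", call. = FALSE)
  if (!is.null(cfg$init_freq) && !is.null(cfg$init_copies))
    stop("give exactly one of 'init_freq' and 'init_copies'", call. = FALSE)
  if (is.null(cfg$regime)) stop("config requires 'regime'", call. = FALSE)

  need <- function(keys) {
    miss <- keys[vapply(keys, function(k) is.null(cfg[[k]]), logical(1))]
    if (length(miss) > 0)
      stop("regime '", cfg$regime, "' requires key(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  regime <- switch(cfg$regime,
    constant = { need("f"); regime_constant(cfg$f) },
    block = { need(c("f1", "f2", "n_switch"))
              regime_block(cfg$f1, cfg$f2, cfg$n_switch) },
    alternating = { need(c("f_odd", "f_even"))
                    regime_alternating(cfg$f_odd, cfg$f_even) },
    markov_switch = { need(c("f1", "f2", "switch_prob"))
                      regime_markov_switch(cfg$f1, cfg$f2, cfg$switch_prob) },
    poisson_block = { need(c("f1", "f2"))
                      regime_poisson_block(cfg$f1, cfg$f2,
                                           if (is.null(cfg$mean_block)) 20 else cfg$mean_block) },
    frequency_dependent = { need(c("f_low", "f_high", "threshold"))
                            regime_frequency_dependent(cfg$f_low, cfg$f_high,
                                                       cfg$threshold) },
    target_delta = { need("delta_schedule")
                     regime_target_delta(cfg$delta_schedule) },
    stop("unknown regime kind: ", cfg$regime, call. = FALSE)
  )
  init_copies <- resolve_init_copies(cfg$ne, cfg$init_copies, cfg$init_freq)
  structure(list(
    ne = as.integer(cfg$ne),
    init_copies = init_copies,
    regime = regime,
    max_generations = if (is.null(cfg$max_generations)) Inf else cfg$max_generations,
    seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed),
    stop_on_absorption = if (is.null(cfg$stop_on_absorption)) TRUE
                         else isTRUE(cfg$stop_on_absorption)
  ), class = "wf_config")
}

#' Run a simulation from a configuration object
#'
#' Convenience wrapper: `wf_sim_config(load_config(...))` is the programmatic
#' equivalent of the command-line `simulate` subcommand.
#'
#' @param config a `wf_config` from [load_config()].
#' @return A `wf_traj` object.
#' @export
wf_sim_config <- function(config) {
  stopifnot(inherits(config, "wf_config"))
  wf_sim(ne = config$ne, init_copies = config$init_copies,
         regime = config$regime, max_generations = config$max_generations,
         seed = config$seed, stop_on_absorption = config$stop_on_absorption)
}
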