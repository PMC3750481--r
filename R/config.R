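#' Parse a simulation configuration file
#'
#' Reads a YAML configuration with sections `population`, `phases`, and
#' `output` (plus optional `name` and `seed`) into a validated
#' [scenario_config()].  Parsing is strict: unknown keys anywhere are
#' fatal (no silent ignoring of a misspelled rate), and all missing
#' required keys are reported at once, each error qualified with its
#' path in the file.
#'
#' Schema (all numbers in days / normalized label units):
#' ```yaml
#' name: my_run            # optional
#' population:
#'   n_init: 1000
#'   alpha: 0.1            # division rate per day
#'   beta: 0.1             # death rate per day
#'   S: 20                 # truncation order per phase
#' phases:                 # chronological
#'   - duration: 10
#'     efficacy: {variant: normal, mean: 1, sd: 0.2}
#'   - duration: 10
#'     efficacy: {variant: dirac, location: 0}
#' output:
#'   eval_times: [2, 4, 6, 8, 10]
#'   grid: {min: -0.5, max: 1.5, n_points: 2001}   # optional
#'   l_theta: [0.1]        # optional thresholds
#'   sample_size: 0        # optional
#' seed: 1                 # optional
#' ```
#' Efficacy variants: `dirac` (`location`), `normal` (`mean`, `sd`),
#' `mixture` (`weights`, `means`, `sds`), `gridded` (`x`, `density`).
#'
#' @param path path to the YAML file.
#' @return A validated [scenario_config()].
#' @export
parse_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("parse_config: no such file: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  errs <- character()
  note <- function(...) errs <<- c(errs, sprintf(...))

  check_keys <- function(x, allowed, required, where) {
    unknown <- setdiff(names(x), allowed)
    for (u in unknown) note("%s: unknown key '%s'", where, u)
    missing <- setdiff(required, names(x))
    for (m in missing) note("%s: missing required key '%s'", where, m)
    length(missing) == 0L
  }

  check_keys(raw, c("name", "population", "phases", "output", "seed"),
             c("population", "phases", "output"), "top level")

  pop <- raw$population
  if (!is.null(pop)) {
    if (check_keys(pop, c("n_init", "alpha", "beta", "S"),
                   c("n_init", "alpha", "beta", "S"), "population")) {
      if (!is.numeric(pop$n_init) || pop$n_init <= 0)
        note("population.n_init: must be a positive number")
      if (!is.numeric(pop$alpha) || pop$alpha < 0)
        note("population.alpha: must be a non-negative rate per day")
      if (!is.numeric(pop$beta) || pop$beta < 0)
        note("population.beta: must be a non-negative rate per day")
      if (!is.numeric(pop$S) || pop$S < 1)
        note("population.S: must be a positive integer")
    }
  }

  parse_efficacy <- function(e, where) {
    if (!is.list(e) || is.null(e$variant)) {
      note("%s: efficacy must be a map with a 'variant' key", where)
      return(NULL)
    }
    tryCatch(switch(e$variant,
      dirac = {
        check_keys(e, c("variant", "location"), c("location"), where)
        efficacy_dirac(e$location)
      },
      normal = {
        check_keys(e, c("variant", "mean", "sd"), c("mean", "sd"), where)
        efficacy_normal(e$mean, e$sd)
      },
      mixture = {
        check_keys(e, c("variant", "weights", "means", "sds"),
                   c("weights", "means", "sds"), where)
        efficacy_mixture(unlist(e$weights), unlist(e$means), unlist(e$sds))
      },
      gridded = {
        check_keys(e, c("variant", "x", "density"), c("x", "density"), where)
        efficacy_gridded(unlist(e$x), unlist(e$density))
      },
      {
        note("%s: unknown efficacy variant '%s'", where, e$variant)
        NULL
      }),
      error = function(err) {
        note("%s: %s", where, conditionMessage(err))
        NULL
      })
  }

  phases <- list()
  if (!is.null(raw$phases)) {
    if (!is.list(raw$phases) || length(raw$phases) == 0L)
      note("phases: must be a non-empty list")
    else for (k in seq_along(raw$phases)) {
      ph <- raw$phases[[k]]
      where <- sprintf("phases[%d]", k)
      if (check_keys(ph, c("duration", "efficacy"),
                     c("duration", "efficacy"), where)) {
        if (!is.numeric(ph$duration) || ph$duration <= 0)
          note("%s.duration: must be a positive number of days", where)
        eff <- parse_efficacy(ph$efficacy, paste0(where, ".efficacy"))
        if (!is.null(eff))
          phases[[k]] <- list(duration = ph$duration, efficacy = eff)
      }
    }
  }

  out <- raw$output
  grid <- label_grid()
  if (!is.null(out)) {
    if (check_keys(out, c("eval_times", "grid", "l_theta", "sample_size"),
                   c("eval_times"), "output")) {
      if (!is.numeric(unlist(out$eval_times)))
        note("output.eval_times: must be numeric")
      if (!is.null(out$grid)) {
        # ("n" itself is a YAML 1.1 boolean token, hence "n_points")
        if (check_keys(out$grid, c("min", "max", "n_points"),
                       c("min", "max", "n_points"), "output.grid"))
          grid <- tryCatch(label_grid(out$grid$min, out$grid$max,
                                      out$grid$n_points),
                           error = function(e) {
                             note("output.grid: %s", conditionMessage(e))
                             label_grid()
                           })
      }
      if (!is.null(out$sample_size) &&
          (!is.numeric(out$sample_size) || out$sample_size < 0))
        note("output.sample_size: must be a non-negative integer")
    }
  }

  if (length(errs))
    stop(paste0("parse_config: invalid configuration:\n  ",
                paste(errs, collapse = "\n  ")), call. = FALSE)

  scenario_config(
    name = if (is.null(raw$name)) tools::file_path_sans_ext(basename(path))
           else raw$name,
    n_init = pop$n_init, alpha = pop$alpha, beta = pop$beta, S = pop$S,
    phases = phases,
    eval_times = as.numeric(unlist(out$eval_times)),
    grid = grid,
    l_theta = if (is.null(out$l_theta)) 0.1 else as.numeric(unlist(out$l_theta)),
    sample_size = if (is.null(out$sample_size)) 0L else out$sample_size,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

# canonical serialization of a config, hashed into the run manifest
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  stripped <- config
  saveRDS(stripped, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run a simulation and write the output bundle
#'
#' Orchestrates [run_scenario()] and writes, under `outdir`:
#'
#' * `population.csv`: long-format counts (`time_d`, `i_1..i_K`,
#'   `count`), time ascending then lexicographic index.
#' * `distribution.csv`: the overall label density (`time_d`, `x`,
#'   `density`).
#' * `atoms.csv`: point masses (`time_d`, `x`, `weight`).
#' * `intensities.csv`: single-column intensity sample at the last
#'   evaluation time (only when `sample_size > 0`).
#' * `summaries.json`: per-time total mass, mean intensity, fraction
#'   labeled at the configured thresholds, and peak counts.
#' * `manifest.json`: config hash, seed, package version, timestamp, and
#'   the md5 checksum of every output file.
#'
#' Reruns with the same configuration and seed produce byte-identical
#' CSV/summaries files.
#'
#' @param config a [scenario_config()] (e.g. from [parse_config()]).
#' @param outdir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @inheritParams run_scenario
#' @return Invisibly, the [run_scenario()] result with an added
#'   `manifest` field.
#' @export
run_simulation <- function(config, outdir, seed = NULL,
                           backend = c("auto", "analytic", "gridded"),
                           min_prominence = 0.02) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- run_scenario(config, backend = match.arg(backend),
                      min_prominence = min_prominence)

  paths <- file.path(outdir, c(population = "population.csv",
                               distribution = "distribution.csv",
                               atoms = "atoms.csv",
                               summaries = "summaries.json",
                               manifest = "manifest.json"))
  names(paths) <- c("population", "distribution", "atoms", "summaries",
                    "manifest")

  utils::write.csv(as.data.frame(res$population), paths["population"],
                   row.names = FALSE, quote = FALSE)

  dist_df <- do.call(rbind, lapply(res$distributions, function(d)
    data.frame(time_d = d$time, x = d$x, density = d$density)))
  utils::write.csv(dist_df, paths["distribution"], row.names = FALSE,
                   quote = FALSE)

  atom_df <- do.call(rbind, lapply(res$distributions, function(d)
    if (nrow(d$atoms)) data.frame(time_d = d$time, x = d$atoms$location,
                                  weight = d$atoms$weight)))
  if (is.null(atom_df))
    atom_df <- data.frame(time_d = numeric(), x = numeric(),
                          weight = numeric())
  atom_df <- atom_df[order(atom_df$time_d, atom_df$x), , drop = FALSE]
  utils::write.csv(atom_df, paths["atoms"], row.names = FALSE, quote = FALSE)

  if (!is.null(res$sample)) {
    paths <- c(paths, intensities = file.path(outdir, "intensities.csv"))
    utils::write.csv(data.frame(intensity = res$sample$intensities),
                     paths["intensities"], row.names = FALSE, quote = FALSE)
  }

  jsonlite::write_json(
    list(scenario = config$name, seed = config$seed,
         summaries = res$summaries),
    paths["summaries"], auto_unbox = TRUE, digits = NA, dataframe = "rows")

  file_paths <- paths[names(paths) != "manifest"]
  manifest <- list(
    scenario = config$name,
    config_hash = .config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("brdusim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(stats::setNames(as.list(file_paths), names(file_paths)),
                     function(p) list(path = basename(p),
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE)

  res$manifest <- manifest
  invisible(res)
}

#' Built-in self-check
#'
#' Runs a reduced version of the package's oracle-equivalence checks:
#' population solver against the constant-rate closed form, mass
#' conservation with equal rates, the closed-form Gaussian moments
#' against the composed one-division updates, and the normalization of
#' analytic and gridded densities.  Used by the `check` subcommand of
#' the command-line tool.
#'
#' @param fast if `TRUE`, smaller problem sizes.
#' @return Invisibly `TRUE` if all checks pass, otherwise an error is
#'   thrown naming the failed check.
#' @export
self_check <- function(fast = FALSE) {
  fail <- function(what) stop(sprintf("self_check failed: %s", what),
                              call. = FALSE)
  S <- if (fast) 10L else 20L
  part <- time_partition(c(0, 10))
  rates <- constant_rates(0.1, 0.1)
  sol <- solve_population(part, rates, 1000, S, c(5, 10))
  expect <- analytic_population_constant_rates(1000, 0.1, 0.1, 10, 0:(S - 1L))
  got <- sol$counts[2, 1:S]
  if (max(abs(got - expect) / pmax(expect, 1e-12)) > 1e-6)
    fail("population solver disagrees with the constant-rate closed form")
  if (abs(sum(sol$counts[2, ]) - 1000) / 1000 > 1e-4)
    fail("total count not conserved for alpha == beta")

  effs <- list(efficacy_normal(1, 0.2), efficacy_dirac(0))
  for (i1 in c(1L, 3L)) for (i2 in c(0L, 2L)) {
    ld <- conditional_label_density(c(i1, i2), effs, backend = "analytic")
    cf <- closed_form_normal(i1, i2, 1, 0.2)
    if (abs(density_mean(ld) - cf$mean) > 1e-10 ||
        abs(density_variance(ld) - cf$variance) > 1e-10)
      fail("analytic recursion disagrees with the closed-form moments")
  }
  gd <- conditional_label_density(c(2L, 0L), effs, backend = "gridded")
  if (abs(density_total(gd) - 1) > 1e-4)
    fail("gridded density is not normalized")
  invisible(TRUE)
}
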