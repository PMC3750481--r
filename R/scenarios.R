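#' Scenario configurations
#'
#' A `scenario_config` bundles everything one simulation needs: the
#' population parameters, the labeling phases (duration plus efficacy
#' distribution), the evaluation times, the label-axis grid, detection
#' thresholds, an optional intensity sample size, and the seed.
#'
#' @param name scenario name.
#' @param n_init initial cell count.
#' @param alpha,beta constant division and death rates (per day).
#' @param S truncation order per phase.
#' @param phases list of `list(duration =, efficacy =)` entries in
#'   chronological order.
#' @param eval_times evaluation times (days, non-decreasing, within the
#'   experiment).
#' @param grid a [label_grid()].
#' @param l_theta detection threshold(s) for the fraction-labeled
#'   summary.
#' @param sample_size intensity sample size (`0` for none; drawn at the
#'   last evaluation time).
#' @param seed integer seed for all randomness of the run.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(name, n_init, alpha, beta, S, phases,
                            eval_times, grid = label_grid(),
                            l_theta = 0.1, sample_size = 0L, seed = 1L) {
  if (!is.numeric(n_init) || n_init <= 0)
    stop("scenario_config: n_init must be positive", call. = FALSE)
  if (alpha < 0 || beta < 0)
    stop("scenario_config: rates must be non-negative", call. = FALSE)
  S <- as.integer(S)
  if (S < 1L) stop("scenario_config: S must be at least 1", call. = FALSE)
  if (!length(phases))
    stop("scenario_config: at least one phase is required", call. = FALSE)
  for (p in phases) {
    if (!is.list(p) || is.null(p$duration) || is.null(p$efficacy) ||
        !inherits(p$efficacy, "efficacy") || p$duration <= 0)
      stop("scenario_config: each phase needs a positive duration and an efficacy",
           call. = FALSE)
  }
  boundaries <- cumsum(c(0, vapply(phases, `[[`, numeric(1), "duration")))
  eval_times <- as.numeric(eval_times)
  if (is.unsorted(eval_times) || any(eval_times < 0) ||
      any(eval_times > boundaries[length(boundaries)] + 1e-12))
    stop("scenario_config: eval_times must be non-decreasing and within the experiment",
         call. = FALSE)
  structure(list(name = name, n_init = n_init, alpha = alpha, beta = beta,
                 S = S, phases = phases,
                 partition = time_partition(boundaries),
                 eval_times = eval_times, grid = grid,
                 l_theta = as.numeric(l_theta),
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s'\n", x$name))
  cat(sprintf("  n_init = %g, alpha = %g/d, beta = %g/d, S = %d\n",
              x$n_init, x$alpha, x$beta, x$S))
  for (k in seq_along(x$phases))
    cat(sprintf("  phase %d: %g d, efficacy %s\n", k,
                x$phases[[k]]$duration, x$phases[[k]]$efficacy$variant))
  cat(sprintf("  eval times (d): %s\n", paste(x$eval_times, collapse = ", ")))
  invisible(x)
}

#' Built-in scenario: noisy label uptake
#'
#' A population of 1000 cells with equal division and death rates of
#' 0.1 per day is uplabeled for 10 days with a normally distributed
#' labeling efficacy `N(1, sigma^2)` (noise in the uptake at each
#' division), then delabeled (zero efficacy) so that content halves per
#' division.  Evaluations every 2 days.  The delabeling duration is not
#' fixed by the study setup; the default mirrors the uplabeling phase.
#'
#' @param sigma uptake noise level (default 0.2).
#' @param uplabel_days,delabel_days phase durations in days.
#' @param eval_step spacing of evaluation times in days.
#' @param S truncation order per phase.
#' @return A [scenario_config()].
#' @export
#' @examples
#' scenario_noisy_uptake()
scenario_noisy_uptake <- function(sigma = 0.2, uplabel_days = 10,
                                  delabel_days = 10, eval_step = 2, S = 20L) {
  scenario_config(
    name = "noisy_uptake",
    n_init = 1000, alpha = 0.1, beta = 0.1, S = S,
    phases = list(
      list(duration = uplabel_days, efficacy = efficacy_normal(1, sigma)),
      list(duration = delabel_days, efficacy = efficacy_dirac(0))),
    eval_times = seq(eval_step, uplabel_days + delabel_days, by = eval_step))
}

#' Built-in scenario: spatially heterogeneous labeling efficacy
#'
#' Same population as [scenario_noisy_uptake()], but the organism is
#' split into two compartments with different label concentration: two
#' thirds of divisions take up the full label (`N(1, sigma^2)`), one
#' third only half (`N(0.5, sigma^2)`).  Uplabeling for 10 days; the
#' per-division densities `p(x|i_1)` are available via
#' [division_densities()].
#'
#' @param sigma within-compartment standard deviation (default 0.05).
#' @param uplabel_days phase duration in days.
#' @param eval_step spacing of evaluation times in days.
#' @param S truncation order.
#' @return A [scenario_config()].
#' @export
#' @examples
#' scenario_spatial_heterogeneity()
scenario_spatial_heterogeneity <- function(sigma = 0.05, uplabel_days = 10,
                                           eval_step = 2, S = 20L) {
  scenario_config(
    name = "spatial_heterogeneity",
    n_init = 1000, alpha = 0.1, beta = 0.1, S = S,
    phases = list(
      list(duration = uplabel_days,
           efficacy = heterogeneous_efficacy(c(1/3, 2/3), c(0.5, 1), sigma))),
    eval_times = seq(eval_step, uplabel_days, by = eval_step))
}

#' Per-division label densities of a scenario's first phase
#'
#' Returns `p(x|i_1)` for the requested division numbers under the
#' phase-1 efficacy (no later-phase divisions), as plotted for the
#' heterogeneity scenario.
#'
#' @param config a [scenario_config()].
#' @param i division numbers (default 1..7).
#' @inheritParams conditional_label_density
#' @return Named list of `label_density` objects.
#' @export
division_densities <- function(config, i = 1:7,
                               backend = c("auto", "analytic", "gridded"),
                               grid = config$grid) {
  backend <- match.arg(backend)
  eff <- list(config$phases[[1]]$efficacy)
  out <- lapply(i, conditional_label_density, efficacies = eff,
                backend = backend, grid = grid)
  names(out) <- paste0("i1=", i)
  out
}

#' Run a scenario end to end
#'
#' Solves the population model, builds the conditional density table,
#' assembles the overall label distribution at every evaluation time,
#' and computes the summaries (total mass, mean intensity, fraction
#' labeled at each threshold, peak count).
#'
#' @param config a [scenario_config()].
#' @inheritParams conditional_label_density
#' @param min_prominence prominence floor passed to [count_peaks()].
#' @return Object of class `simulation_result` with fields `config`,
#'   `population` ([solve_population()] output), `densities`,
#'   `distributions` (one [overall_distribution()] per eval time),
#'   `summaries` (data frame), and `sample` (an `intensity_sample` or
#'   `NULL`).
#' @export
#' @examples
#' \donttest{
#' res <- run_scenario(scenario_noisy_uptake())
#' res$summaries
#' }
run_scenario <- function(config, backend = c("auto", "analytic", "gridded"),
                         min_prominence = 0.02) {
  stopifnot(inherits(config, "scenario_config"))
  backend <- match.arg(backend)
  rates <- constant_rates(config$alpha, config$beta)
  pop <- solve_population(config$partition, rates, config$n_init, config$S,
                          config$eval_times)
  effs <- lapply(config$phases, `[[`, "efficacy")
  densities <- conditional_density_table(config$S, effs, backend = backend,
                                         grid = config$grid)
  distributions <- lapply(config$eval_times, function(tq)
    overall_distribution(population_state(pop, tq), densities, config$grid))
  names(distributions) <- paste0("t=", config$eval_times)

  summaries <- do.call(rbind, lapply(distributions, function(d) {
    fl <- vapply(config$l_theta, function(lt) fraction_labeled(d, lt),
                 numeric(1))
    row <- data.frame(time_d = d$time, total = d$total,
                      mean_intensity = mean_intensity(d),
                      peaks = as.integer(count_peaks(d, min_prominence)))
    for (j in seq_along(config$l_theta))
      row[[paste0("frac_labeled_", config$l_theta[j])]] <- fl[j]
    row
  }))
  rownames(summaries) <- NULL

  sample <- NULL
  if (config$sample_size > 0L)
    sample <- sample_intensities(distributions[[length(distributions)]],
                                 config$sample_size, seed = config$seed)

  structure(list(config = config, population = pop, densities = densities,
                 distributions = distributions, summaries = summaries,
                 sample = sample),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> scenario '%s'\n", x$config$name))
  print(x$summaries, digits = 4)
  invisible(x)
}

#' Small oracle-backed test fixtures
#'
#' Tiny scenario configurations with closed-form expected outputs, used
#' by the test-suite and by the command-line self-check:
#'
#' * `dirac_toy`: uniform uptake value 1; after `i` divisions the content
#'   is exactly `1 - 2^-i`, so the overall distribution is a set of atoms
#'   with Poisson-form weights.
#' * `normal_toy`: noisy uptake; conditional moments from
#'   [closed_form_normal()].
#' * `mixture_toy`: two-compartment uptake; after one division the
#'   density has modes at 0.25 and 0.5.
#'
#' @param kind one of `"dirac_toy"`, `"normal_toy"`, `"mixture_toy"`.
#' @param seed integer seed stored in the configuration.
#' @return `list(config =, expected =)`; `expected` holds the
#'   oracle-computed values the fixture promises.
#' @export
generate_fixture <- function(kind = c("dirac_toy", "normal_toy",
                                      "mixture_toy"), seed = 1L) {
  kind <- match.arg(kind)
  base <- function(eff, S) scenario_config(
    name = kind, n_init = 100, alpha = 0.1, beta = 0.1, S = S,
    phases = list(list(duration = 2, efficacy = eff)),
    eval_times = c(1, 2), seed = seed)
  switch(kind,
    dirac_toy = {
      S <- 4L
      cfg <- base(efficacy_dirac(1), S)
      i <- 0:S
      list(config = cfg, expected = list(
        atom_locations = 1 - 2^(-i),
        atom_weights_t2 = analytic_population_constant_rates(
          100, 0.1, 0.1, 2, i)))
    },
    normal_toy = {
      S <- 3L
      cfg <- base(efficacy_normal(1, 0.2), S)
      mom <- lapply(0:S, function(ii) closed_form_normal(ii, 0, 1, 0.2))
      list(config = cfg, expected = list(
        means = vapply(mom, `[[`, numeric(1), "mean"),
        variances = vapply(mom, `[[`, numeric(1), "variance")))
    },
    mixture_toy = {
      S <- 3L
      cfg <- base(heterogeneous_efficacy(c(1/3, 2/3), c(0.5, 1), 0.05), S)
      list(config = cfg, expected = list(
        modes_after_one_division = c(0.25, 0.5),
        efficacy_mean = 5 / 6))
    })
}
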