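make_state <- function(counts, S, K = 1L) {
  structure(list(time = 0, counts = counts,
                 index = division_index_matrix(K, S), S = S, K = K),
            class = "population_state")
}

test_that("number densities integrate to their cell counts", {
  effs <- list(efficacy_normal(1, 0.2))
  dens <- conditional_density_table(2, effs, backend = "analytic")
  state <- make_state(c(135.34, 50, 0), 2L)
  nd <- number_density(state, dens)
  expect_equal(sum(nd[[1]]$atoms$weight), 135.34)
  expect_equal(sum(nd[[2]]$gaussians$weight), 50)
  expect_equal(density_total(nd[[3]]), 0)
  expect_error(number_density(state, dens[1:2]), "density is required")
})

test_that("the initial population is a single unlabeled atom", {
  effs <- list(efficacy_normal(1, 0.2))
  dens <- conditional_density_table(3, effs)
  state <- make_state(c(1000, 0, 0, 0), 3L)
  dist <- overall_distribution(state, dens)
  expect_equal(dist$atoms$weight, 1000)
  expect_equal(dist$atoms$location, 0)
  expect_equal(dist$total, 1000, tolerance = 1e-12)
  expect_equal(mean_intensity(dist), 0)
  expect_equal(fraction_labeled(dist, 0.1), 0)
})

test_that("uniform uptake yields atoms at the geometric dilution ladder", {
  S <- 6L
  part <- time_partition(c(0, 10))
  sol <- solve_population(part, constant_rates(0.1, 0.1), 1000, S, 10)
  dens <- conditional_density_table(S, list(efficacy_dirac(1)))
  dist <- overall_distribution(population_state(sol, 10), dens)
  ord <- order(dist$atoms$location)
  expect_equal(dist$atoms$location[ord], 1 - 2^-(0:S))
  counts <- analytic_population_constant_rates(1000, 0.1, 0.1, 10, 0:(S - 1))
  expect_equal(dist$atoms$weight[ord][1:S], counts, tolerance = 1e-6)
  # threshold fraction from the atom ladder: i with 1 - 2^-i >= 0.4
  frac <- fraction_labeled(dist, 0.4)
  expect_equal(frac, sum(dist$atoms$weight[dist$atoms$location >= 0.4]) /
                 dist$total, tolerance = 1e-12)
  expect_equal(frac, 1 - counts[1] / sum(dist$atoms$weight),
               tolerance = 1e-5)
})

test_that("assembled mass matches the population at every eval time", {
  S <- 12L
  part <- time_partition(c(0, 6))
  sol <- solve_population(part, constant_rates(0.12, 0.06), 800, S,
                          c(2, 4, 6))
  dens <- conditional_density_table(S, list(efficacy_normal(1, 0.2)))
  for (tq in c(2, 4, 6)) {
    st <- population_state(sol, tq)
    dist <- overall_distribution(st, dens)
    expect_equal(dist$total, sum(st$counts), tolerance = 1e-4)
    expect_true(all(dist$density >= 0))
  }
})

test_that("fraction labeled is exact at the extremes and monotone", {
  S <- 8L
  sol <- solve_population(time_partition(c(0, 6)), constant_rates(0.1, 0.1),
                          1000, S, 6)
  dens <- conditional_density_table(S, list(efficacy_normal(1, 0.2)))
  dist <- overall_distribution(population_state(sol, 6), dens)
  expect_equal(fraction_labeled(dist, 10), 0)
  expect_equal(fraction_labeled(dist, -10), 1)
  fr <- vapply(seq(-0.2, 1.2, by = 0.1),
               function(lt) fraction_labeled(dist, lt), numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
  expect_error(fraction_labeled(dist, Inf), "finite")
})

test_that("mean intensity equals the population-weighted component means", {
  S <- 15L
  sol <- solve_population(time_partition(c(0, 10)), constant_rates(0.1, 0.1),
                          1000, S, 10)
  st <- population_state(sol, 10)
  dens <- conditional_density_table(S, list(efficacy_normal(1, 0.2)))
  dist <- overall_distribution(st, dens)
  expected <- sum(st$counts * (1 - 2^-(0:S))) / sum(st$counts)
  expect_equal(mean_intensity(dist), expected, tolerance = 1e-6)
})

test_that("intensity sampling is reproducible and exact on atoms", {
  dens <- conditional_density_table(2, list(efficacy_dirac(1)))
  state <- make_state(c(0, 100, 0), 2L)
  dist <- overall_distribution(state, dens)
  s <- sample_intensities(dist, 50, seed = 3)
  expect_true(all(s$intensities == 0.5))
  # Gaussian case: CLT bound on the sample mean, and bit-identical reruns
  dens <- conditional_density_table(1, list(efficacy_normal(1, 0.2)))
  dist <- overall_distribution(make_state(c(0, 1000), 1L), dens)
  M <- 1e5
  s1 <- sample_intensities(dist, M, seed = 11)
  s2 <- sample_intensities(dist, M, seed = 11)
  expect_identical(s1$intensities, s2$intensities)
  expect_lt(abs(mean(s1$intensities) - 0.5), 4 * 0.1 / sqrt(M))
})

test_that("peak counting detects separated modes and merges close ones", {
  grid <- label_grid()
  two <- data.frame(kind = "gaussian", weight = c(60, 40),
                    mean = c(0.25, 0.5), sd = 0.025)
  mk <- function(m) {
    d <- numeric(grid$n)
    for (r in seq_len(nrow(m)))
      d <- d + m$weight[r] * dnorm(grid$x, m$mean[r], m$sd[r])
    structure(list(time = 0, x = grid$x, density = d,
                   atoms = data.frame(weight = numeric(),
                                      location = numeric()),
                   grid = grid, total = sum(m$weight), mixture = m),
              class = "overall_distribution")
  }
  expect_identical(as.integer(count_peaks(mk(two[1, ]), 0.05)), 1L)
  expect_identical(as.integer(count_peaks(mk(two), 0.05)), 2L)
  merged <- data.frame(kind = "gaussian", weight = c(50, 50),
                       mean = c(0.49, 0.50), sd = 0.1)
  expect_identical(as.integer(count_peaks(mk(merged), 0.05)), 1L)
  # atoms count separately on request
  d <- mk(two)
  d$atoms <- data.frame(weight = 10, location = 0)
  expect_identical(as.integer(count_peaks(d, 0.05, include_atoms = TRUE)), 3L)
  d$density <- d$density * 0
  expect_error(count_peaks(d), NA)
  d$atoms <- d$atoms[0, ]
  expect_error(count_peaks(d), "identically zero")
})

test_that("transport-equation oracle matches the decomposed construction", {
  part <- time_partition(c(0, 1))
  rates <- constant_rates(0.1, 0.1)
  eff <- list(efficacy_normal(1, 0.2))
  grid <- label_grid(n = 401)
  pde <- pde_reference_solver(part, rates, 1000, eff, S = 3, grid = grid,
                              eval_times = 1)[[1]]
  sol <- solve_population(part, rates, 1000, 3, 1)
  dens <- conditional_density_table(3, eff, backend = "analytic")
  ode <- overall_distribution(population_state(sol, 1), dens, grid)
  expect_lt(max(abs(pde$density - ode$density)), 1e-2 * max(ode$density))
  expect_equal(pde$total, sum(sol$counts[1, ]), tolerance = 1e-3)
  expect_equal(pde$atoms$weight, ode$atoms$weight, tolerance = 1e-6)
})

test_that("transport-equation oracle handles the no-division limit", {
  part <- time_partition(c(0, 2))
  pde <- pde_reference_solver(part, constant_rates(0, 0.1), 1000,
                              list(efficacy_normal(1, 0.2)), S = 2,
                              grid = label_grid(n = 201),
                              eval_times = 2)[[1]]
  expect_equal(pde$atoms$weight, 1000 * exp(-0.2), tolerance = 1e-8)
  expect_lt(max(abs(pde$density)), 1e-8)
})

test_that("transport-equation oracle rejects unsupported inputs", {
  part <- time_partition(c(0, 1))
  rates <- constant_rates(0.1, 0.1)
  expect_error(pde_reference_solver(part, rates, 100,
                                    list(efficacy_dirac(1)), 2,
                                    eval_times = 1), "atomic")
  expect_error(pde_reference_solver(time_partition(c(0, 1, 2)), rates, 100,
                                    list(efficacy_normal(1, 0.2),
                                         efficacy_dirac(0)), 2,
                                    eval_times = 1), "single labeling")
})
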