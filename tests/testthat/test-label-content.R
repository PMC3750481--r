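test_that("efficacy constructors validate their parameters", {
  expect_error(efficacy_normal(1, -0.1), "non-negative")
  expect_error(efficacy_mixture(c(0.5, 0.49), c(0, 1), 0.1), "sum to")
  expect_error(efficacy_mixture(c(0.5, 0.5), c(0, 1), -1), "non-negative")
  expect_error(efficacy_gridded(c(0, 1, 2), c(1, 1, 1)), "integrates to")
  # sd = 0 degenerates to an atom
  e <- efficacy_normal(0.7, 0)
  expect_equal(e$atoms$location, 0.7)
  # dirac(0) is the delabeling distribution
  expect_equal(efficacy_dirac(0)$atoms$location, 0)
})

test_that("one division halves the prior and adds half an uptake draw", {
  d0 <- label_density_atom(0)
  # fixed uptake of 1 from the unlabeled state: atom at 0.5
  d <- one_division_update(d0, efficacy_dirac(1))
  expect_equal(d$atoms$location, 0.5)
  expect_equal(d$atoms$weight, 1)
  # noisy uptake from the unlabeled state: N(0.5, 0.1^2)
  d <- one_division_update(d0, efficacy_normal(1, 0.2))
  expect_equal(d$gaussians$mean, 0.5)
  expect_equal(d$gaussians$sd, 0.1)
  # delabeling division: pure halving
  prior <- one_division_update(d0, efficacy_normal(1, 0.2))
  d <- one_division_update(prior, efficacy_dirac(0))
  expect_equal(d$gaussians$mean, 0.25)
  expect_equal(d$gaussians$sd, 0.05)
})

test_that("conditional densities follow the dilution recursion", {
  effs <- noisy_efficacies()
  # no divisions: delta(x)
  d <- conditional_label_density(c(0, 0), effs)
  expect_equal(nrow(d$gaussians), 0)
  expect_equal(d$atoms$location, 0)
  # two fixed-uptake divisions: geometric sum (1 - 2^-2)
  d <- conditional_label_density(c(2, 0),
                                 list(efficacy_dirac(1), efficacy_dirac(0)))
  expect_equal(d$atoms$location, 0.75)
  # one noisy uplabeling division then three delabeling halvings
  d <- conditional_label_density(c(1, 3), effs)
  expect_equal(d$gaussians$mean, 0.0625)
  expect_equal(d$gaussians$sd, 0.0125)
  expect_error(conditional_label_density(c(1, 1), list()), "non-empty")
  expect_error(conditional_label_density(c(1), effs), "number of phases")
})

test_that("closed-form moments obey the dilution scaling laws", {
  cf <- closed_form_normal(1, 0, 1, 0.2)
  expect_equal(cf$mean, 0.5)
  expect_equal(cf$variance, 0.01)
  # geometric-series limit of the mean
  expect_equal(closed_form_normal(40, 0, 0.8, 0.2)$mean, 0.8,
               tolerance = 1e-10)
  # each delabeling division halves the mean and quarters the variance
  for (i1 in c(1, 4)) for (i2 in c(0, 3)) {
    a <- closed_form_normal(i1, i2, 1, 0.2)
    b <- closed_form_normal(i1, i2 + 1, 1, 0.2)
    expect_equal(b$mean, a$mean / 2)
    expect_equal(b$variance, a$variance / 4)
  }
})

test_that("analytic recursion reproduces the closed-form moments exactly", {
  effs <- noisy_efficacies()
  for (i1 in 0:6) for (i2 in 0:3) {
    ld <- conditional_label_density(c(i1, i2), effs, backend = "analytic")
    cf <- closed_form_normal(i1, i2, 1, 0.2)
    expect_lt(abs(density_mean(ld) - cf$mean), 1e-10)
    expect_lt(abs(density_variance(ld) - cf$variance), 1e-10)
  }
})

test_that("Monte-Carlo simulation of the recursion matches the densities", {
  set.seed(42)
  n <- 1e5
  effs <- noisy_efficacies()
  mix <- spatial_efficacy()
  cases <- list(list(i = c(1L, 0L), eff = effs),
                list(i = c(3L, 0L), eff = effs),
                list(i = c(2L, 2L), eff = effs),
                list(i = 2L, eff = list(mix)),
                list(i = 5L, eff = list(mix)))
  for (cs in cases) {
    x <- mc_sample_recursion(cs$i, cs$eff, n)
    se <- mc_se(x)
    ld <- conditional_label_density(cs$i, cs$eff)
    expect_lt(abs(mean(x) - density_mean(ld)), 4 * se$mean)
    expect_lt(abs(var(x) - density_variance(ld)), 4 * se$variance)
  }
})

test_that("analytic and gridded backends agree on smooth cases", {
  grid <- label_grid()
  cases <- list(list(i = c(3L, 0L), eff = noisy_efficacies()),
                list(i = c(2L, 1L), eff = noisy_efficacies()),
                list(i = 3L, eff = list(spatial_efficacy())))
  for (cs in cases) {
    a <- conditional_label_density(cs$i, cs$eff, backend = "analytic")
    g <- conditional_label_density(cs$i, cs$eff, backend = "gridded",
                                   grid = grid)
    expect_lt(max(abs(density_at(a, grid$x) - g$density)), 1e-3)
    expect_equal(density_total(g), 1, tolerance = 1e-4)
  }
})

test_that("densities stay normalized after any update sequence", {
  set.seed(7)
  pool <- list(efficacy_normal(1, 0.2), efficacy_dirac(0.8),
               spatial_efficacy(0.1), efficacy_dirac(0))
  for (rep in 1:8) {
    effs <- pool[sample.int(length(pool), 2)]
    i <- sample(0:4, 2, replace = TRUE)
    ld <- conditional_label_density(i, effs, backend = "analytic")
    expect_equal(density_total(ld), 1, tolerance = 1e-8)
  }
  gd <- conditional_label_density(4L, list(spatial_efficacy()),
                                  backend = "gridded")
  expect_equal(density_total(gd), 1, tolerance = 1e-4)
})

test_that("update order matters across phases but not within one", {
  up <- efficacy_normal(1, 0.2)
  del <- efficacy_dirac(0)
  d0 <- label_density_atom(0)
  chrono <- one_division_update(one_division_update(
    one_division_update(d0, up), up), del)
  permuted <- one_division_update(one_division_update(
    one_division_update(d0, del), up), up)
  expect_gt(abs(density_mean(chrono) - density_mean(permuted)), 0.3)
  # within one phase the updates are identical operations: swapping the
  # two uplabeling updates is a no-op by construction
  swapped <- one_division_update(one_division_update(
    one_division_update(d0, up), up), del)
  expect_equal(density_mean(chrono), density_mean(swapped))
})

test_that("Dirac efficacy reproduces the uniform-label atom chain", {
  for (i in 1:5) {
    d <- conditional_label_density(i, list(efficacy_dirac(0.8)))
    expect_equal(nrow(d$gaussians), 0)
    expect_equal(d$atoms$location, (1 - 2^-i) * 0.8)
    expect_equal(d$atoms$weight, 1)
  }
})

test_that("bounded-support efficacies keep the density inside [0, u_max)", {
  # triangular efficacy on [0, 1]
  x <- seq(0, 1, by = 0.001)
  tri <- efficacy_gridded(x, 2 * x)
  ld <- label_density_atom(0)
  ld <- as_gridded(ld, label_grid())
  for (d in 1:3) ld <- one_division_update(ld, tri)
  outside <- ld$grid$x < -1e-9 | ld$grid$x >= 1
  expect_lt(sum(ld$density[outside]) * ld$grid$h, 1e-6)
  # mixture case: tail mass outside [0, 1.15] is tiny even though the
  # normals are untruncated
  m <- conditional_label_density(2L, list(spatial_efficacy()),
                                 backend = "gridded")
  outside <- m$grid$x < 0 | m$grid$x > 1.15
  expect_lt(sum(m$density[outside]) * m$grid$h, 1e-6)
})

test_that("a grid too coarse for a narrow efficacy is rejected", {
  ld <- as_gridded(label_density_atom(0), label_grid())
  expect_error(one_division_update(ld, efficacy_normal(1, 0.003)),
               "refine the grid")
  expect_error(as_gridded(conditional_label_density(
    c(1, 6), noisy_efficacies(), backend = "analytic"), label_grid()),
    "refine the grid")
})

test_that("optional zero-truncation removes negative-label mass", {
  ld <- conditional_label_density(1L, list(efficacy_normal(0.1, 0.2)),
                                  backend = "gridded",
                                  truncate_at_zero = TRUE)
  expect_true(all(ld$density[ld$grid$x < 0] == 0))
  expect_equal(density_total(ld), 1, tolerance = 1e-6)
  expect_error(conditional_label_density(1L, list(efficacy_normal(1, 0.2)),
                                         backend = "analytic",
                                         truncate_at_zero = TRUE),
               "gridded")
})

test_that("mixture efficacy helper produces the intended distribution", {
  mx <- heterogeneous_efficacy(c(1 / 3, 2 / 3), c(0.5, 1), 0.05)
  expect_equal(sum(mx$gaussians$weight * mx$gaussians$mean), 5 / 6)
  g <- label_grid()
  vals <- density_at(new_label_density_analytic(
    mx$gaussians, data.frame(weight = numeric(), location = numeric())), g$x)
  expect_equal(g$h * (sum(vals) - (vals[1] + vals[g$n]) / 2), 1,
               tolerance = 1e-6)
  # degenerate single-component mixture equals a plain normal
  one <- efficacy_mixture(1, 0.9, 0.1)
  expect_equal(one$gaussians, efficacy_normal(0.9, 0.1)$gaussians)
  # one division from delta(0): modes at 0.25 and 0.5
  d <- conditional_label_density(1L, list(mx), backend = "gridded")
  pk <- count_peaks(structure(list(density = d$density, x = d$grid$x,
                                   atoms = d$atoms, grid = d$grid,
                                   total = 1, mixture = NULL),
                              class = "overall_distribution"), 0.05)
  expect_identical(as.integer(pk), 2L)
  expect_equal(sort(attr(pk, "locations")), c(0.25, 0.5), tolerance = 1e-2)
})

test_that("L1 distance behaves like a metric on the extremes", {
  a <- conditional_label_density(c(2, 0), noisy_efficacies())
  expect_equal(l1_distance(a, a), 0, tolerance = 1e-12)
  d1 <- label_density_atom(0)
  d2 <- label_density_atom(0.5)
  expect_equal(l1_distance(d1, d2), 2)
})
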