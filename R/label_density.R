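#' Label-content densities conditional on a division history
#'
#' `p(x|i)` is the probability density of the label content of a cell
#' that has divided `i_k` times during labeling phase `k`.  Two backends
#' represent it:
#'
#' * analytic: a list of weighted Gaussian components plus weighted point
#'   masses (atoms).  Exact for Dirac/normal/mixture efficacies.
#' * gridded: nodal density values on a [label_grid()], plus atoms.
#'   Atoms are always carried symbolically and never discretized.
#'
#' `label_density_atom()` builds the degenerate density `delta(x - loc)`;
#' the undivided pool has `p(x|0) = delta(x)`.
#'
#' @param location atom location (label content units).
#' @return An object of class `label_density`.
#' @export
#' @examples
#' label_density_atom(0)   # undivided cells carry no label
label_density_atom <- function(location = 0) {
  new_label_density_analytic(
    gaussians = data.frame(weight = numeric(), mean = numeric(),
                           sd = numeric()),
    atoms = data.frame(weight = 1, location = location))
}

new_label_density_analytic <- function(gaussians, atoms, condition = NULL) {
  structure(list(backend = "analytic", gaussians = gaussians, atoms = atoms,
                 grid = NULL, density = NULL, condition = condition),
            class = "label_density")
}

new_label_density_gridded <- function(grid, density, atoms, condition = NULL) {
  structure(list(backend = "gridded", gaussians = NULL, atoms = atoms,
                 grid = grid, density = density, condition = condition),
            class = "label_density")
}

#' @export
print.label_density <- function(x, ...) {
  cond <- if (is.null(x$condition)) "" else
    sprintf(" | i = (%s)", paste(x$condition, collapse = ","))
  if (x$backend == "analytic")
    cat(sprintf("<label_density%s> analytic: %d Gaussian(s), %d atom(s), mass %.8g\n",
                cond, nrow(x$gaussians), nrow(x$atoms), density_total(x)))
  else
    cat(sprintf("<label_density%s> gridded (%d nodes), %d atom(s), mass %.8g\n",
                cond, x$grid$n, nrow(x$atoms), density_total(x)))
  invisible(x)
}

#' Total probability, mean, and variance of a label density
#'
#' `density_total()` returns the total probability mass (continuous
#' integral plus atom weights); it should be 1 for any normalized
#' density.  `density_mean()` and `density_variance()` return exact
#' moments for the analytic backend and trapezoid-quadrature moments for
#' the gridded backend.
#'
#' @param ld a `label_density`.
#' @export
density_total <- function(ld) {
  a <- sum(ld$atoms$weight)
  if (ld$backend == "analytic") a + sum(ld$gaussians$weight)
  else a + grid_trapz(ld$grid, ld$density)
}

#' @rdname density_total
#' @export
density_mean <- function(ld) {
  if (ld$backend == "analytic")
    sum(ld$gaussians$weight * ld$gaussians$mean) +
      sum(ld$atoms$weight * ld$atoms$location)
  else
    grid_trapz(ld$grid, ld$grid$x * ld$density) +
      sum(ld$atoms$weight * ld$atoms$location)
}

#' @rdname density_total
#' @export
density_variance <- function(ld) {
  m <- density_mean(ld)
  if (ld$backend == "analytic")
    ex2 <- sum(ld$gaussians$weight * (ld$gaussians$mean^2 + ld$gaussians$sd^2)) +
      sum(ld$atoms$weight * ld$atoms$location^2)
  else
    ex2 <- grid_trapz(ld$grid, ld$grid$x^2 * ld$density) +
      sum(ld$atoms$weight * ld$atoms$location^2)
  ex2 - m^2
}

#' Evaluate the continuous part of a label density
#'
#' Atoms are not included (they have no density value); use `ld$atoms`
#' for the point masses.
#'
#' @param ld a `label_density`.
#' @param x evaluation points.
#' @export
density_at <- function(ld, x) {
  if (ld$backend == "analytic") {
    g <- ld$gaussians
    if (nrow(g) == 0L) return(numeric(length(x)))
    rowSums(vapply(seq_len(nrow(g)),
                   function(r) g$weight[r] * stats::dnorm(x, g$mean[r], g$sd[r]),
                   numeric(length(x))))
  } else {
    grid_interp(ld$grid, ld$density, x)
  }
}

# maximum analytic component count before the analytic backend refuses;
# mixtures multiply component counts per division
.max_components <- 65536L

#' Convert an analytic label density to the gridded backend
#'
#' Gaussian components are evaluated at the grid nodes; a component whose
#' standard deviation is below two grid steps cannot be resolved and is
#' rejected (refine the grid).  Atoms stay symbolic.
#'
#' @param ld a `label_density`.
#' @param grid a [label_grid()].
#' @export
as_gridded <- function(ld, grid = label_grid()) {
  if (ld$backend == "gridded") {
    if (!same_grid(ld$grid, grid))
      ld$density <- grid_interp(ld$grid, ld$density, grid$x)
    ld$grid <- grid
    return(ld)
  }
  g <- ld$gaussians
  if (nrow(g) && any(g$sd < 2 * grid$h))
    stop(sprintf(
      "as_gridded: component sd %.3g is below two grid steps (%.3g); refine the grid",
      min(g$sd), 2 * grid$h), call. = FALSE)
  d <- density_at(ld, grid$x)
  new_label_density_gridded(grid, d, ld$atoms, ld$condition)
}

# halve an analytic component set (per-division dilution of the prior or
# of the freshly drawn uptake)
.halve_components <- function(gaussians, atoms) {
  gaussians$mean <- gaussians$mean / 2
  gaussians$sd <- gaussians$sd / 2
  atoms$location <- atoms$location / 2
  list(gaussians = gaussians, atoms = atoms)
}

# merge duplicate components (exact dilution chains produce repeats)
.merge_components <- function(gaussians, atoms) {
  if (nrow(gaussians) > 1L) {
    key <- paste(signif(gaussians$mean, 13), signif(gaussians$sd, 13))
    if (anyDuplicated(key)) {
      w <- tapply(gaussians$weight, key, sum)
      first <- !duplicated(key)
      gaussians <- gaussians[first, , drop = FALSE]
      gaussians$weight <- as.numeric(w[paste(signif(gaussians$mean, 13),
                                             signif(gaussians$sd, 13))])
    }
  }
  if (nrow(atoms) > 1L) {
    key <- as.character(signif(atoms$location, 13))
    if (anyDuplicated(key)) {
      w <- tapply(atoms$weight, key, sum)
      first <- !duplicated(key)
      atoms <- atoms[first, , drop = FALSE]
      atoms$weight <- as.numeric(w[as.character(signif(atoms$location, 13))])
    }
  }
  list(gaussians = gaussians, atoms = atoms)
}

#' One cell division: dilution plus fresh uptake
#'
#' A daughter cell keeps half of its mother's label content and receives
#' half of a fresh uptake draw `U` from the labeling-efficacy
#' distribution: `X' = U/2 + X/2`.  The density of `X'` is obtained by
#' scaling both input supports by one half and convolving.  The analytic
#' backend composes Gaussian and atom components in closed form; the
#' gridded backend halves both nodal densities exactly (grid design) and
#' applies a discrete convolution.
#'
#' @param prior a normalized `label_density` (the mother's content).
#' @param eff an [efficacy_normal()]-family distribution.
#' @param grid grid used when `prior` is gridded.
#' @return The daughter-cell `label_density` (same backend as `prior`).
#' @export
#' @examples
#' d0 <- label_density_atom(0)
#' d1 <- one_division_update(d0, efficacy_normal(1, 0.2))
#' c(density_mean(d1), sqrt(density_variance(d1)))  # 0.5, 0.1
one_division_update <- function(prior, eff, grid = label_grid()) {
  stopifnot(inherits(prior, "label_density"), inherits(eff, "efficacy"))
  if (prior$backend == "analytic") {
    if (eff$variant == "gridded")
      stop("one_division_update: gridded efficacy requires a gridded prior",
           call. = FALSE)
    hp <- .halve_components(prior$gaussians, prior$atoms)
    he <- .halve_components(eff$gaussians, eff$atoms)
    np <- nrow(hp$gaussians) + nrow(hp$atoms)
    ne <- nrow(he$gaussians) + nrow(he$atoms)
    if (np * ne > .max_components)
      stop(sprintf(
        "one_division_update: %d analytic components would result; use the gridded backend",
        np * ne), call. = FALSE)
    gg <- expand.grid(p = seq_len(nrow(hp$gaussians)),
                      e = seq_len(nrow(he$gaussians)))
    ga <- expand.grid(p = seq_len(nrow(hp$gaussians)),
                      e = seq_len(nrow(he$atoms)))
    ag <- expand.grid(p = seq_len(nrow(hp$atoms)),
                      e = seq_len(nrow(he$gaussians)))
    aa <- expand.grid(p = seq_len(nrow(hp$atoms)),
                      e = seq_len(nrow(he$atoms)))
    gaussians <- rbind(
      if (nrow(gg)) data.frame(
        weight = hp$gaussians$weight[gg$p] * he$gaussians$weight[gg$e],
        mean = hp$gaussians$mean[gg$p] + he$gaussians$mean[gg$e],
        sd = sqrt(hp$gaussians$sd[gg$p]^2 + he$gaussians$sd[gg$e]^2)),
      if (nrow(ga)) data.frame(
        weight = hp$gaussians$weight[ga$p] * he$atoms$weight[ga$e],
        mean = hp$gaussians$mean[ga$p] + he$atoms$location[ga$e],
        sd = hp$gaussians$sd[ga$p]),
      if (nrow(ag)) data.frame(
        weight = hp$atoms$weight[ag$p] * he$gaussians$weight[ag$e],
        mean = hp$atoms$location[ag$p] + he$gaussians$mean[ag$e],
        sd = he$gaussians$sd[ag$e]))
    if (is.null(gaussians))
      gaussians <- data.frame(weight = numeric(), mean = numeric(),
                              sd = numeric())
    atoms <- if (nrow(aa)) data.frame(
      weight = hp$atoms$weight[aa$p] * he$atoms$weight[aa$e],
      location = hp$atoms$location[aa$p] + he$atoms$location[aa$e])
    else data.frame(weight = numeric(), location = numeric())
    m <- .merge_components(gaussians, atoms)
    new_label_density_analytic(m$gaussians, m$atoms, prior$condition)
  } else {
    grid <- prior$grid
    hp_cont <- grid_halve(grid, prior$density)
    hp_atoms <- prior$atoms
    hp_atoms$location <- hp_atoms$location / 2

    out <- numeric(grid$n)
    out_atoms <- data.frame(weight = numeric(), location = numeric())

    if (eff$variant == "gridded") {
      # efficacy tabulated on its own axis: resample onto the working
      # grid, then halve
      eff_on_grid <- stats::approx(eff$x, eff$density, xout = grid$x,
                                   yleft = 0, yright = 0)$y
      he_cont <- grid_halve(grid, eff_on_grid)
      out <- out + grid_conv(grid, hp_cont, he_cont)
      for (r in seq_len(nrow(hp_atoms)))
        out <- out + hp_atoms$weight[r] *
          grid_shift(grid, he_cont, hp_atoms$location[r])
    } else {
      he <- .halve_components(eff$gaussians, eff$atoms)
      if (nrow(he$gaussians)) {
        if (any(he$gaussians$sd < 2 * grid$h))
          stop(sprintf(
            "one_division_update: halved efficacy sd %.3g is below two grid steps (%.3g); refine the grid",
            min(he$gaussians$sd), 2 * grid$h), call. = FALSE)
        for (r in seq_len(nrow(he$gaussians))) {
          comp <- he$gaussians$weight[r] *
            stats::dnorm(grid$x, he$gaussians$mean[r], he$gaussians$sd[r])
          out <- out + grid_conv(grid, hp_cont, comp)
          # prior atoms against a Gaussian uptake: exact shifted Gaussian
          for (s in seq_len(nrow(hp_atoms)))
            out <- out + hp_atoms$weight[s] * he$gaussians$weight[r] *
              stats::dnorm(grid$x,
                           he$gaussians$mean[r] + hp_atoms$location[s],
                           he$gaussians$sd[r])
        }
      }
      if (nrow(he$atoms)) {
        for (r in seq_len(nrow(he$atoms))) {
          out <- out + he$atoms$weight[r] *
            grid_shift(grid, hp_cont, he$atoms$location[r])
          if (nrow(hp_atoms))
            out_atoms <- rbind(out_atoms, data.frame(
              weight = hp_atoms$weight * he$atoms$weight[r],
              location = hp_atoms$location + he$atoms$location[r]))
        }
      }
    }
    m <- .merge_components(data.frame(weight = numeric(), mean = numeric(),
                                      sd = numeric()), out_atoms)
    new_label_density_gridded(grid, out, m$atoms, prior$condition)
  }
}

#' Label density after a full division history
#'
#' Starts from the unlabeled state `p(x|0) = delta(x)` and applies
#' [one_division_update()] `i_1` times with the phase-1 efficacy, then
#' `i_2` times with the phase-2 efficacy, and so on in chronological
#' order (later divisions further dilute earlier uptakes, so the order
#' across phases matters; within a phase it does not).
#'
#' Backend `"auto"` stays analytic while the component count is modest
#' and switches to the gridded backend for mixture efficacies with many
#' divisions (components multiply per division).
#'
#' @param i integer vector of per-phase division counts.
#' @param efficacies list of [efficacy_normal()]-family objects, one per
#'   phase (`length(i)` entries).
#' @param backend `"auto"`, `"analytic"`, or `"gridded"`.
#' @param grid [label_grid()] for the gridded backend.
#' @param truncate_at_zero if `TRUE` (gridded backend only), mass on
#'   negative label content is removed and the density renormalized.
#'   Default `FALSE`: untruncated normal efficacies place small mass at
#'   negative label, and the model keeps it.
#' @return A normalized `label_density` with `condition = i`.
#' @export
#' @examples
#' effs <- list(efficacy_normal(1, 0.2), efficacy_dirac(0))
#' d <- conditional_label_density(c(2, 1), effs)
#' density_mean(d)  # (1 - 2^-2) * 2^-1
conditional_label_density <- function(i, efficacies,
                                      backend = c("auto", "analytic", "gridded"),
                                      grid = label_grid(),
                                      truncate_at_zero = FALSE) {
  backend <- match.arg(backend)
  if (!is.list(efficacies) || length(efficacies) == 0L)
    stop("conditional_label_density: need a non-empty list of efficacies",
         call. = FALSE)
  i <- as.integer(i)
  if (length(i) != length(efficacies))
    stop("conditional_label_density: length(i) must equal the number of phases",
         call. = FALSE)
  if (any(i < 0))
    stop("conditional_label_density: division counts must be non-negative",
         call. = FALSE)
  if (backend == "auto") {
    nc <- vapply(efficacies, efficacy_ncomp, integer(1))
    backend <- if (anyNA(nc) || prod(nc^i) > .max_components) "gridded"
    else "analytic"
  }
  ld <- label_density_atom(0)
  if (backend == "gridded") ld <- as_gridded(ld, grid)
  for (k in seq_along(i)) {
    for (rep in seq_len(i[k])) ld <- one_division_update(ld, efficacies[[k]])
  }
  if (truncate_at_zero) {
    if (ld$backend != "gridded")
      stop("conditional_label_density: truncate_at_zero needs the gridded backend",
           call. = FALSE)
    ld$density[ld$grid$x < 0] <- 0
    ld$atoms <- ld$atoms[ld$atoms$location >= 0, , drop = FALSE]
    tot <- density_total(ld)
    if (tot <= 0)
      stop("conditional_label_density: no mass left after truncation",
           call. = FALSE)
    ld$density <- ld$density / tot
    ld$atoms$weight <- ld$atoms$weight / tot
  }
  ld$condition <- i
  ld
}

#' Closed-form moments for normal uplabeling followed by delabeling
#'
#' With a normal labeling efficacy `N(mu, sigma^2)` during uplabeling and
#' zero efficacy during delabeling, `p(x|i1, i2)` is a single Gaussian
#' with
#' `mean = (1 - 2^-i1) * 2^-i2 * mu` and
#' `variance = 2^(-2 i2) * sigma^2 * sum_{j=1..i1} 2^(-2 j)`:
#' each uplabeling division contributes a fresh uptake diluted by the
#' divisions that follow it, and every delabeling division halves the
#' content (hence quarters the variance).
#'
#' @param i1 divisions during uplabeling; `i2` divisions during
#'   delabeling (both non-negative integers).
#' @param i2 see `i1`.
#' @param mu,sigma efficacy mean and standard deviation.
#' @return `list(mean =, variance =)`.
#' @export
#' @examples
#' closed_form_normal(1, 0, 1, 0.2)  # mean 0.5, variance 0.01
closed_form_normal <- function(i1, i2, mu = 1, sigma = 0.2) {
  if (i1 < 0 || i2 < 0 || sigma < 0)
    stop("closed_form_normal: negative input", call. = FALSE)
  i1 <- as.integer(i1); i2 <- as.integer(i2)
  v <- if (i1 == 0L) 0 else sigma^2 * sum(2^(-2 * seq_len(i1)))
  list(mean = (1 - 2^(-i1)) * 2^(-i2) * mu,
       variance = 2^(-2 * i2) * v)
}

#' L1 distance between two label densities
#'
#' Continuous parts are compared on a shared grid by trapezoid
#' quadrature; atoms are matched by location and their weight
#' differences added.  Two identical normalized densities give 0; two
#' disjoint ones give 2.
#'
#' @param a,b `label_density` objects.
#' @param grid comparison grid.
#' @export
l1_distance <- function(a, b, grid = label_grid()) {
  da <- as_gridded(a, grid); db <- as_gridded(b, grid)
  d <- grid_trapz(grid, abs(da$density - db$density))
  locs <- sort(unique(signif(c(da$atoms$location, db$atoms$location), 12)))
  for (l in locs) {
    wa <- sum(da$atoms$weight[abs(da$atoms$location - l) < 1e-10])
    wb <- sum(db$atoms$weight[abs(db$atoms$location - l) < 1e-10])
    d <- d + abs(wa - wb)
  }
  d
}

#' Draw samples from a label density
#'
#' Analytic densities are sampled exactly by mixture sampling (choose a
#' component by weight, then draw from it); gridded continuous parts use
#' inverse-CDF sampling with linear interpolation.
#'
#' @param ld a normalized `label_density`.
#' @param n number of draws.
#' @export
sample_label_density <- function(ld, n) {
  tot <- density_total(ld)
  if (ld$backend == "analytic") {
    g <- ld$gaussians; a <- ld$atoms
    w <- c(g$weight, a$weight) / tot
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    out <- numeric(n)
    gi <- idx <= nrow(g)
    if (any(gi))
      out[gi] <- stats::rnorm(sum(gi), g$mean[idx[gi]], g$sd[idx[gi]])
    if (any(!gi))
      out[!gi] <- a$location[idx[!gi] - nrow(g)]
    out
  } else {
    wc <- grid_trapz(ld$grid, ld$density) / tot
    from_atom <- stats::runif(n) > wc
    out <- numeric(n)
    if (any(!from_atom)) {
      cdf <- cumsum(ld$density) * ld$grid$h
      cdf <- cdf / cdf[length(cdf)]
      u <- stats::runif(sum(!from_atom))
      out[!from_atom] <- stats::approx(cdf, ld$grid$x, xout = u,
                                       ties = "ordered", rule = 2)$y
    }
    if (any(from_atom)) {
      a <- ld$atoms
      idx <- sample.int(nrow(a), sum(from_atom), replace = TRUE,
                        prob = a$weight)
      out[from_atom] <- a$location[idx]
    }
    out
  }
}
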