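#' Conditional label densities for every tracked division history
#'
#' Builds `p(x|i)` for all `i` in `{0..S}^K` by the dilution/uptake
#' recursion, reusing each parent density (the density for `i` is one
#' [one_division_update()] away from the density for `i - e_k`, where
#' `k` is the last phase with a nonzero count — chronological order).
#'
#' @param S truncation order.
#' @param efficacies list of per-phase efficacy distributions (length
#'   `K`).
#' @inheritParams conditional_label_density
#' @return A list of `label_density` objects in [division_index_matrix()]
#'   order, named by the comma-separated history vector.
#' @export
conditional_density_table <- function(S, efficacies,
                                      backend = c("auto", "analytic", "gridded"),
                                      grid = label_grid()) {
  backend <- match.arg(backend)
  K <- length(efficacies)
  if (backend == "auto") {
    nc <- vapply(efficacies, efficacy_ncomp, integer(1))
    backend <- if (anyNA(nc) || prod(nc^S) > .max_components) "gridded"
    else "analytic"
  }
  imat <- division_index_matrix(K, S)
  out <- vector("list", nrow(imat))
  root <- label_density_atom(0)
  if (backend == "gridded") root <- as_gridded(root, grid)
  root$condition <- imat[1, ]
  out[[1]] <- root
  if (nrow(imat) > 1L) for (r in 2:nrow(imat)) {
    i <- imat[r, ]
    k <- max(which(i > 0L))
    parent <- i
    parent[k] <- parent[k] - 1L
    pr <- division_index_row(parent, S)
    ld <- one_division_update(out[[pr]], efficacies[[k]], grid)
    ld$condition <- i
    out[[r]] <- ld
  }
  names(out) <- apply(imat, 1, paste, collapse = ",")
  out
}

#' Number densities n(x, i|t) = N(i|t) p(x|i)
#'
#' Scales each conditional density by the cell count of its history so
#' that it integrates to `N(i|t)` (cells per unit label content).
#'
#' @param state a [population_state()].
#' @param densities list of `label_density` objects in canonical state
#'   order (e.g. from [conditional_density_table()]).
#' @return List of weighted `label_density` objects (same order); each
#'   carries its cell count in the component weights.
#' @export
number_density <- function(state, densities) {
  stopifnot(inherits(state, "population_state"))
  if (length(densities) != length(state$counts))
    stop(sprintf(
      "number_density: %d densities for %d populated states; a density is required for every history",
      length(densities), length(state$counts)), call. = FALSE)
  out <- vector("list", length(densities))
  for (r in seq_along(densities)) {
    ld <- densities[[r]]
    w <- state$counts[r]
    if (ld$backend == "analytic") ld$gaussians$weight <- ld$gaussians$weight * w
    else ld$density <- ld$density * w
    ld$atoms$weight <- ld$atoms$weight * w
    out[[r]] <- ld
  }
  names(out) <- names(densities)
  out
}

#' Overall label distribution of the population
#'
#' The measurable model output: the truncated sum
#' `m(x|t) = sum_i N(i|t) p(x|i)` over all tracked division histories.
#' Its integral (continuous part plus atoms) equals the total cell count
#' up to the truncation deficit.
#'
#' When all conditional densities are analytic, the full mixture
#' decomposition (weights in cells) is retained, so threshold fractions,
#' moments, and samples are computed exactly; the continuous part is also
#' evaluated on the grid for peak detection and export.
#'
#' @inheritParams number_density
#' @param grid evaluation grid for the continuous part.
#' @return Object of class `overall_distribution`: `time`, `x`,
#'   `density` (cells per unit label content), `atoms`
#'   (`location`, `weight` in cells), `total` (measured mass),
#'   `pop_total` (sum of counts), and `mixture` (exact Gaussian/atom
#'   decomposition, or `NULL` for gridded inputs).
#' @export
overall_distribution <- function(state, densities, grid = label_grid()) {
  nd <- number_density(state, densities)
  analytic <- all(vapply(nd, function(d) d$backend == "analytic", logical(1)))
  dens <- numeric(grid$n)
  atoms <- data.frame(weight = numeric(), location = numeric())
  mixture <- NULL
  if (analytic) {
    mixture <- do.call(rbind, lapply(nd, function(d) {
      rbind(
        if (nrow(d$gaussians)) data.frame(kind = "gaussian",
                                          weight = d$gaussians$weight,
                                          mean = d$gaussians$mean,
                                          sd = d$gaussians$sd),
        if (nrow(d$atoms)) data.frame(kind = "atom", weight = d$atoms$weight,
                                      mean = d$atoms$location, sd = 0))
    }))
    rownames(mixture) <- NULL
    mixture <- mixture[mixture$weight > 0, , drop = FALSE]
    g <- mixture[mixture$kind == "gaussian", , drop = FALSE]
    for (r in seq_len(nrow(g)))
      dens <- dens + g$weight[r] * stats::dnorm(grid$x, g$mean[r], g$sd[r])
    a <- mixture[mixture$kind == "atom", , drop = FALSE]
    atoms <- data.frame(weight = a$weight, location = a$mean)
  } else {
    for (d in nd) {
      d <- as_gridded(d, grid)
      dens <- dens + d$density
      if (nrow(d$atoms)) atoms <- rbind(atoms, d$atoms)
    }
  }
  atoms <- .merge_components(data.frame(weight = numeric(), mean = numeric(),
                                        sd = numeric()), atoms)$atoms
  atoms <- atoms[atoms$weight > 0, , drop = FALSE]
  structure(list(time = state$time, x = grid$x, density = dens,
                 atoms = atoms, grid = grid,
                 total = grid_trapz(grid, dens) + sum(atoms$weight),
                 pop_total = sum(state$counts), mixture = mixture),
            class = "overall_distribution")
}

#' @export
print.overall_distribution <- function(x, ...) {
  cat(sprintf(
    "<overall_distribution> t = %g d, mass %.6g cells (%d atom(s))\n",
    x$time, x$total, nrow(x$atoms)))
  invisible(x)
}

#' Fraction of labeled cells above a threshold
#'
#' The classical readout: mass of the overall distribution at label
#' content `>= l_theta`, divided by the total mass.  Exact (Gaussian tail
#' probabilities and atom weights) when the mixture decomposition is
#' available, otherwise trapezoid quadrature with a partial first cell.
#'
#' @param dist an [overall_distribution()].
#' @param l_theta detection threshold (finite).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_labeled <- function(dist, l_theta) {
  if (!is.finite(l_theta))
    stop("fraction_labeled: l_theta must be finite", call. = FALSE)
  if (!is.null(dist$mixture)) {
    m <- dist$mixture
    g <- m[m$kind == "gaussian", , drop = FALSE]
    a <- m[m$kind == "atom", , drop = FALSE]
    mass <- sum(g$weight * stats::pnorm(l_theta, g$mean, g$sd,
                                        lower.tail = FALSE)) +
      sum(a$weight[a$mean >= l_theta])
  } else {
    x <- dist$x; d <- dist$density; h <- dist$grid$h
    above <- x >= l_theta
    mass <- if (!any(above)) 0 else {
      j <- which(above)[1]
      da <- d[above]
      tail_mass <- h * (sum(da) - (da[1] + da[length(da)]) / 2)
      if (j > 1L) {
        # partial cell between l_theta and the first node above it
        dl <- d[j - 1L] + (d[j] - d[j - 1L]) * (l_theta - x[j - 1L]) / h
        tail_mass <- tail_mass + (x[j] - l_theta) * (dl + d[j]) / 2
      }
      tail_mass
    }
    mass <- mass + sum(dist$atoms$weight[dist$atoms$location >= l_theta])
  }
  min(1, max(0, mass / dist$total))
}

#' Mean fluorescence intensity of the population
#'
#' First moment of the normalized overall distribution (atoms included
#' exactly).
#'
#' @param dist an [overall_distribution()].
#' @export
mean_intensity <- function(dist) {
  if (dist$total <= 0)
    stop("mean_intensity: distribution has no mass", call. = FALSE)
  if (!is.null(dist$mixture)) {
    sum(dist$mixture$weight * dist$mixture$mean) / dist$total
  } else {
    (grid_trapz(dist$grid, dist$x * dist$density) +
       sum(dist$atoms$weight * dist$atoms$location)) / dist$total
  }
}

#' Simulate a cytometry-style intensity sample
#'
#' Draws `M` per-cell label intensities from the normalized overall
#' distribution by inverse-mixture sampling: a component (division
#' history, then Gaussian/atom) is chosen by weight, then the value is
#' drawn from it, so analytic-backend samples are exact.  Gridded
#' continuous parts fall back to inverse-CDF sampling on the grid.
#'
#' @param dist an [overall_distribution()].
#' @param M sample size.
#' @param seed integer seed (samples are reproducible bit-for-bit).
#' @return Object of class `intensity_sample`: `intensities`, `M`,
#'   `seed`, `time`.
#' @export
sample_intensities <- function(dist, M, seed = 1L) {
  M <- as.integer(M)
  if (M < 1L) stop("sample_intensities: M must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  if (!is.null(dist$mixture)) {
    m <- dist$mixture
    idx <- sample.int(nrow(m), M, replace = TRUE, prob = m$weight)
    vals <- numeric(M)
    gi <- m$kind[idx] == "gaussian"
    if (any(gi)) vals[gi] <- stats::rnorm(sum(gi), m$mean[idx[gi]],
                                          m$sd[idx[gi]])
    if (any(!gi)) vals[!gi] <- m$mean[idx[!gi]]
  } else {
    ld <- new_label_density_gridded(dist$grid, dist$density, dist$atoms)
    vals <- sample_label_density(ld, M)
  }
  structure(list(intensities = vals, M = M, seed = as.integer(seed),
                 time = dist$time),
            class = "intensity_sample")
}

#' @export
print.intensity_sample <- function(x, ...) {
  cat(sprintf("<intensity_sample> M = %d draws at t = %g d (seed %d)\n",
              x$M, x$time, x$seed))
  invisible(x)
}

# strict local maxima and their topographic prominences
.peak_prominences <- function(y) {
  idx <- which(diff(sign(diff(y))) == -2) + 1L
  prom <- vapply(idx, function(j) {
    n <- length(y)
    left <- if (j > 1L) {
      hi <- which(y[seq_len(j - 1L)] > y[j])
      if (length(hi)) min(y[(max(hi) + 1L):j]) else min(y[seq_len(j)])
    } else y[j]
    right <- if (j < n) {
      hi <- which(y[(j + 1L):n] > y[j]) + j
      if (length(hi)) min(y[j:(min(hi) - 1L)]) else min(y[j:n])
    } else y[j]
    y[j] - max(left, right)
  }, numeric(1))
  list(index = idx, prominence = prom)
}

#' Count peaks of the overall label distribution
#'
#' Strict local maxima of the continuous density whose topographic
#' prominence exceeds `min_prominence` times the global maximum.  The
#' small prominence floor keeps grid noise from registering as modes.
#' Atoms (point masses, e.g. the undivided unlabeled pool at `x = 0`)
#' are reported separately and excluded by default: in a cytometry
#' histogram the unlabeled spike sits at the background signal, not in
#' the labeled-density shape that the peak count describes.
#'
#' @param dist an [overall_distribution()].
#' @param min_prominence prominence floor as a fraction of the global
#'   maximum of the continuous density (default 0.02; see the package
#'   vignette for sensitivity).
#' @param include_atoms if `TRUE`, atoms at distinct locations are added
#'   to the count.
#' @return Integer peak count with attributes `locations` (grid positions
#'   of the counted continuous modes) and `prominences`.
#' @export
count_peaks <- function(dist, min_prominence = 0.02, include_atoms = FALSE) {
  if (min_prominence < 0)
    stop("count_peaks: min_prominence must be non-negative", call. = FALSE)
  y <- dist$density
  if (all(y <= 0) && nrow(dist$atoms) == 0L)
    stop("count_peaks: distribution is identically zero", call. = FALSE)
  n <- 0L; locs <- numeric(); proms <- numeric()
  if (any(y > 0)) {
    p <- .peak_prominences(y)
    keep <- p$prominence > min_prominence * max(y)
    n <- sum(keep)
    locs <- dist$x[p$index[keep]]
    proms <- p$prominence[keep]
  }
  if (include_atoms && nrow(dist$atoms))
    n <- n + length(unique(signif(
      dist$atoms$location[dist$atoms$weight > 0], 12)))
  structure(n, locations = locs, prominences = proms)
}
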