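#' Reference solver: number-density transport equations
#'
#' Cross-validation oracle for the decomposed construction
#' ([solve_population()] times [conditional_label_density()]): it
#' integrates the number densities `n(x, i|t)` directly by method of
#' lines.  Each division both doubles the cells and maps the label
#' density through the dilution/uptake convolution, so the influx into
#' history `i` at content `x` is
#' `8 alpha_{i-1}(t) * integral( p_eff(2x - 2chi) n(2chi, i-1|t) dchi )`
#' (the factor 8 = 2 daughters times the change-of-variables factor 4
#' that also normalizes the one-step density update).  The convolution
#' integral uses trapezoid quadrature on the `x`-grid, making the scheme
#' O(grid-step^2) accurate — which sets the tolerance of the equivalence
#' tests.  The undivided pool stays an atom at `x = 0` and is integrated
#' as a scalar.
#'
#' This is a test oracle, not a production path: it supports a single
#' labeling phase, smooth (non-atomic) efficacies, and small `S`.
#'
#' @inheritParams solve_population
#' @param efficacies list with one smooth efficacy distribution.
#' @param grid [label_grid()] for the method of lines (coarse grids are
#'   fine for an oracle).
#' @return A list of [overall_distribution()] objects, one per eval
#'   time, with a `components` attribute holding the per-history nodal
#'   densities.
#' @export
pde_reference_solver <- function(partition, rates, n_init, efficacies, S,
                                 grid = label_grid(n = 401),
                                 eval_times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(partition, "time_partition"))
  if (partition$K != 1L)
    stop("pde_reference_solver: the reference solver supports a single labeling interval",
         call. = FALSE)
  if (length(efficacies) != 1L)
    stop("pde_reference_solver: one efficacy per interval", call. = FALSE)
  eff <- efficacies[[1]]
  if (efficacy_is_atomic(eff))
    stop("pde_reference_solver: atomic efficacies are not supported by the reference solver",
         call. = FALSE)
  S <- as.integer(S)
  if (S < 1L || S > 8L)
    stop("pde_reference_solver: S must be in 1..8 (oracle scale)",
         call. = FALSE)
  eval_times <- as.numeric(eval_times)
  if (is.unsorted(eval_times))
    stop("pde_reference_solver: eval_times must be non-decreasing",
         call. = FALSE)

  nx <- grid$n
  # efficacy sampled on the grid (for the convolution) and at 2x (for the
  # influx out of the undivided atom)
  if (eff$variant == "gridded") {
    peff <- stats::approx(eff$x, eff$density, xout = grid$x,
                          yleft = 0, yright = 0)$y
    peff2x <- stats::approx(eff$x, eff$density, xout = 2 * grid$x,
                            yleft = 0, yright = 0)$y
  } else {
    g <- eff$gaussians
    peff <- density_at(new_label_density_analytic(
      g, data.frame(weight = numeric(), location = numeric())), grid$x)
    peff2x <- density_at(new_label_density_analytic(
      g, data.frame(weight = numeric(), location = numeric())), 2 * grid$x)
  }

  alpha_i <- function(i, t) rates$division_rate(i, t)
  beta_i <- function(i, t) rates$death_rate(i, t)

  # state: c(A0, n_1 nodes, ..., n_S nodes)
  comp_idx <- function(i) 1L + (i - 1L) * nx + seq_len(nx)
  # g(2 x_j) lookup: conv result node r corresponds to y = 2*min + (r-1)h,
  # and 2 x_j has r = 2j - 1
  r2 <- 2L * seq_len(nx) - 1L

  deriv <- function(t, y, p) {
    a <- vapply(0:S, function(i) alpha_i(i, t), numeric(1))
    b <- vapply(0:S, function(i) beta_i(i, t), numeric(1))
    if (any(a < 0) || any(b < 0))
      stop(sprintf("pde_reference_solver: negative rate at t = %g", t),
           call. = FALSE)
    dy <- numeric(length(y))
    dy[1] <- -(a[1] + b[1]) * y[1]
    for (i in seq_len(S)) {
      ni <- y[comp_idx(i)]
      infl <- if (i == 1L) {
        4 * a[1] * y[1] * peff2x
      } else {
        nprev <- y[comp_idx(i - 1L)]
        cc <- grid_conv_full(peff, nprev)
        4 * a[i] * grid$h * cc[r2]
      }
      out_rate <- if (i == S) b[i + 1L] else a[i + 1L] + b[i + 1L]
      dy[comp_idx(i)] <- -out_rate * ni + infl
    }
    list(dy)
  }

  y0 <- numeric(1L + S * nx)
  y0[1] <- n_init
  tt <- sort(unique(c(0, eval_times)))
  sol <- deSolve::lsoda(y0, tt, deriv, parms = NULL, rtol = rtol, atol = atol)

  lapply(eval_times, function(tq) {
    row <- which(abs(sol[, 1] - tq) < 1e-9)[1]
    y <- unname(sol[row, -1])
    comps <- lapply(seq_len(S), function(i) y[comp_idx(i)])
    dens <- Reduce(`+`, comps)
    atoms <- data.frame(weight = y[1], location = 0)
    structure(list(time = tq, x = grid$x, density = dens, atoms = atoms,
                   grid = grid,
                   total = grid_trapz(grid, dens) + y[1],
                   pop_total = NA_real_, mixture = NULL,
                   components = comps),
              class = "overall_distribution")
  })
}

# raw linear convolution (unnormalized nodes, full length 2n-1)
grid_conv_full <- function(a, b) {
  n <- length(a)
  N <- stats::nextn(2L * n - 1L, 2)
  fa <- stats::fft(c(a, numeric(N - n)))
  fb <- stats::fft(c(b, numeric(N - n)))
  cc <- Re(stats::fft(fa * fb, inverse = TRUE)) / N
  cc[seq_len(2L * n - 1L)]
}
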