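#' Label-axis grid
#'
#' Uniform grid on which gridded label densities are represented.  The
#' default spans `[-0.5, 1.5]` in normalized label units with 2001 nodes
#' (step 0.001): labeling-efficacy means are at most 1 and division
#' dilution only shrinks support, so one division maps the support into
#' `[-0.25, 0.75]` and a convolution of two halved densities stays inside
#' the grid.
#'
#' The grid origin must be an integer multiple of the step: halving a
#' density (the per-division dilution) then maps grid nodes exactly onto
#' grid nodes, so no interpolation error enters the convolution pipeline.
#'
#' @param min,max grid end points (normalized label content).
#' @param n number of nodes (at least 51).
#' @return An object of class `label_grid` with fields `x`, `h`, `n`,
#'   `min`, `max`.
#' @export
#' @examples
#' g <- label_grid()
#' g$h
label_grid <- function(min = -0.5, max = 1.5, n = 2001) {
  if (!is.numeric(min) || !is.numeric(max) || max <= min)
    stop("label_grid: 'max' must exceed 'min'", call. = FALSE)
  n <- as.integer(n)
  if (n < 51) stop("label_grid: need at least 51 nodes", call. = FALSE)
  h <- (max - min) / (n - 1)
  if (abs(min / h - round(min / h)) > 1e-8)
    stop("label_grid: the origin must be an integer multiple of the step ",
         "(required for exact per-division halving)", call. = FALSE)
  structure(list(x = seq(min, max, length.out = n), h = h, n = n,
                 min = min, max = max),
            class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  cat(sprintf("<label_grid> [%g, %g], %d nodes, step %g\n",
              x$min, x$max, x$n, x$h))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(a$n == b$n) && abs(a$min - b$min) < 1e-12 && abs(a$max - b$max) < 1e-12
}

# trapezoid integral of nodal values
grid_trapz <- function(grid, y) grid$h * (sum(y) - (y[1] + y[grid$n]) / 2)

# density of 2X from density of X sampled on the same grid: d'(x) = 2 d(2x).
# 2*x_j is itself a node whenever within range (guaranteed by the origin
# constraint), so this is exact.
grid_halve <- function(grid, d) {
  j <- seq_len(grid$n)
  m <- round(grid$min / grid$h) + 2L * j - 1L
  out <- numeric(grid$n)
  ok <- m >= 1L & m <= grid$n
  out[ok] <- 2 * d[m[ok]]
  out
}

# linear convolution of two nodal density vectors on the shared grid,
# rescaled by the step so it approximates the continuous convolution;
# result resampled onto the same grid (support outside is dropped, which
# is exact for supports within [min/2, max/2] after halving).
grid_conv <- function(grid, a, b) {
  n <- grid$n
  N <- stats::nextn(2L * n - 1L, 2)
  fa <- stats::fft(c(a, numeric(N - n)))
  fb <- stats::fft(c(b, numeric(N - n)))
  cc <- Re(stats::fft(fa * fb, inverse = TRUE)) / N
  cc <- cc[seq_len(2L * n - 1L)] * grid$h
  r <- seq_len(n) - round(grid$min / grid$h)
  out <- numeric(n)
  ok <- r >= 1L & r <= 2L * n - 1L
  out[ok] <- cc[r[ok]]
  # FFT round-off can leave ~1e-16 negatives; larger negatives would be a
  # genuine error and are kept for the normalization checks to catch
  out[out < 0 & out > -1e-12] <- 0
  out
}

# shift nodal values by an arbitrary offset (fractional shifts by linear
# interpolation between the two neighbouring integer shifts)
grid_shift <- function(grid, d, delta) {
  s <- delta / grid$h
  s0 <- floor(s)
  fr <- s - s0
  shift_int <- function(v, k) {
    n <- length(v)
    out <- numeric(n)
    if (k >= n || k <= -n) return(out)
    if (k >= 0) out[(k + 1):n] <- v[seq_len(n - k)]
    else out[seq_len(n + k)] <- v[(-k + 1):n]
    out
  }
  if (fr < 1e-12) shift_int(d, s0)
  else (1 - fr) * shift_int(d, s0) + fr * shift_int(d, s0 + 1L)
}

# evaluate nodal values at arbitrary points (0 outside the grid)
grid_interp <- function(grid, d, xout) {
  stats::approx(grid$x, d, xout = xout, yleft = 0, yright = 0)$y
}
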