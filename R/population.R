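#' Partition of the experiment into labeling phases
#'
#' A labeling experiment is divided into `K` consecutive time intervals
#' `(T[k-1], T[k]]` (days), e.g. an uplabeling phase followed by a
#' delabeling phase.  Interval membership is half-open from the left;
#' `t = 0` is attached to interval 1 for initialization.
#'
#' @param boundaries numeric vector `T_0 .. T_K` with `T_0 = 0`, strictly
#'   increasing.
#' @return An object of class `time_partition` with fields `boundaries`
#'   and `K`.
#' @export
#' @examples
#' time_partition(c(0, 10, 20))  # 10 d uplabeling + 10 d delabeling
time_partition <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L)
    stop("time_partition: need at least two boundaries (T_0 = 0 and T_1)",
         call. = FALSE)
  if (abs(boundaries[1]) > 1e-12)
    stop("time_partition: the first boundary must be 0", call. = FALSE)
  if (any(diff(boundaries) <= 0))
    stop("time_partition: boundaries must be strictly increasing",
         call. = FALSE)
  structure(list(boundaries = boundaries, K = length(boundaries) - 1L),
            class = "time_partition")
}

#' @export
print.time_partition <- function(x, ...) {
  cat(sprintf("<time_partition> K = %d interval(s): %s (days)\n", x$K,
              paste(x$boundaries, collapse = " | ")))
  invisible(x)
}

#' Division and death rates of the population
#'
#' Rates may depend on the division-history vector `i` and on time `t`
#' (days); both must be non-negative.  Most applications use constant
#' rates, for which [constant_rates()] enables a fast vectorized solver
#' path.
#'
#' @param division_rate,death_rate functions `(i, t) -> rate per day`,
#'   where `i` is an integer vector of per-interval division counts.
#' @return An object of class `rate_model`.
#' @seealso [constant_rates()]
#' @export
rate_model <- function(division_rate, death_rate) {
  if (!is.function(division_rate) || !is.function(death_rate))
    stop("rate_model: both rates must be functions of (i, t)", call. = FALSE)
  structure(list(division_rate = division_rate, death_rate = death_rate,
                 constant = FALSE, alpha = NA_real_, beta = NA_real_),
            class = "rate_model")
}

#' @rdname rate_model
#' @param alpha,beta constant division and death rates (per day).
#' @export
#' @examples
#' constant_rates(0.1, 0.1)
constant_rates <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha < 0 || beta < 0)
    stop("constant_rates: rates must be non-negative numbers", call. = FALSE)
  rm <- rate_model(function(i, t) alpha, function(i, t) beta)
  rm$constant <- TRUE
  rm$alpha <- alpha
  rm$beta <- beta
  rm
}

#' @export
print.rate_model <- function(x, ...) {
  if (x$constant)
    cat(sprintf("<rate_model> constant: alpha = %g/d, beta = %g/d\n",
                x$alpha, x$beta))
  else cat("<rate_model> general (i, t)-dependent rates\n")
  invisible(x)
}

#' All division-history vectors of the truncated model
#'
#' Enumerates `i = (i_1, ..., i_K)` with entries in `0..S`, in
#' lexicographic order (`i_1` major).  This is the canonical state order
#' used throughout the package.
#'
#' @param K number of intervals.
#' @param S truncation order (maximum tracked divisions per interval).
#' @return Integer matrix with `(S+1)^K` rows and columns `i_1..i_K`.
#' @export
division_index_matrix <- function(K, S) {
  K <- as.integer(K); S <- as.integer(S)
  if (K < 1L || S < 0L)
    stop("division_index_matrix: K >= 1 and S >= 0 required", call. = FALSE)
  # expand.grid varies its first argument fastest; lexicographic order
  # needs i_K fastest, so feed columns reversed and flip back
  m <- as.matrix(expand.grid(rep(list(0:S), K)))[, K:1, drop = FALSE]
  colnames(m) <- paste0("i_", seq_len(K))
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

# row number of a division vector in division_index_matrix(K, S)
division_index_row <- function(i, S) {
  K <- length(i)
  strides <- (S + 1L)^(K - seq_len(K))
  as.integer(sum(i * strides)) + 1L
}

# evaluate the two rates for all states at time t
.rate_vectors <- function(rates, imat, t) {
  n <- nrow(imat)
  if (rates$constant) {
    list(alpha = rep(rates$alpha, n), beta = rep(rates$beta, n))
  } else {
    a <- vapply(seq_len(n),
                function(s) rates$division_rate(imat[s, ], t), numeric(1))
    b <- vapply(seq_len(n),
                function(s) rates$death_rate(imat[s, ], t), numeric(1))
    if (any(a < 0) || any(b < 0)) {
      bad <- which(a < 0 | b < 0)[1]
      stop(sprintf(
        "solve_population: negative rate at i = (%s), t = %g",
        paste(imat[bad, ], collapse = ","), t), call. = FALSE)
    }
    list(alpha = a, beta = b)
  }
}

#' Solve the division-structured population model
#'
#' Integrates the cell counts `N(i|t)` over the labeling phases.  During
#' interval `k` only the `i_k` coordinate of the history vector grows:
#' a division moves a cell from `i - e_k` to `i` and doubles it (flux
#' `2 * alpha * N(i - e_k|t)`), while cells leave state `i` by division
#' and death at rate `alpha + beta`.  The index set is truncated at `S`
#' divisions per interval: the top bin still receives influx and still
#' dies, but its division outflux is dropped, so the truncated total
#' slightly undercounts rather than distorts the distribution (quantified
#' by [truncation_error()]).
#'
#' @param partition a [time_partition()].
#' @param rates a [rate_model()] or [constant_rates()].
#' @param n_init initial cell count (all cells undivided at `t = 0`).
#' @param S truncation order per interval (the model tracks
#'   `(S+1)^K` states).
#' @param eval_times non-decreasing times (days) in `[0, T_K]` at which
#'   counts are requested.
#' @param rtol,atol integrator tolerances (the system is linear and at
#'   most mildly stiff; `lsoda` is used).
#' @return An object of class `population_solution`: fields `times`,
#'   `counts` (matrix, one row per eval time, one column per state in
#'   [division_index_matrix()] order), `index`, `S`, `K`, `partition`,
#'   `n_init`.
#' @export
#' @examples
#' part <- time_partition(c(0, 10))
#' sol <- solve_population(part, constant_rates(0.1, 0.1), 1000, S = 20,
#'                         eval_times = c(2, 10))
#' sum(sol$counts[2, ])  # total is conserved when alpha == beta
solve_population <- function(partition, rates, n_init, S, eval_times,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(partition, "time_partition"),
            inherits(rates, "rate_model"))
  if (!is.numeric(n_init) || n_init <= 0)
    stop("solve_population: n_init must be positive", call. = FALSE)
  S <- as.integer(S)
  if (S < 1L) stop("solve_population: S must be at least 1", call. = FALSE)
  eval_times <- as.numeric(eval_times)
  if (length(eval_times) < 1L)
    stop("solve_population: no eval_times given", call. = FALSE)
  if (is.unsorted(eval_times))
    stop("solve_population: eval_times must be non-decreasing", call. = FALSE)
  TK <- partition$boundaries[partition$K + 1L]
  if (any(eval_times < -1e-12) || any(eval_times > TK + 1e-12))
    stop(sprintf("solve_population: eval_times must lie in [0, %g]", TK),
         call. = FALSE)

  K <- partition$K
  if (K > 3L)
    warning(sprintf(
      "solve_population: K = %d intervals give %d states; expect long runtimes",
      K, (S + 1L)^K), call. = FALSE)
  imat <- division_index_matrix(K, S)
  nstate <- nrow(imat)

  out <- matrix(NA_real_, nrow = length(eval_times), ncol = nstate)
  y <- numeric(nstate)
  y[1] <- n_init                         # all-zero vector is row 1
  done <- eval_times < 1e-12
  out[done, ] <- rep(y, each = sum(done))

  for (k in seq_len(K)) {
    t0 <- partition$boundaries[k]
    t1 <- partition$boundaries[k + 1L]
    stride <- (S + 1L)^(K - k)
    ik <- imat[, k]
    has_par <- ik >= 1L
    par_idx <- which(has_par) - stride   # i - e_k in canonical order
    top <- ik == S
    deriv <- function(t, y, p) {
      rv <- .rate_vectors(rates, imat, t)
      dy <- -(rv$alpha + rv$beta) * y
      dy[top] <- -rv$beta[top] * y[top]  # top bin: division outflux dropped
      dy[has_par] <- dy[has_par] + 2 * rv$alpha[par_idx] * y[par_idx]
      list(dy)
    }
    req <- eval_times[eval_times > t0 + 1e-12 & eval_times <= t1 + 1e-12]
    tt <- sort(unique(c(t0, req, t1)))
    sol <- deSolve::lsoda(y, tt, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    for (tq in req) {
      row <- which(abs(sol[, 1] - tq) < 1e-9)[1]
      out[which(abs(eval_times - tq) < 1e-12), ] <-
        rep(sol[row, -1], each = sum(abs(eval_times - tq) < 1e-12))
    }
    y <- sol[nrow(sol), -1]
  }

  if (any(out < -10 * atol, na.rm = TRUE))
    stop("solve_population: integrator produced significantly negative counts",
         call. = FALSE)
  out[out < 0] <- 0
  structure(list(times = eval_times, counts = out, index = imat,
                 S = S, K = K, partition = partition, n_init = n_init),
            class = "population_solution")
}

#' @export
print.population_solution <- function(x, ...) {
  cat(sprintf(
    "<population_solution> K = %d, S = %d (%d states), %d eval time(s)\n",
    x$K, x$S, ncol(x$counts), length(x$times)))
  tot <- rowSums(x$counts)
  cat("  totals:", paste(sprintf("%.4g", tot), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.population_solution <- function(x, ...) {
  n <- ncol(x$counts)
  df <- data.frame(
    time_d = rep(x$times, each = n),
    x$index[rep(seq_len(n), times = length(x$times)), , drop = FALSE],
    count = as.vector(t(x$counts)))
  rownames(df) <- NULL
  df
}

#' Extract the population state at one evaluation time
#'
#' @param solution a [solve_population()] result.
#' @param time one of its evaluation times.
#' @return Object of class `population_state`: `time`, `counts` (vector in
#'   canonical state order), `index`, `S`, `K`.
#' @export
population_state <- function(solution, time) {
  stopifnot(inherits(solution, "population_solution"))
  row <- which(abs(solution$times - time) < 1e-9)
  if (length(row) == 0L)
    stop(sprintf("population_state: time %g was not an eval time", time),
         call. = FALSE)
  structure(list(time = time, counts = solution$counts[row[1], ],
                 index = solution$index, S = solution$S, K = solution$K),
            class = "population_state")
}

#' Closed-form counts for one interval with constant rates
#'
#' For a single interval and constant rates the division-structured model
#' has the classical solution
#' `N(i|t) = n_init * (2 alpha t)^i / i! * exp(-(alpha + beta) t)`:
#' a Poisson number of divisions with mean `2 alpha t`, scaled by the net
#' growth factor.  Used as an independent oracle for [solve_population()].
#'
#' @param n_init initial count; `alpha,beta` constant rates per day;
#'   `t` time in days; `i` division count (vectorized).
#' @return Cell counts `N(i|t)`.
#' @export
#' @examples
#' analytic_population_constant_rates(1000, 0.1, 0.1, 10, 0:5)
analytic_population_constant_rates <- function(n_init, alpha, beta, t, i) {
  if (n_init < 0 || alpha < 0 || beta < 0 || any(t < 0) || any(i < 0))
    stop("analytic_population_constant_rates: negative input", call. = FALSE)
  i <- as.integer(i)
  lam <- 2 * alpha * t
  mass <- if (lam == 0) as.numeric(i == 0L)
  else exp(i * log(lam) - lfactorial(i))
  n_init * mass * exp(-(alpha + beta) * t)
}

#' Mass deficit caused by truncating the division index at S
#'
#' Compares the total count of the model truncated at `S` against a
#' reference truncated at `S + margin` and returns the missing mass
#' fraction `1 - total_S / total_ref`.  Non-increasing in `S`; with the
#' usual Poisson-like division numbers it decays super-exponentially, so
#' a moderate order (S around 20) is ample for the packaged scenarios.
#'
#' @inheritParams solve_population
#' @param t single time (days) at which the deficit is measured.
#' @param margin extra divisions used for the reference solve.
#' @return Mass fraction in `[0, 1]`.
#' @export
truncation_error <- function(partition, rates, n_init, S, t, margin = 10L) {
  S <- as.integer(S)
  if (S < 0L) stop("truncation_error: S must be non-negative", call. = FALSE)
  solve_at <- function(SS) {
    if (SS == 0L) {
      # degenerate model: the all-zero vector is the top bin of every
      # interval, so only death acts (division outflux dropped)
      i0 <- rep(0L, partition$K)
      deriv <- function(t, y, p) list(-rates$death_rate(i0, t) * y)
      sol <- deSolve::lsoda(n_init, sort(unique(c(0, t))), deriv, NULL,
                            rtol = 1e-8, atol = 1e-10)
      return(sol[nrow(sol), 2])
    }
    sum(solve_population(partition, rates, n_init, SS, t)$counts[1, ])
  }
  tot_S <- solve_at(S)
  tot_ref <- solve_at(S + as.integer(margin))
  max(0, 1 - tot_S / tot_ref)
}
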