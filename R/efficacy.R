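#' Labeling-efficacy distributions
#'
#' The amount of label incorporated into the newly synthesized DNA
#' strands at one division is a random draw `U` from a labeling-efficacy
#' distribution.  Label content is measured in normalized
#' fluorescence-equivalent units where the full expected uptake is
#' `mu = 1`.  Four variants are supported:
#'
#' * `efficacy_dirac(location)`: a fixed uptake value (the uniform
#'   labeling assumption of earlier models); `efficacy_dirac(0)` encodes
#'   delabeling (no label in the environment).
#' * `efficacy_normal(mean, sd)`: noisy uptake.
#' * `efficacy_mixture(weights, means, sds)`: Gaussian mixture, e.g. for
#'   spatially heterogeneous label concentrations.
#' * `efficacy_gridded(x, density)`: arbitrary tabulated density.
#'
#' Internally every analytic variant is stored as a set of weighted
#' Gaussian components plus weighted point masses (atoms); a normal
#' component with `sd = 0` degenerates into an atom.
#'
#' @param mean,sd mean and standard deviation of the normal variant
#'   (`sd >= 0`).
#' @return An object of class `efficacy`.
#' @export
#' @examples
#' efficacy_normal(1, 0.2)
#' efficacy_dirac(0)                      # delabeling phase
#' efficacy_mixture(c(1/3, 2/3), c(0.5, 1), 0.05)
efficacy_normal <- function(mean = 1, sd = 0.2) {
  if (!is.numeric(sd) || sd < 0)
    stop("efficacy_normal: sd must be non-negative", call. = FALSE)
  if (sd == 0) return(efficacy_dirac(mean))
  new_efficacy("normal",
               gaussians = data.frame(weight = 1, mean = mean, sd = sd))
}

#' @rdname efficacy_normal
#' @param location the fixed uptake value of the Dirac variant.
#' @export
efficacy_dirac <- function(location = 1) {
  new_efficacy("dirac",
               atoms = data.frame(weight = 1, location = location))
}

#' @rdname efficacy_normal
#' @param weights,means,sds component weights (must sum to 1 within
#'   `1e-9`), means, and standard deviations (`sds` is recycled, so a
#'   single shared value may be given).
#' @export
efficacy_mixture <- function(weights, means, sds) {
  weights <- as.numeric(weights); means <- as.numeric(means)
  sds <- rep_len(as.numeric(sds), length(weights))
  if (length(means) != length(weights))
    stop("efficacy_mixture: weights and means must have equal length",
         call. = FALSE)
  if (any(weights < 0) || any(sds < 0))
    stop("efficacy_mixture: weights and sds must be non-negative",
         call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop(sprintf("efficacy_mixture: weights sum to %.12g, not 1",
                 sum(weights)), call. = FALSE)
  zero <- sds == 0
  g <- data.frame(weight = weights[!zero], mean = means[!zero],
                  sd = sds[!zero])
  a <- data.frame(weight = weights[zero], location = means[zero])
  new_efficacy("mixture", gaussians = g, atoms = a)
}

#' @rdname efficacy_normal
#' @param x,density grid nodes (strictly increasing) and density values
#'   of the gridded variant; the trapezoid integral must be 1 within
#'   `1e-6`.
#' @export
efficacy_gridded <- function(x, density) {
  x <- as.numeric(x); density <- as.numeric(density)
  if (length(x) != length(density) || length(x) < 3L)
    stop("efficacy_gridded: x and density must be equal-length (>= 3)",
         call. = FALSE)
  if (any(diff(x) <= 0))
    stop("efficacy_gridded: x must be strictly increasing", call. = FALSE)
  if (any(density < 0))
    stop("efficacy_gridded: density must be non-negative", call. = FALSE)
  mass <- sum(diff(x) * (density[-1] + density[-length(density)]) / 2)
  if (abs(mass - 1) > 1e-6)
    stop(sprintf("efficacy_gridded: density integrates to %.8g, not 1", mass),
         call. = FALSE)
  e <- new_efficacy("gridded")
  e$x <- x
  e$density <- density
  e
}

#' Two-compartment (or general) heterogeneous labeling efficacy
#'
#' Convenience wrapper for spatially heterogeneous labeling: cell
#' divisions happen in compartments with different label concentration,
#' each contributing a normal component with a shared within-compartment
#' standard deviation.  The packaged heterogeneity scenario uses
#' `(1/3) N(0.5, sigma^2) + (2/3) N(1, sigma^2)`.
#'
#' @param weights compartment weights (sum to 1).
#' @param means expected uptake per compartment.
#' @param sigma shared within-compartment standard deviation.
#' @return An `efficacy` mixture object.
#' @export
#' @examples
#' heterogeneous_efficacy(c(1/3, 2/3), c(0.5, 1), 0.05)
heterogeneous_efficacy <- function(weights, means, sigma) {
  efficacy_mixture(weights, means, sigma)
}

new_efficacy <- function(variant,
                         gaussians = data.frame(weight = numeric(),
                                                mean = numeric(),
                                                sd = numeric()),
                         atoms = data.frame(weight = numeric(),
                                            location = numeric())) {
  structure(list(variant = variant, gaussians = gaussians, atoms = atoms,
                 x = NULL, density = NULL),
            class = "efficacy")
}

#' @export
print.efficacy <- function(x, ...) {
  cat(sprintf("<efficacy> variant: %s\n", x$variant))
  if (x$variant == "gridded")
    cat(sprintf("  %d grid nodes on [%g, %g]\n", length(x$x),
                min(x$x), max(x$x)))
  if (nrow(x$gaussians))
    for (r in seq_len(nrow(x$gaussians)))
      cat(sprintf("  %.4g * N(%g, %g^2)\n", x$gaussians$weight[r],
                  x$gaussians$mean[r], x$gaussians$sd[r]))
  if (nrow(x$atoms))
    for (r in seq_len(nrow(x$atoms)))
      cat(sprintf("  %.4g * delta(x - %g)\n", x$atoms$weight[r],
                  x$atoms$location[r]))
  invisible(x)
}

# number of analytic components (for backend selection)
efficacy_ncomp <- function(e) {
  if (e$variant == "gridded") return(NA_integer_)
  nrow(e$gaussians) + nrow(e$atoms)
}

efficacy_is_atomic <- function(e) {
  e$variant != "gridded" && nrow(e$atoms) > 0L
}
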