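#' Truncated integer degree distributions
#'
#' A `degree_dist` is a probability mass function over an inclusive integer
#' degree range `support = k_lo:k_hi`, renormalized after truncation. It is
#' the shared currency of the network generator (degree sequences are sampled
#' from it) and the tree-like solver (degree sums are truncated to its
#' support).
#'
#' @param kind One of `"poisson"`, `"power_law"`, `"regular"`, `"empirical"`.
#' @param params Named list of parameters: `z` (Poisson mean); `lambda`,
#'   `k_min`, `k_max` (power law, `pmf(k) ~ k^-lambda` on `[k_min, k_max]`);
#'   `degree` (regular); `degrees` + `probs` (empirical histogram).
#' @param truncation_mass For the Poisson kind, the support is cut at the
#'   smallest `k_hi` whose untruncated upper-tail mass is at most this value.
#'   Must lie in `(0, 1e-6]`.
#' @return An object of class `degree_dist` with fields `kind`, `params`,
#'   `support`, `pmf` (summing to 1 within 1e-12) and `mean`.
#' @examples
#' d <- make_distribution("poisson", list(z = 15))
#' d$mean
#' make_distribution("regular", list(degree = 5))$support
#' @export
make_distribution <- function(kind = c("poisson", "power_law", "regular", "empirical"),
                              params = list(),
                              truncation_mass = 1e-10) {
  kind <- match.arg(kind)
  if (!is.numeric(truncation_mass) || truncation_mass <= 0 || truncation_mass > 1e-6) {
    stop("'truncation_mass' must lie in (0, 1e-6]", call. = FALSE)
  }
  switch(kind,
    poisson = {
      z <- params$z
      if (is.null(z) || !is.numeric(z) || z < 0) {
        stop("poisson kind requires params$z >= 0", call. = FALSE)
      }
      if (z == 0) {
        support <- 0L
        pmf <- 1
      } else {
        k_hi <- stats::qpois(truncation_mass, z, lower.tail = FALSE)
        # qpois guarantees P(K > k_hi) <= truncation_mass
        support <- 0L:as.integer(k_hi)
        pmf <- stats::dpois(support, z)
        pmf <- pmf / sum(pmf)
      }
      new_degree_dist(kind, list(z = z), support, pmf)
    },
    power_law = {
      lambda <- params$lambda
      k_min <- params$k_min
      k_max <- params$k_max
      if (is.null(lambda) || lambda <= 2) {
        stop("power_law kind requires params$lambda > 2", call. = FALSE)
      }
      if (is.null(k_min) || k_min < 1) {
        stop("power_law kind requires params$k_min >= 1", call. = FALSE)
      }
      if (is.null(k_max)) k_max <- 10L * as.integer(ceiling(k_min))
      if (k_max < k_min) {
        stop("power_law kind requires params$k_min <= params$k_max", call. = FALSE)
      }
      support <- as.integer(k_min):as.integer(k_max)
      # exact discrete normalization by direct summation over the support
      pmf <- support^(-lambda)
      pmf <- pmf / sum(pmf)
      new_degree_dist(kind, list(lambda = lambda, k_min = as.integer(k_min),
                                 k_max = as.integer(k_max)), support, pmf)
    },
    regular = {
      degree <- params$degree
      if (is.null(degree) || degree < 0 || degree != round(degree)) {
        stop("regular kind requires a non-negative integer params$degree", call. = FALSE)
      }
      new_degree_dist(kind, list(degree = as.integer(degree)),
                      as.integer(degree), 1)
    },
    empirical = {
      degrees <- params$degrees
      probs <- params$probs
      if (is.null(degrees) || is.null(probs) || length(degrees) != length(probs)) {
        stop("empirical kind requires params$degrees and params$probs of equal length",
             call. = FALSE)
      }
      if (any(degrees < 0) || any(degrees != round(degrees))) {
        stop("empirical degrees must be non-negative integers", call. = FALSE)
      }
      if (any(probs < 0) || sum(probs) <= 0) {
        stop("empirical probs must be non-negative with positive sum", call. = FALSE)
      }
      o <- order(degrees)
      degrees <- as.integer(degrees[o])
      probs <- probs[o] / sum(probs[o])
      k_lo <- degrees[1L]
      k_hi <- degrees[length(degrees)]
      support <- k_lo:k_hi
      pmf <- numeric(length(support))
      pmf[degrees - k_lo + 1L] <- probs
      new_degree_dist(kind, list(degrees = degrees, probs = probs), support, pmf)
    }
  )
}

new_degree_dist <- function(kind, params, support, pmf) {
  stopifnot(length(support) == length(pmf), all(pmf >= 0),
            abs(sum(pmf) - 1) < 1e-12)
  structure(
    list(kind = kind, params = params,
         support = as.integer(support), pmf = as.numeric(pmf),
         mean = sum(support * pmf)),
    class = "degree_dist"
  )
}

#' @export
print.degree_dist <- function(x, ...) {
  cat(sprintf("<degree_dist %s> support [%d, %d], mean %.4f\n",
              x$kind, min(x$support), max(x$support), x$mean))
  invisible(x)
}

#' Convenience constructors for common degree distributions
#'
#' Thin wrappers around [make_distribution()].
#'
#' @param z Poisson mean degree.
#' @param truncation_mass Upper-tail mass retained beyond the support cut.
#' @rdname degree_dist_shortcuts
#' @export
poisson_dist <- function(z, truncation_mass = 1e-10) {
  make_distribution("poisson", list(z = z), truncation_mass)
}

#' @param lambda Power-law exponent (must exceed 2 so the mean exists).
#' @param k_min,k_max Inclusive integer degree range.
#' @rdname degree_dist_shortcuts
#' @export
power_law_dist <- function(lambda, k_min, k_max = NULL) {
  make_distribution("power_law",
                    list(lambda = lambda, k_min = k_min, k_max = k_max))
}

#' @param degree Fixed degree of the regular distribution.
#' @rdname degree_dist_shortcuts
#' @export
regular_dist <- function(degree) {
  make_distribution("regular", list(degree = degree))
}

#' @param degrees,probs Observed degree histogram.
#' @rdname degree_dist_shortcuts
#' @export
empirical_dist <- function(degrees, probs) {
  make_distribution("empirical", list(degrees = degrees, probs = probs))
}

#' Choose the power-law lower cutoff that matches a target mean
#'
#' For a truncated discrete power law `pmf(k) ~ k^-lambda` on
#' `[k_min, k_max]`, the mean is increasing in `k_min`. This scans integer
#' `k_min` values and returns the one whose truncated mean is closest to
#' `target_mean`.
#'
#' @param lambda Exponent (> 2).
#' @param target_mean Desired mean degree.
#' @param k_max Upper cutoff of the support.
#' @return List with `k_min` and the `achieved_mean`, so callers can record
#'   the deviation from the target.
#' @export
calibrate_power_law_mean <- function(lambda, target_mean, k_max) {
  if (lambda <= 2) stop("'lambda' must exceed 2", call. = FALSE)
  if (k_max < 1) stop("'k_max' must be at least 1", call. = FALSE)
  means <- vapply(1:as.integer(k_max), function(km) {
    s <- km:k_max
    w <- s^(-lambda)
    sum(s * w) / sum(w)
  }, numeric(1))
  # achievable range: mean is increasing in k_min, from means[1] up to k_max
  if (target_mean < means[1L] - 0.5 || target_mean > k_max) {
    stop(sprintf(
      "target_mean %.4g not achievable on [1, %d] with lambda = %.3g (range [%.4g, %d])",
      target_mean, as.integer(k_max), lambda, means[1L], as.integer(k_max)),
      call. = FALSE)
  }
  i <- which.min(abs(means - target_mean))
  list(k_min = as.integer(i), achieved_mean = means[i])
}

#' Sample node degrees from a degree distribution
#'
#' Draws `n` i.i.d. degrees from the distribution's pmf using R's current
#' RNG stream (Mersenne-Twister by default); call `set.seed()` beforehand
#' for reproducibility.
#'
#' @param dist A [make_distribution()] object.
#' @param n Number of draws (>= 1).
#' @return Integer vector of length `n`.
#' @export
sample_degrees <- function(dist, n) {
  stopifnot(inherits(dist, "degree_dist"))
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (length(dist$support) == 1L) {
    return(rep(dist$support, n))
  }
  sample(dist$support, size = n, replace = TRUE, prob = dist$pmf)
}
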