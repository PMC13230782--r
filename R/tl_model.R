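#' Analytic block-model description for the tree-like solver
#'
#' A `tl_model` describes an n-community network by degree distributions
#' alone: one intra-community distribution per module and one inter
#' distribution per module pair (each node draws an independent inter degree
#' toward every foreign module). This is the input of [tl_fixed_point()].
#'
#' @param intra A [make_distribution()] object shared by all modules, or a
#'   list with one per module.
#' @param inter A single distribution shared by all pairs, or a list of
#'   lists with `inter[[i]][[j]]` for `i != j` (symmetric access).
#' @param n Number of communities.
#' @param weights Fraction of nodes in each community (defaults to equal).
#' @return Object of class `tl_model` with `dists[[I]][[J]]` (links of an
#'   I-node toward community J), per-community mean degree `z_comm`, global
#'   mean `z`, and (for n = 2) the mixing parameter `mu`.
#' @examples
#' m <- tl_model_poisson(z = 15, mu = 0.5)
#' m$mu
#' @export
tl_model <- function(intra, inter, n = 2L, weights = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights <= 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("'weights' must be positive fractions summing to 1", call. = FALSE)
  }
  pick <- function(spec, i, j = NULL) {
    if (inherits(spec, "degree_dist")) return(spec)
    if (is.null(j)) return(spec[[i]])
    spec[[i]][[j]]
  }
  dists <- lapply(seq_len(n), function(I) {
    lapply(seq_len(n), function(J) {
      if (I == J) pick(intra, I) else pick(inter, I, J)
    })
  })
  z_comm <- vapply(dists, function(dd) sum(vapply(dd, `[[`, 0, "mean")), numeric(1))
  mu <- NA_real_
  if (n == 2L) {
    z_in <- dists[[1L]][[1L]]$mean
    z_out <- dists[[1L]][[2L]]$mean
    if (z_in + z_out > 0) mu <- z_out / (z_in + z_out)
  }
  structure(
    list(n = n, weights = weights, dists = dists,
         z_comm = z_comm, z = sum(weights * z_comm), mu = mu),
    class = "tl_model"
  )
}

#' @export
print.tl_model <- function(x, ...) {
  cat(sprintf("<tl_model> n = %d, z = %.3f%s\n", x$n, x$z,
              if (!is.na(x$mu)) sprintf(", mu = %.3f", x$mu) else ""))
  invisible(x)
}

#' Symmetric two-community Poisson block model
#'
#' The workhorse model family: both communities share Poisson intra- and
#' inter-degree distributions with `z_intra = (1 - mu) z` and
#' `z_inter = mu z`.
#'
#' @param z Total mean degree.
#' @param mu Mixing parameter in `[0, 1]`.
#' @param truncation_mass Poisson support truncation (see
#'   [make_distribution()]).
#' @return A [tl_model()] with n = 2.
#' @export
tl_model_poisson <- function(z, mu, truncation_mass = 1e-10) {
  if (mu < 0 || mu > 1) stop("'mu' must be in [0, 1]", call. = FALSE)
  tl_model(intra = poisson_dist((1 - mu) * z, truncation_mass),
           inter = poisson_dist(mu * z, truncation_mass))
}

#' Per-community seed fractions from a global seed fraction
#'
#' The initial adopter fraction `rho0` counts all N nodes but the seeds are
#' placed in a single community, so that community starts at local density
#' `rho0 / weight` (= `2 rho0` for equal halves) and the others at 0.
#'
#' @param rho0 Global seed fraction.
#' @param n Number of communities.
#' @param seed_module Seeded community index.
#' @param weights Community node fractions.
#' @return Numeric vector of per-community initial densities.
#' @export
seed_fractions <- function(rho0, n = 2L, seed_module = 1L,
                           weights = rep(1 / n, n)) {
  v <- numeric(n)
  v[seed_module] <- rho0 / weights[seed_module]
  if (v[seed_module] > 1) {
    stop("rho0 exceeds the seeded community's share of nodes", call. = FALSE)
  }
  v
}
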