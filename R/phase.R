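#' Classify the diffusion regime of a final state
#'
#' Non-diffusion: every community stays within `eps_contain` of its initial
#' density. Global diffusion: every community reaches at least
#' `1 - eps_saturate`. Anything else is localized diffusion (typically the
#' seed community saturates while another remains near its seed level, so
#' the global density sits near 0.5 for equal halves).
#'
#' @param rho_inf_mod Per-community final adoption densities.
#' @param rho0_mod Per-community initial densities.
#' @param eps_contain Absolute containment band.
#' @param eps_saturate Absolute saturation band.
#' @return One of `"non_diffusion"`, `"localized"`, `"global_diffusion"`.
#' @export
classify_regime <- function(rho_inf_mod, rho0_mod,
                            eps_contain = 0.1, eps_saturate = 0.05) {
  stopifnot(length(rho_inf_mod) == length(rho0_mod),
            eps_contain > 0, eps_contain < 0.5,
            eps_saturate > 0, eps_saturate < 0.5)
  if (all(rho_inf_mod <= rho0_mod + eps_contain)) return("non_diffusion")
  if (all(rho_inf_mod >= 1 - eps_saturate)) return("global_diffusion")
  "localized"
}

#' Phase diagram over regulation and mixing parameters
#'
#' Evaluates the final adoption density at every point of a 2-D grid with
#' either the tree-like solver or ensemble simulation, and classifies each
#' point's regime. Axes can be any two of `omega_intra`, `omega_inter`,
#' `mu`; the remaining parameter is fixed. The model family is the
#' symmetric two-community Poisson block model with total mean degree `z`
#' (intra/inter split by `mu`) unless `model_fn` supplies another family.
#'
#' @param axes Named list of two numeric grids, names among
#'   `"omega_intra"`, `"omega_inter"`, `"mu"`.
#' @param z Total mean degree of the Poisson family.
#' @param theta Adoption threshold.
#' @param rho0 Global seed fraction (seeds in community A).
#' @param omega_intra,omega_inter,mu Fixed values for whichever parameters
#'   are not on the axes.
#' @param solver `"tl"` (analytic) or `"sim"` (ensemble means).
#' @param model_fn Optional `function(mu)` returning a [tl_model()] to
#'   replace the Poisson family (TL solver only).
#' @param N,n_realizations,seed Simulation controls (`solver = "sim"`).
#' @param eps_contain,eps_saturate Regime classification bands.
#' @return Data frame with the two axis columns, `rho_inf`, `rho_A`,
#'   `rho_B`, `regime`; solver and parameters are attached as attributes.
#' @export
phase_diagram <- function(axes, z = NULL, theta, rho0,
                          omega_intra = NULL, omega_inter = NULL, mu = NULL,
                          solver = c("tl", "sim"), model_fn = NULL,
                          N = 2e4, n_realizations = 10L, seed = 1L,
                          eps_contain = 0.1, eps_saturate = 0.05) {
  solver <- match.arg(solver)
  ax_names <- names(axes)
  valid <- c("omega_intra", "omega_inter", "mu")
  if (length(axes) != 2L || !all(ax_names %in% valid)) {
    stop("'axes' must name two of omega_intra, omega_inter, mu", call. = FALSE)
  }
  fixed <- list(omega_intra = omega_intra, omega_inter = omega_inter, mu = mu)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  if (is.null(model_fn)) {
    if (is.null(z)) stop("'z' is required for the Poisson model family", call. = FALSE)
    model_fn <- function(mu) tl_model_poisson(z, mu)
  }

  res <- lapply(seq_len(nrow(grid)), function(r) {
    p <- fixed
    for (nm in ax_names) p[[nm]] <- grid[r, nm]
    if (is.null(p$mu)) stop("'mu' must be fixed or on an axis", call. = FALSE)
    omega <- c(p$omega_intra, p$omega_inter)
    tryCatch({
      if (solver == "tl") {
        fp <- tl_fixed_point(model_fn(p$mu), omega, theta = theta, rho0 = rho0)
        rho_mod <- fp$rho_inf
      } else {
        half <- as.integer(N / 2)
        ens <- ensemble_rho_inf(
          c(half, half),
          intra = poisson_dist((1 - p$mu) * z),
          inter = poisson_dist(p$mu * z),
          omega = omega,
          config = contagion_config(theta = theta, rho0 = rho0),
          n_realizations = n_realizations,
          seed = seed + r)
        rho_mod <- ens$mean_mod
      }
      rho0_mod <- seed_fractions(rho0, 2L)
      c(rho_A = rho_mod[1L], rho_B = rho_mod[2L],
        rho_inf = mean(rho_mod),
        regime = classify_regime(rho_mod, rho0_mod, eps_contain, eps_saturate))
    }, error = function(e) {
      stop(sprintf("solver failed at grid point (%s = %g, %s = %g): %s",
                   ax_names[1L], grid[r, 1L], ax_names[2L], grid[r, 2L],
                   conditionMessage(e)), call. = FALSE)
    })
  })
  out <- data.frame(
    grid,
    rho_inf = as.numeric(vapply(res, `[[`, "", "rho_inf")),
    rho_A = as.numeric(vapply(res, `[[`, "", "rho_A")),
    rho_B = as.numeric(vapply(res, `[[`, "", "rho_B")),
    regime = vapply(res, `[[`, "", "regime"),
    stringsAsFactors = FALSE
  )
  attr(out, "solver") <- solver
  attr(out, "params") <- list(z = z, theta = theta, rho0 = rho0, fixed = fixed)
  class(out) <- c("phase_diagram", class(out))
  out
}

#' Locate a critical parameter value by bisection
#'
#' Bisects one moving parameter (a regulation entry or `mu`) on the
#' tree-like containment indicator: the bracket must contain exactly one
#' regime change (containment differs at its endpoints). Returns the final
#' bracket midpoint, accurate to `tol`.
#'
#' @param param `"omega_intra"`, `"omega_inter"`, or `"mu"`.
#' @param bracket Length-2 numeric search interval.
#' @param z Total mean degree of the Poisson model family.
#' @param theta Adoption threshold.
#' @param rho0 Global seed fraction (seeds in community A).
#' @param omega_intra,omega_inter,mu Fixed values of the non-moving
#'   parameters.
#' @param tol Bracket width at which bisection stops.
#' @param eps_contain Containment band of the indicator.
#' @param model_fn Optional `function(mu)` model family override.
#' @return Critical value (numeric scalar).
#' @examples
#' \donttest{
#' find_critical("omega_intra", c(0.5, 0.9), z = 15, theta = 0.25,
#'               rho0 = 0.1, omega_inter = 1, mu = 0.5)
#' }
#' @export
find_critical <- function(param = c("omega_intra", "omega_inter", "mu"),
                          bracket, z = NULL, theta, rho0,
                          omega_intra = NULL, omega_inter = NULL, mu = NULL,
                          tol = 1e-3, eps_contain = 0.1, model_fn = NULL) {
  param <- match.arg(param)
  stopifnot(length(bracket) == 2L, bracket[1L] < bracket[2L])
  if (is.null(model_fn)) {
    if (is.null(z)) stop("'z' is required for the Poisson model family", call. = FALSE)
    model_fn <- function(mu) tl_model_poisson(z, mu)
  }
  fixed <- list(omega_intra = omega_intra, omega_inter = omega_inter, mu = mu)
  contained_at <- function(v) {
    p <- fixed
    p[[param]] <- v
    tl_contained(model_fn(p$mu), c(p$omega_intra, p$omega_inter),
                 theta = theta, rho0 = rho0, eps_contain = eps_contain)
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  c_lo <- contained_at(lo)
  c_hi <- contained_at(hi)
  if (c_lo == c_hi) {
    stop(sprintf(
      "bracket endpoints are in the same regime (contained = %s at both); widen or move the bracket",
      c_lo), call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (contained_at(mid) == c_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
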