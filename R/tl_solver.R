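# pmf re-indexed from degree 0 (padding below the support's k_lo)
pmf_from_zero <- function(dist) {
  k_hi <- max(dist$support)
  p <- numeric(k_hi + 1L)
  p[dist$support + 1L] <- dist$pmf
  p
}

as_omega_matrix <- function(omega, n) {
  if (is.matrix(omega)) {
    if (nrow(omega) != n) stop("omega matrix has the wrong size", call. = FALSE)
    return(omega)
  }
  regulation_matrix(omega[1L], omega[2L], n)
}

# P(sum_j weights_j * m_j > thresh) with independent m_j ~ Binom(sizes_j, y_j);
# exact enumeration by convolution of the weighted supports. This is the
# literal inner sum of the general recursion, used by the reference solver.
prob_wsum_exceeds <- function(sizes, y, weights, thresh) {
  vals <- 0
  pr <- 1
  for (j in seq_along(sizes)) {
    bj <- stats::dbinom(0:sizes[j], sizes[j], y[j])
    vj <- weights[j] * (0:sizes[j])
    vals <- as.vector(outer(vals, vj, "+"))
    pr <- as.vector(outer(pr, bj, "*"))
  }
  sum(pr[vals > thresh + 1e-9])
}

#' One step of the two-community tree-like recursion
#'
#' Updates the link-level adoption probabilities `(y_A, y_B)`: a
#' degree-weighted sum over the joint intra/inter degree pmf, split into an
#' intra-cavity term (binomial over `k_intra - 1` intra neighbors) and an
#' inter-cavity term (`k_inter - 1` inter neighbors), each gated by the
#' threshold rule (see `cavity_threshold` for the degree argument used).
#' Runs in compiled code with the inner double sum reduced to binomial tail
#' probabilities.
#'
#' @param y Numeric length-2 vector of current link-level adoption
#'   probabilities.
#' @param model A [tl_model()] with `n = 2`.
#' @param omega [regulation_matrix()] or `c(omega_intra, omega_inter)`.
#' @param theta Proportional adoption threshold.
#' @param rho0 Per-community initial densities (see [seed_fractions()]).
#' @param rule `"proportional"` or `"constant"`.
#' @param C Activation constant for the constant rule.
#' @param cavity_threshold Degree argument handed to the threshold rule
#'   inside the cavity recursion: `"full"` (the node's actual degree
#'   `k_intra + k_inter`, default) or `"decremented"`
#'   (`k_intra + k_inter - 1`). The cavity binomials always exclude the
#'   parent link; only the rule's degree argument differs. The full-degree
#'   form reproduces the synchronous dynamics (see the methods vignette).
#' @return Updated length-2 vector.
#' @export
tl_update_two <- function(y, model, omega, theta = NULL, rho0,
                          rule = c("proportional", "constant"), C = NULL,
                          cavity_threshold = c("full", "decremented")) {
  stopifnot(inherits(model, "tl_model"), model$n == 2L)
  rule <- match.arg(rule)
  cavity_threshold <- match.arg(cavity_threshold)
  omega <- as_omega_matrix(omega, 2L)
  p_intra <- list(pmf_from_zero(model$dists[[1L]][[1L]]),
                  pmf_from_zero(model$dists[[2L]][[2L]]))
  p_inter <- list(pmf_from_zero(model$dists[[1L]][[2L]]),
                  pmf_from_zero(model$dists[[2L]][[1L]]))
  tl_update_two_cpp(p_intra, p_inter, y, omega,
                    if (rule == "proportional") theta else 0,
                    rule == "constant", if (rule == "constant") C else 0,
                    rho0, cavity_threshold == "full")
}

#' One step of the general n-community tree-like recursion
#'
#' Literal evaluation of the n-community cavity recursion: nested sums over
#' all per-community degrees with the joint degree pmf, the cavity
#' community's degree decremented by one, and the adopted-neighbor sums
#' enumerated exactly. Reduces to [tl_update_two()] at n = 2; intended as
#' the reference implementation and for small-support multi-module models
#' (the enumeration grows as the product of support sizes, guarded by
#' `max_terms`).
#'
#' @inheritParams tl_update_two
#' @param max_terms Guard on the degree-enumeration size.
#' @return Updated length-n vector.
#' @export
tl_update_general <- function(y, model, omega, theta = NULL, rho0,
                              rule = c("proportional", "constant"), C = NULL,
                              cavity_threshold = c("full", "decremented"),
                              max_terms = 2e5) {
  stopifnot(inherits(model, "tl_model"))
  rule <- match.arg(rule)
  cavity_threshold <- match.arg(cavity_threshold)
  kdec <- if (cavity_threshold == "full") 0L else 1L
  n <- model$n
  omega <- as_omega_matrix(omega, n)
  out <- numeric(n)
  for (I in seq_len(n)) {
    dd <- model$dists[[I]]
    supports <- lapply(dd, `[[`, "support")
    if (prod(lengths(supports)) > max_terms) {
      stop(sprintf(
        "degree enumeration for community %d needs %g terms (> max_terms); use smaller supports",
        I, prod(lengths(supports))), call. = FALSE)
    }
    z_I <- sum(vapply(dd, `[[`, 0, "mean"))
    grid <- as.matrix(expand.grid(supports, KEEP.OUT.ATTRS = FALSE))
    pk <- rep(1, nrow(grid))
    for (j in seq_len(n)) {
      pmf_j <- dd[[j]]$pmf
      pk <- pk * pmf_j[match(grid[, j], supports[[j]])]
    }
    S <- 0
    for (r in seq_len(nrow(grid))) {
      k <- grid[r, ]
      tot <- sum(k)
      if (tot == 0L || pk[r] <= 0) next
      thresh <- if (rule == "proportional") theta * (tot - kdec) else C
      for (i in seq_len(n)) {
        if (k[i] < 1L) next
        sizes <- k
        sizes[i] <- k[i] - 1L
        p <- prob_wsum_exceeds(sizes, y, omega[I, ], thresh)
        S <- S + (k[i] / z_I) * pk[r] * p
      }
    }
    out[I] <- rho0[I] + (1 - rho0[I]) * S
  }
  out
}

# steady-state densities from converged y (general n, literal sums)
tl_rho_general <- function(y, model, omega, theta = NULL, rho0,
                           rule = c("proportional", "constant"), C = NULL) {
  rule <- match.arg(rule)
  n <- model$n
  omega <- as_omega_matrix(omega, n)
  out <- numeric(n)
  for (I in seq_len(n)) {
    dd <- model$dists[[I]]
    supports <- lapply(dd, `[[`, "support")
    grid <- as.matrix(expand.grid(supports, KEEP.OUT.ATTRS = FALSE))
    pk <- rep(1, nrow(grid))
    for (j in seq_len(n)) {
      pk <- pk * dd[[j]]$pmf[match(grid[, j], supports[[j]])]
    }
    S <- 0
    for (r in seq_len(nrow(grid))) {
      k <- grid[r, ]
      if (pk[r] <= 0) next
      thresh <- if (rule == "proportional") theta * sum(k) else C
      S <- S + pk[r] * prob_wsum_exceeds(k, y, omega[I, ], thresh)
    }
    out[I] <- rho0[I] + (1 - rho0[I]) * S
  }
  out
}

#' Tree-like fixed point of the regulated threshold cascade
#'
#' Iterates the cavity recursion from `y_0 = rho0` until the largest
#' component change falls below `tol`, then evaluates the steady-state
#' per-community adoption densities (full binomials, full degree, no cavity
#' decrement) and the module-weighted global density. The iteration is
#' monotone non-decreasing and bounded by 1, so it always converges.
#'
#' @param model A [tl_model()].
#' @param omega [regulation_matrix()] or `c(omega_intra, omega_inter)`.
#' @param theta Proportional adoption threshold (ignored for the constant
#'   rule).
#' @param rho0 Per-community initial densities, or a single global fraction
#'   which is converted via [seed_fractions()] (seeds in community 1).
#' @param rule `"proportional"` or `"constant"`.
#' @param C Activation constant for the constant rule.
#' @param tol Convergence tolerance on `max |y_{l+1} - y_l|`.
#' @param max_iter Iteration cap.
#' @param engine `"auto"` uses compiled code for n = 2 and the reference
#'   evaluation otherwise; `"two"` / `"general"` force a path.
#' @return Object of class `tl_result`: `y_inf`, `rho_inf` (per community),
#'   `rho_inf_global`, `iterations`, `converged`, `residual`.
#' @examples
#' m <- tl_model_poisson(z = 15, mu = 0.5)
#' tl_fixed_point(m, c(1, 1), theta = 0.25, rho0 = 0.1)$rho_inf_global
#' @export
tl_fixed_point <- function(model, omega, theta = NULL, rho0,
                           rule = c("proportional", "constant"), C = NULL,
                           tol = 1e-10, max_iter = 1e4,
                           engine = c("auto", "two", "general"),
                           cavity_threshold = c("full", "decremented")) {
  stopifnot(inherits(model, "tl_model"), tol > 0)
  rule <- match.arg(rule)
  engine <- match.arg(engine)
  cavity_threshold <- match.arg(cavity_threshold)
  n <- model$n
  if (length(rho0) == 1L) rho0 <- seed_fractions(rho0, n, weights = model$weights)
  omega <- as_omega_matrix(omega, n)
  use_two <- (engine == "two") || (engine == "auto" && n == 2L)

  step <- if (use_two) {
    # bind the reindexed pmfs once; the C++ core is called per iteration
    p_intra <- list(pmf_from_zero(model$dists[[1L]][[1L]]),
                    pmf_from_zero(model$dists[[2L]][[2L]]))
    p_inter <- list(pmf_from_zero(model$dists[[1L]][[2L]]),
                    pmf_from_zero(model$dists[[2L]][[1L]]))
    th <- if (rule == "proportional") theta else 0
    cc <- if (rule == "constant") C else 0
    function(y) tl_update_two_cpp(p_intra, p_inter, y, omega, th,
                                  rule == "constant", cc, rho0,
                                  cavity_threshold == "full")
  } else {
    function(y) tl_update_general(y, model, omega, theta, rho0, rule, C,
                                  cavity_threshold)
  }

  y <- rho0
  converged <- FALSE
  residual <- NA_real_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    y_new <- step(y)
    residual <- max(abs(y_new - y))
    y <- y_new
    if (residual < tol) {
      converged <- TRUE
      break
    }
  }
  rho <- if (use_two) {
    p_intra <- list(pmf_from_zero(model$dists[[1L]][[1L]]),
                    pmf_from_zero(model$dists[[2L]][[2L]]))
    p_inter <- list(pmf_from_zero(model$dists[[1L]][[2L]]),
                    pmf_from_zero(model$dists[[2L]][[1L]]))
    tl_rho_two_cpp(p_intra, p_inter, y, omega,
                   if (rule == "proportional") theta else 0,
                   rule == "constant", if (rule == "constant") C else 0, rho0)
  } else {
    tl_rho_general(y, model, omega, theta, rho0, rule, C)
  }
  structure(
    list(y_inf = as.numeric(y), rho_inf = as.numeric(rho),
         rho_inf_global = sum(model$weights * rho),
         iterations = iter, converged = converged, residual = residual),
    class = "tl_result"
  )
}

#' @export
print.tl_result <- function(x, ...) {
  cat(sprintf("<tl_result> rho_inf = %.5f (%s), %d iterations%s\n",
              x$rho_inf_global,
              paste(sprintf("%.4f", x$rho_inf), collapse = ", "),
              x$iterations,
              if (x$converged) "" else sprintf(" [residual %.2e]", x$residual)))
  invisible(x)
}

#' Containment indicator of the tree-like solution
#'
#' TRUE when the TL global final density stays within `eps_contain` of the
#' global seed fraction (diffusion fails to percolate). Exploits the
#' monotonicity of the iteration for an early exit: as soon as an iterate's
#' implied density exceeds the containment band the point is classified as
#' uncontained without iterating to convergence.
#'
#' @inheritParams tl_fixed_point
#' @param eps_contain Containment band above the global seed fraction.
#' @param check_every How often (in iterations) to evaluate the density for
#'   the early exit.
#' @return Logical scalar.
#' @export
tl_contained <- function(model, omega, theta = NULL, rho0,
                         rule = c("proportional", "constant"), C = NULL,
                         eps_contain = 0.1, tol = 1e-10, max_iter = 1e4,
                         check_every = 10L,
                         cavity_threshold = c("full", "decremented")) {
  stopifnot(inherits(model, "tl_model"), model$n == 2L)
  rule <- match.arg(rule)
  cavity_threshold <- match.arg(cavity_threshold)
  full_thr <- cavity_threshold == "full"
  n <- model$n
  if (length(rho0) == 1L) rho0 <- seed_fractions(rho0, n, weights = model$weights)
  omega <- as_omega_matrix(omega, n)
  rho0_global <- sum(model$weights * rho0)

  p_intra <- list(pmf_from_zero(model$dists[[1L]][[1L]]),
                  pmf_from_zero(model$dists[[2L]][[2L]]))
  p_inter <- list(pmf_from_zero(model$dists[[1L]][[2L]]),
                  pmf_from_zero(model$dists[[2L]][[1L]]))
  th <- if (rule == "proportional") theta else 0
  cc <- if (rule == "constant") C else 0
  is_const <- rule == "constant"

  rho_of <- function(y) {
    sum(model$weights *
          tl_rho_two_cpp(p_intra, p_inter, y, omega, th, is_const, cc, rho0))
  }
  y <- rho0
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    y_new <- tl_update_two_cpp(p_intra, p_inter, y, omega, th, is_const, cc,
                               rho0, full_thr)
    residual <- max(abs(y_new - y))
    y <- y_new
    if (residual < tol) {
      return(rho_of(y) <= rho0_global + eps_contain)
    }
    if (iter %% check_every == 0L && rho_of(y) > rho0_global + eps_contain) {
      return(FALSE) # densities only grow along the iteration
    }
  }
  rho_of(y) <= rho0_global + eps_contain
}
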