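#' Regulation matrix
#'
#' The n x n matrix of effective transmissibilities: entry `[I, J]` scales
#' the influence of adopted module-J neighbors on module-I nodes. `1 - omega`
#' is the regulatory (intervention) intensity, so `omega = 0` is complete
#' suppression and `omega = 1` unrestricted transmission.
#'
#' @param omega_intra Diagonal entries (within-community transmissibility).
#' @param omega_inter Off-diagonal entries (cross-community transmissibility).
#' @param n Number of modules.
#' @return An n x n numeric matrix.
#' @export
regulation_matrix <- function(omega_intra, omega_inter, n = 2L) {
  if (any(c(omega_intra, omega_inter) < 0) || any(c(omega_intra, omega_inter) > 1)) {
    stop("omega entries must lie in [0, 1]", call. = FALSE)
  }
  W <- matrix(omega_inter, n, n)
  diag(W) <- omega_intra
  W
}

# ties must not adopt: strict inequality with a small guard against
# floating-point noise in sums of products
.RULE_EPS <- 1e-9

#' Threshold adoption rules
#'
#' `threshold_rule()` is the proportional rule: a node with total degree `k`
#' and regulated influence `m . omega_row` adopts iff that dot product
#' strictly exceeds `theta * k`. `constant_threshold_rule()` compares against
#' a fixed activation constant `C` instead. Ties never adopt.
#'
#' @param m Integer vector of adopted-neighbor counts per module.
#' @param omega_row Matching row of the [regulation_matrix()].
#' @param theta Adoption threshold in `[0, 1]`.
#' @param k Total node degree (intra + inter).
#' @param C Activation constant (>= 0).
#' @return 0 or 1.
#' @examples
#' threshold_rule(c(2, 0), c(1, 1), theta = 0.25, k = 4) # 2 > 1 -> 1
#' threshold_rule(c(1, 0), c(1, 1), theta = 0.25, k = 4) # 1 > 1 is false -> 0
#' @export
threshold_rule <- function(m, omega_row, theta, k) {
  as.integer(sum(m * omega_row) > theta * k + .RULE_EPS)
}

#' @rdname threshold_rule
#' @export
constant_threshold_rule <- function(m, omega_row, C) {
  as.integer(sum(m * omega_row) > C + .RULE_EPS)
}

#' Cascade configuration
#'
#' Bundles the contagion rule and seeding parameters for [run_cascade()].
#' `rho0` is a fraction of *all* N nodes, all of which are placed in
#' `seed_module`; for two equal halves the seed module therefore starts at
#' local density `2 * rho0`.
#'
#' @param rule `"proportional"` (threshold `theta`) or `"constant"`
#'   (activation constant `C`).
#' @param theta Adoption threshold for the proportional rule.
#' @param C Activation constant for the constant rule.
#' @param rho0 Initial adopter fraction of all nodes, in `[0, 1)`.
#' @param seed_module Module receiving the seeds (default 1).
#' @param max_steps Cap on synchronous sweeps (monotone dynamics reach a
#'   fixed point in at most N sweeps, so the default never truncates).
#' @return A list of class `contagion_config`.
#' @export
contagion_config <- function(rule = c("proportional", "constant"),
                             theta = NULL, C = NULL, rho0,
                             seed_module = 1L, max_steps = Inf) {
  rule <- match.arg(rule)
  if (rule == "proportional") {
    if (is.null(theta) || theta < 0 || theta > 1) {
      stop("proportional rule requires theta in [0, 1]", call. = FALSE)
    }
    C <- NULL
  } else {
    if (is.null(C) || C < 0) stop("constant rule requires C >= 0", call. = FALSE)
    theta <- NULL
  }
  if (rho0 < 0 || rho0 >= 1) stop("rho0 must lie in [0, 1)", call. = FALSE)
  structure(list(rule = rule, theta = theta, C = C, rho0 = rho0,
                 seed_module = as.integer(seed_module), max_steps = max_steps),
            class = "contagion_config")
}

#' Place initial adopters in one module
#'
#' Sets exactly `round(rho0 * N)` nodes of the seed module to adopted,
#' chosen uniformly without replacement from that module; all other nodes
#' stay susceptible. Uses R's current RNG stream.
#'
#' @param net A [modular_network()].
#' @param rho0 Seed fraction of all N nodes.
#' @param seed_module Module index receiving the seeds.
#' @return Integer 0/1 state vector of length N.
#' @export
seed_initial <- function(net, rho0, seed_module = 1L) {
  n_seed <- round(rho0 * net$n_nodes)
  members <- which(net$labels == seed_module)
  if (n_seed > length(members)) {
    stop(sprintf("rho0 * N = %d exceeds module %d size %d",
                 n_seed, seed_module, length(members)), call. = FALSE)
  }
  x <- integer(net$n_nodes)
  if (n_seed > 0L) x[members[sample.int(length(members), n_seed)]] <- 1L
  x
}

#' Run a regulated threshold cascade to its fixed point
#'
#' Synchronous susceptible-to-adopted dynamics: at each sweep every
#' susceptible node evaluates the threshold rule against the previous
#' sweep's state, all simultaneously; adopted nodes never revert. Iterates
#' until no node changes (or `max_steps`).
#'
#' @param net A [modular_network()].
#' @param omega A [regulation_matrix()] with `net$n_modules` rows, or a
#'   length-2 vector `c(omega_intra, omega_inter)`.
#' @param config A [contagion_config()].
#' @param init Optional explicit 0/1 initial state vector; when omitted,
#'   seeds are drawn via [seed_initial()].
#' @return A list of class `cascade_trajectory`: per-step global density
#'   `rho` (starting at t = 0), per-module density matrix `rho_mod`, final
#'   `state`, `rho_inf`, `rho_inf_mod`, `steps`, and `converged`.
#' @examples
#' # two triangles joined by a bridge; threshold 0.4 confines the cascade
#' net <- modular_network(rbind(c(1, 2), c(1, 3), c(2, 3),
#'                              c(4, 5), c(4, 6), c(5, 6), c(3, 4)),
#'                        labels = c(1, 1, 1, 2, 2, 2))
#' cfg <- contagion_config(theta = 0.4, rho0 = 0)
#' run_cascade(net, c(1, 1), cfg, init = c(1, 0, 0, 0, 0, 0))$rho_inf
#' @export
run_cascade <- function(net, omega, config, init = NULL) {
  stopifnot(inherits(net, "modular_network"), inherits(config, "contagion_config"))
  if (!is.matrix(omega)) omega <- regulation_matrix(omega[1L], omega[2L], net$n_modules)
  if (nrow(omega) != net$n_modules) {
    stop("regulation matrix size does not match module count", call. = FALSE)
  }
  N <- net$n_nodes
  n_mod <- net$n_modules
  x <- if (is.null(init)) {
    seed_initial(net, config$rho0, config$seed_module)
  } else {
    as.integer(init)
  }
  A <- Matrix::sparseMatrix(
    i = c(net$edges[, 1L], net$edges[, 2L]),
    j = c(net$edges[, 2L], net$edges[, 1L]),
    x = 1, dims = c(N, N))
  deg <- net$degree
  thr <- if (config$rule == "proportional") config$theta * deg else rep(config$C, N)
  module_of <- net$labels
  sizes <- net$module_sizes

  mod_density <- function(x) tabulate(module_of[x == 1L], nbins = n_mod) / sizes
  rho <- sum(x) / N
  rho_mod <- matrix(mod_density(x), nrow = 1L)
  steps <- 0L
  converged <- FALSE
  while (steps < config$max_steps) {
    influence <- numeric(N)
    for (J in seq_len(n_mod)) {
      xa <- as.numeric(x == 1L & module_of == J)
      if (!any(xa > 0)) next
      cnt <- as.numeric(A %*% xa)
      influence <- influence + omega[module_of, J] * cnt
    }
    newly <- x == 0L & influence > thr + .RULE_EPS
    if (!any(newly)) {
      converged <- TRUE
      break
    }
    x[newly] <- 1L
    steps <- steps + 1L
    rho <- c(rho, sum(x) / N)
    rho_mod <- rbind(rho_mod, mod_density(x))
  }
  structure(
    list(rho = rho, rho_mod = rho_mod, state = x,
         rho_inf = rho[length(rho)],
         rho_inf_mod = rho_mod[nrow(rho_mod), ],
         steps = steps, converged = converged),
    class = "cascade_trajectory"
  )
}

#' @export
print.cascade_trajectory <- function(x, ...) {
  cat(sprintf("<cascade_trajectory> steps = %d, rho_inf = %.4f (%s)%s\n",
              x$steps, x$rho_inf,
              paste(sprintf("%.3f", x$rho_inf_mod), collapse = ", "),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Ensemble statistics of the final adoption density
#'
#' Builds `n_realizations` fresh networks from the given block model, seeds
#' and runs each cascade to its fixed point, and returns the ensemble mean
#' and standard deviation of `rho_inf`. Realization r uses RNG seed
#' `seed + r - 1`, so results are reproducible and realizations independent.
#'
#' @param module_sizes,intra,inter Passed to [build_modular_network()].
#' @param omega Regulation matrix or `c(omega_intra, omega_inter)`.
#' @param config A [contagion_config()].
#' @param n_realizations Number of independent realizations.
#' @param seed Master RNG seed.
#' @return List with `mean`, `sd`, per-realization `rho_inf`, and the
#'   per-module mean densities `mean_mod`.
#' @export
ensemble_rho_inf <- function(module_sizes, intra, inter, omega, config,
                             n_realizations = 100L, seed = 1L) {
  stopifnot(n_realizations >= 1L)
  vals <- numeric(n_realizations)
  mods <- NULL
  for (r in seq_len(n_realizations)) {
    set.seed(seed + r - 1L, kind = "Mersenne-Twister")
    net <- build_modular_network(module_sizes, intra, inter)
    traj <- run_cascade(net, omega, config)
    vals[r] <- traj$rho_inf
    mods <- rbind(mods, traj$rho_inf_mod)
  }
  list(mean = mean(vals), sd = stats::sd(vals), rho_inf = vals,
       mean_mod = colMeans(mods))
}
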