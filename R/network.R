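#' Modular network objects
#'
#' A `modular_network` is an explicit node/edge realization with community
#' labels. Edges are stored as an m x 2 integer matrix of unordered pairs
#' (`edges[, 1] < edges[, 2]`), with no self-loops and no duplicates. Node
#' indices are 1-based.
#'
#' @param edges Two-column integer matrix (or data frame) of node pairs.
#' @param labels Integer vector of community labels in `1..n_modules`, one
#'   per node; its length fixes the node count.
#' @return An object of class `modular_network` with per-node `intra_degree`
#'   and `inter_degree`, mean degrees `z`, `z_intra`, `z_inter`, and the
#'   mixing parameter `mu = z_inter / z`.
#' @export
modular_network <- function(edges, labels) {
  labels <- as.integer(labels)
  n_nodes <- length(labels)
  n_modules <- max(labels)
  stopifnot(all(labels >= 1L))
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L) stop("'edges' must have two columns", call. = FALSE)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_nodes)) {
      stop("edge endpoints out of node range", call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(edge_keys(edges, n_nodes))) {
      stop("duplicate edges are not allowed", call. = FALSE)
    }
  }
  is_inter <- if (nrow(edges)) labels[edges[, 1L]] != labels[edges[, 2L]] else logical(0)
  deg_from <- function(rows) {
    tabulate(c(edges[rows, 1L], edges[rows, 2L]), nbins = n_nodes)
  }
  intra_degree <- deg_from(!is_inter)
  inter_degree <- deg_from(is_inter)
  z_intra <- mean(intra_degree)
  z_inter <- mean(inter_degree)
  z <- z_intra + z_inter
  structure(
    list(n_nodes = n_nodes, n_modules = n_modules, labels = labels,
         module_sizes = tabulate(labels, nbins = n_modules),
         edges = edges, is_inter = is_inter,
         intra_degree = intra_degree, inter_degree = inter_degree,
         degree = intra_degree + inter_degree,
         z = z, z_intra = z_intra, z_inter = z_inter,
         mu = if (z > 0) z_inter / z else NA_real_),
    class = "modular_network"
  )
}

#' @export
print.modular_network <- function(x, ...) {
  cat(sprintf(
    "<modular_network> N = %d, modules = %d (%s), edges = %d, z = %.3f, mu = %.4f\n",
    x$n_nodes, x$n_modules, paste(x$module_sizes, collapse = "+"),
    nrow(x$edges), x$z, x$mu))
  invisible(x)
}

# unique integer key per unordered pair; N+1 base keeps keys < 2^53 for any
# network this package targets
edge_keys <- function(edges, n_nodes) {
  edges[, 1L] * (n_nodes + 1) + edges[, 2L]
}

#' Mixing parameter of a modular network
#'
#' The fraction of edges that run between communities,
#' `mu = z_inter / (z_inter + z_intra)`, computed directly from the edge set.
#'
#' @param net A [modular_network()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
mixing_parameter <- function(net) {
  stopifnot(inherits(net, "modular_network"))
  if (nrow(net$edges) == 0L) {
    stop("mixing parameter undefined for an empty edge set", call. = FALSE)
  }
  sum(net$is_inter) / nrow(net$edges)
}

# Configuration-model pairing of a stub list (intra case). Returns a matrix
# of accepted edges; collisions (self-loops, duplicates, duplicates of
# `existing` keys) are re-paired for up to `sweeps` shuffles, leftover stubs
# are dropped with a message.
pair_stubs <- function(stubs, n_nodes, sweeps = 100L) {
  accepted <- matrix(integer(0), 0L, 2L)
  seen <- numeric(0)
  for (s in seq_len(sweeps)) {
    if (length(stubs) < 2L) break
    stubs <- stubs[sample.int(length(stubs))] # index shuffle: safe for length 1
    m <- length(stubs) %/% 2L
    u <- stubs[seq_len(m)]
    v <- stubs[m + seq_len(m)]
    lo <- pmin(u, v); hi <- pmax(u, v)
    keys <- lo * (n_nodes + 1) + hi
    ok <- lo != hi & !duplicated(keys) & !(keys %in% seen)
    accepted <- rbind(accepted, cbind(lo[ok], hi[ok]))
    seen <- c(seen, keys[ok])
    leftover <- c(lo[!ok], hi[!ok])
    if (length(stubs) %% 2L == 1L) leftover <- c(leftover, stubs[length(stubs)])
    stubs <- leftover
  }
  if (length(stubs) >= 2L) {
    message(sprintf("dropping %d unmatched stubs after retry budget", length(stubs)))
  }
  accepted
}

# Bipartite pairing between two stub lists (inter case).
pair_stubs_bipartite <- function(stubs_a, stubs_b, n_nodes, sweeps = 100L) {
  accepted <- matrix(integer(0), 0L, 2L)
  seen <- numeric(0)
  for (s in seq_len(sweeps)) {
    m <- min(length(stubs_a), length(stubs_b))
    if (m < 1L) break
    stubs_a <- stubs_a[sample.int(length(stubs_a))]
    stubs_b <- stubs_b[sample.int(length(stubs_b))]
    u <- stubs_a[seq_len(m)]
    v <- stubs_b[seq_len(m)]
    lo <- pmin(u, v); hi <- pmax(u, v)
    keys <- lo * (n_nodes + 1) + hi
    ok <- !duplicated(keys) & !(keys %in% seen)
    accepted <- rbind(accepted, cbind(lo[ok], hi[ok]))
    seen <- c(seen, keys[ok])
    stubs_a <- c(u[!ok], stubs_a[seq_len(length(stubs_a)) > m])
    stubs_b <- c(v[!ok], stubs_b[seq_len(length(stubs_b)) > m])
  }
  n_left <- length(stubs_a) + length(stubs_b)
  if (n_left >= 2L) {
    message(sprintf("dropping %d unmatched inter stubs after retry budget", n_left))
  }
  accepted
}

# Make a sampled stub-count vector have even total by incrementing one
# uniformly chosen node's count (standard configuration-model fix).
fix_parity <- function(deg) {
  if (sum(deg) %% 2L == 1L) {
    i <- sample.int(length(deg), 1L)
    deg[i] <- deg[i] + 1L
  }
  deg
}

#' Build a modular network with the configuration model
#'
#' Each module's internal edges are formed by stub matching on an
#' intra-degree sequence sampled from that module's distribution; edges
#' between each module pair are formed by bipartite stub matching on
#' per-pair inter-degree sequences. Self-loops and duplicate edges are
#' rejected and re-paired (up to 100 sweeps), then leftover stubs dropped.
#' Uses R's current RNG stream; call `set.seed()` for reproducibility.
#'
#' @param module_sizes Integer vector of module sizes (each >= 2).
#' @param intra A single [make_distribution()] object shared by all modules,
#'   or a list with one distribution per module.
#' @param inter A single distribution shared by all module pairs, or a list
#'   indexed as `inter[[i]][[j]]` for the pair `(i, j)`, `i < j`. Each node
#'   draws one inter-degree per foreign module.
#' @return A [modular_network()].
#' @examples
#' set.seed(1)
#' net <- build_modular_network(c(200, 200),
#'                              intra = poisson_dist(6),
#'                              inter = poisson_dist(2))
#' mixing_parameter(net)
#' @export
build_modular_network <- function(module_sizes, intra, inter) {
  module_sizes <- as.integer(module_sizes)
  n_mod <- length(module_sizes)
  if (n_mod < 1L || any(module_sizes < 2L)) {
    stop("each module needs size >= 2", call. = FALSE)
  }
  get_dist <- function(spec, idx) {
    if (inherits(spec, "degree_dist")) spec else spec[[idx]]
  }
  n_nodes <- sum(module_sizes)
  labels <- rep(seq_len(n_mod), module_sizes)
  offsets <- c(0L, cumsum(module_sizes))
  nodes_of <- function(i) (offsets[i] + 1L):offsets[i + 1L]

  edge_blocks <- vector("list", 0L)
  for (i in seq_len(n_mod)) {
    d <- get_dist(intra, i)
    deg <- fix_parity(sample_degrees(d, module_sizes[i]))
    if (sum(deg) > 0L) {
      stubs <- rep(nodes_of(i), deg)
      edge_blocks[[length(edge_blocks) + 1L]] <- pair_stubs(stubs, n_nodes)
    }
  }
  if (n_mod >= 2L) {
    for (i in seq_len(n_mod - 1L)) {
      for (j in (i + 1L):n_mod) {
        d <- if (inherits(inter, "degree_dist")) inter else inter[[i]][[j]]
        deg_a <- sample_degrees(d, module_sizes[i])
        deg_b <- sample_degrees(d, module_sizes[j])
        # balance stub totals between the two sides by incrementing random
        # nodes on the deficit side
        diff <- sum(deg_a) - sum(deg_b)
        while (diff != 0L) {
          if (diff < 0L) {
            k <- sample.int(module_sizes[i], 1L)
            deg_a[k] <- deg_a[k] + 1L
            diff <- diff + 1L
          } else {
            k <- sample.int(module_sizes[j], 1L)
            deg_b[k] <- deg_b[k] + 1L
            diff <- diff - 1L
          }
        }
        if (sum(deg_a) > 0L) {
          stubs_a <- rep(nodes_of(i), deg_a)
          stubs_b <- rep(nodes_of(j), deg_b)
          edge_blocks[[length(edge_blocks) + 1L]] <-
            pair_stubs_bipartite(stubs_a, stubs_b, n_nodes)
        }
      }
    }
  }
  edges <- do.call(rbind, c(edge_blocks, list(matrix(integer(0), 0L, 2L))))
  modular_network(edges, labels)
}

#' Degree-preserving rewiring toward a target mixing parameter
#'
#' Repeatedly applies double-edge swaps that convert two intra edges from
#' different modules into two inter edges (raising `mu`) or two inter edges
#' between the same module pair into two intra edges (lowering `mu`). Every
#' node's total degree is preserved exactly; moves creating self-loops or
#' duplicate edges are rejected.
#'
#' @param net A [modular_network()] with at least 2 modules.
#' @param target_mu Target mixing parameter in `[0, 1]`.
#' @param max_steps Attempt budget before giving up.
#' @return The rewired network, with attributes `converged` (logical) and
#'   `achieved_mu`. Convergence means `|mu - target_mu| <= 1 / n_edges`.
#' @export
rewire_to_mu <- function(net, target_mu, max_steps = 1e6) {
  stopifnot(inherits(net, "modular_network"))
  if (net$n_modules < 2L) stop("need at least 2 modules", call. = FALSE)
  if (target_mu < 0 || target_mu > 1) stop("'target_mu' must be in [0, 1]", call. = FALSE)
  E <- net$edges
  m <- nrow(E)
  if (m == 0L) stop("cannot rewire an empty edge set", call. = FALSE)
  labels <- net$labels
  n_nodes <- net$n_nodes
  slack <- 1 / m

  keys <- new.env(hash = TRUE, size = 2L * m)
  for (r in seq_len(m)) {
    assign(as.character(edge_keys(E[r, , drop = FALSE], n_nodes)), TRUE, envir = keys)
  }
  has_edge <- function(u, v) {
    exists(as.character(min(u, v) * (n_nodes + 1) + max(u, v)), envir = keys)
  }
  put_edge <- function(r, u, v) {
    rm(list = as.character(edge_keys(E[r, , drop = FALSE], n_nodes)), envir = keys)
    E[r, ] <<- c(min(u, v), max(u, v))
    assign(as.character(min(u, v) * (n_nodes + 1) + max(u, v)), TRUE, envir = keys)
  }

  is_inter <- labels[E[, 1L]] != labels[E[, 2L]]
  n_inter <- sum(is_inter)
  steps <- 0L
  repeat {
    mu_now <- n_inter / m
    if (abs(mu_now - target_mu) <= slack) break
    if (steps >= max_steps) break
    steps <- steps + 1L
    if (mu_now < target_mu) {
      # raise mu: cross two intra edges from different modules
      cand <- which(!is_inter)
      if (length(cand) < 2L) break
      pick <- cand[sample.int(length(cand), 2L)]
      i1 <- pick[1L]; i2 <- pick[2L]
      if (labels[E[i1, 1L]] == labels[E[i2, 1L]]) next
      a1 <- E[i1, 1L]; a2 <- E[i1, 2L]
      b1 <- E[i2, 1L]; b2 <- E[i2, 2L]
      if (has_edge(a1, b1) || has_edge(a2, b2)) next
      put_edge(i1, a1, b1)
      put_edge(i2, a2, b2)
      is_inter[c(i1, i2)] <- TRUE
      n_inter <- n_inter + 2L
    } else {
      # lower mu: merge two inter edges between the same module pair
      cand <- which(is_inter)
      if (length(cand) < 2L) break
      pick <- cand[sample.int(length(cand), 2L)]
      i1 <- pick[1L]; i2 <- pick[2L]
      # orient both edges as (module X endpoint, module Y endpoint)
      x1 <- E[i1, 1L]; y1 <- E[i1, 2L]
      x2 <- E[i2, 1L]; y2 <- E[i2, 2L]
      if (labels[x2] == labels[y1] && labels[y2] == labels[x1]) {
        tmp <- x2; x2 <- y2; y2 <- tmp
      }
      if (labels[x1] != labels[x2] || labels[y1] != labels[y2]) next
      if (x1 == x2 || y1 == y2) next
      if (has_edge(x1, x2) || has_edge(y1, y2)) next
      put_edge(i1, x1, x2)
      put_edge(i2, y1, y2)
      is_inter[c(i1, i2)] <- FALSE
      n_inter <- n_inter - 2L
    }
  }
  out <- modular_network(E, labels)
  attr(out, "converged") <- abs(out$mu - target_mu) <= slack
  attr(out, "achieved_mu") <- out$mu
  attr(out, "swap_attempts") <- steps
  out
}
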