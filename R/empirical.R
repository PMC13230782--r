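#' Select the community pair to analyze
#'
#' Among all pairs of ground-truth communities whose inter-community edge
#' count is at least `min_inter_edges`, returns the pair with the largest
#' total node count (union). Ties are broken by more inter edges, then by
#' lower community indices. Inter edges are counted between the exclusive
#' memberships (endpoints in one community only), since shared nodes have
#' no side yet.
#'
#' @param edges Two-column matrix of node IDs (e.g. from
#'   [read_edge_list()]).
#' @param communities List of integer node-ID vectors (e.g. from
#'   [read_communities()]).
#' @param min_inter_edges Minimum inter-community connectivity required.
#' @return List with `a`, `b` (node-ID vectors), `indices` of the chosen
#'   communities, and `inter_edges`.
#' @export
select_community_pair <- function(edges, communities, min_inter_edges = 1L) {
  nc <- length(communities)
  if (nc < 2L) stop("need at least 2 communities", call. = FALSE)
  best <- NULL
  candidates <- character(0)
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      a <- communities[[i]]
      b <- communities[[j]]
      a_only <- setdiff(a, b)
      b_only <- setdiff(b, a)
      u_in_a <- edges[, 1L] %in% a_only
      v_in_a <- edges[, 2L] %in% a_only
      u_in_b <- edges[, 1L] %in% b_only
      v_in_b <- edges[, 2L] %in% b_only
      n_inter <- sum((u_in_a & v_in_b) | (u_in_b & v_in_a))
      size <- length(union(a, b))
      candidates <- c(candidates,
                      sprintf("(%d,%d): %d nodes, %d inter edges", i, j, size, n_inter))
      if (n_inter < min_inter_edges) next
      if (is.null(best) || size > best$size ||
          (size == best$size && n_inter > best$inter_edges)) {
        best <- list(a = a, b = b, indices = c(i, j),
                     size = size, inter_edges = n_inter)
      }
    }
  }
  if (is.null(best)) {
    stop(paste0("no community pair meets min_inter_edges = ", min_inter_edges,
                "; candidates:\n  ", paste(candidates, collapse = "\n  ")),
         call. = FALSE)
  }
  best$size <- NULL
  best
}

#' Assign overlapping nodes to one community
#'
#' Shared nodes are resolved either by the biased rule — each shared node
#' (taken in ascending ID order) goes to the currently smaller community,
#' recounted after every assignment, which balances sizes — or uniformly at
#' random (uses R's current RNG stream).
#'
#' @param a,b Node-ID vectors of the two communities (may overlap).
#' @param mode `"biased"` or `"random"`.
#' @return List with disjoint `a` and `b`.
#' @export
assign_overlaps <- function(a, b, mode = c("biased", "random")) {
  mode <- match.arg(mode)
  a <- as.integer(a)
  b <- as.integer(b)
  shared <- sort(intersect(a, b))
  a_only <- setdiff(a, b)
  b_only <- setdiff(b, a)
  if (length(shared) == 0L) return(list(a = a, b = b))
  if (mode == "biased") {
    for (v in shared) {
      if (length(a_only) <= length(b_only)) {
        a_only <- c(a_only, v)
      } else {
        b_only <- c(b_only, v)
      }
    }
  } else {
    to_a <- stats::runif(length(shared)) < 0.5
    a_only <- c(a_only, shared[to_a])
    b_only <- c(b_only, shared[!to_a])
  }
  list(a = sort(a_only), b = sort(b_only))
}

#' Two-community subnetwork induced by a community pair
#'
#' Keeps only edges with both endpoints inside the two (disjoint) node
#' sets, relabels nodes to `1..N` (community A first), and wraps the result
#' as a [modular_network()]. The pair is analyzed in isolation: edges to
#' the rest of the graph are dropped.
#'
#' @param edges Two-column matrix of node IDs.
#' @param a,b Disjoint node-ID vectors (see [assign_overlaps()]).
#' @return A [modular_network()] with attribute `node_ids` mapping internal
#'   indices back to original IDs.
#' @export
extract_subnetwork <- function(edges, a, b) {
  if (length(intersect(a, b)) > 0L) {
    stop("'a' and 'b' must be disjoint; resolve overlaps first", call. = FALSE)
  }
  ids <- c(sort(a), sort(b))
  labels <- rep(1:2, c(length(a), length(b)))
  keep <- edges[, 1L] %in% ids & edges[, 2L] %in% ids
  e <- edges[keep, , drop = FALSE]
  e <- cbind(match(e[, 1L], ids), match(e[, 2L], ids))
  net <- modular_network(e, labels)
  attr(net, "node_ids") <- ids
  net
}

#' Summary statistics of an empirical two-community subnetwork
#'
#' @param net A two-module [modular_network()].
#' @return List with `N` (node count), `mu` (mixing parameter), and `z_A`,
#'   `z_B` (mean intra-community degree within each module, full
#'   precision).
#' @export
empirical_stats <- function(net) {
  stopifnot(inherits(net, "modular_network"), net$n_modules == 2L)
  if (any(net$module_sizes == 0L)) stop("empty module", call. = FALSE)
  list(N = net$n_nodes,
       mu = mixing_parameter(net),
       z_A = mean(net$intra_degree[net$labels == 1L]),
       z_B = mean(net$intra_degree[net$labels == 2L]))
}

#' Generate a synthetic SNAP-format fixture
#'
#' Writes an edge list and a ground-truth community file in the SNAP
#' dialects with a known planted structure: two main communities (with an
#' optional overlap) wired as Bernoulli blocks, plus a few small peripheral
#' communities so that pair selection is non-trivial. The generative
#' parameters are recorded in a JSON sidecar for assertions. Uses R's
#' current RNG stream.
#'
#' @param dir Output directory (created if needed).
#' @param sizes Length-2 sizes of the planted communities (including
#'   overlap).
#' @param p_intra Within-community edge probability.
#' @param p_inter Edge probability between the exclusive parts of the two
#'   planted communities.
#' @param overlap Number of nodes shared by the planted pair.
#' @param n_extra Number of small peripheral communities.
#' @param extra_size Size of each peripheral community.
#' @return List of file paths (`edges`, `communities`, `meta`) plus the
#'   planted `truth`.
#' @export
make_snap_fixture <- function(dir, sizes = c(60L, 50L), p_intra = 0.2,
                              p_inter = 0.05, overlap = 0L,
                              n_extra = 3L, extra_size = 12L) {
  stopifnot(length(sizes) == 2L, p_intra >= 0, p_intra <= 1,
            p_inter >= 0, p_inter <= 1, overlap >= 0L,
            overlap <= min(sizes))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sA <- as.integer(sizes[1L]); sB <- as.integer(sizes[2L])
  comm_a <- 1:sA
  comm_b <- (sA - overlap + 1L):(sA - overlap + sB)
  n_main <- sA + sB - overlap

  bernoulli_block <- function(nodes_u, nodes_v = NULL, p) {
    if (p <= 0) return(matrix(integer(0), 0L, 2L))
    if (is.null(nodes_v)) { # within-group: all unordered pairs
      pr <- utils::combn(nodes_u, 2L)
      keep <- stats::runif(ncol(pr)) < p
      t(pr[, keep, drop = FALSE])
    } else {
      pr <- expand.grid(u = nodes_u, v = nodes_v)
      keep <- stats::runif(nrow(pr)) < p
      as.matrix(pr[keep, , drop = FALSE])
    }
  }
  a_only <- setdiff(comm_a, comm_b)
  b_only <- setdiff(comm_b, comm_a)
  blocks <- list(bernoulli_block(comm_a, p = p_intra),
                 bernoulli_block(comm_b, p = p_intra),
                 bernoulli_block(a_only, b_only, p_inter))
  communities <- list(comm_a, comm_b)
  next_id <- n_main
  for (e in seq_len(n_extra)) {
    nodes <- next_id + seq_len(extra_size)
    next_id <- next_id + extra_size
    communities[[length(communities) + 1L]] <- nodes
    blocks[[length(blocks) + 1L]] <- bernoulli_block(nodes, p = p_intra)
    # a single tie into the main pair keeps the file connected without
    # making the peripheral pair competitive
    blocks[[length(blocks) + 1L]] <- cbind(nodes[1L], comm_a[e %% sA + 1L])
  }
  edges <- do.call(rbind, blocks)
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  edges <- edges[!duplicated(edges[, 1L] * (next_id + 1) + edges[, 2L]), ,
                 drop = FALSE]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]

  paths <- list(edges = file.path(dir, "fixture_edges.txt"),
                communities = file.path(dir, "fixture_communities.txt"),
                meta = file.path(dir, "fixture_meta.json"))
  write_edge_list(edges, paths$edges, header = "synthetic fixture edge list")
  write_communities(communities, paths$communities)
  truth <- list(sizes = c(sA, sB), overlap = overlap,
                shared_ids = if (overlap > 0L) intersect(comm_a, comm_b) else integer(0),
                planted_pair = c(1L, 2L), p_intra = p_intra,
                p_inter = p_inter, n_extra = n_extra,
                n_nodes = next_id, n_edges = nrow(edges))
  jsonlite::write_json(truth, paths$meta, auto_unbox = TRUE, digits = NA)
  c(paths, list(truth = truth))
}
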