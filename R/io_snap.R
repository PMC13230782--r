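#' Read and write SNAP-style edge lists
#'
#' The SNAP dialect is one whitespace-separated node-ID pair per line, with
#' lines beginning with `#` treated as comments. Reading returns an
#' undirected, deduplicated edge set (`(u,v)` and `(v,u)` collapse);
#' self-loops are dropped with a message reporting the count.
#'
#' @param path File path.
#' @return `read_edge_list()`: a two-column integer matrix of node IDs (as
#'   found in the file, not remapped).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) == 0L) return(matrix(integer(0), 0L, 2L))
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge line %d: %s",
                 which(keep)[bad[1L]], lines[bad[1L]]), call. = FALSE)
  }
  u <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  v <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(u) || anyNA(v)) {
    i <- which(is.na(u) | is.na(v))[1L]
    stop(sprintf("malformed edge line %d: %s", which(keep)[i], lines[i]),
         call. = FALSE)
  }
  loops <- u == v
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
    u <- u[!loops]; v <- v[!loops]
  }
  edges <- cbind(pmin(u, v), pmax(u, v))
  edges <- edges[!duplicated(edges[, 1L] * (max(edges) + 1) + edges[, 2L]), ,
                 drop = FALSE]
  edges
}

#' @param edges Two-column matrix of node IDs, or a [modular_network()]
#'   (whose 1-based node indices are written as-is).
#' @param header Optional comment written as a leading `#` line.
#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path, header = NULL) {
  if (inherits(edges, "modular_network")) edges <- edges$edges
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(edges[, 1L], edges[, 2L], sep = "\t"), con)
  invisible(path)
}

#' Read and write SNAP-style ground-truth community files
#'
#' One community per line, node IDs separated by tabs (any whitespace is
#' accepted on input). Empty lines are skipped with a message.
#'
#' @param path File path.
#' @return `read_communities()`: a list of integer vectors of node IDs.
#' @export
read_communities <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!startsWith(lines, "#")]
  empty <- !nzchar(lines)
  if (any(empty)) message(sprintf("skipped %d empty line(s)", sum(empty)))
  lines <- lines[!empty]
  lapply(strsplit(lines, "[[:space:]]+"), function(p) as.integer(p))
}

#' @param communities List of integer node-ID vectors.
#' @rdname read_communities
#' @export
write_communities <- function(communities, path) {
  writeLines(vapply(communities, paste, "", collapse = "\t"), path)
  invisible(path)
}
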