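#' Construct a directed acyclic graph
#'
#' @param nodes Character vector of variable names.
#' @param edges Two-column character matrix (or data frame) of
#'   parent -> child edges; may have zero rows.
#' @param check_acyclic Validate acyclicity (default `TRUE`).
#' @return An object of class `dag` with elements `nodes` and `edges`
#'   (a two-column character matrix with columns `from`, `to`).
#' @export
new_dag <- function(nodes, edges = NULL, check_acyclic = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  edges <- as_edge_matrix(edges)
  if (nrow(edges)) {
    if (!all(edges %in% nodes)) stop("edge endpoint not among nodes")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loop edge")
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    if (anyDuplicated(key)) edges <- edges[!duplicated(key), , drop = FALSE]
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "dag")
  if (check_acyclic && !is_acyclic(g)) stop("graph contains a directed cycle")
  g
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0L) {
    return(matrix(character(), 0L, 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("`edges` must have two columns (from, to)")
  storage.mode(edges) <- "character"
  colnames(edges) <- c("from", "to")
  edges
}

#' Test acyclicity of a directed graph by topological sorting
#'
#' Kahn's algorithm: repeatedly remove in-degree-zero nodes; the graph is
#' acyclic iff all nodes are removed.
#'
#' @param dag A [new_dag()] object (possibly built with
#'   `check_acyclic = FALSE`).
#' @return `TRUE` iff the edge set has no directed cycle.
#' @export
is_acyclic <- function(dag) {
  !is.null(topological_order(dag))
}

# Topological order of nodes, or NULL when the graph is cyclic.
topological_order <- function(dag) {
  nodes <- dag$nodes
  nn <- length(nodes)
  if (nn == 0L) return(character())
  idx <- stats::setNames(seq_len(nn), nodes)
  from <- idx[dag$edges[, 1L]]
  to <- idx[dag$edges[, 2L]]
  indeg <- tabulate(to, nbins = nn)
  children <- split(to, factor(from, levels = seq_len(nn)))
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < nn) NULL else nodes[out]
}

# Named list of parent vectors, in node order.
dag_parents <- function(dag) {
  out <- stats::setNames(vector("list", length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) out[[v]] <- character()
  if (nrow(dag$edges)) {
    sp <- split(dag$edges[, 1L], dag$edges[, 2L])
    out[names(sp)] <- lapply(sp, as.character)
  }
  out
}

#' @export
print.dag <- function(x, ...) {
  cat("dag:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L]), sep = "\n")
  }
  invisible(x)
}

#' Whitelist/blacklist edge constraints for structure search
#'
#' @param whitelist,blacklist Two-column matrices (or data frames) of
#'   parent -> child edges that must be present / absent. Either may be
#'   `NULL`.
#' @return An object of class `edge_constraints`.
#' @export
edge_constraints <- function(whitelist = NULL, blacklist = NULL) {
  wl <- as_edge_matrix(whitelist)
  bl <- as_edge_matrix(blacklist)
  if (nrow(wl) && nrow(bl)) {
    kw <- paste(wl[, 1L], wl[, 2L], sep = "\r")
    kb <- paste(bl[, 1L], bl[, 2L], sep = "\r")
    if (any(kw %in% kb)) stop("whitelist and blacklist overlap")
  }
  if (nrow(wl)) {
    nodes <- unique(c(wl))
    if (!is_acyclic(new_dag(nodes, wl, check_acyclic = FALSE))) {
      stop("whitelist is cyclic")
    }
  }
  structure(list(whitelist = wl, blacklist = bl), class = "edge_constraints")
}

#' Check that a DAG satisfies edge constraints
#'
#' @param dag A [new_dag()] object.
#' @param constraints An [edge_constraints()] object.
#' @return `TRUE` iff every whitelist edge is present and no blacklist edge is.
#' @export
satisfies_constraints <- function(dag, constraints) {
  key <- paste(dag$edges[, 1L], dag$edges[, 2L], sep = "\r")
  wl <- constraints$whitelist
  bl <- constraints$blacklist
  ok_wl <- !nrow(wl) || all(paste(wl[, 1L], wl[, 2L], sep = "\r") %in% key)
  ok_bl <- !nrow(bl) || !any(paste(bl[, 1L], bl[, 2L], sep = "\r") %in% key)
  ok_wl && ok_bl
}

#' Export a DAG in DOT format
#'
#' @param dag A [new_dag()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(dag, path) {
  lines <- c("digraph dag {",
             paste0("  \"", dag$nodes, "\";"),
             if (nrow(dag$edges)) {
               paste0("  \"", dag$edges[, 1L], "\" -> \"",
                      dag$edges[, 2L], "\";")
             },
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export a DAG as a two-column edge-list text file
#'
#' @inheritParams write_dot
#' @param sep Field delimiter.
#' @export
write_edge_list <- function(dag, path, sep = "\t") {
  utils::write.table(dag$edges, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column edge list
#'
#' @param path File with header columns `from`, `to` (extra columns ignored).
#' @param sep Field delimiter.
#' @return A two-column character matrix usable as a whitelist/blacklist.
#' @export
read_edge_list <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_edge_matrix(df[, c("from", "to")])
}
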