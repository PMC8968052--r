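#' Directed acyclic graph over named variables
#'
#' Constructs the DAG used throughout the package: a set of node names plus a
#' two-column arc matrix (`from`, `to`).  Self-arcs, duplicate arcs, arcs
#' referencing undeclared nodes, and directed cycles are all rejected.
#'
#' @param nodes Character vector of unique variable names.
#' @param arcs Two-column character matrix or data frame of directed arcs,
#'   or `NULL` for an empty graph.
#' @return An object of class `tierbn_dag` with elements `nodes` and `arcs`.
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' check_acyclic(g)
#' @export
dag <- function(nodes, arcs = NULL) {
  if (!is.character(nodes) || anyDuplicated(nodes) || any(nodes == ""))
    stop_arg("nodes must be unique non-empty character names")
  arcs <- as_arc_matrix(arcs)
  if (nrow(arcs)) {
    if (any(arcs[, 1L] == arcs[, 2L])) stop_arg("self-arcs are not allowed")
    if (anyDuplicated(arc_ids(arcs))) stop_arg("duplicate arcs are not allowed")
    bad <- setdiff(c(arcs), nodes)
    if (length(bad))
      stop_arg("arcs reference undeclared nodes: %s", paste(bad, collapse = ", "))
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "tierbn_dag")
  ord <- topo_order(nodes, arcs)
  if (is.null(ord)) {
    cyc <- find_cycle(nodes, arcs)
    stop_arg("arc set contains a directed cycle: %s", paste(cyc, collapse = " -> "))
  }
  g
}

#' @export
print.tierbn_dag <- function(x, ...) {
  cat(sprintf("<tierbn_dag> %d nodes, %d arcs\n", length(x$nodes), nrow(x$arcs)))
  if (nrow(x$arcs))
    cat(paste0("  ", x$arcs[, 1L], " -> ", x$arcs[, 2L], collapse = "\n"), "\n")
  invisible(x)
}

# Kahn's algorithm; NULL when a cycle exists.
topo_order <- function(nodes, arcs) {
  arcs <- as_arc_matrix(arcs)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(arcs)) {
    tab <- table(factor(arcs[, 2L], levels = nodes))
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- split(arcs[, 2L], factor(arcs[, 1L], levels = nodes))
  order <- character(0)
  # lexicographic queue keeps the order deterministic
  avail <- sort(names(indeg)[indeg == 0L])
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

find_cycle <- function(nodes, arcs) {
  arcs <- as_arc_matrix(arcs)
  out <- split(arcs[, 2L], factor(arcs[, 1L], levels = nodes))
  state <- stats::setNames(integer(length(nodes)), nodes) # 0 new, 1 open, 2 done
  path <- character(0)
  res <- NULL
  visit <- function(v) {
    if (!is.null(res)) return()
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in out[[v]]) {
      if (state[w] == 1L) {
        i <- match(w, path)
        res <<- c(path[i:length(path)], w)
        return()
      }
      if (state[w] == 0L) visit(w)
      if (!is.null(res)) return()
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in nodes) if (state[v] == 0L) visit(v)
  res
}

#' Test a candidate arc set for acyclicity
#'
#' @param dag A `tierbn_dag`, or a list with `nodes` and `arcs` that has not
#'   yet been validated (useful for candidate structures during search).
#' @return `TRUE` when no directed cycle exists.
#' @export
check_acyclic <- function(dag) {
  !is.null(topo_order(dag$nodes, dag$arcs))
}

parents_of <- function(dag, node) unname(dag$arcs[dag$arcs[, 2L] == node, 1L])
children_of <- function(dag, node) unname(dag$arcs[dag$arcs[, 1L] == node, 2L])

# adjacency test used by the CPDAG labeller
has_arc <- function(arcs, from, to) {
  any(arcs[, 1L] == from & arcs[, 2L] == to)
}

#' Completed partially directed acyclic graph (Markov-equivalence class)
#'
#' Labels every arc of a DAG as compelled (same orientation in every
#' equivalent DAG) or reversible, following Chickering's edge-labelling
#' procedure, and returns the CPDAG: compelled arcs stay directed, reversible
#' arcs become undirected edges.
#'
#' @param dag A `tierbn_dag`.
#' @return Object of class `tierbn_cpdag`: `nodes`, `directed` (arc matrix),
#'   `undirected` (arc matrix in canonical node order).
#' @export
cpdag <- function(dag) {
  stopifnot(inherits(dag, "tierbn_dag"))
  arcs <- dag$arcs
  if (!nrow(arcs)) {
    return(structure(list(nodes = dag$nodes,
                          directed = as_arc_matrix(NULL),
                          undirected = as_arc_matrix(NULL)),
                     class = "tierbn_cpdag"))
  }
  ord <- topo_order(dag$nodes, arcs)
  rank <- stats::setNames(seq_along(ord), ord)
  # total order on edges: by child ascending, then parent descending
  eo <- order(rank[arcs[, 2L]], -rank[arcs[, 1L]])
  arcs <- arcs[eo, , drop = FALSE]
  m <- nrow(arcs)
  lab <- rep(NA_character_, m) # "compelled" / "reversible"
  edge_idx <- function(from, to) which(arcs[, 1L] == from & arcs[, 2L] == to)
  while (anyNA(lab)) {
    e <- which(is.na(lab))[1L]
    x <- arcs[e, 1L]; y <- arcs[e, 2L]
    done <- FALSE
    for (w in arcs[lab %in% "compelled" & arcs[, 2L] == x, 1L]) {
      if (!has_arc(arcs, w, y)) {
        into_y <- which(arcs[, 2L] == y)
        lab[into_y] <- "compelled"
        done <- TRUE
        break
      } else {
        lab[edge_idx(w, y)] <- "compelled"
      }
    }
    if (done) next
    zs <- arcs[arcs[, 2L] == y & arcs[, 1L] != x, 1L]
    ext <- any(vapply(zs, function(z) !has_arc(arcs, z, x), logical(1L)))
    into_y_unlab <- which(arcs[, 2L] == y & is.na(lab))
    lab[into_y_unlab] <- if (ext) "compelled" else "reversible"
  }
  und <- arcs[lab == "reversible", , drop = FALSE]
  if (nrow(und)) {
    swap <- und[, 1L] > und[, 2L]
    und[swap, ] <- und[swap, 2:1]
  }
  structure(list(nodes = dag$nodes,
                 directed = arcs[lab == "compelled", , drop = FALSE],
                 undirected = und),
            class = "tierbn_cpdag")
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# orientation category of each adjacency in a dag or cpdag:
# named vector over unordered pair keys with values "fwd"/"bwd"/"und"
# ("fwd" means min-name -> max-name)
adjacency_classes <- function(g) {
  if (inherits(g, "tierbn_dag")) {
    d <- g$arcs; u <- as_arc_matrix(NULL)
  } else {
    d <- g$directed; u <- g$undirected
  }
  keys <- character(0); vals <- character(0)
  if (nrow(d)) {
    keys <- pair_key(d[, 1L], d[, 2L])
    vals <- ifelse(d[, 1L] <= d[, 2L], "fwd", "bwd")
  }
  if (nrow(u)) {
    keys <- c(keys, pair_key(u[, 1L], u[, 2L]))
    vals <- c(vals, rep("und", nrow(u)))
  }
  stats::setNames(vals, keys)
}

#' Structural Hamming distance
#'
#' Number of adjacency insertions, deletions, and orientation changes needed
#' to turn one graph into the other.  Accepts two DAGs or two CPDAGs; mixing
#' a DAG with a CPDAG compares the DAG's arcs as directed edges.
#'
#' @param a,b Graphs (`tierbn_dag` or `tierbn_cpdag`).
#' @return Non-negative integer distance.
#' @export
shd <- function(a, b) {
  ca <- adjacency_classes(a)
  cb <- adjacency_classes(b)
  keys <- union(names(ca), names(cb))
  sum(vapply(keys, function(k) {
    va <- ca[k]; vb <- cb[k]
    if (is.na(va) || is.na(vb)) 1L else if (va == vb) 0L else 1L
  }, integer(1L)))
}

#' Structural comparison of two DAGs
#'
#' Partitions the union of adjacencies into arcs only in `dag_a`, only in
#' `dag_b`, shared with the same direction, and shared but reversed; reports
#' the structural Hamming distance and the outcome node's parents and
#' children in each graph.
#'
#' @param dag_a,dag_b `tierbn_dag` objects (node universes are unioned).
#' @param outcome Name of the outcome variable (optional).
#' @return Object of class `tierbn_structure_diff`.
#' @export
structure_diff <- function(dag_a, dag_b, outcome = NULL) {
  a <- dag_a$arcs; b <- dag_b$arcs
  ia <- arc_ids(a); ib <- arc_ids(b)
  rev_b <- arc_ids(b[, 2:1, drop = FALSE])
  shared <- a[ia %in% ib, , drop = FALSE]
  reversed <- a[ia %in% rev_b & !(ia %in% ib), , drop = FALSE]
  only_a <- a[!(ia %in% ib) & !(ia %in% rev_b), , drop = FALSE]
  only_b <- b[!(ib %in% ia) & !(ib %in% arc_ids(a[, 2:1, drop = FALSE])), , drop = FALSE]
  d <- nrow(only_a) + nrow(only_b) + nrow(reversed)
  out <- list(
    only_a = only_a, only_b = only_b,
    shared = shared, reversed = reversed,
    shd = d,
    outcome = outcome,
    outcome_parents_a = if (!is.null(outcome)) sort(parents_of(dag_a, outcome)),
    outcome_parents_b = if (!is.null(outcome)) sort(parents_of(dag_b, outcome)),
    outcome_children_a = if (!is.null(outcome)) sort(children_of(dag_a, outcome)),
    outcome_children_b = if (!is.null(outcome)) sort(children_of(dag_b, outcome))
  )
  structure(out, class = "tierbn_structure_diff")
}

#' @export
print.tierbn_structure_diff <- function(x, ...) {
  cat(sprintf("<structure diff> SHD = %d\n", x$shd))
  cat(sprintf("  only in A: %d | only in B: %d | shared: %d | reversed: %d\n",
              nrow(x$only_a), nrow(x$only_b), nrow(x$shared), nrow(x$reversed)))
  if (!is.null(x$outcome)) {
    cat(sprintf("  %s parents  A: {%s}  B: {%s}\n", x$outcome,
                paste(x$outcome_parents_a, collapse = ", "),
                paste(x$outcome_parents_b, collapse = ", ")))
  }
  invisible(x)
}
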