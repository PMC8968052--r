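# Decomposable BIC scoring and greedy search.
#
# Sign convention: HIGHER IS BETTER.  local_score = maximised log-likelihood
# of the node given its parents minus (log N / 2) * (r - 1) * q, so the
# network score is the usual log-lik minus complexity penalty; many texts
# report the negated quantity.

# columns pre-encoded once for speed: integer matrix + cardinalities
encode_score_data <- function(data, nodes) {
  for (v in nodes) {
    if (is.null(data[[v]])) stop_arg("data is missing column `%s`", v)
    if (!is.factor(data[[v]])) stop_arg("column `%s` must be a factor", v)
    if (anyNA(data[[v]])) stop_arg("column `%s` has missing values", v)
  }
  codes <- vapply(nodes, function(v) as.integer(data[[v]]), integer(nrow(data)))
  codes <- matrix(codes, nrow = nrow(data), dimnames = list(NULL, nodes))
  cards <- vapply(nodes, function(v) nlevels(data[[v]]), integer(1L))
  list(codes = codes, cards = cards, n = nrow(data))
}

local_score_encoded <- function(enc, node, parents) {
  cards <- enc$cards[parents]
  q <- prod(cards, 1L)
  r <- enc$cards[[node]]
  cfg <- config_index(enc$codes[, parents, drop = FALSE], cards)
  cnt <- matrix(tabulate((enc$codes[, node] - 1L) * q + cfg, nbins = q * r), q, r)
  tot <- rowSums(cnt)
  nz <- cnt > 0
  ll <- sum(cnt[nz] * log(cnt[nz] / tot[row(cnt)[nz]]))
  ll - log(enc$n) / 2 * (r - 1) * q
}

#' Local BIC score of one node given a parent set
#'
#' Maximum-likelihood log-likelihood of `node | parents` minus
#' `(log N / 2) (r - 1) q` where `r` is the node cardinality and `q` the
#' product of parent cardinalities.  Decomposable: unaffected by arcs
#' elsewhere in the graph.  Higher is better.
#'
#' @param node Node name.
#' @param parents Character vector of parent names (possibly empty).
#' @param data Data frame of complete factors.
#' @return A single number.
#' @export
local_score <- function(node, parents, data) {
  if (!is.data.frame(data) || !nrow(data)) stop_arg("data must have rows")
  enc <- encode_score_data(data, unique(c(node, parents)))
  local_score_encoded(enc, node, parents)
}

#' Network BIC score (higher is better)
#'
#' Sum of [local_score()] over the DAG's nodes.
#'
#' @param dag A `tierbn_dag` (cyclic structures are rejected by construction).
#' @param data Data frame of complete factors covering the DAG's nodes.
#' @return A single number.
#' @export
bic <- function(dag, data) {
  if (!inherits(dag, "tierbn_dag")) stop_arg("dag must be a tierbn_dag")
  if (!check_acyclic(dag)) stop_arg("cyclic input")
  if (!is.data.frame(data) || !nrow(data)) stop_arg("data must have rows")
  enc <- encode_score_data(data, dag$nodes)
  sum(vapply(dag$nodes, function(v)
    local_score_encoded(enc, v, unname(parents_of(dag, v))), numeric(1L)))
}

# memoised local score, keyed by node + sorted parent set
make_score_cache <- function(enc) {
  cache <- new.env(parent = emptyenv())
  function(node, parents) {
    key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- local_score_encoded(enc, node, parents)
    cache[[key]] <- val
    val
  }
}

# parent lookup from an arc matrix
arcs_parents <- function(arcs, node) unname(arcs[arcs[, 2L] == node, 1L])

# would adding from->to create a cycle? (arcs currently acyclic)
creates_cycle <- function(nodes, arcs, from, to) {
  # cycle iff `from` reachable from `to`
  reach <- to
  frontier <- to
  out <- split(arcs[, 2L], factor(arcs[, 1L], levels = nodes))
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(out[frontier])), reach)
    if (from %in% nxt) return(TRUE)
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Hill-climbing structure learning under BIC
#'
#' Greedy best-improvement search from the empty graph: at each step the
#' single arc addition, deletion, or reversal with the largest BIC gain
#' above `tol` is applied (equal gains broken by lexicographically smallest
#' `(from, to, move)`).  After convergence, each random restart perturbs
#' the incumbent optimum with `perturb` random valid moves and re-climbs;
#' the best structure seen anywhere is returned.  Blacklisted arcs are
#' never proposed (also not via reversal) and every returned structure is
#' acyclic.
#'
#' @param data Data frame of complete factors.
#' @param nodes Variables to learn over (default: all columns).
#' @param forbidden Optional arc blacklist (two-column matrix), e.g.
#'   [forbidden_arc_set()] of a tier map.
#' @param restarts Number of random restarts (default 5).
#' @param perturb Random moves applied per restart (default 5).
#' @param seed Integer seed for the restart perturbations.
#' @param tol Minimal accepted score gain (default 1e-9).
#' @return The learned `tierbn_dag`; attribute `score` holds its BIC and
#'   attribute `trace` a data frame of accepted moves.
#' @export
hill_climb <- function(data, nodes = NULL, forbidden = NULL, restarts = 5L,
                       perturb = 5L, seed = 1L, tol = 1e-9) {
  if (!is.data.frame(data) || !nrow(data)) stop_arg("data must have rows")
  nodes <- sort(nodes %||% names(data))
  assert_scalar_int(restarts, "restarts", min = 0)
  assert_scalar_int(perturb, "perturb", min = 0)
  enc <- encode_score_data(data, nodes)
  score_of <- make_score_cache(enc)
  forbidden_ids <- arc_ids(as_arc_matrix(forbidden))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
  pair_ids <- arc_ids(as.matrix(pairs))
  addable <- !(pair_ids %in% forbidden_ids)

  trace <- list()
  graph_score <- function(arcs) {
    sum(vapply(nodes, function(v) score_of(v, arcs_parents(arcs, v)),
               numeric(1L)))
  }

  # enumerate all legal moves on `arcs`; returns data.frame or NULL
  legal_moves <- function(arcs) {
    ids <- arc_ids(arcs)
    present <- pair_ids %in% ids
    rev_ids <- arc_ids(as.matrix(pairs)[, 2:1, drop = FALSE])
    rev_present <- rev_ids %in% ids
    move <- character(0); from <- character(0); to <- character(0)
    add_ok <- addable & !present & !rev_present
    if (any(add_ok)) {
      move <- c(move, rep("add", sum(add_ok)))
      from <- c(from, pairs$from[add_ok]); to <- c(to, pairs$to[add_ok])
    }
    if (any(present)) {
      move <- c(move, rep("delete", sum(present)))
      from <- c(from, pairs$from[present]); to <- c(to, pairs$to[present])
    }
    rev_ok <- present & !(rev_ids %in% forbidden_ids)
    if (any(rev_ok)) {
      move <- c(move, rep("reverse", sum(rev_ok)))
      from <- c(from, pairs$from[rev_ok]); to <- c(to, pairs$to[rev_ok])
    }
    if (!length(move)) return(NULL)
    data.frame(move = move, from = from, to = to, stringsAsFactors = FALSE)
  }

  apply_move <- function(arcs, move, from, to) {
    if (move == "add") return(rbind(arcs, c(from, to)))
    keep <- !(arcs[, 1L] == from & arcs[, 2L] == to)
    arcs <- arcs[keep, , drop = FALSE]
    if (move == "reverse") arcs <- rbind(arcs, c(to, from))
    arcs
  }

  move_gain <- function(arcs, move, from, to) {
    p_to <- arcs_parents(arcs, to)
    if (move == "add") {
      if (creates_cycle(nodes, arcs, from, to)) return(NA_real_)
      return(score_of(to, c(p_to, from)) - score_of(to, p_to))
    }
    if (move == "delete")
      return(score_of(to, setdiff(p_to, from)) - score_of(to, p_to))
    # reverse from->to
    arcs_del <- arcs[!(arcs[, 1L] == from & arcs[, 2L] == to), , drop = FALSE]
    if (creates_cycle(nodes, arcs_del, to, from)) return(NA_real_)
    p_from <- arcs_parents(arcs, from)
    (score_of(to, setdiff(p_to, from)) - score_of(to, p_to)) +
      (score_of(from, c(p_from, to)) - score_of(from, p_from))
  }

  climb <- function(arcs, phase) {
    repeat {
      mv <- legal_moves(arcs)
      if (is.null(mv)) break
      gains <- mapply(move_gain, mv$move, mv$from, mv$to,
                      MoreArgs = list(arcs = arcs))
      ok <- which(!is.na(gains) & gains > tol)
      if (!length(ok)) break
      mtype <- match(mv$move[ok], c("add", "delete", "reverse"))
      best <- ok[order(-gains[ok], mv$from[ok], mv$to[ok], mtype)][1L]
      arcs <- apply_move(arcs, mv$move[best], mv$from[best], mv$to[best])
      trace[[length(trace) + 1L]] <<- data.frame(
        phase = phase, move = mv$move[best], from = mv$from[best],
        to = mv$to[best], gain = gains[best], stringsAsFactors = FALSE)
    }
    arcs
  }

  empty <- as_arc_matrix(NULL)
  best_arcs <- climb(empty, phase = "initial")
  best_score <- graph_score(best_arcs)
  if (restarts > 0L) {
    with_seed(derive_seed(seed, "hc-restart"), {
      for (rs in seq_len(restarts)) {
        arcs <- best_arcs
        for (p in seq_len(perturb)) {
          mv <- legal_moves(arcs)
          if (is.null(mv)) break
          # keep only moves that leave the graph acyclic
          okc <- vapply(seq_len(nrow(mv)), function(i) {
            !is.na(move_gain(arcs, mv$move[i], mv$from[i], mv$to[i]))
          }, logical(1L))
          mv <- mv[okc, , drop = FALSE]
          if (!nrow(mv)) break
          pick <- sample.int(nrow(mv), 1L)
          arcs <- apply_move(arcs, mv$move[pick], mv$from[pick], mv$to[pick])
        }
        arcs <- climb(arcs, phase = sprintf("restart%02d", rs))
        sc <- graph_score(arcs)
        if (sc > best_score + tol) {
          best_score <- sc
          best_arcs <- arcs
        }
      }
    })
  }
  g <- dag(nodes, best_arcs)
  attr(g, "score") <- best_score
  attr(g, "trace") <- if (length(trace)) do.call(rbind, trace) else
    data.frame(phase = character(0), move = character(0), from = character(0),
               to = character(0), gain = numeric(0))
  g
}
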