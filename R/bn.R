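#' Conditional probability table
#'
#' One CPT per network node: a `q x r` probability matrix where `r` is the
#' number of node categories and `q` the number of parent configurations.
#' Parent configurations are indexed with the first parent varying fastest
#' (the `expand.grid` convention), so row `1 + sum((code_i - 1) * stride_i)`
#' corresponds to parent level codes `code_i`.
#'
#' @param node Node name.
#' @param levels Character vector of node categories.
#' @param parents Character vector of parent names (possibly empty).
#' @param parent_levels Named list of category vectors, one per parent.
#' @param prob Numeric matrix `q x r` of conditional probabilities; a bare
#'   vector is accepted for a parentless node.
#' @return Object of class `tierbn_cpt`.
#' @export
cpt <- function(node, levels, parents = character(0), parent_levels = list(),
                prob) {
  if (!is.character(levels) || length(levels) < 2L || anyDuplicated(levels))
    stop_arg("node `%s` needs >= 2 unique categories", node)
  if (length(parents)) {
    if (!setequal(names(parent_levels), parents))
      stop_arg("parent_levels must be named by the parents of `%s`", node)
    parent_levels <- parent_levels[parents]
  } else parent_levels <- list()
  q <- prod(vapply(parent_levels, length, integer(1L)), 1L)
  r <- length(levels)
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = q, byrow = TRUE)
  if (!is.matrix(prob) || nrow(prob) != q || ncol(prob) != r)
    stop_arg("prob for `%s` must be a %d x %d matrix", node, q, r)
  if (any(prob < 0)) stop_arg("negative probability in CPT of `%s`", node)
  if (any(abs(rowSums(prob) - 1) > 1e-9))
    stop_arg("CPT rows of `%s` must sum to 1 (tol 1e-9)", node)
  colnames(prob) <- levels
  structure(list(node = node, levels = levels, parents = parents,
                 parent_levels = parent_levels, prob = prob),
            class = "tierbn_cpt")
}

# strides for the expand.grid-style parent configuration index
config_strides <- function(cards) {
  if (!length(cards)) return(integer(0))
  cumprod(c(1L, utils::head(cards, -1L)))
}

# integer config index per row from a matrix of level codes (columns = parents)
config_index <- function(codes, cards) {
  if (!length(cards)) return(rep(1L, nrow(codes)))
  as.integer(1L + (codes - 1L) %*% config_strides(cards))
}

#' Discrete Bayesian network
#'
#' Binds a DAG to one CPT per node and validates their mutual consistency:
#' CPT parent sets must equal the DAG parent sets and category vocabularies
#' must agree between a parent's own CPT and every child referencing it.
#'
#' @param dag A `tierbn_dag`.
#' @param cpts Named list of `tierbn_cpt`, one per node.
#' @return Object of class `tierbn_bn`.
#' @export
bayesian_network <- function(dag, cpts) {
  stopifnot(inherits(dag, "tierbn_dag"))
  if (!setequal(names(cpts), dag$nodes))
    stop_arg("need exactly one CPT per DAG node")
  cpts <- cpts[dag$nodes]
  for (v in dag$nodes) {
    ct <- cpts[[v]]
    if (!identical(sort(ct$parents), sort(unname(parents_of(dag, v)))))
      stop_arg("CPT parents of `%s` do not match the DAG", v)
    for (p in ct$parents) {
      if (!identical(ct$parent_levels[[p]], cpts[[p]]$levels))
        stop_arg("category set of `%s` differs between its CPT and child `%s`",
                 p, v)
    }
  }
  structure(list(dag = dag, cpts = cpts), class = "tierbn_bn")
}

#' @export
print.tierbn_bn <- function(x, ...) {
  cat(sprintf("<tierbn_bn> %d nodes, %d arcs\n",
              length(x$dag$nodes), nrow(x$dag$arcs)))
  invisible(x)
}

node_levels <- function(bn, node) bn$cpts[[node]]$levels

# data.frame of factors -> integer code matrix in bn level order, with checks
encode_data <- function(data, nodes, levels_list) {
  codes <- matrix(0L, nrow(data), length(nodes), dimnames = list(NULL, nodes))
  for (v in nodes) {
    if (is.null(data[[v]])) stop_arg("data is missing column `%s`", v)
    x <- as.character(data[[v]])
    code <- match(x, levels_list[[v]])
    bad <- which(is.na(code) & !is.na(x))
    if (length(bad))
      stop_arg("row %d has unseen category `%s` for variable `%s`",
               bad[1L], x[bad[1L]], v)
    if (anyNA(x))
      stop_arg("variable `%s` contains missing values; encode them first", v)
    codes[, v] <- code
  }
  codes
}

#' Estimate CPTs from complete categorical data
#'
#' Maximum-likelihood (`alpha = 0`) or Laplace-smoothed conditional
#' frequencies: `(count + alpha) / (config total + alpha * r)`.  Parent
#' configurations never observed get a uniform row when `alpha = 0`, with a
#' single consolidated warning.
#'
#' @param dag A `tierbn_dag` whose nodes are columns of `data`.
#' @param data Data frame of factors (levels define the category sets).
#' @param alpha Non-negative pseudocount (default 0, maximum likelihood).
#' @return A fitted `tierbn_bn`.
#' @export
fit_parameters <- function(dag, data, alpha = 0) {
  stopifnot(inherits(dag, "tierbn_dag"))
  if (!is.data.frame(data) || !nrow(data)) stop_arg("data must have rows")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop_arg("alpha must be a single non-negative number")
  levels_list <- lapply(dag$nodes, function(v) {
    if (is.null(data[[v]])) stop_arg("data is missing column `%s`", v)
    if (!is.factor(data[[v]]))
      stop_arg("column `%s` must be a factor (its levels fix the categories)", v)
    levels(data[[v]])
  })
  names(levels_list) <- dag$nodes
  codes <- encode_data(data, dag$nodes, levels_list)
  unseen <- character(0)
  cpts <- lapply(dag$nodes, function(v) {
    pars <- unname(parents_of(dag, v))
    lv <- levels_list[[v]]
    r <- length(lv)
    cards <- vapply(pars, function(p) length(levels_list[[p]]), integer(1L))
    q <- prod(cards, 1L)
    cfg <- config_index(codes[, pars, drop = FALSE], cards)
    cnt <- matrix(tabulate((codes[, v] - 1L) * q + cfg, nbins = q * r), q, r)
    tot <- rowSums(cnt)
    prob <- (cnt + alpha) / (tot + alpha * r)
    if (alpha == 0 && any(tot == 0)) {
      unseen <<- c(unseen, v)
      prob[tot == 0, ] <- 1 / r
    }
    cpt(v, lv, pars, stats::setNames(levels_list[pars], pars), prob)
  })
  names(cpts) <- dag$nodes
  if (length(unseen))
    warning(sprintf(
      "unseen parent configuration(s) for %s with alpha = 0: uniform row substituted",
      paste(unique(unseen), collapse = ", ")), call. = FALSE)
  bayesian_network(dag, cpts)
}

#' Log-likelihood of complete data under a network
#'
#' Sum over rows and nodes of the log conditional probabilities; `-Inf` when
#' any observation hits a zero-probability CPT cell.
#'
#' @param bn A `tierbn_bn`.
#' @param data Data frame whose values lie in the network's category sets.
#' @return A single number (possibly `-Inf`).
#' @export
log_likelihood <- function(bn, data) {
  stopifnot(inherits(bn, "tierbn_bn"))
  levels_list <- lapply(bn$cpts, function(ct) ct$levels)
  codes <- encode_data(data, bn$dag$nodes, levels_list)
  ll <- 0
  for (v in bn$dag$nodes) {
    ct <- bn$cpts[[v]]
    cards <- vapply(ct$parents, function(p) length(levels_list[[p]]), integer(1L))
    cfg <- config_index(codes[, ct$parents, drop = FALSE], cards)
    p <- ct$prob[cbind(cfg, codes[, v])]
    if (any(p == 0)) return(-Inf)
    ll <- ll + sum(log(p))
  }
  ll
}

#' Forward (ancestral) sampling from a network
#'
#' Draws `n` complete rows in topological order; every column is a factor
#' with the network's category set as levels.  Deterministic for fixed seed.
#'
#' @param bn A `tierbn_bn`.
#' @param n Number of rows (>= 1).
#' @param seed Integer seed.
#' @return Data frame of `n` rows.
#' @export
ancestral_sample <- function(bn, n, seed = 1L) {
  stopifnot(inherits(bn, "tierbn_bn"))
  assert_scalar_int(n, "n", min = 1)
  ord <- topo_order(bn$dag$nodes, bn$dag$arcs)
  codes <- matrix(0L, n, length(bn$dag$nodes),
                  dimnames = list(NULL, bn$dag$nodes))
  with_seed(seed, {
    for (v in ord) {
      ct <- bn$cpts[[v]]
      cards <- vapply(ct$parents, function(p) length(bn$cpts[[p]]$levels),
                      integer(1L))
      cfg <- config_index(codes[, ct$parents, drop = FALSE], cards)
      u <- stats::runif(n)
      # inverse-CDF against the cumulative row of each sample's config
      cum <- t(apply(ct$prob, 1L, cumsum))
      val <- rep(1L, n)
      for (k in seq_len(ncol(cum) - 1L))
        val <- val + as.integer(u > cum[cfg, k])
      codes[, v] <- val
    }
  })
  out <- as.data.frame(lapply(bn$dag$nodes, function(v) {
    factor(bn$cpts[[v]]$levels[codes[, v]], levels = bn$cpts[[v]]$levels)
  }), col.names = bn$dag$nodes, stringsAsFactors = TRUE, optional = TRUE)
  names(out) <- bn$dag$nodes
  out
}
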