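# Exact inference by variable elimination.
#
# Factors are plain lists: vars (character), arr (array with one dimension
# per variable, dimnames = category labels).  Small networks only (the
# package targets <= ~15-node clinical models), so clarity beats micro-
# optimisation; elimination order is min-degree with alphabetical ties for
# deterministic output.

cpt_factor <- function(ct) {
  vars <- c(ct$parents, ct$node)
  dims <- c(vapply(ct$parent_levels, length, integer(1L)), length(ct$levels))
  # prob rows index parent configs with first parent fastest; node varies
  # slowest across the matrix columns -> matches array(dim = c(parents, node))
  arr <- array(as.vector(ct$prob), dim = dims,
               dimnames = c(ct$parent_levels, stats::setNames(list(ct$levels),
                                                              ct$node)))
  list(vars = vars, arr = arr)
}

factor_reduce <- function(f, var, value) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  pos <- match(value, dimnames(f$arr)[[i]])
  if (is.na(pos)) stop_arg("evidence value `%s` not a category of `%s`", value, var)
  idx[[i]] <- pos
  arr <- do.call(`[`, c(list(f$arr), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), i)
  if (!length(keep)) {
    return(list(vars = character(0), arr = array(as.numeric(arr), dim = 1L)))
  }
  arr <- array(arr, dim = dim(f$arr)[keep], dimnames = dimnames(f$arr)[keep])
  list(vars = f$vars[keep], arr = arr)
}

expand_to <- function(f, vars_u, dims_u, dn_u) {
  extra <- setdiff(vars_u, f$vars)
  a <- f$arr
  if (length(extra)) {
    a <- array(a, dim = c(dim(f$arr) %||% integer(0), dims_u[extra]))
    dimnames(a) <- c(dimnames(f$arr), dn_u[extra])
  }
  ord <- match(vars_u, c(f$vars, extra))
  if (length(vars_u)) a <- aperm(a, ord)
  a
}

factor_product <- function(f1, f2) {
  if (!length(f1$vars)) {
    return(list(vars = f2$vars, arr = f2$arr * as.numeric(f1$arr)))
  }
  if (!length(f2$vars)) {
    return(list(vars = f1$vars, arr = f1$arr * as.numeric(f2$arr)))
  }
  vars_u <- union(f1$vars, f2$vars)
  dn_u <- c(dimnames(f1$arr), dimnames(f2$arr))
  dn_u <- dn_u[!duplicated(names(dn_u))][vars_u]
  dims_u <- vapply(dn_u, length, integer(1L))
  a <- expand_to(f1, vars_u, dims_u, dn_u) * expand_to(f2, vars_u, dims_u, dn_u)
  list(vars = vars_u, arr = array(a, dim = dims_u, dimnames = dn_u))
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  keep <- setdiff(seq_along(f$vars), i)
  if (!length(keep)) {
    return(list(vars = character(0), arr = array(sum(f$arr), dim = 1L)))
  }
  a <- aperm(f$arr, c(keep, i))
  m <- matrix(a, nrow = prod(dim(f$arr)[keep]), ncol = dim(f$arr)[i])
  arr <- array(rowSums(m), dim = dim(f$arr)[keep],
               dimnames = dimnames(f$arr)[keep])
  list(vars = f$vars[keep], arr = arr)
}

# eliminate all variables except `keep`, with evidence already reduced out
run_elimination <- function(factors, keep) {
  hidden <- sort(setdiff(unique(unlist(lapply(factors, `[[`, "vars"))), keep))
  while (length(hidden)) {
    # min-degree: variable whose elimination touches the fewest other vars
    deg <- vapply(hidden, function(v) {
      touch <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      length(setdiff(touch, v))
    }, integer(1L))
    v <- hidden[order(deg, hidden)][1L]
    inv <- vapply(factors, function(f) v %in% f$vars, logical(1L))
    prod <- Reduce(factor_product, factors[inv])
    factors <- c(factors[!inv], list(factor_marginalize(prod, v)))
    hidden <- setdiff(hidden, v)
  }
  Reduce(factor_product, factors)
}

#' Exact posterior distribution of one variable
#'
#' Computes `P(query | evidence)` by variable elimination.  Evidence is a
#' named character vector of observed categories; an "Unknown" category is
#' ordinary evidence like any other level, not absence of evidence.
#'
#' @param bn A `tierbn_bn`.
#' @param query Name of the query variable (must not appear in evidence).
#' @param evidence Named character vector, possibly empty.
#' @return Named numeric vector over the query's categories, summing to 1.
#' @export
posterior <- function(bn, query, evidence = character(0)) {
  stopifnot(inherits(bn, "tierbn_bn"))
  if (!query %in% bn$dag$nodes) stop_arg("unknown query variable `%s`", query)
  if (query %in% names(evidence)) stop_arg("query `%s` cannot also be evidence", query)
  bad <- setdiff(names(evidence), bn$dag$nodes)
  if (length(bad)) stop_arg("evidence names not in network: %s",
                            paste(bad, collapse = ", "))
  factors <- lapply(bn$cpts, cpt_factor)
  for (v in names(evidence)) {
    val <- as.character(evidence[[v]])
    if (!val %in% bn$cpts[[v]]$levels)
      stop_arg("evidence value `%s` not a category of `%s`", val, v)
    factors <- lapply(factors, factor_reduce, var = v, value = val)
  }
  res <- run_elimination(factors, keep = query)
  p <- as.numeric(res$arr)
  names(p) <- dimnames(res$arr)[[match(query, res$vars)]]
  z <- sum(p)
  if (z <= 0)
    stop_arg("evidence has zero probability under the network: %s",
             paste(sprintf("%s=%s", names(evidence), evidence), collapse = ", "))
  p <- p / z
  p[node_levels(bn, query)]
}

# joint distribution over a set of variables (no evidence); returns a factor
joint_distribution <- function(bn, vars) {
  if (length(bad <- setdiff(vars, bn$dag$nodes)))
    stop_arg("variables not in network: %s", paste(bad, collapse = ", "))
  factors <- lapply(bn$cpts, cpt_factor)
  res <- run_elimination(factors, keep = vars)
  ord <- match(vars, res$vars)
  if (length(vars) > 1L) res$arr <- aperm(res$arr, ord)
  res$vars <- vars
  res
}
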