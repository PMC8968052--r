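#' Timeline tier map
#'
#' Orders variables by their availability in the clinical workflow
#' (diagnosis, neoadjuvant treatment, surgery, pathology, follow-up).  Arcs
#' may connect variables within one tier or point to any later tier; arcs
#' pointing backward in time are invalid.
#'
#' @param tiers Named integer vector (or named list) mapping each variable to
#'   a tier index `0, 1, 2, ...`.
#' @return Validated named integer vector of class `tierbn_tiers`.
#' @export
tier_map <- function(tiers) {
  tiers <- unlist(tiers)
  if (is.null(names(tiers)) || any(names(tiers) == "") ||
      anyDuplicated(names(tiers)))
    stop_arg("tiers must be uniquely named by variable")
  if (!is.numeric(tiers) || any(tiers != floor(tiers)) || any(tiers < 0))
    stop_arg("tier indices must be non-negative integers")
  structure(stats::setNames(as.integer(tiers), names(tiers)),
            class = "tierbn_tiers")
}

#' All arcs forbidden by a tier map
#'
#' Returns exactly the ordered pairs `(u, v)` with `tier(v) < tier(u)`:
#' within-tier arcs and arcs to any later tier are permitted and therefore
#' absent from the set.
#'
#' @param tiers A `tier_map()`.
#' @param nodes Optional subset of variables to restrict to (all must be
#'   mapped).
#' @return Two-column arc matrix usable as a hill-climbing blacklist.
#' @export
forbidden_arc_set <- function(tiers, nodes = names(tiers)) {
  if (!inherits(tiers, "tierbn_tiers")) tiers <- tier_map(tiers)
  unmapped <- setdiff(nodes, names(tiers))
  if (length(unmapped))
    stop_arg("variables without a tier: %s", paste(unmapped, collapse = ", "))
  grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  bad <- tiers[grid$to] < tiers[grid$from]
  as_arc_matrix(as.matrix(grid[bad, , drop = FALSE]))
}

arcs_respect_tiers <- function(arcs, tiers) {
  arcs <- as_arc_matrix(arcs)
  if (!nrow(arcs)) return(TRUE)
  unmapped <- setdiff(c(arcs), names(tiers))
  if (length(unmapped))
    stop_arg("variables without a tier: %s", paste(unmapped, collapse = ", "))
  all(tiers[arcs[, 2L]] >= tiers[arcs[, 1L]])
}

#' Arcs proposed independently by two experts: keep the common subset
#'
#' Direction-sensitive set intersection (`A -> B` and `B -> A` are different
#' proposals).
#'
#' @param arcs_a,arcs_b Two-column arc matrices or data frames.
#' @return Arc matrix of the shared directed arcs.
#' @export
consensus_intersection <- function(arcs_a, arcs_b) {
  a <- as_arc_matrix(arcs_a)
  b <- as_arc_matrix(arcs_b)
  a[arc_ids(a) %in% arc_ids(b), , drop = FALSE]
}

#' Keep only arcs unanimously approved by two reviewers
#'
#' @param arcs Arc matrix under review.
#' @param approvals Data frame with columns `from`, `to`, `reviewer`,
#'   `approve` (logical); every arc needs exactly one vote from each of two
#'   reviewers.
#' @return Arc matrix of arcs approved by both reviewers.
#' @export
approval_filter <- function(arcs, approvals) {
  arcs <- as_arc_matrix(arcs)
  need <- c("from", "to", "reviewer", "approve")
  if (!all(need %in% names(approvals)))
    stop_arg("approvals needs columns %s", paste(need, collapse = ", "))
  reviewers <- sort(unique(approvals$reviewer))
  if (length(reviewers) != 2L)
    stop_arg("exactly two reviewers expected, got %d", length(reviewers))
  vid <- paste(arc_ids(approvals[, c("from", "to")]), approvals$reviewer)
  if (anyDuplicated(vid)) stop_arg("duplicate votes for the same arc/reviewer")
  keep <- logical(nrow(arcs))
  for (i in seq_len(nrow(arcs))) {
    votes <- approvals$approve[approvals$from == arcs[i, 1L] &
                                 approvals$to == arcs[i, 2L]]
    if (length(votes) != 2L)
      stop_arg("arc %s -> %s is missing a reviewer vote",
               arcs[i, 1L], arcs[i, 2L])
    keep[i] <- all(votes)
  }
  arcs[keep, , drop = FALSE]
}

#' Build the expert DAG from protocol-surviving arcs
#'
#' Retains only variables incident to at least one surviving arc, then
#' verifies acyclicity and tier validity.  Variables of the tier map left
#' isolated are reported in the `excluded` attribute.
#'
#' @param arcs Arc matrix that survived the full elicitation protocol.
#' @param tiers A `tier_map()` covering every arc endpoint.
#' @return A `tierbn_dag` with attribute `excluded` (isolated variables).
#' @export
build_expert_dag <- function(arcs, tiers) {
  if (!inherits(tiers, "tierbn_tiers")) tiers <- tier_map(tiers)
  arcs <- as_arc_matrix(arcs)
  if (!arcs_respect_tiers(arcs, tiers)) {
    bad <- arcs[tiers[arcs[, 2L]] < tiers[arcs[, 1L]], , drop = FALSE]
    stop_arg("backward-tier arc(s): %s",
             paste(sprintf("%s -> %s", bad[, 1L], bad[, 2L]), collapse = ", "))
  }
  nodes <- sort(unique(c(arcs)))
  g <- dag(nodes, arcs) # errors with the cycle listed if cyclic
  attr(g, "excluded") <- setdiff(names(tiers), nodes)
  g
}

#' Summary statistics of an expert structure
#'
#' Counts used to audit a transcribed structure: arcs, non-outcome
#' variables, outcome parents, excluded variables.
#'
#' @param dag A `tierbn_dag` (typically from [build_expert_dag()]).
#' @param outcome Outcome variable name.
#' @return List with `n_arcs`, `n_variables` (non-outcome nodes),
#'   `outcome_parents`, `excluded`.
#' @export
expert_structure_summary <- function(dag, outcome) {
  list(
    n_arcs = nrow(dag$arcs),
    n_variables = length(setdiff(dag$nodes, outcome)),
    outcome_parents = sort(unname(parents_of(dag, outcome))),
    excluded = sort(attr(dag, "excluded") %||% character(0))
  )
}
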