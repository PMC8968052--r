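# Packaged fixtures.
#
# The tier map and expert arc list are SYNTHETIC reconstructions: the
# original structure is published only as figures that are not
# redistributable here.  The reconstruction honours every textual
# constraint: 19 arcs over 10 non-outcome variables, six parents of the
# outcome including CRM and pathological T/N stage, exclusion of age,
# gender, adjuvant chemotherapy and overall treatment time, tier validity
# (no backward-in-time arcs, within-tier arcs allowed), and acyclicity.

tierbn_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tierbn")
  if (path == "") stop_arg("fixture `%s` not found", file)
  path
}

#' Clinical extraction-timeline tier map (synthetic reconstruction)
#'
#' Fourteen predictor variables on tiers 0-3 (diagnosis, neoadjuvant
#' treatment, surgery, pathology) plus one entry per outcome on the final
#' tier.
#'
#' @param outcomes Names to assign to the outcome tier (default the three
#'   recurrence time points).
#' @return A `tier_map()`.
#' @export
rectal_tier_map <- function(outcomes = c("lr2y", "lr3y", "lr5y")) {
  raw <- jsonlite::read_json(tierbn_extdata("tier_map_synthetic.json"))
  tiers <- unlist(raw$tiers)
  out_tier <- tiers[["outcome"]]
  tiers <- tiers[names(tiers) != "outcome"]
  tier_map(c(tiers, stats::setNames(rep(out_tier, length(outcomes)), outcomes)))
}

#' Expert-consensus arc list (synthetic reconstruction)
#'
#' The 19 arcs surviving the two-expert proposal, two-reviewer approval and
#' final validation protocol, with the generic target `"outcome"` replaced
#' by `outcome`.
#'
#' @param outcome Name to substitute for the outcome node.
#' @return Two-column arc matrix.
#' @export
rectal_expert_arcs <- function(outcome = "outcome") {
  arcs <- utils::read.csv(tierbn_extdata("expert_arcs_synthetic.csv"),
                          stringsAsFactors = FALSE)
  arcs[arcs == "outcome"] <- outcome
  as_arc_matrix(arcs)
}

#' Elicitation vote audit trail (synthetic demonstration)
#'
#' A complete vote log (`from`, `to`, `stage`, `actor`, `vote`) whose
#' protocol run reproduces the packaged expert arc list.
#'
#' @return Data frame of votes.
#' @export
rectal_elicitation_votes <- function() {
  v <- utils::read.csv(tierbn_extdata("elicitation_votes_synthetic.csv"),
                       stringsAsFactors = FALSE)
  v$vote <- as.logical(v$vote)
  v
}

#' Run the full elicitation protocol from a vote log
#'
#' Stages, in order: each of two experts proposes arcs; the direction-
#' sensitive intersection is kept; two reviewers vote and only unanimous
#' arcs survive; a final validator approves or rejects each remaining arc.
#' Each stage's output is a subset of its input.
#'
#' @param votes Data frame with columns `from`, `to`, `stage`
#'   (`proposed`/`review`/`final`), `actor`, `vote` (logical).
#' @return List with per-stage arc sets: `proposed_a`, `proposed_b`,
#'   `common`, `reviewed`, `final`.
#' @export
run_elicitation <- function(votes) {
  need <- c("from", "to", "stage", "actor", "vote")
  if (!all(need %in% names(votes)))
    stop_arg("votes needs columns %s", paste(need, collapse = ", "))
  prop <- votes[votes$stage == "proposed" & votes$vote, , drop = FALSE]
  experts <- sort(unique(prop$actor))
  if (length(experts) != 2L) stop_arg("exactly two proposing experts expected")
  a <- as_arc_matrix(prop[prop$actor == experts[1L], c("from", "to")])
  b <- as_arc_matrix(prop[prop$actor == experts[2L], c("from", "to")])
  common <- consensus_intersection(a, b)
  rev <- votes[votes$stage == "review", , drop = FALSE]
  reviewed <- approval_filter(common, data.frame(
    from = rev$from, to = rev$to, reviewer = rev$actor, approve = rev$vote,
    stringsAsFactors = FALSE))
  fin <- votes[votes$stage == "final", , drop = FALSE]
  fid <- arc_ids(fin[, c("from", "to")])
  rid <- arc_ids(reviewed)
  if (!all(rid %in% fid))
    stop_arg("final validation vote missing for %d arc(s)", sum(!rid %in% fid))
  approved <- fid[fin$vote]
  final <- reviewed[rid %in% approved, , drop = FALSE]
  list(proposed_a = a, proposed_b = b, common = common,
       reviewed = reviewed, final = final)
}
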