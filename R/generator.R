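# Synthetic cohort generator.
#
# A generator spec declares, per variable: name, tier, category labels and
# either an explicit CPT or a marginal target plus parent tilt strengths.
# build_ground_truth() turns the spec into a full Bayesian network whose
# arcs respect the tier map and whose node marginals match the targets:
# child CPTs start from a log-linear tilt of the target marginal (ordinal
# scores in [-1, 1] for both parent and child levels) and are then scaled
# iteratively against the exact parent joint (computed by the package's own
# variable elimination) until the implied marginal matches the target.

#' Validate and normalise a generator spec
#' @keywords internal
validate_generator_spec <- function(spec) {
  if (is.null(spec$variables) || !length(spec$variables))
    stop_arg("generator spec declares no variables")
  nm <- vapply(spec$variables, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop_arg("duplicate variable names in spec")
  tiers <- vapply(spec$variables, function(v) as.integer(v$tier), integer(1L))
  names(tiers) <- nm
  outcomes <- spec$outcomes %||% character(0)
  if (length(bad <- setdiff(outcomes, nm)))
    stop_arg("unknown outcome variable(s): %s", paste(bad, collapse = ", "))
  for (v in spec$variables) {
    if (length(v$levels) < 2L)
      stop_arg("variable `%s` needs >= 2 categories", v$name)
    for (p in v$parents %||% character(0)) {
      if (!p %in% nm) stop_arg("parent `%s` of `%s` is not declared", p, v$name)
      if (tiers[[p]] > tiers[[v$name]])
        stop_arg("tier constraint violation: arc %s -> %s points backward in time",
                 p, v$name)
    }
    if (v$name %in% outcomes) {
      tgt <- v$target
      if (is.null(tgt) || any(tgt <= 0) || any(tgt >= 1))
        stop_arg("degenerate spec: outcome `%s` needs prevalence strictly inside (0,1)",
                 v$name)
    }
  }
  miss <- spec$missingness %||% numeric(0)
  if (length(bad <- setdiff(names(miss), nm)))
    stop_arg("missingness rates for undeclared variable(s): %s",
             paste(bad, collapse = ", "))
  if (length(miss) && (any(miss < 0) || any(miss > 1)))
    stop_arg("missingness rates must lie in [0, 1]")
  invisible(list(names = nm, tiers = tiers))
}

ordinal_score <- function(r) if (r == 1L) 0 else 2 * (seq_len(r) - 1) / (r - 1) - 1

# calibrate CPT rows so that sum_cfg q(cfg) p(x | cfg) = target
calibrate_cpt_rows <- function(p0, q, target, max_iter = 300L, tol = 1e-10) {
  p <- p0
  for (i in seq_len(max_iter)) {
    m <- as.numeric(crossprod(q, p))
    if (max(abs(m - target)) < tol) break
    p <- sweep(p, 2L, target / m, `*`)
    p <- p / rowSums(p)
  }
  p
}

#' Build a ground-truth network from a generator spec
#'
#' @param spec Generator spec (see [clinical_generator_spec()] for the
#'   documented schema).
#' @param seed Integer seed recorded on the result; construction itself is
#'   deterministic.
#' @return Object of class `tierbn_ground_truth`: `network` (`tierbn_bn`),
#'   `tiers`, `missingness`, `outcomes`, `cohorts`, `seed_used`.
#' @export
build_ground_truth <- function(spec, seed = 1L) {
  info <- validate_generator_spec(spec)
  vars <- spec$variables
  # true topological order over the declared parent arcs (tier validity is
  # already checked, but same-tier parents may be declared in any order)
  spec_arcs <- do.call(rbind, lapply(vars, function(v) {
    if (length(v$parents %||% character(0)))
      cbind(v$parents, v$name) else NULL
  }))
  topo <- topo_order(info$names, spec_arcs)
  if (is.null(topo)) stop_arg("generator spec arcs contain a directed cycle")
  ord <- match(topo, info$names)
  cpts <- list()
  done_arcs <- NULL
  done_nodes <- character(0)
  for (i in ord) {
    v <- vars[[i]]
    r <- length(v$levels)
    pars <- v$parents %||% character(0)
    plev <- stats::setNames(lapply(pars, function(p) cpts[[p]]$levels), pars)
    if (!is.null(v$cpt)) {
      ct <- cpt(v$name, v$levels, pars, plev, v$cpt)
    } else if (!length(pars)) {
      tgt <- v$target / sum(v$target)
      ct <- cpt(v$name, v$levels, prob = matrix(tgt, 1L))
    } else {
      tgt <- v$target / sum(v$target)
      cards <- vapply(plev, length, integer(1L))
      q_n <- prod(cards)
      betas <- v$betas %||% stats::setNames(rep(0.8, length(pars)), pars)
      cfg <- as.matrix(expand.grid(lapply(cards, seq_len)))
      tilt <- rep(0, q_n)
      for (j in seq_along(pars))
        tilt <- tilt + betas[[pars[j]]] * ordinal_score(cards[j])[cfg[, j]]
      t_x <- ordinal_score(r)
      p0 <- exp(outer(tilt, t_x)) * rep(tgt, each = q_n)
      p0 <- p0 / rowSums(p0)
      # exact parent joint under the already-built ancestor network
      sub_dag <- dag(done_nodes, done_arcs)
      sub_bn <- bayesian_network(sub_dag, cpts[done_nodes])
      jq <- joint_distribution(sub_bn, pars)
      ct <- cpt(v$name, v$levels, pars, plev,
                calibrate_cpt_rows(p0, as.numeric(jq$arr), tgt))
    }
    cpts[[v$name]] <- ct
    done_nodes <- c(done_nodes, v$name)
    if (length(pars))
      done_arcs <- rbind(done_arcs, cbind(from = pars, to = v$name))
  }
  g <- dag(done_nodes, done_arcs)
  tiers <- tier_map(info$tiers[done_nodes])
  structure(list(network = bayesian_network(g, cpts),
                 tiers = tiers,
                 missingness = spec$missingness %||% numeric(0),
                 outcomes = spec$outcomes %||% character(0),
                 cohorts = spec$cohorts,
                 seed_used = as.integer(seed)),
            class = "tierbn_ground_truth")
}

#' @export
print.tierbn_ground_truth <- function(x, ...) {
  cat(sprintf("<tierbn_ground_truth> %d nodes, %d arcs, outcomes: %s\n",
              length(x$network$dag$nodes), nrow(x$network$dag$arcs),
              paste(x$outcomes, collapse = ", ")))
  invisible(x)
}

#' Sample a complete synthetic cohort
#'
#' Ancestral sampling from the ground-truth network plus a `cohort` label
#' column emulating the multi-trial provenance of the study data (labels
#' carry no distributional information).
#'
#' @param gt A `tierbn_ground_truth`.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; sampling and cohort labelling use distinct
#'   derived streams (`"sample"`, `"cohort"`).
#' @return Data frame with one factor column per variable plus `cohort`.
#' @export
sample_cohort <- function(gt, n, seed = 1L) {
  stopifnot(inherits(gt, "tierbn_ground_truth"))
  assert_scalar_int(n, "n", min = 1)
  tab <- ancestral_sample(gt$network, n, derive_seed(seed, "sample"))
  sizes <- gt$cohorts %||% stats::setNames(n, "trial01")
  prop <- sizes / sum(sizes)
  cnt <- floor(prop * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(prop * n - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  lab <- rep(names(sizes), cnt)
  tab$cohort <- factor(with_seed(derive_seed(seed, "cohort"), sample(lab)),
                       levels = names(sizes))
  tab
}

#' Mask values completely at random, per variable
#'
#' Each listed variable has its values replaced by `NA` independently with
#' the given rate (missing completely at random); outcome columns may be
#' masked too, emulating loss to follow-up.
#'
#' @param cohort Data frame.
#' @param rates Named vector of fractions in `[0, 1]`.
#' @param seed Integer seed (one derived stream per variable).
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, rates, seed = 1L) {
  if (length(bad <- setdiff(names(rates), names(cohort))))
    stop_arg("rates name variables absent from the cohort: %s",
             paste(bad, collapse = ", "))
  if (any(rates < 0) || any(rates > 1))
    stop_arg("missingness rates must lie in [0, 1]")
  for (v in names(rates)) {
    if (rates[[v]] == 0) next
    mask <- with_seed(derive_seed(seed, paste0("miss:", v)),
                      stats::runif(nrow(cohort)) < rates[[v]])
    cohort[[v]][mask] <- NA
  }
  cohort
}

#' Write / read a cohort CSV (missing marker = empty field)
#'
#' @param cohort Data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a data
#'   frame of factors (levels optionally fixed by a generator spec).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @param spec Optional generator spec fixing factor levels.
#' @rdname write_cohort
#' @export
read_cohort <- function(path, spec = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  if (!is.null(spec)) {
    for (v in spec$variables) {
      if (!is.null(tab[[v$name]]))
        tab[[v$name]] <- factor(tab[[v$name]], levels = v$levels)
    }
  }
  for (j in names(tab)) if (is.character(tab[[j]])) tab[[j]] <- factor(tab[[j]])
  tab
}
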