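#' Per-patient recurrence probabilities from a fitted network
#'
#' Exact posterior probability of the positive outcome category for every
#' row, given that row's values as evidence ("Unknown" counts as evidence
#' like any other category).  When every non-outcome network variable is
#' observed — the usual case after Unknown encoding — the posterior reduces
#' to the outcome's Markov blanket and is computed vectorised; otherwise
#' the row falls back to full variable elimination.  Both routes are exact.
#'
#' @param bn Fitted `tierbn_bn` containing `outcome`.
#' @param table Data frame covering the network's non-outcome variables.
#' @param outcome Outcome variable name.
#' @param positive Positive category (default `"True"`).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_cohort <- function(bn, table, outcome, positive = "True") {
  stopifnot(inherits(bn, "tierbn_bn"))
  if (!outcome %in% bn$dag$nodes) stop_arg("outcome `%s` not in network", outcome)
  lev <- node_levels(bn, outcome)
  if (!positive %in% lev)
    stop_arg("positive category `%s` not a level of `%s`", positive, outcome)
  vars <- setdiff(bn$dag$nodes, outcome)
  missing_cols <- setdiff(vars, names(table))
  complete <- if (length(missing_cols)) rep(FALSE, nrow(table)) else
    !Reduce(`|`, lapply(table[vars], is.na), rep(FALSE, nrow(table)))
  probs <- numeric(nrow(table))
  if (any(complete)) {
    levels_list <- lapply(bn$cpts, `[[`, "levels")
    sub <- table[complete, vars, drop = FALSE]
    for (v in vars) {
      x <- as.character(sub[[v]])
      bad <- which(!x %in% levels_list[[v]])
      if (length(bad))
        stop_arg("row %d has unseen category `%s` for variable `%s`",
                 which(complete)[bad[1L]], x[bad[1L]], v)
    }
    codes <- encode_data(sub, vars, levels_list[vars])
    fam <- c(outcome, unname(children_of(bn$dag, outcome)))
    logp <- matrix(0, nrow(sub), length(lev))
    for (li in seq_along(lev)) {
      full <- cbind(codes, matrix(li, nrow(sub), 1L,
                                  dimnames = list(NULL, outcome)))
      for (v in fam) {
        ct <- bn$cpts[[v]]
        cards <- vapply(ct$parents, function(p) length(levels_list[[p]]),
                        integer(1L))
        cfg <- config_index(full[, ct$parents, drop = FALSE], cards)
        val <- if (v == outcome) rep(li, nrow(sub)) else full[, v]
        logp[, li] <- logp[, li] + log(ct$prob[cbind(cfg, val)])
      }
    }
    mx <- apply(logp, 1L, max)
    w <- exp(logp - mx)
    tot <- rowSums(w)
    if (any(!is.finite(tot) | tot <= 0))
      stop_arg("row %d has zero probability under the network",
               which(complete)[which(!is.finite(tot) | tot <= 0)[1L]])
    probs[complete] <- w[, match(positive, lev)] / tot
  }
  for (i in which(!complete)) {
    obs <- vars[vars %in% names(table)]
    vals <- vapply(obs, function(v) as.character(table[[v]][i]), character(1L))
    ev <- vals[!is.na(vals)]
    probs[i] <- posterior(bn, outcome, ev)[[positive]]
  }
  probs
}

check_binary_labels <- function(labels) {
  y <- as.integer(factor(as.character(labels))) - 1L
  if (is.logical(labels)) y <- as.integer(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) y <- as.integer(labels)
  if (is.factor(labels)) y <- as.integer(labels == levels(labels)[nlevels(labels)])
  if (is.character(labels)) {
    u <- sort(unique(labels))
    y <- as.integer(labels == u[length(u)])
  }
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop_arg("labels must be binary with no missing values")
  y
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Concordant pairs plus half the ties over all positive-negative pairs,
#' computed via mid-ranks.
#'
#' @param probs Numeric scores.
#' @param labels Binary labels (0/1, logical, or two-level factor where the
#'   last level is the event).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probs, labels) {
  y <- check_binary_labels(labels)
  if (length(y) != length(probs)) stop_arg("probs and labels differ in length")
  m <- sum(y == 1L); n <- sum(y == 0L)
  if (m == 0L || n == 0L) stop_arg("both classes must be present")
  r <- rank(probs)
  (sum(r[y == 1L]) - m * (m + 1) / 2) / (m * n)
}

# DeLong placements: list(auc, v10 (events), v01 (non-events))
delong_placements <- function(probs, y) {
  m <- sum(y == 1L); n <- sum(y == 0L)
  r_all <- rank(probs)
  r_pos <- rank(probs[y == 1L])
  r_neg <- rank(probs[y == 0L])
  v10 <- (r_all[y == 1L] - r_pos) / n
  v01 <- 1 - (r_all[y == 0L] - r_neg) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong confidence interval for the AUC
#'
#' Variance from the DeLong placement components; interval clipped to
#' `[0, 1]`.  A nonparametric bootstrap percentile interval is available
#' behind `method = "bootstrap"`.
#'
#' @param probs Numeric scores.
#' @param labels Binary labels (see [roc_auc()]).
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param boot,seed Bootstrap replicates and seed (bootstrap method only).
#' @return Named vector `c(low, high)`.
#' @export
auc_confidence_interval <- function(probs, labels, level = 0.95,
                                    method = c("delong", "bootstrap"),
                                    boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  y <- check_binary_labels(labels)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop_arg("both classes need >= 2 members")
  if (method == "bootstrap") {
    auc_b <- with_seed(derive_seed(seed, "auc-boot"), vapply(seq_len(boot),
      function(b) {
        i <- sample.int(length(y), replace = TRUE)
        if (length(unique(y[i])) < 2L) return(NA_real_)
        roc_auc(probs[i], y[i])
      }, numeric(1L)))
    ci <- stats::quantile(auc_b, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    return(c(low = max(0, ci[1L]), high = min(1, ci[2L])))
  }
  pl <- delong_placements(probs, y)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = max(0, pl$auc - z * sqrt(v)), high = min(1, pl$auc + z * sqrt(v)))
}

#' Paired DeLong test for the difference of two correlated AUCs
#'
#' Both probability vectors must score the same rows against the same
#' labels.  Two-sided p-value; exactly equal predictions give p = 1.
#'
#' @param probs_a,probs_b Numeric score vectors of equal length.
#' @param labels Binary labels (see [roc_auc()]).
#' @return List with `p_value`, `auc_a`, `auc_b`, `z`.
#' @export
compare_auc <- function(probs_a, probs_b, labels) {
  if (length(probs_a) != length(probs_b))
    stop_arg("probability vectors differ in length")
  y <- check_binary_labels(labels)
  if (length(y) != length(probs_a)) stop_arg("labels differ in length")
  pa <- delong_placements(probs_a, y)
  pb <- delong_placements(probs_b, y)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  v <- stats::var(d10) / pa$m + stats::var(d01) / pa$n
  diff <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (abs(diff) < .Machine$double.eps^0.5) 0 else Inf * sign(diff)
  } else z <- diff / sqrt(v)
  list(p_value = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z)),
       auc_a = pa$auc, auc_b = pb$auc, z = z)
}

#' Accuracy, sensitivity, specificity at a probability cut
#'
#' @param probs Numeric probabilities.
#' @param labels Binary labels (see [roc_auc()]).
#' @param threshold Classification cut (default 0.5); predictions are
#'   positive when `probs >= threshold`.
#' @return Named vector `c(accuracy, sensitivity, specificity)`; an absent
#'   class yields `NA` for its rate with a warning.
#' @export
confusion_metrics <- function(probs, labels, threshold = 0.5) {
  y <- check_binary_labels(labels)
  pred <- as.integer(probs >= threshold)
  acc <- mean(pred == y)
  sens <- if (any(y == 1L)) mean(pred[y == 1L] == 1L) else NA_real_
  spec <- if (any(y == 0L)) mean(pred[y == 0L] == 0L) else NA_real_
  if (is.na(sens) || is.na(spec))
    warning("single-class labels: sensitivity or specificity undefined",
            call. = FALSE)
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Calibration curve with bootstrap intervals
#'
#' Predictions are grouped into (up to) `bins` equal-count bins; each bin
#' reports the mean predicted probability, the observed event frequency, a
#' bootstrap percentile confidence interval for the observed frequency, and
#' a bias-corrected estimate `2 * apparent - mean(bootstrap)` (apparent
#' minus bootstrap optimism).
#'
#' @param probs Numeric probabilities.
#' @param labels Binary labels (see [roc_auc()]).
#' @param bins Requested bin count (default 10; ties can merge bins).
#' @param boot Bootstrap replicates (default 200; 0 disables intervals).
#' @param seed Integer seed.
#' @param level Confidence level for the interval (default 0.95).
#' @return Object of class `tierbn_calibration`: data frame `bins` plus
#'   settings.
#' @export
calibration <- function(probs, labels, bins = 10L, boot = 200L, seed = 1L,
                        level = 0.95) {
  assert_scalar_int(bins, "bins", min = 2)
  assert_scalar_int(boot, "boot", min = 0)
  y <- check_binary_labels(labels)
  if (length(y) < bins) stop_arg("need at least `bins` observations")
  breaks <- unique(stats::quantile(probs, seq(0, 1, length.out = bins + 1L),
                                   names = FALSE))
  assign_bin <- function(p) {
    if (length(breaks) <= 2L) rep(1L, length(p)) else
      as.integer(cut(p, breaks, include.lowest = TRUE))
  }
  g <- assign_bin(probs)
  ids <- sort(unique(g))
  apparent <- t(vapply(ids, function(b) {
    c(mean_pred = mean(probs[g == b]), observed = mean(y[g == b]),
      n = sum(g == b))
  }, numeric(3L)))
  lo <- hi <- bc <- rep(NA_real_, length(ids))
  if (boot > 0L) {
    obs_b <- with_seed(derive_seed(seed, "calibration"), {
      vapply(seq_len(boot), function(b) {
        i <- sample.int(length(y), replace = TRUE)
        gb <- assign_bin(probs[i])
        vapply(ids, function(k)
          if (any(gb == k)) mean(y[i][gb == k]) else NA_real_, numeric(1L))
      }, numeric(length(ids)))
    })
    obs_b <- matrix(obs_b, nrow = length(ids))
    a <- (1 - level) / 2
    lo <- apply(obs_b, 1L, stats::quantile, probs = a, na.rm = TRUE)
    hi <- apply(obs_b, 1L, stats::quantile, probs = 1 - a, na.rm = TRUE)
    bc <- 2 * apparent[, "observed"] - rowMeans(obs_b, na.rm = TRUE)
  }
  structure(list(
    bins = data.frame(bin = ids,
                      mean_pred = apparent[, "mean_pred"],
                      observed = apparent[, "observed"],
                      n = apparent[, "n"],
                      ci_low = pmin(pmax(lo, 0), 1),
                      ci_high = pmin(pmax(hi, 0), 1),
                      bias_corrected = bc),
    requested_bins = bins, boot = boot, level = level),
    class = "tierbn_calibration")
}

#' @export
print.tierbn_calibration <- function(x, ...) {
  cat(sprintf("<calibration> %d bin(s), %d bootstrap replicates\n",
              nrow(x$bins), x$boot))
  print(x$bins, row.names = FALSE)
  invisible(x)
}
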