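#' Dichotomize the circumferential resection margin
#'
#' Positive when the tumor lies within 1 mm of the circumferential margin
#' (boundary included), negative beyond 1 mm.
#'
#' @param margin_mm Numeric vector of non-negative distances in millimetres;
#'   `NA` stays `NA`.
#' @return Factor with levels `Negative`, `Positive`.
#' @examples
#' dichotomize_crm(c(0.5, 1, 2))
#' @export
dichotomize_crm <- function(margin_mm) {
  if (any(margin_mm < 0, na.rm = TRUE))
    stop_arg("margin distances must be non-negative")
  factor(ifelse(margin_mm <= 1, "Positive", "Negative"),
         levels = c("Negative", "Positive"))
}

#' Categorization rules for continuous variables
#'
#' Each rule is a strictly increasing cut-point vector plus `k + 1` unique
#' bin labels; bins are `(-Inf, c1], (c1, c2], ..., (ck, Inf)` (or
#' left-closed with `right = FALSE`), so out-of-range values land in the
#' terminal bins.
#'
#' @param ... Named rules, each `list(cuts =, labels =, right = TRUE)`.
#' @return Object of class `tierbn_rules`.
#' @export
categorization_rules <- function(...) {
  rules <- list(...)
  if (length(rules) == 1L && is.null(names(rules)) && is.list(rules[[1]]) &&
      !is.null(names(rules[[1]])) && is.list(rules[[1]][[1]]))
    rules <- rules[[1]]
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (is.unsorted(r$cuts, strictly = TRUE))
      stop_arg("cut points for `%s` must be strictly increasing", nm)
    if (length(r$labels) != length(r$cuts) + 1L || anyDuplicated(r$labels))
      stop_arg("`%s` needs %d unique labels", nm, length(r$cuts) + 1L)
    rules[[nm]]$right <- r$right %||% TRUE
  }
  structure(rules, class = "tierbn_rules")
}

#' Default categorization rules
#'
#' Literature-style defaults for the cohort's continuous variables (age
#' <50 / 50-65 / >65 years; dose <=45 / >45 Gy; distance to anal verge
#' <=5 / >5 cm; overall treatment time <=38 / >38 days; radiotherapy-surgery
#' interval <=1 / >1 week).  All overridable; the source study did not print
#' its cut points.
#'
#' @return A `categorization_rules()` object.
#' @export
default_categorization_rules <- function() {
  categorization_rules(
    age = list(cuts = c(50, 65), labels = c("<50", "50-65", ">65"),
               right = FALSE),
    rt_dose = list(cuts = 45, labels = c("<=45Gy", ">45Gy")),
    tumor_distance = list(cuts = 5, labels = c("<=5cm", ">5cm")),
    overall_treatment_time = list(cuts = 38, labels = c("<=38d", ">38d")),
    interval_rt_surgery = list(cuts = 1, labels = c("<=1wk", ">1wk"))
  )
}

#' Categorize continuous columns of a cohort
#'
#' Numeric columns with a rule are binned; categorical columns pass through
#' unchanged (so the operation is idempotent); missing values stay missing.
#'
#' @param cohort Data frame.
#' @param rules A `categorization_rules()` covering every numeric column.
#' @return The cohort with all columns categorical.
#' @export
categorize <- function(cohort, rules = default_categorization_rules()) {
  num <- names(cohort)[vapply(cohort, is.numeric, logical(1L))]
  if (length(bad <- setdiff(num, names(rules))))
    stop_arg("no categorization rule for numeric column(s): %s",
             paste(bad, collapse = ", "))
  for (v in num) {
    r <- rules[[v]]
    cohort[[v]] <- cut(cohort[[v]], breaks = c(-Inf, r$cuts, Inf),
                       labels = r$labels, right = r$right)
  }
  cohort
}

#' Encode missingness as a category and drop outcome-missing rows
#'
#' Predictor missing markers become the first-class category `"Unknown"`
#' (the level is added to every predictor column so train/validation level
#' sets stay aligned); patients with a missing value for `outcome` are
#' excluded and the dropped count reported.
#'
#' @param cohort Data frame of factors.
#' @param outcome Outcome column to filter on.
#' @param predictors Columns to Unknown-encode (default: everything except
#'   the outcome columns in `all_outcomes` and the `cohort` id).
#' @param all_outcomes Columns treated as outcomes (never Unknown-encoded).
#' @return Filtered, encoded cohort; dropped row count in attribute
#'   `dropped`.
#' @export
encode_missing_and_filter <- function(cohort, outcome,
                                      all_outcomes = outcome,
                                      predictors = NULL) {
  if (is.null(cohort[[outcome]]))
    stop_arg("outcome column `%s` not present", outcome)
  predictors <- predictors %||%
    setdiff(names(cohort), c(all_outcomes, "cohort"))
  for (v in predictors) {
    x <- as.character(cohort[[v]])
    lev <- if (is.factor(cohort[[v]])) levels(cohort[[v]]) else sort(unique(x))
    x[is.na(x)] <- "Unknown"
    cohort[[v]] <- factor(x, levels = c(setdiff(lev, "Unknown"), "Unknown"))
  }
  keep <- !is.na(cohort[[outcome]])
  dropped <- sum(!keep)
  if (dropped) message(sprintf("excluded %d patient(s) with missing %s status",
                               dropped, outcome))
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Stratified train/validation split
#'
#' Within every stratum (trial cohort by default), `round(test_fraction *
#' n)` rows are drawn into the validation set; strata with fewer than two
#' rows go entirely to training with a warning.  The two parts partition
#' the input.
#'
#' @param cohort Data frame.
#' @param test_fraction Fraction held out (default 0.2).
#' @param stratify_by Stratum column (default `"cohort"`).
#' @param seed Integer seed.
#' @return List with elements `train` and `validation`.
#' @export
stratified_split <- function(cohort, test_fraction = 0.2,
                             stratify_by = "cohort", seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop_arg("test_fraction must lie strictly between 0 and 1")
  strata <- if (!is.null(cohort[[stratify_by]]))
    as.character(cohort[[stratify_by]]) else rep("all", nrow(cohort))
  val_idx <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (s in sort(unique(strata))) {
      idx <- which(strata == s)
      if (length(idx) < 2L) {
        warning(sprintf("stratum `%s` has < 2 rows; all assigned to training", s),
                call. = FALSE)
        next
      }
      k <- round(test_fraction * length(idx))
      if (k > 0L) val_idx <- c(val_idx, sample(idx, k))
    }
  })
  val_idx <- sort(val_idx)
  list(train = cohort[setdiff(seq_len(nrow(cohort)), val_idx), , drop = FALSE],
       validation = cohort[val_idx, , drop = FALSE])
}

#' Nominal-feature SMOTE: balance classes on all-categorical records
#'
#' Synthetic minority rows are appended until both outcome classes are
#' equally frequent.  For each synthetic row a minority seed row is chosen;
#' its `k` nearest minority neighbours under Hamming distance (over the
#' predictor columns) are found; each feature takes the majority vote among
#' the seed row and its neighbours, ties resolved by the seed row's value
#' (the standard nominal-feature adaptation of SMOTE).  Original rows are
#' never modified and no unseen category can be created.
#'
#' @param train Data frame of factors (training partition only).
#' @param outcome Binary outcome column.
#' @param k Number of neighbours (`1 <= k <= minority count - 1`).
#' @param seed Integer seed.
#' @return The balanced data frame; synthetic rows flagged in attribute
#'   `synthetic` (logical vector over output rows).
#' @export
smote_categorical <- function(train, outcome, k = 5L, seed = 1L) {
  if (is.null(train[[outcome]])) stop_arg("outcome column `%s` not present", outcome)
  y <- droplevels(factor(train[[outcome]]))
  if (nlevels(y) != 2L)
    stop_arg("SMOTE needs exactly two outcome classes present, found %d",
             nlevels(y))
  assert_scalar_int(k, "k", min = 1)
  cnt <- table(y)
  if (cnt[1L] == cnt[2L]) {
    attr(train, "synthetic") <- rep(FALSE, nrow(train))
    return(train)
  }
  minority <- names(cnt)[which.min(cnt)]
  n_min <- min(cnt)
  if (k > n_min - 1L)
    stop_arg("k = %d too large for %d minority rows (need k <= minority - 1)",
             k, n_min)
  n_syn <- max(cnt) - n_min
  feats <- setdiff(names(train), c(outcome, "cohort"))
  min_rows <- which(as.character(train[[outcome]]) == minority)
  codes <- vapply(feats, function(v) as.integer(factor(train[[v]]))[min_rows],
                  integer(length(min_rows)))
  codes <- matrix(codes, nrow = length(min_rows))
  # pairwise Hamming distances among minority rows
  d <- matrix(0L, n_min, n_min)
  for (j in seq_len(ncol(codes)))
    d <- d + outer(codes[, j], codes[, j], `!=`)
  # how many synthetic copies per seed row
  base <- n_syn %/% n_min
  reps <- rep(base, n_min)
  extra <- n_syn - base * n_min
  if (extra > 0L)
    reps[with_seed(derive_seed(seed, "smote"), sample.int(n_min, extra))] <-
      base + 1L
  syn_list <- vector("list", n_min)
  for (i in which(reps > 0L)) {
    ord <- order(d[i, ], seq_len(n_min)) # deterministic tie-break by index
    nb <- setdiff(ord, i)[seq_len(k)]
    group <- min_rows[c(i, nb)]
    row <- train[min_rows[i], , drop = FALSE]
    for (v in feats) {
      vals <- as.character(train[[v]][group])
      tab <- sort(table(vals), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      seed_val <- as.character(train[[v]][min_rows[i]])
      row[[v]] <- factor(if (seed_val %in% top) seed_val else top[1L],
                         levels = levels(train[[v]]))
    }
    syn_list[[i]] <- row[rep(1L, reps[i]), , drop = FALSE]
  }
  syn <- do.call(rbind, syn_list[!vapply(syn_list, is.null, logical(1L))])
  out <- rbind(train, syn)
  rownames(out) <- NULL
  attr(out, "synthetic") <- c(rep(FALSE, nrow(train)), rep(TRUE, nrow(syn)))
  out
}
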