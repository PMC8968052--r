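#' Experiment configuration
#'
#' One object drives the full comparison: data source (a cohort data frame
#' or CSV path, or `NULL` to simulate from `spec`), tier map, expert arc
#' list (with the generic `"outcome"` endpoint), categorization rules,
#' SMOTE/search/evaluation settings, and seeds.
#'
#' @param data Cohort data frame, CSV path, or `NULL` (simulate).
#' @param spec Generator spec for simulation (default
#'   [clinical_generator_spec()]).
#' @param n Simulated cohort size (default 6754).
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param outcomes Outcome columns (default from `spec`).
#' @param tiers Tier map; default [rectal_tier_map()] over `outcomes`.
#' @param expert_arcs Expert arc matrix with target `"outcome"` (default
#'   [rectal_expert_arcs()]).
#' @param rules Categorization rules for numeric columns.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param smote Logical: rebalance training data per time point.
#' @param smote_k SMOTE neighbour count (default 5).
#' @param alpha Pseudocount for prediction fits (default 1, Laplace).
#' @param restarts,perturb Hill-climbing restart settings.
#' @param threshold Classification threshold (default 0.5).
#' @param bins,boot Calibration bins and bootstrap replicates.
#' @param train_metrics_on `"original"` (default) or `"smote"`: rows used
#'   for training-set metrics.
#' @param outdir Output directory for report files, or `NULL`.
#' @return Config list of class `tierbn_config`.
#' @export
experiment_config <- function(data = NULL, spec = clinical_generator_spec(),
                              n = 6754L, seed = 1L, outcomes = NULL,
                              tiers = NULL, expert_arcs = rectal_expert_arcs(),
                              rules = default_categorization_rules(),
                              test_fraction = 0.2, smote = TRUE, smote_k = 5L,
                              alpha = 1, restarts = 5L, perturb = 5L,
                              threshold = 0.5, bins = 10L, boot = 200L,
                              train_metrics_on = c("original", "smote"),
                              outdir = NULL) {
  outcomes <- outcomes %||% spec$outcomes
  tiers <- tiers %||% rectal_tier_map(outcomes)
  structure(list(data = data, spec = spec, n = n, seed = seed,
                 outcomes = outcomes, tiers = tiers,
                 expert_arcs = expert_arcs, rules = rules,
                 test_fraction = test_fraction, smote = smote,
                 smote_k = smote_k, alpha = alpha, restarts = restarts,
                 perturb = perturb, threshold = threshold, bins = bins,
                 boot = boot,
                 train_metrics_on = match.arg(train_metrics_on),
                 outdir = outdir),
            class = "tierbn_config")
}

resolve_cohort <- function(config) {
  if (is.null(config$data)) {
    gt <- build_ground_truth(config$spec, config$seed)
    cohort <- sample_cohort(gt, config$n, config$seed)
    cohort <- inject_missingness(cohort, gt$missingness, config$seed)
  } else if (is.character(config$data)) {
    cohort <- read_cohort(config$data, config$spec)
  } else cohort <- config$data
  categorize(cohort, config$rules)
}

eval_block <- function(bn, data, outcome, threshold, bins, boot, seed) {
  probs <- predict_cohort(bn, data, outcome)
  labels <- data[[outcome]]
  cm <- confusion_metrics(probs, labels, threshold)
  ci <- auc_confidence_interval(probs, labels)
  list(probs = probs,
       metrics = c(n = length(probs), accuracy = unname(cm["accuracy"]),
                   auc = roc_auc(probs, labels),
                   auc_ci_low = unname(ci["low"]),
                   auc_ci_high = unname(ci["high"]),
                   sensitivity = unname(cm["sensitivity"]),
                   specificity = unname(cm["specificity"]),
                   threshold = threshold),
       calibration = calibration(probs, labels, bins = bins, boot = boot,
                                 seed = seed))
}

#' Run the full expert-versus-algorithm comparison
#'
#' For each outcome time point: split the cohort (once, stratified per
#' trial), Unknown-encode predictors and drop outcome-missing rows, SMOTE
#' the training partition, fit the expert structure and learn a
#' tier-constrained hill-climbing structure, evaluate both on training and
#' validation rows (AUC with DeLong CI, accuracy/sensitivity/specificity,
#' calibration, paired DeLong AUC comparison) and diff the structures.
#' Deterministic for a fixed config.
#'
#' @param config An [experiment_config()].
#' @return Report bundle (class `tierbn_bundle`): `metrics` data frame,
#'   per-time-point details, run `log`.  Files are written when
#'   `config$outdir` is set.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "tierbn_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  cohort <- resolve_cohort(config)
  say("cohort: %d rows, %d columns", nrow(cohort), ncol(cohort))
  parts <- stratified_split(cohort, config$test_fraction, "cohort", config$seed)
  say("split: %d training / %d validation rows",
      nrow(parts$train), nrow(parts$validation))
  predictors <- setdiff(names(cohort), c(config$outcomes, "cohort"))
  metrics <- list()
  details <- list()
  for (tp in config$outcomes) {
    seed_tp <- derive_seed(config$seed, paste0("tp:", tp))
    tr <- encode_missing_and_filter(parts$train, tp,
                                    all_outcomes = config$outcomes)
    va <- encode_missing_and_filter(parts$validation, tp,
                                    all_outcomes = config$outcomes)
    say("[%s] outcome-complete rows: %d train (%d dropped), %d validation (%d dropped)",
        tp, nrow(tr), attr(tr, "dropped"), nrow(va), attr(va, "dropped"))
    model_cols <- c(predictors, tp)
    tr_model <- droplevels_outcome(tr[model_cols], tp)
    va_model <- droplevels_outcome(va[model_cols], tp)
    fit_data <- if (config$smote) {
      b <- smote_categorical(tr_model, tp, k = config$smote_k, seed = seed_tp)
      say("[%s] SMOTE: %d -> %d rows", tp, nrow(tr_model), nrow(b))
      b
    } else tr_model
    expert_dag <- build_expert_dag(sub_outcome(config$expert_arcs, tp),
                                   config$tiers)
    expert_bn <- fit_parameters(expert_dag, fit_data[expert_dag$nodes],
                                alpha = config$alpha)
    algo_dag <- hill_climb(fit_data[model_cols],
                           forbidden = forbidden_arc_set(config$tiers,
                                                         model_cols),
                           restarts = config$restarts,
                           perturb = config$perturb, seed = seed_tp)
    say("[%s] hill climbing: %d arcs, BIC %.2f", tp, nrow(algo_dag$arcs),
        attr(algo_dag, "score"))
    algo_bn <- fit_parameters(algo_dag, fit_data[model_cols],
                              alpha = config$alpha)
    train_eval <- if (config$train_metrics_on == "smote") fit_data else tr_model
    sets <- list(training = train_eval, validation = va_model)
    blocks <- list()
    for (structure_name in c("expert", "algorithm")) {
      bn <- if (structure_name == "expert") expert_bn else algo_bn
      for (ds in names(sets)) {
        blk <- eval_block(bn, sets[[ds]], tp, config$threshold, config$bins,
                          config$boot, derive_seed(seed_tp, paste(ds, structure_name)))
        blocks[[paste(structure_name, ds, sep = ".")]] <- blk
        metrics[[length(metrics) + 1L]] <- data.frame(
          timepoint = tp, structure = structure_name, dataset = ds,
          t(blk$metrics), stringsAsFactors = FALSE)
      }
    }
    auc_tests <- lapply(names(sets), function(ds) {
      compare_auc(blocks[[paste0("expert.", ds)]]$probs,
                  blocks[[paste0("algorithm.", ds)]]$probs,
                  sets[[ds]][[tp]])
    })
    names(auc_tests) <- names(sets)
    say("[%s] DeLong expert vs algorithm: p = %.3f (training), p = %.3f (validation)",
        tp, auc_tests$training$p_value, auc_tests$validation$p_value)
    diff <- structure_diff(expert_dag, algo_dag, outcome = tp)
    details[[tp]] <- list(expert_dag = expert_dag, algo_dag = algo_dag,
                          expert_bn = expert_bn, algo_bn = algo_bn,
                          blocks = blocks, auc_tests = auc_tests,
                          structure_diff = diff,
                          n_train = nrow(tr_model), n_validation = nrow(va_model))
  }
  metrics <- do.call(rbind, metrics)
  bundle <- structure(list(config = config, metrics = metrics,
                           details = details, log = log_lines),
                      class = "tierbn_bundle")
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

droplevels_outcome <- function(df, tp) {
  df[[tp]] <- droplevels(df[[tp]])
  df
}

sub_outcome <- function(arcs, tp) {
  arcs <- as_arc_matrix(arcs)
  arcs[arcs == "outcome"] <- tp
  arcs
}

#' @export
print.tierbn_bundle <- function(x, ...) {
  cat("<tierbn_bundle>\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$metrics, file.path(outdir, "metrics.csv"),
                   row.names = FALSE)
  writeLines(bundle$log, file.path(outdir, "run_log.txt"))
  for (tp in names(bundle$details)) {
    d <- bundle$details[[tp]]
    utils::write.csv(as.data.frame(d$algo_dag$arcs),
                     file.path(outdir, sprintf("arcs_algorithm_%s.csv", tp)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(d$expert_dag$arcs),
                     file.path(outdir, sprintf("arcs_expert_%s.csv", tp)),
                     row.names = FALSE)
    write_network(d$expert_bn, file.path(outdir, sprintf("network_expert_%s.json", tp)))
    write_network(d$algo_bn, file.path(outdir, sprintf("network_algorithm_%s.json", tp)))
    cal <- do.call(rbind, lapply(names(d$blocks), function(k) {
      cbind(run = k, d$blocks[[k]]$calibration$bins)
    }))
    utils::write.csv(cal, file.path(outdir, sprintf("calibration_%s.csv", tp)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(bundle$details, function(d) list(
      shd = d$structure_diff$shd,
      outcome_parents_expert = d$structure_diff$outcome_parents_a,
      outcome_parents_algorithm = d$structure_diff$outcome_parents_b,
      p_value_training = d$auc_tests$training$p_value,
      p_value_validation = d$auc_tests$validation$p_value)),
    file.path(outdir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Serialize / load a fitted network (JSON schema)
#'
#' Schema: `nodes` (array of objects `name`, `levels`, `parents`, `prob`
#' with CPT rows in parent-configuration order, first parent fastest) and
#' `arcs` (array of `[from, to]`).
#'
#' @param bn A `tierbn_bn`.
#' @param path JSON file path.
#' @return `write_network` returns `path` invisibly; `read_network` a
#'   `tierbn_bn`.
#' @export
write_network <- function(bn, path) {
  stopifnot(inherits(bn, "tierbn_bn"))
  nodes <- lapply(bn$dag$nodes, function(v) {
    ct <- bn$cpts[[v]]
    list(name = v, levels = ct$levels, parents = ct$parents,
         prob = unname(apply(ct$prob, 1L, as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(list(nodes = nodes,
                            arcs = apply(bn$dag$arcs, 1L, as.list)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cpts <- list()
  names_all <- vapply(raw$nodes, `[[`, character(1L), "name")
  levels_all <- lapply(raw$nodes, function(x) unlist(x$levels))
  names(levels_all) <- names_all
  arcs <- NULL
  for (x in raw$nodes) {
    pars <- unlist(x$parents) %||% character(0)
    prob <- do.call(rbind, lapply(x$prob, unlist))
    cpts[[x$name]] <- cpt(x$name, unlist(x$levels), pars,
                          stats::setNames(levels_all[pars], pars), prob)
    if (length(pars)) arcs <- rbind(arcs, cbind(pars, x$name))
  }
  bayesian_network(dag(names_all, arcs), cpts)
}
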