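minimal_spec <- function(p = 0.5) {
  list(name = "mini",
       variables = list(list(name = "A", tier = 0L, levels = c("F", "T"),
                             target = c(1 - p, p))),
       outcomes = character(0), missingness = numeric(0), cohorts = NULL)
}

test_that("build_ground_truth handles the minimal one-node spec", {
  gt <- build_ground_truth(minimal_spec(0.5), seed = 1)
  expect_equal(unname(gt$network$cpts$A$prob[1, ]), c(0.5, 0.5))
  expect_equal(gt$seed_used, 1L)
})

test_that("backward-tier arcs and degenerate prevalences are rejected", {
  bad <- list(
    name = "bad",
    variables = list(
      list(name = "age", tier = 0L, levels = c("a", "b"), target = c(.5, .5)),
      list(name = "pathological_t", tier = 3L, levels = c("x", "y"),
           target = c(.5, .5)),
      list(name = "age2", tier = 0L, levels = c("a", "b"), target = c(.5, .5),
           parents = "pathological_t")),
    outcomes = character(0))
  expect_error(build_ground_truth(bad), "tier constraint")

  degen <- minimal_spec(1)
  degen$variables[[1]]$target <- c(0, 1)
  degen$outcomes <- "A"
  expect_error(build_ground_truth(degen), "degenerate")
})

test_that("every generated arc respects the tier map", {
  for (spec in list(clinical_generator_spec(), recovery_generator_spec())) {
    gt <- build_ground_truth(spec, seed = 1)
    expect_true(arcs_respect_tiers(gt$network$dag$arcs, gt$tiers))
    fb <- forbidden_arc_set(gt$tiers)
    expect_length(intersect(tierbn:::arc_ids(gt$network$dag$arcs),
                            tierbn:::arc_ids(fb)), 0L)
  }
})

test_that("marginal calibration: node marginals match their targets exactly", {
  spec <- clinical_generator_spec()
  gt <- build_ground_truth(spec, seed = 1)
  for (v in spec$variables) {
    if (is.null(v$target) || !is.null(v$cpt)) next
    m <- tierbn:::joint_distribution(gt$network, v$name)
    expect_equal(as.numeric(m$arr), unname(v$target), tolerance = 1e-6,
                 label = v$name)
  }
})

test_that("sampled outcome prevalence matches the published 2-year rate", {
  gt <- build_ground_truth(clinical_generator_spec(), seed = 1)
  co <- sample_cohort(gt, 100000, seed = 1)
  expect_lt(abs(mean(co$lr2y == "True") - 385 / (385 + 4168)), 0.01)
})

test_that("sample_cohort validates n, is reproducible and labels cohorts", {
  gt <- build_ground_truth(clinical_generator_spec(), seed = 1)
  expect_error(sample_cohort(gt, 0), "n")
  one <- sample_cohort(gt, 1, seed = 2)
  expect_equal(nrow(one), 1L)
  expect_false(anyNA(one))
  a <- sample_cohort(gt, 500, seed = 3)
  expect_identical(a, sample_cohort(gt, 500, seed = 3))
  expect_equal(length(unique(a$cohort)), 14L)
  # all values in declared category sets
  for (v in gt$network$dag$nodes)
    expect_true(all(a[[v]] %in% gt$network$cpts[[v]]$levels))
})

test_that("sampled conditional frequencies converge to the CPTs", {
  gt <- build_ground_truth(recovery_generator_spec(), seed = 1)
  s <- ancestral_sample(gt$network, 20000, seed = 21)
  f <- fit_parameters(gt$network$dag, s, alpha = 0)
  for (v in gt$network$dag$nodes) {
    expect_lt(max(abs(f$cpts[[v]]$prob - gt$network$cpts[[v]]$prob)), 0.04)
  }
})

test_that("inject_missingness masks at the requested MCAR rates", {
  gt <- build_ground_truth(clinical_generator_spec(), seed = 1)
  co <- sample_cohort(gt, 10000, seed = 5)
  expect_identical(inject_missingness(co, c(crm = 0), seed = 1), co)
  all_gone <- inject_missingness(co, c(crm = 1), seed = 1)
  expect_true(all(is.na(all_gone$crm)))
  part <- inject_missingness(co, c(crm = 0.819), seed = 1)
  expect_lt(abs(mean(is.na(part$crm)) - 0.819),
            3 * sqrt(0.819 * 0.181 / 10000))
  expect_error(inject_missingness(co, c(crm = 1.2), seed = 1), "\\[0, 1\\]")
  expect_error(inject_missingness(co, c(nope = 0.5), seed = 1), "absent")
})

test_that("cohort CSV round-trips with empty-field missing markers", {
  gt <- build_ground_truth(clinical_generator_spec(), seed = 1)
  co <- inject_missingness(sample_cohort(gt, 200, seed = 6),
                           c(crm = 0.5), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  txt <- readLines(path, n = 5)
  expect_false(any(grepl("NA", txt, fixed = TRUE)))
  back <- read_cohort(path, clinical_generator_spec())
  expect_equal(mean(is.na(back$crm)), mean(is.na(co$crm)))
  expect_equal(as.character(back$clinical_t), as.character(co$clinical_t))
})
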