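test_that("CRM dichotomization includes the 1 mm boundary as positive", {
  expect_equal(as.character(dichotomize_crm(c(0.5, 1.0, 2.0))),
               c("Positive", "Positive", "Negative"))
  expect_true(is.na(dichotomize_crm(NA_real_)))
  expect_error(dichotomize_crm(-1), "non-negative")
})

test_that("categorize bins numeric columns and is idempotent", {
  d <- data.frame(age = c(61, NA, 47.2, 80),
                  rt_dose = c(47.7, 44, NA, 50.4))
  out <- categorize(d)
  expect_equal(as.character(out$age), c("50-65", NA, "<50", ">65"))
  expect_equal(as.character(out$rt_dose), c(">45Gy", "<=45Gy", NA, ">45Gy"))
  expect_identical(categorize(out), out)
  expect_error(categorize(data.frame(mystery = 1:3)), "mystery")
  expect_error(categorization_rules(x = list(cuts = c(2, 1), labels = c("a", "b", "c"))),
               "strictly increasing")
})

test_that("encode_missing_and_filter adds Unknown and drops outcome-missing rows", {
  d <- data.frame(
    crm = fct(c("Negative", NA, "Positive", NA), c("Negative", "Positive")),
    age = fct(rep("50-65", 4), c("<50", "50-65", ">65")),
    lr2y = fct(c("False", "True", NA, "False"), c("False", "True")))
  expect_error(encode_missing_and_filter(d, "nope"), "not present")
  out <- suppressMessages(encode_missing_and_filter(d, "lr2y"))
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "dropped"), 1L)
  expect_equal(as.character(out$crm), c("Negative", "Unknown", "Unknown"))
  # Unknown level is appended to every predictor even without missingness
  expect_true("Unknown" %in% levels(out$age))
  expect_false(anyNA(out$crm))

  clean <- data.frame(x = fct(c("a", "b")), y = fct(c("T", "F")))
  out2 <- encode_missing_and_filter(clean, "y")
  expect_equal(nrow(out2), 2L)
  expect_equal(attr(out2, "dropped"), 0L)
})

test_that("ten rows with three missing outcomes leave seven", {
  d <- data.frame(x = fct(rep("a", 10)),
                  y = fct(c("T", "F", NA, "T", NA, "F", "T", NA, "F", "T")))
  expect_equal(nrow(suppressMessages(encode_missing_and_filter(d, "y"))), 7L)
})

test_that("stratified_split partitions, rounds per stratum and is seeded", {
  d <- data.frame(x = fct(rep("a", 10)), cohort = fct(rep("t1", 10)))
  sp <- stratified_split(d, 0.2, seed = 1)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$validation), 2L)

  d2 <- data.frame(x = fct(rep("a", 30)),
                   cohort = fct(rep(c("t1", "t2", "t3"), each = 10)))
  sp2 <- stratified_split(d2, 0.2, seed = 5)
  expect_equal(nrow(sp2$train) + nrow(sp2$validation), 30L)
  key <- function(df) paste(rownames(df))
  expect_length(intersect(key(sp2$train), key(sp2$validation)), 0L)
  expect_identical(stratified_split(d2, 0.2, seed = 5)$validation,
                   sp2$validation)
  expect_error(stratified_split(d2, 1.2), "between 0 and 1")

  tiny <- data.frame(x = fct(c("a", "a", "a")),
                     cohort = fct(c("t1", "t1", "solo")))
  expect_warning(sp3 <- stratified_split(tiny, 0.5, seed = 2), "solo")
  expect_true(all(sp3$train$cohort == "solo" | sp3$train$cohort == "t1"))
})

test_that("the default cohort splits about 80/20 at full size", {
  gt <- build_ground_truth(clinical_generator_spec(), seed = 1)
  co <- sample_cohort(gt, 6754, seed = 1)
  sp <- stratified_split(co, 0.2, seed = 1)
  expect_lt(abs(nrow(sp$train) - 5404), 6)
  expect_lt(abs(nrow(sp$validation) - 1350), 6)
})

test_that("smote_categorical balances, preserves originals and vocabulary", {
  set.seed(42)
  n_maj <- 90; n_min <- 10
  d <- data.frame(
    a = fct(sample(c("x", "y", "z"), n_maj + n_min, TRUE)),
    b = fct(sample(c("u", "v"), n_maj + n_min, TRUE)),
    y = fct(rep(c("False", "True"), c(n_maj, n_min)), c("False", "True")))
  out <- smote_categorical(d, "y", k = 5, seed = 1)
  expect_equal(as.integer(table(out$y)), c(90L, 90L))
  expect_equal(out[seq_len(nrow(d)), ], d, ignore_attr = "synthetic")
  expect_true(all(levels(out$a) == levels(d$a)))
  expect_false(any(attr(out, "synthetic")[seq_len(nrow(d))]))
  expect_equal(sum(attr(out, "synthetic")), 80L)

  balanced <- d[c(1:10, 91:100), ]
  expect_equal(smote_categorical(balanced, "y", k = 3, seed = 1),
               balanced, ignore_attr = "synthetic")

  single <- d[1:90, ]
  expect_error(smote_categorical(single, "y", k = 5), "two outcome classes")
  expect_error(smote_categorical(d, "y", k = 50), "too large")
})

test_that("each synthetic SMOTE value comes from its k+1 source rows", {
  set.seed(7)
  d <- data.frame(
    a = fct(sample(c("x", "y", "z"), 60, TRUE)),
    b = fct(sample(c("u", "v", "w"), 60, TRUE)),
    c = fct(sample(c("p", "q"), 60, TRUE)),
    y = fct(rep(c("False", "True"), c(48, 12)), c("False", "True")))
  k <- 4
  out <- smote_categorical(d, "y", k = k, seed = 3)
  syn <- out[attr(out, "synthetic"), ]
  minority <- d[d$y == "True", ]
  # brute-force membership: every synthetic value must occur among the values
  # of some (seed, k neighbours) group; verify against all size-(k+1)
  # minority neighbourhoods by checking the value exists in >= k+1 rows'
  # pooled vocabulary of at least one seed row's neighbourhood
  ham <- function(r1, r2) sum(as.character(unlist(r1[c("a", "b", "c")])) !=
                                as.character(unlist(r2[c("a", "b", "c")])))
  groups <- lapply(seq_len(nrow(minority)), function(i) {
    dd <- vapply(seq_len(nrow(minority)), function(j)
      ham(minority[i, ], minority[j, ]), numeric(1L))
    ord <- order(dd, seq_along(dd))
    minority[c(i, setdiff(ord, i)[seq_len(k)]), ]
  })
  for (r in seq_len(nrow(syn))) {
    ok <- any(vapply(groups, function(g) {
      all(vapply(c("a", "b", "c"), function(v)
        as.character(syn[[v]][r]) %in% as.character(g[[v]]), logical(1L)))
    }, logical(1L)))
    expect_true(ok, label = sprintf("synthetic row %d traceable", r))
  }
})
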