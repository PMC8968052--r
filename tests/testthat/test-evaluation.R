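test_that("predict_cohort reproduces hand-computed posteriors", {
  bn <- toy_bn()
  tab <- data.frame(B = fct(c("T", "F", "T"), c("F", "T")))
  p <- predict_cohort(bn, tab, "A", positive = "T")
  expect_equal(p[1], 0.27 / 0.41, tolerance = 1e-12)
  expect_equal(p[2], (0.3 * 0.1) / (0.3 * 0.1 + 0.7 * 0.8), tolerance = 1e-12)
  expect_equal(p[1], p[3])  # identical rows, identical probabilities
  expect_error(predict_cohort(bn, data.frame(B = fct("zzz")), "A", "T"),
               "unseen category")
})

test_that("an outcome with no parents or children gets its prior everywhere", {
  cY <- cpt("Y", c("False", "True"), prob = c(0.8, 0.2))
  cX <- cpt("X", c("a", "b"), prob = c(0.5, 0.5))
  bn <- bayesian_network(dag(c("X", "Y")), list(X = cX, Y = cY))
  p <- predict_cohort(bn, data.frame(X = fct(c("a", "b", "a"))), "Y")
  expect_equal(p, rep(0.2, 3), tolerance = 1e-12)
})

test_that("the Markov-blanket fast path agrees with variable elimination", {
  for (seed in 1:10) {
    bn <- random_bn(sample(4:7, 1L), seed + 900)
    outcome <- sample(bn$dag$nodes, 1L)
    d <- ancestral_sample(bn, 40, seed = seed)
    pos <- bn$cpts[[outcome]]$levels[1L]
    fast <- predict_cohort(bn, d[setdiff(names(d), outcome)], outcome, pos)
    slow <- vapply(seq_len(nrow(d)), function(i) {
      ev <- vapply(setdiff(bn$dag$nodes, outcome),
                   function(v) as.character(d[[v]][i]), character(1L))
      posterior(bn, outcome, ev)[[pos]]
    }, numeric(1L))
    expect_equal(fast, slow, tolerance = 1e-9, label = sprintf("seed %d", seed))
  }
})

test_that("roc_auc equals brute-force pair counting", {
  expect_equal(roc_auc(c(.9, .8, .4, .3), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(c(.1, .2), c(1, 1)), "both classes")
  set.seed(51)
  for (i in 1:8) {
    n <- sample(20:120, 1L)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2) # rounding forces ties
    expect_equal(roc_auc(p, y), brute_auc(p, y), tolerance = 1e-12)
  }
})

test_that("DeLong intervals contain the point estimate, clip, and shrink", {
  set.seed(52)
  mk <- function(n) {
    y <- rbinom(n, 1, 0.4)
    list(y = y, p = plogis(ifelse(y == 1, 1, 0) + rnorm(n)))
  }
  small <- mk(100); big <- mk(10000)
  ci_s <- auc_confidence_interval(small$p, small$y)
  ci_b <- auc_confidence_interval(big$p, big$y)
  expect_true(ci_s["low"] <= roc_auc(small$p, small$y) &&
                roc_auc(small$p, small$y) <= ci_s["high"])
  expect_lt(diff(unname(ci_b)), diff(unname(ci_s)))

  sep <- c(rep(0.9, 50), rep(0.1, 50))
  ysep <- rep(c(1, 0), each = 50)
  expect_equal(unname(auc_confidence_interval(sep, ysep)["high"]), 1.0)
  expect_error(auc_confidence_interval(c(.1, .9), c(0, 1)), ">= 2")

  boot_ci <- auc_confidence_interval(small$p, small$y, method = "bootstrap",
                                     boot = 200, seed = 1)
  expect_true(boot_ci["low"] < boot_ci["high"])
})

test_that("compare_auc is exact for identical inputs and validates lengths", {
  set.seed(53)
  y <- rbinom(200, 1, 0.3)
  p <- runif(200)
  expect_equal(compare_auc(p, p, y)$p_value, 1.0)
  expect_error(compare_auc(p, p[-1], y), "length")
})

test_that("compare_auc has power against an uninformative competitor", {
  set.seed(54)
  hits <- 0L
  for (b in 1:100) {
    y <- rbinom(500, 1, 0.3)
    pa <- plogis(ifelse(y == 1, 1.7, 0) + rnorm(500))
    pb <- runif(500)
    hits <- hits + (compare_auc(pa, pb, y)$p_value < 0.05)
  }
  expect_gte(hits / 100, 0.95)
})

test_that("confusion_metrics counts the 2x2 table at the cut", {
  perfect <- confusion_metrics(c(.9, .8, .1, .2), c(1, 1, 0, 0))
  expect_equal(unname(perfect), c(1, 1, 1))
  mixed <- confusion_metrics(c(.9, .4, .6, .1), c(1, 1, 0, 0), threshold = 0.5)
  expect_equal(unname(mixed), c(0.5, 0.5, 0.5))
  lowcut <- confusion_metrics(c(.9, .4, .6, .1), c(1, 1, 0, 0),
                              threshold = 1e-9)
  expect_equal(unname(lowcut["sensitivity"]), 1)
  expect_warning(one <- confusion_metrics(c(.9, .2), c(1, 1)), "single-class")
  expect_true(is.na(one["specificity"]))
})

test_that("calibration handles the degenerate single-bin case", {
  set.seed(55)
  y <- rbinom(5000, 1, 0.3)
  cal <- calibration(rep(0.3, 5000), y, bins = 10, boot = 50, seed = 1)
  expect_equal(nrow(cal$bins), 1L)
  expect_equal(cal$bins$mean_pred, 0.3)
  expect_lt(abs(cal$bins$observed - 0.3), 0.02)
  expect_error(calibration(runif(5), rbinom(5, 1, .5), bins = 10), "at least")
})

test_that("shuffled labels flatten the calibration curve at prevalence", {
  set.seed(56)
  n <- 10000
  y <- rbinom(n, 1, 0.3)
  p <- plogis(ifelse(y == 1, 1, 0) + rnorm(n))
  shuffled <- sample(y)
  cal <- calibration(p, shuffled, bins = 10, boot = 0, seed = 1)
  expect_true(all(abs(cal$bins$observed - mean(y)) < 0.05))
})

test_that("calibration bins partition the data and bias correction is sane", {
  set.seed(57)
  n <- 2000
  y <- rbinom(n, 1, 0.4)
  p <- plogis(ifelse(y == 1, 0.8, 0) + rnorm(n))
  cal <- calibration(p, y, bins = 10, boot = 100, seed = 2)
  expect_equal(sum(cal$bins$n), n)
  expect_true(all(cal$bins$ci_low <= cal$bins$ci_high))
  expect_true(all(is.finite(cal$bins$bias_corrected)))
  expect_true(all(abs(cal$bins$bias_corrected - cal$bins$observed) < 0.2))
})
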