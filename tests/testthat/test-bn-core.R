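test_that("cpt validates probability rows", {
  expect_error(cpt("A", c("F", "T"), prob = c(0.6, 0.5)), "sum to 1")
  expect_error(cpt("A", c("F", "T"), prob = c(1.2, -0.2)), "negative")
  ct <- cpt("A", c("F", "T"), prob = c(0.5, 0.5))
  expect_equal(dim(ct$prob), c(1L, 2L))
})

test_that("fit_parameters reproduces ML and Laplace closed forms", {
  d <- data.frame(A = fct(c("T", "T", "F", "F"), c("F", "T")))
  g <- dag("A")
  expect_equal(unname(fit_parameters(g, d, alpha = 0)$cpts$A$prob[1, ]),
               c(0.5, 0.5))
  expect_equal(unname(fit_parameters(g, d, alpha = 1)$cpts$A$prob[1, ]),
               c(3 / 6, 3 / 6))
  d2 <- data.frame(A = fct(c("T", "T", "T", "F"), c("F", "T")))
  expect_equal(unname(fit_parameters(g, d2, alpha = 1)$cpts$A$prob[1, ]),
               c(2 / 6, 4 / 6))
})

test_that("unseen parent configurations fall back to uniform with a warning", {
  d <- data.frame(A = fct(c("F", "F"), c("F", "T")),
                  B = fct(c("x", "y"), c("x", "y")))
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  expect_warning(bn <- fit_parameters(g, d, alpha = 0), "unseen parent")
  expect_equal(unname(bn$cpts$B$prob[2, ]), c(0.5, 0.5))
})

test_that("log_likelihood matches closed forms and flags contradictions", {
  bn1 <- bayesian_network(dag("A"), list(A = cpt("A", c("F", "T"),
                                                 prob = c(0.5, 0.5))))
  d4 <- data.frame(A = fct(c("T", "F", "T", "F"), c("F", "T")))
  expect_equal(log_likelihood(bn1, d4), 4 * log(0.5), tolerance = 1e-12)

  det <- bayesian_network(dag("A"), list(A = cpt("A", c("F", "T"),
                                                 prob = c(0, 1))))
  expect_equal(log_likelihood(det, data.frame(A = fct("T", c("F", "T")))), 0)
  expect_identical(log_likelihood(det, data.frame(A = fct("F", c("F", "T")))),
                   -Inf)
})

test_that("posterior reproduces hand-computed Bayes results", {
  bn <- toy_bn()
  expect_equal(unname(posterior(bn, "A")), c(0.7, 0.3), tolerance = 1e-12)
  p <- posterior(bn, "A", c(B = "T"))
  expect_equal(unname(p[["T"]]), 0.27 / 0.41, tolerance = 1e-12)
  expect_error(posterior(bn, "B", c(B = "T")), "cannot also be evidence")
  expect_error(posterior(bn, "A", c(B = "zzz")), "not a category")
})

test_that("posterior rejects zero-probability evidence by name", {
  cA <- cpt("A", c("F", "T"), prob = c(1, 0))
  cB <- cpt("B", c("F", "T"), parents = "A",
            parent_levels = list(A = c("F", "T")),
            prob = rbind(c(1, 0), c(0, 1)))
  bn <- bayesian_network(dag(c("A", "B"), rbind(c("A", "B"))),
                         list(A = cA, B = cB))
  expect_error(posterior(bn, "A", c(B = "T")), "zero probability.*B=T")
})

test_that("variable elimination equals full-joint enumeration", {
  for (seed in 1:30) {
    bn <- random_bn(sample(3:6, 1L), seed)
    nodes <- bn$dag$nodes
    query <- sample(nodes, 1L)
    n_ev <- sample(0:min(2L, length(nodes) - 1L), 1L)
    ev_vars <- sample(setdiff(nodes, query), n_ev)
    ev <- vapply(ev_vars, function(v) sample(bn$cpts[[v]]$levels, 1L),
                 character(1L))
    got <- posterior(bn, query, ev)
    want <- enum_posterior(bn, query, ev)
    expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-9,
                 label = sprintf("seed %d", seed))
  }
})

test_that("ancestral sampling is seeded, typed and distributionally correct", {
  bn <- toy_bn()
  expect_error(ancestral_sample(bn, 0), "n")
  one <- ancestral_sample(bn, 1, seed = 4)
  expect_equal(nrow(one), 1L)
  expect_identical(ancestral_sample(bn, 200, seed = 9),
                   ancestral_sample(bn, 200, seed = 9))

  det <- bayesian_network(
    dag(c("A", "B"), rbind(c("A", "B"))),
    list(A = cpt("A", c("F", "T"), prob = c(0, 1)),
         B = cpt("B", c("F", "T"), parents = "A",
                 parent_levels = list(A = c("F", "T")),
                 prob = rbind(c(1, 0), c(0, 1)))))
  s <- ancestral_sample(det, 50, seed = 1)
  expect_true(all(s$A == "T" & s$B == "T"))

  p3 <- bayesian_network(dag("X"), list(X = cpt("X", c("F", "T"),
                                                prob = c(0.7, 0.3))))
  freq <- mean(ancestral_sample(p3, 50000, seed = 11)$X == "T")
  expect_lt(abs(freq - 0.3), 3 * sqrt(0.3 * 0.7 / 50000))
})

test_that("deleting a true arc can only lower the fit on large samples", {
  bn <- toy_bn()
  d <- ancestral_sample(bn, 20000, seed = 5)
  full <- log_likelihood(fit_parameters(bn$dag, d, alpha = 0), d)
  cutg <- dag(c("A", "B"))
  cut <- log_likelihood(fit_parameters(cutg, d, alpha = 0), d)
  expect_gt(full, cut)
})

test_that("network JSON serialization round-trips", {
  bn <- random_bn(5, 77)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(bn, path)
  bn2 <- read_network(path)
  expect_identical(sort(arc_strings <- paste(bn$dag$arcs[, 1], bn$dag$arcs[, 2])),
                   sort(paste(bn2$dag$arcs[, 1], bn2$dag$arcs[, 2])))
  q <- bn$dag$nodes[1L]
  expect_equal(posterior(bn, q), posterior(bn2, q), tolerance = 1e-12)
})
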