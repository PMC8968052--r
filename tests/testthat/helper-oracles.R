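# Independent oracles and fixture builders, kept deliberately naive:
# enumeration over the full joint, pairwise AUC counting, equivalence-class
# enumeration for CPDAGs, exhaustive DAG enumeration for 3 variables.

# full joint table: data.frame of all configurations + prob column
enum_joint <- function(bn) {
  nodes <- bn$dag$nodes
  grid <- expand.grid(lapply(nodes, function(v) bn$cpts[[v]]$levels),
                      stringsAsFactors = FALSE)
  names(grid) <- nodes
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    ct <- bn$cpts[[v]]
    for (i in seq_len(nrow(grid))) {
      row <- 1L
      stride <- 1L
      for (pa in ct$parents) {
        code <- match(grid[[pa]][i], ct$parent_levels[[pa]])
        row <- row + (code - 1L) * stride
        stride <- stride * length(ct$parent_levels[[pa]])
      }
      p[i] <- p[i] * ct$prob[row, match(grid[[v]][i], ct$levels)]
    }
  }
  grid$prob <- p
  grid
}

# posterior by explicit conditioning on the full joint
enum_posterior <- function(bn, query, evidence = character(0)) {
  joint <- enum_joint(bn)
  keep <- rep(TRUE, nrow(joint))
  for (v in names(evidence)) keep <- keep & joint[[v]] == evidence[[v]]
  sub <- joint[keep, , drop = FALSE]
  lev <- bn$cpts[[query]]$levels
  p <- vapply(lev, function(l) sum(sub$prob[sub[[query]] == l]), numeric(1L))
  p / sum(p)
}

# random discrete network: random tiered-free DAG + Dirichlet(2) CPT rows
random_bn <- function(n_nodes, seed, edge_prob = 0.35, max_card = 3L) {
  set.seed(seed)
  nodes <- sprintf("V%02d", seq_len(n_nodes))
  ord <- sample(nodes)
  arcs <- NULL
  for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
    if (stats::runif(1) < edge_prob) arcs <- rbind(arcs, c(ord[i], ord[j]))
  }
  cards <- sample(2:max_card, n_nodes, replace = TRUE)
  names(cards) <- nodes
  g <- dag(nodes, arcs)
  cpts <- lapply(nodes, function(v) {
    pars <- unname(g$arcs[g$arcs[, 2L] == v, 1L])
    lev <- letters[seq_len(cards[[v]])]
    q <- prod(cards[pars], 1L)
    prob <- t(vapply(seq_len(q), function(i) {
      x <- stats::rgamma(cards[[v]], shape = 2)
      x / sum(x)
    }, numeric(cards[[v]])))
    cpt(v, lev, pars,
        stats::setNames(lapply(pars, function(p) letters[seq_len(cards[[p]])]),
                        pars), prob)
  })
  names(cpts) <- nodes
  bayesian_network(g, cpts)
}

# pairwise-concordance AUC, O(n^2)
brute_auc <- function(probs, labels) {
  y <- as.integer(labels == sort(unique(as.character(labels)))[2L] |
                    (is.numeric(labels) & labels == 1))
  if (is.logical(labels)) y <- as.integer(labels)
  pos <- probs[y == 1L]; neg <- probs[y == 0L]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# all unordered pairs of arcs forming v-structures a->c<-b with a,b non-adjacent
v_structures <- function(nodes, arcs) {
  if (is.null(arcs) || !nrow(arcs)) return(character(0))
  out <- character(0)
  adj <- paste(pmin(arcs[, 1], arcs[, 2]), pmax(arcs[, 1], arcs[, 2]))
  for (c_ in nodes) {
    pa <- arcs[arcs[, 2] == c_, 1]
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) for (j in (i + 1L):length(pa)) {
      a <- min(pa[i], pa[j]); b <- max(pa[i], pa[j])
      if (!(paste(a, b) %in% adj)) out <- c(out, paste(a, b, "->", c_))
    }
  }
  sort(out)
}

# enumeration oracle for the CPDAG: orient the skeleton every acyclic way
# that preserves the v-structures; an edge is compelled iff it keeps one
# direction across the whole class.  Only for tiny graphs.
oracle_cpdag <- function(g) {
  arcs <- g$arcs
  vs <- v_structures(g$nodes, arcs)
  und <- cbind(pmin(arcs[, 1], arcs[, 2]), pmax(arcs[, 1], arcs[, 2]))
  m <- nrow(und)
  dir_mat <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), m)))
  class_members <- list()
  for (k in seq_len(nrow(dir_mat))) {
    cand <- t(vapply(seq_len(m), function(e) {
      if (dir_mat[k, e]) und[e, ] else und[e, 2:1]
    }, character(2L)))
    ok <- tryCatch({
      dd <- dag(g$nodes, cand)
      identical(v_structures(g$nodes, cand), vs)
    }, error = function(e) FALSE)
    if (ok) class_members[[length(class_members) + 1L]] <- cand
  }
  directed <- NULL; undirected <- NULL
  for (e in seq_len(m)) {
    dirs <- unique(vapply(class_members, function(cand) {
      paste(cand[e, 1L], cand[e, 2L])
    }, character(1L)))
    if (length(dirs) == 1L) {
      directed <- rbind(directed, strsplit(dirs, " ")[[1L]])
    } else undirected <- rbind(undirected, und[e, ])
  }
  list(directed = directed, undirected = undirected)
}

# every DAG over the given nodes (use with <= 3 nodes: 25 DAGs)
enumerate_dags <- function(nodes) {
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^m - 1L)) {
    take <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    arcs <- as.matrix(pairs[take, , drop = FALSE])
    g <- tryCatch(dag(nodes, arcs), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# tiny two-node network used across evaluation tests
toy_bn <- function() {
  cA <- cpt("A", c("F", "T"), prob = c(0.7, 0.3))
  cB <- cpt("B", c("F", "T"), parents = "A",
            parent_levels = list(A = c("F", "T")),
            prob = rbind(c(0.8, 0.2), c(0.1, 0.9)))
  bayesian_network(dag(c("A", "B"), rbind(c("A", "B"))), list(A = cA, B = cB))
}

# factor column helper
fct <- function(x, lev = sort(unique(x))) factor(x, levels = lev)
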