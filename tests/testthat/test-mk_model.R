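test_that("rate matrices honor constraint patterns and conservation", {
  m1 <- mk_model(2, "single")
  expect_equal(rate_matrix(m1, 1), matrix(c(-1, 1, 1, -1), 2, byrow = TRUE))
  m2 <- mk_model(2, "two_rate")
  expect_equal(rate_matrix(m2, c(1, 2)),
               matrix(c(-1, 1, 2, -2), 2, byrow = TRUE))
  m4 <- mk_model(4, "ard")
  expect_equal(m4$n_free, 12)
  Q <- rate_matrix(m4, seq(0.1, 1.2, by = 0.1))
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12)
  expect_error(rate_matrix(m1, -1), "non-negative")
  expect_error(rate_matrix(m2, 1), "expected 2")
  expect_error(mk_model(4, "two_rate"), "binary")
})

test_that("transition probabilities: identity, closed form, stationarity", {
  m <- mk_model(2)
  Q <- rate_matrix(m, 0.5)
  expect_equal(transition_prob(Q, 0), diag(2))
  # binary symmetric closed form: P(stay) = 1/2 + 1/2 exp(-2qt)
  expect_equal(transition_prob(Q, 1)[1, 1], 0.6839397, tolerance = 1e-7)
  P100 <- transition_prob(rate_matrix(m, 1), 100)
  expect_equal(as.numeric(P100), rep(0.5, 4), tolerance = 1e-12)
  expect_error(transition_prob(Q, -1), "non-negative")
})

test_that("P(t) is row-stochastic and Chapman-Kolmogorov holds", {
  set.seed(5)
  for (i in 1:10) {
    k <- sample(c(2, 3, 4), 1)
    m <- mk_model(k, "ard")
    Q <- rate_matrix(m, stats::runif(m$n_free, 0.05, 2))
    t1 <- stats::runif(1, 0.01, 1)
    t2 <- stats::runif(1, 0.01, 1)
    P1 <- transition_prob(Q, t1)
    expect_equal(rowSums(P1), rep(1, k), tolerance = 1e-12)
    expect_true(all(P1 >= 0 & P1 <= 1))
    expect_equal(P1 %*% transition_prob(Q, t2),
                 transition_prob(Q, t1 + t2), tolerance = 1e-10)
  }
})

test_that("transition probabilities agree with a series-expansion oracle", {
  set.seed(6)
  for (i in 1:5) {
    m <- mk_model(4, "ard")
    Q <- rate_matrix(m, stats::runif(12, 0.05, 1.5))
    t <- stats::runif(1, 0.05, 2)
    expect_equal(transition_prob(Q, t), expm_via_series(Q, t),
                 tolerance = 1e-9)
  }
})

test_that("pruning equals enumeration on random binary and 4-state trees", {
  set.seed(7)
  for (i in 1:25) {
    inst <- random_instance(sample(4:6, 1), sample(c(2, 4), 1), "ard")
    rootf <- rep(1 / nrow(inst$Q), nrow(inst$Q))
    expect_equal(
      pruning_loglik(inst$tree, inst$states, inst$Q, rootf),
      enum_loglik(inst$tree, inst$states, inst$Q, rootf),
      tolerance = 1e-10)
  }
})

test_that("pruning limit cases: collapsed tip, no-change limit", {
  # two-tip tree carrying a single state each, uniform root, k = 2
  tr <- parse_newick("(A:1,B:1);")
  m <- mk_model(2)
  # q -> 0: both tips state 0 gives ln(root_freq[0])
  Q0 <- rate_matrix(m, 1e-12)
  expect_equal(pruning_loglik(tr, c(A = 0L, B = 0L), Q0), log(0.5),
               tolerance = 1e-6)
  # 5-tip tree, all tips 0, q -> 0
  tr5 <- fixed_five_tip()
  st0 <- stats::setNames(rep(0L, 5), tr5$tip.label)
  expect_equal(pruning_loglik(tr5, st0, Q0), log(0.5), tolerance = 1e-6)
  expect_error(pruning_loglik(tr5, st0[1:4], rate_matrix(m, 1)), "state")
})

test_that("brute_force_loglik matches its closed 2-tip definition", {
  tr <- parse_newick("(A:0.7,B:1.3);")
  m <- mk_model(2)
  Q <- rate_matrix(m, 0.4)
  P1 <- transition_prob(Q, 0.7)
  P2 <- transition_prob(Q, 1.3)
  by_hand <- log(sum(0.5 * P1[, 1] * P2[, 2])) # tips (0, 1)
  expect_equal(brute_force_loglik(tr, c(A = 0L, B = 1L), Q), by_hand,
               tolerance = 1e-12)
  expect_error(brute_force_loglik(ape::rtree(12),
                                  stats::setNames(rep(0L, 12),
                                                  ape::rtree(12)$tip.label),
                                  Q), "too many")
})

test_that("node marginals equal enumeration posteriors and edge cases", {
  set.seed(8)
  for (i in 1:15) {
    inst <- random_instance(5, sample(c(2, 4), 1), "ard")
    rootf <- rep(1 / nrow(inst$Q), nrow(inst$Q))
    ntip <- 5
    node <- sample((ntip + 1):(ntip + inst$tree$Nnode), 1)
    expect_equal(
      unname(node_marginal(inst$tree, inst$states, inst$Q, rootf,
                           node = node)),
      enum_marginal(inst$tree, inst$states, inst$Q, rootf, node),
      tolerance = 1e-10)
  }
  # q -> 0, all tips 0: point mass on 0 everywhere
  tr5 <- fixed_five_tip()
  m <- mk_model(2)
  st0 <- stats::setNames(rep(0L, 5), tr5$tip.label)
  mg <- node_marginal(tr5, st0, rate_matrix(m, 1e-10), node = 6L)
  expect_equal(unname(mg), c(1, 0), tolerance = 1e-6)
  # symmetric cherry with opposite states: exactly (1/2, 1/2)
  tr2 <- parse_newick("(A:1,B:1);")
  mg2 <- node_marginal(tr2, c(A = 0L, B = 1L), rate_matrix(m, 0.6),
                       node = c("A", "B"))
  expect_equal(unname(mg2), c(0.5, 0.5), tolerance = 1e-12)
  expect_error(node_marginal(tr2, c(A = 0L, B = 1L), rate_matrix(m, 0.6),
                             node = 1L), "tip")
})

test_that("likelihood is invariant to child order and to rerooting", {
  set.seed(9)
  inst <- random_instance(6, 2, "single")
  rootf <- c(0.5, 0.5)
  base <- pruning_loglik(inst$tree, inst$states, inst$Q, rootf)
  rot <- ape::rotateConstr(inst$tree, sample(inst$tree$tip.label))
  expect_equal(pruning_loglik(rot, inst$states, inst$Q, rootf), base,
               tolerance = 1e-10)
  # reversible + uniform root: rerooting along a branch preserves lnL
  rr <- ape::root(ape::unroot(inst$tree), outgroup = inst$tree$tip.label[1],
                  resolve.root = TRUE)
  expect_equal(pruning_loglik(rr, inst$states, inst$Q, rootf), base,
               tolerance = 1e-10)
})

test_that("marginals approach uniform as qt grows (single-rate)", {
  tr5 <- fixed_five_tip()
  m <- mk_model(2)
  st <- stats::setNames(c(0L, 0L, 1L, 1L, 0L), tr5$tip.label)
  mg <- node_marginal(tr5, st, rate_matrix(m, 500), node = 6L)
  expect_equal(unname(mg), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("stationary distributions solve pi Q = 0", {
  m <- mk_model(2, "two_rate")
  Q <- rate_matrix(m, c(1, 3))
  expect_equal(stationary_distribution(Q), c(0.75, 0.25), tolerance = 1e-12)
  m4 <- mk_model(4, "ard")
  Q4 <- rate_matrix(m4, stats::runif(12, 0.1, 2))
  pi4 <- stationary_distribution(Q4)
  expect_equal(as.numeric(pi4 %*% Q4), rep(0, 4), tolerance = 1e-10)
})
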