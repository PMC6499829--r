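test_that("settings and prior constructors validate their inputs", {
  s <- mcmc_settings(profile = "desk")
  expect_equal(s$generations, 500000L)
  expect_equal(s$thin, 100L)
  expect_equal(s$burnin, 100000L)
  expect_equal(mcmc_settings(profile = "paper")$generations, 10000000L)
  expect_error(mcmc_settings(generations = 100, burnin = 200))
  expect_error(rate_prior(2, 1))
})

test_that("symmetric two-tip data give an equivocal root", {
  tr <- parse_newick("(A:1,B:1);")
  pat <- make_pattern(c(A = 0L, B = 1L))
  fit <- asr_bayes(tr, pat,
                   settings = mcmc_settings(generations = 20000, thin = 20,
                                            burnin = 4000,
                                            scale_target_mean = 0),
                   target_nodes = list(root = c("A", "B")), seed = 5)
  np <- node_posterior(fit, "root")
  expect_equal(unname(np$mean_pp), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(np$mean_pp), 1, tolerance = 1e-9)
})

test_that("chains are bit-identical under a fixed seed", {
  ds <- echinoderm_dataset()
  trs <- sample_tree_set(ds$topology, ds$calibrations, n = 5, seed = 6)
  pat <- restrict_pattern(ds$matrix, "alx1")
  st <- mcmc_settings(generations = 5000, thin = 50, burnin = 1000)
  f1 <- asr_bayes(trs, pat, settings = st,
                  target_nodes = ds$clades["Eleutherozoa"], seed = 99)
  f2 <- asr_bayes(trs, pat, settings = st,
                  target_nodes = ds$clades["Eleutherozoa"], seed = 99)
  expect_identical(f1$chain, f2$chain)
  expect_identical(f1$node_pp, f2$node_pp)
})

test_that("posterior of q matches dense quadrature on one fixed tree", {
  # binary single-rate model: compare MCMC moments with deterministic
  # quadrature of prior x likelihood over the prior support
  tr <- fixed_five_tip()
  st <- stats::setNames(c(0L, 0L, 1L, 1L, 0L), tr$tip.label)
  pat <- make_pattern(st)
  m <- mk_model(2)
  qs <- seq(1e-4, 2, length.out = 4000)
  dens <- vapply(qs, function(q)
    exp(pruning_loglik(tr, st, rate_matrix(m, q))), 0)
  dens <- dens / sum(dens)
  mean_quad <- sum(qs * dens)
  sd_quad <- sqrt(sum(qs^2 * dens) - mean_quad^2)
  fit <- asr_bayes(tr, pat, m,
                   settings = mcmc_settings(generations = 120000, thin = 40,
                                            burnin = 20000,
                                            scale_target_mean = 0),
                   seed = 17)
  q_chain <- fit$chain$q
  se <- stats::sd(q_chain) / sqrt(ess(q_chain))
  expect_lt(abs(mean(q_chain) - mean_quad), 3 * se + 0.01)
  expect_lt(abs(stats::sd(q_chain) - sd_quad), 0.05)
})

test_that("a one-tree sample repeated N times matches the single tree", {
  ds <- echinoderm_dataset()
  tr <- sample_chronogram(ds$topology, ds$calibrations, seed = 20)
  pat <- restrict_pattern(ds$matrix, "alx1")
  st <- mcmc_settings(generations = 40000, thin = 40, burnin = 8000)
  rep10 <- as_tree_sample(rep(list(tr), 10))
  f_one <- asr_bayes(tr, pat, settings = st, seed = 41)
  f_rep <- asr_bayes(rep10, pat, settings = st, seed = 42)
  ks <- stats::ks.test(f_one$chain$q, f_rep$chain$q)
  expect_gt(ks$p.value, 0.01)
})

test_that("summary, coef, print and plot methods work", {
  ds <- echinoderm_dataset()
  tr <- sample_chronogram(ds$topology, ds$calibrations, seed = 2)
  pat <- restrict_pattern(ds$matrix, "tbrain")
  fit <- asr_bayes(tr, pat,
                   settings = mcmc_settings(generations = 6000, thin = 30,
                                            burnin = 1500),
                   target_nodes = ds$clades["Camarodonta"], seed = 8)
  expect_named(coef(fit), "q")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.asr_bayes")
  cam <- sm$nodes[sm$nodes$node == "Camarodonta", ]
  expect_equal(sum(cam$mean_pp), 1, tolerance = 1e-6) # 4-state normalization
  expect_output(print(fit), "ancestral state reconstruction")
  expect_output(print(sm), "Node posterior")
  expect_output(print(node_posterior(fit, "Camarodonta")), "PP")
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
  expect_error(node_posterior(fit, "Nope"), "not recorded")
})

test_that("summarize handles degenerate chains exactly", {
  # chain of identical vectors: mean equals the vector, SE 0
  fake <- structure(list(
    chain = data.frame(generation = 1:10, lnL = rep(-1, 10),
                       q = rep(0.5, 10), tree_index = 1L),
    node_pp = array(rep(c(0.7, 0.3), each = 10), dim = c(10, 1, 2),
                    dimnames = list(NULL, "n1", c("a", "b"))),
    model = mk_model(2)), class = "asr_bayes")
  np <- node_posterior(fake, "n1")
  expect_equal(unname(np$mean_pp), c(0.7, 0.3))
  expect_equal(unname(np$mc_se), c(0, 0))
  # two opposite point-mass samples average to (1/2, 1/2)
  fake$node_pp <- array(c(1, 0, 0, 1), dim = c(2, 1, 2),
                        dimnames = list(NULL, "n1", c("a", "b")))
  fake$chain <- fake$chain[1:2, ]
  expect_equal(unname(node_posterior(fake, "n1")$mean_pp), c(0.5, 0.5))
})

test_that("ess behaves like an autocorrelation-time estimator", {
  set.seed(30)
  x <- stats::rnorm(10000)
  e_iid <- ess(x)
  expect_gt(e_iid, 8000)
  expect_lt(e_iid, 10000 * 1.05)
  # AR(1): ESS ~ n (1 - rho) / (1 + rho)
  rho <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = rho), 20000))
  target <- 20000 * (1 - rho) / (1 + rho)
  expect_lt(ess(ar) / target, 1.5)
  expect_gt(ess(ar) / target, 1 / 1.5)
  # alternating series: negative autocorrelation, ESS >= n
  alt <- rep(c(-1, 1), 500)
  expect_gte(ess(alt), 1000)
  # constant series: degenerate flag, ESS = n
  cst <- ess(rep(2, 100))
  expect_equal(as.numeric(cst), 100)
  expect_true(attr(cst, "degenerate"))
  expect_error(ess(1:5), "too short")
})

test_that("ess roughly agrees with an independent spectral estimator", {
  set.seed(31)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.8), 20000))
  e1 <- ess(ar)
  e2 <- coda::effectiveSize(coda::mcmc(ar))
  expect_lt(abs(log(e1 / e2)), log(1.5))
})

test_that("autocorrelation matches definition and sampling bounds", {
  set.seed(32)
  x <- stats::rnorm(10000)
  r <- autocorrelation(x, 5)
  expect_equal(r[1], 1)
  expect_lt(abs(r[2]), 0.05)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.8), 10000))
  expect_lt(abs(autocorrelation(ar, 1)[2] - 0.8), 0.05)
  expect_error(autocorrelation(x, 6000), "max_lag")
})
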