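#' MCMC settings for ancestral state reconstruction
#'
#' Defaults mirror the study-scale protocol: 10,000,000 generations,
#' sampling every 1,000th, with the first 2,000,000 discarded as burn-in.
#' A shorter desk-scale profile (500,000 / 100 / 100,000) is available via
#' `profile = "desk"` and is what the package's own tests use.
#'
#' @param generations Total MCMC generations.
#' @param thin Sampling interval.
#' @param burnin Generations discarded before sampling starts.
#' @param window Initial sliding-window width per free rate; `NULL` means
#'   one tenth of the prior range.
#' @param adapt Tune the window during burn-in toward acceptance 0.2-0.4,
#'   then freeze it.
#' @param scale_target_mean Branch lengths of every input tree are scaled
#'   to this mean before likelihood evaluation (0 disables scaling).
#' @param profile Shortcut: `"paper"` (the defaults above) or `"desk"`.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(generations = 1e7, thin = 1000, burnin = 2e6,
                          window = NULL, adapt = TRUE,
                          scale_target_mean = 0.1,
                          profile = c("custom", "paper", "desk")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    generations <- 1e7; thin <- 1000; burnin <- 2e6
  } else if (profile == "desk") {
    generations <- 5e5; thin <- 100; burnin <- 1e5
  }
  stopifnot(burnin < generations, thin >= 1,
            (generations - burnin) >= thin)
  structure(list(generations = as.integer(generations),
                 thin = as.integer(thin), burnin = as.integer(burnin),
                 window = window, adapt = isTRUE(adapt),
                 scale_target_mean = scale_target_mean),
            class = "mcmc_settings")
}

#' Uniform prior on transition rates
#'
#' Applied independently to each free rate. The default U(0, 2) is the
#' analysis-scale prior; U(0, 0.2), U(0, 20) and U(0, 200) are the
#' standard sensitivity settings.
#'
#' @param lower,upper Bounds, `lower < upper`.
#' @return An object of class `rate_prior`.
#' @export
rate_prior <- function(lower = 0, upper = 2) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  structure(list(kind = "uniform", lower = lower, upper = upper),
            class = "rate_prior")
}

#' @export
print.rate_prior <- function(x, ...) {
  cat(sprintf("Uniform rate prior U(%g, %g)\n", x$lower, x$upper))
  invisible(x)
}

# internal: prune each tree to the pattern taxa, scale, and prep for C++
prep_tree_set <- function(trees, pattern, target_taxa, scale_target_mean,
                          constraint = NULL) {
  if (inherits(trees, "phylo")) trees <- as_tree_sample(c(trees))
  states <- pattern$states
  taxa <- pattern$taxa
  lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (length(setdiff(taxa, tr$tip.label)) > 0)
      stop("tree ", i, " lacks scored taxa")
    if (length(taxa) < length(tr$tip.label)) tr <- prune_to_taxa(tr, taxa)
    if (scale_target_mean > 0) tr <- scale_branches(tr, scale_target_mean)
    prep_tree(tr, states, target_taxa = target_taxa, constraint = constraint)
  })
}

#' Bayesian ancestral state reconstruction over a tree sample
#'
#' Fits the Mk model to a single discrete character by
#' Metropolis-Hastings sampling of the free transition rates under a
#' uniform prior, integrating over chronogram uncertainty by drawing a
#' tree uniformly at random from `trees` as part of every proposal. At
#' each retained sample the exact marginal state distribution at every
#' target node is recorded under the current (tree, rates) — a
#' Rao-Blackwellised estimate of the node posterior whose mean is the
#' "mean posterior probability" reported at ancestral nodes.
#'
#' Each tree is pruned to the pattern's scored taxa and branch-scaled to
#' `settings$scale_target_mean` before use. Target nodes are named clades
#' given as taxon sets; they are resolved to the MRCA per tree, so the
#' trees in the sample may differ in topology.
#'
#' @param trees A tree sample ([as_tree_sample()], [read_tree_sample()],
#'   [sample_tree_set()]) or a single `phylo`.
#' @param pattern A [restrict_pattern()] result (single-gene tip states).
#' @param model An [mk_model()] with `k` matching the pattern's state
#'   space.
#' @param prior A [rate_prior()].
#' @param settings An [mcmc_settings()].
#' @param target_nodes Named list of taxon sets; each defines a node at
#'   which marginal state probabilities are recorded.
#' @param seed Integer seed; the chain is bit-reproducible given the seed.
#' @return An object of class `asr_bayes` with components `chain`
#'   (data.frame: generation, lnL, rates, tree index), `node_pp` (array:
#'   samples x nodes x states), plus the inputs and acceptance/window
#'   diagnostics.
#' @seealso [summary.asr_bayes()], [node_posterior()], [ess()]
#' @export
asr_bayes <- function(trees, pattern, model = mk_model(pattern$space$k),
                      prior = rate_prior(), settings = mcmc_settings(),
                      target_nodes = list(), seed = NULL) {
  stopifnot(inherits(pattern, "gene_pattern"), inherits(model, "mk_model"),
            inherits(prior, "rate_prior"), inherits(settings, "mcmc_settings"))
  if (model$k != pattern$space$k)
    stop("model k (", model$k, ") does not match state space k (",
         pattern$space$k, ")")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(target_nodes)) && length(target_nodes) > 0)
    names(target_nodes) <- paste0("node", seq_along(target_nodes))
  pts <- prep_tree_set(trees, pattern, target_nodes,
                       settings$scale_target_mean)
  w0 <- settings$window
  if (is.null(w0)) w0 <- (prior$upper - prior$lower) / 10
  window <- rep_len(w0, model$n_free)
  init <- stats::runif(model$n_free, prior$lower, prior$upper)
  res <- mk_mcmc_cpp(pts, cpp_pattern(model), model$n_free, prior$lower,
                     prior$upper, root_frequencies_safe(model),
                     model$root == "equilibrium", 1.0,
                     settings$generations, settings$thin, settings$burnin,
                     init, window, settings$adapt,
                     length(target_nodes) > 0, 1.0)
  nsamp <- length(res$lnL)
  gen_seq <- seq(from = settings$thin * ceiling((settings$burnin + 1) /
                                                  settings$thin),
                 by = settings$thin, length.out = nsamp)
  chain <- data.frame(generation = gen_seq, lnL = res$lnL)
  rates <- as.matrix(res$rates)
  colnames(rates) <- model$rate_names
  chain <- cbind(chain, rates)
  chain$tree_index <- as.integer(res$tree_index)
  node_pp <- NULL
  if (length(target_nodes) > 0) {
    node_pp <- res$marginals
    dimnames(node_pp) <- list(NULL, names(target_nodes),
                              pattern$space$labels)
  }
  structure(list(chain = chain, node_pp = node_pp,
                 target_nodes = target_nodes, pattern = pattern,
                 model = model, prior = prior, settings = settings,
                 seed = seed, accept_rate = res$accept_rate,
                 window = as.numeric(res$window), n_trees = length(pts)),
            class = "asr_bayes")
}

root_frequencies_safe <- function(model) rep(1 / model$k, model$k)

#' Rate MCMC pooled over many independent characters
#'
#' Posterior sampling of the free transition rates when many characters
#' evolve independently under one shared Mk model on the same tree(s):
#' the likelihood is the product over characters. Duplicate site patterns
#' are collapsed with weights before sampling. Used for
#' parameter-recovery simulation studies.
#'
#' @inheritParams asr_bayes
#' @param states Taxa x characters integer matrix of 0-based states
#'   (rownames = taxon labels, no missing values).
#' @return A data.frame chain with columns `lnL`, one per free rate, and
#'   `tree_index`.
#' @export
pooled_rate_mcmc <- function(trees, states, model, prior = rate_prior(),
                             settings = mcmc_settings(profile = "desk"),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(trees, "phylo")) trees <- as_tree_sample(c(trees))
  stopifnot(is.matrix(states), !is.null(rownames(states)), !anyNA(states))
  key <- apply(states, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  weights <- as.numeric(table(key)[key[uniq]])
  ustates <- states[, uniq, drop = FALSE]
  pts <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (settings$scale_target_mean > 0)
      tr <- scale_branches(tr, settings$scale_target_mean)
    prep_tree(tr, ustates)
  })
  window <- rep((prior$upper - prior$lower) / 10, model$n_free)
  init <- stats::runif(model$n_free, prior$lower, prior$upper)
  res <- mk_mcmc_cpp(pts, cpp_pattern(model), model$n_free, prior$lower,
                     prior$upper, rep(1 / model$k, model$k),
                     model$root == "equilibrium", 1.0,
                     settings$generations, settings$thin, settings$burnin,
                     init, window, settings$adapt, FALSE, weights)
  chain <- data.frame(lnL = res$lnL)
  rates <- as.matrix(res$rates)
  colnames(rates) <- model$rate_names
  chain <- cbind(chain, rates)
  chain$tree_index <- as.integer(res$tree_index)
  chain
}

#' @export
print.asr_bayes <- function(x, ...) {
  cat("Bayesian ancestral state reconstruction (Mk model)\n")
  cat(sprintf("  gene: %s  (%d taxa, k = %d, %s model)\n", x$pattern$gene,
              length(x$pattern$taxa), x$model$k, x$model$rates))
  cat(sprintf("  prior U(%g, %g); %d trees; %d generations (thin %d, burn-in %d)\n",
              x$prior$lower, x$prior$upper, x$n_trees,
              x$settings$generations, x$settings$thin, x$settings$burnin))
  cat(sprintf("  %d retained samples, acceptance %.2f\n", nrow(x$chain),
              x$accept_rate))
  cat("  posterior mean rate(s): ",
      paste(sprintf("%s = %.4g", x$model$rate_names, coef(x)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.asr_bayes <- function(object, ...) {
  m <- colMeans(object$chain[, object$model$rate_names, drop = FALSE])
  stats::setNames(as.numeric(m), object$model$rate_names)
}

#' @export
logLik.asr_bayes <- function(object, ...) {
  structure(mean(object$chain$lnL), df = object$model$n_free,
            class = "logLik")
}

#' Summarize an ASR fit
#'
#' Node-by-node mean posterior probabilities with ESS-adjusted Monte Carlo
#' standard errors, posterior rate summaries, and chain diagnostics.
#'
#' @param object An [asr_bayes()] fit.
#' @param ... Unused.
#' @return An object of class `summary.asr_bayes` with a `nodes`
#'   data.frame (node, state, mean_pp, mc_se), `rates` summary and ESS
#'   values.
#' @export
summary.asr_bayes <- function(object, ...) {
  nodes <- NULL
  if (!is.null(object$node_pp)) {
    nodes <- do.call(rbind, lapply(dimnames(object$node_pp)[[2]],
                                   function(nd) {
      np <- node_posterior(object, nd)
      data.frame(node = nd, state = names(np$mean_pp),
                 mean_pp = as.numeric(np$mean_pp),
                 mc_se = as.numeric(np$mc_se), row.names = NULL)
    }))
  }
  rn <- object$model$rate_names
  rates <- data.frame(
    rate = rn,
    mean = vapply(rn, function(r) mean(object$chain[[r]]), 0),
    sd = vapply(rn, function(r) stats::sd(object$chain[[r]]), 0),
    q2.5 = vapply(rn, function(r) stats::quantile(object$chain[[r]], .025), 0),
    q97.5 = vapply(rn, function(r) stats::quantile(object$chain[[r]], .975), 0),
    ess = vapply(rn, function(r) ess(object$chain[[r]]), 0),
    row.names = NULL)
  structure(list(nodes = nodes, rates = rates,
                 ess_lnL = ess(object$chain$lnL),
                 accept_rate = object$accept_rate,
                 n_samples = nrow(object$chain), fit = object),
            class = "summary.asr_bayes")
}

#' @export
print.summary.asr_bayes <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  ESS(lnL) = %.0f\n", x$ess_lnL))
  cat("\nPosterior rates:\n")
  print(x$rates, digits = 4, row.names = FALSE)
  if (!is.null(x$nodes)) {
    cat("\nNode posterior probabilities (mean over samples):\n")
    print(x$nodes, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Mean posterior state probabilities at a target node
#'
#' Arithmetic mean over retained samples of the per-sample exact node
#' marginals, with Monte Carlo standard errors computed from an
#' ESS-adjusted variance.
#'
#' @param fit An [asr_bayes()] fit.
#' @param node Name of a target node recorded in the fit.
#' @return An object of class `node_posterior`: list with `node`,
#'   `mean_pp` (named, sums to one), `mc_se`, `n`.
#' @export
node_posterior <- function(fit, node) {
  stopifnot(inherits(fit, "asr_bayes"))
  if (is.null(fit$node_pp)) stop("fit has no recorded target nodes")
  if (!node %in% dimnames(fit$node_pp)[[2]])
    stop("node not recorded in chain: ", node)
  pp <- fit$node_pp[, node, , drop = TRUE]
  if (is.null(dim(pp))) pp <- matrix(pp, ncol = dim(fit$node_pp)[3])
  m <- colMeans(pp)
  se <- vapply(seq_len(ncol(pp)), function(j) {
    s <- pp[, j]
    if (stats::sd(s) == 0) return(0)
    n_eff <- if (length(s) >= 10) ess(s) else length(s)
    sqrt(stats::var(s) / n_eff)
  }, 0)
  labels <- dimnames(fit$node_pp)[[3]]
  structure(list(node = node, mean_pp = stats::setNames(m, labels),
                 mc_se = stats::setNames(se, labels), n = nrow(pp)),
            class = "node_posterior")
}

#' @export
print.node_posterior <- function(x, ...) {
  cat("Node:", x$node, sprintf("(%d samples)\n", x$n))
  for (s in names(x$mean_pp))
    cat(sprintf("  %-16s PP = %.3f (MC SE %.4f)\n", s, x$mean_pp[[s]],
                x$mc_se[[s]]))
  invisible(x)
}

#' Trace, density and autocorrelation plots for an ASR chain
#'
#' @param x An [asr_bayes()] fit.
#' @param which_rate Rate name to plot (default: first free rate).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.asr_bayes <- function(x, which_rate = x$model$rate_names[1], ...) {
  s <- x$chain[[which_rate]]
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::plot(x$chain$generation, s, type = "l", xlab = "generation",
                 ylab = which_rate, main = "trace", ...)
  graphics::plot(stats::density(s), main = "posterior density",
                 xlab = which_rate)
  r <- autocorrelation(s, max_lag = min(50, floor(length(s) / 2) - 1))
  graphics::plot(seq_along(r) - 1, r, type = "h", xlab = "lag",
                 ylab = "autocorrelation", main = "autocorrelation")
  invisible(x)
}

#' Effective sample size
#'
#' Initial-positive-sequence estimator (Geyer): autocovariances are summed
#' in adjacent pairs until a pair sum turns non-positive, giving an
#' estimate of the autocorrelation time; ESS = n / autocorrelation time.
#' Antithetic (negatively autocorrelated) series can legitimately return
#' ESS > n. A constant series returns `n` with attribute
#' `degenerate = TRUE`.
#'
#' @param x Numeric series (length >= 10).
#' @return Effective sample size (scalar, possibly with a `degenerate`
#'   attribute).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10) stop("series too short for ESS estimation")
  if (stats::sd(x) == 0)
    return(structure(as.numeric(n), degenerate = TRUE))
  max_lag <- min(n - 2, 2000)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # pair sums Gamma_m = rho(2m) + rho(2m+1), summed while positive;
  # tau = -1 + 2 * sum_m Gamma_m
  tau_sum <- 0
  m <- 0
  repeat {
    i1 <- 2 * m + 1 # R index of lag 2m
    i2 <- 2 * m + 2
    if (i2 > length(ac)) break
    g <- ac[i1] + ac[i2]
    if (g <= 0) break
    tau_sum <- tau_sum + g
    m <- m + 1
  }
  tau <- max(-1 + 2 * tau_sum, .Machine$double.eps)
  as.numeric(n / tau)
}

#' Autocorrelation function of a chain
#'
#' Standard biased autocovariance estimator normalized by lag 0.
#'
#' @param x Numeric series.
#' @param max_lag Maximum lag, `< length(x) / 2`.
#' @return Numeric vector of correlations for lags `0..max_lag`.
#' @export
autocorrelation <- function(x, max_lag) {
  n <- length(x)
  if (max_lag >= n / 2) stop("max_lag must be < n/2")
  stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
}
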