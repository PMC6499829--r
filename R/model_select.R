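#' Stepping-stone sampler settings
#'
#' Defaults mirror the study-scale protocol (1,000 stones of 100,000
#' iterations each); the package's tests use a desk-scale 100 x 10,000.
#' Stone powers are spaced as quantiles of a Beta(`alpha`, 1)
#' distribution, concentrating stones near the prior where the power
#' posterior changes fastest.
#'
#' @param stones Number of stones (>= 2).
#' @param iterations MCMC iterations per stone.
#' @param alpha Beta shape parameter for power spacing.
#' @param burn_frac Fraction of each stone's iterations discarded before
#'   collecting likelihoods.
#' @return An object of class `ss_settings`.
#' @export
ss_settings <- function(stones = 1000, iterations = 1e5, alpha = 0.4,
                        burn_frac = 0.1) {
  stopifnot(stones >= 2, iterations >= 10, alpha > 0,
            burn_frac >= 0, burn_frac < 1)
  structure(list(stones = as.integer(stones),
                 iterations = as.integer(iterations), alpha = alpha,
                 burn_frac = burn_frac),
            class = "ss_settings")
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Runs a path of power posteriors `L(q)^beta * prior(q)` from the prior
#' (`beta = 0`) to the posterior (`beta = 1`) with powers at Beta(alpha, 1)
#' quantiles, and sums the per-stone log ratio estimates
#' `ln E_beta_k[L^(beta_{k+1} - beta_k)]`. Trees are drawn uniformly from
#' the sample within each stone's MCMC, as in [asr_bayes()].
#'
#' With `node_constraint`, the likelihood restricts the named internal
#' node to a fixed state by masking all other states' partial likelihoods
#' at that node ("fossilizing"), which is the mechanism behind node-fixed
#' hypothesis tests.
#'
#' @inheritParams asr_bayes
#' @param ss An [ss_settings()].
#' @param node_constraint Optional `list(taxa =, state =)`: fix the MRCA
#'   of `taxa` to 0-based state `state`.
#' @return An object of class `stepping_stone`: list with `logml`, `se`
#'   (Monte Carlo standard error from ESS-adjusted per-stone variances),
#'   `stones` (per-stone data.frame) and the settings used.
#' @export
stepping_stone_logml <- function(trees, pattern,
                                 model = mk_model(pattern$space$k),
                                 prior = rate_prior(), ss = ss_settings(),
                                 node_constraint = NULL, seed = NULL,
                                 scale_target_mean = 0.1) {
  stopifnot(inherits(pattern, "gene_pattern"), inherits(model, "mk_model"),
            inherits(prior, "rate_prior"), inherits(ss, "ss_settings"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(node_constraint)) {
    if (node_constraint$state < 0 || node_constraint$state >= model$k)
      stop("constrained state index out of range [0, k)")
  }
  pts <- prep_tree_set(trees, pattern, list(), scale_target_mean,
                       constraint = node_constraint)
  betas <- stats::qbeta(seq(0, 1, length.out = ss$stones + 1), ss$alpha, 1)
  rates <- stats::runif(model$n_free, prior$lower, prior$upper)
  window <- rep((prior$upper - prior$lower) / 10, model$n_free)
  burn <- max(1L, as.integer(round(ss$burn_frac * ss$iterations)))
  keep <- ss$iterations - burn
  log_ratios <- numeric(ss$stones)
  vars <- numeric(ss$stones)
  rootf <- rep(1 / model$k, model$k)
  for (s in seq_len(ss$stones)) {
    b0 <- betas[s]; b1 <- betas[s + 1]
    res <- mk_mcmc_cpp(pts, cpp_pattern(model), model$n_free, prior$lower,
                       prior$upper, rootf,
                       model$root == "equilibrium", b0,
                       ss$iterations, 1L, burn, rates, window,
                       s == 1L, FALSE, 1.0)
    rates <- res$final_rates
    window <- res$window
    d <- b1 - b0
    lw <- d * res$lnL
    mx <- max(lw)
    w <- exp(lw - mx)
    log_ratios[s] <- mx + log(mean(w))
    # delta-method variance of the log mean, ESS-adjusted
    n_eff <- if (stats::sd(w) == 0 || length(w) < 10) length(w) else
      min(length(w), ess(w))
    vars[s] <- if (mean(w) > 0) stats::var(w) / (n_eff * mean(w)^2) else 0
  }
  structure(list(logml = sum(log_ratios), se = sqrt(sum(vars)),
                 stones = data.frame(beta_from = betas[-length(betas)],
                                     beta_to = betas[-1],
                                     log_ratio = log_ratios,
                                     var = vars),
                 settings = ss, constraint = node_constraint),
            class = "stepping_stone")
}

#' @export
print.stepping_stone <- function(x, ...) {
  cat(sprintf("Stepping-stone log marginal likelihood: %.4f (MC SE %.4f)\n",
              x$logml, x$se))
  cat(sprintf("  %d stones, %d iterations each\n", x$settings$stones,
              x$settings$iterations))
  if (!is.null(x$constraint))
    cat(sprintf("  node constraint: MRCA(%s) fixed to state %d\n",
                paste(x$constraint$taxa, collapse = ","),
                x$constraint$state))
  invisible(x)
}

#' Bayes factor from two log marginal likelihoods
#'
#' Computes the statistic `2 * (lnML0 - lnML1)` and classifies its
#' magnitude on the conventional interpretation scale: 0-2 negligible,
#' 2-6 positive, 6-10 strong, > 10 very strong (sign-symmetric; the sign
#' says which hypothesis is favored).
#'
#' @param lnml0,lnml1 Log marginal likelihoods of hypotheses 0 and 1
#'   (scalars or `stepping_stone` objects).
#' @return An object of class `bayes_factor` with `statistic`
#'   (`2 ln BF`), `category`, `favors` (0 or 1; `NA` when exactly 0) and
#'   the inputs.
#' @export
bayes_factor <- function(lnml0, lnml1) {
  if (inherits(lnml0, "stepping_stone")) lnml0 <- lnml0$logml
  if (inherits(lnml1, "stepping_stone")) lnml1 <- lnml1$logml
  if (is.na(lnml0) || is.na(lnml1)) stop("NaN/NA log marginal likelihood")
  stat <- 2 * (lnml0 - lnml1)
  a <- abs(stat)
  category <- if (a < 2) "negligible" else if (a < 6) "positive" else
    if (a < 10) "strong" else "very strong"
  structure(list(statistic = stat, category = category,
                 favors = if (stat > 0) 0L else if (stat < 0) 1L else
                   NA_integer_,
                 lnml0 = lnml0, lnml1 = lnml1),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("2 ln BF = %.3f (%s%s)\n", x$statistic, x$category,
              if (!is.na(x$favors))
                paste0(", favors hypothesis ", x$favors) else ""))
  invisible(x)
}

#' Compare two rate models by Bayes factor
#'
#' Two stepping-stone runs on the same data (e.g. single-rate vs two-rate
#' for a binary character, or single-rate vs all-rates-different for a
#' multistate one) and their Bayes factor.
#'
#' @inheritParams stepping_stone_logml
#' @param model0,model1 Two [mk_model()] objects sharing `k`.
#' @return A `bayes_factor` whose hypotheses 0/1 are `model0`/`model1`,
#'   with the two `stepping_stone` fits attached as `ss0`, `ss1`.
#' @export
compare_rate_models <- function(trees, pattern, model0, model1,
                                prior = rate_prior(), ss = ss_settings(),
                                seed = NULL, scale_target_mean = 0.1) {
  if (model0$k != model1$k) stop("models must share the number of states")
  if (!is.null(seed)) set.seed(seed)
  f0 <- stepping_stone_logml(trees, pattern, model0, prior, ss,
                             scale_target_mean = scale_target_mean)
  f1 <- stepping_stone_logml(trees, pattern, model1, prior, ss,
                             scale_target_mean = scale_target_mean)
  bf <- bayes_factor(f0, f1)
  bf$ss0 <- f0
  bf$ss1 <- f1
  bf
}
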