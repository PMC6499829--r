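#' Run the full reconstruction for one gene
#'
#' End-to-end per-gene analysis: restrict the character matrix to the
#' gene's scored taxa, prune every chronogram in the tree sample
#' accordingly, scale branch lengths, run the rate MCMC, and report mean
#' posterior state probabilities at every named ancestral clade resolvable
#' on the pruned tree, together with convergence diagnostics and full
#' provenance.
#'
#' @param gene Gene name present in the dataset's matrix.
#' @param dataset An [echinoderm_dataset()]-shaped list (`matrix`,
#'   `clades`, and either `topology` + `calibrations` or your own trees).
#' @param trees A tree sample; if `NULL`, `n_trees` chronograms are drawn
#'   from the dataset's calibrations.
#' @param n_trees Number of chronograms to sample when `trees` is `NULL`.
#' @param model An [mk_model()]; defaults to single-rate with the gene's
#'   `k`.
#' @param prior A [rate_prior()].
#' @param settings An [mcmc_settings()].
#' @param seed Integer seed covering tree sampling and MCMC.
#' @return An object of class `gene_asr_report`: list with `fit` (the
#'   [asr_bayes()] object), `nodes` (per-node, per-state mean PP table
#'   with MC SE), `diagnostics` (ESS, acceptance, low-ESS flag), and
#'   `provenance`.
#' @export
run_gene_analysis <- function(gene, dataset = echinoderm_dataset(),
                              trees = NULL, n_trees = 100,
                              model = NULL, prior = rate_prior(),
                              settings = mcmc_settings(profile = "desk"),
                              seed = 1L) {
  set.seed(seed)
  pattern <- restrict_pattern(dataset$matrix, gene)
  if (is.null(model)) model <- mk_model(pattern$space$k)
  if (is.null(trees))
    trees <- sample_tree_set(dataset$topology, dataset$calibrations,
                             n = n_trees)
  targets <- resolvable_clades(dataset$clades, pattern$taxa, trees[[1]])
  fit <- asr_bayes(trees, pattern, model, prior, settings,
                   target_nodes = targets)
  sm <- summary(fit)
  diag_ess <- sm$ess_lnL
  report <- structure(list(
    gene = gene, fit = fit, nodes = sm$nodes, rates = sm$rates,
    diagnostics = list(ess_lnL = diag_ess, accept_rate = fit$accept_rate,
                       low_ess = diag_ess < 100),
    provenance = list(seed = seed, n_trees = length(trees),
                      prior = c(fit$prior$lower, fit$prior$upper),
                      model = model$rates,
                      settings = unclass(fit$settings)[c("generations",
                                                         "thin", "burnin")],
                      matrix_hash = pattern_hash(pattern))),
    class = "gene_asr_report")
  if (report$diagnostics$low_ess)
    warning("ESS of lnL below 100 for gene ", gene,
            "; treat node PPs with caution")
  report
}

# clades resolvable on the pruned tree: >= 2 scored taxa whose MRCA is
# internal after pruning
resolvable_clades <- function(clades, scored_taxa, tree) {
  pruned <- if (length(scored_taxa) < length(tree$tip.label))
    prune_to_taxa(tree, scored_taxa) else tree
  out <- list()
  for (nm in names(clades)) {
    tx <- intersect(clades[[nm]], scored_taxa)
    if (length(tx) < 2) next
    out[[nm]] <- tx
  }
  # drop clades collapsing onto the same node as a larger clade is fine;
  # each is still reported under its own label
  out
}

pattern_hash <- function(pattern) {
  s <- paste(pattern$gene, paste(names(pattern$states), pattern$states,
                                 sep = "=", collapse = ";"))
  # small stable checksum without external dependencies
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000000007
}

#' @export
print.gene_asr_report <- function(x, ...) {
  cat("Gene analysis report:", x$gene, "\n")
  cat(sprintf("  trees: %d  ESS(lnL): %.0f  acceptance: %.2f%s\n",
              x$provenance$n_trees, x$diagnostics$ess_lnL,
              x$diagnostics$accept_rate,
              if (x$diagnostics$low_ess) "  [LOW ESS]" else ""))
  cat("\nMean posterior probabilities at ancestral nodes:\n")
  print(x$nodes, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a per-node posterior report as TSV
#'
#' @param report A `gene_asr_report`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_node_report <- function(report, file) {
  utils::write.table(report$nodes, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write the MCMC chain log as TSV
#'
#' Columns: generation, lnL, one per free rate, tree_index.
#'
#' @param fit An [asr_bayes()] fit.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_chain_log <- function(fit, file) {
  stopifnot(inherits(fit, "asr_bayes"))
  utils::write.table(fit$chain, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read an analysis configuration file
#'
#' A YAML file collecting the knobs of [run_gene_analysis()]: `gene`,
#' `model` (k, rates, root), `prior` (lower, upper), `settings`
#' (generations, thin, burnin, scale_target_mean), `n_trees` and `seed`.
#' Omitted entries keep the package defaults.
#'
#' @param file Path to the YAML file.
#' @return A named list with `gene`, `model`, `prior`, `settings`,
#'   `n_trees`, `seed`, ready to splice into [run_gene_analysis()].
#' @export
read_analysis_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$gene)) stop("config must name a gene")
  model <- NULL
  if (!is.null(cfg$model))
    model <- mk_model(cfg$model$k %||% 2,
                      cfg$model$rates %||% "single",
                      cfg$model$root %||% "uniform")
  prior <- rate_prior(cfg$prior$lower %||% 0, cfg$prior$upper %||% 2)
  s <- cfg$settings
  settings <- mcmc_settings(
    generations = s$generations %||% 5e5,
    thin = s$thin %||% 100,
    burnin = s$burnin %||% 1e5,
    scale_target_mean = s$scale_target_mean %||% 0.1)
  list(gene = cfg$gene, model = model, prior = prior, settings = settings,
       n_trees = cfg$n_trees %||% 100, seed = cfg$seed %||% 1L)
}

#' Run a gene analysis from a configuration file
#'
#' @param file Path to a [read_analysis_config()] YAML file.
#' @param dataset Dataset list as in [run_gene_analysis()].
#' @param trees Optional tree sample overriding `n_trees` sampling.
#' @return A `gene_asr_report`.
#' @export
run_configured_analysis <- function(file, dataset = echinoderm_dataset(),
                                    trees = NULL) {
  cfg <- read_analysis_config(file)
  run_gene_analysis(cfg$gene, dataset, trees = trees, n_trees = cfg$n_trees,
                    model = cfg$model, prior = cfg$prior,
                    settings = cfg$settings, seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prior / model / taxon-sampling sensitivity suite
#'
#' Re-runs [run_gene_analysis()] for one gene over a grid of rate priors,
#' rate models and taxon subsets, and cross-tabulates the node posterior
#' probabilities, flagging nodes whose most-probable state changes across
#' conditions.
#'
#' @inheritParams run_gene_analysis
#' @param priors List of [rate_prior()] objects (default the four
#'   standard widths U(0,0.2), U(0,2), U(0,20), U(0,200)).
#' @param models List of [mk_model()] objects; `NULL` means single-rate
#'   only.
#' @param taxon_subsets Named list of taxon sets (default: full, plus one
#'   genus per class).
#' @return An object of class `sensitivity_report`: `table` (long
#'   data.frame: prior, model, subset, node, state, mean_pp),
#'   `flagged_nodes` (nodes whose modal state is condition-dependent) and
#'   the per-condition reports.
#' @export
run_sensitivity_suite <- function(gene, dataset = echinoderm_dataset(),
                                  trees = NULL, n_trees = 100,
                                  priors = list(rate_prior(0, 0.2),
                                                rate_prior(0, 2),
                                                rate_prior(0, 20),
                                                rate_prior(0, 200)),
                                  models = NULL,
                                  taxon_subsets = NULL,
                                  settings = mcmc_settings(profile = "desk"),
                                  seed = 1L) {
  set.seed(seed)
  k <- dataset$matrix$spaces[[gene]]$k
  if (is.null(models)) models <- list(single = mk_model(k))
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "rates")
  if (is.null(taxon_subsets))
    taxon_subsets <- list(full = dataset$matrix$taxa,
                          one_per_class = one_per_class_taxa(dataset))
  if (is.null(trees))
    trees <- sample_tree_set(dataset$topology, dataset$calibrations,
                             n = n_trees)
  rows <- list()
  reports <- list()
  for (si in names(taxon_subsets)) {
    for (mi in names(models)) {
      for (pi in seq_along(priors)) {
        pr <- priors[[pi]]
        pr_label <- sprintf("U(%g,%g)", pr$lower, pr$upper)
        ds <- dataset
        pattern <- restrict_pattern(dataset$matrix, gene,
                                    taxa = taxon_subsets[[si]])
        targets <- resolvable_clades(dataset$clades, pattern$taxa,
                                     trees[[1]])
        fit <- asr_bayes(trees, pattern, models[[mi]], pr, settings,
                         target_nodes = targets)
        nodes <- summary(fit)$nodes
        nodes$prior <- pr_label
        nodes$model <- mi
        nodes$subset <- si
        key <- paste(si, mi, pr_label, sep = "|")
        rows[[key]] <- nodes
        reports[[key]] <- fit
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  modal <- stats::aggregate(mean_pp ~ node + prior + model + subset,
                            data = tab, FUN = max)
  modal$state <- tab$state[match(
    paste(modal$node, modal$prior, modal$model, modal$subset, modal$mean_pp),
    paste(tab$node, tab$prior, tab$model, tab$subset, tab$mean_pp))]
  flip <- stats::aggregate(state ~ node, data = modal,
                           FUN = function(s) length(unique(s)))
  flagged <- flip$node[flip$state > 1]
  structure(list(gene = gene, table = tab, modal = modal,
                 flagged_nodes = flagged, fits = reports),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity suite for", x$gene, "-",
      length(unique(paste(x$table$prior, x$table$model, x$table$subset))),
      "conditions\n")
  if (length(x$flagged_nodes) > 0)
    cat("Nodes whose modal state changes across conditions:",
        paste(x$flagged_nodes, collapse = ", "), "\n")
  else cat("Modal states stable across all conditions\n")
  invisible(x)
}

#' Node-fixed hypothesis tests at a named clade
#'
#' For each candidate state, estimates the stepping-stone log marginal
#' likelihood with the clade's MRCA fixed to that state, then reports all
#' pairwise `2 ln BF` statistics with their interpretation categories.
#'
#' @inheritParams run_gene_analysis
#' @param clade Name of a clade in `dataset$clades` (e.g. `"Asterozoa"`).
#' @param states 0-based states to test (default: all k states).
#' @param ss An [ss_settings()].
#' @return An object of class `node_bf_report`: `logml` (per-state
#'   data.frame), `bf` (pairwise data.frame with `2 ln BF` and category)
#'   and provenance.
#' @export
run_node_hypothesis_tests <- function(gene, clade,
                                      dataset = echinoderm_dataset(),
                                      trees = NULL, n_trees = 50,
                                      model = NULL, prior = rate_prior(),
                                      ss = ss_settings(stones = 100,
                                                       iterations = 1e4),
                                      seed = 1L) {
  set.seed(seed)
  pattern <- restrict_pattern(dataset$matrix, gene)
  if (is.null(model)) model <- mk_model(pattern$space$k)
  if (is.null(trees))
    trees <- sample_tree_set(dataset$topology, dataset$calibrations,
                             n = n_trees)
  taxa <- intersect(dataset$clades[[clade]], pattern$taxa)
  if (length(taxa) < 2) stop("clade ", clade,
                             " has fewer than 2 scored taxa for ", gene)
  states <- 0:(pattern$space$k - 1)
  fits <- lapply(states, function(s)
    stepping_stone_logml(trees, pattern, model, prior, ss,
                         node_constraint = list(taxa = taxa, state = s)))
  logml <- data.frame(state = states,
                      label = pattern$space$labels[states + 1],
                      logml = vapply(fits, `[[`, 0, "logml"),
                      se = vapply(fits, `[[`, 0, "se"))
  pairs <- utils::combn(seq_along(states), 2)
  bf <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i0 <- pairs[1, j]; i1 <- pairs[2, j]
    b <- bayes_factor(fits[[i0]]$logml, fits[[i1]]$logml)
    data.frame(state0 = states[i0], state1 = states[i1],
               two_ln_bf = b$statistic, category = b$category,
               favors = c(states[i0], states[i1])[b$favors + 1L])
  }))
  structure(list(gene = gene, clade = clade, logml = logml, bf = bf,
                 fits = fits,
                 provenance = list(seed = seed, n_trees = length(trees),
                                   stones = ss$stones,
                                   iterations = ss$iterations)),
            class = "node_bf_report")
}

#' @export
print.node_bf_report <- function(x, ...) {
  cat(sprintf("Node-fixed hypothesis tests: %s at the %s MRCA\n", x$gene,
              x$clade))
  print(x$logml, digits = 5, row.names = FALSE)
  cat("\nPairwise 2 ln BF (positive favors the first state):\n")
  print(x$bf, digits = 4, row.names = FALSE)
  invisible(x)
}
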