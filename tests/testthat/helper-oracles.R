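# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately avoid the package's pruning code paths: they
# enumerate internal-node state assignments directly.

# joint probability of one full assignment of states to all nodes
assignment_prob <- function(tree, full, P, root_freqs) {
  ntip <- ape::Ntip(tree)
  term <- root_freqs[full[ntip + 1L] + 1]
  for (e in seq_len(nrow(tree$edge))) {
    term <- term * P[[e]][full[tree$edge[e, 1]] + 1, full[tree$edge[e, 2]] + 1]
  }
  term
}

enum_grid <- function(tree, k) {
  as.matrix(expand.grid(rep(list(0:(k - 1)), tree$Nnode)))
}

edge_pmats <- function(tree, Q) {
  lapply(seq_len(nrow(tree$edge)),
         function(e) expm_via_series(Q, tree$edge.length[e]))
}

# matrix exponential by plain truncated Taylor series with scaling —
# independent of the package's closed forms and of arma::expmat
expm_via_series <- function(Q, t) {
  A <- Q * t
  s <- max(0, ceiling(log2(max(1, max(abs(A))))))
  A <- A / 2^s
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (i in 1:30) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

enum_loglik <- function(tree, states, Q, root_freqs, constraint_node = NULL,
                        constraint_state = NULL) {
  k <- nrow(Q)
  ntip <- ape::Ntip(tree)
  P <- edge_pmats(tree, Q)
  grid <- enum_grid(tree, k)
  sts <- states[tree$tip.label]
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    full <- c(as.integer(sts), as.integer(grid[r, ]))
    if (!is.null(constraint_node) &&
        full[constraint_node] != constraint_state) next
    tot <- tot + assignment_prob(tree, full, P, root_freqs)
  }
  log(tot)
}

enum_marginal <- function(tree, states, Q, root_freqs, node) {
  k <- nrow(Q)
  ntip <- ape::Ntip(tree)
  P <- edge_pmats(tree, Q)
  grid <- enum_grid(tree, k)
  sts <- states[tree$tip.label]
  post <- rep(0, k)
  for (r in seq_len(nrow(grid))) {
    full <- c(as.integer(sts), as.integer(grid[r, ]))
    post[full[node] + 1] <- post[full[node] + 1] +
      assignment_prob(tree, full, P, root_freqs)
  }
  post / sum(post)
}

# random non-ultrametric tree with lengths in a likelihood-friendly range
random_instance <- function(ntip, k, model_kind = "single") {
  tr <- ape::rtree(ntip)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  m <- mk_model(k, model_kind)
  Q <- rate_matrix(m, stats::runif(m$n_free, 0.1, 1.5))
  st <- stats::setNames(sample(0:(k - 1), ntip, replace = TRUE),
                        tr$tip.label)
  list(tree = tr, Q = Q, states = st, model = m)
}

# wrap a named 0-based state vector as the gene_pattern the fitters expect
make_pattern <- function(states, labels = NULL, gene = "sim") {
  k <- max(states) + 1L
  if (is.null(labels)) labels <- paste0("s", seq_len(max(2, k)) - 1L)
  sp <- state_space(gene, labels)
  structure(list(gene = gene, states = states, taxa = names(states),
                 space = sp),
            class = "gene_pattern")
}

# one fixed small ultrametric tree reused by several suites
fixed_five_tip <- function() {
  parse_newick("(((A:0.08,B:0.08):0.05,C:0.13):0.07,(D:0.1,E:0.1):0.1);")
}
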