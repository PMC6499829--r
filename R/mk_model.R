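#' Specify an Mk model
#'
#' Defines a continuous-time Markov (Mk) model for a discrete character
#' with `k` states: the constraint pattern tying the `k(k-1)` off-diagonal
#' instantaneous rates to free parameters, and the root state distribution.
#'
#' Constraint patterns:
#' * `"single"`: all off-diagonal rates equal (one free rate; for binary
#'   characters this constrains q01 = q10),
#' * `"two_rate"`: binary characters only; q01 and q10 free,
#' * `"ard"`: all `k(k-1)` rates different.
#'
#' @param k Number of states (>= 2).
#' @param rates Constraint pattern.
#' @param root Root state distribution: `"uniform"` (1/k each, the
#'   default) or `"equilibrium"` (stationary distribution of the rate
#'   matrix, recomputed as rates change).
#' @return An object of class `mk_model` with elements `k`, `pattern`
#'   (k x k integer matrix mapping off-diagonals to 1-based free-rate
#'   indices), `n_free`, `rates_name`, `root`.
#' @export
mk_model <- function(k, rates = c("single", "two_rate", "ard"),
                     root = c("uniform", "equilibrium")) {
  rates <- match.arg(rates)
  root <- match.arg(root)
  stopifnot(k >= 2, k == as.integer(k))
  k <- as.integer(k)
  if (rates == "two_rate" && k != 2)
    stop("two_rate is defined for binary characters only; use \"ard\"")
  pat <- matrix(NA_integer_, k, k)
  if (rates == "single") {
    pat[row(pat) != col(pat)] <- 1L
    n_free <- 1L
  } else { # two_rate (k = 2) and ard share row-major free-rate ordering
    idx <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      idx <- idx + 1L
      pat[i, j] <- idx
    }
    n_free <- idx
  }
  free_names <- if (rates == "single") "q" else {
    nm <- character(n_free)
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
      nm[pat[i, j]] <- sprintf("q%d%d", i - 1L, j - 1L)
    nm
  }
  structure(list(k = k, rates = rates, pattern = pat, n_free = n_free,
                 rate_names = free_names, root = root),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("Mk model: k = %d, %s (%d free rate%s), root = %s\n",
              x$k, x$rates, x$n_free, if (x$n_free > 1) "s" else "", x$root))
  invisible(x)
}

#' Build the instantaneous rate matrix Q
#'
#' Fills the off-diagonals of a `k x k` rate matrix from the free-rate
#' vector according to the model's constraint pattern, and sets the
#' diagonal so every row sums to zero.
#'
#' @param model An [mk_model()].
#' @param rates Non-negative numeric vector of length `model$n_free`, in
#'   the order given by `model$rate_names` (row-major over off-diagonals).
#' @return A `k x k` rate matrix.
#' @export
rate_matrix <- function(model, rates) {
  stopifnot(inherits(model, "mk_model"))
  if (length(rates) != model$n_free)
    stop("expected ", model$n_free, " rates, got ", length(rates))
  if (any(rates < 0) || anyNA(rates)) stop("rates must be non-negative")
  Q <- matrix(0, model$k, model$k)
  off <- !is.na(model$pattern)
  Q[off] <- rates[model$pattern[off]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Root state frequencies for a model
#'
#' @param model An [mk_model()].
#' @param Q Rate matrix (required for `root = "equilibrium"`).
#' @return A probability vector of length `k`.
#' @export
root_frequencies <- function(model, Q = NULL) {
  if (model$root == "uniform") return(rep(1 / model$k, model$k))
  if (is.null(Q)) stop("equilibrium root frequencies require Q")
  stationary_distribution(Q)
}

#' Stationary distribution of a rate matrix
#'
#' Solves pi' Q = 0 with pi summing to one.
#'
#' @param Q A rate matrix (rows sum to zero).
#' @return A probability vector.
#' @export
stationary_distribution <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Closed form for binary and equal-rates models, scaling-and-squaring
#' matrix exponential otherwise. Rows sum to one.
#'
#' @param Q Rate matrix.
#' @param t Branch length (>= 0).
#' @return A `k x k` stochastic matrix.
#' @export
transition_prob <- function(Q, t) {
  if (t < 0) stop("branch length must be non-negative")
  expm_qt(Q, t)
}

# --- internal: convert a phylo + pattern into the list the C++ core reads --
#
# states: named 0-based integer vector (single character) or a taxa x nchar
# integer matrix. target_taxa: list of taxon sets defining marginal-recording
# nodes. constraint: NULL or list(taxa =, state =) fixing an internal node.
prep_tree <- function(tree, states, target_taxa = list(), constraint = NULL) {
  validate_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(po)
  if (is.null(dim(states))) states <- matrix(states, ncol = 1,
                                             dimnames = list(names(states)))
  if (is.null(rownames(states))) stop("states must be named by taxon")
  miss <- setdiff(po$tip.label, rownames(states))
  if (length(miss) > 0)
    stop("tip(s) without a state: ", paste(miss, collapse = ", "),
         " (prune the tree to scored taxa first)")
  ts <- states[po$tip.label, , drop = FALSE]
  if (anyNA(ts)) stop("missing state at a retained tip; prune instead")
  targets <- vapply(target_taxa, function(tx) mrca_node(po, tx), integer(1))
  cnode <- 0L; cstate <- -1L
  if (!is.null(constraint)) {
    cnode <- mrca_node(po, constraint$taxa)
    cstate <- as.integer(constraint$state)
    if (cstate < 0) stop("constrained state index out of range")
  }
  list(edge = po$edge, elen = po$edge.length, ntip = ntip,
       tipstates = matrix(as.integer(ts), nrow = ntip),
       targets = as.integer(targets), cnode = cnode, cstate = cstate)
}

#' Felsenstein pruning log-likelihood
#'
#' Computes the log-likelihood of tip states under the Mk process with
#' rate matrix `Q` by post-order pruning with per-node rescaling. With a
#' matrix of tip states (taxa x characters), characters are treated as
#' independent and the summed log-likelihood is returned.
#'
#' @param tree A `phylo` tree whose tips are exactly the scored taxa.
#' @param states Named 0-based integer vector of tip states (or a taxa x
#'   characters integer matrix).
#' @param Q Rate matrix.
#' @param root_freqs Root state distribution (default uniform).
#' @param constraint Optional `list(taxa =, state =)` fixing the MRCA of
#'   `taxa` to `state` (partial-likelihood masking, as used in node-fixed
#'   hypothesis tests).
#' @return The log-likelihood (sum over characters).
#' @export
pruning_loglik <- function(tree, states, Q,
                           root_freqs = rep(1 / nrow(Q), nrow(Q)),
                           constraint = NULL) {
  check_states(states, nrow(Q))
  pt <- prep_tree(tree, states, constraint = constraint)
  ll <- tree_loglik_cpp(pt, Q, root_freqs, equal_rates_q(Q))
  sum(ll)
}

#' Brute-force log-likelihood by enumeration
#'
#' Explicitly sums, over all joint assignments of states to internal
#' nodes, the product of root frequency and per-branch transition
#' probabilities. Exponential in the number of internal nodes; intended as
#' an independent oracle for [pruning_loglik()] on small trees.
#'
#' @inheritParams pruning_loglik
#' @return The log-likelihood.
#' @export
brute_force_loglik <- function(tree, states, Q,
                               root_freqs = rep(1 / nrow(Q), nrow(Q))) {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  if (nint > 8) stop("too many internal nodes for enumeration")
  k <- nrow(Q)
  states <- states[tree$tip.label]
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) transition_prob(Q, tree$edge.length[e]))
  root <- ntip + 1L
  grid <- as.matrix(expand.grid(rep(list(0:(k - 1)), nint)))
  lik <- 0
  for (r in seq_len(nrow(grid))) {
    # full state vector indexed by node id (tips 1..ntip, internals after)
    full <- integer(ntip + nint)
    full[seq_len(ntip)] <- states
    full[(ntip + 1):(ntip + nint)] <- grid[r, ]
    term <- root_freqs[full[root] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
      term <- term * P[[e]][full[p] + 1, full[c] + 1]
    }
    lik <- lik + term
  }
  log(lik)
}

#' Exact marginal state distribution at an internal node
#'
#' The conditional distribution of an internal node's state given all tip
#' states and fixed rates, combining below-node partial likelihoods with
#' above-node partials (the two-pass algorithm). Sums to one.
#'
#' @inheritParams pruning_loglik
#' @param node Taxon set (character vector) whose MRCA is the query node,
#'   or an internal node id.
#' @return A named probability vector of length `k`.
#' @export
node_marginal <- function(tree, states, Q,
                          root_freqs = rep(1 / nrow(Q), nrow(Q)), node) {
  check_states(states, nrow(Q))
  ntip <- ape::Ntip(tree)
  if (is.character(node)) {
    pt <- prep_tree(tree, states, target_taxa = list(node))
    if (pt$targets[1] <= ntip) stop("node is a tip, not an internal node")
  } else {
    node <- as.integer(node)
    if (node <= ntip) stop("node is a tip, not an internal node")
    po <- ape::reorder.phylo(tree, "postorder")
    # node ids are preserved by reordering, so map directly
    pt <- prep_tree(tree, states)
    pt$targets <- node
  }
  m <- node_marginals_cpp(pt, Q, root_freqs, equal_rates_q(Q), 1L)
  drop(m)
}

check_states <- function(states, k) {
  v <- as.integer(states)
  v <- v[!is.na(v)]
  if (any(v < 0 | v >= k)) stop("state index out of range [0, k)")
  invisible(TRUE)
}

# 0-based constraint pattern for the C++ core (diagonal entries unused)
cpp_pattern <- function(model) {
  p <- model$pattern
  p[is.na(p)] <- 1L
  p - 1L
}

# All off-diagonal rates equal? (enables the closed-form P(t))
equal_rates_q <- function(Q) {
  off <- Q[row(Q) != col(Q)]
  diff(range(off)) <= 1e-14 * max(abs(off), 1e-300)
}
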