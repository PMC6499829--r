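#' Gamma prior parameters for a relaxed molecular clock
#'
#' Converts a point estimate of the substitution rate (e.g. from a
#' strict-clock fit) and a scale into the shape/rate parameters of the
#' gamma prior placed on the mean clock rate:
#' `alpha = (mean_rate / scale)^2`, `beta = mean_rate / scale^2`, so the
#' implied gamma mean `alpha / beta` equals `mean_rate`. With the strict
#' clock estimate 0.016 substitutions per unit time and scale 0.016 this
#' gives `alpha = 1`, `beta = 62.5`.
#'
#' @param mean_rate Positive substitution rate per unit time.
#' @param scale Positive scale in the same units.
#' @return Named numeric vector `c(alpha =, beta =)`.
#' @examples
#' gamma_clock_prior(0.016, 0.016) # alpha 1, beta 62.5
#' @export
gamma_clock_prior <- function(mean_rate, scale) {
  if (!is.numeric(mean_rate) || mean_rate <= 0)
    stop("mean_rate must be positive")
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  c(alpha = (mean_rate / scale)^2, beta = mean_rate / scale^2)
}

#' The seven echinoderm fossil calibrations
#'
#' Hard minimum and maximum bounds (Ma) on the ages of seven named
#' divergences, each anchored by first/absence fossil occurrences:
#' cidaroid-euechinoid, camarodont-irregular, holothuroid-echinoid,
#' neognathostomate-atelostomate, asterozoan-echinozoan,
#' asteroid-ophiuroid, and holothuriid-neoholothuriid splits. Taxon pairs
#' refer to the 12-genus example topology ([echinoderm_dataset()]); remap
#' them for other tip sets.
#'
#' @return A data.frame of class `calibration_table` with columns `clade`,
#'   `taxon_a`, `taxon_b`, `min`, `max`.
#' @export
default_calibrations <- function() {
  tab <- data.frame(
    clade = c("Eleutherozoa", "Asterozoa", "Echinozoa", "Holothuroidea",
              "Echinoidea", "Euechinoidea", "Irregularia"),
    taxon_a = c("Patiria", "Patiria", "Holothuria", "Holothuria",
                "Cidaroid_sp", "Strongylocentrotus", "Scaphechinus"),
    taxon_b = c("Holothuria", "Amphipholis", "Cidaroid_sp", "Apostichopus",
                "Strongylocentrotus", "Scaphechinus", "Echinocardium"),
    min = c(481, 477, 464, 241, 269, 190.8, 174),
    max = c(521, 521, 470, 260, 346.7, 235, 201),
    stringsAsFactors = FALSE)
  class(tab) <- c("calibration_table", "data.frame")
  tab
}

#' Read a calibration table from TSV
#'
#' Columns: `clade`, `taxon_a`, `taxon_b`, `min`, `max` (ages in Ma).
#'
#' @param file Path to the TSV file.
#' @return A `calibration_table`.
#' @export
read_calibrations <- function(file) {
  tab <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  need <- c("clade", "taxon_a", "taxon_b", "min", "max")
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols) > 0)
    stop("calibration table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  validate_calibrations(tab)
  class(tab) <- c("calibration_table", "data.frame")
  tab
}

#' Write a calibration table to TSV
#'
#' @param cal A `calibration_table`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_calibrations <- function(cal, file) {
  utils::write.table(as.data.frame(cal), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

validate_calibrations <- function(cal) {
  if (any(!(cal$min > 0)) || any(!(cal$max > cal$min)))
    stop("each calibration needs 0 < min < max")
  invisible(cal)
}

# Resolve calibrations to node ids on a topology; error on duplicates.
resolve_calibrations <- function(topology, cal) {
  validate_calibrations(cal)
  nodes <- vapply(seq_len(nrow(cal)), function(i)
    mrca_node(topology, c(cal$taxon_a[i], cal$taxon_b[i])), integer(1))
  if (anyDuplicated(nodes)) {
    d <- which(duplicated(nodes) | duplicated(nodes, fromLast = TRUE))
    stop("calibrations resolve to the same node: ",
         paste(cal$clade[d], collapse = ", "))
  }
  nodes
}

#' Sample one calibration-consistent chronogram
#'
#' Draws node ages on a fixed rooted topology so that every calibrated
#' node's age lies inside its fossil bounds and every parent is older than
#' its children. Ages are assigned in a root-to-tip pass: a calibrated
#' node is drawn uniformly on its bounds truncated above by its parent's
#' age; an uncalibrated node uniformly between the oldest calibrated
#' minimum among its descendants (zero if none; tips are extant, age 0)
#' and its parent's age. The result is ultrametric by construction, with
#' branch lengths in Ma.
#'
#' This sampler stands in for a sequence-based divergence-time posterior:
#' it reproduces the calibrated age windows and the nesting structure, not
#' the data-driven concentration of a real posterior. An externally
#' produced tree sample can be supplied to the analysis functions instead
#' ([read_tree_sample()]).
#'
#' @param topology A rooted `phylo` (branch lengths ignored).
#' @param calibrations A `calibration_table`; taxon pairs must resolve to
#'   distinct nodes.
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` chronogram.
#' @export
sample_chronogram <- function(topology, calibrations = default_calibrations(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  topo <- topology
  if (is.null(topo$edge.length)) topo$edge.length <- rep(1, nrow(topo$edge))
  validate_tree(topo)
  nodes <- resolve_calibrations(topo, calibrations)
  ntip <- ape::Ntip(topo)
  nnode_total <- ntip + topo$Nnode
  cal_min <- rep(NA_real_, nnode_total)
  cal_max <- rep(NA_real_, nnode_total)
  cal_min[nodes] <- calibrations$min
  cal_max[nodes] <- calibrations$max
  # floor(v): oldest calibrated minimum in v's subtree (v excluded), 0 at tips
  po <- ape::reorder.phylo(topo, "postorder")
  floor_age <- rep(0, nnode_total)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; v <- po$edge[e, 2]
    child_bound <- max(floor_age[v], if (!is.na(cal_min[v])) cal_min[v] else 0)
    floor_age[p] <- max(floor_age[p], child_bound)
  }
  root <- ntip + 1L
  ages <- rep(0, nnode_total)
  preorder_edges <- rev(seq_len(nrow(po$edge)))
  draw_age <- function(v, parent_age) {
    lo <- floor_age[v]
    hi <- parent_age
    if (!is.na(cal_min[v])) lo <- max(lo, cal_min[v])
    if (!is.na(cal_max[v])) hi <- min(hi, cal_max[v])
    if (lo >= hi)
      stop(sprintf(paste0("inconsistent calibrations at node %d: ",
                          "lower bound %.3f >= upper bound %.3f"), v, lo, hi))
    stats::runif(1, lo, hi)
  }
  ages[root] <- {
    lo <- max(floor_age[root], if (!is.na(cal_min[root])) cal_min[root] else 0)
    hi <- if (!is.na(cal_max[root])) cal_max[root] else lo * 1.2 + 1
    if (lo >= hi) stop("inconsistent calibrations at the root")
    stats::runif(1, lo, hi)
  }
  for (e in preorder_edges) {
    p <- po$edge[e, 1]; v <- po$edge[e, 2]
    if (v <= ntip) next # extant tips: age 0
    ages[v] <- draw_age(v, ages[p])
  }
  out <- po
  out$edge.length <- ages[po$edge[, 1]] - ages[po$edge[, 2]]
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Sample a set of calibration-consistent chronograms
#'
#' `n` independent draws from [sample_chronogram()], reproducible per
#' seed, with a per-node age summary attached.
#'
#' @inheritParams sample_chronogram
#' @param n Number of trees (>= 1).
#' @return A `multiPhylo` tree sample (provenance `"sampled"`) with an
#'   `"age_summary"` attribute: per calibrated clade, the mean and
#'   2.5/97.5 percentiles of the sampled node age.
#' @export
sample_tree_set <- function(topology, calibrations = default_calibrations(),
                            n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", n)
  nodes <- NULL
  age_mat <- matrix(NA_real_, n, nrow(calibrations))
  for (i in seq_len(n)) {
    tr <- sample_chronogram(topology, calibrations)
    trees[[i]] <- tr
    if (is.null(nodes)) nodes <- resolve_calibrations(tr, calibrations)
    age_mat[i, ] <- node_ages(tr)[nodes]
  }
  out <- as_tree_sample(trees, provenance = "sampled")
  attr(out, "age_summary") <- data.frame(
    clade = calibrations$clade,
    mean = colMeans(age_mat),
    q2.5 = apply(age_mat, 2, stats::quantile, 0.025),
    q97.5 = apply(age_mat, 2, stats::quantile, 0.975))
  out
}
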