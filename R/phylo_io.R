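#' Parse a rooted Newick tree with branch lengths
#'
#' Reads a single Newick string into an [ape::phylo] tree and validates it
#' for use as a chronogram: the tree must be rooted (no basal polytomy),
#' tip labels must be unique and non-empty, and every branch must carry a
#' length.
#'
#' @param text A Newick string (terminating `;` optional).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("`text` must be a single character string")
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: malformed tree string")
  validate_tree(tr)
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @return A Newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

# Structural validation shared by all entry points that accept trees.
validate_tree <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` tree")
  tips <- tree$tip.label
  if (any(!nzchar(tips))) stop("empty tip label")
  dup <- tips[duplicated(tips)]
  if (length(dup) > 0)
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  if (require_lengths) {
    if (is.null(tree$edge.length))
      stop("tree has no branch lengths")
    if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
      stop("missing or non-finite branch length")
    if (any(tree$edge.length < 0)) stop("negative branch length")
  }
  root <- ape::Ntip(tree) + 1L
  root_children <- sum(tree$edge[, 1] == root)
  if (root_children > 2L)
    stop("basal polytomy: tree must be rooted with a bifurcating root")
  invisible(tree)
}

#' Check that a tree is ultrametric within tolerance
#'
#' All root-to-tip path lengths must agree within `tol` (absolute, in the
#' tree's length units). Used to validate chronograms whose branch lengths
#' are node ages in Ma.
#'
#' @param tree A `phylo` object.
#' @param tol Absolute tolerance on root-to-tip path length differences.
#' @return `TRUE`/`FALSE`.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depths)) <= tol
}

#' Node ages of an ultrametric tree
#'
#' @param tree An ultrametric `phylo` object.
#' @return Numeric vector of ages (time before present) indexed by node id
#'   (tips first, then internal nodes).
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_len(ape::Ntip(tree))]) - depths
}

#' Most recent common ancestor of a set of tips
#'
#' Returns the id of the deepest node ancestral to all named taxa. A single
#' taxon is its own MRCA (the tip id is returned).
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels (length >= 1).
#' @return Integer node id (ape numbering: tips `1..Ntip`, root `Ntip+1`).
#' @export
mrca_node <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"), length(taxa) >= 1)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
  if (length(unique(taxa)) == 1L)
    return(match(taxa[1], tree$tip.label))
  ape::getMRCA(tree, unique(taxa))
}

#' Rescale branch lengths to a target mean
#'
#' Multiplies all branch lengths by a single constant so that their mean
#' equals `target_mean`. Topology and branch-length ratios are preserved.
#' This mirrors the standard practice of scaling chronogram branch lengths
#' to mean 0.1 before rate estimation, which keeps transition rates in a
#' numerically convenient range.
#'
#' @param tree A `phylo` object with at least one positive branch length.
#' @param target_mean Positive target mean branch length.
#' @return The rescaled tree.
#' @export
scale_branches <- function(tree, target_mean = 0.1) {
  validate_tree(tree)
  stopifnot(target_mean > 0)
  m <- mean(tree$edge.length)
  if (m <= 0) stop("degenerate tree: all branch lengths are zero")
  tree$edge.length <- tree$edge.length * (target_mean / m)
  tree
}

#' Prune a tree to a subset of taxa
#'
#' Returns the induced subtree on `keep`: unary internal nodes are
#' suppressed with their branch lengths summed, so all pairwise path
#' lengths among kept tips (and tip ages) are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (length >= 2).
#' @return The pruned tree.
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(keep)
  if (length(keep) < 2) stop("need at least 2 taxa to keep")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
  ape::keep.tip(tree, keep)
}

#' Read a tree sample
#'
#' Reads an ordered collection of trees sharing a tip set, either from a
#' file of one Newick string per line or from a NEXUS file with a TREES
#' block (translate tables supported). All members must have identical tip
#' label sets.
#'
#' @param file Path to the tree file.
#' @param format `"newick"` (default) or `"nexus"`.
#' @return A `multiPhylo` object with a `"provenance"` attribute set to
#'   `"file"`.
#' @export
read_tree_sample <- function(file, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- if (format == "newick") ape::read.tree(file) else
    ape::read.nexus(file)
  if (inherits(trees, "phylo")) trees <- c(trees)  # single tree -> multiPhylo
  as_tree_sample(trees, provenance = "file")
}

#' Write a tree sample as one Newick string per line
#'
#' @param trees A `multiPhylo` object or list of `phylo` trees.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tree_sample <- function(trees, file) {
  writeLines(vapply(trees, ape::write.tree, character(1)), file)
  invisible(file)
}

#' Validate and tag a collection of trees as a tree sample
#'
#' @param trees A `multiPhylo` or list of `phylo` trees.
#' @param provenance `"sampled"` or `"file"`.
#' @return A `multiPhylo` with a `"provenance"` attribute.
#' @export
as_tree_sample <- function(trees, provenance = c("sampled", "file")) {
  provenance <- match.arg(provenance)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!inherits(trees, "multiPhylo")) {
    stopifnot(is.list(trees), length(trees) >= 1)
    class(trees) <- "multiPhylo"
  }
  if (length(trees) == 0) stop("empty tree sample")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    validate_tree(trees[[i]])
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("tree ", i, " has a different tip set from tree 1")
  }
  attr(trees, "provenance") <- provenance
  trees
}
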