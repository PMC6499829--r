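#' Define a per-gene state space
#'
#' A state space names the discrete spatial-expression states a gene can
#' take and fixes their integer coding: the first label is state 0, the
#' second state 1, and so on. State 0 is, by convention, the state named
#' first in node-fixing hypothesis tests (the "echinozoan-like" baseline
#' differs per gene; see [default_state_spaces()]).
#'
#' @param gene Gene name.
#' @param labels Character vector of >= 2 unique state labels, in coding
#'   order.
#' @return An object of class `state_space`.
#' @export
state_space <- function(gene, labels) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  if (length(labels) < 2) stop("need at least 2 state labels")
  if (anyDuplicated(labels)) stop("state labels must be unique")
  structure(list(gene = gene, labels = labels, k = length(labels)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space for", x$gene, "(k =", x$k, "):\n")
  cat(paste0("  ", seq_len(x$k) - 1L, " = ", x$labels, collapse = "\n"), "\n")
  invisible(x)
}

#' Default state spaces for the five skeletogenic regulatory genes
#'
#' Binary spaces for `alx1`, `ets1`, `erg`, `vegfr` and a four-state space
#' for `tbrain`. State 0 is always the mesodermal/absent baseline used in
#' node-fixing tests:
#' * `alx1`: 0 = mesoderm, 1 = SM-specific (skeletogenic mesenchyme)
#' * `ets1`, `erg`: 0 = mesoderm, 1 = SM+NSM (skeletogenic plus
#'   nonskeletogenic mesoderm)
#' * `vegfr`: 0 = absent-in-SM, 1 = present-in-SM
#' * `tbrain`: 0 = SM-specific, 1 = mesoderm (SM+NSM), 2 = endomesoderm,
#'   3 = other
#'
#' The mapping is configuration, not data: pass your own [state_space()]
#' objects to the readers to re-map labels.
#'
#' @return Named list of `state_space` objects.
#' @export
default_state_spaces <- function() {
  list(
    alx1   = state_space("alx1",   c("mesoderm", "SM-specific")),
    erg    = state_space("erg",    c("mesoderm", "SM+NSM")),
    ets1   = state_space("ets1",   c("mesoderm", "SM+NSM")),
    tbrain = state_space("tbrain", c("SM-specific", "mesoderm",
                                     "endomesoderm", "other")),
    vegfr  = state_space("vegfr",  c("absent-in-SM", "present-in-SM"))
  )
}

#' Construct a character matrix from state labels
#'
#' @param taxa Character vector of taxon names (rows).
#' @param states Named list, one character vector per gene, of state labels
#'   (or `NA`/`"?"` for missing), each of length `length(taxa)`.
#' @param spaces Named list of [state_space()] objects covering every gene
#'   in `states`.
#' @return An object of class `character_matrix`: a list with `taxa`, a
#'   `states` integer matrix (taxa x genes, 0-based indices, `NA` =
#'   missing) and `spaces`.
#' @export
character_matrix <- function(taxa, states, spaces) {
  stopifnot(is.character(taxa), length(taxa) >= 1)
  if (anyDuplicated(taxa)) stop("duplicate taxon name")
  genes <- names(states)
  if (is.null(genes) || any(!nzchar(genes))) stop("`states` must be named by gene")
  missing_space <- setdiff(genes, names(spaces))
  if (length(missing_space) > 0)
    stop("no state space for gene(s): ", paste(missing_space, collapse = ", "))
  idx <- matrix(NA_integer_, length(taxa), length(genes),
                dimnames = list(taxa, genes))
  for (g in genes) {
    lab <- states[[g]]
    if (length(lab) != length(taxa))
      stop("gene ", g, ": expected ", length(taxa), " states, got ", length(lab))
    miss <- is.na(lab) | lab == "?"
    m <- match(lab[!miss], spaces[[g]]$labels)
    if (anyNA(m)) {
      bad <- which(!miss)[which(is.na(m))[1]]
      stop("unknown state label \"", lab[bad], "\" for gene ", g,
           ", taxon ", taxa[bad])
    }
    idx[!miss, g] <- m - 1L
  }
  structure(list(taxa = taxa, states = idx, spaces = spaces[genes]),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix:", length(x$taxa), "taxa x",
      ncol(x$states), "genes\n")
  scored <- colSums(!is.na(x$states))
  for (g in colnames(x$states))
    cat(sprintf("  %-8s k=%d  scored %d/%d\n", g, x$spaces[[g]]$k,
                scored[[g]], length(x$taxa)))
  invisible(x)
}

#' Read a character matrix from tab-separated text
#'
#' Expects a header row naming the genes, one row per taxon (first column =
#' taxon name), cells holding state labels from the corresponding state
#' space or `"?"` for missing.
#'
#' @param file Path to the TSV file.
#' @param spaces Named list of [state_space()] objects.
#' @return A `character_matrix`.
#' @export
read_character_matrix <- function(file, spaces = default_state_spaces()) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("matrix must have a taxon column and >= 1 gene")
  taxa <- tab[[1]]
  if (anyDuplicated(taxa)) stop("duplicate taxon name in matrix file")
  genes <- colnames(tab)[-1]
  states <- lapply(genes, function(g) {
    v <- tab[[g]]
    v[v %in% c("", "?", "NA")] <- NA_character_
    v
  })
  names(states) <- genes
  character_matrix(taxa, states, spaces)
}

#' Write a character matrix as tab-separated text
#'
#' Inverse of [read_character_matrix()]: state labels as strings, `?` for
#' missing.
#'
#' @param mat A `character_matrix`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_character_matrix <- function(mat, file) {
  stopifnot(inherits(mat, "character_matrix"))
  genes <- colnames(mat$states)
  out <- data.frame(taxon = mat$taxa, check.names = FALSE)
  for (g in genes) {
    lab <- mat$spaces[[g]]$labels[mat$states[, g] + 1L]
    lab[is.na(lab)] <- "?"
    out[[g]] <- lab
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a character matrix as a NEXUS CHARACTERS block
#'
#' Emits a minimal NEXUS file (TAXA + CHARACTERS blocks) coding states as
#' their integer indices, `?` for missing, for interoperability with other
#' phylogenetics software.
#'
#' @param mat A `character_matrix`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_nexus_characters <- function(mat, file) {
  stopifnot(inherits(mat, "character_matrix"))
  ntax <- length(mat$taxa)
  genes <- colnames(mat$states)
  sym <- max(vapply(mat$spaces, `[[`, 1L, "k")) - 1L
  rows <- vapply(seq_len(ntax), function(i) {
    states <- mat$states[i, ]
    code <- ifelse(is.na(states), "?", as.character(states))
    sprintf("    %s  %s", gsub("\\s", "_", mat$taxa[i]),
            paste(code, collapse = ""))
  }, character(1))
  lines <- c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", ntax),
    "  TAXLABELS",
    paste0("    ", gsub("\\s", "_", mat$taxa)),
    "  ;",
    "END;",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NCHAR=%d;", length(genes)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=?;",
            paste(0:sym, collapse = "")),
    sprintf("  CHARLABELS %s;", paste(genes, collapse = " ")),
    "  MATRIX",
    rows,
    "  ;",
    "END;")
  writeLines(lines, file)
  invisible(file)
}

#' Restrict a matrix to one gene's scored taxa
#'
#' Extracts the single-gene pattern over exactly the taxa with non-missing
#' data for that gene, plus the induced taxon set used to prune trees.
#' Missing data are handled by taxon exclusion, not ambiguity coding.
#'
#' @param mat A `character_matrix`.
#' @param gene Gene name present in `mat`.
#' @param taxa Optional character vector restricting the candidate taxa
#'   before missing-data exclusion.
#' @return An object of class `gene_pattern`: list with `gene`, `states`
#'   (named 0-based integer vector over scored taxa), `taxa`, and `space`.
#' @export
restrict_pattern <- function(mat, gene, taxa = NULL) {
  stopifnot(inherits(mat, "character_matrix"))
  if (!gene %in% colnames(mat$states)) stop("gene not in matrix: ", gene)
  keep <- mat$taxa
  if (!is.null(taxa)) {
    unknown <- setdiff(taxa, mat$taxa)
    if (length(unknown) > 0)
      stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
    keep <- intersect(keep, taxa)
  }
  v <- mat$states[keep, gene]
  scored <- keep[!is.na(v)]
  if (length(scored) < 2)
    stop("gene ", gene, ": fewer than 2 scored taxa")
  states <- mat$states[scored, gene]
  names(states) <- scored
  structure(list(gene = gene, states = states, taxa = scored,
                 space = mat$spaces[[gene]]),
            class = "gene_pattern")
}

#' @export
print.gene_pattern <- function(x, ...) {
  cat("Pattern for", x$gene, "over", length(x$taxa), "taxa:\n")
  lab <- x$space$labels[x$states + 1L]
  for (i in seq_along(x$taxa))
    cat(sprintf("  %-18s %d (%s)\n", x$taxa[i], x$states[i], lab[i]))
  invisible(x)
}
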