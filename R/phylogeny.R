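#' Read and validate a rooted phylogeny
#'
#' Parses a Newick or Nexus tree and enforces the contract the downstream
#' comparative machinery relies on: the tree is rooted, every non-root edge
#' carries a branch length, branch lengths are non-negative, and tip labels
#' are unique. Nexus TRANSLATE tables are resolved to full labels. A root
#' edge in the input is dropped with a warning, since the Brownian-motion
#' covariance is defined from the root node itself.
#'
#' @param text a character scalar holding the tree, or NULL if `file` given.
#' @param file path to a tree file; exactly one of `text`/`file`.
#' @param dialect "auto" (default, sniffed from a leading "#NEXUS"),
#'   "newick" or "nexus".
#' @param grafen if TRUE, a tree without branch lengths is accepted and
#'   assigned Grafen-style depths (node height proportional to clade size);
#'   the assignment is reported via a message. Default FALSE: such trees
#'   are rejected.
#' @return an object of class `phylo` (see \pkg{ape}).
#' @export
read_tree <- function(text = NULL, file = NULL,
                      dialect = c("auto", "newick", "nexus"),
                      grafen = FALSE) {
  dialect <- match.arg(dialect)
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`")
  }
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  if (dialect == "auto") {
    dialect <- if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) "nexus" else "newick"
  }
  tr <- if (dialect == "nexus") {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    out <- tryCatch(ape::read.nexus(tf), error = function(e) {
      stop("Nexus parse error: ", conditionMessage(e), call. = FALSE)
    })
    out <- if (inherits(out, "multiPhylo")) out[[1L]] else out
    if (any(grepl("[(),:;]", out$tip.label))) {
      stop("Nexus parse error: tree statement not recognized ",
           "(check TRANSLATE/TREE block layout)", call. = FALSE)
    }
    out
  } else {
    out <- tryCatch(ape::read.tree(text = text), error = function(e) {
      stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
    })
    if (is.null(out)) {
      # locate the first structural problem for a usable message
      bal <- cumsum((strsplit(text, "")[[1L]] == "(") -
                    (strsplit(text, "")[[1L]] == ")"))
      pos <- if (any(bal < 0)) which(bal < 0)[1L] else nchar(text)
      stop("Newick parse error near character ", pos, call. = FALSE)
    }
    if (inherits(out, "multiPhylo")) out[[1L]] else out
  }
  validate_phylogeny(tr, grafen = grafen)
}

#' @keywords internal
validate_phylogeny <- function(tr, grafen = FALSE) {
  if (!inherits(tr, "phylo")) stop("not a phylogeny")
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    if (!grafen) {
      stop("tree has no branch lengths; supply them or set grafen = TRUE",
           call. = FALSE)
    }
    tr <- ape::compute.brlen(tr, method = "Grafen")
    message("branch lengths absent: assigned Grafen depths")
  }
  if (anyNA(tr$edge.length)) {
    stop("missing branch length on ", sum(is.na(tr$edge.length)),
         " edge(s); refusing to invent unit lengths", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) stop("negative branch length", call. = FALSE)
  if (!is.null(tr$root.edge) && tr$root.edge != 0) {
    warning("root edge of length ", tr$root.edge,
            " ignored: covariance is measured from the root node")
  }
  tr$root.edge <- NULL
  # a phylo object is structurally rooted (unique parentless node); basal
  # polytomies — including star phylogenies — are legitimate comparative
  # input and are kept as-is
  tr
}

#' Write a phylogeny as strict Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if NULL the Newick string is returned.
#' @param digits significant digits for branch lengths (default 12).
#' @export
write_tree <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Prune a phylogeny to a set of taxa
#'
#' Returns the induced subtree on `keep`: path lengths between retained
#' tips are unchanged, and internal nodes left with a single child are
#' collapsed with their branch lengths summed.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least two taxa to keep", call. = FALSE)
  out <- ape::keep.tip(tree, keep)
  out$root.edge <- NULL
  out
}

# Canonical form used when reconciling tree tip labels with trait-table
# taxa: trim surrounding whitespace, collapse runs of internal
# whitespace/underscores to a single underscore.
normalize_taxon <- function(x) {
  x <- trimws(x)
  gsub("[ _]+", "_", x)
}

#' Reconcile tree tips with trait-table taxa
#'
#' Matching is exact after trimming whitespace and normalizing
#' underscores/spaces. By default any mismatch is an error carrying a
#' side-by-side report of the unmatched names on each side; with
#' `prune = TRUE` the tree is pruned to the intersection instead (the
#' dropped names are reported in a message).
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of trait-table taxa.
#' @param prune drop unmatched tips/taxa instead of failing.
#' @return list with elements `tree` (possibly pruned) and `taxa` (the
#'   trait taxa, in their original spelling, that are on the tree).
#' @export
match_taxa <- function(tree, taxa, prune = FALSE) {
  tip_norm <- normalize_taxon(tree$tip.label)
  tab_norm <- normalize_taxon(taxa)
  only_tree <- tree$tip.label[!(tip_norm %in% tab_norm)]
  only_tab  <- taxa[!(tab_norm %in% tip_norm)]
  if (length(only_tree) || length(only_tab)) {
    if (!prune) {
      n <- max(length(only_tree), length(only_tab))
      pad <- function(v) c(v, rep("", n - length(v)))
      report <- paste(sprintf("  %-30s | %s", pad(only_tree), pad(only_tab)),
                      collapse = "\n")
      stop("tree/trait taxon mismatch (tree-only | table-only):\n",
           sprintf("  %-30s | %s\n", "TREE", "TABLE"), report,
           "\nset prune = TRUE to analyse the intersection", call. = FALSE)
    }
    message("pruning to intersection; dropped: ",
            paste(c(only_tree, only_tab), collapse = ", "))
  }
  shared <- tree$tip.label[tip_norm %in% tab_norm]
  tree2 <- if (length(shared) < length(tree$tip.label)) {
    prune_to_taxa(tree, shared)
  } else tree
  list(tree = tree2, taxa = taxa[tab_norm %in% tip_norm])
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip depths.
#' Under Brownian motion with rate sigma^2 the tip values are multivariate
#' normal with covariance sigma^2 * C.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return a `phylo_cov` object: the covariance matrix with tip labels as
#'   dimnames and a `transform` attribute recording the tree scalings
#'   applied ("raw" here).
#' @export
vcv_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  C <- ape::vcv.phylo(tree)
  new_phylo_cov(C, transform = list(lambda = 1, delta = 1, kappa = 1,
                                    record = "raw"))
}

new_phylo_cov <- function(C, transform) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  attr(C, "transform") <- transform
  class(C) <- c("phylo_cov", "matrix")
  C
}

#' @export
print.phylo_cov <- function(x, ...) {
  tr <- attr(x, "transform")
  cat(sprintf("phylogenetic covariance: %d taxa; transform %s (lambda=%g, delta=%g, kappa=%g)\n",
              nrow(x), tr$record, tr$lambda, tr$delta, tr$kappa))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
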