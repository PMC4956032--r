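#' Pagel tree transforms
#'
#' Three scalar transforms that deform the Brownian-motion covariance to
#' model departures from a strict clock-like random walk:
#' \describe{
#'   \item{lambda}{phylogenetic signal. Multiplies the off-diagonal
#'     (shared-history) covariance entries; lambda = 0 is a star phylogeny
#'     (independence), lambda = 1 is pure Brownian motion.}
#'   \item{delta}{early versus late bursts of change. Raises shared path
#'     lengths to the power delta; delta < 1 concentrates change early
#'     (deep branches stretched), delta > 1 late.}
#'   \item{kappa}{punctuational scaling. Raises each branch length to the
#'     power kappa; kappa -> 0 makes change proportional to the number of
#'     speciation events rather than to time.}
#' }
#' Composition order is fixed: kappa acts on branch lengths, the covariance
#' is then built, delta acts on its entries, and lambda scales the
#' off-diagonals last.
#'
#' @name transforms
NULL

.param_caps <- new.env(parent = emptyenv())
.param_caps$delta_max <- 3
.param_caps$kappa_max <- 3

#' Set the upper caps for delta and kappa
#'
#' Defaults mirror the usual comparative-methods software ranges
#' (delta, kappa in (0, 3]).
#' @param delta_max,kappa_max positive caps.
#' @export
set_transform_caps <- function(delta_max = 3, kappa_max = 3) {
  stopifnot(delta_max > 0, kappa_max > 0)
  .param_caps$delta_max <- delta_max
  .param_caps$kappa_max <- kappa_max
  invisible(list(delta_max = delta_max, kappa_max = kappa_max))
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]", call. = FALSE)
  }
  lambda
}

check_delta <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta <= 0 || delta > .param_caps$delta_max) {
    stop(sprintf("delta must lie in (0, %g]", .param_caps$delta_max),
         call. = FALSE)
  }
  delta
}

check_kappa <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) ||
      kappa < 0 || kappa > .param_caps$kappa_max) {
    stop(sprintf("kappa must lie in [0, %g]", .param_caps$kappa_max),
         call. = FALSE)
  }
  kappa
}

#' Apply the kappa (punctuational) transform to a tree
#'
#' Every branch length b becomes b^kappa. By convention 0^kappa = 0 for
#' all kappa (a zero-length branch stays zero — zero-length resolutions of
#' polytomies are preserved), and kappa = 0 maps every positive branch to
#' 1, so change tracks speciation events rather than elapsed time.
#'
#' @param tree a `phylo` object.
#' @param kappa scalar in [0, kappa_max].
#' @export
apply_kappa <- function(tree, kappa) {
  check_kappa(kappa)
  stopifnot(inherits(tree, "phylo"))
  b <- tree$edge.length
  tree$edge.length <- ifelse(b == 0, 0, b^kappa)
  tree
}

#' Apply the delta (node-depth power) transform to a covariance
#'
#' Raises every entry of the shared-path-length matrix to the power delta.
#'
#' @param C a `phylo_cov` matrix (raw or kappa-transformed).
#' @param delta scalar in (0, delta_max].
#' @export
apply_delta <- function(C, delta) {
  check_delta(delta)
  stopifnot(inherits(C, "phylo_cov"))
  tr <- attr(C, "transform")
  out <- unclass(C)^delta
  tr$delta <- tr$delta * delta
  tr$record <- if (delta == 1) tr$record else "transformed"
  new_phylo_cov(out, tr)
}

#' Apply the lambda (phylogenetic signal) transform to a covariance
#'
#' Multiplies the off-diagonal entries by lambda and leaves the diagonal
#' untouched. Implemented on the covariance (rather than by shrinking
#' internal branches) so it is well defined on non-ultrametric trees; the
#' two formulations coincide for ultrametric trees.
#'
#' @param C a `phylo_cov` matrix.
#' @param lambda scalar in [0, 1].
#' @export
apply_lambda <- function(C, lambda) {
  check_lambda(lambda)
  stopifnot(inherits(C, "phylo_cov"))
  tr <- attr(C, "transform")
  out <- unclass(C) * lambda
  diag(out) <- diag(unclass(C))
  tr$lambda <- tr$lambda * lambda
  tr$record <- if (lambda == 1) tr$record else "transformed"
  new_phylo_cov(out, tr)
}

#' Build the transformed Brownian-motion covariance for a tree
#'
#' Fixed composition order: kappa on branch lengths, covariance built,
#' delta on entries, lambda on off-diagonals. With all parameters at 1
#' this is exactly `vcv_matrix(tree)`.
#'
#' @param tree a `phylo` object.
#' @param lambda,delta,kappa transform parameters (identity defaults).
#' @export
transform_covariance <- function(tree, lambda = 1, delta = 1, kappa = 1) {
  check_lambda(lambda); check_delta(delta); check_kappa(kappa)
  C <- vcv_matrix(apply_kappa(tree, kappa))
  tr <- attr(C, "transform")
  tr$kappa <- kappa
  tr$record <- if (kappa == 1) "raw" else "transformed"
  C <- new_phylo_cov(unclass(C), tr)
  C <- apply_delta(C, delta)
  apply_lambda(C, lambda)
}

# Fast covariance builder used inside samplers/optimizers. The raw entry
# C[i, j] is the root-to-MRCA path length, so under kappa it becomes the
# kappa-depth of the MRCA: depth_k(v) = sum over root->v edges of b^kappa.
# Precomputing the tip-pair MRCA index matrix once reduces each rebuild to
# an O(edges) depth accumulation plus an O(n^2) table lookup; delta and
# lambda are elementwise on the result.
make_cov_builder <- function(tree) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  b <- tr$edge.length
  M <- ape::mrca(tree)                 # n x n MRCA node ids (tip order)
  storage.mode(M) <- "integer"
  labels <- tree$tip.label
  nnode <- max(edge)
  pre <- rev(seq_len(nrow(edge)))      # preorder edge sequence
  par <- edge[pre, 1L]; child <- edge[pre, 2L]; bpre <- b[pre]
  diag_idx <- which(diag(n) == 1)
  function(lambda = 1, delta = 1, kappa = 1) {
    bk <- if (kappa == 1) bpre else ifelse(bpre == 0, 0, bpre^kappa)
    depthk <- numeric(nnode)
    for (k in seq_along(par)) depthk[child[k]] <- depthk[par[k]] + bk[k]
    C <- matrix(depthk[M], n, n, dimnames = list(labels, labels))
    if (delta != 1) C <- C^delta
    if (lambda != 1) {
      d <- C[diag_idx]
      C <- C * lambda
      C[diag_idx] <- d
    }
    C
  }
}
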