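#' Simulate a Yule (pure-birth) tree
#'
#' Exact forward simulation of the constant-rate pure-birth process: the
#' root splits at time zero, each interval while k lineages exist lasts
#' Exp(birth_rate * k), a uniformly chosen lineage splits, and the tree
#' is cut at the end of the interval during which it holds `n_tips`
#' lineages. The result is ultrametric; the waiting-time law makes the
#' expected tree age (H(n) - 1) / birth_rate with H the harmonic number,
#' which the test suite uses as a distributional oracle.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time.
#' @param seed integer seed; all randomness flows from it.
#' @return an ultrametric `phylo` object with tips t1..tn.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  n <- as.integer(n_tips)
  # active lineages: parent node id and birth time
  par_of <- c(n + 1L, n + 1L)
  born <- c(0, 0)
  t <- 0
  edge <- matrix(0L, 2L * n - 2L, 2L)
  elen <- numeric(2L * n - 2L)
  ne <- 0L
  for (k in 2:(n - 1L)) {
    if (n == 2L) break
    t <- t + stats::rexp(1, birth_rate * k)
    i <- sample.int(k, 1L)
    node <- n + k         # k-th split creates internal node n+k
    ne <- ne + 1L
    edge[ne, ] <- c(par_of[i], node)
    elen[ne] <- t - born[i]
    par_of <- c(par_of[-i], node, node)
    born <- c(born[-i], t, t)
  }
  t <- t + stats::rexp(1, birth_rate * n)   # no further split before the cut
  for (i in seq_len(n)) {
    ne <- ne + 1L
    edge[ne, ] <- c(par_of[i], i)
    elen[ne] <- t - born[i]
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = paste0("t", seq_len(n)),
                       Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

# Pick an internal clade whose tip count is closest to frac * n, used for
# the clade-block predictor rule (mirrors a trait concentrated in a few
# related large-bodied lineages rather than scattered at random).
pick_clade <- function(tree, frac) {
  n <- length(tree$tip.label)
  target <- max(2L, round(frac * n))
  nodes <- (n + 2L):max(tree$edge)       # exclude the root
  sizes <- vapply(nodes, function(v) {
    length(ape::extract.clade(tree, v)$tip.label)
  }, integer(1))
  ok <- which(sizes < n)                  # proper subclade
  nodes[ok][which.min(abs(sizes[ok] - target))]
}

#' Simulate the regression model on a tree
#'
#' Draws y ~ MVN(X beta, sigma2 * C(lambda, delta, kappa)) through a
#' Cholesky factor of the transformed Brownian covariance, with the
#' binary predictor assigned either to one clade ("clade" rule, default —
#' the realistic, phylogenetically clustered pattern) or i.i.d.
#' Bernoulli(p) ("bernoulli" rule, used for null-calibration checks).
#'
#' @param tree a `phylo` object.
#' @param beta1,beta2 intercept and state-1 shift (ln-cm scale).
#' @param sigma2 Brownian rate (> 0).
#' @param lambda,delta,kappa generating transform values.
#' @param predictor "clade" or "bernoulli".
#' @param p target fraction of state-1 tips (default 0.2, roughly the
#'   packaged dataset's 12/56).
#' @param seed integer seed.
#' @return list: `y` (named response), `z` (named 0/1 predictor), `X`,
#'   and `truth` (the generating parameter record).
#' @export
simulate_bm_regression <- function(tree, beta1, beta2, sigma2,
                                   lambda = 1, delta = 1, kappa = 1,
                                   predictor = c("clade", "bernoulli"),
                                   p = 0.2, seed) {
  predictor <- match.arg(predictor)
  stopifnot(sigma2 > 0, p > 0, p < 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(tree$tip.label)
  z <- stats::setNames(integer(n), tree$tip.label)
  if (predictor == "clade") {
    node <- pick_clade(tree, p)
    z[ape::extract.clade(tree, node)$tip.label] <- 1L
  } else {
    z[] <- stats::rbinom(n, 1L, p)
  }
  C <- transform_covariance(tree, lambda = lambda, delta = delta,
                            kappa = kappa)
  U <- tryCatch(chol(unclass(C)), error = function(e) {
    stop("transformed covariance is not positive definite", call. = FALSE)
  })
  X <- cbind(intercept = 1, projections = as.numeric(z))
  mu <- drop(X %*% c(beta1, beta2))
  y <- mu + sqrt(sigma2) * drop(crossprod(U, stats::rnorm(n)))
  names(y) <- tree$tip.label
  list(y = y, z = z, X = X,
       truth = list(beta1 = beta1, beta2 = beta2, sigma2 = sigma2,
                    lambda = lambda, delta = delta, kappa = kappa,
                    predictor = predictor, p = p, seed = as.integer(seed)))
}

#' Simulate a binary character under the Mk model
#'
#' The root state is drawn from the stationary distribution (or fixed),
#' then states evolve edge by edge using the closed-form transition
#' matrix.
#'
#' @param tree a `phylo` object.
#' @param q01,q10 transition rates, not both zero.
#' @param root_state 0, 1, or NULL (draw from the stationary
#'   distribution).
#' @param seed integer seed.
#' @return named integer vector of tip states.
#' @export
simulate_mk <- function(tree, q01, q10, root_state = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (q01 == 0 && q10 == 0) stop("both rates zero", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  state <- integer(max(tr$edge))
  root <- n + 1L
  state[root] <- if (is.null(root_state)) {
    stats::rbinom(1, 1, mk_root_dist(q01, q10, "stationary")[2])
  } else as.integer(root_state)
  for (k in rev(seq_len(nrow(tr$edge)))) {   # preorder
    par <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
    P <- mk_transition_matrix(q01, q10, tr$edge.length[k])
    state[child] <- stats::rbinom(1, 1, P[state[par] + 1L, 2L])
  }
  stats::setNames(state[seq_len(n)], tr$tip.label)
}
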