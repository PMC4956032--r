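# Independent oracles used to check the package's analytic routines.
# Each one deliberately takes the slow, direct route (path enumeration,
# dense determinants, exhaustive state sums, numerical optimization) so it
# shares no code path with the implementation under test.

# BM covariance by explicit root-to-MRCA path summation, one pair at a time.
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  edge_len <- function(a, b) {
    k <- which(tree$edge[, 1] == a & tree$edge[, 2] == b)
    tree$edge.length[k]
  }
  path_len_to <- function(node) {
    if (node == root) return(0)
    p <- ape::nodepath(tree, root, node)
    sum(vapply(seq_len(length(p) - 1L),
               function(i) edge_len(p[i], p[i + 1L]), numeric(1)))
  }
  M <- ape::mrca(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in 1:n) for (j in 1:n) C[i, j] <- path_len_to(M[i, j])
  C
}

# Dense multivariate-normal log density via explicit determinant + solve.
oracle_mvn_loglik <- function(y, mu, S) {
  n <- length(y)
  r <- y - mu
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(crossprod(r, solve(S, r))))
}

# Mk likelihood by exhaustive enumeration over all internal-state
# assignments (2^(#internal nodes) terms).
oracle_mk_lik <- function(tree, states, q01, q10, root_dist) {
  n <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internal <- (n + 1L):nnode
  st <- integer(nnode)
  st[1:n] <- states[tree$tip.label]
  total <- 0
  for (mask in 0:(2^length(internal) - 1L)) {
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    pr <- root_dist[st[n + 1L] + 1L]
    for (k in seq_len(nrow(tree$edge))) {
      P <- spinetrait::mk_transition_matrix(q01, q10, tree$edge.length[k])
      pr <- pr * P[st[tree$edge[k, 1]] + 1L, st[tree$edge[k, 2]] + 1L]
    }
    total <- total + pr
  }
  total
}

# Per-node marginals by the same enumeration.
oracle_mk_marginals <- function(tree, states, q01, q10, root_dist) {
  n <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internal <- (n + 1L):nnode
  st <- integer(nnode)
  st[1:n] <- states[tree$tip.label]
  acc <- matrix(0, length(internal), 2,
                dimnames = list(as.character(internal), c("0", "1")))
  for (mask in 0:(2^length(internal) - 1L)) {
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    pr <- root_dist[st[n + 1L] + 1L]
    for (k in seq_len(nrow(tree$edge))) {
      P <- spinetrait::mk_transition_matrix(q01, q10, tree$edge.length[k])
      pr <- pr * P[st[tree$edge[k, 1]] + 1L, st[tree$edge[k, 2]] + 1L]
    }
    for (i in seq_along(internal)) {
      acc[i, st[internal[i]] + 1L] <- acc[i, st[internal[i]] + 1L] + pr
    }
  }
  acc / rowSums(acc)
}

# Posterior node marginals under the equal-rates model, integrating the
# rate over its (hyper)prior on a fine grid: p(q) = int_0^hm U(m; 0, hm)
# Exp(q | mean m) dm, posterior weight w(q) proportional to p(q) L(q).
oracle_mk_marginals_grid <- function(tree, states, root = "stationary",
                                     hyper_max = 10,
                                     q_grid = exp(seq(log(1e-4), log(40),
                                                      length.out = 400))) {
  m_grid <- seq(1e-3, hyper_max, length.out = 400)
  prior_q <- vapply(q_grid, function(q) {
    mean(stats::dexp(q, rate = 1 / m_grid))
  }, numeric(1))
  lik <- vapply(q_grid, function(q) {
    exp(spinetrait::mk_loglik(tree, states, q, q, root = root))
  }, numeric(1))
  # trapezoid quadrature weights: the grid is log-spaced, so each point
  # carries its local dq
  dq <- diff(q_grid)
  quad <- c(dq[1] / 2, (dq[-1] + dq[-length(dq)]) / 2,
            dq[length(dq)] / 2)
  w <- prior_q * lik * quad
  w <- w / sum(w)
  margs <- lapply(q_grid, function(q) {
    spinetrait::mk_node_marginals(tree, states, q, q, root = root)
  })
  out <- Reduce(`+`, Map(`*`, margs, w))
  out
}

# ML ancestral states under BM by direct numerical optimization of the
# joint likelihood over internal-node values (and the BM rate).
oracle_bm_anc <- function(tree, y) {
  n <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internal <- (n + 1L):nnode
  obj <- function(a) {
    x <- c(y[tree$tip.label], a)
    sum((x[tree$edge[, 2]] - x[tree$edge[, 1]])^2 / tree$edge.length)
  }
  start <- rep(mean(y), length(internal))
  o <- stats::optim(start, obj, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  stats::setNames(o$par, as.character(internal))
}

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$root.edge <- NULL
  tr
}
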