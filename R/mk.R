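#' Two-state Mk transition probability matrix
#'
#' Closed form for the binary continuous-time Markov chain with gain rate
#' q01 (0 -> 1) and loss rate q10 (1 -> 0) over a branch of length t:
#' with s = q01 + q10,
#' P00(t) = (q10 + q01 e^{-st})/s and P11(t) = (q01 + q10 e^{-st})/s.
#'
#' @param q01,q10 non-negative rates (events per unit branch length), not
#'   both zero.
#' @param t branch length >= 0.
#' @return 2x2 row-stochastic matrix, states ordered (0, 1).
#' @export
mk_transition_matrix <- function(q01, q10, t) {
  stopifnot(q01 >= 0, q10 >= 0, t >= 0)
  if (q01 == 0 && q10 == 0) stop("both rates zero", call. = FALSE)
  s <- q01 + q10
  e <- exp(-s * t)
  P <- matrix(c((q10 + q01 * e) / s, (q01 - q01 * e) / s,
                (q10 - q10 * e) / s, (q01 + q10 * e) / s),
              2, 2, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  P
}

mk_root_dist <- function(q01, q10, root = c("stationary", "uniform")) {
  root <- match.arg(root)
  if (root == "uniform") c(0.5, 0.5) else c(q10, q01) / (q01 + q10)
}

# Precompute traversal structure shared by the pruning passes.
mk_prep <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss)) {
    stop("no character state for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  st <- tip_states[tree$tip.label]
  if (!all(st %in% c(0, 1))) stop("tip states must be 0 or 1", call. = FALSE)
  tr <- ape::reorder.phylo(tree, "postorder")
  list(n = n, nnode = max(tr$edge), root = n + 1L,
       edge = tr$edge, elen = tr$edge.length, states = as.integer(st))
}

# Felsenstein pruning. Returns the per-node conditional likelihoods
# L[v, s] = P(tip data below v | state s at v) together with per-node
# "messages" D[v, s_parent] = sum_s P(s_parent -> s; t_v) L[v, s], which
# the marginal (outside) pass reuses. Transition probabilities are
# vectorized over edges and the node loop works on scalars, since this is
# the sampler's innermost kernel.
mk_prune_pass <- function(prep, q01, q10) {
  s <- q01 + q10
  e <- exp(-s * prep$elen)
  P00 <- (q10 + q01 * e) / s; P01 <- 1 - P00
  P10 <- (q10 - q10 * e) / s; P11 <- 1 - P10
  L0 <- rep(1, prep$nnode); L1 <- L0
  tips <- seq_len(prep$n)
  L1[tips][prep$states == 0] <- 0
  L0[tips][prep$states == 1] <- 0
  D0 <- numeric(prep$nnode); D1 <- D0
  logscale <- 0
  par <- prep$edge[, 1L]; child <- prep$edge[, 2L]
  for (k in seq_along(par)) {
    ch <- child[k]; pa <- par[k]
    d0 <- P00[k] * L0[ch] + P01[k] * L1[ch]
    d1 <- P10[k] * L0[ch] + P11[k] * L1[ch]
    D0[ch] <- d0; D1[ch] <- d1
    l0 <- L0[pa] * d0; l1 <- L1[pa] * d1
    if (l0 < 1e-100 && l1 < 1e-100 && (l0 > 0 || l1 > 0)) {
      m <- max(l0, l1)
      l0 <- l0 / m; l1 <- l1 / m
      logscale <- logscale + log(m)
    }
    L0[pa] <- l0; L1[pa] <- l1
  }
  list(L = cbind(L0, L1, deparse.level = 0),
       D = cbind(D0, D1, deparse.level = 0),
       P = cbind(P00, P01, P10, P11, deparse.level = 0),
       logscale = logscale)
}

#' Mk model log-likelihood by Felsenstein pruning
#'
#' @param tree a `phylo` object.
#' @param tip_states named vector of 0/1 states covering every tip.
#' @param q01,q10 transition rates.
#' @param root root-state prior: "stationary" (of the rate matrix,
#'   the default) or "uniform".
#' @return log-likelihood of the tip data.
#' @export
mk_loglik <- function(tree, tip_states, q01, q10,
                      root = c("stationary", "uniform")) {
  prep <- mk_prep(tree, tip_states)
  pass <- mk_prune_pass(prep, q01, q10)
  pi0 <- mk_root_dist(q01, q10, root)
  log(sum(pi0 * pass$L[prep$root, ])) + pass$logscale
}

#' Exact per-node state marginals under fixed Mk rates
#'
#' Inside-outside computation: the pruning pass supplies the "inside"
#' likelihoods, a preorder pass propagates the "outside" term, and the
#' node marginal is their normalized product.
#'
#' @inheritParams mk_loglik
#' @return matrix (internal nodes x 2) of P(state 0), P(state 1), rows
#'   named by ape node number.
#' @export
mk_node_marginals <- function(tree, tip_states, q01, q10,
                              root = c("stationary", "uniform")) {
  prep <- mk_prep(tree, tip_states)
  pass <- mk_prune_pass(prep, q01, q10)
  pi0 <- mk_root_dist(q01, q10, root)
  .mk_marginals(prep, pass, pi0)
}

.mk_marginals <- function(prep, pass, pi0) {
  U0 <- numeric(prep$nnode); U1 <- U0
  U0[prep$root] <- pi0[1]; U1[prep$root] <- pi0[2]
  L <- pass$L; D <- pass$D; P <- pass$P
  par <- prep$edge[, 1L]; child <- prep$edge[, 2L]
  # preorder (reverse postorder):
  # outside(child, s) = sum_{s_par} outside(par, s_par) *
  #   [prod over siblings of their messages](s_par) * P(s_par -> s)
  for (k in rev(seq_along(par))) {
    pa <- par[k]; ch <- child[k]
    s0 <- U0[pa] * L[pa, 1L] / D[ch, 1L]
    s1 <- U1[pa] * L[pa, 2L] / D[ch, 2L]
    if (!is.finite(s0)) s0 <- 0   # guard 0/0 when a message vanishes
    if (!is.finite(s1)) s1 <- 0
    U0[ch] <- s0 * P[k, 1L] + s1 * P[k, 3L]
    U1[ch] <- s0 * P[k, 2L] + s1 * P[k, 4L]
  }
  nodes <- (prep$n + 1L):prep$nnode
  r0 <- L[nodes, 1L] * U0[nodes]
  r1 <- L[nodes, 2L] * U1[nodes]
  out <- cbind(r0, r1) / (r0 + r1)
  dimnames(out) <- list(as.character(nodes), c("0", "1"))
  out
}

#' Reversible-jump MCMC ancestral-state reconstruction
#'
#' Samples the transition rates of a binary-character Mk model, jumping
#' between an equal-rates (q01 = q10) and a different-rates
#' parameterization, under an exponential prior on the rates whose mean m
#' is itself a sampled hyperparameter, uniform on (0, hyper_max]. At each
#' retained sample the exact per-node state marginals are computed by the
#' inside-outside pass and averaged, giving Rao-Blackwellized posterior
#' node-state probabilities.
#'
#' Move set (random-walk proposals reflected at bounds):
#' \itemize{
#'   \item hyperprior mean m: likelihood-free update (prior ratio only);
#'   \item rates: multiplicative log-scale random walk (Hastings ratio
#'     q'/q);
#'   \item model jump equal -> different: draw u ~ Uniform(0,1) and set
#'     q01 = 2qu, q10 = 2q(1-u), which preserves the mean rate; the
#'     Jacobian of (q, u) -> (q01, q10) is |J| = 4q. The reverse merge
#'     sets q = (q01+q10)/2 with |J|^{-1} = 1/(4q).
#' }
#'
#' @param tree a `phylo` object with >= 3 tips.
#' @param tip_states named 0/1 vector covering the tips. A warning is
#'   emitted if only one state is present (rates weakly identified).
#' @param settings list from [mcmc_settings()].
#' @param seed integer, mandatory.
#' @param root root-state prior convention (see [mk_loglik()]).
#' @param rate_model "rj" (default: jump between equal and different),
#'   "equal" or "different" (fixed dimension).
#' @param fixed_rates optional c(q01, q10): disable all rate sampling and
#'   condition on these rates (validation mode).
#' @param hyper_max upper bound of the uniform hyperprior on the
#'   exponential mean (default 10).
#' @return an `mk_posterior`: list with `samples` (data.frame of q01, q10,
#'   different-rates indicator, m, loglik), `node_prob` (internal nodes x
#'   2 averaged marginals), and run metadata.
#' @export
rjmcmc_ancestral <- function(tree, tip_states,
                             settings = mcmc_settings("quick"), seed,
                             root = c("stationary", "uniform"),
                             rate_model = c("rj", "equal", "different"),
                             fixed_rates = NULL, hyper_max = 10) {
  root <- match.arg(root)
  rate_model <- match.arg(rate_model)
  if (missing(seed)) stop("seed is mandatory for MCMC runs", call. = FALSE)
  if (length(tree$tip.label) < 3L) stop("need >= 3 tips", call. = FALSE)
  set.seed(as.integer(seed))
  prep <- mk_prep(tree, tip_states)
  if (length(unique(prep$states)) == 1L) {
    warning("only one character state present: rates are weakly identified")
  }
  dexp_mean <- function(q, m) stats::dexp(q, rate = 1 / m, log = TRUE)
  ll_of <- function(q01, q10) {
    pass <- mk_prune_pass(prep, q01, q10)
    log(sum(mk_root_dist(q01, q10, root) * pass$L[prep$root, ])) + pass$logscale
  }

  fixed <- !is.null(fixed_rates)
  if (fixed) {
    q01 <- fixed_rates[1]; q10 <- fixed_rates[2]
    different <- q01 != q10
    m <- hyper_max / 2
  } else {
    m <- stats::runif(1, 0, hyper_max)
    q01 <- q10 <- stats::rexp(1, rate = 1 / m)
    different <- FALSE
    if (rate_model == "different") {
      q10 <- stats::rexp(1, rate = 1 / m)
      different <- TRUE
    }
  }
  cur_ll <- ll_of(q01, q10)

  it <- settings$iterations; burn <- settings$burnin; thin <- settings$thin
  nkeep <- floor((it - burn) / thin)
  samples <- matrix(NA_real_, nkeep, 5,
                    dimnames = list(NULL, c("q01", "q10", "different", "m",
                                            "loglik")))
  nodes <- (prep$n + 1L):prep$nnode
  prob_sum <- matrix(0, length(nodes), 2)
  k <- 0L
  sc_m <- 1; sc_q <- 0.5
  for (i in seq_len(it)) {
    if (!fixed) {
      # hyperprior mean: likelihood does not involve m
      m2 <- reflect(m + stats::rnorm(1, 0, sc_m), 1e-8, hyper_max)
      lr <- dexp_mean(q01, m2) - dexp_mean(q01, m)
      if (different) lr <- lr + dexp_mean(q10, m2) - dexp_mean(q10, m)
      if (log(stats::runif(1)) < lr) m <- m2
      # rate updates, multiplicative random walk
      for (which_q in if (different) c("q01", "q10") else "q") {
        f <- exp(stats::rnorm(1, 0, sc_q))
        if (which_q == "q") { p01 <- q01 * f; p10 <- p01 } else
        if (which_q == "q01") { p01 <- q01 * f; p10 <- q10 } else {
          p01 <- q01; p10 <- q10 * f
        }
        new_ll <- ll_of(p01, p10)
        pr <- if (different) {
          dexp_mean(p01, m) + dexp_mean(p10, m) -
            dexp_mean(q01, m) - dexp_mean(q10, m)
        } else dexp_mean(p01, m) - dexp_mean(q01, m)
        hast <- log(f)   # log(q'/q) for the changed rate
        if (log(stats::runif(1)) < new_ll - cur_ll + pr + hast) {
          q01 <- p01; q10 <- p10; cur_ll <- new_ll
        }
      }
      # reversible jump between rate parameterizations
      if (rate_model == "rj") {
        if (!different) {
          u <- stats::runif(1)
          p01 <- 2 * q01 * u; p10 <- 2 * q01 * (1 - u)
          if (p01 > 0 && p10 > 0) {
            new_ll <- ll_of(p01, p10)
            lacc <- new_ll - cur_ll +
              dexp_mean(p01, m) + dexp_mean(p10, m) - dexp_mean(q01, m) +
              log(4 * q01)   # |J| of (q, u) -> (2qu, 2q(1-u))
            if (log(stats::runif(1)) < lacc) {
              q01 <- p01; q10 <- p10; different <- TRUE; cur_ll <- new_ll
            }
          }
        } else {
          qm <- (q01 + q10) / 2
          new_ll <- ll_of(qm, qm)
          lacc <- new_ll - cur_ll +
            dexp_mean(qm, m) - dexp_mean(q01, m) - dexp_mean(q10, m) -
            log(4 * qm)
          if (log(stats::runif(1)) < lacc) {
            q01 <- q10 <- qm; different <- FALSE; cur_ll <- new_ll
          }
        }
      }
    }
    if (i > burn && (i - burn) %% thin == 0L) {
      k <- k + 1L
      samples[k, ] <- c(q01, q10, as.numeric(different), m, cur_ll)
      pass <- mk_prune_pass(prep, q01, q10)
      prob_sum <- prob_sum + .mk_marginals(prep, pass,
                                           mk_root_dist(q01, q10, root))
    }
  }
  node_prob <- prob_sum / k
  dimnames(node_prob) <- list(as.character(nodes), c("0", "1"))
  out <- list(samples = as.data.frame(samples), node_prob = node_prob,
              tree = tree, root = root, rate_model = rate_model,
              settings = c(settings, list(seed = as.integer(seed),
                                          hyper_max = hyper_max,
                                          fixed_rates = fixed_rates)))
  class(out) <- "mk_posterior"
  out
}

#' Per-node ancestral-state report
#'
#' One row per internal node: a stable fingerprint built from the sorted
#' descendant tip labels (so rows are comparable across runs and node
#' numberings), the posterior probabilities of each state, and a
#' "supported" flag when the larger probability reaches `threshold`
#' (default 0.95, the conventional strong-support cutoff).
#'
#' @param post an `mk_posterior`.
#' @param threshold support flag cutoff in (0.5, 1].
#' @export
ancestral_report <- function(post, threshold = 0.95) {
  stopifnot(inherits(post, "mk_posterior"), nrow(post$samples) > 0)
  tree <- post$tree
  n <- length(tree$tip.label)
  nodes <- as.integer(rownames(post$node_prob))
  fp <- vapply(nodes, function(v) {
    tips <- ape::extract.clade(tree, v)$tip.label
    paste(sort(tips), collapse = "|")
  }, character(1))
  data.frame(node = nodes,
             tips = fp,
             n_tips = lengths(strsplit(fp, "|", fixed = TRUE)),
             p0 = post$node_prob[, "0"],
             p1 = post$node_prob[, "1"],
             supported = pmax(post$node_prob[, "0"],
                              post$node_prob[, "1"]) >= threshold,
             row.names = NULL)
}
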