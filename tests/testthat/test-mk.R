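test_that("transition matrices take their closed form", {
  expect_equal(mk_transition_matrix(0.7, 1.3, 0), diag(2),
               ignore_attr = TRUE)
  # symmetric rates, long time: stationary 50/50
  Pinf <- mk_transition_matrix(1, 1, 500)
  expect_equal(as.vector(Pinf), rep(0.5, 4), tolerance = 1e-12)
  # e^{-2t} = 1/2 at t = ln(2)/2: P00 = (1 + 1/2)/2 = 0.75
  P <- mk_transition_matrix(1, 1, log(2) / 2)
  expect_equal(P[1, 1], 0.75, tolerance = 1e-12)
  expect_error(mk_transition_matrix(0, 0, 1), "both rates zero")
})

test_that("transition matrices are row-stochastic across random draws", {
  set.seed(40)
  for (i in 1:2000) {
    P <- mk_transition_matrix(rexp(1, 0.2), rexp(1, 0.2), rexp(1, 0.5))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("pruning likelihood matches independence and fusion limits", {
  # long symmetric branches: tips independent at stationarity,
  # uniform root: 0.5 * 0.5 * 0.5 summed over root states = 0.25
  t2 <- read_tree("(A:400,B:400);")
  ll <- mk_loglik(t2, c(A = 0, B = 0), 1, 1, root = "uniform")
  expect_equal(exp(ll), 0.25, tolerance = 1e-9)

  # zero-length branches fuse nodes: pruning over the resolved tree must
  # equal the likelihood on the fused (cherry collapsed to one tip) tree
  tz <- read_tree("((A:0,B:0):1,C:1);")
  tf <- read_tree("(AB:1,C:1);")
  ll_z <- mk_loglik(tz, c(A = 1, B = 1, C = 0), 0.4, 0.9)
  ll_f <- mk_loglik(tf, c(AB = 1, C = 0), 0.4, 0.9)
  expect_equal(ll_z, ll_f, tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on random trees", {
  for (i in 1:20) {
    tr <- random_tree(5, seed = 8000 + i)
    set.seed(9000 + i)
    st <- setNames(rbinom(5, 1, 0.5), tr$tip.label)
    q01 <- rexp(1, 1); q10 <- rexp(1, 1)
    for (root in c("stationary", "uniform")) {
      pd <- if (root == "uniform") c(0.5, 0.5) else c(q10, q01) / (q01 + q10)
      expect_equal(exp(mk_loglik(tr, st, q01, q10, root = root)),
                   oracle_mk_lik(tr, st, q01, q10, pd),
                   tolerance = 1e-12)
    }
  }
})

test_that("pruning is invariant to child order", {
  tr <- read_tree("((A:1,B:2):0.5,(C:0.7,D:0.3):1.5);")
  sw <- read_tree("((D:0.3,C:0.7):1.5,(B:2,A:1):0.5);")
  st <- c(A = 0, B = 1, C = 1, D = 0)
  expect_equal(mk_loglik(tr, st, 0.3, 0.8), mk_loglik(sw, st, 0.3, 0.8),
               tolerance = 1e-12)
})

test_that("exact node marginals agree with the enumeration oracle", {
  for (i in 1:10) {
    tr <- random_tree(5, seed = 8100 + i)
    set.seed(9100 + i)
    st <- setNames(rbinom(5, 1, 0.5), tr$tip.label)
    q01 <- rexp(1, 1); q10 <- rexp(1, 1)
    mine <- mk_node_marginals(tr, st, q01, q10, root = "uniform")
    orac <- oracle_mk_marginals(tr, st, q01, q10, c(0.5, 0.5))
    expect_equal(mine, orac[rownames(mine), ], tolerance = 1e-12)
  }
})

test_that("rjmcmc with fixed rates reproduces the exact marginals", {
  tr3 <- read_tree("(A:1,(B:0.5,C:0.5):0.5);")
  st3 <- c(A = 0, B = 1, C = 0)
  exact <- mk_node_marginals(tr3, st3, 0.7, 1.3)
  post <- rjmcmc_ancestral(tr3, st3,
                           settings = mcmc_settings(iterations = 600,
                                                    burnin = 100, thin = 1),
                           seed = 41, fixed_rates = c(0.7, 1.3))
  expect_equal(post$node_prob, exact, tolerance = 1e-12)
  expect_equal(nrow(post$samples), 500)
})

test_that("a fully symmetric configuration gives root P(0) = 0.5", {
  tr <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
  st <- c(A = 0, B = 1, C = 0, D = 1)
  post <- rjmcmc_ancestral(tr, st,
                           settings = mcmc_settings(iterations = 45000,
                                                    burnin = 5000, thin = 10),
                           seed = 42, root = "uniform")
  expect_lt(abs(post$node_prob["5", "0"] - 0.5), 0.03)
  # mirror-image cherries get mirror-image posteriors
  expect_equal(unname(post$node_prob["6", "0"]),
               unname(post$node_prob["7", "0"]), tolerance = 1e-12)
})

test_that("rjmcmc is reproducible and warns on a constant character", {
  tr3 <- read_tree("(A:0.3,(B:0.2,C:0.2):0.1);")
  s <- mcmc_settings(iterations = 2000, burnin = 500, thin = 5)
  p1 <- rjmcmc_ancestral(tr3, c(A = 0, B = 1, C = 0), settings = s, seed = 43)
  p2 <- rjmcmc_ancestral(tr3, c(A = 0, B = 1, C = 0), settings = s, seed = 43)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$node_prob, p2$node_prob)
  expect_warning(
    rjmcmc_ancestral(tr3, c(A = 0, B = 0, C = 0), settings = s, seed = 44),
    "one character state")
  expect_error(rjmcmc_ancestral(tr3, c(A = 0, B = 1, C = 0), settings = s),
               "seed")
})

test_that("the rate-model indicator actually jumps and both rates stay positive", {
  tr <- read_tree("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  st <- c(A = 0, B = 0, C = 1, D = 1)
  post <- rjmcmc_ancestral(tr, st,
                           settings = mcmc_settings(iterations = 20000,
                                                    burnin = 2000, thin = 10),
                           seed = 45)
  frac_diff <- mean(post$samples$different)
  expect_gt(frac_diff, 0.05)
  expect_lt(frac_diff, 0.95)
  expect_true(all(post$samples$q01 > 0))
  expect_true(all(post$samples$m > 0 & post$samples$m <= 10))
  # equal-model samples really have equal rates
  eq <- post$samples$different == 0
  expect_true(all(post$samples$q01[eq] == post$samples$q10[eq]))
})

test_that("ancestral_report flags supported nodes and normalizes rows", {
  tr3 <- read_tree("(A:0.2,(B:0.1,C:0.1):0.1);")
  post <- rjmcmc_ancestral(tr3, c(A = 0, B = 0, C = 1),
                           settings = mcmc_settings(iterations = 5000,
                                                    burnin = 1000, thin = 5),
                           seed = 46)
  rep <- ancestral_report(post)
  expect_equal(nrow(rep), 2)
  expect_true(all(abs(rep$p0 + rep$p1 - 1) < 1e-9))
  expect_setequal(rep$tips, c("A|B|C", "B|C"))
  expect_equal(rep$supported, pmax(rep$p0, rep$p1) >= 0.95)
  # threshold is configurable
  rep2 <- ancestral_report(post, threshold = 0.5)
  expect_true(all(rep2$supported))
})
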