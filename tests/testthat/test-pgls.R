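tree3 <- read_tree("(A:1,(B:0.5,C:0.5):0.5);")

test_that("gls_loglik reproduces hand-computable densities", {
  # two independent standard normals at zero: density = -ln(2*pi)
  t2 <- read_tree("(A:1,B:1);")
  ll <- gls_loglik(c(0, 0), cbind(c(1, 1), c(0, 1)), vcv_matrix(t2),
                   c(0, 0), 1)
  expect_equal(ll, -log(2 * pi), tolerance = 1e-12)
})

test_that("gls_loglik matches the dense multivariate-normal oracle", {
  set.seed(11)
  for (i in 1:25) {
    tr <- random_tree(sample(3:8, 1), seed = 6000 + i)
    n <- length(tr$tip.label)
    X <- cbind(1, rbinom(n, 1, 0.5))
    y <- rnorm(n, 2, 1)
    beta <- rnorm(2)
    s2 <- runif(1, 0.2, 2)
    C <- vcv_matrix(tr)
    expect_equal(gls_loglik(y, X, C, beta, s2),
                 oracle_mvn_loglik(y, drop(X %*% beta), s2 * unclass(C)),
                 tolerance = 1e-10)
  }
})

test_that("gls_loglik is invariant to a joint shift of y and the intercept", {
  set.seed(12)
  y <- rnorm(3); X <- cbind(1, c(0, 1, 0)); C <- vcv_matrix(tree3)
  base <- gls_loglik(y, X, C, c(0.5, 1), 0.7)
  expect_equal(gls_loglik(y + 5, X, C, c(5.5, 1), 0.7), base,
               tolerance = 1e-12)
})

test_that("gls_loglik refuses a singular covariance and names the transform", {
  tr <- read_tree("((A:0,B:0):1,C:1);")   # A and B are duplicated points
  C <- vcv_matrix(tr)
  expect_error(gls_loglik(c(1, 2, 3), cbind(1, c(0, 1, 1)), C, c(0, 0), 1),
               "singular")
})

test_that("fit_ml reduces to OLS on a star phylogeny", {
  star <- read_tree("(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(13)
  z <- c(0, 1, 0, 1, 1, 0)
  y <- 2 + 0.9 * z + rnorm(6, 0, 0.3)
  names(y) <- star$tip.label
  fit <- fit_ml(y, cbind(1, z), star)
  ols <- coef(lm(y ~ z))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-8)
})

test_that("fit_ml flags an exact linear fit as degenerate", {
  star <- read_tree("(A:1,B:1,C:1,D:1);")
  z <- c(0, 1, 0, 1)
  y <- 3 + 0.5 * z
  expect_warning(fit <- fit_ml(y, cbind(1, z), star), "degenerate")
  expect_true(fit$degenerate)
  expect_equal(unname(fit$beta), c(3, 0.5), tolerance = 1e-8)
})

test_that("fit_ml needs more taxa than coefficients and attains the optimum", {
  t2 <- read_tree("(A:1,B:1);")
  expect_error(fit_ml(c(1, 2), cbind(1, c(0, 1)), t2), "more taxa")

  tr <- simulate_yule(40, 1, seed = 14)
  sim <- simulate_bm_regression(tr, 3, 0.8, 0.2, lambda = 0.7, seed = 15)
  fit <- fit_ml(sim$y, sim$X, tr, model = "lambda")
  # spot-check optimality over a lambda grid with profiled beta/sigma2
  for (lam in c(0, 0.25, 0.5, 0.75, 0.9, 1)) {
    C <- transform_covariance(tr, lambda = lam)
    ll <- gls_loglik(sim$y, sim$X, C, fit$beta, fit$sigma2)
    expect_gte(fit$loglik + 1e-6, ll)
  }
})

test_that("fit_mcmc is deterministic under a fixed seed and sized correctly", {
  tr <- simulate_yule(25, 1, seed = 16)
  sim <- simulate_bm_regression(tr, 3, 0.8, 0.2, seed = 17)
  s <- mcmc_settings(iterations = 3000, burnin = 500, thin = 5)
  p1 <- suppressWarnings(fit_mcmc(sim$y, sim$X, tr, model = "lambda",
                                  settings = s, seed = 99))
  p2 <- suppressWarnings(fit_mcmc(sim$y, sim$X, tr, model = "lambda",
                                  settings = s, seed = 99))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(nrow(p1), floor((3000 - 500) / 5))
  expect_true(all(is.finite(p1$loglik)))
  expect_error(fit_mcmc(sim$y, sim$X, tr, settings = s), "seed")
})

test_that("with the likelihood held constant the sampler returns its prior", {
  tr <- simulate_yule(10, 1, seed = 18)
  sim <- simulate_bm_regression(tr, 3, 0.8, 0.2, seed = 19)
  s <- mcmc_settings(iterations = 45000, burnin = 5000, thin = 10)
  pp <- suppressWarnings(fit_mcmc(sim$y, sim$X, tr, model = "lambda",
                                  settings = s, seed = 20, prior_only = TRUE))
  ks_b2 <- suppressWarnings(ks.test(pp$beta2, pnorm, 0, 10)$statistic)
  ks_lam <- suppressWarnings(ks.test(pp$lambda, punif)$statistic)
  expect_lt(unname(ks_b2), 0.05)
  expect_lt(unname(ks_lam), 0.05)
})

test_that("posterior means track the ML estimates on moderate data", {
  tr <- simulate_yule(100, 1, seed = 21)
  sim <- simulate_bm_regression(tr, 3.24, 0.88, 0.1, lambda = 0.88, seed = 22)
  ml <- fit_ml(sim$y, sim$X, tr, model = "lambda")
  post <- suppressWarnings(fit_mcmc(sim$y, sim$X, tr, model = "lambda",
                                    settings = mcmc_settings("quick"),
                                    seed = 23))
  sm <- phylo_ttest_summary(post)
  expect_lt(abs(sm$mean["beta2"] - ml$beta[2]), 0.15)
  expect_lt(abs(sm$mean["beta1"] - ml$beta[1]), 0.15)
})

test_that("the predictor must have contrast", {
  tab <- theropod_traits()
  tab$projections[] <- 0L
  expect_error(build_regression_data(tab, theropod_tree_standin()),
               "no contrast")
})

test_that("phylo_ttest_summary reports tail proportions", {
  fake <- data.frame(beta1 = c(1, 1, 1), beta2 = c(1, 2, 3),
                     sigma2 = c(1, 1, 1), loglik = c(0, 0, 0))
  class(fake) <- c("regression_posterior", "data.frame")
  s <- phylo_ttest_summary(fake)
  expect_equal(s$prop_positive, 1)
  expect_equal(s$tail_two_sided, 0)

  fake2 <- data.frame(beta1 = c(0, 0), beta2 = c(-1, 1),
                      sigma2 = c(1, 1), loglik = c(0, 0))
  class(fake2) <- c("regression_posterior", "data.frame")
  s2 <- phylo_ttest_summary(fake2)
  expect_equal(s2$prop_positive, 0.5)
  expect_equal(s2$tail_two_sided, 1)
})

test_that("BM ancestral estimates obey symmetry and match the oracle", {
  t2 <- read_tree("(A:1,B:1);")
  est <- bm_ancestral_continuous(t2, c(A = 2, B = 6))
  expect_equal(unname(est["3"]), 4)   # midpoint of a symmetric cherry

  star <- read_tree("(A:1,B:1,C:1,D:1);")
  y <- c(A = 1, B = 2, C = 3, D = 10)
  expect_equal(unname(bm_ancestral_continuous(star, y)["5"]), mean(y))

  for (i in 1:5) {
    tr <- random_tree(5, seed = 7000 + i)
    yy <- setNames(rnorm(5, 3, 1), tr$tip.label)
    mine <- bm_ancestral_continuous(tr, yy)
    orac <- oracle_bm_anc(tr, yy)
    expect_equal(mine[names(orac)], orac, tolerance = 1e-6)
  }
})

test_that("BM ancestral estimates agree with an independent implementation", {
  tr <- simulate_yule(20, 1, seed = 24)
  sim <- simulate_bm_regression(tr, 3, 0, 0.3, seed = 25)
  mine <- bm_ancestral_continuous(tr, sim$y)
  ref <- ape::ace(sim$y[tr$tip.label], tr, method = "REML")$ace
  expect_equal(unname(mine[names(ref)]), unname(ref), tolerance = 0.05)
})
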