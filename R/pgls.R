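#' Assemble regression data aligned to a tree
#'
#' Builds the response (ln femur length), the design matrix (intercept and
#' binary projection indicator) and the taxon ordering shared with the
#' phylogenetic covariance. Taxa are matched by exact string comparison
#' after whitespace/underscore normalization.
#'
#' @param traits a trait table (see [read_trait_table()]).
#' @param tree a `phylo` object.
#' @param prune prune tree/table to their intersection instead of failing
#'   on a mismatch.
#' @return list with `y` (named response), `X` (n x 2 design matrix),
#'   `z` (binary predictor), `taxa`, `tree` (possibly pruned).
#' @export
build_regression_data <- function(traits, tree, prune = FALSE) {
  m <- match_taxa(tree, traits$taxon, prune = prune)
  tree <- m$tree
  idx <- match(normalize_taxon(tree$tip.label), normalize_taxon(traits$taxon))
  y <- log(traits$femur_cm[idx])
  z <- traits$projections[idx]
  if (all(z == z[1L])) stop("predictor has no contrast", call. = FALSE)
  X <- cbind(intercept = 1, projections = z)
  names(y) <- tree$tip.label
  list(y = y, X = X, z = z, taxa = tree$tip.label, tree = tree)
}

#' Phylogenetic GLS log-likelihood
#'
#' Log density of y ~ MVN(X beta, sigma2 * C):
#' -1/2 [ n log(2 pi sigma2) + log|C| + (y - X beta)' (sigma2 C)^{-1} (y - X beta) ],
#' evaluated through a Cholesky factorization (no explicit inverse).
#'
#' @param y response vector.
#' @param X design matrix.
#' @param C covariance structure (a `phylo_cov` or plain SPD matrix).
#' @param beta coefficient vector (length ncol(X)).
#' @param sigma2 Brownian-motion rate, > 0.
#' @export
gls_loglik <- function(y, X, C, beta, sigma2) {
  stopifnot(length(y) == nrow(X), length(beta) == ncol(X), sigma2 > 0)
  n <- length(y)
  U <- chol_or_fail(C)
  r <- y - drop(X %*% beta)
  rt <- backsolve(U, r, transpose = TRUE)
  logdet <- 2 * sum(log(diag(U)))
  -0.5 * (n * log(2 * pi * sigma2) + logdet + sum(rt^2) / sigma2)
}

chol_or_fail <- function(C) {
  tr <- attr(C, "transform")
  U <- tryCatch(chol(unclass(C)), error = function(e) NULL)
  if (is.null(U)) {
    what <- if (is.null(tr)) "supplied matrix" else {
      sprintf("transform (lambda=%g, delta=%g, kappa=%g)",
              tr$lambda, tr$delta, tr$kappa)
    }
    stop("phylogenetic covariance is singular under ", what, call. = FALSE)
  }
  U
}

# Profile log-likelihood machinery: for a fixed transformed covariance the
# GLS coefficient estimate and the ML rate have closed forms, obtained by
# ordinary least squares in the whitened coordinates ytil = U^{-T} y.
profile_fit <- function(y, X, C) {
  n <- length(y)
  U <- chol_or_fail(C)
  yt <- backsolve(U, y, transpose = TRUE)
  Xt <- backsolve(U, X, transpose = TRUE)
  fit <- stats::lm.fit(Xt, yt)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(U)))
  loglik <- if (sigma2 > 0) {
    -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  } else Inf
  list(beta = beta, sigma2 = sigma2, loglik = loglik, logdet = logdet,
       yt = yt, Xt = Xt, U = U)
}

#' Maximum-likelihood phylogenetic regression
#'
#' Fits y ~ MVN(X beta, sigma2 * C(lambda, delta, kappa)) by maximum
#' likelihood. Coefficients and the rate are profiled in closed form at
#' each transform value; the free transform parameters named in `model`
#' are optimized numerically within their ranges from a small grid of
#' starting points.
#'
#' @param y,X response and design matrix (see [build_regression_data()]).
#' @param tree a `phylo` object whose tip order matches `y`.
#' @param model character subset of c("lambda", "delta", "kappa") to
#'   estimate; omitted transforms are fixed at 1 (pure Brownian motion).
#' @return list: `beta`, `sigma2`, `transforms` (all three values),
#'   `loglik`, `degenerate` (TRUE when the residual rate collapsed to the
#'   numerical floor, e.g. an exact linear fit).
#' @export
fit_ml <- function(y, X, tree, model = character()) {
  stopifnot(all(model %in% c("lambda", "delta", "kappa")))
  n <- length(y)
  if (n <= ncol(X)) {
    stop("need more taxa than regression coefficients", call. = FALSE)
  }
  build <- make_cov_builder(tree)
  full <- function(th) {
    p <- list(lambda = 1, delta = 1, kappa = 1)
    p[model] <- as.list(th)
    p
  }
  obj <- function(th) {
    p <- full(th)
    C <- tryCatch(build(p$lambda, p$delta, p$kappa), error = function(e) NULL)
    if (is.null(C)) return(1e10)
    pf <- tryCatch(profile_fit(y, X, C), error = function(e) NULL)
    if (is.null(pf) || !is.finite(pf$loglik)) return(1e10)
    -pf$loglik
  }
  lo <- c(lambda = 0, delta = 1e-4, kappa = 0)[model]
  hi <- c(lambda = 1, delta = .param_caps$delta_max,
          kappa = .param_caps$kappa_max)[model]
  if (length(model) == 0L) {
    th <- numeric(0)
  } else {
    starts <- lapply(c(0.25, 0.75), function(f) lo + f * (hi - lo))
    starts <- c(starts, list(pmin(hi, pmax(lo, rep(1, length(model))))))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        stats::optim(s, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("transform optimization failed to converge",
                            call. = FALSE)
    th <- best$par
  }
  p <- full(th)
  C <- build(p$lambda, p$delta, p$kappa)
  pf <- profile_fit(y, X, C)
  degenerate <- pf$sigma2 < 1e-12
  if (degenerate) {
    warning("residual rate at numerical floor (near-perfect fit); ",
            "estimates flagged degenerate")
    pf$sigma2 <- max(pf$sigma2, 1e-12)
    pf$loglik <- -0.5 * (n * log(2 * pi * pf$sigma2) + pf$logdet + n)
  }
  list(beta = pf$beta, sigma2 = pf$sigma2,
       transforms = p, loglik = pf$loglik, degenerate = degenerate)
}

#' MCMC chain settings
#'
#' @param preset "paper" (5,000,000 iterations, 100,000 burn-in, sampling
#'   every 1,000 — the published run length) or "quick" (50,000 / 5,000 /
#'   10 — a desk-scale preset used throughout the tests).
#' @param iterations,burnin,thin explicit overrides.
#' @export
mcmc_settings <- function(preset = c("quick", "paper"),
                          iterations = NULL, burnin = NULL, thin = NULL) {
  preset <- match.arg(preset)
  s <- switch(preset,
              paper = list(iterations = 5e6, burnin = 1e5, thin = 1000),
              quick = list(iterations = 5e4, burnin = 5e3, thin = 10))
  s$iterations <- iterations %||% s$iterations
  s$burnin <- burnin %||% s$burnin
  s$thin <- thin %||% s$thin
  if (s$burnin >= s$iterations) stop("burn-in must be below iterations")
  if (s$thin < 1) stop("thin must be >= 1")
  s
}

default_priors <- function() {
  list(beta_sd = 10,          # beta1, beta2 ~ Normal(0, 10) on the ln-cm scale
       log_sigma2_range = c(-30, 30),  # ln sigma2 ~ Uniform (effectively flat)
       lambda = c(0, 1),      # Uniform(0, 1)
       delta = c(1e-4, NA),   # Uniform(0, cap]
       kappa = c(0, NA))      # Uniform[0, cap]
}

reflect <- function(x, lo, hi) {
  if (!is.finite(x)) return(x)
  w <- hi - lo
  z <- (x - lo) %% (2 * w)      # closed-form folding, O(1) for any step
  if (z > w) z <- 2 * w - z
  lo + z
}

#' Bayesian phylogenetic regression by MCMC
#'
#' Gibbs-within-Metropolis sampler for (beta1, beta2, sigma2, free
#' transforms). The coefficients and the rate have exact conjugate
#' conditionals under the default priors (normal and inverse-gamma) and
#' are block-updated by Gibbs draws every sweep; the transform
#' parameters use adaptive Gaussian random-walk Metropolis with
#' reflection at their bounds (one randomly chosen transform per sweep,
#' since each proposal costs a covariance rebuild and Cholesky).
#' Proposal scales adapt toward a 20-40% acceptance rate during burn-in
#' and are frozen when burn-in ends, so the post-burn-in chain is a
#' fixed-kernel Markov chain. The per-sample log-likelihood is stored
#' for harmonic-mean marginal likelihood estimation.
#'
#' Priors (configurable via `priors`): beta ~ Normal(0, 10); ln sigma2 ~
#' Uniform(-30, 30); lambda ~ Uniform(0, 1); delta, kappa ~ Uniform on
#' (0, cap] / [0, cap] with cap 3. Boundary proposals are reflected, which
#' keeps the kernel symmetric.
#'
#' @param y,X response and design (see [build_regression_data()]).
#' @param tree a `phylo` object, tips ordered as `y`.
#' @param model character subset of c("lambda","delta","kappa") to sample;
#'   others fixed at 1.
#' @param settings list from [mcmc_settings()].
#' @param seed integer; mandatory, all randomness flows from it.
#' @param priors optional override of the default prior list.
#' @param prior_only if TRUE the likelihood is held constant so the chain
#'   samples the prior (a standard sampler-validation mode).
#' @return a `regression_posterior`: data.frame of retained samples with
#'   columns beta1, beta2, sigma2, any free transforms, and loglik;
#'   settings, model, seed and acceptance rates in attributes.
#' @export
fit_mcmc <- function(y, X, tree, model = character(),
                     settings = mcmc_settings("quick"), seed,
                     priors = default_priors(), prior_only = FALSE) {
  stopifnot(all(model %in% c("lambda", "delta", "kappa")))
  if (missing(seed)) stop("seed is mandatory for MCMC runs", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(y)
  build <- make_cov_builder(tree)
  caps <- c(lambda = 1, delta = .param_caps$delta_max,
            kappa = .param_caps$kappa_max)
  los <- c(lambda = 0, delta = 1e-8, kappa = 0)

  # state
  tpar <- c(lambda = 1, delta = 1, kappa = 1)
  if (!prior_only && length(model)) {
    ml <- tryCatch(fit_ml(y, X, tree, model), error = function(e) NULL)
    if (!is.null(ml)) tpar[model] <- unlist(ml$transforms[model])
  } else if (prior_only && length(model)) {
    tpar["lambda"] <- stats::runif(1)
    tpar["delta"] <- stats::runif(1, los["delta"], caps["delta"])
    tpar["kappa"] <- stats::runif(1, 0, caps["kappa"])
    tpar[setdiff(c("lambda", "delta", "kappa"), model)] <- 1
  }
  prep <- local({
    tr <- ape::reorder.phylo(tree, "postorder")
    pre <- rev(seq_len(nrow(tr$edge)))
    M <- ape::mrca(tree)
    list(M0 = as.integer(M) - 1L, par0 = as.integer(tr$edge[pre, 1L]) - 1L,
         child0 = as.integer(tr$edge[pre, 2L]) - 1L,
         b = tr$edge.length[pre], nnode = max(tr$edge))
  })
  refresh <- function(tp) {
    res <- gls_cache_cpp(prep$M0, prep$par0, prep$child0, prep$b, prep$nnode,
                         tp[["lambda"]], tp[["delta"]], tp[["kappa"]], y, X)
    if (!isTRUE(res$ok)) return(NULL)
    list(logdet = res$logdet, yt = drop(res$yt), Xt = res$Xt)
  }
  cache <- refresh(tpar)
  if (is.null(cache)) {
    stop("phylogenetic covariance is singular at the starting transforms",
         call. = FALSE)
  }
  beta <- if (prior_only) stats::rnorm(2, 0, priors$beta_sd) else {
    drop(stats::lm.fit(cache$Xt, cache$yt)$coefficients)
  }
  logs2 <- if (prior_only) stats::runif(1, priors$log_sigma2_range[1],
                                        priors$log_sigma2_range[2]) else {
    log(max(mean((cache$yt - cache$Xt %*% beta)^2), 1e-8))
  }

  # cached cross-products for the conjugate block updates
  sigma2 <- exp(logs2)
  xprod <- function(cache) {
    list(XtX = crossprod(cache$Xt), Xty = drop(crossprod(cache$Xt, cache$yt)),
         yty = sum(cache$yt^2))
  }
  cp <- xprod(cache)
  rss_of <- function(cp, beta) {
    # ||yt - Xt beta||^2 from cached cross-products
    cp$yty - 2 * sum(beta * cp$Xty) + drop(crossprod(beta, cp$XtX %*% beta))
  }
  loglik_of <- function(cache, cp, beta, sigma2) {
    if (prior_only) return(0)
    -0.5 * (n * log(2 * pi * sigma2) + cache$logdet + rss_of(cp, beta) / sigma2)
  }
  cur_ll <- loglik_of(cache, cp, beta, sigma2)

  # adaptive random-walk scales for the transform parameters only; beta
  # and sigma2 use exact conjugate (Gibbs) conditionals
  scale <- stats::setNames(rep(0.2, length(model)), model)
  acc <- win <- acc_total <- try_total <-
    stats::setNames(numeric(length(model)), model)
  rng <- priors$log_sigma2_range
  prior_prec <- 1 / priors$beta_sd^2

  it <- settings$iterations; burn <- settings$burnin; thin <- settings$thin
  nkeep <- floor((it - burn) / thin)
  keep <- matrix(NA_real_, nkeep, length(model) + 4L,
                 dimnames = list(NULL, c("beta1", "beta2", "sigma2", model,
                                         "loglik")))
  k <- 0L
  for (i in seq_len(it)) {
    # 1. transform parameters: random-scan Metropolis, one per sweep
    #    (each proposal triggers a covariance rebuild + Cholesky)
    if (length(model)) {
      p <- model[sample.int(length(model), 1L)]
      prop_tpar <- tpar
      prop_tpar[p] <- reflect(tpar[p] + stats::rnorm(1, 0, scale[p]),
                              los[p], caps[p])
      ok <- TRUE
      if (!prior_only) {
        new_cache <- refresh(prop_tpar)
        if (is.null(new_cache)) ok <- FALSE   # left the PD region
      } else new_cache <- cache
      if (ok) {
        new_cp <- if (prior_only) cp else xprod(new_cache)
        new_ll <- loglik_of(new_cache, new_cp, beta, sigma2)
        if (is.finite(new_ll) &&
            log(stats::runif(1)) < new_ll - cur_ll) {
          tpar <- prop_tpar; cache <- new_cache; cp <- new_cp
          cur_ll <- new_ll
          acc[p] <- acc[p] + 1; acc_total[p] <- acc_total[p] + 1
        }
      }
      win[p] <- win[p] + 1; try_total[p] <- try_total[p] + 1
      # adapt during burn-in only; kernel frozen afterwards (bounded so a
      # flat target, e.g. a prior-only run, cannot run the scale away)
      if (i <= burn && i %% 50L == 0L) {
        rate <- acc / pmax(win, 1)
        scale <- pmin(pmax(scale * exp(0.5 * (rate - 0.3)), 1e-3), 50)
        acc[] <- 0; win[] <- 0
      }
    }
    # 2. sigma2 | beta, C — inverse-gamma conditional under the flat
    #    ln-sigma2 prior; a draw outside the stated support keeps the
    #    current value (exact Metropolised-Gibbs for the truncated prior)
    if (prior_only) {
      sigma2 <- exp(stats::runif(1, rng[1], rng[2]))
    } else {
      s2_new <- 1 / stats::rgamma(1, shape = n / 2, rate = rss_of(cp, beta) / 2)
      if (log(s2_new) >= rng[1] && log(s2_new) <= rng[2]) sigma2 <- s2_new
    }
    # 3. beta | sigma2, C — conjugate normal conditional with the
    #    N(0, beta_sd^2) prior
    if (prior_only) {
      beta <- stats::rnorm(2, 0, priors$beta_sd)
    } else {
      A <- cp$XtX / sigma2 + diag(prior_prec, 2)
      U <- chol(A)
      mu <- backsolve(U, backsolve(U, cp$Xty / sigma2, transpose = TRUE))
      beta <- drop(mu + backsolve(U, stats::rnorm(2)))
    }
    cur_ll <- loglik_of(cache, cp, beta, sigma2)

    if (i > burn && (i - burn) %% thin == 0L) {
      k <- k + 1L
      keep[k, ] <- c(beta[1], beta[2], sigma2,
                     if (length(model)) tpar[model], cur_ll)
    }
  }
  rates <- acc_total / pmax(try_total, 1)
  if (length(rates) && any(rates < 0.05 | rates > 0.7)) {
    warning("acceptance rate outside [0.05, 0.7] for: ",
            paste(names(rates)[rates < 0.05 | rates > 0.7], collapse = ", "))
  }
  out <- as.data.frame(keep)
  attr(out, "settings") <- c(settings, list(seed = as.integer(seed)))
  attr(out, "model") <- model
  attr(out, "acceptance") <- rates
  attr(out, "priors") <- priors
  attr(out, "prior_only") <- prior_only
  class(out) <- c("regression_posterior", "data.frame")
  out
}

#' Summarize the phylogenetic t-test
#'
#' Posterior means and standard deviations for every sampled parameter,
#' the proportion of posterior mass on each side of slope = 0, and a
#' two-sided tail proportion (twice the smaller one-sided mass, capped at
#' 1) reported as the test summary.
#'
#' @param post a `regression_posterior`.
#' @export
phylo_ttest_summary <- function(post) {
  stopifnot(nrow(post) > 0)
  num <- post[, setdiff(colnames(post), "loglik"), drop = FALSE]
  b2 <- post$beta2
  p_pos <- mean(b2 > 0)
  p_neg <- mean(b2 < 0)
  out <- list(
    mean = vapply(num, mean, numeric(1)),
    sd = vapply(num, stats::sd, numeric(1)),
    prop_positive = p_pos,
    prop_negative = p_neg,
    tail_two_sided = min(1, 2 * min(p_pos, 1 - p_pos)),
    n_samples = nrow(post))
  class(out) <- "phylo_ttest_summary"
  out
}

#' @export
print.phylo_ttest_summary <- function(x, ...) {
  cat("phylogenetic t-test (", x$n_samples, " posterior samples)\n", sep = "")
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, 4))
  cat(sprintf("P(slope > 0) = %.1f%%; P(slope < 0) = %.1f%%; two-sided tail = %.4f\n",
              100 * x$prop_positive, 100 * x$prop_negative, x$tail_two_sided))
  invisible(x)
}

#' Brownian-motion ancestral estimates for a continuous trait
#'
#' Maximum-likelihood estimates of the trait value at every internal node
#' under Brownian motion, via the GLS / conditional-expectation
#' formulation: the root value is the GLS mean of the tips, and internal
#' nodes take their conditional expectation given the tips (which for a
#' Gaussian model is also the joint mode).
#'
#' @param tree a `phylo` object.
#' @param y named trait vector covering all tips.
#' @return numeric vector of estimates indexed by internal node number
#'   (ape convention: root is n_tips + 1).
#' @export
bm_ancestral_continuous <- function(tree, y) {
  n <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(y))
  if (length(miss)) stop("no trait value for: ", paste(miss, collapse = ", "))
  y <- y[tree$tip.label]
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)   # (2n-1) x (2n-1) MRCA node ids
  Cfull <- matrix(depth[M], nrow(M), ncol(M))
  tips <- seq_len(n)
  nodes <- (n + 1L):max(tree$edge)
  Ctt <- Cfull[tips, tips]
  Cat <- Cfull[nodes, tips, drop = FALSE]
  U <- chol_or_fail(Ctt + diag(1e-12, n))
  one <- rep(1, n)
  ot <- backsolve(U, one, transpose = TRUE)
  yt <- backsolve(U, y, transpose = TRUE)
  mu <- sum(ot * yt) / sum(ot^2)        # GLS root estimate
  w <- backsolve(U, backsolve(U, y - mu * one, transpose = TRUE))
  est <- mu + drop(Cat %*% w)
  names(est) <- as.character(nodes)
  est
}
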