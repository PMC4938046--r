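# Independent oracles used to verify the statistical operations. These
# implement the contracts from first principles (enumeration, closed
# formulas, brute-force quadrature + optimisation) and never call the
# package functions they check.

# Exact binomial p-value by full enumeration of the outcome distribution.
# Two-sided: point-probability rule — include every outcome whose pmf does
# not exceed that of the observed k, up to relative tolerance 1e-7.
enum_binom_p <- function(k, n, p0, alternative = "two_sided") {
  pmf <- stats::dbinom(0:n, n, p0)
  switch(alternative,
    two_sided = sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]),
    greater = sum(pmf[(k + 1):(n + 1)]),
    less = sum(pmf[1:(k + 1)])
  )
}

# Direct evaluation of the Agresti-Coull formula.
ac_oracle <- function(k, n, confidence) {
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n_adj <- n + z^2
  p_adj <- (k + z^2 / 2) / n_adj
  half <- z * sqrt(p_adj * (1 - p_adj) / n_adj)
  list(point = p_adj, lower = max(0, p_adj - half), upper = min(1, p_adj + half))
}

# Brute-force marginal maximum likelihood for the random-intercept logistic
# model: 64-point (non-adaptive) Gauss-Hermite quadrature over the colony
# intercept, maximised directly with nlminb over (beta, sigma).
gh_marginal_loglik <- function(par, X, y, colony, nodes, weights) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma <- par[p + 1]
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (lev in levels(colony)) {
    idx <- colony == lev
    contrib <- vapply(seq_along(nodes), function(q) {
      u <- sqrt(2) * sigma * nodes[q]
      exp(sum(stats::dbinom(y[idx], 1L, stats::plogis(eta[idx] + u), log = TRUE)))
    }, numeric(1))
    ll <- ll + log(sum(weights * contrib) / sqrt(pi))
  }
  ll
}

gh_glmm_oracle <- function(records, n_nodes = 64L) {
  skip_if_not_installed("pracma")
  gh <- pracma::gaussHermite(n_nodes)
  y <- as.integer(records$first_choice_cued)
  cue <- as.integer(records$cue_type == "social")
  dist <- as.integer(records$distribution == "high_variance")
  X <- cbind(1, cue, dist, cue * dist)
  colony <- factor(records$colony)
  start_glm <- stats::glm.fit(X, y, family = stats::binomial())
  start <- c(stats::coef(start_glm), 0.3)
  obj <- function(par) -gh_marginal_loglik(par, X, y, colony, gh$x, gh$w)
  opt <- stats::nlminb(start, obj,
                       lower = c(rep(-Inf, ncol(X)), 0),
                       control = list(rel.tol = 1e-14, iter.max = 2000,
                                      eval.max = 4000))
  list(loglik = -opt$objective, coefficients = opt$par[seq_len(ncol(X))],
       sigma = opt$par[ncol(X) + 1], convergence = opt$convergence)
}

# Build a bee_choices data frame by hand (used for small fixed fixtures).
make_bee_choices <- function(bee_id, colony, cue_type, distribution, landings) {
  out <- data.frame(bee_id = bee_id, colony = colony, cue_type = cue_type,
                    distribution = distribution,
                    first_choice_cued = vapply(landings, `[`, integer(1), 1L),
                    stringsAsFactors = FALSE)
  out$landings <- landings
  class(out) <- c("bee_choices", "data.frame")
  out
}
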