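# Shared fixtures and independent oracles, all constructed in code.

# Parameter-pair grid per kernel family covering both case branches of each
# sampling scheme (and, for two-parameter discrete families, each
# single-parameter move).
kernel_grid <- list(
  poisson = list(list(list(lambda = 1), list(lambda = 2.5)),
                 list(list(lambda = 2.5), list(lambda = 1)),
                 list(list(lambda = 0.3), list(lambda = 0.3))),
  bernoulli = list(list(list(prob = 0.3), list(prob = 0.6)),
                   list(list(prob = 0.6), list(prob = 0.3)),
                   list(list(prob = 0.05), list(prob = 0.95))),
  binomial = list(list(list(size = 10, prob = 0.2), list(size = 10, prob = 0.7)),
                  list(list(size = 10, prob = 0.7), list(size = 10, prob = 0.2)),
                  list(list(size = 6, prob = 0.4), list(size = 11, prob = 0.4)),
                  list(list(size = 11, prob = 0.4), list(size = 6, prob = 0.4))),
  geometric = list(list(list(prob = 0.3), list(prob = 0.7)),
                   list(list(prob = 0.7), list(prob = 0.3))),
  negative_binomial = list(
    list(list(size = 3, prob = 0.35), list(size = 3, prob = 0.6)),
    list(list(size = 3, prob = 0.6), list(size = 3, prob = 0.35)),
    list(list(size = 2, prob = 0.4), list(size = 5, prob = 0.4)),
    list(list(size = 5, prob = 0.4), list(size = 2, prob = 0.4))),
  normal = list(list(list(mean = 0, var = 1), list(mean = 2, var = 9)),
                list(list(mean = 2, var = 9), list(mean = 0, var = 1))),
  exponential = list(list(list(rate = 1), list(rate = 2.5)),
                     list(list(rate = 2.5), list(rate = 1))),
  gamma = list(list(list(shape = 2, rate = 1), list(shape = 5, rate = 2)),
               list(list(shape = 5, rate = 2), list(shape = 2, rate = 1))),
  beta = list(list(list(shape1 = 1.2, shape2 = 2), list(shape1 = 3, shape2 = 2)),
              list(list(shape1 = 3, shape2 = 2), list(shape1 = 1.2, shape2 = 2)),
              list(list(shape1 = 2, shape2 = 1.2), list(shape1 = 2, shape2 = 3)),
              list(list(shape1 = 2, shape2 = 3), list(shape1 = 2, shape2 = 1.2))),
  uniform = list(list(list(min = 0, max = 1), list(min = 2, max = 4)),
                 list(list(min = -1, max = 3), list(min = 0, max = 1))),
  lognormal = list(list(list(meanlog = 0, varlog = 1), list(meanlog = 1, varlog = 0.25)),
                   list(list(meanlog = 1, varlog = 0.25), list(meanlog = 0, varlog = 1)))
)

# identifiable default parameters per family (for identity/support tests)
family_defaults <- list(
  poisson = list(lambda = 2), normal = list(mean = 1, var = 2),
  exponential = list(rate = 1.5), gamma = list(shape = 2, rate = 1),
  beta = list(shape1 = 2, shape2 = 3), bernoulli = list(prob = 0.4),
  binomial = list(size = 8, prob = 0.4), uniform = list(min = 0, max = 2),
  geometric = list(prob = 0.4), negative_binomial = list(size = 3, prob = 0.4),
  lognormal = list(meanlog = 0, varlog = 1))

# Marginal posterior over the 2^P latent disease-status configurations of a
# small diagnostic-test data set, with all parameters integrated out
# analytically/numerically: flat Beta(1,1) prior on prevalence (conjugate)
# and flat priors on each (Se, Sp) pair truncated to Se + Sp > 1 (2-D
# integral reduced to 1-D adaptive quadrature).
enum_diag_posterior <- function(y1, y2) {
  P <- length(y1)
  configs <- as.matrix(expand.grid(rep(list(0:1), P)))
  tr_int <- function(a, b, cc, d) {
    stats::integrate(function(se)
      se^a * (1 - se)^b *
        stats::pbeta(1 - se, cc + 1, d + 1, lower.tail = FALSE) * beta(cc + 1, d + 1),
      0, 1, rel.tol = 1e-12)$value
  }
  w <- apply(configs, 1, function(D) {
    n1 <- sum(D)
    beta(1 + n1, 1 + P - n1) *
      tr_int(sum(y1[D == 1]), sum(1 - y1[D == 1]),
             sum(1 - y1[D == 0]), sum(y1[D == 0])) *
      tr_int(sum(y2[D == 1]), sum(1 - y2[D == 1]),
             sum(1 - y2[D == 0]), sum(y2[D == 0]))
  })
  list(configs = configs, prob = w / sum(w))
}

# empirical distribution over latent configurations from a stored trace
latent_config_freq <- function(trace, nbins) {
  L <- attr(trace, "latent")
  idx <- 1 + L %*% 2^(0:(ncol(L) - 1))
  tabulate(idx, nbins = nbins) / nrow(L)
}

# fixed 3-individual diagnostic fixture with mixed test outcomes
tiny_diag_data <- data.frame(individual = 1:3, y1 = c(1, 0, 1), y2 = c(1, 0, 0))

# two-node Bernoulli chain: z1 fixed, z2 depends on the first value
two_bern_model <- function(z1 = 0.3, za = 0.2, zb = 0.7) {
  pbp_model(
    params = list(pbp_param("dummy", 0, 1, init = 0.5)),
    nodes = list(
      pbp_node("bernoulli", integer(), function(xi, theta) list(prob = z1)),
      pbp_node("bernoulli", 1L, function(xi, theta)
        list(prob = if (xi[1] == 1) zb else za))))
}

# closed-form logistic growth curve matching the mean dynamics of the
# tau-leap model (r* = r_b - mu, K* = K (r_b - mu)/r_b)
logistic_ode <- function(t, P0, r_b, mu, K) {
  rs <- r_b - mu
  Ks <- K * rs / r_b
  Ks / (1 + (Ks / P0 - 1) * exp(-rs * t))
}
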