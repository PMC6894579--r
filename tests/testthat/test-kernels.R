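test_that("every kernel family preserves its marginal across both branches", {
  set.seed(11)
  for (fam in names(kernel_grid)) {
    for (pair in kernel_grid[[fam]]) {
      dev <- pbp_check_condition1(fam, pair[[1]], pair[[2]], n_mc = 4e4)
      tol <- if (fam %in% c("poisson", "bernoulli", "binomial", "geometric",
                            "negative_binomial")) 1e-10 else 3 / sqrt(4e4)
      expect_lt(dev, tol)
    }
  }
})

test_that("equal initial and proposed parameters return the input unchanged", {
  set.seed(12)
  for (fam in PBP_FAMILIES) {
    pr <- family_defaults[[fam]]
    xi <- pbp_rdraw <- pbpmcmc:::pbp_rdraw(fam, pr, 1e4)
    expect_identical(pbp_propose(fam, pr, pr, xi), xi)
  }
})

test_that("proposed values stay inside the proposed family's support", {
  set.seed(13)
  for (fam in names(kernel_grid)) {
    for (pair in kernel_grid[[fam]]) {
      xi <- pbpmcmc:::pbp_rdraw(fam, pair[[1]], 2000)
      xp <- pbp_propose(fam, pair[[1]], pair[[2]], xi)
      expect_true(all(is.finite(xp)))
      if (fam %in% c("poisson", "binomial", "geometric", "negative_binomial",
                     "bernoulli")) {
        expect_true(all(xp >= 0 & xp == round(xp)))
        if (fam == "bernoulli") expect_true(all(xp %in% 0:1))
        if (fam == "binomial") expect_true(all(xp <= pair[[2]]$size))
      }
      if (fam == "beta") expect_true(all(xp > 0 & xp < 1))
      if (fam %in% c("exponential", "gamma", "lognormal")) expect_true(all(xp > 0))
      if (fam == "uniform")
        expect_true(all(xp >= pair[[2]]$min & xp <= pair[[2]]$max))
    }
  }
})

test_that("normal kernel variance identity holds on both branches", {
  for (kappa in c(0, 0.03, 0.5, 1)) {
    for (vv in list(c(1, 9), c(9, 1), c(2, 2))) {
      vi <- vv[1]; vp <- vv[2]
      if (vp > vi) {
        a2 <- kappa + (1 - kappa) * vp / vi
        expect_equal(a2 * vi + kappa * (vp - vi), vp, tolerance = 1e-14)
      } else {
        a2 <- kappa + (1 - kappa) * vi / vp
        expect_equal(a2 * (vp / vi)^2 * vi + kappa * (vp / vi) * (vi - vp), vp,
                     tolerance = 1e-14)
      }
    }
  }
})

test_that("kappa = 0 reduces the normal kernel to the deterministic rescale", {
  out <- propose_normal(0, 1, 2, 9, xi_i = c(-1, 0, 1.7), kappa = 0)
  expect_equal(out, 2 + 3 * c(-1, 0, 1.7), tolerance = 1e-12)
})

test_that("ID densities are normalized", {
  for (fam in PBP_FAMILIES) {
    pr <- family_defaults[[fam]]
    if (fam %in% c("poisson", "bernoulli", "binomial", "geometric",
                   "negative_binomial")) {
      hi <- pbpmcmc:::.discrete_upper(fam, pr)
      expect_equal(sum(exp(pbp_density(fam, pr, 0:hi))), 1, tolerance = 1e-10)
    } else {
      lims <- switch(fam, normal = c(-Inf, Inf), uniform = c(pr$min, pr$max),
                     c(0, Inf))
      f <- function(x) exp(pbp_density(fam, pr, x))
      expect_equal(stats::integrate(f, lims[1], lims[2], rel.tol = 1e-10)$value,
                   1, tolerance = 1e-6)
    }
  }
})

test_that("worked single-case examples match hand calculations", {
  # Poisson mean drop to zero empties the count
  expect_equal(propose_poisson(3, 0, c(0L, 2L, 7L)), c(0L, 0L, 0L))
  # deterministic uniform affine map
  expect_equal(pbp_propose("uniform", list(min = 0, max = 1),
                           list(min = 2, max = 4), 0.25), 2.5)
  # gamma pure rate rescale when the shape is unchanged
  expect_equal(pbp_propose("gamma", list(shape = 2, rate = 1),
                           list(shape = 2, rate = 2), 3.0), 1.5)
  # certain-success Bernoulli move
  expect_equal(propose_bernoulli(0.3, 1, c(0L, 1L, 0L)), c(1L, 1L, 1L))
  # negative binomial pmf value (success-probability parameterization)
  expect_equal(pbp_density("negative_binomial", list(size = 3, prob = 0.4), 2),
               log(choose(4, 2) * 0.4^2 * 0.6^3), tolerance = 1e-12)
  # out-of-support values have zero density
  expect_identical(pbp_density("poisson", list(lambda = 2), -1), -Inf)
  expect_identical(pbp_density("beta", list(shape1 = 2, shape2 = 3), 1.5), -Inf)
  # poisson log pmf at zero is -lambda
  expect_equal(pbp_density("poisson", list(lambda = 2), 0), -2)
})

test_that("invalid characteristic parameters are rejected", {
  expect_error(propose_poisson(-1, 2, 0L), "negative")
  expect_error(propose_normal(0, -1, 0, 1, 0), "variance")
  expect_error(propose_bernoulli(0.5, 1.2, 1L), "0,1")
  expect_error(char_params("poisson", lambda = -2), "invalid")
  expect_error(char_params("poisson", rate = 2), "needs parameters")
  expect_error(propose_binomial(10, 0.3, 6, 0.5, 3L), "only one")
})

test_that("joint two-parameter changes decompose into valid sub-moves", {
  set.seed(14)
  # beta with both shapes changed: composition still maps marginals exactly
  i <- list(shape1 = 2, shape2 = 3); p <- list(shape1 = 4, shape2 = 1.5)
  xi <- stats::rbeta(4e4, i$shape1, i$shape2)
  xp <- pbp_propose("beta", i, p, xi)
  xs <- sort(xp)
  n <- length(xs)
  Fp <- stats::pbeta(xs, p$shape1, p$shape2)
  expect_lt(max(abs((1:n) / n - Fp), abs((0:(n - 1)) / n - Fp)), 3 / sqrt(n))
  # binomial with both size and prob changed
  i <- list(size = 10, prob = 0.3); p <- list(size = 6, prob = 0.6)
  xi <- stats::rbinom(4e4, i$size, i$prob)
  xp <- pbp_propose("binomial", i, p, xi)
  emp <- tabulate(xp + 1, nbins = p$size + 1) / length(xp)
  expect_lt(max(abs(emp - stats::dbinom(0:p$size, p$size, p$prob))), 3 / sqrt(4e4))
})
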