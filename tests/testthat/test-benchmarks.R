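test_that("scenario constructors validate their domains", {
  expect_error(svt_scenario(phi = 1.2))
  expect_error(svt_scenario(nu = 1.5))
  expect_error(mixed_scenario(r2 = 1.4))
  expect_error(diagnostic_scenario(p_D = -0.1))
  expect_error(logistic_scenario(K = -5))
})

test_that("diagnostic simulator matches its closed-form positive rate", {
  set.seed(61)
  scn <- diagnostic_scenario(P = 4e4, p_D = 0.3, Se = c(0.7, 0.6), Sp = c(0.95, 0.85))
  sim <- simulate_scenario(scn)
  pexp <- scn$p_D * scn$Se[1] + (1 - scn$p_D) * (1 - scn$Sp[1])
  expect_lt(abs(mean(sim$data$y1) - pexp), 3 * sqrt(pexp * (1 - pexp) / scn$P))
  expect_lt(abs(mean(sim$latent) - scn$p_D), 3 * sqrt(0.25 / scn$P))
})

test_that("volatility simulator reproduces the AR(1) stationary variance", {
  set.seed(62)
  scn <- svt_scenario(E = 2e4, phi = 0.9, sigma2 = 0.04)
  sim <- simulate_scenario(scn)
  vstat <- scn$sigma2 / (1 - scn$phi^2)
  expect_lt(abs(stats::var(sim$latent) / vstat - 1), 0.15)
  expect_lt(abs(mean(sim$latent) - scn$mu), 0.1)
})

test_that("pedigree simulation and relationship matrix follow the tabular rules", {
  set.seed(63)
  ped1 <- simulate_pedigree(1, 6)
  expect_true(all(ped1$sire == 0))
  expect_equal(pedigree_A(ped1), diag(6))
  # explicit full-sib / parent-offspring pedigree
  ped <- data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 2))
  A <- pedigree_A(ped)
  expect_equal(A[1, 3], 0.5)   # parent-offspring
  expect_equal(A[3, 4], 0.5)   # full sibs
  expect_equal(diag(A), rep(1, 4))
  # simulated breeding values reproduce sigma_a^2 A on a small pedigree
  ped5 <- simulate_pedigree(2, 3)[1:5, ]
  scn <- mixed_scenario(generations = 2, n_per_gen = 3, r2 = 0.5, sigma_p2 = 2)
  s2a <- scn$r2 * scn$sigma_p2
  n <- 2e4
  draws <- matrix(0, n, 5)
  for (k in seq_len(n)) {
    a <- numeric(5)
    for (e in 1:5) {
      a[e] <- if (ped5$sire[e] == 0) stats::rnorm(1, 0, sqrt(s2a))
              else stats::rnorm(1, (a[ped5$sire[e]] + a[ped5$dam[e]]) / 2, sqrt(s2a / 2))
    }
    draws[k, ] <- a
  }
  A5 <- pedigree_A(ped5)
  expect_true(all(abs(stats::cov(draws) - s2a * A5) < 6 / sqrt(n) * s2a))
})

test_that("population simulator tracks the logistic growth curve at small tau", {
  set.seed(64)
  scn <- logistic_scenario(T = 201, tau = 0.05, r_b = 0.8, mu = 0.2, K = 200,
                           P0 = 10, M = 5)
  reps <- 300
  traj <- matrix(0, reps, scn$T)
  for (k in seq_len(reps))
    traj[k, ] <- simulate_scenario(scn)$latent$P
  mtraj <- colMeans(traj)
  tgrid <- (seq_len(scn$T) - 1) * scn$tau
  ode <- logistic_ode(tgrid, scn$P0, scn$r_b, scn$mu, scn$K)
  pre_eq <- which(ode < 0.9 * max(ode) & tgrid > 0.5)
  expect_lt(max(abs(mtraj[pre_eq] / ode[pre_eq] - 1)), 0.05)
  # equilibrium near K (1 - mu / r_b)
  expect_lt(abs(mean(traj[, scn$T]) / (scn$K * (1 - scn$mu / scn$r_b)) - 1), 0.05)
})

test_that("fast-path likelihoods equal the generic per-node evaluation", {
  set.seed(65)
  checks <- list(
    {
      scn <- diagnostic_scenario(P = 8); sim <- simulate_scenario(scn, 66)
      list(bm = build_diagnostic(scn, sim$data), xi = sim$latent,
           th = c(p_D = 0.4, Se1 = 0.7, Se2 = 0.6, Sp1 = 0.9, Sp2 = 0.8))
    },
    {
      scn <- svt_scenario(E = 10); sim <- simulate_scenario(scn, 67)
      list(bm = build_svt(scn, sim$data), xi = sim$latent,
           th = c(mu = -9, phi = 0.9, nu = 8, sigma2 = 0.05))
    },
    {
      scn <- mixed_scenario(2, 4); sim <- simulate_scenario(scn, 68)
      list(bm = build_mixed(scn, sim$pedigree, sim$data), xi = sim$latent,
           th = c(beta1 = 10, beta2 = 2, sigma_a2 = 0.5, sigma_e2 = 0.5))
    },
    {
      scn <- logistic_scenario(T = 9, M = 3, P0 = 30); sim <- simulate_scenario(scn, 69)
      bm <- build_logistic(scn, sim$data)
      xi <- numeric(16)
      xi[seq(1, 15, 2)] <- sim$latent$b
      xi[seq(2, 16, 2)] <- sim$latent$d
      list(bm = bm, xi = xi, th = c(r_b = 0.6, mu_d = 0.3, K = 100, p = 0.5))
    })
  for (cs in checks) {
    mg <- cs$bm$model; mg$fast <- NULL
    expect_equal(latent_loglik(cs$bm$model, cs$th, cs$xi),
                 latent_loglik(mg, cs$th, cs$xi), tolerance = 1e-10)
    expect_equal(obs_loglik(cs$bm$model, cs$th, cs$xi),
                 obs_loglik(mg, cs$th, cs$xi), tolerance = 1e-10)
  }
})

test_that("compiled regeneration reproduces the generic route draw for draw", {
  # same RNG stream, same branch logic: outputs must be bit-identical
  cases <- list(
    {
      scn <- svt_scenario(E = 20); sim <- simulate_scenario(scn, 71)
      bm <- build_svt(scn, sim$data)
      list(bm = bm, xi = sim$latent, lv = 1L,
           ti = c(mu = -9.8, phi = 0.95, nu = 11, sigma2 = 0.02),
           tp = c(mu = -9.7, phi = 0.96, nu = 12, sigma2 = 0.018))
    },
    {
      scn <- mixed_scenario(3, 5); sim <- simulate_scenario(scn, 72)
      bm <- build_mixed(scn, sim$pedigree, sim$data)
      list(bm = bm, xi = sim$latent, lv = 2L,
           ti = c(beta1 = 10, beta2 = 2, sigma_a2 = 0.5, sigma_e2 = 0.5),
           tp = c(beta1 = 10.1, beta2 = 1.9, sigma_a2 = 0.55, sigma_e2 = 0.45))
    },
    {
      scn <- logistic_scenario(T = 15, M = 4, P0 = 40)
      sim <- simulate_scenario(scn, 73)
      bm <- build_logistic(scn, sim$data)
      xi <- numeric(28)
      xi[seq(1, 27, 2)] <- sim$latent$b
      xi[seq(2, 28, 2)] <- sim$latent$d
      list(bm = bm, xi = xi, lv = 0L,
           ti = c(r_b = 0.6, mu_d = 0.3, K = 100, p = 0.5),
           tp = c(r_b = 0.63, mu_d = 0.29, K = 105, p = 0.5))
    })
  for (cs in cases) {
    mg <- cs$bm$model; mg$fast <- NULL
    ids_g <- switch(cs$lv + 1L, make_id0(mg),
                    make_id1(cs$bm$model), make_id2(cs$bm$model))
    ids_f <- switch(cs$lv + 1L, make_id0(cs$bm$model),
                    make_id1(cs$bm$model), make_id2(cs$bm$model))
    set.seed(74)
    rf <- pbpmcmc:::.regen_latent(cs$bm$model, ids_f, cs$ti, cs$tp, cs$xi, 0.03)
    set.seed(74)
    rg <- pbpmcmc:::.regen_latent(mg, ids_g, cs$ti, cs$tp, cs$xi, 0.03)
    expect_equal(rf$xi_p, rg$xi_p, tolerance = 1e-12)
    expect_equal(rf$fid_i, rg$fid_i, tolerance = 1e-9)
    expect_equal(rf$fid_p, rg$fid_p, tolerance = 1e-9)
  }
})

test_that("benchmark forward simulation matches declared observation laws", {
  set.seed(75)
  scn <- diagnostic_scenario(P = 2000, p_D = 0.5, Se = c(0.6, 0.6), Sp = c(0.9, 0.9))
  sim <- simulate_scenario(scn)
  bm <- build_diagnostic(scn, sim$data)
  th <- c(p_D = 0.5, Se1 = 0.6, Se2 = 0.6, Sp1 = 0.9, Sp2 = 0.9)
  fs <- simulate_forward(bm$model, th)
  expect_lt(abs(mean(fs$xi) - 0.5), 3 * sqrt(0.25 / scn$P))
  y1 <- vapply(fs$y, `[`, 0, 1)
  expect_lt(abs(mean(y1) - 0.35), 3 * sqrt(0.35 * 0.65 / scn$P))
})

test_that("pedigrees violating the ordering contract are rejected", {
  bad <- data.frame(id = 1:3, sire = c(0, 3, 1), dam = c(0, 0, 2))
  expect_error(build_mixed(mixed_scenario(2, 2), bad,
                           data.frame(individual = 1:3, x2 = 0:2 %% 2,
                                      record = c(1, 2, 3))),
               "pedigree")
})
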