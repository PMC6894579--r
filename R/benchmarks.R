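#' Benchmark scenarios
#'
#' Constructors for the generating scenarios of the four benchmark models.
#' Defaults reproduce the published study conditions; tests and examples
#' scale the sizes down.
#'
#' @name scenarios
NULL

#' @describeIn scenarios Latent-class diagnostic-test model: `P` individuals
#'   with true disease status `D_e ~ Bernoulli(p_D)` and two imperfect test
#'   results per individual (sensitivities `Se`, specificities `Sp`).
#' @param P Number of individuals.
#' @param p_D Disease prevalence.
#' @param Se,Sp Length-2 sensitivities and specificities of the two tests.
#' @export
diagnostic_scenario <- function(P = 1000, p_D = 0.5, Se = c(0.6, 0.6),
                                Sp = c(0.9, 0.9)) {
  stopifnot(P >= 1, p_D >= 0, p_D <= 1, all(Se >= 0 & Se <= 1),
            all(Sp >= 0 & Sp <= 1), length(Se) == 2, length(Sp) == 2)
  structure(list(P = as.integer(P), p_D = p_D, Se = Se, Sp = Sp),
            class = c("diagnostic_scenario", "pbp_scenario"))
}

#' @describeIn scenarios Stochastic volatility model with Student-t returns:
#'   log-volatilities follow the AR(1) `h_e = mu + phi (h_{e-1} - mu) + eta_e`
#'   with `eta_e ~ N(0, sigma2)` and stationary initial state, and daily
#'   log returns are `y_e = exp(h_e/2) u_e` with `u_e ~ t_nu`. Defaults are
#'   estimates typical of a broad equity index.
#' @param E Number of days.
#' @param mu Mean log-volatility.
#' @param phi AR(1) persistence, in (0, 1).
#' @param nu Student-t degrees of freedom (> 2).
#' @param sigma2 Innovation variance.
#' @export
svt_scenario <- function(E = 3000, mu = -10, phi = 0.99, nu = 12,
                         sigma2 = 0.0121) {
  stopifnot(E >= 2, phi > 0, phi < 1, nu > 2, sigma2 > 0)
  structure(list(E = as.integer(E), mu = mu, phi = phi, nu = nu,
                 sigma2 = sigma2),
            class = c("svt_scenario", "pbp_scenario"))
}

#' @describeIn scenarios Pedigree-based mixed model (animal model): records
#'   `y = X beta + a + eps` with breeding values decomposed along a pedigree
#'   of `generations` generations of `n_per_gen` randomly mated individuals,
#'   `a` having covariance `sigma_a^2 A`, and `r2 = sigma_a^2 /
#'   (sigma_a^2 + sigma_e^2)`. One record per individual; fixed effects are
#'   an intercept and one binary covariate.
#' @param generations,n_per_gen Pedigree depth and width.
#' @param r2 Variance ratio `sigma_a^2 / (sigma_a^2 + sigma_e^2)`.
#' @param sigma_p2 Total (phenotypic) variance.
#' @param beta Fixed-effect vector (intercept, binary-covariate effect).
#' @export
mixed_scenario <- function(generations = 4, n_per_gen = 1000, r2 = 0.5,
                           sigma_p2 = 1, beta = c(10, 2)) {
  stopifnot(generations >= 1, n_per_gen >= 2, r2 >= 0, r2 <= 1, sigma_p2 > 0,
            length(beta) == 2)
  structure(list(generations = as.integer(generations),
                 n_per_gen = as.integer(n_per_gen), r2 = r2,
                 sigma_p2 = sigma_p2, beta = beta),
            class = c("mixed_scenario", "pbp_scenario"))
}

#' @describeIn scenarios Tau-leaping logistic birth-death population model:
#'   `b_t ~ Pois(tau r_b P_t (1 - P_t/K))`, `d_t ~ Pois(tau mu P_t)`,
#'   `P_{t+1} = P_t + b_t - d_t`, observed through `M` equally spaced
#'   binomial trap counts with capture probability `p`.
#' @param T Number of time points (so `T - 1` tau-leap steps).
#' @param tau Time-step size.
#' @param r_b,mu Birth and mortality rates.
#' @param K Carrying capacity.
#' @param p Capture probability.
#' @param M Number of measurements (equally spaced over the `T` points).
#' @param P0 Known released population size at the first time point.
#' @export
logistic_scenario <- function(T = 401, tau = 0.1, r_b = 0.6, mu = 0.3,
                              K = 100, p = 0.5, M = 21, P0 = 10) {
  stopifnot(T >= 3, tau > 0, r_b >= 0, mu >= 0, K > 0, p >= 0, p <= 1,
            M >= 1, P0 >= 0)
  structure(list(T = as.integer(T), tau = tau, r_b = r_b, mu = mu, K = K,
                 p = p, M = as.integer(M), P0 = as.integer(P0)),
            class = c("logistic_scenario", "pbp_scenario"))
}

#' Simulate synthetic data from a benchmark scenario
#'
#' Draws one data set from the scenario's generating model, returning tidy
#' data tables (as written by the command-line interface), the true latent
#' values for parameter-recovery checks, and any auxiliary design objects
#' (pedigree, covariates).
#'
#' @param scn A scenario object.
#' @param seed Optional integer seed.
#' @return A list whose elements depend on the scenario class; always
#'   includes `data` (a data frame) and `latent`.
#' @export
simulate_scenario <- function(scn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  UseMethod("simulate_scenario")
}

#' @export
simulate_scenario.diagnostic_scenario <- function(scn, seed = NULL) {
  D <- stats::rbinom(scn$P, 1, scn$p_D)
  y1 <- stats::rbinom(scn$P, 1, ifelse(D == 1, scn$Se[1], 1 - scn$Sp[1]))
  y2 <- stats::rbinom(scn$P, 1, ifelse(D == 1, scn$Se[2], 1 - scn$Sp[2]))
  list(data = data.frame(individual = seq_len(scn$P), y1 = y1, y2 = y2),
       latent = D)
}

#' @export
simulate_scenario.svt_scenario <- function(scn, seed = NULL) {
  h <- numeric(scn$E)
  h[1] <- stats::rnorm(1, scn$mu, sqrt(scn$sigma2 / (1 - scn$phi^2)))
  for (e in 2:scn$E)
    h[e] <- scn$mu + scn$phi * (h[e - 1] - scn$mu) + stats::rnorm(1, 0, sqrt(scn$sigma2))
  y <- exp(h / 2) * stats::rt(scn$E, scn$nu)
  list(data = data.frame(day = seq_len(scn$E), y = y), latent = h)
}

#' @export
simulate_scenario.mixed_scenario <- function(scn, seed = NULL) {
  ped <- simulate_pedigree(scn$generations, scn$n_per_gen)
  E <- nrow(ped)
  s2a <- scn$r2 * scn$sigma_p2
  s2e <- (1 - scn$r2) * scn$sigma_p2
  a <- numeric(E)
  for (e in seq_len(E)) {
    a[e] <- if (ped$sire[e] == 0) stats::rnorm(1, 0, sqrt(s2a))
            else stats::rnorm(1, (a[ped$sire[e]] + a[ped$dam[e]]) / 2, sqrt(s2a / 2))
  }
  x2 <- stats::rbinom(E, 1, 0.5)
  y <- scn$beta[1] + scn$beta[2] * x2 + a + stats::rnorm(E, 0, sqrt(s2e))
  list(data = data.frame(individual = seq_len(E), x2 = x2, record = y),
       pedigree = ped, latent = a)
}

#' @export
simulate_scenario.logistic_scenario <- function(scn, seed = NULL) {
  nst <- scn$T - 1L
  b <- d <- integer(nst)
  P <- integer(scn$T)
  P[1] <- scn$P0
  for (t in seq_len(nst)) {
    lb <- max(0, scn$tau * scn$r_b * P[t] * (1 - P[t] / scn$K))
    b[t] <- stats::rpois(1, lb)
    d[t] <- stats::rpois(1, max(0, scn$tau * scn$mu * P[t]))
    P[t + 1] <- P[t] + b[t] - d[t]
    if (P[t + 1] < 0) { d[t] <- d[t] + P[t + 1]; P[t + 1] <- 0 }  # exhaust at zero
  }
  obs_times <- unique(round(seq(1, scn$T, length.out = scn$M)))
  y <- stats::rbinom(length(obs_times), P[obs_times], scn$p)
  list(data = data.frame(time = obs_times, count = y),
       latent = list(b = b, d = d, P = P))
}

# ---------------------------------------------------------------------------
# diagnostic-test benchmark

#' Build the diagnostic-test benchmark model
#'
#' Latent-class model for disease prevalence and test performance without a
#' gold standard: each individual's true status is Bernoulli(`p_D`) and two
#' conditionally independent test results are observed, positive with
#' probability `Se_t` when infected and `1 - Sp_t` when not. All five
#' parameters carry uniform priors on the unit interval; chains are started
#' in the `Se, Sp > 0.5` half to select the scientifically meaningful mode
#' of the label-switching pair. The level-1 importance distribution is the
#' exact per-individual conditional posterior, and conjugate beta Gibbs
#' samplers for all parameters are registered for the baseline.
#'
#' @param scn A [diagnostic_scenario()].
#' @param data Data frame with columns `individual`, `y1`, `y2` (as from
#'   [simulate_scenario()]); `NULL` leaves observations unbound.
#' @return List with elements `model` ([pbp_model]) and `ids` (the
#'   recommended level-1 `id_spec`).
#' @export
build_diagnostic <- function(scn, data = NULL) {
  P <- scn$P
  env <- new.env(parent = emptyenv())
  env$y1 <- if (is.null(data)) rep(NA_real_, P) else data$y1
  env$y2 <- if (is.null(data)) rep(NA_real_, P) else data$y2

  params <- list(
    pbp_param("p_D", 0, 1, init = function(y) 0.5),
    pbp_param("Se1", 0, 1, init = function(y) stats::runif(1, 0.55, 0.95)),
    pbp_param("Se2", 0, 1, init = function(y) stats::runif(1, 0.55, 0.95)),
    pbp_param("Sp1", 0, 1, init = function(y) stats::runif(1, 0.55, 0.95)),
    pbp_param("Sp2", 0, 1, init = function(y) stats::runif(1, 0.55, 0.95)))

  nodes <- lapply(seq_len(P), function(e)
    pbp_node("bernoulli", integer(),
             function(xi, theta) list(prob = theta[["p_D"]])))
  obs <- lapply(seq_len(P), function(e) {
    force(e)
    pbp_obs(
      value = c(env$y1[e], env$y2[e]),
      log_density = function(value, xi, theta) {
        pr1 <- if (xi[e] == 1) theta[["Se1"]] else 1 - theta[["Sp1"]]
        pr2 <- if (xi[e] == 1) theta[["Se2"]] else 1 - theta[["Sp2"]]
        stats::dbinom(value[1], 1, pr1, log = TRUE) +
          stats::dbinom(value[2], 1, pr2, log = TRUE)
      },
      depends = e,
      simulate = function(xi, theta) {
        pr1 <- if (xi[e] == 1) theta[["Se1"]] else 1 - theta[["Sp1"]]
        pr2 <- if (xi[e] == 1) theta[["Se2"]] else 1 - theta[["Sp2"]]
        c(stats::rbinom(1, 1, pr1), stats::rbinom(1, 1, pr2))
      })
  })

  id1_z <- function(theta) {
    l1 <- theta[["Se1"]]^env$y1 * (1 - theta[["Se1"]])^(1 - env$y1) *
          theta[["Se2"]]^env$y2 * (1 - theta[["Se2"]])^(1 - env$y2)
    l0 <- (1 - theta[["Sp1"]])^env$y1 * theta[["Sp1"]]^(1 - env$y1) *
          (1 - theta[["Sp2"]])^env$y2 * theta[["Sp2"]]^(1 - env$y2)
    w1 <- theta[["p_D"]] * l1
    w1 / (w1 + (1 - theta[["p_D"]]) * l0)
  }

  fast <- list(
    regen_levels = c(0L, 1L),
    latent_loglik = function(theta, xi)
      sum(stats::dbinom(xi, 1, theta[["p_D"]], log = TRUE)),
    obs_loglik = function(theta, xi) {
      pr1 <- xi * theta[["Se1"]] + (1 - xi) * (1 - theta[["Sp1"]])
      pr2 <- xi * theta[["Se2"]] + (1 - xi) * (1 - theta[["Sp2"]])
      sum(stats::dbinom(env$y1, 1, pr1, log = TRUE)) +
        sum(stats::dbinom(env$y2, 1, pr2, log = TRUE))
    },
    regen = function(model, level, theta_i, theta_p, xi_i, kappa) {
      if (level == 0L) {
        z_i <- rep(theta_i[["p_D"]], P); z_p <- rep(theta_p[["p_D"]], P)
      } else {
        z_i <- id1_z(theta_i); z_p <- id1_z(theta_p)
      }
      xi_p <- propose_bernoulli(z_i, z_p, xi_i)
      list(xi_p = xi_p,
           fid_i = sum(stats::dbinom(xi_i, 1, z_i, log = TRUE)),
           fid_p = sum(stats::dbinom(xi_p, 1, z_p, log = TRUE)))
    },
    sweep = function(model, state, steps) {
      z <- id1_z(state$theta)  # exact conditional posterior: vectorized Gibbs
      state$xi <- stats::rbinom(P, 1, z)
      state$ll_lat <- model$fast$latent_loglik(state$theta, state$xi)
      state$ll_obs <- model$fast$obs_loglik(state$theta, state$xi)
      list(state = state, acc = P, att = P)
    },
    gibbs_params = function(model, state) {
      D <- state$xi
      n1 <- sum(D); n0 <- P - n1
      th <- state$theta
      th[["p_D"]] <- stats::rbeta(1, 1 + n1, 1 + n0)
      th[["Se1"]] <- stats::rbeta(1, 1 + sum(env$y1[D == 1]), 1 + sum(1 - env$y1[D == 1]))
      th[["Se2"]] <- stats::rbeta(1, 1 + sum(env$y2[D == 1]), 1 + sum(1 - env$y2[D == 1]))
      th[["Sp1"]] <- stats::rbeta(1, 1 + sum(1 - env$y1[D == 0]), 1 + sum(env$y1[D == 0]))
      th[["Sp2"]] <- stats::rbeta(1, 1 + sum(1 - env$y2[D == 0]), 1 + sum(env$y2[D == 0]))
      # drawing from the unconstrained conditionals and keeping the current
      # state when the draw violates the identifiability constraint is an
      # exact Metropolized-Gibbs move on the truncated posterior
      if (!isTRUE(model$constraint(th))) return(state)
      state$theta <- th
      state$ll_lat <- model$fast$latent_loglik(th, state$xi)
      state$ll_obs <- model$fast$obs_loglik(th, state$xi)
      state$lp <- prior_loglik(model, th)
      state
    },
    id1_rule = function(model) lapply(seq_len(P), function(e) {
      force(e)
      list(family = "bernoulli",
           params_fn = function(xi, theta) list(prob = id1_z(theta)[e]))
    }),
    rebind = function(model, y) {
      env$y1 <- vapply(y, `[`, 0, 1)
      env$y2 <- vapply(y, `[`, 0, 2)
      model
    },
    simulate = function(theta) {
      D <- stats::rbinom(P, 1, theta[["p_D"]])
      y1 <- stats::rbinom(P, 1, D * theta[["Se1"]] + (1 - D) * (1 - theta[["Sp1"]]))
      y2 <- stats::rbinom(P, 1, D * theta[["Se2"]] + (1 - D) * (1 - theta[["Sp2"]]))
      list(xi = D, y = lapply(seq_len(P), function(e) c(y1[e], y2[e])))
    })

  model <- pbp_model(params, nodes, obs, fast = fast,
                     info = list(benchmark = "diagnostic", scenario = scn),
                     # identifiability: each test informative (Se + Sp > 1),
                     # which removes the label-switched mirror mode
                     constraint = function(theta)
                       theta[["Se1"]] + theta[["Sp1"]] > 1 &&
                       theta[["Se2"]] + theta[["Sp2"]] > 1)
  list(model = model, ids = make_id1(model))
}

# ---------------------------------------------------------------------------
# stochastic volatility benchmark

#' Build the stochastic-volatility benchmark model
#'
#' AR(1) log-volatility chain with Student-t observation noise. Normal
#' kernels drive the latent moves; the level-1 importance distribution
#' folds each day's return into the conditional via a quadratic expansion
#' of the log observation term about its mode `h = log(y^2)` (curvature
#' `nu / (2 (nu + 1))`, exact at the mode), which keeps the ID normal and
#' the per-day parameters closed-form.
#'
#' @param scn An [svt_scenario()].
#' @param data Data frame with columns `day`, `y`; `NULL` leaves
#'   observations unbound.
#' @return List with elements `model` and `ids` (level-1 spec).
#' @export
build_svt <- function(scn, data = NULL) {
  E <- scn$E
  env <- new.env(parent = emptyenv())
  .bind <- function(y) {
    env$y <- y
    env$yzero <- y == 0
    env$h0 <- ifelse(env$yzero, 0, log(y^2))
  }
  .bind(if (is.null(data)) rep(NA_real_, E) else data$y)

  # method-of-moments starting values from log squared returns:
  # log y^2 = h + log u^2, and for Student-t noise log u^2 has mean ~ -1.27
  # and variance ~ 5, so the variance and lag-1 autocovariance of log y^2
  # identify the AR(1) variance and persistence
  mom_init <- function() {
    ly <- env$h0
    v <- stats::var(ly)
    r1 <- stats::cor(ly[-1], ly[-length(ly)])
    var_h <- max(v - 5, 0.01)
    phi <- min(max(r1 * v / var_h, 0.2), 0.98)
    list(mu = mean(ly) + 1.27, phi = phi, sigma2 = var_h * (1 - phi^2))
  }
  params <- list(
    pbp_param("mu", -Inf, Inf,
              init = function(y) mom_init()$mu + stats::rnorm(1, 0, 0.3)),
    pbp_param("phi", 1e-6, 1 - 1e-6,
              init = function(y) min(max(mom_init()$phi + stats::rnorm(1, 0, 0.02),
                                         0.1), 0.995)),
    pbp_param("nu", 2.001, 100, init = function(y) stats::runif(1, 5, 20)),
    pbp_param("sigma2", 1e-10, Inf,
              init = function(y) mom_init()$sigma2 * stats::runif(1, 0.7, 1.4)))

  nodes <- lapply(seq_len(E), function(e) {
    force(e)
    if (e == 1)
      pbp_node("normal", integer(), function(xi, theta)
        list(mean = theta[["mu"]],
             var = theta[["sigma2"]] / (1 - theta[["phi"]]^2)))
    else
      pbp_node("normal", e - 1L, function(xi, theta)
        list(mean = theta[["mu"]] + theta[["phi"]] * (xi[e - 1] - theta[["mu"]]),
             var = theta[["sigma2"]]))
  })
  obs <- lapply(seq_len(E), function(e) {
    force(e)
    pbp_obs(
      value = env$y[e],
      log_density = function(value, xi, theta)
        stats::dt(value * exp(-xi[e] / 2), theta[["nu"]], log = TRUE) - xi[e] / 2,
      depends = e,
      simulate = function(xi, theta) exp(xi[e] / 2) * stats::rt(1, theta[["nu"]]))
  })

  ar1_means <- function(theta, h) {
    c(theta[["mu"]],
      theta[["mu"]] + theta[["phi"]] * (h[-E] - theta[["mu"]]))
  }
  ar1_vars <- function(theta) {
    c(theta[["sigma2"]] / (1 - theta[["phi"]]^2), rep(theta[["sigma2"]], E - 1))
  }

  fast <- list(
    regen_levels = c(0L, 1L),
    latent_loglik = function(theta, xi)
      sum(stats::dnorm(xi, ar1_means(theta, xi), sqrt(ar1_vars(theta)), log = TRUE)),
    obs_loglik = function(theta, xi)
      sum(stats::dt(env$y * exp(-xi / 2), theta[["nu"]], log = TRUE) - xi / 2),
    regen = function(model, level, theta_i, theta_p, xi_i, kappa) {
      cpp_svt_regen(xi_i, env$h0, env$yzero,
                    theta_i[["mu"]], theta_i[["phi"]], theta_i[["sigma2"]],
                    theta_i[["nu"]] / (2 * (theta_i[["nu"]] + 1)),
                    theta_p[["mu"]], theta_p[["phi"]], theta_p[["sigma2"]],
                    theta_p[["nu"]] / (2 * (theta_p[["nu"]] + 1)),
                    as.integer(level), kappa)
    },
    sweep = function(model, state, steps) {
      sw <- cpp_svt_sweep(state$xi, env$y, state$theta[["mu"]],
                          state$theta[["phi"]], state$theta[["sigma2"]],
                          state$theta[["nu"]], steps$xi[1])
      state$xi <- sw$xi
      state$ll_lat <- model$fast$latent_loglik(state$theta, state$xi)
      state$ll_obs <- model$fast$obs_loglik(state$theta, state$xi)
      list(state = state, acc = sw$acc, att = sw$att)
    },
    id1_rule = function(model) lapply(seq_len(E), function(e) {
      force(e)
      list(family = "normal", params_fn = function(xi, theta) {
        m <- if (e == 1) theta[["mu"]]
             else theta[["mu"]] + theta[["phi"]] * (xi[e - 1] - theta[["mu"]])
        v <- if (e == 1) theta[["sigma2"]] / (1 - theta[["phi"]]^2)
             else theta[["sigma2"]]
        c2 <- if (env$yzero[e]) 0 else theta[["nu"]] / (2 * (theta[["nu"]] + 1))
        c1 <- if (env$yzero[e]) -0.5 else 0
        tau <- 1 / v + c2
        list(mean = (m / v + c2 * env$h0[e] + c1) / tau, var = 1 / tau)
      })
    }),
    rebind = function(model, y) { .bind(unlist(y)); model },
    simulate = function(theta) {
      h <- numeric(E)
      h[1] <- stats::rnorm(1, theta[["mu"]],
                           sqrt(theta[["sigma2"]] / (1 - theta[["phi"]]^2)))
      for (e in seq_len(E)[-1])
        h[e] <- theta[["mu"]] + theta[["phi"]] * (h[e - 1] - theta[["mu"]]) +
          stats::rnorm(1, 0, sqrt(theta[["sigma2"]]))
      y <- exp(h / 2) * stats::rt(E, theta[["nu"]])
      list(xi = h, y = as.list(y))
    })

  model <- pbp_model(params, nodes, obs, fast = fast,
                     info = list(benchmark = "svt", scenario = scn))
  list(model = model, ids = make_id1(model))
}

# ---------------------------------------------------------------------------
# pedigree mixed-model benchmark

#' Simulate a random-mating pedigree
#'
#' Generation 0 consists of founders (unknown parents, coded 0); each
#' individual in a later generation receives a sire and a dam drawn at
#' random (distinct) from the previous generation.
#'
#' @param generations Number of generations.
#' @param n_per_gen Individuals per generation (at least 2).
#' @return Data frame with columns `id`, `sire`, `dam`, `generation`
#'   (parents always precede offspring).
#' @export
simulate_pedigree <- function(generations, n_per_gen) {
  stopifnot(generations >= 1, n_per_gen >= 2)
  id <- seq_len(generations * n_per_gen)
  sire <- dam <- integer(length(id))
  gen <- rep(seq_len(generations) - 1L, each = n_per_gen)
  for (g in seq_len(generations - 1)) {
    prev <- id[gen == g - 1L]
    cur <- id[gen == g]
    for (i in cur) {
      pair <- sample(prev, 2)
      sire[i] <- pair[1]; dam[i] <- pair[2]
    }
  }
  data.frame(id = id, sire = sire, dam = dam, generation = gen)
}

#' Pedigree relationship matrix (tabular method)
#'
#' Builds the additive relationship matrix `A` implied by a pedigree by the
#' tabular method, ignoring inbreeding in the diagonal adjustment (exact
#' for non-inbred pedigrees and consistent with the Mendelian-sampling
#' variance `sigma_a^2 / 2` used by the benchmark). Intended for small
#' pedigrees in tests; the sampler itself never materializes `A`.
#'
#' @param ped Pedigree data frame (`id`, `sire`, `dam`; 0 = unknown).
#' @return The `n x n` relationship matrix.
#' @export
pedigree_A <- function(ped) {
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1) for (j in seq_len(i - 1)) {
      A[i, j] <- A[j, i] <-
        0.5 * ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0))
    }
  }
  A
}

#' Build the pedigree mixed-model benchmark
#'
#' Animal model `y = X beta + a + eps` with one record per individual and
#' breeding values decomposed along the pedigree: founders
#' `a_e ~ N(0, sigma_a^2)`, non-founders
#' `a_e ~ N((a_sire + a_dam)/2, sigma_a^2/2)` (Mendelian sampling,
#' inbreeding ignored), which reproduces the covariance `sigma_a^2 A` for
#' the relationship matrix implied by the pedigree. Normal kernels; the
#' level-1 ID folds the individual's own record and the level-2 ID also
#' folds the records of children whose other parent precedes the individual
#' in the pedigree order (exact conjugate normal algebra throughout).
#' Conjugate Gibbs samplers for `beta` and both variances, and an exact
#' single-site Gibbs sweep for the breeding values, are registered for the
#' baseline.
#'
#' @param scn A [mixed_scenario()].
#' @param pedigree Pedigree data frame (`id`, `sire`, `dam`).
#' @param data Data frame with columns `individual`, `x2`, `record`;
#'   `NULL` leaves observations unbound.
#' @return List with elements `model` and `ids` (level-2 spec).
#' @export
build_mixed <- function(scn, pedigree, data = NULL) {
  E <- nrow(pedigree)
  sire <- pedigree$sire; dam <- pedigree$dam
  if (any((sire > 0 & sire >= pedigree$id) | (dam > 0 & dam >= pedigree$id)) ||
      any(xor(sire > 0, dam > 0)))
    stop("pedigree must list parents before offspring (both known or both unknown)")
  env <- new.env(parent = emptyenv())
  env$x2 <- if (is.null(data)) stats::rbinom(E, 1, 0.5) else data$x2
  env$y <- if (is.null(data)) rep(NA_real_, E) else data$record

  # flattened child adjacency: for each parent, its children and the
  # child's other parent
  ch <- vector("list", E)
  for (e in seq_len(E)) {
    if (sire[e] > 0) ch[[sire[e]]] <- rbind(ch[[sire[e]]], c(e, dam[e]))
    if (dam[e] > 0) ch[[dam[e]]] <- rbind(ch[[dam[e]]], c(e, sire[e]))
  }
  nch <- vapply(ch, function(m) if (is.null(m)) 0L else nrow(m), 0L)
  child_ptr <- c(0L, cumsum(nch))
  flat <- do.call(rbind, ch[nch > 0])
  child_id <- if (is.null(flat)) integer() else as.integer(flat[, 1] - 1L)
  child_mate <- if (is.null(flat)) integer() else as.integer(flat[, 2] - 1L)

  params <- list(
    pbp_param("beta1", -Inf, Inf,
              init = function(y) mean(env$y) + stats::rnorm(1, 0, stats::sd(env$y) / 4)),
    pbp_param("beta2", -Inf, Inf, init = function(y) stats::rnorm(1, 0, 1)),
    pbp_param("sigma_a2", 1e-10, Inf,
              init = function(y) stats::var(env$y) * stats::runif(1, 0.2, 0.8)),
    pbp_param("sigma_e2", 1e-10, Inf,
              init = function(y) stats::var(env$y) * stats::runif(1, 0.2, 0.8)))

  nodes <- lapply(seq_len(E), function(e) {
    force(e)
    if (sire[e] == 0)
      pbp_node("normal", integer(), function(xi, theta)
        list(mean = 0, var = theta[["sigma_a2"]]))
    else
      pbp_node("normal", c(sire[e], dam[e]), function(xi, theta)
        list(mean = (xi[sire[e]] + xi[dam[e]]) / 2,
             var = theta[["sigma_a2"]] / 2))
  })
  obs <- lapply(seq_len(E), function(e) {
    force(e)
    pbp_obs(
      value = env$y[e],
      log_density = function(value, xi, theta)
        stats::dnorm(value, theta[["beta1"]] + theta[["beta2"]] * env$x2[e] + xi[e],
                     sqrt(theta[["sigma_e2"]]), log = TRUE),
      depends = e,
      simulate = function(xi, theta)
        stats::rnorm(1, theta[["beta1"]] + theta[["beta2"]] * env$x2[e] + xi[e],
                     sqrt(theta[["sigma_e2"]])))
  })

  resid <- function(theta) env$y - theta[["beta1"]] - theta[["beta2"]] * env$x2

  # per-node ID parameters in R (mirrors the compiled path; used by the
  # generic engine route and the cross-checks)
  id_params <- function(e, xi, theta, level) {
    s2a <- theta[["sigma_a2"]]; s2e <- theta[["sigma_e2"]]
    if (sire[e] == 0) { pm <- 0; pv <- s2a }
    else { pm <- (xi[sire[e]] + xi[dam[e]]) / 2; pv <- s2a / 2 }
    prec <- 1 / pv; num <- pm / pv
    r <- resid(theta)
    if (level >= 1) { prec <- prec + 1 / s2e; num <- num + r[e] / s2e }
    if (level >= 2 && nch[e] > 0) {
      v2 <- 4 * (s2a / 2 + s2e)
      for (k in seq_len(nch[e])) {
        cd <- ch[[e]][k, 1]; cm <- ch[[e]][k, 2]
        if (cm >= e) next
        prec <- prec + 1 / v2
        num <- num + (2 * r[cd] - xi[cm]) / v2
      }
    }
    list(mean = num / prec, var = 1 / prec)
  }

  fast <- list(
    regen_levels = c(0L, 1L, 2L),
    latent_loglik = function(theta, xi) {
      fo <- sire == 0
      sum(stats::dnorm(xi[fo], 0, sqrt(theta[["sigma_a2"]]), log = TRUE)) +
        sum(stats::dnorm(xi[!fo], (xi[sire[!fo]] + xi[dam[!fo]]) / 2,
                         sqrt(theta[["sigma_a2"]] / 2), log = TRUE))
    },
    obs_loglik = function(theta, xi)
      sum(stats::dnorm(env$y, theta[["beta1"]] + theta[["beta2"]] * env$x2 + xi,
                       sqrt(theta[["sigma_e2"]]), log = TRUE)),
    regen = function(model, level, theta_i, theta_p, xi_i, kappa) {
      cpp_mixed_regen(xi_i, as.integer(sire - 1L), as.integer(dam - 1L),
                      resid(theta_i), resid(theta_p),
                      theta_i[["sigma_a2"]], theta_i[["sigma_e2"]],
                      theta_p[["sigma_a2"]], theta_p[["sigma_e2"]],
                      child_ptr, child_id, child_mate,
                      as.integer(level), kappa)
    },
    sweep = function(model, state, steps) {
      sw <- cpp_mixed_sweep(state$xi, as.integer(sire - 1L), as.integer(dam - 1L),
                            resid(state$theta), state$theta[["sigma_a2"]],
                            state$theta[["sigma_e2"]],
                            child_ptr, child_id, child_mate)
      state$xi <- sw$xi
      state$ll_lat <- model$fast$latent_loglik(state$theta, state$xi)
      state$ll_obs <- model$fast$obs_loglik(state$theta, state$xi)
      list(state = state, acc = sw$acc, att = sw$att)
    },
    gibbs_params = function(model, state) {
      th <- state$theta; a <- state$xi
      w <- env$y - a
      X <- cbind(1, env$x2)
      XtX <- crossprod(X)
      bhat <- solve(XtX, crossprod(X, w))
      bcov <- th[["sigma_e2"]] * solve(XtX)
      bdraw <- drop(bhat) + drop(stats::rnorm(2) %*% chol(bcov))
      th[["beta1"]] <- bdraw[1]; th[["beta2"]] <- bdraw[2]
      fo <- sire == 0
      S_a <- sum(a[fo]^2) + 2 * sum((a[!fo] - (a[sire[!fo]] + a[dam[!fo]]) / 2)^2)
      th[["sigma_a2"]] <- S_a / (2 * stats::rgamma(1, E / 2 - 1, 1))
      rr <- env$y - th[["beta1"]] - th[["beta2"]] * env$x2 - a
      th[["sigma_e2"]] <- sum(rr^2) / (2 * stats::rgamma(1, E / 2 - 1, 1))
      state$theta <- th
      state$ll_lat <- model$fast$latent_loglik(th, a)
      state$ll_obs <- model$fast$obs_loglik(th, a)
      state$lp <- prior_loglik(model, th)
      state
    },
    id1_rule = function(model) lapply(seq_len(E), function(e) {
      force(e)
      list(family = "normal",
           params_fn = function(xi, theta) id_params(e, xi, theta, 1L))
    }),
    id2_rule = function(model) lapply(seq_len(E), function(e) {
      force(e)
      list(family = "normal",
           params_fn = function(xi, theta) id_params(e, xi, theta, 2L))
    }),
    rebind = function(model, y) { env$y <- unlist(y); model },
    simulate = function(theta) {
      a <- numeric(E)
      for (e in seq_len(E)) {
        a[e] <- if (sire[e] == 0) stats::rnorm(1, 0, sqrt(theta[["sigma_a2"]]))
        else stats::rnorm(1, (a[sire[e]] + a[dam[e]]) / 2, sqrt(theta[["sigma_a2"]] / 2))
      }
      y <- stats::rnorm(E, theta[["beta1"]] + theta[["beta2"]] * env$x2 + a,
                        sqrt(theta[["sigma_e2"]]))
      list(xi = a, y = as.list(y))
    })

  model <- pbp_model(params, nodes, obs, fast = fast,
                     info = list(benchmark = "mixed", scenario = scn,
                                 pedigree = pedigree))
  list(model = model, ids = make_id2(model))
}

# ---------------------------------------------------------------------------
# logistic population benchmark

#' Build the tau-leaping logistic population benchmark
#'
#' Discrete-time birth-death model with logistic density dependence:
#' at each step births `b_t ~ Pois(max(0, tau r_b P_t (1 - P_t/K)))` and
#' deaths `d_t ~ Pois(tau mu P_t)` update the population
#' `P_{t+1} = P_t + b_t - d_t` (a deterministic accumulator, not a latent
#' node), observed through equally spaced binomial trap counts with capture
#' probability `p`. Trajectories reaching a negative population have zero
#' likelihood. The latent order interleaves births and deaths
#' (`b_1, d_1, b_2, ...`); Poisson kernels with the level-0 (model-based)
#' importance distribution drive the joint updates, since the informative
#' observations lie many steps ahead of each latent variable. Priors:
#' semi-informative Gamma (mean 0.3, CV 0.25) on the mortality rate and
#' Beta(10, 10) on the capture probability (mirroring external
#' mark-recapture knowledge), flat on the birth rate and carrying capacity.
#'
#' @param scn A [logistic_scenario()].
#' @param data Data frame with columns `time`, `count`; `NULL` leaves
#'   observations unbound.
#' @return List with elements `model` and `ids` (level-0 spec).
#' @export
build_logistic <- function(scn, data = NULL) {
  nst <- scn$T - 1L
  tau <- scn$tau; P0 <- scn$P0
  env <- new.env(parent = emptyenv())
  obs_times <- if (is.null(data)) unique(round(seq(1, scn$T, length.out = scn$M)))
               else data$time
  env$yc <- if (is.null(data)) rep(NA_real_, length(obs_times)) else data$count
  # obs_at[m] = trap count at population index m, -1 where unobserved
  obs_at <- rep(-1L, scn$T)
  obs_at[obs_times] <- 0L

  bidx <- function(t) 2L * t - 1L
  didx <- function(t) 2L * t
  pop_at <- function(xi, t) {  # population entering step t (generic path)
    if (t == 1) return(P0)
    P0 + sum(xi[bidx(seq_len(t - 1))]) - sum(xi[didx(seq_len(t - 1))])
  }

  params <- list(
    pbp_param("r_b", 0, 10, init = function(y) stats::runif(1, 0.3, 1)),
    pbp_param("mu_d", 0, 10,
              log_prior = function(x) stats::dgamma(x, 16, rate = 16 / 0.3, log = TRUE),
              init = function(y) stats::rgamma(1, 16, rate = 16 / 0.3)),
    pbp_param("K", 1, 10000,
              init = function(y) max(4 * max(env$yc, na.rm = TRUE), 20) * stats::runif(1, 0.8, 1.2)),
    pbp_param("p", 0, 1,
              log_prior = function(x) stats::dbeta(x, 10, 10, log = TRUE),
              init = function(y) stats::rbeta(1, 10, 10)))

  nodes <- vector("list", 2L * nst)
  for (t in seq_len(nst)) {
    local({
      tt <- t
      prev <- if (tt > 1) seq_len(2L * (tt - 1L)) else integer()
      nodes[[bidx(tt)]] <<- pbp_node("poisson", prev, function(xi, theta) {
        P <- pop_at(xi, tt)
        list(lambda = max(0, tau * theta[["r_b"]] * P * (1 - P / theta[["K"]])))
      })
      nodes[[didx(tt)]] <<- pbp_node("poisson", prev, function(xi, theta) {
        P <- pop_at(xi, tt)
        list(lambda = max(0, tau * theta[["mu_d"]] * P))
      })
    })
  }
  obs <- lapply(seq_along(obs_times), function(m) {
    force(m)
    tm <- obs_times[m]
    deps <- if (tm > 1) seq_len(2L * (tm - 1L)) else integer()
    pbp_obs(
      value = env$yc[m],
      log_density = function(value, xi, theta) {
        P <- pop_at(xi, tm)
        if (P < 0) return(-Inf)
        stats::dbinom(value, P, theta[["p"]], log = TRUE)
      },
      depends = deps,
      simulate = function(xi, theta) {
        P <- pop_at(xi, tm)
        if (P < 0) return(NA_integer_)
        stats::rbinom(1, P, theta[["p"]])
      })
  })

  traj <- function(xi) {
    b <- xi[bidx(seq_len(nst))]; d <- xi[didx(seq_len(nst))]
    c(P0, P0 + cumsum(b - d))
  }

  fast <- list(
    regen_levels = 0L,
    latent_loglik = function(theta, xi) {
      P <- traj(xi)
      if (any(P < 0)) return(-Inf)
      Pt <- P[seq_len(nst)]
      lb <- pmax(0, tau * theta[["r_b"]] * Pt * (1 - Pt / theta[["K"]]))
      ld <- pmax(0, tau * theta[["mu_d"]] * Pt)
      sum(stats::dpois(xi[bidx(seq_len(nst))], lb, log = TRUE)) +
        sum(stats::dpois(xi[didx(seq_len(nst))], ld, log = TRUE))
    },
    obs_loglik = function(theta, xi) {
      P <- traj(xi)[obs_times]
      if (any(P < 0)) return(-Inf)
      sum(stats::dbinom(env$yc, P, theta[["p"]], log = TRUE))
    },
    regen = function(model, level, theta_i, theta_p, xi_i, kappa) {
      rg <- cpp_logistic_regen(as.integer(xi_i[bidx(seq_len(nst))]),
                               as.integer(xi_i[didx(seq_len(nst))]),
                               P0, tau,
                               theta_i[["r_b"]], theta_i[["mu_d"]], theta_i[["K"]],
                               theta_p[["r_b"]], theta_p[["mu_d"]], theta_p[["K"]])
      xi_p <- numeric(2L * nst)
      xi_p[bidx(seq_len(nst))] <- rg$xi_p_b
      xi_p[didx(seq_len(nst))] <- rg$xi_p_d
      list(xi_p = xi_p, fid_i = rg$fid_i, fid_p = rg$fid_p)
    },
    sweep = function(model, state, steps) {
      oa <- obs_at
      oa[obs_times] <- as.integer(env$yc)
      sw <- cpp_logistic_sweep(as.integer(state$xi[bidx(seq_len(nst))]),
                               as.integer(state$xi[didx(seq_len(nst))]),
                               P0, tau, state$theta[["r_b"]], state$theta[["mu_d"]],
                               state$theta[["K"]], state$theta[["p"]], oa)
      xi <- state$xi
      xi[bidx(seq_len(nst))] <- sw$b
      xi[didx(seq_len(nst))] <- sw$d
      state$xi <- xi
      state$ll_lat <- model$fast$latent_loglik(state$theta, xi)
      state$ll_obs <- model$fast$obs_loglik(state$theta, xi)
      list(state = state, acc = sw$acc, att = sw$att)
    },
    rebind = function(model, y) { env$yc <- unlist(y); model },
    simulate = function(theta) {
      b <- d <- integer(nst)
      P <- P0
      for (t in seq_len(nst)) {
        b[t] <- stats::rpois(1, max(0, tau * theta[["r_b"]] * P * (1 - P / theta[["K"]])))
        d[t] <- stats::rpois(1, max(0, tau * theta[["mu_d"]] * P))
        P <- P + b[t] - d[t]
      }
      xi <- numeric(2L * nst)
      xi[bidx(seq_len(nst))] <- b
      xi[didx(seq_len(nst))] <- d
      Ptr <- traj(xi)[obs_times]
      y <- lapply(seq_along(obs_times), function(m)
        if (Ptr[m] >= 0) stats::rbinom(1, Ptr[m], theta[["p"]]) else NA_integer_)
      list(xi = xi, y = y)
    })

  model <- pbp_model(params, nodes, obs, fast = fast,
                     info = list(benchmark = "logistic", scenario = scn,
                                 obs_times = obs_times))
  list(model = model, ids = make_id0(model))
}
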