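#' Engine configuration
#'
#' Run-length, adaptation and proposal settings for [run_chain()].
#'
#' @param updates Number of post-burn-in MCMC updates.
#' @param burnin Number of discarded adaptation updates (covariance of the
#'   joint parameter proposal and the jump scale are tuned here and frozen
#'   afterwards, preserving detailed balance in the sampling phase).
#' @param U Interleave period: within each block of `U` updates, `U - 1`
#'   are joint posterior-based proposals and one is a standard single-site
#'   sweep over latent variables and parameters. Mixing is insensitive to
#'   the exact value; 4 is approximately optimal. Ignored in baseline mode.
#' @param j Initial jump scale of the joint parameter proposal.
#' @param target_accept Target acceptance fraction for joint proposals that
#'   the adaptation steers `j` towards (0.33 by default).
#' @param kappa Noise weight of the normal/lognormal kernels.
#' @param seed Integer RNG seed (`NULL` leaves the RNG state alone).
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param adapt_every Updates between adaptation steps during burn-in.
#' @param store_latent If `TRUE`, keep the latent vector of every retained
#'   sample (as the `"latent"` attribute of the trace); intended for small
#'   models.
#' @return An `engine_config` list.
#' @export
engine_config <- function(updates = 10000, burnin = max(1000, updates %/% 10),
                          U = 4, j = 0.5, target_accept = 0.33, kappa = 0.03,
                          seed = NULL, thin = 1, adapt_every = 100,
                          store_latent = FALSE) {
  stopifnot(updates >= 1, burnin >= 0, U >= 2, j > 0,
            target_accept > 0, target_accept < 1)
  structure(list(updates = as.integer(updates), burnin = as.integer(burnin),
                 U = as.integer(U), j = j, target_accept = target_accept,
                 kappa = kappa, seed = seed, thin = as.integer(thin),
                 adapt_every = as.integer(adapt_every),
                 store_latent = isTRUE(store_latent)),
            class = "engine_config")
}

#' Joint parameter proposal
#'
#' Draws `theta_p ~ N(theta_i, j^2 Sigma)` using a cached Cholesky factor of
#' the adapted covariance approximation `Sigma`. The proposal is symmetric,
#' so its density cancels from the acceptance probability.
#'
#' @param theta Named current parameter vector.
#' @param chol_sigma Upper-triangular Cholesky factor of `Sigma`.
#' @param j Jump scale.
#' @return Proposed parameter vector.
#' @export
propose_theta <- function(theta, chol_sigma, j) {
  theta + j * drop(stats::rnorm(length(theta)) %*% chol_sigma)
}

.chol_jitter <- function(S) {
  for (eps in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(S + diag(eps * (1 + diag(S)), nrow(S))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("proposal covariance is not positive definite even after jittering")
}

# regenerate the latent state through the ID kernels: returns the proposed
# latent vector and the summed log ID densities at the initial and proposed
# states (the acceptance correction).
.regen_latent <- function(model, ids, theta_i, theta_p, xi_i, kappa) {
  if (!is.null(model$fast) && !is.null(model$fast$regen) &&
      ids$level %in% model$fast$regen_levels)
    return(model$fast$regen(model, ids$level, theta_i, theta_p, xi_i, kappa))
  E <- length(xi_i)
  xi_p <- xi_i
  fid_i <- 0; fid_p <- 0
  for (e in seq_len(E)) {
    nd <- ids$nodes[[e]]
    p_i <- nd$params_fn(xi_i, theta_i)
    p_p <- nd$params_fn(xi_p, theta_p)
    xi_p[e] <- pbp_propose(nd$family, p_i, p_p, xi_i[e], kappa)
    fid_i <- fid_i + pbp_density(nd$family, p_i, xi_i[e])
    fid_p <- fid_p + pbp_density(nd$family, p_p, xi_p[e])
  }
  list(xi_p = xi_p, fid_i = fid_i, fid_p = fid_p)
}

#' One joint posterior-based proposal update
#'
#' Draws a proposed parameter vector from the multivariate normal jump
#' proposal, regenerates every latent variable in topological order through
#' the importance-distribution kernels, and accepts or rejects the joint
#' move with the Metropolis-Hastings probability
#' `min(1, [pi(y|xi_p,theta_p) pi(xi_p|theta_p) pi(theta_p) /
#' pi(y|xi_i,theta_i) pi(xi_i|theta_i) pi(theta_i)] *
#' prod_e f_ID(xi_e^i | ., theta_i, y) / f_ID(xi_e^p | ., theta_p, y)`.
#' A proposal outside the prior support is rejected immediately.
#'
#' @param model A [pbp_model].
#' @param ids An `id_spec` ([make_id0()], [make_id1()], [make_id2()]).
#' @param state Current `pbp_state`.
#' @param chol_sigma Cholesky factor of the parameter proposal covariance.
#' @param j Jump scale.
#' @param kappa Normal-kernel noise weight.
#' @param detail If `TRUE`, attach the acceptance components (log
#'   acceptance ratio, the level-0 reduction `obs x prior` ratio, and the
#'   ID correction sums) as attributes -- used by tests and diagnostics.
#' @return List with elements `state` (new or unchanged) and `accepted`.
#' @export
pbp_update <- function(model, ids, state, chol_sigma, j, kappa = 0.03,
                       detail = FALSE) {
  theta_p <- propose_theta(state$theta, chol_sigma, j)
  lp_p <- prior_loglik(model, theta_p)
  if (!is.finite(lp_p)) {
    out <- list(state = state, accepted = FALSE)
    if (detail) attr(out, "detail") <- list(log_alpha = -Inf, log_alpha_mbp = -Inf)
    return(out)
  }
  rg <- .regen_latent(model, ids, state$theta, theta_p, state$xi, kappa)
  ll_lat_p <- latent_loglik(model, theta_p, rg$xi_p)
  ll_obs_p <- obs_loglik(model, theta_p, rg$xi_p)
  log_alpha <- (ll_obs_p + ll_lat_p + lp_p) -
               (state$ll_obs + state$ll_lat + state$lp) +
               (rg$fid_i - rg$fid_p)
  accepted <- is.finite(log_alpha) && log(stats::runif(1)) < log_alpha
  new_state <- if (accepted) {
    structure(list(theta = theta_p, xi = rg$xi_p, ll_lat = ll_lat_p,
                   ll_obs = ll_obs_p, lp = lp_p), class = "pbp_state")
  } else state
  out <- list(state = new_state, accepted = accepted)
  if (detail)
    attr(out, "detail") <- list(
      log_alpha = log_alpha,
      log_alpha_mbp = (ll_obs_p + lp_p) - (state$ll_obs + state$lp),
      fid_i = rg$fid_i, fid_p = rg$fid_p,
      ll_lat_i = state$ll_lat, ll_lat_p = ll_lat_p, theta_p = theta_p)
  out
}

# generic single-site latent sweep: Gibbs for Bernoulli nodes (exact
# two-point conditional), random-walk MH otherwise, all through the local
# delta evaluation. Caches are refreshed once at the end of the sweep.
.generic_latent_sweep <- function(model, state, steps) {
  acc <- 0; att <- 0
  for (e in seq_along(model$nodes)) {
    fam <- model$nodes[[e]]$family
    if (fam == "bernoulli") {
      d1 <- delta_loglik(model, state, e, 1)
      d0 <- delta_loglik(model, state, e, 0)
      pr1 <- 1 / (1 + exp(d0 - d1))
      state$xi[e] <- as.numeric(stats::runif(1) < pr1)
    } else {
      att <- att + 1
      prop <- if (fam %in% .discrete_families)
        state$xi[e] + sample(c(-1L, 1L), 1) * stats::rpois(1, steps$xi[e]) else
        state$xi[e] + stats::rnorm(1, 0, steps$xi[e])
      d <- delta_loglik(model, state, e, prop)
      if (is.finite(d) && log(stats::runif(1)) < d) {
        state$xi[e] <- prop
        acc <- acc + 1
      }
    }
  }
  state$ll_lat <- latent_loglik(model, state$theta, state$xi)
  state$ll_obs <- obs_loglik(model, state$theta, state$xi)
  list(state = state, acc = acc, att = att)
}

# random-walk MH sweep over parameters (used when no conjugate sampler is
# registered); full likelihood recomputation per proposal.
.generic_param_sweep <- function(model, state, steps) {
  acc <- numeric(length(model$params))
  for (k in seq_along(model$params)) {
    theta_p <- state$theta
    theta_p[k] <- theta_p[k] + stats::rnorm(1, 0, steps$theta[k])
    lp_p <- prior_loglik(model, theta_p)
    if (!is.finite(lp_p)) next
    ll_lat_p <- latent_loglik(model, theta_p, state$xi)
    ll_obs_p <- obs_loglik(model, theta_p, state$xi)
    la <- (ll_obs_p + ll_lat_p + lp_p) - (state$ll_obs + state$ll_lat + state$lp)
    if (is.finite(la) && log(stats::runif(1)) < la) {
      state$theta <- theta_p; state$lp <- lp_p
      state$ll_lat <- ll_lat_p; state$ll_obs <- ll_obs_p
      acc[k] <- 1
    }
  }
  list(state = state, acc = acc)
}

#' One standard MCMC sweep
#'
#' Sequentially updates each model parameter (conjugate Gibbs sampler where
#' the model registers one, random-walk Metropolis-Hastings otherwise) and
#' each latent variable (single-site, through the local delta evaluation, or
#' a model-registered vectorized sweep). Detailed balance holds per
#' sub-move.
#'
#' @param model A [pbp_model].
#' @param state Current `pbp_state`.
#' @param steps List of step sizes: `theta` (per parameter) and `xi` (per
#'   latent node or scalar).
#' @return List with elements `state`, `acc_theta` (0/1 per parameter, NA
#'   for Gibbs) and `acc_xi`/`att_xi` (latent acceptance counters).
#' @export
standard_update <- function(model, state, steps) {
  if (!is.null(model$fast) && !is.null(model$fast$gibbs_params)) {
    state <- model$fast$gibbs_params(model, state)
    acc_theta <- rep(NA_real_, length(model$params))
  } else {
    ps <- .generic_param_sweep(model, state, steps)
    state <- ps$state; acc_theta <- ps$acc
  }
  if (!is.null(model$fast) && !is.null(model$fast$sweep)) {
    sw <- model$fast$sweep(model, state, steps)
  } else {
    sw <- .generic_latent_sweep(model, state, steps)
  }
  list(state = sw$state, acc_theta = acc_theta, acc_xi = sw$acc, att_xi = sw$att)
}

.init_theta <- function(model, y_list) {
  th <- numeric(length(model$params))
  for (k in seq_along(model$params)) {
    p <- model$params[[k]]
    th[k] <- if (is.function(p$init)) p$init(y_list)
      else if (!is.null(p$init)) p$init
      else if (is.finite(p$lower) && is.finite(p$upper)) stats::runif(1, p$lower, p$upper)
      else stop(sprintf("parameter '%s' has unbounded support and no init", p$name))
  }
  stats::setNames(th, model$theta_names)
}

#' Run a PBP or baseline MCMC chain
#'
#' Executes a burn-in/adaptation phase followed by the sampling phase. With
#' an `id_spec`, each block of `U` updates comprises `U - 1` joint
#' posterior-based proposals and one standard sweep (latent variables and
#' parameters); with `ids = NULL` every update is a standard sweep (the
#' Gibbs/random-walk baseline). During burn-in the parameter proposal
#' covariance is re-estimated from the chain history (with shrinkage
#' regularization), the jump scale `j` is steered multiplicatively towards
#' the target acceptance rate, and random-walk step sizes are tuned; all
#' adaptation is frozen when sampling starts.
#'
#' @param model A [pbp_model] with bound observations.
#' @param ids An `id_spec`, or `NULL` for the baseline sampler.
#' @param config An [engine_config()].
#' @param init Optional list with elements `theta` and/or `xi` overriding
#'   the default initialization (parameters from their `init` rules or
#'   priors, latent state by forward simulation, re-drawn up to 100 times
#'   until the observation likelihood is finite).
#' @return A `pbp_trace`: data frame of retained parameter samples plus the
#'   log posterior, with acceptance summaries, the adapted `j` and
#'   covariance, the final state and the configuration as attributes.
#' @export
run_chain <- function(model, ids = NULL, config = engine_config(), init = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  npar <- length(model$params)
  y_list <- lapply(model$obs, `[[`, "value")

  theta <- if (!is.null(init$theta)) init$theta else .init_theta(model, y_list)
  theta <- stats::setNames(as.numeric(theta), model$theta_names)
  if (!is.finite(prior_loglik(model, theta)))
    stop("initial parameters have zero prior density")
  if (!is.null(init$xi)) {
    state <- chain_state(model, theta, init$xi)
  } else {
    state <- NULL
    for (try in 1:100) {
      xi <- simulate_forward(model, theta)$xi
      st <- chain_state(model, theta, xi)
      if (is.finite(st$ll_obs) && is.finite(st$ll_lat)) { state <- st; break }
      theta <- .init_theta(model, y_list)
    }
    if (is.null(state))
      stop("could not find a feasible initial state in 100 forward simulations; supply init")
  }
  if (!is.finite(state$ll_obs + state$ll_lat))
    stop("initial state has non-finite likelihood; supply a feasible init")

  scale0 <- ifelse(is.finite(model$lower) & is.finite(model$upper),
                   (model$upper - model$lower) / 10, pmax(abs(state$theta), 1) / 10)
  Sigma <- diag(scale0^2, npar)
  cholS <- .chol_jitter(Sigma)
  j <- config$j
  steps <- list(theta = scale0, xi = rep(0.5, length(model$nodes)))

  total <- config$burnin + config$updates
  nkeep <- config$updates %/% config$thin
  draws <- matrix(NA_real_, nkeep, npar, dimnames = list(NULL, model$theta_names))
  lpost <- numeric(nkeep)
  lat <- if (config$store_latent) matrix(NA_real_, nkeep, length(model$nodes)) else NULL
  keep_i <- 0L
  hist_theta <- matrix(NA_real_, config$burnin, npar)
  pbp_att_win <- 0L; pbp_acc_win <- 0L
  logj_tail <- numeric()
  pbp_att <- 0L; pbp_acc <- 0L          # post-burn-in counters
  std_att <- 0L; std_acc <- 0L
  th_att_win <- 0L; th_acc_win <- rep(0, npar)
  xi_acc_win <- 0L; xi_att_win <- 0L

  use_pbp <- !is.null(ids)
  for (it in seq_len(total)) {
    adapting <- it <= config$burnin
    if (use_pbp && it %% config$U != 0L) {
      up <- pbp_update(model, ids, state, cholS, j, config$kappa)
      state <- up$state
      if (adapting) {
        pbp_att_win <- pbp_att_win + 1L
        pbp_acc_win <- pbp_acc_win + up$accepted
      } else {
        pbp_att <- pbp_att + 1L
        pbp_acc <- pbp_acc + up$accepted
      }
    } else {
      up <- standard_update(model, state, steps)
      state <- up$state
      if (adapting) {
        if (!anyNA(up$acc_theta)) {
          th_att_win <- th_att_win + 1L
          th_acc_win <- th_acc_win + up$acc_theta
        }
        xi_acc_win <- xi_acc_win + up$acc_xi
        xi_att_win <- xi_att_win + up$att_xi
      } else {
        std_att <- std_att + max(up$att_xi, 1L)
        std_acc <- std_acc + up$acc_xi
      }
    }
    if (adapting) {
      hist_theta[it, ] <- state$theta
      if (it %% config$adapt_every == 0L) {
        nwin <- it %/% config$adapt_every
        if (pbp_att_win > 0) {
          # Robbins-Monro on log j: strong early gain, decaying with window
          # but floored so j keeps tracking once the covariance is frozen
          # (the Polyak average below absorbs the extra window noise)
          gain <- max(1 / sqrt(nwin), 0.25)
          j <- j * exp(gain * (pbp_acc_win / pbp_att_win - config$target_accept))
          j <- min(max(j, 1e-4), 10)
          # Polyak averaging over the last quarter of burn-in removes the
          # single-window noise from the frozen value
          if (it > 0.75 * config$burnin) {
            logj_tail <- c(logj_tail, log(j))
          }
        }
        if (th_att_win > 0) {
          steps$theta <- steps$theta * exp(0.2 * (th_acc_win / th_att_win - 0.44))
          th_acc_win <- rep(0, npar); th_att_win <- 0L
        }
        if (xi_att_win > 0) {
          steps$xi <- steps$xi * exp(0.2 * (xi_acc_win / xi_att_win - 0.44))
          steps$xi <- pmin(pmax(steps$xi, 1e-3), 1e3)
          xi_acc_win <- 0L; xi_att_win <- 0L
        }
        # covariance from the later half of the history so far, discarding
        # the initial transient; frozen at 70% of burn-in so the jump scale
        # has time to equilibrate against the final covariance
        if (it <= 0.7 * config$burnin) {
          win <- hist_theta[max(1, it %/% 2):it, , drop = FALSE]
          if (nrow(win) >= 10 && npar >= 1) {
            S <- stats::cov(win)
            # shrink towards the diagonal to keep the factorization stable
            S <- 0.9 * S + 0.1 * diag(pmax(diag(S), 1e-12 * scale0^2), npar)
            Sigma <- S
            cholS <- .chol_jitter(Sigma)
          }
        }
        pbp_att_win <- 0L; pbp_acc_win <- 0L
      }
    } else {
      k <- it - config$burnin
      if (k == 1L && length(logj_tail) >= 3) j <- exp(mean(logj_tail))
      if (k %% config$thin == 0L && keep_i < nkeep) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- state$theta
        lpost[keep_i] <- state$ll_obs + state$ll_lat + state$lp
        if (!is.null(lat)) lat[keep_i, ] <- state$xi
      }
    }
  }
  tr <- as.data.frame(draws[seq_len(keep_i), , drop = FALSE])
  tr$log_post <- lpost[seq_len(keep_i)]
  structure(tr, class = c("pbp_trace", "data.frame"),
            accept = list(pbp_attempted = pbp_att, pbp_accepted = pbp_acc,
                          pbp_rate = if (pbp_att > 0) pbp_acc / pbp_att else NA_real_,
                          std_rate = if (std_att > 0) std_acc / std_att else NA_real_),
            j = j, Sigma = Sigma, config = config, final_state = state,
            latent = if (!is.null(lat)) lat[seq_len(keep_i), , drop = FALSE],
            mode = if (use_pbp) sprintf("pbp_id%d", ids$level) else "baseline")
}

#' @export
print.pbp_trace <- function(x, ...) {
  a <- attr(x, "accept")
  cat(sprintf("MCMC trace (%s): %d samples of %d parameters\n",
              attr(x, "mode"), nrow(x), ncol(x) - 1L))
  if (!is.na(a$pbp_rate))
    cat(sprintf("  joint-proposal acceptance: %.1f%% (%d/%d), final jump scale %.3g\n",
                100 * a$pbp_rate, a$pbp_accepted, a$pbp_attempted, attr(x, "j")))
  invisible(x)
}
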