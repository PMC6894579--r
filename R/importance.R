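#' Importance-distribution specifications
#'
#' An importance distribution (ID) approximates, for each latent node, the
#' conditional posterior `pi(xi_e | xi_{e'<e}, theta, y)`. The hierarchy of
#' levels folds in successively more of the data:
#'
#' * level 0: the model conditional itself (ignores the data). Proposals
#'   built on it are model-based proposals (MBPs) and need no hand tuning.
#' * level 1: the normalized product of the model conditional and the
#'   node's own observation terms.
#' * level 2: level 1 further multiplied, for each child node, by the
#'   integral over the child of its conditional times its observation term.
#'
#' An `id_spec` holds, per node, a kernel family and a map
#' `(xi, theta) -> char params` (observed data enters through the closure).
#' The engine samples the proposed latent state through the family kernels
#' using these parameters and corrects the acceptance probability by the ID
#' density ratio.
#'
#' @name id_spec
NULL

.new_id_spec <- function(level, nodes) {
  structure(list(level = level, nodes = nodes), class = "id_spec")
}

#' @export
print.id_spec <- function(x, ...) {
  cat(sprintf("importance distribution spec: level %d, %d nodes\n",
              x$level, length(x$nodes)))
  invisible(x)
}

#' Level-0 importance distribution (model conditional)
#'
#' Per node, the ID is exactly the model's conditional distribution; the
#' data are ignored. With this spec the ID ratio in the joint acceptance
#' probability cancels the latent-likelihood ratio, so the acceptance
#' reduces to the observation-likelihood times prior ratio: the
#' model-based-proposal (MBP) special case.
#'
#' @param model A [pbp_model] whose node families all have kernels.
#' @return An `id_spec` of level 0.
#' @export
make_id0 <- function(model) {
  nodes <- lapply(model$nodes, function(nd) {
    if (!nd$family %in% PBP_FAMILIES)
      stop(sprintf("no kernel for family '%s'", nd$family))
    list(family = nd$family, params_fn = nd$params_fn)
  })
  .new_id_spec(0L, nodes)
}

#' Level-1 importance distribution (fold own observations)
#'
#' Per node, the normalized product of the model conditional and the
#' observation terms attached to that node, expressed within a kernel
#' family. Nodes without observations keep their level-0 ID. The product is
#' computed exactly where the algebra is closed:
#'
#' * Bernoulli nodes: the two-point posterior
#'   `z1 = z L(1) / (z L(1) + (1-z) L(0))` where `L(d)` is the likelihood
#'   of the node's observations given latent value `d` -- exact for any
#'   observation model.
#' * Normal nodes: if the model supplies an analytic rule
#'   (`model$fast$id1_rule`) it is used; otherwise the log observation term
#'   is expanded to second order around the conditional mean (with one
#'   Newton refinement of the expansion point when the curvature is
#'   negative), giving a moment-matched normal.
#'
#' Other families with observations raise an error directing the user to
#' level 0.
#'
#' @param model A [pbp_model] with bound observations.
#' @return An `id_spec` of level 1.
#' @export
make_id1 <- function(model) {
  if (!is.null(model$fast) && !is.null(model$fast$id1_rule))
    return(.new_id_spec(1L, model$fast$id1_rule(model)))
  nodes <- vector("list", length(model$nodes))
  for (e in seq_along(model$nodes)) {
    nd <- model$nodes[[e]]
    obs_r <- model$node_obs[[e]]
    if (length(obs_r) == 0) {
      nodes[[e]] <- list(family = nd$family, params_fn = nd$params_fn)
    } else if (nd$family == "bernoulli") {
      nodes[[e]] <- .id1_bernoulli(model, e, obs_r)
    } else if (nd$family == "normal") {
      nodes[[e]] <- .id1_normal_laplace(model, e, obs_r)
    } else {
      stop(sprintf(
        "no level-1 construction for family '%s' with observations (node %d); use make_id0",
        nd$family, e))
    }
  }
  .new_id_spec(1L, nodes)
}

# exact two-point posterior for a Bernoulli node given its observations
.id1_bernoulli <- function(model, e, obs_r) {
  nd <- model$nodes[[e]]
  obs <- model$obs[obs_r]
  params_fn <- function(xi, theta) {
    z <- nd$params_fn(xi, theta)$prob
    l1 <- 0; l0 <- 0
    xi1 <- xi; xi1[e] <- 1
    xi0 <- xi; xi0[e] <- 0
    for (ob in obs) {
      l1 <- l1 + ob$log_density(ob$value, xi1, theta)
      l0 <- l0 + ob$log_density(ob$value, xi0, theta)
    }
    m <- max(l1, l0)
    w1 <- z * exp(l1 - m); w0 <- (1 - z) * exp(l0 - m)
    list(prob = w1 / (w1 + w0))
  }
  list(family = "bernoulli", params_fn = params_fn)
}

# Laplace-style moment match for a normal node: second-order expansion of
# the summed log observation terms around the conditional mean, one Newton
# refinement of the expansion point when curvature is negative.
.id1_normal_laplace <- function(model, e, obs_r) {
  nd <- model$nodes[[e]]
  obs <- model$obs[obs_r]
  ell <- function(v, xi, theta) {
    xi[e] <- v
    s <- 0
    for (ob in obs) s <- s + ob$log_density(ob$value, xi, theta)
    s
  }
  params_fn <- function(xi, theta) {
    cp <- nd$params_fn(xi, theta)
    m0 <- cp$mean; v0 <- cp$var
    h <- 1e-4 * max(sqrt(v0), 1)
    expand <- function(x0) {
      f0 <- ell(x0, xi, theta); fp <- ell(x0 + h, xi, theta); fm <- ell(x0 - h, xi, theta)
      list(g = (fp - fm) / (2 * h), c = (fp - 2 * f0 + fm) / h^2)
    }
    ex <- expand(m0)
    if (ex$c < 0) {  # one Newton refinement of the expansion point
      tau <- 1 / v0 - ex$c
      m1 <- (m0 / v0 + ex$g - ex$c * m0) / tau
      ex <- expand(m1)
      if (ex$c < 0) {
        tau <- 1 / v0 - ex$c
        return(list(mean = (m0 / v0 + ex$g - ex$c * m1) / tau, var = 1 / tau))
      }
      m0 <- m1
    }
    # non-concave observation term: keep the prior variance, tilt the mean
    list(mean = m0 + v0 * ex$g, var = v0)
  }
  list(family = "normal", params_fn = params_fn)
}

#' Level-2 importance distribution (fold child observations)
#'
#' Extends the level-1 ID with, for each child node of `e`, the integral
#' over the child of its conditional times its own observation terms. The
#' integral is performed with exact conjugate algebra where available; only
#' models that register an analytic rule (`model$fast$id2_rule`, provided
#' by the pedigree mixed-model benchmark) are supported, and models without
#' one raise an error directing the user to level 1. Nodes without children
#' keep their level-1 ID.
#'
#' @param model A [pbp_model] with bound observations.
#' @return An `id_spec` of level 2.
#' @export
make_id2 <- function(model) {
  if (is.null(model$fast) || is.null(model$fast$id2_rule))
    stop("this model has no analytic level-2 rule; use make_id1")
  .new_id_spec(2L, model$fast$id2_rule(model))
}
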