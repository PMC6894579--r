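#' Effective sample size
#'
#' `ESS = N / (1 + 2 sum_k rho_k)` with the autocorrelation sum truncated by
#' Geyer's initial-positive-sequence rule: sample autocorrelations are
#' grouped into consecutive pairs `Gamma_m = rho_{2m} + rho_{2m+1}` and the
#' sum runs while the pair sums remain positive (for a reversible chain the
#' true pair sums are positive and decreasing, so the first non-positive
#' estimate marks noise). The estimate is capped at `N`; a constant series
#' reports `N` with a degeneracy warning.
#'
#' @param x Numeric vector of ordered MCMC samples (at least 10).
#' @return List with elements `ess` and `cutoff_lag` (last lag entering the
#'   sum).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  if (stats::var(x) == 0) {
    warning("constant series: ESS reported as N")
    return(list(ess = n, cutoff_lag = 0L))
  }
  lag_max <- min(n - 1L, max(100L, floor(10 * log10(n))^2))
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)
  npair <- (length(rho) - 1L) %/% 2L
  s <- 0
  cutoff <- 0L
  for (m in 0:npair) {
    g <- rho[2 * m + 1] + (if (2 * m + 2 <= length(rho)) rho[2 * m + 2] else 0)
    if (g <= 0) break
    s <- s + g
    cutoff <- 2L * m + 1L
  }
  iat <- max(2 * s - 1, 1e-12)  # sum includes rho_0 = 1
  e <- n / iat
  if (e > n) {
    warning("ESS estimate exceeded N (antithetic chain); capped at N")
    e <- n
  }
  list(ess = e, cutoff_lag = cutoff)
}

#' Posterior summary of a trace
#'
#' Per-parameter posterior mean, standard deviation, central 95% interval,
#' median and effective sample size, with the sampler's acceptance rates
#' attached.
#'
#' @param object A `pbp_trace` from [run_chain()] (or any data frame of
#'   samples whose non-parameter columns are named `log_post`).
#' @param ... Unused.
#' @return A data frame with one row per parameter, classed
#'   `pbp_summary`; acceptance rates are kept in the `"accept"` attribute.
#' @export
summary.pbp_trace <- function(object, ...) {
  pars <- setdiff(names(object), "log_post")
  rows <- lapply(pars, function(pn) {
    v <- object[[pn]]
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = pn, mean = mean(v), sd = stats::sd(v),
               q2.5 = q[1], median = q[2], q97.5 = q[3],
               ess = suppressWarnings(ess(v)$ess))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("pbp_summary", "data.frame"),
            accept = attr(object, "accept"), mode = attr(object, "mode"))
}

#' @export
print.pbp_summary <- function(x, ...) {
  cat("posterior summary (", attr(x, "mode"), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  a <- attr(x, "accept")
  if (!is.null(a) && !is.na(a$pbp_rate))
    cat(sprintf("joint-proposal acceptance: %.1f%%\n", 100 * a$pbp_rate))
  invisible(x)
}

#' Write / read a trace as CSV with a JSON metadata sidecar
#'
#' The CSV holds one row per retained update (parameter columns plus
#' `log_post`); the sidecar records the sampler mode, acceptance summaries,
#' the adapted jump scale and the full configuration, which suffices to
#' replay the run.
#'
#' @param trace A `pbp_trace`.
#' @param path CSV output path (the sidecar gets the extension
#'   `.meta.json`).
#' @return `path`, invisibly (for `write_trace`); the reconstructed
#'   `pbp_trace` (for `read_trace`).
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  # full double precision so summaries of a reloaded trace are bit-identical
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(mode = attr(trace, "mode"), accept = attr(trace, "accept"),
               j = attr(trace, "j"), config = unclass(attr(trace, "config")))
  jsonlite::write_json(meta, sub("\\.csv$", ".meta.json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @param path CSV path written by [write_trace()].
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  mpath <- sub("\\.csv$", ".meta.json", path)
  if (file.exists(mpath)) {
    meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    attr(tr, "mode") <- meta$mode
    attr(tr, "accept") <- meta$accept
    attr(tr, "j") <- meta$j
    attr(tr, "config") <- meta$config
  }
  class(tr) <- c("pbp_trace", "data.frame")
  tr
}

.cli_scenario <- function(benchmark, cfg) {
  sc <- cfg$scenario
  arg <- function(name, default) if (!is.null(sc[[name]])) sc[[name]] else default
  switch(benchmark,
    diagnostic = diagnostic_scenario(
      P = arg("P", 1000), p_D = arg("p_D", 0.5),
      Se = unlist(arg("Se", c(0.6, 0.6))), Sp = unlist(arg("Sp", c(0.9, 0.9)))),
    svt = svt_scenario(E = arg("E", 3000), mu = arg("mu", -10),
                       phi = arg("phi", 0.99), nu = arg("nu", 12),
                       sigma2 = arg("sigma2", 0.0121)),
    mixed = mixed_scenario(generations = arg("generations", 4),
                           n_per_gen = arg("n_per_gen", 1000),
                           r2 = arg("r2", 0.5), sigma_p2 = arg("sigma_p2", 1),
                           beta = unlist(arg("beta", c(10, 2)))),
    logistic = logistic_scenario(T = arg("T", 401), tau = arg("tau", 0.1),
                                 r_b = arg("r_b", 0.6), mu = arg("mu", 0.3),
                                 K = arg("K", 100), p = arg("p", 0.5),
                                 M = arg("M", 21), P0 = arg("P0", 10)),
    stop("unknown benchmark: ", benchmark))
}

.cli_build <- function(benchmark, scn, sim) {
  switch(benchmark,
    diagnostic = build_diagnostic(scn, sim$data),
    svt = build_svt(scn, sim$data),
    mixed = build_mixed(scn, sim$pedigree, sim$data),
    logistic = build_logistic(scn, sim$data))
}

.cli_fail <- function(code, ...) {
  message(...)
  code
}

#' Command-line interface
#'
#' Thin subcommand dispatcher used by the installed `pbpmcmc` script
#' (`exec/pbpmcmc`):
#'
#' * `simulate <benchmark> --config cfg.json --seed S --out dir` writes the
#'   scenario data tables (`data.csv`, plus `pedigree.csv` for the mixed
#'   model) and the true latent values (`latent.csv`).
#' * `run <benchmark> --config cfg.json --seed S --out dir [--id-level L]
#'   [--baseline]` simulates the scenario, runs the sampler and writes
#'   `trace.csv`, its JSON metadata sidecar and `summary.csv`.
#' * `diagnose --trace trace.csv --out summary.csv` recomputes posterior
#'   summaries from a stored trace.
#'
#' The JSON config may contain a `scenario` object (fields as in the
#' scenario constructors) and an `engine` object (fields of
#' [engine_config()]). Unknown benchmarks or malformed configs exit
#' non-zero with a message; a missing required key exits with code 2 naming
#' the key.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit code (0 on success).
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) < 1)
    return(.cli_fail(2, "usage: pbpmcmc <simulate|run|diagnose> ..."))
  cmd <- argv[1]
  opts <- list(`id-level` = NULL, baseline = FALSE)
  pos <- character()
  i <- 2
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--baseline") { opts$baseline <- TRUE; i <- i + 1 }
    else if (startsWith(a, "--")) {
      if (i + 1 > length(argv)) return(.cli_fail(2, "missing value for ", a))
      opts[[substring(a, 3)]] <- argv[i + 1]
      i <- i + 2
    } else { pos <- c(pos, a); i <- i + 1 }
  }
  need <- function(key) {
    if (is.null(opts[[key]])) stop("missing config key: --", key, call. = FALSE)
    opts[[key]]
  }
  tryCatch({
    if (cmd == "diagnose") {
      tr <- read_trace(need("trace"))
      out <- if (!is.null(opts$out)) opts$out else "summary.csv"
      utils::write.csv(summary(tr), out, row.names = FALSE)
      message("wrote ", out)
      return(0L)
    }
    if (!cmd %in% c("simulate", "run"))
      return(.cli_fail(2, "unknown subcommand: ", cmd))
    if (length(pos) < 1) return(.cli_fail(2, "missing benchmark name"))
    benchmark <- pos[1]
    cfg <- if (!is.null(opts$config)) jsonlite::read_json(opts$config, simplifyVector = TRUE)
           else list()
    seed <- as.integer(if (!is.null(opts$seed)) opts$seed
                       else if (!is.null(cfg$seed)) cfg$seed else 1L)
    outdir <- if (!is.null(opts$out)) opts$out else "."
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    scn <- .cli_scenario(benchmark, cfg)
    sim <- simulate_scenario(scn, seed = seed)
    if (cmd == "simulate") {
      utils::write.csv(sim$data, file.path(outdir, "data.csv"), row.names = FALSE)
      lat <- sim$latent
      if (is.list(lat)) lat <- data.frame(lat) else lat <- data.frame(value = lat)
      utils::write.csv(lat, file.path(outdir, "latent.csv"), row.names = FALSE)
      if (!is.null(sim$pedigree))
        utils::write.csv(sim$pedigree, file.path(outdir, "pedigree.csv"),
                         row.names = FALSE)
      message("wrote scenario data to ", outdir)
      return(0L)
    }
    bm <- .cli_build(benchmark, scn, sim)
    eng <- cfg$engine
    config <- engine_config(
      updates = if (!is.null(eng$updates)) eng$updates else 10000,
      burnin = if (!is.null(eng$burnin)) eng$burnin else max(1000, (if (!is.null(eng$updates)) eng$updates else 10000) %/% 10),
      U = if (!is.null(eng$U)) eng$U else 4,
      j = if (!is.null(eng$j)) eng$j else 0.5,
      target_accept = if (!is.null(eng$target_accept)) eng$target_accept else 0.33,
      kappa = if (!is.null(eng$kappa)) eng$kappa else 0.03,
      thin = if (!is.null(eng$thin)) eng$thin else 1,
      seed = seed + 1L)
    ids <- if (opts$baseline) NULL
      else if (!is.null(opts$`id-level`)) {
        lvl <- as.integer(opts$`id-level`)
        switch(lvl + 1L, make_id0(bm$model), make_id1(bm$model), make_id2(bm$model))
      } else bm$ids
    message(sprintf("running %s (%s), %d updates + %d burn-in, seed %d",
                    benchmark,
                    if (is.null(ids)) "baseline" else sprintf("PBP ID%d", ids$level),
                    config$updates, config$burnin, seed))
    tr <- run_chain(bm$model, ids, config)
    write_trace(tr, file.path(outdir, "trace.csv"))
    utils::write.csv(summary(tr), file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    a <- attr(tr, "accept")
    if (!is.na(a$pbp_rate))
      message(sprintf("joint-proposal acceptance %.1f%%, adapted jump scale %.3g",
                      100 * a$pbp_rate, attr(tr, "j")))
    message("wrote trace and summary to ", outdir)
    0L
  }, error = function(e) {
    if (grepl("^missing config key", conditionMessage(e)))
      .cli_fail(2, conditionMessage(e))
    else .cli_fail(1, "error: ", conditionMessage(e))
  })
}
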