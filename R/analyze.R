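#' Full exit-bound analysis of a model and region
#'
#' Pipeline: build the cut-off process, check connectivity, compute the QSD
#' and decay parameter, run the compensatory-constant algorithm for the given
#' initial distribution, and evaluate the survival lower bound and
#' switching-probability upper bound over the time grid.
#'
#' @param net a [bcrn()], or omit and pass `config`.
#' @param region a region spec.
#' @param initial state vector (point mass) or the string `"qsd"`.
#' @param times time grid in seconds.
#' @param eps,max_loops,stall_tol passed to [compensatory_constant()].
#' @param qsd_method,solver passed to [compute_qsd()].
#' @param config optional path to a YAML run config ([read_run_config()]);
#'   its blocks are used for any argument not supplied explicitly.
#' @param out_dir if non-NULL, writes `result.json`, `bounds.csv` and
#'   `qsd.csv` there.
#' @return list with `lam`, `below_floor`, `A`, `bound` (the
#'   [compensatory_constant()] result), `qsd`, `cp`, `bounds` (data frame:
#'   t, survival_lower, switching_upper), `n_states`, `config_hash`,
#'   `version`.
#' @export
qsb_analyze <- function(net = NULL, region = NULL, initial = NULL,
                        times = c(21600, 43200, 86400),
                        eps = 1e-6, max_loops = 100000L, stall_tol = 1e-13,
                        qsd_method = "restriction",
                        solver = "auto", config = NULL, out_dir = NULL) {
  if (!is.null(config)) {
    rc <- read_run_config(config)
    net <- net %||% rc$net
    region <- region %||% rc$region
    if (is.null(initial))
      initial <- if (rc$initial$kind == "qsd") "qsd" else rc$initial$state
    if (missing(times)) times <- rc$times
    if (missing(eps)) eps <- rc$eps
    if (missing(max_loops)) max_loops <- rc$max_loops
    if (missing(qsd_method)) qsd_method <- rc$qsd_method
  }
  if (is.null(net) || is.null(region) || is.null(initial))
    stop("`net`, `region` and `initial` are required (directly or via config)")
  cp <- build_cutoff(net, region)
  qsd <- compute_qsd(cp, method = qsd_method, solver = solver)
  J <- jump_chain(cp)
  d <- if (identical(initial, "qsd")) qsd$pi_q
       else initial_point_mass(cp, initial)
  bound <- compensatory_constant(cp, qsd, J, d, eps = eps,
                                 max_loops = max_loops,
                                 stall_tol = stall_tol)
  bounds <- data.frame(
    t = times,
    survival_lower = survival_lower_bound(qsd$lam, bound$A, times),
    switching_upper = switching_probability_upper(qsd$lam, bound$A, times)
  )
  res <- list(lam = qsd$lam, below_floor = qsd$below_floor, A = bound$A,
              bound = bound, qsd = qsd, cp = cp, bounds = bounds,
              n_states = nrow(cp$states),
              config_hash = config_hash(list(
                n = nrow(cp$states), initial = initial, times = times,
                eps = eps, max_loops = max_loops, qsd_method = qsd_method)),
              version = as.character(utils::packageVersion("qsdbound")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- list(lambda_per_s = res$lam, below_floor = res$below_floor,
                 A = res$A, iterations = bound$iterations,
                 residual = bound$residual, eps = eps,
                 max_loops = max_loops, converged = bound$converged,
                 n_states = res$n_states, qsd_method = qsd_method,
                 config_hash = res$config_hash, version = res$version)
    jsonlite::write_json(meta, file.path(out_dir, "result.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(cbind(bounds, config_hash = res$config_hash,
                           version = res$version),
                     file.path(out_dir, "bounds.csv"), row.names = FALSE)
    qsb_qsd_export(cp, qsd, file.path(out_dir, "qsd.csv"))
  }
  res
}

# small polynomial string hash; enough to tie output files to their inputs
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Export a QSD as a CSV of states and probabilities
#' @param cp cut-off process.
#' @param qsd its [compute_qsd()] result.
#' @param path output CSV.
#' @export
qsb_qsd_export <- function(cp, qsd, path) {
  df <- data.frame(cp$states, probability = qsd$pi_q[seq_len(nrow(cp$states))])
  names(df) <- c(cp$net$species, "probability")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Robustness table of the toggle-switch family
#'
#' For each copy number / Hill coefficient pair: the decay parameter, its
#' characteristic time 1/lambda, the compensatory constant for a point mass
#' at the deterministic stable state, and switching-probability upper bounds
#' at the requested horizons.
#'
#' @param P,nh vectors defining the grid (defaults: the full study grid).
#' @param times bound horizons in seconds (defaults: 6, 12, 24 hours).
#' @param s2_bound region convention, see [toggle_table_config()].
#' @param qsd_method passed to [compute_qsd()].
#' @param compute_A set FALSE to skip the compensatory constant (the decay
#'   parameter alone is much cheaper on the larger grid members).
#' @param eps,max_loops,stall_tol passed to [compensatory_constant()].
#' @return data frame with one row per configuration.
#' @export
qsb_table <- function(P = c(2, 6, 10, 20, 40), nh = c(2, 3, 4),
                      times = c(21600, 43200, 86400),
                      s2_bound = "copy-number",
                      qsd_method = "restriction",
                      compute_A = TRUE,
                      eps = 1e-6, max_loops = 100000L, stall_tol = 1e-13) {
  grid <- expand.grid(nh = nh, P = P)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- toggle_table_config(grid$P[i], grid$nh[i], s2_bound = s2_bound)
    cp <- build_cutoff(cfg$net, cfg$region)
    qsd <- compute_qsd(cp, method = qsd_method)
    A <- NA_real_
    if (compute_A) {
      b <- compensatory_constant(cp, qsd, d = initial_point_mass(cp, cfg$x0),
                                 eps = eps, max_loops = max_loops,
                                 stall_tol = stall_tol)
      A <- b$A
    }
    out <- data.frame(P = grid$P[i], nh = grid$nh[i], lambda = qsd$lam,
                      inv_lambda = ifelse(qsd$lam > 0, 1 / qsd$lam, Inf),
                      below_floor = qsd$below_floor, A = A,
                      n_states = nrow(cp$states))
    for (t in times)
      out[[sprintf("P_exit_by_%gh", t / 3600)]] <-
        if (is.na(A)) NA_real_ else switching_probability_upper(qsd$lam, A, t)
    out
  })
  do.call(rbind, rows)
}

#' Certificate suite for a model/region pair
#'
#' Runs the package's independent oracles against the computed bound:
#' connectivity; the exponential survival law from the QSD (exact transient
#' survival within `tol_eq9` of `exp(-lambda t)` up to `t = horizon/lambda`);
#' monotone total-variation convergence of the conditioned law to the QSD;
#' validity of the compensated bound (exact survival at least
#' `exp(-lambda t) - A - 1e-9` on a log time grid); and, for one-species
#' chains, monotonicity of the exit probability in the distance from the
#' boundary.
#'
#' @param net model; @param region region spec; @param initial point state.
#' @param horizon time horizon in units of `1/lambda`.
#' @param n_grid log-grid size.
#' @param tol_eq9 tolerance on the exponential-law certificate.
#' @param max_states refuse larger systems (transient oracle cost).
#' @return data frame with `certificate`, `pass`, `detail`.
#' @export
qsb_validate <- function(net, region, initial, horizon = 3, n_grid = 20,
                         tol_eq9 = 1e-8, max_states = 50000) {
  cp <- build_cutoff(net, region)
  if (nrow(cp$states) > max_states)
    stop("region has ", nrow(cp$states), " states; the exact transient ",
         "oracle is limited to ", max_states)
  conn <- check_connectivity(cp)
  out <- data.frame(certificate = "connectivity", pass = conn$ok,
                    detail = if (conn$ok) "strongly connected"
                             else "disconnected region")
  if (!conn$ok) return(out)
  qsd <- compute_qsd(cp)
  lam <- qsd$lam
  t_top <- if (lam > 0) horizon / lam else 1 / max(-Matrix::diag(cp$Qtilde))
  t_grid <- exp(seq(log(t_top * 1e-3), log(t_top), length.out = n_grid))

  tr_q <- transient_solve(cp, qsd$pi_q, t_grid)
  err9 <- max(abs(tr_q$survival - exp(-lam * t_grid)))
  out <- rbind(out, data.frame(
    certificate = "exponential survival law from the QSD",
    pass = err9 <= tol_eq9,
    detail = sprintf("max |survival - exp(-lambda t)| = %.2e", err9)))

  d <- initial_point_mass(cp, initial)
  conv <- conditioned_convergence(cp, qsd, d, t_grid)
  mono <- all(diff(conv$tv) <= 1e-9)
  out <- rbind(out, data.frame(
    certificate = "conditioned law converges to the QSD",
    pass = mono && min(conv$tv) < conv$tv[1] + 1e-12,
    detail = sprintf("TV %.2e -> %.2e, monotone: %s",
                     conv$tv[1], conv$tv[length(conv$tv)], mono)))

  b <- compensatory_constant(cp, qsd, d = d)
  tr_d <- transient_solve(cp, d, t_grid)
  slack <- min(tr_d$survival - survival_lower_bound(lam, b$A, t_grid))
  out <- rbind(out, data.frame(
    certificate = "compensated survival bound is valid",
    pass = slack >= -1e-9,
    detail = sprintf("min(exact - bound) = %.3e (A = %.3e)", slack, b$A)))

  if (ncol(cp$states) == 1L) {
    mc <- exit_monotonicity_check(cp, t_grid)
    out <- rbind(out, data.frame(
      certificate = "exit probability monotone in boundary distance",
      pass = mc$monotone,
      detail = sprintf("%d violations", nrow(mc$violations))))
  }
  out
}
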