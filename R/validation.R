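#' Exact transient solution of the cut-off master equation
#'
#' Integrates `dp/dt = p Qtilde` (row-vector orientation) from the initial
#' distribution over a time grid by uniformization: with `Lam` at least the
#' largest total exit rate, `exp(Qtilde t) = exp(-Lam t) sum_k (Lam t)^k/k! P^k`
#' where `P = I + Qtilde/Lam` is a stochastic matrix. The Poisson series is
#' truncated when its remaining tail is below `tol`, so the result is exact
#' to that tolerance; there is no stiffness issue because every term is a
#' probability vector. Survival is one minus the mass on the absorbing state.
#'
#' @param cp a [build_cutoff()] result.
#' @param d initial distribution over V plus the absorbing state.
#' @param t_grid non-decreasing vector of times (s), may start at 0.
#' @param tol truncation tolerance of the Poisson series per step.
#' @return object of class `transient_result`: `times`, `p` (matrix, one row
#'   per time, |V|+1 columns), `survival`, `absorbed`, `tol`.
#' @export
transient_solve <- function(cp, d, t_grid, tol = 1e-12) {
  stopifnot(inherits(cp, "cutoff_process"))
  if (length(d) != cp$a_index || any(d < 0) || abs(sum(d) - 1) > 1e-9)
    stop("`d` must be a probability vector over V plus the absorbing state")
  if (is.unsorted(t_grid) || any(t_grid < 0))
    stop("`t_grid` must be non-decreasing and non-negative")
  Lam <- max(-Matrix::diag(cp$Qtilde)) * 1.0000001
  if (Lam <= 0) stop("generator has no transitions")
  Pt <- Matrix::t(Matrix::Diagonal(cp$a_index) + cp$Qtilde / Lam)
  out <- matrix(NA_real_, length(t_grid), cp$a_index)
  p <- d
  t_prev <- 0
  for (k in seq_along(t_grid)) {
    dt <- t_grid[k] - t_prev
    if (dt > 0) p <- uniformization_step(Pt, p, Lam * dt, tol)
    out[k, ] <- p
    t_prev <- t_grid[k]
  }
  absorbed <- out[, cp$a_index]
  structure(
    list(times = t_grid, p = out, survival = 1 - absorbed,
         absorbed = absorbed, tol = tol),
    class = "transient_result"
  )
}

# advance a distribution by exp(Q dt) through the Poisson mixture of powers
# of the uniformized chain; m = Lam * dt
uniformization_step <- function(Pt, p, m, tol) {
  if (m == 0) return(p)
  # start the series at the mode region to avoid underflow for large m
  k_max <- ceiling(m + 10 * sqrt(m + 10) + 20)
  log_w <- -m            # log Poisson(0)
  acc <- numeric(length(p))
  v <- p
  w_sum <- 0
  for (k in 0:k_max) {
    w <- exp(log_w)
    acc <- acc + w * v
    w_sum <- w_sum + w
    if (k >= m && 1 - w_sum < tol) break
    v <- as.vector(Pt %*% v)
    log_w <- log_w + log(m) - log(k + 1)
  }
  acc + (1 - w_sum) * v  # assign the tiny tail to the last computed power
}

#' Stochastic simulation of exit times from a region
#'
#' Gillespie simulation of the original BCRN, watched until it first leaves
#' the region V (or until `t_max`). Because the dynamics inside V are those
#' of the original process, the recorded first-exit times are equal in
#' distribution to the absorption times of the cut-off process. Transition
#' tables over V are precomputed, so each step is a table lookup.
#'
#' A master seed fans out one sub-seed per trajectory, so any single
#' trajectory is reproducible independently of how many are run.
#'
#' @param net a [bcrn()].
#' @param spec region ([region_box()] / [region_states()]).
#' @param d initial distribution over V plus absorbing state (mass on the
#'   absorbing entry is disallowed here).
#' @param n_runs number of trajectories.
#' @param seed master seed (integer).
#' @param t_max censoring time (s).
#' @return data frame with `time` (exit or censoring time) and `exited`
#'   (logical).
#' @export
ssa_simulate <- function(net, spec, d, n_runs, seed, t_max = Inf) {
  stopifnot(n_runs >= 1)
  cp <- if (inherits(spec, "cutoff_process")) spec else build_cutoff(net, spec)
  n <- nrow(cp$states)
  if (length(d) != n + 1L || d[n + 1L] > 0)
    stop("`d` must put all its mass inside V")
  Q <- cp$Qtilde
  tot <- -Matrix::diag(Q)[seq_len(n)]
  # per-state target/rate tables (absorbing target = 0)
  Qrow <- methods::as(Q, "TsparseMatrix")
  keep <- Qrow@i + 1L <= n & Qrow@i != Qrow@j
  src <- Qrow@i[keep] + 1L
  dst <- Qrow@j[keep] + 1L
  dst[dst == cp$a_index] <- 0L
  rate <- Qrow@x[keep]
  ord <- order(src)
  src <- src[ord]; dst <- dst[ord]; rate <- rate[ord]
  counts <- tabulate(src, nbins = n)
  row_end <- cumsum(counts)
  row_begin <- row_end - counts + 1L
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_runs)
  times <- numeric(n_runs); exited <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(sub_seeds[r])
    i <- sample.int(n, 1L, prob = d[seq_len(n)])
    t_now <- 0
    repeat {
      if (tot[i] <= 0) { times[r] <- t_max; exited[r] <- FALSE; break }
      t_now <- t_now + stats::rexp(1L, tot[i])
      if (t_now >= t_max) { times[r] <- t_max; exited[r] <- FALSE; break }
      a <- row_begin[i]; b <- row_end[i]
      idx <- if (a == b) a else sample(a:b, 1L, prob = rate[a:b])
      j <- dst[idx]
      if (j == 0L) { times[r] <- t_now; exited[r] <- TRUE; break }
      i <- j
    }
  }
  data.frame(time = times, exited = exited)
}

#' Total variation distance between two probability vectors
#' @param p,q probability vectors of equal length.
#' @return `sum(abs(p - q)) / 2`, in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  if (length(p) != length(q)) stop("`p` and `q` must have equal length")
  sum(abs(p - q)) / 2
}

#' Convergence of the conditioned law to the quasi-stationary distribution
#'
#' Computes the law of the cut-off process at each grid time conditioned on
#' not yet being absorbed, and its total variation distance to the QSD. For a
#' connected region this distance decreases to 0, which is the defining limit
#' of the QSD.
#'
#' @param cp a [build_cutoff()] result.
#' @param qsd a [compute_qsd()] result for `cp`.
#' @param d initial distribution supported in V.
#' @param t_grid time grid (s).
#' @param survival_floor grid times where survival drops below this are
#'   dropped (conditioning breaks down numerically), with a warning.
#' @return data frame with `time`, `survival`, `tv`.
#' @export
conditioned_convergence <- function(cp, qsd, d, t_grid,
                                    survival_floor = 1e-12) {
  tr <- transient_solve(cp, d, t_grid)
  ok <- tr$survival > survival_floor
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " grid times with survival below ",
            survival_floor)
  }
  n <- nrow(cp$states)
  tv <- vapply(which(ok), function(k) {
    cond <- tr$p[k, seq_len(n)] / tr$survival[k]
    tv_distance(cond, qsd$pi_q[seq_len(n)])
  }, numeric(1))
  data.frame(time = tr$times[ok], survival = tr$survival[ok], tv = tv)
}
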