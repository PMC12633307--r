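#' Initial distributions over a cut-off process
#'
#' An initial distribution is a probability vector over V plus the absorbing
#' state; any mass the user places outside V is lumped onto the absorbing
#' state, since from the cut-off process's point of view it has already left.
#'
#' @param cp a [build_cutoff()] result.
#' @param x a state vector inside V.
#' @return numeric vector of length |V| + 1 summing to 1.
#' @export
initial_point_mass <- function(cp, x) {
  i <- state_index(cp, x)
  d <- numeric(cp$a_index)
  if (i == 0L) d[cp$a_index] <- 1 else d[i] <- 1
  d
}

#' @rdname initial_point_mass
#' @param states matrix of states (one per row) with `weights` their
#'   probabilities; mass on states outside V goes to the absorbing state.
#' @param weights non-negative weights, normalised to sum 1.
#' @export
initial_from_weights <- function(cp, states, weights) {
  states <- as.matrix(states)
  if (nrow(states) != length(weights)) stop("one weight per state required")
  if (any(weights < 0)) stop("weights must be non-negative")
  d <- numeric(cp$a_index)
  for (k in seq_len(nrow(states))) {
    i <- state_index(cp, states[k, ])
    i <- if (i == 0L) cp$a_index else i
    d[i] <- d[i] + weights[k]
  }
  d / sum(d)
}

#' Compensatory constant for the quasi-stationary survival bound
#'
#' Iterative mass-matching between the initial distribution and the QSD.
#' Working vectors are `D`, the initial mass not yet matched, and `q`, the
#' QSD mass not yet used for matching. Each sweep cancels `D` against `q`
#' statewise, then pushes the unmatched remainder one step of the embedded
#' jump chain (`D_new(y) = sum_x D'(x) J(x, y)`, the push-forward of the
#' defective distribution `D'`). The returned constant `A = sum(D)` at
#' termination satisfies `P_d(T > t) >= exp(-lambda t) - A` for all `t`.
#'
#' Mass that reaches the absorbing state during propagation stays there and,
#' because the QSD puts no mass on it, contributes permanently to `A`; this
#' is deliberate, not leakage. Consequently `sum(D)` generally converges to a
#' positive limit rather than to 0: iteration stops when it falls below
#' `eps`, when it stalls (per-sweep decrease below `stall_tol`, i.e. the
#' limit has been reached to numerical precision), or at `max_loops`.
#' Stopping early only makes `A` larger, hence the bound more conservative,
#' never invalid. If `sum(D) <= eps` already holds at entry the loop body
#' never runs and that entry value is returned.
#'
#' @param cp a [build_cutoff()] result.
#' @param qsd a [compute_qsd()] result for `cp`.
#' @param J the [jump_chain()] of `cp` (computed if missing).
#' @param d initial distribution over V plus absorbing state, e.g.
#'   [initial_point_mass()].
#' @param eps target residual mass.
#' @param max_loops iteration cap.
#' @param stall_tol per-sweep decrease below which the iteration is declared
#'   converged to its limit; set 0 to disable.
#' @param record_trace keep the sequence of `sum(D)` values (field `trace`).
#' @return object of class `bound_result`: `A` in \[0, 1\], `lam` (copied
#'   from `qsd`), `iterations`, `residual` (= final `sum(D)`), `converged`
#'   (residual <= eps), `stalled`, `eps`, `max_loops`.
#' @export
compensatory_constant <- function(cp, qsd, J = NULL, d,
                                  eps = 1e-6, max_loops = 100000L,
                                  stall_tol = 1e-13, record_trace = FALSE) {
  stopifnot(inherits(cp, "cutoff_process"), inherits(qsd, "qsd_result"))
  if (is.null(J)) J <- jump_chain(cp)
  if (length(d) != cp$a_index || any(d < 0) ||
      abs(sum(d) - 1) > 1e-9)
    stop("`d` must be a probability vector over V plus the absorbing state")
  Jt <- Matrix::t(J)
  D <- d
  q <- qsd$pi_q
  i <- 0L
  prev <- Inf
  stalled <- FALSE
  trace <- if (record_trace) sum(D) else NULL
  while (sum(D) > eps && i < max_loops) {
    Dp <- pmax(D - q, 0)
    q <- pmax(q - D, 0)
    D <- as.vector(Jt %*% Dp)
    i <- i + 1L
    s <- sum(D)
    if (record_trace) trace <- c(trace, s)
    if (stall_tol > 0 && (prev - s) < stall_tol && i > 5L) {
      stalled <- TRUE
      break
    }
    prev <- s
  }
  A <- min(max(sum(D), 0), 1)
  structure(
    list(A = A, lam = qsd$lam, iterations = i, residual = sum(D),
         converged = sum(D) <= eps, stalled = stalled,
         eps = eps, max_loops = max_loops, trace = trace),
    class = "bound_result"
  )
}

#' @export
print.bound_result <- function(x, ...) {
  cat("<bound_result> A =", format(x$A, digits = 4),
      "| lambda =", format(x$lam, digits = 4), "1/s |",
      x$iterations, "sweeps |",
      if (x$converged) "converged"
      else if (x$stalled) "stalled at its limit" else "hit max_loops", "\n")
  invisible(x)
}

#' Survival lower bound and switching-probability upper bound
#'
#' `survival_lower_bound()` returns `exp(-lam * t) - A`, a lower bound on the
#' probability of still being inside V at time `t` (it may be negative; the
#' switching bound clamps it). `switching_probability_upper()` returns
#' `1 - max(0, exp(-lam * t) - A)`, the upper bound on the probability of
#' having left V by time `t`.
#'
#' @param lam decay parameter (1/s), non-negative.
#' @param A compensatory constant in \[0, 1\].
#' @param t time or vector of times (s), non-negative.
#' @export
survival_lower_bound <- function(lam, A, t) {
  check_bound_args(lam, A, t)
  exp(-lam * t) - A
}

#' @rdname survival_lower_bound
#' @export
switching_probability_upper <- function(lam, A, t) {
  check_bound_args(lam, A, t)
  1 - pmax(0, exp(-lam * t) - A)
}

check_bound_args <- function(lam, A, t) {
  if (any(t < 0)) stop("`t` must be non-negative")
  if (lam < 0) stop("`lam` must be non-negative")
  if (A < 0 || A > 1) stop("`A` must lie in [0, 1]")
  invisible(TRUE)
}
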