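#' Bounded birth-death chains
#'
#' A 1-D CTMC on `{0, ..., P}` moving only by plus or minus one. The chain is
#' bounded: the birth rate at the top state and the death rate at 0 are zero.
#' For such chains the exit-time bound needs no compensatory constant for
#' initial distributions dominated by the QSD in the cumulative sense, and in
#' particular for point masses at the boundary state farthest from the exit.
#'
#' @param birth,death numeric rate vectors over states `0..P` (length P + 1);
#'   `death[1]` (state 0) and `birth[P + 1]` (state P) must be 0.
#' @return object of class `bd_chain`.
#' @export
bd_chain <- function(birth, death) {
  if (length(birth) != length(death))
    stop("`birth` and `death` must have equal length")
  if (length(birth) < 2L) stop("need at least two states")
  if (any(birth < 0) || any(death < 0)) stop("rates must be non-negative")
  if (death[1L] != 0) stop("death rate at state 0 must be 0")
  if (birth[length(birth)] != 0)
    stop("birth rate at the maximum state must be 0")
  structure(list(n_states = length(birth), birth = birth, death = death),
            class = "bd_chain")
}

#' @export
print.bd_chain <- function(x, ...) {
  cat("<bd_chain> states 0 ..", x$n_states - 1L, "\n")
  invisible(x)
}

#' @rdname bd_chain
#' @param chain a `bd_chain`.
#' @export
as_bcrn <- function(chain) {
  stopifnot(inherits(chain, "bd_chain"))
  make_birth_death(chain$birth, chain$death)
}

#' Can the QSD bound be used without a compensatory constant?
#'
#' Sufficient condition for `P_d(T > t) >= exp(-lambda t)` on a birth-death
#' cut-off: there must exist auxiliary transport functions that cover each
#' demand `d(y)` using QSD mass only from states at least as close to the
#' absorbing boundary as `y`, without overdrawing the QSD anywhere. Because
#' the admissible supply sets are nested along the chain, feasibility reduces
#' to cumulative-mass domination counted from the exit boundary: for every
#' threshold, the initial mass within that distance of the boundary must not
#' exceed the QSD mass there. (The equivalence is a Hall-type argument; the
#' test suite verifies it against a max-flow transportation oracle.)
#'
#' @param d initial distribution over the ordered states of V.
#' @param pi_q QSD over the same states.
#' @param exit_side `"low"` if the absorbing boundary adjoins the smallest
#'   state of V, `"high"` if it adjoins the largest.
#' @return TRUE or FALSE.
#' @export
qsd_condition_check <- function(d, pi_q, exit_side = c("high", "low")) {
  exit_side <- match.arg(exit_side)
  if (length(d) != length(pi_q)) stop("`d` and `pi_q` must have equal length")
  if (abs(sum(d) - 1) > 1e-8 || abs(sum(pi_q) - 1) > 1e-8)
    stop("`d` and `pi_q` must be normalised distributions")
  if (exit_side == "low") { d <- rev(d); pi_q <- rev(pi_q) }
  # states are now ordered with the exit boundary last
  all(rev(cumsum(rev(d))) <= rev(cumsum(rev(pi_q))) + 1e-12)
}

#' Dual-boundary bounds for a bounded birth-death chain
#'
#' Builds two cut-off processes: one on a low interval `VL` containing 0
#' (absorbing state just above it) and one on a high interval `VH` containing
#' the top state (absorbing just below it). Starting at 0, the exit time from
#' `VL` satisfies `P(T_L > t) >= exp(-lambda_L t)` with no compensatory
#' constant, and symmetrically for starts at the top state and `VH`. In a
#' biosensor reading the two bounds cap the false-positive rate (leaving the
#' low, analyte-absent region) and the false-negative rate (leaving the high,
#' analyte-present region).
#'
#' @param chain a [bd_chain()].
#' @param VL integer interval (vector of states) containing 0.
#' @param VH integer interval containing the maximum state.
#' @return object of class `dual_cutoff`: `cp_L`, `cp_H` (cut-off processes),
#'   `qsd_L`, `qsd_H`, `lam_L`, `lam_H`, and bound evaluators
#'   `survival_L(t)`, `survival_H(t)`.
#' @export
boundary_bounds <- function(chain, VL, VH) {
  stopifnot(inherits(chain, "bd_chain"))
  P <- chain$n_states - 1L
  VL <- sort(as.integer(VL)); VH <- sort(as.integer(VH))
  if (!identical(VL, VL[1]:VL[length(VL)]) ||
      !identical(VH, VH[1]:VH[length(VH)]))
    stop("`VL` and `VH` must be contiguous integer intervals")
  if (VL[1] != 0L) stop("`VL` must contain the state 0")
  if (VH[length(VH)] != P) stop("`VH` must contain the maximum state ", P)
  net <- as_bcrn(chain)
  cp_L <- build_cutoff(net, region_box(0, max(VL)))
  cp_H <- build_cutoff(net, region_box(min(VH), P))
  qsd_L <- compute_qsd(cp_L)
  qsd_H <- compute_qsd(cp_H)
  structure(
    list(cp_L = cp_L, cp_H = cp_H, qsd_L = qsd_L, qsd_H = qsd_H,
         lam_L = qsd_L$lam, lam_H = qsd_H$lam,
         survival_L = local({ l <- qsd_L$lam; function(t) exp(-l * t) }),
         survival_H = local({ l <- qsd_H$lam; function(t) exp(-l * t) })),
    class = "dual_cutoff"
  )
}

#' @export
print.dual_cutoff <- function(x, ...) {
  cat("<dual_cutoff> lambda_L =", format(x$lam_L, digits = 4),
      "1/s, lambda_H =", format(x$lam_H, digits = 4), "1/s\n")
  invisible(x)
}

#' Exit probabilities are monotone in the distance from the boundary
#'
#' For a 1-D cut-off process, `P(T <= t | X(0) = x)` should decrease as `x`
#' moves away from the absorbing boundary, at every time. This diagnostic
#' computes the absorption probability for every start state (one backward
#' uniformization run per grid time, evolving the absorbing indicator) and
#' reports any ordering violations beyond the integrator tolerance.
#'
#' @param cp a [build_cutoff()] result of a single-species chain.
#' @param t_grid times to check (s).
#' @param tol violation tolerance.
#' @return list with `monotone` (logical), `absorbed` (matrix states x
#'   times), `violations` (data frame).
#' @export
exit_monotonicity_check <- function(cp, t_grid, tol = 1e-8) {
  stopifnot(inherits(cp, "cutoff_process"))
  if (ncol(cp$states) != 1L) stop("requires a single-species chain")
  n <- nrow(cp$states)
  # which side is the absorbing boundary on?
  exit_rate <- cp$Qtilde[seq_len(n), cp$a_index]
  low_exit <- if (n == 1L) exit_rate[1] > 0 else exit_rate[1] >= exit_rate[n]
  Lam <- max(-Matrix::diag(cp$Qtilde)) * 1.0000001
  Pm <- Matrix::Diagonal(cp$a_index) + cp$Qtilde / Lam
  # forward evolution of the indicator of absorption: w(t) = exp(Qt) e_a
  w <- as.numeric(seq_len(cp$a_index) == cp$a_index)
  absorbed <- matrix(NA_real_, n, length(t_grid))
  t_prev <- 0
  for (k in seq_along(t_grid)) {
    dt <- t_grid[k] - t_prev
    if (dt > 0) w <- uniformization_step(Pm, w, Lam * dt, 1e-12)
    absorbed[, k] <- w[seq_len(n)]
    t_prev <- t_grid[k]
  }
  # distance from the absorbing boundary increases with index when the exit
  # is at the low end, decreases otherwise
  viol <- list()
  for (k in seq_along(t_grid)) {
    col <- absorbed[, k]
    diffs <- diff(col)
    bad <- if (low_exit) which(diffs > tol) else which(diffs < -tol)
    if (length(bad))
      viol[[length(viol) + 1L]] <-
        data.frame(time = t_grid[k], state = cp$states[bad, 1L],
                   jump = diffs[bad])
  }
  violations <- if (length(viol)) do.call(rbind, viol)
                else data.frame(time = numeric(), state = integer(),
                                jump = numeric())
  list(monotone = nrow(violations) == 0L, absorbed = absorbed,
       violations = violations)
}
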