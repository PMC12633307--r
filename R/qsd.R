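#' Quasi-stationary distribution and decay parameter of a cut-off process
#'
#' The decay parameter lambda is the negative of the eigenvalue with largest
#' real part of the restriction `Qv` of the cut-off generator to V (the
#' diagonal keeps the exit rates, so `Qv` is strictly substochastic whenever
#' some state can exit). The quasi-stationary distribution (QSD) is the
#' corresponding left eigenvector, normalised to a probability vector over
#' V with zero mass on the absorbing state. Started from the QSD, the
#' survival probability is exactly `exp(-lambda * t)`.
#'
#' `method = "conditioned"` instead returns the stationary distribution of
#' the conditioned generator (exit rates removed, diagonal re-zeroed). That
#' vector is the long-run law of a modified process that is forbidden to
#' exit; it is close to the QSD when absorption is slow but does not satisfy
#' the exponential survival law exactly. It is provided because published
#' robustness analyses of the toggle switch used it as the matching input of
#' the compensatory-constant algorithm (see the vignette).
#'
#' @param cp a [build_cutoff()] result; V must be strongly connected.
#' @param method `"restriction"` (the QSD proper, default) or
#'   `"conditioned"`.
#' @param solver `"auto"` (dense below 1500 states, else sparse), `"dense"`
#'   (full eigendecomposition) or `"sparse"` (shift-invert power iteration on
#'   a cached sparse LU factorisation; exact for this spectrum because the
#'   eigenvalue of largest real part is also the one of smallest modulus).
#' @param tol relative residual tolerance of the sparse solver.
#' @param lambda_floor decay parameters below this value (1/s) are reported
#'   as 0 with `below_floor = TRUE`; double-precision eigenvalues that close
#'   to the machine epsilon of the generator's scale are not meaningful.
#' @return object of class `qsd_result`: `pi_q` (length |V|+1, zero on the
#'   absorbing state), `lam` (1/s), `below_floor`, `residual`, `method`,
#'   `solver`.
#' @export
compute_qsd <- function(cp, method = c("restriction", "conditioned"),
                        solver = c("auto", "dense", "sparse"),
                        tol = 1e-12, lambda_floor = 1e-14) {
  stopifnot(inherits(cp, "cutoff_process"))
  method <- match.arg(method)
  solver <- match.arg(solver)
  assert_connected(cp)
  n <- nrow(cp$states)
  if (solver == "auto") solver <- if (n < 1500) "dense" else "sparse"
  M <- if (method == "restriction") cp$Qv else conditioned_generator(cp)
  scale <- max(abs(M@x), 1e-300)

  if (solver == "dense") {
    ev <- eigen(t(as.matrix(M)))
    k <- if (method == "restriction") which.max(Re(ev$values))
         else which.min(abs(ev$values))
    ew <- Re(ev$values[k])
    v <- Re(ev$vectors[, k])
  } else {
    si <- shift_invert_leading(Matrix::t(M),
                               sigma = if (method == "restriction") 0
                                       else scale * 1e-10,
                               tol = tol)
    ew <- si$value
    v <- si$vector
  }
  v <- v / sum(v)
  if (min(v) < -1e-6)
    stop("principal eigenvector has large sign-indefinite entries ",
         "(min relative entry ", format(min(v)), "); wrong eigenpair or ",
         "disconnected region")
  v[v < 0] <- 0
  v <- v / sum(v)
  # the decay parameter is a property of Qv in either case; the conditioned
  # matrix is conservative and its principal eigenvalue is 0 by construction
  lam <- if (method == "restriction") -ew
         else as.numeric(decay_parameter(cp, solver = solver, tol = tol,
                                         lambda_floor = lambda_floor))
  residual <- max(abs(as.vector(Matrix::crossprod(cp$Qv, v)) + lam * v))
  below <- is.na(lam) || lam < lambda_floor
  structure(
    list(pi_q = c(v, 0), lam = if (below) 0 else lam, below_floor = below,
         residual = residual, method = method, solver = solver),
    class = "qsd_result"
  )
}

#' @export
print.qsd_result <- function(x, ...) {
  cat("<qsd_result> lambda =", format(x$lam, digits = 4), "1/s",
      if (x$below_floor) "(below numerical floor)" else "",
      "| method:", x$method, "| residual:", format(x$residual, digits = 3),
      "\n")
  invisible(x)
}

#' Decay parameter of a cut-off process
#'
#' Negative of the largest real part among the eigenvalues of the restricted
#' generator `Qv`; the exponential rate of the absorption law from the QSD.
#' Values below `lambda_floor` are reported as 0 (attribute `below_floor`).
#'
#' @inheritParams compute_qsd
#' @return non-negative scalar (1/s) with logical attribute `below_floor`.
#' @export
decay_parameter <- function(cp, solver = c("auto", "dense", "sparse"),
                            tol = 1e-12, lambda_floor = 1e-14) {
  stopifnot(inherits(cp, "cutoff_process"))
  solver <- match.arg(solver)
  assert_connected(cp)
  n <- nrow(cp$states)
  if (solver == "auto") solver <- if (n < 1500) "dense" else "sparse"
  lam <- if (solver == "dense") {
    -max(Re(eigen(as.matrix(cp$Qv), only.values = TRUE)$values))
  } else {
    -shift_invert_leading(Matrix::t(cp$Qv), sigma = 0, tol = tol)$value
  }
  below <- is.na(lam) || lam < lambda_floor
  structure(if (below) 0 else lam, below_floor = below)
}

conditioned_generator <- function(cp) {
  M <- cp$Qv
  Matrix::diag(M) <- 0
  Matrix::diag(M) <- -Matrix::rowSums(M)
  M
}

# Leading (largest real part) eigenpair of a sparse matrix whose spectrum
# lies in Re <= 0, via inverse power iteration at shift sigma. For such a
# spectrum the target eigenvalue is simultaneously the smallest-modulus one:
# any other eigenvalue mu has |mu| >= |Re(mu)| >= |target|, so the inverse
# iteration converges to it. The LU factorisation is computed once.
shift_invert_leading <- function(M, sigma = 0, tol = 1e-12,
                                 max_iter = 500L) {
  n <- nrow(M)
  A <- M
  if (sigma != 0) Matrix::diag(A) <- Matrix::diag(A) - sigma
  LU <- tryCatch(Matrix::lu(A), error = function(e) NULL)
  if (is.null(LU)) {
    # singular at the shift: the eigenvalue is 0 to machine precision
    return(list(value = sigma, vector = stationary_by_power(M), iters = 0L,
                residual = NA_real_))
  }
  scale <- max(abs(M@x))
  v <- rep(1 / n, n)
  value <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- as.vector(Matrix::solve(LU, v))
    w <- w / sum(abs(w))
    if (sum(w) < 0) w <- -w
    w[w < 0] <- 0
    s <- sum(w)
    if (s == 0) stop("inverse iteration collapsed to the zero vector")
    w <- w / s
    Mw <- as.vector(M %*% w)
    val <- sum(w * Mw) / sum(w * w)
    done <- !is.na(value) && abs(val - value) <= tol * max(abs(val), scale * 1e-16)
    value <- val; v <- w
    if (done) break
  }
  res <- max(abs(as.vector(M %*% v) - value * v))
  list(value = value, vector = v, iters = it, residual = res)
}

# fallback stationary vector when the generator is numerically singular:
# a few uniformized power steps from uniform, enough for the reported
# distribution to be meaningful (the eigenvalue is already pinned at ~0)
stationary_by_power <- function(M, steps = 2000L) {
  n <- nrow(M)
  lam_max <- max(abs(Matrix::diag(M)))
  P <- Matrix::Diagonal(n) + M / (lam_max * 1.01)
  v <- rep(1 / n, n)
  Pt <- Matrix::t(P)
  for (i in seq_len(steps)) v <- as.vector(Pt %*% v)
  v / sum(v)
}

#' Embedded jump chain of a cut-off process
#'
#' `J(x, y)` is the probability that the next state is `y` given the current
#' state is `x`: the generator row normalised by the total exit rate. A state
#' with zero total rate (the absorbing state) gets `J(x, x) = 1`; all other
#' diagonal entries are 0.
#'
#' @param cp a [build_cutoff()] result.
#' @return row-stochastic sparse matrix over V plus the absorbing state.
#' @export
jump_chain <- function(cp) {
  stopifnot(inherits(cp, "cutoff_process"))
  Q <- cp$Qtilde
  tot <- -Matrix::diag(Q)
  J <- Q
  Matrix::diag(J) <- 0
  inv <- ifelse(tot > 0, 1 / tot, 0)
  J <- Matrix::Diagonal(x = inv) %*% J
  zero <- which(tot <= 0)
  if (length(zero))
    J <- J + Matrix::sparseMatrix(i = zero, j = zero,
                                  x = rep(1, length(zero)),
                                  dims = dim(J))
  J
}
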