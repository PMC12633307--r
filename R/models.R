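#' Toggle-switch study configurations
#'
#' The robustness-analysis family: a symmetric toggle switch (`P1 = P2 = P`)
#' with a strong promoter, `alpha = 0.05` 1/s per gene copy, and fast
#' first-order degradation, `beta = 0.01` 1/s (protein half-life of about a
#' minute). These parameters are a deliberate stress test that maximises
#' stochastic fluctuations; typical circuits have weaker promoters and slower
#' turnover and switch far less often, so the resulting bounds should not be
#' read as typical-parameter predictions. The deterministic stable state
#' under study is `(S1, S2) = (alpha/beta * P, 0)`.
#'
#' Two region conventions are provided for the monitored set V around that
#' state:
#' * `"copy-number"` (default): `S1` in `[alpha/(3 beta) P, 2 alpha/beta P]`,
#'   `S2` in `[0, P]`. This is the region whose decay parameters match the
#'   published robustness table for this model family; crossing `S2 = P`
#'   already signals commitment to the opposite state under these parameters.
#' * `"formula"`: `S2` in `[0, alpha/(3 beta) P]`, the symmetric-threshold
#'   variant (same formula as the `S1` lower bound). It gives a larger `S2`
#'   margin and accordingly smaller decay parameters.
#'
#' Fractional bounds are resolved by rounding the lower bound up and the
#' upper bound down (largest integer box inside the real box).
#'
#' @param P gene copy number.
#' @param nh Hill coefficient.
#' @param s2_bound region convention for the S2 bound, see above.
#' @param alpha,beta,K model constants (1/s, 1/s, molecule counts).
#' @return a `toggle_config` list: `net`, `region`, `x0` (initial state,
#'   the deterministic stable state), `params`, `label`.
#' @export
toggle_table_config <- function(P, nh, s2_bound = c("copy-number", "formula"),
                                alpha = 0.05, beta = 0.01, K = 10) {
  s2_bound <- match.arg(s2_bound)
  s1_lo <- alpha / (3 * beta) * P
  s1_hi <- 2 * alpha / beta * P
  s2_hi <- if (s2_bound == "copy-number") P else alpha / (3 * beta) * P
  net <- make_toggle_switch(alpha, beta, P1 = P, nh = nh, K = K)
  structure(
    list(net = net,
         region = region_box(c(s1_lo, 0), c(s1_hi, s2_hi)),
         x0 = c(round(alpha / beta * P), 0),
         params = c(alpha = alpha, beta = beta, P = P, nh = nh, K = K),
         label = sprintf("toggle-P%g-nh%g", P, nh)),
    class = "toggle_config"
  )
}

#' @export
print.toggle_config <- function(x, ...) {
  cat("<toggle_config>", x$label, "| region:")
  print(x$region)
  invisible(x)
}

#' @rdname toggle_table_config
#' @description `toggle_table_grid()` returns the full robustness grid: gene
#'   copy numbers `P` in `{2, 6, 10, 20, 40}` crossed with Hill coefficients
#'   `nh` in `{2, 3, 4}` (15 configurations).
#' @export
toggle_table_grid <- function(s2_bound = c("copy-number", "formula")) {
  s2_bound <- match.arg(s2_bound)
  grid <- expand.grid(nh = c(2, 3, 4), P = c(2, 6, 10, 20, 40))
  lapply(seq_len(nrow(grid)),
         function(i) toggle_table_config(grid$P[i], grid$nh[i],
                                         s2_bound = s2_bound))
}

#' Weak-promoter toggle switch for QSD illustration
#'
#' Balanced production and degradation, `alpha = beta = 0.001` 1/s with
#' `P = 30` gene copies: a small, slow system in which the quasi-stationary
#' distribution develops fully before exits become likely, convenient for
#' visualising the QSD itself. Region: `S1` in `[0, 2 alpha/beta P] = [0,60]`,
#' `S2` in `[0, alpha/(3 beta) P] = [0, 10]` (671 states). The Hill
#' coefficient is a free choice here; `nh = 2` is the default used throughout
#' the package's worked examples.
#'
#' @param nh Hill coefficient.
#' @return a `toggle_config`.
#' @export
illustrative_config <- function(nh = 2) {
  alpha <- 0.001; beta <- 0.001; P <- 30; K <- 10
  net <- make_toggle_switch(alpha, beta, P1 = P, nh = nh, K = K)
  structure(
    list(net = net,
         region = region_box(c(0, 0),
                             c(2 * alpha / beta * P, alpha / (3 * beta) * P)),
         x0 = c(round(alpha / beta * P), 0),
         params = c(alpha = alpha, beta = beta, P = P, nh = nh, K = K),
         label = sprintf("toggle-illustrative-nh%g", nh)),
    class = "toggle_config"
  )
}

#' Random bounded birth-death chain (property-test fixture)
#'
#' Interior birth/death rates drawn uniformly from `(0.1, 1.1) * rate_scale`,
#' boundary rates zero, so the chain is connected by construction and fully
#' reproducible from the seed.
#'
#' @param n_states number of states (at least 2).
#' @param rate_scale multiplicative scale of all rates (1/s).
#' @param seed RNG seed.
#' @return a [bd_chain()].
#' @export
random_bd_chain <- function(n_states, rate_scale = 1, seed) {
  stopifnot(n_states >= 2)
  set.seed(seed)
  birth <- c(stats::runif(n_states - 1L, 0.1, 1.1), 0) * rate_scale
  death <- c(0, stats::runif(n_states - 1L, 0.1, 1.1)) * rate_scale
  bd_chain(birth, death)
}
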