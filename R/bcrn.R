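#' Biochemical reaction networks as continuous-time Markov chains
#'
#' A BCRN is a set of species plus a set of reactions. Each reaction carries an
#' integer count-change vector `delta` and a rate law mapping a state (vector
#' of species counts) to a non-negative propensity in 1/s. The induced CTMC
#' lives on integer count vectors; its generator has `Q(x, x + delta) =
#' rate(x)` for every reaction with positive propensity at `x`.
#'
#' @param species character vector of unique species names; the position of a
#'   name is its index in state vectors.
#' @param reactions list of [reaction()] objects whose `delta` length equals
#'   the number of species.
#' @param params named numeric vector of model constants, kept for
#'   serialisation and region formulas; the rate laws close over the values
#'   they need.
#' @return an object of class `bcrn`.
#' @export
bcrn <- function(species, reactions, params = numeric()) {
  if (!is.character(species) || length(species) < 1L || anyDuplicated(species))
    stop("`species` must be a non-empty character vector of unique names")
  if (!is.list(reactions) || length(reactions) < 1L)
    stop("at least one reaction is required")
  ns <- length(species)
  for (r in reactions) {
    if (!inherits(r, "qsb_reaction"))
      stop("all elements of `reactions` must be created by reaction()")
    if (length(r$delta) != ns)
      stop("reaction delta length ", length(r$delta), " does not match ",
           ns, " species")
  }
  structure(
    list(species = species, reactions = reactions,
         params = unlist(params)),
    class = "bcrn"
  )
}

#' Define a single reaction
#'
#' The rate law must return 0 for any state from which the reaction would
#' drive a count negative; the constructors in this package guarantee that for
#' the mass-action and Hill families. `type` and `type_params` form a
#' declarative record of the rate-law family so models can be serialised to
#' the plain-text config schema (see [write_model_config()]).
#'
#' @param delta integer count-change vector.
#' @param rate function of a state vector returning a non-negative scalar
#'   propensity (1/s).
#' @param type one of `"mass-action"`, `"hill-repression"`, `"constant"`,
#'   `"custom"`.
#' @param type_params named list describing the family parameters (for
#'   serialisation); ignored for `"custom"`.
#' @param label free-text reaction label.
#' @export
reaction <- function(delta, rate, type = "custom", type_params = list(),
                     label = "") {
  if (any(delta != round(delta))) stop("`delta` must be integer-valued")
  if (!is.function(rate)) stop("`rate` must be a function")
  type <- match.arg(type, c("mass-action", "hill-repression", "constant",
                            "custom"))
  structure(list(delta = as.integer(delta), rate = rate, type = type,
                 type_params = type_params, label = label),
            class = "qsb_reaction")
}

#' @export
print.bcrn <- function(x, ...) {
  cat("<bcrn> ", length(x$species), " species (",
      paste(x$species, collapse = ", "), "), ",
      length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Enumerate the outgoing CTMC transitions of a state
#'
#' Evaluates every reaction's rate law at `x` and returns the reachable
#' targets with their rates. Reactions with zero propensity are dropped;
#' reactions producing the same target have their rates summed.
#'
#' @param net a [bcrn()].
#' @param x integer state vector with non-negative counts.
#' @return list with `targets` (matrix, one row per distinct target) and
#'   `rates` (positive numeric vector of matching length).
#' @export
transitions <- function(net, x) {
  stopifnot(inherits(net, "bcrn"))
  x <- as.numeric(x)
  if (length(x) != length(net$species))
    stop("state length does not match the number of species")
  if (any(x < 0)) stop("state counts must be non-negative")
  tg <- list(); rt <- numeric()
  for (r in net$reactions) {
    rate <- r$rate(x)
    if (rate < 0) stop("negative propensity from reaction '", r$label, "'")
    if (rate == 0) next
    y <- x + r$delta
    if (any(y < 0))
      stop("reaction '", r$label, "' has positive rate at a state where it ",
           "would drive a count negative")
    tg[[length(tg) + 1L]] <- y
    rt <- c(rt, rate)
  }
  if (length(rt) == 0L)
    return(list(targets = matrix(numeric(), 0, length(x)), rates = numeric()))
  targets <- do.call(rbind, tg)
  key <- apply(targets, 1L, paste, collapse = ",")
  if (anyDuplicated(key)) {
    rt <- as.numeric(tapply(rt, key, sum)[unique(key)])
    targets <- targets[!duplicated(key), , drop = FALSE]
  }
  list(targets = targets, rates = rt)
}

#' Total propensity (exit rate) of a state
#' @inheritParams transitions
#' @export
total_propensity <- function(net, x) {
  sum(transitions(net, x)$rates)
}

hill_repression_rate <- function(vmax, K, nh, repressor_index) {
  force(vmax); force(K); force(nh); force(repressor_index)
  function(x) vmax / (1 + (x[repressor_index] / K)^nh)
}

mass_action_decay_rate <- function(k, species_index) {
  force(k); force(species_index)
  function(x) k * x[species_index]
}

#' Mutually repressing two-gene toggle switch
#'
#' Two proteins S1 and S2, each produced from a constant pool of gene copies
#' under Hill-type repression by the other, each degraded first-order:
#' S1 birth at rate `alpha * P1 / (1 + (S2/K)^nh)`, S2 birth at rate
#' `alpha * P2 / (1 + (S1/K)^nh)`, deaths at `beta * S1` and `beta * S2`.
#' With symmetric copy numbers `P1 = P2 = P` the deterministic rate equations
#' have stable fixed points at `(alpha/beta * P, 0)` and `(0, alpha/beta * P)`.
#'
#' @param alpha per-copy maximal production rate (1/s).
#' @param beta first-order degradation rate (1/s).
#' @param P1,P2 gene copy numbers of the two producers.
#' @param nh Hill coefficient (cooperativity), at least 1.
#' @param K Hill repression threshold in molecule counts.
#' @return a [bcrn()] with species `S1`, `S2`.
#' @export
make_toggle_switch <- function(alpha, beta, P1, P2 = P1, nh, K = 10) {
  vals <- c(alpha = alpha, beta = beta, P1 = P1, P2 = P2, nh = nh, K = K)
  if (nh < 1) stop("Hill coefficient `nh` must be at least 1")
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all toggle-switch parameters must be positive")
  bcrn(
    species = c("S1", "S2"),
    reactions = list(
      reaction(c(1L, 0L), hill_repression_rate(alpha * P1, K, nh, 2L),
               type = "hill-repression",
               type_params = list(vmax = alpha * P1, K = K, nh = nh,
                                  repressor = "S2"),
               label = "S1 production"),
      reaction(c(0L, 1L), hill_repression_rate(alpha * P2, K, nh, 1L),
               type = "hill-repression",
               type_params = list(vmax = alpha * P2, K = K, nh = nh,
                                  repressor = "S1"),
               label = "S2 production"),
      reaction(c(-1L, 0L), mass_action_decay_rate(beta, 1L),
               type = "mass-action",
               type_params = list(k = beta, species = "S1"),
               label = "S1 degradation"),
      reaction(c(0L, -1L), mass_action_decay_rate(beta, 2L),
               type = "mass-action",
               type_params = list(k = beta, species = "S2"),
               label = "S2 degradation")
    ),
    params = vals
  )
}

#' One-species birth-death network from rate vectors or functions
#'
#' Builds a single-species BCRN whose only moves are +1 (birth) and -1
#' (death). Rates may be given as functions of the count, or as vectors
#' indexed by state `0, 1, ..., length - 1`; vector rates define a bounded
#' chain (birth at the maximum state must then be 0, and any state beyond the
#' vector has rate 0).
#'
#' @param birth,death non-negative rate vectors over states `0..P`, or
#'   functions of the count. `death` must vanish at state 0.
#' @export
make_birth_death <- function(birth, death) {
  b_fun <- rate_fun_1d(birth, "birth")
  d_fun <- rate_fun_1d(death, "death")
  if (d_fun(0) != 0) stop("death rate at state 0 must be 0")
  if (is.numeric(birth) && birth[length(birth)] != 0)
    stop("birth rate at the maximum state of a bounded chain must be 0")
  bcrn(
    species = "N",
    reactions = list(
      reaction(1L, function(x) b_fun(x[1L]), type = "custom",
               label = "birth"),
      reaction(-1L, function(x) d_fun(x[1L]), type = "custom",
               label = "death")
    )
  )
}

rate_fun_1d <- function(r, what) {
  if (is.function(r)) return(r)
  if (!is.numeric(r) || any(r < 0))
    stop(what, " rates must be non-negative")
  force(r)
  function(n) if (n + 1 <= length(r)) r[n + 1] else 0
}
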