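#' Finite state regions
#'
#' A region is the finite connected subset V of the count state space on which
#' the cut-off process lives. It is either a box of per-species inclusive
#' integer bounds or an explicit list of states. Real-valued box bounds are
#' admitted because region formulas such as `alpha/(3*beta) * P` need not be
#' integer; the lower bound is rounded up and the upper bound rounded down,
#' i.e. the region is the largest integer box inside the real box.
#'
#' @param lo,hi numeric vectors of per-species lower/upper bounds
#'   (`lo <= hi` after rounding, all non-negative).
#' @return a `region_spec` object.
#' @export
region_box <- function(lo, hi) {
  if (length(lo) != length(hi)) stop("`lo` and `hi` must have equal length")
  lo_i <- ceiling(lo); hi_i <- floor(hi)
  if (any(lo_i < 0)) stop("region bounds must be non-negative")
  if (any(lo_i > hi_i))
    stop("empty region: lower bound exceeds upper bound after rounding")
  structure(list(kind = "box", lo = as.integer(lo_i), hi = as.integer(hi_i)),
            class = "region_spec")
}

#' @rdname region_box
#' @param states integer matrix, one state per row; rows must be distinct and
#'   non-negative.
#' @export
region_states <- function(states) {
  states <- as.matrix(states)
  if (nrow(states) == 0L) stop("empty region")
  if (any(states < 0) || any(states != round(states)))
    stop("states must be non-negative integers")
  key <- apply(states, 1L, paste, collapse = ",")
  if (anyDuplicated(key)) stop("region states must be distinct")
  structure(list(kind = "list", states = states), class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  if (x$kind == "box")
    cat("<region_spec> box [", paste(x$lo, collapse = ","), "] .. [",
        paste(x$hi, collapse = ","), "], ", prod(x$hi - x$lo + 1),
        " states\n", sep = "")
  else
    cat("<region_spec> explicit list of", nrow(x$states), "states\n")
  invisible(x)
}

#' Enumerate a region as an ordered state list
#'
#' States are sorted lexicographically by species counts (first species most
#' significant), giving a deterministic indexing for reproducible eigenvectors.
#'
#' @param spec a [region_box()] or [region_states()].
#' @return integer matrix, one state per row, in lexicographic order.
#' @export
enumerate_region <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  if (spec$kind == "box") {
    ranges <- Map(seq.int, spec$lo, spec$hi)
    # expand.grid varies the first factor fastest; feed reversed ranges so the
    # first species is most significant, then restore column order
    grid <- do.call(expand.grid, rev(ranges))
    states <- as.matrix(grid[, rev(seq_along(ranges)), drop = FALSE])
  } else {
    states <- spec$states
    ord <- do.call(order, lapply(seq_len(ncol(states)),
                                 function(j) states[, j]))
    states <- states[ord, , drop = FALSE]
  }
  dimnames(states) <- NULL
  storage.mode(states) <- "integer"
  states
}

state_keys <- function(states) {
  apply(states, 1L, paste, collapse = ",")
}
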