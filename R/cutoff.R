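#' Build the cut-off process of a BCRN on a finite region
#'
#' The cut-off process keeps the original transition rates between states
#' inside the region V and redirects every transition that would leave V to a
#' single artificial absorbing state `a`, appended as the last row/column of
#' the generator. The absorbing row is identically zero and every row sums to
#' zero, so absorption time of the cut-off process equals, in distribution,
#' the first exit time of the original process from V.
#'
#' @param net a [bcrn()].
#' @param spec a [region_box()] or [region_states()].
#' @return an object of class `cutoff_process` with fields
#'   `states` (ordered |V| x ns matrix), `a_index` (= |V| + 1),
#'   `Qtilde` (sparse (|V|+1)-square generator), `Qv` (restriction of
#'   `Qtilde` to V, diagonal retaining exit rates), `net`, `spec`.
#' @export
build_cutoff <- function(net, spec) {
  stopifnot(inherits(net, "bcrn"), inherits(spec, "region_spec"))
  states <- enumerate_region(spec)
  n <- nrow(states)
  a_index <- n + 1L
  index <- new.env(hash = TRUE, parent = emptyenv())
  keys <- state_keys(states)
  for (i in seq_len(n)) assign(keys[i], i, envir = index)
  ii <- vector("list", n); jj <- vector("list", n); vv <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- transitions(net, states[i, ])
    if (length(tr$rates) == 0L) next
    tk <- state_keys(tr$targets)
    j <- vapply(tk, function(k) {
      v <- index[[k]]
      if (is.null(v)) a_index else v
    }, integer(1), USE.NAMES = FALSE)
    ii[[i]] <- rep.int(i, length(j)); jj[[i]] <- j; vv[[i]] <- tr$rates
  }
  trip <- data.frame(i = unlist(ii), j = unlist(jj), x = unlist(vv))
  Qtilde <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                                 dims = c(a_index, a_index))
  Matrix::diag(Qtilde) <- 0
  Matrix::diag(Qtilde) <- -Matrix::rowSums(Qtilde)
  structure(
    list(states = states, a_index = a_index, Qtilde = Qtilde,
         Qv = Qtilde[seq_len(n), seq_len(n), drop = FALSE],
         net = net, spec = spec),
    class = "cutoff_process"
  )
}

#' @export
print.cutoff_process <- function(x, ...) {
  n <- nrow(x$states)
  cat("<cutoff_process> |V| =", n, "states +1 absorbing;",
      length(x$Qtilde@x), "non-zeros in Qtilde\n")
  invisible(x)
}

#' Index of a state within a cut-off process (0 if outside V)
#' @param cp a [build_cutoff()] result.
#' @param x state vector.
#' @export
state_index <- function(cp, x) {
  key <- paste(as.integer(x), collapse = ",")
  i <- match(key, state_keys(cp$states))
  if (is.na(i)) 0L else i
}

#' Verify that the region is connected under the within-V dynamics
#'
#' The quasi-stationary theory requires V to be a communicating class of the
#' cut-off process. Connectivity is checked from the lexicographically
#' smallest state `sc`: every state must be reachable from `sc`, and `sc`
#' must be reachable from every state (reachability on the transposed
#' transition graph), using only transitions that stay inside V.
#'
#' @param cp a [build_cutoff()] result.
#' @return a `connectivity_report` list with `ok`, and on failure the
#'   unreachable state indices in each direction.
#' @export
check_connectivity <- function(cp) {
  stopifnot(inherits(cp, "cutoff_process"))
  n <- nrow(cp$states)
  adj <- cp$Qv
  Matrix::diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "directed")
  fwd <- as.integer(igraph::subcomponent(g, 1L, mode = "out"))
  bwd <- as.integer(igraph::subcomponent(g, 1L, mode = "in"))
  miss_fwd <- setdiff(seq_len(n), fwd)
  miss_bwd <- setdiff(seq_len(n), bwd)
  structure(
    list(ok = length(miss_fwd) == 0L && length(miss_bwd) == 0L,
         root = cp$states[1L, ],
         unreachable_from_root = miss_fwd,
         not_reaching_root = miss_bwd),
    class = "connectivity_report"
  )
}

#' @export
print.connectivity_report <- function(x, ...) {
  if (x$ok) cat("<connectivity_report> ok: V is strongly connected\n")
  else cat("<connectivity_report> FAILED:",
           length(x$unreachable_from_root), "states unreachable from root;",
           length(x$not_reaching_root), "states cannot reach root\n")
  invisible(x)
}

assert_connected <- function(cp) {
  rep <- check_connectivity(cp)
  if (!rep$ok)
    stop("region V is not strongly connected under the cut-off dynamics (",
         length(rep$unreachable_from_root), " unreachable from the root, ",
         length(rep$not_reaching_root), " not reaching it); the ",
         "quasi-stationary distribution is not well defined", call. = FALSE)
  invisible(TRUE)
}

#' Export a cut-off process as plain tables
#'
#' Returns the generator in coordinate-list form plus the state index table,
#' the exchange format used by the command-line interface.
#'
#' @param cp a [build_cutoff()] result.
#' @return list of two data frames: `matrix` (row, col, rate; 1-based, the
#'   absorbing state is the last index) and `states` (index and one column
#'   per species).
#' @export
cutoff_to_tables <- function(cp) {
  m <- methods::as(cp$Qtilde, "TsparseMatrix")
  coord <- data.frame(row = m@i + 1L, col = m@j + 1L, rate = m@x)
  coord <- coord[order(coord$row, coord$col), ]
  st <- data.frame(index = seq_len(nrow(cp$states)), cp$states)
  names(st) <- c("index", cp$net$species)
  list(matrix = coord, states = st)
}
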