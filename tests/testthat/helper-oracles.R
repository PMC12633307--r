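# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (sparse matrices, vectorised constructions) so
# that agreement is meaningful.

# dense breadth-first reachability on an adjacency matrix
bfs_reachable <- function(adj, from) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  which(seen)
}

# transportation feasibility for the no-compensation condition, solved as a
# max-flow problem: demand d(y) may draw only from QSD mass at states at
# least as close to the exit boundary; feasible iff max flow carries all of d.
# States are ordered with the exit boundary LAST (position m).
flow_feasible <- function(d, pi_q) {
  m <- length(d)
  # vertices: 1 = source, 2..m+1 demands, m+2..2m+1 supplies, 2m+2 = sink
  from <- c(); to <- c(); cap <- c()
  for (y in 1:m) { from <- c(from, 1); to <- c(to, 1 + y); cap <- c(cap, d[y]) }
  for (y in 1:m) for (w in y:m) {       # supplies at w >= y (closer to exit)
    from <- c(from, 1 + y); to <- c(to, 1 + m + w); cap <- c(cap, 2)
  }
  for (w in 1:m) {
    from <- c(from, 1 + m + w); to <- c(to, 2 * m + 2); cap <- c(cap, pi_q[w])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to))
  f <- igraph::max_flow(g, source = 1, target = 2 * m + 2, capacity = cap)
  f$value >= sum(d) - 1e-9
}

# scalar, loop-based re-implementation of the compensatory-constant sweep
# (dense vectors, explicit index loops, no sparse algebra)
trace_compensatory <- function(Qtilde, pi_q, d, eps = 1e-6, max_loops = 1e5) {
  Q <- as.matrix(Qtilde)
  n <- nrow(Q)
  J <- matrix(0, n, n)
  for (x in 1:n) {
    tot <- 0
    for (z in 1:n) if (z != x) tot <- tot + Q[x, z]
    if (tot > 0) {
      for (y in 1:n) if (y != x) J[x, y] <- Q[x, y] / tot
    } else J[x, x] <- 1
  }
  D <- d; q <- pi_q
  i <- 0
  sums <- sum(D)
  while (sum(D) > eps && i < max_loops) {
    Dp <- numeric(n)
    for (x in 1:n) {
      if (D[x] - q[x] > 0) {
        Dp[x] <- D[x] - q[x]; q[x] <- 0
      } else {
        q[x] <- q[x] - D[x]; Dp[x] <- 0
      }
    }
    Dn <- numeric(n)
    for (y in 1:n) for (x in 1:n) Dn[y] <- Dn[y] + Dp[x] * J[x, y]
    D <- Dn
    i <- i + 1
    sums <- c(sums, sum(D))
  }
  list(A = sum(D), iterations = i, sums = sums)
}

# unit-rate birth-death network on an unbounded lattice (rates 1 everywhere
# except death at 0), handy for tiny cut-off examples
unit_bd_net <- function() {
  make_birth_death(function(n) 1, function(n) if (n > 0) 1 else 0)
}

# a two-well ("detection") birth-death chain on 0..P: production with
# positive feedback against first-order loss, giving a low and a high mode
bistable_bd_chain <- function(P = 20, k0 = 0.3, k1 = 4, K = 10, nh = 4,
                              gamma = 0.2) {
  s <- 0:P
  birth <- k0 + k1 * s^nh / (K^nh + s^nh)
  birth[P + 1] <- 0
  death <- gamma * s
  bd_chain(birth, death)
}
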