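test_that("trivial no-compensation cases are accepted", {
  pi_q <- c(0.05, 0.15, 0.3, 0.5)  # exit boundary at the high end
  # point mass at the state farthest from the exit
  expect_true(qsd_condition_check(c(1, 0, 0, 0), pi_q, exit_side = "high"))
  # the QSD itself
  expect_true(qsd_condition_check(pi_q, pi_q, exit_side = "high"))
  # all mass on the exit-adjacent state with a thin QSD there: infeasible
  expect_false(qsd_condition_check(c(0, 0, 0, 1), pi_q, exit_side = "high"))
  # the same situations mirrored to a low-side exit
  expect_true(qsd_condition_check(c(0, 0, 0, 1), rev(pi_q),
                                  exit_side = "low"))
  expect_error(qsd_condition_check(c(0.5, 0.2), c(0.5, 0.5)), "normalised")
})

test_that("cumulative domination is equivalent to transport feasibility", {
  set.seed(2024)
  n_agree <- 0
  for (i in 1:200) {
    m <- sample(5:10, 1)
    d <- stats::rexp(m); d <- d / sum(d)
    pi_q <- stats::rexp(m); pi_q <- pi_q / sum(pi_q)
    # occasionally push d toward the far state so both outcomes occur
    if (i %% 3 == 0) { d[1] <- d[1] + 2; d <- d / sum(d) }
    got <- qsd_condition_check(d, pi_q, exit_side = "high")
    want <- flow_feasible(d, pi_q)
    expect_equal(got, want)
    n_agree <- n_agree + (got == want)
  }
  expect_equal(n_agree, 200)
})

test_that("dual-boundary bounds: symmetry and one-state closed forms", {
  # mirror-symmetric chain: birth(x) = death(P - x)
  P <- 11
  r <- c(0.8, 0.6, 0.9, 0.4, 0.7, 0.5, 0.3, 0.9, 1.1, 0.2, 0.6)
  birth <- c(r, 0)
  death <- c(0, rev(r))
  chain <- bd_chain(birth, death)
  db <- boundary_bounds(chain, VL = 0:3, VH = (P - 3):P)
  expect_equal(db$lam_L, db$lam_H, tolerance = 1e-10)
  expect_equal(db$survival_L(100), exp(-db$lam_L * 100))
  # single-state VL = {0}: the restriction is 1x1 with the birth rate
  chain2 <- bd_chain(c(0.37, 0.5, 0), c(0, 0.2, 0.4))
  db2 <- boundary_bounds(chain2, VL = 0, VH = 1:2)
  expect_equal(db2$lam_L, 0.37, tolerance = 1e-12)
  expect_error(boundary_bounds(chain2, VL = 1, VH = 1:2), "state 0")
})

test_that("boundary starts never pay compensation (condition always holds)", {
  for (seed in 1:10) {
    chain <- random_bd_chain(12, seed = seed)
    db <- boundary_bounds(chain, VL = 0:5, VH = 6:11)
    nL <- nrow(db$cp_L$states)
    d0 <- c(1, rep(0, nL - 1))           # start at 0; exit at the high side
    expect_true(qsd_condition_check(d0, db$qsd_L$pi_q[seq_len(nL)],
                                    exit_side = "high"))
    nH <- nrow(db$cp_H$states)
    dP <- c(rep(0, nH - 1), 1)           # start at the top; exit at the low side
    expect_true(qsd_condition_check(dP, db$qsd_H$pi_q[seq_len(nH)],
                                    exit_side = "low"))
  }
})

test_that("any distribution passing the check obeys the pure QSD bound", {
  chain <- random_bd_chain(10, seed = 31)
  cp <- build_cutoff(as_bcrn(chain), region_box(0, 6))
  q <- compute_qsd(cp)
  n <- nrow(cp$states)
  set.seed(99)
  checked <- 0
  for (i in 1:20) {
    d <- stats::rexp(n); d <- d / sum(d)
    if (i <= 5) d <- c(1, rep(0, n - 1))          # include boundary starts
    if (!qsd_condition_check(d, q$pi_q[seq_len(n)], exit_side = "high")) next
    checked <- checked + 1
    t_grid <- seq(0.2, 3, by = 0.4) / q$lam
    tr <- transient_solve(cp, c(d, 0), t_grid)
    expect_true(all(tr$survival >= exp(-q$lam * t_grid) - 1e-9))
  }
  expect_gte(checked, 5)
})

test_that("exit probability is monotone in the distance from the boundary", {
  for (seed in c(5, 6)) {
    chain <- random_bd_chain(10, seed = seed)
    cp <- build_cutoff(as_bcrn(chain), region_box(0, 7))
    mc <- exit_monotonicity_check(cp, t_grid = c(0.5, 1, 2, 5, 10))
    expect_true(mc$monotone)
  }
  # low-side exit orientation
  chain <- random_bd_chain(10, seed = 8)
  cp_hi <- build_cutoff(as_bcrn(chain), region_box(4, 9))
  mc_hi <- exit_monotonicity_check(cp_hi, t_grid = c(1, 5))
  expect_true(mc_hi$monotone)
  # one-state region is trivially monotone
  net1 <- make_birth_death(function(n) 1, function(n) 0)
  expect_true(exit_monotonicity_check(build_cutoff(net1, region_box(0, 0)),
                                      t_grid = c(1, 2))$monotone)
})
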