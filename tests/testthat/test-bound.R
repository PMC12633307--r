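test_that("starting from the QSD needs no compensation", {
  cfg <- toggle_table_config(2, 2)
  cp <- build_cutoff(cfg$net, cfg$region)
  q <- compute_qsd(cp)
  b <- compensatory_constant(cp, q, d = q$pi_q)
  expect_lte(b$A, b$eps)
  expect_true(b$converged)
})

test_that("the sweep matches a scalar loop oracle on a 3-state chain", {
  net <- make_birth_death(function(n) 2, function(n) if (n > 0) 1 else 0)
  cp <- build_cutoff(net, region_box(1, 3))
  q <- compute_qsd(cp)
  d <- initial_point_mass(cp, 3)
  b <- compensatory_constant(cp, q, d = d, stall_tol = 0, max_loops = 500L,
                             record_trace = TRUE)
  oracle <- trace_compensatory(cp$Qtilde, q$pi_q, d, max_loops = 500L)
  expect_equal(b$A, oracle$A, tolerance = 1e-12)
  expect_equal(b$iterations, oracle$iterations)
  expect_equal(b$trace, oracle$sums, tolerance = 1e-12)
})

test_that("unmatched mass never increases across sweeps", {
  cfg <- toggle_table_config(2, 3)
  cp <- build_cutoff(cfg$net, cfg$region)
  q <- compute_qsd(cp)
  b <- compensatory_constant(cp, q, d = initial_point_mass(cp, cfg$x0),
                             record_trace = TRUE)
  expect_true(all(diff(b$trace) <= 1e-12))
  expect_gte(b$A, 0)
  expect_lte(b$A, 1)
})

test_that("mass concentrated near the boundary costs more compensation", {
  cfg <- toggle_table_config(6, 2)
  cp <- build_cutoff(cfg$net, cfg$region)
  q <- compute_qsd(cp)
  A_interior <- compensatory_constant(cp, q,
                                      d = initial_point_mass(cp, c(30, 0)))$A
  A_boundary <- compensatory_constant(cp, q,
                                      d = initial_point_mass(cp, c(10, 6)))$A
  expect_gt(A_boundary, A_interior)
})

test_that("moving the initial law toward the QSD cannot raise the constant", {
  cfg <- toggle_table_config(2, 2)
  cp <- build_cutoff(cfg$net, cfg$region)
  q <- compute_qsd(cp)
  d0 <- initial_point_mass(cp, cfg$x0)
  A_prev <- Inf
  for (theta in c(0, 0.3, 0.7, 1)) {
    d <- (1 - theta) * d0 + theta * q$pi_q
    A <- compensatory_constant(cp, q, d = d)$A
    expect_lte(A, A_prev + 1e-9)
    A_prev <- A
  }
})

test_that("the compensated bound is valid against the exact transient law", {
  fixtures <- list(
    toggle_table_config(2, 2),
    toggle_table_config(2, 4)
  )
  for (cfg in fixtures) {
    cp <- build_cutoff(cfg$net, cfg$region)
    q <- compute_qsd(cp)
    b <- compensatory_constant(cp, q, d = initial_point_mass(cp, cfg$x0))
    t_grid <- exp(seq(log(0.01 / q$lam), log(3 / q$lam), length.out = 20))
    tr <- transient_solve(cp, initial_point_mass(cp, cfg$x0), t_grid)
    expect_true(all(tr$survival >=
                      survival_lower_bound(q$lam, b$A, t_grid) - 1e-9))
  }
  chain <- bistable_bd_chain()
  cpb <- build_cutoff(as_bcrn(chain), region_box(0, 6))
  qb <- compute_qsd(cpb)
  bb <- compensatory_constant(cpb, qb, d = initial_point_mass(cpb, 2))
  tg <- exp(seq(log(0.01 / qb$lam), log(3 / qb$lam), length.out = 20))
  trb <- transient_solve(cpb, initial_point_mass(cpb, 2), tg)
  expect_true(all(trb$survival >=
                    survival_lower_bound(qb$lam, bb$A, tg) - 1e-9))
})

test_that("bound evaluators follow their closed forms and clamps", {
  expect_equal(survival_lower_bound(0.5, 0.1, 0), 0.9)
  expect_equal(survival_lower_bound(0, 0.1, 1e6), 0.9)
  expect_equal(survival_lower_bound(1.93e-3, 4.62e-2, 3600),
               exp(-6.948) - 0.0462)
  expect_equal(switching_probability_upper(0.5, 0.1, 0), 0.1)
  expect_equal(switching_probability_upper(10, 0.2, 100), 1)  # clamp at 1
  expect_error(survival_lower_bound(0.5, 0.1, -1), "non-negative")
  expect_error(switching_probability_upper(0.5, 1.2, 1), "0, 1")
})
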