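p_ref <- rate_constants(1, 1, 1, 6)   # nullcline trapping-region set

test_that("full-model trajectories respect conservation and enter Gamma", {
  gc <- qss_curve("gamma_c", p_ref)
  for (s0 in 1:6) {
    tr <- integrate_full(p_ref, c(s0, 0))
    expect_true(all(tr$c <= p_ref$e0 + 1e-8))
    expect_true(all(tr$c >= -1e-8))
    expect_true(all(tr$s <= s0 + 1e-8))
    tc <- find_crossing(tr, gc)
    expect_false(is.na(tc))
    expect_gt(tc, 0)
    expect_lt(tc, max(tr$times))
  }
})

test_that("no-flux and degenerate cases integrate to constants", {
  p0 <- rate_constants(1, 1, 1, 0)          # k1*e0 = 0
  tr <- integrate_full(p0, c(5, 0), horizon = 10)
  expect_equal(tr$s, rep(5, length(tr$s)))
  # slow-product reduction with k2 = 0 is constant
  pz <- rate_constants(1, 2, 0, 3)
  trz <- integrate_reduction("slow_product", pz, 4, horizon = 10)
  expect_equal(trz$s, rep(4, length(trz$s)))
})

test_that("sQSSA integration matches the closed-form quadrature", {
  # t(s) = (K_M log(s0/s) + s0 - s)/(k2 e0), inverted numerically,
  # is an oracle independent of the ODE path
  p <- rate_constants(1, 1, 1, 0.5)
  s0 <- 10
  tr <- integrate_reduction("sqssa", p, s0)
  for (frac in c(0.2, 0.5, 0.8)) {
    tq <- frac * max(tr$times)
    s_num <- trajectory_interp(tr, tq)$s
    s_orc <- uniroot(function(s)
      (p$K_M * log(s0 / s) + s0 - s) / (p$k2 * p$e0) - tq,
      c(1e-10, s0), tol = 1e-13)$root
    expect_equal(s_num, s_orc, tolerance = 1e-7)
  }
})

test_that("rQSSA outer piece depletes linearly from the shifted IC", {
  p <- rate_constants(1, 0.05, 0.1, 6)
  ic <- shifted_initial_condition(p, 10)
  tr <- integrate_reduction("rqssa_outer", p, ic$s)
  expect_equal(trajectory_interp(tr, 0.5)$s,
               ic$s - p$k2 * p$e0 * 0.5, tolerance = 1e-9)
  expect_true(all(tr$s >= 0))                   # clipped at hand-off
  expect_equal(tr$c, rep(p$e0, length(tr$c)))
  # inner piece: exponential complex decay
  tri <- integrate_reduction("rqssa_inner", p, p$e0)
  expect_equal(trajectory_interp(tri, 1)$c, p$e0 * exp(-p$k2),
               tolerance = 1e-8)
})

test_that("crossing detection is exact on-curve and ordered for fences", {
  gc <- qss_curve("gamma_c", p_ref)
  # start exactly on the c-nullcline
  s0 <- 3
  tr <- integrate_full(p_ref, c(s0, gc$value(s0)))
  expect_identical(find_crossing(tr, gc), 0)
  # both fence crossings exist and are finite for a high-s0 launch
  tr2 <- integrate_full(p_ref, c(12, 0))
  t_c <- find_crossing(tr2, "gamma_c")
  t_sp <- find_crossing(tr2, "gamma_SP")
  expect_false(is.na(t_c))
  expect_false(is.na(t_sp))
  # launched below s* the slow-product curve lies above the c-nullcline,
  # so it is crossed second
  tr4 <- integrate_full(p_ref, c(4, 0))       # s0 = 4 < s* = 5
  expect_gt(find_crossing(tr4, "gamma_SP"), find_crossing(tr4, "gamma_c"))
  # a curve never reached reports NA
  p_iso <- rate_constants(1, 1, 1, 6)
  tr3 <- integrate_full(p_iso, c(0.5, 0), horizon = 0.01, s_stop = 0)
  expect_true(is.na(find_crossing(tr3, "gamma_s")))
})

test_that("trajectories stay inside Gamma_0 after entering", {
  for (s0 in c(2, 6, 12)) {
    tr <- integrate_full(p_ref, c(s0, 0))
    tc <- find_crossing(tr, "gamma_c")
    g0 <- anti_funnel("Gamma_0", p_ref)
    sel <- tr$times >= tc & tr$times > 0
    expect_true(all(g0$contains(tr$s[sel], tr$c[sel], tol = 1e-7)))
  }
})

test_that("error metrics are zero for identical inputs and well-behaved", {
  tr <- integrate_full(p_ref, c(6, 0))
  met <- error_metrics(tr, tr)
  expect_identical(c(met$max_abs, met$max_rel, met$l2), c(0, 0, 0))
  expect_error(error_metrics(tr, tr, window = c(5, 5)), "empty")
})

test_that("metrics are solver-discretization independent (10x tolerances)", {
  p <- rate_constants(1, 100, 10, 6)
  run <- function(rtol, atol) {
    f <- integrate_full(p, c(9, 0), rtol = rtol, atol = atol)
    r <- integrate_reduction("sqssa", p, 9, rtol = rtol, atol = atol)
    error_metrics(f, r, c(find_crossing(f, "gamma_c"), Inf))$max_rel
  }
  m1 <- run(1e-8, 1e-10)
  m2 <- run(1e-9, 1e-11)
  expect_lt(abs(m1 - m2) / m1, 0.01)
})

test_that("explicit and Rosenbrock steppers agree", {
  p <- rate_constants(1, 500, 1, 10)
  tr1 <- integrate_full(p, c(10, 0), method = "dp45")
  tr2 <- integrate_full(p, c(10, 0), method = "ros23", rtol = 1e-9)
  tq <- seq(0.05, min(max(tr1$times), max(tr2$times)), length.out = 200)
  expect_equal(trajectory_interp(tr1, tq)$s, trajectory_interp(tr2, tq)$s,
               tolerance = 1e-5)
})

test_that("rate bounds hold along trajectories (props 1, 2 and the chain)", {
  tr <- integrate_full(p_ref, c(6, 0))
  for (which in c("prop1", "prop2")) {
    bc <- rate_bound_check(tr, p_ref, which)
    expect_identical(bc$n_violations, 0L, info = which)
    expect_gt(bc$n_checked, 10)
  }
  # chain bound after the slow-product crossing while s <= s_star
  tr2 <- integrate_full(p_ref, c(12, 0))
  bc <- rate_bound_check(tr2, p_ref, "eq67")
  expect_identical(bc$n_violations, 0L)
  expect_gt(bc$n_checked, 10)
  # degenerate e0 = 0 collapses the envelope without error
  p0 <- rate_constants(1, 1, 1, 0)
  tr0 <- integrate_full(p0, c(1, 0), horizon = 1)
  expect_identical(rate_bound_check(tr0, p0, "prop2")$n_violations, 0L)
  # eq67 preconditions are enforced
  expect_error(rate_bound_check(tr, rate_constants(1, 1, 10, 6), "eq67"),
               "e0 > K")
})

test_that("trajectories serialize to CSV and JSON", {
  tr <- integrate_full(p_ref, c(2, 0))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_trajectory(tr, csv)
  tab <- utils::read.csv(csv)
  expect_identical(names(tab), c("t", "s", "c", "model"))
  expect_equal(nrow(tab), length(tr$times))
  write_trajectory(tr, js)
  payload <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(payload$params$e0, 6)
})
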