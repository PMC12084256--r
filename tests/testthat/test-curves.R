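fig4 <- list(
  top_left = rate_constants(0.1, 1, 1, 6),
  top_right = rate_constants(0.1, 1, 0.6, 6),
  bottom_left = rate_constants(1, 1, 1, 6),
  bottom_right = rate_constants(1, 1, 0.4, 6)
)

test_that("curves evaluate and differentiate per their closed forms", {
  p <- rate_constants(1, 1, 1, 6)
  expect_equal(qss_curve("gamma_c", p)$value(p$K_M), p$e0 / 2)
  expect_equal(qss_curve("alpha_cs", p)$deriv(0), origin_spectrum(p)$m)
  # gamma_SP'(0) closed form
  for (q in random_params(100, seed = 31)) {
    got <- qss_curve("gamma_SP", q)$deriv(0)
    want <- q$k1 * q$e0 / q$k_neg1 -
      q$k2 * q$e0 / (q$k_neg1 * (q$K_S + q$e0))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # all five curves pass through the origin; analytic derivatives match
  # central differences away from 0
  s <- c(0.05, 0.7, 3, 25)
  h <- 1e-6
  for (nm in c("gamma_c", "gamma_s", "alpha_cs", "gamma", "gamma_SP")) {
    cv <- qss_curve(nm, p)
    expect_equal(cv$value(0), 0, info = nm)
    num <- (cv$value(s + h) - cv$value(s - h)) / (2 * h)
    expect_equal(cv$deriv(s), num, tolerance = 1e-6, info = nm)
  }
})

test_that("s_star reproduces the four reference intersection points", {
  expect_equal(s_star(fig4$top_left), -4)
  expect_equal(s_star(fig4$top_right), 0, tolerance = 1e-12)
  expect_equal(s_star(fig4$bottom_left), 5)
  expect_equal(s_star(fig4$bottom_right), 14)
  expect_error(s_star(rate_constants(1, 1, 0, 1)), "k2 = 0")
})

test_that("fence residuals have the theorem-mandated signs", {
  # the Gamma_0 fences hold for any positive parameters; the sign is
  # asserted down to the roundoff floor of the residual evaluation
  # (the residual vanishes as the fences converge at large s)
  floor_of <- function(det) 1e-12 * det$scale
  for (p in random_params(50, seed = 17)) {
    g <- default_s_grid(p, n = 60)
    dg <- fence_residual(qss_curve("gamma", p), p, g, detail = TRUE)
    expect_true(all(dg$residual < floor_of(dg)))
    dc <- fence_residual(qss_curve("gamma_c", p), p, g, detail = TRUE)
    expect_true(all(dc$residual > -floor_of(dc)))
  }
  # gamma_SP is an upper fence under e0 < 8 K_S
  set.seed(18)
  found <- 0
  while (found < 30) {
    d <- exp(runif(4, log(1e-2), log(1e2)))
    p <- rate_constants(d[1], d[2], d[3], d[4])
    if (!(p$e0 < 8 * p$K_S)) next
    found <- found + 1
    g <- default_s_grid(p, n = 60)
    dsp <- fence_residual(qss_curve("gamma_SP", p), p, g, detail = TRUE)
    expect_true(all(dsp$residual > -floor_of(dsp)))
  }
  expect_error(fence_residual(qss_curve("gamma_c", fig4$top_left),
                              fig4$top_left, c(0, 1)),
               "strictly positive")
})

test_that("anti-funnels order their fences and narrow", {
  p <- rate_constants(1, 1, 1, 6)
  g0 <- anti_funnel("Gamma_0", p)
  s <- exp(seq(log(1e-3), log(1e4), length.out = 100))
  w <- g0$width(s)
  expect_true(all(w > 0))
  # narrowing: width decreases at large s and tends to 0
  tail_w <- w[s > 100]
  expect_true(all(diff(tail_w) < 0))
  expect_lt(g0$width(1e8), 1e-6)
  # boundary membership
  gc_val <- qss_curve("gamma_c", p)$value(2)
  expect_true(g0$contains(2, gc_val))
  expect_false(g0$contains(2, gc_val - 1e-6))
  # Gamma_SP: ordering gamma_SP < gamma on a grid, and the 8 K_S guard
  gsp <- anti_funnel("Gamma_SP", p)       # e0 = 6 < 8 K_S = 8
  expect_true(all(gsp$width(s) > 0))
  p_bad <- rate_constants(1, 0.1, 1, 6)   # 8 K_S = 0.8 < e0
  expect_error(anti_funnel("Gamma_SP", p_bad), "8\\*K_S")
  # Gamma and Gamma_cs construct with the documented fence pairs
  expect_identical(anti_funnel("Gamma", p)$upper$name, "gamma_s")
  expect_identical(anti_funnel("Gamma_cs", p)$upper$name, "alpha_cs")
})

test_that("curve ordering matches the sign of s_star", {
  g <- exp(seq(log(1e-3), log(50), length.out = 150))
  # e0 < K: gamma_SP below gamma_c everywhere (the gamma_c < gamma_SP
  # ordering holds on none of the grid)
  rep1 <- curve_ordering_report(fig4$top_left, g)
  row <- subset(rep1$orderings, lower == "gamma_c" & upper == "gamma_SP")
  expect_identical(row$fraction_of_grid, 0)
  expect_equal(rep1$s_star, -4)
  expect_true(is.na(rep1$crossover))
  # e0 > K: crossover at s_star, located by bracketed root-finding
  rep2 <- curve_ordering_report(fig4$bottom_left, g)
  expect_equal(rep2$crossover, 5, tolerance = 1e-8)
  # gamma_SP above gamma_c exactly on (0, s_star)
  above <- qss_curve("gamma_SP", fig4$bottom_left)$value(g) >
    qss_curve("gamma_c", fig4$bottom_left)$value(g)
  expect_identical(above, g < rep2$crossover)
})

test_that("s_star agrees with bisection over random e0 > K draws", {
  set.seed(77)
  found <- 0
  while (found < 100) {
    d <- exp(runif(4, log(1e-2), log(1e2)))
    p <- rate_constants(d[1], d[2], d[3], d[4])
    if (p$e0 <= p$K * 1.01) next
    found <- found + 1
    rep <- curve_ordering_report(p, default_s_grid(p, n = 50))
    expect_equal(rep$crossover, s_star(p),
                 tolerance = 1e-8)
  }
})

test_that("slow-eigenvector slope dominates both QSS-curve slopes", {
  # strict in exact arithmetic; asserted up to a relative roundoff
  # slack of 1e-10 because the gap can fall below double precision
  for (p in random_params(1000, seed = 4242)) {
    m <- origin_spectrum(p)$m
    slack <- 1e-10 * m
    expect_lt(qss_curve("gamma_SP", p)$deriv(0), m + slack)
    expect_lt(qss_curve("gamma_c", p)$deriv(0), m + slack)
  }
})

test_that("curve tables export (s, c) pairs", {
  p <- rate_constants(1, 1, 1, 6)
  tab <- curve_table(qss_curve("gamma_c", p), c(1, 2))
  expect_equal(tab$c, c(6 / 3, 12 / 4))
  path <- withr::local_tempfile(fileext = ".csv")
  curve_table(qss_curve("gamma_c", p), c(1, 2), file = path)
  expect_equal(utils::read.csv(path)$c, tab$c)
})
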