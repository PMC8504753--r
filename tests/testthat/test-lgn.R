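test_that("implied moments match closed forms on small networks", {
  # single node: mean = intercept, var = sd^2
  g <- dag("x")
  net <- lgn(g, list(x = list(intercept = 3, coefficients = setNames(numeric(0), character(0)), sd = 2)))
  m <- implied_moments(net)
  expect_equal(unname(m$mean["x"]), 3)
  expect_equal(unname(m$cov["x", "x"]), 4)

  # deterministic child y = 2x, x ~ N(0,1): var(y) = 4, cov(x,y) = 2
  net2 <- chain_xy(beta = 2, sd_y = 0)
  m2 <- implied_moments(net2)
  expect_equal(unname(m2$cov["y", "y"]), 4)
  expect_equal(unname(m2$cov["x", "y"]), 2)
})

test_that("implied moments of a collider match a Monte-Carlo oracle", {
  # x -> z <- y with coefficients (1, -1), all residual sd 1
  g <- dag(c("x", "y", "z"), rbind(c("x", "z"), c("y", "z")))
  none <- setNames(numeric(0), character(0))
  net <- lgn(g, list(
    x = list(intercept = 0, coefficients = none, sd = 1),
    y = list(intercept = 0, coefficients = none, sd = 1),
    z = list(intercept = 0, coefficients = c(x = 1, y = -1), sd = 1)
  ))
  m <- implied_moments(net)
  n <- 1e6
  d <- rlgn(net, n, seed = 11)
  # 3 standard errors: SE(mean) = sd/sqrt(n); SE(var) ~ var * sqrt(2/n)
  for (v in c("x", "y", "z")) {
    expect_lt(abs(mean(d[[v]]) - m$mean[v]), 3 * sqrt(m$cov[v, v] / n))
    expect_lt(abs(var(d[[v]]) - m$cov[v, v]), 3 * m$cov[v, v] * sqrt(2 / n))
  }
  expect_equal(unname(m$cov["x", "z"]), 1)
  expect_equal(unname(m$cov["y", "z"]), -1)
  expect_lt(abs(cov(d$x, d$z) - 1), 3 * sqrt(2 / n) * 2)
})

test_that("sampled moments agree with implied moments on random networks", {
  for (seed in 1:4) {
    net <- random_lgn(sample(3:8, 1), seed = 100 + seed)
    m <- implied_moments(net)
    n <- 1e5
    d <- rlgn(net, n, seed = 200 + seed)
    for (v in net$graph$nodes) {
      expect_lt(abs(mean(d[[v]]) - m$mean[v]), 3 * sqrt(m$cov[v, v] / n) + 1e-12)
    }
  }
})

test_that("conditioning is exact: vacuous, deterministic, and chain cases", {
  net <- chain_xy(beta = 2, sd_y = 0)
  # vacuous conditioning equals the joint moments exactly
  m0 <- conditional_moments(net, numeric(0))
  expect_equal(m0, implied_moments(net))

  # y = 2x exactly: conditioning on x = 1 pins y at 2 with zero variance
  mc <- conditional_moments(net, c(x = 1))
  expect_equal(unname(mc$mean["y"]), 2, tolerance = 1e-6)
  expect_lt(mc$cov["y", "y"], 1e-6)

  # chain a -> b -> c with coefficients 0.5: effect of a = 2 on c is 0.5
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  none <- setNames(numeric(0), character(0))
  net3 <- lgn(g, list(
    a = list(intercept = 0, coefficients = none, sd = 1),
    b = list(intercept = 1, coefficients = c(a = 0.5), sd = 1),
    c = list(intercept = -1, coefficients = c(b = 0.5), sd = 1)
  ))
  base <- implied_moments(net3)$mean["c"]
  mc3 <- conditional_moments(net3, c(a = 2))
  expect_equal(unname(mc3$mean["c"] - base), 0.5 * 0.5 * 2, tolerance = 1e-10)

  # conditioning matches the regression-on-samples answer
  d <- rlgn(net3, 2e5, seed = 5)
  fit <- lm(c ~ a, data = d)
  expect_lt(abs(coef(fit)[2] - 0.25), 0.02)
})

test_that("conditioning on unknown or degenerate evidence errors descriptively", {
  net <- chain_xy()
  expect_error(conditional_moments(net, c(zzz = 1)), "unknown evidence")
  net0 <- chain_xy(sd_y = 0, sd_x = 0)  # point mass
  expect_error(conditional_moments(net0, c(x = 0, y = 0)), "singular")
})

test_that("ancestral sampling is deterministic under a seed and degenerate without noise", {
  net <- random_lgn(5, seed = 3)
  d1 <- rlgn(net, 50, seed = 42)
  d2 <- rlgn(net, 50, seed = 42)
  expect_identical(d1, d2)

  # all-zero residuals: every row identical
  net0 <- chain_xy(beta = 1.5, sd_y = 0, sd_x = 0)
  d0 <- rlgn(net0, 10)
  expect_true(all(d0$x == d0$x[1]) && all(d0$y == d0$y[1]))

  # CLT bound on a single standard normal node
  g <- dag("x")
  net1 <- lgn(g, list(x = list(intercept = 0, coefficients = setNames(numeric(0), character(0)), sd = 1)))
  d <- rlgn(net1, 1e5, seed = 9)
  expect_lt(abs(mean(d$x)), 0.02)
})

test_that("binary roots sample Bernoulli and keep exact first/second moments", {
  net <- bench5()
  d <- rlgn(net, 2e4, seed = 77)
  expect_true(all(d$g %in% c(0, 1)))
  m <- implied_moments(net)
  expect_equal(unname(m$mean["g"]), 0.5)
  expect_equal(unname(m$cov["g", "g"]), 0.25)
  expect_lt(abs(mean(d$g) - 0.5), 3 * sqrt(0.25 / 2e4))
  expect_lt(abs(mean(d$a) - m$mean["a"]), 3 * sqrt(m$cov["a", "a"] / 2e4))
})

test_that("JSON serialization round-trips structure, parameters and binary flags", {
  net <- bench5()
  tf <- tempfile(fileext = ".json")
  lgn_to_json(net, tf)
  back <- lgn_from_json(tf)
  expect_true(same_graph(net$graph, back$graph))
  expect_equal(back$binary, "g")
  for (v in net$graph$nodes) {
    expect_equal(back$params[[v]]$intercept, net$params[[v]]$intercept)
    expect_equal(back$params[[v]]$coefficients, net$params[[v]]$coefficients)
    expect_equal(back$params[[v]]$sd, net$params[[v]]$sd)
  }
})
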