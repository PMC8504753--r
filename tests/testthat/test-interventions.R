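test_that("fixing arcs zeroes coefficients and nothing else", {
  net <- bench5()
  mut <- fix_arcs(net, c("a", "b"))
  expect_equal(unname(mut$params$b$coefficients["a"]), 0)
  expect_equal(mut$params$b$sd, net$params$b$sd)
  expect_equal(mut$params$c$coefficients, net$params$c$coefficients)
  expect_error(fix_arcs(net, c("a", "zzz")), "not present")

  # fixing an already-zero arc leaves the distribution unchanged
  net0 <- fix_arcs(net, c("a", "b"))
  again <- fix_arcs(net0, c("a", "b"))
  expect_equal(implied_moments(again), implied_moments(net0))
})

test_that("severing a chain kills the downstream total effect", {
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  none <- setNames(numeric(0), character(0))
  net <- lgn(g, list(
    a = list(intercept = 0, coefficients = none, sd = 1),
    b = list(intercept = 0, coefficients = c(a = 0.6), sd = 1),
    c = list(intercept = 0, coefficients = c(b = 0.5), sd = 1)
  ))
  expect_equal(total_effect(net, "a", "c"), 0.3)
  expect_equal(total_effect(fix_arcs(net, c("a", "b")), "a", "c"), 0)

  # fixing all incoming arcs of a node leaves it intercept + noise
  mut <- fix_arcs(net, rbind(c("a", "b")))
  m <- implied_moments(mut)
  expect_equal(unname(m$cov["b", "b"]), 1)
})

test_that("parallel paths add and absent paths give zero", {
  # two paths a -> m1 -> y (0.02) and a -> m2 -> y (0.025)
  g <- dag(c("a", "m1", "m2", "y"),
           rbind(c("a", "m1"), c("a", "m2"), c("m1", "y"), c("m2", "y")))
  none <- setNames(numeric(0), character(0))
  net <- lgn(g, list(
    a = list(intercept = 0, coefficients = none, sd = 1),
    m1 = list(intercept = 0, coefficients = c(a = 0.1), sd = 1),
    m2 = list(intercept = 0, coefficients = c(a = 0.5), sd = 1),
    y = list(intercept = 0, coefficients = c(m1 = 0.2, m2 = 0.05), sd = 1)
  ))
  expect_equal(total_effect(net, "a", "y"), 0.1 * 0.2 + 0.5 * 0.05, tolerance = 1e-12)
  expect_equal(total_effect(net, "y", "a"), 0)
})

test_that("path tracing agrees with a do-simulation regression oracle", {
  for (seed in 1:6) {
    net <- random_lgn(sample(4:6, 1), seed = 1100 + seed)
    nodes <- topo_sort(net$graph)
    src <- nodes[1]
    tgt <- nodes[length(nodes)]
    beta <- total_effect(net, src, tgt)
    n <- 1e5
    d <- rlgn(net, n, seed = 1200 + seed)
    fit <- lm.fit(cbind(1, d[[src]]), d[[tgt]])
    se <- sqrt(sum(fit$residuals^2) / (n - 2) / sum((d[[src]] - mean(d[[src]]))^2))
    # source is exogenous (first in topological order), so the marginal
    # regression identifies the total do-effect
    expect_lt(abs(fit$coefficients[2] - beta), 3 * se + 1e-8)
  }
})

test_that("pathway decomposition reproduces the printed worked example", {
  # a two-pathway toy calibrated to the published coefficients: full effect
  # 0.045; zeroing the strong mediator leg leaves 0.028 (38%); zeroing the
  # weak one leaves 0.042 (7%)
  g <- dag(c("s", "m1", "m2", "t"),
           rbind(c("s", "m1"), c("s", "m2"), c("m1", "t"), c("m2", "t"), c("s", "t")))
  none <- setNames(numeric(0), character(0))
  net <- lgn(g, list(
    s = list(intercept = 0, coefficients = none, sd = 1),
    m1 = list(intercept = 0, coefficients = c(s = 0.1), sd = 1),
    m2 = list(intercept = 0, coefficients = c(s = 0.1), sd = 1),
    t = list(intercept = 0, coefficients = c(m1 = 0.17, m2 = 0.03, s = 0.025), sd = 1)
  ))
  # legs carry 0.017 (strong), 0.003 (weak); direct 0.025; total 0.045
  expect_equal(total_effect(net, "s", "t"), 0.045, tolerance = 1e-12)
  dec <- decompose_pathways(net, "s", "t", list(
    strong = c("m1", "t"), weak = c("m2", "t"),
    both = rbind(c("m1", "t"), c("m2", "t"))
  ))
  expect_equal(dec$scenarios$beta_fixed, c(0.028, 0.042, 0.025), tolerance = 1e-12)
  expect_equal(dec$scenarios$contribution_pct_rounded[1], 38)
  expect_equal(dec$scenarios$contribution_pct_rounded[2], 7)
  # severing the strong leg upstream is equivalent to severing it downstream
  dec0 <- decompose_pathways(net, "s", "t", list(up = c("s", "m1")))
  expect_equal(dec0$scenarios$beta_fixed[1], 0.028, tolerance = 1e-12)
})

test_that("contributions of disjoint parallel paths are additive", {
  g <- dag(c("a", "m1", "m2", "y"),
           rbind(c("a", "m1"), c("a", "m2"), c("m1", "y"), c("m2", "y")))
  none <- setNames(numeric(0), character(0))
  net <- lgn(g, list(
    a = list(intercept = 0, coefficients = none, sd = 1),
    m1 = list(intercept = 0, coefficients = c(a = 0.4), sd = 1),
    m2 = list(intercept = 0, coefficients = c(a = 0.3), sd = 1),
    y = list(intercept = 0, coefficients = c(m1 = 0.5, m2 = 0.2), sd = 1)
  ))
  dec <- decompose_pathways(net, "a", "y", list(
    p1 = c("m1", "y"), p2 = c("m2", "y"),
    both = rbind(c("m1", "y"), c("m2", "y"))
  ))
  pc <- dec$scenarios$contribution_pct
  expect_equal(pc[1] + pc[2], pc[3], tolerance = 1e-10)
})

test_that("zero full effect is rejected", {
  net <- chain_xy(beta = 0)
  expect_error(decompose_pathways(net, "x", "y", list(a = c("x", "y"))), "undefined")
})

test_that("fixing arcs never alters non-descendants of the fixed arcs' children", {
  net <- bench5()
  mut <- fix_arcs(net, c("b", "c"))
  m0 <- implied_moments(net)
  m1 <- implied_moments(mut)
  for (v in c("g", "a", "b", "d")) {
    expect_equal(m1$mean[v], m0$mean[v])
    expect_equal(m1$cov[v, v], m0$cov[v, v])
  }
})

test_that("mediation check detects full and partial mediation", {
  # only group -> a -> b path: severing group -> a leaves no effect on b
  net <- bench5()
  med <- mediation_check(net, c("g", "a"), "b", n_samples = 2e4, seed = 17, group = "g")
  mc_se <- 3 * sqrt(implied_moments(net)$cov["b", "b"] / 2e4) / 0.5
  expect_lt(abs(med$beta), mc_se * 3)

  # add a direct group -> b arc with beta 1: it survives the severing
  g2 <- dag(net$graph$nodes, rbind(net$graph$arcs, c("g", "b")))
  p2 <- net$params
  p2$b$coefficients <- c(p2$b$coefficients, g = 1)
  net2 <- lgn(g2, p2, binary = "g")
  med2 <- mediation_check(net2, c("g", "a"), "b", n_samples = 2e4, seed = 18, group = "g")
  expect_lt(abs(med2$beta - 1), 0.15)
  expect_equal(total_effect(fix_arcs(net2, c("g", "a")), "g", "b"), 1)

  # severing an arc off every group -> target path changes nothing
  med3 <- mediation_check(net, c("b", "c"), "b", n_samples = 2e4, seed = 17, group = "g")
  base <- group_effect(net, "b", n_samples = 2e4, seed = 17, group = "g")
  expect_equal(med3$beta, base$beta, tolerance = 1e-12)
})
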