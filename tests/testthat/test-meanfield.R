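test_that("configuration statistics follow their defining formulas", {
  k2 <- net_k2()
  cs <- config_stats(k2, c(1, 0))
  expect_equal(cs$t[1, 1], -1/2)
  expect_equal(cs$t[1, 2], 1/2)
  expect_equal(cs$t[2, 2], 1/2)
  # absorbing configurations have vanishing statistics
  cs1 <- config_stats(k2, c(1, 1))
  expect_true(all(cs1$t == 0))
  expect_equal(cs1$B0, 0)
  expect_equal(c(cs1$C0, cs1$C1, cs1$C2), c(0, 0, 0))
})

test_that("uniform gamma terms on regular graphs and the fixed gap", {
  g3 <- gamma_uniform(net_k(3))
  expect_equal(g3[["g2"]], 1/2)
  expect_equal(g3[["g3"]] - g3[["g1"]], -1/4)
  # k-regular: gamma2 = N/2 - 1 and gamma3 - gamma1 = N/(2k) - 1
  for (p in list(c(8, 2), c(6, 5), c(10, 3))) {
    n <- p[1]; k <- p[2]
    net <- if (k == n - 1) net_k(n) else if (k == 2) net_cycle(n) else {
      set.seed(n + k)
      static_network(as.matrix(igraph::as_adjacency_matrix(
        igraph::sample_degseq(rep(k, n), method = "vl"))))
    }
    g <- gamma_uniform(net)
    expect_equal(g[["g2"]], n / 2 - 1)
    expect_equal(g[["g3"]] - g[["g1"]], n / (2 * k) - 1)
  }
  # on any network gamma2 - gamma1 = -1/2
  set.seed(61)
  for (rep in 1:4) {
    g <- gamma_uniform(rand_net(sample(4:9, 1)))
    expect_equal(g[["g2"]] - g[["g1"]], -1/2)
  }
})

test_that("config gammas average to the uniform ones over single cooperators", {
  set.seed(62)
  net <- rand_net(7)
  gs <- vapply(1:7, function(i) {
    xi <- rep(0, 7); xi[i] <- 1
    gamma_config(net, xi)
  }, numeric(3))
  expect_equal(rowMeans(gs), gamma_uniform(net), tolerance = 1e-10)
})

test_that("mean-field critical ratios: closed forms and the gamma-ratio identity", {
  expect_equal(mf_critical_uniform(net_cycle(8)), 3.0)
  expect_equal(mf_critical_uniform(net_k(3)), -2)
  for (p in list(c(8, 3), c(12, 4))) {
    set.seed(p[1])
    net <- static_network(as.matrix(igraph::as_adjacency_matrix(
      igraph::sample_degseq(rep(p[2], p[1]), method = "vl"))))
    expect_equal(mf_critical_uniform(net),
                 p[2] * (p[1] - 2) / (p[1] - 2 * p[2]))
  }
  # printed ratio formula == root of the gamma bracket, random (G, xi)
  set.seed(63)
  for (rep in 1:6) {
    net <- rand_net(sample(5:9, 1))
    xi <- sample(0:1, net$n, replace = TRUE)
    if (all(xi == 0) || all(xi == 1)) next
    g <- gamma_config(net, xi)
    expect_equal(mf_critical_config(net, xi),
                 g[["g2"]] / (g[["g3"]] - g[["g1"]]), tolerance = 1e-10)
  }
  expect_error(mf_critical_config(net_k(3), c(1, 1, 1)), "absorbing")
})

test_that("mean-field fixation: neutral limits, root property, clipping", {
  net <- rand_net(6, 0.6)
  expect_equal(mf_fixation(net, "uniform", b = 3, c = 1, delta = 0), 1/6)
  expect_equal(mf_fixation(net, "uniform", b = 0, c = 1e-12, delta = 0.3), 1/6,
               tolerance = 1e-10)
  xi <- c(1, 0, 0, 1, 0, 0)
  bc <- mf_critical_config(net, xi)
  r <- mf_fixation(net, xi, b = bc, c = 1, delta = 0.02)
  expect_equal(r, neutral_fixation_config(net, xi), tolerance = 1e-12)
  big <- mf_fixation(net, "uniform", b = 1e6, c = 1, delta = 0.5)
  expect_true(isTRUE(attr(big, "clipped")))
  expect_lte(as.numeric(big), 1)
})

test_that("temporal mean-field ratio: single snapshot, worked example, sign", {
  net <- rand_net(7, 0.5)
  expect_equal(mf_critical_temporal(as_static_chain(net)),
               mf_critical_uniform(net), tolerance = 1e-12)
  ex <- example_temporal_networks()
  expect_equal(round(mf_critical_temporal(ex$ring_regular), 1), 5.1)
  expect_equal(round(mf_critical_uniform(ex$ring_regular$net), 1), 9.0)
  # temporal and static ratios share their sign on the generator families
  lat <- lattice_temporal(6)
  expect_equal(sign(mf_critical_temporal(lat)),
               sign(mf_critical_uniform(lat$net)))
  ba <- ba_temporal(20, 2, seed = 14)
  expect_equal(sign(mf_critical_temporal(ba)),
               sign(mf_critical_uniform(ba$net)))
})

test_that("mean-field and exact ratios coincide on unweighted regular graphs", {
  for (p in list(c(8, 3), c(10, 3), c(9, 4))) {
    set.seed(p[1] * 10 + p[2])
    net <- static_network(as.matrix(igraph::as_adjacency_matrix(
      igraph::sample_degseq(rep(p[2], p[1]), method = "vl"))))
    expect_equal(critical_ratio_static(net), mf_critical_uniform(net),
                 tolerance = 1e-10)
  }
})

test_that("two-snapshot mean-field comparison flips at the difference crossing", {
  T <- example_temporal_networks()$ring_regular
  # growth helps for every b/c above the crossing of the two first-order
  # terms (-0.75 for this example) and hurts below it
  expect_true(mf_compare_L2(T, b = 6, c = 1))
  expect_true(mf_compare_L2(T, b = 3, c = 1))
  expect_false(mf_compare_L2(T, b = -1, c = 1))
  expect_false(mf_compare_L2(T, b = -2, c = 1))
  expect_error(mf_compare_L2(example_temporal_networks()$doubling, 2, 1),
               "two-snapshot")
})
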