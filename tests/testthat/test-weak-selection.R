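test_that("coalescence times solve their system on canonical graphs", {
  expect_equal(coalescence_times(net_k2())$tau[1, 2], 1)
  ct <- coalescence_times(net_k(3))
  expect_equal(ct$tau[1, 2], 2)
  expect_equal(c(ct$t1, ct$t2, ct$t3), c(2, 1, 1.5))
  # residual and symmetry on random graphs
  set.seed(21)
  for (rep in 1:4) {
    net <- rand_net(sample(5:9, 1))
    ct <- coalescence_times(net)
    tau <- ct$tau
    expect_lt(max(abs(tau - t(tau))), 1e-12)
    P <- walk_probs(net, 1)$P[[2]]
    resid <- 2 * tau - P %*% tau - tau %*% t(P) - 2
    expect_lt(max(abs(resid[upper.tri(resid)])), 1e-10)
    expect_true(all(diag(tau) == 0))
    expect_true(all(tau[upper.tri(tau)] >= 1))
  }
  # vertex-transitive graphs have identical tau row sums
  rs <- rowSums(coalescence_times(net_cycle(6))$tau)
  expect_equal(max(rs) - min(rs), 0, tolerance = 1e-10)
})

test_that("static critical ratio: complete and cycle graphs", {
  expect_equal(critical_ratio_static(net_k(3)), -2)
  for (n in c(4, 6, 9)) expect_equal(critical_ratio_static(net_k(n)), -(n - 1))
  for (n in c(5, 7, 8, 11))
    expect_equal(critical_ratio_static(net_cycle(n)), 2 * (n - 2) / (n - 4),
                 tolerance = 1e-10)
  # N = 2k sits on the spite/cooperation boundary
  expect_true(isTRUE(attr(critical_ratio_static(net_cycle(4)), "boundary")))
})

test_that("uniform first-order coefficients are the remeeting summaries", {
  set.seed(31)
  for (rep in 1:3) {
    net <- rand_net(sample(5:8, 1))
    fo <- first_order_static(net)
    ct <- coalescence_times(net)
    expect_equal(fo$C, ct$t2 / 2, tolerance = 1e-10)
    expect_equal(fo$B, (ct$t3 - ct$t1) / 2, tolerance = 1e-10)
    # and equal the single-cooperator average of configuration coefficients
    cfg <- lapply(seq_len(net$n), function(i) {
      xi <- rep(0, net$n); xi[i] <- 1
      first_order_static(net, xi)
    })
    expect_equal(mean(vapply(cfg, `[[`, 0, "C")), fo$C, tolerance = 1e-10)
    expect_equal(mean(vapply(cfg, `[[`, 0, "B")), fo$B, tolerance = 1e-10)
  }
})

test_that("configuration coefficients match a brute-force chain solve", {
  # independent oracle: finite difference of the full 2^n Markov chain
  set.seed(41)
  cases <- list(
    list(net = net_path(4), xi = c(1, 1, 0, 0), b = 3, c = 1),
    list(net = net_star(3), xi = c(0, 1, 1, 0), b = -2, c = 1),
    list(net = rand_net(5), xi = c(1, 0, 1, 0, 0), b = 4, c = 1))
  for (cs in cases) {
    fo <- first_order_static(cs$net, cs$xi)
    pred <- (-cs$c * fo$C + cs$b * fo$B) / cs$net$n
    d <- 1e-5
    r0 <- neutral_fixation_config(cs$net, cs$xi)
    r1 <- rho_chain_exact(cs$net, cs$xi, cs$b, cs$c, d)
    expect_equal((r1 - r0) / d, pred, tolerance = 1e-3)
  }
  # absorbing configurations have zero coefficients
  fo <- first_order_static(net_k(3), c(1, 1, 1))
  expect_true(fo$absorbing)
  expect_equal(c(fo$C, fo$B), c(0, 0))
})

test_that("worked 8-node example: tie at neutrality, ratios 9.0 and 5.1", {
  T <- example_temporal_networks()$ring_regular
  nc <- neutral_chain(T)
  expect_equal(nc$rho_T, 0.125)
  expect_true(nc$tie)
  expect_equal(round(critical_ratio_static(T$net), 1), 9.0)
  expect_equal(round(critical_ratio_temporal(T), 1), 5.1)
})

test_that("temporal coefficients respect the product-rule structure", {
  # one snapshot: identical to the static uniform coefficients
  net <- rand_net(6, 0.6)
  foS <- first_order_static(net)
  foT <- first_order_temporal(as_static_chain(net))
  expect_equal(foT$C, foS$C, tolerance = 1e-12)
  expect_equal(foT$B, foS$B, tolerance = 1e-12)
  # a repeated identical snapshot is a no-op transition
  T2 <- seq_temporal_network(net, activation_schedule(rep(1L, 6), L = 2L))
  foT2 <- first_order_temporal(T2)
  expect_equal(foT2$C, foS$C, tolerance = 1e-12)
  expect_equal(foT2$B, foS$B, tolerance = 1e-12)
})

test_that("temporal slope matches simulation on the tied worked example", {
  T <- example_temporal_networks()$ring_regular
  fo <- first_order_temporal(T)
  b <- 2; c <- 1; delta <- 0.02
  pred <- (-c * fo$C + b * fo$B) / T$n
  e <- estimate_fixation(T, game_params(b, c, delta), 4e5, seed = 12)
  slope <- (e$p_hat - 0.125) / delta
  expect_lt(abs(slope - pred), 3 * e$stderr / delta)
})

test_that("network comparison verdicts follow neutral then first order", {
  ex <- example_temporal_networks()
  v <- compare_networks(ex$ring_sparse, b = 2, c = 1)
  expect_equal(v$verdict, "promotes")
  expect_equal(v$order, "neutral")
  v2 <- compare_networks(ex$ring_dense, b = 2, c = 1)
  expect_equal(v2$verdict, "suppresses")
  # tied neutral values: decided at first order, between the two ratios
  v3 <- compare_networks(ex$ring_regular, b = 6, c = 1)
  expect_equal(v3$order, "first-order")
  expect_equal(v3$verdict, "promotes")
  expect_true(v3$bc_S > v3$bc_T, info = "growth lowers the critical ratio")
  # a single-snapshot chain is indistinguishable from its own static network
  v4 <- compare_networks(as_static_chain(net_k(4)), b = 2, c = 1)
  expect_equal(v4$verdict, "equal")
})
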