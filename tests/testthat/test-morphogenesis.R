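test_that("resting neurons produce no compensation changes", {
  cfg <- tiny_config()
  set.seed(1)
  C <- init_connectivity(cfg)
  pools <- new_element_pools(cfg)
  got <- compensation_update(C, pools, rep(0.2, cfg$n), cfg)
  expect_equal(got$dC, matrix(0, cfg$n, cfg$n))
  expect_equal(got$pools, pools)
})

test_that("high activity dismantles excitatory inputs and offers elements", {
  cfg <- tiny_config()
  set.seed(2)
  C <- init_connectivity(cfg)
  pools <- new_element_pools(cfg)
  s <- rep(0.2, cfg$n); s[1] <- 0.35  # one HIGH granule cell
  got <- compensation_update(C, pools, s, cfg)
  exc <- cfg$classes %in% c("GC", "MC")
  expect_true(all(got$dC[1, exc & C[1, ] > 0] < 0))   # exc inputs shrink
  expect_true(all(got$dC[1, !exc] == 0))              # inh inputs untouched
  expect_true(all(got$dC[-1, ] == 0))
  expect_gt(got$pools$free_exc_post[1], 0)            # released units
  expect_gt(got$pools$free_inh_post[1], 0)            # inhibition demand
  expect_gt(got$pools$free_pre[1], 0)
  # released mass matches the connectivity removed, one element per unit
  expect_equal(got$pools$free_exc_post[1], -sum(got$dC[1, exc]))
})

test_that("low activity prunes inhibition and outputs, offers excitation", {
  cfg <- tiny_config()
  set.seed(3)
  C <- init_connectivity(cfg)
  pools <- new_element_pools(cfg)
  pools$free_pre[1] <- 2
  s <- rep(0.2, cfg$n); s[1] <- 0.05  # one LOW granule cell
  got <- compensation_update(C, pools, s, cfg)
  exc <- cfg$classes %in% c("GC", "MC")
  expect_true(all(got$dC[1, !exc] < 0))               # inh inputs pruned
  expect_true(all(got$dC[-1, 1][C[-1, 1] > 0] < 0))   # outputs pruned
  expect_gt(got$pools$free_exc_post[1], 0)
  expect_lt(got$pools$free_pre[1], 2 * (1 - cfg$free_decay) + 1e-12)
})

test_that("a single compatible pre/post element pair forms one synapse", {
  cfg <- tiny_config(free_decay = 0)
  pools <- new_element_pools(cfg)
  pools$free_pre[2] <- 1        # granule cell 2 offers one presynaptic unit
  pools$free_exc_post[1] <- 1   # granule cell 1 demands one excitatory unit
  got <- form_synapses(pools, cfg)
  expected <- matrix(0, cfg$n, cfg$n)
  expected[1, 2] <- 1
  expect_equal(got$dC, expected)
  expect_equal(sum(unlist(got$pools)), 0)  # both pools emptied
})

test_that("synapse formation conserves elements and respects both pools", {
  cfg <- tiny_config(free_decay = 0)
  set.seed(9)
  for (rep in 1:20) {
    pools <- new_element_pools(cfg)
    pools$free_pre <- runif(cfg$n, 0, 2)
    pools$free_exc_post <- runif(cfg$n, 0, 2)
    pools$free_inh_post <- runif(cfg$n, 0, 2)
    got <- form_synapses(pools, cfg)
    expect_true(all(got$dC >= 0))
    expect_true(all(diag(got$dC) == 0))
    # conservation: bound increase equals free decrease on each side
    pre_used <- pools$free_pre - got$pools$free_pre
    post_used <- (pools$free_exc_post + pools$free_inh_post) -
      (got$pools$free_exc_post + got$pools$free_inh_post)
    expect_equal(sum(got$dC), sum(pre_used), tolerance = 1e-9)
    expect_equal(sum(got$dC), sum(post_used), tolerance = 1e-9)
    expect_true(all(unlist(got$pools) >= -1e-12))
  }
})

test_that("Hebbian reinforcement scales existing synapses only", {
  C <- matrix(0, 3, 3)
  C[1, 2] <- 1
  d <- hebbian_update(z_prev = c(0, 1, 0), z_now = c(1, 0, 0), C,
                      rho = 0.3, eta = 0.001)
  expect_equal(d[1, 2], 0.3 * 0.001)
  expect_equal(sum(d != 0), 1)
  # no presynaptic firing -> nothing
  expect_equal(hebbian_update(c(0, 0, 0), c(1, 1, 1), C, 0.3, 0.001),
               matrix(0, 3, 3))
  # rho = 0 disables the rule
  expect_equal(hebbian_update(c(1, 1, 1), c(1, 1, 1), C, 0, 0.001),
               matrix(0, 3, 3))
})

test_that("anti-Hebbian depression reduces but never inverts connectivity", {
  C <- matrix(0.5, 3, 3); diag(C) <- 0
  d <- anti_hebbian_update(z_prev = c(0, 0, 1), z_now = c(1, 0, 0), C,
                           rho = 0.3, eta_anti = 0.1)
  expect_lt(d[1, 2], 0)
  expect_equal(d[1, 3], 0)   # presynaptic neuron fired: rule not triggered
  expect_equal(d[2, 1], 0)   # postsynaptic neuron silent
  expect_true(all(C + d >= 0))
  # a zero synapse stays zero
  C0 <- matrix(0, 2, 2)
  expect_equal(anti_hebbian_update(c(0, 0), c(1, 1), C0, 0.5, 10),
               matrix(0, 2, 2))
})

test_that("accumulated Hebb/anti-Hebb equals a per-pair replay oracle", {
  set.seed(31)
  n <- 3
  C <- matrix(runif(n * n, 0.5, 1.5), n, n); diag(C) <- 0
  rho <- 0.3; eta <- 0.01; eta_anti <- 0.0025
  zs <- matrix(sample(0:1, 20 * n, replace = TRUE), ncol = n)

  # package path: accumulate per-iteration updates (C fixed within a step)
  acc <- matrix(0, n, n)
  for (t in 2:nrow(zs)) {
    acc <- acc + hebbian_update(zs[t - 1, ], zs[t, ], C, rho, eta) +
      anti_hebbian_update(zs[t - 1, ], zs[t, ], C, rho, eta_anti)
  }

  # brute-force oracle: replay every (post, pre, t) triple
  oracle <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j || C[i, j] == 0) next
    for (t in 2:nrow(zs)) {
      if (zs[t, i] == 1 && zs[t - 1, j] == 1) {
        oracle[i, j] <- oracle[i, j] + rho * eta * C[i, j]
      }
      if (zs[t, i] == 1 && zs[t - 1, j] == 0) {
        oracle[i, j] <- oracle[i, j] - rho * eta_anti * C[i, j]
      }
    }
  }
  expect_equal(acc, oracle, tolerance = 1e-12)
})

test_that("group change rates average rule-attributed changes exactly", {
  cfg <- tiny_config()
  g <- connectivity_groups(cfg)
  zero <- matrix(0, cfg$n, cfg$n)
  r0 <- group_change_rates(list(CT = zero, Hebb = zero), g)
  expect_true(all(r0$rate == 0))

  dI <- zero
  dI[!is.na(g) & g == 1L] <- 0.7
  r1 <- group_change_rates(list(CT = dI), g)
  expect_equal(r1$rate[r1$group == "I"], 0.7)
  expect_true(all(r1$rate[r1$group != "I"] == 0))

  # additivity: rule-wise rates sum to the total rate
  set.seed(4)
  dA <- matrix(runif(cfg$n^2), cfg$n, cfg$n)
  dB <- matrix(runif(cfg$n^2), cfg$n, cfg$n)
  rs <- group_change_rates(list(a = dA, b = dB, tot = dA + dB), g)
  wide <- tidyr::pivot_wider(rs, names_from = rule, values_from = rate)
  expect_equal(wide$a + wide$b, wide$tot, tolerance = 1e-12)
})

test_that("blockage zeroes frozen groups and rejects unknown labels", {
  cfg <- tiny_config()
  g <- connectivity_groups(cfg)
  d <- matrix(1, cfg$n, cfg$n)
  out <- apply_blockage(d, c("I", "IX"), g)
  expect_true(all(out[!is.na(g) & g %in% c(1L, 9L)] == 0))
  expect_true(all(out[!is.na(g) & !(g %in% c(1L, 9L))] == 1))
  expect_error(apply_blockage(d, "X", g), "unknown")
  expect_equal(apply_blockage(d, character(0), g), d)
})

test_that("bound elements are derived from connectivity row/column sums", {
  cfg <- tiny_config()
  set.seed(6)
  C <- init_connectivity(cfg)
  b <- bound_elements(C, cfg)
  exc <- cfg$classes %in% c("GC", "MC")
  expect_equal(b$bound_exc_post, rowSums(C[, exc]))
  expect_equal(b$bound_inh_post, rowSums(C[, !exc]))
  expect_equal(b$bound_pre, colSums(C))
})
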