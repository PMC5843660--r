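test_that("the GABAa weight envelope has the analytic limits", {
  pb <- 0.4
  # far below the window the first tanh saturates at -1
  expect_lt(phi(-3, t_i = 2, t_f = 16, phi_bar = pb), 1e-6)
  # deep inside a long window both factors saturate at 2: phi -> 4 phi_bar
  expect_equal(phi(500, t_i = 2, t_f = 1000, phi_bar = pb), 4 * pb,
               tolerance = 1e-6)
  # at t = t_i with a 14-day window: first factor exactly 1
  expect_equal(phi(2, t_i = 2, t_f = 16, phi_bar = pb),
               pb * 1.0 * (tanh(14 / 1.5) + 1), tolerance = 1e-12)
  # smooth: small time increments give small changes
  ts <- seq(0, 20, by = 1e-3)
  expect_lt(max(abs(diff(phi(ts, 2, 16, pb)))), 1e-2)
  # bounded by the asymptotic maximum
  expect_lt(max(phi(ts, 2, 16, pb)), 4 * pb)
  expect_true(all(phi(ts, 2, 16, pb) >= 0))
})

test_that("the signed GABAa weight inverts transiently and returns", {
  pb <- 0.4
  # non-inverted cells are always at the inhibitory baseline
  expect_equal(gabaa_weight(c(0, 5, 50), inverted = FALSE,
                            t_i = 2, t_f = 16, phi_bar = pb),
               rep(-pb, 3))
  # inverted: baseline before, excitatory mid-window, back after
  expect_equal(gabaa_weight(0, TRUE, 2, 16, pb), -pb, tolerance = 1e-6)
  expect_gt(gabaa_weight(9, TRUE, 2, 16, pb), 0)
  expect_lt(abs(gabaa_weight(9, TRUE, 2, 16, pb) - 3 * pb), 0.25 * pb)
  # transience: within 1% of baseline beyond t_f + 5 * 1.5 days
  late <- gabaa_weight(16 + 7.5, TRUE, 2, 16, pb)
  expect_lt(abs(late - (-pb)), 0.01 * pb)
})

test_that("inverted-cell selection matches the requested fraction", {
  set.seed(10)
  got <- select_inverted_cells(0.25, 100)
  expect_length(got, 25)
  expect_true(all(got >= 1 & got <= 100))
  expect_equal(select_inverted_cells(0, 100), integer(0))
  set.seed(99); a <- select_inverted_cells(0.45, 100)
  set.seed(99); b <- select_inverted_cells(0.45, 100)
  expect_identical(a, b)
})

test_that("protocol validation enforces the schedule ordering", {
  expect_error(experiment_protocol(stim_start = 3, t_i = 2), "schedule")
  expect_error(experiment_protocol(inverted_fraction = 1.5), "fraction")
  expect_error(experiment_protocol(gabaa_duration_days = -1), ">= 0")
  # no stimulus: ordering constraint does not apply
  p <- experiment_protocol(alpha = 0, stim_start = 3, t_i = 2)
  expect_s3_class(p, "dg_protocol")
})

test_that("zero rewiring rates freeze the connectivity matrix", {
  cfg <- tiny_config(nu = 0, rho = 0)
  r <- run_experiment(cfg, tiny_protocol(), seed = 5)
  expect_equal(r$C_final, r$C_baseline, tolerance = 1e-14)
  expect_true(all(r$groups$r_ct == 0))
  expect_true(all(r$groups$r_hebb == 0))
  expect_true(all(r$groups$r_antihebb == 0))
})

test_that("runs are bit-reproducible under a fixed seed", {
  cfg <- tiny_config()
  r1 <- run_experiment(cfg, tiny_protocol(), seed = 77)
  r2 <- run_experiment(cfg, tiny_protocol(), seed = 77)
  expect_identical(r1$steps, r2$steps)
  expect_identical(r1$C_final, r2$C_final)
  expect_identical(r1$groups, r2$groups)
  r3 <- run_experiment(cfg, tiny_protocol(), seed = 78)
  expect_false(identical(r3$C_final, r1$C_final))
})

test_that("the compiled engine matches the pure-R reference", {
  cfg <- tiny_config()
  pr <- tiny_protocol()
  rr <- run_experiment(cfg, pr, seed = 42, engine = "r",
                       record_neurons = TRUE)
  rc <- run_experiment(cfg, pr, seed = 42, engine = "cpp",
                       record_neurons = TRUE)
  expect_equal(rr$activity$s, rc$activity$s, tolerance = 1e-8)
  expect_equal(rr$C_final, rc$C_final, tolerance = 1e-8)
  expect_equal(rr$pools, rc$pools, tolerance = 1e-8)
  expect_equal(rr$groups$mean_c, rc$groups$mean_c, tolerance = 1e-8)
  expect_equal(rr$nse_iter, rc$nse_iter, tolerance = 1e-8)
})

test_that("morphogenesis fires exactly once per 150 iterations", {
  cfg <- tiny_config()
  pr <- experiment_protocol(alpha = 0, stim_start = 0,
                            inverted_fraction = 0,
                            gabaa_duration_days = 0, total_days = 0.075)
  r <- run_experiment(cfg, pr, seed = 1)
  # 0.075 days = 300 iterations = exactly 2 morphogenetic steps
  expect_equal(nrow(r$steps), 2L)
})

test_that("derived sweep seeds are deterministic, distinct and 32-bit", {
  s1 <- derive_seed(123, 1, 1)
  expect_identical(s1, derive_seed(123, 1, 1))
  expect_false(s1 == derive_seed(123, 1, 2))
  expect_false(s1 == derive_seed(123, 2, 1))
  ss <- sapply(1:50, function(r) derive_seed(2^30, 3, r))
  expect_true(all(ss > 0 & ss < 2^31))
  expect_equal(length(unique(ss)), 50)
})

test_that("sweeps are reproducible and carry per-run summaries", {
  cfg <- tiny_config()
  pr <- tiny_protocol()
  grid <- data.frame(gabaa_duration_days = 0.2)
  sw1 <- run_sweep(cfg, pr, grid, n_reps = 2, base_seed = 7)
  sw2 <- run_sweep(cfg, pr, grid, n_reps = 2, base_seed = 7)
  expect_identical(sw1, sw2)
  expect_equal(nrow(sw1), 2L)
  expect_false(sw1$seed[1] == sw1$seed[2])
  expect_true(all(paste0("chg_", c("I", "IX")) %in% names(sw1)))
})

test_that("frozen groups stay constant for the whole run", {
  cfg <- tiny_config()
  pr <- tiny_protocol(frozen_groups = c("IV", "VII"))
  r <- run_experiment(cfg, pr, seed = 12)
  g <- connectivity_groups(cfg)
  frozen <- !is.na(g) & g %in% c(4L, 7L)
  set.seed(12)
  C0 <- init_connectivity(cfg)
  expect_equal(r$C_final[frozen], C0[frozen], tolerance = 1e-14)
  # everything frozen -> whole matrix constant
  pr_all <- tiny_protocol(frozen_groups = attr(g, "labels"))
  r_all <- run_experiment(cfg, pr_all, seed = 12)
  expect_equal(r_all$C_final, C0, tolerance = 1e-14)
})

test_that("tidiers expose the result tables", {
  cfg <- tiny_config()
  r <- run_experiment(cfg, tiny_protocol(), seed = 3,
                      record_neurons = TRUE)
  expect_s3_class(tidy(r, "steps"), "tbl_df")
  expect_s3_class(tidy(r, "groups"), "tbl_df")
  expect_s3_class(tidy(r, "activity"), "tbl_df")
  expect_equal(nrow(tidy(r, "changes")), 9L)
  g <- glance(r)
  expect_equal(nrow(g), 1L)
  expect_true(all(c("n_events", "latency_days", "asmf_64d") %in% names(g)))
})
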