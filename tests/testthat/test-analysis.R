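test_that("the event detector finds constructed excursions exactly", {
  step_days <- 0.36 * 150 / 1440
  flat <- make_trace(rep(0.2, 200))
  expect_equal(nrow(detect_events(flat)), 0L)

  # one ~60-min excursion (2 steps) near day 30 of a 50-day trace
  s <- rep(0.2, round(50 / step_days))
  k <- round(30 / step_days)
  s[k:(k + 1)] <- 0.4
  ev <- detect_events(make_trace(s), min_steps = 1)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$spontaneous)
  expect_equal(ev$peak_s, 0.4)
  expect_equal(ev$onset_days, 30, tolerance = 0.1)

  # the same excursion inside the stimulus window is not spontaneous
  ev2 <- detect_events(make_trace(s), min_steps = 1,
                       stim_window = c(29.9, 30.2))
  expect_equal(sum(ev2$spontaneous), 0L)

  # outside the counting window it is not counted either
  ev3 <- detect_events(make_trace(s), min_steps = 1,
                       count_window = c(35, 100))
  expect_equal(sum(ev3$spontaneous), 0L)

  expect_error(detect_events(make_trace(numeric(0))), "empty")
})

test_that("raising the detection threshold never adds events", {
  set.seed(8)
  s <- pmin(pmax(0.2 + cumsum(rnorm(500, 0, 0.02)), 0), 0.6)
  counts <- sapply(seq(0.2, 0.5, by = 0.05), function(th) {
    nrow(detect_events(make_trace(s), threshold = th, min_steps = 2))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("a longer minimum duration never adds events", {
  set.seed(9)
  s <- pmin(pmax(0.2 + cumsum(rnorm(500, 0, 0.02)), 0), 0.6)
  counts <- sapply(1:6, function(ms) {
    nrow(detect_events(make_trace(s), min_steps = ms))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("latency is the first spontaneous onset minus the reference", {
  res <- list(
    events = tibble::tibble(
      onset_days = c(1.5, 20), offset_days = c(1.6, 20.1),
      peak_s = c(0.4, 0.3), spontaneous = c(FALSE, TRUE)),
    protocol = experiment_protocol(),
    config = network_config(n_gc = 4)
  )
  class(res) <- "dg_result"
  got <- event_latency(res)
  expect_false(got$censored)
  expect_equal(got$latency_days, 20 - 1.6)

  # explicit reference and exclusion of earlier events
  got2 <- event_latency(res, reference = 30)
  expect_true(got2$censored)

  res$events <- res$events[1, ]
  got3 <- event_latency(res)
  expect_true(got3$censored)
  expect_true(is.na(got3$latency_days))
})

test_that("connectivity change uses relative means with a Group I guard", {
  cfg <- tiny_config()
  g <- connectivity_groups(cfg)
  set.seed(2)
  C0 <- init_connectivity(cfg)
  expect_equal(connectivity_change(C0, C0, g)$change, rep(0, 9))

  C1 <- C0
  C1[!is.na(g) & g == 4L] <- C0[!is.na(g) & g == 4L] / 2
  got <- connectivity_change(C1, C0, g)
  expect_equal(got$change[got$group == "IV"], -50)
  expect_equal(got$change[got$group == "II"], 0)

  # Group I reported in units of the network-wide baseline mean
  C2 <- C0
  C2[!is.na(g) & g == 1L] <- 0.4
  got2 <- connectivity_change(C2, C0, g)
  net0 <- mean(C0[!is.na(g)])
  expect_equal(got2$change[got2$group == "I"], 0.4 / net0)
  expect_equal(got2$metric[got2$group == "I"], "rel_network_baseline")
  expect_error(connectivity_change(C0[1:3, 1:3], C0, g), "shape")
})

test_that("replicate summaries compute mean, SEM and Dunnett flags", {
  d <- data.frame(y = c(rep(5, 12), 1, 2, 3),
                  cond = c(rep("ctrl", 12), rep("b", 3)))
  s <- summarize_replicates(d, "y", "cond", control = "ctrl")
  expect_equal(s$sem[s$condition == "ctrl"], 0)
  expect_equal(s$sem[s$condition == "b"], 1 / sqrt(3))
  expect_equal(s$mean[s$condition == "b"], 2)
  expect_true(s$significant[s$condition == "b"])  # 2 vs 5, tiny variance
  expect_true(is.na(s$p_dunnett[s$condition == "ctrl"]))

  # replicate order does not matter
  dperm <- d[sample(nrow(d)), ]
  s2 <- summarize_replicates(dperm, "y", "cond", control = "ctrl")
  expect_equal(s, s2)

  # single replicate: SEM undefined, reported as NA
  d1 <- data.frame(y = c(1, 2), cond = c("a", "b"))
  s1 <- summarize_replicates(d1, "y", "cond")
  expect_true(all(is.na(s1$sem)))
})

test_that("the ANOVA keeps its nominal type-I error under the null", {
  set.seed(20180308)
  rejections <- replicate(200, {
    d <- data.frame(y = rnorm(24), cond = rep(c("a", "b"), each = 12))
    s <- summarize_replicates(d, "y", "cond", control = "a")
    isTRUE(attr(s, "anova_p") < 0.05)
  })
  # nominal 5%; binomial slack for 200 draws
  expect_lt(mean(rejections), 0.10)
})

test_that("the duration-sensitivity threshold detects the right fraction", {
  set.seed(5)
  grid <- expand.grid(inverted_fraction = c(0.05, 0.25, 0.45),
                      gabaa_duration_days = c(1, 7, 14, 21),
                      rep = 1:4)
  # synthetic outcome: flat at 5% and 25%, duration-dependent above
  grid$n_events <- ifelse(grid$inverted_fraction > 0.3,
                          2 * grid$gabaa_duration_days + rnorm(nrow(grid)),
                          rpois(nrow(grid), 2))
  grid$latency_days <- ifelse(grid$inverted_fraction > 0.3,
                              60 - 2 * grid$gabaa_duration_days +
                                rnorm(nrow(grid)), NA)
  # dependence appears beyond the 25% fraction
  expect_equal(duration_sensitivity_threshold(grid), 25)
})

test_that("the saturation estimator finds the plateau onset", {
  set.seed(3)
  durs <- c(1, 3, 5, 7, 14, 21)
  d <- expand.grid(gabaa_duration_days = durs, rep = 1:6)
  plateau <- function(x) ifelse(x < 5, 4 * x, 20)
  d$n_events <- plateau(d$gabaa_duration_days) + rnorm(nrow(d), 0, 0.2)
  d$chg_I <- plateau(d$gabaa_duration_days) / 10 + rnorm(nrow(d), 0, 0.05)
  expect_equal(saturation_duration(d), 5)
})

test_that("result bundles round-trip through the writers", {
  cfg <- tiny_config()
  r <- run_experiment(cfg, tiny_protocol(), seed = 2)
  dir <- withr::local_tempdir()
  write_result(r, dir)
  expect_true(file.exists(file.path(dir, "steps.csv")))
  steps <- utils::read.csv(file.path(dir, "steps.csv"))
  expect_equal(nrow(steps), nrow(r$steps))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 2)
  expect_equal(man$network$n_gc, cfg$n_gc)

  sw <- run_sweep(cfg, tiny_protocol(), data.frame(gabaa_duration_days = 0.2),
                  n_reps = 2, base_seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 2L)
})
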