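#' Time course of the transiently excitatory GABAa weight
#'
#' The GABAa weight envelope
#' \deqn{\varphi(t) = \bar\varphi (\tanh((t - t_i)/0.2) + 1)(\tanh((t_f - t)/1.5) + 1)}
#' with `t`, `t_i`, `t_f` in days. It is ~0 well before `t_i`, approaches
#' `4 * phi_bar` in the middle of a long window and returns to ~0 after
#' `t_f`; it is smooth and nonnegative.
#'
#' @param t Time, days (vectorised).
#' @param t_i,t_f Start and end of the excitatory-GABAa period, days.
#' @param phi_bar Baseline GABAa weight magnitude (> 0).
#' @return Numeric vector of `phi` values.
#' @export
#' @examples
#' phi(2.0, t_i = 2.0, t_f = 16.0, phi_bar = 0.4)
phi <- function(t, t_i, t_f, phi_bar) {
  phi_bar * (tanh((t - t_i) / 0.2) + 1.0) * (tanh((t_f - t) / 1.5) + 1.0)
}

#' Signed GABAa synaptic weight onto a granule cell
#'
#' For a granule cell whose GABAa response is not inverted the IN_A -> GC
#' weight is the constant inhibitory `-phi_bar`. For an inverted cell the
#' effective signed weight is `phi(t) - phi_bar`: it matches `-phi_bar`
#' well outside the window, rises through zero after `t_i`, peaks near
#' `+3 * phi_bar` (excitatory) mid-window, and returns to `-phi_bar` after
#' `t_f`.
#'
#' @param t Time, days (vectorised).
#' @param inverted Logical: does the target granule cell carry the
#'   transient GABAa inversion?
#' @param t_i,t_f Window bounds, days.
#' @param phi_bar Baseline weight magnitude.
#' @return Signed weight (negative = inhibitory).
#' @export
gabaa_weight <- function(t, inverted, t_i, t_f, phi_bar) {
  if (inverted) phi(t, t_i, t_f, phi_bar) - phi_bar else
    rep_len(-phi_bar, length(t))
}

#' Select the granule cells with transient excitatory GABAa
#'
#' Uniform sampling without replacement of `round(fraction * n_gc)` granule
#' cells, reproducible under [set.seed()].
#'
#' @param fraction Fraction of granule cells in `[0, 1]`.
#' @param n_gc Number of granule cells.
#' @return Sorted integer vector of granule-cell indices (possibly empty).
#' @export
select_inverted_cells <- function(fraction, n_gc) {
  stopifnot(fraction >= 0, fraction <= 1)
  k <- round(fraction * n_gc)
  if (k == 0) return(integer(0))
  sort(sample.int(n_gc, k))
}

#' Experiment schedule
#'
#' The status epilepticus -> latent period -> spontaneous activity
#' protocol: rest warm-up, a strong depolarising stimulus (`alpha`) for
#' `stim_duration_min` minutes starting at `stim_start` days, a transient
#' excitatory-GABAa window `[t_i, t_i + gabaa_duration_days]` applied to a
#' random fraction of granule cells, and continuation to `total_days` days
#' after the stimulus.
#'
#' @param stim_start Stimulus onset, days (warm-up at rest before it).
#' @param stim_duration_min Stimulus duration, minutes.
#' @param alpha Stimulus drive added to every membrane potential during the
#'   stimulus.
#' @param t_i Start of the excitatory-GABAa window, days.
#' @param gabaa_duration_days Duration of the window, days (`t_f = t_i +`
#'   duration). Zero disables the inversion.
#' @param inverted_fraction Fraction of granule cells inverted.
#' @param total_days Simulated days after stimulus onset.
#' @param frozen_groups Character vector of connectivity groups whose
#'   changes are withdrawn (blocked), e.g. `c("I")`.
#' @param latency_reference `"se_end"` (default) measures latency from the
#'   end of the stimulus-driven episode; `"stim_onset"` from stimulus
#'   onset.
#' @return An object of class `dg_protocol`.
#' @export
experiment_protocol <- function(stim_start = 1.5, stim_duration_min = 70,
                                alpha = 1.0, t_i = 2.0,
                                gabaa_duration_days = 14,
                                inverted_fraction = 0.25,
                                total_days = 100,
                                frozen_groups = character(0),
                                latency_reference = c("se_end",
                                                      "stim_onset")) {
  if (inverted_fraction < 0 || inverted_fraction > 1) {
    stop("inverted_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (gabaa_duration_days < 0) {
    stop("gabaa_duration_days must be >= 0", call. = FALSE)
  }
  t_f <- t_i + gabaa_duration_days
  if (alpha != 0 && !(stim_start < t_i)) {
    stop("invalid schedule: stimulus must precede the GABAa window",
         call. = FALSE)
  }
  structure(list(stim_start = stim_start,
                 stim_duration_min = stim_duration_min,
                 alpha = alpha, t_i = t_i, t_f = t_f,
                 gabaa_duration_days = gabaa_duration_days,
                 inverted_fraction = inverted_fraction,
                 total_days = total_days,
                 frozen_groups = as.character(frozen_groups),
                 latency_reference = match.arg(latency_reference)),
            class = "dg_protocol")
}

#' @export
print.dg_protocol <- function(x, ...) {
  cat("<dg_protocol>\n")
  cat(sprintf("  stimulus: alpha = %g for %g min at day %g\n",
              x$alpha, x$stim_duration_min, x$stim_start))
  cat(sprintf("  excitatory GABAa: %g%% of GC, days %g-%g\n",
              100 * x$inverted_fraction, x$t_i, x$t_f))
  cat(sprintf("  horizon: %g days post-stimulus\n", x$total_days))
  if (length(x$frozen_groups)) {
    cat("  blocked groups:", paste(x$frozen_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run one full experiment
#'
#' Simulates the complete schedule and returns activity, non-synaptic and
#' connectivity traces at morphogenetic-step resolution, connectivity
#' snapshots at the pre-stimulus baseline and 64 days post-SE, and detected
#' epileptiform events. Two engines are available: the compiled C++ core
#' (default; used for all full-size runs) and a pure-R reference that
#' composes the exported module operations step by step (for small
#' networks and cross-checking).
#'
#' @param config A `dg_config`.
#' @param protocol A `dg_protocol`.
#' @param seed Integer RNG seed; the whole run is reproducible from
#'   `(config, protocol, seed)`.
#' @param engine `"cpp"` or `"r"`.
#' @param record_neurons Record per-neuron activity traces (adds an
#'   `activity` tibble; off by default for sweeps).
#' @return A `dg_result` list with elements `steps` (population summary
#'   tibble per morphogenetic step), `groups` (per-group mean connectivity
#'   and per-rule change rates), `events` (detected epileptiform events),
#'   `activity` (optional per-neuron tibble), `C_baseline`, `C_post64`,
#'   `C_final`, `pools`, `inverted`, `config`, `protocol`, `seed`.
#' @export
run_experiment <- function(config, protocol, seed,
                           engine = c("cpp", "r"),
                           record_neurons = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "dg_config"), inherits(protocol, "dg_protocol"))
  set.seed(as.integer(seed))

  C0 <- init_connectivity(config)
  inverted <- select_inverted_cells(protocol$inverted_fraction, config$n_gc)
  theta_run <- theta_vector(config)

  dt <- config$dt_iter
  ipm <- config$iters_per_morph
  total_sim_days <- protocol$stim_start + protocol$total_days
  n_steps <- as.integer(ceiling(total_sim_days * 1440 / dt / ipm))
  step_days <- dt * ipm / 1440

  if (protocol$alpha != 0) {
    stim_start_iter <- as.integer(round(protocol$stim_start * 1440 / dt)) + 1L
    stim_len <- as.integer(round(protocol$stim_duration_min / dt))
  } else {
    stim_start_iter <- 0L
    stim_len <- 0L
  }
  inversion_on <- length(inverted) > 0 && protocol$t_f > protocol$t_i

  snap_baseline <- min(max(1L, as.integer(floor(protocol$stim_start /
                                                  step_days))), n_steps)
  snap_post64 <- min(as.integer(floor((protocol$stim_start + 64) /
                                        step_days)), n_steps)
  snap_steps <- unique(c(snap_baseline, snap_post64))

  gmap <- connectivity_groups(config)
  frozen9 <- attr(gmap, "labels") %in% protocol$frozen_groups

  if (engine == "cpp") {
    raw <- dg_sim_cpp(
      C0, base_weight_matrix(config),
      as.integer(as.integer(config$classes)),
      theta_run, offer_vector(config$kappa, config),
      offer_vector(config$vm_smooth, config),
      config$nu, config$rho, config$eta, config$eta_anti,
      config$hebb_on_inhibitory,
      config$rest_lo, config$rest_hi, config$L, config$p_rest,
      dt, ipm, n_steps,
      offer_vector(config$k_offer_exc, config),
      offer_vector(config$k_offer_inh, config),
      offer_vector(config$k_offer_pre, config),
      config$ct_gain, config$ct_margin, config$free_decay,
      config$prune_exc, offer_vector(config$prune_inh, config),
      offer_vector(config$prune_out, config),
      config$ns$a_e, config$ns$b_e, config$ns$tau_e,
      config$ns$a_i, config$ns$tau_i, config$ns$g_e, config$ns$g_i,
      protocol$alpha, stim_start_iter, stim_len,
      as.integer(inverted), config$phi_bar,
      protocol$t_i, protocol$t_f, inversion_on,
      ifelse(is.na(gmap), 0L, gmap), frozen9,
      as.integer(snap_steps), record_neurons
    )
  } else {
    raw <- dg_sim_r(config, protocol, C0, inverted, n_steps,
                    stim_start_iter, stim_len, inversion_on,
                    gmap, snap_steps, record_neurons, theta_run)
  }

  assemble_result(raw, config, protocol, seed, inverted, gmap,
                  n_steps, step_days, snap_baseline, snap_post64,
                  record_neurons, engine)
}

# Shape engine output into the dg_result tibbles.
assemble_result <- function(raw, config, protocol, seed, inverted, gmap,
                            n_steps, step_days, snap_baseline, snap_post64,
                            record_neurons, engine) {
  labels <- attr(gmap, "labels")
  time_days <- seq_len(n_steps) * step_days
  steps <- tibble::tibble(
    step = seq_len(n_steps),
    time_days = time_days,
    s_gc = raw$mean_s_gc,
    s_gc_inverted = raw$mean_s_gc_inv,
    s_mc = raw$mean_s_mc,
    s_in = raw$mean_s_in,
    nse = raw$mean_nse,
    nsi = raw$mean_nsi
  )
  groups <- tibble::tibble(
    step = rep(seq_len(n_steps), times = 9),
    time_days = rep(time_days, times = 9),
    group = factor(rep(labels, each = n_steps), levels = labels),
    mean_c = as.vector(raw$group_mean),
    r_ct = as.vector(raw$r_ct),
    r_hebb = as.vector(raw$r_hebb),
    r_antihebb = as.vector(raw$r_anti)
  )
  activity <- NULL
  if (record_neurons) {
    cl <- config$classes
    activity <- tibble::tibble(
      step = rep(seq_len(n_steps), times = config$n),
      time_days = rep(time_days, times = config$n),
      neuron = rep(seq_len(config$n), each = n_steps),
      cell_class = rep(as.character(cl), each = n_steps),
      inverted = rep(seq_len(config$n) %in% inverted, each = n_steps),
      s = as.vector(raw$s_mat),
      nse = as.vector(raw$nse_mat),
      nsi = as.vector(raw$nsi_mat)
    )
  }
  res <- structure(list(
    steps = steps, groups = groups, activity = activity,
    C_baseline = raw$snapshots[[as.character(snap_baseline)]],
    C_post64 = raw$snapshots[[as.character(min(snap_post64, n_steps))]],
    C_final = raw$C_final,
    pools = raw$pools,
    nse_iter = raw$nse_iter, nsi_iter = raw$nsi_iter,
    inverted = inverted, config = config, protocol = protocol,
    seed = seed, engine = engine
  ), class = "dg_result")
  res$events <- detect_events(res)
  res
}

#' @export
print.dg_result <- function(x, ...) {
  cat("<dg_result>\n")
  cat(sprintf("  %d morphogenetic steps (%.1f days), seed %s, engine %s\n",
              nrow(x$steps), max(x$steps$time_days),
              format(x$seed), x$engine))
  n_sp <- sum(x$events$spontaneous)
  cat(sprintf("  events: %d detected, %d spontaneous\n",
              nrow(x$events), n_sp))
  invisible(x)
}

# Pure-R engine: composes the exported module operations; mirrors the C++
# core (same RNG call order), practical only for small networks.
dg_sim_r <- function(config, protocol, C0, inverted, n_steps,
                     stim_start_iter, stim_len, inversion_on,
                     gmap, snap_steps, record_neurons,
                     theta = theta_vector(config)) {
  n <- config$n
  ipm <- config$iters_per_morph
  dt <- config$dt_iter
  cl <- config$classes
  cellular <- cl %in% c("GC", "MC")
  gc_mask <- cl == "GC"
  frozen <- if (length(protocol$frozen_groups))
    frozen_mask(protocol$frozen_groups, gmap) else NULL

  C <- C0
  pools <- new_element_pools(config)
  s <- rep(config$p_rest, n)
  nse <- numeric(n); nsi <- numeric(n)
  z <- as.integer(stats::runif(n) < config$p_rest)
  lam <- offer_vector(config$vm_smooth, config)
  vm_ema <- rep(NA_real_, n)
  Nh <- matrix(0, n, n); Na <- matrix(0, n, n)
  prob_acc <- numeric(n)

  out <- list(
    mean_s_gc = numeric(n_steps), mean_s_gc_inv = numeric(n_steps),
    mean_s_mc = numeric(n_steps), mean_s_in = numeric(n_steps),
    mean_nse = numeric(n_steps), mean_nsi = numeric(n_steps),
    group_mean = matrix(0, n_steps, 9),
    r_ct = matrix(0, n_steps, 9), r_hebb = matrix(0, n_steps, 9),
    r_anti = matrix(0, n_steps, 9),
    snapshots = list()
  )
  if (record_neurons) {
    out$s_mat <- matrix(0, n_steps, n)
    out$nse_mat <- matrix(0, n_steps, n)
    out$nsi_mat <- matrix(0, n_steps, n)
  }
  out$nse_iter <- numeric(n_steps * ipm)
  out$nsi_iter <- numeric(n_steps * ipm)
  gvec <- as.vector(gmap); keep <- !is.na(gvec)
  grp_mean <- function(M) as.numeric(tapply(as.vector(M)[keep], gvec[keep],
                                            mean))

  T_total <- n_steps * ipm
  for (t in seq_len(T_total)) {
    time_days <- (t - 1) * dt / 1440
    gw <- if (inversion_on)
      phi(time_days, protocol$t_i, protocol$t_f, config$phi_bar) -
        config$phi_bar else NULL
    alpha_t <- if (stim_len > 0 && t >= stim_start_iter &&
                     t < stim_start_iter + stim_len) protocol$alpha else 0
    vm <- membrane_potential(z, C, config, gabaa_w = gw,
                             inverted = inverted,
                             ns_effect = ns_effect(nse, nsi, config),
                             alpha = alpha_t)
    vm_ema <- ifelse(is.na(vm_ema), vm, vm_ema + lam * (vm - vm_ema))
    prob <- firing_probability(vm_ema, config, theta = theta)
    z_new <- sample_firing(prob)
    prob_acc <- prob_acc + prob
    Nh <- Nh + outer(z_new, z)
    Na <- Na + outer(z_new, 1L - z)
    nsx <- update_nonsynaptic(nse, nsi, s, config)
    nse <- nsx$nse; nsi <- nsx$nsi
    z <- z_new
    out$nse_iter[t] <- mean(nse[cellular])
    out$nsi_iter[t] <- mean(nsi[cellular])

    if (t %% ipm == 0L) {
      k <- t %/% ipm
      s <- prob_acc / ipm
      prob_acc <- numeric(n)

      ct <- compensation_update(C, pools, s, config, frozen)
      fs <- form_synapses(ct$pools, config, frozen)
      pools <- fs$pools
      dC_ct <- ct$dC + fs$dC
      dC_h <- config$rho * config$eta * C * Nh
      dC_a <- -config$rho * config$eta_anti * C * Na
      if (!config$hebb_on_inhibitory) {
        inh_col <- !(config$classes %in% c("GC", "MC"))
        dC_h[, inh_col] <- 0
        dC_a[, inh_col] <- 0
      }
      if (!is.null(frozen)) {
        dC_h[frozen] <- 0
        dC_a[frozen] <- 0
      }
      C <- pmax(C + dC_ct + dC_h + dC_a, 0)
      Nh <- matrix(0, n, n); Na <- matrix(0, n, n)

      out$mean_s_gc[k] <- mean(s[gc_mask])
      out$mean_s_gc_inv[k] <- if (length(inverted)) mean(s[inverted]) else NA
      out$mean_s_mc[k] <- mean(s[cl == "MC"])
      out$mean_s_in[k] <- mean(s[cl %in% c("IN_A", "IN_B")])
      out$mean_nse[k] <- mean(nse[cellular])
      out$mean_nsi[k] <- mean(nsi[cellular])
      out$group_mean[k, ] <- grp_mean(C)
      out$r_ct[k, ] <- grp_mean(dC_ct)
      out$r_hebb[k, ] <- grp_mean(dC_h)
      out$r_anti[k, ] <- grp_mean(dC_a)
      if (record_neurons) {
        out$s_mat[k, ] <- s
        out$nse_mat[k, ] <- nse
        out$nsi_mat[k, ] <- nsi
      }
      if (k %in% snap_steps) out$snapshots[[as.character(k)]] <- C
    }
  }
  out$C_final <- C
  out$pools <- pools
  out
}

#' Deterministic replicate seed derivation
#'
#' @param base_seed Base seed of the sweep.
#' @param point Grid-point index (1-based).
#' @param rep Replicate index (1-based).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(base_seed, point, rep) {
  as.integer((as.numeric(base_seed) %% 65536 * 10007 +
                point * 1009 + rep * 9973) %% 2147483646 + 1)
}

#' Parameter sweep with replicates
#'
#' Runs `run_experiment()` over a grid of protocol modifications, with
#' `n_reps` replicates per grid point and deterministically derived seeds,
#' and summarises every run into one row: spontaneous-event count within
#' the counting window, latency, and the 64-day per-group connectivity
#' changes (columns `chg_I`..`chg_IX`).
#'
#' @param config A `dg_config` (its `nu`, `rho` can be overridden per grid
#'   point via columns `nu`, `rho` in `grid`).
#' @param protocol Base `dg_protocol`; grid columns override its fields.
#' @param grid Data frame of protocol/config overrides; recognised columns:
#'   `inverted_fraction`, `gabaa_duration_days`, `nu`, `rho`,
#'   `frozen_groups` (list-column).
#' @param n_reps Replicates per grid point.
#' @param base_seed Base seed for [derive_seed()].
#' @param engine Simulation engine.
#' @return Tibble with one row per run: the grid columns plus `rep`,
#'   `seed`, `n_events`, `latency_days` (NA when censored), `censored`,
#'   and the nine `chg_*` columns.
#' @export
run_sweep <- function(config, protocol, grid, n_reps = 12,
                      base_seed = 20180308, engine = "cpp") {
  stopifnot(n_reps >= 1, nrow(grid) >= 1)
  grid <- tibble::as_tibble(grid)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(gi) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      cfg <- config
      proto <- protocol
      g <- grid[gi, ]
      has <- function(col) col %in% names(g)
      if (has("nu")) cfg$nu <- g$nu
      if (has("rho")) cfg$rho <- g$rho
      if (has("inverted_fraction")) {
        proto$inverted_fraction <- g$inverted_fraction
      }
      if (has("gabaa_duration_days")) {
        proto$gabaa_duration_days <- g$gabaa_duration_days
        proto$t_f <- proto$t_i + g$gabaa_duration_days
      }
      if (has("frozen_groups")) {
        proto$frozen_groups <- unlist(g$frozen_groups)
      }
      sd <- derive_seed(base_seed, gi, r)
      res <- run_experiment(cfg, proto, seed = sd, engine = engine)
      chg <- connectivity_change(res)
      chg_row <- stats::setNames(as.list(chg$change),
                                 paste0("chg_", chg$group))
      lat <- event_latency(res)
      dplyr::bind_cols(
        g, tibble::tibble(rep = r, seed = sd,
                          n_events = sum(res$events$spontaneous),
                          latency_days = lat$latency_days,
                          censored = lat$censored),
        tibble::as_tibble(chg_row)
      )
    })
  })
  rows
}
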