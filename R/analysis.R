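#' Detect epileptiform events in a population activity trace
#'
#' An event is a maximal period in which the mean granule-cell activity
#' exceeds `threshold` for at least `min_steps` consecutive morphogenetic
#' steps. Events overlapping the stimulus window are the stimulus-driven
#' status epilepticus episode and are flagged non-spontaneous; the
#' spontaneous count is restricted to the counting window (100 days after
#' stimulus onset by default).
#'
#' @param x A `dg_result`, or a data frame with columns `time_days` and
#'   `s_gc` sampled once per morphogenetic step.
#' @param threshold Activity threshold (defaults to the HIGH boundary of
#'   the rest band, 0.25).
#' @param min_steps Minimum duration in morphogenetic steps. Ictal
#'   episodes are terminated by the non-synaptic inhibitory process after
#'   roughly 40 minutes, i.e. within a single 54-minute morphogenetic step,
#'   so the default is 1.
#' @param stim_window Length-2 numeric `(start, end)` in days, or `NULL`.
#'   Taken from the protocol when `x` is a `dg_result`.
#' @param count_window Length-2 numeric window (days) within which
#'   spontaneous events are counted; defaults to 100 days from stimulus
#'   onset (or the whole trace when there is no stimulus).
#' @return Tibble with one row per event: `onset_days`, `offset_days`,
#'   `peak_s`, `spontaneous`.
#' @export
detect_events <- function(x, threshold = 0.25, min_steps = 1,
                          stim_window = NULL, count_window = NULL) {
  if (inherits(x, "dg_result")) {
    trace <- x$steps
    p <- x$protocol
    if (is.null(stim_window) && p$alpha != 0) {
      stim_window <- c(p$stim_start,
                       p$stim_start + p$stim_duration_min / 1440)
    }
    if (is.null(count_window)) {
      origin <- if (p$alpha != 0) p$stim_start else 0
      count_window <- c(origin, origin + 100)
    }
  } else {
    trace <- x
  }
  if (is.null(trace) || nrow(trace) == 0) {
    stop("empty activity trace", call. = FALSE)
  }
  tv <- trace$time_days
  sv <- trace$s_gc
  step_days <- if (nrow(trace) > 1) stats::median(diff(tv)) else 0

  above <- sv > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_steps
  ev <- tibble::tibble(
    onset_days = tv[starts[keep]] - step_days,  # activity rose within the
    offset_days = tv[ends[keep]],               # step ending at onset time
    peak_s = purrr::map2_dbl(starts[keep], ends[keep],
                             ~ max(sv[.x:.y]))
  )
  ev$onset_days <- pmax(ev$onset_days, 0)
  ev$spontaneous <- rep(TRUE, nrow(ev))
  if (!is.null(stim_window) && nrow(ev) > 0) {
    overlap <- ev$onset_days <= stim_window[2] &
      ev$offset_days >= stim_window[1]
    ev$spontaneous <- !overlap
  }
  if (!is.null(count_window) && nrow(ev) > 0) {
    inside <- ev$onset_days >= count_window[1] &
      ev$onset_days <= count_window[2]
    ev$spontaneous <- ev$spontaneous & inside
  }
  ev
}

#' Ictal episodes by the NSE/NSI crossing rule
#'
#' An ictal episode starts when the population-mean non-synaptic excitatory
#' effect exceeds the inhibitory effect (`NSE > NSI`) and ends when NSI
#' overtakes NSE. Measured on the iteration-resolution traces, so episode
#' durations (tens of minutes) are resolved well below the morphogenetic
#' step length.
#'
#' @param result A `dg_result`.
#' @param tol Ignition floor: NSE must also exceed `tol` (guards the
#'   all-zero rest state).
#' @return Tibble with `onset_days`, `offset_days`, `duration_min`.
#' @export
ns_episodes <- function(result, tol = 1e-6) {
  ge <- result$config$ns$g_e
  gi <- result$config$ns$g_i
  up <- ge * result$nse_iter > gi * result$nsi_iter &
    result$nse_iter > tol
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  dt <- result$config$dt_iter
  tibble::tibble(
    onset_days = (starts[keep] - 1) * dt / 1440,
    offset_days = ends[keep] * dt / 1440,
    duration_min = (ends[keep] - starts[keep] + 1) * dt
  )
}

#' Latency to the first spontaneous epileptiform event
#'
#' Onset of the first spontaneous event minus the reference time. The
#' default reference is the end of the stimulus-driven SE episode (the end
#' of the stimulus when no episode was detected); `"stim_onset"` measures
#' from stimulus onset instead. Runs without any spontaneous event are
#' censored (`latency_days = NA`).
#'
#' @param result A `dg_result`.
#' @param reference Optional explicit reference time, days; overrides the
#'   protocol's `latency_reference` setting.
#' @return Tibble with `latency_days`, `censored`, `reference_days`.
#' @export
event_latency <- function(result, reference = NULL) {
  p <- result$protocol
  ev <- result$events
  if (is.null(reference)) {
    if (p$latency_reference == "stim_onset" || p$alpha == 0) {
      reference <- p$stim_start
    } else {
      se <- ev[!ev$spontaneous, , drop = FALSE]
      reference <- if (nrow(se) > 0) se$offset_days[1] else
        p$stim_start + p$stim_duration_min / 1440
    }
  }
  sp <- ev[ev$spontaneous & ev$onset_days >= reference, , drop = FALSE]
  if (nrow(sp) == 0) {
    tibble::tibble(latency_days = NA_real_, censored = TRUE,
                   reference_days = reference)
  } else {
    tibble::tibble(latency_days = sp$onset_days[1] - reference,
                   censored = FALSE, reference_days = reference)
  }
}

#' Per-group connectivity change at 64 days post-SE
#'
#' For Groups II-IX the change is the percent difference of the group mean
#' connectivity relative to the pre-stimulus baseline:
#' `100 * (mean64 - mean0) / mean0`. Group I starts at exactly zero, so the
#' relative formula is undefined; its change is reported as the absolute
#' group mean at 64 days in units of the network-wide baseline mean
#' connectivity, and labelled with `metric = "rel_network_baseline"`.
#'
#' @param x A `dg_result`, or a connectivity snapshot matrix (then
#'   `C_baseline` and `gmap` must be given).
#' @param C_baseline Baseline snapshot (matrix) when `x` is a matrix.
#' @param gmap Group map when `x` is a matrix.
#' @return Tibble with `group`, `change`, `metric`.
#' @export
connectivity_change <- function(x, C_baseline = NULL, gmap = NULL) {
  if (inherits(x, "dg_result")) {
    C64 <- x$C_post64
    C0 <- x$C_baseline
    gmap <- connectivity_groups(x$config)
  } else {
    C64 <- x
    C0 <- C_baseline
  }
  if (!all(dim(C64) == dim(C0))) {
    stop("snapshot shape mismatch", call. = FALSE)
  }
  labels <- attr(gmap, "labels")
  m64 <- group_mean_connectivity(C64, gmap)$mean_c
  m0 <- group_mean_connectivity(C0, gmap)$mean_c
  net0 <- mean(C0[!is.na(gmap)])
  change <- ifelse(m0 > 0, 100 * (m64 - m0) / m0, m64 / net0)
  tibble::tibble(group = factor(labels, levels = labels),
                 change = change,
                 metric = ifelse(m0 > 0, "pct_vs_baseline",
                                 "rel_network_baseline"))
}

#' Replicate summary with ANOVA and Dunnett comparisons
#'
#' Condition means and standard errors (`SEM = sd / sqrt(n)`), a one-way
#' ANOVA across conditions, and Dunnett many-to-one comparisons against the
#' control condition at `alpha = 0.05` (via [multcomp::glht()]).
#'
#' @param data Data frame of replicate-level values.
#' @param response Name of the response column (string).
#' @param condition Name of the condition column (string).
#' @param control Control condition label (compared against by Dunnett);
#'   `NULL` uses the first level.
#' @param alpha Significance level for the flags.
#' @return Tibble with one row per condition: `mean`, `sem`, `n`,
#'   `p_dunnett` (NA for the control row), `significant`; attributes
#'   `anova_p` (one-way ANOVA p-value) carry the omnibus test.
#' @export
summarize_replicates <- function(data, response, condition,
                                 control = NULL, alpha = 0.05) {
  y <- data[[response]]
  g <- factor(data[[condition]])
  if (!is.null(control)) {
    if (!control %in% levels(g)) {
      stop("control level not found in condition column", call. = FALSE)
    }
    g <- stats::relevel(g, ref = as.character(control))
  }
  ok <- !is.na(y)
  y <- y[ok]; g <- droplevels(g[ok])
  out <- tibble::tibble(
    condition = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(y, g, mean)),
    sem = as.numeric(tapply(y, g, function(v) {
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    }))
  )
  anova_p <- NA_real_
  out$p_dunnett <- NA_real_
  if (nlevels(g) >= 2 && all(table(g) >= 2) && stats::var(y) > 0) {
    fit <- stats::aov(y ~ g)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    dn <- try(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")),
              silent = TRUE)
    if (!inherits(dn, "try-error")) {
      tst <- summary(dn)$test
      # comparison names are "level - control"
      lev <- sub(" - .*$", "", names(tst$coefficients))
      out$p_dunnett[match(lev, out$condition)] <- as.numeric(tst$pvalues)
    }
  }
  out$significant <- !is.na(out$p_dunnett) & out$p_dunnett < alpha
  attr(out, "anova_p") <- anova_p
  out
}

#' Write the result bundle of one run to delimited files
#'
#' Writes `steps.csv`, `groups.csv`, `events.csv`, optionally
#' `activity.csv` (per-neuron), and a `manifest.json` recording the seed,
#' protocol, key network parameters and a configuration hash.
#'
#' @param result A `dg_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$steps, file.path(dir, "steps.csv"),
                   row.names = FALSE)
  utils::write.csv(result$groups, file.path(dir, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(result$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(result$activity)) {
    utils::write.csv(result$activity, file.path(dir, "activity.csv"),
                     row.names = FALSE)
  }
  cfg <- result$config
  manifest <- list(
    seed = result$seed,
    engine = result$engine,
    config_hash = rlang::hash(cfg),
    network = list(n_gc = cfg$n_gc, n_mc = cfg$n_mc, n_in_a = cfg$n_in_a,
                   n_in_b = cfg$n_in_b, nu = cfg$nu, rho = cfg$rho,
                   phi_bar = cfg$phi_bar),
    protocol = unclass(result$protocol)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a sweep table to CSV
#'
#' @param sweep Tibble from [run_sweep()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_sweep <- function(sweep, path) {
  sw <- sweep
  if ("frozen_groups" %in% names(sw)) {
    sw$frozen_groups <- purrr::map_chr(sw$frozen_groups,
                                       ~ paste(.x, collapse = "+"))
  }
  utils::write.csv(sw, path, row.names = FALSE)
  invisible(path)
}

#' Smallest inversion fraction with duration-dependent epileptogenesis
#'
#' For each inverted fraction in a sweep over fraction x excitatory-GABAa
#' duration, regresses the spontaneous-event count on duration and the
#' latency on duration (censored latencies imputed at the counting-window
#' length). A fraction qualifies when the occurrence slope is positive and
#' significant at `alpha` and the latency slope is non-positive. The
#' reported threshold is the largest grid fraction that does not itself
#' qualify while every larger fraction does — the fraction beyond which
#' increasing the excitatory-GABAa duration measurably intensifies
#' epileptogenesis. If every fraction qualifies the smallest grid value is
#' returned (the threshold lies at or below the grid).
#'
#' @param sweep Tibble from [run_sweep()] with columns `inverted_fraction`,
#'   `gabaa_duration_days`, `n_events`, `latency_days`.
#' @param alpha Significance level for the occurrence regression.
#' @param censor_days Imputed latency for runs without spontaneous events.
#' @return Smallest qualifying fraction in percent (`NA` if none).
#' @export
duration_sensitivity_threshold <- function(sweep, alpha = 0.05,
                                           censor_days = 100) {
  fr <- sort(unique(sweep$inverted_fraction))
  qualifies <- vapply(fr, function(f) {
    d <- sweep[sweep$inverted_fraction == f, ]
    if (length(unique(d$gabaa_duration_days)) < 2) return(FALSE)
    occ <- stats::lm(n_events ~ gabaa_duration_days, data = d)
    co <- summary(occ)$coefficients
    if (nrow(co) < 2 || is.na(co[2, 4])) return(FALSE)
    occ_ok <- co[2, 1] > 0 && co[2, 4] < alpha
    lat <- ifelse(is.na(d$latency_days), censor_days, d$latency_days)
    lat_slope <- stats::coef(stats::lm(lat ~ d$gabaa_duration_days))[2]
    occ_ok && lat_slope <= 0
  }, logical(1))
  if (!any(qualifies)) return(NA_real_)
  if (all(qualifies)) return(100 * fr[1])
  # largest fraction below an unbroken qualifying tail
  k <- max(which(!qualifies))
  if (k == length(fr)) return(NA_real_)  # top fraction fails: no threshold
  100 * fr[k]
}

#' Excitatory-GABAa duration beyond which outcomes plateau
#'
#' Given a sweep over duration at fixed fraction, finds for each metric
#' (spontaneous-event count and each per-group 64-day connectivity change)
#' the smallest duration after which every adjacent-duration difference of
#' means lies within the combined replicate SEM, and returns the largest
#' such onset so that all metrics have plateaued.
#'
#' @param sweep Tibble from [run_sweep()] with `gabaa_duration_days`,
#'   `n_events` and the `chg_*` columns.
#' @param sem_mult Multiplier on the combined SEM used as the equivalence
#'   band. Adjacent-mean differences have standard deviation equal to one
#'   combined SEM under the null, so the default band of 3 keeps the
#'   false-non-plateau rate low while still flagging real dose effects,
#'   which are an order of magnitude larger.
#' @return Plateau-onset duration in days.
#' @export
saturation_duration <- function(sweep, sem_mult = 3) {
  durs <- sort(unique(sweep$gabaa_duration_days))
  metrics <- c("n_events", grep("^chg_", names(sweep), value = TRUE))
  onset_of <- function(values) {
    m <- tapply(values, sweep$gabaa_duration_days, mean)[as.character(durs)]
    se <- tapply(values, sweep$gabaa_duration_days, function(v) {
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else 0
    })[as.character(durs)]
    flat <- vapply(seq_len(length(durs) - 1), function(j) {
      abs(m[j + 1] - m[j]) <= sem_mult * sqrt(se[j]^2 + se[j + 1]^2)
    }, logical(1))
    for (k in seq_along(flat)) {
      if (all(flat[k:length(flat)])) return(durs[k])
    }
    durs[length(durs)]
  }
  max(vapply(metrics, function(mt) onset_of(sweep[[mt]]), numeric(1)))
}
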