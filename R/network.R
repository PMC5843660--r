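#' Initialise the connectivity matrix
#'
#' Draws the initial synaptic connectivity: granule-to-granule synapses
#' (Group I) start at zero — mossy fibres do not contact other granule
#' cells in the healthy dentate gyrus — and every other group is drawn
#' i.i.d. Normal(1.0, 0.2), truncated at zero. The diagonal is zero (no
#' self-synapses). Uses the current RNG state, so results are reproducible
#' under [set.seed()].
#'
#' @param config A `dg_config`.
#' @return An `n x n` nonnegative matrix `C`; `C[i, j]` is the connectivity
#'   from presynaptic `j` to postsynaptic `i`.
#' @export
#' @examples
#' set.seed(1)
#' C <- init_connectivity(network_config(n_gc = 10))
init_connectivity <- function(config) {
  n <- config$n
  C <- matrix(pmax(stats::rnorm(n * n, mean = 1.0, sd = 0.2), 0), n, n)
  g <- connectivity_groups(config)
  C[!is.na(g) & g == 1L] <- 0
  diag(C) <- 0
  C
}

#' Membrane potential of every neuron
#'
#' Linear integration of presynaptic firing:
#' `vm_i = sum_j W(i,j) c_ij z_j + ns_effect_i + alpha_i`, where `W(i,j)`
#' is the signed group weight except for (inverted GC, IN_A) pairs, whose
#' weight is supplied by `gabaa_w` (the time-varying excitatory-GABAa
#' weight).
#'
#' @param z Integer/logical firing vector (length `n`).
#' @param C Connectivity matrix.
#' @param config A `dg_config`.
#' @param gabaa_w Either `NULL` (no inversion anywhere) or a numeric scalar:
#'   the signed weight that replaces `-phi_bar` on IN_A -> inverted-GC
#'   pairs.
#' @param inverted Integer indices of inverted granule cells (empty for
#'   none).
#' @param ns_effect Per-neuron non-synaptic contribution (0 for
#'   interneurons), default all zero.
#' @param alpha Per-neuron stimulus drive (scalar recycled), default 0.
#' @return Numeric vector `vm` of length `n`.
#' @export
membrane_potential <- function(z, C, config, gabaa_w = NULL,
                               inverted = integer(0),
                               ns_effect = 0, alpha = 0) {
  n <- config$n
  if (length(z) != n || !all(dim(C) == n)) {
    stop("dimension mismatch between state and C", call. = FALSE)
  }
  W <- base_weight_matrix(config)
  if (!is.null(gabaa_w) && length(inverted) > 0) {
    W[inverted, config$classes == "IN_A"] <- gabaa_w
  }
  as.numeric((W * C) %*% as.numeric(z)) +
    rep_len(ns_effect, n) + rep_len(alpha, n)
}

#' Firing probability from membrane potential
#'
#' Logistic sigmoid `prob_i = 1 / (1 + exp(-(vm_i - theta_i) / kappa))`
#' with per-class half-activation thresholds `theta` (calibrated so the
#' unstimulated network rests at `p_rest`) and common slope `kappa`.
#'
#' @param vm Membrane-potential vector.
#' @param config A `dg_config`.
#' @param theta Optional per-neuron threshold vector; defaults to the
#'   class-level calibrated thresholds. [run_experiment()] passes the
#'   per-neuron thresholds calibrated against the realized connectivity
#'   draw (see [calibrate_network_thresholds()]).
#' @return Probability vector in (0, 1).
#' @export
firing_probability <- function(vm, config, theta = theta_vector(config)) {
  stats::plogis((vm - theta) / offer_vector(config$kappa, config))
}

#' Per-neuron thresholds calibrated to a connectivity draw
#'
#' Sets each neuron's half-activation threshold so that, with every neuron
#' firing at the resting rate and the realized initial connectivity, its
#' expected membrane potential maps to firing probability exactly
#' `p_rest`. This intrinsic-excitability calibration removes the
#' neuron-to-neuron offsets induced by the Normal(1, 0.2) connectivity
#' draw, anchoring the whole network at the midpoint of the resting band.
#'
#' @param C Initial connectivity matrix.
#' @param config A `dg_config`.
#' @return Numeric threshold vector of length `n`.
#' @export
calibrate_network_thresholds <- function(C, config) {
  W <- base_weight_matrix(config)
  p0 <- config$p_rest
  p0 * rowSums(W * C) +
    offer_vector(config$kappa, config) * log((1 - p0) / p0)
}

#' Sample the firing vector
#'
#' `z_i = 1` iff `u_i < prob_i`, with `u_i ~ Uniform(0, 1)` drawn from the
#' current RNG state; independent across neurons and iterations.
#'
#' @param prob Probability vector in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
sample_firing <- function(prob) {
  if (any(prob < 0 | prob > 1)) stop("prob must lie in [0, 1]", call. = FALSE)
  as.integer(stats::runif(length(prob)) < prob)
}

#' Activity level over one morphogenetic step
#'
#' The activity level `s_i` is the mean firing probability over exactly one
#' completed morphogenetic step (`iters_per_morph` iterations); it is
#' recomputed once per step and held constant in between.
#'
#' @param prob_history Matrix with `iters_per_morph` rows (iterations) and
#'   `n` columns (neurons).
#' @param config A `dg_config`.
#' @return Numeric vector `s` of length `n`.
#' @export
update_activity <- function(prob_history, config) {
  if (nrow(prob_history) != config$iters_per_morph) {
    stop(sprintf("activity window must hold exactly %d iterations, got %d",
                 config$iters_per_morph, nrow(prob_history)), call. = FALSE)
  }
  colMeans(prob_history)
}

#' Classify activity levels
#'
#' `LOW` if `s < rest_lo`, `HIGH` if `s > rest_hi`, otherwise `REST`
#' (both boundaries inclusive to REST, matching the strict inequalities of
#' the low/high definitions).
#'
#' @param s Activity vector in `[0, 1]`.
#' @param config A `dg_config`.
#' @return Factor with levels `LOW`, `REST`, `HIGH`.
#' @export
classify_activity <- function(s, config) {
  stopifnot(all(s >= 0 & s <= 1))
  out <- ifelse(s < config$rest_lo, "LOW",
                ifelse(s > config$rest_hi, "HIGH", "REST"))
  factor(out, levels = c("LOW", "REST", "HIGH"))
}

#' Non-synaptic contribution to the membrane potential
#'
#' `g_e * nse - g_i * nsi` for granule and mossy cells, 0 for interneurons.
#'
#' @param nse,nsi Nonnegative per-neuron non-synaptic state vectors.
#' @param config A `dg_config`.
#' @return Numeric vector of length `n`.
#' @export
ns_effect <- function(nse, nsi, config) {
  out <- config$ns$g_e * nse - config$ns$g_i * nsi
  out[!(config$classes %in% c("GC", "MC"))] <- 0
  out
}

#' Advance the non-synaptic state by one iteration
#'
#' Euler step of the NSE/NSI integrator pair (see [ns_params()]) at
#' `dt_iter`, clipped at zero; interneurons stay identically zero.
#'
#' @param nse,nsi Current state vectors.
#' @param s Current activity vector (held constant between morphogenetic
#'   steps).
#' @param config A `dg_config`.
#' @return List with updated `nse` and `nsi`.
#' @export
update_nonsynaptic <- function(nse, nsi, s, config) {
  p <- config$ns
  dt <- config$dt_iter
  active <- (nse > 0) | (s > config$L)
  d_nse <- p$a_e * pmax(s - config$L, 0) + p$b_e * nse * active -
    nse / p$tau_e
  d_nsi <- p$a_i * nse - nsi / p$tau_i
  nse2 <- pmax(nse + dt * d_nse, 0)
  nsi2 <- pmax(nsi + dt * d_nsi, 0)
  cellular <- config$classes %in% c("GC", "MC")
  nse2[!cellular] <- 0
  nsi2[!cellular] <- 0
  list(nse = nse2, nsi = nsi2)
}
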