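#' Network configuration for the dentate gyrus model
#'
#' Builds the full parameter set of the stochastic binary-neuron network:
#' population sizes, signed per-group synaptic weights, firing-function
#' parameters, the two timescales (iteration and morphogenetic step), the
#' rewiring rates of compensation theory (`nu`) and of the Hebbian /
#' anti-Hebbian rules (`rho`), and the non-synaptic (NSE/NSI) process
#' parameters. Per-class firing thresholds are calibrated on construction so
#' the unstimulated network rests at activity `p_rest`, the midpoint of the
#' resting band.
#'
#' The network holds four cell classes: granule cells (GC, excitatory),
#' mossy cells (MC, excitatory), GABAa-type interneurons (IN_A, inhibitory,
#' the class whose synapses onto granule cells can transiently invert to
#' excitatory) and GABAb-type interneurons (IN_B, inhibitory). The nine
#' connectivity groups are indexed by (presynaptic, postsynaptic) class:
#' I GC->GC, II GC->MC, III GC->IN, IV MC->GC, V MC->MC, VI MC->IN,
#' VII IN->GC, VIII IN->MC, IX IN->IN.
#'
#' @param n_gc,n_mc,n_in_a,n_in_b Population sizes (granule cells, mossy
#'   cells, GABAa-type and GABAb-type interneurons).
#' @param nu Compensation-theory rate, in `[0, 0.1]`.
#' @param rho Hebbian/anti-Hebbian rate, in `[0, 0.5]`.
#' @param phi_bar Magnitude of the baseline GABAa inhibitory weight (> 0).
#'   The IN_A -> GC weight is `-phi_bar`; the excitatory-GABAa protocol
#'   replaces it by `phi(t) - phi_bar` for inverted cells.
#' @param w_group Named numeric vector of signed weights for groups
#'   `I`..`IX`. Groups I-VI must be positive (excitatory), VII-IX negative
#'   (inhibitory). `VII` is used for IN_B -> GC; IN_A -> GC always uses
#'   `-phi_bar`.
#' @param kappa Slope of the logistic firing function (> 0), per class
#'   (`c(GC =, MC =, IN =)`, scalar recycled).
#' @param vm_smooth Per-class membrane integration weight in `(0, 1]`: the
#'   membrane potential used by the firing function is an exponential
#'   moving average `vm <- (1 - w) vm + w vm_instantaneous`. `1` is the
#'   memoryless binary-neuron limit (granule and mossy cells).
#'   Interneurons integrate the whole granule-cell population, whose
#'   iteration-scale firing noise is large; a slower membrane (default
#'   0.2) suppresses that noise so the interneurons rest inside the
#'   activity band, while their response to ictal episodes (which last
#'   ~100 iterations) is essentially unchanged.
#' @param p_rest Target resting firing probability (midpoint of the rest
#'   band).
#' @param rest_lo,rest_hi Activity band: `s < rest_lo` is LOW,
#'   `s > rest_hi` is HIGH, otherwise REST (boundaries inclusive to REST).
#' @param L Actuation threshold of the non-synaptic mechanisms on activity.
#' @param dt_iter Duration of one iteration, minutes.
#' @param iters_per_morph Iterations per morphogenetic step.
#' @param eta Hebbian per-coincidence gain (per iteration, multiplicative
#'   on existing connectivity).
#' @param eta_anti Anti-Hebbian gain; default `eta * p_rest / (1 - p_rest)`
#'   so the two rules balance exactly at the resting firing rate.
#' @param k_offer_exc,k_offer_inh,k_offer_pre Element-offer gains of
#'   compensation theory: free elements created per morphogenetic step per
#'   unit activity deviation (scaled by `nu`). Each is a named per-class
#'   vector `c(GC =, MC =, IN =)` (scalars are recycled): granule cells
#'   sprout readily (mossy-fibre sprouting substrate), mossy cells offer
#'   few elements (their connections are vulnerable and net-retract), and
#'   interneurons have a high presynaptic offer rate (GABAergic
#'   sprouting).
#' @param ct_gain Gain on the activity deviation in all compensation
#'   rates: effective deviation = `ct_gain * (s - band edge)`. Sets how
#'   strongly homeostasis reacts near the band edge relative to the
#'   Hebbian drift; calibrated so chronic mild hyperactivity is pruned
#'   back into the band and epileptiform activity stays episodic.
#' @param ct_margin Actuation margin of compensation theory beyond the
#'   rest band: deviations are measured from `rest_hi + ct_margin` /
#'   `rest_lo - ct_margin`, so stochastic band crossings at rest (which
#'   scale with the firing noise) trigger no rewiring while genuine ictal
#'   or silence deviations (an order of magnitude larger) are barely
#'   affected.
#' @param free_decay Per-morphogenetic-step decay fraction of all free
#'   element pools (elements retract if they fail to bind); gives net
#'   synapse removal under sustained high activity instead of pure churn.
#' @param hebb_on_inhibitory Apply the Hebbian/anti-Hebbian rules to
#'   synapses whose presynaptic neuron is an interneuron (Groups VII-IX)?
#'   Default `FALSE`: Hebbian plasticity is treated as a property of the
#'   excitatory (glutamatergic) synapses (Groups I-VI); inhibitory
#'   connectivity changes are then governed by compensation theory alone.
#' @param prune_exc,prune_inh,prune_out Relative rates of the three
#'   compensation removal terms: dismantling of excitatory inputs of HIGH
#'   neurons, removal of inhibitory inputs of LOW neurons, and removal of
#'   the output synapses of LOW neurons. `prune_inh` is per postsynaptic
#'   class (sprouted GABAergic terminals on granule cells and interneurons
#'   are durable; inhibition onto mossy cells shares their synaptic
#'   vulnerability), and interneuron axonal withdrawal uses the
#'   interneuron entry. `prune_out` is per-class
#'   (`c(GC =, MC =, IN =)`, scalar recycled): sprouted mossy fibres are
#'   durable (small GC rate) while mossy-cell axons are vulnerable (large
#'   MC rate); interneuron outputs always use the `prune_inh` stability
#'   scale. These are the per-state magnitudes of the element-pool
#'   bookkeeping, calibrated against the directional rewiring pattern of
#'   the epileptogenesis experiments.
#' @param ns Non-synaptic process parameters, see [ns_params()].
#' @param theta Optional per-class firing thresholds (named vector with
#'   entries `GC`, `MC`, `IN_A`, `IN_B`); calibrated automatically when
#'   `NULL`.
#'
#' @return An object of class `dg_config` (a list), with derived fields:
#'   `n` (total neurons), `classes` (per-neuron class factor), `theta`
#'   (per-class calibrated thresholds).
#' @export
#' @examples
#' cfg <- network_config(n_gc = 20)
#' cfg$n
#' cfg$theta
network_config <- function(n_gc = 100, n_mc = 3, n_in_a = 2, n_in_b = 1,
                           nu = 0.1, rho = 0.3,
                           phi_bar = 0.4,
                           w_group = c(I = 0.5, II = 0.01, III = 0.15,
                                       IV = 0.4, V = 0.15, VI = 0.15,
                                       VII = -0.4, VIII = -0.25, IX = -0.25),
                           kappa = c(GC = 1, MC = 1, IN = 1.2),
                           vm_smooth = c(GC = 0.2, MC = 0.2, IN = 0.2),
                           p_rest = 0.2,
                           rest_lo = 0.15, rest_hi = 0.25, L = 0.32,
                           dt_iter = 0.36, iters_per_morph = 150,
                           eta = 2e-4,
                           eta_anti = eta * p_rest / (1 - p_rest),
                           k_offer_exc = c(GC = 16, MC = 0.5, IN = 8),
                           k_offer_inh = c(GC = 96, MC = 2, IN = 96),
                           k_offer_pre = c(GC = 16, MC = 1, IN = 256),
                           ct_gain = 1, ct_margin = 0, free_decay = 0.3,
                           hebb_on_inhibitory = FALSE,
                           prune_exc = 1.3,
                           prune_inh = c(GC = 0.02, MC = 1, IN = 0.02),
                           prune_out = c(GC = 0.3, MC = 2, IN = 1),
                           ns = ns_params(),
                           theta = NULL) {
  counts <- c(n_gc = n_gc, n_mc = n_mc, n_in_a = n_in_a, n_in_b = n_in_b)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all population counts must be integers >= 1", call. = FALSE)
  }
  if (nu < 0 || nu > 0.1) stop("nu must lie in [0, 0.1]", call. = FALSE)
  if (rho < 0 || rho > 0.5) stop("rho must lie in [0, 0.5]", call. = FALSE)
  if (phi_bar <= 0) stop("phi_bar must be > 0", call. = FALSE)
  kappa <- expand_class3(kappa, "kappa")
  if (any(kappa <= 0)) stop("kappa must be > 0", call. = FALSE)
  vm_smooth <- expand_class3(vm_smooth, "vm_smooth")
  if (any(vm_smooth <= 0 | vm_smooth > 1)) {
    stop("vm_smooth must lie in (0, 1]", call. = FALSE)
  }
  if (!(rest_lo < rest_hi)) stop("rest_lo must be < rest_hi", call. = FALSE)
  if (!(rest_lo < L)) stop("rest_lo must be < L", call. = FALSE)
  if (dt_iter <= 0) stop("dt_iter must be > 0", call. = FALSE)
  if (iters_per_morph < 1) stop("iters_per_morph must be >= 1", call. = FALSE)
  if (p_rest <= rest_lo || p_rest >= rest_hi) {
    stop("p_rest must lie strictly inside the rest band", call. = FALSE)
  }
  gn <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX")
  if (!all(gn %in% names(w_group))) {
    stop("w_group must name all nine groups I..IX", call. = FALSE)
  }
  w_group <- w_group[gn]
  if (any(w_group[1:6] <= 0) || any(w_group[7:9] >= 0)) {
    stop("w_group: groups I-VI must be positive, VII-IX negative",
         call. = FALSE)
  }
  stopifnot(inherits(ns, "dg_ns_params"))

  cfg <- list(
    n_gc = as.integer(n_gc), n_mc = as.integer(n_mc),
    n_in_a = as.integer(n_in_a), n_in_b = as.integer(n_in_b),
    n = as.integer(n_gc + n_mc + n_in_a + n_in_b),
    nu = nu, rho = rho, phi_bar = phi_bar, w_group = w_group,
    kappa = kappa, vm_smooth = vm_smooth, p_rest = p_rest,
    rest_lo = rest_lo, rest_hi = rest_hi, L = L,
    dt_iter = dt_iter, iters_per_morph = as.integer(iters_per_morph),
    eta = eta, eta_anti = eta_anti,
    k_offer_exc = expand_class3(k_offer_exc, "k_offer_exc"),
    k_offer_inh = expand_class3(k_offer_inh, "k_offer_inh"),
    k_offer_pre = expand_class3(k_offer_pre, "k_offer_pre"),
    ct_gain = ct_gain, ct_margin = ct_margin, free_decay = free_decay,
    hebb_on_inhibitory = isTRUE(hebb_on_inhibitory),
    prune_exc = prune_exc,
    prune_inh = expand_class3(prune_inh, "prune_inh"),
    prune_out = expand_class3(prune_out, "prune_out"),
    ns = ns
  )
  cfg$classes <- cell_classes(cfg)
  cfg$theta <- if (is.null(theta)) calibrate_thresholds(cfg) else {
    stopifnot(all(c("GC", "MC", "IN_A", "IN_B") %in% names(theta)))
    theta[c("GC", "MC", "IN_A", "IN_B")]
  }
  structure(cfg, class = "dg_config")
}

#' Non-synaptic (NSE/NSI) process parameters
#'
#' The slow non-synaptic excitatory (NSE) and inhibitory (NSI) processes are
#' a fast-excitation / slow-inhibition leaky-integrator pair per granule or
#' mossy cell, Euler-stepped at the iteration duration:
#' \deqn{dNSE/dt = a_e \max(s - L, 0) + b_e NSE \cdot 1[NSE > 0 \lor s > L] - NSE/\tau_e}
#' \deqn{dNSI/dt = a_i NSE - NSI/\tau_i}
#' NSE ignites under supra-threshold activity and self-amplifies; NSI
#' integrates NSE more slowly and outlasts it, terminating the episode and
#' producing post-ictal silence. Defaults are calibrated so the status
#' epilepticus stimulus yields an elevated-activity episode of about 40
#' minutes that self-terminates well before the stimulus ends, followed by
#' silence, with full relaxation to zero in under half a day. Episode
#' termination is guaranteed whenever `a_i > b_e + 1/tau_i` (NSI eventually
#' outgrows even free-running NSE).
#'
#' @param a_e Drive gain of NSE per unit supra-threshold activity (1/min).
#' @param b_e Self-amplification rate of NSE (1/min).
#' @param tau_e NSE decay time constant (min).
#' @param a_i NSI integration gain of NSE (1/min).
#' @param tau_i NSI decay time constant (min).
#' @param g_e,g_i Coupling of NSE and NSI onto the membrane potential
#'   (dimensionless); the non-synaptic contribution is
#'   `g_e * nse - g_i * nsi` for GC/MC and 0 for interneurons.
#' @return An object of class `dg_ns_params`.
#' @export
ns_params <- function(a_e = 1.0, b_e = 0.03, tau_e = 20,
                      a_i = 0.05, tau_i = 120, g_e = 1, g_i = 1) {
  if (tau_e <= 0 || tau_i <= 0) {
    stop("non-synaptic time constants must be positive", call. = FALSE)
  }
  if (a_e < 0 || a_i < 0 || b_e < 0 || g_e < 0 || g_i < 0) {
    stop("non-synaptic gains must be nonnegative", call. = FALSE)
  }
  structure(list(a_e = a_e, b_e = b_e, tau_e = tau_e,
                 a_i = a_i, tau_i = tau_i, g_e = g_e, g_i = g_i),
            class = "dg_ns_params")
}

# normalise a per-class (GC, MC, IN) offer-rate spec to a named triple
expand_class3 <- function(x, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(c(GC = unname(x), MC = unname(x), IN = unname(x)))
  }
  if (!all(c("GC", "MC", "IN") %in% names(x))) {
    stop(what, " must be a scalar or a named vector with GC, MC, IN",
         call. = FALSE)
  }
  if (any(x < 0)) stop(what, " rates must be nonnegative", call. = FALSE)
  c(GC = unname(x[["GC"]]), MC = unname(x[["MC"]]), IN = unname(x[["IN"]]))
}

#' Per-neuron offer-rate vector
#' @param k Named per-class triple (GC, MC, IN).
#' @param config A `dg_config`.
#' @return Numeric vector of length `n`.
#' @keywords internal
offer_vector <- function(k, config) {
  cl3 <- ifelse(config$classes == "GC", "GC",
                ifelse(config$classes == "MC", "MC", "IN"))
  unname(k[cl3])
}

#' Per-neuron cell classes
#'
#' Neurons are ordered GC (1..n_gc), MC, IN_A, IN_B.
#'
#' @param config A `dg_config` (only the counts are used, so a plain list
#'   with `n_gc`, `n_mc`, `n_in_a`, `n_in_b` also works).
#' @return Factor of length `n` with levels `GC`, `MC`, `IN_A`, `IN_B`.
#' @export
cell_classes <- function(config) {
  factor(rep(c("GC", "MC", "IN_A", "IN_B"),
             times = c(config$n_gc, config$n_mc, config$n_in_a,
                       config$n_in_b)),
         levels = c("GC", "MC", "IN_A", "IN_B"))
}

#' Static connectivity-group map
#'
#' Maps every (postsynaptic, presynaptic) pair to its connectivity group
#' I..IX by cell class; for grouping, both interneuron classes count as IN.
#' The diagonal (self-synapse) carries `NA`.
#'
#' @param config A `dg_config`.
#' @return An `n x n` integer matrix with entries 1..9 (`connectivity_groups(config)[i, j]` is
#'   the group of the synapse from presynaptic `j` to postsynaptic `i`) and
#'   `NA` on the diagonal. Attribute `labels` holds the Roman-numeral names.
#' @export
connectivity_groups <- function(config) {
  cl <- cell_classes(config)
  cat3 <- ifelse(cl == "GC", 1L, ifelse(cl == "MC", 2L, 3L))
  pre <- matrix(cat3, nrow = config$n, ncol = config$n, byrow = TRUE)
  post <- matrix(cat3, nrow = config$n, ncol = config$n)
  g <- (pre - 1L) * 3L + post
  diag(g) <- NA_integer_
  attr(g, "labels") <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                         "IX")
  g
}

#' Effective baseline weight matrix
#'
#' Signed per-pair weights before connectivity scaling: `w_group` by group,
#' except IN_A -> GC pairs which carry `-phi_bar` (the invertible GABAa
#' weight).
#'
#' @param config A `dg_config`.
#' @return An `n x n` numeric matrix (diagonal 0).
#' @keywords internal
base_weight_matrix <- function(config) {
  g <- connectivity_groups(config)
  w <- matrix(0, config$n, config$n)
  idx <- !is.na(g)
  w[idx] <- config$w_group[g[idx]]
  cl <- config$classes
  w[cl == "GC", cl == "IN_A"] <- -config$phi_bar
  diag(w) <- 0
  w
}

#' Calibrate per-class firing thresholds
#'
#' Sets the half-activation threshold of the logistic firing function per
#' cell class so that, at the baseline connectivity (mean 1 everywhere
#' except the empty GC->GC group) with every neuron firing at the resting
#' rate `p_rest`, the expected membrane potential maps to firing probability
#' exactly `p_rest`. This anchors the rest fixed point at the midpoint of
#' the resting band; the slope `kappa` then controls how tightly the
#' 150-iteration activity averages concentrate around it.
#'
#' @param config A `dg_config` (theta may be absent).
#' @return Named numeric vector of thresholds for `GC`, `MC`, `IN_A`,
#'   `IN_B`.
#' @export
calibrate_thresholds <- function(config) {
  w <- config$w_group
  p0 <- config$p_rest
  n_in <- config$n_in_a + config$n_in_b
  # expected resting drive per class at baseline connectivity c = 1
  # (Group I starts empty so GC->GC contributes nothing)
  e_gc <- p0 * (config$n_mc * w["IV"] +
                  config$n_in_a * (-config$phi_bar) +
                  config$n_in_b * w["VII"])
  e_mc <- p0 * (config$n_gc * w["II"] + (config$n_mc - 1) * w["V"] +
                  n_in * w["VIII"])
  e_in <- p0 * (config$n_gc * w["III"] + config$n_mc * w["VI"] +
                  (n_in - 1) * w["IX"])
  kap <- config$kappa
  l0 <- log((1 - p0) / p0)
  th <- c(GC = unname(e_gc) + kap[["GC"]] * l0,
          MC = unname(e_mc) + kap[["MC"]] * l0,
          IN_A = unname(e_in) + kap[["IN"]] * l0,
          IN_B = unname(e_in) + kap[["IN"]] * l0)
  th
}

#' Per-neuron threshold vector
#' @param config A `dg_config`.
#' @return Numeric vector of length `n`.
#' @keywords internal
theta_vector <- function(config) {
  unname(config$theta[as.character(config$classes)])
}

#' @export
print.dg_config <- function(x, ...) {
  cat("<dg_config> dentate gyrus network\n")
  cat(sprintf("  neurons: %d GC + %d MC + %d IN_A + %d IN_B = %d\n",
              x$n_gc, x$n_mc, x$n_in_a, x$n_in_b, x$n))
  cat(sprintf("  rates: nu = %g, rho = %g; phi_bar = %g\n",
              x$nu, x$rho, x$phi_bar))
  cat(sprintf("  timescales: %g min/iteration, %d iterations/morph step\n",
              x$dt_iter, x$iters_per_morph))
  cat(sprintf("  rest band: (%g, %g), NS threshold L = %g\n",
              x$rest_lo, x$rest_hi, x$L))
  invisible(x)
}

#' Read a network/protocol configuration from a YAML file
#'
#' Structured-text configuration mirroring [network_config()] and
#' [experiment_protocol()]: top-level sections `network`, `ns` and
#' `protocol`, each a mapping of argument names to values. Every field is
#' optional and defaults apply.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` (`dg_config`) and `protocol`
#'   (`dg_protocol`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  net_args <- raw$network %||% list()
  if (!is.null(raw$ns)) net_args$ns <- do.call(ns_params, raw$ns)
  if (!is.null(net_args$w_group)) {
    net_args$w_group <- unlist(net_args$w_group)
  }
  cfg <- do.call(network_config, net_args)
  proto <- do.call(experiment_protocol, raw$protocol %||% list())
  list(config = cfg, protocol = proto)
}
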