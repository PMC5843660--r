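#' Synaptic element pools
#'
#' The substrate of compensation theory: per neuron, counts of free
#' excitatory-postsynaptic, free inhibitory-postsynaptic and free
#' presynaptic elements. Bound element counts are derived from the
#' connectivity matrix at one element per unit connectivity
#' (`bound_exc_post_i = sum_j c_ij` over excitatory presynaptic `j`, etc.),
#' so connectivity bookkeeping can never drift from the pools.
#'
#' @param config A `dg_config`.
#' @return List of numeric vectors `free_exc_post`, `free_inh_post`,
#'   `free_pre`, all zero.
#' @export
new_element_pools <- function(config) {
  z <- numeric(config$n)
  list(free_exc_post = z, free_inh_post = z, free_pre = z)
}

#' Bound element counts derived from connectivity
#'
#' @param C Connectivity matrix.
#' @param config A `dg_config`.
#' @return List with `bound_exc_post`, `bound_inh_post` (row sums over
#'   excitatory / inhibitory presynaptic neurons) and `bound_pre` (column
#'   sums).
#' @export
bound_elements <- function(C, config) {
  exc <- config$classes %in% c("GC", "MC")
  list(bound_exc_post = as.numeric(C[, exc, drop = FALSE] %*% rep(1, sum(exc))),
       bound_inh_post = as.numeric(C[, !exc, drop = FALSE] %*% rep(1, sum(!exc))),
       bound_pre = colSums(C))
}

#' Frozen-pair mask from blocked connectivity groups
#'
#' @param frozen_groups Character vector of Roman-numeral group labels
#'   (subset of `I`..`IX`), possibly empty.
#' @param gmap Group map from [connectivity_groups()].
#' @return Logical matrix, `TRUE` where the pair belongs to a frozen group.
#' @export
frozen_mask <- function(frozen_groups, gmap) {
  labels <- attr(gmap, "labels")
  if (length(frozen_groups) == 0) {
    return(matrix(FALSE, nrow(gmap), ncol(gmap)))
  }
  bad <- setdiff(frozen_groups, labels)
  if (length(bad) > 0) {
    stop("unknown connectivity group label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ids <- match(frozen_groups, labels)
  m <- !is.na(gmap) & matrix(gmap %in% ids, nrow(gmap))
  m
}

#' Compensation-theory update
#'
#' Homeostatic element-pool dynamics, applied once per morphogenetic step
#' and scaled by `nu` and by the deviation of the activity from the rest
#' band. Per postsynaptic neuron:
#' \itemize{
#' \item REST: no change.
#' \item HIGH (`d = s - rest_hi`): a fraction `nu * d` of every excitatory
#'   input synapse is dismantled and its mass credited to
#'   `free_exc_post`; offers of free inhibitory-postsynaptic and free
#'   presynaptic elements grow by `nu * d * k_offer`.
#' \item LOW (`d = rest_lo - s`): `free_exc_post` offer grows by
#'   `nu * d * k_offer_exc`; a fraction `nu * d` of every inhibitory input
#'   synapse is removed (elements discarded); the free presynaptic offer
#'   decays by the factor `1 - nu * d`; a fraction `nu * d` of every output
#'   synapse is removed (bound presynaptic loss).
#' }
#' Removal is proportional to current connectivity within the affected row
#' or column. Frozen pairs are excluded from all connectivity changes and
#' from the associated element releases.
#'
#' @param C Connectivity matrix.
#' @param pools Element pools (see [new_element_pools()]).
#' @param s Activity vector.
#' @param config A `dg_config`.
#' @param frozen Logical matrix of frozen pairs, or `NULL`.
#' @return List with `dC` (the compensation-attributed connectivity change,
#'   to be applied with the other rules) and updated `pools`.
#' @export
compensation_update <- function(C, pools, s, config, frozen = NULL) {
  n <- config$n
  exc_pre <- config$classes %in% c("GC", "MC")
  d_high <- config$ct_gain * pmax(s - config$rest_hi - config$ct_margin, 0)
  d_low <- config$ct_gain * pmax(config$rest_lo - config$ct_margin - s, 0)
  r_high <- pmin(config$nu * d_high * config$prune_exc, 1)
  r_low_inh <- pmin(config$nu * d_low *
                      offer_vector(config$prune_inh, config), 1)
  r_low_out <- pmin(config$nu * d_low *
                      offer_vector(config$prune_out, config), 1)
  r_low <- pmin(config$nu * d_low, 1)

  # free elements retract if they fail to bind
  pools$free_exc_post <- pools$free_exc_post * (1 - config$free_decay)
  pools$free_inh_post <- pools$free_inh_post * (1 - config$free_decay)
  pools$free_pre <- pools$free_pre * (1 - config$free_decay)

  # HIGH: dismantle excitatory inputs, credit free_exc_post
  d1 <- -r_high * C
  d1[, !exc_pre] <- 0
  if (!is.null(frozen)) d1[frozen] <- 0
  released <- -rowSums(d1)

  # LOW: remove inhibitory inputs (no credit)
  d2 <- -r_low_inh * C
  d2[, exc_pre] <- 0
  if (!is.null(frozen)) d2[frozen] <- 0

  # LOW: prune outputs of the low neuron (columns); synapses from
  # interneurons share the inhibitory stability scale
  out_rate <- ifelse(exc_pre, r_low_out, r_low_inh)
  d3 <- -C * matrix(out_rate, n, n, byrow = TRUE)
  if (!is.null(frozen)) d3[frozen] <- 0

  pools$free_exc_post <- pools$free_exc_post + released +
    config$nu * d_low * offer_vector(config$k_offer_exc, config)
  pools$free_inh_post <- pools$free_inh_post +
    config$nu * d_high * offer_vector(config$k_offer_inh, config)
  pools$free_pre <- pools$free_pre * (1 - r_low) +
    config$nu * d_high * offer_vector(config$k_offer_pre, config)

  list(dC = d1 + d2 + d3, pools = pools)
}

#' Deterministic synapse formation from free element pools
#'
#' Free presynaptic elements of excitatory neurons pair with free
#' excitatory-postsynaptic elements; free presynaptic elements of
#' interneurons pair with free inhibitory-postsynaptic elements. Within
#' each market the total paired mass is `min(total pre offer, total post
#' offer)`, allocated across compatible (post `i`, pre `j`) pairs
#' proportionally to the offer product `free_post_i * free_pre_j`
#' (deterministic expectation form; no sampling). Self-pairs and frozen
#' pairs are excluded. Paired mass moves free -> bound on both sides
#' exactly, so formation is conservative. Granule-to-granule pairs are
#' allowed: this is the route by which abnormal mossy-fibre sprouting
#' emerges from the initially empty Group I block.
#'
#' @inheritParams compensation_update
#' @return List with `dC` (nonnegative formation matrix, compensation-rule
#'   attributed) and updated `pools`.
#' @export
form_synapses <- function(pools, config, frozen = NULL) {
  n <- config$n
  exc <- config$classes %in% c("GC", "MC")
  dC <- matrix(0, n, n)

  pair_market <- function(post_offer, pre_offer, pre_mask) {
    a <- ifelse(pre_mask, pre_offer, 0)
    b <- post_offer
    M <- min(sum(a), sum(b))
    if (M <= 0) return(NULL)
    O <- outer(b, a)
    diag(O) <- 0
    if (!is.null(frozen)) O[frozen] <- 0
    Z <- sum(O)
    if (Z <= 0) return(NULL)
    D <- M * O / Z
    # a single global scale keeps every pool nonnegative
    rs <- rowSums(D); cs <- colSums(D)
    ratios <- c(ifelse(rs > 0, b / rs, Inf), ifelse(cs > 0, a / cs, Inf))
    D * min(1, ratios)
  }

  D_exc <- pair_market(pools$free_exc_post, pools$free_pre, exc)
  if (!is.null(D_exc)) {
    pools$free_exc_post <- pools$free_exc_post - rowSums(D_exc)
    pools$free_pre <- pools$free_pre - colSums(D_exc)
    dC <- dC + D_exc
  }
  D_inh <- pair_market(pools$free_inh_post, pools$free_pre, !exc)
  if (!is.null(D_inh)) {
    pools$free_inh_post <- pools$free_inh_post - rowSums(D_inh)
    pools$free_pre <- pools$free_pre - colSums(D_inh)
    dC <- dC + D_inh
  }
  # numerical guard
  pools$free_exc_post <- pmax(pools$free_exc_post, 0)
  pools$free_inh_post <- pmax(pools$free_inh_post, 0)
  pools$free_pre <- pmax(pools$free_pre, 0)
  list(dC = dC, pools = pools)
}

#' Hebbian reinforcement
#'
#' When presynaptic `j` fired in the previous iteration and postsynaptic
#' `i` fires in the current one, existing synapses are reinforced
#' multiplicatively: `dc_ij = rho * eta * c_ij` per coincidence. Synapses
#' with `c_ij = 0` are not created (creation is compensation theory's job).
#'
#' @param z_prev,z_now 0/1 firing vectors of consecutive iterations.
#' @param C Connectivity matrix.
#' @param rho Hebbian rate.
#' @param eta Per-coincidence gain.
#' @return Nonnegative change matrix `dC`.
#' @export
hebbian_update <- function(z_prev, z_now, C, rho, eta) {
  rho * eta * C * outer(as.numeric(z_now), as.numeric(z_prev))
}

#' Anti-Hebbian depression
#'
#' When postsynaptic `i` fires without the presynaptic neuron `j` having
#' fired in the preceding iteration, the synapse is depressed:
#' `dc_ij = -rho * eta_anti * c_ij` per such event, floored so connectivity
#' never becomes negative.
#'
#' @inheritParams hebbian_update
#' @param eta_anti Per-event depression gain.
#' @return Nonpositive change matrix `dC`, bounded below by `-C`.
#' @export
anti_hebbian_update <- function(z_prev, z_now, C, rho, eta_anti) {
  d <- -rho * eta_anti * C * outer(as.numeric(z_now), 1 - as.numeric(z_prev))
  pmax(d, -C)
}

#' Per-group per-rule connectivity change rates
#'
#' Averages each rule-attributed change matrix over the (off-diagonal)
#' pairs of every connectivity group.
#'
#' @param dC_by_rule Named list of change matrices, e.g.
#'   `list(CT = ..., Hebb = ..., AntiHebb = ...)`.
#' @param gmap Group map from [connectivity_groups()].
#' @return A tibble with columns `group`, `rule`, `rate`.
#' @export
group_change_rates <- function(dC_by_rule, gmap) {
  labels <- attr(gmap, "labels")
  gvec <- as.vector(gmap)
  keep <- !is.na(gvec)
  out <- purrr::map_dfr(names(dC_by_rule), function(rule) {
    v <- as.vector(dC_by_rule[[rule]])[keep]
    means <- tapply(v, gvec[keep], mean)
    tibble::tibble(group = factor(labels[as.integer(names(means))],
                                  levels = labels),
                   rule = rule, rate = as.numeric(means))
  })
  out
}

#' Per-group mean connectivity
#'
#' @param C Connectivity matrix.
#' @param gmap Group map from [connectivity_groups()].
#' @return Tibble with columns `group`, `mean_c`.
#' @export
group_mean_connectivity <- function(C, gmap) {
  labels <- attr(gmap, "labels")
  gvec <- as.vector(gmap)
  keep <- !is.na(gvec)
  means <- tapply(as.vector(C)[keep], gvec[keep], mean)
  tibble::tibble(group = factor(labels[as.integer(names(means))],
                                levels = labels),
                 mean_c = as.numeric(means))
}

#' Blockage of connectivity changes for selected groups
#'
#' Zeroes the entries of a change matrix that fall in frozen groups; used
#' to emulate experimental withdrawal of the connectivity changes of
#' specific groups.
#'
#' @param dC Change matrix.
#' @param frozen_groups Character vector of group labels.
#' @param gmap Group map from [connectivity_groups()].
#' @return The change matrix with frozen-group entries set to zero.
#' @export
apply_blockage <- function(dC, frozen_groups, gmap) {
  dC[frozen_mask(frozen_groups, gmap)] <- 0
  dC
}
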