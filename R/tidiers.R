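#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' Returns one tibble, selectable by `what`: the per-step population
#' summary (`"steps"`), the per-group connectivity traces (`"groups"`),
#' detected events (`"events"`), the 64-day connectivity changes
#' (`"changes"`) or the per-neuron activity (`"activity"`, only when the
#' run recorded it).
#'
#' @param x A `dg_result`.
#' @param what One of `"steps"`, `"groups"`, `"events"`, `"changes"`,
#'   `"activity"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dg_result <- function(x, what = c("steps", "groups", "events",
                                       "changes", "activity"), ...) {
  what <- match.arg(what)
  switch(what,
         steps = x$steps,
         groups = x$groups,
         events = x$events,
         changes = connectivity_change(x),
         activity = {
           if (is.null(x$activity)) {
             stop("run_experiment(..., record_neurons = TRUE) to record ",
                  "per-neuron activity", call. = FALSE)
           }
           x$activity
         })
}

#' One-row summary of a simulation result
#'
#' @param x A `dg_result`.
#' @param ... Unused.
#' @return A one-row tibble with the replicate-level summary used by
#'   sweeps: number of spontaneous events, latency (NA if censored), the
#'   Group I connectivity at 64 days (abnormal mossy-fibre sprouting), and
#'   run identifiers.
#' @export
glance.dg_result <- function(x, ...) {
  lat <- event_latency(x)
  chg <- connectivity_change(x)
  tibble::tibble(
    seed = x$seed,
    nu = x$config$nu,
    rho = x$config$rho,
    inverted_fraction = x$protocol$inverted_fraction,
    gabaa_duration_days = x$protocol$gabaa_duration_days,
    n_events = sum(x$events$spontaneous),
    latency_days = lat$latency_days,
    censored = lat$censored,
    asmf_64d = chg$change[chg$group == "I"]
  )
}
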