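#' Tidy an evacuation timing table
#'
#' @param x An `evac_timing` object.
#' @param ... Unused.
#' @return A plain tibble, one row per recipient.
#' @exportS3Method generics::tidy
tidy.evac_timing <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "evac_timing")
  attr(out, "params") <- NULL
  attr(out, "arrival_factor") <- NULL
  as_tibble(out)
}

#' One-row summary of an evacuation timing table
#'
#' @param x An `evac_timing` object.
#' @param ... Unused.
#' @return A one-row tibble: recipient counts, delayed count and share
#'   (denominator = all recipients), margin range among defined margins, and
#'   the model parameters used.
#' @exportS3Method generics::glance
glance.evac_timing <- function(x, ...) {
  p <- attr(x, "params")
  m <- x$margin[!is.na(x$margin)]
  tibble(n_recipients = nrow(x),
         n_with_deadline = length(m),
         n_delayed = sum(x$delayed, na.rm = TRUE),
         pct_delayed = round_display(100 * sum(x$delayed, na.rm = TRUE) / nrow(x), 1),
         margin_min = if (length(m)) min(m) else NA_real_,
         margin_max = if (length(m)) max(m) else NA_real_,
         nurse_speed = p$nurse_speed, walk_speed = p$walk_speed,
         transfer_time = p$transfer_time)
}

#' Tidy a sensitivity analysis
#'
#' @param x An `evac_sensitivity` object.
#' @param ... Unused.
#' @return The long margins tibble (one row per recipient and run).
#' @exportS3Method generics::tidy
tidy.evac_sensitivity <- function(x, ...) x$margins

#' One-row summary of a sensitivity analysis
#'
#' @param x An `evac_sensitivity` object.
#' @param ... Unused.
#' @return A one-row tibble with the analysis type, grid size, and the range
#'   of delayed-escape counts across runs.
#' @exportS3Method generics::glance
glance.evac_sensitivity <- function(x, ...) {
  tibble(type = x$type,
         n_runs = nrow(x$summary),
         n_recipients = length(unique(x$margins$id)),
         n_delayed_min = min(x$summary$n_delayed),
         n_delayed_max = max(x$summary$n_delayed))
}
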