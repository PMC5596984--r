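#' Molecular clock calibration
#'
#' A calibration converts an uncorrected pairwise distance directly into a
#' divergence time: a rate \eqn{r} in percent uncorrected pairwise distance
#' per million years gives \eqn{t = p / r} Myr. Typical COI calibrations for
#' invertebrates span roughly 1.5 %/Myr (COI-specific) to 2.3 %/Myr (whole
#' mitochondrial genome, arthropods); both are the package defaults.
#'
#' The rate is a \emph{pairwise} rate — no factor of 2 for per-lineage rates
#' is applied — and no multiple-hit correction is made before division, so
#' estimates inherit the slight downward bias of uncorrected distances.
#'
#' @param rate Rate in percent uncorrected pairwise distance per Myr; > 0.
#' @param label Free-text label for reports.
#' @return A \code{clock_calibration} object.
#' @examples
#' clock_calibration(1.5, "COI, invertebrates")
#' @export
clock_calibration <- function(rate, label = paste0(rate, " %/Myr")) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate <= 0) {
    stop("input-error: calibration rate must be a single positive number",
         call. = FALSE)
  }
  structure(list(rate = rate, label = label), class = "clock_calibration")
}

#' Divergence time from an uncorrected p-distance
#'
#' \eqn{t = p / r}: divides a minimal uncorrected pairwise distance by a
#' pairwise rate calibration. With \eqn{p = 2.4\%} and \eqn{r = 1.5} \%/Myr
#' this gives 1.6 Myr.
#'
#' @param p Uncorrected p-distance, non-negative; its unit must be stated
#'   via \code{p_unit}.
#' @param calibration A [clock_calibration()] (or a bare positive rate in
#'   \%/Myr).
#' @param p_unit \code{"percent"} (default; \code{p = 2.4} means 2.4 \%) or
#'   \code{"fraction"} (\code{p = 0.024}).
#' @return Divergence time in Myr (numeric scalar).
#' @examples
#' divergence_time(2.4, clock_calibration(1.5))   # 1.6 Myr
#' divergence_time(0.024, 2.3, p_unit = "fraction")
#' @export
divergence_time <- function(p, calibration, p_unit = c("percent", "fraction")) {
  p_unit <- match.arg(p_unit)
  if (!inherits(calibration, "clock_calibration")) {
    calibration <- clock_calibration(calibration)
  }
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0) {
    stop("input-error: p must be a single non-negative number", call. = FALSE)
  }
  p_pct <- if (p_unit == "fraction") p * 100 else p
  p_pct / calibration$rate
}

#' Divergence-time interval under a pair of calibrations
#'
#' Computes the point estimate \eqn{t = p / r} under each of two
#' calibrations and returns the ordered interval: the faster rate gives the
#' younger bound, the slower rate the older. With \eqn{p = 2.4\%} and rates
#' 1.5 and 2.3 \%/Myr the rendered interval is 1.0–1.6 Myr.
#'
#' @param p Uncorrected p-distance (see \code{p_unit}).
#' @param calibrations A list of two [clock_calibration()] objects, or a
#'   numeric vector of two rates in \%/Myr. Default \code{c(1.5, 2.3)}.
#' @param p_unit As in [divergence_time()].
#' @return An object of class \code{divergence_interval}; see \code{tidy()}
#'   and \code{glance()} methods. Fields \code{t_low} (fastest rate),
#'   \code{t_high} (slowest rate), per-calibration estimates, and a rendered
#'   one-decimal (round-half-up) interval string.
#' @examples
#' divergence_interval(2.4)                      # 1.0-1.6 Myr
#' divergence_interval(2.0, c(1.5, 2.3))
#' @export
divergence_interval <- function(p, calibrations = c(1.5, 2.3),
                                p_unit = c("percent", "fraction")) {
  p_unit <- match.arg(p_unit)
  if (is.numeric(calibrations)) {
    calibrations <- lapply(calibrations, clock_calibration)
  }
  if (length(calibrations) != 2) {
    stop("input-error: exactly two calibrations are required", call. = FALSE)
  }
  est <- vapply(calibrations, function(cal) divergence_time(p, cal, p_unit),
                numeric(1))
  rates <- vapply(calibrations, `[[`, numeric(1), "rate")
  labels <- vapply(calibrations, `[[`, character(1), "label")
  ord <- order(est)  # fastest rate -> smallest t first
  rendered <- sprintf("%.1f-%.1f Myr",
                      round_half_up(min(est), 1), round_half_up(max(est), 1))
  structure(list(p_percent = if (p_unit == "fraction") p * 100 else p,
                 t_low = min(est), t_high = max(est),
                 estimates = tibble::tibble(label = labels[ord],
                                            rate = rates[ord],
                                            t = est[ord]),
                 rendered = rendered),
            class = "divergence_interval")
}

#' @export
print.divergence_interval <- function(x, ...) {
  cat(sprintf("Divergence time for p = %s %%: %s\n", format(x$p_percent),
              x$rendered))
  for (i in seq_len(nrow(x$estimates))) {
    cat(sprintf("  rate %.3g %%/Myr (%s): t = %.4f Myr\n",
                x$estimates$rate[i], x$estimates$label[i], x$estimates$t[i]))
  }
  invisible(x)
}

#' Tidy a divergence-time interval
#'
#' @param x A \code{divergence_interval}.
#' @param ... Unused.
#' @return A tibble with one row per calibration: \code{label}, \code{rate}
#'   (\%/Myr), \code{t} (Myr).
#' @method tidy divergence_interval
#' @export
tidy.divergence_interval <- function(x, ...) x$estimates

#' One-row summary of a divergence-time interval
#'
#' @param x A \code{divergence_interval}.
#' @param ... Unused.
#' @return A one-row tibble: \code{p_percent}, \code{t_low}, \code{t_high},
#'   \code{rendered}.
#' @method glance divergence_interval
#' @export
glance.divergence_interval <- function(x, ...) {
  tibble::tibble(p_percent = x$p_percent, t_low = x$t_low, t_high = x$t_high,
                 rendered = x$rendered)
}
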