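#' Generate a biexponential vascular input function
#'
#' Plasma contrast-agent concentration over time as sampled at the superior
#' sagittal sinus, modelled as a population biexponential decay starting at
#' bolus arrival:
#' \deqn{C_p(t) = a_1 e^{-m_1 (t - t_0)} + a_2 e^{-m_2 (t - t_0)}, \quad t \ge t_0,}
#' and 0 before arrival. The fast term captures the first-pass bolus, the slow
#' term the equilibrium washout. No hematocrit correction is applied.
#'
#' @param a1,a2 Amplitudes of the fast and slow components (mM); must be >= 0.
#' @param m1,m2 Decay rates (1/s); must be > 0.
#' @param arrival_time Bolus arrival time t0 (s).
#' @param times Strictly increasing sample times (s).
#' @return An object of class `bbb_vif`: a list with `times`, `cp` (mM) and
#'   `arrival_time`.
#' @export
#' @examples
#' vif <- generate_vif()
#' head(tibble::as_tibble(vif))
generate_vif <- function(a1 = 4, m1 = 0.05, a2 = 1.5, m2 = 8e-4,
                         arrival_time = 30, times = seq(0, 1230, by = 24)) {
  stopifnot_scalar_number(a1, "a1", lower = 0)
  stopifnot_scalar_number(a2, "a2", lower = 0)
  stopifnot_scalar_number(m1, "m1", lower = .Machine$double.xmin)
  stopifnot_scalar_number(m2, "m2", lower = .Machine$double.xmin)
  stopifnot_scalar_number(arrival_time, "arrival_time")
  if (!is.numeric(times) || length(times) < 2L || any(diff(times) <= 0)) {
    stop("`times` must be a strictly increasing numeric vector", call. = FALSE)
  }
  dt <- times - arrival_time
  cp <- ifelse(dt < 0, 0, a1 * exp(-m1 * pmax(dt, 0)) + a2 * exp(-m2 * pmax(dt, 0)))
  structure(
    list(times = as.numeric(times), cp = as.numeric(cp),
         arrival_time = arrival_time,
         params = c(a1 = a1, m1 = m1, a2 = a2, m2 = m2)),
    class = "bbb_vif"
  )
}

#' @export
as_tibble.bbb_vif <- function(x, ...) {
  tibble::tibble(time_s = x$times, cp_mM = x$cp)
}

#' @export
print.bbb_vif <- function(x, ...) {
  cat(sprintf(
    "<bbb_vif> %d samples, %.0f-%.0f s, arrival %.0f s, peak %.3g mM\n",
    length(x$times), min(x$times), max(x$times), x$arrival_time, max(x$cp)))
  invisible(x)
}

#' @rdname generate_vif
#' @param x A `bbb_vif` object.
#' @param object,... Passed through by the `autoplot` generic.
#' @export
autoplot.bbb_vif <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$cp_mM)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(C[p] ~ "(mM)"),
                  title = "Vascular input function")
}

#' Cumulative integral of the vascular input function
#'
#' Trapezoidal cumulative integral of plasma concentration,
#' \eqn{\int_0^t C_p \, d\tau}, converted from mM.s to mM.min so that the
#' Patlak slope is in 1/min. The first element is 0 and the result is
#' non-decreasing since \eqn{C_p \ge 0}.
#'
#' @param vif A `bbb_vif` object (or list with `times` and `cp`).
#' @return Numeric vector, same length as `vif$times`, in mM.min.
#' @export
#' @examples
#' cumulative_vif_integral(generate_vif())[1:5]
cumulative_vif_integral <- function(vif) {
  t <- vif$times
  cp <- vif$cp
  if (length(t) != length(cp)) stop("times and cp lengths differ", call. = FALSE)
  n <- length(t)
  c(0, cumsum(diff(t) * (cp[-1L] + cp[-n]) / 2)) / 60
}
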