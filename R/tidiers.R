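#' Tidy a residence-time fit
#'
#' @param x A `residence_fit`.
#' @param ... Ignored.
#' @return One row per fitted parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.residence_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "B", "theta1", "theta2"),
    estimate = c(x$A, x$B, x$theta1, x$theta2),
    std.error = c(x$sd_A, x$sd_B, x$sd_theta1, x$sd_theta2)
  )
}

#' One-row summary of a residence-time fit
#'
#' @param x A `residence_fit`.
#' @param ... Ignored.
#' @return A one-row tibble: reported residence time and its SD, both time
#'   constants, amplitudes, fit diagnostics and the observable-window flag.
#' @export
glance.residence_fit <- function(x, ...) {
  tibble::tibble(
    residence_time = x$reported_residence_time,
    sd = x$sd_theta2,
    theta1 = x$theta1, theta2 = x$theta2, A = x$A, B = x$B,
    rss = x$rss, n_points = x$n_points, n_lipids = x$N_j,
    fit_t_max = x$fit_t_max,
    exceeds_window = x$exceeds_window
  )
}
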