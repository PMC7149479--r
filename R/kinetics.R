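#' Normalised survival time-correlation function
#'
#' For each lag t the survival function counts, over all lipids j and start
#' times v, the indicator that lipid j is continuously bound from v to
#' v + t (inclusive), averages it as
#' sigma_raw(t) = (1/N_j) (1/(T - t)) sum_j sum_v rho_j(v, v + t),
#' and normalises by sigma_raw(0) so that sigma(0) = 1. N_j counts only
#' lipids with nonzero interaction time; all-false series are excluded.
#'
#' The discrete convention (recorded in the attributes) reads T - t as the
#' number of admissible start frames, i.e. F - k for lag k at F frames, so
#' that e.g. a single lipid bound for 4 of 11 frames gives
#' sigma_raw(0) = 4/11. Lags run from 0 to (F - 2) dt, strictly below the
#' total time T = (F - 1) dt.
#'
#' With `gap_tolerance = g > 0`, interruptions of at most g consecutive
#' unoccupied frames inside a bound interval do not break continuity
#' (frame-sampling artifacts commonly drop contacts for single frames).
#' With g = 0 the curve is non-increasing by construction.
#'
#' @param occupancy A `site_occupancy` matrix from [site_occupancy()], or
#'   any logical lipids-by-frames matrix.
#' @param frame_interval Frame spacing in ns (default: taken from the
#'   occupancy attribute).
#' @param gap_tolerance Maximum ignorable interruption, frames.
#' @return A `survival_curve` tibble: `t` (ns), `sigma` (normalised),
#'   `n_pairs` (raw continuity counts). Attributes: `N_j`, `T`,
#'   `frame_interval`, `sigma0_raw`, `gap_tolerance`, `convention`.
#' @export
survival_curve <- function(occupancy, frame_interval = NULL,
                           gap_tolerance = 0L) {
  occ <- unclass(occupancy)
  if (is.null(dim(occ))) occ <- matrix(occ, nrow = 1L)
  storage.mode(occ) <- "logical"
  dt <- frame_interval %||% attr(occupancy, "frame_interval") %||% 1
  nF <- ncol(occ)
  if (nF < 2L) stop("need at least two frames", call. = FALSE)
  active <- rowSums(occ) > 0L
  if (!any(active)) stop("no interacting lipids", call. = FALSE)
  occ <- occ[active, , drop = FALSE]
  Nj <- nrow(occ)

  # occupied-run lengths per lipid, after closing gaps <= gap_tolerance
  run_lengths <- unlist(lapply(seq_len(Nj), function(j) {
    r <- rle(occ[j, ])
    if (gap_tolerance > 0L && length(r$lengths) > 2L) {
      inner <- seq_along(r$values)[-c(1L, length(r$values))]
      fill <- inner[!r$values[inner] & r$lengths[inner] <= gap_tolerance]
      if (length(fill)) {
        r$values[fill] <- TRUE
        r <- rle(inverse.rle(r))
      }
    }
    r$lengths[r$values]
  }))

  ks <- 0:(nF - 2L)
  m <- max(run_lengths)
  c_len <- tabulate(run_lengths, nbins = m)
  # suffix sums: counts(k) = sum over runs of max(0, len - k)
  s1 <- rev(cumsum(rev(c_len)))             # number of runs with len >= l
  s2 <- rev(cumsum(rev(c_len * seq_len(m))))  # sum of len over len >= l
  counts <- vapply(ks, function(k) {
    if (k + 1L > m) 0 else s2[k + 1L] - k * s1[k + 1L]
  }, numeric(1L))

  sigma_raw <- counts / (Nj * (nF - ks))
  structure(
    tibble::tibble(t = ks * dt, sigma = sigma_raw / sigma_raw[1L],
                   n_pairs = counts),
    N_j = Nj, T = (nF - 1L) * dt, frame_interval = dt,
    sigma0_raw = sigma_raw[1L], gap_tolerance = gap_tolerance,
    convention = "start-frame count normalisation: sigma_raw(k) = counts / (N_j * (n_frames - k))",
    class = c("survival_curve", class(tibble::tibble()))
  )
}

#' Biexponential residence-time fit
#'
#' Fits A exp(-t / theta1) + B exp(-t / theta2) to a normalised survival
#' curve by bounded nonlinear least squares (Levenberg-Marquardt), with
#' A, B >= 0 and theta1, theta2 > 0, over lags up to `fit_t_max` (default
#' T/2: the start-frame normalisation makes long-lag values noisy). The two
#' exponentials model a short-lived population that fails to engage the
#' site and a long-lived, tightly bound one; the residence time reported is
#' the larger time constant. Parameter errors are the standard deviations
#' of the fitted estimates (from the fit covariance). Initialisation is
#' deterministic: theta1 starts at one third of the lag where sigma first
#' drops below 1/e, theta2 at three times that lag, A = B = 0.5.
#'
#' A fitted time constant at or beyond `fit_t_max` is flagged
#' `exceeds_window`: the trajectory cannot resolve it, only bound it below.
#'
#' @param curve A `survival_curve`.
#' @param fit_t_max Largest lag (ns) entering the fit.
#' @return A `residence_fit` object; see [tidy.residence_fit()] /
#'   [glance.residence_fit()].
#' @export
fit_biexponential <- function(curve, fit_t_max = NULL) {
  total_T <- attr(curve, "T")
  fit_t_max <- fit_t_max %||% (total_T / 2)
  pts <- curve[curve$t <= fit_t_max + 1e-9, ]
  if (nrow(pts) < 8L) {
    stop("need at least 8 survival points within the fit range (have ",
         nrow(pts), ")", call. = FALSE)
  }
  dt <- attr(curve, "frame_interval") %||% diff(pts$t[1:2])
  below <- which(pts$sigma < exp(-1))
  t_e <- if (length(below)) pts$t[below[1L]] else max(pts$t) / 2
  t_e <- max(t_e, dt)

  lm_fit <- function(resid_fn, par, lower) {
    fit <- minpack.lm::nls.lm(
      par = par, lower = lower, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    if (!(fit$info %in% 1:4)) return(NULL)
    rss <- sum(fit$fvec^2)
    dfree <- length(fit$fvec) - length(par)
    se <- tryCatch(
      sqrt(diag(solve(fit$hessian)) * rss / dfree),
      error = function(e) rep(NA_real_, length(par))
    )
    names(se) <- names(par)
    list(est = fit$par, se = se, rss = rss)
  }
  biexp_resid <- function(p) {
    pts$sigma - (p[["A"]] * exp(-pts$t / p[["theta1"]]) +
                   p[["B"]] * exp(-pts$t / p[["theta2"]]))
  }
  lo4 <- c(A = 0, B = 0, theta1 = dt * 1e-6, theta2 = dt * 1e-6)
  # deterministic ladder of starting points; the first convergent fit wins
  starts <- list(
    c(A = 0.5, B = 0.5, theta1 = t_e / 3, theta2 = 3 * t_e),
    c(A = 0.3, B = 0.7, theta1 = t_e / 2, theta2 = t_e),
    c(A = 0.5, B = 0.5, theta1 = t_e / 5, theta2 = 8 * t_e)
  )
  fit <- NULL
  for (start in starts) {
    fit <- lm_fit(biexp_resid, start, lo4)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    start <- starts[[1L]]
    stop("biexponential fit did not converge from any starting point",
         " (initial RSS ", signif(sum(biexp_resid(start)^2), 4), ")",
         call. = FALSE)
  }
  est <- fit$est
  se <- fit$se

  # degenerate single-exponential data: one amplitude collapses to zero
  # while its time constant floats; refit the single exponential so the
  # reported residence time is the meaningful constant
  if (min(est[c("A", "B")]) < 1e-3 * sum(est[c("A", "B")])) {
    dead <- if (est[["A"]] <= est[["B"]]) "A" else "B"
    th0 <- unname(est[[if (dead == "A") "theta2" else "theta1"]])
    sfit <- lm_fit(
      function(p) pts$sigma - p[["C"]] * exp(-pts$t / p[["theta"]]),
      c(C = unname(est[["A"]] + est[["B"]]), theta = th0),
      c(C = 0, theta = dt * 1e-6)
    )
    if (!is.null(sfit)) {
      est <- c(A = 0, B = unname(sfit$est[["C"]]),
               theta1 = unname(sfit$est[["theta"]]),
               theta2 = unname(sfit$est[["theta"]]))
      se <- c(A = NA_real_, B = unname(sfit$se[["C"]]),
              theta1 = unname(sfit$se[["theta"]]),
              theta2 = unname(sfit$se[["theta"]]))
      fit$rss <- sfit$rss
    }
  }
  if (est[["theta1"]] > est[["theta2"]]) {  # enforce theta1 <= theta2
    est <- est[c("B", "A", "theta2", "theta1")]
    se <- se[c("B", "A", "theta2", "theta1")]
    names(est) <- names(se) <- c("A", "B", "theta1", "theta2")
  }
  structure(
    list(
      A = unname(est["A"]), B = unname(est["B"]),
      theta1 = unname(est["theta1"]), theta2 = unname(est["theta2"]),
      sd_A = unname(se["A"]), sd_B = unname(se["B"]),
      sd_theta1 = unname(se["theta1"]), sd_theta2 = unname(se["theta2"]),
      reported_residence_time = max(unname(est["theta1"]),
                                    unname(est["theta2"])),
      fit_t_max = fit_t_max,
      exceeds_window = max(est["theta1"], est["theta2"]) >= fit_t_max,
      n_points = nrow(pts),
      rss = fit$rss,
      N_j = attr(curve, "N_j")
    ),
    class = "residence_fit"
  )
}

#' @export
print.residence_fit <- function(x, ...) {
  cat("<residence_fit> residence time ",
      signif(x$reported_residence_time, 4), " +/- ",
      signif(x$sd_theta2, 3), " ns",
      if (isTRUE(x$exceeds_window)) "  [exceeds observable window]" else "",
      "\n  A = ", signif(x$A, 3), ", theta1 = ", signif(x$theta1, 4),
      " ns; B = ", signif(x$B, 3), ", theta2 = ", signif(x$theta2, 4),
      " ns (fit over t <= ", signif(x$fit_t_max, 4), " ns, n = ",
      x$n_points, ")\n", sep = "")
  invisible(x)
}

#' Residence time of a lipid species at an interaction site
#'
#' Composes [site_occupancy()], [survival_curve()] and
#' [fit_biexponential()]. Pass `site = NULL` for whole-surface residence
#' times (the usual convention for cholesterol, whose records should then
#' come from its conservative 1.0-nm cutoff).
#'
#' @param records A `contact_records` for one species.
#' @param site An `interaction_site`, residue-key vector, or `NULL` for
#'   the entire protein surface.
#' @param frame_interval,gap_tolerance Passed to [survival_curve()].
#' @param fit_t_max Passed to [fit_biexponential()].
#' @return A `residence_fit` with the survival curve attached as
#'   `$curve`.
#' @export
residence_time_for_site <- function(records, site = NULL,
                                    frame_interval = NULL,
                                    gap_tolerance = 0L, fit_t_max = NULL) {
  occ <- site_occupancy(records, site)
  curve <- survival_curve(occ, frame_interval = frame_interval,
                          gap_tolerance = gap_tolerance)
  fit <- fit_biexponential(curve, fit_t_max = fit_t_max)
  fit$curve <- curve
  fit
}
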