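# Dose-response analysis: four-parameter logistic (4PL) fitting of
# phenotypic distances or normalized viability, EC50 reporting with a
# fit / no-fit decision, and small auxiliary assay calculations.

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of `r(d) = bottom + (top - bottom) / (1 + (ec50/d)^hill)`
#' on log10 dose, using bounded Levenberg-Marquardt ([minpack.lm::nlsLM])
#' with a deterministic data-driven initialization (plateaus from the extreme
#' doses, EC50 from the half-maximal crossing). `log10(ec50)` is bounded to
#' within one decade of the dose range; `hill` is positive, with the curve
#' direction carried by the sign of `top - bottom` (distances rise with dose,
#' viability falls). The fit status is then decided by [classify_fit()].
#'
#' @param doses Dose per observation, nM, strictly positive.
#' @param responses Response per observation (per-well points, each well
#'   weighted equally).
#' @param control_sd Optional pooled SD of the control wells, used by the
#'   dynamic-range no-fit rule.
#' @param bottom_min Lower bound for the bottom plateau (default `-Inf`);
#'   responses that are non-negative by construction, such as Euclidean
#'   distances, warrant `bottom_min = 0`.
#' @return An object of class `fit_result`: `bottom`, `top`, `ec50`, `hill`,
#'   `r_squared`, `converged`, `status` (`"fit"` or `"no_fit"`),
#'   `status_reason`, and the bounds used.
#' @examples
#' d <- 50 / 2^(0:8)
#' r <- 10 / (1 + (36 / d))
#' fit_4pl(d, r)$ec50
#' @export
fit_4pl <- function(doses, responses, control_sd = NULL,
                    bottom_min = -Inf) {
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (length(unique(doses)) < 4)
    stop("at least 4 distinct doses are required")

  ld <- log10(doses)
  lo_b <- min(ld) - 1; hi_b <- max(ld) + 1
  med <- tapply(responses, ld, mean)
  lvl <- as.numeric(names(med))
  o <- order(lvl); lvl <- lvl[o]; med <- as.numeric(med)[o]

  bottom0 <- med[1]; top0 <- med[length(med)]
  half <- (bottom0 + top0) / 2
  cross <- which(diff(sign(med - half)) != 0)
  le0 <- if (length(cross)) {
    i <- cross[1]
    if (med[i + 1] != med[i])
      lvl[i] + (half - med[i]) / (med[i + 1] - med[i]) * (lvl[i + 1] - lvl[i])
    else mean(lvl[i:(i + 1)])
  } else stats::median(lvl)
  le0 <- min(max(le0, lo_b + 0.05), hi_b - 0.05)

  # deterministic grid multistart: the half-crossing estimate plus the dose
  # range quartiles, crossed with three Hill-slope starts; the basin with
  # the lowest residual sum of squares wins. Guards against convergence to
  # degenerate shallow-slope solutions when one plateau is weakly sampled.
  le_starts <- unique(c(le0, stats::quantile(ld, c(0.25, 0.5, 0.75),
                                             names = FALSE)))
  fit <- NULL; best_ss <- Inf
  for (le_s in le_starts) for (h_s in c(0.7, 1, 2)) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ bottom + (top - bottom) / (1 + 10^((le - ld) * hill)),
        start = list(bottom = max(bottom0, bottom_min), top = top0,
                     le = le_s, hill = h_s),
        lower = c(bottom_min, -Inf, lo_b, 0.05),
        upper = c(Inf, Inf, hi_b, 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand)) {
      ss <- sum(stats::residuals(cand)^2)
      if (ss < best_ss - 1e-12) { best_ss <- ss; fit <- cand }
    }
  }

  if (is.null(fit)) {
    res <- structure(list(bottom = NA_real_, top = NA_real_,
                          ec50 = NA_real_, hill = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          ec50_bounds = 10^c(lo_b, hi_b),
                          status = "no_fit",
                          status_reason = "convergence failure"),
                     class = "fit_result")
    return(res)
  }
  p <- stats::coef(fit)
  pred <- stats::predict(fit)
  ss_res <- sum((responses - pred)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  res <- structure(list(bottom = unname(p["bottom"]), top = unname(p["top"]),
                        ec50 = unname(10^p["le"]), hill = unname(p["hill"]),
                        r_squared = r2, converged = TRUE,
                        ec50_bounds = 10^c(lo_b, hi_b),
                        status = NA_character_, status_reason = NA_character_),
                   class = "fit_result")
  cls <- classify_fit(res, control_sd = control_sd)
  res$status <- cls$status
  res$status_reason <- cls$reason
  res
}

#' Decide fit vs no-fit for a 4PL result
#'
#' A curve is declared `no_fit` when any of the following holds: the
#' optimizer failed to converge; the dynamic range `|top - bottom|` is less
#' than twice the pooled control SD (when supplied); the coefficient of
#' determination is below 0.5 (strict); or the EC50 sits at one of its
#' bounds. Otherwise the status is `fit`.
#'
#' @param fit A `fit_result` from [fit_4pl()].
#' @param control_sd Optional pooled control SD for the dynamic-range rule.
#' @return A list with `status` (`"fit"`/`"no_fit"`) and `reason`.
#' @export
classify_fit <- function(fit, control_sd = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  if (!isTRUE(fit$converged))
    return(list(status = "no_fit", reason = "convergence failure"))
  if (!is.null(control_sd) && is.finite(control_sd) &&
      abs(fit$top - fit$bottom) < 2 * control_sd)
    return(list(status = "no_fit", reason = "dynamic range below noise"))
  if (!is.finite(fit$r_squared) || fit$r_squared < 0.5)
    return(list(status = "no_fit", reason = "r_squared below 0.5"))
  lb <- log10(fit$ec50_bounds)
  if (min(abs(log10(fit$ec50) - lb)) < 0.01)
    return(list(status = "no_fit", reason = "EC50 at bound"))
  list(status = "fit", reason = "ok")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$status == "fit")
    cat(sprintf(
      "4PL fit: EC50 = %.3g nM, hill = %.2f, bottom = %.3g, top = %.3g, R2 = %.3f\n",
      x$ec50, x$hill, x$bottom, x$top, x$r_squared))
  else
    cat("4PL: No fit (", x$status_reason, ")\n", sep = "")
  invisible(x)
}

#' Normalize raw viability readings to the vehicle control
#'
#' `100 * raw / mean(control)`, the percent-of-DMSO normalization used for
#' luminescence viability readouts.
#'
#' @param raw Numeric vector of raw per-well readings.
#' @param control_raw Numeric vector of raw control-well readings.
#' @return Percent of control, same length as `raw`.
#' @export
normalize_viability <- function(raw, control_raw) {
  if (length(control_raw) < 1) stop("at least one control well required")
  m <- mean(control_raw)
  if (!is.finite(m) || m == 0) stop("control mean is zero")
  100 * raw / m
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddct = (ct_target_t - ct_ref_t) - (ct_target_c - ct_ref_c)`;
#' fold change `2^(-ddct)` of the target gene in treated vs control samples,
#' normalized to the reference (housekeeping) gene.
#'
#' @param ct_target_t,ct_ref_t Target/reference-gene Ct in the treated
#'   sample.
#' @param ct_target_c,ct_ref_c Target/reference-gene Ct in the control
#'   sample.
#' @return A list with `ddct` and `fold_change`.
#' @examples
#' delta_delta_ct(25, 20, 23, 20)  # fold change 0.25
#' @export
delta_delta_ct <- function(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c) {
  cts <- c(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c)
  if (!all(is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_t - ct_ref_t) - (ct_target_c - ct_ref_c)
  list(ddct = ddct, fold_change = 2^(-ddct))
}

#' Culture derivation ('take') rate
#'
#' Percentage of collected samples successfully established in culture.
#'
#' @param established Number of established cultures.
#' @param collected Number of collected samples (> 0).
#' @return Percent.
#' @examples
#' derivation_rate(48, 59)
#' @export
derivation_rate <- function(established, collected) {
  if (collected <= 0) stop("collected must be positive")
  if (established < 0 || established > collected)
    stop("established must be between 0 and collected")
  100 * established / collected
}
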