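#' Normal + lognormal (NLN) convolution parameters
#'
#' The measured peak-radius distribution is modelled as R = T + S with
#' T ~ Normal(mu_tip, sigma_tip) attributed to the tip and
#' S ~ Lognormal(mu_log, sigma_log) attributed to the surface grain
#' curvature. All radii in nm; `mu_log` is on the log-nm scale.
#'
#' @param mu_tip Mean of the normal (tip) component, nm.
#' @param sigma_tip Standard deviation of the normal component, nm (> 0).
#' @param mu_log Lognormal location (log-nm).
#' @param sigma_log Lognormal scale (> 0).
#' @return An object of class `nln_params`.
#' @export
nln_params <- function(mu_tip, sigma_tip, mu_log, sigma_log) {
  if (!is.finite(mu_tip) || !is.finite(mu_log) ||
      !is.finite(sigma_tip) || sigma_tip <= 0 ||
      !is.finite(sigma_log) || sigma_log <= 0)
    stop("invalid NLN parameters: sigma_tip and sigma_log must be > 0")
  structure(list(mu_tip = mu_tip, sigma_tip = sigma_tip,
                 mu_log = mu_log, sigma_log = sigma_log),
            class = "nln_params")
}

#' NLN density
#'
#' Density of R = T + S computed by numerical convolution on a uniform grid
#' (step at most `min(sigma_tip, exp(mu_log) * sigma_log) / 10`, capped at
#' 2^14 points), linearly interpolated at the evaluation points. When the
#' lognormal component is narrower than one grid step it is treated as a
#' point mass at its mean (the degenerate limit), giving the shifted normal
#' density exactly.
#'
#' @param params An [nln_params()].
#' @param eval_points Radii (nm) at which to evaluate the density.
#' @return Non-negative densities at `eval_points`.
#' @export
nln_pdf <- function(params, eval_points) {
  if (!inherits(params, "nln_params")) params <- do.call(nln_params, as.list(params))
  if (params$sigma_tip < 1e-3)     # normal component unresolvably narrow
    return(stats::dlnorm(eval_points - params$mu_tip,
                         params$mu_log, params$sigma_log))
  g <- nln_grid(params)
  if (is.null(g))
    return(stats::dnorm(eval_points,
                        params$mu_tip + lognormal_mean(params),
                        params$sigma_tip))
  d <- stats::approx(g$x, g$f, xout = eval_points, yleft = 0, yright = 0,
                     rule = 1)$y
  pmax(d, 0)
}

lognormal_mean <- function(p) exp(p$mu_log + p$sigma_log^2 / 2)

## Convolution grid; NULL signals the degenerate (near-delta lognormal) case.
nln_grid <- function(p) {
  ln_sd <- sqrt(exp(p$sigma_log^2) - 1) * lognormal_mean(p)
  step <- min(p$sigma_tip, exp(p$mu_log) * p$sigma_log) / 10
  t_lo <- p$mu_tip - 7 * p$sigma_tip
  t_hi <- p$mu_tip + 7 * p$sigma_tip
  s_hi <- stats::qlnorm(1 - 1e-7, p$mu_log, p$sigma_log)
  span <- (t_hi - t_lo) + s_hi
  if (span / step > 16384) step <- span / 16384
  if (ln_sd < step) return(NULL)        # lognormal unresolvable: point mass
  tx <- seq(t_lo, t_hi, by = step)
  sx <- seq(step / 2, s_hi, by = step)  # midpoint samples avoid the 0 edge
  ft <- stats::dnorm(tx, p$mu_tip, p$sigma_tip)
  fs <- stats::dlnorm(sx, p$mu_log, p$sigma_log)
  conv <- stats::convolve(ft, rev(fs), type = "open") * step
  x0 <- tx[[1L]] + sx[[1L]]
  list(x = x0 + step * (seq_along(conv) - 1L), f = conv, step = step)
}

nln_loglik <- function(params, radii) {
  d <- nln_pdf(params, radii)
  sum(log(pmax(d, 1e-300)))
}

default_radius_filter <- function(radii, min_nm = 1, max_nm = 500) {
  radii[is.finite(radii) & radii > min_nm & radii < max_nm]
}

## Deterministic bounded optimization of (mu_tip, log sigma_tip) for fixed
## surface parameters; multi-start grid per the documented defaults.
fit_tip_optim <- function(radii, mu_log, sigma_log,
                          mu_starts = c(10, 20, 35, 50), sigma_start = NULL,
                          warm = NULL) {
  if (is.null(sigma_start))
    sigma_start <- max(stats::sd(radii) / 4, 0.5)
  nll <- function(th) {
    p <- tryCatch(nln_params(th[[1L]], exp(th[[2L]]), mu_log, sigma_log),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    v <- -nln_loglik(p, radii)
    if (!is.finite(v)) 1e10 else v
  }
  # moment-matched start: mean/variance of the data minus the fixed
  # lognormal component
  ln_m <- exp(mu_log + sigma_log^2 / 2)
  ln_v <- (exp(sigma_log^2) - 1) * ln_m^2
  mm <- c(mean(radii) - ln_m,
          log(sqrt(max(stats::var(radii) - ln_v, 0.25))))
  starts <- c(list(mm), lapply(mu_starts, function(m) c(m, log(sigma_start))))
  if (!is.null(warm)) starts <- c(list(warm), starts)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    # the moment and warm starts land in the right basin; once two starts
    # agree to 1e-4 the remaining grid cannot improve materially
    if (!is.null(best) && length(starts) > 1L && fit$value - best$value < 1e-4 &&
        !identical(st, starts[[1L]])) break
  }
  if (is.null(best)) stop("tip fit failed to converge from any start")
  list(mu_tip = best$par[[1L]], sigma_tip = exp(best$par[[2L]]),
       loglik = -best$value, par = best$par, nll = nll)
}

#' Fit the tip radius with fixed surface parameters
#'
#' Maximum-likelihood fit of the normal (tip) component of the NLN model to a
#' sample of peak radii, with the lognormal (surface) parameters held fixed
#' (as obtained from [fit_nln_surface()]). The 95% confidence interval on
#' `mu_tip` is a profile-likelihood interval (log-likelihood drop of 1.92),
#' assuming the surface properties are determined accurately. Optimization is
#' deterministic: bounded Nelder-Mead from a fixed 4-point start grid on
#' mu_tip (10, 20, 35, 50 nm), sigma log-transformed.
#'
#' Radii outside (1, 500) nm are excluded first as physically implausible
#' parabola-fit artifacts (configurable).
#'
#' @param radii Peak radii in nm (>= `min_n` after filtering).
#' @param surface Surface parameters: an `nln_surface` fit, or
#'   `c(mu_log, sigma_log)`.
#' @param min_n Minimum number of radii (default 50).
#' @param filter_range Plausibility range in nm, default `c(1, 500)`.
#' @return An object of class `nln_tip` with fields `mu_tip`, `sigma_tip`,
#'   `ci95_low`, `ci95_high`, `n_radii`, `loglik`, `surface`.
#' @examples
#' set.seed(1)
#' r <- rnorm(500, 20, 4) + rlnorm(500, 3, 0.5)
#' fit <- fit_nln_tip(r, c(3, 0.5))
#' coef(fit); confint(fit)
#' @export
fit_nln_tip <- function(radii, surface, min_n = 50L,
                        filter_range = c(1, 500)) {
  sp <- surface_params(surface)
  radii <- default_radius_filter(radii, filter_range[[1]], filter_range[[2]])
  if (length(radii) < min_n)
    stop("need at least ", min_n, " plausible radii (have ",
         length(radii), ")")
  if (stats::sd(radii) == 0)
    stop("degenerate sample: all radii identical, tip not identifiable")
  fit <- fit_tip_optim(radii, sp[[1L]], sp[[2L]])
  ci <- profile_ci_mu(fit, radii, sp[[1L]], sp[[2L]])
  structure(list(mu_tip = fit$mu_tip, sigma_tip = fit$sigma_tip,
                 ci95_low = ci[[1L]], ci95_high = ci[[2L]],
                 n_radii = length(radii), loglik = fit$loglik,
                 surface = c(mu_log = sp[[1L]], sigma_log = sp[[2L]]),
                 radii = radii),
            class = "nln_tip")
}

surface_params <- function(surface) {
  if (inherits(surface, "nln_surface"))
    return(c(surface$mu_log, surface$sigma_log))
  surface <- as.numeric(surface)
  if (length(surface) != 2L || surface[[2L]] <= 0)
    stop("surface must be an nln_surface fit or c(mu_log, sigma_log > 0)")
  surface
}

## Profile-likelihood 95% CI on mu_tip (Delta logLik = 1.92), re-optimizing
## sigma_tip at each fixed mu.
profile_ci_mu <- function(fit, radii, mu_log, sigma_log) {
  target <- fit$loglik - stats::qchisq(0.95, 1) / 2
  prof <- function(mu) {
    o <- stats::optimize(function(ls) {
      -nln_loglik(nln_params(mu, exp(ls), mu_log, sigma_log), radii)
    }, interval = log(fit$sigma_tip) + c(-3, 3))
    -o$objective
  }
  side <- function(dir) {
    step <- max(0.25, fit$sigma_tip / sqrt(length(radii)))
    mu0 <- fit$mu_tip
    for (i in 1:60) {
      mu1 <- mu0 + dir * step
      if (prof(mu1) < target) {
        r <- stats::uniroot(function(m) prof(m) - target,
                            sort(c(mu0, mu1)), tol = 1e-4)
        return(r$root)
      }
      mu0 <- mu1
      step <- step * 1.6
    }
    dir * Inf + fit$mu_tip
  }
  c(side(-1), side(1))
}

#' Global calibration of the surface (lognormal) parameters
#'
#' Joint maximum-likelihood fit over several radius samples (e.g. images
#' taken with new tips at low force): the lognormal surface parameters
#' `(mu_log, sigma_log)` are shared across all sets while each set keeps its
#' own free normal tip parameters. Implemented as a nested optimization: the
#' outer search over the surface parameters (deterministic Nelder-Mead
#' multi-start) maximizes the sum of the per-set profiled log-likelihoods,
#' each inner fit warm-started from its previous optimum.
#'
#' @param radius_sets A list of radius vectors (each >= `min_n` after the
#'   plausibility filter), or a `radius_samples` object.
#' @param min_n Minimum radii per set (default 50).
#' @param filter_range Plausibility range in nm.
#' @return An object of class `nln_surface` with fields `mu_log`,
#'   `sigma_log`, `tips` (per-set data frame), `loglik`.
#' @export
fit_nln_surface <- function(radius_sets, min_n = 50L,
                            filter_range = c(1, 500)) {
  if (inherits(radius_sets, "radius_samples"))
    radius_sets <- lapply(radius_sets, `[[`, "radii")
  if (!is.list(radius_sets) || !length(radius_sets))
    stop("radius_sets must be a non-empty list of radius vectors")
  sets <- lapply(radius_sets, default_radius_filter,
                 filter_range[[1]], filter_range[[2]])
  short <- lengths(sets) < min_n
  if (any(short))
    stop("set(s) ", paste(which(short), collapse = ", "),
         " have fewer than ", min_n, " plausible radii")

  m <- length(sets)
  ## joint parameter vector: (mu_log, log sigma_log,
  ##                          mu_tip_1, log sigma_tip_1, ...)
  obj <- function(th) {
    sl <- exp(th[[2L]])
    if (!is.finite(sl) || sl <= 0 || sl > 3) return(1e10)
    tot <- 0
    for (k in seq_len(m)) {
      p <- tryCatch(nln_params(th[[2L * k + 1L]], exp(th[[2L * k + 2L]]),
                               th[[1L]], sl), error = function(e) NULL)
      if (is.null(p)) return(1e10)
      v <- nln_loglik(p, sets[[k]])
      if (!is.finite(v)) return(1e10)
      tot <- tot + v
    }
    -tot
  }
  ## deterministic multi-start: assume a fraction of the pooled median
  ## radius is surface, the rest tip; two surface-share hypotheses
  pooled_med <- stats::median(unlist(sets))
  make_start <- function(share, sig0) {
    c(log(pmax(share * pooled_med, 1)), log(sig0),
      unlist(lapply(sets, function(r)
        c(max(stats::median(r) - share * pooled_med, 1),
          log(max(stats::sd(r) / 4, 0.5))))))
  }
  starts <- list(make_start(0.3, 0.4), make_start(0.5, 0.4),
                 make_start(0.7, 0.6))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nlminb(st, obj, control = list(iter.max = 400, eval.max = 800)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e10)
    stop("global surface fit failed to converge from all starts")
  th <- best$par
  mu_log <- th[[1L]]; sigma_log <- exp(th[[2L]])
  tips <- do.call(rbind, lapply(seq_len(m), function(k)
    data.frame(set = k, mu_tip = th[[2L * k + 1L]],
               sigma_tip = exp(th[[2L * k + 2L]]),
               n = length(sets[[k]]),
               loglik = nln_loglik(
                 nln_params(th[[2L * k + 1L]], exp(th[[2L * k + 2L]]),
                            mu_log, sigma_log), sets[[k]]))))
  structure(list(mu_log = mu_log, sigma_log = sigma_log, tips = tips,
                 loglik = -best$objective, n_sets = m),
            class = "nln_surface")
}

#' Track tip radius against sliding distance
#'
#' Applies [fit_nln_tip()] to each section's radii, with the surface
#' parameters fixed, and assembles the (sliding distance, fitted radius, CI)
#' trajectory. Sections whose fit fails are flagged, not fatal.
#'
#' @param samples A `radius_samples` object from [collect_radii()], or a list
#'   with elements carrying `radii` and `sliding_distance_nm`.
#' @param surface Surface parameters (see [fit_nln_tip()]).
#' @param min_n Minimum radii per section.
#' @return A data frame of class `weartrack` with columns
#'   `sliding_distance_nm`, `mu_tip`, `ci95_low`, `ci95_high`, `n_radii`,
#'   `ok`.
#' @export
track_wear <- function(samples, surface, min_n = 50L) {
  rows <- lapply(samples, function(s) {
    fit <- tryCatch(fit_nln_tip(s$radii, surface, min_n = min_n),
                    error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(sliding_distance_nm = s$sliding_distance_nm,
                 mu_tip = NA_real_, ci95_low = NA_real_,
                 ci95_high = NA_real_, n_radii = length(s$radii), ok = FALSE)
    else
      data.frame(sliding_distance_nm = s$sliding_distance_nm,
                 mu_tip = fit$mu_tip, ci95_low = fit$ci95_low,
                 ci95_high = fit$ci95_high, n_radii = fit$n_radii, ok = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sliding_distance_nm), ]
  rownames(out) <- NULL
  class(out) <- c("weartrack", "data.frame")
  out
}

## ---- methods ----

#' @export
print.nln_tip <- function(x, ...) {
  cat(sprintf("NLN tip fit: mu_tip %.2f nm (95%% CI %.2f-%.2f), sigma_tip %.2f nm\n",
              x$mu_tip, x$ci95_low, x$ci95_high, x$sigma_tip))
  cat(sprintf("  n = %d radii, logLik %.2f, surface LogN(%.3f, %.3f) fixed\n",
              x$n_radii, x$loglik, x$surface[["mu_log"]],
              x$surface[["sigma_log"]]))
  invisible(x)
}

#' @export
coef.nln_tip <- function(object, ...)
  c(mu_tip = object$mu_tip, sigma_tip = object$sigma_tip)

#' @export
logLik.nln_tip <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n_radii, class = "logLik")
}

#' @export
confint.nln_tip <- function(object, parm = "mu_tip", level = 0.95, ...) {
  if (!identical(level, 0.95))
    stop("only the 95% profile-likelihood interval is computed")
  matrix(c(object$ci95_low, object$ci95_high), nrow = 1,
         dimnames = list("mu_tip", c("2.5 %", "97.5 %")))
}

#' @export
predict.nln_tip <- function(object, eval_points, ...) {
  p <- nln_params(object$mu_tip, object$sigma_tip,
                  object$surface[["mu_log"]], object$surface[["sigma_log"]])
  nln_pdf(p, eval_points)
}

#' @export
simulate.nln_tip <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(nsim, object$mu_tip, object$sigma_tip) +
    stats::rlnorm(nsim, object$surface[["mu_log"]],
                  object$surface[["sigma_log"]])
}

#' @export
summary.nln_tip <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.nln_tip <- function(x, breaks = 40, ...) {
  hh <- graphics::hist(x$radii, breaks = breaks, freq = FALSE,
                       xlab = "peak radius (nm)", main = "NLN fit", ...)
  xs <- seq(min(hh$breaks), max(hh$breaks), length.out = 400)
  graphics::lines(xs, predict(x, xs), lwd = 2)
  invisible(x)
}

#' @export
print.nln_surface <- function(x, ...) {
  cat(sprintf("NLN surface calibration: mu_log %.3f, sigma_log %.3f (%d sets, logLik %.2f)\n",
              x$mu_log, x$sigma_log, x$n_sets, x$loglik))
  print(x$tips, row.names = FALSE)
  invisible(x)
}

#' @export
coef.nln_surface <- function(object, ...)
  c(mu_log = object$mu_log, sigma_log = object$sigma_log)

#' @export
print.weartrack <- function(x, ...) {
  cat("Tip wear track (radius vs sliding distance):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.weartrack <- function(x, ...) {
  graphics::plot(x$sliding_distance_nm / 1e6, x$mu_tip,
                 xlab = "sliding distance (mm)", ylab = "tip radius (nm)",
                 type = "b", pch = 19,
                 ylim = range(c(x$ci95_low, x$ci95_high), na.rm = TRUE), ...)
  graphics::arrows(x$sliding_distance_nm / 1e6, x$ci95_low,
                   x$sliding_distance_nm / 1e6, x$ci95_high,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
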