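# 15N spin-relaxation analysis: exponential decay fits, pooled duplicate-delay
# noise, Monte-Carlo rate errors, tilted-field R1rho -> R2 correction, hetNOE.

#' Pooled noise from duplicated-delay measurements
#'
#' The intensity noise is estimated as the pooled standard deviation over the
#' duplicated relaxation-delay planes,
#' \deqn{\sigma = \sqrt{\sum_i (s_{i,1}-s_{i,2})^2 / (2k)},}
#' where \eqn{s_{i,1}, s_{i,2}} are the two intensities of peak \eqn{i} at
#' the duplicated delay and \eqn{k} is the number of peaks pooled.
#'
#' @param x a \code{\link{peak_table}} containing duplicated
#'   (residue, delay) rows, a list of \code{\link{decay_series}}, or a
#'   two-column matrix with one duplicate pair per row.
#' @return An object of class \code{noise_estimate}: list with elements
#'   \code{sigma} (intensity units) and \code{k} (pairs pooled).
#' @export
estimate_pooled_noise <- function(x) {
  if (inherits(x, "peak_table")) {
    key <- paste(x$residue, x$delay)
    dup_keys <- unique(key[duplicated(key)])
    pairs <- t(vapply(dup_keys,
                      function(k) x$intensity[key == k][1:2], numeric(2)))
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "decay_series"))) {
    pairs <- do.call(rbind, lapply(x, function(s) {
      if (nrow(s$duplicate_pairs) == 0L) return(NULL)
      cbind(s$I[s$duplicate_pairs[, 1]], s$I[s$duplicate_pairs[, 2]])
    }))
  } else {
    pairs <- as.matrix(x)
  }
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop_foxdyn("no duplicated-delay pairs available for noise estimation",
                "foxdyn_insufficient_duplicates")
  stopifnot(ncol(pairs) == 2L)
  k <- nrow(pairs)
  sigma <- sqrt(sum((pairs[, 1] - pairs[, 2])^2) / (2 * k))
  structure(list(sigma = sigma, k = k), class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("Pooled duplicate-delay noise: sigma = %.6g (%d peak pairs)\n",
              x$sigma, x$k))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Batch Levenberg-Marquardt fitter for I(t) = I0 * exp(-R t), vectorised
# across curves sharing one delay schedule. Used both for single series and
# for the Monte-Carlo replicates, where thousands of refits per residue make
# a per-curve optimiser call prohibitive.
exp_decay_batch <- function(t, Y, max_iter = 100L, tol = 1e-12) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  n <- nrow(Y); m <- ncol(Y)
  stopifnot(length(t) == m, m >= 3L)

  # Initialisation: I0 = max intensity; R from the endpoint log-ratio,
  # clipped to [1e-3, 1e3] s^-1 (robust for monotone decays).
  I0 <- apply(Y, 1L, max)
  ord <- order(t)
  ratio <- Y[, ord[1L]] / Y[, ord[m]]
  R <- suppressWarnings(log(ratio) / (t[ord[m]] - t[ord[1L]]))
  R[!is.finite(R)] <- 1
  R <- pmin(pmax(R, 1e-3), 1e3)
  I0[!is.finite(I0) | I0 == 0] <- 1e-6

  sse_of <- function(I0v, Rv)
    rowSums((Y - I0v * exp(-outer(Rv, t)))^2)

  S <- sse_of(I0, R)
  lambda <- rep(1e-3, n)
  active <- is.finite(S)
  converged <- rep(FALSE, n)

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    E <- exp(-outer(R, t))
    Fv <- I0 * E
    resid <- Y - Fv
    tE <- sweep(E, 2L, t, "*")
    J2 <- -I0 * tE
    g1 <- rowSums(resid * E)
    g2 <- rowSums(resid * J2)
    A11 <- rowSums(E * E)
    A12 <- rowSums(E * J2)
    A22 <- rowSums(J2 * J2)

    pend <- active
    improved <- rep(FALSE, n)
    for (att in 1:40) {
      if (!any(pend)) break
      d11 <- A11 * (1 + lambda); d22 <- A22 * (1 + lambda)
      det <- d11 * d22 - A12^2
      s1 <- (g1 * d22 - g2 * A12) / det
      s2 <- (g2 * d11 - g1 * A12) / det
      cI0 <- I0 + s1; cR <- R + s2
      cS <- sse_of(cI0, cR)
      ok <- pend & is.finite(cS) & is.finite(cI0) & is.finite(cR) & (cS <= S)
      if (any(ok)) {
        gain <- (S[ok] - cS[ok]) <= tol * (S[ok] + tol)
        I0[ok] <- cI0[ok]; R[ok] <- cR[ok]; S[ok] <- cS[ok]
        lambda[ok] <- pmax(lambda[ok] / 3, 1e-12)
        improved[ok] <- TRUE
        conv_idx <- which(ok)[gain]
        converged[conv_idx] <- TRUE
        active[conv_idx] <- FALSE
      }
      worse <- pend & !ok
      lambda[worse] <- lambda[worse] * 4
      pend <- worse
    }
    # Rows where no damped step improved the fit are at a (local) optimum.
    stalled <- active & !improved
    converged[stalled] <- TRUE
    active[stalled] <- FALSE
  }
  failed <- !is.finite(I0) | !is.finite(R) | !is.finite(S)
  converged[failed] <- FALSE
  list(I0 = I0, R = R, sse = S, converged = converged)
}

#' Fit a two-parameter exponential decay to a relaxation series
#'
#' Fits \eqn{I(t) = I_0 e^{-Rt}} by least squares (damped Gauss-Newton /
#' Levenberg-Marquardt). Duplicated-delay points enter the fit as independent
#' observations; negative intensities are permitted (noise can push weak
#' peaks below zero) and no log-linearisation is used.
#'
#' @param series a \code{\link{decay_series}}, or a \code{\link{peak_table}}
#'   together with \code{residue}.
#' @param noise optional \code{\link{estimate_pooled_noise}} result, stored
#'   for error propagation.
#' @param residue residue number when \code{series} is a peak table.
#' @return An object of class \code{decay_fit} with components
#'   \code{coefficients} (\code{I0}, \code{rate} in \eqn{s^{-1}}),
#'   \code{fitted.values}, \code{residuals}, \code{sse}, \code{converged},
#'   and the input series. Use \code{\link{monte_carlo_rate_error}} for the
#'   rate uncertainty.
#' @examples
#' tt <- default_r1_delays()
#' fit <- fit_decay(list(t = tt, I = 100 * exp(-1.5 * tt)))
#' coef(fit)
#' @export
fit_decay <- function(series, noise = NULL, residue = NULL) {
  if (inherits(series, "peak_table")) {
    stopifnot(!is.null(residue))
    series <- decay_series(series, residue)
  }
  t <- series$t; I <- series$I
  stopifnot(length(t) == length(I))
  if (length(unique(t)) < 3L)
    stop_foxdyn("decay fit needs >= 3 distinct delays",
                "foxdyn_precondition_error")
  if (all(I == 0))
    stop_foxdyn("all intensities are zero", "foxdyn_precondition_error")
  res <- exp_decay_batch(t, matrix(I, nrow = 1L))
  cf <- c(I0 = res$I0[1L], rate = res$R[1L])
  fitted <- cf[["I0"]] * exp(-cf[["rate"]] * t)
  structure(list(coefficients = cf,
                 t = t, I = I,
                 residue = series$residue %||% NA_integer_,
                 duplicate_pairs = series$duplicate_pairs,
                 fitted.values = fitted,
                 residuals = I - fitted,
                 sse = res$sse[1L],
                 converged = res$converged[1L],
                 noise = noise),
            class = "decay_fit")
}

#' @method coef decay_fit
#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @method residuals decay_fit
#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @rdname fit_decay
#' @param object,x a \code{decay_fit}.
#' @param newdata optional numeric vector of delays (s) at which to evaluate
#'   the fitted decay.
#' @param ... unused.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$t else as.numeric(newdata)
  object$coefficients[["I0"]] * exp(-object$coefficients[["rate"]] * t)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential relaxation decay fit",
      if (!is.na(x$residue)) sprintf("(residue %d)", x$residue), "\n")
  cat(sprintf("  I0   = %.6g\n  rate = %.6g s^-1\n",
              x$coefficients[["I0"]], x$coefficients[["rate"]]))
  if (!is.null(x$mc))
    cat(sprintf("  rate error: sigma = %.4g s^-1, 2*sigma = %.4g s^-1 (n_mc = %d)\n",
                x$mc$sigma_rate, x$mc$ci95, x$mc$n_mc_used))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @method summary decay_fit
#' @export
summary.decay_fit <- function(object, ...) {
  structure(list(fit = object,
                 n = length(object$t),
                 n_distinct_delays = length(unique(object$t)),
                 rmsd = sqrt(object$sse / length(object$t))),
            class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d points over %d distinct delays; residual rmsd %.4g\n",
              x$n, x$n_distinct_delays, x$rmsd))
  invisible(x)
}

#' @rdname fit_decay
#' @method plot decay_fit
#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$t, x$I, xlab = "delay (s)", ylab = "intensity",
       main = if (!is.na(x$residue))
         sprintf("residue %d", x$residue) else "decay fit", ...)
  tt <- seq(min(x$t), max(x$t), length.out = 200)
  lines(tt, predict(x, tt))
  invisible(x)
}

#' Simulate synthetic intensity sets from a fitted decay
#'
#' Draws replicate datasets around the \emph{measured} intensities, the
#' resampling scheme of the Monte-Carlo error analysis: each point is drawn
#' from a normal with the measured value as centre and
#' \code{width_factor * sigma} as width.
#'
#' @param object a \code{\link{fit_decay}} result.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed (required for reproducibility).
#' @param width_factor multiple of the noise used as resampling width.
#' @param sigma noise level; defaults to the stored noise estimate.
#' @param ... unused.
#' @return A matrix with \code{nsim} rows, one replicate intensity set each.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = 1L,
                               width_factor = 2, sigma = NULL, ...) {
  sigma <- sigma %||% object$noise$sigma
  if (is.null(sigma))
    stop_foxdyn("no noise estimate available for simulation",
                "foxdyn_precondition_error")
  m <- length(object$t)
  with_seed(seed, {
    matrix(rnorm(nsim * m, mean = rep(object$I, each = nsim),
                 sd = width_factor * sigma), nrow = nsim)
  })
}

#' Monte-Carlo error of a fitted relaxation rate
#'
#' For each of \code{n_mc} replicates every intensity is resampled from a
#' normal centred at the measured value with width
#' \code{width_factor * noise$sigma}; the exponential fit is repeated on each
#' replicate and the rate error is obtained by fitting the histogram of
#' best-fit rates (30 bins spanning the mean +/- 5 sample SD) to a
#' three-parameter normal \eqn{A\exp(-(x-\mu)^2/2\sigma^2)}. The reported
#' \code{ci95} is \eqn{2\sigma}. If the histogram fit fails the sample SD is
#' used. The default \code{width_factor = 2} deliberately reproduces the
#' conservative stacking of the original error model (resampling at twice
#' the pooled noise \emph{and} reporting \eqn{2\sigma}).
#'
#' @param fit a converged \code{\link{fit_decay}} result.
#' @param noise a \code{\link{estimate_pooled_noise}} result (or the stored
#'   one).
#' @param n_mc number of replicates (>= 2; default 1000).
#' @param width_factor resampling width as a multiple of the noise.
#' @param seed RNG seed; the result is a pure function of
#'   (fit, noise, n_mc, width_factor, seed).
#' @param max_fail_frac maximum tolerated fraction of failed replicate fits.
#' @return List with \code{sigma_rate}, \code{ci95} (= 2 sigma),
#'   \code{n_mc_used}, \code{n_failed}, \code{method} ("histogram" or
#'   "sample_sd"), \code{rates} (the replicate estimates) and the normal-fit
#'   parameters \code{mu} and \code{amplitude} when available.
#' @export
monte_carlo_rate_error <- function(fit, noise = NULL, n_mc = 1000L,
                                   width_factor = 2, seed = 1L,
                                   max_fail_frac = 0.2) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!fit$converged)
    stop_foxdyn("decay fit did not converge; no error estimate",
                "foxdyn_precondition_error")
  noise <- noise %||% fit$noise
  if (is.null(noise))
    stop_foxdyn("a noise estimate is required", "foxdyn_precondition_error")
  if (!is_count(n_mc) || n_mc < 2)
    stop_foxdyn("n_mc must be an integer >= 2", "foxdyn_precondition_error")
  Y <- simulate(fit, nsim = n_mc, seed = seed, width_factor = width_factor,
                sigma = noise$sigma)
  res <- exp_decay_batch(fit$t, Y)
  ok <- res$converged
  n_failed <- sum(!ok)
  if (n_failed > max_fail_frac * n_mc)
    stop_foxdyn(sprintf("error estimation failed: %d/%d replicate fits did not converge",
                        n_failed, n_mc), "foxdyn_mc_failure")
  rates <- res$R[ok]
  out <- fit_rate_histogram(rates)
  c(out, list(n_mc_used = length(rates), n_failed = n_failed, rates = rates))
}

# Normal fit to the histogram of Monte-Carlo rates; sample SD fallback.
fit_rate_histogram <- function(rates) {
  mu0 <- mean(rates); sd0 <- sd(rates)
  if (!is.finite(sd0) || sd0 < 1e-12 * max(1, abs(mu0)))
    return(list(sigma_rate = 0, ci95 = 0, mu = mu0, amplitude = NA_real_,
                method = "sample_sd"))
  breaks <- seq(mu0 - 5 * sd0, mu0 + 5 * sd0, length.out = 31L)
  rates_in <- rates[rates >= breaks[1] & rates <= breaks[31]]
  h <- hist(rates_in, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                      start = list(A = max(h$counts), mu = mu0, s = sd0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    list(sigma_rate = sd0, ci95 = 2 * sd0, mu = mu0, amplitude = NA_real_,
         method = "sample_sd")
  } else {
    cf <- coef(fit)
    s <- abs(unname(cf[["s"]]))
    list(sigma_rate = s, ci95 = 2 * s, mu = unname(cf[["mu"]]),
         amplitude = unname(cf[["A"]]), method = "histogram")
  }
}

#' Linearised least-squares rate uncertainty
#'
#' First-order (delta-method) standard error of the fitted rate: with
#' Jacobian \eqn{J} of the exponential model at the fitted parameters and
#' iid intensity noise \eqn{\sigma}, the parameter covariance is
#' \eqn{\sigma^2 (J^T J)^{-1}}. Serves as an analytic cross-check of the
#' Monte-Carlo error.
#'
#' @param fit a converged \code{\link{fit_decay}} result.
#' @param sigma intensity noise standard deviation (use
#'   \code{width_factor * noise$sigma} to match the Monte-Carlo resampling
#'   width).
#' @return Standard error of the rate (\eqn{s^{-1}}).
#' @export
linearized_rate_sigma <- function(fit, sigma) {
  stopifnot(inherits(fit, "decay_fit"))
  I0 <- fit$coefficients[["I0"]]; R <- fit$coefficients[["rate"]]
  E <- exp(-R * fit$t)
  J <- cbind(E, -I0 * fit$t * E)
  covm <- sigma^2 * solve(crossprod(J))
  sqrt(covm[2, 2])
}

# ---------------------------------------------------------------------------

#' Spin-lock context for the tilted-field correction
#'
#' @param spinlock_khz spin-lock field strength \eqn{\omega_1/2\pi} in kHz.
#' @param offset_hz resonance offset \eqn{\Omega/2\pi} in Hz (vector, one
#'   per residue); 0 means on-resonance.
#' @return List of class \code{spinlock_context} with \code{omega1} (rad/s),
#'   \code{omega_offset} (rad/s) and the tilt angle \code{theta}
#'   (rad, in (0, pi/2]), \eqn{\theta = \arctan(\omega_1/\Omega)}.
#' @export
spinlock_context <- function(spinlock_khz, offset_hz = 0) {
  if (!is.numeric(spinlock_khz) || spinlock_khz <= 0)
    stop_foxdyn("spin-lock field strength must be > 0",
                "foxdyn_precondition_error")
  omega1 <- 2 * pi * 1e3 * spinlock_khz
  omega_off <- 2 * pi * offset_hz
  theta <- ifelse(omega_off == 0, pi / 2, atan(omega1 / abs(omega_off)))
  structure(list(omega1 = omega1, omega_offset = omega_off, theta = theta),
            class = "spinlock_context")
}

#' Off-resonance tilted-field correction R1rho -> R2
#'
#' \deqn{R_2 = R_{1\rho}/\sin^2\theta - R_1/\tan^2\theta,}
#' with \eqn{\theta = \arctan(\omega_1/\Omega)}; on resonance
#' (\eqn{\Omega = 0}, \eqn{\theta = \pi/2}) this reduces to
#' \eqn{R_2 = R_{1\rho}}.
#'
#' @param r1rho rotating-frame relaxation rate(s), \eqn{s^{-1}}.
#' @param r1 longitudinal relaxation rate(s), \eqn{s^{-1}}.
#' @param ctx a \code{\link{spinlock_context}} (or a numeric vector of tilt
#'   angles in radians).
#' @return \eqn{R_2} in \eqn{s^{-1}}, vectorised over residues.
#' @export
r1rho_to_r2 <- function(r1rho, r1, ctx) {
  theta <- if (inherits(ctx, "spinlock_context")) ctx$theta else as.numeric(ctx)
  if (any(theta <= 0 | theta > pi / 2))
    stop_foxdyn("tilt angle theta must lie in (0, pi/2]",
                "foxdyn_precondition_error")
  r1rho / sin(theta)^2 - r1 / tan(theta)^2
}

#' Steady-state heteronuclear NOE with propagated error
#'
#' \eqn{\mathrm{NOE} = I_{sat}/I_{ref}}; the uncertainty follows from the
#' intensity noise of both planes,
#' \eqn{\sigma_{NOE} = |NOE|\sqrt{(\sigma/I_{sat})^2 + (\sigma/I_{ref})^2}}
#' (the saturated term is dropped when \eqn{I_{sat} = 0}).
#'
#' @param sat intensity in the saturated plane (vector).
#' @param ref intensity in the reference plane (vector, > 0).
#' @param noise a \code{\link{estimate_pooled_noise}} result or a numeric
#'   noise sigma.
#' @return Data frame with columns \code{value} and \code{sigma}.
#' @export
compute_hetnoe <- function(sat, ref, noise) {
  sigma <- if (inherits(noise, "noise_estimate")) noise$sigma else
    as.numeric(noise)
  if (any(ref <= 0))
    stop_foxdyn("reference intensity must be > 0", "foxdyn_invalid_reference")
  value <- sat / ref
  err <- ifelse(sat == 0, sigma / ref,
                abs(value) * sqrt((sigma / sat)^2 + (sigma / ref)^2))
  data.frame(value = value, sigma = err)
}

#' Classify backbone flexibility from a heteronuclear NOE value
#'
#' Bands follow the usual reading of steady-state \eqn{^{15}}N\{\eqn{^1}H\}
#' NOE values for amide bond vectors: above 0.5 the residue sits in a stable
#' structural element ("ordered"), negative values indicate rapid ps-ns
#' motions ("highly_flexible"), the closed interval [0, 0.5] in between is
#' "intermediate".
#'
#' @param value NOE value(s) (finite).
#' @param ordered_min lower (exclusive) bound of the ordered band.
#' @param flexible_max upper (exclusive) bound of the highly flexible band.
#' @return Factor with levels \code{ordered}, \code{intermediate},
#'   \code{highly_flexible}.
#' @export
classify_flexibility <- function(value, ordered_min = 0.5, flexible_max = 0) {
  stopifnot(all(is.finite(value)))
  band <- ifelse(value > ordered_min, "ordered",
                 ifelse(value < flexible_max, "highly_flexible",
                        "intermediate"))
  factor(band, levels = c("ordered", "intermediate", "highly_flexible"))
}

#' Fit all residues of a relaxation peak table
#'
#' Convenience wrapper: extracts each residue's decay series, fits the
#' exponential, and attaches Monte-Carlo rate errors. Residues whose fit or
#' error estimation fails are flagged rather than aborting the run.
#'
#' @param table a \code{\link{peak_table}} (kind T1 or T1rho).
#' @param noise a \code{\link{estimate_pooled_noise}} result; estimated from
#'   the table's duplicated delays when omitted.
#' @param config a \code{\link{run_config}} (supplies \code{n_mc},
#'   \code{mc_width_factor}, \code{seed}).
#' @param mc whether to run the Monte-Carlo error analysis.
#' @return Data frame with one row per residue: \code{residue}, \code{rate},
#'   \code{sigma_rate}, \code{ci95}, \code{i0}, \code{converged},
#'   \code{mc_method}.
#' @export
fit_relaxation <- function(table, noise = NULL, config = run_config(),
                           mc = TRUE) {
  stopifnot(inherits(table, "peak_table"))
  noise <- noise %||% estimate_pooled_noise(table)
  residues <- sort(unique(table$residue))
  out <- data.frame(residue = residues, rate = NA_real_,
                    sigma_rate = NA_real_, ci95 = NA_real_, i0 = NA_real_,
                    converged = FALSE, mc_method = NA_character_)
  for (i in seq_along(residues)) {
    fit <- tryCatch(fit_decay(table, noise, residue = residues[i]),
                    foxdyn_error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    out$rate[i] <- fit$coefficients[["rate"]]
    out$i0[i] <- fit$coefficients[["I0"]]
    out$converged[i] <- TRUE
    if (mc) {
      err <- tryCatch(
        monte_carlo_rate_error(fit, noise, n_mc = config$n_mc,
                               width_factor = config$mc_width_factor,
                               seed = config$seed + i),
        foxdyn_error = function(e) NULL)
      if (!is.null(err)) {
        out$sigma_rate[i] <- err$sigma_rate
        out$ci95[i] <- err$ci95
        out$mc_method[i] <- err$method
      }
    }
  }
  out
}

#' Full relaxation analysis of one protein state
#'
#' Chains the per-residue fits of the longitudinal (\eqn{R_1}) and
#' rotating-frame (\eqn{R_{1\rho}}) series, the tilted-field conversion to
#' \eqn{R_2}, the heteronuclear NOE with its propagated error, and the
#' flexibility classification.
#'
#' @param r1_table,r1rho_table \code{\link{peak_table}}s of kinds T1/T1rho.
#' @param sat_table,ref_table optional hetNOE \code{\link{peak_table}}s
#'   (saturated / reference planes; one row per residue).
#' @param config a \code{\link{run_config}}.
#' @param offset_hz per-residue \eqn{^{15}}N resonance offsets in Hz, in the
#'   order of the common residues; alternatively supply \code{shifts} plus
#'   \code{config$carrier_n_ppm}.
#' @param shifts optional \code{\link{shift_table}} used (with the
#'   configured carrier) to compute offsets from nitrogen shifts.
#' @return Data frame with per-residue columns \code{R1}, \code{R1_err},
#'   \code{R1rho}, \code{R1rho_err}, \code{R2}, \code{R2_err},
#'   \code{hetNOE}, \code{hetNOE_err}, \code{flexibility_band}.
#' @export
relaxation_analysis <- function(r1_table, r1rho_table, sat_table = NULL,
                                ref_table = NULL, config = run_config(),
                                offset_hz = 0, shifts = NULL) {
  r1 <- fit_relaxation(r1_table, config = config)
  r1rho <- fit_relaxation(r1rho_table, config = config)
  residues <- intersect(r1$residue, r1rho$residue)
  r1 <- r1[match(residues, r1$residue), ]
  r1rho <- r1rho[match(residues, r1rho$residue), ]
  if (!is.null(shifts)) {
    if (!is.finite(config$carrier_n_ppm))
      stop_foxdyn("carrier_n_ppm must be set to derive offsets from shifts",
                  "foxdyn_precondition_error")
    # 15N Larmor frequency from the proton field via the gyromagnetic ratio.
    nu_n_mhz <- config$b0_proton_mhz * 0.101329118
    dN <- shifts$dN[match(residues, shifts$residue)]
    offset_hz <- (dN - config$carrier_n_ppm) * nu_n_mhz
    offset_hz[!is.finite(offset_hz)] <- 0
  }
  ctx <- spinlock_context(config$spinlock_khz, offset_hz)
  r2 <- r1rho_to_r2(r1rho$rate, r1$rate, ctx)
  # Error propagation through the (linear) tilted-field correction.
  theta <- if (length(ctx$theta) == 1L) rep(ctx$theta, length(residues)) else
    ctx$theta
  r2_err <- sqrt((r1rho$sigma_rate * 2 / sin(theta)^2)^2 +
                 (r1$sigma_rate * 2 / tan(theta)^2)^2) / 2
  out <- data.frame(residue = residues,
                    R1 = r1$rate, R1_err = r1$ci95,
                    R1rho = r1rho$rate, R1rho_err = r1rho$ci95,
                    R2 = r2, R2_err = 2 * r2_err,
                    hetNOE = NA_real_, hetNOE_err = NA_real_,
                    flexibility_band = NA_character_)
  if (!is.null(sat_table) && !is.null(ref_table)) {
    noise <- estimate_pooled_noise(r1_table)
    sat <- sat_table$intensity[match(residues, sat_table$residue)]
    ref <- ref_table$intensity[match(residues, ref_table$residue)]
    keep <- is.finite(sat) & is.finite(ref) & ref > 0
    noe <- compute_hetnoe(sat[keep], ref[keep], noise)
    out$hetNOE[keep] <- noe$value
    out$hetNOE_err[keep] <- noe$sigma
    out$flexibility_band[keep] <-
      as.character(classify_flexibility(noe$value))
  }
  out
}
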