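# MSD estimation with overlapping time intervals, random-walk model fitting,
# AICc-based model selection, and motility-parameter extraction.
#
# The three candidate models (2D, tau in minutes, MSD in um^2):
#   constrained  MSD(tau) = R^2 (1 - exp(-4 Dc tau / R^2))      k = 2 (Dc, R)
#   brownian     MSD(tau) = 4 D tau                             k = 1 (D)
#   prw          MSD(tau) = 2 v^2 P^2 (tau/P - (1 - e^{-tau/P}))k = 2 (v, P)
# plus the descriptive power law MSD = A tau^alpha (not part of selection).

.msd_model_names <- c("constrained", "brownian", "prw", "powerlaw")

#' MSD model specification
#'
#' @param name One of `"constrained"`, `"brownian"`, `"prw"`, `"powerlaw"`.
#' @return A list with the model name, free-parameter count `k`, parameter
#'   names/units, and positive box bounds used during fitting.
#' @export
msd_model_spec <- function(name = .msd_model_names) {
  name <- match.arg(name)
  switch(name,
    constrained = list(name = name, k = 2L, params = c("Dc", "R"),
                       units = c(Dc = "um^2/min", R = "um"),
                       lower = c(Dc = 1e-9, R = 1e-6),
                       upper = c(Dc = 1e9, R = 1e6)),
    brownian    = list(name = name, k = 1L, params = "D",
                       units = c(D = "um^2/min"),
                       lower = c(D = 1e-12), upper = c(D = 1e9)),
    prw         = list(name = name, k = 2L, params = c("v", "P"),
                       units = c(v = "um/min", P = "min"),
                       lower = c(v = 1e-9, P = 1e-6),
                       upper = c(v = 1e6, P = 1e9)),
    powerlaw    = list(name = name, k = 2L, params = c("A", "alpha"),
                       units = c(A = "um^2/min^alpha", alpha = ""),
                       lower = c(A = 1e-12, alpha = 1e-6),
                       upper = c(A = 1e12, alpha = 2)))
}

#' Evaluate an MSD model at given lag times
#'
#' Numerically stable across extreme regimes (`expm1`-based evaluation of the
#' exponential terms), valid for `tau/P` and `4 Dc tau / R^2` anywhere in
#' `[1e-6, 1e6]`.
#'
#' @param name Model name (see [msd_model_spec]).
#' @param params Named numeric parameters (positive; `alpha` in (0, 2]).
#' @param lags Positive lag times, minutes.
#' @return MSD values, um^2.
#' @export
eval_msd_model <- function(name, params, lags) {
  name <- match.arg(name, .msd_model_names)
  spec <- msd_model_spec(name)
  p <- params[spec$params]
  if (anyNA(p) || any(p <= 0))
    stop("eval_msd_model: parameters must be positive and named (",
         paste(spec$params, collapse = ", "), ")", call. = FALSE)
  if (name == "powerlaw" && p[["alpha"]] > 2)
    stop("eval_msd_model: alpha must lie in (0, 2]", call. = FALSE)
  if (any(lags <= 0))
    stop("eval_msd_model: lags must be positive", call. = FALSE)
  switch(name,
    brownian = 4 * p[["D"]] * lags,
    constrained = {
      R2 <- p[["R"]]^2
      R2 * (-expm1(-4 * p[["Dc"]] * lags / R2))
    },
    prw = {
      x <- lags / p[["P"]]
      # tau/P - (1 - e^{-tau/P}) = x + expm1(-x)
      2 * p[["v"]]^2 * p[["P"]]^2 * (x + expm1(-x))
    },
    powerlaw = p[["A"]] * lags^p[["alpha"]])
}

#' Per-track MSD using overlapping time intervals
#'
#' For each lag `k*dt` with `k = 1 .. floor(max_lag_fraction * (n-1))`,
#' averages `|r(i+k) - r(i)|^2` over all `n - k` overlapping index pairs.
#'
#' @param track A uniformly sampled [cell_track] with at least 3 points.
#' @param max_lag_fraction Fraction of the maximal lag to retain (default 1).
#' @return An object of class `msd_curve`: list with `track_id`, `lags`
#'   (minutes), `msd` (um^2), `n_pairs`, `frame_interval`, `condition`, and
#'   `fitted_window` (NA until [truncate_for_fit]).
#' @export
compute_msd <- function(track, max_lag_fraction = 1.0) {
  stopifnot(inherits(track, "cell_track"))
  n <- length(track$t)
  if (n < 3L)
    stop("compute_msd: degenerate track (< 3 points)", call. = FALSE)
  if (!is_uniform_track(track))
    stop("compute_msd: track has gaps; apply_track_filters first",
         call. = FALSE)
  stopifnot(max_lag_fraction > 0, max_lag_fraction <= 1)
  K <- max(1L, as.integer(floor(max_lag_fraction * (n - 1L))))
  msd <- numeric(K)
  for (k in seq_len(K)) {
    dx <- track$x[(1L + k):n] - track$x[1L:(n - k)]
    dy <- track$y[(1L + k):n] - track$y[1L:(n - k)]
    msd[k] <- mean(dx * dx + dy * dy)
  }
  structure(list(track_id = track$track_id, condition = track$condition,
                 lags = seq_len(K) * track$frame_interval, msd = msd,
                 n_pairs = n - seq_len(K),
                 frame_interval = track$frame_interval,
                 fitted_window = NA_integer_),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %s: %d lags (dt = %g min), fitted_window = %s\n",
              x$track_id, length(x$lags), x$frame_interval,
              ifelse(is.na(x$fitted_window), "unset", x$fitted_window)))
  invisible(x)
}

#' Select the initial portion of an MSD curve for fitting
#'
#' Model fits use only the leading `floor(fraction * K)` lags of the K-lag
#' curve (default the initial 40%), clamped below at `k_max + 2 = 4` points so
#' that the AICc denominator stays positive for the largest (2-parameter)
#' candidate model. The full curve is preserved; only `fitted_window` is set.
#'
#' @param curve An `msd_curve`.
#' @param fraction Leading fraction of lags to fit (default 0.4).
#' @return The curve with `fitted_window` set.
#' @export
truncate_for_fit <- function(curve, fraction = 0.4) {
  stopifnot(inherits(curve, "msd_curve"), fraction > 0, fraction <= 1)
  K <- length(curve$lags)
  k_min <- 4L  # largest candidate model has k = 2 -> needs k + 2 points
  if (K < k_min)
    stop("truncate_for_fit: curve too short (", K, " lags < ", k_min, ")",
         call. = FALSE)
  curve$fitted_window <- max(k_min, as.integer(floor(fraction * K)))
  curve
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)`, with `n` the number of MSD
#' points in the fitted window and `k` the number of free parameters. An exact
#' fit (`rss = 0`) maps to `-Inf` (flagged upstream); `n <= k + 1` is an
#' error (zero/negative denominator).
#'
#' @param rss Residual sum of squares (um^4), non-negative.
#' @param n_points Number of fitted MSD points.
#' @param k Number of free model parameters.
#' @return AICc value (dimensionless), `-Inf` when `rss == 0`.
#' @export
aicc <- function(rss, n_points, k) {
  stopifnot(is.numeric(rss), rss >= 0, n_points == round(n_points),
            k == round(k), k >= 1)
  if (n_points <= k + 1)
    stop("aicc: undefined for n_points <= k + 1 (denominator n - k - 1 <= 0)",
         call. = FALSE)
  if (rss == 0) return(-Inf)
  n_points * log(rss / n_points) + 2 * k + 2 * k * (k + 1) / (n_points - k - 1)
}

# Deterministic data-driven multi-start initializers (no RNG in fitting).
.fit_starts <- function(name, tau, y, dt) {
  slope1 <- max(y[1L] / tau[1L], 1e-9)
  switch(name,
    brownian = list(c(D = slope1 / 4)),
    constrained = {
      R0 <- sqrt(max(max(y), 1e-9))
      list(c(Dc = slope1 / 4, R = R0),
           c(Dc = slope1 / 4, R = R0 * 2),
           c(Dc = slope1 / 20, R = R0),
           c(Dc = slope1, R = R0))
    },
    prw = {
      v0 <- max(sqrt(max(y[1L], 1e-12)) / tau[1L], 1e-6)
      list(c(v = v0, P = dt), c(v = v0, P = 5 * dt), c(v = v0, P = 25 * dt))
    },
    powerlaw = {
      ok <- y > 0
      st <- if (sum(ok) >= 2) {
        cf <- stats::coef(stats::lm(log(y[ok]) ~ log(tau[ok])))
        c(A = exp(unname(cf[1L])),
          alpha = min(max(unname(cf[2L]), 0.05), 2))
      } else c(A = slope1, alpha = 1)
      list(st, c(A = slope1, alpha = 1),
           c(A = max(y[1L], 1e-9) / tau[1L]^2, alpha = 2))
    })
}

#' Fit one MSD model to a truncated MSD curve
#'
#' Bounded nonlinear least squares in linear MSD space over the fitted window
#' (unweighted by default, matching an RSS-minimization workflow; per-lag
#' weights `n_pairs` available via `weighted = TRUE`). Brownian has a
#' closed-form solution; the two-parameter models use `nlminb` in
#' log-parameter space from at least 3 deterministic data-driven starts.
#'
#' @param curve An `msd_curve` with `fitted_window` set ([truncate_for_fit]).
#' @param model Model name.
#' @param weighted Use `n_pairs` as least-squares weights (default `FALSE`).
#' @return An object of class `msd_fit`: `track_id`, `model`, `params`
#'   (named, with units per [msd_model_spec]), `rss`, `n_points`, `aicc`,
#'   `converged`, `n_starts_used`, `exact_fit`.
#' @export
fit_msd_model <- function(curve, model = .msd_model_names, weighted = FALSE) {
  stopifnot(inherits(curve, "msd_curve"))
  model <- match.arg(model)
  if (is.na(curve$fitted_window))
    stop("fit_msd_model: call truncate_for_fit() first", call. = FALSE)
  w <- curve$fitted_window
  tau <- curve$lags[seq_len(w)]
  y <- curve$msd[seq_len(w)]
  wt <- if (weighted) curve$n_pairs[seq_len(w)] else rep(1, w)
  spec <- msd_model_spec(model)
  if (w < spec$k + 2L)
    stop("fit_msd_model: fitted window too small for model ", model,
         call. = FALSE)
  scale2 <- sum(wt * y^2)

  if (model == "brownian") {
    D <- sum(wt * y * tau) / (4 * sum(wt * tau^2))
    D <- min(max(D, spec$lower[["D"]]), spec$upper[["D"]])
    params <- c(D = D)
    rss <- sum(wt * (y - 4 * D * tau)^2)
    conv <- TRUE; nst <- 1L
  } else {
    # optimize log-parameters (alpha stays linear, box-bounded)
    to_theta <- function(p) {
      if (model == "powerlaw") c(log(p[["A"]]), p[["alpha"]])
      else log(unname(p[spec$params]))
    }
    from_theta <- function(th) {
      if (model == "powerlaw") setNames(c(exp(th[1L]), th[2L]), spec$params)
      else setNames(exp(th), spec$params)
    }
    obj <- function(th) {
      p <- from_theta(th)
      sum(wt * (eval_msd_model(model, p, tau) - y)^2)
    }
    lo <- if (model == "powerlaw") c(log(spec$lower[["A"]]), spec$lower[["alpha"]])
          else log(unname(spec$lower))
    hi <- if (model == "powerlaw") c(log(spec$upper[["A"]]), spec$upper[["alpha"]])
          else log(unname(spec$upper))
    best <- NULL
    nst <- 0L
    for (st in .fit_starts(model, tau, y, curve$frame_interval)) {
      nst <- nst + 1L
      fit <- tryCatch(
        stats::nlminb(to_theta(st), obj, lower = lo, upper = hi,
                      control = list(iter.max = 500, eval.max = 1000)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    if (is.null(best)) {
      return(structure(list(track_id = curve$track_id, model = model,
                            params = setNames(rep(NA_real_, spec$k),
                                              spec$params),
                            rss = NA_real_, n_points = w, aicc = Inf,
                            converged = FALSE, n_starts_used = nst,
                            exact_fit = FALSE),
                       class = "msd_fit"))
    }
    params <- from_theta(best$par)
    rss <- best$objective
    conv <- TRUE
  }

  exact <- rss <= max(1e-12 * scale2, 1e-300)
  ai <- if (exact) -Inf else aicc(rss, w, spec$k)
  structure(list(track_id = curve$track_id, model = model, params = params,
                 rss = rss, n_points = w, aicc = ai, converged = conv,
                 n_starts_used = nst, exact_fit = exact),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> %s ~ %s: %s | rss = %.4g, n = %d, AICc = %.4g%s\n",
              x$track_id, x$model,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$rss, x$n_points, x$aicc,
              if (isTRUE(x$exact_fit)) " (exact fit)" else ""))
  invisible(x)
}

#' Descriptive power-law fit of an MSD curve
#'
#' Fits `MSD = A tau^alpha` over the fitted window. The diffusion exponent
#' `alpha` is reported per track but the power law takes no part in model
#' selection (a Brownian curve gives `alpha = 1`, ballistic motion
#' `alpha = 2`, confinement averaged over the window `alpha < 1`).
#'
#' @inheritParams fit_msd_model
#' @return An `msd_fit` for the power law.
#' @export
fit_power_law <- function(curve, weighted = FALSE) {
  fit_msd_model(curve, "powerlaw", weighted = weighted)
}

.selection_order <- c(brownian = 1L, constrained = 2L, prw = 3L)

#' Classify a track by AICc among the three random-walk models
#'
#' Fits the constrained, Brownian, and persistent random-walk models to the
#' truncated MSD curve and selects the minimum-AICc model. Ties within 1e-9
#' (including double exact fits) are broken toward fewer parameters, then the
#' fixed order brownian < constrained < prw. Persistence speed and time are
#' populated only when the persistent model wins; the random motility
#' coefficient `rmc` is always the Brownian-fit D.
#'
#' @param curve An `msd_curve`; if `fitted_window` is unset, the default 40%
#'   truncation is applied.
#' @param fit_fraction Truncation fraction used when the window is unset.
#' @param weighted Passed to [fit_msd_model].
#' @return An object of class `track_classification`: `track_id`,
#'   `best_model` (or `"unclassified"`), `delta_aicc` (named, 0 at the best
#'   model), `params_best`, `persistence_speed`, `persistence_time`, `rmc`,
#'   and the full `fits` list.
#' @export
classify_track <- function(curve, fit_fraction = 0.4, weighted = FALSE) {
  stopifnot(inherits(curve, "msd_curve"))
  if (is.na(curve$fitted_window))
    curve <- truncate_for_fit(curve, fit_fraction)
  models <- c("brownian", "constrained", "prw")
  fits <- lapply(models, function(m)
    fit_msd_model(curve, m, weighted = weighted))
  names(fits) <- models
  ai <- vapply(fits, `[[`, numeric(1), "aicc")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv)) {
    cls <- structure(
      list(track_id = curve$track_id, condition = curve$condition,
           best_model = "unclassified",
           delta_aicc = setNames(rep(NA_real_, 3L), models),
           params_best = NULL, persistence_speed = NA_real_,
           persistence_time = NA_real_, rmc = NA_real_, fits = fits),
      class = "track_classification")
    return(cls)
  }
  ai[!conv] <- Inf
  lo <- min(ai)
  tied <- if (is.finite(lo)) which(ai - lo <= 1e-9) else which(ai == lo)
  ks <- vapply(models[tied], function(m) msd_model_spec(m)$k, integer(1))
  tied <- tied[ks == min(ks)]
  best <- models[tied[order(.selection_order[models[tied]])][1L]]
  delta <- ai - lo
  delta[best] <- 0  # exact 0 even for -Inf ties
  bf <- fits[[best]]
  structure(
    list(track_id = curve$track_id, condition = curve$condition,
         best_model = best, delta_aicc = delta, params_best = bf$params,
         persistence_speed = if (best == "prw") bf$params[["v"]] else NA_real_,
         persistence_time = if (best == "prw") bf$params[["P"]] else NA_real_,
         rmc = if (fits$brownian$converged) fits$brownian$params[["D"]]
               else NA_real_,
         fits = fits),
    class = "track_classification")
}

#' @export
print.track_classification <- function(x, ...) {
  cat(sprintf("<track_classification> %s -> %s", x$track_id, x$best_model))
  if (!is.null(x$params_best))
    cat(": ", paste(sprintf("%s = %.4g", names(x$params_best), x$params_best),
                    collapse = ", "), sep = "")
  cat(sprintf(" | rmc = %.4g\n", x$rmc))
  invisible(x)
}

#' Derive motility parameters from a classification
#'
#' The random motility coefficient `rmc` is the Brownian-fit D (always
#' reported when that fit converged). The model-specific effective coefficient
#' is `D` for Brownian, `Dc` for constrained, and `v^2 P / 2` for the
#' persistent walk (its long-lag MSD slope is `2 v^2 P = 4 D_eff` in 2D).
#'
#' @param classification A `track_classification`.
#' @return A one-row data.frame: `track_id`, `condition`, `best_model`,
#'   `rmc`, `effective_coefficient`, `persistence_speed`, `persistence_time`.
#' @export
derive_motility <- function(classification) {
  stopifnot(inherits(classification, "track_classification"))
  cls <- classification
  eff <- NA_real_
  if (cls$best_model != "unclassified" && !is.null(cls$params_best)) {
    p <- cls$params_best
    eff <- switch(cls$best_model,
                  brownian = p[["D"]],
                  constrained = p[["Dc"]],
                  prw = p[["v"]]^2 * p[["P"]] / 2)
  }
  data.frame(track_id = cls$track_id, condition = cls$condition,
             best_model = cls$best_model, rmc = cls$rmc,
             effective_coefficient = eff,
             persistence_speed = cls$persistence_speed,
             persistence_time = cls$persistence_time,
             stringsAsFactors = FALSE)
}

#' Classify every track in a collection
#'
#' Convenience wrapper: computes each track's MSD, truncates, classifies, and
#' returns the classification objects.
#'
#' @param tracks A [track_collection] (uniformly sampled).
#' @param max_lag_fraction Passed to [compute_msd].
#' @param fit_fraction Passed to [truncate_for_fit].
#' @param weighted Passed to [fit_msd_model].
#' @return A named list of `track_classification` objects.
#' @export
classify_tracks <- function(tracks, max_lag_fraction = 1.0,
                            fit_fraction = 0.4, weighted = FALSE) {
  stopifnot(inherits(tracks, "track_collection"))
  lapply(tracks$tracks, function(tr) {
    curve <- truncate_for_fit(compute_msd(tr, max_lag_fraction), fit_fraction)
    classify_track(curve, weighted = weighted)
  })
}
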