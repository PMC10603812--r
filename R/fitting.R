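# Fitting the crowding model to reduced folding data. nu and chi are fixed
# from binary-solution measurements; epsilon is the only free parameter of
# the free-energy fit, and epsilon_TS the only free parameter of the
# enthalpy-entropy fit. Uncertainties come from seeded residual-resampling
# bootstrap.

new_fit_result <- function(parameter, estimate, data, fitted, residuals,
                           ci = NULL, B = 0, seed = NA_integer_,
                           level = NA_real_, converged = TRUE,
                           multimodal = FALSE) {
  structure(
    list(parameter = parameter, estimate = estimate,
         ci_level = level,
         ci_low = if (is.null(ci)) NA_real_ else ci[[1]],
         ci_high = if (is.null(ci)) NA_real_ else ci[[2]],
         data = data, fitted = fitted, residuals = residuals,
         B = B, seed = seed, converged = converged, multimodal = multimodal,
         method = "bounded scalar least squares; residual-resampling percentile bootstrap"),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$parameter, "\n", sep = "")
  cat(sprintf("  estimate = %.5f", x$estimate))
  if (is.finite(x$ci_low)) {
    cat(sprintf("  [%.0f%% CI %.5f, %.5f; B = %d, seed = %s]",
                100 * x$ci_level, x$ci_low, x$ci_high, x$B, x$seed))
  }
  cat("\n")
  cat(sprintf("  RMS residual = %.4g kJ/mol on %d points%s%s\n",
              sqrt(mean(x$residuals^2)), length(x$residuals),
              if (x$converged) "" else "; NOT converged (estimate at bound)",
              if (x$multimodal) "; objective looks multimodal" else ""))
  invisible(x)
}

#' @export
tidy.fit_result <- function(x, ...) {
  tibble::tibble(term = x$parameter, estimate = x$estimate,
                 conf_level = x$ci_level, conf_low = x$ci_low,
                 conf_high = x$ci_high)
}

#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(n = length(x$residuals),
                 rms_residual = sqrt(mean(x$residuals^2)),
                 B = x$B, seed = x$seed,
                 converged = x$converged, multimodal = x$multimodal)
}

# Shared machinery for one-parameter bounded least squares. The model is
# exponentially sensitive to the parameter (phi_s ~ exp(-nu * epsilon)), so
# the least-squares objective can be a narrow well on a nearly flat
# background; a dense deterministic grid scan locates the global basin
# before Brent refinement. The scan doubles as a multimodality diagnostic.
scalar_ls_fit <- function(objective, bounds, tol = 1e-10, grid_n = 401,
                          quiet_multimodal = FALSE) {
  grid <- seq(bounds[1], bounds[2], length.out = grid_n)
  ov <- vapply(grid, objective, numeric(1))
  interior <- 2:(grid_n - 1)
  # a local minimum only counts if the dip is deeper than numerical noise
  dip <- 1e-6 * (max(ov) - min(ov) + .Machine$double.eps)
  minima <- sum(ov[interior] < ov[interior - 1] - dip &
                  ov[interior] < ov[interior + 1] - dip)
  multimodal <- minima > 1
  if (multimodal && !quiet_multimodal) {
    warn("Objective has more than one local minimum over the bound interval; reporting the best one.")
  }
  i <- which.min(ov)
  est <- refine_minimum(objective, grid[max(1, i - 1)], grid[min(grid_n, i + 1)],
                        x_best = grid[i], f_best = ov[i], tol = tol)
  converged <- min(est - bounds[1], bounds[2] - est) > 1e-6
  if (!converged) warn("Estimate sits at the bound of the search interval; flagged as not converged.")
  list(estimate = est, multimodal = multimodal, converged = converged)
}

# Deterministic refinement inside a bracket known to contain the best
# scanned point. Nearby secondary basins (the model curve is non-monotone in
# epsilon) can defeat plain Brent on a wide bracket, so the bracket is
# narrowed by a second dense scan first; the best scanned candidate is kept
# if Brent lands in a worse basin.
refine_minimum <- function(objective, lo, hi, x_best, f_best, tol = 1e-10) {
  grid2 <- seq(lo, hi, length.out = 41)
  ov2 <- vapply(grid2, objective, numeric(1))
  j <- which.min(ov2)
  opt <- optimize(objective, interval = c(grid2[max(1, j - 1)],
                                          grid2[min(41, j + 1)]), tol = tol)
  cands <- c(opt$minimum, grid2[j], x_best)
  fvals <- c(opt$objective, ov2[j], f_best)
  cands[which.min(fvals)]
}

#' Bootstrap confidence interval by residual resampling
#'
#' Resamples residuals with replacement, adds them to the fitted values and
#' refits, returning a percentile interval. Deterministic under a fixed
#' seed. The default 68% level mirrors +/- 1 sigma error bars.
#'
#' @param refit A function taking a response vector (same length as
#'   `fitted`) and returning a scalar estimate.
#' @param residuals,fitted Residuals and fitted values of the original fit.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param level Interval level, default 0.68.
#' @return A list with `low`, `high`, `estimates` (length-B vector),
#'   `level`, `B`, `seed`.
#' @export
bootstrap_ci <- function(refit, residuals, fitted, B = 1000, seed = 1,
                         level = 0.68) {
  if (B < 100) abort("Use B >= 100 bootstrap replicates.")
  if (sd(residuals) < 1e-14) {
    warn("Degenerate (constant) residuals: bootstrap interval has zero width.")
  }
  est <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      refit(fitted + sample(residuals, replace = TRUE))
    }, numeric(1))
  })
  qs <- unname(quantile(est, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
  list(low = qs[1], high = qs[2], estimates = est, level = level,
       B = B, seed = seed)
}

#' Fit the soft-interaction parameter epsilon from a ddG curve
#'
#' One-dimensional least squares of the crowding model against measured
#' `ddG0(c)` at a single temperature, with `nu` and `chi` fixed from
#' binary-solution measurements and `epsilon` the only fit parameter
#' (bounded scalar minimization on `[-10, 10]` kT). A grid diagnostic checks
#' that the objective has a single interior minimum.
#'
#' @param data A data frame with columns `molality` and `ddg` (kJ/mol),
#'   the measured change in folding free energy relative to buffer.
#' @param cosolute A [cosolute_params()] object (fixes `nu`, `chi`).
#' @param dsasa Buried surface area, Angstrom^2.
#' @param T_K Temperature of the data, K.
#' @param bounds Search interval for epsilon, kT.
#' @param B Bootstrap replicates for the confidence interval; `0` skips the
#'   bootstrap.
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level (default 0.68, i.e. +/- 1 sigma-like).
#' @param d_s Optional lattice site length override, Angstrom.
#' @return A `fit_result` for `"epsilon"`; see [tidy.fit_result()].
#' @examples
#' tre <- cosolute_params("trehalose", 342.3, 209.5, chi_a = 1.2, chi_b = -180)
#' met <- protein_params("MET16", dsasa = 1000, epsilon = 0.3)
#' d <- decompose_free_energy(seq(0.25, 1.5, 0.25), 298, tre, met)
#' fit <- fit_epsilon(dplyr::transmute(d, molality, ddg = ddg_total),
#'                    tre, dsasa = 1000, T_K = 298)
#' fit$estimate
#' @export
fit_epsilon <- function(data, cosolute, dsasa, T_K = fh_constants$T_ref,
                        bounds = c(-10, 10), B = 0, seed = 1, level = 0.68,
                        d_s = NULL) {
  stopifnot(all(c("molality", "ddg") %in% names(data)))
  d <- data[data$molality > 0, , drop = FALSE]
  if (nrow(d) < 3) abort("Need >= 3 nonzero concentrations to fit epsilon.")

  proto <- protein_params("fit", dsasa = dsasa, epsilon = 0, eps_ts = 0,
                          d_s = d_s, Vbar_S = cosolute$Vbar_S, T0 = T_K)
  Tvec <- rep_len(T_K, nrow(d))
  model_curve <- function(eps) {
    prot <- proto
    prot$eps_h <- eps
    ddg_total_fast(d$molality, Tvec, cosolute, prot)
  }
  objective <- function(eps) sum((model_curve(eps) - d$ddg)^2)
  sol <- scalar_ls_fit(objective, bounds)
  fitted <- model_curve(sol$estimate)
  res <- d$ddg - fitted

  ci <- NULL
  if (B > 0) {
    # resampled responses stay close to the fitted curve, so refits scan a
    # window around the point estimate (the objective can be multi-basin)
    win_grid <- seq(max(bounds[1], sol$estimate - 2),
                    min(bounds[2], sol$estimate + 2), length.out = 41)
    refit <- function(y) {
      obj <- function(eps) sum((model_curve(eps) - y)^2)
      ov <- vapply(win_grid, obj, numeric(1))
      i <- which.min(ov)
      refine_minimum(obj, win_grid[max(1, i - 1)], win_grid[min(41, i + 1)],
                     x_best = win_grid[i], f_best = ov[i], tol = 1e-7)
    }
    bs <- bootstrap_ci(refit, res, fitted, B = B, seed = seed, level = level)
    ci <- c(bs$low, bs$high)
  }
  new_fit_result("epsilon", sol$estimate, data = tibble::as_tibble(d),
                 fitted = fitted, residuals = res, ci = ci, B = B,
                 seed = if (B > 0) seed else NA_integer_,
                 level = if (B > 0) level else NA_real_,
                 converged = sol$converged, multimodal = sol$multimodal)
}

#' Fit the entropic soft-interaction component epsilon_TS
#'
#' With `epsilon` already fixed by the free-energy fit, matches the model's
#' Gibbs-Helmholtz enthalpy and entropy (via [model_enthalpy_entropy()]) to
#' measured `ddH0(c)` and `T ddS0(c)` with `epsilon_TS` as the sole fit
#' parameter. The split is carried as `eps_s = -epsilon_TS` and
#' `eps_h = epsilon + epsilon_TS`, so `epsilon(T0)` is preserved exactly for
#' every candidate value. Enthalpy and entropy points are weighted equally.
#'
#' @param data A data frame with columns `molality`, `ddh` and `tdds`
#'   (kJ/mol), relative to buffer.
#' @param epsilon Fixed soft-interaction parameter from [fit_epsilon()].
#' @param cosolute A [cosolute_params()] object.
#' @param dsasa Buried surface area, Angstrom^2.
#' @param T0 Reference temperature, K.
#' @param bounds Search interval for epsilon_TS, kT.
#' @param dT Finite-difference step of the Gibbs-Helmholtz route, K.
#' @inheritParams fit_epsilon
#' @return A `fit_result` for `"epsilon_ts"`, with an `epsilon_split` element
#'   giving the implied (`eps_h`, `eps_s`) pair.
#' @export
fit_epsilon_ts <- function(data, epsilon, cosolute, dsasa,
                           T0 = fh_constants$T_ref, bounds = c(-10, 10),
                           B = 0, seed = 1, level = 0.68, dT = 0.5,
                           d_s = NULL) {
  stopifnot(all(c("molality", "ddh", "tdds") %in% names(data)))
  d <- data[data$molality > 0, , drop = FALSE]
  if (nrow(d) < 2) abort("Need >= 2 nonzero concentrations to fit epsilon_TS.")

  proto <- protein_params("fit", dsasa = dsasa, epsilon = epsilon,
                          eps_ts = 0, d_s = d_s, Vbar_S = cosolute$Vbar_S,
                          T0 = T0)
  Tvec <- rep_len(T0, nrow(d))
  model_he <- function(eps_ts) {
    prot <- proto
    prot$eps_s <- -eps_ts
    prot$eps_h <- epsilon + eps_ts
    g_lo <- ddg_total_fast(d$molality, Tvec - dT, cosolute, prot)
    g_hi <- ddg_total_fast(d$molality, Tvec + dT, cosolute, prot)
    g_mid <- ddg_total_fast(d$molality, Tvec, cosolute, prot)
    ddh <- (g_lo / (T0 - dT) - g_hi / (T0 + dT)) /
      (1 / (T0 - dT) - 1 / (T0 + dT))
    c(ddh, ddh - g_mid)
  }
  y <- c(d$ddh, d$tdds)
  objective <- function(eps_ts) sum((model_he(eps_ts) - y)^2)
  sol <- scalar_ls_fit(objective, bounds)
  fitted <- model_he(sol$estimate)
  res <- y - fitted

  ci <- NULL
  if (B > 0) {
    n <- nrow(d)
    win_grid <- seq(max(bounds[1], sol$estimate - 2),
                    min(bounds[2], sol$estimate + 2), length.out = 41)
    refit <- function(ystar) {
      obj <- function(e) sum((model_he(e) - ystar)^2)
      ov <- vapply(win_grid, obj, numeric(1))
      i <- which.min(ov)
      refine_minimum(obj, win_grid[max(1, i - 1)], win_grid[min(41, i + 1)],
                     x_best = win_grid[i], f_best = ov[i], tol = 1e-6)
    }
    # resample (ddh, tdds) residual pairs jointly to preserve their
    # anticorrelation about the ddG constraint
    est <- withr::with_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, replace = TRUE)
        refit(fitted + c(res[seq_len(n)][idx], res[n + seq_len(n)][idx]))
      }, numeric(1))
    })
    qs <- unname(quantile(est, c((1 - level) / 2, 1 - (1 - level) / 2)))
    ci <- qs
  }
  out <- new_fit_result("epsilon_ts", sol$estimate, data = tibble::as_tibble(d),
                        fitted = fitted, residuals = res, ci = ci, B = B,
                        seed = if (B > 0) seed else NA_integer_,
                        level = if (B > 0) level else NA_real_,
                        converged = sol$converged, multimodal = sol$multimodal)
  out$epsilon_split <- tibble::tibble(
    epsilon = epsilon, epsilon_ts = sol$estimate,
    eps_s = -sol$estimate, eps_h = epsilon + sol$estimate
  )
  out
}
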