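# Ensemble-level analysis: rupture-force statistics, work statistics and
# free-energy profiles along the pulling coordinate.
#
# Two profile estimators are provided and always labelled:
#   mean-work              G(z) = <W(z)>
#   jarzynski-2nd-cumulant G(z) = <W(z)> - Var W(z) / (2 kB T)
# The second is the Gaussian-work truncation of the Jarzynski equality; it
# is exact when the work distribution at each z is Gaussian and never
# exceeds the mean-work estimate (variances are non-negative). The
# unbinding barrier is max_z G(z) - G(0) with G(0) = 0 by construction.

#' Bundle pulling traces into an ensemble
#'
#' @param traces list of [pull_trace] objects sharing `v` and `k`.
#' @param mode optional restraint-mode label.
#' @param label optional system label.
#' @return Object of class `pull_ensemble`.
#' @export
pull_ensemble <- function(traces, mode = NA, label = NULL) {
  if (!length(traces)) stop("empty ensemble")
  if (!all(vapply(traces, inherits, TRUE, "pull_trace")))
    stop("all elements must be pull_trace objects")
  v <- vapply(traces, `[[`, 0, "v")
  k <- vapply(traces, `[[`, 0, "k")
  if (length(unique(v)) > 1 || length(unique(k)) > 1)
    stop("traces do not share pulling velocity/spring constant")
  structure(list(traces = traces, v = v[1], k = k[1],
                 mode = mode, label = label),
            class = "pull_ensemble")
}

#' @export
length.pull_ensemble <- function(x) length(x$traces)

#' @export
print.pull_ensemble <- function(x, ...) {
  cat("pull_ensemble:", length(x$traces), "trajectories",
      if (!is.na(x$mode)) paste0("(mode ", x$mode, ")") else "", "\n")
  cat(sprintf("  v = %g nm/ns, k = %g kJ/mol/nm^2\n", x$v, x$k))
  invisible(x)
}

#' Rupture-force statistics of an ensemble
#'
#' Per-trajectory maxima of the spring force (pN), their mean and standard
#' error, and optionally a skew-normal fit of their distribution.
#'
#' @param ensemble a [pull_ensemble].
#' @param fit_skew also fit a skew-normal to the Fmax sample (needs >= 10
#'   trajectories).
#' @return Object of class `rupture_stats`: `fmax` (vector, pN),
#'   `mean`, `se`, and `skew_fit` (or NULL).
#' @export
rupture_stats <- function(ensemble, fit_skew = FALSE) {
  fmax <- vapply(ensemble$traces, function(tr) rupture_force(tr)$fmax, 0)
  n <- length(fmax)
  fit <- if (fit_skew && n >= 10) fit_skewed_gaussian(fmax) else NULL
  structure(list(fmax = fmax, mean = mean(fmax),
                 se = if (n >= 2) sd(fmax) / sqrt(n) else NA_real_,
                 n = n, skew_fit = fit),
            class = "rupture_stats")
}

#' @export
print.rupture_stats <- function(x, ...) {
  cat(sprintf("rupture force: <Fmax> = %.1f +/- %.2f pN (n = %d)\n",
              x$mean, x$se, x$n))
  if (!is.null(x$skew_fit)) print(x$skew_fit)
  invisible(x)
}

#' Pulling-work statistics of an ensemble
#'
#' @param ensemble a [pull_ensemble].
#' @return list: `work` (vector, kcal/mol), `mean`, `se`, `n`.
#' @export
work_stats <- function(ensemble) {
  w <- vapply(ensemble$traces, pulling_work, 0)
  n <- length(w)
  list(work = w, mean = mean(w),
       se = if (n >= 2) sd(w) / sqrt(n) else NA_real_, n = n)
}

#' Free-energy profile along the pulling coordinate
#'
#' Re-indexes each trajectory's cumulative work by ligand displacement
#' (first passage of a common grid), then forms per-grid-point work moments
#' across the ensemble and the chosen free-energy estimate. The grid spans
#' displacement 0 to the largest displacement every trace reaches, so all
#' trajectories contribute at every point.
#'
#' @param ensemble a [pull_ensemble]; the cumulant estimator needs >= 2
#'   trajectories.
#' @param estimator `"jarzynski-2nd-cumulant"` (default) or `"mean-work"`.
#' @param temperature kelvin, used by the cumulant estimator.
#' @param dz displacement bin width, nm.
#' @param coordinate `"displacement"` (ligand first passage, default) or
#'   `"anchor"` (spring anchor position; deterministic, exact for the
#'   cumulant estimator under the stiff-spring approximation) — see
#'   [work_vs_displacement()].
#' @return Object of class `fe_profile`: data.frame with `displacement`,
#'   `mean_work`, `var_work`, `G` (all work/energy in kcal/mol), plus
#'   attributes `barrier`, `barrier_se`, `estimator`, `temperature`.
#' @export
free_energy_profile <- function(ensemble,
                                estimator = c("jarzynski-2nd-cumulant",
                                              "mean-work"),
                                temperature = 300, dz = 0.05,
                                coordinate = c("displacement", "anchor")) {
  estimator <- match.arg(estimator)
  coordinate <- match.arg(coordinate)
  n <- length(ensemble$traces)
  if (estimator == "jarzynski-2nd-cumulant" && n < 2)
    stop("the cumulant estimator needs at least 2 trajectories")
  zmax <- if (coordinate == "anchor")
    min(vapply(ensemble$traces,
               function(tr) max(tr$time - tr$time[1]) * tr$v / 1000, 0))
  else
    min(vapply(ensemble$traces, function(tr) max(tr$displacement), 0))
  if (zmax <= 0) stop("no common displacement range across traces")
  grid <- seq(0, zmax, by = dz)
  W <- vapply(ensemble$traces,
              function(tr) work_vs_displacement(tr, grid = grid,
                                                coordinate = coordinate)$work,
              numeric(length(grid)))
  W <- matrix(W, nrow = length(grid))
  mean_w <- rowMeans(W)
  var_w <- if (n >= 2) apply(W, 1, var) else rep(0, length(grid))
  kBT <- rk_constants$kB_kcal * temperature
  G <- if (estimator == "mean-work") mean_w else mean_w - var_w / (2 * kBT)
  G <- G - G[1]
  imax <- which.max(G)
  # spread of the per-trace work at the arg-max grid point
  barrier_se <- if (n >= 2) sd(W[imax, ]) / sqrt(n) else NA_real_
  out <- data.frame(displacement = grid, mean_work = mean_w,
                    var_work = var_w, G = G)
  structure(out, class = c("fe_profile", "data.frame"),
            barrier = max(G) - G[1], barrier_se = barrier_se,
            estimator = estimator, temperature = temperature,
            n_traces = n)
}

#' Unbinding barrier of a free-energy profile
#' @param profile an `fe_profile`.
#' @return barrier height, kcal/mol.
#' @export
unbinding_barrier <- function(profile) attr(profile, "barrier")

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf(
    "free-energy profile (%s, T = %g K, %d traces): barrier %.2f kcal/mol\n",
    attr(x, "estimator"), attr(x, "temperature"), attr(x, "n_traces"),
    attr(x, "barrier")))
  cat(sprintf("  grid: %d points, 0-%.2f nm\n", nrow(x),
              x$displacement[nrow(x)]))
  invisible(x)
}

#' @export
plot.fe_profile <- function(x, ...) {
  plot(x$displacement, x$G, type = "l", xlab = "displacement (nm)",
       ylab = "G (kcal/mol)", ...)
  graphics::lines(x$displacement, x$mean_work, lty = 2)
  graphics::legend("topleft", c(attr(x, "estimator"), "mean work"),
                   lty = 1:2, bty = "n")
  invisible(x)
}

#' Per-mode summary of a pulling ensemble
#'
#' @param object a [pull_ensemble].
#' @param temperature kelvin for the barrier estimate.
#' @param estimator passed to [free_energy_profile()].
#' @param ... unused.
#' @return one-row data.frame: n, mean/se of Fmax (pN) and work
#'   (kcal/mol), and the unbinding barrier (kcal/mol).
#' @export
summary.pull_ensemble <- function(object, temperature = 300,
                                  estimator = "jarzynski-2nd-cumulant",
                                  ...) {
  rs <- rupture_stats(object)
  ws <- work_stats(object)
  barrier <- if (length(object$traces) >= 2)
    unbinding_barrier(free_energy_profile(object, estimator = estimator,
                                          temperature = temperature))
  else NA_real_
  data.frame(mode = object$mode, n = rs$n,
             fmax_mean = rs$mean, fmax_se = rs$se,
             work_mean = ws$mean, work_se = ws$se,
             barrier = barrier)
}
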