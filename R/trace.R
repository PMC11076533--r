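# Single-trajectory pulling records and their basic analysis.
#
# A pull trace is the (time, spring force, ligand-COM displacement) record
# of one constant-velocity pulling run: time in ps, force in kJ/mol/nm
# (engine convention; converted to pN on report), displacement in nm along
# the pulling axis with displacement zero at t = 0.

#' Construct a pulling trace
#'
#' @param time strictly increasing times, ps.
#' @param force spring forces, kJ/mol/nm.
#' @param displacement ligand-COM displacement along the pull axis, nm;
#'   shifted so the first sample is 0.
#' @param v pulling velocity, nm/ns.
#' @param k pulling spring constant, kJ/mol/nm^2.
#' @return Object of class `pull_trace`.
#' @export
pull_trace <- function(time, force, displacement, v = 1.0, k = 600) {
  n <- length(time)
  if (n == 0) stop("empty trace")
  if (length(force) != n || length(displacement) != n)
    stop("time/force/displacement lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  displacement <- displacement - displacement[1]
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 displacement = as.numeric(displacement),
                 v = v, k = k),
            class = "pull_trace")
}

#' @export
print.pull_trace <- function(x, ...) {
  cat("pull_trace:", length(x$time), "samples,",
      sprintf("%.4g-%.4g ps", x$time[1], x$time[length(x$time)]), "\n")
  cat(sprintf("  v = %g nm/ns, k = %g kJ/mol/nm^2\n", x$v, x$k))
  rf <- rupture_force(x)
  cat(sprintf("  Fmax = %.1f pN at %.4g ps; final displacement %.3f nm\n",
              rf$fmax, rf$time, x$displacement[length(x$displacement)]))
  invisible(x)
}

#' @export
plot.pull_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time, force_to_pN(x$force), type = "l", xlab = "time (ps)",
       ylab = "force (pN)", ...)
  plot(x$time, x$displacement, type = "l", xlab = "time (ps)",
       ylab = "displacement (nm)", ...)
  invisible(x)
}

#' Read a two-column XVG-style file
#'
#' Lines beginning with `#` or `@` are comments/headers and are skipped.
#'
#' @param path file.
#' @return two-column numeric matrix.
#' @export
read_xvg <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path)
  d <- read.table(text = lines)
  as.matrix(d[, 1:2])
}

#' Write a two-column XVG-style file
#' @param x,y numeric columns.
#' @param path output file.
#' @param title optional title line written as an `@` header.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(x, y, path, title = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(title)) writeLines(paste0("@ title \"", title, "\""), con)
  writeLines(sprintf("%.10g %.10g", x, y), con)
  invisible(path)
}

#' Read a pulling trace from force and position files
#'
#' Both files are XVG-style (time, value). The position file may contain
#' either absolute ligand-COM coordinates or displacements; the series is
#' zeroed at its first sample. If the two time grids differ they are joined
#' by nearest time with a tolerance of half the sampling step.
#'
#' @param force_file time vs pulling force (kJ/mol/nm).
#' @param position_file time vs ligand-COM position/displacement (nm).
#' @param v pulling velocity, nm/ns.
#' @param k spring constant, kJ/mol/nm^2.
#' @return A [pull_trace].
#' @export
read_pull_trace <- function(force_file, position_file, v = 1.0, k = 600) {
  f <- read_xvg(force_file)
  p <- read_xvg(position_file)
  if (any(diff(f[, 1]) <= 0) || any(diff(p[, 1]) <= 0))
    stop("non-monotone time column")
  if (nrow(f) == nrow(p) && max(abs(f[, 1] - p[, 1])) < 1e-9) {
    disp <- p[, 2]
  } else {
    step <- stats::median(diff(f[, 1]))
    j <- findInterval(f[, 1], p[, 1], all.inside = FALSE)
    j <- pmax(j, 1L)
    jn <- pmin(j + 1L, nrow(p))
    use_next <- abs(p[jn, 1] - f[, 1]) < abs(p[j, 1] - f[, 1])
    j[use_next] <- jn[use_next]
    if (any(abs(p[j, 1] - f[, 1]) > step / 2))
      stop("force/position time grids differ by more than half a step")
    disp <- p[j, 2]
  }
  pull_trace(f[, 1], f[, 2], disp, v = v, k = k)
}

#' Rupture force of a trace
#'
#' The global maximum of the spring force, marking the ligand-receptor
#' rupture event; ties are broken by the earliest time.
#'
#' @param trace a [pull_trace].
#' @return list with `fmax` (pN) and `time` (ps).
#' @export
rupture_force <- function(trace) {
  i <- which.max(trace$force)
  list(fmax = force_to_pN(trace$force[i]), time = trace$time[i])
}

#' External pulling work of a trace
#'
#' The work done by the moving spring, \eqn{W = v \int F\,dt}, by the
#' trapezoidal rule over the full trace.
#'
#' @param trace a [pull_trace].
#' @return work in kcal/mol.
#' @export
pulling_work <- function(trace) {
  # v nm/ns -> nm/ps; F kJ/mol/nm * ps -> kJ/mol
  w_kJ <- (trace$v / 1000) * pracma::trapz(trace$time, trace$force)
  kJ_to_kcal(w_kJ)
}

#' Cumulative pulling work along a trace
#' @param trace a [pull_trace].
#' @return numeric vector, kcal/mol, one value per sample (first is 0).
#' @export
cumulative_work <- function(trace) {
  w_kJ <- (trace$v / 1000) * pracma::cumtrapz(trace$time, trace$force)
  kJ_to_kcal(as.numeric(w_kJ))
}

#' Re-index cumulative work by displacement
#'
#' With `coordinate = "displacement"` (default) the cumulative trapezoidal
#' work is evaluated at the first passage of each grid point by the ligand
#' displacement (linear interpolation between the bracketing samples of
#' the running-maximum displacement). Because the ligand coordinate is
#' noisy, first-passage evaluation carries a small selection bias of order
#' kT; `coordinate = "anchor"` instead indexes work by the spring-anchor
#' displacement \eqn{v t}, which is deterministic and makes the
#' second-cumulant free-energy estimator exact for Gaussian work (the
#' stiff-spring convention). Grid points beyond the trace's reach are NA.
#'
#' @param trace a [pull_trace].
#' @param grid displacement grid, nm; default uniform bins of `dz` from 0
#'   to the trace's maximum displacement.
#' @param dz grid spacing when `grid` is NULL, nm.
#' @param coordinate `"displacement"` (ligand first passage) or
#'   `"anchor"` (spring anchor position).
#' @return data.frame with columns `displacement` and `work` (kcal/mol).
#' @export
work_vs_displacement <- function(trace, grid = NULL, dz = 0.05,
                                 coordinate = c("displacement", "anchor")) {
  coordinate <- match.arg(coordinate)
  W <- cumulative_work(trace)
  if (coordinate == "anchor") {
    za <- (trace$time - trace$time[1]) * trace$v / 1000  # nm
    if (is.null(grid)) grid <- seq(0, max(za), by = dz)
    w <- approx(za, W, xout = grid, rule = 1)$y
    return(data.frame(displacement = grid, work = w))
  }
  runmax <- cummax(trace$displacement)
  if (is.null(grid)) grid <- seq(0, max(runmax), by = dz)
  # first-passage: first index where runmax >= z
  idx <- findInterval(grid, runmax, left.open = TRUE) + 1L
  w <- rep(NA_real_, length(grid))
  ok <- idx <= length(runmax)
  for (m in which(ok)) {
    i <- idx[m]
    if (i == 1L) { w[m] <- W[1]; next }
    z0 <- runmax[i - 1L]; z1 <- runmax[i]
    frac <- if (z1 > z0) (grid[m] - z0) / (z1 - z0) else 0
    w[m] <- W[i - 1L] + frac * (W[i] - W[i - 1L])
  }
  data.frame(displacement = grid, work = w)
}

#' Running (cumulative) mean
#'
#' Element i is the mean of the first i values; the last element is the
#' full ensemble mean. Used to monitor convergence of rupture-force and
#' work averages with the number of trajectories.
#'
#' @param values numeric vector.
#' @param n number of leading values to use (default all).
#' @return numeric vector of length `n`.
#' @export
running_mean <- function(values, n = length(values)) {
  v <- values[seq_len(n)]
  cumsum(v) / seq_along(v)
}

#' Maximum-likelihood skew-normal fit
#'
#' Fits the Azzalini skew-normal density
#' \eqn{f(x) = (2/\omega)\,\phi(u)\,\Phi(\alpha u)}, \eqn{u=(x-\xi)/\omega},
#' to a sample by direct likelihood maximisation. With shape
#' \eqn{\alpha = 0} this is a plain Gaussian; rupture-force and work
#' distributions from pulling ensembles are typically skewed.
#'
#' @param samples numeric vector, length >= 10, non-degenerate.
#' @return list of class `skew_fit`: `location`, `scale`, `shape`,
#'   `loglik`, `convergence`.
#' @export
fit_skewed_gaussian <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 10) stop("need at least 10 samples")
  s <- sd(samples)
  if (!is.finite(s) || s == 0) stop("degenerate (zero-variance) sample")

  nll <- function(par) {
    xi <- par[1]; omega <- exp(par[2]); alpha <- par[3]
    u <- (samples - xi) / omega
    -sum(log(2) - par[2] + dnorm(u, log = TRUE) +
           pnorm(alpha * u, log.p = TRUE))
  }
  # method-of-moments start from the sample skewness
  g1 <- mean((samples - mean(samples))^3) / s^3
  g1 <- sign(g1) * min(abs(g1), 0.9)
  r <- (2 * abs(g1) / (4 - pi))^(1 / 3)
  delta <- sign(g1) * r / sqrt(1 + r^2)
  delta <- max(min(delta, 0.95), -0.95)
  alpha0 <- delta / sqrt(1 - delta^2)
  omega0 <- s / sqrt(max(1 - 2 * delta^2 / pi, 0.1))
  xi0 <- mean(samples) - omega0 * delta * sqrt(2 / pi)
  fit <- optim(c(xi0, log(omega0), alpha0), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  structure(list(location = fit$par[1], scale = exp(fit$par[2]),
                 shape = fit$par[3], loglik = -fit$value,
                 convergence = fit$convergence),
            class = "skew_fit")
}

#' @export
print.skew_fit <- function(x, ...) {
  cat(sprintf(
    "skew-normal fit: location %.4g, scale %.4g, shape %.3g (loglik %.2f)\n",
    x$location, x$scale, x$shape, x$loglik))
  invisible(x)
}
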