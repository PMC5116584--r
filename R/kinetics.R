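#' Kinetic simulation parameters
#'
#' Defaults emulate the real-time RCA readout: ~15 min of fluorescence
#' collected every 30 s, a short lag before linear product accumulation,
#' additive Gaussian instrument noise, and a saturation ceiling. `k_full` is
#' the slope contributed by a fully active template; a bound site lets
#' through its repressor's `leak` fraction of that. `capacity` caps the
#' summed template contributions (in units of fully active templates),
#' modelling the polymerase/primer-limited regime in which one running
#' template already produces the full-scale signal.
#'
#' @param baseline_rfu Starting fluorescence (RFU).
#' @param k_full Slope per fully active template (RFU/min).
#' @param duration Total time (min).
#' @param sample_interval Sampling interval (min).
#' @param lag Lag before amplification starts (min); must be < duration.
#' @param noise_sd Gaussian noise s.d. (RFU); default 5% of `k_full`.
#' @param plateau_rfu Saturation ceiling (RFU).
#' @param capacity Cap on summed template activity (template equivalents).
#' @param seed Optional integer seed used by stochastic simulation.
#' @return List of class `rca_kinetic_params`.
#' @export
kinetic_params <- function(baseline_rfu = 100, k_full = 10, duration = 15,
                           sample_interval = 0.5, lag = 1,
                           noise_sd = 0.05 * k_full, plateau_rfu = 400,
                           capacity = 1, seed = NULL) {
  stopifnot(duration > lag, lag >= 0, noise_sd >= 0, k_full > 0,
            sample_interval > 0, capacity > 0)
  structure(list(baseline_rfu = baseline_rfu, k_full = k_full,
                 duration = duration, sample_interval = sample_interval,
                 lag = lag, noise_sd = noise_sd, plateau_rfu = plateau_rfu,
                 capacity = capacity, seed = seed),
            class = "rca_kinetic_params")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

template_rate_fraction <- function(template, registry, state) {
  occupied <- vapply(template$sites, site_occupied, integer(1),
                     registry = registry, state = state)
  if (!any(occupied == 1L)) return(1)
  leaks <- vapply(template$sites[occupied == 1L], function(s) {
    registry$repressors[[s$repressor]]$leak
  }, numeric(1))
  max(leaks)
}

simulate_curve_state <- function(system, state, params, label, seed) {
  fractions <- vapply(system$templates, template_rate_fraction, numeric(1),
                      registry = system$registry, state = state)
  total_rate <- params$k_full * min(params$capacity, sum(fractions))
  times <- seq(0, params$duration, by = params$sample_interval)
  clean <- params$baseline_rfu + total_rate * pmax(0, times - params$lag)
  values <- if (params$noise_sd > 0) {
    if (is.null(seed)) {
      stop("a seed is required when noise_sd > 0")
    }
    with_seed(seed, clean + stats::rnorm(length(times), 0, params$noise_sd))
  } else clean
  values <- pmin(values, params$plateau_rfu)
  structure(list(label = label, times = times, values = values,
                 true_rate = total_rate),
            class = "rca_curve")
}

#' Simulate a real-time RCA fluorescence curve
#'
#' Deterministic piecewise-linear signal (baseline, lag, linear rise capped
#' at the plateau) plus i.i.d. Gaussian noise. The slope is
#' `k_full * min(capacity, sum_i f_i)` where `f_i` is 1 for an active
#' template and the maximal leak over its occupied sites otherwise.
#'
#' @param system An `rca_system`.
#' @param assignment Named 0/1 vector over the system's inputs.
#' @param params An [kinetic_params()] object.
#' @param seed Integer seed (required when `noise_sd > 0`); defaults to
#'   `params$seed`.
#' @return Object of class `rca_curve` with `times` (min), `values` (RFU),
#'   the condition `label` and the noise-free `true_rate`.
#' @export
simulate_curve <- function(system, assignment, params = kinetic_params(),
                           seed = params$seed) {
  state <- resolve_state(system, assignment)
  inputs <- names(system$input_map)
  a <- check_assignment(assignment, inputs)
  label <- paste(inputs, a, sep = "=", collapse = ",")
  simulate_curve_state(system, state, params, label, seed)
}

#' Estimate the RCA rate as the slope of the linear part
#'
#' Fits ordinary least squares over every contiguous window spanning at
#' least `min_frac` of the samples and returns the steepest slope among
#' windows whose fit quality (R^2) reaches `quality_floor`; windows
#' containing the lag or the plateau fit poorly and are thereby excluded.
#' If no window reaches the floor (e.g. a flat, fully repressed curve) the
#' best-fitting window is used. Deterministic given the curve.
#'
#' @param curve An `rca_curve` (or list with `times` and `values`) with at
#'   least 6 samples.
#' @param min_frac Minimal window span as a fraction of samples.
#' @param quality_floor Minimal R^2 for a window to qualify.
#' @return List with `raw_slope` (RFU/min), `window` (start/end sample
#'   indices) and `r_squared`.
#' @export
estimate_rate <- function(curve, min_frac = 0.4, quality_floor = 0.9) {
  t <- curve$times; y <- curve$values
  n <- length(t)
  if (n < 6L) stop("rate estimation needs at least 6 samples")
  lmin <- max(3L, ceiling(min_frac * n))
  cx <- c(0, cumsum(t)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(t * t)); cyy <- c(0, cumsum(y * y))
  cxy <- c(0, cumsum(t * y))
  lens <- lmin:n
  starts <- unlist(lapply(lens, function(L) 1:(n - L + 1L)))
  L <- rep(lens, times = n - lens + 1L)
  e <- starts + L - 1L
  Sx <- cx[e + 1L] - cx[starts]; Sy <- cy[e + 1L] - cy[starts]
  Sxx <- cxx[e + 1L] - cxx[starts]; Syy <- cyy[e + 1L] - cyy[starts]
  Sxy <- cxy[e + 1L] - cxy[starts]
  vx <- L * Sxx - Sx^2
  vy <- L * Syy - Sy^2
  cov <- L * Sxy - Sx * Sy
  slope <- cov / vx
  r2 <- ifelse(vy <= .Machine$double.eps * pmax(1, Syy), 1,
               cov^2 / pmax(vx * vy, .Machine$double.xmin))
  ok <- which(r2 >= quality_floor)
  pick <- if (length(ok)) {
    ok[order(-slope[ok], -L[ok], starts[ok])][1L]
  } else {
    order(-r2, -L, starts)[1L]
  }
  list(raw_slope = slope[pick], window = c(starts[pick], e[pick]),
       r_squared = r2[pick])
}

#' Simulate, quantify and binarize a full gate experiment
#'
#' Simulates every input combination of the system plus a repressor-free
#' control condition, estimates each curve's linear-part slope, normalizes
#' slopes to the maximum across all conditions (control included) to obtain
#' relative RCA rates (RRR), and thresholds: output 1 iff RRR is strictly
#' above the threshold (default 0.5). The control keeps normalization
#' well-defined for gates whose every condition is repressed (NOT/NONE
#' type), for which RRR then stays at the leak level, well below threshold.
#'
#' @param system An `rca_system` with at least 1 input.
#' @param params An [kinetic_params()] object.
#' @param seed Base integer seed; condition `i` uses `seed * 1000 + i`.
#'   Required when `noise_sd > 0`.
#' @param threshold RRR threshold in (0, 1); default 0.5.
#' @return Object of class `rca_quantification`: empirical `truth_table`,
#'   per-condition `results` data frame (slope, rrr, output), and the
#'   `control` slope.
#' @export
quantify_experiment <- function(system, params = kinetic_params(),
                                seed = params$seed, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  inputs <- names(system$input_map)
  n <- length(inputs)
  if (n < 1L) stop("system has no inputs; nothing to quantify")
  rows <- assignment_rows(inputs)
  cond_seed <- function(i) {
    if (is.null(seed)) NULL else (seed * 1000 + i) %% .Machine$integer.max
  }
  est <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    curve <- simulate_curve(system, stats::setNames(rows[i, ], inputs),
                            params, seed = cond_seed(i))
    est[[i]] <- estimate_rate(curve)
  }
  control_curve <- simulate_curve_state(system, species_state(), params,
                                        "control",
                                        cond_seed(nrow(rows) + 1L))
  control_est <- estimate_rate(control_curve)
  slopes <- vapply(est, function(e) e$raw_slope, numeric(1))
  max_rate <- max(c(slopes, control_est$raw_slope))
  if (max_rate <= 0) {
    stop("degenerate experiment: maximal rate is not positive")
  }
  rrr <- pmin(1, pmax(0, slopes / max_rate))
  outputs <- as.integer(rrr > threshold)
  results <- as.data.frame(rows)
  results$raw_slope <- slopes
  results$rrr <- rrr
  results$output <- outputs
  structure(list(truth_table = truth_table(inputs, outputs),
                 results = results,
                 control_slope = control_est$raw_slope,
                 threshold = threshold, params = params, seed = seed),
            class = "rca_quantification")
}

#' @export
print.rca_quantification <- function(x, ...) {
  cat("RCA quantification (threshold", x$threshold, ")\n")
  df <- x$results
  df$rrr <- round(df$rrr, 3)
  df$raw_slope <- round(df$raw_slope, 3)
  print(df, row.names = FALSE)
  cat("control slope:", round(x$control_slope, 3), "RFU/min\n")
  invisible(x)
}

#' Fraction of seeded runs recovering an expected truth table
#'
#' Repeats [quantify_experiment()] `n_runs` times at distinct derived seeds
#' and reports how often the empirical table equals `expected`.
#'
#' @param system An `rca_system`.
#' @param expected An `rca_truth_table`.
#' @param n_runs Number of runs.
#' @param params Kinetic parameters.
#' @param seed Base seed; run `k` uses `seed + k`.
#' @return Fraction in `[0, 1]`.
#' @export
recovery_rate <- function(system, expected, n_runs = 1000,
                          params = kinetic_params(), seed = 1) {
  hits <- 0L
  for (k in seq_len(n_runs)) {
    q <- quantify_experiment(system, params, seed = seed + k)
    if (identical(q$truth_table$outputs, as.integer(expected$outputs))) {
      hits <- hits + 1L
    }
  }
  hits / n_runs
}

#' Export fluorescence curves as tidy CSV
#'
#' @param curves List of `rca_curve` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(condition = cv$label, time_min = cv$times, rfu = cv$values)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import fluorescence curves from tidy CSV
#'
#' Expects columns `condition`, `time_min`, `rfu`; returns one `rca_curve`
#' per condition, suitable for [estimate_rate()] re-analysis of measured
#' data.
#'
#' @param path CSV file path.
#' @return Named list of `rca_curve` objects.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "time_min", "rfu")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("curve CSV misses column(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(split(df, df$condition), function(d) {
    d <- d[order(d$time_min), ]
    structure(list(label = d$condition[1], times = d$time_min,
                   values = d$rfu, true_rate = NA_real_),
              class = "rca_curve")
  })
  out
}

#' @export
print.rca_curve <- function(x, ...) {
  cat("RCA curve '", x$label, "': ", length(x$times), " samples, ",
      min(x$times), "-", max(x$times), " min\n", sep = "")
  invisible(x)
}

#' @export
plot.rca_curve <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (min)",
                 ylab = "fluorescence (RFU)", main = x$label, ...)
  invisible(x)
}
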