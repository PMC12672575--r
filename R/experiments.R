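#' Calibrate the characteristic off-switching time
#'
#' Finds the 488 nm illumination duration at which the instantaneous
#' fluorescence of an initially fully on-switched ensemble has decayed to
#' 20% of its initial value, the convention used to normalize off-switching
#' doses across power densities and protein variants. The time is found by
#' bracketing (doubling) followed by bisection on the exactly simulated
#' decay.
#'
#' @param params A [rate_params()] object with a nonzero off-switching
#'   yield.
#' @param p488 488 nm power density (W/cm^2, > 0).
#' @param target Residual fraction (default 0.20).
#' @param rel_tol Relative bisection tolerance (default 1e-4).
#' @param t_cap Maximum simulated time in seconds before giving up.
#' @return Duration in seconds.
#' @export
calibrate_offswitch_time <- function(params, p488, target = 0.20,
                                     rel_tol = 1e-4, t_cap = 10) {
  stopifnot(p488 > 0)
  if (params$phi_off <= 0) stop("model has no off-switching channel")
  il <- illumination(488, p488)
  ops <- make_ops(build_rate_matrix(params, list(il)))
  w <- fluorescence_weights(params, list(il))
  p0 <- population()
  f0 <- drop(w %*% p0)
  resid <- function(t) drop(w %*% (ops_propagator(ops, t) %*% p0)) / f0
  ## bracket by doubling
  hi <- 1e-6
  while (resid(hi) > target) {
    hi <- hi * 2
    if (hi > t_cap) stop("fluorescence never decays to ",
                         target * 100, "% within ", t_cap, " s")
  }
  lo <- hi / 2
  while ((hi - lo) / hi > rel_tol) {
    mid <- (lo + hi) / 2
    if (resid(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Fatigue curve container
#'
#' @param cycle Integer cycle indices, contiguous from 1.
#' @param signal Per-cycle integrated fluorescence (a.u.).
#' @param normalization One of `"raw"`, `"cycle1"`, `"reference"`.
#' @param sigma Optional per-cycle replicate standard deviation.
#' @param label Free-text label.
#' @return A `fatigue_curve` data frame (`cycle`, `signal`, optional
#'   `sigma`).
#' @export
fatigue_curve <- function(cycle, signal, normalization = "raw",
                          sigma = NULL, label = "") {
  stopifnot(length(cycle) == length(signal),
            all(diff(cycle) == 1), cycle[1] == 1)
  if (!is.null(sigma) && any(sigma < 0)) stop("sigma must be >= 0")
  df <- data.frame(cycle = as.integer(cycle), signal = signal)
  if (!is.null(sigma)) df$sigma <- sigma
  structure(df, class = c("fatigue_curve", "data.frame"),
            normalization = normalization, label = label)
}

#' Normalize a fatigue curve to its first cycle
#' @param curve A `fatigue_curve`.
#' @export
normalize_curve <- function(curve) {
  f1 <- curve$signal[1]
  if (f1 <= 0) stop("cannot normalize: cycle-1 signal is not positive")
  out <- curve
  out$signal <- curve$signal / f1
  if (!is.null(out$sigma)) out$sigma <- curve$sigma / f1
  attr(out, "normalization") <- "cycle1"
  out
}

#' Run a photoswitching-fatigue experiment
#'
#' Repeats one on-off illumination cycle `n_cycles` times, carrying the
#' exact end-of-cycle populations into the next cycle, and records the
#' integrated fluorescence emitted during the 488 nm window(s) of each
#' cycle. Per-window propagation and integration operators are
#' precomputed once, so the cost per cycle is a handful of 8 x 8
#' matrix-vector products.
#'
#' @param params A [rate_params()] object.
#' @param cycle A [pulse_scheme()] describing one cycle; must contain at
#'   least one window with 488 nm light. Include a trailing dark window to
#'   model the inter-cycle dwell.
#' @param n_cycles Number of cycles.
#' @param p0 Initial population (default all `C_MINUS`).
#' @return A `fatigue_curve` (raw integrated signal per cycle) with the
#'   final population in attribute `"final"`.
#' @export
run_fatigue <- function(params, cycle, n_cycles, p0 = population()) {
  stopifnot(inherits(cycle, "pulse_scheme"), n_cycles >= 1)
  compiled <- compile_scheme(params, cycle)
  if (all(vapply(compiled, function(cw) all(cw$w_fl == 0), TRUE)))
    stop("cycle contains no 488 nm readout window")
  sig <- numeric(n_cycles)
  p <- p0
  for (n in seq_len(n_cycles)) {
    s <- 0
    for (cw in compiled) {
      if (any(cw$w_fl != 0)) s <- s + drop(cw$w_fl %*% (cw$J %*% p))
      p <- cw$P %*% p
    }
    sig[n] <- s
    p <- drop(p)
    if (any(p < 0)) p <- clip_population(stats::setNames(p, photo_states()))
  }
  out <- fatigue_curve(seq_len(n_cycles), sig, normalization = "raw",
                       label = cycle$label)
  attr(out, "final") <- stats::setNames(drop(p), photo_states())
  out
}

#' Fatigue metrics: initial drop and fatigue fraction
#'
#' The initial drop is the sharp loss over the first cycles attributable
#' to on-switching kinetics, `1 - F(2)/F(1)` by default; the fatigue
#' fraction is the loss between cycle 4 and cycle 2000,
#' `1 - F(2000)/F(4)`. Both are invariant under global rescaling of the
#' curve. Curves shorter than the late cycle report over the available
#' range with `truncated = TRUE`.
#'
#' @param curve A `fatigue_curve` with at least 4 cycles.
#' @param drop_cycles Cycle pair for the initial drop (default `c(1, 2)`).
#' @param fatigue_cycles Cycle pair for the fatigue fraction (default
#'   `c(4, 2000)`).
#' @return List with `initial_drop`, `fatigue_fraction`, `n_cycles`,
#'   `truncated`.
#' @export
fatigue_metrics <- function(curve, drop_cycles = c(1, 2),
                            fatigue_cycles = c(4, 2000)) {
  n <- nrow(curve)
  if (n < 4) stop("fatigue metrics need at least 4 cycles")
  late <- min(fatigue_cycles[2], n)
  list(initial_drop = 1 - curve$signal[drop_cycles[2]] /
         curve$signal[drop_cycles[1]],
       fatigue_fraction = 1 - curve$signal[late] /
         curve$signal[fatigue_cycles[1]],
       n_cycles = n,
       truncated = late < fatigue_cycles[2])
}

#' Fluorescence loss of a fatigue curve at a cycle
#'
#' `1 - F(at_cycle) / F(1)`, with replicate standard deviation propagated
#' when present (dividing by the cycle-1 mean).
#'
#' @param curve A `fatigue_curve`.
#' @param at_cycle Cycle index.
#' @return List with `loss` and `sigma` (NA if the curve has no sigma).
#' @export
fluorescence_loss <- function(curve, at_cycle) {
  if (at_cycle > nrow(curve)) stop("at_cycle beyond curve length")
  f1 <- curve$signal[1]
  loss <- 1 - curve$signal[at_cycle] / f1
  sg <- if (!is.null(curve$sigma)) curve$sigma[at_cycle] / f1 else NA_real_
  list(loss = loss, sigma = sg)
}

#' Light-induced recovery between a control and a treated fatigue curve
#'
#' Recovery is the difference between the mean fluorescence loss of the
#' control condition and of the treated (co-illuminated or long-dwell)
#' condition at a given cycle; its uncertainty is propagated as
#' `sqrt(sigma_control^2 + sigma_treated^2)`.
#'
#' @param control,treated `fatigue_curve` objects on the same cycle grid,
#'   or lists as returned by [fluorescence_loss()].
#' @param at_cycle Cycle at which to compare (required for curves).
#' @return List with `control_loss`, `treated_loss`, `recovery`,
#'   `sigma` (all fractions; multiply by 100 for percentage points).
#' @export
recovery <- function(control, treated, at_cycle = NULL) {
  as_loss <- function(x) {
    if (inherits(x, "fatigue_curve")) {
      if (is.null(at_cycle)) stop("at_cycle required for fatigue curves")
      fluorescence_loss(x, at_cycle)
    } else x
  }
  if (inherits(control, "fatigue_curve") && inherits(treated, "fatigue_curve") &&
      nrow(control) != nrow(treated))
    stop("mismatched cycle grids between control and treated curves")
  cl <- as_loss(control); tl <- as_loss(treated)
  list(control_loss = cl$loss, treated_loss = tl$loss,
       recovery = cl$loss - tl$loss,
       sigma = sqrt(ifelse(is.na(cl$sigma), 0, cl$sigma)^2 +
                    ifelse(is.na(tl$sigma), 0, tl$sigma)^2))
}

## ---- canonical cycle builders ------------------------------------------

#' Canonical fatigue cycle
#'
#' One on-off photoswitching cycle as used in the fatigue experiments: a
#' 405 nm on-switching window, a 488 nm off-switching/readout window
#' (optionally with overlapped orange/NIR co-illumination plus a trailing
#' co-illumination-only window), and a dark dwell.
#'
#' @param p405,t405 405 nm power density (W/cm^2) and duration (s).
#' @param p488,t488 488 nm power density and duration.
#' @param dwell Inter-cycle dark time (s).
#' @param co_wavelength,co_power Optional co-illumination wavelength (nm)
#'   and power density; the co-illumination spans `co_duration` seconds
#'   starting with the 488 nm pulse.
#' @param co_duration Total co-illumination time (default 1 ms).
#' @return A [pulse_scheme()] describing one cycle.
#' @export
fatigue_cycle <- function(p405 = 160, t405 = 1e-3,
                          p488 = 300, t488 = 0.9e-3,
                          dwell = 10e-3,
                          co_wavelength = NULL, co_power = NULL,
                          co_duration = 1e-3) {
  windows <- list(time_window(t405, illumination(405, p405)))
  if (is.null(co_wavelength)) {
    windows <- c(windows, list(time_window(t488, illumination(488, p488))))
  } else {
    co <- illumination(co_wavelength, co_power)
    overlap <- min(t488, co_duration)
    windows <- c(windows,
                 list(time_window(overlap,
                                  list(illumination(488, p488), co))))
    if (t488 > overlap)
      windows <- c(windows, list(time_window(t488 - overlap,
                                             illumination(488, p488))))
    if (co_duration > overlap)
      windows <- c(windows, list(time_window(co_duration - overlap, co)))
  }
  if (dwell > 0) windows <- c(windows, list(time_window(dwell)))
  pulse_scheme(windows, label = "fatigue-cycle")
}

## ---- protocol-level experiments ----------------------------------------

#' Stretched on-switching at constant energy dose
#'
#' Delivers a fixed total 405 nm energy dose (default 64 mJ/cm^2) over a
#' range of activation times, with the power density set by the
#' constant-dose rule `power = dose / time`. Each condition runs one
#' 488-only reference cycle (taken to report the true on-state
#' concentration) followed by `n_cycles` on-off cycles; the reported value
#' per condition is the mean integrated fluorescence of cycles
#' `report_cycles`, normalized to the reference cycle.
#'
#' @param params A [rate_params()] object.
#' @param times Activation durations in seconds.
#' @param total_dose Total 405 nm energy dose in J/cm^2 (default 0.064).
#' @param p488,t488 488 nm readout power density and duration; by default
#'   `t488` is calibrated to off-switch to 20% at `p488`.
#' @param dwell Inter-cycle dark time (s).
#' @param n_cycles On-off cycles per condition (default 25).
#' @param report_cycles Cycles averaged for the report (default 2:21,
#'   skipping the first-cycle transient).
#' @return Data frame with `time_s`, `power_wcm2`, `norm_fluorescence`,
#'   `loss`.
#' @export
stretched_activation <- function(params, times,
                                 total_dose = 64e-3,
                                 p488 = 300, t488 = NULL,
                                 dwell = 10e-3,
                                 n_cycles = 25, report_cycles = 2:21) {
  if (is.null(t488)) t488 <- calibrate_offswitch_time(params, p488)
  out <- lapply(times, function(t405) {
    p405 <- total_dose / t405
    ref <- pulse_scheme(list(time_window(t488, illumination(488, p488)),
                             time_window(dwell)),
                        label = "488-only-reference")
    ## reference cycle from the fully relaxed on state
    ref_curve <- run_fatigue(params, ref, 1)
    p_after <- attr(ref_curve, "final")
    cyc <- fatigue_cycle(p405 = p405, t405 = t405, p488 = p488,
                         t488 = t488, dwell = dwell)
    curve <- run_fatigue(params, cyc, n_cycles, p0 = p_after)
    fl <- mean(curve$signal[report_cycles]) / ref_curve$signal[1]
    data.frame(time_s = t405, power_wcm2 = p405,
               norm_fluorescence = fl, loss = 1 - fl)
  })
  do.call(rbind, out)
}

#' Two-pulse dark-state relaxation scan
#'
#' Protocol: a 5 us 405 nm burst at 30 kW/cm^2 switches the ensemble on, a
#' 3 ms dark gap lets the on-switching intermediates relax, then two
#' identical 488 nm pulses (500 us at 40 kW/cm^2) are delivered, separated
#' by a variable dark delay. The integrated fluorescence of the second
#' pulse, normalized to a zero-delay control, rises with delay as
#' shelved dark states (dominated by the triplet) relax back to the
#' emissive state.
#'
#' @param params A [rate_params()] object.
#' @param delays Inter-pulse dark delays in seconds (>= 0).
#' @param p405,t405 Activation burst parameters.
#' @param p488,t488 488 nm pulse parameters.
#' @param relax_gap Dark gap between activation and first 488 pulse.
#' @param p0 Starting population (default all `TH`, i.e. off-switched).
#' @return Data frame with `delay_s`, `signal` (a.u.), `norm` (relative to
#'   the zero-delay control).
#' @export
two_pulse_delay_scan <- function(params, delays,
                                 p405 = 30e3, t405 = 5e-6,
                                 p488 = 40e3, t488 = 500e-6,
                                 relax_gap = 3e-3,
                                 p0 = population(c(TH = 1))) {
  stopifnot(all(delays >= 0))
  pulse488 <- time_window(t488, illumination(488, p488))
  pre <- pulse_scheme(list(time_window(t405, illumination(405, p405)),
                           time_window(relax_gap),
                           pulse488))
  ## state right after the first 488 pulse is shared by all delays
  traj_pre <- simulate_scheme(params, pre, p0 = p0, n_per_window = 2)
  p_after1 <- final_population(traj_pre)
  second_signal <- function(delay) {
    p <- p_after1
    sch <- if (delay > 0)
      pulse_scheme(list(time_window(delay), pulse488))
    else pulse_scheme(list(pulse488))
    traj <- simulate_scheme(params, sch, p0 = p, n_per_window = 2)
    t_end <- traj$time_s[nrow(traj)]
    integrated_fluorescence(traj, from = t_end - t488, to = t_end)
  }
  sig <- vapply(delays, second_signal, 0)
  ctrl <- second_signal(0)
  data.frame(delay_s = delays, signal = sig, norm = sig / ctrl)
}

#' Dwell-time fatigue experiment
#'
#' Runs identical fatigue experiments whose cycles differ only in the dark
#' dwell separating them. Longer dwells let long-lived reversible dark
#' products relax between cycles, reducing the apparent fatigue.
#'
#' @param params A [rate_params()] object.
#' @param dwells Dark dwell times in seconds.
#' @param n_cycles Cycles per experiment.
#' @param ... Remaining cycle parameters passed to [fatigue_cycle()].
#' @return Named list of normalized `fatigue_curve`s, one per dwell.
#' @export
dwell_time_experiment <- function(params, dwells, n_cycles = 1600, ...) {
  stopifnot(all(dwells >= 0))
  out <- lapply(dwells, function(dw) {
    normalize_curve(run_fatigue(params, fatigue_cycle(dwell = dw, ...),
                                n_cycles))
  })
  names(out) <- paste0(format(dwells * 1e3, trim = TRUE), "ms")
  out
}

#' Recovery versus co-illumination power sweep
#'
#' For each co-illumination power density, runs a 2000-cycle fatigue
#' experiment with the co-illumination overlapped with the 488 nm pulse
#' and compares the fluorescence loss at the final cycle against the
#' control (no co-illumination) experiment.
#'
#' @param params A [rate_params()] object.
#' @param powers Co-illumination power densities (W/cm^2).
#' @param wavelength Co-illumination wavelength in nm (default 592).
#' @param n_cycles Cycles (default 2000).
#' @param at_cycle Cycle at which recovery is evaluated (default
#'   `n_cycles`).
#' @param ... Base cycle parameters passed to [fatigue_cycle()].
#' @return Data frame with `power_wcm2`, `control_loss`, `treated_loss`,
#'   `recovery` (fractions).
#' @export
recovery_power_sweep <- function(params, powers, wavelength = 592,
                                 n_cycles = 2000, at_cycle = n_cycles,
                                 ...) {
  ctrl <- normalize_curve(run_fatigue(params, fatigue_cycle(...), n_cycles))
  cl <- fluorescence_loss(ctrl, at_cycle)
  out <- lapply(powers, function(pw) {
    cyc <- fatigue_cycle(co_wavelength = wavelength, co_power = pw, ...)
    tr <- normalize_curve(run_fatigue(params, cyc, n_cycles))
    r <- recovery(cl, fluorescence_loss(tr, at_cycle))
    data.frame(power_wcm2 = pw, control_loss = r$control_loss,
               treated_loss = r$treated_loss, recovery = r$recovery)
  })
  do.call(rbind, out)
}

#' Metric sweep over an illumination-power grid
#'
#' Evaluates a fatigue metric over a grid of 405 nm power densities
#' crossed with either 488 nm or co-illumination power densities, one
#' fatigue simulation per grid point.
#'
#' @param params A [rate_params()] object.
#' @param p405_grid 405 nm power densities (W/cm^2).
#' @param p2_grid Second-axis power densities (W/cm^2).
#' @param metric `"fatigue_fraction"` or `"recovery"`.
#' @param axis2 `"488"` (vary 488 power; with `dose488` fixed the 488 time
#'   is `dose488 / power`) or `"592"` (vary co-illumination at fixed 488).
#' @param n_cycles Cycles per grid point.
#' @param dose488 Constant 488 energy dose in J/cm^2 used when
#'   `axis2 = "488"` (default `300 * 0.9e-3`).
#' @param ... Base cycle parameters passed to [fatigue_cycle()].
#' @return Matrix of metric values, rows indexed by `p405_grid`, columns
#'   by `p2_grid`, with axis values in dimnames.
#' @export
power_sweep <- function(params, p405_grid, p2_grid,
                        metric = c("fatigue_fraction", "recovery"),
                        axis2 = c("488", "592"),
                        n_cycles = 2000, dose488 = 300 * 0.9e-3, ...) {
  metric <- match.arg(metric)
  axis2 <- match.arg(axis2)
  M <- matrix(NA_real_, length(p405_grid), length(p2_grid),
              dimnames = list(p405 = format(p405_grid, trim = TRUE),
                              p2 = format(p2_grid, trim = TRUE)))
  for (i in seq_along(p405_grid)) for (j in seq_along(p2_grid)) {
    if (axis2 == "488") {
      t488 <- dose488 / p2_grid[j]
      cyc <- fatigue_cycle(p405 = p405_grid[i], p488 = p2_grid[j],
                           t488 = t488, ...)
      curve <- run_fatigue(params, cyc, n_cycles)
      M[i, j] <- if (metric == "fatigue_fraction")
        fatigue_metrics(curve)$fatigue_fraction
      else stop("recovery metric requires axis2 = '592'")
    } else {
      if (metric == "fatigue_fraction") {
        cyc <- fatigue_cycle(p405 = p405_grid[i],
                             co_wavelength = 592, co_power = p2_grid[j], ...)
        M[i, j] <- fatigue_metrics(run_fatigue(params, cyc, n_cycles))$fatigue_fraction
      } else {
        sw <- recovery_power_sweep(params, p2_grid[j], wavelength = 592,
                                   n_cycles = n_cycles,
                                   p405 = p405_grid[i], ...)
        M[i, j] <- sw$recovery
      }
    }
  }
  M
}

#' Write a sweep matrix as CSV with axis headers
#' @param m Matrix from [power_sweep()].
#' @param path Output path.
#' @export
write_sweep <- function(m, path) {
  df <- data.frame(p405_wcm2 = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
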