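#' Camera noise specification
#'
#' Emulates sCMOS-like detection: expected photon counts are
#' `scale * signal` (Poisson shot noise), read noise is additive Gaussian
#' in counts, and the recorded value is the non-negative rounded count.
#'
#' @param scale Expected photons (counts) per arbitrary unit of simulated
#'   signal (> 0; `Inf` disables shot noise).
#' @param read_sd Gaussian read noise standard deviation in counts (>= 0).
#' @param seed Integer seed recorded in every generator output.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(scale = 1e4, read_sd = 0, seed = 1) {
  stopifnot(scale > 0, read_sd >= 0)
  structure(list(scale = scale, read_sd = read_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

## Noisy counts for a vector/array of signal values (a.u.); shape
## preserved. With an infinite photon budget the signal passes through
## unchanged (count scale 1).
apply_noise <- function(x, noise, counts = TRUE) {
  dims <- dim(x)
  v <- pmax(0, as.numeric(x))
  out <- if (is.finite(noise$scale))
    stats::rpois(length(v), noise$scale * v) else v
  if (noise$read_sd > 0)
    out <- out + stats::rnorm(length(v), 0, noise$read_sd)
  if (counts) out <- pmax(0, round(out))
  dim(out) <- dims
  out
}

## counts-per-a.u. factor actually applied by apply_noise
noise_gain <- function(noise) if (is.finite(noise$scale)) noise$scale else 1

#' Generate noisy replicate fatigue curves
#'
#' Forward-simulates a fatigue experiment and overlays Poisson shot noise
#' and Gaussian read noise to emulate replicate gel measurements; the
#' noiseless generative truth is returned alongside.
#'
#' @param params A [rate_params()] object.
#' @param cycle One fatigue cycle ([pulse_scheme()] or [fatigue_cycle()]).
#' @param n_cycles Cycles per curve.
#' @param replicates Number of replicate curves (>= 1).
#' @param noise A [noise_spec()].
#' @return List with `truth` (noiseless `fatigue_curve`), `replicates`
#'   (list of noisy curves, in a.u. of the truth), `aggregate`
#'   (`fatigue_curve` with replicate mean and sigma) and `seed`.
#' @export
gen_fatigue_curves <- function(params, cycle, n_cycles, replicates = 3,
                               noise = noise_spec()) {
  stopifnot(replicates >= 1)
  set.seed(noise$seed)
  truth <- run_fatigue(params, cycle, n_cycles)
  ## express the per-cycle signal in detected counts, then back in a.u.
  reps <- lapply(seq_len(replicates), function(r) {
    counts <- apply_noise(truth$signal, noise, counts = FALSE)
    fatigue_curve(truth$cycle, counts / noise_gain(noise),
                  label = sprintf("replicate-%d", r))
  })
  m <- rowMeans(vapply(reps, `[[`, numeric(n_cycles), "signal"))
  s <- apply(vapply(reps, `[[`, numeric(n_cycles), "signal"), 1, stats::sd)
  if (replicates == 1) s <- rep(0, n_cycles)
  list(truth = truth, replicates = reps,
       aggregate = fatigue_curve(truth$cycle, m, sigma = s,
                                 label = "replicate-mean"),
       seed = noise$seed)
}

#' Synthetic bacteria scene specification
#'
#' Describes a field of rod-shaped objects ("bacteria"), each expressing
#' one RSFP class whose photophysics is given by a per-class parameter
#' set. Objects are placed by rejection sampling without overlap (a 1 px
#' margin), hard-edged rods later smoothed by a 1 px Gaussian blur as a
#' point-spread-function proxy.
#'
#' @param size Image size `c(rows, cols)`.
#' @param n_per_class Objects per class.
#' @param class_params Named list of [rate_params()] (one per class).
#' @param rod_length,rod_width Length/width ranges in px.
#' @param brightness Per-object brightness factor range (uniform).
#' @param max_tries Rejection-sampling cap before erroring.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(size = c(96, 96), n_per_class = 12, class_params,
                       rod_length = c(8, 14), rod_width = c(3, 4.5),
                       brightness = c(0.8, 1.2), max_tries = 5000) {
  stopifnot(length(class_params) >= 1, !is.null(names(class_params)))
  structure(list(size = size, n_per_class = n_per_class,
                 class_params = class_params, rod_length = rod_length,
                 rod_width = rod_width, brightness = brightness,
                 max_tries = max_tries),
            class = "scene_spec")
}

## pixels within width/2 of a segment of given center/angle/length
rod_pixels <- function(size, center, angle, length, width, margin = 0) {
  half <- length / 2
  ux <- cos(angle); uy <- sin(angle)
  r <- width / 2 + margin
  rmin <- max(1, floor(center[1] - half - r)); rmax <- min(size[1], ceiling(center[1] + half + r))
  cmin <- max(1, floor(center[2] - half - r)); cmax <- min(size[2], ceiling(center[2] + half + r))
  if (rmin > rmax || cmin > cmax) return(integer(0))
  g <- expand.grid(row = rmin:rmax, col = cmin:cmax)
  dx <- g$row - center[1]; dy <- g$col - center[2]
  t <- pmax(-half, pmin(half, dx * ux + dy * uy))
  d2 <- (dx - t * ux)^2 + (dy - t * uy)^2
  sel <- d2 <= r^2
  (g$col[sel] - 1L) * size[1] + g$row[sel]
}

## place all objects of a scene; returns list of (class, pixels, amp, ...)
place_objects <- function(scene) {
  size <- scene$size
  occupied <- matrix(FALSE, size[1], size[2])
  out <- list()
  id <- 0L
  for (cl in names(scene$class_params)) {
    for (i in seq_len(scene$n_per_class)) {
      placed <- FALSE
      for (try in seq_len(scene$max_tries)) {
        len <- stats::runif(1, scene$rod_length[1], scene$rod_length[2])
        wid <- stats::runif(1, scene$rod_width[1], scene$rod_width[2])
        ctr <- c(stats::runif(1, 1 + len / 2, size[1] - len / 2),
                 stats::runif(1, 1 + len / 2, size[2] - len / 2))
        ang <- stats::runif(1, 0, pi)
        pad <- rod_pixels(size, ctr, ang, len, wid, margin = 1.5)
        if (length(pad) == 0 || any(occupied[pad])) next
        px <- rod_pixels(size, ctr, ang, len, wid)
        occupied[pad] <- TRUE
        id <- id + 1L
        out[[id]] <- list(id = id, class = cl, pixels = px,
                          amp = stats::runif(1, scene$brightness[1],
                                             scene$brightness[2]))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("cannot place objects: scene overflow after ",
             scene$max_tries, " tries")
    }
  }
  out
}

## per-frame integrated 488 fluorescence of one class under a frame-wise
## window sequence, populations carried across frames
class_frame_trace <- function(params, frames, p0 = population()) {
  cache <- new.env(parent = emptyenv())
  p <- p0
  sig <- numeric(length(frames))
  for (f in seq_along(frames)) {
    s <- 0
    for (w in frames[[f]]) {
      key <- window_key(w)
      if (is.null(cache[[key]])) {
        K <- build_rate_matrix(params, w$illums)
        cache[[key]] <- list(ops = make_ops(K),
                             w_fl = fluorescence_weights(params, w$illums))
      }
      cw <- cache[[key]]
      kd <- paste0(key, "@", w$duration)
      if (is.null(cache[[kd]]))
        cache[[kd]] <- list(P = ops_propagator(cw$ops, w$duration),
                            J = ops_integral(cw$ops, w$duration))
      if (any(cw$w_fl != 0))
        s <- s + drop(cw$w_fl %*% (cache[[kd]]$J %*% p))
      p <- drop(cache[[kd]]$P %*% p)
    }
    sig[f] <- s
  }
  sig
}

render_stack <- function(scene, objects, traces, noise) {
  n_frames <- ncol(traces)
  size <- scene$size
  label_mask <- matrix(0L, size[1], size[2])
  for (ob in objects) label_mask[ob$pixels] <- ob$id
  stack <- array(0, dim = c(n_frames, size[1], size[2]))
  for (f in seq_len(n_frames)) {
    img <- matrix(0, size[1], size[2])
    for (ob in objects)
      img[ob$pixels] <- img[ob$pixels] + ob$amp * traces[ob$class, f]
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 1))
    stack[f, , ] <- apply_noise(img, noise)
  }
  list(stack = stack, label_mask = label_mask,
       labels = data.frame(object = vapply(objects, `[[`, 0L, "id"),
                           class = vapply(objects, `[[`, "", "class")))
}

#' Generate a four-dose multiplexing image stack
#'
#' Emulates the intra-pixel 405 nm dose-modulation acquisition: each
#' repeat consists of four frames with increasing on-switching doses
#' followed by a 488 nm readout, repeated `repeats` times
#' (`4 * repeats` frames in total, 60 by default). Each object's
#' per-frame brightness is its class photocycle simulated under the full
#' dose history, including cumulative photobleaching; rods are rendered
#' with shot and read noise, and the ground truth (label mask, class
#' table, noiseless traces) is returned alongside.
#'
#' @param scene A [scene_spec()].
#' @param doses Four 405 nm dose durations in seconds (ascending; the 4th,
#'   largest dose is the normalizer frame).
#' @param repeats Number of four-frame repeats (default 15).
#' @param noise A [noise_spec()].
#' @param p405,p488,t488 Illumination parameters of the activation and
#'   readout windows.
#' @param gap Dark gap after each readout (s).
#' @return List with `stack` (`4*repeats x rows x cols` counts),
#'   `label_mask`, `labels`, `traces` (class x frame, noiseless), `seed`.
#' @export
gen_multiplex_stack <- function(scene,
                                doses = c(0.05, 0.15, 0.5, 2) * 1e-3,
                                repeats = 15, noise = noise_spec(),
                                p405 = 160, p488 = 300, t488 = 0.9e-3,
                                gap = 10e-3) {
  if (length(doses) != 4) stop("need exactly 4 on-switching doses")
  stopifnot(repeats >= 1)
  set.seed(noise$seed)
  objects <- place_objects(scene)
  frame_windows <- rep(lapply(doses, function(d) {
    list(time_window(d, illumination(405, p405)),
         time_window(t488, illumination(488, p488)),
         time_window(gap))
  }), repeats)
  traces <- t(vapply(scene$class_params, function(cp)
    class_frame_trace(cp, frame_windows), numeric(length(frame_windows))))
  rownames(traces) <- names(scene$class_params)
  out <- render_stack(scene, objects, traces, noise)
  c(out, list(traces = traces, seed = noise$seed))
}

#' Generate an off-switching decay time-lapse
#'
#' Emulates the decay-classification experiment: starting from a fully
#' on-switched ensemble, every frame delivers a weak 405 nm re-activation
#' followed by a 488 nm readout (optionally with 592 nm co-illumination
#' overlapped). The across-frame trace decays toward a
#' re-activation/off-switching quasi-steady state at a rate set by each
#' class's off-switching yield — the classification signature — while
#' photobleaching accumulates through the class photocycle, so
#' co-illumination visibly reduces the measured fluorescence loss for
#' triplet-bleach-dominated classes.
#'
#' @param scene A [scene_spec()] (>= 2 classes for classification tests).
#' @param n_frames Number of readout frames (default 50).
#' @param co592 592 nm co-illumination power density (W/cm^2), or `NULL`.
#' @param noise A [noise_spec()].
#' @param p405,t405 Per-frame weak re-activation pulse.
#' @param p488,t488 Per-frame readout window.
#' @param gap Dark gap between frames (s).
#' @return As [gen_multiplex_stack()].
#' @export
gen_decay_stack <- function(scene, n_frames = 50, co592 = NULL,
                            noise = noise_spec(),
                            p405 = 160, t405 = 3e-5,
                            p488 = 300, t488 = 0.4e-3, gap = 5e-3) {
  set.seed(noise$seed)
  objects <- place_objects(scene)
  readout <- if (is.null(co592))
    list(time_window(t488, illumination(488, p488)))
  else list(time_window(t488, list(illumination(488, p488),
                                   illumination(592, co592))))
  frames <- rep(list(c(list(time_window(t405, illumination(405, p405))),
                       readout, list(time_window(gap)))), n_frames)
  traces <- t(vapply(scene$class_params, function(cp)
    class_frame_trace(cp, frames), numeric(n_frames)))
  rownames(traces) <- names(scene$class_params)
  out <- render_stack(scene, objects, traces, noise)
  c(out, list(traces = traces, seed = noise$seed))
}
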