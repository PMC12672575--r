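#' Photon flux of an illumination
#'
#' Converts a power density (W/cm^2) at a given wavelength into a photon
#' flux, `power / (h * c / lambda)`.
#'
#' @param illum An [illumination()] object.
#' @return Photon flux in photons cm^-2 s^-1.
#' @export
photon_flux <- function(illum) {
  stopifnot(inherits(illum, "illumination"))
  photon_energy <- PLANCK_H * SPEED_C / (illum$wavelength * 1e-9)  # J
  illum$power / photon_energy
}

#' Build the kinetic generator matrix for a set of illuminations
#'
#' Assembles the rate matrix `K` of the linear system `dP/dt = K P` over
#' the eight photocycle states for a fixed set of simultaneously active
#' lasers. Entry `K[j, i]` is the first-order rate of the `i -> j`
#' transition; diagonal entries close each column to zero so that total
#' population (including the `BLEACHED` sink) is conserved.
#'
#' Light-driven entries are `sigma_s(lambda) * flux(lambda) * yield`,
#' summed over active lasers; thermal entries are present regardless of
#' light. Branching out of `C_INT` uses its 405 nm absorption only; its
#' 488 nm cross-section contributes to the fluorescence observable, not to
#' the kinetics.
#'
#' @param params A [rate_params()] object.
#' @param illums List of [illumination()] objects (possibly empty = dark).
#' @return 8 x 8 generator matrix (1/s) with state dimnames.
#' @export
build_rate_matrix <- function(params, illums = list()) {
  if (inherits(illums, "illumination")) illums <- list(illums)
  st <- photo_states()
  K <- matrix(0, N_STATES, N_STATES, dimnames = list(st, st))
  add <- function(from, to, rate) {
    if (rate < 0) stop("negative rate for ", from, " -> ", to)
    K[state_index(to), state_index(from)] <<-
      K[state_index(to), state_index(from)] + rate
  }

  ## thermal transitions (always on)
  add("T_ANION", "TH",      params$k_prot)
  add("CH",      "C_INT",   params$k_deprot)
  add("C_INT",   "C_MINUS", params$k_int)
  add("D_REV",   "C_MINUS", params$k_drev)
  if (params$tau_t > 0) {
    kT <- 1 / params$tau_t
    add("T1", "C_MINUS",  kT * (1 - params$f_drev - params$phi_t1))
    add("T1", "D_REV",    kT * params$f_drev)
    add("T1", "BLEACHED", kT * params$phi_t1)
  }

  ## light-driven transitions
  for (il in illums) {
    flux <- photon_flux(il)
    lam <- il$wavelength
    a_c <- sigma_at(params, "C_MINUS", lam) * flux
    if (a_c > 0) {
      add("C_MINUS", "T_ANION",  a_c * params$phi_off)
      add("C_MINUS", "T1",       a_c * params$phi_isc)
      add("C_MINUS", "BLEACHED", a_c * params$phi_bleach_on)
    }
    a_th <- sigma_at(params, "TH", lam) * flux
    if (a_th > 0) add("TH", "CH", a_th * params$phi_on)
    a_i <- sigma_at(params, "C_INT", lam) * flux
    if (a_i > 0) {
      if (lam == 405) {
        ## violet absorption of the intermediate drives it back to the off
        ## state and feeds the on-switching-path bleaching channel
        add("C_INT", "TH",       a_i * params$phi_int_off)
        add("C_INT", "BLEACHED", a_i * params$phi_int_bleach)
      } else {
        ## under excitation light the anionic on-like intermediate shares
        ## the photochemistry of the on state
        add("C_INT", "T_ANION",  a_i * params$phi_off)
        add("C_INT", "T1",       a_i * params$phi_isc)
        add("C_INT", "BLEACHED", a_i * params$phi_bleach_on)
      }
    }
    a_t1 <- sigma_at(params, "T1", lam) * flux
    if (a_t1 > 0) {
      add("T1", "C_MINUS",  a_t1 * params$phi_risc)
      add("T1", "BLEACHED", a_t1 * params$phi_tn)
    }
    a_d <- sigma_at(params, "D_REV", lam) * flux
    if (a_d > 0) add("D_REV", "BLEACHED", a_d * params$phi_drev_bleach)
  }

  diag(K) <- diag(K) - colSums(K)
  K
}

## Instantaneous-fluorescence state weights (a.u./s per unit population):
## emission is driven by 488 nm excitation of the emissive states.
fluorescence_weights <- function(params, illums) {
  if (inherits(illums, "illumination")) illums <- list(illums)
  w <- stats::setNames(numeric(N_STATES), photo_states())
  for (il in illums) {
    if (il$wavelength != 488) next
    flux <- photon_flux(il)
    w["C_MINUS"] <- w["C_MINUS"] +
      params$beta * sigma_at(params, "C_MINUS", 488) * flux
    w["C_INT"] <- w["C_INT"] +
      params$beta * params$w_cint * sigma_at(params, "C_INT", 488) * flux
  }
  w
}

## ---- exact propagation --------------------------------------------------

EIG_COND_LIMIT <- 1e12

## Prepare a propagation operator for a generator matrix: spectral
## decomposition when well-conditioned, otherwise a flag for the
## scaling-and-squaring matrix-exponential fallback.
make_ops <- function(K) {
  e <- tryCatch(eigen(K), error = function(e) NULL)
  if (!is.null(e)) {
    Vi <- tryCatch(solve(e$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      cond <- max(colSums(Mod(e$vectors))) * max(colSums(Mod(Vi)))
      if (is.finite(cond) && cond < EIG_COND_LIMIT)
        return(list(type = "eig", K = K, V = e$vectors, lam = e$values,
                    Vi = Vi))
    }
  }
  list(type = "expm", K = K)
}

## exp(K t)
ops_propagator <- function(ops, t) {
  if (ops$type == "eig") {
    M <- Re(ops$V %*% (exp(ops$lam * t) * ops$Vi))
  } else {
    M <- as.matrix(Matrix::expm(ops$K * t))
  }
  dimnames(M) <- dimnames(ops$K)
  M
}

## integral operator J(t) = \int_0^t exp(K s) ds
ops_integral <- function(ops, t) {
  if (ops$type == "eig") {
    z <- ops$lam * t
    g <- ifelse(abs(z) < 1e-6,
                t * (1 + z / 2 + z * z / 6),
                (exp(z) - 1) / ops$lam)
    M <- Re(ops$V %*% (g * ops$Vi))
  } else {
    ## augmented-matrix trick: expm([[K, I], [0, 0]] t) upper-right block
    n <- nrow(ops$K)
    A <- rbind(cbind(ops$K, diag(n)), matrix(0, n, 2 * n))
    M <- as.matrix(Matrix::expm(A * t))[seq_len(n), n + seq_len(n)]
  }
  dimnames(M) <- dimnames(ops$K)
  M
}

#' Propagate a population vector under a constant generator
#'
#' Exact solution of `dP/dt = K P` over a duration `t`, via spectral
#' decomposition of `K` (falling back to a scaling-and-squaring matrix
#' exponential when the eigenvector matrix is ill-conditioned). Tiny
#' negative entries (> -1e-12) arising from roundoff are clipped and the
#' vector renormalized.
#'
#' @param p0 Initial population ([population()]).
#' @param K Generator matrix from [build_rate_matrix()].
#' @param t Duration in seconds (>= 0).
#' @return Population vector at time `t`.
#' @export
propagate <- function(p0, K, t) {
  stopifnot(t >= 0)
  if (t == 0) return(p0)
  p <- drop(ops_propagator(make_ops(K), t) %*% p0)
  clip_population(stats::setNames(p, photo_states()))
}

## ---- scheme simulation --------------------------------------------------

window_key <- function(w) {
  if (length(w$illums) == 0) return("dark")
  paste(sort(vapply(w$illums, function(i)
    sprintf("%g@%.10g", i$wavelength, i$power), "")), collapse = "|")
}

## Compile the per-window operators of a scheme once; windows sharing an
## illumination set share a generator.
compile_scheme <- function(params, scheme) {
  cache <- new.env(parent = emptyenv())
  lapply(scheme$windows, function(w) {
    key <- window_key(w)
    if (is.null(cache[[key]])) {
      K <- build_rate_matrix(params, w$illums)
      cache[[key]] <- list(ops = make_ops(K),
                           w_fl = fluorescence_weights(params, w$illums))
    }
    c(cache[[key]],
      list(duration = w$duration,
           P = ops_propagator(cache[[key]]$ops, w$duration),
           J = ops_integral(cache[[key]]$ops, w$duration)))
  })
}

#' Simulate a pulse scheme
#'
#' Propagates an initial population window by window through a pulse
#' scheme. Propagation is exact at window boundaries (final populations do
#' not depend on the sampling density); within each window the trajectory
#' is sampled on a uniform grid for output.
#'
#' @param params A [rate_params()] object.
#' @param scheme A [pulse_scheme()].
#' @param p0 Initial population; default all `C_MINUS` (the
#'   thermodynamically stable on state).
#' @param n_per_window Output samples per window (>= 2).
#' @return A `trajectory` object: data frame with `time_s`, one column per
#'   state, and `fluorescence_au` (instantaneous emission rate), carrying
#'   the exact per-window operators for [integrated_fluorescence()].
#' @export
simulate_scheme <- function(params, scheme, p0 = population(),
                            n_per_window = 64) {
  stopifnot(inherits(scheme, "pulse_scheme"), n_per_window >= 2)
  compiled <- compile_scheme(params, scheme)
  t0 <- 0
  p <- p0
  times <- numeric(0)
  pops <- list()
  fl <- numeric(0)
  segments <- list()
  for (rep in seq_len(scheme$repeats)) {
    for (cw in compiled) {
      ts <- seq(0, cw$duration, length.out = n_per_window)
      Pt <- vapply(ts, function(t)
        drop(ops_propagator(cw$ops, t) %*% p), numeric(N_STATES))
      Pt[Pt < 0 & Pt > -1e-12] <- 0
      times <- c(times, t0 + ts)
      pops[[length(pops) + 1]] <- t(Pt)
      fl <- c(fl, drop(cw$w_fl %*% Pt))
      segments[[length(segments) + 1]] <-
        list(t0 = t0, t1 = t0 + cw$duration, ops = cw$ops, w_fl = cw$w_fl,
             p0 = p)
      p <- clip_population(stats::setNames(drop(cw$P %*% p), photo_states()))
      t0 <- t0 + cw$duration
    }
  }
  P <- do.call(rbind, pops)
  colnames(P) <- photo_states()
  traj <- data.frame(time_s = times, P, fluorescence_au = fl,
                     check.names = FALSE)
  structure(traj, class = c("trajectory", "data.frame"),
            segments = segments, final = p)
}

#' Final population of a simulated trajectory
#' @param traj A `trajectory` from [simulate_scheme()].
#' @return Population vector at the end of the scheme (exact).
#' @export
final_population <- function(traj) attr(traj, "final")

#' Integrated fluorescence over a time interval
#'
#' Integrates the instantaneous emission rate `beta * sum_s sigma_s(488) *
#' flux(488) * w_s * P_s(t)` over `[from, to]`. The integral is evaluated
#' analytically segment by segment from the spectral decomposition of each
#' window's generator, not by quadrature on the sampled trajectory.
#'
#' @param traj A `trajectory` from [simulate_scheme()].
#' @param from,to Interval bounds in seconds; default the full trajectory.
#' @return Integrated signal (a.u.).
#' @export
integrated_fluorescence <- function(traj, from = NULL, to = NULL) {
  segs <- attr(traj, "segments")
  span <- c(segs[[1]]$t0, segs[[length(segs)]]$t1)
  if (is.null(from)) from <- span[1]
  if (is.null(to)) to <- span[2]
  if (to <= from) stop("empty integration window")
  if (from < span[1] - 1e-12 || to > span[2] + 1e-12)
    stop("integration window outside trajectory span")
  total <- 0
  for (s in segs) {
    a <- max(from, s$t0); b <- min(to, s$t1)
    if (b <= a) next
    if (all(s$w_fl == 0)) next
    Jb <- ops_integral(s$ops, b - s$t0)
    Ja <- if (a > s$t0) ops_integral(s$ops, a - s$t0) else 0
    total <- total + drop(s$w_fl %*% ((Jb - Ja) %*% s$p0))
  }
  total
}

#' Write a trajectory as CSV
#'
#' Columns: `time_s`, one column per state, `fluorescence_au`.
#' @param traj A `trajectory`.
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
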