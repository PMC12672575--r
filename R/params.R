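#' Rate parameters for an RSFP photocycle model
#'
#' Collects the absorption cross-sections, per-absorption branching yields
#' and thermal rates that define the photocycle generator. Absorption is
#' treated adiabatically: excited singlet and upper triplet states decay on
#' ns/ps scales, far below any illumination window, so a photon absorption
#' maps directly onto branching yields between the ground and metastable
#' states.
#'
#' @param sigma Named list of per-state cross-section tables. Each element
#'   is a named numeric vector, wavelength (nm, as name) to cross-section
#'   (cm^2). States absent from the list do not absorb.
#' @param phi_off Off-switching yield: probability per photon absorbed by
#'   `C_MINUS` of branching to `T_ANION` (cis-to-trans isomerization).
#' @param phi_isc Intersystem-crossing yield per `C_MINUS` absorption
#'   (to `T1`).
#' @param phi_bleach_on Direct photobleaching yield per `C_MINUS`
#'   absorption (small residual channel).
#' @param phi_on On-switching yield per photon absorbed by `TH` (to `CH`).
#' @param phi_int_off Yield per 405 nm photon absorbed by `C_INT` of
#'   converting back to `TH` (the on-switching-path loss channel).
#' @param phi_int_bleach Photobleaching yield per `C_INT` absorption
#'   (bleaching pathway rooted in the on-switching intermediates).
#' @param phi_risc Reverse-intersystem-crossing yield per photon absorbed
#'   by `T1` (back to `C_MINUS` via the upper triplet manifold).
#' @param phi_tn Photobleaching yield per `T1` photon absorption
#'   (excited-triplet bleaching).
#' @param tau_t Thermal lifetime of `T1` in seconds.
#' @param f_drev Branch fraction of thermal `T1` decay that forms the
#'   long-lived reversible dark product `D_REV`.
#' @param phi_t1 Branch fraction of thermal `T1` decay that bleaches
#'   (ground-triplet bleaching yield). The remainder,
#'   `1 - f_drev - phi_t1`, returns to `C_MINUS`.
#' @param k_prot Protonation rate `T_ANION -> TH` (1/s; about 1/50 us at
#'   physiological pH).
#' @param k_deprot Deprotonation rate `CH -> C_INT` (1/s, fast).
#' @param k_int Relaxation rate `C_INT -> C_MINUS` (1/s; about 1/1 ms).
#' @param k_drev Thermal recovery rate `D_REV -> C_MINUS` (1/s; tens of
#'   milliseconds).
#' @param phi_drev_bleach Photobleaching yield per photon absorbed by
#'   `D_REV`: the long-lived photoproduct is itself photolabile, so light
#'   arriving before it has relaxed converts it irreversibly (the
#'   "reversible and irreversible" consequences of the triplet-seeded dark
#'   product).
#' @param beta Fluorescence brightness constant (arbitrary units per
#'   excitation event).
#' @param w_cint Emission weight of `C_INT` relative to `C_MINUS`.
#' @param label Free-text parameter-set label.
#'
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(sigma,
                        phi_off, phi_isc, phi_bleach_on = 0,
                        phi_on,
                        phi_int_off = 0, phi_int_bleach = 0,
                        phi_risc = 0, phi_tn = 0,
                        tau_t = 2.5e-3, f_drev = 0, phi_t1 = 0,
                        k_prot = 2e4, k_deprot = 2e5, k_int = 1e3,
                        k_drev = 25, phi_drev_bleach = 0,
                        beta = 1, w_cint = 1, label = "") {
  p <- list(sigma = sigma,
            phi_off = phi_off, phi_isc = phi_isc,
            phi_bleach_on = phi_bleach_on,
            phi_on = phi_on,
            phi_int_off = phi_int_off, phi_int_bleach = phi_int_bleach,
            phi_risc = phi_risc, phi_tn = phi_tn,
            tau_t = tau_t, f_drev = f_drev, phi_t1 = phi_t1,
            k_prot = k_prot, k_deprot = k_deprot, k_int = k_int,
            k_drev = k_drev, phi_drev_bleach = phi_drev_bleach,
            beta = beta, w_cint = w_cint, label = label)
  class(p) <- "rate_params"
  validate_rate_params(p)
  p
}

validate_rate_params <- function(p) {
  yields <- c(p$phi_off, p$phi_isc, p$phi_bleach_on, p$phi_on,
              p$phi_int_off, p$phi_int_bleach, p$phi_risc, p$phi_tn,
              p$f_drev, p$phi_t1, p$phi_drev_bleach)
  if (any(yields < 0) || any(yields > 1))
    stop("branching yields must lie in [0, 1]")
  if (p$phi_off + p$phi_isc + p$phi_bleach_on > 1)
    stop("C_MINUS absorption branch yields sum to > 1")
  if (p$phi_int_off + p$phi_int_bleach > 1)
    stop("C_INT absorption branch yields sum to > 1")
  if (p$phi_risc + p$phi_tn > 1)
    stop("T1 absorption branch yields sum to > 1")
  if (p$f_drev + p$phi_t1 > 1)
    stop("T1 thermal branch fractions sum to > 1")
  rates <- c(p$tau_t, p$k_prot, p$k_deprot, p$k_int, p$k_drev, p$beta)
  if (any(rates < 0)) stop("rates and lifetimes must be >= 0")
  if (!is.list(p$sigma)) stop("sigma must be a named list of state tables")
  for (s in names(p$sigma)) {
    state_index(s)
    sg <- p$sigma[[s]]
    if (any(sg < 0)) stop("cross-sections must be >= 0")
    wl <- as.numeric(names(sg))
    if (anyNA(wl) || !all(wl %in% SUPPORTED_WAVELENGTHS))
      stop("cross-section wavelengths must be among: ",
           paste(SUPPORTED_WAVELENGTHS, collapse = ", "))
  }
  invisible(p)
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>", if (nzchar(x$label)) paste0(" ", x$label), "\n", sep = "")
  cat(sprintf("  phi_off=%.4g phi_isc=%.4g phi_on=%.4g\n",
              x$phi_off, x$phi_isc, x$phi_on))
  cat(sprintf("  tau_T=%.3g s  f_drev=%.3g phi_T1=%.3g phi_Tn=%.3g phi_RISC=%.3g\n",
              x$tau_t, x$f_drev, x$phi_t1, x$phi_tn, x$phi_risc))
  invisible(x)
}

## Cross-section of `state` at `wavelength` (0 if unspecified).
sigma_at <- function(params, state, wavelength) {
  sg <- params$sigma[[state]]
  if (is.null(sg)) return(0)
  v <- sg[as.character(wavelength)]
  if (is.na(v)) 0 else unname(v)
}

#' Read / write a rate-parameter set as annotated key:value text
#'
#' The on-disk format is one `key: value` pair per line; `#` starts a
#' comment. Cross-sections are flattened as `sigma.<STATE>.<wavelength_nm>`
#' in cm^2. All other values are in the internal units documented in
#' [rate_params()] (seconds, cm^2, dimensionless yields).
#'
#' @param path File path.
#' @return `read_params()` returns a `rate_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed parameter line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  out <- list(sigma = list())
  label <- ""
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k == "label") { label <- vals[i]; next }
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) stop("non-numeric value for key ", k)
    if (startsWith(k, "sigma.")) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      if (length(parts) != 3) stop("malformed sigma key: ", k)
      st <- parts[2]; wl <- parts[3]
      out$sigma[[st]][wl] <- v
    } else {
      out[[k]] <- v
    }
  }
  out$label <- label
  do.call(rate_params, out)
}

#' @rdname read_params
#' @param params A `rate_params` object.
#' @export
write_params <- function(params, path) {
  ln <- c("# RSFP photocycle rate parameters",
          "# units: cross-sections cm^2, rates 1/s, lifetimes s, yields dimensionless",
          paste0("label: ", params$label))
  for (st in names(params$sigma)) {
    sg <- params$sigma[[st]]
    ln <- c(ln, sprintf("sigma.%s.%s: %.8g", st, names(sg), sg))
  }
  scalars <- setdiff(names(params), c("sigma", "label"))
  ln <- c(ln, sprintf("%s: %.10g", scalars,
                      vapply(scalars, function(k) params[[k]], 0)))
  writeLines(ln, path)
  invisible(path)
}

#' Export a parameter set as JSON
#'
#' @inheritParams write_params
#' @export
params_to_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Shipped parameter sets
#'
#' `rsegfp2_params()` loads the calibrated default rsEGFP2 parameter set
#' (`"rsEGFP2-default-v1"`) shipped with the package. `variant_params()`
#' derives per-variant sets for other green negative photoswitchers, which
#' differ from rsEGFP2 only in switching yields, brightness and bleach
#' yields.
#'
#' @return A `rate_params` object.
#' @export
rsegfp2_params <- function() {
  read_params(system.file("extdata", "params", "rsEGFP2-default-v1.txt",
                          package = "rsfatigue", mustWork = TRUE))
}

#' @rdname rsegfp2_params
#' @param variant One of `"rsEGFP2"`, `"rsEGFP(N205S)"`, `"Dronpa(M159T)"`,
#'   `"rsGreen1"`, `"rsGreenF"`.
#' @export
variant_params <- function(variant = c("rsEGFP2", "rsEGFP(N205S)",
                                       "Dronpa(M159T)", "rsGreen1",
                                       "rsGreenF")) {
  variant <- match.arg(variant)
  p <- rsegfp2_params()
  ## Scale factors chosen so that the calibrated 488 doses of the
  ## per-variant fatigue comparison off-switch each protein to ~20%:
  ## slower switchers have smaller phi_off and, with longer dwell in the
  ## on state, a proportionally larger triplet-bleach exposure.
  adj <- switch(variant,
    "rsEGFP2"       = c(off = 1.00, on = 1.00, bl = 1.0,  beta = 1.0),
    "rsEGFP(N205S)" = c(off = 0.18, on = 0.80, bl = 1.2,  beta = 0.9),
    "Dronpa(M159T)" = c(off = 1.25, on = 0.90, bl = 0.8,  beta = 0.8),
    "rsGreen1"      = c(off = 0.47, on = 0.95, bl = 1.3,  beta = 1.1),
    "rsGreenF"      = c(off = 1.10, on = 0.95, bl = 1.0,  beta = 1.05))
  p$phi_off <- p$phi_off * adj[["off"]]
  p$phi_on  <- p$phi_on  * adj[["on"]]
  p$phi_tn  <- min(1 - p$phi_risc, p$phi_tn * adj[["bl"]])
  p$phi_t1  <- min(1 - p$f_drev,  p$phi_t1 * adj[["bl"]])
  p$beta    <- p$beta * adj[["beta"]]
  p$label   <- paste0(variant, "-derived-v1")
  validate_rate_params(p)
  p
}
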