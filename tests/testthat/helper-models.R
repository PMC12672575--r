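# shared fixtures: reduced models, random model generator, oracles

# pure off-switching two-state toy: C_MINUS -> T_ANION (-> TH) only
toy_off_params <- function(phi_off = 0.01, sigma488 = 2.34e-16) {
  rate_params(sigma = list(C_MINUS = c("488" = sigma488)),
              phi_off = phi_off, phi_isc = 0, phi_on = 0,
              k_prot = 2e4, k_deprot = 2e5, k_int = 1e3, k_drev = 0,
              tau_t = 2.5e-3, label = "toy-off")
}

# fatigue-free limit of the default model: no bleaching, no ISC, no D_REV
fatigue_free_params <- function() {
  p <- rsegfp2_params()
  p$phi_isc <- 0
  p$phi_bleach_on <- 0
  p$phi_int_bleach <- 0
  p$phi_tn <- 0
  p$phi_t1 <- 0
  p$f_drev <- 0
  p$phi_drev_bleach <- 0
  p$label <- "fatigue-free"
  p
}

# random valid parameter set (for property tests); rates scaled so the
# dynamics are neither frozen nor ultra-stiff
random_params <- function() {
  rp <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  rate_params(
    sigma = list(C_MINUS = c("488" = rp(1e-17, 5e-16), "405" = rp(1e-19, 1e-17)),
                 C_INT = c("405" = rp(1e-18, 1e-16), "488" = rp(1e-17, 3e-16)),
                 TH = c("405" = rp(1e-17, 2e-16)),
                 T1 = c("488" = rp(1e-20, 1e-17), "592" = rp(1e-19, 1e-17)),
                 D_REV = c("488" = rp(1e-18, 1e-16))),
    phi_off = rp(1e-3, 0.05), phi_isc = rp(1e-4, 0.02),
    phi_bleach_on = rp(1e-8, 1e-5),
    phi_on = rp(0.05, 0.4), phi_int_off = rp(0.05, 0.5),
    phi_int_bleach = rp(1e-6, 1e-3),
    phi_risc = rp(0.01, 0.2), phi_tn = rp(1e-6, 1e-3),
    tau_t = rp(5e-4, 5e-3), f_drev = stats::runif(1, 0, 0.4),
    phi_t1 = rp(1e-5, 1e-3),
    k_prot = rp(5e3, 5e4), k_deprot = rp(5e4, 5e5),
    k_int = rp(2e2, 5e3), k_drev = rp(2, 50),
    phi_drev_bleach = rp(1e-8, 1e-5))
}

random_population <- function() {
  x <- stats::rexp(8)
  population(x / sum(x))
}

random_illums <- function() {
  n <- sample(0:2, 1)
  if (n == 0) return(list())
  wl <- sample(c(405, 488, 592), n)
  lapply(wl, function(w) illumination(w, stats::runif(1, 10, 2000)))
}

# independent oracle: adaptive ODE integration of dP/dt = K P (deSolve)
ode_oracle <- function(p0, K, t) {
  deriv <- function(t, y, parms) list(as.vector(K %*% y))
  out <- deSolve::ode(y = unname(p0), times = c(0, t), func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-13)
  stats::setNames(as.numeric(out[2, -1]), photo_states())
}

# stochastic oracle: single-molecule continuous-time Markov jumps driven
# by the generator of each window
gillespie_scheme <- function(params, scheme, n_mol, seed) {
  set.seed(seed)
  Ks <- lapply(scheme$windows, function(w) build_rate_matrix(params, w$illums))
  durs <- vapply(scheme$windows, `[[`, 0, "duration")
  counts <- integer(8)
  for (m in seq_len(n_mol)) {
    s <- 1L  # C_MINUS
    for (rep in seq_len(scheme$repeats)) {
      for (wi in seq_along(Ks)) {
        K <- Ks[[wi]]
        remaining <- durs[wi]
        repeat {
          out_rate <- -K[s, s]
          if (out_rate <= 0) break
          dt <- stats::rexp(1, out_rate)
          if (dt > remaining) break
          remaining <- remaining - dt
          probs <- K[, s]; probs[s] <- 0
          s <- sample.int(8L, 1L, prob = probs)
        }
      }
    }
    counts[s] <- counts[s] + 1L
  }
  stats::setNames(counts / n_mol, photo_states())
}

# majority-vote ground-truth label of segmented objects against a label mask
truth_labels <- function(objects, label_mask, labels_df) {
  vapply(objects, function(ob) {
    ids <- label_mask[ob$pixels]
    ids <- ids[ids > 0]
    if (length(ids) == 0) return(NA_character_)
    as.character(labels_df$class[match(as.integer(names(which.max(table(ids)))),
                                       labels_df$object)])
  }, "")
}
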