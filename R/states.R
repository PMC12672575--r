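#' @keywords internal
"_PACKAGE"

## Physical constants (SI)
PLANCK_H <- 6.62607015e-34   # J s
SPEED_C  <- 2.99792458e8     # m/s

#' Photocycle state identifiers
#'
#' The package models an RSFP chromophore as an eight-state continuous-time
#' linear kinetic system:
#' \describe{
#'   \item{C_MINUS}{cis anionic, the thermodynamically stable emissive (on)
#'     form}
#'   \item{C_INT}{millisecond-lived on-like intermediate of the
#'     on-switching cascade; emissive, absorbs violet light}
#'   \item{CH}{cis neutral, transient product of the trans-to-cis
#'     photoisomerization}
#'   \item{TH}{trans neutral, the stable off state}
#'   \item{T_ANION}{trans anionic ground-state intermediate formed by the
#'     cis-to-trans photoisomerization, protonates to TH in tens of
#'     microseconds}
#'   \item{T1}{lowest triplet state, populated by intersystem crossing from
#'     the excited on state}
#'   \item{D_REV}{long-lived reversible dark photoproduct seeded by the
#'     triplet state}
#'   \item{BLEACHED}{absorbing sink collecting all irreversible
#'     photodestruction}
#' }
#'
#' @return Character vector of the eight state names, in canonical order.
#' @export
photo_states <- function() {
  c("C_MINUS", "C_INT", "CH", "TH", "T_ANION", "T1", "D_REV", "BLEACHED")
}

N_STATES <- 8L

## Wavelengths (nm) for which cross-sections may be specified
SUPPORTED_WAVELENGTHS <- c(405, 488, 592, 810, 900, 915)

state_index <- function(state) {
  i <- match(state, photo_states())
  if (anyNA(i)) stop("unknown photocycle state: ",
                     paste(state[is.na(i)], collapse = ", "))
  i
}

#' Population vector constructor
#'
#' @param x Named numeric vector of state fractions (missing states are 0),
#'   or an unnamed length-8 vector in canonical state order.
#' @return Numeric length-8 vector named by [photo_states()], summing to 1.
#' @export
population <- function(x = c(C_MINUS = 1)) {
  p <- stats::setNames(numeric(N_STATES), photo_states())
  if (is.null(names(x))) {
    if (length(x) != N_STATES) stop("unnamed population must have length 8")
    p[] <- x
  } else {
    p[names(x)] <- x
  }
  validate_population(p)
  p
}

validate_population <- function(p, neg_tol = 1e-12, sum_tol = 1e-9) {
  if (any(p < -neg_tol)) stop("negative population entry")
  if (abs(sum(p) - 1) > sum_tol) stop("population does not sum to 1")
  invisible(p)
}

## Clip numerically negative entries and renormalize.
clip_population <- function(p, neg_tol = 1e-12) {
  if (any(p < -neg_tol)) stop("propagation produced negative population < -1e-12")
  p[p < 0] <- 0
  p / sum(p)
}
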