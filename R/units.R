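#' Unit conversion constants and helpers
#'
#' The whole model works in CGS units (dyn, cm, s): pressures in
#' dyn cm^-2, resistances in dyn s cm^-5, compliances in cm^5 dyn^-1,
#' inertances in dyn s^2 cm^-5, volumes in cm^3 and flows in cm^3 s^-1.
#' Pressures are reported in mmHg and energies in Joule where stated.
#'
#' @name units
NULL

#' One mmHg in dyn cm^-2
#' @export
MMHG <- 1333.22

#' One Joule in erg
#' @export
ERG_PER_JOULE <- 1e7

#' Convert pressure between CGS and mmHg
#'
#' @param p pressure in dyn cm^-2 (`to_mmhg`) or mmHg (`from_mmhg`)
#' @return converted pressure
#' @export
to_mmhg <- function(p) p / MMHG

#' @rdname to_mmhg
#' @export
from_mmhg <- function(p) p * MMHG

#' Convert work between erg and Joule
#'
#' @param w work in erg (`erg_to_joule`) or Joule (`joule_to_erg`)
#' @return converted work
#' @export
erg_to_joule <- function(w) w / ERG_PER_JOULE

#' @rdname erg_to_joule
#' @export
joule_to_erg <- function(w) w * ERG_PER_JOULE
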