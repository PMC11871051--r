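# Physical constants and per-site reference data.
#
# Internal computations run in Hartree atomic units; user-facing coordinates
# are in angstrom, masses in amu (most-abundant isotope), times in fs.

#' Unit conversions used throughout the package
#'
#' A named list of the fixed conversion factors between the user-facing units
#' (angstrom, amu, fs, eV) and the Hartree atomic units used internally.
#'
#' @return Named list with elements `bohr_per_ang`, `me_per_amu`, `ev_per_ha`
#'   and `fs_per_aut`.
#' @examples
#' ce_units()$bohr_per_ang
#' @export
ce_units <- function() {
  list(
    bohr_per_ang = 1.8897261255,
    me_per_amu   = 1822.888486,
    ev_per_ha    = 27.211386245988,
    fs_per_aut   = 0.024188843265857
  )
}

# Most-abundant-isotope masses in amu.
.tu_masses_amu <- c(
  H = 1.007825, C = 12.0, N = 14.003074, O = 15.994915, S = 31.972071
)

# Canonical 2-thiouracil site table: ring sites N1..C6, the exocyclic sulfur
# (on C2) and oxygen (on C4), and the four protons.  Hydrogen labels follow
# the frozen assignment validated against the simulated planar angular
# layout: H9 on N3, H10 on N1, H11 on C6, H12 on C5 (H10/H12 end up at the
# poles of the sum/difference frame, H9 at azimuth 0, H11 at +-180 degrees).
.tu_sites <- tibble::tibble(
  site    = c("N1", "C2", "N3", "C4", "C5", "C6", "S", "O",
              "H9", "H10", "H11", "H12"),
  element = c("N", "C", "N", "C", "C", "C", "S", "O", "H", "H", "H", "H"),
  parent  = c(NA, NA, NA, NA, NA, NA, "C2", "C4", "N3", "N1", "C6", "C5")
)

# Frozen planar base skeleton (angstrom, z = 0).  Constructed once from a
# molecular-mechanics (MMFF94) embedding of the thione tautomer, centred,
# planarized by projection on its principal plane, and oriented with the
# N1 -> C2 -> N3 circuit counterclockwise viewed from +z.  The exocyclic
# C-S / C-O bond-vector angle of this skeleton is 120.19 degrees; the
# builder rotates the S and O positions in plane to the requested angle
# (116 degrees for the ground state).
.tu_base_xy <- matrix(
  c(-0.767818,  1.087192,
    -1.351908, -0.149462,
    -0.503804, -1.220464,
     0.863451, -1.136078,
     1.424818,  0.230555,
     0.588428,  1.271638,
    -3.003057, -0.334063,
     1.593304, -2.120042,
    -0.899169, -2.149253,
    -1.387641,  1.892179,
     0.941885,  2.297776,
     2.501512,  0.330023),
  ncol = 2, byrow = TRUE,
  dimnames = list(c("N1", "C2", "N3", "C4", "C5", "C6", "S", "O",
                    "H9", "H10", "H11", "H12"), c("x", "y"))
)

#' Atomic masses of the 2-thiouracil elements
#'
#' @param elements Character vector of element symbols (subset of H, C, N, O,
#'   S).
#' @return Numeric vector of most-abundant-isotope masses in amu.
#' @examples
#' tu_mass(c("H", "S"))
#' @export
tu_mass <- function(elements) {
  bad <- setdiff(unique(elements), names(.tu_masses_amu))
  if (length(bad) > 0) {
    rlang::abort(paste0("unsupported element(s): ", paste(bad, collapse = ", ")))
  }
  unname(.tu_masses_amu[elements])
}
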