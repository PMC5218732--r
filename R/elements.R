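#' Atomic parameter tables
#'
#' Per-element lookup tables used throughout the package: Bondi van der
#' Waals radii (Angstrom), covalent radii used for geometric bond
#' perception, additive atomic polarizabilities (Angstrom^3, by element and
#' -- for C, N, O -- hybridization), and the PEOE electronegativity
#' parameters used by the default partial-charge scheme. All tables are
#' plain data frames so a user can swap in an alternative parameter set.
#'
#' @name atom-parameters
NULL

# Bondi vdW radii, Angstrom
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

# single-bond covalent radii, Angstrom (bond perception only)
.cov_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

#' Default van der Waals radius table (Bondi)
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_vdw_table <- function() .vdw_radii

#' Default additive atomic polarizability table
#'
#' Atomic hybrid polarizabilities in Angstrom^3. Keys are either plain
#' element symbols or element.hybridization (e.g. `C.sp2`); lookup falls
#' back from the hybridized key to the element key.
#'
#' @return Named numeric vector of polarizabilities in Angstrom^3.
#' @export
default_polarizability_table <- function() {
  c(
    H = 0.387,
    C.sp3 = 1.061, C.sp2 = 1.352, C.sp = 1.283, C = 1.061,
    N.sp3 = 0.964, N.sp2 = 1.090, N.sp = 1.090, N = 0.964,
    O.sp3 = 0.637, O.sp2 = 0.569, O = 0.637,
    F = 0.296, S = 3.000, P = 1.538,
    Cl = 2.315, Br = 3.013, I = 5.415
  )
}

# PEOE parameters (a, b, c) of chi(q) = a + b q + c q^2, by element/hybridization
.peoe_params <- rbind(
  H     = c(7.17,  6.24, -0.56),
  C.sp3 = c(7.98,  9.18,  1.88),
  C.sp2 = c(8.79,  9.32,  1.51),
  C.sp  = c(10.39, 9.45,  0.73),
  N.sp3 = c(11.54, 10.82, 1.36),
  N.sp2 = c(12.87, 11.15, 0.85),
  N.sp  = c(15.68, 11.70, -0.27),
  O.sp3 = c(14.18, 12.92, 1.39),
  O.sp2 = c(17.07, 13.79, 0.47),
  F     = c(14.66, 13.85, 2.31),
  Cl    = c(11.00, 9.69,  1.35),
  Br    = c(10.08, 8.47,  1.16),
  I     = c(9.90,  7.96,  0.96),
  S     = c(10.14, 9.13,  1.38),
  P     = c(8.90,  8.24,  0.96)
)
colnames(.peoe_params) <- c("a", "b", "c")

.lookup_by_hyb <- function(table, element, hybrid) {
  key <- paste(element, hybrid, sep = ".")
  out <- ifelse(key %in% names(table), table[key],
    ifelse(element %in% names(table), table[element], NA_real_)
  )
  names(out) <- element
  out
}

.vdw_of <- function(element, table = .vdw_radii) {
  r <- table[element]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
      paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}
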