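#' Assign net atomic charges by partial equalization of orbital
#' electronegativity (PEOE)
#'
#' Iterative Gasteiger-type scheme: each atom carries an electronegativity
#' chi(q) = a + b q + c q^2; at iteration n a charge increment
#' (chi_j - chi_i) / chi_plus * (1/2)^n flows across every bond from the
#' less to the more electronegative atom, where chi_plus is the cation
#' electronegativity (a + b + c) of the donating atom (20.02 for hydrogen).
#' Converges geometrically; eight iterations are ample. The scheme is
#' pluggable: any function(mol) returning a per-atom charge vector can be
#' substituted via `scheme`.
#'
#' @param mol a `mol_structure` with bonds.
#' @param formal_charge total molecular charge, elementary units.
#' @param n_iter number of PEOE iterations.
#' @param scheme optional replacement charge function(mol) -> numeric.
#' @return the molecule with `atoms$charge` filled; charges sum to
#'   `formal_charge` to machine precision.
#' @export
assign_partial_charges <- function(mol, formal_charge = 0, n_iter = 8,
                                   scheme = NULL) {
  if (!is.null(scheme)) {
    mol$atoms$charge <- scheme(mol)
    return(mol)
  }
  el <- mol$atoms$element
  hyb <- hybridization(mol)
  key <- ifelse(paste(el, hyb, sep = ".") %in% rownames(.peoe_params),
    paste(el, hyb, sep = "."), el)
  bad <- !key %in% rownames(.peoe_params)
  if (any(bad)) {
    stop("no PEOE parameters for element(s): ",
      paste(unique(el[bad]), collapse = ", "))
  }
  par <- .peoe_params[key, , drop = FALSE]
  n <- nrow(mol$atoms)
  # seed with the formal charge spread over heavy atoms bonded to most
  # electronegative environment; for neutral molecules this is all zero
  q <- rep(0, n)
  if (formal_charge != 0) {
    heavy <- which(el != "H")
    q[heavy] <- formal_charge / length(heavy)
  }
  chi_plus <- par[, "a"] + par[, "b"] + par[, "c"]
  chi_plus[el == "H"] <- 20.02
  if (nrow(mol$bonds) == 0) {
    mol$atoms$charge <- q
    return(mol)
  }
  bi <- mol$bonds$i; bj <- mol$bonds$j
  damp <- 0.5
  for (it in seq_len(n_iter)) {
    chi <- par[, "a"] + par[, "b"] * q + par[, "c"] * q^2
    f <- damp^it
    dchi <- chi[bj] - chi[bi]
    denom <- ifelse(dchi > 0, chi_plus[bi], chi_plus[bj])
    dq <- dchi / denom * f
    delta <- rep(0, n)
    for (b in seq_along(bi)) {
      delta[bi[b]] <- delta[bi[b]] + dq[b]
      delta[bj[b]] <- delta[bj[b]] - dq[b]
    }
    q <- q + delta
  }
  mol$atoms$charge <- q
  mol
}

#' Assign effective atomic polarizabilities from an additive table
#'
#' @param mol a `mol_structure`.
#' @param table named numeric vector; keys element or element.hybridization.
#' @return the molecule with `atoms$alpha` filled (all > 0).
#' @export
assign_polarizabilities <- function(mol, table = default_polarizability_table()) {
  hyb <- hybridization(mol)
  a <- .lookup_by_hyb(table, mol$atoms$element, hyb)
  if (anyNA(a)) {
    stop("polarizability table has no entry for element(s): ",
      paste(unique(mol$atoms$element[is.na(a)]), collapse = ", "))
  }
  mol$atoms$alpha <- unname(a)
  mol
}

#' Assign van der Waals radii from a table
#'
#' @param mol a `mol_structure`.
#' @param table named numeric vector of radii (Angstrom).
#' @return the molecule with `atoms$vdw` filled.
#' @export
assign_vdw_radii <- function(mol, table = default_vdw_table()) {
  mol$atoms$vdw <- .vdw_of(mol$atoms$element, table)
  mol
}

#' Prepare a ligand for field evaluation
#'
#' Convenience wrapper: radii, PEOE charges, polarizabilities.
#'
#' @inheritParams assign_partial_charges
#' @param vdw_table,alpha_table parameter tables.
#' @return fully parameterized `mol_structure`.
#' @export
parameterize_ligand <- function(mol, formal_charge = 0,
                                vdw_table = default_vdw_table(),
                                alpha_table = default_polarizability_table()) {
  mol <- assign_vdw_radii(mol, vdw_table)
  mol <- assign_partial_charges(mol, formal_charge)
  assign_polarizabilities(mol, alpha_table)
}
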