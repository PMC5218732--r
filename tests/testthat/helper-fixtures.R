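# in-code molecular fixtures shared across test files

methane_mol <- function() {
  d <- 1.09 / sqrt(3)
  mol_structure(
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, d, d, -d, -d), y = c(0, d, -d, d, -d),
               z = c(0, d, -d, -d, d)),
    data.frame(i = 1L, j = 2:5, order = 1L), name = "methane"
  )
}

ethane_mol <- function() {
  atoms <- data.frame(
    element = c("C", "C", "H", "H", "H", "H", "H", "H"),
    x = c(0, 1.54, -0.51, -0.51, -0.51, 2.05, 2.05, 2.05),
    y = c(0, 0, 1.02, -0.51, -0.51, 1.02, -0.51, -0.51),
    z = c(0, 0, 0, 0.89, -0.89, 0, -0.89, 0.89)
  )
  mol_structure(atoms, data.frame(i = c(1, 1, 1, 1, 2, 2, 2),
                                  j = c(2, 3, 4, 5, 6, 7, 8),
                                  order = 1L), name = "ethane")
}

benzene_mol <- function() {
  th <- seq(0, 300, 60) * pi / 180
  atoms <- data.frame(element = "C", x = 1.39 * cos(th),
                      y = 1.39 * sin(th), z = 0)
  mol_structure(atoms, data.frame(i = 1:6, j = c(2:6, 1), order = 1L),
                name = "benzene")
}

phenol_mol <- function() {
  make_toy_complex("phenol", character(), "moved_back")$ligand
}

# single neutral pseudo-atom with assigned parameters
lone_atom_mol <- function(element = "C", q = 0, alpha = 0) {
  m <- mol_structure(data.frame(element = element, x = 0, y = 0, z = 0))
  m$atoms$charge <- q
  m$atoms$alpha <- alpha
  m
}

# one-shot electronegativity-equalization oracle: solves for charges that
# equalize chi_i = chi0_i + 2*eta_i*q_i subject to sum(q) = 0; used only to
# cross-check the sign ordering of the iterative scheme
eem_charge_oracle <- function(mol) {
  chi0 <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98, S = 2.58)
  eta <- c(H = 6.4, C = 5.0, N = 5.9, O = 6.1, F = 7.0, S = 4.1)
  el <- mol$atoms$element
  n <- length(el)
  A <- diag(2 * eta[el])
  A <- rbind(cbind(A, rep(-1, n)), c(rep(1, n), 0))
  b <- c(-chi0[el], 0)
  drop(solve(A, b))[seq_len(n)]
}

# build a surface_grid object directly (for contact/integral unit tests)
manual_grid <- function(points) {
  structure(list(points = points, probe_radius = 1.4, density = NA,
                 coeffs = field_coefficients(), ligand_ref = "manual"),
            class = "surface_grid")
}

hit_features <- function(hits) vapply(hits, function(h) h$feature,
                                      character(1))

expect_feature_set <- function(cplx, expected,
                               constitutive = c("pistack_F404",
                                                "aring_ok")) {
  got <- sort(hit_features(detect_features(cplx)))
  expect_identical(got, sort(unique(c(expected, constitutive))))
}
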