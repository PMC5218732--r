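#' Hydrophobicity field coefficients
#'
#' Empirical coefficients of the hydrophobicity density
#' log P_j = C1 |sum q_i / r_ij^2| + C2 sum q_i^2 / r_ij^3 +
#' C3 sum alpha_i / r_ij^3 + C4 sum alpha_i / r_ij^6 + Ccav,
#' evaluated at grid point j on the ligand solvent-accessible surface, with
#' q_i the net atomic charge, alpha_i the effective atomic polarizability
#' and r_ij the atom-to-point distance. Defaults are the published
#' solvation-model values and are not refit here.
#'
#' @param C1,C2,C3,C4,Ccav dimensionless empirical coefficients.
#' @return object of class `field_coefficients`.
#' @export
field_coefficients <- function(C1 = -8.85e-2, C2 = -1.45e-1, C3 = 1.57e-2,
                               C4 = -4.88e-1, Ccav = 2.34e-3) {
  structure(list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, Ccav = Ccav),
            class = "field_coefficients")
}

# deterministic Fibonacci-sphere unit vectors
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (i - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Canonical molecular frame
#'
#' Principal-axis frame of the heavy atoms with a deterministic sign
#' convention (third coordinate moment positive along each axis, falling
#' back to the largest-projection atom; right-handedness enforced). Grids
#' are built in this frame so that surface integrals are exactly invariant
#' under rigid-body motion of the input.
#'
#' @param mol a `mol_structure`.
#' @return list with rotation `R` (3x3) and center `origin` such that
#'   canonical coords = (xyz - origin) %*% R.
#' @export
canonical_frame <- function(mol) {
  xyz <- coords_of(mol)
  hv <- heavy_idx(mol)
  if (length(hv) >= 2) xyz_h <- xyz[hv, , drop = FALSE] else xyz_h <- xyz
  ctr <- colMeans(xyz_h)
  cen <- sweep(xyz_h, 2, ctr)
  if (nrow(xyz_h) < 2) {
    return(list(R = diag(3), origin = ctr))
  }
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  V <- ev$vectors[, order(ev$values, decreasing = TRUE), drop = FALSE]
  for (k in 1:2) {
    p <- cen %*% V[, k]
    m3 <- sum(p^3)
    if (abs(m3) > 1e-8) {
      if (m3 < 0) V[, k] <- -V[, k]
    } else if (p[which.max(abs(p))] < 0) {
      V[, k] <- -V[, k]
    }
  }
  V[, 3] <- c(
    V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
    V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
    V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2]
  )
  list(R = V, origin = ctr)
}

#' Generate a solvent-accessible-surface grid on a ligand
#'
#' Deterministic tessellation: each atom's SAS sphere (radius r_vdW + probe)
#' is covered with a Fibonacci point set at the requested density; points
#' buried inside any other atom's SAS sphere are removed (Shrake-Rupley
#' style accessibility). Each surviving point carries an area weight equal
#' to its atom's SAS sphere area divided by the points generated on that
#' sphere, so the weights of surviving points sum to the SAS area. Points
#' are placed in the ligand's canonical frame and mapped back, making the
#' grid exactly rigid-motion covariant.
#'
#' @param ligand parameterized `mol_structure` (radii required; charges and
#'   polarizabilities required for field evaluation).
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param density target points per square Angstrom.
#' @param coeffs `field_coefficients` used to evaluate log P_j per point.
#' @return object of class `surface_grid`: data.frame `points` (x, y, z,
#'   parent_atom, area_weight, logp, hydrophobic) plus grid metadata.
#' @export
generate_sas_grid <- function(ligand, probe_radius = 1.4, density = 2.0,
                              coeffs = field_coefficients()) {
  stopifnot(inherits(ligand, "mol_structure"), density > 0,
            probe_radius >= 0)
  if (nrow(ligand$atoms) < 1) stop("ligand has no atoms")
  if (anyNA(ligand$atoms$vdw)) stop("ligand atoms lack vdW radii")
  frame <- canonical_frame(ligand)
  xyz <- sweep(coords_of(ligand), 2, frame$origin) %*% frame$R
  rs <- ligand$atoms$vdw + probe_radius
  n <- nrow(xyz)
  pts <- list()
  # coincident identical spheres tessellate once
  dup <- rep(FALSE, n)
  if (n > 1) {
    for (a in 2:n) {
      for (b in 1:(a - 1)) {
        if (!dup[b] && abs(rs[a] - rs[b]) < 1e-9 &&
            sum((xyz[a, ] - xyz[b, ])^2) < 1e-12) {
          dup[a] <- TRUE
          break
        }
      }
    }
  }
  for (a in seq_len(n)) {
    if (dup[a]) next
    area <- 4 * pi * rs[a]^2
    npt <- max(12L, as.integer(ceiling(area * density)))
    sph <- sweep(rs[a] * .fib_sphere(npt), 2, xyz[a, ], "+")
    keep <- rep(TRUE, npt)
    for (b in seq_len(n)) {
      if (b == a) next
      d2 <- (sph[, 1] - xyz[b, 1])^2 + (sph[, 2] - xyz[b, 2])^2 +
        (sph[, 3] - xyz[b, 3])^2
      keep <- keep & d2 > (rs[b] - 1e-9)^2
      if (!any(keep)) break
    }
    if (!any(keep)) next
    pts[[length(pts) + 1L]] <- data.frame(
      cx = sph[keep, 1], cy = sph[keep, 2], cz = sph[keep, 3],
      parent_atom = a, area_weight = area / npt
    )
  }
  if (!length(pts)) stop("no accessible surface points generated")
  g <- do.call(rbind, pts)
  # back to the lab frame
  lab <- sweep(as.matrix(g[, c("cx", "cy", "cz")]) %*% t(frame$R), 2,
               -frame$origin)
  points <- data.frame(
    x = lab[, 1], y = lab[, 2], z = lab[, 3],
    parent_atom = g$parent_atom, area_weight = g$area_weight
  )
  points$logp <- logp_density(ligand, as.matrix(points[, c("x", "y", "z")]),
                              coeffs)
  points$hydrophobic <- points$logp > 0
  structure(
    list(points = points, probe_radius = probe_radius, density = density,
         coeffs = coeffs, ligand_ref = ligand$name),
    class = "surface_grid"
  )
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf(
    "<surface_grid> %s: %d points, SAS area %.2f A^2, %.0f%% hydrophobic\n",
    x$ligand_ref, nrow(x$points), sum(x$points$area_weight),
    100 * mean(x$points$hydrophobic)
  ))
  invisible(x)
}

#' Hydrophobicity density at a point
#'
#' Evaluates log P_j = C1 |sum q_i / r^2| + C2 sum q_i^2 / r^3 +
#' C3 sum alpha_i / r^3 + C4 sum alpha_i / r^6 + Ccav over all ligand
#' atoms. The first term takes the absolute value of the signed charge sum;
#' the remaining sums are non-negative termwise.
#'
#' @param ligand parameterized `mol_structure` (charges + polarizabilities).
#' @param point numeric 3-vector, or an n x 3 matrix of points.
#' @param coeffs `field_coefficients`.
#' @return numeric vector of log P_j values.
#' @export
logp_density <- function(ligand, point, coeffs = field_coefficients()) {
  q <- ligand$atoms$charge
  al <- ligand$atoms$alpha
  if (anyNA(q)) stop("ligand charges not assigned")
  if (anyNA(al)) stop("ligand polarizabilities not assigned")
  xyz <- coords_of(ligand)
  p <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  npt <- nrow(p)
  t1 <- numeric(npt); t2 <- numeric(npt); t3 <- numeric(npt)
  t4 <- numeric(npt)
  for (a in seq_len(nrow(xyz))) {
    d2 <- (p[, 1] - xyz[a, 1])^2 + (p[, 2] - xyz[a, 2])^2 +
      (p[, 3] - xyz[a, 3])^2
    if (any(d2 < 1e-12)) stop("grid point coincides with an atomic center")
    r3 <- d2^1.5
    t1 <- t1 + q[a] / d2
    t2 <- t2 + q[a]^2 / r3
    t3 <- t3 + al[a] / r3
    t4 <- t4 + al[a] / r3^2
  }
  unname(coeffs$C1 * abs(t1) + coeffs$C2 * t2 + coeffs$C3 * t3 +
           coeffs$C4 * t4 + coeffs$Ccav)
}

#' Assign pocket-residue contacts to grid points
#'
#' A grid point contacts residue k when it lies within the van der Waals
#' sphere of any atom of that residue. A point inside two residues'
#' surfaces is recorded for both (each residue's contact set C_k is
#' independent, following the double sum of the contact integral).
#'
#' @param grid a `surface_grid`.
#' @param pocket list of `pocket_residue` (radii assigned).
#' @return the grid with a `contact` list-column of residue ids per point.
#' @export
assign_contact_residues <- function(grid, pocket) {
  npt <- nrow(grid$points)
  contact <- vector("list", npt)
  for (k in seq_len(npt)) contact[[k]] <- character()
  p <- as.matrix(grid$points[, c("x", "y", "z")])
  for (res in pocket) {
    rx <- as.matrix(res$atoms[, c("x", "y", "z")])
    rv <- res$atoms$vdw
    inres <- rep(FALSE, npt)
    for (a in seq_len(nrow(rx))) {
      d2 <- (p[, 1] - rx[a, 1])^2 + (p[, 2] - rx[a, 2])^2 +
        (p[, 3] - rx[a, 3])^2
      inres <- inres | d2 <= rv[a]^2
      if (all(inres)) break
    }
    id <- residue_id(res)
    for (k in which(inres)) contact[[k]] <- c(contact[[k]], id)
  }
  grid$points$contact <- contact
  grid
}

#' Hydrophobic contact integral log P_C
#'
#' Sums the hydrophobicity density over hydrophobic grid points
#' (log P_j > 0) in contact with each hydrophobic pocket residue:
#' log P_C = sum_k sum_{j in C_k, log P_j > 0} log P_j (dA_j). By default
#' each point is weighted by its surface area element so the integral is
#' grid-density independent; `raw_sum = TRUE` gives the literal unweighted
#' point sum. Points inside two residues' surfaces count once per residue
#' (`unique_count = TRUE` restricts to once overall).
#'
#' @param grid a `surface_grid` with contacts assigned (if not, `pocket`
#'   is used to assign them).
#' @param pocket list of hydrophobic `pocket_residue`.
#' @param raw_sum unweighted literal point sum instead of area weighting.
#' @param unique_count count doubly-contacted points once.
#' @return list with `logpc` (non-negative) and `per_residue` breakdown.
#' @export
compute_logpc <- function(grid, pocket, raw_sum = FALSE,
                          unique_count = FALSE) {
  hyd <- Filter(function(r) isTRUE(r$hydrophobic), pocket)
  if (!length(hyd)) {
    return(list(logpc = 0, per_residue = stats::setNames(numeric(0),
                                                         character(0))))
  }
  if (is.null(grid$points$contact)) {
    grid <- assign_contact_residues(grid, hyd)
  }
  ids <- vapply(hyd, residue_id, character(1))
  w <- if (raw_sum) rep(1, nrow(grid$points)) else grid$points$area_weight
  contrib <- grid$points$logp * w
  ok <- grid$points$logp > 0
  per <- stats::setNames(numeric(length(ids)), ids)
  counted <- rep(FALSE, nrow(grid$points))
  for (id in ids) {
    hit <- ok & vapply(grid$points$contact, function(cr) id %in% cr,
                       logical(1))
    if (unique_count) {
      hit <- hit & !counted
      counted <- counted | hit
    }
    per[id] <- sum(contrib[hit])
  }
  list(logpc = sum(per), per_residue = per)
}

#' Whole-surface hydrophobicity (QC diagnostic)
#'
#' Area-weighted integral of log P_j over the entire SAS; reported for
#' consistency checks only, not used in scoring.
#'
#' @param grid a `surface_grid`.
#' @return numeric scalar.
#' @export
molecular_logp <- function(grid) {
  sum(grid$points$logp * grid$points$area_weight)
}
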