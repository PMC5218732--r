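#' Molecular structure container
#'
#' A `mol_structure` holds one small molecule (a ligand or a pseudo-residue
#' fragment): an atom table, a bond list, and perceived rings. Atom fields
#' follow the quantities entering the hydrophobicity density field: position,
#' van der Waals radius, net atomic charge q_i and effective atomic
#' polarizability alpha_i.
#'
#' @param atoms data.frame with columns `serial`, `element`, `x`, `y`, `z`
#'   and optionally `name`, `vdw`, `charge`, `alpha`, `is_polar_h`,
#'   `parent_id`.
#' @param bonds data.frame with columns `i`, `j`, `order` (indices into
#'   `atoms`), or NULL for no bonds.
#' @param name label for the molecule.
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, bonds = NULL, name = "mol") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$name)) atoms$name <- atoms$element
  if (is.null(atoms$vdw)) atoms$vdw <- .vdw_of(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$alpha)) atoms$alpha <- NA_real_
  if (is.null(atoms$parent_id)) atoms$parent_id <- name
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > nrow(atoms) |
            bonds$j < 1 | bonds$j > nrow(atoms))) {
      stop("bond indices out of range")
    }
  }
  x <- structure(
    list(atoms = atoms, bonds = bonds, rings = list(), name = name),
    class = "mol_structure"
  )
  x$rings <- perceive_rings(x)
  x$atoms$is_polar_h <- flag_polar_hydrogens(x)
  x
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf(
    "<mol_structure> %s: %d atoms (%d heavy), %d bonds, %d rings\n",
    x$name, nrow(x$atoms), sum(x$atoms$element != "H"),
    nrow(x$bonds), length(x$rings)
  ))
  invisible(x)
}

coords_of <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

heavy_idx <- function(mol) which(mol$atoms$element != "H")

#' Perceive bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of covalent
#' radii plus a tolerance. Bond order is left at 1 (geometric perception
#' cannot resolve order); ring planarity is used downstream where
#' aromaticity matters.
#'
#' @param atoms atom data.frame (element, x, y, z).
#' @param tol tolerance added to the covalent-radius sum, Angstrom.
#' @return bonds data.frame (i, j, order).
#' @export
perceive_bonds <- function(atoms, tol = 0.45) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(i = integer(), j = integer(), order = integer()))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rc <- .cov_radii[atoms$element]
  rc[is.na(rc)] <- 0.77
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(rc, rc, "+") + tol
  hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(i = integer(), j = integer(), order = integer()))
  }
  # never bond two hydrogens
  hh <- atoms$element[hit[, 1]] == "H" & atoms$element[hit[, 2]] == "H"
  hit <- hit[!hh, , drop = FALSE]
  data.frame(i = unname(hit[, 1]), j = unname(hit[, 2]),
             order = rep(1L, nrow(hit)))
}

bond_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

#' Perceive rings (smallest set of smallest rings, approximate)
#'
#' For each bond, the shortest cycle through it is recovered by removing the
#' bond and taking the shortest remaining path between its endpoints.
#' Duplicate cycles are collapsed. Adequate for the small ligands this
#' package handles.
#'
#' @param mol a `mol_structure`.
#' @return list of integer vectors of atom indices, each a cycle.
#' @export
perceive_rings <- function(mol) {
  if (nrow(mol$bonds) == 0) return(list())
  g <- bond_graph(mol)
  rings <- list()
  seen <- character()
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(i), to = as.character(j)
    )$vpath[[1]])
    if (length(sp) == 0) next
    cyc <- as.integer(names(sp))
    if (length(cyc) < 3 || length(cyc) > 8) next
    key <- paste(sort(cyc), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- cyc
    }
  }
  rings
}

#' Hybridization guess per atom
#'
#' sp3 by default; sp2 for atoms in small planar rings or with trigonal
#' heavy coordination; carbonyl/carboxylate oxygens are sp2. Used only to
#' pick rows of parameter tables.
#'
#' @param mol a `mol_structure`.
#' @return character vector ("sp", "sp2", "sp3") per atom.
#' @export
hybridization <- function(mol) {
  n <- nrow(mol$atoms)
  hyb <- rep("sp3", n)
  el <- mol$atoms$element
  nb <- neighbor_list(mol)
  ring_at <- unique(unlist(mol$rings))
  planar <- planar_ring_atoms(mol)
  for (a in seq_len(n)) {
    if (el[a] == "H") next
    heavy_nb <- nb[[a]][el[nb[[a]]] != "H"]
    deg <- length(nb[[a]])
    if (a %in% planar) {
      hyb[a] <- "sp2"
    } else if (el[a] == "C" && deg == 2 && length(heavy_nb) == 2 &&
               .bond_angle_at(mol, a, nb[[a]]) > 172) {
      hyb[a] <- "sp"
    } else if (el[a] == "O" && length(nb[[a]]) == 1 &&
               el[nb[[a]]] == "C") {
      # terminal O on carbon with no H: carbonyl-like
      hyb[a] <- "sp2"
    } else if (el[a] == "C" && deg == 3) {
      # trigonal carbon with a terminal O neighbor: carbonyl carbon
      if (any(el[nb[[a]]] == "O" &
              vapply(nb[[a]], function(k) length(nb[[k]]) == 1, logical(1)))) {
        hyb[a] <- "sp2"
      }
    }
  }
  hyb
}

.bond_angle_at <- function(mol, a, nbrs) {
  xyz <- coords_of(mol)
  u <- xyz[nbrs[1], ] - xyz[a, ]
  v <- xyz[nbrs[2], ] - xyz[a, ]
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

neighbor_list <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  for (k in seq_len(n)) nb[[k]] <- integer()
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

# atoms belonging to a 5/6-ring that is planar within rms 0.15 A
planar_ring_atoms <- function(mol, rms_tol = 0.15) {
  out <- integer()
  xyz <- coords_of(mol)
  for (ring in mol$rings) {
    if (!length(ring) %in% c(5L, 6L)) next
    p <- xyz[ring, , drop = FALSE]
    ctr <- colMeans(p)
    s <- svd(sweep(p, 2, ctr))
    rms <- sqrt(mean((sweep(p, 2, ctr) %*% s$v[, 3])^2))
    if (rms < rms_tol) out <- c(out, ring)
  }
  unique(out)
}

flag_polar_hydrogens <- function(mol) {
  el <- mol$atoms$element
  polar <- rep(FALSE, nrow(mol$atoms))
  if (nrow(mol$bonds) == 0) return(polar)
  nb <- neighbor_list(mol)
  for (a in which(el == "H")) {
    if (any(el[nb[[a]]] %in% c("N", "O", "S"))) polar[a] <- TRUE
  }
  polar
}

#' Apply a rigid-body transform to a molecule
#'
#' @param mol a `mol_structure`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector, Angstrom.
#' @return transformed `mol_structure`.
#' @export
transform_mol <- function(mol, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords_of(mol) %*% t(R)
  xyz <- sweep(xyz, 2, -t)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Apply a rigid-body transform to a whole complex
#'
#' Ligand and every pocket residue move in the one shared frame.
#'
#' @param cplx a `complex_structure`.
#' @inheritParams transform_mol
#' @return transformed complex.
#' @export
transform_complex <- function(cplx, R = diag(3), t = c(0, 0, 0)) {
  cplx$ligand <- transform_mol(cplx$ligand, R, t)
  cplx$pocket <- lapply(cplx$pocket, function(res) {
    xyz <- as.matrix(res$atoms[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, -t)
    res$atoms$x <- xyz[, 1]; res$atoms$y <- xyz[, 2]; res$atoms$z <- xyz[, 3]
    res
  })
  cplx
}

#' Pocket residue constructor
#'
#' @param res_name 3-letter residue code.
#' @param chain chain identifier.
#' @param seq_num residue sequence number.
#' @param atoms atom data.frame (name, element, x, y, z).
#' @param hydrophobic logical flag.
#' @return object of class `pocket_residue`.
#' @export
pocket_residue <- function(res_name, chain, seq_num, atoms,
                           hydrophobic = FALSE) {
  if (is.null(atoms$vdw)) atoms$vdw <- .vdw_of(atoms$element)
  if (is.null(atoms$name)) atoms$name <- atoms$element
  structure(
    list(res_name = res_name, chain = chain, seq_num = as.integer(seq_num),
         atoms = atoms, hydrophobic = hydrophobic),
    class = "pocket_residue"
  )
}

residue_id <- function(res) paste0(res$res_name, res$seq_num)

#' Protein-ligand complex constructor
#'
#' @param ligand a `mol_structure`.
#' @param pocket list of `pocket_residue`.
#' @param receptor_label identifier for the receptor structure.
#' @param receptor_class one of "closed", "moved_back", "open", "unknown".
#' @return object of class `complex_structure`.
#' @export
complex_structure <- function(ligand, pocket, receptor_label = "receptor",
                              receptor_class = "unknown") {
  stopifnot(inherits(ligand, "mol_structure"))
  receptor_class <- match.arg(receptor_class,
    c("closed", "moved_back", "open", "unknown"))
  structure(
    list(ligand = ligand, pocket = pocket, receptor_label = receptor_label,
         receptor_class = receptor_class),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf(
    "<complex_structure> %s [%s]: ligand %s (%d atoms), pocket %d residues\n",
    x$receptor_label, x$receptor_class, x$ligand$name,
    nrow(x$ligand$atoms), length(x$pocket)
  ))
  invisible(x)
}

find_residue <- function(pocket, res_name = NULL, seq_num = NULL) {
  for (res in pocket) {
    if (!is.null(res_name) && res$res_name != res_name) next
    if (!is.null(seq_num) && res$seq_num != seq_num) next
    return(res)
  }
  NULL
}
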