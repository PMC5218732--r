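#' Read a protein-ligand complex from a PDB file
#'
#' Extracts the ligand named by `ligand_code` from the HETATM records and
#' collects every protein residue having any atom within `pocket_radius` of
#' any ligand atom as the binding pocket. Waters are excluded; alternate
#' locations are resolved to the highest-occupancy copy (with a warning).
#' Ligand bonds are perceived from geometry; missing non-polar hydrogens on
#' carbon are rebuilt at standard geometry so the surface field is not
#' corrupted by hydrogen-depleted deposition/docking conventions.
#'
#' @param path PDB file.
#' @param ligand_code 3-letter het code of the ligand.
#' @param pocket_radius pocket inclusion radius around ligand atoms, Angstrom.
#' @param hydrophobic_residues residue list used to flag hydrophobic pocket
#'   members (see [default_hydrophobic_residues()]).
#' @param complete_h rebuild missing non-polar hydrogens on the ligand.
#' @return a `complex_structure`.
#' @export
read_pdb_complex <- function(path, ligand_code, pocket_radius = 6.0,
                             hydrophobic_residues = default_hydrophobic_residues(),
                             complete_h = TRUE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  # altloc: keep highest occupancy per atom slot
  if (any(!is.na(at$alt) & at$alt != "")) {
    warning("alternate locations present; keeping highest-occupancy copies")
    key <- paste(at$chain, at$resno, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  lig_rows <- at$type == "HETATM" & at$resid == ligand_code
  if (!any(lig_rows)) {
    hets <- sort(unique(at$resid[at$type == "HETATM"]))
    stop("ligand code '", ligand_code, "' not found; available het codes: ",
      if (length(hets)) paste(hets, collapse = ", ") else "(none)")
  }
  lig_at <- at[lig_rows, , drop = FALSE]
  lig_atoms <- data.frame(
    serial = lig_at$eleno,
    name = trimws(lig_at$elety),
    element = .pdb_element(lig_at),
    x = lig_at$x, y = lig_at$y, z = lig_at$z,
    stringsAsFactors = FALSE
  )
  ligand <- mol_structure(lig_atoms, perceive_bonds(lig_atoms),
                          name = ligand_code)
  if (complete_h) ligand <- complete_hydrogens(ligand)

  prot <- at[at$type == "ATOM", , drop = FALSE]
  pocket <- list()
  if (nrow(prot) > 0) {
    lig_xyz <- coords_of(ligand)[ligand$atoms$element != "H", , drop = FALSE]
    px <- as.matrix(prot[, c("x", "y", "z")])
    # min distance of each protein atom to any ligand heavy atom
    mind <- apply(px, 1, function(p) {
      sqrt(min(colSums((t(lig_xyz) - p)^2)))
    })
    prot$..near <- mind <= pocket_radius
    key <- paste(prot$chain, prot$resno)
    for (k in unique(key[prot$..near])) {
      rows <- prot[key == k, , drop = FALSE]
      ratoms <- data.frame(
        serial = rows$eleno, name = trimws(rows$elety),
        element = .pdb_element(rows),
        x = rows$x, y = rows$y, z = rows$z,
        stringsAsFactors = FALSE
      )
      res <- pocket_residue(rows$resid[1], rows$chain[1], rows$resno[1],
                            ratoms)
      res$hydrophobic <- .is_hydrophobic(res, hydrophobic_residues)
      pocket[[length(pocket) + 1L]] <- res
    }
  }
  # stable order by chain then sequence number
  if (length(pocket)) {
    ord <- order(vapply(pocket, function(r) r$chain, character(1)),
                 vapply(pocket, function(r) r$seq_num, integer(1)))
    pocket <- pocket[ord]
  }
  complex_structure(ligand, pocket,
    receptor_label = sub("\\.pdb$", "", basename(path)))
}

.pdb_element <- function(rows) {
  el <- trimws(rows$elesy)
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # derive from atom name: strip digits, take leading letters
    nm <- gsub("[0-9']", "", trimws(rows$elety[miss]))
    two <- toupper(substr(nm, 1, 2))
    el2 <- ifelse(two %in% c("CL", "BR"), .cap(two), substr(nm, 1, 1))
    el[miss] <- el2
  }
  .cap(el)
}

.cap <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Write a complex to a PDB file
#'
#' Pocket residues as ATOM records, the ligand as HETATM records (residue
#' name = ligand name truncated to 3 characters, chain L).
#'
#' @param cplx a `complex_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_complex <- function(cplx, path) {
  lines <- character()
  serial <- 0L
  fmt <- "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  for (res in cplx$pocket) {
    for (k in seq_len(nrow(res$atoms))) {
      serial <- serial + 1L
      a <- res$atoms[k, ]
      lines <- c(lines, sprintf(fmt, "ATOM", serial, .pdb_name(a$name),
        res$res_name, res$chain, res$seq_num, a$x, a$y, a$z, 1, 0,
        toupper(a$element)))
    }
  }
  lig <- cplx$ligand
  code <- toupper(substr(lig$name, 1, 3))
  for (k in seq_len(nrow(lig$atoms))) {
    serial <- serial + 1L
    a <- lig$atoms[k, ]
    lines <- c(lines, sprintf(fmt, "HETATM", serial, .pdb_name(a$name),
      code, "L", 1L, a$x, a$y, a$z, 1, 0, toupper(a$element)))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

.pdb_name <- function(name) {
  # atom name starts in column 14 for short names (PDB convention)
  ifelse(nchar(name) >= 4, substr(name, 1, 4), paste0(name))
}

#' Rebuild missing hydrogens at standard geometry
#'
#' Adds hydrogens to under-coordinated atoms (carbon by default; oxygen and
#' nitrogen too when `polar = TRUE`) assuming standard valences (C 4, N 3,
#' O 2). New hydrogens are placed at standard bond lengths along directions
#' chosen deterministically to maximize separation from existing bonds.
#'
#' @param mol a `mol_structure`.
#' @param polar also complete O/N hydrogens (off by default: protonation
#'   states are not predicted).
#' @param expected optional named integer vector (atom index -> H count)
#'   overriding the valence rule, e.g. taken from a template molecule.
#' @return the molecule with hydrogens appended (re-perceived flags/rings).
#' @export
complete_hydrogens <- function(mol, polar = FALSE, expected = NULL) {
  el <- mol$atoms$element
  nb <- neighbor_list(mol)
  hyb <- hybridization(mol)
  # expected neighbor counts by element and hybridization
  want_deg <- function(a) {
    switch(el[a],
      C = if (hyb[a] == "sp3") 4L else if (hyb[a] == "sp2") 3L else 2L,
      N = if (hyb[a] == "sp3") 3L else 2L,
      O = if (hyb[a] == "sp3") 2L else 1L,
      0L
    )
  }
  blen <- c(C = 1.09, N = 1.01, O = 0.96)
  new_atoms <- list(); new_bonds <- list()
  xyz <- coords_of(mol)
  for (a in seq_len(nrow(mol$atoms))) {
    if (!el[a] %in% c("C", if (polar) c("N", "O"))) next
    if (!is.null(expected)) {
      nH_want <- expected[as.character(a)]
      if (is.na(nH_want)) next
      deficit <- nH_want - sum(el[nb[[a]]] == "H")
    } else {
      deficit <- want_deg(a) - length(nb[[a]])
    }
    if (is.na(deficit) || deficit <= 0) next
    dirs <- .spread_directions(xyz, a, nb[[a]], deficit)
    for (d in seq_len(deficit)) {
      pos <- xyz[a, ] + blen[el[a]] * dirs[d, ]
      new_atoms[[length(new_atoms) + 1L]] <- data.frame(
        serial = NA_integer_, name = "H", element = "H",
        x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE
      )
      new_bonds[[length(new_bonds) + 1L]] <-
        data.frame(i = a, j = nrow(mol$atoms) + length(new_atoms),
                   order = 1L)
    }
  }
  if (!length(new_atoms)) return(mol)
  add <- do.call(rbind, new_atoms)
  add$vdw <- .vdw_of(add$element)
  add$charge <- NA_real_; add$alpha <- NA_real_
  add$parent_id <- mol$name
  keep_cols <- intersect(names(mol$atoms), names(add))
  atoms <- rbind(mol$atoms[, keep_cols], add[, keep_cols])
  atoms$serial <- seq_len(nrow(atoms))
  bonds <- rbind(mol$bonds, do.call(rbind, new_bonds))
  mol_structure(atoms, bonds, name = mol$name)
}

# deterministic well-spread unit directions avoiding existing neighbors
.spread_directions <- function(xyz, a, neighbors, k) {
  cand <- .fib_sphere(64)
  occupied <- NULL
  if (length(neighbors)) {
    occupied <- t(apply(xyz[neighbors, , drop = FALSE], 1, function(p) {
      v <- p - xyz[a, ]; v / sqrt(sum(v^2))
    }))
  }
  out <- matrix(0, k, 3)
  for (d in seq_len(k)) {
    if (is.null(occupied)) {
      best <- 1L
    } else {
      sc <- apply(cand, 1, function(v) max(occupied %*% v))
      best <- which.min(sc)
    }
    out[d, ] <- cand[best, ]
    occupied <- rbind(occupied, cand[best, , drop = FALSE])
  }
  out
}
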