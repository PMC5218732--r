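#' Geometric interaction criteria
#'
#' Thresholds for the geometric detectors. Hydrogen bonds: heavy-atom
#' distance d and donor-H...acceptor angle theta. Salt bridge: amine
#' N-to-carboxylate O distance. T-shaped pi-stacking / A-ring arrangement:
#' ring-centroid distance and interplanar angle window. `hydroxyl_pair_range`
#' is the phenol-O-to-distal-hydroxyl-O separation that makes a His524
#' hydrogen bond geometrically possible; `length_open_threshold` is the
#' ligand length above which the open receptor class is required. All bounds
#' are inclusive.
#'
#' @param hbond_max_dist Angstrom. @param hbond_min_angle degrees.
#' @param saltbridge_max_dist Angstrom.
#' @param ring_centroid_max_dist Angstrom.
#' @param ring_interplanar_range degrees, length-2 (min, max).
#' @param length_open_threshold Angstrom.
#' @param hydroxyl_pair_range Angstrom, length-2 (min, max).
#' @param his524_closed_max,his524_moved_back_max anchor-distance cutoffs
#'   (Angstrom) separating the closed / moved-back / open His524 classes.
#' @return object of class `geometric_criteria`.
#' @export
geometric_criteria <- function(hbond_max_dist = 3.5, hbond_min_angle = 120,
                               saltbridge_max_dist = 4.0,
                               ring_centroid_max_dist = 5.5,
                               ring_interplanar_range = c(60, 90),
                               length_open_threshold = 13,
                               hydroxyl_pair_range = c(10, 12),
                               his524_closed_max = hydroxyl_pair_range[2] +
                                 hbond_max_dist,
                               his524_moved_back_max = 18) {
  stopifnot(hbond_max_dist > 0, saltbridge_max_dist > 0,
            ring_centroid_max_dist > 0,
            all(ring_interplanar_range >= 0 & ring_interplanar_range <= 180),
            hbond_min_angle >= 0, hbond_min_angle <= 180)
  structure(
    list(hbond_max_dist = hbond_max_dist,
         hbond_min_angle = hbond_min_angle,
         saltbridge_max_dist = saltbridge_max_dist,
         ring_centroid_max_dist = ring_centroid_max_dist,
         ring_interplanar_range = ring_interplanar_range,
         length_open_threshold = length_open_threshold,
         hydroxyl_pair_range = hydroxyl_pair_range,
         his524_closed_max = his524_closed_max,
         his524_moved_back_max = his524_moved_back_max),
    class = "geometric_criteria"
  )
}

feature_hit <- function(feature, partner, measured, atoms = integer()) {
  structure(list(feature = feature, partner = partner,
                 measured = measured, atoms = atoms),
            class = "feature_hit")
}

.vnorm <- function(v) sqrt(sum(v^2))
.angle_deg <- function(a, b, c) {
  # angle at b of the path a-b-c, degrees
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Geometric hydrogen-bond test
#'
#' A hit requires donor-acceptor heavy-atom distance <= d and a
#' donor-H...acceptor angle (at the hydrogen) >= theta. Only the geometry
#' of the (donor heavy, hydrogen, acceptor heavy) triplet enters.
#'
#' @param donor list with `heavy` (3-vector) and `h` (3-vector or matrix of
#'   candidate hydrogens).
#' @param acceptor list with `heavy` (3-vector).
#' @param criteria a `geometric_criteria`.
#' @param feature,partner labels stored on the hit.
#' @return a `feature_hit`, or NULL if the criteria are not met.
#' @export
detect_hbond <- function(donor, acceptor, criteria = geometric_criteria(),
                         feature = "hbond", partner = "") {
  hs <- donor$h
  if (is.null(hs) || (is.matrix(hs) && nrow(hs) == 0)) {
    warning("hydrogen-bond donor has no attached hydrogen")
    return(NULL)
  }
  if (!is.matrix(hs)) hs <- matrix(hs, nrow = 1)
  d <- .vnorm(acceptor$heavy - donor$heavy)
  if (d > criteria$hbond_max_dist) return(NULL)
  angs <- apply(hs, 1, function(h) {
    .angle_deg(donor$heavy, h, acceptor$heavy)
  })
  best <- max(angs)
  if (best < criteria$hbond_min_angle) return(NULL)
  feature_hit(feature, partner, c(distance = d, angle = best))
}

ligand_hydroxyls <- function(mol) {
  nb <- neighbor_list(mol)
  el <- mol$atoms$element
  out <- list()
  for (o in which(el == "O")) {
    hs <- nb[[o]][el[nb[[o]]] == "H"]
    if (length(hs)) out[[length(out) + 1L]] <- list(o = o, h = hs)
  }
  out
}

res_atom_xyz <- function(res, names) {
  rows <- res$atoms[res$atoms$name %in% names, , drop = FALSE]
  as.matrix(rows[, c("x", "y", "z")])
}

#' Salt-bridge test against an Asp/Glu carboxylate
#'
#' A hit requires a protonatable (basic, tertiary) amine nitrogen of the
#' ligand within `saltbridge_max_dist` of either carboxylate oxygen. Amide
#' and other non-basic nitrogens never hit. Aliphatic amines are treated as
#' protonated at physiological pH; no pKa prediction is attempted.
#'
#' @param ligand a `mol_structure`.
#' @param asp_res a `pocket_residue`, must be ASP or GLU.
#' @param criteria a `geometric_criteria`.
#' @return a `feature_hit` or NULL.
#' @export
detect_salt_bridge <- function(ligand, asp_res,
                               criteria = geometric_criteria()) {
  if (!asp_res$res_name %in% c("ASP", "GLU")) {
    stop("salt-bridge partner must be ASP or GLU, got ", asp_res$res_name)
  }
  oxy <- res_atom_xyz(asp_res, c("OD1", "OD2", "OE1", "OE2"))
  if (nrow(oxy) == 0) return(NULL)
  xyz <- coords_of(ligand)
  for (n in basic_amine_nitrogens(ligand)) {
    d <- min(sqrt(colSums((t(oxy) - xyz[n, ])^2)))
    if (d <= criteria$saltbridge_max_dist) {
      return(feature_hit("salt_bridge_D351", residue_id(asp_res),
                         c(distance = d), c(N = n)))
    }
  }
  NULL
}

#' Basic (protonatable) amine nitrogens of a ligand
#'
#' Nitrogens with three heavy single-bonded neighbors and no adjacent
#' carbonyl carbon (amides excluded).
#'
#' @param mol a `mol_structure`.
#' @return integer atom indices.
#' @export
basic_amine_nitrogens <- function(mol) {
  el <- mol$atoms$element
  nb <- neighbor_list(mol)
  out <- integer()
  for (n in which(el == "N")) {
    heavy_nb <- nb[[n]][el[nb[[n]]] != "H"]
    if (length(heavy_nb) != 3) next
    if (n %in% unlist(mol$rings) && n %in% planar_ring_atoms(mol)) next
    amide <- any(vapply(heavy_nb, function(c_at) {
      el[c_at] == "C" && any(vapply(nb[[c_at]], function(o) {
        el[o] == "O" && length(nb[[o]]) == 1
      }, logical(1)))
    }, logical(1)))
    if (!amide) out <- c(out, n)
  }
  out
}

#' Ring descriptor: centroid and plane normal
#'
#' @param coords n x 3 matrix of ring-member coordinates (n >= 3).
#' @return list with `centroid`, unit `normal`, and `coords`.
#' @export
ring_descriptor <- function(coords) {
  stopifnot(is.matrix(coords), nrow(coords) >= 3)
  ctr <- colMeans(coords)
  s <- svd(sweep(coords, 2, ctr))
  n <- s$v[, 3]
  list(centroid = ctr, normal = n / .vnorm(n), coords = coords)
}

interplanar_angle <- function(n1, n2) {
  cosang <- abs(sum(n1 * n2) / (.vnorm(n1) * .vnorm(n2)))
  acos(pmin(1, cosang)) * 180 / pi
}

#' T-shaped pi-stacking test between two aromatic rings
#'
#' Hit when ring-centroid separation and interplanar angle fall inside the
#' configured window (near-perpendicular for a T-stack).
#'
#' @param ligand_ring,phe_ring ring descriptors (see [ring_descriptor()]).
#' @param criteria a `geometric_criteria`.
#' @return a `feature_hit` or NULL.
#' @export
detect_pi_stack <- function(ligand_ring, phe_ring,
                            criteria = geometric_criteria()) {
  if (is.null(ligand_ring$normal) || is.null(phe_ring$normal)) {
    stop("pi-stack test requires ring descriptors")
  }
  d <- .vnorm(ligand_ring$centroid - phe_ring$centroid)
  ang <- interplanar_angle(ligand_ring$normal, phe_ring$normal)
  if (d <= criteria$ring_centroid_max_dist &&
      ang >= criteria$ring_interplanar_range[1] &&
      ang <= criteria$ring_interplanar_range[2]) {
    return(feature_hit("pistack_F404", "PHE404",
                       c(distance = d, angle = ang)))
  }
  NULL
}

ligand_aromatic_rings <- function(mol) {
  planar <- planar_ring_atoms(mol)
  xyz <- coords_of(mol)
  out <- list()
  for (ring in mol$rings) {
    if (!length(ring) %in% c(5L, 6L)) next
    if (!all(ring %in% planar)) next
    if (!all(mol$atoms$element[ring] %in% c("C", "N"))) next
    out[[length(out) + 1L]] <- ring_descriptor(xyz[ring, , drop = FALSE])
  }
  out
}

#' Count internal hydrogen bonds of a ligand
#'
#' Exhaustive enumeration of donor (O/N bearing H) to acceptor (O/N) pairs
#' satisfying the hydrogen-bond criteria, excluding pairs fewer than 4
#' bonds apart on the molecular graph. Each donor-acceptor pair counts
#' once.
#'
#' @param mol a `mol_structure` with explicit hydrogens.
#' @param criteria a `geometric_criteria`.
#' @return non-negative integer.
#' @export
count_internal_hbonds <- function(mol, criteria = geometric_criteria()) {
  el <- mol$atoms$element
  nb <- neighbor_list(mol)
  xyz <- coords_of(mol)
  donors <- list()
  for (d in which(el %in% c("O", "N"))) {
    hs <- nb[[d]][el[nb[[d]]] == "H"]
    if (length(hs)) donors[[length(donors) + 1L]] <- list(d = d, h = hs)
  }
  acceptors <- which(el %in% c("O", "N"))
  if (!length(donors) || !length(acceptors)) return(0L)
  g <- bond_graph(mol)
  dists <- igraph::distances(g)
  count <- 0L
  for (don in donors) {
    for (acc in acceptors) {
      if (acc == don$d) next
      if (dists[don$d, acc] < 4) next
      hit <- detect_hbond(
        donor = list(heavy = xyz[don$d, ],
                     h = xyz[don$h, , drop = FALSE]),
        acceptor = list(heavy = xyz[acc, ]),
        criteria = criteria
      )
      if (!is.null(hit)) count <- count + 1L
    }
  }
  count
}

#' A-ring arrangement check against the Phe404 pincer
#'
#' TRUE when some aromatic ring of the ligand lies within the centroid
#' distance and interplanar angle window of the Phe404 phenyl ring
#' (inclusive bounds). Ligands without an aromatic ring always fail: the
#' pincer imposes an absolute requirement for one.
#'
#' @param ligand a `mol_structure`.
#' @param phe_ring descriptor of the Phe404 ring.
#' @param criteria a `geometric_criteria`.
#' @return logical flag.
#' @export
check_aring_arrangement <- function(ligand, phe_ring,
                                    criteria = geometric_criteria()) {
  rings <- ligand_aromatic_rings(ligand)
  if (!length(rings)) return(FALSE)
  for (r in rings) {
    d <- .vnorm(r$centroid - phe_ring$centroid)
    ang <- interplanar_angle(r$normal, phe_ring$normal)
    if (d <= criteria$ring_centroid_max_dist &&
        ang >= criteria$ring_interplanar_range[1] &&
        ang <= criteria$ring_interplanar_range[2]) {
      return(TRUE)
    }
  }
  FALSE
}

#' Ligand length
#'
#' Maximum heavy-atom pairwise distance.
#'
#' @param mol a `mol_structure` with >= 2 heavy atoms.
#' @return length in Angstrom.
#' @export
ligand_length <- function(mol) {
  hv <- heavy_idx(mol)
  stopifnot(length(hv) >= 2)
  max(stats::dist(coords_of(mol)[hv, , drop = FALSE]))
}

#' Classify the His524 side-chain conformation
#'
#' The imidazole nitrogen position relative to the pocket anchor (the
#' Glu353 carboxylate centroid) separates the three receptor classes:
#' closed (imidazole at the distal-hydroxyl site, hydrogen-bond capable;
#' anchor distance up to `his524_closed_max`), moved back (retracted,
#' up to `his524_moved_back_max`), open (swung out beyond that, extending
#' the pocket). "unknown" when His524 or its side chain is absent.
#'
#' @param pocket list of `pocket_residue`.
#' @param criteria a `geometric_criteria`.
#' @return one of "closed", "moved_back", "open", "unknown".
#' @export
classify_his524 <- function(pocket, criteria = geometric_criteria()) {
  his <- find_residue(pocket, "HIS", 524)
  glu <- find_residue(pocket, "GLU", 353)
  if (is.null(his) || is.null(glu)) return("unknown")
  nxy <- res_atom_xyz(his, c("ND1", "NE2"))
  axy <- res_atom_xyz(glu, c("OE1", "OE2"))
  if (nrow(nxy) == 0 || nrow(axy) == 0) return("unknown")
  anchor <- colMeans(axy)
  d <- min(sqrt(colSums((t(nxy) - anchor)^2)))
  if (d <= criteria$his524_closed_max) "closed"
  else if (d <= criteria$his524_moved_back_max) "moved_back"
  else "open"
}

#' Pose filter from the His524 geometric relationship
#'
#' A docked pose is acceptable only when the Glu353 hydrogen bond (HB1) is
#' present and the pose is consistent with the receptor class: on a closed
#' receptor the ligand must fit the unexpanded pocket (length at most the
#' open threshold) and, if it carries a second hydroxyl 10-12 Angstrom
#' (O-to-O) from the Glu353-bonded phenol oxygen, that hydroxyl must form
#' the His524 hydrogen bond (HB2); a moved-back receptor requires nothing
#' further; an open receptor requires the ligand to exceed the length
#' threshold.
#'
#' @param pose_ligand the posed ligand (`mol_structure`).
#' @param receptor_class one of "closed", "moved_back", "open".
#' @param hits list of `feature_hit` computed for this pose.
#' @param criteria a `geometric_criteria`.
#' @return logical flag.
#' @export
pose_his524_filter <- function(pose_ligand, receptor_class, hits,
                               criteria = geometric_criteria()) {
  feats <- vapply(hits, function(h) h$feature, character(1))
  if (!"hb_E353" %in% feats) return(FALSE)
  if (receptor_class == "open") {
    return(ligand_length(pose_ligand) > criteria$length_open_threshold)
  }
  if (receptor_class == "moved_back") return(TRUE)
  # closed: the pocket is not expanded, so an over-long ligand cannot fit
  if (ligand_length(pose_ligand) > criteria$length_open_threshold) {
    return(FALSE)
  }
  # closed: a distal hydroxyl in the pair window must realize HB2
  hb1 <- hits[[match("hb_E353", feats)]]
  anchor_o <- hb1$atoms["O"]
  if (is.na(anchor_o)) return(TRUE)
  xyz <- coords_of(pose_ligand)
  ohs <- ligand_hydroxyls(pose_ligand)
  for (oh in ohs) {
    if (oh$o == anchor_o) next
    sep <- .vnorm(xyz[oh$o, ] - xyz[anchor_o, ])
    if (sep >= criteria$hydroxyl_pair_range[1] &&
        sep <= criteria$hydroxyl_pair_range[2]) {
      if (!"hb_H524" %in% feats) return(FALSE)
    }
  }
  TRUE
}

#' Detect all interaction features of a complex
#'
#' Runs every geometric detector against the canonical ERa pocket residues
#' (Asp351 salt bridge; hydrogen bonds with Glu353, His524, Thr347, Leu346
#' backbone carbonyl; Arg394 donation to the ligand; Phe404 T-stack) plus
#' the ligand-internal hydrogen-bond count. Residues absent from the pocket
#' simply yield no hit.
#'
#' @param cplx a `complex_structure`.
#' @param criteria a `geometric_criteria`.
#' @return list of `feature_hit`.
#' @export
detect_features <- function(cplx, criteria = geometric_criteria()) {
  lig <- cplx$ligand
  xyz <- coords_of(lig)
  ohs <- ligand_hydroxyls(lig)
  hits <- list()
  add <- function(h) if (!is.null(h)) hits[[length(hits) + 1L]] <<- h

  hb_to_residue <- function(res, acc_names, feature) {
    acc <- res_atom_xyz(res, acc_names)
    if (nrow(acc) == 0) return(NULL)
    best <- NULL
    for (oh in ohs) {
      for (a in seq_len(nrow(acc))) {
        h <- detect_hbond(
          donor = list(heavy = xyz[oh$o, ], h = xyz[oh$h, , drop = FALSE]),
          acceptor = list(heavy = acc[a, ]),
          criteria = criteria, feature = feature, partner = residue_id(res)
        )
        if (!is.null(h)) {
          h$atoms <- c(O = oh$o)
          if (is.null(best) || h$measured["distance"] <
                best$measured["distance"]) best <- h
        }
      }
    }
    best
  }

  glu <- find_residue(cplx$pocket, "GLU", 353)
  if (!is.null(glu)) add(hb_to_residue(glu, c("OE1", "OE2"), "hb_E353"))

  thr <- find_residue(cplx$pocket, "THR", 347)
  if (!is.null(thr)) add(hb_to_residue(thr, "OG1", "hb_T347"))

  his <- find_residue(cplx$pocket, "HIS", 524)
  if (!is.null(his)) {
    h <- hb_to_residue(his, c("ND1", "NE2"), "hb_H524")
    if (is.null(h)) {
      # His as donor (N-H) to a ligand oxygen
      nh <- res_atom_xyz(his, c("HD1", "HE2"))
      nn <- res_atom_xyz(his, c("ND1", "NE2"))
      if (nrow(nh) > 0 && nrow(nn) > 0) {
        for (o in which(lig$atoms$element == "O")) {
          hh <- detect_hbond(
            donor = list(heavy = nn[1, ], h = nh),
            acceptor = list(heavy = xyz[o, ]),
            criteria = criteria, feature = "hb_H524",
            partner = residue_id(his)
          )
          if (!is.null(hh)) { hh$atoms <- c(O = o); h <- hh; break }
        }
      }
    }
    add(h)
  }

  leu346 <- find_residue(cplx$pocket, "LEU", 346)
  if (!is.null(leu346)) add(hb_to_residue(leu346, "O", "hb_L346"))

  arg <- find_residue(cplx$pocket, "ARG", 394)
  if (!is.null(arg)) {
    ns <- res_atom_xyz(arg, c("NE", "NH1", "NH2"))
    hs <- res_atom_xyz(arg, c("HE", "HH11", "HH12", "HH21", "HH22"))
    if (nrow(ns) > 0 && nrow(hs) > 0) {
      for (o in which(lig$atoms$element == "O")) {
        for (n in seq_len(nrow(ns))) {
          h <- detect_hbond(
            donor = list(heavy = ns[n, ], h = hs),
            acceptor = list(heavy = xyz[o, ]),
            criteria = criteria, feature = "hb_R394",
            partner = residue_id(arg)
          )
          if (!is.null(h)) { h$atoms <- c(O = o); add(h); break }
        }
        if (any(vapply(hits, function(x) x$feature == "hb_R394",
                       logical(1)))) break
      }
    }
  }

  asp <- find_residue(cplx$pocket, "ASP", 351)
  if (!is.null(asp)) add(detect_salt_bridge(lig, asp, criteria))

  phe <- find_residue(cplx$pocket, "PHE", 404)
  if (!is.null(phe)) {
    pxy <- res_atom_xyz(phe, c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
    if (nrow(pxy) >= 3) {
      phe_ring <- ring_descriptor(pxy)
      for (r in ligand_aromatic_rings(lig)) {
        h <- detect_pi_stack(r, phe_ring, criteria)
        if (!is.null(h)) { add(h); break }
      }
      if (check_aring_arrangement(lig, phe_ring, criteria)) {
        add(feature_hit("aring_ok", residue_id(phe), c(ok = 1)))
      }
    }
  }

  n_int <- count_internal_hbonds(lig, criteria)
  if (n_int > 0) {
    add(feature_hit("internal_hb", "ligand", c(count = n_int)))
  }
  hits
}

#' Phe404 ring descriptor from a pocket
#'
#' @param pocket list of `pocket_residue`.
#' @return ring descriptor or NULL when Phe404 is absent.
#' @export
phe404_ring <- function(pocket) {
  phe <- find_residue(pocket, "PHE", 404)
  if (is.null(phe)) return(NULL)
  pxy <- res_atom_xyz(phe, c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  if (nrow(pxy) < 3) return(NULL)
  ring_descriptor(pxy)
}
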