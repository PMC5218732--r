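crit <- geometric_criteria()

test_that("hydrogen-bond detection follows distance and angle criteria", {
  don <- list(heavy = c(0, 0, 0), h = c(0.96, 0, 0))
  # linear at 2.8 A
  expect_s3_class(detect_hbond(don, list(heavy = c(2.8, 0, 0)), crit),
                  "feature_hit")
  # far apart
  expect_null(detect_hbond(don, list(heavy = c(5, 0, 0)), crit))
  # 3.2 A but bent to 100 degrees at the hydrogen: independent angle check
  a_deg <- 100 * pi / 180
  acc <- c(0.96, 0, 0) + 3.0 * c(cos(pi - a_deg), sin(pi - a_deg), 0)
  dd <- sqrt(sum(acc^2))
  expect_lt(dd, crit$hbond_max_dist)  # rejected on angle, not distance
  expect_null(detect_hbond(don, list(heavy = acc), crit))
  # donor without hydrogen warns and returns nothing
  expect_warning(
    res <- detect_hbond(list(heavy = c(0, 0, 0), h = NULL),
                        list(heavy = c(2.8, 0, 0)), crit),
    "hydrogen")
  expect_null(res)
  # stored measurements re-satisfy the criteria (self-consistency)
  hit <- detect_hbond(don, list(heavy = c(3.1, 0.4, 0)), crit)
  expect_lte(hit$measured[["distance"]], crit$hbond_max_dist)
  expect_gte(hit$measured[["angle"]], crit$hbond_min_angle)
})

test_that("salt-bridge detection requires a basic amine near the
           carboxylate", {
  asp <- pocket_residue("ASP", "A", 351, data.frame(
    name = c("CG", "OD1", "OD2"), element = c("C", "O", "O"),
    x = c(0, 1.25, -0.6), y = c(0, 0, 1.1), z = 0))
  amine <- make_toy_complex("amine_tail", "salt_bridge",
                            "moved_back")$ligand
  n_idx <- basic_amine_nitrogens(amine)
  expect_length(n_idx, 1)

  place_n_at <- function(mol, target) {
    xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
    shift <- target - xyz[basic_amine_nitrogens(mol)[1], ]
    transform_mol(mol, diag(3), shift)
  }
  near <- place_n_at(amine, c(1.25 + 3.5, 0, 0))
  expect_s3_class(detect_salt_bridge(near, asp, crit), "feature_hit")
  far <- place_n_at(amine, c(1.25 + 6.0, 0, 0))
  expect_null(detect_salt_bridge(far, asp, crit))

  # amide nitrogen at 3.0 A is not basic: N-methylacetamide-like fragment
  amide <- mol_structure(
    data.frame(element = c("C", "C", "O", "N", "C", "C", "H"),
               x = c(-1.5, 0, 0.6, 0.7, 2.1, 0.2, 1.0),
               y = c(0, 0, 1.1, -1.1, -1.3, -2.4, -1.0),
               z = c(0, 0, 0, 0, 0, 0, 0.9)),
    data.frame(i = c(1, 2, 2, 4, 4, 4), j = c(2, 3, 4, 5, 6, 7),
               order = c(1L, 2L, 1L, 1L, 1L, 1L)), name = "amide")
  expect_length(basic_amine_nitrogens(amide), 0)
  shifted <- transform_mol(amide, diag(3),
                           c(1.25 + 3.0, 1.1, 0) -
                             as.numeric(amide$atoms[4, c("x", "y", "z")]))
  expect_null(detect_salt_bridge(shifted, asp, crit))

  leu <- pocket_residue("LEU", "A", 384, data.frame(
    name = "CD1", element = "C", x = 0, y = 0, z = 0))
  expect_error(detect_salt_bridge(near, leu, crit), "ASP")
})

test_that("T-shaped pi-stacking needs near-perpendicular close rings", {
  ring_at <- function(centroid, normal) {
    normal <- normal / sqrt(sum(normal^2))
    ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * normal) * normal
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
            normal[3] * e1[1] - normal[1] * e1[3],
            normal[1] * e1[2] - normal[2] * e1[1])
    th <- seq(0, 300, 60) * pi / 180
    ring_descriptor(t(vapply(th, function(a) {
      centroid + 1.39 * (cos(a) * e1 + sin(a) * e2)
    }, numeric(3))))
  }
  base <- ring_at(c(0, 0, 0), c(0, 0, 1))
  perp <- ring_at(c(0, 0, 5), c(1, 0, 0))
  expect_s3_class(detect_pi_stack(base, perp, crit), "feature_hit")
  parl <- ring_at(c(0, 0, 5), c(0, 0, 1))
  expect_null(detect_pi_stack(base, parl, crit))
  # 75 degrees at 4.8 A: direct dihedral computation
  n75 <- c(sin(75 * pi / 180), 0, cos(75 * pi / 180))
  tilt <- ring_at(c(0, 0, 4.8), n75)
  hit <- detect_pi_stack(base, tilt, crit)
  expect_s3_class(hit, "feature_hit")
  expect_equal(unname(hit$measured["angle"]), 75, tolerance = 1e-6)
})

test_that("internal hydrogen bonds are counted by exhaustive
           enumeration", {
  expect_identical(count_internal_hbonds(ethane_mol()), 0L)

  one <- make_toy_complex("phenol", c("internal_hb"), "moved_back")$ligand
  expect_identical(count_internal_hbonds(one), 1L)

  # two independent donor-acceptor motifs four bonds apart
  mk_motif <- function(offset) {
    # O-H ... O=C with a 3-carbon bridge (graph distance O..O = 4 bonds)
    data.frame(
      element = c("O", "H", "C", "C", "C", "C", "O"),
      x = offset + c(0, 0.7, 0.5, 1.9, 3.1, 2.5, 1.6),
      y = c(0, 0.66, -1.3, -1.8, -0.9, 0.4, 0.9),
      z = 0)
  }
  atoms <- rbind(mk_motif(0), mk_motif(20))
  bonds <- data.frame(
    i = c(1, 1, 3, 4, 5, 6, 7 + c(1, 1, 3, 4, 5, 6)),
    j = c(2, 3, 4, 5, 6, 7, 7 + c(2, 3, 4, 5, 6, 7)),
    order = rep(c(1L, 1L, 1L, 1L, 1L, 2L), 2))
  two <- mol_structure(atoms, bonds, name = "double_motif")
  # verify by direct pair enumeration that exactly two pairs qualify
  expect_identical(count_internal_hbonds(two), 2L)
})

test_that("A-ring arrangement uses inclusive bounds and requires an
           aromatic ring", {
  cplx <- make_toy_complex("phenol", character(), "moved_back")
  phe <- phe404_ring(cplx$pocket)
  expect_true(check_aring_arrangement(cplx$ligand, phe, crit))
  moved <- transform_mol(cplx$ligand, diag(3), c(8, 0, 0))
  expect_false(check_aring_arrangement(moved, phe, crit))
  # centroid distance exactly at the bound is accepted (inclusive)
  at_bound <- transform_mol(
    cplx$ligand, diag(3),
    c(0, 0, -(crit$ring_centroid_max_dist - 4.8 - 1e-9)))
  expect_true(check_aring_arrangement(at_bound, phe, crit))
  just_out <- transform_mol(cplx$ligand, diag(3), c(0, 0, -0.76))
  expect_false(check_aring_arrangement(just_out, phe, crit))
  # no aromatic ring: absolute requirement fails
  expect_false(check_aring_arrangement(ethane_mol(), phe, crit))
})

test_that("ligand length is the maximum heavy-atom separation", {
  two <- mol_structure(data.frame(element = c("C", "C"),
                                  x = c(0, 3), y = 0, z = 0),
                       data.frame(i = 1, j = 2, order = 1L))
  expect_equal(ligand_length(two), 3.0)
  chain <- mol_structure(data.frame(element = c("C", "C", "C"),
                                    x = c(0, 2, 5), y = 0, z = 0),
                         data.frame(i = c(1, 2), j = c(2, 3), order = 1L))
  expect_equal(ligand_length(chain), 5.0)
  # O(N^2) oracle on a larger fixture, hydrogens excluded
  lig <- make_toy_complex("e2_like", "HB_E353", "closed")$ligand
  hv <- which(lig$atoms$element != "H")
  xyz <- as.matrix(lig$atoms[hv, c("x", "y", "z")])
  brute <- max(vapply(seq_len(nrow(xyz)), function(i) {
    max(sqrt(colSums((t(xyz) - xyz[i, ])^2)))
  }, numeric(1)))
  expect_equal(ligand_length(lig), brute)
})

test_that("His524 classification separates the three receptor classes", {
  for (cls in c("closed", "moved_back", "open")) {
    cplx <- make_toy_complex("diol_11A",
      if (cls == "closed") c("HB_E353", "HB_H524") else "HB_E353", cls)
    expect_identical(classify_his524(cplx$pocket), cls)
  }
  # hydrogen-bond-capable imidazole 11 A from the anchor is closed
  glu <- pocket_residue("GLU", "A", 353, data.frame(
    name = c("CD", "OE1", "OE2"), element = c("C", "O", "O"),
    x = c(0, 1.2, -0.4), y = c(0, 0.3, 1.1), z = 0))
  anchor <- c((1.2 - 0.4) / 2, (0.3 + 1.1) / 2, 0)
  his <- pocket_residue("HIS", "A", 524, data.frame(
    name = "NE2", element = "N",
    x = anchor[1] + 11, y = anchor[2], z = 0))
  expect_identical(classify_his524(list(glu, his)), "closed")
  # displaced past the open cutoff
  his_open <- pocket_residue("HIS", "A", 524, data.frame(
    name = "NE2", element = "N", x = anchor[1] + 19, y = anchor[2], z = 0))
  expect_identical(classify_his524(list(glu, his_open)), "open")
  # missing side chain -> unknown
  his_bare <- pocket_residue("HIS", "A", 524, data.frame(
    name = "CB", element = "C", x = 5, y = 0, z = 0))
  expect_identical(classify_his524(list(glu, his_bare)), "unknown")
})

test_that("the His524 pose filter enforces HB1 and class consistency", {
  closed <- make_toy_complex("diol_11A", c("HB_E353", "HB_H524"),
                             "closed")
  hits <- detect_features(closed)
  expect_true(pose_his524_filter(closed$ligand, "closed", hits, crit))

  # drop HB1: fails in every class
  no_hb1 <- Filter(function(h) h$feature != "hb_E353", hits)
  for (cls in c("closed", "moved_back", "open")) {
    expect_false(pose_his524_filter(closed$ligand, cls, no_hb1, crit))
  }

  # closed receptor, diol in the pair window but no HB2: rejected
  no_hb2 <- Filter(function(h) h$feature != "hb_H524", hits)
  expect_false(pose_his524_filter(closed$ligand, "closed", no_hb2, crit))
  # moved back tolerates the missing HB2
  expect_true(pose_his524_filter(closed$ligand, "moved_back", no_hb2,
                                 crit))

  # 14 A ligand with HB1: accepted on open, rejected on closed
  long_cplx <- make_toy_complex("diol_11A", "HB_E353", "open",
                                oo_dist = 14)
  long_hits <- detect_features(long_cplx)
  expect_gt(ligand_length(long_cplx$ligand), 13)
  expect_true(pose_his524_filter(long_cplx$ligand, "open", long_hits,
                                 crit))
  expect_false(pose_his524_filter(long_cplx$ligand, "closed", long_hits,
                                  crit))
})

test_that("detectors are invariant under rigid-body motion of the whole
           complex", {
  cplx <- make_toy_complex("diol_11A", c("HB_E353", "HB_H524", "HB_T347"),
                           "closed")
  th <- 2.2
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  moved <- transform_complex(cplx, R, c(-11, 6, 4))
  expect_identical(sort(hit_features(detect_features(moved))),
                   sort(hit_features(detect_features(cplx))))
  expect_identical(classify_his524(moved$pocket),
                   classify_his524(cplx$pocket))
})
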