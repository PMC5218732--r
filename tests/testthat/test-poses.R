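test_that("heavy-atom RMSD has the closed-form and symmetry behavior", {
  lig <- phenol_mol()
  a <- docked_pose(lig)
  expect_identical(heavy_atom_rmsd(a, a), 0)

  b <- docked_pose(transform_mol(lig, diag(3), c(1, 0, 0) / sqrt(1)))
  expect_equal(heavy_atom_rmsd(a, b, symmetry_aware = FALSE), 1.0,
               tolerance = 1e-12)

  # flipped benzene: zero under symmetry, nonzero without
  benz <- benzene_mol()
  flip <- transform_mol(benz, diag(c(1, -1, -1)), c(0, 0, 0))
  expect_lt(heavy_atom_rmsd(benz, flip, symmetry_aware = TRUE), 1e-9)
  expect_gt(heavy_atom_rmsd(benz, flip, symmetry_aware = FALSE), 1)

  expect_error(heavy_atom_rmsd(docked_pose(benz), docked_pose(lig)),
               "graphs")
})

test_that("greedy consensus clustering flags candidates by occurrence", {
  lig <- phenol_mol()
  ident <- lapply(1:10, function(k) docked_pose(lig, run_index = k))
  cl <- cluster_poses(ident)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$count, 10L)
  expect_true(cl[[1]]$candidate)

  apart <- lapply(1:10, function(k) {
    docked_pose(transform_mol(lig, diag(3), c(6 * k, 0, 0)),
                run_index = k)
  })
  cl2 <- cluster_poses(apart)
  expect_length(cl2, 10)
  expect_false(any(vapply(cl2, function(x) x$candidate, logical(1))))

  # every reported candidate re-validates count and RMSD bound post hoc
  ps <- make_pose_set(lig, cluster_plan = list(c(0.15, 5), c(0.15, 3),
                                               c(0.2, 2)), seed = 3)
  for (c3 in cluster_poses(ps$poses)) {
    if (!c3$candidate) next
    expect_gte(c3$count, 3)
    for (m in c3$members) {
      expect_lt(heavy_atom_rmsd(m, c3$representative), 1.0)
    }
  }
})

test_that("greedy clustering agrees with the clique-decomposition oracle
           on separated random fixtures", {
  lig <- benzene_mol()
  cfg <- cluster_config(symmetry_aware = FALSE)
  n_checked <- 0
  for (s in 1:300) {
    set.seed(s)
    sizes <- sample(1:4, sample(2:3, 1), replace = TRUE)
    sizes <- sizes[cumsum(sizes) <= 8]
    if (!length(sizes)) next
    ps <- make_pose_set(lig, n_runs = sum(sizes), n_per_run = 1,
                        cluster_plan = lapply(sizes, function(k)
                          c(0.2, k)),
                        seed = s)
    oracle <- cluster_poses_oracle(ps$poses, cfg)
    if (is.null(oracle)) next  # ambiguous draw; oracle undefined
    greedy <- cluster_poses(ps$poses, cfg)
    greedy_sets <- lapply(Filter(function(x) x$candidate, greedy),
                          function(x) sort(vapply(x$members, function(p)
                            which(vapply(ps$poses, identical, logical(1),
                                         p)), integer(1))))
    oracle_sets <- lapply(oracle, sort)
    expect_setequal(
      vapply(greedy_sets, paste, character(1), collapse = ","),
      vapply(oracle_sets, paste, character(1), collapse = ","))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 250)
})

test_that("pose files round-trip and hydrogen-depleted poses are
           completed", {
  lig <- phenol_mol()
  dir <- tempfile()
  ps <- make_pose_set(lig, n_runs = 10, n_per_run = 1, seed = 5,
                      dir = dir)
  poses <- load_poses(ps$files, lig)
  expect_length(poses, 10)
  expect_identical(vapply(poses, function(p) p$run_index, integer(1)),
                   1:10)

  # empty file: warning and zero poses
  empty <- file.path(dir, "empty.sdf")
  writeLines(character(), empty)
  expect_warning(p0 <- load_poses(empty, lig), "no poses")
  expect_length(p0, 0)

  # PDBQT with merged non-polar hydrogens: rebuilt from the template
  hv <- which(lig$atoms$element != "H")
  pq <- file.path(dir, "pose.pdbqt")
  lines <- c("MODEL 1", "REMARK VINA RESULT:    -8.3  0.0  0.0")
  for (k in seq_along(hv)) {
    a <- lig$atoms[hv[k], ]
    type <- c(C = "C", O = "OA", N = "N")[a$element]
    lines <- c(lines, sprintf(
      "%-6s%5d  %-3s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00    %6.3f %-2s",
      "ATOM", k, a$element, a$x, a$y, a$z, 0, type))
  }
  writeLines(c(lines, "ENDMDL"), pq)
  pqt <- load_poses(pq, lig)
  expect_length(pqt, 1)
  expect_true(pqt[[1]]$h_rebuilt)
  expect_equal(sum(pqt[[1]]$conformer$atoms$element == "H"),
               sum(lig$atoms$element == "H"))
  expect_equal(pqt[[1]]$engine_score, -8.3)

  # graph mismatch errors with the file named
  expect_error(load_poses(ps$files[1], benzene_mol()), "mismatch")
})

test_that("candidate ranking filters on geometry and orders by predicted
           affinity", {
  cplx <- make_toy_complex("diol_11A", c("HB_E353", "HB_H524"), "closed")
  ps <- make_pose_set(cplx$ligand,
                      cluster_plan = list(c(0.05, 5), c(0.05, 3)),
                      seed = 7)
  clusters <- cluster_poses(ps$poses)
  ranked <- rank_candidates(clusters, cplx)
  ok <- ranked[!is.na(ranked$rank), ]
  expect_gte(nrow(ok), 1)
  expect_identical(ok$rank, seq_len(nrow(ok)))
  # rank order equals the order of the recomputed predictions
  expect_identical(order(-ok$log_rba), seq_len(nrow(ok)))
  # the planted in-pocket cluster wins
  expect_equal(ok$count[ok$rank == 1], 5)

  # a cluster displaced out of the pocket loses HB1 and is filtered out
  far_poses <- lapply(ps$poses, function(p) {
    p$conformer <- transform_mol(p$conformer, diag(3), c(40, 0, 0))
    p
  })
  expect_warning(
    ni <- rank_candidates(cluster_poses(far_poses), cplx),
    "NI|no candidate")
  expect_true(all(is.na(ni$rank)))
})

test_that("topological fingerprints are deterministic, discriminating
           and order-invariant", {
  a <- topo_fingerprint(phenol_mol())
  b <- topo_fingerprint(phenol_mol())
  expect_identical(a, b)

  expect_false(identical(topo_fingerprint(methane_mol()),
                         topo_fingerprint(ethane_mol())))

  # permuting atom order never changes the bitset
  lig <- phenol_mol()
  base_fp <- topo_fingerprint(lig)
  for (s in 1:25) {
    set.seed(s)
    perm <- sample(nrow(lig$atoms))
    inv <- order(perm)
    shuf <- mol_structure(
      lig$atoms[perm, ],
      data.frame(i = inv[lig$bonds$i], j = inv[lig$bonds$j],
                 order = lig$bonds$order),
      name = lig$name)
    expect_identical(topo_fingerprint(shuf), base_fp)
  }
})

test_that("Tanimoto similarity has its set-theoretic values", {
  w <- 64L
  mk <- function(idx) { v <- rep(FALSE, w); v[idx] <- TRUE; v }
  expect_identical(tanimoto(mk(c(1, 5, 9)), mk(c(1, 5, 9))), 1)
  expect_identical(tanimoto(mk(1:3), mk(4:6)), 0)
  expect_identical(tanimoto(mk(1:3), mk(2:4)), 0.5)
  expect_identical(tanimoto(mk(integer(0)), mk(integer(0))), 1.0)
  expect_error(tanimoto(mk(1), rep(FALSE, 32)), "width")
})

test_that("receptor selection picks the most similar co-crystal ligand
           per class", {
  mk_entry <- function(label, cls, lig) {
    list(receptor = complex_structure(lig, list(), receptor_label = label,
                                      receptor_class = cls),
         cocrystal_ligand = lig, receptor_class = cls)
  }
  phen <- phenol_mol()
  diol <- make_toy_complex("diol_11A", character(), "moved_back")$ligand
  amin <- make_toy_complex("amine_tail", character(), "moved_back")$ligand
  benz <- benzene_mol()
  eth <- ethane_mol()
  lib <- list(
    mk_entry("r_phen", "closed", phen),
    mk_entry("r_benz", "closed", benz),
    mk_entry("r_diol", "moved_back", diol),
    mk_entry("r_eth", "moved_back", eth),
    mk_entry("r_amin", "open", amin),
    mk_entry("r_benz2", "open", benz)
  )
  sel <- select_receptors(phen, lib)
  # identical query: its own receptor wins the class
  expect_identical(sel$closed$receptor$receptor_label, "r_phen")
  expect_identical(sel$closed$similarity, 1)

  # brute-force argmax oracle over the whole library
  qfp <- topo_fingerprint(phen)
  for (cls in c("closed", "moved_back", "open")) {
    entries <- Filter(function(e) e$receptor_class == cls, lib)
    sims <- vapply(entries, function(e)
      tanimoto(qfp, topo_fingerprint(e$cocrystal_ligand)), numeric(1))
    labels <- vapply(entries, function(e) e$receptor$receptor_label,
                     character(1))
    expect_identical(sel[[cls]]$receptor$receptor_label,
                     labels[order(-sims, labels)[1]])
  }

  # single-entry classes are chosen regardless of similarity; empty
  # classes are skipped with warnings
  one <- list(mk_entry("only_open", "open", eth))
  w <- capture_warnings(sel1 <- select_receptors(phen, one))
  expect_true(any(grepl("closed", w)) && any(grepl("moved_back", w)))
  expect_identical(sel1$open$receptor$receptor_label, "only_open")
  expect_null(sel1$closed)
})
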