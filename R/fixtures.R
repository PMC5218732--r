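#' Toy complex generator
#'
#' Builds a fully synthetic ERa-like binding situation: a small template
#' ligand (phenolic A-ring, optionally a distal hydroxyl about 11 Angstrom
#' from the phenol oxygen, an amine tail, or an internal hydrogen-bond
#' motif) surrounded by pseudo-residues -- minimal chemical groups carrying
#' real residue names and ERa numbering (GLU353 carboxylate, HIS524
#' imidazole, THR347 hydroxyl, ASP351 carboxylate, PHE404 phenyl, plus a
#' hydrophobic LEU/MET wall) -- placed so that exactly the switched-on
#' interaction features satisfy the default geometric criteria. Phe404 is
#' always positioned in the A-ring pincer: the pocket imposes an absolute
#' aromatic-ring requirement, so the A-ring arrangement and T-stack are
#' constitutive rather than switchable. Deterministic given the seed.
#'
#' None of this mimics real ERa coordinates; geometries are idealized so
#' that detector outcomes are known by construction.
#'
#' @param template one of "phenol", "diol_11A", "amine_tail", "e2_like".
#' @param features character vector of switches to realize, from
#'   {"HB_E353", "HB_H524", "HB_T347", "salt_bridge", "internal_hb"}.
#' @param his524_class target receptor class ("closed", "moved_back",
#'   "open").
#' @param jitter standard deviation of Gaussian coordinate noise, Angstrom.
#' @param seed integer seed for the jitter.
#' @param oo_dist phenol-O to distal-O separation for diol-bearing
#'   templates, Angstrom.
#' @param out_pdb optional path; when given the complex is also written as
#'   a PDB file.
#' @return a `complex_structure` (ligand fully parameterized).
#' @export
make_toy_complex <- function(template = c("phenol", "diol_11A",
                                          "amine_tail", "e2_like"),
                             features = character(),
                             his524_class = c("closed", "moved_back",
                                              "open"),
                             jitter = 0, seed = 1, oo_dist = 11.0,
                             out_pdb = NULL) {
  template <- match.arg(template)
  his524_class <- match.arg(his524_class)
  known <- c("HB_E353", "HB_H524", "HB_T347", "salt_bridge", "internal_hb")
  if (!all(features %in% known)) {
    stop("unknown feature switch(es): ",
         paste(setdiff(features, known), collapse = ", "))
  }
  has_diol <- template %in% c("diol_11A", "e2_like")
  if ("HB_H524" %in% features && !has_diol) {
    stop("HB_H524 needs a distal hydroxyl: use the diol_11A or e2_like ",
         "template")
  }
  if ("HB_H524" %in% features && his524_class != "closed") {
    stop("HB_H524 requires the closed His524 class; a retracted imidazole ",
         "cannot reach the distal hydroxyl")
  }
  if ("HB_T347" %in% features && !has_diol) {
    stop("HB_T347 needs a distal hydroxyl: use the diol_11A or e2_like ",
         "template")
  }
  if ("salt_bridge" %in% features && template != "amine_tail") {
    stop("salt_bridge needs a basic amine: use the amine_tail template")
  }
  if (jitter < 0) stop("jitter must be non-negative")

  lig <- .toy_ligand(template, "internal_hb" %in% features, oo_dist)
  geo <- lig$geo

  pocket <- list()
  addres <- function(res) pocket[[length(pocket) + 1L]] <<- res

  # GLU 353: carboxylate accepting (or not) the phenol hydroxyl
  u_glu <- c(-1, 0, 0)
  if ("HB_E353" %in% features) {
    oe1 <- geo$phenol_o + 2.8 * u_glu
    cd <- oe1 + 1.25 * u_glu
    oe2 <- cd + 1.25 * c(-0.5, 0.866, 0)
    cg <- cd + 1.52 * c(-0.5, -0.866, 0)
  } else {
    # same O...O distance, donor angle far below threshold: no bond
    v <- c(0.5, 0.866, 0)
    oe1 <- geo$phenol_o + 2.8 * v
    cd <- oe1 + 1.25 * v
    oe2 <- cd + 1.25 * c(-0.866, 0.5, 0)
    cg <- cd + 1.52 * c(0.866, 0.5, 0)
  }
  addres(.mkres("GLU", 353, rbind(CG = cg, CD = cd, OE1 = oe1, OE2 = oe2)))
  anchor <- (oe1 + oe2) / 2

  # HIS 524 imidazole placed per requested class
  D <- geo$distal_site
  u_da <- (D - anchor) / .vnorm(D - anchor)
  w_perp <- geo$w - sum(geo$w * u_da) * u_da
  w_perp <- w_perp / .vnorm(w_perp)
  if (his524_class == "closed") {
    if ("HB_H524" %in% features) {
      reach <- sqrt(sum((D - anchor)^2) + 2.85^2)
      if (reach > geometric_criteria()$his524_closed_max) {
        stop("geometric conflict: distal site too far from the Glu353 ",
             "anchor for a hydrogen-bond-capable closed imidazole")
      }
      ne2 <- D + 2.85 * w_perp
    } else {
      ne2 <- D - 4.5 * u_da + 1.5 * c(0, 0, 1)
    }
  } else if (his524_class == "moved_back") {
    ne2 <- anchor + 16.5 * u_da + 3.5 * c(0, 0, 1)
  } else {
    ne2 <- anchor + 20.0 * u_da + 4.0 * c(0, 0, 1)
  }
  addres(.mkres("HIS", 524, .imidazole(ne2, (ne2 - D) / .vnorm(ne2 - D))))

  # THR 347 hydroxyl accepting (or not) the distal hydroxyl
  if (has_diol) {
    if ("HB_T347" %in% features) {
      og1 <- D + 2.8 * (0.866 * w_perp + 0.5 * c(0, 0, 1))
    } else {
      og1 <- D + 8.0 * c(0, 0, -1)
    }
    cb <- og1 + 1.43 * c(0, 0.5, -0.866)
    addres(.mkres("THR", 347, rbind(CB = cb, OG1 = og1)))
  }

  # ASP 351 carboxylate near (or far from) the amine tail
  if (template == "amine_tail") {
    base <- geo$amine_n
    shift <- if ("salt_bridge" %in% features) 3.4 else 8.4
    od1 <- base + shift * c(1, 0, 0)
  } else {
    od1 <- c(9.26, -4, -3)
  }
  cg_a <- od1 + 1.25 * c(1, 0, 0)
  od2 <- cg_a + 1.25 * c(0.5, 0.866, 0)
  cb_a <- cg_a + 1.52 * c(0.5, -0.866, 0)
  addres(.mkres("ASP", 351, rbind(CB = cb_a, CG = cg_a, OD1 = od1,
                                  OD2 = od2)))

  # PHE 404: phenyl perpendicular over the A-ring (pincer), always present
  phe_ctr <- c(0, 0, 4.8)
  th <- seq(90, 390, by = 60)[1:6] * pi / 180
  phe_xyz <- t(vapply(th, function(a) {
    phe_ctr + 1.39 * (cos(a) * c(0, 1, 0) + sin(a) * c(0, 0, 1))
  }, numeric(3)))
  rownames(phe_xyz) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  addres(.mkres("PHE", 404, phe_xyz))

  # hydrophobic wall: LEU/MET methyl-like carbons under the ligand
  addres(.mkres("LEU", 384, rbind(CD1 = c(-1.2, 0, -4.0),
                                  CD2 = c(1.2, 0, -4.0))))
  if (has_diol || template == "amine_tail") {
    mid <- (geo$phenol_o + D) / 2
    addres(.mkres("LEU", 387, rbind(CD1 = mid + c(0, 0, -4.0),
                                    CD2 = mid + c(1.8, 0, -4.0))))
    addres(.mkres("MET", 421, rbind(SD = D + c(0, -1.5, -4.0),
                                    CE = D + c(1.5, -1.5, -4.0))))
  }

  # hydrophobic flags from the default residue list
  pocket <- lapply(pocket, function(res) {
    res$hydrophobic <- .is_hydrophobic(res, default_hydrophobic_residues())
    res
  })
  ord <- order(vapply(pocket, function(r) r$chain, character(1)),
               vapply(pocket, function(r) r$seq_num, integer(1)))
  pocket <- pocket[ord]

  cplx <- complex_structure(lig$mol, pocket,
    receptor_label = sprintf("toy_%s_%s", template, his524_class))
  if (jitter > 0) {
    cplx <- with_seed(seed, .jitter_complex(cplx, jitter))
  }
  cplx$ligand <- parameterize_ligand(cplx$ligand)
  if (!is.null(out_pdb)) write_pdb_complex(cplx, out_pdb)
  cplx
}

.mkres <- function(res_name, seq_num, xyz, chain = "A") {
  el <- .cap(substr(rownames(xyz), 1, 1))
  el[substr(rownames(xyz), 1, 1) == "S"] <- "S"
  atoms <- data.frame(
    serial = seq_len(nrow(xyz)), name = rownames(xyz), element = el,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE
  )
  pocket_residue(res_name, chain, seq_num, atoms)
}

.imidazole <- function(ne2, away) {
  # pentagon with NE2 at one vertex, extending along `away` from the ligand
  e1 <- -away
  ref <- if (abs(away[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / .vnorm(e2)
  ctr <- ne2 + 1.16 * away
  th <- c(NE2 = 180, CE1 = 252, ND1 = 324, CG = 36, CD2 = 108) * pi / 180
  xyz <- t(vapply(th, function(a) {
    ctr + 1.16 * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3)))
  rownames(xyz) <- names(th)
  xyz
}

.jitter_complex <- function(cplx, sd) {
  n_l <- nrow(cplx$ligand$atoms)
  cplx$ligand$atoms$x <- cplx$ligand$atoms$x + stats::rnorm(n_l, 0, sd)
  cplx$ligand$atoms$y <- cplx$ligand$atoms$y + stats::rnorm(n_l, 0, sd)
  cplx$ligand$atoms$z <- cplx$ligand$atoms$z + stats::rnorm(n_l, 0, sd)
  cplx$pocket <- lapply(cplx$pocket, function(res) {
    n <- nrow(res$atoms)
    res$atoms$x <- res$atoms$x + stats::rnorm(n, 0, sd)
    res$atoms$y <- res$atoms$y + stats::rnorm(n, 0, sd)
    res$atoms$z <- res$atoms$z + stats::rnorm(n, 0, sd)
    res
  })
  cplx
}

# template ligand in a canonical pose: A-ring in the xy-plane centred at
# the origin, phenol oxygen on -x, growth direction 20 degrees off +x
.toy_ligand <- function(template, internal_hb, oo_dist) {
  u20 <- c(cos(20 * pi / 180), sin(20 * pi / 180), 0)
  w <- c(-sin(20 * pi / 180), cos(20 * pi / 180), 0)
  ring_th <- c(180, 240, 300, 0, 60, 120) * pi / 180
  ring <- t(vapply(ring_th, function(a) 1.39 * c(cos(a), sin(a), 0),
                   numeric(3)))
  atoms <- data.frame(
    name = paste0("C", 1:6), element = "C",
    x = ring[, 1], y = ring[, 2], z = ring[, 3],
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = 1L)
  add_atom <- function(name, element, pos) {
    atoms <<- rbind(atoms, data.frame(name = name, element = element,
      x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE))
    nrow(atoms)
  }
  add_bond <- function(i, j) {
    bonds <<- rbind(bonds, data.frame(i = i, j = j, order = 1L))
  }
  phenol_o <- c(-2.75, 0, 0)
  o1 <- add_atom("O1", "O", phenol_o)
  add_bond(1, o1)
  h1 <- add_atom("HO1", "H", phenol_o + 0.96 * c(-1, 0, 0))
  add_bond(o1, h1)
  # ring hydrogens on unsubstituted carbons
  ring_sub <- c(1L, 4L)
  if (internal_hb) ring_sub <- c(ring_sub, 5L, 6L)
  for (k in setdiff(1:6, ring_sub)) {
    h <- add_atom(paste0("H", k), "H", ring[k, ] * (1.39 + 1.09) / 1.39)
    add_bond(k, h)
  }
  geo <- list(phenol_o = phenol_o, w = w)
  distal_site <- phenol_o + oo_dist * u20
  geo$distal_site <- distal_site

  if (template %in% c("diol_11A", "e2_like")) {
    c_end <- distal_site - 1.43 * u20
    v <- c_end - ring[4, ]
    nseg <- max(2L, ceiling(.vnorm(v) / 1.5))
    prev <- 4L
    for (k in seq_len(nseg)) {
      pos <- ring[4, ] + v * k / nseg
      # mild zigzag off-plane for realism
      pos[3] <- pos[3] + 0.25 * (k %% 2)
      if (k == nseg) pos <- c_end
      idx <- add_atom(paste0("CT", k), "C", pos)
      add_bond(prev, idx)
      prev <- idx
    }
    o2 <- add_atom("O2", "O", distal_site)
    add_bond(prev, o2)
    h2 <- add_atom("HO2", "H", distal_site + 0.96 * w)
    add_bond(o2, h2)
    if (template == "e2_like") {
      # fatten the body: methyl branches along the chain
      mid <- (phenol_o + distal_site) / 2
      b1 <- add_atom("CB1", "C", mid + c(0, -1.5, 0.6))
      b2 <- add_atom("CB2", "C", mid + c(1.2, -1.5, -0.6))
      chain_rows <- grep("^CT", atoms$name)
      near <- chain_rows[which.min((atoms$x[chain_rows] - mid[1])^2 +
                                     (atoms$y[chain_rows] - mid[2])^2 +
                                     (atoms$z[chain_rows] - mid[3])^2)]
      add_bond(near, b1)
      add_bond(b1, b2)
    }
  } else if (template == "amine_tail") {
    t1 <- add_atom("CT1", "C", ring[4, ] + c(1.5, 0, 0))
    t2 <- add_atom("CT2", "C", ring[4, ] + c(3.0, 0, 0))
    nn <- add_atom("N1", "N", ring[4, ] + c(4.47, 0, 0))
    m1 <- add_atom("CM1", "C", ring[4, ] + c(4.47, 0, 0) +
                     1.47 * c(-0.5, 0, 0.866))
    m2 <- add_atom("CM2", "C", ring[4, ] + c(4.47, 0, 0) +
                     1.47 * c(-0.5, 0, -0.866))
    add_bond(4L, t1); add_bond(t1, t2); add_bond(t2, nn)
    add_bond(nn, m1); add_bond(nn, m2)
    geo$amine_n <- ring[4, ] + c(4.47, 0, 0)
  }

  if (internal_hb) {
    # hydroxyl on C6 + formyl on C5 forming one internal hydrogen bond
    o3 <- add_atom("O3", "O", ring[6, ] + 1.36 * c(-0.5, 0.866, 0))
    add_bond(6L, o3)
    cf <- add_atom("CF", "C", ring[5, ] + 1.5 * c(0.5, 0.866, 0))
    add_bond(5L, cf)
    of <- add_atom("OF", "O", ring[5, ] + 1.5 * c(0.5, 0.866, 0) +
                     1.23 * c(-0.5, 0.866, 0))
    bonds <- rbind(bonds, data.frame(i = cf, j = of, order = 2L))
    hf <- add_atom("HF", "H", ring[5, ] + 1.5 * c(0.5, 0.866, 0) +
                     1.09 * c(0.94, 0.34, 0))
    add_bond(cf, hf)
    o3p <- atoms[o3, c("x", "y", "z")]
    ofp <- atoms[of, c("x", "y", "z")]
    dirv <- as.numeric(ofp - o3p)
    dirv <- dirv / .vnorm(dirv)
    h3 <- add_atom("HO3", "H", as.numeric(o3p) + 0.96 * dirv)
    add_bond(o3, h3)
  }
  mol <- mol_structure(atoms, bonds, name = paste0("toy_", template))
  mol <- complete_hydrogens(mol)
  list(mol = mol, geo = geo)
}

#' Synthetic fingerprint/affinity tables
#'
#' Draws fingerprint rows emulating the structure of the training data --
#' binary interaction bits as Bernoulli draws, a small-integer internal
#' hydrogen-bond count, a continuous hydrophobic-contact value on the
#' published training range (0.80 to 2.44) -- and responses
#' y = intercept + sum(c FP) + Gaussian noise. Stands in for transcribed
#' supplementary data; all draws are seeded.
#'
#' @param n number of rows (>= 5).
#' @param true_coefficients named per-bit coefficients (default: the
#'   published model).
#' @param intercept true intercept.
#' @param noise_sd Gaussian noise standard deviation in log RBA units.
#' @param bit_probabilities Bernoulli probabilities for FP1-FP4.
#' @param fp5_lambda Poisson mean for the internal hydrogen-bond count.
#' @param logpc_range uniform range for FP6, within [0, 4].
#' @param seed integer seed.
#' @return list with matrix `X` (n x 6, columns FP1..FP6) and vector `y`.
#' @export
make_synthetic_table <- function(n = 31,
                                 true_coefficients = published_model()$coefficients,
                                 intercept = published_model()$intercept,
                                 noise_sd = 0.3,
                                 bit_probabilities = c(FP1 = 0.2, FP2 = 0.8,
                                                       FP3 = 0.3, FP4 = 0.15),
                                 fp5_lambda = 0.4,
                                 logpc_range = c(0.80, 2.44),
                                 seed = 1) {
  stopifnot(n >= 5, noise_sd >= 0,
            all(logpc_range >= 0), all(logpc_range <= 4))
  with_seed(seed, {
    X <- cbind(
      FP1 = stats::rbinom(n, 1, bit_probabilities["FP1"]),
      FP2 = stats::rbinom(n, 1, bit_probabilities["FP2"]),
      FP3 = stats::rbinom(n, 1, bit_probabilities["FP3"]),
      FP4 = stats::rbinom(n, 1, bit_probabilities["FP4"]),
      FP5 = pmin(stats::rpois(n, fp5_lambda), 3L),
      FP6 = stats::runif(n, logpc_range[1], logpc_range[2])
    )
    y <- intercept + drop(X %*% true_coefficients[colnames(X)]) +
      stats::rnorm(n, 0, noise_sd)
    list(X = X, y = y)
  })
}

#' Synthetic docked-pose sets with planted consensus clusters
#'
#' Emulates repeated independent docking runs: each plan entry places a
#' cluster of poses around a translated copy of the base ligand (centers
#' 5 Angstrom apart), jittered by a random rigid translation of the given
#' magnitude; leftover slots become scattered singleton poses. Ground-
#' truth cluster labels are returned for assertions; poses can also be
#' written as one SDF file per run.
#'
#' @param base ligand `mol_structure`.
#' @param n_runs number of docking runs emulated.
#' @param n_per_run poses per run.
#' @param cluster_plan list of `c(jitter, multiplicity)` pairs; the
#'   multiplicities must sum to at most `n_runs * n_per_run`.
#' @param seed integer seed.
#' @param dir optional directory; when given, `run_<i>.sdf` files are
#'   written and their paths returned.
#' @return list with `poses` (list of `docked_pose`), `labels` (integer,
#'   0 = scattered noise pose), and `files` (paths or NULL).
#' @export
make_pose_set <- function(base, n_runs = 10, n_per_run = 1,
                          cluster_plan = list(c(0.15, 5), c(0.15, 3),
                                              c(0.15, 2)),
                          seed = 1, dir = NULL) {
  total <- n_runs * n_per_run
  mult <- vapply(cluster_plan, function(p) as.integer(p[2]), integer(1))
  if (sum(mult) > total) {
    stop("cluster multiplicities exceed n_runs * n_per_run")
  }
  with_seed(seed, {
    poses <- list(); labels <- integer()
    for (k in seq_along(cluster_plan)) {
      jit <- cluster_plan[[k]][1]
      center_shift <- c(5 * (k - 1), 0, 0)
      for (m in seq_len(mult[k])) {
        t_vec <- center_shift + stats::rnorm(3, 0, jit / sqrt(3))
        conf <- transform_mol(base, diag(3), t_vec)
        conf$name <- sprintf("%s_c%d_%d", base$name, k, m)
        poses[[length(poses) + 1L]] <- docked_pose(conf)
        labels <- c(labels, k)
      }
    }
    n_noise <- total - sum(mult)
    for (m in seq_len(n_noise)) {
      conf <- transform_mol(base, diag(3),
                            c(-6 * m, 7 * m, 3 * (m %% 2)))
      conf$name <- sprintf("%s_noise_%d", base$name, m)
      poses[[length(poses) + 1L]] <- docked_pose(conf)
      labels <- c(labels, 0L)
    }
    # interleave across runs deterministically
    run_of <- rep(seq_len(n_runs), length.out = length(poses))
    for (i in seq_along(poses)) poses[[i]]$run_index <- run_of[i]
    files <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- character(n_runs)
      for (r in seq_len(n_runs)) {
        mols <- lapply(poses[run_of == r], function(p) p$conformer)
        files[r] <- file.path(dir, sprintf("run_%02d.sdf", r))
        write_sdf(mols, files[r])
      }
    }
    list(poses = poses, labels = labels, files = files)
  })
}
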