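#' Clustering configuration for docked poses
#'
#' @param rmsd_threshold Angstrom; poses within this of a cluster
#'   representative join the cluster.
#' @param min_count minimum occurrence for a cluster to be a bioactive-
#'   conformation candidate.
#' @param runs_expected number of independent docking runs expected.
#' @param symmetry_aware minimize RMSD over graph automorphisms.
#' @return list of settings.
#' @export
cluster_config <- function(rmsd_threshold = 1.0, min_count = 3L,
                           runs_expected = 10L, symmetry_aware = TRUE) {
  stopifnot(rmsd_threshold > 0, min_count >= 1)
  list(rmsd_threshold = rmsd_threshold, min_count = as.integer(min_count),
       runs_expected = as.integer(runs_expected),
       symmetry_aware = symmetry_aware)
}

#' Docked pose constructor
#'
#' @param conformer `mol_structure` in the receptor frame.
#' @param run_index docking run the pose came from.
#' @param source_receptor receptor label.
#' @param engine_score docking engine energy (kcal/mol), or NA.
#' @return object of class `docked_pose`.
#' @export
docked_pose <- function(conformer, run_index = 1L,
                        source_receptor = "receptor",
                        engine_score = NA_real_) {
  structure(
    list(conformer = conformer, run_index = as.integer(run_index),
         source_receptor = source_receptor, engine_score = engine_score),
    class = "docked_pose"
  )
}

#' Load docked poses from files
#'
#' Multi-model SDF (via ChemmineR) or PDBQT pose files. Heavy atoms are
#' matched to the template by element sequence; files whose molecular graph
#' disagrees with the template raise an error naming the file and model.
#' Poses with hydrogens merged onto heavy atoms (the common docking output
#' convention) have them rebuilt at standard geometry, with the
#' `h_rebuilt` flag recorded, since missing non-polar hydrogens corrupt
#' the surface field.
#'
#' @param paths character vector of pose files; `run_index` follows file
#'   order.
#' @param template ligand `mol_structure` defining atom identity.
#' @return list of `docked_pose`.
#' @export
load_poses <- function(paths, template) {
  t_heavy <- heavy_idx(template)
  t_el <- template$atoms$element[t_heavy]
  nb <- neighbor_list(template)
  t_hcount <- vapply(t_heavy, function(a) {
    sum(template$atoms$element[nb[[a]]] == "H")
  }, integer(1))
  poses <- list()
  for (fi in seq_along(paths)) {
    path <- paths[fi]
    mols <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) {
      .read_pdbqt_models(path)
    } else {
      .read_sdf_models(path)
    }
    if (!length(mols)) {
      warning("no poses in file: ", path)
      next
    }
    for (mi in seq_along(mols)) {
      m <- mols[[mi]]
      m_heavy <- which(m$atoms$element != "H")
      if (length(m_heavy) != length(t_heavy) ||
          !all(m$atoms$element[m_heavy] == t_el)) {
        stop("pose graph mismatch with template in ", path,
             " (model ", mi, ")")
      }
      pose_mol <- m$mol
      h_rebuilt <- FALSE
      if (sum(m$atoms$element == "H") < sum(template$atoms$element == "H")) {
        expected <- stats::setNames(t_hcount, as.character(m_heavy))
        pose_mol <- complete_hydrogens(pose_mol, polar = TRUE,
                                       expected = expected)
        h_rebuilt <- TRUE
      }
      p <- docked_pose(pose_mol, run_index = fi,
                       engine_score = m$score)
      p$h_rebuilt <- h_rebuilt
      poses[[length(poses) + 1L]] <- p
    }
  }
  poses
}

.read_sdf_models <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("ChemmineR is required to read SDF pose files")
  }
  if (!any(nzchar(trimws(readLines(path, warn = FALSE))))) return(list())
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  lapply(seq_along(ChemmineR::sdfid(sdf)), function(k) {
    one <- sdf[[k]]
    ab <- ChemmineR::atomblock(one)
    bb <- ChemmineR::bondblock(one)
    el <- gsub("_.*$", "", rownames(ab))
    atoms <- data.frame(
      serial = seq_len(nrow(ab)), name = el, element = el,
      x = ab[, 1], y = ab[, 2], z = ab[, 3], stringsAsFactors = FALSE
    )
    bonds <- if (!is.null(bb) && nrow(bb) > 0) {
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else NULL
    mol <- mol_structure(atoms, bonds, name = ChemmineR::sdfid(sdf)[k])
    score <- NA_real_
    dd <- ChemmineR::datablock(one)
    if (!is.null(dd) && "score" %in% names(dd)) {
      score <- suppressWarnings(as.numeric(dd[["score"]]))
    }
    list(mol = mol, atoms = atoms, score = score)
  })
}

.read_pdbqt_models <- function(path) {
  lines <- readLines(path)
  model_breaks <- c(grep("^MODEL", lines), length(lines) + 1L)
  if (length(model_breaks) == 1L) model_breaks <- c(0L, model_breaks)
  out <- list()
  for (k in seq_len(length(model_breaks) - 1L)) {
    seg <- lines[(model_breaks[k] + 1L):(model_breaks[k + 1L] - 1L)]
    at <- seg[grepl("^(ATOM|HETATM)", seg)]
    if (!length(at)) next
    type <- trimws(substr(at, 78, 79))
    el <- .pdbqt_element(type)
    atoms <- data.frame(
      serial = seq_along(at), name = trimws(substr(at, 13, 16)),
      element = el,
      x = as.numeric(substr(at, 31, 38)),
      y = as.numeric(substr(at, 39, 46)),
      z = as.numeric(substr(at, 47, 54)),
      stringsAsFactors = FALSE
    )
    score <- NA_real_
    sc <- seg[grepl("REMARK VINA RESULT", seg)]
    if (length(sc)) {
      score <- suppressWarnings(
        as.numeric(strsplit(trimws(sub(".*RESULT:", "", sc[1])),
                            "\\s+")[[1]][1]))
    }
    mol <- mol_structure(atoms, perceive_bonds(atoms),
                         name = basename(path))
    out[[length(out) + 1L]] <- list(mol = mol, atoms = atoms,
                                    score = score)
  }
  out
}

.pdbqt_element <- function(type) {
  map <- c(A = "C", C = "C", N = "N", NA. = "N", OA = "O", O = "O",
           SA = "S", S = "S", HD = "H", H = "H", F = "F", Cl = "Cl",
           CL = "Cl", Br = "Br", BR = "Br", I = "I", P = "P")
  key <- ifelse(type == "NA", "NA.", type)
  el <- map[key]
  el[is.na(el)] <- .cap(substr(type[is.na(el)], 1, 1))
  unname(el)
}

# automorphisms of the heavy-atom graph (element-colored), as index maps
.heavy_automorphisms <- function(mol) {
  hv <- heavy_idx(mol)
  sub <- data.frame(old = hv, new = seq_along(hv))
  bonds <- mol$bonds[mol$bonds$i %in% hv & mol$bonds$j %in% hv, ,
                     drop = FALSE]
  bi <- match(bonds$i, hv); bj <- match(bonds$j, hv)
  g <- igraph::graph_from_data_frame(
    data.frame(i = bi, j = bj), directed = FALSE,
    vertices = data.frame(name = seq_along(hv))
  )
  col <- as.integer(factor(mol$atoms$element[hv]))
  maps <- igraph::graph.get.isomorphisms.vf2(
    g, g, vertex.color1 = col, vertex.color2 = col
  )
  # each map sends heavy atom i (creation order) to heavy atom perm[i]
  lapply(maps, function(m) as.integer(igraph::as_ids(m)))
}

#' Heavy-atom RMSD between two poses
#'
#' Computed in the shared receptor frame (no superposition). With
#' `symmetry_aware`, the minimum over automorphisms of the element-colored
#' heavy-atom graph is returned, so topologically equivalent orientations
#' of symmetric ligands (e.g. a flipped benzene) score zero.
#'
#' @param a,b `docked_pose` objects (or `mol_structure`s) on the same
#'   ligand graph.
#' @param symmetry_aware logical.
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(a, b, symmetry_aware = TRUE) {
  ma <- if (inherits(a, "docked_pose")) a$conformer else a
  mb <- if (inherits(b, "docked_pose")) b$conformer else b
  ha <- heavy_idx(ma); hb <- heavy_idx(mb)
  if (length(ha) != length(hb) ||
      !all(ma$atoms$element[ha] == mb$atoms$element[hb])) {
    stop("pose ligand graphs do not match")
  }
  xa <- coords_of(ma)[ha, , drop = FALSE]
  xb <- coords_of(mb)[hb, , drop = FALSE]
  plain <- sqrt(mean(rowSums((xa - xb)^2)))
  if (!symmetry_aware) return(plain)
  maps <- tryCatch(.heavy_automorphisms(ma), error = function(e) NULL)
  if (is.null(maps) || length(maps) <= 1) return(plain)
  best <- plain
  for (m in maps) {
    r <- sqrt(mean(rowSums((xa - xb[m, , drop = FALSE])^2)))
    if (r < best) best <- r
  }
  best
}

#' Consensus clustering of docked poses
#'
#' Deterministic greedy leader clustering: poses are ordered by engine
#' score (best first; ties and missing scores by run index, then input
#' position); the first unassigned pose seeds a cluster and every later
#' pose joins the first cluster whose representative lies within the RMSD
#' threshold. Clusters observed at least `min_count` times are flagged as
#' bioactive-conformation candidates. The cluster representative is the
#' member with the best engine score, or the medoid when scores are
#' absent.
#'
#' @param poses list of `docked_pose`.
#' @param config settings from [cluster_config()].
#' @return list of `pose_cluster` (members, count, representative,
#'   candidate flag), candidates first, ordered by count.
#' @export
cluster_poses <- function(poses, config = cluster_config()) {
  stopifnot(length(poses) >= 1)
  score <- vapply(poses, function(p) {
    if (is.na(p$engine_score)) Inf else p$engine_score
  }, numeric(1))
  run <- vapply(poses, function(p) p$run_index, integer(1))
  ord <- order(score, run, seq_along(poses))
  leaders <- integer()
  assign <- integer(length(poses))
  for (k in ord) {
    placed <- FALSE
    for (ci in seq_along(leaders)) {
      if (heavy_atom_rmsd(poses[[k]], poses[[leaders[ci]]],
                          config$symmetry_aware) < config$rmsd_threshold) {
        assign[k] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, k)
      assign[k] <- length(leaders)
    }
  }
  clusters <- lapply(seq_along(leaders), function(ci) {
    mem <- which(assign == ci)
    msc <- score[mem]
    rep_idx <- if (all(is.infinite(msc))) {
      # medoid: minimum total RMSD to the other members
      if (length(mem) == 1) mem else {
        tot <- vapply(mem, function(i) {
          sum(vapply(mem, function(j) {
            if (i == j) 0 else heavy_atom_rmsd(poses[[i]], poses[[j]],
                                               config$symmetry_aware)
          }, numeric(1)))
        }, numeric(1))
        mem[which.min(tot)]
      }
    } else mem[which.min(msc)]
    structure(
      list(members = poses[mem], count = length(mem),
           representative = poses[[rep_idx]],
           candidate = length(mem) >= config$min_count,
           predicted = NULL),
      class = "pose_cluster"
    )
  })
  counts <- vapply(clusters, function(cl) cl$count, integer(1))
  cand <- vapply(clusters, function(cl) cl$candidate, logical(1))
  clusters[order(!cand, -counts)]
}

#' Reference clustering oracle (clique decomposition)
#'
#' Independent check for the greedy clustering: builds the full pairwise
#' RMSD graph (edge when RMSD < threshold) and requires its connected
#' components to be cliques, i.e. genuinely unambiguous consensus groups.
#' Candidate clusters are the components with at least `min_count`
#' members. Returns NULL when a component is not a clique (the fixture is
#' ambiguous and no partition-free answer exists).
#'
#' @inheritParams cluster_poses
#' @return list of integer member-index vectors (candidates only), or
#'   NULL for ambiguous inputs.
#' @export
cluster_poses_oracle <- function(poses, config = cluster_config()) {
  n <- length(poses)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      adj[i, j] <- adj[j, i] <-
        heavy_atom_rmsd(poses[[i]], poses[[j]],
                        config$symmetry_aware) < config$rmsd_threshold
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- list()
  for (c_id in unique(comp)) {
    mem <- which(comp == c_id)
    k <- length(mem)
    if (k > 1 && sum(adj[mem, mem]) != k * (k - 1)) return(NULL)
    if (k >= config$min_count) out[[length(out) + 1L]] <- mem
  }
  out[order(vapply(out, min, integer(1)))]
}

#' Filter, score and rank candidate pose clusters
#'
#' For each candidate cluster representative: re-detect interaction
#' features in the receptor, apply the His524 pose filter and the A-ring
#' arrangement check (failing poses are dropped and reported), evaluate
#' the surface field and log P_C, assemble the fingerprint and predict
#' log RBA, then rank descending. Ties break by cluster count, then
#' engine score.
#'
#' @param clusters list of `pose_cluster` from [cluster_poses()].
#' @param receptor a `complex_structure` supplying the pocket (its ligand
#'   slot is replaced by each pose).
#' @param model a `qsar_model`.
#' @param criteria a `geometric_criteria`.
#' @param grid_density,probe_radius surface-grid settings.
#' @param coeffs `field_coefficients`.
#' @return data.frame with one row per candidate (cluster, count,
#'   filtered, FP1..FP6, log_rba, rank); zero ranked rows when every
#'   candidate is filtered out (the no-identification outcome), with a
#'   warning.
#' @export
rank_candidates <- function(clusters, receptor, model = published_model(),
                            criteria = geometric_criteria(),
                            grid_density = 2.0, probe_radius = 1.4,
                            coeffs = field_coefficients()) {
  cand <- Filter(function(cl) cl$candidate, clusters)
  if (!length(cand)) {
    warning("no candidate clusters to rank")
    return(.empty_ranking())
  }
  receptor_class <- if (receptor$receptor_class != "unknown") {
    receptor$receptor_class
  } else classify_his524(receptor$pocket, criteria)
  hyd <- extract_hydrophobic_pocket(receptor)
  phe <- phe404_ring(receptor$pocket)
  rows <- list()
  for (ci in seq_along(cand)) {
    cl <- cand[[ci]]
    lig <- cl$representative$conformer
    lig <- parameterize_ligand(lig)
    cplx <- receptor
    cplx$ligand <- lig
    hits <- detect_features(cplx, criteria)
    ok_his <- pose_his524_filter(lig, receptor_class, hits, criteria)
    ok_aring <- if (is.null(phe)) TRUE else
      check_aring_arrangement(lig, phe, criteria)
    filtered <- !(ok_his && ok_aring)
    fpv <- rep(NA_real_, 6)
    log_rba <- NA_real_
    if (!filtered) {
      grid <- generate_sas_grid(lig, probe_radius, grid_density, coeffs)
      lpc <- compute_logpc(grid, hyd)
      fp <- build_fingerprint(hits, lpc$logpc, cplx)
      pred <- predict_log_rba(fp, model)
      fpv <- unname(fp$fp)
      log_rba <- pred$log_rba
    }
    rows[[ci]] <- data.frame(
      cluster = ci, count = cl$count,
      engine_score = cl$representative$engine_score,
      filtered = filtered,
      FP1 = fpv[1], FP2 = fpv[2], FP3 = fpv[3], FP4 = fpv[4],
      FP5 = fpv[5], FP6 = fpv[6], log_rba = log_rba
    )
  }
  out <- do.call(rbind, rows)
  keep <- !out$filtered
  if (!any(keep)) {
    warning("all candidate poses removed by geometric filters (NI)")
    out$rank <- NA_integer_
    return(out)
  }
  ranked <- out[keep, , drop = FALSE]
  ord <- order(-ranked$log_rba, -ranked$count, ranked$engine_score)
  ranked$rank <- NA_integer_
  ranked$rank[ord] <- seq_len(nrow(ranked))
  out$rank <- NA_integer_
  out$rank[keep] <- ranked$rank
  out[order(is.na(out$rank), out$rank), ]
}

.empty_ranking <- function() {
  data.frame(cluster = integer(), count = integer(),
             engine_score = numeric(), filtered = logical(),
             FP1 = numeric(), FP2 = numeric(), FP3 = numeric(),
             FP4 = numeric(), FP5 = numeric(), FP6 = numeric(),
             log_rba = numeric(), rank = integer())
}
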