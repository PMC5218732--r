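#' Run configuration
#'
#' Bundles every knob of the scoring pipeline so a report can embed the
#' exact configuration that produced it.
#'
#' @param criteria `geometric_criteria`.
#' @param coeffs `field_coefficients`.
#' @param model `qsar_model`.
#' @param hydrophobic_residues residue list for the contact integral.
#' @param grid_density,probe_radius surface-grid settings.
#' @param raw_sum literal unweighted contact sum instead of the surface
#'   integral.
#' @param cluster `cluster_config()` settings (ranking pipeline).
#' @param seed integer seed recorded for provenance.
#' @return list of class `run_config`.
#' @export
run_config <- function(criteria = geometric_criteria(),
                       coeffs = field_coefficients(),
                       model = published_model(),
                       hydrophobic_residues = default_hydrophobic_residues(),
                       grid_density = 2.0, probe_radius = 1.4,
                       raw_sum = FALSE, cluster = cluster_config(),
                       seed = 1L) {
  structure(
    list(criteria = criteria, coeffs = coeffs, model = model,
         hydrophobic_residues = hydrophobic_residues,
         grid_density = grid_density, probe_radius = probe_radius,
         raw_sum = raw_sum, cluster = cluster, seed = seed),
    class = "run_config"
  )
}

#' End-to-end scoring of one complex
#'
#' Reads/receives a complex, detects interaction features, builds the
#' surface grid, integrates log P_C, assembles the fingerprint and
#' predicts log RBA, returning a report with the per-feature contribution
#' breakdown and the full configuration used.
#'
#' @param cplx a `complex_structure`, or a PDB path (then `ligand_code`
#'   is required).
#' @param config a `run_config`.
#' @param ligand_code het code when `cplx` is a path.
#' @return list of class `score_report`.
#' @export
run_score_pipeline <- function(cplx, config = run_config(),
                               ligand_code = NULL) {
  if (is.character(cplx)) {
    if (is.null(ligand_code)) stop("ligand_code required with a PDB path")
    cplx <- read_pdb_complex(cplx, ligand_code,
      hydrophobic_residues = config$hydrophobic_residues)
    cplx$ligand <- parameterize_ligand(cplx$ligand)
  }
  if (!length(cplx$pocket)) stop("empty pocket: nothing to score against")
  if (anyNA(cplx$ligand$atoms$charge)) {
    cplx$ligand <- parameterize_ligand(cplx$ligand)
  }
  hits <- detect_features(cplx, config$criteria)
  grid <- generate_sas_grid(cplx$ligand, config$probe_radius,
                            config$grid_density, config$coeffs)
  hyd <- suppressWarnings(
    extract_hydrophobic_pocket(cplx, config$hydrophobic_residues))
  lpc <- compute_logpc(grid, hyd, raw_sum = config$raw_sum)
  fp <- build_fingerprint(hits, lpc$logpc, cplx)
  pred <- predict_log_rba(fp, config$model)
  structure(
    list(
      receptor = cplx$receptor_label,
      receptor_class = classify_his524(cplx$pocket, config$criteria),
      features = data.frame(
        feature = vapply(hits, function(h) h$feature, character(1)),
        partner = vapply(hits, function(h) h$partner, character(1)),
        stringsAsFactors = FALSE
      ),
      fingerprint = fp$fp,
      candidate_bits = fp$candidate_bits,
      logpc = lpc$logpc,
      logpc_per_residue = lpc$per_residue,
      log_rba = pred$log_rba,
      contributions = pred$per_feature_contribution,
      intercept = pred$intercept,
      sas_area = sum(grid$points$area_weight),
      config = .config_echo(config)
    ),
    class = "score_report"
  )
}

#' Cluster, filter and rank docked poses end to end
#'
#' @param pose_paths pose files (multi-model SDF or PDBQT), or a list of
#'   `docked_pose` objects.
#' @param template ligand `mol_structure` defining atom identity.
#' @param receptor `complex_structure` providing the pocket.
#' @param config a `run_config`.
#' @return list of class `rank_report`; `ni` is TRUE when no candidate
#'   survives the geometric filters.
#' @export
run_rank_pipeline <- function(pose_paths, template, receptor,
                              config = run_config()) {
  poses <- if (is.list(pose_paths) && length(pose_paths) &&
               inherits(pose_paths[[1]], "docked_pose")) {
    pose_paths
  } else {
    load_poses(pose_paths, template)
  }
  clusters <- cluster_poses(poses, config$cluster)
  ranking <- withCallingHandlers(
    rank_candidates(clusters, receptor, config$model, config$criteria,
                    config$grid_density, config$probe_radius,
                    config$coeffs),
    warning = function(w) invokeRestart("muffleWarning")
  )
  ni <- nrow(ranking) == 0 || all(is.na(ranking$rank))
  structure(
    list(
      n_poses = length(poses),
      n_clusters = length(clusters),
      n_candidates = sum(vapply(clusters, function(cl) cl$candidate,
                                logical(1))),
      ranking = ranking,
      ni = ni,
      config = .config_echo(config)
    ),
    class = "rank_report"
  )
}

.config_echo <- function(config) {
  list(
    criteria = unclass(config$criteria),
    coeffs = unclass(config$coeffs),
    model = list(coefficients = as.list(config$model$coefficients),
                 intercept = config$model$intercept),
    hydrophobic_residues = config$hydrophobic_residues,
    grid_density = config$grid_density,
    probe_radius = config$probe_radius,
    raw_sum = config$raw_sum,
    cluster = config$cluster,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("hydroqsar"))
  )
}

#' Serialize a report as JSON or TSV
#'
#' Deterministic output: identical inputs and configuration produce
#' byte-identical text.
#'
#' @param report a `score_report` or `rank_report`.
#' @param format "json" or "tsv".
#' @return character scalar (JSON) or vector of TSV lines.
#' @export
format_report <- function(report, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- unclass(report)
    # keep names of numeric vectors (jsonlite drops atomic-vector names)
    for (f in c("fingerprint", "candidate_bits", "contributions",
                "logpc_per_residue")) {
      if (!is.null(out[[f]])) out[[f]] <- as.list(out[[f]])
    }
    return(as.character(jsonlite::toJSON(out,
      auto_unbox = TRUE, digits = 10, dataframe = "rows", pretty = TRUE)))
  }
  if (inherits(report, "score_report")) {
    kv <- c(
      receptor = report$receptor,
      receptor_class = report$receptor_class,
      stats::setNames(sprintf("%.6f", report$fingerprint),
                      names(report$fingerprint)),
      logpc = sprintf("%.6f", report$logpc),
      log_rba = sprintf("%.6f", report$log_rba)
    )
    return(paste(names(kv), kv, sep = "\t"))
  }
  df <- report$ranking
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0) {
    return(c(header, "NI"))
  }
  rows <- apply(df, 1, function(r) paste(
    vapply(r, function(x) {
      if (is.na(x)) "NA"
      else if (is.numeric(x)) sprintf("%.6f", x)
      else as.character(x)
    }, character(1)), collapse = "\t"))
  out <- c(header, unname(rows))
  if (report$ni) out <- c(out, "NI")
  out
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %s [%s]\n", x$receptor, x$receptor_class))
  cat("  fingerprint:",
      paste(sprintf("%s=%.3g", names(x$fingerprint), x$fingerprint),
            collapse = " "), "\n")
  cat(sprintf("  log P_C = %.4f; log RBA = %.3f (RBA %.3g%%)\n",
              x$logpc, x$log_rba, 10^x$log_rba))
  invisible(x)
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("<rank_report> %d poses -> %d clusters, %d candidates%s\n",
              x$n_poses, x$n_clusters, x$n_candidates,
              if (x$ni) " (NI: none survive filters)" else ""))
  if (!x$ni) print(x$ranking[!is.na(x$ranking$rank), ])
  invisible(x)
}
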