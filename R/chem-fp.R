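#' Hashed path-based topological fingerprint
#'
#' Enumerates simple paths of up to `max_path` bonds on the heavy-atom
#' graph, canonicalizes each path string (element symbols joined by bond
#' orders, lexicographic minimum of the two reading directions), and hashes
#' it onto a fixed-width bitset. Deterministic and invariant under atom
#' reordering; used only for molecular similarity, not for scoring.
#'
#' @param mol a `mol_structure`.
#' @param max_path maximum path length in bonds.
#' @param nbits bitset width.
#' @return logical vector of length `nbits` with attribute `nbits`.
#' @export
topo_fingerprint <- function(mol, max_path = 5L, nbits = 1024L) {
  hv <- heavy_idx(mol)
  el <- mol$atoms$element
  bonds <- mol$bonds[mol$bonds$i %in% hv & mol$bonds$j %in% hv, ,
                     drop = FALSE]
  adj <- vector("list", nrow(mol$atoms))
  ordmap <- new.env(parent = emptyenv())
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    assign(paste(min(i, j), max(i, j)), bonds$order[b], envir = ordmap)
  }
  strings <- character()
  walk <- function(path) {
    s <- .path_string(path, el, ordmap)
    strings[[length(strings) + 1L]] <<- s
    if (length(path) > max_path) return()
    tail <- path[length(path)]
    for (nxt in adj[[tail]]) {
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  for (a in hv) walk(a)
  strings <- unique(strings)
  bits <- rep(FALSE, nbits)
  for (s in strings) bits[.string_hash(s, nbits) + 1L] <- TRUE
  attr(bits, "nbits") <- nbits
  bits
}

.path_string <- function(path, el, ordmap) {
  piece <- function(idx) {
    out <- el[idx[1]]
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        key <- paste(min(idx[k - 1], idx[k]), max(idx[k - 1], idx[k]))
        out <- paste0(out, get(key, envir = ordmap), el[idx[k]])
      }
    }
    out
  }
  fwd <- piece(path)
  rev_ <- piece(rev(path))
  if (fwd <= rev_) fwd else rev_
}

.string_hash <- function(s, nbits) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% nbits
  as.integer(h)
}

#' Tanimoto similarity of two bitsets
#'
#' |a AND b| / |a OR b|; defined as 1 when both sets are empty.
#'
#' @param a,b logical vectors of equal width.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint widths differ")
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

#' Select one receptor per His524 class by ligand similarity
#'
#' For each receptor class (closed, moved back, open), picks the library
#' entry whose co-crystallized ligand is most similar (Tanimoto on the
#' topological fingerprint) to the query ligand. Ties break by receptor
#' label; empty classes are skipped with a warning.
#'
#' @param query ligand `mol_structure`.
#' @param library list of entries, each a list with `receptor`
#'   (`complex_structure`), `cocrystal_ligand` (`mol_structure`) and
#'   `receptor_class`.
#' @return named list (class -> chosen entry, with `similarity` added).
#' @export
select_receptors <- function(query, library) {
  qfp <- topo_fingerprint(query)
  classes <- c("closed", "moved_back", "open")
  out <- list()
  for (cls in classes) {
    entries <- Filter(function(e) e$receptor_class == cls, library)
    if (!length(entries)) {
      warning("no receptor library entries of class: ", cls)
      next
    }
    sims <- vapply(entries, function(e) {
      tanimoto(qfp, topo_fingerprint(e$cocrystal_ligand))
    }, numeric(1))
    labels <- vapply(entries, function(e) e$receptor$receptor_label,
                     character(1))
    best <- order(-sims, labels)[1]
    chosen <- entries[[best]]
    chosen$similarity <- sims[best]
    out[[cls]] <- chosen
  }
  out
}

#' Write molecules to an SDF (V2000) file
#'
#' Minimal writer for pose sets and fixtures; one record per molecule.
#'
#' @param mols list of `mol_structure` (or a single one).
#' @param path output file.
#' @param scores optional numeric vector written as a `score` data field.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, scores = NULL) {
  if (inherits(mols, "mol_structure")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
    writeLines(c(mol$name, "  hydroqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
               con)
    for (a in seq_len(n)) {
      writeLines(sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        mol$atoms$x[a], mol$atoms$y[a], mol$atoms$z[a],
        mol$atoms$element[a]), con)
    }
    for (b in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i[b],
                         mol$bonds$j[b], mol$bonds$order[b]), con)
    }
    writeLines("M  END", con)
    if (!is.null(scores)) {
      writeLines(c("> <score>", sprintf("%.4f", scores[k]), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Read ligand structures from an SDF/MOL file
#'
#' Parses all records via ChemmineR; explicit hydrogens are preserved and
#' rings re-perceived from the bond block.
#'
#' @param path SDF or MOL file.
#' @param all return every record as a list even when only one is present.
#' @return a `mol_structure`, or a list of them for multi-record files.
#' @export
read_ligand_sdf <- function(path, all = FALSE) {
  mols <- .read_sdf_models(path)
  if (!length(mols)) stop("no molecules parsed from ", path)
  out <- lapply(mols, function(m) m$mol)
  if (length(out) == 1 && !all) out[[1]] else out
}
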