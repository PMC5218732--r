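#' Default hydrophobic residues of the ERa ligand binding pocket
#'
#' Residues whose van der Waals surfaces define the hydrophobic contact
#' regions integrated into log P_C. Entries are position-specific
#' (name + ERa sequence number); the list is fully configurable and entries
#' may also be bare residue names ("LEU") or bare positions (404).
#'
#' @return character vector of residue identifiers.
#' @export
default_hydrophobic_residues <- function() {
  c("MET343", "LEU346", "LEU349", "ALA350", "LEU384", "LEU387", "MET388",
    "LEU391", "PHE404", "VAL418", "MET421", "ILE424", "LEU428", "LEU525",
    "MET528")
}

.is_hydrophobic <- function(res, residue_list) {
  if (!length(residue_list)) return(FALSE)
  spec <- toupper(as.character(residue_list))
  id <- paste0(toupper(res$res_name), res$seq_num)
  name <- toupper(res$res_name)
  num <- as.character(res$seq_num)
  any(spec == id | spec == name | spec == num)
}

#' Extract the hydrophobic subset of a binding pocket
#'
#' @param cplx a `complex_structure` with a populated pocket.
#' @param residue_list hydrophobic residue specification; each entry is a
#'   name+number identifier ("PHE404"), a bare 3-letter name ("LEU", matches
#'   every leucine), or a bare sequence number (404, matches by position).
#' @return list of `pocket_residue` flagged hydrophobic, ordered stably by
#'   (chain, seq_num). Warns when the intersection is empty (log P_C will
#'   be 0 downstream).
#' @export
extract_hydrophobic_pocket <- function(cplx,
    residue_list = default_hydrophobic_residues()) {
  stopifnot(inherits(cplx, "complex_structure"))
  hits <- Filter(function(res) .is_hydrophobic(res, residue_list),
                 cplx$pocket)
  if (!length(hits)) {
    warning("no hydrophobic residues in pocket; log P_C will be 0")
    return(list())
  }
  ord <- order(vapply(hits, function(r) as.character(r$chain), character(1)),
               vapply(hits, function(r) r$seq_num, integer(1)))
  hits <- hits[ord]
  lapply(hits, function(res) { res$hydrophobic <- TRUE; res })
}
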