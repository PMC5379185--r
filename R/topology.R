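## Topology: per-atom identity, charges, Lennard-Jones parameters and group
## tags. Residue ids always keep the author numbering of the source file
## (Switch I of RhoA stays 28-40), so selections in documentation and
## configuration match the crystallographic numbering.

.group_tags <- c("protein", "water", "nucleotide", "ion", "other")

#' Construct an atom topology
#'
#' @param atom_id integer atom serials, unique and strictly increasing.
#' @param atom_name atom names (PDB convention: "CA", "N", "OW", ...).
#' @param residue_id author residue numbers.
#' @param residue_name three-letter residue names.
#' @param element element symbols; guessed from the atom name when missing.
#' @param charge partial charges (e); NA when energetics are not needed.
#' @param lj_epsilon LJ well depth (kcal/mol); NA allowed as for charge.
#' @param lj_rmin_half LJ Rmin/2 (Angstrom); NA allowed.
#' @param group_tag one of protein, water, nucleotide, ion, other.
#' @return an object of class `swi_topology` (a data frame).
#' @export
topology <- function(atom_id, atom_name, residue_id, residue_name,
                     element = NA_character_, charge = NA_real_,
                     lj_epsilon = NA_real_, lj_rmin_half = NA_real_,
                     group_tag = "protein") {
  n <- length(atom_id)
  atom_id <- as.integer(atom_id)
  if (anyDuplicated(atom_id) || is.unsorted(atom_id, strictly = TRUE)) {
    .stopf("topology: atom_id must be unique and strictly increasing")
  }
  element <- rep_len(as.character(element), n)
  guess <- is.na(element) | element == ""
  element[guess] <- substr(gsub("[^A-Za-z].*$", "", atom_name[guess]), 1, 1)
  group_tag <- rep_len(as.character(group_tag), n)
  bad <- setdiff(unique(group_tag), .group_tags)
  if (length(bad)) .stopf("topology: unknown group tag(s): %s",
                          paste(bad, collapse = ", "))
  top <- data.frame(
    atom_id = atom_id,
    atom_name = as.character(atom_name),
    residue_id = as.integer(residue_id),
    residue_name = as.character(residue_name),
    element = element,
    charge = rep_len(as.numeric(charge), n),
    lj_epsilon = rep_len(as.numeric(lj_epsilon), n),
    lj_rmin_half = rep_len(as.numeric(lj_rmin_half), n),
    group_tag = group_tag,
    stringsAsFactors = FALSE
  )
  class(top) <- c("swi_topology", "data.frame")
  top
}

#' @export
print.swi_topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues, groups: %s\n",
              nrow(x), length(unique(paste(x$residue_id, x$group_tag))),
              paste(sort(unique(x$group_tag)), collapse = "/")))
  invisible(x)
}

#' Read a topology sidecar table
#'
#' CSV with header `atom_id,charge,epsilon,rmin_half,group`, keyed by
#' atom serial. Applied on top of an existing topology.
#'
#' @param top a `swi_topology`.
#' @param path path to the sidecar CSV.
#' @return the topology with charges/LJ/groups filled in.
#' @export
apply_sidecar <- function(top, path) {
  sc <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("atom_id", "charge", "epsilon", "rmin_half", "group")
  miss <- setdiff(need, names(sc))
  if (length(miss)) .stopf("sidecar %s: missing column(s) %s", path,
                           paste(miss, collapse = ", "))
  idx <- match(top$atom_id, sc$atom_id)
  if (anyNA(idx)) {
    .stopf("sidecar %s: atom_id mismatch (first missing serial: %d)",
           path, top$atom_id[which(is.na(idx))[1]])
  }
  top$charge <- sc$charge[idx]
  top$lj_epsilon <- sc$epsilon[idx]
  top$lj_rmin_half <- sc$rmin_half[idx]
  top$group_tag <- sc$group[idx]
  bad <- setdiff(unique(top$group_tag), .group_tags)
  if (length(bad)) .stopf("sidecar %s: unknown group tag(s): %s", path,
                          paste(bad, collapse = ", "))
  top
}

#' Write a topology sidecar table
#' @param top a `swi_topology`.
#' @param path output CSV path.
#' @export
write_sidecar <- function(top, path) {
  out <- data.frame(atom_id = top$atom_id, charge = top$charge,
                    epsilon = top$lj_epsilon, rmin_half = top$lj_rmin_half,
                    group = top$group_tag)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## residue chemistry tables --------------------------------------------------

# chi1 is defined by N-CA-CB-XG with XG depending on residue type; GLY and
# ALA have no chi1.
.chi1_table <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1"
)

# polarity split used for hydration reporting
.nonpolar_residues <- c("ALA", "VAL", "LEU", "ILE", "PHE", "PRO", "MET",
                        "GLY", "TRP")

#' Residue polarity class
#' @param residue_name three-letter residue name(s).
#' @return "nonpolar" or "polar" per residue.
#' @export
residue_polarity <- function(residue_name) {
  ifelse(toupper(residue_name) %in% .nonpolar_residues, "nonpolar", "polar")
}

#' chi1 terminal atom for a residue type
#' @param residue_name three-letter residue name.
#' @return atom name completing the N-CA-CB-? quadruple, or NA if the
#'   residue has no chi1.
#' @export
chi1_atom <- function(residue_name) {
  out <- .chi1_table[toupper(residue_name)]
  unname(out)
}
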