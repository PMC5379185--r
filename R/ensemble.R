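## ConformationalEnsemble: ordered frames of coordinates over one topology.
## Frames are stored as an n_frames x n_atoms x 3 array in Angstrom.

#' Construct a conformational ensemble
#'
#' @param top a [topology()].
#' @param frames coordinates: an `n_frames x n_atoms x 3` array, or a single
#'   `n_atoms x 3` matrix for a one-frame ensemble.
#' @param times optional frame times in ps, strictly increasing.
#' @return an object of class `swi_ensemble`.
#' @export
ensemble <- function(top, frames, times = NULL) {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1L, nrow(frames), ncol(frames)))
  }
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] == 3L)
  if (dim(frames)[2] != nrow(top)) {
    .stopf("ensemble: %d atoms in frames but %d in topology",
           dim(frames)[2], nrow(top))
  }
  if (!all(is.finite(frames))) .stopf("ensemble: non-finite coordinates")
  if (!is.null(times)) {
    if (length(times) != dim(frames)[1] || is.unsorted(times, strictly = TRUE))
      .stopf("ensemble: times must be strictly increasing, one per frame")
  }
  structure(list(topology = top, frames = frames, times = times),
            class = "swi_ensemble")
}

#' @export
print.swi_ensemble <- function(x, ...) {
  cat(sprintf("Conformational ensemble: %d frame(s), %d atoms, %d residues\n",
              n_frames(x), n_atoms(x),
              length(unique(x$topology$residue_id[
                x$topology$group_tag == "protein"]))))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens a `swi_ensemble`.
#' @export
n_frames <- function(ens) dim(ens$frames)[1]

#' Number of atoms in an ensemble
#' @param ens a `swi_ensemble`.
#' @export
n_atoms <- function(ens) dim(ens$frames)[2]

#' Extract one frame as an n_atoms x 3 matrix
#' @param ens a `swi_ensemble`.
#' @param i frame index.
#' @export
get_frame <- function(ens, i) {
  stopifnot(i >= 1, i <= n_frames(ens))
  matrix(ens$frames[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Keep a subset of frames
#' @param ens a `swi_ensemble`.
#' @param idx frame indices to keep.
#' @export
subset_frames <- function(ens, idx) {
  ensemble(ens$topology, ens$frames[idx, , , drop = FALSE],
           times = ens$times[idx])
}

#' Read a structure or ensemble from file
#'
#' Accepts a single- or multi-MODEL PDB file (parsed with bio3d) or a
#' whitespace/comma-delimited coordinate table with a header naming at least
#' `atom_id,atom_name,residue_id,residue_name,x,y,z` and optionally `frame`.
#' Author residue numbering is preserved.
#'
#' @param path input file.
#' @param topology_sidecar optional CSV supplying charges, LJ parameters and
#'   group tags keyed by atom serial (see [apply_sidecar()]).
#' @return a `swi_ensemble` with one frame per MODEL (or per `frame` value).
#' @export
read_structure <- function(path, topology_sidecar = NULL) {
  if (!file.exists(path)) .stopf("read_structure: no such file: %s", path)
  first <- readLines(path, n = 50L)
  is_pdb <- grepl("\\.pdb$", path, ignore.case = TRUE) ||
    any(grepl("^(ATOM  |HETATM|MODEL )", first))
  ens <- if (is_pdb) .read_pdb_ensemble(path) else .read_table_ensemble(path)
  if (!is.null(topology_sidecar)) {
    ens$topology <- apply_sidecar(ens$topology, topology_sidecar)
  }
  ens
}

.read_pdb_ensemble <- function(path) {
  # reject MODELs with differing atom sets up front (a truncated MODEL can
  # otherwise be mis-read as shifted coordinates)
  raw <- readLines(path)
  model_starts <- grep("^MODEL ", raw)
  if (length(model_starts) > 1L) {
    ends <- grep("^ENDMDL", raw)
    if (length(ends) == length(model_starts)) {
      counts <- vapply(seq_along(model_starts), function(i)
        sum(grepl("^(ATOM  |HETATM)",
                  raw[model_starts[i]:ends[i]])), integer(1))
      if (length(unique(counts)) != 1L)
        .stopf("read_structure: %s: MODEL records have inconsistent atom sets",
               path)
    }
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) .stopf("read_structure: malformed PDB %s: %s",
                               path, conditionMessage(e)))
  at <- pdb$atom
  # bio3d pads truncated MODELs with NA coordinates; treat as inconsistency
  if (!all(is.finite(pdb$xyz))) {
    .stopf("read_structure: %s: MODEL records have inconsistent atom sets",
           path)
  }
  nf <- nrow(pdb$xyz)
  na <- nrow(at)
  frames <- array(NA_real_, dim = c(nf, na, 3L))
  for (f in seq_len(nf)) {
    frames[f, , ] <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  water_names <- c("HOH", "SOL", "WAT", "TIP3")
  ion_names <- c("MG", "NA", "CL", "K", "CA2", "ZN", "SOD", "CLA")
  nuc_names <- c("GTP", "GDP", "GNP", "GSP", "ATP", "ADP")
  grp <- ifelse(at$resid %in% water_names, "water",
         ifelse(at$resid %in% ion_names, "ion",
         ifelse(at$resid %in% nuc_names, "nucleotide",
         ifelse(at$type == "ATOM", "protein", "other"))))
  top <- topology(atom_id = at$eleno, atom_name = at$elety,
                  residue_id = at$resno, residue_name = at$resid,
                  element = at$elesy, group_tag = grp)
  ensemble(top, frames)
}

.read_table_ensemble <- function(path) {
  sep <- if (grepl(",", readLines(path, n = 1L))) "," else ""
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("atom_id", "atom_name", "residue_id", "residue_name",
            "x", "y", "z")
  miss <- setdiff(need, names(tab))
  if (length(miss)) .stopf("read_structure: %s lacks column(s) %s", path,
                           paste(miss, collapse = ", "))
  if (is.null(tab$frame)) tab$frame <- 1L
  frames_ids <- sort(unique(tab$frame))
  ref <- tab[tab$frame == frames_ids[1], ]
  ref <- ref[order(ref$atom_id), ]
  na <- nrow(ref)
  arr <- array(NA_real_, dim = c(length(frames_ids), na, 3L))
  for (f in seq_along(frames_ids)) {
    sub <- tab[tab$frame == frames_ids[f], ]
    sub <- sub[order(sub$atom_id), ]
    if (nrow(sub) != na || !all(sub$atom_id == ref$atom_id)) {
      .stopf("read_structure: %s: frame %s has a different atom set",
             path, frames_ids[f])
    }
    arr[f, , ] <- cbind(sub$x, sub$y, sub$z)
  }
  grp <- if (is.null(ref$group)) "protein" else ref$group
  top <- topology(atom_id = ref$atom_id, atom_name = ref$atom_name,
                  residue_id = ref$residue_id, residue_name = ref$residue_name,
                  group_tag = grp)
  ensemble(top, arr)
}

#' Write an ensemble as a multi-MODEL PDB file
#'
#' Standard fixed columns with MODEL/ENDMDL bracketing; coordinates are
#' written at PDB precision (1e-3 Angstrom). Optionally writes the topology
#' sidecar next to it.
#'
#' @param ens a `swi_ensemble`.
#' @param path output PDB path.
#' @param sidecar optional path for the charge/LJ/group sidecar CSV.
#' @return `path`, invisibly.
#' @export
write_structure <- function(ens, path, sidecar = NULL) {
  top <- ens$topology
  hetero <- top$group_tag != "protein"
  record <- ifelse(hetero, "HETATM", "ATOM  ")
  # PDB splits the 4-char atom-name field: element right-padded from col 14
  nm <- ifelse(nchar(top$atom_name) >= 4L, substr(top$atom_name, 1, 4),
               sprintf(" %-3s", top$atom_name))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- get_frame(ens, f)
    writeLines(sprintf(
      "%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, top$atom_id, nm, top$residue_name, "A", top$residue_id,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, top$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(sidecar)) write_sidecar(top, sidecar)
  invisible(path)
}
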