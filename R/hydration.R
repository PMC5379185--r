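## Hydration-shell analysis: waters within a cutoff of each residue,
## averaged over frames with block-averaged standard errors and a
## polar/nonpolar class per residue.

#' Count waters within a cutoff of a residue in one frame
#'
#' A water counts once if its oxygen site lies within `cutoff` of any
#' heavy atom of the residue set (oxygen-only convention; hydrogens of the
#' residue are ignored too when `heavy_only`).
#'
#' @param frame `n_atoms x 3` coordinates of the full system.
#' @param top the matching `swi_topology`.
#' @param residue_atoms atom indices of the focal residue.
#' @param waters atom indices of the water sites considered (defaults to
#'   all water oxygens; any-atom counting is available via
#'   `oxygen_only = FALSE`, which counts a molecule when any of its atoms
#'   is inside).
#' @param cutoff shell radius, Angstrom (default 4).
#' @param oxygen_only judge water presence by the oxygen position only.
#' @param heavy_only measure from residue heavy atoms only.
#' @return non-negative integer count.
#' @export
water_count <- function(frame, top, residue_atoms, waters = NULL,
                        cutoff = 4.0, oxygen_only = TRUE,
                        heavy_only = TRUE) {
  if (is.null(waters)) {
    waters <- which(top$group_tag == "water" &
                      (!oxygen_only | top$element == "O"))
  }
  if (!length(waters)) .stopf("water_count: no atoms tagged water")
  if (cutoff <= 0) return(0L)
  res <- residue_atoms
  if (heavy_only) res <- res[top$element[res] != "H"]
  if (!length(res)) .stopf("water_count: no residue atoms to measure from")
  A <- frame[res, , drop = FALSE]
  B <- frame[waters, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  inside <- colSums(d2 <= cutoff^2) > 0L
  if (oxygen_only) {
    sum(inside)
  } else {
    # count each water molecule (residue_id) once
    length(unique(top$residue_id[waters][inside]))
  }
}

#' Per-residue hydration profile with block-averaged errors
#'
#' Mean water count within `cutoff` of each residue over all frames, with
#' the standard error estimated by block averaging (robust to the serial
#' correlation of consecutive frames) and a polar/nonpolar class from the
#' built-in residue table.
#'
#' @param ens a `swi_ensemble` whose topology tags waters.
#' @param residues author residue ids to profile (default: all protein
#'   residues).
#' @param cutoff shell radius, Angstrom.
#' @param block_len block length in frames; needs >= 2 full blocks.
#' @param oxygen_only,heavy_only see [water_count()].
#' @return data frame `residue, residue_name, mean_waters, se, class`
#'   (class `swi_hydration`).
#' @export
hydration_profile <- function(ens, residues = NULL, cutoff = 4.0,
                              block_len = 100L, oxygen_only = TRUE,
                              heavy_only = TRUE) {
  top <- ens$topology
  if (is.null(residues)) {
    residues <- sort(unique(top$residue_id[top$group_tag == "protein"]))
  }
  nf <- n_frames(ens)
  if (nf < 2L * block_len)
    .stopf("hydration_profile: %d frames < 2 blocks of %d", nf, block_len)
  waters <- which(top$group_tag == "water" &
                    (!oxygen_only | top$element == "O"))
  if (!length(waters)) .stopf("hydration_profile: no atoms tagged water")
  rows <- lapply(residues, function(rid) {
    ra <- which(top$group_tag == "protein" & top$residue_id == rid)
    counts <- vapply(seq_len(nf), function(f)
      water_count(get_frame(ens, f), top, ra, waters, cutoff,
                  oxygen_only, heavy_only), numeric(1))
    rn <- top$residue_name[ra[1]]
    data.frame(residue = rid, residue_name = rn,
               mean_waters = mean(counts),
               se = if (sd(counts) == 0) 0 else block_se(counts, block_len),
               class = residue_polarity(rn), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "se_method") <- sprintf("block averaging, block_len = %d frames",
                                    block_len)
  class(out) <- c("swi_hydration", "data.frame")
  out
}

#' @export
print.swi_hydration <- function(x, ...) {
  cat(sprintf("Hydration profile (%s):\n", attr(x, "se_method")))
  print.data.frame(x, digits = 3)
  invisible(x)
}
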