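## Atom selection mini-grammar: conjunctions of clauses joined by "and".
## Clauses:
##   resid A-B | resid A [B C ...]   author residue numbers (ranges allowed)
##   name X [Y ...]                  atom names
##   group G [H ...]                 topology group tags
## Example: "resid 28-40 and name CA"

#' Select atoms by a selection expression
#'
#' @param ens a `swi_ensemble`.
#' @param spec selection string, e.g. `"resid 28-40 and name CA"`.
#' @return sorted integer vector of (1-based) atom indices; may be empty.
#' @export
select_atoms <- function(ens, spec) {
  top <- ens$topology
  keep <- rep(TRUE, nrow(top))
  clauses <- strsplit(spec, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "[,[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) next
    kw <- toks[1]
    args <- toks[-1]
    if (!length(args)) .stopf("select_atoms: clause '%s' has no arguments", cl)
    keep <- keep & switch(kw,
      resid = {
        ids <- integer(0)
        for (a in args) {
          if (grepl("^-?[0-9]+--?[0-9]+$", a)) {
            m <- regmatches(a, regexec("^(-?[0-9]+)-(-?[0-9]+)$", a))[[1]]
            ids <- c(ids, seq.int(as.integer(m[2]), as.integer(m[3])))
          } else if (grepl("^-?[0-9]+$", a)) {
            ids <- c(ids, as.integer(a))
          } else .stopf("select_atoms: bad residue token '%s' in '%s'", a, cl)
        }
        top$residue_id %in% ids
      },
      name = top$atom_name %in% args,
      group = {
        bad <- setdiff(args, .group_tags)
        if (length(bad)) .stopf("select_atoms: unknown group '%s'", bad[1])
        top$group_tag %in% args
      },
      .stopf("select_atoms: unknown keyword '%s' in '%s'", kw, cl)
    )
  }
  sort(which(keep))
}
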