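# Canonical-sequence export, FASTA output, and reference-sequence QC.

#' Canonical IUPAC/IUBMB sequence of a polymer
#'
#' Each residue maps to the concatenation of its base-monomer codes (a
#' phosphoserine maps to `S`); a residue with no recorded base monomers
#' (e.g. a 5' cap of unknown parentage) maps to the alphabet's unknown
#' code (`N` for DNA/RNA, `X` for protein). Plain descriptions over
#' canonical codes round-trip: `canonicalSequence(parsePolymer(s, a))`
#' equals `s`.
#'
#' @param p a [Polymer-class]
#' @return single character string
#' @examples
#' canonicalSequence(parsePolymer("A{pS}D", "protein"))  # "ASD"
#' @export
canonicalSequence <- function(p) {
  stopifnot(is(p, "Polymer"))
  unk <- unknownCode(p@alphabet)
  paste(vapply(p@occurrences, function(occ) {
    bm <- occ$residue@baseMonomers
    if (length(bm) == 0L) unk else paste(bm, collapse = "")
  }, ""), collapse = "")
}

#' Export canonical sequences of polymers to a FASTA file
#'
#' One record per polymer, 80-column wrapping.
#'
#' @param polymers a list of [Polymer-class] objects; record ids are taken
#'   from the list names (falling back to `polymer_<i>`)
#' @param path output file path
#' @return invisibly, `path`
#' @export
exportFasta <- function(polymers, path) {
  if (is(polymers, "Polymer")) polymers <- list(polymers)
  ids <- names(polymers)
  if (is.null(ids)) ids <- rep("", length(polymers))
  blank <- !nzchar(ids)
  ids[blank] <- sprintf("polymer_%d", which(blank))
  seqs <- vapply(polymers, canonicalSequence, "")
  set <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Check a polymer against a reference canonical sequence
#'
#' Quality control in the style used to audit proteoform registries:
#' residue i of the polymer is compared with character `i + offset` of the
#' reference. A residue whose base monomers exclude the reference
#' character is an error (e.g. a phosphoserine annotated at the position
#' of a tyrosine); a residue with no recorded base monomers is a wildcard
#' and only warns. `offset` reconciles coordinate systems that count from
#' the translated sequence rather than from the processed protein: with
#' `offset = 1` the polymer positions are interpreted relative to a
#' reference that still carries its initiator methionine.
#'
#' Rule ids: Q1 length mismatch, Q2 residue/reference mismatch,
#' Q3 (warning) wildcard residue skipped.
#'
#' @param p a [Polymer-class]
#' @param ref reference sequence over canonical codes (single string)
#' @param offset integer coordinate shift (reference index minus polymer
#'   position), default 0
#' @return a [ValidationReport-class]
#' @export
checkAgainstReference <- function(p, ref, offset = 0L) {
  stopifnot(is(p, "Polymer"), is.character(ref), length(ref) == 1L)
  offset <- as.integer(offset)
  out <- list()
  n <- length(p)
  if (nchar(ref) != n + offset)
    out[[length(out) + 1L]] <- finding("error", "Q1", "sequence",
      sprintf("polymer length %d plus offset %d does not match reference length %d",
        n, offset, nchar(ref)))
  for (i in seq_len(min(n, max(0L, nchar(ref) - offset)))) {
    bm <- p@occurrences[[i]]$residue@baseMonomers
    refch <- substr(ref, i + offset, i + offset)
    if (length(bm) == 0L) {
      out[[length(out) + 1L]] <- finding("warning", "Q3",
        sprintf("residue %d", i),
        sprintf("residue %s has no recorded base monomers; treated as a wildcard against reference %s",
          p@occurrences[[i]]$code, refch))
    } else if (!refch %in% bm) {
      out[[length(out) + 1L]] <- finding("error", "Q2",
        sprintf("residue %d", i),
        sprintf("residue %s derives from %s but the reference has %s at this position",
          p@occurrences[[i]]$code, paste(bm, collapse = "/"), refch))
    }
  }
  validationReport(if (length(out)) do.call(rbind, out) else NULL)
}
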