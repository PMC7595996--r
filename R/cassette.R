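# sgRNA cassette construction: hammerhead-ribozyme-flanked inserts and
# annealed-oligo pairs for restriction-site cloning

#' Default hammerhead catalytic core
#'
#' Catalytic core of the hammerhead ribozyme used in the
#' hammerhead--sgRNA--HDV cassette scheme for Pol II-expressed guides: the
#' full 5' ribozyme is the reverse complement of the spacer's first six bases
#' (closing the ribozyme's stem I against the spacer) followed by this core.
#' Users cloning into a different backbone should supply their own core and
#' overhangs; this constant is data, not logic.
#' @export
DEFAULT_HAMMERHEAD_CORE <- "CTGATGAGTCCGTGAGGACGAAACGAGTAAGCTCGTC"

#' Default HDV ribozyme sequence
#'
#' The hepatitis delta virus ribozyme that releases the sgRNA 3' end. In the
#' default cassette split this element (and the tracrRNA scaffold) resides on
#' the destination plasmid, directly downstream of the restriction site the
#' annealed oligos are cloned into, so it is not part of the insert.
#' @export
DEFAULT_HDV_RIBOZYME <- paste0(
  "GGCCGGCATGGTCCCAGCCTCCTCGCTGGCGCCGGCTGGGCAACATGCTTCGGCATGGCGAATGGGAC")

#' Build a spacer-matched hammerhead ribozyme
#'
#' The hammerhead ribozyme preceding the spacer must base-pair with the
#' spacer's 5' end to fold correctly: its first six bases are the reverse
#' complement of the spacer's first six bases, followed by the fixed
#' catalytic core.
#'
#' @param spacer 20-nt spacer, unambiguous A/C/G/T.
#' @param core Catalytic core sequence (default
#'   [DEFAULT_HAMMERHEAD_CORE]).
#' @return The hammerhead ribozyme sequence (character).
#' @examples
#' substr(buildHammerhead("GATTCAGGTACCGGTAGGTC"), 1, 6)  # "TGAATC"
#' @export
buildHammerhead <- function(spacer, core = DEFAULT_HAMMERHEAD_CORE) {
  if (!grepl("^[ACGT]+$", spacer))
    stop("spacer contains ambiguous bases; unsuitable for ribozyme cassette design")
  paste0(revComp(substr(spacer, 1L, 6L)), core)
}

#' Emit annealed-oligo pair for cassette insertion
#'
#' Builds the double-stranded insert (hammerhead ribozyme + spacer; the HDV
#' ribozyme and tracrRNA scaffold live on the destination plasmid) and the
#' two single-stranded oligos whose annealing reconstructs it, each carrying
#' a configurable 5' single-stranded overhang matching the linearised vector
#' ends. The default overhangs are empty placeholders: the exact overhangs
#' depend on the destination backbone and must be confirmed by the user
#' (declare `scheme = "Eco91I"` to enforce the 5-nt 5' overhangs that enzyme
#' leaves).
#'
#' @param spacer 20-nt spacer, unambiguous A/C/G/T.
#' @param fwdOverhang,revOverhang 5' single-stranded overhangs for the
#'   forward and reverse oligo (default `""`).
#' @param core Hammerhead catalytic core (default
#'   [DEFAULT_HAMMERHEAD_CORE]).
#' @param scheme Optional restriction scheme name; `"Eco91I"` requires both
#'   overhangs to be 5 nt (G^GTNACC leaves 5-nt 5' overhangs).
#' @return A list of class `CassetteInsert`: `spacer`, `hammerhead`,
#'   `insert`, `forward_oligo`, `reverse_oligo`, `fwd_overhang`,
#'   `rev_overhang`.
#' @export
emitOligos <- function(spacer, fwdOverhang = "", revOverhang = "",
                       core = DEFAULT_HAMMERHEAD_CORE, scheme = NULL) {
  hh <- buildHammerhead(spacer, core)
  if (!is.null(scheme)) {
    if (scheme == "Eco91I") {
      if (nchar(fwdOverhang) != 5L || nchar(revOverhang) != 5L)
        stop("Eco91I cloning requires 5-nt single-stranded overhangs")
    } else stop("unknown restriction scheme: ", scheme)
  }
  insert <- paste0(hh, spacer)
  structure(list(
    spacer = spacer, hammerhead = hh, insert = insert,
    forward_oligo = paste0(fwdOverhang, insert),
    reverse_oligo = paste0(revOverhang, revComp(insert)),
    fwd_overhang = fwdOverhang, rev_overhang = revOverhang),
    class = "CassetteInsert")
}

#' @export
print.CassetteInsert <- function(x, ...) {
  cat("CassetteInsert\n",
      " spacer:  ", x$spacer, "\n",
      " insert:  ", x$insert, " (", nchar(x$insert), " nt)\n",
      " forward: ", x$forward_oligo, "\n",
      " reverse: ", x$reverse_oligo, "\n", sep = "")
  invisible(x)
}

#' Write an oligo order sheet and insert FASTA
#'
#' `writeOligoSheet()` writes one row per guide (name, forward and reverse
#' oligo, lengths) as TSV; `writeInsertFasta()` writes the double-stranded
#' insert sequences as FASTA.
#'
#' @param spacers Character vector of spacers (named; unnamed spacers are
#'   auto-named `sg1..sgN`).
#' @param path Output path.
#' @param ... Passed to [emitOligos()] (overhangs, core, scheme).
#' @return `path`, invisibly.
#' @export
writeOligoSheet <- function(spacers, path, ...) {
  if (is.null(names(spacers)) || any(!nzchar(names(spacers))))
    names(spacers) <- sprintf("sg%d", seq_along(spacers))
  ins <- lapply(spacers, emitOligos, ...)
  df <- data.frame(
    name = names(spacers),
    forward_oligo = vapply(ins, `[[`, "", "forward_oligo"),
    reverse_oligo = vapply(ins, `[[`, "", "reverse_oligo"),
    forward_length = vapply(ins, function(i) nchar(i$forward_oligo), 0L),
    reverse_length = vapply(ins, function(i) nchar(i$reverse_oligo), 0L),
    stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' @rdname writeOligoSheet
#' @export
writeInsertFasta <- function(spacers, path, ...) {
  if (is.null(names(spacers)) || any(!nzchar(names(spacers))))
    names(spacers) <- sprintf("sg%d", seq_along(spacers))
  ins <- vapply(lapply(spacers, emitOligos, ...), `[[`, "", "insert")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(ins, names(spacers))), path)
  invisible(path)
}
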