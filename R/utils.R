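# shared helpers: sequence utilities and coordinate conversion

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA strings (A/C/G/T/N and IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# chromosome length lookup for a Genome (named DNAStringSet)
.chromLength <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("unknown chromosome '", chrom, "'")
  Biostrings::width(genome)[match(chrom, names(genome))]
}

# 1-based inclusive GRanges -> 0-based half-open BED columns
.toBed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# deterministic TSV writer (fixed eol, no quoting surprises)
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# write a BED6 file by hand so column layout and number formatting are
# byte-stable across runs (rtracklayer is used for parsing-heavy formats)
.writeBed6 <- function(gr, path, name, score) {
  bed <- .toBed(gr)
  bed$name <- name
  bed$score <- score
  bed$strand <- as.character(GenomicRanges::strand(gr))
  bed$strand[bed$strand == "*"] <- "."
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

.assertScalarNum <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop("'", name, "' must be a single number >= ", min)
  invisible(x)
}
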