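# protospacer enumeration (NGG PAM, both strands) and exhaustive
# Hamming-distance off-target vetting over PAM-adjacent loci

.IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                  H = "[ACT]", V = "[ACG]", N = "[ACGT]")

.iupacRegex <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1L]]
  if (any(!ch %in% names(.IUPAC_CLASS)))
    stop("invalid IUPAC pattern: ", pattern)
  paste0(.IUPAC_CLASS[ch], collapse = "")
}

# overlapping match start positions of an IUPAC pattern in a DNA string
.patternStarts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", .iupacRegex(pattern), ")"), seq, perl = TRUE)[[1L]]
  if (length(m) == 1L && m[1L] == -1L) integer() else as.integer(m)
}

# Hamming distances of many equal-length strings against one reference
.hammingMany <- function(strings, ref) {
  if (!length(strings)) return(integer())
  L <- nchar(ref)
  mat <- matrix(charToRaw(paste(strings, collapse = "")), nrow = L)
  as.integer(colSums(mat != charToRaw(ref)))
}

#' Enumerate protospacer sites in a promoter region
#'
#' Scans both strands of `region` for every position where a `spacerLen`-mer
#' is immediately followed (in sgRNA orientation) by a PAM matching
#' `pamPattern` (default `NGG`, the *S. pyogenes* Cas9 motif). Spacers
#' containing `N` are excluded. The full spacer-plus-PAM must lie inside the
#' region.
#'
#' @param region A `GRanges` of length 1 (e.g. from [promoterRegion()] or
#'   [detectBidirectional()]).
#' @param genome Genome from [loadGenome()].
#' @param spacerLen Spacer length in nt (>= 16; default 20).
#' @param pamPattern IUPAC PAM pattern in sgRNA orientation (default `"NGG"`).
#' @return A `GRanges` over the genomic spacer intervals (strand-resolved)
#'   with metadata columns `spacer` (5'->3' in sgRNA orientation), `pam`
#'   (sgRNA orientation), `pam_start`, `pam_end` (1-based genomic). Sorted by
#'   genomic position, `+` before `-` at equal positions. On the `+` strand
#'   the genome substring at the spacer interval equals the spacer and the
#'   PAM is 3'-adjacent; on `-` it equals the spacer's reverse complement and
#'   the PAM interval is 5'-adjacent in genome coordinates.
#' @export
scanProtospacers <- function(region, genome, spacerLen = 20L,
                             pamPattern = "NGG") {
  stopifnot(length(region) == 1L)
  if (spacerLen < 16L) stop("'spacerLen' must be >= 16")
  chrom <- as.character(GenomicRanges::seqnames(region))
  rs <- GenomicRanges::start(region)
  re <- GenomicRanges::end(region)
  pamLen <- nchar(pamPattern)
  empty <- GenomicRanges::GRanges(
    spacer = character(), pam = character(),
    pam_start = integer(), pam_end = integer())
  if (re - rs + 1L < spacerLen + pamLen) {
    warning("region shorter than spacer + PAM; no sites")
    return(empty)
  }
  seq <- as.character(Biostrings::subseq(genome[[chrom]], rs, re))
  w <- nchar(seq)
  rows <- list()
  # + strand: PAM directly 3' of the spacer
  for (p in .patternStarts(seq, pamPattern)) {
    if (p - spacerLen < 1L || p + pamLen - 1L > w) next
    spacer <- substr(seq, p - spacerLen, p - 1L)
    if (grepl("N", spacer, fixed = TRUE)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = rs + p - spacerLen - 1L, strand = "+", spacer = spacer,
      pam = substr(seq, p, p + pamLen - 1L),
      pam_start = rs + p - 1L, pam_end = rs + p + pamLen - 2L)
  }
  # - strand: reverse-complement PAM directly 5' of the spacer in genome coords
  for (p in .patternStarts(seq, revComp(pamPattern))) {
    if (p + pamLen + spacerLen - 1L > w) next
    fwd <- substr(seq, p + pamLen, p + pamLen + spacerLen - 1L)
    if (grepl("N", fwd, fixed = TRUE)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = rs + p + pamLen - 1L, strand = "-", spacer = revComp(fwd),
      pam = revComp(substr(seq, p, p + pamLen - 1L)),
      pam_start = rs + p - 1L, pam_end = rs + p + pamLen - 2L)
  }
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(df$start, width = spacerLen), strand = df$strand,
    spacer = df$spacer, pam = df$pam,
    pam_start = as.integer(df$pam_start), pam_end = as.integer(df$pam_end))
}

# all PAM-adjacent candidate protospacers of one chromosome, both strands:
# returns start (genomic, of the spacer interval), strand and spacer string in
# sgRNA orientation (minus-strand spacers left as forward substrings; the
# caller compares them against the reverse-complemented reference instead,
# which gives identical Hamming distances without reversing every candidate)
.pamAdjacentKmers <- function(seq, spacerLen, pamPattern, requirePam) {
  w <- nchar(seq)
  pamLen <- nchar(pamPattern)
  if (requirePam) {
    pPlus <- .patternStarts(seq, pamPattern)
    pPlus <- pPlus[pPlus - spacerLen >= 1L & pPlus + pamLen - 1L <= w]
    sPlus <- pPlus - spacerLen
    pMinus <- .patternStarts(seq, revComp(pamPattern))
    pMinus <- pMinus[pMinus + pamLen + spacerLen - 1L <= w]
    sMinus <- pMinus + pamLen
  } else {
    sPlus <- seq_len(max(0L, w - spacerLen + 1L))
    sMinus <- sPlus
  }
  list(
    plus = list(start = sPlus,
                kmer = substring(seq, sPlus, sPlus + spacerLen - 1L)),
    minus = list(start = sMinus,
                 kmer = substring(seq, sMinus, sMinus + spacerLen - 1L)))
}

#' Count genome-wide off-targets of a protospacer site
#'
#' Exhaustive mismatch enumeration: for every genomic position on either
#' strand where (if `requirePam`) a PAM-pattern match is adjacent in the
#' proper orientation, the Hamming distance between the site's spacer and the
#' candidate protospacer is computed, and candidates within `maxMismatches`
#' are tallied by distance. The on-target locus itself (identical coordinates
#' and strand) is excluded. Insertions/deletions (bulges) are not modelled.
#'
#' @param site A single site from [scanProtospacers()] (`GRanges` row).
#' @param genome Genome from [loadGenome()].
#' @param maxMismatches Highest mismatch tier tallied (default 3; must not
#'   exceed the spacer length).
#' @param requirePam Only count PAM-adjacent loci (default `TRUE`).
#' @param pamPattern IUPAC PAM pattern (default `"NGG"`).
#' @param maxExamples Number of example hits reported at the lowest non-empty
#'   tier (default 10).
#' @return A list with elements `counts` (named integer vector, tiers
#'   `0..maxMismatches`, on-target excluded) and `examples` (`data.frame`
#'   with `chrom`, `start` (1-based spacer-interval start), `strand`,
#'   `mismatches`).
#' @export
countOfftargets <- function(site, genome, maxMismatches = 3L,
                            requirePam = TRUE, pamPattern = "NGG",
                            maxExamples = 10L) {
  stopifnot(length(site) == 1L)
  spacer <- site$spacer
  L <- nchar(spacer)
  if (maxMismatches > L)
    stop("'maxMismatches' must not exceed the spacer length")
  spacerRc <- revComp(spacer)
  siteChrom <- as.character(GenomicRanges::seqnames(site))
  siteStart <- GenomicRanges::start(site)
  siteStrand <- as.character(GenomicRanges::strand(site))
  counts <- stats::setNames(integer(maxMismatches + 1L),
                            as.character(0:maxMismatches))
  ex <- list()
  for (chrom in names(genome)) {
    seq <- as.character(genome[[chrom]])
    cand <- .pamAdjacentKmers(seq, L, pamPattern, requirePam)
    for (str in c("+", "-")) {
      cc <- if (str == "+") cand$plus else cand$minus
      ref <- if (str == "+") spacer else spacerRc
      d <- .hammingMany(cc$kmer, ref)
      onTarget <- chrom == siteChrom & str == siteStrand & cc$start == siteStart
      keep <- d <= maxMismatches & !onTarget
      if (!any(keep)) next
      counts <- counts + tabulate(d[keep] + 1L, nbins = maxMismatches + 1L)
      ex[[length(ex) + 1L]] <- data.frame(
        chrom = chrom, start = cc$start[keep], strand = str,
        mismatches = d[keep], stringsAsFactors = FALSE)
    }
  }
  examples <- data.frame(chrom = character(), start = integer(),
                         strand = character(), mismatches = integer(),
                         stringsAsFactors = FALSE)
  if (length(ex)) {
    all <- do.call(rbind, ex)
    low <- min(all$mismatches)
    all <- all[all$mismatches == low, , drop = FALSE]
    all <- all[order(all$chrom, all$start, all$strand), , drop = FALSE]
    examples <- utils::head(all, maxExamples)
  }
  list(counts = counts, examples = examples)
}

#' Off-target reports for a set of sites
#'
#' Vectorised convenience over [countOfftargets()].
#'
#' @inheritParams countOfftargets
#' @param sites Sites `GRanges` from [scanProtospacers()].
#' @return A list of per-site reports (see [countOfftargets()]).
#' @export
countOfftargetsAll <- function(sites, genome, maxMismatches = 3L,
                               requirePam = TRUE, pamPattern = "NGG") {
  lapply(seq_along(sites), function(i)
    countOfftargets(sites[i], genome, maxMismatches = maxMismatches,
                    requirePam = requirePam, pamPattern = pamPattern))
}

#' Filter candidate sites by off-target ceilings
#'
#' Retains sites whose per-tier off-target counts are at or below the given
#' ceilings. The defaults (no exact-match and no one-mismatch off-targets;
#' two-mismatch hits reported but not filtered) implement a conservative
#' "least possible off-targets" policy.
#'
#' @param sites Sites `GRanges` from [scanProtospacers()].
#' @param reports Aligned list of reports from [countOfftargetsAll()].
#' @param maxTier0,maxTier1,maxTier2 Per-tier ceilings (defaults 0, 0, Inf).
#' @return The retained subset of `sites`, input order preserved.
#' @export
filterCandidates <- function(sites, reports, maxTier0 = 0L, maxTier1 = 0L,
                             maxTier2 = Inf) {
  stopifnot(length(sites) == length(reports))
  keep <- vapply(reports, function(r) {
    cnt <- r$counts
    t0 <- if ("0" %in% names(cnt)) cnt[["0"]] else 0L
    t1 <- if ("1" %in% names(cnt)) cnt[["1"]] else 0L
    t2 <- if ("2" %in% names(cnt)) cnt[["2"]] else 0L
    t0 <= maxTier0 && t1 <= maxTier1 && t2 <= maxTier2
  }, logical(1))
  sites[keep]
}

#' Write / read a candidate table
#'
#' The candidate TSV carries 0-based half-open spacer coordinates, strand,
#' spacer and PAM sequences and the per-tier off-target counts.
#'
#' @param sites Sites `GRanges` from [scanProtospacers()].
#' @param reports Aligned list of reports from [countOfftargetsAll()].
#' @param path Output / input TSV path.
#' @return `writeCandidates()` returns `path` invisibly; `readCandidates()`
#'   returns a sites `GRanges` with `mm0..mmK` columns added to its metadata.
#' @export
writeCandidates <- function(sites, reports, path) {
  stopifnot(length(sites) == length(reports))
  bed <- .toBed(sites)
  df <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                   strand = as.character(GenomicRanges::strand(sites)),
                   spacer = sites$spacer, pam = sites$pam,
                   pam_start = sites$pam_start - 1L, pam_end = sites$pam_end,
                   stringsAsFactors = FALSE)
  if (length(reports)) {
    cnts <- do.call(rbind, lapply(reports, function(r) r$counts))
    colnames(cnts) <- paste0("mm", colnames(cnts))
    df <- cbind(df, as.data.frame(cnts))
  }
  .writeTsv(df, path)
}

#' @rdname writeCandidates
#' @export
readCandidates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  keep <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  md <- df[keep]
  md$pam_start <- md$pam_start + 1L
  S4Vectors::mcols(gr) <- md
  gr
}
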