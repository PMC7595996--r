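# dyad-axis calling (profile peak maxima) and nucleosome-free-region
# delineation by a fixed dyad offset

# local maxima of a numeric vector with plateau handling: the leftmost base of
# a maximal plateau is the peak position. Returns positions (1-based), heights
# and topographic prominences (height minus the higher of the two bounding
# minima; the scan on each side stops at the first strictly higher value or
# the chromosome end).
.localMaxima <- function(x) {
  r <- rle(x)
  nr <- length(r$lengths)
  if (nr < 2L) return(data.frame(pos = integer(), height = numeric(),
                                 prominence = numeric()))
  runStart <- cumsum(c(1L, r$lengths[-nr]))
  isMax <- vapply(seq_len(nr), function(j) {
    leftLower <- j == 1L || r$values[j - 1L] < r$values[j]
    rightLower <- j == nr || r$values[j + 1L] < r$values[j]
    leftLower && rightLower
  }, logical(1))
  idx <- which(isMax)
  if (!length(idx)) return(data.frame(pos = integer(), height = numeric(),
                                      prominence = numeric()))
  prom <- vapply(idx, function(j) {
    h <- r$values[j]
    sideMin <- function(js) {
      m <- Inf
      for (jj in js) {
        if (r$values[jj] > h) break
        m <- min(m, r$values[jj])
      }
      m
    }
    lm <- if (j > 1L) sideMin((j - 1L):1L) else -Inf   # open chromosome end
    rm_ <- if (j < nr) sideMin((j + 1L):nr) else -Inf
    h - max(lm, rm_)
  }, numeric(1))
  data.frame(pos = runStart[idx], height = r$values[idx], prominence = prom)
}

#' Call nucleosome dyad axes from an occupancy profile
#'
#' Dyad axes are operationalised as the peak maxima of the (smoothed)
#' occupancy profile. All local maxima (leftmost base of a maximal plateau)
#' are enumerated, maxima whose topographic prominence falls below
#' `minProminenceFraction` of the profile maximum are discarded as noise, and
#' the remainder are retained greedily in descending height order subject to a
#' minimum mutual separation. An all-zero profile yields an empty call set.
#'
#' @param profile An [OccupancyProfile-class], ideally smoothed
#'   ([smoothProfile()]).
#' @param minSeparation Minimum distance between retained dyads in bp
#'   (default 120, below the nucleosome repeat length but above the smoothing
#'   scale).
#' @param minProminenceFraction Minimum prominence as a fraction of the
#'   profile maximum (default 0.05).
#' @return A width-1 [GenomicRanges::GRanges] of dyad positions, sorted by
#'   position, with metadata columns `height` and `prominence`.
#' @export
callDyads <- function(profile, minSeparation = 120L,
                      minProminenceFraction = 0.05) {
  .assertScalarNum(minSeparation, "minSeparation", 1)
  .assertScalarNum(minProminenceFraction, "minProminenceFraction", 0)
  x <- profileValues(profile)
  cand <- .localMaxima(x)
  if (nrow(cand)) {
    cand <- cand[cand$prominence >= minProminenceFraction * max(x), ,
                 drop = FALSE]
  }
  kept <- integer()
  if (nrow(cand)) {
    ord <- order(-cand$height, cand$pos)
    for (i in ord) {
      if (!length(kept) || all(abs(cand$pos[kept] - cand$pos[i]) >= minSeparation))
        kept <- c(kept, i)
    }
    kept <- kept[order(cand$pos[kept])]
  }
  GenomicRanges::GRanges(
    rep(profileChrom(profile), length(kept)),
    IRanges::IRanges(cand$pos[kept], width = 1L),
    height = cand$height[kept], prominence = cand$prominence[kept])
}

#' Delineate nucleosome-free regions between adjacent dyads
#'
#' For each consecutive dyad pair the candidate NFR is the interval left after
#' removing `offset` bp on each side of the pair (default 75 bp, the offset
#' from the adjacent dyad axis that defines the nucleosomal borders). In the
#' emitted BED (0-based half-open) coordinates both region borders are exactly
#' `offset` bp from their adjacent dyad axis and the region width equals the
#' dyad separation minus `2 * offset`. Candidates narrower than `minWidth` are
#' suppressed, and no region is called outside the outermost dyads (the rule
#' requires a dyad on both sides).
#'
#' @param dyads Width-1 dyad `GRanges` from [callDyads()], position-sorted,
#'   one chromosome.
#' @param offset Border offset from the dyad axis in bp (default 75).
#' @param minWidth Minimum region width in bp (default 20, admitting the
#'   ~50 bp promoter NFRs seen in compact fungal genomes while rejecting
#'   degenerate gaps).
#' @param condition Free-text condition label (e.g. `"15h"`, `"48h"`).
#' @return `GRanges` of NFRs with metadata columns `left_dyad`, `right_dyad`
#'   (1-based dyad positions) and `condition`.
#' @export
delineateNfrs <- function(dyads, offset = 75L, minWidth = 20L, condition = "") {
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0)
    stop("'offset' must be a single number >= 0")
  if (!is.numeric(minWidth) || length(minWidth) != 1L || minWidth < 1)
    stop("'minWidth' must be a single number >= 1")
  if (length(dyads) < 2L)
    return(GenomicRanges::GRanges(left_dyad = integer(), right_dyad = integer(),
                                  condition = character()))
  pos <- GenomicRanges::start(dyads)
  if (is.unsorted(pos)) stop("dyads must be sorted by position")
  chrom <- as.character(GenomicRanges::seqnames(dyads))[1L]
  p1 <- pos[-length(pos)]
  p2 <- pos[-1L]
  w <- p2 - p1 - 2L * offset
  keep <- w >= minWidth
  GenomicRanges::GRanges(
    rep(chrom, sum(keep)),
    IRanges::IRanges(start = p1[keep] + offset, width = w[keep]),
    left_dyad = p1[keep], right_dyad = p2[keep],
    condition = rep(condition, sum(keep)))
}

#' Compare NFR calls between two conditions
#'
#' Labels each nucleosome-free region as *shared* (it has a 1-to-1 partner in
#' the other condition with reciprocal overlap at or above the threshold) or
#' *condition-specific*. Pairing is greedy by greatest overlap, ties broken by
#' the leftmost partner.
#'
#' @param nfrsA,nfrsB NFR `GRanges` from [delineateNfrs()] for the two
#'   conditions (same genome).
#' @param minReciprocalOverlap Minimum fraction of *each* region covered by
#'   the intersection (default 0.5).
#' @return A `data.frame` with one row per NFR: `condition` (`"A"`/`"B"` or
#'   the region's own condition label when set), `chrom`, `start`, `end`
#'   (0-based half-open), `width`, `status` (`"shared"` /
#'   `"condition-specific"`) and `partner` (row index of the partner within
#'   the other condition, `NA` if none).
#' @export
compareConditions <- function(nfrsA, nfrsB, minReciprocalOverlap = 0.5) {
  .assertScalarNum(minReciprocalOverlap, "minReciprocalOverlap", 0)
  hit <- GenomicRanges::findOverlaps(nfrsA, nfrsB)
  qi <- S4Vectors::queryHits(hit)
  si <- S4Vectors::subjectHits(hit)
  ov <- GenomicRanges::width(IRanges::pintersect(nfrsA[qi], nfrsB[si]))
  recip <- pmin(ov / GenomicRanges::width(nfrsA)[qi],
                ov / GenomicRanges::width(nfrsB)[si])
  ok <- recip >= minReciprocalOverlap
  qi <- qi[ok]; si <- si[ok]; ov <- ov[ok]
  partnerA <- rep(NA_integer_, length(nfrsA))
  partnerB <- rep(NA_integer_, length(nfrsB))
  if (length(qi)) {
    ord <- order(-ov, GenomicRanges::start(nfrsB)[si], GenomicRanges::start(nfrsA)[qi])
    for (k in ord) {
      if (is.na(partnerA[qi[k]]) && is.na(partnerB[si[k]])) {
        partnerA[qi[k]] <- si[k]
        partnerB[si[k]] <- qi[k]
      }
    }
  }
  lab <- function(gr, default) {
    cl <- S4Vectors::mcols(gr)$condition
    if (is.null(cl) || !length(cl) || all(!nzchar(cl))) rep(default, length(gr))
    else cl
  }
  row <- function(gr, partner, default) {
    bed <- .toBed(gr)
    data.frame(condition = lab(gr, default), chrom = bed$chrom,
               start = bed$start, end = bed$end,
               width = GenomicRanges::width(gr),
               status = ifelse(is.na(partner), "condition-specific", "shared"),
               partner = partner, stringsAsFactors = FALSE)
  }
  rbind(row(nfrsA, partnerA, "A"), row(nfrsB, partnerB, "B"))
}

#' Write dyad calls / NFRs as BED6
#'
#' `writeDyadsBed()` writes dyad calls with the prominence in the score
#' column; `writeNfrsBed()` writes NFRs with the condition label in the name
#' field. Coordinates are 0-based half-open per the BED convention, so every
#' NFR border is exactly `offset` bp from its dyad axis.
#'
#' @param dyads,nfrs `GRanges` from [callDyads()] / [delineateNfrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDyadsBed <- function(dyads, path) {
  .writeBed6(dyads, path,
             name = sprintf("dyad_%d", seq_along(dyads)),
             score = round(dyads$prominence, 4))
}

#' @rdname writeDyadsBed
#' @export
writeNfrsBed <- function(nfrs, path) {
  nm <- nfrs$condition
  if (is.null(nm)) nm <- rep("", length(nfrs))
  nm <- ifelse(nzchar(nm), sprintf("NFR_%d_%s", seq_along(nfrs), nm),
               sprintf("NFR_%d", seq_along(nfrs)))
  .writeBed6(nfrs, path, name = nm, score = GenomicRanges::width(nfrs))
}

#' Read NFRs from a BED file
#'
#' Inverse of [writeNfrsBed()] for pipeline use: imports a BED file of
#' nucleosome-free regions (the condition label, when embedded in the name
#' field, is recovered).
#'
#' @param path BED file path.
#' @return NFR `GRanges` with a `condition` metadata column.
#' @export
readNfrsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  cond <- sub("^NFR_\\d+_?", "", ifelse(is.na(gr$name), "", gr$name))
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr))
  out$condition <- cond
  out
}
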