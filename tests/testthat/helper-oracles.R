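# independent brute-force oracles, deliberately written as plain per-base /
# per-offset loops so they share no code path with the package implementation

# per-base overlap count
oracleCoverage <- function(starts, ends, len) {
  v <- numeric(len)
  for (i in seq_along(starts))
    for (b in starts[i]:ends[i]) v[b] <- v[b] + 1
  v
}

# per-base fragment-midpoint histogram
oracleDyadDensity <- function(starts, ends, len) {
  v <- numeric(len)
  for (i in seq_along(starts)) {
    m <- floor((starts[i] + ends[i]) / 2)
    v[m] <- v[m] + 1
  }
  v
}

# all local maxima (leftmost base of a maximal plateau, chromosome ends
# allowed) with topographic prominence, then the greedy retention rule
oracleDyads <- function(x, minSep, minPromFrac) {
  n <- length(x)
  peaks <- integer()
  for (i in seq_len(n)) {
    # leftmost base of a plateau strictly above both neighbours (or the edge)
    if (i > 1 && x[i - 1] == x[i]) next
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    leftLower <- i == 1 || x[i - 1] < x[i]
    rightLower <- j == n || x[j + 1] < x[i]
    if (leftLower && rightLower) peaks <- c(peaks, i)
  }
  if (!length(peaks)) return(data.frame(pos = integer(), height = numeric()))
  prom <- vapply(peaks, function(p) {
    h <- x[p]
    lmin <- -Inf
    if (p > 1) {
      lmin <- Inf
      for (b in (p - 1):1) {
        if (x[b] > h) break
        lmin <- min(lmin, x[b])
      }
    }
    rmin <- -Inf
    if (p < n) {
      rmin <- Inf
      for (b in (p + 1):n) {
        if (x[b] > h) break
        rmin <- min(rmin, x[b])
      }
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= minPromFrac * max(x)
  peaks <- peaks[keep]
  hts <- x[peaks]
  sel <- integer()
  for (i in order(-hts, peaks)) {
    ok <- TRUE
    for (s in sel) if (abs(peaks[s] - peaks[i]) < minSep) ok <- FALSE
    if (ok) sel <- c(sel, i)
  }
  sel <- sel[order(peaks[sel])]
  data.frame(pos = peaks[sel], height = hts[sel])
}

oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# every offset and strand tested independently against the NGG rule
oracleScan <- function(seq, L = 20) {
  w <- nchar(seq)
  out <- list()
  for (p in seq_len(w)) {
    # + strand: spacer [p, p+L-1], PAM [p+L, p+L+2] with base 2,3 == G
    if (p + L + 2 <= w) {
      pam <- substr(seq, p + L, p + L + 2)
      sp <- substr(seq, p, p + L - 1)
      if (substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G" &&
          !grepl("[^ACGT]", substr(pam, 1, 1)) && !grepl("N", sp, fixed = TRUE))
        out[[length(out) + 1]] <- data.frame(start = p, strand = "+",
                                             spacer = sp, pam = pam)
    }
    # - strand: genomic PAM [p-3, p-1] must read CCN; spacer genomic [p, p+L-1]
    if (p - 3 >= 1 && p + L - 1 <= w) {
      gpam <- substr(seq, p - 3, p - 1)
      sp <- substr(seq, p, p + L - 1)
      if (substr(gpam, 1, 1) == "C" && substr(gpam, 2, 2) == "C" &&
          !grepl("[^ACGT]", substr(gpam, 3, 3)) && !grepl("N", sp, fixed = TRUE))
        out[[length(out) + 1]] <- data.frame(start = p, strand = "-",
                                             spacer = oracleRevComp(sp),
                                             pam = oracleRevComp(gpam))
    }
  }
  if (!length(out)) return(data.frame(start = integer(), strand = character(),
                                      spacer = character(), pam = character()))
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

oracleHamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# exhaustive off-target tally over every offset and strand of every chromosome
oracleOfftargets <- function(spacer, genomeStrings, maxMM, requirePam = TRUE,
                             site = NULL) {
  L <- nchar(spacer)
  counts <- setNames(integer(maxMM + 1), as.character(0:maxMM))
  for (chrom in names(genomeStrings)) {
    seq <- genomeStrings[[chrom]]
    w <- nchar(seq)
    for (p in seq_len(w - L + 1)) {
      # + strand candidate
      pamOk <- !requirePam ||
        (p + L + 2 <= w && substr(seq, p + L + 1, p + L + 1) == "G" &&
         substr(seq, p + L + 2, p + L + 2) == "G")
      if (pamOk) {
        d <- oracleHamming(substr(seq, p, p + L - 1), spacer)
        onT <- !is.null(site) && site$chrom == chrom && site$strand == "+" &&
          site$start == p
        if (d <= maxMM && !onT) counts[d + 1] <- counts[d + 1] + 1L
      }
      # - strand candidate: genomic PAM CC immediately 5'
      pamOk <- !requirePam ||
        (p - 3 >= 1 && substr(seq, p - 3, p - 3) == "C" &&
         substr(seq, p - 2, p - 2) == "C")
      if (pamOk) {
        d <- oracleHamming(oracleRevComp(substr(seq, p, p + L - 1)), spacer)
        onT <- !is.null(site) && site$chrom == chrom && site$strand == "-" &&
          site$start == p
        if (d <= maxMM && !onT) counts[d + 1] <- counts[d + 1] + 1L
      }
    }
  }
  counts
}

# brute-force sort with the documented ranking key
oracleRankOrder <- function(scores) {
  key <- data.frame(a = -scores$total, b = abs(scores$tss_distance),
                    c = scores$strand != "+", d = scores$start)
  do.call(order, key)
}

# exhaustive multiplex oracle: the unique subset S such that, scanning in
# rank order, a guide is in S iff it is compatible with all better-ranked
# members of S and S has not yet reached k
oracleMultiplex <- function(centers, k, minSpacing) {
  n <- length(centers)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    consistent <- TRUE
    for (i in seq_len(n)) {
      better <- S[S < i]
      compat <- all(abs(centers[better] - centers[i]) >= minSpacing)
      should <- compat && length(better) < k
      if ((i %in% S) != should) { consistent <- FALSE; break }
    }
    if (consistent) { best <- S; break }
  }
  best
}

# closed-form two-sample equal-variance t test
oracleTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  list(t = t, p = p)
}
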