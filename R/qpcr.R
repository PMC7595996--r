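# relative expression readout: 2^-ddCt fold changes against reference genes
# with primer-efficiency filtering and significance testing

#' Read a long-format Ct table
#'
#' Expected columns: `sample_id` (biological sample), `gene_id`, `replicate`
#' (technical replicate index), `Ct`, `efficiency` (primer efficiency in
#' percent).
#'
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
readCtTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "replicate", "Ct", "efficiency")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$Ct)) || any(df$Ct <= 0) || any(df$Ct >= 45))
    stop("Ct values must lie in (0, 45)")
  df
}

#' Primer efficiency filter
#'
#' Only primer pairs with an efficiency between `low` and `high` percent
#' (inclusive; defaults 90 and 110) are considered valid for relative
#' quantification.
#'
#' @param efficiency Numeric vector of efficiencies in percent.
#' @param low,high Inclusive bounds in percent (defaults 90 and 110).
#' @return Logical vector.
#' @export
validateEfficiency <- function(efficiency, low = 90, high = 110) {
  efficiency >= low & efficiency <= high
}

# mean Ct per (sample, gene) after technical-replicate averaging, with the
# efficiency filter applied (failing measurements dropped with a message)
.meanCt <- function(ct, genes, samples, low, high) {
  sub <- ct[ct$gene_id %in% genes & ct$sample_id %in% samples, , drop = FALSE]
  bad <- !validateEfficiency(sub$efficiency, low, high)
  if (any(bad)) {
    drop <- unique(sub[bad, c("sample_id", "gene_id")])
    message("excluding measurement(s) failing the efficiency filter: ",
            paste(sprintf("%s/%s", drop$sample_id, drop$gene_id), collapse = ", "))
    sub <- sub[!bad, , drop = FALSE]
  }
  if (!nrow(sub)) return(sub[0, c("sample_id", "gene_id")])
  stats::aggregate(Ct ~ sample_id + gene_id, data = sub, FUN = mean)
}

#' Relative fold change by the 2^-ddCt method
#'
#' Computes Livak fold changes of a target gene in treated samples relative
#' to calibrator samples, normalised against one or more reference
#' (housekeeping) genes. Technical replicates are averaged first; the
#' reference Ct of a sample is the arithmetic mean of the per-reference-gene
#' mean Cts (set `refCombine = "separate"` for one result per reference
#' gene); `dCt = Ct_target - Ct_ref` per sample; `ddCt` of a treated sample
#' is its `dCt` minus the mean calibrator `dCt`; `fold = 2^(-ddCt)`. The
#' reported group fold is the mean of the per-replicate folds, with the
#' exponentiated mean ddCt (`fold_from_mean_ddct`) also reported. When both
#' groups hold at least two samples a two-sided equal-variance Student's t
#' test on the per-sample dCt values is attached.
#'
#' @param ct Long-format Ct table ([readCtTable()]).
#' @param target Target gene id.
#' @param refs Character vector of reference gene ids (e.g. actin and
#'   beta-tubulin housekeeping genes).
#' @param treated,calibrator Character vectors of sample ids for the two
#'   groups (calibrator = the baseline the fold is expressed against).
#' @param refCombine `"mean"` (default) or `"separate"`.
#' @param efficiencyLow,efficiencyHigh Efficiency bounds in percent passed to
#'   [validateEfficiency()].
#' @return For `refCombine = "mean"` a list of class `FoldChangeResult`:
#'   `target`, `refs`, `per_sample` (`data.frame` with sample, group, dCt,
#'   ddCt, fold), `mean_fold`, `fold_from_mean_ddct`, `t_statistic`,
#'   `p_value`, `stars`. For `"separate"`, a named list of such results (one
#'   per reference gene).
#' @export
foldChange <- function(ct, target, refs, treated, calibrator,
                       refCombine = c("mean", "separate"),
                       efficiencyLow = 90, efficiencyHigh = 110) {
  refCombine <- match.arg(refCombine)
  if (refCombine == "separate") {
    res <- lapply(refs, function(r)
      foldChange(ct, target, r, treated, calibrator, "mean",
                 efficiencyLow, efficiencyHigh))
    names(res) <- refs
    return(res)
  }
  samples <- c(treated, calibrator)
  tMean <- .meanCt(ct, target, samples, efficiencyLow, efficiencyHigh)
  rMean <- .meanCt(ct, refs, samples, efficiencyLow, efficiencyHigh)
  dCt <- vapply(samples, function(s) {
    tc <- tMean$Ct[tMean$sample_id == s]
    if (!length(tc)) stop("no valid target measurement for sample ", s)
    rc <- vapply(refs, function(r) {
      v <- rMean$Ct[rMean$sample_id == s & rMean$gene_id == r]
      if (!length(v)) stop("missing reference ", r, " for sample ", s)
      v
    }, numeric(1))
    tc - mean(rc)
  }, numeric(1))
  group <- ifelse(samples %in% treated, "treated", "calibrator")
  calBase <- mean(dCt[group == "calibrator"])
  ddCt <- dCt - calBase
  fold <- 2^(-ddCt)
  per <- data.frame(sample_id = samples, group = group, dCt = unname(dCt),
                    ddCt = unname(ddCt), fold = unname(fold),
                    stringsAsFactors = FALSE)
  trt <- per[per$group == "treated", , drop = FALSE]
  cal <- per[per$group == "calibrator", , drop = FALSE]
  tt <- list(t = NA_real_, p = NA_real_)
  if (nrow(trt) >= 2L && nrow(cal) >= 2L)
    tt <- significanceTest(trt$dCt, cal$dCt)
  structure(list(
    target = target, refs = refs, per_sample = per,
    mean_fold = mean(trt$fold),
    fold_from_mean_ddct = 2^(-mean(trt$ddCt)),
    t_statistic = tt$t, p_value = tt$p,
    stars = significanceStars(tt$p)),
    class = "FoldChangeResult")
}

#' @export
print.FoldChangeResult <- function(x, ...) {
  cat(sprintf(
    "FoldChangeResult: %s vs %s\n mean fold %.4g (2^-mean ddCt: %.4g), t = %.3g, p = %.3g %s\n",
    x$target, paste(x$refs, collapse = "+"), x$mean_fold,
    x$fold_from_mean_ddct, x$t_statistic, x$p_value, x$stars))
  invisible(x)
}

#' Two-sample Student's t test
#'
#' Two-sided, equal-variance two-sample t test, as used to verify the
#' significance of activation over control strains. The degenerate case of
#' zero variance in both groups is resolved by convention: p = 1 (t = 0) for
#' equal means, p = 0 (infinite t) otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `t` and `p`.
#' @export
significanceTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group must hold at least two values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Significance stars
#'
#' Figure-legend annotation: `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of annotations.
#' @export
significanceStars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Write fold-change results
#'
#' One TSV row per result: target, references, group sizes, mean fold,
#' exponentiated-mean-ddCt fold, t statistic, p value and significance stars.
#'
#' @param results A `FoldChangeResult` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeFoldChanges <- function(results, path) {
  if (inherits(results, "FoldChangeResult")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) data.frame(
    target = r$target, refs = paste(r$refs, collapse = ","),
    n_treated = sum(r$per_sample$group == "treated"),
    n_calibrator = sum(r$per_sample$group == "calibrator"),
    mean_fold = r$mean_fold, fold_from_mean_ddct = r$fold_from_mean_ddct,
    t_statistic = r$t_statistic, p_value = r$p_value,
    significance = r$stars, stringsAsFactors = FALSE)))
  .writeTsv(df, path)
}
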