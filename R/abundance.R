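#' FACS bin weights for sort-seq abundance scoring
#'
#' Default 4-bin weights follow the weighted-average abundance score: bin 1
#' (lowest abundance) 0.1, bin 2 0.15, bin 3 0.2, bin 4 (highest abundance)
#' 1. The two-bin mode (weights 0 and 1) scores a variant by its relative
#' frequency in the reporter-positive bin, as used for organoid (cardioid)
#' sorts with negative/positive gates.
#'
#' @param weights Numeric vector of non-decreasing per-bin weights, lowest
#'   bin first; at least two bins.
#' @return Numeric vector of class `sge_bin_weights`.
#' @export
bin_weights <- function(weights = c(0.1, 0.15, 0.2, 1)) {
  weights <- as.numeric(weights)
  stopifnot(length(weights) >= 2L, !is.unsorted(weights))
  structure(weights, class = "sge_bin_weights")
}

#' Weighted-bin abundance score
#'
#' For each variant the within-bin frequency f_vb is its count divided by the
#' bin's total variant-assigned reads; the raw score is the weighted average
#' w_v = sum_b(omega_b f_vb) / sum_b(f_vb). Bins with zero total contribute
#' nothing. Variants with no reads in any bin get `NA` (flagged, not zero).
#'
#' @param counts Integer matrix, variants x bins (lowest bin first). The
#'   wild-type row, if present, must be removed first: frequencies are over
#'   variant-assigned reads only.
#' @param weights [bin_weights()] with one weight per column.
#' @param bin_totals Optional per-bin totals for the frequency denominator;
#'   defaults to `colSums(counts)`.
#' @return Named numeric vector of raw scores, within
#'   `[min(weights), max(weights)]` where defined.
#' @export
weighted_bin_score <- function(counts, weights = bin_weights(),
                               bin_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(weights), all(counts >= 0),
            all(bin_totals >= 0))
  freq <- sweep(counts, 2L, ifelse(bin_totals > 0, bin_totals, NA), "/")
  freq[, bin_totals == 0] <- 0  # empty bins contribute nothing
  denom <- rowSums(freq)
  num <- as.vector(freq %*% as.numeric(weights))
  out <- ifelse(denom > 0, num / denom, NA_real_)
  names(out) <- rownames(counts)
  out
}

#' Anchor scores to the synonymous and nonsense medians
#'
#' Normalizes raw scores so that the median of synonymous-variant scores is
#' exactly 1 and the median of nonsense-variant scores is exactly 0:
#' s_v = (w_v - med_nonsense) / (med_synonymous - med_nonsense). Applied per
#' experiment (per exon library), so scores are comparable across exons.
#'
#' @param raw Named numeric vector of raw scores (NAs allowed).
#' @param consequence Character vector of consequence labels aligned to
#'   `raw`.
#' @param min_anchor Minimum number of scored synonymous and nonsense
#'   variants required (default 5).
#' @return Numeric vector of normalized scores.
#' @export
normalize_scores <- function(raw, consequence, min_anchor = 5L) {
  stopifnot(length(raw) == length(consequence))
  syn <- raw[consequence == "synonymous" & !is.na(raw)]
  non <- raw[consequence == "nonsense" & !is.na(raw)]
  if (length(syn) < min_anchor || length(non) < min_anchor) {
    stop("need at least ", min_anchor,
         " scored synonymous and nonsense variants (have ",
         length(syn), " and ", length(non), ")")
  }
  m_syn <- stats::median(syn)
  m_non <- stats::median(non)
  if (m_syn <= m_non) {
    stop("degenerate assay: synonymous median (", signif(m_syn, 3),
         ") does not exceed nonsense median (", signif(m_non, 3), ")")
  }
  (raw - m_non) / (m_syn - m_non)
}

#' Classify abundance against the synonymous distribution
#'
#' Scores are converted to z-scores against the synonymous normalized-score
#' distribution; z above -2 is normal abundance, below -3 is low abundance,
#' and between (boundaries included) is indeterminate.
#'
#' @param scores Normalized scores (NAs allowed, returned as `NA` class).
#' @param consequence Consequence labels aligned to `scores`.
#' @param thresholds Named numeric: `normal` (default -2) and `low`
#'   (default -3), with `low < normal`.
#' @param robust Use median/MAD instead of mean/sd for the synonymous
#'   reference (default `FALSE`).
#' @return List with `z` (numeric) and `class` (factor over
#'   normal/indeterminate/low).
#' @export
classify_abundance <- function(scores, consequence,
                               thresholds = c(normal = -2, low = -3),
                               robust = FALSE) {
  stopifnot(thresholds["low"] < thresholds["normal"])
  syn <- scores[consequence == "synonymous" & !is.na(scores)]
  ctr <- if (robust) stats::median(syn) else mean(syn)
  disp <- if (robust) stats::mad(syn) else stats::sd(syn)
  if (!length(syn) || !is.finite(disp) || disp == 0) {
    stop("degenerate synonymous score distribution (sd = 0 or empty)")
  }
  z <- (scores - ctr) / disp
  cls <- ifelse(is.na(z), NA_character_,
                ifelse(z > thresholds["normal"], "normal",
                       ifelse(z < thresholds["low"], "low", "indeterminate")))
  list(z = z,
       class = factor(cls, levels = c("normal", "indeterminate", "low")))
}

#' Score a sort-seq abundance experiment
#'
#' Orchestrates the full abundance pipeline on a count table: per replicate,
#' extracts the bin columns in order, computes raw weighted-bin scores over
#' variant-assigned reads, applies the read-support floor, normalizes to the
#' synonymous/nonsense medians, then combines replicates and classifies
#' against the synonymous distribution.
#'
#' @param counts An `sge_counts` object whose samples carry bin conditions
#'   (`bin1` < `bin2` < ... in abundance order, or `mApple_neg`/`mApple_pos`
#'   for two-bin mode).
#' @param designs Design table from [enumerate_snvs()].
#' @param weights [bin_weights()]; length must match the number of bin
#'   conditions present.
#' @param thresholds,robust Passed to [classify_abundance()].
#' @param read_floor Minimum total variant-assigned reads across bins (per
#'   replicate) for a variant to be scored; below it the variant is reported
#'   unscored (default 10).
#' @param replicate_policy `"average"` (default: average per-replicate
#'   normalized scores) or `"pool"` (sum counts across replicates first).
#' @param min_anchor Passed to [normalize_scores()].
#' @return An object of class `sge_scores`: data.frame with `variant_id`,
#'   `consequence`, `raw_score`, `normalized_score`, `z_score`, `class`,
#'   `total_reads`, plus per-replicate normalized scores as attribute
#'   `"replicates"`.
#' @export
score_abundance <- function(counts, designs, weights = bin_weights(),
                            thresholds = c(normal = -2, low = -3),
                            robust = FALSE, read_floor = 10L,
                            replicate_policy = c("average", "pool"),
                            min_anchor = 5L) {
  replicate_policy <- match.arg(replicate_policy)
  smp <- counts$samples
  bin_levels <- bin_condition_levels(smp$condition)
  if (length(bin_levels) != length(weights)) {
    stop("count table has ", length(bin_levels), " bin condition(s) but ",
         length(weights), " weights were supplied")
  }
  vids <- setdiff(rownames(counts$counts), "WT")
  cons <- designs$consequence[match(vids, designs$variant_id)]

  reps <- sort(unique(smp$replicate))
  if (replicate_policy == "pool" && length(reps) > 1L) {
    pooled <- sapply(bin_levels, function(b) {
      rowSums(counts$counts[vids, smp$condition == b, drop = FALSE])
    })
    mats <- list(pooled)
  } else {
    mats <- lapply(reps, function(r) {
      sel <- smp$replicate == r
      sapply(bin_levels, function(b) {
        cols <- which(sel & smp$condition == b)
        if (!length(cols)) stop("replicate ", r, " is missing condition ", b)
        rowSums(counts$counts[vids, cols, drop = FALSE])
      })
    })
  }

  per_rep <- sapply(mats, function(m) {
    raw <- weighted_bin_score(m, weights)
    raw[rowSums(m) < read_floor] <- NA_real_
    normalize_scores(raw, cons, min_anchor = min_anchor)
  })
  rownames(per_rep) <- vids
  norm <- rowMeans(per_rep, na.rm = FALSE)
  raw_all <- sapply(mats, function(m) {
    raw <- weighted_bin_score(m, weights)
    raw[rowSums(m) < read_floor] <- NA_real_
    raw
  })
  total_reads <- as.integer(Reduce(`+`, lapply(mats, rowSums)))
  cl <- classify_abundance(norm, cons, thresholds, robust)

  out <- data.frame(variant_id = vids, consequence = cons,
                    raw_score = rowMeans(raw_all, na.rm = FALSE),
                    normalized_score = norm, z_score = cl$z,
                    class = cl$class, total_reads = total_reads,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "replicates") <- per_rep
  attr(out, "weights") <- weights
  attr(out, "thresholds") <- thresholds
  class(out) <- c("sge_scores", "data.frame")
  out
}

# Ordered bin condition labels present in a condition vector.
bin_condition_levels <- function(conditions) {
  known <- c(paste0("bin", 1:8), "mApple_neg", "mApple_pos")
  lv <- known[known %in% conditions]
  if (!length(lv)) stop("no bin conditions (bin1..binN or mApple_neg/pos) found")
  lv
}

#' @export
print.sge_scores <- function(x, ...) {
  scored <- sum(!is.na(x$normalized_score))
  cat("SGE abundance score table: ", nrow(x), " designed variants, ",
      scored, " scored\n", sep = "")
  print(table(class = x$class, useNA = "ifany"))
  invisible(x)
}

#' @export
summary.sge_scores <- function(object, ...) {
  tab <- table(consequence = object$consequence, class = object$class,
               useNA = "ifany")
  cat("Class by consequence:\n")
  print(tab)
  syn <- object$normalized_score[object$consequence == "synonymous"]
  non <- object$normalized_score[object$consequence == "nonsense"]
  cat("\nAnchors: synonymous median = ",
      signif(stats::median(syn, na.rm = TRUE), 4),
      ", nonsense median = ", signif(stats::median(non, na.rm = TRUE), 4),
      "\n", sep = "")
  invisible(tab)
}

#' @export
plot.sge_scores <- function(x, breaks = 40, ...) {
  s <- x$normalized_score
  graphics::hist(s, breaks = breaks, col = "grey80", border = NA,
                 main = "Normalized abundance scores", xlab = "score", ...)
  for (cc in c("synonymous", "nonsense")) {
    m <- stats::median(s[x$consequence == cc], na.rm = TRUE)
    graphics::abline(v = m, lty = 2)
  }
  invisible(x)
}

#' Compare two score tables (e.g. monolayer vs organoid experiments)
#'
#' @param a,b `sge_scores` tables sharing variants.
#' @return List with `paired` (data.frame of shared scored variants),
#'   `pearson_r`, and `agreement` (class-by-class contingency table).
#' @export
compare_scores <- function(a, b) {
  shared <- merge(a[!is.na(a$normalized_score),
                    c("variant_id", "normalized_score", "class")],
                  b[!is.na(b$normalized_score),
                    c("variant_id", "normalized_score", "class")],
                  by = "variant_id", suffixes = c("_a", "_b"))
  if (nrow(shared) < 3L) {
    stop("need at least 3 shared scored variants, have ", nrow(shared))
  }
  r <- stats::cor(shared$normalized_score_a, shared$normalized_score_b,
                  method = "pearson")
  list(paired = shared, pearson_r = r,
       agreement = table(a = shared$class_a, b = shared$class_b))
}

#' Export scores in a MaveDB-style CSV (hgvs, score)
#'
#' @param scores `sge_scores` table.
#' @param designs Design table providing `hgvs_c`.
#' @param path Output CSV path.
#' @export
write_mave_csv <- function(scores, designs, path) {
  hg <- designs$hgvs_c[match(scores$variant_id, designs$variant_id)]
  utils::write.csv(data.frame(hgvs = hg, score = scores$normalized_score),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
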