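#' Per-variant log2 frequency ratio between two samples
#'
#' r_v = log2( f_v(endpoint) / f_v(reference) ) with pseudocounted
#' frequencies f_v = (c_v + pc) / (T + pc * V), where T is the sample's total
#' variant-assigned reads and V the number of designed variants. The
#' pseudocount (default 0.5) keeps fully depleted variants finite.
#'
#' @param counts_end,counts_ref Named integer vectors over the same designed
#'   variants (endpoint, e.g. day-14 cells; reference, e.g. plasmid library).
#' @param pseudocount Added to every count (default 0.5).
#' @return Named numeric vector of log2 ratios.
#' @export
log2_ratio <- function(counts_end, counts_ref, pseudocount = 0.5) {
  stopifnot(length(counts_end) == length(counts_ref), all(counts_ref >= 0),
            all(counts_end >= 0))
  if (sum(counts_ref) <= 0) stop("reference sample has zero total reads")
  v <- length(counts_end)
  f_end <- (counts_end + pseudocount) / (sum(counts_end) + pseudocount * v)
  f_ref <- (counts_ref + pseudocount) / (sum(counts_ref) + pseudocount * v)
  out <- log2(f_end / f_ref)
  names(out) <- names(counts_end)
  out
}

#' Classify fitness against the synonymous distribution
#'
#' Log2 ratios are z-scored against the synonymous-variant ratios. In the
#' default two-class mode, z below `depleted_z` (default -2) is `depleted`
#' and everything else `functionally_normal`; the three-class mode adds an
#' `indeterminate` band between `depleted_z` and `normal_z`, mirroring the
#' abundance thresholds.
#'
#' @param ratios Named numeric log2 ratios (NAs allowed).
#' @param consequence Consequence labels aligned to `ratios`.
#' @param depleted_z Depletion threshold (default -2).
#' @param normal_z Upper edge of the indeterminate band in three-class mode
#'   (default -2; set e.g. `depleted_z = -3, normal_z = -2`).
#' @param mode `"two"` (default) or `"three"` classes.
#' @return List with `z` and `class`.
#' @export
classify_fitness <- function(ratios, consequence, depleted_z = -2,
                             normal_z = -2, mode = c("two", "three")) {
  mode <- match.arg(mode)
  syn <- ratios[consequence == "synonymous" & !is.na(ratios)]
  if (length(syn) < 5L) stop("need at least 5 scored synonymous variants")
  s <- stats::sd(syn)
  if (!is.finite(s) || s == 0) stop("degenerate synonymous ratio distribution")
  z <- (ratios - mean(syn)) / s
  cls <- if (mode == "two") {
    ifelse(is.na(z), NA_character_,
           ifelse(z < depleted_z, "depleted", "functionally_normal"))
  } else {
    stopifnot(depleted_z < normal_z)
    ifelse(is.na(z), NA_character_,
           ifelse(z < depleted_z, "depleted",
                  ifelse(z > normal_z, "functionally_normal",
                         "indeterminate")))
  }
  list(z = z, class = factor(cls, levels = c("functionally_normal",
                                             "indeterminate", "depleted")))
}

#' Label the variant mechanism from two genetic backgrounds
#'
#' Combines per-background fitness classes measured on a null background
#' allele and a partial-function background allele: depletion on the
#' partial-function background indicates a dominant negative (such variants
#' are expected to deplete on the null background too); depletion only on
#' the null background indicates simple loss of function; no depletion on
#' either is functionally normal; depletion on the partial-function
#' background without depletion on the null background is discordant and
#' flagged for review.
#'
#' @param class_null,class_partial Class labels
#'   (`depleted`/`functionally_normal`/`indeterminate`), vectorized.
#' @return Factor over `loss_of_function`, `dominant_negative`,
#'   `functionally_normal`, `discordant`, `unscored`.
#' @export
label_mechanism <- function(class_null, class_partial) {
  cn <- as.character(class_null)
  cp <- as.character(class_partial)
  out <- ifelse(is.na(cn) | is.na(cp) | cn == "indeterminate" |
                  cp == "indeterminate", "unscored",
         ifelse(cp == "depleted" & cn == "depleted", "dominant_negative",
         ifelse(cp == "depleted", "discordant",
         ifelse(cn == "depleted", "loss_of_function",
                "functionally_normal"))))
  factor(out, levels = c("functionally_normal", "loss_of_function",
                         "dominant_negative", "discordant", "unscored"))
}

#' Score a growth-selection fitness experiment
#'
#' For each genetic background present, computes per-variant log2 ratios of
#' endpoint (day-14) versus reference (plasmid) frequencies, centers them on
#' the synonymous median (`centered` column; raw ratios are kept), z-scores
#' and classifies against the synonymous distribution, and, when both a null
#' and a partial-function background are scored, labels each variant's
#' mechanism.
#'
#' @param counts An `sge_counts` object; samples need `condition` in
#'   `{plasmid, day14}` (or `{t0, endpoint}`) and, for two-background
#'   experiments, a `background` column in `{null, partial}`.
#' @param designs Design table from [enumerate_snvs()].
#' @param pseudocount Passed to [log2_ratio()].
#' @param center `"synonymous"` (default; subtract the synonymous median so
#'   neutral variants sit at 0) or `"none"`.
#' @param ... Passed to [classify_fitness()].
#' @return An object of class `sge_fitness`: data.frame with, per background,
#'   `log2_ratio_<bg>`, `centered_<bg>`, `z_<bg>`, `class_<bg>`, plus
#'   `mechanism` when two backgrounds are present.
#' @export
score_fitness <- function(counts, designs, pseudocount = 0.5,
                          center = c("synonymous", "none"), ...) {
  center <- match.arg(center)
  smp <- counts$samples
  if (is.null(smp$background)) smp$background <- "null"
  ref_cond <- intersect(c("plasmid", "t0"), smp$condition)
  end_cond <- intersect(c("day14", "endpoint"), smp$condition)
  if (!length(ref_cond) || !length(end_cond)) {
    stop("count table must contain a reference (plasmid/t0) and an endpoint ",
         "(day14/endpoint) condition")
  }
  vids <- setdiff(rownames(counts$counts), "WT")
  cons <- designs$consequence[match(vids, designs$variant_id)]
  out <- data.frame(variant_id = vids, consequence = cons,
                    stringsAsFactors = FALSE)
  bgs <- unique(smp$background)
  for (bg in bgs) {
    sel <- smp$background == bg
    c_ref <- rowSums(counts$counts[vids, which(sel & smp$condition %in% ref_cond),
                                   drop = FALSE])
    c_end <- rowSums(counts$counts[vids, which(sel & smp$condition %in% end_cond),
                                   drop = FALSE])
    lr <- log2_ratio(c_end, c_ref, pseudocount)
    ctr <- if (center == "synonymous") {
      lr - stats::median(lr[cons == "synonymous"], na.rm = TRUE)
    } else lr
    cl <- classify_fitness(lr, cons, ...)
    out[[paste0("log2_ratio_", bg)]] <- unname(lr)
    out[[paste0("centered_", bg)]] <- unname(ctr)
    out[[paste0("z_", bg)]] <- unname(cl$z)
    out[[paste0("class_", bg)]] <- cl$class
  }
  if (all(c("null", "partial") %in% bgs)) {
    out$mechanism <- label_mechanism(out$class_null, out$class_partial)
  }
  class(out) <- c("sge_fitness", "data.frame")
  out
}

#' @export
print.sge_fitness <- function(x, ...) {
  cat("SGE fitness score table: ", nrow(x), " designed variants\n", sep = "")
  for (col in grep("^class_", names(x), value = TRUE)) {
    cat(sub("class_", "background ", col), ": ", sep = "")
    print(table(x[[col]]))
  }
  if (!is.null(x$mechanism)) {
    cat("mechanism:\n")
    print(table(x$mechanism))
  }
  invisible(x)
}
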