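#' Per-guide log2 fold change versus a reference library
#'
#' Endpoint counts are first normalized to the reference using the median
#' ratio of the non-targeting control guides (fallback: total counts), then
#' each guide's log2 pseudocounted frequency ratio is computed.
#'
#' @param counts_end,counts_ref Named integer vectors over the same guides.
#' @param nontargeting Logical vector flagging non-targeting control guides.
#' @param pseudocount Added to every count (default 0.5).
#' @param normalization `"median_ratio_nt"` (default) or `"total"`.
#' @return Named numeric vector of per-guide log2 fold changes.
#' @export
guide_log2fc <- function(counts_end, counts_ref, nontargeting,
                         pseudocount = 0.5,
                         normalization = c("median_ratio_nt", "total")) {
  normalization <- match.arg(normalization)
  stopifnot(length(counts_end) == length(counts_ref),
            length(nontargeting) == length(counts_end))
  if (sum(counts_ref) <= 0) stop("reference library has zero total reads")
  size <- if (normalization == "median_ratio_nt") {
    if (!any(nontargeting)) {
      stop("median-ratio normalization requires non-targeting guides")
    }
    stats::median((counts_end[nontargeting] + pseudocount) /
                    (counts_ref[nontargeting] + pseudocount))
  } else {
    sum(counts_end) / sum(counts_ref)
  }
  out <- log2((counts_end + pseudocount) /
                (size * (counts_ref + pseudocount)))
  names(out) <- names(counts_end)
  out
}

#' Gene-level score from guide log2 fold changes
#'
#' @param lfc Numeric guide log2 fold changes (across guides and
#'   replicates).
#' @param gene Character vector of gene labels aligned to `lfc`
#'   (`NA` for non-targeting guides).
#' @return data.frame `gene`, `log2fc` (arithmetic mean), `n_guides`.
#' @export
gene_score <- function(lfc, gene) {
  keep <- !is.na(gene)
  agg <- tapply(lfc[keep], gene[keep], mean)
  data.frame(gene = names(agg), log2fc = as.numeric(agg),
             n_guides = as.integer(table(gene[keep])[names(agg)]),
             stringsAsFactors = FALSE)
}

#' Empirical significance of gene scores against non-targeting controls
#'
#' Builds a null distribution of gene-level scores by resampling
#' `guides_per_gene` non-targeting guide log2 fold changes with replacement
#' `n_resamples` times (seeded) and taking their mean, or by exhaustive
#' enumeration of all selections when `exhaustive = TRUE`. Each gene gets a
#' two-sided empirical p-value with add-one correction, BH-adjusted across
#' genes; genes with q at or below `q_level` are called depleted or enriched
#' by sign.
#'
#' @param gene_scores data.frame from [gene_score()].
#' @param nt_lfc Non-targeting guide log2 fold changes (at least 20 for
#'   sampled mode).
#' @param guides_per_gene Number of guides drawn per null gene (default 2).
#' @param n_resamples Null size (default 10000; values below 1000 trigger a
#'   warning).
#' @param seed Integer seed for the resampling.
#' @param q_level BH threshold for calls (default 0.05).
#' @param exhaustive Enumerate every `guides_per_gene`-tuple of
#'   non-targeting guides instead of sampling (feasible for tiny controls).
#' @return Object of class `sge_screen`: data.frame `gene`, `log2fc`,
#'   `n_guides`, `p`, `q`, `call`.
#' @export
gene_significance <- function(gene_scores, nt_lfc, guides_per_gene = 2L,
                              n_resamples = 10000L, seed = 1L,
                              q_level = 0.05, exhaustive = FALSE) {
  if (!exhaustive && length(nt_lfc) < 20L) {
    stop("need at least 20 non-targeting guides, have ", length(nt_lfc))
  }
  if (!exhaustive && n_resamples < 1000L) {
    warning("n_resamples < 1000; empirical p-values will be coarse")
  }
  null <- if (exhaustive) {
    grid <- do.call(expand.grid,
                    rep(list(seq_along(nt_lfc)), guides_per_gene))
    apply(grid, 1L, function(ix) mean(nt_lfc[ix]))
  } else {
    with_seed(seed, {
      draws <- matrix(sample(nt_lfc, guides_per_gene * n_resamples,
                             replace = TRUE),
                      nrow = guides_per_gene)
      colMeans(draws)
    })
  }
  ctr <- stats::median(null)
  p <- vapply(gene_scores$log2fc, function(x) {
    lo <- (sum(null <= x) + 1) / (length(null) + 1)
    hi <- (sum(null >= x) + 1) / (length(null) + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  call <- ifelse(q <= q_level,
                 ifelse(gene_scores$log2fc < ctr, "depleted", "enriched"),
                 "neutral")
  out <- cbind(gene_scores, p = p, q = q,
               call = factor(call, levels = c("depleted", "neutral",
                                              "enriched")))
  class(out) <- c("sge_screen", "data.frame")
  attr(out, "null_size") <- length(null)
  out
}

#' Score a pooled knockout screen end-to-end
#'
#' Computes per-guide log2 fold changes of an endpoint versus a reference
#' sample (per replicate, then pooled into gene means) and tests each gene
#' against the non-targeting null.
#'
#' @param guides data.frame with `guide_id`, `gene` (`NA` for non-targeting
#'   guides), and count columns.
#' @param endpoint,reference Names of the count columns (character vectors
#'   over replicates are averaged at the guide-lfc level).
#' @param ... Passed to [gene_significance()].
#' @param pseudocount,normalization Passed to [guide_log2fc()].
#' @return An `sge_screen` result; per-guide log2FCs in attribute
#'   `"guide_lfc"`.
#' @examples
#' \dontrun{
#' res <- score_screen(tab, endpoint = "ipsc_d21", reference = "plasmid")
#' }
#' @export
score_screen <- function(guides, endpoint, reference, pseudocount = 0.5,
                         normalization = c("median_ratio_nt", "total"),
                         ...) {
  normalization <- match.arg(normalization)
  stopifnot(all(c(endpoint, reference) %in% names(guides)))
  nt <- is.na(guides$gene)
  lfc_reps <- sapply(seq_along(endpoint), function(i) {
    ref_col <- reference[min(i, length(reference))]
    guide_log2fc(stats::setNames(guides[[endpoint[i]]], guides$guide_id),
                 guides[[ref_col]], nt, pseudocount, normalization)
  })
  lfc <- rowMeans(lfc_reps)
  gs <- gene_score(lfc, guides$gene)
  res <- gene_significance(gs, lfc[nt], ...)
  attr(res, "guide_lfc") <- lfc
  res
}

#' Neuron-versus-iPSC differentiation contrast
#'
#' Scores the neuron endpoint against the iPSC endpoint as reference,
#' isolating genes specifically required during or after differentiation.
#'
#' @param guides,... As in [score_screen()].
#' @param neuron,ipsc Count column names for the two endpoints.
#' @export
differentiation_contrast <- function(guides, neuron, ipsc, ...) {
  score_screen(guides, endpoint = neuron, reference = ipsc, ...)
}

#' @export
print.sge_screen <- function(x, ...) {
  cat("SGE screen result: ", nrow(x), " genes (null size ",
      attr(x, "null_size"), ")\n", sep = "")
  print(table(x$call))
  invisible(x)
}
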