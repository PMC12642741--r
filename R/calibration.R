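#' OddsPath: Bayesian likelihood ratio for a functional-assay class
#'
#' Quantifies how strongly membership in a functional score class (e.g. "low
#' abundance") shifts the odds of pathogenicity, from counts of clinically
#' classified truth variants. With prior P1 = nP_total / (nP_total +
#' nB_total) and class posterior P2 = nP_class / (nP_class + nB_class),
#' OddsPath = \[P2 (1 - P1)\] / \[(1 - P2) P1\]. When a class cell is zero
#' and `zero_cell_adjust` is on, one variant of the opposing classification
#' is added to the class counts only (the prior totals are untouched).
#'
#' @param nP_class,nB_class Pathogenic / benign truth variants in the class.
#' @param nP_total,nB_total Pathogenic / benign truth variants overall.
#' @param zero_cell_adjust Apply the zero-cell adjustment (default `TRUE`).
#' @return List of class `sge_oddspath` with `P1`, `P2`, `oddspath`,
#'   `adjusted`, and the (possibly adjusted) class counts.
#' @examples
#' oddspath(26, 1, 28, 63)$oddspath   # 58.5
#' oddspath(0, 59, 28, 63)$oddspath   # 0.0381...
#' @export
oddspath <- function(nP_class, nB_class, nP_total, nB_total,
                     zero_cell_adjust = TRUE) {
  stopifnot(nP_total + nB_total > 0, nP_class <= nP_total,
            nB_class <= nB_total, nP_class >= 0, nB_class >= 0)
  if (nP_class + nB_class == 0) {
    stop("class contains no truth variants; OddsPath undefined")
  }
  P1 <- nP_total / (nP_total + nB_total)
  adjusted <- FALSE
  if ((nP_class == 0 || nB_class == 0)) {
    if (!zero_cell_adjust) {
      stop("zero cell in class counts and zero_cell_adjust is disabled; ",
           "OddsPath undefined")
    }
    if (nP_class == 0) nP_class <- nP_class + 1
    if (nB_class == 0) nB_class <- nB_class + 1
    adjusted <- TRUE
  }
  P2 <- nP_class / (nP_class + nB_class)
  op <- (P2 * (1 - P1)) / ((1 - P2) * P1)
  structure(list(P1 = P1, P2 = P2, oddspath = op, adjusted = adjusted,
                 nP_class = nP_class, nB_class = nB_class),
            class = "sge_oddspath")
}

#' @export
print.sge_oddspath <- function(x, ...) {
  cat("OddsPath = ", signif(x$oddspath, 4), "  (P1 = ", signif(x$P1, 4),
      ", P2 = ", signif(x$P2, 4),
      if (x$adjusted) ", zero-cell adjusted" else "", ")\n", sep = "")
  invisible(x)
}

#' OddsPath-to-evidence-strength cutpoints
#'
#' The ClinGen-approved interval boundaries mapping an OddsPath value to
#' ACMG evidence strength: pathogenic side 2.08 / 4.33 / 18.7 / 350
#' (supporting / moderate / strong / very strong), benign side 0.48 / 0.23 /
#' 0.053 / 0.00286.
#'
#' @param pathogenic,benign Named numeric cutpoints
#'   (supporting/moderate/strong/very_strong); pathogenic strictly
#'   increasing, benign strictly decreasing.
#' @return List of class `sge_evidence_thresholds`.
#' @export
evidence_thresholds <- function(
    pathogenic = c(supporting = 2.08, moderate = 4.33, strong = 18.7,
                   very_strong = 350),
    benign = c(supporting = 0.48, moderate = 0.23, strong = 0.053,
               very_strong = 0.00286)) {
  stopifnot(!is.unsorted(pathogenic, strictly = TRUE),
            !is.unsorted(rev(benign), strictly = TRUE))
  structure(list(pathogenic = pathogenic, benign = benign),
            class = "sge_evidence_thresholds")
}

#' Map an OddsPath value to an ACMG evidence code and strength
#'
#' OddsPath at or above a pathogenic cutpoint (and below the next) yields
#' PS3 at that strength; at or below a benign cutpoint (and above the next)
#' yields BS3; values in the uninformative middle yield no evidence.
#'
#' @param op OddsPath value (> 0), or an `sge_oddspath` object.
#' @param thresholds [evidence_thresholds()].
#' @return List with `code` (`"PS3"`, `"BS3"`, or `NA`), `direction`, and
#'   `strength` (`supporting`/`moderate`/`strong`/`very_strong` or `NA`).
#' @export
evidence_strength <- function(op, thresholds = evidence_thresholds()) {
  if (inherits(op, "sge_oddspath")) op <- op$oddspath
  stopifnot(is.numeric(op), op > 0)
  pt <- thresholds$pathogenic
  bt <- thresholds$benign
  lv <- c("supporting", "moderate", "strong", "very_strong")
  if (op >= pt["supporting"]) {
    strength <- lv[max(which(op >= pt))]
    return(list(code = "PS3", direction = "pathogenic", strength = strength))
  }
  if (op <= bt["supporting"]) {
    strength <- lv[max(which(op <= bt))]
    return(list(code = "BS3", direction = "benign", strength = strength))
  }
  list(code = NA_character_, direction = NA_character_,
       strength = NA_character_)
}

#' Calibrate functional score classes against a clinical truth set
#'
#' Counts pathogenic/likely-pathogenic (PLP) and benign/likely-benign (BLB)
#' truth variants in each functional class, computes each class's OddsPath
#' (indeterminate-class variants stay in the prior totals but form no
#' calibrated class), and maps it to an evidence code and strength.
#'
#' @param classes Named character/factor vector: variant_id -> functional
#'   class (`low`/`normal`/`indeterminate`, or fitness classes).
#' @param truth data.frame with `variant_id` and `label` (`PLP`/`BLB`);
#'   optionally `stars` (review status; rows below `min_stars` are dropped).
#' @param evidence_classes Classes that receive calibrated evidence and
#'   their direction; default low -> pathogenic, normal -> benign.
#' @param thresholds [evidence_thresholds()].
#' @param zero_cell_adjust Passed to [oddspath()].
#' @param min_stars Minimum review stars when `truth$stars` exists
#'   (default 1).
#' @return Object of class `sge_calibration`: list with `prior`, `totals`,
#'   and per-class rows (`class`, `nP`, `nB`, `P2`, `oddspath`, `code`,
#'   `strength`).
#' @export
calibrate_classes <- function(classes, truth,
                              evidence_classes = c(low = "pathogenic",
                                                   normal = "benign"),
                              thresholds = evidence_thresholds(),
                              zero_cell_adjust = TRUE, min_stars = 1L) {
  stopifnot(all(truth$label %in% c("PLP", "BLB")),
            !anyDuplicated(truth$variant_id))
  if (!is.null(truth$stars)) truth <- truth[truth$stars >= min_stars, ]
  truth <- truth[truth$variant_id %in% names(classes), ]
  cls <- as.character(classes[truth$variant_id])
  nP_total <- sum(truth$label == "PLP")
  nB_total <- sum(truth$label == "BLB")
  rows <- lapply(names(evidence_classes), function(cc) {
    nP <- sum(truth$label == "PLP" & cls == cc)
    nB <- sum(truth$label == "BLB" & cls == cc)
    if (nP + nB == 0) {
      return(data.frame(class = cc, nP = nP, nB = nB, P2 = NA_real_,
                        oddspath = NA_real_, code = NA_character_,
                        strength = NA_character_))
    }
    op <- oddspath(nP, nB, nP_total, nB_total, zero_cell_adjust)
    ev <- evidence_strength(op, thresholds)
    data.frame(class = cc, nP = nP, nB = nB, P2 = op$P2,
               oddspath = op$oddspath, code = ev$code,
               strength = ev$strength)
  })
  structure(list(prior = nP_total / (nP_total + nB_total),
                 totals = c(PLP = nP_total, BLB = nB_total),
                 classes = do.call(rbind, rows)),
            class = "sge_calibration")
}

#' @export
print.sge_calibration <- function(x, ...) {
  cat("Functional-evidence calibration: prior P1 = ", signif(x$prior, 4),
      " (", x$totals["PLP"], " PLP, ", x$totals["BLB"], " BLB)\n", sep = "")
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Attach calibrated functional evidence to scored variants
#'
#' Variants in a calibrated class receive that class's evidence code at its
#' calibrated strength; indeterminate or uncalibrated classes receive none.
#'
#' @param classes Named vector: variant_id -> functional class.
#' @param calibration [calibrate_classes()] result.
#' @return data.frame `variant_id`, `code`, `direction`, `strength` (rows
#'   only for variants that receive evidence).
#' @export
assign_functional_evidence <- function(classes, calibration) {
  cal <- calibration$classes
  cal <- cal[!is.na(cal$code), , drop = FALSE]
  idx <- match(as.character(classes), cal$class)
  keep <- !is.na(idx)
  data.frame(variant_id = names(classes)[keep],
             code = cal$code[idx[keep]],
             direction = ifelse(cal$code[idx[keep]] == "PS3", "pathogenic",
                                "benign"),
             strength = cal$strength[idx[keep]],
             stringsAsFactors = FALSE)
}

acmg_points <- c(supporting = 1, moderate = 2, strong = 4, very_strong = 8)

#' Combine ACMG evidence items with the point system
#'
#' Each evidence item carries signed points by strength (supporting 1,
#' moderate 2, strong 4, very strong 8; pathogenic positive, benign
#' negative). The summed total classifies the variant: >= 10 pathogenic,
#' 6..9 likely pathogenic, 0..5 VUS, -6..-1 likely benign, <= -7 benign.
#'
#' @param profile data.frame with `code`, `direction`
#'   (`pathogenic`/`benign`), `strength`; at most one strength per code.
#' @return List with `points` and `classification` in
#'   `{P, LP, VUS, LB, B}`.
#' @export
combine_evidence <- function(profile) {
  if (is.null(profile) || nrow(profile) == 0L) {
    return(list(points = 0, classification = "VUS"))
  }
  stopifnot(all(profile$direction %in% c("pathogenic", "benign")),
            all(profile$strength %in% names(acmg_points)))
  if (anyDuplicated(profile$code)) {
    stop("conflicting duplicate evidence codes: ",
         paste(unique(profile$code[duplicated(profile$code)]), collapse = ", "))
  }
  pts <- sum(ifelse(profile$direction == "pathogenic", 1, -1) *
               acmg_points[profile$strength])
  cls <- if (pts >= 10) "P"
         else if (pts >= 6) "LP"
         else if (pts >= 0) "VUS"
         else if (pts >= -6) "LB"
         else "B"
  list(points = pts, classification = cls)
}

#' Reclassify a VUS cohort with calibrated functional evidence
#'
#' For each VUS, appends the calibrated functional evidence item (if its
#' functional class has one) to the variant's existing evidence profile and
#' recombines with the point system. Summarizes how many variants leave VUS,
#' to which side, and why the rest remain (indeterminate functional score vs
#' insufficient other evidence).
#'
#' @param profiles Named list of per-variant evidence data.frames (may be
#'   empty data.frames) as taken by [combine_evidence()].
#' @param classes Named vector: variant_id -> functional class (must cover
#'   all profiled variants).
#' @param calibration [calibrate_classes()] result.
#' @return List of class `sge_reclassification` with `per_variant`
#'   (data.frame: variant_id, functional class, points, classification,
#'   reason) and `summary` (n, n_reclassified, to_LP_or_P, to_LB_or_B,
#'   remaining_VUS).
#' @export
reclassify_cohort <- function(profiles, classes, calibration) {
  stopifnot(all(names(profiles) %in% names(classes)))
  fun_ev <- assign_functional_evidence(classes[names(profiles)], calibration)
  rows <- lapply(names(profiles), function(v) {
    prof <- profiles[[v]]
    fe <- fun_ev[fun_ev$variant_id == v, c("code", "direction", "strength")]
    full <- rbind(prof[, c("code", "direction", "strength")], fe)
    res <- combine_evidence(full)
    reason <- if (res$classification != "VUS") NA_character_
              else if (nrow(fe) == 0L) "indeterminate_score"
              else "insufficient_other_evidence"
    data.frame(variant_id = v, class = as.character(classes[[v]]),
               points = res$points, classification = res$classification,
               reason = reason, stringsAsFactors = FALSE)
  })
  per_variant <- do.call(rbind, rows)
  summary <- list(
    n = nrow(per_variant),
    n_reclassified = sum(per_variant$classification != "VUS"),
    to_LP_or_P = sum(per_variant$classification %in% c("LP", "P")),
    to_LB_or_B = sum(per_variant$classification %in% c("LB", "B")),
    remaining_VUS = sum(per_variant$classification == "VUS"))
  structure(list(per_variant = per_variant, summary = summary),
            class = "sge_reclassification")
}

#' @export
print.sge_reclassification <- function(x, ...) {
  s <- x$summary
  cat("VUS reclassification: ", s$n_reclassified, "/", s$n, " reclassified (",
      round(100 * s$n_reclassified / s$n), "%): ", s$to_LP_or_P,
      " to LP/P, ", s$to_LB_or_B, " to LB/B; ", s$remaining_VUS,
      " remain VUS\n", sep = "")
  invisible(x)
}

#' Translate REVEL scores into PP3/BP4 evidence items
#'
#' Helper for building evidence profiles from a computational predictor
#' column using ClinGen-recalibrated strength thresholds.
#'
#' @param revel Numeric REVEL scores (0-1), named by variant.
#' @param pathogenic Named increasing cutpoints for PP3 strength (defaults
#'   to the ClinGen recalibration: supporting 0.644, moderate 0.773, strong
#'   0.932).
#' @param benign Named decreasing cutpoints for BP4 strength (supporting
#'   0.290, moderate 0.183, strong 0.016).
#' @return data.frame `variant_id`, `code`, `direction`, `strength` for
#'   variants meeting a threshold.
#' @export
revel_evidence <- function(revel,
                           pathogenic = c(supporting = 0.644,
                                          moderate = 0.773, strong = 0.932),
                           benign = c(supporting = 0.290, moderate = 0.183,
                                      strong = 0.016)) {
  out <- lapply(names(revel), function(v) {
    r <- revel[[v]]
    if (is.na(r)) return(NULL)
    if (r >= pathogenic["supporting"]) {
      s <- names(pathogenic)[max(which(r >= pathogenic))]
      return(data.frame(variant_id = v, code = "PP3",
                        direction = "pathogenic", strength = s))
    }
    if (r <= benign["supporting"]) {
      s <- names(benign)[max(which(r <= benign))]
      return(data.frame(variant_id = v, code = "BP4", direction = "benign",
                        strength = s))
    }
    NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), code = character(),
                      direction = character(), strength = character())
  }
  out
}
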