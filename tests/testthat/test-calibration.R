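test_that("uninformative class composition gives OddsPath exactly 1", {
  # class composition equals the prior (30% pathogenic)
  op <- oddspath(3, 7, 30, 70)
  expect_equal(op$oddspath, 1, tolerance = 1e-12)
  expect_true(is.na(evidence_strength(op)$code))
})

test_that("OddsPath is monotone in the class composition", {
  prev <- 0
  for (nP in 1:9) {
    op <- oddspath(nP, 10 - nP, 30, 70)$oddspath
    expect_gt(op, prev)
    prev <- op
  }
})

test_that("zero-cell handling adjusts class counts only", {
  op <- oddspath(0, 59, 28, 63, zero_cell_adjust = TRUE)
  expect_true(op$adjusted)
  expect_equal(op$P1, 28 / 91)        # prior untouched
  expect_equal(op$P2, 1 / 60)         # one pathogenic added to the class
  expect_error(oddspath(0, 59, 28, 63, zero_cell_adjust = FALSE),
               "undefined")
  expect_error(oddspath(0, 0, 28, 63), "no truth variants")
})

test_that("evidence bands map OddsPath to PS3/BS3 strengths", {
  expect_equal(evidence_strength(2.5)$strength, "supporting")
  expect_equal(evidence_strength(18.7)$strength, "strong")
  expect_equal(evidence_strength(349.9)$strength, "strong")
  expect_equal(evidence_strength(351)$strength, "very_strong")
  expect_equal(evidence_strength(18.7)$code, "PS3")
  expect_equal(evidence_strength(0.053)$code, "BS3")
  expect_equal(evidence_strength(0.053)$strength, "strong")
  expect_equal(evidence_strength(0.001)$strength, "very_strong")
  expect_true(is.na(evidence_strength(1.0)$code))
})

test_that("calibration on an engineered truth set matches hand arithmetic", {
  # low class 90% pathogenic (18 P, 2 B), prior 30% (30 P, 70 B):
  # OddsPath = (0.9 * 0.7) / (0.1 * 0.3) = 21 -> strong
  ids <- paste0("v", 1:100)
  classes <- stats::setNames(rep("normal", 100), ids)
  classes[1:20] <- "low"
  truth <- data.frame(variant_id = ids,
                      label = c(rep("PLP", 18), rep("BLB", 2),
                                rep("PLP", 12), rep("BLB", 68)))
  cal <- calibrate_classes(classes, truth)
  low_row <- cal$classes[cal$classes$class == "low", ]
  expect_equal(low_row$oddspath, 21, tolerance = 1e-9)
  expect_equal(low_row$code, "PS3")
  expect_equal(low_row$strength, "strong")
  ev <- assign_functional_evidence(classes, cal)
  expect_equal(ev$strength[ev$variant_id == "v1"], "strong")
})

test_that("truth-set star filtering happens at ingestion", {
  ids <- paste0("v", 1:30)
  classes <- stats::setNames(rep(c("low", "normal"), 15), ids)
  truth <- data.frame(variant_id = ids,
                      label = rep(c("PLP", "BLB"), 15),
                      stars = rep(c(0L, 2L), each = 15))
  cal <- calibrate_classes(classes, truth, min_stars = 1L)
  expect_equal(unname(sum(cal$totals)), 15)
})

test_that("indeterminate variants stay in the prior but form no class", {
  ids <- paste0("v", 1:20)
  classes <- stats::setNames(c(rep("low", 8), rep("normal", 8),
                               rep("indeterminate", 4)), ids)
  truth <- data.frame(variant_id = ids,
                      label = c(rep("PLP", 8), rep("BLB", 8),
                                rep("PLP", 2), rep("BLB", 2)))
  cal <- calibrate_classes(classes, truth)
  expect_equal(unname(cal$totals["PLP"]), 10)  # indeterminates included
  expect_equal(sum(cal$classes$nP + cal$classes$nB), 16)
  ev <- assign_functional_evidence(classes, cal)
  expect_false(any(grepl("v1[7-9]|v20", ev$variant_id)))
})

test_that("the point combiner agrees with brute force on all small profiles", {
  strengths <- c("supporting", "moderate", "strong", "very_strong")
  dirs <- c("pathogenic", "benign")
  items <- expand.grid(direction = dirs, strength = strengths,
                       stringsAsFactors = FALSE)
  for (n_items in 0:3) {
    combos <- if (n_items == 0) list(integer(0)) else {
      asplit(as.matrix(expand.grid(rep(list(seq_len(nrow(items))),
                                       n_items))), 1)
    }
    for (cb in combos) {
      prof <- items[unlist(cb), , drop = FALSE]
      prof$code <- if (nrow(prof)) paste0("EV", seq_len(nrow(prof)))
                   else character(0)
      got <- combine_evidence(prof)
      want <- oracle_combine(prof)
      expect_identical(got$points, want$points)
      expect_identical(got$classification, want$classification)
    }
  }
})

test_that("forced point-table cases land where expected", {
  p <- function(...) {
    df <- data.frame(...)
    combine_evidence(df)
  }
  expect_equal(p(code = c("PS3", "PM5"),
                 direction = c("pathogenic", "pathogenic"),
                 strength = c("strong", "moderate"))$classification, "LP")
  expect_equal(p(code = "BS3", direction = "benign",
                 strength = "strong")$classification, "LB")
  expect_error(p(code = c("PS3", "PS3"),
                 direction = c("pathogenic", "benign"),
                 strength = c("strong", "strong")), "duplicate")
})

test_that("adding pathogenic evidence never moves a call toward benign", {
  rank <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)
  base <- data.frame(code = "BP4", direction = "benign",
                     strength = "moderate")
  prev <- combine_evidence(base)$classification
  for (s in c("supporting", "moderate", "strong", "very_strong")) {
    prof <- rbind(base, data.frame(code = paste0("PX_", s),
                                   direction = "pathogenic", strength = s))
    cur <- combine_evidence(prof)$classification
    expect_gte(rank[[cur]], rank[[prev]])
  }
})

test_that("cohort reclassification summarises the constructed 43-VUS case", {
  # 13 VUS: low class + one moderate pathogenic item -> 6 points -> LP
  # 16 VUS: normal class, no opposing evidence -> -4 -> LB
  # 6 VUS: indeterminate class -> no functional evidence -> VUS
  # 8 VUS: low class alone -> 4 points -> VUS (insufficient other evidence)
  ids <- sprintf("vus%02d", 1:43)
  classes <- stats::setNames(
    c(rep("low", 13), rep("normal", 16), rep("indeterminate", 6),
      rep("low", 8)), ids)
  profiles <- stats::setNames(lapply(1:43, function(i) {
    if (i <= 13) data.frame(code = "PM5", direction = "pathogenic",
                            strength = "moderate")
    else data.frame(code = character(), direction = character(),
                    strength = character())
  }), ids)
  # calibration that maps low -> PS3 strong, normal -> BS3 strong
  cal <- calibrate_classes(
    stats::setNames(c(rep("low", 27), rep("normal", 59),
                      rep("indeterminate", 5)), paste0("t", 1:91)),
    data.frame(variant_id = paste0("t", 1:91),
               label = c(rep("PLP", 26), "BLB", rep("BLB", 59),
                         rep("PLP", 2), rep("BLB", 3))))
  rec <- reclassify_cohort(profiles, classes, cal)
  expect_equal(rec$summary$n, 43)
  expect_equal(rec$summary$n_reclassified, 29)
  expect_equal(rec$summary$to_LP_or_P, 13)
  expect_equal(rec$summary$to_LB_or_B, 16)
  expect_equal(round(100 * rec$summary$n_reclassified / rec$summary$n), 67)
  reasons <- rec$per_variant$reason[rec$per_variant$classification == "VUS"]
  expect_equal(sum(reasons == "indeterminate_score"), 6)
  expect_equal(sum(reasons == "insufficient_other_evidence"), 8)
})

test_that("all-normal cohorts with no opposing evidence all reach LB", {
  ids <- paste0("v", 1:5)
  classes <- stats::setNames(rep("normal", 5), ids)
  profiles <- stats::setNames(replicate(5, data.frame(
    code = character(), direction = character(), strength = character()),
    simplify = FALSE), ids)
  cal <- calibrate_classes(
    stats::setNames(c(rep("low", 27), rep("normal", 60)), paste0("t", 1:87)),
    data.frame(variant_id = paste0("t", 1:87),
               label = c(rep("PLP", 26), rep("BLB", 61))))
  rec <- reclassify_cohort(profiles, classes, cal)
  expect_true(all(rec$per_variant$classification == "LB"))
})

test_that("REVEL scores translate to PP3/BP4 at the strength cutpoints", {
  ev <- revel_evidence(c(a = 0.95, b = 0.7, c = 0.5, d = 0.1, e = NA))
  expect_equal(ev$code[ev$variant_id == "a"], "PP3")
  expect_equal(ev$strength[ev$variant_id == "a"], "strong")
  expect_equal(ev$strength[ev$variant_id == "b"], "supporting")
  expect_false("c" %in% ev$variant_id)
  expect_equal(ev$code[ev$variant_id == "d"], "BP4")
})
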