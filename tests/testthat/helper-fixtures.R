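# Shared fixtures and independent oracles, built in code.

# Single-exon toy region: 60 nt, exon at 13..48 (36 nt = 12 non-stop
# codons, several one substitution away from a stop so the library holds
# enough nonsense designs to anchor normalization), 12-nt intronic flanks.
toy_region_1exon <- function() {
  cds <- "ATGGCTTGGTACCAAGAACGATCATTAAAACGTCAC"
  flank5 <- "TTGACCTGTCAG"
  flank3 <- "GTAAGTACCTGA"
  target_region("toy1", paste0(flank5, cds, flank3),
                rbind(c(13L, 48L)))
}

# Two-exon toy region with a codon split across the junction: exon 1
# carries 10 CDS bases (3 codons + 1), exon 2 carries 14 (2 + 4 codons),
# separated and flanked by 12-nt introns.
toy_region_2exon <- function() {
  cds <- "ATGGCTGAAAAACGTTGGCTGTCT"  # 8 codons, no stop
  ex1 <- substr(cds, 1, 10)
  ex2 <- substr(cds, 11, 24)
  i1 <- "CACTGTGATTAG"; i2 <- "GTTACGATCCTA"; i3 <- "ACGGTCATTGCA"
  target_region("toy2", paste0(i1, ex1, i2, ex2, i3),
                rbind(c(13L, 22L), c(35L, 48L)))
}

# Independent full-CDS retranslation oracle: rebuild the mutant region,
# splice, translate both proteins with Biostrings, and derive the label
# from first principles. Intronic labels from raw boundary distances.
oracle_consequence <- function(pos, alt, region,
                               splice_region_range = c(3L, 8L)) {
  bases <- strsplit(region$sequence, "", fixed = TRUE)[[1L]]
  ei <- region$exon_intervals
  expos <- unlist(lapply(seq_len(nrow(ei)), function(i) ei[i, 1]:ei[i, 2]))
  if (pos %in% expos) {
    splice <- function(b) paste(b[expos], collapse = "")
    mut <- bases
    mut[pos] <- alt
    ref_p <- as.character(Biostrings::translate(
      Biostrings::DNAString(splice(bases)), no.init.codon = TRUE))
    mut_p <- as.character(Biostrings::translate(
      Biostrings::DNAString(splice(mut)), no.init.codon = TRUE))
    if (mut_p == ref_p) return("synonymous")
    rp <- strsplit(ref_p, "")[[1]]
    mp <- strsplit(mut_p, "")[[1]]
    diff <- which(rp != mp)
    if (any(mp[diff] == "*")) return("nonsense")
    return("missense")
  }
  d <- min(abs(pos - expos))
  if (d <= 2) return("canonical_splice")
  if (d >= splice_region_range[1] && d <= splice_region_range[2]) {
    return("splice_region")
  }
  "intronic"
}

# Independent read-classification oracle driven purely by the unit-cost
# edit-distance transformation script (utils::adist), with no anchoring
# heuristics.
oracle_read_call <- function(read, region, designs) {
  amp <- region$sequence
  if (!nzchar(read)) return("unalignable")
  tr <- attr(utils::adist(amp, read, counts = TRUE), "trafos")[1, 1]
  ops <- strsplit(tr, "")[[1]]
  if (any(ops %in% c("I", "D"))) return("indel")
  n_sub <- sum(ops == "S")
  if (n_sub == 0) return("WT")
  if (n_sub >= 2) return("multi_snv")
  p <- which(ops == "S")
  b <- substr(read, p, p)
  designed <- any(designs$position == p & designs$alt == b) &&
    p >= region$design_window[1] && p <= region$design_window[2]
  if (designed) "variant" else "undesigned_snv"
}

# Brute-force ACMG point combiner used as the exhaustive oracle.
oracle_combine <- function(profile) {
  pts_tab <- c(supporting = 1, moderate = 2, strong = 4, very_strong = 8)
  pts <- if (nrow(profile) == 0) 0 else {
    sum(vapply(seq_len(nrow(profile)), function(i) {
      sgn <- if (profile$direction[i] == "pathogenic") 1 else -1
      sgn * pts_tab[[profile$strength[i]]]
    }, numeric(1)))
  }
  cls <- if (pts >= 10) "P" else if (pts >= 6) "LP" else if (pts >= 0) "VUS"
    else if (pts >= -6) "LB" else "B"
  list(points = pts, classification = cls)
}

# Small annotated library + per-bin counts with prescribed per-class bin
# placement (plus deterministic per-variant jitter so score distributions
# are non-degenerate), for abundance tests that do not need the simulator.
toy_abundance_counts <- function(n_rep = 1L) {
  reg <- toy_region_1exon()
  des <- enumerate_snvs(reg)
  n <- nrow(des)
  low <- des$consequence %in% c("nonsense", "canonical_splice")
  counts <- matrix(0L, n, 4L, dimnames = list(des$variant_id, NULL))
  counts[low, ] <- rep(c(60L, 30L, 8L, 2L), each = sum(low))
  counts[!low, ] <- rep(c(2L, 8L, 30L, 60L), each = sum(!low))
  idx <- seq_len(n)
  counts[, 2] <- counts[, 2] + idx %% 3L
  counts[, 4] <- counts[, 4] + idx %% 7L
  cols <- list(); sheet <- list()
  for (r in seq_len(n_rep)) {
    m <- counts
    colnames(m) <- paste0("bin", 1:4, "_r", r)
    cols[[r]] <- m
    sheet[[r]] <- data.frame(sample_id = colnames(m),
                             condition = paste0("bin", 1:4), replicate = r,
                             stringsAsFactors = FALSE)
  }
  mat <- do.call(cbind, cols)
  mat <- rbind(mat, WT = 0L)
  obj <- structure(list(
    counts = mat,
    discards = matrix(0L, 5, ncol(mat),
                      dimnames = list(c("multi_snv", "indel", "unalignable",
                                        "undesigned_snv", "low_quality"),
                                      colnames(mat))),
    samples = do.call(rbind, sheet)), class = "sge_counts")
  list(counts = obj, designs = des, region = reg)
}
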