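DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate a saturation SNV library over a target region
#'
#' Designs every possible single-nucleotide substitution at every position of
#' the region's design window (three alternates per position) and annotates
#' each design's molecular consequence.
#'
#' @param region An [target_region()] object.
#' @param annotate Logical; annotate consequences (default `TRUE`).
#' @param splice_region_range Passed to [annotate_consequence()].
#' @return A data.frame with one row per designed SNV: `variant_id`,
#'   `position` (1-based), `ref`, `alt`, and (if annotated) `consequence`,
#'   `protein_change`, `hgvs_c`.
#' @examples
#' reg <- target_region("toy", "ATGGCTAAATAG", rbind(c(1, 12)))
#' nrow(enumerate_snvs(reg))  # 3 x 12 = 36
#' @export
enumerate_snvs <- function(region, annotate = TRUE,
                           splice_region_range = c(3L, 8L)) {
  dw <- region$design_window
  pos <- dw[1L]:dw[2L]
  bases <- strsplit(region$sequence, "", fixed = TRUE)[[1L]]
  ref <- bases[pos]
  designs <- do.call(rbind, lapply(seq_along(pos), function(i) {
    alts <- setdiff(DNA_BASES, ref[i])
    data.frame(position = pos[i], ref = ref[i], alt = alts,
               stringsAsFactors = FALSE)
  }))
  designs$variant_id <- sprintf("%s:g.%d%s>%s", region$region_id,
                                designs$position, designs$ref, designs$alt)
  designs <- designs[, c("variant_id", "position", "ref", "alt")]
  rownames(designs) <- NULL
  if (annotate) {
    ann <- annotate_consequence(designs, region,
                                splice_region_range = splice_region_range)
    designs <- cbind(designs, ann)
  }
  designs
}

#' Annotate the molecular consequence of designed SNVs
#'
#' Exonic variants are classified by translating the affected codon of the
#' spliced CDS (codons split across exon junctions are assembled from the
#' spliced exonic sequence): a new stop codon is `nonsense`, an unchanged
#' amino acid `synonymous`, anything else `missense`. Intronic variants are
#' classified by distance from the nearest exon boundary: 1-2 nt is
#' `canonical_splice`, within `splice_region_range` (default 3-8 nt, the
#' Sequence Ontology splice-region window) is `splice_region`, deeper is
#' `intronic`. Each variant receives exactly one label; coding consequence
#' takes precedence for exonic positions near a junction.
#'
#' @param designs data.frame with columns `position`, `ref`, `alt` (1-based).
#' @param region An [target_region()] object.
#' @param splice_region_range Length-2 integer vector: the intronic distance
#'   band (inclusive) labelled `splice_region`.
#' @return data.frame with columns `consequence`, `protein_change`, `hgvs_c`
#'   aligned to `designs`.
#' @export
annotate_consequence <- function(designs, region,
                                 splice_region_range = c(3L, 8L)) {
  bases <- strsplit(region$sequence, "", fixed = TRUE)[[1L]]
  if (any(designs$position < 1L | designs$position > length(bases))) {
    stop("variant position outside the region")
  }
  if (any(bases[designs$position] != designs$ref)) {
    bad <- which(bases[designs$position] != designs$ref)[1L]
    stop("ref base mismatch at position ", designs$position[bad])
  }
  if (any(designs$alt == designs$ref)) stop("alt base equals ref base")

  expos <- exonic_positions(region)
  # cds index of each region position (NA for intronic)
  cds_index <- rep(NA_integer_, length(bases))
  cds_index[expos] <- seq_along(expos)
  spliced <- bases[expos]
  phase <- region$cds_phase
  # index (into spliced) of the first base of the first complete codon
  origin <- ((3L - phase) %% 3L) + 1L

  n_des <- nrow(designs)
  consequence <- character(n_des)
  protein_change <- rep(NA_character_, n_des)
  hgvs <- character(n_des)

  for (i in seq_len(n_des)) {
    p <- designs$position[i]
    ci <- cds_index[p]
    if (!is.na(ci)) {
      if (ci < origin) {
        stop("exonic position ", p, " lies upstream of the CDS frame origin")
      }
      codon_no <- (ci - origin) %/% 3L
      idx <- origin + 3L * codon_no + 0:2
      if (max(idx) > length(spliced)) {
        stop("exonic position ", p,
             " falls in an incomplete trailing codon; extend the exon annotation")
      }
      ref_codon <- spliced[idx]
      alt_codon <- ref_codon
      alt_codon[ci - idx[1L] + 1L] <- designs$alt[i]
      ref_aa <- unname(Biostrings::GENETIC_CODE[paste(ref_codon, collapse = "")])
      alt_aa <- unname(Biostrings::GENETIC_CODE[paste(alt_codon, collapse = "")])
      consequence[i] <-
        if (alt_aa == "*" && ref_aa != "*") "nonsense"
        else if (alt_aa == ref_aa) "synonymous"
        else "missense"
      protein_change[i] <- paste0(ref_aa, codon_no + 1L, alt_aa)
      hgvs[i] <- sprintf("c.%d%s>%s",
                         region$cdna_offset + ci - 1L,
                         designs$ref[i], designs$alt[i])
    } else if (length(expos) == 0L) {
      consequence[i] <- "intronic"
      hgvs[i] <- sprintf("g.%d%s>%s", p, designs$ref[i], designs$alt[i])
    } else {
      # intronic: signed distance to the nearest exon edge
      up <- expos[expos < p]     # exon to the left
      down <- expos[expos > p]   # exon to the right
      d_left <- if (length(up)) p - max(up) else NA_integer_
      d_right <- if (length(down)) min(down) - p else NA_integer_
      d <- min(d_left, d_right, na.rm = TRUE)
      consequence[i] <-
        if (d <= 2L) "canonical_splice"
        else if (d >= splice_region_range[1L] && d <= splice_region_range[2L])
          "splice_region"
        else "intronic"
      hgvs[i] <- if (!is.na(d_left) && (is.na(d_right) || d_left <= d_right)) {
        sprintf("c.%d+%d%s>%s",
                region$cdna_offset + cds_index[max(up)] - 1L, d_left,
                designs$ref[i], designs$alt[i])
      } else {
        sprintf("c.%d-%d%s>%s",
                region$cdna_offset + cds_index[min(down)] - 1L, d_right,
                designs$ref[i], designs$alt[i])
      }
    }
  }
  data.frame(consequence = consequence, protein_change = protein_change,
             hgvs_c = hgvs, stringsAsFactors = FALSE)
}

#' Write a designed library to TSV
#'
#' @param designs data.frame from [enumerate_snvs()].
#' @param path Output path.
#' @export
write_design_table <- function(designs, path) {
  utils::write.table(designs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
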