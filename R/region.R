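#' Define a target region for saturation mutagenesis
#'
#' A target region is the coordinate frame shared by every downstream step: an
#' amplicon sequence in coding-strand orientation, the exon structure within
#' it, the reading-frame phase of the first exonic base, and the window of
#' positions to mutagenize. All coordinates are 1-based and intervals are
#' closed (`[start, end]`), following the usual R/Bioconductor convention.
#'
#' @param region_id Character scalar naming the region (e.g. an exon label).
#' @param sequence Nucleotide string over the alphabet `A`, `C`, `G`, `T`,
#'   given in coding-strand orientation.
#' @param exon_intervals Two-column integer matrix (or list of length-2
#'   vectors) of exonic `[start, end]` intervals, 1-based inclusive, sorted
#'   and non-overlapping, within the sequence.
#' @param cds_phase Integer 0-2: number of bases of the first exonic codon
#'   that lie upstream of the region (0 means the first exonic base starts a
#'   codon).
#' @param cdna_offset Integer: transcript (cDNA) coordinate of the first
#'   exonic base, used only for HGVS-style reporting.
#' @param design_window Length-2 integer vector `[start, end]` (1-based,
#'   inclusive) of positions to mutagenize; defaults to the whole sequence.
#'
#' @return An object of class `sge_region`.
#' @examples
#' reg <- target_region("toy", "ATGGCTAAATAG", rbind(c(1, 12)))
#' reg
#' @export
target_region <- function(region_id, sequence, exon_intervals,
                          cds_phase = 0L, cdna_offset = 1L,
                          design_window = NULL) {
  stopifnot(is.character(region_id), length(region_id) == 1L)
  sequence <- toupper(as.character(sequence))
  bad <- gregexpr("[^ACGT]", sequence)[[1L]]
  if (bad[1L] != -1L) {
    stop("non-ACGT base in sequence at position ", bad[1L])
  }
  n <- nchar(sequence)
  if (is.list(exon_intervals)) {
    exon_intervals <- do.call(rbind, exon_intervals)
  }
  exon_intervals <- matrix(as.integer(exon_intervals), ncol = 2L,
                           dimnames = list(NULL, c("start", "end")))
  if (nrow(exon_intervals) > 0L) {
    o <- order(exon_intervals[, 1L])
    exon_intervals <- exon_intervals[o, , drop = FALSE]
    if (any(exon_intervals[, 1L] > exon_intervals[, 2L]) ||
        any(exon_intervals < 1L) || any(exon_intervals > n)) {
      stop("exon intervals must satisfy 1 <= start <= end <= ", n)
    }
    if (nrow(exon_intervals) > 1L &&
        any(exon_intervals[-1L, 1L] <= exon_intervals[-nrow(exon_intervals), 2L])) {
      stop("exon intervals must be disjoint and sorted")
    }
  }
  cds_phase <- as.integer(cds_phase)
  stopifnot(cds_phase >= 0L, cds_phase <= 2L)
  if (is.null(design_window)) design_window <- c(1L, n)
  design_window <- as.integer(design_window)
  stopifnot(length(design_window) == 2L,
            design_window[1L] >= 1L, design_window[2L] <= n,
            design_window[1L] <= design_window[2L])
  structure(
    list(region_id = region_id, sequence = sequence,
         exon_intervals = exon_intervals, cds_phase = cds_phase,
         cdna_offset = as.integer(cdna_offset),
         design_window = design_window),
    class = "sge_region")
}

#' @export
print.sge_region <- function(x, ...) {
  cat("Target region '", x$region_id, "': ", nchar(x$sequence), " nt, ",
      nrow(x$exon_intervals), " exon(s), design window ",
      x$design_window[1L], "-", x$design_window[2L],
      ", CDS phase ", x$cds_phase, "\n", sep = "")
  invisible(x)
}

#' Read a target region from FASTA plus a JSON sidecar
#'
#' The FASTA file holds the amplicon sequence; the JSON sidecar holds the
#' structural annotation (`region_id` optional, `exon_intervals`, `cds_phase`,
#' `cdna_offset`, `design_window`), with intervals 1-based inclusive.
#'
#' @param fasta Path to a single-record FASTA file.
#' @param json Path to the JSON annotation sidecar.
#' @return An `sge_region`.
#' @export
read_target_region <- function(fasta, json) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("expected exactly one FASTA record, got ", length(seqs))
  ann <- jsonlite::read_json(json, simplifyVector = TRUE)
  target_region(
    region_id = if (!is.null(ann$region_id)) ann$region_id else names(seqs)[1L],
    sequence = as.character(seqs[[1L]]),
    exon_intervals = matrix(as.integer(unlist(ann$exon_intervals)),
                            ncol = 2L, byrow = is.list(ann$exon_intervals)),
    cds_phase = ann$cds_phase %||% 0L,
    cdna_offset = ann$cdna_offset %||% 1L,
    design_window = ann$design_window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Positions (1-based) of all exonic bases, in splicing order.
exonic_positions <- function(region) {
  ei <- region$exon_intervals
  if (nrow(ei) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(ei)), function(i) ei[i, 1L]:ei[i, 2L]))
}

# Spliced exonic sequence as a character vector of single bases.
spliced_bases <- function(region) {
  strsplit(region$sequence, "", fixed = TRUE)[[1L]][exonic_positions(region)]
}

# Reverse-complement a region, mirroring every coordinate, so that the same
# biology is described from the opposite strand. Used for strand-convention
# property checks.
reverse_region <- function(region) {
  n <- nchar(region$sequence)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(region$sequence)))
  ei <- region$exon_intervals
  mirrored <- cbind(n - ei[, 2L] + 1L, n - ei[, 1L] + 1L)
  target_region(region$region_id, rc, mirrored,
                cds_phase = region$cds_phase,
                cdna_offset = region$cdna_offset,
                design_window = c(n - region$design_window[2L] + 1L,
                                  n - region$design_window[1L] + 1L))
}
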