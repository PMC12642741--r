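#' Parameters for paired-end read merging
#'
#' Defaults mirror the assembly settings used for SGE amplicon data:
#' assembled length within \[30, 300\] and mean assembled quality at least
#' Q30.
#'
#' @param min_assembled_length,max_assembled_length Allowed merged length.
#' @param quality_threshold Minimum mean phred quality of the merged read.
#' @param min_overlap Minimum mate overlap in nt.
#' @return A list of class `sge_merge_params`.
#' @export
merge_params <- function(min_assembled_length = 30L,
                         max_assembled_length = 300L,
                         quality_threshold = 30,
                         min_overlap = 10L) {
  stopifnot(min_assembled_length > 0L,
            min_assembled_length <= max_assembled_length,
            min_overlap >= 1L)
  structure(list(min_assembled_length = as.integer(min_assembled_length),
                 max_assembled_length = as.integer(max_assembled_length),
                 quality_threshold = quality_threshold,
                 min_overlap = as.integer(min_overlap)),
            class = "sge_merge_params")
}

#' Merge one read pair by ungapped overlap
#'
#' The reverse mate is reverse-complemented, then every ungapped overlap of at
#' least `min_overlap` nt between the forward read's suffix and the reverse
#' mate's prefix is scored as matches minus mismatches; the best-scoring
#' overlap wins (ties go to the longer overlap). At disagreeing overlap
#' positions the higher-quality base is kept (its quality retained); at
#' agreeing positions the higher of the two qualities is kept.
#'
#' @param r1,r2 Nucleotide strings (R2 in sequencing orientation).
#' @param q1,q2 Numeric phred quality vectors matching `r1`/`r2`.
#' @param params [merge_params()].
#' @return A list with `status` (`"merged"` or a rejection reason among
#'   `"no_overlap"`, `"too_short"`, `"too_long"`, `"low_quality"`), and for
#'   merged pairs `sequence` and `qualities`.
#' @export
merge_pair <- function(r1, q1, r2, q2, params = merge_params()) {
  stopifnot(nzchar(r1), nzchar(r2),
            length(q1) == nchar(r1), length(q2) == nchar(r2))
  s1 <- strsplit(toupper(r1), "", fixed = TRUE)[[1L]]
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r2)))
  s2 <- strsplit(toupper(rc2), "", fixed = TRUE)[[1L]]
  q2 <- rev(q2)
  n1 <- length(s1); n2 <- length(s2)

  if (min(n1, n2) < params$min_overlap) return(list(status = "no_overlap"))
  best <- NULL
  for (ov in seq(min(n1, n2), params$min_overlap)) {
    a <- s1[(n1 - ov + 1L):n1]
    b <- s2[1:ov]
    score <- sum(a == b) - sum(a != b)
    if (is.null(best) || score > best$score) best <- list(ov = ov, score = score)
  }
  if (is.null(best)) return(list(status = "no_overlap"))
  ov <- best$ov
  merged_len <- n1 + n2 - ov
  if (merged_len < params$min_assembled_length) return(list(status = "too_short"))
  if (merged_len > params$max_assembled_length) return(list(status = "too_long"))

  seq_out <- c(s1, s2[(ov + 1L):n2][seq_len(n2 - ov)])
  qual_out <- c(q1, q2[(ov + 1L):n2][seq_len(n2 - ov)])
  # resolve the overlapped stretch
  for (k in seq_len(ov)) {
    i1 <- n1 - ov + k
    b1 <- s1[i1]; b2 <- s2[k]
    if (b1 == b2) {
      qual_out[i1] <- max(q1[i1], q2[k])
    } else if (q2[k] > q1[i1]) {
      seq_out[i1] <- b2
      qual_out[i1] <- q2[k]
    }
  }
  if (mean(qual_out) < params$quality_threshold) return(list(status = "low_quality"))
  list(status = "merged",
       sequence = paste(seq_out, collapse = ""),
       qualities = qual_out)
}

#' Classify one amplicon read against a designed SNV library
#'
#' Reads spanning the full amplicon are compared base-by-base: zero
#' mismatches is wild type; exactly one mismatch at a designed
#' (position, alt) pair is that variant; one mismatch not in the design (or
#' a designed SNV outside the design window) is an undesigned SNV; two or
#' more mismatches means multiple SNVs and the read is filtered. A read of
#' the wrong length is an indel if it can be anchored to the amplicon (exact
#' match of a terminal anchor, or a unit-cost edit alignment whose optimum
#' contains a gap within the edit budget); otherwise it is unalignable.
#'
#' @param read Nucleotide string (merged/pre-merged read).
#' @param region [target_region()]; the amplicon is the full region sequence.
#' @param designs Design table from [enumerate_snvs()].
#' @param anchor_len Terminal anchor length for indel anchoring (default 12).
#' @param max_edit_frac Maximum edit distance, as a fraction of the amplicon
#'   length, beyond which an unanchored read is unalignable (default 0.3).
#' @return A list with `call` (one of `WT`, `variant`, `multi_snv`, `indel`,
#'   `unalignable`, `undesigned_snv`) and `variant_id` (for `variant` calls).
#' @export
classify_read <- function(read, region, designs, anchor_len = 12L,
                          max_edit_frac = 0.3) {
  amp <- region$sequence
  n <- nchar(amp)
  read <- toupper(read)
  if (!nzchar(read)) return(list(call = "unalignable", variant_id = NA_character_))

  if (nchar(read) == n) {
    a <- strsplit(amp, "", fixed = TRUE)[[1L]]
    b <- strsplit(read, "", fixed = TRUE)[[1L]]
    mm <- which(a != b)
    if (length(mm) == 0L) return(list(call = "WT", variant_id = NA_character_))
    if (length(mm) == 1L) {
      p <- mm[1L]
      hit <- designs$variant_id[designs$position == p & designs$alt == b[p]]
      in_window <- p >= region$design_window[1L] & p <= region$design_window[2L]
      if (length(hit) == 1L && in_window) {
        return(list(call = "variant", variant_id = hit))
      }
      return(list(call = "undesigned_snv", variant_id = NA_character_))
    }
    return(list(call = "multi_snv", variant_id = NA_character_))
  }

  # length mismatch: indel vs unalignable
  k <- min(anchor_len, n, nchar(read))
  anchored <-
    substr(read, 1L, k) == substr(amp, 1L, k) ||
    substr(read, nchar(read) - k + 1L, nchar(read)) ==
      substr(amp, n - k + 1L, n)
  if (anchored) return(list(call = "indel", variant_id = NA_character_))
  d <- utils::adist(amp, read)[1L, 1L]
  if (d <= max_edit_frac * n) {
    # lengths differ, so any optimal unit-cost path must contain a gap
    return(list(call = "indel", variant_id = NA_character_))
  }
  list(call = "unalignable", variant_id = NA_character_)
}

#' Count designed variants across samples
#'
#' Applies [classify_read()] to every read of every sample and tallies
#' per-variant counts (plus a reserved wild-type row) and per-sample discard
#' reasons. Reads may be given in-memory (`samples$reads` as a list of
#' character vectors), as pre-merged FASTQ paths (`samples$fastq`), or as
#' mate-pair FASTQ paths (`samples$fastq1`/`samples$fastq2`, merged with
#' [merge_pair()]).
#'
#' @param samples data.frame with `sample_id`, `condition`, `replicate` and a
#'   read source column as above.
#' @param region [target_region()].
#' @param designs Design table from [enumerate_snvs()].
#' @param merge [merge_params()] used when mate pairs are supplied.
#' @param ... Passed to [classify_read()].
#' @return An object of class `sge_counts`: list with `counts` (variants +
#'   `"WT"` by samples integer matrix), `discards` (reason-by-sample matrix
#'   over `multi_snv`, `indel`, `unalignable`, `undesigned_snv`,
#'   `low_quality`), and `samples`.
#' @export
count_variants <- function(samples, region, designs,
                           merge = merge_params(), ...) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L)
  vids <- c(designs$variant_id, "WT")
  counts <- matrix(0L, nrow = length(vids), ncol = nrow(samples),
                   dimnames = list(vids, samples$sample_id))
  reasons <- c("multi_snv", "indel", "unalignable", "undesigned_snv",
               "low_quality")
  discards <- matrix(0L, nrow = length(reasons), ncol = nrow(samples),
                     dimnames = list(reasons, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    reads <- sample_reads(samples[j, , drop = FALSE], merge)
    discards["low_quality", j] <- reads$n_unmerged
    for (rd in reads$reads) {
      cl <- classify_read(rd, region, designs, ...)
      if (cl$call == "variant") {
        counts[cl$variant_id, j] <- counts[cl$variant_id, j] + 1L
      } else if (cl$call == "WT") {
        counts["WT", j] <- counts["WT", j] + 1L
      } else {
        discards[cl$call, j] <- discards[cl$call, j] + 1L
      }
    }
  }
  structure(list(counts = counts, discards = discards, samples = samples),
            class = "sge_counts")
}

# Resolve one sample's reads; returns list(reads = character(), n_unmerged).
sample_reads <- function(sample, merge) {
  if (!is.null(sample$reads)) {
    return(list(reads = sample$reads[[1L]], n_unmerged = 0L))
  }
  if (!is.null(sample$fastq1) && !is.na(sample$fastq1)) {
    f1 <- read_fastq(sample$fastq1)
    f2 <- read_fastq(sample$fastq2)
    if (length(f1$seq) != length(f2$seq)) {
      stop("mate FASTQ files differ in record count for sample ",
           sample$sample_id)
    }
    merged <- character(0)
    n_rej <- 0L
    for (i in seq_along(f1$seq)) {
      m <- merge_pair(f1$seq[i], f1$qual[[i]], f2$seq[i], f2$qual[[i]], merge)
      if (m$status == "merged") merged <- c(merged, m$sequence)
      else n_rej <- n_rej + 1L
    }
    return(list(reads = merged, n_unmerged = n_rej))
  }
  if (!is.null(sample$fastq) && !is.na(sample$fastq)) {
    return(list(reads = read_fastq(sample$fastq)$seq, n_unmerged = 0L))
  }
  stop("sample ", sample$sample_id, " has no read source")
}

# Minimal FASTQ reader returning sequences and numeric phred qualities.
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  quals <- S4Vectors::mcols(x)$qualities
  list(seq = as.character(x),
       qual = lapply(as.character(quals), function(q) {
         as.integer(charToRaw(q)) - 33L
       }))
}

#' @export
print.sge_counts <- function(x, ...) {
  cat("SGE variant count table: ", nrow(x$counts) - 1L, " designed variants",
      " (+WT row), ", ncol(x$counts), " sample(s)\n", sep = "")
  tot <- colSums(x$counts) + colSums(x$discards)
  cat("reads/sample: ", paste0(colnames(x$counts), "=", tot, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a count table and its discard sidecar to TSV
#'
#' @param x An `sge_counts` object.
#' @param path Count table path; the discard summary is written next to it
#'   with suffix `.discards.tsv`.
#' @export
write_count_table <- function(x, path) {
  utils::write.table(data.frame(variant_id = rownames(x$counts), x$counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(reason = rownames(x$discards), x$discards,
                                check.names = FALSE),
                     sub("\\.tsv$", "", path) |> paste0(".discards.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()] (or any TSV with a
#' `variant_id` column followed by sample columns)
#'
#' @param path Count table TSV.
#' @param samples Optional sample sheet data.frame.
#' @return An `sge_counts` (discards zeroed if no sidecar is present).
#' @export
read_count_table <- function(path, samples = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$variant_id
  side <- sub("\\.tsv$", "", path) |> paste0(".discards.tsv")
  reasons <- c("multi_snv", "indel", "unalignable", "undesigned_snv",
               "low_quality")
  discards <- matrix(0L, length(reasons), ncol(counts),
                     dimnames = list(reasons, colnames(counts)))
  if (file.exists(side)) {
    dd <- utils::read.delim(side, check.names = FALSE)
    discards[dd$reason, colnames(counts)] <-
      as.matrix(dd[, colnames(counts), drop = FALSE])
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(counts),
                          condition = colnames(counts), replicate = 1L)
  }
  structure(list(counts = counts, discards = discards, samples = samples),
            class = "sge_counts")
}
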