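rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("perfectly overlapping halves reassemble the template", {
  reg <- toy_region_1exon()
  tmpl <- reg$sequence  # 60 nt
  r1 <- substr(tmpl, 1, 40)
  r2 <- rc(substr(tmpl, 21, 60))
  m <- merge_pair(r1, rep(37, 40), r2, rep(37, 40))
  expect_equal(m$status, "merged")
  expect_identical(m$sequence, tmpl)
})

test_that("assembled length below the minimum is rejected", {
  tmpl <- "GATTACAGGCTGACCTGTAAGCTCGATCC"  # 29 nt, aperiodic
  r1 <- substr(tmpl, 1, 20)
  r2 <- rc(substr(tmpl, 10, 29))
  m <- merge_pair(r1, rep(37, 20), r2, rep(37, 20))
  expect_equal(m$status, "too_short")  # merged length 29 < 30
  m2 <- merge_pair(r1, rep(37, 20), r2, rep(37, 20),
                   merge_params(min_assembled_length = 20))
  expect_equal(m2$status, "merged")
  expect_identical(m2$sequence, tmpl)
})

test_that("disagreements in the overlap resolve to the higher-quality base", {
  tmpl <- "GATTACAGGCTGACCTGTAAGCTCGATCCAGT"  # 32 nt, aperiodic
  r1 <- substr(tmpl, 1, 20)
  r2_frag <- substr(tmpl, 9, 32)
  # corrupt the forward read inside the overlap (position 15) with low quality
  r1_bad <- r1
  substr(r1_bad, 15, 15) <- if (substr(r1, 15, 15) == "A") "C" else "A"
  q1 <- rep(37, 20); q1[15] <- 5
  m <- merge_pair(r1_bad, q1, rc(r2_frag), rep(37, 24),
                  merge_params(min_assembled_length = 20))
  expect_equal(m$status, "merged")
  expect_identical(m$sequence, tmpl)
})

test_that("chosen overlap matches an exhaustive offset scan on toy mates", {
  with_seed <- sgescore:::with_seed
  with_seed(42, {
    for (trial in 1:25) {
      n <- sample(40:70, 1)
      tmpl <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      l1 <- sample(20:40, 1); l2 <- sample(20:40, 1)
      l1 <- min(l1, n); l2 <- min(l2, n)
      r1 <- substr(tmpl, 1, l1)
      r2f <- substr(tmpl, n - l2 + 1, n)
      true_ov <- l1 + l2 - n
      if (true_ov < 10) next
      m <- merge_pair(r1, rep(37, l1), rc(r2f), rep(37, l2),
                      merge_params(min_assembled_length = 10))
      # exhaustive oracle over all ungapped offsets
      s1 <- strsplit(r1, "")[[1]]; s2 <- strsplit(r2f, "")[[1]]
      best <- -Inf; best_ov <- NA
      for (ov in seq(min(l1, l2), 10)) {
        a <- s1[(l1 - ov + 1):l1]; b <- s2[1:ov]
        sc <- sum(a == b) - sum(a != b)
        if (sc > best) { best <- sc; best_ov <- ov }
      }
      expect_equal(m$status, "merged")
      expect_equal(nchar(m$sequence), l1 + l2 - best_ov)
    }
  })
})

test_that("read classification handles identity, single and double SNVs", {
  reg <- toy_region_1exon()
  des <- enumerate_snvs(reg)
  amp <- reg$sequence
  expect_equal(classify_read(amp, reg, des)$call, "WT")
  one <- amp
  substr(one, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                 substr(amp, 20, 20))[1]
  cl <- classify_read(one, reg, des)
  expect_equal(cl$call, "variant")
  expect_equal(cl$variant_id,
               des$variant_id[des$position == 20 &
                                des$alt == substr(one, 20, 20)])
  two <- one
  substr(two, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                 substr(amp, 40, 40))[1]
  expect_equal(classify_read(two, reg, des)$call, "multi_snv")
  expect_equal(classify_read("", reg, des)$call, "unalignable")
})

test_that("single SNVs outside the design window are undesigned", {
  base <- toy_region_1exon()
  reg <- target_region(base$region_id, base$sequence, base$exon_intervals,
                       design_window = c(13L, 48L))
  des <- enumerate_snvs(reg)
  read <- reg$sequence
  substr(read, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                substr(reg$sequence, 3, 3))[1]
  expect_equal(classify_read(read, reg, des)$call, "undesigned_snv")
})

test_that("classification agrees with the edit-distance oracle for every injected mutation", {
  amp30 <- "ACGGTCATTGCAATGGCTGAACACCGTTGG"
  reg <- target_region("amp30", amp30, rbind(c(1L, 30L)))
  des <- enumerate_snvs(reg, annotate = FALSE)
  reads <- character(0)
  for (p in 1:30) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(amp30, p, p))) {
      r <- amp30; substr(r, p, p) <- b
      reads <- c(reads, r)
    }
  }
  for (p in 0:30) {
    for (b in c("A", "C", "G", "T")) {
      reads <- c(reads, paste0(substr(amp30, 0, p), b,
                               substr(amp30, p + 1, 30)))
    }
  }
  for (p in 1:30) {
    reads <- c(reads, paste0(substr(amp30, 1, p - 1), substr(amp30, p + 1, 30)))
  }
  got <- vapply(reads, function(r) classify_read(r, reg, des)$call,
                character(1), USE.NAMES = FALSE)
  want <- vapply(reads, oracle_read_call, character(1),
                 region = reg, designs = des, USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("counting conserves reads across counted and discarded", {
  reg <- toy_region_1exon()
  des <- enumerate_snvs(reg)
  amp <- reg$sequence
  v <- amp; substr(v, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                         substr(amp, 25, 25))[1]
  two <- v; substr(two, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                           substr(amp, 40, 40))[1]
  reads <- c(rep(amp, 6), rep(v, 3), two)
  smp <- data.frame(sample_id = "s1", condition = "bin1", replicate = 1L)
  smp$reads <- list(reads)
  ct <- count_variants(smp, reg, des)
  vid <- des$variant_id[des$position == 25 & des$alt == substr(v, 25, 25)]
  expect_equal(unname(ct$counts[vid, 1]), 3L)
  expect_equal(unname(ct$counts["WT", 1]), 6L)
  expect_equal(unname(ct$discards["multi_snv", 1]), 1L)
  expect_equal(sum(ct$counts) + sum(ct$discards), length(reads))
})

test_that("an empty FASTQ yields an all-zero column with zero discards", {
  reg <- toy_region_1exon()
  des <- enumerate_snvs(reg)
  fq <- tempfile(fileext = ".fastq")
  file.create(fq)
  smp <- data.frame(sample_id = "empty", condition = "bin1",
                    replicate = 1L, fastq = fq)
  ct <- count_variants(smp, reg, des)
  expect_true(all(ct$counts == 0L))
  expect_true(all(ct$discards == 0L))
})

test_that("noise-free simulated FASTQ is inverted exactly by counting", {
  reg <- toy_region_1exon()
  des <- enumerate_snvs(reg)
  cfg <- sim_config(cells_per_variant = 40, reads_per_variant_per_bin = 15,
                    error_rate = 0, indel_rate = 0, wt_fraction = 0.05)
  tr <- assign_true_effects(des, cfg, seed = 1)
  fq <- simulate_sortseq(tr, reg, des, cfg, seed = 2, output = "fastq",
                         dir = tempfile("rt"))
  ct <- count_variants(fq$samples, reg, des)
  expect_identical(ct$counts, fq$counts$counts)
  expect_true(all(ct$discards == 0L))
})

test_that("raising the error rate never rescues reads into designed variants", {
  reg <- toy_region_1exon()
  des <- enumerate_snvs(reg)
  amp <- strsplit(reg$sequence, "")[[1]]
  L <- length(amp)
  sgescore:::with_seed(7, {
    # 60 variant reads; coupled corruption: error positions for the lower
    # rate are a subset of those for the higher rate
    picks <- sample(nrow(des), 60, TRUE)
    err_pos <- lapply(1:60, function(i) sample.int(L, 3))
    assigned <- sapply(c(0, 1, 2, 3), function(k) {
      n_assigned <- 0
      for (i in 1:60) {
        rd <- amp
        rd[des$position[picks[i]]] <- des$alt[picks[i]]
        if (k > 0) {
          at <- err_pos[[i]][seq_len(k)]
          rd[at] <- vapply(rd[at], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        }
        cl <- classify_read(paste(rd, collapse = ""), reg, des)
        if (cl$call == "variant") n_assigned <- n_assigned + 1
      }
      n_assigned
    })
    expect_true(all(diff(assigned) <= 0))
    expect_equal(assigned[1], 60)
  })
})

test_that("mate-pair FASTQ input is merged then counted", {
  reg <- toy_region_1exon()
  des <- enumerate_snvs(reg)
  amp <- reg$sequence
  v <- amp; substr(v, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                         substr(amp, 30, 30))[1]
  d <- tempfile("pairs"); dir.create(d)
  write_fq <- function(path, seqs) {
    con <- file(path, "w")
    for (i in seq_along(seqs)) {
      writeLines(c(paste0("@r", i), seqs[i], "+",
                   strrep("F", nchar(seqs[i]))), con)
    }
    close(con)
  }
  tmpls <- c(amp, v, v)
  write_fq(file.path(d, "r1.fastq"), substr(tmpls, 1, 40))
  write_fq(file.path(d, "r2.fastq"),
           vapply(substr(tmpls, 21, 60), rc, character(1)))
  smp <- data.frame(sample_id = "p1", condition = "bin1", replicate = 1L,
                    fastq1 = file.path(d, "r1.fastq"),
                    fastq2 = file.path(d, "r2.fastq"))
  ct <- count_variants(smp, reg, des)
  vid <- des$variant_id[des$position == 30 & des$alt == substr(v, 30, 30)]
  expect_equal(unname(ct$counts["WT", 1]), 1L)
  expect_equal(unname(ct$counts[vid, 1]), 2L)
})
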