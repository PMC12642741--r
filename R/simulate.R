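#' Configuration for the synthetic-data generator
#'
#' One config drives every simulation mode. Defaults describe a typical SGE
#' experiment: sort-seq with four quartile bins and multiplicative
#' fluorescence noise, 14-day outgrowth at roughly nine population doublings
#' with strong negative selection on damaging variants, and a two-guide
#' knockout screen with 200 non-targeting controls.
#'
#' @param missense_low_prop Probability that a missense or splice-region
#'   variant is functionally damaging (low abundance / depleted).
#' @param normal_center,normal_sd,low_center,low_sd Latent normalized-score
#'   distributions per class (normal class centered at 1, low class at 0,
#'   on the abundance-score scale); latent scores are floored at
#'   `latent_floor`.
#' @param latent_floor Minimum latent score (keeps the fluorescence ratio
#'   positive).
#' @param cells_per_variant Cells carrying each variant at sort time.
#' @param ratio_log2_sd Per-cell fluorescence-ratio noise, sd on the log2
#'   scale (multiplicative lognormal noise).
#' @param n_bins Number of sort bins (4 quartile bins, or 2 for
#'   negative/positive gating).
#' @param reads_per_variant_per_bin Sequencing depth: bin read total is this
#'   times the number of designed variants.
#' @param error_rate Per-base substitution error rate.
#' @param indel_rate Per-read indel contamination rate.
#' @param wt_fraction Fraction of unedited (wild-type) cells in the pool.
#' @param doublings Population doublings between reference and endpoint
#'   (default 9, for a 14-day outgrowth).
#' @param sel_low Selection coefficient of damaging variants (relative
#'   growth `1 + s` per doubling).
#' @param dn_fraction Fraction of damaging missense variants acting as
#'   dominant negatives (depleted on both backgrounds) rather than simple
#'   loss of function (depleted on the null background only).
#' @param reads_per_variant Growth-mode sequencing depth per variant.
#' @param representation_log_sd Lognormal sd of plasmid-library variant
#'   representation.
#' @param frac_labeled Fraction of variants carrying a clinical truth label.
#' @param label_noise Probability a truth label contradicts the variant's
#'   functional class.
#' @param aux_evidence_prob Probability a variant carries one auxiliary
#'   (non-functional) evidence item.
#' @param n_genes,guides_per_gene,n_nontargeting,essential_fraction,
#'   screen_effect,reads_per_guide Screen-mode layout and effect size.
#' @param neuron_essential_fraction Fraction of non-iPSC-essential genes
#'   essential only after neuron differentiation.
#' @return List of class `sge_sim_config`.
#' @export
sim_config <- function(missense_low_prop = 0.35,
                       normal_center = 1, normal_sd = 0.05,
                       low_center = 0.05, low_sd = 0.03,
                       latent_floor = 0.01,
                       cells_per_variant = 2000L, ratio_log2_sd = 0.35,
                       n_bins = 4L,
                       reads_per_variant_per_bin = 500L,
                       error_rate = 0.001, indel_rate = 0.0002,
                       wt_fraction = 0.02,
                       doublings = 9, sel_low = -0.4, dn_fraction = 0.2,
                       reads_per_variant = 1000L,
                       representation_log_sd = 0.3,
                       frac_labeled = 0.2, label_noise = 0.05,
                       aux_evidence_prob = 0.3,
                       n_genes = 500L, guides_per_gene = 2L,
                       n_nontargeting = 200L, essential_fraction = 0.1,
                       screen_effect = -0.4, reads_per_guide = 500L,
                       neuron_essential_fraction = 0.1) {
  cfg <- as.list(environment())
  stopifnot(missense_low_prop >= 0, missense_low_prop <= 1,
            error_rate >= 0, indel_rate >= 0, n_bins >= 2L,
            cells_per_variant >= 1L)
  structure(cfg, class = "sge_sim_config")
}

#' Simulate a target region with a valid exon layout
#'
#' Generates a random ACGT sequence whose exonic portion is assembled from
#' non-stop codons (so the reference CDS translates without an internal
#' stop), with intronic flanks and separators of at least 12 nt, CDS phase
#' 0, and the whole sequence as design window.
#'
#' @param length Total region length (>= 30).
#' @param n_exons Number of exons (default 1).
#' @param seed Integer seed.
#' @return An [target_region()] object.
#' @export
simulate_region <- function(length, n_exons = 1L, seed = 1L) {
  stopifnot(length >= 30L, n_exons >= 1L)
  n_introns <- n_exons + 1L
  intron_each <- 12L
  exon_total <- length - n_introns * intron_each
  exon_total <- exon_total - (exon_total %% 3L)
  if (exon_total < 3L * n_exons) {
    stop("infeasible layout: region of length ", length, " cannot hold ",
         n_exons, " exon(s) with ", intron_each, "-nt introns")
  }
  with_seed(seed, {
    n_codons <- exon_total %/% 3L
    codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    cds <- paste(sample(codons, n_codons, replace = TRUE), collapse = "")
    # split the CDS across exons (multiples of one base; junctions may split
    # codons)
    cuts <- if (n_exons > 1L) {
      sort(sample(seq_len(exon_total - 1L), n_exons - 1L))
    } else integer(0)
    exon_lens <- diff(c(0L, cuts, exon_total))
    # distribute leftover intronic bases onto the last intron
    leftover <- length - exon_total - n_introns * intron_each
    intron_lens <- rep(intron_each, n_introns)
    intron_lens[n_introns] <- intron_lens[n_introns] + leftover
    rand_seq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                  collapse = "")
    pieces <- character(0)
    intervals <- matrix(0L, n_exons, 2L)
    pos <- 0L
    cds_off <- 0L
    for (i in seq_len(n_exons)) {
      pieces <- c(pieces, rand_seq(intron_lens[i]))
      pos <- pos + intron_lens[i]
      ex <- substr(cds, cds_off + 1L, cds_off + exon_lens[i])
      pieces <- c(pieces, ex)
      intervals[i, ] <- c(pos + 1L, pos + exon_lens[i])
      pos <- pos + exon_lens[i]
      cds_off <- cds_off + exon_lens[i]
    }
    pieces <- c(pieces, rand_seq(intron_lens[n_introns]))
    target_region(paste0("sim", seed), paste(pieces, collapse = ""),
                  intervals, cds_phase = 0L, cdna_offset = 1L)
  })
}

#' Assign latent functional effects to a designed library
#'
#' Nonsense and canonical splice variants are damaging (low class);
#' synonymous and deep intronic variants are normal; missense and
#' splice-region variants are damaging with probability
#' `missense_low_prop`. Each variant draws a latent abundance score from its
#' class distribution, a selection coefficient per genetic background, and a
#' mechanism label (damaging missense are dominant negatives with
#' probability `dn_fraction`, otherwise loss of function; dominant negatives
#' carry negative selection on both backgrounds, loss of function on the
#' null background only).
#'
#' @param designs Annotated design table from [enumerate_snvs()].
#' @param config [sim_config()].
#' @param seed Integer seed.
#' @return data.frame of class `sge_sim_truth`: `variant_id`, `consequence`,
#'   `class` (`low`/`normal`), `latent_score`, `s_null`, `s_partial`,
#'   `mechanism`.
#' @export
assign_true_effects <- function(designs, config = sim_config(), seed = 1L) {
  with_seed(seed, {
    n <- nrow(designs)
    cons <- designs$consequence
    cls <- ifelse(cons %in% c("nonsense", "canonical_splice"), "low",
           ifelse(cons %in% c("synonymous", "intronic"), "normal", NA))
    amb <- is.na(cls)
    cls[amb] <- ifelse(stats::runif(sum(amb)) < config$missense_low_prop,
                       "low", "normal")
    latent <- ifelse(cls == "low",
                     stats::rnorm(n, config$low_center, config$low_sd),
                     stats::rnorm(n, config$normal_center, config$normal_sd))
    latent <- pmax(latent, config$latent_floor)
    mech <- rep("functionally_normal", n)
    low <- cls == "low"
    mech[low] <- "loss_of_function"
    dn <- low & cons == "missense" &
      stats::runif(n) < config$dn_fraction
    mech[dn] <- "dominant_negative"
    s_null <- ifelse(low, config$sel_low, 0)
    s_partial <- ifelse(mech == "dominant_negative", config$sel_low, 0)
    out <- data.frame(variant_id = designs$variant_id, consequence = cons,
                      class = cls, latent_score = latent,
                      s_null = s_null, s_partial = s_partial,
                      mechanism = mech, stringsAsFactors = FALSE)
    class(out) <- c("sge_sim_truth", "data.frame")
    out
  })
}

#' Simulate a sort-seq abundance experiment
#'
#' Forward model: every variant contributes `cells_per_variant` cells (plus
#' a wild-type fraction); each cell's fluorescence ratio is the variant's
#' latent score times lognormal noise (`ratio_log2_sd` on the log2 scale);
#' cells are cut at quartile gates computed on the pooled ratio distribution
#' (for 2 bins, at the pooled median); each bin's reads are drawn
#' multinomially from its cell composition; sequencing noise then reassigns
#' or discards reads (substitution errors at `error_rate` per base, indels
#' at `indel_rate` per read).
#'
#' With `output = "counts"` the classification outcome of each read is
#' simulated directly and returned as an `sge_counts` table; with
#' `output = "fastq"` actual reads are written per bin (constant Q37
#' qualities) for processing with [count_variants()].
#'
#' @param truth [assign_true_effects()] result.
#' @param region,designs The region and design table.
#' @param config [sim_config()].
#' @param seed Integer seed.
#' @param output `"counts"` (default) or `"fastq"`.
#' @param dir Output directory for FASTQ mode.
#' @return List with `counts` (`sge_counts`; in FASTQ mode the noise-free
#'   generating per-bin counts), `truth`, `gates` (ratio cutpoints on the
#'   log2 scale), `occupancy` (cells per variant per bin), and in FASTQ mode
#'   `samples` (sheet with file paths) and `manifest` (path to a truth
#'   JSON).
#' @export
simulate_sortseq <- function(truth, region, designs, config = sim_config(),
                             seed = 1L, output = c("counts", "fastq"),
                             dir = NULL) {
  output <- match.arg(output)
  with_seed(seed, {
    stopifnot(config$cells_per_variant >= 1L)
    n_var <- nrow(designs)
    latent <- truth$latent_score[match(designs$variant_id, truth$variant_id)]
    n_wt <- round(config$wt_fraction * n_var * config$cells_per_variant)
    units <- c(designs$variant_id, if (n_wt > 0) "WT")
    n_cells <- c(rep(config$cells_per_variant, n_var),
                 if (n_wt > 0) n_wt)
    centers <- log2(c(latent, if (n_wt > 0) config$normal_center))
    owner <- rep(seq_along(units), n_cells)
    ratio <- centers[owner] + stats::rnorm(length(owner), 0,
                                           config$ratio_log2_sd)
    probs <- seq(0, 1, length.out = config$n_bins + 1L)
    gates <- stats::quantile(ratio, probs[-c(1L, length(probs))])
    bin <- findInterval(ratio, gates) + 1L
    occupancy <- matrix(0L, length(units), config$n_bins,
                        dimnames = list(units, NULL))
    tab <- table(factor(owner, levels = seq_along(units)),
                 factor(bin, levels = seq_len(config$n_bins)))
    occupancy[] <- as.integer(tab)

    reads_per_bin <- config$reads_per_variant_per_bin * n_var
    bin_names <- if (config$n_bins == 2L) c("mApple_neg", "mApple_pos")
                 else paste0("bin", seq_len(config$n_bins))
    gen_counts <- matrix(0L, length(units), config$n_bins,
                         dimnames = list(units, bin_names))
    for (b in seq_len(config$n_bins)) {
      if (sum(occupancy[, b]) == 0L) next
      gen_counts[, b] <- stats::rmultinom(1L, reads_per_bin,
                                          occupancy[, b])[, 1L]
    }
    if (!("WT" %in% units)) {
      gen_counts <- rbind(gen_counts, WT = 0L)
      units <- c(units, "WT")
    }

    samples <- data.frame(sample_id = bin_names, condition = bin_names,
                          replicate = 1L, stringsAsFactors = FALSE)
    if (output == "counts") {
      counts <- sortseq_noise_counts(gen_counts, region, designs, config)
      return(list(counts = counts, truth = truth, gates = gates,
                  occupancy = occupancy))
    }
    c(sortseq_write_fastq(gen_counts, region, designs, config, dir, samples,
                          truth),
      list(gates = gates, occupancy = occupancy))
  })
}

# Apply the sequencing-noise model at count level: each read independently
# gains an indel with prob delta, otherwise k ~ Binom(L, eps) substitution
# errors. A variant read with any error carries >= 2 mismatches and is
# filtered as multi_snv; a WT read with one error becomes a designed variant
# (if the error falls in the design window) or an undesigned SNV.
sortseq_noise_counts <- function(gen_counts, region, designs, config) {
  L <- nchar(region$sequence)
  eps <- config$error_rate; delta <- config$indel_rate
  p_err <- 1 - (1 - eps)^L
  vids <- setdiff(rownames(gen_counts), "WT")
  win <- region$design_window
  p_window <- (win[2L] - win[1L] + 1L) / L
  n_bins <- ncol(gen_counts)
  counts <- matrix(0L, length(vids) + 1L, n_bins,
                   dimnames = list(c(vids, "WT"), colnames(gen_counts)))
  reasons <- c("multi_snv", "indel", "unalignable", "undesigned_snv",
               "low_quality")
  discards <- matrix(0L, length(reasons), n_bins,
                     dimnames = list(reasons, colnames(gen_counts)))
  for (b in seq_len(n_bins)) {
    nv <- gen_counts[vids, b]
    ind <- stats::rbinom(length(nv), nv, delta)
    err <- stats::rbinom(length(nv), nv - ind, p_err)
    counts[vids, b] <- nv - ind - err
    discards["indel", b] <- sum(ind)
    discards["multi_snv", b] <- discards["multi_snv", b] + sum(err)
    nw <- gen_counts["WT", b]
    if (nw > 0L) {
      w_ind <- stats::rbinom(1L, nw, delta)
      k <- stats::rbinom(nw - w_ind, L, eps)
      n1 <- sum(k == 1L)
      n2 <- sum(k >= 2L)
      hits_window <- stats::rbinom(1L, n1, p_window)
      if (hits_window > 0L) {
        spurious <- sample(vids, hits_window, replace = TRUE)
        tv <- table(spurious)
        counts[names(tv), b] <- counts[names(tv), b] + as.integer(tv)
      }
      counts["WT", b] <- sum(k == 0L)
      discards["indel", b] <- discards["indel", b] + w_ind
      discards["multi_snv", b] <- discards["multi_snv", b] + n2
      discards["undesigned_snv", b] <- n1 - hits_window
    }
  }
  samples <- data.frame(sample_id = colnames(gen_counts),
                        condition = colnames(gen_counts), replicate = 1L,
                        stringsAsFactors = FALSE)
  structure(list(counts = counts, discards = discards, samples = samples),
            class = "sge_counts")
}

# Emit per-bin FASTQ with explicit error injection; qualities constant Q37.
sortseq_write_fastq <- function(gen_counts, region, designs, config, dir,
                                samples, truth) {
  if (is.null(dir)) dir <- tempfile("sortseq")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  amp <- strsplit(region$sequence, "", fixed = TRUE)[[1L]]
  L <- length(amp)
  make_read <- function(vid) {
    rd <- amp
    if (vid != "WT") {
      i <- match(vid, designs$variant_id)
      rd[designs$position[i]] <- designs$alt[i]
    }
    nerr <- stats::rbinom(1L, L, config$error_rate)
    if (nerr > 0L) {
      at <- sample.int(L, nerr)
      rd[at] <- vapply(rd[at], function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
    }
    if (stats::runif(1L) < config$indel_rate) {
      at <- sample.int(L, 1L)
      if (stats::runif(1L) < 0.5) {
        rd <- append(rd, sample(DNA_BASES, 1L), after = at)
      } else {
        rd <- rd[-at]
      }
    }
    paste(rd, collapse = "")
  }
  paths <- character(ncol(gen_counts))
  for (b in seq_len(ncol(gen_counts))) {
    ids <- rep(rownames(gen_counts), gen_counts[, b])
    if (length(ids)) ids <- sample(ids)   # shuffle read order
    reads <- vapply(ids, make_read, character(1), USE.NAMES = FALSE)
    paths[b] <- file.path(dir, paste0(colnames(gen_counts)[b], ".fastq"))
    con <- file(paths[b], "w")
    for (i in seq_along(reads)) {
      writeLines(c(paste0("@read", i), reads[i], "+",
                   strrep("F", nchar(reads[i]))), con)
    }
    close(con)
  }
  samples$fastq <- paths
  manifest <- file.path(dir, "truth_manifest.json")
  jsonlite::write_json(list(region_id = region$region_id,
                            truth = truth,
                            generating_counts = as.data.frame(gen_counts)),
                       manifest, dataframe = "columns", auto_unbox = TRUE)
  gen <- structure(list(
    counts = rbind(gen_counts[setdiff(rownames(gen_counts), "WT"), ,
                              drop = FALSE],
                   WT = gen_counts["WT", ]),
    discards = matrix(0L, 5L, ncol(gen_counts),
                      dimnames = list(c("multi_snv", "indel", "unalignable",
                                        "undesigned_snv", "low_quality"),
                                      colnames(gen_counts))),
    samples = samples), class = "sge_counts")
  list(counts = gen, truth = truth, samples = samples, manifest = manifest)
}

#' Simulate a growth-selection (fitness) experiment
#'
#' Plasmid-library representation is lognormal across variants; endpoint
#' expected frequencies follow exponential outgrowth, proportional to
#' p0 * (1 + s)^g over `doublings` g with the background-specific selection
#' coefficient s; reads are multinomial at depth `reads_per_variant` times
#' the library size for both samples.
#'
#' @param truth [assign_true_effects()] result.
#' @param designs Design table.
#' @param config [sim_config()].
#' @param seed Integer seed.
#' @param backgrounds Subset of `c("null", "partial")`.
#' @return An `sge_counts` with conditions `plasmid` and `day14` per
#'   background (sample sheet carries a `background` column).
#' @export
simulate_growth <- function(truth, designs, config = sim_config(),
                            seed = 1L, backgrounds = c("null", "partial")) {
  with_seed(seed, {
    vids <- designs$variant_id
    n <- length(vids)
    depth <- config$reads_per_variant * n
    p0 <- stats::rlnorm(n, 0, config$representation_log_sd)
    p0 <- p0 / sum(p0)
    cols <- list(); sheet <- list()
    for (bg in backgrounds) {
      s <- truth[[paste0("s_", bg)]][match(vids, truth$variant_id)]
      plasmid <- stats::rmultinom(1L, depth, p0)[, 1L]
      w <- p0 * (1 + s)^config$doublings
      day14 <- stats::rmultinom(1L, depth, w / sum(w))[, 1L]
      cols[[paste0("plasmid_", bg)]] <- plasmid
      cols[[paste0("day14_", bg)]] <- day14
      sheet[[bg]] <- data.frame(
        sample_id = paste0(c("plasmid_", "day14_"), bg),
        condition = c("plasmid", "day14"), replicate = 1L,
        background = bg, stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, cols)
    counts <- rbind(counts, 0L)
    rownames(counts) <- c(vids, "WT")
    storage.mode(counts) <- "integer"
    samples <- do.call(rbind, sheet)
    rownames(samples) <- NULL
    discards <- matrix(0L, 5L, ncol(counts),
                       dimnames = list(c("multi_snv", "indel", "unalignable",
                                         "undesigned_snv", "low_quality"),
                                       colnames(counts)))
    structure(list(counts = counts, discards = discards, samples = samples),
              class = "sge_counts")
  })
}

#' Simulate a clinical truth set and evidence profiles
#'
#' A random subset of variants receives a ClinVar-style truth label:
#' low-class variants are PLP and normal-class BLB, each flipped with
#' probability `label_noise`. Every labeled variant also receives, with
#' probability `aux_evidence_prob`, one auxiliary evidence item (supporting
#' or moderate) pointing in its class's direction.
#'
#' @param truth [assign_true_effects()] result.
#' @param config [sim_config()].
#' @param seed Integer seed.
#' @return List with `truth_set` (data.frame `variant_id`, `label`,
#'   `stars`) and `profiles` (named list of evidence data.frames).
#' @export
simulate_truth_labels <- function(truth, config = sim_config(), seed = 1L) {
  with_seed(seed, {
    n <- nrow(truth)
    labeled <- which(stats::runif(n) < config$frac_labeled)
    ideal <- ifelse(truth$class[labeled] == "low", "PLP", "BLB")
    flip <- stats::runif(length(labeled)) < config$label_noise
    label <- ifelse(flip, ifelse(ideal == "PLP", "BLB", "PLP"), ideal)
    ts <- data.frame(variant_id = truth$variant_id[labeled], label = label,
                     stars = sample(1:3, length(labeled), replace = TRUE),
                     stringsAsFactors = FALSE)
    profiles <- stats::setNames(lapply(seq_along(labeled), function(i) {
      if (stats::runif(1L) >= config$aux_evidence_prob) {
        return(data.frame(code = character(), direction = character(),
                          strength = character()))
      }
      dir <- if (truth$class[labeled[i]] == "low") "pathogenic" else "benign"
      code <- if (dir == "pathogenic") sample(c("PM5", "PP3"), 1L)
              else sample(c("BP4", "BS4"), 1L)
      data.frame(code = code, direction = dir,
                 strength = sample(c("supporting", "moderate"), 1L),
                 stringsAsFactors = FALSE)
    }), truth$variant_id[labeled])
    list(truth_set = ts, profiles = profiles)
  })
}

#' Simulate a pooled knockout screen
#'
#' Genes carry `guides_per_gene` guides plus `n_nontargeting` non-targeting
#' controls. A random `essential_fraction` of genes are iPSC-essential
#' (selection `screen_effect` per doubling); of the remainder, a random
#' `neuron_essential_fraction` become essential only during the neuron
#' phase. Counts follow the same lognormal-representation multinomial model
#' as [simulate_growth()]; the neuron endpoint grows out of the iPSC
#' endpoint composition.
#'
#' @param config [sim_config()].
#' @param seed Integer seed.
#' @return List with `guides` (data.frame `guide_id`, `gene`, `plasmid`,
#'   `ipsc_d21`, `neuron_d21`) and `truth` (data.frame `gene`,
#'   `essential_ipsc`, `essential_neuron`).
#' @export
simulate_screen <- function(config = sim_config(), seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(config$n_genes))
    ess_ipsc <- stats::runif(config$n_genes) < config$essential_fraction
    ess_neuron <- !ess_ipsc &
      stats::runif(config$n_genes) < config$neuron_essential_fraction
    gene_of <- rep(genes, each = config$guides_per_gene)
    guide_id <- c(paste0(gene_of, "_g",
                         rep(seq_len(config$guides_per_gene),
                             config$n_genes)),
                  sprintf("NT_%03d", seq_len(config$n_nontargeting)))
    gene_of <- c(gene_of, rep(NA_character_, config$n_nontargeting))
    s_ipsc <- ifelse(is.na(gene_of), 0,
                     ifelse(ess_ipsc[match(gene_of, genes)],
                            config$screen_effect, 0))
    s_neuron <- ifelse(is.na(gene_of), 0,
                       ifelse(ess_neuron[match(gene_of, genes)],
                              config$screen_effect, 0))
    n_guides <- length(guide_id)
    depth <- config$reads_per_guide * n_guides
    p0 <- stats::rlnorm(n_guides, 0, config$representation_log_sd)
    p0 <- p0 / sum(p0)
    plasmid <- stats::rmultinom(1L, depth, p0)[, 1L]
    w1 <- p0 * (1 + s_ipsc)^config$doublings
    w1 <- w1 / sum(w1)
    ipsc <- stats::rmultinom(1L, depth, w1)[, 1L]
    w2 <- w1 * (1 + s_neuron)^config$doublings
    neuron <- stats::rmultinom(1L, depth, w2 / sum(w2))[, 1L]
    list(guides = data.frame(guide_id = guide_id, gene = gene_of,
                             plasmid = plasmid, ipsc_d21 = ipsc,
                             neuron_d21 = neuron, stringsAsFactors = FALSE),
         truth = data.frame(gene = genes, essential_ipsc = ess_ipsc,
                            essential_neuron = ess_neuron,
                            stringsAsFactors = FALSE))
  })
}
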