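#' Construct a synthetic-study configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults
#' emulate the study design the package targets: a two-replicate
#' ChIP-seq experiment over five planted promoter states, a
#' differential-expression response in which H3K27me3-bearing and
#' bivalent promoters are preferentially upregulated after EZH2
#' inhibition, limiting-dilution assays on the 1000/100/10/1 dose
#' ladder with a fourfold frequency difference between groups, and a
#' clinical cohort in which a high composite IHC score raises
#' recurrence odds.
#'
#' @param seed integer root seed; every generator derives its own
#'   substream.
#' @param n_genes number of genes (default 500).
#' @param chrom_sizes named numeric chromosome lengths in bp.
#' @param state_proportions named fractions over
#'   none/k4_only/k27_only/mixed/bivalent summing to 1 (default
#'   0.4/0.2/0.2/0.1/0.1).
#' @param peak_width planted peak width in bp (default 500).
#' @param peak_jitter_sd per-replicate peak position jitter sd in bp
#'   (default 0: noiseless).
#' @param peak_drop_prob per-replicate probability a planted peak is
#'   missing from that replicate (default 0).
#' @param n_decoy_peaks intergenic decoy peaks per mark per replicate
#'   (default 100).
#' @param de_effect log-odds increase of upregulation for
#'   H3K27me3-bearing promoters (default 3).
#' @param de_baseline baseline log-odds of regulation (default -3).
#' @param strict_derepression when TRUE (default) and de_effect > 0, no
#'   H3K27me3-bearing gene is planted downregulated.
#' @param lda_frequencies named true initiating-cell frequencies per
#'   group (default control 1/200, treated 1/800).
#' @param lda_doses cells per well (default 1000, 100, 10, 1; the in
#'   vivo ladder would be 10000, 1000, 100, 10).
#' @param lda_wells wells per dose (default 24).
#' @param n_patients clinical cohort size (default 250).
#' @param clinical_effect recurrence log-odds per unit composite score
#'   (default 0.15).
#' @param clinical_baseline baseline recurrence log-odds (default -2.2).
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 7, n_genes = 50,
#'                  chrom_sizes = c(chr1 = 1e6))
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      n_genes = 500L,
                      chrom_sizes = c(chr1 = 3e6, chr2 = 3e6),
                      state_proportions = c(none = 0.4, k4_only = 0.2,
                                            k27_only = 0.2, mixed = 0.1,
                                            bivalent = 0.1),
                      peak_width = 500,
                      peak_jitter_sd = 0,
                      peak_drop_prob = 0,
                      n_decoy_peaks = 100L,
                      de_effect = 3,
                      de_baseline = -3,
                      strict_derepression = TRUE,
                      lda_frequencies = c(control = 1 / 200,
                                          treated = 1 / 800),
                      lda_doses = c(1000L, 100L, 10L, 1L),
                      lda_wells = 24L,
                      n_patients = 250L,
                      clinical_effect = 0.15,
                      clinical_baseline = -2.2) {
  new("SimConfig",
      seed = as.integer(seed),
      n_genes = as.integer(n_genes),
      chrom_sizes = chrom_sizes,
      state_proportions = state_proportions[c("none", "k4_only", "k27_only",
                                              "mixed", "bivalent")],
      peak_width = peak_width,
      peak_jitter_sd = peak_jitter_sd,
      peak_drop_prob = peak_drop_prob,
      n_decoy_peaks = as.integer(n_decoy_peaks),
      de_effect = de_effect,
      de_baseline = de_baseline,
      strict_derepression = strict_derepression,
      lda_frequencies = lda_frequencies,
      lda_doses = as.integer(lda_doses),
      lda_wells = as.integer(lda_wells),
      n_patients = as.integer(n_patients),
      clinical_effect = clinical_effect,
      clinical_baseline = clinical_baseline)
}

## promoter window extent used by the generators (the standard -2.5 kb /
## +0.5 kb promoter definition)
.SIM_UPSTREAM <- 2500
.SIM_DOWNSTREAM <- 500

#' Generate a gene annotation with non-colliding promoter windows
#'
#' Genes are placed so that their full promoter windows (-2.5 kb/+0.5 kb
#' around the TSS, in transcription direction) are pairwise disjoint and
#' fit their chromosomes, making planted promoter states unambiguous.
#' Strands are assigned ~50/50. Deterministic under the config seed.
#'
#' @param config a [SimConfig-class].
#' @return gene GRanges (names = gene ids, strand, `tss` mcol,
#'   seqlengths set), same shape as [readGeneAnnotation()] output.
#' @export
generateGeneAnnotation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  w <- .SIM_UPSTREAM + .SIM_DOWNSTREAM
  sizes <- config@chrom_sizes
  cap <- floor(sizes / w)
  if (sum(cap) < config@n_genes)
    stop("capacity error: ", config@n_genes, " promoter windows of ", w,
         " bp need ", config@n_genes * w, " bp; chromosomes hold ",
         sum(cap * w), " bp of window space")
  withStageSeed(config@seed, "annotation", {
    ## apportion genes to chromosomes by capacity (largest remainder)
    quota <- config@n_genes * cap / sum(cap)
    n_per <- floor(quota)
    left <- config@n_genes - sum(n_per)
    if (left > 0) {
      o <- order(quota - n_per, decreasing = TRUE)
      n_per[o[seq_len(left)]] <- n_per[o[seq_len(left)]] + 1L
    }
    n_per <- pmin(n_per, cap)
    short <- config@n_genes - sum(n_per)
    while (short > 0) {  # spill over if rounding hit a capacity ceiling
      room <- which(n_per < cap)
      take <- room[seq_len(min(short, length(room)))]
      n_per[take] <- n_per[take] + 1L
      short <- config@n_genes - sum(n_per)
    }
    recs <- lapply(seq_along(sizes), function(ci) {
      n <- n_per[ci]
      if (n == 0L) return(NULL)
      L <- sizes[ci]
      ## n disjoint windows of width w: sorted draws plus stacked offsets
      slack <- L - n * w
      offs <- sort(sample.int(slack + 1, n, replace = TRUE) - 1L)
      win_start0 <- offs + (seq_len(n) - 1L) * w  # 0-based window starts
      strand <- sample(c("+", "-"), n, replace = TRUE)
      tss0 <- ifelse(strand == "+",
                     win_start0 + .SIM_UPSTREAM,
                     win_start0 + .SIM_DOWNSTREAM - 1L)
      tss1 <- tss0 + 1L
      body_len <- sample(2000:8000, n, replace = TRUE)
      bstart <- ifelse(strand == "+", tss1, pmax(1, tss1 - body_len + 1L))
      bend <- ifelse(strand == "+", pmin(L, tss1 + body_len - 1L), tss1)
      data.frame(chrom = names(sizes)[ci], start = bstart, end = bend,
                 strand = strand, tss = tss1)
    })
    tab <- do.call(rbind, recs)
    gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end),
                  strand = tab$strand)
    names(gr) <- sprintf("gene%04d", seq_len(nrow(tab)))
    gr$tss <- tab$tss
    GenomeInfoDb::seqlengths(gr) <- sizes[GenomeInfoDb::seqlevels(gr)]
    gr
  })
}

#' Plant per-gene ground truth: promoter states and DE directions
#'
#' Promoter states are assigned in exact largest-remainder counts from
#' `state_proportions` and shuffled over genes. The DE direction follows
#' a logistic model: P(up) = plogis(de_baseline + de_effect * k27bearing)
#' where k27bearing marks the k27_only, mixed and bivalent states; genes
#' not upregulated are downregulated with probability
#' plogis(de_baseline), except that in strict-derepression mode no
#' H3K27me3-bearing gene is planted downregulated.
#'
#' @param annotation gene GRanges from [generateGeneAnnotation()].
#' @param config a [SimConfig-class].
#' @return list with `states` and `de_direction` (named character
#'   vectors over genes), and `lda_frequencies` echoed from the config.
#' @export
plantTruth <- function(annotation, config) {
  stopifnot(is(config, "SimConfig"))
  n <- length(annotation)
  props <- config@state_proportions
  counts <- floor(n * props)
  left <- n - sum(counts)
  if (left > 0) {
    o <- order(n * props - counts, decreasing = TRUE)
    counts[o[seq_len(left)]] <- counts[o[seq_len(left)]] + 1L
  }
  withStageSeed(config@seed, "truth", {
    states <- sample(rep(names(counts), counts))
    names(states) <- names(annotation)
    k27bearing <- states %in% c("k27_only", "mixed", "bivalent")
    p_up <- stats::plogis(config@de_baseline +
                            config@de_effect * k27bearing)
    up <- stats::runif(n) < p_up
    p_down <- stats::plogis(config@de_baseline)
    down <- !up & stats::runif(n) < p_down
    if (config@strict_derepression && config@de_effect > 0)
      down[k27bearing] <- FALSE
    dir <- ifelse(up, "up", ifelse(down, "down", "unchanged"))
    names(dir) <- names(annotation)
    list(states = states, de_direction = dir,
         lda_frequencies = config@lda_frequencies)
  })
}

## plant the peaks realising one gene's state inside its promoter window
## (1-based window coords); returns data.frame(mark, start, end)
.plantGenePeaks <- function(ws, we, state, pw) {
  W <- we - ws + 1L
  pw <- min(pw, floor((W - 20) / 2))
  half <- floor(pw / 2)
  switch(state,
    none = NULL,
    k4_only = data.frame(mark = "H3K4me3",
                         start = ws + floor((W - pw) / 2),
                         end = ws + floor((W - pw) / 2) + pw - 1L),
    k27_only = data.frame(mark = "H3K27me3",
                          start = ws + floor((W - pw) / 2),
                          end = ws + floor((W - pw) / 2) + pw - 1L),
    mixed = rbind(
      data.frame(mark = "H3K4me3", start = ws + 5L, end = ws + 5L + pw - 1L),
      data.frame(mark = "H3K27me3", start = we - pw + 1L - 5L, end = we - 5L)),
    bivalent = {
      a <- ws + floor((W - pw - half) / 2)
      rbind(
        data.frame(mark = "H3K4me3", start = a, end = a + pw - 1L),
        data.frame(mark = "H3K27me3", start = a + half,
                   end = a + half + pw - 1L))
    },
    stop("unknown planted state: ", state)
  )
}

#' Generate two-replicate peak sets realising planted promoter states
#'
#' For each gene, peaks are planted inside the promoter window so that
#' the five-state classification recovers the planted label exactly:
#' bivalent genes get an H3K4me3 and an H3K27me3 peak overlapping inside
#' the window, mixed genes two disjoint peaks, single-mark genes one
#' peak, `none` genes no peak. With zero jitter and drop probability the
#' two replicates are identical. Decoy intergenic peaks are added
#' outside all promoter windows. Per-replicate noise: peak positions
#' jittered by a normal shift (sd `peak_jitter_sd`) and peaks dropped
#' with probability `peak_drop_prob`, independently per replicate.
#'
#' @param annotation gene GRanges from [generateGeneAnnotation()].
#' @param truth list from [plantTruth()].
#' @param config a [SimConfig-class].
#' @return nested list `$H3K4me3$rep1/$rep2`, `$H3K27me3$rep1/$rep2` of
#'   [PeakCollection-class] objects.
#' @export
generatePeakSets <- function(annotation, truth, config) {
  stopifnot(is(config, "SimConfig"))
  states <- truth$states[names(annotation)]
  if (any(is.na(states))) stop("truth does not cover every gene")
  bad <- setdiff(unique(states),
                 c("none", "k4_only", "k27_only", "mixed", "bivalent"))
  if (length(bad)) stop("unknown planted state: ", paste(bad, collapse = ", "))
  win <- promoterWindows(annotation, .SIM_UPSTREAM, .SIM_DOWNSTREAM,
                         chrom_sizes = config@chrom_sizes)
  planted <- lapply(seq_along(annotation), function(i) {
    p <- .plantGenePeaks(start(win)[i], end(win)[i], states[[i]],
                         config@peak_width)
    if (is.null(p)) return(NULL)
    p$chrom <- as.character(seqnames(annotation))[i]
    p
  })
  planted <- do.call(rbind, planted)

  decoys <- if (config@n_decoy_peaks == 0L) NULL else
    withStageSeed(config@seed, "decoys", {
    out <- lapply(c("H3K4me3", "H3K27me3"), function(mk) {
      chrom <- sample(names(config@chrom_sizes), 3L * config@n_decoy_peaks,
                      replace = TRUE,
                      prob = config@chrom_sizes / sum(config@chrom_sizes))
      len <- config@chrom_sizes[chrom]
      st <- floor(stats::runif(length(chrom), 1, len - config@peak_width))
      gr <- GRanges(chrom, IRanges(st, st + config@peak_width - 1L))
      gr <- gr[!IRanges::overlapsAny(gr, win, minoverlap = 1L)]
      gr <- utils::head(gr, config@n_decoy_peaks)
      if (!length(gr)) return(NULL)  # genome too crowded for decoys
      data.frame(mark = mk, start = start(gr), end = end(gr),
                 chrom = as.character(seqnames(gr)))
    })
    do.call(rbind, out)
  })
  all_peaks <- rbind(planted, decoys)
  if (is.null(all_peaks))
    all_peaks <- data.frame(mark = character(), start = integer(),
                            end = integer(), chrom = character())

  makeRep <- function(repid) {
    withStageSeed(config@seed, paste0("peaks_", repid), {
      keep <- stats::runif(nrow(all_peaks)) >= config@peak_drop_prob
      pk <- all_peaks[keep, , drop = FALSE]
      if (config@peak_jitter_sd > 0 && nrow(pk)) {
        shift <- round(stats::rnorm(nrow(pk), 0, config@peak_jitter_sd))
        pk$start <- pmax(1L, pk$start + shift)
        pk$end <- pmax(pk$start, pk$end + shift)
      }
      lapply(stats::setNames(c("H3K4me3", "H3K27me3"),
                             c("H3K4me3", "H3K27me3")), function(mk) {
        sel <- pk[pk$mark == mk, , drop = FALSE]
        PeakCollection(GRanges(sel$chrom, IRanges(sel$start, sel$end)),
                       mark = mk, replicate = repid,
                       condition = "untreated")
      })
    })
  }
  r1 <- makeRep("rep1")
  r2 <- makeRep("rep2")
  list(H3K4me3 = list(rep1 = r1$H3K4me3, rep2 = r2$H3K4me3),
       H3K27me3 = list(rep1 = r1$H3K27me3, rep2 = r2$H3K27me3))
}

#' Generate a differential-expression table realising planted directions
#'
#' Genes planted `up` or `down` receive q uniform on (0, 0.05) and a
#' log2 fold change of matching sign; `unchanged` genes receive q
#' uniform on (0.05, 1] (only the threshold partition matters
#' downstream). Effect sizes are |N(1.5, 0.5)| + 0.2 for regulated genes
#' and N(0, 0.2) otherwise.
#'
#' @param annotation gene GRanges.
#' @param truth list from [plantTruth()].
#' @param config a [SimConfig-class].
#' @return data.frame with gene_id, log2fc, q.
#' @export
generateDETable <- function(annotation, truth, config) {
  stopifnot(is(config, "SimConfig"))
  dir <- truth$de_direction[names(annotation)]
  if (any(is.na(dir))) stop("truth does not cover every gene")
  n <- length(dir)
  withStageSeed(config@seed, "de", {
    reg <- dir != "unchanged"
    q <- numeric(n)
    q[reg] <- stats::runif(sum(reg), 0, 0.05)
    q[!reg] <- stats::runif(sum(!reg), 0.05, 1)
    mag <- abs(stats::rnorm(n, 1.5, 0.5)) + 0.2
    lfc <- stats::rnorm(n, 0, 0.2)
    lfc[dir == "up"] <- mag[dir == "up"]
    lfc[dir == "down"] <- -mag[dir == "down"]
    lfc[lfc == 0] <- 1e-6
    data.frame(gene_id = names(dir), log2fc = lfc, q = q,
               stringsAsFactors = FALSE)
  })
}

#' Generate single-hit limiting-dilution outcomes
#'
#' For each group g and dose d, the number of positive wells is drawn
#' Binomial(lda_wells, 1 - exp(-f_g d)).
#'
#' @param config a [SimConfig-class].
#' @param seed optional seed overriding the config root seed (used by
#'   replicate simulations).
#' @return data.frame with group, dose, n_tested, n_positive.
#' @export
generateLdaTable <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  grid <- expand.grid(group = names(config@lda_frequencies),
                      dose = config@lda_doses,
                      stringsAsFactors = FALSE)
  withStageSeed(seed, "lda", {
    f <- config@lda_frequencies[grid$group]
    p <- 1 - exp(-f * grid$dose)
    data.frame(group = grid$group, dose = grid$dose,
               n_tested = config@lda_wells,
               n_positive = stats::rbinom(nrow(grid), config@lda_wells, p),
               stringsAsFactors = FALSE)
  })
}

#' Generate a clinical IHC cohort
#'
#' Per patient, P is drawn uniformly from 0..4 and I from 0..3;
#' recurrence is Bernoulli with logit
#' clinical_baseline + clinical_effect * P * I.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with patient_id, P, I, composite, recurrence and a
#'   `true_prob` column holding each patient's planted recurrence
#'   probability.
#' @export
generateClinicalTable <- function(config) {
  stopifnot(is(config, "SimConfig"))
  withStageSeed(config@seed, "clinical", {
    n <- config@n_patients
    P <- sample(0:4, n, replace = TRUE)
    I <- sample(0:3, n, replace = TRUE)
    comp <- compositeScore(P, I)
    prob <- stats::plogis(config@clinical_baseline +
                            config@clinical_effect * comp)
    data.frame(patient_id = sprintf("pt%04d", seq_len(n)),
               P = P, I = I, composite = comp,
               recurrence = stats::rbinom(n, 1, prob),
               true_prob = prob,
               stringsAsFactors = FALSE)
  })
}

#' Generate the full synthetic study
#'
#' Convenience wrapper running every generator in order.
#'
#' @param config a [SimConfig-class].
#' @return list with annotation, truth, peaks, de, lda, clinical.
#' @export
generateStudy <- function(config) {
  annotation <- generateGeneAnnotation(config)
  truth <- plantTruth(annotation, config)
  list(annotation = annotation,
       truth = truth,
       peaks = generatePeakSets(annotation, truth, config),
       de = generateDETable(annotation, truth, config),
       lda = generateLdaTable(config),
       clinical = generateClinicalTable(config))
}

#' Write a PeakCollection as BED6 or narrowPeak
#'
#' Coordinates are converted back to the BED 0-based half-open
#' convention.
#'
#' @param peaks a [PeakCollection-class].
#' @param path output path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @export
writePeaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  gr <- peakRanges(peaks)
  chrom <- as.character(seqnames(gr))
  s0 <- start(gr) - 1L
  e0 <- end(gr)
  nm <- sprintf("%s_%s_%d", peaks@mark, peaks@replicate, seq_along(gr))
  lines <- if (format == "bed") {
    sprintf("%s\t%d\t%d\t%s\t0\t.", chrom, s0, e0, nm)
  } else {
    sprintf("%s\t%d\t%d\t%s\t0\t.\t1.0\t-1\t-1\t%d",
            chrom, s0, e0, nm, pmax(0L, (e0 - s0) %/% 2L))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene annotation as BED6 or minimal GTF
#'
#' @param genes gene GRanges (names = gene ids).
#' @param path output path.
#' @param format `"bed"` (0-based half-open) or `"gtf"` (1-based
#'   inclusive, feature `gene`).
#' @export
writeGeneAnnotation <- function(genes, path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  chrom <- as.character(seqnames(genes))
  st <- as.character(strand(genes))
  lines <- if (format == "bed") {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, start(genes) - 1L, end(genes),
            names(genes), st)
  } else {
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            chrom, start(genes), end(genes), st, names(genes))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as a tab-separated table with header
#'
#' @param tab data.frame (DE, LDA, clinical or truth table).
#' @param path output path.
#' @export
writeTsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
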