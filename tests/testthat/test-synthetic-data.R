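test_that("gene placement respects capacity, determinism and window fit", {
  cfg1 <- simConfig(seed = 2, n_genes = 1, chrom_sizes = c(chr1 = 1e6))
  ann1 <- generateGeneAnnotation(cfg1)
  expect_equal(length(ann1), 1L)
  expect_gte(ann1$tss, 1)
  expect_lte(ann1$tss, 1e6)

  # identical config, two runs: byte-identical annotation
  a <- generateGeneAnnotation(simConfig(seed = 9, n_genes = 80,
                                        chrom_sizes = c(chr1 = 1e6)))
  b <- generateGeneAnnotation(simConfig(seed = 9, n_genes = 80,
                                        chrom_sizes = c(chr1 = 1e6)))
  expect_identical(as.data.frame(a), as.data.frame(b))

  # 100 disjoint 3 kb windows cannot fit on a 10 kb chromosome
  expect_error(generateGeneAnnotation(
    simConfig(seed = 1, n_genes = 100, chrom_sizes = c(chr1 = 1e4))),
    "capacity")

  # promoter windows are pairwise disjoint and inside the chromosome
  cfg <- simConfig(seed = 12, n_genes = 150,
                   chrom_sizes = c(chr1 = 1e6, chr2 = 5e5))
  ann <- generateGeneAnnotation(cfg)
  win <- promoterWindows(ann, chrom_sizes = cfg@chrom_sizes)
  self <- findOverlaps(win, win, minoverlap = 1L, ignore.strand = TRUE)
  expect_equal(length(self), length(win))  # only self-hits
  expect_true(all(start(win) >= 1))
  expect_true(all(end(win) <= cfg@chrom_sizes[as.character(seqnames(win))]))
  # strands roughly balanced
  expect_gt(mean(strand(ann) == "+"), 0.3)
  expect_lt(mean(strand(ann) == "+"), 0.7)
})

test_that("planted states drive peak geometry per the classification rules", {
  cfg <- simConfig(seed = 5, n_genes = 100,
                   chrom_sizes = c(chr1 = 1e6), n_decoy_peaks = 0L)
  ann <- generateGeneAnnotation(cfg)
  truth <- plantTruth(ann, cfg)
  pk <- generatePeakSets(ann, truth, cfg)
  win <- promoterWindows(ann, chrom_sizes = cfg@chrom_sizes)
  for (g in names(ann)) {
    w <- win[g]
    k4 <- peaksOverlapping(w, pk$H3K4me3$rep1)
    k27 <- peaksOverlapping(w, pk$H3K27me3$rep1)
    st <- truth$states[[g]]
    if (st == "none") {
      expect_equal(length(k4) + length(k27), 0L)
    } else if (st == "k4_only") {
      expect_equal(c(length(k4), length(k27)), c(1L, 0L))
    } else if (st == "k27_only") {
      expect_equal(c(length(k4), length(k27)), c(0L, 1L))
    } else if (st == "mixed") {
      expect_equal(c(length(k4), length(k27)), c(1L, 1L))
      expect_equal(overlapLength(k4, k27), 0L)
    } else {
      expect_equal(c(length(k4), length(k27)), c(1L, 1L))
      expect_gte(overlapLength(k4, k27), 1L)
    }
  }
  # noiseless: both replicates carry identical peaks
  expect_identical(as.data.frame(peakRanges(pk$H3K4me3$rep1)),
                   as.data.frame(peakRanges(pk$H3K4me3$rep2)))
  bad <- truth
  bad$states[1] <- "sideways"
  expect_error(generatePeakSets(ann, bad, cfg), "unknown planted state")
})

test_that("per-replicate peak dropout follows the binomial expectation", {
  cfg <- simConfig(seed = 31, n_genes = 1000,
                   chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                   state_proportions = c(none = 0, k4_only = 1, k27_only = 0,
                                         mixed = 0, bivalent = 0),
                   peak_drop_prob = 0.5, n_decoy_peaks = 0L)
  ann <- generateGeneAnnotation(cfg)
  truth <- plantTruth(ann, cfg)
  pk <- generatePeakSets(ann, truth, cfg)
  win <- promoterWindows(ann, chrom_sizes = cfg@chrom_sizes)
  in1 <- countOverlaps(win, peakRanges(pk$H3K4me3$rep1)) > 0
  in2 <- countOverlaps(win, peakRanges(pk$H3K4me3$rep2)) > 0
  lost_one <- sum(xor(in1, in2))
  # P(exactly one replicate keeps the peak) = 2 * 0.5 * 0.5 = 0.5
  expect_lt(abs(lost_one - 500), 3 * sqrt(1000 * 0.5 * 0.5))
})

test_that("DE generator reflects the planted logistic model", {
  # strong effect: bivalent up-fraction near 0.5, background near 0.047
  cfg <- simConfig(seed = 17, n_genes = 2000,
                   chrom_sizes = c(chr1 = 4e6, chr2 = 4e6),
                   de_effect = 3, de_baseline = -3)
  ann <- generateGeneAnnotation(cfg)
  truth <- plantTruth(ann, cfg)
  biv <- truth$states == "bivalent"
  none <- truth$states == "none"
  up <- truth$de_direction == "up"
  p_biv <- mean(up[biv]); n_biv <- sum(biv)
  p_non <- mean(up[none]); n_non <- sum(none)
  expect_lt(abs(p_biv - 0.5), 3 * sqrt(0.5 * 0.5 / n_biv))
  p0 <- plogis(-3)
  expect_lt(abs(p_non - p0), 3 * sqrt(p0 * (1 - p0) / n_non))
  # strict derepression: no H3K27me3-bearing gene planted down
  k27b <- truth$states %in% c("k27_only", "mixed", "bivalent")
  expect_equal(sum(truth$de_direction[k27b] == "down"), 0L)

  de <- generateDETable(ann, truth, cfg)
  expect_true(all(de$q > 0 & de$q <= 1))
  expect_true(all(de$q[truth$de_direction != "unchanged"] < 0.05))
  expect_true(all(de$q[truth$de_direction == "unchanged"] >= 0.05))
  expect_true(all(sign(de$log2fc[truth$de_direction == "up"]) == 1))
  expect_true(all(sign(de$log2fc[truth$de_direction == "down"]) == -1))

  # null effect: up-fraction independent of planted state (20 seeded runs
  # aggregated into one chi-square)
  counts <- matrix(0, 2, 5,
                   dimnames = list(c("up", "not"),
                                   c("none", "k4_only", "k27_only", "mixed",
                                     "bivalent")))
  for (s in 1:20) {
    cfg0 <- simConfig(seed = s, n_genes = 300, de_effect = 0,
                      chrom_sizes = c(chr1 = 1e6))
    ann0 <- generateGeneAnnotation(cfg0)
    tr0 <- plantTruth(ann0, cfg0)
    upf <- tr0$de_direction == "up"
    for (st in colnames(counts)) {
      counts["up", st] <- counts["up", st] + sum(upf[tr0$states == st])
      counts["not", st] <- counts["not", st] + sum(!upf[tr0$states == st])
    }
  }
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})

test_that("limiting-dilution outcomes follow the single-hit response", {
  # saturation: f = 1 at dose 1000 leaves no negative well
  sat <- generateLdaTable(simConfig(seed = 3,
                                    lda_frequencies = c(g = 1),
                                    lda_doses = 1000L, lda_wells = 50L))
  expect_equal(sat$n_positive, 50L)
  # vanishing frequency: nothing grows
  non <- generateLdaTable(simConfig(seed = 3,
                                    lda_frequencies = c(g = 1e-12),
                                    lda_doses = c(1000L, 100L),
                                    lda_wells = 50L))
  expect_equal(non$n_positive, c(0L, 0L))
  # f = 1/100 at dose 100: positive fraction near 1 - exp(-1)
  many <- generateLdaTable(simConfig(seed = 29,
                                     lda_frequencies = c(g = 1 / 100),
                                     lda_doses = 100L, lda_wells = 2000L))
  p <- 1 - exp(-1)
  expect_lt(abs(many$n_positive / 2000 - p), 3 * sqrt(p * (1 - p) / 2000))
  # determinism
  expect_identical(generateLdaTable(simConfig(seed = 8)),
                   generateLdaTable(simConfig(seed = 8)))
})

test_that("clinical cohort realises the score-recurrence link", {
  cfg <- simConfig(seed = 23, n_patients = 4000L)
  cl <- generateClinicalTable(cfg)
  expect_true(all(cl$composite >= 0 & cl$composite <= 12))
  expect_true(all(cl$P %in% 0:4) && all(cl$I %in% 0:3))
  qg <- quintileGroups(cl)
  expect_gt(mean(qg$top$recurrence), mean(qg$bottom$recurrence))

  cfg0 <- simConfig(seed = 23, n_patients = 4000L, clinical_effect = 0)
  cl0 <- generateClinicalTable(cfg0)
  qg0 <- quintileGroups(cl0)
  d <- mean(qg0$top$recurrence) - mean(qg0$bottom$recurrence)
  pbar <- mean(cl0$recurrence)
  n <- min(nrow(qg0$top), nrow(qg0$bottom))
  expect_lt(abs(d), 3 * sqrt(2 * pbar * (1 - pbar) / n))
})

test_that("generated files round-trip through the readers without warnings", {
  cfg <- simConfig(seed = 41, n_genes = 60, chrom_sizes = c(chr1 = 1e6))
  st <- generateStudy(cfg)
  d <- tempfile(); dir.create(d)

  bed <- file.path(d, "genes.bed")
  writeGeneAnnotation(st$annotation, bed, format = "bed")
  expect_no_warning(back <- readGeneAnnotation(bed, cfg@chrom_sizes))
  expect_equal(unname(back$tss), unname(st$annotation$tss))
  expect_equal(as.character(strand(back)), as.character(strand(st$annotation)))

  gtf <- file.path(d, "genes.gtf")
  writeGeneAnnotation(st$annotation, gtf, format = "gtf")
  expect_no_warning(backg <- readGeneAnnotation(gtf))
  expect_equal(unname(backg$tss), unname(st$annotation$tss))

  pk <- file.path(d, "k4_rep1.bed")
  writePeaks(st$peaks$H3K4me3$rep1, pk)
  expect_no_warning(pb <- readPeaks(pk, mark = "H3K4me3"))
  expect_equal(granges(peakRanges(pb)), granges(peakRanges(st$peaks$H3K4me3$rep1)))

  np <- file.path(d, "k27_rep2.narrowPeak")
  writePeaks(st$peaks$H3K27me3$rep2, np, format = "narrowPeak")
  expect_no_warning(nb <- readPeaks(np, mark = "H3K27me3"))
  expect_equal(granges(peakRanges(nb)),
               granges(peakRanges(st$peaks$H3K27me3$rep2)))

  tsv <- file.path(d, "de.tsv")
  writeTsv(st$de, tsv)
  back_de <- utils::read.table(tsv, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  expect_equal(back_de$gene_id, st$de$gene_id)
  expect_equal(back_de$log2fc, st$de$log2fc, tolerance = 1e-9)
})

test_that("classification recovers every planted label on noiseless data", {
  cfg <- simConfig(seed = 19, n_genes = 250,
                   chrom_sizes = c(chr1 = 2e6, chr2 = 2e6))
  st <- generateStudy(cfg)
  calls <- suppressMessages(
    classifyAll(st$annotation, st$peaks$H3K4me3, st$peaks$H3K27me3,
                chrom_sizes = cfg@chrom_sizes))
  planted <- toupper(st$truth$states[calls$gene_id])
  expect_equal(as.character(calls$state), unname(planted))
})
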