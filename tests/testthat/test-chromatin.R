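mkpc <- function(s, e, mark = "H3K4me3", rep = "rep1", cond = "untreated") {
  gr <- if (length(s)) GRanges("chr1", IRanges(s, e)) else GRanges()
  PeakCollection(gr, mark, rep, cond)
}

test_that("replicate retention keeps overlapping rep1 peaks unchanged", {
  r1 <- mkpc(101, 600)
  r2 <- mkpc(551, 900, rep = "rep2")
  kept <- reproduciblePeaks(r1, r2)
  expect_equal(start(peakRanges(kept)), 101L)
  expect_equal(end(peakRanges(kept)), 600L)

  # half-open abutment in BED terms = adjacent closed intervals: not overlap
  r2b <- mkpc(601, 900, rep = "rep2")
  expect_equal(length(reproduciblePeaks(r1, r2b)), 0L)

  # identical replicates: idempotent
  expect_equal(peakRanges(reproduciblePeaks(r1, mkpc(101, 600, rep = "rep2"))),
               peakRanges(r1))

  expect_error(reproduciblePeaks(r1, mkpc(1, 10, mark = "H3K27me3")),
               "mark mismatch")
})

test_that("retained peaks are a subset of rep1; superset rep2 retains all", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    s1 <- sample.int(10000, n)
    r1 <- mkpc(s1, s1 + sample(50:200, n, replace = TRUE))
    s2 <- sample.int(10000, n)
    r2 <- mkpc(s2, s2 + sample(50:200, n, replace = TRUE), rep = "rep2")
    kept <- peakRanges(reproduciblePeaks(r1, r2))
    expect_true(all(as.character(kept) %in% as.character(peakRanges(r1))))
    # rep2 containing rep1 exactly: everything retained
    kept2 <- peakRanges(reproduciblePeaks(r1, mkpc(start(peakRanges(r1)),
                                                   end(peakRanges(r1)),
                                                   rep = "rep2")))
    expect_equal(as.character(kept2), as.character(peakRanges(r1)))
  }
})

test_that("five-state classification resolves each geometry correctly", {
  win <- GRanges("chr1", IRanges(7501, 10500))  # 0-based [7500, 10500)
  names(win) <- "g"

  # direct overlap inside the window: bivalent, with its intersection
  call <- classifyPromoter(win, mkpc(8001, 9000),
                           mkpc(8501, 9500, mark = "H3K27me3"))
  expect_equal(as.character(call$state), "BIVALENT")
  expect_equal(call$bivalent_overlap, "chr1:8501-9000")

  # both marks, disjoint peaks: mixed
  call <- classifyPromoter(win, mkpc(7601, 7700),
                           mkpc(10001, 10400, mark = "H3K27me3"))
  expect_equal(as.character(call$state), "MIXED")
  expect_true(is.na(call$bivalent_overlap))

  # single mark / no marks
  empty <- mkpc(integer(), integer(), mark = "H3K27me3")
  expect_equal(as.character(
    classifyPromoter(win, mkpc(8001, 9000), empty)$state), "K4_ONLY")
  expect_equal(as.character(
    classifyPromoter(win, mkpc(integer(), integer()),
                     mkpc(8001, 9000, mark = "H3K27me3"))$state), "K27_ONLY")
  expect_equal(as.character(
    classifyPromoter(win, mkpc(integer(), integer()), empty)$state), "NONE")
})

test_that("a peak pair whose only member near the window misses it gives a single-mark call", {
  # window 0-based [7500, 8000); K4 0-based [7900, 8300) touches it, K27
  # 0-based [8100, 8600) overlaps the K4 peak at [8100, 8300) but lies
  # entirely outside the window, so only H3K4me3 is present at the promoter
  win <- GRanges("chr1", IRanges(7501, 8000))
  names(win) <- "g"
  k4 <- mkpc(7901, 8300)
  k27 <- mkpc(8101, 8600, mark = "H3K27me3")
  expect_equal(overlapLength(peakRanges(k4), peakRanges(k27)), 200L)
  expect_equal(overlapLength(peakRanges(k27), win), 0L)
  for (scope in c("in_window", "anywhere")) {
    call <- classifyPromoter(win, k4, k27, bivalent_scope = scope)
    expect_equal(as.character(call$state), "K4_ONLY")
  }
})

test_that("both bivalent-overlap scopes agree when peaks must touch the window", {
  # whenever a K4 and a K27 interval each touch the window and each other,
  # their intersection necessarily touches the window too; check over
  # randomised single-chromosome cases
  set.seed(33)
  for (i in 1:40) {
    ws <- sample(1000:4000, 1)
    win <- GRanges("chr1", IRanges(ws, ws + sample(100:500, 1)))
    names(win) <- "g"
    n4 <- sample(1:6, 1); n27 <- sample(1:6, 1)
    s4 <- sample(500:5000, n4); s27 <- sample(500:5000, n27)
    k4 <- mkpc(s4, s4 + sample(50:400, n4, replace = TRUE))
    k27 <- mkpc(s27, s27 + sample(50:400, n27, replace = TRUE),
                mark = "H3K27me3")
    a <- classifyPromoter(win, k4, k27, bivalent_scope = "in_window")
    b <- classifyPromoter(win, k4, k27, bivalent_scope = "anywhere")
    expect_equal(as.character(a$state), as.character(b$state))
  }
})

test_that("classification partitions genes and respects monotonicity", {
  set.seed(55)
  cfg <- simConfig(seed = 8, n_genes = 120,
                   chrom_sizes = c(chr1 = 1e6, chr2 = 1e6))
  st <- generateStudy(cfg)
  calls <- suppressMessages(
    classifyAll(st$annotation, st$peaks$H3K4me3, st$peaks$H3K27me3))
  expect_equal(nrow(calls), 120L)
  expect_false(any(is.na(calls$state)))
  expect_equal(sum(table(calls$state)), 120L)

  # adding a K27 peak to a K4_ONLY promoter never yields NONE or K4_ONLY
  win <- GRanges("chr1", IRanges(7501, 10500)); names(win) <- "g"
  k4 <- mkpc(8001, 9000)
  for (i in 1:20) {
    s <- sample(7501:10400, 1)
    k27 <- mkpc(s, s + sample(50:1000, 1), mark = "H3K27me3")
    state <- as.character(classifyPromoter(win, k4, k27)$state)
    expect_true(state %in% c("MIXED", "BIVALENT"))
  }
})

test_that("classifyAll rejects empty input and drop-everything noise gives NONE", {
  cfg <- simConfig(seed = 4, n_genes = 40, chrom_sizes = c(chr1 = 1e6),
                   peak_drop_prob = 1, n_decoy_peaks = 0L)
  st <- generateStudy(cfg)
  calls <- suppressMessages(
    classifyAll(st$annotation, st$peaks$H3K4me3, st$peaks$H3K27me3))
  expect_true(all(calls$state == "NONE"))

  expect_error(suppressMessages(
    classifyAll(GRanges(), st$peaks$H3K4me3, st$peaks$H3K27me3)),
    "no genes")
})

test_that("state-DE cross-tabulation applies strict threshold semantics", {
  calls <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    state = factor(c("BIVALENT", "K27_ONLY", "K4_ONLY", "NONE"),
                   levels = c("NONE", "K4_ONLY", "K27_ONLY", "MIXED",
                              "BIVALENT")),
    stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(1.2, -0.8, 2.0, 0.5),
                   q = c(0.049, 0.01, 0.05, 0.9))
  xt <- crosstabStateDE(calls, de)
  pg <- xt@per_gene
  expect_equal(as.character(pg$de_class[pg$gene_id == "a"]), "up")
  expect_equal(as.character(pg$de_class[pg$gene_id == "b"]), "down")
  # q exactly at the threshold: strict inequality, unchanged
  expect_equal(as.character(pg$de_class[pg$gene_id == "c"]), "unchanged")
  expect_equal(as.character(pg$de_class[pg$gene_id == "d"]), "unchanged")
  expect_equal(sum(stateCounts(xt)), 4L)

  # significant q with exactly zero fold change: unchanged plus warning
  de0 <- data.frame(gene_id = "a", log2fc = 0, q = 0.001)
  expect_warning(xt0 <- crosstabStateDE(calls[1, , drop = FALSE], de0),
                 "log2FC exactly 0")
  expect_equal(as.character(xt0@per_gene$de_class), "unchanged")

  # DE genes missing from the calls are skipped with a message
  dex <- rbind(de, data.frame(gene_id = "zz", log2fc = 3, q = 0.001))
  expect_message(crosstabStateDE(calls, dex), "absent")
})

test_that("cross-tab margins reproduce planted state-by-DE counts exactly", {
  cfg <- simConfig(seed = 14, n_genes = 400,
                   chrom_sizes = c(chr1 = 2e6, chr2 = 2e6))
  st <- generateStudy(cfg)
  calls <- suppressMessages(
    classifyAll(st$annotation, st$peaks$H3K4me3, st$peaks$H3K27me3))
  xt <- crosstabStateDE(calls, st$de)
  # planted truth as the reference cross-tabulation
  planted_state <- toupper(st$truth$states[calls$gene_id])
  planted_state[planted_state == "NONE"] <- "NONE"
  want <- table(
    state = factor(planted_state,
                   levels = c("NONE", "K4_ONLY", "K27_ONLY", "MIXED",
                              "BIVALENT")),
    de_class = factor(st$truth$de_direction[calls$gene_id],
                      levels = c("up", "down", "unchanged")))
  expect_equal(unclass(as.matrix(want)), unclass(stateCounts(xt)),
               ignore_attr = TRUE)
  # in strict-derepression mode no H3K27me3-bearing gene is downregulated
  expect_equal(sum(stateCounts(xt)[c("K27_ONLY", "MIXED", "BIVALENT"),
                                   "down"]), 0L)
})
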