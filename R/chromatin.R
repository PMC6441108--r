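#' StateDETable: promoter state x differential-expression cross-tabulation
#'
#' @slot per_gene data.frame with gene_id, state, de_class, log2fc, q.
#' @slot counts 5 x 3 integer matrix (states x up/down/unchanged).
#' @slot q_threshold the significance threshold used.
#'
#' @export
setClass("StateDETable",
  representation(
    per_gene = "data.frame",
    counts = "matrix",
    q_threshold = "numeric"
  )
)

setValidity("StateDETable", function(object) {
  if (sum(object@counts) != nrow(object@per_gene))
    "marginal counts must sum to the number of classified genes"
  else TRUE
})

#' @describeIn StateDETable display summary
#' @param object a StateDETable
#' @export
setMethod("show", "StateDETable", function(object) {
  cat("StateDETable (q <", object@q_threshold, "):\n")
  print(object@counts)
})

#' @describeIn StateDETable the 5 x 3 state-by-DE count matrix
#' @param x a StateDETable
#' @export
stateCounts <- function(x) x@counts

#' Retain peaks reproduced in a second replicate
#'
#' Keeps each replicate-1 peak that shares at least one base with any
#' replicate-2 peak, with its coordinates unchanged (retention, not
#' merging). Both collections must carry the same mark and condition.
#'
#' @param rep1,rep2 [PeakCollection-class] objects for the two replicates.
#' @return a [PeakCollection-class] of the retained rep1 peaks, sorted.
#' @examples
#' r1 <- PeakCollection(GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(101, 600)), "H3K4me3", "rep1")
#' r2 <- PeakCollection(GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(551, 900)), "H3K4me3", "rep2")
#' reproduciblePeaks(r1, r2)
#' @export
reproduciblePeaks <- function(rep1, rep2) {
  stopifnot(is(rep1, "PeakCollection"), is(rep2, "PeakCollection"))
  if (rep1@mark != rep2@mark)
    stop("mark mismatch: ", rep1@mark, " vs ", rep2@mark)
  if (rep1@condition != rep2@condition)
    stop("condition mismatch: ", rep1@condition, " vs ", rep2@condition)
  hits <- findOverlaps(peakRanges(rep1), peakRanges(rep2),
                       minoverlap = 1L, ignore.strand = TRUE)
  kept <- peakRanges(rep1)[sort(unique(queryHits(hits)))]
  new("PeakCollection", ranges = GenomicRanges::sort(kept),
      mark = rep1@mark, replicate = "reproducible",
      condition = rep1@condition)
}

## Vectorised five-state classification over a set of promoter windows.
## Returns a data.frame; classifyPromoter and classifyAll wrap it.
.classifyWindows <- function(windows, k4, k27,
                             bivalent_scope = c("in_window", "anywhere")) {
  bivalent_scope <- match.arg(bivalent_scope)
  k4gr <- if (is(k4, "PeakCollection")) peakRanges(k4) else k4
  k27gr <- if (is(k27, "PeakCollection")) peakRanges(k27) else k27
  n <- length(windows)
  h4 <- findOverlaps(windows, k4gr, minoverlap = 1L, ignore.strand = TRUE)
  h27 <- findOverlaps(windows, k27gr, minoverlap = 1L, ignore.strand = TRUE)
  has4 <- tabulate(queryHits(h4), n) > 0L
  has27 <- tabulate(queryHits(h27), n) > 0L

  fmt <- function(gr) if (length(gr)) sprintf("%s:%d-%d",
    as.character(seqnames(gr)), start(gr), end(gr)) else character()
  collapseBy <- function(hits, gr) {
    out <- character(n)
    if (length(hits)) {
      lab <- split(fmt(gr[subjectHits(hits)]), queryHits(hits))
      out[as.integer(names(lab))] <- vapply(lab, paste, "", collapse = ",")
    }
    out
  }
  k4_evidence <- collapseBy(h4, k4gr)
  k27_evidence <- collapseBy(h27, k27gr)

  ## candidate bivalent pairs: all (k4 peak, k27 peak) pairs attached to the
  ## same window; a window is bivalent when some pair's intersection is
  ## non-empty (and, under in_window scope, itself intersects the window)
  bivalent <- logical(n)
  biv_overlap <- rep(NA_character_, n)
  both <- which(has4 & has27)
  if (length(both)) {
    d4 <- data.frame(win = queryHits(h4), p4 = subjectHits(h4))
    d27 <- data.frame(win = queryHits(h27), p27 = subjectHits(h27))
    pairs <- merge(d4[d4$win %in% both, ], d27[d27$win %in% both, ],
                   by = "win")
    if (nrow(pairs)) {
      a <- k4gr[pairs$p4]
      b <- k27gr[pairs$p27]
      ov_start <- pmax(start(a), start(b))
      ov_end <- pmin(end(a), end(b))
      ok <- as.character(seqnames(a)) == as.character(seqnames(b)) &
        ov_start <= ov_end
      if (bivalent_scope == "in_window") {
        w <- windows[pairs$win]
        ok <- ok & pmax(ov_start, start(w)) <= pmin(ov_end, end(w))
      }
      if (any(ok)) {
        hit <- pairs[ok, , drop = FALSE]
        hs <- ov_start[ok]; he <- ov_end[ok]
        chr <- as.character(seqnames(a))[ok]
        ## first qualifying intersection in genomic order per window
        o <- order(hit$win, hs, he)
        first <- o[!duplicated(hit$win[o])]
        bivalent[hit$win[first]] <- TRUE
        biv_overlap[hit$win[first]] <-
          sprintf("%s:%d-%d", chr[first], hs[first], he[first])
      }
    }
  }
  state <- rep("NONE", n)
  state[has4 & !has27] <- "K4_ONLY"
  state[!has4 & has27] <- "K27_ONLY"
  state[has4 & has27] <- "MIXED"
  state[bivalent] <- "BIVALENT"
  data.frame(
    gene_id = if (!is.null(names(windows))) names(windows)
              else as.character(seq_len(n)),
    state = factor(state, levels = PROMOTER_STATES),
    n_k4 = tabulate(queryHits(h4), n),
    n_k27 = tabulate(queryHits(h27), n),
    k4_evidence = k4_evidence,
    k27_evidence = k27_evidence,
    bivalent_overlap = biv_overlap,
    stringsAsFactors = FALSE
  )
}

#' Classify one promoter window into the five-state chromatin scheme
#'
#' States: NONE (no peak of either mark in the window), K4_ONLY, K27_ONLY,
#' MIXED (both marks present but no H3K4me3/H3K27me3 peak pair overlaps),
#' BIVALENT (some H3K4me3 peak and H3K27me3 peak directly overlap, and --
#' under the default `in_window` scope -- their intersection itself
#' intersects the window).
#'
#' @param window single-range GRanges promoter window.
#' @param k4,k27 [PeakCollection-class] or GRanges of
#'   replicate-reproducible peaks for each mark.
#' @param bivalent_scope `"in_window"` (default: the K4/K27 intersection
#'   must fall inside the window) or `"anywhere"` (any direct overlap
#'   between two window-touching peaks qualifies).
#' @return one-row data.frame with gene_id, state, evidence columns and
#'   the bivalent overlap interval (or NA).
#' @export
classifyPromoter <- function(window, k4, k27,
                             bivalent_scope = c("in_window", "anywhere")) {
  stopifnot(is(window, "GRanges"), length(window) == 1L)
  .classifyWindows(window, k4, k27, bivalent_scope)
}

#' Classify every gene's promoter from two-replicate peak sets
#'
#' Applies [reproduciblePeaks()] per mark, derives promoter windows, and
#' classifies each gene. A state-count summary is emitted as a message.
#'
#' @param genes gene GRanges as from [readGeneAnnotation()].
#' @param k4_reps,k27_reps lists of two [PeakCollection-class] objects
#'   (replicates 1 and 2) per mark; a single PeakCollection is accepted
#'   and used as already-reproducible peaks.
#' @param upstream,downstream promoter window extent (bp).
#' @param chrom_sizes optional named lengths for window clipping.
#' @param bivalent_scope see [classifyPromoter()].
#' @return data.frame of per-gene calls (one row per gene).
#' @export
classifyAll <- function(genes, k4_reps, k27_reps,
                        upstream = 2500, downstream = 500,
                        chrom_sizes = NULL,
                        bivalent_scope = c("in_window", "anywhere")) {
  stopifnot(is(genes, "GRanges"))
  if (length(genes) == 0L) stop("no genes to classify")
  retain <- function(reps) {
    if (is(reps, "PeakCollection")) return(reps)
    stopifnot(is.list(reps), length(reps) == 2L)
    reproduciblePeaks(reps[[1]], reps[[2]])
  }
  k4 <- retain(k4_reps)
  k27 <- retain(k27_reps)
  win <- promoterWindows(genes, upstream = upstream,
                         downstream = downstream, chrom_sizes = chrom_sizes)
  calls <- .classifyWindows(win, k4, k27, bivalent_scope)
  counts <- table(calls$state)
  message("promoter states: ",
          paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                collapse = " "))
  calls
}

#' Cross-tabulate promoter states against differential expression
#'
#' Genes are classed up (q below threshold and log2FC > 0), down (q below
#' threshold and log2FC < 0) or unchanged; the threshold is strict
#' (q exactly equal to it is unchanged). DE genes absent from the calls
#' are skipped with a message.
#'
#' @param calls per-gene state calls from [classifyAll()].
#' @param de data.frame with columns gene_id, log2fc, q.
#' @param q_threshold FDR threshold, default 0.05.
#' @return a [StateDETable-class].
#' @export
crosstabStateDE <- function(calls, de, q_threshold = 0.05) {
  stopifnot(is.data.frame(de), all(c("gene_id", "log2fc", "q") %in% names(de)))
  missing <- setdiff(de$gene_id, calls$gene_id)
  if (length(missing)) {
    message(length(missing), " DE gene(s) absent from classification, skipped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
    de <- de[!de$gene_id %in% missing, , drop = FALSE]
  }
  de_class <- rep("unchanged", nrow(de))
  sig <- de$q < q_threshold
  de_class[sig & de$log2fc > 0] <- "up"
  de_class[sig & de$log2fc < 0] <- "down"
  if (any(sig & de$log2fc == 0))
    warning("gene(s) with q below threshold but log2FC exactly 0 classed unchanged")
  idx <- match(calls$gene_id, de$gene_id)
  per_gene <- data.frame(
    gene_id = calls$gene_id,
    state = calls$state,
    de_class = factor(ifelse(is.na(idx), "unchanged", de_class[idx]),
                      levels = DE_CLASSES),
    log2fc = de$log2fc[idx],
    q = de$q[idx],
    stringsAsFactors = FALSE
  )
  counts <- table(state = per_gene$state, de_class = per_gene$de_class)
  new("StateDETable",
      per_gene = per_gene,
      counts = unclass(as.matrix(counts)),
      q_threshold = q_threshold)
}
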