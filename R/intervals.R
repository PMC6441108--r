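#' Read a peak file (BED3/BED6 or narrowPeak) into a PeakCollection
#'
#' BED-family coordinates are 0-based half-open; they are converted to the
#' 1-based closed convention of GRanges on load. Malformed lines are
#' reported with their line numbers.
#'
#' @param path path to a .bed, .narrowPeak or .np file.
#' @param mark histone mark label stored on the collection.
#' @param replicate replicate identifier.
#' @param condition condition label.
#' @return a [PeakCollection-class].
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t600\tp1\t0\t.", f)
#' readPeaks(f, mark = "H3K4me3")
#' @export
readPeaks <- function(path, mark, replicate = "rep1", condition = "untreated") {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("bed", "narrowpeak", "np"))
    stop("unknown peak file dialect: .", ext,
         " (expected .bed, .narrowPeak or .np)")
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty peak file: ", path)
    return(PeakCollection(GRanges(), mark = mark, replicate = replicate,
                          condition = condition))
  }
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  minf <- if (ext == "bed") 3L else 10L
  if (any(nf < minf))
    stop("format error: line(s) ", paste(which(nf < minf), collapse = ", "),
         " have fewer than ", minf, " fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0)
  if (length(bad))
    stop("format error: start >= end (or non-numeric coordinates) at line(s) ",
         paste(bad, collapse = ", "))
  name <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  score <- if (all(nf >= 5L))
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))) else NULL
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  if (!is.null(name)) gr$name <- name
  if (!is.null(score)) gr$score <- score
  PeakCollection(gr, mark = mark, replicate = replicate, condition = condition)
}

#' Read a gene annotation (BED6 or minimal GTF) into a gene GRanges
#'
#' BED6 input: TSS = start for + strand, end - 1 for - strand (0-based).
#' GTF input: records with feature "gene" are taken; coordinates converted
#' from 1-based inclusive. The returned GRanges holds one gene body per
#' gene id (names = gene ids) with a `tss` metadata column giving the
#' 1-based TSS position.
#'
#' @param path path to a .bed or .gtf/.gff file.
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   supplied, TSS positions are validated against them and recorded as
#'   seqlengths.
#' @return a GRanges with names = gene ids, strand set, and mcols `tss`.
#' @export
readGeneAnnotation <- function(path, chrom_sizes = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6L))
      stop("format error: gene BED needs 6 columns (strand missing) at line(s) ",
           paste(which(nf < 6L), collapse = ", "))
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- as.numeric(vapply(fields, `[[`, "", 2L))
    end0 <- as.numeric(vapply(fields, `[[`, "", 3L))
    gene_id <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, `[[`, "", 6L)
    if (any(is.na(start0) | is.na(end0) | start0 >= end0))
      stop("format error: start >= end at line(s) ",
           paste(which(start0 >= end0), collapse = ", "))
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  } else if (ext %in% c("gtf", "gff")) {
    tab <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "source", "feature",
                                           "start", "end", "score", "strand",
                                           "frame", "attributes"))
    tab <- tab[tab$feature == "gene", , drop = FALSE]
    if (!nrow(tab)) stop("no 'gene' features found in ", path)
    m <- regmatches(tab$attributes,
                    regexpr('gene_id "[^"]+"', tab$attributes))
    if (length(m) != nrow(tab))
      stop("format error: gene_id attribute missing from some records")
    gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
    gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end), strand = tab$strand)
  } else {
    stop("unknown annotation dialect: .", ext)
  }
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("format error: every gene needs strand + or -")
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  names(gr) <- gene_id
  gr$tss <- ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
  if (!is.null(chrom_sizes)) {
    cs <- chrom_sizes[as.character(seqnames(gr))]
    if (any(is.na(cs)))
      stop("genes on chromosomes absent from chrom_sizes")
    if (any(gr$tss < 1 | gr$tss > cs))
      stop("TSS outside [1, chromosome length] for some genes")
    GenomeInfoDb::seqlengths(gr) <-
      chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Read a two-column chromosome-sizes TSV
#'
#' @param path TSV with columns chromosome name and length (no header).
#' @return named numeric vector of lengths.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Strand-aware promoter windows around gene TSSs
#'
#' The window spans `upstream` bp upstream to `downstream` bp downstream of
#' the TSS in the direction of transcription (defaults -2.5 kb to +0.5 kb,
#' the usual promoter definition). Windows are clipped to chromosome
#' bounds when sizes are available; a window entirely off its chromosome
#' is an error.
#'
#' @param genes a GRanges of gene bodies as returned by
#'   [readGeneAnnotation()] (names = gene ids, `tss` metadata column), or
#'   any stranded GRanges whose start/end encode the TSS.
#' @param upstream,downstream window extent in bp (both >= 0, not both 0).
#' @param chrom_sizes optional named vector of chromosome lengths used for
#'   clipping (seqlengths on `genes` are used if present).
#' @return a GRanges of promoter windows, names = gene ids, with mcols
#'   `tss`, `upstream`, `downstream`.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 15000),
#'                             strand = "+")
#' names(g) <- "geneA"
#' promoterWindows(g)  # chr1:7501-10500
#' @export
promoterWindows <- function(genes, upstream = 2500, downstream = 500,
                            chrom_sizes = NULL) {
  stopifnot(is(genes, "GRanges"))
  if (upstream < 0 || downstream < 0 || (upstream == 0 && downstream == 0))
    stop("upstream and downstream must be >= 0 and not both 0")
  st <- as.character(strand(genes))
  if (any(!st %in% c("+", "-"))) stop("all genes must be stranded + or -")
  tss <- if (!is.null(genes$tss)) genes$tss else
    ifelse(st == "+", start(genes), end(genes))
  win_start <- ifelse(st == "+", tss - upstream, tss - downstream + 1)
  win_end <- ifelse(st == "+", tss + downstream - 1, tss + upstream)
  if (is.null(chrom_sizes) &&
      !all(is.na(GenomeInfoDb::seqlengths(genes)))) {
    chrom_sizes <- GenomeInfoDb::seqlengths(genes)
  }
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes[as.character(seqnames(genes))]
    dead <- which(win_end < 1 | (!is.na(len) & win_start > len))
    if (length(dead))
      stop("degenerate promoter window (entirely off chromosome) for gene(s): ",
           paste(names(genes)[dead], collapse = ", "))
    win_start <- pmax(win_start, 1)
    win_end <- ifelse(is.na(len), win_end, pmin(win_end, len))
  } else {
    dead <- which(win_end < 1)
    if (length(dead))
      stop("degenerate promoter window (entirely off chromosome) for gene(s): ",
           paste(names(genes)[dead], collapse = ", "))
    win_start <- pmax(win_start, 1)
  }
  win <- GRanges(seqnames(genes), IRanges(win_start, win_end), strand = st)
  names(win) <- names(genes)
  win$tss <- tss
  win$upstream <- upstream
  win$downstream <- downstream
  win
}

#' Overlap length between two intervals
#'
#' Number of shared bases between interval `a` and interval `b`; zero when
#' they lie on different chromosomes or merely abut.
#'
#' @param a,b single-range GRanges (or parallel GRanges of equal length,
#'   compared element-wise).
#' @return integer vector of shared base counts.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 15))
#' overlapLength(a, b)  # 5
#' @export
overlapLength <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stop("a and b must have equal length (or one of length 1)")
  }
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  as.integer(ifelse(same, pmax(0L, ov), 0L))
}

#' Peaks overlapping a promoter window
#'
#' Returns every peak sharing at least one base with the window, in
#' genomic order (interval-tree lookup via [GenomicRanges::findOverlaps]).
#'
#' @param window a single-range GRanges (a promoter window).
#' @param peaks a [PeakCollection-class] or GRanges.
#' @return GRanges of the overlapping peaks in genomic order.
#' @export
peaksOverlapping <- function(window, peaks) {
  stopifnot(is(window, "GRanges"), length(window) == 1L)
  gr <- if (is(peaks, "PeakCollection")) peakRanges(peaks) else peaks
  hits <- findOverlaps(window, gr, minoverlap = 1L, ignore.strand = TRUE)
  GenomicRanges::sort(gr[subjectHits(hits)], ignore.strand = TRUE)
}
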