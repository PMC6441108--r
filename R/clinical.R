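#' Composite immunohistochemistry score
#'
#' Product of the percent-positive class P (0-4) and the staining
#' intensity class I (0-3), giving a composite score between 0 and 12.
#'
#' @param P integer ordinal in 0..4.
#' @param I integer ordinal in 0..3.
#' @return integer composite score(s), vectorised.
#' @examples
#' compositeScore(4, 3)  # 12
#' @export
compositeScore <- function(P, I) {
  if (any(is.na(P)) || any(P != as.integer(P)) || any(P < 0) || any(P > 4))
    stop("P must be an integer in 0..4")
  if (any(is.na(I)) || any(I != as.integer(I)) || any(I < 0) || any(I > 3))
    stop("I must be an integer in 0..3")
  as.integer(P) * as.integer(I)
}

#' Top and bottom quintiles by composite IHC score
#'
#' Ranks patients by composite score and takes the lowest and highest
#' ceiling(n/5) as the extreme groups. Records tied with the realised cut
#' score are all included in the nearer extreme group, and the realised
#' cut points are reported. Fully degenerate scores (overlapping groups)
#' are an error: explicit cut points are needed then.
#'
#' @param records data.frame with columns patient_id, composite (or P and
#'   I, from which composite is computed) and recurrence (logical/0-1).
#' @return list with `top`, `bottom` (data.frame subsets) and `cuts`
#'   (named numeric: low, high).
#' @export
quintileGroups <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"composite" %in% names(records)) {
    stopifnot(all(c("P", "I") %in% names(records)))
    records$composite <- compositeScore(records$P, records$I)
  }
  n <- nrow(records)
  if (n < 5L) stop("need at least 5 records for quintiles")
  k <- ceiling(n / 5)
  s <- sort(records$composite)
  cut_low <- s[k]
  cut_high <- s[n - k + 1L]
  bottom <- records[records$composite <= cut_low, , drop = FALSE]
  top <- records[records$composite >= cut_high, , drop = FALSE]
  if (any(rownames(top) %in% rownames(bottom)))
    stop("quintile groups overlap (scores too degenerate); ",
         "supply explicit cut points")
  list(top = top, bottom = bottom,
       cuts = c(low = cut_low, high = cut_high))
}

#' Chi-square test of recurrence between extreme IHC score groups
#'
#' Pearson chi-square without continuity correction on the 2x2
#' group-by-recurrence table, with per-group recurrence percentages.
#'
#' @param top,bottom data.frames with a `recurrence` column (logical or
#'   0/1), as returned by [quintileGroups()].
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `table` (2x2), `statistic`, `p.value` and
#'   `percentages` (named: top, bottom).
#' @export
recurrenceTest <- function(top, bottom, correct = FALSE) {
  if (!nrow(top) || !nrow(bottom)) stop("both groups must be non-empty")
  tab <- rbind(
    top = c(recur = sum(top$recurrence), no = sum(!top$recurrence)),
    bottom = c(recur = sum(bottom$recurrence), no = sum(!bottom$recurrence))
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the 2x2 table; use an exact test")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(table = tab,
       statistic = unname(ct$statistic),
       p.value = ct$p.value,
       percentages = c(top = 100 * mean(top$recurrence != 0),
                       bottom = 100 * mean(bottom$recurrence != 0)))
}

#' Correlate a target gene with each gene of a signature
#'
#' Pearson correlation of the target gene's expression row against every
#' signature gene's row across samples, ordered by r for heat-strip
#' display (inverse correlations at one end, positive at the other).
#' Signature genes absent from the matrix are listed, not imputed;
#' zero-variance rows yield NA with a flag.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns; at least 3 samples.
#' @param target target gene id, present in `expr`.
#' @param signature character vector of signature gene ids.
#' @param signature_name label stored on the result.
#' @return data.frame with columns gene_id, r, sorted by r; attributes
#'   `target`, `signature_name`, `n_samples`, `missing` (absent genes)
#'   and `zero_variance` (flagged genes).
#' @export
signatureCorrelation <- function(expr, target, signature,
                                 signature_name = "signature") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  if (!target %in% rownames(expr)) stop("target gene absent from matrix")
  present <- intersect(signature, rownames(expr))
  if (!length(present)) stop("no signature gene present in matrix")
  missing <- setdiff(signature, present)
  tvec <- expr[target, ]
  if (stats::sd(tvec) == 0) stop("target row has zero variance")
  r <- vapply(present, function(g) {
    if (stats::sd(expr[g, ]) == 0) return(NA_real_)
    stats::cor(tvec, expr[g, ])
  }, numeric(1))
  zerovar <- present[is.na(r)]
  if (length(zerovar))
    warning("zero-variance signature row(s): ",
            paste(zerovar, collapse = ", "))
  out <- data.frame(gene_id = present, r = unname(r),
                    stringsAsFactors = FALSE)
  out <- out[order(out$r, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "signature_name") <- signature_name
  attr(out, "n_samples") <- ncol(expr)
  attr(out, "missing") <- missing
  attr(out, "zero_variance") <- zerovar
  out
}

#' Read a clinical IHC table
#'
#' @param path TSV with header columns patient_id, P, I, recurrence.
#' @return data.frame with an added composite column.
#' @export
readClinicalTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("patient_id", "P", "I", "recurrence")
  if (!all(need %in% names(tab)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  tab$composite <- compositeScore(tab$P, tab$I)
  tab
}
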