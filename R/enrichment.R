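#' Rank genes by a signed differential-expression metric
#'
#' @param de data.frame with columns gene_id, log2fc, q.
#' @param metric `"signed_log2fc"` (default) or `"signed_logq"`
#'   (-log10(q) carrying the sign of log2FC).
#' @return named numeric vector, sorted in decreasing metric order with
#'   ties broken by gene id (lexicographic); attribute `metric` records
#'   the choice.
#' @examples
#' de <- data.frame(gene_id = c("A", "B", "C"),
#'                  log2fc = c(2, -1, 0.5), q = c(0.01, 0.2, 0.04))
#' rankGenes(de)
#' @export
rankGenes <- function(de, metric = c("signed_log2fc", "signed_logq")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(de), all(c("gene_id", "log2fc") %in% names(de)))
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene ids in DE table")
  vals <- switch(metric,
    signed_log2fc = de$log2fc,
    signed_logq = -log10(de$q) * sign(de$log2fc))
  if (any(!is.finite(vals))) stop("non-finite ranking metric values")
  o <- order(-vals, de$gene_id)
  out <- stats::setNames(vals[o], de$gene_id[o])
  attr(out, "metric") <- metric
  out
}

## Signed maximum deviation of the weighted running sum, computed from the
## sorted hit positions only (O(k) per evaluation). Candidates for the
## extreme are the values just after each hit and just before each hit;
## ties in |value| resolve to the earliest list position, matching a full
## left-to-right scan.
.esFromHits <- function(h, absw_h, N) {
  k <- length(h)
  nw <- N - k
  W <- sum(absw_h)
  chit <- if (W > 0) cumsum(absw_h) / W else seq_len(k) / k
  miss <- (h - seq_len(k)) / nw
  after <- chit - miss
  before <- c(0, chit[-k]) - miss
  vals <- c(after, before)
  pos <- c(h, h - 1L)
  best <- max(abs(vals))
  if (best == 0) return(0)
  cand <- which(abs(vals) >= best - 0)
  vals[cand[which.min(pos[cand])]]
}

#' Weighted GSEA enrichment score with running-sum profile
#'
#' Classic weighted Kolmogorov-Smirnov statistic: walking down the ranked
#' list, set members add |metric|^p normalised by the total hit weight,
#' non-members subtract 1/(N - n_set); the enrichment score is the signed
#' maximum deviation of this running sum.
#'
#' @param ranked named numeric from [rankGenes()] (decreasing).
#' @param set character vector of member gene ids (a GMT entry).
#' @param weight_exponent p in |metric|^p; 1 (default) is standard
#'   weighted GSEA, 0 the unweighted KS statistic.
#' @return an [EnrichmentResult-class] with `es` and the full
#'   `running_sum` profile (no permutation fields).
#' @export
enrichmentScore <- function(ranked, set, weight_exponent = 1) {
  N <- length(ranked)
  ids <- names(ranked)
  hit <- ids %in% set
  k <- sum(hit)
  if (k == 0L) stop("gene set does not intersect the ranked list")
  if (k == N) stop("gene set spans the whole ranked universe (degenerate)")
  w <- abs(ranked)^weight_exponent
  W <- sum(w[hit])
  inc <- if (W > 0) w * hit / W else hit / k
  dec <- (!hit) / (N - k)
  rs <- cumsum(inc - dec)
  i <- which.max(abs(rs))
  new("EnrichmentResult", set_name = "set", es = rs[[i]],
      running_sum = as.numeric(rs), null_es = numeric())
}

## Null ES for B random same-size gene sets (gene-set permutation),
## vectorised across permutations.
.nullES <- function(absw, N, k, B) {
  nw <- N - k
  vapply(seq_len(B), function(b) {
    h <- sort.int(sample.int(N, k))
    .esFromHits(h, absw[h], N)
  }, numeric(1))
}

#' Permutation test of one gene set against a ranked list
#'
#' The null distribution is built by gene-set permutation: random sets of
#' the same size drawn without replacement from the ranked universe. NES
#' is the observed ES divided by the mean |null ES| of the same sign;
#' the nominal p-value is add-one smoothed within the same-sign null,
#' p = (1 + #same-sign nulls at least as extreme) / (1 + #same-sign nulls).
#'
#' @param ranked named numeric from [rankGenes()].
#' @param set character vector of member gene ids.
#' @param n_permutations number of random sets (default 10000, the usual
#'   gene-set-permutation depth).
#' @param weight_exponent see [enrichmentScore()].
#' @param seed integer seed for the permutation stream.
#' @param set_name label stored on the result.
#' @return an [EnrichmentResult-class] with es, nes, nominal_p and the
#'   stored null sample (needed by [fwerCorrect()]).
#' @export
permutationTest <- function(ranked, set, n_permutations = 10000,
                            weight_exponent = 1, seed = 1,
                            set_name = "set") {
  stopifnot(n_permutations >= 1)
  obs <- enrichmentScore(ranked, set, weight_exponent)
  N <- length(ranked)
  k <- sum(names(ranked) %in% set)
  absw <- abs(ranked)^weight_exponent
  null_es <- withStageSeed(seed, "permutation",
                           .nullES(absw, N, k, as.integer(n_permutations)))
  s <- if (obs@es >= 0) 1 else -1
  same <- null_es * s > 0
  m <- sum(same)
  if (m == 0L) {
    warning("no same-sign null enrichment scores; p-value saturated at 1")
    nes <- if (mean(abs(null_es)) > 0) obs@es / mean(abs(null_es)) else NA_real_
    p <- 1
  } else {
    nes <- obs@es / mean(abs(null_es[same]))
    p <- (1 + sum(abs(null_es[same]) >= abs(obs@es))) / (1 + m)
  }
  new("EnrichmentResult", set_name = set_name, es = obs@es, nes = nes,
      nominal_p = p, running_sum = obs@running_sum, null_es = null_es,
      n_permutations = as.integer(n_permutations), seed = as.integer(seed))
}

#' Family-wise error correction across enrichment results
#'
#' Max-statistic permutation FWER: each permutation round's null ES values
#' are normalised per set (sign-matched null means, as for NES) and the
#' family maximum of |null NES| per round forms the reference
#' distribution; a set's FWER p is the add-one-smoothed fraction of
#' rounds whose maximum reaches its |NES|. Corrected p-values are floored
#' at the nominal p-value, as a correction never increases significance.
#'
#' @param results list of [EnrichmentResult-class] sharing one null family
#'   (same n_permutations).
#' @return the list with `fwer_p` filled in.
#' @export
fwerCorrect <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  lens <- vapply(results, function(r) length(r@null_es), integer(1))
  if (length(unique(lens)) != 1L || lens[1] == 0L)
    stop("all results must carry null samples of equal length")
  null_nes <- vapply(results, function(r) {
    ne <- r@null_es
    mp <- mean(ne[ne > 0])
    mn <- mean(abs(ne[ne < 0]))
    out <- ifelse(ne > 0, ne / mp, ne / mn)
    out[ne == 0] <- 0
    out
  }, numeric(lens[1]))
  maxstat <- apply(abs(null_nes), 1L, max)
  R <- lens[1]
  lapply(results, function(r) {
    raw <- (1 + sum(maxstat >= abs(r@nes))) / (1 + R)
    r@fwer_p <- max(raw, r@nominal_p)
    r
  })
}

#' Resampled gene-subset enrichment summary
#'
#' Repeatedly draws random subsets of a promoter-state gene pool, runs the
#' gene-set permutation test on each, and summarises the NES distribution,
#' the percentage of subsets significantly enriched in each direction, and
#' the least significant subset (largest nominal p). Subsets are drawn
#' independently (they may share genes across draws), each without
#' replacement within the draw.
#'
#' @param ranked named numeric from [rankGenes()].
#' @param pool character vector: the state class's gene pool.
#' @param n_subsets number of subsets (default 30).
#' @param subset_size genes per subset (default 200).
#' @param n_permutations permutations per subset test.
#' @param alpha nominal-p significance threshold (default 0.25, the usual
#'   exploratory GSEA cut).
#' @param weight_exponent see [enrichmentScore()].
#' @param seed integer root seed; subset draws and per-subset permutation
#'   streams derive from it.
#' @param state_class label stored on the summary.
#' @return a [ResampleSummary-class].
#' @export
resampledEnrichment <- function(ranked, pool, n_subsets = 30,
                                subset_size = 200, n_permutations = 1000,
                                alpha = 0.25, weight_exponent = 1,
                                seed = 1, state_class = "pool") {
  pool <- intersect(pool, names(ranked))
  if (length(pool) < subset_size)
    stop("pool has ", length(pool), " genes in the ranked list; ",
         subset_size, " required per subset")
  subsets <- withStageSeed(seed, "subsets",
    lapply(seq_len(n_subsets), function(i) sample(pool, subset_size)))
  results <- lapply(seq_len(n_subsets), function(i) {
    permutationTest(ranked, subsets[[i]], n_permutations = n_permutations,
                    weight_exponent = weight_exponent,
                    seed = deriveSeed(seed, paste0("subset", i)),
                    set_name = paste0(state_class, "_subset_", i))
  })
  nes_v <- vapply(results, nes, numeric(1))
  p_v <- vapply(results, nominalP, numeric(1))
  es_v <- vapply(results, es, numeric(1))
  pct <- function(dir) {
    inDir <- if (dir > 0) es_v > 0 else es_v < 0
    if (!any(inDir)) return(0)
    100 * sum(inDir & p_v < alpha) / sum(inDir)
  }
  new("ResampleSummary",
      state_class = state_class,
      n_subsets = as.integer(n_subsets),
      subset_size = as.integer(subset_size),
      alpha = alpha,
      results = results,
      nes_quartiles = unname(stats::quantile(nes_v, c(0.25, 0.5, 0.75),
                                             na.rm = TRUE)),
      pct_significant_up = pct(+1),
      pct_significant_down = pct(-1),
      least_significant_index = which.max(p_v))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: set name, description, then member ids,
#'   tab-separated.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("format error: GMT lines need name, description and >= 1 member")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked list as a two-column RNK-style TSV
#'
#' @param ranked named numeric from [rankGenes()].
#' @param path output path.
#' @export
writeRnk <- function(ranked, path) {
  utils::write.table(data.frame(gene_id = names(ranked),
                                metric = as.numeric(ranked)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
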