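#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   promoters findOverlaps pintersect sort
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata
NULL

PROMOTER_STATES <- c("NONE", "K4_ONLY", "K27_ONLY", "MIXED", "BIVALENT")
DE_CLASSES <- c("up", "down", "unchanged")

#' PeakCollection: one mark's peak calls for one replicate and condition
#'
#' Thin wrapper around a [GenomicRanges::GRanges] holding ChIP-seq peak
#' intervals for a single histone mark, replicate and condition. Intervals
#' are kept sorted by (seqname, start); duplicate identical peaks are
#' deduplicated at construction with a warning.
#'
#' @slot ranges GRanges of peak intervals (1-based, closed; converted from
#'   BED's 0-based half-open convention at read time).
#' @slot mark character, e.g. "H3K4me3" or "H3K27me3".
#' @slot replicate character replicate identifier.
#' @slot condition character condition label, e.g. "DMSO".
#'
#' @export
setClass("PeakCollection",
  representation(
    ranges = "GRanges",
    mark = "character",
    replicate = "character",
    condition = "character"
  )
)

setValidity("PeakCollection", function(object) {
  msg <- character()
  if (length(object@mark) != 1L || is.na(object@mark) || !nzchar(object@mark))
    msg <- c(msg, "'mark' must be a single non-empty string")
  if (length(object@replicate) != 1L)
    msg <- c(msg, "'replicate' must be a single string")
  if (length(object@condition) != 1L)
    msg <- c(msg, "'condition' must be a single string")
  if (length(object@ranges) && any(width(object@ranges) < 1L))
    msg <- c(msg, "all peaks must have width >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakCollection
#'
#' @param ranges a GRanges of peak intervals.
#' @param mark histone mark label.
#' @param replicate replicate identifier.
#' @param condition condition label.
#' @return a [PeakCollection-class] object with sorted, deduplicated peaks.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 600))
#' PeakCollection(gr, mark = "H3K4me3", replicate = "rep1")
#' @export
PeakCollection <- function(ranges, mark, replicate = "rep1",
                           condition = "untreated") {
  stopifnot(is(ranges, "GRanges"))
  if (anyDuplicated(ranges)) {
    warning("duplicate identical peaks removed on load")
    ranges <- unique(ranges)
  }
  new("PeakCollection", ranges = GenomicRanges::sort(ranges),
      mark = as.character(mark), replicate = as.character(replicate),
      condition = as.character(condition))
}

#' @describeIn PeakCollection peak intervals as a GRanges
#' @param x,object a PeakCollection
#' @export
peakRanges <- function(x) x@ranges

#' @describeIn PeakCollection histone mark label
#' @export
peakMark <- function(x) x@mark

#' @describeIn PeakCollection number of peaks
#' @export
setMethod("length", "PeakCollection", function(x) length(x@ranges))

#' @describeIn PeakCollection display summary
#' @export
setMethod("show", "PeakCollection", function(object) {
  cat("PeakCollection:", object@mark, "/", object@replicate,
      "/", object@condition, "\n")
  cat(" ", length(object@ranges), "peaks on",
      length(unique(as.character(seqnames(object@ranges)))), "chromosome(s)\n")
})

#' SimConfig: parameters of the synthetic study generator
#'
#' Defines the full study design the generators emulate: genome layout,
#' planted promoter-state proportions, ChIP-seq replicate noise, the
#' differential-expression effect of H3K27me3-bearing promoters, the
#' limiting-dilution dose ladder, and the clinical score-recurrence effect.
#'
#' @slot seed integer root seed; every generator derives an independent
#'   substream from it so stages never perturb one another.
#' @slot n_genes number of genes to simulate.
#' @slot chrom_sizes named numeric vector of chromosome lengths (bp).
#' @slot state_proportions named numeric over
#'   none/k4_only/k27_only/mixed/bivalent, summing to 1.
#' @slot peak_width typical planted peak width (bp).
#' @slot peak_jitter_sd per-replicate peak boundary jitter sd (bp).
#' @slot peak_drop_prob per-replicate probability that a planted peak is
#'   missing from that replicate's call set.
#' @slot n_decoy_peaks intergenic decoy peaks per mark per replicate.
#' @slot de_effect log-odds increase of upregulation for genes whose
#'   promoter carries H3K27me3 (k27_only, mixed or bivalent states).
#' @slot de_baseline baseline log-odds of a gene being significantly
#'   regulated.
#' @slot strict_derepression logical; when TRUE and de_effect > 0, no
#'   H3K27me3-bearing gene is planted as downregulated.
#' @slot lda_frequencies named numeric, true initiating-cell frequency per
#'   group (per cell).
#' @slot lda_doses integer vector, cells per well/injection.
#' @slot lda_wells wells (replicates) per dose.
#' @slot n_patients patients in the clinical table.
#' @slot clinical_effect recurrence log-odds per unit composite IHC score.
#' @slot clinical_baseline baseline recurrence log-odds.
#'
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    n_genes = "integer",
    chrom_sizes = "numeric",
    state_proportions = "numeric",
    peak_width = "numeric",
    peak_jitter_sd = "numeric",
    peak_drop_prob = "numeric",
    n_decoy_peaks = "integer",
    de_effect = "numeric",
    de_baseline = "numeric",
    strict_derepression = "logical",
    lda_frequencies = "numeric",
    lda_doses = "integer",
    lda_wells = "integer",
    n_patients = "integer",
    clinical_effect = "numeric",
    clinical_baseline = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  sp <- object@state_proportions
  if (!setequal(names(sp), c("none", "k4_only", "k27_only", "mixed", "bivalent")))
    msg <- c(msg, "state_proportions must be named none/k4_only/k27_only/mixed/bivalent")
  if (any(sp < 0)) msg <- c(msg, "state_proportions must be nonnegative")
  if (abs(sum(sp) - 1) > 1e-9) msg <- c(msg, "state_proportions must sum to 1")
  if (object@n_genes < 1L) msg <- c(msg, "n_genes must be >= 1")
  if (!length(object@chrom_sizes) || is.null(names(object@chrom_sizes)))
    msg <- c(msg, "chrom_sizes must be a named vector")
  if (object@peak_drop_prob < 0 || object@peak_drop_prob > 1)
    msg <- c(msg, "peak_drop_prob must be in [0, 1]")
  if (any(object@lda_frequencies <= 0) || any(object@lda_frequencies > 1))
    msg <- c(msg, "lda_frequencies must be in (0, 1]")
  if (any(object@lda_doses < 1L)) msg <- c(msg, "lda_doses must be positive integers")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig display summary
#' @param object a SimConfig
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|", object@n_genes, "genes on",
      length(object@chrom_sizes), "chromosome(s)\n")
  cat("  states:", paste(sprintf("%s=%.2f", names(object@state_proportions),
                                 object@state_proportions), collapse = " "), "\n")
  cat("  peaks: width", object@peak_width, "bp, jitter sd",
      object@peak_jitter_sd, "bp, drop prob", object@peak_drop_prob, "\n")
  cat("  DE: baseline", object@de_baseline, "effect", object@de_effect,
      if (object@strict_derepression) "(strict derepression)" else "", "\n")
  cat("  LDA: doses", paste(object@lda_doses, collapse = "/"), "x",
      object@lda_wells, "wells;", length(object@lda_frequencies), "group(s)\n")
})

#' EnrichmentResult: one gene set scored against one ranked list
#'
#' @slot set_name gene-set name.
#' @slot es enrichment score in [-1, 1], the signed maximum deviation of
#'   the weighted running sum.
#' @slot nes normalised enrichment score (ES divided by the mean |null ES|
#'   of the same sign).
#' @slot nominal_p add-one-smoothed permutation p-value within the
#'   same-sign null.
#' @slot fwer_p family-wise-error-corrected p (max-statistic method), NA
#'   until [fwerCorrect()] is applied.
#' @slot running_sum numeric profile of the running enrichment statistic
#'   over the ranked list, for plotting.
#' @slot null_es the permutation null ES sample (kept for FWER correction).
#' @slot n_permutations,seed permutation count and seed used.
#'
#' @export
setClass("EnrichmentResult",
  representation(
    set_name = "character",
    es = "numeric",
    nes = "numeric",
    nominal_p = "numeric",
    fwer_p = "numeric",
    running_sum = "numeric",
    null_es = "numeric",
    n_permutations = "integer",
    seed = "integer"
  ),
  prototype(fwer_p = NA_real_, nes = NA_real_, nominal_p = NA_real_,
            n_permutations = 0L, seed = NA_integer_)
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (abs(object@es) > 1 + 1e-12) msg <- c(msg, "|ES| must be <= 1")
  if (!is.na(object@nominal_p) && object@n_permutations > 0 &&
      object@nominal_p < 1 / (object@n_permutations + 1) - 1e-12)
    msg <- c(msg, "nominal_p below the attainable permutation floor")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentResult display summary
#' @param object an EnrichmentResult
#' @export
setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult '%s': ES = %.4f", object@set_name, object@es))
  if (!is.na(object@nes)) cat(sprintf(", NES = %.4f", object@nes))
  if (!is.na(object@nominal_p)) cat(sprintf(", p = %.4g", object@nominal_p))
  if (!is.na(object@fwer_p)) cat(sprintf(", FWER p = %.4g", object@fwer_p))
  cat("\n")
})

#' @describeIn EnrichmentResult the enrichment score
#' @param x an EnrichmentResult
#' @export
es <- function(x) x@es

#' @describeIn EnrichmentResult the normalised enrichment score
#' @export
nes <- function(x) x@nes

#' @describeIn EnrichmentResult the nominal permutation p-value
#' @export
nominalP <- function(x) x@nominal_p

#' @describeIn EnrichmentResult the FWER-corrected p-value
#' @export
fwerP <- function(x) x@fwer_p

#' ResampleSummary: resampled gene-subset enrichment summary
#'
#' Holds the per-subset enrichment results for repeated random subsets of
#' one promoter-state gene pool, the NES distribution quartiles, the
#' percentage of subsets significantly enriched in each direction, and the
#' least significant result (largest nominal p).
#'
#' @slot state_class label of the pooled promoter state class.
#' @slot n_subsets,subset_size,alpha resampling design.
#' @slot results list of [EnrichmentResult-class], one per subset.
#' @slot nes_quartiles numeric of length 3 (25/50/75% of subset NES).
#' @slot pct_significant_up percentage of positively enriched subsets with
#'   nominal p < alpha, among positively enriched subsets (0 if none).
#' @slot pct_significant_down same for negative enrichment.
#' @slot least_significant_index index into results of the subset with the
#'   largest nominal p.
#'
#' @export
setClass("ResampleSummary",
  representation(
    state_class = "character",
    n_subsets = "integer",
    subset_size = "integer",
    alpha = "numeric",
    results = "list",
    nes_quartiles = "numeric",
    pct_significant_up = "numeric",
    pct_significant_down = "numeric",
    least_significant_index = "integer"
  )
)

setValidity("ResampleSummary", function(object) {
  msg <- character()
  if (object@pct_significant_up < 0 || object@pct_significant_up > 100 ||
      object@pct_significant_down < 0 || object@pct_significant_down > 100)
    msg <- c(msg, "pct_significant_* must lie in [0, 100]")
  if (length(object@results) != object@n_subsets)
    msg <- c(msg, "results length must equal n_subsets")
  if (length(msg)) msg else TRUE
})

#' @describeIn ResampleSummary display summary
#' @param object a ResampleSummary
#' @export
setMethod("show", "ResampleSummary", function(object) {
  cat(sprintf("ResampleSummary '%s': %d subsets of %d genes\n",
              object@state_class, object@n_subsets, object@subset_size))
  cat(sprintf("  NES quartiles: %.3f / %.3f / %.3f\n",
              object@nes_quartiles[1], object@nes_quartiles[2],
              object@nes_quartiles[3]))
  cat(sprintf("  significant (p < %.2f): %.0f%% up, %.0f%% down\n",
              object@alpha, object@pct_significant_up,
              object@pct_significant_down))
  ls <- object@results[[object@least_significant_index]]
  cat(sprintf("  least significant subset: ES = %.3f, p = %.4g\n",
              ls@es, ls@nominal_p))
})

#' @describeIn ResampleSummary the least significant subset result
#' @param x a ResampleSummary
#' @export
leastSignificant <- function(x) x@results[[x@least_significant_index]]

#' LDAFit: single-hit Poisson limiting-dilution fit for one group
#'
#' @slot group group label.
#' @slot log_f natural log of the per-cell initiating frequency.
#' @slot se_log_f Wald standard error of log f.
#' @slot frequency point estimate of f.
#' @slot one_in "1 in N" presentation of 1/f.
#' @slot ci95_one_in 95% CI for 1/N (named lower/upper on the 1-in-N scale,
#'   lower meaning fewer cells per initiating cell).
#' @slot deviance,df residual deviance and degrees of freedom.
#' @slot converged logical.
#' @slot boundary "none", "all_negative" or "all_positive"; boundary data
#'   yield a one-sided exact-binomial bound instead of a point estimate.
#' @slot observations the input table (group, dose, n_tested, n_positive).
#'
#' @export
setClass("LDAFit",
  representation(
    group = "character",
    log_f = "numeric",
    se_log_f = "numeric",
    frequency = "numeric",
    one_in = "numeric",
    ci95_one_in = "numeric",
    deviance = "numeric",
    df = "integer",
    converged = "logical",
    boundary = "character",
    observations = "data.frame"
  )
)

setValidity("LDAFit", function(object) {
  msg <- character()
  if (object@boundary == "none") {
    if (!is.finite(object@frequency) || object@frequency <= 0)
      msg <- c(msg, "frequency must be finite and positive")
  }
  if (!object@boundary %in% c("none", "all_negative", "all_positive"))
    msg <- c(msg, "invalid boundary flag")
  if (length(msg)) msg else TRUE
})

#' @describeIn LDAFit display summary in the "1 in N (lower, upper)" style
#' @param object an LDAFit
#' @export
setMethod("show", "LDAFit", function(object) {
  cat(sprintf("LDAFit '%s': ", object@group))
  if (object@boundary == "all_negative") {
    cat(sprintf("all wells negative; f < %.3g (95%% upper bound), i.e. rarer than 1 in %.1f\n",
                object@frequency, object@one_in))
  } else if (object@boundary == "all_positive") {
    cat(sprintf("all wells positive; f > %.3g (95%% lower bound), i.e. more frequent than 1 in %.1f\n",
                object@frequency, object@one_in))
  } else {
    cat(sprintf("1 in %.1f (95%% CI %.1f, %.1f)\n", object@one_in,
                object@ci95_one_in[["lower"]], object@ci95_one_in[["upper"]]))
  }
})

#' @describeIn LDAFit estimated initiating-cell frequency (per cell)
#' @param x an LDAFit
#' @export
ldaFrequency <- function(x) x@frequency

#' LDAComparison: between-group frequency comparison
#'
#' @slot groups the two group labels (a, b).
#' @slot frequency_ratio f_a / f_b point estimate.
#' @slot ratio_ci95 Wald 95% CI for the ratio.
#' @slot lrt_statistic,lrt_df,p likelihood-ratio test of a shared
#'   frequency against per-group frequencies.
#'
#' @export
setClass("LDAComparison",
  representation(
    groups = "character",
    frequency_ratio = "numeric",
    ratio_ci95 = "numeric",
    lrt_statistic = "numeric",
    lrt_df = "integer",
    p = "numeric"
  )
)

setValidity("LDAComparison", function(object) {
  msg <- character()
  if (object@frequency_ratio <= 0) msg <- c(msg, "ratio must be positive")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn LDAComparison display summary
#' @param object an LDAComparison
#' @export
setMethod("show", "LDAComparison", function(object) {
  cat(sprintf("LDAComparison %s vs %s: ratio = %.3f (95%% CI %.3f, %.3f), LRT chisq = %.3f (df %d), p = %.4g\n",
              object@groups[1], object@groups[2], object@frequency_ratio,
              object@ratio_ci95[["lower"]], object@ratio_ci95[["upper"]],
              object@lrt_statistic, object@lrt_df, object@p))
})
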