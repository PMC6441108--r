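suppressPackageStartupMessages(library(GenomicRanges))

# Independent oracles used by unit and acceptance tests. These deliberately
# share no code with the package: plain loops and per-base arithmetic.

# Brute-force weighted running-sum enrichment score: walk the ranked list
# left to right, track the extreme deviation (earliest position wins ties).
esOracle <- function(metric, ids, set, p = 1) {
  N <- length(metric)
  hit <- ids %in% set
  w <- abs(metric)^p
  W <- sum(w[hit])
  rs <- 0
  best <- 0
  best_abs <- -1
  for (i in seq_len(N)) {
    if (hit[i]) {
      rs <- rs + (if (W > 0) w[i] / W else 1 / sum(hit))
    } else {
      rs <- rs - 1 / (N - sum(hit))
    }
    if (abs(rs) > best_abs) {
      best_abs <- abs(rs)
      best <- rs
    }
  }
  best
}

# Per-base bitmap promoter-state oracle. Works on plain integer vectors
# (1-based closed coordinates, single chromosome). For each window: a mark
# is present if any of its peaks shares a base with the window; bivalent if
# (in_window) some base carries both marks inside the window, or (anywhere)
# some window-touching K4 peak and window-touching K27 peak share any base.
stateOracle <- function(win_start, win_end, k4_start, k4_end,
                        k27_start, k27_end, scope = "in_window") {
  touches <- function(s, e) s <= win_end & e >= win_start
  t4 <- which(touches(k4_start, k4_end))
  t27 <- which(touches(k27_start, k27_end))
  if (!length(t4) && !length(t27)) return("NONE")
  if (length(t4) && !length(t27)) return("K4_ONLY")
  if (!length(t4) && length(t27)) return("K27_ONLY")
  biv <- FALSE
  if (scope == "in_window") {
    L <- win_end - win_start + 1L
    b4 <- logical(L)
    b27 <- logical(L)
    for (i in t4) {
      a <- max(k4_start[i], win_start) - win_start + 1L
      b <- min(k4_end[i], win_end) - win_start + 1L
      b4[a:b] <- TRUE
    }
    for (i in t27) {
      a <- max(k27_start[i], win_start) - win_start + 1L
      b <- min(k27_end[i], win_end) - win_start + 1L
      b27[a:b] <- TRUE
    }
    biv <- any(b4 & b27)
  } else {
    for (i in t4) for (j in t27) {
      if (max(k4_start[i], k27_start[j]) <= min(k4_end[i], k27_end[j])) {
        biv <- TRUE
      }
    }
  }
  if (biv) "BIVALENT" else "MIXED"
}

# Textbook Pearson chi-square (no continuity correction) on a 2x2 table.
chisqOracle <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Random small genome for classification-oracle tests: windows and peaks on
# one chromosome as plain coordinate vectors.
randomGenomeCase <- function(seed, max_genes = 50, max_peaks = 300) {
  set.seed(seed)
  n_genes <- sample(1:max_genes, 1)
  n4 <- sample(1:max_peaks, 1)
  n27 <- sample(1:max_peaks, 1)
  L <- 50000L
  tss <- sample(1000:(L - 1000), n_genes)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  rpeaks <- function(n) {
    s <- sample.int(L - 500L, n)
    w <- sample(1:400, n, replace = TRUE)
    list(start = s, end = pmin(L, s + w - 1L))
  }
  list(L = L, tss = tss, strand = strand, k4 = rpeaks(n4), k27 = rpeaks(n27))
}
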