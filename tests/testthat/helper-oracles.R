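# Independent oracles and small fixture builders used across the suite.

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# hairpin sequence with a perfect stem; useful for forced fold optima
stem_loop <- function(stem, loop = "AAAAAAAAAA") {
  paste0(stem, loop, rc(stem))
}

# ---- Audic-Claverie oracle: direct tail summation in log space ------------
# P(k | x) = r^k * (x+k)! / (x! k! (1+r)^(x+k+1)),  r = n2/n1
ac_logpmf <- function(k, x, n1, n2) {
  r <- n2 / n1
  k * log(r) + lchoose(x + k, k) - (x + k + 1) * log1p(r)
}

ac_pvalue_oracle <- function(x, y, n1, n2) {
  lower <- sum(exp(ac_logpmf(0:y, x, n1, n2)))
  # upper tail summed directly until the geometric decay is exhausted
  hi <- max(y, ceiling((x + 1) * n2 / n1)) + 5000L
  upper <- sum(exp(ac_logpmf(y:hi, x, n1, n2)))
  min(1, 2 * min(lower, upper))
}

# ---- Allen score oracle: recursive enumeration of all alignments ----------
# Same scoring definition (mismatch 1, wobble 0.5, gap 2, doubled over
# miRNA positions 2-13; target insertions weighted by the next miRNA
# position), but explored by exhaustive recursion rather than positional
# construction.
allen_oracle <- function(mirna, site, maxGaps = 1, doubled = 2:13) {
  mi <- strsplit(toupper(mirna), "")[[1]]
  t <- rev(strsplit(toupper(site), "")[[1]])
  m <- length(mi); n <- length(t)
  w <- rep(1, m); w[intersect(seq_len(m), doubled)] <- 2
  pen <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) 0
    else if ((a == "G" && b == "T") || (a == "T" && b == "G")) 0.5
    else 1
  }
  best <- Inf
  recurse <- function(i, k, gaps, acc) {
    if (acc >= best) return()
    if (i > m && k > n) { best <<- acc; return() }
    if (i <= m && k <= n)
      recurse(i + 1, k + 1, gaps, acc + pen(mi[i], t[k]) * w[i])
    if (gaps < maxGaps) {
      if (i <= m && (m - i) >= (n - k))       # gap in site: mi[i] unpaired
        recurse(i + 1, k, gaps + 1, acc + 2 * w[i])
      if (k <= n && (n - k) >= (m - i))       # insertion: t[k] unpaired
        recurse(i, k + 1, gaps + 1, acc + 2 * w[min(i, m)])
    }
  }
  recurse(1, 1, 0, 0)
  best
}

# ---- hypergeometric enrichment oracle: exhaustive enumeration -------------
# probability that a uniformly drawn n-subset of 1..N contains at least k
# of the first K elements
hyper_oracle <- function(k, K, n, N) {
  combs <- utils::combn(N, n)
  mean(apply(combs, 2, function(s) sum(s <= K) >= k))
}

# small deterministic demo dataset shared by a few tests
small_sim <- function(seed = 7, reads = 4000, ...) {
  sg <- makeGenome(chromLen = 30000, nKnown = 6, nNovel = 3, nNcrna = 4,
                   seed = seed)
  libs <- simulateLibraries(sg, readSimConfig(readsPerLib = reads,
                                              seed = seed, ...))
  list(sg = sg, libs = libs)
}
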