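# Novel miRNA hairpin prediction: fold the genomic context of mapped tags
# and apply the ten Drosha/Dicer duplex constraints.

#' Fold an RNA (or DNA) sequence
#'
#' Predicts a pseudoknot-free secondary structure by interval dynamic
#' programming with stacking energies: a base pair contributes GC -3,
#' AU -2 or GU -1 kcal/mol when stacked on an adjacent pair (lone pairs
#' contribute nothing), and hairpin loops are at least \code{minLoop} nt.
#' Deterministic: the same sequence always returns the same structure, and
#' the energy decreases (more negative) monotonically as complementary
#' stems lengthen.
#'
#' @param seq a single sequence (ACGTU; case-insensitive).
#' @param minLoop minimal hairpin loop length (nt).
#' @return A list with \code{structure} (dot-bracket string, same length as
#'   the sequence, balanced brackets) and \code{energy} (kcal/mol, <= 0).
#' @examples
#' foldRNA(paste0(strrep("GC", 10), strrep("A", 10), strrep("GC", 10)))$energy
#' @export
foldRNA <- function(seq, minLoop = 3) {
  seq <- .clean_seq(seq)
  if (length(seq) != 1L) stop("foldRNA folds one sequence at a time")
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGTU characters")
  .nussinov_fold(seq, as.integer(minLoop))
}

# partner table from a dot-bracket string (0 = unpaired), 1-based
.pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  p <- integer(length(ch))
  st <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") st <- c(st, i)
    else if (ch[i] == ")") {
      j <- st[length(st)]
      st <- st[-length(st)]
      p[i] <- j; p[j] <- i
    }
  }
  p
}

# duplex statistics of a mature arm within a folded window.
# mStart/mLen are 1-based local coordinates of the mature arm.  Partners on
# the dominant side of the mature arm define the star arm (a folded flank
# may grab a few mature bases; those stray pairs are not part of the
# duplex).  When a read-supported star window is given, the duplex is
# restricted to partners inside it.
.duplex_stats <- function(db, mStart, mLen, starWindow = NULL) {
  p <- .pair_table(db)
  m2 <- mStart + mLen - 1L
  idx <- mStart:m2
  pr <- p[idx]
  outside <- pr != 0 & (pr < mStart | pr > m2)
  paired <- idx[outside]
  partners <- pr[outside]
  none <- list(pairs = 0L, bulge = Inf, space = Inf, starStart = NA_integer_,
               starEnd = NA_integer_, starLen = 0L)
  if (!length(paired)) return(none)
  if (!is.null(starWindow)) {
    keep <- partners >= starWindow[1] - 2L & partners <= starWindow[2] + 2L
  } else {
    up <- partners < mStart
    keep <- if (sum(up) >= sum(!up)) up else !up
  }
  paired <- paired[keep]; partners <- partners[keep]
  if (!length(paired)) return(none)
  starStart <- min(partners); starEnd <- max(partners)
  space <- if (starStart > m2) starStart - m2 - 1L else mStart - starEnd - 1L
  bulge <- 0L
  if (length(paired) > 1L) {
    gapsM <- diff(paired) - 1L
    gapsS <- abs(diff(partners)) - 1L
    bulge <- max(pmax(gapsM, gapsS))
  }
  list(pairs = length(paired), bulge = bulge, space = space,
       starStart = starStart, starEnd = starEnd,
       starLen = starEnd - starStart + 1L)
}

# canonical constraint order; rejection tallies and first-fail reasons use
# these names
MIREAP_CONSTRAINTS <- c("mature_min_len", "mature_max_len", "star_min_len",
                        "star_max_len", "cut_depth", "copy_number",
                        "free_energy", "duplex_space", "duplex_pairs",
                        "duplex_bulge")

#' Build a hairpin candidate record
#'
#' Convenience constructor for a candidate row carrying the statistics the
#' constraint filter consumes; used for fixtures and by
#' \code{\link{extractCandidates}}.
#'
#' @param id candidate identifier.
#' @param matureLen,starLen mature and star arm lengths (nt).
#' @param cutDepth read depth at the mature 5' cut site.
#' @param copyNumber genomic loci of the mature sequence.
#' @param energy precursor folding free energy (kcal/mol).
#' @param space spacing between mature and star arms (nt).
#' @param pairs paired bases in the miRNA/miRNA* duplex.
#' @param bulge largest bulge in the duplex (nt).
#' @param ... further columns (coordinates, sequences) stored verbatim.
#' @return A one-row data.frame.
#' @export
hairpinCandidate <- function(id = "cand", matureLen = 22, starLen = 22,
                             cutDepth = 10, copyNumber = 1, energy = -30,
                             space = 15, pairs = 20, bulge = 1, ...) {
  extra <- list(...)
  df <- data.frame(id = id, matureLen = matureLen, starLen = starLen,
                   cutDepth = cutDepth, copyNumber = copyNumber,
                   energy = energy, space = space, pairs = pairs,
                   bulge = bulge, stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

.constraint_matrix <- function(cands, p) {
  cbind(
    mature_min_len = cands$matureLen >= p@minMatureLen,
    mature_max_len = cands$matureLen <= p@maxMatureLen,
    star_min_len   = cands$starLen >= p@minStarLen,
    star_max_len   = cands$starLen <= p@maxStarLen,
    cut_depth      = cands$cutDepth >= p@minCutDepth,
    copy_number    = cands$copyNumber <= p@maxCopyNumber,
    free_energy    = cands$energy <= p@maxFreeEnergy,
    duplex_space   = cands$space <= p@maxDuplexSpace,
    duplex_pairs   = cands$pairs >= p@minDuplexPairs,
    duplex_bulge   = cands$bulge <= p@maxDuplexBulge
  )
}

#' Apply the ten hairpin-prediction constraints
#'
#' A candidate is accepted iff every constraint passes.  Rejected
#' candidates record the first failing constraint (in the canonical order
#' mature length bounds, star length bounds, cut depth, copy number, free
#' energy, duplex spacing, duplex pairs, duplex bulge); the tally counts
#' every failing constraint over all candidates.
#'
#' @param cands data.frame of candidates (from
#'   \code{\link{extractCandidates}} or \code{\link{hairpinCandidate}}).
#' @param params a \linkS4class{MireapParams}.
#' @return A list: \code{accepted} and \code{rejected} data.frames (the
#'   latter with a \code{firstFail} column), \code{tally} (named integer
#'   vector of failure counts per constraint), \code{params}.
#' @examples
#' res <- applyMireapFilter(hairpinCandidate(pairs = 13))
#' res$rejected$firstFail
#' @export
applyMireapFilter <- function(cands, params = mireapParams()) {
  if (is.null(cands) || nrow(cands) == 0)
    return(list(accepted = cands, rejected = cands,
                tally = stats::setNames(integer(length(MIREAP_CONSTRAINTS)),
                                        MIREAP_CONSTRAINTS),
                params = params))
  ok <- .constraint_matrix(cands, params)
  pass <- rowSums(!ok) == 0
  firstFail <- apply(ok, 1, function(r) {
    f <- which(!r)
    if (length(f)) MIREAP_CONSTRAINTS[f[1]] else NA_character_
  })
  rejected <- cands[!pass, , drop = FALSE]
  if (nrow(rejected)) rejected$firstFail <- firstFail[!pass]
  tally <- colSums(!ok)
  list(accepted = cands[pass, , drop = FALSE], rejected = rejected,
       tally = tally, params = params)
}

# map tag sequences to the genome by exact match, both strands
.map_tags <- function(seqs, counts, genome) {
  gen <- Biostrings::DNAStringSet(genome)
  hits <- list()
  for (strand in c("+", "-")) {
    qry <- if (strand == "+") seqs else .revcomp(seqs)
    for (w in unique(nchar(qry))) {
      grp <- which(nchar(qry) == w)
      pd <- Biostrings::PDict(qry[grp])
      for (ci in seq_along(gen)) {
        m <- Biostrings::matchPDict(pd, gen[[ci]])
        nh <- S4Vectors::elementNROWS(m)
        if (!sum(nh)) next
        ir <- unlist(m)
        hits[[length(hits) + 1L]] <- data.frame(
          tag = rep(grp, nh),
          chrom = names(genome)[ci],
          start = IRanges::start(ir), end = IRanges::end(ir),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

#' Extract hairpin candidates from genome-mapped tags
#'
#' Maps tags to the genome by exact match on both strands, clusters
#' overlapping hits per strand into loci, takes the most abundant tag of
#' each locus as the mature arm, folds the mature arm with \code{flank} nt
#' of genomic context on each side, and derives the miRNA/miRNA* duplex
#' statistics from the fold (the star arm is the paired-partner span of the
#' mature arm; a mapped tag overlapping the inferred star 5' end overrides
#' it).  Windows overlapping known miRNA loci are excluded.  Candidates are
#' returned pre-filter; apply \code{\link{applyMireapFilter}} to select.
#'
#' @param tags a \linkS4class{TagSet}.
#' @param genome named character vector, FASTA path or DNAStringSet.
#' @param flank genomic context on each side of the mature arm (nt).
#' @param knownLoci optional data.frame (chrom, start, end; 0-based
#'   half-open) of known miRNA loci to exclude.
#' @param minTagCount only tags with at least this many total reads are
#'   mapped.
#' @return A data.frame of candidates with coordinates (0-based half-open),
#'   strand, precursor sequence and structure, energy, mature/star
#'   sequences and the duplex statistics consumed by the filter.
#' @export
extractCandidates <- function(tags, genome, flank = 100, knownLoci = NULL,
                              minTagCount = 1) {
  stopifnot(is(tags, "TagSet"))
  genome <- .read_seqs(genome)
  seqs <- tagSequences(tags)
  tot <- tags@countHH + tags@countLL
  keep <- tot >= minTagCount
  seqs <- seqs[keep]; tot <- tot[keep]
  if (!length(seqs)) return(NULL)

  hits <- .map_tags(seqs, tot, genome)
  if (is.null(hits)) return(NULL)
  copyNum <- table(hits$tag)                      # loci per tag, both strands
  hits$count <- tot[hits$tag]
  # 5' genomic position of each hit (strand-aware)
  hits$p5 <- ifelse(hits$strand == "+", hits$start, hits$end)

  cands <- list()
  for (key in unique(paste(hits$chrom, hits$strand))) {
    sub <- hits[paste(hits$chrom, hits$strand) == key, , drop = FALSE]
    ir <- IRanges::IRanges(sub$start, sub$end)
    # merge tags within hairpin range so both duplex arms join one locus
    red <- IRanges::reduce(ir, min.gapwidth = 50L)
    cl <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    for (k in unique(cl)) {
      rows <- sub[cl == k, , drop = FALSE]
      ord <- order(-rows$count, seqs[rows$tag], rows$start)
      mat <- rows[ord[1], ]
      chromSeq <- genome[[mat$chrom]]
      if (!is.null(knownLoci)) {
        kl <- knownLoci[knownLoci$chrom == mat$chrom, , drop = FALSE]
        if (nrow(kl) && any(mat$start <= kl$end & mat$end >= kl$start + 1L))
          next
      }
      ws <- max(1L, mat$start - flank)
      we <- min(nchar(chromSeq), mat$end + flank)
      win <- substr(chromSeq, ws, we)
      if (mat$strand == "-") win <- .revcomp(win)
      mLocal <- if (mat$strand == "+") mat$start - ws + 1L else we - mat$end + 1L
      mLen <- mat$end - mat$start + 1L
      fold <- foldRNA(win)
      st <- .duplex_stats(fold$structure, mLocal, mLen)
      starSeq <- if (!is.na(st$starStart))
        substr(win, st$starStart, st$starEnd) else NA_character_
      starLen <- st$starLen
      obsSpan <- NULL
      # a read-supported star tag overrides the inferred one, and the
      # duplex statistics are recomputed against its span
      if (!is.na(st$starStart)) {
        starG <- if (mat$strand == "+")
          c(ws + st$starStart - 1L, ws + st$starEnd - 1L)
        else c(we - st$starEnd + 1L, we - st$starStart + 1L)
        ovS <- pmin(rows$end, starG[2]) - pmax(rows$start, starG[1]) + 1L
        ovM <- pmin(rows$end, mat$end) - pmax(rows$start, mat$start) + 1L
        obs <- rows[ovS >= 8L & ovM <= 0L & rows$tag != mat$tag, , drop = FALSE]
        if (nrow(obs)) {
          o <- obs[order(-obs$count)[1], ]
          starSeq <- seqs[o$tag]
          starLen <- nchar(starSeq)
          obsSpan <- if (mat$strand == "+")
            c(o$start - ws + 1L, o$end - ws + 1L)
          else c(we - o$end + 1L, we - o$start + 1L)
          st2 <- .duplex_stats(fold$structure, mLocal, mLen,
                               starWindow = obsSpan)
          if (st2$pairs > 0) st <- st2
        }
      }
      # the precursor is the mature..star span, refolded on its own so the
      # free-energy constraint scores the hairpin, not the whole window
      if (!is.na(st$starStart)) {
        span <- if (is.null(obsSpan)) c(st$starStart, st$starEnd) else obsSpan
        pLo <- min(mLocal, span[1])
        pHi <- max(mLocal + mLen - 1L, span[2])
        precursor <- substr(win, pLo, pHi)
        pf <- foldRNA(precursor)
        mInPre <- mLocal - pLo + 1L
        swInPre <- if (is.null(obsSpan)) NULL else obsSpan - pLo + 1L
        stp <- .duplex_stats(pf$structure, mInPre, mLen, starWindow = swInPre)
        if (stp$pairs > 0) st <- stp
        energy <- pf$energy
        structure <- pf$structure
        gs <- if (mat$strand == "+") ws + pLo - 1L else we - pHi + 1L
        ge <- if (mat$strand == "+") ws + pHi - 1L else we - pLo + 1L
        mStartOut <- mInPre
      } else {
        precursor <- win; energy <- fold$energy; structure <- fold$structure
        gs <- ws; ge <- we; mStartOut <- mLocal
      }
      depth <- sum(rows$count[rows$p5 == mat$p5])
      cands[[length(cands) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%d", mat$chrom, mat$strand, gs),
        chrom = mat$chrom, start = gs - 1L, end = ge,   # 0-based half-open
        strand = mat$strand,
        precursor = precursor, structure = structure, energy = energy,
        matureSeq = seqs[mat$tag], matureStart = mStartOut, matureLen = mLen,
        starSeq = starSeq, starLen = starLen,
        cutDepth = depth, copyNumber = as.integer(copyNum[as.character(mat$tag)]),
        space = st$space, pairs = st$pairs, bulge = st$bulge,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cands)) return(NULL)
  do.call(rbind, cands)
}

#' Predict novel miRNAs from tags and a genome
#'
#' Convenience wrapper: extract candidates, exclude known loci, apply the
#' constraint filter.
#'
#' @inheritParams extractCandidates
#' @param params a \linkS4class{MireapParams}.
#' @return As \code{\link{applyMireapFilter}}, plus \code{candidates} (the
#'   pre-filter set).
#' @export
predictNovel <- function(tags, genome, flank = 100, knownLoci = NULL,
                         params = mireapParams(),
                         minTagCount = params@minCutDepth) {
  cands <- extractCandidates(tags, genome, flank = flank,
                             knownLoci = knownLoci,
                             minTagCount = minTagCount)
  res <- applyMireapFilter(cands, params)
  res$candidates <- cands
  res
}
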