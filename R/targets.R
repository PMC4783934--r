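# miRNA-target complementarity scoring (position-weighted Allen penalty,
# Schwab positional filter), 3' UTR scanning, and hypergeometric term
# enrichment of predicted target sets.

# penalty of miRNA base (row) against the target base pairing it (column):
# Watson-Crick 0, G:U wobble 0.5, otherwise mismatch 1
.PEN <- local({
  b <- c("A", "C", "G", "T")
  m <- matrix(1, 4, 4, dimnames = list(b, b))
  m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- 0
  m["G", "T"] <- m["T", "G"] <- 0.5
  m
})
.GAP_PEN <- 2

.base_idx <- function(ch) match(ch, BASES)

.pos_weight <- function(m, doubled = 2:13) {
  w <- rep(1, m)
  w[intersect(seq_len(m), doubled)] <- 2
  w
}

.aln_symbol <- function(pen) ifelse(pen == 0, "|", ifelse(pen == 0.5, "o", "x"))

#' Position-weighted complementarity penalty of a miRNA against a site
#'
#' Aligns the miRNA (5' to 3', position 1 = 5' end) against the reverse
#' complement of the target site and returns the minimal penalty:
#' mismatches cost 1, G:U wobbles 0.5, gaps 2, all doubled over miRNA
#' positions 2-13.  At most one gap is allowed (\code{maxGaps = 1}), so the
#' site must be within one nt of the miRNA length.  Ties are broken by
#' fewest gaps, then leftmost gap.  A perfect complement scores 0.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param site target site on the mRNA sense strand, 5' to 3'.
#' @param maxGaps maximal gaps in the alignment (0 or 1).
#' @param doubled miRNA positions whose penalties are doubled.
#' @return A list: \code{score}, \code{alignment} (one symbol per alignment
#'   column: \code{|} pair, \code{o} wobble, \code{x} mismatch, \code{-}
#'   gap), \code{status} (per miRNA position: \code{|}, \code{o}, \code{x}
#'   or \code{-}), \code{gaps}.
#' @examples
#' allenScore("TGGAATGTAAAGAAGTATGTAT",
#'            as.character(Biostrings::reverseComplement(
#'              Biostrings::DNAString("TGGAATGTAAAGAAGTATGTAT"))))$score  # 0
#' @export
allenScore <- function(mirna, site, maxGaps = 1, doubled = 2:13) {
  mirna <- .clean_seq(mirna); site <- .clean_seq(site)
  if (grepl("[^ACGT]", mirna) || grepl("[^ACGT]", site))
    stop("non-nucleotide characters in miRNA or site")
  mi <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(site, "")[[1]])    # t[k] pairs miRNA position k (ungapped)
  m <- length(mi); n <- length(t)
  if (abs(n - m) > maxGaps)
    stop("site length must be within the miRNA length +/- ", maxGaps)
  w <- .pos_weight(m, doubled)
  P <- function(i, k) .PEN[mi[i], t[k]] * w[i]

  best <- NULL
  consider <- function(score, alignment, status, gaps) {
    if (is.null(best) || score < best$score - 1e-12 ||
        (abs(score - best$score) < 1e-12 && gaps < best$gaps))
      best <<- list(score = score, alignment = alignment, status = status,
                    gaps = gaps)
  }
  if (n == m) {
    pen <- vapply(seq_len(m), function(i) P(i, i), numeric(1))
    sym <- .aln_symbol(.PEN[cbind(mi, t)])
    consider(sum(pen), paste(sym, collapse = ""), sym, 0L)
  } else if (n == m - 1) {
    for (g in seq_len(m)) {        # miRNA position g faces a gap in the site
      pen <- .GAP_PEN * w[g]
      status <- character(m)
      for (i in seq_len(m)) {
        if (i == g) { status[i] <- "-"; next }
        k <- if (i < g) i else i - 1L
        pen <- pen + P(i, k)
        status[i] <- .aln_symbol(.PEN[mi[i], t[k]])
      }
      consider(pen, paste(status, collapse = ""), status, 1L)
    }
  } else {                         # n == m + 1: one unpaired site base
    for (g in 0:m) {               # inserted after miRNA position g
      pen <- .GAP_PEN * w[min(g + 1L, m)]
      status <- character(m)
      for (i in seq_len(m)) {
        k <- if (i <= g) i else i + 1L
        pen <- pen + P(i, k)
        status[i] <- .aln_symbol(.PEN[mi[i], t[k]])
      }
      aln <- append(status, "-", after = g)
      consider(pen, paste(aln, collapse = ""), status, 1L)
    }
  }
  best
}

#' Schwab positional filter for a target alignment
#'
#' Passes iff the per-position alignment has (i) no mismatch at miRNA
#' positions 10-11, (ii) at most one mismatch within positions 2-12, and
#' (iii) no run of more than two consecutive mismatches.  Gaps count as
#' mismatches; G:U wobbles do not.
#'
#' @param status per-miRNA-position status vector (or the list returned by
#'   \code{\link{allenScore}}).
#' @return TRUE or FALSE.
#' @export
schwabFilter <- function(status) {
  if (is.list(status)) status <- status$status
  mm <- status %in% c("x", "-")
  m <- length(mm)
  if (any(mm[intersect(10:11, seq_len(m))])) return(FALSE)
  if (sum(mm[intersect(2:12, seq_len(m))]) > 1) return(FALSE)
  r <- rle(mm)
  !any(r$lengths[r$values] > 2)
}

# vectorized scan of one miRNA over one UTR at a given window width;
# returns data.frame(start, width, score) per window (best gap placement)
.scan_one <- function(mic, wt, uc, width) {
  m <- length(mic); L <- length(uc)
  S <- L - width + 1L
  if (S < 1L) return(NULL)
  penAt <- function(i, off) .PEN[mic[i], uc[off + seq_len(S) - 1L]] * wt[i]
  if (width == m) {
    sc <- numeric(S)
    for (i in seq_len(m)) sc <- sc + penAt(i, m - i + 1L)
    return(data.frame(start = seq_len(S), width = width, score = sc))
  }
  if (width == m - 1L) {
    # A[i,]: i aligned in the left (unshifted) part; B[i,]: right part
    A <- matrix(0, m, S); B <- matrix(0, m, S)
    for (i in seq_len(m - 1L)) A[i, ] <- penAt(i, m - i)      # u[s+m-1-i]
    for (i in 2:m)            B[i, ] <- penAt(i, m - i + 1L)  # u[s+m-i]
    cumA <- apply(A, 2, cumsum); cumB <- apply(B, 2, cumsum)
    totB <- cumB[m, ]
    sc <- rep(Inf, S)
    for (g in seq_len(m)) {
      left <- if (g > 1) cumA[g - 1L, ] else 0
      right <- totB - cumB[g, ]
      sc <- pmin(sc, left + .GAP_PEN * wt[g] + right)
    }
    return(data.frame(start = seq_len(S), width = width, score = sc))
  }
  if (width == m + 1L) {
    C <- matrix(0, m, S); D <- matrix(0, m, S)
    for (i in seq_len(m)) C[i, ] <- penAt(i, m - i + 2L)      # u[s+m+1-i]
    for (i in seq_len(m)) D[i, ] <- penAt(i, m - i + 1L)      # u[s+m-i]
    cumC <- apply(C, 2, cumsum); cumD <- apply(D, 2, cumsum)
    totD <- cumD[m, ]
    sc <- rep(Inf, S)
    for (g in 0:m) {
      left <- if (g > 0) cumC[g, ] else 0
      right <- totD - (if (g > 0) cumD[g, ] else 0)
      sc <- pmin(sc, left + .GAP_PEN * wt[min(g + 1L, m)] + right)
    }
    return(data.frame(start = seq_len(S), width = width, score = sc))
  }
  NULL
}

#' Scan 3' UTRs for miRNA target sites
#'
#' Every window of each UTR (widths within one nt of the miRNA length) is
#' scored with the position-weighted complementarity penalty; windows with
#' penalty at most \code{maxScore} are reported as sites, with the Schwab
#' positional filter flag and, per (miRNA, transcript), the best site
#' flagged.  Empty UTRs are skipped with a warning.
#'
#' @param mirnas named miRNA sequences (character vector, FASTA path or
#'   XStringSet).
#' @param utrs named UTR sequences.
#' @param maxScore maximal penalty for a reported site.
#' @param maxGaps maximal gaps per alignment (0 or 1).
#' @return A data.frame: mirna, transcript, position (0-based position of
#'   the target base pairing miRNA position 1), start (0-based window
#'   start), width, score, schwab, best, alignment.
#' @export
scanUTRs <- function(mirnas, utrs, maxScore = 4.0, maxGaps = 1) {
  mirnas <- .read_seqs(mirnas); utrs <- .read_seqs(utrs)
  if (!length(mirnas) || !length(utrs)) stop("empty miRNA or UTR input")
  if (is.null(names(mirnas))) names(mirnas) <- paste0("mir", seq_along(mirnas))
  if (is.null(names(utrs))) names(utrs) <- paste0("utr", seq_along(utrs))
  out <- list()
  for (uname in names(utrs)) {
    u <- utrs[[uname]]
    if (!nchar(u)) { warning("empty UTR skipped: ", uname); next }
    if (grepl("[^ACGT]", u)) stop("non-nucleotide characters in UTR ", uname)
    uc <- .base_idx(strsplit(u, "")[[1]])
    for (mname in names(mirnas)) {
      mi <- strsplit(mirnas[[mname]], "")[[1]]
      mic <- .base_idx(mi)
      wt <- .pos_weight(length(mi))
      widths <- length(mi) + (-maxGaps:maxGaps)
      for (wd in widths[widths >= 1]) {
        sc <- .scan_one(mic, wt, uc, wd)
        if (is.null(sc)) next
        hit <- which(sc$score <= maxScore)
        if (!length(hit)) next
        for (h in hit) {
          s <- sc$start[h]
          site <- substr(u, s, s + wd - 1L)
          al <- allenScore(mirnas[[mname]], site, maxGaps = maxGaps)
          out[[length(out) + 1L]] <- data.frame(
            mirna = mname, transcript = uname,
            position = s + wd - 2L, start = s - 1L, width = wd,
            score = al$score, schwab = schwabFilter(al),
            alignment = al$alignment, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(mirna = character(0), transcript = character(0),
                      position = integer(0), start = integer(0),
                      width = integer(0), score = numeric(0),
                      schwab = logical(0), best = logical(0),
                      alignment = character(0)))
  sites <- do.call(rbind, out)
  key <- paste(sites$mirna, sites$transcript)
  sites$best <- FALSE
  for (k in unique(key)) {
    idx <- which(key == k)
    sites$best[idx[order(sites$score[idx], sites$position[idx])[1]]] <- TRUE
  }
  rownames(sites) <- NULL
  sites
}

#' Hypergeometric term enrichment of a target gene set
#'
#' One-sided (upper tail) hypergeometric p-value per term: the probability
#' of drawing at least the observed number of term genes when sampling the
#' target set from the background without replacement, plus BH q-values
#' across terms.  The default background is every gene carrying at least
#' one annotation term.
#'
#' @param targetGenes character vector of target gene ids.
#' @param annotation data.frame mapping genes to terms, with columns
#'   \code{gene}, \code{term} and optionally \code{termName},
#'   \code{category}.
#' @param background optional character vector of background gene ids;
#'   \code{targetGenes} must be a subset.
#' @return A data.frame sorted by p: term, termName, category, k (targets
#'   in term), K (term size), n (target set size), N (background size),
#'   pvalue, qvalue.
#' @export
enrichTerms <- function(targetGenes, annotation, background = NULL) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  if (is.null(background)) background <- unique(annotation$gene)
  orphan <- setdiff(targetGenes, background)
  if (length(orphan))
    stop("target gene(s) absent from background: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  targetGenes <- unique(targetGenes)
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  N <- length(unique(background))
  n <- length(targetGenes)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    g <- unique(ann$gene[ann$term == tm])
    K <- length(g)
    k <- length(intersect(g, targetGenes))
    data.frame(term = tm,
               termName = if ("termName" %in% names(ann))
                 ann$termName[match(tm, ann$term)] else tm,
               category = if ("category" %in% names(ann))
                 ann$category[match(tm, ann$term)] else NA_character_,
               k = k, K = K, n = n, N = N,
               pvalue = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$qvalue <- bhFdr(res$pvalue)
  res <- res[order(res$pvalue, res$term), ]
  rownames(res) <- NULL
  res
}
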