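# Tag processing: adapter trimming, read collapsing, length filtering,
# hierarchical annotation and known-miRNA matching.

# trim the 3' adapter by exact prefix match: the earliest suffix of the
# read (of at least minOverlap nt) equal to a prefix of the adapter is
# removed; the overlap floor keeps chance 1-2 nt suffix matches intact
.trim_adapter <- function(reads, adapter, minOverlap = 3L) {
  if (!nchar(adapter) || !length(reads)) return(reads)
  n <- nchar(reads)
  cut <- n + 1L                      # first adapter base position, per read
  maxP <- max(n) - minOverlap + 1L
  for (p in seq_len(max(maxP, 0L))) {
    cand <- which(cut > n & p <= n - minOverlap + 1L)   # not yet cut
    if (!length(cand)) break
    sufLen <- n[cand] - p + 1L
    hit <- substr(reads[cand], p, n[cand]) ==
      substr(rep(adapter, length(cand)), 1L, sufLen)
    cut[cand[hit]] <- p
  }
  substr(reads, 1L, cut - 1L)
}

#' Collapse reads from two libraries into unique tags
#'
#' Removes the 3' adapter (earliest exact match of an adapter prefix of at
#' least 3 nt at the read end), uppercases and converts U to T, and merges
#' identical
#' sequences with summed per-library counts.  Output is sorted by total
#' count descending with lexicographic sequence order as tie-break, so the
#' collapsed table is reproducible.
#'
#' @param hh,ll reads of the first (HH) and second (LL) library: FASTA or
#'   FASTQ paths, character vectors or XStringSets.
#' @param adapter 3' adapter sequence; empty string disables trimming.
#' @return A \linkS4class{TagSet}.
#' @examples
#' collapseReads(c("ACGTACGTACGTACGTACGTAC", "ACGTACGTACGTACGTACGTAC"),
#'               "ACGTACGTACGTACGTACGTAC")
#' @export
collapseReads <- function(hh, ll = character(0), adapter = "") {
  hh <- .read_seqs(hh)
  ll <- .read_seqs(ll)
  adapter <- .clean_seq(adapter)
  if (any(grepl("[^ACGTN]", c(hh, ll))))
    stop("malformed record: non-nucleotide characters in reads ",
         paste(utils::head(which(grepl("[^ACGTN]", c(hh, ll)))), collapse = ","))
  hh <- .trim_adapter(hh, adapter)
  ll <- .trim_adapter(ll, adapter)
  hh <- hh[nchar(hh) > 0]
  ll <- ll[nchar(ll) > 0]
  all <- unique(c(hh, ll))
  if (!length(all)) return(TagSet())
  cHH <- table(factor(hh, levels = all))
  cLL <- table(factor(ll, levels = all))
  ord <- order(-(as.integer(cHH) + as.integer(cLL)), all)
  TagSet(all[ord], as.integer(cHH)[ord], as.integer(cLL)[ord])
}

#' Filter tags by length
#'
#' Retains tags with \code{min <= length <= max} (the standard 18-30 nt
#' small-RNA window).  The read totals removed per library are recorded in
#' the result's metadata under \code{removed}.
#'
#' @param tags a \linkS4class{TagSet}.
#' @param min,max inclusive length bounds (nt).
#' @return A filtered \linkS4class{TagSet}.
#' @export
filterLength <- function(tags, min = 18, max = 30) {
  stopifnot(is(tags, "TagSet"), min <= max)
  len <- nchar(tagSequences(tags))
  keep <- len >= min & len <= max
  out <- tags[keep]
  out@metadata$removed <- list(
    tags = sum(!keep),
    readsHH = sum(tags@countHH[!keep]),
    readsLL = sum(tags@countLL[!keep]))
  out
}

DEFAULT_PRIORITY <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                      "repeat", "exon", "intron")

# which tags occur as a full-length subsequence of any reference sequence
.match_category <- function(seqs, refs) {
  if (!length(refs)) return(rep(FALSE, length(seqs)))
  subj <- Biostrings::DNAStringSet(.clean_seq(refs))
  hit <- rep(FALSE, length(seqs))
  for (w in unique(nchar(seqs))) {
    grp <- which(nchar(seqs) == w)
    if (w > max(nchar(refs))) next
    pd <- Biostrings::PDict(seqs[grp])
    cnt <- rowSums(Biostrings::vcountPDict(pd, subj))
    hit[grp] <- cnt > 0
  }
  hit
}

#' Annotate tags hierarchically against reference sets
#'
#' Each tag is assigned exactly one category: the first category in
#' \code{priority} order for which the tag is an exact full-length
#' subsequence of a reference sequence, or \code{"unannotated"}.  The
#' summary therefore partitions tags and reads, and category read counts
#' per library sum to the library totals.
#'
#' @param tags a \linkS4class{TagSet}.
#' @param references named list of reference sequence sets (character
#'   vectors, FASTA paths or XStringSets), e.g. \code{list(miRNA = ...,
#'   rRNA = ...)}.  For the miRNA category supply mature plus hairpin
#'   sequences.
#' @param priority character vector of categories, highest first.  Every
#'   entry must be a known category (a name of \code{references} or one of
#'   the standard small-RNA categories).
#' @return A list: \code{category} (per-tag assignment), \code{summary}
#'   (data.frame per category: tags, readsHH, readsLL).
#' @export
annotateTags <- function(tags, references, priority = DEFAULT_PRIORITY) {
  stopifnot(is(tags, "TagSet"))
  known <- union(DEFAULT_PRIORITY, names(references))
  bad <- setdiff(priority, known)
  if (length(bad))
    stop("unknown category in priority list: ", paste(bad, collapse = ", "))
  seqs <- tagSequences(tags)
  category <- rep("unannotated", length(seqs))
  for (cat in priority) {
    refs <- references[[cat]]
    if (is.null(refs)) next
    open <- category == "unannotated"
    if (!any(open)) break
    refSeqs <- .read_seqs(refs)
    hit <- .match_category(seqs[open], refSeqs)
    category[open][hit] <- cat
  }
  cats <- c(priority, "unannotated")
  summary <- data.frame(
    category = cats,
    tags = vapply(cats, function(cc) sum(category == cc), integer(1)),
    readsHH = vapply(cats, function(cc) sum(tags@countHH[category == cc]), integer(1)),
    readsLL = vapply(cats, function(cc) sum(tags@countLL[category == cc]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(category = category, summary = summary)
}

# arm class from a miRBase-style mature name suffix
.arm_class <- function(name) {
  ifelse(endsWith(name, "-5p"), "miRNA-5p",
    ifelse(endsWith(name, "-3p"), "miRNA-3p",
      ifelse(endsWith(name, "*"), "miRNA*", "miRNA")))
}

#' Match tags to known mature miRNAs
#'
#' A tag is a hit for a mature reference when it aligns exactly within the
#' mature sequence extended by \code{maxOffset} nt into its hairpin on each
#' side.  The arm class (miRNA, miRNA*, miRNA-5p, miRNA-3p) is taken from
#' the reference name suffix.  Per-miRNA expression sums the counts of its
#' hit tags; a tag hitting several miRNAs counts towards each.
#'
#' @param tags a \linkS4class{TagSet}.
#' @param mature named mature reference sequences (FASTA path, character
#'   vector or XStringSet) with miRBase-style names.
#' @param hairpin hairpin (precursor) reference sequences; names are
#'   matched to mature names case-insensitively after stripping arm
#'   suffixes (miR -> mir).  A mature sequence absent from any hairpin is
#'   matched on the mature sequence alone, with a warning.
#' @param maxOffset maximal extension into the hairpin (nt).
#' @return A list: \code{hits} (data.frame tag, mirna, armClass, offset of
#'   the tag start relative to the mature start), \code{expression}
#'   (data.frame mirna, armClass, countHH, countLL), \code{summary}
#'   (distinct mature miRNAs and precursors hit, per library and total).
#' @export
matchKnown <- function(tags, mature, hairpin = NULL, maxOffset = 2) {
  stopifnot(is(tags, "TagSet"))
  mat <- .read_seqs(mature)
  hp <- if (is.null(hairpin)) character(0) else .read_seqs(hairpin)
  if (is.null(names(mat))) stop("mature references must be named")
  seqs <- tagSequences(tags)

  # build the search window per mature: mature +/- maxOffset within hairpin
  win <- character(length(mat))
  hpOf <- character(length(mat))
  hpKey <- tolower(names(hp))
  for (i in seq_along(mat)) {
    key <- tolower(gsub("(-5p|-3p|\\*)$", "", names(mat)[i]))
    j <- which(hpKey == key)
    if (!length(j)) j <- which(vapply(hp, function(h) grepl(mat[i], h, fixed = TRUE),
                                      logical(1)))
    if (length(j)) {
      h <- hp[j[1]]
      pos <- regexpr(mat[i], h, fixed = TRUE)
      if (pos > 0) {
        s <- max(1L, pos - maxOffset)
        e <- min(nchar(h), pos + nchar(mat[i]) - 1L + maxOffset)
        win[i] <- substr(h, s, e)
        hpOf[i] <- names(hp)[j[1]]
        next
      }
    }
    warning("mature sequence ", names(mat)[i],
            " not found in any hairpin; matching on mature only")
    win[i] <- mat[i]
    hpOf[i] <- NA_character_
  }

  hits <- list()
  for (i in seq_along(mat)) {
    pos <- regexpr(mat[i], win[i], fixed = TRUE)  # mature start inside window
    cand <- which(nchar(seqs) <= nchar(win[i]))
    if (!length(cand)) next
    at <- vapply(seqs[cand], function(s) regexpr(s, win[i], fixed = TRUE),
                 integer(1), USE.NAMES = FALSE)
    hit <- at > 0
    if (!any(hit)) next
    hits[[length(hits) + 1L]] <- data.frame(
      tag = seqs[cand[hit]],
      tagIdx = cand[hit],
      mirna = names(mat)[i],
      armClass = .arm_class(names(mat)[i]),
      offset = at[hit] - as.integer(pos),
      precursor = hpOf[i],
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    hits <- data.frame(tag = character(0), tagIdx = integer(0),
                       mirna = character(0), armClass = character(0),
                       offset = integer(0), precursor = character(0))
  } else hits <- do.call(rbind, hits)

  expr <- NULL
  if (nrow(hits)) {
    agg <- stats::aggregate(cbind(countHH = tags@countHH[hits$tagIdx],
                                  countLL = tags@countLL[hits$tagIdx]),
                            by = list(mirna = hits$mirna), FUN = sum)
    agg$armClass <- .arm_class(agg$mirna)
    expr <- agg[order(-(agg$countHH + agg$countLL), agg$mirna),
                c("mirna", "armClass", "countHH", "countLL")]
    rownames(expr) <- NULL
  } else {
    expr <- data.frame(mirna = character(0), armClass = character(0),
                       countHH = integer(0), countLL = integer(0))
  }
  summary <- data.frame(
    library = c("HH", "LL", "either"),
    miRNAs = c(length(unique(expr$mirna[expr$countHH > 0])),
               length(unique(expr$mirna[expr$countLL > 0])),
               length(unique(expr$mirna))),
    precursors = c(
      length(unique(stats::na.omit(hits$precursor[hits$tagIdx %in% which(tags@countHH > 0)]))),
      length(unique(stats::na.omit(hits$precursor[hits$tagIdx %in% which(tags@countLL > 0)]))),
      length(unique(stats::na.omit(hits$precursor)))),
    stringsAsFactors = FALSE)
  list(hits = hits[, c("tag", "mirna", "armClass", "offset", "precursor")],
       expression = expr, summary = summary)
}

#' Write a collapsed tag set as FASTA
#'
#' Headers follow the \code{>tag<i>_x<countHH>_y<countLL>} convention.
#'
#' @param tags a \linkS4class{TagSet}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeTagFasta <- function(tags, path) {
  seqs <- tagSequences(tags)
  names(seqs) <- sprintf("tag%d_x%d_y%d", seq_along(seqs),
                         tags@countHH, tags@countLL)
  .write_fasta(seqs, path)
}
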