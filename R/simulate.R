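# Synthetic-data generator: genomes with planted miRNA hairpins and ncRNA
# loci, plus two-condition small-RNA read sets with known differential
# expression.  Every downstream stage of the pipeline is exercised on this
# output, so the generator verifies at construction time that planted novel
# hairpins satisfy all ten prediction constraints.

#' Build a hairpin precursor around a mature sequence
#'
#' The star arm is the reverse complement of the mature sequence with at
#' most \code{maxMut} substitutions and at most one engineered G:U wobble,
#' separated from the mature arm by a random loop.  The precursor is folded
#' and checked against the full constraint set before being accepted.
#' @keywords internal
.make_hairpin <- function(params = mireapParams(), mlen = NULL,
                          matureLens = 20:24,
                          matureProbs = c(.1, .2, .4, .2, .1),
                          loopLens = 10:30, maxMut = 2, tries = 60) {
  if (is.null(mlen)) mlen <- sample(matureLens, 1, prob = matureProbs)
  for (t in seq_len(tries)) {
    mature <- .rand_dna(1, mlen)
    star <- strsplit(.revcomp(mature), "")[[1]]
    nmut <- sample(0:maxMut, 1)
    if (nmut > 0) {
      pos <- sample(4:(mlen - 3), nmut)
      for (p in pos) star[p] <- sample(setdiff(BASES, star[p]), 1)
    }
    if (stats::runif(1) < 0.5) {            # at most one G:U wobble
      cpos <- which(star == "C")
      cpos <- cpos[cpos > 3 & cpos < mlen - 2]
      if (length(cpos)) star[sample(rep(cpos, 2), 1)] <- "T"
    }
    star <- paste(star, collapse = "")
    loop <- .rand_dna(1, sample(loopLens, 1))
    arm <- sample(c("5p", "3p"), 1)
    precursor <- if (arm == "5p") paste0(mature, loop, star)
                 else paste0(star, loop, mature)
    m1 <- if (arm == "5p") 1L else nchar(star) + nchar(loop) + 1L
    fold <- foldRNA(precursor)
    st <- .duplex_stats(fold$structure, m1, mlen)
    ok <- mlen >= params@minMatureLen && mlen <= params@maxMatureLen &&
      st$starLen >= params@minStarLen && st$starLen <= params@maxStarLen &&
      st$pairs >= params@minDuplexPairs && st$bulge <= params@maxDuplexBulge &&
      st$space <= params@maxDuplexSpace && fold$energy <= params@maxFreeEnergy
    if (ok)
      return(list(mature = mature, star = star, precursor = precursor,
                  arm = arm, matureStart = m1, energy = fold$energy,
                  stats = st))
  }
  stop("failed to construct a constraint-satisfying hairpin after ",
       tries, " attempts")
}

.place_loci <- function(widths, classes, nChrom, chromLen, minGap = 150,
                        tries = 500) {
  occ <- vector("list", nChrom)
  chrom <- integer(length(widths)); start <- integer(length(widths))
  for (i in seq_along(widths)) {
    placed <- FALSE
    for (t in seq_len(tries)) {
      ch <- sample.int(nChrom, 1)
      if (chromLen - widths[i] < 1) break
      s <- sample.int(chromLen - widths[i] + 1L, 1)
      e <- s + widths[i] - 1L
      clash <- FALSE
      if (length(occ[[ch]]))
        for (iv in occ[[ch]])
          if (s <= iv[2] + minGap && e >= iv[1] - minGap) { clash <- TRUE; break }
      if (!clash) {
        occ[[ch]] <- c(occ[[ch]], list(c(s, e)))
        chrom[i] <- ch; start[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement failure for locus of class '", classes[i],
           "': chromosome space exhausted")
  }
  list(chrom = chrom, start = start)
}

#' Generate a synthetic genome with planted small-RNA loci
#'
#' Builds random chromosomes and plants three kinds of loci without overlap:
#' known miRNA hairpins (which also go into the miRBase-style mature and
#' hairpin reference sets), novel miRNA hairpins (absent from the
#' references, to be rediscovered by the prediction stage), and ncRNA loci
#' (rRNA/tRNA/snRNA/snoRNA contamination sources).  Novel hairpins are
#' verified at construction time to satisfy every prediction constraint.
#' Each planted miRNA receives a mean expression per condition; a designated
#' subset is differentially expressed with known log2 fold change (LL over
#' HH), and the truth table flags a miRNA as DE iff |log2FC| > 1.
#'
#' @param chromLen chromosome length (nt).
#' @param nChrom number of chromosomes.
#' @param nKnown,nNovel,nNcrna numbers of known-miRNA, novel-miRNA and ncRNA
#'   loci to plant.
#' @param seed integer random seed; the same seed reproduces the genome
#'   byte-for-byte.
#' @param deProp proportion of planted miRNAs that are differentially
#'   expressed.
#' @param deLog2FC absolute true log2 fold change (LL over HH) given to the
#'   DE subset (signs alternate).
#' @param baseMeanLog,baseMeanSd log-normal parameters for per-miRNA
#'   expression weights.
#' @param params \linkS4class{MireapParams} used for the construction-time
#'   hairpin check.
#' @return An object of class \code{SyntheticGenome}: a list with
#'   \code{genome} (named character vector of chromosome sequences),
#'   \code{loci} (data.frame: id, chrom, start, end, strand, class; 0-based
#'   half-open coordinates), \code{truth} (data.frame per planted miRNA:
#'   name, class, arm, matureSeq, starSeq, precursor, meanHH, meanLL,
#'   log2FC, de), and \code{refs} (list of named character vectors:
#'   \code{mature}, \code{hairpin}, \code{ncrna}).
#' @examples
#' sg <- makeGenome(chromLen = 30000, nKnown = 4, nNovel = 2, nNcrna = 3, seed = 7)
#' table(sg$loci$class)
#' @export
makeGenome <- function(chromLen = 100000, nChrom = 1, nKnown = 20,
                       nNovel = 5, nNcrna = 10, seed = 1, deProp = 0.4,
                       deLog2FC = 2, baseMeanLog = log(400), baseMeanSd = 1,
                       params = mireapParams()) {
  set.seed(seed)
  ncClasses <- rep_len(c("rRNA", "tRNA", "snRNA", "snoRNA"), max(nNcrna, 1L))
  nMir <- nKnown + nNovel
  if (nMir < 1) stop("at least one miRNA locus is required")

  # expression weights come first so mature lengths can be stratified: the
  # loci carrying the majority of the read mass get the modal 22-nt mature,
  # which makes the configured length mode hold at the read level
  w <- stats::rlnorm(nMir, baseMeanLog, baseMeanSd)
  mlens <- integer(nMir)
  ord <- order(-w)
  kTop <- max(1L, which(cumsum(w[ord]) / sum(w) >= 0.55)[1])
  mlens[ord[seq_len(kTop)]] <- 22L
  rest <- ord[-seq_len(kTop)]
  if (length(rest))
    mlens[rest] <- sample(c(20L, 21L, 22L, 23L, 24L), length(rest),
                          replace = TRUE)

  hairpins <- lapply(mlens, function(l) .make_hairpin(params, mlen = l))
  ncSeqs <- .rand_dna(nNcrna, sample(70:120, max(nNcrna, 1L), replace = TRUE)[seq_len(nNcrna)])

  classes <- c(rep("known_mirna", nKnown), rep("novel_mirna", nNovel),
               ncClasses[seq_len(nNcrna)])
  seqs <- c(vapply(hairpins, `[[`, character(1), "precursor"), ncSeqs)
  strands <- sample(c("+", "-"), length(seqs), replace = TRUE)

  pl <- .place_loci(nchar(seqs), classes, nChrom, chromLen)

  genome <- .rand_dna(nChrom, chromLen)
  names(genome) <- paste0("chr", seq_len(nChrom))
  for (i in seq_along(seqs)) {
    ins <- if (strands[i] == "+") seqs[i] else .revcomp(seqs[i])
    substr(genome[pl$chrom[i]], pl$start[i], pl$start[i] + nchar(seqs[i]) - 1L) <- ins
  }

  idseq <- function(prefix, n)
    if (n > 0) paste0(prefix, seq_len(n)) else character(0)
  ncIds <- if (nNcrna > 0)
    paste0(tolower(ncClasses[seq_len(nNcrna)]), "-", seq_len(nNcrna))
  else character(0)
  ids <- c(idseq("bta-mir-sim", nKnown), idseq("novel-mir-", nNovel), ncIds)
  loci <- data.frame(
    id = ids, chrom = names(genome)[pl$chrom],
    start = pl$start - 1L,                       # 0-based half-open
    end = pl$start - 1L + nchar(seqs),
    strand = strands, class = classes, stringsAsFactors = FALSE)

  # expression truth
  nDE <- ceiling(deProp * nMir)
  de_idx <- sample.int(nMir, nDE)
  lfc <- numeric(nMir)
  lfc[de_idx] <- rep_len(c(deLog2FC, -deLog2FC), nDE)
  meanHH <- w
  meanLL <- w * 2^lfc

  # mature naming styles for known loci (plain / -5p / -3p, as in miRBase)
  style <- sample(c("", "-5p", "-3p"), nKnown, replace = TRUE,
                  prob = c(.6, .2, .2))
  matureNames <- c(if (nKnown > 0) paste0("bta-miR-sim", seq_len(nKnown), style)
                   else character(0),
                   idseq("novel-mir-", nNovel))
  truth <- data.frame(
    name = matureNames,
    class = classes[seq_len(nMir)],
    arm = vapply(hairpins, `[[`, character(1), "arm"),
    matureSeq = vapply(hairpins, `[[`, character(1), "mature"),
    starSeq = vapply(hairpins, `[[`, character(1), "star"),
    precursor = vapply(hairpins, `[[`, character(1), "precursor"),
    meanHH = meanHH, meanLL = meanLL, log2FC = lfc, de = abs(lfc) > 1,
    stringsAsFactors = FALSE)

  mature <- truth$matureSeq[seq_len(nKnown)]
  names(mature) <- matureNames[seq_len(nKnown)]
  # some known miRNAs also contribute their star strand to the reference
  starIn <- which(stats::runif(nKnown) < 0.2)
  if (length(starIn)) {
    stars <- truth$starSeq[starIn]
    names(stars) <- paste0("bta-miR-sim", starIn, "*")
    mature <- c(mature, stars)
  }
  hairpinRef <- truth$precursor[seq_len(nKnown)]
  names(hairpinRef) <- idseq("bta-mir-sim", nKnown)
  ncr <- ncSeqs
  if (nNcrna > 0) names(ncr) <- ids[nMir + seq_len(nNcrna)]

  structure(list(genome = genome, loci = loci, truth = truth,
                 refs = list(mature = mature, hairpin = hairpinRef,
                             ncrna = ncr),
                 seed = seed),
            class = "SyntheticGenome")
}

#' @export
print.SyntheticGenome <- function(x, ...) {
  cat("SyntheticGenome:", length(x$genome), "chromosome(s),",
      sum(nchar(x$genome)), "nt\n")
  print(table(x$loci$class))
  invisible(x)
}

#' Read-simulation configuration
#'
#' @param readsPerLib target reads per library (scalar or length-2 vector
#'   \code{c(HH, LL)}).
#' @param dispersion negative-binomial size parameter for per-miRNA counts;
#'   \code{Inf} gives Poisson counts.
#' @param errorRate per-base sequencing error probability.
#' @param adapter 3' adapter sequence appended to inserts shorter than the
#'   read length.
#' @param readLen instrument read length (nt).
#' @param lengthMode modal fragment length (nt) for ncRNA/background reads;
#'   mature miRNA lengths are fixed by the genome.
#' @param ncrnaFrac,bgFrac expected fractions of the library drawn from
#'   ncRNA loci and from random background positions.
#' @param starFrac star-strand expression as a fraction of the mature
#'   strand's.
#' @param seed integer random seed; fixed seed gives byte-identical output.
#' @return A list of class \code{ReadSimConfig}.
#' @export
readSimConfig <- function(readsPerLib = 50000, dispersion = 100,
                          errorRate = 0.001,
                          adapter = "TGGAATTCTCGGGTGCCAAGG",
                          readLen = 36, lengthMode = 22, ncrnaFrac = 0.15,
                          bgFrac = 0.05, starFrac = 0.1, seed = 1) {
  if (length(readsPerLib) == 1L) readsPerLib <- c(readsPerLib, readsPerLib)
  stopifnot(all(readsPerLib > 0), errorRate >= 0, errorRate < 1)
  structure(list(readsPerLib = c(HH = readsPerLib[1], LL = readsPerLib[2]),
                 dispersion = dispersion, errorRate = errorRate,
                 adapter = .clean_seq(adapter), readLen = readLen,
                 lengthMode = lengthMode, ncrnaFrac = ncrnaFrac,
                 bgFrac = bgFrac, starFrac = starFrac, seed = seed),
            class = "ReadSimConfig")
}

.draw_counts <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = size)
}

.frag_lens <- function(n, mode, lo = 18, hi = 30) {
  lens <- lo:hi
  sample(lens, n, replace = TRUE, prob = 1 / (1 + abs(lens - mode)))
}

.mutate_reads <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  nerr <- stats::rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0)) {
    ch <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(ch), nerr[i])
    for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate two small-RNA libraries from a synthetic genome
#'
#' Per-miRNA read counts are drawn negative-binomially around the truth
#' table's condition means, scaled so each library hits its target size;
#' star strands are expressed at a configurable fraction of the mature
#' strand.  ncRNA loci shed random fragments and a small background of
#' random genomic fragments is added.  Reads shorter than the read length
#' carry the 3' adapter.  The drawn (true) per-miRNA counts are returned
#' for recovery tests.
#'
#' @param sg a \code{SyntheticGenome} from \code{\link{makeGenome}}.
#' @param cfg a \code{\link{readSimConfig}}.
#' @return A list of class \code{SimulatedLibraries}: \code{reads} (list of
#'   two character vectors, HH and LL), \code{counts} (data.frame of drawn
#'   counts per planted miRNA arm: name, source, countHH, countLL), and
#'   \code{cfg}.
#' @examples
#' sg <- makeGenome(chromLen = 30000, nKnown = 4, nNovel = 2, nNcrna = 3, seed = 7)
#' libs <- simulateLibraries(sg, readSimConfig(readsPerLib = 2000, seed = 7))
#' head(libs$counts)
#' @export
simulateLibraries <- function(sg, cfg = readSimConfig()) {
  stopifnot(inherits(sg, "SyntheticGenome"), inherits(cfg, "ReadSimConfig"))
  set.seed(cfg$seed)
  truth <- sg$truth
  if (nrow(truth) == 0 || sum(truth$meanHH + truth$meanLL) <= 0)
    stop("zero total expression in truth table")

  mirFrac <- 1 - cfg$ncrnaFrac - cfg$bgFrac
  srcSeq <- c(truth$matureSeq, truth$starSeq)
  srcName <- c(truth$name, paste0(truth$name, "*"))
  srcType <- rep(c("mature", "star"), each = nrow(truth))
  wHH <- c(truth$meanHH, truth$meanHH * cfg$starFrac)
  wLL <- c(truth$meanLL, truth$meanLL * cfg$starFrac)

  ncLoci <- sg$loci[!sg$loci$class %in% c("known_mirna", "novel_mirna"), , drop = FALSE]
  ncSeq <- sg$refs$ncrna

  out <- list()
  countTab <- NULL
  for (lib in c("HH", "LL")) {
    size <- cfg$readsPerLib[[lib]]
    w <- if (lib == "HH") wHH else wLL
    mu <- size * mirFrac * w / sum(w)
    counts <- .draw_counts(length(mu), mu, cfg$dispersion)
    reads <- rep(srcSeq, counts)

    if (length(ncSeq)) {
      ncMu <- size * cfg$ncrnaFrac / length(ncSeq)
      ncCounts <- .draw_counts(length(ncSeq), ncMu, cfg$dispersion)
      for (i in seq_along(ncSeq)) {
        if (ncCounts[i] == 0) next
        L <- nchar(ncSeq[i])
        fl <- pmin(.frag_lens(ncCounts[i], cfg$lengthMode), L)
        st <- vapply(L - fl + 1L, function(m) sample.int(m, 1), integer(1))
        reads <- c(reads, substring(ncSeq[i], st, st + fl - 1L))
      }
    }
    nBg <- .draw_counts(1, size * cfg$bgFrac, cfg$dispersion)
    if (nBg > 0) {
      ch <- sample(seq_along(sg$genome), nBg, replace = TRUE)
      fl <- .frag_lens(nBg, cfg$lengthMode)
      st <- vapply(nchar(sg$genome)[ch] - fl, function(m) sample.int(m, 1), integer(1))
      bg <- substring(sg$genome[ch], st, st + fl - 1L)
      flip <- stats::runif(nBg) < 0.5
      bg[flip] <- .revcomp(bg[flip])
      reads <- c(reads, bg)
    }

    reads <- .mutate_reads(reads, cfg$errorRate)
    reads <- reads[sample.int(length(reads))]
    # append 3' adapter, truncate to instrument read length
    reads <- substr(paste0(reads, cfg$adapter), 1L, cfg$readLen)
    names(reads) <- sprintf("%s_read%06d", lib, seq_along(reads))
    out[[lib]] <- reads
    countTab <- cbind(countTab, counts)
  }
  counts <- data.frame(name = srcName, source = srcType,
                       countHH = countTab[, 1], countLL = countTab[, 2],
                       stringsAsFactors = FALSE)
  structure(list(reads = out, counts = counts, cfg = cfg),
            class = "SimulatedLibraries")
}

#' Write a synthetic genome bundle to disk
#'
#' Writes \code{genome.fa}, miRBase-style \code{mature.fa} and
#' \code{hairpin.fa} (known loci only), \code{ncrna.fa}, and the
#' \code{truth.tsv} and \code{loci.tsv} tables.
#'
#' @param sg a \code{SyntheticGenome}.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
writeGenomeBundle <- function(sg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_fasta(sg$genome, file.path(dir, "genome.fa"))
  .write_fasta(sg$refs$mature, file.path(dir, "mature.fa"))
  .write_fasta(sg$refs$hairpin, file.path(dir, "hairpin.fa"))
  if (length(sg$refs$ncrna))
    .write_fasta(sg$refs$ncrna, file.path(dir, "ncrna.fa"))
  .write_tsv(sg$truth, file.path(dir, "truth.tsv"))
  .write_tsv(sg$loci, file.path(dir, "loci.tsv"))
  invisible(dir)
}

#' Write simulated libraries as FASTQ (Phred+33)
#'
#' @param libs a \code{SimulatedLibraries} object.
#' @param dir output directory.
#' @return Paths of the two FASTQ files, invisibly.
#' @export
writeLibraryFastq <- function(libs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "reads_HH.fastq"), file.path(dir, "reads_LL.fastq"))
  .write_fastq(libs$reads$HH, paths[1])
  .write_fastq(libs$reads$LL, paths[2])
  .write_tsv(libs$counts, file.path(dir, "drawn_counts.tsv"))
  invisible(paths)
}

#' Simulate UTRs, annotation and target-expression tables
#'
#' Builds the inputs the target-prediction and screening stages consume,
#' with known ground truth: random 3' UTRs with perfect-complement target
#' sites planted for a subset of the DE miRNAs; a gene-to-term annotation
#' map in which planted target genes of the "concordant" and "discordant"
#' groups carry lipid-pathway terms; and a gene-level expression table in
#' which concordant targets change significantly in the direction opposite
#' their miRNA, discordant targets do not (same direction or
#' non-significant), and all other genes are null.
#'
#' @param truth truth table from \code{\link{makeGenome}}.
#' @param seed integer random seed.
#' @param nGenes number of genes (each with one UTR).
#' @param utrLen UTR length (nt).
#' @param nConcordant,nDiscordant,nUnannotated DE miRNAs planted with a
#'   concordant lipid-pathway target, a non-concordant lipid-pathway
#'   target, or an unannotated target only.
#' @return A list of class \code{TargetBundle}: \code{utrs} (named
#'   character), \code{annotation} (gene, term, termName, category),
#'   \code{targetExpr} (gene, log2FC, pvalue), \code{screenTruth} (mirna,
#'   group, gene, expectRetained), \code{plantedSites} (mirna, gene,
#'   start).
#' @export
simulateTargetBundle <- function(truth, seed = 1, nGenes = 24, utrLen = 400,
                                 nConcordant = 3, nDiscordant = 2,
                                 nUnannotated = 1) {
  set.seed(seed)
  deMir <- truth[truth$de, , drop = FALSE]
  need <- nConcordant + nDiscordant + nUnannotated
  if (nrow(deMir) < need)
    stop("truth table has ", nrow(deMir), " DE miRNAs; ", need, " needed")
  deMir <- deMir[seq_len(need), ]
  grp <- rep(c("concordant", "discordant", "unannotated"),
             c(nConcordant, nDiscordant, nUnannotated))

  genes <- sprintf("gene%02d", seq_len(nGenes))
  utrs <- .rand_dna(nGenes, utrLen)
  names(utrs) <- genes

  lipid <- lipidPathways()
  ann <- data.frame(gene = genes,
                    term = paste0("GO:", 9000 + seq_len(nGenes)),
                    termName = paste0("generic process ", seq_len(nGenes)),
                    category = "GO-BP", stringsAsFactors = FALSE)
  expr <- data.frame(gene = genes, log2FC = stats::rnorm(nGenes, 0, 0.2),
                     pvalue = stats::runif(nGenes, 0.2, 1),
                     stringsAsFactors = FALSE)

  planted <- NULL; screenTruth <- NULL
  gi <- 0L
  for (i in seq_len(nrow(deMir))) {
    gi <- gi + 1L
    g <- genes[gi]
    site <- .revcomp(deMir$matureSeq[i])
    pos <- sample.int(utrLen - nchar(site) - 10L, 1) + 5L
    substr(utrs[g], pos, pos + nchar(site) - 1L) <- site
    planted <- rbind(planted, data.frame(
      mirna = deMir$name[i], gene = g, start = pos - 1L,
      stringsAsFactors = FALSE))
    if (grp[i] != "unannotated") {
      ann <- rbind(ann, data.frame(
        gene = g, term = lipid[(i - 1L) %% length(lipid) + 1L],
        termName = lipid[(i - 1L) %% length(lipid) + 1L],
        category = "pathway", stringsAsFactors = FALSE))
    }
    j <- match(g, expr$gene)
    if (grp[i] == "concordant") {
      expr$log2FC[j] <- -sign(deMir$log2FC[i]) * 1.5
      expr$pvalue[j] <- 0.001
    } else if (grp[i] == "discordant") {
      # same-signed significant change: inverse-concordance must fail
      expr$log2FC[j] <- sign(deMir$log2FC[i]) * 1.5
      expr$pvalue[j] <- 0.001
    }
    screenTruth <- rbind(screenTruth, data.frame(
      mirna = deMir$name[i], group = grp[i], gene = g,
      expectRetained = grp[i] == "concordant", stringsAsFactors = FALSE))
  }
  structure(list(utrs = utrs, annotation = ann, targetExpr = expr,
                 screenTruth = screenTruth, plantedSites = planted),
            class = "TargetBundle")
}

#' Write a target bundle to disk
#'
#' @param bundle a \code{TargetBundle}.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeTargetBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_fasta(bundle$utrs, file.path(dir, "utrs.fa"))
  .write_tsv(bundle$annotation, file.path(dir, "annotation.tsv"))
  .write_tsv(bundle$targetExpr, file.path(dir, "target_expression.tsv"))
  .write_tsv(bundle$screenTruth, file.path(dir, "screen_truth.tsv"))
  invisible(dir)
}
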