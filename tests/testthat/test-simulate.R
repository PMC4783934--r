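# synthetic genome and library generator

test_that("locus counts, truth size and non-overlap follow the arguments", {
  sg <- makeGenome(chromLen = 100000, nChrom = 1, nKnown = 20, nNovel = 5,
                   nNcrna = 10, seed = 7)
  expect_equal(nrow(sg$loci), 35)
  expect_equal(nrow(sg$truth), 25)
  expect_true(all(sg$loci$start >= 0 & sg$loci$end <= 100000))
  expect_true(all(sg$loci$end > sg$loci$start))
  s <- sg$loci[order(sg$loci$start), ]
  expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  # novel matures are absent from the known reference
  novel <- sg$truth$matureSeq[sg$truth$class == "novel_mirna"]
  expect_false(any(novel %in% sg$refs$mature))
})

test_that("impossible placements raise an error naming the locus class", {
  expect_error(makeGenome(chromLen = 1000, nKnown = 200, nNovel = 0,
                          nNcrna = 0, seed = 1),
               "placement failure.*known_mirna")
})

test_that("a fixed seed reproduces the genome bundle and FASTQ byte-for-byte", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  for (d in c(d1, d2)) {
    sg <- makeGenome(chromLen = 20000, nKnown = 3, nNovel = 2, nNcrna = 2,
                     seed = 42)
    libs <- simulateLibraries(sg, readSimConfig(readsPerLib = 1500, seed = 42))
    writeGenomeBundle(sg, d)
    writeLibraryFastq(libs, d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted precursors satisfy every duplex constraint by construction", {
  sg <- makeGenome(chromLen = 50000, nKnown = 5, nNovel = 5, nNcrna = 0,
                   seed = 9)
  p <- mireapParams()
  for (i in seq_len(nrow(sg$truth))) {
    tr <- sg$truth[i, ]
    f <- foldRNA(tr$precursor)
    m1 <- regexpr(tr$matureSeq, tr$precursor, fixed = TRUE)
    st <- milkmiR:::.duplex_stats(f$structure, as.integer(m1),
                                  nchar(tr$matureSeq))
    expect_gte(st$pairs, p@minDuplexPairs)
    expect_lte(st$bulge, p@maxDuplexBulge)
    expect_lte(st$space, p@maxDuplexSpace)
    expect_lte(f$energy, p@maxFreeEnergy)
    expect_true(st$starLen >= p@minStarLen && st$starLen <= p@maxStarLen)
  }
  # DE flag definition
  expect_equal(sg$truth$de, abs(sg$truth$log2FC) > 1)
})

test_that("the simulated length distribution has its mode at 22 nt", {
  for (s in c(5, 6, 7)) {
    sim <- small_sim(seed = s, reads = 6000)
    tags <- collapseReads(sim$libs$reads$HH, sim$libs$reads$LL,
                          adapter = sim$libs$cfg$adapter)
    lens <- rep(nchar(tagSequences(tags)), tags@countHH + tags@countLL)
    lens <- lens[lens >= 18 & lens <= 30]
    expect_gte(length(lens), 10000)
    tab <- table(lens)
    expect_equal(as.integer(names(tab)[which.max(tab)]), 22)
  }
})

test_that("drawn counts match the configured means across seeds", {
  sg <- makeGenome(chromLen = 30000, nKnown = 6, nNovel = 3, nNcrna = 4,
                   seed = 7)
  cfg0 <- readSimConfig(readsPerLib = 4000)
  mirShare <- 1 - cfg0$ncrnaFrac - cfg0$bgFrac
  wHH <- c(sg$truth$meanHH, sg$truth$meanHH * cfg0$starFrac)
  wLL <- c(sg$truth$meanLL, sg$truth$meanLL * cfg0$starFrac)
  muHH <- 4000 * mirShare * sg$truth$meanHH / sum(wHH)
  muLL <- 4000 * mirShare * sg$truth$meanLL / sum(wLL)
  pooled <- matrix(0, nrow(sg$truth), 2)
  nSeeds <- 40
  for (s in seq_len(nSeeds)) {
    libs <- simulateLibraries(sg, readSimConfig(readsPerLib = 4000, seed = s))
    cnt <- libs$counts[libs$counts$source == "mature", ]
    idx <- match(sg$truth$name, cnt$name)
    pooled <- pooled + cbind(cnt$countHH[idx], cnt$countLL[idx])
  }
  big <- muHH >= 20 & muLL >= 20
  expect_gt(sum(big), 0)
  expect_true(all(abs(pooled[big, 1] / (nSeeds * muHH[big]) - 1) < 0.15))
  expect_true(all(abs(pooled[big, 2] / (nSeeds * muLL[big]) - 1) < 0.15))
  # a designated DE miRNA at log2FC +/-2 shows the ~4x count ratio
  de <- which(sg$truth$de & muHH >= 20 & muLL >= 20)
  expect_gt(length(de), 0)
  expect_true(all(abs(log2(pooled[de, 2] / pooled[de, 1]) -
                      log2(muLL[de] / muHH[de])) < 0.3))
})

test_that("equal means give an empirical log2 fold change near zero at large n", {
  sg <- makeGenome(chromLen = 30000, nKnown = 6, nNovel = 2, nNcrna = 2,
                   seed = 13, deProp = 0)
  libs <- simulateLibraries(sg, readSimConfig(readsPerLib = 20000, seed = 13,
                                              dispersion = Inf))
  cnt <- libs$counts[libs$counts$source == "mature", ]
  big <- cnt[cnt$countHH + cnt$countLL > 400, ]
  expect_gt(nrow(big), 0)
  expect_true(all(abs(log2(big$countLL / big$countHH)) < 0.5))
})

test_that("zero total expression is rejected", {
  sg <- makeGenome(chromLen = 20000, nKnown = 2, nNovel = 1, nNcrna = 1,
                   seed = 3)
  sg$truth$meanHH <- 0; sg$truth$meanLL <- 0
  expect_error(simulateLibraries(sg, readSimConfig(readsPerLib = 100)),
               "zero total expression")
})

test_that("the target bundle plants sites, pathways and expression as labelled", {
  sg <- makeGenome(chromLen = 50000, nKnown = 10, nNovel = 3, nNcrna = 2,
                   seed = 21)
  tb <- simulateTargetBundle(sg$truth, seed = 21)
  expect_s3_class(tb$annotation, "data.frame")
  # every planted site is a perfect reverse complement of its miRNA
  for (i in seq_len(nrow(tb$plantedSites))) {
    ps <- tb$plantedSites[i, ]
    mir <- sg$truth$matureSeq[sg$truth$name == ps$mirna]
    win <- substr(tb$utrs[[ps$gene]], ps$start + 1,
                  ps$start + nchar(mir))
    expect_identical(win, rc(mir))
  }
  # concordant targets carry a lipid pathway term and opposite-signed change
  conc <- tb$screenTruth[tb$screenTruth$group == "concordant", ]
  for (i in seq_len(nrow(conc))) {
    g <- conc$gene[i]
    expect_true(any(tb$annotation$gene == g &
                    tb$annotation$term %in% lipidPathways()))
    mirFC <- sg$truth$log2FC[sg$truth$name == conc$mirna[i]]
    j <- match(g, tb$targetExpr$gene)
    expect_lt(sign(tb$targetExpr$log2FC[j]) * sign(mirFC), 0)
    expect_lt(tb$targetExpr$pvalue[j], 0.05)
  }
})
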