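# read collapsing, length filtering, annotation, known-miRNA matching

test_that("identical sequences merge with summed per-library counts", {
  s <- "ACGTACGTACGTACGTACGTAC"
  tags <- collapseReads(rep(s, 3), rep(s, 2))
  expect_equal(length(tags), 1L)
  expect_equal(unname(tagCounts(tags)[1, ]), c(3L, 2L))
})

test_that("empty input collapses to an empty tag set", {
  tags <- collapseReads(character(0), character(0))
  expect_equal(length(tags), 0L)
})

test_that("adapter suffixes are trimmed by earliest exact prefix match", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACGTAC"
  reads <- substr(paste0(insert, adapter), 1, 36)
  tags <- collapseReads(reads, character(0), adapter = adapter)
  expect_equal(tagSequences(tags), insert)
  # a full-length read with no adapter is kept whole
  long <- rand_dna(36)
  tags2 <- collapseReads(long, character(0), adapter = adapter)
  expect_equal(tagSequences(tags2), long)
})

test_that("collapsing simulated error-free reads conserves read counts", {
  sg <- makeGenome(chromLen = 50000, nKnown = 10, nNovel = 0, nNcrna = 0,
                   seed = 17)
  cfg <- readSimConfig(readsPerLib = 500, seed = 17, errorRate = 0,
                       ncrnaFrac = 0, bgFrac = 0, starFrac = 0)
  libs <- simulateLibraries(sg, cfg)
  tags <- collapseReads(libs$reads$HH, libs$reads$LL, adapter = cfg$adapter)
  expect_lte(length(tags), 10L)
  expect_equal(sum(tagCounts(tags)),
               length(libs$reads$HH) + length(libs$reads$LL))
})

test_that("collapsing is idempotent and deterministically ordered", {
  set.seed(2)
  reads <- sample(c("ACGTACGTACGTACGTACGTAC", "TTGTACGTACGTACGTACGTAC",
                    "GGGTACGTACGTACGTACGTAC"), 60, replace = TRUE)
  t1 <- collapseReads(reads, rev(reads))
  # expanding the collapsed table back to reads and re-collapsing is a no-op
  t2 <- collapseReads(rep(tagSequences(t1), t1@countHH),
                      rep(tagSequences(t1), t1@countLL))
  expect_identical(tagSequences(t2), tagSequences(t1))
  expect_identical(tagCounts(t2), tagCounts(t1))
  # ordering: total count descending, sequence ascending on ties
  tot <- rowSums(tagCounts(t1))
  expect_true(all(diff(tot) <= 0))
  ties <- split(tagSequences(t1), tot)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
})

test_that("length filtering keeps the 18-30 window and reports removals", {
  tags <- TagSet(c(rand_dna(17), rand_dna(22), rand_dna(30), rand_dna(31)),
                 c(5L, 2L, 1L, 4L), c(1L, 1L, 1L, 1L))
  out <- filterLength(tags)
  expect_equal(nchar(tagSequences(out)), c(22L, 30L))
  rem <- out@metadata$removed
  expect_equal(rem$tags, 2L)
  expect_equal(rem$readsHH + rem$readsLL, 5L + 1L + 4L + 1L)
  # conservation: retained + removed = input
  expect_equal(sum(tagCounts(out)) + rem$readsHH + rem$readsLL,
               sum(tagCounts(tags)))
  only22 <- filterLength(tags, 22, 22)
  expect_equal(nchar(tagSequences(only22)), 22L)
})

test_that("annotation follows the priority order and partitions all tags", {
  trna <- rand_dna(80)
  frag <- substr(trna, 10, 31)
  exon <- paste0(rand_dna(20), frag, rand_dna(20))   # engineered double match
  tags <- TagSet(c(frag, rand_dna(22)), c(3L, 2L), c(1L, 0L))
  res <- annotateTags(tags, list(tRNA = trna, exon = exon),
                      priority = c("tRNA", "exon"))
  expect_equal(res$category, c("tRNA", "unannotated"))
  res2 <- annotateTags(tags, list(tRNA = trna, exon = exon),
                       priority = c("exon", "tRNA"))
  expect_equal(res2$category[1], "exon")
  # partition + conservation invariants
  expect_equal(sum(res$summary$tags), length(tags))
  expect_equal(sum(res$summary$readsHH), sum(tags@countHH))
  expect_equal(sum(res$summary$readsLL), sum(tags@countLL))
  expect_error(annotateTags(tags, list(tRNA = trna), priority = c("bogus")),
               "unknown category")
})

test_that("error-free simulated miRNA tags all annotate as miRNA", {
  sg <- makeGenome(chromLen = 50000, nKnown = 8, nNovel = 0, nNcrna = 0,
                   seed = 19)
  cfg <- readSimConfig(readsPerLib = 400, seed = 19, errorRate = 0,
                       ncrnaFrac = 0, bgFrac = 0)
  libs <- simulateLibraries(sg, cfg)
  tags <- collapseReads(libs$reads$HH, libs$reads$LL, adapter = cfg$adapter)
  res <- annotateTags(tags, list(miRNA = c(sg$refs$mature, sg$refs$hairpin)))
  expect_true(all(res$category == "miRNA"))
})

test_that("known-miRNA matching respects the hairpin extension window", {
  hairpin <- stem_loop(rand_dna(30), "CAACTTGAAC")
  mature <- substr(hairpin, 5, 26)
  mat <- c("bta-miR-x" = mature)
  hp <- c("bta-mir-x" = hairpin)
  # exact mature tag: hit at offset 0
  tags <- TagSet(mature, 4L, 2L)
  res <- matchKnown(tags, mat, hp)
  expect_equal(res$hits$offset, 0L)
  expect_equal(res$hits$armClass, "miRNA")
  expect_equal(res$expression$countHH, 4L)
  # 2 nt shift into the hairpin is allowed, 3 nt is not (maxOffset = 2)
  shift2 <- substr(hairpin, 7, 28)
  shift3 <- substr(hairpin, 8, 29)
  expect_equal(nrow(matchKnown(TagSet(shift2, 1L, 0L), mat, hp)$hits), 1L)
  expect_equal(nrow(matchKnown(TagSet(shift3, 1L, 0L), mat, hp)$hits), 0L)
})

test_that("arm classes come from the reference name suffix", {
  expect_equal(milkmiR:::.arm_class(c("bta-miR-1", "bta-miR-2-5p",
                                      "bta-miR-3-3p", "bta-miR-4*")),
               c("miRNA", "miRNA-5p", "miRNA-3p", "miRNA*"))
})

test_that("a mature absent from all hairpins matches with a warning", {
  mat <- c("bta-miR-y" = rand_dna(22))
  hp <- c("bta-mir-z" = rand_dna(70))
  tags <- TagSet(mat[[1]], 2L, 0L)
  expect_warning(res <- matchKnown(tags, mat, hp), "not found in any hairpin")
  expect_equal(nrow(res$hits), 1L)
})

test_that("per-miRNA counts equal the simulator's drawn counts", {
  sg <- makeGenome(chromLen = 60000, nKnown = 8, nNovel = 0, nNcrna = 0,
                   seed = 23)
  cfg <- readSimConfig(readsPerLib = 600, seed = 23, errorRate = 0,
                       ncrnaFrac = 0, bgFrac = 0, starFrac = 0)
  libs <- simulateLibraries(sg, cfg)
  tags <- collapseReads(libs$reads$HH, libs$reads$LL, adapter = cfg$adapter)
  res <- matchKnown(tags, sg$refs$mature, sg$refs$hairpin)
  drawn <- libs$counts[libs$counts$source == "mature", ]
  expr <- res$expression
  # restrict to plain mature references (no star entries in refs)
  idx <- match(expr$mirna, drawn$name)
  expect_false(any(is.na(idx)))
  expect_equal(expr$countHH, drawn$countHH[idx])
  expect_equal(expr$countLL, drawn$countLL[idx])
})
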