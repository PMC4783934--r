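# Allen complementarity penalty, Schwab filter, UTR scanning, enrichment

test_that("perfect complements score zero and wobbles/mismatches are weighted", {
  set.seed(6)
  mir <- rand_dna(22)
  expect_equal(allenScore(mir, rc(mir))$score, 0)

  # single G:U wobble opposite miRNA position 5: 0.5 doubled = 1.0
  mir2 <- paste0("ACAC", "G", paste(rep("A", 17), collapse = ""))
  sitechars <- strsplit(rc(mir2), "")[[1]]
  sitechars[22 - 5 + 1] <- "T"      # site base pairing miRNA position 5: C -> T
  res <- allenScore(mir2, paste(sitechars, collapse = ""))
  expect_equal(res$score, 1.0)
  expect_equal(res$status[5], "o")

  # single mismatch opposite miRNA position 20 (outside 2-13): weight 1
  mir3 <- strsplit(mir, "")[[1]]
  site3 <- strsplit(rc(mir), "")[[1]]
  pos20 <- 22 - 20 + 1              # site base pairing miRNA position 20
  repl <- setdiff(c("A", "C", "G", "T"),
                  c(site3[pos20], "G", "T"))[1]   # avoid creating a wobble
  site3[pos20] <- repl
  res3 <- allenScore(mir, paste(site3, collapse = ""))
  expect_equal(res3$score, 1.0)
  expect_equal(res3$status[20], "x")
})

test_that("gap penalties are 2, doubled over positions 2-13", {
  set.seed(8)
  mir <- rand_dna(16)
  site <- rc(mir)
  # drop the site base pairing miRNA position 16 (outside 2-13): gap costs 2
  res <- allenScore(mir, substr(site, 2, 16))
  expect_equal(res$gaps, 1L)
  expect_equal(res$score, 2)
  # drop the base pairing position 8 (inside 2-13): the cheapest single gap
  # still sits in the doubled region, costing 4
  res2 <- allenScore(mir, paste0(substr(site, 1, 8), substr(site, 10, 16)))
  expect_equal(res2$score, 4)
})

test_that("the scorer equals the exhaustive enumeration oracle", {
  set.seed(10)
  for (i in 1:120) {
    m <- sample(6:12, 1)
    mir <- rand_dna(m)
    n <- m + sample(-1:1, 1)
    site <- if (runif(1) < 0.5) rand_dna(n) else {
      s <- strsplit(rc(mir), "")[[1]]
      idx <- sample(m, sample(0:2, 1))
      for (j in idx) s[j] <- sample(c("A", "C", "G", "T"), 1)
      paste(utils::head(s, n), collapse = "")
    }
    if (nchar(site) < m - 1) next
    expect_equal(allenScore(mir, site)$score, allen_oracle(mir, site),
                 info = paste(mir, site))
  }
})

test_that("the positional filter enforces the three mismatch rules", {
  ok <- rep("|", 21)
  expect_true(schwabFilter(ok))
  m10 <- ok; m10[10] <- "x"
  expect_false(schwabFilter(m10))
  m11 <- ok; m11[11] <- "x"
  expect_false(schwabFilter(m11))
  two212 <- ok; two212[c(3, 7)] <- "x"          # two mismatches in 2-12
  expect_false(schwabFilter(two212))
  run3 <- ok; run3[15:17] <- "x"                # three consecutive
  expect_false(schwabFilter(run3))
  run2 <- ok; run2[15:16] <- "x"                # two consecutive is allowed
  expect_true(schwabFilter(run2))
  wob <- ok; wob[c(10, 3, 7)] <- "o"            # wobbles are not mismatches
  expect_true(schwabFilter(wob))
})

test_that("UTR scanning finds planted sites at the right position and score", {
  set.seed(12)
  mir <- c(mirA = rand_dna(22))
  utr <- rand_dna(300)
  site <- rc(mir[[1]])
  substr(utr, 101, 100 + nchar(site)) <- site
  hits <- scanUTRs(mir, c(tx1 = utr), maxScore = 3)
  best <- hits[hits$best, ]
  expect_equal(nrow(best), 1L)
  expect_equal(best$score, 0)
  expect_equal(best$start, 100L)                 # 0-based window start
  expect_equal(best$position, 100L + 22L - 1L)   # base pairing position 1
  expect_true(best$schwab)
})

test_that("two seed-region mismatches score 4.0 and survive the threshold", {
  set.seed(14)
  mir <- c(m = rand_dna(22))
  s <- strsplit(rc(mir[[1]]), "")[[1]]
  # mutate the site bases pairing miRNA positions 5 and 9 (both doubled)
  for (p in c(5, 9)) {
    i <- 22 - p + 1
    s[i] <- setdiff(c("A", "C", "G", "T"), c(s[i], "G", "T"))[1]
  }
  utr <- paste0(rand_dna(60), paste(s, collapse = ""), rand_dna(60))
  hits <- scanUTRs(mir, c(tx = utr), maxScore = 4.0)
  expect_true(any(hits$score == 4.0 & hits$start == 60))
  # the same site is dropped when the threshold is tightened
  hits2 <- scanUTRs(mir, c(tx = utr), maxScore = 3.9)
  expect_false(any(hits2$start == 60 & hits2$width == 22))
})

test_that("scan scores agree with the single-pair scorer on every window", {
  set.seed(16)
  mir <- c(m = rand_dna(10))
  utr <- rand_dna(60)
  hits <- scanUTRs(mir, c(u = utr), maxScore = 99)
  for (i in seq_len(nrow(hits))) {
    win <- substr(utr, hits$start[i] + 1, hits$start[i] + hits$width[i])
    expect_equal(hits$score[i], allenScore(mir[[1]], win)$score)
  }
})

test_that("mirrored scanning is consistent for unweighted, wobble-free scoring", {
  # with uniform position weights and no wobble asymmetry, scanning the
  # reverse-complemented UTR with the reverse-complemented miRNA mirrors
  # positions and preserves scores
  set.seed(18)
  mir <- rand_dna(6)
  utr <- rand_dna(80)
  sc <- function(m, u) lapply(1:(80 - 6 + 1), function(s)
    allenScore(m, substr(u, s, s + 5), doubled = integer(0)))
  direct <- sc(mir, utr)
  mirrored <- rev(sc(rc(mir), rc(utr)))
  # complementation swaps wobbles and some mismatches; compare windows in
  # which neither orientation uses a wobble
  keep <- !vapply(seq_along(direct), function(i)
    any(direct[[i]]$status == "o") || any(mirrored[[i]]$status == "o"),
    logical(1))
  expect_gt(sum(keep), 5)
  expect_equal(vapply(direct[keep], `[[`, numeric(1), "score"),
               vapply(mirrored[keep], `[[`, numeric(1), "score"))
})

test_that("shuffling a UTR destroys the planted perfect site", {
  set.seed(20)
  mir <- c(m = rand_dna(22))
  utr <- rand_dna(250)
  substr(utr, 80, 80 + 21) <- rc(mir[[1]])
  planted <- sum(scanUTRs(mir, c(u = utr), maxScore = 1)$score <= 1)
  expect_gte(planted, 1)
  nullCounts <- vapply(1:25, function(s) {
    set.seed(1000 + s)
    shuf <- paste(sample(strsplit(utr, "")[[1]]), collapse = "")
    nrow(scanUTRs(mir, c(u = shuf), maxScore = 1))
  }, numeric(1))
  expect_lt(mean(nullCounts), planted)
})

test_that("empty UTRs are skipped with a warning", {
  mir <- c(m = rand_dna(20))
  expect_warning(res <- scanUTRs(mir, c(good = rand_dna(40), bad = "")),
                 "empty UTR")
  expect_true(all(res$transcript == "good"))
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  # a term containing exactly the target set: p = 1 / C(N, n)
  ann <- data.frame(gene = paste0("g", 1:12),
                    term = c(rep("T1", 4), rep("T2", 8)))
  res <- enrichTerms(paste0("g", 1:4), ann)
  expect_equal(res$pvalue[res$term == "T1"], 1 / choose(12, 4))
  # k = 0 gives p = 1 under the upper tail
  expect_equal(res$pvalue[res$term == "T2"], 1)
  # exhaustive enumeration at N = 20, K = 5, n = 5, k = 3
  ann2 <- data.frame(gene = paste0("g", 1:20),
                     term = c(rep("lip", 5), rep("other", 15)))
  targets <- c("g1", "g2", "g3", "g18", "g19")
  res2 <- enrichTerms(targets, ann2)
  expect_equal(res2$pvalue[res2$term == "lip"], hyper_oracle(3, 5, 5, 20),
               tolerance = 1e-12)
  expect_equal(res2$qvalue, bhFdr(res2$pvalue))
  expect_error(enrichTerms(c("g1", "nope"), ann2), "nope")
})
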