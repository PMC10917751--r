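test_that("peptide tables round-trip through TSV and reject bad input", {
  tmp <- tempfile(fileext = ".tsv")
  ds <- PeptideSet(c("LLVEVLREI", "AAAWYLWEV", "KQWYSAVLV"),
                   c("HLA-A*02:01", "HLA-A02:01", "HLA-B0702"),
                   label = c(1L, 0L, 1L), name = "toy")
  expect_identical(pepAlleles(ds)[2L], "HLA-A*02:01")
  expect_identical(pepAlleles(ds)[3L], "HLA-B*07:02")
  writePeptideTable(ds, tmp)
  back <- readPeptideTable(tmp)
  expect_identical(pepSeqs(back), pepSeqs(ds))
  expect_identical(pepAlleles(back), pepAlleles(ds))
  expect_identical(pepLabels(back), pepLabels(ds))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\tlabel",
               "LLVEVLRE1\tHLA-A*02:01\t1"), bad)
  expect_error(readPeptideTable(bad), "LLVEVLRE1")
  expect_error(readPeptideTable(bad), "row 1")

  # binder/non-binder string labels parse too
  txt <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\tlabel",
               "LLVEVLREI\tHLA-A*02:01\tbinder",
               "AAAWYLWEV\tHLA-A*02:01\tnon-binder"), txt)
  expect_identical(pepLabels(readPeptideTable(txt)), c(1L, 0L))
})

test_that("attribution files are lossless, including the empty collection", {
  tmp <- tempfile(fileext = ".tsv")
  a1 <- AttributionVector(c(0.1, -0.2, 1 / 3, pi, -1e-12, 0.5, 2, -3, 0.25),
                          "LLVEVLREI", "HLA-A*02:01", "p1",
                          "exact_shapley", 7L, 0.123456789012345)
  writeAttributions(list(a1), tmp)
  back <- readAttributions(tmp)
  expect_identical(as.numeric(attrValues(back)[1L, ]), a1@values)
  expect_identical(attrMeta(back)$method, "exact_shapley")
  expect_identical(attrMeta(back)$seed, 7L)

  writeAttributions(list(), tmp)
  empty <- readAttributions(tmp)
  expect_s4_class(empty, "AttributionSet")
  expect_identical(length(empty), 0L)

  # 200 random vectors: bitwise-equal floats after the round trip
  vecs <- withr::with_seed(11L, lapply(seq_len(200L), function(i) {
    AttributionVector(rnorm(9), uniformPeptides(1L, seed = i),
                      "HLA-A*02:01", "pX", "lime", i, rnorm(1))
  }))
  writeAttributions(vecs, tmp)
  back <- readAttributions(tmp)
  orig <- do.call(rbind, lapply(vecs, function(v) v@values))
  expect_identical(unname(attrValues(back)), unname(orig))
  expect_identical(attrMeta(back)$baseline,
                   vapply(vecs, attrBaseline, 1.0))

  # length mismatch across vectors is rejected
  expect_error(writeAttributions(
    list(a1, AttributionVector(rnorm(8), "LLVEVLRE", "HLA-A*02:01",
                               "p1", "lime")), tmp),
    "same length")
})

test_that("curation applies the four filters in order and is idempotent", {
  fx <- curationFixture()
  cur <- curateBenchmark(fx$dataset, fx$training, length = 9L)
  expect_identical(length(cur), fx$expectedSurvivors)
  counts <- datasetMetadata(cur)$curation
  expect_identical(counts$removed_length, 1L)
  expect_identical(counts$removed_training_overlap, 1L)
  expect_identical(counts$removed_conflicting_label, 2L)
  expect_identical(counts$removed_single_class_allele, 2L)
  expect_setequal(unique(pepAlleles(cur)), "HLA-A*01:01")

  again <- curateBenchmark(cur, fx$training, length = 9L)
  expect_identical(as.data.frame(again), as.data.frame(cur))

  # empty survivor set warns rather than errors
  allB <- PeptideSet(c("MMPRTEWYV", "HHPRTEWYV"), "HLA-B*07:02",
                     label = c(1L, 1L))
  expect_warning(curateBenchmark(allB, length = 9L), "every record")
})

test_that("conflict and single-class filters commute without training overlap", {
  # the two filters target disjoint record properties, so applying them in
  # either order must agree; checked on random labelled fixtures
  for (seed in 1:5) {
    ds <- withr::with_seed(seed, {
      peps <- uniformPeptides(40L, seed = seed + 77L)
      peps <- sample(peps, 60L, replace = TRUE)  # force duplicates
      PeptideSet(peps,
                 sample(c("HLA-A*02:01", "HLA-B*07:02", "HLA-C*06:02"),
                        60L, replace = TRUE),
                 label = sample(0:1, 60L, replace = TRUE))
    })
    full <- curateBenchmark(ds, length = 9L)
    # reversed order: single-class first, then conflicts, then re-curate
    df <- as.data.frame(ds)
    df <- df[!duplicated(df[c("peptide", "allele", "label")]), ]
    cls <- vapply(split(df$label, df$allele),
                  function(x) length(unique(x)), 1L)
    df <- df[df$allele %in% names(cls)[cls == 2L], ]
    swapped <- curateBenchmark(
      PeptideSet(df$peptide, df$allele, label = df$label), length = 9L)
    expect_identical(sort(paste(pepSeqs(full), pepAlleles(full),
                                pepLabels(full))),
                     sort(paste(pepSeqs(swapped), pepAlleles(swapped),
                                pepLabels(swapped))))
  }
})

test_that("PSSM estimation matches closed forms and recovers a generator", {
  one <- pssmFromPeptides("AAAAAAAAA", pseudocount = 0)
  expect_equal(unname(pssmProb(one)[, "A"]), rep(1, 9))
  two <- pssmFromPeptides(c("AAAAAAAAA", "YYYYYYYYY"), pseudocount = 0)
  expect_equal(unname(pssmProb(two)[, "A"]), rep(0.5, 9))
  expect_equal(unname(pssmProb(two)[, "Y"]), rep(0.5, 9))
  expect_error(pssmFromPeptides(character(0)), "zero peptides")

  gen <- motifFromConsensus("YLFPGAVKV", 0.9)
  est <- pssmFromPeptides(samplePeptidesFromPssm(gen, 100L, seed = 3L),
                          pseudocount = 1)
  tv <- apply(abs(pssmProb(est) - pssmProb(gen)), 1L, sum) / 2
  expect_lt(max(tv), 0.15)
})

test_that("PSSM sampling is reproducible and matches its distribution", {
  onehot <- motifFromConsensus("YLFPGAVKV", 1 - 1e-15)
  expect_true(all(samplePeptidesFromPssm(onehot, 20L, seed = 1L) ==
                    "YLFPGAVKV"))
  expect_identical(samplePeptidesFromPssm(anchoredMotif(), 50L, seed = 9L),
                   samplePeptidesFromPssm(anchoredMotif(), 50L, seed = 9L))
  peps <- uniformPeptides(10000L, seed = 4L)
  freq <- pssmProb(pssmFromPeptides(peps, pseudocount = 0))
  expect_lt(max(abs(freq - 0.05)), 0.02)
})

test_that("resampling a PSSM converges to the source with sample size", {
  gen <- anchoredMotif()
  dists <- vapply(c(100L, 1000L, 10000L), function(n) {
    est <- pssmFromPeptides(samplePeptidesFromPssm(gen, n, seed = 5L),
                            pseudocount = 1)
    max(abs(pssmProb(est) - pssmProb(gen)))
  }, 1.0)
  expect_true(all(diff(dists) < 0))
})

test_that("the synthetic study has exact bookkeeping and usable ground truth", {
  st <- makeSyntheticStudy(anchoredMotif(), nTotal = 1000L,
                           binderFraction = 0.05, ddgNoiseSd = 0, seed = 2L)
  expect_identical(sum(pepLabels(st$dataset) == 1L), 50L)
  pb <- percentBinders(st$dataset)
  expect_equal(pb$fraction, 0.05)

  # noise-free ddG is perfectly correlated with the true contributions
  for (i in seq_len(10L)) {
    prof <- st$ddg[[i]]
    expect_equal(cor(ddgValues(prof), st$contributions[i, ]), 1.0)
  }

  # noise at the scale of the contribution spread degrades the correlation
  # into a middling band
  sdC <- sd(as.numeric(st$contributions * 3))  # kJ/mol scale (kjPerBit = 3)
  noisy <- makeSyntheticStudy(anchoredMotif(), nTotal = 2000L,
                              binderFraction = 0.05, ddgNoiseSd = sdC,
                              seed = 6L)
  rs <- vapply(seq_len(100L), function(i)
    cor(ddgValues(noisy$ddg[[i]]), noisy$contributions[i, ]), 1.0)
  expect_gt(median(rs), 0.5)
  expect_lt(median(rs), 0.9)
})

test_that("percent binders handles edge cases", {
  allB <- PeptideSet(c("MMPRTEWYV", "HHPRTEWYV"), "HLA-B*07:02",
                     label = c(1L, 1L))
  expect_equal(percentBinders(allB)$fraction, 1.0)
  oneIn10 <- PeptideSet(uniformPeptides(10L, seed = 8L), "HLA-A*02:01",
                        label = c(1L, rep(0L, 9L)))
  expect_equal(percentBinders(oneIn10)$fraction, 0.10)
  unlab <- PeptideSet("MMPRTEWYV", "HLA-A*02:01")
  expect_error(percentBinders(unlab), "labelled")
})

test_that("PSSM and ddG files round-trip; incomplete profiles are rejected", {
  tmp <- tempfile(fileext = ".tsv")
  gen <- anchoredMotif()
  writePssm(gen, tmp)
  expect_equal(pssmProb(readPssm(tmp)), pssmProb(gen))
  writePssm(gen, tmp, type = "logodds")
  expect_equal(pssmProb(readPssm(tmp)), pssmProb(gen))

  prof <- DdgProfile(seq(-4, 4), "LLVEVLREI", "HLA-A*02:01", "1AKJ")
  writeDdgTable(list(prof), tmp)
  back <- readDdgTable(tmp)
  expect_identical(length(back), 1L)
  expect_equal(unname(ddgValues(back[[1L]])), seq(-4, 4))
  expect_identical(back[[1L]]@pdbId, "1AKJ")

  # drop P7 -> completeness error naming the missing position
  lines <- readLines(tmp)
  writeLines(lines[!grepl("\t7\t", lines)], tmp)
  expect_error(readDdgTable(tmp), "missing: 7")
})

test_that("FASTA peptide lists are read via Biostrings", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "LLVEVLREI", ">p2", "AAAWYLWEV"), fa)
  expect_identical(readPeptideFasta(fa), c("LLVEVLREI", "AAAWYLWEV"))
})
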