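test_that("KLD has its closed-form values and matches a direct summation", {
  expect_equal(kld(uniformPssm()), 0)
  onehot <- motifFromConsensus("YLFPGAVKV", 1 - 1e-15)
  expect_equal(kld(onehot), log2(20), tolerance = 1e-6)
  # independent double-loop oracle on a random pseudocounted PSSM
  pssm <- pssmFromPeptides(uniformPeptides(30L, seed = 301L),
                           pseudocount = 1)
  p <- pssmProb(pssm)
  q <- pssmBackground(pssm)
  direct <- 0
  for (pos in seq_len(nrow(p)))
    for (a in seq_len(20L))
      if (p[pos, a] > 0)
        direct <- direct + p[pos, a] * log2(p[pos, a] / q[a])
  expect_equal(kld(pssm), unname(direct) / nrow(p))
  expect_gte(kld(pssm), 0)
  expect_error(kld(onehot, background = c(0, rep(1 / 19, 19))),
               "zero background")
})

test_that("PSSM similarity is 1 on self, -1 on negated log-odds, small on noise", {
  p1 <- anchoredMotif()
  expect_equal(pssmSimilarity(p1, p1), 1.0)
  # construct a PSSM whose log-odds columns are the negation of p1's
  lo <- logOdds(p1)
  negProb <- sweep(2^(-lo), 2L, pssmBackground(p1), "*")
  negProb <- negProb / rowSums(negProb)
  p2 <- PSSM(negProb)
  # renormalization preserves column order up to affine shift -> r = -1
  expect_equal(pssmSimilarity(p1, p2), -1.0, tolerance = 1e-9)
  sims <- vapply(1:10, function(s) {
    a <- pssmFromPeptides(uniformPeptides(40L, seed = 400L + s),
                          pseudocount = 1)
    b <- pssmFromPeptides(uniformPeptides(40L, seed = 500L + s),
                          pseudocount = 1)
    pssmSimilarity(a, b)
  }, 1.0)
  expect_lte(max(abs(sims)), 0.3)
})

twoMotifPeptides <- function(nPer = 50L, seedA = 311L, seedB = 312L,
                             consensusB = "KPRQDYEWC") {
  mA <- motifFromConsensus("YLFPGAVKV", 0.9)
  mB <- motifFromConsensus(consensusB, 0.9)
  list(peptides = c(samplePeptidesFromPssm(mA, nPer, seed = seedA),
                    samplePeptidesFromPssm(mB, nPer, seed = seedB)),
       truth = rep(1:2, each = nPer))
}

test_that("Gibbs clustering recovers two disjoint motifs exactly", {
  fx <- twoMotifPeptides()
  asg <- gibbsCluster(fx$peptides,
                      gibbsConfig(nClusters = 2L, nSweeps = 40L,
                                  seed = 313L))
  expect_equal(adjustedRand(clusterLabels(asg), fx$truth), 1.0)
  # determinism
  asg2 <- gibbsCluster(fx$peptides,
                       gibbsConfig(nClusters = 2L, nSweeps = 40L,
                                   seed = 313L))
  expect_identical(asg@labels, asg2@labels)
  expect_identical(averageKld(asg), averageKld(asg2))
})

test_that("k = 1 clustering reduces to the pooled PSSM's KLD", {
  peps <- uniformPeptides(40L, seed = 314L)
  asg <- gibbsCluster(peps, gibbsConfig(nClusters = 1L, nSweeps = 5L,
                                        seed = 315L))
  expect_true(all(asg@labels == 1L))
  pooled <- pssmFromPeptides(peps, pseudocount = 1)
  expect_equal(averageKld(asg), kld(pooled))
})

test_that("downstream outputs are invariant under cluster relabelling", {
  fx <- twoMotifPeptides(nPer = 30L)
  asg <- gibbsCluster(fx$peptides,
                      gibbsConfig(nClusters = 2L, nSweeps = 30L,
                                  seed = 316L))
  flipped <- new("ClusterAssignment", peptides = asg@peptides,
                 labels = 3L - asg@labels,
                 pssms = asg@pssms[c(2L, 1L)],
                 avgKld = asg@avgKld, kldTrace = asg@kldTrace)
  p1 <- selectUnrelatedPairs(asg, kPairs = 1L)
  p2 <- selectUnrelatedPairs(flipped, kPairs = 1L)
  expect_equal(p1$similarity, p2$similarity)
  expect_equal(averageKld(asg), averageKld(flipped))
})

test_that("recovery degrades gracefully when motifs share consensus positions", {
  # motifs share 3 of 9 consensus positions -> ARI still at least 0.8
  fx <- twoMotifPeptides(consensusB = "YLFQDYEWC")  # shares P1..P3 letters
  asg <- gibbsCluster(fx$peptides,
                      gibbsConfig(nClusters = 2L, nSweeps = 40L,
                                  seed = 317L))
  expect_gte(adjustedRand(clusterLabels(asg), fx$truth), 0.8)
})

test_that("greedy-limit sweeps do not lose the objective once converged", {
  fx <- twoMotifPeptides(nPer = 30L)
  asg <- gibbsCluster(fx$peptides,
                      gibbsConfig(nClusters = 2L, nSweeps = 30L,
                                  t0 = 0.01, tMin = 0.001, seed = 318L))
  tr <- asg@kldTrace
  tail5 <- tail(tr, 5L)
  expect_true(all(diff(tail5) >= -1e-9))
  expect_equal(averageKld(asg), max(tr))
})

test_that("the cluster count is chosen by maximum average KLD", {
  single <- list(peptides = samplePeptidesFromPssm(anchoredMotif(), 60L,
                                                   seed = 319L))
  ch1 <- chooseNClusters(single$peptides, kRange = 1L,
                         gibbsConfig(nClusters = 1L, nSweeps = 10L,
                                     seed = 320L))
  expect_identical(ch1$bestK, 1L)

  fx <- twoMotifPeptides()
  ch <- chooseNClusters(fx$peptides, kRange = 1:3,
                        gibbsConfig(nClusters = 1L, nSweeps = 30L,
                                    seed = 321L))
  # multi-restart consensus oracle: rerun each k with 5 fresh seeds and
  # take the best-of-restarts KLD per k
  consensus <- vapply(1:3, function(k) {
    max(vapply(1:5, function(s)
      averageKld(gibbsCluster(fx$peptides,
                              gibbsConfig(nClusters = k, nSweeps = 30L,
                                          seed = 900L + 10L * k + s))),
      1.0))
  }, 1.0)
  expect_identical(ch$bestK, which.max(consensus))
  expect_identical(nrow(ch$table), 3L)
})

test_that("unrelated pair selection ranks ascending with stable ties", {
  fx <- twoMotifPeptides(nPer = 30L)
  asg3 <- gibbsCluster(fx$peptides,
                       gibbsConfig(nClusters = 3L, nSweeps = 25L,
                                   seed = 322L))
  pairs <- selectUnrelatedPairs(asg3, kPairs = 6L)
  expect_lte(nrow(pairs), 3L)  # C(3,2)
  expect_true(all(diff(pairs$similarity) >= 0))
  expect_identical(nrow(selectUnrelatedPairs(asg3, kPairs = 0L)), 0L)

  # two identical clusters + one distinct: mixed pairs rank first
  ident <- pssmFromPeptides(samplePeptidesFromPssm(anchoredMotif(), 40L,
                                                   seed = 323L),
                            pseudocount = 1)
  other <- pssmFromPeptides(samplePeptidesFromPssm(
    motifFromConsensus("KPRQDYEWC", 0.9), 40L, seed = 324L),
    pseudocount = 1)
  fake <- new("ClusterAssignment", peptides = fx$peptides,
              labels = rep(1:3, length.out = length(fx$peptides)),
              pssms = list(ident, ident, other), avgKld = 1,
              kldTrace = numeric(0))
  ranked <- selectUnrelatedPairs(fake, kPairs = 3L)
  expect_setequal(paste(ranked$left[1:2], ranked$right[1:2]),
                  c("1 3", "2 3"))
  expect_identical(c(ranked$left[3L], ranked$right[3L]), c(1L, 2L))
})
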