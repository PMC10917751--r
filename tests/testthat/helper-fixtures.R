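# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

uniformPssm <- function(L = 9L) {
  PSSM(matrix(1 / 20, L, 20L, dimnames = list(NULL, AA_ALPHABET)))
}

uniformPeptides <- function(n, L = 9L, seed = 1L) {
  samplePeptidesFromPssm(uniformPssm(L), n, seed = seed)
}

# anchored test motif: sharp at two anchor positions, diffuse elsewhere
anchoredMotif <- function(consensus = "YLFPGAVKV", anchors = c(2L, 9L),
                          sharpAnchor = 0.95, sharpOther = 0.4) {
  sh <- rep(sharpOther, nchar(consensus))
  sh[anchors] <- sharpAnchor
  motifFromConsensus(consensus, sh)
}

testBackground <- function(k = 10L, L = 9L, seed = 42L) {
  BackgroundSet(uniformPeptides(k, L, seed = seed))
}

randomContext <- function(seed, predictor = NULL, bgK = 10L) {
  motif <- anchoredMotif()
  if (is.null(predictor))
    predictor <- makePssmPredictor(motif, id = paste0("surr", seed))
  pep <- samplePeptidesFromPssm(motif, 1L, seed = seed + 1000L)
  explainContext(pep, "HLA-A*02:01", predictor,
                 testBackground(bgK, seed = seed + 2000L), seed = seed)
}

# Independent exact-Shapley oracle: memoized straightforward double loop
# over subsets (combn) and background peptides; shares no code with the
# package engine beyond the predictor handle itself.
oracleShapley <- function(peptide, allele, predictor, bgPeps, bgW) {
  L <- nchar(peptide)
  orig <- strsplit(peptide, "")[[1L]]
  cache <- new.env(parent = emptyenv())
  v <- function(S) {
    key <- paste0("k", paste(sort(S), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    tot <- 0
    for (b in seq_along(bgPeps)) {
      chars <- strsplit(bgPeps[b], "")[[1L]]
      chars[S] <- orig[S]
      tot <- tot + bgW[b] *
        predictBatch(predictor, paste(chars, collapse = ""), allele)
    }
    cache[[key]] <- tot
    tot
  }
  phi <- numeric(L)
  for (i in seq_len(L)) {
    others <- setdiff(seq_len(L), i)
    for (s in 0:(L - 1L)) {
      subsets <- if (s == 0L) list(integer(0))
                 else utils::combn(others, s, simplify = FALSE)
      w <- factorial(s) * factorial(L - s - 1L) / factorial(L)
      for (S in subsets)
        phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
    }
  }
  phi
}

# analytic Shapley for an additive (linear-link) PSSM surrogate:
# phi_p = a * (s_p(x_p) - sum_b w_b s_p(b_p))
analyticAdditivePhi <- function(motif, peptide, background, slope) {
  s <- logOdds(motif)
  pidx <- match(strsplit(peptide, "")[[1L]], AA_ALPHABET)
  bgm <- do.call(rbind,
                 lapply(strsplit(bgPeptides(background), ""), match,
                        AA_ALPHABET))
  L <- length(pidx)
  vapply(seq_len(L), function(p) {
    slope * (s[p, pidx[p]] - sum(bgWeights(background) * s[p, bgm[, p]]))
  }, 1.0)
}

# slope of the linear-link surrogate's default calibration
linearSlope <- function(motif) {
  s <- logOdds(motif)
  (0.99 - 0.01) / (sum(apply(s, 1L, max)) - sum(apply(s, 1L, min)))
}

# 10-record curation fixture with hand-countable survivors:
#  r1 8-mer (filter 1), r2 training overlap (filter 2),
#  r3+r4 conflicting labels (filter 3), r5+r6 binder-only allele (filter 4),
#  r7..r10 clean two-class allele -> 4 survivors
curationFixture <- function() {
  ds <- PeptideSet(
    c("LLVEVLRE",                      # r1: 8-mer
      "AAAWYLWEV",                     # r2: training overlap
      "KQWYSAVLV", "KQWYSAVLV",        # r3, r4: conflicting labels
      "MMPRTEWYV", "HHPRTEWYV",        # r5, r6: binder-only allele
      "YLFPGAVKV", "QQWDSAVYV",        # r7..r10: clean allele
      "NNFPGAVKV", "PPWDSAVYV"),
    c("HLA-A*02:01", "HLA-A*02:01",
      "HLA-A*02:01", "HLA-A*02:01",
      "HLA-B*07:02", "HLA-B*07:02",
      "HLA-A*01:01", "HLA-A*01:01", "HLA-A*01:01", "HLA-A*01:01"),
    label = c(1L, 1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L),
    name = "curation_fixture")
  training <- list(predA = data.frame(peptide = "AAAWYLWEV",
                                      allele = "HLA-A*02:01"))
  list(dataset = ds, training = training, expectedSurvivors = 4L)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
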