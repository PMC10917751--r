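#' Kullback-Leibler distance of a PSSM from background
#'
#' Mean over positions of \eqn{\sum_a p_a \log_2(p_a / q_a)}, in bits.
#' Zero-probability entries contribute 0; a zero background entry paired
#' with non-zero probability is an error (supply pseudocounted inputs).
#'
#' @param pssm A \linkS4class{PSSM} in probability form.
#' @param background Length-20 background vector (default: the PSSM's own).
#' @return Non-negative mean per-position KLD in bits; 0 iff every column
#'   equals the background.
#' @export
kld <- function(pssm, background = NULL) {
  stopifnot(is(pssm, "PSSM"))
  q <- if (is.null(background)) pssmBackground(pssm)
       else setNames(as.numeric(background), AA_ALPHABET)
  p <- pssmProb(pssm)
  if (any(p > 0 & matrix(q, nrow(p), 20L, byrow = TRUE) == 0))
    stop("zero background entry with non-zero probability; ",
         "use pseudocounted inputs")
  terms <- p * log2(sweep(p, 2L, q, "/"))
  terms[p == 0] <- 0
  mean(rowSums(terms))
}

#' Similarity between two PSSMs
#'
#' Mean over positions of the Pearson correlation between the
#' corresponding log-odds columns (20-vectors). Positions where either
#' log-odds column is constant are skipped with a warning.
#'
#' @param p1,p2 \linkS4class{PSSM}s of equal length.
#' @return Scalar in [-1, 1].
#' @export
pssmSimilarity <- function(p1, p2) {
  stopifnot(is(p1, "PSSM"), is(p2, "PSSM"))
  if (pssmLength(p1) != pssmLength(p2))
    stop("PSSMs must have equal length")
  s1 <- logOdds(p1)
  s2 <- logOdds(p2)
  vals <- vapply(seq_len(nrow(s1)), function(p) {
    if (sd(s1[p, ]) == 0 || sd(s2[p, ]) == 0) NA_real_
    else cor(s1[p, ], s2[p, ])
  }, 1.0)
  if (anyNA(vals))
    warning("skipped ", sum(is.na(vals)),
            " position(s) with constant log-odds column")
  mean(vals, na.rm = TRUE)
}

#' Gibbs clustering configuration
#'
#' @param nClusters Number of clusters k.
#' @param lambda Intercluster-similarity penalty in [0, 1]; the
#'   recommended low value 0.05 suits largely homogeneous binder sets
#'   where subtle motif differences are sought.
#' @param nSweeps Gibbs sweeps (default 100).
#' @param t0,decay,tMin Annealing schedule: initial temperature, per-sweep
#'   multiplicative decay, floor (defaults 1.5, 0.9, 0.05).
#' @param pseudocount PSSM pseudocount (default 1, Laplace-style).
#' @param background Length-20 background vector q (default uniform).
#' @param seed Integer seed.
#' @return Config list for [gibbsCluster()].
#' @export
gibbsConfig <- function(nClusters, lambda = 0.05, nSweeps = 100L,
                        t0 = 1.5, decay = 0.9, tMin = 0.05,
                        pseudocount = 1, background = uniformBackground(),
                        seed = 1L) {
  stopifnot(nClusters >= 1, lambda >= 0, lambda <= 1, t0 > 0,
            pseudocount >= 0)
  list(nClusters = as.integer(nClusters), lambda = lambda,
       nSweeps = as.integer(nSweeps), t0 = t0, decay = decay, tMin = tMin,
       pseudocount = pseudocount,
       background = setNames(as.numeric(background), AA_ALPHABET),
       seed = as.integer(seed))
}

# pseudocounted probability matrix from a count matrix
.countsToProb <- function(counts, nMembers, pseudocount, q) {
  sweep(counts, 2L, pseudocount * q, "+") / (nMembers + pseudocount)
}

#' Gibbs-sampling peptide clustering with a KLD objective
#'
#' Simplified motif clustering for fixed-length peptides: one peptide at a
#' time is removed from its cluster, the affected cluster's pseudocounted
#' PSSM is recomputed, and the peptide is reassigned to cluster c with
#' probability proportional to \eqn{\exp(\mathrm{score}_c / T)}, where
#' \eqn{\mathrm{score}_c} is the peptide's summed per-position log2-odds
#' under cluster c's PSSM minus \eqn{\lambda} times the mean PSSM
#' similarity of cluster c to the other clusters (recomputed once per
#' sweep). The temperature is annealed multiplicatively. The assignment
#' with the highest size-weighted average KLD encountered across sweeps is
#' returned. Clusters that empty out are reseeded with the currently
#' worst-fitting peptide. Reproducible for a fixed seed. No alignment
#' moves: peptides must share one length.
#'
#' @param peptides Character vector of equal-length peptides (at least
#'   \code{nClusters} of them).
#' @param cfg A [gibbsConfig()] list.
#' @return A \linkS4class{ClusterAssignment}.
#' @export
gibbsCluster <- function(peptides, cfg) {
  .assertPeptides(peptides)
  L <- nchar(peptides[1L])
  .assertPeptides(peptides, len = L)
  n <- length(peptides)
  k <- cfg$nClusters
  if (n < k) stop("need at least as many peptides as clusters")
  q <- cfg$background
  pc <- cfg$pseudocount
  idx <- .pepIndex(peptides)
  logq <- log2(q)

  counts <- array(0, dim = c(k, L, 20L))
  sizes <- integer(k)
  addPep <- function(i, c_) {
    for (p in seq_len(L))
      counts[c_, p, idx[i, p]] <<- counts[c_, p, idx[i, p]] + 1
    sizes[c_] <<- sizes[c_] + 1L
  }
  removePep <- function(i, c_) {
    for (p in seq_len(L))
      counts[c_, p, idx[i, p]] <<- counts[c_, p, idx[i, p]] - 1
    sizes[c_] <<- sizes[c_] - 1L
  }
  clusterPssm <- function(c_) {
    PSSM(.countsToProb(counts[c_, , , drop = TRUE], sizes[c_], pc, q),
         pseudocount = pc, background = q)
  }
  # log2-odds score of peptide i under cluster c_'s current counts
  pepScore <- function(i, c_) {
    pos <- cbind(seq_len(L), idx[i, ])
    cnt <- counts[c_, , , drop = TRUE][pos]
    sum(log2((cnt + pc * q[idx[i, ]]) / (sizes[c_] + pc)) - logq[idx[i, ]])
  }
  avgKldNow <- function() {
    sum(vapply(seq_len(k), function(c_) {
      if (sizes[c_] == 0L) return(0)
      (sizes[c_] / n) * kld(clusterPssm(c_), q)
    }, 1.0))
  }

  labels <- integer(n)
  trace <- numeric(cfg$nSweeps)
  bestLabels <- NULL
  bestKld <- -Inf

  .withSeed(cfg$seed, {
    labels <- sample(rep_len(seq_len(k), n))
    for (i in seq_len(n)) addPep(i, labels[i])
    temp <- cfg$t0
    for (sweep_ in seq_len(cfg$nSweeps)) {
      pen <- numeric(k)
      if (k > 1L && cfg$lambda > 0) {
        pssms <- lapply(seq_len(k), clusterPssm)
        for (c_ in seq_len(k)) {
          sims <- vapply(setdiff(seq_len(k), c_), function(o)
            suppressWarnings(pssmSimilarity(pssms[[c_]], pssms[[o]])), 1.0)
          pen[c_] <- cfg$lambda * mean(sims)
        }
      }
      for (i in sample.int(n)) {
        removePep(i, labels[i])
        sc <- vapply(seq_len(k), function(c_) pepScore(i, c_), 1.0) - pen
        pr <- exp((sc - max(sc)) / temp)
        labels[i] <- sample.int(k, 1L, prob = pr)
        addPep(i, labels[i])
      }
      # reseed any empty cluster with the worst-fitting peptide
      for (c_ in which(sizes == 0L)) {
        fits <- vapply(seq_len(n), function(i) pepScore(i, labels[i]), 1.0)
        worst <- which.min(fits)
        message("gibbsCluster: reseeding empty cluster ", c_,
                " with peptide ", peptides[worst])
        removePep(worst, labels[worst])
        labels[worst] <- c_
        addPep(worst, c_)
      }
      objective <- avgKldNow()
      trace[sweep_] <- objective
      if (objective > bestKld) {
        bestKld <- objective
        bestLabels <- labels
      }
      temp <- max(cfg$tMin, temp * cfg$decay)
    }
  })

  # rebuild counts for the best assignment
  counts[] <- 0
  sizes[] <- 0L
  for (i in seq_len(n)) addPep(i, bestLabels[i])
  pssms <- lapply(seq_len(k), clusterPssm)
  new("ClusterAssignment", peptides = peptides,
      labels = as.integer(bestLabels), pssms = pssms,
      avgKld = bestKld, kldTrace = trace)
}

#' Select the number of clusters by average KLD
#'
#' Runs [gibbsCluster()] for each k in \code{kRange} and returns the k
#' whose assignment attains the highest average Kullback-Leibler distance,
#' with the full KLD-versus-k table. Each k gets its own seed derived from
#' the template's seed; ties resolve to the smaller k.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param kRange Integer candidate cluster counts (default 1:10).
#' @param cfg Template [gibbsConfig()] (its \code{nClusters} is ignored).
#' @return List with \code{bestK}, \code{table} (data.frame k,
#'   avg_kld_bits), and \code{assignments} (list keyed by k).
#' @export
chooseNClusters <- function(peptides, kRange = 1:10, cfg = NULL) {
  stopifnot(length(kRange) >= 1L)
  if (is.null(cfg)) cfg <- gibbsConfig(nClusters = 1L)
  assignments <- list()
  klds <- numeric(length(kRange))
  for (ii in seq_along(kRange)) {
    k <- kRange[ii]
    cfgK <- cfg
    cfgK$nClusters <- as.integer(k)
    cfgK$seed <- deriveSeed(cfg$seed, paste0("k", k))
    assignments[[as.character(k)]] <- gibbsCluster(peptides, cfgK)
    klds[ii] <- averageKld(assignments[[as.character(k)]])
  }
  tab <- data.frame(k = as.integer(kRange), avg_kld_bits = klds)
  list(bestK = as.integer(kRange[which.max(klds)]), table = tab,
       assignments = assignments)
}

#' Most unrelated cluster pairs
#'
#' Ranks all unordered cluster pairs by ascending PSSM similarity (most
#' unrelated first) and returns the top \code{kPairs}. Ties break by
#' (smaller index, larger index) lexicographic order. If fewer pairs
#' exist than requested, all are returned.
#'
#' @param assignment A \linkS4class{ClusterAssignment} with at least 2
#'   clusters.
#' @param kPairs Number of pairs to return (default 6).
#' @return Integer matrix with columns \code{left}, \code{right} and a
#'   \code{similarity} attribute column in the data.frame returned;
#'   concretely a data.frame (left, right, similarity), most unrelated
#'   pair first.
#' @export
selectUnrelatedPairs <- function(assignment, kPairs = 6L) {
  stopifnot(is(assignment, "ClusterAssignment"))
  k <- length(assignment@pssms)
  if (k < 2L) stop("need at least 2 clusters to form pairs")
  combos <- utils::combn(k, 2L)
  sims <- vapply(seq_len(ncol(combos)), function(j)
    suppressWarnings(pssmSimilarity(assignment@pssms[[combos[1L, j]]],
                                    assignment@pssms[[combos[2L, j]]])),
    1.0)
  ord <- order(sims, combos[1L, ], combos[2L, ])
  take <- head(ord, max(0L, kPairs))
  data.frame(left = combos[1L, take], right = combos[2L, take],
             similarity = sims[take])
}
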