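.asValues <- function(x) {
  if (is(x, "AttributionVector")) x@values else as.numeric(x)
}

#' Euclidean distance between two explanations
#'
#' @param a,b \linkS4class{AttributionVector}s or numeric vectors of equal
#'   length.
#' @return \eqn{\sqrt{\sum_i (a_i - b_i)^2}}.
#' @export
explanationDistance <- function(a, b) {
  a <- .asValues(a)
  b <- .asValues(b)
  if (length(a) != length(b))
    stop("explanations must have the same length")
  sqrt(sum((a - b)^2))
}

#' Pearson correlation between two explanations
#'
#' @param a,b \linkS4class{AttributionVector}s or numeric vectors of equal
#'   length; errors on constant input (undefined correlation).
#' @return Scalar Pearson r.
#' @export
explanationCorrelation <- function(a, b) {
  a <- .asValues(a)
  b <- .asValues(b)
  if (length(a) != length(b))
    stop("explanations must have the same length")
  .pearson(a, b)
}

#' Permutation baseline distance
#'
#' Random-explanation baseline: the values of the reference explanation
#' are randomly permuted \code{nPerm} times and the mean Euclidean distance
#' from \code{other} to each permuted vector is returned. With
#' \code{exhaustive = TRUE} all \eqn{L!} permutations are enumerated
#' instead (only sensible for small L; used as its own oracle).
#'
#' @param ref Reference explanation whose values are permuted.
#' @param other Explanation the distances are measured from.
#' @param nPerm Number of random permutations (default 100).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return Mean distance over the permutations.
#' @export
permutationBaseline <- function(ref, other, nPerm = 100L, seed = 1L,
                                exhaustive = FALSE) {
  r <- .asValues(ref)
  o <- .asValues(other)
  if (length(r) != length(o))
    stop("explanations must have the same length")
  L <- length(r)
  if (exhaustive) {
    perms <- .allPermutations(L)
    ds <- vapply(seq_len(nrow(perms)), function(i)
      sqrt(sum((o - r[perms[i, ]])^2)), 1.0)
    return(mean(ds))
  }
  stopifnot(nPerm >= 1)
  .withSeed(seed, {
    mean(vapply(seq_len(nPerm), function(i)
      sqrt(sum((o - sample(r))^2)), 1.0))
  })
}

.allPermutations <- function(L) {
  if (L == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(L - 1L)
  do.call(rbind, lapply(seq_len(L), function(i) {
    rest <- seq_len(L)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Kruskal-Wallis rank test with effect size
#'
#' Wraps the standard tie-corrected Kruskal-Wallis H test and reports the
#' epsilon-squared effect size
#' \eqn{\epsilon^2 = (H - k + 1)/(n - k)} alongside H and the chi-square
#' p-value (k - 1 degrees of freedom). When all pooled observations are
#' identical the test is degenerate and H = 0, p = 1 is returned.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with elements \code{H}, \code{p.value}, \code{effectSize},
#'   \code{df}, \code{groupSizes}.
#' @export
kruskalWallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L))
  k <- length(groups)
  n <- sum(lengths(groups))
  pooled <- unlist(groups, use.names = FALSE)
  if (max(pooled) == min(pooled)) {
    return(list(H = 0, p.value = 1, effectSize = (0 - k + 1) / (n - k),
                df = k - 1L, groupSizes = lengths(groups)))
  }
  fit <- kruskal.test(groups)
  H <- unname(fit$statistic)
  list(H = H, p.value = fit$p.value,
       effectSize = (H - k + 1) / (n - k),
       df = unname(fit$parameter), groupSizes = lengths(groups))
}

#' Consistency of explanations across two predictors
#'
#' For explanations of the same instances produced for two predictors
#' (matched on peptide, canonical allele and method), computes per pair
#' the Pearson correlation and Euclidean distance between the two
#' explanations, plus the permutation baseline distance (the reference
#' side's values permuted \code{nPerm} times, distance measured from the
#' other side). The actual-distance distribution is compared to the
#' baseline-distance distribution with a Kruskal-Wallis test, pooled and
#' per allele, and the fraction of instances whose actual distance beats
#' (is below) their baseline is reported.
#'
#' @param attrsA,attrsB Matched \linkS4class{AttributionSet}s (or lists of
#'   \linkS4class{AttributionVector}).
#' @param nPerm Permutations per instance (default 100).
#' @param seed Integer seed.
#' @param reference Which side's values are permuted for the baseline:
#'   \code{"B"} (default) or \code{"A"}.
#' @return List with \code{records} (peptide, allele, method, pearson_r,
#'   euclidean_d, baseline_d, beats_baseline), \code{kw} (pooled
#'   Kruskal-Wallis result), \code{kwPerAllele} (named list),
#'   \code{fractionBeatingBaseline}.
#' @export
consistencyReport <- function(attrsA, attrsB, nPerm = 100L, seed = 1L,
                              reference = c("B", "A")) {
  reference <- match.arg(reference)
  A <- bindAttributions(attrsA)
  B <- bindAttributions(attrsB)
  mA <- attrMeta(A)
  mB <- attrMeta(B)
  keyA <- paste(mA$peptide, mA$allele, mA$method, sep = "|")
  keyB <- paste(mB$peptide, mB$allele, mB$method, sep = "|")
  j <- match(keyA, keyB)
  sel <- which(!is.na(j))
  if (length(sel) == 0L)
    stop("no matched (peptide, allele, method) pairs between the two sets")

  rows <- lapply(seq_along(sel), function(ii) {
    i <- sel[ii]
    va <- attrValues(A)[i, ]
    vb <- attrValues(B)[j[i], ]
    d <- sqrt(sum((va - vb)^2))
    r <- tryCatch(.pearson(va, vb), error = function(e) NA_real_)
    bd <- if (reference == "B")
      permutationBaseline(vb, va, nPerm = nPerm,
                          seed = deriveSeed(seed, keyA[i]))
    else
      permutationBaseline(va, vb, nPerm = nPerm,
                          seed = deriveSeed(seed, keyA[i]))
    data.frame(peptide = mA$peptide[i], allele = mA$allele[i],
               method = mA$method[i], pearson_r = r, euclidean_d = d,
               baseline_d = bd, beats_baseline = d < bd,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  kw <- kruskalWallis(list(actual = records$euclidean_d,
                           baseline = records$baseline_d))
  kwPerAllele <- lapply(split(records, records$allele), function(g) {
    kruskalWallis(list(actual = g$euclidean_d, baseline = g$baseline_d))
  })
  list(records = records, kw = kw, kwPerAllele = kwPerAllele,
       fractionBeatingBaseline = mean(records$beats_baseline))
}

#' Stability of explanations across peptide clusters
#'
#' For each selected cluster pair, samples up to \code{maxPerCluster}
#' peptides per cluster (those with an available explanation), computes
#' the three Euclidean distance distributions -- all unordered pairs
#' within the left cluster (IntraclusterL), all cross pairs (Intercluster),
#' all unordered pairs within the right cluster (IntraclusterR) -- and a
#' Kruskal-Wallis test over the three groups. Stable explanations show
#' intracluster distances below intercluster distances.
#'
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param attrs An \linkS4class{AttributionSet} whose peptides cover the
#'   sampled cluster members.
#' @param clusterPairs Either a list/matrix of cluster index pairs or the
#'   result of [selectUnrelatedPairs()].
#' @param maxPerCluster Sampling cap per cluster (default 100).
#' @param seed Integer seed for the sampling.
#' @return List keyed \code{"cI-cJ"}; each element has \code{intraL},
#'   \code{inter}, \code{intraR} (numeric distance vectors), \code{kw},
#'   and \code{medians}. Pairs with fewer than 2 usable members in a
#'   cluster are skipped with a warning.
#' @export
stabilityReport <- function(assignment, attrs, clusterPairs,
                            maxPerCluster = 100L, seed = 1L) {
  stopifnot(is(assignment, "ClusterAssignment"))
  aset <- bindAttributions(attrs)
  meta <- attrMeta(aset)
  if (is.matrix(clusterPairs))
    clusterPairs <- lapply(seq_len(nrow(clusterPairs)),
                           function(i) clusterPairs[i, ])
  labels <- assignment@labels
  peps <- assignment@peptides

  sampleCluster <- function(ci) {
    members <- unique(peps[labels == ci])
    members <- members[members %in% meta$peptide]
    if (length(members) > maxPerCluster)
      members <- .withSeed(deriveSeed(seed, paste0("cluster", ci)),
                           sample(members, maxPerCluster))
    members
  }
  valuesFor <- function(members) {
    attrValues(aset)[match(members, meta$peptide), , drop = FALSE]
  }
  pairDists <- function(V) {
    n <- nrow(V)
    if (n < 2L) return(numeric(0))
    as.numeric(stats::dist(V))
  }
  crossDists <- function(Va, Vb) {
    out <- matrix(0, nrow(Va), nrow(Vb))
    for (i in seq_len(nrow(Va)))
      out[i, ] <- sqrt(colSums((t(Vb) - Va[i, ])^2))
    as.numeric(out)
  }

  out <- list()
  for (pr in clusterPairs) {
    ci <- pr[[1L]]
    cj <- pr[[2L]]
    mi <- sampleCluster(ci)
    mj <- sampleCluster(cj)
    if (length(mi) < 2L || length(mj) < 2L) {
      warning("skipping cluster pair (", ci, ", ", cj,
              "): fewer than 2 sampled members with explanations")
      next
    }
    Vi <- valuesFor(mi)
    Vj <- valuesFor(mj)
    intraL <- pairDists(Vi)
    intraR <- pairDists(Vj)
    inter <- crossDists(Vi, Vj)
    kw <- kruskalWallis(list(intraL = intraL, inter = inter,
                             intraR = intraR))
    out[[paste0("c", ci, "-c", cj)]] <-
      list(pair = c(ci, cj), intraL = intraL, inter = inter,
           intraR = intraR, kw = kw,
           medians = c(intraL = median(intraL), inter = median(inter),
                       intraR = median(intraR)))
  }
  out
}
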