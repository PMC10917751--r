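#' Convert binding affinity to probability
#'
#' Transforms an IC50-style binding affinity in nM to the standard
#' probability scale used by MHC predictors,
#' \deqn{p_{BA} = 1 - \log_{50000}(BA),}
#' clamped to [0, 1] for affinities outside [1, 50000] nM. The logarithm is
#' computed base-independently as \code{log(ba)/log(50000)}.
#'
#' @param ba Positive binding affinity values in nM.
#' @return Probabilities in [0, 1], strictly decreasing in \code{ba} before
#'   clamping.
#' @examples
#' baToProbability(c(1, sqrt(50000), 50000))
#' @export
baToProbability <- function(ba) {
  ba <- as.numeric(ba)
  if (anyNA(ba) || any(ba <= 0))
    stop("binding affinity must be positive")
  pmin(1, pmax(0, 1 - log(ba) / log(50000)))
}

# sum over positions of log2(pssm/q) for each peptide
.pssmScores <- function(pssm, peptides) {
  s <- logOdds(pssm, base = 2)
  idx <- .pepIndex(peptides)
  L <- pssmLength(pssm)
  vapply(seq_len(nrow(idx)), function(i) {
    sum(s[cbind(seq_len(L), idx[i, ])])
  }, 1.0)
}

#' Per-position log-odds of a peptide under a PSSM
#'
#' Utility for analytical oracles: the additive score decomposition
#' \eqn{s_p(x_p) = \log_2(\mathrm{PSSM}[p, x_p] / q[x_p])}.
#'
#' @param pssm A \linkS4class{PSSM}.
#' @param peptide A single peptide of the PSSM's length.
#' @return Numeric length-L vector of per-position log2 odds.
#' @export
perPositionLogOdds <- function(pssm, peptide) {
  stopifnot(is(pssm, "PSSM"), length(peptide) == 1L)
  .assertPeptides(peptide, len = pssmLength(pssm))
  s <- logOdds(pssm, base = 2)
  idx <- .pepIndex(peptide)[1L, ]
  setNames(s[cbind(seq_along(idx), idx)], paste0("P", seq_along(idx)))
}

#' Surrogate PSSM predictor
#'
#' Builds a deterministic black-box stand-in for a trained MHC class I
#' predictor: the peptide's summed log2-odds score under a per-allele PSSM
#' is mapped to a probability. With \code{link = "logistic"},
#' \eqn{f(x) = \mathrm{logistic}(a \cdot \mathrm{score}(x) + b)}; with
#' \code{link = "linear"} the score is mapped affinely, making \eqn{f}
#' exactly additive over positions (useful for analytical attribution
#' oracles).
#'
#' Default calibration (logistic): \eqn{a, b} are chosen so the motif
#' consensus peptide maps to probability 0.95 and the expected background
#' score maps to 0.05. Default calibration (linear): the attainable score
#' range maps onto [0.01, 0.99], so outputs never need clamping and
#' additivity is exact.
#'
#' @param pssms A single \linkS4class{PSSM}, or a named list of PSSMs keyed
#'   by allele name.
#' @param allele Allele name(s) the predictor serves when \code{pssms} is a
#'   single PSSM; \code{NULL} means the predictor accepts any allele.
#' @param a,b Optional calibration slope/intercept (slope must be > 0);
#'   when \code{NULL} the defaults above are used (per allele).
#' @param link \code{"logistic"} (default) or \code{"linear"}.
#' @param id Predictor identifier.
#' @return A \linkS4class{PredictorHandle}.
#' @export
makePssmPredictor <- function(pssms, allele = NULL, a = NULL, b = NULL,
                              link = c("logistic", "linear"),
                              id = "pssm_surrogate") {
  link <- match.arg(link)
  if (is(pssms, "PSSM")) {
    anyAllele <- is.null(allele)
    key <- if (anyAllele) ".any" else canonicalAllele(allele)[1L]
    pssms <- setNames(list(pssms), key)
  } else {
    stopifnot(is.list(pssms), !is.null(names(pssms)),
              all(vapply(pssms, is, TRUE, "PSSM")))
    names(pssms) <- canonicalAllele(names(pssms))
    anyAllele <- FALSE
  }
  if (!is.null(a) && any(a <= 0))
    stop("calibration slope a must be positive")

  calib <- lapply(pssms, function(pssm) {
    s <- logOdds(pssm, base = 2)
    q <- pssmBackground(pssm)
    if (!is.null(a) && !is.null(b)) return(list(a = a, b = b))
    if (link == "logistic") {
      sCons <- sum(apply(s, 1L, max))
      sBg <- sum(s %*% q)
      slope <- (qlogis(0.95) - qlogis(0.05)) / (sCons - sBg)
      list(a = slope, b = qlogis(0.95) - slope * sCons)
    } else {
      sMin <- sum(apply(s, 1L, min))
      sMax <- sum(apply(s, 1L, max))
      slope <- (0.99 - 0.01) / (sMax - sMin)
      list(a = slope, b = 0.01 - slope * sMin)
    }
  })
  L <- pssmLength(pssms[[1L]])

  fun <- function(peptide, allele) {
    key <- if (anyAllele) rep(".any", length(peptide))
           else canonicalAllele(allele)
    unknown <- setdiff(unique(key), names(pssms))
    if (length(unknown))
      stop("allele unknown to surrogate predictor: ",
           paste(unknown, collapse = ", "))
    out <- numeric(length(peptide))
    for (k in unique(key)) {
      sel <- key == k
      sc <- .pssmScores(pssms[[k]], peptide[sel])
      eta <- calib[[k]]$a * sc + calib[[k]]$b
      out[sel] <- if (link == "logistic") plogis(eta)
                  else pmin(1, pmax(0, eta))
    }
    out
  }
  PredictorHandle(id = id, fun = fun, peptideLength = L,
                  alleles = if (anyAllele) character(0) else names(pssms))
}

#' Wrap a predictor to ignore one position
#'
#' Test fixture for the Shapley dummy axiom: the returned handle replaces
#' the residue at \code{position} with a fixed reference residue before
#' scoring, so its output is invariant to that position.
#'
#' @param base A \linkS4class{PredictorHandle}.
#' @param position 1-based position to blank out.
#' @param reference Residue written at that position (default "A").
#' @return A \linkS4class{PredictorHandle}.
#' @export
makeIgnoresPositionPredictor <- function(base, position, reference = "A") {
  stopifnot(is(base, "PredictorHandle"), position >= 1)
  if (base@peptideLength > 0 && position > base@peptideLength)
    stop("position exceeds predictor peptide length")
  fun <- function(peptide, allele) {
    substr(peptide, position, position) <- reference
    base@fun(peptide, allele)
  }
  PredictorHandle(id = paste0(base@id, "_ignores_P", position), fun = fun,
                  peptideLength = base@peptideLength, alleles = base@alleles)
}

#' Wrap a binding-affinity predictor as a probability predictor
#'
#' For predictors whose raw output is a binding affinity in nM, composes
#' the handle with [baToProbability()] so attribution engines always see
#' probabilities.
#'
#' @param base A \linkS4class{PredictorHandle} returning affinities in nM.
#' @return A \linkS4class{PredictorHandle} returning probabilities.
#' @export
wrapBaPredictor <- function(base) {
  stopifnot(is(base, "PredictorHandle"))
  PredictorHandle(id = paste0(base@id, "_pBA"),
                  fun = function(peptide, allele)
                    baToProbability(base@fun(peptide, allele)),
                  peptideLength = base@peptideLength, alleles = base@alleles)
}

#' Batch prediction through a handle
#'
#' Order-preserving evaluation of a batch of (peptide, allele) pairs; the
#' handle's call counter is incremented by the batch size.
#'
#' @param handle A \linkS4class{PredictorHandle}.
#' @param peptide Character vector of peptides.
#' @param allele Character vector of allele names (recycled if scalar).
#' @return Numeric vector of probabilities, one per input pair.
#' @export
predictBatch <- function(handle, peptide, allele) {
  stopifnot(is(handle, "PredictorHandle"))
  if (length(peptide) == 0L) stop("batch must be non-empty")
  .assertPeptides(peptide,
                  len = if (handle@peptideLength > 0) handle@peptideLength)
  allele <- canonicalAllele(rep_len(as.character(allele), length(peptide)))
  if (length(handle@alleles)) {
    unknown <- setdiff(unique(allele), handle@alleles)
    if (length(unknown))
      stop("allele unknown to predictor \"", handle@id, "\": ",
           paste(unknown, collapse = ", "))
  }
  out <- handle@fun(peptide, allele)
  if (length(out) != length(peptide) || any(is.na(out)) ||
      any(out < 0) || any(out > 1))
    stop("predictor \"", handle@id,
         "\" violated its contract (length or [0,1] range)")
  handle@env$calls <- handle@env$calls + length(peptide)
  out
}

#' Summarize peptides into a weighted background set
#'
#' Reduces a peptide collection to k representatives by k-medoids (PAM)
#' over Hamming distance, with weights proportional to the number of
#' peptides (counting duplicates) assigned to each medoid. Medoids are
#' actual input peptides, so masked positions can always be filled with
#' real residues. The procedure is deterministic; \code{seed} is accepted
#' for interface uniformity.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param k Number of representatives, between 1 and the number of
#'   distinct peptides.
#' @param seed Unused (PAM is deterministic); kept for API symmetry.
#' @return A \linkS4class{BackgroundSet}.
#' @export
summarizeBackground <- function(peptides, k, seed = 1L) {
  .assertPeptides(peptides)
  .assertPeptides(peptides, len = nchar(peptides[1L]))
  distinct <- unique(peptides)
  mult <- as.numeric(table(factor(peptides, levels = distinct)))
  if (k < 1 || k > length(distinct))
    stop("k must be between 1 and the number of distinct peptides (",
         length(distinct), ")")
  if (k == length(distinct))
    return(BackgroundSet(distinct, mult))
  D <- .hammingMatrix(distinct)
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  reps <- distinct[fit$id.med]
  w <- vapply(seq_len(k), function(ci) sum(mult[fit$clustering == ci]), 1.0)
  BackgroundSet(reps, w)
}
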