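#' ExplainContext: everything needed to explain one prediction
#'
#' Bundles the instance (peptide, allele), the black-box predictor, the
#' background set used to fill masked positions, and the seed from which
#' all engine randomness flows.
#'
#' @slot peptide The peptide to explain.
#' @slot allele Allele name of the instance.
#' @slot predictor A \linkS4class{PredictorHandle}.
#' @slot background A \linkS4class{BackgroundSet} of peptides matching the
#'   explained peptide's length.
#' @slot seed Integer RNG seed for the stochastic engines.
#' @export
setClass("ExplainContext",
  representation(peptide = "character", allele = "character",
                 predictor = "PredictorHandle",
                 background = "BackgroundSet", seed = "integer"))

setValidity("ExplainContext", function(object) {
  msg <- character(0)
  if (nchar(object@peptide) !=
      nchar(object@background@peptides[1L]))
    msg <- c(msg, "background peptide length must equal peptide length")
  if (object@predictor@peptideLength > 0 &&
      object@predictor@peptideLength != nchar(object@peptide))
    msg <- c(msg, "predictor peptide length does not match peptide")
  if (length(msg)) msg else TRUE
})

#' Construct an ExplainContext
#' @param peptide Peptide to explain.
#' @param allele Allele name.
#' @param predictor A \linkS4class{PredictorHandle}.
#' @param background A \linkS4class{BackgroundSet}.
#' @param seed Integer seed (default 1).
#' @return An \linkS4class{ExplainContext}.
#' @export
explainContext <- function(peptide, allele, predictor, background,
                           seed = 1L) {
  .assertPeptides(peptide)
  new("ExplainContext", peptide = as.character(peptide),
      allele = canonicalAllele(allele), predictor = predictor,
      background = background, seed = as.integer(seed))
}

#' Splice a peptide against a background peptide
#'
#' Position p keeps the original residue where \code{mask[p]} is 1/TRUE and
#' takes the background peptide's residue where it is 0/FALSE. This is the
#' perturbation primitive shared by all three engines.
#'
#' @param peptide Original peptide.
#' @param mask Length-L binary/logical coalition mask.
#' @param backgroundPeptide Peptide supplying residues at masked positions.
#' @return The perturbed peptide string.
#' @examples
#' perturbPeptide("AAAA", c(1, 0, 1, 0), "YYYY")
#' @export
perturbPeptide <- function(peptide, mask, backgroundPeptide) {
  L <- nchar(peptide)
  stopifnot(length(mask) == L, nchar(backgroundPeptide) == L)
  mask <- as.logical(mask)
  pc <- strsplit(peptide, "")[[1L]]
  bc <- strsplit(backgroundPeptide, "")[[1L]]
  paste(ifelse(mask, pc, bc), collapse = "")
}

# Coalition values for a logical mask matrix (m x L): v(S) for each row,
# averaging predictions of the spliced peptide over the weighted background.
.coalitionValues <- function(masks, ctx) {
  pep <- ctx@peptide
  bg <- bgPeptides(ctx@background)
  w <- bgWeights(ctx@background)
  L <- nchar(pep)
  k <- length(bg)
  m <- nrow(masks)
  bgC <- .pepChars(bg)
  Mrep <- masks[rep(seq_len(m), each = k), , drop = FALSE]
  out <- bgC[rep(seq_len(k), times = m), , drop = FALSE]
  orig <- matrix(strsplit(pep, "")[[1L]], nrow(out), L, byrow = TRUE)
  out[Mrep] <- orig[Mrep]
  seqs <- do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
  preds <- predictBatch(ctx@predictor, seqs, ctx@allele)
  colSums(matrix(preds, nrow = k) * w)
}

#' Value of one coalition
#'
#' \eqn{v(S) = \sum_b w_b f(\mathrm{splice}(x, S, b))} over the weighted
#' background set: the expected prediction when the positions outside the
#' coalition are filled from the background. The whole masked pattern is
#' drawn from one background peptide at a time, preserving background
#' residue co-occurrence.
#'
#' @param mask Length-L binary/logical mask (1 = keep original residue).
#' @param ctx An \linkS4class{ExplainContext}.
#' @return Scalar coalition value.
#' @export
coalitionValue <- function(mask, ctx) {
  stopifnot(is(ctx, "ExplainContext"))
  .coalitionValues(matrix(as.logical(mask), nrow = 1L), ctx)
}

.allMasks <- function(L) {
  nS <- 2L^L
  bits <- matrix(FALSE, nS, L)
  for (i in seq_len(L))
    bits[, i] <- bitwAnd(0:(nS - 1L), bitwShiftL(1L, i - 1L)) > 0L
  bits
}

#' Exact Shapley attribution by full enumeration
#'
#' Computes \eqn{\phi_i = \sum_{S \subseteq N\setminus\{i\}}
#' \frac{|S|!\,(L-|S|-1)!}{L!}\,[v(S \cup \{i\}) - v(S)]} over all
#' \eqn{2^L} coalitions. Deterministic; satisfies efficiency
#' (\eqn{\sum\phi = f(x) - v(\emptyset)}), symmetry and the dummy axiom by
#' construction. Guarded to \eqn{L \le 16}.
#'
#' @param ctx An \linkS4class{ExplainContext}.
#' @return An \linkS4class{AttributionVector} with
#'   \code{method = "exact_shapley"} and baseline \eqn{v(\emptyset)}.
#' @export
exactShapley <- function(ctx) {
  stopifnot(is(ctx, "ExplainContext"))
  L <- nchar(ctx@peptide)
  if (L > 16L)
    stop("exact enumeration is limited to L <= 16; use kernelShap()")
  masks <- .allMasks(L)
  v <- .coalitionValues(masks, ctx)
  sizes <- rowSums(masks)
  lf <- lfactorial(0:L)
  wgt <- exp(lf[1:L] + lf[L:1] - lf[L + 1L])  # wgt[s+1], s = 0..L-1
  phi <- numeric(L)
  for (i in seq_len(L)) {
    without <- which(!masks[, i])
    with_i <- without + 2L^(i - 1L)
    phi[i] <- sum(wgt[sizes[without] + 1L] * (v[with_i] - v[without]))
  }
  AttributionVector(phi, ctx@peptide, ctx@allele,
                    predictorId(ctx@predictor), "exact_shapley",
                    seed = ctx@seed, baseline = v[1L])
}

#' Kernel-SHAP configuration
#' @param nEvaluations Coalition-evaluation budget (default 25000); must be
#'   at least \code{2L + 2}. The full and empty coalitions are always
#'   evaluated and the remainder of the budget is spent on sampled proper
#'   coalitions.
#' @param enforceEfficiency Enforce \eqn{\sum\phi = f(x) - v(\emptyset)}
#'   by constraint elimination (default TRUE).
#' @param sampling \code{"sample"} (with replacement, duplicates aggregated
#'   by count) or \code{"enumerate"} (every proper coalition once, weighted
#'   by the Shapley kernel; exact for small L).
#' @return A list of class settings passed to [kernelShap()].
#' @export
shapConfig <- function(nEvaluations = 25000L, enforceEfficiency = TRUE,
                       sampling = c("sample", "enumerate")) {
  list(nEvaluations = as.integer(nEvaluations),
       enforceEfficiency = isTRUE(enforceEfficiency),
       sampling = match.arg(sampling))
}

#' Kernel-SHAP attribution
#'
#' Regression-based Shapley estimate: proper coalitions are sampled in
#' proportion to the Shapley kernel
#' \eqn{\pi(z) = (L-1) / (C(L,|z|)\,|z|\,(L-|z|))}, their values computed
#' via [coalitionValue()] semantics, and the attribution solves the
#' weighted least-squares problem. The infinite kernel weights at
#' \eqn{|z| \in \{0, L\}} are handled by constraint elimination: the
#' intercept is fixed to \eqn{v(\emptyset)} and, when
#' \code{enforceEfficiency} is on, the last coefficient is substituted from
#' \eqn{\sum\phi = f(x) - v(\emptyset)}. Reproducible for a fixed context
#' seed.
#'
#' @param ctx An \linkS4class{ExplainContext}.
#' @param cfg A [shapConfig()] list.
#' @return An \linkS4class{AttributionVector} with
#'   \code{method = "kernel_shap"}.
#' @export
kernelShap <- function(ctx, cfg = shapConfig()) {
  stopifnot(is(ctx, "ExplainContext"))
  L <- nchar(ctx@peptide)
  if (cfg$nEvaluations < 2L * L + 2L)
    stop("nEvaluations must be at least 2L + 2 = ", 2L * L + 2L)

  sizes <- seq_len(L - 1L)
  sizeMass <- (L - 1) / (sizes * (L - sizes))
  sizeMass <- sizeMass / sum(sizeMass)

  if (cfg$sampling == "enumerate") {
    masks <- .allMasks(L)
    proper <- rowSums(masks) > 0 & rowSums(masks) < L
    Z <- masks[proper, , drop = FALSE]
    s <- rowSums(Z)
    wls <- (L - 1) / (choose(L, s) * s * (L - s))
  } else {
    nDraw <- cfg$nEvaluations - 2L
    codes <- .withSeed(ctx@seed, {
      sz <- sample(sizes, nDraw, replace = TRUE, prob = sizeMass)
      vapply(sz, function(s) {
        sum(2^(sample.int(L, s) - 1L))
      }, 1.0)
    })
    tab <- table(codes)
    uniq <- as.numeric(names(tab))
    Z <- t(vapply(uniq, function(code)
      bitwAnd(code, 2^(seq_len(L) - 1L)) > 0, logical(L)))
    wls <- as.numeric(tab)
  }
  if (nrow(Z) < L)
    stop("singular design after deduplication; increase nEvaluations")

  ends <- .coalitionValues(rbind(rep(FALSE, L), rep(TRUE, L)), ctx)
  v0 <- ends[1L]
  fx <- ends[2L]
  v <- .coalitionValues(Z, ctx)
  Zn <- Z * 1

  if (cfg$enforceEfficiency) {
    X <- Zn[, -L, drop = FALSE] - Zn[, L]
    y <- v - v0 - Zn[, L] * (fx - v0)
    A <- t(X) %*% (X * wls)
    qrA <- qr(A)
    if (qrA$rank < L - 1L)
      stop("singular design after deduplication; increase nEvaluations")
    beta <- solve(qrA, t(X) %*% (y * wls))
    phi <- c(beta, (fx - v0) - sum(beta))
  } else {
    X <- cbind(1, Zn)
    A <- t(X) %*% (X * wls)
    qrA <- qr(A)
    if (qrA$rank < L + 1L)
      stop("singular design after deduplication; increase nEvaluations")
    beta <- solve(qrA, t(X) %*% (v * wls))
    phi <- beta[-1L]
  }
  AttributionVector(as.numeric(phi), ctx@peptide, ctx@allele,
                    predictorId(ctx@predictor), "kernel_shap",
                    seed = ctx@seed, baseline = v0)
}

#' LIME configuration
#' @param nSamples Number of perturbed samples (default 25000); at least
#'   L + 2.
#' @param kernelWidth Proximity kernel width \eqn{\sigma}; default
#'   \code{0.75 * sqrt(L)}.
#' @param ridge Ridge penalty \eqn{\alpha} on the coefficients (intercept
#'   unpenalized; default 1).
#' @param substitution How masked positions are filled:
#'   \code{"background_sample"} (one background peptide per sample, drawn
#'   by weight) or \code{"uniform_residue"} (independent uniform residues).
#' @return A list of settings passed to [limeExplain()].
#' @export
limeConfig <- function(nSamples = 25000L, kernelWidth = NULL, ridge = 1.0,
                       substitution = c("background_sample",
                                        "uniform_residue")) {
  list(nSamples = as.integer(nSamples), kernelWidth = kernelWidth,
       ridge = as.numeric(ridge), substitution = match.arg(substitution))
}

#' LIME attribution
#'
#' Draws binary masks with per-position keep probability 0.5, builds
#' perturbed peptides, and fits a proximity-weighted ridge regression of
#' the predictions on the mask bits. Proximity uses the normalized Hamming
#' distance in mask space, \eqn{D(z) = } fraction of masked positions, with
#' weight \eqn{\exp(-D^2/\sigma^2)}. The fitted coefficients are the
#' attribution values. Reproducible for a fixed context seed.
#'
#' @param ctx An \linkS4class{ExplainContext}.
#' @param cfg A [limeConfig()] list.
#' @return An \linkS4class{AttributionVector} with \code{method = "lime"}.
#'   If the predictor returns identical values for all samples, a zero
#'   vector with a warning (uninformative instance).
#' @export
limeExplain <- function(ctx, cfg = limeConfig()) {
  stopifnot(is(ctx, "ExplainContext"))
  L <- nchar(ctx@peptide)
  n <- cfg$nSamples
  if (n < L + 2L) stop("nSamples must be at least L + 2 = ", L + 2L)
  sigma <- if (is.null(cfg$kernelWidth)) 0.75 * sqrt(L) else cfg$kernelWidth
  bg <- bgPeptides(ctx@background)
  wbg <- bgWeights(ctx@background)
  bgC <- .pepChars(bg)
  pepC <- strsplit(ctx@peptide, "")[[1L]]

  sampled <- .withSeed(ctx@seed, {
    masks <- matrix(runif(n * L) < 0.5, n, L)
    fill <- if (cfg$substitution == "background_sample") {
      bi <- sample.int(length(bg), n, replace = TRUE, prob = wbg)
      bgC[bi, , drop = FALSE]
    } else {
      matrix(sample(AA_ALPHABET, n * L, replace = TRUE), n, L)
    }
    list(masks = masks, fill = fill)
  })
  masks <- sampled$masks
  out <- sampled$fill
  orig <- matrix(pepC, n, L, byrow = TRUE)
  out[masks] <- orig[masks]
  seqs <- do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
  preds <- predictBatch(ctx@predictor, seqs, ctx@allele)
  v0 <- .coalitionValues(matrix(rep(FALSE, L), 1L), ctx)

  if (max(preds) - min(preds) == 0) {
    warning("predictor output is constant over all perturbations; ",
            "returning a zero attribution")
    return(AttributionVector(rep(0, L), ctx@peptide, ctx@allele,
                             predictorId(ctx@predictor), "lime",
                             seed = ctx@seed, baseline = v0))
  }
  D <- rowMeans(!masks)
  wts <- exp(-D^2 / sigma^2)
  X1 <- cbind(1, masks * 1)
  A <- t(X1) %*% (X1 * wts) + diag(c(0, rep(cfg$ridge, L)))
  beta <- solve(A, t(X1) %*% (preds * wts))
  AttributionVector(as.numeric(beta[-1L]), ctx@peptide, ctx@allele,
                    predictorId(ctx@predictor), "lime",
                    seed = ctx@seed, baseline = v0)
}

#' Explain one prediction with a chosen engine
#'
#' Dispatch front-end over [exactShapley()], [kernelShap()] and
#' [limeExplain()]; provenance (method, seed, predictor id) is stamped on
#' the result.
#'
#' @param method One of \code{"exact_shapley"}, \code{"kernel_shap"},
#'   \code{"lime"}.
#' @param ctx An \linkS4class{ExplainContext}.
#' @param cfg Optional [shapConfig()] / [limeConfig()] for the stochastic
#'   engines.
#' @return An \linkS4class{AttributionVector}.
#' @export
explainPeptide <- function(method, ctx, cfg = NULL) {
  switch(match.arg(method, .ATTR_METHODS),
    exact_shapley = exactShapley(ctx),
    kernel_shap = kernelShap(ctx, if (is.null(cfg)) shapConfig() else cfg),
    lime = limeExplain(ctx, if (is.null(cfg)) limeConfig() else cfg))
}
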