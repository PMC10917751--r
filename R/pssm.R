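#' Build a PSSM from aligned peptides
#'
#' Per-position residue frequencies with Laplace-style pseudocounts
#' distributed according to the background:
#' \deqn{P_{p,a} = (n_{p,a} + c \, q_a) / (n + c)}
#' where \eqn{n_{p,a}} counts residue \eqn{a} at position \eqn{p}, \eqn{n}
#' is the number of peptides and \eqn{c} the pseudocount.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param pseudocount Non-negative pseudocount \eqn{c} (default 1).
#' @param background Length-20 background probability vector \eqn{q}
#'   (default uniform).
#' @return A \linkS4class{PSSM} in probability form.
#' @examples
#' pssmProb(pssmFromPeptides(c("AAA", "AYA"), pseudocount = 0))
#' @export
pssmFromPeptides <- function(peptides, pseudocount = 1,
                             background = uniformBackground()) {
  if (length(peptides) == 0L) stop("cannot build a PSSM from zero peptides")
  .assertPeptides(peptides)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  L <- nchar(peptides[1L])
  .assertPeptides(peptides, len = L)
  idx <- .pepIndex(peptides)
  n <- length(peptides)
  counts <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  for (p in seq_len(L))
    counts[p, ] <- tabulate(idx[, p], nbins = 20L)
  prob <- sweep(counts, 2L, pseudocount * background, "+") / (n + pseudocount)
  PSSM(prob, pseudocount = pseudocount, background = background)
}

#' Sample peptides from a PSSM
#'
#' Each peptide is drawn position-independently from the PSSM's per-position
#' residue distributions; reproducible for a fixed seed.
#'
#' @param pssm A \linkS4class{PSSM}.
#' @param n Number of peptides to draw.
#' @param seed Integer RNG seed.
#' @return Character vector of n peptides.
#' @export
samplePeptidesFromPssm <- function(pssm, n, seed = 1L) {
  stopifnot(is(pssm, "PSSM"), n >= 1)
  prob <- pssmProb(pssm)
  if (any(rowSums(prob) == 0))
    stop("degenerate PSSM column: a position has zero total probability")
  L <- nrow(prob)
  .withSeed(seed, {
    chars <- vapply(seq_len(L), function(p) {
      sample(AA_ALPHABET, n, replace = TRUE, prob = prob[p, ])
    }, character(n))
    if (n == 1L) chars <- matrix(chars, nrow = 1L)
    apply(chars, 1L, paste, collapse = "")
  })
}

#' Fraction of binders per allele
#'
#' @param dataset A labelled \linkS4class{PeptideSet}.
#' @return data.frame with columns allele, n_binders, n_total, fraction
#'   (fraction in [0, 1]), one row per allele.
#' @export
percentBinders <- function(dataset) {
  stopifnot(is(dataset, "PeptideSet"))
  if (anyNA(pepLabels(dataset)))
    stop("percentBinders requires every record to be labelled")
  df <- as.data.frame(dataset)
  agg <- aggregate(label ~ allele, df,
                   function(x) c(nb = sum(x == 1L), nt = length(x)))
  out <- data.frame(allele = agg$allele,
                    n_binders = agg$label[, "nb"],
                    n_total = agg$label[, "nt"],
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_binders / out$n_total
  out[order(out$allele), , drop = FALSE]
}
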