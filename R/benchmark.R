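#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation with midrank tie handling:
#' \eqn{\mathrm{AUROC} = (\bar R_1 - (n_1 + 1)/2) / n_0} where
#' \eqn{\bar R_1} is the mean midrank of the positive scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive), both classes present.
#' @return AUROC in [0, 1]; ties give 0.5.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (mean(r[labels == 1L]) - (n1 + 1) / 2) / n0
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision without interpolation: records are sorted
#' by descending score (ties broken by stable input order) and AP is the
#' mean, over positives, of the precision at that positive's rank. The
#' stable tie order makes the value deterministic; no tie-group
#' interpolation is applied.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive); at least one positive.
#' @return Average precision in (0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  if (sum(labels == 1L) == 0L)
    stop("at least one positive is required to compute AUPRC")
  ord <- order(-scores)            # stable: ties keep input order
  lab <- labels[ord]
  cumPos <- cumsum(lab)
  prec <- cumPos / seq_along(lab)
  mean(prec[lab == 1L])
}

#' Per-allele benchmark metrics
#'
#' AUROC and AUPRC per allele and predictor, mirroring per-allele
#' benchmarking of MHC class I predictors. Alleles represented by a single
#' class are excluded with a warning (their metrics are undefined).
#'
#' @param dataset A labelled \linkS4class{PeptideSet}.
#' @param predictions Named list, one numeric score vector per predictor,
#'   each aligned with the dataset records.
#' @return data.frame with columns allele, predictor, auroc, auprc,
#'   n_binders, n_total.
#' @export
perAlleleMetrics <- function(dataset, predictions) {
  stopifnot(is(dataset, "PeptideSet"), is.list(predictions),
            !is.null(names(predictions)))
  labels <- pepLabels(dataset)
  if (anyNA(labels)) stop("dataset must be fully labelled")
  bad <- names(predictions)[vapply(predictions, function(p)
    length(p) != length(dataset) || anyNA(p), TRUE)]
  if (length(bad))
    stop("missing or misaligned predictions for predictor(s): ",
         paste(bad, collapse = ", "))
  alleles <- pepAlleles(dataset)
  out <- list()
  for (al in unique(alleles)) {
    sel <- alleles == al
    if (length(unique(labels[sel])) < 2L) {
      warning("allele ", al, " has a single class; excluded from metrics")
      next
    }
    for (pid in names(predictions)) {
      sc <- predictions[[pid]][sel]
      out[[length(out) + 1L]] <- data.frame(
        allele = al, predictor = pid,
        auroc = auroc(sc, labels[sel]), auprc = auprc(sc, labels[sel]),
        n_binders = sum(labels[sel] == 1L), n_total = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no allele with both classes present")
  do.call(rbind, out)
}

#' Top-performer counts per predictor
#'
#' For each allele and each metric, credits the predictor(s) achieving the
#' maximum value; exact ties credit all tied predictors.
#'
#' @param table A data.frame from [perAlleleMetrics()] (complete for all
#'   allele x predictor cells).
#' @return data.frame with columns predictor, metric, n_top.
#' @export
topPerformerCounts <- function(table) {
  stopifnot(all(c("allele", "predictor", "auroc", "auprc") %in%
                  names(table)))
  preds <- unique(table$predictor)
  counts <- matrix(0L, length(preds), 2L,
                   dimnames = list(preds, c("auroc", "auprc")))
  for (al in unique(table$allele)) {
    sub <- table[table$allele == al, , drop = FALSE]
    if (!setequal(sub$predictor, preds))
      stop("table is incomplete for allele ", al)
    for (metric in c("auroc", "auprc")) {
      best <- sub$predictor[sub[[metric]] == max(sub[[metric]])]
      counts[best, metric] <- counts[best, metric] + 1L
    }
  }
  data.frame(predictor = rep(preds, 2L),
             metric = rep(c("auroc", "auprc"), each = length(preds)),
             n_top = c(counts[, "auroc"], counts[, "auprc"]),
             stringsAsFactors = FALSE)
}
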