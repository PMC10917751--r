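#' Benchmark-style dataset curation
#'
#' Applies, in order, the four filters used to assemble a fair evaluation
#' set from labelled candidate tables:
#' \enumerate{
#'   \item keep only peptides of the given length;
#'   \item drop any (peptide, allele) pair present in any predictor's
#'     training set;
#'   \item after collapsing identical (peptide, allele, label) duplicates
#'     (first occurrence wins), drop pairs that appear with both labels;
#'   \item drop every record of an allele whose surviving records contain a
#'     single class only.
#' }
#' Counts removed per filter are recorded in the result's metadata under
#' \code{curation}. The operation is idempotent.
#'
#' @param candidates A \linkS4class{PeptideSet} or list of them (all
#'   labelled).
#' @param trainingSets Named list (one element per predictor) of
#'   data.frames/\linkS4class{PeptideSet}s with peptide and allele columns;
#'   pairs found in any of them are excluded.
#' @param length Required peptide length (default 9).
#' @param name Name of the curated dataset.
#' @return A curated \linkS4class{PeptideSet}; metadata field
#'   \code{curation} holds the per-filter removal counts.
#' @export
curateBenchmark <- function(candidates, trainingSets = list(), length = 9L,
                            name = "curated_benchmark") {
  if (is(candidates, "PeptideSet")) candidates <- list(candidates)
  dfs <- lapply(candidates, function(x) {
    stopifnot(is(x, "PeptideSet"))
    as.data.frame(x)
  })
  df <- do.call(rbind, dfs)
  if (anyNA(df$label))
    stop("curation requires labelled candidate records")
  n0 <- nrow(df)

  keep <- nchar(df$peptide) == length
  removedLength <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  trainKeys <- unlist(lapply(trainingSets, function(ts) {
    tdf <- if (is(ts, "PeptideSet")) as.data.frame(ts) else as.data.frame(ts)
    paste(tdf$peptide, canonicalAllele(tdf$allele), sep = "|")
  }), use.names = FALSE)
  pairKey <- paste(df$peptide, df$allele, sep = "|")
  keep <- !(pairKey %in% trainKeys)
  removedTraining <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  pairKey <- pairKey[keep]

  # collapse exact (peptide, allele, label) duplicates before conflict check
  recKey <- paste(pairKey, df$label, sep = "|")
  keep <- !duplicated(recKey)
  removedDuplicate <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  pairKey <- pairKey[keep]

  nLabels <- vapply(split(df$label, pairKey), function(x) length(unique(x)), 1L)
  conflicted <- names(nLabels)[nLabels > 1L]
  keep <- !(pairKey %in% conflicted)
  removedConflict <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  classes <- vapply(split(df$label, df$allele),
                    function(x) length(unique(x)), 1L)
  singleClass <- names(classes)[classes < 2L]
  keep <- !(df$allele %in% singleClass)
  removedSingleClass <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  if (nrow(df) == 0L)
    warning("curation removed every record")
  PeptideSet(df$peptide, df$allele, label = df$label, score = df$score,
             name = name,
             metadata = list(curation = list(
               input = n0,
               removed_length = removedLength,
               removed_training_overlap = removedTraining,
               removed_duplicate = removedDuplicate,
               removed_conflicting_label = removedConflict,
               removed_single_class_allele = removedSingleClass,
               surviving = nrow(df))))
}
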