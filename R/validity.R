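#' Classify residues from a ddG profile
#'
#' Applies the alanine-scanning thresholds: a position is \code{hot}
#' (important for binding) if ddG >= 4.184 kJ/mol, \code{enhancing}
#' (alanine improves binding) if ddG <= -4.184 kJ/mol, and \code{neutral}
#' otherwise. Boundaries are inclusive. 4.184 kJ/mol is 1 kcal/mol.
#'
#' @param profile A \linkS4class{DdgProfile}.
#' @param threshold Threshold in kJ/mol (default 4.184).
#' @return Factor of length L with levels hot, neutral, enhancing.
#' @export
classifyResidues <- function(profile, threshold = 4.184) {
  stopifnot(is(profile, "DdgProfile"))
  v <- profile@values
  cls <- ifelse(v >= threshold, "hot",
                ifelse(v <= -threshold, "enhancing", "neutral"))
  factor(setNames(cls, paste0("P", seq_along(v))),
         levels = c("hot", "neutral", "enhancing"))
}

#' Pearson correlation of an explanation with its ddG profile
#'
#' The headline validity statistic: standard Pearson correlation over the
#' L paired per-position values. Errors (rather than returning 0) when
#' either side is constant, since the correlation is then undefined.
#'
#' @param attr An \linkS4class{AttributionVector}.
#' @param profile The matching \linkS4class{DdgProfile} (same peptide).
#' @return Scalar Pearson r.
#' @export
validityCorrelation <- function(attr, profile) {
  stopifnot(is(attr, "AttributionVector"), is(profile, "DdgProfile"))
  if (attr@peptide != profile@wildtype)
    stop("attribution and ddG profile refer to different peptides")
  if (length(attr@values) != length(profile@values))
    stop("length mismatch between attribution and ddG profile")
  .pearson(attr@values, profile@values)
}

#' Validity report across predictors and methods
#'
#' For every explanation with a matching ddG profile (joined on peptide and
#' canonical allele), computes the per-instance Pearson correlation, then
#' summarizes per predictor x method: median r, fraction positive, and a
#' sensitivity column where positions whose wild-type residue already is
#' alanine are excluded before correlating (ddG is conceptually undefined
#' there, since the mutation is a no-op).
#'
#' @param attrs An \linkS4class{AttributionSet} (or list of
#'   \linkS4class{AttributionVector}).
#' @param profiles List of \linkS4class{DdgProfile}s, as returned by
#'   [readDdgTable()] or [makeSyntheticStudy()].
#' @return List with \code{records} (per-instance data.frame: peptide,
#'   allele, predictor, method, r, r_excl_ala, n_ala_positions) and
#'   \code{summary} (per predictor x method: n, median_r,
#'   fraction_positive, median_r_excl_ala).
#' @export
validityReport <- function(attrs, profiles) {
  aset <- bindAttributions(attrs)
  if (length(aset) == 0L) stop("no attributions supplied")
  profKey <- vapply(profiles, function(p)
    paste(p@wildtype, p@allele, sep = "|"), "")
  meta <- attrMeta(aset)
  key <- paste(meta$peptide, meta$allele, sep = "|")
  hit <- match(key, profKey)
  if (all(is.na(hit)))
    stop("no attribution matches any ddG profile")

  rows <- lapply(which(!is.na(hit)), function(i) {
    prof <- profiles[[hit[i]]]
    vals <- attrValues(aset)[i, ]
    wtA <- strsplit(prof@wildtype, "")[[1L]] == "A"
    r <- tryCatch(.pearson(vals, prof@values), error = function(e) NA_real_)
    rEx <- if (sum(!wtA) >= 3L)
      tryCatch(.pearson(vals[!wtA], prof@values[!wtA]),
               error = function(e) NA_real_)
    else NA_real_
    data.frame(peptide = meta$peptide[i], allele = meta$allele[i],
               predictor = meta$predictor[i], method = meta$method[i],
               r = r, r_excl_ala = rEx, n_ala_positions = sum(wtA),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  grp <- interaction(records$predictor, records$method, drop = TRUE)
  summ <- do.call(rbind, lapply(split(records, grp), function(g) {
    data.frame(predictor = g$predictor[1L], method = g$method[1L],
               n = nrow(g), median_r = median(g$r, na.rm = TRUE),
               fraction_positive = mean(g$r > 0, na.rm = TRUE),
               median_r_excl_ala = median(g$r_excl_ala, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}
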