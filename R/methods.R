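#' Accessors for PeptideSet
#'
#' @param x A \linkS4class{PeptideSet}.
#' @return \code{pepSeqs}, \code{pepAlleles}: character vectors;
#'   \code{pepLabels}: integer vector (1 binder / 0 non-binder / NA);
#'   \code{pepScores}: numeric vector; \code{datasetName}: scalar character;
#'   \code{datasetMetadata}: list.
#' @name PeptideSet-accessors
NULL

#' @rdname PeptideSet-accessors
setMethod("pepSeqs", "PeptideSet", function(x) x@peptide)
#' @rdname PeptideSet-accessors
setMethod("pepAlleles", "PeptideSet", function(x) x@allele)
#' @rdname PeptideSet-accessors
setMethod("pepLabels", "PeptideSet", function(x) x@label)
#' @rdname PeptideSet-accessors
setMethod("pepScores", "PeptideSet", function(x) x@score)
#' @rdname PeptideSet-accessors
setMethod("datasetName", "PeptideSet", function(x) x@name)
#' @rdname PeptideSet-accessors
setMethod("datasetMetadata", "PeptideSet", function(x) x@metadata)

#' @describeIn PeptideSet-accessors number of records
#' @export
setMethod("length", "PeptideSet", function(x) length(x@peptide))

#' Subset a PeptideSet
#' @param x A \linkS4class{PeptideSet}.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @return A \linkS4class{PeptideSet} with the selected records.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, peptide = x@peptide[i], allele = x@allele[i],
             label = x@label[i], score = x@score[i])
})

#' Coerce a PeptideSet to data.frame
#' @param x A \linkS4class{PeptideSet}.
#' @param ... Ignored.
#' @return data.frame with columns peptide, allele, label, score.
#' @export
setMethod("as.data.frame", "PeptideSet", function(x, ...) {
  data.frame(peptide = x@peptide, allele = x@allele, label = x@label,
             score = x@score, stringsAsFactors = FALSE)
})

setMethod("show", "PeptideSet", function(object) {
  nlab <- sum(!is.na(object@label))
  cat("PeptideSet \"", object@name, "\": ", length(object), " records, ",
      length(unique(object@allele)), " allele(s), ", nlab, " labelled",
      if (nlab) sprintf(" (%d binders)", sum(object@label == 1L, na.rm = TRUE)),
      "\n", sep = "")
  if (length(object))
    print(head(as.data.frame(object), 4L))
})

#' Accessors for PSSM
#'
#' @param x A \linkS4class{PSSM}.
#' @param base Logarithm base for \code{logOdds} (default 2, i.e. bits).
#' @return \code{pssmProb}: L x 20 probability matrix; \code{pssmBackground}:
#'   length-20 vector; \code{pssmLength}: integer L; \code{logOdds}: L x 20
#'   matrix of log(p/q); \code{consensusPeptide}: modal peptide string.
#' @name PSSM-accessors
NULL

#' @rdname PSSM-accessors
setMethod("pssmProb", "PSSM", function(x) x@prob)
#' @rdname PSSM-accessors
setMethod("pssmBackground", "PSSM", function(x) x@background)
#' @rdname PSSM-accessors
setMethod("pssmLength", "PSSM", function(x) nrow(x@prob))
#' @rdname PSSM-accessors
setMethod("logOdds", "PSSM", function(x, base = 2) {
  log(sweep(x@prob, 2L, x@background, "/"), base = base)
})
#' @rdname PSSM-accessors
setMethod("consensusPeptide", "PSSM", function(x) {
  paste(AA_ALPHABET[apply(x@prob, 1L, which.max)], collapse = "")
})

setMethod("show", "PSSM", function(object) {
  cat("PSSM: L =", nrow(object@prob), ", pseudocount =", object@pseudocount,
      ", consensus", consensusPeptide(object), "\n")
})

#' Accessors for AttributionVector and AttributionSet
#'
#' @param x An \linkS4class{AttributionVector} or
#'   \linkS4class{AttributionSet}.
#' @return \code{attrValues}: numeric vector (single) or n x L matrix (set);
#'   \code{attrMeta}: one-row / n-row data.frame of provenance;
#'   \code{attrBaseline}: numeric baseline value(s) v(empty).
#' @name AttributionVector-accessors
NULL

#' @rdname AttributionVector-accessors
setMethod("attrValues", "AttributionVector", function(x) {
  setNames(x@values, paste0("P", seq_along(x@values)))
})
#' @rdname AttributionVector-accessors
setMethod("attrValues", "AttributionSet", function(x) x@values)
#' @rdname AttributionVector-accessors
setMethod("attrMeta", "AttributionVector", function(x) {
  data.frame(peptide = x@peptide, allele = x@allele,
             predictor = x@predictorId, method = x@method, seed = x@seed,
             baseline = x@baseline, stringsAsFactors = FALSE)
})
#' @rdname AttributionVector-accessors
setMethod("attrMeta", "AttributionSet", function(x) x@meta)
#' @rdname AttributionVector-accessors
setMethod("attrBaseline", "AttributionVector", function(x) x@baseline)
#' @rdname AttributionVector-accessors
setMethod("attrBaseline", "AttributionSet", function(x) x@meta$baseline)

setMethod("show", "AttributionVector", function(object) {
  cat("AttributionVector [", object@method, "] ", object@peptide, " / ",
      object@allele, " / ", object@predictorId, "\n", sep = "")
  print(round(attrValues(object), 4L))
})

#' @describeIn AttributionVector-accessors number of explanations in a set
#' @export
setMethod("length", "AttributionSet", function(x) nrow(x@values))

setMethod("show", "AttributionSet", function(object) {
  cat("AttributionSet:", nrow(object@values), "explanations of length",
      ncol(object@values), "\n")
  if (nrow(object@meta)) {
    tab <- table(paste(object@meta$predictor, object@meta$method, sep = "/"))
    cat("  by predictor/method:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' Extract one explanation from an AttributionSet
#' @param x An \linkS4class{AttributionSet}.
#' @param i Row index.
#' @param ... Ignored.
#' @return An \linkS4class{AttributionVector}.
#' @export
setMethod("[[", "AttributionSet", function(x, i, ...) {
  m <- x@meta[i, , drop = FALSE]
  AttributionVector(x@values[i, ], m$peptide, m$allele, m$predictor,
                    m$method, m$seed, m$baseline)
})

#' Combine AttributionVectors into an AttributionSet
#'
#' @param attrs List of \linkS4class{AttributionVector}s (or a single
#'   \linkS4class{AttributionSet}, returned unchanged).
#' @return An \linkS4class{AttributionSet}; errors if lengths differ.
#' @export
bindAttributions <- function(attrs) {
  if (is(attrs, "AttributionSet")) return(attrs)
  if (is(attrs, "AttributionVector")) attrs <- list(attrs)
  stopifnot(length(attrs) > 0, all(vapply(attrs, is, TRUE, "AttributionVector")))
  lens <- vapply(attrs, function(a) length(a@values), 1L)
  if (length(unique(lens)) > 1L)
    stop("attribution vectors must all have the same length")
  vals <- do.call(rbind, lapply(attrs, function(a) a@values))
  colnames(vals) <- paste0("P", seq_len(ncol(vals)))
  meta <- do.call(rbind, lapply(attrs, attrMeta))
  rownames(meta) <- NULL
  new("AttributionSet", values = vals, meta = meta)
}

#' @rdname DdgProfile-class
#' @param x A \linkS4class{DdgProfile}.
setMethod("ddgValues", "DdgProfile", function(x) {
  setNames(x@values, paste0("P", seq_along(x@values)))
})
#' @rdname DdgProfile-class
setMethod("ddgWildtype", "DdgProfile", function(x) x@wildtype)

setMethod("show", "DdgProfile", function(object) {
  cat("DdgProfile ", object@wildtype, " / ", object@allele,
      if (!is.na(object@pdbId)) paste0(" [", object@pdbId, "]"),
      " (kJ/mol)\n", sep = "")
  print(round(ddgValues(object), 3L))
})

#' Accessors for PredictorHandle
#' @param x A \linkS4class{PredictorHandle}.
#' @return \code{predictorId}: identifier; \code{callCount}: model
#'   evaluations spent so far; \code{resetCallCount}: resets to 0,
#'   invisibly returns the handle.
#' @name PredictorHandle-accessors
NULL

#' @rdname PredictorHandle-accessors
setMethod("predictorId", "PredictorHandle", function(x) x@id)
#' @rdname PredictorHandle-accessors
setMethod("callCount", "PredictorHandle", function(x) x@env$calls)
#' @rdname PredictorHandle-accessors
setMethod("resetCallCount", "PredictorHandle", function(x) {
  x@env$calls <- 0
  invisible(x)
})

setMethod("show", "PredictorHandle", function(object) {
  cat("PredictorHandle \"", object@id, "\" (L=",
      if (object@peptideLength) object@peptideLength else "any",
      ", alleles: ",
      if (length(object@alleles)) paste(object@alleles, collapse = ", ")
      else "any",
      "), ", object@env$calls, " evaluations\n", sep = "")
})

#' Accessors for BackgroundSet
#' @param x A \linkS4class{BackgroundSet}.
#' @return \code{bgPeptides}: character vector; \code{bgWeights}: numeric
#'   weights summing to 1.
#' @name BackgroundSet-accessors
NULL

#' @rdname BackgroundSet-accessors
setMethod("bgPeptides", "BackgroundSet", function(x) x@peptides)
#' @rdname BackgroundSet-accessors
setMethod("bgWeights", "BackgroundSet", function(x) x@weights)

#' @describeIn BackgroundSet-accessors number of representatives
#' @export
setMethod("length", "BackgroundSet", function(x) length(x@peptides))

setMethod("show", "BackgroundSet", function(object) {
  cat("BackgroundSet:", length(object@peptides), "weighted peptides\n")
})

#' Accessors for ClusterAssignment
#' @param x A \linkS4class{ClusterAssignment}.
#' @return \code{clusterLabels}: integer labels named by peptide;
#'   \code{clusterPssms}: list of \linkS4class{PSSM}; \code{averageKld}:
#'   the objective value in bits.
#' @name ClusterAssignment-accessors
NULL

#' @rdname ClusterAssignment-accessors
setMethod("clusterLabels", "ClusterAssignment", function(x) {
  setNames(x@labels, x@peptides)
})
#' @rdname ClusterAssignment-accessors
setMethod("clusterPssms", "ClusterAssignment", function(x) x@pssms)
#' @rdname ClusterAssignment-accessors
setMethod("averageKld", "ClusterAssignment", function(x) x@avgKld)

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment: k =", length(object@pssms),
      ", n =", length(object@peptides),
      ", avg KLD =", round(object@avgKld, 4L), "bits\n")
  print(table(cluster = object@labels))
})
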