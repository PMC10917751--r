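#' PeptideSet: a labelled peptide-allele table
#'
#' Ordered collection of peptide records, each a fixed-length 9-mer-style
#' amino-acid string paired with an HLA allele name and optional binary
#' binder label and predictor score. The central data container of the
#' package, analogous to a benchmark dataset slice.
#'
#' @slot peptide Character vector of peptide sequences.
#' @slot allele Character vector of allele names (canonicalized form).
#' @slot label Integer vector, 1 = binder, 0 = non-binder, NA = unlabelled.
#' @slot score Numeric vector of predictor scores in [0, 1] (NA allowed).
#' @slot name Scalar character dataset name.
#' @slot metadata List of free-form provenance (e.g. curation counts).
#' @export
setClass("PeptideSet",
  representation(peptide = "character", allele = "character",
                 label = "integer", score = "numeric",
                 name = "character", metadata = "list"))

setValidity("PeptideSet", function(object) {
  n <- length(object@peptide)
  msg <- character(0)
  if (length(object@allele) != n || length(object@label) != n ||
      length(object@score) != n)
    msg <- c(msg, "peptide, allele, label and score must have equal length")
  if (n > 0) {
    bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                 object@peptide)
    if (any(bad))
      msg <- c(msg, paste0("invalid residue in peptide(s): ",
                           paste(head(object@peptide[bad], 3), collapse = ", ")))
    if (any(!is.na(object@allele) & !nzchar(object@allele)))
      msg <- c(msg, "allele names must be non-empty")
    sc <- object@score[!is.na(object@score)]
    if (length(sc) && (any(sc < 0) || any(sc > 1)))
      msg <- c(msg, "scores must lie in [0, 1]")
    lb <- object@label[!is.na(object@label)]
    if (length(lb) && !all(lb %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0, 1 or NA")
  }
  if (length(object@name) != 1L) msg <- c(msg, "name must be a scalar")
  if (length(msg)) msg else TRUE
})

.parseLabel <- function(label) {
  if (is.factor(label)) label <- as.character(label)
  if (is.character(label)) {
    out <- rep(NA_integer_, length(label))
    low <- tolower(trimws(label))
    out[low %in% c("1", "binder", "true", "yes")] <- 1L
    out[low %in% c("0", "non-binder", "nonbinder", "false", "no")] <- 0L
    bad <- !is.na(label) & nzchar(trimws(label)) & is.na(out)
    if (any(bad))
      stop("unparseable label value(s): ",
           paste(unique(head(label[bad], 3)), collapse = ", "))
    out
  } else if (is.logical(label)) {
    as.integer(label)
  } else {
    as.integer(label)
  }
}

#' Construct a PeptideSet
#'
#' @param peptide Character vector of peptide sequences.
#' @param allele Character vector (recycled if scalar) of allele names;
#'   canonicalized via [canonicalAllele()].
#' @param label Binder labels: 0/1, logical, or "binder"/"non-binder"
#'   strings; NA for unlabelled.
#' @param score Optional predictor scores in [0, 1].
#' @param name Dataset name.
#' @param metadata Optional provenance list.
#' @return A \linkS4class{PeptideSet}.
#' @examples
#' ps <- PeptideSet(c("LLVEVLREI", "AAAWYLWEV"), "HLA-A*02:01", label = c(1, 0))
#' ps
#' @export
PeptideSet <- function(peptide, allele, label = NA, score = NA_real_,
                       name = "peptide_set", metadata = list()) {
  peptide <- as.character(peptide)
  n <- length(peptide)
  allele <- canonicalAllele(rep_len(as.character(allele), n))
  label <- rep_len(.parseLabel(label), n)
  score <- rep_len(as.numeric(score), n)
  new("PeptideSet", peptide = peptide, allele = allele, label = label,
      score = score, name = as.character(name), metadata = metadata)
}

#' PSSM: position-specific scoring matrix
#'
#' An L x 20 column-stochastic matrix of per-position residue probabilities
#' over [AA_ALPHABET], with the pseudocount used to build it and the
#' background residue distribution against which log-odds are taken. Doubles
#' as a binding motif and as the core of the surrogate predictors.
#'
#' @slot prob L x 20 probability matrix; each row sums to 1.
#' @slot pseudocount Non-negative pseudocount used at construction.
#' @slot background Length-20 background probability vector q.
#' @export
setClass("PSSM",
  representation(prob = "matrix", pseudocount = "numeric",
                 background = "numeric"))

setValidity("PSSM", function(object) {
  msg <- character(0)
  p <- object@prob
  if (ncol(p) != 20L || !identical(colnames(p), AA_ALPHABET))
    msg <- c(msg, "prob must have 20 columns named by AA_ALPHABET")
  if (any(p < 0)) msg <- c(msg, "probabilities must be non-negative")
  if (nrow(p) > 0 && any(abs(rowSums(p) - 1) > 1e-9))
    msg <- c(msg, "each position row must sum to 1 (within 1e-9)")
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be a length-20 probability vector")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be a non-negative scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a PSSM from a probability matrix
#'
#' @param prob L x 20 matrix of per-position residue probabilities (columns
#'   in [AA_ALPHABET] order; column names optional but checked if present).
#' @param pseudocount Pseudocount recorded with the matrix.
#' @param background Length-20 background probability vector.
#' @return A \linkS4class{PSSM}.
#' @export
PSSM <- function(prob, pseudocount = 0, background = uniformBackground()) {
  prob <- as.matrix(prob)
  if (is.null(colnames(prob))) colnames(prob) <- AA_ALPHABET
  rownames(prob) <- paste0("P", seq_len(nrow(prob)))
  background <- setNames(as.numeric(background), AA_ALPHABET)
  new("PSSM", prob = prob, pseudocount = as.numeric(pseudocount),
      background = background)
}

#' AttributionVector: one local explanation
#'
#' A length-L vector of per-position contributions for one
#' (peptide, allele, predictor, method) instance, with full provenance.
#' The sign convention is that a positive value supports the binding class.
#'
#' @slot values Numeric length-L attribution values (phi_1..phi_L).
#' @slot peptide The explained peptide.
#' @slot allele The allele the prediction was made for.
#' @slot predictorId Identifier of the predictor explained.
#' @slot method One of "exact_shapley", "kernel_shap", "lime".
#' @slot seed RNG seed used by the engine.
#' @slot baseline Expected prediction over the background set, v(empty).
#' @export
setClass("AttributionVector",
  representation(values = "numeric", peptide = "character",
                 allele = "character", predictorId = "character",
                 method = "character", seed = "integer",
                 baseline = "numeric"))

.ATTR_METHODS <- c("exact_shapley", "kernel_shap", "lime")

setValidity("AttributionVector", function(object) {
  msg <- character(0)
  if (length(object@values) != nchar(object@peptide))
    msg <- c(msg, "values length must equal peptide length")
  if (!object@method %in% .ATTR_METHODS)
    msg <- c(msg, paste0("method must be one of: ",
                         paste(.ATTR_METHODS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an AttributionVector
#' @param values Numeric attribution values, one per peptide position.
#' @param peptide,allele Instance identity.
#' @param predictorId Predictor identifier string.
#' @param method Attribution method name.
#' @param seed Integer seed used.
#' @param baseline Background-expected prediction v(empty).
#' @return An \linkS4class{AttributionVector}.
#' @export
AttributionVector <- function(values, peptide, allele, predictorId,
                              method, seed = NA_integer_, baseline = NA_real_) {
  new("AttributionVector", values = as.numeric(values),
      peptide = as.character(peptide),
      allele = canonicalAllele(allele),
      predictorId = as.character(predictorId),
      method = as.character(method), seed = as.integer(seed),
      baseline = as.numeric(baseline))
}

#' AttributionSet: a collection of same-length explanations
#'
#' @slot values n x L numeric matrix, one explanation per row, columns
#'   P1..PL.
#' @slot meta data.frame with columns peptide, allele, predictor, method,
#'   seed, baseline (one row per explanation).
#' @export
setClass("AttributionSet",
  representation(values = "matrix", meta = "data.frame"))

setValidity("AttributionSet", function(object) {
  msg <- character(0)
  need <- c("peptide", "allele", "predictor", "method", "seed", "baseline")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste0("meta must contain columns: ",
                         paste(need, collapse = ", ")))
  if (nrow(object@values) != nrow(object@meta))
    msg <- c(msg, "values and meta must have the same number of rows")
  if (nrow(object@meta) > 0 &&
      any(nchar(object@meta$peptide) != ncol(object@values)))
    msg <- c(msg, "all peptides must match the attribution length")
  if (length(msg)) msg else TRUE
})

#' DdgProfile: per-position alanine-scan free-energy differences
#'
#' The validity ground truth: for one bound peptide-MHC complex, the change
#' in binding free energy (kJ/mol) when each peptide position in turn is
#' mutated to alanine. Positive values mark residues whose loss destabilizes
#' binding ("hot" residues at >= 4.184 kJ/mol).
#'
#' @slot values Numeric length-L ddG values in kJ/mol.
#' @slot wildtype The wild-type peptide sequence.
#' @slot allele Allele of the complex.
#' @slot pdbId Optional structure identifier (NA if none).
#' @export
setClass("DdgProfile",
  representation(values = "numeric", wildtype = "character",
                 allele = "character", pdbId = "character"))

setValidity("DdgProfile", function(object) {
  if (length(object@values) != nchar(object@wildtype))
    "values length must equal wildtype peptide length" else TRUE
})

#' Construct a DdgProfile
#' @param values ddG values in kJ/mol, one per position.
#' @param wildtype Wild-type peptide.
#' @param allele Allele name.
#' @param pdbId Optional structure id.
#' @return A \linkS4class{DdgProfile}.
#' @export
DdgProfile <- function(values, wildtype, allele, pdbId = NA_character_) {
  .assertPeptides(wildtype, what = "wildtype peptide")
  new("DdgProfile", values = as.numeric(values),
      wildtype = as.character(wildtype), allele = canonicalAllele(allele),
      pdbId = as.character(pdbId))
}

#' PredictorHandle: opaque batch predictor contract
#'
#' Wraps any function mapping an ordered batch of (peptide, allele) pairs to
#' binding probabilities in [0, 1]. The handle is what the attribution
#' engines see: they treat it as a black box. A call counter tracks the
#' number of model evaluations spent.
#'
#' @slot id Predictor identifier.
#' @slot fun \code{function(peptide, allele) -> numeric} batch scorer.
#' @slot peptideLength Expected peptide length (0 = any).
#' @slot alleles Allele names the predictor knows (character(0) = any).
#' @slot env Environment holding the mutable call counter.
#' @export
setClass("PredictorHandle",
  representation(id = "character", fun = "function",
                 peptideLength = "integer", alleles = "character",
                 env = "environment"))

#' Construct a PredictorHandle
#' @param id Identifier string.
#' @param fun Batch function \code{(peptide, allele) -> numeric} returning
#'   probabilities in [0, 1], deterministic for identical batches.
#' @param peptideLength Expected peptide length (0 to accept any).
#' @param alleles Known allele names (empty = accept any).
#' @return A \linkS4class{PredictorHandle}.
#' @export
PredictorHandle <- function(id, fun, peptideLength = 0L,
                            alleles = character(0)) {
  env <- new.env(parent = emptyenv())
  env$calls <- 0
  new("PredictorHandle", id = as.character(id), fun = fun,
      peptideLength = as.integer(peptideLength),
      alleles = canonicalAllele(alleles), env = env)
}

#' BackgroundSet: weighted reference peptides
#'
#' Summary of a predictor's training distribution used to fill masked
#' positions during perturbation: k representative peptides (medoids) with
#' weights proportional to the number of peptides they represent.
#'
#' @slot peptides Character vector of representative peptides.
#' @slot weights Non-negative weights summing to 1.
#' @export
setClass("BackgroundSet",
  representation(peptides = "character", weights = "numeric"))

setValidity("BackgroundSet", function(object) {
  msg <- character(0)
  if (length(object@peptides) == 0L)
    msg <- c(msg, "background must be non-empty")
  if (length(object@weights) != length(object@peptides))
    msg <- c(msg, "weights must match peptides in length")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must be non-negative and sum to 1")
  if (length(unique(nchar(object@peptides))) > 1L)
    msg <- c(msg, "background peptides must share one length")
  if (length(msg)) msg else TRUE
})

#' Construct a BackgroundSet
#' @param peptides Representative peptides (equal length).
#' @param weights Optional weights (default uniform); normalized to sum 1.
#' @return A \linkS4class{BackgroundSet}.
#' @export
BackgroundSet <- function(peptides, weights = NULL) {
  .assertPeptides(peptides, what = "background peptide")
  if (is.null(weights)) weights <- rep(1, length(peptides))
  weights <- as.numeric(weights) / sum(weights)
  new("BackgroundSet", peptides = as.character(peptides), weights = weights)
}

#' ClusterAssignment: result of Gibbs peptide clustering
#'
#' @slot peptides The clustered peptides, input order preserved.
#' @slot labels Integer cluster index (1..k) per peptide.
#' @slot pssms List of per-cluster \linkS4class{PSSM}s (pseudocounted).
#' @slot avgKld Size-weighted mean per-position Kullback-Leibler distance of
#'   the cluster PSSMs from background, in bits — the clustering objective.
#' @slot kldTrace Numeric avg-KLD value after each sweep (diagnostics).
#' @export
setClass("ClusterAssignment",
  representation(peptides = "character", labels = "integer",
                 pssms = "list", avgKld = "numeric", kldTrace = "numeric"))

setValidity("ClusterAssignment", function(object) {
  msg <- character(0)
  if (length(object@labels) != length(object@peptides))
    msg <- c(msg, "labels must match peptides in length")
  if (length(object@labels) &&
      (any(object@labels < 1L) || any(object@labels > length(object@pssms))))
    msg <- c(msg, "labels must index into pssms")
  if (length(msg)) msg else TRUE
})
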