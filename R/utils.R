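#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter residue codes, alphabetically ordered. All peptides
#' handled by the package are validated against this alphabet, and all PSSM
#' columns are stored in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Uniform residue background
#'
#' @return Named numeric vector of length 20, each entry 1/20.
#' @export
uniformBackground <- function() {
  setNames(rep(1 / 20, 20), AA_ALPHABET)
}

.assertPeptides <- function(x, len = NULL, what = "peptide") {
  if (!is.character(x) || length(x) == 0L || anyNA(x))
    stop(what, "s must be a non-empty character vector without NA")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), x)
  if (any(bad))
    stop("invalid residue character in ", what, "(s): ",
         paste(unique(head(x[bad], 3L)), collapse = ", "))
  if (!is.null(len) && any(nchar(x) != len))
    stop(what, "s must all have length ", len, "; offending: ",
         paste(head(x[nchar(x) != len], 3L), collapse = ", "))
  invisible(x)
}

# n x L character matrix from a vector of equal-length peptides
.pepChars <- function(x) {
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  m
}

# n x L integer matrix of alphabet indices
.pepIndex <- function(x) {
  m <- .pepChars(x)
  matrix(match(m, AA_ALPHABET), nrow = nrow(m))
}

#' Canonicalize HLA allele names
#'
#' Accepts the three spellings in common predictor use --
#' \code{"HLA-A*02:01"}, \code{"HLA-A02:01"} and \code{"HLA-A0201"} -- and
#' rewrites them to the starred, colon-separated nomenclature form. Names
#' that do not match the HLA pattern are returned unchanged.
#'
#' @param x Character vector of allele names.
#' @return Character vector of the same length, canonicalized where possible.
#' @examples
#' canonicalAllele(c("HLA-A*02:01", "HLA-A02:01", "HLA-A0201", "H-2Kb"))
#' @export
canonicalAllele <- function(x) {
  x <- trimws(as.character(x))
  pat <- "^HLA-([A-Z])\\*?([0-9]{2}):?([0-9]{2,3})$"
  hit <- grepl(pat, x)
  x[hit] <- sub(pat, "HLA-\\1*\\2:\\3", x[hit])
  x
}

# Evaluate expr with a private, restored RNG state. All package randomness
# goes through this: no global RNG pollution, full per-call reproducibility.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a stage seed from a global seed and an operation key
#'
#' Deterministic 31-bit hash combining an integer seed with a string key, so
#' each stage of a pipeline receives its own reproducible stream.
#'
#' @param globalSeed Integer global seed.
#' @param key Character scalar naming the operation/stage.
#' @return An integer in \code{[0, 2^31 - 2]}.
#' @export
deriveSeed <- function(globalSeed, key) {
  h <- as.double(globalSeed) %% 2147483647
  for (b in utf8ToInt(as.character(key)))
    h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Pairwise Hamming distance matrix between equal-length peptides
.hammingMatrix <- function(peptides) {
  m <- .pepChars(peptides)
  n <- nrow(m)
  D <- matrix(0L, n, n)
  for (p in seq_len(ncol(m)))
    D <- D + outer(m[, p], m[, p], "!=")
  storage.mode(D) <- "double"
  dimnames(D) <- list(peptides, peptides)
  D
}

.TSV_SCHEMA <- "# pepXplain-tsv schema=1"

# All package writers emit a schema comment line; readers skip '#' lines.
.writeTsv <- function(df, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(.TSV_SCHEMA, con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# full-precision float formatting for lossless round-trips
.fmtFloat <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.pearson <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined correlation: input vector is constant")
  cor(a, b, method = "pearson")
}
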