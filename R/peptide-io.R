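#' Read a peptide-allele table
#'
#' Reads a delimited peptide table (TSV by default, CSV by extension or
#' \code{sep}) with a header. Required columns: peptide and allele; optional
#' columns: label (0/1 or binder/non-binder) and score (in [0, 1]). Column
#' names can be remapped via \code{columns}. A FASTA file of bare peptides
#' (no alleles) can be read with [readPeptideFasta()].
#'
#' @param path Path to the table.
#' @param columns Named character vector mapping the canonical names
#'   (\code{peptide}, \code{allele}, \code{label}, \code{score}) to the
#'   column names used in the file.
#' @param sep Field separator; default inferred from extension
#'   (".csv" = comma, otherwise tab).
#' @param name Dataset name; defaults to the file name.
#' @return A \linkS4class{PeptideSet} preserving the input row order.
#' @export
readPeptideTable <- function(path,
                             columns = c(peptide = "peptide",
                                         allele = "allele",
                                         label = "label",
                                         score = "score"),
                             sep = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  defaults <- c(peptide = "peptide", allele = "allele",
                label = "label", score = "score")
  defaults[names(columns)] <- columns
  columns <- defaults
  for (need in c("peptide", "allele"))
    if (!columns[[need]] %in% names(df))
      stop("column \"", columns[[need]], "\" (", need, ") not found in ", path)
  peptide <- as.character(df[[columns[["peptide"]]]])
  bad <- !nzchar(peptide) | is.na(peptide) |
    grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), peptide)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("invalid residue character in peptide \"", peptide[i],
         "\" (data row ", i, " of ", path, ")")
  }
  allele <- df[[columns[["allele"]]]]
  if (any(is.na(allele) | !nzchar(trimws(allele)))) {
    i <- which(is.na(allele) | !nzchar(trimws(allele)))[1L]
    stop("missing allele name at data row ", i, " of ", path)
  }
  label <- if (columns[["label"]] %in% names(df))
    df[[columns[["label"]]]] else NA
  score <- if (columns[["score"]] %in% names(df))
    as.numeric(df[[columns[["score"]]]]) else NA_real_
  PeptideSet(peptide, allele, label = label, score = score,
             name = if (is.null(name)) basename(path) else name)
}

#' Write a PeptideSet to TSV
#'
#' Inverse of [readPeptideTable()]: writes columns peptide, allele, label,
#' score (score at full float precision) under a schema comment line.
#'
#' @param dataset A \linkS4class{PeptideSet}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePeptideTable <- function(dataset, path) {
  stopifnot(is(dataset, "PeptideSet"))
  df <- as.data.frame(dataset)
  df$score <- .fmtFloat(df$score)
  .writeTsv(df, path)
  invisible(path)
}

#' Read bare peptides from FASTA
#'
#' Sequence IDs are ignored; every record must be a valid amino-acid string.
#'
#' @param path FASTA file path.
#' @return Character vector of peptides.
#' @export
readPeptideFasta <- function(path) {
  seqs <- as.character(Biostrings::readAAStringSet(path))
  names(seqs) <- NULL
  .assertPeptides(seqs)
  seqs
}

#' Write a collection of explanations to TSV
#'
#' Columns: peptide, allele, predictor, method, seed, baseline, P1..PL.
#' Values are written at full float precision so that
#' [readAttributions()] is a bitwise-exact inverse.
#'
#' @param attrs An \linkS4class{AttributionSet}, a single
#'   \linkS4class{AttributionVector}, or a list of them (all same length).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeAttributions <- function(attrs, path) {
  if (is.list(attrs) && !is(attrs, "AttributionSet") && length(attrs) == 0L) {
    df <- data.frame(peptide = character(0), allele = character(0),
                     predictor = character(0), method = character(0),
                     seed = integer(0), baseline = character(0))
    .writeTsv(df, path)
    return(invisible(path))
  }
  aset <- bindAttributions(attrs)
  L <- ncol(attrValues(aset))
  df <- attrMeta(aset)
  df$baseline <- .fmtFloat(df$baseline)
  vals <- attrValues(aset)
  for (p in seq_len(L)) df[[paste0("P", p)]] <- .fmtFloat(vals[, p])
  .writeTsv(df, path)
  invisible(path)
}

#' Read explanations from TSV
#'
#' @param path File written by [writeAttributions()].
#' @return An \linkS4class{AttributionSet} (possibly with zero rows).
#' @export
readAttributions <- function(path) {
  df <- .readTsv(path)
  pcols <- grep("^P[0-9]+$", names(df), value = TRUE)
  pcols <- pcols[order(as.integer(sub("^P", "", pcols)))]
  need <- c("peptide", "allele", "predictor", "method", "seed", "baseline")
  if (!all(need %in% names(df)))
    stop("attribution file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  vals <- as.matrix(df[, pcols, drop = FALSE])
  storage.mode(vals) <- "double"
  meta <- data.frame(peptide = as.character(df$peptide),
                     allele = canonicalAllele(df$allele),
                     predictor = as.character(df$predictor),
                     method = as.character(df$method),
                     seed = as.integer(df$seed),
                     baseline = as.numeric(df$baseline),
                     stringsAsFactors = FALSE)
  if (nrow(vals) == 0L)
    vals <- matrix(numeric(0), 0L, length(pcols),
                   dimnames = list(NULL, pcols))
  new("AttributionSet", values = vals, meta = meta)
}

#' Read a PSSM file
#'
#' TSV with a \code{#type=probability|logodds} header comment, a position
#' column (1..L) and the 20 residue columns in alphabetical order. Log-odds
#' matrices are converted back to probabilities against the background.
#'
#' @param path PSSM file path.
#' @param background Background vector assumed for log-odds files (default
#'   uniform).
#' @return A \linkS4class{PSSM} (probability form).
#' @export
readPssm <- function(path, background = uniformBackground()) {
  lines <- readLines(path)
  typeLine <- grep("^#\\s*type=", lines, value = TRUE)
  type <- if (length(typeLine))
    sub("^#\\s*type=", "", typeLine[1L]) else "probability"
  df <- .readTsv(path)
  if (!"position" %in% names(df)) stop("PSSM file must have a position column")
  df <- df[order(df$position), , drop = FALSE]
  if (!identical(as.integer(df$position), seq_len(nrow(df))))
    stop("PSSM positions must be exactly 1..L")
  if (!all(AA_ALPHABET %in% names(df)))
    stop("PSSM file must have the 20 residue columns")
  mat <- as.matrix(df[, AA_ALPHABET])
  storage.mode(mat) <- "double"
  if (type == "logodds")
    mat <- sweep(2 ^ mat, 2L, background, "*")
  mat <- mat / rowSums(mat)
  PSSM(mat, background = background)
}

#' Write a PSSM file
#'
#' @param pssm A \linkS4class{PSSM}.
#' @param path Output path.
#' @param type \code{"probability"} (default) or \code{"logodds"}
#'   (log2 odds against the PSSM's background).
#' @return The path, invisibly.
#' @export
writePssm <- function(pssm, path, type = c("probability", "logodds")) {
  type <- match.arg(type)
  mat <- if (type == "probability") pssmProb(pssm) else logOdds(pssm)
  df <- data.frame(position = seq_len(nrow(mat)))
  for (a in AA_ALPHABET) df[[a]] <- .fmtFloat(mat[, a])
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(c(.TSV_SCHEMA, paste0("#type=", type)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-position ddG profiles
#'
#' Expects TSV columns allele, peptide, position, wildtype, ddg_kj_mol and
#' optionally pdb_id; one profile is formed per (peptide, allele) group and
#' must cover positions 1..L exactly once each.
#'
#' @param path ddG table path.
#' @return Named list of \linkS4class{DdgProfile}s
#'   (names \code{"peptide|allele"}).
#' @export
readDdgTable <- function(path) {
  df <- .readTsv(path)
  need <- c("allele", "peptide", "position", "wildtype", "ddg_kj_mol")
  if (!all(need %in% names(df)))
    stop("ddG table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$allele <- canonicalAllele(df$allele)
  key <- paste(df$peptide, df$allele, sep = "|")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    L <- nchar(g$peptide[1L])
    if (anyDuplicated(g$position))
      stop("duplicate position for ", g$peptide[1L], "/", g$allele[1L])
    if (!setequal(g$position, seq_len(L)))
      stop("profile for ", g$peptide[1L], "/", g$allele[1L],
           " must cover positions 1..", L, "; missing: ",
           paste(setdiff(seq_len(L), g$position), collapse = ", "))
    g <- g[order(g$position), , drop = FALSE]
    wt <- paste(g$wildtype, collapse = "")
    if (wt != g$peptide[1L])
      stop("wildtype residues disagree with peptide for ", g$peptide[1L])
    DdgProfile(g$ddg_kj_mol, g$peptide[1L], g$allele[1L],
               if ("pdb_id" %in% names(g)) as.character(g$pdb_id[1L])
               else NA_character_)
  })
  out
}

#' Write ddG profiles
#'
#' Inverse of [readDdgTable()].
#'
#' @param profiles List of \linkS4class{DdgProfile}s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeDdgTable <- function(profiles, path) {
  if (is(profiles, "DdgProfile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(pr) {
    L <- length(pr@values)
    data.frame(pdb_id = rep(pr@pdbId, L), allele = pr@allele,
               peptide = pr@wildtype, position = seq_len(L),
               wildtype = strsplit(pr@wildtype, "")[[1L]],
               ddg_kj_mol = .fmtFloat(pr@values), stringsAsFactors = FALSE)
  })
  .writeTsv(do.call(rbind, rows), path)
  invisible(path)
}
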