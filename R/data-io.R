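#' Construct a SequenceSet
#'
#' Normalizes case and maps `U` to `T` before validation, so RNA-alphabet
#' input is accepted.
#'
#' @param ids circRNA identifiers.
#' @param seqs nucleotide sequences, parallel to `ids`.
#' @return a [SequenceSet].
#' @export
SequenceSet <- function(ids, seqs) {
    seqs <- chartr("u", "t", toupper(as.character(seqs)))
    seqs <- chartr("U", "T", seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
        stopTyped("alphabetError",
                  "record '%s' contains characters outside {A,C,G,T,U,N}",
                  ids[bad][1L])
    if (anyDuplicated(ids))
        stopTyped("duplicateIdentifierError", "duplicate identifier '%s'",
                  ids[duplicated(ids)][1L])
    new("SequenceSet", ids = as.character(ids), sequences = seqs)
}

#' Construct a FingerprintSet
#' @param ids drug identifiers.
#' @param bits 0/1 matrix, one row per drug.
#' @return a [FingerprintSet].
#' @export
FingerprintSet <- function(ids, bits) {
    new("FingerprintSet", ids = as.character(ids),
        bits = as.matrix(bits) * 1)
}

#' Construct an AssociationMatrix
#' @param circIds,drugIds identifier vectors.
#' @param values M x N 0/1 matrix.
#' @return an [AssociationMatrix].
#' @export
AssociationMatrix <- function(circIds, drugIds, values) {
    new("AssociationMatrix", circIds = as.character(circIds),
        drugIds = as.character(drugIds), values = as.matrix(values) * 1)
}

#' Construct a SimilarityMatrix
#' @param ids identifiers.
#' @param values n x n symmetric matrix in `[0,1]`.
#' @param source one of `"sequence"`, `"gip"`, `"structure"`, `"fused"`.
#' @return a [SimilarityMatrix].
#' @export
SimilarityMatrix <- function(ids, values, source) {
    v <- as.matrix(values)
    v[v > 1 & v < 1 + 1e-12] <- 1      # clip numerical overshoot only
    v[v < 0 & v > -1e-12] <- 0
    new("SimilarityMatrix", ids = as.character(ids), values = v,
        source = source)
}

#' Construct a RankingTable
#' @param drugId the drug the ranking is for.
#' @param circRNA candidate identifiers in rank order.
#' @param score prediction scores, non-increasing, in `[0,1]`.
#' @param verified optional logical verification flags (NA when unknown).
#' @return a [RankingTable].
#' @export
RankingTable <- function(drugId, circRNA, score,
                         verified = rep(NA, length(circRNA))) {
    if (any(diff(score) > 1e-12))
        stopTyped("orderingError",
                  "scores must be non-increasing in rank order")
    new("RankingTable", drugId = as.character(drugId),
        table = data.frame(rank = seq_along(circRNA),
                           circRNA = as.character(circRNA),
                           score = as.numeric(score),
                           verified = as.logical(verified),
                           stringsAsFactors = FALSE))
}

#' Read circRNA host-gene sequences from FASTA
#'
#' Standard multi-line FASTA; record order is preserved, sequences are
#' uppercased and `U` is mapped to `T`.  Characters outside
#' `{A,C,G,T,U,N}` raise an alphabet error naming the record, duplicated
#' identifiers a duplicate-identifier error, an empty file a format error.
#'
#' @param path FASTA file path.
#' @return a [SequenceSet].
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stopTyped("ioError", "no such file: %s", path)
    ss <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e)
                       stopTyped("formatError", "not valid FASTA: %s",
                                 conditionMessage(e)))
    if (!length(ss)) stopTyped("formatError", "empty FASTA file: %s", path)
    idsFull <- names(ss)
    recIds <- sub("\\s.*$", "", idsFull)
    if (anyDuplicated(recIds))
        stopTyped("duplicateIdentifierError", "duplicate FASTA id '%s'",
                  recIds[duplicated(recIds)][1L])
    SequenceSet(recIds, as.character(ss))
}

#' Write a SequenceSet as FASTA
#' @param seqs a [SequenceSet].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
    ss <- Biostrings::DNAStringSet(seqs@sequences)
    names(ss) <- seqs@ids
    Biostrings::writeXStringSet(ss, path, width = width)
    invisible(path)
}

.detectSep <- function(header) {
    if (grepl("\t", header)) "\t" else ","
}

.readLabelledMatrix <- function(path, what) {
    if (!file.exists(path)) stopTyped("ioError", "no such file: %s", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
        stopTyped("dimensionError", "%s file has no data rows: %s",
                  what, path)
    sep <- .detectSep(lines[1L])
    header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
    colIds <- header[-1L]
    if (!length(colIds))
        stopTyped("dimensionError", "%s file has no data columns: %s",
                  what, path)
    rows <- strsplit(lines[-1L], sep, fixed = TRUE)
    nc <- lengths(rows)
    if (any(nc != length(header)))
        stopTyped("formatError", "ragged row %d in %s",
                  which(nc != length(header))[1L] + 1L, path)
    rowIds <- vapply(rows, `[[`, character(1), 1L)
    body <- matrix(NA_real_, length(rows), length(colIds))
    for (r in seq_along(rows)) {
        v <- suppressWarnings(as.numeric(rows[[r]][-1L]))
        if (anyNA(v))
            stopTyped("valueError",
                      "non-numeric cell at row '%s', column '%s'",
                      rowIds[r], colIds[which(is.na(v))[1L]])
        body[r, ] <- v
    }
    list(rowIds = rowIds, colIds = colIds, body = body)
}

#' Read a binary association matrix
#'
#' TSV or CSV (auto-detected from the header line) with the first row
#' holding drug identifiers and the first column circRNA identifiers.
#' Non-binary cells raise a value error with the offending location.
#'
#' @param path file path.
#' @return an [AssociationMatrix].
#' @export
readAssociationMatrix <- function(path) {
    m <- .readLabelledMatrix(path, "association")
    bad <- !(m$body %in% c(0, 1))
    if (any(bad)) {
        idx <- which(matrix(bad, nrow(m$body)), arr.ind = TRUE)[1L, ]
        stopTyped("valueError",
                  "non-binary association value at row '%s', column '%s'",
                  m$rowIds[idx[1L]], m$colIds[idx[2L]])
    }
    AssociationMatrix(m$rowIds, m$colIds, m$body)
}

#' @rdname readAssociationMatrix
#' @param A an [AssociationMatrix].
#' @export
writeAssociationMatrix <- function(A, path) {
    .writeLabelledMatrix(valuesMatrix(A), path, format = "%d")
    invisible(path)
}

.writeLabelledMatrix <- function(m, path, format = "%.10g") {
    lines <- c(paste(c("", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(r)
                   paste(c(rownames(m)[r], sprintf(format, m[r, ])),
                         collapse = "\t"), character(1)))
    writeLines(lines, path)
}

#' Read / write drug fingerprints as an id-labelled bit matrix
#'
#' Same TSV/CSV dialect as [readAssociationMatrix()]: first row bit
#' position labels, first column drug identifiers, body in `{0,1}`.
#'
#' @param path file path.
#' @return a [FingerprintSet].
#' @export
readFingerprints <- function(path) {
    m <- .readLabelledMatrix(path, "fingerprint")
    if (!all(m$body %in% c(0, 1)))
        stopTyped("valueError", "fingerprint bits must be 0/1 in %s", path)
    FingerprintSet(m$rowIds, m$body)
}

#' @rdname readFingerprints
#' @param fps a [FingerprintSet].
#' @export
writeFingerprints <- function(fps, path) {
    m <- valuesMatrix(fps)
    colnames(m) <- sprintf("bit%d", seq_len(ncol(m)))
    .writeLabelledMatrix(m, path, format = "%d")
    invisible(path)
}

#' Write / read a similarity matrix TSV
#' @param sim a [SimilarityMatrix].
#' @param path file path.
#' @param source similarity source tag used when reading back.
#' @export
writeSimilarityMatrix <- function(sim, path) {
    .writeLabelledMatrix(valuesMatrix(sim), path)
    invisible(path)
}

#' @rdname writeSimilarityMatrix
#' @export
readSimilarityMatrix <- function(path, source = "fused") {
    m <- .readLabelledMatrix(path, "similarity")
    SimilarityMatrix(m$rowIds, m$body, source)
}

#' Write a top-k ranking table as TSV
#'
#' Columns `rank`, `circRNA`, `score` (6 decimal places) and `verified`
#' (`1`/`0`, blank when no flag is available); byte-deterministic for a
#' fixed table.
#'
#' @param table a [RankingTable].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRanking <- function(table, path) {
    tb <- table@table
    ver <- ifelse(is.na(tb$verified), "", as.character(as.integer(tb$verified)))
    lines <- c(paste(c("rank", "circRNA", "score", "verified"),
                     collapse = "\t"),
               sprintf("%d\t%s\t%.6f\t%s", tb$rank, tb$circRNA, tb$score,
                       ver))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stopTyped("ioError", "cannot write ranking to %s", path)
    invisible(path)
}

#' @rdname writeRanking
#' @param drugId drug identifier to attach to the re-read table.
#' @export
readRanking <- function(path, drugId = NA_character_) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c("integer", "character",
                                           "numeric", "character"))
    ver <- ifelse(df$verified %in% c("", NA), NA,
                  df$verified %in% c("1", "TRUE"))
    RankingTable(drugId, df$circRNA, df$score, ver)
}

#' Read a curated case-study candidate table
#'
#' Reads a published top-k candidate list (columns `rank`, `circRNA`,
#' `verified` with 1 = externally verified) such as the CTRP-verified
#' top-20 tables shipped under `inst/extdata/casestudy/`.  No prediction
#' scores are recorded in such tables; surrogate scores decreasing with
#' rank are filled in so the object satisfies the [RankingTable]
#' invariants.
#'
#' @param path TSV path.
#' @param drugId drug identifier for the table.
#' @return a [RankingTable].
#' @export
readCaseStudyTable <- function(path, drugId = NA_character_) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    k <- nrow(df)
    RankingTable(drugId, df$circRNA, score = 1 - (seq_len(k) - 1) / k,
                 verified = df$verified == 1)
}

#' Write a metrics report as JSON
#'
#' @param report a [MetricsReport].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
    jsonlite::write_json(
        list(perFold = report@perFold,
             mean = as.list(report@summary),
             foldSafe = report@foldSafe,
             config = report@config),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
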