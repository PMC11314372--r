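#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment via
#' [Biostrings::pairwiseAlignment()], defaulting to BLOSUM62 with gap open
#' 11 and gap extension 1 (a gap of length L costs `open + L * extend`).
#' Backtracking is deterministic, so identical inputs give identical
#' alignments.
#'
#' @param query,reference sequences (character or `AAString`).
#' @param substitutionMatrix name of a packaged scoring matrix (e.g.
#'   `"BLOSUM62"`) or a numeric matrix.
#' @param gapOpen,gapExtend non-negative gap penalties.
#' @return a list with elements `score`, `alignedQuery` and
#'   `alignedReference` (equal-length gapped strings).
#' @export
#' @examples
#' alignGlobal("ACD", "AD")$alignedReference   # "A-D"
alignGlobal <- function(query, reference, substitutionMatrix = "BLOSUM62",
                        gapOpen = 11, gapExtend = 1) {
  q <- as.character(query); r <- as.character(reference)
  if (!nzchar(q) || !nzchar(r)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(r),
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpen, gapExtension = gapExtend, type = "global")
  list(score = Biostrings::score(pa),
       alignedQuery = as.character(Biostrings::alignedPattern(pa)),
       alignedReference = as.character(Biostrings::alignedSubject(pa)))
}

#' Map reference positions through an alignment
#'
#' For each 1-based reference position, returns the corresponding 1-based
#' query position, or `NA` when the reference residue is aligned to a gap in
#' the query.
#'
#' @param alignment result of [alignGlobal()] (query vs reference).
#' @param referencePositions integer vector of 1-based reference positions.
#' @return integer vector of query positions (`NA` = gapped).
#' @export
mapPositions <- function(alignment, referencePositions) {
  qa <- strsplit(alignment$alignedQuery, "", fixed = TRUE)[[1]]
  ra <- strsplit(alignment$alignedReference, "", fixed = TRUE)[[1]]
  stopifnot(length(qa) == length(ra))
  refLen <- sum(ra != "-")
  if (any(referencePositions < 1L | referencePositions > refLen))
    stop("reference position out of range")
  refIdx <- cumsum(ra != "-")
  qryIdx <- cumsum(qa != "-")
  vapply(as.integer(referencePositions), function(p) {
    col <- which(refIdx == p & ra != "-")[1L]
    if (qa[col] == "-") NA_integer_ else qryIdx[col]
  }, integer(1))
}
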