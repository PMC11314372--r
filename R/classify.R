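#' Classify a PCS sequence into the N/E/D isoforms
#'
#' The residue four positions upstream of the catalytic cysteine defines the
#' isoform: Asn gives the "N" subtype (group 1, the half-PCS-like proteins),
#' while Glu or Asp give the "E"/"D" subtypes (group 2, the plant-like
#' proteins).  Any other residue leaves the sequence `unclassified`
#' (group `NA`); such sequences are retained in all outputs.  The call also
#' collects the CK2 phosphorylation-context flag, the conserved-cysteine
#' motif hits between the catalytic Cys and His, the total cysteine count
#' and the length of the C-terminal extension after the catalytic Asp.
#'
#' @param record sequence (character or `AAString`).
#' @param triad an accepted [TriadAnnotation-class] for `record`.
#' @return an [IsoformCall-class].
#' @export
#' @examples
#' rec <- generatePcsSequence(scaffoldSpec(subtype = "E", seed = 2))
#' classifyIsoform(rec$seq, detectTriad(rec$seq, mode = "scan"))
classifyIsoform <- function(record, triad) {
  s <- toupper(as.character(record))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!triadFound(triad)) stop("triad not accepted; cannot classify")
  c <- cysPos(triad)
  if (c - 4L < 1L) stop("malformed triad: cysPos - 4 out of range")
  minus4 <- chars[c - 4L]
  minus3 <- chars[c - 3L]
  thr7 <- if (c >= 8L) chars[c - 7L] else NA_character_
  sub <- if (minus4 %in% c("N", "E", "D")) minus4 else "unclassified"
  grp <- if (sub == "N") 1L else if (sub %in% c("E", "D")) 2L else NA_integer_
  hits <- findConservedCys(s, triad)
  new("IsoformCall", subtype = sub, group = grp, minus4 = minus4,
      minus3 = minus3, thr7 = thr7,
      ck2Competent = checkCk2Context(s, triad),
      ccHits = hits$cc, cxxxcHits = hits$cxxxc,
      conservedCysCount = hits$conservedCount,
      cysTotal = countCys(s),
      ctermTailLength = ctermTail(s, triad))
}

#' Casein kinase 2 phosphorylation-context call
#'
#' `TRUE` iff the residue seven positions upstream of the catalytic Cys is
#' Ser or Thr \emph{and} the residue four positions upstream is Asp or Glu
#' -- the `[ST]-X2-[DE]` context that makes the upstream Thr (or Ser) a CK2
#' target.  Out-of-range positions give `FALSE` with a warning.
#'
#' @inheritParams classifyIsoform
#' @return logical flag.
#' @export
checkCk2Context <- function(record, triad) {
  s <- toupper(as.character(record))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!triadFound(triad)) stop("triad not accepted")
  c <- cysPos(triad)
  if (c < 8L) {
    warning("catalytic Cys too close to the N terminus for a CK2 context")
    return(FALSE)
  }
  chars[c - 7L] %in% c("S", "T") && chars[c - 4L] %in% c("D", "E")
}

#' Conserved-cysteine motifs between the catalytic Cys and His
#'
#' Scans the open interval between the catalytic Cys and His for the CC
#' motif (two adjacent cysteines) and the CXXXC motif (two cysteines with
#' exactly three intervening residues), the arrangement carried by the four
#' conserved cysteines of plant-type PCS proteins.  Overlapping hits are all
#' reported.
#'
#' @inheritParams classifyIsoform
#' @return a list with integer vectors `cc` and `cxxxc` (1-based start
#'   positions of each hit) and `conservedCount`, the number of distinct
#'   cysteines participating in hits, capped at 4.
#' @export
findConservedCys <- function(record, triad) {
  s <- toupper(as.character(record))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!triadFound(triad)) stop("triad not accepted")
  lo <- cysPos(triad) + 1L; hi <- hisPos(triad) - 1L
  cc <- integer(0); cx <- integer(0); members <- integer(0)
  if (hi >= lo) {
    cs <- which(chars == "C")
    cs <- cs[cs >= lo & cs <= hi]
    for (p in cs) {
      if ((p + 1L) %in% cs) { cc <- c(cc, p); members <- c(members, p, p + 1L) }
      if ((p + 4L) %in% cs) { cx <- c(cx, p); members <- c(members, p, p + 4L) }
    }
  }
  list(cc = cc, cxxxc = cx,
       conservedCount = min(4L, length(unique(members))))
}

#' Total cysteine count
#'
#' @param record sequence (character or `AAString`).
#' @return number of `C` residues over the whole sequence.
#' @export
countCys <- function(record) {
  s <- toupper(as.character(record))
  sum(strsplit(s, "", fixed = TRUE)[[1]] == "C")
}

#' C-terminal tail length
#'
#' Number of residues after the catalytic Asp.
#'
#' @inheritParams classifyIsoform
#' @return integer tail length.
#' @export
ctermTail <- function(record, triad) {
  if (!triadFound(triad)) stop("triad not accepted")
  nchar(as.character(record)) - aspPos(triad)
}

#' Per-column information content of an aligned block
#'
#' For a gap-free block of equal-length rows, computes the sequence-logo
#' information content per column: `IC_j = log2(20) - H_j`, with `H_j` the
#' Shannon entropy of the empirical residue frequencies in column `j`.
#'
#' @param block character vector of equal-length sequences (or a character
#'   matrix with one row per sequence).
#' @return a data.frame with one row per column: the 20 residue frequencies
#'   plus an `ic` column in bits (`0 <= ic <= log2(20)`).
#' @export
#' @examples
#' columnInformation(c("AC", "AC", "AV"))$ic
columnInformation <- function(block) {
  if (is.matrix(block)) {
    m <- block
  } else {
    block <- as.character(block)
    if (length(block) == 0L) stop("empty alignment block")
    if (length(unique(nchar(block))) != 1L)
      stop("rows must have equal length")
    m <- do.call(rbind, strsplit(block, "", fixed = TRUE))
  }
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty alignment block")
  if (any(m == "-")) stop("block must not contain gaps")
  out <- t(apply(m, 2L, function(col) {
    f <- table(factor(col, levels = AA_ALPHABET)) / length(col)
    as.numeric(f)
  }))
  colnames(out) <- AA_ALPHABET
  ic <- apply(out, 1L, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  data.frame(position = seq_len(nrow(out)), out, ic = ic,
             check.names = FALSE)
}
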