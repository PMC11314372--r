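#' @include PCSkit-package.R
NULL

#' Scaffold specification for synthetic PCS-like sequences
#'
#' Describes one synthetic phytochelatin-synthase-like protein: an N-terminal
#' region, an optional Thr seven residues upstream of the catalytic Cys, the
#' classifying residue (N, E or D) four residues upstream, a Cys--His segment
#' optionally carrying the conserved CC and CXXXC cysteine pairs, a His--Asp
#' spacing of exactly 17 intervening residues, and an optional Cys-rich
#' C-terminal tail.
#'
#' @slot subtype classifying residue at Cys-4: `"N"`, `"E"` or `"D"`.
#' @slot ntermLen integer, residues before the Thr site (catalytic Cys sits
#'   at `ntermLen + 8`).
#' @slot chSpacing integer, residues strictly between catalytic Cys and His.
#' @slot includeThr7,includeCC,includeCxxxC logical feature switches.
#' @slot ctermLen integer, residues after the catalytic Asp.
#' @slot ctermCysFrac fraction of Cys in the C-terminal tail.
#' @slot background named numeric of length 20 summing to 1: residue
#'   composition used for unconstrained positions.
#' @slot seed integer seed driving all random draws for this scaffold.
#' @seealso [scaffoldSpec()], [generatePcsSequence()]
#' @exportClass ScaffoldSpec
setClass("ScaffoldSpec",
  representation(subtype = "character", ntermLen = "integer",
                 chSpacing = "integer", includeThr7 = "logical",
                 includeCC = "logical", includeCxxxC = "logical",
                 ctermLen = "integer", ctermCysFrac = "numeric",
                 background = "numeric", seed = "integer"))

setValidity("ScaffoldSpec", function(object) {
  msg <- character(0)
  if (!object@subtype %in% c("N", "E", "D"))
    msg <- c(msg, "subtype must be one of N, E, D")
  if (object@chSpacing < 8L)
    msg <- c(msg, "chSpacing must be >= 8")
  if ((object@includeCC || object@includeCxxxC) && object@chSpacing < 12L)
    msg <- c(msg, "chSpacing too small to host CC/CXXXC motifs")
  if (object@ntermLen < 0L) msg <- c(msg, "ntermLen must be >= 0")
  if (object@ctermLen < 0L) msg <- c(msg, "ctermLen must be >= 0")
  if (object@ctermCysFrac < 0 || object@ctermCysFrac > 1)
    msg <- c(msg, "ctermCysFrac must be in [0, 1]")
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-9 ||
      any(object@background < 0))
    msg <- c(msg, "background must be a 20-entry simplex (sums to 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScaffoldSpec", function(object) {
  cat(sprintf(
    "ScaffoldSpec: subtype %s | N-term %d | C-H spacing %d | tail %d (Cys frac %.2f)\n",
    object@subtype, object@ntermLen, object@chSpacing, object@ctermLen,
    object@ctermCysFrac))
  cat(sprintf("  Thr at -7: %s | CC: %s | CXXXC: %s | seed %d\n",
              object@includeThr7, object@includeCC, object@includeCxxxC,
              object@seed))
})

#' Catalytic-triad annotation of a PCS candidate
#'
#' Positions (1-based) of the catalytic Cys, His and Asp, the two spacing
#' counts of the annotation table (residues strictly between Cys and His and
#' between His and Asp), and the 7-residue context ending at the catalytic
#' Cys.
#'
#' @slot found logical; `FALSE` when no acceptable triad exists.
#' @slot cysPos,hisPos,aspPos integer 1-based residue indices (NA when not
#'   found).
#' @slot context7 the 7-mer ending at the catalytic Cys.
#' @slot method `"reference_alignment"`, `"constrained_scan"` or `"none"`.
#' @slot score context-plausibility score of the accepted candidate (scan
#'   path; NA for the alignment path).
#' @seealso [detectTriad()]
#' @exportClass TriadAnnotation
setClass("TriadAnnotation",
  representation(found = "logical", cysPos = "integer", hisPos = "integer",
                 aspPos = "integer", context7 = "character",
                 method = "character", score = "numeric"))

setValidity("TriadAnnotation", function(object) {
  if (!object@found) return(TRUE)
  msg <- character(0)
  if (object@aspPos - object@hisPos - 1L != 17L)
    msg <- c(msg, "His-Asp spacing must be exactly 17 intervening residues")
  if (nchar(object@context7) != 7L || substring(object@context7, 7, 7) != "C")
    msg <- c(msg, "context7 must have length 7 and end in C")
  if (object@hisPos <= object@cysPos)
    msg <- c(msg, "His must lie downstream of Cys")
  if (length(msg)) msg else TRUE
})

#' @describeIn TriadAnnotation position of the catalytic cysteine
#' @param x a `TriadAnnotation`
#' @export
cysPos <- function(x) x@cysPos
#' @describeIn TriadAnnotation position of the catalytic histidine
#' @export
hisPos <- function(x) x@hisPos
#' @describeIn TriadAnnotation position of the catalytic aspartate
#' @export
aspPos <- function(x) x@aspPos
#' @describeIn TriadAnnotation residues strictly between Cys and His
#' @export
chDistance <- function(x) if (x@found) x@hisPos - x@cysPos - 1L else NA_integer_
#' @describeIn TriadAnnotation residues strictly between His and Asp
#' @export
hdDistance <- function(x) if (x@found) x@aspPos - x@hisPos - 1L else NA_integer_
#' @describeIn TriadAnnotation 7-mer ending at the catalytic Cys
#' @export
context7 <- function(x) x@context7
#' @describeIn TriadAnnotation TRUE when a triad was accepted
#' @export
triadFound <- function(x) x@found

setMethod("show", "TriadAnnotation", function(object) {
  if (!object@found) {
    cat("TriadAnnotation: no triad found\n")
  } else {
    cat(sprintf(
      "TriadAnnotation: Cys %d / His %d / Asp %d (C-H %d, H-D %d) context %s [%s]\n",
      object@cysPos, object@hisPos, object@aspPos,
      chDistance(object), hdDistance(object), object@context7,
      object@method))
  }
})

#' Isoform classification of one PCS sequence
#'
#' The call made from the residue four positions upstream of the catalytic
#' Cys (N -> group 1; E or D -> group 2), the CK2 phosphorylation-context
#' flag, conserved-cysteine motif hits between the catalytic Cys and His,
#' and cysteine bookkeeping.
#'
#' @slot subtype `"N"`, `"E"`, `"D"` or `"unclassified"`.
#' @slot group `1L`, `2L` or `NA` (unclassified).
#' @slot minus4,minus3,thr7 residues at Cys-4, Cys-3 and Cys-7 (`NA` when out
#'   of range).
#' @slot ck2Competent logical: S/T at Cys-7 and D/E at Cys-4.
#' @slot ccHits,cxxxcHits integer start positions of CC and C-X(3)-C hits
#'   strictly between the catalytic Cys and His.
#' @slot conservedCysCount distinct cysteines participating in hits, capped
#'   at 4.
#' @slot cysTotal total number of C in the sequence.
#' @slot ctermTailLength residues after the catalytic Asp.
#' @seealso [classifyIsoform()]
#' @exportClass IsoformCall
setClass("IsoformCall",
  representation(subtype = "character", group = "integer",
                 minus4 = "character", minus3 = "character",
                 thr7 = "character", ck2Competent = "logical",
                 ccHits = "integer", cxxxcHits = "integer",
                 conservedCysCount = "integer", cysTotal = "integer",
                 ctermTailLength = "integer"))

setValidity("IsoformCall", function(object) {
  msg <- character(0)
  if (!object@subtype %in% c("N", "E", "D", "unclassified"))
    msg <- c(msg, "invalid subtype")
  if (object@subtype == "N" && !identical(object@group, 1L))
    msg <- c(msg, "subtype N must be group 1")
  if (object@subtype %in% c("E", "D") && !identical(object@group, 2L))
    msg <- c(msg, "subtypes E/D must be group 2")
  if (isTRUE(object@ck2Competent) &&
      !(object@minus4 %in% c("D", "E") && object@thr7 %in% c("S", "T")))
    msg <- c(msg, "ck2Competent requires S/T at -7 and D/E at -4")
  if (object@cysTotal < object@conservedCysCount)
    msg <- c(msg, "cysTotal below conservedCysCount")
  if (length(msg)) msg else TRUE
})

#' @describeIn IsoformCall the N/E/D subtype call
#' @param x an `IsoformCall`
#' @export
subtype <- function(x) x@subtype
#' @describeIn IsoformCall group 1 (N) or 2 (E/D); NA when unclassified
#' @export
isoformGroup <- function(x) x@group
#' @describeIn IsoformCall CK2 phosphorylation-context flag
#' @export
ck2Competent <- function(x) x@ck2Competent

setMethod("show", "IsoformCall", function(object) {
  cat(sprintf(
    "IsoformCall: subtype %s (group %s) | CK2 %s | CC %s | CXXXC %s | Cys %d | tail %d\n",
    object@subtype, ifelse(is.na(object@group), "none", object@group),
    object@ck2Competent,
    if (length(object@ccHits)) paste(object@ccHits, collapse = ",") else "-",
    if (length(object@cxxxcHits)) paste(object@cxxxcHits, collapse = ",") else "-",
    object@cysTotal, object@ctermTailLength))
})

#' Ungapped motif model
#'
#' A motif discovered by ZOOPS expectation maximization, represented as a
#' width x 20 letter-probability matrix (each row a distribution over the
#' amino-acid alphabet), with the list of sites supporting it and its
#' likelihood-ratio score.
#'
#' @slot width motif width in residues.
#' @slot ppm numeric matrix, `width` rows x 20 columns (alphabet order),
#'   each row summing to 1.
#' @slot sites data.frame with columns `seq_id`, `start`, `score` (1-based
#'   start of each occurrence).
#' @slot llr log-likelihood ratio of the motif model against the background.
#' @slot penalizedLlr `llr` minus a BIC-style complexity penalty; the model
#'   selection criterion.
#' @slot icTotal total information content in bits (sum over columns of
#'   `log2(20) - H`).
#' @slot gamma fitted ZOOPS occurrence prior.
#' @slot background length-20 background composition the motif was fit
#'   against.
#' @slot trace per-iteration EM objective (monotone non-decreasing).
#' @seealso [discoverMotifs()], [scanMotif()]
#' @exportClass MotifModel
setClass("MotifModel",
  representation(width = "integer", ppm = "matrix", sites = "data.frame",
                 llr = "numeric", penalizedLlr = "numeric",
                 icTotal = "numeric", gamma = "numeric",
                 background = "numeric", trace = "numeric"))

setValidity("MotifModel", function(object) {
  msg <- character(0)
  if (nrow(object@ppm) != object@width || ncol(object@ppm) != 20L)
    msg <- c(msg, "ppm must be width x 20")
  if (any(abs(rowSums(object@ppm) - 1) > 1e-9))
    msg <- c(msg, "every ppm row must sum to 1")
  if (any(object@ppm < 0)) msg <- c(msg, "ppm entries must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifModel motif width in residues
#' @param x a `MotifModel`
#' @export
motifWidth <- function(x) x@width
#' @describeIn MotifModel letter-probability matrix (width x 20)
#' @export
motifPpm <- function(x) x@ppm
#' @describeIn MotifModel supporting sites
#' @export
motifSites <- function(x) x@sites
#' @describeIn MotifModel per-column information content in bits
#' @export
motifIc <- function(x) {
  apply(x@ppm, 1L, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
}
#' @describeIn MotifModel majority-letter consensus string
#' @export
motifConsensus <- function(x) {
  paste(AA_ALPHABET[apply(x@ppm, 1L, which.max)], collapse = "")
}

setMethod("show", "MotifModel", function(object) {
  cat(sprintf(
    "MotifModel: width %d | %d sites | LLR %.1f | IC %.1f bits (%.2f/col) | consensus %s\n",
    object@width, nrow(object@sites), object@llr, object@icTotal,
    object@icTotal / object@width, motifConsensus(object)))
})
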