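#' Packaged annotated reference scaffold
#'
#' Returns the packaged reference used by the alignment-guided triad path: a
#' synthetic PCS-like scaffold (built with [generatePcsSequence()]; it is
#' \emph{not} a natural protein) whose catalytic triad sits at positions
#' 56/162/180, the coordinates of the AtPCS1 triad that anchors PCS residue
#' numbering.
#'
#' @return a list with elements `seq_id`, `seq`, `cys`, `his`, `asp`.
#' @seealso [readReferenceSet()] to supply real annotated references.
#' @export
pcsReference <- function() {
  fa <- system.file("extdata", "synthetic_pcs_reference.fasta",
                    package = "PCSkit", mustWork = TRUE)
  tsv <- system.file("extdata", "synthetic_pcs_reference_triad.tsv",
                     package = "PCSkit", mustWork = TRUE)
  readReferenceSet(fa, tsv)[[1L]]
}

#' Read an annotated reference set
#'
#' Loads reference proteins with known triad coordinates for the
#' alignment-guided triad path.
#'
#' @param fastaPath FASTA file of reference sequences.
#' @param triadPath TSV with header `seq_id`, `cys`, `his`, `asp` (1-based).
#' @return a list of references, each a list with `seq_id`, `seq`, `cys`,
#'   `his`, `asp`.
#' @export
readReferenceSet <- function(fastaPath, triadPath) {
  seqs <- readFasta(fastaPath)
  tab <- utils::read.delim(triadPath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("seq_id", "cys", "his", "asp")
  if (!all(need %in% names(tab)))
    stop("reference triad table needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$seq_id[i]
    if (!id %in% names(seqs)) stop("reference sequence missing: ", id)
    s <- as.character(seqs[[id]])
    ref <- list(seq_id = id, seq = s, cys = as.integer(tab$cys[i]),
                his = as.integer(tab$his[i]), asp = as.integer(tab$asp[i]))
    ch <- substring(s, ref$cys, ref$cys)
    hh <- substring(s, ref$his, ref$his)
    dh <- substring(s, ref$asp, ref$asp)
    if (ch != "C" || hh != "H" || dh != "D")
      stop("reference ", id, " does not carry C/H/D at the stated positions")
    ref
  })
}

.triadNone <- function() {
  new("TriadAnnotation", found = FALSE, cysPos = NA_integer_,
      hisPos = NA_integer_, aspPos = NA_integer_, context7 = NA_character_,
      method = "none", score = NA_real_)
}

.triadAt <- function(chars, c, h, d, method, score = NA_real_) {
  new("TriadAnnotation", found = TRUE, cysPos = as.integer(c),
      hisPos = as.integer(h), aspPos = as.integer(d),
      context7 = paste(chars[(c - 6):c], collapse = ""),
      method = method, score = score)
}

# Context-plausibility score of a candidate catalytic Cys.
.contextScore <- function(chars, c) {
  s <- 0
  if (c >= 5 && chars[c - 4] %in% c("N", "E", "D")) s <- s + 2
  if (c >= 8 && chars[c - 7] %in% c("S", "T", "N")) s <- s + 1
  if (c >= 2 && chars[c - 1] %in% c("Y", "F")) s <- s + 1
  s
}

#' Locate the catalytic Cys/His/Asp triad
#'
#' Two annotation paths, mirroring how PCS residue numbering is anchored in
#' practice:
#' \describe{
#'   \item{reference alignment}{the query is globally aligned to each
#'   annotated reference; the reference triad is mapped through the
#'   alignment and accepted if the mapped query residues are exactly C, H
#'   and D with 17 residues strictly between His and Asp.}
#'   \item{constrained scan}{all (Cys, His, Asp) combinations with C and H
#'   separated by `chBounds` intervening residues and D exactly 18 positions
#'   after H are enumerated and scored for context plausibility (+2 for
#'   N/E/D four residues upstream of the Cys, +1 for S/T/N seven residues
#'   upstream, +1 for Y/F immediately upstream); the best-scoring candidate
#'   wins, ties going to the smallest Cys position.}
#' }
#' Mode `"auto"` tries the alignment path first (when references are
#' available) and falls back to the scan.
#'
#' @param query sequence (character or `AAString`).
#' @param references list of annotated references as returned by
#'   [readReferenceSet()]; defaults to the packaged synthetic reference.
#' @param mode `"auto"`, `"align"` or `"scan"`.
#' @param chBounds length-2 integer vector: admissible range of intervening
#'   residues between the catalytic Cys and His.  The default brackets the
#'   94--155 range observed across annotated PCS proteins.
#' @return a [TriadAnnotation-class] (with `found = FALSE` when no
#'   acceptable triad exists).
#' @export
#' @examples
#' rec <- generatePcsSequence(scaffoldSpec(subtype = "N", seed = 1))
#' detectTriad(rec$seq, mode = "scan")
detectTriad <- function(query, references = NULL,
                        mode = c("auto", "align", "scan"),
                        chBounds = c(90L, 160L)) {
  mode <- match.arg(mode)
  s <- toupper(as.character(query))
  if (nchar(s) < 30L) stop("query too short for triad annotation (< 30 aa)")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]

  if (mode %in% c("auto", "align")) {
    if (is.null(references)) references <- list(pcsReference())
    for (ref in references) {
      aln <- alignGlobal(s, ref$seq)
      pos <- mapPositions(aln, c(ref$cys, ref$his, ref$asp))
      if (!anyNA(pos) && pos[1] >= 7L &&
          chars[pos[1]] == "C" && chars[pos[2]] == "H" &&
          chars[pos[3]] == "D" && (pos[3] - pos[2] - 1L) == 17L) {
        return(.triadAt(chars, pos[1], pos[2], pos[3],
                        method = "reference_alignment"))
      }
    }
    if (mode == "align") return(.triadNone())
  }

  # constrained scan fallback
  cpos <- which(chars == "C")
  cpos <- cpos[cpos >= 7L]                 # need a full 7-mer context
  hpos <- which(chars == "H")
  best <- NULL
  for (c in cpos) {
    hs <- hpos[hpos - c - 1L >= chBounds[1] & hpos - c - 1L <= chBounds[2]]
    for (h in hs) {
      d <- h + 18L
      if (d <= length(chars) && chars[d] == "D") {
        sc <- .contextScore(chars, c)
        if (is.null(best) || sc > best$sc) best <- list(c = c, h = h, d = d, sc = sc)
        # ties: keep the earlier (smaller cysPos, then smaller hisPos) find
      }
    }
  }
  if (is.null(best)) return(.triadNone())
  .triadAt(chars, best$c, best$h, best$d, method = "constrained_scan",
           score = best$sc)
}

#' Annotate triads across a sequence set
#'
#' @param seqs an [Biostrings::AAStringSet] or named character vector.
#' @param ... passed to [detectTriad()].
#' @return a named list of [TriadAnnotation-class] objects.  Sequences with
#'   no acceptable triad get a `found = FALSE` annotation and a warning.
#' @export
annotateTriads <- function(seqs, ...) {
  txt <- .asNamedChar(seqs)
  out <- lapply(seq_along(txt), function(i) detectTriad(txt[[i]], ...))
  names(out) <- names(txt)
  miss <- names(out)[!vapply(out, triadFound, logical(1))]
  if (length(miss))
    warning("no triad found for: ", paste(miss, collapse = ", "))
  out
}
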