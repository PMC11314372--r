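#' Construct a scaffold specification
#'
#' Builds a [ScaffoldSpec-class] with subtype-aware defaults that emulate
#' the two PCS groups: "N" scaffolds are short, cysteine-poor and lack the
#' conserved CC/CXXXC pairs, while "E"/"D" scaffolds carry the conserved
#' cysteines and a long Cys-rich C-terminal tail.  The background
#' composition defaults to uniform over the 20 residues so that no motif
#' signal is present unless planted.
#'
#' @param subtype `"N"`, `"E"` or `"D"`.
#' @param ntermLen residues before the Thr site; the default 48 puts the
#'   catalytic Cys at position 56, matching PCS residue numbering.
#' @param chSpacing residues strictly between the catalytic Cys and His
#'   (observed range in annotated PCS proteins: 94--155).
#' @param includeThr7 plant a Thr seven residues upstream of the catalytic
#'   Cys (when `FALSE`, the position is guaranteed not to be S/T).
#' @param includeCC,includeCxxxC plant the conserved cysteine pairs in the
#'   Cys--His segment; default `TRUE` for subtypes E/D, `FALSE` for N.
#' @param ctermLen tail length after the catalytic Asp; default 50 for
#'   subtype N, 250 for E/D.
#' @param ctermCysFrac fraction of Cys in the tail; default 0.01 (N) or
#'   0.06 (E/D).
#' @param background length-20 composition (alphabetical residue order).
#' @param seed integer seed.
#' @return a validated [ScaffoldSpec-class].
#' @export
scaffoldSpec <- function(subtype = c("N", "E", "D"), ntermLen = 48L,
                         chSpacing = 105L, includeThr7 = TRUE,
                         includeCC = NULL, includeCxxxC = NULL,
                         ctermLen = NULL, ctermCysFrac = NULL,
                         background = NULL, seed = 1L) {
  subtype <- match.arg(subtype)
  grp2 <- subtype %in% c("E", "D")
  if (is.null(includeCC)) includeCC <- grp2
  if (is.null(includeCxxxC)) includeCxxxC <- grp2
  if (is.null(ctermLen)) ctermLen <- if (grp2) 250L else 50L
  if (is.null(ctermCysFrac)) ctermCysFrac <- if (grp2) 0.06 else 0.01
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  new("ScaffoldSpec", subtype = subtype, ntermLen = as.integer(ntermLen),
      chSpacing = as.integer(chSpacing), includeThr7 = includeThr7,
      includeCC = includeCC, includeCxxxC = includeCxxxC,
      ctermLen = as.integer(ctermLen), ctermCysFrac = ctermCysFrac,
      background = background, seed = as.integer(seed))
}

# Draw n letters from the background excluding some letters.
.bgDraw <- function(n, background, exclude = character(0)) {
  if (n == 0L) return(character(0))
  keep <- !(names(background) %in% exclude)
  sample(names(background)[keep], n, replace = TRUE,
         prob = background[keep] / sum(background[keep]))
}

#' Generate one PCS-like scaffold with known truth
#'
#' Assembles a synthetic protein as
#' `[N-term][-7][-6 -5][-4 subtype][-3][-2][-1][C][Cys-His segment][H][17-residue spacer][D][tail]`:
#' the residue at -7 is Thr when requested (and never S/T otherwise), the
#' subtype letter sits at -4 followed by Gln (subtype N) or Pro (E/D) at -3,
#' the residue at -1 is Tyr or Phe as in natural PCS form strings, and the
#' His--Asp spacing is exactly 17 intervening residues.  Reserved letters
#' (C in the upstream regions and segment, H in the segment, H/D in the
#' spacer) are excluded from random draws, the CC and CXXXC pairs are
#' planted at non-overlapping offsets when requested, and the assembled
#' sequence is re-drawn until the constrained scanner recovers exactly the
#' planted triad, so the ground truth is unambiguous.  Output is
#' reproducible for a fixed `spec@seed`.
#'
#' @param spec a [ScaffoldSpec-class].
#' @param seq_id identifier recorded in the truth row.
#' @return a list with `seq` (character), `truth` (one-row data.frame with
#'   columns `seq_id`, `subtype`, `cys_pos`, `his_pos`, `asp_pos`,
#'   `thr_pos`, `cc`, `cxxxc`, `motif_span`).
#' @export
#' @examples
#' out <- generatePcsSequence(scaffoldSpec("E", seed = 2))
#' out$truth$asp_pos - out$truth$his_pos - 1L   # always 17
generatePcsSequence <- function(spec, seq_id = "synthetic") {
  validObject(spec)
  if (spec@includeCxxxC && spec@chSpacing < 5L)
    stop("chSpacing too small for a CXXXC motif")
  bg <- spec@background
  seeds <- .deriveSeeds(spec@seed, 60L)
  cys <- spec@ntermLen + 8L
  his <- cys + spec@chSpacing + 1L
  asp <- his + 18L

  for (attempt in seq_len(50L)) {
    set.seed(seeds[attempt])
    nterm <- .bgDraw(spec@ntermLen, bg, exclude = "C")
    p7 <- if (spec@includeThr7) "T" else .bgDraw(1L, bg, exclude = c("S", "T", "C"))
    p65 <- .bgDraw(2L, bg, exclude = "C")
    p4 <- spec@subtype
    p3 <- if (spec@subtype == "N") "Q" else "P"
    p2 <- .bgDraw(1L, bg, exclude = "C")
    p1 <- sample(c("Y", "F"), 1L)
    seg <- .bgDraw(spec@chSpacing, bg, exclude = c("C", "H"))
    ccStart <- NA_integer_; cxStart <- NA_integer_
    occupied <- integer(0)
    if (spec@includeCC) {
      o <- sample(seq_len(spec@chSpacing - 1L), 1L)
      seg[c(o, o + 1L)] <- "C"
      occupied <- c(o, o + 1L)
      ccStart <- cys + o
    }
    if (spec@includeCxxxC) {
      cand <- setdiff(seq_len(spec@chSpacing - 4L), unique(c(
        outer(occupied, -4:1, "+"))))   # keep the two motifs disjoint
      cand <- cand[!(cand %in% occupied) & !((cand + 4L) %in% occupied)]
      if (!length(cand)) next
      o <- if (length(cand) == 1L) cand else sample(cand, 1L)
      seg[c(o, o + 4L)] <- "C"
      cxStart <- cys + o
    }
    spacer <- .bgDraw(17L, bg, exclude = c("H", "D"))
    tail <- character(spec@ctermLen)
    if (spec@ctermLen > 0L) {
      isC <- runif(spec@ctermLen) < spec@ctermCysFrac
      tail[isC] <- "C"
      tail[!isC] <- .bgDraw(sum(!isC), bg, exclude = "C")
    }
    s <- paste(c(nterm, p7, p65, p4, p3, p2, p1, "C", seg, "H", spacer, "D",
                 tail), collapse = "")
    # uniqueness: the constrained scanner must recover exactly the planted
    # triad (only checkable when the spacing lies inside the scan bounds)
    if (spec@chSpacing >= 90L && spec@chSpacing <= 160L && nchar(s) >= 30L) {
      hit <- detectTriad(s, mode = "scan")
      if (!triadFound(hit) || cysPos(hit) != cys || hisPos(hit) != his ||
          aspPos(hit) != asp) next
    }
    truth <- data.frame(
      seq_id = seq_id, subtype = spec@subtype, cys_pos = cys, his_pos = his,
      asp_pos = asp, thr_pos = if (spec@includeThr7) cys - 7L else NA_integer_,
      cc = ccStart, cxxxc = cxStart, motif_span = NA_character_,
      stringsAsFactors = FALSE)
    return(list(seq = s, truth = truth))
  }
  stop("could not generate an unambiguous scaffold in 50 attempts")
}

#' Generate a synthetic PCS dataset
#'
#' `3 * nPerSubtype` scaffolds (equal numbers of subtypes N, E and D) with
#' unique identifiers and a truth table.  The Cys--His spacing of each
#' scaffold is drawn uniformly from the 94--155 range observed across
#' annotated PCS proteins; everything else follows the subtype-aware
#' defaults of [scaffoldSpec()] unless overridden through `...`.
#' Fully reproducible from `seed`.
#'
#' @param nPerSubtype scaffolds per subtype (>= 1).
#' @param seed integer seed for the whole dataset.
#' @param chRange length-2 integer range the Cys--His spacing is drawn from.
#' @param ... overrides passed to [scaffoldSpec()] (e.g. `ctermLen`).
#' @return a list with `seqs` (an [Biostrings::AAStringSet]) and `truth`
#'   (data.frame, one row per scaffold).
#' @export
#' @examples
#' d <- generatePcsDataset(2, seed = 7)
#' length(d$seqs)   # 6
generatePcsDataset <- function(nPerSubtype, seed = 1L,
                               chRange = c(94L, 155L), ...) {
  if (nPerSubtype < 1L) stop("nPerSubtype must be >= 1")
  subtypes <- rep(c("N", "E", "D"), each = nPerSubtype)
  n <- length(subtypes)
  seeds <- .deriveSeeds(seed, 2L * n)
  set.seed(seeds[1L])
  spacings <- sample(seq(chRange[1], chRange[2]), n, replace = TRUE)
  ids <- sprintf("%s_%02d", subtypes, rep(seq_len(nPerSubtype), times = 3))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- scaffoldSpec(subtype = subtypes[i], chSpacing = spacings[i],
                         seed = seeds[n + i], ...)
    out[[i]] <- generatePcsSequence(spec, seq_id = ids[i])
  }
  seqs <- Biostrings::AAStringSet(vapply(out, `[[`, character(1), "seq"))
  names(seqs) <- ids
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  list(seqs = seqs, truth = truth)
}

#' Plant an ungapped motif into sequences
#'
#' Each sequence independently receives at most one copy of the consensus
#' (zero-or-one-occurrence-per-sequence truth) at a uniformly drawn offset,
#' overwriting the residues there.  Copies may be noisy: each motif position
#' is substituted by a random different residue with probability `subRate`.
#'
#' @param seqs named character vector or [Biostrings::AAStringSet].
#' @param consensus motif string, width 6--50.
#' @param occurrenceProb probability in `(0, 1]` that a sequence receives a
#'   copy.
#' @param subRate per-position substitution probability of planted copies.
#' @param region optional two-column matrix/data.frame (`start`, `end`), one
#'   row per sequence, restricting where copies may be planted.
#' @param seed integer seed.
#' @return a list with `seqs` (same container as input) and `spans`
#'   (data.frame `seq_id`, `start`, `end`, one row per planted copy).
#' @export
plantMotif <- function(seqs, consensus, occurrenceProb = 1, subRate = 0,
                       region = NULL, seed = 1L) {
  w <- nchar(consensus)
  if (w < 6L || w > 50L) stop("consensus width must be in [6, 50]")
  if (occurrenceProb <= 0 || occurrenceProb > 1)
    stop("occurrenceProb must be in (0, 1]")
  txt <- .asNamedChar(seqs)
  if (any(nchar(txt) < w)) stop("consensus longer than shortest sequence")
  ids <- names(txt)
  set.seed(as.integer(seed))
  motif <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  .checkAlphabet(consensus)
  spans <- list()
  for (i in seq_along(txt)) {
    if (runif(1) > occurrenceProb) next
    lo <- 1L; hi <- nchar(txt[i]) - w + 1L
    if (!is.null(region)) {
      lo <- max(lo, as.integer(region[i, 1]))
      hi <- min(hi, as.integer(region[i, 2]) - w + 1L)
      if (hi < lo) next
    }
    start <- if (hi == lo) lo else sample(seq(lo, hi), 1L)
    copy <- motif
    if (subRate > 0) {
      flip <- runif(w) < subRate
      copy[flip] <- vapply(copy[flip], function(a)
        sample(setdiff(AA_ALPHABET, a), 1L), character(1))
    }
    chars <- strsplit(txt[i], "", fixed = TRUE)[[1]]
    chars[start:(start + w - 1L)] <- copy
    txt[i] <- paste(chars, collapse = "")
    spans[[length(spans) + 1L]] <-
      data.frame(seq_id = ids[i], start = start, end = start + w - 1L,
                 stringsAsFactors = FALSE)
  }
  spans <- if (length(spans)) do.call(rbind, spans) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0))
  out <- if (methods::is(seqs, "XStringSet")) {
    x <- Biostrings::AAStringSet(txt); names(x) <- ids; x
  } else setNames(txt, ids)
  list(seqs = out, spans = spans)
}

#' Simulate an ancestor/descendant pair under the JTT model
#'
#' The ancestor is drawn from the JTT equilibrium frequencies; each site of
#' the descendant is substituted according to the JTT transition matrix at
#' divergence `t` (expected substitutions per site).
#'
#' @param length number of sites.
#' @param t divergence (`t >= 0`).
#' @param seed integer seed.
#' @return a list with character strings `ancestor` and `descendant`.
#' @export
#' @examples
#' p <- evolvePair(100, t = 0, seed = 1)
#' identical(p$ancestor, p$descendant)   # TRUE at t = 0
evolvePair <- function(length, t, seed = 1L) {
  if (t < 0) stop("divergence t must be non-negative")
  set.seed(as.integer(seed))
  pi0 <- jttEquilibrium()
  anc <- sample.int(20L, length, replace = TRUE, prob = pi0)
  p <- jttProbMatrix(t)
  desc <- integer(length)
  for (a in unique(anc)) {
    idx <- which(anc == a)
    desc[idx] <- sample.int(20L, base::length(idx), replace = TRUE,
                            prob = p[a, ])
  }
  list(ancestor = .i2s(anc), descendant = .i2s(desc))
}

#' Mutate a sequence while protecting positions
#'
#' Point substitutions (uniform over the 19 alternative residues) applied
#' with probability `subRate` at every unprotected position; used to build
#' homologous test sets around a reference scaffold.
#'
#' @param seq sequence (character).
#' @param subRate per-position substitution probability.
#' @param protect integer positions never mutated (e.g. the triad and its
#'   context).
#' @param seed integer seed.
#' @return mutated sequence (character).
#' @export
mutateSequence <- function(seq, subRate, protect = integer(0), seed = 1L) {
  set.seed(as.integer(seed))
  chars <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  flip <- runif(length(chars)) < subRate
  flip[protect] <- FALSE
  flip[chars == "X"] <- FALSE
  chars[flip] <- vapply(chars[flip], function(a)
    sample(setdiff(AA_ALPHABET, a), 1L), character(1))
  paste(chars, collapse = "")
}
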