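#' Molecular weight of a protein
#'
#' Sum of Expasy average residue masses plus one water, in kilodaltons.
#' `X` residues contribute no mass and trigger a warning.
#'
#' @param residues sequence (character or `AAString`).
#' @return molecular weight in kDa.
#' @export
#' @examples
#' molecularWeight("G") * 1000   # free glycine, 75.07 Da
molecularWeight <- function(residues) {
  chars <- .physchemChars(residues)
  if (length(chars) == 0L) stop("empty sequence")
  known <- chars[chars != "X"]
  (sum(.aaResidueMass[known]) + .waterMass) / 1000
}

.physchemChars <- function(residues, warnX = TRUE) {
  s <- toupper(as.character(residues))
  .checkAlphabet(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (warnX && any(chars == "X"))
    warning("sequence contains X; excluded from mass/charge/instability sums")
  chars
}

# Net charge of a protein at a given pH under the Henderson-Hasselbalch
# model with the Bjellqvist pKa set.
.netCharge <- function(counts, pH) {
  posK <- .pkaPositive; negK <- .pkaNegative
  cr <- function(pK) 10^pK / (10^pK + 10^pH)       # protonated fraction
  cr2 <- function(pK) 10^pH / (10^pK + 10^pH)      # deprotonated fraction
  pos <- cr(posK["Nterm"]) +
    sum(counts[c("K", "R", "H")] * cr(posK[c("K", "R", "H")]))
  neg <- cr2(negK["Cterm"]) +
    sum(counts[c("D", "E", "C", "Y")] * cr2(negK[c("D", "E", "C", "Y")]))
  unname(pos - neg)
}

#' Isoelectric point
#'
#' The pH at which the net charge of the protein is zero under the
#' Henderson-Hasselbalch model with the Bjellqvist pKa set used by the
#' Expasy tools (side chains of C, D, E, Y, K, R, H plus both termini).
#' The charge function is strictly decreasing in pH, so the root is unique;
#' it is found by bisection to `tol` pH units.
#'
#' @param residues sequence (character or `AAString`).
#' @param tol bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
#' @examples
#' isoelectricPoint("KKKK") > isoelectricPoint("DDDD")
isoelectricPoint <- function(residues, tol = 1e-4) {
  chars <- .physchemChars(residues, warnX = FALSE)
  if (length(chars) == 0L) stop("empty sequence")
  if (any(chars == "X"))
    warning("sequence contains X; excluded from the charge sum")
  counts <- table(factor(chars, levels = AA_ALPHABET))
  lo <- 0; hi <- 14
  for (i in seq_len(ceiling(log2((hi - lo) / tol)) + 1L)) {
    mid <- (lo + hi) / 2
    if (.netCharge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Percentage of negatively charged residues
#'
#' `100 * (D + E) / length`; `X` counts toward the length.
#'
#' @param residues sequence (character or `AAString`).
#' @return percentage in `[0, 100]`.
#' @export
percentNegative <- function(residues) {
  chars <- .physchemChars(residues, warnX = FALSE)
  if (length(chars) == 0L) stop("empty sequence")
  100 * sum(chars %in% c("D", "E")) / length(chars)
}

#' Percentage of positively charged residues
#'
#' `100 * (R + K) / length`; `X` counts toward the length.
#'
#' @param residues sequence (character or `AAString`).
#' @return percentage in `[0, 100]`.
#' @export
percentPositive <- function(residues) {
  chars <- .physchemChars(residues, warnX = FALSE)
  if (length(chars) == 0L) stop("empty sequence")
  100 * sum(chars %in% c("R", "K")) / length(chars)
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum DIWV(x_i, x_{i+1})` over the `L - 1` dipeptides, using
#' the dipeptide instability weight values of Guruprasad et al. (1990).
#' Proteins with an index below 40 are predicted stable.  Dipeptides
#' containing `X` contribute 0 (the full length is still used).
#'
#' @param residues sequence of length >= 2.
#' @return instability index.
#' @export
#' @examples
#' instabilityIndex("AA")   # 10/2 * DIWV(A, A)
instabilityIndex <- function(residues) {
  chars <- .physchemChars(residues)
  L <- length(chars)
  if (L < 2L) stop("instability index needs at least 2 residues")
  a <- chars[-L]; b <- chars[-1L]
  ok <- a != "X" & b != "X"
  (10 / L) * sum(.diwv[cbind(a[ok], b[ok])])
}

#' Ikai aliphatic index
#'
#' `X(Ala) + 2.9 * X(Val) + 3.9 * (X(Ile) + X(Leu))`, with `X(aa)` the mole
#' percent of the residue.  Interpreted as an indicator of thermostability.
#'
#' @param residues sequence (character or `AAString`).
#' @return aliphatic index.
#' @export
#' @examples
#' aliphaticIndex("AAAA")   # 100
#' aliphaticIndex("VVVV")   # 290
aliphaticIndex <- function(residues) {
  chars <- .physchemChars(residues, warnX = FALSE)
  if (length(chars) == 0L) stop("empty sequence")
  molePct <- 100 * vapply(c("A", "V", "I", "L"),
                          function(a) sum(chars == a), numeric(1)) /
    length(chars)
  unname(molePct["A"] + 2.9 * molePct["V"] +
           3.9 * (molePct["I"] + molePct["L"]))
}

#' Full physicochemical profile
#'
#' All Table-style physicochemical quantities for one sequence.
#'
#' @param residues sequence (character or `AAString`).
#' @return one-row data.frame with columns `length`, `mw_kda`, `pi`,
#'   `pct_neg`, `pct_pos`, `instability`, `stable` (instability < 40) and
#'   `aliphatic`.
#' @export
physchemProfile <- function(residues) {
  s <- toupper(as.character(residues))
  instab <- instabilityIndex(s)
  data.frame(length = nchar(s),
             mw_kda = molecularWeight(s),
             pi = isoelectricPoint(s),
             pct_neg = percentNegative(s),
             pct_pos = percentPositive(s),
             instability = instab,
             stable = instab < 40,
             aliphatic = aliphaticIndex(s))
}
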