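#' Read protein sequences from FASTA
#'
#' Order-preserving reader built on [Biostrings::readAAStringSet()].
#' Multi-line records are concatenated and the description line is split at
#' the first whitespace into a sequence identifier and a free-text
#' description, stored in the element metadata.
#'
#' Residues must be uppercase letters from the 20 amino-acid alphabet; `X`
#' is accepted as an ambiguity code.  Any other letter is an error naming
#' the record and position.
#'
#' @param path path to a FASTA file.
#' @return an [Biostrings::AAStringSet] named by sequence identifier, with
#'   `mcols()` columns `seq_id` and `description`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 a protein", "ACDEF", ">p2", "GHIKL"), f)
#' readFasta(f)
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
  }
  full <- names(seqs)
  seq_id <- sub("\\s.*$", "", full)
  description <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(seq_id))
    stop("duplicate sequence identifiers in ", path, ": ",
         paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "))
  txt <- as.character(seqs)
  for (i in seq_along(txt)) .checkAlphabet(txt[i], seq_id[i])
  out <- Biostrings::AAStringSet(txt)
  names(out) <- seq_id
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(seq_id = seq_id,
                                               description = description)
  out
}

#' Write protein sequences to FASTA
#'
#' Writes 60-column-wrapped FASTA with deterministic byte output for a fixed
#' input set.
#'
#' @param records an [Biostrings::AAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
  if (is.character(records)) records <- Biostrings::AAStringSet(records)
  if (anyDuplicated(names(records)))
    stop("duplicate sequence identifiers")
  Biostrings::writeXStringSet(records, filepath = path, width = 60L)
  invisible(path)
}

#' Read per-sequence metadata
#'
#' Reads a tab-separated metadata table with a header row.  Recognised
#' columns are `seq_id`, `taxon`, `lineage_class` (`cyanobacteria` or
#' `eukaryote`), `habitat`, `exon_count` and `group_label`; other columns
#' are kept as-is.  Habitat codes are normalised to `S` (soil), `FW` (fresh
#' water), `M` (marine) or `mixed`: compound codes such as `FW/M` become
#' `mixed`, and qualified codes such as `Acidic FW` keep their base code.
#'
#' @param path path to a TSV file with a `seq_id` column.
#' @param seq_ids optional character vector of known sequence identifiers;
#'   metadata rows for unknown identifiers trigger a warning.
#' @return a data.frame keyed by `seq_id`.
#' @export
readMetadata <- function(path, seq_ids = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed TSV ", path, ": ", conditionMessage(e)))
  if (!"seq_id" %in% names(md))
    stop("metadata must contain a 'seq_id' column (line 1)")
  if ("habitat" %in% names(md)) {
    md$habitat <- normalizeHabitat(md$habitat)
  }
  if (!is.null(seq_ids)) {
    unknown <- setdiff(md$seq_id, seq_ids)
    if (length(unknown))
      warning("metadata rows for unknown seq_ids: ",
              paste(unknown, collapse = ", "))
  }
  md
}

#' Normalise habitat codes
#'
#' @param x character vector of habitat codes.
#' @return character vector over `S`, `FW`, `M`, `mixed` (unrecognised codes
#'   are returned unchanged with a warning).
#' @export
#' @examples
#' normalizeHabitat(c("S", "FW/M", "Acidic FW", "M"))
normalizeHabitat <- function(x) {
  out <- vapply(as.character(x), function(h) {
    h0 <- trimws(h)
    if (grepl("/", h0, fixed = TRUE)) return("mixed")
    parts <- strsplit(h0, "\\s+")[[1]]
    base <- parts[length(parts)]
    if (base %in% c("S", "FW", "M")) return(base)
    h0
  }, character(1), USE.NAMES = FALSE)
  bad <- setdiff(unique(out), c("S", "FW", "M", "mixed"))
  if (length(bad)) warning("unrecognised habitat codes kept verbatim: ",
                           paste(bad, collapse = ", "))
  out
}

#' Documented column order of the annotation table
#'
#' The physicochemical columns mirror the published per-accession table
#' (form string, length, MW, C--H and H--D spacings, Cys count, pI, %neg,
#' %pos, instability + stability flag, aliphatic index) with the
#' classification columns appended.
#'
#' @format character vector of column names.
#' @export
ANNOTATION_COLUMNS <- c(
  "seq_id", "form", "length", "mw_kda", "c_h_distance", "h_d_distance",
  "cys_count", "pi", "pct_neg", "pct_pos", "instability", "stable",
  "aliphatic", "subtype", "group", "ck2", "cc", "cxxxc", "conserved_cys",
  "cterm_tail")

#' Write the annotation table
#'
#' Writes the Table-1-style annotation data.frame produced by
#' [runAnnotate()] as a UTF-8, LF, tab-separated file with a header row.
#'
#' @param annotation a data.frame with the columns listed in
#'   `PCSkit::ANNOTATION_COLUMNS` (additional metadata columns are kept).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTable <- function(annotation, path) {
  missing <- setdiff(ANNOTATION_COLUMNS, names(annotation))
  if (length(missing))
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "))
  ord <- c(ANNOTATION_COLUMNS, setdiff(names(annotation), ANNOTATION_COLUMNS))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(annotation[, ord, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Bootstrap supports, when present as `node.label`, are written as
#' internal-node labels.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a truth table for synthetic scaffolds
#'
#' @param truth data.frame as produced by [generatePcsDataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
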