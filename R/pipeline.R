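#' Build and validate a pipeline configuration
#'
#' Collects every setting of the analysis pipeline.  Can be loaded from a
#' YAML file and overridden with arguments; paths are checked at validation
#' time, before any stage runs.
#'
#' @param input path to the input FASTA file.
#' @param metadata optional path to a metadata TSV (see [readMetadata()]).
#' @param outputDir directory for all outputs (created if needed).
#' @param triadMode `"auto"`, `"align"` or `"scan"` (see [detectTriad()]).
#' @param chBounds admissible Cys--His spacing range for the scan path.
#' @param references optional list: `fasta` and `triad` paths of a
#'   user-supplied annotated reference set.
#' @param bootstrap number of bootstrap replicates for the tree stage.
#' @param distanceCap saturated-pair distance cap.
#' @param nMotifs,wMin,wMax,motifModel motif-stage settings (see
#'   [discoverMotifs()]).
#' @param grouping grouping column for the statistics stage.
#' @param seed integer seed for all stochastic stages.
#' @param yamlFile optional YAML file with any of the above fields;
#'   explicit arguments win.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(input = NULL, metadata = NULL,
                           outputDir = "pcskit_out",
                           triadMode = "auto", chBounds = c(90L, 160L),
                           references = NULL, bootstrap = 100L,
                           distanceCap = 10, nMotifs = 15L, wMin = 6L,
                           wMax = 50L, motifModel = "zoops",
                           grouping = "group", seed = 1L,
                           yamlFile = NULL) {
  cfg <- list(input = input, metadata = metadata, outputDir = outputDir,
              triadMode = triadMode, chBounds = chBounds,
              references = references, bootstrap = bootstrap,
              distanceCap = distanceCap, nMotifs = nMotifs, wMin = wMin,
              wMax = wMax, motifModel = motifModel, grouping = grouping,
              seed = seed)
  if (!is.null(yamlFile)) {
    if (!file.exists(yamlFile)) stop("config file not found: ", yamlFile)
    fromFile <- yaml::read_yaml(yamlFile)
    explicit <- names(as.list(match.call())[-1])
    for (k in setdiff(names(fromFile), c(explicit, "yamlFile")))
      cfg[[k]] <- fromFile[[k]]
  }
  if (is.null(cfg$input)) stop("config needs an input FASTA path")
  if (!file.exists(cfg$input)) stop("input FASTA not found: ", cfg$input)
  if (!is.null(cfg$metadata) && !file.exists(cfg$metadata))
    stop("metadata file not found: ", cfg$metadata)
  if (!cfg$triadMode %in% c("auto", "align", "scan"))
    stop("triadMode must be auto, align or scan")
  if (!is.null(cfg$references)) {
    for (p in unlist(cfg$references))
      if (!file.exists(p)) stop("reference file not found: ", p)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Annotate a sequence set
#'
#' One row per input sequence: the 7-mer form string, length, molecular
#' weight, Cys--His and His--Asp spacings, cysteine count, pI, charge
#' percentages, instability (+ stability flag), aliphatic index, subtype,
#' group, CK2 call, conserved-cysteine hits and C-terminal tail length.
#' Sequences with no acceptable triad keep their physicochemical columns
#' and get `NA` in the triad-dependent ones (with a warning); the run
#' continues.
#'
#' @param config a [pipelineConfig()] (or a list with at least `input`).
#' @return the annotation data.frame (columns in
#'   `PCSkit::ANNOTATION_COLUMNS`, plus metadata columns when a metadata
#'   table is configured).
#' @export
runAnnotate <- function(config) {
  seqs <- readFasta(config$input)
  refs <- if (!is.null(config$references))
    readReferenceSet(config$references$fasta, config$references$triad)
  else NULL
  rows <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    prof <- physchemProfile(s)
    tri <- tryCatch(
      detectTriad(s, references = refs, mode = config$triadMode,
                  chBounds = config$chBounds),
      error = function(e) .triadNone())
    base <- data.frame(seq_id = names(seqs)[i], stringsAsFactors = FALSE)
    if (triadFound(tri)) {
      call <- classifyIsoform(s, tri)
      data.frame(base, form = context7(tri), length = prof$length,
                 mw_kda = prof$mw_kda, c_h_distance = chDistance(tri),
                 h_d_distance = hdDistance(tri), cys_count = call@cysTotal,
                 pi = prof$pi, pct_neg = prof$pct_neg,
                 pct_pos = prof$pct_pos, instability = prof$instability,
                 stable = prof$stable, aliphatic = prof$aliphatic,
                 subtype = call@subtype,
                 group = ifelse(is.na(call@group), NA_integer_, call@group),
                 ck2 = call@ck2Competent,
                 cc = paste(call@ccHits, collapse = ";"),
                 cxxxc = paste(call@cxxxcHits, collapse = ";"),
                 conserved_cys = call@conservedCysCount,
                 cterm_tail = call@ctermTailLength,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(base, form = NA_character_, length = prof$length,
                 mw_kda = prof$mw_kda, c_h_distance = NA_integer_,
                 h_d_distance = NA_integer_, cys_count = countCys(s),
                 pi = prof$pi, pct_neg = prof$pct_neg,
                 pct_pos = prof$pct_pos, instability = prof$instability,
                 stable = prof$stable, aliphatic = prof$aliphatic,
                 subtype = NA_character_, group = NA_integer_, ck2 = NA,
                 cc = NA_character_, cxxxc = NA_character_,
                 conserved_cys = NA_integer_, cterm_tail = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  ann <- do.call(rbind, rows)
  if (!is.null(ann) && any(is.na(ann$form)))
    warning("no triad found for: ",
            paste(ann$seq_id[is.na(ann$form)], collapse = ", "))
  if (length(seqs) == 0L) {
    warning("empty input: empty annotation table")
    ann <- stats::setNames(
      data.frame(matrix(ncol = length(ANNOTATION_COLUMNS), nrow = 0)),
      ANNOTATION_COLUMNS)
  }
  if (!is.null(config$metadata)) {
    md <- readMetadata(config$metadata, seq_ids = ann$seq_id)
    ann <- merge(ann, md, by = "seq_id", all.x = TRUE, sort = FALSE)
    ann <- ann[match(names(seqs), ann$seq_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

#' Run the full analysis pipeline
#'
#' Annotation, reference-anchored stacked alignment with JTT-distance NJ
#' tree and bootstrap supports, ZOOPS motif discovery with presence table,
#' and the group-comparison statistics.  All outputs are written under
#' `config$outputDir` together with a manifest of MD5 checksums; the run is
#' deterministic for fixed seeds, and a failing stage is reported while the
#' remaining stages still run.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with `annotation`, `tree`, `motifs`,
#'   `presence`, `stats`, `manifest` and `errors` (named character vector
#'   of per-stage failures, empty on a clean run).
#' @export
runAll <- function(config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  outs <- character(0)
  errors <- character(0)
  res <- list()

  res$annotation <- runAnnotate(config)
  p <- file.path(config$outputDir, "annotation.tsv")
  writeAnnotationTable(res$annotation, p); outs <- c(outs, p)

  seqs <- readFasta(config$input)
  tryCatch({
    aln <- stackAlignment(seqs)
    tree <- bootstrapSupports(aln, nReplicates = config$bootstrap,
                              seed = config$seed, cap = config$distanceCap)
    res$tree <- tree
    p <- file.path(config$outputDir, "tree.nwk")
    writeNewickTree(tree, p); outs <- c(outs, p)
  }, error = function(e) errors["phylo"] <<- conditionMessage(e))

  tryCatch({
    res$motifs <- discoverMotifs(seqs, nMotifs = config$nMotifs,
                                 wMin = config$wMin, wMax = config$wMax,
                                 model = config$motifModel,
                                 seed = config$seed)
    p <- file.path(config$outputDir, "motifs.txt")
    writeMotifReport(res$motifs, p); outs <- c(outs, p)
    if (length(res$motifs)) {
      res$presence <- motifPresenceTable(res$motifs, seqs)
      p <- file.path(config$outputDir, "motif_presence.tsv")
      utils::write.table(res$presence, p, sep = "\t", quote = FALSE,
                         col.names = NA)
      outs <- c(outs, p)
    }
  }, error = function(e) errors["motifs"] <<- conditionMessage(e))

  tryCatch({
    grp <- res$annotation[[config$grouping]]
    if (length(unique(grp[!is.na(grp)])) == 2L) {
      res$stats <- statsReport(res$annotation, grouping = config$grouping)
      p <- file.path(config$outputDir, "stats.tsv")
      utils::write.table(res$stats, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outs <- c(outs, p)
    }
  }, error = function(e) errors["stats"] <<- conditionMessage(e))

  res$manifest <- data.frame(file = basename(outs),
                             md5 = unname(tools::md5sum(outs)),
                             stringsAsFactors = FALSE)
  utils::write.table(res$manifest,
                     file.path(config$outputDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$errors <- errors
  if (length(errors))
    warning("stages failed: ", paste(names(errors), collapse = ", "))
  invisible(res)
}
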