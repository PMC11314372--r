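#' Compare a physicochemical parameter between two groups
#'
#' Two-sided Student's t-test with pooled variance, preceded by the
#' assumption checks used for this kind of comparison: Shapiro-Wilk
#' normality per group and Levene's test (centered on the mean) for
#' variance homogeneity.  Assumption violations are flagged, not fatal --
#' the t-test is always reported.
#'
#' @param profileTable data.frame with one row per sequence.
#' @param grouping name of a two-level grouping column (e.g. `"group"` for
#'   the isoform groups, or `"lineage_class"` for cyanobacteria vs
#'   eukaryotes).  Rows with `NA` group are dropped.
#' @param parameter name of the numeric column to compare.
#' @param alphaAssume significance level for the assumption checks.
#' @param welch use the Welch (unpooled) form instead of pooled-variance
#'   Student's t.
#' @return one-row data.frame: `parameter`, `grouping`, `level1`, `level2`,
#'   `mean1`, `mean2`, `n1`, `n2`, `t`, `df`, `p`, `shapiro_p1`,
#'   `shapiro_p2`, `levene_p`, `assumptions_ok`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 5),
#'                  v = c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6))
#' compareGroups(df, "g", "v")$p
compareGroups <- function(profileTable, grouping, parameter,
                          alphaAssume = 0.05, welch = FALSE) {
  g <- profileTable[[grouping]]
  y <- profileTable[[parameter]]
  keep <- !is.na(g) & !is.na(y)
  g <- factor(g[keep]); y <- y[keep]
  levs <- levels(g)
  if (length(levs) != 2L) stop("grouping must have exactly two levels")
  y1 <- y[g == levs[1]]; y2 <- y[g == levs[2]]
  if (length(y1) < 2L || length(y2) < 2L)
    stop("each group needs at least 2 members")
  sw <- function(v) {
    if (length(unique(v)) == 1L) return(NA_real_)   # constant: undefined
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  sp1 <- sw(y1); sp2 <- sw(y2)
  lev <- tryCatch(
    car::leveneTest(y ~ g, center = "mean")[1, "Pr(>F)"],
    error = function(e) NA_real_)
  tt <- stats::t.test(y1, y2, var.equal = !welch)
  ok <- !anyNA(c(sp1, sp2, lev)) && all(c(sp1, sp2, lev) > alphaAssume)
  data.frame(parameter = parameter, grouping = grouping,
             level1 = levs[1], level2 = levs[2],
             mean1 = mean(y1), mean2 = mean(y2),
             n1 = length(y1), n2 = length(y2),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, shapiro_p1 = sp1, shapiro_p2 = sp2,
             levene_p = unname(lev), assumptions_ok = ok,
             stringsAsFactors = FALSE)
}

#' Per-group descriptive statistics
#'
#' Mean, standard deviation and n of every numeric column, per level of the
#' grouping column.
#'
#' @param profileTable data.frame with one row per sequence.
#' @param grouping name of the grouping column.
#' @return data.frame with one row per (group, parameter).
#' @export
summarizeByGroup <- function(profileTable, grouping = "group") {
  if (nrow(profileTable) == 0L) stop("empty profile table")
  g <- profileTable[[grouping]]
  nums <- names(profileTable)[vapply(profileTable, is.numeric, logical(1))]
  nums <- setdiff(nums, grouping)
  out <- list()
  for (lev in unique(g[!is.na(g)])) {
    sub <- profileTable[!is.na(g) & g == lev, , drop = FALSE]
    for (p in nums) {
      v <- sub[[p]][!is.na(sub[[p]])]
      out[[length(out) + 1L]] <- data.frame(
        group = lev, parameter = p, mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run all group comparisons of the annotation table
#'
#' Applies [compareGroups()] to each physicochemical parameter for one
#' grouping, collecting the reports into a table.
#'
#' @param annotation annotation data.frame from [runAnnotate()].
#' @param grouping grouping column (default the isoform `group`).
#' @param parameters parameter columns to test.
#' @param alphaAssume assumption-check significance level.
#' @return data.frame with one row per parameter.
#' @export
statsReport <- function(annotation, grouping = "group",
                        parameters = c("length", "mw_kda", "pi", "pct_neg",
                                       "pct_pos", "instability",
                                       "aliphatic"),
                        alphaAssume = 0.05) {
  do.call(rbind, lapply(parameters, function(p)
    compareGroups(annotation, grouping, p, alphaAssume = alphaAssume)))
}
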