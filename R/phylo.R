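#' Pairwise maximum-likelihood distance under the JTT model
#'
#' Finds the divergence `t` maximizing the log-likelihood
#' `sum_sites log(pi_a * P_ab(t))` with `P(t) = exp(Qt)` and `Q` the JTT
#' rate matrix scaled to one expected substitution per site per unit `t`.
#' Sites where either sequence carries `X` or a gap (`-`) are removed
#' pairwise before fitting; identical overlapping sequences give distance 0.
#'
#' @param seqA,seqB equal-length sequences (character; may contain `-`/`X`).
#' @param cap maximum reported distance for saturated pairs.
#' @param tol optimizer tolerance on `t`.
#' @return list with `distance` (substitutions per site), `sites` (number of
#'   overlapping sites used) and `se` (curvature-based standard error, `NA`
#'   for boundary fits).  `distance` is `NA` with a warning when no sites
#'   overlap.
#' @export
#' @examples
#' p <- evolvePair(2000, t = 0.2, seed = 1)
#' jttMlDistance(p$ancestor, p$descendant)$distance
jttMlDistance <- function(seqA, seqB, cap = 10, tol = 1e-6) {
  a <- .s2i(toupper(as.character(seqA)))
  b <- .s2i(toupper(as.character(seqB)))
  if (length(a) != length(b))
    stop("sequences must have equal (aligned) length")
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) {
    warning("no overlapping sites; distance undefined")
    return(list(distance = NA_real_, sites = 0L, se = NA_real_))
  }
  a <- a[keep]; b <- b[keep]
  nSites <- length(a)
  counts <- matrix(0, 20, 20)
  tab <- table(a, b)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
  pi0 <- jttEquilibrium()
  negll <- function(t) {
    p <- jttProbMatrix(t)
    lik <- pi0 * p                      # joint probability of each pair
    -sum(counts * log(pmax(lik, 1e-300)))
  }
  if (all(a == b)) return(list(distance = 0, sites = nSites, se = NA_real_))
  opt <- optimize(negll, interval = c(1e-8, cap), tol = tol)
  t_hat <- opt$minimum
  # curvature-based SE from a central second difference
  h <- max(1e-4, t_hat * 1e-3)
  d2 <- (negll(t_hat + h) - 2 * opt$objective + negll(t_hat - h)) / h^2
  se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else NA_real_
  if (t_hat > cap - 10 * tol) {
    t_hat <- cap
    se <- NA_real_
  }
  list(distance = t_hat, sites = nSites, se = se)
}

#' Pairwise JTT ML distance matrix
#'
#' @param aln aligned sequences: equal-length named character vector,
#'   [Biostrings::AAStringSet], or character matrix (rows = sequences).
#' @param cap saturated-pair distance cap.
#' @return symmetric distance matrix with zero diagonal, labelled by
#'   sequence name.  Pairs with no overlapping sites are `NA` (flagged by a
#'   warning in [jttMlDistance()]).
#' @export
jttDistanceMatrix <- function(aln, cap = 10) {
  m <- .asAlnMatrix(aln)
  n <- nrow(m)
  labs <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d[i, j] <- d[j, i] <- jttMlDistance(
        paste(m[i, ], collapse = ""), paste(m[j, ], collapse = ""),
        cap = cap)$distance
    }
  }
  d
}

.asAlnMatrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- aln
  } else {
    txt <- .asNamedChar(aln)
    if (length(unique(nchar(txt))) != 1L)
      stop("sequences must be aligned (equal length)")
    m <- do.call(rbind, strsplit(txt, "", fixed = TRUE))
    rownames(m) <- names(txt)
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("seq_%03d", seq_len(nrow(m)))
  m
}

#' Neighbor-joining tree
#'
#' Classical neighbor joining (Saitou--Nei agglomeration with the
#' Studier--Keppler criterion, as implemented in [ape::nj()]) on a distance
#' matrix; exact on additive matrices.  Negative branch lengths are clamped
#' to zero with a message.
#'
#' @param d symmetric distance matrix with labels.
#' @return an unrooted [ape::phylo] tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(d)) stop("distance matrix contains NA (undefined pairs)")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    message(sum(tree$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the JTT-distance
#' NJ tree per replicate, and reports for each internal edge of the full
#' tree the percentage of replicates containing the same bipartition.
#' With fewer than two distinct columns the supports are undefined and
#' reported as `NA`.
#'
#' @param aln aligned sequences (see [jttDistanceMatrix()]).
#' @param nReplicates number of bootstrap replicates.
#' @param seed integer seed (fixed seed gives identical supports).
#' @param cap saturated-pair distance cap.
#' @return the NJ tree of the full alignment with `node.label` set to the
#'   support percentages (`NA` for the root node).
#' @export
bootstrapSupports <- function(aln, nReplicates = 100L, seed = 1L, cap = 10) {
  m <- .asAlnMatrix(aln)
  base <- njTree(jttDistanceMatrix(m, cap = cap))
  set.seed(as.integer(seed))
  reps <- vector("list", nReplicates)
  for (b in seq_len(nReplicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    # replicate trees only contribute bipartitions; clamping chatter off
    reps[[b]] <- suppressMessages(
      njTree(jttDistanceMatrix(m[, cols, drop = FALSE], cap = cap)))
  }
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  supports <- 100 * counts / nReplicates
  base$node.label <- supports
  base
}

#' Support for the bipartition separating two label sets
#'
#' Convenience lookup: returns the bootstrap support attached to the edge
#' that splits `groupA` from the remaining taxa, or `NA` when the tree does
#' not contain that bipartition.
#'
#' @param tree a tree with `node.label` supports from [bootstrapSupports()].
#' @param groupA character vector of tip labels on one side of the split.
#' @return support percentage, or `NA`.
#' @export
splitSupport <- function(tree, groupA) {
  tips <- tree$tip.label
  groupA <- intersect(groupA, tips)
  groupB <- setdiff(tips, groupA)
  if (!length(groupA) || !length(groupB)) return(NA_real_)
  nTip <- length(tips)
  # find the internal node whose descendant tip set is groupA or groupB
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    out <- integer(0)
    for (k in kids) out <- c(out, if (k <= nTip) k else desc(k))
    out
  }
  for (node in (nTip + 1L):(nTip + tree$Nnode)) {
    dt <- sort(tips[desc(node)])
    if (identical(dt, sort(groupA)) || identical(dt, sort(groupB))) {
      lab <- tree$node.label[node - nTip]
      return(suppressWarnings(as.numeric(lab)))
    }
  }
  NA_real_
}

#' Reference-anchored stacked alignment
#'
#' Builds a fixed-width alignment by aligning every sequence to one
#' reference with [alignGlobal()] and stacking the reference columns:
#' query residues aligned to a reference position fill that column,
#' reference deletions become gaps, and query insertions relative to the
#' reference are dropped.  Adequate for the conserved catalytic domain; a
#' user-supplied multiple alignment can be used instead wherever an `aln`
#' argument is accepted.
#'
#' @param seqs named character vector or [Biostrings::AAStringSet].
#' @param reference reference sequence (character); defaults to the longest
#'   input sequence.
#' @return character matrix (rows = sequences, columns = reference
#'   positions) suitable for [jttDistanceMatrix()].
#' @export
stackAlignment <- function(seqs, reference = NULL) {
  txt <- .asNamedChar(seqs)
  if (is.null(reference)) reference <- txt[[which.max(nchar(txt))]]
  refLen <- nchar(reference)
  m <- matrix("-", length(txt), refLen,
              dimnames = list(names(txt), NULL))
  for (i in seq_along(txt)) {
    aln <- alignGlobal(txt[[i]], reference)
    qa <- strsplit(aln$alignedQuery, "", fixed = TRUE)[[1]]
    ra <- strsplit(aln$alignedReference, "", fixed = TRUE)[[1]]
    keep <- ra != "-"
    m[i, ] <- qa[keep]
  }
  m
}
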