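# Shared construction for the two-cluster grouping experiments: an "N"
# ancestor and an "E" ancestor, each giving rise to a clade of lightly
# mutated descendants (triad and context positions protected).

twoClusterData <- function(nPer = 4, subRate = 0.08, seed = 1,
                           ctermLenE = 120L) {
  ancN <- generatePcsSequence(
    scaffoldSpec("N", chSpacing = 112L, ctermLen = 40L, seed = seed),
    seq_id = "ancN")
  ancE <- generatePcsSequence(
    scaffoldSpec("E", chSpacing = 106L, ctermLen = ctermLenE,
                 seed = seed + 1L), seq_id = "ancE")
  protectOf <- function(truth) {
    c((truth$cys_pos - 7L):(truth$cys_pos + 1L),
      truth$his_pos, truth$asp_pos,
      truth$cc, truth$cc + 1L, truth$cxxxc, truth$cxxxc + 4L)
  }
  seqs <- character(0)
  for (i in seq_len(nPer)) {
    seqs[sprintf("g1_%02d", i)] <- mutateSequence(
      ancN$seq, subRate, protect = protectOf(ancN$truth)[
        !is.na(protectOf(ancN$truth))], seed = seed + 10L + i)
    seqs[sprintf("g2_%02d", i)] <- mutateSequence(
      ancE$seq, subRate, protect = protectOf(ancE$truth)[
        !is.na(protectOf(ancE$truth))], seed = seed + 40L + i)
  }
  list(seqs = seqs, truthN = ancN$truth, truthE = ancE$truth)
}

twoClusterTree <- function(nPer = 4, bootstrap = 50, seed = 1, ...) {
  dat <- twoClusterData(nPer = nPer, seed = seed, ...)
  aln <- stackAlignment(dat$seqs, reference = dat$seqs[["g2_01"]])
  bootstrapSupports(aln, nReplicates = bootstrap, seed = seed)
}
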