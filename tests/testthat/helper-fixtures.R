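## Shared fixtures: everything is generated in code at test time.

uniformPi <- rep(1 / 61, 61)

treeFromText <- function(txt, ...) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(txt, tf)
  readLabeledTree(tf, ...)
}

alnFromSeqs <- function(seqs, ...) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), tf)
  readCodonAlignment(tf, ...)
}

## 7-taxon snake-like study tree: two non-snake outgroups, one henophidian,
## two diurnal and two nocturnal colubrids
snakeTreeText <- paste0("((Out1:0.3,Out2:0.25):0.1,(Heno1:0.15,((D1:0.08,",
                        "D2:0.1):0.06,(N1:0.09,N2:0.11):0.05):0.08):0.1);")
snakeTree <- function() treeFromText(snakeTreeText)

snakeTable <- function() {
  data.frame(
    species = c("Out1", "Out2", "Heno1", "D1", "D2", "N1", "N2"),
    activity = c("diurnal", "diurnal", "nocturnal", "diurnal", "diurnal",
                 "nocturnal", "nocturnal"),
    clade = c("non-snake", "non-snake", "henophidian", "colubrinae",
              "colubrinae", "dipsadinae", "dipsadinae"),
    stringsAsFactors = FALSE)
}

snakeTableFile <- function() {
  tf <- tempfile(fileext = ".tsv")
  tab <- snakeTable()
  writeLines(c("# fixture activity table",
               paste(c("species", "activity", "clade"), collapse = "\t"),
               apply(tab, 1, paste, collapse = "\t")), tf)
  tf
}

## Independent brute-force likelihood oracle: enumerates all internal-node
## state assignments; transition matrices via Matrix::expm on the unit-rate
## generator (no shared code with the pruning path beyond the generator).
bruteForceLogLik <- function(aln, tree, kappa, omega, pi,
                             omegaByBranch = NULL) {
  phy <- tree@phy
  nTip <- length(phy$tip.label)
  nInt <- phy$Nnode
  edges <- phy$edge
  Pe <- lapply(seq_len(nrow(edges)), function(e) {
    w <- if (is.null(omegaByBranch)) omega else omegaByBranch[e]
    Q <- buildRateMatrix(kappa, w, pi, scale = TRUE)
    as.matrix(Matrix::expm(Q * phy$edge.length[e]))
  })
  cells <- aln@cells[match(phy$tip.label, aln@taxa), , drop = FALSE]
  root <- nTip + 1L
  total <- 0
  for (j in seq_len(ncol(cells))) {
    grid <- as.matrix(expand.grid(rep(list(1:61), nInt)))
    siteL <- 0
    for (g in seq_len(nrow(grid))) {
      assign <- grid[g, ]
      term <- pi[assign[root - nTip]]
      for (e in seq_len(nrow(edges))) {
        p <- assign[edges[e, 1] - nTip]
        ch <- edges[e, 2]
        term <- term * if (ch <= nTip)
          sum(Pe[[e]][p, cells[[ch, j]]]) else Pe[[e]][p, assign[ch - nTip]]
        if (term == 0) break
      }
      siteL <- siteL + term
    }
    total <- total + log(siteL)
  }
  total
}

## Count pairwise nonsynonymous codon differences in an alignment
countNonsynDiffs <- function(aln) {
  tab <- opselect:::codonTable()
  n <- 0L
  for (i in seq_len(length(aln@taxa) - 1)) for (k in (i + 1):length(aln@taxa))
    for (j in seq_len(ncol(aln@cells))) {
      a <- aln@cells[[i, j]]; b <- aln@cells[[k, j]]
      if (length(a) == 1L && length(b) == 1L && tab$aa[a] != tab$aa[b])
        n <- n + 1L
    }
  n
}
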