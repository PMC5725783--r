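test_that("rate matrix has GY94 structure", {
  pi <- uniformPi
  Q <- buildRateMatrix(2, 0.5, pi)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)

  ## kappa = omega = 1, uniform pi: all single-step rates equal
  Q1 <- buildRateMatrix(1, 1, pi)
  off <- Q1[row(Q1) != col(Q1)]
  expect_length(unique(round(off[off > 0], 12)), 1L)

  ## AAA->AAG is a synonymous transition, AAA->AAT a nonsynonymous
  ## transversion: ratio = kappa * pi_AAG / (omega * pi_AAT)
  piR <- local({ set.seed(9); x <- rgamma(61, 2); x / sum(x) })
  kappa <- 3.2; omega <- 0.27
  Q2 <- buildRateMatrix(kappa, omega, piR)
  tab <- opselect:::codonTable()
  i <- tab$index[["AAA"]]; jG <- tab$index[["AAG"]]; jT <- tab$index[["AAT"]]
  expect_equal(Q2[i, jG] / Q2[i, jT],
               kappa * piR[jG] / (omega * piR[jT]), tolerance = 1e-10)

  expect_error(buildRateMatrix(2, 0.5, rep(1, 61)), "simplex")
  expect_error(buildRateMatrix(-1, 0.5, uniformPi), "kappa")
})

test_that("transition matrices are stochastic, reversible and converge to pi", {
  piR <- local({ set.seed(11); x <- rgamma(61, 2); x / sum(x) })
  Q <- buildRateMatrix(2.4, 0.3, piR)
  expect_equal(transitionMatrix(Q, 0), diag(61), ignore_attr = TRUE,
               tolerance = 1e-10)
  P <- transitionMatrix(Q, 0.7)
  expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-10)
  ## detailed balance: pi_i P_ij symmetric in (i, j)
  flux <- piR * P
  expect_equal(max(abs(flux - t(flux))), 0, tolerance = 1e-10)
  ## every row approaches pi for large t
  P200 <- transitionMatrix(Q, 200)
  expect_lt(max(abs(sweep(P200, 2, piR))), 1e-8)
  expect_error(transitionMatrix(Q, -1), "non-negative")
})

test_that("codon frequency estimators return valid simplexes", {
  expect_equal(codonFrequencies(NULL, "uniform"), rep(1 / 61, 61),
               ignore_attr = TRUE)
  ## F61 with pseudocount eps on an all-AAA alignment: (n + eps)/(n + 61 eps)
  al <- alnFromSeqs(c(A = "AAAAAA", B = "AAAAAA"))
  f61 <- codonFrequencies(al, "F61", pseudocount = 0.5)
  expect_equal(unname(f61[["AAA"]]), (4 + 0.5) / (4 + 61 * 0.5))
  expect_equal(sum(f61), 1)
  ## F3x4 recovers positional nucleotide frequencies from simulated data
  tr <- treeFromText("(A:0.05,B:0.05);")
  piTrue <- codonFrequencies(NULL, "uniform")
  piTrue <- piTrue * seq(1, 3, length.out = 61); piTrue <- piTrue / sum(piTrue)
  sim <- simulateCodonAlignment(tr, 4000, pi = piTrue, seed = 3)
  f34 <- codonFrequencies(sim$alignment, "F3x4")
  expect_equal(sum(f34), 1)
  tab <- opselect:::codonTable()
  ntOf <- function(p, pivec) vapply(c("A", "C", "G", "T"), function(n)
    sum(pivec[substring(tab$codons, p, p) == n]), numeric(1))
  for (p in 1:3)
    expect_lt(max(abs(ntOf(p, unname(f34)) - ntOf(p, piTrue))), 0.03)
})

test_that("pruning equals brute-force enumeration on small random instances", {
  set.seed(71)
  trees <- c("(A:0.2,B:0.35);",
             "(A:0.21,B:0.08,C:0.5);",
             "((A:0.15,B:0.3):0.1,C:0.2,D:0.4);")
  for (rep in 1:4) {
    for (tx in trees) {
      tr <- treeFromText(tx)
      nTaxa <- length(taxa(tr))
      L <- sample(1:3, 1)
      cells <- matrix(vector("list", nTaxa * L), nTaxa,
                      dimnames = list(taxa(tr), NULL))
      for (i in seq_len(nTaxa)) for (j in seq_len(L))
        cells[[i, j]] <- sort(sample(61,
          if (i == 1) 1 else sample(c(1, 1, 2, 61), 1)))
      al <- new("CodonAlignment", taxa = taxa(tr), cells = cells,
                ntLength = 3L * L)
      kappa <- runif(1, 0.5, 5); omega <- runif(1, 0.05, 3)
      piR <- local({ x <- rgamma(61, 1.5); x / sum(x) })
      expect_equal(codonLogLik(al, tr, kappa, piR, omega),
                   bruteForceLogLik(al, tr, kappa, omega, piR),
                   tolerance = 1e-8)
    }
  }
})

test_that("pruning matches the oracle under branch-heterogeneous omega", {
  set.seed(72)
  tr <- treeFromText("((A:0.15,B:0.3):0.1,C:0.2,D:0.4);")
  part <- new("BranchPartition", classes = branchIds(tr),
              assignment = stats::setNames(seq_along(branchIds(tr)),
                                           branchIds(tr)),
              foreground = character(0))
  omega <- stats::setNames(runif(length(branchIds(tr)), 0.05, 2),
                           branchIds(tr))
  cells <- matrix(vector("list", 8), 4, dimnames = list(taxa(tr), NULL))
  for (i in 1:4) for (j in 1:2) cells[[i, j]] <- sort(sample(61, 1))
  al <- new("CodonAlignment", taxa = taxa(tr), cells = cells, ntLength = 6L)
  omegaByEdge <- unname(omega[tr@branchIds])
  expect_equal(codonLogLik(al, tr, 2.1, uniformPi, omega, partition = part),
               bruteForceLogLik(al, tr, 2.1, NULL, uniformPi,
                                omegaByBranch = omegaByEdge),
               tolerance = 1e-8)
})

test_that("degenerate and invariant likelihood cases behave", {
  ## identical 1-codon sequences on a zero-length star: log pi(codon)
  tr0 <- treeFromText("(A:0,B:0,C:0);")
  al0 <- alnFromSeqs(c(A = "AAA", B = "AAA", C = "AAA"))
  expect_equal(codonLogLik(al0, tr0, 2, uniformPi, 0.5), log(1 / 61))

  ## a two-class mixture with identical omegas equals the single-class value
  tr <- snakeTree()
  sim <- simulateCodonAlignment(tr, 40, seed = 21)
  llSingle <- codonLogLik(sim$alignment, tr, 2, uniformPi, 0.3)
  llMix <- codonLogLik(sim$alignment, tr, 2, uniformPi,
                       mixture = list(list(prop = 0.4, omega = 0.3),
                                      list(prop = 0.6, omega = 0.3)))
  expect_equal(llMix, llSingle, tolerance = 1e-9)

  ## invariance to re-rooting of the input newick
  t1 <- treeFromText("((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.07);")
  t2 <- treeFromText("((C:0.3,D:0.15):0.12,A:0.1,B:0.2);")
  simr <- simulateCodonAlignment(t1, 30, seed = 8)
  expect_equal(codonLogLik(simr$alignment, t1, 2, uniformPi, 0.4),
               codonLogLik(simr$alignment, t2, 2, uniformPi, 0.4),
               tolerance = 1e-9)

  ## taxa mismatch is reported
  expect_error(codonLogLik(simr$alignment, snakeTree(), 2, uniformPi, 0.4),
               "missing from alignment")
})
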