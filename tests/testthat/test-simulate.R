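test_that("simulation honors degenerate limits and forbidden transitions", {
  tr0 <- treeFromText("(A:0,B:0,C:0);")
  sim0 <- simulateCodonAlignment(tr0, 50, seed = 5)
  for (j in 1:50)
    expect_length(unique(unlist(sim0$alignment@cells[, j])), 1L)

  ## omega = 0: no nonsynonymous difference can ever arise
  tr <- snakeTree()
  simP <- simulateCodonAlignment(tr, 150, omega = 0, seed = 6)
  expect_equal(countNonsynDiffs(simP$alignment), 0L)

  expect_error(simulateCodonAlignment(tr, 10), "seed")
  expect_error(simulateCodonAlignment(tr, 0, seed = 1), "L must be")
})

test_that("identical seeds reproduce alignments bit for bit", {
  tr <- snakeTree()
  a <- simulateCodonAlignment(tr, 80, omega = 0.4, seed = 99)
  b <- simulateCodonAlignment(tr, 80, omega = 0.4, seed = 99)
  expect_identical(a$alignment@cells, b$alignment@cells)
  expect_identical(a$truth, b$truth)
  c <- simulateCodonAlignment(tr, 80, omega = 0.4, seed = 100)
  expect_false(identical(a$alignment@cells, c$alignment@cells))
})

test_that("tip codon frequencies approach pi on a long branch", {
  tr <- treeFromText("(A:0.01,B:25);")
  piT <- local({ set.seed(13); x <- rgamma(61, 3); x / sum(x) })
  sim <- simulateCodonAlignment(tr, 5000, pi = piT, omega = 0.5, seed = 14)
  far <- match("B", sim$alignment@taxa)
  counts <- tabulate(unlist(sim$alignment@cells[far, ]), 61)
  tv <- 0.5 * sum(abs(counts / sum(counts) - piT))
  expect_lt(tv, 0.05)
})

test_that("site-class truth labels drive branch-site evolution", {
  tr <- snakeTree()
  part <- labelBranches(tr, snakeTable(), "4w-activity",
                        foreground = "nocturnal-colubrid")
  sim <- simulateCodonAlignment(tr, 200, partition = part,
                                mixture = list(
                                  list(prop = 0.7, omega = 0.1),
                                  list(prop = 0.2, omega = 1),
                                  list(prop = 0.1,
                                       omega = c(background = 0.1,
                                                 foreground = 4))),
                                seed = 31)
  expect_length(sim$truth$siteClass, 200L)
  expect_setequal(unique(sim$truth$siteClass), 1:3)
})

test_that("the MLE dominates the generating parameters", {
  tr <- snakeTree()
  sim <- simulateCodonAlignment(tr, 200, kappa = 2, pi = uniformPi,
                                omega = 0.3, seed = 77)
  llTruth <- codonLogLik(sim$alignment, tr, 2, uniformPi, 0.3)
  fit <- fitCodonModel(sim$alignment, tr, "M0", pi = uniformPi, nStarts = 1,
                       seed = 1)
  expect_gte(fit@logLik, llTruth - 1e-6)
})

test_that("recovery experiments summarize estimates and reject bad input", {
  tr <- snakeTree()
  rec <- recoveryExperiment(tr, L = 100, omega = 0.25, fitModels = "M0",
                            replicates = 2, seed = 3)
  expect_equal(nrow(rec$estimates), 2L)
  expect_true(all(is.finite(rec$estimates$omega_omega)))
  expect_equal(rec$summary$truth, 0.25)
  expect_error(recoveryExperiment(tr, L = 100, replicates = 0, seed = 1),
               "replicate")
})
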