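## Small shared dataset for the fitting tests (purifying, one ratio)
fitTree <- snakeTree()
fitSim <- simulateCodonAlignment(fitTree, 300, kappa = 2, pi = uniformPi,
                                 omega = 0.2, seed = 42)

test_that("M0 recovers omega and kappa from self-simulated data", {
  f <- fitCodonModel(fitSim$alignment, fitTree, "M0", pi = uniformPi,
                     nStarts = 1, seed = 1)
  expect_s4_class(f, "CodonFitResult")
  expect_equal(unname(f@estimates$omega[["omega"]]), 0.2, tolerance = 0.4)
  expect_equal(f@estimates$kappa, 2, tolerance = 0.4)
  expect_equal(f@convergence$status, "converged")
  ## K = branch lengths + kappa + omega
  expect_equal(f@K, length(branchIds(fitTree)) + 2L)
  ## refitting from the solution does not move the likelihood
  f2 <- fitCodonModel(fitSim$alignment, fitTree, "M0", pi = uniformPi,
                      nStarts = 1, seed = 1, init = f)
  expect_equal(f2@logLik, f@logLik, tolerance = 1e-4)
})

test_that("branch model with one class equals M0 and 1w is an alias", {
  part1 <- labelBranches(fitTree, snakeTable(), "1w")
  fM0 <- fitCodonModel(fitSim$alignment, fitTree, "M0", pi = uniformPi,
                       nStarts = 1, seed = 1)
  fB <- fitCodonModel(fitSim$alignment, fitTree, "branch", partition = part1,
                      pi = uniformPi, nStarts = 1, seed = 1)
  expect_equal(fB@logLik, fM0@logLik, tolerance = 1e-4)
  fAlias <- fitCodonModel(fitSim$alignment, fitTree, "1w", pi = uniformPi,
                          nStarts = 1, seed = 1)
  expect_equal(fAlias@model, "M0")
})

test_that("fixed branch lengths are honored and excluded from K", {
  f <- fitCodonModel(fitSim$alignment, fitTree, "M0", pi = uniformPi,
                     nStarts = 1, seed = 1, optimizeBranchLengths = FALSE)
  expect_equal(unname(f@estimates$branchLengths),
               unname(branchLengths(fitTree)[names(f@estimates$branchLengths)]))
  expect_equal(f@K, 2L)
})

test_that("the Model A null keeps omega2 at exactly 1", {
  part <- labelBranches(fitTree, snakeTable(), "4w-activity",
                        foreground = "nocturnal-colubrid")
  warm <- fitCodonModel(fitSim$alignment, fitTree, "M0", pi = uniformPi,
                        nStarts = 1, seed = 1)
  f0 <- fitCodonModel(fitSim$alignment, fitTree, "ModelA-null",
                      partition = part, pi = uniformPi, nStarts = 1,
                      seed = 1, init = warm, optimizeBranchLengths = FALSE)
  expect_identical(unname(f0@estimates$omega[["omega2"]]), 1)
  fA <- fitCodonModel(fitSim$alignment, fitTree, "ModelA",
                      partition = part, pi = uniformPi, nStarts = 1,
                      seed = 1, init = f0, optimizeBranchLengths = FALSE)
  expect_gte(fA@logLik, f0@logLik - 0.01)
  expect_equal(fA@K, f0@K + 1L)
  ## branch-site templates demand a foreground
  expect_error(fitCodonModel(fitSim$alignment, fitTree, "ModelA",
                             partition = labelBranches(fitTree, snakeTable(),
                                                       "4w-activity"),
                             pi = uniformPi, seed = 1),
               "foreground")
})

test_that("fits are deterministic given a seed", {
  a <- fitCodonModel(fitSim$alignment, fitTree, "M0", pi = uniformPi,
                     nStarts = 2, seed = 7)
  b <- fitCodonModel(fitSim$alignment, fitTree, "M0", pi = uniformPi,
                     nStarts = 2, seed = 7)
  expect_identical(a@logLik, b@logLik)
  expect_identical(a@estimates, b@estimates)
})
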