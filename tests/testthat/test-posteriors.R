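## Shared dataset with a genuine positive-selection site class
posTree <- snakeTree()
posSim <- simulateCodonAlignment(posTree, 250, kappa = 2, pi = uniformPi,
                                 mixture = list(
                                   list(prop = 0.5, omega = 0.05),
                                   list(prop = 0.35, omega = 0.5),
                                   list(prop = 0.15, omega = 3)),
                                 seed = 5)
posM0 <- fitCodonModel(posSim$alignment, posTree, "M0", pi = uniformPi,
                       nStarts = 1, seed = 1)
posM1a <- fitCodonModel(posSim$alignment, posTree, "M1a", pi = uniformPi,
                        nStarts = 1, seed = 1, init = posM0,
                        optimizeBranchLengths = FALSE)
posM2a <- fitCodonModel(posSim$alignment, posTree, "M2a", pi = uniformPi,
                        nStarts = 1, seed = 1, init = posM1a,
                        optimizeBranchLengths = FALSE)

test_that("NEB posteriors are proper and enrich for true positive sites", {
  sp <- sitePosteriors(posM2a, posSim$alignment, posTree, method = "NEB")
  expect_equal(rowSums(sp@posterior), rep(1, 250), tolerance = 1e-8)
  expect_true(all(sp@flagged99 %in% sp@flagged95))
  truePos <- which(posSim$truth$siteClass == 3)
  expect_gt(length(sp@flagged95), 0)
  expect_gt(mean(sp@flagged95 %in% truePos), 0.5)
})

test_that("BEB grid averaging stays proper and consistent with NEB", {
  spB <- sitePosteriors(posM2a, posSim$alignment, posTree, method = "BEB",
                        gridSize = 5)
  expect_equal(spB@method, "BEB")
  expect_equal(rowSums(spB@posterior), rep(1, 250), tolerance = 1e-6)
  truePos <- which(posSim$truth$siteClass == 3)
  expect_gt(mean(spB@flagged95 %in% truePos), 0.5)
})

test_that("models without a positive class flag nothing", {
  sp1 <- sitePosteriors(posM1a, posSim$alignment, posTree, method = "NEB")
  expect_length(sp1@flagged95, 0L)
  expect_length(sp1@flagged99, 0L)
  expect_error(sitePosteriors(posM0, posSim$alignment, posTree),
               "site classes")
})

test_that("branch-site Model A posteriors target foreground sites", {
  part <- labelBranches(posTree, snakeTable(), "4w-activity",
                        foreground = "nocturnal-colubrid")
  simBS <- simulateCodonAlignment(posTree, 300, kappa = 2, pi = uniformPi,
                                  partition = part,
                                  mixture = list(
                                    list(prop = 0.65, omega = 0.05),
                                    list(prop = 0.2, omega = 1),
                                    list(prop = 0.15,
                                         omega = c(background = 0.05,
                                                   foreground = 6))),
                                  seed = 17)
  m0 <- fitCodonModel(simBS$alignment, posTree, "M0", pi = uniformPi,
                      nStarts = 1, seed = 1)
  fA <- fitCodonModel(simBS$alignment, posTree, "ModelA", partition = part,
                      pi = uniformPi, nStarts = 1, seed = 1, init = m0,
                      optimizeBranchLengths = FALSE)
  sp <- sitePosteriors(fA, simBS$alignment, posTree, method = "NEB")
  expect_identical(sp@positiveClasses, c(3L, 4L))
  truePos <- which(simBS$truth$siteClass == 3)
  if (length(sp@flagged95))
    expect_gt(mean(sp@flagged95 %in% truePos), 0.5)
})
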