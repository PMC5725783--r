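#' Simulate a codon alignment under branch- and site-heterogeneous omega
#'
#' Root codons are drawn from \code{pi}; each site is assigned a mixture
#' class once at the root (recorded as truth) and evolves along every branch
#' under the class's omega for that branch via the transition matrices of
#' the scaled GY94-style generator. With a \code{partition} and a named
#' \code{omega} vector, branches evolve under their class's omega;
#' \code{mixture} components may carry \code{c(background=, foreground=)}
#' omegas realizing branch-site (Model A) semantics: a site's class is
#' global, the foreground omega applies only on foreground branches.
#' Identical seeds give bit-identical alignments.
#'
#' @param tree a \linkS4class{LabeledTree}.
#' @param L number of codon sites.
#' @param kappa transition/transversion ratio.
#' @param pi codon frequency simplex (default uniform).
#' @param omega scalar, or named per-class vector with \code{partition}.
#' @param partition optional \linkS4class{BranchPartition}.
#' @param mixture optional site mixture (see \code{\link{codonLogLik}}).
#' @param seed mandatory integer seed.
#' @return list with \code{alignment} (a \linkS4class{CodonAlignment}) and
#'   \code{truth} (class labels per site, parameters, seed).
#' @export
simulateCodonAlignment <- function(tree, L, kappa = 2,
                                   pi = rep(1 / 61, 61), omega = 0.2,
                                   partition = NULL, mixture = NULL,
                                   seed) {
  if (missing(seed)) stop("seed is mandatory for simulation")
  checkPi(pi)
  if (L < 1) stop("L must be >= 1")
  ctx <- treeContext(tree)
  str <- modelStructure(ctx, kappa, omega, partition, mixture)
  eigs <- lapply(str$omegaValues, function(w) codonEigen(kappa, w, pi))
  tEff <- effectiveLengths(ctx$t, kappa, pi, str$omegaValues, str$omegaIdx,
                           str$classProp)
  nNodes <- ctx$nTip + ctx$nNode
  root <- ctx$nTip + 1L
  withSeed(seed, {
    siteClass <- sample.int(length(str$classProp), L, replace = TRUE,
                            prob = str$classProp)
    states <- matrix(NA_integer_, nNodes, L)
    states[root, ] <- sample.int(length(pi), L, replace = TRUE, prob = pi)
    ## preorder = reverse postorder: parents are realized before children
    for (e in rev(seq_len(nrow(ctx$edge)))) {
      p <- ctx$edge[e, 1]; ch <- ctx$edge[e, 2]
      for (c in unique(str$omegaIdx[e, siteClass])) {
        eg <- eigs[[c]]
        P <- eg$A %*% (exp(eg$ev * tEff[e]) * eg$B)
        P[P < 0] <- 0
        P <- P / rowSums(P)
        sel <- which(str$omegaIdx[e, siteClass] == c)
        for (sp in unique(states[p, sel])) {
          sites <- sel[states[p, sel] == sp]
          states[ch, sites] <- sample.int(length(pi), length(sites),
                                          replace = TRUE, prob = P[sp, ])
        }
      }
    }
    tab <- codonTable()
    cells <- matrix(vector("list", ctx$nTip * L), nrow = ctx$nTip,
                    dimnames = list(ctx$tipLabels, NULL))
    for (i in seq_len(ctx$nTip)) for (j in seq_len(L))
      cells[[i, j]] <- states[i, j]
    aln <- new("CodonAlignment", taxa = ctx$tipLabels, cells = cells,
               ntLength = 3L * as.integer(L))
    list(alignment = aln,
         truth = list(siteClass = siteClass, omegaValues = str$omegaValues,
                      classProp = str$classProp, kappa = kappa, pi = pi,
                      seed = seed))
  })
}

#' Parameter-recovery and LRT-calibration experiments
#'
#' Simulates \code{replicates} data sets under known truth, fits the
#' requested model templates to each, and reports per-replicate estimates
#' plus, when a nested \code{comparison} is given, the LRT rejection rate at
#' \code{alpha}. Per-replicate seeds derive deterministically from
#' \code{seed}.
#'
#' @param tree,L,kappa,pi,omega,partition,mixture forwarded to
#'   \code{\link{simulateCodonAlignment}}.
#' @param fitModels character vector of templates to fit (fitted in order;
#'   later fits warm-start from the first).
#' @param replicates number of replicates (>= 1).
#' @param seed master seed.
#' @param comparison optional \code{list(null=, alt=, df=)} naming two of
#'   \code{fitModels} for an LRT per replicate.
#' @param alpha rejection level for the LRT calibration.
#' @param fitPartition partition used for fitting (defaults to the
#'   simulation partition).
#' @param nStarts,optimizeBranchLengths,control forwarded to
#'   \code{\link{fitCodonModel}}.
#' @return list with \code{estimates} (data.frame: replicate, model, kappa,
#'   omega columns), \code{lrt} (data.frame or NULL), \code{rejectionRate},
#'   and \code{summary} (bias/RMSE of omega estimates vs truth where
#'   comparable).
#' @export
recoveryExperiment <- function(tree, L, kappa = 2, pi = rep(1 / 61, 61),
                               omega = 0.2, partition = NULL, mixture = NULL,
                               fitModels = "M0", replicates = 20L, seed = 1L,
                               comparison = NULL, alpha = 0.05,
                               fitPartition = NULL, nStarts = 1L,
                               optimizeBranchLengths = TRUE,
                               control = list()) {
  if (replicates < 1) stop("replicate count must be >= 1")
  if (is.null(fitPartition)) fitPartition <- partition
  subSeeds <- withSeed(seed, sample.int(2^31 - 2, replicates))
  estRows <- list(); lrtRows <- list()
  for (r in seq_len(replicates)) {
    sim <- simulateCodonAlignment(tree, L, kappa = kappa, pi = pi,
                                  omega = omega, partition = partition,
                                  mixture = mixture, seed = subSeeds[r])
    fits <- list(); warm <- NULL
    for (m in fitModels) {
      fits[[m]] <- fitCodonModel(sim$alignment, tree, m,
                                 partition = fitPartition, pi = pi,
                                 nStarts = nStarts, seed = subSeeds[r],
                                 optimizeBranchLengths = optimizeBranchLengths,
                                 init = warm, control = control)
      if (is.null(warm)) warm <- fits[[m]]
    }
    for (m in fitModels) {
      om <- fits[[m]]@estimates$omega
      row <- data.frame(replicate = r, model = m,
                        lnL = fits[[m]]@logLik, kappa = fits[[m]]@estimates$kappa)
      for (cn in names(om)) row[[paste0("omega_", cn)]] <- om[[cn]]
      estRows[[length(estRows) + 1L]] <- row
    }
    if (!is.null(comparison)) {
      df <- if (!is.null(comparison$df)) comparison$df else
        fits[[comparison$alt]]@K - fits[[comparison$null]]@K
      lr <- lrt(fits[[comparison$null]], fits[[comparison$alt]], df)
      lr$replicate <- r
      lrtRows[[length(lrtRows) + 1L]] <- lr
    }
  }
  allCols <- unique(unlist(lapply(estRows, names)))
  est <- do.call(rbind, lapply(estRows, function(r) {
    r[setdiff(allCols, names(r))] <- NA
    r[allCols]
  }))
  lrtTab <- if (length(lrtRows)) do.call(rbind, lrtRows) else NULL
  rejRate <- if (!is.null(lrtTab)) mean(lrtTab$p < alpha) else NA_real_
  ## bias/RMSE for omega columns against truth where class names line up
  truthOmega <- if (!is.null(names(omega))) omega else
    c(omega = unname(omega)[1])
  summ <- do.call(rbind, lapply(names(truthOmega), function(cn) {
    col <- paste0("omega_", cn)
    if (!col %in% names(est)) return(NULL)
    v <- est[[col]][!is.na(est[[col]])]
    data.frame(parameter = col, truth = truthOmega[[cn]],
               bias = mean(v) - truthOmega[[cn]],
               rmse = sqrt(mean((v - truthOmega[[cn]])^2)))
  }))
  list(estimates = est, lrt = lrtTab, rejectionRate = rejRate,
       summary = summ, seeds = subSeeds)
}
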