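## ---------------------------------------------------------------------------
## Model templates and maximum-likelihood fitting
## ---------------------------------------------------------------------------

## Internal parameter conventions: positive parameters (branch lengths,
## kappa, omega, beta shapes) are optimized on the log scale; probabilities
## on the raw scale inside (eps, 1 - eps); omegas constrained to >= 1 as
## 1 + exp(x). Box constraints keep the optimizer away from overflow.

.LOGLO <- -18; .LOGHI <- 4; .PEPS <- 1e-4

## Equal-probability discretization of a beta(p, q) into nCat category
## medians (quantile midpoints).
betaCategories <- function(p, q, nCat = 10L) {
  stats::qbeta((2 * seq_len(nCat) - 1) / (2 * nCat), p, q)
}

## Build the template definition: parameter vector layout, bounds, decode()
## from internal scale to the model structure, and reporting.
buildModelDef <- function(model, ctx, partition, foreground, nBeta = 10L,
                          optimizeBranchLengths = TRUE) {
  E <- length(ctx$t)
  fgEdges <- if (!is.null(partition) && length(partition@foreground))
    ctx$ids %in% partition@foreground else rep(FALSE, E)
  if (model %in% c("ModelA", "ModelA-null") && !any(fgEdges))
    stop("branch-site models need a partition with a non-empty foreground")
  branchCls <- if (!is.null(partition)) {
    unname(partition@assignment[ctx$ids])
  } else rep(1L, E)
  nCls <- if (!is.null(partition)) length(partition@classes) else 1L

  pn <- character(0); init <- numeric(0); lo <- numeric(0); hi <- numeric(0)
  addLog <- function(name, value) {
    pn <<- c(pn, name); init <<- c(init, log(value))
    lo <<- c(lo, .LOGLO); hi <<- c(hi, .LOGHI)
  }
  addProb <- function(name, value) {
    pn <<- c(pn, name); init <<- c(init, value)
    lo <<- c(lo, .PEPS); hi <<- c(hi, 1 - .PEPS)
  }
  addOmegaGe1 <- function(name, value) {
    pn <<- c(pn, name); init <<- c(init, log(value - 1 + 1e-6))
    lo <<- c(lo, .LOGLO); hi <<- c(hi, .LOGHI)
  }
  if (optimizeBranchLengths)
    for (e in seq_len(E)) addLog(paste0("t", e), max(ctx$t[e], 1e-4))
  addLog("kappa", 2)

  mk <- switch(model,
    "M0" = , "branch" = {
      for (k in seq_len(if (model == "M0") 1L else nCls))
        addLog(paste0("w", k), 0.4)
      function(th) {
        nW <- if (model == "M0") 1L else nCls
        w <- exp(th[paste0("w", seq_len(nW))])
        list(omegaValues = unname(w),
             omegaIdx = matrix(if (model == "M0") 1L else branchCls, E, 1),
             classProp = 1,
             report = list(omega = stats::setNames(unname(w),
               if (model == "M0") "omega" else partition@classes)))
      }
    },
    "M1a" = {
      addProb("p0", 0.7); addProb("w0", 0.2)
      function(th) {
        list(omegaValues = c(th[["w0"]], 1),
             omegaIdx = matrix(rep(1:2, each = E), E, 2),
             classProp = c(th[["p0"]], 1 - th[["p0"]]),
             report = list(omega = c(omega0 = th[["w0"]], omega1 = 1),
                           proportions = c(p0 = th[["p0"]],
                                           p1 = 1 - th[["p0"]])))
      }
    },
    "M2a" = {
      addProb("a", 0.95); addProb("b", 0.85); addProb("w0", 0.2)
      addOmegaGe1("w2", 1.5)
      function(th) {
        p0 <- th[["a"]] * th[["b"]]; p1 <- th[["a"]] * (1 - th[["b"]])
        w2 <- 1 + exp(th[["w2"]])
        list(omegaValues = c(th[["w0"]], 1, w2),
             omegaIdx = matrix(rep(1:3, each = E), E, 3),
             classProp = c(p0, p1, 1 - p0 - p1),
             report = list(omega = c(omega0 = th[["w0"]], omega1 = 1,
                                     omega2 = w2),
                           proportions = c(p0 = p0, p1 = p1,
                                           p2 = 1 - p0 - p1)))
      }
    },
    "M3" = {
      addProb("a", 0.6); addProb("b", 0.6)
      for (k in 0:2) addLog(paste0("w", k), c(0.05, 0.4, 1.5)[k + 1])
      function(th) {
        p0 <- th[["a"]] * th[["b"]]; p1 <- th[["a"]] * (1 - th[["b"]])
        w <- exp(c(th[["w0"]], th[["w1"]], th[["w2"]]))
        list(omegaValues = w, omegaIdx = matrix(rep(1:3, each = E), E, 3),
             classProp = c(p0, p1, 1 - p0 - p1),
             report = list(omega = stats::setNames(w, paste0("omega", 0:2)),
                           proportions = c(p0 = p0, p1 = p1,
                                           p2 = 1 - p0 - p1)))
      }
    },
    "M7" = {
      addLog("bp", 0.5); addLog("bq", 1.5)
      function(th) {
        w <- betaCategories(exp(th[["bp"]]), exp(th[["bq"]]), nBeta)
        list(omegaValues = w,
             omegaIdx = matrix(rep(seq_len(nBeta), each = E), E, nBeta),
             classProp = rep(1 / nBeta, nBeta),
             report = list(beta = c(p = exp(th[["bp"]]), q = exp(th[["bq"]])),
                           omega = stats::setNames(w,
                             paste0("cat", seq_len(nBeta)))))
      }
    },
    "M8" = {
      addProb("p0", 0.97); addLog("bp", 0.5); addLog("bq", 1.5)
      addOmegaGe1("ws", 1.5)
      function(th) {
        w <- betaCategories(exp(th[["bp"]]), exp(th[["bq"]]), nBeta)
        ws <- 1 + exp(th[["ws"]])
        list(omegaValues = c(w, ws),
             omegaIdx = matrix(rep(seq_len(nBeta + 1), each = E), E,
                               nBeta + 1),
             classProp = c(rep(th[["p0"]] / nBeta, nBeta), 1 - th[["p0"]]),
             report = list(beta = c(p = exp(th[["bp"]]), q = exp(th[["bq"]])),
                           proportions = c(p0 = th[["p0"]]),
                           omega = c(omega_s = ws)))
      }
    },
    "ModelA" = , "ModelA-null" = {
      addProb("a", 0.85); addProb("b", 0.8); addProb("w0", 0.1)
      if (model == "ModelA") addOmegaGe1("w2", 1.5)
      function(th) {
        p0 <- th[["a"]] * th[["b"]]; p1 <- th[["a"]] * (1 - th[["b"]])
        p2a <- (1 - th[["a"]]) * th[["b"]]
        p2b <- (1 - th[["a"]]) * (1 - th[["b"]])
        w2 <- if (model == "ModelA") 1 + exp(th[["w2"]]) else 1
        vals <- c(th[["w0"]], 1, w2)
        idx <- cbind(rep(1L, E), rep(2L, E),
                     ifelse(fgEdges, 3L, 1L), ifelse(fgEdges, 3L, 2L))
        list(omegaValues = vals, omegaIdx = idx,
             classProp = c(p0, p1, p2a, p2b),
             report = list(omega = c(omega0 = th[["w0"]], omega1 = 1,
                                     omega2 = w2),
                           proportions = c(p0 = p0, p1 = p1, p2a = p2a,
                                           p2b = p2b)))
      }
    },
    stop("unknown model template: ", model))

  ## each template's mk() maps its own parameters (probabilities raw,
  ## log-scale omegas exponentiated internally); decode handles the shared
  ## branch-length and kappa parameters
  decode <- function(x) {
    th <- stats::setNames(x, pn)
    tHat <- if (optimizeBranchLengths)
      unname(exp(th[paste0("t", seq_len(E))])) else ctx$t
    c(mk(th), list(tHat = tHat, kappa = exp(th[["kappa"]])))
  }
  list(parNames = pn, init = init, lower = lo, upper = hi, decode = decode,
       E = E, model = model, optimizeBranchLengths = optimizeBranchLengths)
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Implements the model families compared in selection analyses: the
#' single-ratio model \code{M0}; branch models with one omega per class of a
#' \linkS4class{BranchPartition} (\code{"branch"}; the free-ratio model is a
#' partition with one class per branch); the site models \code{M1a}
#' (nearly neutral), \code{M2a} (positive selection), \code{M3} (three
#' discrete classes), \code{M7} (beta) and \code{M8} (beta plus a class with
#' omega >= 1); and branch-site \code{ModelA} with its null
#' (\code{"ModelA-null"}, omega2 fixed at 1). Branch lengths and kappa are
#' jointly re-optimized under every model by default. Optimization is
#' bounded quasi-Newton (L-BFGS-B) on transformed parameters with seeded
#' multi-starts; given the same seed the fit is deterministic.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param tree a \linkS4class{LabeledTree}.
#' @param model template name (see Details above); "1w" is an alias of M0.
#' @param partition \linkS4class{BranchPartition}, required for
#'   \code{"branch"} and the branch-site templates (foreground taken from
#'   it or from \code{foreground}).
#' @param foreground optional class name(s) or branch ids marked foreground.
#' @param pi codon frequencies: a method name for
#'   \code{\link{codonFrequencies}} ("F3x4" default, "F61", "uniform") or a
#'   numeric simplex.
#' @param nBeta number of equal-probability beta categories for M7/M8.
#' @param nStarts number of seeded optimizer starts.
#' @param seed integer seed controlling the multi-start draws.
#' @param optimizeBranchLengths set FALSE to keep the input tree's lengths
#'   fixed (they then do not count towards K).
#' @param init optional warm start: a \linkS4class{CodonFitResult} whose
#'   branch lengths and kappa seed the optimizer.
#' @param control overrides for \code{\link[stats]{optim}} control
#'   (\code{maxit}, \code{factr}).
#' @return A \linkS4class{CodonFitResult}.
#' @export
#' @importFrom stats optim setNames qbeta runif
fitCodonModel <- function(aln, tree, model = "M0", partition = NULL,
                          foreground = NULL, pi = "F3x4", nBeta = 10L,
                          nStarts = 3L, seed = 1L,
                          optimizeBranchLengths = TRUE, init = NULL,
                          control = list()) {
  if (model == "1w") model <- "M0"
  if (model == "branch" && is.null(partition))
    stop("model 'branch' needs a partition")
  if (!is.null(partition) && !is.null(foreground))
    partition <- addForeground(partition, foreground)
  piVec <- if (is.character(pi)) codonFrequencies(aln, pi) else pi
  checkPi(piVec)
  ctx <- treeContext(tree)
  pat <- alignmentPatterns(aln, ctx$tipLabels)
  def <- buildModelDef(model, ctx, partition, foreground, nBeta = nBeta,
                       optimizeBranchLengths = optimizeBranchLengths)
  nEval <- 0L
  objective <- function(x) {
    nEval <<- nEval + 1L
    d <- def$decode(x)
    ll <- tryCatch({
      logf <- patternClassLoglik(ctx, pat, d$kappa, piVec, d$omegaValues,
                                 d$omegaIdx, d$tHat, d$classProp)
      mixLoglik(logf, d$classProp, pat$weights)
    }, error = function(e) -1e10)
    if (!is.finite(ll)) ll <- -1e10
    -ll
  }
  start0 <- stats::setNames(def$init, def$parNames)
  if (!is.null(init)) {
    stopifnot(is(init, "CodonFitResult"))
    bl <- init@estimates$branchLengths
    if (!is.null(bl) && optimizeBranchLengths) {
      tIn <- bl[ctx$ids]
      ok <- which(is.finite(tIn))
      start0[paste0("t", ok)] <- log(pmax(tIn[ok], 1e-6))
    }
    if (!is.null(init@estimates$kappa))
      start0["kappa"] <- log(max(init@estimates$kappa, 1e-3))
    ## carry over any same-named template parameters (e.g. M7 -> M8 beta
    ## shapes, M1a -> ModelA proportions), except branch lengths already set
    prevNames <- init@details$parNames
    if (!is.null(prevNames)) {
      shared <- setdiff(intersect(def$parNames, prevNames),
                        c("kappa", paste0("t", seq_len(def$E))))
      start0[shared] <- init@details$parInternal[match(shared, prevNames)]
    }
    ## seed branch-model omega classes from the previous fit's omega(s)
    omPrev <- init@estimates$omega
    if (!is.null(omPrev) && model %in% c("M0", "branch")) {
      wIdx <- grep("^w[0-9]+$", def$parNames)
      for (k in seq_along(wIdx)) {
        prev <- if (!is.null(partition) &&
                    partition@classes[k] %in% names(omPrev))
          omPrev[[partition@classes[k]]] else mean(omPrev)
        start0[wIdx[k]] <- log(max(prev, 1e-4))
      }
    }
    start0 <- pmin(pmax(unname(start0), def$lower), def$upper)
  }
  ctrl <- list(maxit = 300L, factr = 1e7,
               ndeps = rep(1e-4, length(start0)))
  ctrl[names(control)] <- control
  starts <- withSeed(seed, {
    lapply(seq_len(max(1L, nStarts)), function(k) {
      if (k == 1L) start0 else
        pmin(pmax(start0 + runif(length(start0), -0.75, 0.75), def$lower),
             def$upper)
    })
  })
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "L-BFGS-B",
                        lower = def$lower, upper = def$upper, control = ctrl)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  d <- def$decode(best$par)
  est <- list(kappa = unname(d$kappa),
              branchLengths = stats::setNames(d$tHat, ctx$ids))
  est <- c(est, d$report)
  status <- if (best$convergence == 0L) "converged" else
    paste0("optim code ", best$convergence)
  new("CodonFitResult", model = model, logLik = -best$value,
      estimates = est, K = length(best$par),
      convergence = list(status = status, starts = length(starts),
                         evals = nEval, message = best$message),
      details = list(partition = partition, pi = piVec, nBeta = nBeta,
                     optimizeBranchLengths = optimizeBranchLengths,
                     parInternal = best$par, parNames = def$parNames))
}
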