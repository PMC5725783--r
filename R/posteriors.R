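#' Per-site posterior probabilities of the omega site classes
#'
#' @slot posterior sites x classes matrix, rows summing to 1.
#' @slot positiveClasses indices of the positive-selection class(es).
#' @slot flagged95,flagged99 codon columns (1-based) whose positive-class
#'   posterior exceeds 0.95 / 0.99.
#' @slot method "NEB" or "BEB".
#' @exportClass SitePosterior
setClass("SitePosterior",
  representation(posterior = "matrix", positiveClasses = "integer",
                 flagged95 = "integer", flagged99 = "integer",
                 method = "character"))

setValidity("SitePosterior", function(object) {
  if (nrow(object@posterior) &&
      any(abs(rowSums(object@posterior) - 1) > 1e-6))
    return("each site's posterior must sum to 1")
  if (!all(object@flagged99 %in% object@flagged95))
    return("0.99 list must be nested in the 0.95 list")
  TRUE
})

setMethod("show", "SitePosterior", function(object) {
  cat("SitePosterior [", object@method, "]:", nrow(object@posterior),
      "sites,", ncol(object@posterior), "classes\n")
  cat("  P>0.95:", if (length(object@flagged95))
    paste(object@flagged95, collapse = " ") else "none", "\n")
  cat("  P>0.99:", if (length(object@flagged99))
    paste(object@flagged99, collapse = " ") else "none", "\n")
})

positiveClassesOf <- function(model, nBeta) {
  switch(model,
    M2a = 3L, M8 = nBeta + 1L, ModelA = c(3L, 4L), `ModelA-null` = c(3L, 4L),
    integer(0))
}

## Posterior mixture bookkeeping shared by NEB and each BEB grid point.
classPosterior <- function(logf, classProp) {
  m <- sweep(logf, 2, log(classProp), "+")
  mmax <- apply(m, 1, max)
  w <- exp(m - mmax)
  w / rowSums(w)
}

#' Empirical-Bayes identification of positively selected sites
#'
#' \code{NEB} plugs the maximum-likelihood estimates into Bayes' rule.
#' \code{BEB} averages the site-class posteriors over a coarse grid prior on
#' the mixture parameters (class proportions and the omegas that are free in
#' the template), weighting each grid point by its data likelihood, so
#' sampling error in the mixture estimates is accounted for. Available for
#' M2a, M8 and branch-site Model A; other multi-class models fall back to
#' NEB over their fitted classes with an empty positive class.
#'
#' @param fit a \linkS4class{CodonFitResult} for a model with >= 2 site
#'   classes.
#' @param aln,tree the data the model was fitted to.
#' @param method "NEB" (default) or "BEB".
#' @param gridSize grid points per BEB dimension.
#' @param thresholds posterior thresholds used for the flagged site lists.
#' @return A \linkS4class{SitePosterior}.
#' @export
sitePosteriors <- function(fit, aln, tree, method = c("NEB", "BEB"),
                           gridSize = 8L, thresholds = c(0.95, 0.99)) {
  method <- match.arg(method)
  model <- fit@model
  if (model %in% c("M0", "branch", "1w"))
    stop("site posteriors need a model with at least two site classes")
  ctx <- treeContext(tree)
  pat <- alignmentPatterns(aln, ctx$tipLabels)
  det <- fit@details
  def <- buildModelDef(model, ctx, det$partition, NULL, nBeta = det$nBeta,
                       optimizeBranchLengths = det$optimizeBranchLengths)
  d <- def$decode(det$parInternal)
  posC <- positiveClassesOf(model, det$nBeta)
  if (method == "NEB" || !model %in% c("M2a", "M8", "ModelA", "ModelA-null")) {
    logf <- patternClassLoglik(ctx, pat, d$kappa, det$pi, d$omegaValues,
                               d$omegaIdx, d$tHat, d$classProp)
    post <- classPosterior(logf, d$classProp)[pat$map, , drop = FALSE]
    if (method == "BEB") method <- "NEB"
  } else {
    post <- bebPosterior(model, ctx, pat, d, det, gridSize)[pat$map, ,
                                                            drop = FALSE]
  }
  pp <- if (length(posC)) rowSums(post[, posC, drop = FALSE]) else
    rep(0, nrow(post))
  new("SitePosterior", posterior = post, positiveClasses = posC,
      flagged95 = which(pp > thresholds[1]), flagged99 = which(pp > thresholds[2]),
      method = method)
}

## Coarse-grid Bayes empirical Bayes. The grid covers the mixture
## proportions (triangular grid over (p0, p1) where the template has two
## free proportions, a 1-D grid otherwise), omega0 on (0, 1) and the
## positive-class omega on (1, 11); kappa, branch lengths and beta shapes
## stay at their MLEs. Prior uniform over grid points.
bebPosterior <- function(model, ctx, pat, d, det, gridSize) {
  g <- (2 * seq_len(gridSize) - 1) / (2 * gridSize)
  w0Grid <- g
  w2Grid <- 1 + 10 * g
  E <- nrow(ctx$edge)
  fgEdges <- if (!is.null(det$partition) && length(det$partition@foreground))
    ctx$ids %in% det$partition@foreground else rep(FALSE, E)
  constIdx <- matrix(1L, E, 1)
  ## branch lengths and rate scaling stay at the MLE while the mixture
  ## parameters range over the grid
  tEffMLE <- effectiveLengths(d$tHat, d$kappa, det$pi, d$omegaValues,
                              d$omegaIdx, d$classProp)
  logfFor <- function(omegaValues, omegaIdx)
    patternClassLoglik(ctx, pat, d$kappa, det$pi, omegaValues, omegaIdx,
                       tEff = tEffMLE)

  if (model == "M8") {
    ## classes: nBeta beta categories (kept at MLE) + positive class omega_s
    fBeta <- logfFor(d$omegaValues[seq_len(det$nBeta)],
                     matrix(rep(seq_len(det$nBeta), each = E), E))
    fPos <- logfFor(w2Grid, matrix(rep(seq_along(w2Grid), each = E), E))
    grid <- expand.grid(p0 = g, iw = seq_along(w2Grid))
    comps <- lapply(seq_len(nrow(grid)), function(i) {
      list(logf = cbind(fBeta, fPos[, grid$iw[i]]),
           prop = c(rep(grid$p0[i] / det$nBeta, det$nBeta), 1 - grid$p0[i]))
    })
  } else if (model == "M2a") {
    f0 <- logfFor(w0Grid, matrix(rep(seq_along(w0Grid), each = E), E))
    f1 <- logfFor(1, constIdx)
    fPos <- logfFor(w2Grid, matrix(rep(seq_along(w2Grid), each = E), E))
    pp <- expand.grid(p0 = g, p1 = g)
    pp <- pp[pp$p0 + pp$p1 < 1, ]
    grid <- merge(expand.grid(i0 = seq_along(w0Grid), iw = seq_along(w2Grid)),
                  pp)
    comps <- lapply(seq_len(nrow(grid)), function(i) {
      list(logf = cbind(f0[, grid$i0[i]], f1, fPos[, grid$iw[i]]),
           prop = c(grid$p0[i], grid$p1[i], 1 - grid$p0[i] - grid$p1[i]))
    })
  } else {  ## ModelA / ModelA-null
    idxBg <- function(i) matrix(i, E, 1)
    f0 <- logfFor(w0Grid, matrix(rep(seq_along(w0Grid), each = E), E))
    f1 <- logfFor(1, constIdx)
    ## class 3/4: background omega on background edges, omega2 on foreground
    f2a <- sapply(seq_along(w0Grid), function(i0)
      sapply(seq_along(w2Grid), function(iw)
        logfFor(c(w0Grid[i0], w2Grid[iw]),
                matrix(ifelse(fgEdges, 2L, 1L), E))))
    dim(f2a) <- c(nrow(f0), length(w2Grid), length(w0Grid))
    f2b <- sapply(seq_along(w2Grid), function(iw)
      logfFor(c(1, w2Grid[iw]), matrix(ifelse(fgEdges, 2L, 1L), E)))
    pp <- expand.grid(p0 = g, p1 = g)
    pp <- pp[pp$p0 + pp$p1 < 1, ]
    grid <- merge(expand.grid(i0 = seq_along(w0Grid), iw = seq_along(w2Grid)),
                  pp)
    comps <- lapply(seq_len(nrow(grid)), function(i) {
      a <- grid$p0[i] + grid$p1[i]
      b <- grid$p0[i] / a
      list(logf = cbind(f0[, grid$i0[i]], f1,
                        f2a[, grid$iw[i], grid$i0[i]], f2b[, grid$iw[i]]),
           prop = c(grid$p0[i], grid$p1[i], (1 - a) * b, (1 - a) * (1 - b)))
    })
  }
  ## weight each grid point by its data log likelihood; average posteriors
  lw <- vapply(comps, function(cp)
    mixLoglikSafe(cp$logf, cp$prop, pat$weights), numeric(1))
  lw <- lw - max(lw)
  wts <- exp(lw) / sum(exp(lw))
  post <- 0
  for (i in seq_along(comps))
    post <- post + wts[i] * classPosterior(comps[[i]]$logf, comps[[i]]$prop)
  post
}

## like mixLoglik but returns -Inf instead of erroring on zero-probability
## patterns (grid points may be incompatible with the data)
mixLoglikSafe <- function(logf, classProp, weights) {
  m <- sweep(logf, 2, log(classProp), "+")
  mmax <- apply(m, 1, max)
  sitell <- mmax + log(rowSums(exp(m - mmax)))
  if (any(!is.finite(sitell))) return(-Inf)
  sum(weights * sitell)
}
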