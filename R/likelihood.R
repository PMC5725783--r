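## Tree traversal context shared by likelihood evaluation and simulation:
## postorder edge table, branch lengths, and the branch id of every edge row.
treeContext <- function(tree) {
  phy <- tree@phy
  po <- ape::reorder.phylo(phy, "postorder")
  key <- function(e) paste(e[, 1], e[, 2])
  ord <- match(key(po$edge), key(phy$edge))
  list(edge = po$edge, t = po$edge.length, ids = tree@branchIds[ord],
       nTip = length(phy$tip.label), nNode = phy$Nnode,
       tipLabels = phy$tip.label)
}

## Compress alignment columns into unique site patterns, in the taxon order
## of the tree, and build 61 x S indicator matrices per tip.
alignmentPatterns <- function(aln, tipLabels) {
  if (!all(tipLabels %in% aln@taxa))
    stop("tree leaves missing from alignment: ",
         paste(setdiff(tipLabels, aln@taxa), collapse = ", "))
  cells <- aln@cells[match(tipLabels, aln@taxa), , drop = FALSE]
  L <- ncol(cells)
  if (L == 0L) stop("alignment has no codon columns")
  keys <- vapply(seq_len(L), function(j)
    paste(vapply(cells[, j], paste, character(1), collapse = ","),
          collapse = ";"), character(1))
  firstOfKey <- which(!duplicated(keys))
  map <- match(keys, keys[firstOfKey])
  weights <- tabulate(map, length(firstOfKey))
  n61 <- codonTable()$n
  tips <- lapply(seq_along(tipLabels), function(i) {
    m <- matrix(0, n61, length(firstOfKey))
    for (k in seq_along(firstOfKey)) m[cells[[i, firstOfKey[k]]], k] <- 1
    m
  })
  list(tips = tips, weights = weights, map = map, L = L)
}

## Per-edge effective branch lengths implementing the rate-scaling
## convention: branch lengths measure expected substitutions per codon,
## averaged over the site-class mixture present on that edge.
effectiveLengths <- function(tt, kappa, pi, omegaValues, omegaIdx,
                             classProp) {
  rates <- omegaRates(kappa, omegaValues, pi)
  rho <- as.numeric(matrix(rates[omegaIdx], nrow(omegaIdx)) %*% classProp)
  tt / rho
}

## Per-pattern, per-site-class log likelihoods for an arbitrary model
## structure: omegaValues (distinct omegas), omegaIdx (edge x class), kappa,
## pi, with branch lengths tHat overriding the context's. tEff, when given,
## bypasses the rate-scaling computation (used when mixture parameters vary
## on a grid while the scaling stays at the MLE).
patternClassLoglik <- function(ctx, pat, kappa, pi, omegaValues, omegaIdx,
                               tHat = NULL, classProp = NULL, tEff = NULL) {
  if (is.null(tEff)) {
    tt <- if (is.null(tHat)) ctx$t else tHat
    if (is.null(classProp)) classProp <- rep(1 / ncol(omegaIdx),
                                             ncol(omegaIdx))
    tEff <- effectiveLengths(tt, kappa, pi, omegaValues, omegaIdx, classProp)
  }
  eigs <- lapply(omegaValues, function(w) codonEigen(kappa, w, pi))
  cpp_site_loglik(ctx$edge, ctx$nTip, ctx$nNode, pat$tips,
                  lapply(eigs, `[[`, "A"), lapply(eigs, `[[`, "B"),
                  lapply(eigs, `[[`, "ev"), tEff,
                  matrix(as.integer(omegaIdx), nrow = nrow(omegaIdx)), pi)
}

## Mix per-class pattern log likelihoods into a total log likelihood.
mixLoglik <- function(logf, classProp, weights) {
  lp <- log(classProp)
  m <- sweep(logf, 2, lp, "+")
  mmax <- apply(m, 1, max)
  sitell <- mmax + log(rowSums(exp(m - mmax)))
  if (any(!is.finite(sitell))) {
    bad <- which(!is.finite(sitell))
    stop("zero-probability configuration at pattern(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  sum(weights * sitell)
}

#' Log likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over the 61 sense-codon states with column pattern
#' compression; missing or ambiguous cells sum over their compatible state
#' set. Site-class mixtures average class likelihoods under the class
#' proportions. The result is invariant to root placement because the
#' generator is reversible.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param tree a \linkS4class{LabeledTree} whose leaves appear in the
#'   alignment.
#' @param kappa transition/transversion ratio.
#' @param pi codon frequency simplex (length 61).
#' @param omega either a single value, a named vector over the classes of
#'   \code{partition}, or (with \code{mixture}) ignored.
#' @param partition optional \linkS4class{BranchPartition} for
#'   branch-heterogeneous omega.
#' @param mixture optional site mixture: a list of components, each a list
#'   with \code{prop} and either scalar \code{omega} or
#'   \code{c(background=, foreground=)} values (foreground branches taken
#'   from \code{partition@foreground}).
#' @return Log likelihood (single number).
#' @export
codonLogLik <- function(aln, tree, kappa, pi, omega = NULL, partition = NULL,
                        mixture = NULL) {
  checkPi(pi)
  ctx <- treeContext(tree)
  pat <- alignmentPatterns(aln, ctx$tipLabels)
  E <- nrow(ctx$edge)
  str <- modelStructure(ctx, kappa, omega, partition, mixture)
  logf <- patternClassLoglik(ctx, pat, kappa, pi, str$omegaValues,
                             str$omegaIdx, classProp = str$classProp)
  mixLoglik(logf, str$classProp, pat$weights)
}

## Resolve user-facing omega/partition/mixture arguments into the internal
## model structure (distinct omega values, edge x class index matrix,
## class proportions).
modelStructure <- function(ctx, kappa, omega, partition, mixture) {
  E <- length(ctx$t)
  fgEdges <- if (!is.null(partition) && length(partition@foreground))
    ctx$ids %in% partition@foreground else rep(FALSE, E)
  if (is.null(mixture)) {
    if (is.null(omega)) stop("supply omega or mixture")
    if (length(omega) == 1L && is.null(names(omega))) {
      return(list(omegaValues = unname(omega),
                  omegaIdx = matrix(1L, E, 1), classProp = 1))
    }
    if (is.null(partition)) stop("named omega vector needs a partition")
    if (!all(partition@classes %in% names(omega)))
      stop("omega must name every partition class")
    cls <- partition@assignment[ctx$ids]
    return(list(omegaValues = unname(omega[partition@classes]),
                omegaIdx = matrix(as.integer(cls), E, 1), classProp = 1))
  }
  vals <- numeric(0)
  idx <- matrix(0L, E, length(mixture))
  valueId <- function(w) {
    hit <- which(vals == w)
    if (length(hit)) return(hit[1])
    vals <<- c(vals, w)
    length(vals)
  }
  for (c in seq_along(mixture)) {
    wdef <- mixture[[c]]$omega
    if (length(wdef) == 1L && is.null(names(wdef))) {
      idx[, c] <- valueId(wdef)
    } else {
      if (!all(c("background", "foreground") %in% names(wdef)))
        stop("mixture omega must be scalar or c(background=, foreground=)")
      if (!any(fgEdges))
        stop("branch-site mixture requires a partition with a non-empty foreground")
      idx[, c] <- ifelse(fgEdges, valueId(wdef[["foreground"]]),
                         valueId(wdef[["background"]]))
    }
  }
  props <- vapply(mixture, `[[`, numeric(1), "prop")
  if (abs(sum(props) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  list(omegaValues = vals, omegaIdx = idx, classProp = props)
}
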