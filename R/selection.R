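#' Likelihood ratio test between nested codon models
#'
#' The statistic is twice the log-likelihood difference, referred to a
#' chi-square distribution with \code{df} degrees of freedom. Tiny negative
#' differences (optimizer noise on nested fits) are clamped to zero with a
#' warning; larger negatives signal mis-ordered models and raise an error.
#'
#' @param lnL0,lnL1 log likelihoods of the null and alternative model (the
#'   alternative must not fit worse than the null beyond \code{tol}), or two
#'   \linkS4class{CodonFitResult} objects.
#' @param df degrees of freedom (>= 1).
#' @param tol tolerance for negative statistics due to optimizer noise.
#' @return data.frame row with \code{stat}, \code{df}, \code{p}.
#' @export
#' @importFrom stats pchisq
lrt <- function(lnL0, lnL1, df, tol = 0.5) {
  if (is(lnL0, "CodonFitResult")) lnL0 <- lnL0@logLik
  if (is(lnL1, "CodonFitResult")) lnL1 <- lnL1@logLik
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (lnL1 - lnL0)
  if (stat < -tol)
    stop("alternative model fits worse than null by ", -stat / 2,
         " log units - models mis-ordered?")
  if (stat < 0) {
    warning("negative LRT statistic ", signif(stat, 3), " clamped to 0")
    stat <- 0
  }
  data.frame(stat = stat, df = df,
             p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Bayesian information criterion
#'
#' Computed as -2 lnL + K log(n). The default logarithm base is 10 with n
#' the alignment length in codons, matching the convention this package uses
#' in its comparison tables; the natural log is available via
#' \code{logBase = exp(1)}.
#'
#' @param lnL maximized log likelihood (or a \linkS4class{CodonFitResult}).
#' @param K number of estimated parameters (ignored when \code{lnL} is a
#'   fit result).
#' @param n sample size (alignment length in codons).
#' @param logBase base of the logarithm (default 10).
#' @return BIC value.
#' @export
bic <- function(lnL, K = NULL, n, logBase = 10) {
  if (is(lnL, "CodonFitResult")) { K <- lnL@K; lnL <- lnL@logLik }
  if (!is.finite(lnL) || !is.finite(n) || n < 1 || K < 0)
    stop("bic needs finite lnL, n >= 1 and K >= 0")
  -2 * lnL + K * log(n, base = logBase)
}

#' Model comparison table with a best-by-BIC marker
#'
#' @slot table data.frame with columns model, lnL, K, BIC and one
#'   omega_<class> column per reported omega.
#' @slot n sample size used for BIC.
#' @slot logBase logarithm base used for BIC.
#' @slot best model name with the lowest BIC.
#' @exportClass ModelComparisonTable
setClass("ModelComparisonTable",
  representation(table = "data.frame", n = "numeric", logBase = "numeric",
                 best = "character"))

setMethod("show", "ModelComparisonTable", function(object) {
  cat("ModelComparisonTable (n =", object@n, ", log base", object@logBase,
      ")\n")
  print(object@table, digits = 6)
  cat("best by BIC:", object@best, "\n")
})

## default degrees of freedom for the standard nested comparisons
defaultDf <- function(name0, name1, fits) {
  k0 <- fits[[name0]]@K; k1 <- fits[[name1]]@K
  max(1L, k1 - k0)
}

#' Compare fitted codon models by LRT and BIC
#'
#' Builds a branch/site-model comparison table (one row per fit: lnL, K,
#' BIC, per-class omega estimates, lowest-BIC marker) and a likelihood-ratio
#' test list for the requested nested pairs. Degrees of freedom default to
#' the difference in parameter counts; the branch-site Model A comparison
#' accepts an explicit \code{df} (the table convention here is df = 2, with
#' df = 1 available through the \code{comparisons} argument).
#'
#' @param fits named list of \linkS4class{CodonFitResult} objects sharing
#'   data and tree.
#' @param comparisons list of nested pairs: each element
#'   \code{list(null=, alt=, df=)} (df optional) or a character vector
#'   \code{c(null, alt)}.
#' @param n sample size for BIC (alignment length in codons).
#' @param logBase BIC logarithm base.
#' @return A list with \code{table} (a
#'   \linkS4class{ModelComparisonTable}) and \code{lrt} (data.frame with
#'   comparison, stat, df, p).
#' @export
compareModels <- function(fits, comparisons = list(), n, logBase = 10) {
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    stop("fits must be a named list")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    om <- f@estimates$omega
    r <- data.frame(model = nm, lnL = f@logLik, K = f@K,
                    BIC = bic(f, n = n, logBase = logBase))
    if (!is.null(om) && length(om) <= 8)
      for (cn in names(om)) r[[paste0("omega_", cn)]] <- om[[cn]]
    r
  })
  allCols <- unique(unlist(lapply(rows, names)))
  tab <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(allCols, names(r))] <- NA
    r[allCols]
  }))
  best <- tab$model[which.min(tab$BIC)]
  lrtTab <- do.call(rbind, lapply(comparisons, function(cmp) {
    if (is.character(cmp)) cmp <- list(null = cmp[1], alt = cmp[2])
    if (!all(c(cmp$null, cmp$alt) %in% names(fits)))
      stop("comparison references absent fit: ", cmp$null, " vs ", cmp$alt)
    df <- if (!is.null(cmp$df)) cmp$df else
      defaultDf(cmp$null, cmp$alt, fits)
    r <- lrt(fits[[cmp$null]], fits[[cmp$alt]], df)
    cbind(data.frame(comparison = paste(cmp$alt, "x", cmp$null)), r)
  }))
  list(table = new("ModelComparisonTable", table = tab, n = n,
                   logBase = logBase, best = best),
       lrt = lrtTab)
}

#' Format an LRT statistic and p-value the way comparison tables print them
#'
#' Statistics >= 10 print as integers, smaller ones with one decimal;
#' p-values below 1e-5 print as "<1e-05".
#'
#' @param stat,p numeric vectors.
#' @return character vectors (list with \code{stat} and \code{p}).
#' @export
formatLrt <- function(stat, p) {
  list(stat = ifelse(stat >= 10, sprintf("%.0f", stat),
                     sprintf("%.1f", stat)),
       p = ifelse(p < 1e-5, "<1e-05", sprintf("%.3g", p)))
}
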