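#' Accessors for opselect classes
#'
#' Small generic accessors: \code{taxa} and \code{nCodonSites} for
#' \linkS4class{CodonAlignment}; \code{branchIds} and \code{branchLengths}
#' for \linkS4class{LabeledTree}; \code{branchClasses} for
#' \linkS4class{BranchPartition}; \code{estimates} and \code{modelName} for
#' \linkS4class{CodonFitResult}.
#'
#' @param x an opselect object.
#' @return The corresponding component.
#' @name accessors
#' @aliases taxa nCodonSites branchIds branchLengths branchClasses estimates
#'   modelName
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("nCodonSites", function(x) standardGeneric("nCodonSites"))
#' @rdname accessors
#' @export
setGeneric("branchIds", function(x) standardGeneric("branchIds"))
#' @rdname accessors
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))
#' @rdname accessors
#' @export
setGeneric("branchClasses", function(x) standardGeneric("branchClasses"))
#' @rdname accessors
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))
#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname accessors
setMethod("taxa", "CodonAlignment", function(x) x@taxa)
#' @rdname accessors
setMethod("nCodonSites", "CodonAlignment", function(x) ncol(x@cells))
#' @rdname accessors
setMethod("taxa", "LabeledTree", function(x) x@phy$tip.label)
#' @rdname accessors
setMethod("branchIds", "LabeledTree", function(x) x@branchIds)
#' @rdname accessors
setMethod("branchLengths", "LabeledTree", function(x) {
  b <- x@phy$edge.length
  names(b) <- x@branchIds
  b
})
#' @rdname accessors
setMethod("branchClasses", "BranchPartition", function(x) x@classes)
#' @rdname accessors
setMethod("estimates", "CodonFitResult", function(x) x@estimates)
#' @rdname accessors
setMethod("modelName", "CodonFitResult", function(x) x@model)

#' @importFrom stats logLik
#' @export
setMethod("logLik", "CodonFitResult", function(object, ...) {
  structure(object@logLik, df = object@K, class = "logLik")
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@taxa), "taxa x",
      ncol(object@cells), "codon sites (", object@ntLength, "nt )\n")
  miss <- mean(vapply(object@cells, length, integer(1)) == codonTable()$n)
  cat(sprintf("  missing/ambiguous-to-full cells: %.1f%%\n", 100 * miss))
})

setMethod("show", "LabeledTree", function(object) {
  cat("LabeledTree:", length(object@phy$tip.label), "leaves,",
      nrow(object@phy$edge), "branches\n")
})

setMethod("show", "BranchPartition", function(object) {
  tabs <- table(factor(object@classes[object@assignment],
                       levels = object@classes))
  cat("BranchPartition:", length(object@assignment), "branches in",
      length(object@classes), "classes\n")
  for (cl in names(tabs)) cat("  ", cl, ":", tabs[[cl]], "branches\n")
  if (length(object@foreground))
    cat("  foreground:", length(object@foreground), "branches\n")
})

setMethod("show", "CodonFitResult", function(object) {
  cat("CodonFitResult [", object@model, "]  lnL =",
      format(object@logLik, nsmall = 3), " K =", object@K, "\n")
  om <- object@estimates$omega
  if (!is.null(om))
    cat("  omega:", paste(sprintf("%s=%.4g", names(om), om), collapse = ", "),
        "\n")
  cat("  kappa:", format(object@estimates$kappa, digits = 4),
      " convergence:", object@convergence$status, "\n")
})

setMethod("show", "TuningSiteProfile", function(object) {
  cat("TuningSiteProfile [", object@opsinClass, "]\n")
  res <- vapply(object@residues, function(r)
    if (all(is.na(r))) "?" else paste(r, collapse = "/"), character(1))
  cat(" ", paste(sprintf("%s:%s", names(res), res), collapse = "  "), "\n")
})

setMethod("show", "SpectralPrediction", function(object) {
  for (i in seq_along(object@lambda)) {
    lam <- if (is.na(object@lambda[i])) "  (no numeric claim)" else
      sprintf("%6.1f nm", object@lambda[i])
    cat(sprintf("  lambda-max %s  [%s] %s\n", lam, object@provenance[i],
                object@label[i]))
  }
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "),
                                "\n")
})

setMethod("show", "SpectralRuleSet", function(object) {
  cat("SpectralRuleSet [", object@opsinClass, "] base",
      paste0(names(object@baseProfile), "=", object@baseProfile, collapse = " "),
      "->", object@baseLambda, "nm;", nrow(object@combinations),
      "combination entries,", length(object@shifts), "additive shifts\n")
})
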