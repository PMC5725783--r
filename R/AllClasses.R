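#' @import methods
NULL

setOldClass("phylo")

#' Codon alignment over the 61 sense codons
#'
#' Stores an aligned set of in-frame coding sequences as taxa x codon-column
#' cells, each cell a non-empty subset of the 61 sense codons of the standard
#' genetic code. Singleton cells are observed codons, larger sets arise from
#' IUPAC nucleotide ambiguity, and the full 61-state set encodes gaps or
#' missing data.
#'
#' @slot taxa character vector of unique sequence labels.
#' @slot cells list-matrix (taxa x codon sites); each element an integer
#'   vector of sense-codon indices (see \code{\link{senseCodons}}).
#' @slot ntLength nucleotide length of the source alignment (3 x columns).
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(taxa = "character", cells = "matrix", ntLength = "integer"))

setValidity("CodonAlignment", function(object) {
  n61 <- codonTable()$n
  if (anyDuplicated(object@taxa)) return("taxa labels must be unique")
  if (nrow(object@cells) != length(object@taxa))
    return("cells rows must match taxa")
  if (object@ntLength != 3L * ncol(object@cells))
    return("ntLength must equal 3 * number of codon columns")
  ok <- vapply(object@cells, function(s)
    is.numeric(s) && length(s) >= 1L && all(s >= 1 & s <= n61), logical(1))
  if (!all(ok)) return("every cell must be a non-empty subset of the 61 sense codons")
  if (ncol(object@cells) > 0L) {
    allMissing <- vapply(seq_len(ncol(object@cells)), function(j)
      all(vapply(object@cells[, j], length, integer(1)) == n61), logical(1))
    if (any(allMissing))
      return("columns consisting entirely of missing cells are not allowed")
  }
  TRUE
})

#' Phylogenetic tree with stable branch identifiers
#'
#' Wraps an \pkg{ape} \code{phylo} object (unrooted where the input allows)
#' and attaches a deterministic identifier to every branch: the
#' comma-separated sorted leaf set on the side of the split not containing
#' the alphabetically first leaf. Identifiers are therefore invariant to the
#' leaf order of the input Newick and to (re)rooting.
#'
#' @slot phy an \code{ape::phylo} tree with branch lengths.
#' @slot branchIds character vector, one id per row of \code{phy$edge}.
#' @exportClass LabeledTree
setClass("LabeledTree",
  representation(phy = "phylo", branchIds = "character"))

setValidity("LabeledTree", function(object) {
  phy <- object@phy
  if (is.null(phy$edge.length)) return("tree must carry branch lengths")
  if (any(phy$edge.length < 0)) return("branch lengths must be >= 0")
  if (length(object@branchIds) != nrow(phy$edge))
    return("branchIds must match the number of branches")
  if (anyDuplicated(object@branchIds)) return("branchIds must be unique")
  TRUE
})

#' Assignment of branches to omega classes
#'
#' @slot classes ordered character vector of class names; the first class is
#'   the background class used for internal branches with mixed descendants.
#' @slot assignment integer vector (class index per branch) named by branch id.
#' @slot foreground character vector of branch ids treated as foreground in
#'   branch-site analyses (possibly empty).
#' @exportClass BranchPartition
setClass("BranchPartition",
  representation(classes = "character", assignment = "integer",
                 foreground = "character"))

setValidity("BranchPartition", function(object) {
  a <- object@assignment
  if (is.null(names(a))) return("assignment must be named by branch id")
  if (any(a < 1 | a > length(object@classes)))
    return("assignment indices must reference classes")
  if (!all(object@foreground %in% names(a)))
    return("foreground must be a subset of assigned branches")
  TRUE
})

#' Fitted codon model
#'
#' @slot model model template name (e.g. "M0", "M1a", "branch", "ModelA").
#' @slot logLik maximized log-likelihood.
#' @slot estimates named list of all free-parameter estimates (kappa, omega
#'   values, mixture proportions, branch lengths).
#' @slot K number of parameters actually optimized.
#' @slot convergence list with optimizer status, number of starts and
#'   function evaluations.
#' @slot details internal fitting context used by downstream operations
#'   (site posteriors, refits).
#' @exportClass CodonFitResult
setClass("CodonFitResult",
  representation(model = "character", logLik = "numeric", estimates = "list",
                 K = "integer", convergence = "list", details = "list"))

setValidity("CodonFitResult", function(object) {
  if (!is.finite(object@logLik)) return("logLik must be finite")
  if (object@K < 0L) return("K must be non-negative")
  TRUE
})

#' Residues observed at canonical spectral tuning sites
#'
#' @slot opsinClass one of "LWS", "RH1", "SWS1".
#' @slot residues named list; names are bovine-rhodopsin site numbers, each
#'   element a character vector of amino acids (length > 1 encodes
#'   heterozygosity or ambiguity; NA encodes an unaligned/unknown site).
#' @exportClass TuningSiteProfile
setClass("TuningSiteProfile",
  representation(opsinClass = "character", residues = "list"))

setValidity("TuningSiteProfile", function(object) {
  if (!object@opsinClass %in% c("LWS", "RH1", "SWS1"))
    return("opsinClass must be LWS, RH1 or SWS1")
  canon <- tuningSites(object@opsinClass)
  if (!all(as.integer(names(object@residues)) %in% canon))
    return("site numbers must come from the canonical list for the class")
  TRUE
})

#' Spectral tuning rule set
#'
#' Encodes the base residue combination and absorption peak of an opsin
#' class, known single-substitution wavelength shifts, printed
#' combination-specific peaks (which take precedence over additive sums),
#' and qualitative rules with no numeric claim.
#'
#' @slot opsinClass one of "LWS", "RH1", "SWS1".
#' @slot baseProfile named character vector: base residue per scored site.
#' @slot baseLambda base absorption peak (nm).
#' @slot combinations data.frame with columns \code{pattern} (e.g.
#'   "S164A+T269A", "" for the base combination) and \code{lambda} (nm).
#' @slot shifts named numeric vector of single-substitution shifts (nm,
#'   signed), named like "S164A".
#' @slot qualitative named character vector mapping a substitution to a class
#'   label (e.g. F86V -> "violet-shifted").
#' @exportClass SpectralRuleSet
setClass("SpectralRuleSet",
  representation(opsinClass = "character", baseProfile = "character",
                 baseLambda = "numeric", combinations = "data.frame",
                 shifts = "numeric", qualitative = "character"))

setValidity("SpectralRuleSet", function(object) {
  if (length(object@baseLambda) != 1 || !is.finite(object@baseLambda))
    return("baseLambda must be a single finite value")
  if (length(object@shifts) && any(!is.finite(object@shifts)))
    return("all shift entries must be finite")
  TRUE
})

#' Predicted absorption peak(s) for one opsin sequence
#'
#' @slot lambda numeric vector of predicted lambda-max values in nm, one per
#'   resolved residue combination (NA where only a qualitative call is made).
#' @slot label character vector of phenotype labels parallel to
#'   \code{lambda} (e.g. "UVS", "violet-shifted", "" when none applies).
#' @slot provenance character vector: "combination", "additive" or
#'   "qualitative" per prediction.
#' @slot notes character vector of flags (unknown sites assumed base,
#'   unscored substitutions), possibly empty.
#' @slot combination list of resolved residue assignments (named character
#'   vectors) per prediction.
#' @exportClass SpectralPrediction
setClass("SpectralPrediction",
  representation(lambda = "numeric", label = "character",
                 provenance = "character", notes = "character",
                 combination = "list"))

setValidity("SpectralPrediction", function(object) {
  if (length(object@lambda) < 1L) return("at least one prediction required")
  if (length(object@label) != length(object@lambda) ||
      length(object@provenance) != length(object@lambda))
    return("label and provenance must parallel lambda")
  TRUE
})
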