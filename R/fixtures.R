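## Back-translation helpers -------------------------------------------------

## Preferred codon for an amino acid: highest pi, ties broken alphabetically.
codonForAA <- function(aa, pi = NULL) {
  tab <- codonTable()
  cand <- which(tab$aa == aa)
  if (!length(cand)) stop("no codon encodes residue '", aa, "'")
  if (is.null(pi)) return(tab$codons[cand[1]])
  tab$codons[cand[which.max(pi[cand])]]
}

## A single (possibly IUPAC-ambiguous) codon whose sense expansion encodes
## exactly the requested residue set. Searches position-wise merges of one
## codon choice per residue.
iupacCodonFor <- function(aaSet, pi = NULL) {
  aaSet <- sort(unique(aaSet))
  if (length(aaSet) == 1L) return(codonForAA(aaSet, pi))
  tab <- codonTable()
  revMap <- Biostrings::IUPAC_CODE_MAP
  iupacFor <- function(nts) {
    nts <- sort(unique(nts))
    hit <- names(revMap)[vapply(revMap, function(x)
      identical(sort(strsplit(x, "")[[1]]), nts), logical(1))]
    if (length(hit)) hit[1] else NA_character_
  }
  choices <- lapply(aaSet, function(a) tab$codons[tab$aa == a])
  combos <- expand.grid(choices, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(combos))) {
    cods <- as.character(combos[k, ])
    letters3 <- vapply(1:3, function(p)
      iupacFor(substring(cods, p, p)), character(1))
    if (any(is.na(letters3))) next
    cand <- paste(letters3, collapse = "")
    if (identical(codonSetToAA(expandCodon(cand)), aaSet)) return(cand)
  }
  stop("residue set {", paste(aaSet, collapse = ","),
       "} is not encodable by a single IUPAC codon")
}

#' Construct an opsin coding-sequence fixture with known tuning residues
#'
#' Builds a coding sequence on a bovine-rhodopsin-like backbone whose
#' translation carries the requested residues at the requested
#' bovine-numbered sites, optionally decorated with an N-terminal extension
#' and internal deletions, and with heterozygous sites emitted as single
#' IUPAC codons. The scored tuning sites of the opsin class default to the
#' rule set's base residues so that predictions are fully determined by the
#' requested substitutions. The attached truth record (expected
#' tuning-site profile and lambda-max under the default rules) is built
#' directly from the construction, independent of the extraction pipeline.
#'
#' @param opsinClass "LWS", "RH1" or "SWS1".
#' @param residues named character vector, site number -> residue.
#' @param heterozygous named list, site number -> residue set (emitted as
#'   one IUPAC codon; error if not encodable).
#' @param nTermExtension amino acids prepended before the backbone.
#' @param deletions bovine site numbers deleted from the fixture.
#' @param rules rule set supplying base residues and truth lambda.
#' @param pi optional codon frequencies driving back-translation (most
#'   frequent codon per residue).
#' @return list with \code{dna}, \code{protein} and \code{truth} (profile,
#'   prediction, residue map).
#' @export
makeOpsinFixture <- function(opsinClass, residues = character(0),
                             heterozygous = list(), nTermExtension = "",
                             deletions = integer(0),
                             rules = spectralRules(opsinClass), pi = NULL) {
  backbone <- strsplit(bovineRhodopsin(), "")[[1]]
  prot <- as.list(backbone)
  for (s in names(rules@baseProfile))
    prot[[as.integer(s)]] <- rules@baseProfile[[s]]
  for (s in names(residues)) prot[[as.integer(s)]] <- residues[[s]]
  for (s in names(heterozygous))
    prot[[as.integer(s)]] <- sort(unique(heterozygous[[s]]))
  canon <- tuningSites(opsinClass)
  truthRes <- lapply(canon, function(s) {
    if (s %in% deletions || s > length(prot)) NA_character_ else prot[[s]]
  })
  names(truthRes) <- canon
  profile <- new("TuningSiteProfile", opsinClass = opsinClass,
                 residues = truthRes)
  prediction <- predictLambdaMax(profile, rules)
  if (length(deletions)) prot <- prot[-deletions]
  if (nzchar(nTermExtension))
    prot <- c(as.list(strsplit(nTermExtension, "")[[1]]), prot)
  codons <- vapply(prot, function(r)
    if (length(r) == 1L) codonForAA(r, pi) else iupacCodonFor(r, pi),
    character(1))
  list(dna = paste(codons, collapse = ""),
       protein = paste(vapply(prot, function(r)
         if (length(r) == 1L) r else "X", character(1)), collapse = ""),
       truth = list(profile = profile, prediction = prediction,
                    residues = truthRes, deletions = deletions,
                    nTermExtension = nTermExtension))
}
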