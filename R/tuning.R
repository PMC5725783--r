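#' Canonical spectral tuning sites (bovine rhodopsin numbering)
#'
#' Site lists per opsin class: five sites for LWS (164, 181, 261, 269, 292),
#' thirteen for RH1 (83, 90, 113, 118, 122, 164, 180, 261, 265, 269, 285,
#' 292, 299), and for SWS1 the UV/violet switch at 86 plus eleven accessory
#' sites reported to tune violet pigments without driving the UV/violet
#' switch.
#'
#' @param opsinClass "LWS", "RH1" or "SWS1".
#' @return Integer vector of site numbers.
#' @export
tuningSites <- function(opsinClass = c("LWS", "RH1", "SWS1")) {
  opsinClass <- match.arg(opsinClass)
  switch(opsinClass,
    LWS  = c(164L, 181L, 261L, 269L, 292L),
    RH1  = c(83L, 90L, 113L, 118L, 122L, 164L, 180L, 261L, 265L, 269L, 285L,
             292L, 299L),
    SWS1 = c(86L, 46L, 49L, 52L, 90L, 93L, 97L, 113L, 114L, 116L, 118L, 265L))
}

#' The bovine rhodopsin reference scaffold
#'
#' Amino-acid sequence used as the numbering reference for all tuning-site
#' coordinates, shipped as plain text with the package.
#'
#' @return Single character string (348 residues).
#' @export
bovineRhodopsin <- function() {
  if (!is.null(.opselectCache$bovine)) return(.opselectCache$bovine)
  path <- system.file("extdata", "bovine_rh1_reference.fasta",
                      package = "opselect")
  lines <- readLines(path)
  seqc <- paste(lines[!startsWith(lines, ">")], collapse = "")
  .opselectCache$bovine <- seqc
  seqc
}

#' Default spectral tuning rule sets
#'
#' Encodes the published tuning rules used for prediction. LWS: base
#' S164/H181/Y261/T269/A292 with lambda-max 560 nm; substitutions S164A,
#' H181Y, Y261F, T269A, A292S shift the peak down by 7, 28, 8, 15 and 27 nm;
#' the residue combinations S164A (553 nm), S164A+Y261F (545 nm) and
#' S164A+T269A (537 nm) carry their published peaks directly and take
#' precedence over the additive sum. RH1: base D83/A292/S299 at 500 nm with
#' blue shifts of 6, 10 and 2 nm for D83N, A292S and S299A and published
#' combinations D83N+S299A (493 nm) and D83N+A292S+S299A (483 nm). SWS1: F86
#' confers UV sensitivity (360 nm, "UVS"); F86V is a qualitative
#' violet-shift call with no numeric peak.
#'
#' @param opsinClass "LWS", "RH1" or "SWS1".
#' @return A \linkS4class{SpectralRuleSet}.
#' @export
spectralRules <- function(opsinClass = c("LWS", "RH1", "SWS1")) {
  opsinClass <- match.arg(opsinClass)
  comb <- function(pattern, lambda, label = "")
    data.frame(pattern = pattern, lambda = lambda, label = label,
               stringsAsFactors = FALSE)
  switch(opsinClass,
    LWS = new("SpectralRuleSet", opsinClass = "LWS",
      baseProfile = c(`164` = "S", `181` = "H", `261` = "Y", `269` = "T",
                      `292` = "A"),
      baseLambda = 560,
      combinations = rbind(comb("", 560), comb("S164A", 553),
                           comb("S164A+Y261F", 545), comb("S164A+T269A", 537)),
      shifts = c(S164A = -7, H181Y = -28, Y261F = -8, T269A = -15,
                 A292S = -27),
      qualitative = character(0)),
    RH1 = new("SpectralRuleSet", opsinClass = "RH1",
      baseProfile = c(`83` = "D", `292` = "A", `299` = "S"),
      baseLambda = 500,
      combinations = rbind(comb("", 500), comb("D83N+S299A", 493),
                           comb("A292S+D83N+S299A", 483)),
      shifts = c(D83N = -6, A292S = -10, S299A = -2),
      qualitative = character(0)),
    SWS1 = new("SpectralRuleSet", opsinClass = "SWS1",
      baseProfile = c(`86` = "F"),
      baseLambda = 360,
      combinations = comb("", 360, "UVS"),
      shifts = numeric(0),
      qualitative = c(F86V = "violet-shifted")))
}

#' Load a spectral rule set from a plain-text configuration
#'
#' Key=value format, one entry per line; "#" comments allowed. Keys:
#' \code{class}, \code{base} (comma-separated residue+site, e.g.
#' "S164,H181"), \code{base_lambda}, \code{comb} ("S164A+T269A:537" or
#' "S164A+T269A:537:LABEL"), \code{shift} ("S164A:-7"), \code{qual}
#' ("F86V:violet-shifted").
#'
#' @param path configuration file.
#' @return A \linkS4class{SpectralRuleSet}.
#' @export
readSpectralRules <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  keys <- trimws(keys); vals <- trimws(vals)
  cls <- vals[keys == "class"][1]
  baseSpec <- strsplit(vals[keys == "base"][1], ",")[[1]]
  baseProfile <- substring(baseSpec, 1, 1)
  names(baseProfile) <- sub("^[A-Z]", "", baseSpec)
  combs <- do.call(rbind, lapply(vals[keys == "comb"], function(v) {
    p <- strsplit(v, ":", fixed = TRUE)[[1]]
    data.frame(pattern = canonicalPattern(p[1]), lambda = as.numeric(p[2]),
               label = if (length(p) >= 3) p[3] else "",
               stringsAsFactors = FALSE)
  }))
  if (is.null(combs))
    combs <- data.frame(pattern = character(0), lambda = numeric(0),
                        label = character(0))
  shifts <- vapply(vals[keys == "shift"], function(v) {
    as.numeric(strsplit(v, ":", fixed = TRUE)[[1]][2])
  }, numeric(1))
  names(shifts) <- vapply(vals[keys == "shift"], function(v)
    strsplit(v, ":", fixed = TRUE)[[1]][1], character(1))
  qual <- vapply(vals[keys == "qual"], function(v)
    strsplit(v, ":", fixed = TRUE)[[1]][2], character(1))
  names(qual) <- vapply(vals[keys == "qual"], function(v)
    strsplit(v, ":", fixed = TRUE)[[1]][1], character(1))
  new("SpectralRuleSet", opsinClass = cls, baseProfile = baseProfile,
      baseLambda = as.numeric(vals[keys == "base_lambda"][1]),
      combinations = combs, shifts = unname2(shifts),
      qualitative = unname2(qual))
}

unname2 <- function(x) { names(x) <- unname(names(x)); x }

canonicalPattern <- function(pattern) {
  if (!nzchar(pattern)) return("")
  paste(sort(strsplit(pattern, "+", fixed = TRUE)[[1]]), collapse = "+")
}

#' Map a query opsin onto reference numbering
#'
#' Global pairwise alignment (BLOSUM62, affine gaps) of the query protein
#' against the numbering reference; the returned site map pairs every
#' mutually aligned (non-gap) column. Biostrings' deterministic traceback
#' guarantees bit-reproducible maps.
#'
#' @param query amino-acid string (standard alphabet plus X).
#' @param reference amino-acid string; defaults to the bovine rhodopsin
#'   scaffold.
#' @param scoreFloor minimum acceptable alignment score; lower scores signal
#'   a non-opsin query and raise an error.
#' @return data.frame with columns \code{ref}, \code{query} (1-based
#'   positions, strictly increasing) and attribute \code{score}.
#' @export
#' @importFrom Biostrings pairwiseAlignment AAString
alignToReference <- function(query, reference = bovineRhodopsin(),
                             scoreFloor = 0) {
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  sc <- Biostrings::score(pa)
  if (sc < scoreFloor)
    stop("alignment score ", round(sc, 1), " below floor ", scoreFloor,
         " - query does not look like an opsin homolog")
  qs <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  rs <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- cumsum(qs != "-")
  ri <- cumsum(rs != "-")
  keep <- qs != "-" & rs != "-"
  map <- data.frame(ref = ri[keep], query = qi[keep])
  attr(map, "score") <- sc
  map
}

## Translate an in-frame coding sequence (possibly with IUPAC ambiguity)
## into per-codon amino-acid sets plus a representative protein string
## ("X" where ambiguous, "-" where fully missing).
translateCodonSets <- function(dna) {
  aln <- codonAlignmentFromStrings(dna, "q")
  tab <- codonTable()
  sets <- lapply(seq_len(ncol(aln@cells)), function(j)
    codonSetToAA(aln@cells[[1, j]]))
  protein <- vapply(seq_along(sets), function(j) {
    if (length(aln@cells[[1, j]]) == tab$n) "-" else
    if (length(sets[[j]]) == 1L) sets[[j]] else "X"
  }, character(1))
  list(sets = sets, protein = paste(protein, collapse = ""))
}

#' Extract residues at canonical tuning sites
#'
#' @param residueSets list of amino-acid sets per query position (from DNA
#'   translation), or a plain protein string.
#' @param siteMap site map from \code{\link{alignToReference}}.
#' @param opsinClass "LWS", "RH1" or "SWS1".
#' @return A \linkS4class{TuningSiteProfile}; sites falling in unaligned or
#'   gap regions are recorded as unknown (NA).
#' @export
extractProfile <- function(residueSets, siteMap,
                           opsinClass = c("LWS", "RH1", "SWS1")) {
  opsinClass <- match.arg(opsinClass)
  if (is.character(residueSets) && length(residueSets) == 1L)
    residueSets <- as.list(strsplit(residueSets, "")[[1]])
  sites <- tuningSites(opsinClass)
  res <- lapply(sites, function(s) {
    q <- siteMap$query[match(s, siteMap$ref)]
    if (is.na(q) || q > length(residueSets)) return(NA_character_)
    r <- residueSets[[q]]
    if (length(r) == 0L || any(r == "-")) NA_character_ else r
  })
  names(res) <- sites
  if (all(vapply(res, function(r) all(is.na(r)), logical(1))))
    stop("all canonical tuning sites are unknown - profile unusable")
  new("TuningSiteProfile", opsinClass = opsinClass, residues = res)
}

#' Extract a tuning-site profile directly from a coding sequence
#'
#' Convenience wrapper: translates the in-frame DNA (IUPAC heterozygous
#' codons yield residue sets), aligns the translation to the numbering
#' reference, and extracts the canonical sites.
#'
#' @param dna in-frame coding sequence (single string).
#' @param opsinClass "LWS", "RH1" or "SWS1".
#' @param reference numbering reference protein.
#' @param scoreFloor passed to \code{\link{alignToReference}}.
#' @return A \linkS4class{TuningSiteProfile}.
#' @export
profileFromDNA <- function(dna, opsinClass, reference = bovineRhodopsin(),
                           scoreFloor = 0) {
  tr <- translateCodonSets(dna)
  map <- alignToReference(tr$protein, reference, scoreFloor = scoreFloor)
  extractProfile(tr$sets, map, opsinClass)
}

#' Predict the visual-pigment absorption peak from a tuning-site profile
#'
#' Every resolved residue combination (Cartesian product over heterozygous
#' sites, capped) is scored: a matching published combination entry returns
#' its peak directly; otherwise the prediction is the base peak plus the sum
#' of known single-substitution shifts. Substitutions covered only by a
#' qualitative rule return a class label without a numeric claim. Unknown
#' sites assume the base residue and are flagged; substitutions covered by
#' no rule contribute 0 nm and are flagged as unscored.
#'
#' @param profile a \linkS4class{TuningSiteProfile}.
#' @param rules a \linkS4class{SpectralRuleSet} of the same opsin class;
#'   defaults to \code{spectralRules(profile@opsinClass)}.
#' @param additiveOnly ignore combination entries and always use the
#'   additive computation.
#' @param maxCombinations cap on resolved heterozygous combinations.
#' @return A \linkS4class{SpectralPrediction}.
#' @export
predictLambdaMax <- function(profile, rules = spectralRules(profile@opsinClass),
                             additiveOnly = FALSE, maxCombinations = 16L) {
  if (!identical(profile@opsinClass, rules@opsinClass))
    stop("profile class ", profile@opsinClass, " does not match rule set ",
         rules@opsinClass)
  sites <- names(rules@baseProfile)
  notes <- character(0)
  sets <- lapply(sites, function(s) {
    r <- profile@residues[[s]]
    if (is.null(r) || all(is.na(r))) {
      notes <<- c(notes, paste0("site ", s, " unknown; assumed base residue ",
                                rules@baseProfile[[s]]))
      rules@baseProfile[[s]]
    } else r
  })
  combos <- expand.grid(sets, stringsAsFactors = FALSE)
  if (nrow(combos) > maxCombinations) {
    notes <- c(notes, paste0("heterozygous combinations capped at ",
                             maxCombinations))
    combos <- combos[seq_len(maxCombinations), , drop = FALSE]
  }
  lambda <- numeric(0); label <- character(0); prov <- character(0)
  comblist <- list()
  combPatterns <- vapply(rules@combinations$pattern, canonicalPattern,
                         character(1))
  for (k in seq_len(nrow(combos))) {
    resid <- as.character(combos[k, ])
    names(resid) <- sites
    subs <- sprintf("%s%s%s", rules@baseProfile[sites], sites, resid)
    subs <- subs[resid != rules@baseProfile[sites]]
    qualHit <- subs[subs %in% names(rules@qualitative)]
    patt <- canonicalPattern(paste(sort(subs), collapse = "+"))
    hit <- if (additiveOnly) integer(0) else which(combPatterns == patt)
    if (length(qualHit)) {
      lambda <- c(lambda, NA_real_)
      label <- c(label, unname(rules@qualitative[qualHit[1]]))
      prov <- c(prov, "qualitative")
    } else if (length(hit)) {
      lambda <- c(lambda, rules@combinations$lambda[hit[1]])
      label <- c(label, rules@combinations$label[hit[1]])
      prov <- c(prov, "combination")
    } else {
      scored <- subs %in% names(rules@shifts)
      if (any(!scored))
        notes <- c(notes, paste0("unscored substitution ",
                                 paste(subs[!scored], collapse = ","),
                                 "; additive term 0"))
      lambda <- c(lambda, rules@baseLambda + sum(rules@shifts[subs[scored]]))
      label <- c(label, "")
      prov <- c(prov, "additive")
    }
    comblist[[k]] <- resid
  }
  new("SpectralPrediction", lambda = lambda, label = label, provenance = prov,
      notes = unique(notes), combination = comblist)
}
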