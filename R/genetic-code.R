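## Internal tables for the 61 sense codons of the standard genetic code.
## Built lazily from Biostrings::GENETIC_CODE and cached for the session.

.opselectCache <- new.env(parent = emptyenv())

#' @importFrom Biostrings GENETIC_CODE IUPAC_CODE_MAP
codonTable <- function() {
  if (!is.null(.opselectCache$codonTable)) return(.opselectCache$codonTable)
  nt <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  all64 <- sort(all64)                       # lexicographic ACGT
  gc <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc[all64])
  sense <- all64[aa64 != "*"]
  aa <- unname(gc[sense])
  n <- length(sense)                          # 61
  idx <- seq_len(n)
  names(idx) <- sense

  ## classify all single-nucleotide-difference codon pairs:
  ## 0 = not a single-step neighbour, 1 = syn transversion, 2 = syn transition,
  ## 3 = nonsyn transversion, 4 = nonsyn transition
  m1 <- substring(sense, 1L, 1L)
  m2 <- substring(sense, 2L, 2L)
  m3 <- substring(sense, 3L, 3L)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  cls <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    di <- (m1 != m1[i]) + (m2 != m2[i]) + (m3 != m3[i])
    j <- which(di == 1L)
    for (jj in j) {
      pos <- which(c(m1[i] != m1[jj], m2[i] != m2[jj], m3[i] != m3[jj]))
      a <- substring(sense[i], pos, pos)
      b <- substring(sense[jj], pos, pos)
      ts <- purine[a] == purine[b]            # A<->G or C<->T
      syn <- aa[i] == aa[jj]
      cls[i, jj] <- if (syn && !ts) 1L else if (syn && ts) 2L else
        if (!syn && !ts) 3L else 4L
    }
  }
  tab <- list(codons = sense, aa = aa, index = idx, n = n, pairClass = cls,
              stops = all64[aa64 == "*"])
  .opselectCache$codonTable <- tab
  tab
}

## Expand a 3-letter codon possibly containing IUPAC ambiguity codes into the
## set of compatible sense-codon indices. Gap characters (-, ., ?) or an empty
## expansion make the codon fully missing (all 61 states). Returns integer(0)
## if the codon resolves exclusively to stop codons.
expandCodon <- function(codon) {
  tab <- codonTable()
  codon <- toupper(codon)
  chars <- strsplit(codon, "")[[1]]
  if (length(chars) != 3L) stop("codon must have 3 characters: ", codon)
  if (any(chars %in% c("-", ".", "?"))) return(seq_len(tab$n))
  map <- Biostrings::IUPAC_CODE_MAP
  map["U"] <- "T"
  sets <- lapply(chars, function(ch) {
    if (!ch %in% names(map)) stop("invalid nucleotide character: ", ch)
    strsplit(map[[ch]], "")[[1]]
  })
  combos <- as.vector(outer(outer(sets[[1]], sets[[2]], paste0), sets[[3]],
                            paste0))
  hit <- tab$index[combos[combos %in% tab$codons]]
  unname(sort(hit))
}

## Translate a set of sense-codon indices to the set of amino acids it encodes.
codonSetToAA <- function(set) {
  tab <- codonTable()
  sort(unique(tab$aa[set]))
}
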