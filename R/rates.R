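#' Codon substitution rate matrix (GY94-style)
#'
#' Builds the 61x61 generator with entries q_ij = 0 for codon pairs
#' differing at more than one position and otherwise pi_j multiplied by 1,
#' kappa, omega or kappa*omega for synonymous transversions, synonymous
#' transitions, nonsynonymous transversions and nonsynonymous transitions.
#' The diagonal makes rows sum to zero and the matrix is rescaled so the
#' expected number of substitutions per codon per unit time equals one under
#' pi.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi codon frequencies (length 61, non-negative, summing to 1).
#' @param scale rescale to unit expected rate (default TRUE).
#' @return 61x61 generator with codon row/column names; \code{attr(,"pi")}
#'   carries the frequencies.
#' @export
buildRateMatrix <- function(kappa, omega, pi, scale = TRUE) {
  tab <- codonTable()
  checkPi(pi)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive")
  if (!is.finite(omega) || omega < 0) stop("omega must be non-negative")
  mult <- c(1, kappa, omega, omega * kappa)
  M <- matrix(0, tab$n, tab$n)
  nz <- tab$pairClass > 0L
  M[nz] <- mult[tab$pairClass[nz]]
  Q <- M * rep(pi, each = tab$n)          # q_ij = mult_ij * pi_j
  diag(Q) <- -rowSums(Q)
  if (scale) {
    r <- -sum(pi * diag(Q))
    if (r > 0) Q <- Q / r
  }
  dimnames(Q) <- list(tab$codons, tab$codons)
  attr(Q, "pi") <- pi
  Q
}

checkPi <- function(pi) {
  if (length(pi) != codonTable()$n || any(pi < 0) ||
      abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a length-61 simplex of codon frequencies")
  invisible(TRUE)
}

## Expected substitution rate of the unscaled generator under pi.
unnormRate <- function(kappa, omega, pi) {
  tab <- codonTable()
  mult <- c(1, kappa, omega, omega * kappa)
  M <- matrix(0, tab$n, tab$n)
  nz <- tab$pairClass > 0L
  M[nz] <- mult[tab$pairClass[nz]]
  as.numeric(pi %*% M %*% pi)
}

omegaRates <- function(kappa, omegaValues, pi)
  vapply(omegaValues, function(w) unnormRate(kappa, w, pi), numeric(1))

## Symmetric eigendecomposition of the (unscaled) reversible generator:
## P(t) = A diag(exp(ev t)) B with A = D^{-1/2} U, B = U' D^{1/2}.
## Rate scaling is applied by the caller through effective branch lengths.
codonEigen <- function(kappa, omega, pi) {
  Q <- buildRateMatrix(kappa, omega, pi, scale = FALSE)
  s <- sqrt(pmax(pi, 1e-12))
  Bsym <- (s * Q) / rep(s, each = length(s))   # D^{1/2} Q D^{-1/2}
  Bsym <- (Bsym + t(Bsym)) / 2
  eg <- eigen(Bsym, symmetric = TRUE)
  list(A = eg$vectors / s, B = t(eg$vectors) * rep(s, each = length(s)),
       ev = eg$values)
}

#' Transition probability matrix of a codon generator
#'
#' Matrix exponential exp(Qt) computed through the symmetric
#' eigendecomposition available for reversible generators.
#'
#' @param Q generator from \code{\link{buildRateMatrix}} (must carry
#'   \code{attr(,"pi")}) .
#' @param t elapsed time (branch length), >= 0.
#' @return 61x61 stochastic matrix.
#' @export
transitionMatrix <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("t must be finite and non-negative")
  pi <- attr(Q, "pi")
  if (is.null(pi)) stop("Q must carry attr 'pi' (use buildRateMatrix)")
  s <- sqrt(pmax(pi, 1e-12))
  Bsym <- (s * Q) / rep(s, each = length(s))
  Bsym <- (Bsym + t(Bsym)) / 2
  eg <- eigen(Bsym, symmetric = TRUE)
  P <- (eg$vectors / s) %*% (exp(eg$values * t) * t(eg$vectors) *
                               rep(s, each = length(s)))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Estimate codon frequencies from an alignment
#'
#' \code{F3x4} multiplies position-specific nucleotide frequencies and
#' renormalizes over the 61 sense codons; \code{F61} uses observed codon
#' proportions with a pseudocount; \code{uniform} returns 1/61 everywhere.
#' Only unambiguous (singleton) cells contribute counts. A small floor keeps
#' every sense codon representable so the reversible generator stays
#' well-conditioned.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param method "F3x4", "F61" or "uniform".
#' @param pseudocount added to each codon count under F61.
#' @return Numeric simplex of length 61 named by codon.
#' @export
codonFrequencies <- function(aln, method = c("F3x4", "F61", "uniform"),
                             pseudocount = 0.5) {
  method <- match.arg(method)
  tab <- codonTable()
  if (method == "uniform") {
    pi <- rep(1 / tab$n, tab$n)
    names(pi) <- tab$codons
    return(pi)
  }
  lens <- vapply(aln@cells, length, integer(1))
  obs <- unlist(aln@cells[lens == 1L])
  if (length(obs) == 0L) stop("alignment has no unambiguous codons")
  counts <- tabulate(obs, tab$n)
  if (method == "F61") {
    pi <- (counts + pseudocount) / (sum(counts) + tab$n * pseudocount)
  } else {
    nt <- c("A", "C", "G", "T")
    f <- sapply(1:3, function(p) {
      ch <- substring(tab$codons[obs], p, p)
      tb <- table(factor(ch, levels = nt))
      as.numeric(tb) / sum(tb)
    })
    pi <- f[match(substring(tab$codons, 1, 1), nt), 1] *
          f[match(substring(tab$codons, 2, 2), nt), 2] *
          f[match(substring(tab$codons, 3, 3), nt), 3]
    pi <- pmax(pi, 1e-8)
    pi <- pi / sum(pi)
  }
  names(pi) <- tab$codons
  pi
}
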