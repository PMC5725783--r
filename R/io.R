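#' Read a codon-aligned FASTA file
#'
#' Parses an in-frame nucleotide alignment into a
#' \linkS4class{CodonAlignment}. IUPAC ambiguity codes expand to the
#' compatible sense-codon set, codons containing gap characters become fully
#' missing (all 61 states), and internal stop codons are rejected with the
#' offending taxon and column. A terminal stop codon shared by the alignment
#' is trimmed with a message.
#'
#' @param path FASTA file of equal-length, in-frame sequences.
#' @param frameCheck reject alignments whose width is not divisible by 3.
#' @param cleandata if TRUE, drop every codon column containing a missing
#'   cell (strict mode); default keeps such columns and sums over states.
#' @return A \linkS4class{CodonAlignment}.
#' @export
#' @importFrom Biostrings readBStringSet
readCodonAlignment <- function(path, frameCheck = TRUE, cleandata = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  codonAlignmentFromStrings(as.character(ss), names(ss),
                            frameCheck = frameCheck, cleandata = cleandata)
}

## Shared constructor from raw character sequences.
codonAlignmentFromStrings <- function(seqs, labels, frameCheck = TRUE,
                                      cleandata = FALSE) {
  if (anyDuplicated(labels))
    stop("duplicate taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(range(w), collapse = "-"), ")")
  if (frameCheck && w[1] %% 3L != 0L)
    stop("alignment length ", w[1], " is not divisible by 3")
  L <- w[1] %/% 3L
  tab <- codonTable()
  cells <- matrix(vector("list", length(seqs) * L), nrow = length(seqs),
                  dimnames = list(labels, NULL))
  stopCols <- integer(0)
  for (i in seq_along(seqs)) {
    cod <- substring(toupper(seqs[i]), 3L * seq_len(L) - 2L, 3L * seq_len(L))
    for (j in seq_len(L)) {
      if (cod[j] %in% tab$stops) {
        if (j == L) { stopCols <- c(stopCols, j); cells[[i, j]] <- seq_len(tab$n) }
        else stop("internal stop codon '", cod[j], "' in taxon '", labels[i],
                  "' at codon column ", j)
        next
      }
      set <- expandCodon(cod[j])
      if (length(set) == 0L)
        stop("codon '", cod[j], "' in taxon '", labels[i], "' at codon column ",
             j, " resolves only to stop codons")
      cells[[i, j]] <- set
    }
  }
  if (length(stopCols)) {
    message("trimming terminal stop codon column ", L)
    cells <- cells[, -L, drop = FALSE]
    L <- L - 1L
  }
  if (cleandata && L > 0L) {
    full <- vapply(seq_len(L), function(j)
      any(vapply(cells[, j], length, integer(1)) == tab$n), logical(1))
    if (any(full)) {
      message("cleandata: dropping ", sum(full), " columns with missing cells")
      cells <- cells[, !full, drop = FALSE]
    }
  }
  new("CodonAlignment", taxa = labels, cells = cells,
      ntLength = 3L * ncol(cells))
}

#' Write a codon alignment back to FASTA
#'
#' Singleton cells print their codon, fully missing cells print "---", and
#' ambiguity sets that factorize by codon position print the minimal IUPAC
#' codon; non-factorizable sets degrade to "NNN".
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param path output file.
#' @export
writeCodonAlignment <- function(aln, path) {
  tab <- codonTable()
  revMap <- Biostrings::IUPAC_CODE_MAP
  ntOf <- function(set, pos) sort(unique(substring(tab$codons[set], pos, pos)))
  iupacFor <- function(nts) {
    hit <- names(revMap)[vapply(revMap, function(x)
      identical(sort(strsplit(x, "")[[1]]), nts), logical(1))]
    if (length(hit)) hit[1] else NA_character_
  }
  lines <- character(0)
  for (i in seq_along(aln@taxa)) {
    cods <- vapply(seq_len(ncol(aln@cells)), function(j) {
      set <- aln@cells[[i, j]]
      if (length(set) == tab$n) return("---")
      if (length(set) == 1L) return(tab$codons[set])
      letters3 <- vapply(1:3, function(p) iupacFor(ntOf(set, p)), character(1))
      if (any(is.na(letters3))) return("NNN")
      cand <- paste(letters3, collapse = "")
      if (identical(expandCodon(cand), set)) cand else "NNN"
    }, character(1))
    lines <- c(lines, paste0(">", aln@taxa[i]), paste(cods, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

## Deterministic branch identifiers: the sorted leaf set on the smaller side
## of the split the branch induces (ties broken towards the side without the
## alphabetically first leaf; child side as fallback for the degenerate
## 2-leaf tree). Terminal branches are therefore named by their leaf.
makeBranchIds <- function(phy) {
  ntip <- length(phy$tip.label)
  sides <- edgeLeafSides(phy)
  first <- sort(phy$tip.label)[1]
  ids <- vapply(sides, function(s) {
    other <- setdiff(sort(phy$tip.label), s)
    s <- if (length(s) < length(other)) s
         else if (length(other) < length(s)) other
         else if (first %in% s) other else s
    paste(sort(s), collapse = ",")
  }, character(1))
  if (anyDuplicated(ids))
    ids <- vapply(sides, function(s) paste(sort(s), collapse = ","),
                  character(1))
  ids
}

## Leaf labels on the child side of every edge.
edgeLeafSides <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(phy$edge[, 2], function(ch) desc[[ch]])
}

#' Read a Newick tree and assign stable branch identifiers
#'
#' The tree is stored unrooted (a degree-2 root is collapsed, merging the two
#' root edges into one branch) and every branch receives a deterministic
#' identifier derived from the leaf bipartition it induces, so identifiers do
#' not depend on the leaf order of the input file.
#'
#' @param path Newick file (lines starting with "#" are ignored).
#' @param taxa optional character vector (e.g. alignment taxa); tree leaves
#'   absent from it are pruned or rejected per \code{onExtra}.
#' @param onExtra "reject" (default) or "prune" leaves not in \code{taxa}.
#' @param defaultLength if the file lacks some branch lengths, use this value
#'   for them; NULL (default) rejects such trees.
#' @return A \linkS4class{LabeledTree}.
#' @export
#' @importFrom ape read.tree unroot drop.tip
readLabeledTree <- function(path, taxa = NULL, onExtra = c("reject", "prune"),
                            defaultLength = NULL) {
  onExtra <- match.arg(onExtra)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  phy <- ape::read.tree(text = paste(lines, collapse = "\n"))
  if (is.null(phy)) stop("could not parse Newick in ", path)
  labeledTreeFromPhylo(phy, taxa = taxa, onExtra = onExtra,
                       defaultLength = defaultLength)
}

## Shared constructor from an ape phylo object.
labeledTreeFromPhylo <- function(phy, taxa = NULL, onExtra = "reject",
                                 defaultLength = NULL) {
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    if (is.null(defaultLength))
      stop("tree is missing branch lengths (set defaultLength to accept)")
    if (is.null(phy$edge.length))
      phy$edge.length <- rep(defaultLength, nrow(phy$edge))
    phy$edge.length[is.na(phy$edge.length)] <- defaultLength
  }
  if (!is.null(taxa)) {
    extra <- setdiff(phy$tip.label, taxa)
    if (length(extra)) {
      if (onExtra == "reject")
        stop("tree leaves absent from alignment: ",
             paste(extra, collapse = ", "))
      warning("pruning tree leaves absent from alignment: ",
              paste(extra, collapse = ", "))
      phy <- ape::drop.tip(phy, extra)
    }
  }
  if (length(phy$tip.label) > 2L) phy <- ape::unroot(phy)
  new("LabeledTree", phy = phy, branchIds = makeBranchIds(phy))
}

#' Write a LabeledTree to Newick
#' @param tree a \linkS4class{LabeledTree}.
#' @param path output file.
#' @export
writeLabeledTree <- function(tree, path) {
  ape::write.tree(tree@phy, file = path)
  invisible(path)
}

#' Read a species activity/clade table
#'
#' Tab-separated text with columns \code{species}, \code{activity}
#' (\code{D}/\code{N} or \code{diurnal}/\code{nocturnal}) and optionally
#' \code{clade} (\code{non-snake}, \code{henophidian}, \code{colubrinae},
#' \code{dipsadinae}) plus \code{habitat}. Lines starting with "#" are
#' recorded as comments.
#'
#' @param path file path.
#' @return data.frame with normalized \code{activity}; comment lines kept in
#'   \code{attr(,"comments")}.
#' @export
#' @importFrom utils read.delim
readActivityTable <- function(path) {
  lines <- readLines(path)
  comments <- lines[grepl("^\\s*#", lines)]
  tab <- utils::read.delim(text = paste(lines[!grepl("^\\s*#", lines)],
                                        collapse = "\n"),
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("species", "activity") %in% names(tab)))
    stop("activity table needs 'species' and 'activity' columns")
  act <- tolower(tab$activity)
  act[act == "d"] <- "diurnal"
  act[act == "n"] <- "nocturnal"
  if (!all(act %in% c("diurnal", "nocturnal")))
    stop("activity must be D/N or diurnal/nocturnal")
  tab$activity <- act
  attr(tab, "comments") <- comments
  tab
}

#' Assign tree branches to omega classes under a labeling scheme
#'
#' Implements the lineage-class structures used by branch models: a single
#' ratio for all branches; snake vs non-snake; non-snake / henophidian /
#' colubrid; the two four-class schemes splitting colubrids by subfamily or
#' by daily activity pattern; and a free scheme with one class per branch.
#' Leaf branches take their species' class. By default an internal branch
#' takes a class only when one side of its bipartition consists purely of
#' leaves of that (non-background) class; otherwise it takes the background
#' class (monophyletic-clade labeling). \code{internal = "leaf-only"}
#' restricts non-background classes to terminal branches.
#'
#' @param tree a \linkS4class{LabeledTree}.
#' @param table activity/clade data.frame (see
#'   \code{\link{readActivityTable}}); unused for schemes "1w" and "free".
#' @param scheme one of "1w", "2w", "3w", "4w", "4w-activity", "free".
#' @param internal "clade" (default) or "leaf-only".
#' @param foreground optional class name(s) whose branches are marked
#'   foreground for branch-site analyses, or explicit branch ids.
#' @return A \linkS4class{BranchPartition}.
#' @export
labelBranches <- function(tree, table = NULL,
                          scheme = c("1w", "2w", "3w", "4w", "4w-activity",
                                     "free"),
                          internal = c("clade", "leaf-only"),
                          foreground = NULL) {
  scheme <- match.arg(scheme)
  internal <- match.arg(internal)
  ids <- tree@branchIds
  if (scheme == "free") {
    part <- new("BranchPartition", classes = ids,
                assignment = structure(seq_along(ids), names = ids),
                foreground = character(0))
    return(addForeground(part, foreground))
  }
  if (scheme == "1w") {
    part <- new("BranchPartition", classes = "all",
                assignment = structure(rep(1L, length(ids)), names = ids),
                foreground = character(0))
    return(addForeground(part, foreground))
  }
  if (is.null(table)) stop("scheme '", scheme, "' needs an activity table")
  leaves <- tree@phy$tip.label
  missing <- setdiff(leaves, table$species)
  if (length(missing))
    stop("species missing from table: ", paste(missing, collapse = ", "))
  row <- match(leaves, table$species)
  clade <- if ("clade" %in% names(table)) tolower(table$clade[row]) else
    rep("colubrid", length(leaves))
  act <- table$activity[row]
  leafClass <- switch(scheme,
    "2w" = ifelse(clade == "non-snake", "non-snake", "snake"),
    "3w" = ifelse(clade == "non-snake", "non-snake",
            ifelse(clade == "henophidian", "henophidian", "colubrid")),
    "4w" = {
      ok <- clade %in% c("non-snake", "henophidian", "colubrinae", "dipsadinae")
      if (!all(ok))
        stop("scheme 4w needs clade values non-snake/henophidian/",
             "colubrinae/dipsadinae; offending: ",
             paste(unique(clade[!ok]), collapse = ", "))
      clade
    },
    "4w-activity" = ifelse(clade == "non-snake", "non-snake",
            ifelse(clade == "henophidian", "henophidian",
                   paste0(act, "-colubrid"))))
  classes <- switch(scheme,
    "2w" = c("non-snake", "snake"),
    "3w" = c("non-snake", "henophidian", "colubrid"),
    "4w" = c("non-snake", "henophidian", "colubrinae", "dipsadinae"),
    "4w-activity" = c("non-snake", "henophidian", "diurnal-colubrid",
                      "nocturnal-colubrid"))
  classes <- classes[classes %in% leafClass]     # tolerate absent lineages
  if (length(classes) == 0L) stop("contradictory clade definition: no leaves classified")
  names(leafClass) <- leaves
  sides <- edgeLeafSides(tree@phy)
  assign <- vapply(seq_along(ids), function(k) {
    s1 <- sides[[k]]
    s2 <- setdiff(leaves, s1)
    ## a terminal branch always takes its species' class
    if (length(s1) == 1L) return(match(leafClass[s1], classes))
    if (length(s2) == 1L) return(match(leafClass[s2], classes))
    if (internal == "leaf-only") return(1L)
    c1 <- unique(leafClass[s1]); c2 <- unique(leafClass[s2])
    if (length(c1) == 1L && match(c1, classes) > 1L) return(match(c1, classes))
    if (length(c2) == 1L && match(c2, classes) > 1L) return(match(c2, classes))
    1L
  }, integer(1))
  names(assign) <- ids
  part <- new("BranchPartition", classes = classes, assignment = assign,
              foreground = character(0))
  addForeground(part, foreground)
}

addForeground <- function(part, foreground) {
  if (is.null(foreground)) return(part)
  ids <- names(part@assignment)
  if (all(foreground %in% part@classes)) {
    fg <- ids[part@classes[part@assignment] %in% foreground]
  } else if (all(foreground %in% ids)) {
    fg <- foreground
  } else stop("foreground must name partition classes or branch ids")
  part@foreground <- fg
  validObject(part)
  part
}
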