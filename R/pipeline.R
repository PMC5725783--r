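## ---------------------------------------------------------------------------
## End-to-end orchestration: selection analysis and spectral report
## ---------------------------------------------------------------------------

## tiny FNV-1a hash so outputs can carry a config fingerprint without extra
## dependencies
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% (2^31 - 1)
  sprintf("%08x", as.integer(h))
}

parseModelName <- function(m) {
  hit <- regmatches(m, regexec("^(ModelA(?:-null)?)\\((.+)\\)$", m))[[1]]
  if (length(hit)) list(template = hit[2], foreground = hit[3])
  else list(template = m, foreground = NULL)
}

branchSchemes <- c("1w", "2w", "3w", "4w", "4w-activity", "free")

#' Run a full selection analysis over branch, site and branch-site models
#'
#' Fits every requested model (branch schemes are labeled from the activity
#' table; "ModelA(class)" / "ModelA-null(class)" use that class's branches
#' as foreground), compares them by LRT and BIC, flags the best branch
#' model, and computes site posteriors for positive-selection models whose
#' LRT is significant at \code{alpha}.
#'
#' @param alignment \linkS4class{CodonAlignment} or FASTA path.
#' @param tree \linkS4class{LabeledTree} or Newick path.
#' @param labels activity table data.frame or TSV path (needed for branch
#'   schemes other than "1w"/"free" and for foreground classes).
#' @param models character vector of model names.
#' @param comparisons "default" or an explicit list for
#'   \code{\link{compareModels}}.
#' @param bicN sample size for BIC; default alignment length in codons.
#' @param logBase BIC logarithm base.
#' @param siteMethod "NEB" or "BEB" for site posteriors.
#' @param pi frequency method or numeric simplex.
#' @param alpha significance level gating posterior computation.
#' @param seed seed forwarded to every fit.
#' @param nStarts optimizer starts per fit.
#' @param outDir optional output directory for TSV/JSON artifacts (created
#'   if needed); every file carries the config hash and seed.
#' @param ... further arguments to \code{\link{fitCodonModel}}.
#' @return list with \code{fits}, \code{table}
#'   (\linkS4class{ModelComparisonTable}), \code{lrt}, \code{posteriors},
#'   \code{best}, \code{config}.
#' @export
runSelectionAnalysis <- function(alignment, tree, labels = NULL,
                                 models = c("1w", "2w"),
                                 comparisons = "default", bicN = NULL,
                                 logBase = 10, siteMethod = "NEB",
                                 pi = "F3x4", alpha = 0.05, seed = 1L,
                                 nStarts = 1L, outDir = NULL, ...) {
  if (is.character(alignment)) alignment <- readCodonAlignment(alignment)
  if (is.character(tree)) tree <- readLabeledTree(tree, taxa = taxa(alignment),
                                                 onExtra = "prune")
  if (is.character(labels)) labels <- readActivityTable(labels)
  if (!length(models)) stop("model set must be non-empty")
  cfg <- list(models = models, bicN = bicN, logBase = logBase,
              siteMethod = siteMethod, alpha = alpha, seed = seed,
              nStarts = nStarts)
  if (is.null(bicN)) bicN <- nCodonSites(alignment)
  piVec <- if (is.character(pi)) codonFrequencies(alignment, pi) else pi

  fits <- list(); warm <- NULL
  for (m in models) {
    pm <- parseModelName(m)
    stage <- paste0("fit[", m, "]")
    res <- tryCatch({
      if (pm$template %in% branchSchemes) {
        part <- labelBranches(tree, labels, scheme = pm$template)
        fitCodonModel(alignment, tree,
                      if (pm$template == "1w") "M0" else "branch",
                      partition = part, pi = piVec, seed = seed,
                      nStarts = nStarts, init = warm, ...)
      } else if (!is.null(pm$foreground)) {
        part <- labelBranches(tree, labels, scheme = "4w-activity",
                              foreground = pm$foreground)
        fitCodonModel(alignment, tree, pm$template, partition = part,
                      pi = piVec, seed = seed, nStarts = nStarts,
                      init = warm, ...)
      } else {
        fitCodonModel(alignment, tree, pm$template, pi = piVec, seed = seed,
                      nStarts = nStarts, init = warm, ...)
      }
    }, error = function(e)
      stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE))
    fits[[m]] <- res
    if (is.null(warm)) warm <- res
  }

  if (identical(comparisons, "default")) comparisons <- defaultComparisons(models)
  cmp <- compareModels(fits, comparisons, n = bicN, logBase = logBase)

  ## positive-selection models with a significant LRT get site posteriors
  posteriors <- list()
  posMap <- list(M2a = "M1a", M8 = "M7")
  for (m in names(fits)) {
    pm <- parseModelName(m)
    isPos <- pm$template %in% c("M2a", "M8", "ModelA")
    if (!isPos) next
    nullName <- if (pm$template == "ModelA")
      sub("ModelA", "ModelA-null", m, fixed = TRUE) else posMap[[pm$template]]
    sig <- TRUE
    if (!is.null(nullName) && nullName %in% names(fits)) {
      row <- cmp$lrt[grepl(paste0("^", escapeRe(m), " x "), cmp$lrt$comparison), ]
      sig <- nrow(row) == 0 || any(row$p < alpha)
    }
    if (sig)
      posteriors[[m]] <- sitePosteriors(fits[[m]], alignment, tree,
                                        method = siteMethod)
  }
  out <- list(fits = fits, table = cmp$table, lrt = cmp$lrt,
              posteriors = posteriors, best = cmp$table@best,
              config = c(cfg, hash = configHash(cfg)))
  if (!is.null(outDir)) writeSelectionOutputs(out, outDir)
  out
}

escapeRe <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

defaultComparisons <- function(models) {
  cand <- list(c("1w", "2w"), c("2w", "3w"), c("3w", "4w"),
               c("3w", "4w-activity"), c("1w", "free"),
               c("M0", "M3"), c("M1a", "M2a"), c("M7", "M8"))
  out <- Filter(function(p) all(p %in% models), cand)
  out <- lapply(out, function(p) list(null = p[1], alt = p[2]))
  for (m in models) {
    pm <- parseModelName(m)
    if (pm$template == "ModelA") {
      nullName <- sub("ModelA", "ModelA-null", m, fixed = TRUE)
      if (nullName %in% models)
        out[[length(out) + 1L]] <- list(null = nullName, alt = m, df = 2)
    }
  }
  out
}

writeSelectionOutputs <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# opselect selection analysis  config=%s seed=%s",
                 out$config[["hash"]], out$config[["seed"]])
  tf <- file.path(outDir, "model_table.tsv")
  writeLines(hdr, tf)
  suppressWarnings(utils::write.table(out$table@table, tf, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  lf <- file.path(outDir, "lrt.tsv")
  writeLines(hdr, lf)
  if (!is.null(out$lrt))
    suppressWarnings(utils::write.table(out$lrt, lf, sep = "\t",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
  fitsJson <- lapply(out$fits, function(f)
    list(model = f@model, lnL = f@logLik, K = f@K,
         estimates = f@estimates[setdiff(names(f@estimates),
                                         "branchLengths")],
         branchLengths = as.list(f@estimates$branchLengths),
         convergence = f@convergence))
  jsonlite::write_json(list(config = out$config, fits = fitsJson,
                            best = out$best),
                       file.path(outDir, "fits.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (m in names(out$posteriors)) {
    sp <- out$posteriors[[m]]
    pf <- file.path(outDir, paste0("posterior_", gsub("[^A-Za-z0-9-]", "_", m),
                                   ".tsv"))
    writeLines(c(hdr, paste0("# method=", sp@method)), pf)
    df <- data.frame(site = seq_len(nrow(sp@posterior)),
                     round(sp@posterior, 6),
                     positive = round(rowSums(
                       sp@posterior[, sp@positiveClasses, drop = FALSE]), 6))
    suppressWarnings(utils::write.table(df, pf, sep = "\t",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
  }
  invisible(outDir)
}

#' Per-species spectral tuning report
#'
#' Translates each coding sequence, maps it onto bovine rhodopsin
#' numbering, extracts the canonical tuning sites for the opsin class and
#' predicts lambda-max, yielding one row per species: residues per site,
#' predicted peak(s), rule provenance and a heterozygosity flag.
#'
#' @param sequences named character vector of coding sequences, or a FASTA
#'   path.
#' @param opsinClass "LWS", "RH1" or "SWS1".
#' @param rules optional \linkS4class{SpectralRuleSet} override.
#' @param outFile optional TSV output path.
#' @param scoreFloor forwarded to \code{\link{alignToReference}}.
#' @return data.frame (zero rows, with a warning, for empty input).
#' @export
runSpectralReport <- function(sequences, opsinClass, rules = NULL,
                              outFile = NULL, scoreFloor = 0) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    ss <- Biostrings::readBStringSet(sequences)
    sequences <- stats::setNames(as.character(ss), names(ss))
  }
  if (length(sequences) && is.null(names(sequences)))
    stop("sequences must be a named vector or an existing FASTA path")
  if (is.null(rules)) rules <- spectralRules(opsinClass)
  sites <- tuningSites(opsinClass)
  if (!length(sequences)) {
    warning("empty input: no sequences to report on")
    return(data.frame(species = character(0)))
  }
  rows <- lapply(names(sequences), function(sp) {
    prof <- tryCatch(profileFromDNA(sequences[[sp]], opsinClass,
                                    scoreFloor = scoreFloor),
                     error = function(e)
                       stop("species '", sp, "': ", conditionMessage(e),
                            call. = FALSE))
    pred <- predictLambdaMax(prof, rules)
    r <- data.frame(species = sp)
    for (s in sites) {
      v <- prof@residues[[as.character(s)]]
      r[[paste0("site", s)]] <- if (all(is.na(v))) "?" else
        paste(v, collapse = "/")
    }
    lam <- ifelse(is.na(pred@lambda), pred@label,
                  sub("\\.0$", "", sprintf("%.1f", pred@lambda)))
    r$lambda_max <- paste(lam, collapse = " / ")
    r$provenance <- paste(unique(pred@provenance), collapse = "+")
    r$heterozygous <- any(vapply(prof@residues, function(v)
      length(v) > 1L, logical(1)))
    r$notes <- paste(pred@notes, collapse = "; ")
    r
  })
  tab <- do.call(rbind, rows)
  if (!is.null(outFile)) {
    writeLines(sprintf("# opselect spectral report  class=%s", opsinClass),
               outFile)
    suppressWarnings(utils::write.table(tab, outFile, sep = "\t",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
  }
  tab
}
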