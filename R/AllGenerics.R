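## Generics, accessors and show methods.

#' Equilibrium frequencies of a substitution model
#'
#' @param object an \linkS4class{AminoAcidModel} or
#'   \linkS4class{CodonModel}.
#' @param site optional 1-based alignment column; in site-specific mode the
#'   column's own frequency vector is returned.
#' @return a named numeric vector of stationary frequencies.
#' @export
setGeneric("modelFrequencies", function(object, site = NULL)
  standardGeneric("modelFrequencies"))

#' @rdname modelFrequencies
#' @export
setMethod("modelFrequencies", "AminoAcidModel", function(object, site = NULL) {
  row <- .freqRow(object, site)
  stats::setNames(object@frequencies[row, ], AA_ALPHABET)
})

#' @rdname modelFrequencies
#' @export
setMethod("modelFrequencies", "CodonModel", function(object, site = NULL) {
  stats::setNames(object@codonFrequencies, SENSE_CODONS)
})

#' Model mode accessor
#' @param object an \linkS4class{AminoAcidModel}.
#' @return the mode string.
#' @export
setGeneric("modelMode", function(object) standardGeneric("modelMode"))

#' @rdname modelMode
#' @export
setMethod("modelMode", "AminoAcidModel", function(object) object@mode)

#' MAP ancestral states
#'
#' @param object an \linkS4class{AncestralReconstruction}.
#' @param node optional internal-node label.
#' @return character matrix of MAP residues (node x site), or one node's
#'   vector.
#' @export
setGeneric("mapStates", function(object, node = NULL)
  standardGeneric("mapStates"))

#' @rdname mapStates
#' @export
setMethod("mapStates", "AncestralReconstruction", function(object, node = NULL) {
  if (is.null(node)) object@mapStates else object@mapStates[node, ]
})

#' Posterior state distributions of an ancestral reconstruction
#'
#' @param object an \linkS4class{AncestralReconstruction}.
#' @param node optional internal-node label.
#' @param site optional 1-based site index.
#' @return the posterior array, sliced if \code{node}/\code{site} given.
#' @export
setGeneric("nodePosteriors", function(object, node = NULL, site = NULL)
  standardGeneric("nodePosteriors"))

#' @rdname nodePosteriors
#' @export
setMethod("nodePosteriors", "AncestralReconstruction",
  function(object, node = NULL, site = NULL) {
    p <- object@posteriors
    if (!is.null(node) && !is.null(site)) return(p[node, site, ])
    if (!is.null(node)) return(p[node, , ])
    if (!is.null(site)) return(p[, site, ])
    p
  })

#' Per-site log-likelihoods
#' @param object an \linkS4class{AncestralReconstruction}.
#' @return numeric vector, one value per alignment column.
#' @export
setGeneric("siteLogLikelihoods", function(object)
  standardGeneric("siteLogLikelihoods"))

#' @rdname siteLogLikelihoods
#' @export
setMethod("siteLogLikelihoods", "AncestralReconstruction",
  function(object) object@siteLogLik)

#' Substitution-class counts of a branch-pair profile
#' @param object a \linkS4class{BranchPairProfile} or
#'   \linkS4class{ConvergenceTest}.
#' @return named integer vector of per-class site counts.
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))

#' @rdname classCounts
#' @export
setMethod("classCounts", "BranchPairProfile", function(object) object@counts)

#' @rdname classCounts
#' @export
setMethod("classCounts", "ConvergenceTest",
  function(object) object@profile@counts)

#' Per-branch rate table
#' @param object a \linkS4class{BranchRates}.
#' @return data frame with branch, t, dN, dS, omega.
#' @export
setGeneric("branchRates", function(object) standardGeneric("branchRates"))

#' @rdname branchRates
#' @export
setMethod("branchRates", "BranchRates", function(object) object@rates)

show_counts <- function(counts) {
  paste(sprintf("%s=%d", names(counts), counts), collapse = " ")
}

setMethod("show", "AminoAcidModel", function(object) {
  cat(sprintf("AminoAcidModel (%s), %d frequency vector(s), pseudocount %g\n",
              object@mode, nrow(object@frequencies), object@pseudocount))
})

setMethod("show", "CodonModel", function(object) {
  om <- object@omega
  om_txt <- if (length(om) == 1L) sprintf("omega = %.4g", om)
    else sprintf("%d branch omegas in [%.3g, %.3g]",
                 length(om), min(om), max(om))
  cat(sprintf("CodonModel (GY94, %s): kappa = %.4g, %s\n",
              object@frequencyModel, object@kappa, om_txt))
})

setMethod("show", "AncestralReconstruction", function(object) {
  d <- dim(object@posteriors)
  cat(sprintf(paste0("AncestralReconstruction (%s): %d internal nodes x %d",
                     " sites, total lnL = %.4f\n"),
              object@mode, d[1], d[2], sum(object@siteLogLik)))
})

setMethod("show", "BranchPairProfile", function(object) {
  cat(sprintf("BranchPairProfile %s vs %s\n  %s\n",
              object@branchA, object@branchB, show_counts(object@counts)))
})

setMethod("show", "ConvergenceTest", function(object) {
  cat(sprintf("ConvergenceTest (%s) %s vs %s\n", object@method,
              object@profile@branchA, object@profile@branchB))
  cat(sprintf("  observed conv = %d (E = %.4g, p = %.4g)\n",
              object@profile@counts[["convergent"]], object@expectedConv,
              object@pConv))
  cat(sprintf("  observed par  = %d (E = %.4g, p = %.4g)\n",
              object@profile@counts[["parallel"]], object@expectedPar,
              object@pPar))
})

setMethod("show", "RegressionNull", function(object) {
  cat(sprintf(paste0("RegressionNull: %d branch pairs, y = %.4g + %.4g x,",
                     " r^2 = %.4f, %d flagged\n"),
              nrow(object@points), object@intercept, object@slope,
              object@rSquared, sum(object@points$flagged)))
})

setMethod("show", "BranchRates", function(object) {
  cat(sprintf("BranchRates (%s): %d branches, kappa = %.4g\n",
              object@method, nrow(object@rates), object@kappa))
  print(utils::head(object@rates, 8))
  if (nrow(object@rates) > 8) cat("  ...\n")
})

setMethod("show", "BranchSiteFit", function(object) {
  cat(sprintf("BranchSiteFit (foreground: %s)\n", object@foreground))
  cat(sprintf("  lnL alt = %.4f, lnL null = %.4f, LRT = %.4f, p = %.4g\n",
              object@lnLAlt, object@lnLNull, object@lrt, object@pValue))
  cat(sprintf("  omega2 = %.4g, %d sites with posterior > 0.5\n",
              object@paramsAlt[["omega2"]],
              sum(object@sitePosteriors > 0.5)))
})

setMethod("show", "GeneScreenReport", function(object) {
  st <- object@status$status
  cat(sprintf("GeneScreenReport: %d genes (%d ok, %d skipped/failed)\n",
              nrow(object@status), sum(st == "ok"), sum(st != "ok")))
  if (nrow(object@psg))
    cat(sprintf("  branch-site: %d genes with q < 0.05\n",
                sum(object@psg$q < 0.05, na.rm = TRUE)))
  if (nrow(object@convergence))
    cat(sprintf("  convergence: %d gene-pair tests with p < 0.05\n",
                sum(pmin(object@convergence$pConv,
                         object@convergence$pPar) < 0.05, na.rm = TRUE)))
})
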