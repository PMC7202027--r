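## S4 classes for the screen's central objects.

setOldClass("phylo")

#' Amino-acid substitution model (JTT family)
#'
#' A general time-reversible amino-acid model built from the published JTT
#' exchangeabilities and a set of equilibrium frequencies. Frequencies may be
#' the published JTT stationary frequencies (\code{mode = "JTT"}), observed
#' gene-wide frequencies (\code{"JTT-Fgene"}, alias \code{"JTT-F"}), or one
#' frequency vector per alignment column (\code{"JTT-Fsite"}). The rate
#' matrix for each frequency vector is normalised to one expected
#' substitution per site per unit branch length.
#'
#' @slot exchangeabilities symmetric 20 x 20 nonnegative matrix.
#' @slot frequencies numeric matrix, one row per frequency vector (a single
#'   row except in site-specific mode), columns in fixed residue order.
#' @slot mode character, one of \code{"JTT"}, \code{"JTT-F"},
#'   \code{"JTT-Fgene"}, \code{"JTT-Fsite"}.
#' @slot pseudocount per-residue smoothing count used for observed
#'   frequencies.
#' @slot decompositions list of symmetric eigendecompositions (one per
#'   frequency row) used to compute transition matrices.
#' @slot siteMap integer vector mapping alignment columns to frequency rows
#'   (length one in non-site-specific modes).
#' @export
setClass("AminoAcidModel",
  representation(
    exchangeabilities = "matrix",
    frequencies = "matrix",
    mode = "character",
    pseudocount = "numeric",
    decompositions = "list",
    siteMap = "integer"
  )
)

setValidity("AminoAcidModel", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@exchangeabilities,
                        t(object@exchangeabilities), tolerance = 1e-12)))
    msg <- c(msg, "exchangeabilities must be symmetric")
  if (any(object@exchangeabilities < 0))
    msg <- c(msg, "exchangeabilities must be nonnegative")
  if (ncol(object@frequencies) != 20L)
    msg <- c(msg, "frequencies must have 20 columns")
  rs <- rowSums(object@frequencies)
  if (any(abs(rs - 1) > 1e-12))
    msg <- c(msg, "each frequency vector must sum to 1 (within 1e-12)")
  if (any(object@frequencies <= 0))
    msg <- c(msg, "all frequencies must be positive after smoothing")
  if (!object@mode %in% c("JTT", "JTT-F", "JTT-Fgene", "JTT-Fsite"))
    msg <- c(msg, "unknown model mode")
  if (length(msg)) msg else TRUE
})

#' Goldman-Yang codon substitution model
#'
#' @slot kappa transition/transversion rate ratio, positive.
#' @slot omega named numeric vector of dN/dS ratios: a single shared value,
#'   or one value per branch (names are branch identifiers).
#' @slot codonFrequencies numeric vector over the 61 sense codons, summing
#'   to 1.
#' @slot frequencyModel character, one of \code{"F1x4"}, \code{"F3x4"},
#'   \code{"F61"}.
#' @export
setClass("CodonModel",
  representation(
    kappa = "numeric",
    omega = "numeric",
    codonFrequencies = "numeric",
    frequencyModel = "character"
  )
)

setValidity("CodonModel", function(object) {
  msg <- character()
  if (length(object@kappa) != 1L || object@kappa <= 0)
    msg <- c(msg, "kappa must be a single positive value")
  if (any(object@omega < 0))
    msg <- c(msg, "omega values must be nonnegative")
  if (length(object@codonFrequencies) != 61L)
    msg <- c(msg, "codonFrequencies must cover the 61 sense codons")
  else if (abs(sum(object@codonFrequencies) - 1) > 1e-12)
    msg <- c(msg, "codon frequencies must sum to 1 (within 1e-12)")
  if (!object@frequencyModel %in% c("F1x4", "F3x4", "F61"))
    msg <- c(msg, "unknown codon frequency model")
  if (length(msg)) msg else TRUE
})

#' Marginal ancestral reconstruction
#'
#' Per internal node and alignment column, the empirical-Bayes posterior
#' distribution over residues and the most-probable (MAP) state, from one
#' down-pass and one up-pass of Felsenstein pruning.
#'
#' @slot tree rooted \code{phylo} tree with stable node labels.
#' @slot posteriors 3-d array (internal node x site x residue) of posterior
#'   probabilities; each site vector sums to 1.
#' @slot mapStates character matrix (internal node x site) of MAP residues.
#' @slot tipStates character matrix (tip x site) of observed residues.
#' @slot siteLogLik per-site log-likelihood under the model used.
#' @slot mode model mode used for the reconstruction.
#' @export
setClass("AncestralReconstruction",
  representation(
    tree = "phylo",
    posteriors = "array",
    mapStates = "matrix",
    tipStates = "matrix",
    siteLogLik = "numeric",
    mode = "character"
  )
)

setValidity("AncestralReconstruction", function(object) {
  msg <- character()
  s <- apply(object@posteriors, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-9))
    msg <- c(msg, "posterior vectors must sum to 1 (within 1e-9)")
  if (!identical(dim(object@posteriors)[1:2], dim(object@mapStates)))
    msg <- c(msg, "mapStates dimensions must match posteriors")
  if (length(msg)) msg else TRUE
})

#' Per-site substitution classification for a branch pair
#'
#' @slot branchA,branchB branch identifiers (derived-side clade labels).
#' @slot perSiteClass character vector over sites with values in
#'   \code{c("convergent", "parallel", "divergent", "single", "none",
#'   "excluded")}.
#' @slot counts named integer vector of class totals.
#' @export
setClass("BranchPairProfile",
  representation(
    branchA = "character",
    branchB = "character",
    perSiteClass = "character",
    counts = "integer"
  )
)

setValidity("BranchPairProfile", function(object) {
  ok <- c("convergent", "parallel", "divergent", "single", "none", "excluded")
  if (!all(object@perSiteClass %in% ok))
    return("perSiteClass contains an unknown class label")
  tab <- table(factor(object@perSiteClass, levels = ok))
  if (!all(object@counts[ok] == as.integer(tab)))
    return("counts do not match the per-site classification")
  TRUE
})

#' Model-based convergence/parallelism test for a branch pair
#'
#' Expected numbers of convergent and parallel substitutions under the
#' substitution model (summed per-site event probabilities) and tail
#' probabilities for the observed counts.
#'
#' @slot profile observed \linkS4class{BranchPairProfile}.
#' @slot perSiteProbConv,perSiteProbPar per-site event probabilities.
#' @slot expectedConv,expectedPar sums of the per-site probabilities.
#' @slot pConv,pPar,pJoint upper-tail probabilities of the observed counts.
#' @slot method \code{"poisson_binomial"} (exact) or \code{"poisson"}.
#' @export
setClass("ConvergenceTest",
  representation(
    profile = "BranchPairProfile",
    perSiteProbConv = "numeric",
    perSiteProbPar = "numeric",
    expectedConv = "numeric",
    expectedPar = "numeric",
    pConv = "numeric",
    pPar = "numeric",
    pJoint = "numeric",
    method = "character"
  )
)

setValidity("ConvergenceTest", function(object) {
  msg <- character()
  pr <- c(object@perSiteProbConv, object@perSiteProbPar,
          object@pConv, object@pPar, object@pJoint)
  if (any(pr < -1e-12 | pr > 1 + 1e-12))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (abs(object@expectedConv - sum(object@perSiteProbConv)) > 1e-10 ||
      abs(object@expectedPar - sum(object@perSiteProbPar)) > 1e-10)
    msg <- c(msg, "expected counts must equal summed per-site probabilities")
  if (length(msg)) msg else TRUE
})

#' Genome-wide divergence regression null
#'
#' Ordinary least squares of observed convergent-plus-parallel counts on
#' observed divergent counts across branch pairs; the fitted line is the
#' empirical null against which individual pairs are tested for excess.
#'
#' @slot points data frame with one row per branch pair: \code{pair},
#'   \code{nDiv}, \code{nConvPar}, fitted value, studentized residual and
#'   one-sided excess p-value, and a logical \code{flagged}.
#' @slot slope,intercept,rSquared least-squares fit summaries.
#' @export
setClass("RegressionNull",
  representation(
    points = "data.frame",
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric"
  )
)

setValidity("RegressionNull", function(object) {
  if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' Per-branch dN/dS estimates (free-ratio model)
#'
#' @slot rates data frame with one row per branch: \code{branch}, \code{t}
#'   (expected substitutions per codon), \code{dN}, \code{dS}, \code{omega}.
#' @slot logLik maximised log-likelihood (\code{NA} for counting method).
#' @slot kappa transition/transversion ratio used.
#' @slot method \code{"ML"} or \code{"counting"}.
#' @export
setClass("BranchRates",
  representation(
    rates = "data.frame",
    logLik = "numeric",
    kappa = "numeric",
    method = "character"
  )
)

#' Branch-site positive-selection fit
#'
#' Maximum-likelihood fit of the branch-site mixture model (site classes 0,
#' 1, 2a, 2b; foreground omega2 free in the alternative, fixed to 1 in the
#' null), the likelihood-ratio test against chi-square df = 1, and per-site
#' empirical-Bayes posteriors of the positively-selected classes on the
#' foreground branch.
#'
#' @slot lnLAlt,lnLNull maximised log-likelihoods.
#' @slot paramsAlt,paramsNull named numeric parameter vectors
#'   (\code{p0, p1, p2a, p2b, omega0, omega2, kappa, treeScale}).
#' @slot lrt likelihood-ratio statistic \code{2 * (lnLAlt - lnLNull)}.
#' @slot pValue chi-square (df 1) upper-tail p-value.
#' @slot fdrQ FDR-adjusted p-value (NA until a screen-level adjustment).
#' @slot sitePosteriors per-site posterior probability of classes 2a or 2b
#'   under the alternative fit.
#' @slot foreground foreground branch identifier.
#' @export
setClass("BranchSiteFit",
  representation(
    lnLAlt = "numeric",
    lnLNull = "numeric",
    paramsAlt = "numeric",
    paramsNull = "numeric",
    lrt = "numeric",
    pValue = "numeric",
    fdrQ = "numeric",
    sitePosteriors = "numeric",
    foreground = "character"
  )
)

setValidity("BranchSiteFit", function(object) {
  msg <- character()
  if (object@lrt < -1e-6)
    msg <- c(msg, "LRT statistic must be nonnegative (models are nested)")
  if (any(object@sitePosteriors < -1e-9 | object@sitePosteriors > 1 + 1e-9))
    msg <- c(msg, "site posteriors must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Whole-screen report
#'
#' Per-gene and cross-gene results of the full screen: branch-site tests
#' with FDR, convergence tests on configured branch pairs, per-branch
#' dN/dS, lineage-specific substitutions, the genome-wide regression null,
#' the cross-gene dS rank-sum comparison, and run metadata.
#'
#' @slot status data frame: gene, status (\code{ok} or
#'   \code{skipped:<reason>} / \code{failed:<reason>}).
#' @slot psg data frame of branch-site results (one row per analysed gene).
#' @slot convergence data frame of per-gene, per-pair convergence tests.
#' @slot rates data frame of per-gene, per-branch dN/dS.
#' @slot specific data frame of lineage-specific substitutions.
#' @slot regression \linkS4class{RegressionNull} or \code{NULL} (as a
#'   zero-length list when absent).
#' @slot wilcoxon named list: \code{W}, \code{p}, branch identifiers, genes
#'   used and genes flagged for zero synonymous divergence.
#' @slot metadata named list: seeds, config hash, package version.
#' @export
setClass("GeneScreenReport",
  representation(
    status = "data.frame",
    psg = "data.frame",
    convergence = "data.frame",
    rates = "data.frame",
    specific = "data.frame",
    regression = "list",
    wilcoxon = "list",
    metadata = "list"
  )
)
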