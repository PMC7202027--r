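## Classification and model-based testing of convergent/parallel
## substitutions on branch pairs.
##
## On a branch pair, with inferred (ancestor -> descendant) states
## (a1 -> d1) and (a2 -> d2): the site is "parallel" when both branches
## substituted to the same residue from the same ancestral residue,
## "convergent" when both substituted to the same residue from different
## ancestral residues, "divergent" when both substituted but to different
## residues, "single" when exactly one branch substituted.

SITE_CLASSES <- c("convergent", "parallel", "divergent", "single", "none",
                  "excluded")

#' Classify substitution quadruples
#'
#' Vectorised classification of (ancestor, descendant) state pairs on two
#' branches into convergent / parallel / divergent / single / none.
#'
#' @param anc1,der1 ancestral and derived states on the first branch.
#' @param anc2,der2 ancestral and derived states on the second branch.
#' @return character vector of class labels.
#' @examples
#' classifySubstitutionPair("T", "S", "T", "S")  # parallel
#' classifySubstitutionPair("A", "S", "V", "S")  # convergent
#' @export
classifySubstitutionPair <- function(anc1, der1, anc2, der2) {
  sub1 <- anc1 != der1
  sub2 <- anc2 != der2
  out <- rep("none", length(anc1))
  out[xor(sub1, sub2)] <- "single"
  both <- sub1 & sub2
  out[both & der1 != der2] <- "divergent"
  out[both & der1 == der2 & anc1 == anc2] <- "parallel"
  out[both & der1 == der2 & anc1 != anc2] <- "convergent"
  out
}

## Ancestor/descendant MAP states along one branch, plus the exclusion mask
## (tip branches with gap or ambiguity at the derived side).
.branchStates <- function(recon, edgeIdx) {
  tree <- recon@tree
  ntip <- length(tree$tip.label)
  ids <- nodeIds(tree)
  par <- tree$edge[edgeIdx, 1]
  ch <- tree$edge[edgeIdx, 2]
  anc <- recon@mapStates[ids[par], ]
  if (ch <= ntip) {
    der <- recon@tipStates[tree$tip.label[ch], ]
    excl <- !(der %in% AA_ALPHABET)
  } else {
    der <- recon@mapStates[ids[ch], ]
    excl <- rep(FALSE, length(der))
  }
  list(anc = anc, der = der, excluded = excl, parent = par, child = ch,
       t = tree$edge.length[edgeIdx])
}

.checkPair <- function(tree, branchA, branchB) {
  eA <- resolveBranch(tree, branchA)
  eB <- resolveBranch(tree, branchB)
  if (eA == eB) stop("the two branches of a pair must differ")
  if (edgesNested(tree, eA, eB))
    stop("branches '", branchA, "' and '", branchB,
         "' are nested (ancestor and descendant); pair not testable")
  list(eA = eA, eB = eB)
}

#' Observed substitution classification for a branch pair
#'
#' Uses the MAP ancestral states of a reconstruction (and observed residues
#' at tips) to classify every alignment column. Sites where a derived-side
#' tip of either branch carries a gap or ambiguity code are flagged
#' \code{"excluded"}: the ancestral state above a gapped tip is
#' unidentifiable.
#'
#' @param recon an \linkS4class{AncestralReconstruction}.
#' @param branchA,branchB branch identifiers (see \code{\link{branchIds}});
#'   the pair must not be nested.
#' @return a \linkS4class{BranchPairProfile}.
#' @export
classifyBranchPair <- function(recon, branchA, branchB) {
  pr <- .checkPair(recon@tree, branchA, branchB)
  A <- .branchStates(recon, pr$eA)
  B <- .branchStates(recon, pr$eB)
  cls <- classifySubstitutionPair(A$anc, A$der, B$anc, B$der)
  cls[A$excluded | B$excluded] <- "excluded"
  counts <- table(factor(cls, levels = SITE_CLASSES))
  ids <- branchIds(recon@tree)
  methods::new("BranchPairProfile", branchA = ids[pr$eA],
               branchB = ids[pr$eB], perSiteClass = cls,
               counts = stats::setNames(as.integer(counts), SITE_CLASSES))
}

## Event-probability kernels for one pair of transition matrices.
## Kpar[a]       = sum_{d != a} PA[a,d] PB[a,d]
## Kconv[a1,a2]  = sum_{d != a1, d != a2} PA[a1,d] PB[a2,d], zero diagonal
.pairKernels <- function(PA, PB) {
  n <- nrow(PA)
  Kpar <- rowSums(PA * PB) - diag(PA) * diag(PB)
  Kconv <- PA %*% t(PB)
  Kconv <- Kconv - diag(PA) * t(PB)          # d = a1 term: PA[a1,a1] PB[a2,a1]
  Kconv <- Kconv - t(t(PA) * diag(PB))       # d = a2 term: PA[a1,a2] PB[a2,a2]
  diag(Kconv) <- 0
  list(par = Kpar, conv = Kconv)
}

#' Expected convergent/parallel substitution counts for a branch pair
#'
#' Per-site probability that a convergent (resp. parallel) event arises by
#' chance under the substitution model: a sum over ancestral-state pairs,
#' weighted by their posterior, of the probability that both branches
#' substitute to a shared destination satisfying the class definition.
#' Expected counts are the sums of per-site probabilities. In site-specific
#' frequency mode each site's own rate matrix is used.
#'
#' @param model the \linkS4class{AminoAcidModel} defining the null.
#' @param recon an \linkS4class{AncestralReconstruction} on the same
#'   alignment and tree.
#' @param branchA,branchB branch identifiers (non-nested pair).
#' @param useMAP use point-mass MAP ancestral states instead of integrating
#'   over the parent-state posteriors.
#' @return list with \code{perSiteProbConv}, \code{perSiteProbPar},
#'   \code{expectedConv}, \code{expectedPar}.
#' @export
expectedSubstitutionCounts <- function(model, recon, branchA, branchB,
                                       useMAP = FALSE) {
  tree <- recon@tree
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("branch lengths are required for expected counts")
  pr <- .checkPair(tree, branchA, branchB)
  A <- .branchStates(recon, pr$eA)
  B <- .branchStates(recon, pr$eB)
  ids <- nodeIds(tree)
  L <- dim(recon@posteriors)[2]
  sharedParent <- A$parent == B$parent

  weightMat <- function(side) {
    if (useMAP) {
      W <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
      W[cbind(seq_len(L), match(side$anc, AA_ALPHABET))] <- 1
      W
    } else {
      matrix(recon@posteriors[ids[side$parent], , ], nrow = L, ncol = 20,
             dimnames = list(NULL, AA_ALPHABET))
    }
  }
  W1 <- weightMat(A)
  W2 <- weightMat(B)
  excluded <- A$excluded | B$excluded

  siteSpecific <- nrow(model@frequencies) > 1L
  if (siteSpecific && length(model@siteMap) != L)
    stop("site-specific model was built for a different alignment length")

  pconv <- numeric(L)
  ppar <- numeric(L)
  if (!siteSpecific) {
    dec <- model@decompositions[[1]]
    K <- .pairKernels(decompTransition(dec, A$t), decompTransition(dec, B$t))
    if (sharedParent) {
      ppar <- as.numeric(W1 %*% K$par)
    } else {
      ppar <- rowSums(W1 * W2 * rep(K$par, each = L))
      pconv <- rowSums((W1 %*% K$conv) * W2)
    }
  } else {
    PAa <- .sitePArray(model, A$t)
    PBa <- .sitePArray(model, B$t)
    probs <- .sitewisePairProbs(PAa, PBa, W1, W2, sharedParent)
    ppar <- probs$par
    pconv <- probs$conv
  }
  pconv[excluded] <- 0
  ppar[excluded] <- 0
  list(perSiteProbConv = pconv, perSiteProbPar = ppar,
       expectedConv = sum(pconv), expectedPar = sum(ppar))
}

## Per-site transition matrices of a site-specific model along one branch,
## stacked as an L x 20 x 20 array.
.sitePArray <- function(model, t) {
  L <- length(model@siteMap)
  out <- array(NA_real_, c(L, 20, 20))
  for (s in seq_len(L)) {
    out[s, , ] <- decompTransition(
      model@decompositions[[model@siteMap[s]]], t)
  }
  out
}

## Vectorised per-site convergent/parallel event probabilities for one
## branch pair under per-site transition arrays (L x 20 x 20) and parent
## weight matrices (L x 20). Same quantities as .pairKernels, summed over
## ancestral states site by site.
.sitewisePairProbs <- function(PAa, PBa, W1, W2, sharedParent) {
  L <- dim(PAa)[1]
  ## Kfull[s, a] = sum_d PA[s,a,d] PB[s,a,d]; diagonal products
  Kfull <- rowSums(PAa * PBa, dims = 2)
  dgA <- sapply(1:20, function(a) PAa[, a, a])
  dgB <- sapply(1:20, function(a) PBa[, a, a])
  if (L == 1) { dgA <- matrix(dgA, 1); dgB <- matrix(dgB, 1) }
  if (sharedParent) {
    par <- rowSums(W1 * (Kfull - dgA * dgB))
    return(list(par = pmax(par, 0), conv = numeric(L)))
  }
  par <- rowSums(W1 * W2 * (Kfull - dgA * dgB))
  ## u[s, d] = sum_a W1[s,a] PA[s,a,d]; v likewise for branch B
  u <- matrix(0, L, 20)
  v <- matrix(0, L, 20)
  for (a in 1:20) {
    u <- u + W1[, a] * PAa[, a, ]
    v <- v + W2[, a] * PBa[, a, ]
  }
  full <- rowSums(u * v)
  corr1 <- rowSums((W1 * dgA) * v)      # d = a1 term
  corr2 <- rowSums((W2 * dgB) * u)      # d = a2 term
  diagTerm <- rowSums(W1 * W2 * (Kfull - 2 * dgA * dgB))
  conv <- full - corr1 - corr2 - diagTerm
  list(par = pmax(par, 0), conv = pmax(conv, 0))
}

## Batched expected counts for many branch pairs sharing one site-specific
## model and reconstruction: per-branch P arrays are built once.
.expectedAllPairs <- function(model, recon, pairIdx) {
  tree <- recon@tree
  L <- dim(recon@posteriors)[2]
  ids <- nodeIds(tree)
  edges <- sort(unique(c(pairIdx$eA, pairIdx$eB)))
  Parr <- lapply(stats::setNames(edges, edges), function(e)
    .sitePArray(model, tree$edge.length[e]))
  st <- lapply(stats::setNames(edges, edges), function(e)
    .branchStates(recon, e))
  wts <- lapply(st, function(side)
    matrix(recon@posteriors[ids[side$parent], , ], nrow = L, ncol = 20))
  out <- data.frame(expConv = numeric(nrow(pairIdx)),
                    expPar = numeric(nrow(pairIdx)))
  for (i in seq_len(nrow(pairIdx))) {
    eA <- as.character(pairIdx$eA[i])
    eB <- as.character(pairIdx$eB[i])
    shared <- st[[eA]]$parent == st[[eB]]$parent
    probs <- .sitewisePairProbs(Parr[[eA]], Parr[[eB]],
                                wts[[eA]], wts[[eB]], shared)
    excl <- st[[eA]]$excluded | st[[eB]]$excluded
    probs$conv[excl] <- 0
    probs$par[excl] <- 0
    out$expConv[i] <- sum(probs$conv)
    out$expPar[i] <- sum(probs$par)
  }
  out
}

#' Tail probability of an observed event count
#'
#' Probability of observing at least \code{observed} events when sites are
#' independent Bernoulli trials with the given per-site probabilities:
#' either the exact Poisson-binomial tail (dynamic-programming
#' convolution) or its Poisson approximation with mean \code{sum(probs)}.
#'
#' @param probs per-site event probabilities in [0, 1].
#' @param observed nonnegative observed count.
#' @param method \code{"poisson_binomial"} (exact) or \code{"poisson"}.
#' @return the upper-tail probability \code{P(X >= observed)}; 1 when
#'   \code{observed} is 0.
#' @examples
#' tailProbability(rep(0.05, 10), 3, method = "poisson")
#' tailProbability(c(0.1, 0.2), 2)  # exactly 0.02
#' @export
tailProbability <- function(probs,
                            observed,
                            method = c("poisson_binomial", "poisson")) {
  method <- match.arg(method)
  if (observed < 0) stop("observed count must be nonnegative")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (observed == 0) return(1)
  if (method == "poisson")
    return(stats::ppois(observed - 1, lambda = sum(probs),
                        lower.tail = FALSE))
  if (observed > length(probs)) return(0)
  ## P(X < observed) by convolution over the first `observed` mass points
  f <- c(1, numeric(observed - 1))
  for (p in probs) {
    shifted <- c(0, f[-observed]) * p
    f <- f * (1 - p) + shifted
  }
  max(0, min(1, 1 - sum(f)))
}

#' Model-based convergence/parallelism test for a branch pair
#'
#' Combines the observed classification with the model-based expected
#' counts and computes upper-tail probabilities for the observed convergent
#' count, parallel count, and their sum.
#'
#' @inheritParams expectedSubstitutionCounts
#' @param method tail-probability method.
#' @return a \linkS4class{ConvergenceTest}.
#' @export
convergenceTest <- function(recon, model, branchA, branchB,
                            method = c("poisson_binomial", "poisson"),
                            useMAP = FALSE) {
  method <- match.arg(method)
  profile <- classifyBranchPair(recon, branchA, branchB)
  ec <- expectedSubstitutionCounts(model, recon, branchA, branchB,
                                   useMAP = useMAP)
  counts <- profile@counts
  methods::new("ConvergenceTest",
    profile = profile,
    perSiteProbConv = ec$perSiteProbConv,
    perSiteProbPar = ec$perSiteProbPar,
    expectedConv = ec$expectedConv,
    expectedPar = ec$expectedPar,
    pConv = tailProbability(ec$perSiteProbConv, counts[["convergent"]],
                            method),
    pPar = tailProbability(ec$perSiteProbPar, counts[["parallel"]], method),
    pJoint = tailProbability(ec$perSiteProbConv + ec$perSiteProbPar,
                             counts[["convergent"]] + counts[["parallel"]],
                             method),
    method = method)
}

#' Genome-wide divergence regression null
#'
#' Ordinary least squares of observed convergent-plus-parallel site counts
#' on observed divergent site counts across branch pairs. The fitted line
#' is the empirical null; pairs are tested for excess convergence by their
#' studentized residual (one-sided t-tail).
#'
#' @param profiles list of \linkS4class{BranchPairProfile} objects (at
#'   least 3, from non-nested branch pairs).
#' @param alpha per-pair significance threshold for flagging excess.
#' @return a \linkS4class{RegressionNull}.
#' @export
genomeRegressionNull <- function(profiles, alpha = 0.05) {
  if (length(profiles) < 3L)
    stop("at least 3 branch pairs are required for the regression null")
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(pair = paste(p@branchA, p@branchB, sep = " vs "),
               nDiv = p@counts[["divergent"]],
               nConvPar = p@counts[["convergent"]] + p@counts[["parallel"]],
               nBothSubst = p@counts[["divergent"]] +
                 p@counts[["convergent"]] + p@counts[["parallel"]],
               stringsAsFactors = FALSE)
  }))
  if (length(unique(df$nDiv)) == 1L)
    stop("degenerate input: all pairs have identical divergence counts")
  fit <- stats::lm(nConvPar ~ nDiv, data = df)
  ## externally studentized residuals by explicit leave-one-out refits:
  ## robust when the held-out fit is exact (zero residual variance), where
  ## stats::rstudent degenerates to NaN
  n <- nrow(df)
  res <- numeric(n)
  for (i in seq_len(n)) {
    ri <- tryCatch(suppressWarnings({
      f2 <- stats::lm(nConvPar ~ nDiv, data = df[-i, ])
      pr <- stats::predict(f2, newdata = df[i, , drop = FALSE],
                           se.fit = TRUE)
      se <- sqrt(max(summary(f2)$sigma^2 + pr$se.fit^2, 0))
      r <- df$nConvPar[i] - unname(pr$fit)
      if (!is.finite(se) || se == 0) sign(r) * 1e6 else r / se
    }), error = function(e) 0)
    res[i] <- if (is.finite(ri)) ri else 0
  }
  pval <- stats::pt(res, df = max(1, n - 3L), lower.tail = FALSE)
  df$fitted <- stats::fitted(fit)
  df$residual <- res
  df$pExcess <- pval
  ## control the expected number of false flags across the many tested
  ## pairs: flag on BH-adjusted one-sided excess p-values
  df$pExcessAdj <- stats::p.adjust(pval, method = "BH")
  df$flagged <- df$pExcessAdj < alpha
  rownames(df) <- NULL
  r2 <- suppressWarnings(summary(fit)$r.squared)
  methods::new("RegressionNull", points = df,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               rSquared = r2)
}
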