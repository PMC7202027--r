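## Codon-level selection inference: fourfold-degenerate site extraction,
## free-ratio per-branch dN/dS (ML or ancestral-counting), and the
## branch-site positive-selection likelihood-ratio test.

#' Extract fourfold-degenerate sites
#'
#' Returns the third codon positions of columns where every taxon carries a
#' codon from a fourfold-degenerate family (third position free to vary
#' synonymously) and all taxa share the same first two nucleotides, so that
#' any mutation at the extracted position is synonymous in every lineage.
#' Codons containing gaps or ambiguity codes disqualify their column.
#'
#' @param codonAlignment in-frame nucleotide alignment (width divisible
#'   by 3; internal stop codons are an error reported with taxon and
#'   position).
#' @return nucleotide alignment matrix of the extracted third positions
#'   (zero columns when no site qualifies), with attribute
#'   \code{"codonIndex"} giving the 1-based source codon of each column.
#' @export
extract4DSites <- function(codonAlignment) {
  cs <- checkCodonAlignment(asAlignmentMatrix(codonAlignment))
  keep <- integer()
  for (j in seq_len(ncol(cs))) {
    col <- cs[, j]
    if (!all(col %in% SENSE_CODONS)) next
    pre <- substr(col, 1, 2)
    if (length(unique(pre)) != 1L) next
    if (!pre[1] %in% FOURFOLD_PREFIXES) next
    keep <- c(keep, j)
  }
  out <- matrix(substr(cs[, keep, drop = FALSE], 3, 3), nrow = nrow(cs),
                dimnames = list(rownames(cs), NULL))
  attr(out, "codonIndex") <- keep
  out
}

## Encoded codon data shared by the likelihood fits.
.codonData <- function(codonAlignment, tree) {
  cs <- checkCodonAlignment(asAlignmentMatrix(codonAlignment))
  cs <- .alignTipsToTree(tree, cs)
  enc <- encodeAlignment(cs, SENSE_CODONS)
  cp <- compressPatterns(enc)
  list(codons = cs, states = cp$states, weights = cp$weights, map = cp$map,
       L = ncol(cs))
}

## Per-edge transition matrices for a shared-or-per-edge omega assignment.
## omegaEdges: numeric vector along eng$edges rows. Decompositions are
## cached per distinct omega.
.codonPlist <- function(eng, freq, kappa, omegaEdges, tvec,
                        refOmega = NULL) {
  uo <- unique(omegaEdges)
  decs <- lapply(uo, function(w) codonDecompose(freq, kappa, w, refOmega))
  names(decs) <- sprintf("%.15g", uo)
  lapply(seq_along(tvec), function(k) {
    decompTransition(decs[[sprintf("%.15g", omegaEdges[k])]], tvec[k])
  })
}

.codonLogLik <- function(eng, dat, freq, kappa, omegaEdges, tvec,
                         refOmega = NULL) {
  Pl <- .codonPlist(eng, freq, kappa, omegaEdges, tvec, refOmega)
  engineLogLik(eng, Pl, dat$states, freq, dat$weights)
}

## One-ratio (M0) fit with branch lengths scaled proportionally from the
## input tree: parameters are (tree scale, kappa, omega).
.fitM0 <- function(eng, dat, freq, init = c(scale = 1, kappa = 2,
                                            omega = 0.3),
                   refOmega = NULL) {
  t0 <- eng$branchLengths
  obj <- function(x) {
    sc <- exp(x[1]); ka <- exp(x[2]); om <- exp(x[3])
    -.codonLogLik(eng, dat, freq, ka, rep(om, length(t0)), sc * t0,
                  refOmega)
  }
  fit <- stats::nlminb(log(init), obj,
                       lower = log(c(1e-4, 0.05, 1e-6)),
                       upper = log(c(1e3, 100, 50)),
                       control = list(rel.tol = 1e-7, iter.max = 200))
  list(scale = exp(fit$par[1]), kappa = exp(fit$par[2]),
       omega = exp(fit$par[3]), logLik = -fit$objective,
       tvec = exp(fit$par[1]) * t0)
}

## dN/dS bookkeeping from the substitution-flux decomposition of a branch's
## rate matrix: expected substitutions per codon split into nonsynonymous
## and synonymous, each normalised by the corresponding mutational
## opportunity ("sites") computed at omega = 1.
.branchDnDs <- function(freq, kappa, omega, t) {
  d <- codonDecompose(freq, kappa, omega)
  p1 <- codonSiteProportions(freq, kappa)
  dN <- t * d$rhoN / (3 * p1[["pN"]])
  dS <- t * d$rhoS / (3 * p1[["pS"]])
  c(dN = unname(dN), dS = unname(dS),
    omega = if (dS > 0) unname(dN / dS) else unname(omega))
}

#' Free-ratio dN/dS fit
#'
#' Per-branch dN/dS under the Goldman-Yang model. With
#' \code{method = "ML"}, a maximum-likelihood fit with a shared kappa and
#' one free (t, omega) per branch; with \code{method = "counting"}, a fast
#' approximation that fits the one-ratio model, reconstructs marginal MAP
#' ancestral codons, and counts synonymous/nonsynonymous changes per branch
#' Nei-Gojobori style (pathway averaging, stop-free paths).
#'
#' @param codonAlignment in-frame nucleotide alignment.
#' @param tree rooted \code{phylo} with branch lengths (used as ML starting
#'   values / proportional constraint).
#' @param method \code{"ML"} or \code{"counting"}.
#' @param codonFreq codon frequency model for
#'   \code{\link{codonModel}}.
#' @param control list: \code{maxOmega} (default 999), \code{dsFloor}
#'   (default 1e-8) guarding reported omega ratios.
#' @return a \linkS4class{BranchRates}.
#' @export
freeRatioFit <- function(codonAlignment, tree,
                         method = c("ML", "counting"),
                         codonFreq = "F3x4",
                         control = list()) {
  method <- match.arg(method)
  maxOmega <- control$maxOmega %||% 999
  dsFloor <- control$dsFloor %||% 1e-8
  tree <- prepareTree(tree, requireLengths = TRUE)
  if (length(tree$tip.label) < 2L)
    stop("free-ratio fit needs at least 2 taxa")
  model <- codonModel(codonAlignment, codonFreq = codonFreq)
  freq <- model@codonFrequencies
  eng <- buildEngine(tree)
  dat <- .codonData(codonAlignment, eng$tree)
  ids <- branchIds(eng$tree)
  nb <- nrow(eng$edges)

  if (method == "counting")
    return(.freeRatioCounting(eng, dat, freq, ids, maxOmega, dsFloor,
                              m0 = control$m0))

  ## no variation at all: every branch has zero divergence, no fit needed
  if (all(apply(dat$states, 2, function(x) {
    length(unique(x[x > 0L])) <= 1L
  }))) {
    rates <- data.frame(branch = ids, t = 0, dN = 0, dS = 0, omega = 0,
                        stringsAsFactors = FALSE)
    return(methods::new("BranchRates", rates = rates, logLik = NA_real_,
                        kappa = NA_real_, method = "ML"))
  }

  t0 <- pmax(eng$branchLengths, 1e-4)
  init <- c(log(2), log(t0), rep(log(0.3), nb))
  obj <- function(x) {
    ka <- exp(x[1])
    tv <- exp(x[2:(nb + 1)])
    om <- exp(x[(nb + 2):(2 * nb + 1)])
    -.codonLogLik(eng, dat, freq, ka, om, tv)
  }
  fit <- stats::nlminb(init, obj,
                       lower = c(log(0.05), rep(log(1e-7), nb),
                                 rep(log(1e-6), nb)),
                       upper = c(log(100), rep(log(20), nb),
                                 rep(log(maxOmega), nb)),
                       control = list(rel.tol = 1e-8, eval.max = 5000,
                                      iter.max = 1000))
  ka <- exp(fit$par[1])
  tv <- exp(fit$par[2:(nb + 1)])
  om <- exp(fit$par[(nb + 2):(2 * nb + 1)])
  rows <- t(vapply(seq_len(nb), function(k) {
    .branchDnDs(freq, ka, om[k], tv[k])
  }, numeric(3)))
  rates <- data.frame(branch = ids, t = tv, dN = rows[, "dN"],
                      dS = rows[, "dS"],
                      omega = rows[, "dN"] / pmax(rows[, "dS"], dsFloor),
                      stringsAsFactors = FALSE)
  ## identical sequences: no divergence on any branch
  zero <- tv <= 1.1e-7
  rates$dN[zero] <- 0; rates$dS[zero] <- 0; rates$omega[zero] <- 0
  methods::new("BranchRates", rates = rates, logLik = -fit$objective,
               kappa = ka, method = "ML")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Nei-Gojobori opportunity counts for one codon: expected numbers of
## synonymous and nonsynonymous "sites" among its 9 single-nucleotide
## neighbours (paths to stop codons excluded from the numerator but kept in
## the per-position denominator of 3).
.ngSiteCounts <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    syn <- numeric(61); non <- numeric(61)
    for (i in seq_len(61)) {
      cod <- SENSE_CODONS[i]
      for (pos in 1:3) {
        for (nt in setdiff(NUCLEOTIDES, substr(cod, pos, pos))) {
          mut <- cod
          substr(mut, pos, pos) <- nt
          if (!mut %in% SENSE_CODONS) next
          if (CODON_AA[[mut]] == CODON_AA[[cod]])
            syn[i] <- syn[i] + 1 / 3
          else non[i] <- non[i] + 1 / 3
        }
      }
    }
    cache <<- cbind(S = syn, N = non)
    cache
  }
})

## Pathway-averaged synonymous/nonsynonymous change counts between two
## sense codons (orderings passing through stop codons are dropped).
## Memoised: at most 61 x 61 distinct pairs.
.ngChangeCache <- new.env(parent = emptyenv())

.ngChangeCounts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ngChangeCache[[key]]
  if (!is.null(hit)) return(hit)
  val <- .ngChangeCountsRaw(c1, c2)
  assign(key, val, envir = .ngChangeCache)
  val
}

.ngChangeCountsRaw <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  paths <- switch(length(pos),
    list(pos),
    list(pos, rev(pos)),
    {
      idx <- expand.grid(1:3, 1:3, 1:3)
      idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3L), ]
      lapply(seq_len(nrow(idx)), function(i) pos[as.integer(idx[i, ])])
    })
  tot <- c(Sd = 0, Nd = 0); nok <- 0
  for (ord in paths) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!nxt %in% SENSE_CODONS) { ok <- FALSE; break }
      if (CODON_AA[[nxt]] == CODON_AA[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + c(Sd = sd, Nd = nd); nok <- nok + 1 }
  }
  if (nok == 0) return(c(Sd = 0, Nd = length(pos)))
  tot / nok
}

## Counting-based free-ratio: M0 fit, marginal MAP codon ancestors, then
## per-branch Nei-Gojobori counting of changes and sites.
.freeRatioCounting <- function(eng, dat, freq, ids, maxOmega, dsFloor,
                               m0 = NULL) {
  if (is.null(m0)) m0 <- .fitM0(eng, dat, freq)
  Pl <- .codonPlist(eng, freq, m0$kappa,
                    rep(m0$omega, length(m0$tvec)), m0$tvec)
  st <- engineDown(eng, Pl, dat$states, freq)
  st <- engineUp(eng, st, Pl)
  nodeState <- matrix(NA_integer_, eng$nnode, st$npat)
  for (v in (eng$ntip + 1L):eng$nnode)
    nodeState[v, ] <- apply(enginePosterior(eng, st, v), 2, which.max)
  for (v in seq_len(eng$ntip)) nodeState[v, ] <- st$tipStates[v, ]
  sites <- .ngSiteCounts()
  nb <- nrow(eng$edges)
  rates <- data.frame(branch = ids, t = NA_real_, dN = NA_real_,
                      dS = NA_real_, omega = NA_real_,
                      stringsAsFactors = FALSE)
  for (k in seq_len(nb)) {
    par <- eng$edges[k, 1]; ch <- eng$edges[k, 2]
    a <- nodeState[par, dat$map]
    d <- nodeState[ch, dat$map]
    ok <- a > 0L & d > 0L
    if (!any(ok)) next
    Ssites <- mean((sites[a[ok], "S"] + sites[d[ok], "S"]) / 2) * sum(ok)
    Nsites <- mean((sites[a[ok], "N"] + sites[d[ok], "N"]) / 2) * sum(ok)
    ## tally changes over differing ancestor/descendant codon pairs
    Sd <- 0; Nd <- 0
    diffs <- which(ok & a != d)
    if (length(diffs)) {
      key <- paste(a[diffs], d[diffs])
      for (u in unique(key)) {
        n <- sum(key == u)
        pairIdx <- as.integer(strsplit(u, " ")[[1]])
        cc <- .ngChangeCounts(SENSE_CODONS[pairIdx[1]],
                              SENSE_CODONS[pairIdx[2]])
        Sd <- Sd + n * cc[["Sd"]]
        Nd <- Nd + n * cc[["Nd"]]
      }
    }
    dN <- if (Nsites > 0) Nd / Nsites else 0
    dS <- if (Ssites > 0) Sd / Ssites else 0
    rates$t[k] <- (Sd + Nd) / sum(ok)
    rates$dN[k] <- dN
    rates$dS[k] <- dS
    rates$omega[k] <- min(maxOmega, dN / max(dS, dsFloor))
  }
  methods::new("BranchRates", rates = rates, logLik = m0$logLik,
               kappa = m0$kappa, method = "counting")
}

## Mixture weights of the branch-site model expressed as a product of two
## proportions: s = p0 + p1 (classes without foreground selection) and
## r = p0 / (p0 + p1); then (w0, w1, w2a, w2b) = (sr, s(1-r), (1-s)r,
## (1-s)(1-r)). This makes the EM weight updates closed-form.
.bsWeights <- function(r, s) {
  c(s * r, s * (1 - r), (1 - s) * r, (1 - s) * (1 - r))
}

## Profile log-likelihood over mixture weights by EM, given the per-pattern
## class log-likelihood matrix (4 x npat). Returns the maximised
## log-likelihood, the weights, and per-pattern responsibilities.
.bsProfileEM <- function(classLogLik, weights, r = 0.5, s = 0.8,
                         tol = 1e-8, maxit = 150) {
  n <- sum(weights)
  m <- apply(classLogLik, 2, max)
  E <- exp(sweep(classLogLik, 2, m, "-"))
  prev <- -Inf
  for (i in seq_len(maxit)) {
    w <- .bsWeights(r, s)
    lik <- colSums(w * E)
    ll <- sum(weights * (log(lik) + m))
    g <- (w * E) / rep(lik, each = 4)
    r <- sum(weights * (g[1, ] + g[3, ])) / n
    s <- sum(weights * (g[1, ] + g[2, ])) / n
    r <- min(max(r, 1e-9), 1 - 1e-9)
    s <- min(max(s, 1e-9), 1 - 1e-9)
    if (ll - prev < tol && i > 3) break
    prev <- ll
  }
  w <- .bsWeights(r, s)
  lik <- colSums(w * E)
  ll <- sum(weights * (log(lik) + m))
  g <- (w * E) / rep(lik, each = 4)
  list(logLik = ll, r = r, s = s, weights = w, resp = g)
}

#' Branch-site positive-selection test
#'
#' Fits the branch-site mixture model on a designated foreground branch:
#' site classes 0 (omega0 everywhere), 1 (neutral everywhere), 2a/2b
#' (omega2 on the foreground, omega0 / 1 on the background), with class
#' proportions tied as in the standard branch-site parameterisation. The
#' alternative model frees omega2 >= 1; the null fixes omega2 = 1. The LRT
#' is referred to chi-square with df = 1 (optionally the 50:50 mixture).
#'
#' Branch lengths and kappa are estimated once under the one-ratio model
#' (tree lengths rescaled proportionally) and then held fixed while the
#' mixture parameters (omega0, omega2 and the class proportions, the
#' latter profiled out by EM) are optimised from a deterministic grid of
#' starting points.
#'
#' @param codonAlignment in-frame nucleotide alignment.
#' @param tree rooted \code{phylo} with branch lengths.
#' @param foreground foreground branch identifier.
#' @param codonFreq codon frequency model.
#' @param mixtureRef use the 50:50 chi-square mixture reference instead of
#'   plain chi-square df 1.
#' @param control list: \code{maxOmega2} (default 999).
#' @return a \linkS4class{BranchSiteFit}.
#' @export
branchSiteFit <- function(codonAlignment, tree, foreground,
                          codonFreq = "F3x4", mixtureRef = FALSE,
                          control = list()) {
  maxOmega2 <- control$maxOmega2 %||% 999
  tree <- prepareTree(tree, requireLengths = TRUE)
  resolveBranch(tree, foreground)      # fail early on unknown foreground
  if (length(tree$tip.label) < 4L)
    stop("branch-site test needs at least 4 taxa")
  model <- codonModel(codonAlignment, codonFreq = codonFreq)
  freq <- model@codonFrequencies
  eng <- buildEngine(tree)
  fgEdge <- resolveBranch(eng$tree, foreground)
  dat <- .codonData(codonAlignment, eng$tree)
  m0 <- control$m0 %||% .fitM0(eng, dat, freq, refOmega = 1)
  tvec <- m0$tvec
  kappa <- m0$kappa

  decCache <- new.env(parent = emptyenv())
  getDec <- function(om) {
    key <- sprintf("%.15g", om)
    if (is.null(decCache[[key]]))
      decCache[[key]] <- codonDecompose(freq, kappa, om, refOmega = 1)
    decCache[[key]]
  }
  tFg0 <- max(tvec[fgEdge], 1e-6)
  regime <- function(om) {
    Pl <- .codonPlist(eng, freq, kappa, rep(om, length(tvec)), tvec,
                      refOmega = 1)
    st <- engineDown(eng, Pl, dat$states, freq)
    engineUp(eng, st, Pl)
  }
  st1 <- regime(1)
  prep1 <- engineEdgePrep(eng, st1, fgEdge)

  ## The partials on either side of the foreground edge do not depend on
  ## the foreground parameters, so the foreground branch length tFg is
  ## re-optimised cheaply alongside omega2 (only edge contractions move).
  lastW0 <- new.env(parent = emptyenv())
  classLogLik <- function(w0, w2, tFg) {
    if (is.null(lastW0$w0) || lastW0$w0 != w0) {
      st0 <- regime(w0)
      lastW0$prep <- engineEdgePrep(eng, st0, fgEdge)
      lastW0$w0 <- w0
    }
    Pfg2 <- decompTransition(getDec(w2), tFg)
    rbind(engineEdgeLogLikPrep(lastW0$prep,
                               decompTransition(getDec(w0), tFg)),
          engineEdgeLogLikPrep(prep1, decompTransition(getDec(1), tFg)),
          engineEdgeLogLikPrep(lastW0$prep, Pfg2),
          engineEdgeLogLikPrep(prep1, Pfg2))
  }

  em <- function(w0, w2, tFg)
    .bsProfileEM(classLogLik(w0, w2, tFg), dat$weights)

  bestTfg <- function(w0, w2, tFg) {
    o <- stats::optimize(function(y) -em(w0, w2, exp(y))$logLik,
                         log(c(max(1e-6, tFg0 / 50), 50 * tFg0 + 1)),
                         tol = 2e-3)
    if (-o$objective > em(w0, w2, tFg)$logLik)
      list(tFg = exp(o$minimum), negLogLik = o$objective)
    else
      list(tFg = tFg, negLogLik = -em(w0, w2, tFg)$logLik)
  }

  ## null: omega2 = 1; alternate optimising omega0 (full passes) and the
  ## foreground branch length (contractions only)
  tFgNull <- tFg0
  w0Null <- 0.2
  for (sweep in 1:2) {
    o <- stats::optimize(function(x) -em(stats::plogis(x), 1,
                                         tFgNull)$logLik,
                         c(-9, 9), tol = 2e-3)
    w0Null <- stats::plogis(o$minimum)
    prevT <- tFgNull
    tf <- bestTfg(w0Null, 1, tFgNull)
    tFgNull <- tf$tFg
    lnLNull <- -tf$negLogLik
    if (abs(log(tFgNull / prevT)) < 0.02) break
  }
  emNull <- em(w0Null, 1, tFgNull)
  lnLNull <- emNull$logLik

  ## alternative: nested optimisation. The full-tree pass depends only on
  ## omega0; for a given omega0, profiling over (omega2, tFg) and the
  ## class proportions (EM) costs only foreground-edge contractions.
  bestW2 <- function(w0, tFg) {
    innerObj <- function(y) -em(w0, 1 + exp(y), tFg)$logLik
    inner <- stats::optimize(innerObj, c(log(1e-4), log(maxOmega2 - 1)),
                             tol = 2e-3)
    atOne <- -em(w0, 1, tFg)$logLik
    if (atOne < inner$objective)
      list(w2 = 1, negLogLik = atOne)
    else
      list(w2 = 1 + exp(inner$minimum), negLogLik = inner$objective)
  }
  tFgAlt <- tFgNull
  w0Alt <- w0Null
  w2Alt <- 1
  for (sweep in 1:2) {
    outer <- stats::optimize(function(x) {
      bestW2(stats::plogis(x), tFgAlt)$negLogLik
    }, c(-9, 9), tol = 2e-3)
    cand <- unique(c(outer$minimum, stats::qlogis(w0Null)))
    best <- NULL
    for (x in cand) {
      w0 <- stats::plogis(x)
      b <- bestW2(w0, tFgAlt)
      if (is.null(best) || b$negLogLik < best$negLogLik) {
        best <- b
        best$w0 <- w0
      }
    }
    w0Alt <- best$w0
    w2Alt <- best$w2
    prevT <- tFgAlt
    tf <- bestTfg(w0Alt, w2Alt, tFgAlt)
    tFgAlt <- tf$tFg
    w2b <- bestW2(w0Alt, tFgAlt)
    w2Alt <- w2b$w2
    if (abs(log(tFgAlt / prevT)) < 0.02) break
  }
  emAlt <- em(w0Alt, w2Alt, tFgAlt)
  lnLAlt <- emAlt$logLik
  if (lnLAlt < lnLNull) {           # numerical safety: null is nested
    lnLAlt <- lnLNull
    w0Alt <- w0Null; w2Alt <- 1; tFgAlt <- tFgNull
    emAlt <- emNull
  }
  lrt <- max(0, 2 * (lnLAlt - lnLNull))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (mixtureRef) p <- if (lrt <= 0) 1 else 0.5 * p
  sitePost <- colSums(emAlt$resp[3:4, , drop = FALSE])[dat$map]
  pars <- function(emRes, w0, w2, tFg) {
    w <- emRes$weights
    c(p0 = w[1], p1 = w[2], p2a = w[3], p2b = w[4], omega0 = w0,
      omega2 = w2, tForeground = tFg, kappa = unname(kappa),
      treeScale = unname(m0$scale))
  }
  methods::new("BranchSiteFit",
               lnLAlt = lnLAlt, lnLNull = lnLNull,
               paramsAlt = pars(emAlt, w0Alt, w2Alt, tFgAlt),
               paramsNull = pars(emNull, w0Null, 1, tFgNull),
               lrt = lrt, pValue = p, fdrQ = NA_real_,
               sitePosteriors = pmin(1, pmax(0, sitePost)),
               foreground = branchIds(eng$tree)[fgEdge])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1).
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return adjusted q-values in the input order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03))
#' @export
fdrAdjust <- function(pValues) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "BH")
}
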