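## Amino-acid (JTT family) and codon (Goldman-Yang) substitution models.
##
## Both model families are general time-reversible: Q[i,j] = s[i,j] * pi[j]
## off the diagonal, with symmetric exchangeabilities s. Every rate matrix is
## normalised so that -sum_i pi_i Q_ii = 1, i.e. branch lengths are measured
## in expected substitutions per site (per codon for codon models).

## Symmetric eigendecomposition of a GTR rate matrix via the pi^(1/2)
## similarity transform; numerically stable for reversible models.
## Returns the normalised Q plus factors for fast P(t) = U exp(Lt) Vt.
gtrDecompose <- function(exch, freq) {
  ## states unobserved in the data would give a singular similarity
  ## transform; give them negligible stationary mass instead
  freq <- pmax(freq, 1e-10)
  freq <- freq / sum(freq)
  Q <- exch * rep(freq, each = nrow(exch))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix: no substitution flux")
  Q <- Q / scale
  sq <- sqrt(freq)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(Q = Q, pi = freq, lambda = e$values,
       U = e$vectors / sq, Vt = t(e$vectors * sq))
}

## P(t) from a decomposition; clamps eigen-roundoff negatives at zero.
decompTransition <- function(dec, t) {
  if (t == 0) {                    # exact: impossible events stay impossible
    P <- diag(length(dec$pi))
    dimnames(P) <- list(names(dec$pi), names(dec$pi))
    return(P)
  }
  P <- dec$U %*% (exp(dec$lambda * t) * dec$Vt)
  P[P < 0] <- 0
  dimnames(P) <- list(names(dec$pi), names(dec$pi))
  P
}

## Frequency-row lookup for possibly site-specific models.
.freqRow <- function(model, site = NULL) {
  if (nrow(model@frequencies) == 1L) return(1L)
  if (is.null(site))
    stop("model is site-specific; a site index is required")
  model@siteMap[site]
}

#' Build an amino-acid substitution model
#'
#' Combines the published JTT exchangeabilities with equilibrium
#' frequencies chosen by \code{mode}: the published JTT stationary
#' frequencies (\code{"JTT"}), pseudocount-smoothed observed gene-wide
#' frequencies (\code{"JTT-Fgene"} / \code{"JTT-F"}), or one
#' pseudocount-smoothed frequency vector per alignment column
#' (\code{"JTT-Fsite"}). Columns with no scoreable residue under
#' \code{"JTT-Fsite"} fall back to the gene-wide vector (with a message).
#'
#' @param alignment amino-acid alignment (any form accepted by
#'   \code{\link{asAlignmentMatrix}}); may be omitted for mode
#'   \code{"JTT"}.
#' @param mode model mode.
#' @param pseudocount per-residue smoothing count added to observed
#'   frequency counts (default 0.1).
#' @return an \linkS4class{AminoAcidModel}.
#' @examples
#' aln <- rbind(t1 = c("A", "W"), t2 = c("A", "W"))
#' m <- aminoAcidModel(aln, mode = "JTT-Fgene")
#' modelFrequencies(m)
#' @export
aminoAcidModel <- function(alignment = NULL,
                           mode = c("JTT", "JTT-F", "JTT-Fgene",
                                    "JTT-Fsite"),
                           pseudocount = 0.1) {
  mode <- match.arg(mode)
  countFreq <- function(x) {
    cnt <- table(factor(x[x %in% AA_ALPHABET], levels = AA_ALPHABET))
    as.numeric(cnt)
  }
  if (mode == "JTT") {
    freqs <- matrix(JTT_FREQUENCIES, nrow = 1,
                    dimnames = list(NULL, AA_ALPHABET))
    siteMap <- 1L
  } else {
    if (is.null(alignment))
      stop("mode ", mode, " requires an alignment")
    aln <- asAlignmentMatrix(alignment)
    if (!any(aln %in% AA_ALPHABET))
      stop("alignment has no scoreable residues")
    geneCnt <- countFreq(aln)
    geneFreq <- (geneCnt + pseudocount) / sum(geneCnt + pseudocount)
    if (mode %in% c("JTT-F", "JTT-Fgene")) {
      freqs <- matrix(geneFreq, nrow = 1,
                      dimnames = list(NULL, AA_ALPHABET))
      siteMap <- 1L
    } else {
      L <- ncol(aln)
      freqs <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
      empty <- logical(L)
      for (s in seq_len(L)) {
        cnt <- countFreq(aln[, s])
        if (sum(cnt) == 0) {
          empty[s] <- TRUE
          freqs[s, ] <- geneFreq
        } else {
          freqs[s, ] <- (cnt + pseudocount) / sum(cnt + pseudocount)
        }
      }
      if (any(empty))
        message(sum(empty), " column(s) with no scoreable residue; ",
                "gene-wide frequencies used for them")
      siteMap <- seq_len(L)
    }
  }
  decs <- lapply(seq_len(nrow(freqs)), function(i) {
    d <- gtrDecompose(JTT_EXCHANGEABILITIES, freqs[i, ])
    d$pi <- stats::setNames(d$pi, AA_ALPHABET)
    d
  })
  methods::new("AminoAcidModel",
               exchangeabilities = JTT_EXCHANGEABILITIES,
               frequencies = freqs, mode = mode,
               pseudocount = pseudocount, decompositions = decs,
               siteMap = as.integer(siteMap))
}

#' Build a Goldman-Yang codon model
#'
#' Codon frequencies are estimated from the alignment under \code{"F3x4"}
#' (position-specific nucleotide frequencies, the default), \code{"F1x4"}
#' (pooled nucleotide frequencies) or \code{"F61"} (observed codon
#' frequencies, pseudocount-smoothed); with no alignment they are uniform
#' over the 61 sense codons.
#'
#' @param codonAlignment optional in-frame nucleotide alignment.
#' @param kappa transition/transversion rate ratio.
#' @param omega dN/dS ratio: a single value, or a named vector with one
#'   value per branch identifier for free-ratio use.
#' @param codonFreq frequency model.
#' @param pseudocount smoothing count for \code{"F61"}.
#' @return a \linkS4class{CodonModel}.
#' @export
codonModel <- function(codonAlignment = NULL, kappa = 2, omega = 0.3,
                       codonFreq = c("F3x4", "F1x4", "F61"),
                       pseudocount = 0.1) {
  codonFreq <- match.arg(codonFreq)
  if (is.null(codonAlignment)) {
    freq <- rep(1 / 61, 61)
  } else {
    aln <- asAlignmentMatrix(codonAlignment)
    if (ncol(aln) %% 3L != 0L)
      stop("codon alignment length is not divisible by 3")
    pos <- (seq_len(ncol(aln)) - 1L) %% 3L + 1L
    ntFreq <- function(x) {
      cnt <- table(factor(x[x %in% NUCLEOTIDES], levels = NUCLEOTIDES))
      p <- as.numeric(cnt)
      if (sum(p) == 0) rep(0.25, 4) else p / sum(p)
    }
    if (codonFreq == "F3x4") {
      pf <- lapply(1:3, function(k) {
        stats::setNames(ntFreq(aln[, pos == k]), NUCLEOTIDES)
      })
      freq <- vapply(SENSE_CODONS, function(cod) {
        b <- strsplit(cod, "")[[1]]
        pf[[1]][b[1]] * pf[[2]][b[2]] * pf[[3]][b[3]]
      }, numeric(1))
    } else if (codonFreq == "F1x4") {
      pf <- stats::setNames(ntFreq(aln), NUCLEOTIDES)
      freq <- vapply(SENSE_CODONS, function(cod) {
        b <- strsplit(cod, "")[[1]]
        pf[b[1]] * pf[b[2]] * pf[b[3]]
      }, numeric(1))
    } else {
      cs <- codonStrings(aln)
      cnt <- table(factor(cs[cs %in% SENSE_CODONS], levels = SENSE_CODONS))
      freq <- as.numeric(cnt) + pseudocount
    }
    freq <- freq / sum(freq)
  }
  methods::new("CodonModel", kappa = kappa, omega = omega,
               codonFrequencies = stats::setNames(as.numeric(freq),
                                                  SENSE_CODONS),
               frequencyModel = codonFreq)
}

## Symmetric exchangeabilities of the GY94 model for given kappa/omega.
codonExchangeabilities <- function(kappa, omega) {
  s <- matrix(0, 61, 61, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  s[CODON_ONE_DIFF] <- 1
  s[CODON_ONE_DIFF & CODON_TRANSITION] <- kappa
  nonsyn <- CODON_ONE_DIFF & !CODON_SYNONYMOUS
  s[nonsyn] <- s[nonsyn] * omega
  s
}

## Raw (unnormalised) substitution flux of the GY94 rate matrix: the
## expected number of substitutions per codon per unit time before any
## rescaling. Used to put several site classes on one time scale.
codonFlux <- function(freq, kappa, omega) {
  freq <- freq / sum(freq)
  Q <- codonExchangeabilities(kappa, omega) * rep(freq, each = 61)
  sum(freq * rowSums(Q))
}

## Decomposition of a codon Q for one omega value. By default Q is
## normalised to one expected substitution per codon per unit t at its own
## omega; with refOmega set, the normalising flux is taken at that omega
## instead, so that site classes sharing a refOmega live on one time scale
## (classes with higher omega then evolve faster, as in branch-site
## mixtures). Also reports the fractions of substitution flux that are
## nonsynonymous (rhoN) and synonymous (rhoS).
codonDecompose <- function(freq, kappa, omega, refOmega = NULL) {
  dec <- gtrDecompose(codonExchangeabilities(kappa, omega), freq)
  if (!is.null(refOmega) && refOmega != omega) {
    rescale <- codonFlux(freq, kappa, omega) /
      codonFlux(freq, kappa, refOmega)
    dec$Q <- dec$Q * rescale
    dec$lambda <- dec$lambda * rescale
  }
  flux <- dec$pi * dec$Q             # element [i, j] is pi_i * Q_ij
  nonsyn <- CODON_ONE_DIFF & !CODON_SYNONYMOUS
  dec$rhoN <- sum(flux[nonsyn])
  dec$rhoS <- sum(flux[CODON_ONE_DIFF & CODON_SYNONYMOUS])
  dec
}

## Mutational-opportunity proportions under omega = 1 (same kappa/freqs):
## the proportions of nonsynonymous and synonymous "sites" per codon.
codonSiteProportions <- function(freq, kappa) {
  d1 <- codonDecompose(freq, kappa, 1)
  c(pN = d1$rhoN, pS = d1$rhoS)
}

#' Rate matrix of a substitution model
#'
#' @param object an \linkS4class{AminoAcidModel} or
#'   \linkS4class{CodonModel}.
#' @param site optional column index (site-specific amino-acid mode).
#' @param omega optional dN/dS value overriding the model's (codon models).
#' @param ... unused.
#' @return the normalised rate matrix Q (rows sum to zero; expected
#'   substitution rate at equilibrium is 1).
#' @export
setGeneric("rateMatrix", function(object, ...) standardGeneric("rateMatrix"))

#' @rdname rateMatrix
#' @export
setMethod("rateMatrix", "AminoAcidModel", function(object, site = NULL, ...) {
  object@decompositions[[.freqRow(object, site)]]$Q
})

#' @rdname rateMatrix
#' @export
setMethod("rateMatrix", "CodonModel", function(object, omega = NULL, ...) {
  if (is.null(omega)) {
    if (length(object@omega) != 1L)
      stop("model has per-branch omega; supply omega explicitly")
    omega <- object@omega
  }
  codonDecompose(object@codonFrequencies, object@kappa, omega)$Q
})

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param object an \linkS4class{AminoAcidModel} or
#'   \linkS4class{CodonModel}.
#' @param t branch length (expected substitutions per site), nonnegative.
#' @param site optional column index (site-specific amino-acid mode).
#' @param omega optional dN/dS value overriding the model's (codon models).
#' @param ... unused.
#' @return a row-stochastic matrix.
#' @examples
#' m <- aminoAcidModel(mode = "JTT")
#' range(rowSums(transitionMatrix(m, 0.1)))
#' @export
setGeneric("transitionMatrix", function(object, t, ...)
  standardGeneric("transitionMatrix"))

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "AminoAcidModel",
  function(object, t, site = NULL, ...) {
    if (t < 0) stop("branch length must be nonnegative")
    decompTransition(object@decompositions[[.freqRow(object, site)]], t)
  })

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "CodonModel",
  function(object, t, omega = NULL, ...) {
    if (t < 0) stop("branch length must be nonnegative")
    if (is.null(omega)) {
      if (length(object@omega) != 1L)
        stop("model has per-branch omega; supply omega explicitly")
      omega <- object@omega
    }
    decompTransition(
      codonDecompose(object@codonFrequencies, object@kappa, omega), t)
  })
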