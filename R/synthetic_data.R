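## Seeded sequence-evolution simulator: ortholog-set fixtures with known
## ground truth for every downstream screen.

## Evaluate expr under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Derive a per-unit seed from one master seed
#'
#' Fixed affine map (modulo 2^31 - 1) giving each gene or replicate its
#' own reproducible RNG stream from a single master seed.
#'
#' @param seed master seed (integer).
#' @param index 1-based unit index.
#' @return an integer seed below 2^31.
#' @export
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + as.numeric(index) * 131071) %% 2147483647)
}

#' Default 11-taxon fixture phylogeny
#'
#' A rooted 11-taxon vertebrate topology: two sister pit-vipers plus a
#' five-pacer viper clade inside squamates, archosaurs and a turtle,
#' a mammal, and a frog outgroup. Branch lengths are synthetic (not
#' estimates), fixed in [0.01, 0.5] expected substitutions per site.
#'
#' @return a rooted \code{phylo} object with branch lengths.
#' @export
defaultViperTree <- function() {
  txt <- paste0(
    "(frog:0.45,(mouse:0.35,((gecko:0.22,(anole:0.2,(python:0.12,",
    "(fivepacer_viper:0.08,(shedao_viper:0.02,mainland_viper:0.03):0.05)",
    ":0.06):0.08):0.1):0.05,(turtle:0.15,(alligator:0.12,chicken:0.18)",
    ":0.06):0.07):0.04):0.1);")
  ape::read.tree(text = txt)
}

## Simulate states (integer-coded) down a tree. PfromEdge(k) returns the
## per-edge transition matrix; rootStates is an integer vector over sites.
.simulateDown <- function(eng, rootStates, PfromEdge) {
  nnode <- eng$nnode
  L <- length(rootStates)
  states <- matrix(NA_integer_, nnode, L)
  states[eng$root, ] <- rootStates
  for (k in rev(seq_len(nrow(eng$edges)))) {
    par <- eng$edges[k, 1]
    ch <- eng$edges[k, 2]
    P <- PfromEdge(k)
    out <- integer(L)
    ps <- states[par, ]
    for (p in unique(ps)) {
      idx <- which(ps == p)
      out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                             prob = P[p, ])
    }
    states[ch, ] <- out
  }
  states
}

#' Simulate a protein-coding gene at the amino-acid level
#'
#' Draws a root sequence from the model's equilibrium frequencies and
#' evolves it independently per site along every branch using the model's
#' transition probabilities. Reproducible given the seed.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param model an \linkS4class{AminoAcidModel} (single frequency vector).
#' @param length number of sites.
#' @param seed integer seed.
#' @return list with \code{alignment} (tip character matrix) and
#'   \code{truth} (seed, root sequence, internal-node states).
#' @export
simulateProteinGene <- function(tree, model, length, seed) {
  stopifnot(length >= 1)
  tree <- prepareTree(tree, requireLengths = TRUE)
  eng <- buildEngine(tree)
  dec <- model@decompositions[[1]]
  Pl <- lapply(eng$branchLengths, function(t) decompTransition(dec, t))
  states <- withSeed(seed, {
    root <- sample.int(20, length, replace = TRUE, prob = dec$pi)
    .simulateDown(eng, root, function(k) Pl[[k]])
  })
  ntip <- eng$ntip
  aln <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip, dimnames = list(tree$tip.label, NULL))
  internal <- (ntip + 1L):eng$nnode
  anc <- matrix(AA_ALPHABET[states[internal, , drop = FALSE]],
                nrow = base::length(internal),
                dimnames = list(nodeIds(tree)[internal], NULL))
  list(alignment = aln,
       truth = list(seed = seed, length = length, mode = model@mode,
                    rootSequence = AA_ALPHABET[states[eng$root, ]],
                    internalStates = anc))
}

#' Simulate a protein-coding gene at the codon level
#'
#' Goldman-Yang simulation on the tree. \code{model@omega} may be a single
#' value or a named per-branch vector (free-ratio truth). Alternatively a
#' branch-site regime can be simulated by giving \code{foreground} and
#' \code{siteClasses}: sites are assigned to classes 0, 1, 2a, 2b with the
#' branch-site proportions and the foreground branch evolves under
#' \code{omega2} at class-2 sites. No stop codons are ever produced (the
#' state space is the 61 sense codons).
#'
#' @param tree rooted \code{phylo} with branch lengths (expected
#'   substitutions per codon).
#' @param model a \linkS4class{CodonModel}.
#' @param length number of codons.
#' @param seed integer seed.
#' @param foreground optional foreground branch identifier.
#' @param siteClasses optional list \code{(p0, p1, omega0, omega2)} for the
#'   branch-site regime (requires \code{foreground}).
#' @return list with \code{alignment} (tip nucleotide matrix, 3*length
#'   columns) and \code{truth} (seed, per-site class, class-2 site indices,
#'   per-branch omega, kappa).
#' @export
simulateCodonGene <- function(tree, model, length, seed, foreground = NULL,
                              siteClasses = NULL) {
  stopifnot(length >= 1)
  tree <- prepareTree(tree, requireLengths = TRUE)
  eng <- buildEngine(tree)
  ids <- branchIds(eng$tree)
  freq <- model@codonFrequencies
  kappa <- model@kappa

  omegaOf <- function(edgeIdx) {
    om <- model@omega
    if (base::length(om) == 1L) return(unname(om))
    if (is.null(names(om))) stop("per-branch omega must be named")
    if (!ids[edgeIdx] %in% names(om))
      stop("no omega for branch '", ids[edgeIdx], "'")
    unname(om[[ids[edgeIdx]]])
  }

  fgEdge <- if (!is.null(foreground)) resolveBranch(eng$tree, foreground)
            else NA_integer_
  if (!is.null(siteClasses)) {
    if (is.null(foreground))
      stop("siteClasses requires a foreground branch")
    p0 <- siteClasses$p0; p1 <- siteClasses$p1
    w0 <- siteClasses$omega0; w2 <- siteClasses$omega2
    stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1, w0 >= 0, w2 >= 0)
    p2 <- 1 - p0 - p1
    clsProb <- c(`0` = p0, `1` = p1,
                 `2a` = p2 * p0 / (p0 + p1), `2b` = p2 * p1 / (p0 + p1))
    ## per class, omega on background and foreground branches
    omBg <- c(`0` = w0, `1` = 1, `2a` = w0, `2b` = 1)
    omFg <- c(`0` = w0, `1` = 1, `2a` = w2, `2b` = w2)
  }

  ## site classes of a branch-site regime share one (neutral-referenced)
  ## time scale, so high-omega classes evolve faster; single-omega and
  ## per-branch simulations use each omega's own normalisation (branch
  ## lengths are expected substitutions per codon on that branch)
  refOmega <- if (is.null(siteClasses)) NULL else 1
  decCache <- new.env(parent = emptyenv())
  getDec <- function(om) {
    key <- sprintf("%.12g", om)
    if (is.null(decCache[[key]]))
      decCache[[key]] <- codonDecompose(freq, kappa, om, refOmega)
    decCache[[key]]
  }

  res <- withSeed(seed, {
    if (is.null(siteClasses)) {
      cls <- rep("0", length)
    } else {
      cls <- sample(names(clsProb), length, replace = TRUE, prob = clsProb)
    }
    root <- sample.int(61, length, replace = TRUE, prob = freq)
    states <- matrix(NA_integer_, eng$nnode, length)
    states[eng$root, ] <- root
    for (k in rev(seq_len(nrow(eng$edges)))) {
      par <- eng$edges[k, 1]; ch <- eng$edges[k, 2]
      t <- eng$branchLengths[k]
      for (cl in unique(cls)) {
        om <- if (is.null(siteClasses)) omegaOf(k)
              else if (!is.na(fgEdge) && k == fgEdge) omFg[[cl]]
              else omBg[[cl]]
        P <- decompTransition(getDec(om), t)
        idx <- which(cls == cl)
        ps <- states[par, idx]
        out <- integer(base::length(idx))
        for (p in unique(ps)) {
          w <- which(ps == p)
          out[w] <- sample.int(61, base::length(w), replace = TRUE,
                               prob = P[p, ])
        }
        states[ch, idx] <- out
      }
    }
    list(states = states, cls = cls)
  })
  ntip <- eng$ntip
  codons <- matrix(SENSE_CODONS[res$states[seq_len(ntip), , drop = FALSE]],
                   nrow = ntip)
  nt <- do.call(cbind, lapply(seq_len(length), function(s) {
    do.call(rbind, strsplit(codons[, s], ""))
  }))
  rownames(nt) <- eng$tree$tip.label
  omegaTruth <- if (base::length(model@omega) == 1L && is.null(siteClasses))
    stats::setNames(rep(model@omega, nrow(eng$edges)), ids)
  else if (is.null(siteClasses)) model@omega[ids]
  else NULL
  list(alignment = nt,
       truth = list(seed = seed, length = length, kappa = kappa,
                    siteClass = res$cls,
                    class2Sites = which(res$cls %in% c("2a", "2b")),
                    omega = omegaTruth,
                    foreground = if (is.null(foreground)) NA_character_
                                 else ids[fgEdge]))
}

#' Inject convergent or parallel substitutions into an alignment
#'
#' Rewrites the residues of the two clades subtended by a branch pair at
#' sampled sites so that the MAP-reconstructible history matches the
#' requested class: for \code{"parallel"}, both stem ancestors reconstruct
#' to the same residue and both clades carry a shared different derived
#' residue; for \code{"convergent"}, the two stem ancestors differ and the
#' clades share a derived residue distinct from both. Other taxa are left
#' untouched, so eligibility is judged from a quick MAP reconstruction of
#' the current alignment: parallel needs equal stem MAP states, convergent
#' needs differing ones. Sites are sampled without replacement.
#'
#' @param alignment amino-acid alignment matrix.
#' @param tree rooted \code{phylo} with branch lengths.
#' @param branchA,branchB non-nested branch pair.
#' @param nSites number of sites to rewrite.
#' @param mode \code{"parallel"} or \code{"convergent"}.
#' @param seed integer seed.
#' @param avoidSites site indices never to touch (e.g. previous
#'   injections).
#' @return list with the modified \code{alignment} and \code{truth} data
#'   frame (site, mode, stem ancestors, derived residue).
#' @export
injectConvergence <- function(alignment, tree, branchA, branchB, nSites,
                              mode = c("parallel", "convergent"), seed,
                              avoidSites = integer()) {
  mode <- match.arg(mode)
  tree <- prepareTree(tree, requireLengths = TRUE)
  aln <- .alignTipsToTree(tree, asAlignmentMatrix(alignment))
  truth0 <- data.frame(site = integer(), mode = character(),
                       ancestorA = character(), ancestorB = character(),
                       derived = character(), stringsAsFactors = FALSE)
  if (nSites == 0)
    return(list(alignment = aln, truth = truth0))
  pr <- .checkPair(tree, branchA, branchB)
  model <- aminoAcidModel(aln, mode = "JTT-Fgene")
  recon <- marginalReconstruction(tree, model, aln)
  A <- .branchStates(recon, pr$eA)
  B <- .branchStates(recon, pr$eB)
  okData <- !(A$excluded | B$excluded)
  eligible <- which(okData & (if (mode == "parallel") A$anc == B$anc
                              else A$anc != B$anc))
  eligible <- setdiff(eligible, avoidSites)
  if (length(eligible) < nSites)
    stop("not enough eligible sites for ", mode, " injection: need ",
         nSites, ", have ", length(eligible))
  sets <- .nodeTipSets(tree)
  cladeA <- sets[[tree$edge[pr$eA, 2]]]
  cladeB <- sets[[tree$edge[pr$eB, 2]]]
  picks <- withSeed(seed, {
    sites <- sort(sample(eligible, nSites))
    derived <- vapply(sites, function(s) {
      sample(setdiff(AA_ALPHABET, c(A$anc[s], B$anc[s])), 1)
    }, character(1))
    list(sites = sites, derived = derived)
  })
  for (i in seq_len(nSites)) {
    s <- picks$sites[i]
    aln[cladeA, s] <- picks$derived[i]
    aln[cladeB, s] <- picks$derived[i]
  }
  list(alignment = aln,
       truth = data.frame(site = picks$sites, mode = mode,
                          ancestorA = A$anc[picks$sites],
                          ancestorB = B$anc[picks$sites],
                          derived = picks$derived,
                          stringsAsFactors = FALSE))
}

#' Generate a multi-gene codon fixture set
#'
#' Simulates \code{nGenes} independent codon alignments on one tree with
#' per-gene seeds derived from a single master seed (gene i uses a fixed
#' affine function of the master seed, so truth tables are reproducible).
#' Gene lengths are drawn uniformly from \code{lengthRange}.
#'
#' @param tree rooted \code{phylo} with branch lengths; defaults to
#'   \code{\link{defaultViperTree}}.
#' @param nGenes number of genes.
#' @param lengthRange inclusive codon-length range.
#' @param seed master seed.
#' @param omega shared dN/dS for background genes.
#' @param kappa transition/transversion ratio.
#' @return named list of genes, each with \code{alignment} and
#'   \code{truth}.
#' @export
makeGeneSet <- function(tree = defaultViperTree(), nGenes = 10,
                        lengthRange = c(300, 600), seed = 1, omega = 0.2,
                        kappa = 2) {
  model <- codonModel(kappa = kappa, omega = omega)
  lens <- withSeed(seed, {
    sample(seq(lengthRange[1], lengthRange[2]), nGenes, replace = TRUE)
  })
  genes <- lapply(seq_len(nGenes), function(i) {
    simulateCodonGene(tree, model, lens[i], deriveSeed(seed, i))
  })
  names(genes) <- sprintf("gene%03d", seq_len(nGenes))
  genes
}

#' Write an injection truth table as TSV
#' @param truth data frame from \code{\link{injectConvergence}}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeSimulationTruth <- function(truth, file) {
  utils::write.table(truth, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read an injection truth table
#' @param file TSV path written by \code{\link{writeSimulationTruth}}.
#' @return the truth data frame.
#' @export
readSimulationTruth <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
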