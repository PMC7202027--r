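## Marginal (empirical Bayes) ancestral sequence reconstruction on a fixed
## rooted tree, and the site-likelihood kernel beneath it.

.alignTipsToTree <- function(tree, aln) {
  if (!setequal(rownames(aln), tree$tip.label))
    stop("alignment taxa and tree leaves do not match")
  aln[tree$tip.label, , drop = FALSE]
}

## Per-edge amino-acid transition matrices for one frequency row.
.aaPlist <- function(eng, model, site = NULL) {
  dec <- model@decompositions[[.freqRow(model, site)]]
  lapply(eng$branchLengths, function(t) decompTransition(dec, t))
}

#' Site log-likelihood by Felsenstein pruning
#'
#' Log of the equilibrium-frequency-weighted sum, over root states, of the
#' pruning likelihood of a single alignment column. Gapped or ambiguous
#' leaves contribute all-ones partial likelihoods.
#'
#' @param tree rooted \code{phylo} tree with branch lengths.
#' @param model an \linkS4class{AminoAcidModel}.
#' @param column named character vector mapping every leaf to a residue
#'   (\code{"-"} for gap).
#' @param site optional column index used to pick the frequency vector in
#'   site-specific mode.
#' @return the log-likelihood (\code{-Inf} for an impossible column).
#' @examples
#' tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
#' m <- aminoAcidModel(mode = "JTT")
#' siteLogLikelihood(tr, m, c(a = "A", b = "A"))
#' @export
siteLogLikelihood <- function(tree, model, column, site = NULL) {
  tree <- prepareTree(tree, requireLengths = TRUE)
  if (!setequal(names(column), tree$tip.label))
    stop("column taxa and tree leaves do not match")
  aln <- matrix(toupper(column[tree$tip.label]), ncol = 1,
                dimnames = list(tree$tip.label, NULL))
  eng <- buildEngine(tree)
  tipStates <- encodeAlignment(aln, AA_ALPHABET)
  dec <- model@decompositions[[.freqRow(model, site)]]
  st <- engineDown(eng, .aaPlist(eng, model, site), tipStates, dec$pi)
  unname(st$siteLogLik[1])
}

#' Marginal ancestral reconstruction
#'
#' For every internal node and alignment column, computes the posterior
#' distribution over residues by one down-pass and one up-pass of pruning
#' (the posterior combines the partial likelihood below the node with the
#' partial from the rest of the tree), and records the most-probable (MAP)
#' state. Ties are broken by fixed alphabetical residue order.
#'
#' @param tree rooted \code{phylo} tree with branch lengths (root an
#'   unrooted input first via \code{\link{prepareTree}}).
#' @param model an \linkS4class{AminoAcidModel}.
#' @param alignment amino-acid alignment whose taxa are the tree leaves.
#' @return an \linkS4class{AncestralReconstruction}.
#' @export
marginalReconstruction <- function(tree, model, alignment) {
  tree <- prepareTree(tree, requireLengths = TRUE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  aln <- .alignTipsToTree(tree, asAlignmentMatrix(alignment))
  L <- ncol(aln)
  eng <- buildEngine(tree)
  ntip <- eng$ntip
  internal <- (ntip + 1L):eng$nnode
  ids <- nodeIds(tree)[internal]
  post <- array(NA_real_, c(length(internal), L, 20),
                dimnames = list(ids, NULL, AA_ALPHABET))
  siteLogLik <- numeric(L)
  enc <- encodeAlignment(aln, AA_ALPHABET)

  runBlock <- function(states, Plist, rootFreq) {
    st <- engineDown(eng, Plist, states, rootFreq)
    st <- engineUp(eng, st, Plist)
    list(st = st,
         post = lapply(internal, function(v) enginePosterior(eng, st, v)))
  }

  if (nrow(model@frequencies) == 1L) {
    cp <- compressPatterns(enc)
    res <- runBlock(cp$states, .aaPlist(eng, model),
                    model@decompositions[[1]]$pi)
    siteLogLik <- res$st$siteLogLik[cp$map]
    for (i in seq_along(internal))
      post[i, , ] <- t(res$post[[i]][, cp$map, drop = FALSE])
  } else {
    if (length(model@siteMap) != L)
      stop("site-specific model was built for a different alignment length")
    for (s in seq_len(L)) {
      res <- runBlock(enc[, s, drop = FALSE], .aaPlist(eng, model, s),
                      model@decompositions[[.freqRow(model, s)]]$pi)
      siteLogLik[s] <- res$st$siteLogLik[1]
      for (i in seq_along(internal)) post[i, s, ] <- res$post[[i]][, 1]
    }
  }
  map <- matrix(NA_character_, length(internal), L,
                dimnames = list(ids, NULL))
  for (i in seq_along(internal)) {
    pm <- matrix(post[i, , ], nrow = L, ncol = 20)
    map[i, ] <- AA_ALPHABET[max.col(pm, ties.method = "first")]
  }
  methods::new("AncestralReconstruction", tree = tree, posteriors = post,
               mapStates = map, tipStates = aln,
               siteLogLik = as.numeric(siteLogLik), mode = model@mode)
}

#' Write a reconstruction as TSV
#'
#' One row per internal node and site: node identifier, 1-based site, MAP
#' residue, and the MAP posterior probability.
#'
#' @param recon an \linkS4class{AncestralReconstruction}.
#' @param file output path.
#' @return invisibly, the path written.
#' @export
writeReconstructionTSV <- function(recon, file) {
  d <- dim(recon@posteriors)
  nodes <- rownames(recon@mapStates)
  df <- data.frame(
    node = rep(nodes, times = d[2]),
    site = rep(seq_len(d[2]), each = d[1]),
    map = as.vector(recon@mapStates),
    posterior = sprintf("%.6f", as.vector(apply(recon@posteriors,
                                                c(1, 2), max))),
    stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
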