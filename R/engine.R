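## Generic Felsenstein-pruning engine, shared by the 20-state amino-acid and
## 61-state codon likelihoods.
##
## Partial likelihoods are rescaled per node (per-pattern log accumulators)
## to prevent underflow on long alignments. Tip contributions are column
## selections of P rather than matrix products; missing tip data (gaps,
## ambiguity codes) contribute all-ones partials.

## Array slab accessor that never drops dimensions (npat may be 1).
.slab <- function(A, v) matrix(A[, , v], nrow = dim(A)[1], ncol = dim(A)[2])

## Precompute traversal structure. The returned engine carries the tree in
## postorder; Plist arguments to the passes below must be aligned with
## eng$edges rows.
buildEngine <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  nnode <- ntip + po$Nnode
  edges <- po$edge
  root <- setdiff(edges[, 1], edges[, 2])[1]
  edgeOfChild <- integer(nnode)
  edgeOfChild[edges[, 2]] <- seq_len(nrow(edges))
  childEdges <- vector("list", nnode)
  for (k in seq_len(nrow(edges)))
    childEdges[[edges[k, 1]]] <- c(childEdges[[edges[k, 1]]], k)
  ## internal nodes in completion order: a node is ready once its last child
  ## edge has been passed in postorder
  lastPos <- tapply(seq_len(nrow(edges)), edges[, 1], max)
  nodeOrder <- as.integer(names(sort(lastPos)))
  list(tree = po, edges = edges, ntip = ntip, nnode = nnode, root = root,
       edgeOfChild = edgeOfChild, childEdges = childEdges,
       nodeOrder = nodeOrder, branchLengths = po$edge.length)
}

.colMax <- function(m) {
  tm <- t(m)
  tm[cbind(seq_len(nrow(tm)), max.col(tm, ties.method = "first"))]
}

## Contribution of the child of edge k to its parent's partial:
## P %*% G_child for internal children, a column selection for tips.
.edgeContribution <- function(eng, k, P, G, tipStates, npat, nstate) {
  ch <- eng$edges[k, 2]
  if (ch <= eng$ntip) {
    M <- matrix(1, nstate, npat)
    s <- tipStates[ch, ]
    ok <- s > 0L
    if (any(ok)) M[, ok] <- P[, s[ok]]
    M
  } else {
    P %*% .slab(G, ch)
  }
}

## Down-pass (tips to root). Returns per-node scaled partials G with log
## rescaling accumulators, cached per-edge contributions, and per-pattern
## log-likelihoods.
engineDown <- function(eng, Plist, tipStates, rootFreq) {
  nstate <- length(rootFreq)
  npat <- ncol(tipStates)
  G <- array(NA_real_, c(nstate, npat, eng$nnode))
  gls <- matrix(0, npat, eng$nnode)
  contribs <- vector("list", nrow(eng$edges))
  for (v in eng$nodeOrder) {
    part <- matrix(1, nstate, npat)
    sc <- numeric(npat)
    for (k in eng$childEdges[[v]]) {
      M <- .edgeContribution(eng, k, Plist[[k]], G, tipStates, npat, nstate)
      contribs[[k]] <- M
      part <- part * M
      ch <- eng$edges[k, 2]
      if (ch > eng$ntip) sc <- sc + gls[, ch]
    }
    mx <- .colMax(part)
    mx[mx <= 0] <- 1
    G[, , v] <- part / rep(mx, each = nstate)
    gls[, v] <- sc + log(mx)
  }
  lik <- colSums(rootFreq * .slab(G, eng$root))
  siteLogLik <- log(lik) + gls[, eng$root]
  list(G = G, gls = gls, contribs = contribs, siteLogLik = siteLogLik,
       rootFreq = rootFreq, tipStates = tipStates, nstate = nstate,
       npat = npat)
}

## Up-pass (root to tips): "outside" partials O_v(x) = likelihood weight of
## everything not below v given state x at v, with the root prior folded in.
## Marginal posteriors are O * G normalised per pattern.
engineUp <- function(eng, st, Plist) {
  nstate <- st$nstate
  npat <- st$npat
  O <- array(NA_real_, c(nstate, npat, eng$nnode))
  ols <- matrix(0, npat, eng$nnode)
  O[, , eng$root] <- st$rootFreq
  for (k in rev(seq_len(nrow(eng$edges)))) {
    par <- eng$edges[k, 1]
    ch <- eng$edges[k, 2]
    if (ch <= eng$ntip) next
    W <- .slab(O, par)
    sc <- ols[, par]
    for (o in eng$childEdges[[par]]) {
      if (o == k) next
      W <- W * st$contribs[[o]]
      och <- eng$edges[o, 2]
      if (och > eng$ntip) sc <- sc + st$gls[, och]
    }
    M <- crossprod(Plist[[k]], W)
    mx <- .colMax(M)
    mx[mx <= 0] <- 1
    O[, , ch] <- M / rep(mx, each = nstate)
    ols[, ch] <- sc + log(mx)
  }
  st$O <- O
  st$ols <- ols
  st
}

## Posterior state distributions at an internal node (nstate x npat).
enginePosterior <- function(eng, st, node) {
  post <- .slab(st$O, node) * .slab(st$G, node)
  tot <- colSums(post)
  tot[tot <= 0] <- 1
  post / rep(tot, each = st$nstate)
}

## Precomputed flanks of one focal edge: the outside partial at the
## parent (with sibling contributions folded in) and the below partial at
## the child, with their log scales. Lets mixture models re-evaluate the
## edge under many transition matrices cheaply.
engineEdgePrep <- function(eng, st, edgeIdx) {
  par <- eng$edges[edgeIdx, 1]
  ch <- eng$edges[edgeIdx, 2]
  W <- .slab(st$O, par)
  sc <- st$ols[, par]
  for (o in eng$childEdges[[par]]) {
    if (o == edgeIdx) next
    W <- W * st$contribs[[o]]
    och <- eng$edges[o, 2]
    if (och > eng$ntip) sc <- sc + st$gls[, och]
  }
  if (ch <= eng$ntip) {
    Gch <- matrix(1, st$nstate, st$npat)
    sdx <- st$tipStates[ch, ]
    ok <- sdx > 0L
    if (any(ok)) Gch[, ok] <- diag(st$nstate)[, sdx[ok]]
    scG <- 0
  } else {
    Gch <- .slab(st$G, ch)
    scG <- st$gls[, ch]
  }
  list(W = W, sc = sc, Gch = Gch, scG = scG)
}

## Per-pattern site log-likelihood across the prepared edge under P.
engineEdgeLogLikPrep <- function(prep, P) {
  log(colSums(prep$W * (P %*% prep$Gch))) + prep$sc + prep$scG
}

## Per-pattern site log-likelihood computed across one focal edge with a
## substituted transition matrix P (used by mixture models that vary a
## single branch): sum_{x,y} F(x) P[x,y] G_child(y).
engineEdgeLogLik <- function(eng, st, edgeIdx, P) {
  par <- eng$edges[edgeIdx, 1]
  ch <- eng$edges[edgeIdx, 2]
  W <- .slab(st$O, par)
  sc <- st$ols[, par]
  for (o in eng$childEdges[[par]]) {
    if (o == edgeIdx) next
    W <- W * st$contribs[[o]]
    och <- eng$edges[o, 2]
    if (och > eng$ntip) sc <- sc + st$gls[, och]
  }
  if (ch <= eng$ntip) {
    Gch <- matrix(1, st$nstate, st$npat)
    s <- st$tipStates[ch, ]
    ok <- s > 0L
    if (any(ok)) Gch[, ok] <- diag(st$nstate)[, s[ok]]
    scG <- 0
  } else {
    Gch <- .slab(st$G, ch)
    scG <- st$gls[, ch]
  }
  lik <- colSums(W * (P %*% Gch))
  log(lik) + sc + scG
}

## Whole-alignment likelihood for one shared substitution process.
## model-agnostic: caller supplies per-edge P matrices and the root
## frequency vector.
engineLogLik <- function(eng, Plist, tipStates, rootFreq, weights) {
  st <- engineDown(eng, Plist, tipStates, rootFreq)
  sum(weights * st$siteLogLik)
}
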