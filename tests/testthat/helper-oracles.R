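## Independent oracles and small fixtures used across the suite. These
## deliberately avoid the package's engine internals: likelihoods by
## exhaustive enumeration, classifications by a literal restatement of the
## definitions, tail probabilities by outcome enumeration.

aaAlphabet <- function() {
  sort(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
}

## Exhaustive-pruning likelihood: sum over all internal-node state
## assignments of prior x transition products. Feasible for <= 5 leaves.
bruteForceSiteLik <- function(tree, model, column, clamp = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  internals <- sort(setdiff(unique(tree$edge[, 1]), NULL))
  alpha <- aaAlphabet()
  pi <- phyloscreen::modelFrequencies(model)
  Pl <- lapply(seq_len(nrow(tree$edge)), function(k)
    phyloscreen::transitionMatrix(model, tree$edge.length[k]))
  tipState <- match(toupper(column[tree$tip.label]), alpha)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:20),
                                             length(internals))))
  assign_ <- matrix(NA_integer_, nrow(grid), nnode)
  assign_[, internals] <- grid
  assign_[, seq_len(ntip)] <- rep(tipState, each = nrow(grid))
  keep <- if (is.null(clamp)) rep(TRUE, nrow(grid)) else
    assign_[, clamp$node] == clamp$state
  assign_ <- assign_[keep, , drop = FALSE]
  w <- pi[assign_[, root]]
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    if (ch <= ntip && is.na(tipState[ch])) next    # gap tip: marginalised
    w <- w * Pl[[k]][cbind(assign_[, par], assign_[, ch])]
  }
  sum(w)
}

## Literal restatement of the convergent/parallel/divergent definitions.
directClassify <- function(a1, d1, a2, d2) {
  s1 <- a1 != d1
  s2 <- a2 != d2
  if (s1 && s2) {
    if (d1 == d2) {
      if (a1 == a2) return("parallel") else return("convergent")
    }
    return("divergent")
  }
  if (s1 || s2) return("single")
  "none"
}

## Exact Poisson-binomial tail by enumerating all 2^n outcomes (n small).
enumTail <- function(probs, k) {
  n <- length(probs)
  tot <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) < k) next
    tot <- tot + prod(ifelse(bits == 1, probs, 1 - probs))
  }
  tot
}

## Benjamini-Hochberg step-up computed literally from the definition.
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

## Hand-built codon alignment with known fourfold-degenerate columns:
## `n4d` columns where all taxa share a fourfold prefix (variable third
## position), the rest built from non-degenerate or inconsistent codons.
make4DFixture <- function(taxa = paste0("t", 1:4), nCodons = 100,
                          n4d = 7, seed = 42) {
  set.seed(seed)
  fourfold <- c("GG", "GC", "CC", "CT")
  nonq <- c("AAA", "AAG", "TGG", "ATG", "GAA", "TTT", "CAT")
  cod <- matrix("", length(taxa), nCodons)
  sites4d <- sort(sample(nCodons, n4d))
  for (j in seq_len(nCodons)) {
    if (j %in% sites4d) {
      pre <- sample(fourfold, 1)
      cod[, j] <- paste0(pre, sample(c("A", "C", "G", "T"), length(taxa),
                                     replace = TRUE))
    } else if (j %% 3 == 0) {
      ## fourfold family but prefixes differ across taxa: must not qualify
      pres <- sample(c("GG", "GT"), length(taxa), replace = TRUE)
      if (length(unique(pres)) == 1L) pres[1] <- setdiff(c("GG", "GT"),
                                                         pres[1])
      cod[, j] <- paste0(pres, "A")
    } else {
      cod[, j] <- sample(nonq, 1)
    }
  }
  nt <- do.call(cbind, lapply(seq_len(nCodons), function(j)
    do.call(rbind, strsplit(cod[, j], ""))))
  rownames(nt) <- taxa
  list(alignment = nt, sites4d = sites4d)
}

## Shared small fixtures.
tree4 <- function() ape::read.tree(
  text = "((a:0.2,b:0.33):0.12,(c:0.41,d:0.07):0.3);")
tree5 <- function() ape::read.tree(
  text = "(((a:0.15,b:0.2):0.1,c:0.3):0.05,(d:0.25,e:0.1):0.2);")
tree6 <- function() ape::read.tree(
  text = "((((s1:0.1,s2:0.1):0.1,s3:0.8):0.1,(s4:0.25,s5:0.2):0.1):0.1,s6:0.4);")
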