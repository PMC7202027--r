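test_that("zero branch lengths copy the root; equal seeds reproduce
           byte-identical genes", {
  tr <- defaultViperTree()
  tr0 <- tr
  tr0$edge.length[] <- 0
  m <- aminoAcidModel(mode = "JTT")
  g <- simulateProteinGene(tr0, m, 50, seed = 1)
  for (tx in rownames(g$alignment))
    expect_identical(unname(g$alignment[tx, ]), g$truth$rootSequence)
  g1 <- simulateProteinGene(tr, m, 200, seed = 123)
  g2 <- simulateProteinGene(tr, m, 200, seed = 123)
  expect_identical(g1, g2)
  g3 <- simulateProteinGene(tr, m, 200, seed = 124)
  expect_false(identical(g1$alignment, g3$alignment))
  ## written FASTA is byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  writeAlignment(g1$alignment, f1, type = "AA")
  writeAlignment(g2$alignment, f2, type = "AA")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulator respects the RNG contract without disturbing the
           caller's stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulateProteinGene(defaultViperTree(),
                                aminoAcidModel(mode = "JTT"), 10,
                                seed = 7))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("omega = 0 forbids nonsynonymous change; large kappa suppresses
           transversions", {
  tr <- tree6()
  g0 <- simulateCodonGene(tr, codonModel(kappa = 2, omega = 0), 200,
                          seed = 5)
  aa <- translateCodonAlignment(g0$alignment)
  for (s in seq_len(ncol(aa)))
    expect_equal(length(unique(aa[, s])), 1L)
  ## transition/transversion audit at high kappa
  countTv <- function(g) {
    cs <- codonStrings(g$alignment)
    tv <- 0; ts <- 0
    pur <- c("A", "G")
    for (i in 1:(nrow(cs) - 1)) for (j in (i + 1):nrow(cs)) {
      for (s in seq_len(ncol(cs))) {
        b1 <- strsplit(cs[i, s], "")[[1]]; b2 <- strsplit(cs[j, s], "")[[1]]
        d <- which(b1 != b2)
        for (k in d) {
          if ((b1[k] %in% pur) == (b2[k] %in% pur)) ts <- ts + 1
          else tv <- tv + 1
        }
      }
    }
    c(ts = ts, tv = tv)
  }
  hi <- countTv(simulateCodonGene(tr, codonModel(kappa = 60, omega = 0.5),
                                  150, seed = 6))
  lo <- countTv(simulateCodonGene(tr, codonModel(kappa = 1, omega = 0.5),
                                  150, seed = 6))
  expect_lt(hi[["tv"]] / sum(hi), lo[["tv"]] / sum(lo))
  expect_lt(hi[["tv"]] / sum(hi), 0.2)
})

test_that("branch-site truth records exactly the class-2 site indices", {
  tr <- tree6()
  g <- simulateCodonGene(tr, codonModel(kappa = 2, omega = 0.2), 300,
                         seed = 9, foreground = "s3",
                         siteClasses = list(p0 = 0.4, p1 = 0.4,
                                            omega0 = 0.1, omega2 = 4))
  expect_identical(g$truth$class2Sites,
                   which(g$truth$siteClass %in% c("2a", "2b")))
  expect_identical(g$truth$foreground, "s3")
  expect_true(all(g$truth$class2Sites <= 300))
  ## no stop codons ever
  cs <- codonStrings(g$alignment)
  expect_false(any(phyloscreen:::GENETIC_CODE_STD[cs] == "*"))
})

test_that("per-branch substitution counts track t x L within wide Poisson
           bands", {
  tr <- ape::read.tree(text = "(a:0.02,(b:0.3,c:0.02):0.02);")
  m <- aminoAcidModel(mode = "JTT")
  g <- simulateProteinGene(tr, m, 5000, seed = 13)
  ## b is far from a and c; a and c are nearly identical
  dab <- sum(g$alignment["a", ] != g$alignment["b", ])
  dac <- sum(g$alignment["a", ] != g$alignment["c", ])
  expAB <- 5000 * (1 - sum(modelFrequencies(m) *
                           diag(transitionMatrix(m, 0.34))))
  expect_lt(abs(dab - expAB), 4 * sqrt(expAB))
  expect_lt(dac, dab / 3)
})

test_that("injection edits only the targeted clades, samples disjoint
           sites, and round-trips its truth table", {
  tr <- defaultViperTree()
  m <- aminoAcidModel(mode = "JTT")
  g <- simulateProteinGene(tr, m, 300, seed = 41)
  un <- injectConvergence(g$alignment, tr, "shedao_viper", "alligator", 0,
                          "parallel", seed = 1)
  expect_identical(un$alignment, g$alignment[rownames(un$alignment), ])
  inj1 <- injectConvergence(g$alignment, tr, "shedao_viper", "alligator",
                            8, "parallel", seed = 2)
  untouched <- setdiff(rownames(g$alignment),
                       c("shedao_viper", "alligator"))
  expect_identical(inj1$alignment[untouched, ],
                   g$alignment[untouched, ])
  diffCols <- which(apply(
    inj1$alignment[c("shedao_viper", "alligator"), , drop = FALSE] !=
      g$alignment[c("shedao_viper", "alligator"), , drop = FALSE],
    2, any))
  expect_setequal(diffCols, inj1$truth$site)
  ## a second injection avoiding the first is disjoint
  inj2 <- injectConvergence(inj1$alignment, tr, "shedao_viper",
                            "alligator", 5, "parallel", seed = 3,
                            avoidSites = inj1$truth$site)
  expect_length(intersect(inj1$truth$site, inj2$truth$site), 0)
  ## truth table round-trip
  f <- tempfile(fileext = ".tsv")
  writeSimulationTruth(inj1$truth, f)
  expect_identical(readSimulationTruth(f), inj1$truth)
  expect_error(injectConvergence(g$alignment, tr, "shedao_viper",
                                 "alligator", 10000, "parallel",
                                 seed = 1),
               "not enough eligible")
})

test_that("convergent-mode injection yields convergent classifications", {
  tr <- defaultViperTree()
  m <- aminoAcidModel(mode = "JTT")
  g <- simulateProteinGene(tr, m, 500, seed = 61)
  inj <- injectConvergence(g$alignment, tr, "shedao_viper", "alligator",
                           5, "convergent", seed = 4)
  mg <- aminoAcidModel(inj$alignment, mode = "JTT-Fgene")
  rec <- marginalReconstruction(tr, mg, inj$alignment)
  prof <- classifyBranchPair(rec, "shedao_viper", "alligator")
  expect_gte(sum(prof@perSiteClass[inj$truth$site] == "convergent"), 3)
})

test_that("gene sets derive reproducible per-gene seed streams", {
  tr <- defaultViperTree()
  gs1 <- makeGeneSet(tr, nGenes = 3, lengthRange = c(50, 80), seed = 11)
  gs2 <- makeGeneSet(tr, nGenes = 3, lengthRange = c(50, 80), seed = 11)
  expect_identical(gs1, gs2)
  expect_length(unique(vapply(gs1, function(g) g$truth$seed,
                              numeric(1))), 3L)
})
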