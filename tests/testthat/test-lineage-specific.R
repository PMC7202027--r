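mkColAln <- function(cols, taxa) {
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  m
}

test_that("detection requires a constant background and a different focal
           residue", {
  taxa <- c(paste0("bg", 1:10), "focal")
  aln <- mkColAln(list(c(rep("A", 10), "T"),      # reported: A->T
                       c(rep("A", 9), "S", "T"),  # background not constant
                       rep("A", 11),              # no substitution
                       c(rep("A", 9), "-", "T"),  # gap in background
                       c(rep("W", 10), "G")),     # reported: W->G
                  taxa)
  hits <- detectSpecificSubstitutions(aln, "focal", minBackground = 8)
  expect_equal(hits$site, c(1L, 5L))
  expect_equal(hits$label, c("A1T", "W5G"))
  expect_equal(hits$reference, c("A", "W"))
  expect_equal(hits$focal, c("T", "G"))
  expect_error(detectSpecificSubstitutions(aln, "nothere"), "absent")
})

test_that("the relaxed background threshold admits partially gapped
           columns; strict mode rejects them", {
  taxa <- c(paste0("bg", 1:10), "focal")
  col <- c(rep("A", 8), "-", "-", "T")
  aln <- mkColAln(list(col), taxa)
  expect_equal(nrow(detectSpecificSubstitutions(aln, "focal",
                                                minBackground = 8)), 0L)
  colOk <- c(rep("A", 9), "-", "T")
  aln2 <- mkColAln(list(colOk), taxa)
  expect_equal(nrow(detectSpecificSubstitutions(aln2, "focal",
                                                minBackground = 8)), 0L)
  ## gap among background always disqualifies (strict constancy);
  ## a fully present background passes either threshold
  aln3 <- mkColAln(list(c(rep("A", 10), "T")), taxa)
  expect_equal(nrow(detectSpecificSubstitutions(aln3, "focal",
                                                minBackground = 10)), 1L)
})

test_that("tryptophan-column glycine variant scores -13 and is called
           deleterious at the -2.5 threshold", {
  taxa <- c(paste0("bg", 1:10), "focal")
  aln <- mkColAln(list(c(rep("W", 10), "G")), taxa)
  sc <- conservationDeltaScore(aln, 1, "W", "G", focal = "focal")
  expect_equal(sc, -13)
  hits <- detectSpecificSubstitutions(aln, "focal")
  expect_equal(hits$score, -13)
  expect_identical(hits$call, "deleterious")
  expect_error(conservationDeltaScore(aln, 1, "W", "W"), "differ")
})

test_that("the decision threshold separates calls at -2.5 exactly", {
  taxa <- c(paste0("bg", 1:10), "focal")
  aln <- mkColAln(list(c(rep("A", 10), "T")), taxa)
  ## synthetic scores around the threshold via the threshold argument
  h1 <- detectSpecificSubstitutions(aln, "focal", threshold = 0.1)
  h2 <- detectSpecificSubstitutions(aln, "focal", threshold = -100)
  expect_identical(h1$call, "deleterious")   # score 0 <= 0.1
  expect_identical(h2$call, "neutral")
  ## direct boundary check of the decision rule
  expect_identical(ifelse(-2.4 <= -2.5, "deleterious", "neutral"),
                   "neutral")
  expect_identical(ifelse(-2.6 <= -2.5, "deleterious", "neutral"),
                   "deleterious")
})

test_that("conservative variants never score below radical ones on the
           same column", {
  taxa <- c(paste0("bg", 1:8), "focal")
  col <- rep("L", 8)
  aln <- mkColAln(list(c(col, "X")), taxa)
  ## I (BLOSUM62-positive with L) vs G (negative): conservative >= radical
  sI <- conservationDeltaScore(aln, 1, "L", "I", focal = "focal")
  sG <- conservationDeltaScore(aln, 1, "L", "G", focal = "focal")
  expect_gt(sI, sG)
  expect_gte(sI, -2.5)
  expect_lte(sG, -2.5)
})

test_that("detection is invariant to background order and removed by a
           matching background taxon", {
  taxa <- c(paste0("bg", 1:10), "focal")
  aln <- mkColAln(list(c(rep("A", 10), "T"), c(rep("K", 10), "R")), taxa)
  h <- detectSpecificSubstitutions(aln, "focal")
  perm <- aln[c(sample(1:10), 11), , drop = FALSE]
  h2 <- detectSpecificSubstitutions(perm, "focal")
  expect_equal(h[order(h$site), ], h2[order(h2$site), ])
  ## adding a background taxon that carries the focal residue kills site 1
  aln3 <- rbind(aln, bgNew = c("T", "K"))
  h3 <- detectSpecificSubstitutions(aln3, "focal")
  expect_false(1L %in% h3$site)
  expect_true(2L %in% h3$site)
})

test_that("injected focal-specific sites are recovered exactly on
           conserved simulated alignments", {
  tr <- defaultViperTree()
  short <- tr
  short$edge.length <- tr$edge.length * 0.02   # highly conserved genes
  m <- aminoAcidModel(mode = "JTT")
  g <- simulateProteinGene(short, m, 300, seed = 77)
  aln <- g$alignment
  ## plant k focal-only substitutions at conserved columns
  conserved <- which(apply(aln, 2, function(x) length(unique(x)) == 1))
  set.seed(3)
  planted <- sort(sample(conserved, 6))
  for (s in planted) {
    ref <- aln[1, s]
    aln["shedao_viper", s] <- sample(setdiff(aaAlphabet(), ref), 1)
  }
  base <- detectSpecificSubstitutions(g$alignment, "shedao_viper",
                                      minBackground = 10)
  hits <- detectSpecificSubstitutions(aln, "shedao_viper",
                                      minBackground = 10)
  expect_setequal(hits$site, union(planted, base$site))
})
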