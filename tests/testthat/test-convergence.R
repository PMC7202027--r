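test_that("classification follows the convergent/parallel definitions", {
  expect_identical(classifySubstitutionPair("T", "S", "T", "S"), "parallel")
  expect_identical(classifySubstitutionPair("A", "S", "V", "S"),
                   "convergent")
  expect_identical(classifySubstitutionPair("T", "S", "T", "A"),
                   "divergent")
  expect_identical(classifySubstitutionPair("T", "S", "A", "A"), "single")
  expect_identical(classifySubstitutionPair("T", "T", "A", "A"), "none")
  ## randomized quadruples against the literal oracle
  set.seed(2)
  alpha <- aaAlphabet()
  a1 <- sample(alpha, 500, TRUE); d1 <- sample(alpha, 500, TRUE)
  a2 <- sample(alpha, 500, TRUE); d2 <- sample(alpha, 500, TRUE)
  expect_identical(classifySubstitutionPair(a1, d1, a2, d2),
                   mapply(directClassify, a1, d1, a2, d2, USE.NAMES = FALSE))
})

test_that("branch-pair profiles classify, exclude gaps, and are
           symmetric", {
  tr <- defaultViperTree()
  m <- aminoAcidModel(mode = "JTT")
  g <- simulateProteinGene(tr, m, 300, seed = 31)
  aln <- g$alignment
  aln["shedao_viper", 5] <- "-"          # forces exclusion at site 5
  mg <- aminoAcidModel(aln, mode = "JTT-Fgene")
  rec <- marginalReconstruction(tr, mg, aln)
  p1 <- classifyBranchPair(rec, "shedao_viper", "alligator")
  p2 <- classifyBranchPair(rec, "alligator", "shedao_viper")
  expect_identical(p1@perSiteClass[5], "excluded")
  expect_equal(sum(classCounts(p1)), 300L)           # partition of sites
  expect_equal(classCounts(p1), classCounts(p2))
  expect_error(classifyBranchPair(rec, "shedao_viper",
                                  "shedao_viper+mainland_viper"),
               "nested")
  expect_error(classifyBranchPair(rec, "shedao_viper", "nosuchtaxon"),
               "not found")
})

test_that("expected counts vanish on zero-length branches and match a
           direct sum for fixed ancestors", {
  tr <- ape::read.tree(
    text = "((a:0,b:0.1):0.1,(c:0,d:0.1):0.1);")
  aln <- rbind(a = "A", b = "A", c = "A", d = "A")
  m <- aminoAcidModel(mode = "JTT")
  rec <- marginalReconstruction(tr, m, aln)
  ec0 <- expectedSubstitutionCounts(m, rec, "a", "c")
  expect_equal(ec0$expectedConv, 0, tolerance = 1e-12)
  expect_equal(ec0$expectedPar, 0, tolerance = 1e-12)

  ## single site, ancestors effectively fixed at 'A': parallel probability
  ## equals the directly summed squared transition probabilities
  tr2 <- ape::read.tree(
    text = "((a:0.1,b:0.001):0.001,(c:0.1,d:0.001):0.001);")
  rec2 <- marginalReconstruction(tr2, m, aln)
  ec <- expectedSubstitutionCounts(m, rec2, "a", "c", useMAP = TRUE)
  P <- transitionMatrix(m, 0.1)
  direct <- sum(P["A", setdiff(colnames(P), "A")]^2)
  expect_equal(ec$perSiteProbPar[1], direct, tolerance = 1e-12)
  expect_equal(ec$perSiteProbConv[1], 0, tolerance = 1e-12)
  expect_equal(ec$expectedPar, sum(ec$perSiteProbPar), tolerance = 1e-12)
})

test_that("expected counts agree with Monte-Carlo branch-pair simulation", {
  ## two independent branches from known ancestors; compare the analytic
  ## per-site convergence/parallelism probabilities with simulation
  m <- aminoAcidModel(mode = "JTT")
  set.seed(5)
  alpha <- aaAlphabet()
  for (cfg in 1:4) {
    a1 <- sample(alpha, 1); a2 <- sample(alpha, 1)
    tA <- runif(1, 0.05, 0.6); tB <- runif(1, 0.05, 0.6)
    PA <- transitionMatrix(m, tA); PB <- transitionMatrix(m, tB)
    K <- phyloscreen:::.pairKernels(PA, PB)
    nrep <- 4000
    d1 <- sample(alpha, nrep, TRUE, prob = PA[a1, ])
    d2 <- sample(alpha, nrep, TRUE, prob = PB[a2, ])
    cls <- classifySubstitutionPair(rep(a1, nrep), d1, rep(a2, nrep), d2)
    for (what in c("parallel", "convergent")) {
      pAna <- if (what == "parallel") {
        if (a1 == a2) K$par[[a1]] else 0
      } else {
        if (a1 == a2) 0 else K$conv[a1, a2]
      }
      pObs <- mean(cls == what)
      se <- sqrt(max(pAna * (1 - pAna), 1e-12) / nrep)
      expect_lt(abs(pObs - pAna), 3 * se + 1e-9)
    }
  }
})

test_that("tail probabilities match closed forms and enumeration", {
  expect_equal(tailProbability(runif(5), 0), 1)
  expect_equal(tailProbability(c(0.25, 0.25), 3, method = "poisson"),
               1 - exp(-0.5) * (1 + 0.5 + 0.125), tolerance = 1e-10)
  expect_equal(tailProbability(c(0.1, 0.2), 2), 0.02, tolerance = 1e-14)
  set.seed(8)
  probs <- runif(8, 0, 0.4)
  for (k in c(1, 3, 6))
    expect_equal(tailProbability(probs, k), enumTail(probs, k),
                 tolerance = 1e-12)
  expect_equal(tailProbability(c(0.1, 0.2), 5), 0)   # beyond max count
  expect_error(tailProbability(c(0.5, 2), 1), "0, 1")
})

test_that("regression null recovers exact lines and flags injections", {
  mkProfile <- function(ndiv, ncp) {
    cls <- rep(c("divergent", "parallel"), c(ndiv, ncp))
    counts <- table(factor(cls, levels = phyloscreen:::SITE_CLASSES))
    methods::new("BranchPairProfile", branchA = "x", branchB = "y",
                 perSiteClass = cls,
                 counts = stats::setNames(as.integer(counts),
                                          phyloscreen:::SITE_CLASSES))
  }
  xs <- c(10, 20, 30, 40, 50)
  profs <- lapply(xs, function(x) mkProfile(x, round(0.1 * x)))
  rn <- genomeRegressionNull(profs)
  expect_equal(rn@rSquared, 1, tolerance = 1e-9)
  expect_equal(rn@slope, 0.1, tolerance = 1e-9)
  expect_false(any(rn@points$flagged))
  ## a clear outlier pair is flagged with the largest residual
  profs2 <- c(profs, list(mkProfile(30, 30)))
  rn2 <- genomeRegressionNull(profs2)
  expect_true(rn2@points$flagged[6])
  expect_equal(which.max(rn2@points$residual), 6L)
  expect_error(genomeRegressionNull(profs[1:2]), "at least 3")
  expect_error(genomeRegressionNull(rep(list(mkProfile(10, 1)), 4)),
               "degenerate")
})

test_that("injected parallel sites drive the per-gene test p-value down", {
  tr <- defaultViperTree()
  m <- aminoAcidModel(mode = "JTT")
  g <- simulateProteinGene(tr, m, 400, seed = 55)
  pv <- vapply(c(0, 2, 5, 10), function(k) {
    aln <- if (k == 0) g$alignment else
      injectConvergence(g$alignment, tr, "shedao_viper", "alligator", k,
                        "parallel", seed = 100 + k)$alignment
    mg <- aminoAcidModel(aln, mode = "JTT-Fgene")
    rec <- marginalReconstruction(tr, mg, aln)
    convergenceTest(rec, mg, "shedao_viper", "alligator")@pPar
  }, numeric(1))
  expect_true(all(diff(pv) <= 0))
  expect_gt(pv[1], 0.5)
  expect_lt(pv[4], 1e-6)
})
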