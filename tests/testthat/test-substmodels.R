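test_that("site-specific frequencies follow the pseudocount formula", {
  aln <- matrix(c("A", "A", "A", "A"), ncol = 1,
                dimnames = list(paste0("t", 1:4), NULL))
  m <- aminoAcidModel(aln, mode = "JTT-Fsite", pseudocount = 0.1)
  f <- modelFrequencies(m, site = 1)
  expect_equal(unname(f["A"]), (4 + 0.1) / (4 + 20 * 0.1), tolerance = 1e-12)
  expect_equal(unname(f["W"]), 0.1 / 6.0, tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-12)
})

test_that("JTT mode ignores the data; balanced data give uniform Fgene", {
  aln <- rbind(x = c("W", "W"), y = c("W", "W"))
  m <- aminoAcidModel(aln, mode = "JTT")
  expect_equal(unname(modelFrequencies(m)), unname(phyloscreen:::JTT_FREQUENCIES),
               tolerance = 1e-12)
  balanced <- matrix(aaAlphabet(), nrow = 4, ncol = 20, byrow = TRUE,
                     dimnames = list(paste0("t", 1:4), NULL))
  mf <- aminoAcidModel(balanced, mode = "JTT-Fgene")
  expect_equal(unname(modelFrequencies(mf)), rep(0.05, 20),
               tolerance = 1e-12)
  expect_equal(modelMode(mf), "JTT-Fgene")
})

test_that("rate matrices are normalised, balanced and generator-valid", {
  for (mode in c("JTT", "JTT-Fgene")) {
    aln <- rbind(a = c("A", "C", "W", "H"), b = c("A", "C", "W", "Y"))
    m <- aminoAcidModel(aln, mode = mode)
    Q <- rateMatrix(m)
    pi <- modelFrequencies(m)
    expect_lt(max(abs(rowSums(Q))), 1e-10)
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-10)
    F <- diag(pi) %*% Q            # detailed balance: F symmetric
    expect_lt(max(abs(F - t(F))), 1e-10)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
  }
})

test_that("transition matrices satisfy identity, stationarity and
           Chapman-Kolmogorov", {
  m <- aminoAcidModel(mode = "JTT")
  expect_equal(transitionMatrix(m, 0), diag(20), tolerance = 1e-12,
               ignore_attr = TRUE)
  Pinf <- transitionMatrix(m, 1e6)
  pi <- modelFrequencies(m)
  for (i in c(1, 7, 20))
    expect_equal(unname(Pinf[i, ]), unname(pi), tolerance = 1e-6)
  set.seed(1)
  for (rep in 1:5) {
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    expect_equal(transitionMatrix(m, t1 + t2),
                 transitionMatrix(m, t1) %*% transitionMatrix(m, t2),
                 tolerance = 1e-8)
  }
  expect_lt(max(abs(rowSums(transitionMatrix(m, 0.37)) - 1)), 1e-10)
  expect_error(transitionMatrix(m, -0.1), "nonnegative")
})

test_that("long-branch simulation recovers the stationary frequencies", {
  tr <- ape::read.tree(text = "(a:5,b:5);")
  m <- aminoAcidModel(mode = "JTT")
  g <- simulateProteinGene(tr, m, 50000, seed = 9)
  obs <- table(factor(g$alignment["a", ], levels = aaAlphabet()))
  gof <- suppressWarnings(
    stats::chisq.test(as.integer(obs), p = unname(modelFrequencies(m))))
  expect_gt(gof$p.value, 0.001)
})

test_that("codon model frequencies and symmetry behave", {
  m <- codonModel(kappa = 1, omega = 1)
  expect_equal(sum(modelFrequencies(m)), 1, tolerance = 1e-12)
  expect_equal(length(modelFrequencies(m)), 61L)
  expect_false(any(grepl("^(TAA|TAG|TGA)$", names(modelFrequencies(m)))))
  Q <- rateMatrix(m)
  ## kappa = omega = 1 and uniform frequencies: symmetric up to scale
  expect_lt(max(abs(Q - t(Q))), 1e-12)
  pi <- modelFrequencies(m)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-10)
  expect_lt(max(abs(rowSums(transitionMatrix(m, 0.3)) - 1)), 1e-10)
})

test_that("F3x4 frequencies come from positional nucleotide composition", {
  nt <- rbind(a = strsplit("ATGGCT", "")[[1]],
              b = strsplit("ATGGCT", "")[[1]])
  m <- codonModel(nt, codonFreq = "F3x4")
  f <- modelFrequencies(m)
  ## position 1 nucleotides: A,G; position 2: T,C; position 3: G,T
  p1 <- c(A = .5, C = 0, G = .5, T = 0)
  p2 <- c(A = 0, C = .5, G = 0, T = .5)
  p3 <- c(A = 0, C = 0, G = .5, T = .5)
  raw <- vapply(names(f), function(cod) {
    b <- strsplit(cod, "")[[1]]
    p1[b[1]] * p2[b[2]] * p3[b[3]]
  }, numeric(1))
  expect_equal(unname(f), unname(raw / sum(raw)), tolerance = 1e-12)
})

test_that("pruning matches an established likelihood implementation", {
  skip_if_not_installed("phangorn")
  tr <- tree4()
  set.seed(3)
  aln <- matrix(sample(aaAlphabet(), 4 * 30, replace = TRUE), nrow = 4,
                dimnames = list(tr$tip.label, NULL))
  m <- aminoAcidModel(mode = "JTT")
  ours <- sum(siteLogLikelihoods(marginalReconstruction(tr, m, aln)))
  pd <- phangorn::phyDat(aln, type = "AA")
  fit <- phangorn::pml(tr, pd, model = "JTT")
  expect_equal(ours, as.numeric(stats::logLik(fit)), tolerance = 1e-4)
  ## same published frequencies, independent residue ordering
  expect_equal(sort(unname(fit$bf)), sort(unname(modelFrequencies(m))),
               tolerance = 1e-6)
})
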