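test_that("fourfold-degenerate extraction follows the all-taxa rule", {
  ## glycine family (GGx) qualifies; lysine/asparagine (AAx) never does
  gg <- rbind(a = strsplit("GGAGGT", "")[[1]],
              b = strsplit("GGCGGG", "")[[1]])
  out <- extract4DSites(gg)
  expect_equal(ncol(out), 2L)
  expect_equal(unname(out[, 1]), c("A", "C"))
  aa <- rbind(a = strsplit("AAAGGA", "")[[1]],
              b = strsplit("AACGGA", "")[[1]])
  out2 <- extract4DSites(aa)
  expect_equal(ncol(out2), 1L)           # only the GGA column
  ## mixed fourfold families at one column do not qualify
  mix <- rbind(a = strsplit("GGA", "")[[1]], b = strsplit("GTA", "")[[1]])
  expect_equal(ncol(extract4DSites(mix)), 0L)
  ## gapped codons disqualify
  gap <- rbind(a = strsplit("GGAGGA", "")[[1]],
               b = strsplit("GG-GGA", "")[[1]])
  expect_equal(ncol(extract4DSites(gap)), 1L)
})

test_that("the 100-codon fixture yields exactly its 7 built-in 4D columns", {
  fx <- make4DFixture(nCodons = 100, n4d = 7)
  out <- extract4DSites(fx$alignment)
  expect_equal(ncol(out), 7L)
  expect_equal(attr(out, "codonIndex"), fx$sites4d)
  expect_true(all(out %in% c("A", "C", "G", "T")))
  ## positional audit: extracted content equals the third codon positions
  cs <- codonStrings(fx$alignment)
  expect_equal(unname(out), unname(substr(cs[, fx$sites4d], 3, 3)),
               ignore_attr = TRUE)
})

test_that("frame violations and internal stops are reported", {
  bad <- rbind(a = c("A", "T", "G", "C"))
  expect_error(extract4DSites(bad), "divisible by 3")
  stopAln <- rbind(a = strsplit("ATGTAAGGA", "")[[1]],
                   b = strsplit("ATGAAAGGA", "")[[1]])
  expect_error(extract4DSites(stopAln), "stop codon.*'a' at codon 2")
})

test_that("identical sequences give zero divergence on every branch", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  nt <- do.call(rbind, rep(list(strsplit(paste(rep("ATGGCTAAGCTT", 5),
                                               collapse = ""),
                                         "")[[1]]), 4))
  rownames(nt) <- letters[1:4]
  fr <- freeRatioFit(nt, tr, method = "ML")
  expect_true(all(branchRates(fr)$dN == 0))
  expect_true(all(branchRates(fr)$dS == 0))
})

test_that("counting mode sees one synonymous change as dS > 0, dN = 0", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  s1 <- "ATGGCTAAGCTTGGACCA"
  s2 <- "ATGGCAAAGCTTGGACCA"            # GCT -> GCA, synonymous (Ala)
  nt <- rbind(a = strsplit(s1, "")[[1]], b = strsplit(s2, "")[[1]])
  fr <- freeRatioFit(nt, tr, method = "counting")
  rt <- branchRates(fr)
  expect_true(all(rt$dN == 0))
  expect_gt(sum(rt$dS), 0)
})

test_that("two-branch ML fit matches a grid-search oracle", {
  ## two taxa: the likelihood depends on (kappa, omega, total t); compare
  ## the package's maximised lnL with a direct grid search + refinement
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  cm <- codonModel(kappa = 3, omega = 0.4)
  g <- simulateCodonGene(tr, cm, 300, seed = 17)
  fr <- freeRatioFit(g$alignment, tr, method = "ML")
  model <- codonModel(g$alignment, codonFreq = "F3x4")
  freq <- unname(modelFrequencies(model))
  pairLik <- function(kappa, omega, t) {
    P <- phyloscreen:::decompTransition(
      phyloscreen:::codonDecompose(freq, kappa, omega), t)
    cs <- codonStrings(g$alignment)
    i <- match(cs["a", ], phyloscreen:::SENSE_CODONS)
    j <- match(cs["b", ], phyloscreen:::SENSE_CODONS)
    sum(log(freq[i] * P[cbind(i, j)]))
  }
  grid <- expand.grid(kappa = seq(1.5, 5, by = 0.25),
                      omega = seq(0.1, 1, by = 0.05),
                      t = seq(0.1, 0.6, by = 0.02))
  gl <- mapply(pairLik, grid$kappa, grid$omega, grid$t)
  best <- grid[which.max(gl), ]
  ref <- stats::optim(log(unlist(best)), function(x)
    -pairLik(exp(x[1]), exp(x[2]), exp(x[3])),
    control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(fr@logLik, -ref$value, tolerance = 0.01)
})

test_that("ML free-ratio recovers the simulated omega", {
  tr <- tree6()
  cm <- codonModel(kappa = 2, omega = 0.2)
  g <- simulateCodonGene(tr, cm, 500, seed = 23)
  fr <- freeRatioFit(g$alignment, tr, method = "ML")
  rt <- branchRates(fr)
  expect_gte(stats::median(rt$omega), 0.1)
  expect_lte(stats::median(rt$omega), 0.35)
  ## omega column is consistent with dN/dS wherever dS > 0
  ok <- rt$dS > 1e-6
  expect_equal(rt$omega[ok], rt$dN[ok] / rt$dS[ok], tolerance = 1e-8)
})

test_that("branch-site alternative always dominates its null", {
  tr <- tree6()
  cm <- codonModel(kappa = 2, omega = 0.2)
  for (seed in c(101, 102)) {
    g <- simulateCodonGene(tr, cm, 150, seed = seed)
    bs <- branchSiteFit(g$alignment, tr, "s3")
    expect_gte(bs@lnLAlt, bs@lnLNull - 1e-6)
    expect_gte(bs@lrt, 0)
    expect_true(all(bs@sitePosteriors >= 0 & bs@sitePosteriors <= 1))
    p <- bs@paramsAlt
    expect_equal(sum(p[c("p0", "p1", "p2a", "p2b")]), 1, tolerance = 1e-8)
  }
})

test_that("branch-site test detects strong engineered selection", {
  tr <- tree6()
  cm <- codonModel(kappa = 2, omega = 0.2)
  g <- simulateCodonGene(tr, cm, 400, seed = 12, foreground = "s3",
                         siteClasses = list(p0 = 0.4, p1 = 0.4,
                                            omega0 = 0.1, omega2 = 8))
  bs <- branchSiteFit(g$alignment, tr, "s3")
  expect_lt(bs@pValue, 0.01)
  expect_gt(bs@paramsAlt[["omega2"]], 1.5)
  ## the mixture-reference option can only make p smaller
  bs2 <- branchSiteFit(g$alignment, tr, "s3", mixtureRef = TRUE)
  expect_lte(bs2@pValue, bs@pValue + 1e-12)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3),
               tolerance = 1e-12)
  expect_equal(fdrAdjust(0.2), 0.2)
  set.seed(12)
  p <- runif(15)
  expect_equal(fdrAdjust(p), bhStepUp(p), tolerance = 1e-12)
  grid <- seq(0.1, 1, by = 0.1)
  expect_equal(fdrAdjust(grid), bhStepUp(grid), tolerance = 1e-12)
  expect_equal(fdrAdjust(grid), rep(1, 10), tolerance = 1e-12)
  expect_error(fdrAdjust(c(0.1, 1.2)), "0, 1")
})
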