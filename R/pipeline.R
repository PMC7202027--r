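## Orchestration of the per-gene screen and cross-gene statistics.

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two samples: midranks for ties, exact
#' enumeration when both samples have at most 10 observations and there
#' are no ties, otherwise the normal approximation with continuity
#' correction. The reported W is the rank sum of the first sample.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with \code{W} (rank sum of \code{x}), \code{U} (the
#'   Mann-Whitney statistic), and \code{p}.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))$p  # exact: 1/3
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    stop("degenerate input: all pooled values are identical")
  n1 <- length(x)
  exact <- n1 <= 10 && length(y) <= 10 && !anyDuplicated(pooled)
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  U <- unname(ht$statistic)
  list(W = U + n1 * (n1 + 1) / 2, U = U, p = ht$p.value)
}

## Deterministic config fingerprint (md5 of the deparsed config).
.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Default screen configuration
#'
#' @param focal focal (foreground) taxon label.
#' @param comparators taxa whose terminal branches are tested against the
#'   focal branch for convergent/parallel substitutions.
#' @return named list of configuration values; see the package vignette
#'   for the meaning and defaults of each key.
#' @export
screenConfig <- function(focal = "shedao_viper",
                         comparators = c("alligator", "turtle")) {
  list(
    focal = focal,
    comparators = comparators,
    minTaxa = 4,                    # genes with fewer taxa are skipped
    maxGapFraction = 0.5,           # drop genes with a mostly-gap sequence
    codonFreq = "F3x4",
    freeRatioMethod = "counting",   # "ML" for the full per-branch ML fit
    tailMethod = "poisson_binomial",
    convergenceMode = "JTT-Fgene",  # per-gene test model
    pseudocount = 0.1,
    alpha = 0.05,
    minBackground = 8,              # lineage-specific substitution screen
    deleteriousThreshold = -2.5,
    dsCompare = NULL,               # c(branchA, branchB); NULL = focal vs
                                    # its sister terminal branch
    regressionPairs = "terminal"    # "terminal" or "all"
  )
}

#' Read a screen configuration from YAML
#'
#' Values present in the file override \code{\link{screenConfig}}
#' defaults.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readScreenConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- screenConfig()
  cfg[names(usr)] <- usr
  cfg
}

## Sister terminal branch of a tip (NULL when the sibling is a clade).
.sisterTip <- function(tree, tip) {
  ntip <- length(tree$tip.label)
  tipIdx <- match(tip, tree$tip.label)
  par <- tree$edge[tree$edge[, 2] == tipIdx, 1]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == par, 2], tipIdx)
  if (length(sibs) == 1L && sibs <= ntip) tree$tip.label[sibs] else NULL
}

## Observed classification profiles for a set of branch pairs, sharing the
## per-branch ancestor/descendant state vectors.
.pairProfiles <- function(recon, pairIdx) {
  tree <- recon@tree
  ids <- branchIds(tree)
  edges <- sort(unique(c(pairIdx$eA, pairIdx$eB)))
  stCache <- lapply(stats::setNames(edges, edges), function(e)
    .branchStates(recon, e))
  lapply(seq_len(nrow(pairIdx)), function(i) {
    A <- stCache[[as.character(pairIdx$eA[i])]]
    B <- stCache[[as.character(pairIdx$eB[i])]]
    cls <- classifySubstitutionPair(A$anc, A$der, B$anc, B$der)
    cls[A$excluded | B$excluded] <- "excluded"
    counts <- table(factor(cls, levels = SITE_CLASSES))
    methods::new("BranchPairProfile", branchA = ids[pairIdx$eA[i]],
                 branchB = ids[pairIdx$eB[i]], perSiteClass = cls,
                 counts = stats::setNames(as.integer(counts), SITE_CLASSES))
  })
}

#' Run the full per-gene screen
#'
#' For every gene: (1) the branch-site positive-selection test on the
#' focal branch, (2) convergence/parallelism tests against the configured
#' comparator branches, (3) a free-ratio dN/dS fit, and (4) the
#' focal-specific substitution scan. Cross-gene statistics: BH-FDR over
#' the branch-site p-values, a genome-wide divergence regression null over
#' summed branch-pair counts, and a Wilcoxon rank-sum comparison of
#' per-gene synonymous divergence between the focal branch and a
#' comparison branch. Per-gene failures are quarantined with a reason and
#' never abort the screen.
#'
#' @param genes named list of in-frame codon alignments (matrices, FASTA
#'   paths, or \code{list(alignment = ...)} objects from the simulator).
#' @param tree rooted species tree with branch lengths covering all taxa.
#' @param config configuration list from \code{\link{screenConfig}} /
#'   \code{\link{readScreenConfig}}.
#' @param seed seed recorded in the metadata (the screen itself is
#'   deterministic given inputs).
#' @return a \linkS4class{GeneScreenReport}.
#' @export
runScreen <- function(genes, tree, config = screenConfig(), seed = 1) {
  tree <- prepareTree(tree, requireLengths = TRUE)
  focal <- config$focal
  if (!focal %in% tree$tip.label)
    stop("focal taxon '", focal, "' is not in the tree")
  if (is.null(names(genes)) && length(genes))
    names(genes) <- sprintf("gene%03d", seq_along(genes))

  status <- character(length(genes))
  names(status) <- names(genes)
  psg <- list(); conv <- list(); rates <- list(); specific <- list()
  dsTab <- list()
  aggPairs <- new.env(parent = emptyenv())

  cmpPairs <- lapply(intersect(config$comparators, tree$tip.label),
                     function(cmp) c(focal, cmp))

  for (gene in names(genes)) {
    res <- tryCatch({
      obj <- genes[[gene]]
      if (is.list(obj) && !is.null(obj$alignment)) obj <- obj$alignment
      if (is.character(obj) && length(obj) == 1L)
        obj <- readAlignment(obj, type = "DNA")
      aln <- asAlignmentMatrix(obj)
      if (!all(rownames(aln) %in% tree$tip.label))
        stop("alignment taxa not all present in the tree")
      gapFrac <- rowMeans(aln == "-" | aln == "?")
      if (any(gapFrac > config$maxGapFraction))
        return_status <- paste0("skipped:gap-heavy sequence (",
                                rownames(aln)[which.max(gapFrac)], ")")
      else if (nrow(aln) < config$minTaxa)
        return_status <- "skipped:too few taxa"
      else if (!focal %in% rownames(aln))
        return_status <- "skipped:focal taxon missing"
      else {
        gtree <- if (length(setdiff(tree$tip.label, rownames(aln))))
          ape::keep.tip(tree, rownames(aln)) else tree
        aaAln <- translateCodonAlignment(aln)

        ## reconstruction + convergence tests on configured pairs
        aaModel <- aminoAcidModel(aaAln, mode = config$convergenceMode,
                                  pseudocount = config$pseudocount)
        recon <- marginalReconstruction(gtree, aaModel, aaAln)
        for (pr in cmpPairs) {
          if (!all(pr %in% rownames(aln))) next
          ct <- convergenceTest(recon, aaModel, pr[1], pr[2],
                                method = config$tailMethod)
          cc <- classCounts(ct)
          conv[[length(conv) + 1L]] <- data.frame(
            gene = gene, branchA = ct@profile@branchA,
            branchB = ct@profile@branchB,
            nConv = cc[["convergent"]], nPar = cc[["parallel"]],
            nDiv = cc[["divergent"]],
            eConv = ct@expectedConv, ePar = ct@expectedPar,
            pConv = ct@pConv, pPar = ct@pPar, pJoint = ct@pJoint,
            stringsAsFactors = FALSE)
        }

        ## genome-wide branch-pair accumulation
        pairDf <- branchPairs(gtree,
                              terminalOnly =
                                config$regressionPairs == "terminal")
        if (nrow(pairDf)) {
          pairIdx <- data.frame(
            eA = vapply(pairDf$branchA, resolveBranch, integer(1),
                        tree = gtree),
            eB = vapply(pairDf$branchB, resolveBranch, integer(1),
                        tree = gtree))
          profs <- .pairProfiles(recon, pairIdx)
          for (p in profs) {
            key <- paste(sort(c(p@branchA, p@branchB)), collapse = " vs ")
            prev <- aggPairs[[key]]
            cc <- p@counts
            add <- c(cc[["convergent"]], cc[["parallel"]],
                     cc[["divergent"]])
            aggPairs[[key]] <- if (is.null(prev)) add else prev + add
          }
        }

        ## codon fits: shared one-ratio stage feeds both analyses
        eng <- buildEngine(gtree)
        dat <- .codonData(aln, eng$tree)
        freq <- codonModel(aln, codonFreq = config$codonFreq
                           )@codonFrequencies
        m0 <- .fitM0(eng, dat, freq, refOmega = 1)
        bs <- branchSiteFit(aln, gtree, focal,
                            codonFreq = config$codonFreq,
                            control = list(m0 = m0))
        psg[[length(psg) + 1L]] <- data.frame(
          gene = gene, lnLNull = bs@lnLNull, lnLAlt = bs@lnLAlt,
          lrt = bs@lrt, p = bs@pValue, q = NA_real_,
          omega2 = bs@paramsAlt[["omega2"]],
          nSelectedSites = sum(bs@sitePosteriors > 0.5),
          selectedSites = paste(which(bs@sitePosteriors > 0.95),
                                collapse = ","),
          stringsAsFactors = FALSE)

        fr <- freeRatioFit(aln, gtree, method = config$freeRatioMethod,
                           codonFreq = config$codonFreq,
                           control = list(m0 = m0))
        rt <- branchRates(fr)
        rt <- cbind(gene = gene, rt, stringsAsFactors = FALSE)
        rates[[length(rates) + 1L]] <- rt

        ## focal-specific substitutions
        sp <- detectSpecificSubstitutions(
          aaAln, focal,
          minBackground = min(config$minBackground, nrow(aaAln) - 1L),
          threshold = config$deleteriousThreshold)
        if (nrow(sp))
          specific[[length(specific) + 1L]] <-
            cbind(gene = gene, sp, stringsAsFactors = FALSE)

        dsTab[[gene]] <- rt[, c("branch", "dS")]
        return_status <- "ok"
      }
      return_status
    }, error = function(e) paste0("failed:", conditionMessage(e)))
    status[gene] <- res
  }

  psg <- if (length(psg)) do.call(rbind, psg) else
    data.frame(gene = character(), lnLNull = numeric(),
               lnLAlt = numeric(), lrt = numeric(), p = numeric(),
               q = numeric(), omega2 = numeric(),
               nSelectedSites = integer(), selectedSites = character(),
               stringsAsFactors = FALSE)
  if (nrow(psg)) psg$q <- fdrAdjust(psg$p)

  convDf <- if (length(conv)) do.call(rbind, conv) else
    data.frame(gene = character(), branchA = character(),
               branchB = character(), nConv = integer(), nPar = integer(),
               nDiv = integer(), eConv = numeric(), ePar = numeric(),
               pConv = numeric(), pPar = numeric(), pJoint = numeric(),
               stringsAsFactors = FALSE)
  ratesDf <- if (length(rates)) do.call(rbind, rates) else
    data.frame(gene = character(), branch = character(), t = numeric(),
               dN = numeric(), dS = numeric(), omega = numeric(),
               stringsAsFactors = FALSE)
  specDf <- if (length(specific)) do.call(rbind, specific) else
    data.frame(gene = character(), site = integer(), label = character(),
               reference = character(), focal = character(),
               nBackground = integer(), score = numeric(),
               call = character(), stringsAsFactors = FALSE)

  ## genome-wide regression null over aggregated pair counts
  regression <- list()
  keys <- sort(ls(aggPairs))
  if (length(keys) >= 3L) {
    profiles <- lapply(keys, function(k) {
      v <- aggPairs[[k]]
      br <- strsplit(k, " vs ", fixed = TRUE)[[1]]
      cls <- rep(c("convergent", "parallel", "divergent"), v)
      counts <- table(factor(cls, levels = SITE_CLASSES))
      methods::new("BranchPairProfile", branchA = br[1], branchB = br[2],
                   perSiteClass = cls,
                   counts = stats::setNames(as.integer(counts),
                                            SITE_CLASSES))
    })
    regression <- tryCatch(
      list(genomeRegressionNull(profiles, alpha = config$alpha)),
      error = function(e) list())
  }

  ## cross-gene dS comparison between two branches
  dsCompare <- config$dsCompare
  if (is.null(dsCompare)) {
    sis <- .sisterTip(tree, focal)
    if (!is.null(sis)) dsCompare <- c(focal, sis)
  }
  wil <- list()
  if (!is.null(dsCompare) && length(dsTab)) {
    getDs <- function(branch) {
      vapply(dsTab, function(d) {
        i <- match(branch, d$branch)
        if (is.na(i)) NA_real_ else d$dS[i]
      }, numeric(1))
    }
    dsA <- getDs(dsCompare[1])
    dsB <- getDs(dsCompare[2])
    ok <- !is.na(dsA) & !is.na(dsB)
    zeroFlag <- names(dsTab)[ok & (dsA == 0 | dsB == 0)]
    if (sum(ok) >= 2 && length(unique(c(dsA[ok], dsB[ok]))) > 1) {
      wt <- wilcoxonRankSum(dsA[ok], dsB[ok])
      wil <- list(branchA = dsCompare[1], branchB = dsCompare[2],
                  W = wt$W, U = wt$U, p = wt$p, nGenes = sum(ok),
                  medianA = stats::median(dsA[ok]),
                  medianB = stats::median(dsB[ok]),
                  zeroDsGenes = zeroFlag)
    }
  }

  methods::new("GeneScreenReport",
    status = data.frame(gene = names(status), status = unname(status),
                        stringsAsFactors = FALSE),
    psg = psg, convergence = convDf, rates = ratesDf, specific = specDf,
    regression = regression, wilcoxon = wil,
    metadata = list(seed = seed, focal = focal,
                    nGenes = length(genes),
                    configHash = .configHash(config),
                    packageVersion = tryCatch(
                      as.character(utils::packageVersion("phyloscreen")),
                      error = function(e) "dev")))
}

#' Write a screen report as TSV tables plus JSON metadata
#'
#' Files written: \code{status.tsv}, \code{psg.tsv},
#' \code{convergence.tsv}, \code{rates.tsv}, \code{specific.tsv},
#' \code{regression.tsv} (when present), \code{wilcoxon.json},
#' \code{metadata.json}. Output is deterministic for identical reports.
#'
#' @param report a \linkS4class{GeneScreenReport}.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
writeScreenReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report@status, "status.tsv")
  wt(report@psg, "psg.tsv")
  wt(report@convergence, "convergence.tsv")
  wt(report@rates, "rates.tsv")
  wt(report@specific, "specific.tsv")
  if (length(report@regression))
    wt(report@regression[[1]]@points, "regression.tsv")
  jsonlite::write_json(report@wilcoxon, file.path(dir, "wilcoxon.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report@metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
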