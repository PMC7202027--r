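## Focal-lineage-specific amino-acid substitutions and a conservation-based
## functional-impact score.
##
## A site is a focal-lineage-specific substitution when every background
## taxon carries one identical residue (no gaps or ambiguity codes among
## them) and the focal taxon carries a different residue. Predicted impact
## is scored as the mean BLOSUM62 difference, over background residues, of
## substituting the variant for the reference; scores at or below the
## decision threshold (default -2.5) are called "deleterious". This score
## preserves the decision structure of homology-profile tools (threshold
## and deleterious/neutral vocabulary) but is computed from the alignment
## column alone, so it does not reproduce database-backed scores
## numerically.

#' Conservation-based substitution impact score
#'
#' Mean over background residues b of \code{BLOSUM62[variant, b] -
#' BLOSUM62[reference, b]}: how much worse (negative) or better the
#' variant fits the column's conservation profile than the reference.
#'
#' @param alignment amino-acid alignment matrix.
#' @param site 1-based column index.
#' @param reference reference residue (the background consensus).
#' @param variant variant residue carried by the focal taxon; must differ
#'   from \code{reference}.
#' @param focal optional focal taxon label to exclude from the background
#'   profile.
#' @return the delta score (0 would mean an exactly equivalent residue).
#' @examples
#' aln <- matrix("W", nrow = 10, ncol = 1,
#'               dimnames = list(paste0("t", 1:10), NULL))
#' conservationDeltaScore(aln, 1, "W", "G")  # -13
#' @export
conservationDeltaScore <- function(alignment, site, reference, variant,
                                   focal = NULL) {
  if (variant == reference)
    stop("variant must differ from the reference residue")
  aln <- asAlignmentMatrix(alignment)
  col <- aln[, site]
  if (!is.null(focal)) col <- col[setdiff(names(col), focal)]
  bg <- col[col %in% AA_ALPHABET]
  if (length(bg) < 2L)
    stop("need at least 2 scoreable background residues at site ", site)
  mean(BLOSUM62[variant, bg] - BLOSUM62[reference, bg])
}

#' Detect focal-lineage-specific substitutions
#'
#' Scans an alignment for columns where all background (non-focal) taxa
#' share one residue with no gaps or ambiguity codes among them, at least
#' \code{minBackground} background taxa are present, and the focal taxon
#' carries a different residue. Each hit is scored with
#' \code{\link{conservationDeltaScore}} and called deleterious when the
#' score is at or below \code{threshold}.
#'
#' @param alignment amino-acid alignment matrix including the focal taxon.
#' @param focal focal taxon label.
#' @param minBackground minimum number of non-gap background taxa required
#'   at a reported site (strict mode: all background taxa).
#' @param threshold deleteriousness decision threshold (default -2.5).
#' @return data frame with columns \code{site}, \code{label} (e.g.
#'   \code{"A318T"}), \code{reference}, \code{focal}, \code{nBackground},
#'   \code{score}, \code{call}.
#' @export
detectSpecificSubstitutions <- function(alignment, focal,
                                        minBackground = 8,
                                        threshold = -2.5) {
  aln <- asAlignmentMatrix(alignment)
  if (!focal %in% rownames(aln))
    stop("focal taxon '", focal, "' is absent from the alignment")
  bgTaxa <- setdiff(rownames(aln), focal)
  if (length(bgTaxa) < minBackground)
    stop("fewer than minBackground background taxa in the alignment")
  out <- list()
  for (s in seq_len(ncol(aln))) {
    bg <- aln[bgTaxa, s]
    if (!all(bg %in% AA_ALPHABET)) next      # strict: gaps/ambiguity
    if (length(unique(bg)) != 1L) next       # background not constant
    if (length(bg) < minBackground) next
    ref <- bg[[1]]
    foc <- aln[focal, s]
    if (!foc %in% AA_ALPHABET || foc == ref) next
    sc <- mean(BLOSUM62[foc, bg] - BLOSUM62[ref, bg])
    out[[length(out) + 1L]] <- data.frame(
      site = s, label = sprintf("%s%d%s", ref, s, foc), reference = ref,
      focal = foc, nBackground = length(bg), score = sc,
      call = if (sc <= threshold) "deleterious" else "neutral",
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site = integer(), label = character(),
                      reference = character(), focal = character(),
                      nBackground = integer(), score = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
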