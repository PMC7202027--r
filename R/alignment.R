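## Alignment handling. Alignments are plain character matrices: one row per
## taxon (rownames are taxon labels), one column per site, uppercase symbols,
## "-" for gaps. Codon alignments are nucleotide matrices whose length is a
## multiple of three.

AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O", "*", "-", ".", "?")
NT_AMBIGUOUS <- setdiff(c(LETTERS, "-", ".", "?"), NUCLEOTIDES)

#' Coerce to an alignment matrix
#'
#' Accepts a character matrix, a named character vector of sequences, a
#' named list of single sequences, or an \code{ape} \code{AAbin}/\code{DNAbin}
#' alignment, and returns the package's canonical representation: an
#' uppercase character matrix with one row per taxon.
#'
#' @param x the object to coerce.
#' @return a character matrix with taxon rownames.
#' @export
asAlignmentMatrix <- function(x) {
  if (inherits(x, "AAbin") || inherits(x, "DNAbin")) {
    x <- as.character(as.matrix(x))
  }
  if (is.list(x)) x <- vapply(x, paste0, character(1), collapse = "")
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("sequences have unequal lengths; not an alignment")
    x <- do.call(rbind, strsplit(x, ""))
    rownames(x) <- names(lens)
  }
  if (!is.matrix(x)) stop("cannot interpret input as an alignment")
  if (is.null(rownames(x))) stop("alignment must have taxon rownames")
  x[] <- toupper(x)
  x
}

#' Read a FASTA alignment
#'
#' @param file path to an (uncompressed) FASTA file.
#' @param type \code{"AA"} or \code{"DNA"}.
#' @return a character alignment matrix.
#' @export
readAlignment <- function(file, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- ape::read.FASTA(file, type = type)
  lens <- lengths(x)
  if (length(unique(lens)) != 1L)
    stop("sequences in ", file, " have unequal lengths; not an alignment")
  asAlignmentMatrix(x)
}

#' Write a FASTA alignment
#'
#' @param aln a character alignment matrix.
#' @param file output path.
#' @param type \code{"AA"} or \code{"DNA"}.
#' @return invisibly, the path written.
#' @export
writeAlignment <- function(aln, file, type = c("AA", "DNA")) {
  type <- match.arg(type)
  aln <- asAlignmentMatrix(aln)
  obj <- if (type == "AA") ape::as.AAbin(aln) else ape::as.DNAbin(aln)
  ape::write.FASTA(obj, file)
  invisible(file)
}

#' Split a codon alignment into codon strings
#'
#' @param codonAln nucleotide alignment matrix, width divisible by 3.
#' @return character matrix (taxa x codons) of 3-letter codon strings.
#' @export
codonStrings <- function(codonAln) {
  codonAln <- asAlignmentMatrix(codonAln)
  L <- ncol(codonAln)
  if (L %% 3L != 0L)
    stop("codon alignment length ", L, " is not divisible by 3")
  idx <- seq(1L, L, by = 3L)
  out <- vapply(idx, function(i) {
    paste0(codonAln[, i], codonAln[, i + 1L], codonAln[, i + 2L])
  }, character(nrow(codonAln)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(codonAln))
  rownames(out) <- rownames(codonAln)
  out
}

#' Validate an in-frame codon alignment
#'
#' Checks the reading frame and scans every sequence for internal stop
#' codons, which are reported with taxon and codon position.
#'
#' @param codonAln nucleotide alignment matrix.
#' @param allowFinalStop drop a shared terminal stop codon instead of
#'   failing on it.
#' @return invisibly, the codon-string matrix.
#' @export
checkCodonAlignment <- function(codonAln, allowFinalStop = TRUE) {
  cs <- codonStrings(codonAln)
  nc <- ncol(cs)
  aa <- matrix(GENETIC_CODE_STD[cs], nrow = nrow(cs),
               dimnames = dimnames(cs))
  last <- if (allowFinalStop) nc else nc + 1L
  stop_hits <- which(aa == "*" & col(aa) < last, arr.ind = TRUE)
  if (nrow(stop_hits)) {
    hit <- stop_hits[1, ]
    stop(sprintf("internal stop codon in taxon '%s' at codon %d",
                 rownames(cs)[hit[1]], hit[2]))
  }
  invisible(cs)
}

#' Translate a codon alignment
#'
#' Standard genetic code; fully gapped codons become \code{"-"}, any codon
#' containing a gap or ambiguity code becomes \code{"X"}.
#'
#' @param codonAln nucleotide alignment matrix, width divisible by 3.
#' @return amino-acid alignment matrix (taxa x codons).
#' @export
translateCodonAlignment <- function(codonAln) {
  cs <- codonStrings(codonAln)
  aa <- matrix("X", nrow = nrow(cs), ncol = ncol(cs), dimnames = dimnames(cs))
  known <- cs %in% names(GENETIC_CODE_STD)
  aa[known] <- GENETIC_CODE_STD[cs[known]]
  aa[cs == "---"] <- "-"
  aa[aa == "*"] <- "X"
  aa
}

## Integer-encode alignment columns against an alphabet; 0 marks gaps and
## ambiguity codes (treated as missing data in likelihoods).
encodeAlignment <- function(aln, alphabet) {
  m <- match(aln, alphabet)
  m[is.na(m)] <- 0L
  matrix(as.integer(m), nrow = nrow(aln), dimnames = dimnames(aln))
}

## Collapse identical columns into patterns.
## Returns list(states = ntaxa x npat integer matrix, weights, map) where
## map[j] is the pattern index of original column j.
compressPatterns <- function(stateMat) {
  key <- apply(stateMat, 2, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(states = stateMat[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(u))),
       map = idx)
}
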