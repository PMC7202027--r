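## Published constants and genetic-code lookup tables.
##
## Amino acids are kept in fixed alphabetical one-letter order everywhere in
## the package; this order also breaks maximum-a-posteriori ties.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

JTT_EXCHANGEABILITIES <- matrix(c(
  0, 56, 81, 105, 15, 179, 27, 36, 35, 30, 54, 54, 194, 57, 58, 378, 475, 298, 9, 11,
  56, 0, 10, 5, 78, 59, 69, 17, 7, 23, 31, 34, 14, 9, 113, 223, 42, 62, 115, 209,
  81, 10, 0, 767, 4, 130, 112, 11, 26, 7, 15, 528, 15, 49, 16, 59, 38, 31, 4, 46,
  105, 5, 767, 0, 5, 119, 26, 12, 181, 9, 18, 58, 18, 323, 29, 30, 32, 45, 10, 7,
  15, 78, 4, 5, 0, 5, 40, 89, 4, 248, 43, 10, 17, 4, 5, 92, 12, 62, 53, 536,
  179, 59, 130, 119, 5, 0, 23, 6, 27, 6, 14, 81, 24, 26, 137, 201, 33, 47, 55, 8,
  27, 69, 112, 26, 40, 23, 0, 16, 45, 56, 33, 391, 115, 597, 328, 73, 46, 11, 8, 573,
  36, 17, 11, 12, 89, 6, 16, 0, 21, 229, 479, 47, 10, 9, 22, 40, 245, 961, 9, 32,
  35, 7, 26, 181, 4, 27, 45, 21, 0, 14, 65, 263, 21, 292, 646, 47, 103, 14, 10, 8,
  30, 23, 7, 9, 248, 6, 56, 229, 14, 0, 388, 12, 102, 72, 38, 59, 25, 180, 52, 24,
  54, 31, 15, 18, 43, 14, 33, 479, 65, 388, 0, 30, 16, 43, 44, 29, 226, 323, 24, 18,
  54, 34, 528, 58, 10, 81, 391, 47, 263, 12, 30, 0, 15, 86, 45, 503, 232, 16, 8, 70,
  194, 14, 15, 18, 17, 24, 115, 10, 21, 102, 16, 15, 0, 164, 74, 285, 118, 23, 6, 10,
  57, 9, 49, 323, 4, 26, 597, 9, 292, 72, 43, 86, 164, 0, 310, 53, 51, 20, 18, 24,
  58, 113, 16, 29, 5, 137, 328, 22, 646, 38, 44, 45, 74, 310, 0, 101, 64, 17, 126, 20,
  378, 223, 59, 30, 92, 201, 73, 40, 47, 59, 29, 503, 285, 53, 101, 0, 477, 38, 35, 63,
  475, 42, 38, 32, 12, 33, 46, 245, 103, 25, 226, 232, 118, 51, 64, 477, 0, 112, 12, 21,
  298, 62, 31, 45, 62, 47, 11, 961, 14, 180, 323, 16, 23, 20, 17, 38, 112, 0, 25, 16,
  9, 115, 4, 10, 53, 55, 8, 9, 10, 52, 24, 8, 6, 18, 126, 35, 12, 25, 0, 71,
  11, 209, 46, 7, 536, 8, 573, 32, 8, 24, 18, 70, 10, 24, 20, 63, 21, 16, 71, 0 
), nrow = 20, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))

JTT_FREQUENCIES <- c(A = 0.076748, C = 0.019803, D = 0.051544, E = 0.061830, F = 0.040126, G = 0.073152, H = 0.022944, I = 0.053761, K = 0.058676, L = 0.091904, M = 0.023826, N = 0.042645, P = 0.050901, Q = 0.040752, R = 0.051691, S = 0.068765, T = 0.058565, V = 0.066005, W = 0.014261, Y = 0.032102)
JTT_FREQUENCIES <- JTT_FREQUENCIES / sum(JTT_FREQUENCIES)

BLOSUM62 <- matrix(c(
  4, 0, -2, -1, -2, 0, -2, -1, -1, -1, -1, -2, -1, -1, -1, 1, 0, 0, -3, -2,
  0, 9, -3, -4, -2, -3, -3, -1, -3, -1, -1, -3, -3, -3, -3, -1, -1, -1, -2, -2,
  -2, -3, 6, 2, -3, -1, -1, -3, -1, -4, -3, 1, -1, 0, -2, 0, -1, -3, -4, -3,
  -1, -4, 2, 5, -3, -2, 0, -3, 1, -3, -2, 0, -1, 2, 0, 0, -1, -2, -3, -2,
  -2, -2, -3, -3, 6, -3, -1, 0, -3, 0, 0, -3, -4, -3, -3, -2, -2, -1, 1, 3,
  0, -3, -1, -2, -3, 6, -2, -4, -2, -4, -3, 0, -2, -2, -2, 0, -2, -3, -2, -3,
  -2, -3, -1, 0, -1, -2, 8, -3, -1, -3, -2, 1, -2, 0, 0, -1, -2, -3, -2, 2,
  -1, -1, -3, -3, 0, -4, -3, 4, -3, 2, 1, -3, -3, -3, -3, -2, -1, 3, -3, -1,
  -1, -3, -1, 1, -3, -2, -1, -3, 5, -2, -1, 0, -1, 1, 2, 0, -1, -2, -3, -2,
  -1, -1, -4, -3, 0, -4, -3, 2, -2, 4, 2, -3, -3, -2, -2, -2, -1, 1, -2, -1,
  -1, -1, -3, -2, 0, -3, -2, 1, -1, 2, 5, -2, -2, 0, -1, -1, -1, 1, -1, -1,
  -2, -3, 1, 0, -3, 0, 1, -3, 0, -3, -2, 6, -2, 0, 0, 1, 0, -3, -4, -2,
  -1, -3, -1, -1, -4, -2, -2, -3, -1, -3, -2, -2, 7, -1, -2, -1, -1, -2, -4, -3,
  -1, -3, 0, 2, -3, -2, 0, -3, 1, -2, 0, 0, -1, 5, 1, 0, -1, -2, -2, -1,
  -1, -3, -2, 0, -3, -2, 0, -3, 2, -2, -1, 0, -2, 1, 5, -1, -1, -3, -3, -2,
  1, -1, 0, 0, -2, 0, -1, -2, 0, -2, -1, 1, -1, 0, -1, 4, 1, -2, -3, -2,
  0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1, 0, -1, -1, -1, 1, 5, 0, -2, -2,
  0, -1, -3, -2, -1, -3, -3, 3, -2, 1, 1, -3, -2, -2, -3, -2, 0, 4, -3, -1,
  -3, -2, -4, -3, 1, -2, -2, -3, -3, -2, -1, -4, -4, -2, -3, -3, -2, -3, 11, 2,
  -2, -2, -3, -2, 3, -3, 2, -1, -2, -1, -1, -2, -3, -1, -2, -2, -2, -1, 2, 7
), nrow = 20, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))

GENETIC_CODE_STD <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L", TCT = "S", TCC = "S", TCA = "S", TCG = "S", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*", TGT = "C", TGC = "C", TGA = "*", TGG = "W", CTT = "L", CTC = "L", CTA = "L", CTG = "L", CCT = "P", CCC = "P", CCA = "P", CCG = "P", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", CGT = "R", CGC = "R", CGA = "R", CGG = "R", ATT = "I", ATC = "I", ATA = "I", ATG = "M", ACT = "T", ACC = "T", ACA = "T", ACG = "T", AAT = "N", AAC = "N", AAA = "K", AAG = "K", AGT = "S", AGC = "S", AGA = "R", AGG = "R", GTT = "V", GTC = "V", GTA = "V", GTG = "V", GCT = "A", GCC = "A", GCA = "A", GCG = "A", GAT = "D", GAC = "D", GAA = "E", GAG = "E", GGT = "G", GGC = "G", GGA = "G", GGG = "G")

NUCLEOTIDES <- c("A", "C", "G", "T")

## Sense codons of the standard genetic code, alphabetical, stops excluded.
SENSE_CODONS <- {
  all <- apply(expand.grid(NUCLEOTIDES, NUCLEOTIDES, NUCLEOTIDES,
                           stringsAsFactors = FALSE)[, 3:1], 1,
               paste, collapse = "")
  sort(all[GENETIC_CODE_STD[all] != "*"])
}

CODON_AA <- GENETIC_CODE_STD[SENSE_CODONS]

## Codon-pair structure used by the Goldman-Yang model: for the 61 x 61
## sense-codon grid, which pairs differ at exactly one position, whether that
## change is a transition, and whether it is synonymous.
.codonPairInfo <- local({
  n <- length(SENSE_CODONS)
  mat <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  one <- matrix(FALSE, n, n)
  ts <- matrix(FALSE, n, n)
  syn <- matrix(FALSE, n, n)
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (pos in 1:3) {
    same_other <- outer(mat[, (1:3)[-pos][1]], mat[, (1:3)[-pos][1]], "==") &
      outer(mat[, (1:3)[-pos][2]], mat[, (1:3)[-pos][2]], "==")
    diff_here <- outer(mat[, pos], mat[, pos], "!=")
    hit <- same_other & diff_here
    one <- one | hit
    ts[hit] <- outer(mat[, pos], mat[, pos], is_ts)[hit]
  }
  syn <- outer(CODON_AA, CODON_AA, "==")
  dimnames(one) <- dimnames(ts) <- dimnames(syn) <-
    list(SENSE_CODONS, SENSE_CODONS)
  list(one_diff = one, transition = ts, synonymous = syn)
})

CODON_ONE_DIFF <- .codonPairInfo$one_diff
CODON_TRANSITION <- .codonPairInfo$transition
CODON_SYNONYMOUS <- .codonPairInfo$synonymous

## Fourfold-degenerate codon families: first two nucleotides determine the
## amino acid whatever the third position is.
FOURFOLD_PREFIXES <- {
  pre <- unique(substr(SENSE_CODONS, 1, 2))
  keep <- vapply(pre, function(p) {
    cods <- paste0(p, NUCLEOTIDES)
    all(cods %in% SENSE_CODONS) && length(unique(CODON_AA[cods])) == 1L
  }, logical(1))
  pre[keep]
}
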