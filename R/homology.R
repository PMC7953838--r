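## Seeded local alignment helpers shared by the TE-annotation, collinearity
## and HGT stages. A cheap exact-word seed filter selects candidate pairs;
## candidates are then scored with Smith-Waterman local alignment
## (Biostrings::pairwiseAlignment).

NT_SUBMAT <- local({
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                baseOnly = TRUE)
  storage.mode(m) <- "double"
  m
})

## all words of length w of one sequence
seq_words <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  unique(substring(s, 1:(n - w + 1), w:n))
}

## canonical DNA words (strand-insensitive seeding)
canonical_words <- function(s, w) {
  ws <- seq_words(s, w)
  if (length(ws) == 0) return(ws)
  unique(pmin(ws, revcomp(ws)))
}

## map: word -> indices of subject sequences containing it
word_index <- function(seqs, w, canonical = FALSE) {
  words <- lapply(seqs, if (canonical) canonical_words else seq_words, w = w)
  split(rep(seq_along(seqs), lengths(words)), unlist(words))
}

## candidate subject indices per query (shared exact word)
seed_candidates <- function(queries, index, w, canonical = FALSE) {
  lapply(queries, function(q) {
    ws <- if (canonical) canonical_words(q, w) else seq_words(q, w)
    hit <- ws[ws %in% names(index)]
    if (length(hit) == 0) integer(0) else sort(unique(unlist(index[hit],
                                                             use.names = FALSE)))
  })
}

## vectorized local alignment of many patterns against one subject;
## returns score, percent identity and aligned pattern length
local_align <- function(patterns, subject, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (type == "DNA") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = NT_SUBMAT,
      gapOpening = 5, gapExtension = 2)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
  }
  pat <- Biostrings::pattern(aln)
  data.frame(score = Biostrings::score(aln),
             pid = Biostrings::pid(aln, type = "PID1"),
             aln_len = BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L)
}

## Karlin-Altschul e-value approximation for gapped BLOSUM62 local scores
KA_LAMBDA <- 0.267
KA_K <- 0.041
bitscore <- function(score) (KA_LAMBDA * score - log(KA_K)) / log(2)
evalue <- function(score, m, n) m * n * 2^(-bitscore(score))
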