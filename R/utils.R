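# Shared helpers: seeded RNG plumbing and random sequence construction.

NT <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Derive a reproducible sub-seed
#'
#' All stage- and object-level randomness in the package flows from one
#' top-level seed; sub-seeds are derived deterministically from it and a
#' character tag, and always fit in a 32-bit integer.
#'
#' @param seed Integer top-level seed.
#' @param tag Character tag naming the consumer.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  h <- digest::digest(list(as.integer(seed), as.character(tag)), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Random DNA with a target G+C fraction.
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(NT, n, replace = TRUE, prob = p), collapse = "")
}

# Random ORF: ATG + (n_codons - 2) non-stop codons + stop codon, composed at
# the requested G+C. Length in nt is 3 * n_codons.
random_orf <- function(n_codons, gc = 0.5) {
  stopifnot(n_codons >= 3)
  n_inner <- n_codons - 2L
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  draw <- function(k) {
    cod <- character(k)
    todo <- seq_len(k)
    while (length(todo)) {
      cand <- vapply(todo, function(i) {
        paste(sample(NT, 3, replace = TRUE, prob = p), collapse = "")
      }, character(1))
      ok <- !(cand %in% STOP_CODONS)
      cod[todo[ok]] <- cand[ok]
      todo <- todo[!ok]
    }
    cod
  }
  paste0("ATG", paste(draw(n_inner), collapse = ""),
         sample(STOP_CODONS, 1, prob = c(0.5, 0.25, 0.25)))
}

# codon-table translation (standard code); vastly cheaper than S4 dispatch
# for the per-codon lookups the generator makes
translate_nt <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    n <- nchar(s) - nchar(s) %% 3
    if (n < 3) return("")
    cods <- substring(toupper(s), seq(1, n - 2, 3), seq(3, n, 3))
    aa <- unname(code[cods])
    aa[is.na(aa)] <- "X"
    sub("\\*$", "", paste(aa, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute bases at given 1-based positions with a different base each.
substitute_positions <- function(seq, pos, alphabet = NT) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  }
  paste(ch, collapse = "")
}
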