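# Conflicting island pairs at shared core-flank loci: homology mapping of
# homeoalleles vs iORFans with shuffle-permutation significance, and
# homeocassette classification.

#' Find conflicting island pairs
#'
#' Every unordered pair of islands sharing the same unordered core-flank
#' pair is a conflicting pair. Genomes carrying both islands are reported
#' as mutual-exclusivity violations (not fatal).
#'
#' @param islands Result of [find_islands()].
#' @return Tibble: pair_id, island_a, island_b, flank pair, list-column
#'   `exclusivity_violations`.
#' @export
find_conflicting_pairs <- function(islands) {
  out <- list()
  for (idx in split(seq_len(nrow(islands)), islands$locus)) {
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      out[[length(out) + 1]] <- tibble(
        island_a = islands$island_id[a], island_b = islands$island_id[b],
        flank_left = islands$flank_left[a], flank_right = islands$flank_right[a],
        locus = islands$locus[a],
        exclusivity_violations = list(
          intersect(islands$carriers[[a]], islands$carriers[[b]])))
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble(
    island_a = character(), island_b = character(), flank_left = character(),
    flank_right = character(), locus = character(),
    exclusivity_violations = list())
  dplyr::mutate(res, pair_id = sprintf("CP_%02d", dplyr::row_number()),
                .before = 1)
}

# representative amino-acid sequence per member family of an island: the
# (alphabetically) first carrier occurrence's gene
island_member_seqs <- function(island_row, genes) {
  occ <- island_row$occ[[1]]
  members <- island_row$members[[1]]
  nt <- setNames(rep(NA_character_, length(members)), members)
  for (k in order(occ$genome_id)) {
    sub <- genes |>
      dplyr::filter(.data$genome_id == occ$genome_id[k],
                    .data$contig_id == occ$contig_id[k],
                    .data$index >= occ$start[k], .data$index <= occ$end[k])
    for (j in seq_len(nrow(sub))) {
      f <- sub$family_id[j]
      if (f %in% members && is.na(nt[f]) && !is.na(sub$nt_seq[j])) {
        s <- sub$nt_seq[j]
        if (sub$strand[j] == "-") s <- revcomp(s)
        nt[f] <- s
      }
    }
  }
  nt
}

aa_sub_matrix <- local({
  env <- new.env()
  function() {
    if (is.null(env$BLOSUM62)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
    }
    env$BLOSUM62
  }
})

#' Map homeoalleles, duplications and iORFans across a conflicting pair
#'
#' Every cross-island gene pair is locally aligned on amino acids
#' (BLOSUM62, affine gaps 11/1; nucleotide identity is also recorded when
#' both sequences are available, match/mismatch +2/-3, gaps 5/2).
#' Significance comes from a shuffle-permutation test: the observed score
#' is compared with `n_shuffles` alignments against independent residue
#' shuffles of the second gene, with the pseudocount estimator
#' `perm_p = (1 + #null >= obs) / (1 + n_shuffles)`. A pair is homologous
#' when `perm_p <= max(alpha, 1/(1 + n_shuffles))` (the estimator's
#' attainable floor counts as significant) and the aligned region covers
#' at least half of the shorter gene. Significant hits are resolved
#' greedily by descending score (ties broken lexicographically) into
#' one-to-one homeoalleles; leftover significant hits attached to an
#' already-matched gene become unbalanced duplications; unmatched genes
#' are iORFans.
#'
#' @param pairs Result of [find_conflicting_pairs()].
#' @param islands The island tibble the pairs refer to.
#' @param genes Gene records with `nt_seq`.
#' @param alpha Significance level; default 0.001.
#' @param n_shuffles Number of shuffles; default 200.
#' @param seed Integer seed (shuffles are reproducible).
#' @return `pairs` with list-columns `hits` (all cross-pair alignments),
#'   `homeoalleles`, `duplications`, `iorfans_a`, `iorfans_b`, and member
#'   counts `n_a`, `n_b`.
#' @export
homology_search <- function(pairs, islands, genes, alpha = 0.001,
                            n_shuffles = 200, seed = 1) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    homology_search_one(pairs[i, ], islands, genes, alpha, n_shuffles,
                        derive_seed(seed, pairs$pair_id[i]))
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(res))
}

homology_search_one <- function(pair, islands, genes, alpha, n_shuffles, seed) {
  ia <- islands[islands$island_id == pair$island_a, ]
  ib <- islands[islands$island_id == pair$island_b, ]
  nt_a <- island_member_seqs(ia, genes)
  nt_b <- island_member_seqs(ib, genes)
  mem_a <- names(nt_a); mem_b <- names(nt_b)
  missing <- c(names(nt_a)[is.na(nt_a)], names(nt_b)[is.na(nt_b)])
  if (length(missing)) {
    warn(paste("missing sequences for", paste(missing, collapse = ", "),
               "- treated as non-homologous"))
  }
  aa_a <- ifelse(is.na(nt_a), NA, translate_nt(ifelse(is.na(nt_a), "ATG", nt_a)))
  aa_b <- ifelse(is.na(nt_b), NA, translate_nt(ifelse(is.na(nt_b), "ATG", nt_b)))
  B62 <- aa_sub_matrix()
  ntmat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = TRUE)
  hits <- list()
  with_seed(seed, {
    for (a in mem_a) {
      if (is.na(aa_a[[a]])) next
      sa <- Biostrings::AAString(aa_a[[a]])
      for (b in mem_b) {
        if (is.na(aa_b[[b]])) next
        sb_chr <- aa_b[[b]]
        aln <- Biostrings::pairwiseAlignment(
          sa, Biostrings::AAString(sb_chr), type = "local",
          substitutionMatrix = B62, gapOpening = 11, gapExtension = 1)
        obs <- Biostrings::score(aln)
        short_len <- min(nchar(aa_a[[a]]), nchar(sb_chr))
        span <- if (nchar(aa_a[[a]]) <= nchar(sb_chr)) {
          Biostrings::width(Biostrings::pattern(aln))
        } else Biostrings::width(Biostrings::subject(aln))
        coverage <- span / short_len
        aa_ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
        nt_ident <- NA_real_
        if (!is.na(nt_a[[a]]) && !is.na(nt_b[[b]])) {
          naln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(nt_a[[a]]), Biostrings::DNAString(nt_b[[b]]),
            type = "local", substitutionMatrix = ntmat,
            gapOpening = 5, gapExtension = 2)
          nt_ident <- Biostrings::nmatch(naln) / Biostrings::nchar(naln)
        }
        ch <- strsplit(sb_chr, "")[[1]]
        shuf <- Biostrings::AAStringSet(vapply(seq_len(n_shuffles), function(.)
          paste(sample(ch), collapse = ""), character(1)))
        null_scores <- Biostrings::pairwiseAlignment(
          shuf, sa, type = "local", substitutionMatrix = B62,
          gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
        perm_p <- (1 + sum(null_scores >= obs)) / (1 + n_shuffles)
        hits[[length(hits) + 1]] <- tibble(
          gene_a = a, gene_b = b, aln_score = obs, aa_identity = aa_ident,
          nt_identity = nt_ident, coverage = coverage, perm_p = perm_p)
      }
    }
  })
  hits <- if (length(hits)) dplyr::bind_rows(hits) else tibble(
    gene_a = character(), gene_b = character(), aln_score = double(),
    aa_identity = double(), nt_identity = double(), coverage = double(),
    perm_p = double())
  p_floor <- 1 / (1 + n_shuffles)
  sig <- hits |>
    dplyr::filter(.data$perm_p <= max(alpha, p_floor), .data$coverage >= 0.5) |>
    dplyr::arrange(dplyr::desc(.data$aln_score), .data$gene_a, .data$gene_b)
  matched_a <- character(); matched_b <- character()
  homeo <- list(); dups <- list()
  for (k in seq_len(nrow(sig))) {
    a <- sig$gene_a[k]; b <- sig$gene_b[k]
    if (!(a %in% matched_a) && !(b %in% matched_b)) {
      homeo[[length(homeo) + 1]] <- sig[k, c("gene_a", "gene_b", "aa_identity",
                                             "nt_identity", "perm_p")]
      matched_a <- c(matched_a, a); matched_b <- c(matched_b, b)
    } else if (xor(a %in% matched_a, b %in% matched_b)) {
      # unbalanced duplication: the unmatched endpoint joins as an extra copy
      dups[[length(dups) + 1]] <- sig[k, c("gene_a", "gene_b", "aa_identity",
                                           "nt_identity", "perm_p")]
      matched_a <- union(matched_a, a); matched_b <- union(matched_b, b)
    }
  }
  homeo_tbl <- if (length(homeo)) dplyr::bind_rows(homeo) else
    tibble(gene_a = character(), gene_b = character(), aa_identity = double(),
           nt_identity = double(), perm_p = double())
  dup_tbl <- if (length(dups)) dplyr::bind_rows(dups) else
    tibble(gene_a = character(), gene_b = character(), aa_identity = double(),
           nt_identity = double(), perm_p = double())
  tibble(hits = list(hits), homeoalleles = list(homeo_tbl),
         duplications = list(dup_tbl),
         iorfans_a = list(setdiff(mem_a, matched_a)),
         iorfans_b = list(setdiff(mem_b, matched_b)),
         n_a = length(mem_a), n_b = length(mem_b))
}

#' Classify conflicting pairs as homeocassettes
#'
#' A pair is a homeocassette when, on each island, at least `threshold`
#' (default 50%, inclusive) of the gene content participates in
#' homeoallele or duplication matches; otherwise it is `conflicting_only`.
#'
#' @param pairs Result of [homology_search()].
#' @param threshold Matched fraction required on both islands; default 0.5.
#' @return `pairs` with `matched_frac_a`, `matched_frac_b`,
#'   `n_homeoalleles` and `classification` columns.
#' @export
classify_pair <- function(pairs, threshold = 0.5) {
  stopifnot(all(c("homeoalleles", "duplications") %in% names(pairs)))
  frac <- function(h, d, side, n) {
    genes <- unique(c(h[[side]], d[[side]]))
    if (n == 0) 0 else length(genes) / n
  }
  pairs |>
    dplyr::mutate(
      matched_frac_a = map_dbl(seq_len(dplyr::n()), function(i)
        frac(.data$homeoalleles[[i]], .data$duplications[[i]], "gene_a",
             .data$n_a[i])),
      matched_frac_b = map_dbl(seq_len(dplyr::n()), function(i)
        frac(.data$homeoalleles[[i]], .data$duplications[[i]], "gene_b",
             .data$n_b[i])),
      n_homeoalleles = map_int(.data$homeoalleles, nrow),
      classification = ifelse(.data$matched_frac_a >= threshold &
                                .data$matched_frac_b >= threshold,
                              "homeocassette", "conflicting_only"))
}

#' Write the pair report and homeoallele map as TSV
#'
#' @param pairs Result of [classify_pair()].
#' @param path Output file for the pair summary.
#' @param map_path Optional output file for the per-gene homeoallele map.
#' @export
write_pair_report <- function(pairs, path, map_path = NULL) {
  flat <- pairs |>
    dplyr::mutate(
      orfs = paste(.data$n_a, "vs", .data$n_b),
      exclusivity_violations = map_chr(.data$exclusivity_violations,
                                       paste, collapse = ","),
      iorfans_a = map_chr(.data$iorfans_a, paste, collapse = ","),
      iorfans_b = map_chr(.data$iorfans_b, paste, collapse = ",")) |>
    dplyr::select(dplyr::any_of(c("pair_id", "island_a", "island_b",
                                  "flank_left", "flank_right", "orfs",
                                  "n_homeoalleles", "matched_frac_a",
                                  "matched_frac_b", "classification",
                                  "exclusivity_violations", "iorfans_a",
                                  "iorfans_b")))
  readr::write_tsv(flat, path)
  if (!is.null(map_path)) {
    map <- pairs |>
      dplyr::select("pair_id", "homeoalleles") |>
      tidyr::unnest("homeoalleles")
    readr::write_tsv(map, map_path)
  }
  invisible(path)
}
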