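# Total average nucleotide identity (tANI) distances and phylogeny:
# fragment-based ANI + alignment fraction, -ln(ANI x AF) distance,
# fragment-resampling bootstrap, neighbor-joining tree.

#' tANI distance from ANI and alignment fraction
#'
#' `-ln(ANI x AF)`. At AF = 1, a distance of 0.315 corresponds to an ANI
#' of 73%, the conventional species boundary for this distance.
#'
#' @param ani,af Fractions in (0, 1]. Vectorized.
#' @param cap Value substituted (with a warning) when `ani * af` is 0 or
#'   undefined; default 10.
#' @return Numeric distances.
#' @export
tani_distance <- function(ani, af, cap = 10) {
  bad <- !is.finite(ani * af) | ani * af <= 0
  out <- ifelse(bad, cap, -log(ani * af))
  if (any(bad)) warn("undefined ANI*AF: distance capped")
  out
}

#' Invert the tANI distance
#'
#' The ANI implied by a tANI distance at a given alignment fraction:
#' `exp(-d) / af`.
#'
#' @param d tANI distance.
#' @param af Alignment fraction; default 1.
#' @return ANI fraction.
#' @export
tani_ani_at <- function(d, af = 1) exp(-d) / af

# ---- fragment ANI ----------------------------------------------------------

# Cut a (possibly multi-contig) genome into consecutive windows.
genome_fragments <- function(seqs, fragment_len, min_tail = 100L) {
  seqs <- as.character(seqs)
  frags <- character(0)
  for (s in seqs) {
    L <- nchar(s)
    starts <- seq(1L, L, by = fragment_len)
    for (st in starts) {
      en <- min(st + fragment_len - 1L, L)
      if (en - st + 1L >= min_tail || st == 1L) {
        frags <- c(frags, substr(s, st, en))
      }
    }
  }
  frags
}

# Best local hit of one fragment against a subject: exact k-mer seeds at a
# few offsets locate candidate windows; the fragment is aligned locally to
# each window and the best-scoring hit retained.
frag_best_hit <- function(frag, subject_fwd, subject_rev, k = 14L, pad = 40L,
                          submat, max_hits_per_seed = 4L) {
  L <- nchar(frag)
  if (L < k) return(NULL)
  # seeds every ~80 nt: at 5% per-site divergence the chance that every
  # seed misses an exact match is ~1e-4 per fragment
  offs <- unique(pmin(seq(1L, max(1L, L - k + 1L),
                          by = max(80L, k)), L - k + 1L))
  cands <- list()
  # try seed offsets in turn and keep the first offset that hits at all:
  # nearly always the first seed on related genomes, so one exact search
  # per fragment in the common case
  for (o in offs) {
    seed <- substr(frag, o, o + k - 1L)
    for (dir in c("fwd", "rev")) {
      subj <- if (dir == "fwd") subject_fwd else subject_rev
      st <- Biostrings::start(Biostrings::matchPattern(seed, subj))
      if (length(st) > max_hits_per_seed) st <- st[seq_len(max_hits_per_seed)]
      for (p in st) {
        diag <- p - (o - 1L)
        cands[[length(cands) + 1]] <- list(dir = dir, diag = diag,
                                           ws = max(1L, diag - pad))
      }
    }
    if (length(cands)) break
  }
  if (!length(cands)) return(NULL)
  cands <- unique(cands)
  # fast path: ungapped comparison on the seeded diagonal; exact whenever
  # the two genomes differ by substitutions only, gapped fallback otherwise
  fr_chars <- strsplit(frag, "")[[1]]
  best_ug <- NULL
  for (cd in cands) {
    subj <- if (cd$dir == "fwd") subject_fwd else subject_rev
    p0 <- cd$diag
    if (p0 < 1 || p0 + L - 1L > length(subj)) next
    win <- strsplit(as.character(Biostrings::subseq(subj, p0, p0 + L - 1L)),
                    "")[[1]]
    ident <- mean(fr_chars == win)
    if (is.null(best_ug) || ident > best_ug$identity) {
      best_ug <- list(score = NA_real_, identity = ident, aligned = L)
    }
  }
  if (!is.null(best_ug) && best_ug$identity >= 0.9) return(best_ug)
  best <- NULL
  fr <- Biostrings::DNAString(frag)
  for (cd in cands) {
    subj <- if (cd$dir == "fwd") subject_fwd else subject_rev
    we <- min(length(subj), cd$ws + L + 2L * pad)
    win <- Biostrings::subseq(subj, cd$ws, we)
    aln <- Biostrings::pairwiseAlignment(fr, win, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      best <- list(score = sc,
                   identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln),
                   aligned = Biostrings::width(Biostrings::pattern(aln)))
    }
  }
  best
}

# One direction of the fragment ANI computation: returns per-fragment stats
# so bootstrap replicates can resample without realigning.
ani_direction <- function(query, subject, fragment_len, min_identity,
                          min_coverage) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = TRUE)
  frags <- genome_fragments(query, fragment_len)
  subject_fwd <- Biostrings::DNAString(paste(as.character(subject), collapse = ""))
  subject_rev <- Biostrings::reverseComplement(subject_fwd)
  res <- lapply(frags, function(fr) {
    hit <- frag_best_hit(fr, subject_fwd, subject_rev, submat = submat)
    len <- nchar(fr)
    if (is.null(hit) || hit$identity < min_identity ||
        hit$aligned / len < min_coverage) {
      tibble(frag_len = len, retained = FALSE, identity = NA_real_,
             aligned = 0L)
    } else {
      tibble(frag_len = len, retained = TRUE, identity = hit$identity,
             aligned = hit$aligned)
    }
  })
  dplyr::bind_rows(res)
}

ani_from_frags <- function(ft, idx = seq_len(nrow(ft))) {
  ft <- ft[idx, ]
  ret <- ft[ft$retained, ]
  list(ani = if (nrow(ret)) mean(ret$identity) else NA_real_,
       af = sum(ret$aligned) / sum(ft$frag_len),
       n_fragments = nrow(ft), retained = nrow(ret))
}

#' Pairwise ANI and alignment fraction
#'
#' The query is cut into consecutive `fragment_len` windows; each fragment
#' is aligned locally to the subject (exact k-mer seeding, both strands).
#' Hits with identity >= `min_identity` covering >= `min_coverage` of the
#' fragment are retained; ANI is the mean identity of retained hits and AF
#' the retained aligned length over the fragmented query length. The
#' result is symmetrized by averaging the two directions.
#'
#' @param query,subject Genome sequences: character vectors (one element
#'   per contig) or `DNAStringSet`.
#' @param fragment_len Fragment window, nt; default 1020.
#' @param min_identity,min_coverage Retention cutoffs; default 0.7 / 0.7.
#' @return A list of class `ani_result`: `ani`, `af`, `n_fragments`,
#'   `retained`, `flagged` (no retained hits in either direction).
#' @export
compute_ani_af <- function(query, subject, fragment_len = 1020,
                           min_identity = 0.7, min_coverage = 0.7) {
  d1 <- ani_direction(query, subject, fragment_len, min_identity, min_coverage)
  d2 <- ani_direction(subject, query, fragment_len, min_identity, min_coverage)
  s1 <- ani_from_frags(d1); s2 <- ani_from_frags(d2)
  flagged <- s1$retained == 0 || s2$retained == 0
  structure(list(ani = mean(c(s1$ani, s2$ani)), af = mean(c(s1$af, s2$af)),
                 n_fragments = s1$n_fragments + s2$n_fragments,
                 retained = s1$retained + s2$retained, flagged = flagged,
                 directions = list(d1, d2)),
            class = "ani_result")
}

#' tANI distance matrix for a set of genomes
#'
#' @param genomes Named list of genome sequences (each a character vector
#'   of contigs or a `DNAStringSet`).
#' @param fragment_len,min_identity,min_coverage See [compute_ani_af()].
#' @param cap Distance cap for undefined pairs.
#' @return A symmetric matrix of tANI distances with zero diagonal;
#'   attribute `flagged` marks capped pairs, attribute `frag_cache` holds
#'   per-direction fragment statistics for bootstrap resampling.
#' @export
tani_matrix <- function(genomes, fragment_len = 1020, min_identity = 0.7,
                        min_coverage = 0.7, cap = 10) {
  n <- length(genomes)
  ids <- names(genomes)
  stopifnot(!is.null(ids), n >= 2)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  flagged <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  cache <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- compute_ani_af(genomes[[i]], genomes[[j]], fragment_len,
                          min_identity, min_coverage)
      d[i, j] <- d[j, i] <- suppressWarnings(
        tani_distance(r$ani, r$af, cap = cap))
      flagged[i, j] <- flagged[j, i] <- r$flagged
      cache[[paste(ids[i], ids[j], sep = "\r")]] <- r$directions
    }
  }
  structure(d, flagged = flagged, frag_cache = cache, cap = cap)
}

#' Neighbor-joining tree from a tANI distance matrix
#'
#' @param dist Square distance matrix (e.g. from [tani_matrix()]).
#' @return An unrooted `phylo` tree with tANI branch lengths.
#' @export
build_tree <- function(dist) {
  if (nrow(dist) < 3) abort("need at least 3 taxa", class = "panisles_input_error")
  if (all(dist == 0)) {
    # degenerate all-zero matrix: star tree with zero branch lengths
    n <- nrow(dist)
    tr <- ape::read.tree(text = paste0("(", paste(rownames(dist),
                                                  collapse = ","), ");"))
    tr$edge.length <- rep(0, nrow(tr$edge))
    return(tr)
  }
  tr <- ape::nj(as.dist(dist))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Fragment-resampling bootstrap supports for a tANI tree
#'
#' Each replicate resamples every query's fragments with replacement
#' (reusing the cached per-fragment alignment statistics), recomputes the
#' ANI/AF matrix and the NJ tree; supports are bipartition frequencies
#' (x100) on the internal edges of the main tree.
#'
#' @param dist Result of [tani_matrix()] (carries the fragment cache).
#' @param n_reps Bootstrap replicates; default 100.
#' @param seed Integer seed.
#' @return A list of class `tani_phylo`: `tree` (main NJ tree), `supports`
#'   (per internal node, 0-100), `dist`, `n_reps`.
#' @export
bootstrap_supports <- function(dist, n_reps = 100, seed = 1) {
  cache <- attr(dist, "frag_cache")
  cap <- attr(dist, "cap") %||% 10
  if (is.null(cache)) abort("distance matrix lacks a fragment cache",
                            class = "panisles_input_error")
  ids <- rownames(dist)
  main <- build_tree(dist)
  boots <- with_seed(derive_seed(seed, "tani-boot"), {
    lapply(seq_len(n_reps), function(rep) {
      # one fragment resampling per query genome per replicate
      idx_of <- lapply(ids, function(g) NULL)
      names(idx_of) <- ids
      d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
      for (g in ids) {
        n_frag <- NULL
        for (key in names(cache)) {
          parts <- strsplit(key, "\r")[[1]]
          if (parts[1] == g) n_frag <- nrow(cache[[key]][[1]])
          if (parts[2] == g) n_frag <- nrow(cache[[key]][[2]])
          if (!is.null(n_frag)) break
        }
        idx_of[[g]] <- sample.int(n_frag, n_frag, replace = TRUE)
      }
      for (i in seq_along(ids)[-length(ids)]) {
        for (j in (i + 1):length(ids)) {
          dirs <- cache[[paste(ids[i], ids[j], sep = "\r")]]
          s1 <- ani_from_frags(dirs[[1]], idx_of[[ids[i]]])
          s2 <- ani_from_frags(dirs[[2]], idx_of[[ids[j]]])
          d[i, j] <- d[j, i] <- suppressWarnings(tani_distance(
            mean(c(s1$ani, s2$ani)), mean(c(s1$af, s2$af)), cap = cap))
        }
      }
      build_tree(d)
    })
  })
  pc <- ape::prop.clades(main, boots, rooted = FALSE)
  pc[is.na(pc)] <- 0
  structure(list(tree = main, supports = round(100 * pc / n_reps),
                 dist = dist, n_reps = n_reps),
            class = "tani_phylo")
}

#' @export
print.tani_phylo <- function(x, ...) {
  cat("tANI phylogeny:", length(x$tree$tip.label), "genomes,",
      x$n_reps, "bootstrap replicates; internal-edge supports:",
      paste(x$supports, collapse = " "), "\n")
  invisible(x)
}

#' Tidy pairwise tANI distances
#'
#' @param x A `tani_phylo`.
#' @param ... Unused.
#' @return Tibble: genome_a, genome_b, tani.
#' @method tidy tani_phylo
#' @export
tidy.tani_phylo <- function(x, ...) {
  d <- x$dist
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble(genome_a = rownames(d)[idx[, 1]], genome_b = colnames(d)[idx[, 2]],
         tani = d[idx])
}

#' @rdname tidy.tani_phylo
#' @method glance tani_phylo
#' @export
glance.tani_phylo <- function(x, ...) {
  tibble(n_genomes = length(x$tree$tip.label), n_reps = x$n_reps,
         min_support = min(x$supports), mean_dist = mean(x$dist[upper.tri(x$dist)]),
         max_dist = max(x$dist))
}

#' Write a tree as Newick with support labels
#'
#' @param phylo A `tani_phylo` or `phylo`.
#' @param path Output file.
#' @export
write_tree_newick <- function(phylo, path) {
  tr <- if (inherits(phylo, "tani_phylo")) {
    t2 <- phylo$tree
    t2$node.label <- as.character(phylo$supports)
    t2
  } else phylo
  ape::write.tree(tr, path)
  invisible(path)
}

#' Write a distance matrix as square TSV
#'
#' @param dist Square matrix.
#' @param path Output file.
#' @export
write_dist_tsv <- function(dist, path) {
  df <- as.data.frame(unclass(dist)[seq_len(nrow(dist)), , drop = FALSE])
  readr::write_tsv(dplyr::bind_cols(tibble(genome_id = rownames(dist)),
                                    as_tibble(df)), path)
  invisible(path)
}
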