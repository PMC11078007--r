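# Neutral-core population structure: Tajima's D per core gene, SNP matrix
# from concatenated neutral genes, nested population clustering.

#' Tajima's D for one core-gene alignment
#'
#' The standard 1989 statistic: with `n` sequences, `S` segregating sites
#' and mean pairwise difference `pi` (computed after removing columns
#' containing gaps or N), `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with
#' the canonical coefficients `a1, a2, b1, b2, c1, c2, e1, e2`. A family
#' is flagged neutral when `|D| < 0.2` (strict); `D` is undefined when
#' `S = 0`.
#'
#' @param aln Named character vector (or `DNAStringSet`) of equal-length
#'   aligned sequences; at least 4.
#' @param family_id Optional label carried through to the result.
#' @return A one-row tibble: family_id, n, S, pi, D, neutral.
#' @export
tajimas_d <- function(aln, family_id = NA_character_) {
  aln <- as.character(aln)
  n <- length(aln)
  if (n < 4) abort("Tajima's D needs at least 4 sequences",
                   class = "panisles_input_error")
  if (length(unique(nchar(aln))) != 1) {
    abort("aligned sequences must have equal length",
          class = "panisles_input_error")
  }
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  poly <- apply(m, 2, function(col) length(unique(col)) > 1)
  S <- sum(poly)
  if (S == 0) {
    return(tibble(family_id = family_id, n = n, S = 0L, pi = 0,
                  D = NA_real_, neutral = FALSE))
  }
  mp <- m[, poly, drop = FALSE]
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diffs <- diffs + sum(mp[i, ] != mp[j, ])
  }
  pi <- diffs / (n * (n - 1) / 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  tibble(family_id = family_id, n = n, S = as.integer(S), pi = pi, D = D,
         neutral = is.finite(D) && abs(D) < 0.2)
}

#' Tajima's D table for a set of core-gene alignments
#'
#' @param alignments Named list of alignments (each as in [tajimas_d()]).
#'   Families with fewer than 4 present sequences are skipped with a
#'   warning.
#' @return Tibble with one row per family.
#' @export
tajima_table <- function(alignments) {
  rows <- lapply(names(alignments), function(f) {
    a <- alignments[[f]]
    if (length(a) < 4) {
      warn(paste("family", f, "has <4 sequences; skipped"))
      return(NULL)
    }
    tajimas_d(a, family_id = f)
  })
  dplyr::bind_rows(rows)
}

#' SNP matrix from concatenated neutral core genes
#'
#' Neutral alignments are concatenated; only polymorphic columns (at least
#' two distinct non-N states) are kept. Genomes missing a family
#' contribute `N` for its columns.
#'
#' @param alignments Named list of named alignments (names = genome ids).
#' @param genomes All genome ids (rows of the matrix); default: union of
#'   names seen.
#' @return A character matrix (genomes x variable sites) of class
#'   `snp_matrix`; attribute `site_family` maps columns to families. A
#'   zero-column matrix is returned with a warning when nothing is
#'   polymorphic.
#' @export
build_snp_matrix <- function(alignments, genomes = NULL) {
  stopifnot(length(alignments) >= 1)
  genomes <- genomes %||% sort(unique(unlist(lapply(alignments, names))))
  cols <- list(); fams <- character()
  for (f in names(alignments)) {
    a <- toupper(as.character(alignments[[f]]))
    L <- unique(nchar(a))
    stopifnot(length(L) == 1)
    m <- matrix("N", length(genomes), L, dimnames = list(genomes, NULL))
    present <- intersect(genomes, names(alignments[[f]]))
    m[present, ] <- do.call(rbind, strsplit(a[match(present, names(alignments[[f]]))], ""))
    poly <- apply(m, 2, function(col) {
      st <- unique(col[col %in% c("A", "C", "G", "T")])
      length(st) >= 2
    })
    if (any(poly)) {
      cols[[length(cols) + 1]] <- m[, poly, drop = FALSE]
      fams <- c(fams, rep(f, sum(poly)))
    }
  }
  if (!length(cols)) {
    warn("no polymorphic columns: empty SNP matrix")
    out <- matrix(character(), nrow = length(genomes), ncol = 0,
                  dimnames = list(genomes, NULL))
  } else {
    out <- do.call(cbind, cols)
  }
  structure(out, site_family = fams, class = c("snp_matrix", class(out)))
}

#' N-aware pairwise SNP distances
#'
#' Proportion of differing sites among columns where both genomes have a
#' called base (non-N); `NA` columns are excluded from the denominator.
#'
#' @param snp A `snp_matrix`.
#' @return Symmetric numeric matrix of distances.
#' @export
snp_dist <- function(snp) {
  g <- rownames(snp)
  n <- length(g)
  d <- matrix(0, n, n, dimnames = list(g, g))
  called <- snp %in% c("A", "C", "G", "T")
  dim(called) <- dim(snp)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      ok <- called[i, ] & called[j, ]
      d[i, j] <- d[j, i] <- if (any(ok)) {
        sum(snp[i, ok] != snp[j, ok]) / sum(ok)
      } else 0
    }
  }
  d
}

# mean silhouette width from a distance matrix and integer labels
mean_silhouette <- function(d, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

cluster_once <- function(d, kmax = 10) {
  n <- nrow(d)
  if (n < 3 || max(d) == 0) return(rep(1L, n))
  hc <- hclust(as.dist(d), method = "average")
  ks <- 2:min(kmax, n - 1)
  sil <- vapply(ks, function(k) mean_silhouette(d, cutree(hc, k)), numeric(1))
  cutree(hc, ks[which.max(sil)])
}

#' Assign genomes to nested populations from a SNP matrix
#'
#' Level 1: agglomerative (average-linkage) clustering on N-aware SNP
#' Hamming distances, with the cut chosen by maximum mean silhouette over
#' k in 2..10. Each level-1 cluster is re-clustered the same way for level
#' 2 (clusters of fewer than 3 genomes, or with all-zero internal
#' distances, stay whole). Level-2 labels refine level-1 labels by
#' construction. This silhouette-guided stand-in approximates
#' model-based nested clustering (rhierBAPS-style) without its Bayesian
#' machinery.
#'
#' @param snp A `snp_matrix`.
#' @param max_levels Nesting depth (1 or 2); default 2.
#' @param seed Unused by the deterministic procedure; kept for interface
#'   stability.
#' @return Tibble: genome_id, level1, level2 (class
#'   `population_assignment`).
#' @export
cluster_populations <- function(snp, max_levels = 2, seed = 1) {
  g <- rownames(snp)
  if (length(g) < 3 || ncol(snp) == 0) {
    out <- tibble(genome_id = g, level1 = "P1", level2 = "P1.1")
    class(out) <- c("population_assignment", class(out))
    return(out)
  }
  d <- snp_dist(snp)
  lv1_int <- cluster_once(d)
  lv1 <- paste0("P", lv1_int)
  lv2 <- lv1
  if (max_levels >= 2) {
    for (cl in unique(lv1_int)) {
      idx <- which(lv1_int == cl)
      sub <- cluster_once(d[idx, idx, drop = FALSE])
      lv2[idx] <- paste0("P", cl, ".", sub)
    }
  }
  out <- tibble(genome_id = g, level1 = lv1, level2 = lv2)
  class(out) <- c("population_assignment", class(out))
  out
}

#' Write the Tajima table, SNP matrix or population assignment as TSV
#'
#' @param x Object to write.
#' @param path Output file.
#' @export
write_snp_tsv <- function(x, path) {
  if (inherits(x, "snp_matrix")) {
    x <- dplyr::bind_cols(tibble(genome_id = rownames(x)),
                          as_tibble(unclass(x), .name_repair = "minimal") |>
                            setNames(paste0("site_", seq_len(ncol(x)))))
  }
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
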