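# Genomic island discovery: maximal runs of non-core families bounded by
# core genes, grouped and merged per core-flank locus, then annotated with
# mobilome neighborhood, G+C, and cross-carrier identity.

#' G+C content of nucleotide sequences
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` is excluded from both numerator
#' and denominator. Vectorized.
#'
#' @param seq Character vector of sequences over `A,C,G,T,N`.
#' @return Numeric vector of fractions; `NA` (with a warning) for all-`N`
#'   sequences.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq)) || any(is.na(seq))) {
    abort("empty sequence in gc_content", class = "panisles_input_error")
  }
  up <- toupper(seq)
  cnt <- function(p) vapply(gregexpr(p, up), function(m)
    sum(m > 0), integer(1))
  gcn <- cnt("[GC]")
  acgt <- cnt("[ACGT]")
  out <- ifelse(acgt == 0, NA_real_, gcn / acgt)
  if (anyNA(out)) warn("all-N sequence: G+C undefined")
  out
}

#' Find genomic islands in a classified pan-genome
#'
#' Scans every genome contig for maximal runs of non-core families bounded
#' on both sides by core families, groups the runs by their unordered
#' core-flank pair (the locus), and merges occurrences within a locus:
#' identical, reverse-ordered or subset member sets collapse into one
#' island (subsets contribute `partial_carriers`); member sets with
#' Jaccard similarity below 0.5 against every island at the locus found a
#' new island; intermediate cases merge into the closest island and flag
#' it `merged_variants`. Loci accumulating more than
#' `max_variants_per_locus` islands are discarded and reported. Islands
#' shorter than `min_len` are kept only when their locus hosts at least
#' two islands. Runs truncated by a contig end (one flank missing) are
#' skipped and counted.
#'
#' @param graph A `pan_graph` (provides divisions and the core threshold).
#' @param genes Tibble of ordered gene records (same families as `graph`).
#' @param min_len Minimum island length (genes); default 2.
#' @param max_len Maximum run length considered; default 40.
#' @param max_variants_per_locus Maximum merged islands per locus before
#'   the locus is discarded as too multifurcated; default 3.
#' @return A tibble of islands (one row each) with list-columns `members`,
#'   `carriers`, `partial_carriers` and `occ` (per-carrier occurrence
#'   coordinates), plus `gc` and `identical_flag` when sequences are
#'   available. Attributes `discarded` (tibble) and `skipped_contig_end`
#'   (count) carry the report.
#' @export
find_islands <- function(graph, genes, min_len = 2, max_len = 40,
                         max_variants_per_locus = 3) {
  stopifnot(inherits(graph, "pan_graph"))
  division <- setNames(graph$nodes$division, graph$nodes$family_id)
  genes <- dplyr::arrange(genes, .data$genome_id, .data$contig_id, .data$index)
  # occurrence accumulators (plain vectors: this loop runs over every
  # accessory run in every genome, so per-row tibble allocation is avoided)
  o_genome <- character(); o_contig <- character()
  o_fa <- character(); o_fb <- character()
  o_fl <- character(); o_fr <- character()
  o_start <- integer(); o_end <- integer(); o_leftfirst <- logical()
  o_members <- list()
  skipped <- 0L
  tl_locus <- character(); tl_genome <- character(); tl_n <- integer()
  for (key in split(seq_len(nrow(genes)),
                    paste(genes$genome_id, genes$contig_id, sep = "\r"))) {
    fam <- genes$family_id[key]
    g <- genes$genome_id[key[1]]
    ctg <- genes$contig_id[key[1]]
    is_core <- division[fam] == "core"
    r <- rle(is_core)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k]) next
      s <- starts[k]; e <- ends[k]
      if (s == 1 || e == length(fam)) { skipped <- skipped + 1L; next }
      fl <- fam[s - 1]; fr <- fam[e + 1]
      if (e - s + 1 > max_len) {
        tl_locus <- c(tl_locus, paste(sort(c(fl, fr)), collapse = "|"))
        tl_genome <- c(tl_genome, g)
        tl_n <- c(tl_n, e - s + 1L)
        next
      }
      left_first <- fl <= fr
      mem <- fam[s:e]
      i <- length(o_genome) + 1L
      o_genome[i] <- g; o_contig[i] <- ctg
      o_fa[i] <- min(fl, fr); o_fb[i] <- max(fl, fr)
      o_fl[i] <- fl; o_fr[i] <- fr
      o_start[i] <- genes$index[key[s]]; o_end[i] <- genes$index[key[e]]
      o_leftfirst[i] <- left_first
      o_members[[i]] <- if (left_first) mem else rev(mem)
    }
  }
  discarded <- tibble(locus = tl_locus, reason = rep("run_too_long",
                                                     length(tl_locus)),
                      genome_id = tl_genome, n_genes = tl_n)
  empty <- tibble(island_id = character(), flank_left = character(),
                  flank_right = character(), locus = character(),
                  members = list(), length = integer(), carriers = list(),
                  n_carriers = integer(), partial_carriers = list(),
                  merged_variants = logical(), gc = double(),
                  identical_flag = logical(), occ = list())
  if (!length(o_genome)) {
    return(structure(empty, discarded = discarded,
                     skipped_contig_end = skipped, class = class(empty)))
  }
  ord <- order(o_fa, o_fb, o_genome, o_contig, o_start)
  occs <- tibble(genome_id = o_genome[ord], contig_id = o_contig[ord],
                 flank_a = o_fa[ord], flank_b = o_fb[ord],
                 flank_left = o_fl[ord], flank_right = o_fr[ord],
                 members = o_members[ord], start = o_start[ord],
                 end = o_end[ord], left_first = o_leftfirst[ord])

  islands <- list()
  for (idx in split(seq_len(nrow(occs)),
                    paste(occs$flank_a, occs$flank_b, sep = "|"))) {
    locus_islands <- list()
    for (i in idx) {
      mem <- occs$members[[i]]
      placed <- FALSE
      best_j <- 0L; best_jac <- 0
      for (j in seq_along(locus_islands)) {
        isl <- locus_islands[[j]]
        jac <- length(intersect(mem, isl$members)) /
          length(union(mem, isl$members))
        if (identical(mem, isl$members) || identical(rev(mem), isl$members) ||
            setequal(mem, isl$members)) {
          isl$carriers <- union(isl$carriers, occs$genome_id[i])
          isl$occ <- c(isl$occ, i)
          locus_islands[[j]] <- isl; placed <- TRUE; break
        }
        if (all(mem %in% isl$members) && length(mem) < length(isl$members)) {
          isl$partial_carriers <- union(isl$partial_carriers, occs$genome_id[i])
          isl$occ <- c(isl$occ, i)
          locus_islands[[j]] <- isl; placed <- TRUE; break
        }
        if (all(isl$members %in% mem) && length(mem) > length(isl$members)) {
          isl$partial_carriers <- union(isl$partial_carriers, isl$carriers)
          isl$carriers <- occs$genome_id[i]
          isl$members <- mem
          isl$occ <- c(isl$occ, i)
          locus_islands[[j]] <- isl; placed <- TRUE; break
        }
        if (jac > best_jac) { best_jac <- jac; best_j <- j }
      }
      if (!placed) {
        if (best_jac >= 0.5) {
          isl <- locus_islands[[best_j]]
          isl$carriers <- union(isl$carriers, occs$genome_id[i])
          isl$members <- c(isl$members, setdiff(mem, isl$members))
          isl$merged_variants <- TRUE
          isl$occ <- c(isl$occ, i)
          locus_islands[[best_j]] <- isl
        } else {
          locus_islands[[length(locus_islands) + 1]] <- list(
            flank_left = occs$flank_left[i], flank_right = occs$flank_right[i],
            locus = paste(occs$flank_a[i], occs$flank_b[i], sep = "|"),
            members = mem, carriers = occs$genome_id[i],
            partial_carriers = character(), merged_variants = FALSE,
            occ = i)
        }
      }
    }
    if (length(locus_islands) > max_variants_per_locus) {
      discarded <- dplyr::bind_rows(discarded, tibble(
        locus = locus_islands[[1]]$locus, reason = "too_many_variants",
        genome_id = NA_character_,
        n_genes = sum(lengths(lapply(locus_islands, `[[`, "members")))))
      next
    }
    keep_short <- length(locus_islands) >= 2
    for (isl in locus_islands) {
      if (length(isl$members) < min_len && !keep_short) {
        discarded <- dplyr::bind_rows(discarded, tibble(
          locus = isl$locus, reason = "below_min_len",
          genome_id = NA_character_, n_genes = length(isl$members)))
        next
      }
      islands[[length(islands) + 1]] <- isl
    }
  }
  if (!length(islands)) {
    return(structure(empty, discarded = discarded,
                     skipped_contig_end = skipped, class = class(empty)))
  }
  out <- dplyr::bind_rows(lapply(islands, function(isl) tibble(
    flank_left = isl$flank_left, flank_right = isl$flank_right,
    locus = isl$locus, members = list(isl$members),
    length = length(isl$members), carriers = list(sort(isl$carriers)),
    n_carriers = length(isl$carriers),
    partial_carriers = list(sort(isl$partial_carriers)),
    merged_variants = isl$merged_variants,
    occ = list(occs[isl$occ, ])))) |>
    dplyr::arrange(.data$locus, dplyr::desc(.data$length)) |>
    dplyr::mutate(island_id = sprintf("GI_%03d", dplyr::row_number()),
                  .before = 1)
  seqs <- island_carrier_seqs(out, genes)
  if (nrow(seqs)) {
    gc_tbl <- seqs |>
      dplyr::group_by(.data$island_id) |>
      dplyr::summarise(gc = mean(gc_content(.data$seq)), .groups = "drop")
    out <- dplyr::left_join(out, gc_tbl, by = "island_id")
  } else out$gc <- NA_real_
  out <- find_identical_islands(out, genes, .seqs = seqs)
  structure(out, discarded = discarded, skipped_contig_end = skipped,
            class = class(out))
}

#' Report of loci discarded or skipped during island discovery
#'
#' @param islands Result of [find_islands()].
#' @return Tibble with columns locus, reason, genome_id, n_genes; the
#'   count of contig-end truncated runs is in attribute
#'   `skipped_contig_end` of the islands tibble.
#' @export
islands_report <- function(islands) attr(islands, "discarded")

# Concatenated member-gene sequence per island carrier, in genome order.
island_carrier_seqs <- function(islands, genes) {
  if (!nrow(islands) || !"nt_seq" %in% names(genes) || all(is.na(genes$nt_seq))) {
    return(tibble(island_id = character(), genome_id = character(),
                  seq = character()))
  }
  rows <- list()
  for (i in seq_len(nrow(islands))) {
    occ <- islands$occ[[i]]
    for (k in seq_len(nrow(occ))) {
      sub <- genes |>
        dplyr::filter(.data$genome_id == occ$genome_id[k],
                      .data$contig_id == occ$contig_id[k],
                      .data$index >= occ$start[k], .data$index <= occ$end[k]) |>
        dplyr::arrange(.data$index)
      if (anyNA(sub$nt_seq)) next
      rows[[length(rows) + 1]] <- tibble(
        island_id = islands$island_id[i], genome_id = occ$genome_id[k],
        seq = paste(sub$nt_seq, collapse = ""))
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble(island_id = character(), genome_id = character(), seq = character())
}

#' Flag islands whose sequence is identical across carriers
#'
#' Carrier sequences are the concatenated member genes of each occurrence;
#' orientation is normalized by comparing each sequence's canonical form
#' (the lexicographic minimum of the sequence and its reverse complement),
#' so a reverse-complemented occurrence still counts as identical.
#'
#' @param islands Result of [find_islands()].
#' @param genes Gene records with `nt_seq`.
#' @param .seqs Internal: precomputed carrier sequences.
#' @return `islands` with `identical_flag` set (`NA` where fewer than two
#'   carriers have sequence).
#' @export
find_identical_islands <- function(islands, genes, .seqs = NULL) {
  seqs <- .seqs %||% island_carrier_seqs(islands, genes)
  flag <- rep(NA, nrow(islands))
  if (nrow(seqs)) {
    canon <- function(s) pmin(s, revcomp(s))
    for (i in seq_len(nrow(islands))) {
      s <- seqs$seq[seqs$island_id == islands$island_id[i]]
      if (length(s) >= 2) flag[i] <- length(unique(canon(s))) == 1
    }
  }
  islands$identical_flag <- flag
  islands
}

#' Scan the genomic neighborhood of islands for mobilome elements
#'
#' For each carrier occurrence, genes at offsets 1..`radius` beyond each
#' flanking core gene are checked against transposase / integrase / tRNA
#' annotation vocabularies. Genes belonging to the island itself are never
#' counted (the scan is strictly outside the flanks, and island-member
#' families reappearing in the window are skipped).
#'
#' @param islands Result of [find_islands()].
#' @param genes Ordered gene records with `annotation`.
#' @param radius Neighborhood radius in genes; default 5.
#' @return Tibble: island_id, genome_id, element, offset (signed; negative
#'   = upstream of the left flank), family_id.
#' @export
neighborhood_scan <- function(islands, genes, radius = 5) {
  genes <- dplyr::arrange(genes, .data$genome_id, .data$contig_id, .data$index)
  key <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  by_ctg <- split(seq_len(nrow(genes)), key)
  out <- list()
  for (i in seq_len(nrow(islands))) {
    occ <- islands$occ[[i]]
    members <- islands$members[[i]]
    if (is.null(occ) || !nrow(occ)) {
      warn(paste("island", islands$island_id[i],
                 "has no located occurrence; neighborhood flags empty"))
      next
    }
    for (k in seq_len(nrow(occ))) {
      rows <- by_ctg[[paste(occ$genome_id[k], occ$contig_id[k], sep = "\r")]]
      if (is.null(rows)) next
      idxs <- genes$index[rows]
      flank_l_pos <- which(idxs == occ$start[k]) - 1L
      flank_r_pos <- which(idxs == occ$end[k]) + 1L
      scan_one <- function(pos, offset) {
        if (pos < 1 || pos > length(rows)) return(NULL)
        r <- rows[pos]
        fam <- genes$family_id[r]
        if (fam %in% members) return(NULL)
        ann <- genes$annotation[r] %||% ""
        if (is.na(ann)) return(NULL)
        el <- if (grepl("transposase|insertion sequence|\\bIS[0-9]",
                        ann, ignore.case = TRUE)) "transposase"
        else if (grepl("integrase|recombinase", ann, ignore.case = TRUE)) "integrase"
        else if (grepl("tRNA", ann, ignore.case = TRUE)) "tRNA"
        else return(NULL)
        tibble(island_id = islands$island_id[i], genome_id = occ$genome_id[k],
               element = el, offset = offset, family_id = fam)
      }
      for (o in seq_len(radius)) {
        out[[length(out) + 1]] <- scan_one(flank_l_pos - o, -o)
        out[[length(out) + 1]] <- scan_one(flank_r_pos + o, o)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(island_id = character(), genome_id = character(),
                  element = character(), offset = integer(),
                  family_id = character())
  }
  dplyr::distinct(res)
}

#' Presence/absence matrix of islands across genomes
#'
#' @param islands Result of [find_islands()].
#' @param genomes Character vector of all genome ids (rows).
#' @return Tibble, genomes x islands, entries 1 (carrier), 2 (partial
#'   carrier), 0 (absent).
#' @export
island_presence_matrix <- function(islands, genomes) {
  m <- matrix(0L, nrow = length(genomes), ncol = nrow(islands),
              dimnames = list(genomes, islands$island_id))
  for (i in seq_len(nrow(islands))) {
    m[intersect(islands$carriers[[i]], genomes), i] <- 1L
    m[intersect(islands$partial_carriers[[i]], genomes), i] <- 2L
  }
  dplyr::bind_cols(tibble(genome_id = genomes), as_tibble(m))
}

#' Write the island table as TSV
#'
#' List-columns are serialized as comma-separated strings.
#'
#' @param islands Result of [find_islands()].
#' @param path Output file.
#' @export
write_island_table <- function(islands, path) {
  flat <- islands |>
    dplyr::mutate(members = map_chr(.data$members, paste, collapse = ","),
                  carriers = map_chr(.data$carriers, paste, collapse = ","),
                  partial_carriers = map_chr(.data$partial_carriers, paste,
                                             collapse = ",")) |>
    dplyr::select(-"occ")
  readr::write_tsv(flat, path)
  invisible(path)
}
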