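# Synthetic pan-genome generator with planted ground truth.
#
# Emulates a set of ~47 closely related prokaryotic genomes: a shared core
# backbone in conserved gene order, scattered shell/cloud genes, genomic
# islands inserted between specific core gene pairs (with distinct G+C,
# optional mobilome flanking elements, and optional mutually exclusive
# partner islands carrying divergent homeoalleles), and SNPs on core genes
# arranged on a two-level nested population structure.

#' Specify one planted genomic island
#'
#' @param locus 1-based index of the core-gene pair to invade: the island is
#'   inserted between core gene `locus` and core gene `locus + 1`.
#' @param n_genes Number of genes on the island.
#' @param carriers Character vector of genome ids (e.g. `"G03"`) or integer
#'   genome indices that carry the island.
#' @param gc_target Target G+C fraction of island gene sequences.
#' @param partner_of Optional integer index (into the `island_specs` list) of
#'   the partner island of a conflicting pair. The partner must occupy the
#'   same locus; carriers must be disjoint unless listed in
#'   `shared_carriers`.
#' @param homeoallele_fraction For a partner island, the fraction of its
#'   genes generated as divergent homologs of partner genes.
#' @param target_identity Amino-acid identity targeted for homeoallele
#'   pairs.
#' @param flank_elements List of `list(type =, offset =)` entries with type
#'   in `"transposase"`, `"integrase"`, `"tRNA"` and signed gene-order
#'   offset (negative = upstream of the left flank).
#' @param identical_across_carriers If `TRUE` the island sequence is
#'   byte-identical in every carrier; otherwise carriers accumulate private
#'   SNPs.
#' @param shared_carriers Genome ids allowed to carry both islands of a
#'   conflicting pair (planted mutual-exclusivity violations).
#' @param reversed_in Genome ids in which the island occurs in reverse
#'   orientation (members reversed, minus strand, reverse-complemented
#'   sequence).
#' @return An object of class `island_spec`.
#' @export
island_spec <- function(locus, n_genes, carriers, gc_target = 0.45,
                        partner_of = NULL, homeoallele_fraction = 0,
                        target_identity = 0.5, flank_elements = list(),
                        identical_across_carriers = TRUE,
                        shared_carriers = character(),
                        reversed_in = character()) {
  stopifnot(n_genes >= 1, locus >= 1,
            homeoallele_fraction >= 0, homeoallele_fraction <= 1,
            target_identity > 0, target_identity <= 1)
  structure(list(locus = as.integer(locus), n_genes = as.integer(n_genes),
                 carriers = carriers, gc_target = gc_target,
                 partner_of = partner_of,
                 homeoallele_fraction = homeoallele_fraction,
                 target_identity = target_identity,
                 flank_elements = flank_elements,
                 identical_across_carriers = identical_across_carriers,
                 shared_carriers = shared_carriers,
                 reversed_in = reversed_in),
            class = "island_spec")
}

#' Configure a synthetic pan-genome
#'
#' Defaults mirror the study conditions the pipeline targets: 47 genomes of
#' one species, a core backbone of 2,000 families with a 44-of-47 core
#' threshold, and a scaled shell/cloud complement.
#'
#' @param n_genomes Number of genomes (>= 4).
#' @param n_core Number of core-backbone gene families.
#' @param n_shell,n_cloud Number of shell (2+ genomes) and cloud (single
#'   genome) families scattered one per inter-core locus.
#' @param gene_len_range Length interval (nt) for generated genes; rounded
#'   to whole codons.
#' @param core_gc G+C fraction of core and accessory genes.
#' @param core_snp_rate Per-site substitution probability scale for core
#'   gene SNPs (clade-shared sites use twice this rate, private sites half).
#' @param island_specs List of [island_spec()] objects; `NULL` for none.
#' @param core_threshold Core representation threshold (default 44 when
#'   `n_genomes` is 47, else `ceiling(0.94 * n_genomes)`).
#' @param fragmentation Number of random extra contig breaks per genome,
#'   placed away from planted islands.
#' @param seed Integer seed; together with the config it fully determines
#'   the generated pan-genome.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_genomes = 47, n_core = 2000, n_shell = 400,
                         n_cloud = 200, gene_len_range = c(300, 1200),
                         core_gc = 0.68, core_snp_rate = 0.005,
                         island_specs = NULL, core_threshold = NULL,
                         fragmentation = 0, seed = 1) {
  stopifnot(n_genomes >= 4, n_core >= 2, n_shell >= 0, n_cloud >= 0,
            core_gc >= 0, core_gc <= 1, core_snp_rate >= 0,
            core_snp_rate <= 1, length(gene_len_range) == 2)
  if (is.null(core_threshold)) {
    core_threshold <- if (n_genomes == 47) 44L else ceiling(0.94 * n_genomes)
  }
  island_specs <- island_specs %||% list()
  genome_ids <- sprintf("G%02d", seq_len(n_genomes))
  # resolve integer carriers, validate loci and partner structure
  island_specs <- lapply(island_specs, function(sp) {
    if (is.numeric(sp$carriers)) sp$carriers <- genome_ids[sp$carriers]
    if (!all(sp$carriers %in% genome_ids)) {
      abort("island_spec carriers reference unknown genomes",
            class = "panisles_config_error")
    }
    if (sp$locus < 1 || sp$locus >= n_core) {
      abort("island_spec locus index out of range",
            class = "panisles_config_error")
    }
    sp
  })
  for (i in seq_along(island_specs)) {
    po <- island_specs[[i]]$partner_of
    if (!is.null(po)) {
      if (po < 1 || po > length(island_specs) || po == i) {
        abort("partner_of index out of range", class = "panisles_config_error")
      }
      a <- island_specs[[po]]; b <- island_specs[[i]]
      if (a$locus != b$locus) {
        abort("partner islands must share a locus",
              class = "panisles_config_error")
      }
      bad <- setdiff(intersect(a$carriers, b$carriers), b$shared_carriers)
      if (length(bad)) {
        abort(paste("partner island carriers overlap without declared",
                    "exclusivity violation:", paste(bad, collapse = ", ")),
              class = "panisles_config_error")
      }
    }
  }
  n_loci_needed <- length(unique(vapply(island_specs, `[[`, 1L, "locus"))) +
    n_shell + n_cloud
  if (n_loci_needed > n_core - 1) {
    abort("not enough inter-core loci for shell/cloud/island placement",
          class = "panisles_config_error")
  }
  structure(list(n_genomes = as.integer(n_genomes), n_core = as.integer(n_core),
                 n_shell = as.integer(n_shell), n_cloud = as.integer(n_cloud),
                 gene_len_range = gene_len_range, core_gc = core_gc,
                 core_snp_rate = core_snp_rate, island_specs = island_specs,
                 core_threshold = as.integer(core_threshold),
                 fragmentation = as.integer(fragmentation),
                 seed = as.integer(seed), genome_ids = genome_ids),
            class = "synth_config")
}

#' Default planted-island layout
#'
#' Ten islands with lengths spanning 2-22 genes, carrier counts between 2
#' and 15 genomes, loci spaced at least 12 core genes apart, and a
#' transposase next to every other island.
#'
#' @param config A [synth_config()] (used for genome/core counts).
#' @param n Number of islands.
#' @param seed Seed for locus/carrier sampling.
#' @return A list of [island_spec()] objects.
#' @export
default_island_specs <- function(config, n = 10, seed = 1) {
  lens <- round(seq(2, 22, length.out = n))
  with_seed(derive_seed(seed, "island-specs"), {
    loci <- spaced_sample(seq(10, config$n_core - 10), n, min_gap = 12)
    lapply(seq_len(n), function(i) {
      k <- sample(2:15, 1)
      fl <- if (i %% 2 == 1) {
        list(list(type = "transposase", offset = if (i %% 4 == 1) -2L else 3L))
      } else list()
      island_spec(locus = loci[i], n_genes = lens[i],
                  carriers = sort(sample(config$genome_ids, k)),
                  gc_target = runif(1, 0.40, 0.55), flank_elements = fl)
    })
  })
}

# sample `n` values from `pool` pairwise at least `min_gap` apart
spaced_sample <- function(pool, n, min_gap) {
  out <- integer(0)
  pool <- sample(pool)
  for (p in pool) {
    if (!length(out) || all(abs(out - p) >= min_gap)) out <- c(out, p)
    if (length(out) == n) break
  }
  if (length(out) < n) abort("could not place loci with requested spacing")
  sort(out)
}

#' Mutate a sequence to a target pairwise identity
#'
#' Substitutes a deterministic number of positions (`round((1 - target) *
#' length)`), each to a different symbol, so the realized global-alignment
#' identity to the input is `1 - k/L`.
#'
#' @param seq A single nucleotide or amino-acid sequence string.
#' @param target_identity Fraction in (0, 1].
#' @param alphabet `"nt"` or `"aa"`.
#' @param seed Integer seed; output is reproducible.
#' @return The mutated sequence string.
#' @export
mutate_to_identity <- function(seq, target_identity, alphabet = c("nt", "aa"),
                               seed = 1) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(seq)) abort("empty sequence", class = "panisles_input_error")
  stopifnot(target_identity > 0, target_identity <= 1)
  if (target_identity == 1) return(seq)
  L <- nchar(seq)
  k <- round((1 - target_identity) * L)
  if (k == 0) return(seq)
  ab <- if (alphabet == "nt") NT else AA20
  with_seed(derive_seed(seed, paste0("mut2id:", substr(seq, 1, 32))), {
    substitute_positions(seq, sample.int(L, k), alphabet = ab)
  })
}

# Codon-level divergence: replace round((1-target)*n_inner) interior codons
# with random non-stop codons encoding a different amino acid. Realized
# amino-acid identity is 1 - k / n_codons (start/stop conserved).
mutate_orf_to_aa_identity <- function(nt, target_identity, gc) {
  cods <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  inner <- 2:(length(cods) - 1)
  k <- round((1 - target_identity) * length(inner))
  if (k == 0) return(nt)
  idx <- sample(inner, k)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  aa_of <- function(c3) translate_nt(paste0(c3, "TAA"))
  for (i in idx) {
    old_aa <- aa_of(cods[i])
    repeat {
      cand <- paste(sample(NT, 3, replace = TRUE, prob = p), collapse = "")
      if (!(cand %in% STOP_CODONS) && aa_of(cand) != old_aa) break
    }
    cods[i] <- cand
  }
  paste(cods, collapse = "")
}

#' Generate a synthetic pan-genome
#'
#' @param config A [synth_config()].
#' @param sequences Which nucleotide sequences to generate: `"all"`,
#'   `"islands"` (island + mobilome genes only), or `"none"` (gene orders
#'   and truth tables only; fastest). Gene orders and truth tables are
#'   identical across the three modes for a given config and seed.
#' @return A list of class `synth_pangenome` with elements `genes` (a
#'   tibble of gene records: `genome_id`, `contig_id`, `index`, `strand`,
#'   `family_id`, `annotation`, `nt_seq`), `truth` (tibbles `islands`,
#'   `pairs`, `populations`), and `config`.
#' @export
generate <- function(config, sequences = c("all", "islands", "none")) {
  stopifnot(inherits(config, "synth_config"))
  sequences <- match.arg(sequences)
  st <- with_seed(derive_seed(config$seed, "structure"),
                  synth_structure(config))
  seqs <- if (sequences == "none") NULL else {
    with_seed(derive_seed(config$seed, "sequences"),
              synth_sequences(config, st, islands_only = sequences == "islands"))
  }
  genes <- synth_gene_table(config, st, seqs)
  structure(list(genes = genes, truth = st$truth, config = config),
            class = "synth_pangenome")
}

# ---- structure: family layout, carriers, per-genome gene orders ------------

synth_structure <- function(config) {
  n <- config$n_genomes
  gids <- config$genome_ids
  specs <- config$island_specs
  core_ids <- sprintf("core_%04d", seq_len(config$n_core))
  island_loci <- vapply(specs, `[[`, 1L, "locus")

  # accessory loci: one family per locus, away from island neighborhoods
  near_island <- unique(unlist(lapply(island_loci, function(l) (l - 6):(l + 6))))
  free_loci <- setdiff(seq_len(config$n_core - 1), near_island)
  if (length(free_loci) < config$n_shell + config$n_cloud) {
    free_loci <- setdiff(seq_len(config$n_core - 1), island_loci)
  }
  acc_loci <- sample(free_loci, config$n_shell + config$n_cloud)
  shell_loci <- acc_loci[seq_len(config$n_shell)]
  cloud_loci <- acc_loci[config$n_shell + seq_len(config$n_cloud)]

  shell <- lapply(seq_len(config$n_shell), function(k) {
    pool <- 2:max(2, n - 4)
    r <- pool[sample.int(length(pool), 1, prob = 1 / pool)]
    list(family_id = sprintf("shell_%04d", k), locus = shell_loci[k],
         carriers = sort(sample(gids, r)))
  })
  cloud <- lapply(seq_len(config$n_cloud), function(k) {
    list(family_id = sprintf("cloud_%04d", k), locus = cloud_loci[k],
         carriers = sample(gids, 1))
  })

  # core representation: families next to any occupied locus stay universal
  protected <- unique(c(island_loci, island_loci + 1L, acc_loci, acc_loci + 1L))
  core_missing <- setNames(vector("list", config$n_core), core_ids)
  if (config$core_threshold <= n - 1) {
    droppable <- setdiff(seq_len(config$n_core), protected)
    n_drop <- min(length(droppable), round(0.1 * config$n_core))
    for (i in sample(droppable, n_drop)) {
      r <- if (config$core_threshold == n - 1) n - 1L else {
        sample(seq(config$core_threshold, n - 1), 1)
      }
      core_missing[[i]] <- sample(gids, n - r)
    }
  }

  # island genes + flank elements
  isl <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    members <- sprintf("isl%02d_g%02d", i, seq_len(sp$n_genes))
    mge <- lapply(seq_along(sp$flank_elements), function(j) {
      el <- sp$flank_elements[[j]]
      list(family_id = sprintf("mge%02d_%02d", i, j), type = el$type,
           offset = as.integer(el$offset))
    })
    list(spec = sp, members = members, mge = mge, idx = i)
  })

  # homeoallele truth maps for partner pairs
  pairs <- list()
  homeo_map <- setNames(vector("list", length(specs)), as.character(seq_along(specs)))
  for (i in seq_along(specs)) {
    po <- specs[[i]]$partner_of
    if (is.null(po)) next
    a <- isl[[po]]; b <- isl[[i]]
    h <- round(specs[[i]]$homeoallele_fraction * length(b$members))
    h <- min(h, length(a$members))
    map <- if (h > 0) {
      tibble(gene_a = sample(a$members, h), gene_b = sample(b$members, h))
    } else tibble(gene_a = character(), gene_b = character())
    homeo_map[[as.character(i)]] <- map
    pairs[[length(pairs) + 1]] <- tibble(
      island_a = sprintf("TI%02d", po), island_b = sprintf("TI%02d", i),
      locus = specs[[i]]$locus,
      homeoallele_map = list(map),
      homeoallele_fraction = specs[[i]]$homeoallele_fraction,
      target_identity = specs[[i]]$target_identity,
      shared_carriers = list(specs[[i]]$shared_carriers),
      expected_class = ifelse(specs[[i]]$homeoallele_fraction >= 0.5,
                              "homeocassette", "conflicting_only"))
  }

  # nested two-level population structure
  perm <- sample(gids)
  half <- ceiling(n / 2)
  lv1 <- ifelse(gids %in% perm[seq_len(half)], "P1", "P2")
  lv2 <- lv1
  for (cl in c("P1", "P2")) {
    mem <- gids[lv1 == cl]
    sub <- sample(rep(c(".1", ".2"), length.out = length(mem)))
    lv2[match(mem, gids)] <- paste0(cl, sub)
  }
  populations <- tibble(genome_id = gids, level1 = lv1, level2 = lv2)

  truth_islands <- if (length(isl)) {
    dplyr::bind_rows(lapply(isl, function(x) tibble(
      island_id = sprintf("TI%02d", x$idx), locus = x$spec$locus,
      flank_left = core_ids[x$spec$locus], flank_right = core_ids[x$spec$locus + 1],
      n_genes = length(x$members), members = list(x$members),
      carriers = list(sort(x$spec$carriers)))))
  } else {
    tibble(island_id = character(), locus = integer(), flank_left = character(),
           flank_right = character(), n_genes = integer(), members = list(),
           carriers = list())
  }
  truth_pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else tibble(
    island_a = character(), island_b = character(), locus = integer(),
    homeoallele_map = list(), homeoallele_fraction = double(),
    target_identity = double(), shared_carriers = list(),
    expected_class = character())

  # per-genome gene orders
  at_locus <- setNames(vector("list", config$n_core), as.character(seq_len(config$n_core)))
  add_at <- function(locus, entry) {
    key <- as.character(locus)
    at_locus[[key]][[length(at_locus[[key]]) + 1]] <<- entry
  }
  for (s in shell) add_at(s$locus, list(kind = "acc", fam = s$family_id,
                                        carriers = s$carriers))
  for (s in cloud) add_at(s$locus, list(kind = "acc", fam = s$family_id,
                                        carriers = s$carriers))
  for (x in isl) add_at(x$spec$locus, list(kind = "island", idx = x$idx,
                                           members = x$members,
                                           carriers = x$spec$carriers,
                                           reversed_in = x$spec$reversed_in))

  occupied <- which(!vapply(at_locus, is.null, logical(1)))
  orders <- lapply(gids, function(g) {
    # one chunk per core index (core gene + any slot content); unlist once
    chunks <- as.list(core_ids)
    for (i in seq_len(config$n_core)) {
      if (g %in% core_missing[[i]]) chunks[[i]] <- character(0)
    }
    for (i in occupied) {
      add <- character(0)
      for (entry in at_locus[[i]]) {
        if (!(g %in% entry$carriers)) next
        if (entry$kind == "acc") add <- c(add, entry$fam)
        else {
          m <- entry$members
          if (g %in% entry$reversed_in) m <- rev(m)
          add <- c(add, m)
        }
      }
      if (length(add)) chunks[[i]] <- c(chunks[[i]], add)
    }
    out <- unlist(chunks, use.names = FALSE)
    # flank elements inserted relative to realized flank positions,
    # closest offsets first so earlier placements keep their distance
    for (x in isl) {
      if (!(g %in% x$spec$carriers) || !length(x$mge)) next
      fl <- core_ids[x$spec$locus]; fr <- core_ids[x$spec$locus + 1]
      mge <- x$mge[order(abs(vapply(x$mge, `[[`, 1L, "offset")))]
      for (el in mge) {
        if (el$offset < 0) {
          f <- match(fl, out)
          q <- f + 1L + el$offset   # insert so final distance = |offset|
          out <- append(out, el$family_id, after = q - 1L)
        } else {
          f <- match(fr, out)
          out <- append(out, el$family_id, after = f + el$offset - 1L)
        }
      }
    }
    out
  })
  names(orders) <- gids

  # contig assignment (breaks away from island loci)
  contigs <- lapply(gids, function(g) {
    ord <- orders[[g]]
    breaks <- integer(0)
    if (config$fragmentation > 0) {
      island_fams <- unlist(lapply(isl, function(x) c(x$members,
        core_ids[x$spec$locus], core_ids[x$spec$locus + 1])))
      ok <- which(!(ord %in% island_fams))[-1]
      if (length(ok)) breaks <- sort(sample(ok, min(config$fragmentation,
                                                    length(ok))))
    }
    cid <- cumsum(seq_along(ord) %in% breaks) + 1L
    sprintf("%s_c%02d", g, cid)
  })
  names(contigs) <- gids

  list(core_ids = core_ids, core_missing = core_missing, shell = shell,
       cloud = cloud, isl = isl, homeo_map = homeo_map, orders = orders,
       contigs = contigs,
       truth = list(islands = truth_islands, pairs = truth_pairs,
                    populations = populations))
}

# ---- sequences -------------------------------------------------------------

synth_sequences <- function(config, st, islands_only = FALSE) {
  lenr <- round(config$gene_len_range / 3)
  rand_len <- function() sample(max(3, lenr[1]):max(4, lenr[2]), 1)
  pops <- st$truth$populations
  gids <- config$genome_ids

  fam_seq <- list()      # family -> single (shared) sequence
  per_genome <- list()   # family -> named vector genome -> sequence

  # island + mobilome genes first (same RNG stream in both modes)
  for (x in st$isl) {
    sp <- x$spec
    map <- st$homeo_map[[as.character(x$idx)]]
    for (m in x$members) {
      src <- if (!is.null(map) && m %in% map$gene_b) {
        a_gene <- map$gene_a[match(m, map$gene_b)]
        mutate_orf_to_aa_identity(fam_seq[[a_gene]], sp$target_identity,
                                  sp$gc_target)
      } else random_orf(rand_len(), sp$gc_target)
      fam_seq[[m]] <- src
      if (!sp$identical_across_carriers) {
        vs <- vapply(sp$carriers, function(g) {
          k <- rbinom(1, nchar(src), config$core_snp_rate)
          if (k) substitute_positions(src, sample.int(nchar(src), k)) else src
        }, character(1))
        per_genome[[m]] <- setNames(vs, sp$carriers)
      }
    }
    for (el in x$mge) {
      fam_seq[[el$family_id]] <- if (el$type == "tRNA") {
        random_dna(75, 0.60)
      } else random_orf(100, sp$gc_target)
    }
  }

  if (!islands_only) {
    for (s in c(st$shell, st$cloud)) {
      fam_seq[[s$family_id]] <- random_orf(rand_len(), config$core_gc)
    }
    rate <- config$core_snp_rate
    lv1 <- setNames(pops$level1, pops$genome_id)
    lv2 <- setNames(pops$level2, pops$genome_id)
    for (i in seq_along(st$core_ids)) {
      f <- st$core_ids[i]
      anc <- random_orf(rand_len(), config$core_gc)
      L <- nchar(anc)
      fam_seq[[f]] <- anc
      # clade-shared, subclade-shared and private substitutions
      site_set <- function(k) if (k) sample.int(L, k) else integer(0)
      clade_sites <- site_set(rbinom(1, L, 2 * rate))
      sub_sites <- lapply(c("P1.1", "P1.2", "P2.1", "P2.2"),
                          function(s) site_set(rbinom(1, L, rate)))
      names(sub_sites) <- c("P1.1", "P1.2", "P2.1", "P2.2")
      clade_seq <- if (length(clade_sites)) {
        substitute_positions(anc, clade_sites)
      } else anc
      sub_seq <- lapply(names(sub_sites), function(s) {
        base <- if (startsWith(s, "P2")) clade_seq else anc
        if (length(sub_sites[[s]])) substitute_positions(base, sub_sites[[s]])
        else base
      })
      names(sub_seq) <- names(sub_sites)
      present <- setdiff(gids, st$core_missing[[i]])
      vs <- vapply(present, function(g) {
        s <- sub_seq[[lv2[[g]]]]
        k <- rbinom(1, L, rate / 2)
        if (k) substitute_positions(s, sample.int(L, k)) else s
      }, character(1))
      per_genome[[f]] <- vs
    }
  }
  list(fam_seq = fam_seq, per_genome = per_genome)
}

# ---- assemble the gene-record tibble ---------------------------------------

synth_gene_table <- function(config, st, seqs) {
  isl_rev <- lapply(st$isl, function(x)
    list(members = x$members, reversed_in = x$spec$reversed_in))
  ann <- family_annotations(st)
  rows <- lapply(config$genome_ids, function(g) {
    ord <- st$orders[[g]]
    ctg <- st$contigs[[g]]
    idx <- stats::ave(seq_along(ord), ctg, FUN = seq_along) - 1L
    strand <- rep("+", length(ord))
    nt <- rep(NA_character_, length(ord))
    if (!is.null(seqs)) {
      for (j in seq_along(ord)) {
        f <- ord[j]
        s <- if (!is.null(seqs$per_genome[[f]]) &&
                 g %in% names(seqs$per_genome[[f]])) {
          seqs$per_genome[[f]][[g]]
        } else seqs$fam_seq[[f]]
        nt[j] <- s %||% NA_character_
      }
    }
    for (x in isl_rev) {
      if (g %in% x$reversed_in) {
        pos <- which(ord %in% x$members)
        strand[pos] <- "-"
        nt[pos] <- ifelse(is.na(nt[pos]), NA_character_, revcomp(nt[pos]))
      }
    }
    tibble(genome_id = g, contig_id = ctg, index = as.integer(idx),
           strand = strand, family_id = ord,
           annotation = unname(ann[ord]), nt_seq = nt)
  })
  dplyr::bind_rows(rows)
}

family_annotations <- function(st) {
  ann <- c(setNames(rep("core protein", length(st$core_ids)), st$core_ids))
  for (s in st$shell) ann[s$family_id] <- "hypothetical protein"
  for (s in st$cloud) ann[s$family_id] <- "hypothetical protein"
  for (x in st$isl) {
    ann[x$members] <- "island protein"
    for (el in x$mge) {
      ann[el$family_id] <- switch(el$type,
        transposase = "transposase (IS4 family)",
        integrase   = "integrase",
        tRNA        = "tRNA-Lys")
    }
  }
  ann
}

#' @export
print.synth_pangenome <- function(x, ...) {
  cat("Synthetic pan-genome:", x$config$n_genomes, "genomes,",
      x$config$n_core, "core families,",
      nrow(x$truth$islands), "planted islands,",
      nrow(x$truth$pairs), "planted pairs\n")
  invisible(x)
}
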