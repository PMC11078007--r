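# Shared fixtures built in code.

# small pan-genome with one conflicting pair at a shared locus
fixture_pair_sim <- function(seed = 3, hf = 0.5, n_genes = 4,
                             target_identity = 0.5) {
  cfg <- synth_config(
    n_genomes = 12, n_core = 80, n_shell = 8, n_cloud = 4,
    gene_len_range = c(300, 450),
    island_specs = list(
      island_spec(20, n_genes, paste0("G0", 1:3), gc_target = 0.45),
      island_spec(20, n_genes, c("G05", "G06", "G07"), gc_target = 0.50,
                  partner_of = 1, homeoallele_fraction = hf,
                  target_identity = target_identity)),
    seed = seed)
  generate(cfg)
}

# hand-built gene table: one genome per row-set, families in given order
genes_from_orders <- function(orders, contig = "c1") {
  dplyr::bind_rows(lapply(names(orders), function(g) {
    ord <- orders[[g]]
    tibble::tibble(genome_id = g, contig_id = paste0(g, "_", contig),
                   index = seq_along(ord) - 1L, strand = "+",
                   family_id = ord, annotation = NA_character_,
                   nt_seq = NA_character_)
  }))
}

# island tibble built directly (for homology tests with known sequences):
# two islands at one locus; seqs is a named list family -> nt sequence
fixture_islands_manual <- function(members_a, members_b, seqs,
                                   carriers_a = "GA", carriers_b = "GB") {
  mk_genes <- function(genome, members) {
    fams <- c("coreL", members, "coreR")
    tibble::tibble(genome_id = genome, contig_id = paste0(genome, "_c1"),
                   index = seq_along(fams) - 1L, strand = "+",
                   family_id = fams, annotation = NA_character_,
                   nt_seq = unname(c("ATGAAATAA", seqs[members], "ATGCCCTAA")))
  }
  genes <- dplyr::bind_rows(
    lapply(carriers_a, mk_genes, members = members_a),
    lapply(carriers_b, mk_genes, members = members_b))
  occ_of <- function(carriers, members) {
    n_mem <- length(members)
    dplyr::bind_rows(lapply(carriers, function(g) tibble::tibble(
      genome_id = g, contig_id = paste0(g, "_c1"),
      flank_a = "coreL", flank_b = "coreR",
      flank_left = "coreL", flank_right = "coreR",
      members = list(members), start = 1L, end = n_mem,
      left_first = TRUE)))
  }
  islands <- tibble::tibble(
    island_id = c("GI_A", "GI_B"), flank_left = "coreL", flank_right = "coreR",
    locus = "coreL|coreR",
    members = list(members_a, members_b),
    length = c(length(members_a), length(members_b)),
    carriers = list(carriers_a, carriers_b),
    n_carriers = c(length(carriers_a), length(carriers_b)),
    partial_carriers = list(character(), character()),
    merged_variants = FALSE,
    occ = list(occ_of(carriers_a, members_a), occ_of(carriers_b, members_b)))
  list(islands = islands, genes = genes)
}

random_orf_fixture <- function(n_codons, gc = 0.5, seed = 1) {
  withr::with_seed(seed, panisles:::random_orf(n_codons, gc))
}

random_aa_fixture <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(panisles:::AA20, n, TRUE), collapse = ""))
}
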