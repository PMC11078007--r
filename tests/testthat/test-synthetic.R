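test_that("generated pan-genomes honour the configured truth by construction", {
  cfg <- synth_config(n_genomes = 47, n_core = 120, n_shell = 10, n_cloud = 5,
                      island_specs = list(island_spec(40, 3, 1:5)), seed = 2)
  sim <- generate(cfg, sequences = "none")
  expect_equal(nrow(sim$truth$islands), 1L)
  expect_equal(sim$truth$islands$n_genes, 3L)
  expect_length(sim$truth$islands$carriers[[1]], 5L)
  expect_equal(sim$truth$islands$flank_left, "core_0040")
  # planted members are flanked by the core pair in every carrier
  for (g in sim$truth$islands$carriers[[1]]) {
    ord <- sim$genes$family_id[sim$genes$genome_id == g]
    pos <- which(ord %in% sim$truth$islands$members[[1]])
    expect_equal(ord[min(pos) - 1], "core_0040")
    expect_equal(ord[max(pos) + 1], "core_0041")
  }
  # indices contiguous from 0 within each contig
  by_ctg <- split(sim$genes$index, paste(sim$genes$genome_id, sim$genes$contig_id))
  expect_true(all(vapply(by_ctg, function(ix)
    identical(sort(ix), seq_along(ix) - 1L), logical(1))))
})

test_that("identical config and seed reproduce byte-identical outputs", {
  cfg <- synth_config(n_genomes = 8, n_core = 40, n_shell = 5, n_cloud = 3,
                      island_specs = list(island_spec(10, 2, c("G01", "G02"))),
                      seed = 42)
  s1 <- generate(cfg)
  s2 <- generate(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth$islands, s2$truth$islands)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genomes(s1, d1); write_genomes(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # gene orders are invariant to the sequences mode
  s3 <- generate(cfg, sequences = "none")
  expect_identical(dplyr::select(s1$genes, -"nt_seq"),
                   dplyr::select(s3$genes, -"nt_seq"))
})

test_that("mutate_to_identity realizes the target within tolerance", {
  aa <- random_aa_fixture(300, seed = 5)
  expect_identical(mutate_to_identity(aa, 1.0, "aa", seed = 1), aa)
  m <- mutate_to_identity(aa, 0.5, "aa", seed = 1)
  expect_equal(nchar(m), 300L)
  id <- oracle_identity(aa, m, "aa")
  expect_gte(id, 0.45); expect_lte(id, 0.55)
  expect_identical(mutate_to_identity(aa, 0.5, "aa", seed = 1), m)
  nt <- withr::with_seed(5, panisles:::random_dna(600, 0.5))
  mnt <- mutate_to_identity(nt, 0.8, "nt", seed = 2)
  expect_gte(oracle_identity(nt, mnt, "nt"), 0.75)
  expect_error(mutate_to_identity("", 0.5, "nt"), class = "panisles_input_error")
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_genomes = 10, n_core = 50,
                            island_specs = list(island_spec(5, 2, c("ZZZ")))),
               class = "panisles_config_error")
  expect_error(synth_config(n_genomes = 10, n_core = 50,
                            island_specs = list(island_spec(99, 2, 1:2))),
               class = "panisles_config_error")
  expect_error(
    synth_config(n_genomes = 10, n_core = 50, island_specs = list(
      island_spec(5, 2, 1:3),
      island_spec(5, 2, 2:4, partner_of = 1))),
    class = "panisles_config_error")
})

test_that("island sequence G+C tracks gc_target for islands over 2 kb", {
  for (gc in c(0.42, 0.55)) {
    cfg <- synth_config(n_genomes = 8, n_core = 60, n_shell = 0, n_cloud = 0,
                        gene_len_range = c(600, 900),
                        island_specs = list(island_spec(20, 5, 1:3,
                                                        gc_target = gc)),
                        seed = round(100 * gc))
    sim <- generate(cfg, sequences = "islands")
    seqs <- sim$genes$nt_seq[sim$genes$family_id %in%
                               sim$truth$islands$members[[1]]]
    concat <- paste(seqs[!is.na(seqs)], collapse = "")
    expect_gte(nchar(concat), 2000L)
    expect_lt(abs(gc_content(concat) - gc), 0.03)
  }
})

test_that("homeoallele pairs in partner islands hit the target identity", {
  sim <- fixture_pair_sim(seed = 9, hf = 0.5, target_identity = 0.5)
  map <- sim$truth$pairs$homeoallele_map[[1]]
  expect_gt(nrow(map), 0)
  for (k in seq_len(nrow(map))) {
    nta <- sim$genes$nt_seq[sim$genes$family_id == map$gene_a[k]][1]
    ntb <- sim$genes$nt_seq[sim$genes$family_id == map$gene_b[k]][1]
    aa <- panisles:::translate_nt(c(nta, ntb))
    id <- oracle_identity(aa[1], aa[2], "aa")
    expect_gt(id, 0.40); expect_lt(id, 0.60)
  }
})
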