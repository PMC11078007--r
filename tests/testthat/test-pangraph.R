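test_that("family clustering joins by global identity with a 98% threshold", {
  s1 <- random_orf_fixture(100, seed = 1)
  s2 <- mutate_to_identity(s1, 0.99, "nt", seed = 2)   # ~99% identical
  s3 <- mutate_to_identity(s1, 0.90, "nt", seed = 3)   # ~90% identical
  genes <- genes_from_orders(list(gA = c("x", "y", "z")))
  genes$nt_seq <- c(s1, s2, s3)
  out <- cluster_families(genes, identity_threshold = 0.98)
  expect_equal(out$family_id[1], out$family_id[2])
  expect_false(out$family_id[1] == out$family_id[3])
  # identical sequences always share a family
  genes2 <- genes_from_orders(list(gA = c("x", "y")))
  genes2$nt_seq <- c(s1, s1)
  expect_equal(dplyr::n_distinct(cluster_families(genes2)$family_id), 1L)
  empty <- cluster_families(genes[0, ])
  expect_equal(nrow(empty), 0L)
  expect_error(cluster_families(genes_from_orders(list(gA = "x"))),
               class = "panisles_input_error")
})

test_that("graph construction follows gene adjacency and contig bounds", {
  g <- build_pangraph(genes_from_orders(list(g1 = c("A", "B", "C"))))
  ekey <- paste(g$edges$from, g$edges$to)
  expect_setequal(ekey, c("A B", "B C"))
  expect_equal(g$edges$support[[which(ekey == "A B")]], "g1")

  g2 <- build_pangraph(genes_from_orders(list(g1 = c("A", "B", "C"),
                                              g2 = c("A", "C"))))
  ekey2 <- paste(g2$edges$from, g2$edges$to)
  expect_setequal(ekey2, c("A B", "A C", "B C"))
  expect_equal(g2$edges$support[[which(ekey2 == "A B")]], "g1")
  expect_equal(g2$edges$support[[which(ekey2 == "A C")]], "g2")

  # two contigs: no edge across the boundary
  genes3 <- dplyr::bind_rows(
    tibble::tibble(genome_id = "g1", contig_id = "c1", index = 0:1,
                   strand = "+", family_id = c("A", "B"),
                   annotation = NA_character_, nt_seq = NA_character_),
    tibble::tibble(genome_id = "g1", contig_id = "c2", index = 0:1,
                   strand = "+", family_id = c("C", "D"),
                   annotation = NA_character_, nt_seq = NA_character_))
  g3 <- build_pangraph(genes3)
  expect_setequal(paste(g3$edges$from, g3$edges$to), c("A B", "C D"))

  # a genome supports an edge once regardless of copy number
  g4 <- build_pangraph(genes_from_orders(list(g1 = c("A", "B", "A", "B"))))
  ab <- g4$edges[g4$edges$from == "A" & g4$edges$to == "B", ]
  expect_equal(ab$n_support, 1L)
})

test_that("divisions follow the 44-of-47 core rule and partition families", {
  reps <- c(47, 44, 43, 2, 1)
  nodes <- tibble::tibble(family_id = paste0("f", seq_along(reps)),
                          name = family_id, representation = reps)
  graph <- structure(list(nodes = nodes, edges = tibble::tibble(),
                          n_genomes = 47L, core_threshold = 44L),
                     class = "pan_graph")
  div <- classify_families(graph)$division
  expect_equal(div, c("core", "core", "shell", "shell", "cloud"))

  cfg <- synth_config(n_genomes = 10, n_core = 50, n_shell = 6, n_cloud = 4,
                      seed = 1)
  sim <- generate(cfg, sequences = "none")
  g <- build_pangraph(sim$genes)
  expect_equal(sum(table(g$nodes$division)), nrow(g$nodes))
  expect_true(all(g$nodes$division[g$nodes$representation == 1] == "cloud"))
  # rebuilding from the same gene orders is idempotent
  expect_identical(g$nodes, build_pangraph(sim$genes)$nodes)
  expect_identical(g$edges, build_pangraph(sim$genes)$edges)
})

test_that("GML export round-trips through the Panaroo-dialect importer", {
  cfg <- synth_config(n_genomes = 6, n_core = 30, n_shell = 4, n_cloud = 2,
                      seed = 5)
  sim <- generate(cfg, sequences = "none")
  g <- build_pangraph(sim$genes)
  gml <- withr::local_tempfile(fileext = ".gml")
  write_graph_gml(g, gml)
  g2 <- read_panaroo(gml = gml)
  expect_equal(nrow(g2$nodes), nrow(g$nodes))
  expect_equal(nrow(g2$edges), nrow(g$edges))
})

test_that("Panaroo presence/absence tables drive representation counts", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Gene,Non-unique Gene name,Annotation,s1,s2,s3",
    "famA,,thing A,g1,g2,g3",
    "famB,,,g1,,g3",
    "famC,,thing C,,,g3"), csv)
  g <- read_panaroo(presence_absence = csv, core_threshold = 3)
  expect_equal(g$n_genomes, 3L)
  expect_equal(g$nodes$representation, c(3, 2, 1))
  expect_equal(g$nodes$division, c("core", "shell", "cloud"))
  expect_error(read_panaroo(presence_absence = csv, gml = "no/such.gml"),
               regexp = "no/such.gml", class = "panisles_config_error")
})
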