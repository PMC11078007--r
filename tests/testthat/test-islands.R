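core3 <- function() {
  # A..F core in 4 genomes so threshold is met; x,y,z accessory
  list(g1 = c("A", "B", "C", "D", "E", "F"),
       g2 = c("A", "B", "C", "D", "E", "F"),
       g3 = c("A", "B", "C", "D", "E", "F"),
       g4 = c("A", "B", "C", "D", "E", "F"))
}

test_that("gc_content counts G+C over called bases only", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AATT"), 0.0)
  expect_equal(gc_content("GCATN"), 0.5)
  expect_equal(gc_content(c("GC", "AT")), c(1, 0))
  expect_error(gc_content(""), class = "panisles_input_error")
  expect_warning(res <- gc_content("NNN"))
  expect_true(is.na(res))
})

test_that("maximal non-core runs flanked by core genes become islands", {
  ords <- core3()
  ords$g1 <- c("A", "x", "y", "B", "C", "D", "E", "F")
  ords$g2 <- c("A", "x", "y", "B", "C", "D", "E", "F")
  genes <- genes_from_orders(ords)
  graph <- build_pangraph(genes, core_threshold = 4)
  isl <- find_islands(graph, genes)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$members[[1]], c("x", "y"))
  expect_setequal(isl$carriers[[1]], c("g1", "g2"))
  expect_setequal(c(isl$flank_left, isl$flank_right), c("A", "B"))
  # no island member is core; flanks reach the core threshold
  div <- setNames(graph$nodes$division, graph$nodes$family_id)
  expect_true(all(div[isl$members[[1]]] != "core"))
  rep <- setNames(graph$nodes$representation, graph$nodes$family_id)
  expect_true(all(rep[c(isl$flank_left, isl$flank_right)] >=
                    graph$core_threshold))
})

test_that("single-gene runs are rejected unless the locus hosts two islands", {
  ords <- core3()
  ords$g1 <- c("A", "x", "B", "C", "D", "E", "F")
  genes <- genes_from_orders(ords)
  graph <- build_pangraph(genes, core_threshold = 4)
  isl <- find_islands(graph, genes)
  expect_equal(nrow(isl), 0L)
  expect_true("below_min_len" %in% islands_report(isl)$reason)

  # same locus invaded by a second single-gene island: both kept
  ords$g2 <- c("A", "w", "B", "C", "D", "E", "F")
  genes2 <- genes_from_orders(ords)
  isl2 <- find_islands(build_pangraph(genes2, core_threshold = 4), genes2)
  expect_equal(nrow(isl2), 2L)
})

test_that("contig-end runs are skipped and counted", {
  genes <- dplyr::bind_rows(
    genes_from_orders(core3()),
    tibble::tibble(genome_id = "g5", contig_id = "g5_c1", index = 0:2,
                   strand = "+", family_id = c("x", "y", "B"),
                   annotation = NA_character_, nt_seq = NA_character_))
  graph <- build_pangraph(genes, core_threshold = 4)
  isl <- find_islands(graph, genes)
  expect_equal(nrow(isl), 0L)
  expect_gte(attr(isl, "skipped_contig_end"), 1L)
})

test_that("locus grouping merges subsets and splits disjoint member sets", {
  ords <- core3()
  ords$g1 <- c("A", "x", "y", "z", "B", "C", "D", "E", "F")
  ords$g2 <- c("A", "x", "y", "B", "C", "D", "E", "F")      # subset
  ords$g3 <- c("A", "p", "q", "B", "C", "D", "E", "F")      # disjoint
  genes <- genes_from_orders(ords)
  isl <- find_islands(build_pangraph(genes, core_threshold = 4), genes)
  expect_equal(nrow(isl), 2L)
  big <- isl[vapply(isl$members, length, 1L) == 3, ]
  expect_equal(big$carriers[[1]], "g1")
  expect_equal(big$partial_carriers[[1]], "g2")
  pr <- find_conflicting_pairs(isl)
  expect_equal(nrow(pr), 1L)
  # reverse-ordered occurrence merges into the same island
  ords$g4 <- c("A", "z", "y", "x", "B", "C", "D", "E", "F")
  genes4 <- genes_from_orders(ords)
  isl4 <- find_islands(build_pangraph(genes4, core_threshold = 4), genes4)
  big4 <- isl4[vapply(isl4$members, length, 1L) == 3, ]
  expect_setequal(big4$carriers[[1]], c("g1", "g4"))
})

test_that("overloaded loci are discarded with a report", {
  ords <- core3()
  ords$g1 <- c("A", "p1", "p2", "B", "C", "D", "E", "F")
  ords$g2 <- c("A", "q1", "q2", "B", "C", "D", "E", "F")
  ords$g3 <- c("A", "r1", "r2", "B", "C", "D", "E", "F")
  ords$g4 <- c("A", "s1", "s2", "B", "C", "D", "E", "F")
  # keep the flanks core despite accessory runs in all genomes
  ords$g5 <- c("A", "B", "C", "D", "E", "F")
  ords$g6 <- c("A", "B", "C", "D", "E", "F")
  genes <- genes_from_orders(ords)
  isl <- find_islands(build_pangraph(genes, core_threshold = 5), genes,
                      max_variants_per_locus = 3)
  expect_equal(nrow(isl), 0L)
  expect_true("too_many_variants" %in% islands_report(isl)$reason)
})

test_that("per-genome scan matches a brute-force run scanner on random inputs", {
  for (seed in 1:5) {
    cfg <- synth_config(n_genomes = 10, n_core = 60, n_shell = 8, n_cloud = 6,
                        island_specs = list(
                          island_spec(15, 3, 1:4),
                          island_spec(45, 2, c(2, 5, 6))),
                        seed = seed)
    sim <- generate(cfg, sequences = "none")
    graph <- build_pangraph(sim$genes)
    div <- setNames(graph$nodes$division, graph$nodes$family_id)
    runs <- oracle_island_runs(sim$genes, div)
    multi <- Filter(function(r) length(r$members) >= 2, runs)
    isl <- find_islands(graph, sim$genes)
    got <- lapply(seq_len(nrow(isl)), function(i)
      list(flanks = sort(c(isl$flank_left[i], isl$flank_right[i])),
           members = sort(isl$members[[i]])))
    want <- unique(lapply(multi, function(r)
      list(flanks = r$flanks, members = sort(r$members))))
    expect_setequal(got, want)
  }
})

test_that("identical-sequence flag normalizes orientation", {
  cfg <- synth_config(n_genomes = 8, n_core = 40, n_shell = 0, n_cloud = 0,
                      island_specs = list(
                        island_spec(10, 3, 1:3, reversed_in = "G02")),
                      seed = 6)
  sim <- generate(cfg)
  graph <- build_pangraph(sim$genes)
  isl <- find_islands(graph, sim$genes)
  expect_equal(nrow(isl), 1L)
  expect_true(isl$identical_flag)
  # one substitution in one carrier breaks identity
  genes2 <- sim$genes
  row <- which(genes2$family_id == sim$truth$islands$members[[1]][1] &
                 genes2$genome_id == "G01")[1]
  genes2$nt_seq[row] <- panisles:::substitute_positions(genes2$nt_seq[row], 10)
  isl2 <- find_islands(graph, genes2)
  expect_false(isl2$identical_flag)
})

test_that("neighborhood scan honours the radius and excludes island genes", {
  full <- c("T5", "K1", "K2", "K3", "K4", "Tn", "K5", "x", "y", "K6", "K7",
            "tr", "K8")
  bare <- c("T5", "K1", "K2", "K3", "K4", "K5", "K6", "K7", "K8")
  ords <- list(g1 = full, g2 = full, g3 = bare, g4 = bare)
  genes <- genes_from_orders(ords)
  ann <- c(Tn = "transposase (IS200 family)", tr = "tRNA-Gly",
           T5 = "transposase")
  genes$annotation <- unname(ann[genes$family_id])
  graph <- build_pangraph(genes, core_threshold = 4)
  isl <- find_islands(graph, genes)
  nb <- neighborhood_scan(isl, genes, radius = 5)
  tn <- nb[nb$element == "transposase", ]
  expect_setequal(tn$family_id, "Tn")            # T5 is 6 genes away -> absent
  expect_equal(unique(tn$offset), -1L)
  tr <- nb[nb$element == "tRNA", ]
  expect_equal(unique(tr$offset), 2L)
  # widen the radius: the far transposase appears at offset -6
  nb7 <- neighborhood_scan(isl, genes, radius = 7)
  expect_true(any(nb7$family_id == "T5" & nb7$offset == -6L))
  # a tRNA inside the island is not a neighborhood element
  ords2 <- lapply(ords, function(o) o)
  ords2$g1 <- c("C1", "C2", "C3", "x", "tr", "C4", "C5", "C6")
  ords2$g2 <- ords2$g1
  genes2 <- genes_from_orders(ords2[c("g1", "g2", "g3", "g4")])
  genes2$annotation <- unname(ann[genes2$family_id])
  isl2 <- find_islands(build_pangraph(genes2, core_threshold = 4), genes2)
  nb2 <- neighborhood_scan(isl2, genes2, radius = 5)
  expect_false("tRNA" %in% nb2$element)
})
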