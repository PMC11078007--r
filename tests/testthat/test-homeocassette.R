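test_that("conflicting pairs require a shared flank pair and report violations", {
  islands <- tibble::tibble(
    island_id = c("I1", "I2", "I3"),
    flank_left = c("gbp2", "gbp2", "rpap1"),
    flank_right = c("mptD", "mptD", "acaB1"),
    locus = c("gbp2|mptD", "gbp2|mptD", "acaB1|rpap1"),
    members = list("a", "b", "c"), length = 1L,
    carriers = list(c("g1", "g2"), c("g3", "AMM015"), "g4"),
    n_carriers = c(2L, 2L, 1L), partial_carriers = list(character()),
    merged_variants = FALSE, occ = list(NULL))
  pr <- find_conflicting_pairs(islands)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$exclusivity_violations[[1]], character(0))
  islands$carriers[[1]] <- c("g1", "AMM015")
  pr2 <- find_conflicting_pairs(islands)
  expect_equal(pr2$exclusivity_violations[[1]], "AMM015")
})

test_that("identical genes are homeoalleles at the permutation floor and
           random genes are iORFans", {
  orf1 <- random_orf_fixture(150, seed = 1)
  orf2 <- random_orf_fixture(150, seed = 2)  # independent random gene
  fx <- fixture_islands_manual(c("a1", "a2"), c("b1", "b2"),
                               seqs = c(a1 = orf1, a2 = orf2,
                                        b1 = orf1,
                                        b2 = random_orf_fixture(150, seed = 3)))
  pr <- find_conflicting_pairs(fx$islands)
  out <- homology_search(pr, fx$islands, fx$genes, n_shuffles = 200, seed = 1)
  hits <- out$hits[[1]]
  self <- hits[hits$gene_a == "a1" & hits$gene_b == "b1", ]
  expect_equal(self$aa_identity, 1.0)
  expect_equal(self$perm_p, 1 / 201)
  expect_equal(out$homeoalleles[[1]]$gene_a, "a1")
  expect_equal(out$homeoalleles[[1]]$gene_b, "b1")
  expect_setequal(out$iorfans_a[[1]], "a2")
  expect_setequal(out$iorfans_b[[1]], "b2")
  rand <- hits[hits$gene_a == "a2" & hits$gene_b == "b2", ]
  expect_gt(rand$perm_p, 0.001)
})

test_that("divergent homeoalleles built at 50% identity are matched and the
           partition covers every member exactly once", {
  orfs <- lapply(1:3, function(i) random_orf_fixture(140, seed = i + 10))
  partners <- lapply(seq_along(orfs), function(i)
    withr::with_seed(i, panisles:::mutate_orf_to_aa_identity(orfs[[i]], 0.5, 0.5)))
  seqs <- c(setNames(unlist(orfs), paste0("a", 1:3)),
            setNames(unlist(partners), paste0("b", 1:3)),
            b4 = random_orf_fixture(140, seed = 99))
  fx <- fixture_islands_manual(paste0("a", 1:3), paste0("b", 1:4), seqs = seqs)
  pr <- find_conflicting_pairs(fx$islands)
  out <- homology_search(pr, fx$islands, fx$genes, seed = 2)
  hm <- out$homeoalleles[[1]]
  expect_equal(nrow(hm), 3L)
  expect_setequal(paste(hm$gene_a, hm$gene_b),
                  paste(paste0("a", 1:3), paste0("b", 1:3)))
  # partition completeness
  n_cov <- 2 * nrow(hm) + nrow(out$duplications[[1]]) +
    length(out$iorfans_a[[1]]) + length(out$iorfans_b[[1]])
  expect_equal(n_cov, out$n_a + out$n_b)
  # symmetry: swapping the islands yields the same partition
  fx_sw <- fx
  fx_sw$islands <- fx$islands[2:1, ]
  pr_sw <- find_conflicting_pairs(fx_sw$islands)
  out_sw <- homology_search(pr_sw, fx_sw$islands, fx$genes, seed = 2)
  expect_setequal(paste(out_sw$homeoalleles[[1]]$gene_b,
                        out_sw$homeoalleles[[1]]$gene_a),
                  paste(hm$gene_a, hm$gene_b))
})

test_that("an unbalanced duplication adds a one-to-many match", {
  base <- random_orf_fixture(150, seed = 21)
  copy <- withr::with_seed(7, panisles:::mutate_orf_to_aa_identity(base, 0.8, 0.5))
  fx <- fixture_islands_manual(c("a1", "a2"), "b1",
                               seqs = c(a1 = base, a2 = copy, b1 = base))
  pr <- find_conflicting_pairs(fx$islands)
  out <- homology_search(pr, fx$islands, fx$genes, seed = 3)
  expect_equal(nrow(out$homeoalleles[[1]]), 1L)
  expect_equal(nrow(out$duplications[[1]]), 1L)
  expect_length(out$iorfans_a[[1]], 0L)
  cls <- classify_pair(out)
  expect_equal(cls$matched_frac_a, 1.0)
  expect_equal(cls$matched_frac_b, 1.0)
})

test_that("lowering alpha never increases the homeoallele count", {
  sim <- fixture_pair_sim(seed = 4, hf = 0.5)
  graph <- build_pangraph(sim$genes)
  isl <- find_islands(graph, sim$genes)
  pr <- find_conflicting_pairs(isl)
  counts <- vapply(c(0.05, 0.005, 0.0005), function(al) {
    out <- homology_search(pr, isl, sim$genes, alpha = al, n_shuffles = 100,
                           seed = 11)
    nrow(out$homeoalleles[[1]])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the 50% rule is inclusive and applies to both islands", {
  fake_pair <- function(na, nb, n_matched) {
    hm <- tibble::tibble(gene_a = paste0("a", seq_len(n_matched)),
                         gene_b = paste0("b", seq_len(n_matched)),
                         aa_identity = 0.5, nt_identity = 0.5, perm_p = 0.001)
    tibble::tibble(pair_id = "p", island_a = "A", island_b = "B",
                   homeoalleles = list(hm),
                   duplications = list(hm[0, ]),
                   iorfans_a = list(paste0("a", setdiff(seq_len(na),
                                                        seq_len(n_matched)))),
                   iorfans_b = list(paste0("b", setdiff(seq_len(nb),
                                                        seq_len(n_matched)))),
                   n_a = na, n_b = nb)
  }
  # 5 of 7 and 5 of 6 matched -> homeocassette
  expect_equal(classify_pair(fake_pair(7, 6, 5))$classification, "homeocassette")
  # only a shared integrase: 1 of 14 vs 1 of 12 -> conflicting only
  expect_equal(classify_pair(fake_pair(14, 12, 1))$classification,
               "conflicting_only")
  # exactly 50% on both islands -> homeocassette (inclusive)
  expect_equal(classify_pair(fake_pair(4, 4, 2))$classification, "homeocassette")
  # 50% on one island, below on the other -> conflicting only
  expect_equal(classify_pair(fake_pair(4, 6, 2))$classification,
               "conflicting_only")
})

test_that("pair reports serialize the Table-1-style columns", {
  fx <- fixture_islands_manual("a1", "b1",
                               seqs = c(a1 = random_orf_fixture(100, seed = 1),
                                        b1 = random_orf_fixture(100, seed = 1)))
  pr <- find_conflicting_pairs(fx$islands)
  out <- classify_pair(homology_search(pr, fx$islands, fx$genes, seed = 1))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_pair_report(out, f1, f2)
  tab <- readr::read_tsv(f1, show_col_types = FALSE)
  expect_equal(tab$orfs, "1 vs 1")
  expect_equal(tab$n_homeoalleles, 1L)
})
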