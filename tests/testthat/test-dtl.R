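test_that("proto-phylogeny inference enforces the paper-style preconditions", {
  aln3 <- c(A = "ACGTACGTAA", B = "ACGTACGTAA", C = "ACGTACGTAA")
  expect_error(infer_gene_tree(aln3), class = "panisles_input_error")
  expect_error(infer_gene_tree(aln3[1:2]), class = "panisles_input_error")
  aln <- c(A = "AAAAAAAAAA", B = "AAAAAAAATT", C = "TTTTTTTTAA")
  tr <- infer_gene_tree(aln)
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))
})

test_that("a planted 4-taxon topology is recovered at 5% divergence", {
  aln <- withr::with_seed(2, {
    L <- 2000
    anc <- sample(c("A", "C", "G", "T"), L, TRUE)
    mut <- function(x, rate) {
      k <- rbinom(1, L, rate)
      i <- sample.int(L, k)
      x[i] <- vapply(x[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      x
    }
    a <- mut(anc, 0.05); b <- mut(anc, 0.05)
    lapply(list(A = mut(a, 0.01), B = mut(a, 0.01),
                C = mut(b, 0.01), D = mut(b, 0.01)),
           paste, collapse = "")
  })
  tr <- infer_gene_tree(unlist(aln))
  ref <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)
})

test_that("reconciliation reproduces the worked 3-leaf cases", {
  sp <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  congruent <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  r0 <- dtl_reconcile(congruent, sp, dtl_costs(2, 3, 1), n_samples = 20, seed = 1)
  expect_equal(r0$min_cost, 0)
  expect_equal(c(r0$D, r0$T, r0$L), c(0, 0, 0))

  transfer_case <- ape::read.tree(text = "((A:1,C:1):1,B:2);")
  r1 <- dtl_reconcile(transfer_case, sp, dtl_costs(2, 3, 1), n_samples = 50,
                      seed = 1)
  expect_equal(r1$min_cost, 3)
  expect_equal(c(r1$D, r1$T, r1$L), c(0, 1, 0))

  sp2 <- ape::read.tree(text = "(A:1,B:1);")
  dup_case <- ape::read.tree(text = "((A_1:1,A_2:1):1,B:2);")
  r2 <- dtl_reconcile(dup_case, sp2, dtl_costs(2, 3, 1), n_samples = 50, seed = 1)
  expect_equal(r2$min_cost, 2)
  expect_equal(c(r2$D, r2$T, r2$L), c(1, 0, 0))
})

test_that("every sampled scenario prices out to the minimum cost", {
  withr::with_seed(30, {
    for (i in 1:6) {
      sp <- ape::rtree(5, tip.label = LETTERS[1:5])
      gn <- ape::rtree(5, tip.label = sample(LETTERS[1:5]))
      for (costs in list(dtl_costs(2, 3, 1), dtl_costs(3, 3, 1))) {
        r <- dtl_reconcile(gn, sp, costs, n_samples = 40,
                           seed = i)
        priced <- costs[["d"]] * r$samples$D + costs[["t"]] * r$samples$T +
          costs[["l"]] * r$samples$L
        expect_true(all(priced == r$min_cost))
      }
    }
  })
})

test_that("with transfers priced out the DP reduces to duplication-loss
           parsimony", {
  withr::with_seed(31, {
    for (i in 1:6) {
      sp <- ape::rtree(5, tip.label = LETTERS[1:5])
      labs <- sample(LETTERS[1:5], 6, replace = TRUE)
      labs <- ifelse(duplicated(labs), paste0(labs, "_2"), labs)
      gn <- ape::rtree(6, tip.label = labs)
      got <- dtl_min_cost(gn, sp, dtl_costs(d = 2, t = 1e9, l = 1))
      want <- oracle_dl_cost(gn, sp, d_cost = 2, l_cost = 1)
      expect_equal(got, want)
    }
  })
})

test_that("optimal rooting minimizes cost deterministically", {
  sp <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  gn <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  rt <- optimal_root(gn, sp, dtl_costs(2, 3, 1))
  expect_equal(attr(rt, "root_cost"), 0)
  expect_true(ape::is.rooted(rt))
  # congruent rooting splits A,B from C,D like the species root
  kids <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1L, 2]
  expect_equal(attr(rt, "root_cost"), dtl_min_cost(rt, sp, dtl_costs(2, 3, 1)))
  rt2 <- optimal_root(gn, sp, dtl_costs(2, 3, 1))
  expect_identical(ape::write.tree(rt), ape::write.tree(rt2))
})

test_that("normalization and rate invariance behave as stated", {
  tr <- ape::read.tree(text = "((A:0.5,B:0.25):0.5,C:0.25);")
  # internal nodes = 2, total length = 1.5; T = 3 -> rate 1
  expect_equal(unname(normalize_events(c(T = 3), tr)[["T"]]), 1.0)
  expect_equal(unname(normalize_events(c(T = 0), tr)[["T"]]), 0)
  tr0 <- tr; tr0$edge.length <- rep(0, nrow(tr$edge))
  expect_error(normalize_events(c(T = 1), tr0),
               class = "panisles_degenerate_tree")
  # rates invariant under genome relabelling
  sp <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  gn <- ape::read.tree(text = "((A:1,C:1):1,B:2);")
  r <- dtl_reconcile(gn, sp, dtl_costs(2, 3, 1), n_samples = 30, seed = 2)
  relab <- function(phy) { phy$tip.label <- sub("A", "X", phy$tip.label); phy }
  r2 <- dtl_reconcile(relab(gn), relab(sp), dtl_costs(2, 3, 1),
                      n_samples = 30, seed = 2)
  expect_equal(normalize_events(c(T = r$T), gn),
               normalize_events(c(T = r2$T), relab(gn)))
})

test_that("Welch comparison matches the closed form and degenerate rules", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  out <- compare_island_vs_core(list(rate_d = a, rate_t = a, rate_l = a),
                                list(rate_d = b, rate_t = b, rate_l = b))
  # hand-computed Welch statistic
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(out$statistic[1], tstat)
  expect_equal(out$df[1], df)
  expect_equal(out$p_value[1], 2 * pt(-abs(tstat), df))
  same <- compare_island_vs_core(list(rate_d = a, rate_t = a, rate_l = a),
                                 list(rate_d = a, rate_t = a, rate_l = a))
  expect_true(all(same$p_value == 1))
  expect_error(
    compare_island_vs_core(list(rate_d = 1, rate_t = 1, rate_l = 1),
                           list(rate_d = b, rate_t = b, rate_l = b)),
    class = "panisles_input_error")
})

test_that("separated rate distributions are detected below the 1% level", {
  withr::with_seed(40, {
    isl <- rnorm(50, 0.23, 0.05)
    core <- rnorm(200, 0.15, 0.05)
    out <- compare_island_vs_core(
      list(rate_d = isl, rate_t = isl, rate_l = isl),
      list(rate_d = core, rate_t = core, rate_l = core))
    expect_lt(out$p_value[out$event == "transfer"], 0.01)
  })
})
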