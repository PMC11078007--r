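# Duplication-transfer-loss reconciliation: NJ proto-phylogenies, optimal
# rooting by reconciliation cost, an undated parsimony DTL dynamic program
# with uniform sampling of optimal event scenarios, rate normalization,
# and the island-vs-core rate comparison.

#' Infer a proto-phylogeny from a nucleotide alignment
#'
#' Neighbor joining on Jukes-Cantor corrected distances; negative branch
#' lengths are clamped to zero. Requires at least three taxa and
#' non-identical sequences.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @return An unrooted `phylo`.
#' @export
infer_gene_tree <- function(aln) {
  labs <- names(aln)
  aln <- setNames(as.character(aln), labs)
  if (length(aln) < 3) {
    abort("tree building needs at least three taxa",
          class = "panisles_input_error")
  }
  if (length(unique(aln)) == 1) {
    abort("tree building needs non-identical sequences",
          class = "panisles_input_error")
  }
  m <- do.call(rbind, strsplit(tolower(aln), ""))
  rownames(m) <- names(aln)
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "JC69",
                     pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 0.75) + 0.1
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' DTL event costs
#'
#' @param d,t,l Positive costs for duplication, transfer and loss. The
#'   conventional schemes are (2,3,1), (3,3,1) and (2,4,1).
#' @return Named numeric vector of class `dtl_costs`.
#' @export
dtl_costs <- function(d = 2, t = 3, l = 1) {
  stopifnot(d > 0, t > 0, l > 0)
  structure(c(d = d, t = t, l = l), class = "dtl_costs")
}

# ---- species tree preprocessing -------------------------------------------

species_index <- function(species) {
  stopifnot(inherits(species, "phylo"))
  if (!ape::is.rooted(species)) abort("species tree must be rooted",
                                      class = "panisles_input_error")
  if (!ape::is.binary(species)) species <- ape::multi2di(species)
  n_tip <- length(species$tip.label)
  n_node <- n_tip + species$Nnode
  kids <- matrix(0L, n_node, 2)
  for (r in seq_len(nrow(species$edge))) {
    p <- species$edge[r, 1]; c <- species$edge[r, 2]
    kids[p, if (kids[p, 1] == 0L) 1 else 2] <- c
  }
  po <- integer(0)   # postorder of all nodes
  stack <- n_tip + 1L; seen <- logical(n_node)
  while (length(stack)) {
    x <- stack[length(stack)]
    if (x <= n_tip || seen[x]) {
      po <- c(po, x); stack <- stack[-length(stack)]
    } else {
      seen[x] <- TRUE
      stack <- c(stack, kids[x, 1], kids[x, 2])
    }
  }
  desc <- matrix(FALSE, n_node, n_node)
  dist_e <- matrix(Inf, n_node, n_node)
  for (x in po) {
    desc[x, x] <- TRUE; dist_e[x, x] <- 0
    if (x > n_tip) {
      for (ch in kids[x, ]) {
        desc[x, ] <- desc[x, ] | desc[ch, ]
        dist_e[x, desc[ch, ]] <- dist_e[ch, desc[ch, ]] + 1
      }
    }
  }
  comparable <- desc | t(desc)
  list(tree = species, n_tip = n_tip, n_node = n_node, kids = kids,
       postorder = po, desc = desc, comparable = comparable,
       tip_of = setNames(seq_len(n_tip), species$tip.label))
}

gene_index <- function(gene, sp_idx) {
  stopifnot(inherits(gene, "phylo"))
  if (!ape::is.rooted(gene)) abort("gene tree must be rooted",
                                   class = "panisles_input_error")
  if (!ape::is.binary(gene)) gene <- ape::multi2di(gene)
  n_tip <- length(gene$tip.label)
  n_node <- n_tip + gene$Nnode
  kids <- matrix(0L, n_node, 2)
  for (r in seq_len(nrow(gene$edge))) {
    p <- gene$edge[r, 1]; c <- gene$edge[r, 2]
    kids[p, if (kids[p, 1] == 0L) 1 else 2] <- c
  }
  po <- integer(0); stack <- n_tip + 1L; seen <- logical(n_node)
  while (length(stack)) {
    x <- stack[length(stack)]
    if (x <= n_tip || seen[x]) { po <- c(po, x); stack <- stack[-length(stack)] }
    else { seen[x] <- TRUE; stack <- c(stack, kids[x, 1], kids[x, 2]) }
  }
  lab <- gene$tip.label
  sig <- sp_idx$tip_of[lab]
  miss <- is.na(sig)
  sig[miss] <- sp_idx$tip_of[sub("_\\d+$", "", lab[miss])]
  if (anyNA(sig)) {
    abort(paste("gene leaves not mappable to species:",
                paste(lab[is.na(sig)], collapse = ", ")),
          class = "panisles_input_error")
  }
  list(tree = gene, n_tip = n_tip, n_node = n_node, kids = kids,
       postorder = po, sigma = unname(sig))
}

# ---- the DP ----------------------------------------------------------------

# Fills cost and solution-count tables. C[u,x]: min cost of the subtree of
# gene node u when u maps to species node x. IN[u,x]: min over descendants
# x' of x of C[u,x'] plus one loss per edge descended. OUT[u,x]: min over
# species nodes incomparable to x of C[u,x'] (transfer landing).
dtl_tables <- function(gi, si, costs) {
  d <- costs[["d"]]; t <- costs[["t"]]; l <- costs[["l"]]
  nG <- gi$n_node; nS <- si$n_node
  C <- matrix(Inf, nG, nS); WC <- matrix(0, nG, nS)
  IN <- matrix(Inf, nG, nS); WIN <- matrix(0, nG, nS)
  OUT <- matrix(Inf, nG, nS); WOUT <- matrix(0, nG, nS)
  sp_po <- si$postorder
  for (u in gi$postorder) {
    if (u <= gi$n_tip) {
      C[u, gi$sigma[u]] <- 0; WC[u, gi$sigma[u]] <- 1
    } else {
      v <- gi$kids[u, 1]; w <- gi$kids[u, 2]
      for (x in sp_po) {
        opts_cost <- c(); opts_ways <- c()
        if (x > si$n_tip) {
          y <- si$kids[x, 1]; z <- si$kids[x, 2]
          opts_cost <- c(opts_cost, IN[v, y] + IN[w, z], IN[v, z] + IN[w, y])
          opts_ways <- c(opts_ways, WIN[v, y] * WIN[w, z], WIN[v, z] * WIN[w, y])
        }
        opts_cost <- c(opts_cost, d + IN[v, x] + IN[w, x],
                       t + IN[v, x] + OUT[w, x], t + IN[w, x] + OUT[v, x])
        opts_ways <- c(opts_ways, WIN[v, x] * WIN[w, x],
                       WIN[v, x] * WOUT[w, x], WIN[w, x] * WOUT[v, x])
        best <- min(opts_cost)
        C[u, x] <- best
        if (is.finite(best)) {
          WC[u, x] <- min(sum(opts_ways[opts_cost == best]), 1e250)
        }
      }
    }
    # IN via species postorder (children before parents)
    for (x in sp_po) {
      oc <- C[u, x]; ow <- WC[u, x]
      if (x > si$n_tip) {
        for (ch in si$kids[x, ]) {
          oc <- c(oc, l + IN[u, ch]); ow <- c(ow, WIN[u, ch])
        }
      }
      best <- min(oc)
      IN[u, x] <- best
      if (is.finite(best)) WIN[u, x] <- min(sum(ow[oc == best]), 1e250)
    }
    for (x in seq_len(nS)) {
      inc <- which(!si$comparable[x, ])
      if (length(inc)) {
        best <- min(C[u, inc])
        OUT[u, x] <- best
        if (is.finite(best)) {
          WOUT[u, x] <- min(sum(WC[u, inc][C[u, inc] == best]), 1e250)
        }
      }
    }
  }
  list(C = C, WC = WC, IN = IN, WIN = WIN, OUT = OUT, WOUT = WOUT)
}

#' Minimum DTL reconciliation cost
#'
#' @param gene Rooted binary gene tree (`phylo`); leaf labels map to
#'   species tips directly or after stripping a `_<digits>` copy suffix.
#' @param species Rooted binary species tree.
#' @param costs A [dtl_costs()].
#' @return The minimum total event cost (numeric).
#' @export
dtl_min_cost <- function(gene, species, costs = dtl_costs()) {
  si <- species_index(species)
  gi <- gene_index(gene, si)
  tb <- dtl_tables(gi, si, costs)
  root <- gi$n_tip + 1L
  min(tb$C[root, ])
}

# sample one optimal reconciliation; returns c(D, T, L)
sample_events <- function(gi, si, costs, tb) {
  d <- costs[["d"]]; t <- costs[["t"]]; l <- costs[["l"]]
  ev <- c(D = 0, T = 0, L = 0)
  pick <- function(ways) {
    w <- pmax(ways, 0)
    if (!sum(w)) w <- rep(1, length(w))
    sample.int(length(w), 1, prob = w)
  }
  go_C <- function(u, x) {
    if (u <= gi$n_tip) return(invisible())
    v <- gi$kids[u, 1]; w <- gi$kids[u, 2]
    kind <- c(); arg <- list(); cost <- c(); ways <- c()
    if (x > si$n_tip) {
      y <- si$kids[x, 1]; z <- si$kids[x, 2]
      kind <- c(kind, "s", "s")
      arg <- c(arg, list(c(y, z)), list(c(z, y)))
      cost <- c(cost, tb$IN[v, y] + tb$IN[w, z], tb$IN[v, z] + tb$IN[w, y])
      ways <- c(ways, tb$WIN[v, y] * tb$WIN[w, z], tb$WIN[v, z] * tb$WIN[w, y])
    }
    kind <- c(kind, "d", "t1", "t2"); arg <- c(arg, list(x), list(x), list(x))
    cost <- c(cost, d + tb$IN[v, x] + tb$IN[w, x],
              t + tb$IN[v, x] + tb$OUT[w, x],
              t + tb$IN[w, x] + tb$OUT[v, x])
    ways <- c(ways, tb$WIN[v, x] * tb$WIN[w, x],
              tb$WIN[v, x] * tb$WOUT[w, x], tb$WIN[w, x] * tb$WOUT[v, x])
    ok <- which(cost == tb$C[u, x])
    k <- ok[pick(ways[ok])]
    switch(kind[k],
      s = { go_IN(v, arg[[k]][1]); go_IN(w, arg[[k]][2]) },
      d = { ev["D"] <<- ev["D"] + 1; go_IN(v, x); go_IN(w, x) },
      t1 = { ev["T"] <<- ev["T"] + 1; go_IN(v, x); go_OUT(w, x) },
      t2 = { ev["T"] <<- ev["T"] + 1; go_IN(w, x); go_OUT(v, x) })
  }
  go_IN <- function(u, x) {
    cost <- tb$C[u, x]; ways <- tb$WC[u, x]; tgt <- list(list("stay", x))
    if (x > si$n_tip) {
      for (ch in si$kids[x, ]) {
        cost <- c(cost, l + tb$IN[u, ch]); ways <- c(ways, tb$WIN[u, ch])
        tgt <- c(tgt, list(list("down", ch)))
      }
    }
    ok <- which(cost == tb$IN[u, x])
    k <- ok[pick(ways[ok])]
    if (tgt[[k]][[1]] == "stay") go_C(u, x)
    else { ev["L"] <<- ev["L"] + 1; go_IN(u, tgt[[k]][[2]]) }
  }
  go_OUT <- function(u, x) {
    inc <- which(!si$comparable[x, ])
    best <- tb$OUT[u, x]
    cand <- inc[tb$C[u, inc] == best]
    x2 <- cand[pick(tb$WC[u, cand])]
    go_C(u, x2)
  }
  root <- gi$n_tip + 1L
  best <- min(tb$C[root, ])
  cand <- which(tb$C[root, ] == best)
  go_C(root, cand[pick(tb$WC[root, cand])])
  ev
}

#' Parsimony DTL reconciliation with sampled optimal scenarios
#'
#' Undated DTL dynamic program (transfers allowed between any two
#' non-ancestrally-related species edges). The minimum cost is exact;
#' event counts are averaged over `n_samples` uniform samples of optimal
#' backtraces (uniformity via dynamic-program solution counting).
#'
#' @inheritParams dtl_min_cost
#' @param n_samples Number of optimal scenarios to sample; default 300.
#' @param seed Integer seed.
#' @return A list of class `dtl_result`: `min_cost`, `D`, `T`, `L` (mean
#'   counts), `samples` (tibble of per-sample counts), `n_samples`,
#'   `costs`.
#' @export
dtl_reconcile <- function(gene, species, costs = dtl_costs(),
                          n_samples = 300, seed = 1) {
  si <- species_index(species)
  gi <- gene_index(gene, si)
  tb <- dtl_tables(gi, si, costs)
  root <- gi$n_tip + 1L
  mc <- min(tb$C[root, ])
  if (!is.finite(mc)) abort("no feasible reconciliation",
                            class = "panisles_input_error")
  samples <- with_seed(derive_seed(seed, "dtl-sample"), {
    t(vapply(seq_len(n_samples), function(.) sample_events(gi, si, costs, tb),
             numeric(3)))
  })
  colnames(samples) <- c("D", "T", "L")
  structure(list(min_cost = mc, D = mean(samples[, "D"]),
                 T = mean(samples[, "T"]), L = mean(samples[, "L"]),
                 samples = as_tibble(samples), n_samples = n_samples,
                 costs = costs),
            class = "dtl_result")
}

#' @export
print.dtl_result <- function(x, ...) {
  cat(sprintf("DTL reconciliation: min cost %g (d=%g,t=%g,l=%g); mean D=%.2f T=%.2f L=%.2f over %d samples\n",
              x$min_cost, x$costs[["d"]], x$costs[["t"]], x$costs[["l"]],
              x$D, x$T, x$L, x$n_samples))
  invisible(x)
}

#' @method tidy dtl_result
#' @export
tidy.dtl_result <- function(x, ...) {
  tibble(event = c("duplication", "transfer", "loss"),
         mean_count = c(x$D, x$T, x$L))
}

#' @method glance dtl_result
#' @export
glance.dtl_result <- function(x, ...) {
  tibble(min_cost = x$min_cost, D = x$D, T = x$T, L = x$L,
         n_samples = x$n_samples,
         cost_d = x$costs[["d"]], cost_t = x$costs[["t"]],
         cost_l = x$costs[["l"]])
}

#' Root a gene tree by minimizing DTL reconciliation cost
#'
#' Every edge of the (unrooted) gene tree is evaluated as a root position;
#' the rooting with minimal reconciliation cost is returned. Ties are
#' broken by the smallest edge index in the tree's postorder edge list, so
#' the result is deterministic.
#'
#' @param gene An unrooted (or rooted) `phylo`.
#' @param species Rooted binary species tree.
#' @param costs A [dtl_costs()].
#' @return A rooted binary `phylo`; attribute `root_cost` carries the
#'   minimal cost.
#' @export
optimal_root <- function(gene, species, costs = dtl_costs()) {
  tr <- if (ape::is.rooted(gene)) ape::unroot(gene) else gene
  tr <- ape::reorder.phylo(tr, "postorder")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  best <- NULL; best_cost <- Inf
  for (e in seq_len(nrow(tr$edge))) {
    node <- tr$edge[e, 2]
    cand <- tryCatch(
      phytools::reroot(tr, node.number = node,
                       position = tr$edge.length[e] / 2),
      error = function(err) NULL)
    if (is.null(cand) || !ape::is.rooted(cand)) next
    cost <- dtl_min_cost(cand, species, costs)
    if (cost < best_cost) { best_cost <- cost; best <- cand }
  }
  if (is.null(best)) abort("could not root gene tree",
                           class = "panisles_input_error")
  attr(best, "root_cost") <- best_cost
  best
}

#' Normalize event counts to rates
#'
#' `rate = count / (n_internal_nodes x total_branch_length)` of the gene
#' tree.
#'
#' @param counts Named numeric (e.g. `c(D=, T=, L=)`).
#' @param tree The gene tree (`phylo`).
#' @return Named numeric rates.
#' @export
normalize_events <- function(counts, tree) {
  n_int <- tree$Nnode
  tot <- sum(tree$edge.length)
  if (n_int < 1) abort("need at least one internal node",
                       class = "panisles_input_error")
  if (!isTRUE(tot > 0)) abort("zero total branch length: gene excluded",
                              class = "panisles_degenerate_tree")
  counts / (n_int * tot)
}

#' DTL analysis over a set of gene alignments
#'
#' For each alignment: proto-phylogeny by NJ, optimal rooting per cost
#' scheme, reconciliation against the species tree, normalization.
#' Alignments where tree building is impossible (fewer than three taxa or
#' identical sequences) or whose tree has zero branch length are skipped
#' and reported.
#'
#' @param alignments Named list of named nucleotide alignments.
#' @param species Rooted binary species tree.
#' @param schemes List of [dtl_costs()]; default the three conventional
#'   schemes (2,3,1), (3,3,1), (2,4,1).
#' @param n_samples Optimal-scenario samples per gene; default 300.
#' @param seed Integer seed.
#' @return Tibble: gene, scheme, min_cost, D, T, L, rate_d, rate_t,
#'   rate_l; attribute `skipped` lists excluded genes with reasons.
#' @export
dtl_analysis <- function(alignments, species,
                         schemes = list(dtl_costs(2, 3, 1),
                                        dtl_costs(3, 3, 1),
                                        dtl_costs(2, 4, 1)),
                         n_samples = 300, seed = 1) {
  rows <- list(); skipped <- list()
  for (g in names(alignments)) {
    tr <- tryCatch(infer_gene_tree(alignments[[g]]), error = function(e) e)
    if (inherits(tr, "error")) {
      skipped[[length(skipped) + 1]] <- tibble(gene = g,
                                               reason = conditionMessage(tr))
      next
    }
    for (sc in schemes) {
      lab <- paste0("(", sc[["d"]], ",", sc[["t"]], ",", sc[["l"]], ")")
      res <- tryCatch({
        rooted <- optimal_root(tr, species, sc)
        rec <- dtl_reconcile(rooted, species, sc, n_samples = n_samples,
                             seed = derive_seed(seed, paste(g, lab)))
        rates <- normalize_events(c(D = rec$D, T = rec$T, L = rec$L), rooted)
        tibble(gene = g, scheme = lab, min_cost = rec$min_cost,
               D = rec$D, T = rec$T, L = rec$L,
               rate_d = rates[["D"]], rate_t = rates[["T"]],
               rate_l = rates[["L"]])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1]] <- tibble(
          gene = g, reason = conditionMessage(res))
      } else rows[[length(rows) + 1]] <- res
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    gene = character(), scheme = character(), min_cost = double(),
    D = double(), T = double(), L = double(), rate_d = double(),
    rate_t = double(), rate_l = double())
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble(gene = character(), reason = character())
  out
}

#' Compare island against core normalized event rates
#'
#' Welch two-sided t-test per event class (duplication, transfer, loss).
#'
#' @param island_rates,core_rates Tibbles with columns `rate_d`, `rate_t`,
#'   `rate_l` (e.g. [dtl_analysis()] rows), or named lists of numeric
#'   vectors.
#' @return Tibble: event, mean_island, mean_core, statistic, df, p_value.
#' @export
compare_island_vs_core <- function(island_rates, core_rates) {
  get <- function(x, col) {
    if (is.data.frame(x)) x[[col]] else x[[col]]
  }
  rows <- lapply(c(rate_d = "duplication", rate_t = "transfer",
                   rate_l = "loss") |> names(), function(col) {
    a <- get(island_rates, col); b <- get(core_rates, col)
    if (length(a) < 2 || length(b) < 2) {
      abort("each sample needs at least 2 rates",
            class = "panisles_input_error")
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) {
        return(tibble(event = col, mean_island = mean(a), mean_core = mean(b),
                      statistic = 0, df = NA_real_, p_value = 1))
      }
      abort("degenerate samples: both variances zero",
            class = "panisles_input_error")
    }
    tt <- t.test(a, b, alternative = "two.sided", var.equal = FALSE)
    tibble(event = col, mean_island = mean(a), mean_core = mean(b),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$event <- c(rate_d = "duplication", rate_t = "transfer",
                 rate_l = "loss")[out$event]
  out
}
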