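# Independent oracles used across the suite. These re-derive expected
# values through a different computational route than the package code.

# ---- global-alignment identity (oracle for mutate_to_identity etc.) -------
oracle_identity <- function(a, b, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nt") {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                         Biostrings::DNAString(b),
                                         type = "global")
  } else {
    aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                         Biostrings::AAString(b),
                                         type = "global",
                                         substitutionMatrix = "BLOSUM62")
  }
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# ---- Tajima's D from scratch (site-frequency route) ------------------------
oracle_tajima_d <- function(aln) {
  m <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, ok, drop = FALSE]
  n <- nrow(m)
  # per-site heterozygosity route for pi, column scan for S
  S <- 0
  pi <- 0
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) > 1) S <- S + 1
    pi <- pi + (1 - sum((tab / n)^2)) * n / (n - 1)
  }
  if (S == 0) return(NA_real_)
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# ---- brute-force DTL minimum over all mappings -----------------------------
# Enumerates every assignment of internal gene nodes to species nodes and
# takes the cheapest valid event interpretation; independent of the DP.
oracle_dtl_min <- function(gene, species, costs) {
  sidx <- oracle_tree_index(species)
  n_tip_g <- length(gene$tip.label)
  kids_g <- matrix(0L, n_tip_g + gene$Nnode, 2)
  for (r in seq_len(nrow(gene$edge))) {
    p <- gene$edge[r, 1]; ch <- gene$edge[r, 2]
    kids_g[p, if (kids_g[p, 1] == 0L) 1 else 2] <- ch
  }
  lab <- gene$tip.label
  sig <- match(lab, species$tip.label)
  miss <- is.na(sig)
  sig[miss] <- match(sub("_\\d+$", "", lab[miss]), species$tip.label)
  stopifnot(!anyNA(sig))
  internals <- (n_tip_g + 1):(n_tip_g + gene$Nnode)
  nS <- sidx$n_node
  grid <- as.matrix(expand.grid(rep(list(seq_len(nS)), length(internals))))
  best <- Inf
  d <- costs[["d"]]; t <- costs[["t"]]; l <- costs[["l"]]
  for (r in seq_len(nrow(grid))) {
    map <- integer(n_tip_g + gene$Nnode)
    map[seq_len(n_tip_g)] <- sig
    map[internals] <- grid[r, ]
    cost <- 0
    for (u in internals) {
      x <- map[u]; m1 <- map[kids_g[u, 1]]; m2 <- map[kids_g[u, 2]]
      opts <- c()
      if (sidx$desc[x, m1] && sidx$desc[x, m2]) {
        if (x > sidx$n_tip) {
          y <- sidx$kids[x, 1]; z <- sidx$kids[x, 2]
          if (sidx$desc[y, m1] && sidx$desc[z, m2]) {
            opts <- c(opts, l * (sidx$dist[y, m1] + sidx$dist[z, m2]))
          }
          if (sidx$desc[z, m1] && sidx$desc[y, m2]) {
            opts <- c(opts, l * (sidx$dist[z, m1] + sidx$dist[y, m2]))
          }
        }
        opts <- c(opts, d + l * (sidx$dist[x, m1] + sidx$dist[x, m2]))
      }
      if (!sidx$comp[x, m1] && sidx$desc[x, m2]) {
        opts <- c(opts, t + l * sidx$dist[x, m2])
      }
      if (!sidx$comp[x, m2] && sidx$desc[x, m1]) {
        opts <- c(opts, t + l * sidx$dist[x, m1])
      }
      if (!length(opts)) { cost <- Inf; break }
      cost <- cost + min(opts)
    }
    if (cost < best) best <- cost
  }
  best
}

oracle_tree_index <- function(tr) {
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  kids <- matrix(0L, n_node, 2)
  parent <- integer(n_node)
  for (r in seq_len(nrow(tr$edge))) {
    p <- tr$edge[r, 1]; ch <- tr$edge[r, 2]
    kids[p, if (kids[p, 1] == 0L) 1 else 2] <- ch
    parent[ch] <- p
  }
  desc <- matrix(FALSE, n_node, n_node)
  dist <- matrix(Inf, n_node, n_node)
  anc_path <- function(x) {
    out <- x
    while (parent[x] != 0L) { x <- parent[x]; out <- c(out, x) }
    out
  }
  for (y in seq_len(n_node)) {
    path <- anc_path(y)
    for (k in seq_along(path)) {
      desc[path[k], y] <- TRUE
      dist[path[k], y] <- k - 1
    }
  }
  list(n_tip = n_tip, n_node = n_node, kids = kids, desc = desc,
       dist = dist, comp = desc | t(desc))
}

# ---- duplication-loss parsimony by LCA mapping (transfers forbidden) -------
oracle_dl_cost <- function(gene, species, d_cost, l_cost) {
  sidx <- oracle_tree_index(species)
  n_tip_g <- length(gene$tip.label)
  kids_g <- matrix(0L, n_tip_g + gene$Nnode, 2)
  for (r in seq_len(nrow(gene$edge))) {
    p <- gene$edge[r, 1]; ch <- gene$edge[r, 2]
    kids_g[p, if (kids_g[p, 1] == 0L) 1 else 2] <- ch
  }
  lab <- gene$tip.label
  sig <- match(lab, species$tip.label)
  miss <- is.na(sig)
  sig[miss] <- match(sub("_\\d+$", "", lab[miss]), species$tip.label)
  lca <- function(a, b) {
    pa <- which(sidx$desc[, a]); pb <- which(sidx$desc[, b])
    anc <- intersect(pa, pb)
    anc[which.min(rowSums(sidx$desc[anc, , drop = FALSE]))]
  }
  map <- integer(n_tip_g + gene$Nnode)
  map[seq_len(n_tip_g)] <- sig
  dups <- 0; losses <- 0
  po <- function(u) {
    if (u <= n_tip_g) return(invisible())
    v <- kids_g[u, 1]; w <- kids_g[u, 2]
    po(v); po(w)
    map[u] <<- lca(map[v], map[w])
  }
  root <- n_tip_g + 1L
  po(root)
  for (u in (n_tip_g + 1):(n_tip_g + gene$Nnode)) {
    v <- kids_g[u, 1]; w <- kids_g[u, 2]
    is_dup <- map[u] == map[v] || map[u] == map[w]
    if (is_dup) dups <- dups + 1
    for (ch in c(v, w)) {
      dd <- sidx$dist[map[u], map[ch]]
      losses <- losses + if (is_dup) dd else max(dd - 1, 0)
    }
  }
  d_cost * dups + l_cost * losses
}

# ---- brute-force island scan (single linear path per locus) ----------------
oracle_island_runs <- function(genes, divisions) {
  runs <- list()
  for (key in split(seq_len(nrow(genes)),
                    paste(genes$genome_id, genes$contig_id, sep = "\r"))) {
    ord <- genes$family_id[key][order(genes$index[key])]
    core <- divisions[ord] == "core"
    i <- 1
    while (i <= length(ord)) {
      if (!core[i]) {
        j <- i
        while (j < length(ord) && !core[j + 1]) j <- j + 1
        if (i > 1 && j < length(ord)) {
          runs[[length(runs) + 1]] <- list(
            genome = genes$genome_id[key[1]],
            flanks = sort(c(ord[i - 1], ord[j + 1])),
            members = ord[i:j])
        }
        i <- j + 1
      } else i <- i + 1
    }
  }
  runs
}

# ---- adjusted Rand index ---------------------------------------------------
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
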