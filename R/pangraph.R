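# Pan-genome data model: gene families, genome representation, and the
# adjacency graph built from ordered gene calls.

#' Cluster genes into families by global nucleotide identity
#'
#' Greedy single-linkage clustering: any gene pair whose global alignment
#' identity reaches the threshold joins the same family. Identical
#' sequences are collapsed first; remaining pairs are aligned with
#' [Biostrings::pairwiseAlignment()]. Family ids are assigned in order of
#' first appearance (genes sorted by their `(genome_id, contig_id, index)`
#' key), so the assignment is deterministic.
#'
#' @param genes Tibble of gene records with `nt_seq` present.
#' @param identity_threshold Fraction in (0, 1]; default 0.98.
#' @return The input tibble with `family_id` replaced by the computed
#'   assignment (`fam_00001`, ...).
#' @export
cluster_families <- function(genes, identity_threshold = 0.98) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(genes) == 0) return(dplyr::mutate(genes, family_id = character(0)))
  if (anyNA(genes$nt_seq)) {
    abort("cluster_families requires nt_seq for every gene",
          class = "panisles_input_error")
  }
  genes <- dplyr::arrange(genes, .data$genome_id, .data$contig_id, .data$index)
  seqs <- genes$nt_seq
  uniq <- unique(seqs)
  n <- length(uniq)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  lens <- nchar(uniq)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        # global identity counts gaps; a length ratio below the threshold
        # already caps identity below it
        if (min(lens[i], lens[j]) / max(lens[i], lens[j]) < identity_threshold) next
        if (find(i) == find(j)) next
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(uniq[i]), Biostrings::DNAString(uniq[j]),
          type = "global")
        ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
        if (ident >= identity_threshold) union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  fam_of_root <- setNames(sprintf("fam_%05d", seq_along(unique(roots))),
                          unique(roots))
  fam_uniq <- fam_of_root[as.character(roots)]
  dplyr::mutate(genes, family_id = unname(fam_uniq[match(seqs, uniq)]))
}

#' Build the pan-genome graph from ordered gene calls
#'
#' Nodes are pan-gene families with their genome representation; an edge
#' joins two families wherever they are adjacent in the gene order of at
#' least one genome, and carries the set of supporting genomes. Edges never
#' cross contig boundaries, are unordered (strand-agnostic), and a genome
#' supports an edge once regardless of copy number.
#'
#' @param genes Tibble of gene records with `family_id` assigned.
#' @param core_threshold Core representation cutoff (count). Default: 44
#'   when there are 47 genomes, else `ceiling(0.94 * n_genomes)`.
#' @return A `pan_graph`: list with `nodes` (family_id, name,
#'   representation, division), `edges` (from, to, support list-column,
#'   n_support), `n_genomes`, `core_threshold`.
#' @export
build_pangraph <- function(genes, core_threshold = NULL) {
  stopifnot(!anyNA(genes$family_id))
  n_genomes <- dplyr::n_distinct(genes$genome_id)
  if (is.null(core_threshold)) {
    core_threshold <- if (n_genomes == 47) 44L else ceiling(0.94 * n_genomes)
  }
  nodes <- genes |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      name = {
        a <- unique(.data$annotation[!is.na(.data$annotation)])
        if (length(a) == 1) a else .data$family_id[1]
      },
      representation = dplyr::n_distinct(.data$genome_id), .groups = "drop")
  g <- dplyr::arrange(genes, .data$genome_id, .data$contig_id, .data$index)
  adj <- g |>
    dplyr::group_by(.data$genome_id, .data$contig_id) |>
    dplyr::reframe(a = head(.data$family_id, -1), b = tail(.data$family_id, -1))
  edges <- if (nrow(adj)) {
    adj |>
      dplyr::mutate(from = pmin(.data$a, .data$b), to = pmax(.data$a, .data$b)) |>
      dplyr::distinct(.data$from, .data$to, .data$genome_id) |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(support = list(sort(unique(.data$genome_id))),
                       .groups = "drop") |>
      dplyr::mutate(n_support = lengths(.data$support))
  } else {
    tibble(from = character(), to = character(), support = list(),
           n_support = integer())
  }
  graph <- structure(list(nodes = nodes, edges = edges, n_genomes = n_genomes,
                          core_threshold = as.integer(core_threshold)),
                     class = "pan_graph")
  graph$nodes <- classify_families(graph)
  graph
}

#' Partition families into core, shell and cloud
#'
#' Core: representation at or above the core threshold (44 of 47 by
#' default, ~94%). Cloud: found in exactly one genome. Shell: everything
#' in between (at least two genomes, below the core threshold).
#'
#' @param graph A `pan_graph`.
#' @return The graph's node tibble with a `division` column.
#' @export
classify_families <- function(graph) {
  stopifnot(inherits(graph, "pan_graph"))
  dplyr::mutate(graph$nodes, division = dplyr::case_when(
    .data$representation >= graph$core_threshold ~ "core",
    .data$representation == 1 ~ "cloud",
    TRUE ~ "shell"))
}

#' @export
print.pan_graph <- function(x, ...) {
  tab <- table(x$nodes$division)
  cat("Pan-genome graph:", nrow(x$nodes), "families (",
      paste(names(tab), unname(tab), collapse = ", "), "),",
      nrow(x$edges), "adjacency edges,", x$n_genomes, "genomes, core >=",
      x$core_threshold, "\n")
  invisible(x)
}

#' Summaries of a pan-genome graph
#'
#' `tidy()` returns the family table; `glance()` one row of pan-genome
#' division counts.
#'
#' @param x A `pan_graph`.
#' @param ... Unused.
#' @method tidy pan_graph
#' @export
tidy.pan_graph <- function(x, ...) x$nodes

#' @rdname tidy.pan_graph
#' @method glance pan_graph
#' @export
glance.pan_graph <- function(x, ...) {
  tibble(n_families = nrow(x$nodes),
         n_core = sum(x$nodes$division == "core"),
         n_shell = sum(x$nodes$division == "shell"),
         n_cloud = sum(x$nodes$division == "cloud"),
         n_edges = nrow(x$edges), n_genomes = x$n_genomes,
         core_threshold = x$core_threshold)
}

#' Convert a pan-genome graph to igraph
#'
#' @param graph A `pan_graph`.
#' @return An [igraph::graph] with node attributes `representation`,
#'   `division` and edge attribute `n_support`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "pan_graph"))
  ig <- igraph::graph_from_data_frame(
    d = dplyr::mutate(graph$edges,
                      members = map_chr(.data$support, paste, collapse = ";"),
                      support = NULL),
    directed = FALSE,
    vertices = graph$nodes)
  ig
}

#' Write a pan-genome graph as GML
#'
#' @param graph A `pan_graph`.
#' @param path Output file.
#' @export
write_graph_gml <- function(graph, path) {
  # fixed creator string keeps the output byte-stable across runs
  igraph::write_graph(as_igraph(graph), path, format = "gml",
                      creator = "panisles")
  invisible(path)
}

#' Write the family table as TSV
#'
#' Columns: family_id, name, representation, division.
#'
#' @param graph A `pan_graph`.
#' @param path Output file.
#' @export
write_family_table <- function(graph, path) {
  readr::write_tsv(graph$nodes, path)
  invisible(path)
}

#' Import a Panaroo-style pan-genome
#'
#' Reads a `gene_presence_absence` table (csv dialect with `Gene`,
#' `Annotation` and per-genome columns, or a binary Rtab) and, optionally,
#' a `final_graph.gml`. Node and edge counts of the returned graph match
#' the GML file exactly; representation comes from the presence/absence
#' table when available, else from GML `size`/`members` attributes.
#'
#' @param presence_absence Path to `gene_presence_absence.csv` or `.Rtab`,
#'   or `NULL`.
#' @param gml Path to the graph GML, or `NULL` (adjacency then unavailable).
#' @param core_threshold Core cutoff; defaults as in [build_pangraph()].
#' @return A `pan_graph`.
#' @export
read_panaroo <- function(presence_absence = NULL, gml = NULL,
                         core_threshold = NULL) {
  if (is.null(presence_absence) && is.null(gml)) {
    abort("need at least one of presence_absence or gml",
          class = "panisles_config_error")
  }
  rep_tbl <- NULL; n_genomes <- NA_integer_
  if (!is.null(presence_absence)) {
    if (!file.exists(presence_absence)) {
      abort(paste("missing file:", presence_absence),
            class = "panisles_config_error")
    }
    if (grepl("\\.Rtab$", presence_absence)) {
      m <- readr::read_tsv(presence_absence, show_col_types = FALSE)
      gcols <- names(m)[-1]
      rep_tbl <- tibble(family_id = m[[1]], name = m[[1]],
                        representation = rowSums(m[gcols] > 0))
    } else {
      m <- readr::read_csv(presence_absence, show_col_types = FALSE)
      meta <- intersect(names(m), c("Gene", "Non-unique Gene name", "Annotation"))
      gcols <- setdiff(names(m), meta)
      rep_tbl <- tibble(
        family_id = m$Gene,
        name = if ("Annotation" %in% names(m)) {
          ifelse(is.na(m$Annotation) | m$Annotation == "", m$Gene, m$Annotation)
        } else m$Gene,
        representation = rowSums(!is.na(m[gcols]) & m[gcols] != ""))
    }
    n_genomes <- length(gcols)
  }
  edges <- tibble(from = character(), to = character(), support = list(),
                  n_support = integer())
  if (!is.null(gml)) {
    if (!file.exists(gml)) {
      abort(paste("missing file:", gml), class = "panisles_config_error")
    }
    ig <- igraph::read_graph(gml, format = "gml")
    va <- igraph::vertex_attr(ig)
    node_ids <- va$name %||% va$label %||% as.character(seq_len(igraph::vcount(ig)))
    el <- igraph::as_edgelist(ig, names = FALSE)
    ea <- igraph::edge_attr(ig)
    support <- if (!is.null(ea$members)) {
      lapply(strsplit(as.character(ea$members), "[;,]"), trimws)
    } else rep(list(character()), nrow(el))
    edges <- tibble(from = pmin(node_ids[el[, 1]], node_ids[el[, 2]]),
                    to = pmax(node_ids[el[, 1]], node_ids[el[, 2]]),
                    support = support,
                    n_support = lengths(support))
    rep_attr <- va$representation %||% va$size
    gml_nodes <- tibble(family_id = node_ids,
                        name = va$label %||% node_ids,
                        representation = if (!is.null(rep_attr)) {
                          as.integer(rep_attr)
                        } else NA_integer_)
    if (is.null(rep_tbl)) rep_tbl <- gml_nodes
    else {
      rep_tbl <- dplyr::bind_rows(
        rep_tbl,
        dplyr::filter(gml_nodes, !(.data$family_id %in% rep_tbl$family_id)))
      rep_tbl <- dplyr::semi_join(rep_tbl, tibble(family_id = node_ids),
                                  by = "family_id")
      rep_tbl <- rep_tbl[match(node_ids, rep_tbl$family_id), ]
    }
  }
  if (is.na(n_genomes)) {
    reps <- rep_tbl$representation
    n_genomes <- if (any(is.finite(reps))) max(reps, na.rm = TRUE) else
      max(c(1L, unlist(lapply(edges$support, length))))
  }
  if (is.null(core_threshold)) {
    core_threshold <- if (n_genomes == 47) 44L else ceiling(0.94 * n_genomes)
  }
  graph <- structure(list(nodes = rep_tbl, edges = edges,
                          n_genomes = as.integer(n_genomes),
                          core_threshold = as.integer(core_threshold)),
                     class = "pan_graph")
  graph$nodes <- classify_families(graph)
  graph
}
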