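# Pipeline orchestration: run all analysis stages in dependency order on
# synthetic, FASTA+GFF3 or Panaroo-style input, with a manifest recording
# inputs, seeds and per-stage record counts.

#' Pipeline configuration
#'
#' @param mode Input mode: `"synthetic"`, `"fasta_gff"` or `"panaroo"`.
#' @param stages Stages to run, in dependency order among
#'   `"pangraph"`, `"islands"`, `"pairs"`, `"tani"`, `"popgen"`, `"dtl"`.
#' @param synth A [synth_config()] (synthetic mode).
#' @param input_dir Directory of per-genome `<id>.fasta` / `<id>.gff3`
#'   (fasta_gff mode).
#' @param presence_absence,gml Panaroo file paths (panaroo mode; only the
#'   pangraph stage is available without per-genome gene orders).
#' @param core_threshold,min_len,max_len,radius,alpha,n_shuffles,fragment_len,n_boot,n_dtl_samples,levels
#'   Stage parameters (see the stage functions).
#' @param n_dtl_core Number of core families reconciled in the dtl stage.
#' @param seed Top-level seed; all stage seeds derive from it.
#' @param out_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "fasta_gff", "panaroo"),
                            stages = c("pangraph", "islands", "pairs",
                                       "tani", "popgen", "dtl"),
                            synth = NULL, input_dir = NULL,
                            presence_absence = NULL, gml = NULL,
                            core_threshold = NULL, min_len = 2, max_len = 40,
                            radius = 5, alpha = 0.001, n_shuffles = 200,
                            fragment_len = 1020, n_boot = 100,
                            n_dtl_samples = 300, n_dtl_core = 15, levels = 2,
                            seed = 1, out_dir = tempfile("panisles_run_")) {
  mode <- match.arg(mode)
  known <- c("pangraph", "islands", "pairs", "tani", "popgen", "dtl")
  stopifnot(all(stages %in% known))
  if (mode == "synthetic" && is.null(synth)) synth <- synth_config(seed = seed)
  if (mode == "fasta_gff" && (is.null(input_dir) || !dir.exists(input_dir))) {
    abort("fasta_gff mode needs an existing input_dir",
          class = "panisles_config_error")
  }
  if (mode == "panaroo") {
    for (p in c(presence_absence, gml)) {
      if (!is.null(p) && !file.exists(p)) {
        abort(paste("missing file:", p), class = "panisles_config_error")
      }
    }
  }
  structure(list(mode = mode, stages = intersect(known, stages), synth = synth,
                 input_dir = input_dir, presence_absence = presence_absence,
                 gml = gml, core_threshold = core_threshold, min_len = min_len,
                 max_len = max_len, radius = radius, alpha = alpha,
                 n_shuffles = n_shuffles, fragment_len = fragment_len,
                 n_boot = n_boot, n_dtl_samples = n_dtl_samples,
                 n_dtl_core = n_dtl_core, levels = levels,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage_deps <- list(pangraph = character(), islands = "pangraph",
                   pairs = "islands", tani = character(),
                   popgen = "pangraph", dtl = "tani")

#' Run the full pipeline
#'
#' Stages execute in dependency order (`pangraph -> islands -> pairs`;
#' `tani`; `popgen`; `tani -> dtl`); a stage failure is recorded in the
#' manifest and its dependents are skipped. Re-running with an identical
#' config and inputs reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list): per-stage status and record counts,
#'   input hash, seed, output files. Invisibly also attached as attribute
#'   to the returned results list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mode = config$mode, seed = config$seed, stages = list(),
                   outputs = character())
  results <- list()
  emit <- function(path) {
    manifest$outputs <<- c(manifest$outputs, basename(path))
    path
  }
  fail <- character()  # failed stages (dependents skip)

  # ---- inputs
  genes <- NULL; graph0 <- NULL
  if (config$mode == "synthetic") {
    sim <- generate(config$synth, sequences = "all")
    genes <- sim$genes
    results$truth <- sim$truth
  } else if (config$mode == "fasta_gff") {
    fas <- sort(list.files(config$input_dir, "\\.fasta$", full.names = TRUE))
    genes <- dplyr::bind_rows(lapply(fas, function(f) {
      g <- sub("\\.fasta$", "", basename(f))
      read_genome_calls(sub("\\.fasta$", ".gff3", f), f, g)
    }))
  } else {
    graph0 <- read_panaroo(config$presence_absence, config$gml,
                           config$core_threshold)
  }
  manifest$input_hash <- digest::digest(genes %||% graph0)

  ran <- character()
  for (st in config$stages) {
    if (any(stage_deps[[st]] %in% fail) ||
        !all(stage_deps[[st]] %in% c(ran, "")) &&
        length(setdiff(stage_deps[[st]], ran))) {
      missing_dep <- setdiff(stage_deps[[st]], ran)
      manifest$stages[[st]] <- list(status = "skipped",
                                    reason = paste("dependency not run:",
                                                   paste(missing_dep, collapse = ",")))
      next
    }
    res <- tryCatch(
      run_stage(st, config, genes, graph0, results, emit),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[st]] <- list(status = "failed",
                                    reason = conditionMessage(res))
      fail <- c(fail, st)
    } else {
      results[names(res$results)] <- res$results
      manifest$stages[[st]] <- list(status = "ok", n_records = res$n_records)
      ran <- c(ran, st)
    }
  }
  manifest$ok <- length(fail) == 0
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!manifest$ok) {
    warn(paste("pipeline stages failed:", paste(fail, collapse = ", ")))
  }
  attr(results, "manifest") <- manifest
  invisible(structure(results, class = "panisles_run"))
}

run_stage <- function(st, config, genes, graph0, results, emit) {
  out <- config$out_dir
  seed <- config$seed
  switch(st,
    pangraph = {
      graph <- graph0 %||% build_pangraph(genes, config$core_threshold)
      write_family_table(graph, emit(file.path(out, "families.tsv")))
      write_graph_gml(graph, emit(file.path(out, "pangraph.gml")))
      list(results = list(graph = graph), n_records = nrow(graph$nodes))
    },
    islands = {
      if (is.null(genes)) abort("island discovery needs per-genome gene orders")
      isl <- find_islands(results$graph, genes, min_len = config$min_len,
                          max_len = config$max_len)
      nb <- neighborhood_scan(isl, genes, radius = config$radius)
      write_island_table(isl, emit(file.path(out, "islands.tsv")))
      readr::write_tsv(islands_report(isl),
                       emit(file.path(out, "islands_discarded.tsv")))
      readr::write_tsv(nb, emit(file.path(out, "island_neighborhood.tsv")))
      readr::write_tsv(island_presence_matrix(isl, sort(unique(genes$genome_id))),
                       emit(file.path(out, "island_presence.tsv")))
      list(results = list(islands = isl, neighborhood = nb),
           n_records = nrow(isl))
    },
    pairs = {
      pr <- find_conflicting_pairs(results$islands)
      if (nrow(pr)) {
        pr <- homology_search(pr, results$islands, genes,
                              alpha = config$alpha,
                              n_shuffles = config$n_shuffles,
                              seed = derive_seed(seed, "pairs"))
        pr <- classify_pair(pr)
      }
      write_pair_report_or_empty(pr, emit(file.path(out, "pairs.tsv")),
                                 emit(file.path(out, "homeoalleles.tsv")))
      list(results = list(pairs = pr), n_records = nrow(pr))
    },
    tani = {
      gseqs <- genome_sequences(genes)
      dm <- tani_matrix(gseqs, fragment_len = config$fragment_len)
      phy <- bootstrap_supports(dm, n_reps = config$n_boot,
                                seed = derive_seed(seed, "tani"))
      write_dist_tsv(dm, emit(file.path(out, "tani_dist.tsv")))
      write_tree_newick(phy, emit(file.path(out, "tani_tree.nwk")))
      list(results = list(tani = phy), n_records = nrow(dm))
    },
    popgen = {
      alns <- core_alignments(results$graph, genes)
      tj <- tajima_table(alns)
      neutral <- tj$family_id[tj$neutral]
      readr::write_tsv(tj, emit(file.path(out, "tajima.tsv")))
      pops <- if (length(neutral)) {
        snp <- suppressWarnings(build_snp_matrix(alns[neutral],
                                genomes = sort(unique(genes$genome_id))))
        write_snp_tsv(snp, emit(file.path(out, "snp_matrix.tsv")))
        cluster_populations(snp, max_levels = config$levels,
                            seed = derive_seed(seed, "popgen"))
      } else {
        warn("no neutral core families; population assignment trivial")
        tibble(genome_id = sort(unique(genes$genome_id)),
               level1 = "P1", level2 = "P1.1")
      }
      readr::write_tsv(pops, emit(file.path(out, "populations.tsv")))
      list(results = list(tajima = tj, populations = pops),
           n_records = nrow(tj))
    },
    dtl = {
      species <- midpoint_root(results$tani$tree)
      alns <- dtl_alignments(config, results, genes)
      dt <- dtl_analysis(alns$all, species, n_samples = config$n_dtl_samples,
                         seed = derive_seed(seed, "dtl"))
      dt$class <- ifelse(dt$gene %in% alns$island_ids, "island", "core")
      readr::write_tsv(dt, emit(file.path(out, "dtl_events.tsv")))
      cmp <- NULL
      isl_r <- dt[dt$class == "island" & dt$scheme == "(2,3,1)", ]
      core_r <- dt[dt$class == "core" & dt$scheme == "(2,3,1)", ]
      if (nrow(isl_r) >= 2 && nrow(core_r) >= 2) {
        cmp <- tryCatch(compare_island_vs_core(isl_r, core_r),
                        error = function(e) NULL)
        if (!is.null(cmp)) {
          readr::write_tsv(cmp, emit(file.path(out, "dtl_comparison.tsv")))
        }
      }
      list(results = list(dtl = dt, dtl_comparison = cmp),
           n_records = nrow(dt))
    })
}

write_pair_report_or_empty <- function(pr, path, map_path) {
  if (nrow(pr) && "homeoalleles" %in% names(pr)) {
    write_pair_report(pr, path, map_path)
  } else {
    readr::write_tsv(tibble(pair_id = character(), island_a = character(),
                            island_b = character(), classification = character()),
                     path)
    readr::write_tsv(tibble(pair_id = character(), gene_a = character(),
                            gene_b = character()), map_path)
  }
}

# per-core-family alignments (named genome -> sequence); SNP-only synthetic
# sequences are equal-length by construction, real inputs must be aligned
core_alignments <- function(graph, genes) {
  core <- graph$nodes$family_id[graph$nodes$division == "core"]
  gg <- genes[genes$family_id %in% core & !is.na(genes$nt_seq), ]
  alns <- lapply(split(gg, gg$family_id), function(d) {
    d <- d[!duplicated(d$genome_id), ]
    s <- setNames(d$nt_seq, d$genome_id)
    if (length(unique(nchar(s))) != 1) NULL else s
  })
  alns[!vapply(alns, is.null, logical(1))]
}

dtl_alignments <- function(config, results, genes) {
  isl <- results$islands
  island_alns <- list()
  if (!is.null(isl) && nrow(isl)) {
    seqs <- island_carrier_seqs(isl, genes)
    for (id in unique(seqs$island_id)) {
      s <- seqs[seqs$island_id == id, ]
      v <- setNames(s$seq, s$genome_id)
      v <- v[!duplicated(names(v))]
      if (length(v) >= 3 && length(unique(nchar(v))) == 1 &&
          length(unique(v)) > 1) {
        island_alns[[id]] <- v
      }
    }
  }
  core_alns <- core_alignments(results$graph, genes)
  # deterministic subsample of core families for reconciliation
  pickable <- names(core_alns)[vapply(core_alns, function(a)
    length(a) >= 3 && length(unique(a)) > 1, logical(1))]
  picked <- with_seed(derive_seed(config$seed, "dtl-core"), {
    sample(pickable, min(config$n_dtl_core, length(pickable)))
  })
  list(all = c(island_alns, core_alns[picked]),
       island_ids = names(island_alns))
}

midpoint_root <- function(tree) {
  rt <- tryCatch(phytools::midpoint_root(tree), error = function(e) NULL)
  if (is.null(rt)) rt <- ape::root(tree, outgroup = tree$tip.label[1],
                                   resolve.root = TRUE)
  if (!ape::is.binary(rt)) rt <- ape::multi2di(rt)
  rt
}

#' Pipeline run summaries
#'
#' @param x A `panisles_run` from [run_pipeline()].
#' @param ... Unused.
#' @method glance panisles_run
#' @export
glance.panisles_run <- function(x, ...) {
  m <- attr(x, "manifest")
  tibble(mode = m$mode, seed = m$seed, ok = m$ok,
         n_stages_ok = sum(vapply(m$stages, function(s)
           s$status == "ok", logical(1))),
         n_islands = if (!is.null(x$islands)) nrow(x$islands) else NA_integer_,
         n_pairs = if (!is.null(x$pairs)) nrow(x$pairs) else NA_integer_)
}
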