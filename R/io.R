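# Readers and writers for the standard interchange formats: per-genome
# FASTA + GFF3 gene calls, truth tables, and key=value config files.

SPACER <- "TTAACTGATCAGGCCTTAAG"  # fixed 20-nt intergenic spacer

# Per-genome contig sequences implied by a gene table (genes joined by the
# fixed spacer). Returns a named list of named character vectors.
genome_sequences <- function(genes) {
  stopifnot(!anyNA(genes$nt_seq))
  genes <- dplyr::arrange(genes, .data$genome_id, .data$contig_id, .data$index)
  lapply(split(genes, genes$genome_id), function(gg) {
    vapply(split(gg, gg$contig_id), function(cc) {
      paste(cc$nt_seq[order(cc$index)], collapse = SPACER)
    }, character(1))
  })
}

#' Write a synthetic pan-genome to disk
#'
#' One FASTA per genome, one GFF3 per genome (with `locus_tag`, `family`
#' and `product` attributes; tRNA genes typed `tRNA`), the truth tables as
#' TSV, and the configuration as a key=value text file.
#'
#' @param sim A `synth_pangenome` from [generate()] (with sequences).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genomes <- function(sim, dir) {
  stopifnot(inherits(sim, "synth_pangenome"))
  if (anyNA(sim$genes$nt_seq)) {
    abort("write_genomes needs sequences; run generate(..., sequences = 'all')",
          class = "panisles_input_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in unique(sim$genes$genome_id)) {
    gg <- dplyr::filter(sim$genes, .data$genome_id == g) |>
      dplyr::arrange(.data$contig_id, .data$index)
    ctg_seqs <- vapply(split(gg, gg$contig_id), function(cc)
      paste(cc$nt_seq[order(cc$index)], collapse = SPACER), character(1))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ctg_seqs),
      file.path(dir, paste0(g, ".fasta")))
    gff <- file.path(dir, paste0(g, ".gff3"))
    lines <- "##gff-version 3"
    for (ctg in names(ctg_seqs)) {
      cc <- gg[gg$contig_id == ctg, ]
      cc <- cc[order(cc$index), ]
      pos <- 1L
      for (k in seq_len(nrow(cc))) {
        len <- nchar(cc$nt_seq[k])
        type <- if (grepl("^tRNA", cc$annotation[k])) "tRNA" else "CDS"
        lines <- c(lines, paste(
          ctg, "panisles", type, pos, pos + len - 1L, ".", cc$strand[k], "0",
          sprintf("ID=%s_%05d;locus_tag=%s_%05d;family=%s;product=%s",
                  g, cc$index[k], g, cc$index[k], cc$family_id[k],
                  cc$annotation[k]),
          sep = "\t"))
        pos <- pos + len + nchar(SPACER)
      }
    }
    writeLines(lines, gff)
  }
  tr <- sim$truth
  readr::write_tsv(tr$islands |>
    dplyr::mutate(members = map_chr(.data$members, paste, collapse = ","),
                  carriers = map_chr(.data$carriers, paste, collapse = ",")),
    file.path(dir, "truth_islands.tsv"))
  readr::write_tsv(tr$pairs |>
    dplyr::mutate(
      homeoallele_map = map_chr(.data$homeoallele_map, function(m)
        paste(paste0(m$gene_a, ":", m$gene_b), collapse = ",")),
      shared_carriers = map_chr(.data$shared_carriers, paste, collapse = ",")),
    file.path(dir, "truth_pairs.tsv"))
  readr::write_tsv(tr$populations, file.path(dir, "truth_populations.tsv"))
  write_synth_config(sim$config, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write / read a synthetic configuration as key=value text
#'
#' @param config A `synth_config`.
#' @param path File path.
#' @export
write_synth_config <- function(config, path) {
  scal <- function(k) paste(k, "=", paste(config[[k]], collapse = ","))
  lines <- vapply(c("n_genomes", "n_core", "n_shell", "n_cloud",
                    "gene_len_range", "core_gc", "core_snp_rate",
                    "core_threshold", "fragmentation", "seed"),
                  scal, character(1))
  for (i in seq_along(config$island_specs)) {
    sp <- config$island_specs[[i]]
    pre <- sprintf("island%02d.", i)
    lines <- c(lines,
      paste0(pre, "locus = ", sp$locus),
      paste0(pre, "n_genes = ", sp$n_genes),
      paste0(pre, "carriers = ", paste(sp$carriers, collapse = ",")),
      paste0(pre, "gc_target = ", sp$gc_target),
      if (!is.null(sp$partner_of)) paste0(pre, "partner_of = ", sp$partner_of),
      paste0(pre, "homeoallele_fraction = ", sp$homeoallele_fraction),
      paste0(pre, "target_identity = ", sp$target_identity))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read per-genome gene calls from GFF3 + FASTA
#'
#' Gene features (`CDS` and `tRNA`) are ordered along each contig to give
#' 0-based gene-order indices; nucleotide sequences are extracted from the
#' FASTA (reverse-complemented for minus-strand genes so `nt_seq` is the
#' coding-strand sequence as stored throughout the package).
#'
#' @param gff Path to GFF3.
#' @param fasta Path to genome FASTA.
#' @param genome_id Genome identifier to assign.
#' @return A gene-record tibble.
#' @export
read_genome_calls <- function(gff, fasta, genome_id) {
  for (p in c(gff, fasta)) {
    if (!file.exists(p)) abort(paste("missing file:", p),
                               class = "panisles_config_error")
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lines <- readLines(gff)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- do.call(rbind, strsplit(lines, "\t"))
  keep <- f[, 3] %in% c("CDS", "tRNA", "gene")
  f <- f[keep, , drop = FALSE]
  attr_get <- function(a, k) {
    m <- regmatches(a, regexpr(paste0("(^|;)", k, "=[^;]*"), a))
    ifelse(lengths(regmatches(a, regexpr(paste0("(^|;)", k, "=[^;]*"), a))) > 0,
           sub(paste0("^.*", k, "="), "", m), NA_character_)
  }
  tbl <- tibble(contig_id = f[, 1], start = as.integer(f[, 4]),
                end = as.integer(f[, 5]), strand = f[, 7],
                family_id = attr_get(f[, 9], "family"),
                annotation = attr_get(f[, 9], "product")) |>
    dplyr::arrange(.data$contig_id, .data$start) |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::mutate(index = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  nt <- vapply(seq_len(nrow(tbl)), function(i) {
    s <- substr(as.character(seqs[[tbl$contig_id[i]]]), tbl$start[i], tbl$end[i])
    if (tbl$strand[i] == "-") revcomp(s) else s
  }, character(1))
  tibble(genome_id = genome_id, contig_id = tbl$contig_id, index = tbl$index,
         strand = tbl$strand, family_id = tbl$family_id,
         annotation = tbl$annotation, nt_seq = nt)
}
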