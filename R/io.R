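#' Readers and writers for the pipeline's file formats
#'
#' Expression matrices and designs travel as TSV, genomes as FASTA, genes
#' as GFF3, ChIP peaks as BED6+2 (`chrom start end name score strand
#' peak_offset fdr_tier`, 0-based half-open per the BED standard, with
#' `peak_offset` the 0-based offset of the peak maximum from `start`),
#' plain interval tracks as BED, and motifs as JASPAR PFM text. All
#' readers error on malformed records with the offending line number.
#'
#' @param path file path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop2(path, ": need an id column plus at least one array")
  if (anyDuplicated(df[[1L]])) stop2(path, ": duplicated probeset ids")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop2(path, ": non-numeric expression values")
  rownames(m) <- as.character(df[[1L]])
  m
}

#' @param values probeset x array matrix.
#' @rdname pipeline_io
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(probeset_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_design_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("array_id", "stage", "genotype", "batch")
  if (!all(need %in% names(df)))
    stop2(path, ": design needs columns ", paste(need, collapse = ", "))
  expression_design(df$array_id, df$stage, df$genotype, df$batch)
}

#' @param design a design data.frame.
#' @rdname pipeline_io
#' @export
write_design_tsv <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) stop2(path, ": empty FASTA")
  names(g) <- vapply(strsplit(names(g), "\\s+"), `[`, "", 1L)
  g
}

#' @param genome named `DNAStringSet`.
#' @rdname pipeline_io
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' @param genes `GRanges` with `gene_id` (and optionally `is_target`).
#' @rdname pipeline_io
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- genes
  gr$type <- "gene"
  gr$ID <- gr$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  gid <- gr$gene_id %||% gr$ID
  if (is.null(gid)) stop2(path, ": gene records lack gene_id/ID attributes")
  out <- GenomicRanges::granges(gr)
  out$gene_id <- as.character(gid)
  if (!is.null(gr$is_target)) out$is_target <- as.logical(gr$is_target)
  out
}

#' @param peaks `GRanges` with `name`, `score`, `peak_max`, `fdr_tier`.
#' @rdname pipeline_io
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,   # BED 0-based half-open
    end = GenomicRanges::end(peaks),
    name = peaks$name,
    score = peaks$score,
    strand = ".",
    peak_offset = peaks$peak_max - GenomicRanges::start(peaks),
    fdr_tier = peaks$fdr_tier,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) != 8L)
  if (length(bad))
    stop2(path, ": line ", bad[1L], ": expected 8 BED6+2 fields")
  f <- function(i) vapply(parts, `[`, "", i)
  start0 <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  off <- suppressWarnings(as.integer(f(7)))
  score <- suppressWarnings(as.numeric(f(5)))
  bad <- which(is.na(start0) | is.na(end) | is.na(off) | is.na(score))
  if (length(bad)) stop2(path, ": line ", bad[1L], ": non-numeric field")
  tier <- f(8)
  if (!all(tier %in% c("strict", "relaxed")))
    stop2(path, ": fdr_tier must be strict or relaxed")
  GenomicRanges::GRanges(f(1), IRanges::IRanges(start0 + 1L, end),
                         name = f(4), score = score,
                         peak_max = start0 + off + 1L, fdr_tier = tier)
}

#' @param track `GRanges`, optionally with `score`.
#' @rdname pipeline_io
#' @export
write_track_bed <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    name = track$name %||% paste0("iv", seq_along(track)),
    score = track$score %||% 0,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_track_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop2(path, ": line ", bad[1L], ": fewer than 3 BED fields")
  f <- function(i, default = NULL) {
    if (all(lengths(parts) >= i)) vapply(parts, `[`, "", i) else default
  }
  start0 <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  bad <- which(is.na(start0) | is.na(end))
  if (length(bad)) stop2(path, ": line ", bad[1L], ": non-numeric coordinate")
  gr <- GenomicRanges::GRanges(f(1), IRanges::IRanges(start0 + 1L, end))
  nm <- f(4); sc <- f(5)
  if (!is.null(nm)) gr$name <- nm
  if (!is.null(sc)) gr$score <- suppressWarnings(as.numeric(sc))
  gr
}

#' Pipeline configuration
#'
#' Collects every threshold of the analysis chain with its standard value:
#' FDR threshold `q = 0.05`; zygotic fold-change filter `fc = 1.1`;
#' degenerate consensus `BSAAGGHYRHH`; gene-to-peak assignment radius
#' `max_distance = 70000`; motif-analysis peak window `window = 401`;
#' candidate region `enhancer_width = 1001` (peak maximum +/- 500);
#' per-position probability-score candidate threshold `prob_threshold =
#' 0.9`; presence/absence classification threshold `presence_threshold =
#' 0.9999` (see [build_presence_matrix()]); `n_perm = 100` genotype
#' permutations; `null_n` windows per Gaussian null; background-model
#' order 5; and the master `seed`.
#'
#' @param seed master seed.
#' @param sim a [simulation_config()] describing the synthetic universe
#'   (defaults to `simulation_config(seed)`).
#' @param q,fc,consensus,max_distance,window,enhancer_width,prob_threshold,presence_threshold,n_perm,null_n,background_order,kmer_k
#'   thresholds as described above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = simulation_config(seed),
                            q = 0.05, fc = 1.1, consensus = "BSAAGGHYRHH",
                            max_distance = 70000L, window = 401L,
                            enhancer_width = 1001L, prob_threshold = 0.9,
                            presence_threshold = 0.9999, n_perm = 100L,
                            null_n = 2000L, background_order = 5L,
                            kmer_k = 4:6) {
  stopifnot(q > 0, q <= 1, fc >= 1, max_distance >= 0,
            window %% 2L == 1L, enhancer_width %% 2L == 1L,
            prob_threshold > 0, prob_threshold <= 1,
            presence_threshold > 0, presence_threshold <= 1,
            n_perm >= 1L, null_n >= 2L, background_order >= 0L)
  structure(list(seed = as.integer(seed), sim = sim, q = q, fc = fc,
                 consensus = consensus, max_distance = max_distance,
                 window = window, enhancer_width = enhancer_width,
                 prob_threshold = prob_threshold,
                 presence_threshold = presence_threshold,
                 n_perm = as.integer(n_perm), null_n = as.integer(null_n),
                 background_order = as.integer(background_order),
                 kmer_k = kmer_k),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop2(path, ": config must set a seed")
  sim_args <- y$sim %||% list()
  sim_seed <- sim_args$seed %||% y$seed
  sim_args$seed <- NULL
  sim <- do.call(simulation_config, c(list(seed = sim_seed), sim_args))
  args <- y[setdiff(names(y), c("sim", "kmer_k"))]
  if (!is.null(y$kmer_k)) args$kmer_k <- as.integer(unlist(y$kmer_k))
  do.call(pipeline_config, c(args, list(sim = sim)))
}

#' @param config a `pipeline_config`.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}
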