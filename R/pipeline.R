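#' Candidate-enhancer discovery for a set of target genes
#'
#' Runs the interval side of the pipeline: assigns peaks to the target
#' genes within `max_distance`, then applies the strongest-peak /
#' consensus-site / tier-fallback selection of
#' [select_candidate_enhancer()] per gene.
#'
#' @param genome named `DNAStringSet`.
#' @param peaks `GRanges` with `name`, `score`, `peak_max`, `fdr_tier`.
#' @param genes `GRanges` with `gene_id`.
#' @param target_ids character vector of gene ids to search.
#' @param consensus IUPAC consensus.
#' @param max_distance assignment radius in bases.
#' @param enhancer_width odd candidate-region width.
#' @param open_chromatin optional accessibility `GRanges`.
#' @return list with `candidates` (list of `candidate_enhancer`) and
#'   `summary` (one data.frame row per target gene).
#' @export
discover_candidates <- function(genome, peaks, genes, target_ids,
                                consensus = "BSAAGGHYRHH",
                                max_distance = 70000L,
                                enhancer_width = 1001L,
                                open_chromatin = NULL) {
  missing_genes <- setdiff(target_ids, genes$gene_id)
  if (length(missing_genes))
    stop2("target gene(s) not in the annotation: ",
          paste(missing_genes, collapse = ", "))
  assign_tab <- assign_peaks_to_genes(peaks, genes, max_distance)
  cands <- lapply(target_ids, function(gid) {
    gene <- genes[genes$gene_id == gid]
    pk <- peaks[assign_tab$peak[assign_tab$gene_id == gid]]
    select_candidate_enhancer(gene, pk, genome, consensus = consensus,
                              enhancer_width = enhancer_width,
                              open_chromatin = open_chromatin)
  })
  names(cands) <- target_ids
  summary <- do.call(rbind, lapply(cands, function(cc) {
    data.frame(
      gene_id = cc$gene_id,
      enhancer = if (is.null(cc$interval)) NA_character_
                 else interval_to_string(cc$interval),
      tier_used = cc$tier_used,
      source_peak = cc$source_peak,
      n_consensus_hits = if (is.null(cc$consensus_hits)) 0L
                         else nrow(cc$consensus_hits),
      open_chromatin = cc$open_chromatin,
      reason = cc$reason,
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(candidates = cands, summary = summary)
}

#' Run the full synthetic-bundle pipeline
#'
#' Chains every stage on a seeded synthetic universe: simulate genome /
#' tracks, expression experiment and motif bank; screen the expression
#' matrix and apply the filter cascade; map the recovered probesets to
#' genes and discover their candidate enhancers; build the order-k Markov
#' background (from merged peak windows, with a genome-slice background
#' for the enrichment and null statistics); test k-mer over-representation
#' in the peak windows; scan the confirmed/false enhancer sets and derive
#' the discriminating-motif lists and the chromatin-track contrast. Every
#' stage draws from a named substream of the single configuration seed, so
#' a rerun with the same configuration reproduces the summary exactly.
#'
#' @param config a [pipeline_config()].
#' @param dir optional output directory for per-stage files and
#'   `summary.json`.
#' @return list with per-stage results (`sim`, `screen`, `cascade`,
#'   `discovery`, `background`, `kmer`, `presence`, `discriminating`,
#'   `tracks`) and the machine-readable `summary` list.
#' @export
run_pipeline <- function(config, dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("[stage ", name, "] ", conditionMessage(e)))
  }

  gen <- stage("simulate-genome", simulate_genome_and_tracks(config$sim, dir = dir))
  expr <- stage("simulate-expression", simulate_expression(config$sim, dir = dir))
  bank <- stage("simulate-pwm-bank", simulate_pwm_bank(config$sim, dir = dir))

  screen <- stage("expression-screen",
    expression_screen(expr$values, expr$design, n_perm = config$n_perm,
                      seed = config$seed))
  cascade <- stage("filter-cascade",
    filter_candidates(screen, q_threshold = config$q, fc_threshold = config$fc))

  map <- expr$probeset_map
  target_genes <- map$gene_id[match(cascade$ranked$probeset_id, map$probeset_id)]
  target_genes <- target_genes[!is.na(target_genes)]
  discovery <- stage("discover",
    discover_candidates(gen$genome, gen$peaks, gen$genes, target_genes,
                        consensus = config$consensus,
                        max_distance = config$max_distance,
                        enhancer_width = config$enhancer_width,
                        open_chromatin = gen$open_chromatin))

  windows <- stage("peak-windows",
    extract_peak_window(gen$peaks, gen$genome, width = config$window))
  merged <- merge_windows(windows)
  merged$seq <- vapply(seq_along(merged), function(i) {
    as.character(Biostrings::subseq(
      gen$genome[[as.character(GenomicRanges::seqnames(merged[i]))]],
      GenomicRanges::start(merged[i]), GenomicRanges::end(merged[i])))
  }, "")
  background <- stage("background-model",
    build_markov_background(merged$seq, order = config$background_order))

  # genome-composition background for enrichment/null statistics: random
  # slices away from the (tiny) peak fraction of the toy genome
  genome_bg <- stage("genome-background", {
    slices <- with_seed(substream_seed(config$seed, "genome-slices"), {
      n <- 200L
      ci <- sample.int(length(gen$genome), n, replace = TRUE)
      lens <- Biostrings::width(gen$genome)[ci]
      pos <- floor(runif(n, 1, lens - 500))
      vapply(seq_len(n), function(i) {
        as.character(Biostrings::subseq(gen$genome[[ci[i]]], pos[i], pos[i] + 499L))
      }, "")
    })
    build_markov_background(slices, order = config$background_order)
  })

  kmer <- stage("kmer-enrichment",
    kmer_enrichment(windows$seq, genome_bg, k_range = config$kmer_k))

  presence_c <- stage("presence-confirmed",
    build_presence_matrix(bank$confirmed, bank$pwms, bank$nulls,
                          threshold = config$presence_threshold))
  presence_f <- stage("presence-false",
    build_presence_matrix(bank$false, bank$pwms, bank$nulls,
                          threshold = config$presence_threshold))
  disc <- stage("discriminating-motifs",
    group_discriminating_motifs(presence_c, presence_f,
      exclude = bank$motif_info$motif[bank$motif_info$homeodomain]))
  tracks <- stage("track-overlap",
    track_overlap_report(bank$enhancer_ranges, bank$tracks))

  summary <- list(
    seed = config$seed,
    cascade = cascade$counts,
    recovered_probesets = cascade$ranked$probeset_id,
    candidates = discovery$summary,
    n_merged_windows = length(merged),
    top_kmer = kmer$kmer[1L],
    discriminating = disc,
    discriminating_tracks =
      tracks$contrast$track[tracks$contrast$discriminates]
  )
  if (!is.null(dir)) {
    write.table(cascade$flags, file.path(dir, "screen_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_markov_background(background, file.path(dir, "background_model.txt"))
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  list(sim = list(genome = gen, expression = expr, bank = bank),
       screen = screen, cascade = cascade, discovery = discovery,
       background = background, genome_background = genome_bg, kmer = kmer,
       presence = list(confirmed = presence_c, false = presence_f),
       discriminating = disc, tracks = tracks, summary = summary)
}
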