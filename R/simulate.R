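#' Configuration of the synthetic study universe
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the design of the study the pipeline targets: a 3-stage x
#' 2-genotype x 3-batch expression experiment (18 arrays) with a small set
#' of planted direct targets reduced ~1.5-fold in the mutant and switched
#' on zygotically between the first two stages; a toy genome with one
#' target gene per chromosome, a consensus-bearing ChIP peak within
#' regulatory range of each (one reachable only at the relaxed FDR tier,
#' one with no peak at all), plus consensus-free decoy peaks; and a motif
#' bank with one confirmed-universal and five false-universal
#' discriminating motifs mirroring the published contrast pattern.
#'
#' @param seed master seed; every stage derives substreams from it.
#' @param genome list: `n_chroms`, `chrom_length` (nt), `background_order`
#'   of the genome-composition model.
#' @param genes list: `per_chrom` count, `width` (nt).
#' @param peaks list: `n_decoys_per_chrom`, `score_true` and `score_decoy`
#'   ranges, `half_width` range of peak intervals, `min_gene_distance` /
#'   `max_gene_distance` of the peak maximum from the target gene,
#'   `relaxed_targets` and `peakless_targets` counts.
#' @param planted_consensus IUPAC consensus planted under true peaks.
#' @param expression list: `n_probesets`, `n_targets`, `stage_effect_target`
#'   (log2 stage-5 to stage-6 step for targets), `genotype_effect` (log2,
#'   negative = reduced in mutant), `frac_stage_responsive` and
#'   `stage_effect_sd` for non-target stage behaviour, `batch_sd`,
#'   `noise_sd`, `n_batches`, `stages`, `baseline` range.
#' @param enhancer_sets list: `n_confirmed`, `n_false`, `length` (nt),
#'   `spacing` of the virtual coordinates used for track overlap.
#' @param pwm_bank list: `width` of the discriminating motifs, `counts`
#'   per consensus base, `n_homeodomain` decoy motifs,
#'   `presence_threshold` used when verifying the planted pattern,
#'   `null_n` windows per Gaussian null.
#' @param max_attempts rejection-sampling cap before the generator errors.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
    genome = list(),
    genes = list(),
    peaks = list(),
    planted_consensus = "BSAAGGHYRHH",
    expression = list(),
    enhancer_sets = list(),
    pwm_bank = list(),
    max_attempts = 1000L) {
  cfg <- list(
    seed = as.integer(seed),
    genome = utils::modifyList(
      list(n_chroms = 8L, chrom_length = 60000L, background_order = 2L),
      genome),
    genes = utils::modifyList(list(per_chrom = 3L, width = 2000L), genes),
    peaks = utils::modifyList(
      list(n_decoys_per_chrom = 2L, score_true = c(6, 10),
           score_decoy = c(1, 8), half_width = c(100L, 300L),
           min_gene_distance = 2000L, max_gene_distance = 35000L,
           relaxed_targets = 1L, peakless_targets = 1L),
      peaks),
    planted_consensus = planted_consensus,
    expression = utils::modifyList(
      list(n_probesets = 1000L, n_targets = 8L, stage_effect_target = 0.6,
           genotype_effect = -log2(1.5), frac_stage_responsive = 0.4,
           stage_effect_sd = 0.4, batch_sd = 0.1, noise_sd = 0.2,
           n_batches = 3L, stages = c("5", "6", "8"), baseline = c(6, 12)),
      expression),
    enhancer_sets = utils::modifyList(
      list(n_confirmed = 10L, n_false = 3L, length = 1000L, spacing = 10000L),
      enhancer_sets),
    pwm_bank = utils::modifyList(
      list(width = 10L, counts = 30, n_homeodomain = 2L,
           presence_threshold = 0.9999, null_n = 2000L),
      pwm_bank),
    max_attempts = as.integer(max_attempts)
  )
  if (!nrow(find_iupac_matches(strrep("A", 50), cfg$planted_consensus)) >= 0)
    stop2("invalid planted consensus")  # validation happens inside the matcher
  if (cfg$peaks$relaxed_targets + cfg$peaks$peakless_targets > cfg$genome$n_chroms)
    stop2("more special-case targets than chromosomes")
  class(cfg) <- "simulation_config"
  cfg
}

# Random order-k composition model for genome generation: transition rows
# drawn Dirichlet(alpha); lower orders uniform (start effects negligible).
.random_markov_model <- function(order, seed, alpha = 5) {
  prob <- vector("list", order + 1L)
  with_seed(seed, {
    for (o in 0:order) {
      if (o < order) {
        m <- matrix(0.25, nrow = 4^o, ncol = 4L)
      } else {
        m <- matrix(rgamma(4^o * 4L, alpha), ncol = 4L)
        m <- m / rowSums(m)
      }
      rownames(m) <- if (o == 0L) "" else .all_kmers(o)
      colnames(m) <- .BASES
      prob[[o + 1L]] <- m
    }
  })
  m <- structure(list(order = as.integer(order), pseudocount = 0,
                      strand_averaged = FALSE, prob = prob),
                 class = "markov_background")
  stationarize_model(m)
}

.instantiate_iupac <- function(pattern) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[
    strsplit(toupper(pattern), "")[[1]]], "")
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], ""),
        collapse = "")
}

.plant_site <- function(seq, site, pos, strand = "+") {
  if (strand == "-")
    site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  substr(seq, pos, pos + nchar(site) - 1L) <- site
  seq
}

#' Simulate a toy genome with planted regulatory signal
#'
#' Generates chromosome sequences from a seeded random Markov composition
#' model and plants, on each chromosome, a target gene flanked by one true
#' ChIP peak (with at least one exact instance of the degenerate consensus
#' inside the peak-maximum +/- 500 window) and consensus-free decoy peaks
#' (rejection-sampled: any decoy window containing a chance consensus
#' match is resampled). A configurable number of targets get their true
#' peak only at the relaxed FDR tier, and a configurable number get no
#' peak at all, exercising the tier fallback and the absence path. True
#' peak windows are marked accessible in the open-chromatin track. The
#' truth record lists every planted site and the intended candidate
#' enhancer per target.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `genes.gff3`, `peaks.bed`, `open_chromatin.bed` and
#'   `genome_truth.json`.
#' @return list with `genome` (`DNAStringSet`), `genes` (`GRanges` with
#'   `gene_id`, `is_target`), `peaks` (`GRanges` with `name`, `score`,
#'   `peak_max`, `fdr_tier`), `open_chromatin` (`GRanges`), `truth` (list)
#'   and the composition `model`.
#' @export
simulate_genome_and_tracks <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  gcf <- config$genome
  pcf <- config$peaks
  cons <- config$planted_consensus
  cons_len <- nchar(cons)
  if (gcf$chrom_length < 2L * (pcf$max_gene_distance %/% 4L) + 5000L)
    stop2("chromosome too short for the requested features")
  model <- .random_markov_model(gcf$background_order,
                                substream_seed(config$seed, "genome-model"))
  chroms <- sample_background(model, gcf$chrom_length, gcf$n_chroms,
                              seed = substream_seed(config$seed, "genome-seq"))
  chrom_names <- paste0("chr", seq_len(gcf$n_chroms))

  # special-case targets: last chromosomes get relaxed tier / no peak
  tier_of <- rep("strict", gcf$n_chroms)
  if (pcf$relaxed_targets > 0L)
    tier_of[seq_len(pcf$relaxed_targets)] <- "relaxed"
  peakless <- rep(FALSE, gcf$n_chroms)
  if (pcf$peakless_targets > 0L)
    peakless[pcf$relaxed_targets + seq_len(pcf$peakless_targets)] <- TRUE

  genes <- list(); peaks <- list(); open <- list()
  truth_targets <- list(); planted_sites <- list()

  with_seed(substream_seed(config$seed, "genome-features"), {
    for (ci in seq_len(gcf$n_chroms)) {
      L <- gcf$chrom_length
      gene_starts <- round(L * seq(0.70, 0.92,
                                   length.out = config$genes$per_chrom))
      gw <- config$genes$width
      gid <- sprintf("gene_%02d_%d", ci, seq_along(gene_starts))
      genes[[ci]] <- GenomicRanges::GRanges(
        chrom_names[ci],
        IRanges::IRanges(gene_starts, width = gw),
        strand = sample(c("+", "-"), length(gene_starts), replace = TRUE),
        gene_id = gid,
        is_target = seq_along(gene_starts) == 1L)
      target_start <- gene_starts[1L]

      if (peakless[ci]) {
        truth_targets[[gid[1L]]] <- list(
          gene_id = gid[1L], chrom = chrom_names[ci], peak = NA,
          tier = NA, enhancer = NA, reason = "no_peaks")
        next
      }

      # true peak: consensus planted inside the +/-500 enhancer window
      d <- round(runif(1, pcf$min_gene_distance, pcf$max_gene_distance))
      pm <- target_start - d
      hw <- round(runif(1, pcf$half_width[1], pcf$half_width[2]))
      site <- .instantiate_iupac(cons)
      off <- round(runif(1, -450, 450 - cons_len))
      strand <- sample(c("+", "-"), 1L)
      chroms[ci] <- .plant_site(chroms[ci], site, pm + off, strand)
      true_score <- round(runif(1, pcf$score_true[1], pcf$score_true[2]), 3)
      pk_name <- sprintf("peak_%02d_true", ci)
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom_names[ci], start = pm - hw, end = pm + hw,
        name = pk_name, score = true_score, peak_max = pm,
        fdr_tier = tier_of[ci], stringsAsFactors = FALSE)
      open[[length(open) + 1L]] <-
        data.frame(chrom = chrom_names[ci], start = pm - 1000L, end = pm + 1000L)
      planted_sites[[length(planted_sites) + 1L]] <- data.frame(
        chrom = chrom_names[ci], start = pm + off,
        end = pm + off + cons_len - 1L, strand = strand, word = site,
        peak = pk_name, stringsAsFactors = FALSE)

      # decoys: no consensus anywhere in their +/-500 windows
      used <- pm
      for (di in seq_len(pcf$n_decoys_per_chrom)) {
        repeat {
          dd <- round(runif(1, pcf$min_gene_distance, pcf$max_gene_distance))
          dpm <- target_start - dd
          if (all(abs(dpm - used) > 1100L)) break
        }
        used <- c(used, dpm)
        for (att in seq_len(config$max_attempts)) {
          win <- substr(chroms[ci], dpm - 500L, dpm + 500L)
          if (nrow(find_iupac_matches(win, cons)) == 0L) break
          repl <- sample_background(model, 1001L, 1L,
                                    seed = sample.int(2^30, 1L))
          substr(chroms[ci], dpm - 500L, dpm + 500L) <- repl
          if (att == config$max_attempts)
            stop2("could not make decoy window consensus-free after ",
                  config$max_attempts, " attempts")
        }
        dhw <- round(runif(1, pcf$half_width[1], pcf$half_width[2]))
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chrom_names[ci], start = dpm - dhw, end = dpm + dhw,
          name = sprintf("peak_%02d_decoy%d", ci, di),
          score = round(runif(1, pcf$score_decoy[1], pcf$score_decoy[2]), 3),
          peak_max = dpm, fdr_tier = "strict", stringsAsFactors = FALSE)
      }

      truth_targets[[gid[1L]]] <- list(
        gene_id = gid[1L], chrom = chrom_names[ci], peak = pk_name,
        tier = tier_of[ci],
        enhancer = sprintf("%s:%d..%d", chrom_names[ci], pm - 500L, pm + 500L),
        reason = NA)
    }
  })

  genome <- Biostrings::DNAStringSet(setNames(chroms, chrom_names))
  genes_gr <- suppressWarnings(do.call(c, genes)) # seqlevels differ per chrom
  pk <- do.call(rbind, peaks)
  peaks_gr <- GenomicRanges::GRanges(pk$chrom,
                                     IRanges::IRanges(pk$start, pk$end),
                                     name = pk$name, score = pk$score,
                                     peak_max = pk$peak_max,
                                     fdr_tier = pk$fdr_tier)
  op <- do.call(rbind, open)
  open_gr <- GenomicRanges::GRanges(op$chrom, IRanges::IRanges(op$start, op$end))
  truth <- list(
    consensus = cons,
    targets = truth_targets,
    planted_sites = do.call(rbind, planted_sites)
  )
  out <- list(genome = genome, genes = genes_gr, peaks = peaks_gr,
              open_chromatin = open_gr, truth = truth, model = model)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(genome, file.path(dir, "genome.fa"))
    write_genes_gff3(genes_gr, file.path(dir, "genes.gff3"))
    write_peaks_bed(peaks_gr, file.path(dir, "peaks.bed"))
    write_track_bed(open_gr, file.path(dir, "open_chromatin.bed"))
    jsonlite::write_json(truth, file.path(dir, "genome_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  out
}

#' Simulate the staged wildtype-vs-mutant expression experiment
#'
#' Log2 values are the sum of a per-probeset baseline, per-stage effects
#' (planted targets switch on between the first two stages by at least the
#' zygotic filter margin; a configurable fraction of non-targets drift
#' with stage), a negative genotype effect on target probesets in mutant
#' arrays, per-batch random effects and i.i.d. Gaussian noise. The first
#' `n_targets` probesets are the targets and are mapped one-to-one onto
#' the genome's target genes (as far as both lists reach).
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; writes `expression.tsv`,
#'   `design.tsv`, `probeset_map.tsv`, `expression_truth.json`.
#' @return list with `values` (matrix), `design` (data.frame),
#'   `probeset_map` (data.frame `probeset_id`, `gene_id`), `truth` (list).
#' @export
simulate_expression <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  e <- config$expression
  stages <- e$stages
  n_arr <- length(stages) * 2L * e$n_batches
  grid <- expand.grid(batch = seq_len(e$n_batches),
                      genotype = c("control", "mutant"),
                      stage = stages, stringsAsFactors = FALSE)
  design <- expression_design(
    array_id = sprintf("arr%02d", seq_len(n_arr)),
    stage = grid$stage, genotype = grid$genotype, batch = grid$batch)

  np <- e$n_probesets
  ids <- sprintf("ps%04d", seq_len(np))
  is_target <- seq_len(np) <= e$n_targets

  vals <- with_seed(substream_seed(config$seed, "expression"), {
    baseline <- runif(np, e$baseline[1], e$baseline[2])
    stage_eff <- matrix(0, nrow = np, ncol = length(stages),
                        dimnames = list(NULL, stages))
    # targets: clean zygotic step that persists
    stage_eff[is_target, -1L] <- e$stage_effect_target
    resp <- !is_target & runif(np) < e$frac_stage_responsive
    stage_eff[resp, -1L] <- rnorm(sum(resp) * (length(stages) - 1L),
                                  0, e$stage_effect_sd)
    geno_eff <- ifelse(is_target, e$genotype_effect, 0)
    batch_eff <- matrix(rnorm(np * e$n_batches, 0, e$batch_sd), nrow = np)
    m <- matrix(0, nrow = np, ncol = n_arr,
                dimnames = list(ids, design$array_id))
    for (j in seq_len(n_arr)) {
      m[, j] <- baseline +
        stage_eff[, as.character(design$stage[j])] +
        geno_eff * (design$genotype[j] == "mutant") +
        batch_eff[, as.integer(as.character(design$batch[j]))] +
        rnorm(np, 0, e$noise_sd)
    }
    m
  })

  n_map <- min(e$n_targets, config$genome$n_chroms)
  probeset_map <- data.frame(
    probeset_id = ids[seq_len(n_map)],
    gene_id = sprintf("gene_%02d_1", seq_len(n_map)),
    stringsAsFactors = FALSE)
  truth <- list(
    target_probesets = ids[is_target],
    genotype_effect_log2 = e$genotype_effect,
    genotype_fold_change = signed_fold_change(0, e$genotype_effect),
    stage_effect_log2 = e$stage_effect_target)
  out <- list(values = vals, design = design, probeset_map = probeset_map,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_expression_tsv(vals, file.path(dir, "expression.tsv"))
    write_design_tsv(design, file.path(dir, "design.tsv"))
    write.table(probeset_map, file.path(dir, "probeset_map.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "expression_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Simulate a motif bank and confirmed/false enhancer sets
#'
#' Builds high-information position weight matrices: a composite-consensus
#' "Ftz-F1-like" motif planted in every enhancer, one motif planted in all
#' confirmed but not all false enhancers, five motifs planted in all false
#' but not all confirmed enhancers (the published 1-vs-5 discriminating
#' pattern), and homeodomain-flagged decoys planted everywhere (excluded
#' from the contrast by flag). Enhancer sequences are sampled from the
#' composition model, sites planted at non-overlapping positions, and the
#' whole sequence rejection-sampled until the scanned presence matrix at
#' the configured threshold equals the designed truth --- so the planted
#' pattern is exactly recoverable. Enhancers also get virtual genomic
#' coordinates on a scaffold chromosome plus GAF/PC/Pho-style chromatin
#' tracks in which only the GAF-like track discriminates the false group.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; writes `pwms.jaspar`,
#'   `enhancers_confirmed.fa`, `enhancers_false.fa`, `tracks_*.bed` and
#'   `bank_truth.json`.
#' @return list with `pwms`, `motif_info` (data.frame with `homeodomain`
#'   flag), `nulls`, `confirmed` / `false` (named sequence vectors),
#'   `enhancer_ranges` (`GRanges` with `name`, `group`), `tracks` (list of
#'   `GRanges`), `design` (logical presence design matrix), `truth`.
#' @export
simulate_pwm_bank <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  b <- config$pwm_bank
  es <- config$enhancer_sets
  model <- .random_markov_model(config$genome$background_order,
                                substream_seed(config$seed, "genome-model"))

  disc_false <- c("Trl_like", "Sd_like", "D_like", "Fkh_like", "Slp1_like")
  hd <- if (b$n_homeodomain > 0L)
    sprintf("Hd%d_like", seq_len(b$n_homeodomain)) else character(0)
  motif_ids <- c("FtzF1_like", "Zeste_like", disc_false, hd)

  pwms <- with_seed(substream_seed(config$seed, "pwm-bank"), {
    out <- list()
    for (id in motif_ids) {
      w <- if (id == "FtzF1_like") nchar(config$planted_consensus) else b$width
      consensus <- if (id == "FtzF1_like")
        .instantiate_iupac(config$planted_consensus)
      else paste(sample(.BASES, w, replace = TRUE), collapse = "")
      cnt <- matrix(0, nrow = 4L, ncol = w, dimnames = list(.BASES, NULL))
      cnt[cbind(match(strsplit(consensus, "")[[1]], .BASES), seq_len(w))] <- b$counts
      out[[id]] <- pwm_from_counts(cnt, id)
      out[[id]]$consensus <- consensus
    }
    out
  })
  motif_info <- data.frame(motif = motif_ids,
                           homeodomain = motif_ids %in% hd,
                           stringsAsFactors = FALSE)

  nulls <- setNames(lapply(motif_ids, function(id) {
    build_gaussian_null(pwms[[id]], model = model, n = b$null_n,
                        seed = substream_seed(config$seed, paste0("null-", id)))
  }), motif_ids)

  enh_names <- c(sprintf("C%02d", seq_len(es$n_confirmed)),
                 sprintf("F%02d", seq_len(es$n_false)))
  group <- rep(c("confirmed", "false"), c(es$n_confirmed, es$n_false))
  design <- matrix(FALSE, nrow = length(motif_ids), ncol = length(enh_names),
                   dimnames = list(motif_ids, enh_names))
  design["FtzF1_like", ] <- TRUE
  design[hd, ] <- TRUE
  seqs <- with_seed(substream_seed(config$seed, "enhancer-design"), {
    design["Zeste_like", group == "confirmed"] <- TRUE
    design["Zeste_like", group == "false"] <-
      seq_len(es$n_false) == sample.int(es$n_false, 1L)
    for (id in disc_false) {
      design[id, group == "false"] <- TRUE
      present_in <- sample(which(group == "confirmed"),
                           ceiling(es$n_confirmed / 2))
      design[id, present_in] <- TRUE
    }
    # draw + plant + verify each enhancer against its designed column
    out <- character(length(enh_names))
    for (j in seq_along(enh_names)) {
      planted_ids <- motif_ids[design[, j]]
      ok <- FALSE
      for (att in seq_len(config$max_attempts)) {
        s <- sample_background(model, es$length, 1L,
                               seed = sample.int(2^30, 1L))
        # non-overlapping slots for the planted sites
        slot_w <- es$length %/% length(planted_ids)
        pos <- (seq_along(planted_ids) - 1L) * slot_w +
          sample.int(slot_w - nchar(config$planted_consensus) - 1L,
                     length(planted_ids), replace = TRUE)
        for (ii in seq_along(planted_ids)) {
          s <- .plant_site(s, pwms[[planted_ids[ii]]]$consensus, pos[ii],
                           sample(c("+", "-"), 1L))
        }
        col <- vapply(motif_ids, function(id) {
          nrow(scan_pwm(s, pwms[[id]], nulls[[id]],
                        threshold = b$presence_threshold)) > 0L
        }, TRUE)
        if (identical(unname(col), unname(design[, j]))) { ok <- TRUE; break }
      }
      if (!ok) stop2("could not realize the designed presence pattern for ",
                     enh_names[j], " after ", config$max_attempts, " attempts")
      out[j] <- s
    }
    out
  })
  names(seqs) <- enh_names

  starts <- (seq_along(enh_names) - 1L) * es$spacing + 1L
  enh_gr <- GenomicRanges::GRanges("chrE",
                                   IRanges::IRanges(starts, width = es$length),
                                   name = enh_names, group = group)
  false_gr <- enh_gr[group == "false"]
  tracks <- list(
    GAF_like = GenomicRanges::GRanges("chrE",
      IRanges::IRanges(GenomicRanges::start(false_gr) + 100L, width = 300L),
      score = 8),
    PC_like = GenomicRanges::GRanges("chrE",
      IRanges::IRanges(GenomicRanges::start(enh_gr) + 200L, width = 300L),
      score = 5),
    Pho_like = GenomicRanges::GRanges("chrE",
      IRanges::IRanges(GenomicRanges::start(enh_gr) + 400L, width = 200L),
      score = 4)
  )

  truth <- list(
    confirmed_universal = "Zeste_like",
    false_universal = disc_false,
    homeodomain = hd,
    discriminating_track = "GAF_like",
    design = design
  )
  out <- list(pwms = pwms, motif_info = motif_info, nulls = nulls,
              confirmed = seqs[group == "confirmed"],
              false = seqs[group == "false"],
              enhancer_ranges = enh_gr, tracks = tracks,
              design = design, truth = truth, model = model)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_jaspar(pwms, file.path(dir, "pwms.jaspar"))
    write_genome_fasta(Biostrings::DNAStringSet(out$confirmed),
                       file.path(dir, "enhancers_confirmed.fa"))
    write_genome_fasta(Biostrings::DNAStringSet(out$false),
                       file.path(dir, "enhancers_false.fa"))
    for (tr in names(tracks))
      write_track_bed(tracks[[tr]], file.path(dir, paste0("track_", tr, ".bed")))
    jsonlite::write_json(truth[names(truth) != "design"],
                         file.path(dir, "bank_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
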