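test_that("one seed reproduces every synthetic output exactly", {
  cfg <- simulation_config(seed = 41)
  a <- simulate_genome_and_tracks(cfg)
  b <- simulate_genome_and_tracks(simulation_config(seed = 41))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_equal(a$peaks$score, b$peaks$score)

  ea <- simulate_expression(cfg)
  eb <- simulate_expression(simulation_config(seed = 41))
  expect_identical(ea$values, eb$values)

  other <- simulate_genome_and_tracks(simulation_config(seed = 42))
  expect_false(identical(as.character(a$genome), as.character(other$genome)))
})

test_that("planted consensus sites are recoverable by the matcher", {
  cfg <- simulation_config(seed = 43)
  gen <- simulate_genome_and_tracks(cfg)
  sites <- gen$truth$planted_sites
  for (i in seq_len(nrow(sites))) {
    chrom <- gen$genome[[sites$chrom[i]]]
    win <- as.character(Biostrings::subseq(chrom, sites$start[i] - 20,
                                           sites$end[i] + 20))
    hits <- find_iupac_matches(win, cfg$planted_consensus)
    expect_true(21L %in% hits$start[hits$strand == sites$strand[i]])
  }
  # decoy peak windows are consensus-free by construction
  decoys <- gen$peaks[grepl("decoy", gen$peaks$name)]
  for (i in seq_along(decoys)) {
    win <- as.character(Biostrings::subseq(
      gen$genome[[as.character(GenomicRanges::seqnames(decoys[i]))]],
      decoys$peak_max[i] - 500L, decoys$peak_max[i] + 500L))
    expect_equal(nrow(find_iupac_matches(win, cfg$planted_consensus)), 0L)
  }
})

test_that("a decoy-free configuration recovers every peak", {
  cfg <- simulation_config(seed = 44,
                           peaks = list(n_decoys_per_chrom = 0L,
                                        relaxed_targets = 0L,
                                        peakless_targets = 0L))
  gen <- simulate_genome_and_tracks(cfg)
  expect_equal(length(gen$peaks), cfg$genome$n_chroms)
  tg <- gen$genes$gene_id[gen$genes$is_target]
  disc <- discover_candidates(gen$genome, gen$peaks, gen$genes, tg)
  expect_true(all(!is.na(disc$summary$enhancer)))
  expect_true(all(disc$summary$tier_used == "strict"))
})

test_that("noiseless expression yields the closed-form fold changes", {
  cfg <- simulation_config(seed = 45,
    expression = list(noise_sd = 0, batch_sd = 0, genotype_effect = -0.575,
                      n_probesets = 300L, n_targets = 5L))
  ex <- simulate_expression(cfg)
  sc <- expression_screen(ex$values, ex$design, n_perm = 40, seed = 46)
  tgt <- sc$probeset_id %in% ex$truth$target_probesets
  expect_equal(sc$fc_genotype[tgt], rep(-2^0.575, 5), tolerance = 1e-9)
  expect_equal(round(sc$fc_genotype[tgt][1], 2), -1.49)
  expect_equal(sc$fc_stage[tgt],
               rep(2^cfg$expression$stage_effect_target, 5), tolerance = 1e-9)
  # cascade recovers exactly the planted targets
  out <- filter_candidates(sc)
  expect_setequal(out$down, ex$truth$target_probesets)
})

test_that("the simulated bank realizes its designed presence pattern", {
  cfg <- simulation_config(seed = 47)
  bank <- simulate_pwm_bank(cfg)
  pc <- build_presence_matrix(bank$confirmed, bank$pwms, bank$nulls,
                              threshold = cfg$pwm_bank$presence_threshold)
  pf <- build_presence_matrix(bank$false, bank$pwms, bank$nulls,
                              threshold = cfg$pwm_bank$presence_threshold)
  expect_equal(dim(pc), dim(bank$design[, colnames(pc)]))
  expect_true(all(pc == bank$design[, colnames(pc)]))
  expect_true(all(pf == bank$design[, colnames(pf)]))
  d <- group_discriminating_motifs(pc, pf,
         exclude = bank$motif_info$motif[bank$motif_info$homeodomain])
  expect_equal(d$confirmed_universal, bank$truth$confirmed_universal)
  expect_setequal(d$false_universal, bank$truth$false_universal)
})
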