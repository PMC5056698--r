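test_that("printed interval strings parse with 1-based closed arithmetic", {
  g <- interval_from_string("3R:4612279..4614294")
  expect_equal(GenomicRanges::width(g), 2016L)       # the ~2 kb exception
  expect_equal(GenomicRanges::width(interval_from_string("2R:23868513..23869466")),
               954L)
  expect_equal(GenomicRanges::width(interval_from_string("X:1..1")), 1L)
  expect_equal(interval_to_string(g), "3R:4612279..4614294")
  expect_error(interval_from_string("X:10..5"), "exceeds")
  expect_error(interval_from_string("X:abc"), "malformed")
})

test_that("peak windows are centered, clamped and flagged", {
  genome <- Biostrings::DNAStringSet(c(chrA = strrep("ACGT", 1000)))
  pk <- GenomicRanges::GRanges("chrA", IRanges::IRanges(900, 1100),
                               peak_max = 1001L, name = "p1")
  win <- extract_peak_window(pk, genome, width = 401L)
  expect_equal(GenomicRanges::start(win), 801L)
  expect_equal(GenomicRanges::end(win), 1201L)
  expect_equal(GenomicRanges::width(win), 401L)
  expect_false(win$clamped)
  expect_equal(nchar(win$seq), 401L)

  edge <- GenomicRanges::GRanges("chrA", IRanges::IRanges(50, 150),
                                 peak_max = 101L, name = "p2")
  winc <- extract_peak_window(edge, genome, width = 401L)
  expect_equal(GenomicRanges::start(winc), 1L)
  expect_equal(GenomicRanges::end(winc), 301L)
  expect_true(winc$clamped)

  expect_error(extract_peak_window(pk, genome, width = 400L), "odd")
  bad <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10), peak_max = 5L)
  expect_error(extract_peak_window(bad, genome), "unknown chromosome")
})

test_that("window merging covers exactly the union", {
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 51), c(100, 150)))
  m <- merge_windows(gr)
  expect_equal(GenomicRanges::start(m), 1L)
  expect_equal(GenomicRanges::end(m), 150L)

  disjoint <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 500), c(100, 600)))
  expect_length(merge_windows(disjoint), 2L)

  nested <- GenomicRanges::GRanges("c", IRanges::IRanges(c(10, 20), c(200, 50)))
  mm <- merge_windows(nested)
  expect_equal(c(GenomicRanges::start(mm), GenomicRanges::end(mm)), c(10L, 200L))

  # per-base bitmap oracle on random interval sets
  set.seed(11)
  for (rep in 1:20) {
    st <- sample(500, 15, replace = TRUE)
    en <- st + sample(0:60, 15, replace = TRUE)
    gr <- GenomicRanges::GRanges("c", IRanges::IRanges(st, en))
    bitmap <- logical(600)
    for (i in seq_along(st)) bitmap[st[i]:en[i]] <- TRUE
    m <- merge_windows(gr)
    expect_equal(sum(GenomicRanges::width(m)), sum(bitmap))
    expect_true(all(GenomicRanges::width(m) <= sum(GenomicRanges::width(gr))))
  }
})

test_that("peak-to-gene assignment honors the distance boundary", {
  genes <- GenomicRanges::GRanges("c", IRanges::IRanges(100001, 102000),
                                  gene_id = "g1")
  ov <- GenomicRanges::GRanges("c", IRanges::IRanges(100500, 100600),
                               peak_max = 100550L)
  expect_equal(assign_peaks_to_genes(ov, genes)$distance, 0L)

  # nearest edges exactly 70,000 apart: assigned; one more base: not
  at <- GenomicRanges::GRanges("c", IRanges::IRanges(29900, 30000))
  expect_equal(nrow(assign_peaks_to_genes(at, genes, 70000L)), 1L)
  expect_equal(assign_peaks_to_genes(at, genes, 70000L)$distance, 70000L)
  beyond <- GenomicRanges::GRanges("c", IRanges::IRanges(29899, 29999))
  expect_equal(nrow(assign_peaks_to_genes(beyond, genes, 70000L)), 0L)

  flank2 <- GenomicRanges::GRanges("c",
    IRanges::IRanges(c(78000, 200001), c(80000, 202000)),
    gene_id = c("gL", "gR"))
  mid <- GenomicRanges::GRanges("c", IRanges::IRanges(150000, 150100),
                                peak_max = 150050L)
  tab <- assign_peaks_to_genes(mid, flank2, 70000L)
  expect_setequal(tab$gene_id, c("gL", "gR"))   # one peak serves both genes
})

test_that("candidate selection prefers the strongest consensus-bearing peak", {
  site <- "CGAAGGACAAA"
  base <- strrep("GC", 3000)
  seq1 <- base
  substr(seq1, 1000, 1010) <- site       # peak A window has a site
  genome <- Biostrings::DNAStringSet(c(chr = seq1))
  gene <- GenomicRanges::GRanges("chr", IRanges::IRanges(4000, 4500),
                                 gene_id = "g")
  peaks <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(c(900, 1900), c(1100, 2100)),
    peak_max = c(1000L, 2000L), score = c(5, 9),
    fdr_tier = c("strict", "strict"), name = c("pA", "pB"))
  # strongest (pB) lacks a consensus match -> second (pA) selected
  cand <- select_candidate_enhancer(gene, peaks, genome)
  expect_equal(cand$source_peak, "pA")
  expect_equal(cand$tier_used, "strict")
  expect_gte(nrow(cand$consensus_hits), 1L)
  expect_equal(GenomicRanges::start(cand$interval), 1000L - 500L)

  # when the strongest also has a site, it wins
  seq2 <- seq1; substr(seq2, 2000, 2010) <- site
  cand2 <- select_candidate_enhancer(gene, peaks,
                                     Biostrings::DNAStringSet(c(chr = seq2)))
  expect_equal(cand2$source_peak, "pB")

  # relaxed-tier fallback when no strict peak qualifies
  peaks3 <- peaks
  peaks3$fdr_tier <- c("relaxed", "strict")
  cand3 <- select_candidate_enhancer(gene, peaks3, genome)
  expect_equal(cand3$tier_used, "relaxed")
  expect_equal(cand3$source_peak, "pA")

  # absence is a value, with a reason code
  none <- select_candidate_enhancer(gene, peaks[0], genome)
  expect_null(none$interval)
  expect_equal(none$reason, "no_peaks")
  no_site <- select_candidate_enhancer(
    gene, peaks, Biostrings::DNAStringSet(c(chr = base)))
  expect_equal(no_site$reason, "no_consensus")

  # open-chromatin flag by overlap
  oc <- GenomicRanges::GRanges("chr", IRanges::IRanges(950, 1050))
  expect_true(select_candidate_enhancer(gene, peaks, genome,
                                        open_chromatin = oc)$open_chromatin)
})
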