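test_that("presence matrix reflects planted sites and masks", {
  model <- fixture_model()
  pwm <- sharp_pwm()
  null <- build_gaussian_null(pwm, model = model, n = 3000, seed = 3)
  with_site <- stripecre:::.plant_site(
    sample_background(model, 400, 1, seed = 4), pwm$consensus, 200, "+")
  allN <- strrep("N", 400)
  m <- build_presence_matrix(c(e1 = with_site, e2 = allN),
                             list(pwm), setNames(list(null), pwm$id),
                             threshold = 0.99)
  expect_true(m["sharp", "e1"])
  expect_false(m["sharp", "e2"])          # masked sequence can never hit
  expect_error(build_presence_matrix(c(e1 = with_site), list(pwm),
                                     list(other = null)), "no null")

  # monotone in threshold: raising it never adds a presence
  lo <- build_presence_matrix(c(e1 = with_site, e2 = allN), list(pwm),
                              setNames(list(null), pwm$id), threshold = 0.9)
  expect_true(all(m <= lo))
})

test_that("universal-presence contrast reproduces the 1-vs-5 pattern", {
  motifs <- c("zeste", paste0("f", 1:5), "hd1")
  conf <- matrix(TRUE, 7, 10, dimnames = list(motifs, paste0("C", 1:10)))
  fal <- matrix(TRUE, 7, 3, dimnames = list(motifs, paste0("F", 1:3)))
  conf[paste0("f", 1:5), 1:5] <- FALSE    # the five absent from some confirmed
  fal["zeste", 2:3] <- FALSE              # zeste absent from some false
  out <- group_discriminating_motifs(conf, fal, exclude = "hd1")
  expect_equal(out$confirmed_universal, "zeste")
  expect_setequal(out$false_universal, paste0("f", 1:5))
  expect_length(out$confirmed_universal, 1L)
  expect_length(out$false_universal, 5L)

  # swapping the groups swaps the two lists exactly
  sw <- group_discriminating_motifs(fal, conf, exclude = "hd1")
  expect_equal(sw$confirmed_universal, out$false_universal)
  expect_equal(sw$false_universal, out$confirmed_universal)

  # identical matrices discriminate nothing
  same <- group_discriminating_motifs(conf, conf[, 1:3])
  expect_length(same$confirmed_universal, 0L)
  expect_length(same$false_universal, 0L)

  # single-member groups reduce to a presence set difference
  one <- group_discriminating_motifs(conf[, 1, drop = FALSE],
                                     fal[, 3, drop = FALSE])
  expect_setequal(one$confirmed_universal,
                  motifs[conf[, 1] & !fal[, 3]])

  expect_error(group_discriminating_motifs(conf[1:3, ], fal), "universes")

  fish <- presence_fisher(conf, fal, exclude = "hd1")
  expect_equal(nrow(fish), 6L)
  expect_true(all(fish$p_value >= 0 & fish$p_value <= 1))
})

test_that("track overlap flags group-discriminating tracks", {
  enh <- GenomicRanges::GRanges("chrE",
    IRanges::IRanges(c(1, 10001, 20001), width = 1000),
    name = c("c1", "c2", "f1"),
    group = c("confirmed", "confirmed", "false"))
  tracks <- list(
    inside = GenomicRanges::GRanges("chrE", IRanges::IRanges(100, 200),
                                    score = 7),
    gaf = GenomicRanges::GRanges("chrE", IRanges::IRanges(20100, 20200),
                                 score = 9),
    near_miss = GenomicRanges::GRanges("chrE", IRanges::IRanges(2002, 2100)))
  rep <- track_overlap_report(enh, tracks, flank = 1000L)
  t1 <- rep$table[rep$table$track == "inside", ]
  expect_true(t1$overlap[t1$name == "c1"])
  expect_equal(t1$max_score[t1$name == "c1"], 7)
  # interval beginning 1,001 bp past the enhancer end is outside the flank
  expect_false(rep$table$overlap[rep$table$track == "near_miss" &
                                 rep$table$name == "c1"])
  ct <- rep$contrast
  expect_true(ct$discriminates[ct$track == "gaf"])     # false group only
  expect_false(ct$discriminates[ct$track == "near_miss"])
})
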