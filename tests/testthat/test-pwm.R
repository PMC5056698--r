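test_that("JASPAR files round-trip and both dialects parse", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 toy1",
    "A [ 10  0  2 ]",
    "C [  0 12  2 ]",
    "G [  1  0  8 ]",
    "T [  1  0  0 ]",
    ">MA0002.1 toy2",
    "4 0 0 4",
    "0 8 0 0",
    "0 0 8 0",
    "4 0 0 4"), path)
  pwms <- read_jaspar(path)
  expect_named(pwms, c("MA0001.1", "MA0002.1"))
  expect_equal(unname(pwms$MA0001.1$counts["C", 2]), 12)
  expect_equal(pwm_width(pwms$MA0002.1), 4L)

  out <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwms, out)
  again <- read_jaspar(out)
  expect_equal(again$MA0001.1$counts, pwms$MA0001.1$counts)
  expect_error(read_jaspar(withr::local_tempfile(lines = "no header")),
               "no motif headers")
})

test_that("window scores follow the log-odds closed forms", {
  model0 <- build_markov_background("ACGT", order = 0L, pseudocount = 0)
  # pwm equal to the background marginals scores 0 everywhere
  flat <- pwm_from_counts(matrix(5, 4, 6), "flat")
  expect_equal(pwm_window_score("ACGTAC", flat, model0), 0)
  # certain pwm on the window's bases, uniform background: width * log(4)
  cert <- sharp_pwm("ACGT", counts = 100, id = "cert")
  s <- pwm_window_score("ACGT", cert, model0, pseudocount = 0)
  expect_equal(s, 4 * log(4))
  # arbitrary 3-wide case against a hand-computed sum
  cnt <- rbind(A = c(3, 0, 1), C = c(1, 1, 1), G = c(0, 2, 1), T = c(0, 1, 1))
  p3 <- pwm_from_counts(cnt, "hand")
  pc <- 0.8
  prob <- sweep(cnt + pc * 0.25, 2, colSums(cnt) + pc, "/")
  hand <- unname(log(prob["A", 1] / .25) + log(prob["G", 2] / .25) +
                 log(prob["C", 3] / .25))
  expect_equal(pwm_window_score("AGC", p3, model0), hand)
  expect_error(pwm_window_score("ACGTA", p3, model0), "width")
})

test_that("gaussian nulls are seeded, reproducible and reject degeneracy", {
  model <- fixture_model()
  pwm <- smooth_pwm()
  n1 <- build_gaussian_null(pwm, model = model, n = 3000, seed = 9)
  n2 <- build_gaussian_null(pwm, model = model, n = 3000, seed = 9)
  expect_equal(n1$mu, n2$mu)
  expect_equal(n1$sigma, n2$sigma)
  # CLT: an independent re-draw's mean lies within 3 sigma / sqrt(n)
  n3 <- build_gaussian_null(pwm, model = model, n = 3000, seed = 10)
  expect_lt(abs(n3$mu - n1$mu), 2 * 3 * n1$sigma / sqrt(3000))

  # pwm identical to the background marginals: all null scores 0
  model0 <- build_markov_background(strrep("ACGT", 50), order = 0L)
  flat <- pwm_from_counts(matrix(25, 4, 8), "flat")
  expect_error(build_gaussian_null(flat, model = model0, n = 100, seed = 1),
               "degenerate")
})

test_that("scanning calibrates against its null and finds planted sites", {
  model <- fixture_model()
  pwm <- smooth_pwm()
  null <- build_gaussian_null(pwm, model = model, n = 10000, seed = 7)

  seqs <- sample_background(model, 401, 20, seed = 13)
  npos <- 20 * (401 - pwm_width(pwm) + 1)
  for (th in c(0.9, 0.95, 0.99)) {
    hits <- sum(vapply(seqs, function(s)
      nrow(scan_pwm(s, pwm, null, threshold = th)), 1L))
    rate <- hits / npos
    tol <- 3 * sqrt(th * (1 - th) / npos)
    # Gaussian-approximation slack on top of the binomial band
    expect_lt(abs(rate - (1 - th)), tol + 0.015)
  }

  # consensus-perfect site for a high-information pwm
  sharp <- sharp_pwm()
  nsharp <- build_gaussian_null(sharp, model = model, n = 5000, seed = 8)
  s <- sample_background(model, 200, 1, seed = 21)
  s <- stripecre:::.plant_site(s, sharp$consensus, 100, "+")
  h <- scan_pwm(s, sharp, nsharp, threshold = 0.9)
  expect_true(100 %in% h$position)
  expect_gt(h$prob_score[h$position == 100], 0.99)

  # threshold 1 can never be reached by a finite score
  expect_equal(nrow(scan_pwm(s, sharp, nsharp, threshold = 1)), 0L)
})

test_that("hit sets are equivariant under reverse complement", {
  model <- fixture_model()
  pwm <- smooth_pwm()
  null <- build_gaussian_null(pwm, model = model, n = 5000, seed = 7)
  s <- sample_background(model, 300, 1, seed = 33)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  w <- pwm_width(pwm); L <- 300
  a <- scan_pwm(s, pwm, null, threshold = 0.8)
  b <- scan_pwm(rc, pwm, null, threshold = 0.8)
  expect_setequal(L - a$position - w + 2L, b$position)
  a2 <- a[order(a$position), ]
  b2 <- b[order(-b$position), ]
  expect_equal(a2$score, b2$score)
  expect_true(all(a2$strand != b2$strand))
})
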