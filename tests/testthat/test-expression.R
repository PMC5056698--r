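test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2), b = c(3, 4))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2, 3))   # per-rank cross-column means
  expect_equal(unname(out[, "b"]), c(2, 3))

  one <- matrix(c(5, 1, 3), ncol = 1)
  expect_equal(quantile_normalize(one), one)  # single column untouched

  same <- matrix(rep(c(2, 7, 4), 3), ncol = 3)
  expect_equal(quantile_normalize(same), same) # fixed point

  set.seed(1)
  r <- matrix(rnorm(60), ncol = 6)
  qn <- quantile_normalize(r)
  # identical sorted multiset per column, idempotent, shape preserved
  sorted <- apply(qn, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(quantile_normalize(qn), qn)
  expect_equal(dim(qn), dim(r))

  expect_error(quantile_normalize(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(quantile_normalize(matrix(c(1, NaN), 1)), "non-finite")
})

test_that("median polish summarization recovers additive structure", {
  one_row <- matrix(c(3, 1, 4), nrow = 1, dimnames = list(NULL, c("x", "y", "z")))
  expect_equal(median_polish_summarize(one_row), c(x = 3, y = 1, z = 4))

  r <- c(0, 1.5, -2, 0.7)          # probe effects
  cc <- c(5, 6, 8, 7.5, 6.2)       # array effects
  add <- outer(r, cc, "+")
  fit <- median_polish_summarize(add)
  expect_equal(diff(fit), diff(cc), tolerance = 1e-8) # c_j up to constant

  const <- matrix(4, 3, 4)
  expect_equal(unname(median_polish_summarize(const)), rep(4, 4))

  expect_error(median_polish_summarize(matrix(numeric(0), 0, 2)), "non-empty")

  probes <- rbind(add, add + 1)
  ps <- summarize_probesets(probes, rep(c("p1", "p2"), each = 4))
  expect_equal(dim(ps), c(2L, 5L))
})

test_that("signed fold change is anti-symmetric with magnitude >= 1", {
  expect_equal(signed_fold_change(0, 1), 2)
  expect_equal(signed_fold_change(1, 0), -2)
  expect_equal(signed_fold_change(3, 3), 1)
  expect_equal(signed_fold_change(0, -0.575), -1.49, tolerance = 0.005)
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(signed_fold_change(a, b), -signed_fold_change(b, a))
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
  expect_error(signed_fold_change(NA, 1), "finite")
  expect_error(signed_fold_change(0, Inf), "finite")
})

test_that("permutation ANOVA matches exhaustive label enumeration", {
  # 6 arrays, 2 stages, no batch: all within-stage label orderings
  des <- expression_design(paste0("a", 1:6),
                           stage = rep(c("5", "6"), each = 3),
                           genotype = c("control", "control", "mutant",
                                        "control", "mutant", "mutant"),
                           batch = rep(1, 6))
  y <- c(1.2, 0.9, 2.4, 1.0, 2.9, 2.6)
  f_of <- function(g) {
    d2 <- des; d2$genotype <- factor(g, levels = c("control", "mutant"))
    stripecre:::.genotype_f(matrix(y, 1), d2$stage, d2$genotype, d2$batch)
  }
  obs <- f_of(as.character(des$genotype))
  p3 <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  g <- as.character(des$genotype)
  fs <- c()
  for (i in 1:6) for (j in 1:6) {
    gp <- c(g[1:3][p3[i, ]], g[4:6][p3[j, ]])
    fs <- c(fs, f_of(gp))
  }
  p_exact <- mean(fs >= obs - 1e-12)
  fit <- fit_probeset_anova(y, des, n_perm = 999, seed = 4)
  expect_equal(fit$f_statistic, unname(obs))
  expect_lt(abs(fit$p_value - p_exact), 0.05)
})

test_that("permutation ANOVA handles degenerate and planted cases", {
  des <- full_design()
  flat <- rep(3.14, 18)
  fit <- fit_probeset_anova(flat, des, n_perm = 30, seed = 1)
  expect_equal(fit$f_statistic, 0)
  expect_equal(fit$p_value, 1)

  # genotype shift of 5 residual SDs -> minimum attainable p
  y <- withr_seed(9, rnorm(18, sd = 0.2)) +
    ifelse(des$genotype == "mutant", 1.0, 0)
  fit <- fit_probeset_anova(y, des, n_perm = 99, seed = 2)
  expect_equal(fit$p_value, 1 / 100)

  bad <- des; bad$genotype <- factor(rep("control", 18),
                                     levels = c("control", "mutant"))
  expect_error(fit_probeset_anova(y, bad, seed = 1), "constant")
  expect_error(fit_probeset_anova(c(y, 1), des, seed = 1), "one value per array")
})

test_that("q-value adjustment reduces to BH at pi0 = 1 and preserves order", {
  expect_equal(qvalue_adjust(c(0.01, 0.02, 0.04), pi0 = 1),
               c(0.03, 0.03, 0.04))
  expect_equal(qvalue_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(qvalue_adjust(0.03, pi0 = 0.5), 0.015)
  expect_equal(qvalue_adjust(0.03), 0.03)  # few p-values: pi0 falls back to 1
  set.seed(3)
  p <- runif(500)^1.5
  q <- qvalue_adjust(p)
  pi0_hat <- min(1, mean(p > 0.5) / 0.5)
  expect_true(all(q >= pi0_hat * p.adjust(p, "BH") - 1e-12))
  expect_true(all(q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))   # monotone in p
  expect_error(qvalue_adjust(c(0.1, 0)), "0, 1")
  expect_error(qvalue_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("filter cascade counts are set-algebraically consistent", {
  res <- data.frame(
    probeset_id = paste0("p", 1:6),
    q_value = c(0.01, 0.01, 0.2, 0.01, 0.04, 0.5),
    fc_stage = c(1.5, 1.2, 1.3, 1.05, 1.2, 2),
    fc_genotype = c(-1.8, 1.4, -1.2, -1.5, -1.3, 1.1))
  out <- filter_candidates(res, 0.05, 1.1)
  expect_setequal(out$responsive, c("p1", "p2", "p4", "p5"))
  expect_setequal(out$zygotic, c("p1", "p2", "p3", "p5", "p6"))
  expect_setequal(out$intersection, c("p1", "p2", "p5"))
  expect_equal(length(out$intersection), length(out$up) + length(out$down))
  expect_equal(out$ranked$probeset_id, c("p1", "p5")) # |fc_genotype| desc
  expect_equal(out$counts$n_intersection, out$counts$n_up + out$counts$n_down)

  none <- filter_candidates(transform(res, q_value = 0.9), 0.05, 1.1)
  expect_length(none$intersection, 0)
  expect_length(none$down, 0)
  expect_error(filter_candidates(res[0, ]), "non-empty")
})

test_that("screen recovers planted down-in-mutant probesets in order", {
  cfg <- simulation_config(seed = 21,
    expression = list(n_probesets = 400L, n_targets = 10L,
                      noise_sd = 0, batch_sd = 0))
  ex <- simulate_expression(cfg)
  sc <- expression_screen(ex$values, ex$design, n_perm = 60, seed = 22)
  out <- filter_candidates(sc)
  expect_setequal(out$down, ex$truth$target_probesets)
  # with equal planted effects the ranking is by |fc_genotype| then id
  expect_true(all(diff(abs(out$ranked$fc_genotype)) <= 1e-12))
})

test_that("array correlations group replicates and flag degenerate columns", {
  set.seed(5)
  base <- matrix(rnorm(200), ncol = 4,
                 dimnames = list(NULL, paste0("a", 1:4)))
  m <- cbind(base, a5 = base[, 1])             # duplicated column
  ac <- array_correlations(m)
  expect_equal(ac$matrix["a1", "a5"], 1)
  expect_true(isSymmetric(ac$matrix))
  expect_equal(unname(diag(ac$matrix)), rep(1, 5))

  m2 <- cbind(base[, 1:2], neg = -base[, 1])
  expect_equal(array_correlations(m2)$matrix[1, "neg"], -1)

  m3 <- cbind(base, flat = rep(1, 50))
  expect_error(array_correlations(m3), "flat")

  # stage effect >> genotype effect: arrays group by stage
  cfg <- simulation_config(seed = 31, expression = list(
    stage_effect_target = 1.5, frac_stage_responsive = 0.9,
    stage_effect_sd = 1.0, genotype_effect = -0.2))
  ex <- simulate_expression(cfg)
  ac <- array_correlations(ex$values)
  d <- ex$design
  ws <- outer(d$stage, d$stage, "==") & !diag(18)
  wg <- outer(d$genotype, d$genotype, "==") & !ws & !diag(18)
  expect_gt(mean(ac$matrix[ws]), mean(ac$matrix[wg]))
})
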