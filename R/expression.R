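#' Construct and validate an array design
#'
#' The expression experiment is a full factorial of developmental stage
#' (blastoderm 5, gastrula 6, germband extension 8), genotype (control
#' wildtype vs maternal-mutant) and hybridization batch, three replicates per
#' stage/genotype cell, eighteen arrays in all. Genotype may be coded
#' `0`/`1`; `0` is taken as control.
#'
#' @param array_id character vector of unique array identifiers.
#' @param stage per-array stage labels (coerced to factor).
#' @param genotype per-array genotype labels; levels are normalized to
#'   `control`/`mutant` (`0` -> control, `1` -> mutant).
#' @param batch per-array batch labels (coerced to factor).
#' @return a `data.frame` with columns `array_id`, `stage`, `genotype`,
#'   `batch`.
#' @export
expression_design <- function(array_id, stage, genotype, batch) {
  n <- length(array_id)
  if (anyDuplicated(array_id)) stop2("array_id values must be unique")
  if (length(stage) != n || length(genotype) != n || length(batch) != n)
    stop2("array_id, stage, genotype and batch must have one entry per array")
  g <- as.character(genotype)
  g[g %in% c("0", "control", "wt", "wildtype")] <- "control"
  g[g %in% c("1", "mutant")] <- "mutant"
  bad <- setdiff(unique(g), c("control", "mutant"))
  if (length(bad)) stop2("unrecognized genotype label(s): ", paste(bad, collapse = ", "))
  data.frame(
    array_id = as.character(array_id),
    stage = factor(as.character(stage)),
    genotype = factor(g, levels = c("control", "mutant")),
    batch = factor(as.character(batch)),
    stringsAsFactors = FALSE
  )
}

#' Quantile-normalize a probe intensity matrix
#'
#' Forces every array (column) onto the identical value distribution: each
#' column's sorted values are replaced by the per-rank cross-column mean
#' (ties share the mean of their ranks). Delegates to
#' [limma::normalizeQuantiles()] after validation.
#'
#' @param values numeric matrix, probes x arrays, no missing values.
#' @return matrix of the same shape with identical column value multisets.
#' @export
quantile_normalize <- function(values) {
  assert_finite_matrix(values, "expression matrix")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Summarize one probeset by median polish
#'
#' Tukey median polish on the probes x arrays block of a single probeset;
#' the per-array summary is the fitted overall effect plus the column
#' (array) effect, the robust equivalent of the standard probe-summary step.
#'
#' @param probe_values numeric matrix, probes x arrays, for one probeset.
#' @param maxiter,eps iteration controls passed to [stats::medpolish()].
#' @return numeric vector of per-array summaries (named by column).
#' @export
median_polish_summarize <- function(probe_values, maxiter = 20L, eps = 0.01) {
  if (is.vector(probe_values)) probe_values <- matrix(probe_values, nrow = 1L)
  assert_finite_matrix(probe_values, "probe matrix")
  if (nrow(probe_values) == 1L) {
    return(setNames(as.numeric(probe_values[1L, ]), colnames(probe_values)))
  }
  fit <- stats::medpolish(probe_values, eps = eps, maxiter = maxiter,
                          trace.iter = FALSE)
  setNames(fit$overall + fit$col, colnames(probe_values))
}

#' Summarize a probe-level matrix to probeset level
#'
#' @param values probe x array matrix (typically quantile-normalized).
#' @param probeset character vector, one probeset id per probe row.
#' @return probeset x array matrix of median-polish summaries.
#' @export
summarize_probesets <- function(values, probeset) {
  assert_finite_matrix(values, "probe matrix")
  if (length(probeset) != nrow(values))
    stop2("probeset must have one id per probe row")
  ids <- unique(probeset)
  out <- t(vapply(ids, function(id) {
    median_polish_summarize(values[probeset == id, , drop = FALSE])
  }, numeric(ncol(values))))
  dimnames(out) <- list(ids, colnames(values))
  out
}

#' Signed fold change between two log2 means
#'
#' With `d = mean_s2 - mean_s1`, returns `2^d` when `d >= 0` and `-2^(-d)`
#' otherwise, so the magnitude is always at least 1 and the sign carries the
#' direction (a halving is reported as -2, not 0.5). Antisymmetric under
#' swapping the arguments.
#'
#' @param mean_s1,mean_s2 numeric log2 means (vectorized).
#' @return signed fold change(s).
#' @export
signed_fold_change <- function(mean_s1, mean_s2) {
  if (any(!is.finite(mean_s1)) || any(!is.finite(mean_s2)))
    stop2("signed_fold_change requires finite inputs")
  d <- mean_s2 - mean_s1
  ifelse(d >= 0, 2^d, -(2^(-d)))
}

# Residual sums of squares of Y rows under the column space of X.
.rss_rows <- function(Y, X) {
  qx <- qr(X)
  res <- qr.resid(qx, t(Y))
  colSums(res * res)
}

# F statistics for the genotype term, rows of Y against a given genotype
# labelling; stage and batch always retained.
.genotype_f <- function(Y, stage, genotype, batch) {
  df <- data.frame(stage = stage, genotype = genotype, batch = batch)
  covars <- c("stage", "batch")[c(nlevels(factor(stage)) > 1L,
                                  nlevels(factor(batch)) > 1L)]
  rhs <- paste(c("1", covars), collapse = " + ")
  X_full <- model.matrix(stats::as.formula(paste("~", rhs, "+ genotype")), df)
  X_red <- model.matrix(stats::as.formula(paste("~", rhs)), df)
  r_full <- qr(X_full)$rank
  df1 <- r_full - qr(X_red)$rank
  df2 <- nrow(X_full) - r_full
  if (df1 < 1L) stop2("genotype is confounded with stage/batch")
  if (df2 < 1L) stop2("fewer than 1 residual degree of freedom")
  rss_f <- .rss_rows(Y, X_full)
  rss_r <- .rss_rows(Y, X_red)
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  # rows with no variation beyond the reduced fit carry no genotype signal;
  # guard against floating-point residual dust masquerading as an F ratio
  tss <- rowSums((Y - rowMeans(Y))^2)
  f[rss_r <= 1e-12 * (1 + tss)] <- 0
  f[is.nan(f)] <- 0
  f
}

# Genotype labels permuted independently within each stage stratum.
.permute_genotype <- function(design, n_perm) {
  strata <- split(seq_len(nrow(design)), design$stage)
  lapply(seq_len(n_perm), function(i) {
    g <- as.character(design$genotype)
    for (idx in strata) g[idx] <- g[sample(idx)]
    factor(g, levels = levels(design$genotype))
  })
}

#' Permutation ANOVA for a single probeset
#'
#' Fits the per-probeset linear model `y ~ stage + genotype + batch` (batch as
#' a fixed blocking term; the design is balanced, so the genotype F-test
#' agrees with the mixed-model formulation) and computes the F statistic for
#' the genotype term after adjusting for stage and batch. The p-value is a
#' permutation p-value: genotype labels are reshuffled within stage strata
#' `n_perm` times and `p = (1 + b) / (n_perm + 1)` where `b` counts permuted F
#' statistics at least as large as the observed one.
#'
#' @param y numeric vector of per-array log2 values.
#' @param design a design from [expression_design()].
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed for the permutations.
#' @return list with `f_statistic`, `p_value`, and the vector `perm_f`.
#' @export
fit_probeset_anova <- function(y, design, n_perm = 100L, seed = 1L) {
  if (length(y) != nrow(design)) stop2("y must have one value per array")
  if (any(!is.finite(y))) stop2("y contains non-finite values")
  if (n_perm < 1L) stop2("n_perm must be at least 1")
  if (length(unique(design$genotype)) < 2L)
    stop2("genotype is constant across arrays")
  Y <- matrix(y, nrow = 1L)
  f_obs <- .genotype_f(Y, design$stage, design$genotype, design$batch)
  perm_f <- with_seed(seed, {
    vapply(.permute_genotype(design, n_perm), function(g) {
      .genotype_f(Y, design$stage, g, design$batch)
    }, numeric(1L))
  })
  list(
    f_statistic = unname(f_obs),
    p_value = (1 + sum(perm_f >= f_obs)) / (n_perm + 1),
    perm_f = unname(perm_f)
  )
}

#' Storey q-values
#'
#' Adjusts p-values for multiple testing with the q-value method: the null
#' proportion pi0 is estimated as `mean(p > lambda) / (1 - lambda)` (capped
#' at 1) and multiplies the Benjamini-Hochberg adjusted values. With fewer
#' than `min_n_pi0` p-values the pi0 estimate is unstable, so pi0 falls back
#' to 1 (plain BH) unless given explicitly.
#'
#' @param p p-values in (0, 1].
#' @param lambda tuning point for the pi0 estimate.
#' @param pi0 optional fixed null proportion overriding estimation.
#' @param min_n_pi0 minimum number of p-values before pi0 is estimated.
#' @return q-values, order-preserving and in `[0, 1]`.
#' @export
qvalue_adjust <- function(p, lambda = 0.5, pi0 = NULL, min_n_pi0 = 100L) {
  if (length(p) == 0L) stop2("no p-values supplied")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop2("p-values must lie in (0, 1]")
  if (is.null(pi0)) {
    pi0 <- if (length(p) < min_n_pi0) 1 else
      min(1, mean(p > lambda) / (1 - lambda))
    if (pi0 <= 0) pi0 <- 1 / length(p)   # degenerate: everything significant
  }
  pmin(1, pi0 * p.adjust(p, method = "BH"))
}

#' Screen every probeset for a genotype response
#'
#' Runs the permutation ANOVA over all rows of a probeset-level log2 matrix.
#' A single set of within-stage genotype permutations is shared across
#' probesets and, by default, the permuted F statistics are pooled across
#' probesets so the permutation p-values have resolution
#' `1 / (n_perm * n_probesets + 1)` rather than `1 / (n_perm + 1)` --- the
#' behaviour of the standard microarray permutation-ANOVA implementations,
#' and necessary for FDR control to have any traction at 100 permutations.
#' Signed fold changes are computed for the zygotic stage step (stage 6 vs
#' stage 5 means in control arrays) and for genotype (mutant vs control
#' means over all stages).
#'
#' @param values probeset x array matrix of log2 intensities.
#' @param design a design from [expression_design()]; rows must match the
#'   columns of `values`.
#' @param n_perm permutations of the genotype labels.
#' @param seed integer seed.
#' @param pool pool permuted F statistics across probesets (default) or keep
#'   each probeset's own permutation distribution.
#' @param stage_from,stage_to stage levels used for the zygotic fold change.
#' @return data.frame with one row per probeset: `probeset_id`,
#'   `f_statistic`, `p_value`, `q_value`, `fc_stage`, `fc_genotype`, the
#'   filter flags `responsive` (filled by [filter_candidates()] thresholds),
#'   `zygotic_increase`, `down_in_mutant`.
#' @export
expression_screen <- function(values, design, n_perm = 100L, seed = 1L,
                              pool = TRUE, stage_from = NULL, stage_to = NULL) {
  assert_finite_matrix(values, "expression matrix")
  if (ncol(values) != nrow(design))
    stop2("design must have one row per array column")
  if (length(unique(design$genotype)) < 2L)
    stop2("genotype is constant across arrays")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("ps_", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values))) stop2("probeset ids must be unique")

  stages <- levels(design$stage)
  stage_from <- stage_from %||% stages[1L]
  stage_to <- stage_to %||% stages[min(2L, length(stages))]

  f_obs <- .genotype_f(values, design$stage, design$genotype, design$batch)
  perms <- with_seed(substream_seed(seed, "anova-perm"),
                     .permute_genotype(design, n_perm))
  perm_f <- vapply(perms, function(g) {
    .genotype_f(values, design$stage, g, design$batch)
  }, numeric(nrow(values)))
  if (!is.matrix(perm_f)) perm_f <- matrix(perm_f, nrow = nrow(values))

  if (pool) {
    pooled <- sort(as.numeric(perm_f))
    n_null <- length(pooled)
    # count of pooled permuted F >= each observed F
    b <- n_null - findInterval(f_obs, pooled, left.open = TRUE)
    p <- (1 + b) / (n_null + 1)
  } else {
    b <- rowSums(perm_f >= f_obs)
    p <- (1 + b) / (n_perm + 1)
  }

  ctrl <- design$genotype == "control"
  m_from <- rowMeans(values[, ctrl & design$stage == stage_from, drop = FALSE])
  m_to <- rowMeans(values[, ctrl & design$stage == stage_to, drop = FALSE])
  m_ctrl <- rowMeans(values[, ctrl, drop = FALSE])
  m_mut <- rowMeans(values[, !ctrl, drop = FALSE])

  data.frame(
    probeset_id = rownames(values),
    f_statistic = unname(f_obs),
    p_value = unname(p),
    q_value = unname(qvalue_adjust(p)),
    fc_stage = unname(signed_fold_change(m_from, m_to)),
    fc_genotype = unname(signed_fold_change(m_ctrl, m_mut)),
    stringsAsFactors = FALSE
  )
}

#' Cascade counts and percentages
#'
#' Bookkeeping for the target-gene filter cascade: given the total number of
#' probesets, the genotype-responsive count, the zygotic-increase count and
#' the up/down split of their intersection, recomputes the derived totals and
#' whole-number percentages (responsive and zygotic relative to the total;
#' up/down relative to the intersection), rounding half away from zero.
#'
#' @param n_total,n_responsive,n_zygotic,n_up,n_down integer counts.
#' @return named list of counts and percentages.
#' @export
cascade_counts <- function(n_total, n_responsive, n_zygotic, n_up, n_down) {
  n_intersection <- n_up + n_down
  list(
    n_total = n_total,
    n_responsive = n_responsive,
    pct_responsive = round_half_away(100 * n_responsive / n_total),
    n_zygotic = n_zygotic,
    pct_zygotic = round_half_away(100 * n_zygotic / n_total),
    n_intersection = n_intersection,
    n_up = n_up,
    pct_up = round_half_away(100 * n_up / n_intersection),
    n_down = n_down,
    pct_down = round_half_away(100 * n_down / n_intersection)
  )
}

#' Filter-cascade selection of candidate direct targets
#'
#' Applies the three-step cascade to a screen result: (i) genotype-responsive
#' probesets (`q_value < q_threshold`); (ii) probesets with a zygotic
#' expression increase (`fc_stage >= fc_threshold`, signed fold change of the
#' stage step in control arrays); (iii) their intersection, split by the sign
#' of the genotype fold change. Probesets *up* in the mutant are set aside as
#' likely indirect; probesets *down* in the mutant (requiring the factor for
#' activation) are ranked by `|fc_genotype|` descending as the candidate
#' direct targets.
#'
#' @param results data.frame from [expression_screen()].
#' @param q_threshold FDR threshold (default 0.05).
#' @param fc_threshold minimum stage signed fold change (default 1.1).
#' @return list with the id sets (`responsive`, `zygotic`, `intersection`,
#'   `up`, `down`), the ranked data.frame `ranked` of down-in-mutant
#'   candidates, the flagged per-probeset table `flags`, and `counts` from
#'   [cascade_counts()].
#' @export
filter_candidates <- function(results, q_threshold = 0.05, fc_threshold = 1.1) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop2("results must be a non-empty data.frame")
  need <- c("probeset_id", "q_value", "fc_stage", "fc_genotype")
  if (!all(need %in% names(results)))
    stop2("results lacks columns: ", paste(setdiff(need, names(results)), collapse = ", "))

  responsive <- results$q_value < q_threshold
  zygotic <- results$fc_stage >= fc_threshold
  both <- responsive & zygotic
  up <- both & results$fc_genotype > 0
  down <- both & results$fc_genotype < 0

  flags <- cbind(results,
                 responsive = responsive,
                 zygotic_increase = zygotic,
                 down_in_mutant = down)
  ranked <- flags[down, , drop = FALSE]
  ranked <- ranked[order(-abs(ranked$fc_genotype), ranked$probeset_id), , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))

  list(
    responsive = results$probeset_id[responsive],
    zygotic = results$probeset_id[zygotic],
    intersection = results$probeset_id[both],
    up = results$probeset_id[up],
    down = results$probeset_id[down],
    ranked = ranked,
    flags = flags,
    counts = cascade_counts(nrow(results), sum(responsive), sum(zygotic),
                            sum(up), sum(down))
  )
}

#' Array-by-array Pearson correlations with average-linkage grouping
#'
#' @param values probeset x array matrix.
#' @return list with the symmetric correlation `matrix` and an `hclust`
#'   grouping on distance `1 - r` (average linkage).
#' @export
array_correlations <- function(values) {
  assert_finite_matrix(values, "expression matrix")
  if (ncol(values) < 2L) stop2("need at least two arrays")
  sds <- apply(values, 2L, sd)
  if (any(sds == 0))
    stop2("zero-variance array column(s): ",
          paste(colnames(values)[sds == 0] %||% which(sds == 0), collapse = ", "))
  r <- cor(values, method = "pearson")
  list(matrix = r, clustering = hclust(as.dist(1 - r), method = "average"))
}
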