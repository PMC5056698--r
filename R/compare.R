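#' Motif presence/absence matrix for an enhancer set
#'
#' A cell is `TRUE` when [scan_pwm()] reports at least one hit for that
#' motif in that enhancer at the given probability-score threshold. Note
#' that at the per-position candidate threshold of 0.9 roughly one position
#' in ten exceeds the null by construction, so presence/absence
#' classification of ~1 kb regions is only meaningful at a much stricter
#' threshold (the pipeline default is 0.9999); the matrix is monotone in
#' the threshold either way.
#'
#' @param enhancers named character vector or `DNAStringSet` of enhancer
#'   sequences.
#' @param pwms named list of `pwm` objects.
#' @param nulls named list of `pwm_null` objects covering every pwm.
#' @param threshold per-position probability-score threshold.
#' @return logical matrix, motifs x enhancers, with a `n_present` attribute
#'   (per-motif presence counts).
#' @export
build_presence_matrix <- function(enhancers, pwms, nulls, threshold = 0.9) {
  seqs <- if (methods::is(enhancers, "DNAStringSet"))
    setNames(as.character(enhancers), names(enhancers))
  else unlist(enhancers)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop2("enhancers must be uniquely named")
  ids <- vapply(pwms, `[[`, "", "id")
  missing_null <- setdiff(ids, names(nulls))
  if (length(missing_null))
    stop2("no null for motif(s): ", paste(missing_null, collapse = ", "))
  m <- matrix(FALSE, nrow = length(pwms), ncol = length(seqs),
              dimnames = list(ids, names(seqs)))
  for (i in seq_along(pwms)) {
    for (j in seq_along(seqs)) {
      hits <- scan_pwm(seqs[[j]], pwms[[i]], nulls[[ids[i]]],
                       threshold = threshold)
      m[i, j] <- nrow(hits) > 0L
    }
  }
  attr(m, "n_present") <- rowSums(m)
  m
}

#' Motifs discriminating confirmed from false enhancers
#'
#' Implements the universal-presence contrast literally: list A holds
#' motifs present in *every* confirmed enhancer but absent from at least
#' one false enhancer; list B holds the converse. Motifs flagged in
#' `exclude` (e.g. the homeodomain motifs, whose sites mimic the bait
#' factor's own) are dropped before the comparison.
#'
#' @param confirmed,false_set presence matrices from
#'   [build_presence_matrix()] over the same motif universe.
#' @param exclude character vector of motif ids to drop (or a named logical
#'   vector, `TRUE` meaning drop).
#' @return list with `confirmed_universal` and `false_universal` motif id
#'   vectors.
#' @export
group_discriminating_motifs <- function(confirmed, false_set, exclude = NULL) {
  if (!identical(rownames(confirmed), rownames(false_set)))
    stop2("presence matrices cover different motif universes")
  keep <- rownames(confirmed)
  if (!is.null(exclude)) {
    if (is.logical(exclude)) exclude <- names(exclude)[exclude]
    keep <- setdiff(keep, exclude)
  }
  cm <- confirmed[keep, , drop = FALSE]
  fm <- false_set[keep, , drop = FALSE]
  all_c <- rowSums(cm) == ncol(cm)
  all_f <- rowSums(fm) == ncol(fm)
  list(
    confirmed_universal = keep[all_c & !all_f],
    false_universal = keep[all_f & !all_c]
  )
}

#' Fisher-exact presence contrast (extension)
#'
#' An optional enrichment-style contrast of per-motif presence counts
#' between the two groups; this is an extension beyond the literal
#' universal-presence comparison, provided for larger enhancer sets where
#' the all-or-none criterion is too brittle.
#'
#' @inheritParams group_discriminating_motifs
#' @return data.frame with per-motif presence counts, odds ratio and
#'   two-sided Fisher p-value.
#' @export
presence_fisher <- function(confirmed, false_set, exclude = NULL) {
  if (!identical(rownames(confirmed), rownames(false_set)))
    stop2("presence matrices cover different motif universes")
  keep <- rownames(confirmed)
  if (!is.null(exclude)) {
    if (is.logical(exclude)) exclude <- names(exclude)[exclude]
    keep <- setdiff(keep, exclude)
  }
  res <- lapply(keep, function(id) {
    a <- sum(confirmed[id, ]); b <- ncol(confirmed) - a
    c <- sum(false_set[id, ]); d <- ncol(false_set) - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L))
    data.frame(motif = id, confirmed_present = a, confirmed_absent = b,
               false_present = c, false_absent = d,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Chromatin-track overlap report for enhancer groups
#'
#' For every enhancer and every track (e.g. GAF, PC, Pho ChIP intervals or
#' open-chromatin calls), reports whether any track interval falls within
#' `flank` bases of the enhancer and the maximum score among overlapping
#' intervals. A group-level contrast flags tracks that overlap every
#' member of one group but not every member of the other.
#'
#' @param enhancers `GRanges` with `name` and `group` metadata columns
#'   (e.g. `"confirmed"` / `"false"`).
#' @param tracks named list of `GRanges`, each optionally carrying a
#'   `score` column.
#' @param flank distance in bases defining "near" (default 1000).
#' @return list with `table` (per enhancer x track rows: `name`, `group`,
#'   `track`, `overlap`, `max_score`) and `contrast` (per track: per-group
#'   overlap counts and a `discriminates` flag).
#' @export
track_overlap_report <- function(enhancers, tracks, flank = 1000L) {
  if (is.null(enhancers$name) || is.null(enhancers$group))
    stop2("enhancers must carry name and group columns")
  rows <- list()
  for (tr in names(tracks)) {
    gr <- tracks[[tr]]
    hits <- GenomicRanges::findOverlaps(enhancers, gr, maxgap = flank,
                                        ignore.strand = TRUE)
    ov <- logical(length(enhancers))
    mx <- rep(NA_real_, length(enhancers))
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      ov[unique(q)] <- TRUE
      sc <- if (!is.null(gr$score)) gr$score[S4Vectors::subjectHits(hits)]
            else rep(NA_real_, length(hits))
      for (i in unique(q)) mx[i] <- suppressWarnings(max(sc[q == i], na.rm = TRUE))
      mx[!is.finite(mx)] <- NA_real_
    }
    rows[[tr]] <- data.frame(name = enhancers$name, group = enhancers$group,
                             track = tr, overlap = ov, max_score = mx,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  groups <- unique(enhancers$group)
  contrast <- do.call(rbind, lapply(names(tracks), function(tr) {
    sub <- tab[tab$track == tr, ]
    cnt <- vapply(groups, function(g) sum(sub$overlap[sub$group == g]), 1L)
    tot <- vapply(groups, function(g) sum(sub$group == g), 1L)
    uni <- cnt == tot
    data.frame(track = tr,
               t(setNames(cnt, paste0("n_", groups))),
               t(setNames(tot, paste0("total_", groups))),
               discriminates = sum(uni) == 1L,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, contrast = contrast)
}
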