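#' Parse a printed genomic interval
#'
#' Parses the `"chrom:start..end"` convention used for printed enhancer
#' coordinates (1-based, fully closed, genome release 6 style) into a
#' `GRanges`. The printed length is `end - start + 1`, which is exactly the
#' `width()` of the returned range.
#'
#' @param text character vector of `"chrom:start..end"` strings.
#' @return a `GRanges` with one range per input string.
#' @export
interval_from_string <- function(text) {
  text <- as.character(text)
  m <- regmatches(text, regexec("^([^:]+):([0-9]+)\\.\\.([0-9]+)$", text))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop2("malformed interval string: ", text[bad][1L])
  chrom <- vapply(m, `[`, "", 2L)
  start <- as.numeric(vapply(m, `[`, "", 3L))
  end <- as.numeric(vapply(m, `[`, "", 4L))
  if (any(start > end)) stop2("interval start exceeds end")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

#' Format a GRanges in the printed interval convention
#'
#' @param gr a `GRanges`.
#' @return character vector of `"chrom:start..end"` strings.
#' @export
interval_to_string <- function(gr) {
  sprintf("%s:%d..%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Fixed-width windows around ChIP peak maxima
#'
#' Centers a window of odd `width` on each peak's position of maximal
#' binding (`peak_max` metadata column, absolute 1-based coordinate) and
#' clamps it at chromosome ends; clamped windows are shorter and flagged
#' rather than discarded.
#'
#' @param peaks `GRanges` of ChIP peaks carrying a `peak_max` column.
#' @param genome named `DNAStringSet` (chromosome sequences).
#' @param width odd window width in bases (default 401).
#' @return `GRanges` of windows with metadata columns `peak_max`, `clamped`
#'   and `seq` (the extracted window sequence); other peak columns carried
#'   through.
#' @export
extract_peak_window <- function(peaks, genome, width = 401L) {
  if (width %% 2L != 1L) stop2("window width must be odd")
  if (is.null(peaks$peak_max)) stop2("peaks must carry a peak_max column")
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  unknown <- setdiff(unique(chroms), names(genome))
  if (length(unknown))
    stop2("peak(s) on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  half <- (width - 1L) %/% 2L
  lens <- setNames(Biostrings::width(genome), names(genome))[chroms]
  start <- pmax(1L, peaks$peak_max - half)
  end <- pmin(as.integer(lens), peaks$peak_max + half)
  win <- GenomicRanges::GRanges(chroms, IRanges::IRanges(start, end))
  S4Vectors::mcols(win) <- S4Vectors::mcols(peaks)
  win$clamped <- (end - start + 1L) < width
  win$seq <- vapply(seq_along(win), function(i) {
    as.character(Biostrings::subseq(genome[[chroms[i]]], start[i], end[i]))
  }, "")
  win
}

#' Merge overlapping windows into disjoint intervals
#'
#' @param intervals a `GRanges`.
#' @return sorted, disjoint `GRanges` covering exactly the union.
#' @export
merge_windows <- function(intervals) {
  GenomicRanges::reduce(GenomicRanges::sort(intervals))
}

#' Assign ChIP peaks to genes by proximity
#'
#' A peak is assigned to every gene whose interval lies within
#' `max_distance` bases of the peak interval (gap of 0 for overlap); one
#' peak may serve several genes. Gap semantics follow
#' [GenomicRanges::distance()].
#'
#' @param peaks `GRanges` of peaks.
#' @param genes `GRanges` of genes with a `gene_id` column.
#' @param max_distance maximum allowed gap in bases (default 70000).
#' @return data.frame with columns `gene_id`, `peak` (index into `peaks`)
#'   and `distance`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, max_distance = 70000L) {
  if (is.null(genes$gene_id)) stop2("genes must carry a gene_id column")
  hits <- GenomicRanges::findOverlaps(peaks, genes, maxgap = max_distance,
                                      ignore.strand = TRUE)
  d <- GenomicRanges::distance(peaks[S4Vectors::queryHits(hits)],
                               genes[S4Vectors::subjectHits(hits)],
                               ignore.strand = TRUE)
  keep <- !is.na(d) & d <= max_distance
  data.frame(
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)][keep],
    peak = S4Vectors::queryHits(hits)[keep],
    distance = d[keep],
    stringsAsFactors = FALSE
  )
}

#' Select the candidate enhancer for one gene
#'
#' Implements the three-criterion choice: among the peaks assigned to the
#' gene, consider first the strict-FDR tier; order peaks by descending
#' binding score (ties: smaller distance from the peak maximum to the gene's
#' nearest edge, then leftmost coordinate) and select the first whose
#' surrounding `enhancer_width` window contains at least one degenerate
#' consensus match. If no strict-tier peak qualifies the relaxed tier is
#' tried (`tier_used = "relaxed"`). Absence is a value: when nothing
#' qualifies the return carries a `reason` (`"no_peaks"` or
#' `"no_consensus"`) instead of an interval.
#'
#' @param gene a length-1 `GRanges` with `gene_id`.
#' @param peaks `GRanges` of the peaks assigned to this gene, with columns
#'   `peak_max`, `score`, `fdr_tier` (`"strict"`/`"relaxed"`) and `name`.
#' @param genome named `DNAStringSet`.
#' @param consensus IUPAC consensus (default `BSAAGGHYRHH`).
#' @param enhancer_width odd width of the candidate region (default 1001,
#'   i.e. peak maximum +/- 500).
#' @param open_chromatin optional `GRanges` of accessible-chromatin
#'   intervals; sets the `open_chromatin` flag by overlap.
#' @param include_soft_masked passed to [find_iupac_matches()].
#' @return an object of class `candidate_enhancer`: a list with `gene_id`,
#'   `interval` (`GRanges` or `NULL`), `source_peak` (name), `tier_used`,
#'   `consensus_hits` (data.frame), `open_chromatin` (logical or `NA`),
#'   `clamped` and `reason` (`NA` when a candidate was found).
#' @export
select_candidate_enhancer <- function(gene, peaks, genome,
                                      consensus = "BSAAGGHYRHH",
                                      enhancer_width = 1001L,
                                      open_chromatin = NULL,
                                      include_soft_masked = TRUE) {
  stopifnot(length(gene) == 1L)
  out <- list(gene_id = gene$gene_id, interval = NULL, source_peak = NA_character_,
              tier_used = NA_character_, consensus_hits = NULL,
              open_chromatin = NA, clamped = FALSE, reason = NA_character_)
  class(out) <- "candidate_enhancer"
  if (length(peaks) == 0L) {
    out$reason <- "no_peaks"
    return(out)
  }
  for (tier in c("strict", "relaxed")) {
    pk <- peaks[peaks$fdr_tier == tier]
    if (length(pk) == 0L) next
    gap <- abs(pmin(pmax(pk$peak_max, GenomicRanges::start(gene)),
                    GenomicRanges::end(gene)) - pk$peak_max)
    ord <- order(-pk$score, gap, GenomicRanges::start(pk))
    for (i in ord) {
      win <- extract_peak_window(pk[i], genome, width = enhancer_width)
      hits <- find_iupac_matches(win$seq, consensus,
                                 include_soft_masked = include_soft_masked)
      if (nrow(hits) == 0L) next
      hits$start <- hits$start + GenomicRanges::start(win) - 1L
      hits$end <- hits$end + GenomicRanges::start(win) - 1L
      out$interval <- GenomicRanges::granges(win)
      out$source_peak <- pk$name[i] %||% as.character(i)
      out$tier_used <- tier
      out$consensus_hits <- hits
      out$clamped <- win$clamped
      if (!is.null(open_chromatin)) {
        out$open_chromatin <-
          length(GenomicRanges::findOverlaps(out$interval, open_chromatin,
                                             ignore.strand = TRUE)) > 0L
      }
      return(out)
    }
  }
  out$reason <- "no_consensus"
  out
}

#' @export
print.candidate_enhancer <- function(x, ...) {
  if (is.null(x$interval)) {
    cat(sprintf("candidate_enhancer <%s>: none (%s)\n", x$gene_id, x$reason))
  } else {
    cat(sprintf("candidate_enhancer <%s>: %s [%s tier, peak %s, %d consensus hit(s)]\n",
                x$gene_id, interval_to_string(x$interval), x$tier_used,
                x$source_peak, nrow(x$consensus_hits)))
  }
  invisible(x)
}
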