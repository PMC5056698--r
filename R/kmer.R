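#' K-mer over-representation against a Markov background
#'
#' An explicit re-casting of the discriminative motif-discovery step as an
#' exact word-count test. Every k-mer (collapsed with its reverse
#' complement) is tested for over-representation in the foreground
#' sequences relative to an order-k Markov background model. The test
#' statistic is the number of *sequences* containing at least one
#' occurrence of the word (on either strand), the zero-or-one-per-sequence
#' convention of discriminative motif finders: it is insensitive to the
#' clumping of self-overlapping words that makes raw occurrence counts
#' overdispersed. Under the model, a sequence with `m` scoreable windows
#' contains the word with probability at most `1 - exp(-m * p)` (Poisson
#' clumping bound), and the p-value is the exact binomial upper tail at the
#' mean of the per-sequence probabilities. Raw occurrence counts and their
#' expectations are reported alongside.
#'
#' @param foreground character vector or `DNAStringSet` of sequences.
#' @param model a `markov_background` (the null).
#' @param k_range word lengths to test (default 4:10, i.e. up to the usual
#'   maximum motif width, with the 4-mer core at the short end).
#' @param collapse_rc collapse each word with its reverse complement
#'   (default `TRUE`; `FALSE` tests each orientation separately on the
#'   forward strand only).
#' @return data.frame ranked by p-value then fold enrichment: `kmer`, `k`,
#'   `n_seqs` (sequences containing the word), `expected_seqs`, `count`
#'   (total occurrences), `expected_count`, `fold`, `p_value`, `q_value`
#'   (Benjamini-Hochberg across every word tested).
#' @export
kmer_enrichment <- function(foreground, model, k_range = 4:10,
                            collapse_rc = TRUE) {
  stopifnot(inherits(model, "markov_background"))
  seqs <- if (methods::is(foreground, "DNAStringSet"))
    as.character(foreground) else as.character(foreground)
  if (length(seqs) == 0L) stop2("foreground is empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(nchar(seqs)) < max(k_range))
    stop2("k (", max(k_range), ") exceeds the shortest foreground sequence (",
          min(nchar(seqs)), " nt)")
  codes <- lapply(seqs, .encode_dna)
  n <- length(seqs)

  res <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    nb <- 4^k
    rc <- .rc_values(k)
    all_vals <- vector("list", n)
    pres_vals <- vector("list", n)
    m_win <- integer(n)
    for (i in seq_len(n)) {
      v <- .window_values(codes[[i]], k)
      v <- v[!is.na(v)]
      m_win[i] <- length(v)
      if (length(v) == 0L) next
      all_vals[[i]] <- v
      pres_vals[[i]] <- unique(if (collapse_rc) pmin(v, rc[v + 1L]) else v)
    }
    cnt_raw <- tabulate(unlist(all_vals) + 1L, nbins = nb)
    pres <- tabulate(unlist(pres_vals) + 1L, nbins = nb)

    pw <- kmer_model_probs(model, k)
    if (collapse_rc) {
      canon <- which(0:(nb - 1) <= rc) # canonical classes (value <= rc value)
      is_pal <- rc[canon] == (canon - 1)
      p_class <- pw[canon] + ifelse(is_pal, 0, pw[rc[canon] + 1L])
      count <- cnt_raw[canon] + ifelse(is_pal, 0, cnt_raw[rc[canon] + 1L])
      n_seqs <- pres[canon]
      kmers <- .all_kmers(k)[canon]
    } else {
      p_class <- pw
      count <- cnt_raw
      n_seqs <- pres
      kmers <- .all_kmers(k)
    }
    # sum of per-sequence containment probabilities, grouped by window count
    m_tab <- table(m_win)
    expected_seqs <- 0
    for (j in seq_along(m_tab)) {
      m <- as.numeric(names(m_tab))[j]
      expected_seqs <- expected_seqs +
        as.numeric(m_tab[j]) * (1 - exp(-m * p_class))
    }
    pi_bar <- expected_seqs / n
    expected_count <- sum(m_win) * p_class
    p_val <- pbinom(n_seqs - 1L, n, pi_bar, lower.tail = FALSE)
    res[[ki]] <- data.frame(
      kmer = kmers, k = k, n_seqs = n_seqs, expected_seqs = expected_seqs,
      count = count, expected_count = expected_count,
      fold = count / expected_count, p_value = p_val,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, -out$fold, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
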