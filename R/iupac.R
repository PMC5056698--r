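#' Degenerate-consensus matching on both strands
#'
#' Scans a DNA sequence for every occurrence of an IUPAC degenerate
#' consensus (default `BSAAGGHYRHH`, the composite nuclear-receptor/homeo
#' binding consensus) on the forward strand and on the reverse complement.
#' Matching is delegated to [Biostrings::matchPattern()] with a literal
#' subject, so hard-masked `N` bases in the sequence never satisfy any
#' pattern code. Soft-masked (lowercase) bases match by default; set
#' `include_soft_masked = FALSE` to treat them as masked.
#'
#' @param sequence a single `DNAString` or character string over
#'   `A/C/G/T/N` (case-insensitive).
#' @param pattern IUPAC consensus string.
#' @param include_soft_masked if `FALSE`, lowercase bases are replaced by `N`
#'   before matching.
#' @return data.frame with columns `start`, `end` (1-based, forward-strand
#'   coordinates of the matched window), `strand` (`+`/`-`) and `match` (the
#'   forward-strand sequence of the window). Zero rows when nothing matches.
#' @export
find_iupac_matches <- function(sequence, pattern = "BSAAGGHYRHH",
                               include_soft_masked = TRUE) {
  pattern <- as.character(pattern)
  letters_ok <- names(Biostrings::IUPAC_CODE_MAP)
  pat_chars <- strsplit(toupper(pattern), "")[[1]]
  if (length(pat_chars) == 0L) stop2("empty pattern")
  if (!all(pat_chars %in% letters_ok))
    stop2("invalid IUPAC letter(s) in pattern: ",
          paste(unique(setdiff(pat_chars, letters_ok)), collapse = ", "))

  s <- if (methods::is(sequence, "DNAString")) as.character(sequence)
       else as.character(sequence)
  if (length(s) != 1L) stop2("sequence must be a single string")
  if (!include_soft_masked) s <- gsub("[acgtn]", "N", s)
  s <- toupper(s)
  if (grepl("[^ACGTN]", s)) stop2("sequence contains letters outside A/C/G/T/N")
  subj <- Biostrings::DNAString(s)

  pat <- Biostrings::DNAString(toupper(pattern))
  fixed <- c(pattern = FALSE, subject = TRUE)
  fwd <- Biostrings::matchPattern(pat, subj, fixed = fixed)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                  fixed = fixed)
  res <- data.frame(
    start = c(Biostrings::start(fwd), Biostrings::start(rev)),
    end = c(Biostrings::end(fwd), Biostrings::end(rev)),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    match = c(as.character(fwd), as.character(rev)),
    stringsAsFactors = FALSE
  )
  # pattern N would match a masked N in the subject; masked bases never match
  if (any(pat_chars == "N") && nrow(res) > 0L)
    res <- res[!grepl("N", res$match, fixed = TRUE), , drop = FALSE]
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Size of the sequence space of an IUPAC consensus
#'
#' Number of distinct exact words matching a degenerate consensus: the
#' product over positions of each code's cardinality (e.g. `BSAAGGHYRHH`
#' admits 3*2*1*1*1*1*3*2*2*3*3 = 648 eleven-mers).
#'
#' @param pattern IUPAC consensus string.
#' @return integer count of matching words.
#' @export
iupac_space_size <- function(pattern) {
  pat_chars <- strsplit(toupper(as.character(pattern)), "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  if (!all(pat_chars %in% names(map)))
    stop2("invalid IUPAC letter(s) in pattern")
  prod(nchar(map[pat_chars]))
}
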