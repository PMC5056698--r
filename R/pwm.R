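#' Read / write JASPAR PFM motif files
#'
#' Parses the JASPAR text format: a `>ID NAME` header followed by four rows
#' of counts, either bare (`13 2 0 ...`) or letter-and-bracket style
#' (`A [ 13  2  0 ... ]`). Rows may appear in any order when lettered;
#' bare rows are taken as A, C, G, T.
#'
#' @param path file path.
#' @return `read_jaspar`: named list of `pwm` objects (id, name, counts
#'   matrix with rows A,C,G,T). `write_jaspar` returns `path` invisibly.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop2("no motif headers in ", path)
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    head_line <- sub("^>\\s*", "", lines[hdr[i]])
    toks <- strsplit(trimws(head_line), "\\s+")[[1]]
    id <- toks[1L]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    body <- lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4L)
      stop2("motif ", id, ": expected 4 count rows (line ", hdr[i], ")")
    body <- body[1:4]
    lettered <- grepl("^\\s*[ACGTacgt]\\b", body)
    rows <- lapply(body, function(l) {
      l <- gsub("[][]", " ", l)
      l <- sub("^\\s*[ACGTacgt]\\b", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (any(vapply(rows, anyNA, TRUE)) ||
        length(unique(lengths(rows))) != 1L)
      stop2("motif ", id, ": malformed count rows (line ", hdr[i], ")")
    m <- do.call(rbind, rows)
    rownames(m) <- if (all(lettered))
      toupper(substr(trimws(body), 1L, 1L)) else .BASES
    m <- m[.BASES, , drop = FALSE]
    out[[id]] <- structure(list(id = id, name = name, counts = m),
                           class = "pwm")
  }
  out
}

#' @param pwms named list of `pwm` objects.
#' @rdname read_jaspar
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in .BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Construct a pwm object from a count matrix
#'
#' @param counts 4 x width numeric matrix (rows A,C,G,T).
#' @param id,name identifiers.
#' @return a `pwm` object.
#' @export
pwm_from_counts <- function(counts, id, name = id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop2("counts must have 4 rows (A,C,G,T)")
  rownames(counts) <- .BASES
  structure(list(id = id, name = name, counts = counts), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), width %d\n", x$id, x$name, ncol(x$counts)))
  invisible(x)
}

#' Width of a pwm
#' @param pwm a `pwm` object.
#' @return integer number of positions.
#' @export
pwm_width <- function(pwm) ncol(pwm$counts)

#' Log-odds matrix of a pwm against background marginals
#'
#' Counts are normalized per position with a total pseudocount split by the
#' background marginals (the conventional 0.8 by default), then converted
#' to `log(p / background)`.
#'
#' @param pwm a `pwm` object.
#' @param background length-4 base probabilities (A,C,G,T).
#' @param pseudocount total pseudocount per position.
#' @return 4 x width log-odds matrix.
#' @export
pwm_log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.8) {
  if (length(background) != 4L || any(background <= 0))
    stop2("background must be 4 positive probabilities")
  background <- background / sum(background)
  cnt <- pwm$counts
  tot <- colSums(cnt) + pseudocount
  prob <- sweep(cnt + pseudocount * background, 2L, tot, "/")
  log(prob / background)
}

# Per-position forward/reverse log-odds scores of a coded sequence.
.score_positions <- function(codes, lodds) {
  w <- ncol(lodds)
  n <- length(codes) - w + 1L
  if (n < 1L) stop2("sequence shorter than pwm width")
  rc_lodds <- lodds[4:1, w:1, drop = FALSE] # minus-strand scoring matrix
  fwd <- numeric(n); rev <- numeric(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)] + 1L
    fwd <- fwd + lodds[cbind(cj, j)]
    rev <- rev + rc_lodds[cbind(cj, j)]
  }
  list(fwd = fwd, rev = rev)
}

#' Log-odds score of a single window
#'
#' Sum over positions of `log(pwm probability / background probability)`,
#' background taken from the order-0 marginal of the supplied Markov model.
#' Forward-strand orientation only; the window must equal the pwm width.
#'
#' @param window character window of exactly the pwm width.
#' @param pwm a `pwm` object.
#' @param model a `markov_background` supplying the marginals.
#' @param pseudocount pwm pseudocount (see [pwm_log_odds()]).
#' @return numeric log-odds score.
#' @export
pwm_window_score <- function(window, pwm, model, pseudocount = 0.8) {
  s <- as.character(window)
  if (nchar(s) != pwm_width(pwm))
    stop2("window length (", nchar(s), ") must equal pwm width (",
          pwm_width(pwm), ")")
  codes <- .encode_dna(s)
  if (anyNA(codes)) stop2("window contains non-ACGT letters")
  bg <- as.numeric(model$prob[[1L]][1L, ])
  lodds <- pwm_log_odds(pwm, background = bg, pseudocount = pseudocount)
  sum(lodds[cbind(codes + 1L, seq_along(codes))])
}

#' Empirical Gaussian null for pwm window scores
#'
#' Draws `n` random windows of the pwm's width --- either sampled from a
#' Markov background model or sliced at random positions from supplied null
#' sequences (e.g. the genome) --- scores each window on its better strand,
#' and fits a Gaussian (mu, sigma) to those scores. The resulting null
#' converts any scanned score into a probability score via the normal CDF.
#' Best-of-both-strands scoring is used here and in [scan_pwm()] so null
#' and scan statistics are exchangeable.
#'
#' @param pwm a `pwm` object.
#' @param model a `markov_background`, or `NULL` when `null_sequences` is
#'   given.
#' @param null_sequences optional character/`DNAStringSet` to slice windows
#'   from.
#' @param n number of null windows (default 10000).
#' @param seed integer seed (mandatory randomness control).
#' @param pseudocount pwm pseudocount.
#' @return an object of class `pwm_null`: list with `pwm_id`, `mu`,
#'   `sigma`, `n`, `seed`, `background` (marginals used for the log-odds)
#'   and `pseudocount`.
#' @export
build_gaussian_null <- function(pwm, model = NULL, null_sequences = NULL,
                                n = 10000L, seed = 1L, pseudocount = 0.8) {
  if (is.null(model) && is.null(null_sequences))
    stop2("supply a background model or null sequences")
  w <- pwm_width(pwm)
  if (n < 2L) stop2("need at least 2 null windows")
  if (!is.null(model)) {
    windows <- sample_background(model, w, n, seed = seed)
    bg <- as.numeric(model$prob[[1L]][1L, ])
  } else {
    seqs <- toupper(as.character(null_sequences))
    seqs <- seqs[nchar(seqs) >= w]
    if (length(seqs) == 0L) stop2("no null sequence reaches the pwm width")
    windows <- with_seed(seed, {
      si <- sample.int(length(seqs), n, replace = TRUE)
      pos <- floor(runif(n, 1, nchar(seqs)[si] - w + 2))
      substr(seqs[si], pos, pos + w - 1L)
    })
    comp <- colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = 1L))
    bg <- as.numeric((comp + 1) / sum(comp + 1))
  }
  lodds <- pwm_log_odds(pwm, background = bg, pseudocount = pseudocount)
  sc <- vapply(windows, function(s) {
    codes <- .encode_dna(s)
    if (anyNA(codes)) return(NA_real_)
    ps <- .score_positions(codes, lodds)
    max(ps$fwd, ps$rev)
  }, numeric(1L), USE.NAMES = FALSE)
  sc <- sc[!is.na(sc)]
  if (length(sc) < 2L) stop2("fewer than 2 scoreable null windows")
  sigma <- sd(sc)
  if (!is.finite(sigma) || sigma < 1e-9)
    stop2("degenerate null for pwm ", pwm$id,
          ": null score standard deviation is zero")
  structure(list(pwm_id = pwm$id, mu = mean(sc), sigma = sigma,
                 n = length(sc), seed = seed, background = bg,
                 pseudocount = pseudocount, width = w),
            class = "pwm_null")
}

#' @export
print.pwm_null <- function(x, ...) {
  cat(sprintf("pwm_null %s: mu %.3f, sigma %.3f (n = %d, seed = %s)\n",
              x$pwm_id, x$mu, x$sigma, x$n, format(x$seed)))
  invisible(x)
}

#' Scan a sequence with a pwm against its Gaussian null
#'
#' Scores every position on both strands, keeps the better strand, and
#' converts the score to a probability score `pnorm((score - mu) / sigma)`
#' under the motif's Gaussian null. Positions reaching `threshold`
#' (default 0.9) are reported as candidate sites. Windows containing
#' non-ACGT letters are unscoreable and skipped.
#'
#' @param sequence a character string or `DNAString` (length >= pwm width).
#' @param pwm a `pwm` object.
#' @param null the matching `pwm_null`.
#' @param threshold minimum probability score for a hit.
#' @return data.frame of hits: `position` (1-based forward-strand start),
#'   `strand`, `score`, `prob_score`.
#' @export
scan_pwm <- function(sequence, pwm, null, threshold = 0.9) {
  stopifnot(inherits(null, "pwm_null"))
  if (!is.finite(null$sigma) || null$sigma <= 0)
    stop2("degenerate null for pwm ", pwm$id)
  if (pwm_width(pwm) != null$width)
    stop2("null was built for width ", null$width, ", pwm has width ",
          pwm_width(pwm))
  s <- toupper(as.character(sequence))
  if (nchar(s) < pwm_width(pwm)) stop2("sequence shorter than pwm width")
  codes <- .encode_dna(s)
  lodds <- pwm_log_odds(pwm, background = null$background,
                        pseudocount = null$pseudocount)
  ps <- .score_positions(codes, lodds)
  best <- pmax(ps$fwd, ps$rev)
  strand <- ifelse(ps$rev > ps$fwd, "-", "+")
  prob <- pnorm((best - null$mu) / null$sigma)
  keep <- which(!is.na(prob) & prob >= threshold)
  data.frame(position = keep, strand = strand[keep], score = best[keep],
             prob_score = prob[keep], stringsAsFactors = FALSE)
}
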