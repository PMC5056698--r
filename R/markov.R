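# Shared encoding helpers: bases A,C,G,T map to 0..3; k-mers map to their
# base-4 big-endian value (the lexicographic rank used by
# Biostrings::oligonucleotideFrequency), so model rows, k-mer counts and
# reverse-complement lookups all share one indexing scheme.

.BASES <- c("A", "C", "G", "T")

.encode_dna <- function(s) {
  x <- utf8ToInt(toupper(s))
  code <- rep(NA_integer_, 128L)
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  code[x]
}

# Base-4 values of all length-k windows of a code vector; NA where the
# window touches a non-ACGT base.
.window_values <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(integer(0))
  if (k == 1L) return(codes)
  e <- embed(codes, k)            # row i = codes[i+k-1], ..., codes[i]
  as.vector(e %*% 4^(0:(k - 1L)))
}

# value of the reverse complement of each 0-based k-mer value 0..4^k-1
.rc_values <- function(k) {
  v <- 0:(4^k - 1)
  rc <- numeric(length(v))
  for (j in seq_len(k)) {
    d <- (v %/% 4^(k - j)) %% 4
    rc <- rc + (3 - d) * 4^(j - 1)
  }
  rc
}

.kmer_cache <- new.env(parent = emptyenv())

.all_kmers <- function(k) {
  key <- as.character(k)
  if (is.null(.kmer_cache[[key]])) {
    .kmer_cache[[key]] <- Biostrings::mkAllStrings(.BASES, width = k)
  }
  .kmer_cache[[key]]
}

#' Estimate an order-k Markov background model
#'
#' Maximum-likelihood transition probabilities of an order-`k` Markov chain
#' over `{A,C,G,T}`, estimated from a set of sequences (for example the
#' merged repeat-masked ChIP peak windows), in the manner of the standard
#' background-model builders: counts are strand-averaged (each sequence and
#' its reverse complement contribute) unless disabled, k-mers containing
#' non-ACGT letters are skipped, and lower-order models are estimated
#' alongside for scoring the first `k` bases of a sequence.
#'
#' @param sequences `DNAStringSet` or character vector.
#' @param order chain order `k >= 0` (default 5).
#' @param pseudocount added to every transition count before normalization
#'   (default 1).
#' @param strand_average count both strands (default `TRUE`).
#' @return an object of class `markov_background`: list with `order`,
#'   `pseudocount`, `strand_averaged` and `prob`, a list of `order + 1`
#'   transition matrices (orders 0..k); matrix `o+1` has `4^o` context rows
#'   (lexicographic) and columns `A,C,G,T` summing to 1.
#' @export
build_markov_background <- function(sequences, order = 5L, pseudocount = 1,
                                    strand_average = TRUE) {
  if (order < 0L) stop2("order must be >= 0")
  seqs <- if (methods::is(sequences, "DNAStringSet")) sequences
          else Biostrings::DNAStringSet(toupper(as.character(sequences)))
  if (length(seqs) == 0L) stop2("no sequences supplied")
  if (strand_average) seqs <- c(seqs, Biostrings::reverseComplement(seqs))

  prob <- vector("list", order + 1L)
  top_total <- NULL
  for (o in 0:order) {
    cnt <- Biostrings::oligonucleotideFrequency(seqs, width = o + 1L,
                                                simplify.as = "collapse")
    m <- matrix(as.numeric(cnt), ncol = 4L, byrow = TRUE)
    if (o == order) top_total <- sum(m)
    m <- m + pseudocount
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, NA_real_)
    rownames(m) <- if (o == 0L) "" else .all_kmers(o)
    colnames(m) <- .BASES
    prob[[o + 1L]] <- m
  }
  if (is.na(top_total) || top_total == 0)
    stop2("no usable k-mers at the requested order")
  if (top_total < 4^order)
    warning("fewer usable ", order + 1L, "-mers (", top_total,
            ") than contexts (", 4^order, "); estimates will be diffuse",
            call. = FALSE)
  structure(list(order = as.integer(order), pseudocount = pseudocount,
                 strand_averaged = strand_average, prob = prob),
            class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat(sprintf("markov_background: order %d, pseudocount %g, %s\n",
              x$order, x$pseudocount,
              if (x$strand_averaged) "strand-averaged" else "single strand"))
  invisible(x)
}

#' Log-likelihood of a sequence under a Markov background model
#'
#' Chain-rule log probability: the first `k` bases are scored with the
#' lower-order models, later bases with the full order-`k` conditionals.
#'
#' @param sequence single character string or `DNAString` over `A/C/G/T`.
#' @param model a `markov_background`.
#' @return log probability (0 for the empty sequence).
#' @export
sequence_loglik <- function(sequence, model) {
  stopifnot(inherits(model, "markov_background"))
  s <- as.character(sequence)
  if (nchar(s) == 0L) return(0)
  codes <- .encode_dna(s)
  if (anyNA(codes)) stop2("sequence contains non-ACGT letters")
  L <- length(codes)
  k <- model$order
  ll <- 0
  head_n <- min(k, L)
  for (i in seq_len(head_n)) {     # lower-order start terms
    o <- i - 1L
    ctx <- if (o == 0L) 0L else sum(codes[1:o] * 4^((o - 1L):0))
    ll <- ll + log(model$prob[[o + 1L]][ctx + 1L, codes[i] + 1L])
  }
  if (L > k) {
    ctx <- if (k == 0L) rep(0L, L) else
      .window_values(codes[seq_len(L - 1L)], k)[seq_len(L - k)]
    b <- codes[(k + 1L):L]
    ll <- ll + sum(log(model$prob[[k + 1L]][cbind(ctx + 1L, b + 1L)]))
  }
  if (is.na(ll))
    stop2("model has undefined transitions for this sequence (unseen context with pseudocount 0)")
  ll
}

#' Sample i.i.d. sequences from a Markov background model
#'
#' @param model a `markov_background`.
#' @param length sequence length (>= 1).
#' @param n number of sequences.
#' @param seed integer seed; fixed seed reproduces the draw exactly.
#' @return character vector of `n` sequences.
#' @export
sample_background <- function(model, length, n = 1L, seed = 1L) {
  stopifnot(inherits(model, "markov_background"))
  if (length < 1L) stop2("length must be >= 1")
  if (n < 1L) return(character(0))
  k <- model$order
  cums <- lapply(model$prob, function(m) {
    if (anyNA(m)) stop2("model has undefined transitions (unseen context with pseudocount 0)")
    t(apply(m, 1L, cumsum))
  })
  with_seed(seed, {
    out <- matrix(0L, nrow = n, ncol = length)
    ctx <- integer(n)
    for (i in seq_len(length)) {
      o <- min(i - 1L, k)
      cm <- cums[[o + 1L]]
      u <- runif(n)
      rows <- ctx + 1L
      b <- (u > cm[rows, 1L]) + (u > cm[rows, 2L]) + (u > cm[rows, 3L])
      out[, i] <- b
      if (k > 0L) {
        ctx <- if (o < k) ctx * 4L + b else (ctx %% 4^(k - 1L)) * 4L + b
        ctx <- as.integer(ctx)
      }
    }
    apply(out, 1L, function(r) paste(.BASES[r + 1L], collapse = ""))
  })
}

#' Replace a model's lower orders by stationary-consistent conditionals
#'
#' An order-k chain's transition matrix determines a stationary
#' distribution over length-k contexts; for the model's marginal k-mer
#' probabilities to describe windows anywhere in a long sequence (not just
#' at its start), the lower-order start models must be the marginals of
#' that stationary distribution. Models estimated from data satisfy this
#' automatically (empirical lower-order counts approximate the stationary
#' marginals); synthetic models with arbitrary start distributions do not,
#' so the generator passes them through here. The stationary distribution
#' is found by power iteration (the Dirichlet-drawn chains used for
#' simulation are ergodic).
#'
#' @param model a `markov_background`.
#' @param max_iter,tol power-iteration controls.
#' @return the model with lower-order matrices replaced.
#' @export
stationarize_model <- function(model, max_iter = 1000L, tol = 1e-12) {
  stopifnot(inherits(model, "markov_background"))
  k <- model$order
  if (k == 0L) return(model)
  Tm <- model$prob[[k + 1L]]
  nk <- 4^k
  pi_k <- rep(1 / nk, nk)
  for (it in seq_len(max_iter)) {
    M <- pi_k * Tm                           # joint (context, next base)
    arr <- array(as.vector(M), dim = c(4^(k - 1L), 4L, 4L)) # (rest, c1, b)
    nxt <- apply(arr, c(1L, 3L), sum)        # marginalize the oldest base
    pi_new <- as.vector(t(nxt))              # state order: rest*4 + b
    if (max(abs(pi_new - pi_k)) < tol) { pi_k <- pi_new; break }
    pi_k <- pi_new
  }
  marg <- function(j) {          # stationary marginal of length-j prefixes
    if (j == 0L) return(1)
    pref <- (0:(nk - 1)) %/% 4^(k - j)
    as.vector(rowsum(pi_k, pref))
  }
  for (o in 0:(k - 1L)) {
    mj <- marg(o)                 # contexts of length o
    mj1 <- marg(o + 1L)           # extended by one base
    m <- matrix(mj1, ncol = 4L, byrow = TRUE) / mj
    rownames(m) <- if (o == 0L) "" else .all_kmers(o)
    colnames(m) <- .BASES
    model$prob[[o + 1L]] <- m
  }
  model
}

#' Marginal probabilities of every k-mer under a Markov model
#'
#' Chain-rule probability of each of the `4^k` words, ordered
#' lexicographically (the ordering of
#' [Biostrings::oligonucleotideFrequency()]).
#'
#' @param model a `markov_background`.
#' @param k word length.
#' @return numeric vector of length `4^k` summing to 1.
#' @export
kmer_model_probs <- function(model, k) {
  stopifnot(inherits(model, "markov_background"), k >= 1L)
  p <- model$prob[[1L]][1L, ]
  if (k == 1L) return(unname(p))
  p <- unname(p)
  for (j in 2:k) {
    o <- min(j - 1L, model$order)
    Tm <- model$prob[[o + 1L]]
    pref <- 0:(4^(j - 1L) - 1)
    ctx <- pref %% 4^o
    p <- rep(p, each = 4L) * as.vector(t(Tm))[rep(ctx, each = 4L) * 4L + rep(0:3, length(ctx)) + 1L]
  }
  p
}

#' Write / read a background model as k-mer marginal probabilities
#'
#' Interchange in the background-file dialect used by the common motif
#' suites: one line per word, `word probability`, for all words of length 1
#' to `order + 1`. Reading reconstructs the conditional transition matrices
#' from the marginals.
#'
#' @param model a `markov_background`.
#' @param path file path.
#' @return `write_markov_background` returns `path` invisibly;
#'   `read_markov_background` returns a `markov_background`.
#' @export
write_markov_background <- function(model, path) {
  stopifnot(inherits(model, "markov_background"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# order %d markov background (pseudocount %g)",
                     model$order, model$pseudocount), con)
  for (len in 1:(model$order + 1L)) {
    p <- kmer_model_probs(model, len)
    writeLines(sprintf("%s %.8e", .all_kmers(len), p), con)
  }
  invisible(path)
}

#' @rdname write_markov_background
#' @export
read_markov_background <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  words <- toupper(vapply(parts, `[`, "", 1L))
  probs <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(probs)) stop2("malformed background file: ", path)
  lens <- nchar(words)
  order <- max(lens) - 1L
  prob <- vector("list", order + 1L)
  marg <- split(probs[order(lens, words)], sort(lens))
  for (o in 0:order) {
    pk1 <- marg[[as.character(o + 1L)]]
    if (length(pk1) != 4^(o + 1L)) stop2("incomplete word set at length ", o + 1L)
    m <- matrix(pk1, ncol = 4L, byrow = TRUE)
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, NA_real_)
    rownames(m) <- if (o == 0L) "" else .all_kmers(o)
    colnames(m) <- .BASES
    prob[[o + 1L]] <- m
  }
  structure(list(order = order, pseudocount = NA_real_,
                 strand_averaged = NA, prob = prob),
            class = "markov_background")
}
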