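# Shared fixture builders; everything is generated in code under fixed seeds.

# the standard 18-array design: 3 stages x 2 genotypes x 3 batches
full_design <- function() {
  grid <- expand.grid(batch = 1:3, genotype = c("control", "mutant"),
                      stage = c("5", "6", "8"), stringsAsFactors = FALSE)
  expression_design(sprintf("arr%02d", seq_len(nrow(grid))),
                    grid$stage, grid$genotype, grid$batch)
}

# order-2 composition model shared by the motif tests
fixture_model <- function() stripecre:::.random_markov_model(2L, seed = 99L)

# sharp position weight matrix on a fixed consensus word
sharp_pwm <- function(consensus = "CGAAGGTACT", counts = 30, id = "sharp") {
  w <- nchar(consensus)
  m <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], rownames(m))
  m[cbind(idx, seq_len(w))] <- counts
  p <- pwm_from_counts(m, id)
  p$consensus <- consensus
  p
}

# moderate-information pwm whose null score distribution is smooth enough
# for the Gaussian approximation to calibrate well
smooth_pwm <- function(width = 11L, seed = 42L, id = "smooth") {
  cnt <- withr_seed(seed, matrix(stats::rgamma(4 * width, 2) * 8, nrow = 4))
  pwm_from_counts(cnt, id)
}

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# brute-force regular-expression oracle for degenerate consensus matching
regex_iupac_oracle <- function(sequence, pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  to_regex <- function(p) {
    paste(vapply(strsplit(toupper(p), "")[[1]], function(ch) {
      set <- map[[ch]]
      if (nchar(set) == 1L) set else paste0("[", set, "]")
    }, ""), collapse = "")
  }
  s <- toupper(as.character(sequence))
  hits <- function(p) {
    m <- gregexpr(paste0("(?=", to_regex(p), ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  rc <- function(p) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(p)))
  list(fwd = hits(pattern), rev = hits(rc(pattern)))
}

# random A/C/G/T string
random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}
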