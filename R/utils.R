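# shared internal helpers

#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the RNG seeded to `seed`, then restores the previous
#' RNG state so simulation helpers do not perturb the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Coerce sequence input to a plain uppercase character vector
#' @noRd
as_seq_chr <- function(x) {
  if (inherits(x, "XStringSet") || inherits(x, "XString")) x <- as.character(x)
  nm <- names(x)
  out <- toupper(as.character(x))
  names(out) <- nm
  out
}

#' Random DNA strings
#' @noRd
random_dna <- function(lengths) {
  vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
}

#' Point-mutate a DNA string at a per-base substitution rate
#' @noRd
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    # draw a base different from the current one
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

#' Reverse-complement for plain character vectors
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Check non-negative scalar integer-ish values
#' @noRd
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}
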