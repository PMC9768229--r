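## shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## population standard deviation (denominator n, not n-1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single fraction in [0, 1]", name), call. = FALSE)
  }
}
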