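## Descriptive sequence statistics: length distribution, positional base
## composition and the ping-pong 5'-overlap signature.

#' Length distribution with deterministic mode
#'
#' @param lengths Integer vector of sequence lengths, optionally weighted.
#' @param weights Optional non-negative weights (e.g. read counts per tag);
#'   defaults to 1 per item.
#' @param range Inclusive length range reported.
#' @return A list of class `length_histogram`: `counts` (named numeric
#'   vector over the range) and `mode_length` (smallest length attaining the
#'   maximum; `NA` for empty input).
#' @export
#' @examples
#' length_distribution(c(29, 29, 27))
length_distribution <- function(lengths, weights = NULL,
                                range = c(24L, 33L)) {
  bins <- seq(range[1], range[2])
  if (length(lengths) == 0L) {
    return(structure(list(counts = setNames(numeric(length(bins)), bins),
                          mode_length = NA_integer_),
                     class = "length_histogram"))
  }
  if (is.null(weights)) weights <- rep(1, length(lengths))
  stopifnot(length(weights) == length(lengths), all(weights >= 0))
  if (any(lengths < range[1] | lengths > range[2])) {
    stop("lengths outside the gated range", call. = FALSE)
  }
  counts <- vapply(bins, function(b) sum(weights[lengths == b]), numeric(1))
  names(counts) <- bins
  mode_length <- bins[which.max(counts)]   # which.max: smallest index on ties
  structure(list(counts = counts, mode_length = mode_length),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat("length histogram, mode =", x$mode_length, "nt\n")
  print(x$counts)
  invisible(x)
}

#' Positional base frequencies in the 5'-3' direction
#'
#' For each position along the sequences, the frequency of A, C, G and U
#' (T reported as U). N bases are excluded from the denominator; positions
#' are covered only by sequences long enough to reach them.
#'
#' @param sequences Character vector (DNA alphabet, `N` allowed).
#' @param weights Optional per-sequence weights (e.g. read counts).
#' @param max_position Number of positions reported.
#' @return A list: `freq` (matrix position x base, rows summing to 1 where
#'   covered), `support` (weighted non-N coverage per position).
#' @export
#' @examples
#' positional_base_frequency(c("TA", "TG"))$freq
positional_base_frequency <- function(sequences, weights = NULL,
                                      max_position = 33L) {
  bases <- c("A", "C", "G", "U")
  freq <- matrix(NA_real_, nrow = max_position, ncol = 4,
                 dimnames = list(seq_len(max_position), bases))
  support <- numeric(max_position)
  if (length(sequences) == 0L) {
    return(list(freq = freq, support = support))
  }
  if (is.null(weights)) weights <- rep(1, length(sequences))
  stopifnot(length(weights) == length(sequences))
  lens <- nchar(sequences)
  for (p in seq_len(max_position)) {
    covered <- lens >= p
    if (!any(covered)) next
    ch <- substr(sequences[covered], p, p)
    w <- weights[covered]
    keep <- ch != "N"
    if (!any(keep)) next
    tot <- c(A = sum(w[keep][ch[keep] == "A"]),
             C = sum(w[keep][ch[keep] == "C"]),
             G = sum(w[keep][ch[keep] == "G"]),
             U = sum(w[keep][ch[keep] == "T"]))
    support[p] <- sum(tot)
    freq[p, ] <- tot / sum(tot)
  }
  list(freq = freq, support = support)
}

#' Ping-pong 5'-overlap signature
#'
#' For every pair of alignments on the same chromosome and opposite strands,
#' the 5'-5' overlap is the number of shared bases spanned by the two 5'
#' ends: with 0-based half-open coordinates, a plus-strand 5' end at `start`
#' and a minus-strand 5' end at `end - 1`, the overlap is
#' `(minus 5') - (plus 5') + 1` when positive. Pairs are tallied once
#' (unordered), weighted by the product of the two alignments' weights
#' (set `weighted = FALSE` to count unique pairs instead). The signature
#' statistic `z10` is the Z-score of the overlap-10 count against overlaps
#' 1-20 excluding 10, using the population standard deviation.
#'
#' @param hits Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`) and optionally `weight`.
#' @param max_overlap Largest overlap tallied.
#' @param weighted Multiply pair contributions by the product of hit weights.
#' @return A list of class `pingpong_profile`: `overlap_counts` (named
#'   vector over 1..max_overlap) and `z10` (`NA` when undefined, e.g. no
#'   opposite-strand pairs or zero background spread).
#' @export
ping_pong_signature <- function(hits, max_overlap = 20L, weighted = TRUE) {
  counts <- setNames(numeric(max_overlap), seq_len(max_overlap))
  empty <- structure(list(overlap_counts = counts, z10 = NA_real_),
                     class = "pingpong_profile")
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if (is.null(hits$weight)) hits$weight <- rep(1, nrow(hits))
  plus <- hits[hits$strand == "+", , drop = FALSE]
  minus <- hits[hits$strand == "-", , drop = FALSE]
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty)
  w <- if (weighted) function(x) x else function(x) rep(1, length(x))
  for (chr in intersect(unique(plus$chrom), unique(minus$chrom))) {
    p <- plus[plus$chrom == chr, , drop = FALSE]
    m <- minus[minus$chrom == chr, , drop = FALSE]
    ## aggregate weight per distinct 5' position
    pw <- rowsum(w(p$weight), p$start)
    mw <- rowsum(w(m$weight), m$end - 1L)
    ppos <- as.integer(rownames(pw))
    mpos <- as.integer(rownames(mw))
    for (k in seq_len(max_overlap)) {
      i <- match(ppos + k - 1L, mpos)
      ok <- !is.na(i)
      if (any(ok)) counts[k] <- counts[k] + sum(pw[ok, 1] * mw[i[ok], 1])
    }
  }
  bg <- counts[-10L]
  s <- pop_sd(bg)
  z10 <- if (max_overlap >= 10L && s > 0) {
    (counts[[10L]] - mean(bg)) / s
  } else NA_real_
  structure(list(overlap_counts = counts, z10 = z10),
            class = "pingpong_profile")
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat("ping-pong profile, z10 =", format(x$z10, digits = 4), "\n")
  print(x$overlap_counts)
  invisible(x)
}
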