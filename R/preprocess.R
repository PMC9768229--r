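## Raw-read filtering, adapter trimming and per-category accounting.
##
## Filter order is fixed: N content -> low quality -> 5' adapter
## contamination -> 3' adapter trim -> homopolymer -> length gate. Each read
## is counted once, in the first category it fails, which makes the
## accounting an exact partition of the input.

#' Low-quality read filter
#'
#' A read fails when bases at or below `q_threshold` make up more than
#' `max_fraction` of its length (strict inequality, so a read exactly at the
#' boundary passes).
#'
#' @param sequence,quality Character vectors of equal length: read sequences
#'   and Phred+33 quality strings (pairwise equal widths).
#' @param q_threshold Phred score at or below which a base counts as low
#'   quality.
#' @param max_fraction Maximum tolerated fraction of low-quality bases.
#' @return Logical vector, `TRUE` where the read passes.
#' @export
#' @examples
#' filter_low_quality("ACGTACGTAC", paste(rep("&", 10), collapse = ""))
filter_low_quality <- function(sequence, quality, q_threshold = 5,
                               max_fraction = 0.5) {
  if (length(sequence) != length(quality)) {
    stop("sequence and quality vectors differ in length", call. = FALSE)
  }
  if (length(sequence) == 0L) return(logical(0))
  if (any(nchar(sequence) != nchar(quality))) {
    bad <- which(nchar(sequence) != nchar(quality))[1]
    stop(sprintf("malformed record %d: sequence and quality widths differ",
                 bad), call. = FALSE)
  }
  q <- as(PhredQuality(quality), "IntegerList")
  frac <- sum(q <= q_threshold) / nchar(sequence)
  frac <= max_fraction
}

#' N-content read filter
#'
#' A read fails when its fraction of `N` bases exceeds `max_n_fraction`
#' (strict inequality).
#'
#' @param sequence Character vector of read sequences.
#' @param max_n_fraction Maximum tolerated N fraction.
#' @return Logical vector, `TRUE` where the read passes.
#' @export
filter_n_content <- function(sequence, max_n_fraction = 0.10) {
  if (length(sequence) == 0L) return(logical(0))
  n_count <- letterFrequency(DNAStringSet(sequence), "N")[, 1]
  n_count / nchar(sequence) <= max_n_fraction
}

## First qualifying 3' adapter match position per read (1-based), NA if none.
## A match is an exact occurrence of the adapter prefix of length
## >= min_overlap, extended to the full adapter or the read end.
find_adapter_start <- function(seqs, adapter, min_overlap = 8L,
                               max_mismatch = 0L) {
  n <- length(seqs)
  pos <- rep(NA_integer_, n)
  if (n == 0L) return(pos)
  seed <- substr(adapter, 1L, min_overlap)
  hits <- vmatchPattern(seed, DNAStringSet(seqs),
                        max.mismatch = max_mismatch)
  starts <- startIndex(hits)
  alen <- nchar(adapter)
  cand_read <- rep.int(seq_len(n), lengths(starts))
  cand_pos <- unlist(starts, use.names = FALSE)
  if (length(cand_pos) == 0L) return(pos)
  rlen <- nchar(seqs)[cand_read]
  cmp_len <- pmin(alen, rlen - cand_pos + 1L)
  observed <- substr(seqs[cand_read], cand_pos, cand_pos + cmp_len - 1L)
  expected <- substr(rep(adapter, length(cand_pos)), 1L, cmp_len)
  ok <- if (max_mismatch == 0L) {
    observed == expected
  } else {
    mapply(function(a, b) {
      sum(utf8ToInt(a) != utf8ToInt(b))
    }, observed, expected, USE.NAMES = FALSE) <= max_mismatch
  }
  ok <- ok & cmp_len >= min_overlap
  if (any(ok)) {
    first <- tapply(cand_pos[ok], cand_read[ok], min)
    pos[as.integer(names(first))] <- as.integer(first)
  }
  pos
}

#' Trim the 3' adapter and categorize the insert
#'
#' Applies, in order: rejection of reads whose body contains the full 5'
#' adapter (`adapter5p_contamination`); location of the first exact
#' occurrence of a 3'-adapter prefix of at least `min_overlap` nt, rejecting
#' reads with no match or an empty insert
#' (`adapter3p_null_or_insert_null`); rejection of homopolymer-dominated
#' inserts (`polyATGC`: one nucleotide makes up at least `poly_frac` of the
#' insert, or a single-base run of at least `poly_run` nt); and the length
#' gate (`length_filtered` outside `length_range`, otherwise `clean`).
#'
#' @param sequence Character vector of read sequences (already past the
#'   quality and N filters).
#' @param adapter_5p,adapter_3p Adapter sequences (DNA alphabet).
#' @param min_overlap Minimum 3'-adapter prefix overlap.
#' @param max_mismatch Mismatches tolerated in the 3'-adapter match (0 or 1).
#' @param poly_frac,poly_run Homopolymer rejection parameters.
#' @param length_range Inclusive insert length range kept as clean.
#' @return A data frame with columns `insert` (NA unless trimming succeeded)
#'   and `category` (one of `clean`, `length_filtered`,
#'   `adapter5p_contamination`, `adapter3p_null_or_insert_null`,
#'   `polyATGC`).
#' @export
#' @examples
#' trim_and_gate(paste0(strrep("A", 5), "TGCATGCATGCATGCATGCATGCAT",
#'                      "TGGAATTCTCGGGTGCCAAGG"),
#'               "GTTCAGAGTTCTACAGTCCGACGATC", "TGGAATTCTCGGGTGCCAAGG")
trim_and_gate <- function(sequence,
                          adapter_5p, adapter_3p,
                          min_overlap = 8L, max_mismatch = 0L,
                          poly_frac = 0.8, poly_run = 15L,
                          length_range = c(24L, 33L)) {
  if (!nzchar(adapter_5p) || !nzchar(adapter_3p)) {
    stop("adapter sequences must be non-empty", call. = FALSE)
  }
  n <- length(sequence)
  category <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  if (n == 0L) {
    return(data.frame(insert = insert, category = category,
                      stringsAsFactors = FALSE))
  }

  has5p <- vcountPattern(adapter_5p, DNAStringSet(sequence),
                         max.mismatch = 0L) > 0L
  category[has5p] <- "adapter5p_contamination"

  todo <- which(!has5p)
  pos <- rep(NA_integer_, n)
  pos[todo] <- find_adapter_start(sequence[todo], adapter_3p,
                                  min_overlap, max_mismatch)
  no3p <- !has5p & (is.na(pos) | pos == 1L)
  category[no3p] <- "adapter3p_null_or_insert_null"

  keep <- which(!has5p & !no3p)
  if (length(keep)) {
    ins <- substr(sequence[keep], 1L, pos[keep] - 1L)
    counts <- letterFrequency(DNAStringSet(ins), DNA_BASES)
    maxfrac <- apply(counts, 1, max) / nchar(ins)
    run_re <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                      poly_run, poly_run, poly_run, poly_run)
    poly <- maxfrac >= poly_frac | grepl(run_re, ins)
    category[keep[poly]] <- "polyATGC"
    ok <- keep[!poly]
    ins_ok <- ins[!poly]
    insert[ok] <- ins_ok
    inlen <- nchar(ins_ok) >= length_range[1] & nchar(ins_ok) <= length_range[2]
    category[ok] <- ifelse(inlen, "clean", "length_filtered")
  }
  data.frame(insert = insert, category = category, stringsAsFactors = FALSE)
}

#' Clean reads implied by an accounting row
#'
#' The accounting identity: clean reads equal total reads minus the five
#' filter-category counts. Exposed so published accounting tables can be
#' checked directly.
#'
#' @param total_reads,n_gt10pct,low_quality,adapter5p_contamination,adapter3p_null_or_insert_null,polyATGC
#'   Non-negative integer counts (vectorized).
#' @return `total_reads` minus the five removal categories.
#' @export
#' @examples
#' accounting_clean_reads(13270313, 615, 54247, 6166, 262996, 58340)
accounting_clean_reads <- function(total_reads, n_gt10pct, low_quality,
                                   adapter5p_contamination,
                                   adapter3p_null_or_insert_null,
                                   polyATGC) {
  total_reads - n_gt10pct - low_quality - adapter5p_contamination -
    adapter3p_null_or_insert_null - polyATGC
}

#' Filter, trim and account for one FASTQ library
#'
#' Runs the fixed filter cascade on a FASTQ file (plain or gzip) and returns
#' both the surviving length-gated inserts and a one-row accounting table in
#' which every input read is counted exactly once. `clean_reads` is the
#' pre-length-gate count (so the accounting identity
#' `total = clean + removed categories` holds exactly); the 24-33 nt
#' survivors are reported separately as `length_pass`.
#'
#' @param fastq Path to a FASTQ file (Phred+33).
#' @param sample_id Sample name for the accounting row.
#' @param adapter_5p,adapter_3p Adapter sequences.
#' @param q_threshold,max_low_fraction Low-quality filter parameters.
#' @param max_n_fraction N-content filter parameter.
#' @param min_overlap,max_mismatch,poly_frac,poly_run,length_range Trimming
#'   parameters, see [trim_and_gate()].
#' @return A list: `accounting` (one-row data frame), `inserts` (character
#'   vector of length-gated inserts, one per surviving read), `categories`
#'   (per-read category vector in file order).
#' @export
run_preprocess <- function(fastq, sample_id,
                           adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                           adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                           q_threshold = 5, max_low_fraction = 0.5,
                           max_n_fraction = 0.10,
                           min_overlap = 8L, max_mismatch = 0L,
                           poly_frac = 0.8, poly_run = 15L,
                           length_range = c(24L, 33L)) {
  reads <- tryCatch(
    suppressWarnings(readQualityScaledDNAStringSet(fastq)),
    error = function(e) {
      stop(sprintf("cannot parse FASTQ '%s': %s", fastq, conditionMessage(e)),
           call. = FALSE)
    })
  seqs <- as.character(reads)
  quals <- as.character(quality(reads))
  n <- length(seqs)
  category <- rep(NA_character_, n)

  if (n > 0L) {
    pass_n <- filter_n_content(seqs, max_n_fraction)
    category[!pass_n] <- "n_gt10pct"
    idx <- which(pass_n)
    pass_q <- filter_low_quality(seqs[idx], quals[idx], q_threshold,
                                 max_low_fraction)
    category[idx[!pass_q]] <- "low_quality"
    idx <- idx[pass_q]
    tg <- trim_and_gate(seqs[idx], adapter_5p, adapter_3p, min_overlap,
                        max_mismatch, poly_frac, poly_run, length_range)
    category[idx] <- tg$category
    inserts <- tg$insert[tg$category == "clean"]
  } else {
    inserts <- character(0)
  }

  cnt <- function(x) sum(category == x)
  accounting <- data.frame(
    sample = sample_id,
    total_reads = n,
    n_gt10pct = cnt("n_gt10pct"),
    low_quality = cnt("low_quality"),
    adapter5p_contamination = cnt("adapter5p_contamination"),
    adapter3p_null_or_insert_null = cnt("adapter3p_null_or_insert_null"),
    polyATGC = cnt("polyATGC"),
    clean_reads = cnt("clean") + cnt("length_filtered"),
    length_filtered = cnt("length_filtered"),
    length_pass = cnt("clean"),
    stringsAsFactors = FALSE)
  stopifnot(accounting$total_reads == accounting$clean_reads +
              accounting$n_gt10pct + accounting$low_quality +
              accounting$adapter5p_contamination +
              accounting$adapter3p_null_or_insert_null +
              accounting$polyATGC)
  list(accounting = accounting, inserts = inserts, categories = category)
}
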