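## Tag collapsing, known small RNA removal and the 1U/10A candidate rule.

#' Collapse clean reads to unique sequence tags
#'
#' Reads with identical insert sequence form one tag; the tag carries one
#' read count per sample. Read order never matters.
#'
#' @param reads_by_sample Named list, one character vector of length-gated
#'   insert sequences per sample.
#' @return A data frame with column `sequence` followed by one integer count
#'   column per sample; row sums over a sample equal that sample's read
#'   count.
#' @export
#' @examples
#' collapse_tags(list(s1 = c("ACGT", "ACGT", "GGTT"), s2 = "ACGT"))
collapse_tags <- function(reads_by_sample) {
  stopifnot(is.list(reads_by_sample), length(reads_by_sample) > 0)
  if (is.null(names(reads_by_sample)) ||
      any(!nzchar(names(reads_by_sample)))) {
    stop("reads_by_sample must be a named list", call. = FALSE)
  }
  all_seqs <- sort(unique(unlist(reads_by_sample, use.names = FALSE)))
  out <- data.frame(sequence = all_seqs, stringsAsFactors = FALSE)
  for (smp in names(reads_by_sample)) {
    tab <- table(factor(reads_by_sample[[smp]], levels = all_seqs))
    out[[smp]] <- as.integer(tab)
  }
  out
}

## TRUE for each query that is an exact substring of any subject sequence or
## of its reverse complement.
matches_reference <- function(queries, subjects, max_mismatch = 0L) {
  if (length(queries) == 0L) return(logical(0))
  subj <- c(subjects, reverseComplement(subjects))
  hit <- rep(FALSE, length(queries))
  for (w in unique(nchar(queries))) {
    idx <- which(nchar(queries) == w)
    pd <- PDict(DNAStringSet(queries[idx]))
    found <- rep(FALSE, length(idx))
    for (s in seq_along(subj)) {
      if (nchar(subj[[s]]) < w) next
      found <- found | lengths(
        Biostrings::matchPDict(pd, subj[[s]])) > 0L
    }
    if (max_mismatch > 0L) {
      ## mismatch-tolerant fallback, per query (rarely used)
      for (k in which(!found)) {
        q <- DNAString(queries[idx[k]])
        for (s in seq_along(subj)) {
          if (nchar(subj[[s]]) < w) next
          if (length(matchPattern(q, subj[[s]],
                                  max.mismatch = max_mismatch)) > 0L) {
            found[k] <- TRUE
            break
          }
        }
      }
    }
    hit[idx] <- found
  }
  hit
}

#' Remove tags matching known small RNA reference sets
#'
#' A tag is removed when it is an exact substring of any reference sequence
#' (or its reverse complement) in one of the supplied classes. Classes are
#' scanned in the order `rRNA, tRNA, snRNA, snoRNA, miRNA` (then any further
#' classes in list order); the first matching class wins, so each tag is
#' removed at most once.
#'
#' @param tags Tag data frame from [collapse_tags()].
#' @param reference_sets Named list of `DNAStringSet` (or FASTA file paths),
#'   one per class.
#' @param max_mismatch Mismatches tolerated in the match (0-2; default 0).
#' @return A list: `tags` (remaining tags), `removed` (named integer vector
#'   of removed tag counts per class), `removed_reads` (matrix of removed
#'   read counts, class x sample), `class` (per-input-tag class assignment,
#'   `NA` for kept tags).
#' @export
remove_known_srna <- function(tags, reference_sets, max_mismatch = 0L) {
  stopifnot(is.data.frame(tags), "sequence" %in% names(tags))
  if (max_mismatch > 2L) stop("max_mismatch must be <= 2", call. = FALSE)
  canonical <- c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA")
  order_classes <- c(intersect(canonical, names(reference_sets)),
                     setdiff(names(reference_sets), canonical))
  sample_cols <- setdiff(names(tags), "sequence")
  assigned <- rep(NA_character_, nrow(tags))
  for (class in order_classes) {
    refs <- reference_sets[[class]]
    if (is.character(refs)) refs <- readDNAStringSet(refs)
    if (length(refs) == 0L) {
      warning(sprintf("empty reference set for class '%s'; skipped", class))
      next
    }
    todo <- which(is.na(assigned))
    if (!length(todo)) break
    hit <- matches_reference(tags$sequence[todo], refs, max_mismatch)
    assigned[todo[hit]] <- class
  }
  removed <- vapply(order_classes, function(cl) sum(assigned == cl,
                                                    na.rm = TRUE),
                    integer(1))
  removed_reads <- matrix(0, nrow = length(order_classes),
                          ncol = length(sample_cols),
                          dimnames = list(order_classes, sample_cols))
  for (cl in order_classes) {
    rows <- which(assigned == cl)
    if (length(rows)) {
      removed_reads[cl, ] <- colSums(tags[rows, sample_cols, drop = FALSE])
    }
  }
  list(tags = tags[is.na(assigned), , drop = FALSE],
       removed = removed,
       removed_reads = removed_reads,
       class = assigned)
}

#' Call candidate piRNAs by the 1U/10A rule
#'
#' A tag is a candidate piRNA when its first base is U (T in the DNA
#' alphabet) or its 10th base is A; positions are 1-based on the tag
#' sequence.
#'
#' @param tags Tag data frame with a `sequence` column (24-33 nt).
#' @return The candidate subset of `tags` with logical columns `is_1U` and
#'   `is_10A` appended.
#' @export
#' @examples
#' call_candidates(data.frame(sequence = c(
#'   "TGCAGCAGCAGCAGCAGCAGCAGCAGCAG",
#'   "GGCAGCAGCAGCAGCAGCAGCAGCAGCAG")))
call_candidates <- function(tags) {
  stopifnot(is.data.frame(tags), "sequence" %in% names(tags))
  if (any(nchar(tags$sequence) < 10L)) {
    stop("tags shorter than 10 nt cannot be scored for the 10A rule",
         call. = FALSE)
  }
  is_1U <- substr(tags$sequence, 1L, 1L) == "T"
  is_10A <- substr(tags$sequence, 10L, 10L) == "A"
  keep <- is_1U | is_10A
  out <- tags[keep, , drop = FALSE]
  out$is_1U <- is_1U[keep]
  out$is_10A <- is_10A[keep]
  rownames(out) <- NULL
  out
}
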