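## Genomic alignment of tags and feature / transposon origin assignment.

FEATURE_PRIORITY <- c("CDS", "5UTR", "3UTR", "repeat", "intron", "lncRNA",
                      "unannotated")

#' Align tags to a genome by exact (or 1-mismatch) search
#'
#' Reports every occurrence of each tag on both strands with at most
#' `max_mismatch` mismatches. Per-tag weight (its total read count) is split
#' equally across that tag's hits, so summed hit weight equals summed read
#' count for every aligned tag.
#'
#' @param tags Tag data frame (`sequence` plus per-sample count columns;
#'   an optional `tag_id` column is carried through, otherwise row order ids
#'   are assigned).
#' @param genome A `DNAStringSet` or path to a genome FASTA.
#' @param max_mismatch 0 or 1.
#' @return Data frame with columns `tag_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `n_mismatch`, `weight`.
#' @export
align_tags <- function(tags, genome, max_mismatch = 0L) {
  stopifnot(is.data.frame(tags), "sequence" %in% names(tags))
  if (!max_mismatch %in% c(0L, 1L)) {
    stop("max_mismatch must be 0 or 1", call. = FALSE)
  }
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))

  valid <- grepl("^[ACGT]+$", tags$sequence)
  if (any(!valid)) {
    warning(sum(!valid), " tag(s) with non-ACGT characters skipped")
    tags <- tags[valid, , drop = FALSE]
  }
  n <- nrow(tags)
  tag_id <- tags$tag_id %||% sprintf("tag%06d", seq_len(n))
  sample_cols <- setdiff(names(tags), c("sequence", "tag_id", "is_1U",
                                        "is_10A"))
  read_count <- if (length(sample_cols)) {
    rowSums(tags[, sample_cols, drop = FALSE])
  } else rep(1, n)

  res <- list()
  add_hits <- function(ti, chrom, starts1, strand, widths, mm) {
    if (!length(starts1)) return(invisible(NULL))
    res[[length(res) + 1L]] <<- data.frame(
      tag_idx = ti, chrom = chrom, start = starts1 - 1L,
      end = starts1 - 1L + widths, strand = strand, n_mismatch = mm,
      stringsAsFactors = FALSE)
  }

  if (n > 0L) {
    fwd <- DNAStringSet(tags$sequence)
    rev <- reverseComplement(fwd)
    for (w in sort(unique(nchar(tags$sequence)))) {
      idx <- which(nchar(tags$sequence) == w)
      pd_f <- PDict(fwd[idx])
      pd_r <- PDict(rev[idx])
      for (ci in seq_along(genome)) {
        chrom <- names(genome)[ci]
        mi <- Biostrings::matchPDict(pd_f, genome[[ci]])
        st <- startIndex(mi)
        for (k in which(lengths(st) > 0L)) {
          add_hits(idx[k], chrom, st[[k]], "+", w, 0L)
        }
        mi <- Biostrings::matchPDict(pd_r, genome[[ci]])
        st <- startIndex(mi)
        for (k in which(lengths(st) > 0L)) {
          add_hits(idx[k], chrom, st[[k]], "-", w, 0L)
        }
      }
    }
    if (max_mismatch == 1L) {
      ## per-tag scan tolerating one mismatch; exact hits already recorded
      exact <- if (length(res)) do.call(rbind, res) else NULL
      for (ti in seq_len(n)) {
        for (ci in seq_along(genome)) {
          chrom <- names(genome)[ci]
          for (strand in c("+", "-")) {
            pat <- if (strand == "+") fwd[[ti]] else rev[[ti]]
            m <- matchPattern(pat, genome[[ci]], max.mismatch = 1L)
            if (!length(m)) next
            starts1 <- start(m)
            for (s1 in starts1) {
              already <- !is.null(exact) &&
                any(exact$tag_idx == ti & exact$chrom == chrom &
                      exact$strand == strand & exact$start == s1 - 1L)
              if (!already) {
                add_hits(ti, chrom, s1, strand, nchar(tags$sequence[ti]), 1L)
              }
            }
          }
        }
      }
    }
  }

  if (!length(res)) {
    return(data.frame(tag_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_mismatch = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, res)
  n_hits <- table(hits$tag_idx)
  hits$weight <- read_count[hits$tag_idx] /
    as.integer(n_hits[as.character(hits$tag_idx)])
  hits$tag_id <- tag_id[hits$tag_idx]
  hits$tag_idx <- NULL
  rownames(hits) <- NULL
  hits[, c("tag_id", "chrom", "start", "end", "strand", "n_mismatch",
           "weight")]
}

## Derive intron intervals: gene bodies minus exons.
derive_introns <- function(genes_gr) {
  gene_body <- genes_gr[genes_gr$type %in% c("gene", "lnc_RNA")]
  exons <- genes_gr[genes_gr$type == "exon"]
  GenomicRanges::setdiff(reduce(gene_body, ignore.strand = TRUE),
                         reduce(exons, ignore.strand = TRUE),
                         ignore.strand = TRUE)
}

#' Assign each alignment a genomic feature category
#'
#' Categories are decided by a fixed priority (`CDS > 5'UTR > 3'UTR >
#' repeat > intron > lncRNA > unannotated`): a hit belongs to the
#' highest-priority feature that covers at least `min_overlap_frac` of its
#' length. Introns are derived as gene bodies minus exons. Repeat hits carry
#' the TE class/family parsed from the repeat track's `name` field.
#'
#' @param hits Alignment data frame from [align_tags()].
#' @param genes Gene annotation: a GFF3 path or a `GRanges` with a `type`
#'   column (`gene`, `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`,
#'   `lnc_RNA`).
#' @param repeats Repeat annotation: a BED path or a `GRanges` with a
#'   `name` column formatted `class/family`.
#' @param genome_seqnames Optional character vector of valid chromosome
#'   names; annotations naming other chromosomes raise an error.
#' @param min_overlap_frac Minimum fraction of the hit covered by a feature.
#' @return A list: `assignments` (the hits with `category`, `te_class`,
#'   `te_family` columns), `fractions` (weighted and unweighted category
#'   shares, each summing to 1).
#' @export
assign_features <- function(hits, genes, repeats,
                            genome_seqnames = NULL,
                            min_overlap_frac = 0.5) {
  if (is.character(genes)) genes <- import(genes, format = "gff3")
  if (is.character(repeats)) repeats <- import(repeats, format = "bed")
  if (!is.null(genome_seqnames)) {
    ann_chr <- unique(c(as.character(seqnames(genes)),
                        as.character(seqnames(repeats))))
    missing <- setdiff(ann_chr, genome_seqnames)
    if (length(missing)) {
      stop("annotation chromosome(s) absent from genome: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  feature_sets <- list(
    CDS = genes[genes$type == "CDS"],
    "5UTR" = genes[genes$type == "five_prime_UTR"],
    "3UTR" = genes[genes$type == "three_prime_UTR"],
    "repeat" = repeats,
    intron = derive_introns(genes),
    lncRNA = genes[genes$type == "lnc_RNA"]
  )

  n <- nrow(hits)
  category <- rep("unannotated", n)
  te_class <- te_family <- rep(NA_character_, n)
  if (n > 0L) {
    hit_gr <- GRanges(hits$chrom, IRanges(hits$start + 1L, hits$end))
    undecided <- rep(TRUE, n)
    for (feat in names(feature_sets)) {
      gr <- feature_sets[[feat]]
      if (length(gr) == 0L) next
      ov <- findOverlaps(hit_gr, gr, ignore.strand = TRUE)
      if (!length(ov)) next
      ovw <- width(pintersect(hit_gr[queryHits(ov)],
                              gr[subjectHits(ov)], ignore.strand = TRUE))
      frac <- ovw / width(hit_gr[queryHits(ov)])
      good <- frac >= min_overlap_frac
      qh <- queryHits(ov)[good]
      sh <- subjectHits(ov)[good]
      pick <- undecided[qh]
      if (any(pick)) {
        first <- !duplicated(qh[pick])
        qsel <- qh[pick][first]
        ssel <- sh[pick][first]
        category[qsel] <- feat
        undecided[qsel] <- FALSE
        if (feat == "repeat") {
          nm <- gr$name[ssel] %||% rep(NA_character_, length(ssel))
          parsed <- parse_te_name(nm)
          te_class[qsel] <- parsed$class
          te_family[qsel] <- parsed$family
        }
      }
    }
  }
  assignments <- hits
  assignments$category <- category
  assignments$te_class <- te_class
  assignments$te_family <- te_family

  lv <- FEATURE_PRIORITY
  wsum <- vapply(lv, function(cl) sum(hits$weight[category == cl]),
                 numeric(1))
  csum <- vapply(lv, function(cl) sum(category == cl), numeric(1))
  fractions <- data.frame(
    category = lv,
    weighted_fraction = if (sum(wsum) > 0) wsum / sum(wsum) else wsum,
    tag_fraction = if (sum(csum) > 0) csum / sum(csum) else csum,
    stringsAsFactors = FALSE)
  list(assignments = assignments, fractions = fractions)
}

## "class/family" -> list(class=, family=); malformed names become class
## "unparsed" with the raw label kept as family.
parse_te_name <- function(x) {
  ok <- !is.na(x) & grepl("^[^/]+/[^/]+$", x)
  class <- family <- rep(NA_character_, length(x))
  class[ok] <- sub("/.*$", "", x[ok])
  family[ok] <- sub("^[^/]*/", "", x[ok])
  if (any(!ok & !is.na(x))) {
    warning("malformed TE name field; binned as 'unparsed'")
    class[!ok & !is.na(x)] <- "unparsed"
    family[!ok & !is.na(x)] <- x[!ok & !is.na(x)]
  }
  list(class = class, family = family)
}

#' Weighted TE class/family composition of repeat-derived hits
#'
#' @param assignments Assignment data frame from [assign_features()]
#'   (rows with `category == "repeat"` are used).
#' @return A list: `by_class` and `by_family` data frames of weighted hit
#'   counts and fractions.
#' @export
classify_te <- function(assignments) {
  rep_hits <- assignments[assignments$category == "repeat", , drop = FALSE]
  agg <- function(key) {
    if (nrow(rep_hits) == 0L) {
      return(data.frame(key = character(0), weight = numeric(0),
                        fraction = numeric(0), stringsAsFactors = FALSE,
                        row.names = NULL))
    }
    w <- rowsum(rep_hits$weight, rep_hits[[key]])
    out <- data.frame(key = rownames(w), weight = w[, 1],
                      stringsAsFactors = FALSE, row.names = NULL)
    out$fraction <- out$weight / sum(out$weight)
    out[order(-out$weight), ]
  }
  by_class <- agg("te_class")
  names(by_class)[1] <- "te_class"
  by_family <- agg("te_family")
  names(by_family)[1] <- "te_family"
  list(by_class = by_class, by_family = by_family)
}

#' Ping-pong signature within each TE class
#'
#' @param assignments Assignment data frame from [assign_features()].
#' @param ... Passed to [ping_pong_signature()].
#' @return Named list of `pingpong_profile`, one per TE class present;
#'   classes too sparse for the statistic carry `z10 = NA`.
#' @export
per_te_pingpong <- function(assignments, ...) {
  rep_hits <- assignments[assignments$category == "repeat" &
                            !is.na(assignments$te_class), , drop = FALSE]
  classes <- sort(unique(rep_hits$te_class))
  setNames(lapply(classes, function(cl) {
    ping_pong_signature(rep_hits[rep_hits$te_class == cl, , drop = FALSE],
                        ...)
  }), classes)
}
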