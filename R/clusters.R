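## Sliding-window piRNA cluster detection and per-cluster statistics.

hit_5prime <- function(hits) {
  ifelse(hits$strand == "+", hits$start, hits$end - 1L)
}

#' Detect piRNA clusters by sliding-window hit density
#'
#' Windows of `window` nt advanced by `step` nt (anchored at the first hit
#' 5' end on each chromosome, so the detector is translation invariant)
#' qualify when they contain at least `min_loci` distinct hit 5' positions
#' and total hit weight at least `min_weight`. Runs of overlapping
#' qualifying windows are trimmed to the extent of their member hits, runs
#' whose trimmed extents lie within `merge_gap` are merged, and merged
#' intervals shorter than `min_length` are dropped.
#'
#' @param hits Alignment data frame (`chrom`, `start`, `end` 0-based
#'   half-open, `strand`, `weight`).
#' @param window,step Window size and stride (nt).
#' @param min_loci Minimum distinct 5' positions per qualifying window.
#' @param min_weight Minimum summed hit weight per qualifying window.
#' @param merge_gap Maximum gap (nt) between merged intervals.
#' @param min_length Minimum reported cluster length (nt).
#' @return Data frame of clusters: `cluster_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `n_loci`, `total_weight`.
#' @export
detect_clusters <- function(hits, window = 5000L, step = 1000L,
                            min_loci = 10L, min_weight = 30,
                            merge_gap = 10000L, min_length = 1000L) {
  empty <- data.frame(cluster_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_loci = integer(0), total_weight = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if (is.null(hits$weight)) hits$weight <- rep(1, nrow(hits))
  hits$pos5 <- hit_5prime(hits)

  out <- list()
  for (chr in sort(unique(hits$chrom))) {
    h <- hits[hits$chrom == chr, , drop = FALSE]
    h <- h[order(h$pos5), , drop = FALSE]
    anchor <- min(h$pos5)
    span <- max(h$pos5) - anchor
    win_starts <- anchor + seq(0L, max(span - 1L, 0L), by = step)
    qual <- logical(length(win_starts))
    for (i in seq_along(win_starts)) {
      inw <- h$pos5 >= win_starts[i] & h$pos5 < win_starts[i] + window
      qual[i] <- length(unique(h$pos5[inw])) >= min_loci &&
        sum(h$weight[inw]) >= min_weight
    }
    if (!any(qual)) next
    ## runs of overlapping qualifying windows
    qs <- win_starts[qual]
    run_id <- cumsum(c(1L, diff(qs) > window))
    extents <- lapply(split(qs, run_id), function(ws) {
      lo <- min(ws); hi <- max(ws) + window
      member <- h$pos5 >= lo & h$pos5 < hi
      c(min(h$start[member]), max(h$end[member]))
    })
    ext <- do.call(rbind, extents)
    ext <- ext[order(ext[, 1]), , drop = FALSE]
    ## merge trimmed extents within merge_gap
    merged <- list(ext[1, ])
    if (nrow(ext) > 1L) {
      for (i in 2:nrow(ext)) {
        last <- merged[[length(merged)]]
        if (ext[i, 1] - last[2] <= merge_gap) {
          merged[[length(merged)]] <- c(last[1], max(last[2], ext[i, 2]))
        } else {
          merged[[length(merged) + 1L]] <- ext[i, ]
        }
      }
    }
    for (iv in merged) {
      if (iv[2] - iv[1] < min_length) next
      member <- h$start < iv[2] & h$end > iv[1]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = iv[1], end = iv[2],
        n_loci = length(unique(h$pos5[member])),
        total_weight = sum(h$weight[member]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  clusters <- do.call(rbind, out)
  clusters <- clusters[order(clusters$chrom, clusters$start), , drop = FALSE]
  clusters <- cbind(cluster_id = seq_len(nrow(clusters)), clusters)
  rownames(clusters) <- NULL
  clusters
}

#' Strand specificity and 5'U bias of a cluster
#'
#' @param cluster One row of the [detect_clusters()] output (or any list
#'   with `chrom`, `start`, `end`).
#' @param hits Alignment data frame with `weight` and `tag_id`.
#' @param tags Tag data frame with `tag_id` (or row order matching) and
#'   `sequence`; used for the weighted first-base U fraction.
#' @param mono_threshold Strand fraction at or above which a cluster is
#'   called mono-directional.
#' @return A list: `plus_fraction`, `minus_fraction`, `u1_fraction`,
#'   `directionality` (`mono-plus`, `mono-minus` or `bidirectional`),
#'   `total_weight`.
#' @export
cluster_stats <- function(cluster, hits, tags = NULL,
                          mono_threshold = 0.75) {
  member <- hits$chrom == cluster$chrom & hits$start < cluster$end &
    hits$end > cluster$start
  h <- hits[member, , drop = FALSE]
  tw <- sum(h$weight)
  plus_fraction <- if (tw > 0) sum(h$weight[h$strand == "+"]) / tw else NA_real_
  directionality <- if (is.na(plus_fraction)) {
    NA_character_
  } else if (plus_fraction >= mono_threshold) {
    "mono-plus"
  } else if (1 - plus_fraction >= mono_threshold) {
    "mono-minus"
  } else {
    "bidirectional"
  }
  u1_fraction <- NA_real_
  if (!is.null(tags) && nrow(h) > 0L) {
    first <- substr(tags$sequence[match(h$tag_id, tags$tag_id)], 1, 1)
    u1_fraction <- sum(h$weight[first == "T"], na.rm = TRUE) / tw
  }
  list(plus_fraction = plus_fraction,
       minus_fraction = if (is.na(plus_fraction)) NA_real_ else
         1 - plus_fraction,
       u1_fraction = u1_fraction,
       directionality = directionality,
       total_weight = tw)
}

#' Annotate a cluster table with per-cluster statistics
#'
#' @param clusters Output of [detect_clusters()].
#' @param hits,tags,mono_threshold See [cluster_stats()].
#' @return `clusters` with `plus_fraction`, `u1_fraction` and
#'   `directionality` columns appended.
#' @export
annotate_clusters <- function(clusters, hits, tags = NULL,
                              mono_threshold = 0.75) {
  stats <- lapply(seq_len(nrow(clusters)), function(i) {
    cluster_stats(clusters[i, ], hits, tags, mono_threshold)
  })
  clusters$plus_fraction <- vapply(stats, `[[`, numeric(1), "plus_fraction")
  clusters$u1_fraction <- vapply(stats, `[[`, numeric(1), "u1_fraction")
  clusters$directionality <- vapply(stats, `[[`, character(1),
                                    "directionality")
  clusters
}

#' Cluster counts and density per chromosome
#'
#' @param clusters Output of [detect_clusters()].
#' @param chrom_lengths Named numeric vector of chromosome lengths (nt).
#' @return Data frame: `chrom`, `n_clusters`, `length`, `density_per_mb`.
#' @export
#' @examples
#' cl <- data.frame(chrom = c("chr1", "chr1", "chr1"))
#' chromosome_distribution(cl, c(chr1 = 2e6, chr2 = 1e6))
chromosome_distribution <- function(clusters, chrom_lengths) {
  unknown <- setdiff(unique(clusters$chrom), names(chrom_lengths))
  if (length(unknown)) {
    stop("cluster chromosome(s) not in chrom_lengths: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- vapply(names(chrom_lengths),
              function(ch) sum(clusters$chrom == ch), numeric(1))
  data.frame(chrom = names(chrom_lengths),
             n_clusters = as.integer(n),
             length = as.numeric(chrom_lengths),
             density_per_mb = n / (as.numeric(chrom_lengths) / 1e6),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate sense/antisense balance over all clusters
#'
#' The aggregate weighted strand split over every cluster's member hits:
#' individual clusters can be almost perfectly strand specific while the
#' aggregate sits near 50/50.
#'
#' @param clusters Cluster table annotated with `plus_fraction` and
#'   `total_weight` (from [annotate_clusters()] plus [detect_clusters()]),
#'   or raw clusters plus `hits` to recompute.
#' @param hits Optional hit table; when supplied, fractions are recomputed
#'   from member hits.
#' @return A list: `plus_fraction`, `minus_fraction` (aggregate, weighted).
#' @export
global_strand_balance <- function(clusters, hits = NULL) {
  if (nrow(clusters) == 0L) stop("no clusters", call. = FALSE)
  if (!is.null(hits)) {
    stats <- lapply(seq_len(nrow(clusters)), function(i) {
      cluster_stats(clusters[i, ], hits)
    })
    w <- vapply(stats, `[[`, numeric(1), "total_weight")
    pf <- vapply(stats, `[[`, numeric(1), "plus_fraction")
  } else {
    w <- clusters$total_weight
    pf <- clusters$plus_fraction
  }
  plus <- sum(w * pf) / sum(w)
  list(plus_fraction = plus, minus_fraction = 1 - plus)
}
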