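## End-to-end orchestration of the piRNA profiling stages.

#' Run the full piRNA profiling pipeline
#'
#' Preprocesses every library (filtering, trimming, accounting), collapses
#' the length-gated inserts to tags, removes known small RNA classes, calls
#' candidate piRNAs by the 1U/10A rule, aligns candidates to the genome,
#' assigns genomic and transposon origins, computes the global and per-TE
#' ping-pong signatures, detects piRNA clusters with per-cluster strand and
#' 5'U statistics, and screens for differential expression between the two
#' groups.
#'
#' @param fastq_files Named character vector of FASTQ paths (names =
#'   sample ids).
#' @param groups Named vector mapping sample id to group; exactly two
#'   groups, the first level (alphabetical or factor order) is the
#'   reference.
#' @param genome Genome FASTA path or `DNAStringSet`.
#' @param genes GFF3 path or `GRanges` gene annotation.
#' @param repeats BED path or `GRanges` repeat annotation.
#' @param reference_sets Named list of FASTA paths or `DNAStringSet` for
#'   known-sRNA removal.
#' @param adapter_5p,adapter_3p Adapters for trimming.
#' @param max_mismatch Mismatches allowed in genome alignment (0 or 1).
#' @param cluster_params Optional list overriding [detect_clusters()]
#'   parameters.
#' @param p_cut,fc_cut DE screening thresholds.
#' @return A list with elements `accounting`, `tags`, `removed_srna`,
#'   `candidates`, `hits`, `features`, `te`, `te_pingpong`, `pingpong`,
#'   `clusters`, `chrom_distribution`, `strand_balance`, `de`.
#' @export
run_pipeline <- function(fastq_files, groups, genome, genes, repeats,
                         reference_sets,
                         adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                         adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                         max_mismatch = 0L,
                         cluster_params = list(),
                         p_cut = 0.05, fc_cut = 1.5) {
  stopifnot(!is.null(names(fastq_files)), all(names(fastq_files) %in%
                                                names(groups)))
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))

  pre <- lapply(names(fastq_files), function(smp) {
    run_preprocess(fastq_files[[smp]], smp, adapter_5p = adapter_5p,
                   adapter_3p = adapter_3p)
  })
  names(pre) <- names(fastq_files)
  accounting <- do.call(rbind, lapply(pre, `[[`, "accounting"))
  rownames(accounting) <- NULL

  tags <- collapse_tags(lapply(pre, `[[`, "inserts"))
  rem <- remove_known_srna(tags, reference_sets)
  candidates <- call_candidates(rem$tags)
  candidates$tag_id <- sprintf("tag%06d", seq_len(nrow(candidates)))

  hits <- align_tags(candidates, genome, max_mismatch = max_mismatch)
  feat <- assign_features(hits, genes, repeats,
                          genome_seqnames = names(genome))
  te <- classify_te(feat$assignments)
  te_pp <- per_te_pingpong(feat$assignments)
  pp <- ping_pong_signature(hits)

  clusters <- do.call(detect_clusters, c(list(hits = hits), cluster_params))
  if (nrow(clusters) > 0L) {
    clusters <- annotate_clusters(clusters, hits, candidates)
    chrom_lengths <- setNames(width(genome), names(genome))
    chrom_dist <- chromosome_distribution(clusters, chrom_lengths)
    balance <- global_strand_balance(clusters, hits)
  } else {
    chrom_dist <- NULL
    balance <- NULL
  }

  sample_ids <- names(fastq_files)
  cmat <- as.matrix(candidates[, sample_ids, drop = FALSE])
  rownames(cmat) <- candidates$tag_id
  de <- run_diffexp(cmat, groups[sample_ids], p_cut = p_cut,
                    fc_cut = fc_cut)
  de$sequence <- candidates$sequence[match(de$tag_id, candidates$tag_id)]

  list(accounting = accounting, tags = tags, removed_srna = rem,
       candidates = candidates, hits = hits, features = feat, te = te,
       te_pingpong = te_pp, pingpong = pp, clusters = clusters,
       chrom_distribution = chrom_dist, strand_balance = balance, de = de)
}
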