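## Simulated FASTQ libraries with a ground-truth manifest.

## Read layout: [optional 5' contamination +] insert + 3' adapter + random
## pad, truncated to the configured read length; constant high base quality
## (Q38) except for reads planted for the low-quality filter.

build_read <- function(insert, adapter_3p, read_length) {
  pad_len <- max(read_length - nchar(insert) - nchar(adapter_3p), 0L)
  pad <- if (pad_len > 0L) paste(sample(DNA_BASES, pad_len, replace = TRUE),
                                 collapse = "") else ""
  substr(paste0(insert, adapter_3p, pad), 1L, read_length)
}

random_insert <- function(len, seed8) {
  repeat {
    s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    if (!grepl(seed8, s, fixed = TRUE)) return(s)
  }
}

#' Simulate replicate small RNA-seq libraries with ground truth
#'
#' Emits one FASTQ library per sample (two groups, `A` and `B`, of
#' `n_samples_per_group` replicates each) plus a per-read manifest. Each
#' library contains exactly `n_reads_per_library` reads: piRNA reads drawn
#' from the planted loci with negative-binomial count noise (gamma-mixed
#' multinomial allocation), known small RNA fragments cut from the reference
#' sets, and one planted read class per QC filter. A configured number of
#' tags is differentially expressed between the groups with absolute log2
#' fold change `de_log2fc` (half up-, half down-regulated in group B; DE tags
#' are chosen among well-expressed 5'U primary loci).
#'
#' @param genome_sim A `pirna_sim_genome` from [make_genome()].
#' @param outdir Directory to write `<sample>.fastq`, `manifest.tsv`,
#'   `samples.tsv`, `truth_counts.tsv` and `truth_de.tsv`.
#' @return A list of class `pirna_sim_libs` with elements `config`, `samples`
#'   (sample sheet data frame), `manifest`, `counts` (true piRNA read counts,
#'   tags x samples), `de` (planted DE table) and `paths`.
#' @export
simulate_libraries <- function(genome_sim, outdir) {
  stopifnot(is(genome_sim, "pirna_sim_genome"))
  cfg <- genome_sim$config
  if (sum(cfg$contaminant_fracs) + sum(cfg$srna_fracs) > 1) {
    stop("contaminant and known-sRNA fractions sum above 1", call. = FALSE)
  }
  set.seed(cfg$seed + 1000L)
  seed8 <- substr(cfg$adapter_3p, 1, 8)
  loci <- genome_sim$truth$loci
  n_tags <- nrow(loci)
  N <- cfg$n_reads_per_library

  samples <- data.frame(
    sample = paste0(rep(c("A", "B"), each = cfg$n_samples_per_group), "_",
                    rep(seq_len(cfg$n_samples_per_group), 2)),
    group = rep(c("A", "B"), each = cfg$n_samples_per_group),
    stringsAsFactors = FALSE)

  ## planted DE tags: well-expressed 5'U primaries
  eligible <- which(loci$role == "primary" & loci$is_1U &
                      loci$mu >= median(loci$mu[loci$role == "primary"]))
  if (length(eligible) < cfg$n_de_tags) {
    stop("not enough eligible tags to plant the requested DE set",
         call. = FALSE)
  }
  de_idx <- sample(eligible, cfg$n_de_tags)
  lfc <- numeric(n_tags)
  n_up <- ceiling(cfg$n_de_tags / 2)
  lfc[de_idx[seq_len(n_up)]] <- cfg$de_log2fc
  lfc[de_idx[-seq_len(n_up)]] <- -cfg$de_log2fc
  de_truth <- data.frame(tag_id = loci$tag_id, is_de = lfc != 0,
                         true_log2fc = lfc, stringsAsFactors = FALSE)

  ## per-class read budgets (recorded draws; identical for every library)
  cont_counts <- round(cfg$contaminant_fracs * N)
  srna_counts <- round(cfg$srna_fracs * N)
  n_pirna <- N - sum(cont_counts) - sum(srna_counts)

  ## known-sRNA insert pools: 24-28 nt fragments of the reference sequences
  srna_pool <- list()
  for (class in names(cfg$srna_fracs)) {
    refs <- genome_sim$refs[[class]]
    k <- 25L
    pool <- character(k)
    for (i in seq_len(k)) {
      src <- sample(length(refs), 1)
      len <- sample(24:28, 1)
      start <- sample(nchar(as.character(refs[[src]])) - len + 1L, 1)
      pool[i] <- substr(as.character(refs[[src]]), start, start + len - 1L)
    }
    srna_pool[[class]] <- unique(pool)
  }

  ## one read sequence per tag (reads of a tag are identical by definition)
  tag_reads <- vapply(loci$sequence, build_read, character(1),
                      adapter_3p = cfg$adapter_3p,
                      read_length = cfg$read_length)

  qual_hi <- strrep(rawToChar(as.raw(38L + 33L)), cfg$read_length)
  n_low <- ceiling(cfg$read_length * 0.6)
  qual_low <- paste0(strrep(rawToChar(as.raw(2L + 33L)), n_low),
                     strrep(rawToChar(as.raw(38L + 33L)),
                            cfg$read_length - n_low))

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  counts <- matrix(0L, nrow = n_tags, ncol = nrow(samples),
                   dimnames = list(loci$tag_id, samples$sample))
  fastq_paths <- character(nrow(samples))

  for (si in seq_len(nrow(samples))) {
    smp <- samples$sample[si]
    grp <- samples$group[si]
    mu <- loci$mu * if (grp == "B") 2^lfc else 1
    w <- rgamma(n_tags, shape = 1 / cfg$dispersion,
                scale = mu * cfg$dispersion)
    w[w <= 0] <- 1e-12
    tag_counts <- as.integer(rmultinom(1, n_pirna, w))
    counts[, si] <- tag_counts

    seqs <- rep(tag_reads, tag_counts)
    quals <- rep(qual_hi, length(seqs))
    labels <- rep(ifelse(loci$role == "secondary", "pirna_secondary",
                         "pirna_primary"), tag_counts)
    tag_ids <- rep(loci$tag_id, tag_counts)

    for (class in names(srna_counts)) {
      nk <- srna_counts[[class]]
      if (nk == 0L) next
      pool <- srna_pool[[class]]
      draws <- as.integer(rmultinom(1, nk, rep(1, length(pool))))
      ins <- rep(pool, draws)
      rd <- vapply(ins, build_read, character(1),
                   adapter_3p = cfg$adapter_3p,
                   read_length = cfg$read_length)
      seqs <- c(seqs, rd)
      quals <- c(quals, rep(qual_hi, nk))
      labels <- c(labels, rep(class, nk))
      tag_ids <- c(tag_ids, rep(NA_character_, nk))
    }

    for (class in names(cont_counts)) {
      nk <- cont_counts[[class]]
      if (nk == 0L) next
      rd <- character(nk)
      qs <- rep(qual_hi, nk)
      for (i in seq_len(nk)) {
        rd[i] <- switch(
          class,
          qc_low_quality = {
            qs[i] <- qual_low
            build_read(random_insert(sample(24:33, 1), seed8),
                       cfg$adapter_3p, cfg$read_length)
          },
          qc_high_N = {
            r <- build_read(random_insert(sample(24:33, 1), seed8),
                            cfg$adapter_3p, cfg$read_length)
            n_n <- ceiling(cfg$read_length * 0.16)
            pos <- sample(cfg$read_length, n_n)
            ch <- strsplit(r, "")[[1]]
            ch[pos] <- "N"
            paste(ch, collapse = "")
          },
          qc_5p_adapter = {
            fill <- random_insert(
              max(cfg$read_length - nchar(cfg$adapter_5p), 0L), seed8)
            substr(paste0(cfg$adapter_5p, fill), 1L, cfg$read_length)
          },
          qc_no_3p_adapter = random_insert(cfg$read_length, seed8),
          qc_homopolymer = build_read(strrep(sample(DNA_BASES, 1), 30L),
                                      cfg$adapter_3p, cfg$read_length),
          qc_bad_length = build_read(
            random_insert(sample(c(19:23, 34:36), 1), seed8),
            cfg$adapter_3p, cfg$read_length),
          stop("unknown contaminant class: ", class)
        )
      }
      seqs <- c(seqs, rd)
      quals <- c(quals, qs)
      labels <- c(labels, rep(class, nk))
      tag_ids <- c(tag_ids, rep(NA_character_, nk))
    }

    stopifnot(length(seqs) == N)
    ord <- sample(N)
    seqs <- seqs[ord]; quals <- quals[ord]
    labels <- labels[ord]; tag_ids <- tag_ids[ord]
    ids <- sprintf("%s_r%07d", smp, seq_len(N))

    x <- QualityScaledDNAStringSet(DNAStringSet(seqs), PhredQuality(quals))
    names(x) <- ids
    fastq_paths[si] <- file.path(outdir, paste0(smp, ".fastq"))
    writeQualityScaledXStringSet(x, fastq_paths[si])

    manifest[[si]] <- data.frame(read_id = ids, sample = smp, label = labels,
                                 tag_id = tag_ids, stringsAsFactors = FALSE)
  }

  manifest <- do.call(rbind, manifest)
  paths <- list(fastq = setNames(fastq_paths, samples$sample),
                manifest = file.path(outdir, "manifest.tsv"),
                samples = file.path(outdir, "samples.tsv"),
                truth_counts = file.path(outdir, "truth_counts.tsv"),
                truth_de = file.path(outdir, "truth_de.tsv"))
  write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(samples, paths$samples, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(tag_id = rownames(counts), counts,
                         check.names = FALSE),
              paths$truth_counts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(de_truth, paths$truth_de, sep = "\t", quote = FALSE,
              row.names = FALSE)

  structure(list(config = cfg, samples = samples, manifest = manifest,
                 counts = counts, de = de_truth, paths = paths),
            class = "pirna_sim_libs")
}

#' @export
print.pirna_sim_libs <- function(x, ...) {
  cat("pirna_sim_libs:", nrow(x$samples), "libraries x",
      x$config$n_reads_per_library, "reads;", nrow(x$counts),
      "planted tags,", sum(x$de$is_de), "DE\n")
  invisible(x)
}
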