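# Shared simulated fixtures (built once per test run) and independent
# brute-force oracles.

sim_env <- new.env(parent = emptyenv())

get_sim <- function(key, cfg_fn) {
  if (!exists(key, envir = sim_env)) {
    dir <- file.path(tempdir(), paste0("pirnakit_", key))
    g <- make_genome(cfg_fn(), outdir = dir)
    libs <- simulate_libraries(g, dir)
    assign(key, list(genome = g, libs = libs, dir = dir), envir = sim_env)
  }
  get(key, envir = sim_env)
}

## moderate-depth study used by most module tests
small_sim <- function() {
  get_sim("small", function() sim_config(seed = 101,
                                         n_reads_per_library = 20000))
}

## full-depth study under default conditions, used by the acceptance suite
big_sim <- function() {
  get_sim("big", function() sim_config(seed = 424242))
}

## genome-only fixture without ping-pong pairs (null signature checks)
nopp_genome <- function() {
  key <- "nopp"
  if (!exists(key, envir = sim_env)) {
    assign(key, make_genome(sim_config(seed = 303,
                                       frac_pingpong_pairs = 0)),
           envir = sim_env)
  }
  get(key, envir = sim_env)
}

sim_pipeline <- function(key) {
  pkey <- paste0(key, "_pipeline")
  if (!exists(pkey, envir = sim_env)) {
    sim <- if (key == "small") small_sim() else big_sim()
    groups <- setNames(sim$libs$samples$group, sim$libs$samples$sample)
    res <- run_pipeline(sim$libs$paths$fastq, groups,
                        genome = sim$genome$genome,
                        genes = sim$genome$genes_gr,
                        repeats = sim$genome$repeats_gr,
                        reference_sets = sim$genome$refs)
    assign(pkey, res, envir = sim_env)
  }
  get(pkey, envir = sim_env)
}

## all-pairs brute-force ping-pong oracle (quadratic; fine below ~1e3 hits)
bf_pingpong <- function(hits, max_overlap = 20L) {
  counts <- setNames(numeric(max_overlap), seq_len(max_overlap))
  if (is.null(hits$weight)) hits$weight <- rep(1, nrow(hits))
  pi <- which(hits$strand == "+")
  mi <- which(hits$strand == "-")
  for (i in pi) {
    for (j in mi) {
      if (hits$chrom[i] != hits$chrom[j]) next
      ov <- (hits$end[j] - 1L) - hits$start[i] + 1L
      if (ov >= 1L && ov <= max_overlap) {
        counts[ov] <- counts[ov] + hits$weight[i] * hits$weight[j]
      }
    }
  }
  bg <- counts[-10L]
  s <- sqrt(mean((bg - mean(bg))^2))
  z10 <- if (s > 0) (counts[[10L]] - mean(bg)) / s else NA_real_
  list(overlap_counts = counts, z10 = z10)
}

## naive sliding-window alignment oracle: exact matches of each tag (and its
## reverse complement) against precomputed substring tables
bf_align <- function(sequences, genome) {
  gch <- vapply(seq_along(genome), function(i) as.character(genome[[i]]),
                character(1))
  names(gch) <- names(genome)
  out <- list()
  for (w in sort(unique(nchar(sequences)))) {
    idx <- which(nchar(sequences) == w)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(sequences[idx])))
    for (chrom in names(gch)) {
      g <- gch[[chrom]]
      nsub <- nchar(g) - w + 1L
      subs <- substring(g, seq_len(nsub), seq_len(nsub) + w - 1L)
      for (k in seq_along(idx)) {
        fw <- which(subs == sequences[idx[k]])
        rv <- which(subs == rc[k])
        if (length(fw)) {
          out[[length(out) + 1L]] <- data.frame(
            seq_idx = idx[k], chrom = chrom, start = fw - 1L,
            end = fw - 1L + w, strand = "+", stringsAsFactors = FALSE)
        }
        if (length(rv)) {
          out[[length(out) + 1L]] <- data.frame(
            seq_idx = idx[k], chrom = chrom, start = rv - 1L,
            end = rv - 1L + w, strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq_idx = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

## reciprocal-overlap fraction of each planted cluster with its best match
reciprocal_overlap <- function(truth, detected) {
  vapply(seq_len(nrow(truth)), function(i) {
    tc <- truth[i, ]
    d <- detected[detected$chrom == tc$chrom, , drop = FALSE]
    if (!nrow(d)) return(0)
    ov <- pmax(0, pmin(d$end, tc$end) - pmax(d$start, tc$start))
    max(pmin(ov / (tc$end - tc$start), ov / (d$end - d$start)))
  }, numeric(1))
}

## write a plain FASTQ from parallel vectors
write_fastq <- function(path, seqs, quals, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%05d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

q_chr <- function(q, n = 1L) strrep(rawToChar(as.raw(q + 33L)), n)
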