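## Synthetic toy genome with planted piRNA biology.
##
## All interval coordinates in the returned truth tables are 0-based
## half-open; GFF3/BED files written to disk follow their own standards
## (1-based inclusive and 0-based half-open respectively, via rtracklayer).

## Gene model layout (relative 0-based offsets within a 2000 nt gene).
GENE_LAYOUT <- list(
  UTR5   = c(0L, 150L),
  CDS1   = c(150L, 600L),
  intron = c(600L, 1300L),
  CDS2   = c(1300L, 1750L),
  UTR3   = c(1750L, 2000L)
)
GENE_LEN <- 2000L
LNC_LEN <- 500L
REPEAT_LEN <- 300L

length_weights <- function(cfg, sd = 1.5) {
  ls <- seq(cfg$pirna_length_range[1], cfg$pirna_length_range[2])
  w <- dnorm(ls, cfg$pirna_length_mode, sd)
  list(lengths = ls, prob = w / sum(w))
}

draw_lengths <- function(n, cfg) {
  lw <- length_weights(cfg)
  sample(lw$lengths, n, replace = TRUE, prob = lw$prob)
}

## a reference sequence free of the 3' adapter seed (so planted known-sRNA
## fragments can never look adapter-bearing)
random_ref_seq <- function(len, seed8) {
  repeat {
    s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    if (!grepl(seed8, s, fixed = TRUE)) return(s)
  }
}

#' Generate a toy genome with planted piRNA biology
#'
#' Builds `n_chromosomes` random chromosomes and plants, without overlap:
#' piRNA clusters (each with a fixed number of distinct piRNA loci, a single
#' cluster strand, and optional opposite-strand ping-pong partner loci whose
#' 5' ends overlap the primary by exactly 10 nt), protein-coding gene models
#' (5'UTR/CDS/intron/CDS/3'UTR), lncRNA genes, repeat intervals labelled with
#' TE "class/family" names drawn from `te_composition`, and piRNA loci inside
#' each feature type as well as in unannotated space. Each locus's 5' genomic
#' base is set to give a U first base with probability `frac_1U`; the 10A
#' mark on ping-pong partners follows from the overlap geometry.
#'
#' The TE family labels are the first random draw after seeding
#' (`sample(names(te_composition), n_repeats, replace = TRUE, prob =
#' te_composition)`), so the family composition of the repeat track can be
#' reproduced independently from the seed alone.
#'
#' Also generates contaminant reference sets (rRNA/tRNA/snRNA/snoRNA/miRNA)
#' used by the known-sRNA removal stage. All outputs are deterministic
#' functions of `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param outdir Optional directory; when given, writes `genome.fa`,
#'   `genes.gff3`, `repeats.bed`, `ref_<class>.fa`, `truth_loci.tsv` and
#'   `truth_clusters.tsv`.
#' @return A list of class `pirna_sim_genome` with elements `config`,
#'   `genome` (DNAStringSet), `genes_gr`, `repeats_gr`, `refs` (named list of
#'   DNAStringSet), and `truth` (`$loci`, `$clusters` data frames, 0-based
#'   half-open coordinates).
#' @export
#' @examples
#' g <- make_genome(sim_config(seed = 7, n_reads_per_library = 1000))
#' names(g$refs)
#' head(g$truth$clusters)
make_genome <- function(config, outdir = NULL) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  seed8 <- substr(cfg$adapter_3p, 1, 8)
  n_chrom <- cfg$n_chromosomes
  chrom_names <- paste0("chr", seq_len(n_chrom))

  ## 1. TE family labels: documented first draw (re-execution oracle).
  fams <- sample(names(cfg$te_composition), cfg$n_repeats,
                 replace = TRUE, prob = cfg$te_composition)

  ## 2. Chromosome sequences, kept as character vectors for base editing.
  genome_chars <- lapply(seq_len(n_chrom), function(i) {
    sample(DNA_BASES, cfg$chrom_length, replace = TRUE)
  })

  ## 3. Entity plan: round-robin chromosome assignment, then sequential
  ##    placement with random gaps; clusters get a wide berth so detected
  ##    clusters can never bridge two planted ones.
  rr <- function(n) ((seq_len(n) - 1L) %% n_chrom) + 1L
  ent <- rbind(
    data.frame(kind = "cluster", id = seq_len(cfg$n_clusters),
               len = as.integer(round(runif(cfg$n_clusters,
                                            cfg$cluster_length_range[1],
                                            cfg$cluster_length_range[2]))),
               chrom = rr(cfg$n_clusters)),
    data.frame(kind = "gene",
               id = seq_len(cfg$n_genes_per_chrom * n_chrom), len = GENE_LEN,
               chrom = rr(cfg$n_genes_per_chrom * n_chrom)),
    data.frame(kind = "lnc", id = seq_len(n_chrom), len = LNC_LEN,
               chrom = rr(n_chrom)),
    data.frame(kind = "repeat", id = seq_len(cfg$n_repeats), len = REPEAT_LEN,
               chrom = rr(cfg$n_repeats))
  )
  ent$start <- NA_integer_
  tail_start <- integer(n_chrom)
  for (ci in seq_len(n_chrom)) {
    idx <- which(ent$chrom == ci)
    idx <- idx[sample(length(idx))]
    cursor <- 0L
    prev_cluster <- FALSE
    for (k in idx) {
      ## clusters are isolated on both sides so a window-based detector can
      ## never chain a cluster with neighbouring feature loci
      gap <- if (ent$kind[k] == "cluster" || prev_cluster) {
        12000L + sample(0:2000, 1)
      } else {
        sample(1500:2500, 1)
      }
      ent$start[k] <- cursor + gap
      cursor <- ent$start[k] + ent$len[k]
      prev_cluster <- ent$kind[k] == "cluster"
    }
    if (cursor > cfg$chrom_length - 4000L) {
      stop(sprintf(
        "planted feature demand (%d nt) exceeds capacity of %s (%d nt)",
        cursor, chrom_names[ci], cfg$chrom_length), call. = FALSE)
    }
    tail_start[ci] <- cursor
  }
  ent$end <- ent$start + ent$len

  clusters <- ent[ent$kind == "cluster", ]
  clusters <- clusters[order(clusters$id), ]
  genes <- ent[ent$kind == "gene", ]
  lncs <- ent[ent$kind == "lnc", ]
  reps <- ent[ent$kind == "repeat", ]
  reps <- reps[order(reps$id), ]
  reps$family <- fams

  ## 4. Feature containers for locus planting (0-based half-open).
  cont <- list(CDS = list(), UTR5 = list(), UTR3 = list(), intron = list(),
               lncRNA = list(), "repeat" = list())
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    add <- function(part) c(g$chrom, g$start + GENE_LAYOUT[[part]][1],
                            g$start + GENE_LAYOUT[[part]][2])
    cont$CDS <- c(cont$CDS, list(add("CDS1")), list(add("CDS2")))
    cont$UTR5 <- c(cont$UTR5, list(add("UTR5")))
    cont$UTR3 <- c(cont$UTR3, list(add("UTR3")))
    cont$intron <- c(cont$intron, list(add("intron")))
  }
  for (k in seq_len(nrow(lncs))) {
    cont$lncRNA <- c(cont$lncRNA,
                     list(c(lncs$chrom[k], lncs$start[k], lncs$end[k])))
  }
  for (k in seq_len(nrow(reps))) {
    cont$"repeat" <- c(cont$"repeat",
                       list(c(reps$chrom[k], reps$start[k], reps$end[k])))
  }

  ## 5. Plant piRNA loci. Margin 35 keeps partner intervals (at most 33 nt
  ##    around the primary 5' end) inside their container.
  margin <- 35L
  loci <- list()
  n_loci <- 0L
  pair_counter <- 0L
  add_locus <- function(chrom, pos5, strand, len, category, te_class,
                        te_family, cluster_id, role, pair_id, cs, ce,
                        overlap = NA_integer_) {
    n_loci <<- n_loci + 1L
    loci[[n_loci]] <<- data.frame(
      tag_id = NA_character_, chrom = chrom, pos5 = pos5, strand = strand,
      length = len, category = category,
      te_class = te_class, te_family = te_family,
      cluster_id = cluster_id, role = role, pair_id = pair_id,
      overlap = overlap, cont_s = cs, cont_e = ce, stringsAsFactors = FALSE)
    n_loci
  }
  place5 <- function(cs, ce, len, strand) {
    if (strand == "+") sample(seq(cs + margin, ce - len - margin), 1)
    else sample(seq(cs + len + margin, ce - 1L - margin), 1)
  }
  add_partner <- function(i, overlap, role) {
    l <- loci[[i]]
    len2 <- draw_lengths(1, cfg)
    pair_counter <<- pair_counter + 1L
    if (l$strand == "+") {
      q <- l$pos5 + overlap - 1L          # minus-strand 5' end
      add_locus(l$chrom, q, "-", len2, l$category, l$te_class, l$te_family,
                l$cluster_id, role, pair_counter, l$cont_s, l$cont_e, overlap)
    } else {
      p <- l$pos5 - overlap + 1L
      add_locus(l$chrom, p, "+", len2, l$category, l$te_class, l$te_family,
                l$cluster_id, role, pair_counter, l$cont_s, l$cont_e, overlap)
    }
    loci[[i]]$pair_id <<- pair_counter
  }
  maybe_partner <- function(i) {
    r <- runif(1)
    if (r < cfg$frac_pingpong_pairs) {
      add_partner(i, 10L, "secondary")    # the ping-pong geometry
    } else if (r < cfg$frac_pingpong_pairs + cfg$frac_antisense_bg) {
      ## incidental antisense overlap away from 10 nt: Z-score background
      add_partner(i, sample(setdiff(1:20, 10L), 1), "background")
    }
  }

  for (k in seq_len(nrow(clusters))) {
    cl <- clusters[k, ]
    cl_strand <- sample(c("+", "-"), 1)
    n <- cfg$loci_per_cluster
    lens <- draw_lengths(n, cfg)
    inner <- c(cl$start + 40L, cl$end - 40L)
    grid <- round(seq(inner[1], inner[2], length.out = n))
    jit <- c(0L, sample(-12:12, max(n - 2L, 0L), replace = TRUE), 0L)[seq_len(n)]
    pos5s <- pmin(pmax(grid + jit, inner[1]), inner[2])
    for (j in seq_len(n)) {
      i <- add_locus(cl$chrom, pos5s[j], cl_strand, lens[j], "unannotated",
                     NA_character_, NA_character_, cl$id, "primary",
                     NA_integer_, inner[1], inner[2])
      maybe_partner(i)
    }
  }

  feat_keys <- names(cfg$n_feature_loci)
  for (key in feat_keys) {
    nk <- cfg$n_feature_loci[[key]]
    if (nk == 0L) next
    if (key == "unannotated") next
    pool <- cont[[key]]
    for (j in seq_len(nk)) {
      cidx <- ((j - 1L) %% length(pool)) + 1L
      cc <- pool[[cidx]]
      strand <- sample(c("+", "-"), 1)
      len <- draw_lengths(1, cfg)
      pos5 <- place5(cc[2], cc[3], len, strand)
      cat_name <- if (key %in% c("UTR5", "UTR3")) sub("UTR5", "5UTR",
                     sub("UTR3", "3UTR", key)) else key
      tec <- tef <- NA_character_
      if (key == "repeat") {
        fam <- reps$family[cidx]
        parts <- strsplit(fam, "/", fixed = TRUE)[[1]]
        tec <- parts[1]
        tef <- parts[2]
      }
      i <- add_locus(cc[1], pos5, strand, len, cat_name, tec, tef,
                     NA_integer_, "primary", NA_integer_, cc[2], cc[3])
      if (key == "repeat") maybe_partner(i)
    }
  }

  n_un <- cfg$n_feature_loci[["unannotated"]] %||% 0L
  if (n_un > 0L) {
    un_chrom <- rr(n_un)
    offs <- integer(n_chrom)
    for (j in seq_len(n_un)) {
      ci <- un_chrom[j]
      ## well clear of the last planted entity so the sparse pocket can
      ## never share a detector window with feature-derived loci
      pos <- tail_start[ci] + 8000L + offs[ci] * 300L
      offs[ci] <- offs[ci] + 1L
      len <- draw_lengths(1, cfg)
      strand <- sample(c("+", "-"), 1)
      pos5 <- if (strand == "+") pos else pos + len - 1L
      if (pos + len + 50L > cfg$chrom_length) {
        stop("unannotated locus demand exceeds chromosome capacity",
             call. = FALSE)
      }
      add_locus(ci, pos5, strand, len, "unannotated", NA_character_,
                NA_character_, NA_integer_, "primary", NA_integer_,
                tail_start[ci] + 8000L, cfg$chrom_length - 50L)
    }
  }

  loci <- do.call(rbind, loci)
  for (col in c("pos5", "length", "cont_s", "cont_e")) {
    loci[[col]] <- as.integer(round(loci[[col]]))
  }
  loci$tag_id <- sprintf("t%05d", seq_len(nrow(loci)))
  loci$start <- ifelse(loci$strand == "+", loci$pos5, loci$pos5 - loci$length + 1L)
  loci$end <- loci$start + loci$length

  ## 6. 5' base edits: U first base with probability frac_1U, an explicit
  ##    non-U base otherwise (so the planted rate is exactly frac_1U).
  edit_5prime <- function(k) {
    ci <- loci$chrom[k]
    pos <- loci$pos5[k] + 1L            # 1-based index into the char vector
    if (loci$strand[k] == "+") {
      genome_chars[[ci]][pos] <<- if (runif(1) < cfg$frac_1U) "T" else
        sample(c("A", "C", "G"), 1)
    } else {
      genome_chars[[ci]][pos] <<- if (runif(1) < cfg$frac_1U) "A" else
        sample(c("T", "G", "C"), 1)
    }
  }
  for (k in seq_len(nrow(loci))) edit_5prime(k)

  ## 7. Extract tag sequences; re-place loci whose sequence collides with an
  ##    adapter or another tag (rare on a random genome).
  extract_seq <- function(k) {
    ci <- loci$chrom[k]
    s <- paste(genome_chars[[ci]][(loci$start[k] + 1L):loci$end[k]],
               collapse = "")
    if (loci$strand[k] == "-") revcomp_chr(s) else s
  }
  for (iter in seq_len(30L)) {
    seqs <- vapply(seq_len(nrow(loci)), extract_seq, character(1))
    bad <- grepl(seed8, seqs, fixed = TRUE) |
      grepl(cfg$adapter_5p, seqs, fixed = TRUE) |
      (duplicated(seqs) | duplicated(seqs, fromLast = TRUE)) &
        duplicated(seqs)
    if (!any(bad)) break
    if (iter == 30L) stop("could not place collision-free piRNA loci",
                          call. = FALSE)
    for (k in which(bad)) {
      ## move the primary of the pair group; partners follow the geometry
      prim <- k
      if (loci$role[k] != "primary") {
        prim <- which(loci$pair_id == loci$pair_id[k] &
                        loci$role == "primary")
      }
      loci$pos5[prim] <- place5(loci$cont_s[prim], loci$cont_e[prim],
                                loci$length[prim], loci$strand[prim])
      moved <- prim
      if (!is.na(loci$pair_id[prim])) {
        sec <- which(loci$pair_id == loci$pair_id[prim] &
                       loci$role != "primary")
        ov <- loci$overlap[sec]
        loci$pos5[sec] <- if (loci$strand[prim] == "+")
          loci$pos5[prim] + ov - 1L else loci$pos5[prim] - ov + 1L
        moved <- c(moved, sec)
      }
      for (m in moved) {
        loci$start[m] <- if (loci$strand[m] == "+") loci$pos5[m] else
          loci$pos5[m] - loci$length[m] + 1L
        loci$end[m] <- loci$start[m] + loci$length[m]
        edit_5prime(m)
      }
    }
  }
  loci$sequence <- vapply(seq_len(nrow(loci)), extract_seq, character(1))
  loci$is_1U <- substr(loci$sequence, 1, 1) == "T"
  loci$is_10A <- substr(loci$sequence, 10, 10) == "A"

  ## 8. Baseline expression means (lognormal; partners weaker than primaries).
  loci$mu <- rlnorm(nrow(loci), meanlog = log(40), sdlog = 1)
  sec <- which(loci$role != "primary")
  for (k in sec) {
    prim <- which(loci$pair_id == loci$pair_id[k] & loci$role == "primary")
    loci$mu[k] <- loci$mu[prim] * runif(1, 0.3, 0.7)
  }

  ## 9. Contaminant reference sets.
  make_refs <- function(n, len, class) {
    s <- vapply(seq_len(n), function(i) random_ref_seq(len, seed8),
                character(1))
    x <- DNAStringSet(s)
    names(x) <- paste0(class, "_", seq_len(n))
    x
  }
  refs <- list(
    rRNA = make_refs(2, 1500, "rRNA"),
    tRNA = make_refs(5, 75, "tRNA"),
    snRNA = make_refs(4, 150, "snRNA"),
    snoRNA = make_refs(4, 120, "snoRNA"),
    miRNA = make_refs(20, 60, "miRNA")
  )

  genome <- DNAStringSet(vapply(genome_chars, paste, character(1),
                                collapse = ""))
  names(genome) <- chrom_names

  truth_clusters <- data.frame(
    cluster_id = clusters$id,
    chrom = chrom_names[clusters$chrom],
    start = clusters$start, end = clusters$end,
    stringsAsFactors = FALSE)
  cl_strands <- vapply(clusters$id, function(id) {
    loci$strand[loci$cluster_id %in% id & loci$role == "primary"][1]
  }, character(1))
  truth_clusters$strand <- cl_strands

  truth_loci <- loci[, c("tag_id", "chrom", "start", "end", "strand",
                         "length", "category", "te_class", "te_family",
                         "cluster_id", "role", "pair_id", "overlap", "mu",
                         "sequence", "is_1U", "is_10A")]
  truth_loci$chrom <- chrom_names[truth_loci$chrom]

  ## 10. Annotation GRanges (1-based inclusive, the GRanges convention).
  gene_rows <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    gid <- paste0("gene", g$id)
    strand <- sample(c("+", "-"), 1)
    at <- function(part) IRanges(g$start + GENE_LAYOUT[[part]][1] + 1L,
                                 g$start + GENE_LAYOUT[[part]][2])
    gene_rows[[length(gene_rows) + 1L]] <- GRanges(
      factor(chrom_names[g$chrom], levels = chrom_names),
      c(IRanges(g$start + 1L, g$end),          # gene
        at("UTR5"),
        IRanges(g$start + GENE_LAYOUT$UTR5[1] + 1L,
                g$start + GENE_LAYOUT$CDS1[2]),  # exon 1
        at("CDS1"),
        IRanges(g$start + GENE_LAYOUT$CDS2[1] + 1L,
                g$start + GENE_LAYOUT$UTR3[2]),  # exon 2
        at("CDS2"),
        at("UTR3")),
      strand = strand,
      type = c("gene", "five_prime_UTR", "exon", "CDS", "exon", "CDS",
               "three_prime_UTR"),
      gene_id = gid)
  }
  for (k in seq_len(nrow(lncs))) {
    g <- lncs[k, ]
    gene_rows[[length(gene_rows) + 1L]] <- GRanges(
      factor(chrom_names[g$chrom], levels = chrom_names),
      IRanges(rep(g$start + 1L, 2), rep(g$end, 2)),
      strand = sample(c("+", "-"), 1),
      type = c("lnc_RNA", "exon"),
      gene_id = paste0("lnc", g$id))
  }
  genes_gr <- do.call(c, gene_rows)
  genes_gr$ID <- paste0(genes_gr$gene_id, "_", seq_along(genes_gr))
  genes_gr$phase <- ifelse(genes_gr$type == "CDS", 0L, NA_integer_)

  repeats_gr <- GRanges(factor(chrom_names[reps$chrom],
                               levels = chrom_names),
                        IRanges(reps$start + 1L, reps$end),
                        strand = sample(c("+", "-"), nrow(reps),
                                        replace = TRUE),
                        name = reps$family,
                        score = 0L)

  out <- structure(list(
    config = cfg,
    genome = genome,
    genes_gr = genes_gr,
    repeats_gr = repeats_gr,
    refs = refs,
    truth = list(loci = truth_loci, clusters = truth_clusters)
  ), class = "pirna_sim_genome")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(outdir, "genome.fa"),
      gff = file.path(outdir, "genes.gff3"),
      repeats = file.path(outdir, "repeats.bed"),
      truth_loci = file.path(outdir, "truth_loci.tsv"),
      truth_clusters = file.path(outdir, "truth_clusters.tsv"))
    writeXStringSet(genome, paths$genome)
    export(genes_gr, paths$gff, format = "gff3")
    export(repeats_gr, paths$repeats, format = "bed")
    write.table(truth_loci, paths$truth_loci, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth_clusters, paths$truth_clusters, sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (class in names(refs)) {
      p <- file.path(outdir, paste0("ref_", class, ".fa"))
      writeXStringSet(refs[[class]], p)
      paths[[paste0("ref_", class)]] <- p
    }
    out$paths <- paths
  }
  out
}

#' @export
print.pirna_sim_genome <- function(x, ...) {
  cat("pirna_sim_genome:", length(x$genome), "chromosomes,",
      nrow(x$truth$loci), "planted piRNA loci,",
      nrow(x$truth$clusters), "clusters\n")
  invisible(x)
}
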