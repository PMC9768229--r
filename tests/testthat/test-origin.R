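toy_genome <- function() {
  set.seed(41)
  base <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                collapse = "")
  Biostrings::DNAStringSet(c(chrA = base))
}

test_that("alignment reports every exact occurrence with split weights", {
  g <- toy_genome()
  s <- as.character(g[[1]])
  tag1 <- substr(s, 101, 128)                       # single locus
  g2 <- Biostrings::DNAStringSet(c(chrA = paste0(s, tag1)))  # two loci
  tags <- data.frame(sequence = tag1, s1 = 10L, stringsAsFactors = FALSE)
  h1 <- align_tags(tags, g)
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$start, 100L)
  expect_identical(h1$end, 128L)
  expect_identical(h1$strand, "+")
  expect_equal(h1$weight, 10)
  h2 <- align_tags(tags, g2)
  expect_identical(nrow(h2), 2L)
  expect_equal(h2$weight, c(5, 5))
  ## a reverse-complement occurrence is a minus-strand hit
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tag1)))
  h3 <- align_tags(data.frame(sequence = rc, s1 = 4L), g)
  expect_identical(h3$strand, "-")
  expect_identical(h3$start, 100L)
  ## non-ACGT tags are skipped with a warning
  expect_warning(
    h4 <- align_tags(data.frame(sequence = c(tag1, "ACGTNACGTNACGTNACGTNACGTN"),
                                s1 = c(1L, 1L)), g),
    "non-ACGT")
  expect_identical(nrow(h4), 1L)
})

test_that("alignment equals the naive sliding-window oracle on random tags", {
  sim <- small_sim()
  genome <- sim$genome$genome
  loci <- sim$genome$truth$loci
  set.seed(909)
  planted <- sample(loci$sequence, min(400L, nrow(loci)))
  random <- vapply(sample(24:33, 500, replace = TRUE), function(w) {
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  }, character(1))
  seqs <- unique(c(planted, random))
  tags <- data.frame(sequence = seqs, s1 = rep(1L, length(seqs)),
                     stringsAsFactors = FALSE)
  hits <- align_tags(tags, genome)
  oracle <- bf_align(seqs, genome)
  key <- function(seq, chrom, start, strand) {
    paste(seq, chrom, start, strand, sep = ":")
  }
  got <- sort(key(tags$sequence[match(hits$tag_id,
                                      sprintf("tag%06d", seq_along(seqs)))],
                  hits$chrom, hits$start, hits$strand))
  want <- sort(key(seqs[oracle$seq_idx], oracle$chrom, oracle$start,
                   oracle$strand))
  expect_identical(got, want)
  ## weight conservation over aligned tags
  aligned <- unique(hits$tag_id)
  expect_equal(sum(hits$weight), length(aligned))
})

test_that("feature priority, overlap rule and TE parsing behave as specified", {
  ## 1-based annotation: gene 1-700 with exons 101-160 / 401-460
  ## (CDS 101-130), 5'UTR 201-260, 3'UTR 301-360; separate lncRNA 801-900;
  ## repeats 101-160 (LINE/L1) and 471-530 (DNA/hAT-Charlie)
  genes <- GenomicRanges::GRanges(
    "chrA",
    IRanges::IRanges(c(1, 101, 101, 201, 301, 401, 801, 801),
                     c(700, 160, 130, 260, 360, 460, 900, 900)),
    type = c("gene", "exon", "CDS", "five_prime_UTR", "three_prime_UTR",
             "exon", "lnc_RNA", "exon"),
    gene_id = c(rep("g1", 6), "lnc1", "lnc1"))
  repeats <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(101, 471), c(160, 530)),
    name = c("LINE/L1", "DNA/hAT-Charlie"))
  mk_hits <- function(start, end) {
    data.frame(tag_id = sprintf("t%02d", seq_along(start)), chrom = "chrA",
               start = start, end = end,
               strand = "+", n_mismatch = 0L, weight = 1,
               stringsAsFactors = FALSE)
  }
  ## hits are 0-based half-open, all 28 nt
  hits <- mk_hits(
    start = c(105, 210, 310, 475, 369, 1000, 117, 820),
    end   = c(133, 238, 338, 503, 397, 1028, 145, 848))
  out <- assign_features(hits, genes, repeats)
  got <- out$assignments$category
  ## fully inside CDS, which also sits inside a repeat: CDS has priority
  expect_identical(got[1], "CDS")
  expect_identical(got[2], "5UTR")
  expect_identical(got[3], "3UTR")
  expect_identical(got[4], "repeat")
  expect_identical(out$assignments$te_class[4], "DNA")
  expect_identical(out$assignments$te_family[4], "hAT-Charlie")
  ## inside the gene body away from exons and repeats: intron
  expect_identical(got[5], "intron")
  expect_identical(got[6], "unannotated")
  ## CDS covers only 13/28 bases (< 50%) so the repeat wins instead
  expect_identical(got[7], "repeat")
  expect_identical(out$assignments$te_class[7], "LINE")
  ## fully inside the lncRNA (whose exon keeps it out of the intron set)
  expect_identical(got[8], "lncRNA")
  expect_equal(sum(out$fractions$weighted_fraction), 1)
})

test_that("a sub-threshold CDS overlap falls through to the intron", {
  genes <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(1, 101, 101), c(700, 130, 130)),
    type = c("gene", "exon", "CDS"), gene_id = "g1")
  repeats <- GenomicRanges::GRanges("chrA", IRanges::IRanges(5, 10),
                                    name = "LINE/L1")
  hits <- data.frame(tag_id = "t1", chrom = "chrA", start = 117L,
                     end = 145L, strand = "+", n_mismatch = 0L, weight = 1,
                     stringsAsFactors = FALSE)
  out <- assign_features(hits, genes, repeats)
  expect_identical(out$assignments$category, "intron")
})

test_that("annotations on unknown chromosomes raise an error", {
  genes <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10),
                                  type = "gene", gene_id = "g")
  repeats <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 10),
                                    name = "LINE/L1")
  hits <- data.frame(tag_id = "t1", chrom = "chrA", start = 0L, end = 28L,
                     strand = "+", n_mismatch = 0L, weight = 1)
  expect_error(assign_features(hits, genes, repeats,
                               genome_seqnames = "chrA"),
               "chrZ")
})

test_that("TE name parsing splits class/family and bins malformed labels", {
  p <- parse_te_name(c("LINE/L1", "DNA/hAT-Charlie"))
  expect_identical(p$class, c("LINE", "DNA"))
  expect_identical(p$family, c("L1", "hAT-Charlie"))
  expect_warning(p <- parse_te_name("LTR-ERVK"), "unparsed")
  expect_identical(p$class, "unparsed")
})

test_that("simulated origin fractions recover the planted composition", {
  sim <- small_sim()
  res <- sim_pipeline("small")
  loci <- sim$genome$truth$loci
  ## expected read-weighted fractions among candidate-eligible planted tags
  cand <- loci$is_1U | loci$is_10A
  w <- rowSums(sim$libs$counts)[loci$tag_id]
  w[!cand] <- 0
  cats <- c("CDS", "5UTR", "3UTR", "repeat", "intron", "lncRNA",
            "unannotated")
  expected <- vapply(cats,
                     function(cl) sum(w[loci$category == cl]) / sum(w),
                     numeric(1))
  got <- setNames(res$features$fractions$weighted_fraction,
                  res$features$fractions$category)[names(expected)]
  expect_lt(max(abs(got - expected)), 0.02)
  ## planted TE composition is recovered within sampling error
  te <- res$te$by_family
  planted <- loci[loci$category == "repeat" & cand, ]
  pw <- w[planted$tag_id]
  for (fam in unique(planted$te_family)) {
    expected_f <- sum(pw[planted$te_family == fam]) / sum(pw)
    got_f <- te$fraction[te$te_family == fam]
    expect_lt(abs(got_f - expected_f), 0.02)
  }
})

test_that("per-TE signatures reflect where pairs were planted", {
  mk <- function(chrom, p5, strand, class, w = 2) {
    data.frame(chrom = chrom, start = ifelse(strand == "+", p5, p5 - 27L),
               end = ifelse(strand == "+", p5 + 28L, p5 + 1L),
               strand = strand, weight = w, category = "repeat",
               te_class = class, stringsAsFactors = FALSE)
  }
  ## LINE: three 10 nt pairs plus off-10 background; SINE: background only
  line <- rbind(mk("chr1", 100, "+", "LINE"), mk("chr1", 109, "-", "LINE"),
                mk("chr1", 500, "+", "LINE"), mk("chr1", 509, "-", "LINE"),
                mk("chr1", 900, "+", "LINE"), mk("chr1", 909, "-", "LINE"),
                mk("chr1", 1300, "+", "LINE"), mk("chr1", 1304, "-", "LINE"),
                mk("chr1", 1700, "+", "LINE"), mk("chr1", 1715, "-", "LINE"))
  sine <- rbind(mk("chr2", 100, "+", "SINE"), mk("chr2", 104, "-", "SINE"),
                mk("chr2", 500, "+", "SINE"), mk("chr2", 517, "-", "SINE"))
  assignments <- rbind(line, sine)
  profiles <- per_te_pingpong(assignments)
  expect_gt(profiles$LINE$z10, 3)
  expect_true(is.na(profiles$SINE$z10) || profiles$SINE$z10 < 3)
  ## per-class counts match brute force within each class
  expect_equal(profiles$LINE$overlap_counts,
               bf_pingpong(line)$overlap_counts)
  ## partition property: per-class counts never exceed the global profile
  global <- ping_pong_signature(assignments)
  per_class_sum <- profiles$LINE$overlap_counts +
    profiles$SINE$overlap_counts
  expect_true(all(per_class_sum <= global$overlap_counts + 1e-9))
})
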