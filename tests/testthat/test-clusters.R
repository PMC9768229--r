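uniform_hits <- function(chrom, lo, hi, n, strand = "+", w = 5,
                         len = 28L, seed = 1) {
  set.seed(seed)
  p5 <- sort(sample(seq(lo, hi), n))
  data.frame(tag_id = sprintf("%s_h%03d", chrom, seq_len(n)), chrom = chrom,
             start = if (strand == "+") p5 else p5 - len + 1L,
             end = if (strand == "+") p5 + len else p5 + 1L,
             strand = strand, weight = w, stringsAsFactors = FALSE)
}

test_that("a single dense span yields one cluster trimmed to its hits", {
  h <- uniform_hits("chr1", 10000, 13000, 50)
  cl <- detect_clusters(h)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$start, min(h$start))
  expect_identical(cl$end, max(h$end))
  expect_identical(cl$n_loci, length(unique(h$start)))
  expect_equal(cl$total_weight, sum(h$weight))
})

test_that("dense spans farther apart than the merge gap stay separate", {
  h <- rbind(uniform_hits("chr1", 10000, 13000, 50, seed = 1),
             uniform_hits("chr1", 63000, 66000, 50, seed = 2))
  cl <- detect_clusters(h)
  expect_identical(nrow(cl), 2L)
  ## and an empty hit set yields an empty cluster set
  expect_identical(nrow(detect_clusters(h[0, ])), 0L)
})

test_that("window thresholds gate sparse or light spans", {
  ## nine distinct loci: below min_loci = 10
  h <- uniform_hits("chr1", 10000, 12000, 9)
  expect_identical(nrow(detect_clusters(h)), 0L)
  ## enough loci but weight below min_weight
  h <- uniform_hits("chr1", 10000, 13000, 50, w = 0.5)
  expect_identical(nrow(detect_clusters(h)), 0L)
  ## merged span shorter than min_length is dropped
  h <- uniform_hits("chr1", 10000, 10500, 30)
  expect_identical(nrow(detect_clusters(h)), 0L)
})

test_that("the detector is translation invariant and monotone in min_loci", {
  h <- rbind(uniform_hits("chr1", 10000, 14000, 30, seed = 3),
             uniform_hits("chr1", 40000, 42000, 12, seed = 4))
  cl <- detect_clusters(h)
  shift <- 3777L
  h2 <- h
  h2$start <- h2$start + shift
  h2$end <- h2$end + shift
  cl2 <- detect_clusters(h2)
  expect_identical(cl2$start, cl$start + shift)
  expect_identical(cl2$end, cl$end + shift)
  ## lowering min_loci never loses a detected cluster
  cl_loose <- detect_clusters(h, min_loci = 5L)
  contained <- vapply(seq_len(nrow(cl)), function(i) {
    any(cl_loose$chrom == cl$chrom[i] & cl_loose$start <= cl$start[i] &
          cl_loose$end >= cl$end[i])
  }, logical(1))
  expect_true(all(contained))
})

test_that("per-cluster statistics report strand split, directionality and 5'U", {
  minus <- uniform_hits("chr1", 10000, 13000, 40, strand = "-", seed = 5)
  cl <- detect_clusters(minus)
  st <- cluster_stats(cl[1, ], minus)
  expect_equal(st$plus_fraction, 0)
  expect_identical(st$directionality, "mono-minus")

  ## 60/40 split sits below the 0.75 threshold: bidirectional
  mixed <- rbind(uniform_hits("chr1", 10000, 13000, 30, "+", w = 6,
                              seed = 6),
                 uniform_hits("chr1", 10010, 13010, 20, "-", w = 6,
                              seed = 7))
  cl <- detect_clusters(mixed)
  st <- cluster_stats(cl[1, ], mixed)
  expect_equal(st$plus_fraction, 0.6)
  expect_identical(st$directionality, "bidirectional")

  ## weighted first-base U fraction from the tag sequences
  tags <- data.frame(tag_id = minus$tag_id,
                     sequence = c(rep("TACGTACGTACGTACGTACGTACGTACG", 30),
                                  rep("GACGTACGTACGTACGTACGTACGTACG", 10)),
                     stringsAsFactors = FALSE)
  st <- cluster_stats(cl_one <- detect_clusters(minus)[1, ], minus, tags)
  expect_equal(st$u1_fraction, 0.75)
})

test_that("chromosome distribution normalizes by length and rejects unknowns", {
  cl <- data.frame(chrom = c("chr1", "chr1", "chr1"))
  d <- chromosome_distribution(cl, c(chr1 = 2e6, chr2 = 1e6))
  expect_equal(d$density_per_mb[d$chrom == "chr1"], 1.5)
  expect_equal(d$density_per_mb[d$chrom == "chr2"], 0)
  expect_identical(d$n_clusters, c(3L, 0L))
  expect_error(chromosome_distribution(data.frame(chrom = "chrX"),
                                       c(chr1 = 1e6)), "chrX")
})

test_that("aggregate strand balance can be even while clusters are specific", {
  h <- rbind(uniform_hits("chr1", 10000, 13000, 40, "+", w = 5, seed = 8),
             uniform_hits("chr2", 10000, 13000, 40, "-", w = 5, seed = 9))
  cl <- detect_clusters(h)
  expect_identical(nrow(cl), 2L)
  bal <- global_strand_balance(cl, h)
  expect_equal(bal$plus_fraction, 0.5)
  st <- cluster_stats(cl[1, ], h)
  expect_true(st$plus_fraction %in% c(0, 1))
  ## a single cluster's aggregate equals its own split
  bal1 <- global_strand_balance(cl[1, ], h)
  expect_equal(bal1$plus_fraction, st$plus_fraction)
})

test_that("planted clusters are recovered with high reciprocal overlap", {
  sim <- small_sim()
  res <- sim_pipeline("small")
  ro <- reciprocal_overlap(sim$genome$truth$clusters, res$clusters)
  expect_identical(nrow(res$clusters), nrow(sim$genome$truth$clusters))
  expect_true(all(ro >= 0.9))
  ## within-cluster strand specificity of the planted mono clusters
  expect_true(all(res$clusters$directionality %in% c("mono-plus",
                                                     "mono-minus")))
})

test_that("cluster 5'U fractions recover the planted rate before the candidate gate", {
  sim <- small_sim()
  res <- sim_pipeline("small")
  ## align the pre-gate tag set so the 1U/10A selection cannot inflate U
  rem <- res$removed_srna$tags
  rem$tag_id <- sprintf("pre%06d", seq_len(nrow(rem)))
  hits <- align_tags(rem, sim$genome$genome)
  clusters <- detect_clusters(hits)
  for (i in seq_len(nrow(clusters))) {
    st <- cluster_stats(clusters[i, ], hits, rem)
    member <- hits$chrom == clusters$chrom[i] &
      hits$start < clusters$end[i] & hits$end > clusters$start[i]
    w <- hits$weight[member]
    n_eff <- sum(w)^2 / sum(w^2)      # Kish effective sample size
    expect_lt(abs(st$u1_fraction - 0.9),
              3 * sqrt(0.9 * 0.1 / n_eff) + 0.02)
  }
})
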