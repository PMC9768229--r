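adapter3 <- "TGGAATTCTCGGGTGCCAAGG"
adapter5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("low-quality filter applies a strict majority threshold", {
  seq30 <- strrep("ACGT", 8)
  seq30 <- substr(seq30, 1, 30)
  fail_q <- paste0(q_chr(5, 16), q_chr(30, 14))   # 16/30 > 0.5
  pass_q <- paste0(q_chr(5, 15), q_chr(30, 15))   # 15/30 is not > 0.5
  expect_false(filter_low_quality(seq30, fail_q))
  expect_true(filter_low_quality(seq30, pass_q))
  expect_error(filter_low_quality(seq30, q_chr(30, 29)), "widths differ")
})

test_that("N-content filter applies a strict 10% threshold", {
  base <- substr(strrep("ACGT", 8), 1, 26)
  expect_false(filter_n_content(paste0(base, "NNNN")))       # 4/30
  expect_true(filter_n_content(paste0(base, "NNN", "A")))    # 3/30
})

test_that("trimming recovers the insert and categorizes rejections", {
  insert29 <- paste0("T", substr(strrep("GCA", 10), 1, 28))
  res <- trim_and_gate(paste0(insert29, adapter3), adapter5, adapter3)
  expect_identical(res$category, "clean")
  expect_identical(nchar(res$insert), 29L)
  expect_identical(res$insert, insert29)

  ## no adapter anywhere: categorized, never trimmed twice
  res <- trim_and_gate(insert29, adapter5, adapter3)
  expect_identical(res$category, "adapter3p_null_or_insert_null")

  ## read that IS only adapter: empty insert
  res <- trim_and_gate(paste0(adapter3, "ACGTACGT"), adapter5, adapter3)
  expect_identical(res$category, "adapter3p_null_or_insert_null")

  ## 5' adapter contamination wins over everything downstream
  res <- trim_and_gate(paste0(adapter5, insert29, adapter3), adapter5,
                       adapter3)
  expect_identical(res$category, "adapter5p_contamination")

  ## homopolymer-dominated insert
  res <- trim_and_gate(paste0(strrep("A", 30), adapter3), adapter5, adapter3)
  expect_identical(res$category, "polyATGC")

  ## length gate boundaries: 23 rejected, 24 kept
  ins23 <- substr(insert29, 1, 23)
  ins24 <- substr(insert29, 1, 24)
  expect_identical(
    trim_and_gate(paste0(ins23, adapter3), adapter5, adapter3)$category,
    "length_filtered")
  expect_identical(
    trim_and_gate(paste0(ins24, adapter3), adapter5, adapter3)$category,
    "clean")

  ## truncated adapter at the read end still matches at >= 8 nt overlap
  res <- trim_and_gate(paste0(insert29, substr(adapter3, 1, 9)), adapter5,
                       adapter3)
  expect_identical(res$category, "clean")
  res <- trim_and_gate(paste0(insert29, substr(adapter3, 1, 7)), adapter5,
                       adapter3)
  expect_identical(res$category, "adapter3p_null_or_insert_null")

  expect_error(trim_and_gate("ACGT", "", adapter3), "non-empty")
})

test_that("an empty library yields an all-zero accounting row", {
  f <- tempfile(fileext = ".fastq")
  file.create(f)
  out <- run_preprocess(f, "empty")
  expect_identical(out$accounting$total_reads, 0L)
  expect_identical(out$accounting$clean_reads, 0L)
  expect_length(out$inserts, 0L)
})

test_that("a garbled FASTQ raises a parse error naming the file", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II", "not a record"), f)
  expect_error(run_preprocess(f, "bad"), "cannot parse FASTQ")
})

test_that("the accounting partitions every simulated read into its planted class", {
  sim <- small_sim()
  man <- sim$libs$manifest
  smp <- "A_1"
  pre <- run_preprocess(sim$libs$paths$fastq[[smp]], smp)
  acc <- pre$accounting
  m <- man[man$sample == smp, ]
  expect_identical(acc$total_reads, nrow(m))
  expect_identical(acc$n_gt10pct, sum(m$label == "qc_high_N"))
  expect_identical(acc$low_quality, sum(m$label == "qc_low_quality"))
  expect_identical(acc$adapter5p_contamination, sum(m$label == "qc_5p_adapter"))
  expect_identical(acc$adapter3p_null_or_insert_null,
                   sum(m$label == "qc_no_3p_adapter"))
  expect_identical(acc$polyATGC, sum(m$label == "qc_homopolymer"))
  expect_identical(acc$length_filtered, sum(m$label == "qc_bad_length"))
  ## conservation identity, exactly
  expect_identical(acc$total_reads,
                   acc$clean_reads + acc$n_gt10pct + acc$low_quality +
                     acc$adapter5p_contamination +
                     acc$adapter3p_null_or_insert_null + acc$polyATGC)
  expect_identical(acc$clean_reads, acc$length_pass + acc$length_filtered)
  ## every planted QC read fails exactly its own filter
  cat_by_read <- setNames(pre$categories,
                          sprintf("%s_r%07d", smp, seq_len(acc$total_reads)))
  qc_map <- c(qc_high_N = "n_gt10pct", qc_low_quality = "low_quality",
              qc_5p_adapter = "adapter5p_contamination",
              qc_no_3p_adapter = "adapter3p_null_or_insert_null",
              qc_homopolymer = "polyATGC", qc_bad_length = "length_filtered")
  for (lab in names(qc_map)) {
    ids <- m$read_id[m$label == lab]
    expect_true(all(cat_by_read[ids] == qc_map[[lab]]))
  }
})

test_that("permuting the input reads leaves the accounting unchanged", {
  sim <- small_sim()
  smp <- "B_1"
  orig <- sim$libs$paths$fastq[[smp]]
  lines <- readLines(orig)
  rec <- matrix(lines, nrow = 4)
  set.seed(99)
  perm <- file.path(tempdir(), "permuted.fastq")
  writeLines(as.vector(rec[, sample(ncol(rec))]), perm)
  a1 <- run_preprocess(orig, smp)$accounting
  a2 <- run_preprocess(perm, smp)$accounting
  expect_identical(a1[, -1], a2[, -1])
})

test_that("the accounting identity holds for published-scale count rows", {
  expect_identical(
    accounting_clean_reads(13270313, 615, 54247, 6166, 262996, 58340),
    12887949)
})
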