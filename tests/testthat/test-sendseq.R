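# Local alignment, paired-read orientation calls, filters, length profiles.

test_that("exact substring matches score match * length", {
  ref <- "GGGGGACGTACGTACGGGG"
  res <- local_align("ACGTACGTAC", ref)
  expect_equal(res$score, 20)
  expect_equal(res$ref_start, 6L)
  expect_equal(res$ref_end, 15L)
})

test_that("an internal mismatch scores 9 matches minus one mismatch", {
  res <- local_align("ACGTACGTAC", "GGGGGACGTTCGTACGGGG")
  expect_equal(res$score, 17)  # 9*2 - 1
})

test_that("U and T are interchangeable; invalid characters error", {
  expect_equal(local_align("ACGU", "ACGT")$score, 8)
  expect_equal(local_align("acgu", "ACGT")$score, 8)
  expect_error(local_align("ACGX", "ACGT"), "invalid")
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("scores equal an independent DP oracle on exhaustive small pairs", {
  alphabet <- c("A", "C")
  seqs <- unlist(lapply(1:5, function(L) {
    apply(expand.grid(rep(list(alphabet), L)), 1, paste, collapse = "")
  }))
  set.seed(77)
  pairs <- cbind(sample(seqs, 400, replace = TRUE),
                 sample(seqs, 400, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    got <- local_align(pairs[i, 1], pairs[i, 2])$score
    want <- r_local_align_score(pairs[i, 1], pairs[i, 2])
    expect_identical(got, want)
  }
})

test_that("gap scoring follows the open-covers-first-position convention", {
  # bridging a 2-base ref insertion: 6 matches (12) + open + extend = 6.5
  expect_equal(local_align("AAATTT", "CCAAAGGTTTCC")$score, 6.5)
  expect_equal(r_local_align_score("AAATTT", "CCAAAGGTTTCC"), 6.5)
  # a 4-base insertion: 8 matches (16) + open + 3 * extend = 9.5
  expect_equal(local_align("AAAATTTT", "CCAAAAGGGGTTTTCC")$score, 9.5)
  expect_equal(r_local_align_score("AAAATTTT", "CCAAAAGGGGTTTTCC"), 9.5)
})

test_that("prefix-extending an exact match adds the match score", {
  ref <- "GGACGTACGTACGTGG"
  s <- vapply(4:12, function(L)
    local_align(substr("ACGTACGTACGT", 1, L), ref)$score, numeric(1))
  expect_equal(diff(s), rep(2, 8))
})

test_that("error-free pairs classify to the correct orientation and ends", {
  set.seed(80)
  fw <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
              collapse = "")
  rv <- paste(sample(c("A", "C", "G", "T"), 140, replace = TRUE),
              collapse = "")
  tmpl <- template_spec(fw, rv)
  cr <- classify_pair(substr(fw, 1, 40), substr(fw, 21, 60), tmpl)
  expect_equal(cr$orientation, "forward")
  expect_equal(cr$five_prime, 1L)
  expect_equal(cr$three_prime, 60L)
  expect_length(cr$filters_failed, 0)

  cr2 <- classify_pair(substr(rv, 1, 40), substr(rv, 31, 70), tmpl)
  expect_equal(cr2$orientation, "reverse")
})

test_that("the end-separation filter is strictly greater-than", {
  set.seed(81)
  fw <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
              collapse = "")
  rv <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
              collapse = "")
  tmpl <- template_spec(fw, rv)
  # ends 1..16: separation 15, not > 15 -> fails
  cr <- classify_pair(substr(fw, 1, 16), substr(fw, 1, 16), tmpl)
  expect_true("short_separation" %in% cr$filters_failed)
  expect_equal(cr$orientation, "unmapped")
  # ends 1..17: separation 16 -> passes
  cr2 <- classify_pair(substr(fw, 1, 17), substr(fw, 1, 17), tmpl)
  expect_false("short_separation" %in% cr2$filters_failed)
  expect_equal(cr2$orientation, "forward")
})

test_that("the TSS window admits |5' end - TSS| up to half the window", {
  set.seed(82)
  fw <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
              collapse = "")
  rv <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
              collapse = "")
  tmpl <- template_spec(fw, rv, tss_window = 10)
  # 5' end 8 nt downstream of the TSS: outside the +/-5 window
  cr <- classify_pair(substr(fw, 9, 48), substr(fw, 41, 80), tmpl)
  expect_true("tss_window" %in% cr$filters_failed)
  expect_equal(cr$orientation, "unmapped")
  # 5' end at TSS + 5: inside
  cr2 <- classify_pair(substr(fw, 6, 45), substr(fw, 41, 80), tmpl)
  expect_false("tss_window" %in% cr2$filters_failed)
})

test_that("exact inter-orientation ties are ambiguous, never assigned", {
  seq <- paste(rep("ACGT", 20), collapse = "")
  tmpl <- template_spec(seq, seq)
  cr <- classify_pair(substr(seq, 1, 30), substr(seq, 31, 60), tmpl)
  expect_equal(cr$orientation, "unmapped")
  expect_true("ambiguous" %in% cr$filters_failed)
})

test_that("classification is deterministic and order-equivariant", {
  set.seed(83)
  fw <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  rv <- paste(sample(c("A", "C", "G", "T"), 180, replace = TRUE),
              collapse = "")
  tmpl <- template_spec(fw, rv)
  sim <- simulate_reads(tmpl, 20, end_model = list(type = "uniform",
                                                   min = 50, max = 150),
                        seed = 84)
  res <- classify_reads(sim$five_reads, sim$three_reads, tmpl)
  perm <- sample(20)
  res2 <- classify_reads(sim$five_reads[perm], sim$three_reads[perm], tmpl,
                         read_ids = res$read_id[perm])
  expect_equal(res2[order(res2$read_id), -1],
               res[order(res$read_id), -1], ignore_attr = TRUE)
})

test_that("length profiles report lengths, 3' histograms and the drop", {
  reads <- data.frame(
    read_id = sprintf("r%d", 1:4),
    orientation = c("forward", "forward", "forward", "unmapped"),
    five_prime = c(1, 1, 1, 1),
    three_prime = c(40, 40, 70, 10),
    score_forward = 0, score_reverse = 0, filters_failed = "")
  tmpl <- template_spec(paste(rep("ACGT", 30), collapse = ""),
                        "GGCCGGCCGGCC", hairpin_region = c(20, 40))
  lp <- length_profiles(reads, tmpl)
  expect_equal(sort(lp$lengths$forward), c(40, 40, 70))
  expect_equal(stats::median(lp$lengths$forward), 40)
  expect_equal(lp$n_mapped, 3L)
  # coverage inside the boundary (positions 36-40) is 3 reads; past it
  # (41-45) only the length-70 read remains -> drop ratio 3
  expect_equal(lp$drop_statistic, 3)
  expect_error(length_profiles(reads[4, ], tmpl), "no mapped")
})

test_that("piled 3' ends produce a large drop; uniform ends do not", {
  set.seed(85)
  fw <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  rv <- paste(sample(c("A", "C", "G", "T"), 180, replace = TRUE),
              collapse = "")
  tmpl <- template_spec(fw, rv, hairpin_region = c(80, 120))
  piled <- simulate_reads(tmpl, 60, seed = 86, forward_fraction = 1,
                          end_model = list(type = "hairpin", prob = 0.8,
                                           min = 60, max = 190))
  lp <- length_profiles(classify_reads(piled$five_reads, piled$three_reads,
                                       tmpl), tmpl)
  expect_gte(lp$drop_statistic, 4)

  unif <- simulate_reads(tmpl, 200, seed = 87, forward_fraction = 1,
                         end_model = list(type = "uniform", min = 60,
                                          max = 190))
  lp2 <- length_profiles(classify_reads(unif$five_reads, unif$three_reads,
                                        tmpl), tmpl)
  expect_lt(lp2$drop_statistic, 3)
  expect_gt(lp2$drop_statistic, 1 / 3)
})

test_that("length comparisons delegate to the Welch test symmetrically", {
  a <- c(30, 31, 29, 30, 32); b <- c(60, 59, 61, 58, 62)
  res <- compare_length_distributions(a, b)
  oracle <- welch_hand(a, b)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  swapped <- compare_length_distributions(b, a)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
  ident <- compare_length_distributions(a, a)
  expect_equal(ident$p, 1)
})

test_that("FASTA and FASTQ read files parse to named sequence vectors", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1 desc", "ACGT", "ACGT", ">r2", "GGCC"), fa)
  s <- read_seqs(fa)
  expect_equal(unname(s), c("ACGTACGT", "GGCC"))
  expect_equal(names(s), c("r1", "r2"))

  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "GGCC", "+", "IIII"), fq)
  s2 <- read_seqs(fq)
  expect_equal(unname(s2), c("ACGT", "GGCC"))
})
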