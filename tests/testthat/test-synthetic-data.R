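test_that("toy genome echoes lengths, is reproducible, and rejects bad input", {
  g <- build_toy_genome(c(a = 2000, b = 1500), seed = 3)
  expect_equal(unname(g$lengths), c(2000L, 1500L))
  expect_equal(unname(Biostrings::width(g$sequences)), c(2000L, 1500L))
  expect_true(all(strsplit(as.character(g$sequences[["a"]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  g2 <- build_toy_genome(c(a = 2000, b = 1500), seed = 3)
  expect_identical(as.character(g$sequences), as.character(g2$sequences))
  g3 <- build_toy_genome(c(a = 2000, b = 1500), seed = 4)
  expect_false(identical(as.character(g$sequences), as.character(g3$sequences)))
  expect_error(build_toy_genome(c(c = 0), 1), "1000")
  expect_error(build_toy_genome(c(2000), 1), "named")
})

test_that("canonical fixture plants the canonical reconstruction layout", {
  plan <- fixture_plan()
  fr <- plan$fragments
  expect_equal(nrow(fr), 19)
  expect_equal(sum(fr$chrom == "chr8t"), 15)
  expect_equal(sum(fr$chrom == "chr18t"), 4)
  expect_setequal(fr$id[fr$chrom == "chr18t"], c(6, 7, 14, 15))
  expect_equal(length(plan$derivatives$derA), 14)
  expect_equal(length(plan$derivatives$derB), 5)
  del <- plan$truth_deletions
  expect_equal(nrow(del), 5)
  expect_equal(sum(del$chrom == "chr8t"), 4)
  expect_equal(sum(del$chrom == "chr18t"), 1)
  expect_setequal((del$end - del$start)[del$chrom == "chr8t"] / 1000,
                  c(456, 1957, 520, 3529))
  expect_equal((del$end - del$start)[del$chrom == "chr18t"], 1528000)
  # 13 internal adjacencies in a 14-fragment path + 4 in a 5-fragment path
  expect_equal(nrow(plan$truth_junctions), 17)
  expect_gte(sum(fr$strand == "-"), 4)
  expect_gte(sum(fr$end - fr$start < 50000), 2)
  expect_error(chromothripsis_fixture(build_toy_genome(c(x = 2e6, y = 1e6), 1,
                                             with_sequence = FALSE)),
               "too small")
})

test_that("coverage conservation holds on the fixture and on random plans", {
  expect_true(check_conservation(fixture_plan()))
  for (s in 1:100) {
    p <- random_plan(seed = 1000 + s)
    expect_true(check_conservation(p))
    # every fragment in exactly one derivative
    expect_setequal(unlist(p$derivatives), p$fragments$id)
  }
})

test_that("random plans are reproducible from the seed", {
  p1 <- random_plan(seed = 42)
  p2 <- random_plan(seed = 42)
  expect_identical(p1$fragments, p2$fragments)
  expect_identical(p1$derivatives, p2$derivatives)
})

test_that("realized derivatives are oriented concatenations of fragments", {
  g <- build_toy_genome(c(a = 5000, b = 4000), seed = 11)
  # identity layout: the derivative equals the reference chromosome
  fr <- data.frame(id = 1:2, chrom = c("a", "b"), start = 0,
                   end = c(5000, 4000), strand = "+")
  plan <- rearrangement_plan(g, fr, list(d1 = 1, d2 = 2))
  rg <- realize_derivatives(plan)
  expect_equal(as.character(rg$derivatives$d1$sequence),
               as.character(g$sequences[["a"]]))
  # forward + reverse layout: length conserved, reverse piece complemented
  fr2 <- data.frame(id = 1:2, chrom = c("a", "b"), start = 0,
                    end = c(5000, 4000), strand = c("+", "-"))
  plan2 <- rearrangement_plan(g, fr2, list(d = 1:2))
  rg2 <- realize_derivatives(plan2)
  expect_equal(length(rg2$derivatives$d$sequence), 9000)
  expect_equal(as.character(Biostrings::subseq(rg2$derivatives$d$sequence, 5001, 9000)),
               as.character(Biostrings::reverseComplement(g$sequences[["b"]])))
  # overlapping fragments are rejected
  fr3 <- data.frame(id = 1:2, chrom = "a", start = c(0, 1000),
                    end = c(2000, 5000), strand = "+")
  expect_error(rearrangement_plan(g, fr3, list(d = 1:2)), "overlap")
})

test_that("fixture derivative lengths equal reference minus deletions", {
  plan <- fixture_plan()
  rg <- realize_derivatives(plan)
  total_der <- sum(vapply(rg$derivatives, `[[`, numeric(1), "length"))
  total_ref <- sum(as.numeric(plan$genome$lengths))
  total_del <- sum(plan$truth_deletions$end - plan$truth_deletions$start)
  expect_equal(total_der, total_ref - total_del)
})

test_that("simulated read volume tracks requested coverage", {
  g <- build_toy_genome(c(a = 1e6), seed = 7, with_sequence = FALSE)
  sim <- simulate_reads(g, sim_read_config(coverage = 20, length_mean = 15000,
                                           length_sd = 8000, seed = 7))
  expect_lt(abs(sum(sim$reads$length) - 20e6) / 20e6, 0.10)
})

test_that("error-free reads are exact substrings of their derivative", {
  g <- build_toy_genome(c(a = 30000, b = 20000), seed = 5)
  fr <- data.frame(id = 1:4, chrom = c("a", "b", "b", "a"),
                   start = c(0, 0, 8000, 12000),
                   end = c(12000, 8000, 20000, 30000),
                   strand = c("+", "-", "-", "+"))
  plan <- rearrangement_plan(g, fr, list(d1 = c(1, 2), d2 = c(3, 4)))
  rg <- realize_derivatives(plan)
  sim <- simulate_reads(rg, sim_read_config(coverage = 3, length_mean = 3000,
                                            length_sd = 1000, seed = 2))
  tmp <- tempfile(fileext = ".fastq")
  write_fastq(sim, tmp)
  fq <- readLines(tmp)
  seqs <- fq[seq(2, length(fq), by = 4)]
  ids <- sub("^@", "", fq[seq(1, length(fq), by = 4)])
  for (i in seq_along(ids)) {
    r <- sim$reads[sim$reads$read_id == ids[i], ]
    hit <- as.character(Biostrings::subseq(
      rg$derivatives[[r$derivative]]$sequence, r$der_start + 1, r$der_end))
    if (r$rc) hit <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(hit)))
    expect_identical(seqs[i], hit)
  }
})

test_that("reads spanning a junction carry multi-segment true chains", {
  sim <- fixture_sim()
  j <- extract_junctions(sim$chains, 1000)
  expect_gt(nrow(j), 0)
  nseg <- table(sim$chains$read_id)
  expect_true(all(nseg[unique(j$read_id)] >= 2))
})

test_that("read simulation is deterministic and empty input is rejected", {
  rg <- realize_derivatives(fixture_plan())
  s1 <- simulate_reads(rg, sim_read_config(coverage = 1, seed = 9))
  s2 <- simulate_reads(rg, sim_read_config(coverage = 1, seed = 9))
  expect_identical(s1$chains, s2$chains)
  expect_error(sim_read_config(coverage = 0), "coverage")
  expect_error(sim_read_config(coverage = 10, sub_rate = 0.5), "rates")
})

test_that("control cohort carries events at their allele frequencies", {
  g <- build_toy_genome(c(a = 1e6), seed = 1, with_sequence = FALSE)
  ev1 <- data.frame(type = "tandem_expansion", chrom = "a", pos = 5e5,
                    span = 2000, insert_len = NA, element = NA, freq = 1.0)
  coh <- simulate_control_cohort(g, control_cohort_spec(5, ev1, seed = 2))
  expect_true(all(coh$carriers[, 1]))
  tj <- event_junctions(ev1)
  for (ch in coh$chains) {
    cj <- extract_junctions(ch, 1000)
    expect_true(thripsis:::junctions_match_any(tj, cj, 200))
  }
  # p = 0.5, n = 33: carrier count within near-certain binomial bounds
  ev2 <- data.frame(type = "tandem_expansion", chrom = "a", pos = 2e5,
                    span = 3000, insert_len = NA, element = NA, freq = 0.5)
  coh2 <- simulate_control_cohort(g, control_cohort_spec(33, ev2, seed = 3))
  expect_gte(sum(coh2$carriers[, 1]), 5)
  expect_lte(sum(coh2$carriers[, 1]), 28)
  coh2b <- simulate_control_cohort(g, control_cohort_spec(33, ev2, seed = 3))
  expect_identical(coh2$carriers, coh2b$carriers)
  # empty pool: no rearranged reads at all
  coh3 <- simulate_control_cohort(g, control_cohort_spec(
    3, ev1[0, ], seed = 4))
  expect_true(all(vapply(coh3$chains, nrow, integer(1)) == 0))
  expect_error(control_cohort_spec(3, transform(ev1, freq = 1.5)), "frequencies")
  expect_error(control_cohort_spec(0, ev1), "n_controls")
})

test_that("truth tables serialize to plain-text formats", {
  plan <- fixture_plan()
  rg <- realize_derivatives(plan)
  dir <- tempfile()
  files <- write_truth(rg, dir)
  expect_true(all(file.exists(files)))
  del <- utils::read.table(file.path(dir, "deletions.bed"), sep = "\t")
  expect_equal(nrow(del), 5)
  frag <- utils::read.table(file.path(dir, "fragments.tsv"), header = TRUE,
                            sep = "\t")
  expect_equal(nrow(frag), 19)
})
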