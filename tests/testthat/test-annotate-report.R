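test_that("event classification follows the rule order", {
  plan <- fixture_plan()
  res <- fixture_result()
  lib <- element_library()
  # all fixture chromothripsis consensuses are linked members
  expect_true(all(res$categories == "chromothripsis_member"))
  # planted tandem duplication of 20 kb: multiplication (unit threshold 5 kb)
  cfg <- detect_config(match_tol = 500, min_reads = 1)
  g <- build_toy_genome(c(a = 1e6), seed = 2, with_sequence = FALSE)
  dup_ev <- data.frame(type = "tandem_multiplication", chrom = "a", pos = 4e5,
                       span = 20000, insert_len = NA, element = NA, freq = 1)
  gr <- group_reads(event_read_chains(dup_ev, g, n_reads = 3, seed = 3), cfg)
  cr <- consensus_rearrangement(gr$groups[[1]], cfg)
  expect_equal(classify_event(cr, lib), "tandem_multiplication")
  # 2.5 kb loop: repeat expansion
  exp_ev <- transform(dup_ev, type = "tandem_expansion", span = 2500)
  gr2 <- group_reads(event_read_chains(exp_ev, g, n_reads = 3, seed = 3), cfg)
  cr2 <- consensus_rearrangement(gr2$groups[[1]], cfg)
  expect_equal(classify_event(cr2, lib), "repeat_expansion")
  # planted insertion copying the toy L1 consensus at ~95% identity
  mei_ev <- data.frame(type = "mobile_element_insertion", chrom = "a",
                       pos = 6e5, span = NA, insert_len = 3000,
                       element = "L1", freq = 1)
  gr3 <- group_reads(event_read_chains(mei_ev, g, n_reads = 3, seed = 4,
                                       library = lib, divergence = 0.05), cfg)
  cr3 <- consensus_rearrangement(gr3$groups[[1]], cfg)
  expect_equal(classify_event(cr3, lib, id_threshold = 0.8),
               "mobile_element_insertion:L1")
  # an insert matching nothing falls through to other
  expect_equal(classify_event(cr3, NULL), "other")
})

test_that("element matcher requires identity and coverage", {
  lib <- element_library()
  hit <- mutate_sequence(substr(as.character(lib$L1), 1000, 3999), 0.05,
                         seed = 8)
  expect_equal(match_element(hit, lib, id_threshold = 0.8), "L1")
  set.seed(4242)  # distinct from every generator seed used in the package
  rng_seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                   collapse = "")
  expect_true(is.na(match_element(rng_seq, lib, id_threshold = 0.8)))
})

test_that("gene impact distinguishes deleted, disrupted and intact genes", {
  plan <- fixture_plan()
  res <- fixture_result()
  # toy RAD21/EXT1 inside the 3529 kb chr8 deletion; TRPS1 outside all
  # deletions and junctions (inside fragment 19)
  genes <- data.frame(chrom = "chr8t",
                      start = c(8.2e6, 9.1e6, 11.6e6),
                      end = c(8.35e6, 9.4e6, 11.8e6),
                      name = c("RAD21t", "EXT1t", "TRPS1t"))
  gi <- gene_impact(res$deletions, all_breakends(res$consensus),
                    genes)
  expect_equal(gi$status[gi$gene == "RAD21t"], "deleted")
  expect_equal(gi$status[gi$gene == "EXT1t"], "deleted")
  expect_equal(gi$status[gi$gene == "TRPS1t"], "intact")
  # a gene straddling a deletion boundary with a breakend inside: disrupted
  strad <- data.frame(chrom = "chr8t", start = 7.8e6, end = 8.0e6,
                      name = "STRADt")
  gi2 <- gene_impact(res$deletions, all_breakends(res$consensus),
                     strad)
  expect_equal(gi2$status, "disrupted")
  # no deletions, no junctions: everything intact
  gi3 <- gene_impact(res$deletions[0, ], data.frame(chrom = character(),
                                                    pos = numeric()), genes)
  expect_true(all(gi3$status == "intact"))
  # monotonicity: enlarging a deletion never rescues a gene
  big <- res$deletions
  big$start <- big$start - 1e5; big$end <- big$end + 1e5
  gi4 <- gene_impact(big, all_breakends(res$consensus), genes)
  expect_true(all(gi4$status[gi$status == "deleted"] == "deleted"))
})

ct_row <- function(sample, role, gene, ct_gene, ct_ref, ref = "GAPDH") {
  data.frame(sample = sample, role = role, gene = gene, reference_gene = ref,
             ct_gene = ct_gene, ct_reference = ct_ref,
             stringsAsFactors = FALSE)
}

test_that("delta-delta-Ct reproduces the closed form", {
  # patient dCt equal to control dCt: fold 1
  t1 <- rbind(ct_row("P", "patient", "G", 25, 20),
              ct_row("C1", "control", "G", 27, 22))
  expect_equal(delta_delta_ct(t1)$fold_change, 1.0)
  # ddCt = +1 halves expression
  t2 <- rbind(ct_row("P", "patient", "G", 26, 20),
              ct_row("C1", "control", "G", 25, 20))
  expect_equal(delta_delta_ct(t2)$fold_change, 0.5)
  # worked example: patient 26/20 vs control 24/20
  t3 <- rbind(ct_row("P", "patient", "G", 26, 20),
              ct_row("C1", "control", "G", 24, 20))
  r3 <- delta_delta_ct(t3)
  expect_equal(r3$ddct_mean, 2)
  expect_equal(r3$fold_change, 0.25)
  expect_error(delta_delta_ct(rbind(t3, ct_row("P2", "patient", "G", 26, NA))),
               "row 3")
})

test_that("delta-delta-Ct matches direct arithmetic on random tables", {
  set.seed(123)
  for (i in 1:25) {
    n_ctl <- sample(1:4, 1); n_rep <- sample(1:3, 1)
    tab <- rbind(
      do.call(rbind, lapply(seq_len(n_rep), function(k)
        ct_row(paste0("P", k), "patient", "G",
               runif(1, 18, 30), runif(1, 18, 30)))),
      do.call(rbind, lapply(seq_len(n_ctl), function(k)
        ct_row(paste0("C", k), "control", "G",
               runif(1, 18, 30), runif(1, 18, 30)))))
    res <- delta_delta_ct(tab)
    dct <- tab$ct_gene - tab$ct_reference
    pat <- dct[tab$role == "patient"]; ctl <- dct[tab$role == "control"]
    folds <- 2^(-(pat - mean(ctl)))
    expect_equal(res$fold_change, mean(folds))
    expect_equal(res$fold_sd, if (length(folds) > 1) sd(folds) else 0)
  }
})

test_that("the end-to-end report renders counts and survives reruns", {
  plan <- fixture_plan()
  res <- fixture_result()
  res$gene_impacts <- gene_impact(
    res$deletions, all_breakends(res$consensus),
    data.frame(chrom = "chr8t", start = 8.2e6, end = 8.35e6, name = "RAD21t"))
  d1 <- tempfile(); d2 <- tempfile()
  write_report(res, d1)
  write_report(res, d2)
  rep <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(length(rep$derivatives), 2)
  expect_equal(rep$n_fragments_total, 19)
  expect_equal(length(rep$deletions), 5)
  expect_equal(rep$category_counts$chromothripsis_member, 14)
  # byte-identical across reruns
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "report.md")),
                   readLines(file.path(d2, "report.md")))
  # empty inputs still render a valid report listing missing sections
  d3 <- tempfile()
  write_report(list(categories = character()), d3)
  rep3 <- jsonlite::read_json(file.path(d3, "report.json"))
  expect_true("derivatives" %in% unlist(rep3$missing_sections))
})
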