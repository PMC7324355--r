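# Shared builders for the test suite. The fixture pipeline run is computed
# once per session and cached.

seg_row <- function(read_id, read_start, read_end, chrom, ref_start, ref_end,
                    strand = "+", identity = 1, read_length = NULL,
                    gap_seq = NA_character_) {
  if (is.null(read_length)) read_length <- read_end
  data.frame(read_id = read_id, read_start = read_start, read_end = read_end,
             ref_chrom = chrom, ref_start = ref_start, ref_end = ref_end,
             strand = strand, identity = identity, read_length = read_length,
             gap_seq = gap_seq, stringsAsFactors = FALSE)
}

.cache <- new.env(parent = emptyenv())

fixture_plan <- function() {
  if (is.null(.cache$plan)) {
    genome <- fixture_genome(seed = 1)
    .cache$plan <- chromothripsis_fixture(genome)
  }
  .cache$plan
}

fixture_sim <- function() {
  if (is.null(.cache$sim)) {
    rg <- realize_derivatives(fixture_plan())
    .cache$sim <- simulate_reads(rg, sim_read_config(coverage = 20, seed = 1))
  }
  .cache$sim
}

fixture_result <- function() {
  if (is.null(.cache$result)) {
    plan <- fixture_plan()
    .cache$result <- run_pipeline(fixture_sim()$chains, plan$genome$lengths,
                                  config = detect_config("error_free"))
  }
  .cache$result
}

# A two-segment read crossing a long-gap junction at `pos` (left breakend)
# joined to `pos + 400000` (right breakend), jittered by `offset`.
make_junction_read <- function(id, pos, offset = 0) {
  rbind(seg_row(id, 0, 5000, "c", pos - 5000 + offset, pos + offset,
                read_length = 10000),
        seg_row(id, 5000, 10000, "c", pos + 400000 + offset,
                pos + 405000 + offset, read_length = 10000))
}

# Reverse-complement a chain table (as if the read were sequenced from the
# other strand): flips read coordinates, strands and segment order.
revcomp_chain <- function(ch) {
  rl <- ch$read_length
  rs <- ch$read_start
  ch$read_start <- rl - ch$read_end
  ch$read_end <- rl - rs
  ch$strand <- ifelse(ch$strand == "+", "-", "+")
  ch[order(ch$read_start), , drop = FALSE]
}

canonical_junction_keys <- function(j, digits = 0) {
  sort(paste(j$chrom_a, round(j$pos_a, digits), j$side_a,
             j$chrom_b, round(j$pos_b, digits), j$side_b))
}
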