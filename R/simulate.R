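#' Long-read simulation configuration
#'
#' Read lengths follow a log-normal model truncated to
#' `[500, min(length_max, sequence length)]`; start positions are uniform.
#' Error rates are per-base probabilities; the all-zero setting is the exact
#' (error-free) mode in which emitted chains are the true reference segment
#' chains of each read. With nonzero rates, chains additionally carry
#' breakpoint wobble emulating aligner endpoint uncertainty: the read cut
#' point at each junction shifts by a rounded normal deviate (standard
#' deviation `600 * total_error_rate` bases).
#'
#' @param coverage Fold coverage (> 0).
#' @param length_mean,length_sd Mean and SD of read length in bases.
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities, each in
#'   \[0, 0.2\].
#' @param length_max Upper truncation bound for read lengths; keeps group
#'   structure deterministic when fragments are larger than any read.
#' @param seed Integer seed.
#' @return Object of class `sim_read_config`.
#' @export
sim_read_config <- function(coverage, length_mean = 11451, length_sd = 6000,
                            sub_rate = 0, ins_rate = 0, del_rate = 0,
                            length_max = 1e5, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.2)) stop("error rates must be in [0, 0.2]")
  if (coverage <= 0) stop("coverage must be > 0")
  structure(list(coverage = coverage, length_mean = length_mean,
                 length_sd = length_sd, sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 length_max = length_max, seed = as.integer(seed)),
            class = "sim_read_config")
}

total_error_rate <- function(config)
  config$sub_rate + config$ins_rate + config$del_rate

empty_chains <- function() {
  data.frame(read_id = character(), read_start = numeric(),
             read_end = numeric(), ref_chrom = character(),
             ref_start = numeric(), ref_end = numeric(), strand = character(),
             identity = numeric(), read_length = numeric(),
             gap_seq = character(), stringsAsFactors = FALSE)
}

#' Simulate long reads from realized derivative chromosomes
#'
#' Draws reads from every derivative of a realized genome and returns their
#' true reference segment chains (the error-free alignment oracle). A read
#' crossing one or more junctions yields one aligned segment per fragment it
#' overlaps; reads are drawn from both strands of the derivative, with minus
#' strand reads reported in forward-read coordinates as an aligner would.
#'
#' @param rg A `realized_genome` (or a `toy_genome`, in which case each
#'   chromosome is treated as a single-fragment identity derivative).
#' @param config A `sim_read_config`.
#' @return List of class `simulated_reads`: `reads` (per-read table) and
#'   `chains` (segment table: `read_id`, `read_start`, `read_end`,
#'   `ref_chrom`, `ref_start`, `ref_end`, `strand`, `identity`,
#'   `read_length`), plus the `config`.
#' @export
simulate_reads <- function(rg, config) {
  if (inherits(rg, "toy_genome")) rg <- identity_realization(rg)
  stopifnot(inherits(rg, "realized_genome"), inherits(config, "sim_read_config"))
  if (!length(rg$derivatives)) stop("no sequences to simulate from")
  rng <- local_rng(config$seed)
  err <- total_error_rate(config)
  sdlog <- sqrt(log(1 + (config$length_sd / config$length_mean)^2))
  meanlog <- log(config$length_mean) - sdlog^2 / 2
  all_reads <- list(); all_chains <- list()
  for (d in rg$derivatives) {
    L <- d$length
    n <- ceiling(config$coverage * L / config$length_mean)
    lens <- round(rng$rlnorm(n, meanlog, sdlog))
    lens <- pmax(500, pmin(lens, config$length_max, L))
    starts <- floor(rng$runif(n, 0, L - lens + 1))
    flip <- rng$runif(n) < 0.5
    ids <- sprintf("%s_read_%06d", d$name, seq_len(n))
    reads <- data.frame(read_id = ids, derivative = d$name,
                        der_start = starts, der_end = starts + lens,
                        length = lens, rc = flip, stringsAsFactors = FALSE)
    ch <- chains_from_layout(reads, d$map, err, rng)
    all_reads[[d$name]] <- reads
    all_chains[[d$name]] <- ch
  }
  chains <- do.call(rbind, all_chains)
  rownames(chains) <- NULL
  structure(list(reads = do.call(rbind, all_reads), chains = chains,
                 config = config, rg = rg), class = "simulated_reads")
}

identity_realization <- function(genome) {
  n <- length(genome$lengths)
  fr <- new_fragments(seq_len(n), names(genome$lengths),
                      rep(0, n), as.numeric(genome$lengths), rep("+", n))
  ders <- as.list(seq_len(n))
  names(ders) <- paste0(names(genome$lengths), "_id")
  plan <- rearrangement_plan(genome, fr, ders)
  realize_derivatives(plan)
}

# Map derivative-coordinate reads onto oriented reference segments.
chains_from_layout <- function(reads, map, err, rng) {
  if (!nrow(reads)) return(empty_chains())
  i1 <- findInterval(reads$der_start, map$der_start)
  i2 <- findInterval(reads$der_end - 1, map$der_start)
  nseg <- i2 - i1 + 1
  ri <- rep(seq_len(nrow(reads)), nseg)
  row <- sequence(nseg) - 1 + i1[ri]
  a <- reads$der_start[ri]; b <- reads$der_end[ri]
  ds <- map$der_start[row]; de <- map$der_end[row]
  os <- pmax(a, ds); oe <- pmin(b, de)
  fwd <- map$strand[row] == "+"
  ref_start <- ifelse(fwd, map$start[row] + (os - ds), map$end[row] - (oe - ds))
  ref_end <- ifelse(fwd, map$start[row] + (oe - ds), map$end[row] - (os - ds))
  ch <- data.frame(read_id = reads$read_id[ri],
                   read_start = os - a, read_end = oe - a,
                   ref_chrom = map$chrom[row],
                   ref_start = ref_start, ref_end = ref_end,
                   strand = map$strand[row],
                   identity = 1 - err,
                   read_length = reads$length[ri],
                   gap_seq = NA_character_, stringsAsFactors = FALSE)
  # reads sequenced from the derivative minus strand: report in forward-read
  # coordinates (segment order reverses, strands flip)
  rc <- reads$rc[ri]
  rs <- ch$read_start
  ch$read_start[rc] <- ch$read_length[rc] - ch$read_end[rc]
  ch$read_end[rc] <- ch$read_length[rc] - rs[rc]
  ch$strand[rc] <- ifelse(ch$strand[rc] == "+", "-", "+")
  ch <- ch[order(ch$read_id, ch$read_start), ]
  if (err > 0) ch <- jitter_boundaries(ch, sd = 600 * err, rng = rng)
  rownames(ch) <- NULL
  ch
}

# Aligner breakpoint wobble: at every junction-internal boundary the cut
# point on the read is ambiguous, so it shifts by one rounded normal deviate
# shared by both flanking segments (read coordinates stay a partition of the
# read; reference coordinates follow each segment's strand). Segments keep
# at least 50 bases.
jitter_boundaries <- function(ch, sd, rng) {
  n <- nrow(ch)
  if (n < 2) return(ch)
  bnd <- which(ch$read_id[-n] == ch$read_id[-1])  # boundary i | i+1
  if (!length(bnd)) return(ch)
  lo <- -(pmax(0, floor((ch$read_end[bnd] - ch$read_start[bnd]) / 2) - 25))
  hi <- pmax(0, floor((ch$read_end[bnd + 1] - ch$read_start[bnd + 1]) / 2) - 25)
  d <- pmax(lo, pmin(hi, round(rng$rnorm(length(bnd), 0, sd))))
  lf <- ch$strand[bnd] == "+"
  rf <- ch$strand[bnd + 1] == "+"
  ch$read_end[bnd] <- ch$read_end[bnd] + d
  ch$ref_end[bnd][lf] <- ch$ref_end[bnd][lf] + d[lf]
  ch$ref_start[bnd][!lf] <- ch$ref_start[bnd][!lf] - d[!lf]
  ch$read_start[bnd + 1] <- ch$read_start[bnd + 1] + d
  ch$ref_start[bnd + 1][rf] <- ch$ref_start[bnd + 1][rf] + d[rf]
  ch$ref_end[bnd + 1][!rf] <- ch$ref_end[bnd + 1][!rf] - d[!rf]
  ch
}

#' Extract read sequences (with errors) and write FASTQ
#'
#' Requires the realized genome to carry sequences. Substitutions, insertions
#' and deletions are applied per base at the configured rates.
#'
#' @param sim A `simulated_reads` object.
#' @param path Output FASTQ path.
#' @return Invisibly, the number of reads written.
#' @export
write_fastq <- function(sim, path) {
  rg <- sim$rg
  if (is.null(rg$derivatives[[1]]$sequence))
    stop("realized genome has no sequences; rebuild with with_sequence = TRUE")
  rng <- local_rng(sim$config$seed + 7919L)
  reads <- sim$reads
  out <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    d <- rg$derivatives[[reads$derivative[i]]]
    s <- Biostrings::subseq(d$sequence, reads$der_start[i] + 1, reads$der_end[i])
    if (reads$rc[i]) s <- Biostrings::reverseComplement(s)
    out[i] <- apply_errors(as.character(s), sim$config, rng)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", out, "\n+\n",
                    vapply(nchar(out), function(k)
                      strrep("I", k), character(1))), con)
  invisible(nrow(reads))
}

apply_errors <- function(seq, config, rng) {
  err <- total_error_rate(config)
  if (err == 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  u <- rng$runif(n)
  sub <- u < config$sub_rate
  del <- u >= config$sub_rate & u < config$sub_rate + config$del_rate
  ins <- u >= config$sub_rate + config$del_rate &
    u < config$sub_rate + config$del_rate + config$ins_rate
  if (any(sub)) {
    alt <- rng$sample_bases(sum(sub) * 2)
    repl <- character(sum(sub)); j <- 1; k <- 1
    for (i in which(sub)) {
      while (alt[k] == bases[i]) k <- k + 1
      repl[j] <- alt[k]; j <- j + 1; k <- k + 1
      if (k > length(alt)) { alt <- c(alt, rng$sample_bases(16)); }
    }
    bases[sub] <- repl
  }
  if (any(ins)) bases[ins] <- paste0(bases[ins], rng$sample_bases(sum(ins)))
  if (any(del)) bases[del] <- ""
  paste(bases, collapse = "")
}

#' Mutate a sequence at a given substitution rate
#'
#' Used to plant diverged copies of mobile-element consensus sequences.
#'
#' @param seq Character DNA string.
#' @param rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Mutated character string.
#' @export
mutate_sequence <- function(seq, rate, seed = 1L) {
  rng <- local_rng(seed)
  cfg <- list(sub_rate = rate, ins_rate = 0, del_rate = 0)
  class(cfg) <- "sim_read_config"
  apply_errors(seq, cfg, rng)
}
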