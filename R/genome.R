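#' Build a toy reference genome
#'
#' Generates uniformly random chromosome sequences of the requested lengths.
#' The toy genome stands in for a real reference at desk scale: it carries no
#' repeat structure, so uniqueness of k-mers is likely but not guaranteed.
#' Regeneration with the same seed is byte-identical.
#'
#' @param chrom_lengths Named numeric vector or list: chromosome name ->
#'   length in bases. Each length must be >= 1000.
#' @param seed Integer seed; all randomness is local to this call.
#' @param with_sequence If `FALSE`, only lengths are stored (sufficient for
#'   coordinate-level simulation and reconstruction; sequences are needed only
#'   for FASTA/FASTQ output and base-level tests).
#' @return An object of class `toy_genome`: list with `lengths` (named
#'   integer), `sequences` (`Biostrings::DNAStringSet` or `NULL`) and `seed`.
#' @export
build_toy_genome <- function(chrom_lengths, seed = 1L, with_sequence = TRUE) {
  chrom_lengths <- unlist(chrom_lengths)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be named")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicate chromosome names")
  if (any(chrom_lengths < 1000))
    stop("chromosome lengths must be >= 1000 bases")
  lens <- as.integer(round(chrom_lengths))
  names(lens) <- names(chrom_lengths)
  seqs <- NULL
  if (with_sequence) {
    rng <- local_rng(seed)
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(lens), function(i) {
      paste(rng$sample_bases(lens[[i]]), collapse = "")
    }, character(1)))
    names(seqs) <- names(lens)
  }
  structure(list(lengths = lens, sequences = seqs, seed = as.integer(seed)),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$lengths), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bases",
      if (is.null(x$sequences)) "(lengths only)" else "", "\n")
  invisible(x)
}

# Local RNG: isolates all generator randomness from the global stream.
local_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample_bases = function(n) with_state(function()
      sample(c("A", "C", "G", "T"), n, replace = TRUE)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    rlnorm = function(n, meanlog, sdlog) with_state(function() stats::rlnorm(n, meanlog, sdlog)),
    sample_int = function(n, size, replace = FALSE) with_state(function()
      sample.int(n, size, replace = replace)),
    derive = function(k) local_rng((seed * 1009L + as.integer(k)) %% .Machine$integer.max)
  )
}
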