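#' Control cohort specification
#'
#' Describes a pool of polymorphic structural events (mobile-element
#' insertions, tandem expansions, tandem multiplications) segregating in the
#' control population. Each control individual carries each pooled event
#' independently with the event's allele frequency. Controls never carry
#' chromothripsis junctions: germline chromothripsis is a private event,
#' while these event classes are common polymorphisms that a patient-only
#' filter must learn to remove.
#'
#' @param n_controls Number of control individuals (>= 1).
#' @param events data.frame with columns `type` (one of
#'   `mobile_element_insertion`, `tandem_expansion`, `tandem_multiplication`),
#'   `chrom`, `pos` (insertion point, or repeat-unit start), `span` (repeat
#'   unit length; ignored for insertions), `insert_len` (inserted bases;
#'   insertions only), `element` (library element name or `NA`), `freq`
#'   (allele frequency in (0, 1]).
#' @param seed Integer seed.
#' @return Object of class `control_cohort_spec`.
#' @export
control_cohort_spec <- function(n_controls, events, seed = 1L) {
  if (n_controls < 1) stop("n_controls must be >= 1")
  ok_types <- c("mobile_element_insertion", "tandem_expansion",
                "tandem_multiplication")
  if (nrow(events)) {
    if (!all(events$type %in% ok_types)) stop("unknown event type")
    if (any(events$freq <= 0 | events$freq > 1))
      stop("event frequencies must be in (0, 1]")
  }
  structure(list(n_controls = as.integer(n_controls), events = events,
                 seed = as.integer(seed)), class = "control_cohort_spec")
}

#' Simulated read chains supporting polymorphic events
#'
#' Generates, for each event, `n_reads` read chains crossing the event's
#' junction with random flank lengths, in forward-read coordinates. Insertion
#' events carry the inserted sequence (a diverged copy of the library
#' element, when one is supplied) in the `gap_seq` column of the segment to
#' the right of the junction.
#'
#' @param events Event table as in [control_cohort_spec()].
#' @param genome A `toy_genome` (for coordinate bounds).
#' @param n_reads Reads per event.
#' @param seed Integer seed.
#' @param flank_range Range of flank lengths in bases.
#' @param library Optional [element_library()] for insertion sequences.
#' @param prefix Read-id prefix.
#' @param divergence Substitution rate applied to inserted element copies.
#' @return Chain data.frame in the same layout as `simulate_reads()` chains.
#' @export
event_read_chains <- function(events, genome, n_reads = 6, seed = 1L,
                              flank_range = c(2000, 8000), library = NULL,
                              prefix = "ev", divergence = 0.03) {
  rng <- local_rng(seed)
  out <- list()
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    for (r in seq_len(n_reads)) {
      f1 <- round(rng$runif(1, flank_range[1], flank_range[2]))
      f2 <- round(rng$runif(1, flank_range[1], flank_range[2]))
      id <- sprintf("%s%02d_r%02d", prefix, e, r)
      if (ev$type == "mobile_element_insertion") {
        gap <- ev$insert_len
        gseq <- NA_character_
        if (!is.null(library) && !is.na(ev$element)) {
          el <- as.character(library[[ev$element]])
          gseq <- mutate_sequence(substr(el, 1, min(nchar(el), gap)),
                                  divergence, seed = seed + e * 131 + r)
          gap <- nchar(gseq)
        }
        rl <- f1 + gap + f2
        seg <- data.frame(
          read_id = id, read_start = c(0, f1 + gap), read_end = c(f1, rl),
          ref_chrom = ev$chrom, ref_start = c(ev$pos - f1, ev$pos),
          ref_end = c(ev$pos, ev$pos + f2), strand = "+", identity = 1,
          read_length = rl, gap_seq = c(NA_character_, gseq),
          stringsAsFactors = FALSE)
      } else {
        # tandem duplication-type: read traverses the unit, steps back, and
        # traverses it again (duplication-loop junction geometry)
        u <- ev$span
        l1 <- f1 + u; l2 <- u + f2
        rl <- l1 + l2
        seg <- data.frame(
          read_id = id, read_start = c(0, l1), read_end = c(l1, rl),
          ref_chrom = ev$chrom, ref_start = c(ev$pos - f1, ev$pos),
          ref_end = c(ev$pos + u, ev$pos + u + f2), strand = "+",
          identity = 1, read_length = rl, gap_seq = NA_character_,
          stringsAsFactors = FALSE)
      }
      out[[length(out) + 1]] <- seg
    }
  }
  if (!length(out)) return(empty_chains())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Canonical truth junctions of an event table
#'
#' @param events Event table as in [control_cohort_spec()].
#' @return data.frame of canonical junctions (one per event).
#' @export
event_junctions <- function(events) {
  rows <- lapply(seq_len(nrow(events)), function(e) {
    ev <- events[e, ]
    if (ev$type == "mobile_element_insertion")
      canonical_junction(ev$chrom, ev$pos, "head", ev$chrom, ev$pos, "tail")
    else
      canonical_junction(ev$chrom, ev$pos + ev$span, "head", ev$chrom, ev$pos, "tail")
  })
  do.call(rbind, rows)
}

#' Simulate a control cohort
#'
#' Each control individual carries each pooled event independently with its
#' allele frequency; carriers receive supporting read chains. No control
#' carries any junction of a chromothripsis plan, by construction.
#'
#' @param genome A `toy_genome`.
#' @param spec A `control_cohort_spec`.
#' @param n_reads Supporting reads per carried event.
#' @param library Optional [element_library()].
#' @return List of class `control_cohort`: `chains` (list of chain
#'   data.frames, one per control) and `carriers` (logical matrix control x
#'   event).
#' @export
simulate_control_cohort <- function(genome, spec, n_reads = 6, library = NULL) {
  stopifnot(inherits(spec, "control_cohort_spec"))
  rng <- local_rng(spec$seed)
  nev <- nrow(spec$events)
  carriers <- matrix(FALSE, spec$n_controls, max(nev, 1))
  chains <- vector("list", spec$n_controls)
  for (i in seq_len(spec$n_controls)) {
    if (nev > 0) carriers[i, seq_len(nev)] <- rng$runif(nev) < spec$events$freq
    carried <- if (nev > 0) spec$events[carriers[i, seq_len(nev)], , drop = FALSE]
               else spec$events
    chains[[i]] <- if (nev > 0 && nrow(carried))
      event_read_chains(carried, genome, n_reads = n_reads,
                        seed = spec$seed + i * 37L, library = library,
                        prefix = sprintf("ctl%02d_", i))
    else empty_chains()
  }
  structure(list(chains = chains, carriers = carriers, spec = spec),
            class = "control_cohort")
}

#' Toy mobile-element consensus library
#'
#' Small random consensus sequences standing in for the retrotransposon
#' families that dominate polymorphic insertions (L1, Alu, SVA analogs).
#'
#' @param seed Integer seed.
#' @return Named `DNAStringSet`-like character list of class
#'   `element_library`.
#' @export
element_library <- function(seed = 99L) {
  rng <- local_rng(seed)
  lens <- c(L1 = 6000, Alu = 300, SVA = 1500)
  lib <- lapply(lens, function(n) paste(rng$sample_bases(n), collapse = ""))
  structure(lib, class = "element_library")
}
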