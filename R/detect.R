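#' Detection and grouping configuration
#'
#' Two named presets are shipped: `"error_free"` (`match_tol` 200) for exact
#' simulated chains and `"noisy"` (`match_tol` 1000) for chains with
#' alignment wobble. All thresholds are in bases.
#'
#' @param preset `"error_free"` or `"noisy"`.
#' @param min_seg_len Minimum aligned segment length on the read.
#' @param max_overlap Maximum tolerated read overlap between chained segments.
#' @param colinear_gap_tol Colinearity tolerance for junction extraction.
#' @param match_tol Breakend matching tolerance for grouping/filtering.
#' @param min_reads Minimum supporting reads per group.
#' @param gap_min Forward reference gap above which a same-strand junction is
#'   a `long_gap` event.
#' @param insert_min Read gap above which a junction with no reference
#'   advance is an `unaligned_insert`.
#' @return Object of class `detect_config`.
#' @export
detect_config <- function(preset = c("error_free", "noisy"),
                          min_seg_len = 200, max_overlap = 50,
                          colinear_gap_tol = 1000,
                          match_tol = NULL, min_reads = 3,
                          gap_min = 10000, insert_min = 300) {
  preset <- match.arg(preset)
  if (is.null(match_tol)) match_tol <- if (preset == "error_free") 200 else 1000
  structure(list(preset = preset, min_seg_len = min_seg_len,
                 max_overlap = max_overlap,
                 colinear_gap_tol = colinear_gap_tol, match_tol = match_tol,
                 min_reads = min_reads, gap_min = gap_min,
                 insert_min = insert_min), class = "detect_config")
}

# Signed reference advance along the read traversal for a same-chromosome,
# same-strand junction occurrence; NA otherwise.
junction_delta <- function(j) {
  ifelse(j$chrom_l == j$chrom_r & j$side_l != j$side_r,
         ifelse(j$side_l == "head", j$pos_r - j$pos_l, j$pos_l - j$pos_r),
         NA_real_)
}

# Geometry category of each junction occurrence.
junction_category <- function(j, config) {
  delta <- junction_delta(j)
  ifelse(j$chrom_l != j$chrom_r, "inter_chromosomal",
  ifelse(j$side_l == j$side_r, "inversion",
  ifelse(j$read_gap > config$insert_min & abs(delta) <= config$insert_min,
         "unaligned_insert",
  ifelse(delta < 0, "duplication_loop",
  ifelse(delta > config$gap_min, "long_gap", "other")))))
}

#' Classify a read chain as rearranged
#'
#' A chain is flagged as rearranged iff it yields at least one junction; its
#' category set derives from junction geometry: `inter_chromosomal`
#' (different chromosomes), `inversion` (strand switch on one chromosome),
#' `long_gap` (forward reference gap > `gap_min`), `duplication_loop`
#' (reference steps backward: the tandem multiplication signature), and
#' `unaligned_insert` (read gap > `insert_min` with no reference advance:
#' the insertion signature).
#'
#' @param chain Segment data.frame of one read.
#' @param config A [detect_config()].
#' @return List with `rearranged` (flag) and `categories` (character vector).
#' @export
is_rearranged <- function(chain, config = detect_config()) {
  j <- extract_junctions(chain, config$colinear_gap_tol)
  if (!nrow(j)) return(list(rearranged = FALSE, categories = character()))
  list(rearranged = TRUE,
       categories = sort(unique(junction_category(j, config))))
}

#' Group rearranged reads sharing junctions
#'
#' Two reads are linked iff they share at least one junction with both
#' breakends within `match_tol` and identical sides; groups are the connected
#' components of this relation. Components supported by fewer than
#' `min_reads` reads are discarded. Each group's signature is the
#' tolerance-merged union of its members' junctions, with lower-median
#' consensus coordinates.
#'
#' @param chains Segment data.frame of one sample (already chained), or a
#'   junction data.frame from [extract_junctions()].
#' @param config A [detect_config()].
#' @return Object of class `rearrangement_groups`: list of groups (each with
#'   `group_id`, `read_ids`, `support`, `signature`, `junctions`) plus the
#'   full junction table.
#' @export
group_reads <- function(chains, config = detect_config()) {
  j <- if (!is.null(chains$chrom_a)) chains
       else extract_junctions(chains, config$colinear_gap_tol)
  if (!nrow(j))
    return(structure(list(groups = list(), junctions = j), class = "rearrangement_groups"))
  cl <- cluster_junctions(j, config$match_tol)
  # connected components over reads via shared junction clusters
  read_f <- factor(j$read_id)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("r", as.integer(read_f)),
               to = paste0("c", cl)), directed = FALSE)
  comp <- igraph::components(g)$membership
  jcomp <- comp[paste0("c", cl)]
  groups <- list()
  for (cid in sort(unique(jcomp))) {
    idx <- which(jcomp == cid)
    rids <- unique(j$read_id[idx])
    if (length(rids) < config$min_reads) next
    sig <- cluster_consensus(j[idx, , drop = FALSE],
                             match(cl[idx], unique(cl[idx])))
    gid <- length(groups) + 1L
    groups[[gid]] <- list(group_id = gid, read_ids = rids,
                          support = length(rids), signature = sig,
                          junctions = j[idx, , drop = FALSE],
                          categories = sort(unique(
                            junction_category(j[idx, , drop = FALSE], config))))
  }
  structure(list(groups = groups, junctions = j),
            class = "rearrangement_groups")
}

#' @export
print.rearrangement_groups <- function(x, ...) {
  cat("rearrangement_groups:", length(x$groups), "group(s)\n")
  invisible(x)
}

#' Subtract rearrangement groups shared with a control cohort
#'
#' A group is removed if ANY control read has a junction matching ANY of the
#' group's signature junctions within `match_tol` (identical sides). Controls
#' are applied in order and the number of surviving groups after each control
#' is recorded (the filter trace); the final surviving set does not depend on
#' control order.
#'
#' @param groups A `rearrangement_groups` object.
#' @param controls A `control_cohort`, or a list of chain (or junction)
#'   data.frames, one per control.
#' @param config A [detect_config()].
#' @return List of class `filter_result`: `groups` (surviving
#'   `rearrangement_groups`), `trace` (data.frame `control`,
#'   `groups_remaining`, monotone non-increasing) and `removed_by`
#'   (first removing control per group id, NA if surviving).
#' @export
subtract_controls <- function(groups, controls, config = detect_config()) {
  if (inherits(controls, "control_cohort")) controls <- controls$chains
  alive <- rep(TRUE, length(groups$groups))
  removed_by <- rep(NA_integer_, length(groups$groups))
  trace <- data.frame(control = seq_along(controls),
                      groups_remaining = NA_integer_)
  for (ci in seq_along(controls)) {
    ctl <- controls[[ci]]
    cj <- if (!is.null(ctl$chrom_a)) ctl
          else extract_junctions(ctl, config$colinear_gap_tol)
    for (gi in which(alive)) {
      if (junctions_match_any(groups$groups[[gi]]$signature, cj,
                              config$match_tol)) {
        alive[gi] <- FALSE
        removed_by[gi] <- ci
      }
    }
    trace$groups_remaining[ci] <- sum(alive)
  }
  surv <- groups
  surv$groups <- groups$groups[alive]
  for (k in seq_along(surv$groups)) surv$groups[[k]]$group_id <- k
  structure(list(groups = surv, trace = trace, removed_by = removed_by),
            class = "filter_result")
}
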