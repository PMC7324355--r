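#' Deduplicate consensus rearrangements by traversal frame
#'
#' @param crs List of `consensus_rearrangement`.
#' @param tol Coordinate tolerance in bases.
#' @return Sub-list with one representative per frame-equivalence class.
#' @export
dedup_frames <- function(crs, tol = 0) {
  keep <- list()
  for (cr in crs) {
    dup <- any(vapply(keep, traversal_frames_equal, logical(1),
                      cr_b = cr, tol = tol))
    if (!dup) keep[[length(keep) + 1]] <- cr
  }
  keep
}

# The consensus events fed to the linking stage: connected components of the
# link-candidate graph that contain at least one inter-chromosomal event.
# Isolated local polymorphism-like events (insertions, expansions) stay
# unlinked; they would otherwise demand chromosome termini they cannot reach.
select_linkable <- function(crs, chrom_lengths) {
  if (!length(crs)) return(list())
  lg <- build_link_graph(crs, chrom_lengths)
  gids <- vapply(crs, `[[`, integer(1), "group_id")
  edges <- cbind(lg$ends$group_id[lg$candidates$end_a],
                 lg$ends$group_id[lg$candidates$end_b])
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(gids)))
  comp <- igraph::components(g)$membership
  inter <- vapply(crs, function(cr)
    any(cr$junctions$chrom_l != cr$junctions$chrom_r), logical(1))
  keep_comp <- unique(comp[as.character(gids[inter])])
  crs[comp[as.character(gids)] %in% keep_comp]
}

#' Run the full rearrangement pipeline on one sample
#'
#' Chains in, reconstruction out: junction extraction, read grouping,
#' control subtraction, per-group breakpoint consensus, frame deduplication,
#' derivative linking, colinear merging and deletion inference.
#'
#' @param chains Segment data.frame of the patient sample (true chains from
#'   [simulate_reads()] or parsed alignments passed through
#'   [chain_segments()]).
#' @param chrom_lengths Named chromosome lengths.
#' @param controls Optional `control_cohort` or list of control chain
#'   tables.
#' @param config A [detect_config()].
#' @param library Optional [element_library()] for event classification.
#' @param min_deletion Minimum deletion size in bases.
#' @return List of class `thripsis_result` with elements `groups`, `trace`,
#'   `consensus`, `unresolved`, `categories`, `reconstructions`,
#'   `deletions`, and `linked` (whether linking succeeded; on ambiguity or
#'   inconsistency the error message is kept in `link_error`).
#' @export
run_pipeline <- function(chains, chrom_lengths, controls = NULL,
                         config = detect_config(), library = NULL,
                         min_deletion = 10000) {
  chains <- chain_segments(chains, config$min_seg_len, config$max_overlap)
  junctions <- extract_junctions(chains, config$colinear_gap_tol)
  groups <- group_reads(junctions, config)
  trace <- NULL
  if (!is.null(controls)) {
    filt <- subtract_controls(groups, controls, config)
    groups <- filt$groups
    trace <- filt$trace
  }
  cons <- consensus_all(groups, config)
  crs <- dedup_frames(cons$consensus, tol = config$match_tol)
  recons <- NULL; link_error <- NULL
  linkable <- select_linkable(crs, chrom_lengths)
  if (length(linkable)) {
    recons <- tryCatch(link(linkable, chrom_lengths),
                       error = function(e) { link_error <<- conditionMessage(e); NULL })
  }
  linked_ids <- if (!is.null(recons)) unlist(lapply(recons, `[[`, "groups"))
                else integer(0)
  categories <- vapply(crs, function(cr)
    classify_event(cr, library = library,
                   linked = cr$group_id %in% linked_ids), character(1))
  deletions <- if (!is.null(recons))
    infer_deletions(recons, chrom_lengths, min_size = min_deletion)
  else NULL
  structure(list(groups = groups, trace = trace, consensus = crs,
                 unresolved = cons$unresolved, categories = categories,
                 reconstructions = recons, deletions = deletions,
                 linked = !is.null(recons), link_error = link_error),
            class = "thripsis_result")
}

#' @export
print.thripsis_result <- function(x, ...) {
  cat("thripsis_result:", length(x$groups$groups), "group(s),",
      length(x$consensus), "consensus event(s)\n")
  if (!is.null(x$reconstructions)) {
    for (r in x$reconstructions) print(r)
    cat(nrow(x$deletions), "deletion(s) inferred\n")
  } else if (!is.null(x$link_error)) cat("linking failed:", x$link_error, "\n")
  invisible(x)
}

#' Write the end-to-end report
#'
#' Renders whatever stages are present in a result: group counts by
#' category, the control filter trace, per-derivative fragment tables,
#' deletion calls, gene impact and expression — as one JSON document plus a
#' human-readable Markdown summary. Missing stages are listed, not invented.
#'
#' @param result A `thripsis_result` (or any list with a subset of its
#'   fields, plus optionally `gene_impacts` and `expression`).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sections <- list()
  missing <- character()
  if (!is.null(result$categories) && length(result$categories)) {
    tab <- table(sub(":.*", "", result$categories))
    sections$category_counts <- as.list(stats::setNames(as.integer(tab), names(tab)))
  } else sections$category_counts <- list()
  if (!is.null(result$trace)) sections$filter_trace <- result$trace
  else missing <- c(missing, "filter_trace")
  if (!is.null(result$reconstructions)) {
    sections$derivatives <- lapply(result$reconstructions, function(r)
      list(name = r$name, n_fragments = nrow(r$fragments),
           groups = r$groups, termini = r$termini, fragments = r$fragments))
    sections$n_fragments_total <- sum(vapply(result$reconstructions,
                                             function(r) nrow(r$fragments),
                                             integer(1)))
  } else missing <- c(missing, "derivatives")
  if (!is.null(result$deletions)) sections$deletions <- result$deletions
  else missing <- c(missing, "deletions")
  if (!is.null(result$gene_impacts)) sections$gene_impacts <- result$gene_impacts
  else missing <- c(missing, "gene_impacts")
  if (!is.null(result$expression)) sections$expression <- result$expression
  else missing <- c(missing, "expression")
  sections$missing_sections <- missing
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(sections, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  md <- c("# Rearrangement report", "")
  if (length(sections$category_counts)) {
    md <- c(md, "## Patient-only events by category", "")
    for (k in names(sections$category_counts))
      md <- c(md, sprintf("- %s: %d", k, sections$category_counts[[k]]))
    md <- c(md, "")
  }
  if (!is.null(result$reconstructions)) {
    md <- c(md, "## Derivative chromosomes", "")
    for (r in result$reconstructions) {
      md <- c(md, sprintf("### %s (%d fragments, %d groups)", r$name,
                          nrow(r$fragments), length(r$groups)), "")
      md <- c(md, "| rank | chrom | start | end | strand |",
              "|---|---|---|---|---|")
      md <- c(md, sprintf("| %d | %s | %d | %d | %s |", r$fragments$rank,
                          r$fragments$chrom, round(r$fragments$start),
                          round(r$fragments$end), r$fragments$strand), "")
    }
  }
  if (!is.null(result$deletions) && nrow(result$deletions)) {
    md <- c(md, "## Deletions", "")
    md <- c(md, sprintf("- %s:%d-%d (%.0f kb)", result$deletions$chrom,
                        round(result$deletions$start),
                        round(result$deletions$end),
                        result$deletions$length / 1000), "")
  }
  if (!is.null(result$gene_impacts)) {
    md <- c(md, "## Gene impact", "")
    md <- c(md, sprintf("- %s: %s %s", result$gene_impacts$gene,
                        result$gene_impacts$status,
                        result$gene_impacts$evidence), "")
  }
  if (length(missing))
    md <- c(md, "## Missing sections", "",
            paste("-", missing), "")
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(c(json_path, md_path))
}
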