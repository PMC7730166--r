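#' Build the gene x pool x annotator evidence table
#'
#' The consensus vote works on presence/absence: a gene is "reported" by an
#' annotator in a pool when that annotator assigned it at least one peak in
#' that pool. Duplicate assignments collapse to a single entry (set
#' semantics).
#'
#' @param annotations a list; each element is a list with `pool` (integer),
#'   `annotator` (string) and `records` (an annotation data frame as
#'   produced by the annotation functions). Alternatively the output of
#'   [annotate_all()] may be wrapped per pool via [evidence_from_pools()].
#' @param n_pools,n_tools declared design size, used for validation.
#' @return An evidence data frame with columns `gene`, `pool`, `annotator`,
#'   one row per distinct triple, with attributes `n_pools`, `n_tools`.
#' @export
build_evidence <- function(annotations, n_pools = 3L, n_tools = 3L) {
  rows <- lapply(annotations, function(a) {
    if (nrow(a$records) == 0) return(NULL)
    if (a$pool < 1 || a$pool > n_pools) stop("pool id out of range")
    data.frame(gene = a$records$gene, pool = as.integer(a$pool),
               annotator = as.character(a$annotator), stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev))
    ev <- data.frame(gene = character(), pool = integer(),
                     annotator = character(), stringsAsFactors = FALSE)
  ev <- unique(ev)
  ev <- ev[order(ev$gene, ev$pool, ev$annotator), , drop = FALSE]
  rownames(ev) <- NULL
  if (length(unique(ev$annotator)) > n_tools)
    stop("more annotators than declared n_tools")
  attr(ev, "n_pools") <- as.integer(n_pools)
  attr(ev, "n_tools") <- as.integer(n_tools)
  ev
}

#' @param pool_annotations list (one element per pool) of [annotate_all()]
#'   outputs; pool ids are the list positions.
#' @rdname build_evidence
#' @export
evidence_from_pools <- function(pool_annotations, n_tools = 3L) {
  ann <- list()
  for (pool in seq_along(pool_annotations)) {
    for (tool in names(pool_annotations[[pool]])) {
      ann[[length(ann) + 1]] <- list(
        pool = pool, annotator = tool,
        records = pool_annotations[[pool]][[tool]]
      )
    }
  }
  build_evidence(ann, n_pools = length(pool_annotations), n_tools = n_tools)
}

#' Select target genes by the tool-and-pool consensus rule
#'
#' The default (`quorum = "per_pool"`) reading of "at least `min_tools` of
#' the tools in at least `min_pools` of the pools" evaluates the tool
#' quorum within each pool: a pool supports a gene when at least
#' `min_tools` distinct annotators report the gene there, and the gene is
#' selected when at least `min_pools` pools support it. The laxer
#' `quorum = "global"` reading selects a gene reported by at least
#' `min_tools` distinct annotators overall and in at least `min_pools`
#' distinct pools overall.
#'
#' @param evidence evidence data frame from [build_evidence()].
#' @param min_tools,min_pools quorum sizes (defaults 2 of 3 / 2 of 3).
#' @param quorum `"per_pool"` (default, stricter) or `"global"`.
#' @return Sorted character vector of selected gene symbols.
#' @export
select_targets <- function(evidence, min_tools = 2L, min_pools = 2L,
                           quorum = c("per_pool", "global")) {
  quorum <- match.arg(quorum)
  n_pools <- attr(evidence, "n_pools") %||% max(evidence$pool, 1L)
  n_tools <- attr(evidence, "n_tools") %||%
    max(length(unique(evidence$annotator)), 1L)
  if (min_tools < 1 || min_tools > n_tools || min_pools < 1 || min_pools > n_pools)
    stop("quorum sizes out of range")
  if (nrow(evidence) == 0) return(character())
  selected <- vapply(split(evidence, evidence$gene), function(e) {
    if (quorum == "per_pool") {
      tools_per_pool <- vapply(split(e$annotator, e$pool),
                               function(a) length(unique(a)), integer(1))
      sum(tools_per_pool >= min_tools) >= min_pools
    } else {
      length(unique(e$annotator)) >= min_tools &&
        length(unique(e$pool)) >= min_pools
    }
  }, logical(1))
  sort(names(selected)[selected])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consensus summary: selected genes and distinct binding regions
#'
#' Applies [select_targets()] and groups the selected genes into distinct
#' binding regions by exact shared coordinate sets
#' ([collapse_shared_regions()]).
#'
#' @param evidence evidence data frame.
#' @param gene_peaks named list mapping every selected gene to its peak
#'   coordinate data frame.
#' @param ... passed to [select_targets()].
#' @return A `consensus_result` list: `selected_genes`, `region_groups`,
#'   `n_regions`, and a `counts` list (evidence genes, selected genes,
#'   regions).
#' @export
summarize_consensus <- function(evidence, gene_peaks, ...) {
  selected <- select_targets(evidence, ...)
  missing <- setdiff(selected, names(gene_peaks))
  if (length(missing) > 0)
    stop("selected genes missing from gene_peaks: ",
         paste(missing, collapse = ", "))
  groups <- collapse_shared_regions(gene_peaks[selected])
  structure(list(
    selected_genes = selected,
    region_groups = groups,
    n_regions = length(groups),
    counts = list(
      evidence_genes = length(unique(evidence$gene)),
      selected_genes = length(selected),
      regions = length(groups)
    )
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus target selection\n")
  cat(sprintf("  genes with any evidence : %d\n", x$counts$evidence_genes))
  cat(sprintf("  selected target genes   : %d\n", x$counts$selected_genes))
  cat(sprintf("  distinct binding regions: %d\n", x$n_regions))
  invisible(x)
}
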