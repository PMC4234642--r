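#' Annotation map: gene-to-term annotations plus the term DAG
#'
#' @param annotations Tibble with columns `gene_id`, `term_id` (direct
#'   annotations).
#' @param dag Tibble with columns `child`, `parent` (term DAG edges).
#' @param propagated Whether term sets are already closed under the parent
#'   relation.
#' @return List of class `annotation_map`.
#' @export
annotation_map <- function(annotations, dag, propagated = FALSE) {
  annotations <- tibble::as_tibble(annotations)
  dag <- tibble::as_tibble(dag)
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)),
            all(c("child", "parent") %in% names(dag)))
  structure(list(annotations = dplyr::distinct(annotations), dag = dag,
                 propagated = isTRUE(propagated)),
            class = "annotation_map")
}

dag_graph <- function(dag) {
  igraph::graph_from_data_frame(dag[, c("child", "parent")], directed = TRUE)
}

find_dag_cycle <- function(g) {
  # a directed cycle exists; name one by closing some edge with a path back
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) {
    p <- suppressWarnings(
      igraph::shortest_paths(g, from = el[i, 2], to = el[i, 1],
                             mode = "out")$vpath[[1]]
    )
    if (length(p)) return(c(names(p), el[i, 2]))
  }
  character(0)
}

#' Propagate annotations up the term DAG
#'
#' Replaces each gene's term set by its ancestral closure: a gene annotated
#' to a term is considered annotated to every ancestor of that term up to the
#' root. Terms absent from the DAG keep themselves only. The DAG must be
#' acyclic; a cycle is an error naming one offending cycle.
#'
#' @param map An [annotation_map()] (or a list with `annotations` and `dag`).
#' @return The map with closed annotation sets and `propagated = TRUE`.
#'   Propagating twice is a no-op.
#' @export
propagate_annotations <- function(map) {
  if (!inherits(map, "annotation_map")) {
    map <- annotation_map(map$annotations, map$dag,
                          propagated = isTRUE(map$propagated))
  }
  if (map$propagated) return(map)
  g <- dag_graph(map$dag)
  if (!igraph::is_dag(g)) {
    cyc <- find_dag_cycle(g)
    stop("term graph contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  terms <- unique(map$annotations$term_id)
  known <- terms[terms %in% igraph::V(g)$name]
  closure <- lapply(known, function(t) {
    names(igraph::subcomponent(g, t, mode = "out"))  # t plus all ancestors
  })
  names(closure) <- known
  expanded <- lapply(seq_len(nrow(map$annotations)), function(i) {
    t <- map$annotations$term_id[i]
    ts <- if (t %in% names(closure)) closure[[t]] else t
    tibble::tibble(gene_id = map$annotations$gene_id[i], term_id = ts)
  })
  annotation_map(dplyr::distinct(dplyr::bind_rows(expanded)), map$dag,
                 propagated = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' adjusted values are returned in the input order. Backed by
#' [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals), all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  p.adjust(pvals, method = "BH")
}

#' Ranked-list gene-set segmentation scan
#'
#' The enrichment test used for ranked differential-expression lists: for
#' each of `n_partitions` evenly spaced rank cuts, and for each term, a 2x2
#' Fisher exact test of (annotated vs not) x (above vs below the cut);
#' Benjamini-Hochberg adjustment is applied across all term-by-partition
#' tests jointly. This detects blocks of functionally related genes
#' concentrated among up- or down-regulated genes without fixing one
#' arbitrary significance cut-off.
#'
#' @param ranked Tibble with `gene_id` and a ranking statistic `stat`
#'   (most up-regulated first); rows are re-ordered by decreasing `stat`,
#'   ties broken by `gene_id`. Ids must be unique.
#' @param map An [annotation_map()]; propagated automatically if needed.
#'   Genes absent from the map count as unannotated. Terms annotating no gene
#'   in the list are skipped with a message.
#' @param n_partitions Number of rank cuts (>= 1), evenly spaced.
#' @param terms Optional subset of term ids to test (default all).
#' @param cuts Optional explicit rank cuts (each in `1..n-1`), overriding
#'   `n_partitions`.
#' @return Tibble of class data with one row per term x partition:
#'   `term_id`, `partition`, `cut_rank`, counts `n_ann_above`,
#'   `n_unann_above`, `n_ann_below`, `n_unann_below`, `pct_above`,
#'   `pct_below`, `direction` (`"up"`/`"down"`), `odds_ratio`, `p_value`
#'   (two-sided), `p_one_sided` (over-representation above the cut),
#'   `p_adj` (BH over all rows).
#' @export
partition_scan <- function(ranked, map, n_partitions = 30, terms = NULL,
                           cuts = NULL) {
  stopifnot(n_partitions >= 1)
  ranked <- tibble::as_tibble(ranked)
  stopifnot(all(c("gene_id", "stat") %in% names(ranked)))
  if (anyDuplicated(ranked$gene_id)) {
    stop("gene ids must be unique", call. = FALSE)
  }
  ranked <- ranked[order(-ranked$stat, ranked$gene_id), ]
  n <- nrow(ranked)
  if (!inherits(map, "annotation_map")) {
    map <- annotation_map(map$annotations, map$dag,
                          propagated = isTRUE(map$propagated))
  }
  map <- propagate_annotations(map)
  ann <- map$annotations[map$annotations$gene_id %in% ranked$gene_id, ]
  if (is.null(terms)) terms <- sort(unique(map$annotations$term_id))

  rank_of <- setNames(seq_len(n), ranked$gene_id)
  if (is.null(cuts)) {
    cuts <- unique(clamp(round(seq_len(n_partitions) * n / (n_partitions + 1)),
                         1, n - 1))
  } else {
    stopifnot(all(cuts >= 1 & cuts <= n - 1))
    cuts <- as.integer(cuts)
  }
  rows <- list()
  for (t in terms) {
    ranks_t <- sort(unname(rank_of[ann$gene_id[ann$term_id == t]]))
    k <- length(ranks_t)
    if (k == 0L) {
      message("term ", t, " annotates no gene in the list; skipped")
      next
    }
    for (pi in seq_along(cuts)) {
      cut <- cuts[pi]
      a <- sum(ranks_t <= cut)      # annotated above the cut
      b <- cut - a                  # unannotated above
      c_ <- k - a                   # annotated below
      d <- (n - cut) - c_           # unannotated below
      ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      p1 <- phyper(a - 1, k, n - k, cut, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term_id = t, partition = pi, cut_rank = cut,
        n_ann_above = a, n_unann_above = b,
        n_ann_below = c_, n_unann_below = d,
        pct_above = 100 * a / cut, pct_below = 100 * c_ / (n - cut),
        direction = if (a / cut >= c_ / (n - cut)) "up" else "down",
        odds_ratio = (a / max(b, 0.5)) / (c_ / max(d, 0.5)),
        p_value = min(ft$p.value, 1), p_one_sided = min(p1, 1)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$p_adj <- bh_adjust(out$p_value)
  out
}

#' Per-term summary of a partition scan
#'
#' For each term, the minimum BH-adjusted p over partitions and the partition
#' where it is attained (with its direction and raw p).
#'
#' @param results Output of [partition_scan()].
#' @return Tibble with one row per term, ordered by `min_p_adj`.
#' @export
scan_summary <- function(results) {
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(results), .data$term_id),
      min_p_adj = min(.data$p_adj),
      best_partition = .data$partition[which.min(.data$p_adj)],
      best_cut = .data$cut_rank[which.min(.data$p_adj)],
      direction = .data$direction[which.min(.data$p_adj)],
      p_value = .data$p_value[which.min(.data$p_adj)],
      .groups = "drop"
    ),
    .data$min_p_adj
  )
}

#' Read a ranked gene list from TSV
#' @param path TSV with columns `gene_id`, `stat`.
#' @return Tibble ordered by decreasing `stat` (ties by id).
#' @export
read_ranked_list <- function(path) {
  x <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("gene_id", "stat") %in% names(x)))
  x[order(-x$stat, x$gene_id), ]
}

#' Read an annotation map from TSV files
#' @param annotations_path TSV with columns `gene_id`, `term_id`.
#' @param dag_path TSV with columns `child`, `parent`.
#' @return An [annotation_map()].
#' @export
read_annotation_map <- function(annotations_path, dag_path) {
  annotation_map(
    tibble::as_tibble(read.delim(annotations_path, stringsAsFactors = FALSE)),
    tibble::as_tibble(read.delim(dag_path, stringsAsFactors = FALSE))
  )
}
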