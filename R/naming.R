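# Distance-based ortholog nomenclature: pairwise p-distances between family
# proteins and a reference species' family, closest-ortholog naming with
# similarity-ranked numeric suffixes, and a neighbor-joining tree used for
# cluster assignment.

#' Pairwise p-distance matrix from aligned sequences
#'
#' `d(i, j)` is the fraction of mismatching columns among columns where
#' neither row carries a gap (`-`).
#'
#' @param aligned Named character vector of equal-length aligned sequences,
#'   or a tibble with columns `id`, `sequence`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(aligned) {
  if (is.data.frame(aligned)) aligned <- setNames(aligned$sequence, aligned$id)
  abort_if(is.null(names(aligned)), "aligned sequences must be named")
  lens <- nchar(aligned)
  abort_if(length(unique(lens)) != 1, "aligned rows must have equal length")
  chars <- do.call(rbind, strsplit(toupper(aligned), ""))
  n <- length(aligned)
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ok <- chars[i, ] != "-" & chars[j, ] != "-"
    abort_if(!any(ok), paste("no comparable columns between",
                             names(aligned)[i], "and", names(aligned)[j]))
    d[i, j] <- d[j, i] <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
  }
  d
}

#' Name family members after their closest reference ortholog
#'
#' Each query is assigned to its minimum-distance reference; queries sharing
#' a reference receive numeric suffixes `.1, .2, ...` in ascending distance
#' order. Ties (equal distance to two references, or equal suffix-ordering
#' distances) are broken lexicographically and flagged.
#'
#' @param d Distance matrix containing all reference and query ids.
#' @param reference_ids,query_ids Disjoint id sets present in `d`.
#' @param stem_of Optional function mapping a reference id to a name stem
#'   (defaults to the reference id itself).
#' @return Tibble `query_id`, `assigned_name`, `reference_id`, `distance`,
#'   `tie` (logical).
#' @export
assign_names <- function(d, reference_ids, query_ids,
                         stem_of = identity) {
  abort_if(length(intersect(reference_ids, query_ids)) > 0,
           "reference and query ids must be disjoint")
  abort_if(!all(c(reference_ids, query_ids) %in% rownames(d)),
           "ids missing from the distance matrix")
  refs <- sort(reference_ids)
  rows <- lapply(sort(query_ids), function(q) {
    dq <- d[q, refs]
    best <- min(dq)
    hit <- refs[dq == best]
    tibble(query_id = q, reference_id = hit[1], distance = best,
           tie = length(hit) > 1)
  })
  out <- dplyr::bind_rows(rows) |>
    group_by(.data$reference_id) |>
    arrange(.data$distance, .data$query_id, .by_group = TRUE) |>
    mutate(
      tie = .data$tie | duplicated(.data$distance) |
        duplicated(.data$distance, fromLast = TRUE),
      assigned_name = paste0(stem_of(.data$reference_id[1]), ".",
                             row_number())
    ) |>
    ungroup() |>
    select("query_id", "assigned_name", "reference_id", "distance", "tie")
  out[match(sort(query_ids), out$query_id), ]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}) with negative branch lengths
#' clamped to zero.
#'
#' @param d Symmetric distance matrix (>= 3 taxa).
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  abort_if(nrow(d) < 3, "neighbor joining needs >= 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Cut a tree into clusters at its deepest splits
#'
#' Removes the `k - 1` longest internal edges of the tree and reports the
#' connected components of the remainder — the distance-based stand-in for
#' the major clades of a phylogeny.
#'
#' @param tree An `ape::phylo` tree.
#' @param k Number of clusters.
#' @return Tibble `taxon`, `cluster` (integer labels 1..k).
#' @export
tree_clusters <- function(tree, k = 2) {
  abort_if(k < 1, "k must be >= 1")
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  drop <- internal[order(tree$edge.length[internal],
                         decreasing = TRUE)][seq_len(min(k - 1, length(internal)))]
  g <- igraph::graph_from_edgelist(
    matrix(as.character(tree$edge[setdiff(seq_len(nrow(tree$edge)), drop), ]),
           ncol = 2), directed = FALSE)
  miss <- setdiff(as.character(seq_len(ntip + tree$Nnode)),
                  igraph::V(g)$name)
  g <- igraph::add_vertices(g, length(miss), name = miss)
  comp <- igraph::components(g)$membership
  tip_comp <- comp[as.character(seq_len(ntip))]
  tibble(taxon = tree$tip.label,
         cluster = as.integer(factor(tip_comp, levels = unique(tip_comp))))
}
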