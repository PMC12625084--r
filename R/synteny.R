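# Synteny stage: MCScanX-parameterized collinear block chaining from homolog
# hit tables and gene order, per-species-pair block censuses with
# orientation, family-filtered blocks, gene collinearity networks via
# connected components, and QTN proximity scans.

#' Default collinear-chaining parameters
#'
#' The MCScanX-style parameter set: e-value cutoff 1e-5, top 5 hits per
#' query, match size >= 5 genes, maximum 25 intervening genes per gap,
#' match score 50, gap penalty -1, overlap window 5.
#'
#' @return Named list of parameters.
#' @export
synteny_params <- function() {
  list(e_max = 1e-5, top_k = 5L, match_size = 5L, max_gaps = 25L,
       match_score = 50, gap_penalty = -1, overlap_window = 5L)
}

#' Per-chromosome gene rank index
#'
#' Ranks genes 0..n-1 along each chromosome by start coordinate.
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`).
#' @return Tibble `gene_id`, `chrom`, `rank`.
#' @export
gene_rank_index <- function(genes) {
  genes |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(rank = row_number() - 1L) |>
    ungroup() |>
    select("gene_id", "chrom", "rank")
}

# Maximum-score chain by dynamic programming over anchors sorted by rank_a.
# Transitions need rank gaps in both genomes in [1, max_gaps + 1] and a
# consistent direction in genome B. Returns the best chain's anchor indices
# (into `anc`), or NULL.
best_chain_dp <- function(anc, dir, p) {
  n <- nrow(anc)
  if (n == 0) return(NULL)
  ord <- order(anc$rank_a, anc$rank_b)
  ra <- anc$rank_a[ord]; rb <- anc$rank_b[ord]
  score <- rep(p$match_score, n)
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- dir * (rb[i] - rb[j])
      if (da < 1 || da > p$max_gaps + 1) next
      if (db < 1 || db > p$max_gaps + 1) next
      cand <- score[j] + p$match_score + p$gap_penalty * ((da - 1) + (db - 1))
      # score ties resolved toward the longer chain
      if (cand > score[i] || (cand == score[i] && len[j] + 1L > len[i])) {
        score[i] <- cand; len[i] <- len[j] + 1L; prev[i] <- j
      }
    }
  }
  end <- order(-score, -len)[1]
  chain <- integer(0)
  k <- end
  while (!is.na(k)) { chain <- c(k, chain); k <- prev[k] }
  list(idx = ord[chain], score = score[end])
}

#' Chain homolog hits into collinear blocks
#'
#' Per chromosome pair, anchors (hit pairs located by gene rank) are chained
#' by dynamic programming: a transition is allowed when the rank gaps in
#' both genomes lie in `[1, max_gaps + 1]` and the genome-B direction is
#' consistent; chain score is `match_score * size + gap_penalty *
#' (intervening genes)`. Maximal-score chains are emitted greedily (best
#' chain first, its anchors removed) while a chain of at least `match_size`
#' anchors with positive score remains; leftover anchors whose ranks fall
#' within `overlap_window` of an emitted block are absorbed by it instead of
#' spawning duplicate blocks. Orientation is the sign of the genome-B
#' direction.
#'
#' @param hits Hit tibble (`query`, `subject`, `evalue`, `bitscore`).
#' @param index_a,index_b Rank indexes from [gene_rank_index()] for the two
#'   genomes (`index_b` defaults to `index_a` for intra-genome analysis).
#' @param params Parameter list, see [synteny_params()].
#' @param species Length-2 labels for the genome pair.
#' @param collapse_tandem Collapse anchors that share a gene on one side
#'   while sitting within `overlap_window` ranks on the other (tandem
#'   arrays) down to the best-scoring anchor before chaining.
#' @return Block tibble: `block_id`, `species_a`, `species_b`, `chrom_a`,
#'   `chrom_b`, `orientation` ("plus"/"minus"), `size`, `score`, and
#'   list-column `anchors` (tibble `gene_a`, `gene_b`, `rank_a`, `rank_b`).
#' @export
chain_collinear <- function(hits, index_a, index_b = index_a,
                            params = synteny_params(),
                            species = c("A", "B"),
                            collapse_tandem = TRUE) {
  p <- utils::modifyList(synteny_params(), params)
  intra <- identical(species[1], species[2]) ||
    isTRUE(all.equal(index_a, index_b))
  unknown <- setdiff(unique(c(hits$query, hits$subject)),
                     unique(c(index_a$gene_id, index_b$gene_id)))
  abort_if(length(unknown) > 0,
           paste("gene(s) in hits absent from index:",
                 paste(head(unknown, 5), collapse = ", ")))
  h <- hits |>
    filter(.data$evalue <= p$e_max, .data$query != .data$subject) |>
    group_by(.data$query) |>
    arrange(.data$evalue, desc(.data$bitscore), .by_group = TRUE) |>
    dplyr::slice_head(n = p$top_k) |>
    ungroup()
  anc <- h |>
    inner_join(index_a, by = c(query = "gene_id")) |>
    rename(chrom_a = "chrom", rank_a = "rank") |>
    inner_join(index_b, by = c(subject = "gene_id")) |>
    rename(chrom_b = "chrom", rank_b = "rank") |>
    rename(gene_a = "query", gene_b = "subject")
  if (intra) {
    # canonical orientation so mirrored intra-genome hits collapse
    swap <- anc$chrom_a > anc$chrom_b |
      (anc$chrom_a == anc$chrom_b & anc$rank_a > anc$rank_b)
    tmp <- anc[swap, ]
    anc[swap, c("gene_a", "chrom_a", "rank_a")] <-
      tmp[, c("gene_b", "chrom_b", "rank_b")]
    anc[swap, c("gene_b", "chrom_b", "rank_b")] <-
      tmp[, c("gene_a", "chrom_a", "rank_a")]
  }
  anc <- distinct(anc, .data$gene_a, .data$gene_b, .keep_all = TRUE)
  if (collapse_tandem) {
    anc <- anc |>
      group_by(.data$gene_b, .data$chrom_a,
               grp_a = .data$rank_a %/% (p$overlap_window + 1L)) |>
      arrange(desc(.data$bitscore), .by_group = TRUE) |>
      dplyr::slice_head(n = 1L) |> ungroup() |>
      group_by(.data$gene_a, .data$chrom_b,
               grp_b = .data$rank_b %/% (p$overlap_window + 1L)) |>
      arrange(desc(.data$bitscore), .by_group = TRUE) |>
      dplyr::slice_head(n = 1L) |> ungroup() |>
      select(-"grp_a", -"grp_b")
  }

  blocks <- list()
  bid <- 0L
  pairs <- distinct(anc, .data$chrom_a, .data$chrom_b)
  for (pr in seq_len(nrow(pairs))) {
    pool <- anc |> filter(.data$chrom_a == pairs$chrom_a[pr],
                          .data$chrom_b == pairs$chrom_b[pr])
    repeat {
      best <- NULL
      for (dir in c(1L, -1L)) {
        ch <- best_chain_dp(pool, dir, p)
        if (is.null(ch)) next
        if (is.null(best) || ch$score > best$score ||
            (ch$score == best$score && dir == 1L && best$dir == -1L)) {
          best <- c(ch, dir = dir)
        }
      }
      if (is.null(best) || length(best$idx) < p$match_size ||
          best$score <= 0) break
      chain <- pool[best$idx, ]
      rest <- pool[-best$idx, ]
      # absorb leftover anchors overlapping the emitted block
      absorbed <- rep(FALSE, nrow(rest))
      if (nrow(rest) > 0) {
        for (i in seq_len(nrow(rest))) {
          absorbed[i] <- any(abs(rest$rank_a[i] - chain$rank_a) <=
                               p$overlap_window &
                             abs(rest$rank_b[i] - chain$rank_b) <=
                               p$overlap_window)
        }
      }
      bid <- bid + 1L
      blocks[[bid]] <- tibble(
        block_id = bid,
        species_a = species[1], species_b = species[2],
        chrom_a = pairs$chrom_a[pr], chrom_b = pairs$chrom_b[pr],
        orientation = if (best$dir == 1L) "plus" else "minus",
        size = nrow(chain), score = best$score,
        anchors = list(select(chain, "gene_a", "gene_b",
                              "rank_a", "rank_b")),
        absorbed = list(select(rest[absorbed, ], "gene_a", "gene_b",
                               "rank_a", "rank_b"))
      )
      pool <- rest[!absorbed, ]
      if (nrow(pool) == 0) break
    }
  }
  if (length(blocks) == 0) {
    return(tibble(block_id = integer(), species_a = character(),
                  species_b = character(), chrom_a = character(),
                  chrom_b = character(), orientation = character(),
                  size = integer(), score = numeric(),
                  anchors = list(), absorbed = list()))
  }
  dplyr::bind_rows(blocks)
}

# Exhaustive maximal-chain search over all valid chains; the in-test oracle
# for best_chain_dp on small instances.
best_chain_exhaustive <- function(anc, dir, p) {
  n <- nrow(anc)
  if (n == 0) return(NULL)
  ord <- order(anc$rank_a, anc$rank_b)
  ra <- anc$rank_a[ord]; rb <- anc$rank_b[ord]
  best <- list(score = -Inf, idx = integer(0))
  extend <- function(chain, score) {
    if (score > best$score ||
        (score == best$score && length(chain) > length(best$idx)))
      best <<- list(score = score, idx = ord[chain])
    last <- chain[length(chain)]
    for (i in seq_len(n)) {
      if (i <= last) next
      da <- ra[i] - ra[last]; db <- dir * (rb[i] - rb[last])
      if (da >= 1 && da <= p$max_gaps + 1 && db >= 1 && db <= p$max_gaps + 1)
        extend(c(chain, i),
               score + p$match_score + p$gap_penalty * ((da - 1) + (db - 1)))
    }
  }
  for (s in seq_len(n)) extend(s, p$match_score)
  best
}

#' Keep blocks containing at least one family gene
#'
#' @param blocks Block tibble from [chain_collinear()].
#' @param family_ids Family gene ids (either genome).
#' @return Subset of `blocks` with an `n_family` column added.
#' @export
filter_family_blocks <- function(blocks, family_ids) {
  if (nrow(blocks) == 0) return(mutate(blocks, n_family = integer(0)))
  nf <- vapply(blocks$anchors, function(a)
    length(intersect(family_ids, c(a$gene_a, a$gene_b))), 0L)
  blocks |> mutate(n_family = nf) |> filter(nf > 0)
}

#' Census of collinear blocks per species pair
#'
#' Counts per species pair with smallest/largest block size and the
#' plus/minus orientation split (plus + minus = total for every pair).
#'
#' @param blocks Block tibble.
#' @return Tibble `species_a`, `species_b`, `n_blocks`, `min_size`,
#'   `max_size`, `n_plus`, `n_minus`.
#' @export
csb_census <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(tibble(species_a = character(), species_b = character(),
                  n_blocks = integer(), min_size = integer(),
                  max_size = integer(), n_plus = integer(),
                  n_minus = integer()))
  }
  blocks |>
    group_by(.data$species_a, .data$species_b) |>
    summarise(n_blocks = n(), min_size = min(.data$size),
              max_size = max(.data$size),
              n_plus = sum(.data$orientation == "plus"),
              n_minus = sum(.data$orientation == "minus"),
              .groups = "drop")
}

#' Gene collinearity network of family genes
#'
#' Nodes are family genes appearing in the retained blocks; an edge joins
#' two family genes that form an anchor pair in at least one block (or,
#' with `co_membership = TRUE`, that co-occur in one block). Clusters are
#' connected components.
#'
#' @param blocks Family-filtered block tibble.
#' @param family_ids Family gene ids.
#' @param co_membership Also connect family genes that share a block
#'   without being direct anchor partners.
#' @return Object of class `gcn` with the igraph graph and a component
#'   table; see [tidy.gcn()].
#' @export
build_gcn <- function(blocks, family_ids, co_membership = FALSE) {
  edges <- list(); nodes <- character(0)
  for (i in seq_len(nrow(blocks))) {
    a <- blocks$anchors[[i]]
    fam_a <- intersect(c(a$gene_a, a$gene_b), family_ids)
    nodes <- union(nodes, fam_a)
    direct <- a |> filter(.data$gene_a %in% family_ids,
                          .data$gene_b %in% family_ids)
    if (nrow(direct) > 0) {
      edges[[length(edges) + 1L]] <- tibble(
        from = direct$gene_a, to = direct$gene_b,
        block_id = blocks$block_id[i])
    }
    if (co_membership && length(fam_a) > 1) {
      cmb <- t(utils::combn(sort(fam_a), 2))
      edges[[length(edges) + 1L]] <- tibble(
        from = cmb[, 1], to = cmb[, 2], block_id = blocks$block_id[i])
    }
  }
  e <- if (length(edges)) distinct(dplyr::bind_rows(edges),
                                   .data$from, .data$to) else
    tibble(from = character(), to = character())
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = sort(nodes))
  comp <- igraph::components(g)
  membership <- tibble(gene_id = names(comp$membership),
                       component = unname(comp$membership))
  structure(list(graph = g, membership = membership,
                 sizes = sort(as.integer(comp$csize), decreasing = TRUE)),
            class = "gcn")
}

#' @describeIn build_gcn Node-to-component membership table.
#' @param x A `gcn` object.
#' @param ... Unused.
#' @export
tidy.gcn <- function(x, ...) x$membership

#' @describeIn build_gcn One-row summary (component count and sizes).
#' @export
glance.gcn <- function(x, ...) {
  tibble(n_nodes = igraph::vcount(x$graph),
         n_edges = igraph::ecount(x$graph),
         n_components = length(x$sizes),
         sizes = paste(x$sizes, collapse = "/"))
}

#' @export
print.gcn <- function(x, ...) {
  cat("Gene collinearity network:", igraph::vcount(x$graph), "genes,",
      igraph::ecount(x$graph), "edges,", length(x$sizes),
      "component(s) of sizes", paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Write a gene collinearity network
#'
#' @param gcn A `gcn` object.
#' @param edges_path Edge-list TSV output path.
#' @param graphml_path Optional GraphML output path.
#' @export
write_gcn <- function(gcn, edges_path, graphml_path = NULL) {
  el <- igraph::as_data_frame(gcn$graph, what = "edges")
  readr::write_tsv(as_tibble(el), edges_path)
  if (!is.null(graphml_path))
    igraph::write_graph(gcn$graph, graphml_path, format = "graphml")
  invisible(edges_path)
}

#' Parse QTN locus identifiers
#'
#' Identifiers encode chromosome and 1-based position as
#' `<chromosome>_<position>` (e.g. `"Lu11_3283122"`).
#'
#' @param ids Character vector of locus ids.
#' @return Tibble `id`, `chrom`, `pos`.
#' @export
parse_qtn_ids <- function(ids) {
  ok <- grepl("^.+_[0-9]+$", ids)
  abort_if(any(!ok), paste("malformed locus id(s):",
                           paste(ids[!ok], collapse = ", ")))
  tibble(id = ids,
         chrom = sub("_[0-9]+$", "", ids),
         pos = as.integer(sub("^.*_", "", ids)))
}

#' Genes within a window of QTL/QTN loci
#'
#' Distance is 0 when the locus falls inside the gene span, otherwise the
#' gap to the nearest span boundary; pairs at distance `<= window_bp`
#' (inclusive) are reported.
#'
#' @param genes Gene-span tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param loci Locus tibble from [parse_qtn_ids()] (or a character vector of
#'   ids, parsed on the fly).
#' @param window_bp Reporting window (default 1 Mb).
#' @return Tibble `gene_id`, `locus_id`, `distance_bp`, `distance_mb`
#'   (2 decimals).
#' @export
qtn_proximity <- function(genes, loci, window_bp = 1e6) {
  if (is.character(loci)) loci <- parse_qtn_ids(loci)
  out <- tidyr::expand_grid(g = seq_len(nrow(genes)),
                            l = seq_len(nrow(loci))) |>
    mutate(gene_chrom = genes$chrom[.data$g],
           locus_chrom = loci$chrom[.data$l]) |>
    filter(.data$gene_chrom == .data$locus_chrom) |>
    mutate(
      gene_id = genes$gene_id[.data$g],
      locus_id = loci$id[.data$l],
      pos = loci$pos[.data$l],
      start = genes$start[.data$g], end = genes$end[.data$g],
      distance_bp = pmax(0, pmax(.data$start - .data$pos,
                                 .data$pos - .data$end))
    ) |>
    filter(.data$distance_bp <= window_bp) |>
    mutate(distance_mb = round(.data$distance_bp / 1e6, 2)) |>
    select("gene_id", "locus_id", "distance_bp", "distance_mb")
  out
}

#' Synteny dot plot of collinear blocks
#'
#' Anchors plotted in rank space, coloured by block orientation and
#' faceted by chromosome pair.
#'
#' @param blocks Block tibble from [chain_collinear()].
#' @return A ggplot object.
#' @export
plot_blocks <- function(blocks) {
  d <- blocks |>
    mutate(pair = paste(.data$chrom_a, .data$chrom_b, sep = " / ")) |>
    select("block_id", "pair", "orientation", "anchors") |>
    tidyr::unnest("anchors")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                                  colour = .data$orientation,
                                  group = .data$block_id)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = "gene rank (genome A)", y = "gene rank (genome B)") +
    ggplot2::theme_minimal()
}
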