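# Collinear block chaining, block censuses, gene collinearity networks,
# QTN proximity.

mk_index <- function(n, chrom = "c1", prefix = "g") {
  tibble::tibble(gene_id = paste0(prefix, seq_len(n)), chrom = chrom,
                 rank = seq_len(n) - 1L)
}

diag_hits <- function(ranks_a, ranks_b, pa = "a", pb = "b") {
  tibble::tibble(query = paste0(pa, ranks_a + 1L),
                 subject = paste0(pb, ranks_b + 1L),
                 evalue = 1e-20, bitscore = 200)
}

test_that("perfect diagonals chain into single oriented blocks", {
  ia <- mk_index(10, "cA", "a"); ib <- mk_index(10, "cB", "b")
  plus <- chain_collinear(diag_hits(0:4, 0:4), ia, ib,
                          species = c("A", "B"), collapse_tandem = FALSE)
  expect_identical(nrow(plus), 1L)
  expect_identical(plus$orientation, "plus")
  expect_identical(plus$size, 5L)
  expect_equal(plus$score, 250)

  minus <- chain_collinear(diag_hits(0:4, 4:0), ia, ib,
                           species = c("A", "B"), collapse_tandem = FALSE)
  expect_identical(minus$orientation, "minus")
  expect_identical(minus$size, 5L)
})

test_that("gaps above max_gaps break chains, at max_gaps they hold", {
  ia <- mk_index(100, "cA", "a"); ib <- mk_index(100, "cB", "b")
  # anchors 1..4 consecutive, 5th after a gap of g intervening genes
  with_gap <- function(g) {
    diag_hits(c(0:3, 4L + g), c(0:3, 4L + g))
  }
  ok <- chain_collinear(with_gap(25L), ia, ib, collapse_tandem = FALSE)
  expect_identical(ok$size, 5L)
  broken <- chain_collinear(with_gap(26L), ia, ib, collapse_tandem = FALSE)
  expect_identical(nrow(broken), 0L)
  # the oracle agrees on both sides of the boundary
  p <- synteny_params()
  anc25 <- tibble::tibble(rank_a = c(0:3, 29L), rank_b = c(0:3, 29L))
  anc26 <- tibble::tibble(rank_a = c(0:3, 30L), rank_b = c(0:3, 30L))
  expect_length(genefamr:::best_chain_exhaustive(anc25, 1L, p)$idx, 5L)
  expect_length(genefamr:::best_chain_exhaustive(anc26, 1L, p)$idx, 4L)
})

test_that("chaining equals exhaustive search on random small instances", {
  withr::local_seed(61)
  p <- utils::modifyList(synteny_params(), list(match_size = 2L))
  ia <- mk_index(50, "cA", "a"); ib <- mk_index(50, "cB", "b")
  for (i in 1:60) {
    anc <- random_anchor_instance()
    hits <- tibble::tibble(query = paste0("a", anc$rank_a + 1L),
                           subject = paste0("b", anc$rank_b + 1L),
                           evalue = 1e-20, bitscore = 100)
    blocks <- chain_collinear(hits, ia, ib, params = p,
                              collapse_tandem = FALSE)
    best_impl <- if (nrow(blocks)) max(blocks$score) else -Inf
    oracle <- max(
      genefamr:::best_chain_exhaustive(anc, 1L, p)$score,
      genefamr:::best_chain_exhaustive(anc, -1L, p)$score)
    # the top emitted block must carry the same score as the best chain
    # found by exhaustive enumeration (when it satisfies the size floor)
    best_len <- max(
      length(genefamr:::best_chain_exhaustive(anc, 1L, p)$idx),
      length(genefamr:::best_chain_exhaustive(anc, -1L, p)$idx))
    if (best_len >= p$match_size && oracle > 0) {
      expect_equal(best_impl, oracle, label = paste("instance", i))
    }
  }
})

test_that("reversing genome B's gene order swaps orientations only", {
  withr::local_seed(67)
  ia <- mk_index(30, "cA", "a"); ib <- mk_index(30, "cB", "b")
  hits <- dplyr::bind_rows(
    diag_hits(0:6, 10:16),
    diag_hits(15:19, 27:23))
  fwd <- chain_collinear(hits, ia, ib, collapse_tandem = FALSE)
  ib_rev <- dplyr::mutate(ib, rank = max(rank) - rank)
  rev <- chain_collinear(hits, ia, ib_rev, collapse_tandem = FALSE)
  expect_identical(nrow(fwd), nrow(rev))
  expect_setequal(fwd$size, rev$size)
  fwd_or <- fwd$orientation[order(fwd$size)]
  rev_or <- rev$orientation[order(rev$size)]
  expect_true(all(fwd_or != rev_or))
})

test_that("emitted blocks always satisfy the monotonicity invariant", {
  sim <- small_sim()
  idx <- gene_rank_index(sim$genes)
  blocks <- chain_collinear(sim$homolog_hits, idx)
  expect_gt(nrow(blocks), 0)
  for (i in seq_len(nrow(blocks))) {
    a <- blocks$anchors[[i]]
    expect_true(all(diff(a$rank_a) > 0))
    db <- diff(a$rank_b)
    if (blocks$orientation[i] == "plus") expect_true(all(db > 0))
    else expect_true(all(db < 0))
    expect_gte(blocks$size[i], synteny_params()$match_size)
  }
})

test_that("unknown genes in hits raise a named error", {
  ia <- mk_index(5, "cA", "a")
  hits <- tibble::tibble(query = "a1", subject = "mystery",
                         evalue = 1e-10, bitscore = 50)
  expect_error(chain_collinear(hits, ia, ia), "mystery")
})

test_that("planted duplicated segments are recovered as family blocks", {
  sim <- small_sim_clean()
  idx <- gene_rank_index(sim$genes)
  blocks <- chain_collinear(sim$homolog_hits, idx)
  fam_blocks <- filter_family_blocks(blocks, sim$truth$family_ids)
  expect_identical(nrow(fam_blocks), nrow(sim$truth$segments))
  expect_true(all(fam_blocks$n_family > 0))
  # a 10-gene segment with zero loss chains into one block of 10 anchors
  expect_true(all(fam_blocks$size == 10))
  expect_identical(nrow(filter_family_blocks(blocks, "no_such_gene")), 0L)
})

test_that("block census totals split into plus and minus counts", {
  expect_identical(nrow(csb_census(
    chain_collinear(tibble::tibble(query = character(),
                                   subject = character(),
                                   evalue = numeric(), bitscore = numeric()),
                    mk_index(5)))), 0L)
  blocks <- tibble::tibble(
    block_id = 1:5, species_a = "A", species_b = "B",
    chrom_a = "c1", chrom_b = "c2",
    orientation = c("plus", "plus", "plus", "minus", "minus"),
    size = c(5L, 6L, 7L, 5L, 9L), score = 250,
    anchors = replicate(5, tibble::tibble(), simplify = FALSE))
  cen <- csb_census(blocks)
  expect_identical(cen$n_blocks, 5L)
  expect_identical(cen$n_plus, 3L)
  expect_identical(cen$n_minus, 2L)
  expect_identical(cen$n_plus + cen$n_minus, cen$n_blocks)
  expect_identical(cen$min_size, 5L)
  expect_identical(cen$max_size, 9L)
})

test_that("collinearity networks cluster family genes by shared anchors", {
  mk_block <- function(id, pairs) {
    tibble::tibble(block_id = id, species_a = "A", species_b = "B",
                   chrom_a = "c1", chrom_b = "c2", orientation = "plus",
                   size = nrow(pairs), score = 100,
                   anchors = list(pairs))
  }
  fam <- c("f1", "f2", "f3", "f4")
  b1 <- mk_block(1L, tibble::tibble(gene_a = c("f1", "x1"),
                                    gene_b = c("f2", "x2"),
                                    rank_a = 1:2, rank_b = 1:2))
  b2 <- mk_block(2L, tibble::tibble(gene_a = "f2", gene_b = "f3",
                                    rank_a = 5L, rank_b = 5L))
  b3 <- mk_block(3L, tibble::tibble(gene_a = "f4", gene_b = "x9",
                                    rank_a = 9L, rank_b = 9L))
  # blocks sharing f2 merge into one component; f4 stays alone
  g <- build_gcn(dplyr::bind_rows(b1, b2, b3), fam)
  expect_identical(g$sizes, c(3L, 1L))
  expect_identical(sort(unique(tidy(g)$gene_id)), sort(fam))
  # disjoint groups give two components
  g2 <- build_gcn(dplyr::bind_rows(b1, b3), fam)
  expect_identical(length(g2$sizes), 2L)
  # component sizes invariant to block input order
  g3 <- build_gcn(dplyr::bind_rows(b3, b2, b1), fam)
  expect_identical(g$sizes, g3$sizes)
  expect_s3_class(glance(g), "tbl_df")
})

test_that("planted duplication groups appear as network components", {
  sim <- small_sim_clean()
  idx <- gene_rank_index(sim$genes)
  blocks <- chain_collinear(sim$homolog_hits, idx)
  fam_blocks <- filter_family_blocks(blocks, sim$truth$family_ids)
  # direct anchor pairs: one component per planted paralog pair
  direct <- build_gcn(fam_blocks, sim$truth$family_ids)
  expect_identical(length(direct$sizes), nrow(sim$truth$paralog_pairs))
  expect_true(all(direct$sizes == 2L))
  # co-membership: one component per duplicated segment
  merged <- build_gcn(fam_blocks, sim$truth$family_ids,
                      co_membership = TRUE)
  expect_identical(length(merged$sizes), nrow(sim$truth$segments))
})

test_that("QTN proximity is inclusive at the window and zero inside spans", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = c("Lu1", "Lu2"),
                          start = c(1000000L, 5000000L),
                          end = c(1005000L, 5002000L))
  loci <- parse_qtn_ids(c("Lu1_1002000", "Lu1_2005000", "Lu1_2005001",
                          "Lu2_4000000"))
  out <- qtn_proximity(genes, loci, window_bp = 1e6)
  inside <- out[out$locus_id == "Lu1_1002000", ]
  expect_equal(inside$distance_bp, 0)
  at_window <- out[out$locus_id == "Lu1_2005000", ]
  expect_equal(at_window$distance_bp, 1e6)
  expect_false("Lu1_2005001" %in% out$locus_id)
  expect_equal(out$distance_mb[out$locus_id == "Lu2_4000000"], 1.0)
  expect_error(parse_qtn_ids("badlocus"), "malformed")
})
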