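# Allele mining: filters, gene-relative coordinates, trait-specific
# classification, SNP/indel typing, consequence annotation, stability.

test_that("quality/depth filter is inclusive at its boundaries", {
  recs <- tibble::tibble(
    chrom = "c", pos = 1:5, ref = "A",
    qual = c(30, 29.9, 100, 50, NA),
    dp = c(5L, 100L, 4L, 10L, 8L),
    acc1 = "T"
  )
  expect_warning(kept <- filter_variants(recs), "missing QUAL/DP")
  expect_identical(kept$pos, c(1L, 4L))
})

test_that("gene-relative coordinates anchor at the start codon on both strands", {
  toy <- toy_minus_gene()
  gene <- toy$gene
  anchor <- genefamr:::cds_anchor(gene)   # genomic position of the ATG 'A'
  expect_identical(genomic_to_relative(anchor, gene), 1L)
  # one base 3' of the ATG on the genome (= upstream on a minus-strand gene)
  expect_identical(genomic_to_relative(anchor + 1L, gene), -1L)
  expect_identical(genomic_to_relative(anchor - 1L, gene), 2L)
  # plus-strand hand check
  g <- tibble::tibble(gene_id = "p", chrom = "c", strand = "+",
                      start = 101L, end = 200L,
                      exons = list(tibble::tibble(start = 101L, end = 200L)))
  expect_identical(genomic_to_relative(101L, g), 1L)
  expect_identical(genomic_to_relative(100L, g), -1L)
  expect_identical(genomic_to_relative(150L, g), 50L)
})

test_that("coordinate transform round-trips on random genes of both strands", {
  withr::local_seed(27)
  for (i in 1:1000) {
    g <- random_gene_model()
    len <- g$end - g$start + 1L
    rel <- sample(c(-(1:2000), 1:len), 5)
    expect_identical(genomic_to_relative(relative_to_genomic(rel, g), g),
                     rel)
  }
  g <- random_gene_model()
  expect_error(relative_to_genomic(0L, g), "position 0")
})

test_that("haplotype tables are windowed, ordered, and strand-corrected", {
  toy <- toy_minus_gene()
  gene <- toy$gene
  anchor <- genefamr:::cds_anchor(gene)
  recs <- tibble::tibble(
    chrom = "chrT",
    pos = c(anchor, anchor + 5L, anchor - 3L, anchor + 3000L, gene$start - 1L),
    ref = c("A", "G", "C", "T", "T"),
    qual = 50, dp = 10,
    e1 = c("A", "G", "C", "T", "T"), e2 = c("A", "G", "A", "T", "T"),
    i1 = c("C", "G", "C", "T", "T"), i2 = c("C", "G", "C", "T", "T")
  )
  ht <- build_haplotype_table(recs, gene, promoter_len = 2000,
                              group1 = c("e1", "e2"), group2 = c("i1", "i2"))
  # row beyond the promoter window and row past the gene 3' end are dropped:
  # anchor+3000 is upstream beyond 2000; gene$start - 1 is past the gene end
  # in coding orientation (relative position > gene length)
  expect_identical(ht$position, c(-5L, 1L, 4L))
  # alleles complemented into coding-strand orientation
  expect_identical(ht$reference[ht$position == 1L],
                   "T")  # genomic A on minus strand reads T... reference was "A"
  expect_error(build_haplotype_table(
    recs, dplyr::mutate(gene, exons = list(tibble::tibble())), 2000,
    c("e1", "e2"), c("i1", "i2")), "no CDS")
})

test_that("trait-specific rule requires within-group identity and between-group difference", {
  ht <- tibble::tibble(
    position = c(-10L, -5L, 1L, 5L, 9L),
    reference = c("A", "C", "G", "T", "A"),
    l1 = c("A", "C", "A", "-", "A"),
    l2 = c("A", "T", "A", "-", "A"),
    e1 = c("G", "C", "G", "T", "."),
    e2 = c("G", "C", "G", "T", "A")
  )
  out <- classify_trait_specific(ht, c("l1", "l2"), c("e1", "e2"))
  # row 1: uniform within both, different between -> flagged
  # row 2: group 1 not uniform -> no; row 3: flagged; row 4: deletion is a
  # comparable allele -> flagged; row 5: missing disqualifies
  expect_identical(out$trait_specific, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  # all identical -> never flagged
  same <- tibble::tibble(position = 1L, reference = "A",
                         l1 = "A", l2 = "A", e1 = "A", e2 = "A")
  expect_false(classify_trait_specific(same, c("l1", "l2"),
                                       c("e1", "e2"))$trait_specific)
  empty <- same[0, ]
  expect_identical(nrow(classify_trait_specific(empty, c("l1", "l2"),
                                                c("e1", "e2"))), 0L)
})

test_that("variant typing separates SNPs from indels", {
  ht <- tibble::tibble(
    position = 1:3, reference = c("A", "C", "-"),
    a1 = c("G", "-", "T"), a2 = c("G", "C", "-")
  )
  out <- classify_variant_type(ht)
  expect_identical(out$type, c("SNP", "indel", "indel"))
})

test_that("planted trait-specific variants are recovered exactly from the VCF", {
  cfg <- small_config(missing_rate = 0)
  sim <- small_sim()
  v <- simulate_variants(cfg, sim)
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "v.vcf")
  write_vcf(v$records, vcf, genome = sim$genome)
  recs <- read_vcf_records(vcf)
  gene <- sim$genes[sim$genes$gene_id == v$gene_id, ]
  kept <- filter_variants(recs)
  ht <- build_haplotype_table(kept, gene, cfg$promoter_length,
                              cfg$accession_groups[[1]],
                              cfg$accession_groups[[2]])
  out <- classify_trait_specific(ht)
  expect_identical(sort(out$position[out$trait_specific]),
                   sort(v$truth$trait_specific_relative))
})

test_that("VCF round-trip preserves alleles including indel expansion", {
  sim <- small_sim()
  chrom <- names(sim$genome)[1]
  base_at <- function(p) substr(sim$genome[[chrom]], p, p)
  recs <- tibble::tibble(
    chrom = chrom, pos = c(5000L, 5100L, 5101L),
    ref = c(base_at(5000), base_at(5100), base_at(5101)),
    qual = c(45, 60, 60), dp = c(12L, 9L, 9L),
    a1 = c("T", "-", "-"),
    a2 = c(base_at(5000), base_at(5100), base_at(5101))
  )
  recs$a1[1] <- setdiff(c("A", "C", "G", "T"), base_at(5000))[1]
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rt.vcf")
  write_vcf(recs, path, genome = sim$genome)
  back <- read_vcf_records(path)
  expect_identical(nrow(back), 3L)
  expect_identical(back$pos, recs$pos)
  expect_identical(back$a1, recs$a1)
  expect_identical(back$a2, recs$a2)
  expect_equal(back$qual, recs$qual, tolerance = 1e-6)
  expect_identical(back$dp, recs$dp)
})

test_that("consequence annotation distinguishes regions and effects", {
  toy <- toy_minus_gene()
  gene <- toy$gene
  # CDS starts with ATG GAT AAA ... (M D K ...); mutate codon 2 GAT
  ht <- tibble::tibble(
    position = c(-40L, 4L, 25L),
    genomic_pos = relative_to_genomic(c(-40L, 4L, 25L), gene),
    reference = c("C", "G", "A"),
    a1 = c("T", "A", "A"), a2 = c("C", "G", "A")
  )
  out <- annotate_consequence(ht, gene, group2 = "a1")
  expect_identical(out$region, c("promoter", "exon", "intron"))
  expect_identical(out$effect[1], "upstream")
  # GAT (Asp) -> AAT (Asn): nonsynonymous at protein position 2
  expect_identical(out$effect[2], "nonsynonymous")
  expect_identical(out$protein_change[2], "Asp2Asn")
  expect_identical(out$effect[3], "intronic")
  expect_true(is.na(out$protein_change[3]))
})

test_that("the canonical Gly-to-Val substitution is called as in the field", {
  # plus-strand gene whose CDS carries GGT at codon 782
  protein <- paste(c("M", rep("A", 780), "G", rep("L", 18)), collapse = "")
  cds <- paste0(paste(genefamr:::CODON_OF[strsplit(protein, "")[[1]]],
                      collapse = ""), "TAA")
  gene <- tibble::tibble(
    gene_id = "gv", chrom = "c", strand = "+",
    start = 1L, end = nchar(cds),
    exons = list(tibble::tibble(start = 1L, end = nchar(cds))),
    cds = cds
  )
  # codon 782 spans CDS 2344..2346 = GGT; position 2 G>T -> GTT (Val)
  pos <- 3L * 782L - 1L
  ht <- tibble::tibble(position = pos, genomic_pos = pos,
                       reference = "G", a1 = "T", a2 = "G")
  out <- annotate_consequence(ht, gene, group2 = "a1")
  expect_identical(out$effect, "nonsynonymous")
  expect_identical(out$protein_change, "Gly782Val")
  # third-position GGT -> GGA stays Gly
  ht2 <- tibble::tibble(position = pos + 1L, genomic_pos = pos + 1L,
                        reference = "T", a1 = "A", a2 = "T")
  expect_identical(annotate_consequence(ht2, gene, group2 = "a1")$effect,
                   "synonymous")
  # single-base exonic deletion is a frameshift
  ht3 <- tibble::tibble(position = pos, genomic_pos = pos,
                        reference = "G", a1 = "-", a2 = "G")
  expect_identical(annotate_consequence(ht3, gene, group2 = "a1")$effect,
                   "frameshift")
  expect_error(
    annotate_consequence(
      tibble::tibble(position = nchar(cds) + 10L,
                     genomic_pos = nchar(cds) + 10L,
                     reference = "G", a1 = "T", a2 = "G"),
      gene, group2 = "a1"),
    "beyond gene span")
})

test_that("stability report applies the neutral band around delta", {
  out <- stability_report(-708.44, -715.47)
  expect_equal(out$delta, -7.03)
  expect_identical(out$label, "Stabilizing")
  expect_identical(stability_report(-700, -700)$label, "Neutral")
  expect_identical(stability_report(-700, -690)$label, "Destabilizing")
  expect_equal(stability_report(-700, -690)$delta, 10)
  expect_error(stability_report(NA, -1), "finite")
})
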