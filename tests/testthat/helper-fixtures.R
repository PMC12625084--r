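# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small synthetic study: 3 chromosomes x 60 genes, 8-member family as 4
# pairs in 2 duplicated segments.
small_config <- function(seed = 42, ...) {
  args <- list(
    seed = seed,
    n_chromosomes = 3L, genes_per_chromosome = 60L,
    family_size = 8L, n_paralog_pairs = 4L,
    duplicated_segments = list(
      list(chrom = 1L, from = 11L, to = 20L, target_chrom = 2L,
           orientation = "+", loss_rate = 0),
      list(chrom = 2L, from = 31L, to = 40L, target_chrom = 3L,
           orientation = "-", loss_rate = 0)
    ),
    n_noise_hits = 50L
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# the same dimensions as a plain list, for pipeline_config(sim = ...)
small_sim_overrides <- function() {
  cfg <- small_config()
  cfg[c("n_chromosomes", "genes_per_chromosome", "family_size",
        "n_paralog_pairs", "duplicated_segments", "n_noise_hits")]
}

small_sim <- function() {
  fixture("small_sim", function() simulate_genome(small_config()))
}

# zero-noise variant: no random homolog hits, for exact planted-truth
# recovery assertions
small_sim_clean <- function() {
  fixture("small_sim_clean",
          function() simulate_genome(small_config(n_noise_hits = 0L)))
}

# Hand-built single-gene model on a toy chromosome; minus strand, two exons.
# Chromosome is 400 bp; gene occupies [201, 260] on the minus strand with
# exons [241,260] and [201,220] (coding order), i.e. a 40-bp CDS with a
# 20-bp intron.
toy_minus_gene <- function() {
  fixture("toy_minus_gene", function() {
    set.seed(99)
    protein <- "MDKLWHGTSCVYF"  # 13 aa -> 39 bp + TAA stop = 42 bp CDS
    cds <- paste0(paste(genefamr:::CODON_OF[strsplit(protein, "")[[1]]],
                        collapse = ""), "TAA")
    intron <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                    collapse = "")
    body_fwd <- paste0(substr(cds, 1, 21), intron, substr(cds, 22, 42))
    chrom <- paste0(
      paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""),
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(body_fwd))),
      paste(sample(c("A", "C", "G", "T"), 138, replace = TRUE), collapse = "")
    )
    gstart <- 201L; gend <- 200L + nchar(body_fwd)
    # coding-order exon 1 = genomic [gend-20, gend], exon 2 = [gstart, gstart+20]
    gene <- tibble::tibble(
      gene_id = "toy1", chrom = "chrT", strand = "-",
      start = gstart, end = gend,
      exons = list(tibble::tibble(start = c(gstart, gend - 20L),
                                  end = c(gstart + 20L, gend))),
      protein = protein, cds = cds, is_family = TRUE
    )
    list(gene = gene, genome = list(chrT = chrom), cds = cds)
  })
}

# random gene model generator for coordinate round-trip properties
random_gene_model <- function() {
  strand <- sample(c("+", "-"), 1)
  start <- sample(1000:5000, 1)
  len <- sample(100:500, 1)
  tibble::tibble(
    gene_id = "rg", chrom = "chrR", strand = strand,
    start = start, end = start + len - 1L,
    exons = list(tibble::tibble(start = start, end = start + len - 1L))
  )
}

accession_groups <- list(g1 = c("EC0115148", "EC0718827"),
                         g2 = c("IC0523807", "IC0525939"))

read_lutps6_haps <- function() {
  read_haplotype_table(
    system.file("extdata", "lutps6.1_haplotypes.tsv", package = "genefamr"),
    group1 = accession_groups$g1, group2 = accession_groups$g2)
}

read_lutps10_haps <- function() {
  read_haplotype_table(
    system.file("extdata", "lutps10.2_haplotypes.tsv", package = "genefamr"),
    group1 = accession_groups$g1, group2 = accession_groups$g2)
}

random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_promoter_tbl <- function(n, len, prefix = "g") {
  tibble::tibble(
    gene_id = paste0(prefix, seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")
  )
}
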