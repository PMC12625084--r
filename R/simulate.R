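# Synthetic-data generator: emits every input the pipeline consumes (genome
# FASTA + GFF3 + proteins, domain hits, VCF, TPM matrix, promoters + PWMs,
# homolog hit tables) with planted ground truth, so each downstream stage can
# be verified against known answers.

# One documented RNG stream per output type, derived from the single config
# seed, so adding an output never shifts an existing one.
.stream_offsets <- c(
  genome = 0L, variants = 101L, expression = 202L, motifs = 303L, pwms = 404L
)

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 30-residue synthase-like and 20-residue phosphatase-like signatures planted
# in every family protein; the domain-hit table keys off these.
SIG_SYNTHASE <- "WDYHLQMVPGLLREAFNSAKIGFFLHTPFP"
SIG_PHOSPHATASE <- "GDDRSDEDMFEVIGNSKGQI"
DOMAIN_SYNTHASE <- "TPS_synthase"
DOMAIN_PHOSPHATASE <- "TPS_phosphatase"

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic reverse-translation table (one codon per residue). Gly = GGT
# so that a position-2 G>T substitution yields GTT (Val).
CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

#' Simulation configuration
#'
#' Builds and validates the configuration that drives the synthetic-data
#' generator. Defaults emulate the study conditions of a linseed-scale TPS
#' family analysis scaled to a toy genome: ~1,000 genes on 5 chromosomes, an
#' 18-member family arranged as 9 paralog pairs planted inside 4 duplicated
#' segments, two phenotype groups of 2 resequenced accessions each, 3 planted
#' trait-specific variants, and one promoter motif enriched in family
#' promoters (insertion rate 0.8 vs 0.05 genome-wide).
#'
#' @param seed Integer seed; drives one documented RNG stream per output type.
#' @param n_chromosomes,genes_per_chromosome Toy genome dimensions.
#' @param family_size Number of family genes (sources plus duplicate copies).
#' @param n_paralog_pairs Number of (source, duplicate) family pairs; must
#'   satisfy `2 * n_paralog_pairs <= family_size`.
#' @param promoter_length Promoter window in bp upstream of the start codon.
#' @param gc_content GC fraction of background DNA.
#' @param planted_motifs List of `list(id, family_rate, background_rate)`;
#'   rates are per-promoter insertion probabilities.
#' @param accession_groups Named list of two disjoint character vectors of
#'   accession ids (group 1 = late-, group 2 = early-phenotype by convention).
#' @param n_trait_specific_variants,n_random_variants Planted variant counts.
#' @param gap_rate Fraction of random variants emitted as deletions.
#' @param missing_rate Per-call probability that a random-variant genotype is
#'   missing (".").
#' @param expression_modules List of `list(genes, noise_sd)`; genes in one
#'   module share a latent profile plus Gaussian noise of the stated sd.
#' @param duplicated_segments List of `list(chrom, from, to, target_chrom,
#'   orientation, loss_rate)` describing segmental duplications by gene index.
#' @param n_expression_filler Number of unrelated background genes in the
#'   expression matrix.
#' @param n_noise_hits Number of random (non-collinear) homolog hits added to
#'   the synteny hit table.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L,
                       genes_per_chromosome = 200L,
                       family_size = 18L,
                       n_paralog_pairs = 9L,
                       promoter_length = 2000L,
                       gc_content = 0.40,
                       planted_motifs = list(
                         list(id = "M001", family_rate = 0.8,
                              background_rate = 0.05)
                       ),
                       accession_groups = list(
                         late = c("EC0115148", "EC0718827"),
                         early = c("IC0523807", "IC0525939")
                       ),
                       n_trait_specific_variants = 3L,
                       n_random_variants = 50L,
                       gap_rate = 0.3,
                       missing_rate = 0,
                       expression_modules = NULL,
                       duplicated_segments = NULL,
                       n_expression_filler = 50L,
                       n_noise_hits = 200L) {
  if (is.null(duplicated_segments)) {
    duplicated_segments <- list(
      list(chrom = 1L, from = 21L, to = 30L, target_chrom = 2L,
           orientation = "+", loss_rate = 0),
      list(chrom = 2L, from = 61L, to = 70L, target_chrom = 3L,
           orientation = "-", loss_rate = 0),
      list(chrom = 3L, from = 101L, to = 110L, target_chrom = 4L,
           orientation = "+", loss_rate = 0),
      list(chrom = 4L, from = 141L, to = 150L, target_chrom = 5L,
           orientation = "-", loss_rate = 0)
    )
  }
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    family_size = as.integer(family_size),
    n_paralog_pairs = as.integer(n_paralog_pairs),
    promoter_length = as.integer(promoter_length),
    gc_content = gc_content,
    planted_motifs = planted_motifs,
    accession_groups = accession_groups,
    n_trait_specific_variants = as.integer(n_trait_specific_variants),
    n_random_variants = as.integer(n_random_variants),
    gap_rate = gap_rate,
    missing_rate = missing_rate,
    expression_modules = expression_modules,
    duplicated_segments = duplicated_segments,
    n_expression_filler = as.integer(n_expression_filler),
    n_noise_hits = as.integer(n_noise_hits)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$gc_content, cfg$gap_rate, cfg$missing_rate,
             unlist(lapply(cfg$planted_motifs,
                           function(m) c(m$family_rate, m$background_rate))),
             vapply(cfg$duplicated_segments, function(s) s$loss_rate, 0))
  abort_if(any(rates < 0 | rates > 1), "all rates must lie in [0, 1]")
  abort_if(cfg$family_size < 1, "family_size must be >= 1")
  abort_if(2L * cfg$n_paralog_pairs > cfg$family_size,
           "2 * n_paralog_pairs must not exceed family_size")
  abort_if(length(cfg$accession_groups) != 2L,
           "accession_groups must name exactly two groups")
  g1 <- cfg$accession_groups[[1]]; g2 <- cfg$accession_groups[[2]]
  abort_if(length(intersect(g1, g2)) > 0,
           "accession groups must be non-overlapping")
  # overlapping duplicated source segments on the same chromosome are invalid
  segs <- cfg$duplicated_segments
  if (length(segs) > 1) {
    for (i in seq_along(segs)) for (j in seq_along(segs)) {
      if (i >= j) next
      a <- segs[[i]]; b <- segs[[j]]
      if (a$chrom == b$chrom && a$from <= b$to && b$from <= a$to)
        stop("duplicated segments overlap on chromosome ", a$chrom,
             call. = FALSE)
    }
  }
  for (s in segs) {
    abort_if(s$to > cfg$genes_per_chromosome || s$from < 1,
             "duplicated segment outside gene index range")
    abort_if(s$chrom > cfg$n_chromosomes || s$target_chrom > cfg$n_chromosomes,
             "duplicated segment chromosome out of range")
  }
  invisible(cfg)
}

random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_protein <- function(n) {
  paste(c("M", sample(AA20, n - 1, replace = TRUE)), collapse = "")
}

reverse_translate <- function(protein) {
  paste0(paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

plant_signatures <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  p1 <- 101L
  p2 <- max(p1 + nchar(SIG_SYNTHASE) + 50L, n - 300L)
  aa[p1:(p1 + nchar(SIG_SYNTHASE) - 1L)] <- strsplit(SIG_SYNTHASE, "")[[1]]
  aa[p2:(p2 + nchar(SIG_PHOSPHATASE) - 1L)] <- strsplit(SIG_PHOSPHATASE, "")[[1]]
  list(protein = paste(aa, collapse = ""), synth_at = p1, phos_at = p2)
}

# Build one gene's genomic sequence and exon layout from its protein.
# Returns list(seq, exons_rel (matrix start,end 1-based within gene, coding
# strand ascending), cds_len).
build_gene_body <- function(protein, n_exons) {
  cds <- reverse_translate(protein)
  cds_len <- nchar(cds)
  if (n_exons == 1L) {
    return(list(seq = cds, exons_rel = cbind(1L, cds_len), cds_len = cds_len))
  }
  # cut the CDS at random interior points, insert introns between pieces
  cuts <- sort(sample(seq(10L, cds_len - 10L), n_exons - 1L))
  piece_bounds <- cbind(c(1L, cuts + 1L), c(cuts, cds_len))
  intron_len <- sample(60:150, n_exons - 1L, replace = TRUE)
  pos <- 0L
  seqs <- character(0)
  exons <- matrix(0L, nrow = n_exons, ncol = 2)
  for (i in seq_len(n_exons)) {
    piece <- substr(cds, piece_bounds[i, 1], piece_bounds[i, 2])
    exons[i, ] <- c(pos + 1L, pos + nchar(piece))
    seqs <- c(seqs, piece)
    pos <- pos + nchar(piece)
    if (i < n_exons) {
      seqs <- c(seqs, random_dna(intron_len[i]))
      pos <- pos + intron_len[i]
    }
  }
  list(seq = paste(seqs, collapse = ""), exons_rel = exons, cds_len = cds_len)
}

#' Simulate a toy genome with a planted gene family
#'
#' Emits a genome (chromosome sequences), gene models with exon/CDS structure
#' consistent with the sequence, protein sequences, a domain-hit table, a
#' homolog hit table covering the planted segmental duplications, and a truth
#' object recording everything that was planted.
#'
#' Family proteins carry two fixed signature peptides (a synthase-like
#' 30-mer and a phosphatase-like 20-mer) recorded as low-e-value hits in the
#' domain table; a handful of decoy proteins carry only one domain or only
#' high-e-value hits, so the census filter is exercised on both sides.
#' Duplicated segments copy gene order (reversed for minus orientation) onto
#' the target chromosome, dropping non-family genes at the stated loss rate.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_genome` with elements `genome` (named list of
#'   chromosome sequences), `genes` (gene-model tibble), `proteins` (tibble
#'   id/sequence), `domain_hits`, `homolog_hits`, and `truth`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + .stream_offsets[["genome"]], {
    nchr <- cfg$n_chromosomes
    gpc <- cfg$genes_per_chromosome

    # decide which (chrom, index) slots hold family source genes: spread the
    # paralog-pair sources across the duplicated segments, extra singletons
    # (family_size - 2*pairs) outside any segment on chromosome 1
    segs <- cfg$duplicated_segments
    n_src <- cfg$n_paralog_pairs
    seg_slots <- list()
    if (n_src > 0) {
      abort_if(length(segs) == 0, "paralog pairs require duplicated segments")
      alloc <- rep(seq_along(segs), length.out = n_src)
      for (k in seq_along(segs)) {
        s <- segs[[k]]
        take <- sum(alloc == k)
        abort_if(take > (s$to - s$from + 1L),
                 "more family sources than genes in a duplicated segment")
        idx <- s$from + round(seq(1, s$to - s$from, length.out = take))
        seg_slots[[k]] <- cbind(chrom = s$chrom, index = idx)
      }
    }
    family_slots <- do.call(rbind, seg_slots)
    n_single <- cfg$family_size - 2L * n_src
    if (n_single > 0) {
      in_seg <- unlist(lapply(segs, function(s)
        if (s$chrom == 1L) seq(s$from, s$to) else integer(0)))
      free <- setdiff(seq_len(gpc), in_seg)
      family_slots <- rbind(family_slots,
                            cbind(chrom = 1L, index = free[seq_len(n_single)]))
    }
    fam_key <- paste(family_slots[, 1], family_slots[, 2])

    # per-gene proteins and bodies
    genes <- list()
    chrom_seqs <- setNames(vector("list", nchr), paste0("chr", 1:nchr))
    for (ch in seq_len(nchr)) {
      pos <- 0L
      parts <- character(0)
      for (i in seq_len(gpc)) {
        gid <- sprintf("g%02d_%04d", ch, i)
        is_fam <- paste(ch, i) %in% fam_key
        prot_len <- if (is_fam) sample(820:970, 1) else sample(90:150, 1)
        prot <- random_protein(prot_len)
        sig <- NULL
        if (is_fam) {
          sig <- plant_signatures(prot)
          prot <- sig$protein
        }
        body <- build_gene_body(prot, sample(1:3, 1))
        strand <- sample(c("+", "-"), 1)
        spacer <- random_dna(sample(2100:2600, 1), cfg$gc_content)
        parts <- c(parts, spacer)
        pos <- pos + nchar(spacer)
        gstart <- pos + 1L
        glen <- nchar(body$seq)
        gseq <- if (strand == "+") body$seq else revcomp_chr(body$seq)
        parts <- c(parts, gseq)
        pos <- pos + glen
        gend <- pos
        # exon coordinates in genomic space (ascending)
        ex <- body$exons_rel
        if (strand == "+") {
          ex_g <- cbind(gstart + ex[, 1] - 1L, gstart + ex[, 2] - 1L)
        } else {
          ex_g <- cbind(gend - ex[, 2] + 1L, gend - ex[, 1] + 1L)
          ex_g <- ex_g[rev(seq_len(nrow(ex_g))), , drop = FALSE]
        }
        genes[[gid]] <- list(
          gene_id = gid, chrom = paste0("chr", ch), strand = strand,
          start = gstart, end = gend,
          exons = tibble(start = ex_g[, 1], end = ex_g[, 2]),
          protein = prot, cds = reverse_translate(prot),
          is_family = is_fam,
          sig = sig
        )
      }
      chrom_seqs[[ch]] <- paste(parts, collapse = "")
    }

    # segmental duplications: append copied genes to the target chromosome
    seg_truth <- list()
    homolog_hits <- list()
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      src_ids <- sprintf("g%02d_%04d", s$chrom, seq(s$from, s$to))
      keep <- vapply(src_ids, function(g) {
        genes[[g]]$is_family || runif(1) >= s$loss_rate
      }, TRUE)
      kept <- src_ids[keep]
      ordered <- if (s$orientation == "-") rev(kept) else kept
      tch <- s$target_chrom
      dup_ids <- character(0)
      for (g in ordered) {
        src <- genes[[g]]
        did <- paste0(g, "_d", k)
        dup_ids <- c(dup_ids, did)
        prot <- src$protein
        body <- build_gene_body(prot, nrow(src$exons))
        strand <- if (s$orientation == "-" && src$strand == "+") "-"
                  else if (s$orientation == "-" && src$strand == "-") "+"
                  else src$strand
        spacer <- random_dna(sample(2100:2600, 1), cfg$gc_content)
        pos <- nchar(chrom_seqs[[tch]])
        chrom_seqs[[tch]] <- paste0(chrom_seqs[[tch]], spacer)
        pos <- pos + nchar(spacer)
        gstart <- pos + 1L
        gseq <- if (strand == "+") body$seq else revcomp_chr(body$seq)
        chrom_seqs[[tch]] <- paste0(chrom_seqs[[tch]], gseq)
        gend <- pos + nchar(body$seq)
        ex <- body$exons_rel
        if (strand == "+") {
          ex_g <- cbind(gstart + ex[, 1] - 1L, gstart + ex[, 2] - 1L)
        } else {
          ex_g <- cbind(gend - ex[, 2] + 1L, gend - ex[, 1] + 1L)
          ex_g <- ex_g[rev(seq_len(nrow(ex_g))), , drop = FALSE]
        }
        genes[[did]] <- list(
          gene_id = did, chrom = paste0("chr", tch), strand = strand,
          start = gstart, end = gend,
          exons = tibble(start = ex_g[, 1], end = ex_g[, 2]),
          protein = prot, cds = reverse_translate(prot),
          is_family = src$is_family,
          sig = src$sig
        )
        homolog_hits[[length(homolog_hits) + 1L]] <- tibble(
          query = g, subject = did, evalue = 1e-50, bitscore = 500
        )
      }
      seg_truth[[k]] <- tibble(
        segment = k, src_chrom = paste0("chr", s$chrom),
        target_chrom = paste0("chr", tch), orientation = s$orientation,
        src_genes = list(kept), dup_genes = list(dup_ids)
      )
    }

    # trailing spacer so the last gene on each chromosome (minus strand)
    # still has a full upstream window
    for (ch in seq_len(nchr)) {
      chrom_seqs[[ch]] <- paste0(chrom_seqs[[ch]],
                                 random_dna(sample(2100:2600, 1),
                                            cfg$gc_content))
    }

    gene_tbl <- dplyr::bind_rows(lapply(genes, function(g) tibble(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      start = g$start, end = g$end, exons = list(g$exons),
      protein = g$protein, cds = g$cds, is_family = g$is_family
    )))

    proteins <- tibble(id = gene_tbl$gene_id, sequence = gene_tbl$protein)

    # domain hits: both domains at planted positions for family members;
    # decoys with one domain only, and both-domain hits at weak e-values
    fam_ids <- gene_tbl$gene_id[gene_tbl$is_family]
    dh <- list()
    for (g in fam_ids) {
      sig <- genes[[g]]$sig
      dh[[length(dh) + 1L]] <- tibble(
        protein_id = g,
        domain_id = c(DOMAIN_SYNTHASE, DOMAIN_PHOSPHATASE),
        evalue = c(1e-40, 1e-25),
        start = c(sig$synth_at, sig$phos_at),
        end = c(sig$synth_at + nchar(SIG_SYNTHASE) - 1L,
                sig$phos_at + nchar(SIG_PHOSPHATASE) - 1L)
      )
    }
    nonfam <- setdiff(gene_tbl$gene_id, fam_ids)
    one_dom <- sample(nonfam, min(5L, length(nonfam)))
    for (g in one_dom) {
      dh[[length(dh) + 1L]] <- tibble(
        protein_id = g, domain_id = DOMAIN_SYNTHASE, evalue = 1e-8,
        start = 5L, end = 5L + nchar(SIG_SYNTHASE) - 1L)
    }
    weak <- sample(setdiff(nonfam, one_dom), min(3L, length(nonfam) - 5L))
    for (g in weak) {
      dh[[length(dh) + 1L]] <- tibble(
        protein_id = g,
        domain_id = c(DOMAIN_SYNTHASE, DOMAIN_PHOSPHATASE),
        evalue = c(1e-3, 1e-2), start = c(5L, 40L),
        end = c(5L + nchar(SIG_SYNTHASE) - 1L, 40L + nchar(SIG_PHOSPHATASE) - 1L))
    }
    domain_hits <- dplyr::bind_rows(dh)

    # noise homolog hits between random unrelated genes (should not chain)
    if (cfg$n_noise_hits > 0) {
      qa <- sample(gene_tbl$gene_id, cfg$n_noise_hits, replace = TRUE)
      qb <- sample(gene_tbl$gene_id, cfg$n_noise_hits, replace = TRUE)
      ok <- qa != qb
      homolog_hits[[length(homolog_hits) + 1L]] <- tibble(
        query = qa[ok], subject = qb[ok],
        evalue = 10^runif(sum(ok), -6.5, -4),
        bitscore = runif(sum(ok), 60, 120)
      )
    }
    homolog_hits <- dplyr::bind_rows(homolog_hits)

    pairs <- dplyr::bind_rows(lapply(seg_truth, function(st) {
      src <- st$src_genes[[1]]; dup <- st$dup_genes[[1]]
      dup_of <- setNames(dup, if (st$orientation == "-") rev(src) else src)
      fam_src <- src[vapply(src, function(g) genes[[g]]$is_family, TRUE)]
      tibble(a = fam_src, b = unname(dup_of[fam_src]), segment = st$segment)
    }))

    truth <- list(
      family_ids = fam_ids,
      paralog_pairs = pairs,
      segments = dplyr::bind_rows(seg_truth)
    )
    structure(list(
      genome = chrom_seqs, genes = gene_tbl, proteins = proteins,
      domain_hits = domain_hits, homolog_hits = homolog_hits,
      truth = truth, cfg = cfg
    ), class = "sim_genome")
  })
}

#' Simulate grouped accession variants over a family gene
#'
#' Plants `n_trait_specific_variants` SNPs whose alleles are uniform within
#' each accession group and differ between groups, plus `n_random_variants`
#' variants constructed to violate that rule, inside the window spanning the
#' promoter and gene body of `gene_id`. QUAL and DP are drawn so both sides of
#' the QUAL >= 30 / DP >= 5 filter are exercised by random variants; planted
#' variants always pass.
#'
#' @param cfg A [sim_config()].
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param gene_id Target gene; defaults to the first planted family member.
#' @return A list of class `sim_variants` with `records` (variant tibble in
#'   the layout of [read_vcf_records()]) and `truth` (planted positions,
#'   genomic and gene-relative).
#' @export
simulate_variants <- function(cfg, sim, gene_id = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sim, "sim_genome"))
  g1 <- cfg$accession_groups[[1]]; g2 <- cfg$accession_groups[[2]]
  abort_if(length(g1) < 2 || length(g2) < 2, "need >= 2 accessions per group")
  accs <- c(g1, g2)
  if (is.null(gene_id)) gene_id <- sim$truth$family_ids[1]
  gene <- sim$genes[sim$genes$gene_id == gene_id, ]
  abort_if(nrow(gene) == 0, "unknown gene_id")
  chrom_seq <- sim$genome[[gene$chrom]]

  with_seed(cfg$seed + .stream_offsets[["variants"]], {
    # candidate genomic window: promoter + gene body on the coding strand
    if (gene$strand == "+") {
      lo <- max(1L, gene$start - cfg$promoter_length); hi <- gene$end
    } else {
      lo <- gene$start
      hi <- min(nchar(chrom_seq), gene$end + cfg$promoter_length)
    }
    n_ts <- cfg$n_trait_specific_variants
    n_rand <- cfg$n_random_variants
    pos_all <- sort(sample(seq(lo, hi), n_ts + n_rand))
    ts_pos <- sort(sample(pos_all, n_ts))
    rand_pos <- setdiff(pos_all, ts_pos)

    other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
    recs <- list()
    for (p in ts_pos) {
      ref <- substr(chrom_seq, p, p)
      alt <- other_base(ref)
      # group 1 keeps the reference allele, group 2 carries the alternate
      alleles <- setNames(c(rep(ref, length(g1)), rep(alt, length(g2))), accs)
      recs[[length(recs) + 1L]] <- tibble(
        chrom = gene$chrom, pos = p, ref = ref,
        qual = runif(1, 40, 90), dp = sample(8:40, 1),
        !!!as.list(alleles))
    }
    for (p in rand_pos) {
      ref <- substr(chrom_seq, p, p)
      is_del <- runif(1) < cfg$gap_rate
      alt <- if (is_del) "-" else other_base(ref)
      # violate the trait-specific rule: alternate allele in exactly one
      # accession, or in all accessions (both patterns fail the rule)
      pat <- sample(c("one", "all"), 1)
      alleles <- setNames(rep(ref, length(accs)), accs)
      if (pat == "one") alleles[sample(accs, 1)] <- alt else alleles[] <- alt
      if (cfg$missing_rate > 0) {
        miss <- runif(length(accs)) < cfg$missing_rate
        alleles[miss] <- "."
      }
      recs[[length(recs) + 1L]] <- tibble(
        chrom = gene$chrom, pos = p, ref = ref,
        qual = runif(1, 10, 90), dp = sample(1:40, 1),
        !!!as.list(alleles))
    }
    records <- dplyr::arrange(dplyr::bind_rows(recs), .data$pos)
    rel <- genomic_to_relative(ts_pos, gene)
    structure(list(
      records = records,
      gene_id = gene_id,
      truth = list(trait_specific_genomic = ts_pos,
                   trait_specific_relative = sort(rel)),
      cfg = cfg
    ), class = "sim_variants")
  })
}

#' Simulate a TPM expression matrix with planted correlation modules
#'
#' Samples are tissue x accession combinations. Genes inside one expression
#' module are generated as positive affine transforms of a shared latent
#' profile plus Gaussian noise at the module's `noise_sd`; with `noise_sd = 0`
#' within-module Pearson correlation is exactly 1. Remaining genes are
#' independent.
#'
#' @param cfg A [sim_config()]. If `cfg$expression_modules` is `NULL`, one
#'   module of two family-like genes plus a flowering-panel gene is planted.
#' @param gene_ids Genes to include (module genes are added automatically).
#' @param tissues Tissue labels; crossed with the accession ids of group 2.
#' @return A list of class `sim_expression` with `tpm` (tibble, first column
#'   `gene_id`), `samples` (metadata tibble), and `truth` (module list).
#' @export
simulate_expression <- function(cfg, gene_ids = NULL,
                                tissues = c("bud1", "bud2", "flower",
                                            "leaf", "stem")) {
  stopifnot(inherits(cfg, "sim_config"))
  accs <- cfg$accession_groups[[2]]
  samples <- tidyr::expand_grid(tissue = tissues, accession = accs)
  samples$sample_id <- paste(samples$tissue, samples$accession, sep = "_")
  ns <- nrow(samples)
  abort_if(ns < 3, "need >= 3 samples for correlation work")

  modules <- cfg$expression_modules
  if (is.null(modules)) {
    modules <- list(list(genes = c("fam_a", "fam_b", "FT"), noise_sd = 0))
  }
  mod_genes <- unique(unlist(lapply(modules, `[[`, "genes")))
  filler <- sprintf("bg_%03d", seq_len(cfg$n_expression_filler))
  all_genes <- unique(c(gene_ids, mod_genes, filler))

  with_seed(cfg$seed + .stream_offsets[["expression"]], {
    mat <- matrix(0, nrow = length(all_genes), ncol = ns,
                  dimnames = list(all_genes, samples$sample_id))
    for (g in all_genes) mat[g, ] <- runif(ns, 0, 50)
    for (m in modules) {
      latent <- runif(ns, 10, 100)
      for (g in m$genes) {
        slope <- runif(1, 0.5, 2)
        mat[g, ] <- pmax(0, slope * latent + rnorm(ns, 0, m$noise_sd))
      }
    }
    tpm <- dplyr::bind_cols(tibble(gene_id = all_genes), as_tibble(mat))
    structure(list(tpm = tpm, samples = samples,
                   truth = list(modules = modules), cfg = cfg),
              class = "sim_expression")
  })
}

#' Simulate a PWM collection
#'
#' Generates `n` informative position weight matrices (consensus base
#' probability `peak`, remainder split evenly), ids `M001...`, for use as the
#' motif collection scanned by the enrichment stage.
#'
#' @param cfg A [sim_config()] (only the seed is used).
#' @param n Number of motifs.
#' @param width Motif width in bp.
#' @param peak Probability mass on the consensus base at each position.
#' @return A named list of PWM objects (see [read_pwms()] for the layout).
#' @export
simulate_pwm_collection <- function(cfg, n = 20L, width = 8L, peak = 0.85) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + .stream_offsets[["pwms"]], {
    out <- list()
    for (i in seq_len(n)) {
      cons <- sample(1:4, width, replace = TRUE)
      mat <- matrix((1 - peak) / 3, nrow = 4, ncol = width,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
      for (k in seq_len(width)) mat[cons[k], k] <- peak
      id <- sprintf("M%03d", i)
      out[[id]] <- list(id = id, matrix = mat, pseudocount = 0)
    }
    out
  })
}

pwm_consensus <- function(pwm) {
  paste(rownames(pwm$matrix)[apply(pwm$matrix, 2, which.max)], collapse = "")
}

#' Plant motif instances into promoter sequences
#'
#' For every motif listed in `cfg$planted_motifs`, inserts one exact
#' consensus instance into each family promoter with probability
#' `family_rate` and into each background promoter with probability
#' `background_rate`, replacing the bases at a random offset. Insertion
#' positions are recorded in the returned truth.
#'
#' @param promoters Tibble with columns `gene_id`, `sequence`.
#' @param cfg A [sim_config()].
#' @param family_ids Character vector of family gene ids.
#' @param pwms PWM collection containing every planted motif id.
#' @return List of class `sim_promoters`: `promoters` (modified tibble) and
#'   `truth` (tibble gene_id/motif_id/offset).
#' @export
plant_promoter_motifs <- function(promoters, cfg, family_ids, pwms) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + .stream_offsets[["motifs"]], {
    seqs <- setNames(promoters$sequence, promoters$gene_id)
    planted <- list()
    for (pm in cfg$planted_motifs) {
      pwm <- pwms[[pm$id]]
      abort_if(is.null(pwm), paste("planted motif not in collection:", pm$id))
      w <- ncol(pwm$matrix)
      for (g in promoters$gene_id) {
        rate <- if (g %in% family_ids) pm$family_rate else pm$background_rate
        if (runif(1) >= rate) next
        L <- nchar(seqs[[g]])
        abort_if(w > L, "motif insertion longer than promoter")
        inst <- pwm_consensus(pwm)
        off <- sample(seq_len(L - w + 1L), 1)
        substr(seqs[[g]], off, off + w - 1L) <- inst
        planted[[length(planted) + 1L]] <- tibble(
          gene_id = g, motif_id = pm$id, offset = off, instance = inst)
      }
    }
    truth <- if (length(planted)) dplyr::bind_rows(planted) else
      tibble(gene_id = character(), motif_id = character(),
             offset = integer(), instance = character())
    structure(list(
      promoters = tibble(gene_id = names(seqs), sequence = unname(seqs)),
      truth = truth, cfg = cfg
    ), class = "sim_promoters")
  })
}
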