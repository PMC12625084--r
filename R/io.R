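# Readers and writers for the standard formats the pipeline consumes and
# emits: FASTA (Biostrings), GFF3 (rtracklayer), VCF 4.x (vcfR in, plain text
# out), TSV tables (readr), and PWM collections (JASPAR / TRANSFAC dialects).

#' Read a FASTA file into a tibble
#' @param path FASTA file (DNA or protein).
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)), sequence = as.character(x))
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / exon / CDS records (1-based inclusive coordinates).
#' Exons double as CDS here: the toy gene models carry no UTRs.
#'
#' @param genes Gene-model tibble as produced by [simulate_genome()].
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    gid <- g$gene_id
    mid <- paste0(gid, ".t1")
    # CDS phase from cumulative exon lengths in coding order
    lens <- ex$end - ex$start + 1L
    coding_order <- if (g$strand == "+") seq_len(nrow(ex))
                    else rev(seq_len(nrow(ex)))
    before <- cumsum(c(0L, lens[coding_order]))[seq_len(nrow(ex))]
    phase <- integer(nrow(ex))
    phase[coding_order] <- (3L - before %% 3L) %% 3L
    rows[[length(rows) + 1L]] <- tibble(
      seqnames = g$chrom,
      start = c(g$start, g$start, ex$start, ex$start),
      end = c(g$end, g$end, ex$end, ex$end),
      strand = g$strand,
      type = c("gene", "mRNA", rep("exon", nrow(ex)), rep("CDS", nrow(ex))),
      ID = c(gid, mid, paste0(mid, ".exon", seq_len(nrow(ex))),
             paste0(mid, ".cds", seq_len(nrow(ex)))),
      Parent = c(NA, gid, rep(mid, 2L * nrow(ex))),
      phase = c(NA, NA, rep(NA, nrow(ex)), phase)
    )
  }
  df <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reconstructs the gene-model tibble (gene span, strand, ordered exon/CDS
#' coordinates) consumed by the promoter, allele-mining, and synteny stages.
#'
#' @param path GFF3 file with gene/mRNA/exon records.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   and list-column `exons` (tibble `start`, `end`, ascending).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, "")
  genes <- df[df$type == "gene", ]
  mrna <- df[df$type == "mRNA", ]
  exons <- df[df$type == "exon", ]
  mrna_of <- setNames(mrna$Parent, mrna$ID)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    mids <- names(mrna_of)[mrna_of == gid]
    ex <- exons[exons$Parent %in% mids, c("start", "end")]
    ex <- ex[order(ex$start), ]
    tibble(gene_id = gid, chrom = as.character(genes$seqnames[i]),
           strand = as.character(genes$strand[i]),
           start = genes$start[i], end = genes$end[i],
           exons = list(as_tibble(ex)))
  })
  dplyr::bind_rows(out)
}

#' Write variant records as VCF 4.2
#'
#' Records carry one allele column per accession ("A", "-" for a deleted
#' base, "." for missing). SNPs are written directly; deletion alleles are
#' left-anchored on the preceding reference base, which requires the genome.
#'
#' @param records Variant tibble (`chrom`, `pos`, `ref`, `qual`, `dp`, one
#'   column per accession).
#' @param path Output file.
#' @param genome Named list of chromosome sequences (needed only when
#'   deletion alleles are present).
#' @param accessions Accession column names; defaults to every column after
#'   `dp`.
#' @export
write_vcf <- function(records, path, genome = NULL, accessions = NULL) {
  if (is.null(accessions))
    accessions <- setdiff(names(records), c("chrom", "pos", "ref", "qual", "dp"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessions), collapse = "\t")
  )
  lines <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    alleles <- unlist(r[accessions])
    is_del <- any(alleles == "-", na.rm = TRUE)
    if (!is_del) {
      alts <- setdiff(unique(alleles), c(r$ref, "."))
      alt_field <- if (length(alts)) paste(alts, collapse = ",") else "."
      gt <- vapply(alleles, function(a) {
        if (a == ".") "." else if (a == r$ref) "0"
        else as.character(match(a, alts))
      }, "")
      pos <- r$pos; ref_field <- r$ref
    } else {
      abort_if(is.null(genome), "deletion alleles require the genome")
      anchor <- substr(genome[[r$chrom]], r$pos - 1L, r$pos - 1L)
      pos <- r$pos - 1L
      ref_field <- paste0(anchor, r$ref)
      alt_field <- anchor
      gt <- vapply(alleles, function(a) {
        if (a == ".") "." else if (a == "-") "1" else "0"
      }, "")
    }
    lines[i] <- paste(c(r$chrom, pos, ".", ref_field, alt_field,
                        sprintf("%.2f", r$qual), "PASS",
                        paste0("DP=", r$dp), "GT", gt), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a VCF into per-base variant records
#'
#' Parses with vcfR, then expands indel records into one row per affected
#' base: a deletion of m bases yields m rows whose carrier allele is "-";
#' an insertion of m bases yields m rows at consecutive positions whose
#' reference allele (and non-carrier allele) is "-". Missing genotypes become
#' ".". This mirrors the per-base haplotype-table representation used for
#' printed allele tables.
#'
#' @param path VCF file.
#' @return Variant tibble (`chrom`, `pos`, `ref`, `qual`, `dp`, one column
#'   per accession).
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  accs <- colnames(gt)
  dp <- suppressWarnings(as.integer(sub(".*DP=([0-9]+).*", "\\1", fix$INFO)))
  out <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]; alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    pos <- as.integer(fix$POS[i])
    qual <- suppressWarnings(as.numeric(fix$QUAL[i]))
    calls <- gt[i, ]
    allele_of <- function(code) {
      if (is.na(code) || code == ".") return(NA_character_)
      k <- as.integer(code)
      if (k == 0) ref else alts[k]
    }
    obs <- vapply(calls, allele_of, "")
    lens <- nchar(c(ref, alts))
    if (all(lens == 1L) && !any(alts == "*")) {
      row <- tibble(chrom = fix$CHROM[i], pos = pos, ref = ref,
                    qual = qual, dp = dp[i])
      for (a in accs) row[[a]] <- ifelse(is.na(obs[[a]]), ".", obs[[a]])
      out[[length(out) + 1L]] <- row
      next
    }
    alt <- alts[1]  # indel records are bi-allelic in this pipeline
    if (nchar(ref) > nchar(alt)) {
      # deletion: bases ref[2..] are absent from carriers
      del <- substring(ref, 2:nchar(ref), 2:nchar(ref))
      for (k in seq_along(del)) {
        row <- tibble(chrom = fix$CHROM[i], pos = pos + k, ref = del[k],
                      qual = qual, dp = dp[i])
        for (a in accs) {
          row[[a]] <- if (is.na(obs[[a]])) "." else
            if (obs[[a]] == alt) "-" else del[k]
        }
        out[[length(out) + 1L]] <- row
      }
    } else {
      # insertion: bases alt[2..] exist only in carriers
      ins <- substring(alt, 2:nchar(alt), 2:nchar(alt))
      for (k in seq_along(ins)) {
        row <- tibble(chrom = fix$CHROM[i], pos = pos + k, ref = "-",
                      qual = qual, dp = dp[i])
        for (a in accs) {
          row[[a]] <- if (is.na(obs[[a]])) "." else
            if (obs[[a]] == alt) ins[k] else "-"
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Read a domain-hit table
#'
#' TSV with columns `protein_id`, `domain_id`, `evalue`, `start`, `end`
#' (an hmmscan domtblout-compatible column subset).
#' @param path TSV file.
#' @return Tibble of domain hits.
#' @export
read_domain_hits <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    protein_id = "c", domain_id = "c", evalue = "d",
                    start = "i", end = "i"))
}

#' Read a TPM expression matrix
#'
#' First column is the gene id, remaining columns are samples.
#' @param path TSV file.
#' @return Tibble with `gene_id` plus one numeric column per sample.
#' @export
read_tpm <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "gene_id"
  abort_if(anyDuplicated(x$gene_id) > 0, "duplicate gene ids in TPM matrix")
  abort_if(any(as.matrix(x[-1]) < 0, na.rm = TRUE), "TPM values must be >= 0")
  x
}

#' Read a PWM collection (JASPAR or TRANSFAC dialect)
#'
#' JASPAR count blocks (`>id` header followed by `A [ ... ]` rows) are
#' converted to probabilities with a +0.8 pseudocount per cell; TRANSFAC-like
#' blocks (`ID`/`NA` header, `P0` column header, numbered probability rows,
#' `//` terminator) are taken as probabilities after per-row renormalisation.
#'
#' @param path Text file containing one or more matrices.
#' @param pseudocount Pseudocount added to JASPAR counts.
#' @return Named list of PWM objects: `list(id, matrix (4 x w, rows A,C,G,T,
#'   columns sum to 1), pseudocount)`.
#' @export
read_pwms <- function(path, pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      id <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
      rows <- list()
      for (k in 1:4) {
        rl <- trimws(lines[i + k])
        base <- sub("^([ACGT]).*$", "\\1", rl)
        nums <- as.numeric(strsplit(gsub("[][]", " ",
                                         sub("^[ACGT]", "", rl)), "\\s+")[[1]] |>
                             (\(x) x[nzchar(x)])())
        rows[[base]] <- nums
      }
      mat <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
      mat <- mat + pseudocount
      mat <- sweep(mat, 2, colSums(mat), "/")
      out[[id]] <- list(id = id, matrix = mat, pseudocount = pseudocount)
      i <- i + 5L
    } else if (grepl("^(ID|NA)\\b", ln)) {
      id <- strsplit(ln, "\\s+")[[1]][2]
      j <- i + 1L
      probs <- list()
      while (j <= length(lines) && !grepl("^//", trimws(lines[j]))) {
        lj <- trimws(lines[j])
        if (grepl("^[0-9]+\\s", lj)) {
          nums <- as.numeric(strsplit(lj, "\\s+")[[1]][2:5])
          probs[[length(probs) + 1L]] <- nums
        }
        j <- j + 1L
      }
      mat <- t(do.call(rbind, probs))
      rownames(mat) <- c("A", "C", "G", "T")
      mat <- sweep(mat, 2, colSums(mat), "/")
      out[[id]] <- list(id = id, matrix = mat, pseudocount = 0)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  abort_if(length(out) == 0, "no matrices recognised in PWM file")
  out
}

#' Write a PWM collection in JASPAR-like text
#' @param pwms Named list of PWM objects.
#' @param path Output file.
#' @param counts_scale Probabilities are written as pseudo-counts at this
#'   total per column (the JASPAR dialect stores counts).
#' @export
write_pwms <- function(pwms, path, counts_scale = 100) {
  lines <- character(0)
  for (p in pwms) {
    m <- round(p$matrix * counts_scale, 4)
    lines <- c(lines, paste0(">", p$id),
               vapply(1:4, function(r) {
                 paste0(rownames(m)[r], " [ ",
                        paste(m[r, ], collapse = " "), " ]")
               }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write every artifact of a simulated study to a directory
#'
#' Emits genome FASTA, protein FASTA, GFF3 gene models, domain-hit and
#' homolog-hit TSVs, VCF, TPM TSV, promoter FASTA, PWM collection, and a
#' JSON truth file. Re-running with the same configuration reproduces every
#' file byte for byte.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(cfg)
  write_fasta(tibble(id = names(sim$genome),
                     sequence = unlist(sim$genome)),
              file.path(dir, "genome.fa"))
  write_fasta(tibble(id = sim$proteins$id, sequence = sim$proteins$sequence),
              file.path(dir, "proteins.faa"))
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(sim$domain_hits, file.path(dir, "domain_hits.tsv"))
  readr::write_tsv(sim$homolog_hits, file.path(dir, "homolog_hits.tsv"))

  vars <- simulate_variants(cfg, sim)
  write_vcf(vars$records, file.path(dir, "variants.vcf"), genome = sim$genome)

  expr <- simulate_expression(cfg, gene_ids = sim$truth$family_ids)
  readr::write_tsv(expr$tpm, file.path(dir, "tpm.tsv"))

  pwms <- simulate_pwm_collection(cfg)
  write_pwms(pwms, file.path(dir, "pwms.txt"))

  prom <- extract_promoters(sim$genome, sim$genes,
                            length = cfg$promoter_length)
  planted <- plant_promoter_motifs(prom$promoters, cfg,
                                   sim$truth$family_ids, pwms)
  write_fasta(tibble(id = planted$promoters$gene_id,
                     sequence = planted$promoters$sequence),
              file.path(dir, "promoters.fa"))

  truth <- list(
    family_ids = sim$truth$family_ids,
    paralog_pairs = as.data.frame(sim$truth$paralog_pairs[, c("a", "b")]),
    trait_specific_genomic = vars$truth$trait_specific_genomic,
    trait_specific_relative = vars$truth$trait_specific_relative,
    variant_gene = vars$gene_id,
    planted_motifs = as.data.frame(planted$truth),
    expression_modules = expr$truth$modules
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genome = sim, variants = vars, expression = expr,
                 pwms = pwms, promoters = planted))
}
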