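# Pipeline orchestration: one structured config with study-default
# parameters drives the stages in dependency order and renders report tables
# in the layouts of a gene-family characterization paper.

#' Pipeline configuration
#'
#' Assembles the full pipeline configuration. Parameter defaults are the
#' study defaults used throughout the package: 2,000-bp promoters filtered
#' at < 500 bp or > 1,500 ambiguous bases, enrichment threshold q <= 0.1,
#' variant filters QUAL >= 30 and DP >= 5, collinearity parameters (match
#' size 5, max gaps 25, match score 50, gap penalty -1, overlap window 5,
#' top 5 hits, e <= 1e-5), and a 1.0-Mb QTN window.
#'
#' @param inputs Named list of input paths (`genome`, `gff`, `proteins`,
#'   `domain_hits`, `homolog_hits`, `vcf`, `tpm`, `pwms`, `promoters`,
#'   `alignment`, `reference_ids`, `qtn_loci` — any subset; stages lacking
#'   inputs are skipped).
#' @param outdir Output directory.
#' @param seed Integer seed funnelled to every source of randomness.
#' @param simulate If `TRUE`, generate the synthetic input bundle into
#'   `outdir/sim` first and use it for every unset input.
#' @param params Overrides for the stage parameters listed above.
#' @param groups Named list `group1`, `group2` of accession ids.
#' @param panel Gene ids of the correlation panel (set B).
#' @param family List with `required_domains` and `e_cutoff` for the census.
#' @param sim Overrides passed to [sim_config()] when `simulate = TRUE`
#'   (e.g. smaller genome dimensions).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), outdir = tempfile("genefam_"),
                            seed = 1L, simulate = FALSE, params = list(),
                            groups = list(
                              group1 = c("EC0115148", "EC0718827"),
                              group2 = c("IC0523807", "IC0525939")),
                            panel = NULL,
                            family = list(
                              required_domains = c(DOMAIN_SYNTHASE,
                                                   DOMAIN_PHOSPHATASE),
                              e_cutoff = 1e-5),
                            sim = list()) {
  defaults <- list(
    promoter_length = 2000L, promoter_min_len = 500L,
    promoter_max_ambiguous = 1500L, q_threshold = 0.1,
    qual_min = 30, dp_min = 5,
    match_size = 5L, max_gaps = 25L, match_score = 50, gap_penalty = -1,
    overlap_window = 5L, top_k = 5L, e_max = 1e-5,
    qtn_window_bp = 1e6, alpha = 0.05, neutral_band = 0.5
  )
  structure(list(
    inputs = inputs, outdir = outdir, seed = as.integer(seed),
    simulate = simulate,
    params = utils::modifyList(defaults, params),
    groups = groups, panel = panel, family = family, sim = sim
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any of the [pipeline_config()] sections.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

write_resolved_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

run_stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full characterization pipeline
#'
#' Executes the stages in dependency order — census, naming, correlation,
#' allele mining, promoter enrichment, synteny, QTN proximity — skipping
#' stages whose inputs are not configured, then renders report tables. A
#' stage failure halts the run with a stage-named error. Every output is
#' reproducible from the resolved config written alongside the outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a named list of stage outputs.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$outdir, "pipeline.log")
  cat("", file = logf)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    message(line)
    cat(line, "\n", file = logf, append = TRUE)
  }
  inp <- cfg$inputs
  if (isTRUE(cfg$simulate)) {
    simdir <- file.path(cfg$outdir, "sim")
    scfg <- do.call(sim_config, utils::modifyList(
      list(seed = cfg$seed, promoter_length = cfg$params$promoter_length),
      cfg$sim %||% list()))
    write_simulation(scfg, simdir)
    sim_inputs <- list(
      genome = file.path(simdir, "genome.fa"),
      gff = file.path(simdir, "genes.gff3"),
      proteins = file.path(simdir, "proteins.faa"),
      domain_hits = file.path(simdir, "domain_hits.tsv"),
      homolog_hits = file.path(simdir, "homolog_hits.tsv"),
      vcf = file.path(simdir, "variants.vcf"),
      tpm = file.path(simdir, "tpm.tsv"),
      pwms = file.path(simdir, "pwms.txt"),
      promoters = file.path(simdir, "promoters.fa")
    )
    inp <- utils::modifyList(sim_inputs, inp)
    log("stage simulate: synthetic bundle written to ", simdir)
  }
  for (nm in names(inp)) {
    if (!is.null(inp[[nm]]) && !file.exists(inp[[nm]]))
      stop("stage ", nm, ": missing input file ", inp[[nm]], call. = FALSE)
  }
  cfg$inputs <- inp
  write_resolved_config(cfg, file.path(cfg$outdir, "config_resolved.yaml"))
  p <- cfg$params
  out <- list()

  genes <- NULL
  if (!is.null(inp$gff)) genes <- read_gff3_genes(inp$gff)

  if (!is.null(inp$proteins) && !is.null(inp$domain_hits)) {
    out$census <- run_stage("census", log, {
      proteins <- read_fasta(inp$proteins)
      hits <- read_domain_hits(inp$domain_hits)
      cens <- family_census(proteins, hits,
                            required = cfg$family$required_domains,
                            e_cutoff = cfg$family$e_cutoff)
      log("stage census: ", nrow(proteins), " proteins in, ",
          nrow(cens), " family rows out")
      cens
    })
  }
  family_ids <- if (!is.null(out$census)) out$census$gene_id else character(0)

  if (!is.null(inp$alignment) && !is.null(inp$reference_ids)) {
    out$naming <- run_stage("naming", log, {
      aln <- read_fasta(inp$alignment)
      refs <- readLines(inp$reference_ids)
      d <- p_distance(aln)
      qry <- setdiff(aln$id, refs)
      nm <- assign_names(d, refs, qry)
      log("stage naming: ", length(qry), " queries named against ",
          length(refs), " references")
      nm
    })
  }

  if (!is.null(inp$tpm) && length(family_ids) > 0) {
    out$correlation <- run_stage("correlation", log, {
      tpm <- read_tpm(inp$tpm)
      set_a <- intersect(family_ids, tpm$gene_id)
      set_b <- cfg$panel %||% setdiff(tpm$gene_id, set_a)
      res <- correlate_panels(tpm, set_a, set_b, alpha = p$alpha)
      log("stage correlation: ", nrow(res), " gene pairs tested")
      res
    })
  }

  if (!is.null(inp$vcf) && !is.null(genes) && length(family_ids) > 0) {
    out$alleles <- run_stage("alleles", log, {
      recs <- read_vcf_records(inp$vcf)
      kept <- filter_variants(recs, p$qual_min, p$dp_min)
      abort_if(is.null(inp$genome),
               "genome FASTA required for consequence calls")
      fa <- read_fasta(inp$genome)
      genome_seqs <- setNames(as.list(fa$sequence), fa$id)
      tabs <- list()
      for (gid in family_ids) {
        gene <- genes[genes$gene_id == gid, ]
        if (nrow(gene) == 0) next
        gene$cds <- splice_cds(genome_seqs, gene)
        ht <- build_haplotype_table(kept, gene, p$promoter_length,
                                    cfg$groups$group1, cfg$groups$group2)
        if (nrow(ht) == 0) next
        ht <- classify_trait_specific(ht)
        ht <- classify_variant_type(ht)
        ht <- annotate_consequence(ht, gene)
        tabs[[gid]] <- mutate(ht, gene_id = gid, .before = 1)
      }
      res <- dplyr::bind_rows(tabs)
      log("stage alleles: ", nrow(recs), " records in, ", nrow(kept),
          " pass filters, ", nrow(res), " haplotype rows out")
      res
    })
  }

  if (!is.null(inp$pwms) && length(family_ids) > 0 &&
      (!is.null(inp$promoters) || (!is.null(inp$genome) && !is.null(genes)))) {
    out$enrichment <- run_stage("enrichment", log, {
      pwms <- read_pwms(inp$pwms)
      if (!is.null(inp$promoters)) {
        pr <- rename(read_fasta(inp$promoters), gene_id = "id")
        excluded <- tibble(gene_id = character(), reason = character())
      } else {
        ex <- extract_promoters(inp$genome, genes, p$promoter_length,
                                p$promoter_min_len, p$promoter_max_ambiguous)
        pr <- ex$promoters; excluded <- ex$excluded
      }
      enr <- motif_enrichment(pr, family_ids, pwms,
                              q_threshold = p$q_threshold)
      log("stage enrichment: ", nrow(pr), " promoters (",
          nrow(excluded), " excluded), ", sum(tidy(enr)$enriched),
          " motifs enriched at q <= ", p$q_threshold)
      enr
    })
  }

  if (!is.null(inp$homolog_hits) && !is.null(genes)) {
    out$synteny <- run_stage("synteny", log, {
      hits <- readr::read_tsv(inp$homolog_hits, show_col_types = FALSE)
      idx <- gene_rank_index(genes)
      blocks <- chain_collinear(hits, idx, params = list(
        e_max = p$e_max, top_k = p$top_k, match_size = p$match_size,
        max_gaps = p$max_gaps, match_score = p$match_score,
        gap_penalty = p$gap_penalty, overlap_window = p$overlap_window))
      fam_blocks <- filter_family_blocks(blocks, family_ids)
      gcn <- build_gcn(fam_blocks, family_ids, co_membership = TRUE)
      log("stage synteny: ", nrow(blocks), " blocks, ", nrow(fam_blocks),
          " with family genes, ", length(gcn$sizes), " network component(s)")
      list(blocks = blocks, family_blocks = fam_blocks, gcn = gcn)
    })
  }

  if (!is.null(inp$qtn_loci) && !is.null(genes)) {
    out$qtl <- run_stage("qtl", log, {
      loci <- readr::read_tsv(inp$qtn_loci, show_col_types = FALSE)
      if (!all(c("chrom", "pos") %in% names(loci)))
        loci <- parse_qtn_ids(loci[[1]])
      span <- genes
      if (length(family_ids)) span <- filter(span, .data$gene_id %in% family_ids)
      prox <- qtn_proximity(span, loci, p$qtn_window_bp)
      log("stage qtl: ", nrow(prox), " gene-locus pairs within ",
          p$qtn_window_bp / 1e6, " Mb")
      prox
    })
  }

  render_report(out, cfg$outdir)
  log("report: tables written to ", cfg$outdir)
  invisible(out)
}

# CDS sequence of a gene model, spliced from preloaded chromosome sequences.
splice_cds <- function(genome_seqs, gene) {
  chrom <- genome_seqs[[gene$chrom]]
  abort_if(is.null(chrom), paste("chromosome missing:", gene$chrom))
  ex <- gene$exons[[1]]
  pieces <- substring(chrom, ex$start, ex$end)
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") s <- revcomp_chr(s)
  s
}

#' Render report tables from stage outputs
#'
#' Writes one TSV per available stage in the column layouts a gene-family
#' characterization reports: the census, per-gene haplotype tables with
#' trait-specific flags, enrichment results, block censuses for all and for
#' family-filtered blocks, plus correlations, network membership, and QTN
#' proximity. Stages without outputs are skipped with a note.
#'
#' @param out Stage-output list from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(out, dir) {
  abort_if(length(out) == 0, "no stage outputs to render")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(tbl, name) {
    p <- file.path(dir, name)
    readr::write_tsv(tbl, p)
    paths <<- c(paths, p)
  }
  skipped <- character(0)
  if (!is.null(out$census)) emit(out$census, "census.tsv")
  else skipped <- c(skipped, "census")
  if (!is.null(out$naming)) emit(out$naming, "naming.tsv")
  if (!is.null(out$correlation)) emit(out$correlation, "correlations.tsv")
  if (!is.null(out$alleles)) emit(out$alleles, "haplotypes.tsv")
  else skipped <- c(skipped, "alleles")
  if (!is.null(out$enrichment)) {
    emit(tidy(out$enrichment), "enrichment.tsv")
    emit(tibble(motif_id = out$enrichment$universal), "universal_motifs.tsv")
  } else skipped <- c(skipped, "enrichment")
  if (!is.null(out$synteny)) {
    emit(csb_census(out$synteny$blocks), "csb_census.tsv")
    emit(csb_census(out$synteny$family_blocks), "family_csbs.tsv")
    emit(tidy(out$synteny$gcn), "gcn_components.tsv")
  } else skipped <- c(skipped, "synteny")
  if (!is.null(out$qtl)) emit(out$qtl, "qtn_proximity.tsv")
  if (length(skipped))
    writeLines(paste("skipped (no output):", paste(skipped, collapse = ", ")),
               file.path(dir, "report_notes.txt"))
  invisible(paths)
}
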