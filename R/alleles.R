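# Allele mining: VCF-record filtering, gene-relative haplotype tables over a
# gene plus its promoter, trait-specific variant classification, SNP/indel
# typing, coding-consequence annotation, and the stability-delta report.

#' Filter variant records on quality and depth
#'
#' Keeps records with `QUAL >= qual_min` and `DP >= dp_min` (both bounds
#' inclusive). Records missing either field are dropped with a warning that
#' reports the count.
#'
#' @param records Variant tibble with `qual` and `dp` columns.
#' @param qual_min Minimum phred-scaled quality (default 30).
#' @param dp_min Minimum read depth (default 5).
#' @return Filtered tibble.
#' @export
filter_variants <- function(records, qual_min = 30, dp_min = 5) {
  miss <- is.na(records$qual) | is.na(records$dp)
  if (any(miss)) {
    warning(sum(miss), " record(s) dropped for missing QUAL/DP",
            call. = FALSE)
  }
  records |> filter(!is.na(.data$qual), !is.na(.data$dp),
                    .data$qual >= qual_min, .data$dp >= dp_min)
}

cds_anchor <- function(gene) {
  ex <- gene$exons[[1]]
  if (gene$strand == "+") min(ex$start) else max(ex$end)
}

#' Convert genomic positions to gene-relative coordinates
#'
#' Position `+1` is the first base of the start codon on the coding strand;
#' the immediately upstream base is `-1`; there is no position 0. Strand
#' aware: on minus-strand genes, upstream means larger genomic coordinates.
#'
#' @param pos Genomic positions (1-based).
#' @param gene One-row gene-model tibble (`strand`, `exons` list-column).
#' @return Signed gene-relative positions.
#' @export
genomic_to_relative <- function(pos, gene) {
  anchor <- cds_anchor(gene)
  if (gene$strand == "+") {
    ifelse(pos >= anchor, pos - anchor + 1L, pos - anchor)
  } else {
    ifelse(pos <= anchor, anchor - pos + 1L, anchor - pos)
  }
}

#' Convert gene-relative coordinates back to genomic positions
#' @param rel Signed gene-relative positions (no zeros).
#' @param gene One-row gene-model tibble.
#' @return Genomic positions.
#' @export
relative_to_genomic <- function(rel, gene) {
  abort_if(any(rel == 0), "gene-relative coordinates have no position 0")
  anchor <- cds_anchor(gene)
  if (gene$strand == "+") {
    ifelse(rel > 0, anchor + rel - 1L, anchor + rel)
  } else {
    ifelse(rel > 0, anchor - rel + 1L, anchor - rel)
  }
}

complement_allele <- function(a) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", `-` = "-", `.` = ".")
  unname(comp[a])
}

#' Build a gene-relative haplotype table
#'
#' Transforms variant records on the gene's chromosome into the signed
#' coordinate system of the gene (promoter rows negative, genic rows
#' positive) and keeps rows within `[-promoter_len, gene length]`. On
#' minus-strand genes, single-base alleles are complemented so the table
#' reads in coding-strand orientation.
#'
#' @param records Variant tibble (see [read_vcf_records()]).
#' @param gene One-row gene-model tibble with a CDS (`exons` list-column).
#' @param promoter_len Promoter window (bp upstream of the start codon).
#' @param group1,group2 Accession id vectors (stored as attributes; group 1
#'   is conventionally the late-, group 2 the early-phenotype group).
#' @return Haplotype tibble: `position` (gene-relative), `genomic_pos`,
#'   `reference`, one column per accession; ordered by `position`.
#' @export
build_haplotype_table <- function(records, gene, promoter_len = 2000,
                                  group1 = NULL, group2 = NULL) {
  abort_if(is.null(gene$exons[[1]]) || nrow(gene$exons[[1]]) == 0,
           "gene has no CDS")
  accs <- setdiff(names(records), c("chrom", "pos", "ref", "qual", "dp"))
  recs <- records |> filter(.data$chrom == gene$chrom)
  gene_len <- gene$end - gene$start + 1L
  rel <- genomic_to_relative(recs$pos, gene)
  keep <- rel >= -promoter_len & rel <= gene_len
  recs <- recs[keep, ]; rel <- rel[keep]
  flip <- gene$strand == "-"
  fix_allele <- function(a) if (flip) complement_allele(a) else a
  out <- tibble(position = rel, genomic_pos = recs$pos,
                reference = fix_allele(recs$ref))
  for (a in accs) out[[a]] <- fix_allele(recs[[a]])
  out <- arrange(out, .data$position)
  attr(out, "group1") <- group1
  attr(out, "group2") <- group2
  attr(out, "gene_id") <- gene$gene_id
  out
}

haplotype_groups <- function(haps, group1, group2) {
  if (is.null(group1)) group1 <- attr(haps, "group1")
  if (is.null(group2)) group2 <- attr(haps, "group2")
  abort_if(is.null(group1) || is.null(group2) ||
             length(group1) == 0 || length(group2) == 0,
           "both accession groups must be given (or set as attributes)")
  abort_if(!all(c(group1, group2) %in% names(haps)),
           "group accession(s) missing from haplotype table")
  list(g1 = group1, g2 = group2)
}

#' Flag trait-specific variant rows
#'
#' A row is trait-specific iff all group-1 alleles are identical, all
#' group-2 alleles are identical, and the two group alleles differ. The
#' deletion symbol `-` is a comparable allele; the missing code `.`
#' disqualifies a row.
#'
#' @param haps Haplotype tibble from [build_haplotype_table()] (or
#'   [read_haplotype_table()]).
#' @param group1,group2 Accession ids (defaults to the table's attributes).
#' @return The table with a logical `trait_specific` column added.
#' @export
classify_trait_specific <- function(haps, group1 = NULL, group2 = NULL) {
  g <- haplotype_groups(haps, group1, group2)
  if (nrow(haps) == 0) return(mutate(haps, trait_specific = logical(0)))
  a1 <- as.matrix(haps[, g$g1, drop = FALSE])
  a2 <- as.matrix(haps[, g$g2, drop = FALSE])
  uni1 <- apply(a1, 1, function(x) length(unique(x)) == 1 && !any(x == "."))
  uni2 <- apply(a2, 1, function(x) length(unique(x)) == 1 && !any(x == "."))
  flag <- uni1 & uni2 & a1[, 1] != a2[, 1]
  mutate(haps, trait_specific = unname(flag))
}

#' Type variant rows as SNP or indel
#'
#' A row is an indel iff any allele (reference or accession, ignoring the
#' missing code `.`) is the deletion symbol `-` or longer than one base;
#' otherwise it is a SNP.
#'
#' @param haps Haplotype tibble.
#' @return The table with a `type` column (`"SNP"` / `"indel"`).
#' @export
classify_variant_type <- function(haps) {
  accs <- setdiff(names(haps),
                  c("position", "genomic_pos", "reference",
                    "trait_specific", "type", "region", "effect"))
  allele_cols <- c("reference", accs)
  type <- apply(as.matrix(haps[, allele_cols, drop = FALSE]), 1, function(x) {
    x <- x[x != "."]
    if (any(x == "-") || any(nchar(x) != 1)) "indel" else "SNP"
  })
  mutate(haps, type = unname(type))
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

# CDS offset (1-based) of a genomic position inside an exon, accumulating
# exon lengths along the coding strand; NA when the position is intronic.
genomic_to_cds <- function(pos, gene) {
  ex <- gene$exons[[1]]
  ex <- ex[order(ex$start), ]
  if (gene$strand == "+") {
    cum <- 0L
    for (i in seq_len(nrow(ex))) {
      if (pos >= ex$start[i] && pos <= ex$end[i])
        return(cum + pos - ex$start[i] + 1L)
      cum <- cum + ex$end[i] - ex$start[i] + 1L
    }
  } else {
    cum <- 0L
    for (i in rev(seq_len(nrow(ex)))) {
      if (pos >= ex$start[i] && pos <= ex$end[i])
        return(cum + ex$end[i] - pos + 1L)
      cum <- cum + ex$end[i] - ex$start[i] + 1L
    }
  }
  NA_integer_
}

#' Annotate the coding consequence of haplotype rows
#'
#' Rows at negative positions are `promoter`/`upstream`; genic rows outside
#' every exon are `intron`/`intronic`. Exonic single-base substitutions are
#' mapped through cumulative exon lengths to a CDS offset, the affected codon
#' (`ceiling(cds_pos / 3)`) is mutated, and the effect is read off the
#' standard genetic code, reporting protein changes like `"Gly782Val"`.
#' Exonic indel rows whose length is not a multiple of 3 are frameshifts.
#'
#' @param haps Haplotype tibble (alleles in coding-strand orientation).
#' @param gene One-row gene-model tibble with `exons` and `cds` (CDS
#'   sequence, coding strand).
#' @param group2 Accessions whose alternate allele is annotated (defaults to
#'   the table's group-2 attribute, falling back to the first non-reference
#'   allele in the row).
#' @return The table with `region` (`promoter`/`exon`/`intron`), `effect`
#'   (`upstream`/`synonymous`/`nonsynonymous`/`frameshift`/`intronic`), and
#'   `protein_change` columns.
#' @export
annotate_consequence <- function(haps, gene, group2 = NULL) {
  if (is.null(group2)) group2 <- attr(haps, "group2")
  accs <- setdiff(names(haps),
                  c("position", "genomic_pos", "reference",
                    "trait_specific", "type", "region", "effect",
                    "protein_change"))
  cds <- gene$cds
  abort_if(is.null(cds) || !nzchar(cds), "gene model carries no CDS sequence")
  gene_len <- gene$end - gene$start + 1L
  region <- character(nrow(haps))
  effect <- character(nrow(haps))
  change <- rep(NA_character_, nrow(haps))
  for (i in seq_len(nrow(haps))) {
    rel <- haps$position[i]
    abort_if(rel > gene_len, "position beyond gene span")
    ref <- haps$reference[i]
    alleles <- unlist(haps[i, accs])
    alts <- setdiff(unique(alleles), c(ref, "."))
    # prefer the group-2 allele when one is designated
    if (!is.null(group2)) {
      g2 <- setdiff(unique(unlist(haps[i, intersect(group2, accs)])),
                    c(ref, "."))
      if (length(g2)) alts <- g2
    }
    is_indel <- ref == "-" || any(alts == "-") || any(nchar(alts) != 1)
    if (rel < 0) {
      region[i] <- "promoter"; effect[i] <- "upstream"
      next
    }
    gpos <- if ("genomic_pos" %in% names(haps) && !is.na(haps$genomic_pos[i]))
      haps$genomic_pos[i] else relative_to_genomic(rel, gene)
    cds_pos <- genomic_to_cds(gpos, gene)
    if (is.na(cds_pos)) {
      region[i] <- "intron"; effect[i] <- "intronic"
      next
    }
    region[i] <- "exon"
    if (is_indel) {
      len <- max(nchar(setdiff(c(ref, alts), "-")), 1L)
      effect[i] <- if (len %% 3 == 0) "inframe_indel" else "frameshift"
      next
    }
    if (length(alts) == 0) { effect[i] <- "synonymous"; next }
    codon_idx <- ceiling(cds_pos / 3)
    within <- cds_pos - 3L * (codon_idx - 1L)
    codon <- substr(cds, 3L * codon_idx - 2L, 3L * codon_idx)
    aa_ref <- translate_codon(codon)
    eff <- "synonymous"
    for (a in alts) {
      mut <- codon
      substr(mut, within, within) <- a
      aa_alt <- translate_codon(mut)
      if (!identical(aa_alt, aa_ref)) {
        eff <- "nonsynonymous"
        change[i] <- paste0(AA3[aa_ref], codon_idx, AA3[aa_alt])
        break
      }
    }
    effect[i] <- eff
  }
  mutate(haps, region = region, effect = effect, protein_change = change)
}

#' Protein stability delta report
#'
#' `delta = e_mut - e_wild`; labelled `Stabilizing` when delta is below
#' `-neutral_band`, `Destabilizing` above `+neutral_band`, otherwise
#' `Neutral`.
#'
#' @param e_wild,e_mut Potential energies (kcal/mol) of the wild-type and
#'   mutant structures.
#' @param neutral_band Half-width of the neutral zone (kcal/mol).
#' @return Tibble `e_wild`, `e_mut`, `delta`, `label`.
#' @export
stability_report <- function(e_wild, e_mut, neutral_band = 0.5) {
  abort_if(!is.finite(e_wild) || !is.finite(e_mut) || !is.finite(neutral_band),
           "energies must be finite")
  delta <- e_mut - e_wild
  label <- if (delta < -neutral_band) "Stabilizing"
           else if (delta > neutral_band) "Destabilizing" else "Neutral"
  tibble(e_wild = e_wild, e_mut = e_mut,
         delta = round(delta, 2), label = label)
}

#' Read a printed-style haplotype table from TSV
#'
#' Expects columns `position`, `reference`, then one column per accession
#' (allele strings; `-` = deletion, `.` = missing).
#'
#' @param path TSV file.
#' @param group1,group2 Accession ids stored as attributes for the
#'   classification helpers.
#' @return Haplotype tibble.
#' @export
read_haplotype_table <- function(path, group1 = NULL, group2 = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(position = "i",
                                               .default = "c"))
  abort_if(!all(c("position", "reference") %in% names(x)),
           "haplotype TSV needs 'position' and 'reference' columns")
  abort_if(any(x$position == 0), "haplotype positions must be non-zero")
  x <- arrange(x, .data$position)
  attr(x, "group1") <- group1
  attr(x, "group2") <- group2
  x
}
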