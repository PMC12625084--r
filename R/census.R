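# Family census: identify family members by required conserved domains and
# compute per-protein physicochemical properties and PROSITE-style site
# counts, the census table a gene-family characterization reports.

# Average residue masses (Da) of the 20 standard amino acids; a peptide's
# mass is the sum of its residue masses plus one water.
AA_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.0153

#' Bjellqvist-style pKa table
#'
#' The ionizable-group pKa values used by [protein_pi()]: terminal groups
#' plus the seven ionizable side chains. `positive` groups contribute
#' `+1/(1+10^(pH-pKa))` to the net charge, `negative` groups
#' `-1/(1+10^(pKa-pH))`.
#'
#' @return List with numeric vectors `positive` and `negative`.
#' @export
pka_bjellqvist <- function() {
  list(
    positive = c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98),
    negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  )
}

check_protein <- function(sequence, strict = TRUE) {
  abort_if(!nzchar(sequence), "empty protein sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(AA_MASS))
  if (length(bad)) {
    if (strict) stop("invalid residue letter(s): ", paste(bad, collapse = ","),
                     call. = FALSE)
    warning("skipping ambiguous residue(s): ", paste(bad, collapse = ","),
            call. = FALSE)
    aa <- aa[aa %in% names(AA_MASS)]
  }
  aa
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water mass.
#'
#' @param sequence Amino-acid string (20-letter alphabet).
#' @param units `"kDa"` (default) or `"Da"`.
#' @param strict If `TRUE`, non-standard letters are an error; otherwise they
#'   are skipped with a warning.
#' @return Molecular weight.
#' @export
protein_mw <- function(sequence, units = c("kDa", "Da"), strict = TRUE) {
  units <- match.arg(units)
  aa <- check_protein(sequence, strict)
  da <- sum(AA_MASS[aa]) + WATER_MASS
  if (units == "kDa") da / 1000 else da
}

protein_net_charge <- function(counts, pH, pka) {
  pos <- pka$positive; neg <- pka$negative
  cp <- c(Nterm = 1, counts[intersect(names(pos), names(counts))])
  cn <- c(Cterm = 1, counts[intersect(names(neg), names(counts))])
  sum(cp * 1 / (1 + 10^(pH - pos[names(cp)]))) -
    sum(cn * 1 / (1 + 10^(neg[names(cn)] - pH)))
}

#' Isoelectric point of a protein
#'
#' pH at which the Henderson-Hasselbalch net charge over the termini and the
#' ionizable side chains is zero, located by bisection on `[0, 14]`.
#'
#' @inheritParams protein_mw
#' @param pka pKa table, see [pka_bjellqvist()].
#' @param tol Bisection tolerance in pH units.
#' @return Isoelectric point (pH units).
#' @export
protein_pi <- function(sequence, pka = pka_bjellqvist(), tol = 1e-4,
                       strict = TRUE) {
  aa <- check_protein(sequence, strict)
  counts <- table(aa)
  counts <- setNames(as.numeric(counts), names(counts))
  lo <- 0; hi <- 14
  # net charge is monotone decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Default PROSITE patterns for the census site columns
#'
#' The canonical patterns for the six site classes reported in the census:
#' casein kinase II and protein kinase C phosphorylation, tyrosine kinase
#' phosphorylation, cAMP/cGMP-dependent kinase phosphorylation, amidation,
#' and N-glycosylation.
#'
#' @return Named character vector of PROSITE-syntax patterns.
#' @export
prosite_patterns <- function() {
  c(ck2 = "[ST]-x(2)-[DE]",
    pkc = "[ST]-x-[RK]",
    tyr = "[RK]-x(2,3)-[DE]-x(2,3)-Y",
    camp = "[RK](2)-x-[ST]",
    amidation = "x-G-[RK]-[RK]",
    n_glycosylation = "N-{P}-[ST]-{P}")
}

#' Convert a PROSITE pattern to a regular expression
#'
#' Supports residue letters, `x` wildcards, `[...]` alternatives, `{...}`
#' exclusions, `(n)` / `(n,m)` repeats, and the `<` / `>` anchors.
#'
#' @param pattern PROSITE-syntax pattern (elements separated by `-`).
#' @return A regular expression string.
#' @export
prosite_to_regex <- function(pattern) {
  abort_if(!nzchar(pattern), "empty PROSITE pattern")
  p <- gsub("\\.$", "", trimws(pattern))
  anchor_start <- startsWith(p, "<")
  anchor_end <- endsWith(p, ">")
  p <- sub("^<", "", sub(">$", "", p))
  elems <- strsplit(p, "-", fixed = TRUE)[[1]]
  rx <- vapply(elems, function(e) {
    m <- regmatches(e, regexec("^(.*?)(\\(([0-9]+)(,([0-9]+))?\\))?$", e))[[1]]
    core <- m[2]; rep_lo <- m[4]; rep_hi <- m[6]
    body <-
      if (core == "x") "." else
      if (grepl("^\\[[A-Z]+\\]$", core)) core else
      if (grepl("^\\{[A-Z]+\\}$", core)) paste0("[^", substr(core, 2, nchar(core) - 1), "]") else
      if (grepl("^[A-Z]$", core)) core else
      stop("malformed PROSITE element: ", e, call. = FALSE)
    if (nzchar(rep_lo)) {
      body <- if (nzchar(rep_hi)) paste0(body, "{", rep_lo, ",", rep_hi, "}")
      else paste0(body, "{", rep_lo, "}")
    }
    body
  }, "")
  paste0(if (anchor_start) "^", paste(rx, collapse = ""),
         if (anchor_end) "$")
}

#' Count PROSITE pattern occurrences in a protein
#'
#' Counts matches over all start positions; overlapping occurrences are all
#' counted.
#'
#' @param sequence Amino-acid string (may be empty: all counts are 0).
#' @param patterns Named character vector of PROSITE patterns.
#' @return Named integer vector of counts.
#' @export
prosite_count <- function(sequence, patterns = prosite_patterns()) {
  abort_if(is.null(names(patterns)) || any(!nzchar(names(patterns))),
           "patterns must be named")
  vapply(patterns, function(p) {
    if (!nzchar(sequence)) return(0L)
    rx <- prosite_to_regex(p)
    m <- gregexpr(paste0("(?=", rx, ")"), toupper(sequence), perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, 0L)
}

#' Filter candidate proteins by required conserved domains
#'
#' A protein is retained iff it has at least one hit at or below the e-value
#' cutoff for EVERY required domain.
#'
#' @param hits Domain-hit tibble (`protein_id`, `domain_id`, `evalue`, ...).
#' @param required Character vector of required domain ids (must be
#'   non-empty: an empty set would silently retain everything).
#' @param e_cutoff Maximum e-value for a hit to count.
#' @return Character vector of retained protein ids.
#' @export
filter_by_domains <- function(hits, required, e_cutoff = 1e-5) {
  abort_if(length(required) == 0, "required domain set must be non-empty")
  ok <- hits |>
    filter(.data$domain_id %in% required, .data$evalue <= e_cutoff) |>
    distinct(.data$protein_id, .data$domain_id) |>
    dplyr::count(.data$protein_id) |>
    filter(.data$n == length(unique(required)))
  sort(ok$protein_id)
}

#' Family census table
#'
#' Applies the domain filter and computes, for each retained protein, its
#' length, molecular weight (kDa), isoelectric point, and the PROSITE site
#' counts — the usual census columns of a gene-family characterization.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param hits Domain-hit tibble.
#' @param required Required domain ids (defaults to the synthase-like plus
#'   phosphatase-like pair used by the synthetic genome).
#' @param e_cutoff Domain e-value cutoff.
#' @param patterns PROSITE patterns for the site-count columns.
#' @param naming Optional [assign_names()] result used to fill the `name`
#'   column.
#' @return Census tibble, one row per family member.
#' @export
family_census <- function(proteins, hits,
                          required = c(DOMAIN_SYNTHASE, DOMAIN_PHOSPHATASE),
                          e_cutoff = 1e-5,
                          patterns = prosite_patterns(),
                          naming = NULL) {
  fam <- filter_by_domains(hits, required, e_cutoff)
  rows <- proteins |> filter(.data$id %in% fam)
  counts <- t(vapply(rows$sequence, prosite_count,
                     prosite_count("", patterns), patterns = patterns))
  out <- tibble(
    gene_id = rows$id,
    name = rows$id,
    length = nchar(rows$sequence),
    mw_kda = vapply(rows$sequence, protein_mw, 0),
    pi = vapply(rows$sequence, protein_pi, 0)
  )
  out <- bind_cols(out, as_tibble(counts))
  if (!is.null(naming)) {
    out$name <- naming$assigned_name[match(out$gene_id, naming$query_id)]
  }
  out
}

#' Summary statistics of a census table
#'
#' Minimum, maximum, and mean (reported at 2 decimals) of protein length,
#' molecular weight, and isoelectric point.
#'
#' @param census Census tibble with columns `length`, `mw_kda`, `pi`.
#' @return Tibble with one row per property.
#' @export
family_summary <- function(census) {
  abort_if(nrow(census) == 0, "empty census table")
  dplyr::bind_rows(lapply(c("length", "mw_kda", "pi"), function(v) {
    x <- census[[v]]
    tibble(property = v, min = min(x), max = max(x),
           mean = round(mean(x), 2))
  }))
}
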