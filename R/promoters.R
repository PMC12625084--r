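# Promoter extraction and PWM-set enrichment: 2-kb promoter windows with
# length/ambiguity filters, odds-based affinity scoring against a PWM
# collection, per-motif log-normal backgrounds fitted over all promoters,
# group enrichment with BH correction, and universal-presence calls.

#' Extract promoter windows upstream of every gene's start codon
#'
#' Strand-aware windows of `length` bp ending at the base immediately before
#' the start codon (reverse-complemented for minus-strand genes), truncated
#' at chromosome edges. Genes without a CDS, promoters shorter than
#' `min_len`, and promoters with more than `max_ambiguous` ambiguous bases
#' are excluded with a logged reason.
#'
#' @param genome Named list of chromosome sequences (or a FASTA path).
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `strand`, `exons`).
#' @param length Promoter window size in bp (default 2000).
#' @param min_len Minimum retained promoter length (default 500).
#' @param max_ambiguous Maximum number of ambiguous bases (default 1500).
#' @return List with `promoters` (tibble `gene_id`, `sequence`) and
#'   `excluded` (tibble `gene_id`, `reason`).
#' @export
extract_promoters <- function(genome, genes, length = 2000, min_len = 500,
                              max_ambiguous = 1500) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    fa <- read_fasta(genome)
    genome <- setNames(as.list(fa$sequence), fa$id)
  }
  proms <- list(); excl <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (is.null(g$exons[[1]]) || nrow(g$exons[[1]]) == 0) {
      excl[[length(excl) + 1L]] <- tibble(gene_id = g$gene_id,
                                          reason = "no CDS")
      next
    }
    anchor <- cds_anchor(g)
    chrom_seq <- genome[[g$chrom]]
    abort_if(is.null(chrom_seq),
             paste("chromosome missing from genome:", g$chrom))
    if (g$strand == "+") {
      lo <- max(1L, anchor - length); hi <- anchor - 1L
      s <- if (hi >= lo) substr(chrom_seq, lo, hi) else ""
    } else {
      lo <- anchor + 1L; hi <- min(nchar(chrom_seq), anchor + length)
      s <- if (hi >= lo) revcomp_chr(substr(chrom_seq, lo, hi)) else ""
    }
    if (nchar(s) < min_len) {
      excl[[length(excl) + 1L]] <- tibble(gene_id = g$gene_id,
                                          reason = "shorter than min_len")
      next
    }
    n_amb <- nchar(s) - sum(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T"))
    if (n_amb > max_ambiguous) {
      excl[[length(excl) + 1L]] <- tibble(gene_id = g$gene_id,
                                          reason = "too many ambiguous bases")
      next
    }
    proms[[length(proms) + 1L]] <- tibble(gene_id = g$gene_id, sequence = s)
  }
  list(
    promoters = if (length(proms)) dplyr::bind_rows(proms) else
      tibble(gene_id = character(), sequence = character()),
    excluded = if (length(excl)) dplyr::bind_rows(excl) else
      tibble(gene_id = character(), reason = character())
  )
}

pwm_odds_matrix <- function(pwm, background) {
  sweep(pwm$matrix, 1, background, "/")
}

#' PWM affinity of a sequence
#'
#' Mean, over both strands and all start positions, of the per-window odds
#' product `prod_k M[k, base] / pi[base]`; ambiguous bases contribute an
#' odds factor of 1. The log of this affinity is the quantity the log-normal
#' background is fitted to.
#'
#' @param seq Nucleotide string (length >= motif width).
#' @param pwm PWM object (`list(id, matrix)`), rows A,C,G,T.
#' @param background Background nucleotide frequencies (A,C,G,T).
#' @return Affinity score (non-negative scalar).
#' @export
pwm_affinity <- function(seq, pwm, background = rep(0.25, 4)) {
  abort_if(nchar(seq) < ncol(pwm$matrix), "sequence shorter than motif")
  cpp_pwm_affinity(encode_dna(seq), pwm_odds_matrix(pwm, background))
}

# Plain-R reference scorer, kept as the independent oracle for the C++ path.
pwm_affinity_ref <- function(seq, pwm, background = rep(0.25, 4)) {
  odds <- pwm_odds_matrix(pwm, background)
  w <- ncol(odds)
  score_strand <- function(s) {
    v <- encode_dna(s)
    n <- length(v) - w + 1L
    vapply(seq_len(n), function(start) {
      prod(vapply(seq_len(w), function(k) {
        b <- v[start + k - 1L]
        if (b == 0L) 1 else odds[b, k]
      }, 0))
    }, 0)
  }
  fwd <- score_strand(seq)
  rev <- score_strand(revcomp_chr(seq))
  mean(c(fwd, rev))
}

#' Score every promoter against every motif
#'
#' @param promoters Tibble `gene_id`, `sequence`.
#' @param pwms Named list of PWM objects.
#' @param background Background nucleotide frequencies; `NULL` estimates
#'   them from the promoter set itself.
#' @return Numeric matrix (promoters x motifs) of affinity scores.
#' @export
score_promoters <- function(promoters, pwms, background = NULL) {
  if (is.null(background)) background <- base_frequencies(promoters$sequence)
  seqs <- lapply(promoters$sequence, encode_dna)
  odds <- lapply(pwms, pwm_odds_matrix, background = background)
  m <- cpp_pwm_affinity_matrix(seqs, unname(odds))
  dimnames(m) <- list(promoters$gene_id, names(pwms))
  m
}

base_frequencies <- function(seqs) {
  tab <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                      levels = c("A", "C", "G", "T")))
  p <- as.numeric(tab) / sum(tab)
  setNames(p, c("A", "C", "G", "T"))
}

#' Fit per-motif log-normal backgrounds
#'
#' `mu` and `sigma` are the mean and sd of `log(affinity)` over the
#' background promoters. Zero scores are floored at the smallest positive
#' score of that motif times 1e-3 before taking logs, so the log stays
#' defined without dominating the fit.
#'
#' @param scores Matrix of affinity scores (promoters x motifs) from
#'   [score_promoters()].
#' @return Tibble `motif_id`, `mu`, `sigma`, `n_background`, `epsilon`.
#' @export
fit_background <- function(scores) {
  abort_if(nrow(scores) < 2, "need >= 2 background promoters")
  dplyr::bind_rows(lapply(colnames(scores), function(m) {
    x <- scores[, m]
    pos <- x[x > 0]
    abort_if(length(pos) < 2,
             paste("fewer than 2 usable scores for motif", m))
    eps <- min(pos) * 1e-3
    lx <- log(pmax(x, eps))
    tibble(motif_id = m, mu = mean(lx), sigma = sd(lx),
           n_background = length(x), epsilon = eps)
  }))
}

#' Group enrichment of target promoters against the background
#'
#' One-sided z test of the target-set mean log affinity against the fitted
#' log-normal background: `z = (mean - mu) / (sigma / sqrt(n))`, upper-tail
#' normal p. A degenerate background (`sigma = 0`) yields p = 0 when the
#' target mean exceeds `mu` and p = 1 otherwise.
#'
#' @param target_scores Affinity matrix of the target promoter set
#'   (promoters x motifs).
#' @param bg Background tibble from [fit_background()].
#' @return Tibble `motif_id`, `mean_log_affinity`, `z`, `p`, `n_target`.
#' @export
group_enrichment <- function(target_scores, bg) {
  n <- nrow(target_scores)
  abort_if(n < 1, "empty target set")
  dplyr::bind_rows(lapply(seq_len(nrow(bg)), function(i) {
    m <- bg$motif_id[i]
    x <- target_scores[, m]
    lx <- log(pmax(x, bg$epsilon[i]))
    mlog <- mean(lx)
    if (bg$sigma[i] == 0) {
      p <- if (mlog > bg$mu[i]) 0 else 1
      z <- if (mlog > bg$mu[i]) Inf else -Inf
    } else {
      z <- (mlog - bg$mu[i]) / (bg$sigma[i] / sqrt(n))
      p <- pnorm(z, lower.tail = FALSE)
    }
    tibble(motif_id = m, mean_log_affinity = mlog, z = z, p = p,
           n_target = n)
  }))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  abort_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

max_logodds <- function(pwm, background) {
  sum(log(apply(pwm_odds_matrix(pwm, background), 2, max)))
}

#' Motifs present in every family promoter
#'
#' A motif is called present in a promoter when its best single-window
#' log-odds reaches `threshold_frac` of the motif's maximum achievable
#' log-odds; motifs present at least once in EVERY family promoter are
#' returned.
#'
#' @param promoters Family promoter tibble (`gene_id`, `sequence`; must be
#'   non-empty).
#' @param pwms Named list of PWM objects.
#' @param background Background nucleotide frequencies.
#' @param threshold_frac Fraction of the maximum log-odds (default 0.85).
#' @return Character vector of motif ids.
#' @export
universal_motifs <- function(promoters, pwms, background = rep(0.25, 4),
                             threshold_frac = 0.85) {
  abort_if(nrow(promoters) == 0, "empty family promoter set")
  if (length(pwms) == 0) return(character(0))
  seqs <- lapply(promoters$sequence, encode_dna)
  odds <- lapply(pwms, pwm_odds_matrix, background = background)
  best <- cpp_pwm_best_matrix(seqs, unname(odds))
  thr <- vapply(pwms, max_logodds, 0, background = background) * threshold_frac
  hit <- sweep(best, 2, thr, ">=")
  names(pwms)[colSums(hit) == nrow(promoters)]
}

#' Promoter-set motif enrichment analysis
#'
#' Runs the full enrichment stage: scores every promoter against every
#' motif, fits the per-motif log-normal background over ALL promoters
#' (genome-wide background), tests the family promoter set, adjusts with
#' Benjamini-Hochberg, flags motifs at `q <= q_threshold`, and calls
#' universally present motifs among the family promoters.
#'
#' @param promoters Promoter tibble for the whole gene set.
#' @param family_ids Gene ids of the family (the target set).
#' @param pwms Named list of PWM objects.
#' @param q_threshold Enrichment significance threshold (default 0.1).
#' @param background Background nucleotide frequencies; `NULL` estimates
#'   them from all promoters.
#' @param threshold_frac Presence threshold for universal calls.
#' @return Object of class `motif_enrichment`; see [tidy.motif_enrichment()].
#' @export
motif_enrichment <- function(promoters, family_ids, pwms, q_threshold = 0.1,
                             background = NULL, threshold_frac = 0.85) {
  abort_if(!any(promoters$gene_id %in% family_ids),
           "no family promoters present")
  if (is.null(background)) background <- base_frequencies(promoters$sequence)
  scores <- score_promoters(promoters, pwms, background)
  bg <- fit_background(scores)
  fam <- promoters$gene_id %in% family_ids
  enr <- group_enrichment(scores[fam, , drop = FALSE], bg)
  enr$q <- bh_adjust(enr$p)
  enr$enriched <- enr$q <= q_threshold

  fam_prom <- promoters[fam, ]
  seqs <- lapply(fam_prom$sequence, encode_dna)
  odds <- lapply(pwms, pwm_odds_matrix, background = background)
  best <- cpp_pwm_best_matrix(seqs, unname(odds))
  thr <- vapply(pwms, max_logodds, 0, background = background) * threshold_frac
  hit <- sweep(best, 2, thr, ">=")
  enr$presence_n <- colSums(hit)[match(enr$motif_id, names(pwms))]
  universal <- names(pwms)[colSums(hit) == nrow(fam_prom)]

  structure(list(
    table = enr |> select("motif_id", "mean_log_affinity", "z", "p", "q",
                          "enriched", "presence_n"),
    background = bg,
    universal = universal,
    n_target = sum(fam),
    n_background = nrow(promoters),
    q_threshold = q_threshold
  ), class = "motif_enrichment")
}

#' @describeIn motif_enrichment Per-motif enrichment table.
#' @param x A `motif_enrichment` object.
#' @param ... Unused.
#' @export
tidy.motif_enrichment <- function(x, ...) x$table

#' @describeIn motif_enrichment One-row summary (counts of enriched and
#'   universal motifs, set sizes).
#' @export
glance.motif_enrichment <- function(x, ...) {
  tibble(n_motifs = nrow(x$table),
         n_enriched = sum(x$table$enriched),
         n_universal = length(x$universal),
         n_target = x$n_target,
         n_background = x$n_background,
         q_threshold = x$q_threshold)
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat("Promoter motif enrichment:", nrow(x$table), "motifs,",
      x$n_target, "target vs", x$n_background, "background promoters\n")
  cat(sum(x$table$enriched), "enriched at q <=", x$q_threshold, ";",
      length(x$universal), "universally present\n")
  print(head(arrange(x$table, .data$q), 10))
  invisible(x)
}

#' @describeIn motif_enrichment Volcano-style plot of z against -log10 q.
#' @param object A `motif_enrichment` object.
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  d <- mutate(object$table, neglog_q = -log10(pmax(.data$q, 1e-16)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$neglog_q,
                                  colour = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$q_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "enrichment z", y = "-log10 q", colour = "enriched") +
    ggplot2::theme_minimal()
}
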