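# Expression-expression Pearson correlation of family genes against a panel
# (e.g. flowering regulators), with t-based p-values and significance calls.

#' Pairwise Pearson correlation between two gene panels
#'
#' For every pair (a in `set_a`, b in `set_b`) computes the Pearson
#' correlation over shared samples, its two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))`, and a significance flag at `alpha`.
#' Constant expression vectors have undefined correlation and are reported
#' with `r = NA`, never coerced to zero.
#'
#' @param tpm Expression tibble: `gene_id` column plus one numeric column per
#'   sample.
#' @param set_a,set_b Character vectors of gene ids (must be present).
#' @param alpha Significance level for the flag.
#' @param log2 If `TRUE`, correlate `log2(TPM + 1)` instead of raw TPM.
#' @param adjust If `TRUE`, add a Benjamini-Hochberg `q` column.
#' @return Tibble `gene_a`, `gene_b`, `r`, `n`, `p`, `significant`
#'   (plus `q` when `adjust`).
#' @export
correlate_panels <- function(tpm, set_a, set_b, alpha = 0.05,
                             log2 = FALSE, adjust = FALSE) {
  missing <- setdiff(c(set_a, set_b), tpm$gene_id)
  abort_if(length(missing) > 0,
           paste("unknown gene id(s):", paste(missing, collapse = ", ")))
  mat <- as.matrix(tpm[, setdiff(names(tpm), "gene_id")])
  rownames(mat) <- tpm$gene_id
  if (log2) mat <- log2(mat + 1)
  n <- ncol(mat)
  abort_if(n < 3, "need >= 3 samples for correlation")
  grid <- tidyr::expand_grid(gene_a = set_a, gene_b = set_b)
  res <- purrr::pmap_dfr(grid, function(gene_a, gene_b) {
    x <- mat[gene_a, ]; y <- mat[gene_b, ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(gene_a = gene_a, gene_b = gene_b, r = NA_real_,
                    n = n, p = NA_real_, significant = NA))
    }
    r <- cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      t_stat <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(t_stat), df = n - 2)
    }
    tibble(gene_a = gene_a, gene_b = gene_b, r = r, n = n, p = p,
           significant = p <= alpha)
  })
  if (adjust) {
    res$q <- bh_adjust(res$p)
    res$significant <- res$q <= alpha & !is.na(res$q)
  }
  res
}

#' Top-expressed genes by mean TPM
#'
#' Ranks genes by mean TPM across all samples; ties broken by gene id.
#'
#' @param tpm Expression tibble (`gene_id` + sample columns).
#' @param k Number of genes to return (`<=` number of genes).
#' @return Tibble `gene_id`, `mean_tpm`, `rank`.
#' @export
top_expressed <- function(tpm, k) {
  abort_if(nrow(tpm) == 0, "empty expression matrix")
  abort_if(k > nrow(tpm), "k exceeds number of genes")
  mat <- as.matrix(tpm[, setdiff(names(tpm), "gene_id")])
  tibble(gene_id = tpm$gene_id, mean_tpm = rowMeans(mat)) |>
    arrange(desc(.data$mean_tpm), .data$gene_id) |>
    mutate(rank = row_number()) |>
    head(k)
}

#' Correlation panel plot
#'
#' Tile/point plot of a [correlate_panels()] table: fill encodes r, point
#' size encodes -log10(p), crosses mark significant pairs.
#'
#' @param cor_tbl Output of [correlate_panels()].
#' @return A ggplot object.
#' @export
plot_correlation <- function(cor_tbl) {
  ggplot2::ggplot(cor_tbl,
                  ggplot2::aes(x = .data$gene_b, y = .data$gene_a)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$r,
                                     size = -log10(pmax(.data$p, 1e-16)))) +
    ggplot2::scale_colour_gradient2(low = "red", mid = "white",
                                    high = "blue", limits = c(-1, 1)) +
    ggplot2::geom_point(data = function(d) d[which(d$significant), ],
                        shape = 4, size = 2) +
    ggplot2::labs(x = NULL, y = NULL, size = "-log10 p", colour = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
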