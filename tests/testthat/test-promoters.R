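# Promoter extraction and PWM enrichment machinery.

test_that("promoter windows respect strand, edges, and filters", {
  # hand-built 60-bp toy chromosome; bases chosen so windows are recognisable
  chrom <- paste0(strrep("A", 20), strrep("C", 10), strrep("G", 10),
                  strrep("T", 20))
  genes <- tibble::tibble(
    gene_id = c("plus", "minus"),
    chrom = "t", strand = c("+", "-"),
    start = c(31L, 11L), end = c(40L, 30L),
    exons = list(tibble::tibble(start = 31L, end = 40L),
                 tibble::tibble(start = 11L, end = 30L))
  )
  out <- extract_promoters(list(t = chrom), genes, length = 10,
                           min_len = 5, max_ambiguous = 100)
  expect_identical(nrow(out$promoters), 2L)
  # plus strand: 10 bases before position 31 = CCCCCCCCCC
  expect_identical(out$promoters$sequence[1], strrep("C", 10))
  # minus strand: downstream window [31, 40] = GGGGGGGGGG, reverse
  # complemented -> CCCCCCCCCC
  expect_identical(out$promoters$sequence[2], strrep("C", 10))

  # truncation below min_len excludes with a reason
  genes_short <- tibble::tibble(
    gene_id = "edge", chrom = "t", strand = "+", start = 4L, end = 10L,
    exons = list(tibble::tibble(start = 4L, end = 10L)))
  out2 <- extract_promoters(list(t = chrom), genes_short, length = 10,
                            min_len = 5, max_ambiguous = 100)
  expect_identical(nrow(out2$promoters), 0L)
  expect_match(out2$excluded$reason, "min_len")
})

test_that("the ambiguity filter excludes on 'more than' the cutoff", {
  mk <- function(n_N) paste0(strrep("N", n_N), strrep("A", 2000 - n_N))
  chrom <- paste0(mk(1500), strrep("T", 10))
  genes <- tibble::tibble(gene_id = "g", chrom = "c", strand = "+",
                          start = 2001L, end = 2010L,
                          exons = list(tibble::tibble(start = 2001L,
                                                      end = 2010L)))
  keep <- extract_promoters(list(c = chrom), genes)
  expect_identical(nrow(keep$promoters), 1L)
  chrom2 <- paste0(mk(1501), strrep("T", 10))
  drop <- extract_promoters(list(c = chrom2), genes)
  expect_identical(nrow(drop$promoters), 0L)
  expect_match(drop$excluded$reason, "ambiguous")
})

test_that("retained plus excluded counts always add to total genes", {
  sim <- small_sim()
  out <- extract_promoters(sim$genome, sim$genes)
  expect_identical(nrow(out$promoters) + nrow(out$excluded),
                   nrow(sim$genes))
})

test_that("affinity scoring matches hand-computable cases", {
  # uniform PWM equal to uniform background: odds 1 everywhere -> A = 1
  unif <- list(id = "u", matrix = matrix(0.25, 4, 8,
                                         dimnames = list(c("A", "C", "G", "T"),
                                                         NULL)))
  withr::local_seed(41)
  seq <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  expect_equal(pwm_affinity(seq, unif), 1, tolerance = 1e-12)
  # width-1 PWM P(A)=1 on "AAAA": forward odds 4 at 4 windows, reverse 0
  w1 <- list(id = "w1", matrix = matrix(c(1, 0, 0, 0), 4, 1,
                                        dimnames = list(c("A", "C", "G", "T"),
                                                        NULL)))
  expect_equal(pwm_affinity("AAAA", w1), 2)
  expect_error(pwm_affinity("AC", unif), "shorter")
})

test_that("affinity is strand-symmetric and ambiguity-neutral", {
  withr::local_seed(43)
  pwm <- simulate_pwm_collection(small_config(), n = 1, width = 6)[[1]]
  for (i in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    expect_equal(pwm_affinity(seq, pwm), pwm_affinity(rc, pwm),
                 tolerance = 1e-12)
  }
  # N contributes odds 1: equivalent to multiplying matched windows by 1
  expect_equal(pwm_affinity(strrep("N", 30), pwm), 1, tolerance = 1e-12)
})

test_that("C++ scorer agrees with the plain-R reference implementation", {
  withr::local_seed(47)
  cfgs <- simulate_pwm_collection(small_config(), n = 5, width = 7)
  for (i in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
    pwm <- cfgs[[sample(5, 1)]]
    bg <- runif(4, 0.5, 1.5); bg <- bg / sum(bg)
    expect_equal(pwm_affinity(seq, pwm, bg),
                 genefamr:::pwm_affinity_ref(seq, pwm, bg),
                 tolerance = 1e-9)
  }
})

test_that("background fits recover known log-normal parameters", {
  scores <- matrix(exp(1), nrow = 10, ncol = 1,
                   dimnames = list(NULL, "m"))
  bg <- fit_background(scores)
  expect_equal(bg$mu, 1, tolerance = 1e-12)
  expect_equal(bg$sigma, 0, tolerance = 1e-12)
  withr::local_seed(51)
  big <- matrix(rlnorm(10000, meanlog = 1, sdlog = 0.5), ncol = 1,
                dimnames = list(NULL, "m"))
  fit <- fit_background(big)
  expect_equal(fit$mu, 1, tolerance = 0.02)
  expect_equal(fit$sigma, 0.5, tolerance = 0.02)
  expect_error(fit_background(big[1, , drop = FALSE]), ">= 2")
})

test_that("zero scores are floored, duplicates shift only the weighting", {
  scores <- matrix(c(0, 1, 2, 4), ncol = 1, dimnames = list(NULL, "m"))
  bg <- fit_background(scores)
  expect_equal(bg$epsilon, 1e-3)
  expect_true(is.finite(bg$mu))
  dup <- matrix(c(2, 2, 8), ncol = 1, dimnames = list(NULL, "m"))
  bg2 <- fit_background(dup)
  expect_equal(bg2$mu, (2 * log(2) + log(8)) / 3, tolerance = 1e-12)
})

test_that("group enrichment reduces to the normal tail", {
  bg <- tibble::tibble(motif_id = "m", mu = 0.5, sigma = 0.2,
                       n_background = 100, epsilon = 1e-8)
  # target mean equal to mu -> p = 0.5
  t1 <- matrix(exp(0.5), nrow = 4, ncol = 1, dimnames = list(NULL, "m"))
  expect_equal(group_enrichment(t1, bg)$p, 0.5, tolerance = 1e-12)
  # z = 1.6449 -> p ~ 0.05
  n <- 9
  target_mean <- 0.5 + 1.6449 * 0.2 / sqrt(n)
  t2 <- matrix(exp(target_mean), nrow = n, ncol = 1,
               dimnames = list(NULL, "m"))
  out <- group_enrichment(t2, bg)
  expect_equal(out$z, 1.6449, tolerance = 1e-4)
  expect_equal(out$p, 0.05, tolerance = 1e-4)
  # degenerate background
  bg0 <- dplyr::mutate(bg, sigma = 0)
  expect_equal(group_enrichment(t2, bg0)$p, 0)
  low <- matrix(exp(0.2), nrow = 3, ncol = 1, dimnames = list(NULL, "m"))
  expect_equal(group_enrichment(low, bg0)$p, 1)
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("universal motifs require presence in every family promoter", {
  cfg <- small_config(planted_motifs = list(
    list(id = "M001", family_rate = 1, background_rate = 0)))
  sim <- small_sim()
  pwms <- simulate_pwm_collection(cfg, n = 3)
  prom <- extract_promoters(sim$genome, sim$genes)$promoters
  fam <- sim$truth$family_ids
  planted <- plant_promoter_motifs(prom, cfg, fam, pwms)
  fam_prom <- planted$promoters[planted$promoters$gene_id %in% fam, ]
  uni <- universal_motifs(fam_prom, pwms)
  expect_true("M001" %in% uni)
  # knock the motif out of one family promoter: no longer universal
  fam_prom2 <- fam_prom
  fam_prom2$sequence[1] <- strrep("A", nchar(fam_prom2$sequence[1]))
  expect_false("M001" %in% universal_motifs(fam_prom2, pwms))
  expect_identical(universal_motifs(fam_prom, list()), character(0))
  expect_error(universal_motifs(fam_prom[0, ], pwms), "empty")
})

test_that("PWM files round-trip through both dialects", {
  cfg <- small_config()
  pwms <- simulate_pwm_collection(cfg, n = 3, width = 6)
  dir <- withr::local_tempdir()
  jaspar <- file.path(dir, "j.txt")
  write_pwms(pwms, jaspar)
  back <- read_pwms(jaspar, pseudocount = 0)
  expect_setequal(names(back), names(pwms))
  for (nm in names(pwms)) {
    expect_equal(back[[nm]]$matrix, pwms[[nm]]$matrix, tolerance = 1e-3)
  }
  # TRANSFAC-like dialect
  transfac <- file.path(dir, "t.txt")
  m <- pwms[[1]]$matrix
  lines <- c("ID MT01", "P0 A C G T",
             vapply(seq_len(ncol(m)), function(k)
               paste(c(sprintf("%02d", k), format(m[, k], digits = 6)),
                     collapse = " "), ""),
             "//")
  writeLines(lines, transfac)
  tf <- read_pwms(transfac)
  expect_identical(names(tf), "MT01")
  expect_equal(tf$MT01$matrix, m, tolerance = 1e-5)
})

test_that("full enrichment flags the planted motif and reports tidy output", {
  cfg <- small_config()
  sim <- small_sim()
  pwms <- simulate_pwm_collection(cfg, n = 10)
  prom <- extract_promoters(sim$genome, sim$genes)$promoters
  fam <- sim$truth$family_ids
  planted <- plant_promoter_motifs(prom, cfg, fam, pwms)
  enr <- motif_enrichment(planted$promoters, fam, pwms)
  tb <- tidy(enr)
  expect_identical(tb$motif_id[which.min(tb$p)], "M001")
  expect_true(tb$enriched[tb$motif_id == "M001"])
  expect_true(all(tb$q >= tb$p, na.rm = TRUE))
  g <- glance(enr)
  expect_identical(g$n_target, length(fam))
  expect_s3_class(autoplot(enr), "ggplot")
})
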