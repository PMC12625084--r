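# Independent oracles used by the equivalence tests.

# Brute-force PROSITE matcher: interprets the pattern element by element with
# explicit repeat expansion, scanning every start position. Independent of
# the regex-based implementation.
parse_prosite_elements <- function(pattern) {
  elems <- strsplit(sub("\\.$", "", pattern), "-", fixed = TRUE)[[1]]
  lapply(elems, function(e) {
    m <- regmatches(e, regexec("^(.*?)(\\(([0-9]+)(,([0-9]+))?\\))?$", e))[[1]]
    core <- m[2]
    lo <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    hi <- if (nzchar(m[6])) as.integer(m[6]) else lo
    match_fun <-
      if (core == "x") function(ch) TRUE
      else if (grepl("^\\[", core)) {
        allowed <- strsplit(gsub("[][]", "", core), "")[[1]]
        function(ch) ch %in% allowed
      } else if (grepl("^\\{", core)) {
        banned <- strsplit(gsub("[{}]", "", core), "")[[1]]
        function(ch) !(ch %in% banned)
      } else {
        function(ch) ch == core
      }
    list(f = match_fun, lo = lo, hi = hi)
  })
}

brute_prosite_count <- function(sequence, pattern) {
  if (!nzchar(sequence)) return(0L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  els <- parse_prosite_elements(pattern)
  n <- length(chars)
  matches_from <- function(pos, k) {
    if (k > length(els)) return(TRUE)
    el <- els[[k]]
    for (reps in el$lo:el$hi) {
      if (pos + reps - 1L > n) next
      if (reps > 0 && !all(vapply(chars[pos:(pos + reps - 1L)], el$f, TRUE)))
        next
      if (matches_from(pos + reps, k + 1L)) return(TRUE)
    }
    FALSE
  }
  sum(vapply(seq_len(n), function(p) matches_from(p, 1L), TRUE))
}

# Whole-CDS translation oracle for consequence calls: mutate the CDS base
# directly, translate both sequences with Biostrings, and compare proteins.
translate_oracle <- function(cds, cds_pos, alt) {
  mut <- cds
  substr(mut, cds_pos, cds_pos) <- alt
  p0 <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                           no.init.codon = TRUE))
  if (identical(p0, p1)) {
    list(effect = "synonymous", change = NA_character_)
  } else {
    i <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
    aa3 <- genefamr:::AA3
    list(effect = "nonsynonymous",
         change = paste0(aa3[substr(p0, i, i)], i, aa3[substr(p1, i, i)]))
  }
}

# Random collinearity instance for the chain-search equivalence tests.
random_anchor_instance <- function(n_max = 12L, rank_max = 40L) {
  n <- sample(2:n_max, 1)
  tibble::tibble(
    gene_a = paste0("a", seq_len(n)),
    gene_b = paste0("b", seq_len(n)),
    rank_a = sample(0:rank_max, n),
    rank_b = sample(0:rank_max, n)
  )
}
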