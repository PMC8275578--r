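# Independent oracles used across tests; deliberately naive implementations
# that never share code with the package.

# character-by-character pair scan: non-ACGT bases excluded from counts and
# breaking dinucleotide adjacency
oracle_count_dinucs <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  acgt <- ch %in% c("A", "C", "G", "T")
  n_cpg <- 0L
  for (i in seq_len(length(ch) - 1L)) {
    if (acgt[i] && acgt[i + 1L] && ch[i] == "C" && ch[i + 1L] == "G")
      n_cpg <- n_cpg + 1L
  }
  c(n_cpg = n_cpg, n_c = sum(ch == "C" & acgt), n_g = sum(ch == "G" & acgt),
    l = sum(acgt))
}

oracle_cpg_oe <- function(seq) {
  cnt <- oracle_count_dinucs(seq)
  if (cnt["n_c"] == 0 || cnt["n_g"] == 0) return(NA_real_)
  unname(cnt["n_cpg"] / (cnt["n_c"] * cnt["n_g"]) *
           cnt["l"]^2 / (cnt["l"] - 1))
}

# two-sided Fisher p by full hypergeometric enumeration (stats::dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  support <- max(0L, (a + c) - (c + d)):min(a + c, m)
  pr <- dhyper(support, m, c + d, a + c)
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

random_dna <- function(len, with_ambiguous = FALSE) {
  alphabet <- c("A", "C", "G", "T")
  probs <- rep(0.25, 4)
  if (with_ambiguous) {
    alphabet <- c(alphabet, "N")
    probs <- c(rep(0.24, 4), 0.04)
  }
  paste(sample(alphabet, len, replace = TRUE, prob = probs), collapse = "")
}

write_toy_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# DE table built directly from simulation truth, bypassing the count model:
# used where a flexibility test needs known DEG flags rather than a fitted
# DE stage
truth_de_table <- function(truth, which = c("origin", "treatment")) {
  which <- match.arg(which)
  resp <- truth[[paste0(which, "_responsive")]]
  fc <- truth[[paste0(which, "_log2fc")]]
  data.frame(gene_id = truth$gene_id,
             log2_fc = fc,
             magnitude = fc * log10(2),
             p = ifelse(resp, 1e-6, 0.5),
             fdr = ifelse(resp, 1e-5, 0.9),
             is_deg = resp,
             stringsAsFactors = FALSE)
}
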