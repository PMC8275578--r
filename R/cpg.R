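#' Count CpG dinucleotides and C/G bases per gene
#'
#' Counts overlapping `CG` dinucleotides scanning 5'->3' on the given strand,
#' together with the number of C bases, G bases, and counted bases.
#' Ambiguous bases (anything outside A/C/G/T, e.g. N) are excluded from all
#' counts and break dinucleotide adjacency: `CNG` contains no CpG.
#'
#' @param seqs A [Biostrings::DNAStringSet] (named by gene id) or a named
#'   character vector of DNA sequences.
#' @return A data.frame with columns `gene_id`, `l` (number of A/C/G/T bases),
#'   `n_cpg`, `n_c`, `n_g`.
#' @export
count_dinucleotides <- function(seqs) {
  seqs <- as_dna(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  # literal CG matching cannot span an ambiguity code, so N already breaks
  # adjacency; CG has no self-overlap, so pattern counts are the overlap
  # counts.
  n_cpg <- Biostrings::vcountPattern("CG", seqs, fixed = TRUE)
  lf <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  data.frame(
    gene_id = ids,
    l = as.integer(rowSums(lf)),
    n_cpg = as.integer(n_cpg),
    n_c = as.integer(lf[, "C"]),
    n_g = as.integer(lf[, "G"]),
    stringsAsFactors = FALSE
  )
}

as_dna <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) return(seqs)
  if (is.character(seqs)) {
    out <- Biostrings::DNAStringSet(toupper(seqs))
    names(out) <- names(seqs)
    return(out)
  }
  stop("'seqs' must be a DNAStringSet or character vector")
}

#' Length-corrected CpG observed/expected ratio
#'
#' Computes `CpG_O/E = n_cpg / (n_c * n_g) * l^2 / (l - 1)`, the observed
#' CpG count over its expectation under base independence, with the
#' `l^2/(l-1)` term correcting for gene length. The ratio is undefined
#' (returned as `NA`) when a sequence has no C or no G.
#'
#' @param n_cpg,n_c,n_g,l Vectors of dinucleotide/base counts as returned by
#'   [count_dinucleotides()].
#' @return Numeric vector of CpG O/E ratios (`NA` where undefined).
#' @export
compute_cpg_oe <- function(n_cpg, n_c, n_g, l) {
  if (any(l < 2L)) {
    stop("degenerate gene(s) with fewer than 2 counted bases: ",
         paste(which(l < 2L), collapse = ", "))
  }
  oe <- ifelse(n_c > 0L & n_g > 0L,
               n_cpg / (as.numeric(n_c) * as.numeric(n_g)) *
                 as.numeric(l)^2 / (as.numeric(l) - 1),
               NA_real_)
  oe
}

#' Profile a transcriptome's CpG depletion
#'
#' Computes per-gene CpG O/E ratios and applies the profiling filters:
#' genes shorter than `min_length` counted bases, genes with an undefined
#' ratio (no C or no G), and optionally genes above `max_oe` are excluded.
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param min_length Minimum number of counted (A/C/G/T) bases; default 201,
#'   a typical minimum contig length of de novo transcriptome assemblies.
#' @param max_oe Optional upper bound on the ratio; `NULL` (default) disables
#'   the cap.
#' @param quiet Suppress the exclusion-count message.
#' @return A data.frame of retained genes with columns `gene_id`, `l`,
#'   `n_cpg`, `n_c`, `n_g`, `cpg_oe`, plus an `"excluded"` attribute holding
#'   a data.frame (`gene_id`, `excluded_reason`) of dropped genes.
#' @export
profile_transcriptome <- function(seqs, min_length = 201L, max_oe = NULL,
                                  quiet = FALSE) {
  if (length(seqs) == 0L) stop("no sequences supplied")
  tab <- count_dinucleotides(seqs)
  reason <- rep(NA_character_, nrow(tab))
  reason[tab$l < min_length] <- "short"
  undef <- is.na(reason) & (tab$n_c == 0L | tab$n_g == 0L)
  reason[undef] <- "undefined_oe"
  tab$cpg_oe <- NA_real_
  ok <- is.na(reason)
  if (any(ok))
    tab$cpg_oe[ok] <- compute_cpg_oe(tab$n_cpg[ok], tab$n_c[ok],
                                     tab$n_g[ok], tab$l[ok])
  if (!is.null(max_oe))
    reason[is.na(reason) & tab$cpg_oe > max_oe] <- "above_max_oe"
  keep <- is.na(reason)
  if (!any(keep))
    stop("all ", nrow(tab), " genes excluded by profiling filters")
  excluded <- data.frame(gene_id = tab$gene_id[!keep],
                         excluded_reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (!quiet && nrow(excluded) > 0L)
    message("profile_transcriptome: excluded ", nrow(excluded), " of ",
            nrow(tab), " genes (",
            paste(sprintf("%s: %d", names(table(excluded$excluded_reason)),
                          table(excluded$excluded_reason)), collapse = ", "),
            ")")
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Write a CpG profile (retained + excluded genes) as TSV
#'
#' @param profile Result of [profile_transcriptome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_profile <- function(profile, path) {
  kept <- profile
  kept$excluded_reason <- NA_character_
  excl <- attr(profile, "excluded")
  if (!is.null(excl) && nrow(excl) > 0L) {
    pad <- data.frame(gene_id = excl$gene_id, l = NA_integer_,
                      n_cpg = NA_integer_, n_c = NA_integer_,
                      n_g = NA_integer_, cpg_oe = NA_real_,
                      excluded_reason = excl$excluded_reason,
                      stringsAsFactors = FALSE)
    kept <- rbind(kept, pad)
  }
  write_tsv(kept, path)
}
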