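#' Read transcript sequences from a FASTA file
#'
#' Reads a FASTA file of (already oriented, 5'->3') transcript sequences.
#' The gene identifier is the first whitespace-delimited token of each
#' header line; sequences are uppercased so downstream dinucleotide counting
#' is case-insensitive.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by gene id, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  validate_fasta_letters(path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, "", 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate gene id(s) in FASTA: ", paste(dup, collapse = ", "))
  if (any(Biostrings::width(seqs) < 1L))
    stop("zero-length sequence in FASTA: ",
         paste(ids[Biostrings::width(seqs) < 1L], collapse = ", "))
  # DNAStringSet construction already rejects non-IUPAC characters with a
  # positioned error; normalize case explicitly.
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  seqs
}

# readDNAStringSet silently drops letters outside the IUPAC alphabet; the
# contract wants a positioned error instead
validate_fasta_letters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seq_lines <- which(!startsWith(lines, ">") & nzchar(lines))
  bad <- regexpr("[^ACGTMRWSYKVHDBNacgtmrwsykvhdbn]", lines[seq_lines])
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    stop("non-IUPAC character '",
         substr(lines[seq_lines[i]], bad[i], bad[i]),
         "' at line ", seq_lines[i], ", position ", bad[i],
         " of ", path)
  }
  invisible(TRUE)
}

#' Read a count matrix and its sample design table
#'
#' The counts file is a TSV whose first column holds gene ids and whose
#' remaining columns are samples; the design file is a TSV with columns
#' `sample_id`, `origin` (`cold`/`warm`), `treatment` (`control`/`heated`)
#' and `replicate`. Every counts column must be described in the design
#' and vice versa.
#'
#' @param counts_path Path to the counts TSV.
#' @param design_path Path to the design TSV.
#' @return A list with `counts` (integer matrix, genes x samples) and
#'   `design` (data.frame with the design columns, in counts-column order).
#' @export
read_counts <- function(counts_path, design_path) {
  for (p in c(counts_path, design_path))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- read.delim(counts_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("counts file has no sample columns: ", counts_path)
  gene_ids <- as.character(raw[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s) in counts: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("missing values in counts matrix")
  if (any(mat < 0)) stop("negative count in counts matrix")
  if (any(mat != round(mat))) {
    bad <- which(mat != round(mat), arr.ind = TRUE)[1L, ]
    stop("non-integer count for gene '", gene_ids[bad[1L]], "', sample '",
         colnames(mat)[bad[2L]], "'")
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- gene_ids

  design <- read.delim(design_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  design <- validate_design(design)
  missing_design <- setdiff(colnames(mat), design$sample_id)
  if (length(missing_design) > 0L)
    stop("sample(s) in counts missing from design: ",
         paste(missing_design, collapse = ", "))
  missing_counts <- setdiff(design$sample_id, colnames(mat))
  if (length(missing_counts) > 0L)
    stop("sample(s) in design missing from counts: ",
         paste(missing_counts, collapse = ", "))
  design <- design[match(colnames(mat), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  list(counts = mat, design = design)
}

validate_design <- function(design) {
  req <- c("sample_id", "origin", "treatment", "replicate")
  miss <- setdiff(req, colnames(design))
  if (length(miss) > 0L)
    stop("design table missing column(s): ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id(s) in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  if (!all(design$origin %in% c("cold", "warm")))
    stop("design origin must be 'cold' or 'warm'")
  if (!all(design$treatment %in% c("control", "heated")))
    stop("design treatment must be 'control' or 'heated'")
  design$replicate <- as.integer(design$replicate)
  if (anyNA(design$replicate) || any(design$replicate < 1L))
    stop("design replicate must be a positive integer")
  design
}

#' Read gene-to-GO annotations
#'
#' Two-column TSV (no header): `gene_id<TAB>term`, one pair per line.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `gene_id` and `term`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE,
                    col.names = c("gene_id", "term"))
  if (nrow(ann) == 0L) stop("annotation file is empty: ", path)
  unique(ann)
}

#' Read GO is_a edges
#'
#' Two-column TSV (no header): `child<TAB>parent`, one is_a edge per line.
#'
#' @param path Path to the edge-list TSV.
#' @return A data.frame with columns `child` and `parent`.
#' @export
read_ontology_edges <- function(path) {
  if (!file.exists(path)) stop("ontology edge file not found: ", path)
  edges <- read.delim(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE,
                      col.names = c("child", "parent"))
  unique(edges)
}

#' Read a GO-slim term list
#'
#' One term per line.
#'
#' @param path Path to the slim list.
#' @return Character vector of slim terms.
#' @export
read_slim_terms <- function(path) {
  if (!file.exists(path)) stop("slim list not found: ", path)
  slim <- unique(trimws(readLines(path)))
  slim <- slim[nzchar(slim)]
  if (length(slim) == 0L) stop("slim list is empty: ", path)
  slim
}

#' Write a numeric table as TSV
#'
#' Numeric columns are serialized with 6 significant digits so repeated runs
#' diff cleanly; character/integer columns are written verbatim.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- signif(out[[j]], 6L)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
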