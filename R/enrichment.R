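#' Map gene annotations to a GO-slim term set
#'
#' Ancestor-closure slim mapping: every annotated term maps to the slim
#' terms found among its is_a ancestors (the term itself included). Genes
#' none of whose terms reach a slim term are reported as unassigned.
#'
#' @param annotations data.frame with columns `gene_id`, `term`.
#' @param is_a_edges data.frame with columns `child`, `parent`
#'   (acyclic is_a edges); may have zero rows when annotations already use
#'   slim terms.
#' @param slim_terms Character vector of slim terms (non-empty).
#' @return List with `gene2slim` (data.frame `gene_id`, `term`, one row per
#'   gene/slim-term pair) and `unassigned` (character vector of gene ids).
#' @export
map_to_slim <- function(annotations, is_a_edges, slim_terms) {
  if (length(slim_terms) == 0L) stop("slim term list is empty")
  stopifnot(all(c("gene_id", "term") %in% colnames(annotations)))
  terms <- unique(annotations$term)
  anc <- term_ancestors(terms, is_a_edges)
  term2slim <- lapply(anc, intersect, slim_terms)
  hits <- annotations[lengths(term2slim[annotations$term]) > 0L, ,
                      drop = FALSE]
  if (nrow(hits) > 0L) {
    slim_list <- term2slim[hits$term]
    gene2slim <- unique(data.frame(
      gene_id = rep(hits$gene_id, lengths(slim_list)),
      term = unlist(slim_list, use.names = FALSE),
      stringsAsFactors = FALSE))
    rownames(gene2slim) <- NULL
  } else {
    gene2slim <- data.frame(gene_id = character(0), term = character(0),
                            stringsAsFactors = FALSE)
  }
  unassigned <- setdiff(unique(annotations$gene_id), gene2slim$gene_id)
  if (length(unassigned) > 0L)
    message("map_to_slim: ", length(unassigned),
            " annotated gene(s) reach no slim term")
  list(gene2slim = gene2slim, unassigned = unassigned)
}

# ancestor sets (self included) for each term over the is_a DAG
term_ancestors <- function(terms, is_a_edges) {
  if (is.null(is_a_edges) || nrow(is_a_edges) == 0L)
    return(setNames(as.list(terms), terms))
  stopifnot(all(c("child", "parent") %in% colnames(is_a_edges)))
  g <- igraph::graph_from_data_frame(
    is_a_edges[, c("child", "parent")], directed = TRUE)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    member <- igraph::ends(g, cyc[1])[1, 1]
    stop("is_a edges contain a cycle (involving term '", member, "')")
  }
  vnames <- igraph::V(g)$name
  setNames(lapply(terms, function(tm) {
    if (!tm %in% vnames) return(tm)
    reach <- igraph::subcomponent(g, tm, mode = "out")
    union(tm, reach$name)
  }), terms)
}

#' Per-slim-term CpG O/E summary
#'
#' Mean CpG O/E (+/- standard error) over the genes annotated to each slim
#' term; genes carrying several terms contribute to each of them.
#'
#' @param slim Result of [map_to_slim()] (or a data.frame like its
#'   `gene2slim` element).
#' @param records CpG profile data.frame (`gene_id`, `cpg_oe`).
#' @return data.frame with `term`, `n_genes`, `mean_cpg_oe`, `se_cpg_oe`
#'   (0 with `single_gene = TRUE` for one-gene terms), sorted by ascending
#'   mean.
#' @export
category_cpg_summary <- function(slim, records) {
  g2s <- if (is.data.frame(slim)) slim else slim$gene2slim
  m <- merge(g2s, records[, c("gene_id", "cpg_oe")], by = "gene_id")
  if (nrow(m) == 0L) stop("no annotated gene has a CpG profile")
  dropped <- setdiff(unique(g2s$term), unique(m$term))
  if (length(dropped) > 0L)
    message("category_cpg_summary: ", length(dropped),
            " term(s) without profiled genes omitted")
  spl <- split(m$cpg_oe, m$term)
  out <- data.frame(
    term = names(spl),
    n_genes = lengths(spl),
    mean_cpg_oe = vapply(spl, mean, 0),
    se_cpg_oe = vapply(spl, function(v)
      if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0, 0),
    single_gene = lengths(spl) == 1L,
    stringsAsFactors = FALSE)
  out <- out[order(out$mean_cpg_oe), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-term enrichment of the low- and high-CpG components
#'
#' For every slim term and each component, genes in the component are
#' compared against the background of all classified, annotated genes with
#' a 2x2 Fisher exact test (in-term/not-in-term x component/background).
#' FDR correction (Benjamini-Hochberg) is applied across terms within each
#' component. A term annotating every gene (or none) is uninformative and
#' reported with odds ratio 1.
#'
#' @param split A `cpg_split` from [classify_genes()].
#' @param slim Result of [map_to_slim()] (or its `gene2slim` data.frame).
#' @param alpha Significance level for the `significant` flag.
#' @return data.frame with one row per term x component: counts, odds
#'   ratio, `p`, `fdr`, `direction` (`low-enriched`/`high-enriched`),
#'   `significant`, and `stars` at 0.05/0.01/0.001.
#' @export
fisher_enrichment <- function(split, slim, alpha = 0.05) {
  stopifnot(inherits(split, "cpg_split"))
  g2s <- if (is.data.frame(slim)) slim else slim$gene2slim
  genes <- split$genes
  g2s <- g2s[g2s$gene_id %in% genes$gene_id, , drop = FALSE]
  if (nrow(g2s) == 0L)
    stop("no genes shared between the component split and the annotations")
  bg <- unique(g2s$gene_id)  # background: all classified, annotated genes
  comp_of <- setNames(genes$component, genes$gene_id)
  terms <- sort(unique(g2s$term))
  term_genes <- split(g2s$gene_id, g2s$term)

  rows <- list()
  for (comp in c("low", "high")) {
    comp_genes <- bg[comp_of[bg] == comp]
    res <- lapply(terms, function(tm) {
      tg <- term_genes[[tm]]
      a <- sum(tg %in% comp_genes)          # in term, in component
      b <- length(comp_genes) - a           # not in term, in component
      cc <- length(tg)                      # in term, background
      d <- length(bg) - cc                  # not in term, background
      ft <- fisher_exact_2x2(a, b, cc, d)
      or <- ft$odds_ratio
      if (is.nan(or)) or <- 1  # term covers all genes or none: no signal
      data.frame(term = tm, component = comp,
                 n_in_component = a, n_component = length(comp_genes),
                 n_in_background = cc, n_background = length(bg),
                 odds_ratio = or, p = ft$p_value,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$fdr <- bh_fdr(res$p)
    rows[[comp]] <- res
  }
  out <- do.call(rbind, rows)
  out$direction <- ifelse(out$odds_ratio > 1,
                          paste0(out$component, "-enriched"),
                          paste0(ifelse(out$component == "low",
                                        "high", "low"), "-enriched"))
  out$significant <- out$fdr < alpha
  out$stars <- significance_stars(out$fdr)
  rownames(out) <- NULL
  out
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}
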