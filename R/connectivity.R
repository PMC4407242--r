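#' Genes associated with every disease in a combination
#'
#' The comorbid gene set of two or more diseases: the intersection of their
#' per-disease association sets. Anti-monotone in the number of diseases —
#' adding a disease can only shrink the set.
#'
#' @param kb A [knowledge_base()].
#' @param disease_ids Character vector of one or more disease ids.
#' @return Character vector of gene ids, radix-sorted.
#' @export
comorbid_gene_set <- function(kb, disease_ids) {
  stopifnot(length(disease_ids) >= 1L)
  sets <- lapply(disease_ids, genes_for, kb = kb)
  sort(Reduce(intersect, sets), method = "radix")
}

#' Subnetwork induced by a gene set
#'
#' All knowledge-base interactions whose two endpoints both lie in
#' `gene_ids`, reported both as distinct connected node pairs and as link
#' records (a pair linked by several typed interactions counts once as a
#' pair but once per record as a link).
#'
#' @param kb A [knowledge_base()].
#' @param gene_ids Character vector of node ids present in `kb`.
#' @return An object of class `induced_subnetwork`: a list with `genes`,
#'   `links` (tibble of interaction records), `n_genes`,
#'   `n_connected_pairs`, `n_links`.
#' @export
induced_subnetwork <- function(kb, gene_ids) {
  gene_ids <- unique(gene_ids)
  miss <- setdiff(gene_ids, kb$genes$id)
  if (length(miss)) {
    stop("unknown gene id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  links <- kb$interactions[kb$interactions$a_id %in% gene_ids &
                             kb$interactions$b_id %in% gene_ids, ]
  structure(list(
    genes = sort(gene_ids, method = "radix"),
    links = links,
    n_genes = length(gene_ids),
    n_connected_pairs = nrow(distinct_pairs(links)),
    n_links = nrow(links)),
    class = "induced_subnetwork")
}

#' @export
print.induced_subnetwork <- function(x, ...) {
  cat("<induced_subnetwork> ", x$n_genes, " genes, ",
      x$n_connected_pairs, " connected pairs, ", x$n_links,
      " link records\n", sep = "")
  invisible(x)
}

#' Connectivity of a comorbid gene set, with degree-matched significance
#'
#' Builds the comorbid gene set of a disease combination (or takes an
#' explicit gene set), induces its subnetwork on the knowledge base, and
#' tests whether the set is more interconnected than degree-matched chance:
#' the p-value is the proportion of `n_null` degree-matched random networks
#' (see [connectivity_null()]) whose connectivity is the same or greater
#' than observed.
#'
#' @param kb A [knowledge_base()].
#' @param disease_ids Disease combination (two or more ids) whose shared
#'   genes form the analysed set; ignored when `genes` is given.
#' @param genes Optional explicit gene set to analyse.
#' @param n_null Number of random networks; 1000 mirrors common practice.
#' @param seed Integer seed.
#' @param stat Connectivity statistic for the test: `"pairs"` (distinct
#'   connected pairs, default) or `"links"` (link records).
#' @param tie Tie convention, see [empirical_pvalue()].
#' @param protein_level If `TRUE`, collapse the knowledge base to a
#'   protein-protein network with [collapse_to_protein_network()] before
#'   analysing.
#' @param keep_samples Passed to [connectivity_null()].
#' @return An object of class `connectivity_report`: a list with
#'   `disease_ids`, `genes`, `n_genes`, `n_connected_pairs`, `n_links`,
#'   `statistic`, `observed`, `p_value`, `n_null`, `seed`, `null` (the
#'   [connectivity_null()] object) and `subnetwork`.
#' @export
score_connectivity <- function(kb, disease_ids = NULL, genes = NULL,
                               n_null = 1000L, seed = 1L,
                               stat = c("pairs", "links"),
                               tie = c("paper", "add_one"),
                               protein_level = FALSE,
                               keep_samples = FALSE) {
  stat <- match.arg(stat)
  tie <- match.arg(tie)
  if (protein_level) kb <- collapse_to_protein_network(kb)
  if (is.null(genes)) {
    if (is.null(disease_ids)) {
      stop("give either disease_ids or genes", call. = FALSE)
    }
    genes <- comorbid_gene_set(kb, disease_ids)
  }
  if (length(genes) < 2L) {
    stop("the analysed gene set has fewer than 2 genes", call. = FALSE)
  }
  sub <- induced_subnetwork(kb, genes)
  observed <- if (stat == "pairs") sub$n_connected_pairs else sub$n_links
  null <- connectivity_null(kb, sub$genes, n = n_null, seed = seed,
                            stat = stat, keep_samples = keep_samples)
  structure(list(
    disease_ids = disease_ids, genes = sub$genes, n_genes = sub$n_genes,
    n_connected_pairs = sub$n_connected_pairs, n_links = sub$n_links,
    statistic = stat, observed = observed,
    p_value = empirical_pvalue(observed, null$values, tie = tie),
    n_null = n_null, seed = seed, null = null, subnetwork = sub),
    class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("<connectivity_report>\n")
  if (!is.null(x$disease_ids)) {
    cat("  diseases:  ", paste(x$disease_ids, collapse = " & "), "\n")
  }
  cat("  genes:     ", x$n_genes, "\n")
  cat("  observed:  ", x$observed, sprintf(" (%s)\n", x$statistic))
  cat("  p-value:   ", format(x$p_value), sprintf(" (n_null = %d)\n",
                                                  x$n_null))
  invisible(x)
}

#' Write connectivity reports as TSV
#'
#' @param reports A `connectivity_report` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_connectivity_report <- function(reports, path) {
  if (inherits(reports, "connectivity_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    tibble::tibble(
      diseases = paste(r$disease_ids, collapse = "|"),
      n_genes = r$n_genes,
      n_connected_pairs = r$n_connected_pairs,
      n_links = r$n_links,
      statistic = r$statistic,
      observed = r$observed,
      p_value = r$p_value,
      n_null = r$n_null,
      seed = r$seed)
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

#' Export an induced subnetwork as GraphML
#'
#' @param subnetwork An [induced_subnetwork()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_subnetwork_graphml <- function(subnetwork, path) {
  kb_like <- list(
    diseases = tibble::tibble(id = character(), name = character()),
    genes = tibble::tibble(id = subnetwork$genes,
                           symbol = subnetwork$genes,
                           entity_class = "gene",
                           coding_gene_id = NA_character_),
    associations = tibble::tibble(disease_id = character(),
                                  gene_id = character(),
                                  source = character()),
    interactions = subnetwork$links)
  write_graphml(kb_like, path)
}
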