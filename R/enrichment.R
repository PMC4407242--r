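#' Build an annotation set
#'
#' A term-to-gene annotation with an explicit reference universe. Every
#' annotated gene must belong to the universe; by default the universe is
#' the set of all annotated genes (the whole annotation as reference set).
#'
#' @param mapping Data frame with columns `term_id`, `gene_id` (duplicates
#'   dropped).
#' @param universe Optional character vector of gene ids; must contain every
#'   annotated gene.
#' @param term_names Optional named character vector mapping term ids to
#'   display names.
#' @return An object of class `annotation_set`: list with `mapping`
#'   (tibble), `universe`, `term_names`.
#' @export
annotation_set <- function(mapping, universe = NULL, term_names = NULL) {
  mapping <- tibble::as_tibble(mapping)[c("term_id", "gene_id")]
  mapping <- mapping[!duplicated(paste(mapping$term_id, mapping$gene_id,
                                       sep = "\r")), ]
  annotated <- unique(mapping$gene_id)
  if (is.null(universe)) {
    universe <- annotated
  } else {
    universe <- unique(universe)
    miss <- setdiff(annotated, universe)
    if (length(miss)) {
      stop("annotated gene(s) outside the reference universe: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(mapping = mapping,
                 universe = sort(universe, method = "radix"),
                 term_names = term_names),
            class = "annotation_set")
}

#' Read a GO annotation from GAF 2.1 or plain TSV
#'
#' GAF files (`!` comment lines; gene id in column 2, GO id in column 5)
#' and two-column `term_id<TAB>gene_id` TSVs (with or without that header)
#' are supported; the format is inferred from the content unless forced.
#'
#' @param path Annotation file path.
#' @param format `"auto"`, `"gaf"` or `"tsv"`.
#' @param universe Optional explicit reference universe.
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path, format = c("auto", "gaf", "tsv"),
                            universe = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^!gaf-version", lines)) ||
                  (length(lines) &&
                   length(strsplit(lines[!grepl("^[!#]", lines)][1],
                                   "\t")[[1]]) >= 5)) "gaf" else "tsv"
  }
  body <- lines[!grepl("^[!#]", lines) & nzchar(lines)]
  if (format == "gaf") {
    parts <- strsplit(body, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 5L)
    if (length(short)) {
      stop("malformed GAF rows: ", paste(short, collapse = ", "),
           call. = FALSE)
    }
    mapping <- tibble::tibble(
      term_id = vapply(parts, `[[`, character(1), 5L),
      gene_id = vapply(parts, `[[`, character(1), 2L))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 2L)
    if (length(short)) {
      stop("malformed annotation rows: ", paste(short, collapse = ", "),
           call. = FALSE)
    }
    mapping <- tibble::tibble(
      term_id = vapply(parts, `[[`, character(1), 1L),
      gene_id = vapply(parts, `[[`, character(1), 2L))
    if (nrow(mapping) && mapping$term_id[1] == "term_id") {
      mapping <- mapping[-1L, ]
    }
  }
  annotation_set(mapping, universe = universe)
}

#' Benjamini-Hochberg step-up q-values
#'
#' False-discovery-rate adjustment: q_(i) = min over j >= i of
#' m * p_(j) / j in sorted order, mapped back to the input order and capped
#' at 1. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overrepresentation of annotation terms
#'
#' For each term with at least one study gene, the exact upper-tail
#' hypergeometric p-value P(X >= k) of drawing k annotated genes in a study
#' set of size n, from a universe of N genes of which K carry the term,
#' with Benjamini-Hochberg q-values over all tested terms. Study genes
#' outside the reference universe are dropped with a warning.
#'
#' @param study Character vector of study gene ids.
#' @param annotation An [annotation_set()].
#' @return A tibble of class `enriched_processes`, one row per tested term:
#'   `term_id`, `term_name`, `k`, `n_study`, `K`, `N`, `p_value`,
#'   `q_value`, `cr` (`NA` until [add_connectivity_rate()] fills it), and a
#'   `study_genes` list-column with the term's study genes. Sorted by
#'   ascending p, ties by term id.
#' @export
hypergeometric_enrichment <- function(study, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  study <- unique(study)
  if (!length(study)) stop("empty study set", call. = FALSE)
  if (!nrow(annotation$mapping)) stop("empty annotation", call. = FALSE)
  outside <- setdiff(study, annotation$universe)
  if (length(outside)) {
    warning(length(outside), " study gene(s) outside the reference ",
            "universe dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
    study <- setdiff(study, outside)
  }
  if (!length(study)) stop("no study genes inside the universe",
                           call. = FALSE)
  N <- length(annotation$universe)
  n <- length(study)
  mp <- annotation$mapping
  terms <- split(mp$gene_id, mp$term_id)
  hits <- lapply(terms, intersect, study)
  k <- lengths(hits)
  keep <- k >= 1L
  terms <- terms[keep]; hits <- hits[keep]; k <- k[keep]
  K <- lengths(terms)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  nm <- names(terms)
  term_name <- if (!is.null(annotation$term_names)) {
    unname(ifelse(nm %in% names(annotation$term_names),
                  annotation$term_names[nm], nm))
  } else nm
  out <- tibble::tibble(
    term_id = nm, term_name = term_name,
    k = as.integer(unname(k)), n_study = n, K = as.integer(unname(K)),
    N = N, p_value = unname(p), q_value = benjamini_hochberg(unname(p)),
    cr = NA_real_,
    study_genes = unname(lapply(hits, sort, method = "radix")))
  out <- out[radix_order(out$term_id), ]
  out <- out[order(out$p_value), ]
  class(out) <- c("enriched_processes", class(out))
  out
}

#' Connectivity rate of a gene group in a network
#'
#' The fraction of the group's possible unordered gene pairs that are
#' directly linked in the analysed network: connected pairs divided by
#' C(|group|, 2). Groups of fewer than two genes have no defined rate and
#' return `NA`. Used to re-rank overrepresented processes: terms whose
#' study genes interact tightly score close to 1, diffuse general terms
#' score low.
#'
#' @param group Character vector of gene ids (duplicates ignored).
#' @param network An [induced_subnetwork()], a [knowledge_base()], or a
#'   data frame of interaction records with columns `a_id`, `b_id`.
#' @return A fraction in \[0, 1\], or `NA` when `|group| < 2`.
#' @examples
#' net <- data.frame(a_id = "a", link_type = "binding", b_id = "b")
#' connectivity_rate(c("a", "b", "c"), net)  # 1/3
#' @export
connectivity_rate <- function(group, network) {
  group <- unique(group)
  if (length(group) < 2L) return(NA_real_)
  links <- if (inherits(network, "induced_subnetwork")) network$links
  else if (inherits(network, "knowledge_base")) network$interactions
  else tibble::as_tibble(network)
  links <- links[links$a_id %in% group & links$b_id %in% group, ]
  nrow(distinct_pairs(links)) / choose(length(group), 2)
}

#' Attach connectivity rates to an enrichment table
#'
#' For every tested term, computes the [connectivity_rate()] of the term's
#' study genes within the analysed network (typically the subnetwork
#' induced by the comorbid gene set).
#'
#' @param processes An [hypergeometric_enrichment()] result.
#' @param network Passed to [connectivity_rate()].
#' @return The same tibble with the `cr` column filled.
#' @export
add_connectivity_rate <- function(processes, network) {
  processes$cr <- vapply(processes$study_genes, connectivity_rate,
                         numeric(1), network = network)
  processes
}

#' Rank enriched processes by connectivity rate
#'
#' Descending by CR; ties broken by ascending q-value, then ascending term
#' id; records with undefined CR (fewer than two study genes) are listed
#' after all scored records, themselves ordered by q then term id.
#'
#' @param processes An enrichment table with the `cr` column filled.
#' @return The reordered tibble.
#' @export
rank_by_cr <- function(processes) {
  if (!nrow(processes)) return(processes)
  missing_cr <- is.na(processes$cr)
  cr_key <- ifelse(missing_cr, -Inf, processes$cr)
  ord <- radix_order(-cr_key, processes$q_value, processes$term_id)
  processes[ord, ]
}

#' Write an enrichment table as TSV
#'
#' Columns term_id, name, k, n, K, N, p, q, CR, in the order given (use
#' [rank_by_cr()] first for the CR-ranked report).
#'
#' @param processes An enrichment table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(processes, path) {
  out <- tibble::tibble(
    term_id = processes$term_id, name = processes$term_name,
    k = processes$k, n = processes$n_study, K = processes$K,
    N = processes$N, p = processes$p_value, q = processes$q_value,
    CR = processes$cr)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
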