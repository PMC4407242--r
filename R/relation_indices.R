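#' Set-overlap relation indices between two gene sets
#'
#' Three indices quantify how strongly two diseases share associated genes,
#' given the gene sets A and B of the two diseases:
#' the intersection index I = |A intersect B|; the Jaccard index
#' J = |A intersect B| / |A union B|; and the Meet/Min index
#' M = |A intersect B| / min(|A|, |B|).
#'
#' Degenerate inputs yield `NA`, never 0: J is `NA` when both sets are
#' empty, M when either set is empty. This lets the permutation-null
#' machinery exclude undefined replicates instead of silently deflating the
#' null distribution (the usual practice is to discard diseases with no
#' associated genes up front).
#'
#' @param a,b Character vectors of gene ids (duplicates ignored).
#' @return `intersection_index()` a non-negative integer; the other two a
#'   fraction in \[0, 1\] or `NA`.
#' @examples
#' intersection_index(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g5"))  # 2
#' jaccard_index(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g5"))       # 0.4
#' meet_min_index(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g5"))      # 2/3
#' @export
intersection_index <- function(a, b) {
  length(intersect(unique(a), unique(b)))
}

#' @rdname intersection_index
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' @rdname intersection_index
#' @export
meet_min_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Relation indices for disease pairs, with empirical p-values
#'
#' Computes I, J and M for each requested disease pair on the knowledge
#' base's association table, and, when a null distribution of the indices
#' over random disease pairs is supplied (see [relation_index_null()]),
#' the empirical p-value of each observed index: the proportion of null
#' replicates with the same or larger value.
#'
#' @param kb A [knowledge_base()].
#' @param disease_a,disease_b Equal-length character vectors of disease ids;
#'   row i of the result describes the pair (disease_a\[i\], disease_b\[i\]).
#' @param null Optional result of [relation_index_null()] computed on the
#'   same knowledge base.
#' @param tie Tie convention passed to [empirical_pvalue()].
#' @return A tibble of class `relation_index_report` with one row per pair:
#'   sizes, `i_ab`, `j_ab`, `m_ab`, a `shared_genes` list-column, and
#'   (given a null) `p_i`, `p_j`, `p_m`, `n_null`, `seed`.
#' @export
relation_indices <- function(kb, disease_a, disease_b, null = NULL,
                             tie = c("paper", "add_one")) {
  stopifnot(length(disease_a) == length(disease_b))
  tie <- match.arg(tie)
  sets_a <- lapply(disease_a, genes_for, kb = kb)
  sets_b <- lapply(disease_b, genes_for, kb = kb)
  shared <- Map(intersect, sets_a, sets_b)
  out <- tibble::tibble(
    disease_a = disease_a,
    disease_b = disease_b,
    size_a = lengths(sets_a),
    size_b = lengths(sets_b),
    i_ab = lengths(shared),
    j_ab = unlist(Map(jaccard_index, sets_a, sets_b)),
    m_ab = unlist(Map(meet_min_index, sets_a, sets_b)),
    shared_genes = shared)
  if (!is.null(null)) {
    stopifnot(inherits(null, "relation_index_null"))
    out$p_i <- vapply(out$i_ab, empirical_pvalue, numeric(1),
                      null = null$values$i, tie = tie)
    out$p_j <- vapply(out$j_ab, empirical_pvalue, numeric(1),
                      null = null$values$j, tie = tie)
    out$p_m <- vapply(out$m_ab, empirical_pvalue, numeric(1),
                      null = null$values$m, tie = tie)
    out$n_null <- null$n
    out$seed <- null$seed
  }
  class(out) <- c("relation_index_report", class(out))
  out
}

#' Write a relation-index report as TSV
#'
#' One row per disease pair with columns disease_a, disease_b, size_a,
#' size_b, I, J, M and, when present, p_I, p_J, p_M, n_null, seed.
#'
#' @param report A [relation_indices()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_relation_report <- function(report, path) {
  out <- tibble::as_tibble(report)
  out$shared_genes <- NULL
  nm <- c(disease_a = "disease_a", disease_b = "disease_b",
          size_a = "size_a", size_b = "size_b",
          i_ab = "I", j_ab = "J", m_ab = "M",
          p_i = "p_I", p_j = "p_J", p_m = "p_M",
          n_null = "n_null", seed = "seed")
  names(out) <- unname(nm[names(out)])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
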