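#' Empirical permutation p-value
#'
#' The proportion of null replicates whose statistic is the same as or
#' larger than the observed value. Under this convention a p-value of
#' exactly 0 is possible; the `"add_one"` convention reports
#' (k + 1) / (n + 1) instead, which never reaches 0 and is mildly
#' conservative.
#'
#' @param observed A single non-missing statistic.
#' @param null Numeric vector of null replicates (`NA`s, from undefined
#'   replicates, are excluded).
#' @param tie `"paper"` for k / n (the default) or `"add_one"` for
#'   (k + 1) / (n + 1), where k counts replicates >= observed.
#' @return A fraction in \[0, 1\].
#' @examples
#' empirical_pvalue(3, c(1, 2, 3, 4))  # 0.5: ties count
#' @export
empirical_pvalue <- function(observed, null, tie = c("paper", "add_one")) {
  tie <- match.arg(tie)
  if (length(observed) != 1L || is.na(observed)) {
    stop("observed must be a single non-missing value", call. = FALSE)
  }
  null <- null[!is.na(null)]
  n <- length(null)
  if (n == 0L) stop("empty null distribution", call. = FALSE)
  k <- sum(null >= observed)
  if (tie == "paper") k / n else (k + 1) / (n + 1)
}

#' Sample random disease pairs
#'
#' Draws `n` unordered pairs of distinct diseases, uniformly over all
#' eligible pairs. A disease is eligible when it has at least one
#' associated gene; diseases with none are discarded from the null, the
#' same filter applied when large disease vocabularies carry many entries
#' with no known protein.
#'
#' @param kb A [knowledge_base()].
#' @param n Number of pairs.
#' @param seed Integer seed; the draw is reproducible from it.
#' @return A tibble with columns `disease_a`, `disease_b` and `n` rows.
#' @export
sample_random_disease_pairs <- function(kb, n, seed) {
  eligible <- eligible_diseases(kb)
  m <- length(eligible)
  if (m < 2L) stop("fewer than 2 diseases with associated genes",
                   call. = FALSE)
  stopifnot(n >= 1L)
  withr::with_seed(seed, {
    a <- sample.int(m, n, replace = TRUE)
    b <- sample.int(m - 1L, n, replace = TRUE)
    b <- b + (b >= a)
  })
  tibble::tibble(disease_a = eligible[a], disease_b = eligible[b])
}

eligible_diseases <- function(kb) {
  sort(intersect(kb$diseases$id, unique(kb$associations$disease_id)),
       method = "radix")
}

#' Null distribution of relation indices over random disease pairs
#'
#' Draws `n` random eligible disease pairs and computes the three relation
#' indices for each, giving the permutation null the observed indices of a
#' disease pair of interest are compared against.
#'
#' @inheritParams sample_random_disease_pairs
#' @return An object of class `relation_index_null` (and `associome_null`)
#'   with elements `values` (tibble of columns `i`, `j`, `m`), `n`, `seed`.
#' @seealso [relation_indices()] which consumes this null;
#'   [empirical_pvalue()].
#' @export
relation_index_null <- function(kb, n, seed) {
  pairs <- sample_random_disease_pairs(kb, n, seed)
  sets <- split(kb$associations$gene_id, kb$associations$disease_id)
  sets <- lapply(sets, unique)
  sa <- sets[pairs$disease_a]
  sb <- sets[pairs$disease_b]
  i <- mapply(function(a, b) length(intersect(a, b)), sa, sb,
              USE.NAMES = FALSE)
  la <- lengths(sa); lb <- lengths(sb)
  j <- i / (la + lb - i)
  m <- i / pmin(la, lb)
  structure(list(values = tibble::tibble(i = as.integer(i), j = j, m = m),
                 n = n, seed = seed, pairs = pairs),
            class = c("relation_index_null", "associome_null"))
}

#' @export
print.associome_null <- function(x, ...) {
  cat("<", class(x)[1], "> n = ", x$n, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Degree-matched candidate sets for network randomization
#'
#' For each vertex of an analysed network (the template), forms the set Q_i
#' of all knowledge-base nodes whose interaction degree equals the degree of
#' that vertex. Random networks built from these sets are matched to the
#' template in per-vertex degree, so their connectivity reflects chance
#' alone at the template's level of study. A vertex always matches its own
#' degree, so Q_i is never empty for template genes present in the
#' knowledge base; if a degree class were empty the set is widened to the
#' nearest available degree (ties toward the smaller degree) and the vertex
#' flagged as a fallback.
#'
#' @param kb A [knowledge_base()].
#' @param template_gene_ids Character vector (non-empty, no duplicates) of
#'   the analysed network's gene ids.
#' @param count Degree definition, see [gene_degree()].
#' @return An object of class `degree_matched_sampler`: a list with
#'   `template` (tibble: gene_id, degree, q_size, fallback), `q_sets`
#'   (list of candidate id vectors, one per template vertex) and `count`.
#' @export
build_q_sets <- function(kb, template_gene_ids,
                         count = c("partners", "records")) {
  count <- match.arg(count)
  if (length(template_gene_ids) == 0L) {
    stop("empty template", call. = FALSE)
  }
  if (anyDuplicated(template_gene_ids)) {
    stop("duplicate template gene ids", call. = FALSE)
  }
  miss <- setdiff(template_gene_ids, kb$genes$id)
  if (length(miss)) {
    stop("template gene(s) not in knowledge base: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  deg <- degree_vector(kb, count)
  by_degree <- split(names(deg), deg)
  tdeg <- unname(deg[template_gene_ids])
  avail <- as.integer(names(by_degree))
  fallback <- logical(length(template_gene_ids))
  q_sets <- vector("list", length(template_gene_ids))
  for (i in seq_along(template_gene_ids)) {
    d <- tdeg[i]
    q <- by_degree[[as.character(d)]]
    if (is.null(q) || !length(q)) {
      # widen to nearest degree, ties toward the smaller degree
      gap <- abs(avail - d)
      cand <- avail[gap == min(gap)]
      d2 <- min(cand)
      q <- by_degree[[as.character(d2)]]
      fallback[i] <- TRUE
      warning("no exact degree match for ", template_gene_ids[i],
              " (degree ", d, "); widened to degree ", d2, call. = FALSE)
    }
    q_sets[[i]] <- q
  }
  structure(list(
    template = tibble::tibble(gene_id = template_gene_ids, degree = tdeg,
                              q_size = lengths(q_sets), fallback = fallback),
    q_sets = q_sets, count = count),
    class = "degree_matched_sampler")
}

# Draw one gene per template vertex, all distinct, from the Q_i sets.
# Vertices are filled most-constrained-first; a handful of restarts covers
# the rare dead end when fallback-widened sets overlap.
draw_assignment <- function(q_sets, max_tries = 100L) {
  ord <- order(lengths(q_sets))
  k <- length(q_sets)
  for (try in seq_len(max_tries)) {
    picked <- character(k)
    used <- character(0)
    ok <- TRUE
    for (i in ord) {
      free <- setdiff(q_sets[[i]], used)
      if (!length(free)) { ok <- FALSE; break }
      g <- if (length(free) == 1L) free else sample(free, 1L)
      picked[i] <- g
      used <- c(used, g)
    }
    if (ok) return(picked)
  }
  stop("cannot draw distinct degree-matched vertices; candidate sets too ",
       "small", call. = FALSE)
}

#' Sample one degree-matched random network
#'
#' Draws one gene per template vertex from its degree-matched candidate set
#' Q_i (distinct within the replicate), then induces the links: every
#' knowledge-base interaction whose two endpoints were both sampled.
#'
#' @param sampler A [build_q_sets()] result.
#' @param kb The same [knowledge_base()] the sampler was built from.
#' @param seed Integer seed.
#' @return A list with `genes` (sampled ids, in template-vertex order) and
#'   `subnetwork` (an [induced_subnetwork()] over them).
#' @export
sample_random_network <- function(sampler, kb, seed) {
  stopifnot(inherits(sampler, "degree_matched_sampler"))
  if (length(unique(unlist(sampler$q_sets))) < length(sampler$q_sets)) {
    stop("distinctness unsatisfiable: fewer candidates than template ",
         "vertices", call. = FALSE)
  }
  genes <- withr::with_seed(seed, draw_assignment(sampler$q_sets))
  list(genes = genes, subnetwork = induced_subnetwork(kb, genes))
}

#' Degree-matched null distribution of connectivity
#'
#' Builds `n` degree-matched random networks for a template gene set and
#' records the connectivity of each: the number of distinct connected node
#' pairs (default) and the number of link records in the induced
#' subnetwork. The empirical p-value of an observed connectivity against
#' this null uses the same-or-greater tie convention of
#' [empirical_pvalue()].
#'
#' @inheritParams build_q_sets
#' @param n Number of random networks.
#' @param seed Integer seed.
#' @param stat Which connectivity statistic the `values` element carries:
#'   `"pairs"` (distinct connected pairs, default) or `"links"` (link
#'   records).
#' @param keep_samples If `TRUE`, also return the matrix of sampled gene ids
#'   (replicates in rows) for audit.
#' @return An object of class `connectivity_null` (and `associome_null`):
#'   `values` (numeric, chosen statistic), `stats` (tibble with both
#'   `pairs` and `links` per replicate), `n`, `seed`, `statistic`,
#'   `sampler`, and optionally `samples`.
#' @export
connectivity_null <- function(kb, template_gene_ids, n, seed,
                              stat = c("pairs", "links"),
                              count = c("partners", "records"),
                              keep_samples = FALSE) {
  stat <- match.arg(stat)
  stopifnot(n >= 1L)
  sampler <- build_q_sets(kb, template_gene_ids, match.arg(count))
  if (length(unique(unlist(sampler$q_sets))) < length(sampler$q_sets)) {
    stop("distinctness unsatisfiable: fewer candidates than template ",
         "vertices", call. = FALSE)
  }
  ids <- kb$genes$id
  n_nodes <- length(ids)
  q_idx <- lapply(sampler$q_sets, match, table = ids)
  # integer endpoint vectors: all link records, and distinct pairs
  ia <- match(kb$interactions$a_id, ids)
  ib <- match(kb$interactions$b_id, ids)
  dp <- distinct_pairs(kb$interactions)
  pa <- match(dp$a, ids)
  pb <- match(dp$b, ids)
  k <- length(q_idx)
  pairs_v <- integer(n)
  links_v <- integer(n)
  samples <- if (keep_samples) matrix(NA_character_, n, k) else NULL
  withr::with_seed(seed, {
    # fast path: exact-degree candidate sets are disjoint across degree
    # classes, so distinct sampling reduces to per-class sampling without
    # replacement
    disjoint <- !any(sampler$template$fallback)
    if (disjoint) {
      classes <- split(seq_len(k), sampler$template$degree)
      class_pool <- lapply(classes, function(v) q_idx[[v[1]]])
    }
    for (r in seq_len(n)) {
      if (disjoint) {
        pick <- integer(k)
        for (ci in seq_along(classes)) {
          v <- classes[[ci]]
          pool <- class_pool[[ci]]
          if (length(pool) < length(v)) {
            stop("distinctness unsatisfiable within a degree class",
                 call. = FALSE)
          }
          pick[v] <- pool[sample.int(length(pool), length(v))]
        }
      } else {
        pick <- match(draw_assignment(sampler$q_sets), ids)
      }
      sel <- logical(n_nodes)
      sel[pick] <- TRUE
      pairs_v[r] <- sum(sel[pa] & sel[pb])
      links_v[r] <- sum(sel[ia] & sel[ib])
      if (keep_samples) samples[r, ] <- ids[pick]
    }
  })
  structure(list(
    values = if (stat == "pairs") pairs_v else links_v,
    stats = tibble::tibble(pairs = pairs_v, links = links_v),
    n = n, seed = seed, statistic = stat, sampler = sampler,
    samples = samples),
    class = c("connectivity_null", "associome_null"))
}

#' Serialize a null distribution to TSV
#'
#' One value per row, preceded by commented header lines recording the
#' statistic name, replicate count and seed, so a null can be audited or
#' re-plotted without recomputation.
#'
#' @param null A `relation_index_null` or `connectivity_null`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_null_tsv <- function(null, path) {
  if (inherits(null, "relation_index_null")) {
    hdr <- c(sprintf("# statistic: I,J,M"), sprintf("# n: %d", null$n),
             sprintf("# seed: %d", null$seed))
    body <- c(paste("i", "j", "m", sep = "\t"),
              sprintf("%d\t%s\t%s", null$values$i,
                      format(null$values$j, digits = 15),
                      format(null$values$m, digits = 15)))
  } else {
    hdr <- c(sprintf("# statistic: %s", null$statistic),
             sprintf("# n: %d", null$n), sprintf("# seed: %d", null$seed))
    body <- c(paste("pairs", "links", sep = "\t"),
              sprintf("%d\t%d", null$stats$pairs, null$stats$links))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
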