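#' Configuration for the synthetic knowledge-base generator
#'
#' Describes a synthetic disease-gene knowledge base with planted
#' comorbidity structure: per-disease association-set sizes follow a
#' log-normal law (heavy tail: a few diseases with very many genes, most
#' with few), the gene-gene interaction graph is a configuration model
#' with discrete power-law degrees and typed links, and selected disease
#' pairs are planted to share `n_shared` genes whose pairwise
#' interconnectivity is raised to about `rho` by rewiring existing edges
#' onto the planted set (total edge count is preserved, so degree-matched
#' nulls remain honest). Planted annotation terms draw a stated fraction
#' of their genes from a planted comorbid set.
#'
#' @param n_diseases,n_genes Universe sizes.
#' @param assoc_meanlog,assoc_sdlog Log-normal parameters of per-disease
#'   association-set size (clamped to \[1, n_genes / 3\]).
#' @param degree_exponent Power-law exponent of the interaction-degree
#'   distribution (density ~ d^-exponent).
#' @param min_degree,max_degree Degree bounds.
#' @param link_type_probs Named numeric vector of link-type probabilities;
#'   defaults to a mix dominated by "association" and "expression" with
#'   regulatory and physical types in the tail.
#' @param multi_type_prob Probability that a connected pair carries a second
#'   link record of a different type.
#' @param planted_pairs `NULL` or a data frame with columns `disease_a`,
#'   `disease_b`, `n_shared`, `rho` and optional `group` (pairs sharing a
#'   `group` value draw their shared genes from one common planted pool, so
#'   several pairs can plant a single multi-disease comorbid set).
#' @param planted_terms `NULL` or a data frame with columns `term_id`,
#'   `n_annotated`, `fraction_from_comorbid` and optional `group` naming the
#'   planted pool to draw from (default: the first).
#' @param n_background_terms,term_meanlog,term_sdlog Background annotation:
#'   number of uniform-draw terms and the log-normal law of their sizes.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_diseases = 60L, n_genes = 1500L,
                             assoc_meanlog = log(12), assoc_sdlog = 1.0,
                             degree_exponent = 2.5, min_degree = 1L,
                             max_degree = 60L,
                             link_type_probs = NULL,
                             multi_type_prob = 0.15,
                             planted_pairs = NULL,
                             planted_terms = NULL,
                             n_background_terms = 50L,
                             term_meanlog = log(15), term_sdlog = 0.8,
                             seed = 1L) {
  if (is.null(link_type_probs)) {
    link_type_probs <- c(association = 0.45, expression = 0.12,
                         `co-expression` = 0.08,
                         `up-regulation` = 0.06, `down-regulation` = 0.06,
                         regulation_of_activity = 0.06,
                         protein_protein = 0.05,
                         transport_regulation = 0.05, catalysis = 0.03,
                         degradation_regulation = 0.02, binding = 0.02)
  }
  if (!is.null(planted_pairs)) {
    planted_pairs <- tibble::as_tibble(planted_pairs)
    need <- c("disease_a", "disease_b", "n_shared", "rho")
    stopifnot(all(need %in% names(planted_pairs)))
    if (is.null(planted_pairs[["group"]])) {
      planted_pairs$group <- paste0("pool_", seq_len(nrow(planted_pairs)))
    }
    stopifnot(all(planted_pairs$rho >= 0), all(planted_pairs$rho <= 1),
              all(planted_pairs$n_shared >= 0),
              all(planted_pairs$n_shared <= n_genes))
  }
  if (!is.null(planted_terms)) {
    planted_terms <- tibble::as_tibble(planted_terms)
    need <- c("term_id", "n_annotated", "fraction_from_comorbid")
    stopifnot(all(need %in% names(planted_terms)),
              all(planted_terms$fraction_from_comorbid >= 0),
              all(planted_terms$fraction_from_comorbid <= 1))
  }
  stopifnot(n_diseases >= 2L, n_genes >= 10L, min_degree >= 1L,
            max_degree >= min_degree, multi_type_prob >= 0,
            multi_type_prob <= 1, length(seed) == 1L, !is.na(seed))
  structure(list(
    n_diseases = as.integer(n_diseases), n_genes = as.integer(n_genes),
    assoc_meanlog = assoc_meanlog, assoc_sdlog = assoc_sdlog,
    degree_exponent = degree_exponent,
    min_degree = as.integer(min_degree),
    max_degree = as.integer(max_degree),
    link_type_probs = link_type_probs / sum(link_type_probs),
    multi_type_prob = multi_type_prob,
    planted_pairs = planted_pairs, planted_terms = planted_terms,
    n_background_terms = as.integer(n_background_terms),
    term_meanlog = term_meanlog, term_sdlog = term_sdlog,
    seed = as.integer(seed)), class = "synthetic_config")
}

# discrete power-law degrees via inverse-transform sampling
sample_powerlaw_degrees <- function(n, exponent, dmin, dmax) {
  u <- stats::runif(n)
  d <- floor(dmin * (1 - u)^(-1 / (exponent - 1)))
  pmin(pmax(d, dmin), dmax)
}

#' Generate a synthetic knowledge base with planted structure
#'
#' Builds the disease, gene, association and interaction tables described
#' by a [synthetic_config()], together with a ground-truth record of what
#' was planted. The interaction graph is a configuration model (stub
#' pairing with self-loops and duplicate pairs erased); planted
#' interconnectivity is realized by rewiring randomly chosen background
#' edges onto unlinked planted-gene pairs until about `rho` of the planted
#' pairs are directly linked, preserving the total number of connected
#' pairs. Disease gene sets are uniform draws, except that planted pairs
#' first receive their shared pool; the realized shared count therefore
#' never falls below `n_shared`.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `kb` (a [knowledge_base()]) and
#'   `ground_truth` (list: `shared_pools` — tibble of label/gene_id for
#'   each planted pool; `planted_pairs` — the config table).
#' @export
generate_kb <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_kb_impl(config))
}

generate_kb_impl <- function(config) {
  n_g <- config$n_genes
  n_d <- config$n_diseases
  gene_ids <- sprintf("G%04d", seq_len(n_g))
  disease_ids <- sprintf("D%03d", seq_len(n_d))

  # configuration-model edges (erased variant)
  degs <- sample_powerlaw_degrees(n_g, config$degree_exponent,
                                  config$min_degree, config$max_degree)
  if (sum(degs) %% 2L == 1L) degs[1L] <- degs[1L] + 1L
  stubs <- sample(rep.int(seq_len(n_g), degs))
  half <- length(stubs) %/% 2L
  ea <- stubs[seq_len(half)]
  eb <- stubs[half + seq_len(half)]
  keep <- ea != eb
  ea <- ea[keep]; eb <- eb[keep]
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  keep <- !duplicated(lo * (n_g + 1) + hi)
  edges <- cbind(lo[keep], hi[keep])

  # planted shared pools
  pools <- list()
  pp <- config$planted_pairs
  if (!is.null(pp) && nrow(pp)) {
    taken <- character(0)
    for (g in unique(pp$group)) {
      size <- max(pp$n_shared[pp$group == g])
      free <- setdiff(gene_ids, taken)
      if (size > length(free)) stop("infeasible config: planted pools ",
                                    "exceed the gene universe",
                                    call. = FALSE)
      pool <- sample(free, size)
      pools[[g]] <- sort(pool, method = "radix")
      taken <- c(taken, pool)
    }
    # rewire background edges onto planted pairs to reach rho
    for (i in seq_len(nrow(pp))) {
      pool_idx <- match(pools[[pp$group[i]]], gene_ids)
      if (length(pool_idx) < 2L) next
      cmb <- utils::combn(sort(pool_idx), 2L)
      pair_keys <- cmb[1L, ] * (n_g + 1) + cmb[2L, ]
      edge_keys <- edges[, 1L] * (n_g + 1) + edges[, 2L]
      linked <- pair_keys %in% edge_keys
      target <- round(pp$rho[i] * ncol(cmb))
      need <- target - sum(linked)
      if (need > 0L) {
        new_cols <- which(!linked)
        new_cols <- new_cols[sample.int(length(new_cols),
                                        min(need, length(new_cols)))]
        in_pool_edge <- edges[, 1L] %in% pool_idx &
          edges[, 2L] %in% pool_idx
        removable <- which(!in_pool_edge)
        drop <- removable[sample.int(length(removable),
                                     min(length(new_cols),
                                         length(removable)))]
        edges <- edges[-drop, , drop = FALSE]
        edges <- rbind(edges, t(cmb[, new_cols, drop = FALSE]))
      }
    }
  }

  # typed link records; some pairs carry a second type
  n_e <- nrow(edges)
  types <- sample(names(config$link_type_probs), n_e, replace = TRUE,
                  prob = config$link_type_probs)
  extra <- which(stats::runif(n_e) < config$multi_type_prob)
  extra_types <- vapply(extra, function(r) {
    sample(setdiff(names(config$link_type_probs), types[r]), 1L)
  }, character(1))
  interactions <- tibble::tibble(
    a_id = gene_ids[c(edges[, 1L], edges[extra, 1L])],
    link_type = c(types, extra_types),
    b_id = gene_ids[c(edges[, 2L], edges[extra, 2L])],
    directed = FALSE)

  # per-disease association sets
  sizes <- pmin(pmax(round(stats::rlnorm(n_d, config$assoc_meanlog,
                                         config$assoc_sdlog)), 1L),
                n_g %/% 3L)
  names(sizes) <- disease_ids
  planted_for <- stats::setNames(vector("list", n_d), disease_ids)
  if (!is.null(pp) && nrow(pp)) {
    for (i in seq_len(nrow(pp))) {
      for (d in c(pp$disease_a[i], pp$disease_b[i])) {
        if (!d %in% disease_ids) {
          stop("planted pair names unknown disease: ", d, call. = FALSE)
        }
        planted_for[[d]] <- union(planted_for[[d]],
                                  pools[[pp$group[i]]][
                                    seq_len(pp$n_shared[i])])
      }
    }
    for (d in disease_ids) {
      sizes[d] <- max(sizes[d], ceiling(1.3 * length(planted_for[[d]])))
    }
  }
  assoc <- lapply(disease_ids, function(d) {
    base <- planted_for[[d]]
    rest <- sizes[[d]] - length(base)
    if (rest > 0L) {
      base <- c(base, sample(setdiff(gene_ids, base), rest))
    }
    tibble::tibble(disease_id = d, gene_id = sort(base, method = "radix"),
                   source = "synthetic")
  })
  associations <- dplyr::bind_rows(assoc)

  kb <- knowledge_base(
    diseases = tibble::tibble(id = disease_ids),
    genes = tibble::tibble(id = gene_ids),
    associations = associations,
    interactions = interactions)
  shared_pools <- if (length(pools)) {
    dplyr::bind_rows(lapply(names(pools), function(g)
      tibble::tibble(label = g, gene_id = pools[[g]])))
  } else {
    tibble::tibble(label = character(), gene_id = character())
  }
  list(kb = kb,
       ground_truth = list(shared_pools = shared_pools,
                           planted_pairs = pp))
}

#' Generate a synthetic annotation with planted enriched terms
#'
#' Planted terms draw `round(fraction_from_comorbid * n_annotated)` genes
#' from the named planted pool (recorded in the knowledge-base ground
#' truth) and the remainder uniformly from the other genes; background
#' terms are uniform draws with log-normal sizes. The reference universe
#' is the full gene table of the knowledge base.
#'
#' @param config The [synthetic_config()] used for the knowledge base.
#' @param kb The generated [knowledge_base()].
#' @param ground_truth The `ground_truth` element returned by
#'   [generate_kb()].
#' @return A list with `annotation` (an [annotation_set()]) and
#'   `ground_truth` (tibble: term_id, gene_id, planted flag).
#' @export
generate_annotation <- function(config, kb, ground_truth) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 104729L, {
    gene_ids <- kb$genes$id
    rows <- list()
    pt <- config$planted_terms
    if (!is.null(pt) && nrow(pt)) {
      pools <- split(ground_truth$shared_pools$gene_id,
                     ground_truth$shared_pools$label)
      if (is.null(pt[["group"]])) pt$group <- names(pools)[1L]
      for (i in seq_len(nrow(pt))) {
        pool <- pools[[pt$group[i]]]
        n_from <- round(pt$fraction_from_comorbid[i] * pt$n_annotated[i])
        if (n_from > length(pool)) {
          stop("infeasible planted term ", pt$term_id[i],
               ": pool smaller than requested draw", call. = FALSE)
        }
        members <- c(sample(pool, n_from),
                     sample(setdiff(gene_ids, pool),
                            pt$n_annotated[i] - n_from))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          term_id = pt$term_id[i],
          gene_id = sort(members, method = "radix"), planted = TRUE)
      }
    }
    if (config$n_background_terms > 0L) {
      sizes <- pmin(pmax(round(stats::rlnorm(config$n_background_terms,
                                             config$term_meanlog,
                                             config$term_sdlog)), 2L),
                    length(gene_ids) %/% 2L)
      for (i in seq_len(config$n_background_terms)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          term_id = sprintf("T%04d", i),
          gene_id = sort(sample(gene_ids, sizes[i]), method = "radix"),
          planted = FALSE)
      }
    }
    truth <- dplyr::bind_rows(rows)
  })
  list(annotation = annotation_set(truth[c("term_id", "gene_id")],
                                   universe = gene_ids),
       ground_truth = truth)
}

#' Write the planted ground truth as TSV
#'
#' The analysis pipeline never reads this file; it exists so benchmark
#' results can be scored against what was planted.
#'
#' @param ground_truth The `ground_truth` element of [generate_kb()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth$shared_pools
  pp <- ground_truth$planted_pairs
  lines <- c("#%section: shared_pools",
             paste("label", "gene_id", sep = "\t"),
             paste(gt$label, gt$gene_id, sep = "\t"))
  if (!is.null(pp) && nrow(pp)) {
    lines <- c(lines, "#%section: planted_pairs",
               paste("disease_a", "disease_b", "n_shared", "rho", "group",
                     sep = "\t"),
               paste(pp$disease_a, pp$disease_b, pp$n_shared, pp$rho,
                     pp$group, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
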