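#' Partition genes by disease specificity
#'
#' Labels every associated gene relative to a focal disease and its partner
#' diseases: genes associated with all configured diseases get the label
#' `"comorbid"`; for each disease D, genes associated with D but not in the
#' comorbid set get `"specific:D"`. A gene may carry several specific
#' labels (shared by some but not all diseases); the comorbid label is
#' exclusive of every specific label. Labels propagate across gene/protein
#' duality: a labelled gene's protein node (and a labelled protein's coding
#' gene) carries the same labels.
#'
#' @param kb A [knowledge_base()].
#' @param focal_disease Focal disease id.
#' @param partner_diseases Character vector of partner disease ids.
#' @return An object of class `gene_partition`: a tibble with columns
#'   `label`, `gene_id`, plus attributes `focal` and `partners`.
#' @export
build_gene_partition <- function(kb, focal_disease, partner_diseases) {
  all_d <- c(focal_disease, partner_diseases)
  miss <- setdiff(all_d, kb$diseases$id)
  if (length(miss)) {
    stop("unknown disease id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  comorbid <- comorbid_gene_set(kb, all_d)
  rows <- list(tibble::tibble(label = rep("comorbid", length(comorbid)),
                              gene_id = comorbid))
  for (d in all_d) {
    spec <- setdiff(genes_for(kb, d), comorbid)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      label = rep(paste0("specific:", d), length(spec)), gene_id = spec)
  }
  part <- dplyr::bind_rows(rows)
  # gene/protein duality: copy labels to the other member of each pair
  prot <- kb$genes[kb$genes$entity_class == "protein" &
                     !is.na(kb$genes$coding_gene_id), ]
  if (nrow(prot)) {
    g2p <- stats::setNames(prot$id, prot$coding_gene_id)
    p2g <- stats::setNames(prot$coding_gene_id, prot$id)
    twin <- c(unname(g2p[part$gene_id]), unname(p2g[part$gene_id]))
    extra <- tibble::tibble(label = rep(part$label, 2L), gene_id = twin)
    extra <- extra[!is.na(extra$gene_id), ]
    part <- dplyr::bind_rows(part, extra)
    part <- part[!duplicated(paste(part$label, part$gene_id, sep = "\r")), ]
  }
  part <- part[radix_order(part$label, part$gene_id), ]
  structure(part, class = c("gene_partition", class(part)),
            focal = focal_disease, partners = partner_diseases,
            labels = c("comorbid", paste0("specific:", all_d)))
}

#' Pattern slots for pathway search
#'
#' A node-class pattern is an ordered list of slots: the first and last
#' slots name diseases (a fixed id or a choice set), interior slots name
#' gene classes by partition label (see [build_gene_partition()]). A slot
#' may list several acceptable labels.
#'
#' @param ids Character vector of acceptable disease ids.
#' @param labels Character vector of acceptable partition labels.
#' @return A slot object for [node_class_pattern()].
#' @export
slot_disease <- function(ids) {
  stopifnot(length(ids) >= 1L)
  structure(list(kind = "disease", ids = ids), class = "pattern_slot")
}

#' @rdname slot_disease
#' @export
slot_gene <- function(labels) {
  stopifnot(length(labels) >= 1L)
  structure(list(kind = "gene", labels = labels), class = "pattern_slot")
}

#' Assemble and validate a node-class pattern
#'
#' @param ... Slots created with [slot_disease()] and [slot_gene()], in
#'   chain order.
#' @return An object of class `node_class_pattern` (a list of slots).
#' @export
node_class_pattern <- function(...) {
  slots <- list(...)
  if (length(slots) == 1L && is.list(slots[[1]]) &&
      !inherits(slots[[1]], "pattern_slot")) {
    slots <- slots[[1]]
  }
  if (length(slots) < 3L) stop("pattern needs at least 3 slots",
                               call. = FALSE)
  kinds <- vapply(slots, `[[`, character(1), "kind")
  if (kinds[1] != "disease" || kinds[length(kinds)] != "disease") {
    stop("first and last slots must be disease slots", call. = FALSE)
  }
  if (any(kinds[-c(1L, length(kinds))] != "gene")) {
    stop("interior slots must be gene slots", call. = FALSE)
  }
  structure(slots, class = "node_class_pattern")
}

#' The standard disease-to-disease comorbidity pattern
#'
#' The five-slot chain focal disease -> gene specific to the focal
#' disease -> comorbid gene -> gene specific to one of the partner
#' diseases -> that partner disease. Comorbid genes are excluded from
#' the specific slots by construction of the partition.
#'
#' @inheritParams build_gene_partition
#' @return A [node_class_pattern()].
#' @export
comorbidity_pattern <- function(focal_disease, partner_diseases) {
  node_class_pattern(
    slot_disease(focal_disease),
    slot_gene(paste0("specific:", focal_disease)),
    slot_gene("comorbid"),
    slot_gene(paste0("specific:", partner_diseases)),
    slot_disease(partner_diseases))
}

#' Enumerate all pathways matching a node-class pattern
#'
#' Returns the complete set of node chains satisfying every slot
#' constraint, with every consecutive connection present in the knowledge
#' base: disease-gene steps are supported by association records,
#' gene-gene steps by interaction records (any link type by default,
#' direction ignored). Interior gene nodes are pairwise distinct within a
#' chain. Output order is deterministic: lexicographic over the node-id
#' sequence.
#'
#' @param kb A [knowledge_base()].
#' @param pattern A [node_class_pattern()].
#' @param partition A [build_gene_partition()] result; required when the
#'   pattern has gene slots.
#' @param link_types Optional character vector restricting which
#'   interaction types may support gene-gene steps.
#' @return A tibble of class `pathway_matches`, one row per match, columns
#'   `node_1` ... `node_k`.
#' @export
find_pathways <- function(kb, pattern, partition = NULL, link_types = NULL) {
  stopifnot(inherits(pattern, "node_class_pattern"))
  k <- length(pattern)
  labels_used <- unlist(lapply(pattern, function(s)
    if (s$kind == "gene") s$labels else character(0)))
  if (length(labels_used)) {
    if (is.null(partition)) stop("pattern has gene slots but no partition",
                                 call. = FALSE)
    defined <- attr(partition, "labels") %||% unique(partition$label)
    unknown <- setdiff(labels_used, defined)
    if (length(unknown)) {
      stop("pattern references undefined partition label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  cand <- lapply(pattern, function(s) {
    if (s$kind == "disease") intersect(s$ids, kb$diseases$id)
    else sort(unique(partition$gene_id[partition$label %in% s$labels]),
              method = "radix")
  })
  if (any(lengths(cand) == 0L)) {
    return(empty_matches(k))
  }
  assoc <- tibble::tibble(d = kb$associations$disease_id,
                          g = kb$associations$gene_id)
  inter <- kb$interactions
  if (!is.null(link_types)) {
    inter <- inter[inter$link_type %in% link_types, ]
  }
  gg <- tibble::tibble(x = c(inter$a_id, inter$b_id),
                       y = c(inter$b_id, inter$a_id))
  gg <- gg[!duplicated(paste(gg$x, gg$y, sep = "\r")), ]

  paths <- tibble::tibble(node_1 = cand[[1]])
  for (s in 2:k) {
    prev <- paste0("node_", s - 1L)
    cur <- paste0("node_", s)
    kinds <- c(pattern[[s - 1L]]$kind, pattern[[s]]$kind)
    edge <- if (all(kinds == "gene")) {
      stats::setNames(gg, c(prev, cur))
    } else if (kinds[1] == "disease") {
      stats::setNames(assoc, c(prev, cur))
    } else {
      stats::setNames(assoc[c("g", "d")], c(prev, cur))
    }
    edge <- edge[edge[[cur]] %in% cand[[s]], ]
    paths <- dplyr::inner_join(paths, edge, by = prev,
                               relationship = "many-to-many")
    if (!nrow(paths)) return(empty_matches(k))
  }
  # interior gene nodes pairwise distinct
  interior <- paste0("node_", 2:(k - 1L))
  if (length(interior) > 1L) {
    mat <- as.matrix(paths[interior])
    keep <- apply(mat, 1L, function(r) !anyDuplicated(r))
    paths <- paths[keep, , drop = FALSE]
  }
  paths <- paths[!duplicated(do.call(paste, c(paths, sep = "\r"))), ]
  paths <- paths[do.call(radix_order, as.list(paths)), ]
  class(paths) <- c("pathway_matches", class(paths))
  attr(paths, "pattern") <- pattern
  paths
}

empty_matches <- function(k) {
  out <- tibble::as_tibble(stats::setNames(
    replicate(k, character(0), simplify = FALSE), paste0("node_", seq_len(k))))
  class(out) <- c("pathway_matches", class(out))
  out
}

#' Merge pathway matches into a single network
#'
#' The deduplicated union of nodes and of supporting links (association
#' records for disease-gene steps, interaction records for gene-gene
#' steps) over all matches. Invariant to the order of the matches.
#'
#' @param matches A [find_pathways()] result.
#' @param kb The knowledge base the matches were found in (supplies the
#'   link evidence).
#' @return An object of class `pathway_network`: list with `nodes`
#'   (tibble: id, kind), `links` (tibble: a_id, link_type, b_id),
#'   `n_nodes`, `n_links`.
#' @export
merge_pathways <- function(matches, kb) {
  k <- sum(startsWith(names(matches), "node_"))
  if (!nrow(matches)) {
    return(structure(list(
      nodes = tibble::tibble(id = character(), kind = character()),
      links = tibble::tibble(a_id = character(), link_type = character(),
                             b_id = character()),
      n_nodes = 0L, n_links = 0L), class = "pathway_network"))
  }
  node_ids <- unique(unlist(matches[paste0("node_", seq_len(k))]))
  nodes <- tibble::tibble(
    id = node_ids,
    kind = ifelse(node_ids %in% kb$diseases$id, "disease",
                  kb$genes$entity_class[match(node_ids, kb$genes$id)]))
  nodes <- nodes[radix_order(nodes$id), ]
  links <- list()
  for (s in seq_len(k - 1L)) {
    a <- matches[[paste0("node_", s)]]
    b <- matches[[paste0("node_", s + 1L)]]
    step <- tibble::tibble(a = a, b = b)
    step <- step[!duplicated(paste(step$a, step$b, sep = "\r")), ]
    d_a <- step$a %in% kb$diseases$id
    d_b <- step$b %in% kb$diseases$id
    if (any(d_a | d_b)) {
      da <- step[d_a | d_b, ]
      links[[length(links) + 1L]] <- tibble::tibble(
        a_id = ifelse(d_a[d_a | d_b], da$a, da$b),
        link_type = "disease_association",
        b_id = ifelse(d_a[d_a | d_b], da$b, da$a))
    }
    ggs <- step[!(d_a | d_b), ]
    if (nrow(ggs)) {
      ev <- kb$interactions[
        (kb$interactions$a_id %in% c(ggs$a, ggs$b)) &
          (kb$interactions$b_id %in% c(ggs$a, ggs$b)), ]
      key_need <- paste(pmin(ggs$a, ggs$b), pmax(ggs$a, ggs$b), sep = "\r")
      key_ev <- paste(pmin(ev$a_id, ev$b_id), pmax(ev$a_id, ev$b_id),
                      sep = "\r")
      ev <- ev[key_ev %in% key_need, ]
      links[[length(links) + 1L]] <- tibble::tibble(
        a_id = pmin(ev$a_id, ev$b_id), link_type = ev$link_type,
        b_id = pmax(ev$a_id, ev$b_id))
    }
  }
  links <- dplyr::bind_rows(links)
  if (nrow(links)) {
    links <- links[!duplicated(paste(links$a_id, links$link_type,
                                     links$b_id, sep = "\r")), ]
    links <- links[radix_order(links$a_id, links$b_id, links$link_type), ]
  }
  structure(list(nodes = nodes, links = links,
                 n_nodes = nrow(nodes), n_links = nrow(links)),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("<pathway_network> ", x$n_nodes, " nodes, ", x$n_links,
      " links\n", sep = "")
  invisible(x)
}

#' Write pathway matches as TSV
#'
#' One row per match: the pipe-joined node-id chain plus one column per
#' slot.
#'
#' @param matches A [find_pathways()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pathways_tsv <- function(matches, path) {
  out <- tibble::as_tibble(matches)
  out <- out[startsWith(names(out), "node_")]
  chain <- do.call(paste, c(out, sep = "|"))
  out <- dplyr::bind_cols(tibble::tibble(chain = chain), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a merged pathway network as GraphML or SIF
#'
#' @param network A [merge_pathways()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pathway_graphml <- function(network, path) {
  kb_like <- list(
    diseases = tibble::tibble(
      id = network$nodes$id[network$nodes$kind == "disease"],
      name = network$nodes$id[network$nodes$kind == "disease"]),
    genes = tibble::tibble(
      id = network$nodes$id[network$nodes$kind != "disease"],
      symbol = network$nodes$id[network$nodes$kind != "disease"],
      entity_class = network$nodes$kind[network$nodes$kind != "disease"],
      coding_gene_id = NA_character_),
    associations = tibble::tibble(disease_id = character(),
                                  gene_id = character(),
                                  source = character()),
    interactions = tibble::tibble(a_id = network$links$a_id,
                                  link_type = network$links$link_type,
                                  b_id = network$links$b_id,
                                  directed = FALSE))
  write_graphml(kb_like, path)
}

#' @rdname write_pathway_graphml
#' @export
write_pathway_sif <- function(network, path) {
  l <- network$links
  l <- l[radix_order(l$a_id, l$b_id, l$link_type), ]
  writeLines(paste(l$a_id, l$link_type, l$b_id, sep = "\t"), path)
  invisible(path)
}
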