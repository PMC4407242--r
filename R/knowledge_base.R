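#' Build a disease-gene knowledge base
#'
#' A knowledge base holds the four tables every downstream analysis samples
#' from: diseases, gene/protein nodes, disease-gene associations and typed
#' gene-gene interactions. It is the universe both permutation nulls
#' (random disease pairs, degree-matched random networks) draw their
#' replicates from.
#'
#' Nodes carry an `entity_class` ("gene" or "protein"); a protein node may
#' name its coding gene so that mixed gene/protein networks can be collapsed
#' onto proteins with [collapse_to_protein_network()]. A pair of nodes may be
#' connected by several interaction records with different `link_type`s;
#' degree and connectivity statistics count distinct partners/pairs by
#' default, and link records as an alternative.
#'
#' @param diseases Data frame with columns `id` and optionally `name`.
#' @param genes Data frame with columns `id` and optionally `symbol`,
#'   `entity_class` ("gene" or "protein", default "gene") and
#'   `coding_gene_id` (for protein nodes; `NA` otherwise).
#' @param associations Data frame with columns `disease_id`, `gene_id` and
#'   optionally `source`.
#' @param interactions Data frame with columns `a_id`, `link_type`, `b_id`
#'   and optionally `directed` (default `FALSE`). Self-links are rejected.
#'
#' @return An object of class `knowledge_base`: a list of the four tibbles,
#'   validated for referential integrity.
#' @examples
#' kb <- knowledge_base(
#'   diseases     = data.frame(id = c("D1", "D2")),
#'   genes        = data.frame(id = c("g1", "g2", "g3")),
#'   associations = data.frame(disease_id = c("D1", "D1", "D2"),
#'                             gene_id    = c("g1", "g2", "g2")),
#'   interactions = data.frame(a_id = "g1", link_type = "binding", b_id = "g2")
#' )
#' genes_for(kb, "D1")
#' @export
knowledge_base <- function(diseases, genes, associations = NULL,
                           interactions = NULL) {
  diseases <- tibble::as_tibble(diseases)
  genes <- tibble::as_tibble(genes)
  if (is.null(diseases[["name"]])) diseases$name <- diseases$id
  if (is.null(genes[["symbol"]])) genes$symbol <- genes$id
  if (is.null(genes[["entity_class"]])) genes$entity_class <- "gene"
  if (is.null(genes[["coding_gene_id"]])) genes$coding_gene_id <- NA_character_
  diseases <- diseases[c("id", "name")]
  genes <- genes[c("id", "symbol", "entity_class", "coding_gene_id")]

  if (is.null(associations)) {
    associations <- tibble::tibble(disease_id = character(),
                                   gene_id = character(),
                                   source = character())
  }
  associations <- tibble::as_tibble(associations)
  if (is.null(associations[["source"]])) associations$source <- ""
  associations <- associations[c("disease_id", "gene_id", "source")]

  if (is.null(interactions)) {
    interactions <- tibble::tibble(a_id = character(),
                                   link_type = character(),
                                   b_id = character(),
                                   directed = logical())
  }
  interactions <- tibble::as_tibble(interactions)
  if (is.null(interactions[["directed"]])) {
    interactions$directed <- rep(FALSE, nrow(interactions))
  }
  interactions <- interactions[c("a_id", "link_type", "b_id", "directed")]

  kb <- structure(list(diseases = diseases, genes = genes,
                       associations = associations,
                       interactions = interactions),
                  class = "knowledge_base")
  validate_kb(kb)
}

validate_kb <- function(kb) {
  if (anyDuplicated(kb$diseases$id)) {
    stop("duplicate disease ids: ",
         paste(unique(kb$diseases$id[duplicated(kb$diseases$id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(kb$genes$id)) {
    stop("duplicate gene ids: ",
         paste(unique(kb$genes$id[duplicated(kb$genes$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(kb$genes$entity_class), c("gene", "protein"))
  if (length(bad_class)) {
    stop("unknown entity_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  coding <- kb$genes$coding_gene_id
  coding <- coding[!is.na(coding)]
  miss <- setdiff(coding, kb$genes$id)
  if (length(miss)) {
    stop("coding_gene_id refers to unknown nodes: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_d <- setdiff(kb$associations$disease_id, kb$diseases$id)
  if (length(bad_d)) {
    stop("associations reference unknown diseases: ",
         paste(utils::head(bad_d, 5L), collapse = ", "), call. = FALSE)
  }
  bad_g <- setdiff(kb$associations$gene_id, kb$genes$id)
  if (length(bad_g)) {
    stop("associations reference unknown genes: ",
         paste(utils::head(bad_g, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(kb$associations$disease_id, kb$associations$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (disease_id, gene_id) association rows", call. = FALSE)
  }
  bad_e <- setdiff(c(kb$interactions$a_id, kb$interactions$b_id), kb$genes$id)
  if (length(bad_e)) {
    stop("interactions reference unknown nodes: ",
         paste(utils::head(bad_e, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(kb$interactions$a_id == kb$interactions$b_id)) {
    stop("self-links are not allowed", call. = FALSE)
  }
  if (any(!nzchar(kb$interactions$link_type))) {
    stop("empty link_type", call. = FALSE)
  }
  kb
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>\n")
  cat("  diseases:     ", nrow(x$diseases), "\n")
  cat("  nodes:        ", nrow(x$genes),
      sprintf(" (%d gene, %d protein)\n",
              sum(x$genes$entity_class == "gene"),
              sum(x$genes$entity_class == "protein")))
  cat("  associations: ", nrow(x$associations), "\n")
  cat("  interactions: ", nrow(x$interactions), "records,",
      nrow(distinct_pairs(x$interactions)), "connected pairs\n")
  invisible(x)
}

# Canonical unordered pair table (a <= b lexicographically, radix order),
# one row per connected node pair regardless of link multiplicity.
distinct_pairs <- function(interactions) {
  if (!nrow(interactions)) {
    return(tibble::tibble(a = character(), b = character()))
  }
  a <- pmin(interactions$a_id, interactions$b_id)
  b <- pmax(interactions$a_id, interactions$b_id)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  tibble::tibble(a = a[keep], b = b[keep])
}

# locale-independent sort, for byte-stable writers
radix_order <- function(...) order(..., method = "radix")

#' Read a knowledge base from TSV/SIF files
#'
#' Associations are a TSV with header `disease_id`, `gene_id` and optional
#' `source`; lines starting with `#` are ignored, except that a directive
#' line `#%diseases: id1 id2 ...` declares the disease universe (rows naming
#' an undeclared disease are then an error, and declared diseases with no
#' associations still exist in the knowledge base). Interactions use the SIF
#' dialect `node_a<TAB>link_type<TAB>node_b`, one record per typed link, no
#' header. An optional node sidecar TSV with header `gene_id`,
#' `entity_class`, `coding_gene_id` declares gene/protein duality; nodes not
#' listed default to entity class "gene".
#'
#' Self-links in the interaction file are dropped with a warning (row
#' numbers reported); malformed rows are an error.
#'
#' @param assoc_path Path to the association TSV.
#' @param interaction_path Path to the SIF interaction file (may list zero
#'   records).
#' @param nodes_path Optional path to the node sidecar TSV.
#' @return A [knowledge_base()] object.
#' @export
read_knowledge_base <- function(assoc_path, interaction_path,
                                nodes_path = NULL) {
  for (p in c(assoc_path, interaction_path, nodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  raw <- readLines(assoc_path, warn = FALSE)
  declared <- NULL
  directive <- grep("^#%diseases:", raw)
  if (length(directive)) {
    declared <- unlist(strsplit(trimws(sub("^#%diseases:", "",
                                           raw[directive])), "[ ,]+"))
    declared <- declared[nzchar(declared)]
  }
  assoc <- readr::read_tsv(assoc_path, comment = "#",
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("disease_id", "gene_id")
  if (!all(need %in% names(assoc))) {
    stop("association file must have columns disease_id, gene_id",
         call. = FALSE)
  }
  bad <- which(is.na(assoc$disease_id) | is.na(assoc$gene_id))
  if (length(bad)) {
    stop("malformed association rows (missing fields): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(assoc$source)) assoc$source <- ""
  assoc$source[is.na(assoc$source)] <- ""

  inter <- readr::read_tsv(
    interaction_path, comment = "#", col_names = c("a_id", "link_type", "b_id"),
    col_types = "ccc", progress = FALSE)
  if (nrow(inter)) {
    bad <- which(is.na(inter$a_id) | is.na(inter$link_type) | is.na(inter$b_id))
    if (length(bad)) {
      stop("malformed interaction rows: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    selfy <- which(inter$a_id == inter$b_id)
    if (length(selfy)) {
      warning("dropping ", length(selfy), " self-link row(s): ",
              paste(utils::head(selfy, 10L), collapse = ", "), call. = FALSE)
      inter <- inter[-selfy, , drop = FALSE]
    }
  }
  inter$directed <- rep(FALSE, nrow(inter))

  node_ids <- sort(unique(c(assoc$gene_id, inter$a_id, inter$b_id)),
                   method = "radix")
  genes <- tibble::tibble(id = node_ids, symbol = node_ids,
                          entity_class = "gene",
                          coding_gene_id = NA_character_)
  if (!is.null(nodes_path)) {
    side <- readr::read_tsv(nodes_path, comment = "#",
                            col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    if (!all(c("gene_id", "entity_class") %in% names(side))) {
      stop("node sidecar must have columns gene_id, entity_class",
           call. = FALSE)
    }
    if (is.null(side$coding_gene_id)) side$coding_gene_id <- NA_character_
    extra <- setdiff(side$gene_id, genes$id)
    if (length(extra)) {
      genes <- dplyr::bind_rows(genes, tibble::tibble(
        id = extra, symbol = extra, entity_class = "gene",
        coding_gene_id = NA_character_))
    }
    idx <- match(side$gene_id, genes$id)
    genes$entity_class[idx] <- side$entity_class
    genes$coding_gene_id[idx] <- side$coding_gene_id
    genes <- genes[radix_order(genes$id), ]
  }

  if (!is.null(declared)) {
    undecl <- setdiff(assoc$disease_id, declared)
    if (length(undecl)) {
      stop("association rows name diseases outside the declared universe: ",
           paste(undecl, collapse = ", "), call. = FALSE)
    }
    disease_ids <- declared
  } else {
    disease_ids <- unique(assoc$disease_id)
  }
  diseases <- tibble::tibble(id = sort(disease_ids, method = "radix"))

  knowledge_base(diseases, genes, assoc, inter)
}

#' Write a knowledge base back to its TSV/SIF dialect
#'
#' Writers sort all tables lexicographically (C locale) so output is
#' byte-stable: the same knowledge base always produces identical files, and
#' a written knowledge base reloads to an identical object.
#'
#' @param kb A [knowledge_base()].
#' @param assoc_path,interaction_path,nodes_path Output paths; the node
#'   sidecar is only written when `nodes_path` is non-`NULL`.
#' @return Invisibly, the paths written.
#' @export
write_knowledge_base <- function(kb, assoc_path, interaction_path,
                                 nodes_path = NULL) {
  a <- kb$associations[radix_order(kb$associations$disease_id,
                                   kb$associations$gene_id), ]
  header <- paste0("#%diseases: ",
                   paste(sort(kb$diseases$id, method = "radix"),
                         collapse = " "))
  writeLines(c(header, paste("disease_id", "gene_id", "source", sep = "\t"),
               paste(a$disease_id, a$gene_id, a$source, sep = "\t")),
             assoc_path)
  i <- kb$interactions[radix_order(kb$interactions$a_id,
                                   kb$interactions$b_id,
                                   kb$interactions$link_type), ]
  writeLines(paste(i$a_id, i$link_type, i$b_id, sep = "\t"), interaction_path)
  if (!is.null(nodes_path)) {
    g <- kb$genes[radix_order(kb$genes$id), ]
    writeLines(c(paste("gene_id", "entity_class", "coding_gene_id",
                       sep = "\t"),
                 paste(g$id, g$entity_class,
                       ifelse(is.na(g$coding_gene_id), "NA", g$coding_gene_id),
                       sep = "\t")),
               nodes_path)
  }
  invisible(c(assoc_path, interaction_path, nodes_path))
}

#' Genes associated with a disease
#'
#' @param kb A [knowledge_base()].
#' @param disease_id A single disease id present in `kb`.
#' @return Character vector of gene ids (possibly empty), in radix-sorted
#'   order.
#' @export
genes_for <- function(kb, disease_id) {
  stopifnot(length(disease_id) == 1L)
  if (!disease_id %in% kb$diseases$id) {
    stop("unknown disease id: ", disease_id, call. = FALSE)
  }
  sort(unique(kb$associations$gene_id[
    kb$associations$disease_id == disease_id]), method = "radix")
}

# Degree of every node as a named integer vector, in kb$genes order.
# "partners": distinct interaction partners; "records": incident link records.
degree_vector <- function(kb, count = c("partners", "records")) {
  count <- match.arg(count)
  deg <- integer(nrow(kb$genes))
  names(deg) <- kb$genes$id
  if (nrow(kb$interactions)) {
    edges <- if (count == "partners") distinct_pairs(kb$interactions) else
      tibble::tibble(a = kb$interactions$a_id, b = kb$interactions$b_id)
    tab <- table(c(edges$a, edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Interaction degree of genes
#'
#' Counts, for each node, the number of distinct interaction partners
#' (default) or the number of incident interaction records. Direction is
#' ignored; multiple typed links between the same pair count once under
#' `count = "partners"`.
#'
#' @param kb A [knowledge_base()].
#' @param gene_ids Gene ids to report; `NULL` means every node in `kb`.
#' @param count `"partners"` (distinct partners, the default used for
#'   degree-matched nulls) or `"records"` (total link records).
#' @return A tibble with columns `gene_id` and `degree`.
#' @export
gene_degree <- function(kb, gene_ids = NULL,
                        count = c("partners", "records")) {
  deg <- degree_vector(kb, match.arg(count))
  if (is.null(gene_ids)) {
    return(tibble::tibble(gene_id = names(deg), degree = unname(deg)))
  }
  miss <- setdiff(gene_ids, names(deg))
  if (length(miss)) {
    stop("unknown gene id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(gene_id = gene_ids, degree = unname(deg[gene_ids]))
}

#' Collapse a mixed gene/protein network onto protein nodes
#'
#' Every interaction or association incident to a gene node is re-attached
#' to that gene's protein node (the protein whose `coding_gene_id` names the
#' gene); gene nodes are then removed. Self-links produced by the
#' reassignment (e.g. a gene linked to its own protein product) are dropped,
#' and duplicate (pair, link_type) interaction records are deduplicated.
#' Gene nodes with no protein product are dropped with a warning, along with
#' their links. Applying the collapse twice equals applying it once.
#'
#' @param kb A [knowledge_base()].
#' @param node_ids Optional subset of node ids to restrict to before
#'   collapsing; `NULL` uses the whole knowledge base.
#' @return A [knowledge_base()] containing protein nodes only.
#' @export
collapse_to_protein_network <- function(kb, node_ids = NULL) {
  genes <- kb$genes
  inter <- kb$interactions
  assoc <- kb$associations
  if (!is.null(node_ids)) {
    miss <- setdiff(node_ids, genes$id)
    if (length(miss)) {
      stop("unknown node id(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    genes <- genes[genes$id %in% node_ids, ]
    inter <- inter[inter$a_id %in% genes$id & inter$b_id %in% genes$id, ]
    assoc <- assoc[assoc$gene_id %in% genes$id, ]
  }
  prot <- genes[genes$entity_class == "protein", ]
  # gene id -> id of the protein it codes for
  map <- stats::setNames(genes$id, genes$id)
  gene_rows <- genes$entity_class == "gene"
  coded <- stats::setNames(prot$id, prot$coding_gene_id)
  coded <- coded[!is.na(names(coded))]
  has_prot <- genes$id[gene_rows] %in% names(coded)
  orphan <- genes$id[gene_rows][!has_prot]
  if (length(orphan)) {
    warning("gene node(s) with no protein product dropped: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  map[names(coded)] <- unname(coded)
  map[orphan] <- NA_character_

  if (nrow(inter)) {
    inter$a_id <- unname(map[inter$a_id])
    inter$b_id <- unname(map[inter$b_id])
    inter <- inter[!is.na(inter$a_id) & !is.na(inter$b_id), ]
    inter <- inter[inter$a_id != inter$b_id, ]
    key <- paste(pmin(inter$a_id, inter$b_id),
                 pmax(inter$a_id, inter$b_id), inter$link_type, sep = "\r")
    inter <- inter[!duplicated(key), ]
  }
  if (nrow(assoc)) {
    assoc$gene_id <- unname(map[assoc$gene_id])
    assoc <- assoc[!is.na(assoc$gene_id), ]
    assoc <- assoc[!duplicated(paste(assoc$disease_id, assoc$gene_id,
                                     sep = "\r")), ]
  }
  prot$coding_gene_id <- NA_character_
  knowledge_base(kb$diseases, prot, assoc, inter)
}

#' Export a knowledge base or subnetwork as GraphML
#'
#' Writes a deterministic (byte-stable) GraphML document: nodes and edges in
#' radix-sorted order, with node kind (disease/gene/protein) and edge
#' `link_type` as attributes. Disease nodes and association edges are
#' included when present.
#'
#' @param kb A [knowledge_base()] (or the restricted one returned by
#'   subsetting helpers).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(kb, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  nodes <- rbind(
    tibble::tibble(id = kb$diseases$id, kind = "disease"),
    tibble::tibble(id = kb$genes$id, kind = kb$genes$entity_class))
  nodes <- nodes[radix_order(nodes$id), , drop = FALSE]
  edges <- rbind(
    tibble::tibble(a = kb$associations$disease_id,
                   b = kb$associations$gene_id,
                   type = "disease_association"),
    tibble::tibble(a = kb$interactions$a_id, b = kb$interactions$b_id,
                   type = kb$interactions$link_type))
  edges <- edges[radix_order(edges$a, edges$b, edges$type), , drop = FALSE]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
    '  <key id="link_type" for="edge" attr.name="link_type" attr.type="string"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"><data key="kind">%s</data></node>',
            esc(nodes$id), esc(nodes$kind)),
    sprintf(paste0('    <edge source="%s" target="%s">',
                   '<data key="link_type">%s</data></edge>'),
            esc(edges$a), esc(edges$b), esc(edges$type)),
    "  </graph>",
    "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

#' Apply a curation include/exclude filter to the association table
#'
#' Stand-in for an expert-curation step: restricts the disease-gene
#' association table to an allow-list and/or removes a block-list of gene
#' ids before indices and nulls are computed. With both arguments `NULL`
#' this is a no-op.
#'
#' @param kb A [knowledge_base()].
#' @param include Optional character vector: keep only associations to these
#'   gene ids.
#' @param exclude Optional character vector: drop associations to these
#'   gene ids.
#' @return A [knowledge_base()] with the filtered association table.
#' @export
filter_associations <- function(kb, include = NULL, exclude = NULL) {
  a <- kb$associations
  if (!is.null(include)) a <- a[a$gene_id %in% include, ]
  if (!is.null(exclude)) a <- a[!a$gene_id %in% exclude, ]
  kb$associations <- a
  validate_kb(kb)
}
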