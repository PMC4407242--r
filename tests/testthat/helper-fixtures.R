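# Hand-built fixtures and brute-force oracles shared across tests.

# Small mixed KB used throughout: two diseases, a handful of typed links,
# including one multi-typed pair (g1-g2 twice).
tiny_kb <- function() {
  knowledge_base(
    diseases = data.frame(id = c("D1", "D2"), name = c("one", "two")),
    genes = data.frame(id = c("g1", "g2", "g3", "g4", "g5")),
    associations = data.frame(
      disease_id = c("D1", "D1", "D1", "D2", "D2"),
      gene_id = c("g1", "g2", "g3", "g2", "g3"),
      source = "fixture"),
    interactions = data.frame(
      a_id = c("g1", "g1", "g2", "g3"),
      link_type = c("association", "expression", "binding", "catalysis"),
      b_id = c("g2", "g2", "g3", "g4")))
}

# KB with gene/protein duality: geneX codes proteinX, geneY codes proteinY;
# one gene-protein cross link and one gene-own-product link.
duality_kb <- function() {
  knowledge_base(
    diseases = data.frame(id = "D1"),
    genes = data.frame(
      id = c("geneX", "geneY", "protX", "protY"),
      entity_class = c("gene", "gene", "protein", "protein"),
      coding_gene_id = c(NA, NA, "geneX", "geneY")),
    associations = data.frame(disease_id = "D1", gene_id = "protX",
                              source = ""),
    interactions = data.frame(
      a_id = c("geneX", "geneX"),
      link_type = c("association", "expression"),
      b_id = c("protY", "protX")))
}

# Small random KB for property tests; sizes kept tiny so brute force stays
# instant.
random_kb <- function(seed, n_diseases = 6, n_genes = 25, n_links = 40,
                      assoc_per_disease = 2:8) {
  withr::with_seed(seed, {
    gene_ids <- sprintf("g%02d", seq_len(n_genes))
    disease_ids <- sprintf("D%02d", seq_len(n_diseases))
    assoc <- dplyr::bind_rows(lapply(disease_ids, function(d) {
      k <- sample(assoc_per_disease, 1)
      data.frame(disease_id = d, gene_id = sample(gene_ids, k),
                 source = "sim")
    }))
    a <- sample(gene_ids, n_links, replace = TRUE)
    b <- sample(gene_ids, n_links, replace = TRUE)
    keep <- a != b
    inter <- data.frame(
      a_id = a[keep],
      link_type = sample(c("association", "expression", "binding"),
                         sum(keep), replace = TRUE),
      b_id = b[keep])
    inter <- inter[!duplicated(paste(pmin(inter$a_id, inter$b_id),
                                     pmax(inter$a_id, inter$b_id),
                                     inter$link_type)), ]
    knowledge_base(data.frame(id = disease_ids),
                   data.frame(id = gene_ids), assoc, inter)
  })
}

# --- brute-force oracles -------------------------------------------------

oracle_degree <- function(kb, gene_id) {
  partners <- character(0)
  for (r in seq_len(nrow(kb$interactions))) {
    a <- kb$interactions$a_id[r]
    b <- kb$interactions$b_id[r]
    if (a == gene_id) partners <- c(partners, b)
    if (b == gene_id) partners <- c(partners, a)
  }
  length(unique(partners))
}

oracle_induced_counts <- function(kb, genes) {
  pairs <- 0L
  links <- 0L
  genes <- unique(genes)
  if (length(genes) >= 2) {
    cmb <- utils::combn(genes, 2)
    for (i in seq_len(ncol(cmb))) {
      rec <- sum((kb$interactions$a_id == cmb[1, i] &
                    kb$interactions$b_id == cmb[2, i]) |
                   (kb$interactions$a_id == cmb[2, i] &
                      kb$interactions$b_id == cmb[1, i]))
      links <- links + rec
      if (rec > 0) pairs <- pairs + 1L
    }
  }
  list(pairs = pairs, links = links)
}

oracle_cr <- function(group, kb) {
  group <- unique(group)
  if (length(group) < 2) return(NA_real_)
  oracle_induced_counts(kb, group)$pairs / choose(length(group), 2)
}

# Exact upper-tail hypergeometric by enumerating all C(N, n) draws.
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K universe elements carry the term
  mean(hits >= k)
}

# Exhaustive BH step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Complete 5-slot pathway enumeration over all tuples.
oracle_pathways <- function(kb, pattern, partition) {
  cand <- lapply(pattern, function(s) {
    if (s$kind == "disease") intersect(s$ids, kb$diseases$id)
    else unique(partition$gene_id[partition$label %in% s$labels])
  })
  assoc_ok <- function(d, g) {
    any(kb$associations$disease_id == d & kb$associations$gene_id == g)
  }
  inter_ok <- function(x, y) {
    any((kb$interactions$a_id == x & kb$interactions$b_id == y) |
          (kb$interactions$a_id == y & kb$interactions$b_id == x))
  }
  out <- list()
  for (d1 in cand[[1]]) for (g1 in cand[[2]]) for (g2 in cand[[3]])
    for (g3 in cand[[4]]) for (d2 in cand[[5]]) {
      if (anyDuplicated(c(g1, g2, g3))) next
      if (assoc_ok(d1, g1) && inter_ok(g1, g2) && inter_ok(g2, g3) &&
          assoc_ok(d2, g3)) {
        out[[length(out) + 1]] <- c(d1, g1, g2, g3, d2)
      }
    }
  if (!length(out)) {
    return(tibble::tibble(node_1 = character(), node_2 = character(),
                          node_3 = character(), node_4 = character(),
                          node_5 = character()))
  }
  m <- do.call(rbind, out)
  out <- tibble::tibble(node_1 = m[, 1], node_2 = m[, 2], node_3 = m[, 3],
                        node_4 = m[, 4], node_5 = m[, 5])
  out[order(out$node_1, out$node_2, out$node_3, out$node_4, out$node_5,
            method = "radix"), ]
}

# Exact null distribution of connectivity by enumerating every valid
# degree-matched distinct assignment.
oracle_connectivity_null <- function(kb, template) {
  sampler <- build_q_sets(kb, template)
  grids <- expand.grid(sampler$q_sets, stringsAsFactors = FALSE)
  keep <- apply(grids, 1, function(r) !anyDuplicated(r))
  grids <- grids[keep, , drop = FALSE]
  apply(grids, 1, function(r)
    oracle_induced_counts(kb, as.character(r))$pairs)
}

# Single-chain pathway fixture: exactly one valid PE-gA-gC-gB-DM chain.
single_chain_kb <- function() {
  knowledge_base(
    diseases = data.frame(id = c("PE", "DM", "Ob", "GD")),
    genes = data.frame(id = c("gA", "gB", "gC", "gZ")),
    associations = data.frame(
      disease_id = c("PE", "PE", "DM", "DM", "Ob", "GD",
                     "PE", "Ob", "GD"),
      gene_id = c("gA", "gC", "gB", "gC", "gC", "gC",
                  "gZ", "gZ", "gZ"),
      source = "fixture"),
    # gZ is associated with PE, Ob, GD but not DM -> not comorbid;
    # no interactions touch gZ, so only one chain exists
    interactions = data.frame(
      a_id = c("gA", "gC"),
      link_type = c("association", "binding"),
      b_id = c("gC", "gB")))
}
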