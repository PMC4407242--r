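test_that("TSV/SIF loading builds the expected knowledge base", {
  assoc <- withr::local_tempfile(fileext = ".tsv")
  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("# a comment",
               "disease_id\tgene_id\tsource",
               "D1\tg1\tkbA",
               "D1\tg2\tkbA",
               "D2\tg2\tkbB"), assoc)
  writeLines(c("g1\tassociation\tg2",
               "g2\texpression\tg3"), sif)
  kb <- read_knowledge_base(assoc, sif)
  expect_equal(nrow(kb$diseases), 2L)
  expect_equal(nrow(kb$genes), 3L)
  expect_equal(nrow(kb$associations), 3L)
  expect_equal(nrow(kb$interactions), 2L)
  expect_equal(genes_for(kb, "D1"), c("g1", "g2"))
  expect_equal(genes_for(kb, "D2"), "g2")
})

test_that("empty interaction files, declared universes and self-links are handled", {
  assoc <- withr::local_tempfile(fileext = ".tsv")
  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("disease_id\tgene_id\tsource", "D1\tg1\tx"), assoc)
  writeLines(character(0), sif)
  kb <- read_knowledge_base(assoc, sif)
  expect_equal(nrow(kb$interactions), 0L)

  # declared universe: an undeclared disease id is an error, a declared
  # disease with no rows still exists
  writeLines(c("#%diseases: D1 D9",
               "disease_id\tgene_id\tsource", "D1\tg1\tx"), assoc)
  kb <- read_knowledge_base(assoc, sif)
  expect_setequal(kb$diseases$id, c("D1", "D9"))
  expect_equal(genes_for(kb, "D9"), character(0))
  writeLines(c("#%diseases: D1",
               "disease_id\tgene_id\tsource", "D2\tg1\tx"), assoc)
  expect_error(read_knowledge_base(assoc, sif), "declared universe")

  # self-links dropped with a warning naming the row
  writeLines(c("disease_id\tgene_id\tsource", "D1\tg1\tx"), assoc)
  writeLines(c("g1\tbinding\tg1", "g1\tbinding\tg2"), sif)
  expect_warning(kb <- read_knowledge_base(assoc, sif), "self-link")
  expect_equal(nrow(kb$interactions), 1L)
})

test_that("constructor enforces referential integrity", {
  expect_error(knowledge_base(
    data.frame(id = "D1"), data.frame(id = "g1"),
    data.frame(disease_id = "D2", gene_id = "g1")), "unknown diseases")
  expect_error(knowledge_base(
    data.frame(id = "D1"), data.frame(id = "g1"),
    interactions = data.frame(a_id = "g1", link_type = "binding",
                              b_id = "gX")), "unknown nodes")
  expect_error(knowledge_base(
    data.frame(id = c("D1", "D1")), data.frame(id = "g1")),
    "duplicate disease")
  expect_error(genes_for(tiny_kb(), "nope"), "unknown disease")
})

test_that("round trip through write + read preserves every table", {
  kb <- tiny_kb()
  assoc <- withr::local_tempfile(fileext = ".tsv")
  sif <- withr::local_tempfile(fileext = ".sif")
  nodes <- withr::local_tempfile(fileext = ".tsv")
  write_knowledge_base(kb, assoc, sif, nodes)
  kb2 <- read_knowledge_base(assoc, sif, nodes)
  expect_setequal(kb2$diseases$id, kb$diseases$id)
  expect_setequal(kb2$genes$id, kb$genes$id)
  expect_setequal(paste(kb2$associations$disease_id,
                        kb2$associations$gene_id),
                  paste(kb$associations$disease_id,
                        kb$associations$gene_id))
  expect_setequal(paste(kb2$interactions$a_id, kb2$interactions$link_type,
                        kb2$interactions$b_id),
                  paste(kb$interactions$a_id, kb$interactions$link_type,
                        kb$interactions$b_id))
  # writers are byte-stable
  assoc2 <- withr::local_tempfile(); sif2 <- withr::local_tempfile()
  write_knowledge_base(kb2, assoc2, sif2)
  write_knowledge_base(kb, assoc, sif)
  expect_identical(readLines(assoc), readLines(assoc2))
  expect_identical(readLines(sif), readLines(sif2))
})

test_that("degree counts distinct partners, matching brute force", {
  kb <- tiny_kb()
  # g1 has two typed links to g2 only -> one partner
  expect_equal(gene_degree(kb, "g1")$degree, 1L)
  expect_equal(gene_degree(kb, "g5")$degree, 0L)
  expect_equal(gene_degree(kb, "g1", count = "records")$degree, 2L)
  expect_error(gene_degree(kb, "nope"), "unknown gene")
  for (seed in 1:5) {
    rkb <- random_kb(seed)
    deg <- gene_degree(rkb)
    for (r in seq_len(nrow(deg))) {
      expect_equal(deg$degree[r], oracle_degree(rkb, deg$gene_id[r]))
    }
  }
})

test_that("collapse to protein network reassigns gene links and is idempotent", {
  kb <- duality_kb()
  collapsed <- collapse_to_protein_network(kb)
  expect_setequal(collapsed$genes$id, c("protX", "protY"))
  # geneX-protY becomes protX-protY; geneX-protX becomes a dropped self-link
  expect_equal(nrow(collapsed$interactions), 1L)
  expect_setequal(c(collapsed$interactions$a_id,
                    collapsed$interactions$b_id), c("protX", "protY"))
  twice <- collapse_to_protein_network(collapsed)
  expect_equal(twice$interactions, collapsed$interactions)
  expect_equal(twice$genes, collapsed$genes)

  # protein-only network is unchanged
  pkb <- knowledge_base(
    data.frame(id = "D1"),
    data.frame(id = c("p1", "p2"), entity_class = "protein"),
    interactions = data.frame(a_id = "p1", link_type = "binding",
                              b_id = "p2"))
  same <- collapse_to_protein_network(pkb)
  expect_equal(same$interactions$a_id, "p1")
  expect_equal(nrow(same$genes), 2L)

  # orphan gene (no protein product) dropped with warning
  okb <- knowledge_base(
    data.frame(id = "D1"),
    data.frame(id = c("gOnly", "p1"),
               entity_class = c("gene", "protein")),
    interactions = data.frame(a_id = "gOnly", link_type = "binding",
                              b_id = "p1"))
  expect_warning(out <- collapse_to_protein_network(okb), "no protein")
  expect_equal(out$genes$id, "p1")
  expect_equal(nrow(out$interactions), 0L)
})

test_that("graphml export is deterministic and well-formed", {
  kb <- tiny_kb()
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_graphml(kb, f1); write_graphml(kb, f2)
  expect_identical(readLines(f1), readLines(f2))
  txt <- readLines(f1)
  expect_equal(sum(grepl("<node ", txt)), nrow(kb$diseases) + nrow(kb$genes))
  expect_equal(sum(grepl("<edge ", txt)),
               nrow(kb$associations) + nrow(kb$interactions))
})

test_that("curation filter restricts associations and defaults to a no-op", {
  kb <- tiny_kb()
  expect_equal(filter_associations(kb)$associations, kb$associations)
  kept <- filter_associations(kb, include = c("g1", "g2"))
  expect_setequal(kept$associations$gene_id, c("g1", "g2"))
  dropped <- filter_associations(kb, exclude = "g2")
  expect_false("g2" %in% dropped$associations$gene_id)
})
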