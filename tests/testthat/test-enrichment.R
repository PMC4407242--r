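test_that("hypergeometric enrichment reproduces the exact worked case", {
  # N = 10, K = 4, n = 3, k = 2:
  # p = (C(4,2) C(6,1) + C(4,3) C(6,0)) / C(10,3) = 40 / 120 = 1/3
  universe <- sprintf("u%02d", 1:10)
  ann <- annotation_set(
    data.frame(term_id = "T1", gene_id = universe[1:4]),
    universe = universe)
  study <- c(universe[1:2], universe[10])
  res <- hypergeometric_enrichment(study, ann)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$k, 2L)
  expect_equal(res$K, 4L)
  expect_equal(res$N, 10L)
})

test_that("terms with no study genes are excluded; saturation gives p = 1", {
  universe <- sprintf("u%02d", 1:8)
  ann <- annotation_set(
    data.frame(term_id = c(rep("hit", 3), rep("miss", 2)),
               gene_id = c(universe[1:3], universe[7:8])),
    universe = universe)
  res <- hypergeometric_enrichment(universe[1:3], ann)
  expect_equal(res$term_id, "hit")
  # study = universe saturates every term at p = 1
  res_all <- hypergeometric_enrichment(universe, ann)
  expect_true(all(res_all$p_value == 1))
  # study genes outside the universe are dropped with a warning
  expect_warning(hypergeometric_enrichment(c(universe[1:2], "alien"), ann),
                 "outside the reference universe")
  expect_error(hypergeometric_enrichment(character(0), ann), "empty study")
})

test_that("hypergeometric tail agrees with exhaustive draw enumeration", {
  for (N in c(5, 8, 12)) {
    universe <- sprintf("u%02d", seq_len(N))
    for (K in c(2, N %/% 2)) {
      ann <- annotation_set(
        data.frame(term_id = "T", gene_id = universe[1:K]),
        universe = universe)
      for (n in c(2, min(5, N - 1))) {
        study <- universe[seq_len(n)]  # k = min(n, K) study hits
        res <- hypergeometric_enrichment(study, ann)
        k <- res$k
        expect_equal(res$p_value, oracle_hyper_tail(N, K, n, k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("BH q-values match the hand-worked case and the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(8, {
    for (rep in 1:50) {
      p <- stats::runif(sample(1:20, 1))
      q <- benjamini_hochberg(p)
      expect_equal(q, oracle_bh(p))
      # the step-up monotonicity enforcement is a fixed point: re-running
      # the cummin pass over sorted q-values changes nothing
      qs <- q[order(p)]
      expect_equal(rev(cummin(rev(qs))), qs)
      expect_true(all(diff(qs) >= -1e-12))
      expect_true(all(q >= p - 1e-12))
    }
  })
})

test_that("connectivity rate equals the brute-force pair ratio", {
  net <- data.frame(a_id = "a", link_type = "binding", b_id = "b")
  expect_equal(connectivity_rate(c("a", "b", "c"), net), 1 / 3)
  tri <- data.frame(a_id = c("a", "a", "b"), link_type = "binding",
                    b_id = c("b", "c", "c"))
  expect_equal(connectivity_rate(c("a", "b", "c"), tri), 1)
  expect_true(is.na(connectivity_rate("a", net)))
  for (seed in 1:10) {
    kb <- random_kb(seed, n_genes = 15, n_links = 30)
    group <- sample(kb$genes$id, sample(2:8, 1))
    expect_equal(connectivity_rate(group, kb), oracle_cr(group, kb))
  }
})

test_that("CR ranking is descending with deterministic tie-breaks", {
  procs <- tibble::tibble(
    term_id = c("t1", "t2", "t3", "t4", "t5"),
    term_name = c("t1", "t2", "t3", "t4", "t5"),
    k = 2L, n_study = 5L, K = 3L, N = 20L,
    p_value = c(0.01, 0.02, 0.03, 0.005, 0.04),
    q_value = c(0.05, 0.02, 0.05, 0.01, 0.08),
    cr = c(0.5, 1.0, NA, 1.0, 0.5))
  ranked <- rank_by_cr(procs)
  # CR desc; CR=1 tie broken by q (t4 before t2); NA CR last
  expect_equal(ranked$term_id, c("t4", "t2", "t1", "t5", "t3"))
  expect_equal(nrow(rank_by_cr(procs[0, ])), 0L)
})

test_that("annotation files parse from GAF and plain TSV", {
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("DB", "g1", "G1", "", "GO:0001", "ref", "IEA", "",
                     "P", "", "", "protein", "taxon:9606", "20130501",
                     "UniProt", sep = "\t"),
               paste("DB", "g2", "G2", "", "GO:0001", "ref", "IEA", "",
                     "P", "", "", "protein", "taxon:9606", "20130501",
                     "UniProt", sep = "\t")), gaf)
  ann <- read_annotation(gaf)
  expect_setequal(ann$mapping$gene_id, c("g1", "g2"))
  expect_equal(unique(ann$mapping$term_id), "GO:0001")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term_id\tgene_id", "GO:1\tg1", "GO:1\tg2", "GO:2\tg2"), tsv)
  ann2 <- read_annotation(tsv)
  expect_equal(nrow(ann2$mapping), 3L)
  expect_setequal(ann2$universe, c("g1", "g2"))
})

test_that("enrichment plus CR flows through on a knowledge base", {
  kb <- random_kb(4, n_genes = 30, n_links = 80)
  withr::with_seed(1, {
    mapping <- data.frame(
      term_id = rep(c("GO:a", "GO:b"), each = 10),
      gene_id = c(sample(kb$genes$id, 10), sample(kb$genes$id, 10)))
  })
  ann <- annotation_set(mapping, universe = kb$genes$id)
  study <- unique(mapping$gene_id)[1:8]
  res <- hypergeometric_enrichment(study, ann)
  res <- add_connectivity_rate(res, kb)
  expect_true(all(is.na(res$cr) | (res$cr >= 0 & res$cr <= 1)))
  expect_true(all(res$cr[res$k < 2] %in% NA_real_))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(rank_by_cr(res), f)
  expect_named(readr::read_tsv(f, show_col_types = FALSE),
               c("term_id", "name", "k", "n", "K", "N", "p", "q", "CR"))
})
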