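small_planted_config <- function(seed = 1L) {
  synthetic_config(
    n_diseases = 12, n_genes = 200,
    planted_pairs = data.frame(
      disease_a = c("D001", "D001"), disease_b = c("D002", "D003"),
      n_shared = 8, rho = 1, group = "core"),
    planted_terms = data.frame(term_id = "GO:planted", n_annotated = 8,
                               fraction_from_comorbid = 1),
    n_background_terms = 10, seed = seed)
}

test_that("generation is deterministic and reloads with zero warnings", {
  cfg <- small_planted_config(5)
  g1 <- generate_kb(cfg)
  g2 <- generate_kb(cfg)
  expect_identical(g1$kb$interactions, g2$kb$interactions)
  expect_identical(g1$kb$associations, g2$kb$associations)
  expect_identical(g1$ground_truth$shared_pools, g2$ground_truth$shared_pools)

  d <- withr::local_tempdir()
  write_knowledge_base(g1$kb, file.path(d, "a.tsv"), file.path(d, "i.sif"))
  write_knowledge_base(g2$kb, file.path(d, "a2.tsv"), file.path(d, "i2.sif"))
  expect_identical(readLines(file.path(d, "a.tsv")),
                   readLines(file.path(d, "a2.tsv")))
  expect_identical(readLines(file.path(d, "i.sif")),
                   readLines(file.path(d, "i2.sif")))
  expect_no_warning(
    kb <- read_knowledge_base(file.path(d, "a.tsv"), file.path(d, "i.sif")))
  expect_equal(nrow(kb$associations), nrow(g1$kb$associations))
})

test_that("planted pairs share at least n_shared genes; rho = 1 forms a clique", {
  cfg <- small_planted_config(3)
  gen <- generate_kb(cfg)
  kb <- gen$kb
  pool <- gen$ground_truth$shared_pools$gene_id
  expect_equal(length(pool), 8L)
  for (i in 1:2) {
    pp <- cfg$planted_pairs[i, ]
    shared <- intersect(genes_for(kb, pp$disease_a),
                        genes_for(kb, pp$disease_b))
    expect_gte(length(shared), pp$n_shared)
    expect_true(all(pool %in% shared))
  }
  # rho = 1: every planted pair of pool genes is linked, CR = 1
  expect_equal(connectivity_rate(pool, kb), 1)
})

test_that("without planted structure, overlaps match the hypergeometric expectation", {
  cfg <- synthetic_config(n_diseases = 40, n_genes = 400,
                          n_background_terms = 0, seed = 11)
  kb <- generate_kb(cfg)$kb
  pairs <- sample_random_disease_pairs(kb, 100, seed = 2)
  sets <- split(kb$associations$gene_id, kb$associations$disease_id)
  obs <- exp_i <- var_i <- numeric(nrow(pairs))
  N <- nrow(kb$genes)
  for (r in seq_len(nrow(pairs))) {
    a <- sets[[pairs$disease_a[r]]]
    b <- sets[[pairs$disease_b[r]]]
    obs[r] <- length(intersect(a, b))
    m <- length(a); k <- length(b)
    exp_i[r] <- m * k / N
    var_i[r] <- m * k * (N - m) * (N - k) / (N^2 * (N - 1))
  }
  z <- (mean(obs) - mean(exp_i)) / sqrt(sum(var_i) / length(obs)^2)
  expect_lt(abs(z), 3)
})

test_that("planted annotation terms draw the stated comorbid fraction", {
  cfg <- small_planted_config(9)
  gen <- generate_kb(cfg)
  ann <- generate_annotation(cfg, gen$kb, gen$ground_truth)
  planted <- ann$ground_truth[ann$ground_truth$planted, ]
  # fraction_from_comorbid = 1 and n_annotated = pool size: the term
  # annotates exactly the planted pool
  expect_setequal(planted$gene_id, gen$ground_truth$shared_pools$gene_id)
  expect_equal(length(unique(ann$ground_truth$term_id)), 11L)
  expect_setequal(ann$annotation$universe, gen$kb$genes$id)

  # fraction 0 terms are uniform draws
  cfg0 <- synthetic_config(
    n_diseases = 12, n_genes = 200,
    planted_pairs = data.frame(disease_a = "D001", disease_b = "D002",
                               n_shared = 8, rho = 0.5, group = "core"),
    planted_terms = data.frame(term_id = "bg", n_annotated = 10,
                               fraction_from_comorbid = 0),
    n_background_terms = 0, seed = 2)
  gen0 <- generate_kb(cfg0)
  ann0 <- generate_annotation(cfg0, gen0$kb, gen0$ground_truth)
  expect_equal(nrow(ann0$ground_truth), 10L)
})

test_that("infeasible configurations error out", {
  expect_error(synthetic_config(n_diseases = 1), "n_diseases")
  expect_error(synthetic_config(planted_pairs = data.frame(
    disease_a = "D001", disease_b = "D002", n_shared = 10, rho = 2)))
  cfg <- synthetic_config(
    n_diseases = 5, n_genes = 20,
    planted_pairs = data.frame(disease_a = "D001", disease_b = "D002",
                               n_shared = 5, rho = 0, group = "g"),
    planted_terms = data.frame(term_id = "t", n_annotated = 10,
                               fraction_from_comorbid = 1),
    n_background_terms = 0, seed = 1)
  gen <- generate_kb(cfg)
  expect_error(generate_annotation(cfg, gen$kb, gen$ground_truth),
               "infeasible")
})

test_that("the pipeline's detection does not hinge on the log-normal size law", {
  # swap in near-uniform association sizes (tiny sdlog): planted overlap is
  # still recovered against the random-pair null
  cfg <- synthetic_config(
    n_diseases = 30, n_genes = 400, assoc_meanlog = log(15),
    assoc_sdlog = 0.05,
    planted_pairs = data.frame(disease_a = "D001", disease_b = "D002",
                               n_shared = 10, rho = 0.3, group = "core"),
    n_background_terms = 0, seed = 21)
  kb <- generate_kb(cfg)$kb
  null <- relation_index_null(kb, 500, seed = 3)
  rep <- relation_indices(kb, "D001", "D002", null = null)
  expect_lte(rep$p_i, 0.05)
  expect_lte(rep$p_j, 0.05)
})

test_that("ground truth serializes alongside the knowledge base", {
  gen <- generate_kb(small_planted_config(4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(gen$ground_truth, f)
  txt <- readLines(f)
  expect_true(any(grepl("shared_pools", txt)))
  expect_true(any(grepl("planted_pairs", txt)))
})
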