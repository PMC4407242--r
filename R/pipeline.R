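#' Assemble an analysis configuration
#'
#' A single configuration object drives the end-to-end analysis: input
#' paths, the focal disease and its partner diseases, replicate counts for
#' the two permutation nulls, the mandatory seed, tie convention,
#' connectivity statistic, an optional curation include/exclude gene list
#' and an optional custom pathway pattern. [read_analysis_config()] loads
#' the same structure from a YAML file.
#'
#' @param associations,interactions Paths to the knowledge-base input
#'   files (see [read_knowledge_base()]).
#' @param focal_disease,partner_diseases The disease combination under
#'   study.
#' @param seed Integer seed; mandatory, so no run is silently
#'   nondeterministic.
#' @param nodes,annotation Optional paths: node sidecar, annotation file.
#' @param n_disease_pairs Replicates for the relation-index null
#'   (default 10000).
#' @param n_networks Replicates for each degree-matched connectivity null
#'   (default 1000).
#' @param tie Tie convention, see [empirical_pvalue()].
#' @param connectivity_stat `"pairs"` or `"links"`.
#' @param protein_level Collapse to a protein-protein network before the
#'   connectivity stage.
#' @param include,exclude Optional curation gene-id lists applied to the
#'   association table before any computation.
#' @param pattern Optional list-of-slots specification for the pathway
#'   search; `NULL` uses [comorbidity_pattern()] over the configured
#'   diseases. Each element is a list with `kind` ("disease"/"gene") and
#'   `ids` or `labels`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(associations, interactions, focal_disease,
                            partner_diseases, seed, nodes = NULL,
                            annotation = NULL, n_disease_pairs = 10000L,
                            n_networks = 1000L,
                            tie = c("paper", "add_one"),
                            connectivity_stat = c("pairs", "links"),
                            protein_level = FALSE,
                            include = NULL, exclude = NULL,
                            pattern = NULL) {
  cfg <- list(associations = associations, interactions = interactions,
              nodes = nodes, annotation = annotation,
              focal_disease = focal_disease,
              partner_diseases = partner_diseases,
              n_disease_pairs = as.integer(n_disease_pairs),
              n_networks = as.integer(n_networks),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              tie = match.arg(tie),
              connectivity_stat = match.arg(connectivity_stat),
              protein_level = isTRUE(protein_level),
              include = include, exclude = exclude, pattern = pattern)
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [analysis_config()]; relative input paths are resolved against the
#'   YAML file's directory.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  analysis_config(
    associations = resolve(y$associations),
    interactions = resolve(y$interactions),
    nodes = resolve(y$nodes),
    annotation = resolve(y$annotation),
    focal_disease = y$focal_disease,
    partner_diseases = unlist(y$partner_diseases),
    seed = y$seed,
    n_disease_pairs = y$n_disease_pairs %||% 10000L,
    n_networks = y$n_networks %||% 1000L,
    tie = y$tie %||% "paper",
    connectivity_stat = y$connectivity_stat %||% "pairs",
    protein_level = y$protein_level %||% FALSE,
    include = unlist(y$include), exclude = unlist(y$exclude),
    pattern = y$pattern)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pattern_from_config <- function(cfg, kb = NULL) {
  if (is.null(cfg$pattern)) {
    return(comorbidity_pattern(cfg$focal_disease, cfg$partner_diseases))
  }
  slots <- lapply(cfg$pattern, function(s) {
    if (identical(s$kind, "disease")) slot_disease(unlist(s$ids))
    else if (identical(s$kind, "gene")) slot_gene(unlist(s$labels))
    else stop("pattern slot kind must be 'disease' or 'gene'",
              call. = FALSE)
  })
  node_class_pattern(slots)
}

#' Validate an analysis configuration
#'
#' Checks every invariant the pipeline relies on, distinguishing warnings
#' from errors: missing seed, unreadable inputs, diseases absent from the
#' knowledge base, pattern slots referencing partition labels that the
#' configured diseases cannot produce.
#'
#' @param config An `analysis_config`.
#' @param kb Optional pre-loaded [knowledge_base()]; when `NULL` the
#'   configured input files are loaded for the check.
#' @return A tibble with columns `level` ("error" or "warning") and
#'   `message`; zero rows means the configuration is valid.
#' @export
validate_config <- function(config, kb = NULL) {
  probs <- list()
  note <- function(level, msg) {
    probs[[length(probs) + 1L]] <<- tibble::tibble(level = level,
                                                   message = msg)
  }
  if (is.null(config$seed) || is.na(config$seed)) {
    note("error", "seed is mandatory")
  }
  for (f in c("associations", "interactions")) {
    if (is.null(config[[f]])) note("error", paste(f, "path missing"))
    else if (!file.exists(config[[f]])) {
      note("error", paste(f, "file not found:", config[[f]]))
    }
  }
  if (is.null(config$focal_disease)) note("error", "focal_disease missing")
  if (length(config$partner_diseases) < 1L) {
    note("error", "at least one partner disease required")
  }
  if (config$n_disease_pairs < 1L || config$n_networks < 1L) {
    note("error", "replicate counts must be positive")
  }
  if (is.null(kb) && is.null(config$associations)) {
    # nothing further checkable
  } else {
    kb_ok <- TRUE
    if (is.null(kb)) {
      kb <- tryCatch(read_knowledge_base(config$associations,
                                         config$interactions,
                                         config$nodes),
                     error = function(e) {
                       note("error", paste("knowledge base:",
                                           conditionMessage(e)))
                       kb_ok <<- FALSE
                       NULL
                     })
    }
    if (kb_ok && !is.null(kb)) {
      miss <- setdiff(c(config$focal_disease, config$partner_diseases),
                      kb$diseases$id)
      if (length(miss)) {
        note("error", paste("disease(s) absent from the knowledge base:",
                            paste(miss, collapse = ", ")))
      }
      if (!is.null(config$pattern)) {
        known <- c("comorbid",
                   paste0("specific:", c(config$focal_disease,
                                         config$partner_diseases)))
        labs <- unlist(lapply(config$pattern, function(s)
          if (identical(s$kind, "gene")) unlist(s$labels)))
        bad <- setdiff(labs, known)
        if (length(bad)) {
          note("error", paste("pattern references undefined partition",
                              "label(s):", paste(bad, collapse = ", ")))
        }
      }
      if (!is.null(config$annotation) &&
          !file.exists(config$annotation)) {
        note("error", paste("annotation file not found:",
                            config$annotation))
      }
    }
  }
  if (length(probs)) dplyr::bind_rows(probs)
  else tibble::tibble(level = character(), message = character())
}

#' Run the full comorbidity analysis
#'
#' Executes every stage in order on a validated configuration and writes a
#' deterministic report bundle into `out_dir`: per-pair relation-index
#' reports with empirical p-values against a shared random-disease-pair
#' null; connectivity reports (degree-matched null) for each focal-partner
#' pair's comorbid set and for the all-diseases intersection; when an
#' annotation is configured, the CR-ranked enrichment table of the
#' all-diseases comorbid set; the pathway matches and merged pathway
#' network; and a manifest recording input checksums, parameters, seed and
#' package version. Identical configuration and seed produce a
#' byte-identical bundle. Stage failures abort with a stage-labelled
#' message and leave no partial outputs (files are staged in a temporary
#' directory and only moved on success).
#'
#' @param config An `analysis_config`.
#' @param out_dir Output directory (created if needed; files inside are
#'   overwritten).
#' @return Invisibly, a list with the in-memory results: `indices`,
#'   `index_null`, `connectivity` (list of reports), `enrichment` (or
#'   `NULL`), `pathways`, `pathway_network`, `manifest`.
#' @export
run_full_analysis <- function(config, out_dir) {
  problems <- validate_config(config)
  if (any(problems$level == "error")) {
    stop("[validate] invalid configuration:\n  ",
         paste(problems$message[problems$level == "error"],
               collapse = "\n  "), call. = FALSE)
  }
  stage <- tempfile("associome_bundle_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  warnings_log <- character(0)
  withCallingHandlers({
    kb <- run_stage("load", {
      kb <- read_knowledge_base(config$associations, config$interactions,
                                config$nodes)
      filter_associations(kb, include = config$include,
                          exclude = config$exclude)
    })
    if (config$protein_level) {
      kb <- run_stage("collapse", collapse_to_protein_network(kb))
    }

    res <- list()
    run_stage("indices", {
      res$index_null <- relation_index_null(kb, config$n_disease_pairs,
                                            config$seed)
      res$indices <- relation_indices(
        kb, rep(config$focal_disease, length(config$partner_diseases)),
        config$partner_diseases, null = res$index_null, tie = config$tie)
      write_relation_report(res$indices,
                            file.path(stage, "relation_indices.tsv"))
      write_null_tsv(res$index_null, file.path(stage, "index_null.tsv"))
    })

    run_stage("connectivity", {
      combos <- c(lapply(config$partner_diseases, function(d)
        c(config$focal_disease, d)),
        list(c(config$focal_disease, config$partner_diseases)))
      res$connectivity <- list()
      for (i in seq_along(combos)) {
        genes <- comorbid_gene_set(kb, combos[[i]])
        if (length(genes) < 2L) {
          warnings_log <- c(warnings_log, paste0(
            "connectivity: comorbid set of ",
            paste(combos[[i]], collapse = "&"),
            " has fewer than 2 genes; skipped"))
          next
        }
        res$connectivity[[length(res$connectivity) + 1L]] <-
          score_connectivity(kb, disease_ids = combos[[i]],
                             n_null = config$n_networks,
                             seed = config$seed + i,
                             stat = config$connectivity_stat,
                             tie = config$tie)
      }
      if (length(res$connectivity)) {
        write_connectivity_report(
          res$connectivity, file.path(stage, "connectivity_reports.tsv"))
        last <- res$connectivity[[length(res$connectivity)]]
        write_subnetwork_graphml(
          last$subnetwork, file.path(stage, "comorbid_subnetwork.graphml"))
      }
    })

    run_stage("enrichment", {
      if (!is.null(config$annotation)) {
        ann <- read_annotation(config$annotation)
        study <- comorbid_gene_set(kb, c(config$focal_disease,
                                         config$partner_diseases))
        if (length(study)) {
          sub <- induced_subnetwork(kb, intersect(study, kb$genes$id))
          res$enrichment <- rank_by_cr(add_connectivity_rate(
            hypergeometric_enrichment(study, ann), sub))
          write_enrichment_tsv(res$enrichment,
                               file.path(stage, "enrichment.tsv"))
        } else {
          warnings_log <- c(warnings_log,
                             "enrichment: empty comorbid study set; skipped")
        }
      }
    })

    run_stage("pathways", {
      partition <- build_gene_partition(kb, config$focal_disease,
                                        config$partner_diseases)
      pattern <- pattern_from_config(config)
      res$pathways <- find_pathways(kb, pattern, partition)
      res$pathway_network <- merge_pathways(res$pathways, kb)
      write_pathways_tsv(res$pathways, file.path(stage, "pathways.tsv"))
      write_pathway_graphml(res$pathway_network,
                            file.path(stage, "pathway_network.graphml"))
      write_pathway_sif(res$pathway_network,
                        file.path(stage, "pathway_network.sif"))
    })

    run_stage("manifest", {
      inputs <- Filter(Negate(is.null),
                       config[c("associations", "interactions", "nodes",
                                "annotation")])
      res$manifest <- list(
        package = "associome",
        version = as.character(utils::packageVersion("associome")),
        seed = config$seed,
        parameters = list(
          focal_disease = config$focal_disease,
          partner_diseases = config$partner_diseases,
          n_disease_pairs = config$n_disease_pairs,
          n_networks = config$n_networks,
          tie = config$tie,
          connectivity_stat = config$connectivity_stat,
          protein_level = config$protein_level,
          include = config$include, exclude = config$exclude),
        inputs = lapply(inputs, function(p)
          list(path = p, md5 = unname(tools::md5sum(p)))),
        warnings = as.list(warnings_log))
      yaml::write_yaml(res$manifest, file.path(stage, "manifest.yaml"))
    })
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(stage)) {
    file.copy(file.path(stage, f), file.path(out_dir, f), overwrite = TRUE)
  }
  invisible(res)
}
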