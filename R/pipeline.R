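#' Modify a simulation configuration
#'
#' Returns a new, re-validated [sim_config()] with the given fields
#' replaced.
#'
#' @param config a `sim_config`.
#' @param ... fields to override.
#' @return a `sim_config`.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  do.call(sim_config, utils::modifyList(unclass(config), list(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

manifest_entry <- function(dir, files) {
  files <- files[file.exists(file.path(dir, files))]
  md5 <- unname(tools::md5sum(file.path(dir, files)))
  stats::setNames(as.list(md5), files)
}

#' Write a complete synthetic study bundle to disk
#'
#' Materializes every input the analysis pipeline consumes, with planted
#' ground truth: two case/control cohorts per RNA class (a main cohort at
#' the configured sample sizes and a small 3 vs 3 replicate sharing the same
#' planted truth, in the spirit of a second independent study), the
#' miRNA-target and miRNA-lncRNA interaction tables, a scored PPI edge
#' table over the mRNA genes, gene sets in GMT with planted enrichment, and
#' the three-timepoint time course. Ground-truth tables and a JSON manifest
#' (package version, configuration, file checksums) are written alongside.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param n_case_b,n_control_b sample sizes of the small replicate cohort.
#' @return invisibly, the manifest as a list.
#' @export
run_simulate <- function(config, out_dir, n_case_b = 3L, n_control_b = 3L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  stage_log("simulate", "cohort A (%d vs %d) and cohort B (%d vs %d)",
            config$n_case, config$n_control, n_case_b, n_control_b)
  cohort_a <- run_stage("simulate-cohorts", generate_cohort(config))
  cfg_b <- update_config(config, n_case = n_case_b, n_control = n_control_b,
                         seed = config$seed + 1L)
  cohort_b <- run_stage("simulate-cohorts",
                        generate_cohort(cfg_b, truth = cohort_a$truth))
  truth <- cohort_a$truth

  for (cl in names(cohort_a$matrices)) {
    write_expression_tsv(cohort_a$matrices[[cl]],
                         p(sprintf("expr_cohortA_%s.tsv", cl)))
    write_expression_tsv(cohort_b$matrices[[cl]],
                         p(sprintf("expr_cohortB_%s.tsv", cl)))
  }
  write_tsv(cohort_a$metadata, p("metadata_cohortA.tsv"))
  write_tsv(cohort_b$metadata, p("metadata_cohortB.tsv"))

  stage_log("simulate", "interaction databases (%d x mir-mRNA + lnc-mir)",
            config$n_databases)
  dbs <- run_stage("simulate-databases",
                   generate_interaction_dbs(truth, config))
  write_tsv(dbs$mir_mrna, p("interactions_mir_mrna.tsv"))
  write_tsv(dbs$lnc_mir, p("interactions_lnc_mir.tsv"))
  write_tsv(dbs$provenance, p("interactions_provenance.tsv"))

  stage_log("simulate", "PPI edges and gene sets over %d mRNA genes",
            config$n_mrna)
  ppi <- run_stage("simulate-ppi",
                   generate_ppi(truth$features$mRNA, config))
  write_tsv(ppi, p("ppi_edges.tsv"))
  gs <- run_stage("simulate-genesets",
                  generate_genesets(truth$features$mRNA, config))
  write_gmt(gs$sets, p("genesets.gmt"))
  writeLines(gs$universe, p("geneset_universe.txt"))
  writeLines(gs$truth$query, p("truth_query.txt"))
  writeLines(gs$truth$enriched_sets, p("truth_enriched_sets.txt"))

  stage_log("simulate", "time course (%s samples)",
            paste(config$samples_per_timepoint, collapse = "/"))
  tc <- run_stage("simulate-timecourse", generate_timecourse(config))
  write_expression_tsv(tc$matrix, p("timecourse_expr.tsv"))
  write_tsv(tc$metadata, p("timecourse_metadata.tsv"))

  write_tsv(truth$de, p("truth_de.tsv"))
  write_tsv(truth$triples, p("truth_triples.tsv"))
  write_tsv(tc$truth$trends, p("truth_trends.tsv"))

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "cernet",
    version = as.character(utils::packageVersion("cernet")),
    seed = config$seed,
    config = unclass(config),
    replicate_cohort = list(n_case = n_case_b, n_control = n_control_b),
    files = manifest_entry(out_dir, sort(files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

default_params <- function(params) {
  utils::modifyList(list(
    p_thresh = 0.05, lfc_thresh = 0.585, min_db = 3L, min_score = 0.7,
    min_sd = 0.05, membership_threshold = 0.5, centers = 10L, m = "auto",
    hub_k = 10L, seed = 1L), params)
}

de_one <- function(bundle, cohort, class, params) {
  mat <- ensure_log2(read_expression_tsv(
    file.path(bundle, sprintf("expr_%s_%s.tsv", cohort, class))))
  meta <- read_tsv(file.path(bundle, sprintf("metadata_%s.tsv", cohort)))
  groups <- meta$group[match(colnames(mat), meta$sample)]
  fit <- moderated_t_test(mat, groups)
  screen_de(fit, class = class, p_thresh = params$p_thresh,
            lfc_thresh = params$lfc_thresh)
}

#' Run the full ceRNA analysis chain on a study bundle
#'
#' Executes, in order: per-dataset differential expression (moderated t +
#' p/fold-change screen) with combination and intersection across the two
#' cohorts; id normalization and >= `min_db` evidence filtering of
#' miRNA-mRNA pairs; sign-consistent triple assembly and ceRNA network
#' construction with degree-ranked hubs; PPI thresholding, summary and hub
#' ranking restricted to the ceRNA mRNAs; Fisher over-representation of the
#' ceRNA mRNAs against the bundle's gene sets; and the time-course chain
#' (timepoint means, SD filter, standardization, fuzzy c-means, trend
#' classification, trend/ceRNA intersections). Every stage writes its
#' outputs as TSV (networks additionally as SIF and GraphML) into
#' `out_dir`; a failure aborts with the stage name while earlier outputs
#' are preserved. A summary table and a JSON manifest complete the bundle.
#'
#' @param bundle_dir directory produced by [run_simulate()] (or files in the
#'   same layout).
#' @param out_dir output directory (created if missing).
#' @param params named list overriding the screening parameters
#'   (`p_thresh = 0.05`, `lfc_thresh = 0.585`, `min_db = 3`,
#'   `min_score = 0.7`, `min_sd = 0.05`, `membership_threshold = 0.5`,
#'   `centers = 10`, `m = "auto"`, `hub_k = 10`, `seed = 1`).
#' @return invisibly, a list with the main in-memory results (DE tables,
#'   triples, networks, enrichment, clustering, summary).
#' @export
run_all <- function(bundle_dir, out_dir, params = list()) {
  params <- default_params(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  summary_rows <- list()
  note <- function(stage, metric, value)
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(stage = stage, metric = metric, value = as.character(value),
                 stringsAsFactors = FALSE)

  ## -- differential expression ------------------------------------------
  stage_log("de", "screening at p < %g, |log2FC| > %g",
            params$p_thresh, params$lfc_thresh)
  de <- run_stage("de", {
    de_sets <- list(
      lncRNA = list(A = de_one(bundle_dir, "cohortA", "lncRNA", params),
                    B = de_one(bundle_dir, "cohortB", "lncRNA", params)),
      miRNA = list(A = de_one(bundle_dir, "cohortA", "miRNA", params)),
      mRNA = list(A = de_one(bundle_dir, "cohortA", "mRNA", params),
                  B = de_one(bundle_dir, "cohortB", "mRNA", params)))
    combined <- list()
    for (cl in names(de_sets)) {
      for (ds in names(de_sets[[cl]]))
        write_tsv(de_sets[[cl]][[ds]], p(sprintf("de_%s_%s.tsv", ds, cl)))
      if (length(de_sets[[cl]]) > 1L) {
        comb <- combine_de(de_sets[[cl]])
        write_tsv(comb$combined, p(sprintf("de_combined_%s.tsv", cl)))
        write_tsv(comb$conflicts, p(sprintf("de_conflicts_%s.tsv", cl)))
        common <- intersect_de(de_sets[[cl]]$A, de_sets[[cl]]$B)
        write_tsv(common, p(sprintf("de_common_%s.tsv", cl)))
        combined[[cl]] <- comb$combined
      } else {
        combined[[cl]] <- de_sets[[cl]]$A
        write_tsv(combined[[cl]], p(sprintf("de_combined_%s.tsv", cl)))
      }
      for (ds in names(de_sets[[cl]]))
        for (dr in c("up", "down"))
          note("de", sprintf("%s_%s_%s", cl, ds, dr),
               sum(de_sets[[cl]][[ds]]$direction == dr))
      note("de", sprintf("%s_combined_total", cl), nrow(combined[[cl]]))
    }
    list(per_dataset = de_sets, combined = combined)
  })

  ## -- ceRNA network ----------------------------------------------------
  stage_log("cerna", "evidence filter >= %d databases", params$min_db)
  cerna <- run_stage("cerna", {
    mm <- normalize_ids(read_tsv(file.path(bundle_dir,
                                           "interactions_mir_mrna.tsv")))
    ml <- normalize_ids(read_tsv(file.path(bundle_dir,
                                           "interactions_lnc_mir.tsv")))
    mm_pairs <- filter_by_evidence(mm, min_db = params$min_db)
    lm_pairs <- unique(ml[, c("miRNA", "target")])
    de_norm <- lapply(de$combined, function(d) {
      d$feature <- normalize_ids(d$feature); d
    })
    triples <- assemble_triples(de_norm$lncRNA, de_norm$miRNA, de_norm$mRNA,
                                lm_pairs, mm_pairs)
    network <- build_cerna_network(triples)
    hubs <- rank_hubs(network, k = params$hub_k)
    write_tsv(mm_pairs, p("pairs_mir_mrna_filtered.tsv"))
    write_tsv(triples, p("triples.tsv"))
    write_sif(network, p("cerna_network.sif"))
    write_graphml(network, p("cerna_network.graphml"))
    write_tsv(hubs, p("cerna_hubs.tsv"))
    note("cerna", "pairs_retained", nrow(mm_pairs))
    for (pol in c("miRNA-up", "miRNA-down"))
      note("cerna", paste0("triples_", pol), sum(triples$polarity == pol))
    note("cerna", "nodes", igraph::vcount(network))
    note("cerna", "edges", igraph::ecount(network))
    list(triples = triples, network = network, hubs = hubs)
  })
  cerna_genes <- unique(cerna$triples$mRNA)

  ## -- PPI --------------------------------------------------------------
  stage_log("ppi", "thresholding combined score >= %g", params$min_score)
  ppi <- run_stage("ppi", {
    edges <- read_tsv(file.path(bundle_dir, "ppi_edges.tsv"))
    edges$protein1 <- normalize_ids(edges$protein1)
    edges$protein2 <- normalize_ids(edges$protein2)
    edges <- edges[edges$protein1 %in% cerna_genes &
                     edges$protein2 %in% cerna_genes, , drop = FALSE]
    network <- threshold_ppi(edges, min_score = params$min_score)
    hubs <- degree_hubs(network, k = params$hub_k)
    smry <- network_summary(network)
    write_sif(network, p("ppi_network.sif"))
    write_graphml(network, p("ppi_network.graphml"))
    write_tsv(hubs, p("ppi_hubs.tsv"))
    note("ppi", "nodes", smry$nodes)
    note("ppi", "edges", smry$edges)
    list(network = network, hubs = hubs, summary = smry)
  })

  ## -- enrichment -------------------------------------------------------
  stage_log("enrich", "Fisher ORA of %d ceRNA mRNAs", length(cerna_genes))
  enrich <- run_stage("enrich", {
    sets <- lapply(read_gmt(file.path(bundle_dir, "genesets.gmt")),
                   normalize_ids)
    universe <- normalize_ids(
      readLines(file.path(bundle_dir, "geneset_universe.txt")))
    if (length(cerna_genes) == 0L ||
        !any(cerna_genes %in% universe)) {
      res <- data.frame(set = character(), k = integer(), K = integer(),
                        n = integer(), N = integer(), p = numeric(),
                        q = numeric(), score = numeric(),
                        stringsAsFactors = FALSE)
    } else {
      res <- fisher_enrich(cerna_genes, sets, universe)
    }
    write_tsv(res, p("enrichment.tsv"))
    note("enrich", "sets_tested", nrow(res))
    note("enrich", "sets_q_below_0.05", sum(res$q < 0.05))
    res
  })

  ## -- time course ------------------------------------------------------
  stage_log("timecourse", "fuzzy c-means, c = %d, m = %s",
            params$centers, format(params$m))
  tc <- run_stage("timecourse", {
    mat <- ensure_log2(read_expression_tsv(
      file.path(bundle_dir, "timecourse_expr.tsv")))
    meta <- read_tsv(file.path(bundle_dir, "timecourse_metadata.tsv"))
    profiles <- profile_means(mat, meta)
    kept <- sd_filter(profiles, min_sd = params$min_sd)
    std <- standardize_profiles(kept)
    cl <- fuzzy_cmeans(std, centers = params$centers, m = params$m,
                       seed = params$seed)
    trends <- classify_trends(cl)
    gs <- cluster_gene_sets(cl, params$membership_threshold)
    write_tsv(data.frame(gene = rownames(cl$membership),
                         round(cl$membership, 6), check.names = FALSE,
                         stringsAsFactors = FALSE),
              p("timecourse_membership.tsv"))
    write_tsv(data.frame(cluster = rownames(cl$centroids),
                         round(cl$centroids, 6), trend = unname(trends),
                         check.names = FALSE, stringsAsFactors = FALSE),
              p("timecourse_centroids.tsv"))
    write_tsv(gs$assignments, p("timecourse_assignments.tsv"))
    inter <- do.call(rbind, lapply(names(gs$by_trend), function(tr) {
      genes <- gs$by_trend[[tr]]
      ov <- intersect(genes, cerna_genes)
      data.frame(trend = tr, n_genes = length(genes),
                 n_cerna_overlap = length(ov),
                 cerna_genes = paste(ov, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(inter))
      inter <- data.frame(trend = character(), n_genes = integer(),
                          n_cerna_overlap = integer(),
                          cerna_genes = character(), stringsAsFactors = FALSE)
    write_tsv(inter, p("timecourse_cerna_intersection.tsv"))
    note("timecourse", "genes_clustered", nrow(cl$membership))
    note("timecourse", "genes_removed_by_sd_filter",
         nrow(profiles) - nrow(kept))
    for (tr in names(gs$by_trend))
      note("timecourse", paste0("genes_", tr), length(gs$by_trend[[tr]]))
    list(clustering = cl, trends = trends, gene_sets = gs,
         intersection = inter)
  })

  smry <- do.call(rbind, summary_rows)
  write_tsv(smry, p("summary.tsv"))
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "cernet",
    version = as.character(utils::packageVersion("cernet")),
    params = params,
    inputs = manifest_entry(bundle_dir, sort(list.files(bundle_dir))),
    outputs = manifest_entry(out_dir, sort(outputs)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_log("done", "outputs in %s", out_dir)
  invisible(list(de = de, cerna = cerna, ppi = ppi, enrichment = enrich,
                 timecourse = tc, summary = smry))
}
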