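#' Simulation configuration for planted-truth synthetic data
#'
#' Bundles every knob of the synthetic-data generators: cohort design,
#' feature counts per RNA class, planted differential expression, interaction
#' database behaviour, time-course design, PPI density and gene-set planting.
#' The defaults describe a desk-scale case/control microarray study on the
#' log2 scale: two groups of 10 circulating-monocyte samples, a 30% DE rate
#' with a mean shift of 2 log2 units against within-group noise of 0.5, five
#' miRNA-target databases each covering 80% of true pairs, and a
#' three-timepoint (0 h / 3 h / 20 h) monocyte-to-macrophage series with
#' 31/31/34 samples per timepoint.
#'
#' @param n_case,n_control samples per group in a cohort.
#' @param n_lnc,n_mir,n_mrna feature counts per RNA class.
#' @param frac_de fraction of features per class planted as differentially
#'   expressed.
#' @param effect_size mean |log2 fold change| of planted DE features.
#' @param noise_sd within-group standard deviation on the log2 scale.
#' @param n_triples number of planted sign-consistent ceRNA triples
#'   (lncRNA, miRNA, mRNA); members are disjoint across triples and must fit
#'   inside the planted DE features of each class.
#' @param n_databases number of simulated miRNA-mRNA target databases.
#' @param db_coverage probability that a true miRNA-mRNA pair is listed in
#'   any one database.
#' @param db_noise expected number of decoy pairs added per database
#'   (Poisson mean).
#' @param n_timepoints number of timepoints (the time-course generator
#'   supports exactly 3).
#' @param samples_per_timepoint integer vector of per-timepoint sample
#'   counts.
#' @param n_timecourse number of genes in the simulated time course.
#' @param trend_amplitude peak-to-trough amplitude (log2 units) of planted
#'   trends.
#' @param ppi_density probability that any gene pair carries a scored
#'   protein-protein edge.
#' @param n_genesets,geneset_size number and size of generated gene sets.
#' @param query_size size of the designated query gene list used when
#'   planting enriched sets.
#' @param enrichment_factor multiplier on the hypergeometric expectation of
#'   the planted sets' overlap with the query list.
#' @param n_enriched_sets number of planted (enriched) sets.
#' @param seed integer master seed; each generator draws from an independent
#'   substream derived from it, so adding one generator never perturbs
#'   another's output.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [generate_interaction_dbs()],
#'   [generate_timecourse()], [generate_ppi()], [generate_genesets()]
#' @export
#' @examples
#' cfg <- sim_config(n_case = 3, n_control = 3, seed = 42)
#' cfg$samples_per_timepoint
sim_config <- function(n_case = 10L, n_control = 10L,
                       n_lnc = 200L, n_mir = 80L, n_mrna = 400L,
                       frac_de = 0.3, effect_size = 2, noise_sd = 0.5,
                       n_triples = 15L, n_databases = 5L,
                       db_coverage = 0.8, db_noise = 20,
                       n_timepoints = 3L,
                       samples_per_timepoint = c(31L, 31L, 34L),
                       n_timecourse = 500L, trend_amplitude = 1,
                       ppi_density = 0.05,
                       n_genesets = 25L, geneset_size = 40L,
                       query_size = 80L, enrichment_factor = 3,
                       n_enriched_sets = 2L,
                       seed = 1L) {
  cfg <- list(
    n_case = assert_count(n_case, "n_case"),
    n_control = assert_count(n_control, "n_control"),
    n_lnc = assert_count(n_lnc, "n_lnc"),
    n_mir = assert_count(n_mir, "n_mir"),
    n_mrna = assert_count(n_mrna, "n_mrna"),
    frac_de = assert_fraction(frac_de, "frac_de"),
    effect_size = assert_positive(effect_size, "effect_size"),
    noise_sd = assert_positive(noise_sd, "noise_sd"),
    n_triples = assert_count(n_triples, "n_triples", min = 0L),
    n_databases = assert_count(n_databases, "n_databases"),
    db_coverage = assert_fraction(db_coverage, "db_coverage"),
    db_noise = {
      if (!is.numeric(db_noise) || db_noise < 0)
        stop("'db_noise' must be a nonnegative number", call. = FALSE)
      as.numeric(db_noise)
    },
    n_timepoints = assert_count(n_timepoints, "n_timepoints", min = 2L),
    samples_per_timepoint = vapply(
      seq_along(samples_per_timepoint),
      function(i) assert_count(samples_per_timepoint[i], "samples_per_timepoint"),
      integer(1)),
    n_timecourse = assert_count(n_timecourse, "n_timecourse"),
    trend_amplitude = assert_positive(trend_amplitude, "trend_amplitude"),
    ppi_density = assert_fraction(ppi_density, "ppi_density"),
    n_genesets = assert_count(n_genesets, "n_genesets"),
    geneset_size = assert_count(geneset_size, "geneset_size"),
    query_size = assert_count(query_size, "query_size"),
    enrichment_factor = assert_positive(enrichment_factor, "enrichment_factor"),
    n_enriched_sets = assert_count(n_enriched_sets, "n_enriched_sets", min = 0L),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$seed > 2^31 - 1e6)
    stop("'seed' too large; must be below 2^31 - 10^6", call. = FALSE)
  if (length(cfg$samples_per_timepoint) != cfg$n_timepoints)
    stop("length(samples_per_timepoint) must equal n_timepoints", call. = FALSE)
  if (cfg$n_triples > min(cfg$n_lnc, cfg$n_mir, cfg$n_mrna))
    stop("n_triples cannot exceed min(n_lnc, n_mir, n_mrna)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Per-generator seed substreams derived from the master seed. Offsets are
# fixed so that adding a generator never shifts another generator's draws.
sub_seed <- function(config, stream) {
  offsets <- c(cohort = 101L, dbs = 202L, timecourse = 303L,
               ppi = 404L, genesets = 505L)
  config$seed + offsets[[stream]]
}

feature_ids <- function(config) {
  list(
    lncRNA = sprintf("LNC%04d", seq_len(config$n_lnc)),
    miRNA  = sprintf("MIR%04d", seq_len(config$n_mir)),
    mRNA   = sprintf("MRNA%04d", seq_len(config$n_mrna))
  )
}

# Plant the ground truth: which features are DE, in which direction, and
# which (lncRNA, miRNA, mRNA) triples are wired together. Triples are chosen
# first and get sign-consistent directions (lncRNA and mRNA share the
# direction opposite to the miRNA's); remaining DE features get random
# directions. Triple members are disjoint across triples.
plant_truth <- function(config) {
  ids <- feature_ids(config)
  n_feat <- c(lncRNA = config$n_lnc, miRNA = config$n_mir, mRNA = config$n_mrna)
  n_de <- round(config$frac_de * n_feat)
  if (config$n_triples > 0 && any(n_de < config$n_triples))
    stop(sprintf(
      "n_triples (%d) exceeds available planted DE features per class (%s)",
      config$n_triples, paste(n_de, collapse = "/")), call. = FALSE)

  de_feat <- lapply(names(ids), function(cl) sort(sample(ids[[cl]], n_de[[cl]])))
  names(de_feat) <- names(ids)

  triples <- NULL
  dir_map <- lapply(de_feat, function(f)
    stats::setNames(sample(c("up", "down"), length(f), replace = TRUE), f))
  if (config$n_triples > 0) {
    t_lnc <- sample(de_feat$lncRNA, config$n_triples)
    t_mir <- sample(de_feat$miRNA, config$n_triples)
    t_mrna <- sample(de_feat$mRNA, config$n_triples)
    mir_dir <- sample(c("up", "down"), config$n_triples, replace = TRUE)
    other <- ifelse(mir_dir == "up", "down", "up")
    dir_map$lncRNA[t_lnc] <- other
    dir_map$miRNA[t_mir] <- mir_dir
    dir_map$mRNA[t_mrna] <- other
    triples <- data.frame(lncRNA = t_lnc, miRNA = t_mir, mRNA = t_mrna,
                          mir_direction = mir_dir, stringsAsFactors = FALSE)
    triples <- triples[order(triples$lncRNA, triples$miRNA, triples$mRNA), ,
                       drop = FALSE]
    rownames(triples) <- NULL
  } else {
    triples <- data.frame(lncRNA = character(), miRNA = character(),
                          mRNA = character(), mir_direction = character(),
                          stringsAsFactors = FALSE)
  }

  de <- do.call(rbind, lapply(names(de_feat), function(cl) {
    f <- de_feat[[cl]]
    if (length(f) == 0L)
      return(data.frame(feature = character(), class = character(),
                        direction = character(), true_lfc = numeric(),
                        stringsAsFactors = FALSE))
    d <- dir_map[[cl]][f]
    data.frame(feature = f, class = cl, direction = unname(d),
               true_lfc = ifelse(d == "up", 1, -1) * config$effect_size,
               stringsAsFactors = FALSE)
  }))
  rownames(de) <- NULL

  structure(list(features = ids, de = de, triples = triples,
                 trends = NULL, enriched_sets = NULL),
            class = "cerna_truth")
}

#' Simulate a case/control expression cohort with planted DE features
#'
#' Draws one log2-scale expression matrix per RNA class (lncRNA, miRNA,
#' mRNA) over a shared set of case and control samples. Each planted DE
#' feature's case-group mean is shifted from its control-group mean by its
#' true log2 fold change; all other features share a common mean between
#' groups. Values are Gaussian around the group mean with standard deviation
#' `noise_sd`. Per-feature baselines are drawn fresh on every call (they play
#' the role of platform-specific probe intensities), so re-planting the same
#' `truth` in a second cohort emulates an independent study of the same
#' biology.
#'
#' @param config a [sim_config()].
#' @param truth optional `cerna_truth` from a previous call; when supplied,
#'   the same DE features, directions, effect sizes and triples are
#'   re-planted (feature counts must match `config`).
#' @return a list with elements
#'   \describe{
#'     \item{matrices}{named list of feature x sample matrices, one per RNA
#'       class, log2 scale;}
#'     \item{metadata}{data frame with columns `sample` and `group`
#'       (`"CAD"` / `"control"`);}
#'     \item{truth}{the `cerna_truth` object (planted DE table and triples).}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_case = 3, n_control = 3, seed = 7))
#' dim(cohort$matrices$mRNA)
#' head(cohort$truth$de)
generate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config, "cohort"), {
    if (is.null(truth)) {
      truth <- plant_truth(config)
    } else {
      stopifnot(inherits(truth, "cerna_truth"))
      n_feat <- vapply(truth$features, length, integer(1))
      if (!identical(unname(n_feat),
                     c(config$n_lnc, config$n_mir, config$n_mrna)))
        stop("feature counts in 'truth' do not match 'config'", call. = FALSE)
    }
    samples <- c(sprintf("CAD_%02d", seq_len(config$n_case)),
                 sprintf("ctrl_%02d", seq_len(config$n_control)))
    group <- rep(c("CAD", "control"), c(config$n_case, config$n_control))
    mats <- lapply(names(truth$features), function(cl) {
      feats <- truth$features[[cl]]
      n <- length(feats)
      baseline <- stats::rnorm(n, mean = 7, sd = 1)
      lfc <- stats::setNames(numeric(n), feats)
      de_cl <- truth$de[truth$de$class == cl, , drop = FALSE]
      lfc[de_cl$feature] <- de_cl$true_lfc
      mu <- outer(baseline, rep(0, length(samples))) +
        outer(unname(lfc), as.numeric(group == "CAD"))
      x <- mu + matrix(stats::rnorm(n * length(samples), sd = config$noise_sd),
                       nrow = n)
      dimnames(x) <- list(feats, samples)
      x
    })
    names(mats) <- names(truth$features)
    list(matrices = mats,
         metadata = data.frame(sample = samples, group = group,
                               stringsAsFactors = FALSE),
         truth = truth)
  })
}

# Sample `n` decoy (miRNA, target) pairs uniformly without replacement from
# the full cross product, excluding `exclude` (a character vector of
# "mir\ttarget" keys).
sample_decoys <- function(mirs, targets, n, exclude) {
  if (n == 0L) return(data.frame(miRNA = character(), target = character(),
                                 stringsAsFactors = FALSE))
  total <- length(mirs) * length(targets)
  picked <- character(0)
  while (length(picked) < n) {
    idx <- sample.int(total, min(total, 2L * (n - length(picked)) + 10L))
    mi <- mirs[(idx - 1L) %% length(mirs) + 1L]
    tg <- targets[(idx - 1L) %/% length(mirs) + 1L]
    key <- paste(mi, tg, sep = "\t")
    key <- setdiff(unique(key), c(exclude, picked))
    picked <- c(picked, key)
  }
  picked <- picked[seq_len(n)]
  parts <- strsplit(picked, "\t", fixed = TRUE)
  data.frame(miRNA = vapply(parts, `[`, "", 1L),
             target = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Simulate miRNA-target interaction databases around planted triples
#'
#' Emulates the evidence base used for target filtering: each true
#' miRNA-mRNA pair (from the planted triples) is listed in each of
#' `n_databases` tables independently with probability `db_coverage`, and
#' each table additionally receives a Poisson(`db_noise`) number of decoy
#' pairs drawn uniformly from non-true pairs. A single separate
#' miRNA-lncRNA table contains every true lncRNA-miRNA pair plus decoys.
#'
#' @param truth a `cerna_truth` with planted triples.
#' @param config the [sim_config()] that produced `truth`.
#' @return list with `mir_mrna` (data frame: miRNA, target, database over all
#'   databases), `lnc_mir` (same columns, single source), and `provenance`
#'   (every emitted pair with an `is_true` flag).
#' @export
generate_interaction_dbs <- function(truth, config) {
  stopifnot(inherits(truth, "cerna_truth"), inherits(config, "sim_config"))
  with_seed(sub_seed(config, "dbs"), {
    mirs <- truth$features$miRNA
    mrnas <- truth$features$mRNA
    lncs <- truth$features$lncRNA
    true_mm <- unique(truth$triples[, c("miRNA", "mRNA")])
    true_ml <- unique(truth$triples[, c("miRNA", "lncRNA")])
    key_mm <- paste(true_mm$miRNA, true_mm$mRNA, sep = "\t")
    key_ml <- paste(true_ml$miRNA, true_ml$lncRNA, sep = "\t")

    db_names <- sprintf("DB%d", seq_len(config$n_databases))
    mm <- do.call(rbind, lapply(db_names, function(db) {
      keep <- stats::runif(nrow(true_mm)) < config$db_coverage
      true_part <- data.frame(miRNA = true_mm$miRNA[keep],
                              target = true_mm$mRNA[keep],
                              stringsAsFactors = FALSE)
      n_decoy <- stats::rpois(1L, config$db_noise)
      decoy <- sample_decoys(mirs, mrnas, n_decoy, key_mm)
      out <- rbind(true_part, decoy)
      if (nrow(out)) out$database <- db
      else out$database <- character(0)
      out
    }))
    rownames(mm) <- NULL

    n_decoy_l <- stats::rpois(1L, config$db_noise)
    decoy_l <- sample_decoys(mirs, lncs, n_decoy_l, key_ml)
    ml <- rbind(
      data.frame(miRNA = true_ml$miRNA, target = true_ml$lncRNA,
                 stringsAsFactors = FALSE),
      decoy_l)
    if (nrow(ml)) ml$database <- "LNCDB" else ml$database <- character(0)
    rownames(ml) <- NULL

    prov_mm <- unique(mm[, c("miRNA", "target")])
    prov_ml <- unique(ml[, c("miRNA", "target")])
    provenance <- rbind(
      if (nrow(prov_mm)) cbind(prov_mm, type = "mir_mrna",
        is_true = paste(prov_mm$miRNA, prov_mm$target, sep = "\t") %in% key_mm),
      if (nrow(prov_ml)) cbind(prov_ml, type = "lnc_mir",
        is_true = paste(prov_ml$miRNA, prov_ml$target, sep = "\t") %in% key_ml))
    rownames(provenance) <- NULL
    list(mir_mrna = mm, lnc_mir = ml, provenance = provenance)
  })
}

timecourse_shapes <- function(amplitude) {
  list(
    "rise-fall" = amplitude * c(0, 1, 0),
    "fall-rise" = amplitude * c(1, 0, 1),
    "up"        = amplitude * c(0, 0.5, 1),
    "down"      = amplitude * c(1, 0.5, 0),
    "flat"      = amplitude * c(0.5, 0.5, 0.5)
  )
}

#' Simulate a three-timepoint time course with planted trend classes
#'
#' Genes are split evenly over five trend classes (`rise-fall`, `fall-rise`,
#' `up`, `down`, `flat`); each gene's per-timepoint mean follows its class
#' shape at `trend_amplitude` on top of a gene-specific baseline, with
#' Gaussian per-sample noise. Flat genes have identical means at every
#' timepoint, so after averaging over the (many) samples per timepoint their
#' profile SD falls below the usual 0.05 filter and the SD filter removes
#' them.
#'
#' @param config a [sim_config()]; `samples_per_timepoint` must have length 3.
#' @return list with `matrix` (genes x samples, log2 scale), `metadata`
#'   (sample, timepoint in `"0h"`, `"3h"`, `"20h"`), and `truth` (a
#'   `cerna_truth` whose `trends` field maps gene to trend class).
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_timepoints != 3L)
    stop("the time-course generator supports exactly 3 timepoints", call. = FALSE)
  with_seed(sub_seed(config, "timecourse"), {
    labels <- c("0h", "3h", "20h")
    n_per <- config$samples_per_timepoint
    # mRNA-style ids so time-course gene lists can be intersected with the
    # ceRNA mRNAs of a cohort simulated under the same id scheme
    genes <- sprintf("MRNA%04d", seq_len(config$n_timecourse))
    classes <- sample(rep_len(names(timecourse_shapes(1)), config$n_timecourse))
    shapes <- timecourse_shapes(config$trend_amplitude)
    baseline <- stats::rnorm(config$n_timecourse, mean = 7, sd = 1)
    centers <- t(vapply(classes, function(cl) shapes[[cl]], numeric(3)))
    cols <- lapply(seq_along(labels), function(j) {
      mu <- baseline + centers[, j]
      m <- mu + matrix(stats::rnorm(config$n_timecourse * n_per[j],
                                    sd = config$noise_sd),
                       nrow = config$n_timecourse)
      colnames(m) <- sprintf("tp%s_s%02d", labels[j], seq_len(n_per[j]))
      m
    })
    x <- do.call(cbind, cols)
    rownames(x) <- genes
    metadata <- data.frame(
      sample = colnames(x),
      timepoint = rep(labels, n_per),
      stringsAsFactors = FALSE)
    truth <- structure(list(
      features = list(timecourse = genes),
      de = NULL, triples = NULL,
      trends = data.frame(gene = genes, trend_class = classes,
                          stringsAsFactors = FALSE),
      enriched_sets = NULL), class = "cerna_truth")
    list(matrix = x, metadata = metadata, truth = truth)
  })
}

#' Simulate a scored protein-protein interaction table
#'
#' Draws an Erdos-Renyi graph over the supplied genes with edge probability
#' `config$ppi_density`; every retained unordered pair carries a combined
#' score drawn uniformly on \[0, 1\]. No self-edges, each pair at most once.
#'
#' @param genes character vector of gene ids.
#' @param config a [sim_config()].
#' @return data frame with columns `protein1`, `protein2`, `combined_score`.
#' @export
generate_ppi <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- unique(as.character(genes))
  n <- length(genes)
  if (n < 2L)
    return(data.frame(protein1 = character(), protein2 = character(),
                      combined_score = numeric(), stringsAsFactors = FALSE))
  with_seed(sub_seed(config, "ppi"), {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < config$ppi_density
    idx <- idx[keep, , drop = FALSE]
    data.frame(protein1 = genes[idx[, 1L]],
               protein2 = genes[idx[, 2L]],
               combined_score = stats::runif(nrow(idx)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate GMT-style gene sets with planted enrichment
#'
#' Generates `n_genesets` sets of size `geneset_size` over the supplied gene
#' universe. A designated query list of `query_size` genes is drawn first;
#' the first `n_enriched_sets` sets are planted so that their expected
#' overlap with the query equals `enrichment_factor` times the hypergeometric
#' expectation `K * q / N` (the number of query members in a planted set is
#' Binomial(K, factor * q / N)); background sets are uniform draws.
#'
#' @param genes character vector: the gene universe.
#' @param config a [sim_config()].
#' @return list with `sets` (named list of member vectors), `universe`, and
#'   `truth` (query list, planted set ids, enrichment factor).
#' @export
generate_genesets <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- unique(as.character(genes))
  N <- length(genes)
  K <- config$geneset_size
  q <- config$query_size
  if (q > N || K > N)
    stop("query_size and geneset_size must not exceed the universe size",
         call. = FALSE)
  with_seed(sub_seed(config, "genesets"), {
    query <- sort(sample(genes, q))
    other <- setdiff(genes, query)
    p_hit <- min(1, config$enrichment_factor * q / N)
    ids <- sprintf("SET%02d", seq_len(config$n_genesets))
    sets <- lapply(seq_len(config$n_genesets), function(i) {
      if (i <= config$n_enriched_sets) {
        k_q <- stats::rbinom(1L, K, p_hit)
        k_q <- min(k_q, q)
        k_q <- max(k_q, K - length(other))
        sort(c(sample(query, k_q), sample(other, K - k_q)))
      } else {
        sort(sample(genes, K))
      }
    })
    names(sets) <- ids
    list(sets = sets, universe = genes,
         truth = list(query = query,
                      enriched_sets = ids[seq_len(config$n_enriched_sets)],
                      enrichment_factor = config$enrichment_factor))
  })
}
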