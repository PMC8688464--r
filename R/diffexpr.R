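#' Collapse probe-level rows to gene-level rows by averaging
#'
#' Maps array probes to genes through an annotation table and replaces the
#' probes of each gene by their per-sample arithmetic mean. Probes without an
#' annotation entry are dropped; output genes are sorted lexicographically.
#'
#' @param matrix numeric probe x sample matrix with probe ids as rownames.
#' @param annotation data frame with columns `probe` and `gene`; the mapping
#'   must be a function on probe ids (one gene per probe).
#' @return gene x sample numeric matrix.
#' @export
#' @examples
#' m <- rbind(p1 = c(2, 4), p2 = c(4, 6), p3 = c(1, 1))
#' colnames(m) <- c("s1", "s2")
#' ann <- data.frame(probe = c("p1", "p2"), gene = c("g", "g"))
#' collapse_probes(m, ann)  # g = (3, 5); p3 dropped
collapse_probes <- function(matrix, annotation) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            all(c("probe", "gene") %in% names(annotation)))
  ann <- annotation[!is.na(annotation$gene) & annotation$gene != "", , drop = FALSE]
  if (anyDuplicated(ann$probe))
    stop("annotation maps some probe to more than one gene", call. = FALSE)
  keep <- intersect(rownames(matrix), ann$probe)
  if (length(keep) == 0L)
    stop("no probe in the matrix has an annotation entry", call. = FALSE)
  gene <- ann$gene[match(keep, ann$probe)]
  sums <- rowsum(matrix[keep, , drop = FALSE], group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Ensure a matrix is on the log2 scale
#'
#' Microarray series matrices arrive either already log2-transformed or on
#' the linear intensity scale. A matrix whose maximum exceeds 50 is judged
#' linear-scale and replaced by `log2(x + 1)`; otherwise it is returned
#' unchanged. The decision is reported via `message()` and recorded in the
#' `"log2_transformed"` attribute.
#'
#' @param matrix numeric matrix.
#' @return the matrix on the log2 scale.
#' @export
ensure_log2 <- function(matrix) {
  mx <- max(matrix)
  if (is.na(mx) || !all(is.finite(matrix)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  if (mx > 50) {
    if (any(matrix < 0))
      stop("matrix judged linear-scale (max > 50) but contains negative values",
           call. = FALSE)
    message(sprintf(
      "ensure_log2: max value %.3g > 50, applying log2(x + 1)", mx))
    matrix <- log2(matrix + 1)
    attr(matrix, "log2_transformed") <- TRUE
  } else {
    attr(matrix, "log2_transformed") <- FALSE
  }
  matrix
}

# Newton solve of trigamma(x) = y, vectorized, following the standard
# empirical-Bayes variance-moderation recipe.
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-8
  hi <- y > 1e7
  out[lo] <- 1 / y[lo]
  out[hi] <- 1 / sqrt(y[hi])
  mid <- !(lo | hi)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

# Moment-matching fit of the scaled-F model for residual variances:
# s2 ~ s0^2 * F(df, d0). Works on log(s2) via digamma/trigamma moments.
# Returns d0 (possibly Inf) and s02.
fit_f_dist <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s02 = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Two-group moderated t-test with empirical-Bayes variance shrinkage
#'
#' For every feature computes the log2 fold change (case mean minus control
#' mean), the pooled within-group variance `s_g^2` with
#' `d_g = n_case + n_control - 2` residual degrees of freedom, and a
#' moderated t-statistic in which `s_g^2` is replaced by the posterior
#' variance
#' `s~_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`. The prior degrees of
#' freedom `d0` and prior variance `s0^2` are estimated by method-of-moments
#' on `log s_g^2` against a scaled-F model (digamma/trigamma matching); when
#' the trigamma equation has no positive solution `d0 = Inf` and the
#' reference distribution is normal. Two-sided p-values use `d0 + d_g`
#' degrees of freedom.
#'
#' @param matrix feature x sample log2 expression matrix.
#' @param groups character/factor vector over columns with the group of each
#'   sample.
#' @param case,control the labels in `groups` denoting case and control
#'   samples (defaults `"CAD"` / `"control"`).
#' @param d0 optional override of the prior degrees of freedom: `0` gives
#'   the classical pooled-variance t-test, `Inf` a z-test against `s0^2`,
#'   `NULL` (default) estimates `d0` from the data.
#' @return an object of class `moderated_fit`: list with `table` (data frame
#'   `feature`, `logFC`, `t`, `p`), `d0`, `s02`, `df_residual`, `df_total`,
#'   `n_case`, `n_control`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 1))
#' fit <- moderated_t_test(cohort$matrices$mRNA, cohort$metadata$group)
#' head(fit$table)
moderated_t_test <- function(matrix, groups, case = "CAD",
                             control = "control", d0 = NULL) {
  stopifnot(is.matrix(matrix), length(groups) == ncol(matrix))
  groups <- as.character(groups)
  i_case <- which(groups == case)
  i_ctrl <- which(groups == control)
  n1 <- length(i_case); n2 <- length(i_ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 samples per group", call. = FALSE)

  m_case <- rowMeans(matrix[, i_case, drop = FALSE])
  m_ctrl <- rowMeans(matrix[, i_ctrl, drop = FALSE])
  lfc <- m_case - m_ctrl
  ss1 <- rowSums((matrix[, i_case, drop = FALSE] - m_case)^2)
  ss2 <- rowSums((matrix[, i_ctrl, drop = FALSE] - m_ctrl)^2)
  df_res <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df_res

  if (is.null(d0)) {
    if (all(s2 == 0)) {
      warning("zero residual variance for every feature; ",
              "falling back to the unmoderated t-test")
      fit <- list(d0 = 0, s02 = NA_real_)
    } else {
      fit <- fit_f_dist(s2, df_res)
    }
  } else {
    fit <- list(d0 = d0,
                s02 = if (is.finite(d0) && d0 == 0) NA_real_
                      else fit_f_dist(s2, df_res)$s02)
  }

  if (fit$d0 == 0) {
    s2_post <- s2
  } else if (is.infinite(fit$d0)) {
    s2_post <- rep(fit$s02, length(s2))
  } else {
    s2_post <- (fit$d0 * fit$s02 + df_res * s2) / (fit$d0 + df_res)
  }
  df_total <- fit$d0 + df_res
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  structure(list(
    table = data.frame(feature = rownames(matrix), logFC = unname(lfc),
                       t = unname(tstat), p = unname(p),
                       stringsAsFactors = FALSE),
    d0 = fit$d0, s02 = fit$s02, df_residual = df_res, df_total = df_total,
    n_case = n1, n_control = n2), class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf(
    "Moderated two-group fit: %d features, %d vs %d samples\n",
    nrow(x$table), x$n_case, x$n_control))
  cat(sprintf("  prior df d0 = %s, prior variance s0^2 = %s\n",
              format(x$d0, digits = 4), format(x$s02, digits = 4)))
  invisible(x)
}

#' Screen a moderated fit into differential expression records
#'
#' Retains features with `p` strictly below `p_thresh` and `|log2FC|`
#' strictly above `lfc_thresh`. The default `lfc_thresh = 0.585` corresponds
#' to a fold change of 1.5 (`2^0.585` rounds to 1.5), so the screen keeps
#' features with FC > 1.5 or FC < 1/1.5 at p < 0.05.
#'
#' @param fit a `moderated_fit`.
#' @param class RNA class of the features: `"lncRNA"`, `"miRNA"` or
#'   `"mRNA"`.
#' @param p_thresh,lfc_thresh positive screening thresholds.
#' @return data frame of DE records: `feature`, `class`, `logFC`, `t`, `p`,
#'   `direction` (`"up"` iff `logFC > 0`).
#' @export
screen_de <- function(fit, class = c("mRNA", "lncRNA", "miRNA"),
                      p_thresh = 0.05, lfc_thresh = 0.585) {
  class <- match.arg(class)
  stopifnot(p_thresh > 0, lfc_thresh > 0)
  tab <- fit$table
  keep <- tab$p < p_thresh & abs(tab$logFC) > lfc_thresh
  out <- tab[keep, , drop = FALSE]
  data.frame(feature = out$feature, class = rep(class, nrow(out)),
             logFC = out$logFC,
             t = out$t, p = out$p,
             direction = ifelse(out$logFC > 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine DE lists from several datasets of the same RNA class
#'
#' Set union by feature id. A feature found in several lists with the same
#' direction is emitted once, carrying the record with the smallest p-value;
#' a feature with conflicting directions across lists is excluded from the
#' combined list and reported separately, since downstream sign-consistency
#' logic needs unambiguous directions.
#'
#' @param ... two or more DE data frames (as from [screen_de()]), or a
#'   single list of them. All must share one `class`.
#' @return list with `combined` (DE data frame sorted by feature) and
#'   `conflicts` (features excluded for direction conflicts, with the
#'   per-dataset directions collapsed into a string).
#' @export
combine_de <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !is.data.frame(sets[[1L]])) sets <- sets[[1L]]
  stopifnot(length(sets) >= 2L)
  all_rec <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (nrow(s)) s$.set <- i else s$.set <- integer(0)
    s
  }))
  if (length(unique(all_rec$class)) > 1L)
    stop("all DE lists must share one feature class", call. = FALSE)
  empty <- all_rec[0, setdiff(names(all_rec), ".set"), drop = FALSE]
  if (nrow(all_rec) == 0L)
    return(list(combined = empty, conflicts = empty))
  dirs <- tapply(all_rec$direction, all_rec$feature,
                 function(d) length(unique(d)))
  conflict_ids <- names(dirs)[dirs > 1L]
  ok <- all_rec[!(all_rec$feature %in% conflict_ids), , drop = FALSE]
  ok <- ok[order(ok$feature, ok$p, ok$.set), , drop = FALSE]
  combined <- ok[!duplicated(ok$feature), , drop = FALSE]
  combined$.set <- NULL
  rownames(combined) <- NULL
  confl <- all_rec[all_rec$feature %in% conflict_ids, , drop = FALSE]
  confl <- confl[order(confl$feature, confl$.set), , drop = FALSE]
  conflicts <- confl[!duplicated(confl$feature),
                     setdiff(names(confl), ".set"), drop = FALSE]
  if (nrow(conflicts)) {
    conflicts$direction <- vapply(conflicts$feature, function(f)
      paste(confl$direction[confl$feature == f], collapse = "/"), "")
  }
  rownames(conflicts) <- NULL
  list(combined = combined, conflicts = conflicts)
}

#' Intersect two DE lists on feature id and direction
#'
#' Reports the features differentially expressed in both datasets with
#' matching direction (the "common genes" of a two-dataset screen).
#'
#' @param a,b DE data frames (as from [screen_de()]).
#' @return data frame `feature`, `class`, `direction`, `logFC_a`, `p_a`,
#'   `logFC_b`, `p_b`, sorted by feature.
#' @export
intersect_de <- function(a, b) {
  m <- merge(a, b, by = c("feature", "class", "direction"),
             suffixes = c("_a", "_b"))
  out <- m[order(m$feature),
           c("feature", "class", "direction",
             "logFC_a", "p_a", "logFC_b", "p_b"), drop = FALSE]
  rownames(out) <- NULL
  out
}
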