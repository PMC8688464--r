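# Independent brute-force oracles. Each recomputes a quantity by the most
# literal route available (loops, enumeration, closed forms) and is kept
# deliberately separate from the package's vectorized implementations.

# group-by mean of probe rows per gene, gene-by-gene
oracle_collapse <- function(mat, ann) {
  genes <- sort(unique(ann$gene[ann$probe %in% rownames(mat)]))
  out <- t(vapply(genes, function(g) {
    pr <- intersect(ann$probe[ann$gene == g], rownames(mat))
    colMeans(mat[pr, , drop = FALSE])
  }, numeric(ncol(mat))))
  rownames(out) <- genes
  out
}

# textbook pooled-variance two-sample t-test, one feature at a time
oracle_pooled_t <- function(mat, case_idx, ctrl_idx) {
  t(vapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, case_idx]; y <- mat[i, ctrl_idx]
    ht <- t.test(x, y, var.equal = TRUE)
    c(t = unname(ht$statistic), p = ht$p.value,
      lfc = mean(x) - mean(y))
  }, numeric(3)))
}

# exact hypergeometric upper tail by binomial-coefficient summation
oracle_hyper_tail <- function(k, K, n, N) {
  if (k > min(n, K)) return(0)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# reference Benjamini-Hochberg step-up with explicit cummin
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

# per-pair distinct-database counting by explicit subset loops
oracle_evidence <- function(tab, min_db) {
  pairs <- unique(tab[, c("miRNA", "target")])
  keep <- list()
  for (i in seq_len(nrow(pairs))) {
    sub <- tab[tab$miRNA == pairs$miRNA[i] & tab$target == pairs$target[i], ]
    ev <- length(unique(sub$database))
    if (ev >= min_db)
      keep[[length(keep) + 1L]] <- data.frame(
        miRNA = pairs$miRNA[i], target = pairs$target[i], evidence = ev,
        stringsAsFactors = FALSE)
  }
  if (length(keep) == 0L)
    return(data.frame(miRNA = character(), target = character(),
                      evidence = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, keep)
  out <- out[order(out$miRNA, out$target), ]
  rownames(out) <- NULL
  out
}

# exhaustive enumeration over all lncRNA x miRNA x mRNA combinations
oracle_triples <- function(de_lnc, de_mir, de_mrna, lm, mm) {
  lm_key <- paste(lm$miRNA, lm$target)
  mm_key <- paste(mm$miRNA, mm$target)
  rows <- list()
  for (L in de_lnc$feature) for (M in de_mir$feature) for (G in de_mrna$feature) {
    if (!(paste(M, L) %in% lm_key)) next
    if (!(paste(M, G) %in% mm_key)) next
    dl <- de_lnc$direction[de_lnc$feature == L]
    dm <- de_mir$direction[de_mir$feature == M]
    dg <- de_mrna$direction[de_mrna$feature == G]
    if (dl == dg && dl != dm)
      rows[[length(rows) + 1L]] <- c(L, M, G)
  }
  if (length(rows) == 0L) return(character(0))
  sort(vapply(rows, paste, "", collapse = " "))
}

# node degrees by counting incidences in the raw edge list
oracle_degrees <- function(from, to) {
  inc <- c(from, to)
  tab <- table(inc)
  setNames(as.integer(tab), names(tab))
}

# small DE-record fixture
make_de <- function(features, class, directions, p = NULL, lfc = NULL) {
  n <- length(features)
  if (is.null(p)) p <- rep(0.01, n)
  if (is.null(lfc)) lfc <- ifelse(directions == "up", 1, -1)
  data.frame(feature = features, class = class, logFC = lfc,
             t = lfc * 5, p = p, direction = directions,
             stringsAsFactors = FALSE)
}

# moderated_fit shell around a bare table, for screening tests
make_fit <- function(logFC, p, feature = sprintf("g%04d", seq_along(logFC))) {
  structure(list(table = data.frame(feature = feature, logFC = logFC,
                                    t = logFC, p = p,
                                    stringsAsFactors = FALSE),
                 d0 = Inf, s02 = 1, df_residual = 4, df_total = Inf,
                 n_case = 3, n_control = 3),
            class = "moderated_fit")
}
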