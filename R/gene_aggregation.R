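#' Rank sgRNAs for gene aggregation
#'
#' Orders guides by a signed significance score
#' `r = sign(log2fc) * -log10(max(padj, 1e-300))`: strongly enriched guides
#' first, strongly depleted guides last. Ties are broken by guide id
#' (ascending); guides with `NA` adjusted p are dropped.
#'
#' @param stats an `sgrna_fit` or its per-guide table.
#' @return data.frame of class `ranked_guides` with columns `guide_id`,
#'   `gene`, `r`, sorted by `r` descending.
#' @export
rank_sgrnas <- function(stats) {
  tb <- if (inherits(stats, "sgrna_fit")) stats$table else as.data.frame(stats)
  tb <- tb[!is.na(tb$padj) & !is.na(tb$log2fc), , drop = FALSE]
  if (!nrow(tb)) stop("no guides with non-missing padj to rank")
  r <- sign(tb$log2fc) * -log10(pmax(tb$padj, 1e-300))
  ord <- order(-r, tb$guide_id)
  out <- data.frame(guide_id = tb$guide_id[ord], gene = tb$gene[ord],
                    r = r[ord], stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ranked_guides", "data.frame")
  out
}

#' Weighted KS enrichment score of a guide set in a ranked list
#'
#' Classic GSEA running-sum statistic: walking down the ranked list, member
#' guides ("hits") add `|r|^weight / sum(|r_member|^weight)` and non-members
#' subtract `1/(N - k)`; the enrichment score is the signed maximum deviation
#' of the walk from zero. With `weight = 0` (default), or when all member
#' `|r|` are zero, hits add the uniform `1/k`.
#'
#' The rank-only statistic (`weight = 0`) is the default because the ranking
#' score here is padj-derived and bounded: with `weight = 1` a random guide
#' set containing a single strongly changing guide puts almost all its weight
#' on that one guide and saturates near +-1, which destroys the contrast
#' between genuine multi-guide signals and singletons. The weighted statistic
#' remains available via `weight = 1`.
#'
#' @param ranked a `ranked_guides`.
#' @param members character vector of member guide ids (a gene's guides).
#' @param weight 0 (default, rank-only) or 1 (weighted statistic).
#' @return enrichment score in `[-1, 1]`.
#' @details The walk only changes slope at member positions, so the extrema
#'   are attained immediately after a hit (maximum candidates) or immediately
#'   before one (minimum candidates); the implementation evaluates just those
#'   `2k` points rather than the full `N`-step walk.
#' @export
enrichment_score <- function(ranked, members, weight = 0) {
  stopifnot(inherits(ranked, "ranked_guides"), weight %in% c(0, 1))
  N <- nrow(ranked)
  pos <- sort(match(members, ranked$guide_id))
  if (anyNA(pos)) stop("members not in ranked list: ",
                       paste(setdiff(members, ranked$guide_id), collapse = ", "))
  k <- length(pos)
  if (k == 0L) stop("empty member set")
  if (k >= N) stop("member set must be a strict subset of the ranked list")
  absr <- abs(ranked$r[pos])
  w <- if (weight == 0 || all(absr == 0)) rep(1 / k, k) else absr / sum(absr)
  cumw <- cumsum(w)
  miss <- (pos - seq_len(k)) / (N - k)   # miss decrement accrued before hit i
  after <- cumw - miss                   # walk value just after hit i
  before <- c(0, cumw[-k]) - miss        # walk value just before hit i
  hi <- max(after)
  lo <- min(0, before)
  if (hi >= -lo) hi else lo
}

#' Permutation p-values for one guide set
#'
#' Draws `n_perm` uniformly random guide sets of the same size from the
#' ranked list and compares their enrichment scores with the observed one,
#' with the add-one estimator: `p_enr = (1 + #[es* >= es]) / (n_perm + 1)`,
#' `p_dep = (1 + #[es* <= es]) / (n_perm + 1)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed (mandatory for reproducibility).
#' @return list with `es`, `p_dep`, `p_enr`.
#' @export
permutation_p <- function(ranked, members, n_perm = 1000L, seed, weight = 0) {
  stopifnot(n_perm >= 100L)
  if (missing(seed)) stop("seed is required")
  es_obs <- enrichment_score(ranked, members, weight)
  k <- length(members)
  null <- with_seed(seed, .null_es(ranked, k, n_perm, weight))
  list(es = es_obs,
       p_dep = (1 + sum(null <= es_obs)) / (n_perm + 1),
       p_enr = (1 + sum(null >= es_obs)) / (n_perm + 1))
}

# Null ES sample for uniformly drawn guide sets of size k. The null depends
# only on the ranked list and k, so aggregate_genes() computes it once per
# distinct set size and shares it across genes. Uses the caller's RNG state.
.null_es <- function(ranked, k, n_perm, weight) {
  N <- nrow(ranked)
  absr_all <- abs(ranked$r)
  vapply(seq_len(n_perm), function(i) {
    pos <- sort(sample.int(N, k))
    absr <- absr_all[pos]
    w <- if (weight == 0 || all(absr == 0)) rep(1 / k, k) else absr / sum(absr)
    cumw <- cumsum(w)
    miss <- (pos - seq_len(k)) / (N - k)
    hi <- max(cumw - miss)
    lo <- min(0, c(0, cumw[-k]) - miss)
    if (hi >= -lo) hi else lo
  }, numeric(1))
}

#' Aggregate ranked sgRNAs to gene-level scores
#'
#' One row per gene: the unweighted mean log2 fold change of its guides
#' (aLFC), the enrichment score of its guide set in the ranked list,
#' permutation p-values for depletion and enrichment (null shared across
#' genes with the same number of guides), BH-adjusted p within each
#' direction, and the count of guides individually significant at
#' `guide_alpha`. The control pseudo-gene is excluded.
#'
#' @param stats an `sgrna_fit` (or its table with `guide_id`, `gene`,
#'   `log2fc`, `padj`).
#' @param ranked optional pre-computed `ranked_guides`; derived from `stats`
#'   if `NULL`.
#' @param n_perm permutations per set size (default 1000).
#' @param seed integer seed (mandatory).
#' @param weight GSEA weight, 0 (default) or 1.
#' @param guide_alpha guide-level padj cutoff counted in `n_sig`.
#' @param control_label pseudo-gene label to exclude.
#' @return Object of class `gene_scores`: data.frame with `gene`,
#'   `n_guides`, `alfc`, `es`, `p_dep`, `p_enr`, `padj_dep`, `padj_enr`,
#'   `padj` (the adjusted p of the direction matching the sign of `es`) and
#'   `n_sig`.
#' @export
aggregate_genes <- function(stats, ranked = NULL, n_perm = 1000L, seed,
                            weight = 0, guide_alpha = 0.05,
                            control_label = "CTRL") {
  if (missing(seed)) stop("seed is required")
  tb <- if (inherits(stats, "sgrna_fit")) stats$table else as.data.frame(stats)
  if (is.null(ranked)) ranked <- rank_sgrnas(tb)
  tb <- tb[!is.na(tb$padj) & !is.na(tb$log2fc), , drop = FALSE]
  tb <- tb[tb$gene != control_label, , drop = FALSE]
  by_gene <- split(tb, tb$gene)
  dropped <- names(by_gene)[vapply(by_gene, nrow, 1L) == 0L]
  if (length(dropped))
    message("dropping ", length(dropped), " gene(s) with no surviving guides")
  by_gene <- by_gene[vapply(by_gene, nrow, 1L) > 0L]
  sizes <- vapply(by_gene, nrow, 1L)
  nulls <- with_seed(seed, {
    lapply(setNames(nm = sort(unique(sizes))), function(k)
      .null_es(ranked, k, n_perm, weight))
  })
  es <- vapply(by_gene, function(g)
    enrichment_score(ranked, g$guide_id, weight), numeric(1))
  p_dep <- p_enr <- numeric(length(es))
  for (i in seq_along(es)) {
    null <- nulls[[as.character(sizes[i])]]
    p_dep[i] <- (1 + sum(null <= es[i])) / (n_perm + 1)
    p_enr[i] <- (1 + sum(null >= es[i])) / (n_perm + 1)
  }
  out <- data.frame(
    gene = names(by_gene),
    n_guides = sizes,
    alfc = vapply(by_gene, function(g) mean(g$log2fc), numeric(1)),
    es = es, p_dep = p_dep, p_enr = p_enr,
    padj_dep = adjust_bh(p_dep), padj_enr = adjust_bh(p_enr),
    n_sig = vapply(by_gene, function(g)
      sum(g$padj < guide_alpha, na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$padj <- ifelse(out$es <= 0, out$padj_dep, out$padj_enr)
  out <- out[order(out$padj, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "weight") <- weight
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' @export
print.gene_scores <- function(x, ...) {
  cat("gene_scores: ", nrow(x), " genes (n_perm = ", attr(x, "n_perm"),
      ")\n", sep = "")
  cat("depleted at padj_dep <= 0.05: ",
      sum(x$padj_dep <= 0.05 & x$alfc < 0), "; enriched at padj_enr <= 0.05: ",
      sum(x$padj_enr <= 0.05 & x$alfc > 0), "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 6), digits = 3)
  invisible(x)
}

#' Call screen hits from gene-level scores
#'
#' Genes with direction-specific adjusted p at or below the cutoff and an
#' average log2 fold change whose sign matches the requested direction.
#'
#' @param genes a `gene_scores` table.
#' @param direction `"depleted"` (default) or `"enriched"`.
#' @param padj_cutoff adjusted-p threshold (default 0.05).
#' @param use_raw_p threshold the permutation p instead of the BH-adjusted p.
#' @return Object of class `hit_list`: character vector of gene symbols with
#'   attributes `direction`, `padj_cutoff`.
#' @export
call_hits <- function(genes, direction = c("depleted", "enriched"),
                      padj_cutoff = 0.05, use_raw_p = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(genes, "gene_scores") || is.data.frame(genes))
  pcol <- if (direction == "depleted") {
    if (use_raw_p) genes$p_dep else genes$padj_dep
  } else {
    if (use_raw_p) genes$p_enr else genes$padj_enr
  }
  keep <- pcol <= padj_cutoff &
    (if (direction == "depleted") genes$alfc < 0 else genes$alfc > 0)
  hits <- sort(genes$gene[keep])
  structure(hits, direction = direction, padj_cutoff = padj_cutoff,
            class = c("hit_list", "character"))
}

#' @export
print.hit_list <- function(x, ...) {
  cat("hit_list: ", length(x), " ", attr(x, "direction"),
      " genes at padj <= ", attr(x, "padj_cutoff"), "\n", sep = "")
  if (length(x)) cat(paste(head(unclass(x), 10), collapse = ", "),
                     if (length(x) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Write gene-level results and hit lists
#'
#' `write_gene_stats` emits a volcano-plot-ready TSV (gene, aLFC, es,
#' p/padj per direction, `neglog10_padj`, n_sig); `write_hits` writes one
#' gene symbol per line.
#' @param genes a `gene_scores`.
#' @param path output path.
#' @export
write_gene_stats <- function(genes, path) {
  df <- as.data.frame(genes)
  df$neglog10_padj <- -log10(pmax(df$padj, 1e-300))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_gene_stats
#' @param hits a `hit_list`.
#' @export
write_hits <- function(hits, path) {
  writeLines(as.character(hits), path)
}
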