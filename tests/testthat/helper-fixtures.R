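# Shared fixture builders; everything is generated in code at test time.

# Write a library-index TSV and return its path.
write_library_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_library_df <- function() {
  data.frame(
    guide_id = c("g1", "g2", "c1"),
    gene = c("GENE1", "GENE1", ""),
    spacer = c("AACCGGTTACAGTCAGGTCA",
               "GATTACAGATTACAGATTAC",
               "CCCTAAGGGTTTCACAATGG"),
    is_control = c(0, 0, 1),
    stringsAsFactors = FALSE
  )
}

tiny_library <- function() load_library(write_library_tsv(tiny_library_df()))

# Minimal screen_counts from a bare matrix (two conditions, n reps each).
counts_fixture <- function(m, conditions) {
  gid <- sprintf("g%02d", seq_len(nrow(m)))
  dimnames(m) <- list(gid, paste0("s", seq_len(ncol(m))))
  idx_path <- write_library_tsv(data.frame(
    guide_id = gid, gene = paste0("G", seq_len(nrow(m))),
    spacer = phagoscreen:::.make_spacers(nrow(m)),
    is_control = 0, stringsAsFactors = FALSE))
  samples <- data.frame(sample_id = colnames(m), condition = conditions,
                        replicate = as.integer(ave(seq_along(conditions),
                                                   conditions, FUN = seq_along)),
                        stringsAsFactors = FALSE)
  screen_counts(m, samples, load_library(idx_path))
}

# Independent O(N) running-sum oracle for the enrichment score.
es_walk_oracle <- function(ranked, members, weight = 0) {
  N <- nrow(ranked)
  hit <- ranked$guide_id %in% members
  k <- sum(hit)
  absr <- abs(ranked$r)
  inc <- if (weight == 0 || all(absr[hit] == 0)) {
    ifelse(hit, 1 / k, 0)
  } else {
    ifelse(hit, absr / sum(absr[hit]), 0)
  }
  step <- ifelse(hit, inc, -1 / (N - k))
  walk <- cumsum(step)
  hi <- max(walk); lo <- min(0, min(walk))
  if (hi >= -lo) hi else lo
}

# Naive O(m^2) BH oracle.
bh_oracle <- function(p) {
  ok <- !is.na(p)
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  for (i in which(ok)) {
    rank_i <- sum(p[ok] <= p[i])
    cand <- vapply(which(ok), function(j) {
      rank_j <- sum(p[ok] <= p[j])
      if (p[j] >= p[i]) m * p[j] / rank_j else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# Exact two-sided Fisher p by hypergeometric enumeration.
fisher_enum_oracle <- function(k, K, n, N) {
  xs <- max(0, n + K - N):min(n, K)
  d <- stats::dhyper(xs, K, N - K, n)
  sum(d[d <= stats::dhyper(k, K, N - K, n) * (1 + 1e-7)])
}
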