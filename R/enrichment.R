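#' Read a GMT gene-set collection
#'
#' One set per line: term id, description, then member symbols, tab
#' separated. The description column is retained (unlike bare pathway
#' readers) because result tables report it.
#' @param path GMT file.
#' @return list of class `geneset_collection`: per set `term_id`, `name`,
#'   `members` (unique, normalized symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 3) stop("malformed GMT line (needs id, name, >=1 gene): ",
                            substr(ln, 1, 50))
    list(term_id = f[1], name = f[2],
         members = unique(norm_symbol(f[-c(1, 2)])))
  })
  ids <- vapply(sets, `[[`, "", "term_id")
  if (anyDuplicated(ids)) stop("duplicate term_id in ", path)
  structure(sets, class = "geneset_collection")
}

#' Fisher over-representation analysis of a hit list
#'
#' For each gene set, forms the 2x2 table of hit membership against set
#' membership within the universe and computes the two-sided Fisher exact
#' p-value (the sum of hypergeometric point masses no larger than the
#' observed one). Sets are intersected with the universe first; sets with no
#' universe member are dropped. P-values are BH-adjusted across the tested
#' terms.
#'
#' @param hits character vector of hit symbols (must lie in `universe`).
#' @param universe background gene symbols; the natural choice for a screen
#'   is every gene in the guide library.
#' @param collection a `geneset_collection` (or named list of symbol
#'   vectors).
#' @return data.frame sorted by `padj` (ties by `p`, then `term_id`) with
#'   columns `term_id`, `name`, `k`, `K`, `n`, `N`, `odds_ratio`, `p`,
#'   `padj`.
#' @export
fisher_ora <- function(hits, universe, collection) {
  hits <- unique(norm_symbol(hits))
  universe <- unique(norm_symbol(universe))
  bad <- setdiff(hits, universe)
  if (length(bad))
    stop("hits not in universe: ", paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  if (!inherits(collection, "geneset_collection"))
    collection <- structure(lapply(seq_along(collection), function(i) list(
      term_id = names(collection)[i], name = names(collection)[i],
      members = unique(norm_symbol(collection[[i]])))),
      class = "geneset_collection")
  n <- length(hits); N <- length(universe)
  rows <- lapply(collection, function(s) {
    mem <- intersect(s$members, universe)
    K <- length(mem)
    if (K == 0L) return(NULL)
    k <- length(intersect(mem, hits))
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), 2, 2)
    p <- stats::fisher.test(tab)$p.value
    or <- (k * (N - n - K + k)) / ((n - k) * (K - k))
    data.frame(term_id = s$term_id, name = s$name, k = k, K = K, n = n,
               N = N, odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), odds_ratio = numeric(), p = numeric(),
                      padj = numeric()))
  out$padj <- adjust_bh(out$p)
  out <- out[order(out$padj, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an ORA result table
#' @param ora result of [fisher_ora()].
#' @param path output TSV.
#' @export
write_ora <- function(ora, path) {
  ora$k_over_K <- paste0(ora$k, "/", ora$K)
  utils::write.table(
    ora[, c("term_id", "name", "k_over_K", "odds_ratio", "p", "padj")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}
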