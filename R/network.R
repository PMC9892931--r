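#' Read a bait-prey interaction table
#'
#' TSV with columns `bait` and `prey` (extra columns such as a source tag are
#' kept). Directionality is permitted on input; it is collapsed when the
#' subnetwork is built.
#' @param path TSV path.
#' @return data.frame with at least `bait`, `prey`.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("bait", "prey") %in% names(df)))
    stop("interaction table needs columns bait, prey; got: ",
         paste(names(df), collapse = ", "))
  df$bait <- norm_symbol(df$bait)
  df$prey <- norm_symbol(df$prey)
  if (any(df$bait == "" | df$prey == ""))
    stop("empty gene symbol in interaction table: ", path)
  df
}

#' Read a protein-complex catalog
#'
#' TSV with columns `complex_id`, `name`, `subunits` (semicolon-joined gene
#' symbols), mirroring a CORUM-style download.
#' @param path TSV path.
#' @return list of class `complex_catalog`: per complex `complex_id`,
#'   `name`, `subunits` (character set).
#' @export
read_complexes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("complex_id", "name", "subunits") %in% names(df)))
    stop("complex catalog needs columns complex_id, name, subunits")
  if (anyDuplicated(df$complex_id))
    stop("duplicate complex_id in ", path)
  cx <- lapply(seq_len(nrow(df)), function(i) list(
    complex_id = df$complex_id[i],
    name = df$name[i],
    subunits = unique(norm_symbol(strsplit(df$subunits[i], ";")[[1]]))
  ))
  structure(cx, class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  sizes <- vapply(x, function(c) length(c$subunits), 1L)
  cat("complex_catalog: ", length(x), " complexes, subunit counts ",
      min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

norm_symbol <- function(x) toupper(trimws(x))

#' Build the hit-restricted PPI subnetwork
#'
#' Keeps interactions whose bait and prey are both screen hits, drops
#' self-pairs, collapses reciprocal (A,B)/(B,A) rows to one undirected edge,
#' and takes as nodes the endpoints of the surviving edges. Hits without any
#' surviving interaction are therefore not network nodes.
#'
#' @param interactions data.frame with `bait`, `prey` columns.
#' @param hits character vector of hit gene symbols.
#' @return list of class `ppi_network`: `nodes` (sorted character vector)
#'   and `edges` (data.frame `a`, `b` with `a < b`, sorted).
#' @export
build_subnetwork <- function(interactions, hits) {
  if (!length(hits)) stop("empty hit list")
  hits <- unique(norm_symbol(as.character(hits)))
  bait <- norm_symbol(interactions$bait)
  prey <- norm_symbol(interactions$prey)
  keep <- bait %in% hits & prey %in% hits & bait != prey
  a <- pmin(bait[keep], prey[keep])
  b <- pmax(bait[keep], prey[keep])
  key <- paste(a, b, sep = "\t")
  uniq <- !duplicated(key)
  edges <- data.frame(a = a[uniq], b = b[uniq], stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " undirected edges\n", sep = "")
  invisible(x)
}

#' Remove homodimers / singleton entries from a complex catalog
#'
#' Complexes with fewer than two distinct subunits carry no grouping
#' information and are dropped.
#' @param catalog a `complex_catalog`.
#' @return filtered `complex_catalog`.
#' @export
filter_catalog <- function(catalog) {
  keep <- vapply(catalog, function(c) length(c$subunits) >= 2L, logical(1))
  structure(catalog[keep], class = "complex_catalog")
}

#' Complex completeness in the screen and in the network
#'
#' `screen_pct` is the percentage of a complex's subunits that are screen
#' hits; `network_pct` the percentage present as nodes of the hit subnetwork.
#' Exact fractions are returned; round only for display.
#'
#' @param complex one catalog entry (list with `subunits`), or a character
#'   vector of subunits.
#' @param hits character vector of hit symbols.
#' @param network_nodes character vector of subnetwork node symbols.
#' @return named numeric: `size`, `screen_pct`, `network_pct`.
#' @export
completeness <- function(complex, hits, network_nodes = character()) {
  sub <- if (is.list(complex)) complex$subunits else complex
  sub <- unique(norm_symbol(sub))
  hits <- norm_symbol(hits)
  network_nodes <- norm_symbol(network_nodes)
  c(size = length(sub),
    screen_pct = 100 * sum(sub %in% hits) / length(sub),
    network_pct = 100 * sum(sub %in% network_nodes) / length(sub))
}

#' Assign each network protein to its best-covered complex
#'
#' Every network node that is a subunit of at least one catalog complex is
#' assigned the complex with the highest screen completeness (`screen_pct`);
#' ties are broken by larger complex size, then lexicographic complex id.
#'
#' @param network a `ppi_network`.
#' @param catalog a filtered `complex_catalog`.
#' @param hits the hit list used to build the network.
#' @return list of class `complex_annotation`: `complexes` (data.frame
#'   `complex_id`, `name`, `size`, `screen_pct`, `network_pct`) and
#'   `assignment` (data.frame `gene`, `complex_id`).
#' @export
assign_complexes <- function(network, catalog, hits) {
  stopifnot(inherits(network, "ppi_network"))
  hits <- norm_symbol(hits)
  comp <- do.call(rbind, lapply(catalog, function(c) {
    cc <- completeness(c, hits, network$nodes)
    data.frame(complex_id = c$complex_id, name = c$name,
               size = unname(cc["size"]), screen_pct = unname(cc["screen_pct"]),
               network_pct = unname(cc["network_pct"]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(comp))
    comp <- data.frame(complex_id = character(), name = character(),
                       size = integer(), screen_pct = numeric(),
                       network_pct = numeric())
  member_of <- lapply(catalog, function(c) c$subunits)
  ids <- vapply(catalog, function(c) c$complex_id, "")
  assign <- lapply(network$nodes, function(g) {
    in_cx <- which(vapply(member_of, function(s) g %in% s, logical(1)))
    if (!length(in_cx)) return(NULL)
    cand <- comp[match(ids[in_cx], comp$complex_id), , drop = FALSE]
    best <- cand[order(-cand$screen_pct, -cand$size, cand$complex_id), ][1, ]
    data.frame(gene = g, complex_id = best$complex_id,
               stringsAsFactors = FALSE)
  })
  assign <- do.call(rbind, assign)
  if (is.null(assign))
    assign <- data.frame(gene = character(), complex_id = character())
  rownames(assign) <- NULL
  structure(list(complexes = comp, assignment = assign),
            class = "complex_annotation")
}

#' @export
print.complex_annotation <- function(x, ...) {
  cat("complex_annotation: ", nrow(x$assignment),
      " network proteins assigned across ",
      length(unique(x$assignment$complex_id)), " complexes\n", sep = "")
  full <- x$complexes[x$complexes$screen_pct == 100, , drop = FALSE]
  if (nrow(full))
    cat("complexes at 100% screen completeness: ",
        paste(head(full$name, 5), collapse = ", "),
        if (nrow(full) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Export node and edge tables for graph tools
#'
#' Writes `<prefix>_edges.tsv` (source, target), `<prefix>_nodes.tsv`
#' (gene, alfc, complex_id, screen_pct, network_pct) and
#' `<prefix>_complexes.tsv` (the completeness table). Rows are sorted so
#' exports are deterministic; display rounding of completeness percentages
#' is nearest-integer half-up, with exact values kept alongside.
#'
#' @param network a `ppi_network`.
#' @param annotation a `complex_annotation` (optional).
#' @param genes a `gene_scores` table to pull `alfc` from (optional).
#' @param prefix output path prefix.
#' @return invisible character vector of the written paths.
#' @export
export_network <- function(network, annotation = NULL, genes = NULL, prefix) {
  paths <- c(edges = paste0(prefix, "_edges.tsv"),
             nodes = paste0(prefix, "_nodes.tsv"))
  edges <- network$edges
  names(edges) <- c("source", "target")
  utils::write.table(edges, paths["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- data.frame(gene = network$nodes, stringsAsFactors = FALSE)
  if (!is.null(genes))
    nodes$alfc <- genes$alfc[match(nodes$gene, norm_symbol(genes$gene))]
  if (!is.null(annotation)) {
    nodes$complex_id <- annotation$assignment$complex_id[
      match(nodes$gene, annotation$assignment$gene)]
    idx <- match(nodes$complex_id, annotation$complexes$complex_id)
    nodes$screen_pct <- round_half_up(annotation$complexes$screen_pct[idx])
    nodes$network_pct <- round_half_up(annotation$complexes$network_pct[idx])
    paths["complexes"] <- paste0(prefix, "_complexes.tsv")
    cx <- annotation$complexes
    cx$screen_pct_display <- round_half_up(cx$screen_pct)
    cx$network_pct_display <- round_half_up(cx$network_pct)
    cx <- cx[order(cx$complex_id), , drop = FALSE]
    utils::write.table(cx, paths["complexes"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(nodes[order(nodes$gene), , drop = FALSE], paths["nodes"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

round_half_up <- function(x) floor(x + 0.5)

#' Re-import an exported network
#' @param prefix the prefix passed to [export_network()].
#' @return a `ppi_network`.
#' @export
import_network <- function(prefix) {
  edges <- utils::read.delim(paste0(prefix, "_edges.tsv"),
                             stringsAsFactors = FALSE)
  names(edges) <- c("a", "b")
  structure(list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges),
            class = "ppi_network")
}

#' Overlap of two gene lists
#'
#' Exact set arithmetic after symbol normalization (upper-case,
#' whitespace-stripped).
#' @param a,b character vectors of gene symbols.
#' @return named integer vector: `both`, `a_only`, `b_only`.
#' @export
list_overlap <- function(a, b) {
  a <- unique(norm_symbol(a)); b <- unique(norm_symbol(b))
  c(both = length(intersect(a, b)),
    a_only = length(setdiff(a, b)),
    b_only = length(setdiff(b, a)))
}
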