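#' Run the screen analysis pipeline from a config
#'
#' Orchestrates counts -> per-guide NB test -> gene aggregation -> hit
#' calling for each configured contrast, writing all tables plus a JSON
#' manifest. The run is a pure composition of the module functions, so the
#' outputs equal direct calls with the same inputs and seed.
#'
#' @param config a list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{library}{path to the guide library TSV (omit when `counts` was
#'       written by [write_counts()] together with a `library`).}
#'     \item{counts}{path to a counts TSV from [write_counts()]; or}
#'     \item{fastq}{named list sample_id -> FASTQ path, plus `samples`
#'       (data.frame-like list with sample_id/condition/replicate) to count
#'       reads first.}
#'     \item{contrasts}{list of two-element vectors `c(A, B)`.}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer; seeds every stochastic stage.}
#'     \item{n_perm, weight, padj_cutoff, direction, use_raw_p,
#'       shrink_weight, count_mode}{optional knobs with module defaults.}
#'   }
#' @return invisible manifest (list), also written as `manifest.json`.
#' @export
run_screen_pipeline <- function(config) {
  cfg <- load_config(config)
  for (f in c("out_dir", "seed", "contrasts"))
    if (is.null(cfg[[f]])) stop("config field missing: ", f)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  index <- load_library(req_file(cfg$library, "library"))
  if (!is.null(cfg$counts)) {
    sc <- read_counts(req_file(cfg$counts, "counts"), index)
  } else if (!is.null(cfg$fastq)) {
    samples <- as.data.frame(lapply(cfg$samples, unlist),
                             stringsAsFactors = FALSE)
    samples$replicate <- as.integer(samples$replicate)
    cols <- list(); reports <- list()
    for (sid in samples$sample_id) {
      res <- count_reads(req_file(cfg$fastq[[sid]], paste0("fastq:", sid)),
                         index, mode = cfg$count_mode %||% "substring")
      cols[[sid]] <- res$counts
      reports[[sid]] <- res$report
    }
    sc <- merge_counts(cols, samples, index)
    jsonlite::write_json(reports, file.path(cfg$out_dir, "counting_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_counts(sc, file.path(cfg$out_dir, "counts.tsv"))
  } else stop("config needs either 'counts' or 'fastq'")
  bad <- setdiff(unique(unlist(cfg$contrasts)), unique(sc$samples$condition))
  if (length(bad))
    stop("contrast references unknown condition(s): ",
         paste(bad, collapse = ", "))

  sf <- size_factors(sc)
  disp <- estimate_dispersions(sc, sf = sf,
                               shrink_weight = cfg$shrink_weight %||% NULL)
  manifest <- list(tool = "phagoscreen",
                   version = as.character(utils::packageVersion("phagoscreen")),
                   seed = cfg$seed, n_guides = nrow(sc$counts),
                   samples = sc$samples$sample_id, outputs = list())
  for (ct in cfg$contrasts) {
    ct <- unlist(ct)
    tag <- paste0(ct[1], "_vs_", ct[2])
    fit <- tryCatch(
      sgrna_test(sc, contrast = ct, sf = sf, dispersions = disp),
      error = function(e) stop("stage sgrna_test [", tag, "] failed: ",
                               conditionMessage(e)))
    genes <- tryCatch(
      aggregate_genes(fit, n_perm = cfg$n_perm %||% 1000L, seed = cfg$seed,
                      weight = cfg$weight %||% 0),
      error = function(e) stop("stage aggregate_genes [", tag, "] failed: ",
                               conditionMessage(e)))
    hits <- call_hits(genes, direction = cfg$direction %||% "depleted",
                      padj_cutoff = cfg$padj_cutoff %||% 0.05,
                      use_raw_p = isTRUE(cfg$use_raw_p))
    paths <- c(guide = file.path(cfg$out_dir, paste0("sgrna_", tag, ".tsv")),
               gene = file.path(cfg$out_dir, paste0("genes_", tag, ".tsv")),
               hits = file.path(cfg$out_dir, paste0("hits_", tag, ".txt")))
    write_sgrna_stats(fit, paths["guide"])
    write_gene_stats(genes, paths["gene"])
    write_hits(hits, paths["hits"])
    manifest$outputs[[tag]] <- list(
      contrast = ct, files = as.list(paths),
      n_guides_tested = sum(!is.na(fit$table$p)),
      n_genes = nrow(genes), n_hits = length(hits))
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the hit-network annotation pipeline from a config
#'
#' Builds the hit-restricted PPI subnetwork, filters the complex catalog,
#' scores completeness, assigns each network protein to its best complex and
#' exports node/edge/completeness tables.
#'
#' @param config list or YAML path with fields `hits` (gene list file, one
#'   symbol per line), `interactions` (bait-prey TSV), `complexes`
#'   (catalog TSV), `out_dir`, optional `gene_stats` (TSV from
#'   [write_gene_stats()], for node aLFC values).
#' @return invisible manifest (list), also written as
#'   `network_manifest.json`.
#' @export
run_network_pipeline <- function(config) {
  cfg <- load_config(config)
  for (f in c("hits", "interactions", "complexes", "out_dir"))
    if (is.null(cfg[[f]])) stop("config field missing: ", f)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hits <- readLines(req_file(cfg$hits, "hits"))
  hits <- hits[nzchar(trimws(hits))]
  if (!length(hits)) stop("empty hit list: ", cfg$hits)
  interactions <- read_interactions(req_file(cfg$interactions, "interactions"))
  catalog <- filter_catalog(read_complexes(req_file(cfg$complexes, "complexes")))
  network <- build_subnetwork(interactions, hits)
  annotation <- assign_complexes(network, catalog, hits)
  genes <- if (!is.null(cfg$gene_stats))
    utils::read.delim(req_file(cfg$gene_stats, "gene_stats"),
                      stringsAsFactors = FALSE) else NULL
  prefix <- file.path(cfg$out_dir, "network")
  paths <- export_network(network, annotation, genes, prefix)
  manifest <- list(tool = "phagoscreen",
                   version = as.character(utils::packageVersion("phagoscreen")),
                   n_hits = length(unique(norm_symbol(hits))),
                   n_nodes = length(network$nodes),
                   n_edges = nrow(network$edges),
                   n_assigned = nrow(annotation$assignment),
                   files = as.list(paths))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "network_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config must be a list or a YAML path")
}

req_file <- function(path, what) {
  if (is.null(path)) stop("config field missing: ", what)
  if (!file.exists(path)) stop(what, " file not found: ", path)
  path
}
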