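#' Simulation settings for a synthetic sorted-fraction CRISPR screen
#'
#' Defaults emulate a genome-wide knockout-library screen read out by cell
#' sorting: four guides per gene, a control-guide block scaled like 142
#' controls per 18,053 genes, two sorted fractions (PhagoNeg reference and
#' PhagoLate) in duplicate, log-normal guide abundance around a mean
#' sequencing depth of 500 reads per guide, and negative-binomial counting
#' noise with dispersion 0.05. Planted genes apply a log2 effect (default
#' -2) to all their guides in the effect condition, with per-guide normal
#' jitter modelling heterogeneous cutting efficiency; control guides are
#' never planted.
#'
#' @param n_genes number of targeting genes.
#' @param guides_per_gene guides per gene (default 4).
#' @param n_controls number of non-targeting controls (default scaled as
#'   142 per 18,053 genes, at least 2).
#' @param conditions condition labels.
#' @param replicates replicates per condition (scalar or per-condition).
#' @param mean_depth mean reads per guide.
#' @param abundance_sdlog log-normal sigma of baseline guide abundance.
#' @param alpha0 NB dispersion of the counting noise.
#' @param planted_fraction fraction of genes carrying an effect, in `[0,1)`.
#' @param planted_lfc log2 effect applied to planted genes in
#'   `effect_condition`.
#' @param jitter_sd per-guide SD around `planted_lfc` (log2 scale).
#' @param effect_condition condition the effect acts on (the sorted fraction,
#'   not the input).
#' @param libsize_sdlog log-normal sigma of per-sample depth multipliers.
#' @param seed integer seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, guides_per_gene = 4L,
                       n_controls = NULL,
                       conditions = c("PhagoNeg", "PhagoLate"),
                       replicates = 2L, mean_depth = 500,
                       abundance_sdlog = 0.5, alpha0 = 0.05,
                       planted_fraction = 0.05, planted_lfc = -2,
                       jitter_sd = 0.3, effect_condition = "PhagoLate",
                       libsize_sdlog = 0.15, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(n_controls))
    n_controls <- max(2L, round(142 * n_genes / 18053))
  if (length(replicates) == 1L)
    replicates <- rep(replicates, length(conditions))
  cfg <- list(n_genes = as.integer(n_genes),
              guides_per_gene = as.integer(guides_per_gene),
              n_controls = as.integer(n_controls),
              conditions = conditions, replicates = as.integer(replicates),
              mean_depth = mean_depth, abundance_sdlog = abundance_sdlog,
              alpha0 = alpha0, planted_fraction = planted_fraction,
              planted_lfc = planted_lfc, jitter_sd = jitter_sd,
              effect_condition = effect_condition,
              libsize_sdlog = libsize_sdlog, seed = as.integer(seed))
  if (cfg$mean_depth < 1) stop("mean_depth must be >= 1")
  if (cfg$planted_fraction < 0 || cfg$planted_fraction >= 1)
    stop("planted_fraction must lie in [0, 1)")
  if (any(cfg$replicates < 1)) stop("each condition needs >= 1 replicate")
  if (cfg$planted_fraction > 0 && !(effect_condition %in% conditions))
    stop("effect_condition must be one of the simulated conditions")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic synthetic spacers: random ACGT L-mers from a fixed internal
# RNG stream (structured encodings collide with each other under shifted
# substring matching; random spacers do not).
.make_spacers <- function(n, L = 20L) {
  with_seed(719L, {
    draw <- function(m) apply(matrix(sample(c("A", "C", "G", "T"), m * L,
                                            replace = TRUE), m, L),
                              1, paste, collapse = "")
    sp <- draw(n)
    while (anyDuplicated(sp)) {
      dup <- which(duplicated(sp))
      sp[dup] <- draw(length(dup))
    }
    sp
  })
}

#' Simulate a sorted-fraction CRISPR screen with known truth
#'
#' Draws baseline guide abundances from a log-normal, per-sample depth
#' multipliers (true size factors) from a log-normal, plants a seeded subset
#' of genes whose guides change by `planted_lfc` (plus per-guide jitter) in
#' the effect condition, and samples counts from a negative binomial with
#' dispersion `alpha0`. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `index` (a `library_index`), `counts` (a
#'   `screen_counts`) and `truth` (planted gene set, per-guide realized
#'   log2 effects, true size factors, the config).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    gid <- c(paste0(rep(genes, each = cfg$guides_per_gene), "_g",
                    seq_len(cfg$guides_per_gene)),
             sprintf("CTRL_g%03d", seq_len(cfg$n_controls)))
    gene_of <- c(rep(genes, each = cfg$guides_per_gene),
                 rep("CTRL", cfg$n_controls))
    n_guides <- length(gid)
    index <- validate_library(data.frame(
      guide_id = gid, gene = gene_of,
      spacer = .make_spacers(n_guides),
      is_control = gene_of == "CTRL", stringsAsFactors = FALSE))

    n_planted <- round(cfg$planted_fraction * cfg$n_genes)
    planted <- sort(sample(genes, n_planted))
    effect <- numeric(n_guides)
    is_planted_guide <- gene_of %in% planted
    effect[is_planted_guide] <- cfg$planted_lfc +
      stats::rnorm(sum(is_planted_guide), 0, cfg$jitter_sd)

    lambda <- cfg$mean_depth *
      stats::rlnorm(n_guides, -cfg$abundance_sdlog^2 / 2, cfg$abundance_sdlog)
    samples <- data.frame(
      sample_id = unlist(mapply(function(c, r) paste0(c, "_r", seq_len(r)),
                                cfg$conditions, cfg$replicates,
                                SIMPLIFY = FALSE)),
      condition = rep(cfg$conditions, cfg$replicates),
      replicate = unlist(lapply(cfg$replicates, seq_len)),
      stringsAsFactors = FALSE)
    sf_true <- stats::rlnorm(nrow(samples), 0, cfg$libsize_sdlog)
    counts <- matrix(0L, n_guides, nrow(samples),
                     dimnames = list(gid, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- lambda * sf_true[j]
      if (samples$condition[j] == cfg$effect_condition)
        mu <- mu * 2^effect
      counts[, j] <- stats::rnbinom(n_guides, mu = mu,
                                    size = 1 / max(cfg$alpha0, 1e-12))
    }
    list(index = index,
         counts = screen_counts(counts, samples, index),
         truth = list(planted = planted, guide_effect = setNames(effect, gid),
                      size_factors = setNames(sf_true, samples$sample_id),
                      config = cfg))
  })
}

#' Emit reads for one sample as FASTQ
#'
#' Embeds each guide's spacer in constant flanking sequence and writes one
#' read per count, so the counting stage can be tested end to end from
#' reads. Optionally appends unmatched filler reads.
#'
#' @param index a `library_index`.
#' @param counts named integer vector (guide id -> read count).
#' @param path output FASTQ (gzipped when the name ends in `.gz`).
#' @param flank5,flank3 constant sequence around the spacer.
#' @param n_unmatched number of random filler reads carrying no spacer.
#' @param seed seed for shuffling read order / filler generation.
#' @export
write_sample_fastq <- function(index, counts, path, flank5 = "TATCTTGTGGAAAGGACGAAACACCG",
                               flank3 = "GTTTTAGAGCTAGAAATAGCAAG",
                               n_unmatched = 0L, seed = 1L) {
  stopifnot(inherits(index, "library_index"))
  counts <- counts[counts > 0]
  seqs <- rep(paste0(flank5, index$spacer[match(names(counts), index$guide_id)],
                     flank3), counts)
  with_seed(seed, {
    if (n_unmatched > 0) {
      L <- nchar(flank5) + nchar(index$spacer[1]) + nchar(flank3)
      filler <- vapply(seq_len(n_unmatched), function(i)
        paste(sample(c("A", "C"), L, replace = TRUE), collapse = ""), "")
      # filler avoids G/T so it cannot spell any ACGT spacer containing them;
      # a pure-AC spacer is astronomically unlikely but checked anyway
      filler <- filler[!vapply(filler, function(s)
        any(vapply(index$spacer, grepl, logical(1), x = s, fixed = TRUE)),
        logical(1))]
      seqs <- c(seqs, filler)
    }
    seqs <- sample(seqs)
  })
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), con)
  invisible(path)
}

#' Simulate a PPI network with planted complexes among hits
#'
#' Generates protein-complex rosters (possibly overlapping), draws
#' within-complex bait-prey edges at `p_within` (with a fraction of
#' reciprocal duplicates to exercise deduplication), sprinkles background
#' edges, and samples hits preferentially from complex members so that
#' completeness varies across complexes.
#'
#' @param n_proteins number of proteins.
#' @param n_complexes number of complexes.
#' @param size_range complex size range (inclusive).
#' @param p_within probability of an edge between two complex co-members.
#' @param p_background probability of an edge between any other pair.
#' @param hit_prob_complex probability a complex member is a hit.
#' @param hit_prob_background probability a non-member is a hit.
#' @param reciprocal_fraction fraction of within-complex edges also emitted
#'   in the reverse orientation (duplicate rows).
#' @param seed integer seed (mandatory).
#' @return list with `interactions` (bait/prey data.frame), `catalog`
#'   (a `complex_catalog`), `hits` (character), `truth` (membership and
#'   parameters).
#' @export
simulate_network <- function(n_proteins = 200L, n_complexes = 10L,
                             size_range = c(3L, 8L), p_within = 0.8,
                             p_background = 0.002, hit_prob_complex = 0.7,
                             hit_prob_background = 0.1,
                             reciprocal_fraction = 0.2, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_proteins >= max(size_range), n_complexes >= 1)
  with_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    sizes <- seq(size_range[1], size_range[2])
    catalog <- lapply(seq_len(n_complexes), function(i) {
      k <- sizes[sample.int(length(sizes), 1)]
      list(complex_id = sprintf("CPX%03d", i),
           name = sprintf("complex %d", i),
           subunits = sort(sample(prot, k)))
    })
    class(catalog) <- "complex_catalog"
    in_complex <- prot %in% unlist(lapply(catalog, `[[`, "subunits"))
    hit_p <- ifelse(in_complex, hit_prob_complex, hit_prob_background)
    hits <- prot[stats::runif(n_proteins) < hit_p]
    edges <- list()
    for (cx in catalog) {
      pairs <- utils::combn(cx$subunits, 2)
      keep <- stats::runif(ncol(pairs)) < p_within
      if (any(keep)) {
        kept <- pairs[, keep, drop = FALSE]
        flip <- stats::runif(ncol(kept)) < 0.5
        bait <- ifelse(flip, kept[2, ], kept[1, ])
        prey <- ifelse(flip, kept[1, ], kept[2, ])
        dup <- stats::runif(ncol(kept)) < reciprocal_fraction
        edges[[length(edges) + 1L]] <- data.frame(
          bait = c(bait, prey[dup]), prey = c(prey, bait[dup]),
          source = cx$complex_id, stringsAsFactors = FALSE)
      }
    }
    n_bg <- stats::rbinom(1, choose(n_proteins, 2), p_background)
    if (n_bg > 0) {
      i <- sample(n_proteins, n_bg, replace = TRUE)
      j <- sample(n_proteins - 1L, n_bg, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      edges[[length(edges) + 1L]] <- data.frame(
        bait = prot[i], prey = prot[j], source = "background",
        stringsAsFactors = FALSE)
    }
    interactions <- if (length(edges)) do.call(rbind, edges)
      else data.frame(bait = character(), prey = character(),
                      source = character())
    list(interactions = interactions, catalog = catalog, hits = hits,
         truth = list(in_complex = setNames(in_complex, prot),
                      params = list(p_within = p_within,
                                    p_background = p_background,
                                    hit_prob_complex = hit_prob_complex,
                                    hit_prob_background = hit_prob_background,
                                    seed = seed)))
  })
}
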