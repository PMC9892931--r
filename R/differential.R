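#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed with the median-of-ratios scheme:
#' for each guide with all-positive counts, the ratio of its count in sample
#' j to its geometric mean across samples; the size factor of sample j is the
#' median of those ratios, rescaled so the factors have geometric mean 1.
#'
#' @param counts guides x samples matrix, or a `screen_counts`.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else counts
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no guide has positive counts in every sample; ",
         "consider a pseudo-reference (add a pseudocount) before normalizing")
  lg <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, stats::median)
  sf / exp(mean(log(sf)))
}

#' Estimate per-guide NB dispersions with trend shrinkage
#'
#' Raw dispersions are method-of-moments estimates pooled across conditions
#' with replication: for each such condition, `(var - mu) / mu^2` on
#' normalized counts, combined with degrees-of-freedom weights and floored at
#' zero. A mean-dispersion trend `a1/mu + a0` is fitted by least squares to
#' the positive raw estimates, and the final dispersion is a weighted
#' geometric interpolation between the raw estimate and the trend value at
#' the guide's mean: `log alpha = (1-w) log alpha_raw + w log alpha_trend`.
#' Guides with a zero raw estimate take the trend value. Everything is
#' floored at `1e-8`.
#'
#' @param x a `screen_counts` (or counts matrix with `conditions` given).
#' @param sf size factors; computed if `NULL`.
#' @param conditions per-sample condition labels (taken from `x$samples` for
#'   a `screen_counts`).
#' @param shrink_weight `NULL` (default) for an adaptive weight, or a fixed
#'   numeric weight in `[0,1]` pulling the log dispersion toward the trend.
#' @details With `shrink_weight = NULL` the weight is set empirical-Bayes
#'   style: `w = v_samp / (v_samp + v_prior)`, where
#'   `v_samp = trigamma(d/2)` approximates the sampling variance of the log
#'   raw dispersion at `d` pooled residual degrees of freedom, and `v_prior`
#'   is the excess spread of observed log dispersions around the trend
#'   (floored at 0.05). At typical screen depth with two replicates per
#'   condition the raw estimates are nearly pure noise, the weight approaches
#'   1 and the trend dominates, which keeps the downstream Wald test
#'   calibrated; with more replicates or genuinely heterogeneous dispersions
#'   the raw estimates keep weight.
#' @return data.frame with `guide_id`, `base_mean`, `disp_raw`, `disp_trend`,
#'   `dispersion`; the trend coefficients and the weight used are in
#'   `attr(,"trend")` / `attr(,"shrink_weight")`.
#' @export
estimate_dispersions <- function(x, sf = NULL, conditions = NULL,
                                 shrink_weight = NULL) {
  m <- if (inherits(x, "screen_counts")) x$counts else x
  if (is.null(conditions))
    conditions <- if (inherits(x, "screen_counts")) x$samples$condition
    else stop("conditions required for a bare matrix")
  if (is.null(sf)) sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  reps <- split(seq_along(conditions), conditions)
  reps <- reps[vapply(reps, length, 1L) >= 2L]
  if (!length(reps))
    stop("no condition has >= 2 replicates; within-condition variance undefined")
  num <- den <- 0
  for (idx in reps) {
    sub <- norm[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    w <- length(idx) - 1L
    # pooled MoM: df-weighted average of (var - mu)/mu^2 across conditions
    num <- num + w * ifelse(mu > 0, (v - mu) / mu^2, 0)
    den <- den + w
  }
  disp_raw <- pmax(0, num / den)
  base_mean <- rowMeans(norm)
  ok <- disp_raw > 0 & base_mean > 0
  if (sum(ok) >= 2) {
    fit <- stats::lm(disp_raw[ok] ~ I(1 / base_mean[ok]))
    a0 <- max(unname(coef(fit)[1]), 1e-8)
    a1 <- max(unname(coef(fit)[2]), 0)
  } else {
    a0 <- max(mean(disp_raw), 1e-8); a1 <- 0
  }
  disp_trend <- pmax(a1 / pmax(base_mean, 1e-8) + a0, 1e-8)
  if (is.null(shrink_weight)) {
    d <- den  # pooled residual df, shared by all guides
    v_samp <- trigamma(d / 2)
    lr <- log(disp_raw[ok]) - log(disp_trend[ok])
    v_prior <- max(if (sum(ok) >= 2) stats::var(lr) - v_samp else 0, 0.05)
    w <- v_samp / (v_samp + v_prior)
  } else {
    stopifnot(shrink_weight >= 0, shrink_weight <= 1)
    w <- shrink_weight
  }
  final <- ifelse(disp_raw > 0,
                  exp((1 - w) * log(pmax(disp_raw, 1e-8)) + w * log(disp_trend)),
                  disp_trend)
  out <- data.frame(guide_id = rownames(m), base_mean = base_mean,
                    disp_raw = disp_raw, disp_trend = disp_trend,
                    dispersion = pmax(final, 1e-8),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "trend") <- c(a0 = a0, a1 = a1)
  attr(out, "shrink_weight") <- w
  out
}

# Vectorized per-group Newton solve of the NB log-mean MLE.
# For a two-group model with sample offsets log(sf), the (intercept, lfc)
# Newton iteration decouples into independent 1-D solves of
# sum_j (y_ij - mu_ij)/(1 + alpha_i mu_ij) = 0 per group; the step is damped
# (clipped at +-3 on the log scale) which plays the role of a line search.
.nb_group_eta <- function(y, sf, alpha, max_iter = 100L, tol = 1e-8) {
  # y: guides x samples counts for one group; sf: size factors of its samples
  n <- nrow(y)
  eta <- log(pmax(rowSums(y) / sum(sf), 1e-8))
  conv <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    mu <- exp(outer(eta, log(sf), "+"))
    wgt <- mu / (1 + alpha * mu)
    score <- rowSums((y - mu) / (1 + alpha * mu))
    info <- rowSums(wgt)
    conv <- abs(score) < tol * pmax(1, info)
    if (all(conv)) break
    step <- ifelse(info > 0, score / info, 0)
    step <- pmin(pmax(step, -3), 3)
    eta <- eta + ifelse(conv, 0, step)
  }
  mu <- exp(outer(eta, log(sf), "+"))
  # observed information at the MLE (expected info would drop the y term)
  info <- rowSums(mu * (1 + alpha * y) / (1 + alpha * mu)^2)
  list(eta = eta, info = info, converged = conv)
}

#' Per-sgRNA negative-binomial Wald test between two conditions
#'
#' Fits, per guide, a negative-binomial GLM with log link and known
#' dispersion: `mu_ij = s_j * q_i * 2^(beta * x_j)` where `x_j` indicates the
#' contrast condition. `beta` is the log2 fold change of condition A over the
#' reference B; its standard error comes from the Fisher information, the
#' Wald statistic is `beta/se` with a two-sided normal p-value, and p-values
#' are Benjamini-Hochberg adjusted across all tested guides. Guides with
#' all-zero counts in both conditions are excluded from testing (and from the
#' BH denominator); guides whose fit does not converge (e.g., all zeros on
#' one side, so the fold change diverges) are reported with `NA` statistics.
#'
#' @param x a `screen_counts`.
#' @param contrast character pair `c(A, B)`: condition A versus reference B.
#' @param sf size factors (computed from the full matrix if `NULL`).
#' @param dispersions data.frame from [estimate_dispersions()] (computed if
#'   `NULL`), or a single numeric dispersion applied to all guides.
#' @param shrink_weight passed to [estimate_dispersions()] when they are
#'   computed here.
#' @return Object of class `sgrna_fit`: a list with `table` (per-guide
#'   statistics: `guide_id`, `gene`, `base_mean`, `log2fc`, `se`, `wald`,
#'   `p`, `padj`, `dispersion`, `converged`), `contrast`, `size_factors`.
#' @export
sgrna_test <- function(x, contrast, sf = NULL, dispersions = NULL,
                       shrink_weight = NULL) {
  stopifnot(inherits(x, "screen_counts"), length(contrast) == 2)
  cond <- x$samples$condition
  for (cc in contrast) {
    if (sum(cond == cc) < 2L)
      stop("condition '", cc, "' needs >= 2 replicates (found ",
           sum(cond == cc), ")")
  }
  if (is.null(sf)) sf <- size_factors(x)
  names(sf) <- colnames(x$counts)
  keep <- cond %in% contrast
  mk <- x$counts[, keep, drop = FALSE]
  sfk <- sf[keep]
  condk <- cond[keep]
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(x, sf = sf, shrink_weight = shrink_weight)
  alpha <- if (is.data.frame(dispersions))
    dispersions$dispersion[match(rownames(mk), dispersions$guide_id)]
  else rep(dispersions, nrow(mk))
  alpha <- pmax(alpha, 1e-8)

  tested <- rowSums(mk) > 0
  A <- condk == contrast[1]
  B <- condk == contrast[2]
  n <- nrow(mk)
  log2fc <- se <- rep(NA_real_, n)
  converged <- rep(NA, n)
  if (any(tested)) {
    ya <- mk[tested, A, drop = FALSE]; yb <- mk[tested, B, drop = FALSE]
    al <- alpha[tested]
    fa <- .nb_group_eta(ya, sfk[A], al)
    fb <- .nb_group_eta(yb, sfk[B], al)
    ok <- fa$converged & fb$converged & rowSums(ya) > 0 & rowSums(yb) > 0
    b <- (fa$eta - fb$eta) / log(2)
    s <- sqrt(1 / fa$info + 1 / fb$info) / log(2)
    b[!ok] <- NA_real_; s[!ok] <- NA_real_
    log2fc[tested] <- b
    se[tested] <- s
    converged[tested] <- ok
  }
  wald <- log2fc / se
  p <- 2 * stats::pnorm(-abs(wald))
  norm <- sweep(mk, 2, sfk, "/")
  tab <- data.frame(
    guide_id = rownames(mk),
    gene = x$index$gene[match(rownames(mk), x$index$guide_id)],
    base_mean = rowMeans(norm),
    log2fc = log2fc, se = se, wald = wald, p = p,
    padj = adjust_bh(p),
    dispersion = alpha, converged = converged,
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$p[tested & !is.na(converged) & !converged] <- NA_real_
  structure(list(table = tab, contrast = contrast, size_factors = sf,
                 n_untested = sum(!tested)),
            class = "sgrna_fit")
}

#' Benjamini-Hochberg adjustment with NA handling
#'
#' Step-up BH across the non-missing p-values (`NA`s are excluded from the
#' number of tests and stay `NA`).
#' @param p numeric vector of p-values in `[0,1]` (NAs allowed).
#' @return adjusted p-values, same length/order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' @export
print.sgrna_fit <- function(x, ...) {
  cat("sgRNA differential abundance fit: ", x$contrast[1], " vs ",
      x$contrast[2], "\n", sep = "")
  tb <- x$table
  cat(nrow(tb), "guides tested;", sum(!is.na(tb$padj) & tb$padj < 0.05),
      "at padj < 0.05;", sum(is.na(tb$p)), "with NA statistics\n")
  invisible(x)
}

#' @export
summary.sgrna_fit <- function(object, alpha = 0.05, ...) {
  tb <- object$table
  out <- list(
    contrast = object$contrast,
    n_guides = nrow(tb),
    n_na = sum(is.na(tb$p)),
    n_sig = sum(tb$padj < alpha, na.rm = TRUE),
    n_depleted = sum(tb$padj < alpha & tb$log2fc < 0, na.rm = TRUE),
    n_enriched = sum(tb$padj < alpha & tb$log2fc > 0, na.rm = TRUE),
    median_dispersion = stats::median(tb$dispersion)
  )
  class(out) <- "summary.sgrna_fit"
  out
}

#' @export
print.summary.sgrna_fit <- function(x, ...) {
  cat("Contrast:", x$contrast[1], "vs", x$contrast[2], "\n")
  cat("Guides:", x$n_guides, " (NA stats:", x$n_na, ")\n")
  cat("padj < 0.05:", x$n_sig, " [depleted", x$n_depleted,
      "/ enriched", x$n_enriched, "]\n")
  cat("Median dispersion:", signif(x$median_dispersion, 3), "\n")
  invisible(x)
}

#' @export
coef.sgrna_fit <- function(object, ...) {
  setNames(object$table$log2fc, object$table$guide_id)
}

#' @export
as.data.frame.sgrna_fit <- function(x, ...) x$table

#' Write the per-guide statistics table
#'
#' TSV with columns guide_id, gene, base_mean, log2fc, se, p, padj,
#' dispersion; the contrast is recorded in a `#` header comment.
#' @param fit an `sgrna_fit`.
#' @param path output path.
#' @export
write_sgrna_stats <- function(fit, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# contrast: ", fit$contrast[1], " vs ", fit$contrast[2]), con)
  utils::write.table(
    fit$table[, c("guide_id", "gene", "base_mean", "log2fc", "se", "p",
                  "padj", "dispersion")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
}
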