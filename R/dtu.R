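#' DTU configuration
#'
#' Expression filters and significance level for differential transcript
#' usage testing. Genes must reach `min_gene_count` summed counts in every
#' sample; transcripts must have at least `min_tx_count` counts in at least
#' `min_tx_samples` samples (3 is appropriate for 3-4 replicate designs,
#' 2 for duplicate spike-in designs).
#'
#' @param min_gene_count minimum per-sample gene count (summed transcripts).
#' @param min_tx_count minimum transcript count.
#' @param min_tx_samples number of samples that must reach `min_tx_count`.
#' @param alpha adjusted p-value cutoff.
#' @return a `dtu_config` list.
#' @export
dtu_config <- function(min_gene_count = 10L, min_tx_count = 10L,
                       min_tx_samples = 3L, alpha = 0.05) {
  stopifnot(min_gene_count >= 0, min_tx_count >= 0, min_tx_samples >= 0,
            alpha > 0, alpha < 1)
  structure(list(min_gene_count = as.integer(min_gene_count),
                 min_tx_count = as.integer(min_tx_count),
                 min_tx_samples = as.integer(min_tx_samples),
                 alpha = alpha), class = "dtu_config")
}

#' Filter lowly expressed genes and transcripts
#'
#' First drops all transcripts of genes whose summed count falls below
#' `min_gene_count` in any sample; then drops transcripts reaching
#' `min_tx_count` in fewer than `min_tx_samples` samples. Genes reduced to
#' a single transcript stay in the matrix but are skipped by [dtu_test()]
#' (a usage comparison needs at least two isoforms).
#'
#' @param m a `nanoiso_counts`.
#' @param cfg a [dtu_config()].
#' @return the filtered `nanoiso_counts`.
#' @export
filter_expression <- function(m, cfg = dtu_config()) {
  counts <- m$counts
  gene_map <- m$gene_map[rownames(counts)]
  if (nrow(counts) == 0L) return(m)
  gene_sum <- rowsum(counts, group = gene_map)
  ok_genes <- rownames(gene_sum)[apply(gene_sum >= cfg$min_gene_count, 1L, all)]
  keep <- gene_map %in% ok_genes
  counts <- counts[keep, , drop = FALSE]
  gene_map <- gene_map[keep]
  if (nrow(counts)) {
    n_ok <- rowSums(counts >= cfg$min_tx_count)
    keep2 <- n_ok >= cfg$min_tx_samples
    counts <- counts[keep2, , drop = FALSE]
    gene_map <- gene_map[keep2]
  }
  structure(list(counts = counts, gene_map = gene_map,
                 unassigned = m$unassigned), class = "nanoiso_counts")
}

#' Simes combination of p-values
#'
#' `min_i p_(i) * k / i` over the `k` ordered p-values, capped at 1. Used
#' to aggregate a gene's transcript-level p-values into a gene-level
#' screening p-value.
#'
#' @param pvals non-empty numeric vector in \[0, 1\].
#' @return a single p-value.
#' @export
simes <- function(pvals) {
  if (length(pvals) == 0L) stop("simes() needs at least one p-value")
  stopifnot(all(pvals >= 0 & pvals <= 1))
  k <- length(pvals)
  min(1, min(sort(pvals) * k / seq_len(k)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (monotone, capped at 1);
#' delegates to [stats::p.adjust()].
#'
#' @param pvals numeric vector in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Empirical-Bayes variance squeezing
#'
#' Moments estimator of a scaled inverse-chi-square prior for per-feature
#' variances. On the log scale, `e = log(s2) - digamma(df/2) + log(df/2)`
#' is unbiased for `log(sigma2)`; the prior location is the mean of `e`
#' (or a non-robust lowess trend on `covariate` -- robust iterations would
#' bias the fit upward on the left-skewed log-chi-square noise), and the
#' prior degrees of freedom solve
#' `trigamma(d0/2) = var(e - location) - trigamma(df/2)`. Posterior
#' variances are the df-weighted average of observed and prior variance;
#' when the residual spread is at or below the pure sampling noise the
#' prior df are infinite and the posterior equals the prior location.
#'
#' @param s2 per-feature sample variances.
#' @param df residual degrees of freedom of `s2`.
#' @param covariate optional per-feature covariate (e.g. average log-CPM)
#'   for a mean-variance trend.
#' @return list with `var_post`, `var_prior`, `df_prior`.
#' @export
squeeze_var <- function(s2, df, covariate = NULL) {
  stopifnot(length(s2) >= 2L, df >= 1)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  if (!is.null(covariate)) {
    fit <- stats::lowess(covariate, e, f = 0.4, iter = 0L)
    loc <- stats::approx(fit$x, fit$y, xout = covariate, rule = 2,
                         ties = mean)$y
  } else {
    loc <- rep(mean(e), length(e))
  }
  evar <- stats::var(e - loc) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(var_post = exp(loc), var_prior = exp(loc), df_prior = Inf))
  }
  d0 <- 2 * trigamma_inverse(evar)
  var_prior <- exp(loc + digamma(d0 / 2) - log(d0 / 2))
  var_post <- (df * s2 + d0 * var_prior) / (df + d0)
  list(var_post = var_post, var_prior = var_prior, df_prior = d0)
}

# Newton solve trigamma(y) = x (x > 0), vectorised.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in seq_len(100)) {
    d <- trigamma(y) - x
    if (all(abs(d) < 1e-12)) break
    y <- y - d / psigamma(y, 2L)
  }
  y
}

#' Differential transcript usage test on a filtered count matrix
#'
#' For each transcript `t` of a gene with at least two retained
#' transcripts, the per-transcript log-fold-change of log2-CPM between the
#' two groups is contrasted against the precision-weighted mean
#' log-fold-change of the gene's other transcripts (a transcript-level
#' analog of exon-level relative-usage tests):
#'
#' \deqn{logFC_t = \bar{y}_{t,2} - \bar{y}_{t,1}}
#' \deqn{w_t = 1 / (s^2_t (1/n_1 + 1/n_2))}
#' \deqn{relFC_t = logFC_t - \sum_{j \ne t} w_j logFC_j / \sum_{j \ne t} w_j}
#' \deqn{se^2_t = 1/w_t + 1/\sum_{j \ne t} w_j, \quad
#'       T_t = relFC_t / se_t}
#'
#' with `s^2_t` the pooled within-group variance. With few replicates the
#' raw variances (and hence the weights defining the rest-of-gene mean) are
#' too unstable to be used directly -- noisy weights leak a gene's true
#' usage changes into the relative log-fold-changes of its unchanged
#' isoforms -- so by default `s^2_t` is squeezed towards a mean-variance
#' trend by an empirical-Bayes moments estimator (see [squeeze_var()]),
#' and the residual degrees of freedom gain the estimated prior df. The
#' null reference is a t distribution with Welch-Satterthwaite effective
#' degrees of freedom combining the transcript's own (moderated) variance
#' with the pooled rest-of-gene term; for a two-isoform gene with equal
#' variances and no moderation this is `2(n1+n2-2)`, the exact null of
#' the paired contrast. Gene-level p-values combine the gene's transcript
#' p-values with [simes()]; BH adjustment is applied across transcripts
#' and across genes separately.
#'
#' @param m a filtered `nanoiso_counts` (see [filter_expression()]).
#' @param design named character/factor: sample id -> group, exactly two
#'   groups with at least two samples each.
#' @param cfg a [dtu_config()].
#' @param prior CPM pseudo-count.
#' @param moderate squeeze per-transcript variances towards a common or
#'   trended value (default `TRUE`); `FALSE` gives the raw closed-form
#'   test with a 1e-8 variance floor.
#' @param trend when moderating, squeeze towards a mean-variance trend
#'   (lowess of the log variances on average log-CPM) rather than a single
#'   common value.
#' @return a `nanoiso_dtu` object: list of data.tables `transcripts`
#'   (transcript_id, gene_id, logFC, relative_logFC, t, df, p, p_bh,
#'   p_stagewise) and `genes` (gene_id, n_tx, p_simes, p_bh, screened).
#'   `p_stagewise`/`screened` are filled by [stagewise()].
#' @export
dtu_test <- function(m, design, cfg = dtu_config(), prior = 0.5,
                     moderate = TRUE, trend = TRUE) {
  counts <- m$counts
  design <- design[colnames(counts)]
  groups <- unique(as.character(design))
  if (length(groups) != 2L) stop("dtu_test() requires exactly two groups")
  i1 <- which(design == groups[1L]); i2 <- which(design == groups[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples (within-group variance undefined)")
  y <- log_cpm(counts, prior = prior)
  gene_map <- m$gene_map[rownames(counts)]
  tx_per_gene <- table(gene_map)
  testable <- names(tx_per_gene)[tx_per_gene >= 2L]
  sel <- gene_map %in% testable
  y <- y[sel, , drop = FALSE]
  gm <- gene_map[sel]
  if (nrow(y) == 0L) {
    return(structure(list(
      transcripts = data.table::data.table(transcript_id = character(0),
        gene_id = character(0), logFC = numeric(0), relative_logFC = numeric(0),
        t = numeric(0), df = numeric(0), p = numeric(0), p_bh = numeric(0),
        p_stagewise = numeric(0)),
      genes = data.table::data.table(gene_id = character(0), n_tx = integer(0),
        p_simes = numeric(0), p_bh = numeric(0), screened = logical(0))),
      class = "nanoiso_dtu"))
  }

  m1 <- rowMeans(y[, i1, drop = FALSE]); m2 <- rowMeans(y[, i2, drop = FALSE])
  logfc <- m2 - m1
  ss1 <- rowSums((y[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((y[, i2, drop = FALSE] - m2)^2)
  dfree <- n1 + n2 - 2L
  s2 <- pmax((ss1 + ss2) / dfree, 1e-8)
  if (moderate) {
    sq <- squeeze_var(s2, dfree, covariate = if (trend) rowMeans(y) else NULL)
    s2 <- pmax(sq$var_post, 1e-8)
    s2_avg <- pmax(sq$var_prior, 1e-8)   # prior: stable averaging weights
    dft <- dfree + sq$df_prior
  } else {
    s2_avg <- s2
    dft <- dfree
  }
  w <- 1 / (s2 * (1 / n1 + 1 / n2))
  # Weights for the rest-of-gene average come from the prior/trended
  # variances: they carry no per-transcript sampling noise, so a gene's
  # true usage changes cannot leak into the relative logFC of its
  # unchanged isoforms through randomly tilted weights.
  wa <- 1 / (s2_avg * (1 / n1 + 1 / n2))

  dt <- data.table::data.table(transcript_id = rownames(y), gene_id = gm,
                               logFC = logfc, w = w, wa = wa)
  dt[, `:=`(swa = sum(wa), swaf = sum(wa * logFC), svar = sum(wa^2 / w)),
     by = gene_id]
  dt[, rest_w := swa - wa]
  dt[, relative_logFC := logFC - (swaf - wa * logFC) / rest_w]
  # variance of the leave-one-out weighted mean, then of the contrast
  dt[, se := sqrt(1 / w + (svar - wa^2 / w) / rest_w^2)]
  dt[, t := relative_logFC / se]
  # Welch-Satterthwaite effective degrees of freedom: the squared SE is a sum
  # of two variance estimates -- the transcript's own (total df = residual +
  # prior) and the pooled rest-of-gene term -- so the reference t
  # distribution uses their combined df (for a 2-isoform gene with equal
  # variances and no moderation this gives 2(n1+n2-2) exactly).
  dt[, k := .N, by = gene_id]
  if (is.finite(dft)) {
    dt[, rest_var := (svar - wa^2 / w) / rest_w^2]
    dt[, df := (1 / w + rest_var)^2 /
          ((1 / w)^2 / dft + rest_var^2 / (dft * (k - 1L)))]
    dt[, rest_var := NULL]
  } else {
    dt[, df := Inf]
  }
  dt[, p := 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)]
  dt[, p_bh := bh_adjust(p)]
  dt[, p_stagewise := NA_real_]

  genes <- dt[, .(n_tx = .N, p_simes = simes(p)), by = gene_id]
  genes[, p_bh := bh_adjust(p_simes)]
  genes[, screened := NA]
  structure(list(transcripts = dt[, .(transcript_id, gene_id, logFC,
                                      relative_logFC, t, df, p, p_bh,
                                      p_stagewise)],
                 genes = genes), class = "nanoiso_dtu")
}

#' @export
print.nanoiso_dtu <- function(x, ...) {
  cat("nanoiso DTU result:", nrow(x$transcripts), "transcripts in",
      nrow(x$genes), "genes\n")
  invisible(x)
}

#' Stage-wise screening and confirmation
#'
#' Stage 1 screens genes by BH-adjusted Simes p-value at level `alpha`.
#' Stage 2 Holm-adjusts the transcript p-values within each screened gene
#' and scales them by `G/R` (tested genes over screened genes), capped at
#' 1, which controls the overall FDR across the two stages. Transcripts of
#' unscreened genes receive a stage-wise p-value of 1.
#'
#' @param result a `nanoiso_dtu` from [dtu_test()].
#' @param cfg a [dtu_config()].
#' @return the `nanoiso_dtu` with `p_stagewise` and `screened` filled in.
#' @export
stagewise <- function(result, cfg = dtu_config()) {
  genes <- data.table::copy(result$genes)
  tx <- data.table::copy(result$transcripts)
  genes[, screened := p_bh <= cfg$alpha]
  G <- nrow(genes); R <- sum(genes$screened)
  tx[, p_stagewise := 1]
  if (R > 0L) {
    sg <- genes$gene_id[genes$screened]
    tx[gene_id %in% sg,
       p_stagewise := pmin(1, stats::p.adjust(p, method = "holm") * G / R),
       by = gene_id]
  }
  structure(list(transcripts = tx, genes = genes), class = "nanoiso_dtu")
}

#' Evaluate DTU calls against ground truth
#'
#' Compares significance calls (adjusted p-value at or below `alpha`) with
#' truth labels at the gene and transcript level, for BH and stage-wise
#' adjustment. FDR uses a guarded denominator (0 when nothing is called).
#'
#' @param result a `nanoiso_dtu` after [stagewise()].
#' @param truth list with data.frames `genes` (gene_id, dtu) and
#'   `transcripts` (transcript_id, dtu); must cover every tested id.
#' @param cfg a [dtu_config()].
#' @return data.table (level, adjustment, TP, FP, FN, FDR, TPR).
#' @export
evaluate_dtu <- function(result, truth, cfg = dtu_config()) {
  tg <- data.table::as.data.table(truth$genes)
  tt <- data.table::as.data.table(truth$transcripts)
  miss_g <- setdiff(result$genes$gene_id, tg$gene_id)
  miss_t <- setdiff(result$transcripts$transcript_id, tt$transcript_id)
  if (length(miss_g) || length(miss_t)) {
    stop("ids missing from truth: ",
         paste(utils::head(c(miss_g, miss_t), 10), collapse = ", "))
  }
  gm <- stats::setNames(tg$dtu, tg$gene_id)
  tm <- stats::setNames(tt$dtu, tt$transcript_id)

  one <- function(level, adjustment, called, labels) {
    tp <- sum(called & labels); fp <- sum(called & !labels)
    fn <- sum(!called & labels)
    data.table::data.table(level = level, adjustment = adjustment,
                           TP = tp, FP = fp, FN = fn,
                           FDR = fp / max(1L, tp + fp),
                           TPR = if (tp + fn > 0L) tp / (tp + fn) else NA_real_)
  }
  g_lab <- as.logical(gm[result$genes$gene_id])
  t_lab <- as.logical(tm[result$transcripts$transcript_id])
  scr <- result$genes$screened
  if (all(is.na(scr))) scr <- result$genes$p_bh <= cfg$alpha
  data.table::rbindlist(list(
    one("gene", "BH", result$genes$p_bh <= cfg$alpha, g_lab),
    one("gene", "stagewise", scr, g_lab),
    one("transcript", "BH", result$transcripts$p_bh <= cfg$alpha, t_lab),
    one("transcript", "stagewise",
        !is.na(result$transcripts$p_stagewise) &
          result$transcripts$p_stagewise <= cfg$alpha, t_lab)))
}
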