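# Per-timepoint disease-vs-control differential expression on gene-level
# counts: low-count filtering, median-of-ratios normalization, and a
# self-contained negative-binomial Wald test with moderated dispersion.

#' Construct a counts table
#'
#' Bundles an integer gene-by-sample count matrix with its sample metadata.
#'
#' @param counts numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); entries must be nonnegative integers.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"disease"` or `"control"`), `timepoint`, `replicate`; must cover all
#'   count columns.
#' @return object of class `counts_table` (list with `counts`, `samples`).
#' @export
counts_table <- function(counts, samples) {
  if (!is.matrix(counts)) stop_input("'counts' must be a matrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop_input("duplicate or missing gene ids in counts")
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop_input("duplicate or missing sample ids in counts")
  }
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_input("counts must be nonnegative integers; offending entry at gene '",
               rownames(counts)[bad[1, 1]], "', sample '", colnames(counts)[bad[1, 2]], "'")
  }
  req <- c("sample_id", "condition", "timepoint", "replicate")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    stop_input("'samples' must be a data.frame with columns ", paste(req, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss)) stop_input("sample(s) in counts missing from sample sheet: ", paste(miss, collapse = ", "))
  if (!all(samples$condition %in% c("disease", "control"))) {
    stop_input("condition must be 'disease' or 'control'")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), req, drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat("counts table:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      "timepoints:", paste(sort(unique(x$samples$timepoint)), collapse = ", "), "\n")
  invisible(x)
}

smallest_group_size <- function(samples) {
  min(table(paste(samples$condition, samples$timepoint)))
}

#' Remove marginally expressed genes
#'
#' Keeps a gene when the number of samples with raw count at least
#' `min_count` is at least `min_samples` (default: the smallest
#' condition-by-timepoint group size). The sample set is unchanged.
#'
#' @param x a [counts_table()].
#' @param min_count raw-count threshold (default 10 reads before
#'   normalization).
#' @param min_samples minimum number of samples meeting `min_count`;
#'   defaults to the smallest experimental group size.
#' @return filtered `counts_table` (possibly with zero genes).
#' @export
filter_low_counts <- function(x, min_count = 10, min_samples = NULL) {
  stopifnot(inherits(x, "counts_table"))
  min_samples <- min_samples %||% smallest_group_size(x$samples)
  if (min_samples > ncol(x$counts)) stop_input("'min_samples' exceeds the number of samples")
  keep <- rowSums(x$counts >= min_count) >= min_samples
  counts_table(x$counts[keep, , drop = FALSE], x$samples)
}

# Median-of-ratios size factors (geometric-mean reference over genes with
# all-positive counts); falls back to library-total scaling when no gene
# qualifies.
size_factors <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (any(pos)) {
    logref <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(col) {
      exp(stats::median(log(col) - logref))
    })
  } else {
    tot <- colSums(counts)
    if (all(tot == 0)) return(setNames(rep(1, ncol(counts)), colnames(counts)))
    sf <- tot / exp(mean(log(tot[tot > 0])))
    sf[sf == 0] <- 1
  }
  sf / exp(mean(log(sf)))
}

#' Per-timepoint negative-binomial Wald test
#'
#' Compares disease vs control at one timepoint on a filtered counts table.
#' Counts are normalized by median-of-ratios size factors computed within
#' the comparison; per-gene dispersion is estimated by method of moments
#' (pooled within groups) and shrunk toward the genewise trend mean; the
#' log2 fold change (disease over control) is tested with a Wald statistic
#' using the delta-method standard error of the log mean ratio. Raw
#' p-values are Benjamini-Hochberg adjusted across all genes tested at the
#' timepoint. A gene is called `induced` when `fdr < alpha` and
#' `log2fc >= lfc_min`, `repressed` when `fdr < alpha` and
#' `log2fc <= -lfc_min`, otherwise `ns`.
#'
#' @param x a filtered [counts_table()].
#' @param timepoint the timepoint to test (must have both conditions with at
#'   least 2 replicates each).
#' @param alpha FDR threshold for calls (default 0.01).
#' @param lfc_min minimum absolute log2 fold change for calls (default 1,
#'   i.e. two-fold).
#' @param prior_df prior degrees of freedom pulling the genewise dispersion
#'   toward the trend mean (default 6).
#' @return data.frame (a DE table): `gene`, `timepoint`, `log2fc`, `p`,
#'   `fdr`, `call`.
#' @export
test_differential <- function(x, timepoint, alpha = 0.01, lfc_min = 1, prior_df = 6) {
  stopifnot(inherits(x, "counts_table"))
  sel <- x$samples$timepoint == timepoint
  if (!any(sel)) stop_input("no samples at timepoint ", timepoint)
  smp <- x$samples[sel, , drop = FALSE]
  cts <- x$counts[, sel, drop = FALSE]
  n_d <- sum(smp$condition == "disease")
  n_c <- sum(smp$condition == "control")
  if (n_d < 2 || n_c < 2) {
    stop_input("both conditions need >= 2 replicates at timepoint ", timepoint)
  }
  genes <- rownames(cts)
  if (!length(genes)) {
    return(data.frame(gene = character(0), timepoint = timepoint[0],
                      log2fc = numeric(0), p = numeric(0), fdr = numeric(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  sf <- size_factors(cts)
  y <- sweep(cts, 2, sf, "/")
  yd <- y[, smp$condition == "disease", drop = FALSE]
  yc <- y[, smp$condition == "control", drop = FALSE]
  mu_d <- rowMeans(yd)
  mu_c <- rowMeans(yc)
  var_d <- apply(yd, 1, var)
  var_c <- apply(yc, 1, var)

  # method-of-moments dispersion, pooled across the two groups, floored at 0
  mom <- function(m, v) ifelse(m > 0, pmax((v - m) / m^2, 0), 0)
  df_d <- n_d - 1; df_c <- n_c - 1
  phi_gene <- (df_d * mom(mu_d, var_d) + df_c * mom(mu_c, var_c)) / (df_d + df_c)
  phi_trend <- mean(phi_gene[mu_d + mu_c > 0])
  if (!is.finite(phi_trend)) phi_trend <- 0
  df_tot <- df_d + df_c
  phi <- pmax((df_tot * phi_gene + prior_df * phi_trend) / (df_tot + prior_df), 1e-8)

  # 0.5 pseudo-count on fitted means only when a group mean is zero
  zero <- mu_d == 0 | mu_c == 0
  md <- ifelse(zero, mu_d + 0.5, mu_d)
  mc <- ifelse(zero, mu_c + 0.5, mu_c)
  log2fc <- log2(md / mc)
  v_log_d <- (1 / md + phi) / n_d
  v_log_c <- (1 / mc + phi) / n_c
  se <- sqrt(v_log_d + v_log_c) / log(2)
  z <- ifelse(log2fc == 0, 0, log2fc / se)
  p <- 2 * pnorm(-abs(z))
  fdr <- adjust_bh(p)
  call <- ifelse(fdr < alpha & log2fc >= lfc_min, "induced",
                 ifelse(fdr < alpha & log2fc <= -lfc_min, "repressed", "ns"))
  data.frame(gene = genes, timepoint = timepoint, log2fc = log2fc, p = p,
             fdr = fdr, call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clipped to `[0, 1]`, input order preserved.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Apply calls to an externally produced DE table
#'
#' Accepts per-timepoint DE results computed elsewhere (e.g. edgeR or limma;
#' columns `gene`, `log2fc`, `p`, `fdr`) and adds/overwrites the
#' induced/repressed/ns call under the standard thresholds, so external
#' tables can replace [test_differential()] in the pipeline.
#'
#' @param de data.frame with columns `gene`, `log2fc`, `p`, `fdr` and
#'   optionally `timepoint`.
#' @param timepoint timepoint label attached to the table when absent.
#' @inheritParams test_differential
#' @return DE table with a `call` column.
#' @export
call_de_table <- function(de, timepoint = NULL, alpha = 0.01, lfc_min = 1) {
  req <- c("gene", "log2fc", "p", "fdr")
  if (!is.data.frame(de) || !all(req %in% names(de))) {
    stop_input("DE table needs columns ", paste(req, collapse = ", "))
  }
  if (any(de$fdr < de$p - 1e-12, na.rm = TRUE)) {
    stop_input("'fdr' must be >= 'p' for every gene")
  }
  if (!"timepoint" %in% names(de)) {
    if (is.null(timepoint)) stop_input("supply 'timepoint' when the table lacks one")
    de$timepoint <- timepoint
  }
  de$call <- ifelse(de$fdr < alpha & de$log2fc >= lfc_min, "induced",
                    ifelse(de$fdr < alpha & de$log2fc <= -lfc_min, "repressed", "ns"))
  de[, c("gene", "timepoint", "log2fc", "p", "fdr", "call")]
}
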