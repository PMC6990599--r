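# Minimal self-contained differential-expression stage for time-course
# counts: low-count filtering, median-of-ratios normalization, a
# negative-binomial Wald test per time point vs time 0, and BH adjustment.
# This is a documented stand-in: downstream logic depends only on
# (log2FC, FDR) tables, which may equally be supplied via read_deg_table().

#' Remove genes with low average counts across a time course
#'
#' Genes whose mean raw count across all samples of the treatment time
#' course (time 0 included) is at or below \code{threshold} are removed
#' before testing; the threshold is inclusive ("an average of 20 reads or
#' less").
#'
#' @param x `pr_counts` for a single condition's time course.
#' @param threshold inclusive mean-count cutoff (default 20).
#' @return Filtered `pr_counts`; removed gene ids in attribute
#'   \code{"removed"}.
#' @export
filter_low_counts <- function(x, threshold = 20) {
  if (nrow(x$counts) == 0) stop("empty count matrix")
  keep <- rowMeans(x$counts) > threshold
  out <- count_matrix(x$counts[keep, , drop = FALSE], x$meta)
  attr(out, "removed") <- rownames(x$counts)[!keep]
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: the reference is the gene-wise
#' geometric mean over genes positive in all samples; each sample's factor
#' is the median of its counts over that reference.
#'
#' @param x `pr_counts` or a numeric counts matrix.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "pr_counts")) x$counts else x
  if (ncol(m) == 1) return(stats::setNames(1, colnames(m)))
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no gene positive in all samples; cannot normalize")
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  apply(m[pos, , drop = FALSE], 2, function(col) stats::median(col / ref))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; the mapping is
#' order-preserving with respect to input positions.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' DEG status from fold change and FDR
#'
#' \code{up} iff \code{log2FC > lfc_threshold} and
#' \code{fdr <= fdr_threshold}; \code{down} symmetric with
#' \code{log2FC < -lfc_threshold}; otherwise \code{ns}. The fold-change
#' inequality is strict, the FDR one inclusive, so (1.0, 0.001) is
#' \code{ns} and (-1.2, 0.05) is \code{down}.
#'
#' @param log2FC,fdr numeric vectors (recycled to common length).
#' @param lfc_threshold,fdr_threshold thresholds (defaults 1 and 0.05).
#' @return Character vector in \code{c("up", "down", "ns")}.
#' @export
call_deg_status <- function(log2FC, fdr, lfc_threshold = 1, fdr_threshold = 0.05) {
  if (any(!is.finite(log2FC)) || any(!is.finite(fdr)))
    stop("log2FC and fdr must be finite")
  ifelse(fdr <= fdr_threshold & log2FC > lfc_threshold, "up",
         ifelse(fdr <= fdr_threshold & log2FC < -lfc_threshold, "down", "ns"))
}

# Method-of-moments NB dispersion per gene, from normalized counts of the
# two groups, shrunk toward a mean-dispersion trend alpha(mu) = a0 + a1/mu
# fitted across genes. Returns the shrunk per-gene dispersions.
estimate_dispersion <- function(norm0, norm1, floor = 1e-8, shrink = 0.5) {
  mu0 <- rowMeans(norm0); mu1 <- rowMeans(norm1)
  # pooled within-group variance
  ss <- (norm0 - mu0)^2 %*% rep(1, ncol(norm0)) +
        (norm1 - mu1)^2 %*% rep(1, ncol(norm1))
  df <- ncol(norm0) + ncol(norm1) - 2
  v <- as.numeric(ss) / df
  mu <- (mu0 * ncol(norm0) + mu1 * ncol(norm1)) / (ncol(norm0) + ncol(norm1))
  raw <- pmax((v - mu) / mu^2, floor)
  # gamma-style trend: alpha ~ a0 + a1/mu, fitted by least squares on the
  # genes with informative raw estimates
  use <- raw > floor & mu > 0
  trend <- rep(stats::median(raw), length(raw))
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
    co <- stats::coef(fit)
    trend <- pmax(co[1] + co[2] / mu, floor)
  }
  pmax(exp((1 - shrink) * log(raw) + shrink * log(trend)), floor)
}

#' Negative-binomial Wald test of one time point against time 0
#'
#' For every gene, counts are normalized by median-of-ratios size factors
#' (computed over the whole time course), a method-of-moments dispersion is
#' estimated and shrunk toward a fitted mean-dispersion trend, and a Wald
#' test is performed on the log2 fold change of the target time point vs
#' time 0. P-values are BH-adjusted across all genes of the contrast.
#'
#' @param x filtered `pr_counts` for one condition.
#' @param timepoint target time point (must have >= 2 replicates, as must
#'   time 0).
#' @param sf optional precomputed size factors (named by sample).
#' @param prior_count pseudo-count added to both group means before the
#'   log ratio (stabilizes low-count fold changes; default 0.5).
#' @param dispersion_floor,dispersion_shrink numerical guards for the
#'   dispersion estimate.
#' @return data.frame: \code{gene_id}, \code{timepoint}, \code{log2FC},
#'   \code{p}, \code{fdr}.
#' @export
test_contrast <- function(x, timepoint, sf = NULL, prior_count = 0.5,
                          dispersion_floor = 1e-8, dispersion_shrink = 0.5) {
  meta <- x$meta
  i0 <- which(meta$timepoint == 0)
  i1 <- which(meta$timepoint == timepoint)
  if (length(i0) < 2 || length(i1) < 2)
    stop("need >= 2 replicates at time 0 and at the target time point")
  if (is.null(sf)) sf <- size_factors(x)
  sf <- sf[colnames(x$counts)]
  norm <- sweep(x$counts, 2, sf, "/")
  n0 <- norm[, i0, drop = FALSE]; n1 <- norm[, i1, drop = FALSE]
  mu0 <- rowMeans(n0); mu1 <- rowMeans(n1)
  alpha <- estimate_dispersion(n0, n1, dispersion_floor, dispersion_shrink)
  lfc <- log2((mu1 + prior_count) / (mu0 + prior_count))
  # delta-method variance of log2(mean + prior): Var(mean of K/sf) =
  # (1/n^2) sum_j (mu/sf_j + alpha mu^2)
  v_mean <- function(mu, idx) {
    (mu * sum(1 / sf[idx]) + alpha * mu^2 * length(idx)) / length(idx)^2
  }
  se2 <- (v_mean(mu0, i0) / (mu0 + prior_count)^2 +
          v_mean(mu1, i1) / (mu1 + prior_count)^2) / log(2)^2
  z <- lfc / sqrt(pmax(se2, 1e-300))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene_id = rownames(x$counts), timepoint = timepoint,
             log2FC = lfc, p = p, fdr = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Call DEGs for every post-reference time point of a condition
#'
#' Runs the full stage: low-count filter, normalization, per-time-point NB
#' Wald contrasts vs time 0, BH adjustment per contrast (the per-time-point
#' DEG lists of time-course supplementary tables), and thresholding into
#' up/down/ns.
#'
#' @inheritParams test_contrast
#' @param count_threshold low-count filter cutoff (inclusive, default 20).
#' @param lfc_threshold,fdr_threshold DEG thresholds.
#' @param pool_fdr if \code{TRUE}, BH is applied once across all time
#'   points of the condition instead of per contrast.
#' @return `pr_degs` data.frame covering every tested gene x time point.
#' @export
call_degs <- function(x, count_threshold = 20, lfc_threshold = 1,
                      fdr_threshold = 0.05, pool_fdr = FALSE, ...) {
  cond <- unique(x$meta$condition)
  if (length(cond) != 1)
    stop("call_degs expects a single condition's time course; got: ",
         paste(cond, collapse = ", "))
  xf <- filter_low_counts(x, count_threshold)
  sf <- size_factors(xf)
  tps <- sort(setdiff(unique(xf$meta$timepoint), 0))
  res <- do.call(rbind, lapply(tps, function(tp)
    test_contrast(xf, tp, sf = sf, ...)))
  if (pool_fdr) res$fdr <- bh_adjust(res$p)
  out <- deg_table(gene_id = res$gene_id, condition = cond,
                   timepoint = res$timepoint, log2FC = res$log2FC,
                   fdr = res$fdr, lfc_threshold = lfc_threshold,
                   fdr_threshold = fdr_threshold)
  attr(out, "removed") <- attr(xf, "removed")
  out
}

#' log2 fold change from FPKM values
#'
#' \code{log2((treated + pseudocount) / (mock + pseudocount))}, used for
#' external datasets distributed as FPKM rather than counts. The default
#' pseudocount is 0, in which case a zero mock value is an error.
#'
#' @param fpkm_treated,fpkm_mock non-negative expression values.
#' @param pseudocount added to both before the ratio (default 0).
#' @return numeric log2 fold changes.
#' @export
fpkm_log2fc <- function(fpkm_treated, fpkm_mock, pseudocount = 0) {
  if (any(fpkm_treated < 0) || any(fpkm_mock < 0)) stop("FPKM must be >= 0")
  if (pseudocount == 0 && any(fpkm_mock == 0))
    stop("mock FPKM of 0 with pseudocount 0")
  log2((fpkm_treated + pseudocount) / (fpkm_mock + pseudocount))
}
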