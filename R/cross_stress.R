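# Consolidation of time-course DEG tables into per-stress profiles,
# family attribution, and outlier-robust Pearson correlation between
# stresses with qualitative strength labels.

#' Consolidate a stress's DEG table into a per-gene profile
#'
#' For each gene, the mean log2FC over the time points at which it was a
#' DEG (\code{status != "ns"}); genes never a DEG are absent.
#'
#' @param degs `pr_degs` for one stress.
#' @param stress stress label (default: the table's condition).
#' @return data.frame of class \code{pr_profile}: \code{gene_id},
#'   \code{stress}, \code{mean_log2FC}, \code{n_timepoints}.
#' @export
consolidate_profile <- function(degs, stress = unique(degs$condition)) {
  if (length(stress) != 1) stop("profile must cover a single stress")
  d <- degs[degs$status != "ns", , drop = FALSE]
  if (!nrow(d)) {
    out <- data.frame(gene_id = character(0), stress = character(0),
                      mean_log2FC = numeric(0), n_timepoints = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    sp <- split(d$log2FC, d$gene_id)
    out <- data.frame(gene_id = names(sp), stress = stress,
                      mean_log2FC = vapply(sp, mean, numeric(1)),
                      n_timepoints = vapply(sp, length, integer(1)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  class(out) <- c("pr_profile", "data.frame")
  out
}

#' Boxplot-rule outliers
#'
#' Flags values outside \eqn{[Q_1 - k \cdot IQR,\; Q_3 + k \cdot IQR]}
#' with quartiles by linear interpolation (R's default type-7 convention)
#' and multiplicative constant \code{k = 2} by default.
#'
#' @param values numeric vector, length >= 4.
#' @param k IQR multiplier.
#' @return integer indices of flagged values.
#' @export
boxplot_outliers <- function(values, k = 2.0) {
  if (length(values) < 4) stop("need at least 4 values for the boxplot rule")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  which(values < q[1] - k * iqr | values > q[2] + k * iqr)
}

#' Evans qualitative strength label for a correlation
#'
#' Bands on \code{|R|}: 0.00-0.19 very weak, 0.20-0.39 weak, 0.40-0.59
#' moderate, 0.60-0.79 strong, 0.80-1.00 very strong.
#'
#' @param R Pearson coefficient in \[-1, 1\].
#' @return character label.
#' @export
evans_label <- function(R) {
  if (abs(R) > 1) stop("|R| > 1")
  a <- abs(R)
  if (a < 0.20) "very weak"
  else if (a < 0.40) "weak"
  else if (a < 0.60) "moderate"
  else if (a < 0.80) "strong"
  else "very strong"
}

#' Correlate two stress profiles with single-pass outlier removal
#'
#' Gene pairs are formed over the intersection of the two profiles. When
#' fewer than \code{min_shared} genes are shared the comparison is skipped
#' (a result with a reason, not an error). Otherwise boxplot-rule outliers
#' are flagged on each coordinate separately, the union removed exactly
#' once, and a two-sided Pearson test run on the survivors.
#'
#' @param a,b `pr_profile` objects.
#' @param min_shared minimum shared DEGs for a correlation (default 10).
#' @param k IQR multiplier for the outlier rule (default 2).
#' @param remove_outliers set \code{FALSE} for comparisons where the
#'   protocol applies no outlier removal.
#' @return list: \code{stress_a}, \code{stress_b}, \code{skipped},
#'   \code{reason}, \code{n_shared}, \code{n_used}, \code{outliers}
#'   (gene ids), \code{R}, \code{p}, \code{strength}.
#' @export
correlate_stresses <- function(a, b, min_shared = 10, k = 2.0,
                               remove_outliers = TRUE) {
  shared <- intersect(a$gene_id, b$gene_id)
  base <- list(stress_a = unique(a$stress), stress_b = unique(b$stress),
               n_shared = length(shared))
  if (length(shared) < min_shared) {
    return(c(base, list(skipped = TRUE,
                        reason = sprintf("fewer than %d shared DEGs", min_shared),
                        n_used = NA_integer_, outliers = character(0),
                        R = NA_real_, p = NA_real_, strength = NA_character_)))
  }
  x <- a$mean_log2FC[match(shared, a$gene_id)]
  y <- b$mean_log2FC[match(shared, b$gene_id)]
  out_idx <- integer(0)
  if (remove_outliers) {
    out_idx <- sort(union(boxplot_outliers(x, k), boxplot_outliers(y, k)))
  }
  keep <- setdiff(seq_along(shared), out_idx)
  xs <- x[keep]; ys <- y[keep]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) stop("zero variance after outlier removal")
  ct <- stats::cor.test(xs, ys, method = "pearson")
  c(base, list(skipped = FALSE, reason = NA_character_,
               n_used = length(keep), outliers = shared[out_idx],
               R = unname(ct$estimate), p = ct$p.value,
               strength = evans_label(unname(ct$estimate))))
}

#' Attribute each stress's DEGs to gene families
#'
#' Per stress, the percent of its DEGs falling in each family (rounded to
#' the nearest integer, so columns sum to 100 up to rounding); per family,
#' the percent of members responsive to at least one stress.
#'
#' @param profiles named list of `pr_profile` objects (one per stress).
#' @param catalog `pr_catalog` covering every profile gene.
#' @return list with \code{per_stress_pct} (families x stresses matrix),
#'   \code{n_degs} (named vector per stress) and \code{per_family}
#'   (family, n_genes, n_responsive, pct).
#' @export
family_attribution <- function(profiles, catalog) {
  all_genes <- unique(unlist(lapply(profiles, `[[`, "gene_id")))
  miss <- setdiff(all_genes, catalog$gene_id)
  if (length(miss)) stop("gene(s) absent from catalog: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  fams <- sort(unique(catalog$family))
  stresses <- names(profiles)
  pct <- matrix(0, length(fams), length(stresses),
                dimnames = list(fams, stresses))
  n_degs <- stats::setNames(integer(length(stresses)), stresses)
  for (s in stresses) {
    g <- profiles[[s]]$gene_id
    n_degs[s] <- length(g)
    f <- catalog$family[match(g, catalog$gene_id)]
    if (length(g)) {
      pct[, s] <- round_half_up(100 * table(factor(f, levels = fams)) / length(g))
    }
  }
  responsive <- unique(unlist(lapply(profiles, `[[`, "gene_id")))
  per_family <- data.frame(
    family = fams,
    n_genes = vapply(fams, function(f) sum(catalog$family == f), integer(1)),
    n_responsive = vapply(fams, function(f)
      sum(catalog$gene_id[catalog$family == f] %in% responsive), integer(1)),
    stringsAsFactors = FALSE)
  per_family$pct <- round_half_up(100 * per_family$n_responsive /
                                    pmax(per_family$n_genes, 1))
  list(per_stress_pct = pct, n_degs = n_degs, per_family = per_family)
}
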