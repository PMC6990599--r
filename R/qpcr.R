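# Comparative-Ct qPCR fold changes and qPCR-vs-sequencing concordance.

#' Fold change by the comparative Ct method
#'
#' Per sample, \eqn{\Delta Ct = Ct_{gene} - Ct_{reference}}; per gene,
#' \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_{treated} -
#' \overline{\Delta Ct}_{control}} (averaged over biological replicates
#' before exponentiation), fold change \eqn{2^{-\Delta\Delta Ct}} and
#' \code{log2FC = -ddCt} identically. The standard error is propagated
#' across replicates as
#' \eqn{\sqrt{SE_{treated}^2 + SE_{control}^2}} on the
#' \eqn{\Delta Ct} scale.
#'
#' @param ct data.frame with columns \code{gene}, \code{sample},
#'   \code{condition}, \code{Ct}.
#' @param ref_gene reference (housekeeping) gene id, measured in every
#'   sample. A character vector of several reference genes is averaged
#'   per sample (geometric mean on the expression scale, i.e. arithmetic
#'   mean of Ct values).
#' @param treated_condition,control_condition condition labels.
#' @return data.frame: \code{gene}, \code{ddCt}, \code{fold},
#'   \code{log2FC}, \code{se}.
#' @export
delta_delta_ct <- function(ct, ref_gene, treated_condition, control_condition) {
  need <- c("gene", "sample", "condition", "Ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  if (any(ct$Ct <= 0)) stop("Ct values must be positive")
  for (cond in c(treated_condition, control_condition)) {
    if (!cond %in% ct$condition) stop("condition absent from Ct table: ", cond)
  }
  ref <- ct[ct$gene %in% ref_gene, , drop = FALSE]
  ref_ct <- tapply(ref$Ct, ref$sample, mean)
  if (any(!ct$sample %in% names(ref_ct)))
    stop("sample(s) lacking a reference measurement: ",
         paste(setdiff(unique(ct$sample), names(ref_ct)), collapse = ", "))
  d <- ct[!ct$gene %in% ref_gene, , drop = FALSE]
  d$dct <- d$Ct - ref_ct[d$sample]
  res <- lapply(split(d, d$gene), function(g) {
    tr <- g$dct[g$condition == treated_condition]
    co <- g$dct[g$condition == control_condition]
    if (!length(tr) || !length(co))
      stop("gene ", g$gene[1], " missing a condition")
    se <- sqrt(stats::var(tr) / length(tr) + stats::var(co) / length(co))
    ddct <- mean(tr) - mean(co)
    data.frame(gene = g$gene[1], ddCt = ddct, fold = 2^(-ddct),
               log2FC = -ddct, se = se, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' qPCR vs sequencing concordance
#'
#' Pearson correlation between paired platform log2 fold changes; no
#' outlier removal is applied for this comparison.
#'
#' @param qpcr_log2fc,seq_log2fc paired numeric vectors (>= 3 pairs).
#' @return list: \code{R}, \code{p}, \code{n}, \code{strength}.
#' @export
platform_concordance <- function(qpcr_log2fc, seq_log2fc) {
  if (length(qpcr_log2fc) != length(seq_log2fc)) stop("length mismatch")
  if (length(qpcr_log2fc) < 3) stop("need at least 3 paired measurements")
  if (stats::sd(qpcr_log2fc) == 0 || stats::sd(seq_log2fc) == 0)
    stop("zero variance")
  ct <- stats::cor.test(qpcr_log2fc, seq_log2fc, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(qpcr_log2fc),
       strength = evans_label(unname(ct$estimate)))
}
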