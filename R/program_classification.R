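# Classification of genes into temporal expression programs, 16
# cross-genotype trend clusters, and SA/JA hormone programs, plus the
# summary tallies and the co-regulation correlation.

#' Temporal expression program of one gene
#'
#' Programs over the four post-infestation time points: \code{early} when
#' the gene is a DEG at 1 and/or 7 dpi only, \code{late} at 14 and/or 22
#' dpi only, \code{sustained} when DEG in both windows, \code{none}
#' otherwise.
#'
#' @param statuses named character vector of DEG statuses
#'   (\code{up}/\code{down}/\code{ns}) with names covering the time points.
#' @param log2FC optional named log2FC vector (same names); used to record
#'   the gene's direction as the sign of the mean log2FC over its DEG time
#'   points.
#' @param early_window,late_window time points defining the windows.
#' @return list with \code{program} and \code{direction} (+1/-1/0).
#' @export
temporal_program <- function(statuses, log2FC = NULL,
                             early_window = c(1, 7), late_window = c(14, 22)) {
  need <- as.character(c(early_window, late_window))
  miss <- setdiff(need, names(statuses))
  if (length(miss)) stop("missing time point(s): ", paste(miss, collapse = ", "))
  deg <- statuses[need] != "ns"
  e <- any(deg[as.character(early_window)])
  l <- any(deg[as.character(late_window)])
  program <- if (e && l) "sustained" else if (e) "early" else if (l) "late" else "none"
  direction <- 0
  if (!is.null(log2FC) && program != "none") {
    direction <- sign(mean(log2FC[need][deg]))
  }
  list(program = program, direction = direction)
}

#' Cross-genotype trend cluster from four trend signs
#'
#' Each DEG receives one of 16 cluster ids encoding the sign of its
#' expression trend in each of the four genotypes. The id is determined
#' bijectively by the sign pattern: the all-positive pattern is cluster 1,
#' the all-negative pattern is cluster 9. Concretely, with
#' \eqn{b_1 = 1} when genotype 1 trends negative and \eqn{c_i = 1}
#' (\eqn{i = 2, 3, 4}) when genotype \eqn{i} disagrees with genotype 1,
#' the id is \eqn{1 + 8 b_1 + 4 c_2 + 2 c_3 + c_4}: clusters 1-8 share a
#' positive genotype-1 trend and 9-16 a negative one, ordered by the
#' pattern of disagreement.
#'
#' @param trends numeric vector of 4 per-genotype trend values (sign of
#'   the mean log2FC across that genotype's post-reference time course).
#' @param last_signs optional vector of the signs at the last time point,
#'   used to break exact-zero trends; an overall exact zero falls back to
#'   negative (logged via a message).
#' @return integer cluster id in 1..16.
#' @export
trend_cluster <- function(trends, last_signs = NULL) {
  if (length(trends) != 4) stop("expected trends for exactly 4 genotypes")
  s <- sign(trends)
  for (i in which(s == 0)) {
    if (!is.null(last_signs) && sign(last_signs[i]) != 0) {
      s[i] <- sign(last_signs[i])
    } else {
      message("zero trend in genotype ", i, "; resolved to negative")
      s[i] <- -1
    }
  }
  b1 <- as.integer(s[1] < 0)
  c234 <- as.integer(s[2:4] != s[1])
  1L + 8L * b1 + 4L * c234[1] + 2L * c234[2] + c234[3]
}

# per-hormone direction: sign of the log2FC with largest magnitude among
# DEG time points (ties broken toward the earlier time point)
hormone_direction <- function(statuses, log2FC) {
  deg <- statuses != "ns"
  if (!any(deg)) return(0)
  v <- log2FC[deg]
  sign(v[which.max(abs(v))])
}

#' Hormone expression program of one gene
#'
#' From its DEG statuses over the SA and JA time grids a gene is
#' \code{co_regulated} when DEG under both hormones in the same direction,
#' \code{reciprocal} when DEG under both in opposite directions,
#' \code{sa_only}/\code{ja_only} when DEG under exactly one, and
#' \code{none} otherwise. The direction per hormone is the sign of the
#' largest-magnitude log2FC among that hormone's DEG time points.
#'
#' @param sa_status,ja_status DEG status vectors over each hormone's time
#'   grid.
#' @param sa_log2FC,ja_log2FC matching log2FC vectors.
#' @return list with \code{program}, \code{sa_direction},
#'   \code{ja_direction}.
#' @export
hormone_program <- function(sa_status, sa_log2FC, ja_status, ja_log2FC) {
  ds <- hormone_direction(sa_status, sa_log2FC)
  dj <- hormone_direction(ja_status, ja_log2FC)
  program <- if (ds != 0 && dj != 0) {
    if (ds == dj) "co_regulated" else "reciprocal"
  } else if (ds != 0) "sa_only" else if (dj != 0) "ja_only" else "none"
  list(program = program, sa_direction = ds, ja_direction = dj)
}

#' Classify every gene of a DEG table set
#'
#' Convenience driver: computes per-gene temporal program and direction per
#' condition, the cross-genotype trend cluster (for genes that are DEGs in
#' at least one genotype), and -- when hormone DEG tables are supplied --
#' the hormone program.
#'
#' @param degs `pr_degs` covering one or more genotype conditions over the
#'   infestation time course.
#' @param sa,ja optional `pr_degs` for the two hormone treatments.
#' @param genotypes condition labels to use (default: all in \code{degs},
#'   in first-appearance order).
#' @return data.frame with one row per gene: temporal program/direction
#'   per genotype, trend cluster, hormone program and directions.
#' @export
classify_programs <- function(degs = NULL, sa = NULL, ja = NULL,
                              genotypes = unique(degs$condition)) {
  genes <- unique(c(degs$gene_id, sa$gene_id, ja$gene_id))
  res <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  trend_mat <- matrix(NA_real_, length(genes), length(genotypes),
                      dimnames = list(genes, genotypes))
  last_mat <- trend_mat
  any_deg <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (g in genotypes) {
    d <- degs[degs$condition == g, ]
    tps <- sort(unique(d$timepoint))
    prog <- dir <- rep(NA_character_, length(genes))
    rows_of <- split(seq_len(nrow(d)), d$gene_id)
    for (i in seq_along(genes)) {
      ri <- rows_of[[genes[i]]]
      if (is.null(ri)) next  # gene filtered out in this genotype
      di <- d[ri, ]
      st <- stats::setNames(di$status, di$timepoint)
      lf <- stats::setNames(di$log2FC, di$timepoint)
      tp <- temporal_program(st, lf)
      prog[i] <- tp$program
      dir[i] <- c("-1" = "down", "0" = "none", "1" = "up")[as.character(tp$direction)]
      trend_mat[i, g] <- mean(lf)
      last_mat[i, g] <- lf[as.character(max(tps))]
      if (tp$program != "none") any_deg[i] <- TRUE
    }
    res[[paste0("program_", g)]] <- prog
    res[[paste0("direction_", g)]] <- dir
  }
  res$trend_cluster <- rep(NA_integer_, nrow(res))
  if (length(genotypes) == 4) {
    for (i in seq_along(genes)) {
      if (any_deg[i] && !anyNA(trend_mat[i, ])) {
        res$trend_cluster[i] <- suppressMessages(
          trend_cluster(trend_mat[i, ], last_mat[i, ]))
      }
    }
  }
  if (!is.null(sa) && !is.null(ja)) {
    res$hormone_program <- rep("none", nrow(res))
    res$sa_direction <- rep(0, nrow(res)); res$ja_direction <- rep(0, nrow(res))
    sa_rows <- split(seq_len(nrow(sa)), sa$gene_id)
    ja_rows <- split(seq_len(nrow(ja)), ja$gene_id)
    for (i in seq_along(genes)) {
      si <- sa[sa_rows[[genes[i]]], ]
      ji <- ja[ja_rows[[genes[i]]], ]
      hp <- hormone_program(si$status, si$log2FC, ji$status, ji$log2FC)
      res$hormone_program[i] <- hp$program
      res$sa_direction[i] <- hp$sa_direction
      res$ja_direction[i] <- hp$ja_direction
    }
  }
  res
}

#' SA vs JA correlation over co-regulated genes
#'
#' Pearson correlation of the mean SA log2FC against the mean JA log2FC of
#' co-regulated genes; no outlier removal is applied for this comparison.
#'
#' @param sa_mean,ja_mean mean log2FC per co-regulated gene (means over
#'   each gene's DEG time points).
#' @return list: \code{R}, \code{p} (two-sided), \code{n},
#'   \code{strength} (Evans label).
#' @export
coreg_correlation <- function(sa_mean, ja_mean) {
  if (length(sa_mean) != length(ja_mean)) stop("length mismatch")
  if (length(sa_mean) < 3) stop("need at least 3 co-regulated genes")
  if (stats::sd(sa_mean) == 0 || stats::sd(ja_mean) == 0)
    stop("zero variance")
  ct <- stats::cor.test(sa_mean, ja_mean, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(sa_mean),
       strength = evans_label(unname(ct$estimate)))
}

# round half away from zero, matching printed percentages
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-family and global program summaries
#'
#' Tallies, per family: up/down DEG counts per genotype, the ALL-genotype
#' counts (genes DEG in the given direction at >= 1 time point in
#' \emph{every} genotype, not necessarily the same one), and hormone
#' program counts when present. Percentages are rounded to the nearest
#' integer, half away from zero.
#'
#' @param assignments output of [classify_programs()].
#' @param catalog `pr_catalog` covering every classified gene.
#' @return list with \code{per_family} (data.frame),
#'   \code{hormone_totals}, \code{n_degs},
#'   \code{conserved_pct} (percent of DEGs in the all-up or all-down trend
#'   cluster) and \code{all_down_pct}/\code{all_up_pct}.
#' @export
program_summary <- function(assignments, catalog) {
  miss <- setdiff(assignments$gene_id, catalog$gene_id)
  if (length(miss)) stop("gene(s) absent from catalog: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  fam <- catalog$family[match(assignments$gene_id, catalog$gene_id)]
  gcols <- grep("^direction_", names(assignments), value = TRUE)
  genos <- sub("^direction_", "", gcols)
  per_family <- data.frame(family = sort(unique(fam)), stringsAsFactors = FALSE)
  dirs <- as.matrix(assignments[gcols])
  dirs[is.na(dirs)] <- "none"  # gene filtered out in that genotype
  for (g in gcols) assignments[[g]][is.na(assignments[[g]])] <- "none"
  for (g in genos) {
    d <- assignments[[paste0("direction_", g)]]
    per_family[[paste0(g, "_up")]] <-
      vapply(per_family$family, function(f) sum(fam == f & d == "up"), integer(1))
    per_family[[paste0(g, "_down")]] <-
      vapply(per_family$family, function(f) sum(fam == f & d == "down"), integer(1))
  }
  all_up <- apply(dirs == "up", 1, all)
  all_down <- apply(dirs == "down", 1, all)
  per_family$ALL_up <- vapply(per_family$family,
                              function(f) sum(fam == f & all_up), integer(1))
  per_family$ALL_down <- vapply(per_family$family,
                                function(f) sum(fam == f & all_down), integer(1))
  is_deg <- rowSums(dirs != "none") > 0
  n_degs <- sum(is_deg)
  out <- list(per_family = per_family, n_degs = n_degs)
  if (!is.null(assignments$trend_cluster)) {
    cl <- assignments$trend_cluster
    n1 <- sum(cl == 1L, na.rm = TRUE); n9 <- sum(cl == 9L, na.rm = TRUE)
    out$cluster1_n <- n1; out$cluster9_n <- n9
    if (n_degs > 0) {
      out$conserved_pct <- round_half_up(100 * (n1 + n9) / n_degs)
      out$all_up_pct <- round_half_up(100 * n1 / n_degs, 1)
      out$all_down_pct <- round_half_up(100 * n9 / n_degs, 1)
    }
  }
  if (!is.null(assignments$hormone_program)) {
    tab <- table(factor(assignments$hormone_program,
                        levels = c("sa_only", "ja_only", "co_regulated",
                                   "reciprocal", "none")))
    out$hormone_totals <- as.list(tab)
    out$hormone_responsive_n <- sum(tab[c("sa_only", "ja_only",
                                          "co_regulated", "reciprocal")])
  }
  out
}
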