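# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance suites. These deliberately re-derive each quantity
# from its definition and stay independent of the implementation paths
# they check.

# Benjamini-Hochberg step-up from the definition: for the i-th smallest
# p-value, adj = min_{k >= i} n p_(k) / k, capped at 1
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(n), function(i)
    min(1, min(n * ps[i:n] / (i:n))), numeric(1))
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# type-7 quartile by the interpolation formula, written out explicitly
quartile_brute <- function(x, q) {
  xs <- sort(x)
  h <- (length(xs) - 1) * q + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}

boxplot_outliers_brute <- function(v, k = 2.0) {
  q1 <- quartile_brute(v, 0.25)
  q3 <- quartile_brute(v, 0.75)
  iqr <- q3 - q1
  which(v < q1 - k * iqr | v > q3 + k * iqr)
}

# Pearson R and two-sided p from the covariance formula and t transform
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(R = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# full correlate_stresses recomputation from explicit formulas
correlate_brute <- function(a, b, min_shared = 10, k = 2.0) {
  shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) < min_shared) return(list(skipped = TRUE))
  x <- a$mean_log2FC[match(shared, a$gene_id)]
  y <- b$mean_log2FC[match(shared, b$gene_id)]
  drop <- sort(union(boxplot_outliers_brute(x, k), boxplot_outliers_brute(y, k)))
  keep <- setdiff(seq_along(shared), drop)
  pr <- pearson_brute(x[keep], y[keep])
  list(skipped = FALSE, R = pr$R, p = pr$p, n_used = length(keep),
       outliers = shared[drop])
}

# exhaustive clade enumeration for expansion detection: walk every internal
# node by following edges directly, collect qualifying tip sets, keep the
# maximal ones
expansions_brute <- function(tree, focal, min_size = 3) {
  species <- attr(tree, "species")
  nt <- length(tree$tip.label)
  tips_under <- function(node) {
    if (node <= nt) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_under))
  }
  sets <- lapply((nt + 1):(nt + tree$Nnode), tips_under)
  qual <- Filter(function(tp)
    length(tp) >= min_size && all(species[tp] == focal), sets)
  maximal <- Filter(function(tp)
    !any(vapply(qual, function(o)
      length(o) > length(tp) && all(tp %in% o), logical(1))), qual)
  sort(vapply(maximal, function(tp)
    paste(sort(sub("^[^_]+_", "", tree$tip.label[tp])), collapse = ","),
    character(1)))
}

# random species-tagged tree with two species
random_species_tree <- function(n, p_focal = 0.6) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0(sample(c("Mes", "Ptr"), n, replace = TRUE,
                                prob = c(p_focal, 1 - p_focal)),
                         "_g", seq_len(n))
  tag_tree_species(tr)
}

# tiny 3-gene x 6-sample count fixture
tiny_counts <- function() {
  m <- matrix(c(10, 20, 30, 40, 50, 60,
                100, 110, 120, 130, 140, 150,
                5, 0, 3, 8, 2, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              paste0("s", 1:6)))
  meta <- data.frame(sample = paste0("s", 1:6), condition = "WF",
                     timepoint = rep(c(0, 14), each = 3),
                     replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  count_matrix(m, meta)
}

# profile builder
profile_of <- function(ids, values, stress = "S") {
  structure(data.frame(gene_id = ids, stress = stress, mean_log2FC = values,
                       n_timepoints = 1L, stringsAsFactors = FALSE),
            class = c("pr_profile", "data.frame"))
}
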