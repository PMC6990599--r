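# Clade-based nomenclature, species-specific expansion detection from
# trees, and tandem physical-cluster detection from gene coordinates.

# tips (indices) descending from each internal node
node_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  phangorn::Descendants(tree, (nt + 1):(nt + tree$Nnode), type = "tips")
}

strip_species <- function(labels) sub("^[^_]+_", "", labels)

#' Detect species-specific family expansions
#'
#' An expansion is a maximal monophyletic clade whose tips all belong to
#' the focal species and number at least \code{min_size} (default 3
#' paralogs). When nested clades qualify only the largest is reported, so
#' expansions are disjoint and every tip lies in at most one.
#'
#' @param tree species-tagged `phylo` (see [read_tree()]).
#' @param focal_species species whose expansions are sought.
#' @param min_size minimum number of paralogs (default 3).
#' @param family family label recorded on each result.
#' @return data.frame with one row per expansion: \code{family},
#'   \code{node}, \code{species}, \code{size}, \code{members}
#'   (comma-joined gene ids, species prefix stripped).
#' @export
detect_expansions <- function(tree, focal_species, min_size = 3,
                              family = NA_character_) {
  species <- attr(tree, "species")
  if (is.null(species)) stop("tree lacks species tags; use read_tree()/tag_tree_species()")
  if (!focal_species %in% species)
    stop("focal species '", focal_species, "' absent from tree")
  nt <- length(tree$tip.label)
  tipsets <- node_tip_sets(tree)
  qual <- vapply(tipsets, function(tp)
    length(tp) >= min_size && all(species[tp] == focal_species), logical(1))
  nodes <- (nt + 1):(nt + tree$Nnode)
  parent <- integer(nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  qual_of <- stats::setNames(qual, nodes)
  maximal <- vapply(seq_along(nodes), function(i) {
    if (!qual[i]) return(FALSE)
    p <- parent[nodes[i]]
    p == 0 || !isTRUE(qual_of[as.character(p)])
  }, logical(1))
  keep <- which(maximal)
  if (!length(keep)) {
    return(data.frame(family = character(0), node = integer(0),
                      species = character(0), size = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    family = family, node = nodes[keep], species = focal_species,
    size = vapply(tipsets[keep], length, integer(1)),
    members = vapply(tipsets[keep], function(tp)
      paste(sort(strip_species(tree$tip.label[tp])), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
}

# letter sequence a..z, aa, ab, ...
clade_letters <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  extra <- n - 26
  c(letters, paste0(rep(letters, each = 26), letters)[seq_len(extra)])
}

#' Assign clade-based gene nomenclature within a family
#'
#' Clades are the child subtrees of the family tree's root that contain at
#' least one focal-species tip; they receive letters a, b, c, ...
#' (extending to aa, ab, ... past 26) in order of their smallest descendant
#' gene id. Within a clade, genes are numbered sequentially in traversal
#' order (children again ordered by smallest descendant id). Genes that
#' were never differentially expressed in any supplied treatment carry an
#' \code{L} ("Like") infix before their index, e.g. \code{PR-1dL1}; an
#' ever-DEG eighth gene of clade e in family PR-2 renders as
#' \code{PR-2e8}.
#'
#' @param tree species-tagged `phylo` for one family.
#' @param family family label, e.g. \code{"PR-2"}.
#' @param deg_history named logical vector gene id -> ever a DEG; genes
#'   absent from it are treated as never-DEG.
#' @param focal_species species whose genes are named.
#' @return data.frame: \code{gene_id}, \code{family}, \code{clade},
#'   \code{like}, \code{index}, \code{name}.
#' @export
assign_nomenclature <- function(tree, family, deg_history = logical(0),
                                focal_species = "Mes") {
  species <- attr(tree, "species")
  if (is.null(species)) stop("tree lacks species tags")
  nt <- length(tree$tip.label)
  gene_of_tip <- strip_species(tree$tip.label)
  focal <- species == focal_species
  if (!any(focal)) stop("focal species absent from tree")
  kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  # deterministic depth-first tip order: children by smallest descendant id
  tip_order <- function(node) {
    if (node <= nt) return(node)
    ch <- kids(node)
    key <- vapply(ch, function(c2) min(gene_of_tip[descend_tips(c2)]), character(1))
    unlist(lapply(ch[order(key)], tip_order))
  }
  descend_tips <- function(node) {
    if (node <= nt) return(node)
    unlist(phangorn::Descendants(tree, node, type = "tips"))
  }
  root <- nt + 1L
  clades <- kids(root)
  has_focal <- vapply(clades, function(c2) any(focal[descend_tips(c2)]), logical(1))
  clades <- clades[has_focal]
  key <- vapply(clades, function(c2)
    min(gene_of_tip[descend_tips(c2)][focal[descend_tips(c2)]]), character(1))
  clades <- clades[order(key)]
  lets <- clade_letters(length(clades))
  out <- list()
  for (k in seq_along(clades)) {
    tips <- tip_order(clades[k])
    tips <- tips[focal[tips]]
    ids <- gene_of_tip[tips]
    like <- !vapply(ids, function(g) isTRUE(deg_history[g]), logical(1))
    idx <- seq_along(ids)
    out[[k]] <- data.frame(
      gene_id = ids, family = family, clade = lets[k], like = like,
      index = idx,
      name = paste0(family, lets[k], ifelse(like, "L", ""), idx),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect tandem physical clusters of same-family genes
#'
#' Genes are sorted by chromosome and start; chains of same-family genes in
#' which each adjacent pair lies within \code{max_gap_bases} (gap measured
#' between intervals) and is separated by at most \code{max_intervening}
#' other catalog genes are reported when maximal and of length >= 2.
#' Unplaced genes are skipped with a message.
#'
#' @param catalog `pr_catalog`.
#' @param max_gap_bases maximum allowed gap between consecutive members
#'   (default 100 kb).
#' @param max_intervening maximum number of intervening genes of any
#'   family (default 5).
#' @return data.frame: \code{cluster_id}, \code{family},
#'   \code{chromosome}, \code{n}, \code{span}, \code{members}
#'   (comma-joined, in chromosomal order).
#' @export
detect_physical_clusters <- function(catalog, max_gap_bases = 1e5,
                                     max_intervening = 5) {
  placed <- catalog$chromosome != "unplaced" & !is.na(catalog$start)
  if (any(!placed)) message(sum(!placed), " unplaced gene(s) skipped")
  cat <- catalog[placed, , drop = FALSE]
  cat <- cat[order(cat$chromosome, cat$start), , drop = FALSE]
  cat$rank <- stats::ave(seq_len(nrow(cat)), cat$chromosome, FUN = seq_along)
  res <- list(); cid <- 0
  for (chr in unique(cat$chromosome)) {
    cc <- cat[cat$chromosome == chr, , drop = FALSE]
    for (fam in unique(cc$family)) {
      f <- cc[cc$family == fam, , drop = FALSE]
      if (nrow(f) < 2) next
      linked <- diff(f$rank) - 1 <= max_intervening &
        (f$start[-1] - f$end[-nrow(f)]) <= max_gap_bases
      run_id <- cumsum(c(1, !linked))
      for (r in split(seq_len(nrow(f)), run_id)) {
        if (length(r) < 2) next
        cid <- cid + 1
        res[[cid]] <- data.frame(
          cluster_id = cid, family = fam, chromosome = chr,
          n = length(r),
          span = max(f$end[r]) - min(f$start[r]) + 1,
          members = paste(f$gene_id[r], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(cluster_id = integer(0), family = character(0),
                      chromosome = character(0), n = integer(0),
                      span = numeric(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Fraction of each family's genes in physical clusters
#'
#' @param clusters output of [detect_physical_clusters()].
#' @param catalog `pr_catalog`.
#' @param min_cluster_size count only clusters of at least this many
#'   members (default 2).
#' @return list with \code{per_family} (family, n_genes, n_clustered,
#'   pct) and \code{overall_pct}; percents rounded to the nearest integer.
#' @export
cluster_summary <- function(clusters, catalog, min_cluster_size = 2) {
  use <- clusters[clusters$n >= min_cluster_size, , drop = FALSE]
  clustered <- unlist(strsplit(use$members, ","))
  fams <- sort(unique(catalog$family))
  per <- data.frame(
    family = fams,
    n_genes = vapply(fams, function(f) sum(catalog$family == f), integer(1)),
    n_clustered = vapply(fams, function(f)
      sum(catalog$gene_id[catalog$family == f] %in% clustered), integer(1)),
    stringsAsFactors = FALSE)
  per$pct <- round_half_up(100 * per$n_clustered / pmax(per$n_genes, 1))
  list(per_family = per,
       overall_pct = round_half_up(100 * sum(per$n_clustered) /
                                     max(sum(per$n_genes), 1)))
}
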