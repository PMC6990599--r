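# Readers/writers for the external formats and the canonical in-memory
# tables consumed by every downstream stage.

#' Construct a gene catalog
#'
#' The gene catalog maps every gene to its family (e.g. \code{"PR-2"}), clade
#' letter, and genomic location. Coordinates are stored 1-based inclusive
#' (GFF3 convention); BED input is converted on read. Genes without a
#' chromosome assignment are an allowed state (\code{"unplaced"}) and are
#' skipped by physical clustering.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param family family label per gene, e.g. \code{"PR-2"}.
#' @param clade single-letter clade label or \code{NA} for unassigned.
#' @param chromosome chromosome name or \code{NA}/\code{"unplaced"}.
#' @param start,end 1-based inclusive positions (\code{NA} for unplaced).
#' @param strand \code{"+"}, \code{"-"} or \code{NA} for unknown.
#' @return A \code{data.frame} of class \code{pr_catalog}.
#' @export
gene_catalog <- function(gene_id, family, clade = NA_character_,
                         chromosome = NA_character_, start = NA_integer_,
                         end = NA_integer_, strand = NA_character_) {
  cat <- data.frame(
    gene_id = as.character(gene_id),
    family = as.character(family),
    clade = rep_len(as.character(clade), length(gene_id)),
    chromosome = rep_len(as.character(chromosome), length(gene_id)),
    start = rep_len(as.numeric(start), length(gene_id)),
    end = rep_len(as.numeric(end), length(gene_id)),
    strand = rep_len(as.character(strand), length(gene_id)),
    stringsAsFactors = FALSE
  )
  validate_catalog(cat)
}

validate_catalog <- function(cat) {
  if (anyDuplicated(cat$gene_id)) {
    stop("duplicate gene_id in catalog: ",
         paste(unique(cat$gene_id[duplicated(cat$gene_id)]), collapse = ", "))
  }
  placed <- !is.na(cat$start) & !is.na(cat$end)
  if (any(placed & cat$start > cat$end)) {
    bad <- cat$gene_id[placed & cat$start > cat$end]
    stop("start > end for gene(s): ", paste(bad, collapse = ", "))
  }
  cat$chromosome[is.na(cat$chromosome)] <- "unplaced"
  class(cat) <- c("pr_catalog", "data.frame")
  cat
}

#' Read a count matrix with sample metadata
#'
#' Counts are a tab-separated table whose first column holds gene ids and
#' whose header holds sample ids; the metadata table must describe every
#' sample (columns \code{sample}, \code{condition}, \code{timepoint},
#' \code{replicate}).
#'
#' @param path counts table path.
#' @param meta sample-metadata path, or a data.frame already in memory.
#' @return An object of class \code{pr_counts}: a list with an integer
#'   matrix \code{counts} (genes x samples) and the joined \code{meta}.
#' @export
read_counts <- function(path, meta) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(meta)) {
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  }
  gene_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gene_ids
  count_matrix(mat, meta)
}

#' Construct a count matrix object
#'
#' @param counts numeric genes x samples matrix of non-negative integers,
#'   with gene ids as rownames and sample ids as colnames.
#' @param meta data.frame with columns \code{sample}, \code{condition},
#'   \code{timepoint}, \code{replicate} covering every column of
#'   \code{counts}.
#' @return `pr_counts` object.
#' @export
count_matrix <- function(counts, meta) {
  req <- c("sample", "condition", "timepoint", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must carry gene ids as rownames")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  unknown <- setdiff(colnames(counts), meta$sample)
  if (length(unknown)) {
    stop("sample(s) in counts header missing from metadata: ",
         paste(unknown, collapse = ", "))
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or non-integer count at gene '%s', sample '%s' (value %s)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])))
  }
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  meta$timepoint <- as.numeric(meta$timepoint)
  meta$replicate <- as.integer(meta$replicate)
  rownames(meta) <- NULL
  if (any(is.na(meta$timepoint))) stop("every sample needs a time point")
  structure(list(counts = counts, meta = meta), class = "pr_counts")
}

#' @export
print.pr_counts <- function(x, ...) {
  cat(sprintf("pr_counts: %d genes x %d samples (%d condition(s), timepoints: %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$condition)),
              paste(sort(unique(x$meta$timepoint)), collapse = ", ")))
  invisible(x)
}

#' Write a count matrix and its metadata
#'
#' @param x `pr_counts` object.
#' @param path counts output path; metadata is written next to it.
#' @param meta_path metadata output path (default `<path>.meta.tsv`).
#' @export
write_counts <- function(x, path, meta_path = paste0(path, ".meta.tsv")) {
  out <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read a differential-expression table
#'
#' Expects columns \code{gene}, \code{condition}, \code{timepoint},
#' \code{log2FC}, \code{FDR} (a \code{col_map} can rename a non-canonical
#' header). The up/down/ns status column is always recomputed from the
#' thresholds, never trusted from the file.
#'
#' @param path tab-separated input.
#' @param col_map optional named character vector mapping canonical names
#'   (\code{gene}, \code{condition}, \code{timepoint}, \code{log2FC},
#'   \code{FDR}) to the file's column names.
#' @param lfc_threshold,fdr_threshold DEG thresholds; status is
#'   \code{up} iff \code{log2FC > lfc_threshold} and
#'   \code{fdr <= fdr_threshold} (strict on the fold change, inclusive on
#'   the FDR), symmetric for \code{down}.
#' @return A \code{data.frame} of class \code{pr_degs} with columns
#'   \code{gene_id}, \code{condition}, \code{timepoint}, \code{log2FC},
#'   \code{fdr}, \code{status}.
#' @export
read_deg_table <- function(path, col_map = NULL,
                           lfc_threshold = 1, fdr_threshold = 0.05) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  canon <- c(gene = "gene", condition = "condition", timepoint = "timepoint",
             log2FC = "log2FC", FDR = "FDR")
  if (!is.null(col_map)) canon[names(col_map)] <- col_map
  miss <- setdiff(unname(canon), names(tab))
  if (length(miss)) stop("DEG table missing column(s): ", paste(miss, collapse = ", "))
  lfc <- suppressWarnings(as.numeric(tab[[canon[["log2FC"]]]]))
  if (anyNA(lfc)) stop("non-numeric log2FC in DEG table")
  fdr <- suppressWarnings(as.numeric(tab[[canon[["FDR"]]]]))
  if (anyNA(fdr) || any(fdr < 0 | fdr > 1)) stop("FDR outside [0, 1] in DEG table")
  deg_table(gene_id = as.character(tab[[canon[["gene"]]]]),
            condition = as.character(tab[[canon[["condition"]]]]),
            timepoint = as.numeric(tab[[canon[["timepoint"]]]]),
            log2FC = lfc, fdr = fdr,
            lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold)
}

#' Construct a DEG table, recomputing status from thresholds
#'
#' @inheritParams read_deg_table
#' @param gene_id,condition,timepoint,log2FC,fdr column vectors.
#' @return `pr_degs` data.frame.
#' @export
deg_table <- function(gene_id, condition, timepoint, log2FC, fdr,
                      lfc_threshold = 1, fdr_threshold = 0.05) {
  d <- data.frame(gene_id = as.character(gene_id),
                  condition = as.character(condition),
                  timepoint = as.numeric(timepoint),
                  log2FC = as.numeric(log2FC), fdr = as.numeric(fdr),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d[c("gene_id", "condition", "timepoint")])) {
    stop("more than one row per gene x condition x time point")
  }
  d$status <- call_deg_status(d$log2FC, d$fdr, lfc_threshold, fdr_threshold)
  class(d) <- c("pr_degs", "data.frame")
  d
}

#' @rdname read_deg_table
#' @param degs `pr_degs` object to write.
#' @export
write_deg_table <- function(degs, path) {
  out <- data.frame(gene = degs$gene_id, condition = degs$condition,
                    timepoint = degs$timepoint, log2FC = degs$log2FC,
                    FDR = degs$fdr, status = degs$status,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene coordinates from BED or GFF3
#'
#' Both dialects are parsed by \pkg{rtracklayer} and unified to 1-based
#' inclusive coordinates (BED's 0-based half-open starts are incremented on
#' read). For GFF3, only \code{gene}-type features are used when a
#' \code{type} column is present; the family is taken from a \code{family}
#' attribute when available.
#'
#' @param path input file.
#' @param dialect \code{"bed"} or \code{"gff3"}.
#' @param family fallback family label applied when the file carries none.
#' @return `pr_catalog` data.frame.
#' @export
read_gene_coords <- function(path, dialect = c("bed", "gff3"),
                             family = NA_character_) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "BED" else "GFF3")
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (dialect == "gff3" && "type" %in% names(md) && any(md$type == "gene")) {
    keep <- md$type == "gene"
    gr <- gr[keep]
    md <- md[keep, , drop = FALSE]
  }
  ids <- if (dialect == "bed") md$name else {
    if (!is.null(md$Name)) md$Name else md$ID
  }
  if (is.null(ids) || anyNA(ids)) stop("every feature needs a gene id (name/ID)")
  fam <- if (!is.null(md$family)) as.character(md$family) else rep(family, length(gr))
  # rtracklayer already yields 1-based inclusive starts for both dialects
  gene_catalog(gene_id = as.character(ids), family = fam,
               chromosome = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)))
}

#' @rdname read_gene_coords
#' @param catalog `pr_catalog` to write (unplaced genes are dropped with a
#'   message).
#' @export
write_gene_coords <- function(catalog, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  placed <- catalog$chromosome != "unplaced" & !is.na(catalog$start)
  if (any(!placed)) message(sum(!placed), " unplaced gene(s) not written")
  cat <- catalog[placed, , drop = FALSE]
  strand <- ifelse(is.na(cat$strand) | !cat$strand %in% c("+", "-"), "*", cat$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = cat$chromosome,
    ranges = IRanges::IRanges(start = cat$start, end = cat$end),
    strand = strand
  )
  if (dialect == "bed") {
    S4Vectors::mcols(gr)$name <- cat$gene_id
    rtracklayer::export(gr, path, format = "BED")
  } else {
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- cat$gene_id
    S4Vectors::mcols(gr)$Name <- cat$gene_id
    S4Vectors::mcols(gr)$family <- cat$family
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Read/write the full gene catalog as a tab-separated table
#' @param path table path.
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  validate_catalog(tab)
}

#' @rdname read_catalog
#' @param catalog `pr_catalog` object.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a species-tagged phylogenetic tree
#'
#' Tip labels must carry a species prefix separated by an underscore
#' (e.g. \code{Mes_g1} for cassava, \code{Ptr_x} for poplar); a
#' \code{species_map} can translate prefixes to full species names.
#' Unrooted input is midpoint-rooted deterministically, since displayed
#' trees in family analyses are conventionally rooted.
#'
#' @param path Newick file.
#' @param species_map optional named character vector prefix -> species.
#' @return An \code{ape} \code{phylo} with a \code{species} attribute
#'   (character vector parallel to \code{tip.label}).
#' @export
read_tree <- function(path, species_map = NULL) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("unparseable Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick in ", path)
  tag_tree_species(tr, species_map)
}

#' @rdname read_tree
#' @param tree a `phylo` object (e.g. already in memory).
#' @export
tag_tree_species <- function(tree, species_map = NULL) {
  no_prefix <- !grepl("_", tree$tip.label)
  if (any(no_prefix)) {
    stop("tip(s) without species prefix: ",
         paste(tree$tip.label[no_prefix], collapse = ", "))
  }
  prefix <- sub("_.*$", "", tree$tip.label)
  species <- if (is.null(species_map)) prefix else {
    unknown <- setdiff(unique(prefix), names(species_map))
    if (length(unknown)) stop("prefix(es) not in species_map: ",
                              paste(unknown, collapse = ", "))
    unname(species_map[prefix])
  }
  # midpoint rooting needs branch lengths; a basal polytomy without them
  # is kept as-is and treated as rooted at that polytomy
  if (!ape::is.rooted(tree) && !is.null(tree$edge.length))
    tree <- phangorn::midpoint(tree)
  attr(tree, "species") <- species
  tree
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
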