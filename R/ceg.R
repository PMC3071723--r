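# Transcriptome coverage estimation from core eukaryotic gene (CEG) hits.
#
# The CEG-248 reference partitions 248 highly conserved eukaryotic genes
# into four conservation categories (least to most conserved). Coverage is
# the fraction of reference genes with at least one transcript hit; it is a
# proxy for transcriptome completeness, and extrapolating it to the whole
# transcriptome assumes CEGs are sampled like an average gene.

#' CEG reference (category sizes and gene identifiers)
#'
#' @param category_sizes Named integer vector of genes per conservation
#'   category; the default is the classic CEG-248 split
#'   (66, 56, 61, 65 genes in categories 1-4, total 248).
#' @param genes Optional named list: category name -> character vector of
#'   gene ids, matching `category_sizes`. When omitted, synthetic
#'   placeholder ids `KOG_<category>_<i>` are generated, since only the
#'   category sizes are needed for coverage arithmetic.
#' @return An object of class `ceg_reference`.
#' @export
ceg_reference <- function(category_sizes = c(category1 = 66, category2 = 56,
                                             category3 = 61, category4 = 65),
                          genes = NULL) {
  if (is.null(names(category_sizes)) || anyDuplicated(names(category_sizes)))
    stop_config("category sizes must have unique names")
  if (any(category_sizes < 1) || any(category_sizes != floor(category_sizes)))
    stop_config("category sizes must be positive integers")
  if (is.null(genes)) {
    genes <- lapply(seq_along(category_sizes), function(i)
      sprintf("KOG_%s_%03d", names(category_sizes)[i],
              seq_len(category_sizes[[i]])))
    names(genes) <- names(category_sizes)
  }
  if (!identical(lengths(genes)[names(category_sizes)],
                 vapply(category_sizes, as.integer, integer(1))))
    stop_config("gene lists do not match category sizes")
  all_genes <- unlist(genes, use.names = FALSE)
  if (anyDuplicated(all_genes)) stop_config("duplicate gene ids in reference")
  structure(list(category_sizes = category_sizes, genes = genes,
                 total_genes = sum(category_sizes)),
            class = "ceg_reference")
}

#' Coverage report from a CEG hit table
#'
#' A reference gene is covered iff it has at least one hit; multiplicity
#' beyond presence does not change coverage. The headline percentage is
#' `100 * covered / total`, kept at full precision with a nearest-integer
#' display value.
#'
#' @param hit_table Data frame with columns `gene_id` and `n_hits`
#'   (integer >= 1); every gene must belong to the reference.
#' @param reference A [ceg_reference()].
#' @return An object of class `ceg_coverage_report`: per-category hit
#'   counts, `total_hits`, `coverage_percent` (exact), `coverage_display`
#'   (rounded to nearest integer) and `single_hit_genes`.
#' @export
coverage_from_hits <- function(hit_table, reference = ceg_reference()) {
  if (!is.data.frame(hit_table) ||
      !all(c("gene_id", "n_hits") %in% names(hit_table)))
    stop_input("hit table needs columns gene_id, n_hits")
  if (nrow(hit_table) > 0) {
    if (anyDuplicated(hit_table$gene_id))
      stop_input("duplicate gene_id: ",
                 hit_table$gene_id[duplicated(hit_table$gene_id)][1L])
    if (any(hit_table$n_hits < 1) || any(hit_table$n_hits != floor(hit_table$n_hits)))
      stop_input("n_hits must be integers >= 1")
  }
  gene2cat <- rep(names(reference$genes), lengths(reference$genes))
  names(gene2cat) <- unlist(reference$genes, use.names = FALSE)
  unknown <- setdiff(hit_table$gene_id, names(gene2cat))
  if (length(unknown) > 0)
    stop_input("gene not in reference: ", unknown[1L])
  cat_of_hit <- gene2cat[hit_table$gene_id]
  hits <- vapply(names(reference$category_sizes),
                 function(cn) sum(cat_of_hit == cn), integer(1))
  total_hits <- sum(hits)
  pct <- 100 * total_hits / reference$total_genes
  structure(list(category_sizes = reference$category_sizes,
                 category_hits = hits,
                 total_genes = reference$total_genes,
                 total_hits = total_hits,
                 coverage_percent = pct,
                 coverage_display = round(pct),
                 single_hit_genes = sum(hit_table$n_hits == 1)),
            class = "ceg_coverage_report")
}

#' Coverage report from per-category hit counts
#'
#' Convenience constructor when only category-level tallies are available
#' (e.g. a published table) rather than a per-gene hit list.
#'
#' @param category_hits Integer vector of covered genes per category,
#'   aligned to the reference categories.
#' @param reference A [ceg_reference()].
#' @param single_hit_genes Optional count of genes with exactly one hit.
#' @return A `ceg_coverage_report`.
#' @export
coverage_from_category_hits <- function(category_hits,
                                        reference = ceg_reference(),
                                        single_hit_genes = NA_integer_) {
  sizes <- reference$category_sizes
  if (length(category_hits) != length(sizes))
    stop_input("need one hit count per reference category")
  if (any(category_hits < 0) || any(category_hits > sizes))
    stop_input("category hits must lie in [0, category size]")
  total_hits <- sum(as.integer(category_hits))
  pct <- 100 * total_hits / reference$total_genes
  hits <- as.integer(category_hits)
  names(hits) <- names(sizes)
  structure(list(category_sizes = sizes, category_hits = hits,
                 total_genes = reference$total_genes, total_hits = total_hits,
                 coverage_percent = pct, coverage_display = round(pct),
                 single_hit_genes = single_hit_genes),
            class = "ceg_coverage_report")
}

#' @export
print.ceg_coverage_report <- function(x, ...) {
  for (cn in names(x$category_sizes))
    cat(sprintf("%s: %d out of %d\n", cn, x$category_hits[[cn]],
                x$category_sizes[[cn]]))
  cat(sprintf("total: %d out of %d (%d%% covered; extrapolation to the full transcriptome assumes CEGs are representative)\n",
              x$total_hits, x$total_genes, x$coverage_display))
  if (!is.na(x$single_hit_genes))
    cat(sprintf("genes with a single hit: %d\n", x$single_hit_genes))
  invisible(x)
}
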