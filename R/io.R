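# Readers and writers for the bespoke TSV formats, plus FASTA length
# extraction. All tables are tab-separated UTF-8 with a header row;
# infinite folds are rendered "inf" and missing p-values "NA".

#' Read a two-library count table
#'
#' Expects a TSV with header `contig_id<TAB>count_a<TAB>count_b`. Counts
#' must be plain base-10 integers: decimals and thousands separators are
#' rejected rather than rounded, with the offending line number in the
#' error. Library sizes are the column sums (basis `reads_in_contigs`).
#'
#' @param path Path to the TSV file.
#' @return A list with `counts` (data frame) and `sizes`
#'   ([library_sizes()]); a header-only file yields an empty table, sizes
#'   (0, 0) are signalled as a warning.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop_input("count table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop_input("empty file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("contig_id", "count_a", "count_b")))
    stop_input("bad header, expected contig_id<TAB>count_a<TAB>count_b")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    warning("count table has no data rows; library sizes are (0, 0)")
    return(list(counts = data.frame(contig_id = character(),
                                    count_a = integer(), count_b = integer(),
                                    stringsAsFactors = FALSE),
                sizes = NULL))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0)
    stop_input("malformed row at line ", bad[1L] + 1L, ": expected 3 fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  a_raw <- vapply(fields, `[[`, character(1), 2L)
  b_raw <- vapply(fields, `[[`, character(1), 3L)
  bad_int <- which(!grepl("^[0-9]+$", a_raw) | !grepl("^[0-9]+$", b_raw))
  if (length(bad_int) > 0)
    stop_input("non-integer count at line ", bad_int[1L] + 1L, ": '",
               a_raw[bad_int[1L]], "' / '", b_raw[bad_int[1L]], "'")
  dup <- which(duplicated(ids))
  if (length(dup) > 0)
    stop_input("duplicate contig_id '", ids[dup[1L]], "' at line ",
               dup[1L] + 1L)
  counts <- data.frame(contig_id = ids,
                       count_a = as.integer(a_raw),
                       count_b = as.integer(b_raw),
                       stringsAsFactors = FALSE)
  list(counts = counts,
       sizes = library_sizes(sum(counts$count_a), sum(counts$count_b),
                             basis = "reads_in_contigs"))
}

#' Write a count table (round-trips with [read_count_table()])
#' @param counts Data frame with `contig_id`, `count_a`, `count_b`.
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(counts[, c("contig_id", "count_a", "count_b")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Contig lengths from a FASTA file
#'
#' Ids are taken up to the first whitespace of the header; multi-line and
#' CRLF records are handled by the underlying Biostrings parser.
#'
#' @param path FASTA file path.
#' @return Named integer vector contig_id -> length in bp. Duplicate ids
#'   are an error; empty sequences are excluded with a warning.
#' @export
read_fasta_lengths <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop_input("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  len <- Biostrings::width(seqs)
  names(len) <- ids
  if (any(len == 0)) {
    warning("excluding ", sum(len == 0), " empty FASTA record(s)")
    len <- len[len > 0]
  }
  len
}

#' Write enrichment calls as TSV
#'
#' Columns: contig_id, partition, x, y, rate_a, rate_b, fold, p_value,
#' direction, enriched, robust (plus robust_by). `Inf` folds are rendered
#' `inf`; p-values use scientific notation with 6 significant digits;
#' untested contigs have `p_value = NA`.
#'
#' @param calls Output of [call_enrichment()].
#' @param path Output path.
#' @export
write_enrichment_calls <- function(calls, path) {
  out <- data.frame(contig_id = calls$contig_id, partition = calls$partition,
                    x = calls$count_a, y = calls$count_b,
                    rate_a = formatC(calls$rate_a, format = "e", digits = 5),
                    rate_b = formatC(calls$rate_b, format = "e", digits = 5),
                    fold = ifelse(is.infinite(calls$fold), "inf",
                                  formatC(calls$fold, format = "g", digits = 6)),
                    p_value = ifelse(is.na(calls$p_value), "NA",
                                     formatC(calls$p_value, format = "e",
                                             digits = 5)),
                    direction = calls$direction, enriched = calls$enriched,
                    robust = calls$robust, robust_by = calls$robust_by,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a partition summary in two-column accounting layout
#' @param summary A `partition_summary`.
#' @param path Output path.
#' @export
write_partition_summary <- function(summary, path) {
  rows <- data.frame(
    item = c("total_reads", "reads_a", "reads_b", "total_contigs",
             "mixed_contigs", "a_only_contigs", "b_only_contigs"),
    value = c(summary$reads_a + summary$reads_b, summary$reads_a,
              summary$reads_b, summary$n_contigs, summary$mixed,
              summary$a_only, summary$b_only))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CEG hit table (TSV gene_id, n_hits)
#' @param path TSV path.
#' @return Data frame `gene_id`, `n_hits`.
#' @export
read_ceg_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "n_hits") %in% names(df)))
    stop_input("CEG hit table needs columns gene_id, n_hits")
  df
}

#' Read a CEG reference from YAML
#'
#' Expected layout: a `categories` map of name -> size (and optionally
#' name -> gene id list under `genes`). The packaged default is
#' `system.file("extdata", "ceg248.yaml", package = "twolibde")`.
#'
#' @param path YAML file path.
#' @return A [ceg_reference()].
#' @export
read_ceg_reference <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$categories)) stop_input("CEG reference YAML needs 'categories'")
  sizes <- unlist(y$categories)
  genes <- if (!is.null(y$genes)) lapply(y$genes, unlist) else NULL
  ceg_reference(category_sizes = sizes, genes = genes)
}

#' Read a long-format qPCR CT table
#' @param path TSV with columns sample_id, group, gene, replicate,
#'   ct_target, ct_reference.
#' @return Validated data frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(df)
  df
}

#' Read an annotation table
#'
#' TSV with columns `contig_id`, `description` and optionally `length_bp`
#' and `go_terms` (semicolon-joined). Lengths missing from the table can be
#' filled from a FASTA of the contigs.
#'
#' @param path TSV path.
#' @param fasta Optional FASTA path used to fill `length_bp`.
#' @return Data frame with at least `contig_id` and `description`.
#' @export
read_annotation_table <- function(path, fasta = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  validate_annotation_table(df)
  if (!is.null(fasta) && !("length_bp" %in% names(df))) {
    len <- read_fasta_lengths(fasta)
    df$length_bp <- unname(len[df$contig_id])
  }
  df
}
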