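# Keyword mining of homology-annotation tables and annotation-rate
# profiling by contig length.

#' Default sex-related keyword set
#'
#' The seven keywords classically used to flag sex-differentiation
#' candidates in BLAST top-hit descriptions.
#' @export
sex_keywords <- function() c("sex", "egg", "ovary", "sperm", "testis",
                             "female", "male")

validate_annotation_table <- function(records) {
  need <- c("contig_id", "description")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_input("annotation table needs columns contig_id, description")
  if (anyDuplicated(records$contig_id))
    stop_input("duplicate contig_id: ",
               records$contig_id[duplicated(records$contig_id)][1L])
  invisible(records)
}

# lowercase tokens at word boundaries; hyphens and any other
# non-alphanumeric characters split tokens ("testis-specific" -> testis,
# specific). Plural tolerance is naive: a token matches a keyword if it
# equals the keyword or the keyword + "s"/"es" ("eggs" -> egg), which keeps
# "sexual" from matching "sex" in word mode.
tokenize_description <- function(s) {
  strsplit(tolower(s), "[^a-z0-9]+")
}

match_keywords <- function(descriptions, keywords, mode) {
  keywords <- tolower(keywords)
  if (mode == "substring") {
    lows <- tolower(descriptions)
    lapply(lows, function(d) keywords[vapply(keywords, grepl, logical(1),
                                             x = d, fixed = TRUE)])
  } else {
    toks <- tokenize_description(descriptions)
    lapply(toks, function(tk) {
      keywords[vapply(keywords, function(kw)
        any(tk == kw | tk == paste0(kw, "s") | tk == paste0(kw, "es")),
        logical(1))]
    })
  }
}

#' Select annotation records matching a keyword set
#'
#' Case-insensitive matching of keywords against the free-text description
#' of each record. In `"word"` mode (default) keywords must match a whole
#' token, where tokens are split at any non-alphanumeric character (so
#' "testis-specific" matches "testis") and naive plurals are tolerated
#' ("eggs" matches "egg"); "sexual" does not match "sex". In `"substring"`
#' mode any occurrence counts. Output preserves input order and is
#' idempotent.
#'
#' @param records Data frame with columns `contig_id` and `description`
#'   (other columns are carried through).
#' @param keywords Character vector of keywords; default [sex_keywords()].
#' @param mode `"word"` or `"substring"`.
#' @return The matching rows of `records` with an added `matched_keywords`
#'   column (comma-joined, in keyword-set order).
#' @export
keyword_select <- function(records, keywords = sex_keywords(),
                           mode = c("word", "substring")) {
  mode <- match.arg(mode)
  validate_annotation_table(records)
  if (length(keywords) == 0) stop_config("keyword set is empty")
  if (anyDuplicated(tolower(keywords))) stop_config("duplicate keywords")
  desc <- as.character(records$description)
  desc[is.na(desc)] <- ""
  hits <- match_keywords(desc, keywords, mode)
  n_hit <- lengths(hits)
  out <- records[n_hit > 0, , drop = FALSE]
  out$matched_keywords <- vapply(hits[n_hit > 0], paste, character(1),
                                 collapse = ",")
  out
}

#' Annotation rate as a function of contig length
#'
#' Bins contigs by length and reports the fraction annotated per bin; the
#' classic diagnostic that longer contigs are more likely to find a
#' homology hit.
#'
#' @param records Data frame with columns `contig_id` and `length_bp`.
#' @param annotated Logical vector aligned to `records` (or the name of a
#'   logical column in `records`).
#' @param bin_width_bp Bin width in bp; minimum 50.
#' @return Data frame with `bin_start`, `bin_end` (half-open
#'   `[start, end)`, last bin closed), `n_contigs`, `n_annotated`,
#'   `frac_annotated`.
#' @export
length_annotation_profile <- function(records, annotated, bin_width_bp = 100) {
  if (bin_width_bp < 50) stop_config("bin width must be >= 50 bp")
  if (is.character(annotated) && length(annotated) == 1L)
    annotated <- records[[annotated]]
  if (!is.logical(annotated) || length(annotated) != nrow(records))
    stop_input("annotated must be a logical vector aligned to records")
  len <- records$length_bp
  if (any(len < 1)) stop_input("length_bp must be >= 1")
  lo <- floor(min(len) / bin_width_bp) * bin_width_bp
  bin <- lo + bin_width_bp * floor((len - lo) / bin_width_bp)
  starts <- seq(lo, max(bin), by = bin_width_bp)
  n <- vapply(starts, function(s) sum(bin == s), integer(1))
  k <- vapply(starts, function(s) sum(annotated[bin == s]), integer(1))
  data.frame(bin_start = starts, bin_end = starts + bin_width_bp,
             n_contigs = n, n_annotated = k,
             frac_annotated = ifelse(n > 0, k / n, NA_real_))
}

#' Count keyword-selected contigs per functional category
#'
#' Applies [keyword_select()] once per category and counts distinct
#' matching contigs; a contig may contribute to several categories.
#'
#' @param records Annotation table as in [keyword_select()].
#' @param category_keyword_map Named list: category name -> character
#'   vector of keywords.
#' @param mode Matching mode passed to [keyword_select()].
#' @return Data frame with `category` and `n_contigs`, in map order.
#' @export
category_counts <- function(records, category_keyword_map,
                            mode = c("word", "substring")) {
  mode <- match.arg(mode)
  if (is.null(names(category_keyword_map)) ||
      anyDuplicated(names(category_keyword_map)))
    stop_config("category names must be unique and non-empty")
  n <- vapply(category_keyword_map, function(keys) {
    if (nrow(records) == 0L) return(0L)
    nrow(keyword_select(records, keys, mode))
  }, integer(1))
  data.frame(category = names(category_keyword_map), n_contigs = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}
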