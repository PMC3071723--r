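# Exact two-library enrichment testing on per-contig read counts.
#
# The test conditions on the combined count t = x + y of a contig: under the
# null hypothesis that both libraries sample the same underlying transcript
# pool, Y | (X + Y = t) ~ Binomial(t, q) with q = N_B / (N_A + N_B) set by the
# relative library sizes. The conditional point mass
#
#   p(y | x) = (N_B/N_A)^y * (x+y)! / (x! * y! * (1 + N_B/N_A)^(x+y))
#
# is exactly the Binomial(t, q) mass at y; all computation is done in log
# space so that counts up to 10^6 neither overflow nor underflow.

#' Library size pair for a two-library experiment
#'
#' @param n_a,n_b Positive integer read totals for library A and library B.
#' @param basis Which totals these are: `"reads_in_contigs"` (reads that made
#'   it into assembled contigs; the default, since these are the reads being
#'   counted per contig) or `"all_reads"` (raw sequencer yield).
#' @return An object of class `library_sizes`.
#' @export
library_sizes <- function(n_a, n_b, basis = c("reads_in_contigs", "all_reads")) {
  basis <- match.arg(basis)
  if (!is.numeric(n_a) || !is.numeric(n_b) || length(n_a) != 1L ||
      length(n_b) != 1L || is.na(n_a) || is.na(n_b) || n_a <= 0 || n_b <= 0)
    stop_input("library sizes must be single positive numbers")
  structure(list(n_a = as.numeric(n_a), n_b = as.numeric(n_b), basis = basis),
            class = "library_sizes")
}

#' @export
print.library_sizes <- function(x, ...) {
  cat(sprintf("library sizes: A = %s, B = %s (basis: %s)\n",
              format(x$n_a, big.mark = ","), format(x$n_b, big.mark = ","),
              x$basis))
  invisible(x)
}

#' Enrichment-calling configuration
#'
#' @param alpha Significance cutoff on the (raw) p-value; default 0.001.
#' @param sidedness `"two_sided"` (default; smaller binomial tail doubled and
#'   capped at 1) or `"one_sided"` (smaller tail).
#' @param robust_min_fold Minimum normalized fold enrichment for the robust
#'   candidate set; default 100.
#' @param robust_min_reads Read-support threshold for the robust set: the
#'   larger of the two counts must exceed this; default 100.
#' @param robust_rule Which magnitude filter defines the robust set:
#'   `"fold"`, `"reads"`, or `"either"` (default; union of the two).
#' @param include_exclusive If `TRUE`, contigs with reads in only one library
#'   also receive a p-value from the same conditional binomial test; by
#'   default they are reported but not tested.
#' @param p_adjust Multiple-testing adjustment applied before comparing to
#'   `alpha`: `"none"` (default, a raw cutoff) or `"BH"`.
#' @return An object of class `enrichment_config`.
#' @export
enrichment_config <- function(alpha = 0.001,
                              sidedness = c("two_sided", "one_sided"),
                              robust_min_fold = 100,
                              robust_min_reads = 100,
                              robust_rule = c("either", "fold", "reads"),
                              include_exclusive = FALSE,
                              p_adjust = c("none", "BH")) {
  sidedness <- match.arg(sidedness)
  robust_rule <- match.arg(robust_rule)
  p_adjust <- match.arg(p_adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_config("alpha must lie in (0, 1)")
  if (robust_min_fold < 1) stop_config("robust_min_fold must be >= 1")
  if (robust_min_reads < 0) stop_config("robust_min_reads must be >= 0")
  structure(list(alpha = alpha, sidedness = sidedness,
                 robust_min_fold = robust_min_fold,
                 robust_min_reads = robust_min_reads,
                 robust_rule = robust_rule,
                 include_exclusive = isTRUE(include_exclusive),
                 p_adjust = p_adjust),
            class = "enrichment_config")
}

check_counts_sizes <- function(x, y, sizes) {
  if (!inherits(sizes, "library_sizes"))
    stop_input("sizes must be a library_sizes object")
  assert_count_vector(x, "x")
  assert_count_vector(y, "y")
  if (length(x) != length(y)) stop_input("x and y must have equal length")
}

#' Conditional point probability of the two-library test
#'
#' Probability of observing `y` reads in library B for a contig with `x`
#' reads in library A, conditional on the combined count, under the shared
#' rate null. Equals the Binomial(x + y, N_B / (N_A + N_B)) mass at `y`.
#' Vectorized over `x` and `y`.
#'
#' @param x,y Non-negative integer read counts (library A, library B).
#' @param sizes A [library_sizes()] object.
#' @return Probabilities in \[0, 1\]; `x = y = 0` gives 1 (the only possible
#'   outcome of a conditional draw of size zero).
#' @export
ac_point_probability <- function(x, y, sizes) {
  check_counts_sizes(x, y, sizes)
  q <- sizes$n_b / (sizes$n_a + sizes$n_b)
  # log-space binomial mass; y*log(q) and x*log(1-q) are finite since
  # 0 < q < 1 whenever both library sizes are positive
  exp(lchoose(x + y, y) + y * log(q) + x * log1p(-q))
}

#' Exact p-value of the two-library enrichment test
#'
#' Tail probability of the conditional binomial law. One-sided: the smaller
#' of P(Y <= y) and P(Y >= y). Two-sided (default): twice the smaller tail,
#' capped at 1. The test is discrete and therefore conservative: under the
#' null, P(p < alpha) <= alpha. Vectorized over `x` and `y`.
#'
#' @inheritParams ac_point_probability
#' @param sidedness `"two_sided"` or `"one_sided"`.
#' @return p-values in (0, 1\]. A contig with `x = y = 0` carries no
#'   information; it gets p = 1 with a warning.
#' @export
ac_pvalue <- function(x, y, sizes, sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  check_counts_sizes(x, y, sizes)
  t <- x + y
  if (any(t == 0)) warning("contig with x = y = 0: p-value set to 1")
  q <- sizes$n_b / (sizes$n_a + sizes$n_b)
  lower <- stats::pbinom(y, t, q)                         # P(Y <= y)
  upper <- stats::pbinom(y - 1, t, q, lower.tail = FALSE) # P(Y >= y)
  smaller <- pmin(lower, upper)
  p <- if (sidedness == "two_sided") pmin(1, 2 * smaller) else smaller
  p[t == 0] <- 1
  p
}

#' Normalized fold enrichment between two libraries
#'
#' Ratio of the library-size-normalized read rates, always reported as the
#' larger rate over the smaller, so the value is >= 1. When exactly one
#' count is zero the fold is `Inf`.
#'
#' @inheritParams ac_point_probability
#' @return Positive reals (or `Inf`); both counts zero is an error.
#' @export
fold_enrichment <- function(x, y, sizes) {
  check_counts_sizes(x, y, sizes)
  if (any(x + y == 0)) stop_input("fold enrichment undefined for x = y = 0")
  r_a <- x / sizes$n_a
  r_b <- y / sizes$n_b
  pmax(r_a, r_b) / pmin(r_a, r_b)
}

validate_count_table <- function(table) {
  need <- c("contig_id", "count_a", "count_b")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop_input("count table needs columns contig_id, count_a, count_b")
  if (nrow(table) == 0L) return(invisible(table))
  if (anyDuplicated(table$contig_id)) {
    dup <- table$contig_id[duplicated(table$contig_id)][1L]
    stop_input("duplicate contig_id: ", dup)
  }
  assert_count_vector(table$count_a, "count_a")
  assert_count_vector(table$count_b, "count_b")
  zero <- table$count_a + table$count_b == 0
  if (any(zero))
    stop_input("contig with zero reads in both libraries: ",
               table$contig_id[which(zero)[1L]])
  invisible(table)
}

#' Partition contigs into mixed and library-exclusive classes
#'
#' A contig is `mixed` when both libraries contributed reads, `a_only` /
#' `b_only` when only one did. The summary mirrors the usual two-library
#' accounting table: class counts plus per-library read totals recovered
#' from the table itself.
#'
#' @param table Data frame with columns `contig_id`, `count_a`, `count_b`.
#' @return A list with `partition` (character vector aligned to the input
#'   rows) and `summary` (class `partition_summary`).
#' @export
classify_partition <- function(table) {
  validate_count_table(table)
  if (nrow(table) == 0L) stop_input("count table is empty")
  part <- ifelse(table$count_b == 0, "a_only",
                 ifelse(table$count_a == 0, "b_only", "mixed"))
  summary <- structure(list(
    n_contigs = nrow(table),
    mixed = sum(part == "mixed"),
    a_only = sum(part == "a_only"),
    b_only = sum(part == "b_only"),
    reads_a = sum(table$count_a),
    reads_b = sum(table$count_b)
  ), class = "partition_summary")
  list(partition = part, summary = summary)
}

#' Two-library accounting summary from class counts and read totals
#'
#' Builds the same summary object as [classify_partition()] directly from
#' pre-tabulated numbers, e.g. a published accounting table.
#'
#' @param mixed,a_only,b_only Contig counts per partition class.
#' @param reads_a,reads_b Per-library read totals.
#' @return A `partition_summary`; `n_contigs` and `reads_total` are derived.
#' @export
partition_summary <- function(mixed, a_only, b_only, reads_a, reads_b) {
  for (v in c(mixed, a_only, b_only, reads_a, reads_b))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_input("summary entries must be single non-negative numbers")
  structure(list(n_contigs = mixed + a_only + b_only,
                 mixed = mixed, a_only = a_only, b_only = b_only,
                 reads_a = reads_a, reads_b = reads_b),
            class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  f <- function(n) format(n, big.mark = ",")
  cat("Total number of reads      ", f(x$reads_a + x$reads_b), "\n",
      "  reads in library A       ", f(x$reads_a), "\n",
      "  reads in library B       ", f(x$reads_b), "\n",
      "Number of contigs          ", f(x$n_contigs), "\n",
      "  mixed contigs            ", f(x$mixed), "\n",
      "  A-only contigs           ", f(x$a_only), "\n",
      "  B-only contigs           ", f(x$b_only), "\n", sep = "")
  invisible(x)
}

#' Call per-contig enrichment between two libraries
#'
#' Applies the exact conditional test to every mixed contig (and, when
#' `config$include_exclusive` is set, to library-exclusive contigs too),
#' assigns a direction from the normalized rates, and flags contigs passing
#' the significance cutoff and the robust magnitude filter. Output rows are
#' in input order.
#'
#' @param table Data frame with columns `contig_id`, `count_a`, `count_b`.
#' @param sizes A [library_sizes()] object.
#' @param config An [enrichment_config()] object.
#' @return A data frame of class `enrichment_calls` with columns
#'   `contig_id`, `partition`, `count_a`, `count_b`, `rate_a`, `rate_b`,
#'   `fold`, `p_value`, `direction`, `enriched`, `robust`, `robust_by`.
#'   Untested exclusive contigs have `p_value = NA` and `enriched = FALSE`.
#' @export
call_enrichment <- function(table, sizes, config = enrichment_config()) {
  if (!inherits(config, "enrichment_config"))
    stop_config("config must be an enrichment_config object")
  if (nrow(table) == 0L) {
    return(structure(data.frame(contig_id = character(), partition = character(),
                                count_a = integer(), count_b = integer(),
                                rate_a = numeric(), rate_b = numeric(),
                                fold = numeric(), p_value = numeric(),
                                direction = character(), enriched = logical(),
                                robust = logical(), robust_by = character()),
                     class = c("enrichment_calls", "data.frame")))
  }
  part <- classify_partition(table)$partition
  x <- table$count_a
  y <- table$count_b
  rate_a <- x / sizes$n_a
  rate_b <- y / sizes$n_b
  fold <- fold_enrichment(x, y, sizes)
  direction <- ifelse(rate_a > rate_b, "A", ifelse(rate_b > rate_a, "B", "none"))

  tested <- if (config$include_exclusive) rep(TRUE, length(x)) else part == "mixed"
  p <- rep(NA_real_, length(x))
  if (any(tested))
    p[tested] <- ac_pvalue(x[tested], y[tested], sizes, config$sidedness)
  p_cut <- p
  if (config$p_adjust == "BH")
    p_cut[tested] <- stats::p.adjust(p[tested], method = "BH")
  enriched <- !is.na(p_cut) & p_cut < config$alpha & direction != "none"

  pass_fold <- fold >= config$robust_min_fold
  pass_reads <- pmax(x, y) > config$robust_min_reads
  pass <- switch(config$robust_rule,
                 fold = pass_fold,
                 reads = pass_reads,
                 either = pass_fold | pass_reads)
  robust <- enriched & pass
  robust_by <- ifelse(!robust, "",
                      ifelse(pass_fold & pass_reads, "fold+reads",
                             ifelse(pass_fold, "fold", "reads")))

  structure(data.frame(contig_id = table$contig_id, partition = part,
                       count_a = x, count_b = y,
                       rate_a = rate_a, rate_b = rate_b, fold = fold,
                       p_value = p, direction = direction,
                       enriched = enriched, robust = robust,
                       robust_by = robust_by,
                       stringsAsFactors = FALSE),
            class = c("enrichment_calls", "data.frame"),
            config = config, sizes = sizes)
}

#' Robust candidate subset of enrichment calls
#'
#' Filters calls to those that are significant at `config$alpha` and pass
#' the configured magnitude rule: `fold` (normalized fold enrichment at
#' least `robust_min_fold`), `reads` (larger count above
#' `robust_min_reads`), or `either` (the union). The result is always a
#' subset of the enriched calls.
#'
#' @param calls Output of [call_enrichment()].
#' @param config An [enrichment_config()]; defaults to the configuration
#'   the calls were made with.
#' @return The filtered rows of `calls`.
#' @export
robust_candidates <- function(calls, config = attr(calls, "config")) {
  if (is.null(config)) config <- enrichment_config()
  if (!inherits(config, "enrichment_config"))
    stop_config("config must be an enrichment_config object")
  keep <- !is.na(calls$p_value) & calls$p_value < config$alpha &
    calls$direction != "none"
  pass_fold <- calls$fold >= config$robust_min_fold
  pass_reads <- pmax(calls$count_a, calls$count_b) > config$robust_min_reads
  pass <- switch(config$robust_rule,
                 fold = pass_fold,
                 reads = pass_reads,
                 either = pass_fold | pass_reads,
                 stop_config("unknown robust rule: ", config$robust_rule))
  calls[keep & pass, , drop = FALSE]
}
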