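# End-to-end pipeline: counting -> enrichment testing -> robust filtering
# -> keyword prediction, with optional CEG coverage and qPCR arms, plus a
# provenance record sufficient to reproduce every output.

#' Pipeline configuration
#'
#' @param counts Path to the two-library count TSV (required).
#' @param annotations Optional annotation TSV for keyword prediction.
#' @param ceg_hits Optional CEG hit TSV.
#' @param ceg_ref Optional CEG reference YAML; defaults to the packaged
#'   CEG-248 category sizes.
#' @param ct Optional qPCR CT TSV.
#' @param ct_calibrator Calibrator group/sample for [ddct_rq()].
#' @param out_dir Output directory (created if absent).
#' @param enrichment An [enrichment_config()].
#' @param keywords Keyword set for annotation mining.
#' @param keyword_mode `"word"` or `"substring"`.
#' @param seed Integer recorded in provenance (the analysis itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, annotations = NULL, ceg_hits = NULL,
                            ceg_ref = NULL, ct = NULL,
                            ct_calibrator = NULL, out_dir,
                            enrichment = enrichment_config(),
                            keywords = sex_keywords(),
                            keyword_mode = c("word", "substring"),
                            seed = 1L) {
  keyword_mode <- match.arg(keyword_mode)
  if (missing(counts) || is.null(counts))
    stop_config("pipeline stage 'counts': no count table configured")
  if (missing(out_dir) || is.null(out_dir))
    stop_config("pipeline stage 'output': no output directory configured")
  structure(list(counts = counts, annotations = annotations,
                 ceg_hits = ceg_hits, ceg_ref = ceg_ref, ct = ct,
                 ct_calibrator = ct_calibrator, out_dir = out_dir,
                 enrichment = enrichment, keywords = keywords,
                 keyword_mode = keyword_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full two-library analysis pipeline
#'
#' Stages: read counts; partition accounting; enrichment calling; robust
#' candidate filtering; keyword-based prediction (if annotations given),
#' with a flag marking predicted candidates that are also robust; CEG
#' coverage (if hits given); qPCR quantification (if CTs given). Each
#' stage's result is written as TSV under `config$out_dir`, plus a JSON
#' provenance record of all inputs and thresholds. Any stage failure
#' aborts with a stage-named error and removes the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory results and the written
#'   file paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must be a pipeline_config object")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, writer, obj) {
    p <- file.path(config$out_dir, name)
    writer(obj, p)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop_input("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  counts <- stage("counts", read_count_table(config$counts))
  if (is.null(counts$sizes))
    stop_input("pipeline stage 'counts' failed: table has no data rows")
  part <- stage("partition", classify_partition(counts$counts))
  calls <- stage("enrichment",
                 call_enrichment(counts$counts, counts$sizes, config$enrichment))
  robust <- stage("robust", robust_candidates(calls, config$enrichment))
  emit("partition_summary.tsv", write_partition_summary, part$summary)
  emit("enrichment_calls.tsv", write_enrichment_calls, calls)
  emit("robust_candidates.tsv", write_enrichment_calls, robust)

  results <- list(summary = part$summary, calls = calls, robust = robust)

  if (!is.null(config$annotations)) {
    ann <- stage("annotation", read_annotation_table(config$annotations))
    sel <- stage("annotation",
                 keyword_select(ann, config$keywords, config$keyword_mode))
    sel$robust_enriched <- sel$contig_id %in% robust$contig_id
    emit("keyword_candidates.tsv", function(obj, p)
      utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE),
      sel)
    results$keyword_candidates <- sel
  }

  if (!is.null(config$ceg_hits)) {
    ref <- stage("ceg", if (is.null(config$ceg_ref)) ceg_reference()
                        else read_ceg_reference(config$ceg_ref))
    rep <- stage("ceg", coverage_from_hits(read_ceg_hits(config$ceg_hits), ref))
    emit("ceg_report.tsv", function(obj, p) {
      utils::write.table(
        data.frame(category = c(names(obj$category_hits), "total"),
                   hits = c(obj$category_hits, obj$total_hits),
                   n_genes = c(obj$category_sizes, obj$total_genes),
                   coverage_percent = c(100 * obj$category_hits / obj$category_sizes,
                                        obj$coverage_percent)),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, rep)
    results$ceg <- rep
  }

  if (!is.null(config$ct)) {
    cal <- config$ct_calibrator
    if (is.null(cal)) stop_input("pipeline stage 'qpcr' failed: no calibrator")
    ct <- stage("qpcr", read_ct_table(config$ct))
    rqs <- stage("qpcr", ddct_rq(ct, cal))
    cmp <- stage("qpcr", compare_groups(rqs))
    emit("qpcr_rq.tsv", function(obj, p)
      utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE),
      rqs)
    emit("qpcr_comparison.tsv", function(obj, p)
      utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE),
      cmp)
    results$qpcr <- list(rq = rqs, comparison = cmp)
  }

  prov <- list(
    package = "twolibde",
    version = as.character(utils::packageVersion("twolibde")),
    # no timestamp: outputs are byte-identical across reruns of one config
    seed = config$seed,
    inputs = Filter(Negate(is.null),
                    list(counts = config$counts,
                         annotations = config$annotations,
                         ceg_hits = config$ceg_hits, ct = config$ct)),
    enrichment = unclass(config$enrichment),
    library_sizes = unclass(counts$sizes),
    keywords = config$keywords,
    keyword_mode = config$keyword_mode)
  pp <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, pp, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, pp)

  invisible(c(results, list(files = written)))
}
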