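#' Configuration for an end-to-end keyness run
#'
#' @param narratives Path to the narrative-level CSV.
#' @param tokens Path to the token-level CoNLL-U file.
#' @param reference Path to the reference-corpus lemma frequency export
#'   (two-column TSV).
#' @param stopwords Path to the stopword file; `NULL` uses the packaged
#'   reconstruction.
#' @param alpha Family-wise error level, default 0.01.
#' @param tail Tail convention for the Bonferroni threshold.
#' @param top_k Rows per panel in the report, default 50.
#' @param out_dir Output directory for result artifacts.
#' @param filter_reference_stopwords Apply the stopword list to the
#'   reference frequency list too (default `TRUE`).
#' @param near_dup_threshold Near-duplicate Jaccard threshold passed to
#'   [filter_participants()].
#' @param seed Seed recorded in the run metadata.
#' @return A `run_config` list.
#' @export
run_config <- function(narratives, tokens, reference, stopwords = NULL,
                       alpha = 0.01, tail = c("one-sided", "two-sided"),
                       top_k = 50L, out_dir = tempfile("keyness-run-"),
                       filter_reference_stopwords = TRUE,
                       near_dup_threshold = 0.9, seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(alpha > 0, alpha < 1, top_k >= 1)
  if (is.null(stopwords)) {
    stopwords <- system.file("extdata", "stopwords_uk.txt", package = "warkeys")
  }
  structure(list(narratives = narratives, tokens = tokens,
                 reference = reference, stopwords = stopwords, alpha = alpha,
                 tail = tail, top_k = as.integer(top_k), out_dir = out_dir,
                 filter_reference_stopwords = filter_reference_stopwords,
                 near_dup_threshold = near_dup_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full keyness pipeline
#'
#' Executes: participant filtering -> token restriction to retained
#' narratives -> stopword removal -> lemma counting -> zero-filled merge
#' with the reference list -> LORIDP scoring -> Bonferroni threshold ->
#' key selection -> artifact writing. Per-stage record counts are logged to
#' a `stage_log` and echoed with `message()` when `verbose`.
#'
#' @param config A [run_config()].
#' @param verbose Emit per-stage messages? Default `TRUE`.
#' @return A `keyness_run` (see [keyness_run()]) with extra elements
#'   `stage_log` (tibble), `summary` (a `corpus_summary`) and `paths`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  input_stage <- c(narratives = "ingest", tokens = "ingest",
                   reference = "count", stopwords = "preprocess")
  for (p in names(input_stage)) {
    if (!file.exists(config[[p]])) {
      stop("pipeline stage '", input_stage[[p]], "' failed: input file not found: ",
           config[[p]], call. = FALSE)
    }
  }
  log_rows <- list()
  note <- function(stage_name, what, n) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      stage = stage_name, quantity = what, n = as.double(n))
    if (verbose) message(sprintf("[%s] %s: %s", stage_name, what,
                                 format(n, big.mark = ",")))
  }

  stopword_lemmas <- stage("preprocess", read_stopwords(config$stopwords))
  note("preprocess", "stopword lemmas", length(stopword_lemmas))

  records <- stage("ingest", read_narrative_table(config$narratives))
  note("ingest", "narrative rows read", nrow(records))
  note("ingest", "rows quarantined", nrow(attr(records, "quarantined")))

  filt <- stage("filter", filter_participants(records, config$near_dup_threshold))
  note("filter", "participants retained", nrow(filt$retained))
  note("filter", "participants excluded", nrow(filt$exclusions))

  tokens <- stage("ingest", read_token_table(config$tokens))
  note("ingest", "token rows read", nrow(tokens))
  tokens <- tokens[tokens$doc_id %in% filt$retained$doc_id, , drop = FALSE]
  note("filter", "tokens in retained narratives", nrow(tokens))

  kept <- stage("preprocess", remove_stopwords(tokens, stopword_lemmas))
  note("preprocess", "tokens after stopword removal", nrow(kept))

  target_tab <- stage("count", count_lemmas(kept, "target"))
  note("count", "distinct target lemmas", length(target_tab$counts))

  ref_tab <- stage("count", read_frequency_list(
    config$reference, "reference",
    stopword_lemmas = if (config$filter_reference_stopwords) stopword_lemmas))
  note("count", "distinct reference lemmas", length(ref_tab$counts))

  combined <- stage("merge", merge_tables(target_tab, ref_tab))
  note("merge", "combined lemmas", nrow(combined))

  run <- stage("keyness", keyness_run(combined, alpha = config$alpha,
                                      tail = config$tail))
  note("keyness", "target-diagnostic keys", nrow(run$target_keys))
  note("keyness", "reference-diagnostic keys", nrow(run$reference_keys))

  summary <- stage("summary", summarize_corpus(filt$retained, tokens,
                                               stopword_lemmas))

  run$stage_log <- dplyr::bind_rows(log_rows)
  run$summary <- summary
  run$exclusions <- filt$exclusions
  run$config <- config
  run$paths <- stage("report", write_run_artifacts(run, config))
  run
}

write_run_artifacts <- function(run, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    results = file.path(config$out_dir, "keyness_results.tsv"),
    target_top = file.path(config$out_dir, "top_target_keys.tsv"),
    reference_top = file.path(config$out_dir, "top_reference_keys.tsv"),
    meta = file.path(config$out_dir, "run_meta.json"),
    exclusions = file.path(config$out_dir, "exclusions.jsonl"),
    plot_data = file.path(config$out_dir, "plot_data.tsv")
  )
  write_keyness_results(run, paths$results)
  readr::write_tsv(top_k_table(run$target_keys, config$top_k),
                   paths$target_top, progress = FALSE)
  readr::write_tsv(top_k_table(run$reference_keys, config$top_k),
                   paths$reference_top, progress = FALSE)
  write_exclusion_log(run$exclusions, paths$exclusions)
  rep <- render_report(run, config$top_k)
  readr::write_tsv(rep$plot_data, paths$plot_data, progress = FALSE)
  jsonlite::write_json(
    list(alpha = run$alpha, m = run$m, threshold_z = run$threshold_z,
         tail_convention = run$tail, top_k = config$top_k, seed = config$seed,
         n_target_keys = nrow(run$target_keys),
         n_reference_keys = nrow(run$reference_keys),
         timestamp = format(Sys.time(), tz = "UTC")),
    paths$meta, auto_unbox = TRUE, digits = NA)
  paths
}

#' Write the per-lemma results table
#'
#' Tab-separated columns: lemma, y_target, y_reference, delta, variance, z,
#' significant, rank. Run metadata belongs in the JSON sidecar written by
#' [run_pipeline()].
#'
#' @param run A `keyness_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keyness_results <- function(run, path) {
  readr::write_tsv(run$results, path, progress = FALSE)
  invisible(path)
}

#' Render the two-panel top-k report
#'
#' Produces the ranked target-diagnostic and reference-diagnostic tables and
#' a long-format plot-data tibble `(panel, rank, lemma, abs_z)` suitable for
#' a two-panel ranked bar chart (absolute z on the x-axis, rank on the
#' y-axis).
#'
#' @param run A `keyness_run`.
#' @param k Rows per panel.
#' @param gloss_map Optional named character vector of lemma translations.
#' @return List with `target_table`, `reference_table`, `plot_data`, `text`
#'   (character vector of report lines).
#' @export
render_report <- function(run, k = 50L, gloss_map = NULL) {
  stopifnot(inherits(run, "keyness_run"))
  tt <- top_k_table(run$target_keys, k, gloss_map)
  rt <- top_k_table(run$reference_keys, k, gloss_map)
  plot_data <- dplyr::bind_rows(
    dplyr::mutate(tt, panel = "target", .before = 1),
    dplyr::mutate(rt, panel = "reference", .before = 1)
  )[, c("panel", "rank", "lemma", "abs_z")]

  fmt_panel <- function(tab, title) {
    if (nrow(tab) == 0L) return(c(title, "  (no significant keys)"))
    c(title, sprintf("  %3d. %-24s |z| = %.2f%s", tab$rank, tab$lemma,
                     tab$abs_z,
                     ifelse(tab$gloss == "", "", paste0("  (", tab$gloss, ")"))))
  }
  text <- c(
    sprintf("Keyness run: %d lemmas tested, |z| threshold %.2f (alpha = %g, %s)",
            run$m, run$threshold_z, run$alpha, run$tail),
    sprintf("Significant keys: %d target-diagnostic, %d reference-diagnostic",
            nrow(run$target_keys), nrow(run$reference_keys)),
    "",
    fmt_panel(tt, sprintf("Top %d target-diagnostic lemmas:", nrow(tt))),
    "",
    fmt_panel(rt, sprintf("Top %d reference-diagnostic lemmas:", nrow(rt)))
  )
  list(target_table = tt, reference_table = rt, plot_data = plot_data,
       text = text)
}
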