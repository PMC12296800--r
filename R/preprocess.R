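#' Construct a lemma frequency table
#'
#' A `frequency_table` holds the lemma counts of one corpus together with its
#' token total \eqn{n}. Zero counts are never stored: absence means zero.
#'
#' @param counts Named non-negative integer vector (names are lemmas) or an
#'   empty vector.
#' @param corpus_label Label used in messages and output files.
#' @return A `frequency_table` object.
#' @export
frequency_table <- function(counts, corpus_label = "corpus") {
  counts <- counts[counts > 0]
  if (length(counts) && (is.null(names(counts)) || anyNA(names(counts)))) {
    stop("counts must be a named vector", call. = FALSE)
  }
  if (any(counts != as.integer(counts))) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"  # totals can exceed .Machine$integer.max
  structure(
    list(corpus_label = corpus_label, counts = counts,
         total_tokens = sum(counts)),
    class = "frequency_table"
  )
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> '", x$corpus_label, "': ",
      length(x$counts), " distinct lemmas, ",
      format(x$total_tokens, big.mark = ","), " tokens\n", sep = "")
  invisible(x)
}

#' Count lemma frequencies in a token table
#'
#' Lemmas are normalized ([normalize_lemma()]: NFC, apostrophe unification,
#' case folding) before counting, so inflectional case variants of the same
#' citation form collapse. A token whose lemma is empty is counted under its
#' case-folded surface form; the number of such fallbacks is recorded in the
#' `empty_lemma_fallbacks` attribute.
#'
#' @param tokens Token tibble (see [read_token_table()]); only `lemma` and
#'   `form` are used.
#' @param corpus_label Label for the resulting table.
#' @return A [frequency_table()].
#' @export
count_lemmas <- function(tokens, corpus_label = "corpus") {
  if (nrow(tokens) == 0L) {
    tab <- frequency_table(integer(0), corpus_label)
    attr(tab, "empty_lemma_fallbacks") <- 0L
    return(tab)
  }
  lem <- normalize_lemma(tokens$lemma)
  empty <- is.na(lem) | lem == ""
  if (any(empty)) lem[empty] <- normalize_lemma(tokens$form[empty])
  cnt <- table(lem)
  out <- frequency_table(stats::setNames(as.integer(cnt), names(cnt)),
                         corpus_label)
  attr(out, "empty_lemma_fallbacks") <- sum(empty)
  out
}

#' Remove punctuation, closed-class and stopword tokens
#'
#' A token is dropped iff its POS tag is `PUNCT`, or its POS tag is in
#' `closed_class_pos`, or its normalized lemma is in `stopword_lemmas`.
#' Order is preserved; the number dropped is recorded in the `n_dropped`
#' attribute. Idempotent.
#'
#' @param tokens Token tibble.
#' @param stopword_lemmas Character vector of stopword lemmas (normalized
#'   internally).
#' @param closed_class_pos Universal POS tags treated as function words.
#' @return Filtered token tibble.
#' @export
remove_stopwords <- function(tokens,
                             stopword_lemmas = character(),
                             closed_class_pos = c("ADP", "PRON", "CCONJ",
                                                  "SCONJ", "PART", "DET",
                                                  "AUX")) {
  if (nrow(tokens) == 0L) {
    attr(tokens, "n_dropped") <- 0L
    return(tokens)
  }
  stop_set <- unique(normalize_lemma(stopword_lemmas))
  drop <- tokens$upos == "PUNCT" |
    tokens$upos %in% closed_class_pos |
    normalize_lemma(tokens$lemma) %in% stop_set
  out <- tokens[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Merge two frequency tables into the combined table the statistic consumes
#'
#' Takes the union of the two lemma sets, zero-filling lemmas absent from one
#' corpus, and attaches the Dirichlet prior quantities: per-lemma
#' \eqn{\alpha_w = y^i_w + y^j_w} and global \eqn{\alpha_0 = n^i + n^j}.
#' Rows are ordered by descending pooled count, ties alphabetical.
#'
#' @param target,reference [frequency_table()] objects; both must be
#'   non-empty (the statistic is undefined otherwise).
#' @return A `combined_lemma_table`: tibble with columns `lemma`, `y_target`,
#'   `y_reference`, `alpha_w` and attributes `n_target`, `n_reference`,
#'   `alpha_0`.
#' @export
merge_tables <- function(target, reference) {
  stopifnot(inherits(target, "frequency_table"),
            inherits(reference, "frequency_table"))
  if (length(target$counts) == 0L || length(reference$counts) == 0L) {
    stop("merge_tables: both frequency tables must be non-empty", call. = FALSE)
  }
  lemmas <- union(names(target$counts), names(reference$counts))
  y_i <- unname(target$counts[lemmas]); y_i[is.na(y_i)] <- 0
  y_j <- unname(reference$counts[lemmas]); y_j[is.na(y_j)] <- 0
  ord <- order(-(y_i + y_j), lemmas, method = "radix")
  out <- tibble::tibble(
    lemma = lemmas[ord],
    y_target = y_i[ord],
    y_reference = y_j[ord],
    alpha_w = (y_i + y_j)[ord]
  )
  attr(out, "n_target") <- target$total_tokens
  attr(out, "n_reference") <- reference$total_tokens
  attr(out, "alpha_0") <- target$total_tokens + reference$total_tokens
  class(out) <- c("combined_lemma_table", class(out))
  out
}

#' De-identify a narrative by tagging person and place names
#'
#' Every whole-word occurrence of any alias of a supplied entity is replaced
#' by a tag. If exactly one distinct entity of a kind occurs in the text its
#' tag is unindexed (`[NAME]`, `[CITY]`); if several occur, tags are indexed
#' `[NAME1]`, `[NAME2]`, ... in order of first appearance and reused
#' consistently throughout the narrative.
#'
#' @param text A single character string.
#' @param entities A data frame / tibble with columns `entity_id`, `kind`
#'   (`"person"` or `"place"`) and `alias` (one row per alias), or a list of
#'   `list(entity_id=, kind=, aliases=)`.
#' @return A list with `text` (tagged) and `log`, a tibble of replacements
#'   `(entity_id, kind, tag, n_replaced)`.
#' @export
deidentify <- function(text, entities) {
  stopifnot(is.character(text), length(text) == 1L)
  ent <- as_entity_tbl(entities)
  if (nrow(ent) == 0L) {
    return(list(text = text,
                log = tibble::tibble(entity_id = character(), kind = character(),
                                     tag = character(), n_replaced = integer())))
  }
  if (any(ent$alias == "")) stop("alias lists must be non-empty", call. = FALSE)
  dup <- ent$alias[duplicated(paste(ent$kind, normalize_lemma(ent$alias)))]
  if (length(dup)) {
    stop("ambiguous aliases shared across entities: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  pat <- function(alias) paste0("\\b", stringi::stri_replace_all_regex(
    alias, "([.^$*+?()\\[\\]{}|\\\\])", "\\\\$1"), "\\b")

  # first occurrence position per entity decides tag indexing
  ent$pos <- vapply(ent$alias, function(a) {
    p <- stringi::stri_locate_first_regex(text, pat(a),
                                          opts_regex = list(case_insensitive = TRUE))[1, 1]
    if (is.na(p)) Inf else as.double(p)
  }, numeric(1))
  first_pos <- tapply(ent$pos, ent$entity_id, min)
  present <- names(first_pos)[is.finite(first_pos)]
  kind_of <- ent$kind[match(present, ent$entity_id)]

  tag_for <- character(0)
  for (k in unique(kind_of)) {
    ids <- present[kind_of == k]
    ids <- ids[order(first_pos[ids])]
    base <- if (k == "person") "NAME" else "CITY"
    tags <- if (length(ids) == 1L) paste0("[", base, "]") else
      paste0("[", base, seq_along(ids), "]")
    tag_for[ids] <- tags
  }

  log_rows <- list()
  # replace longer aliases first so multiword aliases win over substrings
  ent_present <- ent[is.finite(ent$pos), , drop = FALSE]
  ent_present <- ent_present[order(-nchar(ent_present$alias)), , drop = FALSE]
  for (r in seq_len(nrow(ent_present))) {
    a <- ent_present[r, ]
    n_before <- stringi::stri_count_regex(text, pat(a$alias),
                                          opts_regex = list(case_insensitive = TRUE))
    if (n_before > 0) {
      text <- stringi::stri_replace_all_regex(
        text, pat(a$alias), tag_for[[a$entity_id]],
        opts_regex = list(case_insensitive = TRUE))
    }
    log_rows[[r]] <- tibble::tibble(entity_id = a$entity_id, kind = a$kind,
                                    tag = tag_for[[a$entity_id]],
                                    n_replaced = n_before)
  }
  log <- dplyr::bind_rows(log_rows)
  if (nrow(log) == 0L) {
    log <- tibble::tibble(entity_id = character(), kind = character(),
                          tag = character(), n_replaced = integer())
  } else {
    log <- dplyr::summarise(
      dplyr::group_by(log, .data$entity_id, .data$kind, .data$tag),
      n_replaced = sum(.data$n_replaced), .groups = "drop")
    log <- log[log$n_replaced > 0, , drop = FALSE]
  }
  list(text = text, log = log)
}

as_entity_tbl <- function(entities) {
  if (is.data.frame(entities)) {
    stopifnot(all(c("entity_id", "kind", "alias") %in% names(entities)))
    return(tibble::as_tibble(entities[c("entity_id", "kind", "alias")]))
  }
  if (length(entities) == 0L) {
    return(tibble::tibble(entity_id = character(), kind = character(),
                          alias = character()))
  }
  purrr::map_dfr(entities, function(e) {
    if (length(e$aliases %||% character()) == 0L) {
      stop("alias lists must be non-empty", call. = FALSE)
    }
    tibble::tibble(entity_id = e$entity_id, kind = e$kind, alias = e$aliases)
  })
}

#' Read a stopword file
#'
#' One lemma per line, UTF-8; `#` starts a comment; blank lines ignored.
#' The package ships a reconstructed Ukrainian closed-class list at
#' `system.file("extdata", "stopwords_uk.txt", package = "warkeys")`.
#'
#' @param path Path to the stopword file.
#' @return Character vector of normalized stopword lemmas.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) stop("stopword file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- stringi::stri_replace_all_regex(lines, "#.*$", "")
  lines <- stringi::stri_trim_both(lines)
  unique(normalize_lemma(lines[lines != ""]))
}

#' Read a reference-corpus lemma frequency export
#'
#' Two tab-separated columns (lemma, count), UTF-8, optional `#` comment
#' lines, no header — the layout of a corpus-interface frequency-list export.
#'
#' @param path Path to the file.
#' @param corpus_label Label for the resulting table.
#' @param stopword_lemmas Optional stopword lemmas to drop from the list
#'   before building the table (applied to normalized lemmas).
#' @return A [frequency_table()].
#' @export
read_frequency_list <- function(path, corpus_label = "reference",
                                stopword_lemmas = NULL) {
  df <- readr::read_tsv(path, col_names = c("lemma", "count"),
                        col_types = readr::cols(lemma = "c", count = "d"),
                        comment = "#", progress = FALSE)
  lem <- normalize_lemma(df$lemma)
  cnt <- tapply(df$count, lem, sum)  # normalization can merge case variants
  counts <- stats::setNames(as.vector(cnt), names(cnt))
  if (!is.null(stopword_lemmas)) {
    counts <- counts[!(names(counts) %in% unique(normalize_lemma(stopword_lemmas)))]
  }
  frequency_table(counts, corpus_label)
}

#' Write a frequency table as a two-column export
#'
#' @param table A [frequency_table()].
#' @param path Output path (tab-separated lemma, count; descending count).
#' @return `path`, invisibly.
#' @export
write_frequency_list <- function(table, path) {
  stopifnot(inherits(table, "frequency_table"))
  cnt <- table$counts
  ord <- order(-cnt, names(cnt), method = "radix")
  readr::write_lines(paste(names(cnt)[ord], format(cnt[ord], scientific = FALSE,
                                                   trim = TRUE), sep = "\t"),
                     path)
  invisible(path)
}
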