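NARRATIVE_COLUMNS <- c("doc_id", "age", "gender", "marital_status", "education",
                       "region", "occupation_status", "displaced",
                       "trauma_history", "submission_date", "pcl5_total",
                       "miss_total", "consent", "text_original",
                       "text_translation", "original_language")

CATEGORICAL_FIELDS <- list(
  gender = c("man", "woman", "other"),
  marital_status = c("single", "married", "in-a-relationship"),
  education = c("secondary", "college", "bachelor", "master-or-phd"),
  occupation_status = c("never-occupied", "occupied", "de-occupied"),
  trauma_history = c("holocaust", "holodomor", "none", "other")
)

#' Table dialect for the narrative-level release format
#'
#' The narrative table is UTF-8, delimited (comma by default), quoted, with a
#' header row. Synonym-to-canonical mappings for the categorical fields are
#' read from an editable CSV config (columns `field`, `synonym`,
#' `canonical`); the packaged default covers the spellings seen in
#' typical questionnaire exports (e.g., `"Master or PhD"` ->
#' `"master-or-phd"`).
#'
#' @param delimiter Field separator, default `","`.
#' @param canonical_map Path to the synonym config CSV, or a tibble with
#'   those three columns. `NULL` uses the packaged default.
#' @return A list used by [read_narrative_table()] / [write_narrative_table()].
#' @export
narrative_dialect <- function(delimiter = ",", canonical_map = NULL) {
  if (is.null(canonical_map)) {
    canonical_map <- system.file("extdata", "canonical_levels.csv",
                                 package = "warkeys")
  }
  if (is.character(canonical_map)) {
    canonical_map <- readr::read_csv(
      canonical_map, col_types = readr::cols(.default = "c"), progress = FALSE)
  }
  stopifnot(all(c("field", "synonym", "canonical") %in% names(canonical_map)))
  list(delimiter = delimiter, canonical_map = tibble::as_tibble(canonical_map))
}

canonicalize_field <- function(x, field, map) {
  m <- map[map$field == field, , drop = FALSE]
  key <- normalize_narrative(x)
  hit <- m$canonical[match(key, normalize_narrative(m$synonym))]
  # canonical levels map to themselves even if missing from the config
  hit[is.na(hit) & key %in% CATEGORICAL_FIELDS[[field]]] <-
    key[is.na(hit) & key %in% CATEGORICAL_FIELDS[[field]]]
  out <- ifelse(is.na(hit), x, hit)
  out[is.na(x) | x == ""] <- NA_character_
  list(value = out, nonstandard = !is.na(out) & !(out %in% CATEGORICAL_FIELDS[[field]]))
}

parse_doc_id <- function(x) {
  x <- stringi::stri_trim_both(as.character(x))
  x <- stringi::stri_replace_first_regex(x, "^doc", "",
                                         opts_regex = list(case_insensitive = TRUE))
  suppressWarnings(as.integer(x))
}

parse_logical_field <- function(x) {
  key <- normalize_narrative(as.character(x))
  out <- rep(NA, length(x))
  out[key %in% c("true", "yes", "1", "t", "y", "так")] <- TRUE
  out[key %in% c("false", "no", "0", "f", "n", "ні")] <- FALSE
  out
}

#' Read the narrative-level release table
#'
#' One row per participant: demographics, status flags, psychometric totals,
#' submission date and the narrative text (original plus optional
#' translation). Categorical fields are mapped to canonical levels via the
#' dialect's synonym config; unrecognized values are preserved and flagged.
#' Rows whose age or psychometric totals cannot be validated (unparseable
#' age; PCL-5 outside 0-80; MISS outside 10-100) are quarantined rather than
#' read into the main table.
#'
#' @param path Path to the delimited file.
#' @param dialect A [narrative_dialect()].
#' @return A tibble with the canonical narrative columns, plus attributes:
#'   `quarantined` (tibble of rejected rows with a `problem` column) and
#'   `nonstandard` (tibble `row`, `field`, `value` of preserved unknown
#'   categorical values, also signalled as a warning).
#' @export
read_narrative_table <- function(path, dialect = narrative_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = dialect$delimiter,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE, na = character())
  missing_cols <- setdiff(NARRATIVE_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("narrative table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  empty_attrs <- function(tbl) {
    attr(tbl, "quarantined") <- tibble::tibble(row = integer(), doc_id = integer(),
                                               problem = character())
    attr(tbl, "nonstandard") <- tibble::tibble(row = integer(), field = character(),
                                               value = character())
    tbl
  }
  if (nrow(raw) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      replicate(length(NARRATIVE_COLUMNS), character(0), simplify = FALSE),
      NARRATIVE_COLUMNS))
    out$doc_id <- integer(0); out$age <- integer(0)
    out$displaced <- logical(0); out$consent <- logical(0)
    out$pcl5_total <- integer(0); out$miss_total <- integer(0)
    out$submission_date <- as.Date(character(0))
    return(empty_attrs(out))
  }

  blank_to_na <- function(x) ifelse(x == "", NA_character_, x)
  out <- tibble::tibble(
    doc_id = parse_doc_id(raw$doc_id),
    age = suppressWarnings(as.integer(stringi::stri_trim_both(raw$age))),
    gender = raw$gender, marital_status = raw$marital_status,
    education = raw$education, region = blank_to_na(raw$region),
    occupation_status = raw$occupation_status,
    displaced = parse_logical_field(raw$displaced),
    trauma_history = raw$trauma_history,
    submission_date = suppressWarnings(as.Date(raw$submission_date)),
    pcl5_total = suppressWarnings(as.integer(stringi::stri_trim_both(raw$pcl5_total))),
    miss_total = suppressWarnings(as.integer(stringi::stri_trim_both(raw$miss_total))),
    consent = parse_logical_field(raw$consent),
    text_original = raw$text_original,
    text_translation = blank_to_na(raw$text_translation),
    original_language = blank_to_na(raw$original_language)
  )

  nonstandard <- list()
  for (f in names(CATEGORICAL_FIELDS)) {
    cf <- canonicalize_field(out[[f]], f, dialect$canonical_map)
    out[[f]] <- cf$value
    if (any(cf$nonstandard)) {
      nonstandard[[f]] <- tibble::tibble(row = which(cf$nonstandard), field = f,
                                         value = cf$value[cf$nonstandard])
    }
  }
  nonstandard <- dplyr::bind_rows(nonstandard)
  if (nrow(nonstandard %||% tibble::tibble())) {
    warning("non-canonical categorical value(s) preserved in field(s): ",
            paste(unique(nonstandard$field), collapse = ", "), call. = FALSE)
  }

  # row-level validation: unparseable age / out-of-range scores -> quarantine
  problem <- rep(NA_character_, nrow(out))
  age_given <- stringi::stri_trim_both(raw$age) != ""
  problem[is.na(problem) & age_given & is.na(out$age)] <- "unparseable age"
  score_given <- stringi::stri_trim_both(raw$pcl5_total) != ""
  bad <- score_given & (is.na(out$pcl5_total) | out$pcl5_total < 0 | out$pcl5_total > 80)
  problem[is.na(problem) & bad] <- "pcl5_total outside 0-80 or unparseable"
  score_given <- stringi::stri_trim_both(raw$miss_total) != ""
  bad <- score_given & (is.na(out$miss_total) | out$miss_total < 10 | out$miss_total > 100)
  problem[is.na(problem) & bad] <- "miss_total outside 10-100 or unparseable"
  problem[is.na(problem) & is.na(out$doc_id)] <- "unparseable doc_id"

  quarantined <- tibble::tibble(row = which(!is.na(problem)),
                                doc_id = out$doc_id[!is.na(problem)],
                                problem = problem[!is.na(problem)])
  out <- out[is.na(problem), , drop = FALSE]
  if (anyDuplicated(out$doc_id)) {
    stop("doc_id values are not unique: ",
         paste(utils::head(unique(out$doc_id[duplicated(out$doc_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  attr(out, "quarantined") <- quarantined
  attr(out, "nonstandard") <- if (nrow(nonstandard %||% tibble::tibble())) nonstandard else
    tibble::tibble(row = integer(), field = character(), value = character())
  out
}

#' Write the narrative-level release table
#'
#' Inverse of [read_narrative_table()]: writing a valid table and re-reading
#' it yields the identical records.
#'
#' @param records Narrative tibble.
#' @param path Output path.
#' @param dialect A [narrative_dialect()].
#' @return `path`, invisibly.
#' @export
write_narrative_table <- function(records, path, dialect = narrative_dialect()) {
  out <- records[NARRATIVE_COLUMNS]
  out$submission_date <- format(out$submission_date)
  readr::write_delim(out, path, delim = dialect$delimiter, quote = "needed",
                     na = "")
  invisible(path)
}

#' Read the token-level release table (CoNLL-U layout)
#'
#' Parses a CoNLL-U file whose comment lines carry the document, paragraph
#' and sentence structure (`# newdoc id = docN`, `# newpar`, `# sent_id`,
#' `# text`). Multiword-token range lines (`2-3`) are skipped and counted;
#' empty-node lines (`2.1`) likewise.
#'
#' @param path Path to the CoNLL-U file.
#' @return A tibble with columns `doc_id`, `paragraph_index`,
#'   `sentence_index`, `sentence_text`, `token_index`, `form`, `lemma`,
#'   `upos`, `morph`, `dep_relation`, `head_index`; attribute
#'   `n_skipped_ranges` counts skipped range/empty-node lines.
#' @export
read_token_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  empty_tbl <- tibble::tibble(
    doc_id = integer(), paragraph_index = integer(), sentence_index = integer(),
    sentence_text = character(), token_index = integer(), form = character(),
    lemma = character(), upos = character(), morph = character(),
    dep_relation = character(), head_index = integer())
  if (length(lines) == 0L) {
    attr(empty_tbl, "n_skipped_ranges") <- 0L
    return(empty_tbl)
  }

  is_comment <- startsWith(lines, "#")
  is_blank <- lines == ""
  is_token <- !is_comment & !is_blank

  # carry document / paragraph / sentence state down the file
  newdoc <- stringi::stri_match_first_regex(lines, "^# newdoc id = (\\S+)")[, 2]
  doc_at <- which(!is.na(newdoc))
  if (length(doc_at) == 0L && any(is_token)) {
    stop("token table has no '# newdoc id' line: doc_id is unknown",
         call. = FALSE)
  }
  carry <- function(marker_at, values, n) {
    idx <- findInterval(seq_len(n), marker_at)
    out <- rep(NA_character_, n)
    out[idx > 0] <- values[idx[idx > 0]]
    out
  }
  n <- length(lines)
  doc_of <- carry(doc_at, newdoc[doc_at], n)
  doc_id_of <- parse_doc_id(doc_of)

  newpar_at <- which(stringi::stri_detect_regex(lines, "^# newpar"))
  # paragraph/sentence counters restart at each document; single scan
  par_of <- integer(n); sent_of <- integer(n); text_of <- character(n)
  cur_par <- 0L; cur_sent <- 0L; cur_text <- NA_character_
  sent_text <- stringi::stri_match_first_regex(lines, "^# text = (.*)$")[, 2]
  sent_id <- stringi::stri_detect_regex(lines, "^# sent_id")
  for (i in seq_len(n)) {
    if (!is.na(newdoc[i])) { cur_par <- 0L; cur_sent <- 0L }
    if (i %in% newpar_at) cur_par <- cur_par + 1L
    if (sent_id[i]) { cur_sent <- cur_sent + 1L; cur_text <- NA_character_ }
    if (!is.na(sent_text[i])) cur_text <- sent_text[i]
    par_of[i] <- max(cur_par, 1L)
    sent_of[i] <- cur_sent
    text_of[i] <- cur_text
  }

  tok_lines <- lines[is_token]
  if (length(tok_lines) == 0L) {
    attr(empty_tbl, "n_skipped_ranges") <- 0L
    return(empty_tbl)
  }
  nf <- stringi::stri_count_fixed(tok_lines, "\t") + 1L
  if (any(nf != 10L)) {
    stop("malformed token line at line ", which(is_token)[which(nf != 10L)[1]],
         ": expected 10 tab-separated fields, found ", nf[nf != 10L][1],
         call. = FALSE)
  }
  fields <- stringi::stri_split_fixed(tok_lines, "\t", simplify = TRUE)
  is_range <- stringi::stri_detect_regex(fields[, 1], "^\\d+[-.]\\d+$")
  keep <- !is_range
  tok_which <- which(is_token)[keep]
  token_index <- suppressWarnings(as.integer(fields[keep, 1]))
  if (anyNA(token_index)) {
    stop("malformed token id at line ", which(is_token)[keep][which(is.na(token_index))[1]],
         call. = FALSE)
  }
  head_index <- suppressWarnings(as.integer(fields[keep, 7]))
  head_index[fields[keep, 7] == "_"] <- NA_integer_

  doc_id <- doc_id_of[tok_which]
  if (anyNA(doc_id)) {
    stop("token line before any parseable '# newdoc id': doc_id absent",
         call. = FALSE)
  }
  out <- tibble::tibble(
    doc_id = doc_id,
    paragraph_index = par_of[tok_which],
    sentence_index = sent_of[tok_which],
    sentence_text = text_of[tok_which],
    token_index = token_index,
    form = fields[keep, 2],
    lemma = fields[keep, 3],
    upos = fields[keep, 4],
    morph = fields[keep, 6],
    dep_relation = fields[keep, 8],
    head_index = head_index
  )
  attr(out, "n_skipped_ranges") <- sum(is_range)
  out
}

#' Write a token table in the CoNLL-U release layout
#'
#' @param tokens Token tibble (columns of [read_token_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_token_table <- function(tokens, path) {
  if (nrow(tokens) == 0L) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  ord <- order(tokens$doc_id, tokens$paragraph_index, tokens$sentence_index,
               tokens$token_index)
  tk <- tokens[ord, , drop = FALSE]
  sent_key <- paste(tk$doc_id, tk$sentence_index)
  new_sent <- !duplicated(sent_key)
  new_doc <- !duplicated(tk$doc_id)
  par_key <- paste(tk$doc_id, tk$paragraph_index)
  new_par <- !duplicated(par_key)

  tok_line <- paste(tk$token_index, tk$form, tk$lemma, tk$upos, "_",
                    ifelse(is.na(tk$morph) | tk$morph == "", "_", tk$morph),
                    ifelse(is.na(tk$head_index), "_", tk$head_index),
                    ifelse(is.na(tk$dep_relation) | tk$dep_relation == "", "_",
                           tk$dep_relation),
                    "_", "_", sep = "\t")
  header <- character(nrow(tk))
  header[new_sent] <- paste0(
    "# sent_id = ", tk$sentence_index[new_sent], "\n",
    "# text = ", ifelse(is.na(tk$sentence_text[new_sent]), "",
                        tk$sentence_text[new_sent]), "\n")
  header[new_par] <- paste0("# newpar\n", header[new_par])
  header[new_doc] <- paste0("# newdoc id = doc", tk$doc_id[new_doc], "\n",
                            header[new_doc])
  # blank line terminates each sentence
  trailer <- c(ifelse(new_sent[-1], "\n", ""), "\n")
  body <- paste0(header, tok_line, "\n", trailer)
  # write as a single string to keep the exact blank-line structure
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(body, collapse = ""), con, sep = "", useBytes = FALSE)
  invisible(path)
}

#' Apply the participant exclusion rules
#'
#' Retains records that (in this order of precedence for the logged reason):
#' gave consent; have a parseable age inside the 12-120 sanity band; are at
#' least 18; and are not a duplicate of an earlier narrative. Duplicates are
#' exact matches after NFC normalization, whitespace collapse and case
#' folding; near-duplicates are additionally flagged when the character
#' 5-gram Jaccard similarity to an earlier retained narrative reaches
#' `near_dup_threshold`. The first occurrence by `doc_id` is kept.
#'
#' @param records Narrative tibble ([read_narrative_table()]).
#' @param near_dup_threshold Jaccard threshold in (0, 1], or `NULL` to use
#'   only the exact rule. Default 0.9.
#' @return A list with `retained` (tibble) and `exclusions` (tibble
#'   `doc_id`, `reason` with reasons `consent`, `invalid-age`, `underage`,
#'   `duplicate`).
#' @export
filter_participants <- function(records, near_dup_threshold = 0.9) {
  empty_log <- tibble::tibble(doc_id = integer(), reason = character())
  if (nrow(records) == 0L) {
    return(list(retained = records, exclusions = empty_log))
  }
  records <- records[order(records$doc_id), , drop = FALSE]
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$consent) | !records$consent] <- "consent"
  bad_age <- is.na(records$age) | records$age < 12 | records$age > 120
  reason[is.na(reason) & bad_age] <- "invalid-age"
  reason[is.na(reason) & records$age < 18] <- "underage"

  cand <- which(is.na(reason))
  if (length(cand) > 1L) {
    key <- normalize_narrative(records$text_original[cand])
    dup <- duplicated(key)
    if (!is.null(near_dup_threshold) && any(!dup)) {
      near <- near_duplicate_flags(key, already_dup = dup,
                                   threshold = near_dup_threshold)
      dup <- dup | near
    }
    reason[cand[dup]] <- "duplicate"
  }

  list(
    retained = records[is.na(reason), , drop = FALSE],
    exclusions = tibble::tibble(doc_id = records$doc_id[!is.na(reason)],
                                reason = reason[!is.na(reason)])
  )
}

# Character 5-gram Jaccard near-duplicate scan. Jaccard >= t implies the two
# distinct-5-gram set sizes are within a factor t of each other, so after
# sorting by set size only a bounded window of earlier texts needs checking.
near_duplicate_flags <- function(texts, already_dup, threshold) {
  n <- length(texts)
  grams <- lapply(texts, function(s) {
    L <- stringi::stri_length(s)
    if (is.na(L) || L < 5L) return(s)
    unique(stringi::stri_sub(s, 1:(L - 4L), length = 5L))
  })
  # integer-code the grams once for fast set ops
  dict <- unique(unlist(grams, use.names = FALSE))
  grams <- lapply(grams, function(g) match(g, dict))
  sizes <- lengths(grams)
  ord <- order(sizes)
  flag <- logical(n)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (already_dup[i] || flag[i]) next
    p <- pos - 1L
    while (p >= 1L) {
      j <- ord[p]
      if (sizes[j] < threshold * sizes[i]) break
      if (j < i && !already_dup[j] && !flag[j]) {
        inter <- sum(grams[[i]] %in% grams[[j]])
        if (inter / (sizes[i] + sizes[j] - inter) >= threshold) {
          flag[i] <- TRUE
          break
        }
      }
      p <- p - 1L
    }
    if (flag[i]) next
    # texts with equal size sit after i in ord as well
    p <- pos + 1L
    while (p <= n) {
      j <- ord[p]
      if (sizes[i] < threshold * sizes[j]) break
      if (j < i && !already_dup[j] && !flag[j]) {
        inter <- sum(grams[[i]] %in% grams[[j]])
        if (inter / (sizes[i] + sizes[j] - inter) >= threshold) {
          flag[i] <- TRUE
          break
        }
      }
      p <- p + 1L
    }
  }
  flag
}

#' Write the exclusion log as JSON lines
#'
#' @param exclusions Tibble `doc_id`, `reason` from [filter_participants()].
#' @param path Output path; one JSON object per line.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(exclusions, path) {
  lines <- vapply(seq_len(nrow(exclusions)), function(i) {
    jsonlite::toJSON(list(doc_id = exclusions$doc_id[i],
                          reason = exclusions$reason[i]), auto_unbox = TRUE)
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Descriptive summary of a corpus release
#'
#' Computes the participant count; word-token, distinct word-type and
#' distinct-lemma counts with and without stopwords; narrative length
#' mean/SD/range in words (non-punctuation tokens per narrative); the
#' tabulation of every categorical participant variable; age median and
#' range; and psychometric means/SDs/ranges over participants who completed
#' both questionnaires.
#'
#' @param records Narrative tibble (already filtered).
#' @param tokens Token tibble for the same documents.
#' @param stopword_lemmas Stopword lemmas for the "minus stopwords" columns.
#' @param closed_class_pos POS tags treated as function words (see
#'   [remove_stopwords()]).
#' @return A `corpus_summary` list.
#' @export
summarize_corpus <- function(records, tokens, stopword_lemmas = character(),
                             closed_class_pos = c("ADP", "PRON", "CCONJ",
                                                  "SCONJ", "PART", "DET",
                                                  "AUX")) {
  words <- tokens[tokens$upos != "PUNCT", , drop = FALSE]
  nostop <- remove_stopwords(words, stopword_lemmas, closed_class_pos)
  per_doc <- table(factor(words$doc_id, levels = records$doc_id))
  lengths <- as.integer(per_doc)

  type_count <- function(x) length(unique(normalize_lemma(x)))
  psych <- records[!is.na(records$pcl5_total) & !is.na(records$miss_total), ,
                   drop = FALSE]
  num_summary <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(list(n = 0L, mean = NA_real_, sd = NA_real_,
                                min = NA_real_, max = NA_real_))
    list(n = length(x), mean = mean(x), sd = sd_or_zero(x),
         min = min(x), max = max(x))
  }

  structure(list(
    n_participants = nrow(records),
    tokens = list(total = nrow(words), minus_stopwords = nrow(nostop)),
    types = list(total = type_count(words$form),
                 minus_stopwords = type_count(nostop$form)),
    lemmas = list(total = type_count(words$lemma),
                  minus_stopwords = type_count(nostop$lemma)),
    narrative_length = num_summary(lengths),
    single_narrative_sd_flag = length(lengths) == 1L,
    age = list(median = stats::median(records$age),
               min = suppressWarnings(min(records$age)),
               max = suppressWarnings(max(records$age))),
    categorical = lapply(
      stats::setNames(nm = c(names(CATEGORICAL_FIELDS), "displaced")),
      function(f) table(records[[f]], useNA = "no")),
    psychometrics = list(
      n_completers = nrow(psych),
      pcl5 = num_summary(psych$pcl5_total),
      miss = num_summary(psych$miss_total))
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",")
  cat("<corpus_summary>\n")
  cat("  participants:          ", fmt(x$n_participants), "\n", sep = "")
  cat("  word tokens (no stop): ", fmt(x$tokens$total), " (",
      fmt(x$tokens$minus_stopwords), ")\n", sep = "")
  cat("  distinct lemmas:       ", fmt(x$lemmas$total), " (",
      fmt(x$lemmas$minus_stopwords), ")\n", sep = "")
  with(x$narrative_length,
       cat("  narrative length:       Range = ", min, ":", max,
           ", M = ", round(mean), ", SD = ", round(sd), "\n", sep = ""))
  cat("  completed both questionnaires: ", fmt(x$psychometrics$n_completers),
      "\n", sep = "")
  invisible(x)
}
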