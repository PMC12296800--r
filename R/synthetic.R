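#' Specification for a synthetic corpus pair
#'
#' Bundles the parameters of the Zipf-Mandelbrot lexicon, the token totals of
#' the target and reference corpora, the planted per-lemma log-odds shifts,
#' and the master seed. All generators are pure functions of this object.
#'
#' @param vocab_size Number of distinct lemmas (>= 2).
#' @param zipf_exponent Zipf-Mandelbrot exponent s > 0 (s = 0 gives a
#'   uniform lexicon). Default 1.05, typical of natural-language rank
#'   profiles.
#' @param zipf_offset Mandelbrot offset q >= 0. Default 2.7.
#' @param n_target,n_reference Token totals (>= 1).
#' @param effects Named numeric vector: planted log-odds shifts
#'   (natural-log units) keyed by lemma label; empty for a null pair.
#' @param seed Master seed (integer).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(vocab_size, zipf_exponent = 1.05, zipf_offset = 2.7,
                           n_target = 1e5, n_reference = 1e5,
                           effects = numeric(), seed = 1L) {
  stopifnot(vocab_size >= 2, zipf_exponent >= 0, zipf_offset >= 0,
            n_target >= 1, n_reference >= 1)
  lemmas <- lemma_labels(vocab_size)
  if (length(effects)) {
    stopifnot(!is.null(names(effects)))
    bad <- setdiff(names(effects), lemmas)
    if (length(bad)) {
      stop("effects name lemmas outside the generated vocabulary: ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent, zipf_offset = zipf_offset,
                 n_target = n_target, n_reference = n_reference,
                 effects = effects, seed = as.integer(seed)),
            class = "synthetic_spec")
}

lemma_labels <- function(vocab_size) {
  sprintf("lemma%0*d", nchar(as.character(vocab_size)), seq_len(vocab_size))
}

#' Zipf-Mandelbrot base lexicon probabilities
#'
#' Rank-frequency law \eqn{p_r \propto 1/(r+q)^s} over ranks
#' \eqn{r = 1..V}, normalized to sum to one. Lemma labels are the
#' deterministic rank labels `lemma001`, `lemma002`, ...
#'
#' @param vocab_size V >= 2.
#' @param zipf_exponent s >= 0 (0 = uniform).
#' @param zipf_offset q >= 0.
#' @param seed Unused by the closed-form law; accepted so lexicon calls fit
#'   the generator seeding convention.
#' @return Named probability vector of length `vocab_size`.
#' @export
#' @examples
#' generate_lexicon(2, 1, 0)  # (2/3, 1/3)
generate_lexicon <- function(vocab_size, zipf_exponent = 1.05,
                             zipf_offset = 2.7, seed = NULL) {
  if (!is.numeric(vocab_size) || vocab_size < 2) {
    stop("vocab_size must be >= 2", call. = FALSE)
  }
  if (zipf_exponent < 0 || zipf_offset < 0) {
    stop("zipf_exponent and zipf_offset must be non-negative", call. = FALSE)
  }
  w <- (seq_len(vocab_size) + zipf_offset)^(-zipf_exponent)
  stats::setNames(w / sum(w), lemma_labels(vocab_size))
}

# target distribution: base odds multiplied by exp(shift) on effect lemmas,
# then renormalized
tilt_probs <- function(p, effects) {
  w <- p
  if (length(effects)) {
    idx <- match(names(effects), names(p))
    w[idx] <- w[idx] * exp(effects)
  }
  w / sum(w)
}

#' Generate a synthetic target/reference corpus pair
#'
#' Reference counts are drawn multinomially from the base Zipf-Mandelbrot
#' distribution; target counts from the base distribution tilted by
#' `exp(shift)` on the effect lemmas and renormalized. The truth record
#' stores the exact post-normalization probabilities and the implied
#' population log-odds difference per lemma, so recovery checks never rely
#' on the small-probability approximation shift ≈ delta.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `target` and `reference` ([frequency_table()]s) and
#'   `truth`, a tibble `(lemma, p_target, p_reference, implied_delta,
#'   implied_loridp_delta, shift)`: `implied_delta` is the population
#'   log-odds difference, `implied_loridp_delta` the exact large-sample
#'   target of the estimator under the pooled-count prior
#'   ([implied_loridp()]).
#' @export
generate_corpus_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p_ref <- generate_lexicon(spec$vocab_size, spec$zipf_exponent,
                            spec$zipf_offset)
  p_tgt <- tilt_probs(p_ref, spec$effects)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  y_ref <- stats::rmultinom(1, spec$n_reference, p_ref)[, 1]
  y_tgt <- stats::rmultinom(1, spec$n_target, p_tgt)[, 1]

  shift <- stats::setNames(numeric(spec$vocab_size), names(p_ref))
  if (length(spec$effects)) shift[names(spec$effects)] <- spec$effects
  truth <- tibble::tibble(
    lemma = names(p_ref),
    p_target = unname(p_tgt),
    p_reference = unname(p_ref),
    implied_delta = unname(log(p_tgt / (1 - p_tgt)) - log(p_ref / (1 - p_ref))),
    implied_loridp_delta = unname(implied_loridp(p_tgt, p_ref, spec$n_target,
                                                 spec$n_reference)),
    shift = unname(shift)
  )
  list(
    target = frequency_table(stats::setNames(y_tgt, names(p_ref)), "synthetic-target"),
    reference = frequency_table(stats::setNames(y_ref, names(p_ref)), "synthetic-reference"),
    truth = truth
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate independent null corpus pairs as combined tables
#'
#' Each replicate draws a target/reference pair from the identical base
#' distribution (any effects in `spec` are ignored), merges it with
#' [merge_tables()], and applies `.f`. Replicate seeds are derived
#' deterministically from the master seed, so the stream is replay-exact.
#'
#' @param spec A [synthetic_spec()]; its `effects` are dropped.
#' @param replicates Number of replicates (>= 1).
#' @param .f Function applied to each `combined_lemma_table`; default
#'   `identity` returns the tables themselves. Supplying a summary function
#'   keeps long replicate streams memory-flat.
#' @return List of length `replicates` with the `.f` results.
#' @export
generate_null_replicates <- function(spec, replicates, .f = identity) {
  stopifnot(inherits(spec, "synthetic_spec"), replicates >= 1)
  null_spec <- spec
  null_spec$effects <- numeric()
  lapply(seq_len(replicates), function(r) {
    rep_spec <- null_spec
    rep_spec$seed <- derive_seed(spec$seed, r)
    pair <- generate_corpus_pair(rep_spec)
    .f(merge_tables(pair$target, pair$reference))
  })
}

#' Default metadata marginals for synthetic participant samples
#'
#' Category probabilities emulating a large online-collected wartime
#' testimony sample: 43% forcibly displaced, 84% women, education and
#' occupation-status splits as tabulated in such collections, roughly 61%
#' completing both psychometric questionnaires. Each entry is a named
#' probability vector over the canonical levels of that field.
#'
#' @return Named list of probability vectors and scalar parameters.
#' @export
default_metadata_marginals <- function() {
  list(
    gender = c(man = 220, woman = 1152, other = 0) / 1372,
    marital_status = c(single = 1022, married = 961, `in-a-relationship` = 20) / 2003,
    education = c(secondary = 439, college = 564, bachelor = 314,
                  `master-or-phd` = 686) / 2003,
    occupation_status = c(`never-occupied` = 703, occupied = 976,
                          `de-occupied` = 324) / 2003,
    trauma_history = c(holocaust = 22, holodomor = 301, none = 1220,
                       other = 470) / 2013,
    displaced = 0.43,
    completer_rate = 1225 / 2003,
    russian_rate = 12 / 2003,
    age = list(min = 18, max = 86, meanlog = log(33), sdlog = 0.33),
    pcl5 = list(mean = 41, sd = 19, min = 0, max = 80),
    miss = list(mean = 42, sd = 17, min = 10, max = 100),
    date_range = as.Date(c("2022-05-17", "2024-01-14"))
  )
}

#' Generate a synthetic two-format corpus release
#'
#' Writes a narrative-level CSV and a token-level CoNLL-U file that pass
#' [read_narrative_table()] / [read_token_table()] validation, plus a truth
#' JSON with the generating parameters. Narrative lengths are drawn from a
#' log-normal moment-matched to the requested mean/SD (truncated at one
#' word); the "text" is a lemma sequence sampled from the base lexicon,
#' chunked into sentences — a statistical fixture, not grammatical prose.
#' High-frequency lexicon ranks are assigned closed-class POS tags so that
#' stopword removal has realistic bite; the remaining lemmas get open-class
#' tags.
#'
#' @param n_participants Number of narratives (0 gives valid empty files).
#' @param out_dir Output directory (created if needed).
#' @param marginals Metadata marginals, see [default_metadata_marginals()].
#' @param length_mean,length_sd Narrative length moments in words.
#' @param lexicon Named base probability vector ([generate_lexicon()]).
#' @param closed_class_ranks Number of top lexicon ranks tagged as
#'   closed-class function words.
#' @param seed Master seed.
#' @return Invisibly, a list with `narratives_path`, `tokens_path`,
#'   `truth_path`.
#' @export
generate_narratives <- function(n_participants, out_dir,
                                marginals = default_metadata_marginals(),
                                length_mean = 333, length_sd = 237,
                                lexicon = generate_lexicon(5000),
                                closed_class_ranks = 40L,
                                seed = 1L) {
  stopifnot(n_participants >= 0, length_mean > 0, length_sd >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(narratives_path = file.path(out_dir, "narratives.csv"),
                tokens_path = file.path(out_dir, "tokens.conllu"),
                truth_path = file.path(out_dir, "truth.json"))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- n_participants
  draw_cat <- function(p, n) {
    if (n == 0L) return(character(0))
    sample(names(p), n, replace = TRUE, prob = p)
  }
  # log-normal moment matching for lengths
  if (length_sd > 0) {
    sdlog <- sqrt(log(1 + (length_sd / length_mean)^2))
    meanlog <- log(length_mean) - sdlog^2 / 2
    lens <- pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
  } else {
    lens <- rep(as.integer(round(length_mean)), n)
  }
  ages <- if (n) pmin(marginals$age$max, pmax(marginals$age$min, as.integer(
    round(stats::rlnorm(n, marginals$age$meanlog, marginals$age$sdlog))))) else integer(0)
  trunc_score <- function(m, n_draw) pmin(m$max, pmax(m$min, as.integer(
    round(stats::rnorm(n_draw, m$mean, m$sd)))))
  completer <- if (n) stats::runif(n) < marginals$completer_rate else logical(0)
  pcl5 <- rep(NA_integer_, n); miss <- rep(NA_integer_, n)
  if (any(completer)) {
    pcl5[completer] <- trunc_score(marginals$pcl5, sum(completer))
    miss[completer] <- trunc_score(marginals$miss, sum(completer))
  }
  dates <- if (n) marginals$date_range[1] +
    sample.int(as.integer(diff(marginals$date_range)) + 1L, n, replace = TRUE) - 1L
  else as.Date(character(0))

  # per-narrative word sequences from the lexicon
  vocab <- names(lexicon)
  seqs <- lapply(lens, function(L) sample(vocab, L, replace = TRUE,
                                          prob = lexicon))
  if (n == 0L) seqs <- list()
  text <- vapply(seqs, paste, character(1), collapse = " ")
  if (n == 0L) text <- character(0)

  records <- tibble::tibble(
    doc_id = seq_len(n),
    age = ages,
    gender = draw_cat(marginals$gender, n),
    marital_status = draw_cat(marginals$marital_status, n),
    education = draw_cat(marginals$education, n),
    region = if (n) sample(paste0("Region", 1:25), n, replace = TRUE) else character(0),
    occupation_status = draw_cat(marginals$occupation_status, n),
    displaced = if (n) stats::runif(n) < marginals$displaced else logical(0),
    trauma_history = draw_cat(marginals$trauma_history, n),
    submission_date = dates,
    pcl5_total = pcl5,
    miss_total = miss,
    consent = rep(TRUE, n),
    text_original = text,
    text_translation = rep(NA_character_, n),
    original_language = if (n) ifelse(stats::runif(n) < marginals$russian_rate,
                                      "ru", "uk") else character(0)
  )
  write_narrative_table(records, paths$narratives_path)

  # token table: each word is its own lemma; POS deterministic per rank
  pos_pool <- c("NOUN", "VERB", "ADJ", "ADV")
  rank_pos <- c(sample(c("ADP", "PRON", "CCONJ", "SCONJ", "PART", "DET", "AUX"),
                       min(closed_class_ranks, length(vocab)), replace = TRUE),
                sample(pos_pool, max(0L, length(vocab) - closed_class_ranks),
                       replace = TRUE))
  names(rank_pos) <- vocab

  if (n > 0L) {
    doc_id <- rep.int(seq_len(n), lens)
    form <- unlist(seqs, use.names = FALSE)
    # sentences of ~12 words
    tok_in_doc <- unlist(lapply(lens, seq_len), use.names = FALSE)
    sent_in_doc <- (tok_in_doc - 1L) %/% 12L + 1L
    token_index <- (tok_in_doc - 1L) %% 12L + 1L
    sent_key <- paste(doc_id, sent_in_doc)
    sent_text <- stats::ave(form, sent_key, FUN = function(w) paste(w, collapse = " "))
    tokens <- tibble::tibble(
      doc_id = doc_id, paragraph_index = 1L, sentence_index = sent_in_doc,
      sentence_text = sent_text, token_index = token_index, form = form,
      lemma = form, upos = unname(rank_pos[form]),
      morph = "_", dep_relation = ifelse(token_index == 1L, "root", "dep"),
      head_index = ifelse(token_index == 1L, 0L, 1L)
    )
  } else {
    tokens <- tibble::tibble(
      doc_id = integer(), paragraph_index = integer(),
      sentence_index = integer(), sentence_text = character(),
      token_index = integer(), form = character(), lemma = character(),
      upos = character(), morph = character(), dep_relation = character(),
      head_index = integer())
  }
  write_token_table(tokens, paths$tokens_path)

  jsonlite::write_json(
    list(n_participants = n, length_mean = length_mean, length_sd = length_sd,
         vocab_size = length(vocab), closed_class_ranks = closed_class_ranks,
         seed = seed,
         marginals = marginals[c("displaced", "completer_rate")]),
    paths$truth_path, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
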