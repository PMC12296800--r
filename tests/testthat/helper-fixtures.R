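# in-code fixture builders shared across test files

toy_participants <- function(n = 5) {
  tibble::tibble(
    doc_id = seq_len(n),
    age = rep(30L, n),
    gender = rep("woman", n),
    marital_status = rep("married", n),
    education = rep("bachelor", n),
    region = rep("Volyn", n),
    occupation_status = rep("never-occupied", n),
    displaced = rep(FALSE, n),
    trauma_history = rep("none", n),
    submission_date = rep(as.Date("2023-01-15"), n),
    pcl5_total = rep(40L, n),
    miss_total = rep(45L, n),
    consent = rep(TRUE, n),
    text_original = paste("оповідання номер", seq_len(n), "про війну і страх"),
    text_translation = rep(NA_character_, n),
    original_language = rep("uk", n)
  )
}

toy_tokens <- function(doc_id = 1L,
                       forms = c("війна", "прийшла", "несподівано"),
                       lemmas = forms,
                       upos = rep("NOUN", length(forms))) {
  n <- length(forms)
  tibble::tibble(
    doc_id = rep(as.integer(doc_id), n),
    paragraph_index = 1L,
    sentence_index = 1L,
    sentence_text = paste(forms, collapse = " "),
    token_index = seq_len(n),
    form = forms, lemma = lemmas, upos = upos,
    morph = "_",
    dep_relation = c("root", rep("dep", n - 1L)),
    head_index = c(0L, rep(1L, n - 1L))
  )
}

freq_tab <- function(...) {
  frequency_table(unlist(list(...)))
}

conllu_fixture_lines <- function() {
  c("# newdoc id = doc1",
    "# newpar",
    "# sent_id = 1",
    "# text = у нас війна",
    "1\tу\tу\tADP\t_\t_\t3\tcase\t_\t_",
    "2\tнас\tми\tPRON\t_\tCase=Loc\t3\tobl\t_\t_",
    "3\tвійна\tвійна\tNOUN\t_\tCase=Nom\t0\troot\t_\t_",
    "")
}
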