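test_that("narrative table round-trips losslessly through write and read", {
  recs <- toy_participants(2)
  recs$text_original[1] <- "Текст із комою, лапками \"так\" і\nновим рядком."
  recs$pcl5_total[2] <- NA_integer_
  recs$miss_total[2] <- NA_integer_
  f <- tempfile(fileext = ".csv")
  write_narrative_table(recs, f)
  back <- read_narrative_table(f)
  expect_equal(nrow(attr(back, "quarantined")), 0L)
  attr(back, "quarantined") <- NULL
  attr(back, "nonstandard") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("narrative reader canonicalizes categoricals and parses docN ids", {
  f <- tempfile(fileext = ".csv")
  hdr <- paste(c("doc_id", "age", "gender", "marital_status", "education",
                 "region", "occupation_status", "displaced", "trauma_history",
                 "submission_date", "pcl5_total", "miss_total", "consent",
                 "text_original", "text_translation", "original_language"),
               collapse = ",")
  writeLines(c(hdr,
               'doc1,25,Female,Married,Master or PhD,Volyn,Never occupied,yes,Holodomor,2022-06-01,12,30,true,текст один,,uk',
               'doc2,31,Woman,single,College,Lviv,De-occupied,no,none,2023-02-11,,,TRUE,текст два,,uk'),
             f)
  tab <- read_narrative_table(f)
  expect_equal(tab$doc_id, c(1L, 2L))
  expect_equal(tab$gender, c("woman", "woman"))
  expect_equal(tab$education, c("master-or-phd", "college"))
  expect_equal(tab$occupation_status, c("never-occupied", "de-occupied"))
  expect_equal(tab$displaced, c(TRUE, FALSE))
  expect_true(all(tab$consent))
  expect_true(is.na(tab$pcl5_total[2]))
})

test_that("narrative reader enforces schema, quarantines bad rows, flags unknown levels", {
  f <- tempfile(fileext = ".csv")
  # header-only file reads as an empty table
  writeLines("doc_id,age,gender,marital_status,education,region,occupation_status,displaced,trauma_history,submission_date,pcl5_total,miss_total,consent,text_original,text_translation,original_language", f)
  expect_equal(nrow(read_narrative_table(f)), 0L)

  # a missing required column is a schema error naming the column
  writeLines("doc_id,age,gender", f)
  expect_error(read_narrative_table(f), "marital_status")

  recs <- toy_participants(3)
  write_narrative_table(recs, f)
  lines <- readLines(f)
  lines[2] <- sub("^1,30", "1,abc", lines[2])      # unparseable age
  lines[3] <- sub(",40,45,", ",99,45,", lines[3])  # PCL-5 out of 0-80
  writeLines(lines, f)
  tab <- read_narrative_table(f)
  q <- attr(tab, "quarantined")
  expect_equal(nrow(tab), 1L)
  expect_equal(nrow(q), 2L)
  expect_match(q$problem[1], "age")
  expect_match(q$problem[2], "pcl5")

  # unknown categorical value preserved with a warning flag
  recs2 <- toy_participants(1)
  recs2$trauma_history <- "chornobyl"
  write_narrative_table(recs2, f)
  expect_warning(tab2 <- read_narrative_table(f), "non-canonical")
  expect_equal(tab2$trauma_history, "chornobyl")
  expect_equal(attr(tab2, "nonstandard")$field, "trauma_history")
})

test_that("token table parses the CoNLL-U layout with metadata carry-over", {
  f <- tempfile(fileext = ".conllu")
  writeLines(conllu_fixture_lines(), f)
  tok <- read_token_table(f)
  expect_equal(nrow(tok), 3L)
  expect_equal(tok$token_index, 1:3)
  expect_equal(unique(tok$doc_id), 1L)
  expect_equal(unique(tok$sentence_text), "у нас війна")
  expect_equal(tok$lemma, c("у", "ми", "війна"))
  expect_equal(tok$head_index, c(3L, 3L, 0L))
  expect_equal(attr(tok, "n_skipped_ranges"), 0L)
  # empty file -> empty stream
  writeLines(character(0), f)
  expect_equal(nrow(read_token_table(f)), 0L)
})

test_that("multiword range lines are skipped and counted; malformed lines are positioned errors", {
  f <- tempfile(fileext = ".conllu")
  lines <- conllu_fixture_lines()
  lines <- append(lines, "2-3\tнас-таки\t_\t_\t_\t_\t_\t_\t_\t_", after = 5)
  writeLines(lines, f)
  tok <- read_token_table(f)
  expect_equal(nrow(tok), 3L)
  expect_equal(attr(tok, "n_skipped_ranges"), 1L)

  writeLines(c("# newdoc id = doc1", "1\tслово\tслово\tNOUN"), f)
  expect_error(read_token_table(f), "line 2")
  # token rows without any newdoc id have no doc_id
  writeLines("1\tслово\tслово\tNOUN\t_\t_\t0\troot\t_\t_", f)
  expect_error(read_token_table(f), "newdoc")
})

test_that("token table round-trips through write and read", {
  tok <- dplyr::bind_rows(
    toy_tokens(1L, forms = c("у", "нас", "війна"), lemmas = c("у", "ми", "війна"),
               upos = c("ADP", "PRON", "NOUN")),
    dplyr::mutate(toy_tokens(2L, forms = c("страх", "минув")),
                  sentence_index = 1L))
  f <- tempfile(fileext = ".conllu")
  write_token_table(tok, f)
  back <- read_token_table(f)
  attr(back, "n_skipped_ranges") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(tok))
})

test_that("filter_participants applies the exclusion rules in fixed precedence", {
  recs <- toy_participants(5)
  recs$consent[1] <- FALSE
  recs$age[2] <- 17L
  recs$text_original[4] <- recs$text_original[3]  # byte-identical duplicate
  out <- filter_participants(recs)
  expect_equal(nrow(out$retained), 2L)
  expect_setequal(out$exclusions$reason, c("consent", "underage", "duplicate"))
  expect_equal(out$exclusions$doc_id[out$exclusions$reason == "duplicate"], 4L)
  # precedence: a no-consent minor is logged under consent
  recs2 <- toy_participants(1)
  recs2$consent <- FALSE
  recs2$age <- 15L
  expect_equal(filter_participants(recs2)$exclusions$reason, "consent")
  # invalid age outranks underage
  recs3 <- toy_participants(2)
  recs3$age <- c(10L, 130L)
  expect_equal(filter_participants(recs3)$exclusions$reason,
               rep("invalid-age", 2))
  # empty input
  empty <- filter_participants(toy_participants(0))
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(nrow(empty$exclusions), 0L)
})

test_that("duplicate detection normalizes text and catches near-duplicates", {
  recs <- toy_participants(3)
  recs$text_original <- c("Це  ДОВГА історія про жах війни і втечу на захід",
                          "це довга історія про жах війни і втечу на захід",
                          "зовсім інша розповідь про літо і море у дитинстві")
  out <- filter_participants(recs)
  expect_equal(out$retained$doc_id, c(1L, 3L))
  # near-duplicate: long shared text with one edited word at the end
  base <- paste(paste0("слово", sprintf("%02d", 1:60)), collapse = " ")
  recs2 <- toy_participants(2)
  recs2$text_original <- c(base, sub("слово60$", "інакше", base))
  out2 <- filter_participants(recs2, near_dup_threshold = 0.9)
  expect_equal(out2$exclusions$reason, "duplicate")
  # the same pair passes when only the exact rule is active
  out3 <- filter_participants(recs2, near_dup_threshold = NULL)
  expect_equal(nrow(out3$retained), 2L)
})

test_that("filter_participants is idempotent and partitions the input", {
  set.seed(5)
  recs <- toy_participants(12)
  recs$consent[2] <- FALSE
  recs$age[5] <- 16L
  recs$text_original[8] <- recs$text_original[7]
  out <- filter_participants(recs)
  expect_equal(nrow(out$retained) + nrow(out$exclusions), nrow(recs))
  expect_equal(nrow(out$exclusions),
               length(unique(out$exclusions$doc_id)))
  again <- filter_participants(out$retained)
  expect_equal(as.data.frame(again$retained), as.data.frame(out$retained))
  expect_equal(nrow(again$exclusions), 0L)
})

test_that("exclusion log writes one JSON object per excluded record", {
  ex <- tibble::tibble(doc_id = c(3L, 9L), reason = c("consent", "duplicate"))
  f <- tempfile(fileext = ".jsonl")
  write_exclusion_log(ex, f)
  lines <- readLines(f)
  expect_equal(length(lines), 2L)
  obj <- jsonlite::fromJSON(lines[2])
  expect_equal(obj$doc_id, 9L)
  expect_equal(obj$reason, "duplicate")
})

test_that("summarize_corpus computes lengths, counts and completer psychometrics", {
  recs <- toy_participants(3)
  tok <- dplyr::bind_rows(
    toy_tokens(1L, forms = c("a", "b")),
    toy_tokens(2L, forms = c("c", "d", "e", "f")),
    toy_tokens(3L, forms = paste0("g", 1:6)))
  s <- summarize_corpus(recs, tok)
  expect_equal(s$n_participants, 3L)
  expect_equal(s$narrative_length$mean, 4)
  expect_equal(s$narrative_length$sd, 2)  # sample SD of 2, 4, 6
  expect_equal(c(s$narrative_length$min, s$narrative_length$max), c(2, 6))
  expect_equal(s$tokens$total, 12L)
  # token total equals the sum of per-narrative counts
  expect_equal(s$tokens$total, sum(table(tok$doc_id)))
  expect_equal(s$psychometrics$n_completers, 3L)
  expect_equal(s$psychometrics$pcl5$mean, 40)
  # single narrative: SD reported as 0 by convention, with a flag
  s1 <- summarize_corpus(recs[1, ], tok[tok$doc_id == 1, ])
  expect_equal(s1$narrative_length$sd, 0)
  expect_true(s1$single_narrative_sd_flag)
  # stopword removal feeds the minus-stopword columns
  tok$upos[1] <- "ADP"
  s2 <- summarize_corpus(recs, tok)
  expect_equal(s2$tokens$minus_stopwords, 11L)
})
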