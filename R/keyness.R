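#' Log-odds ratio with informative Dirichlet prior (point estimate)
#'
#' Computes the per-lemma difference in log-odds between a target corpus
#' \eqn{i} and a reference corpus \eqn{j}, smoothed by an informative
#' Dirichlet prior whose pseudo-counts are taken from the pooled corpora:
#' \deqn{\delta_w = \log\frac{y^i_w + \alpha_w}{n^i + \alpha_0 - (y^i_w + \alpha_w)}
#'              - \log\frac{y^j_w + \alpha_w}{n^j + \alpha_0 - (y^j_w + \alpha_w)}}
#' where \eqn{y^i_w, y^j_w} are the counts of lemma \eqn{w} in each corpus,
#' \eqn{n^i, n^j} the corpus token totals, \eqn{\alpha_w = y^i_w + y^j_w} the
#' pooled count of \eqn{w}, and \eqn{\alpha_0 = n^i + n^j} the pooled total.
#' Natural logarithms throughout. All arguments are vectorized.
#'
#' @param y_i,y_j Non-negative lemma counts in the target / reference corpus.
#' @param n_i,n_j Token totals of the two corpora.
#' @param alpha_w Per-lemma prior pseudo-count (pooled count of the lemma).
#' @param alpha_0 Prior total pseudo-count (pooled corpus size).
#' @return Numeric vector of log-odds differences (natural-log units).
#' @seealso [loridp_variance()], [compute_keyness()]
#' @export
#' @examples
#' loridp_delta(5, 10, 1, 10, alpha_w = 6, alpha_0 = 20)  # log(253/133)
loridp_delta <- function(y_i, n_i, y_j, n_j, alpha_w, alpha_0) {
  num_i <- y_i + alpha_w
  num_j <- y_j + alpha_w
  den_i <- n_i + alpha_0 - num_i
  den_j <- n_j + alpha_0 - num_j
  if (any(num_i <= 0) || any(num_j <= 0)) {
    stop("loridp_delta: y + alpha_w must be positive", call. = FALSE)
  }
  if (any(den_i <= 0) || any(den_j <= 0)) {
    stop("loridp_delta: non-positive odds denominator (degenerate one-lemma corpus)",
         call. = FALSE)
  }
  (log(num_i) - log(den_i)) - (log(num_j) - log(den_j))
}

#' Approximate variance of the LORIDP log-odds difference
#'
#' \deqn{\sigma^2(\delta_w) \approx \frac{1}{y^i_w + \alpha_w} + \frac{1}{y^j_w + \alpha_w}}
#' Vectorized; symmetric in the two corpora.
#'
#' @inheritParams loridp_delta
#' @return Numeric vector of variances.
#' @export
#' @examples
#' loridp_variance(5, 1, alpha_w = 6)  # 1/11 + 1/7
loridp_variance <- function(y_i, y_j, alpha_w) {
  a <- y_i + alpha_w
  b <- y_j + alpha_w
  if (any(a <= 0) || any(b <= 0)) {
    stop("loridp_variance: y + alpha_w must be positive", call. = FALSE)
  }
  1 / a + 1 / b
}

#' Compute keyness scores for a combined lemma table
#'
#' Applies [loridp_delta()] and [loridp_variance()] to every row of a
#' [merge_tables()] result and standardizes: \eqn{z = \delta / \sqrt{\sigma^2}}.
#' Significance flags and ranks are left unset; see [select_keys()].
#'
#' @param table A `combined_lemma_table`.
#' @return A tibble with columns `lemma`, `y_target`, `y_reference`, `delta`,
#'   `variance`, `z`, `significant` (`NA` until thresholded), `rank` (`NA`).
#' @export
compute_keyness <- function(table) {
  stopifnot(inherits(table, "combined_lemma_table"))
  n_i <- attr(table, "n_target")
  n_j <- attr(table, "n_reference")
  a0 <- attr(table, "alpha_0")
  delta <- withCallingHandlers(
    loridp_delta(table$y_target, n_i, table$y_reference, n_j,
                 table$alpha_w, a0),
    error = function(e) e
  )
  if (inherits(delta, "error")) {
    bad <- which(table$y_target + table$alpha_w <= 0 |
                   table$y_reference + table$alpha_w <= 0 |
                   n_i + a0 - (table$y_target + table$alpha_w) <= 0 |
                   n_j + a0 - (table$y_reference + table$alpha_w) <= 0)
    stop("compute_keyness: domain error for lemma(s) ",
         paste(utils::head(table$lemma[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  variance <- loridp_variance(table$y_target, table$y_reference, table$alpha_w)
  tibble::tibble(
    lemma = table$lemma,
    y_target = table$y_target,
    y_reference = table$y_reference,
    delta = delta,
    variance = variance,
    z = delta / sqrt(variance),
    significant = NA,
    rank = NA_integer_
  )
}

#' Large-sample target of the LORIDP estimate under the pooled-count prior
#'
#' With the prior pseudo-counts taken from the pooled corpora
#' (\eqn{\alpha_w = y^i_w + y^j_w}, \eqn{\alpha_0 = n^i + n^j}), the prior
#' carries as much weight as the data, so the LORIDP point estimate does not
#' converge to the raw population log-odds difference but to the log-odds
#' difference of the prior-blended proportions. This helper evaluates that
#' target exactly by plugging the expected counts
#' \eqn{y^i_w = n^i p^i_w, y^j_w = n^j p^j_w} into [loridp_delta()].
#' Useful as the honest comparison value in parameter-recovery simulations.
#'
#' @param p_target,p_reference Population lemma probabilities (vectorized).
#' @param n_target,n_reference Corpus token totals.
#' @return Numeric vector: the expected-count LORIDP value per lemma.
#' @export
implied_loridp <- function(p_target, p_reference, n_target, n_reference) {
  y_i <- n_target * p_target
  y_j <- n_reference * p_reference
  loridp_delta(y_i, n_target, y_j, n_reference,
               alpha_w = y_i + y_j, alpha_0 = n_target + n_reference)
}

#' Bonferroni-corrected z threshold
#'
#' Standard-normal quantile for a family-wise level `alpha` split over `m`
#' simultaneous tests. Under the one-sided convention the threshold is the
#' upper quantile at `alpha/m`; under the two-sided convention, at
#' `alpha/(2*m)`.
#'
#' @param alpha Family-wise error level, in (0, 1).
#' @param m Number of simultaneous tests (rows of the combined table).
#' @param tail `"one-sided"` (default) or `"two-sided"`.
#' @return The critical |z| value.
#' @export
#' @examples
#' bonferroni_threshold(0.01, 59190)  # 5.10
bonferroni_threshold <- function(alpha, m, tail = c("one-sided", "two-sided")) {
  tail <- match.arg(tail)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("m must be a single integer >= 1", call. = FALSE)
  }
  p <- if (tail == "one-sided") alpha / m else alpha / (2 * m)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Split keyness results into ranked diagnostic word lists
#'
#' Lemmas with `z >= threshold` are diagnostic of the target corpus; lemmas
#' with `z <= -threshold` of the reference corpus. Each list is ranked from
#' most to least extreme z, ties broken alphabetically by lemma.
#'
#' @param results Tibble from [compute_keyness()].
#' @param threshold Positive critical |z|.
#' @return A list with `target_keys`, `reference_keys` (ranked tibbles) and
#'   `results` (input with `significant`/`rank` filled in).
#' @export
select_keys <- function(results, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  results$significant <- abs(results$z) >= threshold
  results$rank <- NA_integer_

  take <- function(side) {
    keep <- if (side > 0) results$z >= threshold else results$z <= -threshold
    keys <- results[keep, , drop = FALSE]
    ord <- order(side * -keys$z, keys$lemma)
    keys <- keys[ord, , drop = FALSE]
    keys$rank <- seq_len(nrow(keys))
    keys
  }
  target_keys <- take(+1)
  reference_keys <- take(-1)
  results$rank[match(target_keys$lemma, results$lemma)] <- target_keys$rank
  results$rank[match(reference_keys$lemma, results$lemma)] <- reference_keys$rank
  list(target_keys = target_keys, reference_keys = reference_keys,
       results = results)
}

#' Top-k report of a ranked key list
#'
#' @param keys Ranked tibble from [select_keys()].
#' @param k Number of rows to report (>= 1).
#' @param gloss_map Optional named character vector mapping lemmas to
#'   translations; unmapped lemmas get an empty gloss.
#' @return Tibble with columns `rank`, `lemma`, `gloss`, `abs_z`.
#' @export
top_k_table <- function(keys, k, gloss_map = NULL) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  keys <- utils::head(keys, k)
  gloss <- if (is.null(gloss_map)) character(nrow(keys)) else {
    g <- unname(gloss_map[keys$lemma])
    g[is.na(g)] <- ""
    g
  }
  tibble::tibble(
    rank = keys$rank %||% seq_len(nrow(keys)),
    lemma = keys$lemma,
    gloss = gloss,
    abs_z = abs(keys$z)
  )
}

#' Run the full keyness test on a combined table
#'
#' Convenience wrapper: scores every lemma, computes the Bonferroni threshold
#' at `m = nrow(table)`, and selects the significant keys.
#'
#' @param table A `combined_lemma_table`.
#' @param alpha Family-wise level (default 0.01).
#' @param tail Tail convention, see [bonferroni_threshold()].
#' @return A `keyness_run` object: list with `results`, `target_keys`,
#'   `reference_keys`, `threshold_z`, `alpha`, `m`, `tail`.
#' @export
keyness_run <- function(table, alpha = 0.01, tail = c("one-sided", "two-sided")) {
  tail <- match.arg(tail)
  results <- compute_keyness(table)
  m <- nrow(results)
  thr <- bonferroni_threshold(alpha, m, tail)
  sel <- select_keys(results, thr)
  structure(
    list(results = sel$results, target_keys = sel$target_keys,
         reference_keys = sel$reference_keys, threshold_z = thr,
         alpha = alpha, m = m, tail = tail),
    class = "keyness_run"
  )
}

#' @export
print.keyness_run <- function(x, ...) {
  cat("<keyness_run> ", x$m, " lemmas tested; |z| threshold ",
      format(round(x$threshold_z, 2), nsmall = 2),
      " (alpha = ", x$alpha, ", ", x$tail, ")\n", sep = "")
  cat("  target-diagnostic keys:    ", nrow(x$target_keys), "\n", sep = "")
  cat("  reference-diagnostic keys: ", nrow(x$reference_keys), "\n", sep = "")
  invisible(x)
}
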