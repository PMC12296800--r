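# Independent oracle for the LORIDP statistic, kept deliberately separate
# from the package's vectorized implementation. All intermediate quantities
# are exact integer products/fractions (counts are tiny, so doubles hold
# them exactly); only the final log/sqrt are floating point:
#   delta = log(num_i * den_j) - log(den_i * num_j)
#   var   = (a + b) / (a * b)   with a = y_i + alpha_w, b = y_j + alpha_w
oracle_loridp <- function(y_i, n_i, y_j, n_j, alpha_w, alpha_0) {
  num_i <- y_i + alpha_w
  den_i <- n_i + alpha_0 - num_i
  num_j <- y_j + alpha_w
  den_j <- n_j + alpha_0 - num_j
  stopifnot(num_i > 0, den_i > 0, num_j > 0, den_j > 0)
  delta <- log(num_i * den_j) - log(den_i * num_j)
  v <- (num_i + num_j) / (num_i * num_j)
  list(delta = delta, variance = v, z = delta / sqrt(v))
}

# brute-force oracle over a whole combined table built from two tiny
# count maps (named integer vectors)
oracle_keyness_table <- function(target_counts, reference_counts) {
  lemmas <- sort(union(names(target_counts), names(reference_counts)))
  y_i <- ifelse(lemmas %in% names(target_counts), target_counts[lemmas], 0)
  y_j <- ifelse(lemmas %in% names(reference_counts), reference_counts[lemmas], 0)
  n_i <- sum(target_counts)
  n_j <- sum(reference_counts)
  a0 <- n_i + n_j
  rows <- lapply(seq_along(lemmas), function(k) {
    o <- oracle_loridp(y_i[[k]], n_i, y_j[[k]], n_j,
                       alpha_w = y_i[[k]] + y_j[[k]], alpha_0 = a0)
    data.frame(lemma = lemmas[k], delta = o$delta, variance = o$variance,
               z = o$z)
  })
  do.call(rbind, rows)
}

# random small count maps for the oracle-equivalence sweep; redraws the
# degenerate case where a single lemma carries the whole of both corpora
# (there the odds denominator is zero and the statistic is undefined)
random_count_pair <- function(max_lemmas = 6L, max_count = 20L) {
  v <- sample(2:max_lemmas, 1)
  lemmas <- paste0("w", seq_len(v))
  draw <- function() {
    x <- sample(0:max_count, v, replace = TRUE)
    if (sum(x) == 0) x[sample(v, 1)] <- sample(1:max_count, 1)
    stats::setNames(as.integer(x), lemmas)
  }
  repeat {
    out <- list(target = draw(), reference = draw())
    union_size <- length(unique(c(names(out$target)[out$target > 0],
                                  names(out$reference)[out$reference > 0])))
    if (union_size >= 2L) return(out)
  }
}
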