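# shared internal helpers

# Row-wise equal-variance two-sample t-test on two numeric matrices with the
# same number of rows. Degenerate rows (zero pooled variance) get p = 1 when
# the group means agree and p = 0 when they differ; this arises after quantile
# normalization when a gene holds the same rank in every sample.
row_t_test <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  n1 <- ncol(x)
  n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) {
    abort("each group needs at least 2 replicates for a two-sample t-test")
  }
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  ss1 <- rowSums((x - m1)^2)
  ss2 <- rowSums((y - m2)^2)
  df <- n1 + n2 - 2
  se <- sqrt((ss1 + ss2) / df * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  degenerate <- se == 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 0
  tt[degenerate] <- 0
  list(statistic = tt, p_value = p)
}

# Numeric matrix view of a wide tibble (id columns dropped).
as_sample_matrix <- function(x, id_cols) {
  m <- as.matrix(x[, setdiff(names(x), id_cols), drop = FALSE])
  if (!is.numeric(m)) abort("sample columns must be numeric")
  rownames(m) <- x[[id_cols[[1L]]]]
  m
}

check_character_set <- function(x, arg) {
  x <- unique(as.character(x))
  if (anyNA(x)) abort(sprintf("`%s` must not contain NA", arg))
  x
}

# round-half-up at one decimal, matching how percentages are printed in
# genome-scale summaries (4.99815 -> 5.0, not 4.9)
percent_of <- function(k, n, digits = 1) {
  floor(100 * k / n * 10^digits + 0.5) / 10^digits
}
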