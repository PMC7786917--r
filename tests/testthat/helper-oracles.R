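# Independent oracles the tests check package operations against.
# Each is a direct transcription of the defining formula, kept free of any
# package internals.

# deficit-sum / adjusted-denominator frailty index, by explicit loop
oracle_fi <- function(weights) {
  s <- 0; miss <- 0
  for (w in weights) {
    if (is.na(w)) miss <- miss + 1 else s <- s + w
  }
  s / (length(weights) - miss)
}

# Pearson chi-square by explicit O/E summation
oracle_pearson <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  sum((m - e)^2 / e)
}

# Wilson score interval, closed form
oracle_wilson <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

# pooled two-sample t from summary statistics
oracle_pooled_t <- function(n1, m1, s1, n2, m2, s2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# two-item Cronbach closed form
oracle_alpha2 <- function(x1, x2) {
  2 * (1 - (var(x1) + var(x2)) / var(x1 + x2))
}

# half-up decimal rounding, as printed tables round (R's round() is half-even)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# a subject record with every deficit absent, as raw response labels
blank_record <- function() {
  rec <- as.data.frame(setNames(as.list(rep("No", 30)), paste0("item_", 1:30)),
                       stringsAsFactors = FALSE)
  rec$item_1 <- "Good"
  rec$item_10 <- "Normal"
  rec$item_17 <- "Normal"
  rec$item_20 <- "Normal depression"
  rec$item_22 <- "Normal"
  rec
}

# random legal deficit vector for a registry (optionally with missing items)
random_deficit_vector <- function(registry, n_missing = 0) {
  w <- vapply(registry, function(it) sample(it$scheme$weights, 1), 1)
  if (n_missing > 0) w[sample(30, n_missing)] <- NA
  unname(w)
}
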