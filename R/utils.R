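# small shared helpers

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# lognormal meanlog/sdlog for a target arithmetic mean and sd (seconds);
# sd = 0 collapses to the constant `mean`
rlnorm_ms <- function(n, mean, sd) {
  if (mean <= 0) abort("lognormal mean must be positive")
  if (sd <= 0) return(rep(mean, n))
  sdlog2 <- log1p((sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# normalized Hamming weights of length n (n = 1 -> identity)
hamming_weights <- function(n) {
  if (n <= 1) return(1)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  w / sum(w)
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s (has: %s)",
      what, paste(missing, collapse = ", "), paste(names(df), collapse = ", ")
    ))
  }
  invisible(df)
}

# canonical token normalization used by the lexical statistics: case-fold and
# strip annotation marks, keeping letters, digits, apostrophes and the <unk> tag
normalize_label <- function(x) {
  x <- tolower(x)
  unk <- x == "<unk>"
  x <- stringr::str_replace_all(x, "[^a-z0-9']+", "")
  x[unk] <- "<unk>"
  x
}
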