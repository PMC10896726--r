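# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# unbiased (n-1) row variances, NA-aware
row_vars <- function(x, na.rm = FALSE) {
  n <- if (na.rm) rowSums(!is.na(x)) else rep(ncol(x), nrow(x))
  mu <- rowMeans(x, na.rm = na.rm)
  ss <- rowSums((x - mu)^2, na.rm = na.rm)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}

# rows scaled to mean 0, sd 1; constant rows left at 0
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(row_vars(x))
  s[is.na(s) | s == 0] <- 1
  (x - mu) / s
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
}
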