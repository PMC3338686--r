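# Fixtures and independent oracles shared across test files.

# small peak table as a data.frame (the canonical four columns)
toy_peaks <- function() {
  data.frame(
    sample_id = rep(c("A", "B"), each = 3),
    time_days = rep(c(0, 15), each = 3),
    fragment_length = c(219, 354, 491, 219, 354, 491),
    area = c(700, 150, 150, 500, 400, 100)
  )
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# textbook Pearson correlation, written independently of the package
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# chi-square residual matrix computed directly from its definition
Q_oracle <- function(Y) {
  P <- Y / sum(Y)
  r <- rowSums(P); c <- colSums(P)
  (P - outer(r, c)) / sqrt(outer(r, c))
}

# unconstrained CA eigenvalues: squared singular values of Q
ca_eigen_oracle <- function(Y) {
  d <- svd(Q_oracle(Y))$d
  d[d^2 > 1e-10]^2
}

# all permutations of 1..n, written independently (n small)
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# random DNA sequence guaranteed free of a given site (mutates collisions)
random_seq_without <- function(n, site = "TCGA") {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  repeat {
    str <- paste(s, collapse = "")
    hit <- regexpr(site, str, fixed = TRUE)
    if (hit == -1L) return(str)
    s[as.integer(hit)] <- if (s[as.integer(hit)] == "G") "C" else "G"
  }
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# profile series built directly from a matrix of abundances
series_from_matrix <- function(mat, times = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("S%02d", seq_len(nrow(mat)))
  if (is.null(times)) times <- (seq_len(nrow(mat)) - 1) * 15
  profile_series(mat, times)
}

# random strictly positive abundance matrix over a few bins
random_abundance <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- matrix(rexp(n * m) + 0.05, n, m,
                dimnames = list(sprintf("S%02d", seq_len(n)),
                                seq(100, by = 17, length.out = m)))
  mat / rowSums(mat)
}
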