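# shared fixtures built in code

# n random points strictly inside the probability simplex
random_simplex <- function(n, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(3 * n, shape = 1), ncol = 3)
    g <- g / rowSums(g)
    colnames(g) <- c("f_BD", "f_FD", "f_CD")
    g
  })
}

# tiny wide abundance table from a taxa-by-sample matrix
abund_tbl <- function(m, sample_ids = paste0("s", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% paste0("t", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1..n (tiny n), for exact null enumeration
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))
  }))
}

# flat-topped synthetic spectrum helpers
gauss_spec <- function(x, center, width, area) {
  area / (width * sqrt(2 * pi)) * exp(-(x - center)^2 / (2 * width^2))
}
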