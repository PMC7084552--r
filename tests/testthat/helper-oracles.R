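# Independent brute-force oracles and small fixture builders.

# Gliding-box masses by explicit double loop over window positions,
# returned in the same column-major order as the fast path.
naive_box_masses <- function(m, b) {
  n1 <- nrow(m) - b + 1L
  res <- matrix(0, n1, n1)
  for (j in seq_len(n1)) {
    for (i in seq_len(n1)) {
      res[i, j] <- sum(m[i:(i + b - 1L), j:(j + b - 1L)])
    }
  }
  as.vector(res)
}

# Reference CGR accumulation: one window at a time through the exported
# expansion and position-map operations (slow path, no tabulate/rowsum).
naive_cgr <- function(seq, config) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- config$L
  A <- matrix(0, 2^L, 2^L)
  for (i in seq_len(length(chars) - L + 1L)) {
    ex <- expand_substring(paste(chars[i:(i + L - 1L)], collapse = ""))
    pm <- position_map(ex$strings, config)
    for (k in seq_len(nrow(pm))) {
      A[pm$row[k], pm$col[k]] <- A[pm$row[k], pm$col[k]] + ex$weight
    }
  }
  A
}

# Random IUPAC sequence with a controlled fraction of undetermined symbols.
rand_iupac_seq <- function(n, p_ambig = 0.1) {
  det <- c("a", "c", "g", "t")
  amb <- setdiff(iupac_alphabet(), det)
  sym <- ifelse(stats::runif(n) < p_ambig, sample(amb, n, TRUE),
                sample(det, n, TRUE))
  paste(sym, collapse = "")
}

# The 8 corner assignments related to the default by symmetries of the
# square: flips of the row bit, flips of the column bit, and bit swap.
dihedral_corner_sets <- function() {
  base <- c(c = "00", g = "01", a = "10", t = "11")
  tf <- function(bits, flip_r, flip_c, swap) {
    r <- as.integer(substr(bits, 1, 1)); c <- as.integer(substr(bits, 2, 2))
    if (flip_r) r <- 1L - r
    if (flip_c) c <- 1L - c
    if (swap) { tmp <- r; r <- c; c <- tmp }
    paste0(r, c)
  }
  out <- list()
  for (fr in c(FALSE, TRUE)) for (fc in c(FALSE, TRUE)) for (sw in c(FALSE, TRUE)) {
    out[[length(out) + 1L]] <- vapply(base, tf, character(1),
                                      flip_r = fr, flip_c = fc, swap = sw)
  }
  out
}

# Exact hyperbola samples.
hyperbola_points <- function(b, alpha, beta, gamma) {
  data.frame(b = b, lambda = beta / b^alpha + gamma)
}
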