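# Independent oracles used across the suite.

NONCYS_LETTERS <- setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                            "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                            "W", "Y"), "C")

random_noncys <- function(n) {
  paste(sample(NONCYS_LETTERS, n, replace = TRUE), collapse = "")
}

# Assemble a sequence with one motif of known gaps at a known offset.
planted_sequence <- function(gaps, nterm = 10L, cterm = 10L) {
  paste0(random_noncys(nterm),
         "C", random_noncys(gaps[1]),
         "C", random_noncys(gaps[2]),
         "CC", random_noncys(gaps[3]),
         "C", random_noncys(1L),
         "C", random_noncys(gaps[4]),
         "C", random_noncys(gaps[5]), "C",
         random_noncys(cterm))
}

# Brute-force ECM oracle: enumerate every 8-subset of cysteine positions,
# keep arrangements satisfying the skeleton (CC adjacency, CXC geometry,
# cysteine-free gaps, bounds), order by start then span.
ecm_oracle <- function(sequence, bounds = default_ecm_bounds()) {
  res <- strsplit(sequence, "")[[1]]
  cpos <- which(res == "C")
  if (length(cpos) < 8) return(NULL)
  best <- NULL
  for (combo in utils::combn(cpos, 8, simplify = FALSE)) {
    p <- sort(combo)
    if (p[4] != p[3] + 1) next
    if (p[6] != p[5] + 2) next
    if (res[p[5] + 1] == "C") next
    gaps <- c(p[2] - p[1] - 1, p[3] - p[2] - 1, p[5] - p[4] - 1,
              p[7] - p[6] - 1, p[8] - p[7] - 1)
    # gaps must not contain cysteines
    spans <- list(p[1]:p[2], p[2]:p[3], p[4]:p[5], p[6]:p[7], p[7]:p[8])
    inner_c <- any(vapply(spans, function(s) {
      s <- setdiff(s, p)
      any(res[s] == "C")
    }, logical(1)))
    if (inner_c) next
    ok <- all(vapply(1:5, function(k) {
      b <- bounds[[k]]
      gaps[k] >= b[1] && gaps[k] <= b[2]
    }, logical(1)))
    if (!ok) next
    cand <- list(start = p[1], end = p[8], spacings = gaps,
                 span = p[8] - p[1] + 1)
    if (is.null(best) || cand$start < best$start ||
        (cand$start == best$start && cand$span < best$span)) {
      best <- cand
    }
  }
  best
}

# Rank-then-Pearson Spearman oracle.
spearman_oracle <- function(a, b) {
  1 - stats::cor(rank(a), rank(b), method = "pearson")
}
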