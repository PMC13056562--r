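# Independent brute-force oracles: explicit rank tables and exhaustive
# window/whitelist scans, no shared code with the package internals.

# midranks computed from positions in the sorted pooled vector
bf_midranks <- function(x) {
  s <- sort(x)
  vapply(x, function(v) mean(which(s == v)), numeric(1L))
}

bf_kruskal <- function(groups) {
  x <- unlist(groups)
  rk <- bf_midranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  H0 <- 12 / (N * (N + 1)) *
    sum(tapply(rk, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tt <- 0
  for (v in unique(x)) { t_ <- sum(x == v); tt <- tt + t_^3 - t_ }
  H <- H0 / (1 - tt / (N^3 - N))
  list(H = H, df = length(groups) - 1L,
       p = pchisq(H, length(groups) - 1L, lower.tail = FALSE))
}

bf_dunn <- function(groups) {
  x <- unlist(groups)
  rk <- bf_midranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  tt <- 0
  for (v in unique(x)) { t_ <- sum(x == v); tt <- tt + t_^3 - t_ }
  vb <- N * (N + 1) / 12 - tt / (12 * (N - 1))
  k <- length(groups)
  m <- k * (k - 1) / 2
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    z <- (mean(rk[idx == i]) - mean(rk[idx == j])) /
      sqrt(vb * (1 / sum(idx == i) + 1 / sum(idx == j)))
    p <- 2 * pnorm(-abs(z))
    out <- rbind(out, data.frame(i = i, j = j, z = z, p = p,
                                 p_adj = min(1, p * m)))
  }
  out
}

bf_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# exhaustive anchor scan: min-mismatch window, leftmost tie-break
bf_locate <- function(read, anchor, max_mm) {
  al <- nchar(anchor)
  if (nchar(read) < al) return(NA_integer_)
  best <- NA_integer_; best_mm <- max_mm + 1L
  for (s in 1:(nchar(read) - al + 1L)) {
    mm <- bf_hamming(substr(read, s, s + al - 1L), anchor)
    if (mm < best_mm) { best_mm <- mm; best <- s }
  }
  if (best_mm <= max_mm) best else NA_integer_
}

# exhaustive whitelist assignment with exact-match priority
bf_assign <- function(obs, whitelist, max_mm) {
  d <- vapply(whitelist, bf_hamming, integer(1L), a = obs)
  if (any(d == 0L)) return(whitelist[which(d == 0L)])
  md <- min(d)
  if (md > max_mm) return("unmatched")
  if (sum(d == md) > 1L) return("ambiguous")
  whitelist[which.min(d)]
}

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}

tiny_kit <- function() {
  kit_design(c("AAAAAA", "CCCCCC"), c("P1", "P2"),
             c("cardiac_specific", "liver_specific"))
}
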