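## Independent oracles: deliberately naive re-derivations used to check the
## implementation, never sharing its code paths.

## Poisson upper tail P(X >= k) by direct term-by-term summation
oracle_poisson_upper <- function(k, lambda) {
  if (k <= 0) return(1)
  if (lambda <= 0) return(0)
  i <- k
  t <- exp(-lambda + i * log(lambda) - lgamma(i + 1))
  s <- 0
  repeat {
    s <- s + t
    i <- i + 1
    t <- t * lambda / i
    if (t < s * 1e-17 || t < 1e-320) break
  }
  min(1, s)
}

## Benjamini-Hochberg step-up by the textbook rule
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## Brute-force window scan + merge + retention mirroring the caller's
## documented model, with naive counting and direct-summation p-values
oracle_call_peaks <- function(ip, bg, window = 200, step = 50,
                              merge_gap = 100, min_fold = 5, max_q = 0.05) {
  scale <- nrow(ip$tags) / nrow(bg$tags)
  genome_rate <- nrow(bg$tags) / sum(ip$chrom_lengths)
  rows <- list()
  for (chrom in names(ip$chrom_lengths)) {
    L <- ip$chrom_lengths[[chrom]]
    ipp <- ip$tags$pos[ip$tags$chrom == chrom]
    bgp <- bg$tags$pos[bg$tags$chrom == chrom]
    for (s in seq(0, L - window, by = step)) {
      k <- sum(ipp >= s & ipp < s + window)
      ctr <- s + window / 2
      lam <- genome_rate
      for (flank in c(1000, 10000)) {
        lo <- max(ctr - flank / 2, 0); hi <- min(ctr + flank / 2, L)
        lam <- max(lam, sum(bgp >= lo & bgp < hi) / (hi - lo))
      }
      lam <- lam * window * scale
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = s + window, ip_count = k,
        lambda = lam, p_value = oracle_poisson_upper(k, lam),
        stringsAsFactors = FALSE)
    }
  }
  win <- do.call(rbind, rows)
  win$q_value <- oracle_bh(win$p_value)
  sig <- win[win$q_value < max_q, , drop = FALSE]
  retained <- list()
  for (chrom in unique(sig$chrom)) {
    s <- sig[sig$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    i <- 1
    while (i <= nrow(s)) {
      j <- i
      E <- s$end[i]
      while (j < nrow(s) && s$start[j + 1] - E <= merge_gap) {
        j <- j + 1
        E <- max(E, s$end[j])
      }
      fold <- max(s$ip_count[i:j] / s$lambda[i:j])
      q <- min(s$q_value[i:j])
      if (fold > min_fold && q < max_q)
        retained[[length(retained) + 1L]] <- data.frame(
          chrom = chrom, start = min(s$start[i:j]), end = E,
          stringsAsFactors = FALSE)
      i <- j + 1
    }
  }
  list(windows = win,
       retained = if (length(retained)) do.call(rbind, retained)
                  else data.frame(chrom = character(), start = integer(),
                                  end = integer()))
}

## exact two-sided permutation p-value for the two-group rank-sum statistic
oracle_perm_ranksum <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(all_v), n)
  stats <- apply(combs, 2, function(i) sum(r[i]))
  mu <- n * (length(all_v) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu))
}
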