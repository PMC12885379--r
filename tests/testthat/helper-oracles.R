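# Independent oracles used by the property suites. These deliberately use
# different primitives than the implementation (no rle(), no dhyper()).

# brute-force run-length scan: returns data.frame(start, end) of maximal
# runs of `above` of length >= min_len
oracle_runs <- function(above, min_len) {
  starts <- integer(0); ends <- integer(0)
  i <- 1L; n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        starts <- c(starts, i); ends <- c(ends, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends)
}

# two-sided Fisher p by explicit hypergeometric enumeration from
# log-binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  supp <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(c1, supp) + lchoose(n - c1, r1 - supp) - lchoose(n, r1)
  p <- exp(logp)
  pobs <- exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1))
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# Kruskal-Wallis H recomputed from first principles (explicit mid-ranks
# and the tie-corrected formula)
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x) # mid-ranks
  ni <- lengths(groups)
  idx <- split(seq_len(n), rep(seq_along(groups), ni))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(idx, function(i) sum(r[i])^2 / length(i), 0)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# simple square mask polygon, um
square_mask <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}
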