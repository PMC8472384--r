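# Exact rational-arithmetic oracle for the two-sided Fisher test,
# independent of the package implementation. Hypergeometric point masses
# with both margins fixed are ratios of products of binomial coefficients;
# for margins <= 40 each factor choose(m, x) is an exact double
# (< 2^53), and products/sums are carried in a little-endian base-1e6
# big-integer representation so that tie comparisons and tail sums are
# exact.

big_from <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  digits <- numeric(0)
  while (x > 0) {
    digits <- c(digits, x %% 1e6)
    x <- (x - x %% 1e6) / 1e6
  }
  digits
}

big_trim <- function(x) {
  while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
  x
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- (s[i] - s[i] %% 1e6) / 1e6
    s[i] <- s[i] %% 1e6
  }
  if (carry > 0) s <- c(s, big_from(carry))
  big_trim(s)
}

big_mul <- function(a, b) {
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    carry <- 0
    for (j in seq_along(b)) {
      # a[i], b[j] < 1e6 so the product is < 1e12 + carry, exact in double
      v <- out[i + j - 1] + a[i] * b[j] + carry
      out[i + j - 1] <- v %% 1e6
      carry <- (v - v %% 1e6) / 1e6
    }
    k <- i + length(b)
    while (carry > 0) {
      v <- out[k] + carry
      out[k] <- v %% 1e6
      carry <- (v - v %% 1e6) / 1e6
      k <- k + 1
    }
  }
  big_trim(out)
}

# sign of a - b
big_cmp <- function(a, b) {
  a <- big_trim(a); b <- big_trim(b)
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

big_to_num <- function(x) Reduce(function(acc, d) acc * 1e6 + d, rev(x), 0)

# Two-sided minimum-likelihood p-value, exact. `guard` applies the same
# 1 + 1e-7 relative tolerance as the implementation, evaluated exactly on
# integers: include x iff 1e7 * w_x <= 1e7 * w_obs + w_obs.
oracle_fisher <- function(a, b, c, d, guard = TRUE) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  w <- lapply(support, function(x)
    big_mul(big_from(choose(m, x)), big_from(choose(n, k - x))))
  w_obs <- w[[match(a, support)]]
  rhs <- big_add(big_mul(w_obs, big_from(1e7)), w_obs)
  num <- 0; den <- 0
  for (i in seq_along(support)) {
    den <- big_add(den, w[[i]])
    ok <- if (guard) big_cmp(big_mul(w[[i]], big_from(1e7)), rhs) <= 0
          else big_cmp(w[[i]], w_obs) <= 0
    if (ok) num <- big_add(num, w[[i]])
  }
  big_to_num(num) / big_to_num(den)
}
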