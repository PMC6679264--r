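# Fixtures built in code; everything deterministic given the stated seeds.

# smooth low-contrast field on a bright offset (gradients well below edge
# strength, so conduction coefficients stay near their flat-region values)
smooth_field <- function(n = 48, offset = 100, amp = 2) {
  outer(seq_len(n), seq_len(n),
        function(i, j) offset + amp * exp(-((i - n / 2)^2 + (j - n / 2)^2) / 80))
}

# vertical step edge: value lo in the left columns, hi in the right
step_image <- function(n = 32, split = NULL, lo = 50, hi = 200) {
  if (is.null(split)) split <- n %/% 2
  m <- matrix(lo, n, n)
  m[, (split + 1):n] <- hi
  m
}

random_image <- function(n = 32, seed = 1, lo = 10, hi = 200) {
  set.seed(seed)
  matrix(runif(n * n, lo, hi), n, n)
}

block_rgb <- function(n = 64) {
  ch <- matrix(30, n, n)
  ch[1:(n / 2), 1:(n / 2)] <- 200
  ch[(n / 2 + 1):n, (n / 2 + 1):n] <- 120
  arr <- array(0, c(n, n, 3))
  arr[, , 1] <- ch
  arr[, , 2] <- ch[n:1, ]
  arr[, , 3] <- t(ch)
  arr
}
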