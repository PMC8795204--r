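# Conference matrices C of orders 6-16: zero diagonal, off-diagonal +/-1,
# C %*% t(C) = (n-1) I. Orders 6, 10, 14 are symmetric Paley matrices
# (q = 5, 9, 13); orders 8, 12 are skew Paley (q = 7, 11); order 16 is a
# block doubling of the order-8 matrix. Verified at load time in .onLoad().
.conference_matrices <- list(
  "6" = matrix(c(
    0, 1, 1, 1, 1, 1, 1, 0, 1, -1, -1, 1, 1, 1, 0, 1, -1, -1, 1, -1, 1, 0,
    1, -1, 1, -1, -1, 1, 0, 1, 1, 1, -1, -1, 1, 0
  ), nrow = 6, ncol = 6),
  "8" = matrix(c(
    0, -1, -1, -1, -1, -1, -1, -1, 1, 0, 1, 1, -1, 1, -1, -1, 1, -1, 0, 1,
    1, -1, 1, -1, 1, -1, -1, 0, 1, 1, -1, 1, 1, 1, -1, -1, 0, 1, 1, -1, 1,
    -1, 1, -1, -1, 0, 1, 1, 1, 1, -1, 1, -1, -1, 0, 1, 1, 1, 1, -1, 1, -1,
    -1, 0
  ), nrow = 8, ncol = 8),
  "10" = matrix(c(
    0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 1, 1, 1, -1, -1, 1, -1, -1, 1, 1,
    0, 1, -1, 1, -1, -1, 1, -1, 1, 1, 1, 0, -1, -1, 1, -1, -1, 1, 1, 1,
    -1, -1, 0, 1, 1, 1, -1, -1, 1, -1, 1, -1, 1, 0, 1, -1, 1, -1, 1, -1,
    -1, 1, 1, 1, 0, -1, -1, 1, 1, 1, -1, -1, 1, -1, -1, 0, 1, 1, 1, -1, 1,
    -1, -1, 1, -1, 1, 0, 1, 1, -1, -1, 1, -1, -1, 1, 1, 1, 0
  ), nrow = 10, ncol = 10),
  "12" = matrix(c(
    0, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, 1, 0, 1, -1, 1, 1, 1,
    -1, -1, -1, 1, -1, 1, -1, 0, 1, -1, 1, 1, 1, -1, -1, -1, 1, 1, 1, -1,
    0, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1, 1, -1, 0, 1, -1, 1, 1, 1, -1,
    -1, 1, -1, -1, 1, -1, 0, 1, -1, 1, 1, 1, -1, 1, -1, -1, -1, 1, -1, 0,
    1, -1, 1, 1, 1, 1, 1, -1, -1, -1, 1, -1, 0, 1, -1, 1, 1, 1, 1, 1, -1,
    -1, -1, 1, -1, 0, 1, -1, 1, 1, 1, 1, 1, -1, -1, -1, 1, -1, 0, 1, -1,
    1, -1, 1, 1, 1, -1, -1, -1, 1, -1, 0, 1, 1, 1, -1, 1, 1, 1, -1, -1,
    -1, 1, -1, 0
  ), nrow = 12, ncol = 12),
  "14" = matrix(c(
    0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 1, -1, 1, 1, -1, -1,
    -1, -1, 1, 1, -1, 1, 1, 1, 0, 1, -1, 1, 1, -1, -1, -1, -1, 1, 1, -1,
    1, -1, 1, 0, 1, -1, 1, 1, -1, -1, -1, -1, 1, 1, 1, 1, -1, 1, 0, 1, -1,
    1, 1, -1, -1, -1, -1, 1, 1, 1, 1, -1, 1, 0, 1, -1, 1, 1, -1, -1, -1,
    -1, 1, -1, 1, 1, -1, 1, 0, 1, -1, 1, 1, -1, -1, -1, 1, -1, -1, 1, 1,
    -1, 1, 0, 1, -1, 1, 1, -1, -1, 1, -1, -1, -1, 1, 1, -1, 1, 0, 1, -1,
    1, 1, -1, 1, -1, -1, -1, -1, 1, 1, -1, 1, 0, 1, -1, 1, 1, 1, 1, -1,
    -1, -1, -1, 1, 1, -1, 1, 0, 1, -1, 1, 1, 1, 1, -1, -1, -1, -1, 1, 1,
    -1, 1, 0, 1, -1, 1, -1, 1, 1, -1, -1, -1, -1, 1, 1, -1, 1, 0, 1, 1, 1,
    -1, 1, 1, -1, -1, -1, -1, 1, 1, -1, 1, 0
  ), nrow = 14, ncol = 14),
  "16" = matrix(c(
    0, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, 1, 0,
    1, 1, -1, 1, -1, -1, 1, -1, 1, 1, -1, 1, -1, -1, 1, -1, 0, 1, 1, -1,
    1, -1, 1, -1, -1, 1, 1, -1, 1, -1, 1, -1, -1, 0, 1, 1, -1, 1, 1, -1,
    -1, -1, 1, 1, -1, 1, 1, 1, -1, -1, 0, 1, 1, -1, 1, 1, -1, -1, -1, 1,
    1, -1, 1, -1, 1, -1, -1, 0, 1, 1, 1, -1, 1, -1, -1, -1, 1, 1, 1, 1,
    -1, 1, -1, -1, 0, 1, 1, 1, -1, 1, -1, -1, -1, 1, 1, 1, 1, -1, 1, -1,
    -1, 0, 1, 1, 1, -1, 1, -1, -1, -1, 1, -1, -1, -1, -1, -1, -1, -1, 0,
    1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, -1, 1, -1, -1, -1, 0, -1, -1, 1, -1,
    1, 1, 1, -1, 1, 1, 1, -1, 1, -1, -1, 1, 0, -1, -1, 1, -1, 1, 1, -1,
    -1, 1, 1, 1, -1, 1, -1, 1, 1, 0, -1, -1, 1, -1, 1, 1, -1, -1, 1, 1, 1,
    -1, -1, -1, 1, 1, 0, -1, -1, 1, 1, -1, 1, -1, -1, 1, 1, 1, -1, 1, -1,
    1, 1, 0, -1, -1, 1, 1, -1, 1, -1, -1, 1, 1, -1, -1, 1, -1, 1, 1, 0,
    -1, 1, 1, 1, -1, 1, -1, -1, 1, -1, -1, -1, 1, -1, 1, 1, 0
  ), nrow = 16, ncol = 16)
)
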