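# Shared fixture builders: everything is generated in code at test time.

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Horn's closed-form quaternion solution to the absolute-orientation
# problem: an independent oracle for Kabsch/SVD registration.
horn_registration <- function(P, Q) {
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  S <- crossprod(Pc, Qc)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  list(R = R, t = qbar - as.numeric(R %*% pbar))
}

# argmin/argmax after light symmetric smoothing: robust to near-ties on
# flat curve bottoms sampled on an even grid
smooth_argmin <- function(x, k = 3) which.min(box_smooth(x, k))
smooth_argmax <- function(x, k = 3) which.max(box_smooth(x, k))

tiny_marker_csv <- function(path, blanks = FALSE) {
  txt <- c("m1_X,m1_Y,m1_Z,m2_X,m2_Y,m2_Z",
           "0,0,0,1,2,2",
           if (blanks) "0.1,0.1," else "0.1,0.1,0.1",
           "0.2,0.2,0.2,1.2,2.2,2.2")
  if (blanks) txt[3] <- "0.1,0.1,,1.1,2.1,2.1" else
    txt[3] <- "0.1,0.1,0.1,1.1,2.1,2.1"
  writeLines(txt, path)
  path
}
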