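# Shared helpers: small constructors and an independent reference SMACOF
# used as an oracle for the weight-zero path. The reference is written as a
# plain elementwise loop straight from the textbook update and shares no
# code with the package's implementation.

toy_loci <- function(n, chrom = "chrT", bin = 1e5) {
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin,
             end = seq_len(n) * bin, stringsAsFactors = FALSE)
}

dist_obj <- function(delta, chrom = "chrT") {
  hic_distances(toy_loci(nrow(delta), chrom), delta)
}

struct_obj <- function(coords, chrom = "chrT") {
  hic_structure(toy_loci(nrow(coords), chrom), coords)
}

# Reference SMACOF: plain majorization loop, elementwise B matrix, stopping
# on relative stress decrease; zero target distances are skipped.
reference_smacof <- function(delta, x0, max_iter = 300, tol = 1e-4) {
  n <- nrow(delta)
  x <- x0
  raw_stress <- function(x) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (delta[i, j] > 0) {
        dij <- sqrt(sum((x[i, ] - x[j, ])^2))
        s <- s + (dij - delta[i, j])^2
      }
    }
    s
  }
  s_prev <- raw_stress(x)
  floor_s <- 1e-12 * sum(delta[upper.tri(delta)]^2)
  for (it in seq_len(max_iter)) {
    b <- matrix(0, n, n)
    dx <- as.matrix(dist(x))
    for (i in 1:n) for (j in 1:n) {
      if (i != j && delta[i, j] > 0 && dx[i, j] > 0)
        b[i, j] <- -delta[i, j] / dx[i, j]
    }
    for (i in 1:n) b[i, i] <- -sum(b[i, -i])
    x <- (b %*% x) / n
    s_cur <- raw_stress(x)
    if (s_cur <= floor_s || s_prev - s_cur < tol * max(s_prev, .Machine$double.eps))
      break
    s_prev <- s_cur
  }
  list(x = x, stress = s_cur)
}

# random rotation matrix via QR of a Gaussian matrix, determinant forced +1
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

expect_no_peaks_or <- function(peaks, allowed) {
  expect_true(all(peaks$index %in% allowed))
}
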