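test_that("stress evaluates the penalized loss exactly", {
  # 2 points, both targets 1, structures identical and perfect: stress 0;
  # shifting X2 by a unit along z adds only the penalty, 2 * 0.5 * 1 = 1
  x1 <- struct_obj(rbind(c(0, 0, 0), c(1, 0, 0)))
  d <- dist_obj(sym2 <- matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(stress(x1, x1, d, d, w = 0.5), 0)
  x2 <- struct_obj(rbind(c(0, 0, 1), c(1, 0, 1)))
  expect_equal(stress(x1, x2, d, d, w = 0.5), 1)

  # missing pairs are excluded from the fit term per condition
  x3 <- struct_obj(rbind(c(0, 0, 0), c(2, 0, 0)))
  dmiss <- dist_obj(matrix(0, 2, 2))
  expect_equal(stress(x3, x3, dmiss, d, w = 0), 1)  # only condition 2 counts

  # identical structures always have zero penalty
  set.seed(1)
  xr <- struct_obj(matrix(rnorm(30), 10, 3))
  dr <- dist_obj(as.matrix(dist(matrix(rnorm(30), 10, 3))))
  expect_equal(stress(xr, xr, dr, dr, w = 5),
               stress(xr, xr, dr, dr, w = 0))
})

test_that("the Guttman transform has the classic fixed point and 2-point solution", {
  # perfect embedding is a fixed point
  set.seed(2)
  co <- matrix(rnorm(24), 8, 3)
  co <- sweep(co, 2, colMeans(co))
  d <- dist_obj(as.matrix(dist(co)))
  expect_equal(guttman_transform(struct_obj(co), d), co, tolerance = 1e-10)

  # 2 points at distance 2 with target 1 land at distance 1, centered
  z <- struct_obj(rbind(c(-1, 0, 0), c(1, 0, 0)))
  up <- guttman_transform(z, dist_obj(matrix(c(0, 1, 1, 0), 2, 2)))
  expect_equal(up, rbind(c(-0.5, 0, 0), c(0.5, 0, 0)))

  # a row with all-missing targets is pulled to the origin
  dm <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  up3 <- guttman_transform(struct_obj(diag(3)), dist_obj(dm))
  expect_equal(up3[3, ], c(0, 0, 0))

  expect_error(guttman_transform(struct_obj(matrix(0, 1, 3)), d), "at least 2")
})

test_that("the penalized update blends the similarity and Guttman pulls", {
  z <- struct_obj(rbind(c(-1, 0, 0), c(1, 0, 0)))
  d <- dist_obj(matrix(c(0, 2, 2, 0), 2, 2))  # already perfect
  g <- guttman_transform(z, d)
  # w = 0 reduces to the plain Guttman update
  expect_equal(penalized_update(z, z, d, w = 0), g)
  # w = 1 with partner at (2,0,0) and Guttman row (0,0,0): midpoint
  zz <- struct_obj(rbind(c(0, 0, 0), c(0, 0, 0)))
  dn <- dist_obj(matrix(0, 2, 2))
  other <- struct_obj(rbind(c(2, 0, 0), c(2, 0, 0)))
  expect_equal(penalized_update(other, zz, dn, w = 1),
               rbind(c(1, 0, 0), c(1, 0, 0)))
  # large w converges to the partner's coordinates
  up <- penalized_update(other, z, d, w = 1e9)
  expect_equal(up, other$coords, tolerance = 1e-6)
  expect_error(penalized_update(other, z, d, w = -1), "non-negative")
})

test_that("joint embedding of exact helix distances recovers the structure", {
  s <- make_structure(fixture_spec(20, "helix"))
  d <- hic_distances(s$loci, as.matrix(dist(s$coords)))
  fit <- joint_mds(d, d, weight = 0.05, seed = 1)
  # the two structures coincide and match the helix up to rigid motion
  # (and possibly reflection, which distances cannot identify)
  expect_lt(rmsd(fit$x1, fit$x2), 1e-6)
  mirror <- hic_structure(s$loci, s$coords %*% diag(c(1, 1, -1)))
  r <- min(kabsch(fit$x1, s)$rmsd, kabsch(fit$x1, mirror)$rmsd)
  expect_lt(r, 0.01 * 1)  # helix radius is 1
})

test_that("stress is non-increasing within a restart and output is centered", {
  set.seed(5)
  for (w in c(0, 0.05, 0.5)) {
    co <- matrix(rnorm(45), 15, 3)
    noisy <- function() {
      d <- as.matrix(dist(co)) * exp(matrix(rnorm(225, 0, 0.2), 15, 15))
      d <- (d + t(d)) / 2; diag(d) <- 0
      dist_obj(d)
    }
    fit <- joint_mds(noisy(), noisy(), weight = w, n_init = 2,
                     seed = sample.int(1000, 1))
    expect_true(all(diff(fit$stress_trace) <=
                      1e-9 * max(fit$stress_trace[1], 1)))
    expect_lt(max(abs(colMeans(fit$x1$coords))), 1e-9)
    expect_lt(max(abs(colMeans(fit$x2$coords))), 1e-9)
  }
})

test_that("swapping the input matrices swaps the output structures exactly", {
  set.seed(6)
  co1 <- matrix(rnorm(36), 12, 3); co2 <- matrix(rnorm(36), 12, 3)
  d1 <- dist_obj(as.matrix(dist(co1)))
  d2 <- dist_obj(as.matrix(dist(co2)))
  f12 <- joint_mds(d1, d2, weight = 0.1, seed = 42, n_init = 2)
  f21 <- joint_mds(d2, d1, weight = 0.1, seed = 42, n_init = 2)
  expect_identical(f12$x1$coords, f21$x2$coords)
  expect_identical(f12$x2$coords, f21$x1$coords)
  expect_identical(f12$final_stress, f21$final_stress)
})

test_that("weight zero reproduces an independent reference SMACOF", {
  set.seed(8)
  co <- matrix(rnorm(45), 15, 3)
  delta <- as.matrix(dist(co)) * exp(matrix(rnorm(225, 0, 0.15), 15, 15))
  delta <- (delta + t(delta)) / 2; diag(delta) <- 0
  d <- dist_obj(delta)
  fit <- joint_mds(d, d, weight = 0, n_init = 1, seed = 99)
  # rebuild the shared initial configuration the same way the fit does
  set.seed(99)
  x0 <- jointmds:::random_init(15, 3, mean(delta[upper.tri(delta)]))
  ref <- reference_smacof(delta, x0)
  expect_equal(embedding_error(fit$x1, d)^2 * sum(upper.tri(delta)),
               ref$stress, tolerance = 1e-6)
  expect_equal(fit$x1$coords, sweep(ref$x, 2, colMeans(ref$x)),
               tolerance = 1e-8)
})

test_that("the penalty term shrinks as the similarity weight grows", {
  set.seed(9)
  co <- matrix(rnorm(60), 20, 3)
  mk <- function() {
    d <- as.matrix(dist(co)) * exp(matrix(rnorm(400, 0, 0.25), 20, 20))
    d <- (d + t(d)) / 2; diag(d) <- 0
    dist_obj(d)
  }
  d1 <- mk(); d2 <- mk()
  pen <- vapply(c(0.01, 0.05, 0.2, 1), function(w) {
    meds <- vapply(1:3, function(s) {
      fit <- joint_mds(d1, d2, weight = w, n_init = 2, seed = s)
      mean(rowSums((fit$x1$coords - fit$x2$coords)^2))
    }, numeric(1))
    median(meds)
  }, numeric(1))
  expect_true(all(diff(pen) <= 1e-9))
})

test_that("classical recovery: exact distances, weight zero", {
  set.seed(10)
  co <- matrix(rnorm(90), 30, 3)
  co <- sweep(co, 2, colMeans(co))
  d <- dist_obj(as.matrix(dist(co)))
  fit <- joint_mds(d, d, weight = 0, seed = 4)
  truth <- struct_obj(co)
  mirror <- struct_obj(co %*% diag(c(1, 1, -1)))
  r <- min(kabsch(fit$x1, truth)$rmsd, kabsch(fit$x1, mirror)$rmsd)
  expect_lt(r, 1e-3 * max(dist(co)))
})

test_that("planted single-locus relocalization is ranked first", {
  hits <- 0
  for (s in 1:10) {
    pr <- make_reloc_pair(seed = s)
    dp <- prepare_distance_pair(pr$a, pr$b)
    fit <- joint_mds(dp$d1, dp$d2, weight = 0.05, seed = s, n_init = 2)
    prof <- relocalization_profile(fit)
    if (which.max(prof$magnitude) == pr$locus) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("embedding error is computed over nonmissing pairs", {
  x <- struct_obj(rbind(c(0, 0, 0), c(2, 0, 0)))
  d <- dist_obj(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(embedding_error(x, d), 1)
  dperf <- dist_obj(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(embedding_error(x, dperf), 0)
  expect_error(embedding_error(x, dist_obj(matrix(0, 2, 2))), "no nonmissing")
})

test_that("the similarity penalty degrades embedding accuracy only mildly", {
  s <- make_structure(fixture_spec(40, "helix"))
  cc <- structure_to_contacts(s, noise_sd = 0.2, seed = 1)
  d <- contacts_to_distances(cc)
  e0 <- embedding_error(joint_mds(d, d, weight = 0, seed = 1)$x1, d)
  e5 <- embedding_error(joint_mds(d, d, weight = 0.5, seed = 1)$x1, d)
  expect_lte(e5, 1.25 * e0)
})

test_that("weight selection returns the smallest plateau weight and its curve", {
  s <- make_structure(fixture_spec(25, "helix"))
  d <- hic_distances(s$loci, as.matrix(dist(s$coords)))
  # identical noiseless inputs: reproducibility ~1 at all positive weights
  sel <- select_similarity_weight(d, d, c(0.01, 0.05), n_runs = 2, seed = 1,
                                  n_init = 1)
  expect_equal(sel$weight, 0.01)
  expect_true(all(sel$curve$reproducibility[sel$curve$weight > 0] > 0.99))
  # a single candidate is returned unconditionally
  sel1 <- select_similarity_weight(d, d, 0.3, n_runs = 2, seed = 1, n_init = 1)
  expect_equal(sel1$weight, 0.3)
  expect_equal(nrow(sel1$curve), 1)
  expect_error(select_similarity_weight(d, d, numeric(0)), "at least one")
})

test_that("fit object methods expose the model summary", {
  pr <- make_reloc_pair(n_loci = 20, seed = 2)
  dp <- prepare_distance_pair(pr$a, pr$b)
  fit <- joint_mds(dp$d1, dp$d2, weight = 0.05, seed = 1, n_init = 2)
  expect_s3_class(fit, "joint_mds_fit")
  expect_output(print(fit), "Joint MDS fit")
  sm <- summary(fit)
  expect_output(print(sm), "embedding error")
  cf <- coef(fit)
  expect_equal(dim(cf$x1), c(20, 3))
  rs <- residuals(fit)
  expect_equal(length(rs$condition1), sum(upper.tri(dp$d1$delta) & dp$d1$delta > 0))
  ft <- fitted(fit)
  expect_equal(ft$d1, ft$d1, tolerance = 0)
  expect_equal(dim(ft$d2), c(20, 20))
})
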