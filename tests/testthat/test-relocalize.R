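test_that("relocalization profiles are displacement norms over shared loci", {
  set.seed(1)
  co <- matrix(rnorm(60), 20, 3)
  fit <- list(x1 = struct_obj(co), x2 = struct_obj(co))
  prof <- relocalization_profile(fit)
  expect_equal(prof$magnitude, rep(0, 20))

  co2 <- co
  co2[7, ] <- co2[7, ] + c(1, 2, 2)
  fit2 <- list(x1 = struct_obj(co), x2 = struct_obj(co2))
  prof2 <- relocalization_profile(fit2)
  expect_equal(prof2$magnitude[7], 3)
  expect_equal(prof2$magnitude[-7], rep(0, 19))
  expect_equal(prof2$magnitude, sqrt(rowSums(prof2$displacement^2)),
               tolerance = 1e-12)

  # swapping the pair negates displacements, magnitudes unchanged
  prof_sw <- relocalization_profile(list(x1 = fit2$x2, x2 = fit2$x1))
  expect_equal(prof_sw$displacement, -prof2$displacement)
  expect_equal(prof_sw$magnitude, prof2$magnitude)

  # absent loci are absent from the profile
  co3 <- co; co3[3, ] <- NA
  prof3 <- relocalization_profile(list(x1 = struct_obj(co3), x2 = struct_obj(co)))
  expect_equal(nrow(prof3$loci), 19)
})

test_that("a flat profile yields no peaks", {
  pk <- call_peaks(rep(1, 100))
  expect_equal(nrow(pk), 0)
})

test_that("a planted Gaussian bump is found within 2 bins nearly always", {
  hits <- 0
  draws <- 100
  for (s in seq_len(draws)) {
    set.seed(s)
    x <- abs(rnorm(200, 0, 0.1))
    x <- x + 1 * exp(-(seq_len(200) - 100)^2 / (2 * 3^2))  # 10x baseline noise
    pk <- call_peaks(x)
    if (any(abs(pk$index - 100) <= 2)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("two well-separated bumps give two ordered peaks", {
  set.seed(11)
  x <- abs(rnorm(200, 0, 0.1))
  x <- x + exp(-(seq_len(200) - 60)^2 / 18) + exp(-(seq_len(200) - 140)^2 / 18)
  pk <- call_peaks(x)
  near60 <- pk$index[abs(pk$index - 60) <= 2]
  near140 <- pk$index[abs(pk$index - 140) <= 2]
  expect_equal(length(near60), 1)
  expect_equal(length(near140), 1)
  expect_true(all(diff(pk$index) > 0))  # ordered by position
})

test_that("peak positions are translation-equivariant", {
  set.seed(12)
  sig <- abs(rnorm(100, 0, 0.05)) + exp(-(seq_len(100) - 50)^2 / 18)
  x <- c(rep(0, 10), sig, rep(0, 60))
  y <- c(rep(0, 40), sig, rep(0, 30))  # same signal shifted by 30 bins
  p1 <- call_peaks(x)
  p2 <- call_peaks(y)
  main1 <- p1$index[which.min(abs(p1$index - 60))]
  main2 <- p2$index[which.min(abs(p2$index - 90))]
  expect_lte(abs((main2 - main1) - 30), 1)
})

test_that("short profiles truncate the width range with a warning", {
  expect_warning(pk <- call_peaks(c(0, 1, 0, 0, 1, 0, 2, 0), widths = 1:10),
                 "truncated")
  expect_true(is.data.frame(pk))
})

test_that("compartment filtering is strict and partitioning is exhaustive", {
  prof <- structure(list(loci = toy_loci(50),
                         displacement = matrix(0, 50, 3),
                         magnitude = rep(0, 50),
                         peaks = data.frame(index = c(5, 10, 20, 30),
                                            width_class = 1L, snr = 2)),
                    class = "reloc_profile")
  diff0 <- rep(0, 50)
  expect_equal(nrow(filter_peaks_by_compartment(prof, diff0)$peaks), 4)
  diff1 <- rep(1, 50)
  expect_equal(nrow(filter_peaks_by_compartment(prof, diff1)$peaks), 0)
  # exactly at the threshold -> dropped (strict inequality)
  diffe <- rep(0, 50); diffe[10] <- 0.2
  expect_equal(filter_peaks_by_compartment(prof, diffe)$peaks$index, c(5, 20, 30))
  # missing difference -> dropped with warning
  diffna <- rep(0, 50); diffna[5] <- NA
  expect_warning(out <- filter_peaks_by_compartment(prof, diffna), "dropped")
  expect_equal(out$peaks$index, c(10, 20, 30))

  mk_track <- function(sc) structure(list(loci = toy_loci(50), score = sc,
                                          pc1_variance_fraction = 0.5),
                                     class = "compartment_track")
  sa <- rep(0.4, 50); sb <- rep(0.3, 50)
  sa[10] <- -0.4; sb[10] <- -0.1   # intra-B
  sb[20] <- -0.1                   # discordant
  sp <- split_peaks_by_compartment(c(5, 10, 20, 30), mk_track(sa), mk_track(sb))
  expect_equal(sp$intra_A, c(5, 30))
  expect_equal(sp$intra_B, 10)
  expect_equal(sp$discordant, 20)
  expect_equal(length(sp$intra_A) + length(sp$intra_B) + length(sp$discordant), 4)
})

test_that("virtual 4C extracts viewpoint rows with the viewpoint masked", {
  set.seed(13)
  n <- 30
  m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
  hc <- hic_contacts(toy_loci(n), m, 1e5)
  # single-bin viewpoint: exactly that row
  prof <- virtual_4c(hc, c(5e5, 6e5))
  expect_true(is.na(prof[6]))
  expect_equal(prof[-6], hc$mat[6, -6])
  # two-bin viewpoint: elementwise mean of the two rows
  prof2 <- virtual_4c(hc, c(5e5, 7e5))
  expect_true(all(is.na(prof2[6:7])))
  expect_equal(prof2[-(6:7)], colMeans(hc$mat[6:7, ])[-(6:7)])
  expect_error(virtual_4c(hc, c(9e6, 9.1e6)), "outside")
})

test_that("a planted distal loop dominates the virtual 4C profile", {
  s <- abs(row(diag(60)) - col(diag(60)))
  m <- 10 / (1 + s)
  diag(m) <- 0
  m[10, 45] <- m[45, 10] <- 12   # planted loop between bins 10 and 45
  hc <- hic_contacts(toy_loci(60), m, 1e5)
  prof <- virtual_4c(hc, c(9e5, 10e5))  # viewpoint = bin 10
  distal <- prof
  distal[1:20] <- NA  # mask the local decay neighborhood
  expect_equal(which.max(distal), 45)
})

test_that("coverage enrichment matches the interval arithmetic and null", {
  peaks <- data.frame(chrom = "chr1", start = c(0, 200), end = c(100, 300))
  background <- data.frame(chrom = "chr1", start = c(400, 600),
                           end = c(500, 700))
  everything <- data.frame(chrom = "chr1", start = 0, end = 1000)
  out <- coverage_enrichment(peaks, background, everything)
  expect_equal(out$enrichment, 1)
  expect_equal(out$peak_coverage, c(1, 1))

  # features identical to peaks, disjoint from background: infinite ratio
  out2 <- coverage_enrichment(peaks, background, peaks)
  expect_equal(out2$enrichment, Inf)
  expect_equal(out2$background_coverage, c(0, 0))

  # half-open semantics: feature [0,50) covers half of [0,100)
  half <- data.frame(chrom = "chr1", start = 0, end = 50)
  out3 <- coverage_enrichment(peaks[1, ], background, half)
  expect_equal(out3$peak_coverage, 0.5)

  expect_error(coverage_enrichment(peaks[0, ], background, everything),
               "non-empty")

  # null: peaks and background drawn from the same process -> p roughly flat
  set.seed(14)
  pv <- replicate(20, {
    st <- sort(sample.int(1e5, 40)) * 10
    iv <- data.frame(chrom = "chr1", start = st, end = st + 50)
    feat_st <- sample.int(1e6, 300)
    feats <- data.frame(chrom = "chr1", start = feat_st, end = feat_st + 100)
    grp <- sample(rep(c(TRUE, FALSE), 20))
    coverage_enrichment(iv[grp, ], iv[!grp, ], feats)$p_value
  })
  expect_gt(mean(pv > 0.05), 0.6)
})

test_that("peak intervals and relocalization tables round-trip to disk", {
  pr <- make_reloc_pair(n_loci = 20, seed = 3)
  dp <- prepare_distance_pair(pr$a, pr$b)
  fit <- joint_mds(dp$d1, dp$d2, weight = 0.05, seed = 1, n_init = 2)
  prof <- call_peaks(relocalization_profile(fit))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_relocalization(prof, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$magnitude, prof$magnitude, tolerance = 1e-6)
  iv <- peak_intervals(prof)
  expect_true(all(c("chrom", "start", "end", "magnitude") %in% names(iv)))
  expect_equal(nrow(iv), nrow(prof$peaks))
})
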