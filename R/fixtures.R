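# Synthetic ground-truth generators: 3D chains whose contacts follow the
# inverse fourth-power law c ~ d^-4, with planted single-locus
# relocalizations, shifted domain boundaries, or compartment-block flips
# between two conditions. Everything an algorithmic claim needs can be
# planted and recovered without external data. All generators are pure
# functions of their arguments and seed.

#' Specification for a synthetic structure fixture
#'
#' @param n_loci number of loci (>= 10).
#' @param base_geometry `"helix"` (fixed radius 1, pitch 0.3, angular step
#'   0.5 rad, so consecutive loci are equidistant) or `"random_walk"`
#'   (unit-length steps in uniformly random directions).
#' @param noise_sd standard deviation of the log-normal multiplicative
#'   contact noise used by [structure_to_contacts()]; default 0.
#' @param planted list of perturbation descriptors, each a list with
#'   `type = "displace"`, `locus` (1-based index) and `vector` (length-3
#'   displacement).
#' @param seed integer seed.
#' @param bin_size,chrom genomic annotation of the fixture loci.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_loci, base_geometry = c("helix", "random_walk"),
                         noise_sd = 0, planted = list(), seed = 1,
                         bin_size = 100000, chrom = "chrS") {
  base_geometry <- match.arg(base_geometry)
  if (n_loci < 10) stop("fixtures need at least 10 loci")
  for (p in planted)
    if (p$locus < 1 || p$locus > n_loci)
      stop("perturbation locus outside the structure")
  structure(list(n_loci = as.integer(n_loci), base_geometry = base_geometry,
                 noise_sd = noise_sd, planted = planted, seed = seed,
                 bin_size = bin_size, chrom = chrom),
            class = "fixture_spec")
}

fixture_loci <- function(spec) {
  new_locus_table(spec$chrom, (seq_len(spec$n_loci) - 1) * spec$bin_size,
                  spec$bin_size)
}

#' Generate a ground-truth 3D structure from a fixture spec
#'
#' Deterministic given the spec's seed. Planted displacements are applied on
#' top of the base geometry.
#'
#' @param spec a [fixture_spec()].
#' @return A [hic_structure()].
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_loci
  set.seed(as.integer(spec$seed))
  coords <- switch(spec$base_geometry,
    helix = {
      t <- (seq_len(n) - 1) * 0.5
      cbind(cos(t), sin(t), 0.3 * t)
    },
    random_walk = {
      steps <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2))
      rbind(0, apply(steps, 2, cumsum))
    })
  for (p in spec$planted) {
    if (!identical(p$type, "displace")) stop("unknown perturbation type: ", p$type)
    coords[p$locus, ] <- coords[p$locus, ] + p$vector
  }
  hic_structure(fixture_loci(spec), coords)
}

#' Contacts implied by a structure under the inverse power law
#'
#' Inverts the contact-to-distance conversion: `c_ij = d_ij(X) ^
#' (1 / exponent_inv)` (default `d^-4`, the inverse of the `c^-1/4` distance
#' law), optionally multiplied by log-normal noise `exp(N(0, noise_sd^2))`.
#' With zero noise, [contacts_to_distances()] recovers the pairwise
#' distances exactly.
#'
#' @param x a [hic_structure()] with no coincident points.
#' @param exponent_inv distance exponent whose reciprocal generates the
#'   contacts; default -0.25.
#' @param noise_sd log-normal noise SD; default 0.
#' @param seed integer seed for the noise draws.
#' @return A [hic_contacts()] object.
#' @export
structure_to_contacts <- function(x, exponent_inv = -0.25, noise_sd = 0,
                                  seed = 1) {
  stopifnot(inherits(x, "hic_structure"))
  d <- euclid_dist(x$coords)
  if (any(d[upper.tri(d)] <= 0)) stop("coincident points have no finite contact")
  cmat <- d ^ (1 / exponent_inv)
  diag(cmat) <- 0
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    n <- nrow(cmat)
    noise <- matrix(0, n, n)
    noise[upper.tri(noise)] <- stats::rnorm(sum(upper.tri(noise)), 0, noise_sd)
    noise <- noise + t(noise)
    cmat <- cmat * exp(noise)
  }
  hic_contacts(x$loci, cmat, x$loci$end[1] - x$loci$start[1])
}

decay_baseline <- function(n, depth) {
  s <- abs(row(diag(n)) - col(diag(n)))
  lam <- depth / (1 + s)
  diag(lam) <- 0
  lam
}

#' Contact-matrix pair with a shifted domain boundary
#'
#' Block-model contacts over a shared distance-decay baseline
#' (`depth / (1 + s)` at separation `s` bins): pairs within the same domain
#' are enriched by `within_enrich`. The two conditions are identical except
#' that the domain boundary sits at bin `boundary_a` in the first and
#' `boundary_b` in the second (1-based index of the first bin of the second
#' domain), so only the loci between the two boundaries change their
#' contact pattern. Independent Poisson noise is drawn for each condition.
#'
#' @param n_loci number of bins; default 200.
#' @param boundary_a,boundary_b boundary bins (interior, distinct);
#'   defaults 100 and 105.
#' @param within_enrich within-domain enrichment factor; default 3.
#' @param depth expected short-range contact count; default 100.
#' @param seed integer seed.
#' @param bin_size,chrom locus annotation.
#' @return A list with [hic_contacts()] elements `a` and `b` and the planted
#'   `boundaries`.
#' @export
make_boundary_pair <- function(n_loci = 200, boundary_a = 100, boundary_b = 105,
                               within_enrich = 3, depth = 100, seed = 1,
                               bin_size = 100000, chrom = "chrS") {
  if (boundary_a == boundary_b) stop("boundaries must differ")
  for (b in c(boundary_a, boundary_b))
    if (b <= 1 || b >= n_loci) stop("boundary at the matrix edge")
  loci <- new_locus_table(chrom, (seq_len(n_loci) - 1) * bin_size, bin_size)
  base <- decay_baseline(n_loci, depth)
  lam_for <- function(boundary) {
    dom <- as.integer(seq_len(n_loci) >= boundary)
    same <- outer(dom, dom, `==`)
    lam <- base * ifelse(same, within_enrich, 1)
    diag(lam) <- 0
    lam
  }
  set.seed(as.integer(seed))
  draw <- function(lam) {
    n <- nrow(lam)
    up <- upper.tri(lam)
    cmat <- matrix(0, n, n)
    cmat[up] <- stats::rpois(sum(up), lam[up])
    cmat <- cmat + t(cmat)
    hic_contacts(loci, cmat, bin_size)
  }
  list(a = draw(lam_for(boundary_a)), b = draw(lam_for(boundary_b)),
       boundaries = c(a = boundary_a, b = boundary_b))
}

#' Contact-matrix pair with a flipped compartment block
#'
#' Two-compartment checkerboard model: loci are labelled A/B in alternating
#' blocks of `block_size` bins; same-compartment pairs are enriched by
#' `enrich` and cross-compartment pairs depleted by `1/enrich` over the
#' shared distance-decay baseline. In condition B the loci inside
#' `flip_block` (1-based inclusive index range) switch compartment
#' membership. Log-normal multiplicative noise is drawn independently for
#' the two conditions.
#'
#' @param n_loci number of bins; default 100.
#' @param flip_block integer range `c(from, to)` of flipped loci (interior,
#'   not the whole matrix); default `c(41, 50)`. Use `NULL` for a no-flip
#'   (null) pair.
#' @param enrich same-compartment enrichment; default 2.
#' @param block_size compartment block width in bins; default 10.
#' @param depth expected short-range contact count; default 100.
#' @param noise_sd log-normal noise SD; default 0.2.
#' @param seed integer seed.
#' @param bin_size,chrom locus annotation.
#' @return A list with [hic_contacts()] elements `a` and `b` and a `truth`
#'   data frame of per-locus compartment labels in each condition.
#' @export
make_compartment_pair <- function(n_loci = 100, flip_block = c(41, 50),
                                  enrich = 2, block_size = 10, depth = 100,
                                  noise_sd = 0.2, seed = 1,
                                  bin_size = 100000, chrom = "chrS") {
  loci <- new_locus_table(chrom, (seq_len(n_loci) - 1) * bin_size, bin_size)
  lab_a <- ifelse(((seq_len(n_loci) - 1) %/% block_size) %% 2 == 0, "A", "B")
  lab_b <- lab_a
  if (!is.null(flip_block)) {
    if (flip_block[1] < 1 || flip_block[2] > n_loci || flip_block[1] > flip_block[2])
      stop("flip block outside the matrix")
    if (flip_block[1] == 1 && flip_block[2] == n_loci)
      stop("flip block cannot cover the whole matrix")
    idx <- flip_block[1]:flip_block[2]
    lab_b[idx] <- ifelse(lab_a[idx] == "A", "B", "A")
  }
  base <- decay_baseline(n_loci, depth)
  lam_for <- function(lab) {
    same <- outer(lab, lab, `==`)
    lam <- base * ifelse(same, enrich, 1 / enrich)
    diag(lam) <- 0
    lam
  }
  set.seed(as.integer(seed))
  draw <- function(lam) {
    n <- nrow(lam)
    up <- upper.tri(lam)
    noise <- exp(stats::rnorm(sum(up), 0, noise_sd))
    cmat <- matrix(0, n, n)
    cmat[up] <- lam[up] * noise
    cmat <- cmat + t(cmat)
    hic_contacts(loci, cmat, bin_size)
  }
  list(a = draw(lam_for(lab_a)), b = draw(lam_for(lab_b)),
       truth = data.frame(locus = seq_len(n_loci), label_a = lab_a,
                          label_b = lab_b, stringsAsFactors = FALSE))
}

#' Contact-matrix pair with a single relocated locus
#'
#' Convenience wrapper for the planted-relocalization experiment: two copies
#' of a base chain, identical except that one locus is displaced in the
#' second condition, converted to contacts with log-normal noise.
#'
#' @param n_loci chain length; default 50.
#' @param locus 1-based index of the displaced locus; default
#'   `round(n_loci / 2)`.
#' @param shift displacement vector; default `c(2, 0, 0)`.
#' @param geometry base geometry passed to [fixture_spec()].
#' @param noise_sd contact noise SD; default 0.1.
#' @param seed integer seed.
#' @return A list with [hic_contacts()] elements `a` and `b`, the ground
#'   truth structures `sa` and `sb`, and `locus`.
#' @export
make_reloc_pair <- function(n_loci = 50, locus = round(n_loci / 2),
                            shift = c(2, 0, 0), geometry = "helix",
                            noise_sd = 0.1, seed = 1) {
  spec_a <- fixture_spec(n_loci, geometry, seed = seed)
  spec_b <- fixture_spec(n_loci, geometry, seed = seed,
                         planted = list(list(type = "displace", locus = locus,
                                             vector = shift)))
  sa <- make_structure(spec_a)
  sb <- make_structure(spec_b)
  list(a = structure_to_contacts(sa, noise_sd = noise_sd, seed = seed),
       b = structure_to_contacts(sb, noise_sd = noise_sd, seed = seed + 1),
       sa = sa, sb = sb, locus = locus)
}
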