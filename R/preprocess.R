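# Turning a pair of contact matrices into comparable target-distance
# matrices. Fixed pipeline order: intersect shared loci, mean-normalize each
# matrix, apply the distance-decay prior to each, convert to distances.
# Intersecting first keeps the stratified expected-contact estimate from
# being diluted by dead bins; normalizing before the prior makes the prior
# weight comparable across datasets.

#' Restrict a pair of contact matrices to jointly informative loci
#'
#' Loci with zero total counts in *both* datasets are excluded from both;
#' a locus that is nonzero in at least one dataset is retained in both, so
#' the two outputs share an identical locus list.
#'
#' @param a,b [hic_contacts()] objects for the same chromosome and bin size.
#' @return A list with elements `a` and `b`.
#' @export
intersect_loci <- function(a, b) {
  stopifnot(inherits(a, "hic_contacts"), inherits(b, "hic_contacts"))
  if (a$bin_size != b$bin_size) stop("mismatched resolution")
  if (a$loci$chrom[1] != b$loci$chrom[1]) stop("mismatched chromosome")
  starts <- intersect(a$loci$start, b$loci$start)
  ia <- match(starts, a$loci$start)
  ib <- match(starts, b$loci$start)
  keep <- rowSums(a$mat[ia, ia, drop = FALSE]) > 0 |
          rowSums(b$mat[ib, ib, drop = FALSE]) > 0
  if (!any(keep)) stop("no shared nonzero loci")
  ia <- ia[keep]; ib <- ib[keep]
  loci <- a$loci[ia, , drop = FALSE]
  rownames(loci) <- NULL
  list(a = hic_contacts(loci, a$mat[ia, ia, drop = FALSE], a$bin_size, a$normalized),
       b = hic_contacts(loci, b$mat[ib, ib, drop = FALSE], b$bin_size, b$normalized))
}

#' Mean-normalize a pair of contact matrices
#'
#' Divides each matrix by the mean of its stored nonzero entries, so the two
#' datasets are on approximately the same scale; within-matrix ratios are
#' preserved and the nonzero entries of each output have mean exactly 1.
#'
#' @param a,b [hic_contacts()] objects.
#' @return A list with elements `a` and `b`, flagged as normalized.
#' @export
mean_normalize_pair <- function(a, b) {
  norm1 <- function(m) {
    v <- m$mat[upper.tri(m$mat)]
    v <- v[v > 0]
    if (length(v) == 0) stop("no informative contacts")
    hic_contacts(m$loci, m$mat / mean(v), m$bin_size, normalized = TRUE)
  }
  list(a = norm1(a), b = norm1(b))
}

#' Shrink contacts toward the distance-decay expectation
#'
#' Replaces every within-span pair (including observed zeros) with the convex
#' combination `c_corrected = c_observed * (1 - k) + c_expected * k`, where
#' `c_expected(s)` is the mean observed contact frequency over all retained
#' pairs at linear separation `s` bins. This mild prior regularizes sparse
#' regions; without it embedded structures tend to look like random tangles.
#' Separations with no retained pairs contribute no prior. The matrix-wide
#' mean over within-span pairs is preserved exactly.
#'
#' @param m a [hic_contacts()] object.
#' @param k prior weight in \[0, 1\]; default 0.05.
#' @return A [hic_contacts()] object with corrected frequencies.
#' @export
distance_decay_prior <- function(m, k = 0.05) {
  stopifnot(inherits(m, "hic_contacts"))
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k > 1)
    stop("prior weight k must be in [0, 1]")
  n <- nrow(m$mat)
  if (n < 2 || k == 0) return(m)
  sep <- abs(row(m$mat) - col(m$mat))
  off <- sep > 0
  expected_by_s <- tapply(m$mat[off], sep[off], mean)
  cexp <- matrix(0, n, n)
  cexp[off] <- expected_by_s[as.character(sep[off])]
  corrected <- m$mat * (1 - k) + cexp * k
  diag(corrected) <- 0
  hic_contacts(m$loci, corrected, m$bin_size, m$normalized)
}

#' Convert contact frequencies to target distances
#'
#' Applies the inverse power law `delta_ij = c_ij ^ exponent` (default
#' exponent -1/4, so contacts fall off as the fourth power of distance).
#' Zero contact frequencies map to zero distances, which downstream MDS
#' treats as missing.
#'
#' @param m a [hic_contacts()] object.
#' @param exponent conversion exponent; default `-0.25`. A non-negative
#'   exponent triggers a warning (distances no longer decrease with contact
#'   frequency) but is applied.
#' @return A [hic_distances()] object.
#' @export
contacts_to_distances <- function(m, exponent = -0.25) {
  stopifnot(inherits(m, "hic_contacts"))
  if (exponent >= 0)
    warning("non-negative exponent: distances will not decrease with contact frequency")
  delta <- matrix(0, nrow(m$mat), ncol(m$mat))
  pos <- m$mat > 0
  delta[pos] <- m$mat[pos] ^ exponent
  diag(delta) <- 0
  hic_distances(m$loci, delta)
}

#' Run the full preprocessing pipeline on a contact-matrix pair
#'
#' Fixed order: [intersect_loci()], [mean_normalize_pair()],
#' [distance_decay_prior()] on each, [contacts_to_distances()] on each.
#' The two returned distance matrices share an identical locus list.
#'
#' @param a,b [hic_contacts()] objects.
#' @param prior_weight distance-decay prior weight `k`; default 0.05.
#' @param exponent contact-to-distance exponent; default -0.25.
#' @return A list with [hic_distances()] elements `d1` and `d2`.
#' @export
prepare_distance_pair <- function(a, b, prior_weight = 0.05, exponent = -0.25) {
  p <- intersect_loci(a, b)
  p <- mean_normalize_pair(p$a, p$b)
  list(d1 = contacts_to_distances(distance_decay_prior(p$a, prior_weight), exponent),
       d2 = contacts_to_distances(distance_decay_prior(p$b, prior_weight), exponent))
}
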