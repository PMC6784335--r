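#' @keywords internal
"_PACKAGE"

# Internal constructors for the package's core containers. All three share the
# same locus table layout: one row per bin, 0-based half-open coordinates
# ([start, end) with end = start + bin_size), so bin index = start / bin_size.

new_locus_table <- function(chrom, starts, bin_size) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  starts <- as.numeric(starts)
  if (any(starts < 0)) stop("locus starts must be non-negative")
  if (any(starts %% bin_size != 0))
    stop("locus starts must be multiples of the bin size")
  data.frame(chrom = rep(chrom, length(starts)), start = starts,
             end = starts + bin_size, stringsAsFactors = FALSE)
}

#' Construct a binned contact-matrix object
#'
#' `hic_contacts` holds normalized intrachromosomal contact frequencies for a
#' single chromosome at a single resolution, as a dense symmetric matrix over
#' a contiguous span of bins. A stored value of zero means "no observed
#' contact" and is treated as missing by the distance conversion.
#'
#' @param loci data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), one row per bin in order.
#' @param mat symmetric numeric matrix of non-negative contact frequencies,
#'   `nrow(loci)` square, zero diagonal.
#' @param bin_size bin width in bp.
#' @param normalized logical flag recording whether the matrix has been
#'   mean-normalized by [mean_normalize_pair()].
#' @return An object of class `hic_contacts`.
#' @export
hic_contacts <- function(loci, mat, bin_size, normalized = FALSE) {
  mat <- as.matrix(mat)
  n <- nrow(loci)
  if (!is.numeric(mat) || nrow(mat) != n || ncol(mat) != n)
    stop("contact matrix must be a square numeric matrix matching the loci")
  if (any(mat < 0)) {
    warning("negative contact frequencies clamped to zero")
    mat[mat < 0] <- 0
  }
  mat <- (mat + t(mat)) / 2  # enforce symmetry; inputs store i <= j only
  diag(mat) <- 0
  dimnames(mat) <- NULL
  structure(list(loci = loci, mat = mat, bin_size = as.numeric(bin_size),
                 normalized = isTRUE(normalized)),
            class = "hic_contacts")
}

#' @export
print.hic_contacts <- function(x, ...) {
  nz <- sum(x$mat[upper.tri(x$mat)] > 0)
  cat(sprintf("hic_contacts: %s, %d bins of %g bp [%g-%g), %d nonzero pairs%s\n",
              x$loci$chrom[1], nrow(x$loci), x$bin_size,
              min(x$loci$start), max(x$loci$end), nz,
              if (x$normalized) ", mean-normalized" else ""))
  invisible(x)
}

#' Construct a target-distance matrix
#'
#' Symmetric matrix of target distances derived from contact frequencies.
#' Zero off-diagonal entries mark missing pairs, which the MDS stress and
#' Guttman transform ignore.
#'
#' @param loci locus table (see [hic_contacts()]).
#' @param delta symmetric non-negative matrix with zero diagonal.
#' @return An object of class `hic_distances`.
#' @export
hic_distances <- function(loci, delta) {
  delta <- as.matrix(delta)
  n <- nrow(loci)
  if (nrow(delta) != n || ncol(delta) != n)
    stop("distance matrix must match the loci")
  if (any(delta < 0)) stop("target distances must be non-negative")
  if (max(abs(delta - t(delta))) > 1e-9) stop("distance matrix must be symmetric")
  diag(delta) <- 0
  dimnames(delta) <- NULL
  structure(list(loci = loci, delta = delta), class = "hic_distances")
}

#' @export
print.hic_distances <- function(x, ...) {
  miss <- sum(x$delta[upper.tri(x$delta)] == 0)
  cat(sprintf("hic_distances: %d loci, %d missing pairs\n", nrow(x$loci), miss))
  invisible(x)
}

#' Construct a 3D structure object
#'
#' Ordered loci with embedded coordinates in arbitrary embedding units.
#' Loci absent from the embedding carry `NA` coordinate rows.
#'
#' @param loci locus table (see [hic_contacts()]).
#' @param coords numeric matrix, one row per locus, `m` columns (3 by
#'   default); rows of `NA` mark absent loci.
#' @return An object of class `hic_structure`.
#' @export
hic_structure <- function(loci, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(loci))
    stop("coordinate rows must match the loci")
  mode(coords) <- "numeric"
  dimnames(coords) <- NULL
  structure(list(loci = loci, coords = coords), class = "hic_structure")
}

#' @export
print.hic_structure <- function(x, ...) {
  pres <- sum(stats::complete.cases(x$coords))
  cat(sprintf("hic_structure: %s, %d loci (%d with coordinates), %d dimensions\n",
              x$loci$chrom[1], nrow(x$loci), pres, ncol(x$coords)))
  invisible(x)
}

present_idx <- function(x) which(stats::complete.cases(x$coords))

same_loci <- function(a, b) {
  isTRUE(all.equal(a$loci$chrom, b$loci$chrom)) &&
    isTRUE(all.equal(a$loci$start, b$loci$start))
}
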