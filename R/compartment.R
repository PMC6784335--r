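# A/B compartment analysis: eigenvector compartment scores from the
# observed/expected correlation matrix, the 3D compartment axis fitted by
# linear support vector regression, and the decomposition of per-locus
# relocalization along that axis.

#' A/B compartment scores from a contact matrix
#'
#' Divides the contact matrix by the separation-stratified expected contact
#' (same estimator as the distance-decay prior), computes the Pearson
#' correlation matrix over locus rows, and takes the loadings of its leading
#' eigenvector (PC1) as compartment scores, scaled so that `max(|score|) = 1`.
#' Loci whose observed/expected row has zero variance are dropped from the
#' eigen-decomposition and carry `NA` scores. The eigenvector sign is fixed
#' so that the score vector sums non-negatively; use [orient_scores()] to
#' anchor the positive sign to the active compartment.
#'
#' @param m a [hic_contacts()] object with >= 3 retained loci.
#' @return An object of class `compartment_track`: list with `loci`, `score`
#'   (per-locus, in \[-1, 1\]) and `pc1_variance_fraction` (share of total
#'   correlation-matrix variance carried by PC1).
#' @export
compartment_scores <- function(m) {
  stopifnot(inherits(m, "hic_contacts"))
  n <- nrow(m$mat)
  if (n < 3) stop("compartment scores need at least 3 loci")
  sep <- abs(row(m$mat) - col(m$mat))
  off <- sep > 0
  expected_by_s <- tapply(m$mat[off], sep[off], mean)
  oe <- matrix(0, n, n)
  exp_mat <- matrix(0, n, n)
  exp_mat[off] <- expected_by_s[as.character(sep[off])]
  pos <- off & exp_mat > 0
  oe[pos] <- m$mat[pos] / exp_mat[pos]
  diag(oe) <- 1

  keep <- apply(oe, 1, stats::sd) > 0
  score <- rep(NA_real_, n)
  if (sum(keep) < 3 || all(stats::sd(oe[keep, keep]) == 0)) {
    warning("contact matrix is effectively constant; zero compartment track")
    return(structure(list(loci = m$loci, score = rep(0, n),
                          pc1_variance_fraction = 0),
                     class = "compartment_track"))
  }
  cm <- suppressWarnings(stats::cor(t(oe[keep, keep, drop = FALSE])))
  if (any(!is.finite(cm))) cm[!is.finite(cm)] <- 0
  eg <- eigen(cm, symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  lam <- pmax(eg$values, 0)
  s <- v1 / max(abs(v1))
  score[keep] <- s
  if (sum(!keep) > 0)
    message(sum(!keep), " zero-variance loci dropped from compartment scoring")
  structure(list(loci = m$loci, score = score,
                 pc1_variance_fraction = lam[1] / sum(lam)),
            class = "compartment_track")
}

#' @export
print.compartment_track <- function(x, ...) {
  cat(sprintf("compartment_track: %d loci, PC1 variance fraction %.3f, %d A / %d B\n",
              length(x$score), x$pc1_variance_fraction,
              sum(x$score > 0, na.rm = TRUE), sum(x$score < 0, na.rm = TRUE)))
  invisible(x)
}

#' Orient compartment scores so the active compartment is positive
#'
#' The eigenvector sign is arbitrary; given a per-locus logical mask of
#' "active" loci (e.g. from gene density or an epigenomic annotation), flips
#' the track sign if the negative compartment is the more active one. Ties
#' (or an empty mask) leave the track unchanged with a warning. Applying the
#' same mask twice is a no-op.
#'
#' @param track a `compartment_track`.
#' @param active_mask logical vector over the track's loci.
#' @return The (possibly sign-flipped) track.
#' @export
orient_scores <- function(track, active_mask) {
  stopifnot(inherits(track, "compartment_track"))
  if (length(active_mask) != length(track$score))
    stop("active mask must cover the track's loci")
  if (!any(active_mask, na.rm = TRUE)) {
    warning("empty active mask; track left unchanged")
    return(track)
  }
  pos <- track$score > 0
  neg <- track$score < 0
  act_pos <- if (any(pos, na.rm = TRUE))
    mean(active_mask[which(pos)], na.rm = TRUE) else 0
  act_neg <- if (any(neg, na.rm = TRUE))
    mean(active_mask[which(neg)], na.rm = TRUE) else 0
  if (act_neg > act_pos) {
    track$score <- -track$score
  } else if (act_neg == act_pos) {
    warning("active fractions tie; track left unchanged")
  }
  track
}

#' Fit the 3D compartment axis of a structure
#'
#' Finds the single direction in the embedding that best predicts the
#' compartment scores, by linear epsilon-insensitive support vector
#' regression of score on the 3D coordinates (cost 1, epsilon 0, no feature
#' scaling), or ordinary least squares with `method = "ols"`. Reports the
#' unit direction, the coefficient of determination of the fit's
#' predictions, and the axis length (mean absolute projection of the
#' centered coordinates onto the direction).
#'
#' @param x a [hic_structure()].
#' @param track a `compartment_track` over the same loci.
#' @param method `"svr"` (default) or `"ols"`.
#' @return An object of class `axis_fit`: list with `direction` (unit
#'   3-vector), `r2`, and `axis_length`.
#' @export
fit_compartment_axis <- function(x, track, method = c("svr", "ols")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "hic_structure"), inherits(track, "compartment_track"))
  ok <- stats::complete.cases(x$coords) & !is.na(track$score)
  if (sum(ok) < 4) stop("need at least 4 loci with coordinates and scores")
  co <- x$coords[ok, , drop = FALSE]
  sc <- track$score[ok]
  if (stats::sd(sc) == 0) stop("no compartment axis: scores are constant")
  if (method == "svr") {
    fit <- e1071::svm(x = co, y = sc, type = "eps-regression",
                      kernel = "linear", cost = 1, epsilon = 0, scale = FALSE)
    beta <- as.numeric(crossprod(fit$coefs, fit$SV))
    pred <- as.numeric(stats::predict(fit, co))
  } else {
    fit <- stats::lm(sc ~ co)
    beta <- as.numeric(stats::coef(fit)[-1])
    beta[is.na(beta)] <- 0  # rank-deficient coordinate columns carry no axis
    pred <- as.numeric(stats::fitted(fit))
  }
  nb <- sqrt(sum(beta^2))
  if (nb < 1e-12) stop("no compartment axis: fitted direction is zero")
  direction <- beta / nb
  r2 <- 1 - sum((sc - pred)^2) / sum((sc - mean(sc))^2)
  proj <- as.numeric(sweep(co, 2, colMeans(co)) %*% direction)
  structure(list(direction = direction, r2 = r2,
                 axis_length = mean(abs(proj))),
            class = "axis_fit")
}

#' @export
print.axis_fit <- function(x, ...) {
  cat(sprintf("axis_fit: direction (%.3f, %.3f, %.3f), R^2 %.3f, length %.4g\n",
              x$direction[1], x$direction[2], x$direction[3],
              x$r2, x$axis_length))
  invisible(x)
}

axis_length_along <- function(coords, direction) {
  proj <- as.numeric(sweep(coords, 2, colMeans(coords)) %*% direction)
  mean(abs(proj))
}

#' Decompose relocalization along the compartment axis
#'
#' Builds a common compartment axis as the normalized mean of the two
#' per-structure axis directions (sign-aligning the second onto the first),
#' completes it to an orthonormal triad, and for every locus with nonzero
#' displacement computes the fraction of its relocalization along each axis,
#' `|displacement . axis| / |displacement|`. To prevent bias from some axes
#' being physically longer, each fraction is divided by the axis length
#' measured on the pooled coordinates of both structures. A two-sided
#' equal-variance t test compares the normalized compartment-axis fractions
#' against the pooled orthogonal-axis fractions across loci.
#'
#' @param fit a `joint_mds_fit` (or any aligned pair with `x1`, `x2`).
#' @param axis1,axis2 `axis_fit` objects for the two structures.
#' @return An object of class `axis_decomposition`: per-locus component
#'   matrix (`components`, columns compartment/ortho1/ortho2), `fraction`
#'   and `norm_fraction` matrices, axis matrix `axes` (columns are the unit
#'   axes), `axis_length` per axis, `t_statistic` and `p_value`.
#' @export
decompose_relocalization <- function(fit, axis1, axis2) {
  stopifnot(inherits(axis1, "axis_fit"), inherits(axis2, "axis_fit"))
  a1 <- axis1$direction
  a2 <- axis2$direction
  if (sum(a1 * a2) < 0) a2 <- -a2
  ang <- acos(pmin(1, pmax(-1, sum(a1 * a2)))) * 180 / pi
  if (ang > 60)
    warning(sprintf("compartment axis unstable: per-structure axes differ by %.1f degrees", ang))
  comp <- a1 + a2
  comp <- comp / sqrt(sum(comp^2))
  # complete to an orthonormal triad by Gram-Schmidt against the least
  # parallel coordinate axes (deterministic)
  basis <- diag(3)[, order(abs(comp))[1:2], drop = FALSE]
  o1 <- basis[, 1] - sum(basis[, 1] * comp) * comp
  o1 <- o1 / sqrt(sum(o1^2))
  o2 <- basis[, 2] - sum(basis[, 2] * comp) * comp - sum(basis[, 2] * o1) * o1
  o2 <- o2 / sqrt(sum(o2^2))
  axes <- cbind(compartment = comp, ortho1 = o1, ortho2 = o2)

  prof <- relocalization_profile(fit)
  disp <- prof$displacement
  mag <- prof$magnitude
  comp_mat <- disp %*% axes                     # signed components
  pooled <- rbind(fit$x1$coords, fit$x2$coords)
  pooled <- pooled[stats::complete.cases(pooled), , drop = FALSE]
  len <- apply(axes, 2, function(a) axis_length_along(pooled, a))

  nz <- which(mag > 0)
  frac <- abs(comp_mat[nz, , drop = FALSE]) / mag[nz]
  norm_frac <- sweep(frac, 2, len, `/`)
  tt <- tryCatch(
    stats::t.test(norm_frac[, 1], c(norm_frac[, 2], norm_frac[, 3]),
                  var.equal = TRUE),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  structure(list(loci = prof$loci, components = comp_mat, magnitude = mag,
                 fraction = frac, norm_fraction = norm_frac,
                 axes = axes, axis_length = len,
                 t_statistic = unname(tt$statistic), p_value = tt$p.value),
            class = "axis_decomposition")
}

#' @export
print.axis_decomposition <- function(x, ...) {
  cat(sprintf(
    "axis_decomposition: %d loci; mean normalized fraction %.4g (compartment) vs %.4g (orthogonal); t = %.3f, p = %.3g\n",
    nrow(x$norm_fraction), mean(x$norm_fraction[, 1]),
    mean(x$norm_fraction[, 2:3]), x$t_statistic, x$p_value))
  invisible(x)
}

#' Per-locus absolute compartment-score difference
#'
#' `|score_a - score_b|` over shared loci; used to filter relocalization
#' peaks down to those not explained by a compartment switch. Warns when the
#' two tracks look oppositely oriented (correlation below -0.3), which
#' usually means [orient_scores()] should be applied first.
#'
#' @param track_a,track_b `compartment_track` objects over the same loci.
#' @return Numeric vector of per-locus absolute differences.
#' @export
compartment_difference <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "compartment_track"),
            inherits(track_b, "compartment_track"))
  if (length(track_a$score) != length(track_b$score))
    stop("tracks must share loci")
  cc <- suppressWarnings(stats::cor(track_a$score, track_b$score,
                                    use = "complete.obs"))
  if (!is.na(cc) && cc < -0.3)
    warning("tracks appear oppositely oriented; consider orient_scores()")
  abs(track_a$score - track_b$score)
}
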