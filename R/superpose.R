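# Rigid-body superposition: the independent-inference baseline aligns two
# separately embedded structures with the closed-form Kabsch rotation. Pure
# rigid motion only — no scaling (the inputs are already on a common scale
# after mean normalization) and no reflection (so chirality mismatches stay
# visible as RMSD).

#' Optimal rigid superposition of two structures (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `moving` and `target` over their shared present loci, and applies it to
#' `moving`. Reflections are disallowed: the rotation determinant is forced
#' to +1 by flipping the sign of the smallest singular vector when needed.
#'
#' @param moving,target [hic_structure()] objects over the same locus set
#'   with >= 3 non-collinear present points.
#' @return A list with `rotation` (3x3 proper orthonormal matrix),
#'   `translation` (length-3 vector; the map is `x %*% rotation +
#'   translation`), `aligned` (the transformed `moving` structure) and
#'   `rmsd` (after superposition).
#' @export
kabsch <- function(moving, target) {
  stopifnot(inherits(moving, "hic_structure"), inherits(target, "hic_structure"))
  pm <- present_idx(moving)
  pt <- present_idx(target)
  if (!identical(pm, pt)) stop("structures must share the same present loci")
  a <- moving$coords[pm, , drop = FALSE]
  b <- target$coords[pt, , drop = FALSE]
  if (nrow(a) < 3) stop("Kabsch superposition needs at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  # collinearity check: rank of the centered point cloud
  sv_a <- svd(a0)$d
  if (sv_a[2] < 1e-12 * max(sv_a[1], 1))
    stop("degenerate input: points are collinear (or coincident)")
  h <- crossprod(a0, b0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  s <- diag(c(1, 1, d))
  rot <- sv$u %*% s %*% t(sv$v)   # x %*% rot rotates moving into target frame
  trans <- cb - ca %*% rot
  new_coords <- moving$coords
  new_coords[pm, ] <- sweep(a %*% rot, 2, as.numeric(trans), `+`)
  aligned <- hic_structure(moving$loci, new_coords)
  list(rotation = rot, translation = as.numeric(trans),
       aligned = aligned, rmsd = rmsd(aligned, target))
}

#' Root-mean-square distance between paired structures
#'
#' `sqrt(mean(|x_i - y_i|^2))` over the shared present loci.
#'
#' @param a,b [hic_structure()] objects with identical present-locus sets.
#' @return Non-negative scalar.
#' @export
rmsd <- function(a, b) {
  pa <- present_idx(a); pb <- present_idx(b)
  if (!identical(pa, pb)) stop("structures must share the same present loci")
  sqrt(mean(rowSums((a$coords[pa, , drop = FALSE] -
                     b$coords[pb, , drop = FALSE])^2)))
}

#' Independent-inference baseline: separate embeddings + Kabsch alignment
#'
#' Embeds each distance matrix independently (zero-weight SMACOF with its
#' own random initialization per matrix), then superposes structure 2 onto
#' structure 1 with [kabsch()]. This is the conventional infer-then-align
#' approach the joint method is compared against; because the two inferences
#' share nothing, its run-to-run alignment is stochastic.
#'
#' @param d1,d2 [hic_distances()] objects over identical loci.
#' @param seed integer seed; the two embeddings draw different
#'   initializations derived from it.
#' @param ... further arguments passed to [joint_mds()].
#' @return A `joint_mds_fit` whose `weight` is 0 and whose `method` element
#'   is `"independent"`; `x2` is Kabsch-aligned onto `x1`.
#' @export
independent_compare <- function(d1, d2, seed = 1, ...) {
  f1 <- joint_mds(d1, d1, weight = 0, seed = seed, ...)
  f2 <- joint_mds(d2, d2, weight = 0, seed = seed + 484081L, ...)
  al <- kabsch(f2$x1, f1$x1)
  structure(list(
    x1 = f1$x1, x2 = al$aligned, weight = 0,
    final_stress = (f1$final_stress + f2$final_stress) / 2,
    n_iter = max(f1$n_iter, f2$n_iter),
    converged = f1$converged && f2$converged,
    seed = seed, stress_trace = f1$stress_trace,
    d1 = d1, d2 = d2, method = "independent"
  ), class = "joint_mds_fit")
}
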