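# Reading sparse Hi-C text dumps and writing structure / relocalization
# tables. Coordinates are 0-based half-open throughout; a bin covers
# [start, start + bin_size), so bin index = start / bin_size exactly.

#' Read a sparse Hi-C contact matrix from a text file
#'
#' Two whitespace/tab-separated dialects are supported:
#' \describe{
#'   \item{`"pairs"`}{`chrom1 start1 chrom2 start2 count`; optional end
#'     columns (`chrom1 start1 end1 chrom2 start2 end2 count`) are tolerated
#'     and ignored.}
#'   \item{`"bins"`}{`bin_i bin_j count` with the bin width given by
#'     `resolution`.}
#' }
#' Gzip-compressed files (by `.gz` extension) are accepted transparently.
#' The matrix spans the observed min..max bin unless `region` is given
#' (`"chrom:start-end"`, 0-based half-open), which fixes the span explicitly —
#' needed e.g. to analyse the two arms of a chromosome separately. Duplicate
#' records for the same pair are summed with a warning; negative normalized
#' values are clamped to zero with a warning.
#'
#' @param path file path.
#' @param resolution bin size in bp.
#' @param dialect `"pairs"`, `"bins"`, or `"auto"` (detect from column count).
#' @param chrom chromosome name to assign in the `"bins"` dialect (default
#'   `"chr"`).
#' @param region optional `"chrom:start-end"` string fixing the matrix span.
#' @return A [hic_contacts()] object.
#' @export
read_contacts <- function(path, resolution, dialect = c("auto", "pairs", "bins"),
                          chrom = "chr", region = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("contact file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    loci <- new_locus_table(chrom, numeric(0), resolution)
    return(hic_contacts(loci, matrix(0, 0, 0), resolution))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (dialect == "auto") {
    dialect <- if (all(ncols == 3)) "bins" else "pairs"
  }

  parse_num <- function(v, what, lineno) {
    x <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(x))
    if (length(bad))
      stop(sprintf("parse error at line %d: bad %s '%s'",
                   lineno[bad[1]], what, v[bad[1]]))
    x
  }
  lineno <- seq_along(fields)

  if (dialect == "bins") {
    if (any(ncols != 3))
      stop(sprintf("parse error at line %d: expected 3 columns, found %d",
                   lineno[ncols != 3][1], ncols[ncols != 3][1]))
    m <- do.call(rbind, fields)
    i <- parse_num(m[, 1], "bin index", lineno)
    j <- parse_num(m[, 2], "bin index", lineno)
    cnt <- parse_num(m[, 3], "count", lineno)
    if (any(i != round(i) | j != round(j)))
      stop("parse error: bin indices must be integers")
    s1 <- i * resolution
    s2 <- j * resolution
    c1 <- c2 <- rep(chrom, length(i))
  } else {
    ok5 <- ncols == 5
    ok7 <- ncols == 7
    if (!all(ok5 | ok7))
      stop(sprintf("parse error at line %d: expected 5 or 7 columns, found %d",
                   lineno[!(ok5 | ok7)][1], ncols[!(ok5 | ok7)][1]))
    pick <- function(f, n) if (length(f) == 5) f[n] else f[c(1, 2, 4, 5, 7)][n]
    c1 <- vapply(fields, pick, "", n = 1L)
    s1 <- parse_num(vapply(fields, pick, "", n = 2L), "start", lineno)
    c2 <- vapply(fields, pick, "", n = 3L)
    s2 <- parse_num(vapply(fields, pick, "", n = 4L), "start", lineno)
    cnt <- parse_num(vapply(fields, pick, "", n = 5L), "count", lineno)
  }

  if (length(unique(c(c1, c2))) > 1)
    stop("mixed chromosomes in intrachromosomal mode: ",
         paste(unique(c(c1, c2)), collapse = ", "))
  chrom <- c1[1]
  bad <- which(s1 %% resolution != 0 | s2 %% resolution != 0)
  if (length(bad))
    stop(sprintf("parse error at line %d: start %g is not a multiple of the resolution %g",
                 lineno[bad[1]], c(s1[bad[1]], s2[bad[1]])[
                   which(c(s1[bad[1]], s2[bad[1]]) %% resolution != 0)[1]],
                 resolution))
  if (any(cnt < 0)) {
    warning("negative contact values clamped to zero")
    cnt[cnt < 0] <- 0
  }

  b1 <- s1 / resolution
  b2 <- s2 / resolution
  if (!is.null(region)) {
    reg <- parse_region(region)
    if (!identical(reg$chrom, chrom))
      stop("region chromosome does not match the data")
    lo <- floor(reg$start / resolution)
    hi <- ceiling(reg$end / resolution) - 1
    keep <- b1 >= lo & b1 <= hi & b2 >= lo & b2 <= hi
    b1 <- b1[keep]; b2 <- b2[keep]; cnt <- cnt[keep]
  } else {
    lo <- min(b1, b2)
    hi <- max(b1, b2)
  }
  n <- hi - lo + 1
  loci <- new_locus_table(chrom, (lo:hi) * resolution, resolution)
  mat <- matrix(0, n, n)
  ii <- pmin(b1, b2) - lo + 1
  jj <- pmax(b1, b2) - lo + 1
  key <- paste(ii, jj)
  if (anyDuplicated(key))
    warning("duplicate (i,j) records summed")
  agg <- rowsum(cnt, key)
  kk <- strsplit(rownames(agg), " ")
  ai <- as.integer(vapply(kk, `[`, "", 1L))
  aj <- as.integer(vapply(kk, `[`, "", 2L))
  mat[cbind(ai, aj)] <- agg[, 1]
  mat[cbind(aj, ai)] <- agg[, 1]
  diag(mat) <- 0
  hic_contacts(loci, mat, resolution)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("region must be 'chrom:start-end'")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Write a 3D structure to a TSV file
#'
#' Emits a header row and one line per locus: chrom, start, end, x, y, z.
#' Absent loci get empty coordinate fields. The file round-trips losslessly
#' through [read_structure()].
#'
#' @param structure a [hic_structure()] object with at least one present locus.
#' @param path output path.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "hic_structure"))
  if (length(present_idx(structure)) == 0)
    stop("structure has no present loci")
  co <- format(structure$coords, digits = 17, trim = TRUE, scientific = TRUE)
  co[is.na(structure$coords)] <- ""
  df <- data.frame(structure$loci, co, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", c("x", "y", "z")[seq_len(ncol(structure$coords))])
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a structure TSV written by [write_structure()]
#'
#' @param path file path.
#' @return A [hic_structure()] object.
#' @export
read_structure <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character")
  coord_cols <- setdiff(names(df), c("chrom", "start", "end"))
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  coords <- vapply(df[coord_cols], as.numeric, numeric(nrow(df)))
  coords <- matrix(coords, nrow = nrow(df))
  loci <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                     stringsAsFactors = FALSE)
  hic_structure(loci, coords)
}

#' Write a relocalization profile as a BED-like TSV
#'
#' Columns: chrom, start, end, magnitude, with per-axis displacement columns
#' appended when present in the profile.
#'
#' @param profile a `reloc_profile` object from [relocalization_profile()].
#' @param path output path.
#' @export
write_relocalization <- function(profile, path) {
  stopifnot(inherits(profile, "reloc_profile"))
  df <- data.frame(profile$loci, magnitude = profile$magnitude,
                   profile$displacement, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "magnitude", "dx", "dy", "dz")
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
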