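# Radius-based spatial neighborhood enrichment with a label-permutation null.
#
# The observed statistic for a (center type A, neighbor type B) pair is the
# mean, over cells of type A that have at least one neighbor within the
# radius, of the fraction of those neighbors that are of type B. The null is
# built by permuting the cell-type label vector over the fixed positions and
# recomputing the matrix; Z = (observed - null mean) / null sd elementwise.

# Validate and normalize a spatial cell table. Accepts x/y or x_um/y_um
# coordinate columns; returns a data.frame with barcode, x_um, y_um,
# cell_type (factor).
.validate_cells <- function(cells, types = NULL) {
  if (!is.data.frame(cells)) stop("'cells' must be a data.frame", call. = FALSE)
  nm <- names(cells)
  xcol <- if ("x_um" %in% nm) "x_um" else if ("x" %in% nm) "x" else
    stop("cell table needs an 'x_um' (or 'x') column", call. = FALSE)
  ycol <- if ("y_um" %in% nm) "y_um" else if ("y" %in% nm) "y" else
    stop("cell table needs a 'y_um' (or 'y') column", call. = FALSE)
  if (!"cell_type" %in% nm) {
    stop("cell table needs a 'cell_type' column", call. = FALSE)
  }
  if (!"barcode" %in% nm) {
    stop("cell table needs a 'barcode' column", call. = FALSE)
  }
  if (anyDuplicated(cells$barcode)) {
    stop("cell barcodes must be unique", call. = FALSE)
  }
  x <- as.numeric(cells[[xcol]])
  y <- as.numeric(cells[[ycol]])
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("cell coordinates must be finite", call. = FALSE)
  }
  lab <- as.character(cells$cell_type)
  if (is.null(types)) types <- sort(unique(lab))
  if (!all(lab %in% types)) {
    stop("unknown cell type label(s): ",
         paste(setdiff(unique(lab), types), collapse = ", "), call. = FALSE)
  }
  data.frame(barcode = as.character(cells$barcode), x_um = x, y_um = y,
             cell_type = factor(lab, levels = types),
             stringsAsFactors = FALSE)
}

# Sparse symmetric adjacency over cells: entry (i, j) = 1 iff
# 0 < d(i, j) <= radius (center excluded from its own neighborhood; boundary
# inclusive). Exact neighbor sets; distances computed blockwise to bound
# memory at n x block.
.neighbor_adjacency <- function(x, y, radius, block = 1024L) {
  n <- length(x)
  r2 <- radius^2
  ii <- vector("list", ceiling(n / block))
  jj <- vector("list", ceiling(n / block))
  b <- 0L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    hit <- which(d2 > 0 & d2 <= r2, arr.ind = TRUE)  # 0 < d <= radius
    b <- b + 1L
    ii[[b]] <- hit[, 1L] + start - 1L
    jj[[b]] <- hit[, 2L]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1, dims = c(n, n))
}

# Per-center-type mean neighbor proportions given an adjacency and an integer
# label vector. Returns k x k matrix (rows: center type, cols: neighbor
# type); rows for types with no eligible centers are zero-filled so that the
# permutation Z remains finite.
.mean_neighbor_proportions <- function(adj, lab_int, k) {
  n <- length(lab_int)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), lab_int)] <- 1
  counts <- as.matrix(adj %*% ind)
  ncount <- rowSums(counts)
  eligible <- ncount > 0
  O <- matrix(0, k, k)
  if (any(eligible)) {
    prop <- counts[eligible, , drop = FALSE] / ncount[eligible]
    grp <- lab_int[eligible]
    sums <- rowsum(prop, group = grp)
    present <- as.integer(rownames(sums))
    O[present, ] <- sums / as.vector(table(factor(grp, levels = 1:k)))[present]
  }
  list(O = O, eligible = eligible)
}

#' Mean neighbor-type proportions within a radius
#'
#' For every cell with at least one neighbor at Euclidean distance
#' `0 < d <= radius`, computes the fraction of its neighbors belonging to each
#' cell type, then averages those fractions over the centers of each type.
#' Cells with no neighbors are excluded from the average (their neighbor
#' proportion is undefined), so each row over types with eligible centers sums
#' to 1.
#'
#' @param cells data.frame with columns `barcode`, `x_um`/`x`, `y_um`/`y`,
#'   `cell_type` (coordinates in micrometers).
#' @param radius neighborhood radius in micrometers (default 200).
#' @param types optional character vector fixing the type order (defaults to
#'   the sorted unique labels).
#' @return numeric matrix `O` with `O[A, B]` the mean proportion of type-B
#'   neighbors around type-A centers; attribute `n_eligible_centers` carries
#'   the per-type count of cells with at least one neighbor.
#' @export
neighbor_proportions <- function(cells, radius = 200, types = NULL) {
  tab <- .validate_cells(cells, types)
  if (nrow(tab) < 2) stop("need at least 2 cells", call. = FALSE)
  .assert_scalar_number(radius, "radius")
  if (radius <= 0) stop("'radius' must be positive", call. = FALSE)

  adj <- .neighbor_adjacency(tab$x_um, tab$y_um, radius)
  lab <- as.integer(tab$cell_type)
  k <- nlevels(tab$cell_type)
  res <- .mean_neighbor_proportions(adj, lab, k)
  if (!any(res$eligible)) {
    stop("no cell has a neighbor within radius ", radius,
         " um; all cells are isolated", call. = FALSE)
  }
  O <- res$O
  dimnames(O) <- list(levels(tab$cell_type), levels(tab$cell_type))
  attr(O, "n_eligible_centers") <-
    table(tab$cell_type[res$eligible])
  O
}

#' Spatial neighborhood enrichment Z scores by label permutation
#'
#' Compares the observed neighbor-proportion matrix (see
#' [neighbor_proportions()]) against a null built by permuting the cell-type
#' label vector over the fixed cell positions. Each permutation is a full
#' relabeling without replacement of the single global label vector. The Z
#' score for a (center type, neighbor type) pair is
#' `(observed - null mean) / null sd`, with the population (n) denominator for
#' the null sd; pairs whose null sd is 0 get Z = 0 (the observed value equals
#' a degenerate null, i.e. no evidence of enrichment either way). Z is
#' returned uncapped; clamp for display with [cap_z()].
#'
#' @inheritParams neighbor_proportions
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed; identical seed and input give identical results.
#' @return object of class `niche_enrichment`: list with `types`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `n_permutations`, `radius`, `seed`,
#'   `n_eligible_centers`, and `sd_denominator` (`"population"`).
#' @examples
#' cells <- data.frame(
#'   barcode = paste0("c", 1:6),
#'   x_um = c(0, 10, 20, 500, 510, 520), y_um = 0,
#'   cell_type = rep(c("A", "B"), each = 3)
#' )
#' res <- niche_enrichment(cells, radius = 50, n_permutations = 200, seed = 1)
#' res$z
#' @export
niche_enrichment <- function(cells, radius = 200, n_permutations = 1000,
                             seed = 1, types = NULL) {
  tab <- .validate_cells(cells, types)
  if (nrow(tab) < 2) stop("need at least 2 cells", call. = FALSE)
  .assert_scalar_number(radius, "radius")
  if (radius <= 0) stop("'radius' must be positive", call. = FALSE)
  n_permutations <- .assert_count(n_permutations, "n_permutations")
  seed <- .assert_count(abs(seed), "seed", positive = FALSE)

  adj <- .neighbor_adjacency(tab$x_um, tab$y_um, radius)
  lab <- as.integer(tab$cell_type)
  k <- nlevels(tab$cell_type)
  lev <- levels(tab$cell_type)

  obs <- .mean_neighbor_proportions(adj, lab, k)
  if (!any(obs$eligible)) {
    stop("no cell has a neighbor within radius ", radius,
         " um; all cells are isolated", call. = FALSE)
  }

  acc <- matrix(0, k, k)
  acc2 <- matrix(0, k, k)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (p in seq_len(n_permutations)) {
    perm <- sample(lab)
    P <- .mean_neighbor_proportions(adj, perm, k)$O
    acc <- acc + P
    acc2 <- acc2 + P^2
  }
  null_mean <- acc / n_permutations
  null_sd <- sqrt(pmax(acc2 / n_permutations - null_mean^2, 0))

  z <- (obs$O - null_mean) / null_sd
  z[null_sd == 0] <- 0

  dn <- list(lev, lev)
  dimnames(z) <- dimnames(null_mean) <- dimnames(null_sd) <- dn
  O <- obs$O
  dimnames(O) <- dn

  structure(
    list(
      types = lev,
      observed = O,
      null_mean = null_mean,
      null_sd = null_sd,
      z = z,
      n_permutations = n_permutations,
      radius = radius,
      seed = seed,
      n_eligible_centers = table(tab$cell_type[obs$eligible]),
      sd_denominator = "population"
    ),
    class = "niche_enrichment"
  )
}

#' @export
print.niche_enrichment <- function(x, ...) {
  cat("Neighborhood enrichment:", length(x$types), "cell types, radius",
      x$radius, "um,", x$n_permutations, "permutations (seed", x$seed, ")\n")
  cat("Z scores (uncapped):\n")
  print(round(x$z, 2))
  invisible(x)
}

#' Clamp a Z-score matrix for display
#'
#' Elementwise clamp to `[-bound, bound]`. Enrichment Z scores from a
#' permutation null can be very large when the observed configuration is far
#' outside the null's range; capping (conventionally at 9) keeps heatmap color
#' scales readable. Idempotent; analysis should use the uncapped values.
#'
#' @param z numeric matrix (or vector) of Z scores.
#' @param bound positive clamp bound (default 9).
#' @return `z` with every element clamped to `[-bound, bound]`.
#' @export
cap_z <- function(z, bound = 9) {
  .assert_scalar_number(bound, "bound")
  if (bound <= 0) stop("'bound' must be positive", call. = FALSE)
  pmin(pmax(z, -bound), bound)
}
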