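# Per-cell usage of predefined gene-expression programs by nonnegative least
# squares, and gene-set signature scoring against expression-matched control
# genes.

#' Depth-normalize and log-transform a count matrix
#'
#' Scales each cell to `scale_factor` total counts, then applies
#' `log(1 + x)`. This is the conventional preprocessing for per-cell
#' regression and module scoring; it makes the result invariant to a cell's
#' sequencing depth. Cells with zero total counts cannot be scaled and are
#' dropped with a warning naming them.
#'
#' @param counts gene x cell matrix of nonnegative counts (dense or
#'   [Matrix::Matrix()] sparse), with gene rownames and cell colnames.
#' @param scale_factor target total per cell (default 1e4).
#' @param log apply the `log(1 + x)` transform after depth scaling
#'   (default TRUE). Signature scoring expects the log scale; nonnegative
#'   program decomposition operates on the linear depth-scaled values,
#'   where expression is an additive mixture of program spectra.
#' @return normalized matrix of the same class, possibly with zero-total
#'   cells removed; attribute `dropped_cells` lists them.
#' @export
normalize_expression <- function(counts, scale_factor = 1e4, log = TRUE) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must carry gene rownames and cell colnames", call. = FALSE)
  }
  if (min(counts) < 0) stop("counts must be nonnegative", call. = FALSE)
  tot <- Matrix::colSums(counts)
  dropped <- colnames(counts)[tot == 0]
  if (length(dropped) == ncol(counts)) {
    stop("every cell has zero total counts: ",
         paste(utils::head(dropped, 10), collapse = ", "),
         if (length(dropped) > 10) ", ...", call. = FALSE)
  }
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " zero-count cell(s): ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
    counts <- counts[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / tot)
  colnames(norm) <- colnames(counts)
  if (log) norm <- log1p(norm)
  attr(norm, "dropped_cells") <- dropped
  norm
}

#' Score per-cell usage of predefined gene-expression programs
#'
#' For each cell solves the nonnegative least-squares problem
#' \deqn{\min_{u \ge 0} \| e - W u \|^2}
#' where `e` is the cell's normalized expression over the genes shared with
#' the program matrix and `W` holds the program spectra over those genes.
#' The solver is the Lawson–Hanson active-set method
#' ([pracma::lsqnonneg()]), which returns the exact KKT-satisfying solution.
#' Usages are comparable across cells on a common normalization; they
#' quantify how strongly each predefined transcriptional program is used by
#' each cell.
#'
#' @param normalized gene x cell normalized matrix (see
#'   [normalize_expression()]).
#' @param programs gene x program matrix of nonnegative spectra weights, with
#'   gene rownames and program colnames (a data.frame is coerced).
#' @param cell_types optional character/factor vector of population labels,
#'   one per cell (or named by cell), for per-population mean usage.
#' @return object of class `program_usage`: list with `usage` (cell x
#'   program matrix), `residual_norm` (per cell), `genes_used` (size of the
#'   gene intersection), and `population_mean` (population x program matrix,
#'   or NULL).
#' @export
score_program_usage <- function(normalized, programs, cell_types = NULL) {
  if (is.data.frame(programs)) programs <- as.matrix(programs)
  if (is.null(rownames(programs)) || is.null(colnames(programs))) {
    stop("'programs' must carry gene rownames and program colnames",
         call. = FALSE)
  }
  if (min(programs) < 0) {
    stop("program weights must be nonnegative", call. = FALSE)
  }
  if (anyDuplicated(colnames(programs)) || anyDuplicated(rownames(programs))) {
    stop("duplicate gene or program names in program matrix", call. = FALSE)
  }
  shared <- intersect(rownames(normalized), rownames(programs))
  if (length(shared) == 0) {
    stop("no genes shared between expression matrix and program matrix",
         call. = FALSE)
  }
  W <- programs[shared, , drop = FALSE]
  zero_prog <- colSums(W) == 0
  if (any(zero_prog)) {
    warning("program(s) with all-zero weights over shared genes get usage 0: ",
            paste(colnames(W)[zero_prog], collapse = ", "), call. = FALSE)
  }
  Wa <- W[, !zero_prog, drop = FALSE]
  E <- as.matrix(normalized[shared, , drop = FALSE])

  n_cells <- ncol(E)
  usage <- matrix(0, n_cells, ncol(W),
                  dimnames = list(colnames(E), colnames(W)))
  resid <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    e <- E[, i]
    if (ncol(Wa) > 0) {
      fit <- pracma::lsqnonneg(Wa, e)
      usage[i, !zero_prog] <- fit$x
      resid[i] <- sqrt(sum((e - Wa %*% fit$x)^2))
    } else {
      resid[i] <- sqrt(sum(e^2))
    }
  }
  names(resid) <- colnames(E)

  pop_mean <- NULL
  if (!is.null(cell_types)) {
    lab <- if (!is.null(names(cell_types))) {
      as.character(cell_types[colnames(E)])
    } else {
      if (length(cell_types) != n_cells) {
        stop("'cell_types' must have one label per cell", call. = FALSE)
      }
      as.character(cell_types)
    }
    pop_mean <- rowsum(usage, lab) / as.vector(table(lab))
  }

  structure(
    list(usage = usage, residual_norm = resid,
         genes_used = length(shared), population_mean = pop_mean),
    class = "program_usage"
  )
}

#' @export
print.program_usage <- function(x, ...) {
  cat("Program usage:", nrow(x$usage), "cells x", ncol(x$usage),
      "programs over", x$genes_used, "shared genes\n")
  if (!is.null(x$population_mean)) {
    cat("Mean usage by population:\n")
    print(round(x$population_mean, 3))
  }
  invisible(x)
}

#' Score a gene signature with expression-matched control genes
#'
#' Computes, per cell, the mean normalized expression of the signature genes
#' minus the mean of a pooled set of control genes matched on overall
#' expression level: all genes are ranked by their mean expression across
#' cells and split into `n_bins` equal-frequency bins; each signature gene
#' contributes `n_controls` control genes drawn from its bin (excluding other
#' signature genes; with replacement when the bin holds fewer candidates).
#' The expression-matched controls remove the component of the score that
#' merely tracks a cell's overall expression of highly expressed genes.
#'
#' @param normalized gene x cell normalized matrix.
#' @param signature_genes character vector of signature gene names; genes
#'   absent from the matrix are dropped (at least one must remain).
#' @param n_bins number of expression bins (default 25).
#' @param n_controls control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draws.
#' @param exclude_signature_from_controls logical; the standard scheme
#'   excludes signature genes from the control pool (disable only for
#'   self-comparison checks).
#' @return object of class `signature_score`: list with `score` (named per
#'   cell), `signature_genes_used`, `n_bins`, `n_controls`, `seed`.
#' @export
score_signature <- function(normalized, signature_genes, n_bins = 25,
                            n_controls = 100, seed = 1,
                            exclude_signature_from_controls = TRUE) {
  n_bins <- .assert_count(n_bins, "n_bins")
  n_controls <- .assert_count(n_controls, "n_controls")
  seed <- .assert_count(abs(seed), "seed", positive = FALSE)
  genes <- rownames(normalized)
  # canonical gene order so the score is invariant to input ordering
  sig <- sort(intersect(unique(signature_genes), genes))
  if (length(sig) == 0) {
    stop("no signature gene present in the expression matrix", call. = FALSE)
  }

  gene_mean <- Matrix::rowMeans(normalized)
  n_bins_eff <- min(n_bins, length(genes))
  bin <- ceiling(rank(gene_mean, ties.method = "first") *
                   n_bins_eff / length(genes))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  controls <- unlist(lapply(sig, function(g) {
    pool <- genes[bin == bin[match(g, genes)]]
    if (exclude_signature_from_controls) pool <- setdiff(pool, sig)
    if (length(pool) == 0) return(character(0))
    sample(pool, n_controls, replace = length(pool) < n_controls)
  }))
  if (length(controls) == 0) {
    stop("control pool is empty; lower n_bins or disable signature exclusion",
         call. = FALSE)
  }

  sig_mean <- Matrix::colMeans(normalized[sig, , drop = FALSE])
  ctl_mean <- Matrix::colMeans(normalized[controls, , drop = FALSE])
  structure(
    list(score = sig_mean - ctl_mean, signature_genes_used = sig,
         n_bins = n_bins, n_controls = n_controls, seed = seed),
    class = "signature_score"
  )
}

#' @export
print.signature_score <- function(x, ...) {
  cat("Signature score over", length(x$signature_genes_used), "genes,",
      length(x$score), "cells (", x$n_bins, "bins x", x$n_controls,
      "controls, seed", x$seed, ")\n")
  print(summary(x$score))
  invisible(x)
}
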