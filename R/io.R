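# Readers and writers for the tabular and alignment formats the pipeline
# consumes, plus small report helpers. All tabular outputs are TSV with a
# header row; sparse expression uses the MatrixMarket trio; TCR chains use
# AIRR Rearrangement column names; alignments are plain SAM.

#' @name cell_table_io
#' @title Read and write the spatial cell table
#' @description TSV with columns `barcode`, `x_um`, `y_um`, `cell_type`.
#' @param cells cell table data.frame.
#' @param path file path.
#' @return `read_cells_tsv` returns the validated data.frame;
#'   `write_cells_tsv` returns `path` invisibly.
NULL

#' @rdname cell_table_io
#' @export
write_cells_tsv <- function(cells, path) {
  tab <- .validate_cells(cells)
  tab$cell_type <- as.character(tab$cell_type)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cell_table_io
#' @export
read_cells_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .validate_cells(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read a sparse expression matrix as a MatrixMarket trio
#'
#' `matrix.mtx` (genes x cells), `features.tsv` (one gene name per line) and
#' `barcodes.tsv` (one cell barcode per line) in `dir`, the layout emitted
#' by the common single-cell quantifiers.
#'
#' @param counts sparse gene x cell matrix with dimnames.
#' @param dir directory (created if needed).
#' @return `read_sparse_counts` returns a `dgCMatrix` with dimnames;
#'   `write_sparse_counts` returns `dir` invisibly.
#' @export
write_sparse_counts <- function(counts, dir) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must carry gene rownames and cell colnames", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_sparse_counts
#' @export
read_sparse_counts <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  rownames(m) <- readLines(paths[2])
  colnames(m) <- readLines(paths[3])
  m
}

#' Read / write TCR chain tables in AIRR Rearrangement TSV dialect
#'
#' Required columns `cell_id`, `locus`, `junction_aa`; extra columns are
#' preserved on read but ignored by the analyses.
#'
#' @param chains chain table with columns `cell_barcode`, `locus`, `cdr3_aa`
#'   (internal names) or the AIRR names.
#' @param path file path.
#' @return `read_airr` returns a data.frame with internal column names;
#'   `write_airr` returns `path` invisibly.
#' @export
write_airr <- function(chains, path) {
  chains <- .validate_chains(chains)
  out <- data.frame(cell_id = chains$cell_barcode, locus = chains$locus,
                    junction_aa = chains$cdr3_aa, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_airr
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .validate_chains(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read / write the UMI read-level allele table
#'
#' TSV with columns `cell_barcode`, `umi`, `allele` (one row per read).
#'
#' @param umi_reads the table.
#' @param path file path.
#' @return `read_umi_reads` returns the data.frame; `write_umi_reads`
#'   returns `path` invisibly.
#' @export
write_umi_reads <- function(umi_reads, path) {
  utils::write.table(umi_reads[, c("cell_barcode", "umi", "allele")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_umi_reads
#' @export
read_umi_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Write alignment records as a plain SAM file
#'
#' @param records data.frame with the 11 mandatory SAM columns `qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`,
#'   `seq`, `qual`, plus optional `cb`/`ub` columns written as `CB:Z:`/
#'   `UB:Z:` tags.
#' @param contig_lengths named integer vector declaring every reference
#'   contig (name -> length) for the `@SQ` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, contig_lengths, path) {
  if (is.null(names(contig_lengths)) || any(names(contig_lengths) == "")) {
    stop("'contig_lengths' must be a named vector", call. = FALSE)
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)))
  body <- character(0)
  if (nrow(records) > 0) {
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                    records$qname, as.integer(records$flag), records$rname,
                    as.integer(records$pos), as.integer(records$mapq),
                    records$cigar, records$rnext, as.integer(records$pnext),
                    as.integer(records$tlen), records$seq, records$qual)
    if (!is.null(records$cb)) body <- paste0(body, "\tCB:Z:", records$cb)
    if (!is.null(records$ub)) body <- paste0(body, "\tUB:Z:", records$ub)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a public TCR reference table
#'
#' Accepts the VDJdb-style export dialect: columns `locus` (or `gene`/
#' `Gene`), `cdr3_aa` (or `cdr3`/`CDR3`), and optionally `antigen_species`
#' (or `antigen.species`) and `antigen_epitope` (or `antigen.epitope`).
#'
#' @param path TSV file path.
#' @return data.frame with columns `locus`, `cdr3_aa`, `antigen_species`,
#'   `antigen_epitope`.
#' @export
read_public_tcrs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
    NULL
  }
  locus <- pick("locus", "gene", "Gene")
  cdr3 <- pick("cdr3_aa", "cdr3", "CDR3")
  if (is.null(locus) || is.null(cdr3)) {
    stop("reference needs locus/gene and cdr3 columns", call. = FALSE)
  }
  species <- pick("antigen_species", "antigen.species", "Epitope.species")
  epitope <- pick("antigen_epitope", "antigen.epitope", "Epitope")
  data.frame(
    locus = toupper(locus), cdr3_aa = toupper(cdr3),
    antigen_species = if (is.null(species)) NA_character_ else species,
    antigen_epitope = if (is.null(epitope)) NA_character_ else epitope,
    stringsAsFactors = FALSE
  )
}

#' Write a complete synthetic bundle to disk
#'
#' Materializes every product of [simulate_lymph_node()]: `cells.tsv`, the
#' MatrixMarket trio under `expression/`, `chains.airr.tsv`,
#' `umi_reads.tsv`, `alignments.sam`, `programs.tsv` (gene x program
#' spectra), `signature_genes.txt`, and the ground-truth sidecar
#' `truth.json`.
#'
#' @param sim a `lymph_node_sim` object.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_lymph_node_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "lymph_node_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cells = file.path(dir, "cells.tsv"),
    expression = file.path(dir, "expression"),
    chains = file.path(dir, "chains.airr.tsv"),
    umi_reads = file.path(dir, "umi_reads.tsv"),
    alignments = file.path(dir, "alignments.sam"),
    programs = file.path(dir, "programs.tsv"),
    signature = file.path(dir, "signature_genes.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_cells_tsv(sim$cells, paths["cells"])
  write_sparse_counts(sim$counts, paths["expression"])
  write_airr(sim$chains, paths["chains"])
  write_umi_reads(sim$umi_reads, paths["umi_reads"])
  contigs <- c(chr1 = 1000000L)
  contigs[sim$construct_contig] <- as.integer(sim$config$construct_length)
  write_sam(sim$alignments, contigs, paths["alignments"])
  utils::write.table(
    data.frame(gene = rownames(sim$programs), sim$programs,
               check.names = FALSE),
    paths["programs"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$signature_genes, paths["signature"])

  truth <- sim$truth
  # named atomic vectors lose their names as JSON arrays; store as objects
  truth$cell_type <- as.list(truth$cell_type)
  truth$genotype <- as.list(truth$genotype)
  truth$program_weights <- data.frame(
    barcode = rownames(sim$truth$program_weights),
    sim$truth$program_weights, check.names = FALSE)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a program spectra matrix from TSV
#'
#' First column `gene`, remaining columns one per program; weights must be
#' nonnegative.
#'
#' @param path TSV file path.
#' @return gene x program numeric matrix.
#' @export
read_program_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (names(raw)[1] != "gene") {
    stop("program matrix TSV must start with a 'gene' column", call. = FALSE)
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw$gene
  storage.mode(m) <- "double"
  m
}

#' Percentage of events, rounded half-up
#'
#' @param n_events event count (0 <= n_events <= n_total).
#' @param n_total total count (> 0).
#' @param digits decimal digits (default 1).
#' @return `100 * n_events / n_total`, rounded half away from zero.
#' @examples
#' proportion_percent(43, 626)  # 6.9
#' @export
proportion_percent <- function(n_events, n_total, digits = 1) {
  n_events <- .assert_count(n_events, "n_events", positive = FALSE)
  n_total <- .assert_count(n_total, "n_total", positive = FALSE)
  if (n_total == 0) stop("'n_total' must be positive", call. = FALSE)
  if (n_events > n_total) {
    stop("'n_events' cannot exceed 'n_total'", call. = FALSE)
  }
  round_half_up(100 * n_events / n_total, digits)
}

#' Summarize secondary-event incidence in a treatment cohort
#'
#' @param n_total number of patients.
#' @param event_breakdown named integer vector of event counts by category.
#' @param digits decimal digits for the percentage.
#' @return list with `n_total`, `n_events`, `event_breakdown`, and
#'   `percent` (half-up rounded incidence percentage).
#' @examples
#' cohort_summary(626, c(MDS_AML = 12, solid_tumor = 28, possible_TCL = 3))
#' @export
cohort_summary <- function(n_total, event_breakdown, digits = 1) {
  if (is.null(names(event_breakdown))) {
    stop("'event_breakdown' must be named", call. = FALSE)
  }
  n_events <- as.integer(sum(event_breakdown))
  list(n_total = n_total, n_events = n_events,
       event_breakdown = as.list(event_breakdown),
       percent = proportion_percent(n_events, n_total, digits))
}
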