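# Synthetic lymph-node generator.
#
# Emulates the data structure of a spatially resolved single-nucleus profile
# of a lymph node dominated by a clonally expanded, spatially clustered
# CD4+CD8+ double-positive (DP) T-cell population: cell positions on a square
# bead-array field, a sparse expression matrix generated as nonnegative
# program mixtures with negative-binomial count noise, single-cell TCR chains
# with one biallelic expanded clone, a read-level UMI allele table for one
# somatic variant, and an alignment set with (optionally zero) construct-
# contig reads. A ground-truth sidecar carries the planted labels, weights
# and genotypes so downstream modules can be validated against them.

.EXPANDED_ALPHA <- c("CASPGGLTGGGNKLTF", "CALSHPFRNSGNTPLVF")
.EXPANDED_BETA <- c("CASSLVVWGRGLNEQFF", "CASSQQDSRNTIYF")

#' Configuration for the synthetic lymph-node generator
#'
#' Defaults describe the emulated tissue: a 5.5 mm square field whose
#' profiled nuclei are 51% clustered double-positive (DP) T cells, 20%
#' macrophages, 10% regulatory T cells, 5% fibroblasts, 5% CD4 T cells and
#' smaller fractions of CD8 T cells, NK, endothelial and dendritic cells.
#' Every DP cell belongs to one expanded clonotype carrying two alpha and two
#' beta chains (biallelic rearrangement), each chain independently dropped
#' with probability `chain_dropout`; other T cells carry singleton random
#' CDR3s. The default `construct_fraction` of 0 produces a construct-free
#' alignment set.
#'
#' @param n_cells number of cells (default 2000).
#' @param field_size square field side in micrometers (default 5500).
#' @param cell_type_proportions named fractions summing to 1.
#' @param dp_label name of the clustered, clonally expanded population.
#' @param dp_cluster_count number of Gaussian DP clusters (default 4).
#' @param dp_cluster_sd cluster standard deviation in micrometers
#'   (default 150).
#' @param expanded_clone_chains list with `alpha` and `beta` character
#'   vectors of CDR3 amino-acid sequences for the expanded clone.
#' @param chain_dropout per-chain per-cell capture dropout probability
#'   (default 0.1).
#' @param n_genes,n_programs expression matrix dimensions (defaults 400, 8).
#' @param target_depth expected total counts per cell (default 1500).
#' @param noise_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson noise. Default 0.5.
#' @param dp_program_boost multiplicative weight of the DP population on the
#'   designated TFH-like program (default 6).
#' @param umis_per_cell_mean mean UMIs covering the genotyped site per cell.
#' @param reads_per_umi_mean mean reads per UMI (default 3).
#' @param min_reads_per_umi minimum reads per UMI (default 1).
#' @param umi_error_rate per-read probability of an allele miscall
#'   (default 0.01).
#' @param construct_fraction fraction of cells bearing the integrated
#'   construct (rho; default 0).
#' @param lambda_autosomal,construct_length,copy_ratio depth-model
#'   parameters used to draw construct read pairs (defaults 0.3, 743, 0.5).
#' @param n_background_reads non-construct alignment records (default 200).
#' @param seed master integer seed; per-product sub-streams are derived from
#'   it, so identical seed and configuration give identical output.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_cells = 2000,
    field_size = 5500,
    cell_type_proportions = c(
      DP_T = 0.51, Macrophage = 0.20, Treg = 0.10, Fibroblast = 0.05,
      CD4_T = 0.05, CD8_T = 0.04, NK = 0.03, Endothelial = 0.01, DC = 0.01
    ),
    dp_label = "DP_T",
    dp_cluster_count = 4,
    dp_cluster_sd = 150,
    expanded_clone_chains = list(alpha = .EXPANDED_ALPHA,
                                 beta = .EXPANDED_BETA),
    chain_dropout = 0.1,
    n_genes = 400,
    n_programs = 8,
    target_depth = 1500,
    noise_dispersion = 0.5,
    dp_program_boost = 6,
    umis_per_cell_mean = 4,
    reads_per_umi_mean = 3,
    min_reads_per_umi = 1,
    umi_error_rate = 0.01,
    construct_fraction = 0,
    lambda_autosomal = 0.3,
    construct_length = 743,
    copy_ratio = 0.5,
    n_background_reads = 200,
    seed = 1) {
  cfg <- list(
    n_cells = .assert_count(n_cells, "n_cells"),
    field_size = .assert_scalar_number(field_size, "field_size", lower = 1),
    cell_type_proportions = cell_type_proportions,
    dp_label = dp_label,
    dp_cluster_count = .assert_count(dp_cluster_count, "dp_cluster_count"),
    dp_cluster_sd = .assert_scalar_number(dp_cluster_sd, "dp_cluster_sd",
                                          lower = 0),
    expanded_clone_chains = expanded_clone_chains,
    chain_dropout = .assert_scalar_number(chain_dropout, "chain_dropout",
                                          0, 1),
    n_genes = .assert_count(n_genes, "n_genes"),
    n_programs = .assert_count(n_programs, "n_programs"),
    target_depth = .assert_scalar_number(target_depth, "target_depth",
                                         lower = 1),
    noise_dispersion = .assert_scalar_number(noise_dispersion,
                                             "noise_dispersion", lower = 0),
    dp_program_boost = .assert_scalar_number(dp_program_boost,
                                             "dp_program_boost", lower = 1),
    umis_per_cell_mean = .assert_scalar_number(umis_per_cell_mean,
                                               "umis_per_cell_mean",
                                               lower = 0),
    reads_per_umi_mean = .assert_scalar_number(reads_per_umi_mean,
                                               "reads_per_umi_mean",
                                               lower = 0),
    min_reads_per_umi = .assert_count(min_reads_per_umi,
                                      "min_reads_per_umi"),
    umi_error_rate = .assert_scalar_number(umi_error_rate, "umi_error_rate",
                                           0, 1),
    construct_fraction = .assert_scalar_number(construct_fraction,
                                               "construct_fraction", 0, 1),
    lambda_autosomal = .assert_scalar_number(lambda_autosomal,
                                             "lambda_autosomal", lower = 0),
    construct_length = .assert_scalar_number(construct_length,
                                             "construct_length", lower = 0),
    copy_ratio = .assert_scalar_number(copy_ratio, "copy_ratio", lower = 0),
    n_background_reads = .assert_count(n_background_reads,
                                       "n_background_reads",
                                       positive = FALSE),
    seed = .assert_count(abs(seed), "seed", positive = FALSE)
  )
  p <- cfg$cell_type_proportions
  if (is.null(names(p)) || any(names(p) == "")) {
    stop("cell_type_proportions must be a fully named vector", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("cell_type_proportions must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  if (any(p < 0)) stop("proportions must be nonnegative", call. = FALSE)
  if (!cfg$dp_label %in% names(p)) {
    stop("unknown dp_label '", cfg$dp_label,
         "'; not among the cell type proportions", call. = FALSE)
  }
  ch <- cfg$expanded_clone_chains
  if (!is.list(ch) || !all(c("alpha", "beta") %in% names(ch))) {
    stop("expanded_clone_chains must be list(alpha = ..., beta = ...)",
         call. = FALSE)
  }
  if (cfg$reads_per_umi_mean < cfg$min_reads_per_umi) {
    stop("reads_per_umi_mean must be >= min_reads_per_umi", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a complete synthetic lymph-node dataset
#'
#' Generates every input of the analysis pipeline with the statistical
#' structure the downstream methods assume, plus a ground-truth sidecar. See
#' [simulation_config()] for the planted structure. Each data product draws
#' from its own sub-stream of the master seed, so the draws of one product
#' do not perturb the others.
#'
#' @param config a [simulation_config()].
#' @return list of class `lymph_node_sim` with elements `cells` (spatial
#'   cell table), `counts` (sparse gene x cell matrix), `programs` (gene x
#'   program spectra), `chains` (TCR chain table), `umi_reads` (read-level
#'   allele table), `alignments` (SAM-style record table),
#'   `construct_contig` (name), `signature_genes` (marker genes of the viral
#'   program), and `truth` (list: `cell_type`, `genotype`, `program_weights`,
#'   `clone_cells`, `n_construct_pairs`, `tfh_program`, `viral_program`).
#' @export
simulate_lymph_node <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  cells <- .sim_cells(config)
  expr <- .sim_expression(config, cells)
  chains <- .sim_chains(config, cells)
  umi <- .sim_umi_reads(config, cells)
  aln <- .sim_alignments(config)

  dp_bc <- cells$barcode[cells$cell_type == config$dp_label]
  beta_bearing <- unique(chains$cell_barcode[chains$locus == "TRB"])
  truth <- list(
    cell_type = stats::setNames(as.character(cells$cell_type),
                                cells$barcode),
    genotype = umi$truth_genotype,
    program_weights = expr$weights,
    clone_cells = sort(intersect(dp_bc, beta_bearing)),
    n_construct_pairs = aln$n_construct_pairs,
    tfh_program = expr$tfh_program,
    viral_program = expr$viral_program
  )
  structure(
    list(cells = cells, counts = expr$counts, programs = expr$programs,
         chains = chains, umi_reads = umi$reads,
         alignments = aln$records, construct_contig = aln$construct_contig,
         signature_genes = expr$signature_genes, truth = truth,
         config = config),
    class = "lymph_node_sim"
  )
}

#' @export
print.lymph_node_sim <- function(x, ...) {
  cat("Synthetic lymph node:", nrow(x$cells), "cells,",
      nrow(x$counts), "genes,", nrow(x$chains), "TCR chains,",
      nrow(x$umi_reads), "UMI reads,", nrow(x$alignments),
      "alignment records (seed", x$config$seed, ")\n")
  print(round(prop.table(table(x$cells$cell_type)), 3))
  invisible(x)
}

# --- individual products -----------------------------------------------

.sim_cells <- function(cfg) {
  set.seed(.sub_seed(cfg$seed, "positions"))
  p <- cfg$cell_type_proportions
  n_by_type <- .largest_remainder(cfg$n_cells, as.numeric(p))
  types <- rep(names(p), n_by_type)
  n <- cfg$n_cells
  x <- stats::runif(n, 0, cfg$field_size)
  y <- stats::runif(n, 0, cfg$field_size)

  dp <- which(types == cfg$dp_label)
  if (length(dp) > 0) {
    pad <- min(2 * cfg$dp_cluster_sd, cfg$field_size / 4)
    cx <- stats::runif(cfg$dp_cluster_count, pad, cfg$field_size - pad)
    cy <- stats::runif(cfg$dp_cluster_count, pad, cfg$field_size - pad)
    assign_to <- sample.int(cfg$dp_cluster_count, length(dp), replace = TRUE)
    x[dp] <- pmin(pmax(stats::rnorm(length(dp), cx[assign_to],
                                    cfg$dp_cluster_sd), 0), cfg$field_size)
    y[dp] <- pmin(pmax(stats::rnorm(length(dp), cy[assign_to],
                                    cfg$dp_cluster_sd), 0), cfg$field_size)
  }
  ord <- sample.int(n)  # shuffle so barcode order does not encode the type
  data.frame(
    barcode = sprintf("cell_%04d", seq_len(n)),
    x_um = x[ord], y_um = y[ord],
    cell_type = factor(types[ord], levels = names(p)),
    stringsAsFactors = FALSE
  )
}

.sim_expression <- function(cfg, cells) {
  set.seed(.sub_seed(cfg$seed, "expression"))
  g <- cfg$n_genes
  k <- cfg$n_programs
  genes <- sprintf("GENE%04d", seq_len(g))
  prog_names <- c("TFH", "Viral",
                  sprintf("Prog%02d", seq_len(max(k - 2, 0))))[seq_len(k)]

  # Spectra: every gene has a home program with concentrated weight, plus a
  # diffuse background, so programs are well separated but not orthogonal.
  home <- sample.int(k, g, replace = TRUE)
  W <- matrix(stats::rgamma(g * k, shape = 0.05, rate = 1), g, k)
  W[cbind(seq_len(g), home)] <- stats::rgamma(g, shape = 3, rate = 1)
  dimnames(W) <- list(genes, prog_names)

  # Per-cell nonnegative weights; DP cells lean on the TFH-like program and
  # away from the viral-reactivity program.
  n <- nrow(cells)
  U <- matrix(stats::rgamma(n * k, shape = 1.5, rate = 1), n, k)
  dp <- cells$cell_type == cfg$dp_label
  U[dp, 1] <- U[dp, 1] * cfg$dp_program_boost
  U[dp, 2] <- U[dp, 2] * 0.1
  dimnames(U) <- list(cells$barcode, prog_names)

  mu <- W %*% t(U)                      # gene x cell expected expression
  depth_scale <- cfg$target_depth / colSums(mu)
  mu <- mu %*% diag(depth_scale)
  U <- U * depth_scale  # effective weights actually parameterizing counts
  counts <- if (cfg$noise_dispersion > 0) {
    matrix(stats::rnbinom(g * n, mu = as.vector(mu),
                          size = 1 / cfg$noise_dispersion), g, n)
  } else {
    matrix(stats::rpois(g * n, as.vector(mu)), g, n)
  }
  dimnames(counts) <- list(genes, cells$barcode)

  viral_markers <- genes[home == 2][
    order(W[home == 2, 2], decreasing = TRUE)]
  list(
    counts = Matrix::Matrix(counts, sparse = TRUE),
    programs = W,
    weights = U,
    signature_genes = utils::head(viral_markers, 30),
    tfh_program = prog_names[1],
    viral_program = prog_names[2]
  )
}

.random_cdr3 <- function(n, min_len = 10, max_len = 16) {
  aa <- strsplit(.AA, "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste0("C", paste(sample(aa, len - 2, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

.sim_chains <- function(cfg, cells) {
  set.seed(.sub_seed(cfg$seed, "chains"))
  t_types <- intersect(c(cfg$dp_label, "Treg", "CD4_T", "CD8_T"),
                       levels(cells$cell_type))
  rows <- list()
  clone <- cfg$expanded_clone_chains
  for (i in which(as.character(cells$cell_type) %in% t_types)) {
    bc <- cells$barcode[i]
    if (cells$cell_type[i] == cfg$dp_label) {
      keep_a <- stats::runif(length(clone$alpha)) >= cfg$chain_dropout
      keep_b <- stats::runif(length(clone$beta)) >= cfg$chain_dropout
      a <- clone$alpha[keep_a]
      b <- clone$beta[keep_b]
    } else {
      a <- if (stats::runif(1) >= cfg$chain_dropout) .random_cdr3(1)
        else character(0)
      b <- if (stats::runif(1) >= cfg$chain_dropout) .random_cdr3(1)
        else character(0)
    }
    if (length(a) + length(b) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      cell_barcode = bc,
      locus = c(rep("TRA", length(a)), rep("TRB", length(b))),
      cdr3_aa = c(a, b),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(cell_barcode = character(), locus = character(),
                      cdr3_aa = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.sim_umi_reads <- function(cfg, cells) {
  set.seed(.sub_seed(cfg$seed, "umi"))
  mutant <- cells$cell_type == cfg$dp_label
  truth <- stats::setNames(ifelse(mutant, "mutant", "wild_type"),
                           cells$barcode)
  n_umis <- stats::rpois(nrow(cells), cfg$umis_per_cell_mean)
  rows <- vector("list", nrow(cells))
  extra_mean <- cfg$reads_per_umi_mean - cfg$min_reads_per_umi
  for (i in which(n_umis > 0)) {
    true_allele <- if (mutant[i]) "variant" else "reference"
    umi_ids <- sprintf("%s-umi%02d", cells$barcode[i], seq_len(n_umis[i]))
    n_reads <- cfg$min_reads_per_umi + stats::rpois(n_umis[i], extra_mean)
    allele <- rep(true_allele, sum(n_reads))
    flip <- stats::runif(sum(n_reads)) < cfg$umi_error_rate
    if (any(flip)) {
      allele[flip] <- vapply(allele[flip], function(a) {
        sample(setdiff(.ALLELES, a), 1)
      }, character(1))
    }
    rows[[i]] <- data.frame(
      cell_barcode = cells$barcode[i],
      umi = rep(umi_ids, n_reads),
      allele = allele,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  reads <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cell_barcode = character(), umi = character(),
               allele = character(), stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  # Shuffle rows: downstream calls must not depend on input order.
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads, truth_genotype = truth)
}

.sim_alignments <- function(cfg) {
  simulate_construct_alignments(
    lambda_autosomal = cfg$lambda_autosomal,
    construct_length = cfg$construct_length,
    copy_ratio = cfg$copy_ratio,
    cell_fraction = cfg$construct_fraction,
    n_background_reads = cfg$n_background_reads,
    seed = .sub_seed(cfg$seed, "alignments")
  )
}

#' Simulate an alignment record set with construct-contig read pairs
#'
#' Draws the number of construct-mapped read pairs from a Poisson
#' distribution with mean
#' `lambda_autosomal * construct_length * copy_ratio * cell_fraction`
#' (the same expectation the closed-form [detection_power()] model assumes),
#' emits two high-MAPQ primary records per pair on the construct contig, and
#' pads the set with background records on a human-like contig. With
#' `cell_fraction = 0` the set is construct-free by construction.
#'
#' @inheritParams detection_power
#' @param n_background_reads non-construct records to emit (default 200).
#' @param seed integer seed.
#' @return list with `records` (SAM-style data.frame), `construct_contig`,
#'   `contig_lengths` (named vector for [write_sam()]), and
#'   `n_construct_pairs` (the Poisson draw).
#' @export
simulate_construct_alignments <- function(lambda_autosomal = 0.3,
                                          construct_length = 743,
                                          copy_ratio = 0.5,
                                          cell_fraction = 0,
                                          n_background_reads = 200,
                                          seed = 1) {
  cfg <- list(
    lambda_autosomal = .assert_scalar_number(lambda_autosomal,
                                             "lambda_autosomal", lower = 0),
    construct_length = .assert_scalar_number(construct_length,
                                             "construct_length", lower = 1),
    copy_ratio = .assert_scalar_number(copy_ratio, "copy_ratio", lower = 0),
    construct_fraction = .assert_scalar_number(cell_fraction,
                                               "cell_fraction", 0, 1),
    n_background_reads = .assert_count(n_background_reads,
                                       "n_background_reads",
                                       positive = FALSE)
  )
  set.seed(.assert_count(abs(seed), "seed", positive = FALSE))
  construct_contig <- "construct_scfv"
  read_len <- 100L
  lambda_car <- cfg$lambda_autosomal * cfg$construct_length *
    cfg$copy_ratio * cfg$construct_fraction
  n_pairs <- stats::rpois(1, lambda_car)

  mk <- function(qname, flag, rname, pos) {
    data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
               mapq = 60L, cigar = sprintf("%dM", read_len),
               rnext = "*", pnext = 0L, tlen = 0L,
               seq = strrep("A", read_len), qual = "*",
               stringsAsFactors = FALSE)
  }
  bg <- if (cfg$n_background_reads > 0) {
    mk(sprintf("bg%05d", seq_len(cfg$n_background_reads)), 0L, "chr1",
       sample.int(1000000L - read_len, cfg$n_background_reads,
                  replace = TRUE))
  } else NULL
  con <- if (n_pairs > 0) {
    pos <- sample.int(max(cfg$construct_length - read_len, 1L), n_pairs,
                      replace = TRUE)
    rbind(
      mk(sprintf("construct%04d", seq_len(n_pairs)), 99L, construct_contig,
         pos),
      mk(sprintf("construct%04d", seq_len(n_pairs)), 147L, construct_contig,
         pos)
    )
  } else NULL
  records <- rbind(bg, con)
  if (is.null(records)) records <- mk(character(0), integer(0),
                                      character(0), integer(0))
  rownames(records) <- NULL
  contig_lengths <- c(chr1 = 1000000L)
  contig_lengths[construct_contig] <- as.integer(cfg$construct_length)
  list(records = records, construct_contig = construct_contig,
       contig_lengths = contig_lengths, n_construct_pairs = n_pairs)
}
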