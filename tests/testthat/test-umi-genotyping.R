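# Per-UMI consensus, cell-level genotype classification, recovery report,
# and the SAM site adapter.

# Independent majority oracle: count each allele, return the unique top
# allele or "discarded" on a tie.
consensus_oracle <- function(alleles) {
  counts <- vapply(c("variant", "reference", "other"),
                   function(a) sum(alleles == a), integer(1))
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) "discarded" else top
}

test_that("UMI consensus is strict majority with tie discard", {
  expect_identical(umi_consensus(c("variant", "variant", "reference")),
                   "variant")
  expect_identical(umi_consensus("variant"), "variant")
  expect_identical(umi_consensus(c("variant", "reference")), "discarded")
  expect_error(umi_consensus(character(0)), "at least one read")
  expect_error(umi_consensus("indel"), "allele")
})

test_that("consensus equals the exhaustive oracle on all short reads sets", {
  alleles <- c("variant", "reference", "other")
  for (len in 1:3) {
    combos <- do.call(expand.grid,
                      c(rep(list(alleles), len), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(combos))) {
      reads <- unlist(combos[i, ], use.names = FALSE)
      expect_identical(umi_consensus(reads), consensus_oracle(reads),
                       info = paste(reads, collapse = ","))
    }
  }
  # a few longer random sets against the same oracle
  set.seed(5)
  for (i in 1:50) {
    reads <- sample(alleles, sample(4:20, 1), replace = TRUE)
    expect_identical(umi_consensus(reads), consensus_oracle(reads))
  }
})

test_that("cell genotype classes follow the UMI-level rules", {
  tab <- data.frame(
    cell_barcode = c(rep("mut", 4), rep("wt", 3), rep("tied", 2)),
    umi = c("u1", "u1", "u2", "u2", "v1", "v1", "v2", "w1", "w1"),
    allele = c("variant", "variant", "reference", "reference", # mut: 1 var UMI
               "reference", "reference", "other",              # wt: covering
               "variant", "reference"),                        # tied: discard
    stringsAsFactors = FALSE
  )
  calls <- genotype_cells(tab)
  g <- setNames(calls$genotype, calls$cell_barcode)
  expect_identical(g[["mut"]], "mutant")
  expect_identical(g[["wt"]], "wild_type")
  expect_identical(g[["tied"]], "unassigned")

  row <- calls[calls$cell_barcode == "mut", ]
  expect_identical(row$n_variant_umis, 1L)
  expect_identical(row$n_covering_umis, 2L)
  row <- calls[calls$cell_barcode == "tied", ]
  expect_identical(row$n_covering_umis, 0L)
  expect_identical(row$n_discarded_umis, 1L)

  # partition: one call per barcode, classes exhaustive
  expect_identical(sort(calls$cell_barcode), sort(unique(tab$cell_barcode)))
  expect_true(all(calls$genotype %in% c("mutant", "wild_type",
                                        "unassigned")))

  # order invariance
  set.seed(3)
  shuf <- tab[sample(nrow(tab)), ]
  expect_identical(genotype_cells(shuf), calls)

  # monotonicity: adding a variant-consensus UMI never demotes to wild-type
  plus <- rbind(tab, data.frame(cell_barcode = "wt", umi = "v9",
                                allele = "variant"))
  g2 <- genotype_cells(plus)
  expect_identical(g2$genotype[g2$cell_barcode == "wt"], "mutant")

  expect_error(genotype_cells(data.frame(cell_barcode = "a", umi = "",
                                         allele = "variant")),
               "malformed")
})

test_that("error-free tables are recovered perfectly; degenerate flips flip all", {
  sim <- simulate_lymph_node(simulation_config(
    n_cells = 300, umi_error_rate = 0, seed = 21))
  calls <- genotype_cells(sim$umi_reads)
  truth <- data.frame(cell_barcode = names(sim$truth$genotype),
                      genotype = unname(sim$truth$genotype),
                      stringsAsFactors = FALSE)
  rep <- genotype_recovery_report(calls, truth)
  # no read errors -> every UMI is unanimous, no ties, perfect calls among
  # cells with any coverage
  expect_equal(unname(rep$precision), c(1, 1))
  expect_equal(unname(rep$recall), c(1, 1))

  # all reads flipped to variant: every covered cell is called mutant
  flipped <- sim$umi_reads
  flipped$allele <- "variant"
  calls2 <- genotype_cells(flipped)
  expect_true(all(calls2$genotype == "mutant"))

  expect_error(genotype_recovery_report(calls, data.frame(
    cell_barcode = "nope", genotype = "mutant")), "overlap")
})

test_that("SAM site adapter reports variant/reference/other per covering read", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr4\tLN:10000",
    # covers site 100 with G (reference)
    paste("r1", 0, "chr4", 95, 60, "10M", "*", 0, 0, strrep("G", 10), "*",
          "CB:Z:cellA", "UB:Z:u1", sep = "\t"),
    # covers site 100 with A (variant)
    paste("r2", 0, "chr4", 100, 60, "10M", "*", 0, 0, strrep("A", 10), "*",
          "CB:Z:cellA", "UB:Z:u2", sep = "\t"),
    # covers site 100 with T (other)
    paste("r3", 0, "chr4", 98, 60, "10M", "*", 0, 0, strrep("T", 10), "*",
          "CB:Z:cellB", "UB:Z:u3", sep = "\t"),
    # deletion spanning the site: covering, non-variant
    paste("r4", 0, "chr4", 97, 60, "3M5D7M", "*", 0, 0, strrep("C", 10),
          "*", "CB:Z:cellB", "UB:Z:u4", sep = "\t"),
    # aligned span ends before the site
    paste("r5", 0, "chr4", 80, 60, "10M", "*", 0, 0, strrep("A", 10), "*",
          "CB:Z:cellC", "UB:Z:u5", sep = "\t"),
    # no CB/UB tags: skipped
    paste("r6", 0, "chr4", 95, 60, "10M", "*", 0, 0, strrep("A", 10), "*",
          sep = "\t"),
    # secondary alignment: skipped
    paste("r7", 256, "chr4", 95, 60, "10M", "*", 0, 0, strrep("A", 10), "*",
          "CB:Z:cellD", "UB:Z:u7", sep = "\t")
  ), sam)
  calls <- read_allele_calls_sam(sam, "chr4:100:G>A")
  calls <- calls[order(calls$umi), ]
  expect_identical(calls$allele, c("reference", "variant", "other", "other"))
  expect_identical(calls$cell_barcode, c("cellA", "cellA", "cellB", "cellB"))
  expect_error(read_allele_calls_sam(sam, "chr4:100"), "CONTIG:POS")
})
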