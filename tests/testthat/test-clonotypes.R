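# Clonotype grouping, biallelic flagging, and public TCR matching.

ALPHA2 <- c("CASPGGLTGGGNKLTF", "CALSHPFRNSGNTPLVF")
BETA2 <- c("CASSLVVWGRGLNEQFF", "CASSQQDSRNTIYF")

chain_rows <- function(bc, locus, cdr3) {
  data.frame(cell_barcode = bc, locus = locus, cdr3_aa = cdr3,
             stringsAsFactors = FALSE)
}

test_that("exact-set keying groups by identical beta chain sets", {
  # two cells share {b1, b2}; one cell captured only b1 -> two clones
  ch <- rbind(
    chain_rows("c1", "TRB", BETA2[1]), chain_rows("c1", "TRB", BETA2[2]),
    chain_rows("c2", "TRB", BETA2[1]), chain_rows("c2", "TRB", BETA2[2]),
    chain_rows("c3", "TRB", BETA2[1])
  )
  tab <- group_clonotypes(ch)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$size, c(2L, 1L))  # ordered by decreasing size

  # shared-chain keying merges the partial-capture cell into the clone
  tab2 <- group_clonotypes(ch, key = "shared_chain")
  expect_identical(nrow(tab2), 1L)
  expect_identical(tab2$size, 3L)
  expect_setequal(attr(tab2, "members")[[1]], c("c1", "c2", "c3"))

  # all-distinct betas: every clone is a singleton
  solo <- chain_rows(paste0("s", 1:5), "TRB",
                     c("CAAAF", "CSSAF", "CSSCF", "CDDDF", "CEEEF"))
  tab3 <- group_clonotypes(solo)
  expect_identical(nrow(tab3), 5L)
  expect_true(all(tab3$size == 1L))
})

test_that("clone sizes partition beta-bearing cells and survive row shuffles", {
  set.seed(31)
  sim <- simulate_lymph_node(simulation_config(n_cells = 300, seed = 31))
  tab <- group_clonotypes(sim$chains, sim$cells)
  beta_cells <- unique(sim$chains$cell_barcode[sim$chains$locus == "TRB"])
  expect_identical(sum(tab$size), length(beta_cells))

  # per-population sizes sum to per-population beta-bearing counts
  pops <- attr(tab, "size_by_population")
  type_of <- setNames(as.character(sim$cells$cell_type), sim$cells$barcode)
  expect_equal(colSums(pops)[order(colnames(pops))],
               table(type_of[beta_cells])[order(names(table(
                 type_of[beta_cells])))],
               ignore_attr = TRUE)

  shuf <- sim$chains[sample(nrow(sim$chains)), ]
  tab2 <- group_clonotypes(shuf, sim$cells)
  expect_identical(tab$size, tab2$size)
  expect_identical(tab$beta_chains, tab2$beta_chains)
})

test_that("planted clone is recovered exactly under shared-chain keying", {
  sim <- simulate_lymph_node(simulation_config(n_cells = 500, seed = 41))
  tab <- group_clonotypes(sim$chains, sim$cells, key = "shared_chain")
  expect_identical(sort(attr(tab, "members")[[1]]),
                   sim$truth$clone_cells)
  expect_identical(strsplit(tab$beta_chains[1], ";")[[1]], sort(BETA2))
  expect_true(tab$biallelic_alpha[1])
  expect_true(tab$biallelic_beta[1])
  # every DP chain set is a subset of the four expanded-clone chains
  dp <- sim$cells$barcode[sim$cells$cell_type == "DP_T"]
  dp_chains <- sim$chains$cdr3_aa[sim$chains$cell_barcode %in% dp]
  expect_true(all(dp_chains %in% c(ALPHA2, BETA2)))
})

test_that("biallelic flags require exactly two defining chains per locus", {
  # clone of 10 cells with both alpha and both beta chains under dropout
  set.seed(51)
  alpha_sets <- lapply(1:10, function(i) ALPHA2[runif(2) > 0.1])
  beta_sets <- lapply(1:10, function(i) BETA2[runif(2) > 0.1])
  fl <- flag_biallelic(alpha_sets, beta_sets)
  expect_true(fl[["alpha"]])
  expect_true(fl[["beta"]])

  # single beta chain: not biallelic
  fl2 <- flag_biallelic(alpha_sets, rep(list(BETA2[1]), 10))
  expect_false(fl2[["beta"]])

  # a third beta present in 1 of 10 cells is not defining at threshold 0.5
  rare <- c(rep(list(BETA2), 9), list(c(BETA2, "CASSRAREF")))
  fl3 <- flag_biallelic(alpha_sets, rare)
  expect_true(fl3[["beta"]])
  # ...but three chains all above threshold break the exactly-2 rule
  fl4 <- flag_biallelic(alpha_sets,
                        rep(list(c(BETA2, "CASSRAREF")), 10))
  expect_false(fl4[["beta"]])

  expect_error(flag_biallelic(list(), list()), "member")
  expect_error(flag_biallelic(alpha_sets, beta_sets,
                              presence_threshold = 0), "0, 1")
})

test_that("public TCR matching is exact on (locus, CDR3) pairs", {
  clone_chains <- rbind(
    chain_rows("c1", "TRA", ALPHA2[1]), chain_rows("c1", "TRA", ALPHA2[2]),
    chain_rows("c1", "TRB", BETA2[1]), chain_rows("c1", "TRB", BETA2[2])
  )
  # reference without the clone's chains: no matches
  ref <- data.frame(locus = c("TRA", "TRB"),
                    cdr3_aa = c("CAVIRTGGFKTIF", "CASSIRSSYEQYF"),
                    antigen_species = c("CMV", "InfluenzaA"),
                    stringsAsFactors = FALSE)
  m <- match_public_tcrs(clone_chains, ref)
  expect_identical(nrow(m$matches), 0L)
  expect_identical(unname(m$n_matched_chains), c(0L, 0L))

  # empty reference
  m0 <- match_public_tcrs(clone_chains, ref[0, ])
  expect_identical(sum(m0$n_matched_chains), 0L)

  # planted hit, case-insensitive
  ref2 <- rbind(ref, data.frame(locus = "trb",
                                cdr3_aa = tolower(BETA2[1]),
                                antigen_species = "SARS-CoV-2"))
  m2 <- match_public_tcrs(clone_chains, ref2)
  expect_identical(unname(m2$n_matched_chains), c(0L, 1L))
  expect_identical(m2$matches$cdr3_aa, BETA2[1])

  # union property: matches against R1 u R2 = union of separate matches
  r1 <- ref2[1:2, ]; r2 <- ref2[3, ]
  mu <- match_public_tcrs(clone_chains, rbind(r1, r2))
  ms <- rbind(match_public_tcrs(clone_chains, r1)$matches,
              match_public_tcrs(clone_chains, r2)$matches)
  expect_identical(mu$matches[order(mu$matches$cdr3_aa), ]$cdr3_aa,
                   ms[order(ms$cdr3_aa), ]$cdr3_aa)

  expect_error(match_public_tcrs(clone_chains,
                                 data.frame(locus = "IGH",
                                            cdr3_aa = "CARF")),
               "TRA or TRB")
})

test_that("cells with more than two chains at a locus are kept and flagged", {
  ch <- rbind(
    chain_rows("c1", "TRB", c("CASAF", "CASDF", "CASEF")),
    chain_rows("c2", "TRB", "CASAF")
  )
  expect_warning(tab <- group_clonotypes(ch), "more than 2 chains")
  expect_identical(attr(tab, "multichain_cells"), "c1")
  expect_identical(sum(tab$size), 2L)
})
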