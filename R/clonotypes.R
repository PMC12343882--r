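# Clonotype grouping from single-cell TCR chains, biallelic-rearrangement
# flagging, and exact CDR3 amino-acid matching to public TCR references.

.AA <- "ACDEFGHIKLMNPQRSTVWY"

.validate_chains <- function(chains) {
  if (!is.data.frame(chains)) {
    stop("'chains' must be a data.frame", call. = FALSE)
  }
  need <- c("cell_barcode", "locus", "cdr3_aa")
  # AIRR Rearrangement dialect aliases
  nm <- names(chains)
  if (!"cell_barcode" %in% nm && "cell_id" %in% nm) {
    chains$cell_barcode <- chains$cell_id
  }
  if (!"cdr3_aa" %in% nm && "junction_aa" %in% nm) {
    chains$cdr3_aa <- chains$junction_aa
  }
  miss <- setdiff(need, names(chains))
  if (length(miss) > 0) {
    stop("chain table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  chains$cell_barcode <- as.character(chains$cell_barcode)
  chains$locus <- toupper(as.character(chains$locus))
  chains$cdr3_aa <- toupper(as.character(chains$cdr3_aa))
  if (!all(chains$locus %in% c("TRA", "TRB"))) {
    stop("locus must be TRA or TRB", call. = FALSE)
  }
  bad <- chains$cdr3_aa == "" |
    grepl(sprintf("[^%s]", .AA), chains$cdr3_aa)
  if (any(bad)) {
    stop("CDR3 sequences must be nonempty amino-acid strings; offending: ",
         paste(utils::head(chains$cdr3_aa[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  chains[, need]
}

#' Group T cells into clonotypes by their beta-chain CDR3 sequences
#'
#' Cells are keyed on beta (TRB) CDR3 amino-acid sequences; alpha (TRA)
#' chains are aggregated descriptively per clone. Cells with no beta chain
#' are excluded from clone sizing. Two keying rules are available:
#' \describe{
#'   \item{`"exact_set"`}{(default) cells sharing an identical \emph{set} of
#'     beta CDR3s form a clone; a cell that captured only one of a clone's
#'     two beta chains keys separately.}
#'   \item{`"shared_chain"`}{cells are merged into one clone whenever their
#'     beta sets intersect (connected components of the cell-chain graph);
#'     robust to per-chain capture dropout in a biallelic clone.}
#' }
#'
#' @param chains data.frame of chain records with columns
#'   `cell_barcode`/`cell_id`, `locus` (`TRA`/`TRB`), `cdr3_aa`/`junction_aa`
#'   (AIRR Rearrangement column names are accepted; extra columns ignored).
#' @param cell_types optional spatial cell table (see
#'   [neighbor_proportions()]) supplying a `cell_type` per barcode; cells
#'   absent from it are labeled `"unknown"`.
#' @param key clone keying rule, `"exact_set"` or `"shared_chain"`.
#' @param presence_threshold fraction in (0, 1] used by [flag_biallelic()]
#'   for the clone-defining chain call (default 0.5).
#' @return object of class `clonotype_table`: data.frame with one row per
#'   clone (`clone_id`, `beta_chains`, `alpha_chains` as `;`-joined strings,
#'   `size`, `biallelic_alpha`, `biallelic_beta`), ordered by decreasing
#'   size. Attributes: `members` (list of barcode vectors per clone),
#'   `size_by_population` (clone x cell-type matrix), `multichain_cells`
#'   (barcodes flagged for > 2 chains at one locus, kept with a warning).
#' @export
group_clonotypes <- function(chains, cell_types = NULL,
                             key = c("exact_set", "shared_chain"),
                             presence_threshold = 0.5) {
  key <- match.arg(key)
  chains <- .validate_chains(chains)
  chains <- unique(chains)

  per_locus <- table(chains$cell_barcode, chains$locus)
  multi <- rownames(per_locus)[apply(per_locus > 2, 1, any)]
  if (length(multi) > 0) {
    warning(length(multi), " cell(s) carry more than 2 chains at one locus ",
            "(kept): ", paste(utils::head(multi, 3), collapse = ", "),
            call. = FALSE)
  }

  beta <- chains[chains$locus == "TRB", ]
  alpha <- chains[chains$locus == "TRA", ]
  if (nrow(beta) == 0) {
    stop("no beta (TRB) chains in input; clones are keyed on beta CDR3s",
         call. = FALSE)
  }
  beta_sets <- lapply(split(beta$cdr3_aa, beta$cell_barcode),
                      function(s) sort(unique(s)))
  cells <- names(beta_sets)

  if (key == "exact_set") {
    keys <- vapply(beta_sets, paste, character(1), collapse = ";")
    clone_of <- as.integer(factor(keys, levels = unique(keys)))
  } else {
    # connected components of the bipartite cell / beta-chain graph
    chain_ids <- sort(unique(beta$cdr3_aa))
    edges <- rbind(match(beta$cell_barcode, cells),
                   length(cells) + match(beta$cdr3_aa, chain_ids))
    g <- igraph::make_graph(edges = as.vector(edges), directed = FALSE,
                            n = length(cells) + length(chain_ids))
    comp <- igraph::components(g)$membership[seq_along(cells)]
    clone_of <- as.integer(factor(comp, levels = unique(comp)))
  }

  alpha_sets <- lapply(split(alpha$cdr3_aa, alpha$cell_barcode),
                       function(s) sort(unique(s)))
  type_of <- rep("unknown", length(cells))
  if (!is.null(cell_types)) {
    ct <- .validate_cells(cell_types)
    hit <- match(cells, ct$barcode)
    type_of[!is.na(hit)] <- as.character(ct$cell_type[hit[!is.na(hit)]])
  }

  n_clones <- max(clone_of)
  members <- split(cells, clone_of)
  rows <- lapply(seq_len(n_clones), function(ci) {
    mem <- members[[ci]]
    bset <- sort(unique(unlist(beta_sets[mem])))
    aset <- sort(unique(unlist(alpha_sets[mem])))
    grab <- function(sets) lapply(mem, function(cell) {
      s <- sets[[cell]]
      if (is.null(s)) character(0) else s
    })
    bi <- flag_biallelic(grab(alpha_sets), grab(beta_sets),
                         presence_threshold)
    data.frame(
      clone_id = ci,
      beta_chains = paste(bset, collapse = ";"),
      alpha_chains = paste(aset, collapse = ";"),
      size = length(mem),
      biallelic_alpha = bi["alpha"],
      biallelic_beta = bi["beta"],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  pop_levels <- sort(unique(type_of))
  size_by_pop <- t(vapply(seq_len(n_clones), function(ci) {
    table(factor(type_of[match(members[[ci]], cells)], levels = pop_levels))
  }, stats::setNames(integer(length(pop_levels)), pop_levels)))
  if (length(pop_levels) == 1) size_by_pop <- t(size_by_pop)
  rownames(size_by_pop) <- tab$clone_id

  ord <- order(tab$size, decreasing = TRUE)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(tab,
            members = members[ord],
            size_by_population = size_by_pop[ord, , drop = FALSE],
            multichain_cells = multi,
            key = key,
            class = c("clonotype_table", "data.frame"))
}

#' Flag biallelic TCR rearrangement in a clone
#'
#' A chain is \emph{clone-defining} when it is present in at least
#' `presence_threshold` of the clone's member cells that bear at least one
#' chain of that locus (cells with total dropout at a locus carry no
#' information about it). A locus is flagged biallelic when it has exactly
#' two defining chains — the signature of both alleles having productively
#' rearranged.
#'
#' @param alpha_sets,beta_sets lists, one element per member cell, each a
#'   character vector of that cell's CDR3 amino-acid sequences at the locus
#'   (empty or missing elements mean dropout).
#' @param presence_threshold fraction in (0, 1] (default 0.5).
#' @return named logical vector `c(alpha = , beta = )`.
#' @examples
#' a <- rep(list(c("CASPGGLTGGGNKLTF", "CALSHPFRNSGNTPLVF")), 10)
#' b <- rep(list(c("CASSLVVWGRGLNEQFF", "CASSQQDSRNTIYF")), 10)
#' flag_biallelic(a, b)
#' @export
flag_biallelic <- function(alpha_sets, beta_sets, presence_threshold = 0.5) {
  if (!is.numeric(presence_threshold) || length(presence_threshold) != 1 ||
      presence_threshold <= 0 || presence_threshold > 1) {
    stop("'presence_threshold' must be in (0, 1]", call. = FALSE)
  }
  n <- max(length(alpha_sets), length(beta_sets))
  if (n == 0) stop("clone has no member cells", call. = FALSE)
  flag_locus <- function(sets) {
    sets <- Filter(function(s) length(s) > 0, sets)
    bearing <- length(sets)
    if (bearing == 0) return(FALSE)
    tab <- table(unlist(lapply(sets, unique)))
    sum(tab / bearing >= presence_threshold) == 2L
  }
  c(alpha = flag_locus(alpha_sets), beta = flag_locus(beta_sets))
}

#' Match repertoire chains against a public TCR reference
#'
#' Exact amino-acid identity matching of CDR3 sequences on (locus, CDR3)
#' pairs, after uppercasing both sides — the convention for querying public
#' TCR databases such as VDJdb for known antigen specificities. No fuzzy
#' matching is performed; V/J gene columns, if present, are ignored.
#'
#' @param chains chain table (see [group_clonotypes()] for accepted columns).
#' @param reference data.frame with columns `locus` (`TRA`/`TRB`), `cdr3_aa`,
#'   and optionally `antigen_species` / `antigen_epitope`.
#' @return list with `matches` (data.frame joining each matched repertoire
#'   chain to its reference rows) and `n_matched_chains` (named vector:
#'   distinct repertoire CDR3s with at least one reference hit, per locus).
#' @export
match_public_tcrs <- function(chains, reference) {
  chains <- .validate_chains(chains)
  if (!is.data.frame(reference) ||
      !all(c("locus", "cdr3_aa") %in% names(reference))) {
    stop("'reference' needs columns locus and cdr3_aa", call. = FALSE)
  }
  ref <- reference
  ref$locus <- toupper(as.character(ref$locus))
  ref$cdr3_aa <- toupper(as.character(ref$cdr3_aa))
  if (nrow(ref) > 0 && !all(ref$locus %in% c("TRA", "TRB"))) {
    stop("reference locus values must be TRA or TRB", call. = FALSE)
  }
  if (!"antigen_species" %in% names(ref)) {
    ref[["antigen_species"]] <- rep(NA_character_, nrow(ref))
  }
  if (!"antigen_epitope" %in% names(ref)) {
    ref[["antigen_epitope"]] <- rep(NA_character_, nrow(ref))
  }

  rep_chains <- unique(chains[, c("locus", "cdr3_aa")])
  hit <- merge(rep_chains, ref[, c("locus", "cdr3_aa", "antigen_species",
                                   "antigen_epitope")],
               by = c("locus", "cdr3_aa"))
  matched <- unique(hit[, c("locus", "cdr3_aa")])
  n_matched <- vapply(c(TRA = "TRA", TRB = "TRB"), function(l) {
    sum(matched$locus == l)
  }, integer(1))
  list(matches = hit[order(hit$locus, hit$cdr3_aa), , drop = FALSE],
       n_matched_chains = n_matched)
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat("Clonotype table:", nrow(x), "clones,",
      sum(x$size), "beta-bearing cells (keying:", attr(x, "key"), ")\n")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more clones\n")
  invisible(x)
}
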