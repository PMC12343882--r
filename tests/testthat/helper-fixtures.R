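# Shared fixture builders. Everything is generated in code at test time.

# Minimal spatial cell table from coordinate/type vectors.
cells_fixture <- function(x, y, type) {
  data.frame(barcode = sprintf("c%03d", seq_along(x)),
             x_um = x, y_um = y, cell_type = type,
             stringsAsFactors = FALSE)
}

# Write a SAM file with given records over chr1 + a construct contig.
sam_fixture <- function(records, path = tempfile(fileext = ".sam"),
                        construct_len = 743L) {
  write_sam(records, c(chr1 = 1000000L, construct_scfv = construct_len),
            path)
  path
}

# One SAM-style record row with overridable fields.
sam_record <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 100L,
                       mapq = 60L, cigar = "50M") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = "*", pnext = 0L,
             tlen = 0L, seq = strrep("A", 50L), qual = "*",
             stringsAsFactors = FALSE)
}

# Brute-force O(n^2) neighbor-proportion oracle, written independently of
# the package's adjacency/rowsum path.
neighbor_proportions_oracle <- function(cells, radius) {
  types <- sort(unique(cells$cell_type))
  n <- nrow(cells)
  per_cell <- matrix(NA_real_, n, length(types),
                     dimnames = list(NULL, types))
  for (i in seq_len(n)) {
    d <- sqrt((cells$x_um - cells$x_um[i])^2 +
                (cells$y_um - cells$y_um[i])^2)
    nb <- which(d > 0 & d <= radius)
    if (length(nb) == 0) next
    for (t in types) {
      per_cell[i, t] <- mean(cells$cell_type[nb] == t)
    }
  }
  O <- matrix(0, length(types), length(types),
              dimnames = list(types, types))
  for (t in types) {
    rows <- which(cells$cell_type == t & !is.na(per_cell[, 1]))
    if (length(rows) > 0) O[t, ] <- colMeans(per_cell[rows, , drop = FALSE])
  }
  O
}

# Small expression fixture: exact mixtures of a known spectra matrix.
mixture_fixture <- function(n_genes = 20, n_programs = 3, n_cells = 10,
                            seed = 42) {
  set.seed(seed)
  W <- matrix(rgamma(n_genes * n_programs, 2), n_genes, n_programs,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("P%d", 1:n_programs)))
  U <- matrix(rgamma(n_cells * n_programs, 1), n_cells, n_programs,
              dimnames = list(sprintf("cell%02d", 1:n_cells),
                              colnames(W)))
  E <- W %*% t(U)
  colnames(E) <- rownames(U)
  list(W = W, U = U, E = E)
}
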