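# Cell-level genotyping of one somatic variant from read-level allele calls.
#
# Reads sharing a (cell barcode, UMI) pair derive from one captured molecule;
# a strict-majority consensus over those reads suppresses sequencing error.
# Cells are then classified: any variant-consensus UMI -> mutant; no variant
# UMI but at least one covering UMI -> wild-type; otherwise unassigned.

.ALLELES <- c("variant", "reference", "other")

#' Consensus allele of one UMI
#'
#' Strict-majority vote over the read-level allele calls of a single
#' (cell barcode, UMI) group. When the top allele count is tied, the UMI is
#' discarded rather than assigned: a tied molecule carries no usable evidence
#' and discarding avoids inflating either the mutant or the wild-type class.
#'
#' @param alleles character vector of read-level calls, each one of
#'   `"variant"`, `"reference"`, `"other"`; must be nonempty.
#' @return single string: the majority allele, or `"discarded"` on a tie.
#' @examples
#' umi_consensus(c("variant", "variant", "reference"))  # "variant"
#' umi_consensus(c("variant", "reference"))             # "discarded"
#' @export
umi_consensus <- function(alleles) {
  if (length(alleles) == 0) {
    stop("UMI consensus needs at least one read", call. = FALSE)
  }
  if (!all(alleles %in% .ALLELES)) {
    stop("allele calls must be one of: ", paste(.ALLELES, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(alleles)
  top <- max(tab)
  winners <- names(tab)[tab == top]
  if (length(winners) > 1) "discarded" else winners
}

#' Genotype cells from a UMI read table
#'
#' Applies [umi_consensus()] to every (cell barcode, UMI) group, then
#' classifies each cell barcode:
#' \itemize{
#'   \item \strong{mutant}: at least one variant-consensus UMI;
#'   \item \strong{wild_type}: no variant-consensus UMI but at least one
#'     covering (non-discarded) UMI — `"reference"` and `"other"` consensus
#'     UMIs both span the queried position and count as covering;
#'   \item \strong{unassigned}: no covering UMI (all UMIs tied/discarded).
#' }
#' Discarded UMIs count only toward `n_discarded_umis`.
#'
#' @param umi_reads data.frame with columns `cell_barcode`, `umi`, `allele`
#'   (values in `variant`/`reference`/`other`); one row per read.
#' @return data.frame with one row per distinct cell barcode: `cell_barcode`,
#'   `genotype` (`mutant`/`wild_type`/`unassigned`), `n_variant_umis`,
#'   `n_covering_umis`, `n_discarded_umis`.
#' @export
genotype_cells <- function(umi_reads) {
  if (!is.data.frame(umi_reads)) {
    stop("'umi_reads' must be a data.frame", call. = FALSE)
  }
  need <- c("cell_barcode", "umi", "allele")
  miss <- setdiff(need, names(umi_reads))
  if (length(miss) > 0) {
    stop("UMI read table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bc <- as.character(umi_reads$cell_barcode)
  umi <- as.character(umi_reads$umi)
  allele <- as.character(umi_reads$allele)
  bad <- which(bc == "" | umi == "" | is.na(bc) | is.na(umi) |
                 !(allele %in% .ALLELES))
  if (length(bad) > 0) {
    stop("malformed UMI read table row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (length(bc) == 0) {
    return(data.frame(cell_barcode = character(), genotype = character(),
                      n_variant_umis = integer(), n_covering_umis = integer(),
                      n_discarded_umis = integer(), stringsAsFactors = FALSE))
  }

  key <- paste(bc, umi, sep = "\r")
  cons <- vapply(split(allele, key), umi_consensus, character(1))
  cons_bc <- vapply(strsplit(names(cons), "\r", fixed = TRUE), `[`,
                    character(1), 1L)

  cells <- sort(unique(bc))
  f <- factor(cons_bc, levels = cells)
  n_variant <- as.integer(tapply(cons == "variant", f, sum, default = 0L))
  n_discard <- as.integer(tapply(cons == "discarded", f, sum, default = 0L))
  n_total <- as.integer(tapply(rep(1L, length(cons)), f, sum, default = 0L))
  n_covering <- n_total - n_discard

  genotype <- ifelse(n_variant >= 1L, "mutant",
                     ifelse(n_covering >= 1L, "wild_type", "unassigned"))
  data.frame(cell_barcode = cells, genotype = genotype,
             n_variant_umis = n_variant, n_covering_umis = n_covering,
             n_discarded_umis = n_discard, stringsAsFactors = FALSE)
}

#' Confusion summary of genotype calls against known truth
#'
#' Compares cell-level genotype calls with a ground-truth assignment (for
#' example the generator's sidecar) and reports per-class precision and
#' recall over the barcodes present in both.
#'
#' @param calls data.frame from [genotype_cells()].
#' @param truth data.frame with columns `cell_barcode` and `genotype`
#'   (`mutant`/`wild_type`); truth has no `unassigned` class.
#' @return list with `confusion` (truth x call contingency table), and
#'   per-class `precision` and `recall` named vectors (class absent from the
#'   calls gives NA precision).
#' @export
genotype_recovery_report <- function(calls, truth) {
  shared <- intersect(calls$cell_barcode, truth$cell_barcode)
  if (length(shared) == 0) {
    stop("no overlap between call and truth barcodes", call. = FALSE)
  }
  call_g <- calls$genotype[match(shared, calls$cell_barcode)]
  true_g <- truth$genotype[match(shared, truth$cell_barcode)]
  lev_call <- c("mutant", "wild_type", "unassigned")
  lev_true <- c("mutant", "wild_type")
  conf <- table(truth = factor(true_g, levels = lev_true),
                call = factor(call_g, levels = lev_call))
  precision <- vapply(lev_true, function(cl) {
    called <- sum(conf[, cl])
    if (called == 0) NA_real_ else conf[cl, cl] / called
  }, numeric(1))
  recall <- vapply(lev_true, function(cl) {
    actual <- sum(conf[cl, ])
    if (actual == 0) NA_real_ else conf[cl, cl] / actual
  }, numeric(1))
  list(confusion = conf, precision = precision, recall = recall,
       n_cells = length(shared))
}

#' Extract read-level allele calls at one genomic site from a SAM/BAM file
#'
#' Thin adapter from alignments to the [genotype_cells()] input: for every
#' primary mapped record whose aligned span covers the queried 1-based
#' reference position, reports the read base there as `variant` (matches the
#' alternate base), `reference` (matches the reference base), or `other`
#' (any other base, or a deletion spanning the site). Cell barcode and UMI
#' are taken from the `CB` and `UB` tags; records lacking either tag are
#' skipped.
#'
#' @param sam_file path to a SAM/BAM file.
#' @param site site specification string `"CONTIG:POS:REF>ALT"` with a 1-based
#'   position on the forward reference strand, e.g. `"chr4:105235000:G>A"`.
#' @return data.frame with columns `cell_barcode`, `umi`, `allele`.
#' @export
read_allele_calls_sam <- function(sam_file, site) {
  m <- regmatches(site, regexec(
    "^([^:]+):([0-9]+):([ACGTN])>([ACGTN])$", site))[[1]]
  if (length(m) != 5) {
    stop("site must look like CONTIG:POS:REF>ALT, got: ", site, call. = FALSE)
  }
  contig <- m[2]; pos <- as.integer(m[3]); ref <- m[4]; alt <- m[5]

  bam <- .as_bam(sam_file)
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "cigar", "seq"),
    tag = c("CB", "UB")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$flag)
  out_bc <- character(0); out_umi <- character(0); out_allele <- character(0)
  if (n > 0) {
    cb <- rec$tag$CB
    ub <- rec$tag$UB
    if (is.null(cb)) cb <- rep(NA_character_, n)
    if (is.null(ub)) ub <- rep(NA_character_, n)
    seqs <- as.character(rec$seq)
    for (i in seq_len(n)) {
      fl <- rec$flag[i]
      if (bitwAnd(fl, 0x4L) != 0L || bitwAnd(fl, 0x100L) != 0L ||
          bitwAnd(fl, 0x800L) != 0L) next
      if (is.na(rec$rname[i]) || as.character(rec$rname[i]) != contig) next
      if (is.na(cb[i]) || is.na(ub[i])) next
      base <- .base_at_ref_pos(rec$pos[i], rec$cigar[i], seqs[i], pos)
      if (is.null(base)) next  # span does not cover the site
      allele <- if (is.na(base)) "other"          # deletion over the site
        else if (base == alt) "variant"
        else if (base == ref) "reference"
        else "other"
      out_bc <- c(out_bc, cb[i]); out_umi <- c(out_umi, ub[i])
      out_allele <- c(out_allele, allele)
    }
  }
  data.frame(cell_barcode = out_bc, umi = out_umi, allele = out_allele,
             stringsAsFactors = FALSE)
}

# Walk a CIGAR string to find the query base aligned to reference position
# `target` for a read starting at reference `pos`. Returns NULL when the
# aligned span does not cover the target, NA for a deletion/skip over it,
# otherwise the base character.
.base_at_ref_pos <- function(pos, cigar, seq, target) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0) return(NULL)
  rpos <- pos        # next reference position to consume
  qpos <- 1L         # next query position to consume
  for (op in ops) {
    len <- as.integer(sub("[MIDNSHP=X]$", "", op))
    type <- sub("^[0-9]+", "", op)
    if (type %in% c("M", "=", "X")) {
      if (target >= rpos && target < rpos + len) {
        return(substr(seq, qpos + (target - rpos), qpos + (target - rpos)))
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (type %in% c("D", "N")) {
      if (target >= rpos && target < rpos + len) {
        return(if (type == "D") NA_character_ else NULL)
      }
      rpos <- rpos + len
    } else if (type %in% c("I", "S")) {
      qpos <- qpos + len
    }
    # H and P consume nothing
  }
  NULL  # aligned span ended before the target
}
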