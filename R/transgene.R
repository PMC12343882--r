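#' Poisson power to detect an integrated transgene in bulk WGS
#'
#' Closed-form power of observing at least one sequencing read (pair) mapping
#' to the uniquely mappable region of an integrated construct, under a Poisson
#' model of read depth. The expected number of construct-mapped read pairs is
#' \deqn{\lambda_{CAR} = \lambda_{autosomal} \cdot L \cdot r_{CAR} \cdot \rho}
#' and the detection power is \eqn{P(n_{read} > 0) = 1 - e^{-\lambda_{CAR}}}.
#'
#' @param lambda_autosomal read pairs per base observed in autosomal regions
#'   (e.g. 0.3 for a ~60x paired-end genome).
#' @param construct_length length in bases of the distinctly mappable construct
#'   region (e.g. 743 for the axi-cel scFv).
#' @param copy_ratio copy ratio of the construct relative to autosomes; 1/2 for
#'   a single heterozygous-equivalent integration event.
#' @param cell_fraction fraction of cells bearing an integrated construct, in
#'   \[0, 1\]. Values above 1 are rejected, not clamped.
#' @return detection power, a probability in \[0, 1\]. Nondecreasing in every
#'   parameter; 0 when `cell_fraction` or `construct_length` is 0.
#' @examples
#' detection_power(0.3, 743, 0.5, 0.034)  # ~0.977
#' @seealso [min_detectable_fraction()] for the algebraic inverse,
#'   [count_construct_reads()] for the empirical counterpart.
#' @export
detection_power <- function(lambda_autosomal, construct_length, copy_ratio,
                            cell_fraction) {
  .assert_scalar_number(lambda_autosomal, "lambda_autosomal", lower = 0)
  .assert_scalar_number(construct_length, "construct_length", lower = 0)
  .assert_scalar_number(copy_ratio, "copy_ratio", lower = 0)
  .assert_scalar_number(cell_fraction, "cell_fraction", lower = 0, upper = 1)
  lambda_car <- lambda_autosomal * construct_length * copy_ratio * cell_fraction
  1 - exp(-lambda_car)
}

#' Smallest construct-bearing cell fraction detectable at a target power
#'
#' Inverts the Poisson detection-power model:
#' \eqn{\rho^\ast = -\log(1 - p) / (\lambda_{autosomal} L r_{CAR})}, so that
#' `detection_power()` evaluated at the returned fraction equals `target_power`.
#'
#' @inheritParams detection_power
#' @param target_power required detection probability, strictly in (0, 1).
#' @return cell fraction at which the target power is attained.
#' @examples
#' min_detectable_fraction(0.3, 743, 0.5, target_power = 0.95)  # ~0.0269
#' @export
min_detectable_fraction <- function(lambda_autosomal, construct_length,
                                    copy_ratio, target_power) {
  .assert_scalar_number(lambda_autosomal, "lambda_autosomal", lower = 0)
  .assert_scalar_number(construct_length, "construct_length", lower = 0)
  .assert_scalar_number(copy_ratio, "copy_ratio", lower = 0)
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      !is.finite(target_power) || target_power <= 0 || target_power >= 1) {
    stop("'target_power' must lie strictly between 0 and 1", call. = FALSE)
  }
  denom <- lambda_autosomal * construct_length * copy_ratio
  if (denom <= 0) {
    stop("lambda_autosomal * construct_length * copy_ratio must be positive",
         call. = FALSE)
  }
  -log(1 - target_power) / denom
}

#' Count high-confidence alignments to construct contigs in a SAM/BAM file
#'
#' Scans alignment records and counts primary, mapped records whose reference
#' name is one of the construct contigs and whose mapping quality meets the
#' threshold. Secondary (0x100) and supplementary (0x800) alignments and
#' unmapped records are excluded: the question is how many reads received a
#' confident primary placement on the construct. The distinct read-pair count
#' (unique query names among passing records) is reported alongside the read
#' count because depth models are usually parameterized in read pairs per base
#' while the filter operates on individual records.
#'
#' @param sam_file path to a plain-text SAM file (or BAM; anything
#'   [Rsamtools::asBam()]/[Rsamtools::scanBam()] accepts). The header must
#'   declare every construct contig.
#' @param construct_contigs character vector of construct contig names.
#' @param mapq_threshold minimum mapping quality (default 30, the conventional
#'   high-confidence cutoff).
#' @return object of class `transgene_detection`, a list with
#'   `n_construct_reads`, `n_construct_pairs`, `mapq_threshold`,
#'   `construct_contig_names`, and `n_records_scanned`.
#' @export
count_construct_reads <- function(sam_file, construct_contigs,
                                  mapq_threshold = 30) {
  if (!file.exists(sam_file)) {
    stop("alignment file not found: ", sam_file, call. = FALSE)
  }
  if (!is.character(construct_contigs) || length(construct_contigs) == 0) {
    stop("'construct_contigs' must be a nonempty character vector",
         call. = FALSE)
  }
  .assert_scalar_number(mapq_threshold, "mapq_threshold", lower = 0)

  bam <- .as_bam(sam_file)
  header_contigs <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  missing <- setdiff(construct_contigs, header_contigs)
  if (length(missing) > 0) {
    stop("construct contig(s) absent from SAM header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "mapq")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- rec$flag
  keep <- !is.na(rec$rname) &
    as.character(rec$rname) %in% construct_contigs &
    !is.na(rec$mapq) & rec$mapq >= mapq_threshold &
    bitwAnd(flag, 0x4L) == 0L &    # mapped
    bitwAnd(flag, 0x100L) == 0L &  # not secondary
    bitwAnd(flag, 0x800L) == 0L    # not supplementary

  structure(
    list(
      n_construct_reads = sum(keep),
      n_construct_pairs = length(unique(rec$qname[keep])),
      mapq_threshold = mapq_threshold,
      construct_contig_names = construct_contigs,
      n_records_scanned = length(flag)
    ),
    class = "transgene_detection"
  )
}

#' @export
print.transgene_detection <- function(x, ...) {
  cat("Construct alignment counts (MAPQ >=", x$mapq_threshold, ")\n")
  cat("  contigs:", paste(x$construct_contig_names, collapse = ", "), "\n")
  cat("  reads:  ", x$n_construct_reads, "\n")
  cat("  pairs:  ", x$n_construct_pairs, "\n")
  invisible(x)
}

# Convert plain SAM to a temporary BAM when needed; pass BAM through untouched.
.as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(path)
  }
  dest <- tempfile(fileext = "")
  suppressMessages(
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  )
}
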