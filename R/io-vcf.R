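#' Read a multi-sample VCF into a CohortCalls object
#'
#' Positions are converted to 0-based on read; multiallelic records are
#' preserved as-is (decomposition happens in [tallyAlleles()]); missing
#' genotypes are kept as missing, never imputed. The VCF must carry a GT
#' FORMAT field.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @param samples optional character vector restricting (and ordering) the
#'   samples to load; unknown names are an error.
#' @return A [CohortCalls-class].
#' @export
readVcfCohort <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0L && nrow(v@fix) > 0L)
    stop("VCF has no genotype columns")
  fmt <- v@gt[, "FORMAT"]
  if (nrow(v@fix) > 0L && !all(vapply(strsplit(fmt, ":"), function(f)
    "GT" %in% f, logical(1))))
    stop("GT field absent from FORMAT")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, ncol = ncol(v@gt) - 1L,
                 dimnames = list(NULL, colnames(v@gt)[-1L]))
  gt[is.na(gt)] <- "./."
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing))
      stop("sample(s) not found: ", paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  variants <- data.frame(
    chrom = as.character(v@fix[, "CHROM"]),
    pos   = as.integer(v@fix[, "POS"]) - 1L,
    ref   = as.character(v@fix[, "REF"]),
    alt   = as.character(v@fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  CohortCalls(variants, gt)
}

#' Write a CohortCalls object as a VCF 4.2 file
#'
#' Emits GT-only records with 1-based positions and contig header lines taken
#' from \code{lengths} (or omitted when \code{lengths} is NULL).
#'
#' @param calls a [CohortCalls-class].
#' @param path output path.
#' @param lengths optional named integer vector of contig lengths for the
#'   header.
#' @return \code{path}, invisibly.
#' @export
writeCohortVcf <- function(calls, path, lengths = NULL) {
  stopifnot(is(calls, "CohortCalls"))
  v <- variantTable(calls)
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(lengths),
                          as.integer(lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sampleNames(calls)),
                      collapse = "\t"))
  gtm <- genotypes(calls)
  body <- if (nrow(v)) {
    fixed <- paste(v$chrom, v$pos + 1L, ".", v$ref, v$alt, ".", ".", ".",
                   "GT", sep = "\t")
    if (ncol(gtm))
      paste(fixed, apply(gtm, 1L, paste, collapse = "\t"), sep = "\t")
    else fixed
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
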