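#' Genome assembly model
#'
#' A genome assembly is the ordered set of chromosome names and lengths that
#' every interval, coverage track and window grid in the package refers to.
#' It is stored as a plain S3 object and converted to a
#' [GenomeInfoDb::Seqinfo] when building `GRanges`.
#'
#' @param chrom_names Character vector of unique chromosome identifiers.
#' @param chrom_lengths Integer-like vector of chromosome lengths in bp,
#'   parallel to `chrom_names`; all must be positive.
#'
#' @return An object of class `genome_assembly` with elements `chrom_names`,
#'   `chrom_lengths` (named) and `total_size` (sum of lengths, as double to
#'   avoid integer overflow on large genomes).
#' @examples
#' asm <- genome_assembly(c("chr1", "chr2"), c(2e6, 1e6))
#' total_size(asm)
#' @export
genome_assembly <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be positive and finite")
  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = setNames(chrom_lengths, chrom_names),
      total_size = sum(chrom_lengths)
    ),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d chromosomes, %s bp total\n",
              length(x$chrom_names), format(x$total_size, big.mark = ",")))
  invisible(x)
}

#' Total genome size in bp
#' @param assembly A [genome_assembly].
#' @return Numeric scalar, the sum of chromosome lengths.
#' @export
total_size <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  assembly$total_size
}

#' Convert an assembly to a Seqinfo
#' @param assembly A [genome_assembly].
#' @return A [GenomeInfoDb::Seqinfo] with the assembly's names and lengths.
#' @export
as_seqinfo <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  Seqinfo(seqnames = assembly$chrom_names,
          seqlengths = as.integer(assembly$chrom_lengths))
}

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @return A [genome_assembly].
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "size"), colClasses = list(character = 1))
  genome_assembly(dt$chrom, dt$size)
}

#' Write a UCSC chrom.sizes file
#' @param assembly A [genome_assembly].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(assembly, path) {
  dt <- data.table(chrom = assembly$chrom_names,
                   size = format(assembly$chrom_lengths, scientific = FALSE,
                                 trim = TRUE))
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
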