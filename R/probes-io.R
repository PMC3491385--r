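#' Construct a ProbeSet from coordinate vectors
#'
#' Coordinates are 0-based half-open, the convention used by all text input
#' and output in this package.  Probes are sorted by (chrom, start, end) on
#' construction.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open probe intervals (`start < end`).
#' @param ratio numeric log2 MeDIP/input ratio per probe; must be finite.
#' @param replicate,stage single strings labelling the replicate and sample.
#' @return a [ProbeSet-class] object.
#' @examples
#' ps <- ProbeSet("chr1", c(100, 0), c(150, 50), c(0.2, -0.1))
#' probeRatios(ps)
#' @export
ProbeSet <- function(chrom, start, end, ratio, replicate = "rep1",
                     stage = "unknown") {
  chrom <- rep_len(as.character(chrom), length(start))
  stopifnot(length(start) == length(end), length(end) == length(ratio))
  if (any(end <= start))
    stop("probe intervals must satisfy start < end")
  gr <- GRanges(chrom, IRanges(start = start + 1L, end = end),
                ratio = as.numeric(ratio))
  o <- order(as.character(seqnames(gr)), GenomicRanges::start(gr),
             GenomicRanges::end(gr))
  new("ProbeSet", probes = gr[o], replicate = as.character(replicate),
      stage = as.character(stage))
}

#' Accessors for ProbeSet objects
#'
#' `probeRanges()` returns the underlying `GRanges`; `probeRatios()` the
#' log2 ratios; `probeMidpoints()` the 0-based genomic midpoints
#' (`(start0 + end0) / 2`, possibly half-integral); `replicateId()` and
#' `stageLabel()` the labels.
#'
#' @param x a [ProbeSet-class].
#' @name ProbeSet-accessors
#' @aliases probeRanges probeRatios replicateId stageLabel probeMidpoints
NULL

#' @rdname ProbeSet-accessors
#' @export
setMethod("probeRanges", "ProbeSet", function(x) x@probes)

#' @rdname ProbeSet-accessors
#' @export
setMethod("probeRatios", "ProbeSet", function(x) mcols(x@probes)$ratio)

#' @rdname ProbeSet-accessors
#' @export
setMethod("replicateId", "ProbeSet", function(x) x@replicate)

#' @rdname ProbeSet-accessors
#' @export
setMethod("stageLabel", "ProbeSet", function(x) x@stage)

#' @rdname ProbeSet-accessors
#' @export
setMethod("probeMidpoints", "ProbeSet", function(x)
  (start(x@probes) - 1 + end(x@probes)) / 2)

#' @export
setMethod("length", "ProbeSet", function(x) length(x@probes))

setMethod("show", "ProbeSet", function(object) {
  cat(sprintf("ProbeSet: %d probes | replicate %s | stage %s\n",
              length(object@probes), object@replicate, object@stage))
  if (length(object@probes)) {
    r <- mcols(object@probes)$ratio
    cat(sprintf("  %d seqnames | ratio range [%.3f, %.3f], median %.4f\n",
                length(seqlevelsInUse(object@probes)), min(r), max(r),
                median(r)))
  }
})

#' Read a probe table into a ProbeSet
#'
#' The native format is a tab-separated file with a header and columns
#' `chrom`, `start`, `end`, `ratio` (0-based half-open coordinates).  A
#' NimbleScan-style GFF is also accepted; its `score` field is taken as the
#' log2 ratio (GFF coordinates are 1-based closed and are converted).
#' Malformed rows (non-numeric coordinates or `end <= start`) are reported
#' with their line numbers.  Unsorted input is sorted with a warning.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"gff"`.
#' @param replicate,stage labels attached to the resulting [ProbeSet-class].
#' @return a [ProbeSet-class].
#' @seealso [writeProbeTable()]
#' @export
readProbeTable <- function(path, format = c("tsv", "gff"),
                           replicate = "rep1", stage = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gff") {
    gr <- rtracklayer::import(path)
    if (is.null(gr$score)) stop("GFF input lacks a score field to use as ratio")
    return(ProbeSet(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                    as.numeric(gr$score), replicate, stage))
  }
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "ratio")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("probe table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  start <- suppressWarnings(as.numeric(tab$start))
  end <- suppressWarnings(as.numeric(tab$end))
  ratio <- suppressWarnings(as.numeric(tab$ratio))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(ratio) |
                 end <= start)
  if (length(bad))
    stop("malformed probe rows at line(s) ",
         paste(bad + 1L, collapse = ", "),
         " (line numbers include the header)")
  o <- order(tab$chrom, start, end)
  if (!identical(o, seq_len(nrow(tab))))
    warning("probe table was not coordinate-sorted; sorting")
  ProbeSet(tab$chrom, start, end, ratio, replicate, stage)
}

#' Write a ProbeSet as a probe table
#'
#' Emits the native tab-separated format (`chrom`, `start`, `end`, `ratio`,
#' 0-based half-open) that [readProbeTable()] reads back identically.
#'
#' @param ps a [ProbeSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProbeTable <- function(ps, path) {
  stopifnot(is(ps, "ProbeSet"))
  gr <- probeRanges(ps)
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr), ratio = mcols(gr)$ratio)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Promoter/TSS annotation
#'
#' Builds the promoter annotation used throughout the package: one record
#' per gene with its transcription start site (TSS) and strand.  Internally
#' a `GRanges` of width-1 ranges anchored at the TSS, with metadata columns
#' `gene_id` and `tss` (the 0-based TSS coordinate).
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param tss 0-based TSS positions.
#' @param strand `"+"` or `"-"` per gene.
#' @return a `GRanges` promoter annotation.
#' @export
promoterAnnotation <- function(gene_id, chrom, tss, strand) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene")
  gr <- GRanges(chrom, IRanges(start = tss + 1L, width = 1L), strand = strand,
                gene_id = gene_id, tss = as.numeric(tss))
  names(gr) <- gene_id
  gr
}

#' Read a promoter annotation from TSV or BED
#'
#' TSV format: header with columns `gene_id`, `chrom`, `tss`, `strand`
#' (0-based TSS).  BED6 format: the TSS is taken strand-aware as
#' `chromStart` for `+` genes and `chromEnd - 1` for `-` genes, and the
#' `name` field is the gene id.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return a `GRanges` promoter annotation (see [promoterAnnotation()]).
#' @export
readPromoterTable <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 6) stop("BED promoter input needs 6 columns")
    tss <- ifelse(bed[[6]] == "+", bed[[2]], bed[[3]] - 1L)
    return(promoterAnnotation(bed[[4]], bed[[1]], tss, bed[[6]]))
  }
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(tab)))
    stop("promoter table format error: need columns ",
         paste(need, collapse = ", "))
  promoterAnnotation(tab$gene_id, tab$chrom, tab$tss, tab$strand)
}
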