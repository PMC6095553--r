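# Feature annotations are tidy tibbles with one row per feature:
# columns `type` (gene/exon/intron/tRNA/rRNA), `start`, `end` (1-based
# inclusive), `strand` ("+"/"-"), `gene` (symbol) and optionally
# `part` (fragment rank of trans-spliced genes) and `trans_spliced`.
# GFF3 reading/writing goes through rtracklayer.

#' Read a GFF3-like annotation into a tidy tibble
#'
#' @param path Path to a GFF3 file. Feature symbols are taken from the
#'   `gene` attribute, falling back to `Name`/`ID`.
#' @return Annotation tibble (see package conventions above).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(S4Vectors::mcols(gr))
  gene <- md[["gene"]]
  if (is.null(gene)) gene <- md[["Name"]]
  if (is.null(gene)) gene <- md[["ID"]]
  out <- tibble(
    type = as.character(md$type),
    start = as.integer(BiocGenerics::start(gr)),
    end = as.integer(BiocGenerics::end(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    gene = as.character(gene))
  if (!is.null(md[["part"]])) out$part <- as.integer(md[["part"]])
  if (!is.null(md[["trans_spliced"]])) {
    out$trans_spliced <- as.logical(md[["trans_spliced"]])
  }
  out
}

#' Write an annotation tibble as GFF3
#'
#' @param annotation Annotation tibble.
#' @param path Output path.
#' @param seqid Sequence identifier for all records.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, seqid = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = annotation$start,
                              end = annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$type <- annotation$type
  S4Vectors::mcols(gr)$gene <- annotation$gene
  S4Vectors::mcols(gr)$source <- "mitomosaic"
  if (!is.null(annotation[["part"]])) S4Vectors::mcols(gr)$part <- annotation[["part"]]
  if (!is.null(annotation[["trans_spliced"]])) {
    S4Vectors::mcols(gr)$trans_spliced <- annotation[["trans_spliced"]]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# interval union helpers (1-based inclusive tibble(start, end) <-> IRanges)
as_iranges <- function(x) {
  IRanges::IRanges(start = x$start, end = x$end)
}

reduce_intervals <- function(x) {
  if (!nrow(x)) return(tibble(start = integer(), end = integer()))
  r <- IRanges::reduce(as_iranges(x))
  tibble(start = BiocGenerics::start(r), end = BiocGenerics::end(r))
}

intervals_width <- function(x) {
  r <- reduce_intervals(x)
  if (!nrow(r)) 0L else sum(r$end - r$start + 1L)
}

# occupied space of all annotated genic features (genes incl. introns,
# plus stand-alone tRNA/rRNA records)
genic_intervals <- function(annotation) {
  g <- filter(annotation, .data$type %in% c("gene", "tRNA", "rRNA"))
  reduce_intervals(tibble(start = g$start, end = g$end))
}
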