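#' Build a feature annotation from gene and exon tables
#'
#' Assembles gene models into an annotation object that partitions every
#' genomic position into exactly one of \{exon, intron, intergenic\}.
#' Overlapping genes are resolved with the precedence exon > intron >
#' intergenic: a position exonic in any gene is exonic, a non-exonic
#' position inside any gene span is intronic.
#'
#' @param genes Tibble with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end` (1-based inclusive).
#' @param exons Tibble with columns `gene_id`, `contig`, `start`, `end`.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return An object of class `feature_annotation`: a list with `genes`,
#'   `exons`, `contig_lengths` and reduced [GenomicRanges::GRanges] indexes
#'   (`exon_gr`, `intron_gr`, `genic_gr`, `intergenic_gr`).
#' @export
feature_annotation <- function(genes, exons, contig_lengths) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  stopifnot(all(c("gene_id", "contig", "strand", "start", "end") %in% names(genes)),
            all(c("gene_id", "contig", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene ids in `genes`")
  if (nrow(genes) && any(genes$end <= genes$start - 1L)) abort("gene span end must be >= start")
  unknown <- setdiff(unique(c(genes$contig, exons$contig)), names(contig_lengths))
  if (length(unknown)) abort(sprintf("features on contig(s) absent from genome: %s",
                                     paste(unknown, collapse = ", ")))
  if (nrow(genes) && any(genes$start < 1 | genes$end > contig_lengths[genes$contig])) {
    abort("gene coordinates out of contig bounds")
  }
  if (nrow(exons)) {
    if (any(exons$start < 1 | exons$end > contig_lengths[exons$contig]))
      abort("exon coordinates out of contig bounds")
    ge <- left_join(exons, genes, by = c("gene_id", "contig"), suffix = c("", ".gene"))
    if (anyNA(ge$start.gene)) {
      abort(sprintf("exon with unresolvable gene parent: %s",
                    paste(unique(exons$gene_id[is.na(ge$start.gene)]), collapse = ", ")))
    }
    if (any(ge$start < ge$start.gene | ge$end > ge$end.gene)) {
      abort("exon outside its gene span")
    }
    # exons of one gene must not overlap each other after sorting
    ov <- exons |>
      arrange(.data$gene_id, .data$start) |>
      group_by(.data$gene_id) |>
      summarise(bad = any(.data$start[-1] <= head(.data$end, -1)), .groups = "drop")
    if (any(ov$bad)) abort(sprintf("overlapping exons within gene(s): %s",
                                   paste(ov$gene_id[ov$bad], collapse = ", ")))
  }
  seqinfo <- GenomeInfoDb::Seqinfo(seqnames = names(contig_lengths),
                                   seqlengths = unname(as.integer(contig_lengths)))
  gr_of <- function(df) {
    if (nrow(df) == 0) return(GenomicRanges::GRanges(seqinfo = seqinfo))
    GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end), seqinfo = seqinfo)
  }
  genic_gr <- GenomicRanges::reduce(gr_of(genes))
  exon_gr <- GenomicRanges::reduce(gr_of(exons))
  intron_gr <- GenomicRanges::setdiff(genic_gr, exon_gr)
  intergenic_gr <- GenomicRanges::gaps(genic_gr)
  intergenic_gr <- intergenic_gr[S4Vectors::decode(GenomicRanges::strand(intergenic_gr)) == "*"]
  structure(
    list(genes = genes, exons = exons,
         contig_lengths = setNames(as.integer(contig_lengths), names(contig_lengths)),
         exon_gr = exon_gr, intron_gr = intron_gr,
         genic_gr = genic_gr, intergenic_gr = intergenic_gr),
    class = "feature_annotation"
  )
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat(sprintf("<feature_annotation> %d gene(s), %d exon row(s) on %d contig(s)\n",
              nrow(x$genes), nrow(x$exons), length(x$contig_lengths)))
  cat(sprintf("  exon %d bp | intron %d bp | intergenic %d bp\n",
              sum(IRanges::width(x$exon_gr)), sum(IRanges::width(x$intron_gr)),
              sum(IRanges::width(x$intergenic_gr))))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` and `exon` features via [rtracklayer::import()], resolves
#' exon `Parent` links to gene `ID`s and validates coordinates against the
#' supplied genome. Unsorted input is tolerated (sorted internally).
#'
#' @param path Path to a GFF3 file.
#' @param genome Named character vector of sequences (for bounds checks).
#' @return A [feature_annotation].
#' @export
read_gff3 <- function(path, genome) {
  check_genome(genome)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  gtab <- function(sel) {
    tibble(contig = as.character(GenomicRanges::seqnames(gr[sel])),
           start = GenomicRanges::start(gr[sel]),
           end = GenomicRanges::end(gr[sel]),
           strand = as.character(GenomicRanges::strand(gr[sel])))
  }
  gsel <- typ == "gene"
  genes <- gtab(gsel) |> mutate(gene_id = as.character(gr$ID[gsel]))
  if (anyNA(genes$gene_id)) abort(sprintf("GFF3 %s: gene feature without ID attribute", path))
  esel <- typ == "exon"
  parents <- gr$Parent[esel]
  if (any(lengths(parents) != 1L)) abort(sprintf("GFF3 %s: exon with %s Parent attribute",
                                                 path, ifelse(any(lengths(parents) == 0), "missing", "multiple")))
  exons <- gtab(esel) |> mutate(gene_id = as.character(unlist(parents))) |> select(-"strand")
  unresolved <- setdiff(exons$gene_id, genes$gene_id)
  if (length(unresolved)) abort(sprintf("GFF3 %s: exon Parent(s) not resolvable to a gene: %s",
                                        path, paste(unresolved, collapse = ", ")))
  feature_annotation(genes = select(genes, "gene_id", "contig", "strand", "start", "end"),
                     exons = select(exons, "gene_id", "contig", "start", "end"),
                     contig_lengths = contig_lengths(genome))
}

#' Write an annotation to GFF3
#'
#' Emits one `gene` line (with `ID`) and one `exon` line (with `Parent`) per
#' record, sorted by contig and start.
#'
#' @param annotation A [feature_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "feature_annotation"))
  g <- annotation$genes |>
    mutate(type = "gene", attr = paste0("ID=", .data$gene_id))
  e <- annotation$exons |>
    left_join(select(annotation$genes, "gene_id", "strand"), by = "gene_id") |>
    mutate(type = "exon", attr = paste0("Parent=", .data$gene_id))
  rows <- bind_rows(g, e) |>
    arrange(.data$contig, .data$start, dplyr::desc(.data$type))
  lines <- sprintf("%s\tbsmethyl\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   rows$contig, rows$type, rows$start, rows$end, rows$strand, rows$attr)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Classify genomic positions into exon / intron / intergenic
#'
#' Vectorised over `contig`/`pos`. Precedence for overlapping genes is
#' exon > intron > intergenic.
#'
#' @param annotation A [feature_annotation].
#' @param contig Character vector of contig ids.
#' @param pos Integer vector of 1-based positions.
#' @return Character vector in \{"exon","intron","intergenic"\}.
#' @export
classify_position <- function(annotation, contig, pos) {
  stopifnot(inherits(annotation, "feature_annotation"))
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n); pos <- rep_len(pos, n)
  lens <- annotation$contig_lengths
  unknown <- setdiff(unique(contig), names(lens))
  if (length(unknown)) abort(sprintf("position(s) on contig(s) absent from annotation: %s",
                                     paste(unknown, collapse = ", ")))
  if (any(pos < 1 | pos > lens[contig])) abort("position out of contig range")
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  out <- rep("intergenic", n)
  out[IRanges::overlapsAny(q, annotation$genic_gr)] <- "intron"
  out[IRanges::overlapsAny(q, annotation$exon_gr)] <- "exon"
  out
}

#' Regions of one feature class as a tibble
#'
#' @param annotation A [feature_annotation].
#' @param class One of "genome", "genic", "intergenic", "exon", "intron".
#' @return Tibble with columns `contig`, `start`, `end` (1-based inclusive);
#'   zero rows when the class is empty.
#' @export
feature_regions <- function(annotation,
                            class = c("genome", "genic", "intergenic", "exon", "intron")) {
  stopifnot(inherits(annotation, "feature_annotation"))
  class <- match.arg(class)
  if (class == "genome") {
    return(tibble(contig = names(annotation$contig_lengths),
                  start = 1L, end = unname(annotation$contig_lengths)))
  }
  gr <- annotation[[paste0(class, "_gr")]]
  tibble(contig = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}
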