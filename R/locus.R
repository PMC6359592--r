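# Restriction-fragment model of a locus: in silico digestion, TSS-relative
# coordinates, fragment lookup, and BED/TSV interchange.
#
# Coordinates are 0-based half-open internally (BED convention on disk);
# 1-based coordinates appear only in human-readable reports.

#' In silico restriction digestion of a sequence
#'
#' Scans a nucleotide sequence for a restriction-enzyme recognition motif and
#' returns the resulting fragments as 0-based half-open intervals that tile
#' the sequence exactly. `N` bases never match the motif (conservative
#' digestion). The cut position within the motif is configurable; the default
#' cuts at the motif start, which preserves fragment identity (sub-motif
#' resolution, e.g. HindIII's A^AGCTT overhang at offset 1, matters only for
#' sticky-end chemistry, not for fragment mapping).
#'
#' @param sequence A single nucleotide string (or [Biostrings::DNAString]),
#'   characters A/C/G/T/N (case-insensitive).
#' @param motif Recognition-site string, A/C/G/T only, length >= 4.
#'   Default `"AAGCTT"` (HindIII).
#' @param cut_offset Integer offset of the cut within the motif (0 =
#'   motif start).
#' @param chrom Contig name recorded on the fragments.
#' @return A `data.frame` with columns `fragment_id` (1-based ordinal along
#'   the locus), `chrom`, `start`, `end` (0-based half-open), `length`.
#'   `k` interior cut positions yield `k + 1` fragments.
#' @examples
#' digest_sequence("CCAAGCTTGGAAGCTTCC")            # 3 fragments
#' digest_sequence("ACGTACGT")                      # no site: 1 fragment
#' @export
digest_sequence <- function(sequence, motif = "AAGCTT", cut_offset = 0L,
                            chrom = "locus") {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("`sequence` must be a single non-empty nucleotide string")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("`sequence` contains characters other than A/C/G/T/N")
  motif <- toupper(motif)
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 4L)
    stop("`motif` must be a single string of length >= 4")
  if (grepl("[^ACGT]", motif))
    stop("`motif` must contain only A/C/G/T")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset >= nchar(motif))
    stop("`cut_offset` must lie within the motif")

  len <- nchar(sequence)
  # fixed = TRUE: N in the subject never matches the motif
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence),
                                   fixed = TRUE)
  cuts <- BiocGenerics::start(hits) - 1L + cut_offset   # 0-based cut positions
  cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
  bounds <- c(0L, cuts, len)
  data.frame(
    fragment_id = seq_len(length(bounds) - 1L),
    chrom = chrom,
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    length = diff(bounds),
    stringsAsFactors = FALSE
  )
}

#' Assign TSS-relative distances to fragments
#'
#' Adds a `tss_distance_kb` column: signed kilobases from the fragment
#' midpoint to the transcription start site, with the sign flipped for genes
#' on the minus strand so that negative always means upstream of the gene.
#'
#' @param fragments Fragment table from [digest_sequence()].
#' @param tss 0-based TSS coordinate; must fall within the locus span.
#' @param gene_strand `"+"` or `"-"`.
#' @return `fragments` with `tss_distance_kb` filled.
#' @export
assign_tss_distances <- function(fragments, tss, gene_strand = "+") {
  stopifnot(is.data.frame(fragments), nrow(fragments) > 0L)
  if (!gene_strand %in% c("+", "-"))
    stop("`gene_strand` must be '+' or '-'")
  span <- c(min(fragments$start), max(fragments$end))
  if (tss < span[1] || tss >= span[2])
    stop("`tss` (", tss, ") lies outside the locus span [",
         span[1], ", ", span[2], ")")
  mid <- (fragments$start + fragments$end) / 2
  d <- (mid - tss) / 1000
  fragments$tss_distance_kb <- if (gene_strand == "-") -d else d
  fragments
}

#' Build a locus model
#'
#' Digests a locus sequence, assigns TSS-relative distances, and identifies
#' the bait fragment (the promoter fragment containing the TSS). Annotation
#' intervals (e.g. externally predicted enhancer candidates) are carried as
#' static metadata.
#'
#' @param sequence Locus nucleotide string (or a fragment table already
#'   produced by [digest_sequence()] via `fragments =`).
#' @param tss 0-based TSS coordinate within the locus.
#' @param gene_strand `"+"` or `"-"` (default `"+"`).
#' @param motif,cut_offset,chrom Passed to [digest_sequence()].
#' @param fragments Optional pre-computed fragment table (alternative to
#'   `sequence`).
#' @param annotations Optional `data.frame` with columns `name`, `start`,
#'   `end` (0-based half-open) of annotation intervals.
#' @return An object of class `locus_model`: a list with elements
#'   `fragments` (including `tss_distance_kb`), `tss`, `gene_strand`,
#'   `bait_fragment_id`, `annotations`.
#' @export
locus_model <- function(sequence = NULL, tss, gene_strand = "+",
                        motif = "AAGCTT", cut_offset = 0L, chrom = "locus",
                        fragments = NULL, annotations = NULL) {
  if (is.null(fragments)) {
    if (is.null(sequence)) stop("supply either `sequence` or `fragments`")
    fragments <- digest_sequence(sequence, motif, cut_offset, chrom)
  }
  fragments <- assign_tss_distances(fragments, tss, gene_strand)
  bait <- fragments$fragment_id[fragments$start <= tss & tss < fragments$end]
  out <- structure(
    list(fragments = fragments,
         tss = tss,
         gene_strand = gene_strand,
         bait_fragment_id = bait,
         annotations = annotations),
    class = "locus_model"
  )
  out
}

#' @export
print.locus_model <- function(x, ...) {
  fr <- x$fragments
  cat("locus_model: ", nrow(fr), " ", fr$chrom[1], " fragments spanning [",
      min(fr$start), ", ", max(fr$end), ")\n", sep = "")
  cat("  TSS at ", x$tss, " (gene strand ", x$gene_strand,
      "), bait fragment ", x$bait_fragment_id, "\n", sep = "")
  if (!is.null(x$annotations))
    cat("  ", nrow(x$annotations), " annotation interval(s)\n", sep = "")
  invisible(x)
}

#' Locate the fragment containing a position
#'
#' @param locus A [locus_model()].
#' @param position 0-based coordinate within the locus span.
#' @return The `fragment_id` of the unique fragment with
#'   `start <= position < end`.
#' @export
locate_fragment <- function(locus, position) {
  fr <- locus$fragments
  if (position < min(fr$start) || position >= max(fr$end))
    stop("position ", position, " is outside the locus span")
  fr$fragment_id[findInterval(position, fr$start)]
}

#' Read a locus sequence from FASTA
#'
#' @param path Path to a single-record FASTA file.
#' @return A character string (the sequence).
#' @export
read_locus_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stop("expected exactly 1 FASTA record in '", path, "', found ",
         length(seqs))
  as.character(seqs[[1L]])
}

#' Write a locus sequence to FASTA
#'
#' @param sequence Nucleotide string.
#' @param path Output path.
#' @param name Record name.
#' @export
write_locus_fasta <- function(sequence, path, name = "locus") {
  x <- Biostrings::DNAStringSet(sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

fragments_to_granges <- function(fragments, strand = "+",
                                 name = fragments$fragment_id, score = 0L) {
  gr <- GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = fragments$start + 1L,
                              end = fragments$end),
    strand = strand
  )
  gr$name <- as.character(name)
  gr$score <- score
  gr
}

#' Write fragments (or any interval table) to BED6
#'
#' Fragment intervals are written 0-based half-open as BED requires, with
#' `name` = fragment id, `score` = 0 and `strand` = the gene strand.
#'
#' @param fragments Fragment table with `chrom`, `start`, `end` and
#'   optionally `fragment_id`/`name` columns.
#' @param path Output path.
#' @param strand Strand recorded on every interval.
#' @export
write_fragments_bed <- function(fragments, path, strand = "+") {
  nm <- if (!is.null(fragments$fragment_id)) fragments$fragment_id
        else if (!is.null(fragments$name)) fragments$name
        else seq_len(nrow(fragments))
  gr <- fragments_to_granges(fragments, strand = strand, name = nm)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file back into a fragment-style interval table
#'
#' @param path BED file path.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `strand`.
#' @export
read_fragments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write the fragment table as TSV
#'
#' Columns: `fragment_id`, `chrom`, `start`, `end`, `length`,
#' `tss_distance_kb`.
#'
#' @param locus A [locus_model()] (or a fragment table).
#' @param path Output path.
#' @export
write_fragment_table <- function(locus, path) {
  fr <- if (inherits(locus, "locus_model")) locus$fragments else locus
  utils::write.table(fr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
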