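# Read-level model: spliced alignments -> exon chains with strand-aware
# soft-clip and polyA annotations.
#
# A read table (tibble) has one row per primary mapped alignment with columns:
#   read_id, sample_id, strand ("+"/"-"), exons (list of 2-column integer
#   matrices [start,end], 1-based inclusive, ascending), n_exons, length,
#   tss, tts, clip5, clip3, polya_qc, polya_length, polya_usable.
# tss/tts are in transcript orientation: for "+" reads tss = start of the
# first exon; for "-" reads tss = end of the last exon, and symmetrically
# for tts.

#' Parse spliced long-read alignments into a read table
#'
#' Reads a SAM or BAM file of spliced alignments (e.g. minimap2 splice-preset
#' output) and extracts, for every primary mapped record, the exon chain
#' implied by its CIGAR: alignment-match (`M`, `=`, `X`) and deletion (`D`)
#' operators extend the current exon, and each reference-skip (`N`) operator
#' closes an exon and opens the next. Unmapped, secondary and supplementary
#' records are skipped and tallied in the `skipped` attribute of the result.
#'
#' Soft clips are reported in transcript orientation: for a reverse-strand
#' alignment the CIGAR-leading clip belongs to the transcript 3' end
#' (`clip3`) and the trailing clip to the 5' end (`clip5`). In direct
#' RNA-seq the molecule is read 3'->5', so clip profiles at the two ends
#' behave very differently and are diagnostic of end-mapping precision.
#'
#' @param path path to a SAM or BAM file (SAM is converted internally).
#' @param sample_id label stored in the `sample_id` column.
#' @param genome optional genome as a named `Biostrings::DNAStringSet` or
#'   FASTA path; when given, the alignment reference name must match one of
#'   its sequence names or parsing aborts (guards against mixing genomes).
#' @param min_mapq minimum mapping quality; default 0 (no filter).
#' @return tibble of reads (see file header for columns) with attribute
#'   `skipped`, a named integer vector of excluded record counts.
#' @export
parse_alignments <- function(path, sample_id, genome = NULL, min_mapq = 0) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }

  if (!is.null(genome)) {
    genome <- load_genome(genome)
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    if (length(hdr) && !any(names(hdr) %in% names(genome))) {
      stop("alignment reference ", paste(names(hdr), collapse = ","),
           " does not match genome sequence ",
           paste(names(genome), collapse = ","))
    }
  }

  # first pass: tally what gets excluded
  flags <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("flag", "mapq")))[[1]]
  fl <- flags$flag
  skipped <- c(
    unmapped      = sum(bitwAnd(fl, 4L) > 0L),
    secondary     = sum(bitwAnd(fl, 256L) > 0L & bitwAnd(fl, 4L) == 0L),
    supplementary = sum(bitwAnd(fl, 2048L) > 0L & bitwAnd(fl, 4L) == 0L &
                          bitwAnd(fl, 256L) == 0L),
    low_mapq      = sum(bitwAnd(fl, 4L + 256L + 2048L) == 0L &
                          !is.na(flags$mapq) & flags$mapq < min_mapq)
  )

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  keep <- is.na(S4Vectors::mcols(gal)$mapq) | S4Vectors::mcols(gal)$mapq >= min_mapq
  gal <- gal[keep]

  if (length(gal) == 0L) {
    out <- empty_reads(sample_id)
    attr(out, "skipped") <- skipped
    return(out)
  }

  cig <- GenomicAlignments::cigar(gal)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  lead <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]
    if (length(o) && o[1] == "S") lens[[i]][1] else 0L
  }, integer(1))
  trail <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]
    k <- length(o)
    if (k && o[k] == "S") lens[[i]][k] else 0L
  }, integer(1))

  exon_rgl <- GenomicAlignments::grglist(gal)  # splits at N, keeps D intra-exon
  u <- unlist(exon_rgl, use.names = FALSE)
  nper <- S4Vectors::elementNROWS(exon_rgl)
  ele <- rep.int(seq_along(nper), nper)
  st_split <- split(GenomicRanges::start(u), ele)
  en_split <- split(GenomicRanges::end(u), ele)
  exons <- mapply(function(s, e) cbind(start = s, end = e),
                  st_split, en_split, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  strand <- as.character(GenomicAlignments::strand(gal))
  strand[strand == "*"] <- "+"
  first_start <- vapply(exons, function(m) m[1, 1], numeric(1))
  last_end <- vapply(exons, function(m) m[nrow(m), 2], numeric(1))

  out <- tibble::tibble(
    read_id = S4Vectors::mcols(gal)$qname,
    sample_id = sample_id,
    strand = strand,
    exons = exons,
    n_exons = vapply(exons, nrow, integer(1)),
    length = vapply(exons, function(m) sum(m[, 2] - m[, 1] + 1), numeric(1)),
    tss = ifelse(strand == "+", first_start, last_end),
    tts = ifelse(strand == "+", last_end, first_start),
    clip5 = ifelse(strand == "+", lead, trail),
    clip3 = ifelse(strand == "+", trail, lead),
    polya_qc = NA_character_,
    polya_length = NA_real_,
    polya_usable = FALSE
  )
  attr(out, "skipped") <- skipped
  out
}

empty_reads <- function(sample_id = character(0)) {
  tibble::tibble(
    read_id = character(0), sample_id = character(0), strand = character(0),
    exons = list(), n_exons = integer(0), length = numeric(0),
    tss = numeric(0), tts = numeric(0), clip5 = numeric(0), clip3 = numeric(0),
    polya_qc = character(0), polya_length = numeric(0), polya_usable = logical(0))
}

#' Load a genome sequence
#'
#' @param genome a `Biostrings::DNAStringSet` (returned unchanged) or a FASTA
#'   file path.
#' @return named `DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  Biostrings::readDNAStringSet(genome)
}

#' Splice junctions of one read
#'
#' One junction per inter-exon gap, ordered 5'->3' along the transcript.
#' The donor is the last exonic base of the transcript-upstream exon and the
#' acceptor the first exonic base of the downstream exon, so for "+" reads
#' donor < acceptor and for "-" reads donor > acceptor.
#'
#' @param exons 2-column matrix of exon start/end (ascending genomic order).
#' @param strand "+" or "-".
#' @return tibble with columns donor, acceptor, strand; zero rows for
#'   single-exon reads.
#' @export
junctions_of <- function(exons, strand = "+") {
  k <- nrow(exons)
  if (k < 2L) {
    return(tibble::tibble(donor = numeric(0), acceptor = numeric(0),
                          strand = character(0)))
  }
  donor <- unname(exons[-k, 2])
  acceptor <- unname(exons[-1, 1])
  if (strand == "-") {
    # transcript order runs right-to-left: upstream exon is the genomic-right
    donor <- rev(unname(exons[-1, 1]))
    acceptor <- rev(unname(exons[-k, 2]))
  }
  tibble::tibble(donor = donor, acceptor = acceptor, strand = strand)
}

#' Junction chain string for a read (internal grouping key component)
#' @noRd
junction_chain <- function(exons, strand) {
  k <- nrow(exons)
  if (k < 2L) return("")
  if (strand == "+") {
    donor <- exons[-k, 2]; acceptor <- exons[-1, 1]
  } else {
    donor <- rev(exons[-1, 1]); acceptor <- rev(exons[-k, 2])
  }
  paste(paste0(donor, "-", acceptor), collapse = ";")
}

#' All junctions of a read table
#'
#' @param reads read table from [parse_alignments()].
#' @return tibble (read_id, strand, donor, acceptor, ord) with one row per
#'   junction, `ord` numbering junctions 5'->3' within each read.
#' @export
all_junctions <- function(reads) {
  keep <- which(reads$n_exons > 1L)
  if (length(keep) == 0L) {
    return(tibble::tibble(read_id = character(0), strand = character(0),
                          donor = numeric(0), acceptor = numeric(0),
                          ord = integer(0)))
  }
  donors <- vector("list", length(keep))
  acceptors <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    m <- reads$exons[[i]]
    k <- nrow(m)
    if (reads$strand[i] == "+") {
      donors[[j]] <- unname(m[-k, 2]); acceptors[[j]] <- unname(m[-1, 1])
    } else {
      donors[[j]] <- rev(unname(m[-1, 1]))
      acceptors[[j]] <- rev(unname(m[-k, 2]))
    }
  }
  nj <- reads$n_exons[keep] - 1L
  tibble::tibble(read_id = rep(reads$read_id[keep], nj),
                 strand = rep(reads$strand[keep], nj),
                 donor = unlist(donors), acceptor = unlist(acceptors),
                 ord = sequence(nj))
}

#' Read a nanopolish-polyA-style per-read tail-length table
#'
#' Expects a tab-separated file with a header row naming at least
#' `readname`, `qc_tag` and `polya_length`; extra columns are ignored.
#'
#' @param path TSV path.
#' @return tibble (read_id, qc_tag, polya_length).
#' @export
read_polya_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("readname", "qc_tag", "polya_length")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("polyA table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  tibble::tibble(read_id = as.character(tab$readname),
                 qc_tag = as.character(tab$qc_tag),
                 polya_length = as.numeric(tab$polya_length))
}

#' Attach per-read polyA tail estimates and flag usable reads
#'
#' A read is "polyA-usable" iff its QC tag is `PASS` and the estimated tail
#' length is at least `min_len` nucleotides (default 20). Reads without a
#' record, or failing the filter, are retained for grouping but excluded
#' from polyA summaries. Duplicate records for a read keep the first and warn.
#'
#' @param reads read table.
#' @param records tibble from [read_polya_table()] (read_id, qc_tag,
#'   polya_length).
#' @param min_len minimum usable tail length in nt.
#' @return read table with polya_qc, polya_length, polya_usable filled in.
#' @export
attach_polya <- function(reads, records, min_len = 20) {
  if (anyDuplicated(records$read_id)) {
    warning("duplicate polyA records for ",
            sum(duplicated(records$read_id)), " read id(s); keeping first")
    records <- records[!duplicated(records$read_id), ]
  }
  idx <- match(reads$read_id, records$read_id)
  reads$polya_qc <- records$qc_tag[idx]
  reads$polya_length <- records$polya_length[idx]
  reads$polya_usable <- !is.na(idx) & records$qc_tag[idx] == "PASS" &
    records$polya_length[idx] >= min_len
  reads
}

#' Soft-clip profile at one transcript end
#'
#' @param reads read table (>= 1 read).
#' @param end "5prime" or "3prime".
#' @return list with `end`, `mean`, `mode` (ties broken toward the smaller
#'   clip length) and `histogram` (tibble clip/count).
#' @export
softclip_profile <- function(reads, end = c("5prime", "3prime")) {
  end <- match.arg(end)
  if (nrow(reads) == 0L) stop("softclip_profile: no reads")
  clips <- if (end == "5prime") reads$clip5 else reads$clip3
  tab <- table(clips)
  lens <- as.numeric(names(tab))
  counts <- as.integer(tab)
  mode <- min(lens[counts == max(counts)])
  list(end = end, mean = mean(clips), mode = mode,
       histogram = tibble::tibble(clip = lens, count = counts))
}

#' Read-length summary
#'
#' Read length is the sum of exon lengths (aligned bases, clips excluded).
#'
#' @param reads read table (>= 1 read).
#' @return one-row tibble (n, longest, mean_length, modal_length); the modal
#'   length breaks ties toward the smaller value.
#' @export
read_stats <- function(reads) {
  if (nrow(reads) == 0L) stop("read_stats: no reads")
  len <- reads$length
  tab <- table(len)
  lens <- as.numeric(names(tab))
  modal <- min(lens[as.integer(tab) == max(tab)])
  tibble::tibble(n = nrow(reads), longest = max(len),
                 mean_length = mean(len), modal_length = modal)
}

#' Serialize an exon chain back to a CIGAR string
#'
#' Inverse of the parsing contract: exons become `M` runs, inter-exon gaps
#' become `N` runs, and soft clips (given in transcript orientation) are
#' emitted at the CIGAR ends in reference orientation.
#'
#' @param exons 2-column start/end matrix (ascending).
#' @param clip5,clip3 soft clip lengths at the transcript 5'/3' end.
#' @param strand "+" or "-".
#' @return CIGAR string.
#' @export
exons_to_cigar <- function(exons, clip5 = 0, clip3 = 0, strand = "+") {
  k <- nrow(exons)
  widths <- exons[, 2] - exons[, 1] + 1
  parts <- character(0)
  for (i in seq_len(k)) {
    parts <- c(parts, paste0(widths[i], "M"))
    if (i < k) parts <- c(parts, paste0(exons[i + 1, 1] - exons[i, 2] - 1, "N"))
  }
  lead <- if (strand == "+") clip5 else clip3
  trail <- if (strand == "+") clip3 else clip5
  paste0(if (lead > 0) paste0(lead, "S") else "",
         paste(parts, collapse = ""),
         if (trail > 0) paste0(trail, "S") else "")
}

# exon chain <-> "start-end;start-end" text (for TSV round trips)
exons_to_string <- function(exons) {
  paste(paste0(exons[, 1], "-", exons[, 2]), collapse = ";")
}

string_to_exons <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.numeric))
  colnames(m) <- c("start", "end")
  m
}

#' Write the read-level TSV report
#'
#' @param reads read table.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_read_table <- function(reads, path) {
  out <- data.frame(
    read_id = reads$read_id, sample = reads$sample_id, strand = reads$strand,
    n_exons = reads$n_exons, length = reads$length,
    tss = reads$tss, tts = reads$tts,
    clip5 = reads$clip5, clip3 = reads$clip3,
    exons = vapply(reads$exons, exons_to_string, character(1)),
    polya_qc = reads$polya_qc, polya_length = reads$polya_length,
    polya_usable = reads$polya_usable)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-load a read table written by [write_read_table()]
#' @param path TSV path.
#' @param sample_id optional override for the sample column.
#' @return read table.
#' @export
read_read_table <- function(path, sample_id = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  exons <- lapply(tab$exons, string_to_exons)
  tibble::tibble(
    read_id = as.character(tab$read_id),
    sample_id = if (is.null(sample_id)) as.character(tab$sample) else sample_id,
    strand = tab$strand, exons = exons,
    n_exons = vapply(exons, nrow, integer(1)),
    length = tab$length, tss = tab$tss, tts = tab$tts,
    clip5 = tab$clip5, clip3 = tab$clip3,
    polya_qc = as.character(tab$polya_qc),
    polya_length = as.numeric(tab$polya_length),
    polya_usable = as.logical(tab$polya_usable))
}
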