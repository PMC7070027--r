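# Cross-validation of nanopore splice junctions against an independent
# short-read (e.g. Illumina) junction set. Matching is exact-coordinate and
# strand-aware: splice sites are never windowed, although an exploratory
# fuzz window is available.

#' Load a short-read junction set
#'
#' Accepts either a TSV (columns donor, acceptor, strand, support, with or
#' without a header row) in 1-based inclusive coordinates with the internal
#' donor/acceptor convention, or a BED12 file of junction-spanning records
#' (e.g. TopHat/RegTools style) whose two blocks flank the intron; BED
#' 0-based half-open coordinates are converted on read, and the BED score
#' column is taken as the support count.
#'
#' @param path input path.
#' @param format "tsv" or "bed"; default guesses from the extension.
#' @param min_support junctions with fewer supporting reads are dropped.
#' @return tibble (donor, acceptor, strand, support).
#' @export
load_junctions <- function(path, format = NULL, min_support = 1) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    bed <- rtracklayer::import(path, format = "bed")
    rows <- list()
    for (i in seq_along(bed)) {
      blocks <- if (!is.null(bed$blocks)) bed$blocks[[i]] else NULL
      std <- as.character(GenomicRanges::strand(bed[i]))
      if (std == "*") std <- "+"
      if (is.null(blocks) || length(blocks) < 2L) {
        stop("malformed junction BED record at line ", i,
             ": need >= 2 blocks")
      }
      # blocks are relative IRanges (1-based within the record)
      abs_start <- GenomicRanges::start(bed[i]) + IRanges::start(blocks) - 1L
      abs_end <- GenomicRanges::start(bed[i]) + IRanges::end(blocks) - 1L
      for (b in seq_len(length(blocks) - 1L)) {
        left_end <- abs_end[b]; right_start <- abs_start[b + 1L]
        donor <- if (std == "+") left_end else right_start
        acceptor <- if (std == "+") right_start else left_end
        rows[[length(rows) + 1L]] <- tibble::tibble(
          donor = donor, acceptor = acceptor, strand = std,
          support = if (!is.null(bed$score)) bed$score[i] else 1)
      }
    }
    jset <- dplyr::bind_rows(rows)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) {
      jset <- tibble::tibble(donor = numeric(0), acceptor = numeric(0),
                             strand = character(0), support = numeric(0))
    } else {
      first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
      has_header <- is.na(suppressWarnings(as.numeric(first[1])))
      if (has_header) lines <- lines[-1]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(vapply(parts, length, integer(1)) < 3L)
      if (length(bad)) {
        stop("malformed junction line ", bad[1] + has_header, " in ", path)
      }
      donor <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
      acceptor <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
      if (anyNA(donor) || anyNA(acceptor)) {
        stop("malformed junction line ",
             which(is.na(donor) | is.na(acceptor))[1] + has_header,
             " in ", path)
      }
      support <- vapply(parts, function(p)
        if (length(p) >= 4L) suppressWarnings(as.numeric(p[4])) else 1,
        numeric(1))
      support[is.na(support)] <- 1
      jset <- tibble::tibble(donor = donor, acceptor = acceptor,
                             strand = vapply(parts, `[`, "", 3),
                             support = support)
    }
  }
  jset <- jset[jset$support >= min_support, ]
  dplyr::distinct(jset, .data$donor, .data$acceptor, .data$strand,
                  .keep_all = TRUE)
}

#' Write a junction set
#'
#' TSV writes the internal representation with a header. BED writes one
#' BED12 junction record per junction with 20 nt anchor blocks flanking the
#' intron (converted back to 0-based half-open), so that
#' `load_junctions(write_junctions(x))` is the identity on
#' (donor, acceptor, strand, support).
#'
#' @param jset junction tibble.
#' @param path output path.
#' @param format "tsv" or "bed" (guessed from extension by default).
#' @param seqname reference name for BED output.
#' @return invisibly, the path.
#' @export
write_junctions <- function(jset, path, format = NULL, seqname = "genome") {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "tsv") {
    utils::write.table(as.data.frame(jset), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  anchor <- 20L
  lines <- vapply(seq_len(nrow(jset)), function(i) {
    d <- jset$donor[i]; a <- jset$acceptor[i]; std <- jset$strand[i]
    left_end <- if (std == "+") d else a      # genomic-left exonic base
    right_start <- if (std == "+") a else d
    chrom_start <- left_end - anchor          # 0-based = (left_end-anchor+1)-1
    chrom_end <- right_start + anchor - 1L    # 0-based half-open end
    block_sizes <- paste0(anchor, ",", anchor)
    block_starts <- paste0(0L, ",", right_start - 1L - chrom_start)
    paste(seqname, chrom_start, chrom_end, paste0("JUNC", i),
          jset$support[i], std, chrom_start, chrom_end, "0,0,0", 2,
          block_sizes, block_starts, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-transcript all-junction concordance with a short-read junction set
#'
#' A spliced read is concordant iff *all* of its junctions are present in
#' the short-read set (exact donor/acceptor/strand match, optionally within
#' `fuzz` nt for exploration). Unspliced reads carry no junctions, so they
#' are tallied separately and excluded from the concordance denominator;
#' a fraction over all reads is also reported.
#'
#' @param reads read table.
#' @param jset junction tibble from [load_junctions()].
#' @param fuzz optional +/- nt tolerance on both coordinates (default 0,
#'   exact matching).
#' @return list(per_read = tibble(read_id, n_junctions, concordant),
#'   summary = one-row tibble(n_reads, n_spliced, n_unspliced, n_concordant,
#'   frac_spliced, frac_all), junction_table = tibble(strand, donor,
#'   acceptor, reads, known)).
#' @export
transcript_concordance <- function(reads, jset, fuzz = 0) {
  jr <- all_junctions(reads)
  key <- function(d, a, s) paste(d, a, s)
  in_set <- if (fuzz == 0) {
    jr_known <- key(jr$donor, jr$acceptor, jr$strand) %in%
      key(jset$donor, jset$acceptor, jset$strand)
    jr_known
  } else {
    vapply(seq_len(nrow(jr)), function(i) {
      any(jset$strand == jr$strand[i] &
            abs(jset$donor - jr$donor[i]) <= fuzz &
            abs(jset$acceptor - jr$acceptor[i]) <= fuzz)
    }, logical(1))
  }
  spliced_ids <- reads$read_id[reads$n_exons > 1L]
  if (length(spliced_ids)) {
    per <- tibble::tibble(read_id = jr$read_id, known = in_set) |>
      dplyr::group_by(.data$read_id) |>
      dplyr::summarise(n_junctions = dplyr::n(),
                       concordant = all(.data$known), .groups = "drop")
  } else {
    per <- tibble::tibble(read_id = character(0), n_junctions = integer(0),
                          concordant = logical(0))
  }
  n_spliced <- length(spliced_ids)
  n_conc <- sum(per$concordant)
  n_all <- nrow(reads)
  summary <- tibble::tibble(
    n_reads = n_all, n_spliced = n_spliced,
    n_unspliced = n_all - n_spliced, n_concordant = n_conc,
    frac_spliced = if (n_spliced > 0) n_conc / n_spliced else NA_real_,
    frac_all = if (n_all > 0) n_conc / n_all else NA_real_)
  jtab <- tibble::tibble(strand = jr$strand, donor = jr$donor,
                         acceptor = jr$acceptor, known = in_set) |>
    dplyr::group_by(.data$strand, .data$donor, .data$acceptor, .data$known) |>
    dplyr::summarise(reads = dplyr::n(), .groups = "drop")
  list(per_read = per, summary = summary,
       junction_table = jtab[, c("strand", "donor", "acceptor", "reads",
                                 "known")])
}
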