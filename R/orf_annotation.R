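# ORF-centric annotation of transcript groups: pseudo-transcript
# construction, AUG scanning, canonical matching with the
# 5'-most-ORF / next-AUG ("2nd Methionine") rule, dominant transcript
# selection and GFF3 output.

#' Read and validate a canonical feature table
#'
#' Tab-separated with header: name, strand, start_codon_pos (genomic
#' coordinate of the A of the AUG), cds_end, and optionally expected_aa
#' (protein length in residues). Two features sharing a start codon and
#' strand are rejected at load, since canonical identity is positional.
#'
#' @param path TSV path, or a data.frame already in memory.
#' @return validated tibble.
#' @export
read_features <- function(path) {
  tab <- if (is.character(path)) {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else as.data.frame(path)
  need <- c("name", "strand", "start_codon_pos", "cds_end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"expected_aa" %in% names(tab)) tab$expected_aa <- NA_real_
  if (anyDuplicated(tab$name)) stop("feature names must be unique")
  key <- paste(tab$start_codon_pos, tab$strand)
  if (anyDuplicated(key)) {
    stop("two canonical features share a start codon: ",
         paste(tab$name[duplicated(key) | duplicated(key, fromLast = TRUE)],
               collapse = ", "))
  }
  tibble::as_tibble(tab[, c(need, "expected_aa")])
}

#' Build the 5'-extended pseudo-transcript of a transcript group
#'
#' The pseudo-transcript is the spliced concatenation of the group's
#' consensus exon model (TSS representative, exact junction chain, TTS
#' representative) in transcript orientation, reverse-complemented for
#' minus-strand groups, with `extension` additional genomic bases prepended
#' upstream of the TSS. The extension compensates for the systematic
#' ~8-15 nt 5' under-read of direct RNA-seq, which otherwise hides start
#' codons that lie close to the true TSS. Extensions are clipped at the
#' genome boundary and the achieved value recorded.
#'
#' @param group one-row slice of the group table from [build_groups()].
#' @param genome `DNAStringSet` or FASTA path.
#' @param extension nt to prepend upstream of the TSS (default 10).
#' @return object of class `pseudo_transcript`: list(sequence, coord_map,
#'   extension, strand, group_id) where `coord_map[i]` is the genomic
#'   coordinate of transcript base i (strictly decreasing for "-" groups).
#' @export
build_pseudo_transcript <- function(group, genome, extension = 10) {
  stopifnot(extension >= 0)
  genome <- load_genome(genome)
  seq <- genome[[1]]
  glen <- length(seq)
  ex <- group_exons(group)
  if (any(ex[, 1] < 1) || any(ex[, 2] > glen)) {
    bad <- ex[ex[, 1] < 1 | ex[, 2] > glen, , drop = FALSE]
    stop("group exon outside genome [1,", glen, "]: ",
         bad[1, 1], "-", bad[1, 2])
  }
  strand <- group$strand
  if (strand == "+") {
    ext_from <- max(1L, unname(ex[1, 1]) - extension)
    ext_real <- unname(ex[1, 1]) - ext_from
    coords <- c(if (ext_real > 0) seq.int(ext_from, ex[1, 1] - 1L) else integer(0),
                unlist(lapply(seq_len(nrow(ex)),
                              function(i) seq.int(ex[i, 1], ex[i, 2]))))
    s <- paste0(vapply(seq_len(nrow(ex)), function(i)
      as.character(Biostrings::subseq(seq, ex[i, 1], ex[i, 2])), character(1)),
      collapse = "")
    pre <- if (ext_real > 0)
      as.character(Biostrings::subseq(seq, ext_from, ex[1, 1] - 1L)) else ""
    txt <- paste0(pre, s)
  } else {
    top <- unname(ex[nrow(ex), 2])          # transcript 5' end (max coord)
    ext_to <- min(glen, top + extension)
    ext_real <- ext_to - top
    coords <- c(if (ext_real > 0) seq.int(ext_to, top + 1L) else integer(0),
                unlist(lapply(rev(seq_len(nrow(ex))),
                              function(i) seq.int(ex[i, 2], ex[i, 1]))))
    s <- paste0(vapply(rev(seq_len(nrow(ex))), function(i) {
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(seq, ex[i, 1], ex[i, 2])))
    }, character(1)), collapse = "")
    pre <- if (ext_real > 0) as.character(Biostrings::reverseComplement(
      Biostrings::subseq(seq, top + 1L, ext_to))) else ""
    txt <- paste0(pre, s)
  }
  structure(list(sequence = txt, coord_map = coords, extension = ext_real,
                 strand = strand,
                 group_id = if ("group_id" %in% names(group))
                   group$group_id else NA_character_),
            class = "pseudo_transcript")
}

# collapse a run of transcript coordinates into genomic blocks
coords_to_blocks <- function(coords) {
  step <- diff(coords)
  brk <- c(0L, which(abs(step) != 1), length(coords))
  blocks <- lapply(seq_len(length(brk) - 1L), function(i) {
    seg <- coords[(brk[i] + 1L):brk[i + 1L]]
    c(start = min(seg), end = max(seg))
  })
  m <- do.call(rbind, blocks)
  m[order(m[, "start"]), , drop = FALSE]
}

#' Scan a pseudo-transcript for open reading frames
#'
#' Every AUG opens a candidate ORF; reading proceeds in that frame to the
#' first stop codon (UAA/UAG/UGA; `complete`) or to the transcript end
#' (`incomplete`). Candidates shorter than `min_aa` residues are dropped
#' unless their start codon matches a canonical feature, which is always
#' retained so that very short canonical peptides stay representable.
#' Calls are ordered by transcript start and ranked 1 = 5'-most.
#'
#' @param pseudo a `pseudo_transcript`.
#' @param min_aa minimum residue count for non-canonical ORFs (default 10).
#' @param features optional canonical feature table; used only for the
#'   short-ORF retention override.
#' @return tibble (rank, tx_start, tx_end, complete, aa_len, start_genomic,
#'   blocks) with blocks a list column of genomic start/end matrices.
#' @export
scan_orfs <- function(pseudo, min_aa = 10, features = NULL) {
  s <- pseudo$sequence
  L <- nchar(s)
  empty <- tibble::tibble(rank = integer(0), tx_start = integer(0),
                          tx_end = integer(0), complete = logical(0),
                          aa_len = integer(0), start_genomic = numeric(0),
                          blocks = list())
  if (L < 3L) return(empty)
  starts <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(empty)
  stops <- c("TAA", "TAG", "TGA")
  canon_pos <- if (is.null(features)) numeric(0) else
    features$start_codon_pos[features$strand == pseudo$strand]
  rows <- list()
  for (st in starts) {
    n_codons <- (L - st + 1L) %/% 3L
    if (n_codons < 1L) next
    codon_starts <- st + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, codon_starts, codon_starts + 2L)
    hit <- which(codons %in% stops)
    if (length(hit)) {
      complete <- TRUE
      tx_end <- st + 3L * hit[1] - 1L
      aa_len <- hit[1] - 1L
    } else {
      complete <- FALSE
      tx_end <- st + 3L * n_codons - 1L
      aa_len <- n_codons
    }
    start_g <- pseudo$coord_map[st]
    canonical <- start_g %in% canon_pos
    if (aa_len < min_aa && !canonical) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tx_start = st, tx_end = tx_end, complete = complete,
      aa_len = aa_len, start_genomic = start_g,
      blocks = list(coords_to_blocks(pseudo$coord_map[st:tx_end])))
  }
  if (length(rows) == 0L) return(empty)
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$tx_start), ]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "tx_start", "tx_end", "complete", "aa_len",
          "start_genomic", "blocks")]
}

#' Match one ORF call against the canonical feature table
#'
#' A match requires the ORF's start-codon genomic position and strand to
#' equal a feature's; `truncated` is set when the feature provides an
#' expected protein length and the ORF is shorter (e.g. a splice removed
#' coding sequence). Incomplete ORFs match only by this positional rule and
#' then also carry `truncated`.
#'
#' @param orf one row of a [scan_orfs()] table.
#' @param strand strand of the pseudo-transcript.
#' @param features canonical feature table.
#' @return list(name = matched name or NA, truncated = flag).
#' @export
match_canonical <- function(orf, strand, features) {
  i <- which(features$start_codon_pos == orf$start_genomic &
               features$strand == strand)
  if (length(i) == 0L) return(list(name = NA_character_, truncated = FALSE))
  exp_aa <- features$expected_aa[i[1]]
  trunc <- (!orf$complete) ||
    (!is.na(exp_aa) && orf$aa_len < exp_aa)
  list(name = features$name[i[1]], truncated = trunc)
}

#' Annotate one transcript group by the protein it can encode
#'
#' Applies the 5'-most-ORF rule: if the rank-1 ORF of the extended
#' pseudo-transcript is canonical the group is named after it; otherwise
#' ranks 2, 3, ... are scanned in order and the first canonical match is
#' taken with the `second_methionine` flag (translation would require the
#' 5'-proximal AUG to be skipped). With no canonical AUG anywhere the group
#' is flagged `no_known_orf`.
#'
#' @param group one-row group slice.
#' @param genome genome sequence.
#' @param features canonical feature table.
#' @param extension 5' extension in nt (default 10).
#' @param min_aa minimum non-canonical ORF length (default 10).
#' @return one-row tibble (group_id, group_key, matched_feature, match_rank,
#'   second_methionine, truncated, incomplete, no_known_orf, n_orfs,
#'   orf_calls list column).
#' @export
annotate_group <- function(group, genome, features, extension = 10,
                           min_aa = 10) {
  if (!group_model_valid(group)) {
    # end-cluster representative inconsistent with the junction chain:
    # no consensus sequence exists, so no ORF can be called
    return(tibble::tibble(
      group_id = group$group_id, group_key = group$group_key,
      matched_feature = NA_character_, match_rank = NA_integer_,
      second_methionine = FALSE, truncated = FALSE, incomplete = FALSE,
      no_known_orf = TRUE, n_orfs = 0L,
      orf_calls = list(tibble::tibble())))
  }
  pseudo <- build_pseudo_transcript(group, genome, extension)
  orfs <- scan_orfs(pseudo, min_aa = min_aa, features = features)
  matched <- NA_character_; rank <- NA_integer_
  trunc <- FALSE; incomplete <- FALSE
  if (nrow(orfs)) {
    for (i in seq_len(nrow(orfs))) {
      m <- match_canonical(orfs[i, ], pseudo$strand, features)
      if (!is.na(m$name)) {
        matched <- m$name; rank <- orfs$rank[i]
        trunc <- m$truncated; incomplete <- !orfs$complete[i]
        break
      }
    }
  }
  tibble::tibble(
    group_id = group$group_id, group_key = group$group_key,
    matched_feature = matched, match_rank = rank,
    second_methionine = !is.na(rank) && rank >= 2L,
    truncated = trunc, incomplete = incomplete,
    no_known_orf = is.na(matched),
    n_orfs = nrow(orfs), orf_calls = list(orfs))
}

#' Annotate every transcript group
#'
#' @param groups group table from [build_groups()].
#' @inheritParams annotate_group
#' @return tibble with one [annotate_group()] row per group.
#' @export
annotate_groups <- function(groups, genome, features, extension = 10,
                            min_aa = 10) {
  genome <- load_genome(genome)
  dplyr::bind_rows(lapply(seq_len(nrow(groups)), function(i)
    annotate_group(groups[i, ], genome, features, extension, min_aa)))
}

#' Dominant transcript group per canonical feature
#'
#' For each feature, the highest-count group whose *rank-1* ORF is that
#' feature (ties to the smaller TSS representative). Features encoded by no
#' rank-1 group are absent from the map.
#'
#' @param annotations annotation table from [annotate_groups()].
#' @param groups group table.
#' @param sample_id optional: rank by this sample's counts instead of pooled
#'   totals.
#' @return tibble (feature, group_id, count).
#' @export
dominant_transcripts <- function(annotations, groups, sample_id = NULL) {
  ann <- annotations[!is.na(annotations$match_rank) &
                       annotations$match_rank == 1L, ]
  if (nrow(ann) == 0L) {
    return(tibble::tibble(feature = character(0), group_id = character(0),
                          count = numeric(0)))
  }
  g <- groups[match(ann$group_id, groups$group_id), ]
  count <- if (is.null(sample_id)) g$total_count else
    vapply(g$samples, group_sample_count, numeric(1), sample_id = sample_id)
  df <- tibble::tibble(feature = ann$matched_feature, group_id = ann$group_id,
                       count = count, tss_rep = g$tss_rep)
  df <- df[df$count > 0, ]
  df <- df[order(df$feature, -df$count, df$tss_rep), ]
  df <- df[!duplicated(df$feature), ]
  df[, c("feature", "group_id", "count")]
}

#' Per-sample ORF usage table
#'
#' For each sample, the percentage of all classified reads whose rank-1 ORF
#' is each canonical feature, plus a `no known ORF` row for reads in groups
#' without any canonical AUG. Second-methionine matches are excluded from a
#' feature's rank-1 row, so columns do not sum to 100.
#'
#' @param annotations annotation table.
#' @param groups group table.
#' @return tibble (feature, sample_id, reads, percent).
#' @export
orf_usage_table <- function(annotations, groups) {
  g <- groups[match(annotations$group_id, groups$group_id), ]
  per_sample <- dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
    s <- g$samples[[i]]
    lab <- if (annotations$no_known_orf[i]) {
      "no known ORF"
    } else if (annotations$match_rank[i] == 1L) {
      annotations$matched_feature[i]
    } else {
      NA_character_   # second-methionine: not a rank-1 row
    }
    tibble::tibble(sample_id = s$sample_id, n = s$n, feature = lab)
  }))
  totals <- per_sample |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  tab <- per_sample[!is.na(per_sample$feature), ] |>
    dplyr::group_by(.data$feature, .data$sample_id) |>
    dplyr::summarise(reads = sum(.data$n), .groups = "drop") |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(percent = 100 * .data$reads / .data$total)
  tab[order(tab$feature, tab$sample_id),
      c("feature", "sample_id", "reads", "percent")]
}

#' Write transcript groups as GFF3
#'
#' One `mRNA` parent with `exon` children per group, 1-based inclusive with
#' ascending coordinates on both strands (GFF3 convention). Attributes carry
#' the supporting read count and, when annotations are supplied, the matched
#' feature and flags. Ordering is deterministic (group table order).
#'
#' @param groups group table.
#' @param path output GFF3 path.
#' @param annotations optional annotation table.
#' @param mode "all" (every group), "dominant" (one group per feature, the
#'   dominant map), or "all_for_feature" with `feature` giving the name.
#' @param feature feature name for mode "all_for_feature".
#' @param seqname reference sequence name used in column 1.
#' @return invisibly, the path.
#' @export
write_gff <- function(groups, path, annotations = NULL,
                      mode = c("all", "dominant", "all_for_feature"),
                      feature = NULL, seqname = "genome") {
  mode <- match.arg(mode)
  sel <- groups
  if (mode == "dominant") {
    stopifnot(!is.null(annotations))
    dom <- dominant_transcripts(annotations, groups)
    sel <- groups[match(dom$group_id, groups$group_id), ]
  } else if (mode == "all_for_feature") {
    stopifnot(!is.null(annotations), !is.null(feature))
    ids <- annotations$group_id[!is.na(annotations$matched_feature) &
                                  annotations$matched_feature == feature]
    sel <- groups[groups$group_id %in% ids, ]
  }
  ok <- vapply(seq_len(nrow(sel)), function(i)
    group_model_valid(sel[i, ]), logical(1))
  if (any(!ok)) {
    message(sum(!ok), " group(s) without a valid consensus exon model ",
            "omitted from GFF")
    sel <- sel[ok, ]
  }
  if (nrow(sel) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  start_v <- integer(0); end_v <- integer(0); strand_v <- character(0)
  type_v <- character(0); id_v <- character(0); parent_v <- character(0)
  reads_v <- character(0); feature_v <- character(0); flags_v <- character(0)
  for (i in seq_len(nrow(sel))) {
    ex <- group_exons(sel[i, ])
    gid <- sel$group_id[i]
    feat <- NA_character_; flg <- NA_character_
    if (!is.null(annotations)) {
      a <- annotations[annotations$group_id == gid, ]
      if (nrow(a) == 1L) {
        flags <- c(if (a$second_methionine) "second_methionine",
                   if (a$truncated) "truncated",
                   if (a$incomplete) "incomplete",
                   if (a$no_known_orf) "no_known_orf")
        if (!is.na(a$matched_feature)) feat <- a$matched_feature
        if (length(flags)) flg <- paste(flags, collapse = ",")
      }
    }
    k <- nrow(ex)
    start_v <- c(start_v, min(ex[, 1]), ex[, 1])
    end_v <- c(end_v, max(ex[, 2]), ex[, 2])
    strand_v <- c(strand_v, rep(sel$strand[i], k + 1L))
    type_v <- c(type_v, "mRNA", rep("exon", k))
    id_v <- c(id_v, gid, paste0(gid, ".exon", seq_len(k)))
    parent_v <- c(parent_v, NA_character_, rep(gid, k))
    reads_v <- c(reads_v, as.character(sel$total_count[i]),
                 rep(NA_character_, k))
    feature_v <- c(feature_v, feat, rep(NA_character_, k))
    flags_v <- c(flags_v, flg, rep(NA_character_, k))
  }
  gr <- GenomicRanges::GRanges(seqname, IRanges::IRanges(start_v, end_v),
                               strand = strand_v)
  gr$type <- type_v
  gr$ID <- id_v
  gr$Parent <- IRanges::CharacterList(
    lapply(parent_v, function(p) if (is.na(p)) character(0) else p))
  gr$reads <- reads_v
  gr$feature <- feature_v
  gr$flags <- flags_v
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write the annotation TSV (group key, matched feature, flags, rank,
#' per-sample counts)
#'
#' @param annotations annotation table.
#' @param groups group table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_annotation_table <- function(annotations, groups, path) {
  g <- groups[match(annotations$group_id, groups$group_id), ]
  sample_ids <- sort(unique(unlist(lapply(g$samples, function(s) s$sample_id))))
  out <- data.frame(
    group_id = annotations$group_id, strand = g$strand, tss = g$tss_rep,
    tts = g$tts_rep, chain = g$chain, total_count = g$total_count,
    matched_feature = annotations$matched_feature,
    match_rank = annotations$match_rank,
    second_methionine = annotations$second_methionine,
    truncated = annotations$truncated,
    incomplete = annotations$incomplete,
    no_known_orf = annotations$no_known_orf)
  for (sid in sample_ids) {
    out[[paste0("n_", sid)]] <-
      vapply(g$samples, group_sample_count, numeric(1), sample_id = sid)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
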