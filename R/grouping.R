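# Transcript grouping: reads -> equivalence classes keyed by
# (strand, TSS cluster, exact junction chain, TTS cluster).

#' Attach group-key columns to a read table
#'
#' Maps each read's observed 5'/3' end to its TSS/TTS cluster representative
#' (member lookup; untallied positions fall back to the nearest in-window
#' representative, else become their own singleton) and records the exact
#' junction chain. The full group key is
#' `strand|tss_rep|junction-chain|tts_rep`; junction coordinates are kept
#' verbatim because splice sites are never windowed.
#'
#' @param reads read table.
#' @param tss_clusters,tts_clusters cluster tables from [greedy_cluster()]
#'   built on the same reads (normally the pooled multi-sample tally, so
#'   group keys are stable across samples).
#' @return read table with tss_rep, tts_rep, chain and group_key columns.
#' @export
assign_groups <- function(reads, tss_clusters, tts_clusters) {
  tss_map <- site_rep_map(tss_clusters)
  tts_map <- site_rep_map(tts_clusters)
  lookup <- function(maps, clusters, pos, strand) {
    out <- rep(NA_real_, length(pos))
    for (std in unique(strand)) {
      sel <- strand == std
      m <- maps[[std]]
      if (!is.null(m)) {
        out[sel] <- unname(m[match(pos[sel], as.numeric(names(m)))])
      }
    }
    for (i in which(is.na(out))) {
      res <- assign_site(pos[i], strand[i], clusters)
      out[i] <- res$representative
    }
    out
  }
  reads$tss_rep <- lookup(tss_map, tss_clusters, reads$tss, reads$strand)
  reads$tts_rep <- lookup(tts_map, tts_clusters, reads$tts, reads$strand)
  reads$chain <- mapply(junction_chain, reads$exons, reads$strand)
  reads$group_key <- paste(reads$strand, reads$tss_rep, reads$chain,
                           reads$tts_rep, sep = "|")
  reads
}

#' Build transcript groups from a keyed read table
#'
#' One group per distinct key, with per-sample read counts and polyA
#' summaries (mean, sample standard deviation, n) over polyA-usable members
#' only. Groups are sorted by total count descending, then key.
#'
#' @param keyed_reads read table from [assign_groups()].
#' @return tibble (group_id, group_key, strand, tss_rep, tts_rep, chain,
#'   n_junctions, total_count, samples) where `samples` is a list column of
#'   per-sample tibbles (sample_id, n, polya_n, polya_mean, polya_sd,
#'   member_ids).
#' @export
build_groups <- function(keyed_reads) {
  r <- keyed_reads
  per <- r |>
    dplyr::group_by(.data$group_key, .data$sample_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      polya_n = sum(.data$polya_usable),
      polya_mean = ifelse(sum(.data$polya_usable) > 0,
                          mean(.data$polya_length[.data$polya_usable]), NA_real_),
      polya_sd = ifelse(sum(.data$polya_usable) > 1,
                        stats::sd(.data$polya_length[.data$polya_usable]), NA_real_),
      member_ids = list(.data$read_id),
      .groups = "drop")
  meta <- r[!duplicated(r$group_key),
            c("group_key", "strand", "tss_rep", "tts_rep", "chain")]
  totals <- per |>
    dplyr::group_by(.data$group_key) |>
    dplyr::summarise(total_count = sum(.data$n), .groups = "drop")
  samples <- split(per[, setdiff(names(per), "group_key")], per$group_key)
  g <- dplyr::left_join(meta, totals, by = "group_key")
  g$samples <- samples[g$group_key]
  g <- g[order(-g$total_count, g$group_key), ]
  g$group_id <- sprintf("TG%05d", seq_len(nrow(g)))
  g$n_junctions <- vapply(g$chain, function(ch)
    if (ch == "") 0L else length(strsplit(ch, ";", fixed = TRUE)[[1]]),
    integer(1))
  tibble::as_tibble(g[, c("group_id", "group_key", "strand", "tss_rep",
                          "tts_rep", "chain", "n_junctions", "total_count",
                          "samples")])
}

#' Per-sample count of a group (0 when absent)
#' @noRd
group_sample_count <- function(group_samples, sample_id) {
  i <- match(sample_id, group_samples$sample_id)
  if (is.na(i)) 0L else group_samples$n[i]
}

#' Reconstruct a group's exon model from its key
#'
#' The consensus exon chain uses the TSS/TTS cluster representatives as
#' outer ends and the exact junction chain internally.
#'
#' @param group one-row slice of the group table.
#' @return 2-column start/end matrix, ascending genomic order.
#' @export
group_exons <- function(group) {
  tss <- group$tss_rep; tts <- group$tts_rep
  chain <- group$chain
  if (chain == "") {
    m <- cbind(start = min(tss, tts), end = max(tss, tts))
    return(m)
  }
  j <- do.call(rbind, lapply(strsplit(chain, ";", fixed = TRUE)[[1]],
                             function(s) as.numeric(strsplit(s, "-", fixed = TRUE)[[1]])))
  donors <- j[, 1]; acceptors <- j[, 2]
  if (group$strand == "+") {
    starts <- c(tss, acceptors)
    ends <- c(donors, tts)
  } else {
    # chain is in transcript (right-to-left) order; genomic ascending:
    starts <- c(tts, rev(donors))
    ends <- c(rev(acceptors), tss)
  }
  m <- cbind(start = starts, end = ends)
  m[order(m[, 1]), , drop = FALSE]
}

#' Is a group's consensus exon model self-consistent?
#'
#' With noisy data an end-cluster representative can fall on the wrong side
#' of the outermost splice site (e.g. a TTS representative upstream of the
#' final acceptor), leaving a negative-length terminal exon. Such groups
#' are real read classes but have no valid consensus model; they are
#' excluded from pseudo-transcript work and GFF output.
#'
#' @param group one-row group slice.
#' @return TRUE when every consensus exon has start <= end.
#' @export
group_model_valid <- function(group) {
  ex <- group_exons(group)
  all(ex[, 1] <= ex[, 2])
}

#' Roll transcript groups up to splice-chain-only classes
#'
#' Collapses groups that differ only in their TSS/TTS clusters but share the
#' exact splice chain, the coarser granularity sometimes used when counting
#' "splice patterns".
#'
#' @param groups group table from [build_groups()].
#' @return tibble (strand, chain, n_groups, total_count).
#' @export
rollup_splice_chains <- function(groups) {
  groups |>
    dplyr::group_by(.data$strand, .data$chain) |>
    dplyr::summarise(n_groups = dplyr::n(),
                     total_count = sum(.data$total_count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_count))
}

#' Splice donor/acceptor usage table with genomic dinucleotides
#'
#' Every distinct junction observed in the reads, with usage counts and the
#' intronic dinucleotides flanking it: the two intronic bases immediately
#' after the donor (canonically GT on the coding strand) and the two
#' immediately before the acceptor (canonically AG). For minus-strand
#' junctions the dinucleotides are read from the reverse complement.
#' Junctions at the genome edge report a partial dinucleotide with a warning.
#'
#' @param reads read table.
#' @param genome `DNAStringSet` or FASTA path (single reference sequence).
#' @return tibble (strand, donor, acceptor, count, donor_dinuc,
#'   acceptor_dinuc).
#' @export
splice_site_table <- function(reads, genome) {
  genome <- load_genome(genome)
  seq <- genome[[1]]
  glen <- length(seq)
  j <- all_junctions(reads)
  if (nrow(j) == 0L) {
    return(tibble::tibble(strand = character(0), donor = numeric(0),
                          acceptor = numeric(0), count = integer(0),
                          donor_dinuc = character(0),
                          acceptor_dinuc = character(0)))
  }
  tab <- dplyr::count(j, .data$strand, .data$donor, .data$acceptor,
                      name = "count")
  safe_sub <- function(from, to) {
    f <- max(1L, from); t <- min(glen, to)
    if (f > t) return("")
    as.character(Biostrings::subseq(seq, f, t))
  }
  n <- nrow(tab)
  dd <- character(n); ad <- character(n)
  partial <- FALSE
  for (i in seq_len(n)) {
    if (tab$strand[i] == "+") {
      dd[i] <- safe_sub(tab$donor[i] + 1, tab$donor[i] + 2)
      ad[i] <- safe_sub(tab$acceptor[i] - 2, tab$acceptor[i] - 1)
    } else {
      rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      dd[i] <- rc(safe_sub(tab$donor[i] - 2, tab$donor[i] - 1))
      ad[i] <- rc(safe_sub(tab$acceptor[i] + 1, tab$acceptor[i] + 2))
    }
    if (nchar(dd[i]) < 2 || nchar(ad[i]) < 2) partial <- TRUE
  }
  if (partial) warning("junction at genome edge: partial dinucleotide reported")
  tibble::tibble(strand = tab$strand, donor = tab$donor,
                 acceptor = tab$acceptor, count = as.integer(tab$count),
                 donor_dinuc = dd, acceptor_dinuc = ad)
}

#' Write the transcript-group TSV (key fields flattened, per-sample counts
#' and polyA summaries as wide columns)
#'
#' @param groups group table.
#' @param path output path.
#' @param min_count report filter: groups with fewer total reads are omitted
#'   from the file (data are never discarded upstream). Default 1.
#' @return invisibly, the path.
#' @export
write_group_table <- function(groups, path, min_count = 1) {
  g <- groups[groups$total_count >= min_count, ]
  sample_ids <- sort(unique(unlist(lapply(g$samples, function(s) s$sample_id))))
  base <- data.frame(group_id = g$group_id, strand = g$strand,
                     tss = g$tss_rep, tts = g$tts_rep, chain = g$chain,
                     n_junctions = g$n_junctions, total_count = g$total_count)
  for (sid in sample_ids) {
    base[[paste0("n_", sid)]] <-
      vapply(g$samples, group_sample_count, numeric(1), sample_id = sid)
    base[[paste0("polya_mean_", sid)]] <- vapply(g$samples, function(s) {
      i <- match(sid, s$sample_id); if (is.na(i)) NA_real_ else s$polya_mean[i]
    }, numeric(1))
    base[[paste0("polya_sd_", sid)]] <- vapply(g$samples, function(s) {
      i <- match(sid, s$sample_id); if (is.na(i)) NA_real_ else s$polya_sd[i]
    }, numeric(1))
    base[[paste0("polya_n_", sid)]] <- vapply(g$samples, function(s) {
      i <- match(sid, s$sample_id); if (is.na(i)) 0 else s$polya_n[i]
    }, numeric(1))
  }
  utils::write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
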