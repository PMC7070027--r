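# Synthetic spliced-transcriptome simulator.
#
# Generates a miniature double-stranded "virus" genome with multiple
# promoters and termination sites on both strands, alternative splice
# chains sharing promoters, and a canonical feature table — plus simulated
# nanopore-like spliced alignments (SAM), a nanopolish-style per-read polyA
# table, and a matched short-read junction set, all with complete ground
# truth. The noise model mirrors what direct RNA-seq shows on real
# promoter-mapped genomes: 5' ends under-read by ~8-15 nt, random breakage
# producing internal 5' ends, jittered 3' ends, end soft-clipping with a
# small 5' mode and a larger 3' mode, and per-sample polyA mean shifts.
#
# Design note: all non-coding fill (intergenic DNA, UTRs, intron interiors,
# promoter-upstream extension windows) is drawn from a {C,A} alphabet on the
# coding strand, which makes it impossible for a spurious AUG to arise
# upstream of, or spanning into, a designed start codon; designed ORFs are
# then laid on top. make_genome() verifies every isoform's intended
# annotation at build time and aborts on infeasible geometry.

SIM_SEQNAME <- "synthvirus"

#' Simulator configuration
#'
#' @param seed integer master seed; every stochastic stage derives its seed
#'   from it.
#' @param genome_length genome size in nt (>= 15000 for the built-in layout).
#' @param reads_per_sample reads simulated per sample.
#' @param n_samples number of time-point samples.
#' @param truncation5 length-2 vector: uniform range (nt) of 5'-end
#'   under-read. Default c(8, 15).
#' @param tts_jitter max absolute 3'-end jitter in nt (uniform on
#'   -jitter..jitter). Default 5.
#' @param fragmentation_rate probability that a read's 5' end is instead
#'   uniform within the transcript (RNA breakage before sequencing).
#' @param polya_decline multiplicative per-sample change in mean polyA
#'   length (0.8 = 20% shorter per successive time point).
#' @param polya_sdlog lognormal sdlog of per-read polyA lengths.
#' @param polya_pass_rate fraction of reads QC-tagged PASS.
#' @param illumina_dropout probability that a true junction is missing from
#'   the simulated short-read junction set.
#' @return config list.
#' @export
sim_config <- function(seed = 1, genome_length = 20000,
                       reads_per_sample = 3000, n_samples = 3,
                       truncation5 = c(8, 15), tts_jitter = 5,
                       fragmentation_rate = 0.05, polya_decline = 0.8,
                       polya_sdlog = 0.4, polya_pass_rate = 0.6,
                       illumina_dropout = 0.05) {
  stopifnot(genome_length >= 15000, length(truncation5) == 2,
            truncation5[1] <= truncation5[2], tts_jitter >= 0,
            fragmentation_rate >= 0, fragmentation_rate <= 1)
  list(seed = as.integer(seed), genome_length = as.integer(genome_length),
       reads_per_sample = as.integer(reads_per_sample),
       n_samples = as.integer(n_samples), truncation5 = truncation5,
       tts_jitter = tts_jitter, fragmentation_rate = fragmentation_rate,
       polya_decline = polya_decline, polya_sdlog = polya_sdlog,
       polya_pass_rate = polya_pass_rate,
       illumina_dropout = illumina_dropout)
}

# non-stop sense codons for random coding sequence
.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# codons free of A..T runs that could seed an ATG within or across codons
.quiet_codons <- c("GCC", "GGC", "CTC", "CCC", "GAC", "CAC")

# random ORF: ATG + (aa-1) sense codons + TAA; aa = residues incl. Met
.random_orf <- function(aa, quiet = FALSE) {
  pool <- if (quiet) .quiet_codons else .sense_codons()
  paste0("ATG", paste(sample(pool, aa - 1, replace = TRUE), collapse = ""),
         "TAA")
}

#' Build the synthetic genome, feature table and isoform definitions
#'
#' The layout is fixed (deterministic coordinates); the master seed controls
#' fill sequence and random codon choice only, so the truth tables are
#' identical across seeds and the FASTA is byte-identical for a given seed.
#' The design covers, by construction: unspliced, multi-exon (up to 2
#' junctions), minus-strand, alternative splice chains sharing a promoter,
#' a second-Methionine isoform (decoy upstream ORF), a truncated-ORF
#' isoform (splice into the coding sequence), and a no-known-ORF isoform.
#' All introns are GT/AG on the coding strand.
#'
#' @param config from [sim_config()].
#' @return truth list: genome (`DNAStringSet`), features tibble, isoforms
#'   tibble (isoform_id, strand, exons, tss, tts, chain, protein,
#'   expect_flag, polya_mean, weight, weight_factor), junctions tibble,
#'   known_sites tibble, config.
#' @export
make_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  glen <- config$genome_length
  g <- sample(c("C", "A"), glen, replace = TRUE)

  put <- function(at, s) {
    ch <- strsplit(s, "")[[1]]
    g[at:(at + length(ch) - 1L)] <<- ch
    invisible(NULL)
  }
  put_rc <- function(from, to, s) {
    # write transcript-sense string s (length to-from+1) as minus-strand
    stopifnot(nchar(s) == to - from + 1)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    put(from, rc)
  }
  fill_tx <- function(n) paste(sample(c("C", "A"), n, replace = TRUE),
                               collapse = "")

  ## ---- plus strand ----
  # unit A: 5 nt 5'UTR, so the start codon sits within reach of the default
  # 10 nt extension for the whole 8-15 nt under-read range
  orfA <- .random_orf(120)                      # [1506..1868]
  put(1501, "CACAC"); put(1506, orfA)
  put(1626, "GT")                               # codon 41 forced GTx: A3 donor
  put(1906, "GT"); put(2044, "AG")              # A2/A3 intron boundaries

  # unit B: decoy 15-aa ORF upstream of the canonical protB AUG
  orfB_decoy <- .random_orf(15, quiet = TRUE)   # [2651..2698]
  orfB <- .random_orf(90)                       # [2729..3001]
  put(2651, orfB_decoy); put(2729, orfB)

  # unit L: shared 2-exon leader, five alternative coding exons + exon2 skip
  put(4101, "GT"); put(4239, "AG")              # intron 1
  put(4321, "GT")                               # shared donor after exon 2
  l_acc <- c(4501, 5201, 5901, 6601, 7301)
  l_aa <- c(120, 100, 110, 90, 130)
  for (i in seq_along(l_acc)) {
    put(l_acc[i] - 2L, "AG")
    put(l_acc[i] + 4L, .random_orf(l_aa[i]))
  }

  # unit N: ORF deliberately absent from the feature table
  put(8021, .random_orf(60))

  ## ---- minus strand ----
  # unit C: 5 nt 5'UTR, ORF split across the junction
  orfC <- .random_orf(115)                      # 348 nt
  put_rc(11701, 12000, paste0("CACAC", substr(orfC, 1, 295)))
  put_rc(11201, 11500, paste0(substr(orfC, 296, 348), fill_tx(247)))
  put_rc(11001, 11100, fill_tx(100))            # C2 terminal exon
  put_rc(11051, 11200, fill_tx(150))            # C3 extended 3' region
  put(11699, "AC"); put(11501, "CT")            # intron 1 (GT/AG on '-')
  put(11399, "AC"); put(11101, "CT")            # intron 2

  # unit D: unspliced minus-strand, 5 nt 5'UTR
  orfD <- .random_orf(100)                      # 303 nt
  put_rc(13501, 14000, paste0("CACAC", orfD, fill_tx(500 - 5 - 303)))

  genome <- Biostrings::DNAStringSet(paste(g, collapse = ""))
  names(genome) <- SIM_SEQNAME

  features <- tibble::tibble(
    name = c("protA", "protB", paste0("protL", 1:5), "protC", "protD"),
    strand = c(rep("+", 7), "-", "-"),
    start_codon_pos = c(1506, 2729, l_acc + 4L, 11995, 13995),
    cds_end = c(1868, 3001, l_acc + 4L + 3 * (l_aa + 1) - 1, 11448, 13693),
    expected_aa = c(120, 90, l_aa, 115, 100))

  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  }
  iso <- list(
    list("A1", "+", ex(1501, 2000), "protA", "none", 100, 6, 0.6),
    list("A2", "+", ex(1501, 1905, 2046, 2185), "protA", "none", 95, 2, 0.6),
    list("A3", "+", ex(1501, 1625, 2046, 2185), "protA", "truncated", 90, 1, 0.6),
    list("B1", "+", ex(2601, 3080), "protB", "second_methionine", 110, 4, 0.6),
    list("N1", "+", ex(8001, 8400), NA, "no_known_orf", 80, 1.5, 1.0),
    list("L1", "+", ex(4001, 4100, 4241, 4320, 4501, 5000), "protL1", "none", 85, 1, 2.5),
    list("L2", "+", ex(4001, 4100, 4241, 4320, 5201, 5700), "protL2", "none", 90, 0.8, 2.5),
    list("L3", "+", ex(4001, 4100, 4241, 4320, 5901, 6400), "protL3", "none", 95, 0.6, 2.5),
    list("L4", "+", ex(4001, 4100, 4241, 4320, 6601, 7100), "protL4", "none", 100, 0.5, 2.5),
    list("L5", "+", ex(4001, 4100, 4241, 4320, 7301, 7800), "protL5", "none", 105, 1, 2.5),
    list("L6", "+", ex(4001, 4100, 4501, 5000), "protL1", "none", 88, 0.2, 2.5),
    list("C1", "-", ex(11201, 11500, 11701, 12000), "protC", "none", 120, 5, 0.6),
    list("C2", "-", ex(11001, 11100, 11401, 11500, 11701, 12000), "protC", "none", 115, 2, 0.6),
    list("C3", "-", ex(11051, 11500, 11701, 12000), "protC", "none", 105, 1, 0.6),
    list("D1", "-", ex(13501, 14000), "protD", "none", 130, 3, 0.6))

  isoforms <- dplyr::bind_rows(lapply(iso, function(x) {
    exm <- x[[3]]
    std <- x[[2]]
    tibble::tibble(
      isoform_id = x[[1]], strand = std, exons = list(exm),
      tss = unname(if (std == "+") exm[1, 1] else exm[nrow(exm), 2]),
      tts = unname(if (std == "+") exm[nrow(exm), 2] else exm[1, 1]),
      chain = junction_chain(exm, std),
      protein = x[[4]], expect_flag = x[[5]], polya_mean = x[[6]],
      weight = x[[7]], weight_factor = x[[8]])
  }))

  jn <- dplyr::bind_rows(lapply(seq_len(nrow(isoforms)), function(i)
    junctions_of(isoforms$exons[[i]], isoforms$strand[i])))
  junctions <- dplyr::distinct(jn, .data$donor, .data$acceptor, .data$strand)

  known_sites <- dplyr::bind_rows(
    tibble::tibble(name = paste0("TSS_", isoforms$isoform_id),
                   position = isoforms$tss, strand = isoforms$strand),
    tibble::tibble(name = paste0("TTS_", isoforms$isoform_id),
                   position = isoforms$tts, strand = isoforms$strand))
  known_sites <- known_sites[!duplicated(paste(known_sites$position,
                                               known_sites$strand)), ]

  truth <- list(genome = genome, features = features, isoforms = isoforms,
                junctions = junctions, known_sites = known_sites,
                config = config)
  verify_truth(truth)
  truth
}

# build-time self-check: each isoform's consensus model must annotate to its
# designed protein and flags under default parameters (extension 10)
verify_truth <- function(truth) {
  feats <- truth$features
  for (i in seq_len(nrow(truth$isoforms))) {
    it <- truth$isoforms[i, ]
    grp <- tibble::tibble(group_id = it$isoform_id,
                          group_key = it$isoform_id, strand = it$strand,
                          tss_rep = it$tss, tts_rep = it$tts,
                          chain = it$chain)
    ann <- annotate_group(grp, truth$genome, feats,
                          extension = 10, min_aa = 10)
    ok <- switch(it$expect_flag,
      none = identical(ann$matched_feature, it$protein) &&
        ann$match_rank == 1L && !ann$truncated,
      truncated = identical(ann$matched_feature, it$protein) && ann$truncated,
      second_methionine = identical(ann$matched_feature, it$protein) &&
        ann$second_methionine,
      no_known_orf = ann$no_known_orf)
    if (!isTRUE(ok)) {
      stop("infeasible simulator geometry: isoform ", it$isoform_id,
           " annotates as ", ann$matched_feature %||% "<none>",
           " (rank ", ann$match_rank, ") instead of designed ",
           it$protein %||% "<no known ORF>", " / ", it$expect_flag)
    }
  }
  invisible(TRUE)
}

# trim t nt from the transcript 5' end and shift the 3' end by delta
# (positive = extend beyond the TTS); exons in ascending genomic order
trim_exons <- function(exons, strand, trim5 = 0, delta3 = 0, glen = Inf) {
  m <- exons
  take5 <- function(m, t, from_left) {
    while (t > 0 && nrow(m) > 0) {
      i <- if (from_left) 1L else nrow(m)
      w <- m[i, 2] - m[i, 1] + 1
      if (t >= w) {
        m <- m[-i, , drop = FALSE]; t <- t - w
      } else {
        if (from_left) m[i, 1] <- m[i, 1] + t else m[i, 2] <- m[i, 2] - t
        t <- 0
      }
    }
    m
  }
  if (strand == "+") {
    m <- take5(m, trim5, from_left = TRUE)
    if (nrow(m)) {
      if (delta3 >= 0) m[nrow(m), 2] <- min(glen, m[nrow(m), 2] + delta3)
      else m <- take5(m, -delta3, from_left = FALSE)
    }
  } else {
    m <- take5(m, trim5, from_left = FALSE)
    if (nrow(m)) {
      if (delta3 >= 0) m[1, 1] <- max(1, m[1, 1] - delta3)
      else m <- take5(m, -delta3, from_left = TRUE)
    }
  }
  m
}

#' Simulate one sample's nanopore-like alignments and polyA table
#'
#' Reads are drawn per isoform with per-sample weights
#' (`weight * weight_factor^(sample-1)`, so "late" units rise over time),
#' their 5' ends truncated by a uniform draw from `truncation5` (or, with
#' probability `fragmentation_rate`, placed uniformly within the transcript
#' to mimic RNA breakage), their 3' ends jittered, and soft clips added with
#' a small 5' mode (1-2 nt) and a larger 3' mode. Emitted as mapped SAM
#' records (the pipeline contract starts at spliced alignments), alongside a
#' nanopolish-style polyA TSV (PASS at `polya_pass_rate`, lognormal lengths
#' whose class mean declines by `polya_decline` per sample) and a per-read
#' provenance table. Deterministic given (config seed, sample index).
#'
#' @param truth from [make_genome()].
#' @param sample_index 1-based time-point index.
#' @param dir output directory.
#' @param sample_id label (default `sampleN`).
#' @return list(sample_id, sam, polya, provenance = tibble and path).
#' @export
simulate_reads <- function(truth, sample_index, dir,
                           sample_id = paste0("sample", sample_index)) {
  config <- truth$config
  set.seed(config$seed + 7919L * sample_index)
  iso <- truth$isoforms
  glen <- config$genome_length
  gchar <- as.character(truth$genome[[1]])
  n <- config$reads_per_sample
  w <- iso$weight * iso$weight_factor^(sample_index - 1)
  pick <- sample.int(nrow(iso), n, replace = TRUE, prob = w / sum(w))

  sam <- character(n)
  rid_v <- character(n); tag_v <- character(n); plen_v <- numeric(n)
  t5_v <- integer(n); j3_v <- integer(n); frag_v <- logical(n)
  iso_strand <- iso$strand[pick]
  iso_pamean <- iso$polya_mean[pick]
  for (r in seq_len(n)) {
    exm <- iso$exons[[pick[r]]]
    strand_r <- iso_strand[r]
    txlen <- sum(exm[, 2] - exm[, 1] + 1)
    fragment <- stats::runif(1) < config$fragmentation_rate
    t5 <- if (fragment) {
      sample.int(max(1L, txlen - 60L), 1)
    } else if (config$truncation5[2] > 0) {
      sample(config$truncation5[1]:config$truncation5[2], 1)
    } else 0L
    j3 <- if (config$tts_jitter > 0)
      sample(seq.int(-config$tts_jitter, config$tts_jitter), 1) else 0L
    obs <- trim_exons(exm, strand_r, trim5 = t5, delta3 = j3, glen = glen)
    if (nrow(obs) == 0L) obs <- exm  # degenerate draw: keep the full model
    clip5 <- sample(0:3, 1, prob = c(0.30, 0.35, 0.25, 0.10))
    clip3 <- sample(0:6, 1, prob = c(0.05, 0.15, 0.30, 0.25, 0.15, 0.07, 0.03))
    rid <- sprintf("%s_r%05d", sample_id, r)
    aligned <- paste(substring(gchar, obs[, 1], obs[, 2]), collapse = "")
    lead <- if (strand_r == "+") clip5 else clip3
    trail <- if (strand_r == "+") clip3 else clip5
    seq_out <- paste0(strrep("A", lead), aligned, strrep("A", trail))
    cigar <- exons_to_cigar(obs, clip5, clip3, strand_r)
    flag <- if (strand_r == "+") 0L else 16L
    sam[r] <- paste(rid, flag, SIM_SEQNAME, obs[1, 1], 60L, cigar,
                    "*", 0L, 0L, seq_out, "*", sep = "\t")
    pass <- stats::runif(1) < config$polya_pass_rate
    mu <- iso_pamean[r] * config$polya_decline^(sample_index - 1)
    plen <- stats::rlnorm(1, log(mu) - config$polya_sdlog^2 / 2,
                          config$polya_sdlog)
    tag <- if (pass) "PASS" else
      sample(c("SUFFCLIP", "ADAPTER", "NOREGION"), 1)
    rid_v[r] <- rid; tag_v[r] <- tag; plen_v[r] <- round(plen, 2)
    t5_v[r] <- t5; j3_v[r] <- j3; frag_v[r] <- fragment
  }

  sam_path <- file.path(dir, paste0(sample_id, ".sam"))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", SIM_SEQNAME, "\tLN:", glen),
               sam), sam_path)
  polya <- tibble::tibble(readname = rid_v, contig = SIM_SEQNAME,
                          polya_length = plen_v, qc_tag = tag_v)
  polya_path <- file.path(dir, paste0(sample_id, "_polya.tsv"))
  utils::write.table(as.data.frame(polya), polya_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  provenance <- tibble::tibble(read_id = rid_v,
                               isoform_id = iso$isoform_id[pick],
                               truncation = t5_v, fragment = frag_v,
                               tts_jitter = j3_v, true_polya = plen_v,
                               qc_tag = tag_v)
  prov_path <- file.path(dir, paste0(sample_id, "_provenance.tsv"))
  utils::write.table(as.data.frame(provenance), prov_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(sample_id = sample_id, sam = sam_path, polya = polya_path,
       provenance = provenance, provenance_path = prov_path)
}

#' Simulate a matched short-read junction set
#'
#' Every true junction is retained independently with probability
#' 1 - dropout; support counts are Poisson(50) + 1.
#'
#' @param truth from [make_genome()].
#' @param dropout per-junction dropout probability.
#' @param seed RNG seed.
#' @return junction tibble (donor, acceptor, strand, support).
#' @export
simulate_illumina_junctions <- function(truth,
                                        dropout = truth$config$illumina_dropout,
                                        seed = truth$config$seed) {
  set.seed(seed + 104729L)
  j <- truth$junctions
  keep <- stats::runif(nrow(j)) >= dropout
  out <- j[keep, ]
  out$support <- stats::rpois(nrow(out), 50) + 1L
  out
}

#' Write a full synthetic dataset to a directory
#'
#' Emits genome FASTA, feature TSV, known-sites TSV, per-sample SAM / polyA
#' TSV / provenance TSV, a short-read junction TSV, and a truth isoform
#' table.
#'
#' @param config from [sim_config()].
#' @param dir output directory (created if needed).
#' @return truth list with an added `paths` element.
#' @export
sim_write_all <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_genome(config)
  genome_path <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(truth$genome, genome_path)
  features_path <- file.path(dir, "features.tsv")
  utils::write.table(as.data.frame(truth$features), features_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sites_path <- file.path(dir, "known_sites.tsv")
  utils::write.table(as.data.frame(truth$known_sites), sites_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  samples <- lapply(seq_len(config$n_samples), simulate_reads, truth = truth,
                    dir = dir)
  jset <- simulate_illumina_junctions(truth)
  junctions_path <- file.path(dir, "illumina_junctions.tsv")
  write_junctions(jset, junctions_path, format = "tsv")
  iso_out <- truth$isoforms
  iso_out$exons <- vapply(iso_out$exons, exons_to_string, character(1))
  iso_path <- file.path(dir, "truth_isoforms.tsv")
  utils::write.table(as.data.frame(iso_out), iso_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth$paths <- list(genome = genome_path, features = features_path,
                      known_sites = sites_path, junctions = junctions_path,
                      isoforms = iso_path,
                      sam = vapply(samples, `[[`, "", "sam"),
                      polya = vapply(samples, `[[`, "", "polya"),
                      sample_ids = vapply(samples, `[[`, "", "sample_id"))
  truth
}
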