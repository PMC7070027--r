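# Pseudo-transcripts, ORF scanning, canonical matching and GFF output.

tiny_genome <- function(s, name = "ref") {
  g <- Biostrings::DNAStringSet(s)
  names(g) <- name
  g
}

grp_row <- function(strand, tss, tts, chain = "", id = "TG00001") {
  tibble::tibble(group_id = id, group_key = id, strand = strand,
                 tss_rep = tss, tts_rep = tts, chain = chain)
}

test_that("pseudo-transcripts splice, extend and clip correctly", {
  g <- tiny_genome("AAATGCCCGGGTTT")
  ps <- build_pseudo_transcript(grp_row("+", 3, 11, "5-9"), g, extension = 0)
  expect_equal(ps$sequence, "ATGGGG")
  expect_equal(ps$coord_map, c(3, 4, 5, 9, 10, 11))
  expect_equal(ps$extension, 0)

  # extension walks upstream in transcript orientation
  ext <- build_pseudo_transcript(grp_row("+", 12, 14), g, extension = 4)
  expect_equal(ext$sequence, substr("AAATGCCCGGGTTT", 8, 14))
  expect_equal(ext$coord_map[1], 8)

  # clipped at the genome start, achieved extension recorded
  clip <- build_pseudo_transcript(grp_row("+", 4, 8), g, extension = 10)
  expect_equal(clip$extension, 3)
  expect_equal(clip$coord_map[1], 1)

  # minus strand: reverse complement, descending coordinate map
  mg <- tiny_genome("CCCCATGGCCC")
  mps <- build_pseudo_transcript(grp_row("-", 7, 5), mg, extension = 2)
  expect_equal(mps$sequence, "GCCAT")   # rev-comp of genomic [5..9] "ATGGC"
  expect_equal(mps$coord_map, c(9, 8, 7, 6, 5))
  expect_error(build_pseudo_transcript(grp_row("+", 5, 99), g, 0),
               "outside genome")
})

test_that("ORF scanning finds complete and incomplete frames", {
  g <- tiny_genome("GGATGAAATAGCC")
  ps <- build_pseudo_transcript(grp_row("+", 1, 13), g, extension = 0)
  orfs <- scan_orfs(ps, min_aa = 2)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$tx_start, 3)
  expect_equal(orfs$tx_end, 11)
  expect_true(orfs$complete)
  expect_equal(orfs$aa_len, 2)     # "MK"
  # dropped below min_aa unless canonical
  expect_equal(nrow(scan_orfs(ps, min_aa = 10)), 0)
  feats <- tibble::tibble(name = "tiny", strand = "+", start_codon_pos = 3,
                          cds_end = 11, expected_aa = 2)
  kept <- scan_orfs(ps, min_aa = 10, features = feats)
  expect_equal(nrow(kept), 1)

  expect_equal(nrow(scan_orfs(
    build_pseudo_transcript(grp_row("+", 1, 5), tiny_genome("CCCCC"), 0))), 0)

  # no stop before the end -> incomplete, runs to the transcript end
  inc <- build_pseudo_transcript(grp_row("+", 1, 8),
                                 tiny_genome("ATGAAAAA"), 0)
  io <- scan_orfs(inc, min_aa = 1)
  expect_false(io$complete[1])
  expect_equal(io$aa_len[1], 2)
})

test_that("canonical matching is positional with truncation flags", {
  feats <- read_features(tibble::tibble(
    name = c("F", "G"), strand = c("+", "+"),
    start_codon_pos = c(10, 100), cds_end = c(40, 130),
    expected_aa = c(9, NA)))
  orf_full <- tibble::tibble(complete = TRUE, aa_len = 9, start_genomic = 10)
  expect_equal(match_canonical(orf_full, "+", feats)$name, "F")
  expect_false(match_canonical(orf_full, "+", feats)$truncated)
  orf_short <- tibble::tibble(complete = TRUE, aa_len = 4, start_genomic = 10)
  expect_true(match_canonical(orf_short, "+", feats)$truncated)
  orf_miss <- tibble::tibble(complete = TRUE, aa_len = 9, start_genomic = 11)
  expect_true(is.na(match_canonical(orf_miss, "+", feats)$name))
  # wrong strand never matches
  expect_true(is.na(match_canonical(orf_full, "-", feats)$name))

  expect_error(read_features(tibble::tibble(
    name = c("X", "Y"), strand = "+", start_codon_pos = 5, cds_end = 20)),
    "share a start codon")
})

test_that("5'-most-ORF rule with next-AUG fallback sets the flags", {
  # transcript: decoy short ORF, then canonical ORF
  s <- paste0("CC", "ATGAAAAAATAG", "CC", "ATGCCCAAACCCAAATAA", "CC")
  g <- tiny_genome(s)
  feats <- tibble::tibble(name = "canon", strand = "+",
                          start_codon_pos = 17, cds_end = 34,
                          expected_aa = 5)
  grp <- grp_row("+", 1, nchar(s))
  ann1 <- annotate_group(grp, g, feats, extension = 0, min_aa = 3)
  expect_equal(ann1$matched_feature, "canon")
  expect_true(ann1$second_methionine)   # decoy (3 aa) is rank 1
  expect_equal(ann1$match_rank, 2L)

  # with the decoy filtered out by min_aa the canonical ORF is rank 1
  ann2 <- annotate_group(grp, g, feats, extension = 0, min_aa = 5)
  expect_false(ann2$second_methionine)
  expect_equal(ann2$match_rank, 1L)

  none <- annotate_group(grp, g, feats[0, ], extension = 0, min_aa = 3)
  expect_true(none$no_known_orf)
})

test_that("genomic blocks of a spliced ORF reproduce its sequence", {
  sim <- sim_noise_free()
  ann <- annotate_groups(sim$groups, sim$truth$genome, sim$truth$features)
  gchar <- as.character(sim$truth$genome[[1]])
  for (i in which(!ann$no_known_orf)) {
    grp <- sim$groups[sim$groups$group_id == ann$group_id[i], ]
    ps <- build_pseudo_transcript(grp, sim$truth$genome, 10)
    orf <- ann$orf_calls[[i]]
    orf <- orf[orf$rank == ann$match_rank[i], ]
    blocks <- orf$blocks[[1]]
    spliced <- paste(substring(gchar, blocks[, 1], blocks[, 2]),
                     collapse = "")
    if (grp$strand == "-") {
      spliced <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(spliced)))
    }
    expect_equal(spliced, substr(ps$sequence, orf$tx_start, orf$tx_end))
  }
})

test_that("growing the extension only prepends ORFs, never demotes", {
  sim <- sim_noise_free()
  for (i in seq_len(min(nrow(sim$groups), 10))) {
    ps0 <- build_pseudo_transcript(sim$groups[i, ], sim$truth$genome, 0)
    ps10 <- build_pseudo_transcript(sim$groups[i, ], sim$truth$genome, 10)
    o0 <- scan_orfs(ps0, features = sim$truth$features)
    o10 <- scan_orfs(ps10, features = sim$truth$features)
    expect_true(all(o0$start_genomic %in% o10$start_genomic))
    if (nrow(o0)) {
      r0 <- o0$rank
      r10 <- o10$rank[match(o0$start_genomic, o10$start_genomic)]
      expect_true(all(r10 >= r0))
    }
  }
})

test_that("dominant transcript selection and usage percentages", {
  sim <- sim_noise_free()
  ann <- annotate_groups(sim$groups, sim$truth$genome, sim$truth$features)
  dom <- dominant_transcripts(ann, sim$groups)
  # protA has three rank-1 groups; the dominant one carries the most reads
  counts <- sim$groups$total_count[match(
    ann$group_id[!is.na(ann$matched_feature) &
                   ann$matched_feature == "protA" & ann$match_rank == 1],
    sim$groups$group_id)]
  expect_equal(dom$count[dom$feature == "protA"], max(counts))

  usage <- orf_usage_table(ann, sim$groups)
  # per sample the rank-1 percentages plus no-known-ORF never exceed 100
  for (sid in unique(usage$sample_id)) {
    expect_lte(sum(usage$percent[usage$sample_id == sid]), 100 + 1e-9)
  }
  # second-methionine reads (unit B) are excluded from rank-1 rows
  expect_false("protB" %in% usage$feature)
  expect_true("no known ORF" %in% usage$feature)

  tie <- tibble::tibble(
    group_id = c("g1", "g2"), group_key = c("g1", "g2"),
    matched_feature = "F", match_rank = 1L, second_methionine = FALSE,
    truncated = FALSE, incomplete = FALSE, no_known_orf = FALSE,
    n_orfs = 1L, orf_calls = list(NULL, NULL))
  gtie <- tibble::tibble(
    group_id = c("g1", "g2"), group_key = c("g1", "g2"), strand = "+",
    tss_rep = c(500, 100), tts_rep = 900, chain = "", n_junctions = 0L,
    total_count = c(10, 10),
    samples = list(tibble::tibble(sample_id = "s1", n = 10, polya_n = 0,
                                  polya_mean = NA_real_, polya_sd = NA_real_,
                                  member_ids = list("x")),
                   tibble::tibble(sample_id = "s1", n = 10, polya_n = 0,
                                  polya_mean = NA_real_, polya_sd = NA_real_,
                                  member_ids = list("y"))))
  expect_equal(dominant_transcripts(tie, gtie)$group_id, "g2")  # smaller TSS
})

test_that("GFF3 output round-trips the exon models", {
  sim <- sim_noise_free()
  ann <- annotate_groups(sim$groups, sim$truth$genome, sim$truth$features)
  path <- tempfile(fileext = ".gff3")
  write_gff(sim$groups, path, ann, mode = "all", seqname = "synthvirus")
  back <- rtracklayer::import(path)
  exons <- back[back$type == "exon"]
  for (i in seq_len(nrow(sim$groups))) {
    gid <- sim$groups$group_id[i]
    sub <- exons[vapply(exons$Parent, function(p) gid %in% p, logical(1))]
    m <- cbind(start = GenomicRanges::start(sub), end = GenomicRanges::end(sub))
    m <- m[order(m[, 1]), , drop = FALSE]
    expect_equal(unname(m), unname(group_exons(sim$groups[i, ])))
    expect_true(all(GenomicRanges::start(sub) <= GenomicRanges::end(sub)))
    expect_equal(unique(as.character(GenomicRanges::strand(sub))),
                 sim$groups$strand[i])
  }
})
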