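# CIGAR -> exon chain parsing, strand-aware clips, polyA attachment and
# read-level summaries.

test_that("spliced CIGARs parse to the documented exon chains and clips", {
  sam <- write_test_sam(c(
    sam_rec("fwd", 0, 1001, "5S100M200N50M3S"),
    sam_rec("rev", 16, 1001, "4S30M100N20M7S"),
    sam_rec("sec", 256, 1001, "50M"),
    sam_rec("sup", 2048, 1001, "50M"),
    sam_rec("unm", 4, 0, "*")))
  reads <- parse_alignments(sam, "s1")

  expect_equal(nrow(reads), 2)
  fwd <- reads[reads$read_id == "fwd", ]
  expect_equal(unname(fwd$exons[[1]][, "start"]), c(1001, 1301))
  expect_equal(unname(fwd$exons[[1]][, "end"]), c(1100, 1350))
  expect_equal(fwd$clip5, 5)
  expect_equal(fwd$clip3, 3)
  expect_equal(fwd$tss, 1001)
  expect_equal(fwd$tts, 1350)

  rev <- reads[reads$read_id == "rev", ]
  expect_equal(rev$strand, "-")
  expect_equal(unname(rev$exons[[1]][, "start"]), c(1001, 1131))
  expect_equal(unname(rev$exons[[1]][, "end"]), c(1030, 1150))
  # transcript orientation: leading CIGAR clip is the 3' clip on '-'
  expect_equal(rev$clip5, 7)
  expect_equal(rev$clip3, 4)
  expect_equal(rev$tss, 1150)
  expect_equal(rev$tts, 1001)

  sk <- attr(reads, "skipped")
  expect_equal(unname(sk["secondary"]), 1)
  expect_equal(unname(sk["supplementary"]), 1)
  expect_equal(unname(sk["unmapped"]), 1)
})

test_that("deletions stay intra-exon; only N opens an intron", {
  sam <- write_test_sam(sam_rec("d", 0, 101, "10M5D10M100N10M"))
  reads <- parse_alignments(sam, "s1")
  ex <- reads$exons[[1]]
  expect_equal(unname(ex[, "start"]), c(101, 226))
  expect_equal(unname(ex[, "end"]), c(125, 235))
})

test_that("reference name must match the genome when one is provided", {
  genome <- Biostrings::DNAStringSet(c(other = strrep("A", 2000)))
  sam <- write_test_sam(sam_rec("r", 0, 1, "100M"))
  expect_error(parse_alignments(sam, "s1", genome = genome),
               "does not match")
})

test_that("junctions_of orders donor/acceptor 5'->3' by strand", {
  plus <- junctions_of(cbind(c(1001, 1301), c(1100, 1350)), "+")
  expect_equal(plus$donor, 1100)
  expect_equal(plus$acceptor, 1301)

  single <- junctions_of(cbind(1001, 1100), "+")
  expect_equal(nrow(single), 0)

  minus <- junctions_of(cbind(c(100, 200, 300), c(150, 250, 350)), "-")
  expect_equal(minus$donor, c(300, 200))
  expect_equal(minus$acceptor, c(250, 150))
})

test_that("polyA usability needs a PASS tag and >= 20 nt", {
  reads <- dplyr::bind_rows(
    make_read("a", "+", c(1, 500)),
    make_read("b", "+", c(1, 500)),
    make_read("c", "+", c(1, 500)),
    make_read("d", "+", c(1, 500)))
  recs <- tibble::tibble(
    read_id = c("a", "b", "c"),
    qc_tag = c("PASS", "PASS", "SUFFCLIP"),
    polya_length = c(35.2, 15.0, 60.0))
  out <- attach_polya(reads, recs)
  expect_equal(out$polya_usable, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$polya_length[1], 35.2)
  expect_true(is.na(out$polya_qc[4]))  # recordless read retained

  dup <- dplyr::bind_rows(recs, tibble::tibble(
    read_id = "a", qc_tag = "PASS", polya_length = 99))
  expect_warning(out2 <- attach_polya(reads, dup), "duplicate")
  expect_equal(out2$polya_length[1], 35.2)
})

test_that("soft-clip profile: mean, and mode with ties to the smaller", {
  reads <- dplyr::bind_rows(lapply(seq_along(c(0, 1, 1, 2, 31)), function(i)
    make_read(paste0("r", i), "+", c(1, 100),
              clip5 = c(0, 1, 1, 2, 31)[i])))
  p <- softclip_profile(reads, "5prime")
  expect_equal(p$mean, 7)
  expect_equal(p$mode, 1)
  expect_equal(sum(p$histogram$count), 5)

  tie <- dplyr::bind_rows(lapply(seq_along(c(4, 4, 9, 9)), function(i)
    make_read(paste0("t", i), "+", c(1, 100), clip3 = c(4, 4, 9, 9)[i])))
  expect_equal(softclip_profile(tie, "3prime")$mode, 4)

  zero <- make_read("z", "+", c(1, 100))
  expect_equal(softclip_profile(zero, "5prime")$mean, 0)
  expect_equal(softclip_profile(zero, "5prime")$mode, 0)
  expect_error(softclip_profile(zero[0, ], "5prime"), "no reads")
})

test_that("read_stats summarises lengths deterministically", {
  reads <- dplyr::bind_rows(
    make_read("a", "+", c(1, 100)),
    make_read("b", "+", c(201, 300)),
    make_read("c", "+", c(1, 300)))
  s <- read_stats(reads)
  expect_equal(s$n, 3)
  expect_equal(s$longest, 300)
  expect_equal(s$mean_length, 500 / 3, tolerance = 1e-9)
  expect_equal(s$modal_length, 100)
  one <- read_stats(reads[1, ])
  expect_equal(unlist(one[c("longest", "mean_length", "modal_length")]),
               c(longest = 100, mean_length = 100, modal_length = 100))
})

test_that("exon chains survive CIGAR round trips and conserve widths", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    widths <- sample(20:200, k)
    gaps <- sample(10:150, k)        # introns of >= 10 nt
    starts <- 1000 + cumsum(gaps) + cumsum(c(0, widths[-k]))
    exons <- cbind(start = starts, end = starts + widths - 1)
    strand <- sample(c("+", "-"), 1)
    clip5 <- sample(0:5, 1); clip3 <- sample(0:5, 1)
    cig <- exons_to_cigar(exons, clip5, clip3, strand)
    sam <- write_test_sam(sam_rec("r", if (strand == "+") 0 else 16,
                                  exons[1, 1], cig))
    got <- parse_alignments(sam, "s")
    expect_equal(unname(got$exons[[1]]), unname(exons))
    expect_equal(got$clip5, clip5)
    expect_equal(got$clip3, clip3)
    # width conservation against the CIGAR's reference-consuming length
    ref_len <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig) -
      sum(exons[-1, 1] - exons[-k, 2] - 1)
    expect_equal(got$length, ref_len)
    # clip-free serialisation round-trips exactly
    expect_equal(exons_to_cigar(got$exons[[1]], 0, 0, strand),
                 exons_to_cigar(exons, 0, 0, strand))
    # junction count invariant
    expect_equal(nrow(junctions_of(got$exons[[1]], strand)), k - 1)
  }
})

test_that("read table TSV round-trips through write/read", {
  reads <- dplyr::bind_rows(
    make_read("a", "+", c(1, 100, 201, 300), polya_qc = "PASS",
              polya_length = 50, polya_usable = TRUE),
    make_read("b", "-", c(400, 500)))
  path <- tempfile(fileext = ".tsv")
  write_read_table(reads, path)
  back <- read_read_table(path)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$exons, lapply(reads$exons, unname) |>
                 lapply(function(m) {
                   colnames(m) <- c("start", "end"); m
                 }))
  expect_equal(back$polya_usable, reads$polya_usable)
})
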