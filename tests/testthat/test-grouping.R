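# Transcript grouping: windowed ends + exact junction chains.

keyed_fixture <- function() {
  reads <- dplyr::bind_rows(
    make_read("a", "+", c(1713, 1800, 2001, 2100), "s1"),
    make_read("b", "+", c(1716, 1800, 2001, 2100), "s1"),
    make_read("c", "+", c(1713, 1800, 2002, 2100), "s1"),
    make_read("d", "+", c(1713, 2100), "s2"))
  tss <- greedy_cluster(tally_ends(reads, "TSS"), 15)
  tts <- greedy_cluster(tally_ends(reads, "TTS"), 15)
  assign_groups(reads, tss, tts)
}

test_that("windowed ends share keys; 1-nt junction shifts split them", {
  keyed <- keyed_fixture()
  expect_equal(keyed$group_key[1], keyed$group_key[2])  # 1713 vs 1716
  expect_false(keyed$group_key[1] == keyed$group_key[3])  # acceptor +1 nt
  expect_equal(keyed$chain[4], "")                      # unspliced
})

test_that("build_groups counts, sorts and summarises polyA per sample", {
  reads <- dplyr::bind_rows(lapply(1:10, function(i) {
    key_exons <- if (i <= 6) c(100, 200) else if (i <= 9) c(300, 400)
      else c(500, 600)
    make_read(paste0("r", i), "+", key_exons,
              polya_qc = "PASS", polya_length = c(30, 40, 50)[(i %% 3) + 1],
              polya_usable = TRUE)
  }))
  tssc <- greedy_cluster(tally_ends(reads, "TSS"), 15)
  ttsc <- greedy_cluster(tally_ends(reads, "TTS"), 15)
  groups <- build_groups(assign_groups(reads, tssc, ttsc))
  expect_equal(groups$total_count, c(6, 3, 1))
  expect_equal(sum(groups$total_count), nrow(reads))

  pa <- dplyr::bind_rows(
    make_read("p1", "+", c(100, 200), polya_qc = "PASS", polya_length = 30,
              polya_usable = TRUE),
    make_read("p2", "+", c(100, 200), polya_qc = "PASS", polya_length = 40,
              polya_usable = TRUE),
    make_read("p3", "+", c(100, 200), polya_qc = "PASS", polya_length = 50,
              polya_usable = TRUE),
    make_read("p4", "+", c(100, 200)))
  g <- build_groups(assign_groups(pa, greedy_cluster(tally_ends(pa, "TSS"), 15),
                                  greedy_cluster(tally_ends(pa, "TTS"), 15)))
  s <- g$samples[[1]]
  expect_equal(s$polya_mean, 40)
  expect_equal(s$polya_sd, 10)
  expect_equal(s$polya_n, 3)
  expect_equal(s$n, 4)
})

test_that("incremental grouping equals batch grouping", {
  set.seed(7)
  base <- dplyr::bind_rows(lapply(1:30, function(i)
    make_read(paste0("r", i), "+",
              c(1000 + sample(0:10, 1), 2000, 3000, 4000 + sample(0:10, 1)))))
  extra <- make_read("extra", "+", c(1003, 2000, 3000, 4005))
  all_reads <- dplyr::bind_rows(base, extra)
  cl <- function(r) list(tss = greedy_cluster(tally_ends(r, "TSS"), 15),
                         tts = greedy_cluster(tally_ends(r, "TTS"), 15))
  ca <- cl(all_reads)
  batch <- build_groups(assign_groups(all_reads, ca$tss, ca$tts))
  incr <- build_groups(dplyr::bind_rows(
    assign_groups(base, ca$tss, ca$tts),
    assign_groups(extra, ca$tss, ca$tts)))
  expect_equal(batch$group_key, incr$group_key)
  expect_equal(batch$total_count, incr$total_count)
})

test_that("group_exons inverts the key on both strands", {
  for (std in c("+", "-")) {
    exm <- cbind(start = c(100, 300, 500), end = c(200, 400, 600))
    grp <- tibble::tibble(strand = std,
                          tss_rep = if (std == "+") 100 else 600,
                          tts_rep = if (std == "+") 600 else 100,
                          chain = nanotx:::junction_chain(exm, std))
    expect_equal(unname(group_exons(grp)), unname(exm))
  }
})

test_that("splice site table reads GT/AG dinucleotides strand-aware", {
  # genome: '+' intron at [151..249] and '-' intron at [501..599]
  g <- rep("A", 1000)
  g[151:152] <- c("G", "T"); g[248:249] <- c("A", "G")
  g[598:599] <- c("A", "C")  # revcomp "GT" after '-' donor 600
  g[501:502] <- c("C", "T")  # revcomp "AG" before '-' acceptor 500
  genome <- Biostrings::DNAStringSet(paste(g, collapse = ""))
  names(genome) <- "ref"
  reads <- dplyr::bind_rows(
    make_read("p", "+", c(100, 150, 250, 300)),
    make_read("m", "-", c(400, 500, 600, 700)))
  tab <- splice_site_table(reads, genome)
  plus <- tab[tab$strand == "+", ]
  expect_equal(plus$donor_dinuc, "GT")
  expect_equal(plus$acceptor_dinuc, "AG")
  minus <- tab[tab$strand == "-", ]
  expect_equal(minus$donor, 600)
  expect_equal(minus$acceptor, 500)
  expect_equal(minus$donor_dinuc, "GT")
  expect_equal(minus$acceptor_dinuc, "AG")

  edge <- make_read("e", "+", c(1, 999, 1000, 1000))
  expect_warning(splice_site_table(edge, genome), "genome edge")
})

test_that("splice-chain rollup collapses end variation only", {
  reads <- dplyr::bind_rows(
    make_read("a", "+", c(100, 200, 300, 400)),
    make_read("b", "+", c(140, 200, 300, 440)),  # same chain, far-apart ends
    make_read("c", "+", c(100, 210, 310, 400)))
  groups <- build_groups(assign_groups(
    reads, greedy_cluster(tally_ends(reads, "TSS"), 15),
    greedy_cluster(tally_ends(reads, "TTS"), 15)))
  expect_equal(nrow(groups), 3)
  roll <- rollup_splice_chains(groups)
  expect_equal(nrow(roll), 2)
  expect_equal(sort(roll$n_groups), c(1, 2))
})
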