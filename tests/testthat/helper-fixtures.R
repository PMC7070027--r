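# Shared fixtures: crafted SAM writers, read-table constructors, and
# independent brute-force oracles used against the package implementations.

cigar_query_len <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  sum(lens[ops %in% c("M", "I", "S", "=", "X")])
}

sam_rec <- function(qname, flag, pos, cigar, sn = "ref", mapq = 60) {
  paste(qname, flag, sn, pos, mapq, cigar, "*", 0, 0,
        strrep("A", cigar_query_len(cigar)), "*", sep = "\t")
}

write_test_sam <- function(records, sn = "ref", ln = 100000L,
                           path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6",
               paste0("@SQ\tSN:", sn, "\tLN:", format(ln, scientific = FALSE)),
               records), path)
  path
}

# one-row read table entry bypassing SAM parsing
make_read <- function(read_id, strand, exons, sample_id = "s1",
                      clip5 = 0, clip3 = 0, polya_qc = NA_character_,
                      polya_length = NA_real_, polya_usable = FALSE) {
  m <- matrix(exons, ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  tibble::tibble(
    read_id = read_id, sample_id = sample_id, strand = strand,
    exons = list(m), n_exons = nrow(m),
    length = sum(m[, 2] - m[, 1] + 1),
    tss = if (strand == "+") m[1, 1] else m[nrow(m), 2],
    tts = if (strand == "+") m[nrow(m), 2] else m[1, 1],
    clip5 = clip5, clip3 = clip3, polya_qc = polya_qc,
    polya_length = polya_length, polya_usable = polya_usable)
}

# ---- independent oracles -------------------------------------------------

# literal replay of the greedy windowed clustering rule
oracle_greedy <- function(pos, count, window) {
  out <- list()
  left <- rep(TRUE, length(pos))
  while (any(left)) {
    mx <- max(count[left])
    seed <- min(pos[left & count == mx])
    inwin <- left & abs(pos - seed) <= window
    out[[length(out) + 1L]] <- list(rep = seed, members = sort(pos[inwin]))
    left <- left & !inwin
  }
  out
}

# exact two-sided signed-rank p by enumeration of all 2^n sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null <- as.vector(signs %*% r)
  min(1, 2 * min(mean(null <= w), mean(null >= w)))
}

# exact two-sided Mann-Whitney p by enumeration of all C(n+m, n) splits
oracle_mann_whitney_p <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u <- u_of(x, y)
  pooled <- c(x, y)
  combs <- utils::combn(length(pooled), length(x))
  null <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(null <= u), mean(null >= u)))
}

# random site tally for clustering properties
random_tally <- function(n_pos = 30, span = 2000, max_count = 50,
                         role = "TSS", strand = "+") {
  pos <- sample.int(span, n_pos)
  tibble::tibble(role = role, strand = strand, pos = sort(pos),
                 count = sample.int(max_count, n_pos, replace = TRUE))
}

# small cached noise-free simulation shared across tests
sim_noise_free <- local({
  cache <- NULL
  function(reads = 600, seed = 11) {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(seed = seed, reads_per_sample = reads,
                      truncation5 = c(0, 0), tts_jitter = 0,
                      fragmentation_rate = 0)
    truth <- make_genome(cfg)
    dir <- tempfile("simnf")
    dir.create(dir)
    samples <- lapply(1:3, simulate_reads, truth = truth, dir = dir)
    reads_tbl <- dplyr::bind_rows(lapply(samples, function(s) {
      r <- parse_alignments(s$sam, s$sample_id, genome = truth$genome)
      attach_polya(r, read_polya_table(s$polya))
    }))
    tss <- greedy_cluster(tally_ends(reads_tbl, "TSS"), 15)
    tts <- greedy_cluster(tally_ends(reads_tbl, "TTS"), 15)
    keyed <- assign_groups(reads_tbl, tss, tts)
    groups <- build_groups(keyed)
    cache <<- list(truth = truth, samples = samples, reads = reads_tbl,
                   keyed = keyed, groups = groups, dir = dir)
    cache
  }
})
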