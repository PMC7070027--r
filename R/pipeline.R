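# Pipeline orchestration: a flat config drives the stages
# (classify -> annotate -> polya -> concord -> report), each writing
# deterministic TSV/GFF artifacts with a provenance header.

#' Read a pipeline configuration
#'
#' Flat key-value YAML. Recognised keys: genome, features, known_sites,
#' alignments (named map sample_id -> SAM/BAM path), polya (named map
#' sample_id -> TSV), junctions, sample_order (list), tss_window,
#' tts_window, extension, min_aa, min_polya, min_mapq, min_support,
#' require_polya_for_grouping, seed, outdir. Defaults mirror the standard
#' analysis: windows 15/15, extension 10, min_aa 10, min_polya 20.
#'
#' @param path YAML path, or a named list already in memory.
#' @return config list with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(tss_window = 15, tts_window = 15, extension = 10,
                   min_aa = 10, min_polya = 20, min_mapq = 0,
                   min_support = 1, require_polya_for_grouping = FALSE,
                   seed = 1, outdir = ".")
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  stopifnot(cfg$tss_window >= 0, cfg$tts_window >= 0, cfg$extension >= 0)
  cfg
}

# provenance header prepended to every pipeline TSV
provenance_header <- function(cfg, inputs = character(0)) {
  inputs <- as.character(inputs %||% character(0))
  cfg_txt <- tempfile()
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), cfg_txt)
  sums <- vapply(inputs[file.exists(inputs)], function(f)
    unname(tools::md5sum(f)), character(1))
  c(paste0("## nanotx ", as.character(utils::packageVersion("nanotx"))),
    paste0("## config_md5 ", unname(tools::md5sum(cfg_txt))),
    if (length(sums)) paste0("## input_md5 ", names(sums), " ", sums))
}

write_with_header <- function(writer, path, header) {
  tmp <- tempfile()
  writer(tmp)
  writeLines(c(header, readLines(tmp)), path)
  invisible(path)
}

#' Run the classification pipeline
#'
#' Stages run in dependency order; later subcommands read the TSV artifacts
#' of earlier ones from `outdir`, so `classify` must precede `annotate`,
#' `polya` and `concord`. `all` runs everything; `simulate` writes a
#' synthetic dataset into `outdir/simulated` and rewrites the config to
#' point at it. Outputs carry a provenance header (tool version, config
#' hash, input checksums), and read counts in and out of every filter are
#' logged via `message()`.
#'
#' @param subcommand one of classify, annotate, polya, concord, simulate,
#'   report, all.
#' @param config config list from [read_config()] (or a YAML path).
#' @return invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(subcommand = c("all", "classify", "annotate",
                                        "polya", "concord", "simulate",
                                        "report"),
                         config) {
  subcommand <- match.arg(subcommand)
  cfg <- read_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (subcommand == "simulate" || (subcommand == "all" &&
                                   is.null(cfg$alignments))) {
    simdir <- file.path(cfg$outdir, "simulated")
    truth <- sim_write_all(
      sim_config(seed = cfg$seed,
                 reads_per_sample = cfg$reads_per_sample %||% 3000), simdir)
    cfg$genome <- truth$paths$genome
    cfg$features <- truth$paths$features
    cfg$known_sites <- truth$paths$known_sites
    cfg$junctions <- truth$paths$junctions
    cfg$alignments <- as.list(stats::setNames(truth$paths$sam,
                                              truth$paths$sample_ids))
    cfg$polya <- as.list(stats::setNames(truth$paths$polya,
                                         truth$paths$sample_ids))
    cfg$sample_order <- as.list(truth$paths$sample_ids)
    paths$simulated <- simdir
    if (subcommand == "simulate") return(invisible(paths))
  }

  need <- function(key) {
    v <- cfg[[key]]
    if (is.null(v)) stop("config is missing required input: ", key)
    v
  }
  artifact <- function(name) file.path(cfg$outdir, name)
  require_artifact <- function(name) {
    p <- artifact(name)
    if (!file.exists(p)) {
      stop("missing artifact ", p, "; run the `classify` stage first")
    }
    p
  }
  hdr <- provenance_header(cfg, unlist(cfg[c("genome", "features",
                                             "junctions")], use.names = FALSE))

  do_classify <- subcommand %in% c("classify", "all")
  do_annotate <- subcommand %in% c("annotate", "all")
  do_polya <- subcommand %in% c("polya", "all")
  do_concord <- subcommand %in% c("concord", "all")
  do_report <- subcommand %in% c("report", "all")

  if (do_classify) {
    genome <- load_genome(need("genome"))
    aln <- need("alignments")
    reads <- dplyr::bind_rows(lapply(names(aln), function(sid) {
      r <- parse_alignments(aln[[sid]], sid, genome = genome,
                            min_mapq = cfg$min_mapq)
      sk <- attr(r, "skipped")
      message(sid, ": ", nrow(r), " reads parsed; skipped ",
              paste(names(sk), sk, sep = "=", collapse = " "))
      r
    }))
    if (!is.null(cfg$polya)) {
      recs <- dplyr::bind_rows(lapply(cfg$polya, read_polya_table))
      reads <- attach_polya(reads, recs, min_len = cfg$min_polya)
      message(sum(reads$polya_usable), "/", nrow(reads),
              " reads polyA-usable (PASS & >= ", cfg$min_polya, " nt)")
    }
    if (isTRUE(cfg$require_polya_for_grouping)) {
      before <- nrow(reads)
      reads <- reads[reads$polya_usable, ]
      message("require_polya_for_grouping: ", nrow(reads), "/", before,
              " reads retained")
    }
    tss_cl <- greedy_cluster(tally_ends(reads, "TSS"), cfg$tss_window)
    tts_cl <- greedy_cluster(tally_ends(reads, "TTS"), cfg$tts_window)
    keyed <- assign_groups(reads, tss_cl, tts_cl)
    groups <- build_groups(keyed)
    message(nrow(groups), " transcript groups from ", nrow(keyed), " reads")
    write_with_header(function(p) write_read_table(keyed, p),
                      artifact("reads.tsv"), hdr)
    write_with_header(function(p) write_site_table(tss_cl, p),
                      artifact("tss_clusters.tsv"), hdr)
    write_with_header(function(p) write_site_table(tts_cl, p),
                      artifact("tts_clusters.tsv"), hdr)
    write_with_header(function(p) write_group_table(groups, p),
                      artifact("groups.tsv"), hdr)
    if (!is.null(cfg$known_sites)) {
      ks <- utils::read.delim(cfg$known_sites, stringsAsFactors = FALSE)
      off <- dplyr::bind_rows(
        offset_report(tss_cl, ks[grepl("^TSS", ks$name), , drop = FALSE]),
        offset_report(tts_cl, ks[grepl("^TSS", ks$name) == FALSE, ,
                                 drop = FALSE]))
      write_with_header(function(p) utils::write.table(
        as.data.frame(off), p, sep = "\t", quote = FALSE, row.names = FALSE),
        artifact("offsets.tsv"), hdr)
    }
    paths$classify <- artifact(c("reads.tsv", "groups.tsv"))
  }

  reload_keyed <- function(path) {
    lines <- readLines(path)
    tmp <- tempfile()
    writeLines(lines[!startsWith(lines, "##")], tmp)
    tmp
  }

  if (do_annotate || do_polya || do_concord) {
    keyed <- read_read_table(reload_keyed(require_artifact("reads.tsv")))
    # the stored table already carries reps/chain implicitly via exons;
    # rebuild keys deterministically from the stored reads
    tss_cl <- greedy_cluster(tally_ends(keyed, "TSS"), cfg$tss_window)
    tts_cl <- greedy_cluster(tally_ends(keyed, "TTS"), cfg$tts_window)
    keyed <- assign_groups(keyed, tss_cl, tts_cl)
    groups <- build_groups(keyed)
  }

  if (do_annotate) {
    genome <- load_genome(need("genome"))
    features <- read_features(need("features"))
    ann <- annotate_groups(groups, genome, features,
                           extension = cfg$extension, min_aa = cfg$min_aa)
    usage <- orf_usage_table(ann, groups)
    dom <- dominant_transcripts(ann, groups)
    write_with_header(function(p) write_annotation_table(ann, groups, p),
                      artifact("annotations.tsv"), hdr)
    write_with_header(function(p) utils::write.table(
      as.data.frame(usage), p, sep = "\t", quote = FALSE, row.names = FALSE),
      artifact("orf_usage.tsv"), hdr)
    write_gff(groups, artifact("transcripts_all.gff3"), ann, mode = "all",
              seqname = names(load_genome(need("genome")))[1])
    write_gff(groups, artifact("transcripts_dominant.gff3"), ann,
              mode = "dominant",
              seqname = names(load_genome(need("genome")))[1])
    sst <- splice_site_table(keyed, genome)
    write_with_header(function(p) utils::write.table(
      as.data.frame(sst), p, sep = "\t", quote = FALSE, row.names = FALSE),
      artifact("splice_sites.tsv"), hdr)
    message(sum(!ann$no_known_orf), "/", nrow(ann),
            " groups matched a canonical feature")
    paths$annotate <- artifact(c("annotations.tsv", "orf_usage.tsv",
                                 "transcripts_all.gff3",
                                 "transcripts_dominant.gff3"))
  }

  if (do_polya) {
    sample_order <- unlist(cfg$sample_order %||%
                             sort(unique(keyed$sample_id)))
    series <- class_series(keyed, class_by = "group")
    trend <- trend_report(series, sample_order)
    write_with_header(function(p) utils::write.table(
      as.data.frame(series), p, sep = "\t", quote = FALSE, row.names = FALSE),
      artifact("polya_trend.tsv"), hdr)
    write_with_header(function(p) utils::write.table(
      as.data.frame(trend$tests), p, sep = "\t", quote = FALSE,
      row.names = FALSE), artifact("polya_trend_tests.tsv"), hdr)
    paths$polya <- artifact(c("polya_trend.tsv", "polya_trend_tests.tsv"))
  }

  if (do_concord) {
    jset <- load_junctions(need("junctions"), min_support = cfg$min_support)
    conc <- transcript_concordance(keyed, jset)
    write_with_header(function(p) utils::write.table(
      as.data.frame(conc$summary), p, sep = "\t", quote = FALSE,
      row.names = FALSE), artifact("concordance_summary.tsv"), hdr)
    write_with_header(function(p) utils::write.table(
      as.data.frame(conc$per_read), p, sep = "\t", quote = FALSE,
      row.names = FALSE), artifact("concordance_per_read.tsv"), hdr)
    novel <- conc$junction_table[!conc$junction_table$known, ]
    write_with_header(function(p) utils::write.table(
      as.data.frame(novel), p, sep = "\t", quote = FALSE, row.names = FALSE),
      artifact("novel_junctions.tsv"), hdr)
    message(sprintf("junction concordance: %.1f%% of spliced reads",
                    100 * conc$summary$frac_spliced))
    paths$concord <- artifact("concordance_summary.tsv")
  }

  if (do_report) {
    gpath <- require_artifact("groups.tsv")
    lines <- readLines(gpath)
    n_groups <- sum(!startsWith(lines, "##")) - 1L
    rep_lines <- c(provenance_header(cfg),
                   paste0("transcript_groups\t", n_groups))
    for (f in c("concordance_summary.tsv", "orf_usage.tsv",
                "polya_trend_tests.tsv")) {
      p <- artifact(f)
      if (file.exists(p)) {
        body <- readLines(p)
        rep_lines <- c(rep_lines, paste0("# ", f),
                       body[!startsWith(body, "##")])
      }
    }
    writeLines(rep_lines, artifact("report.tsv"))
    paths$report <- artifact("report.tsv")
  }

  invisible(paths)
}
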