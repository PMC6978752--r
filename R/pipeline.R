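#' Run the scan -> conserve -> report pipeline
#'
#' Executes the requested stages over a set of transcripts: binding-site
#' scanning, conservation calling for ortholog pairs, and site-map
#' rendering; writes a BED-like site TSV, a conservation TSV, per-transcript
#' maps (SVG + text) and a JSON-lines machine log.  Every table is stamped
#' (as leading `#` comment lines) with the tool version, the seed/scan
#' parameters and the MD5 digests of the inputs, so re-running the same
#' configuration is byte-identical.
#'
#' @param config A named list, or path to a YAML file, with entries:
#'   * `transcripts_fasta`, `annotation_tsv` (required): the transcript set;
#'   * `mirna_fasta` or `extended_seed`: seed source (default: the let-7
#'     extended seed);
#'   * `k` (default 10, used with `mirna_fasta`), `min_match` (default 6),
#'     `min_overlap` (default `min_match`);
#'   * `pairs_tsv`: ortholog pairing table, required when `"conserve"` is
#'     among the stages;
#'   * `stages`: subset of `c("scan", "conserve", "report")` (default: all
#'     three when `pairs_tsv` is given, otherwise scan + report);
#'   * `out_dir` (required): output directory, created if needed.
#' @return Invisibly, a list with the site table, conservation calls and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (key in c("transcripts_fasta", "annotation_tsv", "out_dir"))
    if (is.null(config[[key]])) stop("config: missing '", key, "'")
  stages <- config$stages %||%
    c("scan", if (!is.null(config$pairs_tsv)) "conserve", "report")
  bad <- setdiff(stages, c("scan", "conserve", "report"))
  if (length(bad)) stop("config: unknown stage(s) ", paste(bad, collapse = ", "))
  if ("conserve" %in% stages && is.null(config$pairs_tsv))
    stop("stage 'conserve': pairing TSV required (config key 'pairs_tsv')")
  min_match <- as.integer(config$min_match %||% 6L)
  k <- as.integer(config$k %||% 10L)
  min_overlap <- as.integer(config$min_overlap %||% min_match)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- unlist(config[c("transcripts_fasta", "annotation_tsv",
                            "mirna_fasta", "pairs_tsv")])
  digests <- tools::md5sum(inputs)
  ver <- as.character(packageVersion("seedtrace"))
  log_lines <- character(0)
  log_event <- function(stage, ...) {
    rec <- c(list(tool = "seedtrace", version = ver, stage = stage), list(...))
    log_lines <<- c(log_lines,
                    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }

  transcripts <- read_transcripts(config$transcripts_fasta,
                                  config$annotation_tsv)
  seed <- if (!is.null(config$mirna_fasta)) {
    mir <- read_mirnas(config$mirna_fasta)[[1L]]
    derive_extended_seed(mir, k = k, min_match = min_match)
  } else {
    seed_query(config$extended_seed %||% "TACTACCTCA",
               min_match = min_match)
  }
  stamp <- c(
    sprintf("seedtrace %s", ver),
    sprintf("seed=%s min_match=%d min_overlap=%d", seed$extended_seed,
            seed$min_match, min_overlap),
    sprintf("input %s md5=%s", names(digests), unname(digests)))

  sites <- scan_transcripts(transcripts, seed)
  site_path <- file.path(out_dir, "sites.tsv")
  calls <- NULL
  if ("conserve" %in% stages) {
    pairs <- read_ortholog_pairs(config$pairs_tsv, transcripts)
    calls <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      ta <- transcripts[[pairs$transcript_id_a[i]]]
      tb <- transcripts[[pairs$transcript_id_b[i]]]
      cp <- conserve_pair(ta, tb, seed = seed,
                          sites_a = sites[sites$transcript_id ==
                                            ta$transcript_id, ],
                          sites_b = sites[sites$transcript_id ==
                                            tb$transcript_id, ],
                          min_overlap = min_overlap)
      rbind(cp$calls_a, cp$calls_b)
    }))
    if (!is.null(calls) && nrow(calls)) {
      key_s <- paste(sites$transcript_id, sites$start, sites$end)
      key_c <- paste(calls$transcript_id, calls$start, calls$end)
      hit <- match(key_s, key_c)
      sites$conserved[!is.na(hit)] <- calls$conserved[hit[!is.na(hit)]]
      cons_path <- file.path(out_dir, "conservation.tsv")
      con <- file(cons_path, "w")
      writeLines(paste0("# ", stamp), con)
      write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
      log_event("conserve", pairs = nrow(pairs), calls = nrow(calls),
                output = basename(cons_path))
    }
  }
  write_site_table(sites, site_path, seed = seed, comments = stamp)
  log_event("scan", transcripts = length(transcripts), sites = nrow(sites),
            seed = seed$extended_seed, min_match = seed$min_match,
            output = basename(site_path))

  map_paths <- character(0)
  if ("report" %in% stages) {
    map_dir <- file.path(out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    for (tx in transcripts) {
      sm <- site_map(tx, sites[sites$transcript_id == tx$transcript_id, ])
      svg_path <- file.path(map_dir, paste0(tx$transcript_id, ".svg"))
      txt_path <- file.path(map_dir, paste0(tx$transcript_id, ".txt"))
      writeLines(render_site_map(sm, "svg"), svg_path)
      writeLines(render_site_map(sm, "text"), txt_path)
      map_paths <- c(map_paths, svg_path, txt_path)
    }
    log_event("report", maps = length(map_paths))
  }
  log_path <- file.path(out_dir, "log.jsonl")
  writeLines(log_lines, log_path)
  invisible(list(sites = sites, conservation = calls, seed = seed,
                 paths = c(sites = site_path, log = log_path, map_paths)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a complete synthetic input bundle to disk
#'
#' Generates `n_transcripts` transcripts with random planted sites, a
#' diverged ortholog for each, and the four assay tables; writes FASTA,
#' annotation TSV, pairing TSV, ground-truth site TSV and assay CSVs into
#' `out_dir`.  The bundle feeds directly into [run_pipeline()].
#'
#' @param out_dir Output directory.
#' @param n_transcripts Number of transcript pairs.
#' @param length Transcript length.
#' @param n_sites Planted sites per transcript.
#' @param substitution_rate,indel_rate Ortholog divergence parameters.
#' @param seed A [seed_query()].
#' @param rng_seed Integer seed.
#' @return Invisibly, a list of paths and the ground-truth tables.
#' @export
simulate_bundle <- function(out_dir, n_transcripts = 5L, length = 400L,
                            n_sites = 2L, substitution_rate = 0.05,
                            indel_rate = 0.005, seed = seed_query(),
                            rng_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_rng_seed(rng_seed, {
    transcripts <- list(); truths <- list(); pair_rows <- list()
    for (i in seq_len(n_transcripts)) {
      plants <- sample_plants(n_sites, length, seed)
      g <- generate_transcript(length, plants = plants, seed = seed,
                               transcript_id = sprintf("synthA_%03d", i),
                               species = "mouse",
                               gene_symbol = sprintf("gene%03d", i))
      o <- generate_ortholog(g$transcript, g$truth,
                             substitution_rate = substitution_rate,
                             indel_rate = indel_rate, seed = seed,
                             transcript_id = sprintf("synthB_%03d", i),
                             species = "human")
      transcripts <- c(transcripts, list(g$transcript, o$transcript))
      truths <- c(truths, list(g$truth, o$truth))
      pair_rows[[i]] <- data.frame(
        gene_symbol = g$transcript$gene_symbol,
        transcript_id_a = g$transcript$transcript_id,
        transcript_id_b = o$transcript$transcript_id,
        stringsAsFactors = FALSE)
    }
    names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
    fasta <- file.path(out_dir, "transcripts.fa")
    ann <- file.path(out_dir, "annotation.tsv")
    write_transcripts(transcripts, fasta, ann)
    pairs_path <- file.path(out_dir, "pairs.tsv")
    write.table(do.call(rbind, pair_rows), pairs_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth <- do.call(rbind, truths)
    rownames(truth) <- NULL
    truth_path <- file.path(out_dir, "truth_sites.tsv")
    write_site_table(truth, truth_path, seed = seed)
    assays <- generate_assay_tables(rng_seed = NULL)
    assay_paths <- vapply(c("luciferase", "transwell", "qpcr",
                            "clinical_score"), function(kind) {
      p <- file.path(out_dir, paste0(kind, ".csv"))
      utils::write.csv(as.data.frame(assays[[kind]]), p, row.names = FALSE)
      p
    }, "")
    invisible(list(transcripts_fasta = fasta, annotation_tsv = ann,
                   pairs_tsv = pairs_path, truth_sites = truth_path,
                   assay_paths = assay_paths, truth = truth,
                   transcripts = transcripts))
  })
}
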