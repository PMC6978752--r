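#' Generate a transcript with planted binding sites and known ground truth
#'
#' Draws an i.i.d. background at the requested GC fraction, rejection-samples
#' until the assembled sequence (background plus planted blocks, including
#' all junctions) contains exactly the planted sites and nothing else, and
#' returns the transcript together with the exact expected site table.
#' With no plants the sequence is guaranteed seed-free.  Rejection (rather
#' than post-hoc masking) keeps the ground truth exact: the accepted
#' sequence is re-scanned and must reproduce the planted coordinates
#' verbatim.
#'
#' @param length Transcript length in nt.
#' @param gc_fraction Background GC fraction in (0, 1).
#' @param plants `NULL`, or a data.frame with columns `region` (`"UTR5"`,
#'   `"CDS"`, `"UTR3"`), `offset` (0-based offset of the planted block
#'   within that region), `match_len` (between `seed$min_match` and
#'   `seed$k`) and `seed_offset` (0-based offset of the block within the
#'   extended seed).  Blocks must fit inside their region, not overlap, and
#'   be separated by at least `seed$k` background nt.
#' @param seed A [seed_query()].
#' @param utr5_length,cds_length Region layout (defaults: 15% 5'UTR, 55%
#'   CDS of `length`).
#' @param transcript_id,species,gene_symbol Passed to
#'   [transcript_record()].
#' @param rng_seed Integer seed for reproducibility (`NULL` = current RNG).
#' @param max_retries Rejection-sampling cap (default 10000).
#' @return List with `transcript` (a [transcript_record()]) and `truth`
#'   (the expected [find_sites()] table).
#' @examples
#' g <- generate_transcript(300, plants = data.frame(
#'   region = "UTR3", offset = 20, match_len = 10, seed_offset = 0),
#'   rng_seed = 1)
#' g$truth
#' @export
generate_transcript <- function(length, gc_fraction = 0.5, plants = NULL,
                                seed = seed_query(),
                                utr5_length = max(1L, round(0.15 * length)),
                                cds_length = max(2L, round(0.55 * length)),
                                transcript_id = "synth_tx",
                                species = "synthetic", gene_symbol = "synth",
                                rng_seed = NULL, max_retries = 10000L) {
  stopifnot(inherits(seed, "seed_query"), length >= seed$min_match,
            gc_fraction > 0, gc_fraction < 1)
  length <- as.integer(length)
  utr5_length <- as.integer(utr5_length); cds_length <- as.integer(cds_length)
  if (utr5_length + cds_length >= length)
    stop("region layout exceeds transcript length")
  cds_start <- utr5_length; cds_end <- utr5_length + cds_length
  bounds <- list(UTR5 = c(0L, cds_start), CDS = c(cds_start, cds_end),
                 UTR3 = c(cds_end, length))
  plant_abs <- validate_plants(plants, bounds, seed)
  with_rng_seed(rng_seed, {
    prob <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
              (1 - gc_fraction) / 2)
    for (try in seq_len(max_retries)) {
      chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                      prob = prob)
      if (nrow(plant_abs)) {
        for (i in seq_len(nrow(plant_abs))) {
          block <- substr(seed$extended_seed,
                          plant_abs$seed_offset[i] + 1L,
                          plant_abs$seed_offset[i] + plant_abs$match_len[i])
          chars[(plant_abs$start[i] + 1L):plant_abs$end[i]] <-
            strsplit(block, "", fixed = TRUE)[[1L]]
        }
      }
      sq <- paste(chars, collapse = "")
      found <- merge_match_loci(
        maximal_matches(sq, seed$extended_seed, seed$min_match))
      ok <- if (nrow(plant_abs) == 0L) nrow(found) == 0L else
        nrow(found) == nrow(plant_abs) &&
        identical(found$start, plant_abs$start) &&
        identical(found$end, plant_abs$end) &&
        identical(found$match_len, plant_abs$match_len) &&
        identical(found$seed_offset, plant_abs$seed_offset)
      if (ok) {
        tx <- transcript_record(transcript_id, sq, cds_start, cds_end,
                                species = species,
                                gene_symbol = gene_symbol)
        return(list(transcript = tx, truth = find_sites(tx, seed)))
      }
    }
    stop("rejection sampling failed after ", max_retries,
         " tries (length ", length, ", gc ", gc_fraction,
         "): planted layout too close to a spontaneous seed match?")
  })
}

# Check plant specs against the region layout; return absolute coordinates
# sorted by start.
validate_plants <- function(plants, bounds, seed) {
  if (is.null(plants) || nrow(plants) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      match_len = integer(), seed_offset = integer()))
  need <- c("region", "offset", "match_len", "seed_offset")
  stopifnot(all(need %in% names(plants)))
  abs <- data.frame(
    start = integer(nrow(plants)), end = integer(nrow(plants)),
    match_len = as.integer(plants$match_len),
    seed_offset = as.integer(plants$seed_offset))
  for (i in seq_len(nrow(plants))) {
    b <- bounds[[as.character(plants$region[i])]]
    if (is.null(b)) stop("plant ", i, ": unknown region")
    len <- abs$match_len[i]
    if (len < seed$min_match || len > seed$k)
      stop("plant ", i, ": match_len must be in [", seed$min_match, ", ",
           seed$k, "]")
    if (abs$seed_offset[i] < 0L || abs$seed_offset[i] + len > seed$k)
      stop("plant ", i, ": seed_offset out of range")
    s <- b[1L] + as.integer(plants$offset[i])
    if (s < b[1L] || s + len > b[2L])
      stop("plant ", i, ": block [", s, ", ", s + len,
           ") does not fit inside region ", plants$region[i])
    abs$start[i] <- s; abs$end[i] <- s + len
  }
  abs <- abs[order(abs$start), , drop = FALSE]
  rownames(abs) <- NULL
  if (nrow(abs) > 1L &&
      any(abs$start[-1L] - abs$end[-nrow(abs)] < seed$k))
    stop("planted blocks must be separated by at least k = ", seed$k,
         " background nt")
  abs
}

#' Sample a random plant layout for a transcript
#'
#' Draws `n_sites` non-overlapping planted blocks (match lengths uniform in
#' `min_match..k`, random seed offsets) at random positions across the
#' region layout, respecting the spacing rule of [generate_transcript()].
#'
#' @inheritParams generate_transcript
#' @param n_sites Number of blocks to place.
#' @param max_tries Placement attempts before giving up.
#' @return A `plants` data.frame acceptable to [generate_transcript()].
#' @export
sample_plants <- function(n_sites, length, seed = seed_query(),
                          utr5_length = max(1L, round(0.15 * length)),
                          cds_length = max(2L, round(0.55 * length)),
                          max_tries = 1000L) {
  cds_start <- as.integer(utr5_length)
  cds_end <- cds_start + as.integer(cds_length)
  length <- as.integer(length)
  placed <- data.frame(start = integer(), end = integer())
  out <- NULL
  for (i in seq_len(n_sites)) {
    done <- FALSE
    for (t in seq_len(max_tries)) {
      len <- sample(seed$min_match:seed$k, 1L)
      off <- sample(0:(seed$k - len), 1L)
      s <- sample(0:(length - len), 1L)
      e <- s + len
      reg_s <- if (s < cds_start) "UTR5" else if (s < cds_end) "CDS" else "UTR3"
      reg_e <- if (e - 1L < cds_start) "UTR5" else if (e - 1L < cds_end) "CDS"
               else "UTR3"
      if (reg_s != reg_e) next  # must fit inside one region
      clash <- nrow(placed) &&
        any(s < placed$end + seed$k & e + seed$k > placed$start)
      if (clash) next
      placed <- rbind(placed, data.frame(start = s, end = e))
      region_start <- switch(reg_s, UTR5 = 0L, CDS = cds_start,
                             UTR3 = cds_end)
      out <- rbind(out, data.frame(region = reg_s, offset = s - region_start,
                                   match_len = len, seed_offset = off,
                                   stringsAsFactors = FALSE))
      done <- TRUE
      break
    }
    if (!done)
      stop("could not place ", n_sites, " blocks in a length-", length,
           " transcript")
  }
  out
}

#' Generate a diverged ortholog of a transcript
#'
#' Applies i.i.d. substitutions and geometric-length indels to emulate
#' cross-species divergence.  When `preserve_planted_sites = TRUE`, planted
#' blocks (the `truth` table) are protected: no substitution falls inside
#' them and no indel splits or deletes them, so each site survives verbatim
#' and its new coordinates are returned.  When `FALSE`, each planted block
#' is ablated by forced transversions (one every `min_match` bases) so the
#' scanner finds none of the planted sites on the ortholog.
#'
#' @param transcript A [transcript_record()] (typically from
#'   [generate_transcript()]).
#' @param truth Its ground-truth site table (may have zero rows).
#' @param substitution_rate,indel_rate Per-site event probabilities in
#'   `[0, 1]`.
#' @param mean_indel_len Mean indel length (>= 1, geometric).
#' @param preserve_planted_sites Protect (TRUE) or ablate (FALSE) planted
#'   blocks.
#' @param seed A [seed_query()] (used for ablation verification).
#' @param transcript_id,species Identity of the ortholog record.
#' @param rng_seed Integer seed.
#' @return List with `transcript` (the ortholog), `truth` (surviving sites
#'   in ortholog coordinates; zero rows when ablating) and `survived`
#'   (logical per input truth row).
#' @export
generate_ortholog <- function(transcript, truth,
                              substitution_rate = 0.05, indel_rate = 0.005,
                              mean_indel_len = 2,
                              preserve_planted_sites = TRUE,
                              seed = seed_query(),
                              transcript_id = paste0(transcript$transcript_id,
                                                     "_ortho"),
                              species = "synthetic_b", rng_seed = NULL) {
  stopifnot(inherits(transcript, "transcript_record"),
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, mean_indel_len >= 1)
  chars <- strsplit(transcript$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  protected <- rep(FALSE, n)
  interior <- rep(FALSE, n)  # positions with a protected predecessor
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      ix <- (truth$start[i] + 1L):truth$end[i]
      protected[ix] <- TRUE
      interior[ix[-1L]] <- TRUE
    }
  }
  with_rng_seed(rng_seed, {
    geom_p <- 1 / mean_indel_len
    bases <- c("A", "C", "G", "T")
    pieces <- character(0)
    newpos <- rep(NA_integer_, n)  # 0-based new coordinate of each old pos
    cursor <- 0L
    i <- 1L
    while (i <= n) {
      # insertion before old position i (never inside a protected block)
      if (indel_rate > 0 && !interior[i] && runif(1) < indel_rate) {
        ins <- sample(bases, rgeom(1L, geom_p) + 1L, replace = TRUE)
        pieces <- c(pieces, ins)
        cursor <- cursor + length(ins)
      }
      # deletion starting at old position i (protected positions immune)
      if (indel_rate > 0 && !protected[i] && runif(1) < indel_rate) {
        del <- rgeom(1L, geom_p) + 1L
        while (del > 0L && i <= n && !protected[i]) {
          newpos[i] <- NA_integer_
          i <- i + 1L; del <- del - 1L
        }
        next
      }
      ch <- chars[i]
      if (!protected[i] && substitution_rate > 0 &&
          runif(1) < substitution_rate)
        ch <- sample(setdiff(bases, ch), 1L)
      pieces <- c(pieces, ch)
      newpos[i] <- cursor
      cursor <- cursor + 1L
      i <- i + 1L
    }
    new_seq <- paste(pieces, collapse = "")
    # map CDS bounds through surviving positions
    map_coord <- function(old) {  # first new position at/after old
      cand <- newpos[(old + 1L):n]
      cand <- cand[!is.na(cand)]
      if (length(cand)) cand[1L] else cursor
    }
    new_cds_start <- map_coord(transcript$cds_start)
    new_cds_end_last <- {  # last surviving position before cds_end
      cand <- newpos[seq_len(transcript$cds_end)]
      cand <- cand[!is.na(cand)]
      if (length(cand)) cand[length(cand)] + 1L else new_cds_start + 1L
    }
    if (new_cds_end_last <= new_cds_start)
      new_cds_end_last <- min(new_cds_start + 1L, nchar(new_seq))
    survived <- logical(nrow(truth))
    new_truth <- truth[0, , drop = FALSE]
    mapped <- truth
    if (nrow(truth)) {
      for (s in seq_len(nrow(truth))) {
        ix <- (truth$start[s] + 1L):truth$end[s]
        np <- newpos[ix]
        ok <- !any(is.na(np)) && all(diff(np) == 1L)
        survived[s] <- ok && preserve_planted_sites
        mapped$start[s] <- if (ok) np[1L] else NA_integer_
        mapped$end[s] <- if (ok) np[length(np)] + 1L else NA_integer_
      }
    }
    mut_chars <- strsplit(new_seq, "", fixed = TRUE)[[1L]]
    if (!preserve_planted_sites && any(!is.na(mapped$start))) {
      transversion <- c(A = "C", C = "A", G = "T", T = "G")
      for (s in which(!is.na(mapped$start))) {
        pos <- seq(mapped$start[s], mapped$end[s] - 1L, by = seed$min_match)
        for (p in pos)
          mut_chars[p + 1L] <- transversion[[mut_chars[p + 1L]]]
      }
      # verify ablation: no surviving match overlapping a former block
      for (iter in 1:25) {
        m <- maximal_matches(paste(mut_chars, collapse = ""),
                             seed$extended_seed, seed$min_match)
        hit <- m[unlist(lapply(seq_len(nrow(m)), function(j)
          any(m$start[j] < mapped$end & m$end[j] > mapped$start,
              na.rm = TRUE))), , drop = FALSE]
        if (nrow(hit) == 0L) break
        for (j in seq_len(nrow(hit))) {
          p <- hit$start[j] + (hit$end[j] - hit$start[j]) %/% 2L
          mut_chars[p + 1L] <- transversion[[mut_chars[p + 1L]]]
        }
      }
      new_seq <- paste(mut_chars, collapse = "")
    }
    ortho <- transcript_record(transcript_id, new_seq, new_cds_start,
                               new_cds_end_last, species = species,
                               gene_symbol = transcript$gene_symbol)
    if (any(survived)) {
      new_truth <- mapped[survived, , drop = FALSE]
      new_truth$transcript_id <- transcript_id
      new_truth$region <- region_of(ortho, new_truth$start)
      rownames(new_truth) <- NULL
    }
    list(transcript = ortho, truth = new_truth, survived = survived)
  })
}

#' Effect model for synthetic assay tables
#'
#' Declares the ground truth the assay generator draws around.  Defaults
#' emulate the study conditions at technical-triplicate scale: a functional
#' wild-type binding-site insert represses the reporter to half the control
#' RLU while its mutant restores it; wild-type pathogenic Th17 cells
#' migrate ~3-fold toward chemokine while let-7-overexpressing (Let-7Tg)
#' cells barely respond and let-7-depleted (Lin28Tg) cells over-respond;
#' chemokine-receptor expression follows the same genotype ordering; and
#' mean clinical-score trajectories rise fastest in the let-7-depleted
#' group.
#'
#' @param rlu_constructs Named numeric: true RLU per construct (reporter
#'   repression expressed as the ratio to the empty control).
#' @param rlu_sdlog Lognormal sigma of luminescence noise.
#' @param renilla_mean Mean Renilla counts.
#' @param transwell_folds Data.frame `group_label`, `condition`, `fold`
#'   (relative to media-only control; the control itself is fold 1).
#' @param transwell_control_mean Mean migrated count in control media.
#' @param transwell_poisson Draw transwell counts Poisson (`TRUE`, default)
#'   or set them to their rounded means (`FALSE`, the degenerate-noise
#'   limit).
#' @param qpcr_folds Data.frame `group_label`, `gene`, `fold` (expression
#'   relative to the reference gene).
#' @param ct_reference_mean,ct_sd Reference-gene Ct mean and Gaussian Ct
#'   noise SD.
#' @param clinical_trajectories Data.frame `group_label`, `day`,
#'   `true_mean` (0-5 scale).
#' @param clinical_sd Gaussian score noise SD before rounding/clipping.
#' @param n_replicates Technical replicates per condition.
#' @param n_mice Named integer: animals per group.
#' @return A list of class `assay_effect_model`.
#' @export
assay_effect_model <- function(
    rlu_constructs = c(wt_site = 0.5, mut_site = 1.0,
                       wt_seed = 0.2, mut_seed = 1.0),
    rlu_sdlog = 0.2, renilla_mean = 5e5,
    transwell_folds = data.frame(
      group_label = rep(c("WT", "Let7Tg", "Lin28Tg"), each = 2L),
      condition = rep(c("control", "chemokine"), 3L),
      fold = c(1, 3, 1, 1.2, 1, 4.5)),
    transwell_control_mean = 80, transwell_poisson = TRUE,
    qpcr_folds = data.frame(
      group_label = rep(c("WT", "Let7Tg", "Lin28Tg"), each = 2L),
      gene = rep(c("Ccr2", "Ccr5"), 3L),
      fold = c(1.0, 0.6, 0.25, 0.15, 2.5, 1.8)),
    ct_reference_mean = 20, ct_sd = 0.15,
    clinical_trajectories = data.frame(
      group_label = rep(c("WT", "Let7Tg", "Lin28Tg"), each = 6L),
      day = rep(c(8, 10, 12, 14, 16, 18), 3L),
      true_mean = c(0.2, 1.0, 2.0, 2.8, 3.0, 2.8,
                    0.0, 0.3, 0.8, 1.2, 1.5, 1.4,
                    0.5, 1.5, 2.8, 3.6, 4.0, 3.8)),
    clinical_sd = 0.6,
    n_replicates = 3L,
    n_mice = c(WT = 7L, Let7Tg = 7L, Lin28Tg = 8L)) {
  stopifnot(all(rlu_constructs > 0), rlu_sdlog >= 0, renilla_mean > 0,
            all(transwell_folds$fold > 0), transwell_control_mean > 0,
            all(qpcr_folds$fold > 0), ct_sd >= 0,
            all(clinical_trajectories$true_mean >= 0),
            all(clinical_trajectories$true_mean <= 5),
            clinical_sd >= 0, n_replicates >= 1L, all(n_mice >= 1L))
  structure(list(
    rlu_constructs = rlu_constructs, rlu_sdlog = rlu_sdlog,
    renilla_mean = renilla_mean, transwell_folds = transwell_folds,
    transwell_control_mean = transwell_control_mean,
    transwell_poisson = isTRUE(transwell_poisson),
    qpcr_folds = qpcr_folds, ct_reference_mean = ct_reference_mean,
    ct_sd = ct_sd, clinical_trajectories = clinical_trajectories,
    clinical_sd = clinical_sd, n_replicates = as.integer(n_replicates),
    n_mice = n_mice), class = "assay_effect_model")
}

#' Generate noisy assay tables around a declared effect model
#'
#' Noise models: luciferase counts lognormal around the true RLU (Renilla
#' lognormal around its mean); transwell counts Poisson around the true
#' mean (control mean times fold); Ct values Gaussian; clinical scores
#' Gaussian around the trajectory, rounded and clipped to the integer 0-5
#' scale.  With all noise parameters at zero the quantification stages
#' recover the declared truth exactly.
#'
#' @param model An [assay_effect_model()].
#' @param rng_seed Integer seed.
#' @return List of four [assay_table()]s (`luciferase`, `transwell`,
#'   `qpcr`, `clinical_score`) plus `truth = model`.
#' @export
generate_assay_tables <- function(model = assay_effect_model(),
                                  rng_seed = NULL) {
  stopifnot(inherits(model, "assay_effect_model"))
  with_rng_seed(rng_seed, {
    nr <- model$n_replicates
    # luciferase
    cons <- names(model$rlu_constructs)
    luc <- do.call(rbind, lapply(cons, function(cn) {
      renilla <- model$renilla_mean *
        rlnorm(nr, -model$rlu_sdlog^2 / 2, model$rlu_sdlog)
      firefly <- renilla * model$rlu_constructs[[cn]] *
        rlnorm(nr, -model$rlu_sdlog^2 / 2, model$rlu_sdlog)
      data.frame(sample_id = paste0(cn, "_r", seq_len(nr)),
                 group_label = cn, replicate_index = seq_len(nr),
                 firefly = firefly, renilla = renilla,
                 stringsAsFactors = FALSE)
    }))
    # transwell (Poisson; control replicate redrawn until nonzero so the
    # matched normalization is defined)
    tw <- do.call(rbind, lapply(seq_len(nrow(model$transwell_folds)),
                                function(i) {
      row <- model$transwell_folds[i, ]
      mu <- model$transwell_control_mean * row$fold
      counts <- if (model$transwell_poisson) rpois(nr, mu)
                else rep(round(mu), nr)
      if (row$condition == "control")
        while (any(counts == 0L)) counts[counts == 0L] <-
          rpois(sum(counts == 0L), mu)
      data.frame(sample_id = paste(row$group_label, row$condition,
                                   seq_len(nr), sep = "_"),
                 group_label = row$group_label, replicate_index = seq_len(nr),
                 condition = row$condition, migrated_count = counts,
                 stringsAsFactors = FALSE)
    }))
    # qPCR
    qp <- do.call(rbind, lapply(seq_len(nrow(model$qpcr_folds)),
                                function(i) {
      row <- model$qpcr_folds[i, ]
      ct_ref <- rnorm(nr, model$ct_reference_mean, model$ct_sd)
      ct_tgt <- ct_ref - log2(row$fold) + rnorm(nr, 0, model$ct_sd)
      data.frame(sample_id = paste(row$group_label, row$gene,
                                   seq_len(nr), sep = "_"),
                 group_label = row$group_label, replicate_index = seq_len(nr),
                 gene = row$gene, ct_target = ct_tgt, ct_reference = ct_ref,
                 stringsAsFactors = FALSE)
    }))
    # clinical scores
    cl <- do.call(rbind, lapply(unique(model$clinical_trajectories$group_label),
                                function(g) {
      traj <- model$clinical_trajectories[
        model$clinical_trajectories$group_label == g, ]
      nm <- model$n_mice[[g]]
      do.call(rbind, lapply(seq_len(nm), function(m)
        data.frame(mouse_id = sprintf("%s_m%d", g, m), group_label = g,
                   day = traj$day,
                   score = pmin(5, pmax(0, round(
                     traj$true_mean + rnorm(nrow(traj), 0,
                                            model$clinical_sd)))),
                   stringsAsFactors = FALSE)))
    }))
    list(luciferase = assay_table("luciferase", luc),
         transwell = assay_table("transwell", tw),
         qpcr = assay_table("qpcr", qp),
         clinical_score = assay_table("clinical_score", cl),
         truth = model)
  })
}
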