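#' Relative luminescence units (RLU)
#'
#' Dual-luciferase normalization: Firefly luciferase activity divided by
#' the co-transfected Renilla luciferase activity (transfection control).
#'
#' @param firefly,renilla Non-negative luminescence readings (vectorized);
#'   `renilla` must be strictly positive.
#' @return `firefly / renilla`.
#' @examples
#' rlu(1000, 500)  # 2
#' @export
rlu <- function(firefly, renilla) {
  if (any(!is.finite(firefly)) || any(!is.finite(renilla)) ||
      any(firefly < 0) || any(renilla < 0))
    stop("luminescence readings must be finite and non-negative")
  if (any(renilla == 0))
    stop("Renilla luminescence of 0: normalization undefined")
  firefly / renilla
}

#' Percent chemotaxis relative to the media-only control
#'
#' Transwell migration normalized to the matched media-only control, which
#' is defined as 100%.
#'
#' @param migrated,control_migrated Non-negative cell counts (vectorized);
#'   `control_migrated` must be strictly positive.
#' @return `100 * migrated / control_migrated`.
#' @examples
#' percent_chemotaxis(200, 100)  # 200
#' percent_chemotaxis(100, 100)  # the control itself: exactly 100
#' @export
percent_chemotaxis <- function(migrated, control_migrated) {
  if (any(!is.finite(migrated)) || any(!is.finite(control_migrated)) ||
      any(migrated < 0) || any(control_migrated < 0))
    stop("cell counts must be finite and non-negative")
  if (any(control_migrated == 0))
    stop("control migrated count of 0: normalization undefined")
  100 * migrated / control_migrated
}

#' Relative expression from qPCR cycle thresholds (2^-dCt)
#'
#' Fold expression of a target gene relative to a reference gene, assuming
#' ideal doubling per cycle: `2^-(ct_target - ct_reference)`.  No
#' calibrator sample is used (plain dCt, not ddCt).
#'
#' @param ct_target,ct_reference Finite Ct values (vectorized).
#' @return Fold expression relative to the reference gene.
#' @examples
#' relative_expression(19, 20)  # 2
#' relative_expression(23, 20)  # 0.125
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  2^-(ct_target - ct_reference)
}

#' Per-day mean clinical-score curve with SEM
#'
#' Summarizes disease scores on the 0-5 clinical scale (0 asymptomatic,
#' 1 limp tail, 2 hindlimb weakness, 3 hindlimb paralysis, 4 complete
#' hindlimb and partial frontlimb paralysis, 5 moribund/death; integer
#' values only).  Animals missing on a day are excluded from that day's
#' `n` (no carry-forward) and the day is flagged; with a single animal the
#' SEM is reported as 0 and flagged.
#'
#' @param scores Data.frame with columns `mouse_id`, `day`, `score`.
#' @return Data.frame with one row per day: `day`, `n`, `mean_score`,
#'   `sem`, `incomplete` (some enrolled animal unscored that day),
#'   `single_animal` (`n == 1`, SEM reported as 0).
#' @examples
#' mean_clinical_score(data.frame(mouse_id = c("m1","m2","m3"),
#'                                day = 10, score = c(1, 2, 3)))
#' @export
mean_clinical_score <- function(scores) {
  need <- c("mouse_id", "day", "score")
  stopifnot(is.data.frame(scores), all(need %in% names(scores)))
  s <- scores$score
  if (any(!is.finite(s)) || any(s < 0 | s > 5) || any(s != floor(s)))
    stop("clinical scores must be integers on the 0-5 scale")
  mice <- unique(scores$mouse_id)
  days <- sort(unique(scores$day))
  out <- do.call(rbind, lapply(days, function(d) {
    v <- scores$score[scores$day == d]
    n <- length(v)
    data.frame(day = d, n = n, mean_score = mean(v),
               sem = if (n > 1L) sd(v) / sqrt(n) else 0,
               incomplete = n < length(mice),
               single_animal = n == 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Two-group comparison: two-tailed Student's t-test with stars
#'
#' Equal-variance two-tailed Student's t-test, with significance stars at
#' the conventional thresholds: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `****` p < 0.0001.  Degenerate constant data are handled by
#' the closed form: equal constant groups give p = 1, unequal give p = 0.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return List with `p_value`, `t`, `df`, `stars` (possibly `""`).
#' @examples
#' group_compare(c(1.0, 1.1, 0.9), c(2.0, 2.1, 1.9))
#' @export
group_compare <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  if (any(!is.finite(values_a)) || any(!is.finite(values_b)))
    stop("values must be finite")
  pooled_sd <- sqrt(((length(values_a) - 1) * stats::var(values_a) +
                     (length(values_b) - 1) * stats::var(values_b)) /
                    (length(values_a) + length(values_b) - 2))
  df <- length(values_a) + length(values_b) - 2
  if (pooled_sd == 0) {
    p <- if (mean(values_a) == mean(values_b)) 1 else 0
    tval <- if (p == 1) 0 else Inf * sign(mean(values_a) - mean(values_b))
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    p <- ht$p.value; tval <- unname(ht$statistic)
    df <- unname(ht$parameter)
  }
  list(p_value = p, t = tval, df = df, stars = significance_stars(p))
}

#' @rdname group_compare
#' @param p P-value(s).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***"
    else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, "")
}

#' Construct a validated assay table
#'
#' Tidy replicate measurements for one assay kind.  Required columns by
#' kind:
#' * `luciferase`: `sample_id`, `group_label`, `replicate_index`,
#'   `firefly`, `renilla`
#' * `transwell`: `sample_id`, `group_label`, `replicate_index`,
#'   `condition`, `migrated_count` (each group/replicate must include a
#'   `"control"` media-only row)
#' * `qpcr`: `sample_id`, `group_label`, `replicate_index`, `gene`,
#'   `ct_target`, `ct_reference`
#' * `clinical_score`: `mouse_id`, `group_label`, `day`, `score`
#'
#' @param assay_kind One of `"luciferase"`, `"transwell"`, `"qpcr"`,
#'   `"clinical_score"`.
#' @param data Data.frame with the columns above.
#' @return The data, classed `c("assay_table", "data.frame")` with
#'   attribute `assay_kind`.
#' @export
assay_table <- function(assay_kind, data) {
  assay_kind <- match.arg(assay_kind,
                          c("luciferase", "transwell", "qpcr",
                            "clinical_score"))
  need <- switch(assay_kind,
    luciferase = c("sample_id", "group_label", "replicate_index",
                   "firefly", "renilla"),
    transwell = c("sample_id", "group_label", "replicate_index",
                  "condition", "migrated_count"),
    qpcr = c("sample_id", "group_label", "replicate_index", "gene",
             "ct_target", "ct_reference"),
    clinical_score = c("mouse_id", "group_label", "day", "score"))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop(assay_kind, " table missing column(s): ",
         paste(miss, collapse = ", "))
  if (assay_kind == "luciferase" &&
      (any(data$firefly < 0) || any(data$renilla < 0)))
    stop("luminescence must be non-negative")
  if (assay_kind == "transwell") {
    if (any(data$migrated_count < 0))
      stop("cell counts must be non-negative")
    key <- interaction(data$group_label, data$replicate_index, drop = TRUE)
    has_ctrl <- tapply(data$condition == "control", key, any)
    if (!all(has_ctrl))
      stop("every transwell group/replicate needs a matched 'control' row")
  }
  if (assay_kind == "qpcr" &&
      (any(!is.finite(data$ct_target)) || any(!is.finite(data$ct_reference))))
    stop("Ct values must be finite")
  if (assay_kind == "clinical_score" &&
      (any(data$score < 0 | data$score > 5) ||
       any(data$score != floor(data$score))))
    stop("clinical scores must be integers on the 0-5 scale")
  structure(data, class = c("assay_table", class(data)),
            assay_kind = assay_kind)
}

#' Quantify an assay table with its stated normalization
#'
#' Applies the assay's normalization per row ([rlu()],
#' [percent_chemotaxis()] against the matched media-only control,
#' [relative_expression()], or [mean_clinical_score()]) and, for the first
#' three kinds, returns per-row values; summaries across replicates are a
#' `tapply`/`aggregate` away and are computed by [summarize_assay()].
#'
#' @param table An [assay_table()].
#' @return For `clinical_score`, the per-group per-day mean/SEM curve;
#'   otherwise the input with a `value` column appended (`rlu`,
#'   `percent_migration` or `rel_expression`).
#' @export
quantify_assay <- function(table) {
  stopifnot(inherits(table, "assay_table"))
  kind <- attr(table, "assay_kind")
  df <- as.data.frame(table)
  switch(kind,
    luciferase = {
      df$value <- rlu(df$firefly, df$renilla)
      df
    },
    transwell = {
      ctrl <- df[df$condition == "control", ]
      key <- paste(df$group_label, df$replicate_index, sep = "\r")
      ckey <- paste(ctrl$group_label, ctrl$replicate_index, sep = "\r")
      ctrl_count <- ctrl$migrated_count[match(key, ckey)]
      df$value <- percent_chemotaxis(df$migrated_count, ctrl_count)
      df
    },
    qpcr = {
      df$value <- relative_expression(df$ct_target, df$ct_reference)
      df
    },
    clinical_score = {
      out <- do.call(rbind, lapply(split(df, df$group_label), function(g) {
        curve <- mean_clinical_score(data.frame(
          mouse_id = g$mouse_id, day = g$day, score = g$score))
        cbind(group_label = g$group_label[1L], curve)
      }))
      rownames(out) <- NULL
      out
    })
}

#' Summarize quantified assay values by group
#'
#' @param table An [assay_table()] (not `clinical_score`).
#' @param by Grouping columns (default: `group_label` plus the assay's
#'   natural stratifier — `condition` for transwell, `gene` for qPCR).
#' @return Data.frame of group `n`, `mean`, `sem`.
#' @export
summarize_assay <- function(table, by = NULL) {
  kind <- attr(table, "assay_kind")
  stopifnot(kind != "clinical_score")
  q <- quantify_assay(table)
  if (is.null(by))
    by <- c("group_label",
            switch(kind, transwell = "condition", qpcr = "gene", NULL))
  key <- interaction(q[by], drop = TRUE, sep = " / ")
  out <- do.call(rbind, lapply(split(q, key), function(g)
    cbind(g[1L, by, drop = FALSE],
          data.frame(n = nrow(g), mean = mean(g$value),
                     sem = if (nrow(g) > 1L) sd(g$value) / sqrt(nrow(g))
                           else 0))))
  rownames(out) <- NULL
  out
}
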