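#' Construct a site map for rendering
#'
#' A site map pairs one transcript's region layout with its ordered,
#' optionally conservation-labelled sites, ready for drawing in the style
#' of a gene diagram: a horizontal transcript axis with UTR/CDS boundaries
#' and one vertical tick per site, conserved ticks drawn red and
#' non-conserved black.
#'
#' @param transcript A [transcript_record()].
#' @param sites A [find_sites()]-style table for that transcript (the
#'   `conserved` column may be `NA` when conservation was not assessed).
#' @return An object of class `site_map`.
#' @export
site_map <- function(transcript, sites) {
  stopifnot(inherits(transcript, "transcript_record"))
  n <- nchar(transcript$sequence)
  if (nrow(sites)) {
    if (any(sites$start < 0L | sites$end > n | sites$start >= sites$end))
      stop("site interval outside transcript bounds [0, ", n, ")")
    sites <- sites[order(sites$start), , drop = FALSE]
    rownames(sites) <- NULL
  }
  structure(list(transcript = transcript, sites = sites, length = n),
            class = "site_map")
}

#' Render a site map as SVG or a monospace text diagram
#'
#' @param map A [site_map()].
#' @param format `"svg"` (vector drawing, conserved sites red,
#'   non-conserved/unassessed black) or `"text"` (`|` for conserved sites,
#'   `:` for non-conserved or unassessed, with a legend line).
#' @param width Drawing width: pixels for SVG (default 800), characters for
#'   text (default 80).
#' @return A character vector of lines (text) or a length-1 SVG document
#'   string.  Deterministic for fixed input.
#' @examples
#' g <- generate_transcript(200, plants = data.frame(
#'   region = "CDS", offset = 5, match_len = 8, seed_offset = 1),
#'   rng_seed = 7)
#' cat(render_site_map(site_map(g$transcript, g$truth), "text"), sep = "\n")
#' @export
render_site_map <- function(map, format = c("svg", "text"),
                            width = if (match.arg(format) == "svg") 800 else 80) {
  stopifnot(inherits(map, "site_map"))
  format <- match.arg(format)
  tx <- map$transcript
  n <- map$length
  if (format == "text") {
    w <- as.integer(width)
    scale_pos <- function(p) pmin(w - 1L, as.integer(floor(p / n * w))) + 1L
    axis <- rep("-", w)
    axis[scale_pos(tx$cds_start)] <- "["
    axis[scale_pos(max(0L, tx$cds_end - 1L))] <- "]"
    ticks <- rep(" ", w)
    if (nrow(map$sites)) {
      for (i in seq_len(nrow(map$sites))) {
        ch <- if (isTRUE(map$sites$conserved[i])) "|" else ":"
        ticks[scale_pos(map$sites$start[i])] <- ch
      }
    }
    c(sprintf("%s (%d nt)  5'UTR [0,%d)  CDS [%d,%d)  3'UTR [%d,%d)",
              tx$transcript_id, n, tx$cds_start, tx$cds_start, tx$cds_end,
              tx$cds_end, n),
      paste(ticks, collapse = ""),
      paste(axis, collapse = ""),
      "legend: | conserved site   : non-conserved/unassessed site   [ ] CDS bounds")
  } else {
    w <- as.numeric(width); h <- 120
    margin <- 40
    ax_y <- 70
    px <- function(p) margin + p / n * (w - 2 * margin)
    lines <- c(
      sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g">',
              w, h),
      sprintf('<text x="%g" y="20" font-family="monospace" font-size="12">%s (%d nt)</text>',
              margin, xml_escape(tx$transcript_id), n),
      # region backbone: thin UTRs, thick CDS
      sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="black" stroke-width="2"/>',
              px(0), ax_y, px(n), ax_y),
      sprintf('<rect x="%g" y="%g" width="%g" height="14" fill="lightgray" stroke="black"/>',
              px(tx$cds_start), ax_y - 7,
              px(tx$cds_end) - px(tx$cds_start)))
    if (nrow(map$sites)) {
      for (i in seq_len(nrow(map$sites))) {
        col <- if (isTRUE(map$sites$conserved[i])) "red" else "black"
        x <- px(map$sites$start[i])
        lines <- c(lines, sprintf(
          '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="%s" stroke-width="1.5"/>',
          x, ax_y - 22, x, ax_y + 22, col))
      }
    }
    lines <- c(lines,
      sprintf('<text x="%g" y="%g" font-family="monospace" font-size="10">red = conserved, black = non-conserved/unassessed</text>',
              margin, h - 10),
      "</svg>")
    paste(lines, collapse = "\n")
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
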