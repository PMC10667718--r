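# Peptide-coverage heat maps as SVG 1.1.
#
# Layout follows the field's coverage figures: chain residues run along the
# horizontal axis (1-based) with CDR intervals as a blue band on the axis;
# each peptide is a block spanning its placement, shaded dark green (high
# confidence) or light green (medium confidence); methionine oxidation is a
# purple mark at its chain position, localized deamidation a yellow mark,
# and unlocalized deamidation a red outline across the whole block (no
# position exists to mark). Overlapping peptides are packed into lanes by
# first fit on the start coordinate, ties broken by (start, length,
# sequence), so output is deterministic and golden-file testable.

#' Heat-map style
#'
#' Six distinct colors plus cell geometry. Defaults follow the
#' dark-green/light-green/blue/purple/yellow/red convention of MAPPs
#' coverage figures.
#'
#' @param high,medium block fills for high/medium confidence
#' @param cdr CDR band color
#' @param metox,deam_localized,deam_unlocalized modification mark colors
#' @param cell_w,row_h cell width / row height in px
#' @return a `heatmap_style` list
#' @export
heatmap_style <- function(high = "#1B7837", medium = "#A6DBA0",
                          cdr = "#2166AC", metox = "#762A83",
                          deam_localized = "#FFD92F",
                          deam_unlocalized = "#D73027",
                          cell_w = 6, row_h = 10) {
  cols <- c(high, medium, cdr, metox, deam_localized, deam_unlocalized)
  if (anyDuplicated(toupper(cols))) {
    stop("heat-map colors must be six distinct colors", call. = FALSE)
  }
  structure(list(high = high, medium = medium, cdr = cdr, metox = metox,
                 deam_localized = deam_localized,
                 deam_unlocalized = deam_unlocalized,
                 cell_w = cell_w, row_h = row_h),
            class = "heatmap_style")
}

# First-fit lane packing: returns a lane index per interval.
pack_lanes <- function(start, end, len, sequence) {
  o <- order(start, len, sequence)
  lane <- integer(length(start))
  lane_end <- numeric(0)
  for (i in o) {
    fit <- which(lane_end < start[i])
    if (length(fit)) {
      lane[i] <- fit[1]
    } else {
      lane[i] <- length(lane_end) + 1L
    }
    lane_end[lane[i]] <- end[i]
  }
  lane
}

svg_rect <- function(x, y, w, h, fill, extra = "") {
  sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
          fmt_px(x), fmt_px(y), fmt_px(w), fmt_px(h), fill, extra)
}

fmt_px <- function(x) formatC(x, format = "f", digits = 2, drop0trailing = TRUE)

#' Render a peptide-coverage heat map
#'
#' One panel per chain (HC above LC), one lane group per sample in sorted
#' sample order. Rendering is deterministic: the same input produces a
#' byte-identical document.
#'
#' @param molecule a [therapeutic_molecule()]
#' @param mapped mapped-peptide table from [map_panel()]; every row must
#'   carry `chain_id`, `start`, `end`, `tier`, `sample_id`, `peptide` and
#'   `mods_chain` (chain-coordinate modification string, "" for none)
#' @param path output SVG path
#' @param style a [heatmap_style()]
#' @return invisibly, `path`
#' @export
render_heatmap <- function(molecule, mapped, path, style = heatmap_style()) {
  dt <- data.table::as.data.table(mapped)
  if (nrow(dt)) {
    if (!all(dt$chain_id %in% c("HC", "LC"))) {
      stop("mapped peptides contain unknown chain ids", call. = FALSE)
    }
    for (ch in c("HC", "LC")) {
      len <- nchar(molecule$chains[[ch]])
      bad <- dt$chain_id == ch & (dt$start < 1L | dt$end > len)
      if (any(bad)) {
        stop("peptide placement outside ", ch, " bounds: not mapped to ",
             "this molecule", call. = FALSE)
      }
    }
  }
  cw <- style$cell_w; rh <- style$row_h
  margin_l <- 60; margin_t <- 20; axis_h <- 14; group_gap <- 8
  body <- character(0)
  y <- margin_t
  max_w <- 0
  for (ch in c("HC", "LC")) {
    len <- nchar(molecule$chains[[ch]])
    max_w <- max(max_w, margin_l + len * cw + 20)
    body <- c(body, sprintf(
      '<text x="%s" y="%s" font-size="10" font-family="monospace">%s</text>',
      fmt_px(10), fmt_px(y + 10), ch))
    # axis baseline + CDR band (blue) on the axis
    body <- c(body, svg_rect(margin_l, y + 4, len * cw, 3, "#CCCCCC",
                             ' class="axis"'))
    cdrs <- molecule$cdrs[molecule$cdrs$chain_id == ch, , drop = FALSE]
    if (nrow(cdrs)) {
      for (i in seq_len(nrow(cdrs))) {
        body <- c(body, svg_rect(margin_l + (cdrs$start[i] - 1) * cw, y,
                                 (cdrs$end[i] - cdrs$start[i] + 1) * cw,
                                 axis_h - 4, style$cdr,
                                 sprintf(' class="cdr" data-name="%s"',
                                         cdrs$name[i])))
      }
    }
    y <- y + axis_h + 4
    sub_ch <- dt[dt$chain_id == ch]
    for (sid in sort(unique(sub_ch$sample_id))) {
      sub <- sub_ch[sub_ch$sample_id == sid]
      body <- c(body, sprintf(
        '<text x="%s" y="%s" font-size="8" font-family="monospace">%s</text>',
        fmt_px(10), fmt_px(y + rh - 2), sid))
      lane <- pack_lanes(sub$start, sub$end, nchar(sub$peptide), sub$peptide)
      for (i in order(lane, sub$start, nchar(sub$peptide), sub$peptide)) {
        fill <- if (sub$tier[i] == "high") style$high else style$medium
        bx <- margin_l + (sub$start[i] - 1) * cw
        by <- y + (lane[i] - 1) * rh
        bw <- (sub$end[i] - sub$start[i] + 1) * cw
        body <- c(body, svg_rect(bx, by, bw, rh - 2, fill,
                                 sprintf(' class="peptide" data-start="%d" data-end="%d" data-lane="%d" data-tier="%s"',
                                         sub$start[i], sub$end[i], lane[i],
                                         sub$tier[i])))
        md <- parse_mods(sub$mods_chain[i])
        if (nrow(md)) {
          for (j in seq_len(nrow(md))) {
            if (md$kind[j] == "MetOx") {
              body <- c(body, svg_rect(
                margin_l + (md$position[j] - 1) * cw, by, cw, rh - 2,
                style$metox, sprintf(' class="metox" data-pos="%d"',
                                     md$position[j])))
            } else if (md$localized[j]) {
              body <- c(body, svg_rect(
                margin_l + (md$position[j] - 1) * cw, by, cw, rh - 2,
                style$deam_localized,
                sprintf(' class="deam" data-pos="%d"', md$position[j])))
            } else {
              body <- c(body, sprintf(
                '<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="%s" stroke-width="1.5" class="deam-unloc"/>',
                fmt_px(bx), fmt_px(by), fmt_px(bw), fmt_px(rh - 2),
                style$deam_unlocalized))
            }
          }
        }
      }
      y <- y + max(1L, if (length(lane)) max(lane) else 1L) * rh + 2
    }
    y <- y + group_gap
  }
  height <- y + 10
  doc <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s">',
    fmt_px(max_w), fmt_px(height)),
    sprintf('<title>%s peptide coverage</title>', molecule$name),
    body, "</svg>")
  writeLines(doc, path, sep = "\n")
  invisible(path)
}
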