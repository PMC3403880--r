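# Rendering: color-coding rules, the pluggable depiction-provider contract,
# and composition of the final cloud image (SVG primary, PNG raster).
#
# A provider draws one molecule into a neutral list of primitives (lines,
# text, rects) in its own local coordinate box; the compositor translates
# and scales those into canvas space. Keeping the primitives abstract means
# the same drawing feeds both the SVG writer and the PNG device.

#' Standard target-class palette
#'
#' Named colors for the six target classes used in class-colored clouds:
#' magenta GPCRs, blue kinases, red proteases, green other enzymes, brown
#' nuclear receptors, yellow ion channels.
#' @export
MC_CLASS_PALETTE <- c(
  GPCR             = "#FF00FF",
  kinase           = "#0000FF",
  protease         = "#FF0000",
  other_enzyme     = "#008000",
  nuclear_receptor = "#8B4513",
  ion_channel      = "#FFFF00"
)

#' Color-coding rule
#'
#' @param scheme `"none"`, `"activity_intensity"` (box opacity proportional
#'   to the fraction of bioactive molecules containing the scaffold) or
#'   `"target_class"` (box colored by the dominant target class).
#' @param class_palette named color vector; defaults to
#'   [MC_CLASS_PALETTE].
#' @param class_threshold minimum fraction of molecules active on a single
#'   class for the scaffold box to be colored (default 0.70, inclusive);
#'   must exceed 0.5 so at most one class can qualify... formally in
#'   (0.5, 1].
#' @param intensity_hue hue used by the activity-intensity scheme.
#' @return an object of class `color_rule`.
#' @export
color_rule <- function(scheme = c("none", "activity_intensity",
                                  "target_class"),
                       class_palette = MC_CLASS_PALETTE,
                       class_threshold = 0.70,
                       intensity_hue = "#FF00FF") {
  scheme <- match.arg(scheme)
  stopifnot(class_threshold > 0.5, class_threshold <= 1.0,
            !is.null(names(class_palette)))
  structure(list(scheme = scheme, class_palette = class_palette,
                 class_threshold = class_threshold,
                 intensity_hue = intensity_hue),
            class = "color_rule")
}

#' Activity-intensity box color
#'
#' Background color whose opacity is proportional (linear) to the ratio of
#' bioactive to all molecules containing the scaffold. Ratio 0 means no
#' box.
#'
#' @param activity_ratio number in \[0, 1\].
#' @param rule a [color_rule()] with scheme `"activity_intensity"`.
#' @return `NULL` (no box) or `list(fill = <hue>, opacity = <ratio>)`.
#' @export
activity_color <- function(activity_ratio, rule = color_rule("activity_intensity")) {
  stopifnot(rule$scheme == "activity_intensity")
  if (is.na(activity_ratio) || activity_ratio < 0 || activity_ratio > 1)
    stop("activity_ratio must be in [0, 1]")
  if (activity_ratio == 0) return(NULL)
  list(fill = rule$intensity_hue, opacity = activity_ratio)
}

#' Dominant target-class box color
#'
#' The scaffold box is colored if at least `class_threshold` (default 70%)
#' of the molecules containing the scaffold are active on one particular
#' target class; scaffolds active on multiple classes (or none reaching
#' the threshold) stay uncolored.
#'
#' @param class_fractions named numeric vector of per-class fractions
#'   (names must be palette classes; fractions sum to at most 1).
#' @param rule a [color_rule()] with scheme `"target_class"`.
#' @return `NULL` or `list(fill = <class color>, opacity = 1)`.
#' @export
class_color <- function(class_fractions, rule = color_rule("target_class")) {
  stopifnot(rule$scheme == "target_class")
  unknown <- setdiff(names(class_fractions), names(rule$class_palette))
  if (length(unknown) > 0L)
    stop("unknown target class(es) ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(names(rule$class_palette), collapse = ", "))
  if (sum(class_fractions, na.rm = TRUE) > 1 + 1e-9)
    stop("class fractions sum to more than 1")
  hit <- which(class_fractions >= rule$class_threshold)
  if (length(hit) != 1L) return(NULL)
  list(fill = unname(rule$class_palette[names(class_fractions)[hit]]),
       opacity = 1)
}

# resolve the box color for one record row under a rule
mc_record_color <- function(record, rule) {
  if (rule$scheme == "none") return(NULL)
  if (rule$scheme == "activity_intensity") {
    r <- record$activity_ratio
    if (is.null(r) || is.na(r)) return(NULL)
    return(activity_color(r, rule))
  }
  cls <- grep("^class_", names(record), value = TRUE)
  if (length(cls) == 0L) return(NULL)
  fr <- as.numeric(record[1, cls])
  names(fr) <- sub("^class_", "", cls)
  fr <- fr[names(fr) %in% names(rule$class_palette)]
  if (length(fr) == 0L) return(NULL)
  class_color(fr, rule)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Construct a depiction provider
#'
#' The contract any chemistry toolkit must satisfy to plug into the cloud:
#' parse a SMILES, canonicalize it, report the natural drawing extent, and
#' draw the molecule as abstract primitives. The layout engine itself needs
#' no chemical intelligence; everything chemical funnels through this
#' interface.
#'
#' @param name provider name (reported in run logs).
#' @param parse `function(smiles)` returning an opaque molecule object or
#'   `NULL` on failure.
#' @param canonical `function(mol)` returning canonical SMILES.
#' @param extent `function(mol)` returning `c(width, height)` in natural
#'   units (pixels at scale 1).
#' @param draw `function(mol, width, height)` returning a primitive table:
#'   columns `kind` (`"line"`, `"text"`, `"rect"`), `x1,y1,x2,y2`, `label`,
#'   `size`, `color`, in local coordinates `[0,width] x [0,height]`
#'   (y down).
#' @return an object of class `depiction_provider`.
#' @export
depiction_provider <- function(name, parse, canonical, extent, draw) {
  stopifnot(is.function(parse), is.function(canonical),
            is.function(extent), is.function(draw))
  structure(list(name = name, parse = parse, canonical = canonical,
                 extent = extent, draw = draw),
            class = "depiction_provider")
}

mc_primitive <- function(kind, x1, y1, x2 = NA_real_, y2 = NA_real_,
                         label = NA_character_, size = NA_real_,
                         color = "black") {
  data.frame(kind = kind, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
             label = label, size = size, color = color,
             stringsAsFactors = FALSE)
}

#' Mock depiction provider
#'
#' Draws each structure as a labeled box sized by the SMILES length — no
#' chemistry toolkit involved. Makes the entire pipeline (selection,
#' layout, composition) testable with zero chemical dependencies and
#' mirrors the role of swapping depiction engines behind the provider
#' interface.
#'
#' @return a [depiction_provider()].
#' @export
mock_provider <- function() {
  depiction_provider(
    name = "mock",
    parse = function(smiles) {
      if (!nzchar(trimws(smiles))) NULL else list(smiles = trimws(smiles))
    },
    canonical = function(mol) mol$smiles,
    extent = function(mol) c(10 + 8 * nchar(mol$smiles), 26),
    draw = function(mol, width, height) {
      rbind(
        mc_primitive("rect", 0, 0, width, height, color = "#888888"),
        mc_primitive("text", width / 2, height / 2, label = mol$smiles,
                     size = min(13, 1.6 * width / max(1, nchar(mol$smiles))))
      )
    }
  )
}

#' OpenBabel-backed depiction provider
#'
#' Parses SMILES and lays out 2D coordinates with OpenBabel, then draws
#' bonds as line segments (doubled/tripled for multiple bonds) and
#' heteroatoms as element labels. `px_per_bond` sets the natural size: one
#' standard bond length maps to that many pixels at scale 1.
#'
#' @param px_per_bond pixels per unit bond length at scale 1.
#' @return a [depiction_provider()].
#' @export
openbabel_provider <- function(px_per_bond = 28) {
  pad <- 0.55  # bond-length units of whitespace around the skeleton
  box <- function(mol) {
    list(xr = range(mol$atoms$x) + c(-pad, pad),
         yr = range(mol$atoms$y) + c(-pad, pad))
  }
  depiction_provider(
    name = "openbabel",
    parse = function(smiles) mc_parse_smiles(smiles),
    canonical = function(mol) mc_to_smiles(mol),
    extent = function(mol) {
      b <- box(mol)
      c(diff(b$xr), diff(b$yr)) * px_per_bond
    },
    draw = function(mol, width, height) {
      b <- box(mol)
      # fit the skeleton into the requested frame, preserving aspect
      s <- min(width / diff(b$xr), height / diff(b$yr))
      tx <- function(x) (x - b$xr[1]) * s + (width - diff(b$xr) * s) / 2
      ty <- function(y) (b$yr[2] - y) * s + (height - diff(b$yr) * s) / 2
      prims <- list()
      at <- mol$atoms
      lab <- mc_is_hetero(at$symbol) | at$symbol == "*"
      for (i in seq_len(nrow(mol$bonds))) {
        f <- mol$bonds$from[i]; t <- mol$bonds$to[i]
        ord <- mol$bonds$order[i]
        x1 <- tx(at$x[f]); y1 <- ty(at$y[f])
        x2 <- tx(at$x[t]); y2 <- ty(at$y[t])
        len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
        if (len < 1e-9) next
        # shorten toward labeled atoms so text stays readable
        sh1 <- if (lab[f]) 0.18 else 0; sh2 <- if (lab[t]) 0.18 else 0
        xa <- x1 + (x2 - x1) * sh1; ya <- y1 + (y2 - y1) * sh1
        xb <- x2 - (x2 - x1) * sh2; yb <- y2 - (y2 - y1) * sh2
        off <- 0.08 * s  # parallel-line offset for multiple bonds
        nx <- -(y2 - y1) / len * off; ny <- (x2 - x1) / len * off
        ks <- switch(ord, `1` = 0, `2` = c(-0.5, 0.5), `3` = c(-1, 0, 1), 0)
        for (k in ks) {
          prims[[length(prims) + 1L]] <-
            mc_primitive("line", xa + k * nx * 2, ya + k * ny * 2,
                         xb + k * nx * 2, yb + k * ny * 2)
        }
      }
      for (i in which(lab)) {
        prims[[length(prims) + 1L]] <-
          mc_primitive("text", tx(at$x[i]), ty(at$y[i]),
                       label = at$symbol[i], size = 0.55 * s,
                       color = "#1A1A8C")
      }
      if (length(prims) == 0L) {  # single atom, e.g. methane fragment
        prims[[1L]] <- mc_primitive("text", width / 2, height / 2,
                                    label = at$symbol[1], size = 0.55 * s)
      }
      do.call(rbind, prims)
    }
  )
}

fmt_num <- function(v) formatC(v, format = "f", digits = 2, drop0trailing = TRUE)

# one SVG <g> for an item: optional rounded box + provider primitives
mc_svg_group <- function(item, prims, fill) {
  x0 <- item$x - item$width / 2
  y0 <- item$y - item$height / 2
  padx <- 0.05 * item$width; pady <- 0.05 * item$height
  out <- sprintf('<g class="structure" id="%s">', xml_escape(item$id))
  if (!is.null(fill)) {
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" rx="%s" fill="%s" fill-opacity="%s"/>',
      fmt_num(x0 - padx), fmt_num(y0 - pady),
      fmt_num(item$width + 2 * padx), fmt_num(item$height + 2 * pady),
      fmt_num(0.1 * min(item$width, item$height)),
      fill$fill, fmt_num(fill$opacity)))
  }
  for (i in seq_len(NROW(prims))) {
    p <- prims[i, ]
    if (p$kind == "line") {
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
        fmt_num(x0 + p$x1), fmt_num(y0 + p$y1), fmt_num(x0 + p$x2),
        fmt_num(y0 + p$y2), p$color,
        fmt_num(max(0.75, item$height / 30))))
    } else if (p$kind == "rect") {
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="%s"/>',
        fmt_num(x0 + p$x1), fmt_num(y0 + p$y1), fmt_num(p$x2 - p$x1),
        fmt_num(p$y2 - p$y1), p$color))
    } else if (p$kind == "text") {
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="%s" font-family="Helvetica,sans-serif" text-anchor="middle" dominant-baseline="central" fill="%s">%s</text>',
        fmt_num(x0 + p$x1), fmt_num(y0 + p$y1), fmt_num(p$size), p$color,
        xml_escape(p$label)))
    }
  }
  c(out, "</g>")
}

#' Compose the final cloud image
#'
#' Draws every laid-out structure at its position and scaled size on a
#' white canvas, with an optional colored rounded box behind it (5%
#' padding). Items are drawn in ascending area order so the large
#' structures are never fully hidden by later draws. Records failing
#' depiction are skipped with a warning and composition continues.
#'
#' @param items positioned [cloud_items()]; ids must match record keys.
#' @param records substructure records (row per id, matched on
#'   `canonical_smiles`).
#' @param cfg a [layout_config()] (canvas size).
#' @param provider a [depiction_provider()].
#' @param rule a [color_rule()].
#' @return single string: an SVG 1.1 document.
#' @export
compose_svg <- function(items, records, cfg = layout_config(),
                        provider = openbabel_provider(),
                        rule = color_rule("none")) {
  stopifnot(inherits(provider, "depiction_provider"))
  doc <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
    fmt_num(cfg$canvas_width), fmt_num(cfg$canvas_height),
    fmt_num(cfg$canvas_width), fmt_num(cfg$canvas_height)),
    sprintf('<rect width="%s" height="%s" fill="white"/>',
            fmt_num(cfg$canvas_width), fmt_num(cfg$canvas_height)))
  ord <- order(items$width * items$height, items$id, method = "radix")
  n_drawn <- 0L
  for (i in ord) {
    item <- items[i, ]
    rec <- records[records$canonical_smiles == item$id, , drop = FALSE]
    if (nrow(rec) == 0L) rec <- NULL
    mol <- provider$parse(item$id)
    if (is.null(mol)) {
      warning("depiction failed for ", item$id, "; structure skipped")
      next
    }
    prims <- provider$draw(mol, item$width, item$height)
    fill <- if (!is.null(rec)) mc_record_color(rec[1, ], rule) else NULL
    doc <- c(doc, mc_svg_group(item, prims, fill))
    n_drawn <- n_drawn + 1L
  }
  doc <- c(doc, "</svg>")
  structure(paste(doc, collapse = "\n"), n_drawn = n_drawn)
}

#' Rasterize a cloud to PNG
#'
#' Replays the same drawing primitives as [compose_svg()] onto a PNG
#' device.
#'
#' @inheritParams compose_svg
#' @param path output PNG path.
#' @param dpi raster resolution (canvas units are taken as 1/96 inch).
#' @export
compose_png <- function(items, records, cfg = layout_config(),
                        provider = openbabel_provider(),
                        rule = color_rule("none"), path, dpi = 96) {
  px <- dpi / 96
  grDevices::png(path, width = cfg$canvas_width * px,
                 height = cfg$canvas_height * px)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NULL, xlim = c(0, cfg$canvas_width),
                 ylim = c(cfg$canvas_height, 0), asp = 1, axes = FALSE,
                 xlab = "", ylab = "")
  graphics::rect(0, cfg$canvas_height, cfg$canvas_width, 0, col = "white",
                 border = NA)
  ord <- order(items$width * items$height, items$id, method = "radix")
  for (i in ord) {
    item <- items[i, ]
    rec <- records[records$canonical_smiles == item$id, , drop = FALSE]
    mol <- provider$parse(item$id)
    if (is.null(mol)) next
    prims <- provider$draw(mol, item$width, item$height)
    x0 <- item$x - item$width / 2; y0 <- item$y - item$height / 2
    fill <- if (nrow(rec) > 0L) mc_record_color(rec[1, ], rule) else NULL
    if (!is.null(fill)) {
      graphics::rect(x0 - 0.05 * item$width, y0 + 1.05 * item$height,
                     x0 + 1.05 * item$width, y0 - 0.05 * item$height,
                     col = grDevices::adjustcolor(fill$fill,
                                                  alpha.f = fill$opacity),
                     border = NA)
    }
    for (k in seq_len(NROW(prims))) {
      p <- prims[k, ]
      if (p$kind == "line") {
        graphics::segments(x0 + p$x1, y0 + p$y1, x0 + p$x2, y0 + p$y2,
                           col = p$color)
      } else if (p$kind == "rect") {
        graphics::rect(x0 + p$x1, y0 + p$y2, x0 + p$x2, y0 + p$y1,
                       border = p$color)
      } else if (p$kind == "text") {
        graphics::text(x0 + p$x1, y0 + p$y1, labels = p$label,
                       cex = p$size / 12, col = p$color)
      }
    }
  }
  invisible(path)
}
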