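# Per-atom highlight amplitudes with per-bond decay, and 2D depictions
# with orange atom shading (SVG preferred; PNG via grDevices).

#' Per-atom highlight amplitudes for selected neighborhoods
#'
#' Each neighborhood with center `c` and score `s` contributes
#' `s * decay^d(c, a)` to every atom `a` within `radius` bonds of `c`
#' (geometric reading of a constant 0.8-per-bond decay; the `"linear"`
#' mode uses the additive ramp `s * max(0, 1 - (1 - decay) * d)` instead).
#' Overlapping neighborhoods simply sum.
#'
#' @param graph A `mol_graph`.
#' @param neighborhoods List of `salient_neighborhood` objects (see
#'   [select_salient()]), or a list of bare `list(center=, score=)` pairs.
#' @param decay Per-bond decay factor in (0, 1\] (default 0.8).
#' @param radius Cutoff in bonds (default 3); atoms farther than this from
#'   every center get amplitude 0.
#' @param mode `"geometric"` (default) or `"linear"`.
#' @return A numeric vector of length `n_atom` (class `highlight_map`).
#' @export
highlight_amplitudes <- function(graph, neighborhoods, decay = 0.8,
                                 radius = 3L, mode = c("geometric",
                                                       "linear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "mol_graph"), decay > 0, decay <= 1)
  amp <- numeric(graph$n_atom)
  if (length(neighborhoods) == 0) {
    return(structure(amp, class = "highlight_map"))
  }
  D <- bond_distance_matrix(graph)
  for (nb in neighborhoods) {
    ctr <- nb$center
    if (is.null(ctr) || ctr < 1 || ctr > graph$n_atom) {
      stop("highlight_amplitudes: neighborhood center ", ctr,
           " does not belong to this graph")
    }
    s <- nb$score %||% 1
    d <- D[ctr, ]
    w <- if (mode == "geometric") decay^d else pmax(0, 1 - (1 - decay) * d)
    w[d > radius] <- 0
    amp <- amp + s * w
  }
  structure(amp, class = "highlight_map")
}

## map molecule coordinates into a viewport; returns scaled coords + scale
.fit_coords <- function(coords, width, height, margin = 30) {
  xr <- range(coords[, 1]); yr <- range(coords[, 2])
  span <- max(xr[2] - xr[1], yr[2] - yr[1], 1e-6)
  sc <- (min(width, height) - 2 * margin) / span
  cx <- (xr[1] + xr[2]) / 2; cy <- (yr[1] + yr[2]) / 2
  cbind(x = (coords[, 1] - cx) * sc + width / 2,
        y = height / 2 - (coords[, 2] - cy) * sc)
}

## SVG fragment for one molecule within a viewport offset
.svg_molecule <- function(graph, highlight, ox, oy, width, height,
                          label = NULL) {
  xy <- .fit_coords(graph$coords, width, height)
  xy[, 1] <- xy[, 1] + ox; xy[, 2] <- xy[, 2] + oy
  out <- character(0)
  mx <- if (!is.null(highlight) && max(highlight) > 0) max(highlight) else 1
  ## atom shading first so bonds draw on top
  if (!is.null(highlight)) {
    for (a in which(highlight > 0)) {
      out <- c(out, sprintf(
        paste0('<circle class="atom-highlight" cx="%.1f" cy="%.1f" r="13" ',
               'fill="#ff8c00" fill-opacity="%.3f" stroke="none"/>'),
        xy[a, 1], xy[a, 2], 0.15 + 0.85 * highlight[a] / mx))
    }
  }
  for (r in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[r]; j <- graph$bonds$j[r]
    ordr <- graph$bonds$order[r]
    dx <- xy[j, 2] - xy[i, 2]; dy <- xy[i, 1] - xy[j, 1]
    nrm <- sqrt(dx^2 + dy^2); if (nrm < 1e-9) nrm <- 1
    offs <- switch(as.character(ordr), `1` = 0, `2` = c(-1.6, 1.6),
                   `3` = c(-2.5, 0, 2.5), 0)
    for (o in offs) {
      out <- c(out, sprintf(
        '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#333" stroke-width="1.4"/>',
        xy[i, 1] + o * dx / nrm, xy[i, 2] + o * dy / nrm,
        xy[j, 1] + o * dx / nrm, xy[j, 2] + o * dy / nrm))
    }
  }
  het <- which(graph$atoms$element != "C")
  for (a in het) {
    out <- c(out, sprintf(
      paste0('<text x="%.1f" y="%.1f" font-size="11" text-anchor="middle" ',
             'dy="4" fill="#1040a0" font-family="sans-serif">%s</text>'),
      xy[a, 1], xy[a, 2], graph$atoms$element[a]))
  }
  if (!is.null(label)) {
    out <- c(out, sprintf(
      '<text x="%.1f" y="%.1f" font-size="10" fill="#555" font-family="sans-serif">%s</text>',
      ox + 6, oy + 14, label))
  }
  out
}

#' Render a molecule depiction with saliency highlights
#'
#' 2D depiction with per-atom orange shading scaled to the maximum
#' amplitude. Output format follows the file extension: `.svg` (one
#' `<circle class="atom-highlight">` primitive per nonzero-amplitude atom)
#' or `.png`.
#'
#' @param graph A `mol_graph`.
#' @param highlight A `highlight_map` (or `NULL` for a plain depiction).
#' @param path Output path ending in `.svg` or `.png`.
#' @param width,height Canvas size in pixels (default 360).
#' @return Invisibly, `path`.
#' @export
render_molecule <- function(graph, highlight = NULL, path,
                            width = 360, height = 360) {
  stopifnot(inherits(graph, "mol_graph"))
  if (!is.null(highlight) && length(highlight) != graph$n_atom) {
    stop("render_molecule: highlight length != n_atom")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    body <- .svg_molecule(graph, highlight, 0, 0, width, height)
    ok <- try(writeLines(c(
      sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
              width, height),
      '<rect width="100%" height="100%" fill="white"/>', body, "</svg>"),
      path), silent = TRUE)
    if (inherits(ok, "try-error")) stop("render_molecule: cannot write ", path)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    .plot_molecule_base(graph, highlight)
  } else {
    stop("render_molecule: unsupported extension '", ext, "'")
  }
  invisible(path)
}

.plot_molecule_base <- function(graph, highlight) {
  xy <- graph$coords
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1)
  if (!is.null(highlight) && max(highlight) > 0) {
    mx <- max(highlight)
    for (a in which(highlight > 0)) {
      graphics::points(xy[a, 1], xy[a, 2], pch = 16, cex = 4,
                       col = grDevices::adjustcolor(
                         "darkorange", alpha.f = 0.15 + 0.85 *
                           highlight[a] / mx))
    }
  }
  for (r in seq_len(nrow(graph$bonds))) {
    graphics::segments(xy[graph$bonds$i[r], 1], xy[graph$bonds$i[r], 2],
                       xy[graph$bonds$j[r], 1], xy[graph$bonds$j[r], 2],
                       lwd = 1 + graph$bonds$order[r])
  }
  het <- which(graph$atoms$element != "C")
  if (length(het) > 0) {
    graphics::text(xy[het, 1], xy[het, 2], graph$atoms$element[het],
                   col = "navy", cex = 0.9)
  }
}

#' Render a cluster of molecules, four per page
#'
#' Writes one SVG page per group of four molecules (the supplementary-
#' style layout), each molecule shaded by its own highlight map.
#'
#' @param graphs List of `mol_graph` objects.
#' @param highlights List of `highlight_map`s parallel to `graphs` (or
#'   `NULL`).
#' @param dir Output directory.
#' @param prefix File-name prefix (default `"page"`).
#' @param labels Optional per-molecule labels.
#' @param per_page Molecules per page (default 4, laid out 2 x 2).
#' @return Invisibly, the written file paths.
#' @export
render_cluster_pages <- function(graphs, highlights = NULL, dir,
                                 prefix = "page", labels = NULL,
                                 per_page = 4L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cell <- 300
  ncol <- 2
  pages <- split(seq_along(graphs),
                 ceiling(seq_along(graphs) / per_page))
  paths <- character(0)
  for (pg in seq_along(pages)) {
    idx <- pages[[pg]]
    nrow_pg <- ceiling(length(idx) / ncol)
    body <- character(0)
    for (k in seq_along(idx)) {
      i <- idx[k]
      ox <- ((k - 1) %% ncol) * cell
      oy <- ((k - 1) %/% ncol) * cell
      body <- c(body, .svg_molecule(
        graphs[[i]], if (is.null(highlights)) NULL else highlights[[i]],
        ox, oy, cell, cell,
        label = if (is.null(labels)) NULL else labels[[i]]))
    }
    path <- file.path(dir, sprintf("%s_%03d.svg", prefix, pg))
    writeLines(c(
      sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
              ncol * cell, nrow_pg * cell),
      '<rect width="100%" height="100%" fill="white"/>', body, "</svg>"),
      path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
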