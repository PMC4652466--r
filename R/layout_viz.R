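# run expr with a private RNG state so layouts are reproducible without
# disturbing the caller's random stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fruchterman-Reingold force-directed layout
#'
#' Places nodes in the plane by simulating springs: every node pair repels
#' with force `k^2 / d`, every edge attracts with force `|w| * d^2 / k`,
#' where `d` is the current distance and `k = sqrt(area / n)` is the
#' optimal vertex separation. Attraction uses the *magnitude* of the edge
#' weight, so strongly negatively correlated OTUs are co-located too — a
#' known property of this layout on correlation networks (closeness in the
#' drawing does not imply positive association). Per-iteration displacement
#' is capped by a linearly cooling temperature, so the layout is a
#' deterministic function of the seed.
#'
#' @param net a `cooccurrence_network`.
#' @param seed integer seed for the initial random placement.
#' @param iterations number of cooling steps (default 500).
#' @return a `layout_positions`: list with `coords` (n x 2 matrix, rownames
#'   = OTU ids), `frame` (side length of the square frame), `seed`,
#'   `iterations`.
#' @export
fruchterman_reingold <- function(net, seed = 1L, iterations = 500L) {
  stopifnot(inherits(net, "cooccurrence_network"))
  ids <- net$nodes$otu_id
  n <- length(ids)
  if (n < 1) stop("network has no nodes")
  L <- sqrt(n)                       # frame side; area = n so k = 1
  k <- sqrt(L * L / n)
  pos <- with_local_seed(seed, matrix(stats::runif(2 * n, 0, L), ncol = 2))
  rownames(pos) <- ids
  if (n == 1) {
    pos[1, ] <- c(L / 2, L / 2)
    return(structure(list(coords = pos, frame = L, seed = seed,
                          iterations = 0L), class = "layout_positions"))
  }
  ei <- match(net$edges$from, ids)
  ej <- match(net$edges$to, ids)
  ew <- abs(net$edges$weight)
  t0 <- L / 10
  for (it in seq_len(iterations)) {
    temp <- t0 * (1 - (it - 1) / iterations)
    disp <- matrix(0, n, 2)
    # repulsion: all pairs, k^2 / d
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d2 <- dx * dx + dy * dy
    d <- sqrt(d2)
    d[d < 1e-9] <- 1e-9
    f <- k * k / (d * d)             # force / distance -> multiply by (dx,dy)
    diag(f) <- 0
    disp[, 1] <- rowSums(f * dx)
    disp[, 2] <- rowSums(f * dy)
    # attraction along edges: |w| * d^2 / k
    if (length(ei)) {
      ddx <- pos[ei, 1] - pos[ej, 1]
      ddy <- pos[ei, 2] - pos[ej, 2]
      dd <- sqrt(ddx * ddx + ddy * ddy)
      dd[dd < 1e-9] <- 1e-9
      fa <- ew * dd / k              # force / distance
      for (e in seq_along(ei)) {
        v <- c(ddx[e], ddy[e]) * fa[e]
        disp[ei[e], ] <- disp[ei[e], ] - v
        disp[ej[e], ] <- disp[ej[e], ] + v
      }
    }
    len <- sqrt(rowSums(disp^2))
    len[len < 1e-12] <- 1e-12
    step <- pmin(len, temp) / len
    pos <- pos + disp * step
    pos[, 1] <- pmin(pmax(pos[, 1], 0), L)
    pos[, 2] <- pmin(pmax(pos[, 2], 0), L)
  }
  structure(list(coords = pos, frame = L, seed = seed,
                 iterations = as.integer(iterations)),
            class = "layout_positions")
}

# deterministic club colour order (assigned by decreasing club size)
club_palette <- function(k) {
  base <- c("#E41A1C", "#377EB8", "#2E8B57", "#999999", "#FFD700",
            "#984EA3", "#FF7F00", "#A65628", "#F781BF", "#66C2A5")
  if (k <= length(base)) return(base[seq_len(k)])
  c(base, grDevices::rainbow(k - length(base)))
}

heat_colour <- function(h) {
  # blue (cool, p near 1) -> red (hot, p near 0)
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  grDevices::rgb(ramp(pmin(pmax(h, 0), 1)), maxColorValue = 255)
}

#' Render a co-occurrence network diagram
#'
#' Draws the network with node size proportional to mean log abundance
#' (affine-rescaled), edge thickness proportional to |r|, green edges for
#' positive and red for negative correlations. Edges with
#' `|r| < display_threshold` are omitted from the drawing only — the
#' clustering always reads the full masked matrix. `color_mode = "heat"`
#' colours nodes blue-to-red by differential-abundance heat scalar;
#' `"clubs"` colours by club membership (unassigned nodes white) and marks
#' each club leader with a star.
#'
#' @param net a `cooccurrence_network`.
#' @param pos a `layout_positions` covering all nodes.
#' @param file output SVG path.
#' @param color_mode `"heat"` or `"clubs"`.
#' @param partition a `club_partition`; required for `"clubs"` mode.
#' @param display_threshold minimum |r| for an edge to be drawn
#'   (default 0.2).
#' @return `file`, invisibly.
#' @export
render_network <- function(net, pos, file, color_mode = c("heat", "clubs"),
                           partition = NULL, display_threshold = 0.2) {
  stopifnot(inherits(net, "cooccurrence_network"),
            inherits(pos, "layout_positions"))
  color_mode <- match.arg(color_mode)
  if (color_mode == "clubs" && is.null(partition))
    stop("color_mode 'clubs' requires a club partition")
  ids <- net$nodes$otu_id
  if (!all(ids %in% rownames(pos$coords)))
    stop("positions do not cover all nodes")
  xy <- pos$coords[ids, , drop = FALSE]

  ab <- net$nodes$mean_abundance
  rng <- range(ab)
  cex <- if (diff(rng) > 0) 1 + 2.5 * (ab - rng[1]) / diff(rng) else rep(2, length(ab))
  fill <- if (color_mode == "heat") {
    heat_colour(net$nodes$heat)
  } else {
    pal <- club_palette(length(partition$clubs))
    memb <- partition$membership
    ifelse(is.na(memb), "#FFFFFF", pal[memb])
  }

  grDevices::svg(file, width = 8, height = 8)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(0, pos$frame), ylim = c(0, pos$frame),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = sprintf("co-occurrence network (%s)", color_mode))
  draw <- net$edges[abs(net$edges$weight) >= display_threshold, , drop = FALSE]
  if (nrow(draw)) {
    i <- match(draw$from, ids); j <- match(draw$to, ids)
    graphics::segments(xy[i, 1], xy[i, 2], xy[j, 1], xy[j, 2],
                       col = ifelse(draw$sign == "positive",
                                    "#2CA02CAA", "#D62728AA"),
                       lwd = 0.5 + 3 * draw$weight)
  }
  graphics::points(xy[, 1], xy[, 2], pch = 21, bg = fill, col = "grey30",
                   cex = cex)
  if (color_mode == "clubs") {
    li <- match(partition$leaders, ids)
    li <- li[!is.na(li)]
    if (length(li))
      graphics::points(xy[li, 1], xy[li, 2], pch = 8, cex = cex[li] + 0.8,
                       lwd = 2)
  }
  graphics::text(xy[, 1], xy[, 2], labels = ids, pos = 3, cex = 0.5,
                 offset = 0.4)
  invisible(file)
}

#' Club-ordered correlation heat map
#'
#' Renders the masked correlation matrix with rows/columns grouped by club
#' (unassigned OTUs last), on a diverging blue-white-red scale centred at
#' zero. Row and column labels are tinted with their club's colour, so
#' clubs appear as warm diagonal blocks and rival pairs as cool
#' off-diagonal blocks.
#'
#' @param corr a `correlation_result` (its masked matrix is drawn).
#' @param partition a `club_partition` over the same OTUs.
#' @param file output SVG path.
#' @return `file`, invisibly.
#' @export
club_heatmap <- function(corr, partition, file) {
  stopifnot(inherits(corr, "correlation_result"),
            inherits(partition, "club_partition"))
  ids <- colnames(corr$r_masked)
  ord <- c(unlist(partition$clubs), partition$unassigned)
  if (!setequal(ord, ids)) stop("partition does not cover the correlation matrix")
  R <- corr$r_masked[ord, ord]
  n <- length(ord)
  pal <- club_palette(length(partition$clubs))
  memb <- rep(NA_integer_, n)
  off <- 0
  for (i in seq_along(partition$clubs)) {
    memb[off + seq_along(partition$clubs[[i]])] <- i
    off <- off + length(partition$clubs[[i]])
  }
  labcol <- ifelse(is.na(memb), "grey40", pal[memb])

  grDevices::svg(file, width = 8, height = 8)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 6, 2, 1))
  cols <- grDevices::colorRampPalette(
    c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  # orient so row 1 is at the top; scale fixed to [-1, 1] centred at 0
  graphics::image(seq_len(n), seq_len(n), t(R[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = cols, axes = FALSE,
                  xlab = "", ylab = "", main = "clubs heat map")
  for (j in seq_len(n))
    graphics::mtext(ord[j], side = 1, at = j, las = 2, cex = 0.45,
                    col = labcol[j], line = 0.5)
  for (j in seq_len(n))
    graphics::mtext(ord[j], side = 2, at = n - j + 1, las = 2, cex = 0.45,
                    col = labcol[j], line = 0.5)
  invisible(file)
}
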