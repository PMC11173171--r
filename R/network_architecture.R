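#' Toroidal distance on the unit sheet
#'
#' Wrapped Euclidean distance between points in normalized sheet
#' coordinates `[0, 1)^2` (all population sheets span the same
#' normalized space; periodic boundaries keep the attractor bumps
#' continuous across edges). Each component difference is reduced to at
#' most half the sheet.
#'
#' @param p numeric vector of length 2, or an n x 2 matrix.
#' @param q numeric vector of length 2, or an n x 2 matrix.
#' @return Distance(s).
#' @export
torus_dist <- function(p, q) {
  p <- matrix(p, ncol = 2)
  q <- matrix(q, ncol = 2)
  dx <- abs(p[, 1] - q[, 1]); dx <- pmin(dx, 1 - dx)
  dy <- abs(p[, 2] - q[, 2]); dy <- pmin(dy, 1 - dy)
  sqrt(dx^2 + dy^2)
}

# Signed minimal-image difference q - p on the unit torus.
torus_delta <- function(p, q) {
  d <- q - p
  d - round(d)
}

#' Scale presets for the dorsoventral grid-scale variants
#'
#' Geometry and connection-count presets reproducing the dorsoventral
#' trend: large grid scales (ventral) use wide inhibitory rings but few
#' stellate-to-interneuron connections (rings begin to overlap), small
#' scales (dorsal) use narrow rings with more connections. Mean
#' stellate-to-interneuron out-degree is 5 / 12 / 16 for large /
#' intermediate / small; interneuron counts rise to 1200 per type for
#' the large preset. Radii, widths and offsets are in normalized sheet
#' units (fractions of the stellate sheet side).
#'
#' @param name one of `"large"`, `"intermediate"`, `"small"`.
#' @return A list of class `scale_preset`.
#' @export
scale_preset <- function(name = c("intermediate", "large", "small")) {
  name <- match.arg(name)
  base <- list(
    large        = list(ring_radius = 0.30, out_mean = 5,
                        in_counts = c(1200, 1200, 1200)),
    intermediate = list(ring_radius = 0.21, out_mean = 12,
                        in_counts = c(834, 833, 833)),
    small        = list(ring_radius = 0.15, out_mean = 16,
                        in_counts = c(834, 833, 833)))[[name]]
  # ring width and inhibitory footprint scale with the ring radius so
  # bump and surround geometry stay similar across scales
  structure(list(name = name,
                 ring_radius = base$ring_radius,
                 ring_width = round(base$ring_radius * 4 / 7, 3),
                 offset = 0.033,
                 out_mean = base$out_mean,
                 out_sd = 2,
                 in_mean = 142,
                 in_sd = 66,
                 in_sigma = round(base$ring_radius * 2 / 7, 3),
                 in_counts = base$in_counts),
            class = "scale_preset")
}

#' Build population sheets
#'
#' Arranges every population on a 2-D sheet spanning the same normalized
#' coordinate space. Grid (stellate), conjunctive and place populations
#' must be perfect squares and are aligned one-to-one; interneuron
#' populations use the smallest near-square sheet holding their count,
#' with trailing slots unused.
#'
#' @param counts named integer vector of population sizes; names must be
#'   neuron-type names from [default_neuron_params()]. Defaults to the
#'   table's counts.
#' @return A list of population descriptors (`name`, `role`, `count`,
#'   `rows`, `cols`, `pos` normalized n x 2, `params`), class
#'   `can_populations`.
#' @export
build_sheets <- function(counts = NULL) {
  tab <- default_neuron_params()
  if (is.null(counts)) {
    counts <- stats::setNames(tab$count, tab$name)
  }
  missing <- setdiff(tab$name, names(counts))
  if (length(missing))
    stop("build_sheets: missing counts for: ", paste(missing, collapse = ", "))
  pops <- lapply(tab$name, function(nm) {
    n <- as.integer(counts[[nm]])
    role <- tab$role[tab$name == nm]
    if (role %in% c("grid", "conjunctive", "place")) {
      side <- sqrt(n)
      if (side != round(side))
        stop(sprintf(
          "build_sheets: %s count %d is not a square; nearest squares are %d and %d",
          nm, n, floor(side)^2, ceiling(side)^2))
      rows <- cols <- as.integer(side)
    } else {
      rows <- as.integer(ceiling(sqrt(n)))
      cols <- as.integer(ceiling(n / rows))
    }
    idx <- seq_len(n) - 1L
    pos <- cbind((idx %% cols + 0.5) / cols,
                 (idx %/% cols + 0.5) / rows)
    list(name = nm, role = role, count = n, rows = rows, cols = cols,
         pos = pos, params = default_neuron_params(nm))
  })
  names(pops) <- tab$name
  structure(pops, class = "can_populations")
}

#' @export
print.can_populations <- function(x, ...) {
  cat("CAN populations:\n")
  for (p in x)
    cat(sprintf("  %-32s %5d cells  %dx%d sheet  (%s)\n",
                p$name, p$count, p$rows, p$cols, p$role))
  invisible(x)
}

#' Assign preferred movement directions to the stellate sheet
#'
#' Each grid cell is labelled north, south, east or west. Labels tile
#' the sheet in 2x2 blocks so every block contains all four directions
#' and each direction covers a quarter of the sheet.
#'
#' @param pop a grid population from [build_sheets()].
#' @return Character vector (`"E"`, `"N"`, `"W"`, `"S"`) per cell, with
#'   attribute `angle` holding the direction in radians.
#' @export
assign_preferred_directions <- function(pop) {
  idx <- seq_len(pop$count) - 1L
  row <- idx %/% pop$cols
  col <- idx %% pop$cols
  key <- (row %% 2L) * 2L + (col %% 2L)
  dirs <- c("E", "N", "W", "S")[key + 1L]
  angle <- c(E = 0, N = pi / 2, W = pi, S = 3 * pi / 2)[dirs]
  attr(dirs, "angle") <- unname(angle)
  dirs
}

# Unit vector for a direction label.
dir_vector <- function(dir) {
  switch(dir, E = c(1, 0), N = c(0, 1), W = c(-1, 0), S = c(0, -1))
}

#' Build the center-surround connection set
#'
#' Constructs the full synapse list. Stellate-to-interneuron connections
#' target interneuron-sheet cells on an annulus whose center is the
#' stellate's position shifted by the preset offset along the cell's
#' preferred direction (the displaced ring is what converts directional
#' drive into bump motion). Each interneuron connects back to stellate
#' cells in a Gaussian neighbourhood of its own position, so the
#' composite disynaptic profile seen by a bump is an annulus with
#' Gaussian falloff and an untouched inner disk: center firing survives
#' through absence of inhibition. Conjunctive-to-stellate and
#' place-to-stellate connections are one-to-one with unitary weight.
#'
#' @param pops populations from [build_sheets()].
#' @param dirs preferred directions from [assign_preferred_directions()].
#' @param preset a [scale_preset] (or name accepted by it).
#' @param seed integer seed governing all connection sampling; draws are
#'   made row-major by presynaptic index.
#' @return A list of class `connection_set` with `edges` (data frame:
#'   `pre`, `post` global 1-based indices, `weight`, `class` id into the
#'   class table), `classes` (the [default_synapse_params] table),
#'   `offsets` (global index offset per population) and the preset.
#' @export
build_cs_connectivity <- function(pops, dirs, preset = scale_preset(), seed = 1L) {
  if (is.character(preset)) preset <- scale_preset(preset)
  if (preset$ring_radius + preset$ring_width / 2 > 0.5)
    stop("build_cs_connectivity: annulus radius ", preset$ring_radius,
         " (+ width/2) exceeds half the sheet; rings would overlap themselves")
  classes <- default_synapse_params()
  pop_names <- names(pops)
  offs <- cumsum(c(0L, vapply(pops, `[[`, integer(1), "count")))[seq_along(pops)]
  names(offs) <- pop_names
  stell <- pops[["MEC LII Stellate"]]
  in_names <- pop_names[vapply(pops, function(p) p$role == "interneuron", logical(1))]
  set.seed(as.integer(seed))

  pre_l <- list(); post_l <- list(); w_l <- list(); cl_l <- list()
  add <- function(pre, post, w, cl) {
    k <- length(pre_l) + 1L
    pre_l[[k]] <<- pre; post_l[[k]] <<- post; w_l[[k]] <<- w; cl_l[[k]] <<- cl
  }

  # one-to-one drive classes (unitary weights)
  n_s <- stell$count
  add(offs[["EC LI-II Multipolar Pyramidal"]] + seq_len(n_s),
      offs[["MEC LII Stellate"]] + seq_len(n_s), rep(1, n_s),
      rep(match("EC LI-II Multipolar Pyramidal to MEC LII Stellate",
                classes$name), n_s))
  add(offs[["CA1 Pyramidal"]] + seq_len(n_s),
      offs[["MEC LII Stellate"]] + seq_len(n_s), rep(1, n_s),
      rep(match("CA1 Pyramidal to MEC LII Stellate", classes$name), n_s))

  # stellate -> interneuron annuli
  r_lo <- preset$ring_radius - preset$ring_width / 2
  r_hi <- preset$ring_radius + preset$ring_width / 2
  ang <- attr(dirs, "angle")
  shift <- cbind(cos(ang), sin(ang)) * preset$offset
  centers <- (stell$pos + shift) %% 1
  for (inn in in_names) {
    ip <- pops[[inn]]
    cl <- match(paste("MEC LII Stellate to", inn), classes$name)
    cap <- floor(0.259 * ip$count)  # reported connectivity ceiling
    for (i in seq_len(n_s)) {
      d <- torus_dist(matrix(centers[i, ], nrow(ip$pos), 2, byrow = TRUE), ip$pos)
      members <- which(d >= r_lo & d <= r_hi)
      if (!length(members)) next
      k <- round(stats::rnorm(1, preset$out_mean, preset$out_sd))
      k <- max(1L, min(k, length(members), cap))
      # angularly stratified draw: spread the k targets evenly around the
      # ring (random rotation) so the sampled annulus stays isotropic;
      # unstructured subsampling leaves quenched azimuthal noise that
      # pins the attractor pattern
      delta <- torus_delta(matrix(centers[i, ], length(members), 2,
                                  byrow = TRUE), ip$pos[members, , drop = FALSE])
      angm <- atan2(delta[, 2], delta[, 1])
      ord <- order(angm)
      start <- stats::runif(1)
      pick <- unique(1L + floor(((seq_len(k) - 1) / k + start) %% 1 *
                                  length(members)))
      tgt <- members[ord[pick]]
      add(rep(offs[["MEC LII Stellate"]] + i, length(tgt)),
          offs[[inn]] + tgt, rep(1, length(tgt)), rep(cl, length(tgt)))
    }
  }

  # interneuron -> stellate Gaussian neighbourhoods
  area_scale <- n_s / 1600  # connection counts printed for the 40x40 sheet
  in_mean <- preset$in_mean * area_scale
  in_sd <- preset$in_sd * area_scale
  for (inn in in_names) {
    ip <- pops[[inn]]
    cl <- match(paste(inn, "to MEC LII Stellate"), classes$name)
    for (j in seq_len(ip$count)) {
      d <- torus_dist(matrix(ip$pos[j, ], n_s, 2, byrow = TRUE), stell$pos)
      cand <- which(d <= 4 * preset$in_sigma)  # wide enough that count
      # draws two SDs above the mean are not clipped by the candidate disk
      if (!length(cand)) next
      m <- round(stats::rnorm(1, in_mean, in_sd))
      m <- max(1L, min(m, length(cand)))
      # nearest-m targets with Gaussian center-surround weights; only the
      # count is stochastic, keeping the inhibitory footprint smooth
      tgt <- cand[order(d[cand])][seq_len(m)]
      w <- exp(-d[tgt]^2 / (2 * preset$in_sigma^2))
      add(rep(offs[[inn]] + j, length(tgt)),
          offs[["MEC LII Stellate"]] + tgt, w, rep(cl, length(tgt)))
    }
  }

  edges <- data.frame(pre = unlist(pre_l), post = unlist(post_l),
                      weight = unlist(w_l), class = unlist(cl_l))
  if (any(edges$pre == edges$post))
    stop("build_cs_connectivity: self-connection produced")  # defensive
  structure(list(edges = edges, classes = classes, offsets = offs,
                 preset = preset, seed = as.integer(seed)),
            class = "connection_set")
}

#' @export
print.connection_set <- function(x, ...) {
  cat(sprintf("connection_set: %d synapses, %d classes, preset '%s'\n",
              nrow(x$edges), length(unique(x$edges$class)), x$preset$name))
  invisible(x)
}

#' Census of a connection set
#'
#' Per connection class: number of synapses, mean and SD of the
#' out-degree over all presynaptic cells of the class (cells with no
#' synapse of the class count as zero), mean in-degree over connected
#' postsynaptic cells, and the weight range.
#'
#' @param connset a [build_cs_connectivity()] result.
#' @param pops the populations the set was built from.
#' @return Data frame, one row per connection class.
#' @export
connectivity_census <- function(connset, pops) {
  classes <- connset$classes
  offs <- connset$offsets
  counts <- vapply(pops, `[[`, integer(1), "count")
  out <- lapply(seq_len(nrow(classes)), function(ci) {
    e <- connset$edges[connset$edges$class == ci, ]
    pre_pop <- classes$pre[ci]
    n_pre <- counts[[pre_pop]]
    if (nrow(e) == 0L) {
      return(data.frame(class = classes$name[ci], n_syn = 0L,
                        out_mean = 0, out_sd = 0, in_mean = 0,
                        w_min = NA_real_, w_max = NA_real_))
    }
    od <- tabulate(e$pre - offs[[pre_pop]], nbins = n_pre)
    id <- table(e$post)
    data.frame(class = classes$name[ci], n_syn = nrow(e),
               out_mean = mean(od), out_sd = stats::sd(od),
               in_mean = mean(id), w_min = min(e$weight),
               w_max = max(e$weight))
  })
  do.call(rbind, out)
}
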