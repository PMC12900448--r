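#' Branched neuronal morphology
#'
#' A morphology is a tree of tapered cylindrical segments. Each segment has a
#' proximal and a distal radius (a frustum), a length, and a region tag. The
#' tree must have exactly one root; every non-root segment attaches to the
#' distal end of its parent.
#'
#' @param segments data frame with columns `id` (integer), `parent` (integer
#'   id or `NA` for the root), `prox_radius`, `dist_radius`, `length` (all
#'   micrometre, strictly positive), and `tag` (one of `"soma"`, `"apical"`,
#'   `"basal"`, `"dendrite"`, `"spine"`, `"prp"`).
#' @return An object of class `morphology`.
#' @export
morphology <- function(segments) {
  req <- c("id", "parent", "prox_radius", "dist_radius", "length", "tag")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("segments must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(segments) == 0L) stop("morphology must contain at least one segment")
  if (anyDuplicated(segments$id)) stop("segment ids must be unique")
  if (any(segments$length <= 0)) stop("segment lengths must be positive")
  if (any(segments$prox_radius <= 0) || any(segments$dist_radius <= 0))
    stop("segment radii must be positive")
  root <- which(is.na(segments$parent))
  if (length(root) != 1L)
    stop("morphology must have exactly one root segment, found ", length(root))
  known <- stats::setNames(seq_len(nrow(segments)), segments$id)
  for (i in seq_len(nrow(segments))) {
    p <- segments$parent[i]
    if (!is.na(p) && !as.character(p) %in% names(known))
      stop("segment ", segments$id[i], " references unknown parent ", p)
  }
  # topological sort (parents before children); also detects cycles
  order <- integer(0)
  placed <- rep(FALSE, nrow(segments))
  placed[root] <- TRUE
  order <- root
  repeat {
    ready <- which(!placed &
                     segments$parent %in% segments$id[order])
    if (!length(ready)) break
    placed[ready] <- TRUE
    order <- c(order, ready)
  }
  if (!all(placed))
    stop("morphology contains a cycle or disconnected segments")
  segments <- segments[order, , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(segments = segments), class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<morphology: %d segments, total length %.6g um>\n",
              nrow(s), sum(s$length)))
  tab <- table(s$tag)
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Single unbranched cable
#'
#' @param length,radius cylinder dimensions in micrometre.
#' @param tag region tag.
#' @return A one-segment [morphology()].
#' @export
cylinder_morphology <- function(length, radius, tag = "dendrite") {
  morphology(data.frame(id = 1L, parent = NA_integer_, prox_radius = radius,
                        dist_radius = radius, length = length, tag = tag))
}

# frustum volume and lateral area for radii r0 -> r1 over axial length h
.frustum_volume <- function(r0, r1, h) pi * h / 3 * (r0^2 + r0 * r1 + r1^2)
.frustum_lateral <- function(r0, r1, h) pi * (r0 + r1) * sqrt(h^2 + (r1 - r0)^2)

#' Discretize a morphology into compartments
#'
#' Splits every segment into `ceiling(L / dl)` equal-length compartments and
#' computes per-compartment geometry (frustum volume, lateral membrane area,
#' centre cross-section) plus the compartment tree used by the implicit
#' solvers. Segments tagged `"prp"` (the designated protein-synthesis
#' compartment that cell specifications insert at the soma midpoint) always
#' map to a single compartment.
#'
#' @param morph a [morphology()].
#' @param dl target compartment length, micrometre (> 0).
#' @return An object of class `compartment_grid` with per-compartment vectors
#'   `length`, `volume` (um^3), `area_lateral` (um^2), `a_center` (um^2,
#'   cross-section at the compartment centre), `parent` (1-based index, 0 for
#'   the root), `seg` (owning segment row), `tag`, and per-segment index
#'   ranges `seg_first`/`seg_last`.
#' @export
discretize <- function(morph, dl) {
  stopifnot(inherits(morph, "morphology"))
  if (dl <= 0) stop("dl must be positive")
  s <- morph$segments
  nseg <- nrow(s)
  ncomp_seg <- ifelse(s$tag == "prp", 1L, as.integer(ceiling(s$length / dl)))
  n <- sum(ncomp_seg)
  len <- volume <- alat <- acen <- numeric(n)
  parent <- integer(n)
  seg <- integer(n)
  tag <- character(n)
  seg_first <- seg_last <- integer(nseg)
  # distal compartment of each segment row, for wiring children
  seg_tail <- integer(nseg)
  idx <- 0L
  seg_row <- stats::setNames(seq_len(nseg), s$id)
  for (k in seq_len(nseg)) {
    m <- ncomp_seg[k]
    h <- s$length[k] / m
    r0 <- s$prox_radius[k]
    r1 <- s$dist_radius[k]
    pcomp <- if (is.na(s$parent[k])) 0L else seg_tail[seg_row[[as.character(s$parent[k])]]]
    seg_first[k] <- idx + 1L
    for (j in seq_len(m)) {
      idx <- idx + 1L
      fa <- (j - 1) / m
      fb <- j / m
      ra <- r0 + (r1 - r0) * fa
      rb <- r0 + (r1 - r0) * fb
      len[idx] <- h
      volume[idx] <- .frustum_volume(ra, rb, h)
      alat[idx] <- .frustum_lateral(ra, rb, h)
      rc <- (ra + rb) / 2
      acen[idx] <- pi * rc^2
      parent[idx] <- pcomp
      seg[idx] <- k
      tag[idx] <- s$tag[k]
      pcomp <- idx
    }
    seg_last[k] <- idx
    seg_tail[k] <- idx
  }
  structure(list(n = n, length = len, volume = volume, area_lateral = alat,
                 a_center = acen, parent = parent, seg = seg, tag = tag,
                 seg_first = seg_first, seg_last = seg_last,
                 segments = s),
            class = "compartment_grid")
}

#' @export
print.compartment_grid <- function(x, ...) {
  cat(sprintf("<compartment_grid: %d compartments, total volume %.6g um^3>\n",
              x$n, sum(x$volume)))
  invisible(x)
}

# symmetric inter-compartment coupling 1 / (h_i/(2 q A_i) + h_p/(2 q A_p));
# with q = D this is the diffusive conductance (um^3/ms), with q = 1/R_l the
# axial electrical conductance apart from unit conversion
.series_coupling <- function(grid, q) {
  g <- numeric(grid$n)
  has_parent <- grid$parent > 0L
  i <- which(has_parent)
  p <- grid$parent[i]
  g[i] <- 1 / (grid$length[i] / (2 * q * grid$a_center[i]) +
                 grid$length[p] / (2 * q * grid$a_center[p]))
  g
}

#' Total dissolved amount of a species on a grid
#'
#' Sums concentration times compartment volume, `sum_i c_i V_i`, converting
#' cubic-micrometre volumes to litres, so the result is in micromole when the
#' field is in micromole per litre.
#'
#' @param field a [species_field()].
#' @param grid the [discretize()] grid the field lives on.
#' @return Total amount (umol).
#' @export
total_amount <- function(field, grid) {
  stopifnot(inherits(field, "species_field"), inherits(grid, "compartment_grid"))
  if (length(field$conc) != grid$n)
    stop("field has ", length(field$conc), " compartments, grid has ", grid$n)
  sum(field$conc * grid$volume) * 1e-15
}

# -- morphological cell specifications ---------------------------------------

#' Simplified pyramidal-cell specification
#'
#' Builds the reduced multi-compartment cell used in the network experiments:
#' a cylindrical soma split into two halves with a protein-synthesis
#' compartment at its midpoint, an apical dendrite receiving external input,
#' and a basal dendrite receiving recurrent excitation. All compartments share
#' one radius. With `dl = 1` the long-dendrite small cell discretizes to 48
#' compartments and the short-dendrite one to 31.
#'
#' @param size `"small"` (radius 6 um, soma 12 um) or `"large"` (radius
#'   12 um, soma 24 um).
#' @param dendrites `"short"` (apical 12.5 um, basal 5 um) or `"long"`
#'   (apical 25 um, basal 10 um).
#' @param dl compartment length (um).
#' @return List with the parameter set (`r_comp`, `l_soma`, `l_apical`,
#'   `l_basal`, `dl`, `c_morpho`), the built [morphology()], and the
#'   [discretize()]d grid plus landmark compartment indices (`soma_center`
#'   = the synthesis compartment, `apical_tip`, `basal_tip`, `soma_indices`).
#' @export
morpho_cell_spec <- function(size = c("small", "large"),
                             dendrites = c("short", "long"), dl = 1.0) {
  size <- match.arg(size)
  dendrites <- match.arg(dendrites)
  r <- if (size == "small") 6.0 else 12.0
  l_soma <- if (size == "small") 12.0 else 24.0
  l_api <- if (dendrites == "short") 12.5 else 25.0
  l_bas <- if (dendrites == "short") 5.0 else 10.0
  c_morpho <- if (size == "small") {
    if (dendrites == "short") 1.035 else 1.020
  } else {
    if (dendrites == "short") 1.030 else 1.018
  }
  # chain: basal (root) -> soma half A -> synthesis compartment -> soma half B
  #        -> apical; children attach at the distal end of their parent
  segs <- data.frame(
    id = 1:5,
    parent = c(NA, 1L, 2L, 3L, 4L),
    prox_radius = r, dist_radius = r,
    length = c(l_bas, l_soma / 2, dl, l_soma / 2, l_api),
    tag = c("basal", "soma", "prp", "soma", "apical"))
  morph <- morphology(segs)
  grid <- discretize(morph, dl)
  srow <- match("prp", grid$segments$tag)
  list(size = size, dendrites = dendrites, r_comp = r, l_soma = l_soma,
       l_apical = l_api, l_basal = l_bas, dl = dl, c_morpho = c_morpho,
       morphology = morph, grid = grid,
       soma_center = grid$seg_first[srow],
       basal_tip = grid$seg_first[1L],
       apical_tip = grid$seg_last[match("apical", grid$segments$tag)],
       soma_indices = which(grid$tag %in% c("soma", "prp")))
}

#' Approximate point neuron morphology
#'
#' A single very small cylinder (radius 1e-3 um, length 2e-3 um) discretized
#' as one compartment, used where idealized point-neuron dynamics are wanted
#' within the compartmental framework.
#'
#' @param r_comp,l_cell cylinder radius and length (um).
#' @return A one-compartment [discretize()] grid.
#' @export
point_neuron_grid <- function(r_comp = 1e-3, l_cell = 2e-3) {
  discretize(cylinder_morphology(l_cell, r_comp, tag = "soma"), dl = l_cell)
}

# -- SWC reader / writer -----------------------------------------------------

.swc_tag <- function(type) {
  switch(as.character(type), "1" = "soma", "3" = "basal", "4" = "apical",
         "5" = "spine", "dendrite")
}

#' Load a morphology from an SWC file
#'
#' Reads the standard 7-column SWC sample format (`index type x y z radius
#' parent`). Every non-root sample becomes one frustum segment from its
#' parent sample to itself; the root sample carries the root segment radius.
#' Parse errors report the offending line number.
#'
#' @param path path to an SWC file.
#' @return A [morphology()].
#' @export
load_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- which(keep)
  if (!length(lines)) stop("SWC file contains no samples: ", path)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  n <- length(fields)
  m <- matrix(NA_real_, n, 7)
  for (i in seq_len(n)) {
    f <- suppressWarnings(as.numeric(fields[[i]]))
    if (length(f) != 7 || any(!is.finite(f)))
      stop("SWC parse error at line ", lines[i], ": expected 7 numeric fields")
    m[i, ] <- f
  }
  idx <- m[, 1]; type <- m[, 2]; xyz <- m[, 3:5, drop = FALSE]
  radius <- m[, 6]; par <- m[, 7]
  if (any(radius <= 0)) {
    bad <- which(radius <= 0)[1]
    stop("SWC parse error at line ", lines[bad], ": non-positive radius")
  }
  row_of <- stats::setNames(seq_len(n), idx)
  roots <- which(par == -1)
  if (length(roots) != 1)
    stop("SWC file must contain exactly one root sample (parent -1)")
  for (i in seq_len(n)) {
    if (par[i] != -1 && !as.character(par[i]) %in% names(row_of))
      stop("SWC parse error at line ", lines[i],
           ": sample references undefined parent ", par[i])
  }
  nonroot <- setdiff(seq_len(n), roots)
  if (!length(nonroot))
    stop("SWC file defines a single point and no segments")
  seg_of_sample <- integer(n)  # segment id ending at this sample
  seg_of_sample[roots] <- 0L
  ids <- seq_along(nonroot)
  segs <- data.frame(id = ids, parent = NA_integer_,
                     prox_radius = NA_real_, dist_radius = NA_real_,
                     length = NA_real_,
                     tag = NA_character_)
  for (k in seq_along(nonroot)) {
    i <- nonroot[k]
    p <- row_of[[as.character(par[i])]]
    d <- sqrt(sum((xyz[i, ] - xyz[p, ])^2))
    if (d <= 0)
      stop("SWC parse error at line ", lines[i],
           ": zero-length sample displacement")
    segs$parent[k] <- if (seg_of_sample[p] == 0L) NA_integer_ else seg_of_sample[p]
    segs$prox_radius[k] <- radius[p]
    segs$dist_radius[k] <- radius[i]
    segs$length[k] <- d
    segs$tag[k] <- .swc_tag(type[i])
    seg_of_sample[i] <- k
  }
  # multiple children of the root are allowed in SWC but a morphology has one
  # root segment: attach extra root children to the first root segment's
  # proximal end by making the first one the root
  nroot_children <- sum(is.na(segs$parent))
  if (nroot_children > 1) {
    first_root <- which(is.na(segs$parent))[1]
    extra <- setdiff(which(is.na(segs$parent)), first_root)
    segs$parent[extra] <- segs$id[first_root]
  }
  morphology(segs)
}

#' Write a morphology to an SWC file
#'
#' Emits one root sample plus one sample per segment; samples are laid out
#' geometrically so that inter-sample distances equal segment lengths
#' (branches fan out at distinct angles), making [load_swc()] a round trip up
#' to tree isomorphism.
#'
#' @param morph a [morphology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "morphology"))
  s <- morph$segments
  n <- nrow(s)
  type_of <- function(tag) switch(tag, soma = 1, basal = 3, apical = 4,
                                  spine = 5, 3)
  pos <- matrix(0, n + 1, 3)   # row 1 = root sample
  dir <- matrix(0, n + 1, 3)
  dir[1, ] <- c(1, 0, 0)
  sample_of_seg <- integer(n)
  child_count <- integer(n + 1)
  out <- sprintf("1 1 0 0 0 %.9g -1", s$prox_radius[1])
  for (k in seq_len(n)) {
    psample <- if (is.na(s$parent[k])) 1L else
      sample_of_seg[match(s$parent[k], s$id)]
    nc <- child_count[psample]
    child_count[psample] <- nc + 1L
    ang <- nc * 0.7
    base <- dir[psample, ]
    # rotate the parent direction in the xy-plane by the branch angle
    d <- c(base[1] * cos(ang) - base[2] * sin(ang),
           base[1] * sin(ang) + base[2] * cos(ang), 0)
    p <- pos[psample, ] + d * s$length[k]
    pos[k + 1, ] <- p
    dir[k + 1, ] <- d
    sample_of_seg[k] <- k + 1L
    out <- c(out, sprintf("%d %d %.9g %.9g %.9g %.9g %d", k + 1L,
                          type_of(s$tag[k]), p[1], p[2], p[3],
                          s$dist_radius[k], psample))
  }
  writeLines(out, path)
  invisible(path)
}
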