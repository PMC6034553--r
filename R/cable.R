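#' Passive membrane parameters
#'
#' Container for the passive cable parameters. Defaults follow the biophysics
#' of human L2/L3 pyramidal cells: low specific capacitance (~0.5 uF/cm^2),
#' a membrane time constant near 16 ms (R_m * C_m), axial resistivity in the
#' 200-300 Ohm*cm range, resting potential -86 mV, and a spine-area factor of
#' 1.9 applied to dendrites at least 60 um from the soma.
#'
#' @param c_m specific membrane capacitance, uF/cm^2
#' @param r_m specific membrane resistance, Ohm*cm^2
#' @param r_a axial resistivity, Ohm*cm
#' @param e_rest resting / leak reversal potential, mV
#' @param f_spines dimensionless spine-area correction factor (>= 1)
#' @param spine_min_dist path distance from the soma centre below which the
#'   spine correction is not applied, um
#' @return an object of class `passive_params`
#' @export
passive_params <- function(c_m = 0.5, r_m = 32000, r_a = 250, e_rest = -86,
                           f_spines = 1.9, spine_min_dist = 60) {
  stopifnot(c_m > 0, r_m > 0, r_a > 0, f_spines >= 1, spine_min_dist >= 0)
  structure(list(c_m = c_m, r_m = r_m, r_a = r_a, e_rest = e_rest,
                 f_spines = f_spines, spine_min_dist = spine_min_dist),
            class = "passive_params")
}

#' Read passive parameters from a flat key=value config file
#'
#' Keys match the [passive_params()] argument names; unknown keys error.
#' @param path path to a text file of `key = value` lines (`#` comments allowed)
#' @return a `passive_params` object
#' @export
read_passive_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  known <- names(formals(passive_params))
  if (any(!keys %in% known)) stop("unknown passive parameter key: ",
                                  paste(setdiff(keys, known), collapse = ", "))
  do.call(passive_params, as.list(setNames(vals, keys)))
}

#' Build a compartmental cable model from a morphology
#'
#' Discretises each unbranched section into compartments no longer than
#' `d_lambda` space constants at `f_lambda` Hz (at least one compartment per
#' section). A multi-point soma is collapsed into a single isopotential
#' compartment with the same membrane area. Section surface area is conserved
#' exactly by the discretisation; axial resistances use the frustum formula
#' on the SWC point geometry. The spine-area correction is *not* applied here;
#' see [apply_spine_correction()].
#'
#' @param morph a [morphology()] object
#' @param params a [passive_params()] object
#' @param d_lambda maximum compartment length in units of the AC space
#'   constant at `f_lambda` (default 0.1, the standard d-lambda rule)
#' @param f_lambda frequency (Hz) at which the space constant is evaluated
#' @return an object of class `cable_model`; compartment 1 is the soma
#' @export
build_cable_model <- function(morph, params = passive_params(),
                              d_lambda = 0.1, f_lambda = 100) {
  stopifnot(inherits(morph, "morphology"), inherits(params, "passive_params"))
  pts <- morph$points
  elen <- .point_edge_lengths(pts)
  # path distance of every point from the soma centre (root point)
  pdist <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts$parent_idx[i]
    pdist[i] <- if (p == 0L) 0 else pdist[p] + elen[i]
  }
  # soma: single equivalent-area compartment
  soma_rows <- which(pts$type == 1L)
  if (length(soma_rows) == 1L) {
    soma_area <- 4 * pi * pts$r[soma_rows]^2
  } else {
    a <- 0
    for (i in soma_rows) {
      p <- pts$parent_idx[i]
      if (p > 0L && pts$type[p] == 1L && elen[i] > 0) {
        a <- a + pi * (pts$r[i] + pts$r[p]) * elen[i]
      }
    }
    soma_area <- if (a > 0) a else 4 * pi * max(pts$r[soma_rows])^2
  }
  comp <- list(parent = 0L, ga = 0, area = soma_area,
               cm = .cm_nF(params$c_m, soma_area),
               gl = .gl_uS(params$r_m, soma_area),
               el = params$e_rest, type = 1L, section = 0L,
               path_dist = 0, rhalf = 0, is_spine = 0L)
  comp <- lapply(comp, function(x) x) # columns grown below
  sections <- .swc_sections(morph)
  # map: point row -> compartment holding it (section points map to their bin)
  point_comp <- integer(nrow(pts))
  point_comp[soma_rows] <- 1L
  sec_tab <- data.frame(section = integer(0), type = integer(0),
                        first_comp = integer(0), last_comp = integer(0),
                        length = numeric(0))
  ncomp <- 1L
  for (si in seq_along(sections)) {
    sec <- sections[[si]]
    rows <- sec$point_rows
    start <- sec$parent_point
    # per-edge geometry along the section (start point -> ... -> last point)
    chain <- c(start, rows)
    l_e <- elen[rows]
    d1 <- 2 * pts$r[chain[-length(chain)]]
    d2 <- 2 * pts$r[chain[-1L]]
    L <- sum(l_e)
    dbar <- sum((d1 + d2) / 2 * l_e) / L
    lam_cm <- sqrt((dbar * 1e-4) / (4 * pi * f_lambda * params$r_a * params$c_m * 1e-6))
    nseg <- max(1L, as.integer(ceiling(L / (d_lambda * lam_cm * 1e4))))
    edges <- data.frame(l = l_e, d1 = d1, d2 = d2)
    bins <- .discretize_section(edges, nseg, params$r_a)
    first <- ncomp + 1L
    for (k in seq_len(nseg)) {
      ncomp <- ncomp + 1L
      parent_comp <- if (k == 1L) point_comp[start] else ncomp - 1L
      ga <- 1 / (bins$rhalf[k] +
                 if (k == 1L) comp$rhalf[parent_comp] else bins$rhalf[k - 1L])
      comp$parent <- c(comp$parent, parent_comp)
      comp$ga <- c(comp$ga, ga)
      comp$area <- c(comp$area, bins$area[k])
      comp$cm <- c(comp$cm, .cm_nF(params$c_m, bins$area[k]))
      comp$gl <- c(comp$gl, .gl_uS(params$r_m, bins$area[k]))
      comp$el <- c(comp$el, params$e_rest)
      comp$type <- c(comp$type, sec$type)
      comp$section <- c(comp$section, si)
      comp$path_dist <- c(comp$path_dist, pdist[start] + bins$mid[k])
      comp$rhalf <- c(comp$rhalf, bins$rhalf[k])
      comp$is_spine <- c(comp$is_spine, 0L)
    }
    point_comp[rows] <- first - 1L +
      pmin(nseg, pmax(1L, ceiling((pdist[rows] - pdist[start]) / L * nseg)))
    sec_tab <- rbind(sec_tab, data.frame(section = si, type = sec$type,
                                         first_comp = first, last_comp = ncomp,
                                         length = L))
  }
  comp <- as.data.frame(comp)
  structure(list(comp = comp, sections = sec_tab, params = params,
                 point_comp = point_comp, morph = morph,
                 channels = NULL, ca = NULL,
                 spine_corrected = FALSE, n_spines = 0L,
                 d_lambda = d_lambda, f_lambda = f_lambda),
            class = "cable_model")
}

# Split a section's edge chain into nseg equal-arclength bins, conserving
# frustum surface area and axial resistance. Returns per-bin area (um^2),
# half axial resistance (MOhm) and bin-centre arc position (um).
.discretize_section <- function(edges, nseg, r_a) {
  L <- sum(edges$l)
  bounds <- seq(0, L, length.out = nseg + 1L)
  area <- raxial <- numeric(nseg)
  pos <- 0
  for (e in seq_len(nrow(edges))) {
    e0 <- pos; e1 <- pos + edges$l[e]
    for (k in seq_len(nseg)) {
      lo <- max(e0, bounds[k]); hi <- min(e1, bounds[k + 1L])
      if (hi <= lo) next
      f0 <- (lo - e0) / (e1 - e0); f1 <- (hi - e0) / (e1 - e0)
      da <- edges$d1[e] + (edges$d2[e] - edges$d1[e]) * f0
      db <- edges$d1[e] + (edges$d2[e] - edges$d1[e]) * f1
      area[k] <- area[k] + pi * (da + db) / 2 * (hi - lo)
      raxial[k] <- raxial[k] + .raxial_MOhm(r_a, hi - lo, da, db)
    }
    pos <- e1
  }
  data.frame(area = area, rhalf = raxial / 2,
             mid = (bounds[-1L] + bounds[-(nseg + 1L)]) / 2)
}

#' Spine-area correction factor
#'
#' The factor by which dendritic membrane is scaled to fold the total spine
#' membrane area into the cable model: (dendritic area + total spine area) /
#' dendritic area.
#'
#' @param dendritic_area dendritic membrane area, um^2 (> 0)
#' @param total_spine_area total spine membrane area, um^2 (>= 0)
#' @return the dimensionless factor F >= 1
#' @export
compute_f_spines <- function(dendritic_area, total_spine_area) {
  if (any(dendritic_area <= 0)) stop("dendritic_area must be > 0")
  if (any(total_spine_area < 0)) stop("total_spine_area must be >= 0")
  (dendritic_area + total_spine_area) / dendritic_area
}

#' Apply the global spine-area correction to a cable model
#'
#' For every dendritic compartment at a path distance of at least
#' `spine_min_dist` from the soma centre, the membrane capacitance is
#' multiplied by `f_spines` and the membrane resistance divided by it
#' (equivalently, leak conductance multiplied). Soma, axon, proximal
#' dendrites and explicit spine compartments are never corrected, and the
#' local membrane time constant R_m * C_m is unchanged.
#'
#' @param model a [build_cable_model()] result
#' @param params passive parameters supplying `f_spines` and
#'   `spine_min_dist`; defaults to the model's own
#' @return the corrected `cable_model`
#' @export
apply_spine_correction <- function(model, params = model$params) {
  stopifnot(inherits(model, "cable_model"))
  if (isTRUE(model$spine_corrected)) stop("spine correction already applied")
  if (any(model$comp$path_dist < 0)) stop("internal error: negative path distance")
  sel <- model$comp$type %in% c(3L, 4L) &
    model$comp$path_dist >= params$spine_min_dist &
    model$comp$is_spine == 0L
  model$comp$cm[sel] <- model$comp$cm[sel] * params$f_spines
  model$comp$gl[sel] <- model$comp$gl[sel] * params$f_spines
  model$spine_corrected <- TRUE
  model
}

#' @export
print.cable_model <- function(x, ...) {
  cat("cable_model:", nrow(x$comp), "compartments,",
      nrow(x$sections), "sections,", x$n_spines, "spines;",
      if (isTRUE(x$spine_corrected)) "spine-corrected;" else "uncorrected;",
      if (is.null(x$channels)) "passive\n" else
        paste0(nrow(x$channels), " channel instances\n"))
  invisible(x)
}

#' Indices of dendritic compartments
#'
#' @param model a `cable_model`
#' @param subtree `"all"`, `"basal"` or `"apical"`
#' @param include_spines include explicit spine compartments (default FALSE)
#' @return integer compartment indices
#' @export
dendritic_comps <- function(model, subtree = c("all", "basal", "apical"),
                            include_spines = FALSE) {
  subtree <- match.arg(subtree)
  types <- switch(subtree, all = c(3L, 4L), basal = 3L, apical = 4L)
  sel <- model$comp$type %in% types
  if (!include_spines) sel <- sel & model$comp$is_spine == 0L
  which(sel)
}

#' Terminal dendritic compartments (branch tips)
#'
#' Returns the last compartment of every dendritic section that has no child
#' sections (the electrical tips of the tree).
#' @param model a `cable_model`
#' @param subtree `"all"`, `"basal"` or `"apical"`
#' @return integer compartment indices
#' @export
terminal_comps <- function(model, subtree = c("all", "basal", "apical")) {
  subtree <- match.arg(subtree)
  types <- switch(subtree, all = c(3L, 4L), basal = 3L, apical = 4L)
  comp <- model$comp
  dend_secs <- model$sections[model$sections$type %in% types, ]
  has_child <- unique(comp$section[comp$parent]) # sections that parent some comp
  tips <- dend_secs$last_comp[!vapply(seq_len(nrow(dend_secs)), function(i) {
    lc <- dend_secs$last_comp[i]
    any(comp$parent == lc & comp$is_spine == 0L)
  }, logical(1))]
  tips
}
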