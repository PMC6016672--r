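# Branched compartmental morphology.
#
# A model is a tree of cylindrical compartments. Compartment 1 is the
# root (soma); every other compartment stores the index of its parent,
# which must precede it (topological order), so the tree property
# (edges = nodes - 1) holds by construction and the cable system can be
# solved by a single sweep up and down the tree.

#' Compartment graph constructor
#'
#' Builds a branched compartment tree from a per-compartment table and
#' derives membrane areas and axial coupling conductances.
#'
#' @param comps `data.frame` with one row per compartment and columns:
#'   `label` (unique character), `parent` (integer index of the parent
#'   row, `NA` for the root, which must be row 1; parents must precede
#'   children), `length` and `diam` (um, positive), `x` (path distance of
#'   the compartment centre from the soma, um), `cm` (uF/cm2), `ra`
#'   (axial resistivity, Ohm cm), `g_leak` (mS/cm2), `e_leak` (mV), and
#'   active densities `g_na`, `g_kdr`, `g_ka`, `g_ca` (mS/cm2).
#' @param synapse_comp Label or index of the compartment carrying the
#'   GABAergic synapse (optional).
#' @return An object of class `compartment_graph`.
#' @export
compartment_graph <- function(comps, synapse_comp = NULL) {
  required <- c("label", "parent", "length", "diam", "x", "cm", "ra",
                "g_leak", "e_leak", "g_na", "g_kdr", "g_ka", "g_ca")
  missing_cols <- setdiff(required, names(comps))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(comps)
  if (n < 1L) stop("empty compartment table")
  if (anyDuplicated(comps$label)) stop("compartment labels must be unique")
  if (!is.na(comps$parent[1L])) stop("row 1 must be the root (parent NA)")
  if (n > 1L) {
    p <- comps$parent[-1L]
    if (anyNA(p) || any(p < 1L) || any(p >= seq(2L, n)))
      stop("parents must be earlier rows; exactly one root allowed")
  }
  if (any(comps$length <= 0) || any(comps$diam <= 0))
    stop("invalid geometry: lengths and diameters must be positive")
  if (any(comps$cm <= 0) || any(comps$ra <= 0) || any(comps$g_leak < 0))
    stop("invalid passive parameters")
  dens <- as.matrix(comps[, c("g_na", "g_kdr", "g_ka", "g_ca")])
  if (any(dens < 0)) stop("channel densities must be non-negative")

  # membrane area of a cylinder, um2 -> cm2
  area <- pi * comps$diam * comps$length * 1e-8
  # half axial resistance of each compartment, Ohm (um -> cm)
  half_r <- comps$ra * (comps$length / 2 * 1e-4) /
    (pi * (comps$diam / 2 * 1e-4)^2)
  g_axial <- rep(NA_real_, n)
  if (n > 1L) {
    for (i in 2:n) {
      g_axial[i] <- 1e3 / (half_r[i] + half_r[comps$parent[i]])  # mS
    }
  }

  g <- structure(
    list(comps = comps, n = n, area = area, g_axial = g_axial,
         synapse_comp = NA_integer_),
    class = "compartment_graph")
  if (!is.null(synapse_comp))
    g$synapse_comp <- comp_index(g, synapse_comp)
  g
}

#' Resolve a compartment label or index
#' @param graph A [compartment_graph()].
#' @param comp Label (character) or integer index.
#' @return Integer index.
#' @export
comp_index <- function(graph, comp) {
  stopifnot(inherits(graph, "compartment_graph"))
  if (is.character(comp)) {
    i <- match(comp, graph$comps$label)
    if (anyNA(i)) stop("unknown compartment label: ",
                       paste(comp[is.na(i)], collapse = ", "))
    i
  } else {
    i <- as.integer(comp)
    stopifnot(all(i >= 1L), all(i <= graph$n))
    i
  }
}

#' Number of compartments
#' @param graph A [compartment_graph()].
#' @return Integer.
#' @export
n_compartments <- function(graph) graph$n

#' @export
print.compartment_graph <- function(x, ...) {
  cat("<compartment_graph> ", x$n, " compartments, ",
      x$n - 1L, " edges\n", sep = "")
  cat("  total membrane area: ",
      format(sum(x$area), digits = 4), " cm2\n", sep = "")
  if (!is.na(x$synapse_comp))
    cat("  synapse at: ", x$comps$label[x$synapse_comp], "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.compartment_graph <- function(x, ...) {
  out <- x$comps
  out$area_cm2 <- x$area
  out$g_axial_mS <- x$g_axial
  out
}

#' Build the standard layer-5 pyramidal neuron model
#'
#' Soma (cylinder, 20 x 20 um) plus a 500-um apical trunk divided into
#' 100 segments of 5 um, two accessory apical branches (150 x 1 um)
#' attached at the distal end of the trunk, and a single spine (head
#' 1 x 1 um; neck 1 um long, 0.07 um diameter) attached 122.5 um from
#' the soma. Sodium and delayed-rectifier potassium densities are uniform
#' everywhere; the A-type density follows [ka_density_at()] along the
#' trunk (zero at the soma, `gka_distal` in the most distal segment) and
#' stays at `gka_distal` in the accessory branches. The reporter calcium
#' channel is present only in the spine head and the trunk compartment
#' carrying the synapse; the GABAergic synapse contacts that same trunk
#' compartment.
#'
#' @param gka_distal A-type density in the most distal trunk segment
#'   (mS/cm2). The study sweeps 10-70; 70 is the control condition.
#' @param gna,gkdr,gca Uniform Na, delayed-rectifier and reporter-calcium
#'   densities (mS/cm2).
#' @param cm Specific capacitance (uF/cm2).
#' @param ra Axial resistivity (Ohm cm).
#' @param g_leak,e_leak Leak density (mS/cm2) and reversal (mV).
#' @param trunk_length,trunk_nseg,trunk_diam Trunk geometry (um).
#' @param soma_length,soma_diam Soma cylinder (um).
#' @param branch_length,branch_nseg,branch_diam Accessory branches (um).
#' @param spine_at Path distance of the spine/synapse site (um).
#' @param neck_length,neck_diam,head_length,head_diam Spine geometry (um).
#' @return A [compartment_graph()] with the synapse attached.
#' @export
build_model <- function(gka_distal = 70,
                        gna = 4, gkdr = 0.1, gca = 1e-7,
                        cm = 1, ra = 150, g_leak = 0.25, e_leak = -70,
                        trunk_length = 500, trunk_nseg = 100,
                        trunk_diam = 2,
                        soma_length = 20, soma_diam = 20,
                        branch_length = 150, branch_nseg = 15,
                        branch_diam = 1,
                        spine_at = 122.5,
                        neck_length = 1, neck_diam = 0.07,
                        head_length = 1, head_diam = 1) {
  if (any(c(trunk_length, trunk_diam, soma_length, soma_diam,
            branch_length, branch_diam, neck_length, neck_diam,
            head_length, head_diam) <= 0))
    stop("invalid geometry: all sizes must be positive")
  stopifnot(gka_distal >= 0, trunk_nseg >= 2)
  seg_len <- trunk_length / trunk_nseg
  if (spine_at <= 0 || spine_at >= trunk_length)
    stop("'spine_at' must lie strictly inside the trunk")

  seg_of <- function(x) pmin(floor(x / seg_len), trunk_nseg - 1)  # 0-based
  syn_seg <- seg_of(spine_at)

  mk <- function(label, parent, length, diam, x, g_ka, g_ca_here) {
    data.frame(label = label, parent = parent, length = length,
               diam = diam, x = x, cm = cm, ra = ra,
               g_leak = g_leak, e_leak = e_leak,
               g_na = gna, g_kdr = gkdr, g_ka = g_ka, g_ca = g_ca_here,
               stringsAsFactors = FALSE)
  }

  rows <- list(mk("soma", NA_integer_, soma_length, soma_diam, 0, 0, 0))
  # apical trunk
  for (k in 0:(trunk_nseg - 1)) {
    parent <- if (k == 0) 1L else 1L + k
    rows[[length(rows) + 1L]] <- mk(
      sprintf("trunk_%03d", k + 1L), parent, seg_len, trunk_diam,
      (k + 0.5) * seg_len,
      ka_density_at((k + 0.5) * seg_len, gka_distal,
                    trunk_length, seg_len),
      if (k == syn_seg) gca else 0)
  }
  trunk_last <- 1L + trunk_nseg
  # two accessory apical branches at the distal end of the trunk
  bseg <- branch_length / branch_nseg
  for (b in 1:2) {
    for (k in 0:(branch_nseg - 1)) {
      parent <- if (k == 0) trunk_last else length(rows)
      rows[[length(rows) + 1L]] <- mk(
        sprintf("apical%d_%02d", b, k + 1L), as.integer(parent),
        bseg, branch_diam, trunk_length + (k + 0.5) * bseg,
        gka_distal, 0)
    }
  }
  # spine: neck then head, attached to the trunk segment at spine_at
  syn_idx <- 1L + syn_seg + 1L
  g_ka_site <- rows[[syn_idx]]$g_ka
  rows[[length(rows) + 1L]] <- mk("spine_neck", syn_idx, neck_length,
                                  neck_diam, spine_at, g_ka_site, 0)
  rows[[length(rows) + 1L]] <- mk("spine_head", as.integer(length(rows)),
                                  head_length, head_diam, spine_at,
                                  g_ka_site, gca)

  comps <- do.call(rbind, rows)
  compartment_graph(comps, synapse_comp = comps$label[syn_idx])
}
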