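#' Specification of an analytic test solid
#'
#' Supported kinds and their size parameters (all Angstrom):
#' \describe{
#'   \item{`solid_sphere`}{`radius` (default 8): convex control, no pocket.}
#'   \item{`sphere_with_cap_pocket`}{`radius` (9), `pocket_radius` (6),
#'     `pocket_center_dist` (6.5): a host sphere with a spherical-cap
#'     pocket carved by a second sphere centred `pocket_center_dist` above
#'     the host centre along +z.  The defaults give an open funnel mouth
#'     of about 6 Angstrom radius and 6 Angstrom depth, so the concave
#'     pocket wall makes up roughly a fifth of the surface -- the
#'     proportions of a dominant ligand site on a small domain, and large
#'     enough at 1 Angstrom spacing that the wall's solid-angle profile is
#'     smooth across neighbouring voxel layers.}
#'   \item{`slab`}{`lx`, `ly`, `lz` (30, 30, 8): flat-face reference.}
#'   \item{`cube`}{`edge` (20): corner/edge/face reference.}
#'   \item{`cylindrical_well`}{`lx`, `ly`, `lz` (24, 24, 14),
#'     `well_radius` (2.5), `well_depth` (8): a narrow well sunk into the
#'     top face, deeper than the 6 Angstrom solid-angle sphere.}
#'   \item{`enclosed_void`}{`radius` (9), `void_radius` (3): a buried
#'     spherical cavity with no mouth.}
#'   \item{`complementary_pair`}{`edge` (24): a box split by the plane
#'     z = 0.5 into two solids that exactly partition it, for
#'     solid-angle complementarity checks.}
#' }
#'
#' @param kind One of the shape kinds above.
#' @param ... Size parameters overriding the defaults.
#' @param spacing Grid spacing in Angstrom.
#' @param padding Grid clearance in Angstrom (>= 10 so all downstream
#'   virtual spheres fit).
#' @param seed Integer seed for jittered pseudo-atom placement.
#' @param jitter Half-width (Angstrom) of the uniform jitter applied to
#'   pseudo-atom positions; 0 (default) gives exact lattice placement.
#' @return Object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("solid_sphere", "sphere_with_cap_pocket",
                                "slab", "cube", "cylindrical_well",
                                "enclosed_void", "complementary_pair"),
                       ..., spacing = 1, padding = 10, seed = 1L,
                       jitter = 0) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    solid_sphere = list(radius = 8),
    sphere_with_cap_pocket = list(radius = 9, pocket_radius = 6,
                                  pocket_center_dist = 6.5),
    slab = list(lx = 30, ly = 30, lz = 8),
    cube = list(edge = 20),
    cylindrical_well = list(lx = 24, ly = 24, lz = 14, well_radius = 2.5,
                            well_depth = 8),
    enclosed_void = list(radius = 9, void_radius = 3),
    complementary_pair = list(edge = 24)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) {
    stop("unknown parameter(s) for kind '", kind, "': ",
         paste(bad, collapse = ", "))
  }
  p <- utils::modifyList(defaults, override)
  if (any(unlist(p) <= 0)) stop("all size parameters must be > 0")
  if (kind == "sphere_with_cap_pocket" && p$pocket_radius >= p$radius) {
    stop("pocket_radius must be smaller than the host radius")
  }
  if (kind == "cylindrical_well" && p$well_depth >= p$lz) {
    stop("well_depth must be smaller than the slab thickness lz")
  }
  if (kind == "enclosed_void" && p$void_radius >= p$radius) {
    stop("void_radius must be smaller than the outer radius")
  }
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(kind = kind, params = p, spacing = spacing,
                 padding = padding, seed = as.integer(seed),
                 jitter = jitter),
            class = "shape_spec")
}

# analytic inside-test of a spec; pts is an n x 3 matrix.  For
# complementary_pair, `half` selects the z <= 0.5 ("A") or z > 0.5 ("B")
# part.
shape_inside <- function(spec, pts, half = c("A", "B")) {
  p <- spec$params
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  switch(spec$kind,
    solid_sphere = x^2 + y^2 + z^2 <= p$radius^2,
    sphere_with_cap_pocket = {
      host <- x^2 + y^2 + z^2 <= p$radius^2
      carve <- x^2 + y^2 + (z - p$pocket_center_dist)^2 <= p$pocket_radius^2
      host & !carve
    },
    slab = abs(x) <= p$lx / 2 & abs(y) <= p$ly / 2 & abs(z) <= p$lz / 2,
    cube = abs(x) <= p$edge / 2 & abs(y) <= p$edge / 2 &
      abs(z) <= p$edge / 2,
    cylindrical_well = {
      body <- abs(x) <= p$lx / 2 & abs(y) <= p$ly / 2 & abs(z) <= p$lz / 2
      well <- x^2 + y^2 <= p$well_radius^2 & z > p$lz / 2 - p$well_depth
      body & !well
    },
    enclosed_void = {
      r2 <- x^2 + y^2 + z^2
      r2 <= p$radius^2 & r2 >= p$void_radius^2
    },
    complementary_pair = {
      box <- abs(x) <= p$edge / 2 & abs(y) <= p$edge / 2 &
        abs(z) <= p$edge / 2
      if (match.arg(half) == "A") box & z <= 0.5 else box & z > 0.5
    }
  )
}

# analytic carved-void test (the open pocket region) for pocket shapes
shape_void <- function(spec, pts) {
  p <- spec$params
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  switch(spec$kind,
    sphere_with_cap_pocket =
      x^2 + y^2 + z^2 <= p$radius^2 &
      x^2 + y^2 + (z - p$pocket_center_dist)^2 <= p$pocket_radius^2,
    cylindrical_well =
      abs(x) <= p$lx / 2 & abs(y) <= p$ly / 2 & abs(z) <= p$lz / 2 &
      x^2 + y^2 <= p$well_radius^2 & z > p$lz / 2 - p$well_depth,
    stop("shape kind '", spec$kind, "' has no carved pocket")
  )
}

shape_extent <- function(spec) {
  p <- spec$params
  switch(spec$kind,
    solid_sphere = rep(p$radius, 3),
    sphere_with_cap_pocket = rep(p$radius, 3),
    slab = c(p$lx, p$ly, p$lz) / 2,
    cube = rep(p$edge / 2, 3),
    cylindrical_well = c(p$lx, p$ly, p$lz) / 2,
    enclosed_void = rep(p$radius, 3),
    complementary_pair = rep(p$edge / 2, 3)
  )
}

# snapped symmetric lattice of voxel centres covering the shape + padding
shape_lattice <- function(spec) {
  ext <- shape_extent(spec)
  lo <- floor((-ext - spec$padding) / spec$spacing) * spec$spacing
  hi <- ceiling((ext + spec$padding) / spec$spacing) * spec$spacing
  dims <- as.integer(round((hi - lo) / spec$spacing)) + 1L
  list(lo = lo, dims = dims,
       ax = lapply(1:3, function(a) {
         lo[a] + spec$spacing * (seq_len(dims[a]) - 1)
       }))
}

#' Occupancy grid of an analytic solid
#'
#' Evaluates the shape's inside-test at every voxel centre of a snapped,
#' padded lattice (the same centre-inside convention as [build_grid()]).
#' Deterministic given the spec.
#'
#' @param spec A [shape_spec()].
#' @return A [voxel_grid()]; for `kind = "complementary_pair"`, a list of
#'   two grids `A` (z <= 0.5 part) and `B` (z > 0.5 part) on the same
#'   lattice.
#' @export
generate_grid <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  lat <- shape_lattice(spec)
  pts <- as.matrix(expand.grid(x = lat$ax[[1]], y = lat$ax[[2]],
                               z = lat$ax[[3]], KEEP.OUT.ATTRS = FALSE))
  make <- function(half) {
    occ <- array(shape_inside(spec, pts, half), lat$dims)
    voxel_grid(occ, origin = lat$lo, spacing = spec$spacing)
  }
  if (spec$kind == "complementary_pair") {
    list(A = make("A"), B = make("B"))
  } else {
    make("A")
  }
}

#' Pseudo-atom PDB rendering of an analytic solid
#'
#' Packs carbon pseudo-atoms (vdW 1.70 Angstrom) on a 1.4 Angstrom lattice
#' filling the solid -- the pitch is below one atom diameter so the sphere
#' union has no internal holes and re-voxelization reproduces the analytic
#' grid to within about one atom radius of the boundary.  Atoms are written as standard `ATOM`
#' records on chain A with one residue per atom, so residue-level truth
#' tables are unambiguous.  For pocket-bearing kinds
#' (`sphere_with_cap_pocket`, `cylindrical_well`) a ground-truth table of
#' pocket-lining residues is included: the fixture is re-voxelized with
#' [build_grid()] (the same deterministic centre-inside convention the
#' pipeline uses), the pocket wall is taken as the surface voxels
#' face-adjacent to an empty voxel whose centre lies in the analytic
#' carved void at least `truth_depth_margin` below the host surface (rim
#' contacts are thereby excluded -- a concave-surface detector cannot
#' distinguish the convex rim from the surrounding body), and the truth is
#' every residue with an atom within `truth_contact` of a wall voxel
#' centre.
#'
#' @param spec A [shape_spec()] (not `complementary_pair`).
#' @param path Optional output PDB path; the truth table is then written
#'   alongside as `<path>.truth.tsv`.
#' @param pitch Pseudo-atom lattice pitch in Angstrom.
#' @param truth_contact Contact distance for the truth annotation.
#' @param truth_depth_margin Minimum depth (Angstrom) below the host
#'   surface for a void voxel to define pocket-lining contacts.
#' @return Object of class `shape_fixture`: list with `lines` (PDB text),
#'   `structure` (parsed `pdb_structure`), `truth` (data frame or `NULL`),
#'   and `spec`.
#' @export
generate_pdb <- function(spec, path = NULL, pitch = 1.4,
                         truth_contact = 4.5, truth_depth_margin = 1.5) {
  stopifnot(inherits(spec, "shape_spec"))
  if (spec$kind == "complementary_pair") {
    stop("complementary_pair is a grid-level fixture; no PDB rendering")
  }
  ext <- shape_extent(spec)
  ax <- lapply(1:3, function(a) {
    n <- floor(ext[a] / pitch)
    pitch * seq.int(-n, n)
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  pts <- pts[shape_inside(spec, pts), , drop = FALSE]
  if (nrow(pts) == 0L) stop("shape produced no pseudo-atoms")
  if (spec$jitter > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    pts <- pts + matrix(stats::runif(length(pts), -spec$jitter,
                                     spec$jitter), ncol = 3)
  }
  n <- nrow(pts)
  lines <- c(sprintf(
    "ATOM  %5d  C   DUM A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000L, seq_len(n) %% 10000L,
    pts[, 1], pts[, 2], pts[, 3]), "END")
  tmp <- tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  st <- parse_pdb(tmp)
  unlink(tmp)
  st$source_id <- paste0(spec$kind, ".pdb")
  truth <- NULL
  if (spec$kind %in% c("sphere_with_cap_pocket", "cylindrical_well")) {
    g <- build_grid(st, spacing = spec$spacing, padding = spec$padding)
    surf <- classify_surface(g)
    deep_void <- function(pts) {
      depth_ok <- if (spec$kind == "sphere_with_cap_pocket") {
        sqrt(rowSums(pts^2)) <= spec$params$radius - truth_depth_margin
      } else {
        pts[, 3] <= spec$params$lz / 2 - truth_depth_margin
      }
      shape_void(spec, pts) & depth_ok
    }
    lines_wall <- rep(FALSE, nrow(surf))
    for (d in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                   c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))) {
      nb <- sweep(surf, 2, d, "+")
      lines_wall <- lines_wall |
        (g$label[nb] == VOX_EXTERIOR & deep_void(voxel_centers(g, nb)))
    }
    wall <- voxel_centers(g, surf[lines_wall, , drop = FALSE])
    truth <- residues_near(st, wall, truth_contact)[, c("chain", "resseq")]
    rownames(truth) <- NULL
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    if (!is.null(truth)) write_truth(truth, paste0(path, ".truth.tsv"))
  }
  structure(list(lines = lines, structure = st, truth = truth,
                 spec = spec),
            class = "shape_fixture")
}
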