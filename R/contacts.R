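#' @title Probe-excluded atomic contact areas
#' @description Interface fingerprints of ligand-receptor complexes built
#'   from pairwise atomic contact areas. Each atom is inflated by a solvent
#'   probe radius; the contact area between a ligand atom and a receptor
#'   atom is the part of the ligand atom's probe-expanded sphere buried
#'   inside the receptor atom's probe-expanded sphere (with multiply-buried
#'   surface assigned to the most deeply burying atom). A zero area between
#'   two atoms means a water molecule could be interposed between them;
#'   larger areas mean tighter packing. Areas are aggregated per receptor
#'   residue, with large prosthetic groups (heme) optionally subdivided
#'   into named subsites.
#' @name contacts
NULL

# Bondi-style van der Waals radii (Angstrom); metals get working values
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98,
                Fe = 2.00, Zn = 1.39, Mg = 1.73, Mn = 2.00, Cu = 1.40,
                Se = 1.90)
.VDW_DEFAULT <- 1.70

.element_from_name <- function(elety, elesy = NULL) {
  el <- if (!is.null(elesy)) trimws(elesy) else ""
  el[is.na(el)] <- ""
  fallback <- gsub("[^A-Za-z]", "", trimws(elety))
  # two-letter symbols first (FE, CL, ZN, BR), else first letter
  two <- paste0(toupper(substr(fallback, 1, 1)),
                tolower(substr(fallback, 2, 2)))
  one <- toupper(substr(fallback, 1, 1))
  guess <- ifelse(two %in% names(.VDW_RADII), two, one)
  el_norm <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  ifelse(el_norm %in% names(.VDW_RADII), el_norm, guess)
}

.vdw_radius <- function(element) {
  r <- .VDW_RADII[element]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(element[is.na(r)]),
                                         collapse = ", "),
            "; using default vdW radius ", .VDW_DEFAULT, " A")
    r[is.na(r)] <- .VDW_DEFAULT
  }
  unname(r)
}

#' Load a ligand-receptor complex from a PDB file
#'
#' Reads one posed ligand plus its receptor from a PDB file and splits the
#' atoms into ligand and receptor sphere sets with van der Waals radii
#' assigned from a Bondi-style element table. HETATM cofactors that are not
#' the selected ligand (heme, metal ions, pterins, ...) stay on the
#' receptor side. For alternate locations only the first conformer is
#' kept. Hydrogens are dropped by default because docking outputs differ in
#' protonation.
#'
#' @param path PDB file path.
#' @param ligand_selector residue name (e.g. `"LIG"`) or single-character
#'   chain id identifying the ligand.
#' @param by `"resid"` (default) or `"chain"`: how to interpret
#'   `ligand_selector`.
#' @param drop_hydrogens drop H atoms (default TRUE).
#' @return list with data.frames `receptor` and `ligand`; columns
#'   `serial, element, x, y, z, vdw_radius, owner, residue_key` (and the
#'   raw `chain`, `resid`, `resno`). `residue_key` is
#'   `"chain:resid:resno"`.
#' @export
load_complex <- function(path, ligand_selector, by = c("resid", "chain"),
                         drop_hydrogens = TRUE) {
  by <- match.arg(by)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed PDB file ", path, ": ",
                         conditionMessage(e)))
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  element <- .element_from_name(at$elety, at$elesy)
  if (drop_hydrogens) {
    keep <- element != "H"
    at <- at[keep, , drop = FALSE]
    element <- element[keep]
  }
  is_lig <- if (by == "resid") at$resid == ligand_selector
            else at$chain == ligand_selector
  is_lig[is.na(is_lig)] <- FALSE
  if (!any(is_lig))
    stop("ligand selector '", ligand_selector, "' matches no atoms in ",
         path)
  chain <- ifelse(is.na(at$chain), "_", at$chain)
  spheres <- data.frame(
    serial = at$eleno, atom_name = trimws(at$elety), element = element,
    x = at$x, y = at$y, z = at$z,
    vdw_radius = .vdw_radius(element),
    owner = ifelse(is_lig, "LIGAND", "RECEPTOR"),
    chain = chain, resid = at$resid, resno = at$resno,
    residue_key = paste(chain, at$resid, at$resno, sep = ":"),
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(spheres[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  list(receptor = spheres[spheres$owner == "RECEPTOR", , drop = FALSE],
       ligand = spheres[spheres$owner == "LIGAND", , drop = FALSE])
}

#' Default heme subsite scheme
#'
#' Maps PDB v3 heme (`HEM`) atom names to four subsite labels used as
#' aggregation units: `HFN` the central iron and pyrrole nitrogens, `HCC`
#' the sp2 porphyrin-ring carbons (ring, methine bridges and ring
#' substituent carbons), `HCR` the propionate-branch sp3 carbons that carry
#' the carboxylic groups, `HCO` the carboxylate oxygens at the branch
#' ends.
#'
#' @return data.frame `(resid, atom_name, subsite)`.
#' @export
heme_subsite_scheme <- function() {
  hfn <- c("FE", "NA", "NB", "NC", "ND")
  hcc <- c(paste0("CH", c("A", "B", "C", "D")),
           paste0("C", rep(1:4, times = 4),
                  rep(c("A", "B", "C", "D"), each = 4)),
           paste0("CM", c("A", "B", "C", "D")),
           "CAB", "CBB", "CAC", "CBC")
  hcr <- c("CAA", "CBA", "CGA", "CAD", "CBD", "CGD")
  hco <- c("O1A", "O2A", "O1D", "O2D")
  data.frame(
    resid = "HEM",
    atom_name = c(hfn, hcc, hcr, hco),
    subsite = c(rep("HFN", length(hfn)), rep("HCC", length(hcc)),
                rep("HCR", length(hcr)), rep("HCO", length(hco))),
    stringsAsFactors = FALSE)
}

#' Read or write a subsite scheme as delimited text
#' @param path file with header `resid,atom_name,subsite`.
#' @return data.frame scheme.
#' @export
read_subsite_scheme <- function(path) {
  sch <- utils::read.table(path, sep = ",", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("resid", "atom_name", "subsite") %in% names(sch)))
  sch
}

#' @rdname read_subsite_scheme
#' @param scheme data.frame scheme to write.
#' @export
write_subsite_scheme <- function(scheme, path) {
  utils::write.table(scheme, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Relabel prosthetic-group atoms with subsite labels
#'
#' Atoms of residues covered by the scheme get their `residue_key`
#' replaced by the scheme's subsite label, so that downstream aggregation
#' treats each subsite as its own "residue". All other atoms are
#' unchanged. Every atom name of a targeted residue must be covered.
#'
#' @param receptor receptor atom data.frame from [load_complex()]. Needs
#'   an `atom_name` column or the bio3d `elety` naming carried in
#'   `element`; when absent, pass `atom_names` explicitly.
#' @param scheme data.frame `(resid, atom_name, subsite)`, default
#'   [heme_subsite_scheme()].
#' @param atom_names optional character vector of PDB atom names aligned
#'   with `receptor` rows (needed when the receptor table lacks an
#'   `atom_name` column).
#' @return the receptor data.frame with updated `residue_key`.
#' @export
assign_subsites <- function(receptor, scheme = heme_subsite_scheme(),
                            atom_names = NULL) {
  if (is.null(atom_names)) {
    if (!"atom_name" %in% names(receptor))
      stop("receptor table lacks atom_name; pass atom_names")
    atom_names <- receptor$atom_name
  }
  stopifnot(length(atom_names) == nrow(receptor))
  targeted <- receptor$resid %in% unique(scheme$resid)
  if (!any(targeted)) return(receptor)
  key <- paste(receptor$resid[targeted], toupper(atom_names[targeted]))
  skey <- paste(scheme$resid, toupper(scheme$atom_name))
  hit <- match(key, skey)
  if (anyNA(hit))
    stop("atom name(s) of subdivided residue missing from scheme: ",
         paste(unique(atom_names[targeted][is.na(hit)]), collapse = ", "))
  receptor$residue_key[targeted] <- scheme$subsite[hit]
  receptor
}

# deterministic spherical Fibonacci lattice on the unit sphere
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 1L
  z <- 1 - (2 * k + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Probe-excluded pairwise contact areas
#'
#' For every ligand atom i the sphere of radius `r_i + probe_radius` is
#' sampled with a deterministic spherical Fibonacci lattice of `n_points`
#' points. A sample point lying inside the probe-expanded sphere of one or
#' more receptor atoms is assigned to the receptor atom burying it most
#' deeply (largest penetration depth; ties to the lowest serial), and
#' contributes `4 * pi * R_i^2 / n_points` to that pair's area. Pairs whose
#' expanded spheres do not intersect have exactly zero area at any
#' `n_points`: a water probe can be interposed between the two atoms.
#'
#' @param ligand,receptor atom data.frames (columns `serial, x, y, z,
#'   vdw_radius`), e.g. from [load_complex()].
#' @param probe_radius solvent probe radius in Angstrom, default 1.4
#'   (water).
#' @param n_points lattice points per ligand atom, default 960; >= 100.
#' @return a `contact_map`: data.frame `(ligand_serial, receptor_serial,
#'   area)` (Angstrom^2) containing only pairs with positive area, with the
#'   ligand atom table attached as attribute `ligand` and a receptor
#'   fingerprint as attribute `receptor_id`.
#' @export
contact_areas <- function(ligand, receptor, probe_radius = 1.4,
                          n_points = 960) {
  stopifnot(is.data.frame(ligand), is.data.frame(receptor),
            probe_radius >= 0, n_points >= 100)
  res <- list()
  if (nrow(receptor) > 0L && nrow(ligand) > 0L) {
    rxyz <- as.matrix(receptor[, c("x", "y", "z")])
    rr <- receptor$vdw_radius + probe_radius
    lattice <- fibonacci_sphere(n_points)
    for (i in seq_len(nrow(ligand))) {
      ci <- as.numeric(ligand[i, c("x", "y", "z")])
      Ri <- ligand$vdw_radius[i] + probe_radius
      d0 <- sqrt(colSums((t(rxyz) - ci)^2))
      if (any(d0 < 1e-9))
        stop("ligand atom ", ligand$serial[i],
             " coincides with a receptor atom center")
      near <- which(d0 < Ri + rr)  # only these spheres can bury points
      if (!length(near)) next
      pts <- lattice * Ri
      pts <- sweep(pts, 2, ci, `+`)
      # depth[p, j] = R_j - |p - c_j|, positive means buried
      depth <- matrix(0, n_points, length(near))
      for (jj in seq_along(near)) {
        j <- near[jj]
        depth[, jj] <- rr[j] -
          sqrt((pts[, 1] - rxyz[j, 1])^2 + (pts[, 2] - rxyz[j, 2])^2 +
               (pts[, 3] - rxyz[j, 3])^2)
      }
      buried <- depth > 0
      any_buried <- which(rowSums(buried) > 0L)
      if (!length(any_buried)) next
      # deepest burial wins; ties go to the lowest receptor serial
      ord <- order(receptor$serial[near])
      assigned <- vapply(any_buried, function(p) {
        dp <- depth[p, ord]
        near[ord[which.max(dp)]]
      }, 0L)
      counts <- table(assigned)
      area_per_point <- 4 * pi * Ri^2 / n_points
      res[[length(res) + 1L]] <- data.frame(
        ligand_serial = ligand$serial[i],
        receptor_serial = receptor$serial[as.integer(names(counts))],
        area = as.numeric(counts) * area_per_point)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(ligand_serial = integer(), receptor_serial = integer(),
               area = numeric())
  rownames(out) <- NULL
  structure(out, class = c("contact_map", "data.frame"),
            ligand = ligand, receptor_id = .receptor_fingerprint(receptor),
            probe_radius = probe_radius, n_points = n_points)
}

.receptor_fingerprint <- function(receptor) {
  paste(nrow(receptor),
        sum(receptor$serial),
        format(sum(as.matrix(receptor[, c("x", "y", "z")])^2),
               digits = 12))
}

#' Aggregate per-pose contact maps into a residue/subsite profile
#'
#' Pools contact maps computed for several poses (and several ligands)
#' against one receptor. For each residue key (or subsite label) the
#' per-pose contact area is the sum of all its atom-pair areas in that
#' pose; the profile records the mean of this per-pose area over all
#' poses, the contact frequency (fraction of poses touching the residue at
#' all), and the positions of the ligand atoms that contributed (the dot
#' cloud).
#'
#' @param maps list of `contact_map` objects from [contact_areas()], all
#'   against the same receptor.
#' @param receptor the receptor atom data.frame the maps were computed
#'   against (after any [assign_subsites()] relabelling).
#' @return a `contact_profile`: list with `residues` (data.frame
#'   residue_key, mean_area, frequency, n_poses), `cloud` (data.frame
#'   residue_key, x, y, z of contributing ligand atoms) and `rec_atoms`
#'   (coordinates of receptor atoms seen in any contact, for map export).
#' @export
aggregate_contacts <- function(maps, receptor) {
  stopifnot(is.list(maps), length(maps) > 0L,
            all(vapply(maps, inherits, TRUE, "contact_map")))
  fp <- .receptor_fingerprint(receptor)
  same <- vapply(maps, function(m)
    identical(attr(m, "receptor_id"), fp), TRUE)
  if (!all(same))
    stop("contact map(s) ", paste(which(!same), collapse = ", "),
         " were computed against a different receptor")
  keys <- sort(unique(receptor$residue_key))
  n_poses <- length(maps)
  per_pose <- matrix(0, length(keys), n_poses,
                     dimnames = list(keys, NULL))
  cloud <- list()
  rec_hit <- logical(nrow(receptor))
  for (p in seq_len(n_poses)) {
    m <- maps[[p]]
    if (nrow(m) == 0L) next
    ridx <- match(m$receptor_serial, receptor$serial)
    if (anyNA(ridx)) stop("receptor serial mismatch in map ", p)
    rec_hit[unique(ridx)] <- TRUE
    rk <- receptor$residue_key[ridx]
    sums <- tapply(m$area, rk, sum)
    per_pose[names(sums), p] <- as.numeric(sums)
    lig <- attr(m, "ligand")
    lidx <- match(unique(m$ligand_serial), lig$serial)
    contrib_keys <- split(rk, m$ligand_serial)
    for (ls in names(contrib_keys)) {
      li <- match(as.numeric(ls), lig$serial)
      for (k in unique(contrib_keys[[ls]]))
        cloud[[length(cloud) + 1L]] <- data.frame(
          residue_key = k, x = lig$x[li], y = lig$y[li], z = lig$z[li],
          pose = p, stringsAsFactors = FALSE)
    }
  }
  touched <- rowSums(per_pose) > 0
  residues <- data.frame(
    residue_key = keys[touched],
    mean_area = rowMeans(per_pose)[touched],
    frequency = rowMeans(per_pose > 0)[touched],
    n_poses = n_poses,
    stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  cloud <- if (length(cloud)) do.call(rbind, cloud) else
    data.frame(residue_key = character(), x = numeric(), y = numeric(),
               z = numeric(), pose = integer())
  structure(list(residues = residues, cloud = cloud,
                 rec_atoms = receptor[rec_hit, , drop = FALSE]),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("Contact profile over", x$residues$n_poses[1], "pose(s):",
      nrow(x$residues), "residue/subsite keys in contact\n")
  print(utils::head(x$residues[order(-x$residues$mean_area), ], 10))
  invisible(x)
}

#' Export a contact profile as a plot-ready table
#'
#' Recentres everything at the geometric centre of the receptor atoms
#' involved in contacts, then emits one row per residue/subsite with its
#' (recentred) geometric centre, mean contact area (drives label font
#' size) and contact frequency, plus the recentred ligand-atom dot cloud.
#' Grid metadata of 5 Angstrom is attached for plotting.
#'
#' @param profile a `contact_profile`.
#' @return list with `table` (residue_key, cx, cy, cz, mean_area,
#'   frequency), `cloud` (recentred dot cloud), `center` (the subtracted
#'   centroid) and `grid_spacing` (5).
#' @export
export_contact_map <- function(profile) {
  stopifnot(inherits(profile, "contact_profile"))
  if (nrow(profile$residues) == 0L) stop("empty contact profile")
  ra <- profile$rec_atoms
  center <- colMeans(ra[, c("x", "y", "z")])
  centers <- do.call(rbind, lapply(profile$residues$residue_key,
    function(k) {
      sub <- ra[ra$residue_key == k, , drop = FALSE]
      colMeans(sub[, c("x", "y", "z")]) - center
    }))
  tab <- data.frame(residue_key = profile$residues$residue_key,
                    cx = centers[, 1], cy = centers[, 2],
                    cz = centers[, 3],
                    mean_area = profile$residues$mean_area,
                    frequency = profile$residues$frequency,
                    stringsAsFactors = FALSE)
  cloud <- profile$cloud
  if (nrow(cloud)) {
    cloud$x <- cloud$x - center[1]
    cloud$y <- cloud$y - center[2]
    cloud$z <- cloud$z - center[3]
  }
  list(table = tab, cloud = cloud, center = center, grid_spacing = 5)
}

#' Closed-form contact area for an isolated atom pair
#'
#' Analytic reference for [contact_areas()] on a single, isolated pair of
#' spheres: the spherical-cap area `2 * pi * R_i * h` cut out of the
#' probe-expanded ligand sphere (radius `R_i = r_i + probe`) by the
#' probe-expanded receptor sphere, with
#' `h = R_i - (d^2 + R_i^2 - R_j^2) / (2 d)`. Returns 0 when the expanded
#' spheres are disjoint.
#'
#' @param r_i,r_j van der Waals radii (Angstrom).
#' @param d center distance (Angstrom).
#' @param probe_radius probe radius, default 1.4.
#' @return area in Angstrom^2.
#' @export
cap_contact_area <- function(r_i, r_j, d, probe_radius = 1.4) {
  Ri <- r_i + probe_radius
  Rj <- r_j + probe_radius
  if (d >= Ri + Rj) return(0)
  if (d <= abs(Ri - Rj))
    return(if (Ri <= Rj) 4 * pi * Ri^2 else 0)
  h <- Ri - (d^2 + Ri^2 - Rj^2) / (2 * d)
  2 * pi * Ri * h
}
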