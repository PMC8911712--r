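#' @title Molecular descriptors and descriptor-affinity correlograms
#' @description Ingestion of externally computed molecular descriptor
#'   tables, best-effort computation of a few geometry/composition
#'   descriptors from 3D structures, and Pearson correlograms between
#'   descriptors and per-site mean docking scores.
#' @name descriptors
NULL

KNOWN_DESCRIPTORS <- c(
  "molar_volume", "polarizability", "molar_refractivity", "logP",
  "parachor", "tpsa", "hba", "hbd", "max_length", "rotatable_bonds",
  "molecular_weight"
)

#' Load a molecular descriptor table
#'
#' Delimited text, one ligand per row, first column `ligand_id`, remaining
#' columns numeric descriptors. Recognized descriptor names:
#' `molar_volume`, `polarizability`, `molar_refractivity`, `logP`,
#' `parachor`, `tpsa`, `hba`, `hbd`, `max_length`, `rotatable_bonds`,
#' `molecular_weight`. Unknown columns are kept but flagged with a
#' warning. Missing cells stay `NA` and are excluded pairwise downstream.
#'
#' @param path file path (comma or tab separated, auto-detected).
#' @return a `descriptor_table` (data.frame).
#' @export
load_descriptors <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (names(raw)[1] != "ligand_id")
    stop("first column must be ligand_id")
  out <- data.frame(ligand_id = raw$ligand_id, stringsAsFactors = FALSE)
  for (col in names(raw)[-1]) {
    v <- trimws(raw[[col]])
    v[v %in% c("", "NA", "ND")] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("non-numeric cell in column '", col, "', row ", bad[1],
           " (ligand ", raw$ligand_id[bad[1]], ")")
    out[[col]] <- num
  }
  unknown <- setdiff(names(out)[-1], KNOWN_DESCRIPTORS)
  if (length(unknown))
    warning("unrecognized descriptor column(s) kept as-is: ",
            paste(unknown, collapse = ", "))
  counts <- intersect(c("hba", "hbd", "rotatable_bonds"), names(out))
  for (col in counts) {
    v <- out[[col]]
    if (any(!is.na(v) & (v < 0 | v != round(v))))
      stop("descriptor '", col, "' must be a non-negative integer count")
  }
  for (col in intersect(c("tpsa", "max_length"), names(out))) {
    if (any(!is.na(out[[col]]) & out[[col]] < 0))
      stop("descriptor '", col, "' must be non-negative")
  }
  class(out) <- c("descriptor_table", "data.frame")
  out
}

#' Write a descriptor table
#' @param descriptors a `descriptor_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  utils::write.table(as.data.frame(descriptors), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# covalent radii (Angstrom) for the distance-based bond heuristic
.COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39)

.ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, Cl = 35.45,
                    Br = 79.904, I = 126.904)

#' Compute basic descriptors from ligand 3D structures
#'
#' Best-effort, deterministic descriptors from a single supplied conformer
#' per ligand: molecular weight, hydrogen-bond acceptor count (N + O
#' atoms), hydrogen-bond donor count (N/O atoms with at least one bonded
#' hydrogen; `NA` with a warning when the structure carries no hydrogens),
#' rotatable-bond count (acyclic single bonds between non-terminal heavy
#' atoms, bonds perceived from covalent radii, ring membership from graph
#' bridges), and `max_length`, the maximum pairwise interatomic distance of
#' the conformer as given. Authoritative descriptor values from dedicated
#' calculators should be preferred where available; these complement an
#' ingested table, they do not replace it.
#'
#' @param structures named list; each element a data.frame with columns
#'   `element`, `x`, `y`, `z` (Angstrom). A data.frame with a `ligand_id`
#'   column is also accepted and split.
#' @return a `descriptor_table` with columns `ligand_id`,
#'   `molecular_weight`, `hba`, `hbd`, `rotatable_bonds`, `max_length`.
#' @export
compute_basic_descriptors <- function(structures) {
  if (is.data.frame(structures)) {
    stopifnot("ligand_id" %in% names(structures))
    structures <- split(structures, structures$ligand_id)
  }
  stopifnot(is.list(structures), length(structures) > 0L,
            !is.null(names(structures)))
  rows <- lapply(names(structures), function(id) {
    st <- structures[[id]]
    stopifnot(all(c("element", "x", "y", "z") %in% names(st)))
    el <- toupper(substr(trimws(st$element), 1, 2))
    el <- ifelse(el %in% names(.ATOMIC_MASSES), el, substr(el, 1, 1))
    mw <- sum(.ATOMIC_MASSES[el], na.rm = TRUE)
    hba <- sum(el %in% c("N", "O"))
    xyz <- as.matrix(st[, c("x", "y", "z")])
    if (anyNA(xyz)) {
      warning("missing coordinates for ", id, "; max_length omitted")
      max_len <- NA_real_
      hbd <- NA_integer_
      rot <- NA_integer_
    } else {
      max_len <- if (nrow(xyz) < 2L) 0 else max(stats::dist(xyz))
      bonds <- .perceive_bonds(el, xyz)
      hbd <- if (!any(el == "H")) {
        warning("no hydrogens in structure for ", id, "; hbd is NA")
        NA_integer_
      } else {
        sum(vapply(which(el %in% c("N", "O")), function(i) {
          nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
          any(el[nb] == "H")
        }, TRUE))
      }
      rot <- .count_rotatable(el, bonds)
    }
    data.frame(ligand_id = id, molecular_weight = mw, hba = hba,
               hbd = hbd, rotatable_bonds = rot, max_length = max_len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("descriptor_table", "data.frame")
  out
}

# bond = pair with distance < 1.25 * (r_cov_i + r_cov_j)
.perceive_bonds <- function(el, xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(), 0, 2))
  rc <- .COVALENT_RADII[el]
  rc[is.na(rc)] <- 0.76
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(rc, rc, `+`) * 1.25
  idx <- which(upper.tri(d) & d < cut & d > 0.4, arr.ind = TRUE)
  idx
}

.count_rotatable <- function(el, bonds) {
  heavy <- el != "H"
  hb <- bonds[heavy[bonds[, 1]] & heavy[bonds[, 2]], , drop = FALSE]
  if (nrow(hb) == 0L) return(0L)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(hb), ncol = 2), directed = FALSE)
  br <- igraph::bridges(g)
  deg <- table(c(hb[, 1], hb[, 2]))
  n_rot <- 0L
  for (e in br) {
    ends <- igraph::ends(g, e)
    a <- as.integer(ends[1]); b <- as.integer(ends[2])
    if (deg[as.character(a)] >= 2 && deg[as.character(b)] >= 2)
      n_rot <- n_rot + 1L
  }
  n_rot
}

#' Pearson correlogram between descriptors and docking scores
#'
#' For each (descriptor, target site) cell, the Pearson correlation between
#' the descriptor values and the per-ligand mean docking scores at that
#' site, over pairwise-complete ligands. Negative r means the attribute
#' improves (makes more negative) the predicted affinity.
#'
#' @param descriptors a `descriptor_table`.
#' @param mean_scores data.frame `(ligand_id, site_id, role, mean_score)`
#'   as returned by [average_pose_scores()] (the `role` column may be
#'   absent when `variant = "WITH_CONTROLS"` is used with candidate-only
#'   data already).
#' @param variant `"WITH_CONTROLS"` (all ligands) or `"CANDIDATES_ONLY"`
#'   (rows with role `CANDIDATE`).
#' @param p_adjust `"none"` (default; the raw correlogram) or any method of
#'   [stats::p.adjust()], e.g. `"BH"`.
#' @return a `correlogram`: list with matrices `r`, `p`, `n` (descriptor x
#'   site), `variant`, and `long` (data.frame descriptor, site, r, p, n).
#'   Cells with fewer than 3 complete pairs or zero variance are `NA`.
#' @export
correlogram <- function(descriptors, mean_scores,
                        variant = c("WITH_CONTROLS", "CANDIDATES_ONLY"),
                        p_adjust = "none") {
  variant <- match.arg(variant)
  stopifnot(all(c("ligand_id", "site_id", "mean_score") %in%
                  names(mean_scores)))
  if (variant == "CANDIDATES_ONLY") {
    if (!"role" %in% names(mean_scores))
      stop("CANDIDATES_ONLY needs a role column in mean_scores")
    mean_scores <- mean_scores[mean_scores$role == "CANDIDATE", ,
                               drop = FALSE]
  }
  sites <- sort(unique(mean_scores$site_id))
  desc_cols <- setdiff(names(descriptors), "ligand_id")
  desc_cols <- desc_cols[vapply(descriptors[desc_cols], is.numeric, TRUE)]
  r <- p <- n <- matrix(NA_real_, length(desc_cols), length(sites),
                        dimnames = list(desc_cols, sites))
  for (s in sites) {
    sc <- mean_scores[mean_scores$site_id == s, ]
    idx <- match(sc$ligand_id, descriptors$ligand_id)
    for (dcol in desc_cols) {
      x <- descriptors[[dcol]][idx]
      y <- sc$mean_score
      ok <- stats::complete.cases(x, y)
      n[dcol, s] <- sum(ok)
      if (sum(ok) < 3L) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[dcol, s] <- unname(ct$estimate)
      p[dcol, s] <- ct$p.value
    }
  }
  if (p_adjust != "none")
    p[] <- stats::p.adjust(p, method = p_adjust)
  long <- data.frame(
    descriptor = rep(desc_cols, times = length(sites)),
    site = rep(sites, each = length(desc_cols)),
    r = as.vector(r), p = as.vector(p), n = as.vector(n),
    stringsAsFactors = FALSE)
  structure(list(r = r, p = p, n = n, variant = variant, long = long),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, digits = 2, ...) {
  cat("Descriptor-affinity correlogram (", x$variant, ")\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}
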