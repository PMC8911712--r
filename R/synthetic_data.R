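#' @title Synthetic inputs with planted truth
#' @description Deterministic generators for every input the pipeline
#'   consumes: docking-score panels with planted TOP/MIDDLE/WORST structure
#'   anchored on control means, toy ligand-receptor complexes whose
#'   pairwise contact areas have closed forms, and chromatographic peak
#'   tables straddling the identification/detection thresholds. All
#'   generators are pure functions of their arguments (same spec and seed,
#'   byte-identical output).
#' @name synthetic_data
NULL

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a planted docking-score panel
#'
#' Emulates the control-anchored structure of a virtual-screening score
#' table: two positive controls (the better one at `control_means["positive"]`),
#' two negative controls (the worse one at `control_means["negative"]`),
#' and candidates planted at the best positive mean (TOP-like), the worst
#' negative mean (WORST-like) or midway (MIDDLE-like), each with
#' `poses_per_ligand` poses perturbed by Gaussian noise of sd `pose_sd`.
#'
#' @param n_top,n_middle,n_worst planted candidate counts (default 5, 10,
#'   5).
#' @param control_means named numeric, `positive` and `negative` mean
#'   scores in kcal/mol; positive must be more negative. Default -9, -4.
#' @param pose_sd pose noise sd in kcal/mol, default 0.25 (a tenth of the
#'   default anchor-to-midpoint separation).
#' @param poses_per_ligand default 3, the number of top poses scored.
#' @param site site id, default `"SITE1"`.
#' @param seed RNG seed, default 1.
#' @return list with `scores` (data.frame ligand_id, site_id, role,
#'   pose_rank, score) and `truth` (data.frame ligand_id, truth label for
#'   candidates).
#' @export
gen_scores <- function(n_top = 5, n_middle = 10, n_worst = 5,
                       control_means = c(positive = -9, negative = -4),
                       pose_sd = 0.25, poses_per_ligand = 3,
                       site = "SITE1", seed = 1) {
  stopifnot(n_top >= 0, n_middle >= 0, n_worst >= 0, pose_sd > 0,
            poses_per_ligand >= 2,
            all(c("positive", "negative") %in% names(control_means)))
  if (control_means[["positive"]] >= control_means[["negative"]])
    stop("positive control mean must be below (more negative than) ",
         "the negative control mean")
  best_pos <- control_means[["positive"]]
  worst_neg <- control_means[["negative"]]
  mid <- (best_pos + worst_neg) / 2

  lig <- data.frame(
    ligand_id = c("POS1", "POS2", "NEG1", "NEG2",
                  sprintf("CAND%02d", seq_len(n_top + n_middle + n_worst))),
    role = c("POSITIVE_CONTROL", "POSITIVE_CONTROL",
             "NEGATIVE_CONTROL", "NEGATIVE_CONTROL",
             rep("CANDIDATE", n_top + n_middle + n_worst)),
    planted = c(best_pos, best_pos + 0.4 * (worst_neg - best_pos) / 5,
                worst_neg, worst_neg - 0.4,
                rep(c(best_pos, mid, worst_neg),
                    times = c(n_top, n_middle, n_worst))),
    truth = c(NA, NA, NA, NA,
              rep(c("TOP", "MIDDLE", "WORST"),
                  times = c(n_top, n_middle, n_worst))),
    stringsAsFactors = FALSE)

  scores <- .with_seed(seed, {
    noise <- stats::rnorm(nrow(lig) * poses_per_ligand, 0, pose_sd)
    data.frame(
      ligand_id = rep(lig$ligand_id, each = poses_per_ligand),
      site_id = site,
      role = rep(lig$role, each = poses_per_ligand),
      pose_rank = rep(seq_len(poses_per_ligand), times = nrow(lig)),
      score = rep(lig$planted, each = poses_per_ligand) + noise,
      stringsAsFactors = FALSE)
  })
  truth <- lig[lig$role == "CANDIDATE", c("ligand_id", "truth")]
  rownames(truth) <- NULL
  list(scores = scores, truth = truth)
}

#' Generate a toy complex with closed-form contact areas
#'
#' Writes a PDB file containing isolated ligand-receptor atom pairs placed
#' far enough apart that no cross-pair contact is possible, together with
#' the analytic contact area expected for each pair (the spherical-cap
#' formula of [cap_contact_area()]; zero when the pair distance admits an
#' interposed water probe). Radii are realized by choosing elements whose
#' tabulated van der Waals radii match.
#'
#' @param pairs data.frame with columns `r_lig`, `r_rec` (vdW radii,
#'   Angstrom; must exist in the package's element table) and `d` (center
#'   distance, > 0).
#' @param path output PDB path.
#' @param probe_radius probe used for the expected areas, default 1.4.
#' @param spacing distance between consecutive pair origins along x,
#'   default 40 (keeps every cross-pair separation above 20 Angstrom).
#' @return list with `path` and `expected` (data.frame pair, r_lig, r_rec,
#'   d, area).
#' @export
gen_toy_complex <- function(pairs, path, probe_radius = 1.4,
                            spacing = 40) {
  stopifnot(is.data.frame(pairs),
            all(c("r_lig", "r_rec", "d") %in% names(pairs)),
            all(pairs$d > 0))
  radius_to_element <- function(r) {
    hit <- which(abs(.VDW_RADII - r) < 1e-6)
    if (!length(hit))
      stop("no element with vdW radius ", r, "; available: ",
           paste(names(.VDW_RADII), .VDW_RADII, sep = "=",
                 collapse = ", "))
    names(.VDW_RADII)[hit[1]]
  }
  n <- nrow(pairs)
  gap <- spacing - max(pairs$d)
  if (n > 1L && gap < 20)
    stop("pair spacing leaves cross-pair gaps under 20 Angstrom; ",
         "increase `spacing`")
  lig_el <- vapply(pairs$r_lig, radius_to_element, "")
  rec_el <- vapply(pairs$r_rec, radius_to_element, "")
  x0 <- (seq_len(n) - 1L) * spacing
  xyz <- rbind(cbind(x0, 0, 0),                  # ligand atoms
               cbind(x0 + pairs$d, 0, 0))        # receptor atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("HETATM", 2L * n),
    resno = c(seq_len(n), seq_len(n)),
    resid = rep(c("LIG", "REC"), each = n),
    chain = rep(c("L", "R"), each = n),
    eleno = seq_len(2L * n),
    elety = c(lig_el, rec_el),
    elesy = c(lig_el, rec_el))
  expected <- data.frame(
    pair = seq_len(n), r_lig = pairs$r_lig, r_rec = pairs$r_rec,
    d = pairs$d,
    area = vapply(seq_len(n), function(i)
      cap_contact_area(pairs$r_lig[i], pairs$r_rec[i], pairs$d[i],
                       probe_radius), 0))
  list(path = path, expected = expected)
}

#' Generate a peak table straddling the identification thresholds
#'
#' `n` random rows with RSI uniform on (0, 1200) and S/N uniform on
#' (0, 100), plus four fixed boundary rows (exactly at RSI 600 and/or S/N
#' 50, which must fail the strict filter, and one row just past both
#' thresholds). A `truth` column records whether each row passes
#' `rsi > 600 & snr > 50`.
#'
#' @param n number of random rows, >= 0.
#' @param seed RNG seed.
#' @return data.frame `(rt, rsi, snr, truth)`.
#' @export
gen_peak_table <- function(n, seed = 1) {
  stopifnot(n >= 0)
  boundary <- data.frame(
    rsi = c(600, 900, 601, 599.5),
    snr = c(90, 50, 51, 49.5))
  rand <- .with_seed(seed, data.frame(
    rsi = stats::runif(n, 0, 1200),
    snr = stats::runif(n, 0, 100)))
  out <- rbind(boundary, rand)
  out <- data.frame(rt = seq_len(nrow(out)) * 0.25, out)
  out$truth <- out$rsi > 600 & out$snr > 50
  rownames(out) <- NULL
  out
}
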