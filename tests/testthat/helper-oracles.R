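# Independent oracles used across the suite. These recompute expected
# values through routes separate from the package implementation.

# All-pairs Tukey HSD p-values computed by hand from group means and the
# pooled error mean square (studentized-range distribution), independent
# of stats::aov / stats::TukeyHSD.
oracle_tukey_p <- function(values, groups) {
  groups <- as.character(groups)
  g <- split(values, groups)
  k <- length(g)
  n <- vapply(g, length, 0L)
  m <- vapply(g, mean, 0)
  df <- sum(n) - k
  mse <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0)) / df
  ids <- names(g)
  p <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
    se <- sqrt(mse / 2 * (1 / n[a] + 1 / n[b]))
    q <- abs(m[a] - m[b]) / se
    p[a, b] <- p[b, a] <- stats::ptukey(q, k, df, lower.tail = FALSE)
  }
  p
}

# Closed-form spherical-cap contact area for an isolated pair of
# probe-expanded spheres (lens geometry, written out directly).
oracle_cap_area <- function(r_i, r_j, d, probe = 1.4) {
  Ri <- r_i + probe
  Rj <- r_j + probe
  if (d >= Ri + Rj) return(0)
  if (d <= abs(Ri - Rj)) return(if (Ri <= Rj) 4 * pi * Ri^2 else 0)
  cos_theta <- (d^2 + Ri^2 - Rj^2) / (2 * d * Ri)
  2 * pi * Ri^2 * (1 - cos_theta)
}

# An isolated two-sphere system as ligand/receptor atom tables.
sphere_pair <- function(r_i, r_j, d) {
  list(ligand = data.frame(serial = 1L, x = 0, y = 0, z = 0,
                           vdw_radius = r_i),
       receptor = data.frame(serial = 2L, x = d, y = 0, z = 0,
                             vdw_radius = r_j))
}

# Random well-separated score panel for CLD property tests: k ligands
# with means spread over a range, 3 poses each.
random_panel <- function(k, seed, spread = 5, sd = 0.3) {
  set.seed(seed)
  means <- sort(runif(k, -10, -10 + spread))
  ids <- sprintf("L%02d", seq_len(k))
  data.frame(
    ligand_id = rep(ids, each = 3),
    site_id = "S",
    role = "CANDIDATE",
    pose_rank = rep(1:3, k),
    score = rep(means, each = 3) + rnorm(3 * k, 0, sd),
    stringsAsFactors = FALSE)
}

letters_separate <- function(grouping, a, b) {
  tab <- grouping$table
  la <- strsplit(tab$letters[tab$ligand_id == a], "")[[1]]
  lb <- strsplit(tab$letters[tab$ligand_id == b], "")[[1]]
  length(intersect(la, lb)) == 0L
}
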