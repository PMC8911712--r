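#' @title Control-anchored docking-score triage
#' @description Candidate ligands are docked alongside known binders
#'   (positive controls) and known non-binders (negative controls); the top
#'   few poses of every ligand enter a one-way ANOVA per target site, all
#'   pairwise mean differences are tested with Tukey's HSD, and a compact
#'   letter display (CLD) summarizes which ligands are statistically
#'   indistinguishable. Candidates are then labelled TOP, MIDDLE or WORST
#'   according to whether they share a letter with the best positive
#'   control, the worst negative control, or neither.
#' @name triage
NULL

SCORE_ROLES <- c("CANDIDATE", "POSITIVE_CONTROL", "NEGATIVE_CONTROL")
TRIAGE_GROUPS <- c("TOP", "MIDDLE", "WORST")

.validate_scores <- function(scores) {
  need <- c("ligand_id", "site_id", "role", "pose_rank", "score")
  if (!is.data.frame(scores) || !all(need %in% names(scores)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  if (nrow(scores) == 0L) stop("empty score table")
  if (!all(scores$role %in% SCORE_ROLES))
    stop("role must be one of: ", paste(SCORE_ROLES, collapse = ", "))
  if (!is.numeric(scores$score) || any(!is.finite(scores$score)))
    stop("scores must be finite numbers (kcal/mol)")
  invisible(scores)
}

#' Read a docking score table
#'
#' Two dialects are accepted. The native one is delimited text (comma or
#' tab) with header `ligand_id,site_id,role,pose_rank,score`. As a
#' convenience, concatenated AutoDock-Vina-style log blocks are also
#' understood: each block starts with a line
#' `Ligand: <id> Site: <id> Role: <role>` followed by the usual
#' `mode | affinity ...` table whose rows begin with the pose number and
#' affinity in kcal/mol.
#'
#' @param path file path.
#' @return data.frame with the five native columns.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("ligand_id", first, fixed = TRUE)) {
    sep <- if (grepl("\t", first)) "\t" else ","
    out <- utils::read.table(path, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE)
    out$score <- as.numeric(out$score)
    out$pose_rank <- as.integer(out$pose_rank)
    return(.validate_scores(out))
  }
  # Vina-log dialect
  lines <- readLines(path)
  heads <- grep("^\\s*Ligand:", lines)
  if (!length(heads)) stop("unrecognized score file dialect: ", path)
  blocks <- Map(function(a, b) lines[a:b], heads,
                c(heads[-1] - 1L, length(lines)))
  rows <- lapply(blocks, function(bl) {
    m <- regmatches(bl[1], regexec(
      "Ligand:\\s*(\\S+)\\s+Site:\\s*(\\S+)\\s+Role:\\s*(\\S+)", bl[1]))[[1]]
    if (length(m) != 4L) stop("malformed block header: ", bl[1])
    pose_lines <- grep("^\\s*\\d+\\s+-?\\d", bl, value = TRUE)
    if (!length(pose_lines)) stop("no pose rows under header: ", bl[1])
    fields <- lapply(strsplit(trimws(pose_lines), "\\s+"), as.numeric)
    data.frame(ligand_id = m[2], site_id = m[3], role = toupper(m[4]),
               pose_rank = vapply(fields, `[`, 0, 1L),
               score = vapply(fields, `[`, 0, 2L),
               stringsAsFactors = FALSE)
  })
  .validate_scores(do.call(rbind, rows))
}

#' Write a score table in the native delimited dialect
#' @param scores score data.frame (see [read_scores()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  .validate_scores(scores)
  utils::write.table(scores, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Mean docking score per ligand and site
#'
#' Arithmetic mean of the pose affinities of each (ligand, site), the
#' quantity the triage and correlogram stages work with.
#'
#' @param scores score data.frame (see [read_scores()]).
#' @return data.frame `(ligand_id, site_id, role, mean_score, n_poses)`.
#' @export
average_pose_scores <- function(scores) {
  .validate_scores(scores)
  key <- interaction(scores$ligand_id, scores$site_id, drop = TRUE)
  agg <- lapply(split(scores, key), function(d) {
    data.frame(ligand_id = d$ligand_id[1], site_id = d$site_id[1],
               role = d$role[1], mean_score = mean(d$score),
               n_poses = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$site_id, out$ligand_id), ]
  rownames(out) <- NULL
  out
}

# Piepho-style insert-and-absorb compact letter display.
# `signif_mat`: logical symmetric matrix, TRUE where the pair differs
# significantly. Treatment order of the matrix defines letter order
# (callers pass treatments sorted by ascending mean).
cld_insert_absorb <- function(signif_mat) {
  k <- nrow(signif_mat)
  trt <- rownames(signif_mat)
  cols <- list(rep(TRUE, k))
  pairs <- which(upper.tri(signif_mat) & signif_mat, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    hit <- vapply(cols, function(cl) cl[i] && cl[j], TRUE)
    if (!any(hit)) next
    newcols <- list()
    for (ci in seq_along(cols)) {
      cl <- cols[[ci]]
      if (cl[i] && cl[j]) {
        a <- cl; a[i] <- FALSE
        b <- cl; b[j] <- FALSE
        newcols <- c(newcols, list(a, b))
      } else newcols <- c(newcols, list(cl))
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
      if (a != b && keep[a] && keep[b] &&
          all(newcols[[b]] | !newcols[[a]]) &&
          !identical(newcols[[a]], newcols[[b]]))
        keep[a] <- FALSE
    }
    # among identical duplicates keep the first
    sig <- vapply(newcols, function(cl) paste(as.integer(cl), collapse = ""),
                  "")
    keep <- keep & !duplicated(sig)
    cols <- newcols[keep]
  }
  ord <- order(vapply(cols, function(cl) which(cl)[1], 0L))
  cols <- cols[ord]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  lab <- vapply(seq_len(k), function(i) {
    paste(letters_pool[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, "")
  setNames(lab, trt)
}

#' ANOVA and Tukey HSD compact letter display for one target site
#'
#' Treats the docked poses of each ligand as replicates in a one-way ANOVA,
#' runs all-pairs Tukey HSD, and assigns letters by the insert-and-absorb
#' algorithm so that two ligands share no letter exactly when their mean
#' scores differ significantly at `alpha`. Letters are assigned in order of
#' ascending mean score, i.e. letter "a" starts at the strongest (most
#' negative) binder.
#'
#' @param scores score data.frame restricted or restrictable to one site.
#' @param site site id to analyse; defaults to the single site present.
#' @param alpha significance level, default 0.05.
#' @return a `tukey_grouping`: list with `table` (ligand_id, role,
#'   mean_score, n_poses, letters, ordered by ascending mean), `anova_f`,
#'   `anova_p`, `alpha`, `p_matrix` (Tukey adjusted p-values), `site`.
#' @details Pose scores of one ligand are pseudo-replicates of a single
#'   docking run, not independent measurements; the grouping is a
#'   triage heuristic, not an inferential claim about binding.
#' @export
anova_tukey_cld <- function(scores, site = NULL, alpha = 0.05) {
  .validate_scores(scores)
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(site)) {
    site <- unique(scores$site_id)
    if (length(site) != 1L)
      stop("several sites present; pass `site` explicitly")
  }
  d <- scores[scores$site_id == site, , drop = FALSE]
  if (nrow(d) == 0L) stop("no scores for site ", site)
  n_per <- table(d$ligand_id)
  if (length(n_per) < 2L) stop("need at least 2 ligands")
  if (any(n_per < 2L))
    stop("every ligand needs >= 2 poses; offending: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "))
  within_var <- vapply(split(d$score, d$ligand_id), stats::var, 0)
  if (all(within_var < .Machine$double.eps))
    stop("zero within-ligand variance everywhere; ANOVA is degenerate ",
         "(jitter the poses or skip the test)")

  d$ligand_id <- factor(d$ligand_id)
  fit <- stats::aov(score ~ ligand_id, data = d)
  av <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$ligand_id

  lig <- levels(d$ligand_id)
  means <- vapply(split(d$score, d$ligand_id), mean, 0)[lig]
  # ascending mean; ties broken by ligand id (lig already sorted)
  ord <- order(means, lig)
  lig <- lig[ord]; means <- means[ord]

  pmat <- matrix(NA_real_, length(lig), length(lig),
                 dimnames = list(lig, lig))
  pair_names <- rownames(tk)
  for (r in seq_along(pair_names)) {
    ab <- strsplit(pair_names[r], "-", fixed = TRUE)[[1]]
    # ligand ids may themselves contain "-": split on every cut point and
    # keep the one where both halves are known ligands
    if (length(ab) != 2L || !all(ab %in% lig)) {
      cuts <- gregexpr("-", pair_names[r], fixed = TRUE)[[1]]
      ok <- FALSE
      for (cut in cuts) {
        a <- substr(pair_names[r], 1L, cut - 1L)
        b <- substr(pair_names[r], cut + 1L, nchar(pair_names[r]))
        if (a %in% lig && b %in% lig) { ab <- c(a, b); ok <- TRUE; break }
      }
      if (!ok) stop("cannot split Tukey pair label: ", pair_names[r])
    }
    pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- tk[r, "p adj"]
  }
  letters <- cld_insert_absorb(pmat < alpha & !is.na(pmat))

  roles <- vapply(split(d$role, d$ligand_id), `[`, "", 1L)[lig]
  tab <- data.frame(ligand_id = lig, role = roles, mean_score = means,
                    n_poses = as.integer(table(d$ligand_id)[lig]),
                    letters = letters[lig], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, anova_f = av[["F value"]][1],
                 anova_p = av[["Pr(>F)"]][1], alpha = alpha,
                 p_matrix = pmat, site = site),
            class = "tukey_grouping")
}

#' @export
print.tukey_grouping <- function(x, ...) {
  cat("Tukey grouping for site", x$site, " (alpha =", x$alpha, ")\n")
  cat("  ANOVA F =", format(x$anova_f, digits = 4),
      ", p =", format(x$anova_p, digits = 3), "\n")
  print(x$table, ...)
  invisible(x)
}

.share_letters <- function(a, b) {
  length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0L
}

#' Classify candidates as TOP / MIDDLE / WORST against control anchors
#'
#' The best (most negative mean) positive control and the worst (least
#' negative mean) negative control anchor the score range. A candidate
#' sharing at least one Tukey letter with the top anchor is TOP, with the
#' worst anchor WORST, with neither MIDDLE; a candidate sharing letters
#' with both anchors goes to the anchor with the smaller absolute mean
#' difference (exact tie: MIDDLE).
#'
#' @param grouping a `tukey_grouping` computed jointly over candidates and
#'   controls for one site.
#' @return a `triage_result`: data.frame `(ligand_id, site_id, mean_score,
#'   letters, group)` over candidates, with attributes `anchor_top`,
#'   `anchor_worst` (ligand id and mean of each anchor), `site`, `alpha`.
#' @export
classify_compounds <- function(grouping) {
  stopifnot(inherits(grouping, "tukey_grouping"))
  tab <- grouping$table
  pos <- tab[tab$role == "POSITIVE_CONTROL", ]
  neg <- tab[tab$role == "NEGATIVE_CONTROL", ]
  if (nrow(pos) == 0L) stop("no positive control in grouping")
  if (nrow(neg) == 0L) stop("no negative control in grouping")
  top_anchor <- pos[which.min(pos$mean_score), ]
  worst_anchor <- neg[which.max(neg$mean_score), ]

  cand <- tab[tab$role == "CANDIDATE", ]
  grp <- vapply(seq_len(nrow(cand)), function(i) {
    st <- .share_letters(cand$letters[i], top_anchor$letters)
    sw <- .share_letters(cand$letters[i], worst_anchor$letters)
    if (st && sw) {
      dt <- abs(cand$mean_score[i] - top_anchor$mean_score)
      dw <- abs(cand$mean_score[i] - worst_anchor$mean_score)
      if (dt < dw) "TOP" else if (dw < dt) "WORST" else "MIDDLE"
    } else if (st) "TOP" else if (sw) "WORST" else "MIDDLE"
  }, "")

  res <- data.frame(ligand_id = cand$ligand_id, site_id = grouping$site,
                    mean_score = cand$mean_score, letters = cand$letters,
                    group = grp, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("triage_result", "data.frame"),
            anchor_top = list(ligand_id = top_anchor$ligand_id,
                              mean_score = top_anchor$mean_score),
            anchor_worst = list(ligand_id = worst_anchor$ligand_id,
                                mean_score = worst_anchor$mean_score),
            site = grouping$site, alpha = grouping$alpha)
}

#' Triage a multi-site score table in one call
#'
#' Convenience wrapper: for each site, [anova_tukey_cld()] then
#' [classify_compounds()].
#'
#' @param scores score data.frame covering one or more sites.
#' @param alpha significance level.
#' @return named list of `triage_result`, one per site.
#' @export
triage_scores <- function(scores, alpha = 0.05) {
  .validate_scores(scores)
  sites <- sort(unique(scores$site_id))
  setNames(lapply(sites, function(s)
    classify_compounds(anova_tukey_cld(scores, site = s, alpha = alpha))),
    sites)
}

#' Cross-site overlap of triage labels
#'
#' Compares triage labels of the same candidate universe across target
#' sites: per-label ligand sets per site, every pairwise and higher-order
#' intersection, and the site-specific pattern of ligands that are TOP in
#' exactly one site while WORST in all others (potential selective
#' binders).
#'
#' @param results list of `triage_result` (>= 2 sites, same ligands).
#' @return list with `labels` (ligand x site label matrix), `sets`
#'   (per label, per site, character vectors), `intersections` (per label,
#'   per site combination) and `selective` (data.frame ligand_id,
#'   top_site for the TOP-in-one / WORST-elsewhere pattern).
#' @export
cross_site_overlap <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L)
  stopifnot(all(vapply(results, inherits, TRUE, "triage_result")))
  sites <- vapply(results, function(r) attr(r, "site"), "")
  if (anyDuplicated(sites)) stop("duplicated site ids in results")
  names(results) <- sites
  universe <- sort(results[[1]]$ligand_id)
  for (r in results)
    if (!identical(sort(r$ligand_id), universe))
      stop("ligand universes differ between sites")

  labels <- vapply(results, function(r)
    setNames(r$group, r$ligand_id)[universe], character(length(universe)))
  rownames(labels) <- universe

  sets <- lapply(TRIAGE_GROUPS, function(g)
    lapply(results, function(r) sort(r$ligand_id[r$group == g])))
  names(sets) <- TRIAGE_GROUPS

  combos <- unlist(lapply(2:length(sites), function(k)
    utils::combn(sites, k, simplify = FALSE)), recursive = FALSE)
  intersections <- lapply(TRIAGE_GROUPS, function(g) {
    out <- lapply(combos, function(cm) Reduce(intersect, sets[[g]][cm]))
    names(out) <- vapply(combos, paste, "", collapse = "&")
    out
  })
  names(intersections) <- TRIAGE_GROUPS

  sel <- do.call(rbind, lapply(universe, function(lg) {
    lab <- labels[lg, ]
    if (sum(lab == "TOP") == 1L && all(lab[lab != "TOP"] == "WORST"))
      data.frame(ligand_id = lg, top_site = sites[lab == "TOP"],
                 stringsAsFactors = FALSE)
  }))
  if (is.null(sel))
    sel <- data.frame(ligand_id = character(), top_site = character(),
                      stringsAsFactors = FALSE)
  list(labels = labels, sets = sets, intersections = intersections,
       selective = sel)
}

.resolve_ligands <- function(ids, profile) {
  hit_name <- match(ids, profile$compounds$name)
  hit_id <- match(suppressWarnings(as.integer(ids)),
                  profile$compounds$compound_id)
  idx <- ifelse(is.na(hit_name), hit_id, hit_name)
  if (anyNA(idx))
    stop("ligand id(s) not resolvable in profile: ",
         paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Per-group summary statistics
#'
#' For every (site, triage group): number of compounds, mean docking
#' score, mean across-sample abundance (not-detected = 0) when a VOC
#' profile is supplied, the mean of every numeric descriptor when a
#' descriptor table is supplied, and the chemical-class composition in
#' percent (summing to 100 within each group).
#'
#' @param results a `triage_result` or list of them.
#' @param profile optional `voc_profile`; ligand ids must match compound
#'   names or compound ids.
#' @param descriptors optional `descriptor_table` (see
#'   [load_descriptors()]).
#' @return data.frame, one row per (site, group).
#' @export
summarize_groups <- function(results, profile = NULL, descriptors = NULL) {
  if (inherits(results, "triage_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, TRUE, "triage_result")))
  rows <- list()
  for (r in results) {
    site <- attr(r, "site")
    if (!is.null(profile)) idx <- .resolve_ligands(r$ligand_id, profile)
    if (!is.null(descriptors)) {
      didx <- match(r$ligand_id, descriptors$ligand_id)
      if (anyNA(didx))
        stop("ligand id(s) missing from descriptor table: ",
             paste(r$ligand_id[is.na(didx)], collapse = ", "))
    }
    for (g in TRIAGE_GROUPS) {
      in_g <- r$group == g
      row <- data.frame(site_id = site, group = g, n = sum(in_g),
                        mean_score = if (any(in_g))
                          mean(r$mean_score[in_g]) else NA_real_,
                        stringsAsFactors = FALSE)
      if (!is.null(profile)) {
        ab <- mean_abundance(profile)[idx]
        row$mean_abundance <- if (any(in_g)) mean(ab[in_g]) else NA_real_
        cls <- profile$compounds$class[idx][in_g]
        comp <- 100 * table(factor(cls, levels = VOC_CLASSES)) /
          max(1L, length(cls))
        row$pct_monoterpene <- comp[["MONOTERPENE"]]
        row$pct_sesquiterpene <- comp[["SESQUITERPENE"]]
        row$pct_other <- comp[["OTHER"]]
      }
      if (!is.null(descriptors)) {
        num <- vapply(descriptors, is.numeric, TRUE) &
          names(descriptors) != "ligand_id"
        for (dc in names(descriptors)[num]) {
          row[[paste0("mean_", dc)]] <- if (any(in_g))
            mean(descriptors[[dc]][didx][in_g], na.rm = TRUE) else NA_real_
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Share of total molar content held by selected triage groups
#'
#' Aggregates the pooled mean abundances of the profiled compounds (ND = 0)
#' and reports the percentage contributed by compounds whose triage label
#' falls in `groups`, either in at least one site (`sites = "any"`), in
#' every site (`"all"`), or in one named site. The group set and the
#' across-site rule are deliberately explicit arguments: different choices
#' answer different questions and no single default is privileged.
#'
#' @param results list of `triage_result` (or a single one).
#' @param profile a `voc_profile`.
#' @param groups labels counted as "bound", default `c("TOP", "MIDDLE")`.
#' @param sites `"any"`, `"all"`, or a site id.
#' @return percentage in \[0, 100\].
#' @export
molar_content_share <- function(results, profile,
                                groups = c("TOP", "MIDDLE"),
                                sites = "any") {
  if (inherits(results, "triage_result")) results <- list(results)
  stopifnot(all(groups %in% TRIAGE_GROUPS))
  site_ids <- vapply(results, function(r) attr(r, "site"), "")
  names(results) <- site_ids
  universe <- results[[1]]$ligand_id
  hit <- vapply(results, function(r)
    setNames(r$group %in% groups, r$ligand_id)[universe],
    logical(length(universe)))
  hit <- matrix(hit, nrow = length(universe),
                dimnames = list(universe, site_ids))
  selected <- switch(sites,
    any = rownames(hit)[rowSums(hit) > 0L],
    all = rownames(hit)[rowSums(hit) == ncol(hit)],
    {
      if (!sites %in% site_ids) stop("unknown site: ", sites)
      rownames(hit)[hit[, sites]]
    })
  ab <- mean_abundance(profile)
  idx <- .resolve_ligands(universe, profile)
  ab_universe <- ab[idx]
  names(ab_universe) <- universe
  100 * sum(ab_universe[selected]) / sum(ab)
}
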