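make_scores <- function(ligands, pose_sets, role = "CANDIDATE",
                        site = "S") {
  do.call(rbind, Map(function(lg, ps, rl) {
    data.frame(ligand_id = lg, site_id = site, role = rl,
               pose_rank = seq_along(ps), score = ps,
               stringsAsFactors = FALSE)
  }, ligands, pose_sets,
  if (length(role) == 1L) rep(role, length(ligands)) else role))
}

test_that("pose averaging is the arithmetic mean, per ligand and site", {
  sc <- make_scores(c("A", "B"), list(c(-6.0, -5.8, -5.6), c(-7, -7, -7)))
  av <- average_pose_scores(sc)
  expect_equal(av$mean_score[av$ligand_id == "A"], -5.8)
  expect_equal(av$mean_score[av$ligand_id == "B"], -7)

  set.seed(11)
  panel <- random_panel(50, seed = 11)
  av <- average_pose_scores(panel)
  brute <- tapply(panel$score, panel$ligand_id, mean)
  expect_equal(av$mean_score, as.numeric(brute[av$ligand_id]))
})

test_that("well-separated ligands get distinct letters, identical ones share", {
  sc <- make_scores(c("A", "B", "C"),
                    list(c(-9.0, -9.1, -8.9), c(-6.0, -6.1, -5.9),
                         c(-3.0, -3.1, -2.9)))
  gr <- anova_tukey_cld(sc)
  expect_equal(gr$table$letters, c("a", "b", "c"))
  expect_equal(gr$table$ligand_id, c("A", "B", "C"))  # ascending mean

  sc2 <- make_scores(c("A", "B"),
                     list(c(-5, -5.2, -4.8), c(-5, -5.2, -4.8)))
  gr2 <- anova_tukey_cld(sc2)
  expect_true(.share <- grepl(substr(gr2$table$letters[1], 1, 1),
                              gr2$table$letters[2]))
})

test_that("planted two-cluster panels give exactly two letters", {
  set.seed(3)
  sd <- 0.2
  sc <- make_scores(sprintf("L%d", 1:6),
                    lapply(c(-9, -9, -9, -4, -4, -4), function(m)
                      m + rnorm(3, 0, sd)))
  gr <- anova_tukey_cld(sc)
  expect_equal(length(unique(gr$table$letters)), 2L)
  p <- oracle_tukey_p(sc$score, sc$ligand_id)
  for (a in sprintf("L%d", 1:3)) for (b in sprintf("L%d", 4:6))
    expect_lt(p[a, b], 0.05)
})

test_that("letters separate exactly where the hand-computed Tukey p < alpha", {
  for (seed in 1:20) {
    panel <- random_panel(k = 5 + seed %% 4, seed = seed)
    gr <- anova_tukey_cld(panel, alpha = 0.05)
    p <- oracle_tukey_p(panel$score, panel$ligand_id)
    ids <- gr$table$ligand_id
    for (a in seq_along(ids)[-1]) for (b in seq_len(a - 1)) {
      expect_equal(letters_separate(gr, ids[a], ids[b]),
                   p[ids[a], ids[b]] < 0.05,
                   info = sprintf("seed %d pair %s-%s (p=%.3g)",
                                  seed, ids[a], ids[b],
                                  p[ids[a], ids[b]]))
    }
    # and the implementation's own p-matrix agrees with the oracle
    expect_equal(gr$p_matrix[ids, ids], p[ids, ids], tolerance = 1e-8)
  }
})

test_that("degenerate all-equal poses raise a guidance error", {
  sc <- make_scores(c("A", "B"), list(c(-5, -5, -5), c(-4, -4, -4)))
  expect_error(anova_tukey_cld(sc), "degenerate")
  expect_error(anova_tukey_cld(make_scores("A", list(c(-5, -5.1)))),
               "at least 2 ligands")
})

test_that("candidates are anchored on the best positive and worst negative control", {
  sd <- 0.1
  set.seed(5)
  sc <- make_scores(
    c("POS_A", "POS_B", "NEG_A", "NEG_B", "c_top", "c_mid", "c_worst"),
    lapply(c(-9, -8.5, -4, -4.5, -9, -6.5, -4), function(m)
      m + rnorm(3, 0, sd)),
    role = c("POSITIVE_CONTROL", "POSITIVE_CONTROL",
             "NEGATIVE_CONTROL", "NEGATIVE_CONTROL",
             "CANDIDATE", "CANDIDATE", "CANDIDATE"))
  res <- classify_compounds(anova_tukey_cld(sc))
  expect_equal(attr(res, "anchor_top")$ligand_id, "POS_A")
  expect_equal(attr(res, "anchor_worst")$ligand_id, "NEG_A")
  lab <- setNames(res$group, res$ligand_id)
  expect_equal(unname(lab["c_top"]), "TOP")
  expect_equal(unname(lab["c_mid"]), "MIDDLE")
  expect_equal(unname(lab["c_worst"]), "WORST")
})

test_that("classification errors without controls and ignores input order", {
  g <- gen_scores(seed = 2)
  no_pos <- g$scores[g$scores$role != "POSITIVE_CONTROL", ]
  expect_error(classify_compounds(anova_tukey_cld(no_pos)),
               "no positive control")

  res1 <- classify_compounds(anova_tukey_cld(g$scores))
  shuffled <- g$scores[rev(seq_len(nrow(g$scores))), ]
  res2 <- classify_compounds(anova_tukey_cld(shuffled))
  expect_equal(res1[order(res1$ligand_id), ],
               res2[order(res2$ligand_id), ], ignore_attr = TRUE)
})

test_that("planted panels are recovered at 90%+ accuracy", {
  g <- gen_scores(n_top = 5, n_middle = 10, n_worst = 5, pose_sd = 0.05,
                  seed = 101)
  res <- classify_compounds(anova_tukey_cld(g$scores))
  m <- merge(as.data.frame(res), g$truth)
  expect_gte(mean(m$group == m$truth), 0.9)
})

test_that("cross-site overlap matches brute-force set algebra", {
  sites <- c("COX1", "iNOSas", "iNOScs")
  results <- lapply(sites, function(s) {
    g <- gen_scores(site = s, seed = match(s, sites) + 30)
    classify_compounds(anova_tukey_cld(g$scores))
  })
  ov <- cross_site_overlap(results)
  for (g in c("TOP", "MIDDLE", "WORST")) {
    for (s in sites)
      expect_equal(ov$sets[[g]][[s]],
                   sort(results[[match(s, sites)]]$ligand_id[
                     results[[match(s, sites)]]$group == g]))
    pair <- ov$intersections[[g]][["COX1&iNOScs"]]
    expect_equal(sort(pair),
                 sort(intersect(ov$sets[[g]][["COX1"]],
                                ov$sets[[g]][["iNOScs"]])))
    triple <- ov$intersections[[g]][[paste(sites, collapse = "&")]]
    expect_equal(sort(triple),
                 sort(Reduce(intersect, ov$sets[[g]][sites])))
  }
  # identical results on two sites: intersection is each TOP set
  r2 <- results[[1]]
  attr(r2, "site") <- "X2"
  r2$site_id <- "X2"
  ov2 <- cross_site_overlap(list(results[[1]], r2))
  expect_equal(ov2$intersections$TOP[[1]], ov2$sets$TOP[[1]])
})

test_that("site-selective ligands (TOP in one site, WORST elsewhere) are flagged", {
  mk <- function(site, groups) {
    structure(data.frame(ligand_id = names(groups), site_id = site,
                         mean_score = -5, letters = "a", group = groups,
                         stringsAsFactors = FALSE),
              class = c("triage_result", "data.frame"), site = site)
  }
  r1 <- mk("S1", c(l1 = "TOP", l2 = "WORST", l3 = "MIDDLE"))
  r2 <- mk("S2", c(l1 = "WORST", l2 = "WORST", l3 = "TOP"))
  r3 <- mk("S3", c(l1 = "WORST", l2 = "TOP", l3 = "TOP"))
  ov <- cross_site_overlap(list(r1, r2, r3))
  # l1 is TOP only in S1 (WORST elsewhere); l2 shows the mirror pattern
  # in S3; l3 is TOP in two sites so it is not site-selective
  expect_equal(ov$selective$ligand_id, c("l1", "l2"))
  expect_equal(ov$selective$top_site, c("S1", "S3"))

  r_bad <- mk("S4", c(l1 = "TOP", lX = "WORST", l3 = "MIDDLE"))
  expect_error(cross_site_overlap(list(r1, r_bad)), "universes differ")
})

test_that("group summaries match brute-force recomputation", {
  prof <- aroeira_profile()
  ids <- prof$compounds$name
  g <- gen_scores(n_top = 6, n_middle = 11, n_worst = 6, seed = 8)
  sc <- g$scores
  # rename planted candidates to the profiled compounds
  cand <- unique(sc$ligand_id[sc$role == "CANDIDATE"])
  map <- setNames(ids, cand)
  sc$ligand_id[sc$role == "CANDIDATE"] <- map[sc$ligand_id[
    sc$role == "CANDIDATE"]]
  res <- classify_compounds(anova_tukey_cld(sc))

  desc <- data.frame(ligand_id = ids,
                     polarizability = seq(10, 32, along.with = ids))
  class(desc) <- c("descriptor_table", "data.frame")
  sm <- summarize_groups(res, profile = prof, descriptors = desc)

  ab <- mean_abundance(prof)
  for (grp in unique(res$group)) {
    in_g <- res$ligand_id[res$group == grp]
    row <- sm[sm$group == grp, ]
    expect_equal(row$n, length(in_g))
    expect_equal(row$mean_score, mean(res$mean_score[res$group == grp]))
    expect_equal(row$mean_abundance, mean(ab[in_g]))
    expect_equal(row$mean_polarizability,
                 mean(desc$polarizability[match(in_g, desc$ligand_id)]))
    expect_equal(row$pct_monoterpene + row$pct_sesquiterpene +
                   row$pct_other, 100)
  }
  expect_error(summarize_groups(res, profile = {
    p <- prof; p$compounds$name[1] <- "renamed"; p
  }), "not resolvable")
})

test_that("molar-content aggregation is configurable and consistent", {
  prof <- aroeira_profile()
  ids <- prof$compounds$name
  results <- lapply(c("S1", "S2"), function(s) {
    g <- gen_scores(n_top = 6, n_middle = 11, n_worst = 6, seed = 9,
                    site = s)
    sc <- g$scores
    cand <- unique(sc$ligand_id[sc$role == "CANDIDATE"])
    sc$ligand_id[sc$role == "CANDIDATE"] <-
      setNames(ids, cand)[sc$ligand_id[sc$role == "CANDIDATE"]]
    classify_compounds(anova_tukey_cld(sc))
  })
  all_groups <- molar_content_share(results, prof,
                                    groups = c("TOP", "MIDDLE", "WORST"))
  expect_equal(all_groups, 100)
  tm_any <- molar_content_share(results, prof, sites = "any")
  tm_all <- molar_content_share(results, prof, sites = "all")
  tm_s1 <- molar_content_share(results, prof, sites = "S1")
  expect_gte(tm_any, tm_all)
  expect_gte(tm_any, tm_s1)
  expect_gte(tm_s1, molar_content_share(results, prof, groups = "TOP",
                                        sites = "S1"))
})

test_that("vina-style logs and native tables read to the same scores", {
  g <- gen_scores(seed = 4)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_scores(g$scores, tmp)
  back <- read_scores(tmp)
  expect_equal(back$score, g$scores$score)

  log <- withr::local_tempfile(fileext = ".log")
  lines <- unlist(lapply(split(g$scores,
                               factor(g$scores$ligand_id,
                                      unique(g$scores$ligand_id))),
    function(d) c(sprintf("Ligand: %s Site: %s Role: %s",
                          d$ligand_id[1], d$site_id[1], d$role[1]),
                  "mode |  affinity | dist",
                  sprintf("  %d   %.4f  0.0 0.0", d$pose_rank, d$score))))
  writeLines(lines, log)
  vina <- read_scores(log)
  key <- function(d) d[order(d$ligand_id, d$pose_rank), "score"]
  expect_equal(key(vina), key(g$scores), tolerance = 1e-4)
})
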