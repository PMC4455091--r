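# MS evidence handling: emPAI arithmetic, Mascot filtering and the
# inclusion filters.

test_that("emPAI follows the closed form and its contracts", {
  expect_equal(compute_empai(0, 10), 0)
  expect_equal(compute_empai(10, 10), 10^1 - 1)         # 9 exactly
  expect_equal(compute_empai(3, 10), 10^(3 / 10) - 1)
  expect_error(compute_empai(3, 0), "n_observable")
  expect_error(compute_empai(-1, 10), "n_observed")
  # strictly increasing in n_observed at fixed n_observable
  e <- compute_empai(0:20, 7)
  expect_true(all(diff(e) > 0))
  expect_true(all(e >= 0))
})

test_that("Mascot gate keeps proteins with one high-scoring histone ChIP", {
  ev <- rbind(
    ev_row("A", "H3K4me3", 1, 120, 5),            # clears the 50 gate
    ev_row("A", "H3K4me1", 1, 47, 2),             # annotated (>= 45)
    ev_row("B", "H3K4me3", 1, 44, 3),             # best score 44: dropped
    ev_row("C", "GFP", 1, 200, 6))                # GFP cannot open the gate
  out <- apply_mascot_filters(ev)
  expect_setequal(unique(out$protein_id), "A")
  expect_equal(nrow(out), 2)
  # empty input passes through
  expect_equal(nrow(apply_mascot_filters(ev[0, ])), 0)
})

test_that("scores in the manual-check band require validation", {
  ev <- rbind(
    ev_row("A", "H3K4me3", 1, 120, 5),
    ev_row("A", "H3K27ac", 1, 52, 2, validated = FALSE),  # 45-60, unchecked
    ev_row("A", "H3K9me3", 1, 75, 2, validated = FALSE))  # >= 60: kept
  out <- apply_mascot_filters(ev)
  expect_setequal(out$channel, c("H3K4me3", "H3K9me3"))
  # a protein whose only gate-opening score is unvalidated drops entirely
  ev2 <- ev_row("B", "H3K4me3", 1, 55, 4, validated = FALSE)
  expect_equal(nrow(apply_mascot_filters(ev2)), 0)
})

test_that("missing per-sample threshold is a configuration error", {
  ev <- ev_row("A", "H3K4me3", 1, 120, 5)
  thr <- significance_thresholds("H3K4me3", 2, 28)   # wrong replicate
  expect_error(apply_mascot_filters(ev, thr), "threshold")
})

test_that("profiles average replicates with missing replicates as zero", {
  ev <- rbind(
    ev_row("A", "H3K4me3", 1, 100, 10, 10),   # emPAI 9
    ev_row("A", "H3K4me3", 2, 100, 5, 10),    # emPAI 10^0.5 - 1
    ev_row("A", "GFP", 1, 100, 2, 10),
    ev_row("B", "H3K4me1", 1, 100, 10, 10))   # replicate 2 missing
  prof <- build_empai_profiles(ev)
  expect_equal(prof$empai_H3K4me3[prof$protein_id == "A"],
               (9 + 10^0.5 - 1) / 2)
  expect_equal(prof$empai_H3K4me1[prof$protein_id == "B"], 9 / 2)
  # GFP kept per replicate, not averaged
  expect_equal(prof$empai_GFP_r1[prof$protein_id == "A"],
               compute_empai(2, 10))
  expect_equal(prof$empai_GFP_r2[prof$protein_id == "A"], 0)
  expect_error(build_empai_profiles(rbind(ev[1, ], ev[1, ])), "duplicated")
})

test_that("GFP exclusion compares the best mark against every control", {
  expect_true(gfp_exclusion_filter(
    make_profile(me3 = 0.5, gfp1 = 0.05, gfp2 = 0.08)))   # 0.5 >= 5*0.08
  expect_false(gfp_exclusion_filter(
    make_profile(me3 = 0.5, gfp1 = 0.2, gfp2 = 0)))       # 0.5 < 1.0
  expect_true(gfp_exclusion_filter(make_profile(me1 = 0.01)))  # GFP all 0
  expect_false(gfp_exclusion_filter(make_profile()))      # all-zero fails
})

test_that("discrimination filter needs a three-fold channel pair", {
  expect_true(discrimination_filter(
    make_profile(me3 = 0.6, me1 = 0.1, k27 = 0.2, me9 = 0)))
  expect_false(discrimination_filter(
    make_profile(me3 = 0.3, me1 = 0.2, k27 = 0.25, me9 = 0.15)))
  expect_false(discrimination_filter(
    make_profile(me3 = 0.2, me1 = 0.2, k27 = 0.2, me9 = 0.2)))
  expect_true(discrimination_filter(
    make_profile(me3 = 0.2, me1 = 0)))      # positive over zero passes
})

test_that("inclusion list equals brute-force filtering of planted profiles", {
  set.seed(402)
  profs <- do.call(rbind, lapply(1:20, function(i) {
    make_profile(me3 = round(runif(1, 0, 0.6), 2),
                 me1 = round(runif(1, 0, 0.6), 2),
                 k27 = round(runif(1, 0, 0.6), 2),
                 me9 = round(runif(1, 0, 0.6), 2),
                 gfp1 = round(runif(1, 0, 0.12), 2),
                 gfp2 = round(runif(1, 0, 0.12), 2),
                 id = sprintf("P%02d", i))
  }))
  # brute-force application of both written rules, row by row
  expected <- vapply(seq_len(nrow(profs)), function(i) {
    m <- unlist(profs[i, c("empai_H3K4me3", "empai_H3K4me1",
                           "empai_H3K27ac", "empai_H3K9me3")])
    g <- unlist(profs[i, c("empai_GFP_r1", "empai_GFP_r2")])
    pass_gfp <- max(m) > 0 && all(max(m) >= 5 * g)
    pass_disc <- any(outer(m, m, function(a, b) a >= 3 * b & a > 0))
    pass_gfp && pass_disc
  }, logical(1))
  inc <- build_inclusion_list(profs)
  expect_setequal(inc$protein_id, profs$protein_id[expected])
  expect_gt(nrow(inc), 0)
  expect_lt(nrow(inc), nrow(profs))

  # exclusion list removes a passer with a logged reason
  drop_id <- inc$protein_id[1]
  inc2 <- build_inclusion_list(profs, exclusion_list = drop_id)
  expect_false(drop_id %in% inc2$protein_id)
  all2 <- attr(inc2, "all_profiles")
  expect_equal(all2$excluded_reason[all2$protein_id == drop_id],
               "exclusion_list")

  # order independence and idempotence
  perm <- profs[sample(nrow(profs)), ]
  expect_setequal(build_inclusion_list(perm)$protein_id, inc$protein_id)
  expect_equal(build_inclusion_list(inc)$protein_id, inc$protein_id)
})

test_that("raising the fold thresholds never adds proteins", {
  set.seed(77)
  profs <- do.call(rbind, lapply(1:30, function(i)
    make_profile(me3 = runif(1), me1 = runif(1), k27 = runif(1),
                 me9 = runif(1), gfp1 = runif(1, 0, 0.3),
                 gfp2 = runif(1, 0, 0.3), id = sprintf("Q%02d", i))))
  base <- build_inclusion_list(profs)$protein_id
  for (gf in c(6, 8, 12)) {
    stricter <- build_inclusion_list(
      profs, filter_params(gfp_fold = gf))$protein_id
    expect_true(all(stricter %in% base))
    base_d <- build_inclusion_list(
      profs, filter_params(discrimination_fold = gf / 2))$protein_id
    expect_true(all(base_d %in% base))
  }
})
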