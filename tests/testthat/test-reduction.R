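# Cohorts for the reduction pipeline are generated from the graded-response
# model with planted informative and null items.

make_bank_cohort <- function(bank, null_ids, n_case, n_control,
                             seed, case_mean = 1.6, control_mean = -0.9,
                             groups = c("ASD", "NONPSYCH")) {
  items <- bank_sim_items(bank, null_ids = null_ids)
  prof <- data.frame(group = groups,
                     trait_mean = c(case_mean, control_mean),
                     trait_sd = c(0.8, 0.8),
                     n = c(n_case, n_control))
  cfg <- sim_config(prof, items, straight_line_rate = 0, missing_rate = 0)
  generate_cohort(cfg, seed = seed)
}

test_that("phase-1 selection honours quotas and skips planted noise items", {
  domains <- rep(c("circumscribed_interests", "language",
                   "social_relatedness", "sensory_motor"), c(5, 5, 5, 5))
  bank <- bank_instrument(domains)
  null_ids <- c(3, 8, 13, 18) # one planted noise item per domain
  coh <- make_bank_cohort(bank, null_ids, 400, 400, seed = 401)
  quotas <- stats::setNames(rep(4L, 4), unique(domains))
  sel <- phase1_select(coh, bank, quotas)
  expect_length(sel$selected, 16)
  expect_true(!any(null_ids %in% sel$selected))
  expect_true(all(table(bank$items$domain[sel$selected]) == 4))
})

test_that("an 80-item bank reduces to 18 under the 4/2/8/4 quotas", {
  domains <- rep(c("circumscribed_interests", "language",
                   "social_relatedness", "sensory_motor"),
                 c(14, 15, 39, 12))
  bank <- bank_instrument(domains)
  coh <- make_bank_cohort(bank, integer(0), 150, 250, seed = 402)
  quotas <- c(circumscribed_interests = 4L, language = 2L,
              social_relatedness = 8L, sensory_motor = 4L)
  sel <- phase1_select(coh, bank, quotas)
  expect_length(sel$selected, 18)
  expect_equal(as.integer(table(bank$items$domain[sel$selected])[names(quotas)]),
               as.integer(quotas))
  expect_error(phase1_select(coh, bank, c(language = 16L)), "quota")
})

test_that("tied discrimination indices resolve to the lower item id", {
  domains <- rep("social_relatedness", 4)
  bank <- bank_instrument(domains)
  set.seed(403)
  m <- matrix(sample(0:3, 400, TRUE), 100, 4)
  m[, 3] <- m[, 2] # items 2 and 3 identical -> identical index
  grp <- rep(c("ASD", "NONPSYCH"), each = 50)
  m[grp == "ASD", ] <- pmin(m[grp == "ASD", ] + 1L, 3L)
  coh <- cohort_from_score_matrix(m, grp, bank)
  sel <- phase1_select(coh, bank, c(social_relatedness = 1L))
  tab <- sel$table
  expect_equal(tab$index[tab$item_id == 2], tab$index[tab$item_id == 3])
  expect_lt(tab$rank_in_domain[tab$item_id == 2],
            tab$rank_in_domain[tab$item_id == 3])
})

test_that("phase-2 pruning removes the weakest items and keeps 14 of 18", {
  bank <- bank_instrument(rep(c("social_relatedness", "sensory_motor"), 9))
  coh <- make_bank_cohort(bank, null_ids = c(2, 7, 11, 16),
                          n_case = 500, n_control = 1500, seed = 404,
                          groups = c("ASD", "OPD"))
  rep <- phase2_prune(coh, bank, n_drop = 4)
  expect_length(rep$selected, 14)
  expect_setequal(rep$dropped$item_id, c(2, 7, 11, 16))
  expect_true(all(rep$dropped$auc < min(
    rep$per_item$auc[!rep$per_item$item_id %in% rep$dropped$item_id])))
  expect_error(phase2_prune(coh, bank, n_drop = 18), "n_drop")
})

test_that("a constant item scores chance-level AUC and lands in the drop set", {
  bank <- bank_instrument(rep("social_relatedness", 6))
  coh <- make_bank_cohort(bank, integer(0), 200, 400, seed = 405,
                          groups = c("ASD", "OPD"))
  coh$item_4 <- raads_cats[3] # constant across all subjects
  rep <- phase2_prune(coh, bank, n_drop = 1)
  expect_equal(rep$per_item$auc[rep$per_item$item_id == 4], 0.5)
  expect_equal(rep$dropped$item_id, 4)
})

test_that("pruning recovers planted null items across seeded replicates", {
  bank <- bank_instrument(rep(c("social_relatedness", "sensory_motor",
                                "circumscribed_interests"), 6))
  null_ids <- c(4, 9, 14, 17)
  hits <- vapply(1:20, function(s) {
    coh <- make_bank_cohort(bank, null_ids, 500, 1500, seed = 4000 + s,
                            groups = c("ASD", "OPD"))
    rep <- phase2_prune(coh, bank, n_drop = 4)
    setequal(rep$dropped$item_id, null_ids)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("re-ordering puts the best discriminators first and interleaves subscales", {
  ids <- 1:14
  subs <- rep(c("a", "b", "c"), length.out = 14)
  auc <- seq(0.95, 0.56, length.out = 14)
  ord <- reorder_items(ids, auc, subs)
  expect_equal(ord[1:5], 1:5) # five highest AUCs, descending
  rest_subs <- subs[ord[6:14]]
  expect_true(all(rest_subs[-1] != rest_subs[-length(rest_subs)]))

  # ties: stable by original id
  ord_tied <- reorder_items(ids, rep(0.8, 14), subs)
  expect_equal(ord_tied[1:5], 1:5)

  # infeasible interleaving degrades gracefully
  ord_one_sub <- reorder_items(1:7, seq(0.9, 0.6, length.out = 7),
                               rep("a", 7))
  expect_setequal(ord_one_sub, 1:7)
})

test_that("derived instruments renumber items and keep reverse flags", {
  rep <- list(selected = c(13, 1, 9, 6, 2))
  derived <- derive_instrument(raads14_instrument(), rep$selected,
                               name = "mini", screen_cutoff = 5L,
                               short_form_n = 2L)
  expect_equal(derived$items$item_id, 1:5)
  expect_equal(derived$items$text[1], raads14_instrument()$items$text[13])
  expect_true(derived$items$reversed[4]) # old item 6
  expect_equal(short_form_items(derived), 1:2)
})

test_that("the validation report covers ROC, cut-offs, reliability and factors", {
  cfg <- raads14_sim_config(n_per_group = c(ASD = 200, ADHD = 300,
                                            OPD = 150, NONPSYCH = 400))
  coh <- generate_cohort(cfg, seed = 406)
  rep <- evaluate_final(coh, raads14_instrument())
  expect_s3_class(rep, "evaluation_report")
  expect_setequal(names(rep$roc), c("ADHD", "OPD", "NONPSYCH"))
  expect_equal(nrow(rep$comparisons), 3)
  expect_true(all(rep$operating_points$sensitivity >= 0 &
                    rep$operating_points$sensitivity <= 1))
  expect_equal(rep$factors$n_factors, 3)

  # the factor stage runs on the cohort minus the case group
  sc <- batch_score(coh, raads14_instrument())
  keep <- sc$scores$valid & sc$scores$group != "ASD"
  m <- raads14:::response_score_matrix(coh, raads14_instrument())[keep, ]
  m[is.na(m)] <- 0L
  direct <- principal_factor_analysis(m, n_factors = 3)
  expect_equal(rep$factors$loadings, direct$loadings)

  # identical groups produce chance-level AUC
  coh2 <- coh[coh$group == "NONPSYCH", ]
  half <- seq_len(nrow(coh2)) <= nrow(coh2) / 2
  coh2$group <- ifelse(half, "ASD", "OPD")
  rep2 <- evaluate_final(coh2, raads14_instrument(), n_factors = 2)
  expect_lt(abs(rep2$roc$OPD$auc - 0.5), 0.06)
})

test_that("the reduction pipeline is deterministic given identical input", {
  bank <- bank_instrument(rep(c("social_relatedness", "sensory_motor"), 9))
  coh <- make_bank_cohort(bank, c(1, 5), 300, 600, seed = 407,
                          groups = c("ASD", "OPD"))
  r1 <- phase2_prune(coh, bank)
  r2 <- phase2_prune(coh, bank)
  expect_identical(r1, r2)
})
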