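test_that("auc equals the exhaustive pair-comparison oracle", {
  expect_equal(auc(c(2, 3, 5), c(1, 4)), oracle_auc(c(2, 3, 5), c(1, 4)))
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc(c(5, 6), c(1, 2)), 1)
  expect_error(auc(numeric(0), 1), "non-empty")
  set.seed(31)
  for (r in 1:200) {
    a <- sample(0:8, sample(1:20, 1), TRUE)
    b <- sample(0:8, sample(1:20, 1), TRUE)
    expect_equal(auc(a, b), oracle_auc(a, b))
    expect_equal(auc(a, b) + auc(b, a), 1)
  }
})

test_that("fdr_bh matches the hand-walked step-up rule", {
  expect_equal(fdr_bh(c(0.001, 0.02, 0.03, 0.2), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(fdr_bh(rep(1, 10), 0.05)))
  expect_true(fdr_bh(0.04, 0.05))
  expect_length(fdr_bh(numeric(0)), 0)
  set.seed(32)
  for (r in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p, 0.05), oracle_bh(p, 0.05))
    # BH rejections are a superset of Bonferroni rejections
    expect_true(all(fdr_bh(p, 0.05)[p <= 0.05 / length(p)]))
  }
})

test_that("the signed-count binomial test matches direct summation", {
  # 9 vs 1 significant neurons
  expect_equal(stats::binom.test(9, 10, 0.5)$p.value, oracle_binom_p(9, 10))
  for (n in c(4, 10, 17)) for (k in 0:n)
    expect_equal(stats::binom.test(k, n, 0.5)$p.value, oracle_binom_p(k, n),
                 tolerance = 1e-12)
  # end-to-end on constructed count matrices: window 1 has 3-vs-0 selective
  # neurons, window 2 none
  set.seed(33)
  cond <- rep(c("pd_included", "pd_opposite"), each = 15)
  counts_list <- lapply(1:3, function(j)
    cbind(rpois(30, 10) + 8 * (cond == "pd_included"), rpois(30, 10)))
  r <- signed_count_binomial(counts_list, replicate(3, cond, simplify = FALSE))
  expect_equal(r$n_greater_included[1], 3)
  expect_equal(r$binom_p[1], oracle_binom_p(3, 3))
  expect_equal(r$binom_p[2], 1)  # no significant neurons -> p = 1
})

test_that("determine_pd applies the significance-plus-unique-argmax rule", {
  dirs <- rep(c("LD", "L", "LU", "RU", "R", "RD"), each = 10)
  set.seed(34)
  counts <- rpois(60, 5) + 15 * (dirs == "L")
  r <- determine_pd(counts, dirs)
  expect_true(r$has_pd)
  expect_equal(r$pd_direction, "L")
  expect_lte(r$anova_p, 0.05)
  # identical counts everywhere: no direction effect
  expect_false(determine_pd(rep(5, 60), dirs)$has_pd)
  # exact two-way tie at the maximum: no PD by the uniqueness rule
  tied <- rep(c(9, 11, 9, 11, 4, 6, 4, 6, 4, 6), 6)[1:60]
  tied <- ifelse(dirs %in% c("L", "R"), rep(c(9, 11), 30), rep(c(4, 6), 30))
  r2 <- determine_pd(tied, dirs)
  expect_lte(r2$anova_p, 0.05)
  expect_false(r2$has_pd)
  expect_error(determine_pd(counts[dirs != "L"], dirs[dirs != "L"]), "direction")
})

test_that("neuron typing follows the visual/movement truth table", {
  s <- fixture("typing_session", function() {
    specs <- list(vis = neuron_spec("hemifield_spatial", pd_direction = "R",
                                    vis_gain = 2, mov_gain = 0, kappa = 0,
                                    hemi_gain = 1),
                  mov = neuron_spec("movement"),
                  both = neuron_spec("hemifield_spatial", pd_direction = "R",
                                     vis_gain = 2, mov_gain = 30, kappa = 0,
                                     hemi_gain = 1))
    generate_session(synthetic_config(neurons = specs, n_choice_blocks = 0,
                                      n_delayed_blocks = 20,
                                      generate_eyes = FALSE, master_seed = 55))
  })
  del <- select_trials(s, task = "delayed")
  expect_equal(classify_neuron_type(s$spikes[["vis"]]$spike_times_s, del)$type,
               "visual")
  expect_equal(classify_neuron_type(s$spikes[["mov"]]$spike_times_s, del)$type,
               "movement")
  expect_equal(classify_neuron_type(s$spikes[["both"]]$spike_times_s, del)$type,
               "visuomovement")
  # a silent neuron is none by the all-zero convention
  expect_equal(classify_neuron_type(numeric(0), del)$type, "none")
})

test_that("null neurons are typed none at about the nominal rate", {
  s <- fixture("null_typing_session", function()
    generate_session(synthetic_config(neurons = neuron_cohort(20, "null"),
                                      n_choice_blocks = 0, n_delayed_blocks = 20,
                                      generate_eyes = FALSE, master_seed = 56)))
  del <- select_trials(s, task = "delayed")
  types <- vapply(s$spikes, function(st)
    classify_neuron_type(st$spike_times_s, del)$type, "")
  expect_gte(sum(types == "none"), 15)  # ~90% expected at alpha 0.05 per test
})

test_that("PD condition labels map hemifields correctly", {
  trials <- rbind(make_trial(0L, cue_id = "L1"),
                  make_trial(1L, cue_id = "R1", t0 = 30),
                  make_trial(2L, task = "delayed", t0 = 50, target_direction = "LU"),
                  make_trial(3L, task = "delayed", t0 = 70, target_direction = "RD"))
  pd <- list(has_pd = TRUE, pd_direction = "LU")
  lab <- pd_condition_labels(trials, pd)
  expect_equal(lab, c("pd_included", "pd_opposite", "pd", "anti_pd"))
  # bijection flip under hemifield swap
  pd_r <- list(has_pd = TRUE, pd_direction = "R")
  lab_r <- pd_condition_labels(trials[1:2, ], pd_r)
  expect_equal(lab_r, c("pd_opposite", "pd_included"))
  expect_error(pd_condition_labels(trials, list(has_pd = FALSE)), "no PD")
})

test_that("AUC tracks against the shuffle null behave under the null and the alternative", {
  set.seed(37)
  n <- 60
  cond <- rep(c("pd_included", "pd_opposite"), each = n / 2)
  # null: labels carry no information
  null_tracks <- lapply(1:12, function(j) {
    counts <- matrix(rpois(n * 8, 6), n, 8)
    auc_track_with_null(counts, sample(cond), n_perm = 300, seed = j)
  })
  r <- population_auc_test(null_tracks)
  expect_lte(sum(r$sig_fdr), 2)
  null_aucs <- unlist(lapply(null_tracks, function(t) t$auc - t$null_mean))
  expect_lt(abs(mean(null_aucs)), 0.03)
  # alternative: planted condition effect is flagged
  alt_tracks <- lapply(1:12, function(j) {
    counts <- matrix(rpois(n * 8, 6), n, 8) +
      outer(as.numeric(cond == "pd_included"), c(0, 0, 4, 4, 4, 0, 0, 0))
    auc_track_with_null(counts, cond, n_perm = 300, seed = 100 + j)
  })
  r2 <- population_auc_test(alt_tracks)
  expect_true(all(r2$sig_fdr[3:5]))
  expect_false(any(r2$sig_fdr[c(1, 2, 7, 8)]))
  # guard rails
  counts <- matrix(rpois(n * 2, 6), n, 2)
  expect_error(auc_track_with_null(counts, cond, n_perm = 1), "minimum")
  expect_error(auc_track_with_null(counts[1:6, ], cond[c(1:3, 31:33)]), ">= 5")
})

test_that("tuning matrices and PD alignment follow the stated geometry", {
  # deterministic regular train: constant matrix at the train's rate
  trials <- do.call(rbind, lapply(0:5, function(i)
    make_trial(i, task = "delayed", t0 = 20 + 40 * i,
               target_direction = c("LD", "L", "LU", "RU", "R", "RD")[i + 1])))
  spk <- seq(0.005, 260, by = 0.02)  # 50 Hz, offset to avoid edge coincidences
  g <- window_grid("targets_on", -0.4, 0.6, 0.2, 0.01)
  tm <- tuning_matrix(spk, trials, g)
  expect_true(all(abs(tm - 50) < 1e-9))
  # consistency: disjoint 200-ms windows average to the epoch rate
  g2 <- window_grid("targets_on", 0, 0.4001, 0.2, 0.2)
  cnt2 <- tuning_matrix(spk, trials, g2)
  expect_equal(rowMeans(cnt2)[["L"]],
               spike_count(spk, trials$t_targets_on[2], c(0, 0.4)) / 0.4)
  # a missing direction gives an NA row
  tm_na <- tuning_matrix(spk, trials[trials$target_direction != "LU", ], g2)
  expect_true(all(is.na(tm_na["LU", ])))

  # alignment: single neuron with PD = R, identity rotation post-target
  m <- matrix(seq_len(6 * 4), 6, 4, dimnames = list(c("LD", "L", "LU", "RU", "R", "RD"), NULL))
  al <- align_tuning_population(list(n1 = m), c(n1 = "R"), pre_cols = 1:2)
  expect_equal(unname(al$post["0deg", ]), unname(m["R", 3:4]))
  expect_equal(unname(al$post["45deg", ]), unname(m["RU", 3:4]))
  # interpolated Up slot is the mean of the LU and RU rows
  expect_equal(unname(al$post["90deg", ]),
               unname((m["RU", 3:4] + m["LU", 3:4]) / 2))
  # pre-target block: PD hemifield rows first
  expect_equal(unname(al$pre["included_2", ]), unname(m["R", 1:2]))
  expect_equal(unname(al$pre["opposite_2", ]), unname(m["L", 1:2]))
  # two neurons with opposite PDs and mirror tuning average to identical rows
  m2 <- m[c("RU", "R", "RD", "LD", "L", "LU"), ]
  rownames(m2) <- c("LD", "L", "LU", "RU", "R", "RD")
  al2 <- align_tuning_population(list(a = m, b = m2), c(a = "R", b = "L"),
                                 pre_cols = 1:2)
  expect_equal(al2$pre[1:3, ], al$pre[1:3, ])
  expect_message(align_tuning_population(list(a = m, b = m2), c(a = "R", b = NA),
                                         pre_cols = 1:2), "excluded")
})

test_that("the Rayleigh test separates concentrated from balanced directions", {
  expect_lt(rayleigh_uniformity(rep("L", 20))$p, 1e-6)
  balanced <- rep(c("LD", "L", "LU", "RU", "R", "RD"), 10)
  r <- rayleigh_uniformity(balanced)
  expect_equal(r$value, 0, tolerance = 1e-12)
  expect_gt(r$p, 0.99)
  expect_error(rayleigh_uniformity(c("L", "R")), ">= 3")
  # null calibration: rejection rate ~ alpha for uniform draws
  set.seed(41)
  rej <- vapply(1:1000, function(k) {
    rayleigh_uniformity(sample(c("LD", "L", "LU", "RU", "R", "RD"), 60, TRUE))$p <= 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("effect sizes match their textbook closed forms", {
  # two-sample pooled-SD d on a 3-point example
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  sp <- sqrt((var(x) + var(y)) / 2)
  expect_equal(cohens_d(x, y), (2 - 4) / sp)
  # paired d = mean diff / sd diff
  expect_equal(cohens_d(x, y, paired = TRUE), mean(x - y) / sd(x - y))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # eta squared: hand-computed sums of squares for a 2 x 2 design
  df <- data.frame(y = c(1, 2, 5, 6, 2, 3, 9, 10),
                   a = rep(c("u", "v"), each = 4),
                   b = rep(c("p", "p", "q", "q"), 2))
  fit <- stats::aov(y ~ a * b, data = df)
  ss <- stats::anova(fit)[["Sum Sq"]]
  e2 <- eta_squared(fit)
  expect_equal(unname(e2["a"]), ss[1] / sum(ss))
  expect_equal(unname(e2["b"]), ss[2] / sum(ss))
})
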