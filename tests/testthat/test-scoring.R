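test_that("intrusion reports classify to the binary collapse", {
  expect_identical(classifyIntrusion(c("never", "briefly", "often", "frequent")),
                   c(0L, 1L, 1L, 1L))
  expect_identical(classifyIntrusion(NA_character_), NA_integer_)
  expect_error(classifyIntrusion("sometimes"), "unknown")
})

test_that("two-level intrusion proportion matches the hand-enumerated example", {
  # per-repetition counts (8,8,4,4,4,0,0,0,0,0) over 8 items x 10 reps
  tt <- makeTrialTable(c(8, 8, 4, 4, 4, 0, 0, 0, 0, 0))
  ip <- intrusionProportion(tt)
  expect_equal(ip$intrusion_proportion, 0.35)
  expect_equal(ip$n_intrusions, 28L)
  # degenerate endpoints
  expect_equal(intrusionProportion(makeTrialTable(rep(0, 10)))$intrusion_proportion, 0)
  expect_equal(intrusionProportion(makeTrialTable(rep(8, 10)))$intrusion_proportion, 1)
})

test_that("two-level equals flat averaging under balanced valid counts", {
  co <- makeCohort(n_subjects = 4, seed = 3)
  ip <- intrusionProportion(co$behavior$tnt)
  nt <- co$behavior$tnt[co$behavior$tnt$condition == "NoThink", ]
  flat <- aggregate(list(flat = classifyIntrusion(nt$report)),
                    nt[, c("subject", "valence")], mean)
  m <- merge(ip, flat)
  expect_equal(m$intrusion_proportion, m$flat, tolerance = 1e-12)
})

test_that("missing reports drop from numerator and denominator per repetition", {
  tt <- makeTrialTable(c(4, 4))
  tt$report[tt$block == 1][5:8] <- NA  # 4 intrusions / 4 valid in block 1
  ip <- intrusionProportion(tt)
  expect_equal(ip$intrusion_proportion, mean(c(1, 0.5)))
  # a repetition with no valid trial is omitted with a warning
  tt2 <- makeTrialTable(c(4, 4))
  tt2$report[tt2$block == 2] <- NA
  expect_warning(ip2 <- intrusionProportion(tt2), "omitted")
  expect_equal(ip2$intrusion_proportion, 0.5)
})

test_that("scores are invariant to trial order within repetitions", {
  co <- makeCohort(n_subjects = 3, seed = 4)
  tnt <- co$behavior$tnt
  perm <- sample(nrow(tnt))
  a <- intrusionProportion(tnt)
  b <- intrusionProportion(tnt[perm, ])
  expect_equal(a$intrusion_proportion, b$intrusion_proportion)
})

test_that("valence adjustment is the rating/norm ratio", {
  expect_equal(adjustValence(5, 5), 1.0)
  expect_equal(adjustValence(4.5, 5), 0.9)
  expect_equal(adjustValence(2, 2.8), 2 / 2.8)
  expect_error(adjustValence(5, 0), "positive")
})

test_that("MAD scale matches the hand formula and calibrates to sigma", {
  expect_equal(madScale(c(3, 3, 3, 3)), 0)
  expect_equal(madScale(c(1, 2, 3, 4, 5)), 1.4826)
  set.seed(8)
  expect_equal(madScale(rnorm(20000)), 1, tolerance = 0.05)
  expect_error(madScale(numeric()), "finite")
})

test_that("MAD trimming follows the 2-MAD rule with a zero-MAD guard", {
  tr <- trimOutliers(c(10, 11, 12, 11, 100))
  expect_equal(tr$rejected_idx, 5L)
  expect_equal(tr$kept, c(10, 11, 12, 11))
  expect_length(trimOutliers(c(5, 5.1, 4.9, 5, 5.05))$rejected_idx, 0)
  expect_length(trimOutliers(rep(7, 6))$rejected_idx, 0)  # MAD = 0 guard
})

test_that("trimming semantics are a single pass", {
  x <- c(1, 1.1, 0.9, 1, 1.05, 3, 2.2)
  once <- trimOutliers(x)
  twice <- trimOutliers(once$kept)
  # documented single-pass semantics: a second pass may remove more; the
  # exported operation applies exactly one pass
  expect_true(length(once$rejected_idx) >= 1)
  expect_identical(trimOutliers(x)$kept, once$kept)
  expect_true(is.list(twice))
})

test_that("affect suppression is the No-Think minus Baseline adjusted mean", {
  f <- expand.grid(subject = 1, valence = "negative",
                   condition = c("NoThink", "Baseline"), item = 1:4,
                   stringsAsFactors = FALSE)
  f$norm <- 4
  f$rating <- NA_real_
  f$rating[f$condition == "NoThink"] <- c(3, 4, 3, 4)
  f$rating[f$condition == "Baseline"] <- 3
  af <- affectSuppression(f, trim = FALSE)
  expect_equal(af$affect_suppression, mean(c(3, 4, 3, 4) / 4) - 0.75)
  # identical sets give zero
  f$rating <- 3
  expect_equal(affectSuppression(f, trim = FALSE)$affect_suppression, 0)
})

test_that("planted positive affect effect shows up in the high-control half", {
  co <- makeCohort(n_subjects = 60, seed = 5,
                   truth = cohortTruth(planted_rho_negative = -0.7))
  sc <- scoreSubjects(co$behavior)
  neg <- sc[sc$valence == "negative", ]
  grp <- splitByControl(neg[, c("subject", "intrusion_proportion")])
  hi <- neg$affect_suppression[grp$group == "high_control"]
  lo <- neg$affect_suppression[grp$group == "low_control"]
  expect_gt(mean(hi), 0)
  expect_gt(mean(hi), mean(lo))
})

test_that("RT suppression recovers a planted slowing", {
  co <- makeCohort(n_subjects = 200, seed = 6,
                   truth = cohortTruth(rt_slowing_ms = c(negative = 100,
                                                         neutral = 0)))
  rt <- rtSuppression(co$behavior$final)
  m <- tapply(rt$rt_suppression, rt$valence, mean)
  expect_gt(m["negative"], 80)
  expect_lt(m["negative"], 120)
  expect_lt(abs(m["neutral"]), 40)
  # simple arithmetic on equal sets
  f <- expand.grid(subject = 1, valence = "neutral",
                   condition = c("NoThink", "Baseline"), item = 1:3,
                   stringsAsFactors = FALSE)
  f$rt_ms <- ifelse(f$condition == "NoThink", 1573, 1442)
  expect_equal(rtSuppression(f, trim = FALSE)$rt_suppression, 131)
})

test_that("median split is deterministic with identifier tie-breaking", {
  sc <- data.frame(subject = 1:22, intrusion_proportion = runif(22))
  sp <- splitByControl(sc)
  expect_equal(sum(sp$group == "high_control"), 11)
  expect_true(max(sp$intrusion_proportion[sp$group == "high_control"]) <
                min(sp$intrusion_proportion[sp$group == "low_control"]))
  tied <- data.frame(subject = 1:6, intrusion_proportion = 0.5)
  expect_message(sp2 <- splitByControl(tied), "identifier")
  expect_identical(sp2$group,
                   rep(c("high_control", "low_control"), each = 3))
})

test_that("low-intrusion exclusion matches the 5% rule", {
  co <- makeCohort(n_subjects = 6, seed = 7)
  tnt <- co$behavior$tnt
  # force subjects 1 and 2 to have (almost) no negative intrusions
  idx <- tnt$subject %in% 1:2 & tnt$condition == "NoThink" &
    tnt$valence == "negative"
  tnt$report[idx] <- "never"
  sc <- scoreSubjects(list(tnt = tnt, final = co$behavior$final))
  expect_message(ex <- excludeLowIntrusion(sc, min_trials = 4), "excluded")
  expect_identical(sort(ex$excluded), c(1L, 2L))
  expect_equal(length(ex$kept), 4)
})
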