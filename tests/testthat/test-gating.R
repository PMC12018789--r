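# Gating cascade: label conservation, recall against ground truth,
# idempotence, summaries, modal size.

test_that("labels partition every gallery exactly", {
  f <- mixed_features()
  ga <- apply_gates(f)
  expect_equal(nrow(ga), nrow(f))
  expect_setequal(ga$object_id, f$object_id)
  expect_true(all(ga$label %in%
                    c("debris", "multiple", "cropped", "outlier", "hq_single")))
  expect_equal(sum(table(ga$label)), nrow(f))
})

test_that("gates recover debris, doublets and cropped objects from truth", {
  f <- mixed_features()
  ga <- apply_gates(f)
  tr <- merge(ga, mixed_gallery()$truth, by = "object_id")
  deb <- tr$shape_class == "debris"
  expect_gte(mean(tr$label[deb] == "debris"), 0.90)
  pollen <- tr$shape_class %in% c("spheroid", "oblate_polar")
  expect_lte(mean(tr$label[pollen] == "debris"), 0.05)
  expect_gte(mean(tr$label[tr$shape_class == "doublet"] == "multiple"), 0.90)
  expect_true(all(tr$label[tr$shape_class == "cropped"] == "cropped"))
})

test_that("true single pollen end hq_single with accurate mean length", {
  f <- mixed_features()
  ga <- apply_gates(f)
  tr <- merge(ga, mixed_gallery()$truth, by = "object_id")
  single <- tr$shape_class %in% c("spheroid", "oblate_polar")
  expect_gte(mean(tr$label[single] == "hq_single"), 0.90)
  hq <- merge(f, tr[tr$label == "hq_single" & single,
                    c("object_id", "true_length_um")], by = "object_id")
  expect_lt(abs(mean(hq$length_um) - mean(hq$true_length_um)) /
              mean(hq$true_length_um), 0.02)
})

test_that("re-gating the hq_single subset excludes nothing new", {
  f <- mixed_features()
  ga <- apply_gates(f)
  hq <- f[f$object_id %in% ga$object_id[ga$label == "hq_single"], ]
  # replay with the fitted thresholds (clean subsets are unimodal, so the
  # data-driven gates would find no second mode anyway)
  gates <- attr(ga, "gates")
  ga2 <- apply_gates(hq, debris_thresholds = gates$debris,
                     singlet_threshold = gates$singlet)
  expect_true(all(ga2$label == "hq_single"))
})

test_that("manual gate overrides replay exactly", {
  f <- mixed_features()
  sg <- gate_singlets(f, threshold = 10)
  expect_identical(unname(sg == "multiple"),
                   !is.na(f$circularity) & f$circularity < 10)
  deb <- gate_debris(f, thresholds = list(ch01 = 50, ch09 = 50))
  expect_identical(unname(deb == "debris"),
                   !is.na(f$intensity_ch01) & f$intensity_ch01 < 50 &
                     f$intensity_ch09 < 50)
})

test_that("single-channel debris gate matches two-channel on equal channels", {
  f <- mixed_features()
  two <- suppressWarnings(gate_debris(f))
  f1 <- f; f1$intensity_ch09 <- NULL
  one <- suppressWarnings(gate_debris(f1))
  expect_identical(as.character(two), as.character(one))
})

test_that("outlier flag catches oversized masks, skips tiny samples", {
  set.seed(42)
  f <- data.frame(object_id = sprintf("o%02d", 1:30),
                  area_um2 = c(rnorm(29, 400, 15), 2000),
                  elongatedness = rnorm(30, 1.05, 0.03),
                  border_touch = FALSE)
  lab <- flag_quality(f)
  expect_equal(lab[30], "outlier")
  expect_true(all(lab[1:29] == "ok"))
  expect_warning(flag_quality(f[1:5, ]), "fewer than 8")
})

test_that("oblate view sorting recovers at least 95% of true views", {
  ob <- oblate_features()
  v <- sort_views(ob)
  tr <- merge(data.frame(object_id = ob$object_id, view = as.character(v)),
              oblate_gallery()$truth, by = "object_id")
  expect_gte(mean(tr$view == tr$true_view), 0.95)
  # spherical species: unimodal, all polar with a warning
  f <- mixed_features()
  sph <- f[f$object_id %in% mixed_gallery()$truth$object_id[
    mixed_gallery()$truth$shape_class == "spheroid"], ]
  expect_warning(vs <- sort_views(sph), "unimodal")
  expect_true(all(vs == "polar"))
})

test_that("two-level summaries weight individuals equally", {
  f <- data.frame(species_label = "sp", length_um = c(rep(20, 8), rep(24, 2)),
                  individual_label = c(rep("a", 8), rep("b", 2)))
  s <- summarize_sizes(f)
  im <- s[s$level == "individual_means", ]
  expect_equal(im$mean_um, 22.0)       # (20 + 24) / 2, counts ignored
  expect_equal(im$n_individuals, 2)
  expect_equal(im$n_pollen, 10)
  pool <- s[s$level == "pooled_pollen", ]
  expect_equal(pool$mean_um, mean(f$length_um))  # 20.8: unbalanced pooling
  expect_equal(im$sd_um, sd(c(20, 24)))
  one <- summarize_sizes(f[f$individual_label == "a", ])
  expect_true(is.na(one$sd_um[one$level == "individual_means"]))
})

test_that("hand-computed three-individual table separates the two levels", {
  f <- data.frame(species_label = "sp",
                  length_um = c(10, 12, 14, 20, 30),
                  individual_label = c("a", "a", "a", "b", "c"))
  s <- summarize_sizes(f)
  expect_equal(s$mean_um[s$level == "pooled_pollen"], 17.2)
  expect_equal(s$mean_um[s$level == "individual_means"], (12 + 20 + 30) / 3)
})

test_that("generator year effects are recovered from per-year means", {
  g <- cached("betula", render_gallery(
    150, c(spheroid = 1), seed = 301, n_individuals = 3,
    individual_sd_um = 0.5, year_labels = c("y1", "y2"),
    year_effects_um = c(y1 = 0, y2 = 3), size_cv = 0.04))
  tm <- tapply(g$truth$true_length_um, g$truth$year_label, mean)
  expect_equal(unname(tm["y2"] - tm["y1"]), 3, tolerance = 0.25)
})

test_that("modal size uses pixel-width bins with lowest-bin tie break", {
  expect_warning(m <- modal_size(c(rep(10.1, 5), rep(12.1, 5)), 0.5),
                 "fewer than 30")
  expect_equal(m, 10.25)
  set.seed(3)
  x <- rnorm(500, 25, 0.4)
  expect_lt(abs(modal_size(x, 0.5) - mean(x)), 0.5)
})
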