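test_that("generated heads satisfy the labeled-head invariants", {
  gh <- generate_head(head_spec(noise_sd = 0.1, seed = 3))
  lb <- gh$head
  expect_s3_class(lb, "labeled_head")
  expect_length(intersect(lb$regions$auricle_left, lb$regions$auricle_right), 0)
  expect_length(intersect(lb$regions$mastoid_left, lb$regions$auricle_left), 0)
  expect_length(intersect(lb$regions$mastoid_right, lb$regions$auricle_right), 0)
  expect_true(max(unlist(lb$regions)) <= nrow(lb$mesh$vertices))
  expect_gte(length(lb$regions$mastoid_left), 10L)
  # both auricles span faces
  expect_gt(nrow(auricle_submesh(lb, "left")$faces), 100)
  expect_setequal(names(lb$landmarks$left),
                  c("superaurale", "subaurale", "preaurale", "postaurale",
                    "helix_lateral", "mastoid_base", "tragus"))
})

test_that("generation is bit-identical under a fixed seed", {
  g1 <- generate_head(head_spec(noise_sd = 0.2, seed = 11))
  g2 <- generate_head(head_spec(noise_sd = 0.2, seed = 11))
  expect_identical(g1$head$mesh$vertices, g2$head$mesh$vertices)
  g3 <- generate_head(head_spec(noise_sd = 0.2, seed = 12))
  expect_false(identical(g1$head$mesh$vertices, g3$head$mesh$vertices))
})

test_that("landmark geometry encodes the true parameters", {
  ss <- auricle_side_spec(length = 62, width = 32, protrusion = 20,
                          acangle = 30, inclination = 25)
  gh <- generate_head(head_spec(left = ss, right = ss, noise_sd = 0))
  lm <- gh$head$landmarks$left
  expect_equal(sqrt(sum((lm$superaurale - lm$subaurale)^2)), 62,
               tolerance = 1e-9)
  expect_equal(sqrt(sum((lm$preaurale - lm$postaurale)^2)), 32,
               tolerance = 1e-9)
  expect_equal(sqrt(sum((lm$helix_lateral - lm$mastoid_base)^2)), 20,
               tolerance = 1e-9)
})

test_that("cohort generation matches its truth table", {
  co <- generate_cohort(cohort_spec(n = 5, seed = 8, noise_sd = 0))
  expect_length(co$heads, 5)
  expect_equal(nrow(co$truth), 10)
  expect_equal(nrow(co$bilateral_truth), 5)
  # truth rows agree with each head's embedded truth
  t3 <- co$truth[co$truth$subject == 3 & co$truth$side == "left", ]
  expect_equal(t3$length, co$heads[[3]]$truth$left$length)
  # asymmetry magnitudes vary across subjects
  expect_gt(sd(co$bilateral_truth$length), 0)
})

test_that("repeated scans share truth and differ only by noise", {
  reps <- simulate_repeated_scans(head_spec(noise_sd = 0.15), n_repeats = 3,
                                  seed = 44)
  expect_equal(reps[[1]]$truth, reps[[2]]$truth)
  expect_false(identical(reps[[1]]$head$mesh$vertices,
                         reps[[2]]$head$mesh$vertices))
  delta <- reps[[1]]$head$mesh$vertices - reps[[2]]$head$mesh$vertices
  expect_equal(sd(as.vector(delta)), sqrt(2) * 0.15, tolerance = 0.01)
  # zero noise: repeats are identical
  reps0 <- simulate_repeated_scans(head_spec(noise_sd = 0), n_repeats = 2,
                                   seed = 44)
  expect_identical(reps0[[1]]$head$mesh$vertices,
                   reps0[[2]]$head$mesh$vertices)
})

test_that("landmark perturbation has the stated observer noise", {
  lms <- lapply(seq_len(4000), function(i) c(10, 20, 30))
  names(lms) <- paste0("lm", seq_along(lms))
  pert <- perturb_landmarks(lms, observer_sd = 1, seed = 5)
  mat <- do.call(rbind, pert)
  devs <- sweep(mat, 2, c(10, 20, 30))
  expect_equal(apply(devs, 2, sd), c(1, 1, 1), tolerance = 0.03,
               ignore_attr = TRUE)
  expect_lt(abs(cor(devs[, 1], devs[, 2])), 0.05)
  expect_identical(perturb_landmarks(lms, 0, seed = 5), lms)
})

test_that("invalid specs are rejected", {
  expect_error(auricle_side_spec(length = 30, width = 32),
               class = "auriclesym_input_error")
  expect_error(auricle_side_spec(protrusion = 5, width = 32, acangle = 30),
               class = "auriclesym_input_error")
  expect_error(head_spec(noise_sd = -1), class = "auriclesym_input_error")
  expect_error(cohort_spec(n = 0), class = "auriclesym_input_error")
})

test_that("fixture directories are self-contained and re-measurable", {
  gh <- generate_head(head_spec(noise_sd = 0, subdivisions = 3L,
                                ear_edge = 2.5))
  dir <- withr::local_tempdir()
  write_fixture_dir(gh, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "head.ply", "labels.csv", "landmarks_left.csv", "landmarks_right.csv",
    "truth.csv")))))
  mesh <- load_mesh(file.path(dir, "head.ply"))
  regions <- read_labels(file.path(dir, "labels.csv"))
  lb <- labeled_head(mesh, regions)
  expect_equal(nrow(lb$mesh$vertices), nrow(gh$head$mesh$vertices))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$length[truth$side == "left"], gh$truth$left$length)
})
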