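# construct a stack with a known per-frame pattern for one planted object
make_pattern_stack <- function(pattern, size = c(24, 24), px_box = 8:15) {
  nf <- length(pattern)
  stack <- array(0, dim = c(nf, size[1], size[2]))
  for (f in seq_len(nf)) stack[f, px_box, px_box] <- pattern[f]
  stack
}

box_object <- function(size = c(24, 24), px_box = 8:15) {
  m <- matrix(FALSE, size[1], size[2]); m[px_box, px_box] <- TRUE
  list(structure(list(id = 1L, pixels = which(m),
                      centroid = c(row = mean(px_box), col = mean(px_box)),
                      area = sum(m)), class = "segmented_object"))
}

test_that("unmixing features reproduce hand-computed values", {
  obj <- box_object()
  # constant stack: unit features, no loss
  const <- make_pattern_stack(rep(3, 60))
  f <- build_unmix_features(const, obj)
  expect_equal(unlist(f[1, c("f1", "f2", "f3", "loss")]),
               c(f1 = 1, f2 = 1, f3 = 1, loss = 0))
  # group pattern (2a, a, a, a), normalizer decaying 20% first->last
  ngroup <- 15
  a <- seq(1, 0.8, length.out = ngroup)  # mean(first3)=..., linear decay
  pattern <- as.vector(rbind(2 * a, a, a, a))
  f2 <- build_unmix_features(make_pattern_stack(pattern), obj)
  expect_equal(unlist(f2[1, c("f1", "f2", "f3")]),
               c(f1 = 2, f2 = 1, f3 = 1), tolerance = 1e-12)
  early <- mean(a[1:3]); late <- mean(a[13:15])
  expect_equal(f2$loss, (early - late) / early, tolerance = 1e-12)
  # absolute loss mode reports the raw difference
  f2a <- build_unmix_features(make_pattern_stack(pattern), obj,
                              loss_mode = "absolute")
  expect_equal(f2a$loss, early - late, tolerance = 1e-12)
})

test_that("features are invariant under a global gain and frame counts are checked", {
  obj <- box_object()
  pattern <- abs(sin(1:60)) + 0.5
  s1 <- make_pattern_stack(pattern)
  f1 <- build_unmix_features(s1, obj)
  f2 <- build_unmix_features(s1 * 37.5, obj)
  expect_equal(f1[, c("f1", "f2", "f3", "loss")],
               f2[, c("f1", "f2", "f3", "loss")], tolerance = 1e-12)
  expect_error(build_unmix_features(s1[1:59, , ], obj), "not divisible")
  # zero normalizer: flagged invalid with warning
  bad <- make_pattern_stack(c(rep(1, 59), 0))
  expect_warning(fb <- build_unmix_features(bad, obj), "non-positive")
  expect_false(fb$valid)
})

test_that("segmentation finds planted rods and nothing in empty images", {
  img <- matrix(0, 40, 40)
  img[5:10, 5:20] <- 10   # rod 1
  img[25:30, 18:34] <- 8  # rod 2
  objs <- segment(img)
  expect_length(objs, 2)
  expect_length(segment(matrix(0, 32, 32)), 0)
  # diagonal-touching pixels belong to one 8-connected object
  di <- matrix(0, 20, 20)
  for (i in 1:10) di[i + 4, i + 4] <- 10
  expect_length(segment(di, min_area = 5), 1)
})

test_that("segmentation recovers generator ground truth with sub-pixel centroids", {
  cls <- list(A = rsegfp2_params())
  scene <- scene_spec(size = c(96, 96), n_per_class = 10, class_params = cls)
  g <- gen_multiplex_stack(scene, noise = noise_spec(scale = 200,
                                                     read_sd = 2, seed = 3))
  objs <- segment(apply(g$stack, c(2, 3), mean))
  expect_gte(length(objs), ceiling(0.95 * nrow(g$labels)))
  # match each found object to the nearest planted centroid
  truth_cent <- t(vapply(sort(unique(as.vector(g$label_mask[g$label_mask > 0]))),
                         function(id) {
    rc <- arrayInd(which(g$label_mask == id), dim(g$label_mask))
    c(mean(rc[, 1]), mean(rc[, 2]))
  }, numeric(2)))
  for (ob in objs) {
    d <- sqrt(colSums((t(truth_cent) - ob$centroid)^2))
    expect_lte(min(d), 1)
  }
})

test_that("segmentation is idempotent on its own label mask", {
  img <- matrix(0, 40, 40)
  img[5:10, 5:20] <- 10
  img[25:30, 18:34] <- 8
  objs <- segment(img)
  mask <- attr(objs, "labels")
  objs2 <- segment(1.0 * (mask > 0), min_area = 1)
  expect_length(objs2, length(objs))
  pix1 <- lapply(objs, `[[`, "pixels")
  pix2 <- lapply(objs2, `[[`, "pixels")
  expect_setequal(vapply(pix1, paste, "", collapse = ","),
                  vapply(pix2, paste, "", collapse = ","))
})

test_that("class training recovers generative means and separable mixtures classify perfectly", {
  set.seed(11)
  mk <- function(mu, n = 60, sd = 0.01)
    data.frame(f1 = stats::rnorm(n, mu[1], sd), f2 = stats::rnorm(n, mu[2], sd),
               f3 = stats::rnorm(n, mu[3], sd), loss = stats::rnorm(n, mu[4], sd))
  mus <- list(A = c(1, 1, 1, 0.1), B = c(2, 1, 1, 0.4),
              C = c(1, 2, 1, 0.25), D = c(1, 1, 2, 0.55))
  feats <- do.call(rbind, lapply(mus, mk))
  labels <- rep(names(mus), each = 60)
  model <- train_classes(feats, labels)
  for (cl in names(mus)) {
    se <- 0.01 / sqrt(60)
    expect_true(all(abs(model$components[[cl]]$mean - mus[[cl]]) < 3.5 * se))
  }
  expect_equal(sum(vapply(model$components, `[[`, 0, "weight")), 1)
  # >= 10 sigma separation: perfect accuracy, identity confusion matrix
  cls <- classify(feats, model)
  cm <- confusion(labels, cls$label)
  expect_equal(accuracy(cm), 1)
  expect_equal(unname(cm), diag(60, 4), ignore_attr = TRUE)
  expect_equal(sum(cm), nrow(feats))
  # posteriors: certain at a class mean, split halfway between two classes
  at_mean <- classify(data.frame(f1 = 2, f2 = 1, f3 = 1, loss = 0.4), model)
  expect_equal(at_mean$label, "B")
  expect_gt(at_mean$B, 0.99)
  expect_true(all(abs(rowSums(cls[, names(mus)]) - 1) < 1e-12))
})

test_that("posterior is symmetric for an equidistant object", {
  nm <- c("f1", "f2", "f3", "loss")
  comp <- function(mu) list(mean = stats::setNames(mu, nm),
                            cov = diag(0.01, 4), weight = 0.5)
  model <- structure(list(components = list(A = comp(c(1, 1, 1, 0.2)),
                                            B = comp(c(3, 1, 1, 0.2))),
                          classes = c("A", "B"), covariance = "diagonal"),
                     class = "class_model")
  mid <- classify(data.frame(f1 = 2, f2 = 1, f3 = 1, loss = 0.2), model)
  expect_equal(mid$A, 0.5, tolerance = 1e-12)
  expect_equal(mid$B, 0.5, tolerance = 1e-12)
})

test_that("training enforces class sizes and dimension checks are strict", {
  feats <- data.frame(f1 = stats::rnorm(15), f2 = stats::rnorm(15),
                      f3 = stats::rnorm(15), loss = stats::rnorm(15))
  expect_error(train_classes(feats, c(rep("A", 12), rep("B", 3))),
               "fewer than")
  model <- train_classes(rbind(feats, feats + 5),
                         rep(c("A", "B"), each = 15))
  expect_error(classify(data.frame(f1 = 1, f2 = 1), model))
})

test_that("single-class training yields one component with unit weight", {
  set.seed(4)
  feats <- data.frame(f1 = stats::rnorm(20, 1, 0.1), f2 = stats::rnorm(20, 1, 0.1),
                      f3 = stats::rnorm(20, 1, 0.1), loss = stats::rnorm(20, 0.2, 0.02))
  model <- train_classes(feats, rep("only", 20))
  expect_length(model$components, 1)
  expect_equal(model$components$only$weight, 1)
})

test_that("accuracy degrades gracefully as class separation shrinks", {
  seps <- c(6, 2, 1, 0.4)
  acc <- matrix(NA_real_, 20, length(seps))
  for (s in 1:20) {
    set.seed(1000 + s)
    for (j in seq_along(seps)) {
      n <- 40; sd <- 0.1
      f <- data.frame(f1 = c(stats::rnorm(n, 1, sd),
                             stats::rnorm(n, 1 + seps[j] * sd, sd)),
                      f2 = stats::rnorm(2 * n, 1, sd),
                      f3 = stats::rnorm(2 * n, 1, sd),
                      loss = stats::rnorm(2 * n, 0.3, sd))
      lab <- rep(c("A", "B"), each = n)
      model <- train_classes(f, lab)
      acc[s, j] <- accuracy(confusion(lab, classify(f, model)$label))
    }
  }
  m <- colMeans(acc)
  expect_true(all(diff(m) < 0.02))  # monotone within sampling error
  expect_gt(m[1], 0.99)
  expect_lt(m[4], 0.8)
})

test_that("off-switching-rate classification separates a two-rate mixture", {
  cls <- list(slowP = variant_params("rsGreen1"),
              fastP = variant_params("rsGreenF"))
  scene <- scene_spec(size = c(96, 96), n_per_class = 10, class_params = cls)
  g <- gen_decay_stack(scene, noise = noise_spec(scale = 200, read_sd = 2,
                                                 seed = 11))
  objs <- segment(apply(g$stack[1:5, , , drop = FALSE], c(2, 3), mean))
  oc <- offswitch_classify(g$stack, objs)
  truth <- truth_labels(objs, g$label_mask, g$labels)
  got <- ifelse(oc$label == "slow", "slowP", "fastP")
  expect_gte(mean(got == truth), 0.99)
  expect_false(attr(oc, "degenerate"))
  # identical populations: degenerate flag raised
  one <- scene_spec(size = c(96, 96), n_per_class = 12,
                    class_params = cls["slowP"])
  g1 <- gen_decay_stack(one, noise = noise_spec(scale = 200, read_sd = 2,
                                                seed = 12))
  objs1 <- segment(apply(g1$stack[1:5, , , drop = FALSE], c(2, 3), mean))
  oc1 <- offswitch_classify(g1$stack, objs1)
  expect_true(attr(oc1, "degenerate"))
})

test_that("592 nm co-illumination reduces the measured fluorescence loss", {
  cls <- list(slowP = variant_params("rsGreen1"),
              fastP = variant_params("rsGreenF"))
  scene <- scene_spec(size = c(96, 96), n_per_class = 8, class_params = cls)
  ns <- noise_spec(scale = 200, read_sd = 2, seed = 21)
  g0 <- gen_decay_stack(scene, noise = ns)
  g1 <- gen_decay_stack(scene, co592 = 4000, noise = ns)
  objs <- segment(apply(g0$stack[1:5, , , drop = FALSE], c(2, 3), mean))
  l0 <- offswitch_classify(g0$stack, objs)$loss
  l1 <- offswitch_classify(g1$stack, objs)$loss
  expect_lt(stats::median(l1, na.rm = TRUE), stats::median(l0, na.rm = TRUE))
})

test_that("ratiometric images follow their definition and the activation contrast", {
  base <- matrix(0, 30, 30); base[10:20, 10:20] <- 5
  r1 <- ratiometric_image(base, base)
  expect_true(all(abs(r1$values - 1) < 1e-12))
  r2 <- ratiometric_image(base, base * 0.5)
  expect_true(all(abs(r2$values - 2) < 1e-12))
  expect_error(ratiometric_image(matrix(0, 10, 10), matrix(0, 10, 10)),
               "empty foreground")
  # slow (20 ms @ 14 W/cm2) vs fast (0.25 ms @ 1.05 kW/cm2) activation of
  # the calibrated model: same dose region, slow is brighter
  p <- rsegfp2_params()
  t488 <- calibrate_offswitch_time(p, 300)
  img_for <- function(t405, p405) {
    sch <- pulse_scheme(list(time_window(t405, illumination(405, p405)),
                             time_window(t488, illumination(488, 300))))
    tr <- simulate_scheme(p, sch, p0 = population(c(TH = 1)),
                          n_per_window = 2)
    sig <- integrated_fluorescence(tr)
    img <- matrix(0, 30, 30); img[8:22, 8:22] <- sig
    img
  }
  slow <- img_for(20e-3, 14)
  fast <- img_for(0.25e-3, 1050)
  rr <- ratiometric_image(slow, fast)
  expect_gt(mean(rr$values), 1)
})
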