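test_that("class_reference_centroid averages the m nearest bank rows", {
  # 1-D bank {0, 1, 10}, proto 0.4, m = 2 -> neighbors {0, 1}, centroid 0.5
  bank <- matrix(c(0, 1, 10), ncol = 1)
  res <- class_reference_centroid(bank, 0.4, m = 2)
  expect_equal(sort(res$indices), c(1, 2))
  expect_equal(unname(res$centroid), 0.5)

  # m = bank size -> centroid is the bank mean regardless of the prototype
  set.seed(1)
  R <- matrix(rnorm(30), 10, 3)
  for (p in list(rnorm(3), rep(100, 3))) {
    expect_equal(class_reference_centroid(R, p, m = 10)$centroid, colMeans(R))
  }
  # proto equal to one bank row, m = 1 -> that row
  expect_equal(class_reference_centroid(R, R[4, ], m = 1)$centroid, R[4, ])
  expect_equal(class_reference_centroid(R, R[4, ], m = 1)$indices, 4L)

  expect_error(class_reference_centroid(R, rnorm(3), m = 11), "exceeds",
               class = "fascal_validation_error")
  expect_error(class_reference_centroid(R, rnorm(2), m = 2), "dimension",
               class = "fascal_validation_error")

  # exhaustive sort oracle on random instances
  for (seed in 1:10) {
    set.seed(seed)
    R <- matrix(rnorm(40), 20, 2)
    p <- rnorm(2)
    m <- sample(1:20, 1)
    d <- apply(R, 1, function(r) euclidean_distance(r, p))
    want <- colMeans(R[order(d)[1:m], , drop = FALSE])
    expect_equal(class_reference_centroid(R, p, m)$centroid, want)
  }
})

test_that("build_centroids composes the per-class operation", {
  set.seed(2)
  R <- matrix(rnorm(60), 20, 3)
  protos <- matrix(rnorm(12), 4, 3)
  cb <- build_centroids(R, protos, m = 5)
  expect_equal(dim(cb$centroids), c(4, 3))
  for (i in 1:4) {
    expect_equal(cb$centroids[i, ],
                 class_reference_centroid(R, protos[i, ], 5)$centroid)
  }
  # identical prototypes give identical centroids
  same <- build_centroids(R, protos[c(1, 1), ], m = 5)
  expect_equal(same$centroids[1, ], same$centroids[2, ])
  # single class is fine here (the 2-centroid rule applies later)
  one <- build_centroids(R, protos[1, , drop = FALSE], m = 3)
  expect_equal(nrow(one$centroids), 1)
})

test_that("calibration_target interpolates between the two nearest centroids", {
  cent <- matrix(c(0, 4, 10), ncol = 1)
  res <- calibration_target(1, cent, lam = 0.5)
  expect_equal(res$a, 0L)
  expect_equal(res$b, 1L)
  expect_equal(unname(res$target), 2)  # (1-.5)*0 + .5*4

  expect_equal(unname(calibration_target(1, cent, lam = 0)$target), 0)
  expect_equal(unname(calibration_target(1, cent, lam = 1)$target), 4)
  expect_error(calibration_target(1, matrix(0, 1, 1), 0.5), "2 centroids",
               class = "fascal_validation_error")

  # ties on distance resolve toward the lower class index
  tie <- matrix(c(-1, 1, 5), ncol = 1)
  expect_equal(calibration_target(0, tie, lam = 0)$a, 0L)
})

test_that("shift_prototype moves exactly gamma along the unit direction", {
  expect_equal(shift_prototype(c(1, 2), c(5, 5), gamma = 0), c(1, 2))
  expect_equal(shift_prototype(c(1, 2), c(1, 2), gamma = 3), c(1, 2))
  expect_equal(shift_prototype(c(0, 0), c(3, 4), gamma = 1), c(0.6, 0.8))
  # overshooting past T is allowed
  expect_equal(shift_prototype(c(0, 0), c(3, 4), gamma = 10), c(6, 8))
  expect_error(shift_prototype(c(0, NA), c(1, 1), 1), "finite",
               class = "fascal_validation_error")
})

test_that("calibrate_episode reproduces the 1-D hand trace", {
  # support {0, 10}, bank {-1, 1, 9, 11}, m = 2, lambda = 0, gamma = 0.5:
  # centroids c1 = 0, c2 = 10; each prototype's nearest centroid is itself,
  # so T == s and both prototypes stay put.
  ep <- structure(list(
    support_features = matrix(c(0, 10), ncol = 1),
    support_labels = c(0L, 1L),
    query_features = matrix(c(-0.5, 10.5), ncol = 1),
    query_labels = c(0L, 1L)), class = "episode")
  bank <- matrix(c(-1, 1, 9, 11), ncol = 1)
  params <- calibration_params(m = 2, lam = 0, gamma = 0.5)
  cal <- calibrate_episode(ep, bank, params)

  expect_equal(unname(cal$centroids$centroids), matrix(c(0, 10), 2, 1))
  expect_equal(cal$centroids$neighbor_indices[[1]], c(1L, 2L) , ignore_attr = TRUE)
  expect_equal(sort(cal$centroids$neighbor_indices[[2]]), c(3L, 4L))
  expect_equal(cal$provenance[[1]]$a, 0L)
  expect_equal(cal$provenance[[1]]$b, 1L)
  expect_equal(unname(cal$provenance[[1]]$target), 0)
  expect_equal(cal$provenance[[2]]$a, 1L)
  expect_equal(unname(cal$provenance[[2]]$target), 10)
  # T == s for both classes -> no displacement despite gamma > 0
  expect_equal(cal$prototypes, cal$original)
  td <- tidy(cal)
  expect_equal(td$displacement, c(0, 0))

  # with lambda = 1 the target is the OTHER centroid; displacement = gamma
  cal2 <- calibrate_episode(ep, bank, calibration_params(2, lam = 1, gamma = 0.5))
  expect_equal(unname(cal2$prototypes), matrix(c(0.5, 9.5), 2, 1))
  expect_equal(tidy(cal2)$displacement, c(0.5, 0.5))
})

test_that("gamma = 0 calibration is the identity on classification", {
  pair <- make_shift_pair(shift_spec(
    gaussian_class_spec(n_classes = 6, samples_per_class = 20, dim = 8, seed = 3),
    bank_size_per_class = 30))
  for (seed in 1:5) {
    ep <- sample_episode(pair$target, episode_spec(5, 1, 4), seed = seed)
    params0 <- calibration_params(m = 10, lam = 0.5, gamma = 0)
    expect_identical(
      pdfc_classify(ep, pair$reference, params0),
      classify_queries(compute_prototypes(ep), ep$query_features))
    cal <- calibrate_episode(ep, pair$reference, params0)
    expect_identical(cal$prototypes, cal$original)
  }
})

test_that("every calibrated prototype lies exactly gamma from its original", {
  pair <- make_shift_pair(shift_spec(
    gaussian_class_spec(n_classes = 6, samples_per_class = 20, dim = 8, seed = 4),
    bank_size_per_class = 30))
  for (seed in 1:5) {
    ep <- sample_episode(pair$target, episode_spec(4, 3, 4), seed = seed)
    gam <- runif(1, 0.1, 2)
    cal <- calibrate_episode(ep, pair$reference,
                             calibration_params(m = 7, lam = 0.3, gamma = gam))
    disp <- unname(sqrt(rowSums((cal$prototypes - cal$original)^2)))
    moved <- vapply(seq_len(nrow(cal$original)), function(i) {
      sqrt(sum((cal$provenance[[i]]$target - cal$original[i, ])^2)) >= 1e-12
    }, logical(1))
    expect_equal(disp[moved], rep(gam, sum(moved)))
    expect_equal(disp[!moved], rep(0, sum(!moved)))
  }
})

test_that("the whole calibration pipeline is translation equivariant", {
  pair <- make_shift_pair(shift_spec(
    gaussian_class_spec(n_classes = 6, samples_per_class = 20, dim = 5, seed = 5),
    bank_size_per_class = 30))
  params <- calibration_params(m = 8, lam = 0.4, gamma = 0.7)
  ep <- sample_episode(pair$target, episode_spec(4, 2, 4), seed = 9)
  v <- rnorm(5) * 3

  shift_ep <- ep
  shift_ep$support_features <- sweep(ep$support_features, 2, v, "+")
  shift_ep$query_features <- sweep(ep$query_features, 2, v, "+")
  R <- feature_matrix(pair$reference)
  Rv <- sweep(R, 2, v, "+")

  cal <- calibrate_episode(ep, R, params)
  calv <- calibrate_episode(shift_ep, Rv, params)
  expect_equal(calv$centroids$centroids,
               sweep(cal$centroids$centroids, 2, v, "+"))
  expect_equal(calv$prototypes, sweep(cal$prototypes, 2, v, "+"))
  for (i in seq_along(cal$provenance)) {
    expect_equal(calv$provenance[[i]]$target, cal$provenance[[i]]$target + v)
    expect_equal(calv$provenance[[i]]$a, cal$provenance[[i]]$a)
  }
  expect_identical(pdfc_classify(shift_ep, Rv, params),
                   pdfc_classify(ep, R, params))
})

test_that("pdfc_classify agrees with brute-force distances on calibrated prototypes", {
  pair <- make_shift_pair(shift_spec(
    gaussian_class_spec(n_classes = 7, samples_per_class = 20, dim = 6, seed = 6),
    bank_size_per_class = 25))
  params <- calibration_params(m = 6, lam = 0.2, gamma = 0.5)
  for (seed in 1:5) {
    ep <- sample_episode(pair$target, episode_spec(5, 1, 3), seed = seed)
    cal <- calibrate_episode(ep, pair$reference, params)
    expect_equal(pdfc_classify(ep, pair$reference, params),
                 unname(oracle_classify(cal$prototypes, ep$query_features)))
  }
})

test_that("calibration toward the source bank recovers the shifted prototypes", {
  # strong global bias: with lambda = 0 and gamma ~ the distance to the
  # (clean) source centroid, calibrated prototypes approach the true means
  spec <- shift_spec(gaussian_class_spec(n_classes = 6, samples_per_class = 20,
                                         dim = 16, within_scale = 0.05, seed = 7),
                     bank_size_per_class = 80, bias_norm = 1, extra_noise = 0)
  pair <- make_shift_pair(spec)
  mu <- attr(pair$target, "true_means")
  ep <- sample_episode(pair$target, episode_spec(5, 1, 4), seed = 2)
  protos <- compute_prototypes(ep)
  before <- sqrt(rowSums((protos - mu[ep$class_map + 1L, ])^2))
  cal <- calibrate_episode(ep, pair$reference,
                           calibration_params(m = 10, lam = 0, gamma = 1))
  after <- sqrt(rowSums((cal$prototypes - mu[ep$class_map + 1L, ])^2))
  expect_true(all(after < before))
  expect_lt(mean(after), 0.35 * mean(before))
})

test_that("calibration params are validated", {
  expect_error(calibration_params(m = 0), "positive integer",
               class = "fascal_validation_error")
  expect_error(calibration_params(lam = -1), "lam",
               class = "fascal_validation_error")
  expect_error(calibration_params(gamma = Inf), "gamma",
               class = "fascal_validation_error")
})
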