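test_that("episode sampling respects composition, disjointness and determinism", {
  fs <- rand_fs(8, 10, 6, seed = 1)
  spec <- episode_spec(n_way = 4, k_shot = 2, q_per_class = 3)
  for (seed in 1:10) {
    ep <- sample_episode(fs, spec, seed = seed)
    expect_equal(dim(ep$support_features), c(4 * 2, 6))
    expect_equal(dim(ep$query_features), c(4 * 3, 6))
    expect_equal(ep$support_labels, rep(0:3, each = 2))
    expect_equal(ep$query_labels, rep(0:3, each = 3))
    expect_length(unique(ep$class_map), 4)  # bijective remap
    # support and query rows are disjoint samples
    rows <- rbind(ep$support_features, ep$query_features)
    expect_equal(nrow(unique(as.data.frame(rows))), nrow(rows))
  }
  e1 <- sample_episode(fs, spec, seed = 7)
  e2 <- sample_episode(fs, spec, seed = 7)
  expect_identical(e1, e2)

  # forced composition: N classes of exactly K + q samples uses everything
  small <- rand_fs(3, 4, 2, seed = 2)
  ep <- sample_episode(small, episode_spec(3, 1, 3), seed = 1)
  expect_setequal(ep$class_map, 0:2)
  expect_equal(sort(c(ep$support_features[, 1], ep$query_features[, 1])),
               sort(feature_matrix(small)[, 1]))

  expect_error(sample_episode(small, episode_spec(4, 1, 3), seed = 1),
               "classes", class = "fascal_validation_error")
  expect_error(sample_episode(small, episode_spec(3, 2, 3), seed = 1),
               "fewer than", class = "fascal_validation_error")
})

test_that("class selection is uniform across many episodes", {
  fs <- rand_fs(10, 3, 2, seed = 3)
  spec <- episode_spec(n_way = 2, k_shot = 1, q_per_class = 1)
  src <- fascal:::episode_source(fs, spec)
  set.seed(42)
  n_ep <- 4000
  counts <- integer(10)
  for (i in seq_len(n_ep)) {
    idx <- fascal:::sample_episode_idx(src, spec)
    counts[idx$classes] <- counts[idx$classes] + 1L
  }
  p <- 2 / 10
  sigma <- sqrt(n_ep * p * (1 - p))
  expect_true(all(abs(counts - n_ep * p) < 3.5 * sigma))
})

test_that("vector distances satisfy their defining identities", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  }
  expect_error(euclidean_distance(1:2, 1:3), "dimension",
               class = "fascal_validation_error")

  expect_equal(cosine_distance(c(1, 0), c(3, 0)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 2)), 1)
  expect_equal(cosine_distance(c(1, 1), c(-2, -2)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero",
               class = "fascal_validation_error")
})

test_that("prototypes are support means; K = 1 reduces to the support rows", {
  fs <- rand_fs(6, 8, 5, seed = 5)
  ep1 <- sample_episode(fs, episode_spec(5, 1, 2), seed = 1)
  expect_equal(unname(compute_prototypes(ep1)), unname(ep1$support_features))

  ep <- sample_episode(fs, episode_spec(4, 3, 2), seed = 2)
  protos <- compute_prototypes(ep)
  for (k in 0:3) {
    expect_equal(unname(protos[k + 1, ]),
                 unname(colMeans(ep$support_features[ep$support_labels == k, ])))
  }

  two <- structure(list(
    support_features = matrix(c(0, 2, 0, 2), 2, 2),
    support_labels = c(0L, 0L)), class = "episode")
  expect_equal(unname(compute_prototypes(two)), matrix(c(1, 1), 1, 2))
})

test_that("classification matches the brute-force oracle and tie rule", {
  fs <- rand_fs(6, 6, 4, seed = 6)
  for (metric in c("euclidean", "cosine")) {
    for (seed in 1:5) {
      ep <- sample_episode(fs, episode_spec(4, 2, 3), seed = seed)
      protos <- compute_prototypes(ep)
      expect_equal(classify_queries(protos, ep$query_features, metric),
                   unname(oracle_classify(protos, ep$query_features, metric)))
    }
  }
  # query equal to a prototype goes to that class
  protos <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  expect_equal(classify_queries(protos, c(5, 5)), 1L)
  # equidistant query -> smallest class index
  expect_equal(classify_queries(protos, c(2.5, 2.5)), 0L)
  expect_error(classify_queries(protos, c(1, 2, 3)), "dimension",
               class = "fascal_validation_error")
})

test_that("accuracy counts exact matches and is permutation invariant", {
  expect_equal(episode_accuracy(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(episode_accuracy(c(1, 0), c(0, 1)), 0)
  expect_equal(episode_accuracy(c(0, 1, 1, 0), c(0, 1, 0, 0)), 0.75)
  expect_error(episode_accuracy(0:2, 0:1), "length",
               class = "fascal_validation_error")
  set.seed(7)
  pred <- sample(0:3, 30, replace = TRUE)
  truth <- sample(0:3, 30, replace = TRUE)
  perm <- sample(30)
  expect_equal(episode_accuracy(pred[perm], truth[perm]),
               episode_accuracy(pred, truth))
})

test_that("macro metrics reproduce hand-computed confusion patterns", {
  perfect <- macro_metrics(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1))

  # both classes TP=2 FP=1 FN=1 -> precision = recall = f1 = 2/3
  truth <- c(0, 0, 0, 1, 1, 1)
  pred <- c(0, 0, 1, 1, 1, 0)
  mm <- macro_metrics(pred, truth, 2)
  expect_equal(unlist(mm), c(precision = 2/3, recall = 2/3, f1 = 2/3))

  # all wrong on 2 classes: everything is zero
  aw <- macro_metrics(c(1, 0), c(0, 1), 2)
  expect_equal(unlist(aw), c(precision = 0, recall = 0, f1 = 0))

  # a class never predicted contributes 0 to precision
  expect_warning(np <- macro_metrics(c(0, 0, 0), c(0, 0, 1), 2),
                 "zero denominator")
  expect_equal(np$precision, (2/3 + 0) / 2)
  expect_equal(np$recall, (1 + 0) / 2)

  expect_error(macro_metrics(c(0, 5), c(0, 1), 2), "range",
               class = "fascal_validation_error")
})

test_that("run_evaluation is deterministic and exact on separable clusters", {
  fs <- make_gaussian_classes(gaussian_class_spec(
    n_classes = 6, samples_per_class = 20, dim = 8,
    between_scale = 10, within_scale = 0.01, seed = 8))
  spec <- episode_spec(5, 1, 5)
  ev <- run_evaluation(fs, spec, episodes_per_run = 30, runs = 2, seed = 1)
  expect_equal(ev$summary$mean_accuracy, 1)
  expect_equal(ev$summary$macro_f1, 1)

  ev2 <- run_evaluation(fs, spec, episodes_per_run = 30, runs = 2, seed = 1)
  expect_identical(glance(ev), glance(ev2))
  expect_identical(tidy(ev), tidy(ev2))

  # a different seed samples different episodes (visible off the ceiling)
  noisy <- rand_fs(8, 20, 4, seed = 12)
  n1 <- run_evaluation(noisy, spec, episodes_per_run = 30, runs = 1, seed = 1)
  n2 <- run_evaluation(noisy, spec, episodes_per_run = 30, runs = 1, seed = 2)
  expect_false(identical(tidy(n1)$accuracy, tidy(n2)$accuracy))
})

test_that("summary aggregates equal recomputation from the episode log", {
  fs <- rand_fs(8, 20, 6, seed = 9)
  ev <- run_evaluation(fs, episode_spec(4, 2, 5), episodes_per_run = 40,
                       runs = 3, seed = 11)
  log <- tidy(ev)
  expect_equal(nrow(log), 120)
  expect_equal(ev$summary$mean_accuracy, mean(log$accuracy))
  expect_equal(ev$summary$std_accuracy, sd(log$accuracy))
  expect_equal(ev$summary$runs, 3L)
  # pooled confusion totals match the protocol size
  expect_equal(sum(ev$confusion), 120 * 4 * 5)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})

test_that("euclidean K = 1 evaluation equals nearest-neighbor over support rows", {
  fs <- rand_fs(6, 10, 4, seed = 10)
  spec <- episode_spec(4, 1, 3)
  src <- fascal:::episode_source(fs, spec)
  set.seed(fascal:::derive_seed(5, 1))
  for (e in 1:10) {
    idx <- fascal:::sample_episode_idx(src, spec)
    sup <- src$m[idx$support, , drop = FALSE]
    qry <- src$m[idx$query, , drop = FALSE]
    nn <- apply(qry, 1, function(q) {
      which.min(apply(sup, 1, function(s) sqrt(sum((q - s)^2)))) - 1L
    })
    expect_equal(classify_queries(sup, qry), unname(nn))
  }
})
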