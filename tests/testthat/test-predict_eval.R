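## small labeled datasets shared across this file
local_chains <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- setNames(lapply(c(3, 8, 15), function(s)
        prepared_chain(seed = s, n_helices = 3, helix_length = 10,
                       axis_distance = 8.8, n_rows = 50)$pairs),
        paste0("fix", c(3, 8, 15)))
    cache
  }
})

fake_predictions <- function(pairs, scores) {
  p <- tibble::tibble(
    chain_id = pairs$chain_id, helix_a = pairs$helix_a,
    helix_b = pairs$helix_b, seqpos_i = pairs$seqpos_i,
    seqpos_j = pairs$seqpos_j, score = scores)
  ord <- order(-p$score, p$helix_a, p$helix_b, p$seqpos_i, p$seqpos_j)
  p$rank <- integer(nrow(p)); p$rank[ord] <- seq_len(nrow(p))
  structure(p[order(p$rank), ],
            L = attr(pairs, "L"), n_helices = attr(pairs, "n_helices"),
            chain_id = attr(pairs, "chain_id"))
}

test_that("training-set sampling keeps all positives at the 1:4 ratio", {
  feats <- matrix(rnorm(1100 * 3), 1100, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  pairs <- tibble::tibble(features = feats,
                          label_DEF1 = rep(c(TRUE, FALSE), c(100, 1000)))
  cfg <- model_config(seed = 4)
  s <- sample_training_set(pairs, cfg)
  expect_equal(sum(s$label_DEF1), 100L)
  expect_equal(nrow(s), 500L)
  ## deterministic given the seed
  expect_identical(sample_training_set(pairs, cfg), s)
  ## scarce negatives: clamped with a warning
  pairs2 <- pairs[1:400, ]
  expect_warning(s2 <- sample_training_set(pairs2, cfg), "available")
  expect_equal(nrow(s2), 400L)
})

test_that("the forest learns separable synthetic features", {
  set.seed(2)
  n <- 400
  y <- rep(c(TRUE, FALSE), c(80, 320))
  feats <- cbind(sig = ifelse(y, 1, 0) + rnorm(n, sd = 0.1),
                 noise = rnorm(n))
  pairs <- tibble::tibble(chain_id = "toy", helix_a = 1L, helix_b = 2L,
                          seqpos_i = seq_len(n), seqpos_j = seq_len(n) + n,
                          features = feats, label_DEF1 = y)
  cfg <- model_config(seed = 5)
  model <- tm_train(sample_training_set(pairs, cfg), cfg)
  pred <- predict(model, pairs)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  truth <- y[match(pred$seqpos_i, pairs$seqpos_i)]
  expect_gte(mean((pred$score > 0.5) == truth), 0.95)
})

test_that("persisting a model preserves its predictions", {
  chains <- local_chains()
  cfg <- model_config(definition = "DEF2", seed = 7)
  model <- tm_train(sample_training_set(chains[[1]], cfg), cfg)
  p1 <- predict(model, chains[[2]])
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, f)
  p2 <- predict(readRDS(f), chains[[2]])
  expect_equal(p1$score, p2$score)
  expect_error(tm_train(dplyr::filter(chains[[1]], label_DEF2), cfg),
               "single class")
})

test_that("jackknife holds each chain out and scores all its pairs", {
  chains <- local_chains()
  cfg <- model_config(definition = "DEF2", n_trees = 30, seed = 3)
  preds <- jackknife(chains, cfg)
  expect_length(preds, 3L)
  for (k in seq_along(chains)) {
    expect_equal(nrow(preds[[k]]), nrow(chains[[k]]))
    ## all predictions belong to the held-out chain only
    expect_setequal(unique(preds[[k]]$chain_id), unique(chains[[k]]$chain_id))
    expect_setequal(preds[[k]]$rank, seq_len(nrow(chains[[k]])))
  }
  expect_error(jackknife(chains[1], cfg), "at least 2")
})

test_that("top-k ranking floors L/divisor with a minimum of one", {
  pairs <- local_chains()[[1]]
  p <- fake_predictions(pairs, seq_len(nrow(pairs)) / nrow(pairs))
  expect_equal(nrow(top_k_contacts(p, divisor = 5, L = 35)), 7L)
  expect_equal(nrow(top_k_contacts(p, divisor = 5, L = 33)), 6L)
  expect_equal(nrow(top_k_contacts(p, divisor = 5, L = 2)), 1L)
  expect_lte(nrow(top_k_contacts(p, divisor = 1, L = 10 * nrow(pairs))),
             nrow(pairs))
})

test_that("contact metrics handle exact hits, delta hits and misses", {
  obs <- tibble::tibble(helix_a = 1L, helix_b = 2L,
                        seqpos_i = c(5L, 9L), seqpos_j = c(30L, 44L),
                        distance = 5)
  cm <- structure(list(contacts = obs), class = "tm_contact_map")
  ## predicted == observed
  m <- contact_metrics(obs, cm)
  expect_equal(m$accuracy, 1); expect_equal(m$coverage, 1)
  expect_equal(m$delta_accuracy, 1)
  ## offset (3,3): only a delta hit
  off <- dplyr::mutate(obs[1, ], seqpos_i = seqpos_i + 3,
                       seqpos_j = seqpos_j + 3)
  m2 <- contact_metrics(off, cm, delta = 4)
  expect_equal(m2$accuracy, 0); expect_equal(m2$delta_accuracy, 1)
  ## offset (5,0): outside the delta interval
  off2 <- dplyr::mutate(obs[1, ], seqpos_i = seqpos_i + 5)
  expect_equal(contact_metrics(off2, cm, delta = 4)$delta_accuracy, 0)
  ## no observed contacts: coverage undefined
  cm0 <- structure(list(contacts = obs[0, ]), class = "tm_contact_map")
  expect_true(is.na(contact_metrics(obs, cm0)$coverage))
})

test_that("perfect ranking yields a unit PR curve; duplication is neutral", {
  ch <- prepared_chain(seed = 8, n_helices = 2, helix_length = 8,
                       axis_distance = 8)
  pairs <- ch$pairs
  cm <- ch$contact_maps$DEF2
  scores <- ifelse(pairs$label_DEF2, 0.9, 0.1) +
    runif(nrow(pairs), 0, 0.05)
  p <- fake_predictions(pairs, scores)
  pr1 <- averaged_pr_curve(list(p), list(cm))
  expect_equal(pr1$precision, rep(1, nrow(pr1)), tolerance = 1e-12)
  expect_equal(attr(pr1, "auprc"), 1)
  pr2 <- averaged_pr_curve(list(p, p), list(cm, cm))
  expect_equal(pr2$precision, pr1$precision)
  expect_error(averaged_pr_curve(list(p), list(cm), recall_grid = numeric(0)),
               "empty")
})

test_that("random scores produce precision near the contact prevalence", {
  ch <- prepared_chain(seed = 5, n_helices = 4, helix_length = 12,
                       axis_distance = 10.2)
  pairs <- ch$pairs
  cm <- ch$contact_maps$DEF2
  rho <- mean(pairs$label_DEF2)
  set.seed(99)
  aucs <- replicate(60, {
    p <- fake_predictions(pairs, runif(nrow(pairs)))
    attr(averaged_pr_curve(list(p), list(cm)), "auprc")
  })
  ## small upward bias at low recall is expected; the mean stays close to
  ## the prevalence line
  expect_lt(abs(mean(aucs) - rho), 0.35 * rho)
})

test_that("helix interaction metrics count confusion over all helix pairs", {
  ## a pentagon bundle: adjacent helices interact, diagonals do not
  ch <- prepared_chain(seed = 5, n_helices = 5, helix_length = 12,
                       axis_distance = 10.2)
  pairs <- ch$pairs; cm <- ch$contact_maps$DEF2
  ## perfect scores -> top list dominated by real contacts
  p <- fake_predictions(pairs, ifelse(pairs$label_DEF2, 1, 0))
  hm <- helix_interaction_metrics(list(p), list(cm))
  expect_equal(hm$per_chain$fp, 0L)
  expect_gte(hm$per_chain$mcc, 0)
  ## scores concentrated on one non-interacting helix pair -> sensitivity 0
  non_int <- dplyr::anti_join(
    tibble::tibble(helix_a = utils::combn(5, 2)[1, ],
                   helix_b = utils::combn(5, 2)[2, ]),
    cm$interacting, by = c("helix_a", "helix_b"))
  stopifnot(nrow(non_int) > 0)
  bad <- as.numeric(pairs$helix_a == non_int$helix_a[1] &
                      pairs$helix_b == non_int$helix_b[1])
  p_bad <- fake_predictions(pairs, bad)
  hm_bad <- helix_interaction_metrics(list(p_bad), list(cm))
  expect_equal(hm_bad$per_chain$sensitivity, 0)
})

test_that("the MCC formula matches brute-force arithmetic", {
  expect_equal(tmcontact:::mcc_score(2, 1, 6, 1), oracle_mcc(2, 1, 6, 1))
  expect_equal(oracle_mcc(2, 1, 6, 1),
               (2 * 6 - 1 * 1) / sqrt((2 + 1) * (2 + 1) * (6 + 1) * (6 + 1)))
  expect_equal(tmcontact:::mcc_score(3, 0, 5, 0), 1)
  expect_equal(tmcontact:::mcc_score(0, 0, 5, 2), 0)  # degenerate factor
})

test_that("model tidiers expose importance and fit summaries", {
  chains <- local_chains()
  cfg <- model_config(definition = "DEF2", n_trees = 20, seed = 2)
  model <- tm_train(sample_training_set(chains[[1]], cfg), cfg)
  td <- tidy(model)
  expect_true(all(c("feature", "importance") %in% names(td)))
  expect_equal(nrow(td), 408L)
  g <- glance(model)
  expect_equal(g$n_trees, 20)
  expect_true(g$oob_error >= 0 && g$oob_error <= 1)
})
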