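#' Random-forest model configuration
#'
#' Bundles the training hyper-parameters: 100 trees, `m_try = floor(sqrt(M))`
#' candidate features per split (M = feature count), a 1:4
#' contact:non-contact sampling ratio, the contact definition the labels
#' come from, and the feature mode (all 408 features or a CFS-selected
#' subset).
#'
#' @param n_trees Number of trees (default 100).
#' @param m_try Features tried per split; default `floor(sqrt(M))` at fit
#'   time.
#' @param negative_ratio Non-contacts sampled per contact (default 4).
#' @param definition `"DEF1"` or `"DEF2"`.
#' @param feature_mode `"all"` or `"cfs_selected"`.
#' @param features Feature indices or names when `feature_mode =
#'   "cfs_selected"` (e.g. the `union` of a [select_features()] result).
#' @param seed Integer seed for sampling and tree growth.
#' @return A `tm_model_config` list.
#' @export
model_config <- function(n_trees = 100, m_try = NULL, negative_ratio = 4,
                         definition = c("DEF1", "DEF2"),
                         feature_mode = c("all", "cfs_selected"),
                         features = NULL, seed = 1) {
  stopifnot(n_trees >= 1, negative_ratio > 0)
  feature_mode <- match.arg(feature_mode)
  if (feature_mode == "cfs_selected" && is.null(features))
    abort("feature_mode = 'cfs_selected' needs `features`")
  structure(list(n_trees = n_trees, m_try = m_try,
                 negative_ratio = negative_ratio,
                 definition = match.arg(definition),
                 feature_mode = feature_mode, features = features,
                 seed = seed),
            class = "tm_model_config")
}

label_col <- function(cfg) paste0("label_", cfg$definition)

feature_matrix <- function(pairs, cfg) {
  X <- pairs$features
  if (cfg$feature_mode == "cfs_selected") X <- X[, cfg$features, drop = FALSE]
  X
}

#' Class-balanced sampling of a training set
#'
#' Keeps every contact pair and samples `negative_ratio` times as many
#' non-contact pairs without replacement (all of them, with a warning, when
#' fewer exist).
#'
#' @param pairs A labeled `tm_pairs` dataset.
#' @param cfg A [model_config()].
#' @return The sampled subset of `pairs`.
#' @export
sample_training_set <- function(pairs, cfg) {
  y <- pairs[[label_col(cfg)]]
  if (is.null(y)) abort(sprintf("no %s column", label_col(cfg)))
  pos <- which(y); neg <- which(!y)
  if (length(pos) == 0L) abort("no positive (contact) pairs to train on")
  want <- round(cfg$negative_ratio * length(pos))
  set.seed(cfg$seed)
  if (length(neg) < want) {
    warn(sprintf("only %d non-contacts available for %d requested",
                 length(neg), want))
    take <- neg
  } else take <- sample(neg, want)
  pairs[sort(c(pos, take)), , drop = FALSE]
}

#' Train the random-forest contact classifier
#'
#' Fits a `randomForest` classifier on the dataset's feature matrix with the
#' configured number of trees and `m_try`. The prediction score of a pair is
#' the fraction of trees voting "contact".
#'
#' @param pairs A labeled (typically [sample_training_set()]-balanced)
#'   `tm_pairs` dataset.
#' @param cfg A [model_config()].
#' @return A `tmhhcp_model` wrapping the forest, the config and the feature
#'   names.
#' @export
tm_train <- function(pairs, cfg) {
  y <- pairs[[label_col(cfg)]]
  if (is.null(y)) abort(sprintf("no %s column", label_col(cfg)))
  if (length(unique(y)) < 2L)
    abort("training data contains a single class")
  X <- feature_matrix(pairs, cfg)
  yf <- factor(ifelse(y, "contact", "noncontact"),
               levels = c("noncontact", "contact"))
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(
    x = X, y = yf, ntree = cfg$n_trees,
    mtry = cfg$m_try %||% max(1L, floor(sqrt(ncol(X)))))
  structure(list(forest = rf, config = cfg, feature_names = colnames(X)),
            class = "tmhhcp_model")
}

#' @export
print.tmhhcp_model <- function(x, ...) {
  cat(sprintf("<tmhhcp_model> %s, %d trees, %d features (%s)\n",
              x$config$definition, x$config$n_trees,
              length(x$feature_names), x$config$feature_mode))
  invisible(x)
}

#' Score candidate pairs with a trained model
#'
#' @param object A `tmhhcp_model`.
#' @param pairs A `tm_pairs` dataset of candidate pairs.
#' @param ... Unused.
#' @return A `tm_predictions` tibble: the pair identifiers plus `score`
#'   (fraction of trees voting contact) and `rank` (descending score, ties
#'   broken by helix pair then positions). Attributes `L`, `n_helices`,
#'   `chain_id` are carried over.
#' @export
predict.tmhhcp_model <- function(object, pairs, ...) {
  X <- feature_matrix(pairs, object$config)
  score <- predict(object$forest, X, type = "prob")[, "contact"]
  out <- tibble(
    chain_id = pairs$chain_id, helix_a = pairs$helix_a,
    helix_b = pairs$helix_b, seqpos_i = pairs$seqpos_i,
    seqpos_j = pairs$seqpos_j, score = as.numeric(score))
  ord <- order(-out$score, out$helix_a, out$helix_b,
               out$seqpos_i, out$seqpos_j)
  out$rank <- integer(nrow(out)); out$rank[ord] <- seq_len(nrow(out))
  out <- out[order(out$rank), , drop = FALSE]
  structure(out, class = c("tm_predictions", class(tibble())),
            L = attr(pairs, "L"), n_helices = attr(pairs, "n_helices"),
            chain_id = attr(pairs, "chain_id"))
}

#' Leave-one-protein-out cross-validation
#'
#' For each chain, trains a model on the class-balanced sample of all pairs
#' of the remaining chains and scores every candidate pair of the held-out
#' chain. Per-fold sampling is reseeded deterministically from `cfg$seed`
#' plus the fold index, so runs are reproducible.
#'
#' @param datasets Named list of labeled `tm_pairs`, one per chain.
#' @param cfg A [model_config()].
#' @return Named list of `tm_predictions`, one per chain.
#' @export
jackknife <- function(datasets, cfg) {
  if (length(datasets) < 2L) abort("jackknife needs at least 2 chains")
  nm <- names(datasets) %||% paste0("chain", seq_along(datasets))
  out <- vector("list", length(datasets))
  for (f in seq_along(datasets)) {
    pool <- dplyr::bind_rows(lapply(datasets[-f], as_tibble))
    ## bind_rows drops dimnames of matrix columns
    colnames(pool$features) <- colnames(datasets[[f]]$features)
    fold_cfg <- cfg; fold_cfg$seed <- cfg$seed + f
    train_set <- sample_training_set(pool, fold_cfg)
    model <- tm_train(train_set, fold_cfg)
    held <- datasets[[f]]
    out[[f]] <- predict(model, held)
  }
  setNames(out, nm)
}

#' Top-k predicted contacts of one chain
#'
#' Ranks the `k = max(1, floor(L/divisor))` highest-scoring pairs as
#' predicted contacts, where `L` is the chain's total TM segment length and
#' the divisor is 5, 2 or 1 for the top L/5, L/2 and L lists.
#'
#' @param pred A `tm_predictions` tibble.
#' @param divisor 5, 2 or 1 (or any positive number).
#' @param L Total TM length; defaults to the `L` attribute of `pred`.
#' @return The top-k rows of `pred`.
#' @export
top_k_contacts <- function(pred, divisor = 5, L = attr(pred, "L")) {
  if (is.null(L)) abort("L is unknown; pass it explicitly")
  k <- max(1L, floor(L / divisor))
  pred[pred$rank <= k, , drop = FALSE]
}

pair_key <- function(i, j) paste(i, j)

#' Contact-level accuracy, coverage and delta-accuracy
#'
#' `accuracy` is the fraction of predicted pairs that are observed contacts;
#' `coverage` the fraction of observed contacts that were predicted
#' (undefined -- `NA` -- when the chain has no observed contact);
#' `delta_accuracy` the fraction of predicted pairs within `delta` residues
#' of an observed contact on both helices, matched within the same helix
#' pair (delta = 4 is about one helix turn).
#'
#' @param predicted Tibble of predicted contact pairs (e.g. from
#'   [top_k_contacts()]).
#' @param observed A `tm_contact_map` (or its `contacts` tibble).
#' @param delta Residue interval for the delta-analysis (default 4).
#' @return One-row tibble: `n_predicted`, `n_observed`, `tp`, `accuracy`,
#'   `coverage`, `delta_accuracy`.
#' @export
contact_metrics <- function(predicted, observed, delta = 4) {
  obs <- if (inherits(observed, "tm_contact_map")) observed$contacts else observed
  np <- nrow(predicted); no <- nrow(obs)
  okey <- pair_key(obs$seqpos_i, obs$seqpos_j)
  tp <- sum(pair_key(predicted$seqpos_i, predicted$seqpos_j) %in% okey)
  dhit <- vapply(seq_len(np), function(r) {
    same <- obs[obs$helix_a == predicted$helix_a[r] &
                  obs$helix_b == predicted$helix_b[r], , drop = FALSE]
    any(abs(same$seqpos_i - predicted$seqpos_i[r]) <= delta &
          abs(same$seqpos_j - predicted$seqpos_j[r]) <= delta)
  }, logical(1))
  tibble(n_predicted = np, n_observed = no, tp = tp,
         accuracy = if (np > 0) tp / np else NA_real_,
         coverage = if (no > 0) tp / no else NA_real_,
         delta_accuracy = if (np > 0) mean(dhit) else NA_real_)
}

#' Chain-averaged precision-recall curve and AUPRC
#'
#' For each chain, precision is traced along the score-ranked candidate list
#' and sampled at each grid recall (the precision at the smallest rank whose
#' recall reaches the grid value); the curves are then averaged pointwise
#' across chains, mirroring vertical averaging of per-chain curves. Chains
#' with no observed contact are excluded. AUPRC is the trapezoidal area
#' under the averaged curve.
#'
#' @param preds Named list of `tm_predictions` (all candidate pairs ranked).
#' @param observed Named list of `tm_contact_map`s, parallel to `preds`.
#' @param recall_grid Recall sampling grid (default 0 to 1 in steps of
#'   0.01).
#' @return A `tm_pr_curve` tibble (`recall`, `precision`) with attributes
#'   `auprc` and `per_chain` (chains x grid precision matrix).
#' @export
averaged_pr_curve <- function(preds, observed,
                              recall_grid = seq(0, 1, by = 0.01)) {
  if (length(recall_grid) == 0L) abort("empty recall grid")
  stopifnot(length(preds) == length(observed))
  per <- list()
  for (c in seq_along(preds)) {
    p <- preds[[c]]
    obs <- observed[[c]]$contacts
    if (nrow(obs) == 0L) next
    hit <- pair_key(p$seqpos_i, p$seqpos_j) %in%
      pair_key(obs$seqpos_i, obs$seqpos_j)
    ctp <- cumsum(hit[order(p$rank)])
    rec <- ctp / nrow(obs)
    prec <- ctp / seq_along(ctp)
    per[[length(per) + 1L]] <- vapply(recall_grid, function(g) {
      r <- which(rec >= g)[1]
      if (is.na(r)) prec[length(prec)] else prec[r]
    }, numeric(1))
  }
  if (length(per) == 0L) abort("no chain has observed contacts")
  mat <- do.call(rbind, per)
  avg <- colMeans(mat)
  auprc <- sum(diff(recall_grid) * (head(avg, -1) + avg[-1]) / 2)
  structure(tibble(recall = recall_grid, precision = avg),
            class = c("tm_pr_curve", class(tibble())),
            auprc = auprc, per_chain = mat)
}

## Matthews correlation; 0 when any denominator factor vanishes
mcc_score <- function(tp, fp, tn, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Helix-helix interaction metrics from ranked contacts
#'
#' Two helices are predicted to interact when they share at least one
#' predicted residue contact among the chain's top `L/divisor` pairs. The
#' confusion matrix is counted over all helix pairs of each chain;
#' `accuracy` is the fraction of predicted interactions that are real
#' (i.e. the precision), alongside sensitivity, specificity and the
#' Matthews correlation coefficient (0 when a denominator factor is 0).
#' Chain-level metrics are averaged over chains; chains with fewer than two
#' helices are skipped.
#'
#' @param preds Named list of `tm_predictions`.
#' @param observed Named list of `tm_contact_map`s.
#' @param divisor Ranking depth divisor (default 5, the top L/5 list).
#' @return A list with `per_chain` (tibble of tp/fp/tn/fn and the four
#'   metrics per chain) and `averaged` (one-row tibble of means; `NA`
#'   entries excluded per metric).
#' @export
helix_interaction_metrics <- function(preds, observed, divisor = 5) {
  stopifnot(length(preds) == length(observed))
  rows <- list()
  for (c in seq_along(preds)) {
    p <- preds[[c]]
    nh <- attr(p, "n_helices") %||% observed[[c]]$n_helices
    if (is.null(nh) || nh < 2L) {
      warn("chain with fewer than 2 helices skipped")
      next
    }
    top <- top_k_contacts(p, divisor)
    predicted <- unique(paste(top$helix_a, top$helix_b))
    obs <- observed[[c]]$interacting
    obs_key <- paste(obs$helix_a, obs$helix_b)
    univ <- utils::combn(nh, 2)
    univ_key <- paste(univ[1, ], univ[2, ])
    tp <- sum(univ_key %in% predicted & univ_key %in% obs_key)
    fp <- sum(univ_key %in% predicted & !univ_key %in% obs_key)
    fn <- sum(!univ_key %in% predicted & univ_key %in% obs_key)
    tn <- length(univ_key) - tp - fp - fn
    rows[[length(rows) + 1L]] <- tibble(
      chain_id = attr(p, "chain_id") %||% as.character(c),
      tp = tp, fp = fp, tn = tn, fn = fn,
      accuracy = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      mcc = mcc_score(tp, fp, tn, fn))
  }
  per_chain <- dplyr::bind_rows(rows)
  averaged <- dplyr::summarise(per_chain, dplyr::across(
    c("accuracy", "sensitivity", "specificity", "mcc"),
    ~ mean(.x, na.rm = TRUE)))
  list(per_chain = per_chain, averaged = averaged)
}

#' Full evaluation of jackknifed predictions
#'
#' Computes, per chain and averaged over chains, the top L/5, L/2 and L
#' contact accuracies, coverages and delta-accuracies, the chain-averaged
#' precision-recall curve with its AUPRC, and the helix-interaction metrics
#' at the top L/5 depth. Chains where a metric's denominator is zero are
#' excluded from that metric's average.
#'
#' @param preds Named list of `tm_predictions`.
#' @param observed Named list of `tm_contact_map`s, parallel to `preds`.
#' @param delta Interval for the delta-analysis (default 4).
#' @param recall_grid Grid for the averaged PR curve.
#' @return A `tm_evaluation` list: `contact_per_chain`, `contact_averaged`,
#'   `helix`, `pr_curve`, `auprc`.
#' @export
evaluate_predictions <- function(preds, observed, delta = 4,
                                 recall_grid = seq(0, 1, by = 0.01)) {
  divisors <- c(L5 = 5, L2 = 2, L = 1)
  rows <- list()
  for (c in seq_along(preds)) {
    p <- preds[[c]]
    for (d in names(divisors)) {
      m <- contact_metrics(top_k_contacts(p, divisors[[d]]), observed[[c]],
                           delta = delta)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        m, chain_id = attr(p, "chain_id") %||% as.character(c),
        k_spec = d, .before = 1)
    }
  }
  per_chain <- dplyr::bind_rows(rows)
  averaged <- dplyr::summarise(
    dplyr::group_by(per_chain, .data$k_spec),
    dplyr::across(c("accuracy", "coverage", "delta_accuracy"),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  pr <- averaged_pr_curve(preds, observed, recall_grid)
  hx <- helix_interaction_metrics(preds, observed)
  structure(list(contact_per_chain = per_chain,
                 contact_averaged = averaged,
                 helix = hx, pr_curve = pr, auprc = attr(pr, "auprc")),
            class = "tm_evaluation")
}

#' @export
print.tm_evaluation <- function(x, ...) {
  cat("<tm_evaluation>\n")
  print(x$contact_averaged)
  cat(sprintf("AUPRC: %.3f\n", x$auprc))
  print(x$helix$averaged)
  invisible(x)
}

#' @rdname tm_train
#' @param x A `tmhhcp_model`.
#' @param ... Unused.
#' @export
tidy.tmhhcp_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(feature = rownames(imp),
         importance = as.numeric(imp[, 1])) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tm_train
#' @export
glance.tmhhcp_model <- function(x, ...) {
  rf <- x$forest
  tibble(n_trees = rf$ntree, m_try = rf$mtry,
         n_features = length(x$feature_names),
         oob_error = as.numeric(rf$err.rate[rf$ntree, "OOB"]),
         definition = x$config$definition,
         feature_mode = x$config$feature_mode)
}
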