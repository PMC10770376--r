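#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end run with validated
#' defaults. Unknown keys are rejected on load, and `save_run_config()` /
#' `load_run_config()` round-trip through YAML.
#'
#' @param cohort Named list of [cohort_config()] arguments (the cohort
#'   seed is derived from the global `seed`).
#' @param band ERP filter band in Hz.
#' @param conn_band Connectivity band in Hz.
#' @param baseline Baseline window in ms.
#' @param method Connectivity estimator, `"pcc"` or `"plv"`.
#' @param k1,k2 k-NN neighbour counts of the single- and multi-hop graphs.
#' @param alpha Alignment mixing weight.
#' @param lambdas Sparse-graph penalties (lambda1..lambda4).
#' @param model Named list: `K1`, `K2`, `dropout`.
#' @param train Named list: `folds`, `epochs`, `lr`, `patience`.
#' @param vote Named list: `repeats`, `draw`.
#' @param microstates Named list: `k_min`, `k_max`, `n_init`.
#' @param stages Named list of logical switches: `gsp`, `saliency`,
#'   `microstates`, `vote`.
#' @param seed Global seed; stage seeds are derived from it.
#' @param out_dir Optional directory for stage artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = list(), band = c(1, 20),
                       conn_band = c(4, 12), baseline = c(-200, 0),
                       method = c("pcc", "plv"), k1 = 1, k2 = 8,
                       alpha = 0.5, lambdas = c(0.1, 0.01, 0.1, 0.01),
                       model = list(), train = list(), vote = list(),
                       microstates = list(), stages = list(), seed = 1,
                       out_dir = NULL) {
  method <- match.arg(method)
  merge_known <- function(defaults, user, what) {
    extra <- setdiff(names(user), names(defaults))
    if (length(extra) > 0) {
      stop_invalid("unknown %s key(s): %s", what,
                   paste(extra, collapse = ", "))
    }
    modifyList(defaults, user)
  }
  cohort <- merge_known(
    list(n_subjects_per_group = 10, n_trials = 100, fs = 1000,
         epoch_window = c(-200, 500), p2_latency = 260, p2_effect = 2.5,
         noise_scale = 1, artifact_rate = 0.05),
    cohort, "cohort")
  model <- merge_known(list(K1 = 3, K2 = 3, dropout = 0.35), model, "model")
  train <- merge_known(list(folds = 5, epochs = 200, lr = 1e-3,
                            patience = 20), train, "train")
  vote <- merge_known(list(repeats = 100, draw = 10), vote, "vote")
  microstates <- merge_known(list(k_min = 2, k_max = 8, n_init = 50),
                             microstates, "microstates")
  stages <- merge_known(list(gsp = TRUE, saliency = TRUE,
                             microstates = TRUE, vote = TRUE),
                        stages, "stages")
  structure(list(cohort = cohort, band = band, conn_band = conn_band,
                 baseline = baseline, method = method, k1 = k1, k2 = k2,
                 alpha = alpha, lambdas = lambdas, model = model,
                 train = train, vote = vote, microstates = microstates,
                 stages = stages, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop_invalid("unknown config key(s): %s", paste(extra, collapse = ", "))
  }
  raw$out_dir <- raw$out_dir %||% NULL
  do.call(run_config, raw)
}

hash_object <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(obj, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, connectivity, graph-signal-processing
#' reorganization (network alignment + sparse graph, per fold on the
#' training split), cross-validated GCN training, saliency, microstate
#' analysis and trial voting, in that fixed order, logging a
#' content-hashed manifest per stage. Re-running with the same config
#' reproduces every hash.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress (default `FALSE`).
#' @return A `pipeline_run` with `cv`, `saliency`, `microstates`, `vote`,
#'   `erps`, `graphs`, `manifest`, `config`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  manifest <- list(config_hash = hash_object(unclass(cfg)), stages = list())
  note <- function(stage, t0, objs) {
    manifest$stages[[stage]] <<- list(
      seed = derive_seed(cfg$seed, stage),
      seconds = round(as.numeric(Sys.time()) - t0, 2),
      hashes = lapply(objs, hash_object))
    if (verbose) message(sprintf("[%s] done in %.1fs", stage,
                                 manifest$stages[[stage]]$seconds))
  }

  # -- simulate ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ccfg <- do.call(cohort_config,
                  c(cfg$cohort, list(seed = derive_seed(cfg$seed, "simulate"))))
  montage <- generate_montage(64)
  cohort <- simulate_cohort(ccfg, montage)
  labels <- cohort$subjects_tbl$group
  n_subj <- length(cohort$subjects)
  note("simulate", t0, list(subjects_tbl = cohort$subjects_tbl))

  # -- preprocess + connectivity (streamed per subject) --------------
  t0 <- as.numeric(Sys.time())
  erps <- vector("list", n_subj)
  graphs <- vector("list", n_subj)
  trial_W <- if (cfg$stages$vote) vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    pp <- preprocess_epochs(cohort$subjects[[s]], montage,
                            band = cfg$band, baseline = cfg$baseline)
    erps[[s]] <- pp$erp
    nb <- narrowband(pp$epochs, cfg$conn_band[1], cfg$conn_band[2])
    tw <- connectivity_trials(nb, cfg$method)
    W <- colMeans(tw)
    dimnames(W) <- list(nb$channels, nb$channels)
    graphs[[s]] <- connectivity_graph(W, cfg$method, cfg$conn_band,
                                      cfg$k1, cfg$k2)
    graphs[[s]]$subject_id <- nb$subject_id
    graphs[[s]]$group <- nb$group
    if (cfg$stages$vote) trial_W[[s]] <- tw
    cohort$subjects[[s]] <- NA  # release the raw epochs
  }
  note("preprocess", t0, list(erps = lapply(erps, `[[`, "data")))
  note("connectivity", t0, list(W = lapply(graphs, `[[`, "W")))

  # -- per-fold GSP + training ---------------------------------------
  t0 <- as.numeric(Sys.time())
  folds <- cfg$train$folds
  fold_of <- make_folds(labels, folds, derive_seed(cfg$seed, "folds"))
  gsp_inputs <- function(train_idx, subject_idx) {
    # alignment prior and sparse graph come from the training split only
    if (!cfg$stages$gsp) {
      return(lapply(subject_idx, function(s) {
        list(X = graphs[[s]]$W, A = abs(graphs[[s]]$A2))
      }))
    }
    meanA <- function(g) {
      Reduce(`+`, lapply(graphs[intersect(train_idx,
                                          which(labels == g))],
                         function(x) abs(x$A2))) /
        sum(labels[train_idx] == g)
    }
    prior <- build_prior(meanA(0), meanA(1))
    perms <- lapply(subject_idx, function(s) {
      align_subject(graphs[[s]], prior, alpha = cfg$alpha)$P
    })
    names(perms) <- as.character(subject_idx)
    tr_in_set <- match(intersect(subject_idx, train_idx), subject_idx)
    erp_perm <- lapply(tr_in_set, function(i) {
      reorganize_channels(erps[[subject_idx[i]]], perms[[i]])$data
    })
    A_shared <- sparse_graph_stage(erp_perm,
                                   labels[subject_idx[tr_in_set]],
                                   lambdas = cfg$lambdas)$A
    inputs <- lapply(seq_along(subject_idx), function(i) {
      list(X = reorganize_channels(graphs[[subject_idx[i]]]$W, perms[[i]]),
           A = A_shared)
    })
    attr(inputs, "perms") <- perms
    attr(inputs, "A_shared") <- A_shared
    inputs
  }

  gmodel <- build_model(K1 = cfg$model$K1, K2 = cfg$model$K2, M = 2,
                        n_nodes = 64, dropout = cfg$model$dropout)
  metrics <- list(); fits <- list(); rocs <- list()
  score0 <- rep(NA_real_, n_subj)
  fold_inputs <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    inputs <- gsp_inputs(tr, seq_len(n_subj))
    fold_inputs[[f]] <- inputs
    fit <- gcn_fit(inputs[tr], labels[tr], gmodel,
                   seed = derive_seed(cfg$seed, paste0("train_fold", f)),
                   epochs = cfg$train$epochs, lr = cfg$train$lr,
                   patience = cfg$train$patience)
    probs <- predict.gcn_fit(fit, inputs[te])
    ev <- evaluate_metrics(labels[te], probs[, "0"])
    metrics[[f]] <- tibble::tibble(fold = f, acc = ev$acc, auc = ev$auc,
                                   sensitivity = ev$sensitivity,
                                   specificity = ev$specificity)
    rocs[[f]] <- dplyr::mutate(ev$roc, fold = f)
    fits[[f]] <- fit
    score0[te] <- probs[, "0"]
  }
  cv <- structure(list(metrics = dplyr::bind_rows(metrics),
                       fold_of = fold_of, fits = fits, probs = score0,
                       labels = labels, roc = dplyr::bind_rows(rocs)),
                  class = "gcn_cv")
  note("train", t0, list(metrics = cv$metrics, probs = cv$probs))

  # -- saliency ------------------------------------------------------
  sal <- NULL
  if (cfg$stages$saliency) {
    t0 <- as.numeric(Sys.time())
    inputs_all <- gsp_inputs(seq_len(n_subj), seq_len(n_subj))
    fit_all <- gcn_fit(inputs_all, labels, gmodel,
                       seed = derive_seed(cfg$seed, "saliency_fit"),
                       epochs = cfg$train$epochs, lr = cfg$train$lr,
                       patience = cfg$train$patience)
    A_mean <- Reduce(`+`, lapply(graphs, function(g) abs(g$A2))) / n_subj
    sal <- cohort_saliency(fit_all, inputs_all, labels, class_label = 0,
                           adjacency = A_mean,
                           perms = attr(inputs_all, "perms"),
                           channels = montage$label)
    note("saliency", t0, list(node_scores = sal$node_scores))
  }

  # -- microstates ---------------------------------------------------
  ms <- NULL
  if (cfg$stages$microstates) {
    t0 <- as.numeric(Sys.time())
    grand <- function(g) {
      d <- Reduce(`+`, lapply(erps[labels == g], `[[`, "data")) /
        sum(labels == g)
      eeg_erp(d, ccfg$fs, ccfg$epoch_window, montage$label,
              n_trials_used = sum(labels == g), subject_id = paste0("grand", g),
              group = g)
    }
    ms <- microstate_analysis(
      grand(0), grand(1),
      k_range = cfg$microstates$k_min:cfg$microstates$k_max,
      n_init = cfg$microstates$n_init,
      seed = derive_seed(cfg$seed, "microstates"))
    note("microstates", t0,
         list(chosen_k = ms$clustering$chosen_k,
              templates = ms$clustering$templates))
  }

  # -- trial voting --------------------------------------------------
  vote <- NULL
  if (cfg$stages$vote) {
    t0 <- as.numeric(Sys.time())
    trial_labels <- vector("list", n_subj)
    for (s in seq_len(n_subj)) {
      f <- fold_of[s]
      inputs <- fold_inputs[[f]]
      A_s <- inputs[[s]]$A
      perms <- attr(inputs, "perms")
      tw <- trial_W[[s]]
      t_inputs <- lapply(seq_len(dim(tw)[1]), function(tr) {
        X <- tw[tr, , ]
        if (!is.null(perms)) X <- reorganize_channels(X, perms[[s]])
        list(X = X, A = A_s)
      })
      probs <- predict.gcn_fit(fits[[f]], t_inputs)
      trial_labels[[s]] <- as.integer(colnames(probs)[max.col(probs,
                                                              "first")])
    }
    vote <- posterior_verify(trial_labels, labels,
                             repeats = cfg$vote$repeats,
                             draw = cfg$vote$draw,
                             seed = derive_seed(cfg$seed, "vote"))
    vote$trial_labels <- trial_labels
    note("vote", t0, list(mean = vote$mean, variance = vote$variance))
  }

  run <- structure(list(cv = cv, saliency = sal, microstates = ms,
                        vote = vote, erps = erps, graphs = graphs,
                        montage = montage,
                        ground_truth = cohort$ground_truth,
                        manifest = manifest, config = cfg),
                   class = "pipeline_run")
  if (!is.null(cfg$out_dir)) write_run_outputs(run, cfg$out_dir)
  run
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(run$cv$metrics),
            file.path(dir, "cv_metrics.csv"), row.names = FALSE)
  write.csv(as.data.frame(run$cv$roc), file.path(dir, "roc.csv"),
            row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  if (!is.null(run$saliency)) {
    write.csv(as.data.frame(tidy.saliency_map(run$saliency)),
              file.path(dir, "saliency_nodes.csv"), row.names = FALSE)
  }
  if (!is.null(run$vote)) {
    jsonlite::write_json(glance.vote_summary(run$vote),
                         file.path(dir, "vote.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$cv)
  if (!is.null(x$vote)) print(x$vote)
  if (!is.null(x$microstates)) print(x$microstates$clustering)
  invisible(x)
}

#' Ablation report: effect of the GSP stage
#'
#' Compares two completed runs on the same cohort and folds (typically
#' with and without the graph-signal-processing stage): per-metric mean
#' deltas plus Bonferroni-corrected Mann-Whitney p-values over the
#' per-fold metric vectors.
#'
#' @param run_with,run_without `pipeline_run` objects.
#' @return Tibble with `metric`, `mean_with`, `mean_without`, `delta`,
#'   `p_value`.
#' @export
ablation_report <- function(run_with, run_without) {
  m1 <- run_with$cv$metrics
  m2 <- run_without$cv$metrics
  if (nrow(m1) != nrow(m2)) stop_invalid("runs have different fold counts")
  mets <- c("acc", "auc", "sensitivity", "specificity")
  purrr::map_dfr(mets, function(m) {
    cmp <- compare_models(list(with_gsp = m1[[m]], without_gsp = m2[[m]]))
    tibble::tibble(metric = m,
                   mean_with = mean(m1[[m]]),
                   mean_without = mean(m2[[m]]),
                   delta = mean(m1[[m]]) - mean(m2[[m]]),
                   p_value = cmp$p[1, 2])
  })
}

#' Tidy / glance methods for cross-validation results
#'
#' @param x A `gcn_cv`.
#' @param ... Unused.
#' @return `tidy()`: the per-fold metric tibble; `glance()`: one-row
#'   means with fold count.
#' @method tidy gcn_cv
#' @export
tidy.gcn_cv <- function(x, ...) x$metrics

#' @rdname tidy.gcn_cv
#' @method glance gcn_cv
#' @export
glance.gcn_cv <- function(x, ...) {
  tibble::tibble(folds = nrow(x$metrics),
                 acc = mean(x$metrics$acc), auc = mean(x$metrics$auc),
                 sensitivity = mean(x$metrics$sensitivity),
                 specificity = mean(x$metrics$specificity))
}

#' ROC curves of a cross-validated run
#'
#' @param object A `gcn_cv`.
#' @param ... Unused.
#' @return A ggplot object with one ROC per fold.
#' @method autoplot gcn_cv
#' @export
autoplot.gcn_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(.data$fpr, .data$tpr,
                               color = factor(.data$fold))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, color = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  color = "fold") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
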