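#' Pipeline configuration
#'
#' Assembles the per-stage settings for one end-to-end run. `method` selects
#' the autoencoder variant or baseline:
#' \describe{
#'   \item{dae-mkl}{denoising autoencoder (input dropout 0.1, hidden dropout
#'     0.3) per omic, then kernels, per-omic similarity learning, fusion,
#'     k-means.}
#'   \item{sae-mkl}{sparse autoencoder: no input corruption, L1 penalty on
#'     latent activations instead.}
#'   \item{ae-mkl}{plain autoencoder: no corruption, no dropout, no
#'     sparsity penalty.}
#'   \item{hmkl}{no autoencoder stage; kernels are built on the raw
#'     features.}
#'   \item{cimlr-joint}{kernel banks of all omics pooled into a single
#'     similarity optimization; its similarity is clustered directly
#'     (no fusion step).}
#' }
#'
#' @param method one of the five variants above.
#' @param k fixed number of clusters, or `"auto"` to choose by the
#'   separation-cost drop over `k_range`.
#' @param k_range candidate range for `k = "auto"`.
#' @param hidden_size latent width(s) for the autoencoder stage; more than
#'   one value triggers the held-out grid search.
#' @param epochs,learning_rate autoencoder training schedule (proximal
#'   gradient descent, full batch).
#' @param cimlr_beta,cimlr_gamma,cimlr_rho,cimlr_max_iter similarity-learning
#'   penalties and sweep limit ([cimlr_params()]).
#' @param knn_k fusion-graph neighbor count (`NULL` = `ceiling(n/10)`).
#' @param restarts k-means restarts.
#' @param seed master seed; per-omic autoencoder seeds and the k-means seed
#'   are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(method = c("dae-mkl", "sae-mkl", "ae-mkl",
                                       "hmkl", "cimlr-joint"),
                            k = 4, k_range = c(2, 8),
                            hidden_size = 16L,
                            epochs = 400L, learning_rate = 0.05,
                            cimlr_beta = 1, cimlr_gamma = 1,
                            cimlr_rho = NULL, cimlr_max_iter = 30L,
                            knn_k = NULL, restarts = 20L, seed = 1L) {
  method <- match.arg(method)
  structure(list(method = method, k = k, k_range = k_range,
                 hidden_size = as.integer(hidden_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 cimlr_beta = cimlr_beta, cimlr_gamma = cimlr_gamma,
                 cimlr_rho = cimlr_rho,
                 cimlr_max_iter = as.integer(cimlr_max_iter),
                 knn_k = knn_k, restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# dae_config for the method's autoencoder variant; seed offset per omic so
# the three encoders draw independent initializations.
method_dae_config <- function(config, omic_index) {
  seed <- config$seed + 7919L * omic_index
  base <- list(hidden_size_grid = config$hidden_size,
               epochs = config$epochs,
               learning_rate = config$learning_rate,
               # no held-out split unless widths compete: every sample helps
               # the sparse-recovery margin
               validation_fraction = if (length(config$hidden_size) > 1) 0.1 else 0,
               seed = seed)
  args <- switch(config$method,
    # denoising: input masking plus the framework's weight penalties
    "dae-mkl" = c(base, list(noise_kind = "mask", input_dropout_rate = 0.1)),
    # sparse: latent-activation L1 replaces the input corruption
    "sae-mkl" = c(base, list(noise_kind = "mask", input_dropout_rate = 0,
                             activation_l1 = 0.2)),
    # plain: no corruption and no sparsity penalty of either kind; the
    # principal-subspace warm start converges quickly, so fewer passes
    "ae-mkl"  = c(base[setdiff(names(base), "epochs")],
                  list(noise_kind = "mask", input_dropout_rate = 0,
                       l1_penalty = 0, activation_l1 = 0,
                       epochs = min(config$epochs, 150L))),
    stop("method has no autoencoder stage"))
  do.call(dae_config, args)
}

#' Run the subtyping pipeline end to end
#'
#' Executes the stage sequence of the configured method on a list of omics
#' matrices sharing sample order: (optional) autoencoder reduction per omic,
#' adaptive Gaussian kernel bank, per-omic composite-similarity learning,
#' fusion of the composite similarities, and k-means on the fused kernel.
#' Deterministic given `config$seed`.
#'
#' @param omics list of samples x features matrices (same rows).
#' @param config a [pipeline_config()].
#' @return list with `assignment` ([kmeans_cluster()] result), `fusion`
#'   (`NULL` for `cimlr-joint`), `similarities`, `latents` (`NULL` when no
#'   autoencoder stage ran), `S_final`, chosen `k`, `k_profile` (when
#'   `k = "auto"`), and the `config`.
#' @export
run_pipeline <- function(omics, config = pipeline_config()) {
  if (!is.list(omics) || length(omics) < 1) stop("need at least one omic")
  n <- nrow(omics[[1]])
  if (!all(vapply(omics, nrow, integer(1)) == n)) {
    stop("all omics must share the same samples (row count mismatch)")
  }
  ids <- rownames(omics[[1]])
  if (!is.null(ids)) {
    for (m in seq_along(omics)[-1]) {
      if (!identical(rownames(omics[[m]]), ids)) {
        stop("sample identifiers differ between omics")
      }
    }
  }
  # C for the low-rank factor: the fixed k, or the middle of the auto range
  C <- if (identical(config$k, "auto")) {
    max(2L, as.integer(round(mean(config$k_range))))
  } else as.integer(config$k)
  cp <- cimlr_params(n_clusters = C, beta = config$cimlr_beta,
                     gamma = config$cimlr_gamma, rho = config$cimlr_rho,
                     max_iter = config$cimlr_max_iter)
  up <- umkl_params(knn_k = config$knn_k)

  latents <- NULL
  if (config$method %in% c("dae-mkl", "sae-mkl", "ae-mkl")) {
    latents <- lapply(seq_along(omics), function(m) {
      dcfg <- method_dae_config(config, m)
      fit <- if (length(dcfg$hidden_size_grid) > 1) {
        grid_search_hidden(omics[[m]], dcfg)$model
      } else {
        train_dae(omics[[m]], dcfg)
      }
      encode(omics[[m]], fit)
    })
    reps <- latents
  } else {
    reps <- omics
  }

  if (config$method == "cimlr-joint") {
    banks <- lapply(reps, build_bank)
    sim <- learn_similarity(pool_banks(banks), cp)
    similarities <- list(sim)
    fusion <- NULL
    S_final <- sim$S
  } else {
    similarities <- lapply(reps, function(z) {
      learn_similarity(build_bank(as.matrix(z)), cp)
    })
    fusion <- fuse_similarities(lapply(similarities, `[[`, "S"), up)
    S_final <- fusion$S_final
  }

  k_profile <- NULL
  if (identical(config$k, "auto")) {
    est <- estimate_k(S_final, config$k_range[1], config$k_range[2])
    k <- est$k
    k_profile <- est
  } else {
    k <- as.integer(config$k)
  }
  assignment <- kmeans_cluster(S_final, k, seed = config$seed,
                               restarts = config$restarts)
  list(assignment = assignment, fusion = fusion,
       similarities = similarities, latents = latents,
       S_final = S_final, k = k, k_profile = k_profile, config = config)
}

#' Benchmark methods over a grid of simulation settings
#'
#' For every combination of signal ratio, noise variance and method,
#' generates `n_replicates` fresh datasets (seeds derived deterministically
#' from `base_seed`), runs the pipeline with `k` fixed at the simulated
#' number of subtypes, and scores NMI against the true labels. Replicate
#' failures are recorded and leave the cell marked incomplete instead of
#' aborting the grid. A dataset is generated once per replicate and shared
#' by all methods.
#'
#' @param signal_ratios,noise_variances vectors defining the settings grid.
#' @param methods subset of the pipeline methods.
#' @param n_replicates replicates per cell (>= 2).
#' @param base_seed master seed.
#' @param fuzzy_fraction 0 for clear boundaries; in (0, 0.2] for the
#'   fuzzy-boundary variant.
#' @param config_fn optional function(method, seed) returning the
#'   [pipeline_config()] to use; defaults to the package defaults per method.
#' @param sim_args extra arguments passed to [sim_config()] (e.g. a smaller
#'   `n_features` for quick runs).
#' @return object of class `benchmark_report`: data frame with one row per
#'   cell x method (mean/sd NMI, replicate count, failures), with the
#'   replicate-level scores in `attr(., "replicates")`.
#' @export
benchmark <- function(signal_ratios = c(0.05, 0.075, 0.10),
                      noise_variances = c(4, 8, 12),
                      methods = c("dae-mkl", "hmkl"),
                      n_replicates = 10, base_seed = 1,
                      fuzzy_fraction = 0,
                      config_fn = NULL, sim_args = list()) {
  if (n_replicates < 2) stop("need at least 2 replicates")
  cells <- expand.grid(signal_ratio = signal_ratios,
                       noise_variance = noise_variances,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- list(); reps_log <- list()
  for (ci in seq_len(nrow(cells))) {
    sr <- cells$signal_ratio[ci]; nv <- cells$noise_variance[ci]
    scores <- matrix(NA_real_, n_replicates, length(methods),
                     dimnames = list(NULL, methods))
    for (r in seq_len(n_replicates)) {
      data_seed <- (base_seed - 1) * 100000 + (ci - 1) * 1000 + r
      cfg_args <- c(list(signal_ratio = sr, noise_variance = nv,
                         fuzzy_fraction = fuzzy_fraction,
                         seed = data_seed), sim_args)
      data <- generate_scenario1(do.call(sim_config, cfg_args))
      for (mt in methods) {
        pcfg <- if (is.null(config_fn)) {
          pipeline_config(method = mt, k = data$config$n_subtypes,
                          seed = data_seed)
        } else config_fn(mt, data_seed)
        res <- tryCatch(run_pipeline(data$omics, pcfg),
                        error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf("replicate failed (%s, signal %.3f, var %.0f, rep %d): %s",
                          mt, sr, nv, r, conditionMessage(res)))
        } else {
          scores[r, mt] <- nmi(res$assignment$labels, data$true_labels)
        }
      }
    }
    for (mt in methods) {
      v <- scores[, mt]
      rows[[length(rows) + 1L]] <- data.frame(
        signal_ratio = sr, noise_variance = nv, method = mt,
        mean_nmi = mean(v, na.rm = TRUE),
        sd_nmi = stats::sd(v, na.rm = TRUE),
        n_replicates = sum(!is.na(v)),
        n_failed = sum(is.na(v)))
    }
    reps_log[[ci]] <- scores
  }
  report <- do.call(rbind, rows)
  attr(report, "replicates") <- reps_log
  attr(report, "base_seed") <- base_seed
  class(report) <- c("benchmark_report", class(report))
  report
}
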