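#' Full-pipeline configuration
#'
#' One validated bundle of per-stage parameters for
#' [run_pipeline()]: band-pass preprocessing, segmentation, bispectrum
#' estimation, image quantization, texture extraction, LSDA reduction,
#' t-test selection, and cross-validated classification.
#'
#' @param lo,hi,filter_order Band-pass edges (Hz) and Butterworth order.
#' @param segment_len,overlap Segment length and overlap in samples.
#' @param bispectrum A [bispectrum_config()].
#' @param gray_levels,scaling Image quantization (see [magnitude_image()]).
#' @param entropy An [entropy_config()].
#' @param lsda_k,lsda_alpha,lsda_d LSDA graph size, trade-off, and target
#'   dimension (d is clamped to what the data supports, with a message).
#' @param lsda_mode "cv" refits LSDA + t-test inside every training fold
#'   (no information leakage into held-out subjects); "global" fits once on
#'   the whole cohort before CV, which is how a single printed t-table is
#'   produced but lets the reduction see test labels.
#' @param p_threshold Welch-test selection threshold.
#' @param classifier A [classifier_spec()].
#' @param n_folds CV folds.
#' @param aggregate "subject" (default) averages features over segments and
#'   channels to one 18-feature vector per subject; "channel" keeps
#'   per-channel feature blocks (18 x n_channels columns per subject).
#'   Channel averaging cancels channel-level estimation noise and keeps the
#'   reduction stage far from the n_features ~ n_samples regime.
#' @param seed Global seed; every random stage derives from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lo = 0.3, hi = 40, filter_order = 4L,
                            segment_len = 5519L, overlap = 0L,
                            bispectrum = bispectrum_config(),
                            gray_levels = 64L, scaling = "log1p",
                            entropy = entropy_config(),
                            lsda_k = 5L, lsda_alpha = 0.5, lsda_d = 30L,
                            lsda_mode = c("cv", "global"),
                            p_threshold = 0.05,
                            classifier = classifier_spec("pnn"),
                            n_folds = 10L,
                            aggregate = c("subject", "channel"),
                            seed = 1L) {
  stopifnot(inherits(bispectrum, "bispectrum_config"),
            inherits(entropy, "entropy_config"),
            inherits(classifier, "classifier_spec"))
  cfg <- list(lo = assert_number(lo, "lo", 0), hi = assert_number(hi, "hi"),
              filter_order = assert_count(filter_order, "filter_order"),
              segment_len = assert_count(segment_len, "segment_len"),
              overlap = assert_count(overlap, "overlap", min = 0L),
              bispectrum = bispectrum,
              gray_levels = assert_count(gray_levels, "gray_levels", min = 2L),
              scaling = match.arg(scaling, c("log1p", "linear")),
              entropy = entropy,
              lsda_k = assert_count(lsda_k, "lsda_k"),
              lsda_alpha = assert_number(lsda_alpha, "lsda_alpha", 0, 1),
              lsda_d = assert_count(lsda_d, "lsda_d"),
              lsda_mode = match.arg(lsda_mode),
              p_threshold = assert_number(p_threshold, "p_threshold", 0, 1),
              classifier = classifier,
              n_folds = assert_count(n_folds, "n_folds", min = 2L),
              aggregate = match.arg(aggregate),
              seed = assert_count(seed, "seed", min = 0L))
  if (cfg$lo >= cfg$hi) stopf("`lo` must be below `hi`")
  structure(cfg, class = "pipeline_config")
}

# Polynomial rolling hash over the serialized config, for tagging outputs.
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, xdr = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Texture features for every subject of a cohort
#'
#' For each record: band-pass filter, cut each channel into fixed-length
#' segments, estimate the bispectrum of each segment, quantize its magnitude
#' image, and extract the 18 texture features. Per-channel features are
#' averaged over that channel's segments; depending on
#' `config$aggregate` the channels are kept as feature blocks (one row per
#' subject, 18 x n_channels columns) or averaged down to 18 columns.
#'
#' @param cohort List of [eeg_record()] (or a directory readable by
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param verbose Emit one progress message per subject.
#' @return `feature_matrix`: list(X, labels, sample_ids).
#' @export
cohort_features <- function(cohort, config = pipeline_config(),
                            verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(config, "pipeline_config"))
  mask <- if (config$bispectrum$use_principal_domain)
    principal_domain_mask(config$bispectrum$nfft) else NULL
  rows <- lapply(cohort, function(rec) {
    tryCatch({
      rec <- bandpass(rec, config$lo, config$hi, config$filter_order)
      per_channel <- lapply(seq_along(rec$channel_names), function(ch) {
        segs <- segment_channel(rec, ch, L = config$segment_len,
                                overlap = config$overlap)
        if (!length(segs))
          stopf("no segments (channel shorter than segment_len)")
        feats <- vapply(segs, function(sg) {
          B <- estimate_bispectrum(sg, config$bispectrum)
          img <- magnitude_image(B, G = config$gray_levels,
                                 scaling = config$scaling, mask = mask)
          extract_features(img, config$entropy)
        }, numeric(18L))
        rowMeans(feats)
      })
      if (config$aggregate == "subject") {
        v <- rowMeans(do.call(cbind, per_channel))
        names(v) <- bispeeg_feature_names
      } else {
        v <- unlist(per_channel)
        names(v) <- as.vector(outer(bispeeg_feature_names, rec$channel_names,
                                    function(f, ch) paste(ch, f, sep = "_")))
      }
      if (verbose) message("features: ", rec$subject_id)
      v
    }, error = function(e)
      stopf("feature extraction failed at subject %s: %s",
            rec$subject_id, conditionMessage(e)))
  })
  structure(list(
    X = do.call(rbind, rows),
    labels = factor(vapply(cohort, function(r) r$class_label, character(1)),
                    levels = c("normal", "asd")),
    sample_ids = vapply(cohort, function(r) r$subject_id, character(1))),
    class = "feature_matrix")
}

clamp_lsda_d <- function(d, n_features, n_train) {
  d_eff <- min(d, n_features, n_train - 1L)
  if (d_eff < d)
    message(sprintf("LSDA: d reduced from %d to %d (limited by data size)", d, d_eff))
  d_eff
}

# Composite classifier: LSDA + t-test selection + base classifier, all fit
# on the training fold only.
lsda_pipeline_classifier <- function(config) {
  base <- make_classifier(config$classifier)
  list(
    fit = function(X, y, seed = 1L) {
      d <- clamp_lsda_d(config$lsda_d, ncol(X), nrow(X))
      k <- min(config$lsda_k, nrow(X) - 1L)
      model <- lsda_fit(X, y, k = k, alpha = config$lsda_alpha, d = d)
      Z <- lsda_transform(model, X)
      tt <- ttest_rank(Z, y)
      sel <- select_features(tt, config$p_threshold)
      if (!length(sel)) sel <- which.min(tt$p)  # fall back to the best-ranked
      list(lsda = model, sel = sel,
           base = base$fit(Z[, sel, drop = FALSE], y, seed = seed))
    },
    predict = function(model, X) {
      Z <- lsda_transform(model$lsda, X)
      base$predict(model$base, Z[, model$sel, drop = FALSE])
    })
}

#' Run the complete classification pipeline on a cohort
#'
#' Executes preprocess -> bispectrum -> texture -> LSDA -> t-test ->
#' classification. A global LSDA fit on the whole cohort produces the
#' reported t-table and selected feature set (the printable summary); the
#' cross-validated metrics use either that global reduction
#' (`lsda_mode = "global"`) or, by default, refit the reduction and
#' selection inside each training fold so held-out subjects never influence
#' the projection.
#'
#' @param cohort List of [eeg_record()], a directory path, or a
#'   `feature_matrix` (to skip the signal stages).
#' @param config A [pipeline_config()].
#' @param curve Also compute the accuracy-vs-number-of-features curve
#'   (global mode ranking; adds M extra CV runs).
#' @param verbose Progress messages.
#' @return `bispeeg_report`: features, global LSDA model, t-table, selected
#'   features, `cv` ([cross_validate()] result), optional `curve`, config
#'   and config hash.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), curve = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  fm <- if (inherits(cohort, "feature_matrix")) cohort
        else cohort_features(cohort, config, verbose = verbose)
  n <- nrow(fm$X)
  if (length(unique(fm$sample_ids)) != n)
    stopf("duplicate subject ids in cohort")

  d_glob <- clamp_lsda_d(config$lsda_d, ncol(fm$X), n)
  lsda_global <- lsda_fit(fm$X, fm$labels, k = min(config$lsda_k, n - 1L),
                          alpha = config$lsda_alpha, d = d_glob)
  Z <- lsda_transform(lsda_global, fm$X)
  ttable <- ttest_rank(Z, fm$labels)
  selected <- select_features(ttable, config$p_threshold)

  cv_seed <- derive_seed(config$seed, 7L)
  cv <- if (config$lsda_mode == "global") {
    sel <- if (length(selected)) selected else which.min(ttable$p)
    cross_validate(Z[, sel, drop = FALSE], fm$labels, config$classifier,
                   n_folds = config$n_folds, seed = cv_seed)
  } else {
    cross_validate(fm$X, fm$labels, lsda_pipeline_classifier(config),
                   n_folds = config$n_folds, seed = cv_seed)
  }
  curve_out <- NULL
  if (curve) {
    sel <- if (length(selected)) selected else order(ttable$p)
    curve_out <- accuracy_vs_n_features(Z, fm$labels, sel, config$classifier,
                                        n_folds = config$n_folds,
                                        seed = cv_seed)
  }
  structure(list(features = fm, n_subjects = n, lsda = lsda_global,
                 ttest = ttable, selected = selected, cv = cv,
                 curve = curve_out, config = config,
                 config_hash = config_hash(config)),
            class = "bispeeg_report")
}

#' @export
print.bispeeg_report <- function(x, ...) {
  cat(sprintf("bispeeg pipeline report [config %s]\n", x$config_hash))
  cat(sprintf("  %d subjects (%s), %d raw features, %d LSDA components\n",
              x$n_subjects, paste(sprintf("%s: %d", levels(x$features$labels),
                                          table(x$features$labels)),
                                  collapse = ", "),
              ncol(x$features$X), x$lsda$d))
  cat(sprintf("  selected by t-test (p < %g): %s\n", x$config$p_threshold,
              if (length(x$selected)) paste(names(x$selected), collapse = ", ")
              else "none"))
  print(x$cv)
  invisible(x)
}

#' Write the report's tables to a directory
#'
#' Emits `ttest.csv` (Table-2-style t-table), `metrics.csv` (Table-1-style
#' row with confusion counts), `features.csv`, optionally `curve.csv`, and a
#' JSON run summary carrying the config and its hash.
#'
#' @param report A [run_pipeline()] report.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "bispeeg_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$ttest, file.path(dir, "ttest.csv"), row.names = FALSE)
  m <- report$cv$metrics
  utils::write.csv(data.frame(
    classifier = report$config$classifier$kind,
    n_features = length(report$selected),
    accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
    specificity = m[["specificity"]], ppv = m[["ppv"]],
    TP = report$cv$pooled[["TP"]], FN = report$cv$pooled[["FN"]],
    TN = report$cv$pooled[["TN"]], FP = report$cv$pooled[["FP"]],
    seed = report$config$seed, config_hash = report$config_hash),
    file.path(dir, "metrics.csv"), row.names = FALSE)
  feat <- data.frame(subject_id = report$features$sample_ids,
                     class = report$features$labels,
                     report$features$X, check.names = FALSE)
  utils::write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  if (!is.null(report$curve))
    utils::write.csv(report$curve$curve, file.path(dir, "curve.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = report$config_hash,
         n_subjects = report$n_subjects,
         selected = names(report$selected),
         metrics = as.list(report$cv$metrics),
         pooled_counts = as.list(report$cv$pooled)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
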