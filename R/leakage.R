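#' Run the leakage-evaluation experiment
#'
#' Desk-scale version of the evaluation protocol: for every seed, a fresh
#' synthetic cohort is generated and, under each condition (`original` plus
#' one per encoding method), a target-task model is trained, its test-split
#' task AUROC recorded, every latent attribute probed from the penultimate
#' embedding, and the mutual information between reduced inputs and
#' test-split embeddings estimated. The input side of the MI estimate is
#' always the original (pre-encoding) series, so the value reads directly
#' as retained information about the raw data and is comparable across
#' conditions. Results are aggregated as mean and sd over seeds, and
#' relative drops versus the `original` condition are computed per seed as
#' `100 * (v_orig - v_enc) / v_orig`, then averaged (mean-of-drops).
#'
#' @param cohort_cfg A [cohort_config()]; its `seed` field is re-derived
#'   per experiment seed.
#' @param seeds Integer vector of experiment seeds (>= 1 seed).
#' @param arch Target-model architecture, see [train_target_model()].
#' @param methods Encoding conditions; any of `"projection"`, `"quantum"`,
#'   `"identity"` (an identity projection matrix -- a null encoding useful
#'   as a negative control).
#' @param segment_length Segment length `n`, default 4.
#' @param layers Random-circuit depth for the quantum condition, default 2.
#' @param epochs,probe_epochs Training epochs for target models and probes.
#' @param mi_k Neighbour count of the KSG estimator, default 3.
#' @param mi_reductions Input reductions for the MI estimate.
#' @param verbose Print progress to stderr.
#' @return An object of class `leakage_report`: list with `results` (long
#'   data.frame: condition, metric, attribute, seed, value), `summary`
#'   (mean/sd per condition-metric-attribute), `drops` (relative drops vs
#'   original, %), `config`, `seeds`.
#' @export
run_leakage_experiment <- function(cohort_cfg = cohort_config(), seeds = 1:5,
                                   arch = "mlp",
                                   methods = c("projection", "quantum"),
                                   segment_length = 4, layers = 2,
                                   epochs = 20, probe_epochs = 30, mi_k = 3,
                                   mi_reductions = c("averaged", "vectorized"),
                                   verbose = FALSE) {
  if (length(seeds) < 1) abort_enctsf("need at least one seed", "enctsf_validation_error")
  methods <- match.arg(methods, c("projection", "quantum", "identity"), several.ok = TRUE)
  rows <- list()
  note <- function(...) if (verbose) message(sprintf(...))
  add <- function(condition, metric, attribute, seed, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      condition = condition, metric = metric, attribute = attribute,
      seed = seed, value = value, stringsAsFactors = FALSE)
  }
  for (s in seeds) {
    cfg <- cohort_cfg
    cfg$seed <- as.integer(derive_seed(s, 1))
    ds <- generate_cohort(cfg)
    conditions <- list(original = ds)
    for (m in methods) {
      cond <- tryCatch({
        if (m == "projection") {
          key <- sample_projection_key(segment_length, seed = derive_seed(s, 2))
          encode_cohort(ds, key, framework_config(segment_length))
        } else if (m == "quantum") {
          key <- build_random_circuit(segment_length, layers, seed = derive_seed(s, 3))
          key$scaling <- minmax_stats(ds, split = "train")
          encode_cohort(ds, key, framework_config(segment_length))
        } else {
          key <- sample_projection_key(segment_length, seed = 1)
          key$matrix <- diag(segment_length)
          key$key_id <- "identity"
          encode_cohort(ds, key, framework_config(segment_length))
        }
      }, enctsf_error = function(e) {
        abort_enctsf(sprintf("[condition %s, seed %d] %s", m, s, conditionMessage(e)),
                     class(e)[1])
      })
      conditions[[m]] <- cond
    }
    te <- ds$split == "test"
    inputs_red <- lapply(mi_reductions, function(mode) {
      t(vapply(ds$examples[te], reduce_inputs, mode = mode,
               numeric(length(reduce_inputs(ds$examples[1][[1]], mode)))))
    })
    names(inputs_red) <- mi_reductions
    for (cond_name in names(conditions)) {
      note("seed %d, condition %s: training %s model", s, cond_name, arch)
      cds <- conditions[[cond_name]]
      model <- train_target_model(cds, arch, seed = derive_seed(s, 4), epochs = epochs)
      add(cond_name, "task_auroc", NA_character_, s,
          auroc(predict_score(model, cds)[te], cds$task_labels[te]))
      for (attrib in names(cds$attributes)) {
        pr <- probe_latent(model, cds, attrib, seed = derive_seed(s, 5),
                           epochs = probe_epochs)
        add(cond_name, "probe_auroc", attrib, s, pr$auroc)
      }
      Emb <- embed(model, cds)[te, , drop = FALSE]
      for (mode in mi_reductions) {
        mi <- estimate_mi(inputs_red[[mode]], Emb, k = mi_k,
                          input_reduction = mode,
                          jitter_seed = derive_seed(s, 6))
        add(cond_name, "mi", mode, s, mi$value)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ condition + metric + attribute,
                          data = transform(results, attribute = ifelse(is.na(attribute), "", attribute)),
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary_df <- data.frame(condition = agg$condition, metric = agg$metric,
                           attribute = agg$attribute,
                           mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                           stringsAsFactors = FALSE)
  ## per-seed relative drops vs the original condition
  drops <- NULL
  orig <- results[results$condition == "original", ]
  for (cond_name in setdiff(unique(results$condition), "original")) {
    enc <- results[results$condition == cond_name, ]
    m <- merge(orig, enc, by = c("metric", "attribute", "seed"),
               suffixes = c("_orig", "_enc"))
    m$drop_pct <- ifelse(m$value_orig > 0,
                         100 * (m$value_orig - m$value_enc) / m$value_orig, NA_real_)
    drops <- rbind(drops, data.frame(condition = cond_name, metric = m$metric,
                                     attribute = m$attribute, seed = m$seed,
                                     drop_pct = m$drop_pct, stringsAsFactors = FALSE))
  }
  structure(list(results = results, summary = summary_df, drops = drops,
                 config = list(cohort = unclass(cohort_cfg), arch = arch,
                               methods = methods, segment_length = segment_length,
                               layers = layers, epochs = epochs,
                               probe_epochs = probe_epochs, mi_k = mi_k,
                               mi_reductions = mi_reductions),
                 seeds = as.integer(seeds)),
            class = "leakage_report")
}

#' @export
print.leakage_report <- function(x, ...) {
  cat(sprintf("<leakage_report: %d seeds, conditions: %s>\n",
              length(x$seeds), paste(unique(x$results$condition), collapse = ", ")))
  s <- x$summary
  s$what <- trimws(paste(s$metric, s$attribute))
  for (w in unique(s$what)) {
    sub <- s[s$what == w, ]
    cat(sprintf("  %-24s %s\n", w,
                paste(sprintf("%s=%.3f±%.3f", sub$condition, sub$mean, sub$sd),
                      collapse = "  ")))
  }
  if (!is.null(x$drops)) {
    d <- stats::aggregate(drop_pct ~ condition + metric, data = x$drops, FUN = mean)
    cat("  mean relative drops vs original (%):\n")
    for (i in seq_len(nrow(d))) {
      cat(sprintf("    %-12s %-12s %+.2f%%\n", d$condition[i], d$metric[i], d$drop_pct[i]))
    }
  }
  invisible(x)
}

#' @export
summary.leakage_report <- function(object, ...) object$summary

#' Serialize a leakage report
#'
#' Writes `report.json` (summary, drops, config, seeds) and a flat
#' `results.csv` of `(condition, metric, attribute, seed, value)` rows.
#'
#' @param report A `leakage_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_leakage_report <- function(report, dir) {
  stopifnot(inherits(report, "leakage_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$results, file.path(dir, "results.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, drops = report$drops,
         config = report$config, seeds = report$seeds),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows")
  invisible(dir)
}
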