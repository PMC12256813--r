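#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: where the cohort comes
#' from (a directory of recordings plus participants table, or a
#' [synth_cohort_config()] to simulate one), the preprocessing and model
#' settings, which features to extract, and which classifier families to
#' evaluate.
#'
#' @param input a cohort directory path, or a [synth_cohort_config()].
#' @param output_dir run directory to create.
#' @param format recording format for directory input (see
#'   [read_recording()]).
#' @param preprocess_cfg a [preprocess_config()], or NULL to skip
#'   filtering (synthetic input is already band-limited by construction).
#' @param T_ms model window duration, milliseconds.
#' @param scheme a [region_scheme()].
#' @param eq2_constant sink-index additive constant.
#' @param features subset of `c("sink", "bandpower", "timefreq")`.
#' @param families classifier families for [evaluate_ovr()].
#' @param repeats LOOCV repetitions per family.
#' @param seed master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir, format = "auto",
                            preprocess_cfg = NULL, T_ms = 125,
                            scheme = region_scheme(),
                            eq2_constant = sqrt(2),
                            features = c("sink", "bandpower"),
                            families = "random_forest", repeats = 8,
                            seed = 1) {
  features <- match.arg(features, c("sink", "bandpower", "timefreq"),
                        several.ok = TRUE)
  if (!inherits(input, "synth_cohort_config") && !dir.exists(input))
    stop("config error: input directory does not exist: ", input,
         call. = FALSE)
  if (T_ms <= 0) stop("config error: T_ms must be positive", call. = FALSE)
  bad <- setdiff(families, classifier_families())
  if (length(bad) > 0)
    stop("config error: unknown classifier families: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(input = input, output_dir = output_dir, format = format,
                 preprocess_cfg = preprocess_cfg, T_ms = T_ms,
                 scheme = scheme, eq2_constant = eq2_constant,
                 features = features, families = families,
                 repeats = repeats, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stable_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: load or simulate the cohort, preprocess,
#' fit per-subject dynamic network models, compute sink maps and regional
#' markers, extract the requested baseline features, evaluate every
#' requested classifier with repeated LOOCV, and run the nonparametric
#' group statistics. All tables, reports and a provenance record are
#' written under the run directory. Subjects failing preprocessing are
#' excluded and listed, not fatal.
#'
#' @param cfg a [pipeline_config()].
#' @return The run directory path, invisibly. Files written: per-subject
#'   `sinkmaps/<id>.tsv`, `markers.csv`, `reports/<feature>_<family>.json`,
#'   `stats.json`, `provenance.json`, `excluded.txt` (when any).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config"))
    stop("expected a 'pipeline_config'", call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$output_dir, "sinkmaps"), showWarnings = FALSE)
  dir.create(file.path(cfg$output_dir, "reports"), showWarnings = FALSE)
  set.seed(cfg$seed)
  # ---- cohort ----
  if (inherits(cfg$input, "synth_cohort_config")) {
    synth <- generate_cohort(cfg$input, scheme = cfg$scheme)
    cohort <- synth$cohort
    get_rec <- function(i) synth$recordings[[i]]
  } else {
    cohort <- read_cohort(cfg$input)
    cohort <- cohort[!is.na(cohort$recording_path), , drop = FALSE]
    get_rec <- function(i) read_recording(cohort$recording_path[i],
                                          format = cfg$format,
                                          subject_id = cohort$subject_id[i])
  }
  n <- nrow(cohort)
  rows <- vector("list", n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    sid <- cohort$subject_id[i]
    t0 <- Sys.time()
    res <- tryCatch({
      rec <- get_rec(i)
      if (!is.null(cfg$preprocess_cfg))
        rec <- preprocess(rec, cfg$preprocess_cfg)
      sm <- sink_map(fit_dnm(rec, T_ms = cfg$T_ms),
                     eq2_constant = cfg$eq2_constant)
      tsv <- data.frame(channel = sm$channel_labels, sm$si,
                        check.names = FALSE)
      names(tsv)[-1] <- sprintf("%.3f", sm$window_s)
      utils::write.table(tsv, file.path(cfg$output_dir, "sinkmaps",
                                        paste0(sid, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      row <- subject_marker(sm, cfg$scheme)
      if ("bandpower" %in% cfg$features) {
        bp <- band_power(rec, cfg$scheme)
        row$alpha_power_ratio <- bp$ratio[["alpha"]]
      }
      if ("timefreq" %in% cfg$features) {
        tf <- timefreq_features(rec)
        row <- cbind(row, as.data.frame(as.list(tf), check.names = FALSE))
      }
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, paste0(sid, ": ", conditionMessage(res)))
      message("excluding ", sid, ": ", conditionMessage(res))
    } else {
      res$group <- cohort$group[i]
      rows[[i]] <- res
    }
    message(sprintf("processed %s (%.1f s)", sid,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  if (all(vapply(rows, is.null, TRUE)))
    stop("no subject produced markers (", length(excluded),
         " excluded; is the input directory and format right?)",
         call. = FALSE)
  markers <- do.call(rbind, lapply(rows[!vapply(rows, is.null, TRUE)],
                                   function(r) r[, c("subject_id", "group",
                                                     setdiff(names(r),
                                                             c("subject_id",
                                                               "group")))]))
  utils::write.csv(markers, file.path(cfg$output_dir, "markers.csv"),
                   row.names = FALSE)
  if (length(excluded) > 0)
    writeLines(excluded, file.path(cfg$output_dir, "excluded.txt"))
  # ---- classification ----
  feature_cols <- list(sink = "si_ratio", bandpower = "alpha_power_ratio")
  if ("timefreq" %in% cfg$features) {
    tf_cols <- grep("\\.d[0-9]\\.", names(markers), value = TRUE)
    feature_cols$timefreq <- tf_cols
  }
  if (length(unique(markers$group)) >= 2 && nrow(markers) >= 4) {
    for (feat in intersect(cfg$features,
                           c("sink", "bandpower", "timefreq"))) {
      cols <- feature_cols[[feat]]
      if (is.null(cols) || !all(cols %in% names(markers))) next
      x <- as.matrix(markers[, cols, drop = FALSE])
      if (identical(feat, "timefreq") && ncol(x) > 5) {
        x <- pca_reduce(x, k = 5)$train
        colnames(x) <- paste0("pc", seq_len(ncol(x)))
      }
      for (fam in cfg$families) {
        got <- tryCatch({
          reps <- repeat_loocv(x, markers$group, family = fam,
                               repeats = cfg$repeats, base_seed = cfg$seed)
          rep1 <- evaluate_ovr(x, markers$group, family = fam,
                               seed = cfg$seed)
          TRUE
        }, error = function(e) {
          message("classifier ", fam, " on ", feat, " failed: ",
                  conditionMessage(e))
          FALSE
        })
        if (!got) next
        .stable_json(
          list(feature = feat, classifier = fam, seed = cfg$seed,
               n_subjects = nrow(x),
               per_class_auc = as.list(rep1$per_class_auc),
               micro_auc = rep1$micro_auc, precision = rep1$precision,
               confusion = as.data.frame.matrix(rep1$confusion),
               repeats = reps),
          file.path(cfg$output_dir, "reports",
                    paste0(feat, "_", fam, ".json")))
      }
    }
  }
  # ---- group statistics on the primary marker ----
  groups <- split(markers$si_ratio, markers$group)
  stats_out <- list()
  if (length(groups) >= 2 && all(lengths(groups) >= 2)) {
    kw <- kruskal_wallis(groups)
    dunn <- dunn_posthoc(groups)
    stats_out <- list(
      kruskal_wallis = list(H = kw$statistic, p = kw$p_value,
                            tier = kw$tier),
      dunn = lapply(dunn, function(d)
        list(comparison = d$comparison, z = d$statistic, p = d$p_value,
             adjusted_p = d$adjusted_p, tier = d$tier)))
  }
  .stable_json(stats_out, file.path(cfg$output_dir, "stats.json"))
  .stable_json(
    list(package = "sinkindex",
         version = as.character(utils::packageVersion("sinkindex")),
         r_version = R.version.string, seed = cfg$seed,
         T_ms = cfg$T_ms, eq2_constant = cfg$eq2_constant,
         features = cfg$features, families = cfg$families,
         n_subjects = nrow(markers), excluded = length(excluded),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(cfg$output_dir, "provenance.json"))
  invisible(cfg$output_dir)
}

#' Interpolated scalp topography grid
#'
#' Inverse-distance-weighted interpolation of per-channel values onto a
#' regular grid over the unit-disc scalp outline (top view, nose up),
#' masked outside the head.
#'
#' @param values named numeric vector (names = 10-20 channel labels).
#' @param gridsize grid resolution per axis.
#' @param power inverse-distance weighting exponent.
#' @return List with `x`, `y` (grid axes) and `z` (matrix, NA outside the
#'   scalp disc).
#' @export
topomap_grid <- function(values, gridsize = 67, power = 2) {
  coords <- electrode_coords()
  keep <- intersect(names(values), coords$channel)
  if (length(keep) < 3)
    stop("validation error: need >= 3 channels with known positions",
         call. = FALSE)
  cx <- coords$x[match(keep, coords$channel)]
  cy <- coords$y[match(keep, coords$channel)]
  v <- values[keep]
  ax <- seq(-1.05, 1.05, length.out = gridsize)
  z <- matrix(NA_real_, gridsize, gridsize)
  for (i in seq_len(gridsize)) for (j in seq_len(gridsize)) {
    if (ax[i]^2 + ax[j]^2 > 1.1) next
    d2 <- (cx - ax[i])^2 + (cy - ax[j])^2
    hit <- d2 < 1e-12
    z[i, j] <- if (any(hit)) v[which(hit)[1]]
               else sum(v / d2^(power / 2)) / sum(1 / d2^(power / 2))
  }
  list(x = ax, y = ax, z = z)
}

#' Render figures for a completed run
#'
#' Produces, under `<run_dir>/figures`: a channels-by-time sink-index
#' heatmap per subject, a scalp topomap of each subject's time-averaged
#' sink index, and FT/CPO/ratio boxplots per cohort.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @param format `"png"` or `"pdf"`.
#' @return Character vector of figure paths, invisibly.
#' @export
render_outputs <- function(run_dir, format = c("png", "pdf")) {
  format <- match.arg(format)
  markers_path <- file.path(run_dir, "markers.csv")
  maps_dir <- file.path(run_dir, "sinkmaps")
  if (!file.exists(markers_path) || !dir.exists(maps_dir))
    stop("validation error: ", run_dir,
         " is not a completed run directory", call. = FALSE)
  fig_dir <- file.path(run_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  open_dev <- function(path) {
    if (format == "png") grDevices::png(path, width = 900, height = 600)
    else grDevices::pdf(sub("png$", "pdf", path), width = 9, height = 6)
  }
  made <- character(0)
  markers <- utils::read.csv(markers_path)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  for (tsv in list.files(maps_dir, pattern = "\\.tsv$",
                         full.names = TRUE)) {
    sid <- sub("\\.tsv$", "", basename(tsv))
    tab <- utils::read.delim(tsv, check.names = FALSE)
    z <- as.matrix(tab[, -1, drop = FALSE])
    rownames(z) <- tab$channel
    keep <- colSums(is.na(z)) == 0
    # heatmap
    f1 <- file.path(fig_dir, paste0(sid, "_heatmap.", format))
    open_dev(f1)
    graphics::image(x = as.numeric(colnames(z)[keep]),
                    y = seq_len(nrow(z)), z = t(z[, keep, drop = FALSE]),
                    col = pal, xlab = "time (s)", ylab = "", yaxt = "n",
                    main = paste("Sink index:", sid))
    graphics::axis(2, at = seq_len(nrow(z)), labels = rownames(z),
                   las = 2, cex.axis = 0.7)
    grDevices::dev.off()
    # topomap of the time-averaged sink index
    avg <- rowMeans(z, na.rm = TRUE)
    grid <- topomap_grid(avg)
    f2 <- file.path(fig_dir, paste0(sid, "_topomap.", format))
    open_dev(f2)
    graphics::image(grid$x, grid$y, grid$z, col = pal, asp = 1,
                    xlab = "", ylab = "", axes = FALSE,
                    main = paste("Time-averaged sink index:", sid))
    coords <- electrode_coords()
    graphics::points(coords$x, coords$y, pch = 20, cex = 0.6)
    graphics::text(coords$x, coords$y, coords$channel, pos = 3,
                   cex = 0.6)
    grDevices::dev.off()
    made <- c(made, f1, f2)
  }
  if (nrow(markers) > 0 && length(unique(markers$group)) > 1) {
    f3 <- file.path(fig_dir, paste0("cohort_boxplots.", format))
    open_dev(f3)
    op <- graphics::par(mfrow = c(1, 3))
    graphics::boxplot(si_ft ~ group, markers, main = "FT sink index",
                      xlab = "", ylab = "SI")
    graphics::boxplot(si_cpo ~ group, markers, main = "CPO sink index",
                      xlab = "", ylab = "SI")
    graphics::boxplot(si_ratio ~ group, markers, main = "FT/CPO ratio",
                      xlab = "", ylab = "ratio")
    graphics::par(op)
    grDevices::dev.off()
    made <- c(made, f3)
  }
  invisible(made)
}
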