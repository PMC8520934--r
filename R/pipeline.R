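#' Pipeline configuration
#'
#' One config drives the full study workflow: simulate (or load) the three
#' tables, preprocess, PCA, PLS-DA in rDCV with permutation testing, ComDim,
#' MB-PLSDA, correlation networks and the milk trend analysis. The global
#' seed fans out to per-stage seeds through a fixed stage-name derivation,
#' so stages are individually reproducible.
#'
#' @param out_dir directory for result bundles.
#' @param seed global integer seed.
#' @param simulate a [dyad_config()] used to generate the dataset; mutually
#'   exclusive with `tables`.
#' @param tables optional named list of paths (`stool`, `otu`, `milk`,
#'   `metadata`, `milk_metadata`) to load instead of simulating.
#' @param comparison length-2 period labels for the single-block PLS-DA
#'   (default BM vs FBM).
#' @param window_comparison two day windows (list of length-2 integer
#'   ranges) defining the early-vs-late contrast for MB-PLSDA and the
#'   networks (default days 103-175 vs 219-268).
#' @param dcv a [dcv_config()] (seed overridden by the stage seed).
#' @param n_perm permutation randomizations (study default 1000).
#' @param comdim_k number of ComDim common components.
#' @param r_threshold,p_threshold correlation network thresholds.
#' @param otu_filter_pct OTU inclusion threshold in percent (default 1).
#' @param n_boot bootstrap resamples for the milk trend.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            simulate = dyad_config(seed = seed),
                            tables = NULL,
                            comparison = c("BM", "FBM"),
                            window_comparison = list(early = c(103, 175),
                                                     late = c(219, 268)),
                            dcv = dcv_config(),
                            n_perm = 1000,
                            comdim_k = 2,
                            r_threshold = 0.6, p_threshold = 0.05,
                            otu_filter_pct = 1,
                            n_boot = 500) {
  valid <- c("BM", "FBM", "W")
  if (!all(comparison %in% valid) || length(comparison) != 2)
    stop("undefined period label in comparison: ",
         paste(setdiff(comparison, valid), collapse = ", "))
  if (length(window_comparison) != 2)
    stop("window_comparison must give exactly two day windows")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, tables = tables,
                 comparison = comparison,
                 window_comparison = window_comparison,
                 dcv = dcv, n_perm = as.integer(n_perm),
                 comdim_k = as.integer(comdim_k),
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 otu_filter_pct = otu_filter_pct,
                 n_boot = as.integer(n_boot)),
            class = "pipeline_config")
}

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

#' Run the full dyad analysis pipeline
#'
#' Executes the stages in order — simulate/load, preprocess, PCA, PLS-DA in
#' rDCV with permutation test, ComDim, MB-PLSDA, correlation networks, milk
#' trend — writing a result bundle per stage under `cfg$out_dir` and
#' returning a run report. Any stage failure aborts with the stage name.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return a `pipeline_report` (also serialized to `report.json`).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message("[dyadomics] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  data <- stage("data", {
    if (!is.null(cfg$tables)) {
      stool <- read_feature_table(cfg$tables$stool)
      otu <- read_feature_table(cfg$tables$otu)
      milk <- read_feature_table(cfg$tables$milk)
      md <- utils::read.csv(cfg$tables$metadata, stringsAsFactors = FALSE)
      meta <- sample_metadata(md$sample_id, md$day_after_birth, md$day_block)
      mmd <- utils::read.csv(cfg$tables$milk_metadata,
                             stringsAsFactors = FALSE)
      milk_meta <- sample_metadata(mmd$sample_id, mmd$day_after_birth,
                                   mmd$day_block)
      milk_meta$suction <- mmd$suction
      list(stool = list(table = stool, metadata = meta, truth = NULL),
           otu = list(table = otu, truth = NULL),
           milk = list(table = milk, metadata = milk_meta, truth = NULL))
    } else {
      sim <- cfg$simulate
      sim$seed <- stage_seed(cfg$seed, "simulate")
      simulate_dyad(sim, out_dir = file.path(cfg$out_dir, "simulated"))
    }
  })
  meta <- data$stool$metadata

  prep <- stage("preprocess", {
    otu_f <- filter_otus(close_composition(data$otu$table),
                         cfg$otu_filter_pct)
    auto <- autoscale(data$stool$table)
    list(otu = otu_f, stool_scaled = auto$table)
  })

  pca <- stage("pca", {
    fit <- pca_fit(prep$stool_scaled, K = 2)
    write_result_bundle(fit, file.path(cfg$out_dir, "pca"),
                        extra = list(seed = cfg$seed))
    fit
  })

  dcv_res <- stage("plsda-dcv", {
    keep <- meta$diet_period %in% cfg$comparison
    d <- cfg$dcv
    d$seed <- stage_seed(cfg$seed, "plsda-dcv")
    res <- rdcv(ft_values(data$stool$table)[keep, , drop = FALSE],
                meta$diet_period[keep], d, classes = cfg$comparison)
    perm <- permutation_test(
      ft_values(data$stool$table)[keep, , drop = FALSE],
      meta$diet_period[keep], d, cfg$n_perm, observed = res)
    write_result_bundle(res, file.path(cfg$out_dir, "plsda_dcv"),
                        extra = list(seed = d$seed))
    write_result_bundle(perm, file.path(cfg$out_dir, "plsda_dcv"),
                        extra = list(seed = d$seed))
    list(dcv = res, perm = perm)
  })

  window_label <- function(md) {
    w <- cfg$window_comparison
    lab <- rep(NA_character_, nrow(md))
    for (k in seq_along(w)) {
      lab[md$day_after_birth >= w[[k]][1] &
            md$day_after_birth <= w[[k]][2]] <- names(w)[k]
    }
    lab
  }

  bset <- stage("align", align_blocks(list(metabolome = data$stool$table,
                                           metagenome = prep$otu)))

  comdim <- stage("comdim", {
    pp <- preprocess_blocks(bset)
    fit <- comdim_fit(pp$blocks, K = cfg$comdim_k)
    write_result_bundle(fit, file.path(cfg$out_dir, "comdim"),
                        extra = list(seed = cfg$seed))
    fit
  })

  mb <- stage("mbplsda", {
    common_meta <- meta[match(bset$common_samples, meta$sample_id), ]
    lab <- window_label(common_meta)
    if (anyNA(lab)) stop("samples outside both day windows")
    d <- cfg$dcv
    d$seed <- stage_seed(cfg$seed, "mbplsda")
    fit <- mbplsda_fit(bset, lab, d, classes = names(cfg$window_comparison),
                       n_perm = cfg$n_perm)
    write_result_bundle(fit$dcv, file.path(cfg$out_dir, "mbplsda"),
                        extra = list(seed = d$seed))
    if (!is.null(fit$permutation))
      write_result_bundle(fit$permutation, file.path(cfg$out_dir, "mbplsda"),
                          extra = list(seed = d$seed))
    fit
  })

  nets <- stage("network", {
    lab <- window_label(meta)
    out <- list()
    # variables constant within a window (e.g. below-detection HMOs during
    # weaning) have no defined correlation and are excluded from that
    # window's network
    drop_constant <- function(m) m[, apply(m, 2, stats::sd) > 0,
                                   drop = FALSE]
    for (w in names(cfg$window_comparison)) {
      keep <- !is.na(lab) & lab == w
      net <- pearson_network(
        feature_table(drop_constant(
          ft_values(data$stool$table)[keep, , drop = FALSE])),
        r_threshold = cfg$r_threshold, p_threshold = cfg$p_threshold)
      write_result_bundle(net, file.path(cfg$out_dir,
                                         paste0("network_", w)),
                          extra = list(seed = cfg$seed, window = w))
      out[[w]] <- net
    }
    # cross-omics network on the samples with both blocks
    cm <- meta[match(bset$common_samples, meta$sample_id), ]
    wlab <- window_label(cm)
    keep <- !is.na(wlab) & wlab == names(cfg$window_comparison)[1]
    out$cross <- pearson_network(
      feature_table(ft_values(bset$blocks$metabolome)[keep, , drop = FALSE]),
      feature_table(ft_values(bset$blocks$metagenome)[keep, , drop = FALSE]),
      r_threshold = cfg$r_threshold, p_threshold = cfg$p_threshold)
    write_result_bundle(out$cross, file.path(cfg$out_dir, "network_cross"),
                        extra = list(seed = cfg$seed))
    out
  })

  trend <- stage("milk-trend", {
    d <- cfg$dcv
    d$seed <- stage_seed(cfg$seed, "milk-trend")
    fit <- milk_trend(data$milk$table, data$milk$metadata, d,
                      n_boot = cfg$n_boot)
    write_result_bundle(fit, file.path(cfg$out_dir, "milk_trend"),
                        extra = list(seed = d$seed))
    fit
  })

  utils::write.csv(meta, file.path(cfg$out_dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)

  report <- structure(list(
    seed = cfg$seed,
    pca_explained = pca$explained,
    dcv_summary = dcv_res$dcv$summary,
    dcv_p_values = dcv_res$perm$p_value,
    markers = dcv_res$dcv$markers,
    comdim_saliences = comdim$saliences,
    mbplsda_summary = mb$dcv$summary,
    mbplsda_p_values = if (!is.null(mb$permutation))
      mb$permutation$p_value,
    mbplsda_markers = mb$markers,
    network_edges = vapply(nets, function(n)
      sum(n$mask[upper.tri(n$mask)]), numeric(1)),
    milk_trends = trend$trends[trend$trends$direction != 0, ],
    milk_r2y = trend$r2y[length(trend$r2y)],
    milk_q2y = trend$q2y[trend$n_lv]),
    class = "pipeline_report")
  jsonlite::write_json(
    lapply(report, function(x) if (is.matrix(x))
      as.data.frame(cbind(stat = rownames(x), as.data.frame(x))) else x),
    file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  say("pipeline complete: ", cfg$out_dir)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("dyadomics pipeline report\n")
  cat(sprintf("  PCA explained variance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$pca_explained),
                    collapse = ", ")))
  cat(sprintf("  PLS-DA ccr = %.1f%% +/- %.1f%% | p(NMC) = %.4g\n",
              100 * x$dcv_summary["mean", "ccr"],
              100 * x$dcv_summary["sd", "ccr"], x$dcv_p_values["nmc"]))
  cat(sprintf("  %d PLS-DA markers; MB-PLSDA ccr = %.1f%%%s\n",
              nrow(x$markers), 100 * x$mbplsda_summary["mean", "ccr"],
              if (!is.null(x$mbplsda_p_values))
                sprintf(" | p(NMC) = %.4g", x$mbplsda_p_values["nmc"])
              else ""))
  cat("  ComDim saliences:\n")
  print(round(x$comdim_saliences, 4))
  cat(sprintf("  network edges: %s\n",
              paste(sprintf("%s=%d", names(x$network_edges),
                            x$network_edges), collapse = ", ")))
  cat(sprintf("  milk trend: R2Y = %.3f, Q2Y = %.3f, %d trending variables\n",
              x$milk_r2y, x$milk_q2y, nrow(x$milk_trends)))
  invisible(x)
}

#' Render figures from a pipeline output directory
#'
#' Reads the result bundles written by [run_pipeline()] and renders basic
#' PNG figures: PCA/ComDim scores colored by day block, rank-product bar
#' plots colored by direction, permutation histograms with the observed
#' value marked in red, and red/blue correlation heatmaps.
#'
#' @param bundle_dir the pipeline output directory.
#' @param out_dir where to write figures (default `bundle_dir/figures`).
#' @return character vector of figure files written, invisibly.
#' @export
make_figures <- function(bundle_dir, out_dir = file.path(bundle_dir,
                                                         "figures")) {
  need <- function(p) {
    if (!file.exists(p)) stop("missing bundle file: ", p)
    p
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fig <- function(name, w = 900, h = 700, expr) {
    p <- file.path(out_dir, name)
    grDevices::png(p, width = w, height = h, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    files <<- c(files, p)
  }
  meta <- utils::read.csv(need(file.path(bundle_dir, "metadata.csv")),
                          stringsAsFactors = FALSE)
  block_col <- function(ids) {
    blocks <- meta$day_block[match(ids, meta$sample_id)]
    pal <- grDevices::hcl.colors(length(unique(meta$day_block)), "Dark 3")
    stats::setNames(pal[match(blocks, unique(meta$day_block))], ids)
  }
  scores_plot <- function(path, lab1, lab2, main) {
    sc <- utils::read.csv(need(path), check.names = FALSE)
    cols <- block_col(sc$id)
    graphics::plot(sc[[2]], sc[[3]], col = cols, pch = 19,
                   xlab = lab1, ylab = lab2, main = main)
    graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
    graphics::legend("topright", legend = unique(meta$day_block),
                     col = grDevices::hcl.colors(
                       length(unique(meta$day_block)), "Dark 3"),
                     pch = 19, cex = 0.8)
  }
  # PCA scores with explained-variance axis labels
  expl <- utils::read.csv(need(file.path(bundle_dir, "pca",
                                         "explained.csv")))
  fig("pca_scores.png", expr = scores_plot(
    file.path(bundle_dir, "pca", "scores.csv"),
    sprintf("PC1 (%.0f%%)", 100 * expl$fraction[1]),
    sprintf("PC2 (%.0f%%)", 100 * expl$fraction[2]), "PCA scores"))
  # permutation histograms + marker bar plots for each DCV bundle
  for (b in c("plsda_dcv", "mbplsda")) {
    nullp <- file.path(bundle_dir, b, "fom_null.csv")
    if (!file.exists(nullp)) next
    null <- utils::read.csv(nullp, check.names = FALSE)[, -1]
    pv <- utils::read.csv(need(file.path(bundle_dir, b, "p_values.csv")))
    fig(paste0(b, "_permutation.png"), w = 1200, h = 450, expr = {
      graphics::par(mfrow = c(1, 3))
      for (fom in c("nmc", "auroc", "dq2")) {
        obs <- pv$observed[pv$fom == fom]
        graphics::hist(null[[fom]], breaks = 30, col = "grey80",
                       border = "white", main = toupper(fom),
                       xlab = fom,
                       xlim = range(c(null[[fom]], obs)))
        graphics::abline(v = obs, col = "red", lwd = 2)
      }
    })
    mk <- utils::read.csv(need(file.path(bundle_dir, b, "markers.csv")),
                          stringsAsFactors = FALSE)
    fig(paste0(b, "_rank_product.png"), expr = {
      if (!nrow(mk)) {
        graphics::plot.new()
        graphics::title(main = "rank product")
        graphics::text(0.5, 0.5, "no markers selected (RP < mean RP)")
      } else {
        dircol <- if ("direction" %in% names(mk))
          ifelse(mk$direction == mk$direction[1], "firebrick", "steelblue")
        else "grey50"
        graphics::par(mar = c(9, 4, 2, 1))
        graphics::barplot(mk$rank_product, names.arg = mk$variable,
                          las = 2, col = dircol, cex.names = 0.7,
                          ylab = "rank product",
                          main = "candidate markers (RP < mean RP)")
      }
    })
  }
  # ComDim scores
  fig("comdim_scores.png", expr = scores_plot(
    file.path(bundle_dir, "comdim", "scores.csv"),
    "CC1", "CC2", "ComDim common scores"))
  # correlation heatmaps, red positive / blue negative
  for (d in list.files(bundle_dir, pattern = "^network")) {
    rp <- file.path(bundle_dir, d, "r.csv")
    if (!file.exists(rp)) next
    r <- utils::read.csv(rp, row.names = 1, check.names = FALSE)
    r <- as.matrix(r)
    fig(paste0(d, "_heatmap.png"), w = 900, h = 850, expr = {
      pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
      graphics::par(mar = c(8, 8, 2, 1))
      graphics::image(seq_len(ncol(r)), seq_len(nrow(r)),
                      t(r[rev(seq_len(nrow(r))), ]), zlim = c(-1, 1),
                      col = pal, axes = FALSE, xlab = "", ylab = "",
                      main = paste("Pearson r:", d))
      graphics::axis(1, seq_len(ncol(r)), colnames(r), las = 2,
                     cex.axis = 0.5)
      graphics::axis(2, seq_len(nrow(r)), rev(rownames(r)), las = 2,
                     cex.axis = 0.5)
    })
  }
  invisible(files)
}
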