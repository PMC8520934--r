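#' Configuration for the synthetic dyad-data generator
#'
#' Defaults reproduce the shape of the longitudinal mother-infant dyad
#' design this pipeline targets: 32 stool samples gathered in five sets of
#' consecutive days between day 103 and day 268 after birth, three diet
#' periods (BM = exclusive breastfeeding, FBM = breastfeeding plus fruit
#' snack, W = weaning), 49 quantified stool metabolites, 48 genus-level
#' OTUs, and 16S metagenomics available for only 25 of the 32 samples.
#'
#' Period effects enter on the log scale as additive shifts; `effect_size`
#' is the standardized (log-scale) mean shift between contrasted periods.
#'
#' @param seed integer seed; the same seed and config give a bit-identical
#'   dataset.
#' @param n_per_block samples per consecutive-day block (sums to 32).
#' @param day_blocks named list of day ranges for the five blocks.
#' @param n_metabolites stool metabolites (>= 19; 19 are structured).
#' @param n_milk_metabolites milk metabolites (>= 7; 7 are structured).
#' @param n_otus OTUs (>= 20).
#' @param effect_size standardized log-scale shift between periods.
#' @param noise_sd within-period log-scale standard deviation.
#' @param n_factor latent factors per period inducing correlations.
#' @param detection_floor smallest reportable concentration.
#' @param metagenome_subset sample ids with 16S data; NULL drops the last 7
#'   metabolome samples deterministically.
#' @return a `dyad_config` list.
#' @export
dyad_config <- function(seed = 1,
                        n_per_block = c(6, 3, 10, 8, 5),
                        day_blocks = list("103-108" = 103:108,
                                          "145-147" = 145:147,
                                          "165-175" = 165:175,
                                          "219-228" = 219:228,
                                          "262-268" = 262:268),
                        n_metabolites = 49,
                        n_milk_metabolites = 39,
                        n_otus = 48,
                        effect_size = 2.0,
                        noise_sd = 1.0,
                        n_factor = 2,
                        detection_floor = 1e-3,
                        metagenome_subset = NULL) {
  if (length(n_per_block) != length(day_blocks))
    stop("n_per_block inconsistent with day_blocks")
  if (any(n_per_block > lengths(day_blocks)))
    stop("n_per_block inconsistent with day_blocks: ",
         "more samples than days in a block")
  if (n_metabolites < 19) stop("n_metabolites must be at least 19")
  if (n_milk_metabolites < 7) stop("n_milk_metabolites must be at least 7")
  if (n_otus < 20) stop("n_otus must be at least 20")
  structure(list(seed = as.integer(seed),
                 n_per_block = as.integer(n_per_block),
                 day_blocks = day_blocks,
                 n_metabolites = as.integer(n_metabolites),
                 n_milk_metabolites = as.integer(n_milk_metabolites),
                 n_otus = as.integer(n_otus),
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 n_factor = as.integer(n_factor),
                 detection_floor = detection_floor,
                 metagenome_subset = metagenome_subset),
            class = "dyad_config")
}

# deterministic sampling-day layout and metadata shared by all generators
.dyad_design <- function(config) {
  days <- unlist(Map(function(range, n) {
    d <- unique(round(seq(min(range), max(range), length.out = n)))
    if (length(d) != n) stop("n_per_block inconsistent with day_blocks")
    d
  }, config$day_blocks, config$n_per_block), use.names = FALSE)
  block <- rep(names(config$day_blocks), config$n_per_block)
  sample_metadata(sample_id = sprintf("d%03d", days),
                  day_after_birth = days, day_block = block)
}

# latent-factor contribution: per-period factor scores with small loadings,
# inducing within-period correlations between variables
.factor_effect <- function(period, p, n_factor, loading_sd = 0.3) {
  n <- length(period)
  eff <- matrix(0, n, p)
  loadings <- vector("list", 0)
  for (per in unique(period)) {
    idx <- which(period == per)
    L <- matrix(stats::rnorm(p * n_factor, 0, loading_sd), p, n_factor)
    Z <- matrix(stats::rnorm(length(idx) * n_factor), length(idx), n_factor)
    eff[idx, ] <- Z %*% t(L)
    loadings[[per]] <- L
  }
  list(effect = eff, loadings = loadings)
}

#' Generate a synthetic stool metabolome table
#'
#' Log-normal concentrations with period effects entered as additive
#' log-scale shifts: eight HMO-class variables are high under breastfeeding
#' (BM), reduced under the fruit-snack period (FBM) and at the detection
#' floor during weaning (W); three SCFA-class and six amino-acid-class
#' variables rise in W; two designated variables (1,2-propanediol-like and
#' formate-like) are elevated only in FBM; the remaining variables are
#' unstructured nulls. Within-period correlations come from shared latent
#' factors. All values are nonnegative, floored at the detection limit.
#'
#' @param config a [dyad_config()].
#' @return list with `table` (a [feature_table]), `metadata`
#'   ([sample_metadata]) and `truth` (planted marker ids, class labels and
#'   factor loadings).
#' @export
generate_stool_metabolome <- function(config = dyad_config()) {
  meta <- .dyad_design(config)
  set.seed(config$seed)
  n <- nrow(meta)
  es <- config$effect_size * config$noise_sd
  hmo <- c("HMO_2FL", "HMO_3FL", "HMO_LNFPI", "HMO_LNFPIII", "HMO_LNDFH",
           "HMO_LDFT", "HMO_3SL", "HMO_fucosyl")
  scfa <- c("acetate", "propionate", "butyrate")
  amino <- c("valine", "isoleucine", "phenylalanine", "tyrosine",
             "alanine", "glycine")
  fbm <- c("PD12_like", "formate_like")
  other <- sprintf("met_%02d", seq_len(config$n_metabolites - 19))
  vars <- c(hmo, scfa, amino, fbm, other)
  vclass <- c(rep("HMO", 8), rep("SCFA", 3), rep("amino_acid", 6),
              rep("FBM", 2), rep("other", length(other)))
  p <- length(vars)
  mu <- stats::rnorm(p, 1, 0.5)
  shift <- matrix(0, 3, p, dimnames = list(c("BM", "FBM", "W"), vars))
  shift[, hmo] <- rbind(1.5 * es, 0.5 * es, 0)   # W overwritten by floor
  shift["W", c(scfa, amino)] <- es
  shift["FBM", fbm] <- es
  fac <- .factor_effect(meta$diet_period, p, config$n_factor)
  logc <- rep(mu, each = n) + shift[meta$diet_period, ] + fac$effect +
    matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  vals <- pmax(exp(logc), config$detection_floor)
  vals[meta$diet_period == "W", vclass == "HMO"] <- config$detection_floor
  colnames(vals) <- vars
  rownames(vals) <- meta$sample_id
  truth <- list(
    marker_ids_bm_vs_fbm = c(hmo, fbm),
    marker_ids_milk_vs_weaning = c(hmo, scfa, amino),
    null_ids = other,
    class_labels = stats::setNames(meta$diet_period, meta$sample_id),
    factor_loadings = fac$loadings,
    directions_bm_vs_fbm = stats::setNames(
      c(rep("BM", length(hmo)), rep("FBM", length(fbm))), c(hmo, fbm)))
  list(table = feature_table(vals, variable_class = vclass),
       metadata = meta, truth = truth)
}

#' Generate a synthetic compositional OTU table
#'
#' Logistic-normal compositions (each row closed to 100) for the subset of
#' samples with 16S data. The community is dominated by Firmicutes,
#' Proteobacteria and Actinobacteria; all Bacteroidetes-phylum genera are
#' parameterized to stay below 1% total mean abundance; a
#' Bifidobacterium-like genus has high mean and high variance independent of
#' diet period; designated Ruminococcus-like and Lachnospiraceae-like genera
#' shift up during weaning. Latent factors induce correlated taxa.
#'
#' @param config a [dyad_config()].
#' @param metadata [sample_metadata] defining the samples and periods
#'   (normally from [generate_stool_metabolome()]).
#' @return list with `table` (25 x n_otus by default), `truth` (planted
#'   weaning-associated genera and the phylum map).
#' @export
generate_otu_table <- function(config = dyad_config(), metadata) {
  subset <- config$metagenome_subset
  if (is.null(subset)) {
    # the study has 16S for 25 of 32 stools without naming them; the
    # generator deterministically omits the last 7 sample ids
    subset <- utils::head(metadata$sample_id,
                          max(nrow(metadata) - 7L, 1L))
  }
  if (!all(subset %in% metadata$sample_id))
    stop("metagenome subset ids not in metadata: ",
         setdiff(subset, metadata$sample_id)[1])
  meta <- metadata[match(subset, metadata$sample_id), , drop = FALSE]
  set.seed(config$seed + 1L)
  n <- nrow(meta)
  es <- config$effect_size
  n_generic <- config$n_otus - 16L      # 16 named genera are structured
  g_p <- min(5L, n_generic)
  g_a <- min(4L, max(0L, n_generic - g_p))
  g_f <- max(0L, n_generic - g_p - g_a)
  firmicutes <- c("Ruminococcus_like", "Lachnospiraceae_like",
                  "Ruminococcaceae_like", "Veillonella_like",
                  "Lactobacillus_like", "SMB53_like", "Clostridium_like",
                  sprintf("Firmicutes_g%02d", seq_len(g_f)))
  proteo <- c("Enterobacteriaceae_like", "Pseudomonas_like",
              "Citrobacter_like",
              sprintf("Proteobacteria_g%02d", seq_len(g_p)))
  actino <- c("Bifidobacterium_like", "Coriobacteriaceae_like",
              sprintf("Actinobacteria_g%02d", seq_len(g_a)))
  bacteroidetes <- c("Bacteroides_like", "Prevotella_like",
                     "Flavobacterium_like", "Parabacteroides_like")
  vars <- c(firmicutes, proteo, actino, bacteroidetes)
  phylum <- c(rep("Firmicutes", length(firmicutes)),
              rep("Proteobacteria", length(proteo)),
              rep("Actinobacteria", length(actino)),
              rep("Bacteroidetes", length(bacteroidetes)))
  if (length(vars) != config$n_otus) {       # pad/trim the generic genera
    if (length(vars) > config$n_otus) {
      keep <- seq_len(config$n_otus)
      vars <- vars[keep]; phylum <- phylum[keep]
    } else {
      extra <- sprintf("Firmicutes_x%02d",
                       seq_len(config$n_otus - length(vars)))
      vars <- c(vars, extra)
      phylum <- c(phylum, rep("Firmicutes", length(extra)))
    }
  }
  p <- length(vars)
  alpha <- stats::rnorm(p, 0, 1)
  names(alpha) <- vars
  alpha["Bifidobacterium_like"] <- 3
  alpha[phylum == "Bacteroidetes"] <- -4.5
  sd_taxon <- rep(0.8, p)
  names(sd_taxon) <- vars
  sd_taxon["Bifidobacterium_like"] <- 1.6   # fluctuating, period-independent
  weaning_up <- c("Ruminococcus_like", "Lachnospiraceae_like",
                  "Ruminococcaceae_like")
  shift <- matrix(0, n, p, dimnames = list(meta$sample_id, vars))
  shift[meta$diet_period == "W", weaning_up] <- es
  fac <- .factor_effect(meta$diet_period, p, config$n_factor)
  z <- rep(alpha, each = n) + shift + fac$effect +
    matrix(stats::rnorm(n * p), n, p) * rep(sd_taxon, each = n)
  ez <- exp(z)
  vals <- 100 * ez / rowSums(ez)
  dimnames(vals) <- list(meta$sample_id, vars)
  truth <- list(weaning_up = weaning_up, phylum = stats::setNames(phylum, vars),
                class_labels = stats::setNames(meta$diet_period,
                                               meta$sample_id),
                factor_loadings = fac$loadings)
  list(table = feature_table(vals, variable_class = phylum), truth = truth)
}

#' Generate a synthetic breast-milk metabolome table
#'
#' Milk samples cover the lactation window (the first three day blocks,
#' days 103-175), each sampled at the start and at the end of suction
#' (paired rows). On the log scale one 3'-fucosyllactose-like variable
#' increases linearly with lactation day, several variables
#' (2'-fucosyllactose-like, lacto-N-fucopentaose-like, N-acetyl-like,
#' dimethylamine-like) decrease, a lactate variable is shifted up at the end
#' of suction, and the remainder are flat.
#'
#' @param config a [dyad_config()].
#' @return list with `table` (2 x days rows), `metadata` (with an extra
#'   `suction` column) and `truth` (trend directions per variable).
#' @export
generate_milk_metabolome <- function(config = dyad_config()) {
  full <- .dyad_design(config)
  meta0 <- full[full$day_after_birth <= 175, , drop = FALSE]
  set.seed(config$seed + 2L)
  es <- config$effect_size * config$noise_sd
  increasing <- "FL3_like"
  decreasing <- c("FL2_like", "LNFPI_like", "LNFPIII_like", "NAc_like",
                  "DMA_like")
  flat <- c("lactate",
            sprintf("milk_%02d", seq_len(config$n_milk_metabolites - 7)))
  vars <- c(increasing, decreasing, flat)
  p <- length(vars)
  slope <- stats::setNames(rep(0, p), vars)
  slope[increasing] <- es
  slope[decreasing] <- -es
  nd <- nrow(meta0)
  day_std <- (meta0$day_after_birth - mean(meta0$day_after_birth)) /
    stats::sd(meta0$day_after_birth)
  mu <- stats::rnorm(p, 1, 0.5)
  base <- rep(mu, each = nd) + outer(day_std, slope) +
    matrix(stats::rnorm(nd * p, 0, config$noise_sd), nd, p)
  pair_noise <- function() matrix(stats::rnorm(nd * p, 0,
                                               0.3 * config$noise_sd), nd, p)
  start <- base + pair_noise()
  end <- base + pair_noise()
  end[, vars == "lactate"] <- end[, vars == "lactate"] +
    0.3 * config$effect_size * config$noise_sd
  vals <- pmax(exp(rbind(start, end)), config$detection_floor)
  ids <- c(paste0(meta0$sample_id, "_start"), paste0(meta0$sample_id, "_end"))
  dimnames(vals) <- list(ids, vars)
  meta <- rbind(meta0, meta0)
  meta$sample_id <- ids
  meta$suction <- rep(c("start", "end"), each = nd)
  rownames(meta) <- NULL
  class(meta) <- c("sample_metadata", "data.frame")
  vclass <- c("HMO", rep("HMO", 3), "NAc", "amine", "organic_acid",
              rep("other", length(flat) - 1))
  truth <- list(
    trend_direction = stats::setNames(
      c(1, rep(-1, length(decreasing)), rep(0, length(flat))), vars),
    increasing = increasing, decreasing = decreasing,
    lactate_end_shift = 0.3 * config$effect_size * config$noise_sd)
  list(table = feature_table(vals, variable_class = vclass),
       metadata = meta, truth = truth)
}

#' Generate the full synthetic dyad dataset
#'
#' Convenience wrapper producing the stool metabolome, the OTU table on the
#' metagenome subset, and the milk metabolome under one config, optionally
#' writing all tables, metadata and ground truth to a directory.
#'
#' @param config a [dyad_config()].
#' @param out_dir optional directory; when given, writes
#'   `stool_metabolome.csv`, `otu_table.csv`, `milk_metabolome.csv`,
#'   `metadata.csv`, `milk_metadata.csv` and `ground_truth.json`.
#' @return list with `stool`, `otu`, `milk` (each as returned by its
#'   generator) and `config`.
#' @export
simulate_dyad <- function(config = dyad_config(), out_dir = NULL) {
  stool <- generate_stool_metabolome(config)
  otu <- generate_otu_table(config, stool$metadata)
  milk <- generate_milk_metabolome(config)
  out <- list(stool = stool, otu = otu, milk = milk, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(stool$table,
                        file.path(out_dir, "stool_metabolome.csv"))
    write_feature_table(otu$table, file.path(out_dir, "otu_table.csv"))
    write_feature_table(milk$table,
                        file.path(out_dir, "milk_metabolome.csv"))
    utils::write.csv(stool$metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(milk$metadata, file.path(out_dir, "milk_metadata.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(config = unclass(config),
           stool_truth = stool$truth[c("marker_ids_bm_vs_fbm",
                                       "marker_ids_milk_vs_weaning",
                                       "null_ids")],
           otu_truth = otu$truth["weaning_up"],
           milk_truth = milk$truth[c("increasing", "decreasing")]),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
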