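# End-to-end orchestration: simulate (or load) -> normalize -> pairwise DE
# grids -> subregion/heart classification -> over-representation ->
# deconvolution, from a single config. Every stage writes plain TSVs into
# the output directory and later stages read those files back, so deleting
# downstream outputs and re-running resumes from the cached upstream TSVs.
# All randomness flows from the single config seed.

#' Demo pipeline configuration
#'
#' A desk-scale synthetic study emulating a four-chamber, two-disease-group
#' cohort: 2,000 genes, 10 donors per disease group (one sample per chamber
#' each), planted chamber/axis-enriched genes at 4-fold, 100 left-heart
#' disease-dysregulated genes, a 30-tissue panel with planted heart-enriched
#' genes, and a 7-cell-type reference with mixtures at chamber-like
#' proportions.
#'
#' @param outdir Output directory for pipeline stages.
#' @param seed Integer seed driving every stage.
#' @return A pipeline config list accepted by [run_pipeline()].
#' @export
demo_pipeline_config <- function(outdir = tempfile("cardioregion_demo_"),
                                 seed = 1) {
  planted <- rbind(
    do.call(rbind, lapply(seq_along(c("LV", "RV", "LA", "RA")), function(i) {
      ch <- c("LV", "RV", "LA", "RA")[i]
      data.frame(gene = (i - 1) * 25 + 1:25, chambers = ch, diseases = "*",
                 log2fc = 2, stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(seq_along(c("LV,RV", "LA,RA", "LV,LA", "RV,RA")),
                          function(i) {
      ax <- c("LV,RV", "LA,RA", "LV,LA", "RV,RA")[i]
      data.frame(gene = 100 + (i - 1) * 15 + 1:15, chambers = ax,
                 diseases = "*", log2fc = 2, stringsAsFactors = FALSE)
    })),
    data.frame(gene = 161:210, chambers = "LA,LV", diseases = "HFrEF",
               log2fc = 2, stringsAsFactors = FALSE),
    data.frame(gene = 211:260, chambers = "LA,LV", diseases = "HFrEF",
               log2fc = -2, stringsAsFactors = FALSE)
  )
  list(
    outdir = outdir,
    seed = as.integer(seed),
    simulation = list(
      n_genes = 2000, chambers = CHAMBERS, diseases = DISEASES,
      donors_per_group = 10, dispersion = 0.1, depth_sdlog = 0.1,
      baseline = list(meanlog = log(60), sdlog = 1.2, planted_floor = 50),
      planted_effects = planted,
      heart_planted = c(1:160, 1501:1600),
      panel = list(n_tissues = 30),
      reference = list(n_cell_types = 7, cells_per_type = 50,
                       n_genes = 500, marker_fraction = 0.14),
      mixtures = list(
        n_per_group = 10, depth = 1e6, noise_sd = 0.2, jitter_sdlog = 0.15,
        profiles = list(
          LV_like = c(Cardiomyocytes = 0.61, Endothelium = 0.20,
                      Fibroblasts = 0.08, Macrophages = 0.01,
                      Perivascular = 0.08, Lymphocytes = 0.005,
                      Neurons = 0.015),
          RA_like = c(Cardiomyocytes = 0.41, Endothelium = 0.21,
                      Fibroblasts = 0.24, Macrophages = 0.02,
                      Perivascular = 0.08, Lymphocytes = 0.005,
                      Neurons = 0.035)))
    ),
    thresholds = list(fc = 2, q = 0.01, min_fpkm = 1, min_samples = 5,
                      percentile = 70, anchor = 10),
    chamber_disease = "NF",
    disease_contrasts = list(
      list(name = "LA_HFrEF_vs_NF", chamber = "LA",
           covariates = c("sex", "age")),
      list(name = "LV_HFrEF_vs_NF", chamber = "LV",
           covariates = c("sex", "age"))
    ),
    enrichment = list(class = "LV", n_random_sets = 8,
                      random_set_size = 50, min_set_size = 5)
  )
}

#' Load a pipeline config from YAML
#'
#' @param path YAML file mirroring the structure of
#'   [demo_pipeline_config()].
#' @return Config list.
#' @export
load_pipeline_config <- function(path) {
  config <- yaml::read_yaml(path)
  pe <- config$simulation$planted_effects
  if (!is.null(pe) && !is.data.frame(pe)) {
    cols <- c("gene", "chambers", "diseases", "log2fc")
    config$simulation$planted_effects <- if (all(cols %in% names(pe))) {
      as.data.frame(pe, stringsAsFactors = FALSE)   # column-oriented yaml
    } else {
      do.call(rbind, lapply(pe, as.data.frame, stringsAsFactors = FALSE))
    }
  }
  config
}

#' Validate a pipeline config
#'
#' Checks thresholds, chamber/disease declarations and that every contrast
#' references declared labels; called by [run_pipeline()] before any
#' computation.
#'
#' @param config Config list.
#' @return The config, invisibly; stops with an informative error otherwise.
#' @export
validate_pipeline_config <- function(config) {
  need <- c("outdir", "seed", "simulation", "thresholds")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  th <- config$thresholds
  for (nm in c("fc", "q", "min_fpkm", "min_samples", "percentile", "anchor"))
    if (is.null(th[[nm]]) || !is.numeric(th[[nm]]) || th[[nm]] <= 0)
      stop("threshold '", nm, "' must be a positive number", call. = FALSE)
  sim <- config$simulation
  if (!all(sim$chambers %in% CHAMBERS))
    stop("undeclared chamber label in simulation: ",
         paste(setdiff(sim$chambers, CHAMBERS), collapse = ", "),
         call. = FALSE)
  if (!all(sim$diseases %in% DISEASES))
    stop("undeclared disease label in simulation", call. = FALSE)
  if (!is.null(config$chamber_disease) &&
      !config$chamber_disease %in% sim$diseases)
    stop("chamber_disease '", config$chamber_disease,
         "' is not a declared disease group", call. = FALSE)
  for (ct in config$disease_contrasts) {
    if (is.null(ct$name) || is.null(ct$chamber))
      stop("disease contrast needs 'name' and 'chamber'", call. = FALSE)
    if (!ct$chamber %in% sim$chambers)
      stop("contrast '", ct$name, "' references undefined chamber '",
           ct$chamber, "'", call. = FALSE)
  }
  invisible(config)
}

.stage_done <- function(outdir, files) {
  all(file.exists(file.path(outdir, files)))
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline from a config
#'
#' Executes the stages in fixed order (simulate, normalize, diffexp,
#' classify, enrich, deconvolve, summarize), writing every stage's outputs
#' as TSVs under `config$outdir` and a run manifest (config hash, per-file
#' checksums, package version, seed, timestamps) as `manifest.json`. Stages
#' whose output files already exist are skipped unless `force = TRUE`, so a
#' run resumes from cached upstream files. Re-running with an identical
#' config and seed reproduces byte-identical stage outputs.
#'
#' @param config Config list (see [demo_pipeline_config()]).
#' @param force Recompute stages even when their outputs exist.
#' @return List with `manifest` and `summary` (a metric/value data.frame),
#'   invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  validate_pipeline_config(config)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  t_start <- Sys.time()
  th <- config$thresholds
  seed <- config$seed
  sim <- config$simulation

  ## stage 1: simulate -------------------------------------------------
  sim_files <- c("counts.tsv", "metadata.tsv", "gene_lengths.tsv",
                 "truth_labels.tsv", "effect_matrix.tsv", "panel.tsv",
                 "panel_truth.tsv", "mixtures.tsv", "mixture_truth.tsv",
                 "mixture_groups.tsv", "gene_sets.gmt",
                 "reference/matrix.mtx")
  if (force || !.stage_done(outdir, sim_files)) {
    base <- NULL
    if (!is.null(sim$baseline)) {
      set.seed(seed + 101L)
      base <- rlnorm(sim$n_genes, sim$baseline$meanlog, sim$baseline$sdlog)
      planted_genes <- unique(sim$planted_effects$gene)
      floor_val <- sim$baseline$planted_floor
      if (!is.null(floor_val) && length(planted_genes))
        base[planted_genes] <- pmax(base[planted_genes], floor_val)
    }
    spec <- bulk_sim_spec(
      n_genes = sim$n_genes, chambers = sim$chambers,
      diseases = sim$diseases, donors_per_group = sim$donors_per_group,
      baseline_mean = if (is.null(base)) 100 else base,
      dispersion = sim$dispersion, planted_effects = sim$planted_effects,
      depth_sdlog = sim$depth_sdlog, seed = seed)
    bulk <- simulate_bulk(spec)
    write_matrix_tsv(bulk$counts, file.path(outdir, "counts.tsv"))
    write_metadata_tsv(bulk$metadata, file.path(outdir, "metadata.tsv"))
    write.table(data.frame(gene_id = names(bulk$gene_lengths),
                           length = bulk$gene_lengths),
                file.path(outdir, "gene_lengths.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = names(bulk$truth$label),
                           true_label = as.character(bulk$truth$label)),
                file.path(outdir, "truth_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_matrix_tsv(bulk$truth$effect_matrix,
                     file.path(outdir, "effect_matrix.tsv"))

    panel <- simulate_tissue_panel(sim$n_genes,
                                   n_tissues = sim$panel$n_tissues,
                                   planted_heart_genes = sim$heart_planted,
                                   seed = seed + 1L)
    write_matrix_tsv(panel$panel, file.path(outdir, "panel.tsv"))
    write.table(data.frame(gene_id = rownames(panel$panel),
                           heart_enriched = panel$heart_enriched),
                file.path(outdir, "panel_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    ref <- simulate_reference(
      n_cell_types = sim$reference$n_cell_types,
      cells_per_type = sim$reference$cells_per_type,
      n_genes = sim$reference$n_genes,
      marker_fraction = sim$reference$marker_fraction, seed = seed + 2L)
    write_mtx_triplet(ref$counts, ref$labels,
                      file.path(outdir, "reference"))

    mx <- sim$mixtures
    set.seed(seed + 3L)
    prof <- do.call(rbind, mx$profiles)
    groups <- rep(names(mx$profiles), each = mx$n_per_group)
    P <- t(sapply(groups, function(g) {
      p <- prof[g, ] * rlnorm(ncol(prof), 0, mx$jitter_sdlog)
      p / sum(p)
    }))
    colnames(P) <- colnames(prof)
    mix <- simulate_mixtures(ref, P, depth = mx$depth,
                             noise_sd = mx$noise_sd, seed = seed + 4L)
    write_matrix_tsv(mix$bulk, file.path(outdir, "mixtures.tsv"))
    write_matrix_tsv(mix$proportions, file.path(outdir, "mixture_truth.tsv"))
    write.table(data.frame(sample_id = rownames(mix$proportions),
                           group = groups),
                file.path(outdir, "mixture_groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    enr <- config$enrichment
    truth_lab <- as.character(bulk$truth$label)
    gene_ids <- rownames(bulk$counts)
    set.seed(seed + 5L)
    sets <- lapply(seq_len(enr$n_random_sets), function(i)
      sample(gene_ids, enr$random_set_size))
    names(sets) <- sprintf("random_set_%02d", seq_along(sets))
    sets[[paste0("planted_", enr$class)]] <-
      gene_ids[truth_lab == enr$class]
    write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
    .log_stage("simulate", sim$n_genes, " genes, ",
               ncol(bulk$counts), " bulk samples written")
  } else {
    .log_stage("simulate", "outputs present, skipping")
  }

  counts <- read_matrix_tsv(file.path(outdir, "counts.tsv"))
  metadata <- read_metadata_tsv(file.path(outdir, "metadata.tsv"))
  glen <- read.delim(file.path(outdir, "gene_lengths.tsv"))
  gene_lengths <- setNames(glen$length, glen$gene_id)

  ## stage 2: normalize -------------------------------------------------
  if (force || !.stage_done(outdir, "fpkm.tsv")) {
    fpkm <- anchor_normalize(counts_to_fpkm(counts, gene_lengths),
                             th$percentile, th$anchor)
    write_matrix_tsv(fpkm, file.path(outdir, "fpkm.tsv"))
    .log_stage("normalize", "anchored FPKM for ", ncol(fpkm), " samples")
  } else .log_stage("normalize", "outputs present, skipping")

  ## stage 3: differential expression ----------------------------------
  chamber_pairs <- combn(sim$chambers, 2)
  contrast_names <- c(
    apply(chamber_pairs, 2, paste, collapse = "_vs_"),
    vapply(config$disease_contrasts, `[[`, "", "name"))
  de_files <- sprintf("de_%s.tsv", contrast_names)
  if (force || !.stage_done(outdir, de_files)) {
    for (k in seq_len(ncol(chamber_pairs))) {
      a <- chamber_pairs[1, k]; b <- chamber_pairs[2, k]
      nm <- paste(a, b, sep = "_vs_")
      res <- run_contrast(
        counts, gene_lengths, metadata,
        select_samples(metadata, a, config$chamber_disease),
        select_samples(metadata, b, config$chamber_disease),
        name = nm, percentile = th$percentile, anchor_value = th$anchor,
        min_fpkm = th$min_fpkm, min_samples = th$min_samples)
      write.table(res, file.path(outdir, sprintf("de_%s.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      .log_stage("diffexp", nm, ": ", nrow(res), " genes tested")
    }
    for (ct in config$disease_contrasts) {
      res <- run_contrast(
        counts, gene_lengths, metadata,
        select_samples(metadata, ct$chamber, "HFrEF"),
        select_samples(metadata, ct$chamber, "NF"),
        name = ct$name, covariates = ct$covariates,
        percentile = th$percentile, anchor_value = th$anchor,
        min_fpkm = th$min_fpkm, min_samples = th$min_samples)
      write.table(res, file.path(outdir, sprintf("de_%s.tsv", ct$name)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      .log_stage("diffexp", ct$name, ": ", nrow(res), " genes tested")
    }
  } else .log_stage("diffexp", "outputs present, skipping")

  ## stage 4: classification --------------------------------------------
  if (force || !.stage_done(outdir, "labels.tsv")) {
    grids <- list()
    for (k in seq_len(ncol(chamber_pairs))) {
      nm <- paste(chamber_pairs[1, k], chamber_pairs[2, k], sep = "_vs_")
      grids[[nm]] <- read.delim(file.path(outdir, sprintf("de_%s.tsv", nm)),
                                stringsAsFactors = FALSE)
    }
    grid <- build_pairwise_grid(grids)
    cls <- classify_subregion(grid, th$fc, th$q)
    # genes filtered out of every contrast are unclassifiable -> "none"
    idx <- match(rownames(counts), cls$gene_id)
    labels <- data.frame(
      gene_id = rownames(counts),
      primary_label = ifelse(is.na(idx), "none",
                             as.character(cls$primary_label)[idx]),
      qualifying_labels = ifelse(is.na(idx), "",
                                 cls$qualifying_labels[idx]),
      stringsAsFactors = FALSE)
    panel <- read_matrix_tsv(file.path(outdir, "panel.tsv"))
    heart <- call_heart_enriched(panel, top_k = 3, min_fpkm = th$min_fpkm)
    labels$heart_enriched <- unname(heart[labels$gene_id])
    write.table(labels, file.path(outdir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .log_stage("classify", sum(labels$primary_label != "none"),
               " subregion-enriched, ", sum(labels$heart_enriched),
               " heart-enriched genes")
  } else .log_stage("classify", "outputs present, skipping")

  ## stage 5: enrichment -------------------------------------------------
  if (force || !.stage_done(outdir, "enrichment.tsv")) {
    labels <- read.delim(file.path(outdir, "labels.tsv"),
                         stringsAsFactors = FALSE)
    collection <- read_gmt(file.path(outdir, "gene_sets.gmt"))
    interest <- labels$gene_id[labels$primary_label ==
                                 config$enrichment$class]
    enr_res <- enrich_collection(interest, collection,
                                 universe = labels$gene_id,
                                 min_set_size = config$enrichment$min_set_size)
    write.table(enr_res, file.path(outdir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .log_stage("enrich", nrow(enr_res), " sets tested against ",
               length(interest), " genes of interest")
  } else .log_stage("enrich", "outputs present, skipping")

  ## stage 6: deconvolution ----------------------------------------------
  decon_files <- c("proportions.tsv", "deconv_comparison.tsv")
  if (force || !.stage_done(outdir, decon_files)) {
    ref <- read_mtx_triplet(file.path(outdir, "reference"))
    qc <- qc_reference(ref$counts, ref$labels)
    sig <- build_signature(qc$counts, qc$labels)
    mixtures <- read_matrix_tsv(file.path(outdir, "mixtures.tsv"))
    dec <- wnnls_deconvolve(mixtures, sig)
    write_matrix_tsv(dec$proportions, file.path(outdir, "proportions.tsv"))
    grp <- read.delim(file.path(outdir, "mixture_groups.tsv"),
                      stringsAsFactors = FALSE)
    cmp <- do.call(rbind, lapply(colnames(dec$proportions), function(tp)
      compare_proportions(dec, data.frame(sample_id = grp$sample_id,
                                          group = grp$group),
                          tp, group_by = "group")))
    write.table(cmp, file.path(outdir, "deconv_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .log_stage("deconvolve", nrow(dec$proportions), " samples, ",
               ncol(dec$proportions), " cell types (QC removed ",
               round(100 * qc$removed_fraction, 1), "% of cells)")
  } else .log_stage("deconvolve", "outputs present, skipping")

  ## stage 7: summary + manifest -----------------------------------------
  summary_df <- .pipeline_summary(config, contrast_names)
  write.table(summary_df, file.path(outdir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .log_stage("summary", nrow(summary_df), " metrics written")

  files <- setdiff(list.files(outdir, recursive = TRUE),
                   "manifest.json")
  checksums <- tools::md5sum(file.path(outdir, files))
  names(checksums) <- files
  manifest <- list(
    config_hash = .config_hash(config),
    package_version = as.character(packageVersion("cardioregion")),
    seed = seed,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, summary = summary_df))
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "outdir")]), tmp)
  unname(tools::md5sum(tmp))
}

# planted-truth recovery metrics, computed purely from the stage TSVs
.pipeline_summary <- function(config, contrast_names) {
  outdir <- config$outdir
  th <- config$thresholds
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, value = value,
                                            stringsAsFactors = FALSE)

  truth <- read.delim(file.path(outdir, "truth_labels.tsv"),
                      stringsAsFactors = FALSE)
  eff <- read_matrix_tsv(file.path(outdir, "effect_matrix.tsv"))
  counts <- read_matrix_tsv(file.path(outdir, "counts.tsv"))
  add("n_genes", nrow(counts))
  add("n_samples", ncol(counts))

  lth <- log2(th$fc)
  for (nm in contrast_names) {
    de <- read.delim(file.path(outdir, sprintf("de_%s.tsv", nm)),
                     stringsAsFactors = FALSE)
    called <- !is.na(de$padj) & de$padj < th$q & abs(de$log2FC) >= lth
    add(sprintf("de_%s_n_tested", nm), nrow(de))
    add(sprintf("de_%s_n_de", nm), sum(called))
    # contrast truth from the planted effect matrix
    parts <- strsplit(nm, "_vs_")[[1]]
    if (all(parts %in% CHAMBERS)) {
      ga <- paste(parts[1], config$chamber_disease, sep = "_")
      gb <- paste(parts[2], config$chamber_disease, sep = "_")
    } else {
      ct <- Filter(function(x) x$name == nm, config$disease_contrasts)[[1]]
      ga <- paste(ct$chamber, "HFrEF", sep = "_")
      gb <- paste(ct$chamber, "NF", sep = "_")
    }
    tl <- eff[, ga] - eff[, gb]
    true_de <- abs(tl) > 0
    idx <- match(de$gene_id, rownames(eff))
    if (any(true_de)) {
      sens <- sum(called & true_de[idx]) / sum(true_de)
      fdr <- if (sum(called)) sum(called & !true_de[idx]) / sum(called) else 0
      add(sprintf("de_%s_sensitivity", nm), round(sens, 4))
      add(sprintf("de_%s_fdr", nm), round(fdr, 4))
    }
  }

  labels <- read.delim(file.path(outdir, "labels.tsv"),
                       stringsAsFactors = FALSE)
  stopifnot(identical(labels$gene_id, truth$gene_id))
  for (cls in setdiff(ENRICHMENT_LEVELS, "none"))
    add(sprintf("class_%s_n", cls), sum(labels$primary_label == cls))
  planted <- truth$true_label != "none"
  add("label_sensitivity",
      round(mean(labels$primary_label[planted] ==
                   truth$true_label[planted]), 4))
  add("label_false_rate",
      round(mean(labels$primary_label[!planted] != "none"), 4))

  panel_truth <- read.delim(file.path(outdir, "panel_truth.tsv"),
                            stringsAsFactors = FALSE)
  he <- labels$heart_enriched
  add("heart_enriched_n", sum(he))
  add("heart_sensitivity",
      round(sum(he & panel_truth$heart_enriched) /
              sum(panel_truth$heart_enriched), 4))
  add("heart_specificity",
      round(sum(!he & !panel_truth$heart_enriched) /
              sum(!panel_truth$heart_enriched), 4))

  enr <- read.delim(file.path(outdir, "enrichment.tsv"),
                    stringsAsFactors = FALSE)
  if (nrow(enr)) {
    add("enrichment_top_term", enr$term[1])
    add("enrichment_top_padj", signif(enr$padj[1], 4))
  }

  props <- read_matrix_tsv(file.path(outdir, "proportions.tsv"))
  ptruth <- read_matrix_tsv(file.path(outdir, "mixture_truth.tsv"))
  common_types <- intersect(colnames(props), colnames(ptruth))
  err <- abs(props[rownames(ptruth), common_types] -
               ptruth[, common_types])
  add("deconv_mae", round(mean(err), 4))
  add("deconv_max_type_bias",
      round(max(abs(colMeans(props[rownames(ptruth), common_types] -
                               ptruth[, common_types]))), 4))
  cmp <- read.delim(file.path(outdir, "deconv_comparison.tsv"),
                    stringsAsFactors = FALSE)
  fib <- cmp[cmp$cell_type == "Fibroblasts", ]
  if (nrow(fib)) add("deconv_fibroblast_p", signif(fib$p_two_sided[1], 4))

  do.call(rbind, rows)
}
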