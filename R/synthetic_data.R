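# Seeded generators that emulate the statistical structure of a four-chamber
# heart RNA-seq study: NB bulk counts with planted chamber/disease effects,
# a GTEx-like multi-tissue panel, labeled single-cell references, and bulk
# mixtures of known cell-type composition. Every generator returns the
# planted ground truth alongside the data.

CHAMBERS <- c("LA", "LV", "RA", "RV")
DISEASES <- c("NF", "HFrEF")
ENRICHMENT_LEVELS <- c("LV", "RV", "LA", "RA",
                       "Ventricles", "Atria", "Left", "Right", "none")
CARDIAC_CELL_TYPES <- c("Cardiomyocytes", "Endothelium", "Fibroblasts",
                        "Macrophages", "Perivascular", "Lymphocytes",
                        "Neurons")

#' Specification of a synthetic bulk RNA-seq experiment
#'
#' Describes a chambers x disease-groups design with a common per-donor
#' covariate structure, negative-binomial counts
#' (\eqn{Var = \mu + \alpha\mu^2}) and a list of planted log2 effects. The
#' expected count of gene g in sample s is
#' `baseline_mean[g] * (length_g / mean length) * depth_s * 2^effect(g, group(s))`
#' with per-sample depth factors drawn lognormal(0, `depth_sdlog`).
#'
#' @param n_genes Number of genes.
#' @param chambers Chamber labels (subset of LA, LV, RA, RV).
#' @param diseases Disease group labels (subset of NF, HFrEF).
#' @param donors_per_group Donors per disease group; each donor contributes
#'   one sample per chamber, mirroring a multi-chamber autopsy design.
#' @param baseline_mean Expected baseline count, a positive scalar or a
#'   per-gene vector.
#' @param dispersion NB dispersion \eqn{\alpha > 0}; values below 1e-12 are
#'   simulated as Poisson.
#' @param planted_effects `NULL` or a data.frame with columns `gene`
#'   (1-based index), `chambers` (comma-separated labels or `"*"`),
#'   `diseases` (ditto) and `log2fc`.
#' @param gene_lengths Positive integer lengths in bases; drawn uniformly
#'   from 300-10000 when `NULL`.
#' @param depth_sdlog Lognormal sd of the per-sample depth factors.
#' @param sex_effect `NULL` or a data.frame with columns `gene` and `log2fc`
#'   giving a planted male-vs-female confounder, useful for exercising
#'   covariate adjustment.
#' @param seed Integer seed; identical specs give identical data.
#' @return An object of class `bulk_sim_spec`.
#' @export
bulk_sim_spec <- function(n_genes = 2000, chambers = CHAMBERS,
                          diseases = DISEASES, donors_per_group = 6,
                          baseline_mean = 100, dispersion = 0.1,
                          planted_effects = NULL, gene_lengths = NULL,
                          depth_sdlog = 0.1, sex_effect = NULL, seed = 1) {
  .check_scalar(n_genes, "n_genes", 1)
  if (!all(chambers %in% CHAMBERS) || !length(chambers))
    stop("'chambers' must be drawn from ", paste(CHAMBERS, collapse = ", "),
         call. = FALSE)
  if (!all(diseases %in% DISEASES) || !length(diseases))
    stop("'diseases' must be drawn from ", paste(DISEASES, collapse = ", "),
         call. = FALSE)
  .check_scalar(donors_per_group, "donors_per_group", 1)
  if (!is.numeric(baseline_mean) || any(baseline_mean <= 0) ||
      !(length(baseline_mean) %in% c(1L, n_genes)))
    stop("'baseline_mean' must be positive, length 1 or n_genes", call. = FALSE)
  .check_scalar(dispersion, "dispersion", 0, strict = TRUE)
  .check_scalar(depth_sdlog, "depth_sdlog", 0)
  if (!is.null(gene_lengths)) {
    if (length(gene_lengths) != n_genes || any(gene_lengths <= 0))
      stop("'gene_lengths' must be positive and of length n_genes",
           call. = FALSE)
  }
  planted_effects <- .check_effect_table(planted_effects, n_genes,
                                         chambers, diseases)
  if (!is.null(sex_effect)) {
    if (!is.data.frame(sex_effect) ||
        !all(c("gene", "log2fc") %in% names(sex_effect)) ||
        any(sex_effect$gene < 1 | sex_effect$gene > n_genes))
      stop("'sex_effect' must have in-range columns gene, log2fc",
           call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), chambers = chambers,
                 diseases = diseases,
                 donors_per_group = as.integer(donors_per_group),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 planted_effects = planted_effects,
                 gene_lengths = gene_lengths, depth_sdlog = depth_sdlog,
                 sex_effect = sex_effect, seed = as.integer(seed)),
            class = "bulk_sim_spec")
}

.check_effect_table <- function(eff, n_genes, chambers, diseases) {
  if (is.null(eff) || !nrow(eff)) return(NULL)
  need <- c("gene", "chambers", "diseases", "log2fc")
  if (!is.data.frame(eff) || !all(need %in% names(eff)))
    stop("'planted_effects' must have columns gene, chambers, diseases, log2fc",
         call. = FALSE)
  if (any(eff$gene < 1 | eff$gene > n_genes))
    stop("'planted_effects': gene index out of range 1..n_genes", call. = FALSE)
  expand <- function(x, full) {
    lab <- trimws(strsplit(as.character(x), ",")[[1]])
    if (identical(lab, "*")) full else lab
  }
  for (i in seq_len(nrow(eff))) {
    if (!all(expand(eff$chambers[i], chambers) %in% chambers))
      stop("'planted_effects': unknown chamber in row ", i, call. = FALSE)
    if (!all(expand(eff$diseases[i], diseases) %in% diseases))
      stop("'planted_effects': unknown disease in row ", i, call. = FALSE)
  }
  eff
}

# genes x groups matrix of summed planted log2 effects; group labels
# "<chamber>_<disease>"
.effect_matrix <- function(spec) {
  groups <- as.vector(outer(spec$chambers, spec$diseases, paste, sep = "_"))
  eff <- matrix(0, spec$n_genes, length(groups),
                dimnames = list(NULL, groups))
  pe <- spec$planted_effects
  if (is.null(pe)) return(eff)
  for (i in seq_len(nrow(pe))) {
    ch <- trimws(strsplit(as.character(pe$chambers[i]), ",")[[1]])
    if (identical(ch, "*")) ch <- spec$chambers
    di <- trimws(strsplit(as.character(pe$diseases[i]), ",")[[1]])
    if (identical(di, "*")) di <- spec$diseases
    grp <- as.vector(outer(ch, di, paste, sep = "_"))
    eff[pe$gene[i], grp] <- eff[pe$gene[i], grp] + pe$log2fc[i]
  }
  eff
}

# the enrichment label implied by a gene's true chamber means (NF side):
# same twofold-in-every-comparison rule the classifier applies, evaluated on
# the generating log2 means, with chamber-before-axis precedence
.labels_from_effects <- function(eff, chambers, disease = "NF") {
  cols <- paste(chambers, disease, sep = "_")
  cols <- cols[cols %in% colnames(eff)]
  e <- eff[, cols, drop = FALSE]
  colnames(e) <- sub(paste0("_", disease, "$"), "", cols)
  if (!all(CHAMBERS %in% colnames(e)))
    return(factor(rep("none", nrow(e)), levels = ENRICHMENT_LEVELS))
  beats <- function(a, b) e[, a] - e[, b] >= 1  # true FC >= 2
  rules <- .subregion_rules()
  lab <- rep("none", nrow(e))
  for (cls in rev(names(rules))) {
    ok <- Reduce(`&`, lapply(rules[[cls]], function(p) beats(p[1], p[2])))
    lab[ok] <- cls
  }
  factor(lab, levels = ENRICHMENT_LEVELS)
}

#' Simulate a bulk chamber x disease count matrix with planted truth
#'
#' Draws NB counts under the design in a [bulk_sim_spec()]. Returns the raw
#' counts, gene lengths, per-sample metadata (donor, chamber, disease, sex,
#' age) and a ground-truth list recording the planted per-group log2 effect
#' matrix, the implied true enrichment label of every gene, and the
#' per-sample depth factors.
#'
#' @param spec A [bulk_sim_spec()].
#' @return List with elements `counts`, `gene_lengths`, `metadata`, `truth`.
#' @export
simulate_bulk <- function(spec) {
  if (!inherits(spec, "bulk_sim_spec"))
    stop("'spec' must be a bulk_sim_spec", call. = FALSE)
  set.seed(spec$seed)
  n_genes <- spec$n_genes
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  lens <- spec$gene_lengths
  if (is.null(lens)) lens <- sample(300:10000, n_genes, replace = TRUE)
  lens <- as.numeric(lens)

  donors <- seq_len(spec$donors_per_group)
  meta <- expand.grid(chamber = spec$chambers, donor = donors,
                      disease = spec$diseases, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  meta$donor_id <- sprintf("%s_d%02d", meta$disease, meta$donor)
  meta$sample_id <- sprintf("%s_%s_%02d", meta$chamber, meta$disease,
                            meta$donor)
  meta$group <- paste(meta$chamber, meta$disease, sep = "_")
  donor_ids <- unique(meta$donor_id)
  sex <- setNames(sample(c("M", "F"), length(donor_ids), replace = TRUE),
                  donor_ids)
  age <- setNames(round(runif(length(donor_ids), 45, 75)), donor_ids)
  meta$sex <- unname(sex[meta$donor_id])
  meta$age <- unname(age[meta$donor_id])
  meta <- meta[, c("sample_id", "donor_id", "chamber", "disease",
                   "sex", "age", "group")]
  n_samples <- nrow(meta)
  depth <- rlnorm(n_samples, 0, spec$depth_sdlog)

  eff <- .effect_matrix(spec)
  base <- rep(spec$baseline_mean, length.out = n_genes)
  lenfac <- lens / mean(lens)
  log2fc_gs <- eff[, meta$group, drop = FALSE]
  if (!is.null(spec$sex_effect)) {
    male <- meta$sex == "M"
    for (i in seq_len(nrow(spec$sex_effect)))
      log2fc_gs[spec$sex_effect$gene[i], male] <-
        log2fc_gs[spec$sex_effect$gene[i], male] + spec$sex_effect$log2fc[i]
  }
  mu <- (base * lenfac) * 2^log2fc_gs
  mu <- sweep(mu, 2L, depth, "*")
  counts <- if (spec$dispersion < 1e-12) {
    rpois(length(mu), lambda = mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion)
  }
  counts <- matrix(counts, n_genes, n_samples,
                   dimnames = list(gene_ids, meta$sample_id))

  truth <- list(
    effect_matrix = `rownames<-`(eff, gene_ids),
    label = setNames(.labels_from_effects(eff, spec$chambers), gene_ids),
    depth_factors = setNames(depth, meta$sample_id)
  )
  list(counts = counts, gene_lengths = setNames(lens, gene_ids),
       metadata = meta, truth = truth)
}

#' True log2 fold change for a contrast, from planted effects
#'
#' Mean planted log2 effect over the groups of side A minus side B; the
#' value an ideal differential test would estimate.
#'
#' @param truth The `truth` element returned by [simulate_bulk()].
#' @param groups_a,groups_b Group labels (`"<chamber>_<disease>"`).
#' @return Named numeric vector over genes.
#' @export
true_log2fc <- function(truth, groups_a, groups_b) {
  eff <- truth$effect_matrix
  stopifnot(all(c(groups_a, groups_b) %in% colnames(eff)))
  rowMeans(eff[, groups_a, drop = FALSE]) -
    rowMeans(eff[, groups_b, drop = FALSE])
}

#' Simulate a multi-tissue expression panel with planted heart-enriched genes
#'
#' Emits an already-normalized FPKM panel over `n_tissues` tissues (one of
#' them named `heart`). Planted genes are constructed so heart ranks first
#' with FPKM well above 1; every other gene fails at least one of the two
#' heart-enrichment criteria by construction (either heart FPKM below 1, or
#' at least four tissues strictly above heart).
#'
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues (>= 4; 30 emulates a GTEx-style panel).
#' @param planted_heart_genes Integer indices of genes planted as
#'   heart-enriched (may be empty).
#' @param seed Integer seed.
#' @return List with `panel` (genes x tissues FPKM matrix, a `heart` column)
#'   and `heart_enriched` (logical ground truth per gene).
#' @export
simulate_tissue_panel <- function(n_genes, n_tissues = 30,
                                  planted_heart_genes = integer(0), seed = 1) {
  .check_scalar(n_genes, "n_genes", 1)
  if (n_tissues < 4)
    stop("'n_tissues' must be >= 4 (top-3 rank rule is degenerate below)",
         call. = FALSE)
  if (length(planted_heart_genes) &&
      (any(planted_heart_genes < 1) || any(planted_heart_genes > n_genes)))
    stop("'planted_heart_genes' indices must lie in 1..n_genes", call. = FALSE)
  set.seed(seed)
  tissues <- c("heart", sprintf("tissue_%02d", seq_len(n_tissues - 1)))
  panel <- matrix(0, n_genes, n_tissues,
                  dimnames = list(sprintf("gene_%05d", seq_len(n_genes)),
                                  tissues))
  planted <- logical(n_genes)
  planted[planted_heart_genes] <- TRUE
  for (g in seq_len(n_genes)) {
    if (planted[g]) {
      heart <- runif(1, 5, 50)
      other <- runif(n_tissues - 1, 0, 0.8 * heart)
    } else if (runif(1) < 0.5) {
      heart <- runif(1, 0, 0.9)            # fails the FPKM floor
      other <- runif(n_tissues - 1, 0, 20)
    } else {
      heart <- runif(1, 1, 20)             # fails the top-3 rank
      n_above <- sample(4:min(8, n_tissues - 1), 1)
      above <- runif(n_above, 1.05 * heart, 3 * heart)
      below <- runif(n_tissues - 1 - n_above, 0, 0.95 * heart)
      other <- sample(c(above, below))
    }
    panel[g, ] <- c(heart, other)
  }
  list(panel = panel, heart_enriched = planted)
}

#' Simulate a labeled single-cell reference with planted marker blocks
#'
#' Each cell type receives a disjoint block of marker genes expressed about
#' tenfold above a shared lognormal background; counts are NB draws with
#' per-cell lognormal depth variation. The disjoint marker blocks guarantee a
#' full-rank type-mean signature.
#'
#' @param n_cell_types Number of cell types (>= 2). Up to seven types are
#'   named after the major cardiac cell populations.
#' @param cells_per_type Cells simulated per type.
#' @param n_genes Number of genes.
#' @param marker_fraction Fraction of genes used as markers, split evenly
#'   across types; must provide at least one marker per type.
#' @param dispersion NB dispersion of the cell-level counts.
#' @param seed Integer seed.
#' @return List with `counts` (sparse genes x cells dgCMatrix), `labels`
#'   (cell type per cell), `type_means` (generating mean matrix, genes x
#'   types) and `markers` (list of marker index vectors per type).
#' @export
simulate_reference <- function(n_cell_types = 7, cells_per_type = 50,
                               n_genes = 500, marker_fraction = 0.1,
                               dispersion = 0.2, seed = 1) {
  if (n_cell_types < 2) stop("'n_cell_types' must be >= 2", call. = FALSE)
  .check_scalar(cells_per_type, "cells_per_type", 1)
  .check_scalar(n_genes, "n_genes", 1)
  n_markers <- floor(marker_fraction * n_genes)
  if (n_markers < n_cell_types)
    stop("'marker_fraction' too small: fewer than one marker per cell type",
         call. = FALSE)
  set.seed(seed)
  types <- if (n_cell_types <= length(CARDIAC_CELL_TYPES)) {
    CARDIAC_CELL_TYPES[seq_len(n_cell_types)]
  } else {
    c(CARDIAC_CELL_TYPES,
      sprintf("type_%02d", seq_len(n_cell_types - length(CARDIAC_CELL_TYPES))))
  }
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  base <- rlnorm(n_genes, meanlog = log(2), sdlog = 1)
  block <- n_markers %/% n_cell_types
  markers <- split(seq_len(block * n_cell_types),
                   rep(seq_len(n_cell_types), each = block))
  names(markers) <- types
  type_means <- matrix(base, n_genes, n_cell_types,
                       dimnames = list(gene_ids, types))
  for (t in seq_len(n_cell_types))
    type_means[markers[[t]], t] <- type_means[markers[[t]], t] * 10
  n_cells <- n_cell_types * cells_per_type
  labels <- rep(types, each = cells_per_type)
  cell_depth <- rlnorm(n_cells, 0, 0.1)
  mu <- sweep(type_means[, labels, drop = FALSE], 2L, cell_depth, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, n_cells,
                   dimnames = list(gene_ids,
                                   sprintf("cell_%04d", seq_len(n_cells))))
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       labels = setNames(labels, colnames(counts)),
       type_means = type_means, markers = markers)
}

#' Simulate bulk mixtures of reference cell types at known proportions
#'
#' The expected bulk profile of each sample is the proportion-weighted sum of
#' the reference's depth-normalized type means, rescaled to the requested
#' depth, with optional mean-one multiplicative lognormal noise per
#' gene-and-sample.
#'
#' @param reference A reference as returned by [simulate_reference()] (or any
#'   list with `counts` and `labels`).
#' @param proportions Matrix of mixing proportions, samples x cell types
#'   (columns named by type), each row summing to 1 within 1e-8; a single
#'   vector is treated as one sample.
#' @param depth Target total expression per sample.
#' @param noise_sd Lognormal sd of the multiplicative noise (0 = noiseless).
#' @param seed Integer seed.
#' @return List with `bulk` (genes x samples matrix) and `proportions` (the
#'   ground-truth matrix, rows matching bulk columns).
#' @export
simulate_mixtures <- function(reference, proportions, depth = 1e6,
                              noise_sd = 0, seed = 1) {
  if (is.null(dim(proportions))) proportions <- rbind(proportions)
  M <- .reference_type_means(reference$counts, reference$labels)
  if (is.null(colnames(proportions))) colnames(proportions) <- colnames(M)
  if (!all(colnames(proportions) %in% colnames(M)))
    stop("'proportions' columns must name reference cell types", call. = FALSE)
  if (any(proportions < 0))
    stop("'proportions' must be non-negative", call. = FALSE)
  if (any(abs(rowSums(proportions) - 1) > 1e-8))
    stop("'proportions' rows must sum to 1 (within 1e-8)", call. = FALSE)
  .check_scalar(depth, "depth", 0, strict = TRUE)
  .check_scalar(noise_sd, "noise_sd", 0)
  set.seed(seed)
  P <- proportions[, colnames(M), drop = FALSE]
  bulk <- M %*% t(P)
  bulk <- sweep(bulk, 2L, colSums(bulk) / depth, "/")
  if (noise_sd > 0) {
    noise <- matrix(rlnorm(length(bulk), -noise_sd^2 / 2, noise_sd),
                    nrow(bulk), ncol(bulk))
    bulk <- bulk * noise
  }
  colnames(bulk) <- sprintf("mix_%03d", seq_len(ncol(bulk)))
  rownames(P) <- colnames(bulk)
  list(bulk = as.matrix(bulk), proportions = P)
}
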