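# End-to-end orchestration: configuration, staged execution (load or
# simulate -> mirror -> GPA -> impute -> size-correct -> assemble and
# standardize -> quartet tests -> outlier scans -> convergence -> sex
# assignment -> report), with per-stage derived seeds for bitwise
# reproducibility.

#' Build and validate a pipeline run configuration
#'
#' @param specimen_table,landmark_table,tree_file optional input paths read
#'   with [read_specimen_table()], [read_landmarks()], [read_tree()]; when
#'   absent, a study is simulated from `sim_params`.
#' @param sim_params a [radiation_params()] for simulated runs.
#' @param scaling_population which specimens define the standardization:
#'   `"museum"` (island/ecomorph analyses; default) or `"all"`.
#' @param t_variant `"welch"` (default) or `"pooled"`.
#' @param n_perm,n_boot permutation/bootstrap replicates (>= 99).
#' @param alpha significance level.
#' @param min_n minimum per-cell specimens for quartet enumeration.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it by stable hashing of its labels.
#' @param divergence_contrast list with `island`, `e1`, `e2`: the ecomorph
#'   contrast used for the outlier scan of evolutionary divergence
#'   (default trunk-ground vs trunk-crown on Cuba).
#' @param convergence logical: run the Wheatsheaf analysis per ecomorph.
#' @param signature_traits logical: also run the per-trait signature scan
#'   (slower).
#' @param sex_assignment logical: run the discriminant sex assignment when
#'   specimens of unknown sex are present.
#' @param out_dir optional directory; when set, report tables are written
#'   there as delimited text.
#' @return Validated list of class `run_config`.
#' @export
pipeline_config <- function(specimen_table = NULL, landmark_table = NULL,
                            tree_file = NULL,
                            sim_params = radiation_params(),
                            scaling_population = c("museum", "all"),
                            t_variant = c("welch", "pooled"),
                            n_perm = 999L, n_boot = 999L, alpha = 0.05,
                            min_n = 2L, seed = 1L,
                            divergence_contrast = list(
                              island = "Cuba", e1 = "trunk-ground",
                              e2 = "trunk-crown"),
                            convergence = TRUE, signature_traits = FALSE,
                            sex_assignment = TRUE, out_dir = NULL) {
  scaling_population <- match.arg(scaling_population)
  t_variant <- match.arg(t_variant)
  if (n_perm < 99L || n_boot < 99L)
    .stopf("n_perm and n_boot must be at least 99 (got %d, %d)",
           n_perm, n_boot)
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must lie in (0, 1)")
  for (p in c(specimen_table, landmark_table, tree_file))
    if (!is.null(p) && !file.exists(p)) .stopf("input path not found: %s", p)
  structure(list(specimen_table = specimen_table,
                 landmark_table = landmark_table, tree_file = tree_file,
                 sim_params = sim_params,
                 scaling_population = scaling_population,
                 t_variant = t_variant, n_perm = n_perm, n_boot = n_boot,
                 alpha = alpha, min_n = min_n, seed = as.integer(seed),
                 divergence_contrast = divergence_contrast,
                 convergence = convergence,
                 signature_traits = signature_traits,
                 sex_assignment = sex_assignment, out_dir = out_dir),
            class = "run_config")
}

# Morphometry stage: landmarks + linear -> standardized trait matrix.
.prepare_traits <- function(dataset, scaling_ids = NULL) {
  if (is.null(dataset$landmarks)) {
    if (is.null(dataset$traits)) .stopf("dataset has neither landmarks nor traits")
    x <- dataset$traits
    scl <- standardize_traits(
      if (is.null(scaling_ids)) x else x[scaling_ids, , drop = FALSE])
    return(standardize_traits(x, scaling = scl$scaling))
  }
  pick <- function(struct) {
    cfgs <- lapply(dataset$landmarks, `[[`, struct)
    cfgs <- cfgs[!vapply(cfgs, is.null, logical(1L))]
    lapply(cfgs, function(cfg)
      if (cfg$side == "right") mirror_configuration(cfg) else cfg)
  }
  gpa_pec <- gpa(pick("pectoral"))
  gpa_pel <- gpa(pick("pelvic"))
  lin <- dataset$linear
  ids <- lin$specimen_id
  lin <- as.matrix(lin[setdiff(names(lin), "specimen_id")])
  rownames(lin) <- ids
  if (anyNA(lin)) lin <- impute_missing(lin)
  keep <- intersect(rownames(lin),
                    intersect(names(gpa_pec$centroid_sizes),
                              names(gpa_pel$centroid_sizes)))
  corrected <- size_correct(lin[keep, , drop = FALSE],
                            gpa_pel$centroid_sizes[keep])
  raw <- assemble_traits(
    gpa_pec = .subset_gpa(gpa_pec, keep), gpa_pel = .subset_gpa(gpa_pel, keep),
    corrected_linear = corrected)
  if (!is.null(scaling_ids)) {
    scaling_ids <- intersect(scaling_ids, rownames(raw$values))
    # re-standardize over the chosen population only
    unscaled <- sweep(sweep(raw$values, 2L, raw$scaling$sd, `*`), 2L,
                      raw$scaling$mean, `+`)
    scl <- standardize_traits(unscaled[scaling_ids, , drop = FALSE])
    raw <- standardize_traits(unscaled, scaling = scl$scaling)
  }
  raw
}

.subset_gpa <- function(g, ids) {
  g$aligned <- g$aligned[ids, , , drop = FALSE]
  g$centroid_sizes <- g$centroid_sizes[ids]
  g
}

#' Run the full analysis pipeline
#'
#' Executes every stage on real or simulated inputs and returns the run
#' report: the per-quartet angle/length test table, its summary (mean and
#' sd of theta, classification counts), outlier scans for the divergence
#' contrast and any plasticity contrasts, the convergence table, the sex
#' assignment table, the PCA variance summary, and a provenance block.
#' Identical configurations (including the master seed) give identical
#' reports.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "load"
  res <- tryCatch({
    tree <- NULL
    if (!is.null(config$specimen_table)) {
      dataset <- read_specimen_table(config$specimen_table)
      if (!is.null(config$landmark_table))
        dataset$landmarks <- read_landmarks(config$landmark_table)
      if (!is.null(config$tree_file)) tree <- read_tree(config$tree_file)
    } else {
      stage <- "simulate"
      study <- simulate_study(config$sim_params,
                              seed = derive_seed(config$seed, "simulate"))
      dataset <- study$dataset
      tree <- study$tree
    }

    stage <- "morphometry"
    museum_ids <- dataset$records$specimen_id[dataset$records$source == "museum"]
    scaling_ids <- if (config$scaling_population == "museum" &&
                       length(museum_ids)) museum_ids else NULL
    traits <- .prepare_traits(dataset, scaling_ids = scaling_ids)
    records <- dataset$records[dataset$records$specimen_id %in%
                                 rownames(traits$values), , drop = FALSE]
    museum <- records[records$source == "museum", , drop = FALSE]

    stage <- "pca"
    pca <- pca_variance(traits$values[museum$specimen_id, , drop = FALSE])

    stage <- "quartets"
    quartets <- enumerate_quartets(museum, min_n = config$min_n)
    qt_rows <- vector("list", nrow(quartets))
    for (q in seq_len(nrow(quartets))) {
      qt <- quartets[q, ]
      qseed <- derive_seed(config$seed, qt$e1, qt$e2, qt$i1, qt$i2)
      at <- suppressWarnings(quartet_angle_test(
        qt, traits, museum, n_perm = config$n_perm, n_boot = config$n_boot,
        seed = qseed, method = config$t_variant, alpha = config$alpha))
      qt_rows[[q]] <- data.frame(
        qt, theta = at$theta, delta_L = at$delta_L,
        p_parallel = at$p_parallel, p_length = at$p_length,
        p_orthogonal = at$p_orthogonal, classification = at$classification,
        n_perm = config$n_perm, n_boot = config$n_boot, seed = qseed,
        stringsAsFactors = FALSE)
    }
    quartet_table <- if (length(qt_rows)) do.call(rbind, qt_rows)
                     else data.frame()

    stage <- "outlier_scan"
    outliers <- list()
    dc <- config$divergence_contrast
    div_vec <- NULL
    a <- traits$values[museum$specimen_id[museum$island %in% dc$island &
                                            museum$ecomorph %in% dc$e1], ,
                       drop = FALSE]
    b <- traits$values[museum$specimen_id[museum$island %in% dc$island &
                                            museum$ecomorph %in% dc$e2], ,
                       drop = FALSE]
    if (nrow(a) >= 2L && nrow(b) >= 2L) {
      div_vec <- suppressWarnings(t_vector(
        a, b, method = config$t_variant,
        contrast = c(paste(dc$e1, dc$island, sep = "@"),
                     paste(dc$e2, dc$island, sep = "@"))))
      outliers$divergence <- outlier_traits(div_vec)
      outliers$divergence_vector <- div_vec
    }
    experiment <- records[records$source == "experiment", , drop = FALSE]
    plasticity <- list()
    if (nrow(experiment)) {
      for (sp in unique(experiment$species)) {
        ids_n <- experiment$specimen_id[experiment$species == sp &
                                          experiment$treatment == "narrow"]
        ids_b <- experiment$specimen_id[experiment$species == sp &
                                          experiment$treatment == "broad"]
        if (length(ids_n) < 2L || length(ids_b) < 2L) next
        pv <- suppressWarnings(t_vector(
          traits$values[ids_n, , drop = FALSE],
          traits$values[ids_b, , drop = FALSE], method = config$t_variant,
          contrast = paste(sp, c("narrow", "broad"), sep = "@")))
        plasticity[[sp]] <- list(
          vector = pv, outliers = outlier_traits(pv),
          angle_to_divergence = if (!is.null(div_vec))
            vector_angle(pv, div_vec) else NA_real_)
      }
    }

    stage <- "convergence"
    convergence <- NULL
    if (isTRUE(config$convergence) && !is.null(tree) && nrow(museum)) {
      sp_eco <- unique(museum[c("species", "ecomorph")])
      means <- species_means(traits$values[museum$specimen_id, , drop = FALSE],
                             museum$species)
      conv_rows <- list()
      for (eco in sort(unique(sp_eco$ecomorph))) {
        focal <- sp_eco$species[sp_eco$ecomorph == eco]
        if (length(focal) < 2L) next
        cseed <- derive_seed(config$seed, "wheatsheaf", eco)
        cr <- if (isTRUE(config$signature_traits))
          signature_scan(means, tree, focal, n_perm = config$n_perm,
                         seed = cseed, alpha = config$alpha)
        else wheatsheaf(means, tree, focal, n_perm = config$n_perm,
                        seed = cseed)
        conv_rows[[eco]] <- data.frame(
          ecomorph = eco, w = cr$w, p = cr$p,
          n_signature_traits = if (is.null(cr$per_trait)) NA_integer_
                               else sum(cr$per_trait$signature),
          stringsAsFactors = FALSE)
      }
      convergence <- do.call(rbind, conv_rows)
      rownames(convergence) <- NULL
    }

    stage <- "sex_assignment"
    sex_table <- NULL
    if (isTRUE(config$sex_assignment) && any(records$sex == "unknown")) {
      pel_cols <- which(startsWith(colnames(traits$values), "shape_pel_"))
      known <- records$specimen_id[records$sex %in% c("male", "female")]
      unknown <- records$specimen_id[records$sex == "unknown"]
      if (length(unique(records$sex[records$specimen_id %in% known])) == 2L) {
        model <- lda_fit(traits$values[known, pel_cols, drop = FALSE],
                         records$sex[match(known, records$specimen_id)])
        sex_table <- lda_assign(model,
                                traits$values[unknown, pel_cols, drop = FALSE],
                                threshold = 0.8)
      }
    }

    stage <- "report"
    summary <- list(
      n_quartets = nrow(quartet_table),
      mean_theta = if (nrow(quartet_table)) mean(quartet_table$theta)
                   else NA_real_,
      sd_theta = if (nrow(quartet_table)) stats::sd(quartet_table$theta)
                 else NA_real_,
      classification_counts = if (nrow(quartet_table))
        table(quartet_table$classification) else table(character(0)),
      n_length_indistinguishable = if (nrow(quartet_table))
        sum(quartet_table$p_length >= config$alpha) else NA_integer_)
    report <- structure(list(
      quartets = quartet_table, summary = summary, outliers = outliers,
      plasticity = plasticity, convergence = convergence,
      sex_assignment = sex_table, pca = pca, traits = traits,
      records = records, tree = tree,
      provenance = list(seed = config$seed, config = config,
                        package_version =
                          as.character(utils::packageVersion("morphotraj")),
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
      class = "run_report")
    if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
    report
  }, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  res
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$quartets, file.path(out_dir, "quartets.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(report$convergence))
    utils::write.table(report$convergence,
                       file.path(out_dir, "convergence.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$sex_assignment))
    utils::write.table(report$sex_assignment,
                       file.path(out_dir, "sex_assignment.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$outliers$divergence)) {
    os <- report$outliers$divergence
    utils::write.table(
      data.frame(trait = names(os$z_scores),
                 t = report$outliers$divergence_vector$t_values,
                 z = os$z_scores,
                 flagged = names(os$z_scores) %in% os$flagged),
      file.path(out_dir, "outlier_scan.csv"), sep = ",", quote = FALSE,
      row.names = FALSE)
  }
  summary_lines <- c(
    sprintf("n_quartets: %d", report$summary$n_quartets),
    sprintf("mean_theta: %.4f", report$summary$mean_theta),
    sprintf("sd_theta: %.4f", report$summary$sd_theta),
    sprintf("seed: %d", report$provenance$seed),
    sprintf("package_version: %s", report$provenance$package_version))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  quartets: %d (mean theta %.2f deg, sd %.2f)\n",
              x$summary$n_quartets, x$summary$mean_theta, x$summary$sd_theta))
  if (length(x$summary$classification_counts)) {
    cc <- x$summary$classification_counts
    cat("  classification:",
        paste(sprintf("%s = %d", names(cc), as.integer(cc)), collapse = ", "),
        "\n")
  }
  if (!is.null(x$convergence))
    cat(sprintf("  convergence: %d ecomorph(s), w in [%.2f, %.2f]\n",
                nrow(x$convergence), min(x$convergence$w),
                max(x$convergence$w)))
  if (length(x$plasticity))
    cat(sprintf("  plasticity contrasts: %s\n",
                paste(names(x$plasticity), collapse = ", ")))
  cat(sprintf("  PCA: PC1 %.2f%%, PC2 %.2f%%\n",
              100 * x$pca$variance_fractions[1L],
              100 * x$pca$variance_fractions[2L]))
  invisible(x)
}
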