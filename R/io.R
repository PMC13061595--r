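#' Read a methylation beta-value matrix from TSV
#'
#' Expects CpG probes as rows and sample IDs as columns (the transposed
#' layout methylation scoring tools conventionally use); `orientation =
#' "samples-rows"` transposes on read. Duplicate probe IDs and beta values
#' outside `[0, 1]` are errors.
#'
#' @param path TSV file, first column = probe IDs, header = sample IDs.
#' @param orientation `"probes-rows"` (default) or `"samples-rows"`.
#' @return Numeric matrix, CpGs x samples.
#' @export
read_methylation <- function(path,
                             orientation = c("probes-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- tab[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("read_methylation: duplicated probe row(s) in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  m <- as.matrix(tab[-1])
  rownames(m) <- ids
  if (orientation == "samples-rows") m <- t(m)
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("read_methylation: beta values outside [0, 1] in ", path,
         call. = FALSE)
  m
}

#' Write a methylation matrix as TSV (probes as rows)
#' @param meth Matrix, CpGs x samples.
#' @param path Output TSV path.
#' @export
write_methylation <- function(meth, path) {
  df <- data.frame(cpg_id = rownames(meth), meth, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a covariate table (sample_id, age, sex)
#'
#' Sex given as "F"/"M" (or "female"/"male", any case) is recoded to the
#' numeric convention female = 0, male = 1, with a message; numeric 0/1 is
#' accepted as-is. Duplicate sample IDs are an error.
#'
#' @param path CSV file.
#' @return Data frame with `sample_id`, `age`, numeric `sex`.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex")
  if (!all(need %in% names(tab)))
    stop("read_covariates: ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("read_covariates: duplicated sample IDs in ", path, call. = FALSE)
  if (is.character(tab$sex)) {
    code <- c(f = 0, female = 0, m = 1, male = 1)
    sx <- code[tolower(tab$sex)]
    if (anyNA(sx))
      stop("read_covariates: unrecognized sex code(s): ",
           paste(unique(tab$sex[is.na(sx)]), collapse = ", "), call. = FALSE)
    message("read_covariates: recoded sex to female = 0, male = 1")
    tab$sex <- unname(sx)
  }
  if (!all(tab$sex %in% c(0, 1)))
    stop("read_covariates: sex must be coded 0 (female) / 1 (male)",
         call. = FALSE)
  tab[need]
}

#' Read a fitness table
#' @param path CSV with `sample_id` plus trait columns; missing values are
#'   an error (complete-case pipeline).
#' @return Data frame.
#' @export
read_fitness <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("read_fitness: ", path, " must have a sample_id column",
         call. = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("read_fitness: duplicated sample IDs in ", path, call. = FALSE)
  if (anyNA(tab))
    stop("read_fitness: missing values in ", path,
         " (complete cases required)", call. = FALSE)
  tab
}

#' Read a CpG weight table
#' @param path TSV with columns `protein_id`/`protein`, `cpg_id`/`cpg`,
#'   `weight`.
#' @return Data frame with `protein_id`, `cpg_id`, `weight`.
#' @export
read_weights <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- names(tab)
  nm[nm == "protein"] <- "protein_id"
  nm[nm == "cpg"] <- "cpg_id"
  names(tab) <- nm
  need <- c("protein_id", "cpg_id", "weight")
  if (!all(need %in% names(tab)))
    stop("read_weights: ", path, " must have columns protein, cpg, weight",
         call. = FALSE)
  tab[need]
}

#' Read CpG reference mean betas
#' @param path TSV with columns `cpg_id`/`cpg`, `mean_beta`.
#' @return Named numeric vector.
#' @export
read_ref_means <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- names(tab)
  nm[nm == "cpg"] <- "cpg_id"
  names(tab) <- nm
  if (!all(c("cpg_id", "mean_beta") %in% names(tab)))
    stop("read_ref_means: ", path, " must have columns cpg, mean_beta",
         call. = FALSE)
  if (any(tab$mean_beta < 0 | tab$mean_beta > 1))
    stop("read_ref_means: mean betas outside [0, 1] in ", path, call. = FALSE)
  stats::setNames(tab$mean_beta, tab$cpg_id)
}

#' Read an EpiScore-disease hazard table
#'
#' Accepts a `log_hr` column, or an `hr` column which is natural-logged on
#' read (with a message).
#'
#' @param path CSV with `disease`, `protein_id`/`protein`, and `log_hr` or
#'   `hr`.
#' @return Data frame with `disease`, `protein_id`, `log_hr`.
#' @export
read_hazards <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(tab)
  nm[nm == "protein"] <- "protein_id"
  names(tab) <- nm
  if (!all(c("disease", "protein_id") %in% names(tab)))
    stop("read_hazards: ", path, " must have columns disease, protein",
         call. = FALSE)
  if (!"log_hr" %in% names(tab)) {
    if (!"hr" %in% names(tab))
      stop("read_hazards: ", path, " must have a log_hr or hr column",
           call. = FALSE)
    if (any(tab$hr <= 0))
      stop("read_hazards: hr values must be positive to take logs",
           call. = FALSE)
    message("read_hazards: hr column natural-logged to log_hr")
    tab$log_hr <- log(tab$hr)
  }
  if (anyDuplicated(tab[c("disease", "protein_id")]))
    stop("read_hazards: duplicated (disease, protein) pair(s) in ", path,
         call. = FALSE)
  tab[c("disease", "protein_id", "log_hr")]
}

#' Read a CVD benchmark weight table
#' @param path CSV with `protein_id`/`protein`, `weight`.
#' @return Data frame with `protein_id`, `weight`.
#' @export
read_cvd_weights <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(tab)
  nm[nm == "protein"] <- "protein_id"
  names(tab) <- nm
  if (!all(c("protein_id", "weight") %in% names(tab)))
    stop("read_cvd_weights: ", path, " must have columns protein, weight",
         call. = FALSE)
  tab[c("protein_id", "weight")]
}

#' Read an EpiScore name-mapping table
#' @param path CSV with `raw_name`, `standard_name` (other columns kept).
#' @return Data frame.
#' @export
read_name_mapping <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("raw_name", "standard_name") %in% names(tab)))
    stop("read_name_mapping: ", path,
         " must have columns raw_name, standard_name", call. = FALSE)
  tab
}

#' Write a samples-x-variables matrix as CSV with a sample_id column
#' @param m Matrix with sample rownames.
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a samples-x-variables CSV back into a matrix
#' @param path CSV written by [write_matrix_csv()].
#' @return Numeric matrix with sample rownames.
#' @export
read_matrix_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[-1])
  rownames(m) <- tab[[1]]
  m
}

#' Write the full synthetic study to a directory of plain-text tables
#'
#' @param study A study list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    methylation = file.path(dir, "methylation.tsv"),
    covariates = file.path(dir, "covariates.csv"),
    fitness = file.path(dir, "fitness.csv"),
    weights = file.path(dir, "weights.tsv"),
    ref_means = file.path(dir, "ref_means.tsv"),
    hazards = file.path(dir, "hazards.csv"),
    cvd_weights = file.path(dir, "cvd_weights.csv")
  )
  write_methylation(study$methylation, paths["methylation"])
  utils::write.csv(study$covariates, paths["covariates"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(study$fitness, paths["fitness"], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(
    data.frame(protein = study$weights$protein_id,
               cpg = study$weights$cpg_id,
               weight = study$weights$weight),
    paths["weights"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cpg = names(study$ref_means), mean_beta = study$ref_means),
    paths["ref_means"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(study$hazards, paths["hazards"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(study$cvd_weights, paths["cvd_weights"],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Pipeline configuration
#'
#' @param paths Named list/vector of input file paths (`methylation`,
#'   `covariates`, `fitness`, `weights`, `ref_means`, `hazards`,
#'   `cvd_weights`, optionally `mapping`).
#' @param out_dir Output directory.
#' @param alpha Nominal significance threshold for the association scan.
#' @param thresholds A [threshold_config()].
#' @param expected_directions Named vector for the consistency assessment.
#' @param fdr_family BH family for the scan (`"global"` or `"per-trait"`).
#' @param orientation Methylation matrix orientation on read.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(paths, out_dir,
                            alpha = 0.05,
                            thresholds = threshold_config(),
                            expected_directions = default_expected_directions(),
                            fdr_family = "global",
                            orientation = "probes-rows",
                            seed = 1L) {
  structure(list(paths = paths, out_dir = out_dir, alpha = alpha,
                 thresholds = thresholds,
                 expected_directions = expected_directions,
                 fdr_family = fdr_family, orientation = orientation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read and validate every pipeline input table
#'
#' @param config A [pipeline_config()].
#' @return List of in-memory tables (`methylation`, `covariates`, `fitness`,
#'   `weights`, `ref_means`, `hazards`, `cvd_weights`, optionally `mapping`).
#' @export
read_tables <- function(config) {
  p <- config$paths
  missing_files <- unlist(p)[!file.exists(unlist(p))]
  if (length(missing_files))
    stop("read_tables: input file(s) not found: ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  tabs <- list(
    methylation = read_methylation(p$methylation,
                                   orientation = config$orientation),
    covariates = read_covariates(p$covariates),
    fitness = read_fitness(p$fitness),
    weights = read_weights(p$weights),
    ref_means = read_ref_means(p$ref_means),
    hazards = read_hazards(p$hazards),
    cvd_weights = read_cvd_weights(p$cvd_weights)
  )
  if (!is.null(p$mapping)) tabs$mapping <- read_name_mapping(p$mapping)
  ids <- tabs$covariates$sample_id
  if (!setequal(ids, tabs$fitness$sample_id) ||
      !setequal(ids, colnames(tabs$methylation)))
    stop("read_tables: sample IDs disagree across methylation, covariates ",
         "and fitness tables", call. = FALSE)
  tabs
}

#' Run the full analysis over in-memory tables
#'
#' Stages, in order: EpiScore projection; column standardization;
#' covariate-adjusted association scan; linkage of significant pairs to the
#' hazard table with direction-consistency assessment; composite risk
#' scoring (direct + indirect), z-normalization, high-risk flagging, fitness
#' categorization and top-k ranking; CVD benchmark validation.
#'
#' @param tables List as returned by [read_tables()] or a
#'   [simulate_study()] study.
#' @param alpha Nominal significance threshold.
#' @param thresholds A [threshold_config()].
#' @param expected_directions Named direction vector per trait.
#' @param fdr_family BH family for the scan.
#' @param top_k Patients in the ranked report.
#' @return List with `episcores`, `episcores_std`, `associations`, `links`,
#'   `consistency`, `direct`, `indirect`, `risk`, `fitness_categories`,
#'   `top_patients`, `cvd_scores`, `benchmark`.
#' @export
run_stages <- function(tables, alpha = 0.05,
                       thresholds = threshold_config(),
                       expected_directions = default_expected_directions(),
                       fdr_family = "global", top_k = 10L) {
  episcores <- project_episcores(tables$methylation, tables$weights,
                                 tables$ref_means)
  episcores_std <- standardize_columns(episcores)
  assoc <- association_scan(episcores, tables$fitness, tables$covariates,
                            alpha = alpha, fdr_family = fdr_family)
  sig <- assoc[assoc$significant_nominal, , drop = FALSE]
  links <- link_fitness_disease(sig, tables$hazards)
  consistency <- assess_direction_consistency(links, expected_directions)

  traits <- setdiff(names(tables$fitness), "sample_id")
  fz <- standardize_columns(as.matrix(tables$fitness[traits]))
  rownames(fz) <- tables$fitness$sample_id
  direct <- compute_direct_risk(episcores_std, tables$hazards)
  indirect <- compute_indirect_risk(fz, sig, tables$hazards)
  risk <- compute_risk_scores(direct, indirect, thresholds)
  categories <- categorize_fitness(tables$fitness, tables$covariates,
                                   thresholds)
  top <- rank_high_risk_patients(risk, k = min(top_k, nrow(risk$z)))
  cvd <- compute_cvd_score(episcores_std, tables$cvd_weights)
  benchmark <- validate_against_benchmark(risk, cvd)

  list(episcores = episcores, episcores_std = episcores_std,
       associations = assoc, links = links, consistency = consistency,
       direct = direct, indirect = indirect, risk = risk,
       fitness_categories = categories, top_patients = top,
       cvd_scores = cvd, benchmark = benchmark)
}

#' Run the pipeline from files to files
#'
#' Reads every input of `config`, executes [run_stages()], writes each
#' stage's output table under `config$out_dir` and emits a JSON run manifest
#' recording the seed, per-stage row counts and warnings.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the [run_stages()] result list.
#' @export
run_pipeline <- function(config) {
  tables <- read_tables(config)
  warn <- character(0)
  res <- withCallingHandlers(
    run_stages(tables, alpha = config$alpha,
               thresholds = config$thresholds,
               expected_directions = config$expected_directions,
               fdr_family = config$fdr_family),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_matrix_csv(res$episcores, file.path(out, "episcores.csv"))
  utils::write.csv(attr(res$episcores, "imputation_report"),
                   file.path(out, "imputation_report.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(res$associations),
                   file.path(out, "associations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$consistency$links, file.path(out, "links.csv"),
                   row.names = FALSE, quote = FALSE)
  risk_wide <- data.frame(sample_id = rownames(res$risk$z),
                          res$risk$z, check.names = FALSE)
  names(risk_wide)[-1] <- paste0(colnames(res$risk$z), "_z")
  flags <- res$risk$high_risk
  colnames(flags) <- paste0(colnames(flags), "_flag")
  risk_out <- cbind(risk_wide, flags,
                    res$fitness_categories[match(risk_wide$sample_id,
                                                 res$fitness_categories$sample_id),
                                           -1, drop = FALSE])
  utils::write.csv(risk_out, file.path(out, "risk_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$top_patients, file.path(out, "top_patients.csv"),
                   row.names = FALSE, quote = TRUE)
  utils::write.csv(data.frame(sample_id = names(res$cvd_scores),
                              cvd_score = res$cvd_scores),
                   file.path(out, "cvd_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$benchmark, file.path(out, "benchmark.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    tool = "epirisk",
    version = as.character(utils::packageVersion("epirisk")),
    seed = config$seed,
    alpha = config$alpha,
    row_counts = list(
      samples = nrow(res$episcores),
      proteins = ncol(res$episcores),
      associations = nrow(res$associations),
      significant_nominal = sum(res$associations$significant_nominal),
      links = res$consistency$n_links,
      consistent_links = res$consistency$consistent_count,
      diseases = ncol(res$risk$z),
      flagged_any = sum(rowSums(res$risk$high_risk) > 0)
    ),
    warnings = warn
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
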