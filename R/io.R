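# Readers, writers and the end-to-end pipeline driver.

#' Read a genotype matrix from CSV or VCF
#'
#' CSV: individuals in rows (row names in the first column), markers in
#' columns, calls 0/1/2 with `NA` for missing. VCF (requires the `vcfR`
#' package): GT fields are mapped to dosages (`0/0` -> 0, `0/1` or `1/0` ->
#' 1, `1/1` -> 2, `./.` -> NA; phased separators accepted); multiallelic
#' records are skipped with a warning carrying the count.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"vcf"`.
#' @return Genotype matrix, individuals x markers.
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "csv"
  if (format == "csv") {
    g <- tryCatch(
      as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE)),
      error = function(e) stop("malformed genotype CSV: ",
                               conditionMessage(e), call. = FALSE))
    storage.mode(g) <- "double"
    check_geno_calls(g)
    return(g)
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipped %d multiallelic record(s)", sum(multi)))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_real_, length(x))
    out[x %in% "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% "1/1"] <- 2
    out
  }
  g <- apply(gt, 2, dosage)
  rownames(g) <- rownames(gt)
  t(g)  # individuals x markers
}

#' Read and validate a plot-level phenotype table
#'
#' Accepts a wide table (one or more trait columns) or a long longitudinal
#' table with `time_label`, `gdd`, `value` columns. Duplicated
#' (plot, time/trait) rows are rejected.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_columns(df, c("plot_id", "hybrid_id", "replicate"),
                "phenotype table")
  long <- all(c("time_label", "gdd", "value") %in% names(df))
  if (long) {
    if (anyDuplicated(paste(df$plot_id, df$time_label)))
      stop("duplicate (plot, time) rows", call. = FALSE)
  } else {
    if (anyDuplicated(df$plot_id))
      stop("duplicate plot rows", call. = FALSE)
    traits <- setdiff(names(df),
                      c("plot_id", "hybrid_id", "replicate", "site_year"))
    if (length(traits) == 0)
      stop("no trait columns found", call. = FALSE)
  }
  df
}

#' Write / read a relationship matrix as square CSV with id headers
#'
#' @param G relationship matrix with id dimnames.
#' @param path CSV file path.
#' @return `read_grm()` returns the matrix; `write_grm()` its path,
#'   invisibly.
#' @export
write_grm <- function(G, path) {
  utils::write.csv(as.data.frame(G), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}

pipeline_stages <- c("simulate", "qc", "grm", "indices", "fit_st", "fit_mt",
                     "fit_rr", "cv")

#' Run the end-to-end analysis pipeline from a configuration
#'
#' Executes the requested stages (simulate or ingest, marker QC, GRM
#' construction, model fits, cross-validation) in order, writing each
#' stage's tables plus a manifest with seeds and stage logs to the output
#' directory, so a run can be reproduced exactly. Configuration is a YAML
#' file (or an equivalent named list) with a `stages` block; unknown keys
#' are errors so typos cannot silently change an analysis. Referenced input
#' paths are checked before any computation.
#'
#' @param config path to a YAML file or a named list.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with per-stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("vigblup_run_")) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  known_top <- c("seed", "paths", "stages", "qc", "models")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stages <- config$stages
  if (is.null(stages) || !all(stages %in% pipeline_stages))
    stop("config must list stages from: ",
         paste(pipeline_stages, collapse = ", "), call. = FALSE)
  # preflight: referenced paths must exist before any compute
  for (pth in unlist(config$paths)) {
    if (!file.exists(pth))
      stop("preflight error: missing input file ", pth, call. = FALSE)
  }
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = stages,
                   package_version = as.character(
                     utils::packageVersion("viGBLUP")),
                   log = list())
  res <- list()
  stamp <- function(stage, msg) {
    manifest$log[[stage]] <<- c(manifest$log[[stage]],
                                paste0(format(Sys.time(),
                                              "%Y-%m-%dT%H:%M:%S"),
                                       " [", stage, "] seed=", seed, " ",
                                       msg))
  }
  run_stage <- function(stage, expr) {
    stamp(stage, "start")
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    stamp(stage, "done")
    out
  }

  if ("simulate" %in% stages) {
    res$simulate <- run_stage("simulate", {
      cfg <- do.call(sim_config, c(config$models$simulate %||% list(),
                                   list(seed = seed)))
      mat <- simulate_parents(cfg$n_maternal, cfg$n_markers,
                              seed = substream_seed(seed, "maternal"),
                              prefix = "M")
      pat <- simulate_parents(cfg$n_paternal, cfg$n_markers,
                              seed = substream_seed(seed, "paternal"),
                              prefix = "F")
      ped <- simulate_hybrids(mat, pat, cfg$n_hybrids,
                              seed = substream_seed(seed, "pedigree"))
      layout <- make_field_layout(ped$hybrid_id, cfg$n_reps)
      Gm <- vanraden_grm(impute_mode(mat))
      Gp <- vanraden_grm(impute_mode(pat))
      H <- hybrid_grm(Gm, Gp, ped)
      vi <- simulate_vi_trajectories(cfg, layout, H)
      eos <- simulate_end_of_season(cfg, vi$true_coeffs, H, layout)
      utils::write.csv(ped, file.path(out_dir, "pedigree.csv"),
                       row.names = FALSE)
      utils::write.csv(vi$phenotypes, file.path(out_dir, "vi_long.csv"),
                       row.names = FALSE)
      utils::write.csv(eos$phenotypes, file.path(out_dir, "eos.csv"),
                       row.names = FALSE)
      write_grm(H, file.path(out_dir, "grm.csv"))
      list(config = cfg, pedigree = ped, layout = layout, grm = H,
           vi = vi, eos = eos)
    })
  }
  if ("fit_st" %in% stages) {
    res$fit_st <- run_stage("fit_st", {
      sim <- res$simulate
      if (is.null(sim)) stop("fit_st requires the simulate stage")
      ph <- sim$eos$phenotypes
      fit <- fit_st_gblup(data.frame(hybrid_id = ph$hybrid_id,
                                     replicate = ph$replicate,
                                     value = ph$yield), sim$grm)
      utils::write.csv(
        data.frame(component = c("sigma_a2", "sigma_e2", "h2", "loglik"),
                   value = c(fit$sigma_a2, fit$sigma_e2, fit$h2,
                             fit$loglik)),
        file.path(out_dir, "fit_st.csv"), row.names = FALSE)
      fit
    })
  }
  if ("fit_rr" %in% stages) {
    res$fit_rr <- run_stage("fit_rr", {
      sim <- res$simulate
      if (is.null(sim)) stop("fit_rr requires the simulate stage")
      fit <- fit_random_regression(sim$vi$phenotypes,
                                   knots = sim$config$knot_gdds, sim$grm)
      utils::write.csv(as.data.frame(fit$Sigma_a),
                       file.path(out_dir, "fit_rr_sigma_a.csv"),
                       row.names = FALSE)
      fit
    })
  }
  if ("cv" %in% stages) {
    res$cv <- run_stage("cv", {
      sim <- res$simulate
      if (is.null(sim)) stop("cv requires the simulate stage")
      ph <- sim$eos$phenotypes
      folds <- make_folds(rownames(sim$grm),
                          seed = substream_seed(seed, "folds"))
      cvr <- run_st_cv(ph, "yield", folds, sim$grm)
      utils::write.csv(data.frame(fold = seq_along(cvr$accuracy),
                                  accuracy = cvr$accuracy),
                       file.path(out_dir, "cv_st.csv"), row.names = FALSE)
      cvr
    })
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(results = res, manifest = manifest, out_dir = out_dir))
}
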