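# End-to-end orchestration: CTSS extraction -> peak calling ->
# annotation -> projection -> matching -> rescue -> QC, with a single
# config object carrying every threshold at its published default.

#' Pipeline configuration
#'
#' Collects input paths and thresholds. Thresholds default to the
#' published values: MAPQ 20, flag exclusion 768, identity 0.85,
#' permissive minimum 3, robust minimum 10 counts and 1 TPM, 1 kb
#' association window (half-width 500), TATA scan window (-500, 200),
#' 50 bp match distance, 10 kb rescue distance.
#'
#' @param ctss_beds Named character vector of per-sample CTSS BED paths
#'   (names = sample ids); alternative to `sam_files`.
#' @param sam_files Named character vector of per-sample SAM paths.
#' @param gene_model_files Named character vector (names = source set
#'   labels) of destination BED12 paths.
#' @param rescue_model_files Optional extra BED12 paths whose models are
#'   used for rescue distances (e.g. predicted ORF models), named by
#'   set label.
#' @param chain_file Source-to-destination chain path.
#' @param source_peaks_file BED6 of source (reference species) peaks.
#' @param source_expression_file TSV expression matrix of source peaks.
#' @param source_model_files Named character vector of source BED12
#'   paths (first entry is the annotation used for rescue by default).
#' @param orthology_file Two-column TSV source_gene TAB dest_gene.
#' @param matching_samples Columns of the source expression matrix
#'   matching the profiled cell types.
#' @param genome_file Optional destination FASTA (TATA/CpG analyses).
#' @param pwm_file Optional TATA PWM path.
#' @param cpg_file Optional CpG island BED (detected from `genome_file`
#'   when absent).
#' @param min_mapq,exclude_flags,min_identity CTSS extraction filters.
#' @param max_gap,smooth_sd,valley_fraction,min_subpeak_gap Clustering
#'   and decomposition parameters.
#' @param permissive_min,robust_min,robust_tpm Peak tier thresholds.
#' @param assoc_window Association window half-width (bp).
#' @param tata_window TATA scan window, `c(-500, 200)`.
#' @param match_dist Projection boundary match distance (bp).
#' @param min_match Minimum mapped fraction for projection.
#' @param rescue_dist Maximum peak-to-ortholog-gene distance (bp).
#' @param min_tpm_expressed Source expression filter threshold.
#' @param mds_top_n,mds_dims MDS parameters.
#' @param seed Seed recorded in the run report.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(ctss_beds = NULL, sam_files = NULL,
                            gene_model_files = character(),
                            rescue_model_files = character(),
                            chain_file = NULL,
                            source_peaks_file = NULL,
                            source_expression_file = NULL,
                            source_model_files = character(),
                            orthology_file = NULL,
                            matching_samples = character(),
                            genome_file = NULL, pwm_file = NULL,
                            cpg_file = NULL,
                            min_mapq = 20, exclude_flags = 768L,
                            min_identity = 0.85,
                            max_gap = 20, smooth_sd = 5,
                            valley_fraction = 0.1, min_subpeak_gap = 10,
                            permissive_min = 3, robust_min = 10,
                            robust_tpm = 1.0, assoc_window = 500,
                            tata_window = c(-500, 200), match_dist = 50,
                            min_match = 0.95, rescue_dist = 10000,
                            min_tpm_expressed = 1,
                            mds_top_n = 500, mds_dims = 2, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$ctss_beds) && is.null(cfg$sam_files)) {
    stop("need ctss_beds or sam_files", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (round-trips via JSON)
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `path` invisibly (write) or the restored config (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- lapply(unclass(config), function(v) {
    if (is.character(v) && !is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  devec <- function(v) {
    if (is.list(v)) {
      if (length(v) == 0L) character(0) else unlist(v)
    } else v
  }
  vec_fields <- c("ctss_beds", "sam_files", "gene_model_files",
                  "rescue_model_files", "source_model_files",
                  "matching_samples")
  for (nm in vec_fields) if (nm %in% names(raw)) {
    raw[[nm]] <- devec(raw[[nm]])
  }
  cfg <- pipeline_config(ctss_beds = raw$ctss_beds,
                         sam_files = raw$sam_files)
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Stages run in order: CTSS -> peaks -> annotate -> project -> match ->
#' rescue -> QC. Optional inputs switch their stages off (annotation
#' requires gene models; projection requires a chain plus the source
#' peak set; QC requires >= 2 samples). A rerun with the same config is
#' bit-identical: no stage draws random numbers.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for tab-separated result files.
#' @return List with `libraries`, `peaks` (all tiers), `robust_peaks`,
#'   `expression` (counts + tpm), `associations`, `breakdown`,
#'   `projections`, `matches`, `rescued`, `qc` (factors, spearman, mds,
#'   fraction in peaks) and `report` (stage counts + parameters).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  # ---- CTSS ------------------------------------------------------------
  libraries <- .stage("ctss", {
    if (!is.null(config$ctss_beds)) {
      lapply(names(config$ctss_beds), function(sid) {
        sample_library(sid, read_ctss_bed(config$ctss_beds[[sid]]))
      })
    } else {
      lapply(names(config$sam_files), function(sid) {
        prof <- extract_ctss_from_alignments(
          read_sam(config$sam_files[[sid]]),
          min_mapq = config$min_mapq,
          exclude_flags = config$exclude_flags,
          min_identity = config$min_identity)
        sample_library(sid, prof)
      })
    }
  })
  # ---- peaks -----------------------------------------------------------
  peaks <- .stage("peaks", identify_peaks(
    libraries, max_gap = config$max_gap, smooth_sd = config$smooth_sd,
    valley_fraction = config$valley_fraction,
    min_subpeak_gap = config$min_subpeak_gap,
    permissive_min = config$permissive_min,
    robust_min = config$robust_min, robust_tpm = config$robust_tpm))
  robust <- peaks[peaks$tier == "robust", ]
  expression <- .stage("quantify", quantify_peak_expression(robust,
                                                            libraries))
  frac_in_peaks <- fraction_tags_in_peaks(libraries, robust)

  # ---- annotation ------------------------------------------------------
  models <- NULL; associations <- NULL; breakdown <- NULL
  if (length(config$gene_model_files)) {
    models <- .stage("annotate", rbindlist(lapply(
      names(config$gene_model_files), function(set) {
        read_gene_models(config$gene_model_files[[set]], set)
      })))
    associations <- .stage("annotate", associate_peaks_to_genes(
      robust, models, window_half = config$assoc_window))
    breakdown <- annotation_breakdown(associations, robust,
                                      names(config$gene_model_files))
  }

  # ---- projection + matching + rescue ----------------------------------
  projections <- NULL; matches <- NULL; rescued <- NULL
  if (!is.null(config$chain_file) && !is.null(config$source_peaks_file)) {
    chains <- .stage("project", parse_chain_file(config$chain_file))
    src_peaks <- .stage("project", read_bed(config$source_peaks_file))
    if (!is.null(config$source_expression_file) &&
        length(config$matching_samples)) {
      expr <- read_expression_matrix(config$source_expression_file)
      src_peaks <- .stage("project", filter_expressed(
        src_peaks, expr, config$matching_samples,
        min_tpm = config$min_tpm_expressed))
    }
    projections <- .stage("project", project_intervals(
      src_peaks, chains, min_match = config$min_match))
    matches <- .stage("match", match_projected_peaks(
      projections, robust, max_dist = config$match_dist))
    if (!is.null(config$orthology_file) &&
        length(config$source_model_files) && !is.null(associations)) {
      src_models <- .stage("rescue", rbindlist(lapply(
        names(config$source_model_files), function(set) {
          read_gene_models(config$source_model_files[[set]], set)
        })))
      src_assoc <- .stage("rescue", associate_peaks_to_genes(
        src_peaks, src_models, window_half = config$assoc_window))
      orthology <- read_orthology(config$orthology_file)
      rescue_models <- models
      if (length(config$rescue_model_files)) {
        extra <- rbindlist(lapply(names(config$rescue_model_files),
                                  function(set) {
          read_gene_models(config$rescue_model_files[[set]], set)
        }))
        rescue_models <- rbind(models, extra)
      }
      rescued <- .stage("rescue", rescue_unannotated_peaks(
        robust, associations, matches, src_assoc, orthology,
        rescue_models, max_gene_dist = config$rescue_dist))
    }
  }

  # ---- QC --------------------------------------------------------------
  qc <- NULL
  if (length(libraries) >= 2L && nrow(robust) >= 2L) {
    qc <- .stage("qc", {
      factors <- tmm_factors(expression$counts)
      norm <- normalize_tmm(expression$counts, factors)
      sp <- spearman_matrix(expression$counts)
      mds <- if (length(libraries) > config$mds_dims) {
        mds_coordinates(norm, top_n = config$mds_top_n,
                        dims = config$mds_dims)
      } else NULL
      list(tmm_factors = factors, spearman = sp, mds = mds,
           fraction_in_peaks = frac_in_peaks)
    })
  }

  report <- list(
    n_samples = length(libraries),
    total_tags = vapply(libraries, `[[`, numeric(1), "total_tags"),
    n_peaks_permissive = nrow(peaks),
    n_peaks_robust = nrow(robust),
    breakdown = breakdown,
    n_source_peaks_projected = if (is.null(projections)) NA_integer_ else
      sum(projections$status == "mapped"),
    n_matches = if (is.null(matches)) NA_integer_ else
      sum(!is.na(matches$dest_peak)),
    n_rescued = if (is.null(rescued)) NA_integer_ else
      length(unique(rescued$dest_peak)),
    fraction_in_peaks = frac_in_peaks,
    parameters = unclass(config)[!grepl(
      "_files?$|_beds$|^sam_files$", names(config))])

  result <- list(libraries = libraries, peaks = peaks,
                 robust_peaks = robust, expression = expression,
                 associations = associations, breakdown = breakdown,
                 projections = projections, matches = matches,
                 rescued = rescued, qc = qc, report = report)
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  result
}

#' Write pipeline result tables to a directory
#'
#' Every file starts with a provenance comment naming the package
#' version and key parameters.
#'
#' @param result Output of [run_pipeline()].
#' @param config The [pipeline_config()] used.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  version <- as.character(utils::packageVersion("cagescape"))
  prov <- sprintf(paste0("# cagescape %s | permissive_min=%s robust_min=%s ",
                         "robust_tpm=%s assoc_window=%s match_dist=%s ",
                         "rescue_dist=%s seed=%s"),
                  version, config$permissive_min, config$robust_min,
                  config$robust_tpm, config$assoc_window,
                  config$match_dist, config$rescue_dist, config$seed)
  dump_tsv <- function(x, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(prov, con)
    utils::write.table(x, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  dump_tsv(result$peaks, "peaks.tsv")
  m <- result$expression$counts
  dump_tsv(data.frame(peak = rownames(m), m, check.names = FALSE),
           "peak_counts.tsv")
  m <- result$expression$tpm
  dump_tsv(data.frame(peak = rownames(m), m, check.names = FALSE),
           "peak_tpm.tsv")
  if (!is.null(result$associations)) {
    dump_tsv(result$associations, "associations.tsv")
  }
  if (!is.null(result$matches)) dump_tsv(result$matches, "matches.tsv")
  if (!is.null(result$rescued)) dump_tsv(result$rescued, "rescued.tsv")
  if (!is.null(result$qc)) {
    sp <- result$qc$spearman
    dump_tsv(data.frame(sample = rownames(sp), sp, check.names = FALSE),
             "spearman.tsv")
    f <- result$qc$tmm_factors
    dump_tsv(data.frame(sample = names(f), factor = unname(f)),
             "tmm_factors.tsv")
    if (!is.null(result$qc$mds)) {
      co <- result$qc$mds$coords
      dump_tsv(data.frame(sample = rownames(co), co, check.names = FALSE),
               "mds.tsv")
    }
  }
  report <- result$report
  report$total_tags <- as.list(report$total_tags)
  report$fraction_in_peaks <- as.list(report$fraction_in_peaks)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
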