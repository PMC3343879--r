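# Pipeline orchestration: filter -> allele scan -> residue scan/omnibus ->
# stepwise -> haplotypes -> deletion -> compound genotype -> heterogeneity,
# with per-stage logging, diffable TSV outputs and a JSON run manifest.

#' Build and validate a pipeline run configuration
#'
#' Collects input paths/objects and analysis settings; every referenced
#' path must exist at validation time and all thresholds lie in (0, 1).
#' A YAML file with the same keys can be loaded via `read_run_config()`.
#'
#' @param cohort A [cohort_table()] or path to a cohort file.
#' @param out_dir Output directory (created if absent).
#' @param alignment A `protein_alignment` or path (default: packaged).
#' @param deletion_map A `deletion_map` or path (default: packaged).
#' @param loci Loci to analyse.
#' @param maf_threshold Control-frequency filter threshold.
#' @param n_pcs Number of ancestry PCs to adjust for (default: all).
#' @param stepwise_threshold Entry threshold for stepwise selection.
#' @param haplotype_loci Locus set for the haplotype stage.
#' @param stages Stages to run, in order; any subset of
#'   `"scan"`, `"residues"`, `"stepwise"`, `"haplotypes"`, `"deletion"`,
#'   `"compound"`, `"heterogeneity"`.
#' @param seed Seed for the seeded stages (EM restarts).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort, out_dir,
                       alignment = NULL, deletion_map = NULL,
                       loci = NULL, maf_threshold = 0.01, n_pcs = NULL,
                       stepwise_threshold = STEPWISE_THRESHOLDS[["class1_class2_alleles"]],
                       haplotype_loci = c("B", "C"),
                       stages = c("scan", "residues", "stepwise",
                                  "haplotypes", "deletion", "compound",
                                  "heterogeneity"),
                       seed = 17L) {
  if (is.character(cohort)) {
    if (!file.exists(cohort)) stop_fm("cohort file not found: ", cohort)
    cohort <- read_cohort(cohort)
  }
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.character(alignment)) {
    if (!file.exists(alignment)) {
      stop_fm("alignment file not found: ", alignment)
    }
    alignment <- read_alignment(alignment)
  }
  if (is.null(alignment)) alignment <- read_alignment()
  if (is.character(deletion_map)) {
    if (!file.exists(deletion_map)) {
      stop_fm("deletion map file not found: ", deletion_map)
    }
    deletion_map <- read_deletion_map(deletion_map)
  }
  if (is.null(deletion_map)) deletion_map <- read_deletion_map()
  if (!(maf_threshold > 0 && maf_threshold < 0.5)) {
    stop_fm("maf_threshold must be in (0, 0.5)")
  }
  if (!(stepwise_threshold > 0 && stepwise_threshold < 1)) {
    stop_fm("stepwise_threshold must be in (0, 1)")
  }
  known <- c("scan", "residues", "stepwise", "haplotypes", "deletion",
             "compound", "heterogeneity")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_fm("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(
    cohort = cohort, out_dir = out_dir, alignment = alignment,
    deletion_map = deletion_map, loci = loci %||% cohort$loci,
    maf_threshold = maf_threshold, n_pcs = n_pcs,
    stepwise_threshold = stepwise_threshold,
    haplotype_loci = haplotype_loci, stages = stages, seed = seed
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML keys mirror the [run_config()] arguments (`cohort`,
#' `alignment` and `deletion_map` as paths).
#'
#' @param path Path to the YAML config.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fm("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full fine-mapping pipeline
#'
#' Executes the configured stages in order with per-stage logging, writes
#' one TSV per stage plus a JSON manifest (`manifest.json`) recording the
#' package version, seed, configuration hash and subject/exclusion
#' accounting. Identical configuration and input produce identical
#' outputs. A stage failure aborts the run naming the stage; outputs of
#' completed stages are retained and the manifest flags the run partial.
#'
#' @param config A [run_config()].
#' @return Named list of stage results (also written to `out_dir`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- config$cohort
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  y <- phenotype_vector(cohort)
  covs <- covariate_matrix(cohort, n_pcs = config$n_pcs)
  results <- list()
  manifest <- list(
    package = "hlafinemap",
    version = as.character(utils::packageVersion("hlafinemap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_cases = n_cases(cohort), n_controls = n_controls(cohort),
    loci = config$loci,
    maf_threshold = config$maf_threshold,
    stages = config$stages,
    exclusions = list(),
    status = "running"
  )

  cfg_for_hash <- manifest[c("seed", "loci", "maf_threshold", "stages")]
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(cfg_for_hash, cfg_path, auto_unbox = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    fm_log("stage '", name, "' started")
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <<- paste0("failed at stage '", name, "'")
      write_manifest()
      stop_fm("stage '", name, "' failed: ", conditionMessage(res))
    }
    results[[name]] <<- res
    fm_log("stage '", name, "' done")
    res
  }

  ctrl_freqs <- allele_frequencies(cohort, "controls", loci = config$loci)
  kept <- maf_filter(ctrl_freqs, config$maf_threshold)
  manifest$n_candidate_alleles <- length(kept)
  dosages <- allele_dosage_matrix(cohort, alleles = kept)

  run_stage("scan", function() {
    res <- assoc_scan(y, dosages, covariates = covs)
    case_freqs <- allele_frequencies(cohort, "cases", loci = config$loci)
    res$freq_cases <- case_freqs$freq[match(res$term, case_freqs$allele)]
    res$freq_controls <- ctrl_freqs$freq[match(res$term, ctrl_freqs$allele)]
    write_assoc_tsv(res, file.path(config$out_dir, "alleles_scan.tsv"))
    res
  })

  residue_mat <- NULL
  run_stage("residues", function() {
    residue_mat <<- expand_residues(cohort, config$alignment,
                                    loci = intersect(config$loci,
                                                     names(config$alignment)),
                                    min_control_freq = config$maf_threshold)
    res <- assoc_scan(y, residue_mat$dosage, covariates = covs)
    write_assoc_tsv(res, file.path(config$out_dir, "residues_scan.tsv"))
    # omnibus per multi-residue position
    keycols <- residue_mat$columns
    keys <- unique(keycols[, c("locus", "position")])
    omni <- lapply(seq_len(nrow(keys)), function(i) {
      ids <- keycols$id[keycols$locus == keys$locus[i] &
                          keycols$position == keys$position[i]]
      if (length(ids) < 2) return(NULL)
      ot <- tryCatch(
        omnibus_position_test(y, residue_mat$dosage[, ids, drop = FALSE],
                              covariates = covs),
        error = function(e) NULL
      )
      if (is.null(ot)) return(NULL)
      data.frame(locus = keys$locus[i], position = keys$position[i],
                 p = ot$p, df = ot$df, stat = ot$stat,
                 stringsAsFactors = FALSE)
    })
    omni <- do.call(rbind, omni)
    if (!is.null(omni)) {
      omni <- omni[order(omni$p), , drop = FALSE]
      utils::write.table(omni, file.path(config$out_dir, "omnibus.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(scan = res, omnibus = omni)
  })

  run_stage("stepwise", function() {
    trace <- stepwise_select(y, dosages, covariates = covs,
                             threshold = config$stepwise_threshold)
    write_stepwise_tsv(trace, file.path(config$out_dir, "stepwise.tsv"))
    trace
  })

  run_stage("haplotypes", function() {
    hl <- intersect(config$haplotype_loci, config$loci)
    est_cases <- em_haplotypes(cohort, hl, group = "cases",
                               seed = config$seed)
    est_controls <- em_haplotypes(cohort, hl, group = "controls",
                                  seed = config$seed)
    tab <- write_haplotype_tsv(est_cases, est_controls,
                               file.path(config$out_dir, "haplotypes.tsv"))
    list(cases = est_cases, controls = est_controls, table = tab)
  })

  run_stage("deletion", function() {
    res <- deletion_association(cohort, config$deletion_map,
                                covariates = covs)
    rows <- as.data.frame(res)
    if ("C*06:02" %in% colnames(dosages)) {
      cond <- deletion_association(cohort, config$deletion_map,
                                   covariates = covs,
                                   condition = dosages[, "C*06:02",
                                                       drop = FALSE])
      cond_df <- as.data.frame(cond)
      cond_df$term <- "rs67384697_del|C*06:02"
      rows <- rbind(rows, cond_df)
    }
    write_assoc_tsv(rows, file.path(config$out_dir, "deletion.tsv"))
    rows
  })

  run_stage("compound", function() {
    tab <- compound_genotype_table(cohort, config$alignment)
    utils::write.table(tab, file.path(config$out_dir, "compound.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  run_stage("heterogeneity", function() {
    cohorts <- unique(cohort$subjects$cohort)
    if (length(cohorts) < 2) {
      fm_log("single cohort label; heterogeneity skipped")
      return(NULL)
    }
    top_terms <- utils::head(results$scan$term, 10) %||% colnames(dosages)
    rows <- lapply(top_terms, function(term) {
      per <- lapply(cohorts, function(cl) {
        idx <- cohort$subjects$cohort == cl
        tryCatch(suppressWarnings(
          fit_logistic(y[idx], dosages[idx, term],
                       covariates = if (!is.null(covs)) {
                         covs[idx, , drop = FALSE]
                       },
                       term = term)
        ), error = function(e) NULL)
      })
      per <- Filter(function(r) !is.null(r) && is.finite(r$se) &&
                      !r$unstable, per)
      if (length(per) < 2) return(NULL)
      het <- heterogeneity(vapply(per, `[[`, numeric(1), "beta"),
                           vapply(per, `[[`, numeric(1), "se"),
                           term = term)
      data.frame(term = term, q = het$q, df = het$df, i2 = het$i2,
                 p_q = het$p_q, stringsAsFactors = FALSE)
    })
    het_tab <- do.call(rbind, rows)
    if (!is.null(het_tab)) {
      utils::write.table(het_tab,
                         file.path(config$out_dir, "heterogeneity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    het_tab
  })

  manifest$status <- "complete"
  write_manifest()
  invisible(results)
}

#' Compare association results between two runs
#'
#' Side-by-side odds ratios and p-values for shared terms plus a
#' sign-concordance summary: the fraction of shared terms whose odds
#' ratios fall on the same side of 1 in both runs (the standard display
#' for asking whether two cohorts share the direction of their
#' association architecture).
#'
#' @param run_a,run_b Association data.frames with columns `term`, `or`,
#'   `p` (e.g. from [assoc_scan()]).
#' @param terms Terms to compare (default: union of both).
#' @return List with `table` (per-term comparison), `concordance`
#'   (fraction in \[0, 1\], `NA` when no term is shared), `missing`
#'   (terms absent from either run).
#' @export
compare_runs <- function(run_a, run_b, terms = NULL) {
  stopifnot(all(c("term", "or", "p") %in% names(run_a)),
            all(c("term", "or", "p") %in% names(run_b)))
  if (is.null(terms)) terms <- union(run_a$term, run_b$term)
  ia <- match(terms, run_a$term)
  ib <- match(terms, run_b$term)
  missing <- terms[is.na(ia) | is.na(ib)]
  tab <- data.frame(
    term = terms,
    or_a = run_a$or[ia], p_a = run_a$p[ia],
    or_b = run_b$or[ib], p_b = run_b$p[ib],
    stringsAsFactors = FALSE
  )
  shared <- !is.na(tab$or_a) & !is.na(tab$or_b)
  concordance <- if (any(shared)) {
    mean(sign(log(tab$or_a[shared])) == sign(log(tab$or_b[shared])))
  } else {
    NA_real_
  }
  list(table = tab, concordance = concordance, missing = missing)
}
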