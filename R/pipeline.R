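#' Read a plain-text key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numbers or logicals when possible, and comma-separated values become
#' vectors.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stopf("malformed config line: '%s'", ln)
    key <- trimws(kv[2])
    val <- trimws(strsplit(kv[3], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!anyNA(num)) num
    else if (all(toupper(val) %in% c("TRUE", "FALSE"))) as.logical(toupper(val))
    else val
    out[[key]] <- parsed
  }
  out
}

#' Run the analysis pipeline
#'
#' Wires the package's stages in dependency order:
#' `simulate -> grm -> fit -> summary -> psi -> cv`. Each requested stage
#' writes its outputs (CSV/JSON) into `out_dir`, and a run-metadata JSON
#' records the seed, stage parameters, timings and package version so a run
#' can be reproduced from its metadata alone.
#'
#' Config keys (flat key=value; see [read_run_config()]): `stages`
#' (comma-separated subset of the above), `out_dir`, `seed`, `force`
#' (overwrite outputs), `genotype_file`/`phenotype_file` (inputs when
#' `simulate` is not among the stages), generator settings (`n_genotypes`,
#' `n_checks`, `n_years`, `n_markers`, `n_qtl`, `h2_target`), model settings
#' (`trait`, `time_points`, `genetic`, `residual`, `tol`, `max_iter`),
#' `min_maf`, `ridge`, `psi_iters`, and CV settings (`cv_folds`,
#' `cv_repeats`, `cv2_known_time`, `cv2_target_time`).
#'
#' @param config Path to a config file, or a named list of the same keys.
#' @return Invisibly, a list with the stage results and the metadata path.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config) && length(config) == 1) read_run_config(config)
         else as.list(config)
  stages <- cfg$stages %||% c("simulate", "grm", "fit", "summary", "psi")
  order_all <- c("simulate", "grm", "fit", "summary", "psi", "cv")
  bad <- setdiff(stages, order_all)
  if (length(bad) > 0) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- order_all[order_all %in% stages]
  out_dir <- cfg$out_dir %||% "."
  force <- isTRUE(cfg$force)
  seed <- as.integer(cfg$seed %||% 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outfile <- function(name) {
    fp <- file.path(out_dir, name)
    if (file.exists(fp) && !force) {
      stopf("output %s exists; set force = TRUE to overwrite", fp)
    }
    fp
  }
  timings <- list()
  res <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }

  trait <- cfg$trait %||% "firmness"
  times <- cfg$time_points %||% TIME_LEVELS

  # inputs: simulate, or read from files
  if ("simulate" %in% stages) {
    sim_cfg <- simulation_config(
      n_genotypes = cfg$n_genotypes %||% 588L,
      n_checks = cfg$n_checks %||% 16L,
      n_years = cfg$n_years %||% 3L,
      n_markers = cfg$n_markers %||% 2000L,
      n_qtl = cfg$n_qtl %||% 200L,
      h2_target = cfg$h2_target %||% 0.5,
      time_points = times, trait = trait, seed = seed
    )
    res$sim <- tick("simulate", {
      dos <- simulate_dosages(sim_cfg)
      ph <- simulate_phenotypes(dos, sim_cfg)
      write_dosage_matrix(dos, outfile("genotypes.csv"))
      write_phenotypes(ph$pheno, outfile("phenotypes.csv"))
      jsonlite::write_json(
        list(realized_h2 = ph$truth$realized_h2,
             realized_genetic_corr = ph$truth$realized_genetic_corr,
             year_effects = ph$truth$year_effects),
        outfile("truth.json"), auto_unbox = TRUE, digits = NA)
      list(dosages = dos, pheno = ph$pheno, truth = ph$truth)
    })
    dosages <- res$sim$dosages
    pheno <- res$sim$pheno
  } else {
    dosages <- if (!is.null(cfg$genotype_file)) {
      read_dosage_matrix(cfg$genotype_file, ploidy = cfg$ploidy %||% 4L)
    } else NULL
    pheno <- if (!is.null(cfg$phenotype_file)) {
      read_phenotypes(cfg$phenotype_file)
    } else NULL
  }

  grm <- NULL
  if ("grm" %in% stages) {
    if (is.null(dosages)) stopf("grm stage requires a genotype file or the simulate stage")
    grm <- tick("grm", {
      g <- vanraden_grm(dosages, min_maf = cfg$min_maf %||% 0,
                        ridge = cfg$ridge %||% 1e-6)
      write_square_matrix(g, outfile("grm.csv"))
      g
    })
    res$grm <- grm
  }

  fit <- NULL
  spec <- model_spec(trait, times,
                     genetic = cfg$genetic %||% "us",
                     residual = cfg$residual %||% "us")
  if ("fit" %in% stages || "summary" %in% stages || "psi" %in% stages) {
    if (is.null(pheno) || is.null(grm)) {
      stopf("fit stage requires phenotypes and a relationship matrix")
    }
    fit <- tick("fit", fit_longitudinal(pheno, grm, spec,
                                        tol = cfg$tol %||% 1e-8,
                                        max_iter = cfg$max_iter %||% 200L))
    res$fit <- fit
    utils::write.csv(data.frame(genotype_id = rownames(fit$blups), fit$blups,
                                check.names = FALSE),
                     outfile("blups.csv"), row.names = FALSE)
    write_square_matrix(fit$components$sigma_t, outfile("sigma_t.csv"))
    write_square_matrix(fit$components$sigma_e, outfile("sigma_e.csv"))
  }

  if ("summary" %in% stages) {
    res$summary <- tick("summary", {
      gp <- genetic_parameter_table(pheno, grm, spec,
                                    psi_iter = cfg$psi_iters %||% 1e5,
                                    seed = seed)
      utils::write.csv(gp$table, outfile("genetic_parameters.csv"),
                       row.names = FALSE)
      gp$table
    })
  }

  if ("psi" %in% stages && length(times) >= 2) {
    res$psi <- tick("psi", {
      rand_blups <- fit$blups[fit$rand_ids, , drop = FALSE]
      pairs <- utils::combn(times, 2)
      rows <- lapply(seq_len(ncol(pairs)), function(i) {
        mc <- psi_monte_carlo(rand_blups, pairs[1, i], pairs[2, i],
                              n_iter = cfg$psi_iters %||% 1e5, seed = seed)
        data.frame(time_i = pairs[1, i], time_j = pairs[2, i], psi = mc$psi,
                   stringsAsFactors = FALSE)
      })
      psi_df <- do.call(rbind, rows)
      utils::write.csv(psi_df, outfile("psi.csv"), row.names = FALSE)
      psi_df
    })
  }

  if ("cv" %in% stages) {
    res$cv <- tick("cv", {
      cv1 <- run_cv1(pheno, grm, spec, k = cfg$cv_folds %||% 10L,
                     n_repeats = cfg$cv_repeats %||% 10L, seed = seed)
      out <- data.frame(scheme = "CV1", time_point = names(cv1$pa_mean),
                        pa = as.numeric(cv1$pa_mean), stringsAsFactors = FALSE)
      if (!is.null(cfg$cv2_known_time)) {
        cv2 <- run_cv2(pheno, grm, spec,
                       known_time = cfg$cv2_known_time,
                       target_time = cfg$cv2_target_time %||% times[length(times)],
                       k = cfg$cv_folds %||% 10L,
                       n_repeats = cfg$cv_repeats %||% 10L, seed = seed)
        out <- rbind(out, data.frame(scheme = "CV2",
                                     time_point = cv2$target_time,
                                     pa = cv2$pa_mean, stringsAsFactors = FALSE))
      }
      utils::write.csv(out, outfile("prediction_ability.csv"), row.names = FALSE)
      out
    })
  }

  meta <- list(stages = stages, seed = seed, trait = trait,
               time_points = times,
               config = cfg[setdiff(names(cfg), c("stages"))],
               timings_sec = timings)
  write_run_metadata(meta, file.path(out_dir, "run_metadata.json"))
  invisible(c(res, list(metadata = file.path(out_dir, "run_metadata.json"))))
}
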