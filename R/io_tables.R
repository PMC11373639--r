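#' Construct a validated allele-dosage matrix
#'
#' A `dosage_matrix` holds integer allele dosages for a set of genotypes at a
#' set of markers. Dosages count copies of the alternate allele and range from
#' 0 to the ploidy (0..4 for an autotetraploid). Missing calls are `NA`.
#'
#' @param dosages Integer matrix, genotypes in rows, markers in columns.
#'   Dimnames are used as genotype/marker ids when `genotype_ids`/`marker_ids`
#'   are not given.
#' @param genotype_ids Character vector of unique genotype identifiers.
#' @param marker_ids Character vector of unique marker identifiers.
#' @param ploidy Positive even integer; 4 for autotetraploids (default).
#' @return An object of class `dosage_matrix`: the integer matrix with
#'   `ploidy` attribute and row/column names set.
#' @examples
#' m <- matrix(c(0L, 2L, 4L, 1L, 3L, 2L), nrow = 3)
#' dm <- dosage_matrix(m, genotype_ids = c("g1", "g2", "g3"),
#'                     marker_ids = c("m1", "m2"))
#' @export
dosage_matrix <- function(dosages, genotype_ids = rownames(dosages),
                          marker_ids = colnames(dosages), ploidy = 4L) {
  if (!is.matrix(dosages)) stopf("dosages must be a matrix")
  ploidy <- as.integer(ploidy)
  if (length(ploidy) != 1L || is.na(ploidy) || ploidy <= 0L || ploidy %% 2L != 0L) {
    stopf("ploidy must be a positive even integer")
  }
  if (is.null(genotype_ids)) genotype_ids <- paste0("G", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(dosages)))
  genotype_ids <- as.character(genotype_ids)
  marker_ids <- as.character(marker_ids)
  if (length(genotype_ids) != nrow(dosages)) {
    stopf("genotype_ids length (%d) does not match row count (%d)",
          length(genotype_ids), nrow(dosages))
  }
  if (length(marker_ids) != ncol(dosages)) {
    stopf("marker_ids length (%d) does not match column count (%d)",
          length(marker_ids), ncol(dosages))
  }
  if (anyDuplicated(genotype_ids)) {
    stopf("duplicate genotype ids: %s",
          paste(unique(genotype_ids[duplicated(genotype_ids)]), collapse = ", "))
  }
  if (anyDuplicated(marker_ids)) {
    stopf("duplicate marker ids: %s",
          paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  }
  storage.mode(dosages) <- "integer"
  bad <- which(!is.na(dosages) & (dosages < 0L | dosages > ploidy), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("dosage outside [0, %d] at genotype '%s', marker '%s' (value %d)",
          ploidy, genotype_ids[bad[1, 1]], marker_ids[bad[1, 2]],
          dosages[bad[1, 1], bad[1, 2]])
  }
  dimnames(dosages) <- list(genotype_ids, marker_ids)
  attr(dosages, "ploidy") <- ploidy
  class(dosages) <- c("dosage_matrix", class(dosages))
  dosages
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d genotypes x %d markers, ploidy %d, %.2f%% missing\n",
              nrow(x), ncol(x), attr(x, "ploidy"),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Read an allele-dosage matrix from delimited text
#'
#' Expects a header row of marker ids and a first column of genotype ids;
#' remaining cells are integer dosages in `[0, ploidy]`. Empty cells and "NA"
#' are read as missing; they are flagged, never imputed at this stage.
#'
#' @param path Path to a CSV (or TSV, see `sep`) file.
#' @param ploidy Ploidy level, default 4.
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @return A [dosage_matrix()].
#' @export
read_dosage_matrix <- function(path, ploidy = 4L, sep = ",") {
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          colClasses = "character")
  if (ncol(df) < 2) stopf("dosage file must have a genotype-id column plus >=1 marker column")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  nonint <- which(!is.na(num) & num != round(num), arr.ind = TRUE)
  if (nrow(nonint) > 0) {
    stopf("non-integer dosage at genotype '%s', marker '%s'",
          ids[nonint[1, 1]], colnames(vals)[nonint[1, 2]])
  }
  bad_parse <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad_parse) > 0) {
    stopf("unparseable dosage '%s' at genotype '%s', marker '%s'",
          vals[bad_parse[1, 1], bad_parse[1, 2]],
          ids[bad_parse[1, 1]], colnames(vals)[bad_parse[1, 2]])
  }
  dosage_matrix(num, genotype_ids = ids, marker_ids = colnames(vals),
                ploidy = ploidy)
}

#' Write an allele-dosage matrix to delimited text
#'
#' @param x A [dosage_matrix()].
#' @param path Output file path.
#' @param sep Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(x, path, sep = ",") {
  df <- data.frame(genotype_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

PHENO_COLUMNS <- c("genotype_id", "year", "time_point", "trait", "value",
                   "is_check", "rep")

#' Construct a validated long-format phenotype table
#'
#' Repeated-measures phenotype records: one row per genotype, year, postharvest
#' time point, trait and technical rep. The key
#' (genotype, year, time_point, trait, rep) must be unique; time points are
#' ordered `1D < 1W < 3W < 7W`.
#'
#' @param df A data frame with columns `genotype_id`, `year`, `time_point`,
#'   `trait`, `value`, `is_check`, `rep`.
#' @return A data frame of class `phenotype_table` with typed columns.
#' @export
phenotype_table <- function(df) {
  missing_cols <- setdiff(PHENO_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stopf("phenotype table missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    genotype_id = as.character(df$genotype_id),
    year = as.integer(df$year),
    time_point = as_time_point(df$time_point),
    trait = as.character(df$trait),
    value = as.numeric(df$value),
    is_check = as.logical(df$is_check),
    rep = as.integer(df$rep),
    stringsAsFactors = FALSE
  )
  key <- paste(out$genotype_id, out$year, out$time_point, out$trait, out$rep,
               sep = "\r")
  if (anyDuplicated(key)) {
    first <- out[which(duplicated(key))[1], ]
    stopf("duplicate phenotype record for genotype '%s', year %d, time %s, trait '%s', rep %d",
          first$genotype_id, first$year, as.character(first$time_point),
          first$trait, first$rep)
  }
  if (any(is.na(out$is_check))) stopf("is_check must be TRUE/FALSE with no missing values")
  # in multi-year data every check must connect more than one year
  years <- unique(out$year)
  if (length(years) > 1) {
    chk <- unique(out$genotype_id[out$is_check])
    for (g in chk) {
      ny <- length(unique(out$year[out$genotype_id == g]))
      if (ny < 2) {
        stopf("check genotype '%s' appears in a single year; checks must connect years", g)
      }
    }
  }
  out <- out[order(out$trait, out$genotype_id, out$year, out$time_point, out$rep), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read a long-format phenotype table from delimited text
#'
#' The file must contain the seven canonical columns (`genotype_id`, `year`,
#' `time_point`, `trait`, `value`, `is_check`, `rep`), but arbitrary source
#' column names can be adapted through `col_map` since supplementary
#' spreadsheet exports rarely agree on naming.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @param col_map Named character vector mapping canonical names to the file's
#'   column names, e.g. `c(genotype_id = "ID", value = "firmness")`. Unmapped
#'   canonical names are looked up verbatim.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, sep = ",", col_map = NULL) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  wanted <- stats::setNames(PHENO_COLUMNS, PHENO_COLUMNS)
  if (!is.null(col_map)) {
    unknown <- setdiff(names(col_map), PHENO_COLUMNS)
    if (length(unknown) > 0) {
      stopf("col_map names must be canonical columns; unknown: %s",
            paste(unknown, collapse = ", "))
    }
    wanted[names(col_map)] <- col_map
  }
  missing_cols <- setdiff(unname(wanted), names(df))
  if (length(missing_cols) > 0) {
    stopf("phenotype file missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  out <- df[, unname(wanted), drop = FALSE]
  names(out) <- names(wanted)
  phenotype_table(out)
}

#' Write a phenotype table to delimited text
#'
#' @param x A [phenotype_table()].
#' @param path Output file path.
#' @param sep Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path, sep = ",") {
  df <- as.data.frame(x)
  df$time_point <- as.character(df$time_point)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a square matrix with id headers (e.g. a relationship matrix) to CSV
#'
#' @param m Matrix with row/column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write run metadata (seeds, tolerances, versions) as JSON
#'
#' @param meta Named list of run metadata.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  meta$package_version <- as.character(utils::packageVersion("blupberry"))
  meta$r_version <- R.version.string
  meta$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
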