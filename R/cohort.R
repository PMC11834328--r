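# Cohort table: one row per eye, 63 LAYER_SECTOR thickness columns.

cohort_meta_cols <- function() c("subject_id", "eye", "group", "age")

#' Construct and validate a cohort table
#'
#' A cohort table is a data.frame with one row per eye and columns
#' `subject_id`, `eye` (`OD`/`OS`), `group` (`HC`/`DWOR`), `age` (years) and
#' the 63 `LAYER_SECTOR` thickness columns (micrometres) for the seven
#' primary layers in the nine ETDRS sectors. Extra columns are tolerated and
#' preserved.
#'
#' @param df data.frame in the layout above.
#' @return The validated data.frame with class `cohort_table` prepended.
#' @export
as_cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_meta <- setdiff(cohort_meta_cols(), names(df))
  if (length(missing_meta) > 0L) {
    stop("cohort schema error: missing column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  missing_nodes <- setdiff(node_labels(), names(df))
  if (length(missing_nodes) > 0L) {
    stop("cohort schema error: missing thickness column(s): ",
         paste(missing_nodes, collapse = ", "))
  }
  bad_group <- setdiff(unique(as.character(df$group)), cohort_groups())
  if (length(bad_group) > 0L) {
    stop("cohort validation error: unknown group label(s): ",
         paste(bad_group, collapse = ", "))
  }
  bad_eye <- setdiff(unique(as.character(df$eye)), c("OD", "OS"))
  if (length(bad_eye) > 0L) {
    stop("cohort validation error: unknown eye label(s): ",
         paste(bad_eye, collapse = ", "))
  }
  if (!is.numeric(df$age) || anyNA(df$age) || any(df$age <= 0)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$age))) |
                   suppressWarnings(as.numeric(df$age)) <= 0)
    stop("cohort validation error: non-positive or non-numeric age at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  for (col in node_labels()) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop("cohort validation error: non-numeric thickness in column ", col)
    }
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0L) {
      stop("cohort validation error: non-positive/non-finite thickness in ",
           col, " at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  df$subject_id <- as.character(df$subject_id)
  df$eye <- as.character(df$eye)
  df$group <- as.character(df$group)
  df$age <- as.double(df$age)
  for (col in node_labels()) df[[col]] <- as.double(df[[col]])
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Read a cohort file
#'
#' Reads a delimited text file (CSV or TSV; UTF-8; one row per eye) into a
#' validated cohort table. Column names follow the `LAYER_SECTOR` convention;
#' `header_map` lets other dialects be renamed on the way in, as a named
#' character vector `c(file_name = "canonical_name")`.
#'
#' @param path path to the file.
#' @param sep field separator; `NULL` (default) picks `"\t"` for `.tsv`
#'   files and `","` otherwise.
#' @param header_map optional named character vector renaming file columns
#'   to canonical names.
#' @return A `cohort_table`.
#' @export
load_cohort <- function(path, sep = NULL, header_map = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!is.null(header_map)) {
    idx <- match(names(df), names(header_map))
    names(df)[!is.na(idx)] <- header_map[idx[!is.na(idx)]]
  }
  as_cohort_table(df)
}

#' Write a cohort file
#'
#' Writes the cohort table as delimited text, losslessly (thickness at full
#' double precision) so that a save/load round trip reproduces every field.
#'
#' @param cohort a `cohort_table`.
#' @param path output path; `.tsv` extension selects tab separation.
#' @export
save_cohort <- function(cohort, path) {
  cohort <- as_cohort_table(cohort)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  num <- vapply(cohort, is.numeric, logical(1L))
  out <- as.data.frame(cohort)
  for (col in names(out)[num]) {
    out[[col]] <- formatC(out[[col]], format = "g", digits = 17)
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-eye ring average of a layer
#'
#' Arithmetic mean of the four inner-ring (1--3 mm, `Avg_I`) or four
#' outer-ring (3--6 mm, `Avg_O`) sector thicknesses of one layer. The
#' central subfield is a single sector, not an average, and is rejected.
#'
#' @param cohort a `cohort_table` (or any data.frame with the thickness
#'   columns).
#' @param layer a primary or composite layer code; composites are expanded
#'   with `scheme`.
#' @param ring `"inner"` or `"outer"`.
#' @param scheme composite scheme, see [default_composite_scheme()].
#' @return Numeric vector, one value per eye (row), in micrometres.
#' @export
ring_average <- function(cohort, layer, ring,
                         scheme = default_composite_scheme()) {
  if (identical(ring, "central") || identical(ring, "C")) {
    stop("ring_average usage error: the central subfield is a single ",
         "sector, not an average; read the _C column directly")
  }
  ring <- match.arg(ring, c("inner", "outer"))
  sectors <- ring_sectors(ring)
  vals <- vapply(sectors, function(s) layer_sector_values(cohort, layer, s,
                                                          scheme),
                 numeric(nrow(cohort)))
  if (nrow(cohort) == 1L) vals <- matrix(vals, nrow = 1L)
  rowMeans(vals)
}

#' Composite-layer thickness in one sector
#'
#' Sum of the scheme's primary-layer thicknesses in the requested sector.
#'
#' @param cohort a `cohort_table`.
#' @param composite one of `"IR"`, `"OR"`, `"TRT"` (or any key of `scheme`).
#' @param sector an ETDRS sector code.
#' @param scheme named list mapping composites to primary layers.
#' @return Numeric vector, one value per eye.
#' @export
composite_layer <- function(cohort, composite, sector,
                            scheme = default_composite_scheme()) {
  if (!composite %in% names(scheme)) {
    stop("composite scheme config error: no definition for ", composite)
  }
  members <- scheme[[composite]]
  unknown <- setdiff(members, primary_layers())
  if (length(unknown) > 0L) {
    stop("composite scheme config error: unknown primary layer(s): ",
         paste(unknown, collapse = ", "))
  }
  sector <- match.arg(sector, etdrs_sectors())
  cols <- paste(members, sector, sep = "_")
  rowSums(as.matrix(cohort[, cols, drop = FALSE]))
}

# Internal: thickness of (layer, sector) per eye; expands composites.
layer_sector_values <- function(cohort, layer, sector,
                                scheme = default_composite_scheme()) {
  if (layer %in% primary_layers()) {
    cohort[[paste(layer, sector, sep = "_")]]
  } else {
    composite_layer(cohort, layer, sector, scheme)
  }
}

#' Thickness of a layer in a named region
#'
#' Resolves a region that is either one of the nine sectors or a derived
#' ring average (`"Avg_I"`, `"Avg_O"`).
#'
#' @inheritParams ring_average
#' @param region a sector code, `"Avg_I"` or `"Avg_O"`.
#' @return Numeric vector, one value per eye.
#' @export
region_values <- function(cohort, layer, region,
                          scheme = default_composite_scheme()) {
  if (region == "Avg_I") {
    ring_average(cohort, layer, "inner", scheme)
  } else if (region == "Avg_O") {
    ring_average(cohort, layer, "outer", scheme)
  } else {
    layer_sector_values(cohort, layer, match.arg(region, etdrs_sectors()),
                        scheme)
  }
}

#' Collapse a cohort to one record per subject
#'
#' Averages the two eyes of each subject (per group) to mitigate the
#' inter-eye dependence of eye-level sampling. Off by default throughout the
#' pipeline; eyes are the sampling unit unless requested otherwise.
#'
#' @param cohort a `cohort_table`.
#' @return A `cohort_table` with one row per (subject, group), eye set to
#'   `"OD"` by convention.
#' @export
average_eyes <- function(cohort) {
  cohort <- as_cohort_table(cohort)
  key <- interaction(cohort$subject_id, cohort$group, drop = TRUE)
  num_cols <- c("age", node_labels())
  agg <- stats::aggregate(cohort[, num_cols], by = list(key = key), FUN = mean)
  first <- !duplicated(key)
  out <- data.frame(subject_id = cohort$subject_id[first],
                    eye = "OD",
                    group = cohort$group[first],
                    stringsAsFactors = FALSE)
  ord <- match(interaction(out$subject_id, out$group, drop = TRUE),
               agg$key)
  out <- cbind(out, agg[ord, num_cols, drop = FALSE])
  rownames(out) <- NULL
  as_cohort_table(out)
}
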